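#' Min-max normalize each gene across samples
#'
#' Rescales every gene (attribute) to `[0, 1]` with
#' `(x - min) / (max - min)`, computed across that gene's samples. Genes with
#' zero range carry no discerning information and are dropped; their ids are
#' recorded in the `"dropped_constant"` attribute of the result.
#'
#' @param dataset An [expression_dataset()].
#' @return A normalized `expr_dataset`; attribute `dropped_constant` lists
#'   removed gene ids.
#' @export
normalize_minmax <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  v <- dataset$values
  rng <- apply(v, 1L, range)
  constant <- rng[1, ] == rng[2, ]
  if (all(constant)) {
    stop("all genes are constant; nothing to normalize", call. = FALSE)
  }
  keep <- which(!constant)
  v <- v[keep, , drop = FALSE]
  v <- (v - rng[1, keep]) / (rng[2, keep] - rng[1, keep])
  out <- expression_dataset(v, labels = dataset$labels)
  attr(out, "dropped_constant") <- rownames(dataset$values)[constant]
  out
}

#' Build a grouped-frequency grid over [0, 1]
#'
#' Partitions `[0, 1]` into `n_intervals` classes of equal width
#' `delta = 1/n_intervals` and tallies the class frequencies `fr_c` and
#' cumulative frequencies `cfr_c` of the supplied values. Interval `c` covers
#' `[l_c, l_c + delta)`; the last interval is closed so a value of exactly 1
#' is counted there.
#'
#' @param values Numeric vector of normalized values in `[0, 1]`.
#' @param n_intervals Number of class intervals (>= 2).
#' @return An object of class `quartile_grid` with fields `lower_limits`,
#'   `delta`, `freq`, `cum_freq` and `n_values`.
#' @export
build_quartile_grid <- function(values, n_intervals = 10L) {
  if (!length(values)) stop("values must be nonempty", call. = FALSE)
  if (n_intervals < 2) stop("n_intervals must be >= 2", call. = FALSE)
  if (any(values < 0 | values > 1)) {
    stop("values outside [0, 1]; normalize first", call. = FALSE)
  }
  delta <- 1 / n_intervals
  idx <- pmin(floor(values / delta) + 1L, n_intervals)
  freq <- tabulate(idx, nbins = n_intervals)
  structure(list(lower_limits = (seq_len(n_intervals) - 1L) * delta,
                 delta = delta,
                 freq = freq,
                 cum_freq = cumsum(freq),
                 n_values = length(values)),
            class = "quartile_grid")
}

#' Interpolated partition value from a grouped-frequency grid
#'
#' Returns the k-th of the three quartile partition values (k = 1, 2, 3 for
#' four partitions) by linear interpolation within the class interval that
#' contains the rank `R_k = k * n / 4`:
#' `l_c + ((R_k - cfr_{c-1}) / fr_c) * delta`,
#' where `c` is the lowest interval with cumulative frequency at least `R_k`
#' (this convention also resolves ranks falling on a boundary shared with an
#' empty class).
#'
#' @param grid A [build_quartile_grid()] result.
#' @param k Which partition value: 1, 2 or 3.
#' @return The partition value, a number in `[l_c, l_c + delta]`.
#' @export
partition_value <- function(grid, k) {
  stopifnot(inherits(grid, "quartile_grid"))
  if (!k %in% 1:3) stop("k must be 1, 2 or 3", call. = FALSE)
  r_k <- k * grid$n_values / 4
  c_idx <- which(grid$cum_freq >= r_k)[1L]
  cfr_prev <- if (c_idx > 1L) grid$cum_freq[c_idx - 1L] else 0
  grid$lower_limits[c_idx] +
    ((r_k - cfr_prev) / grid$freq[c_idx]) * grid$delta
}

#' Discretize a normalized dataset to a ternary table
#'
#' Applies the per-gene thresholding rule: a value `<= Th_i` becomes `0`
#' (low), else a value `>= Th_f` becomes `1` (high), else `*` (don't care).
#' The low branch is tested first, so with `Th_i == Th_f` a boundary value
#' maps to `0`. Don't-cares are stored as `NA` internally.
#'
#' @param dataset A normalized [expression_dataset()].
#' @param th_low,th_high Per-gene thresholds `Th_i` and `Th_f`
#'   (`Th_i <= Th_f`), recycled if scalar.
#' @return An object of class `ternary_table`: integer matrix `symbols`
#'   (0/1/`NA`), thresholds, per-gene `star_counts`, and
#'   `kept_gene_indices` mapping rows to the original gene order.
#' @export
ternarize <- function(dataset, th_low, th_high) {
  stopifnot(inherits(dataset, "expr_dataset"))
  n_genes <- nrow(dataset$values)
  th_low <- rep_len(th_low, n_genes)
  th_high <- rep_len(th_high, n_genes)
  if (any(th_low > th_high)) {
    stop("Th_i must not exceed Th_f for any gene", call. = FALSE)
  }
  v <- dataset$values
  symbols <- matrix(NA_integer_, nrow(v), ncol(v), dimnames = dimnames(v))
  symbols[v <= th_low] <- 0L
  symbols[v > th_low & v >= th_high] <- 1L
  new_ternary_table(symbols, th_low, th_high,
                    kept_gene_indices = seq_len(n_genes))
}

new_ternary_table <- function(symbols, th_low, th_high, kept_gene_indices,
                              log = list()) {
  structure(list(symbols = symbols,
                 th_low = stats::setNames(th_low, rownames(symbols)),
                 th_high = stats::setNames(th_high, rownames(symbols)),
                 star_counts = rowSums(is.na(symbols)),
                 kept_gene_indices = kept_gene_indices,
                 gene_ids = rownames(symbols),
                 sample_ids = colnames(symbols),
                 log = log),
            class = "ternary_table")
}

#' @export
print.ternary_table <- function(x, ...) {
  cat("Ternary expression table:", nrow(x$symbols), "genes x",
      ncol(x$symbols), "samples\n")
  cat("Don't-care ('*') entries:", sum(x$star_counts), "\n")
  if (!is.null(x$log$th_a)) cat("Ambiguity threshold Th_a:", x$log$th_a, "\n")
  invisible(x)
}

#' Remove ambiguously expressed genes
#'
#' Computes the ambiguity threshold `Th_a` as the arithmetic mean of the
#' per-gene don't-care counts and removes every gene whose count is `>= Th_a`
#' (non-strict, following the rule as printed). Single-gene tables are
#' returned unchanged: mean-threshold filtering is vacuous at size 1.
#'
#' @param table A `ternary_table`.
#' @return The filtered `ternary_table`; `log$th_a` records the threshold and
#'   `log$removed_ambiguous` the removed gene ids.
#' @export
filter_ambiguous <- function(table) {
  stopifnot(inherits(table, "ternary_table"))
  if (nrow(table$symbols) == 1L) return(table)
  th_a <- mean(table$star_counts)
  keep <- which(table$star_counts < th_a)
  if (!length(keep)) {
    stop("no gene survives ambiguity filtering (all don't-care counts are ",
         "equal); try a different n_intervals", call. = FALSE)
  }
  log <- table$log
  log$th_a <- th_a
  log$removed_ambiguous <- table$gene_ids[-keep]
  new_ternary_table(table$symbols[keep, , drop = FALSE],
                    table$th_low[keep], table$th_high[keep],
                    kept_gene_indices = table$kept_gene_indices[keep],
                    log = log)
}

#' Full discretization pipeline: normalize, threshold, ternarize, filter
#'
#' Composition of [normalize_minmax()], a per-gene grouped-frequency grid
#' ([build_quartile_grid()]) from which the first and third quartile
#' partition values become `Th_i` and `Th_f`, [ternarize()], and
#' [filter_ambiguous()]. The result is the reduced attribute table handed to
#' [build_distinction_table()].
#'
#' @param dataset An [expression_dataset()] of raw intensities.
#' @param n_intervals Grid resolution for the quartile thresholds
#'   (default 10, i.e. delta = 0.1 on the normalized scale).
#' @return A `ternary_table` whose `kept_gene_indices` refer to the original
#'   dataset gene order and whose `log` records dropped constant genes, the
#'   ambiguity threshold `Th_a` and removed ambiguous genes.
#' @examples
#' sim <- generate_dataset(synthetic_spec(seed = 1))
#' tt <- preprocess_pipeline(sim$dataset)
#' tt
#' @export
preprocess_pipeline <- function(dataset, n_intervals = 10L) {
  norm <- normalize_minmax(dataset)
  orig_idx <- match(rownames(norm$values), rownames(dataset$values))
  th <- vapply(seq_len(nrow(norm$values)), function(i) {
    grid <- build_quartile_grid(norm$values[i, ], n_intervals)
    c(partition_value(grid, 1L), partition_value(grid, 3L))
  }, numeric(2))
  tern <- ternarize(norm, th_low = th[1, ], th_high = th[2, ])
  tern$kept_gene_indices <- orig_idx
  tern$log <- list(n_intervals = n_intervals,
                   dropped_constant = attr(norm, "dropped_constant"))
  filter_ambiguous(tern)
}
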