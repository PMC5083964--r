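#' Construct a distinction table from raw bits
#'
#' Low-level constructor, mainly for examples and small experiments where the
#' 0/1 row content is given directly rather than derived from a ternary
#' table. Rows stand for inter-class sample pairs, columns for features.
#'
#' @param bits 0/1 matrix: rows are object pairs, columns are features.
#' @param class_sizes Optional integer vector of per-class sample counts; if
#'   supplied for two classes, `nrow(bits)` must equal `C1 * C2`.
#' @param gene_ids Feature identifiers (default from column names).
#' @param pairs Optional data frame annotating rows with the two sample ids.
#' @return A `distinction_table`.
#' @export
distinction_table <- function(bits, class_sizes = NULL,
                              gene_ids = colnames(bits), pairs = NULL) {
  bits <- as.matrix(bits)
  if (!all(bits %in% c(0, 1))) {
    stop("distinction-table entries must be 0 or 1", call. = FALSE)
  }
  storage.mode(bits) <- "integer"
  if (is.null(gene_ids)) gene_ids <- paste0("F", seq_len(ncol(bits)))
  colnames(bits) <- gene_ids
  if (!is.null(class_sizes)) {
    expected <- pair_row_count(class_sizes)
    if (nrow(bits) != expected) {
      stop("nrow(bits) = ", nrow(bits), " but class sizes imply ",
           expected, " inter-class pairs", call. = FALSE)
    }
  }
  structure(list(bits = bits,
                 pairs = pairs,
                 n_features = ncol(bits),
                 n_rows = nrow(bits),
                 class_sizes = class_sizes,
                 gene_ids = gene_ids),
            class = "distinction_table")
}

# sum over unordered class pairs of the product of their sizes
pair_row_count <- function(class_sizes) {
  s <- as.numeric(class_sizes)
  (sum(s)^2 - sum(s^2)) / 2
}

#' Build the distinction table over inter-class sample pairs
#'
#' One row per pair of samples drawn from two different classes; the entry
#' for feature `i` is 1 exactly when both samples have definite (non `*`)
#' symbols for that feature and the symbols differ — i.e. the feature can
#' discern the pair. Same-class pairs contribute no rows, so for two classes
#' with sizes `C1` and `C2` the table has `C1 * C2` rows; for more classes,
#' every unordered class pair contributes the product of its sizes. Rows are
#' ordered lexicographically by (class pair, first-sample index,
#' second-sample index) so runs are reproducible. Rows no feature discerns
#' are retained: they cap the coverage objective below 1.
#'
#' @param table A `ternary_table` from [preprocess_pipeline()] or
#'   [ternarize()].
#' @param labels Class label per sample (factor or character), aligned with
#'   the table's sample columns.
#' @return A `distinction_table` with fields `bits`, `pairs`, `n_features`,
#'   `n_rows`, `class_sizes`.
#' @export
build_distinction_table <- function(table, labels) {
  stopifnot(inherits(table, "ternary_table"))
  labels <- droplevels(as.factor(as.character(labels)))
  if (length(labels) != ncol(table$symbols)) {
    stop("need one label per sample column", call. = FALSE)
  }
  if (nlevels(labels) < 2) {
    stop("a single class yields no inter-class pairs; need >= 2 classes",
         call. = FALSE)
  }
  lev <- levels(labels)
  ks <- integer(0)
  js <- integer(0)
  for (p in seq_len(nlevels(labels) - 1L)) {
    for (q in seq.int(p + 1L, nlevels(labels))) {
      ip <- which(labels == lev[p])
      iq <- which(labels == lev[q])
      grid <- expand.grid(j = iq, k = ip)  # k varies slowest
      ks <- c(ks, grid$k)
      js <- c(js, grid$j)
    }
  }
  s <- table$symbols
  diffs <- s[, ks, drop = FALSE] != s[, js, drop = FALSE]
  diffs[is.na(diffs)] <- FALSE  # '*' against anything cannot discern
  bits <- t(diffs) * 1L
  colnames(bits) <- table$gene_ids
  pairs <- data.frame(first = table$sample_ids[ks],
                      second = table$sample_ids[js],
                      first_class = as.character(labels[ks]),
                      second_class = as.character(labels[js]),
                      stringsAsFactors = FALSE)
  distinction_table(bits, class_sizes = tabulate(labels),
                    gene_ids = table$gene_ids, pairs = pairs)
}

#' @export
print.distinction_table <- function(x, ...) {
  cat("Distinction table:", x$n_rows, "inter-class pairs x",
      x$n_features, "features\n")
  if (!is.null(x$class_sizes)) {
    cat("Class sizes:", paste(x$class_sizes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of object pairs a feature subset discerns
#'
#' Counts the distinction-table rows having a 1 in at least one selected
#' column — the coverage `R_v` of the candidate subset `v`.
#'
#' @param table A `distinction_table`.
#' @param position 0/1 vector of length `n_features`.
#' @return Integer in `[0, n_rows]`.
#' @export
covered_rows <- function(table, position) {
  stopifnot(inherits(table, "distinction_table"))
  if (length(position) != table$n_features) {
    stop("position length ", length(position), " does not match ",
         table$n_features, " features", call. = FALSE)
  }
  sel <- which(position == 1)
  if (!length(sel)) return(0L)
  sum(rowSums(table$bits[, sel, drop = FALSE]) > 0L)
}

#' Is a feature subset a reduct?
#'
#' A reduct discerns every inter-class pair, i.e. covers every row of the
#' distinction table.
#'
#' @inheritParams covered_rows
#' @return `TRUE` iff [covered_rows()] equals `n_rows`.
#' @export
is_reduct <- function(table, position) {
  covered_rows(table, position) == table$n_rows
}

#' Worked-example distinction table
#'
#' A small fixed table with 7 features and two classes of sizes 2 and 3
#' (6 inter-class pairs), used throughout the documentation and tests to
#' illustrate the objectives: the subset `(1,0,1,1,0,1,1)` has cardinality 5
#' and discerns 5 of the 6 pairs.
#'
#' @return A `distinction_table` with `n_features = 7`, `n_rows = 6`.
#' @examples
#' d0 <- example_distinction_table()
#' covered_rows(d0, c(1, 0, 1, 1, 0, 1, 1))
#' @export
example_distinction_table <- function() {
  bits <- matrix(c(1, 0, 0, 0, 0, 0, 0,
                   0, 1, 0, 0, 0, 0, 0,
                   0, 0, 1, 0, 0, 0, 0,
                   0, 0, 0, 1, 0, 1, 0,
                   0, 0, 0, 0, 1, 0, 1,
                   1, 1, 0, 0, 0, 0, 1),
                 nrow = 6, byrow = TRUE,
                 dimnames = list(NULL, paste0("F", 1:7)))
  distinction_table(bits, class_sizes = c(2L, 3L))
}

#' Export a distinction table as annotated CSV
#'
#' Debugging aid: the 0/1 matrix with one row per inter-class pair, prefixed
#' by the pair's sample ids when known.
#'
#' @param table A `distinction_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
export_distinction_table <- function(table, path) {
  df <- as.data.frame(table$bits)
  if (!is.null(table$pairs)) df <- cbind(table$pairs[, 1:2], df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
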