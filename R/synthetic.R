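#' Specification for a synthetic two-class expression matrix
#'
#' Describes a dataset with planted discriminative structure and a known
#' minimal covering subset, so the whole pipeline can be exercised and
#' verified without external downloads. Default sizes mirror a typical
#' two-class microarray study: classes of 22 and 40 samples with 3 planted
#' informative genes among 30.
#'
#' In `ideal` mode the class-B samples are partitioned into `cover_size`
#' blocks and informative gene `i` is expressed at a high level (0.9) on
#' block `i` and at a low level (0.1) everywhere else, so gene `i` discerns
#' exactly the class-A x block-`i` pairs and the planted minimal reduct has
#' size exactly `cover_size`. The two-level profile ternarizes to definite
#' 0/1 symbols under any quartile threshold estimate, which decouples
#' generator correctness from discretization details. Informative genes
#' beyond `cover_size` duplicate block assignments; noise genes are uniform
#' on `[0, 1]`. `noisy` mode adds Gaussian jitter (`noise_sd`) to every
#' value and clips to `[0, 1]`.
#'
#' @param n_genes Total number of genes.
#' @param n_informative Number of informative genes (>= `cover_size`).
#' @param cover_size Planted minimal cover size `m`.
#' @param class_sizes Integer pair `(a, b)`: class-A and class-B sample
#'   counts; `b >= cover_size` is required for the block construction.
#' @param mode `"ideal"` or `"noisy"`.
#' @param noise_sd Gaussian jitter SD for `noisy` mode.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 30L, n_informative = 3L,
                           cover_size = 3L, class_sizes = c(22L, 40L),
                           mode = c("ideal", "noisy"), noise_sd = 0.05,
                           seed = 1L) {
  mode <- match.arg(mode)
  n_genes <- as.integer(n_genes)
  n_informative <- as.integer(n_informative)
  cover_size <- as.integer(cover_size)
  class_sizes <- as.integer(class_sizes)
  if (cover_size < 1L) stop("cover_size must be >= 1", call. = FALSE)
  if (n_informative < cover_size) {
    stop("n_informative must be >= cover_size", call. = FALSE)
  }
  if (n_informative > n_genes) {
    stop("n_informative must be <= n_genes", call. = FALSE)
  }
  if (length(class_sizes) != 2L || any(class_sizes < 2L)) {
    stop("class_sizes must be two counts >= 2", call. = FALSE)
  }
  if (class_sizes[2] < cover_size) {
    stop("class B needs at least cover_size samples for the block ",
         "construction", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_genes = n_genes, n_informative = n_informative,
                 cover_size = cover_size, class_sizes = class_sizes,
                 mode = mode, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset with a planted minimal cover
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `dataset` (an [expression_dataset()]),
#'   `informative` (ids of the informative genes), `blocks` (block index of
#'   each informative gene) and `cover_size` (the planted minimal reduct
#'   size).
#' @examples
#' sim <- generate_dataset(synthetic_spec(cover_size = 2, seed = 7))
#' sim$dataset
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  a <- spec$class_sizes[1]
  b <- spec$class_sizes[2]
  m <- spec$cover_size
  n_samples <- a + b
  labels <- rep(c("A", "B"), c(a, b))
  sample_ids <- c(paste0("a", seq_len(a)), paste0("b", seq_len(b)))
  # class-B columns split into m contiguous blocks
  block_of_b <- sort(rep_len(seq_len(m), b))
  values <- matrix(NA_real_, spec$n_genes, n_samples)
  gene_blocks <- ((seq_len(spec$n_informative) - 1L) %% m) + 1L
  low <- 0.1
  high <- 0.9
  for (i in seq_len(spec$n_informative)) {
    row <- rep(low, n_samples)
    row[a + which(block_of_b == gene_blocks[i])] <- high
    values[i, ] <- row
  }
  n_noise <- spec$n_genes - spec$n_informative
  if (n_noise > 0) {
    values[spec$n_informative + seq_len(n_noise), ] <-
      stats::runif(n_noise * n_samples)
  }
  if (spec$mode == "noisy" && spec$noise_sd > 0) {
    values <- values + stats::rnorm(length(values), sd = spec$noise_sd)
    values <- pmin(pmax(values, 0), 1)
  }
  gene_ids <- c(sprintf("inf%d", seq_len(spec$n_informative)),
                if (n_noise > 0) sprintf("noise%d", seq_len(n_noise)))
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  list(dataset = expression_dataset(values, labels = labels),
       informative = gene_ids[seq_len(spec$n_informative)],
       blocks = gene_blocks,
       cover_size = m)
}

#' Planted minimal cover size of a synthetic specification
#'
#' Ground truth accessor: the minimal number of genes needed to discern
#' every inter-class pair in the ideal construction. Exists so tests never
#' re-derive the truth from the generated data.
#'
#' @param spec A [synthetic_spec()].
#' @return Integer `cover_size`.
#' @export
planted_cover_size <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  spec$cover_size
}
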