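#' Construct a labelled gene-expression dataset
#'
#' Bundles a genes x samples matrix of raw intensities with one class label
#' per sample. This is the common input container for the whole pipeline:
#' rows are genes (attributes), columns are samples (objects).
#'
#' @param values Numeric matrix, genes in rows and samples in columns.
#' @param labels Class label per sample (character or factor), length
#'   `ncol(values)`.
#' @param gene_ids,sample_ids Optional identifier vectors; default to the
#'   dimnames of `values` or to `g1, g2, ...` / `s1, s2, ...`.
#'
#' @return An object of class `expr_dataset`: a list with elements
#'   `values` (named numeric matrix) and `labels` (factor).
#'
#' @examples
#' x <- matrix(rnorm(12), nrow = 3)
#' ds <- expression_dataset(x, labels = c("A", "A", "B", "B"))
#' ds
#' @export
expression_dataset <- function(values, labels, gene_ids = NULL,
                               sample_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("missing intensities are not supported; impute or drop them first",
         call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("gene_ids length does not match the number of matrix rows",
         call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("sample_ids length does not match the number of matrix columns",
         call. = FALSE)
  }
  if (length(labels) != ncol(values)) {
    stop("need exactly one class label per sample (got ", length(labels),
         " labels for ", ncol(values), " samples)", call. = FALSE)
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop("duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) {
    stop("duplicate sample ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  labels <- droplevels(as.factor(as.character(labels)))
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, labels = labels), class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("Gene-expression dataset:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  cat("Classes:",
      paste(sprintf("%s (%d)", levels(x$labels), tabulate(x$labels)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

# selection-time requirement: >= 2 classes and >= 2 samples per class
check_selectable <- function(dataset) {
  sizes <- tabulate(dataset$labels)
  if (nlevels(dataset$labels) < 2) {
    stop("at least 2 distinct class labels are required for selection",
         call. = FALSE)
  }
  if (any(sizes < 2)) {
    stop("every class needs at least 2 samples for selection (class ",
         levels(dataset$labels)[which.min(sizes)], " has ", min(sizes), ")",
         call. = FALSE)
  }
  invisible(dataset)
}
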