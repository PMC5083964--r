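#' k-nearest-neighbour prediction for one query sample
#'
#' Majority label among the `k` training samples nearest to the query in
#' Euclidean distance over the selected genes. `k` must be odd (avoids
#' two-class vote ties). Distance ties are broken by training order; a label
#' tie among more than two classes is broken in favour of the label of the
#' nearest neighbour carrying one of the tied labels.
#'
#' @param train Numeric matrix, training samples in rows, selected genes in
#'   columns.
#' @param train_labels Class label per training sample.
#' @param query Numeric vector, one value per selected gene.
#' @param k Odd neighbour count, at most `nrow(train)`.
#' @return The predicted class label (character).
#' @export
knn_predict <- function(train, train_labels, query, k = 1L) {
  train <- as.matrix(train)
  if (!nrow(train)) stop("empty training set", call. = FALSE)
  if (k %% 2L == 0L) stop("k must be odd to avoid vote ties", call. = FALSE)
  if (k > nrow(train)) stop("k exceeds the number of training samples",
                            call. = FALSE)
  if (length(query) != ncol(train)) {
    stop("query length does not match the number of selected genes",
         call. = FALSE)
  }
  train_labels <- as.character(train_labels)
  d <- sqrt(colSums((t(train) - query)^2))
  nn <- order(d, seq_along(d))[seq_len(k)]  # distance ties: training order
  votes <- table(train_labels[nn])
  winners <- names(votes)[votes == max(votes)]
  if (length(winners) == 1L) return(winners)
  # multi-class tie: the nearest neighbour among the tied labels decides
  train_labels[nn][match(TRUE, train_labels[nn] %in% winners)]
}

#' Stratified k-fold cross-validation of a gene subset
#'
#' Partitions samples into `folds` disjoint folds, stratified by class so
#' every fold sees every class, then repeatedly trains on all-but-one fold
#' and scores the held-out fold, using only the selected genes. The native
#' classifier is k-NN; any external classifier can be plugged in through a
#' `list(fit = function(train, labels), predict = function(model, test))`
#' adapter (external validation, not part of the core method).
#'
#' @param dataset An [expression_dataset()] (raw intensities).
#' @param subset Gene selection: a 0/1 (or logical) vector over the
#'   dataset's genes, or a character vector of gene ids.
#' @param classifier `"knn"` or a fit/predict adapter list.
#' @param k Odd neighbour count for the native k-NN.
#' @param folds Number of folds (>= 2; every class needs at least `folds`
#'   samples).
#' @param seed Optional seed for the fold assignment.
#' @return An object of class `cv_report`: per-fold accuracies (percent),
#'   their mean, the fold assignment, and the evaluated gene ids.
#' @export
cross_validate <- function(dataset, subset, classifier = "knn", k = 1L,
                           folds = 10L, seed = NULL) {
  stopifnot(inherits(dataset, "expr_dataset"))
  genes <- resolve_subset(dataset, subset)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  class_sizes <- tabulate(dataset$labels)
  if (any(class_sizes < folds)) {
    small <- levels(dataset$labels)[which.min(class_sizes)]
    stop("class '", small, "' has fewer samples (", min(class_sizes),
         ") than folds (", folds, "); reduce the fold count", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  fold_of <- integer(ncol(dataset$values))
  for (cl in levels(dataset$labels)) {
    idx <- sample(which(dataset$labels == cl))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  x <- t(dataset$values[genes, , drop = FALSE])
  lab <- as.character(dataset$labels)
  acc <- vapply(seq_len(folds), function(f) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    if (identical(classifier, "knn")) {
      pred <- vapply(test, function(j) {
        knn_predict(x[train, , drop = FALSE], lab[train], x[j, ], k = k)
      }, character(1))
    } else {
      model <- classifier$fit(x[train, , drop = FALSE], lab[train])
      pred <- as.character(classifier$predict(model,
                                              x[test, , drop = FALSE]))
    }
    100 * mean(pred == lab[test])
  }, numeric(1))
  structure(list(classifier = if (is.character(classifier)) classifier else
                   "external",
                 k = if (identical(classifier, "knn")) k else NA_integer_,
                 folds = folds,
                 fold_accuracy = acc,
                 mean_accuracy = mean(acc),
                 fold_of = fold_of,
                 genes = genes),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %s%s on %d gene(s)\n",
              x$folds, x$classifier,
              if (!is.na(x$k)) sprintf(" (k = %d)", x$k) else "",
              length(x$genes)))
  cat(sprintf("Mean accuracy: %.2f %%\n", x$mean_accuracy))
  cat("Per fold:", paste(sprintf("%.2f", x$fold_accuracy), collapse = " "),
      "\n")
  invisible(x)
}

resolve_subset <- function(dataset, subset) {
  ids <- rownames(dataset$values)
  if (is.character(subset)) {
    missing <- setdiff(subset, ids)
    if (length(missing)) {
      stop("unknown gene id(s): ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    return(subset)
  }
  if (length(subset) != length(ids)) {
    stop("subset vector length does not match the number of genes",
         call. = FALSE)
  }
  sel <- ids[as.logical(subset)]
  if (!length(sel)) stop("subset selects no genes", call. = FALSE)
  sel
}

#' Per-array z-scores of selected genes
#'
#' For each sample (array), the mean and population standard deviation of
#' the intensities of all genes on that array give the standardization; the
#' z-score of a selected gene is `(G_i - mu) / sigma`. Large positive values
#' flag genes highly expressed relative to the array aggregate, large
#' negative values genes barely expressed.
#'
#' @param dataset An [expression_dataset()] with at least 2 genes.
#' @param subset Gene selection as in [cross_validate()].
#' @return An object of class `zscore_report`: matrix `z` (selected genes x
#'   samples), and per-sample `mu` and `sigma`. Standardization uses all
#'   genes and the population SD (divide by n).
#' @export
z_scores <- function(dataset, subset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (nrow(dataset$values) < 2L) {
    stop("z-scores need at least 2 genes", call. = FALSE)
  }
  genes <- resolve_subset(dataset, subset)
  v <- dataset$values
  mu <- colMeans(v)
  sigma <- sqrt(colMeans(v^2) - mu^2)
  if (any(sigma == 0)) {
    bad <- colnames(v)[sigma == 0][1]
    stop("sample '", bad, "' has constant intensities (sigma = 0)",
         call. = FALSE)
  }
  z <- sweep(sweep(v[genes, , drop = FALSE], 2L, mu, "-"), 2L, sigma, "/")
  structure(list(z = z, mu = mu, sigma = sigma, genes = genes,
                 axis = "within sample across all genes, population SD"),
            class = "zscore_report")
}

#' @export
print.zscore_report <- function(x, ...) {
  cat("Z-score report (", x$axis, ")\n", sep = "")
  cat(nrow(x$z), "selected gene(s) x", ncol(x$z), "sample(s)\n")
  print(round(x$z[seq_len(min(5, nrow(x$z))), seq_len(min(6, ncol(x$z))),
                  drop = FALSE], 3))
  invisible(x)
}
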