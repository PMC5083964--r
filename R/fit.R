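#' Multi-objective binary particle swarm gene-subset selection
#'
#' The main fitting function. Runs the full pipeline on a labelled
#' expression matrix: per-gene min-max normalization, quartile ternarization
#' and ambiguity filtering ([preprocess_pipeline()]), distinction-table
#' construction over inter-class sample pairs
#' ([build_distinction_table()]), and the Pareto-ranked binary swarm search
#' ([run_mobpso()]) that trades subset cardinality against discernibility.
#'
#' @param x An [expression_dataset()], or a numeric genes x samples matrix.
#' @param labels Class label per sample; ignored when `x` is already an
#'   `expr_dataset`.
#' @param n_intervals Grid resolution for the quartile thresholds.
#' @param swarm_size,generations,w,c1,c2,v_min,v_max,seed Swarm parameters;
#'   see [mobpso_config()].
#' @return An object of class `mobpso`: a list with the Pareto `archive`,
#'   the distinction `table`, the `ternary` table (whose
#'   `kept_gene_indices` map archive columns back to input genes), the input
#'   `dataset`, the `config`, and the matched `call`. Methods: `print`,
#'   `summary`, `coef`, `predict`, `plot`.
#' @examples
#' sim <- generate_dataset(synthetic_spec(seed = 1))
#' fit <- mobpso(sim$dataset, generations = 25, seed = 1)
#' fit
#' coef(fit)
#' @export
mobpso <- function(x, labels = NULL, n_intervals = 10L, swarm_size = 20L,
                   generations = 50L, w = 0.9, c1 = 2, c2 = 2,
                   v_min = -4, v_max = 4, seed = NULL) {
  dataset <- if (inherits(x, "expr_dataset")) x else
    expression_dataset(x, labels = labels)
  check_selectable(dataset)
  config <- mobpso_config(swarm_size = swarm_size, generations = generations,
                          w = w, c1 = c1, c2 = c2, v_min = v_min,
                          v_max = v_max, seed = seed)
  ternary <- preprocess_pipeline(dataset, n_intervals = n_intervals)
  table <- build_distinction_table(ternary, dataset$labels)
  archive <- run_mobpso(table, config)
  structure(list(archive = archive, table = table, ternary = ternary,
                 dataset = dataset, config = config, call = match.call()),
            class = "mobpso")
}

#' @export
print.mobpso <- function(x, ...) {
  cat("Multi-objective binary PSO gene selection\n\n")
  cat("Call: ", deparse(x$call), "\n\n")
  cat(sprintf("%d genes x %d samples; %d genes retained after filtering\n",
              nrow(x$dataset$values), ncol(x$dataset$values),
              x$table$n_features))
  cat(sprintf("Distinction table: %d inter-class pairs\n", x$table$n_rows))
  cat(sprintf("Pareto archive: %d solution(s)\n", archive_size(x$archive)))
  red <- minimal_reduct(x)
  if (!is.null(red)) {
    cat("Smallest full-cover subset (", length(red), " genes): ",
        paste(red, collapse = ", "), "\n", sep = "")
  } else {
    cat("No archived subset covers every pair (best coverage ",
        sprintf("%.3f", max(x$archive$objectives[, 2])), ")\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.mobpso <- function(object, ...) {
  arch <- object$archive
  card <- rowSums(arch$positions)
  o <- order(card)
  genes <- vapply(o, function(i) {
    paste(object$table$gene_ids[arch$positions[i, ] == 1], collapse = ","
    )
  }, character(1))
  front <- data.frame(cardinality = card[o],
                      fit1 = arch$objectives[o, 1],
                      fit2 = arch$objectives[o, 2],
                      reduct = arch$objectives[o, 2] == 1,
                      genes = genes,
                      stringsAsFactors = FALSE)
  structure(list(front = front, n_features = object$table$n_features,
                 n_rows = object$table$n_rows, config = object$config),
            class = "summary.mobpso")
}

#' @export
print.summary.mobpso <- function(x, ...) {
  cat("Pareto front over", x$n_features, "retained genes (",
      x$n_rows, "inter-class pairs )\n\n")
  df <- x$front
  df$fit1 <- round(df$fit1, 4)
  df$fit2 <- round(df$fit2, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

# smallest-cardinality archived reduct, as original gene ids (or NULL)
minimal_reduct <- function(object) {
  arch <- object$archive
  full <- which(arch$objectives[, 2] == 1)
  if (!length(full)) return(NULL)
  card <- rowSums(arch$positions[full, , drop = FALSE])
  best <- full[which.min(card)]
  object$table$gene_ids[arch$positions[best, ] == 1]
}

#' @export
coef.mobpso <- function(object, ...) {
  red <- minimal_reduct(object)
  if (is.null(red)) {
    warning("no archived subset covers every inter-class pair; ",
            "returning the best-coverage subset")
    best <- which.max(object$archive$objectives[, 2])
    red <- object$table$gene_ids[object$archive$positions[best, ] == 1]
  }
  red
}

#' Classify new samples with the selected gene subset
#'
#' k-nearest-neighbour prediction on the smallest archived reduct, using the
#' training expression values stored in the fit.
#'
#' @param object A `mobpso` fit.
#' @param newdata Numeric genes x samples matrix containing (at least) the
#'   selected genes as rows, or an `expr_dataset`.
#' @param k Odd neighbour count.
#' @param ... Unused.
#' @return Factor of predicted class labels, one per column of `newdata`.
#' @export
predict.mobpso <- function(object, newdata, k = 1L, ...) {
  genes <- coef(object)
  values <- if (inherits(newdata, "expr_dataset")) newdata$values else
    as.matrix(newdata)
  missing <- setdiff(genes, rownames(values))
  if (length(missing)) {
    stop("newdata lacks selected gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  train <- t(object$dataset$values[genes, , drop = FALSE])
  preds <- vapply(seq_len(ncol(values)), function(j) {
    as.character(knn_predict(train, object$dataset$labels,
                             values[genes, j], k = k))
  }, character(1))
  factor(preds, levels = levels(object$dataset$labels))
}

#' Plot the archived Pareto front
#'
#' Subset cardinality against the fraction of inter-class pairs discerned;
#' full-cover subsets (reducts) are filled.
#'
#' @param x A `mobpso` fit or a `pareto_archive`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mobpso <- function(x, ...) {
  plot(x$archive, ...)
  invisible(x)
}

#' @export
plot.pareto_archive <- function(x, ...) {
  card <- rowSums(x$positions)
  cover <- x$objectives[, 2]
  graphics::plot(card, cover, xlab = "subset cardinality",
                 ylab = "fraction of pairs discerned (Fit2)",
                 pch = ifelse(cover == 1, 19, 1),
                 main = "Pareto front", ...)
  invisible(x)
}
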