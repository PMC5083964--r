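#' Read an expression matrix and sample labels from delimited text
#'
#' Reads the common microarray flat-file layouts: a delimited matrix with an
#' identifier first column and a header row, oriented either genes-in-rows
#' (the default) or samples-in-rows. Labels come from a two-column file
#' (`sample_id,label`), from a designated row (or column, when
#' samples-in-rows) of the matrix itself, or from a vector supplied directly.
#'
#' @param path Path to a CSV or TSV file. The delimiter is inferred from the
#'   extension (`.csv` = comma, anything else = tab) unless `sep` is given.
#' @param orientation `"genes"` if rows are genes, `"samples"` if rows are
#'   samples. Internally everything is normalized to genes x samples.
#' @param labels One of: a path to a two-column delimited file mapping sample
#'   id to class label; the identifier of a row/column of the matrix holding
#'   the labels; or a vector with one label per sample.
#' @param sep Field delimiter override.
#'
#' @return An [expression_dataset()].
#' @export
read_expression_table <- function(path, orientation = c("genes", "samples"),
                                  labels, sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- infer_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  row_ids <- as.character(raw[[1L]])
  cell <- raw[-1L]
  col_ids <- colnames(cell)

  label_vec <- NULL
  if (length(labels) == 1L && is.character(labels) && labels %in% row_ids) {
    # designated row (genes-in-rows) or column entry (samples-in-rows matrix
    # stores genes in columns, so a label *column* appears among col_ids below)
    i <- match(labels, row_ids)
    label_vec <- stats::setNames(as.character(cell[i, ]), col_ids)
    row_ids <- row_ids[-i]
    cell <- cell[-i, , drop = FALSE]
  } else if (length(labels) == 1L && is.character(labels) &&
             labels %in% col_ids) {
    i <- match(labels, col_ids)
    label_vec <- stats::setNames(as.character(cell[[i]]), row_ids)
    col_ids <- col_ids[-i]
    cell <- cell[, -i, drop = FALSE]
  }

  mat <- parse_numeric_cells(cell, row_ids, col_ids)
  if (orientation == "samples") {
    mat <- t(mat)
    if (!is.null(label_vec) && !identical(names(label_vec), colnames(mat))) {
      # labels came from a column of the samples-in-rows layout
      label_vec <- label_vec[colnames(mat)]
    }
  }

  if (is.null(label_vec)) {
    if (length(labels) == 1L && is.character(labels)) {
      if (!file.exists(labels)) {
        stop("label source '", labels, "' is neither a file nor a ",
             "row/column of the matrix", call. = FALSE)
      }
      lab <- utils::read.table(labels, header = FALSE, sep = infer_sep(labels),
                               stringsAsFactors = FALSE,
                               colClasses = "character")
      if (ncol(lab) < 2) stop("label file needs two columns: sample_id,label",
                              call. = FALSE)
      if (identical(tolower(lab[1, 1]), "sample_id")) lab <- lab[-1, ]
      label_vec <- stats::setNames(lab[[2L]], lab[[1L]])
    } else {
      if (length(labels) != ncol(mat)) {
        stop("label vector length does not match the number of samples",
             call. = FALSE)
      }
      label_vec <- stats::setNames(as.character(labels), colnames(mat))
    }
  }

  missing <- setdiff(colnames(mat), names(label_vec))
  if (length(missing)) {
    stop("no class label for sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  expression_dataset(mat, labels = label_vec[colnames(mat)])
}

infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

parse_numeric_cells <- function(cell, row_ids, col_ids) {
  mat <- matrix(NA_real_, nrow = length(row_ids), ncol = length(col_ids),
                dimnames = list(row_ids, col_ids))
  for (j in seq_along(col_ids)) {
    v <- suppressWarnings(as.numeric(cell[[j]]))
    bad <- which(is.na(v) & !is.na(cell[[j]]) & nzchar(trimws(cell[[j]])))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   cell[[j]][bad[1]], row_ids[bad[1]], col_ids[j]),
           call. = FALSE)
    }
    mat[, j] <- v
  }
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row '%s', column '%s'",
                 row_ids[bad[1]], col_ids[bad[2]]), call. = FALSE)
  }
  mat
}

#' Write a Pareto-archive selection report
#'
#' Writes a JSON report listing, for every archived solution, its bitstring,
#' the selected gene identifiers, both objective values and the subset
#' cardinality, together with run metadata (seed and configuration echo).
#' A companion flat CSV (same path with a `.csv` extension) holds one row per
#' (solution, gene) pair.
#'
#' @param archive A [pareto_archive] as returned by [run_mobpso()].
#' @param gene_ids Character vector naming the archive's position columns.
#' @param path Output path for the JSON report.
#' @return Invisibly, the paths written (`json`, `csv`).
#' @export
write_selection_report <- function(archive, gene_ids, path) {
  stopifnot(inherits(archive, "pareto_archive"))
  n <- archive_size(archive)
  if (n > 0 && ncol(archive$positions) != length(gene_ids)) {
    stop("gene_ids length does not match archive position length",
         call. = FALSE)
  }
  solutions <- lapply(seq_len(n), function(i) {
    pos <- archive$positions[i, ]
    list(bitstring = paste(pos, collapse = ""),
         genes = as.list(gene_ids[pos == 1]),
         fit1 = unname(archive$objectives[i, 1]),
         fit2 = unname(archive$objectives[i, 2]),
         cardinality = sum(pos))
  })
  cfg <- attr(archive, "config")
  report <- list(
    metadata = list(
      seed = if (is.null(cfg)) NULL else cfg$seed,
      config = if (is.null(cfg)) NULL else unclass(cfg),
      n_solutions = n),
    solutions = solutions)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  csv_path <- sub("\\.json$", "", path)
  csv_path <- paste0(csv_path, ".csv")
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    pos <- archive$positions[i, ]
    sel <- which(pos == 1)
    if (!length(sel)) return(NULL)
    data.frame(solution = i,
               bitstring = paste(pos, collapse = ""),
               gene = gene_ids[sel],
               cardinality = sum(pos),
               fit1 = unname(archive$objectives[i, 1]),
               fit2 = unname(archive$objectives[i, 2]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(solution = integer(), bitstring = character(),
                       gene = character(), cardinality = integer(),
                       fit1 = numeric(), fit2 = numeric())
  }
  utils::write.csv(rows, csv_path, row.names = FALSE)
  invisible(list(json = path, csv = csv_path))
}

#' Re-read a selection report written by [write_selection_report()]
#'
#' @param path Path to the JSON report.
#' @return A [pareto_archive] with the stored positions and objectives.
#' @export
read_selection_report <- function(path) {
  rep <- jsonlite::read_json(path)
  sols <- rep$solutions
  if (!length(sols)) {
    return(new_pareto_archive(matrix(integer(), 0, 0),
                              matrix(numeric(), 0, 2,
                                     dimnames = list(NULL, c("fit1", "fit2"))),
                              integer()))
  }
  positions <- do.call(rbind, lapply(sols, function(s) {
    as.integer(strsplit(s$bitstring, "")[[1]])
  }))
  objectives <- cbind(fit1 = vapply(sols, function(s) s$fit1, 0),
                      fit2 = vapply(sols, function(s) s$fit2, 0))
  new_pareto_archive(positions, objectives, rep(NA_integer_, length(sols)))
}
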