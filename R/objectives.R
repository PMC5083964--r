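#' Subset cardinality
#'
#' Number of selected features, `O_v` — the count of 1's in the position
#' vector.
#'
#' @param position 0/1 vector.
#' @return Integer count of ones.
#' @examples
#' cardinality(c(1, 0, 1, 1, 0, 1, 1))  # 5
#' @export
cardinality <- function(position) {
  check_position(position)
  sum(position == 1)
}

check_position <- function(position) {
  if (!length(position)) stop("position must be nonempty", call. = FALSE)
  if (!all(position %in% c(0, 1))) {
    stop("position must be a 0/1 vector", call. = FALSE)
  }
  invisible(position)
}

#' Parsimony objective
#'
#' `Fit1 = (N - O_v) / N`: credit for selecting few features. Equals 1 for
#' the empty subset and 0 for the full set, and decreases strictly as
#' features are added.
#'
#' @param position 0/1 vector of length `N`.
#' @return A number in `[0, 1]`.
#' @export
fit1 <- function(position) {
  check_position(position)
  n <- length(position)
  (n - sum(position == 1)) / n
}

#' Discernibility objective
#'
#' `Fit2 = R_v / n_rows`: the fraction of inter-class sample pairs the
#' subset discerns (for two classes `n_rows = C1 * C2`). Nondecreasing under
#' adding features; equals 1 exactly for reducts when every row is coverable.
#'
#' @param position 0/1 vector of length `n_features`.
#' @param table A `distinction_table`.
#' @return A number in `[0, 1]`.
#' @export
fit2 <- function(position, table) {
  check_position(position)
  covered_rows(table, position) / table$n_rows
}

#' Evaluate both objectives for a candidate subset
#'
#' @inheritParams fit2
#' @return Named numeric vector `c(fit1 = ..., fit2 = ...)`.
#' @examples
#' d0 <- example_distinction_table()
#' evaluate_pair(c(1, 0, 1, 1, 0, 1, 1), d0)  # (2/7, 5/6)
#' @export
evaluate_pair <- function(position, table) {
  c(fit1 = fit1(position), fit2 = fit2(position, table))
}

#' Weighted-sum scalarization of the two objectives
#'
#' `Fit = Fit1 * alpha + Fit2 * (1 - alpha)` with `0 < alpha < 1` — the
#' single-objective combination used by scalarized (e.g. GA-style) searches.
#'
#' @param pair Numeric pair `(fit1, fit2)` as from [evaluate_pair()].
#' @param alpha Weight on the parsimony objective, strictly between 0 and 1.
#' @return A number in `[0, 1]`.
#' @export
weighted_fitness <- function(pair, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  unname(pair[1] * alpha + pair[2] * (1 - alpha))
}
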