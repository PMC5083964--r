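#' Optimizer configuration
#'
#' Bundles the swarm parameters. Defaults follow the standard published
#' settings for this optimizer: acceleration coefficients `c1 = c2 = 2`,
#' velocity clamp `[-4, 4]`, inertia weight `w = 0.9`, 50 generations, and a
#' swarm of 20 particles with elitist 50 percent survival.
#'
#' @param swarm_size Number of particles `P` (even, >= 2).
#' @param generations Number of generations `G` (>= 1).
#' @param w Inertia weight.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param v_min,v_max Velocity clamp.
#' @param seed Optional integer seed; when given, [run_mobpso()] is fully
#'   reproducible.
#' @param alpha Weight for [weighted_fitness()] in scalarized use.
#' @return An object of class `mobpso_config`.
#' @export
mobpso_config <- function(swarm_size = 20L, generations = 50L, w = 0.9,
                          c1 = 2, c2 = 2, v_min = -4, v_max = 4,
                          seed = NULL, alpha = 0.5) {
  swarm_size <- as.integer(swarm_size)
  generations <- as.integer(generations)
  if (is.na(swarm_size) || swarm_size < 2L || swarm_size %% 2L != 0L) {
    stop("swarm_size must be an even integer >= 2", call. = FALSE)
  }
  if (is.na(generations) || generations < 1L) {
    stop("generations must be >= 1", call. = FALSE)
  }
  if (v_min >= v_max) stop("v_min must be below v_max", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(swarm_size = swarm_size, generations = generations,
                 w = w, c1 = c1, c2 = c2, v_min = v_min, v_max = v_max,
                 survival_fraction = 0.5, seed = seed, alpha = alpha),
            class = "mobpso_config")
}

#' Pareto dominance (maximization)
#'
#' `a` dominates `b` when `a` is at least as good on both objectives and
#' strictly better on at least one.
#'
#' @param a,b Numeric objective pairs `(fit1, fit2)`.
#' @return Logical.
#' @export
dominates <- function(a, b) {
  all(a >= b) && any(a > b)
}

#' Non-dominated sorting
#'
#' Assigns each objective pair its Pareto rank: rank 1 is the non-dominated
#' set; rank `r` is the set that becomes non-dominated once all ranks below
#' `r` are removed. Implemented as fast non-dominated sorting via pairwise
#' domination counts.
#'
#' @param objectives A numeric matrix with one row and two columns per
#'   solution (`fit1`, `fit2`), or a list of numeric pairs.
#' @return Integer vector of ranks (1 = non-dominated).
#' @export
non_dominated_sort <- function(objectives) {
  m <- as_objective_matrix(objectives)
  n <- nrow(m)
  if (!n) stop("objectives must be nonempty", call. = FALSE)
  f1 <- m[, 1]
  f2 <- m[, 2]
  # D[i, j] = TRUE iff solution i dominates solution j
  D <- outer(f1, f1, ">=") & outer(f2, f2, ">=") &
    (outer(f1, f1, ">") | outer(f2, f2, ">"))
  n_dom <- colSums(D)
  ranks <- integer(n)
  r <- 1L
  front <- which(n_dom == 0L & ranks == 0L)
  while (length(front)) {
    ranks[front] <- r
    n_dom <- n_dom - colSums(D[front, , drop = FALSE])
    r <- r + 1L
    front <- which(n_dom == 0L & ranks == 0L)
  }
  ranks
}

as_objective_matrix <- function(objectives) {
  if (is.list(objectives)) {
    objectives <- do.call(rbind, objectives)
  }
  m <- as.matrix(objectives)
  if (ncol(m) != 2L || !is.numeric(m) || anyNA(m) || any(!is.finite(m))) {
    stop("objectives must be finite numeric pairs", call. = FALSE)
  }
  m
}

#' Initialize a particle swarm
#'
#' Positions are i.i.d. Bernoulli(0.5) bits; velocity components are uniform
#' on `[-1, 1]`; each particle's personal best starts at its initial state.
#' Objectives are left unevaluated (`NULL`) until the first generation.
#'
#' @param n_features Position length `N`.
#' @param config A [mobpso_config()].
#' @return List of `P` particles; each particle is a list with `position`,
#'   `velocity`, `pbest_position`, `pbest_objectives`, `current_objectives`.
#' @export
initialize_swarm <- function(n_features, config) {
  stopifnot(n_features >= 1L)
  lapply(seq_len(config$swarm_size), function(i) {
    pos <- stats::rbinom(n_features, 1L, 0.5)
    list(position = pos,
         velocity = stats::runif(n_features, -1, 1),
         pbest_position = pos,
         pbest_objectives = NULL,
         current_objectives = NULL)
  })
}

#' Velocity update
#'
#' The canonical inertia-weighted rule with cognitive and social terms,
#' componentwise:
#' `v <- w * v + c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x)`,
#' with `r1`, `r2` uniform on `[0, 1]` drawn per component, then clamped to
#' `[v_min, v_max]`.
#'
#' @param particle A particle (see [initialize_swarm()]).
#' @param gbest The swarm guide position (0/1 vector).
#' @param config A [mobpso_config()].
#' @param r1,r2 Optional fixed random vectors (for deterministic analysis);
#'   drawn from the session RNG when `NULL`.
#' @return The new clamped velocity vector.
#' @export
update_velocity <- function(particle, gbest, config, r1 = NULL, r2 = NULL) {
  n <- length(particle$position)
  if (length(gbest) != n || length(particle$velocity) != n) {
    stop("particle/gbest dimensions disagree", call. = FALSE)
  }
  if (is.null(r1)) r1 <- stats::runif(n)
  if (is.null(r2)) r2 <- stats::runif(n)
  v <- config$w * particle$velocity +
    config$c1 * r1 * (particle$pbest_position - particle$position) +
    config$c2 * r2 * (gbest - particle$position)
  pmin(pmax(v, config$v_min), config$v_max)
}

#' Position update through the sigmoid transfer function
#'
#' Bit `i` is set to 1 with probability `S(v_i) = 1 / (1 + exp(-v_i))`,
#' sampled independently per component.
#'
#' @param velocity Real velocity vector.
#' @return A 0/1 position vector.
#' @export
update_position <- function(velocity) {
  if (any(!is.finite(velocity))) stop("velocity must be finite", call. = FALSE)
  s <- 1 / (1 + exp(-velocity))
  as.integer(stats::runif(length(velocity)) < s)
}

#' Personal-best update under Pareto dominance
#'
#' The personal best is replaced when the current state dominates it and
#' kept when it dominates the current state; when the two are incomparable,
#' the replacement is decided by a fair coin (a standard multi-objective
#' swarm convention).
#'
#' @param particle A particle with `current_objectives` evaluated.
#' @param coin Optional logical override of the incomparability coin flip
#'   (`TRUE` = replace); drawn from the session RNG when `NULL`.
#' @return The particle with `pbest_position`/`pbest_objectives` updated.
#' @export
update_pbest <- function(particle, coin = NULL) {
  cur <- particle$current_objectives
  pb <- particle$pbest_objectives
  if (is.null(cur)) stop("current_objectives not evaluated", call. = FALSE)
  replace <- if (is.null(pb)) {
    TRUE
  } else if (dominates(cur, pb)) {
    TRUE
  } else if (dominates(pb, cur)) {
    FALSE
  } else {
    if (is.null(coin)) stats::runif(1) < 0.5 else isTRUE(coin)
  }
  if (replace) {
    particle$pbest_position <- particle$position
    particle$pbest_objectives <- cur
  }
  particle
}

#' Select the swarm guide from the top-ranked non-dominated set
#'
#' All rank-1 solutions have equal priority, so the guide is a uniform
#' random choice among their positions.
#'
#' @param particles List of particles with `current_objectives` evaluated.
#' @param ranks Optional precomputed ranks from [non_dominated_sort()].
#' @return A 0/1 position vector.
#' @export
select_gbest <- function(particles, ranks = NULL) {
  if (!length(particles)) stop("empty population", call. = FALSE)
  if (is.null(ranks)) {
    ranks <- non_dominated_sort(lapply(particles,
                                       function(p) p$current_objectives))
  }
  idx <- which(ranks == 1L)
  particles[[idx[sample.int(length(idx), 1L)]]]$position
}

#' Elitist environmental selection (best 50 percent)
#'
#' Ranks the combined parent + offspring population (size `2P`) by
#' non-dominated sorting and keeps the best `P` in ascending rank. Within
#' the boundary rank, ties are broken deterministically by descending
#' coverage (`fit2`), then descending parsimony (`fit1`), then first-seen
#' order.
#'
#' @param parents,offspring Particle lists of equal size `P`, with
#'   `current_objectives` evaluated.
#' @param p Number of survivors (defaults to `length(parents)`).
#' @return List of `p` surviving particles.
#' @export
environmental_selection <- function(parents, offspring,
                                    p = length(parents)) {
  combined <- c(parents, offspring)
  obj <- do.call(rbind, lapply(combined, function(x) x$current_objectives))
  ranks <- non_dominated_sort(obj)
  ord <- order(ranks, -obj[, 2], -obj[, 1], seq_along(combined))
  combined[ord[seq_len(p)]]
}

new_pareto_archive <- function(positions, objectives, generation) {
  structure(list(positions = positions, objectives = objectives,
                 generation = generation),
            class = "pareto_archive")
}

archive_size <- function(archive) nrow(archive$positions)

#' @export
print.pareto_archive <- function(x, ...) {
  cat("Pareto archive:", archive_size(x), "non-dominated solution(s)\n")
  if (archive_size(x)) {
    df <- data.frame(cardinality = rowSums(x$positions),
                     fit1 = round(x$objectives[, 1], 4),
                     fit2 = round(x$objectives[, 2], 4))
    agg <- stats::aggregate(list(n_solutions = seq_len(nrow(df))), df,
                            FUN = length)
    print(agg[order(agg$cardinality), ], row.names = FALSE)
  }
  invisible(x)
}

# merge candidate rank-1 solutions into the archive, keeping the archive
# mutually non-dominated and position-unique (first occurrence wins)
archive_update <- function(archive, positions, objectives, generation) {
  pos <- rbind(archive$positions, positions)
  obj <- rbind(archive$objectives, objectives)
  gen <- c(archive$generation, rep(generation, nrow(positions)))
  keys <- apply(pos, 1L, paste, collapse = "")
  first <- !duplicated(keys)
  pos <- pos[first, , drop = FALSE]
  obj <- obj[first, , drop = FALSE]
  gen <- gen[first]
  ranks <- non_dominated_sort(obj)
  keep <- ranks == 1L
  new_pareto_archive(pos[keep, , drop = FALSE], obj[keep, , drop = FALSE],
                     gen[keep])
}

#' Run the multi-objective binary particle swarm search
#'
#' Searches the distinction table for small, highly discerning feature
#' subsets. Each generation: current positions are evaluated on
#' ([fit1()], [fit2()]); personal bests are updated under dominance; every
#' particle draws a guide uniformly from the population's rank-1 set and
#' moves via the sigmoid-transfer velocity/position rules to form an
#' offspring population; and the best 50 percent of the combined parents +
#' offspring survive ([environmental_selection()]). An external archive accumulates
#' every rank-1 solution encountered, pruned to mutual non-domination.
#'
#' @param table A `distinction_table`.
#' @param config A [mobpso_config()]; when `config$seed` is set the run is
#'   fully reproducible.
#' @return A `pareto_archive` with attributes `config` and `trace` (a per
#'   generation data frame: population size, rank-1 count, best coverage,
#'   maximum absolute velocity, minimal cardinality attaining full cover).
#' @examples
#' d0 <- example_distinction_table()
#' arch <- run_mobpso(d0, mobpso_config(generations = 20, seed = 1))
#' arch
#' @export
run_mobpso <- function(table, config = mobpso_config()) {
  stopifnot(inherits(table, "distinction_table"),
            inherits(config, "mobpso_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- table$n_features
  p_size <- config$swarm_size
  swarm <- initialize_swarm(n, config)
  swarm <- lapply(swarm, evaluate_particle, table = table)
  archive <- new_pareto_archive(
    matrix(integer(), 0, n),
    matrix(numeric(), 0, 2, dimnames = list(NULL, c("fit1", "fit2"))),
    integer())
  archive <- absorb_rank1(archive, swarm, generation = 0L)
  trace <- vector("list", config$generations)

  for (g in seq_len(config$generations)) {
    swarm <- lapply(swarm, update_pbest)
    ranks <- non_dominated_sort(lapply(swarm,
                                       function(x) x$current_objectives))
    offspring <- lapply(swarm, function(particle) {
      # each particle draws its own guide from the rank-1 set: all
      # top-ranked solutions have equal priority, and independent draws
      # spread the pull across the whole current front
      gbest <- select_gbest(swarm, ranks)
      v <- update_velocity(particle, gbest, config)
      child <- particle
      child$velocity <- v
      child$position <- update_position(v)
      child$current_objectives <- NULL
      evaluate_particle(child, table)
    })
    combined <- c(swarm, offspring)
    archive <- absorb_rank1(archive, combined, generation = g)
    swarm <- environmental_selection(swarm, offspring, p_size)
    max_v <- max(abs(unlist(lapply(swarm, function(x) x$velocity))))
    full <- archive$objectives[, 2] == 1
    trace[[g]] <- data.frame(
      generation = g,
      population = length(swarm),
      n_rank1 = sum(non_dominated_sort(
        do.call(rbind, lapply(swarm, function(x) x$current_objectives))) == 1L),
      best_fit2 = max(archive$objectives[, 2]),
      max_abs_velocity = max_v,
      min_reduct_size = if (any(full)) {
        min(rowSums(archive$positions[full, , drop = FALSE]))
      } else NA_integer_)
  }
  attr(archive, "config") <- config
  attr(archive, "trace") <- do.call(rbind, trace)
  archive
}

evaluate_particle <- function(particle, table) {
  particle$current_objectives <- evaluate_pair(particle$position, table)
  if (is.null(particle$pbest_objectives)) {
    particle$pbest_objectives <- particle$current_objectives
  }
  particle
}

absorb_rank1 <- function(archive, particles, generation) {
  obj <- do.call(rbind, lapply(particles, function(x) x$current_objectives))
  ranks <- non_dominated_sort(obj)
  idx <- which(ranks == 1L)
  pos <- do.call(rbind, lapply(particles[idx], function(x) x$position))
  archive_update(archive, pos, obj[idx, , drop = FALSE], generation)
}

#' Exact Pareto front by exhaustive enumeration
#'
#' Enumerates all `2^N` feature subsets of a small distinction table,
#' evaluates both objectives, and returns the maximal non-dominated set of
#' objective pairs with one witness position each. Intended as an
#' independent optimality oracle for the swarm search; guarded to
#' `N <= 20`.
#'
#' @param table A `distinction_table` with at most 20 features.
#' @return A `pareto_archive`.
#' @export
exhaustive_pareto <- function(table) {
  stopifnot(inherits(table, "distinction_table"))
  n <- table$n_features
  if (n > 20L) {
    stop("exhaustive enumeration is limited to N <= 20 features",
         call. = FALSE)
  }
  subsets <- 0:(2^n - 1)
  row_masks <- apply(table$bits, 1L, function(row) {
    sum(2^(which(row == 1L) - 1L))
  })
  coverage <- integer(length(subsets))
  for (mask in row_masks) {
    coverage <- coverage + (bitwAnd(subsets, mask) != 0L)
  }
  card <- colSums(matrix(as.integer(intToBits(subsets)), nrow = 32L))
  # fit1 is a strictly decreasing function of cardinality, so the front is
  # the set of cardinalities whose best coverage strictly exceeds every
  # smaller cardinality's best
  best_cov <- vapply(0:n, function(k) {
    max(coverage[card == k])
  }, numeric(1))
  witness <- vapply(0:n, function(k) {
    subs <- subsets[card == k]
    subs[which.max(coverage[card == k])]
  }, numeric(1))
  on_front <- c(TRUE, vapply(seq_len(n), function(k) {
    best_cov[k + 1] > max(best_cov[seq_len(k)])
  }, logical(1)))
  ks <- (0:n)[on_front]
  positions <- vapply(witness[on_front], function(s) {
    as.integer(intToBits(s))[seq_len(n)]
  }, integer(n))
  positions <- if (n == 1L) matrix(positions, ncol = 1L) else t(positions)
  objectives <- cbind(fit1 = (n - ks) / n,
                      fit2 = best_cov[on_front] / table$n_rows)
  new_pareto_archive(positions, objectives, rep(NA_integer_, length(ks)))
}
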