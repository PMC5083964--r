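# Independent brute-force oracles and small fixture builders.

# row coverage by explicit row loop (independent of covered_rows)
brute_covered <- function(bits, position) {
  sel <- which(position == 1)
  n <- 0L
  for (r in seq_len(nrow(bits))) {
    if (length(sel) && any(bits[r, sel] == 1)) n <- n + 1L
  }
  n
}

# Pareto ranks by naive repeated peeling with pairwise dominates()
peel_ranks <- function(obj) {
  n <- nrow(obj)
  ranks <- rep(NA_integer_, n)
  r <- 1L
  while (anyNA(ranks)) {
    alive <- which(is.na(ranks))
    for (i in alive) {
      dominated <- FALSE
      for (j in alive) {
        if (j != i && dominates(obj[j, ], obj[i, ])) {
          dominated <- TRUE
          break
        }
      }
      if (!dominated) ranks[i] <- r
    }
    r <- r + 1L
  }
  ranks
}

# exact Pareto front of a small table as a set of objective-pair strings,
# by plain subset enumeration + peeling (independent of exhaustive_pareto)
brute_front_pairs <- function(table) {
  n <- table$n_features
  stopifnot(n <= 14)
  all_pos <- as.matrix(expand.grid(rep(list(0:1), n)))
  obj <- t(apply(all_pos, 1, function(p) {
    c((n - sum(p)) / n, brute_covered(table$bits, p) / table$n_rows)
  }))
  obj <- unique(obj)
  keep <- peel_ranks(obj) == 1L
  sort(apply(obj[keep, , drop = FALSE], 1, paste, collapse = "/"))
}

pair_key <- function(objectives) {
  sort(unique(apply(objectives, 1, paste, collapse = "/")))
}

random_distinction <- function(n_features, c1 = 2, c2 = 3, p = 0.35) {
  bits <- matrix(rbinom(c1 * c2 * n_features, 1, p), nrow = c1 * c2)
  distinction_table(bits, class_sizes = c(c1, c2))
}

# a fully-evaluated particle for swarm-operator tests
make_particle <- function(position, table, velocity = NULL) {
  if (is.null(velocity)) velocity <- rep(0, length(position))
  obj <- evaluate_pair(position, table)
  list(position = position, velocity = velocity,
       pbest_position = position, pbest_objectives = obj,
       current_objectives = obj)
}

tiny_dataset <- function() {
  expression_dataset(
    matrix(c(1, 2, 8, 9,
             7, 8, 1, 2,
             5, 5.5, 5.2, 5.1),
           nrow = 3, byrow = TRUE,
           dimnames = list(c("g1", "g2", "g3"),
                           c("s1", "s2", "s3", "s4"))),
    labels = c("A", "A", "B", "B"))
}
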