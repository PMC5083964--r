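test_that("dominance requires at-least-as-good everywhere plus one strict", {
  expect_true(dominates(c(0.5, 0.5), c(0.2, 0.2)))
  expect_false(dominates(c(1, 0), c(0, 1)))
  expect_false(dominates(c(0.5, 0.5), c(0.5, 0.5)))
  expect_true(dominates(c(0.5, 0.5), c(0.5, 0.2)))
})

test_that("non-dominated sorting matches the peeling oracle", {
  expect_equal(non_dominated_sort(rbind(c(1, 0), c(0, 1), c(0.5, 0.5))),
               c(1, 1, 1))
  expect_equal(non_dominated_sort(rbind(c(0.5, 0.5), c(0.2, 0.2))),
               c(1, 2))
  set.seed(51)
  for (rep in 1:30) {
    obj <- matrix(runif(2 * sample(3:30, 1)), ncol = 2)
    expect_equal(non_dominated_sort(obj), peel_ranks(obj))
  }
  # duplicated objective pairs share a rank
  obj <- rbind(c(0.4, 0.4), c(0.4, 0.4), c(0.1, 0.1))
  expect_equal(non_dominated_sort(obj), c(1, 1, 2))
})

test_that("swarm initialization is seeded and unbiased", {
  cfg <- mobpso_config(swarm_size = 4)
  set.seed(7)
  a <- initialize_swarm(10, cfg)
  set.seed(7)
  b <- initialize_swarm(10, cfg)
  expect_identical(a, b)
  set.seed(8)
  c_ <- initialize_swarm(10, cfg)
  expect_false(identical(lapply(a, `[[`, "position"),
                         lapply(c_, `[[`, "position")))
  expect_true(all(vapply(a, function(p)
    all(p$velocity >= -1 & p$velocity <= 1), TRUE)))

  set.seed(9)
  big <- initialize_swarm(500, mobpso_config(swarm_size = 20))
  bits <- unlist(lapply(big, `[[`, "position"))
  expect_gte(mean(bits), 0.47)
  expect_lte(mean(bits), 0.53)
})

test_that("velocity updates follow the canonical clamped rule", {
  cfg <- mobpso_config()
  d0 <- example_distinction_table()
  p <- make_particle(c(1, 0, 1, 1, 0, 1, 1), d0,
                     velocity = rep(0.5, 7))
  # pbest = gbest = x: pure inertia
  expect_equal(update_velocity(p, p$position, cfg), rep(0.9 * 0.5, 7))
  # out-of-clamp inertia input is clamped after the update
  p$velocity <- rep(5, 7)
  expect_equal(update_velocity(p, p$position, cfg), rep(4, 7))
  # forced r1 = r2 = 1, x = 0, pbest = gbest = 1: v = c1 + c2 = 4
  q <- make_particle(rep(0L, 7), d0)
  q$pbest_position <- rep(1L, 7)
  expect_equal(update_velocity(q, rep(1L, 7), cfg,
                               r1 = rep(1, 7), r2 = rep(1, 7)),
               rep(4, 7))
  expect_error(update_velocity(q, c(1, 0), cfg), "dimensions")
})

test_that("the sigmoid transfer drives position sampling", {
  set.seed(52)
  f0 <- mean(replicate(200, mean(update_position(rep(0, 50)))))
  expect_gte(f0, 0.47)
  expect_lte(f0, 0.53)
  fmax <- mean(replicate(200, mean(update_position(rep(4, 50)))))
  expect_gte(fmax, 0.978)  # S(4) = 0.9820 +- 3 sigma over 10^4 draws
  expect_lte(fmax, 0.986)
  fmin <- mean(replicate(200, mean(update_position(rep(-4, 50)))))
  expect_gte(fmin, 0.014)  # S(-4) = 1 - S(4)
  expect_lte(fmin, 0.022)
  expect_error(update_position(c(0, Inf)), "finite")
})

test_that("personal bests update under dominance with a coin for ties", {
  d0 <- example_distinction_table()
  p <- make_particle(rep(1L, 7), d0)       # (0, 1)
  p$pbest_position <- rep(0L, 7)
  p$pbest_objectives <- c(fit1 = 0.1, fit2 = 0.1)
  p$current_objectives <- c(fit1 = 0.5, fit2 = 0.5)
  expect_equal(update_pbest(p)$pbest_objectives,
               c(fit1 = 0.5, fit2 = 0.5))
  p$current_objectives <- c(fit1 = 0.05, fit2 = 0.05)
  expect_equal(update_pbest(p)$pbest_objectives,
               c(fit1 = 0.1, fit2 = 0.1))
  p$current_objectives <- c(fit1 = 0.05, fit2 = 0.9)  # incomparable
  expect_equal(update_pbest(p, coin = TRUE)$pbest_objectives,
               c(fit1 = 0.05, fit2 = 0.9))
  expect_equal(update_pbest(p, coin = FALSE)$pbest_objectives,
               c(fit1 = 0.1, fit2 = 0.1))
})

test_that("the guide is drawn uniformly from the rank-1 set", {
  d0 <- example_distinction_table()
  solo <- list(make_particle(c(1, 1, 1, 1, 0, 0, 1), d0))
  expect_equal(select_gbest(solo), c(1, 1, 1, 1, 0, 0, 1))

  pop <- list(make_particle(c(1, 0, 0, 0, 0, 0, 0), d0),  # (6/7, 1/6)
              make_particle(c(1, 1, 1, 1, 0, 0, 1), d0),  # (2/7, 1)
              make_particle(c(0, 0, 0, 0, 0, 0, 0), d0),  # (1, 0)
              make_particle(c(0, 0, 1, 1, 0, 1, 0), d0))  # dominated by [1]
  ranks <- non_dominated_sort(do.call(rbind,
    lapply(pop, `[[`, "current_objectives")))
  expect_equal(ranks, c(1, 1, 1, 2))
  set.seed(53)
  picks <- replicate(3000, paste(select_gbest(pop, ranks), collapse = ""))
  freq <- table(picks) / 3000
  expect_equal(length(freq), 3)  # the rank-2 member is never picked
  expect_true(all(abs(freq - 1 / 3) < 0.03))
  expect_error(select_gbest(list()), "empty")
})

test_that("environmental selection keeps the best half, size-exactly", {
  d0 <- example_distinction_table()
  good <- lapply(1:4, function(i) make_particle(c(1, 1, 1, 1, 0, 0, 1), d0))
  bad <- lapply(1:4, function(i) make_particle(c(0, 0, 0, 0, 1, 0, 0), d0))
  surv <- environmental_selection(good, bad)
  expect_equal(length(surv), 4)
  expect_true(all(vapply(surv, function(p)
    identical(p$position, c(1, 1, 1, 1, 0, 0, 1)), TRUE)))

  # 2P mutually non-dominated: exactly P kept by the documented tie-break
  set.seed(54)
  pts <- cbind(seq(0, 1, length.out = 12), seq(1, 0, length.out = 12))
  pop <- lapply(seq_len(12), function(i) {
    p <- make_particle(rbinom(7, 1, 0.5), d0)
    p$current_objectives <- pts[i, ]
    p
  })
  surv <- environmental_selection(pop[1:6], pop[7:12])
  expect_equal(length(surv), 6)
  kept <- do.call(rbind, lapply(surv, `[[`, "current_objectives"))
  expect_equal(sort(kept[, 2], decreasing = TRUE),
               sort(pts[, 2], decreasing = TRUE)[1:6])

  # random population matches an oracle that peels then tie-breaks
  for (rep in 1:10) {
    pop <- lapply(seq_len(12), function(i) make_particle(rbinom(7, 1, 0.5), d0))
    obj <- do.call(rbind, lapply(pop, `[[`, "current_objectives"))
    ranks <- peel_ranks(obj)
    ord <- order(ranks, -obj[, 2], -obj[, 1], seq_len(12))
    surv <- environmental_selection(pop[1:6], pop[7:12])
    expect_identical(surv, pop[ord[1:6]])
  }
})

test_that("the swarm recovers the exact Pareto front of the example table", {
  d0 <- example_distinction_table()
  arch <- run_mobpso(d0, mobpso_config(seed = 101))
  expect_equal(pair_key(arch$objectives), pair_key(exhaustive_pareto(d0)$objectives))
})

test_that("a single coverable row forces the one-feature reduct", {
  t1 <- distinction_table(matrix(c(0, 1, 0), nrow = 1))
  arch <- run_mobpso(t1, mobpso_config(generations = 10, seed = 5))
  full <- arch$objectives[, 2] == 1
  expect_true(any(full))
  expect_equal(min(rowSums(arch$positions[full, , drop = FALSE])), 1)
})

test_that("runs are bit-identical under a fixed seed", {
  d0 <- example_distinction_table()
  cfg <- mobpso_config(generations = 15, seed = 77)
  a <- run_mobpso(d0, cfg)
  b <- run_mobpso(d0, cfg)
  expect_identical(a$positions, b$positions)
  expect_identical(a$objectives, b$objectives)
  expect_identical(attr(a, "trace"), attr(b, "trace"))
})

test_that("per-generation invariants hold: size, clamp, non-dominated archive", {
  set.seed(55)
  tbl <- random_distinction(n_features = 9, c1 = 3, c2 = 4)
  arch <- run_mobpso(tbl, mobpso_config(generations = 30, seed = 6))
  trace <- attr(arch, "trace")
  expect_equal(trace$population, rep(20, 30))
  expect_true(all(trace$max_abs_velocity <= 4 + 1e-12))
  # best archived coverage never decreases across generations
  expect_true(all(diff(trace$best_fit2) >= 0))
  # archive is mutually non-dominated
  expect_true(all(peel_ranks(arch$objectives) == 1))
  # archived positions are unique
  keys <- apply(arch$positions, 1, paste, collapse = "")
  expect_equal(anyDuplicated(keys), 0)
})

test_that("exhaustive enumeration reproduces a brute-force front", {
  d0 <- example_distinction_table()
  ex <- exhaustive_pareto(d0)
  expect_equal(pair_key(ex$objectives), brute_front_pairs(d0))
  # front includes the empty set and full coverage at cardinality 5
  expect_true("1/0" %in% pair_key(ex$objectives))
  cards <- rowSums(ex$positions)
  expect_equal(min(cards[ex$objectives[, 2] == 1]), 5)
  # witness positions attain their recorded objectives
  for (i in seq_len(nrow(ex$positions))) {
    expect_equal(unname(evaluate_pair(ex$positions[i, ], d0)),
                 unname(ex$objectives[i, ]))
  }

  t1 <- distinction_table(matrix(1, nrow = 1, ncol = 1))
  ex1 <- exhaustive_pareto(t1)
  expect_equal(pair_key(ex1$objectives), c("0/1", "1/0"))

  big <- distinction_table(matrix(1, nrow = 1, ncol = 21))
  expect_error(exhaustive_pareto(big), "N <= 20")
})

test_that("random small instances: the swarm attains the exhaustive front", {
  set.seed(56)
  hits <- 0
  for (rep in 1:10) {
    tbl <- random_distinction(n_features = sample(5:10, 1),
                              c1 = sample(2:3, 1), c2 = sample(2:4, 1))
    arch <- run_mobpso(tbl, mobpso_config(seed = 500 + rep))
    if (identical(pair_key(arch$objectives),
                  pair_key(exhaustive_pareto(tbl)$objectives))) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})
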