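test_that("min-max normalization maps each gene onto [0, 1]", {
  ds <- expression_dataset(matrix(c(2, 4, 6,
                                    0.1, 0.9, 0.5,
                                    5, 5, 5),
                                  nrow = 3, byrow = TRUE,
                                  dimnames = list(c("g1", "g2", "g3"), NULL)),
                           labels = c("A", "A", "B"))
  norm <- normalize_minmax(ds)
  expect_equal(unname(norm$values["g1", ]), c(0, 0.5, 1))
  expect_equal(unname(norm$values["g2", ]), c(0, 1, 0.5))
  expect_false("g3" %in% rownames(norm$values))
  expect_equal(attr(norm, "dropped_constant"), "g3")

  v4 <- expression_dataset(matrix(c(0.1, 0.9, 0.5, 0.3), 1,
                                  dimnames = list("g", NULL)),
                           labels = c("A", "A", "B", "B"))
  expect_equal(unname(normalize_minmax(v4)$values[1, ]),
               c(0, 1, 0.5, 0.25))

  all_const <- expression_dataset(matrix(c(1, 1, 2, 2), 2, byrow = TRUE),
                                  labels = c("A", "B"))
  expect_error(normalize_minmax(all_const), "constant")
})

test_that("normalization preserves per-gene value ordering", {
  set.seed(11)
  for (rep in 1:20) {
    x <- runif(15, -3, 7)
    ds <- expression_dataset(matrix(x, 1), labels = rep(c("A", "B"), c(7, 8)))
    norm <- normalize_minmax(ds)
    expect_equal(cor(x, norm$values[1, ], method = "spearman"), 1)
  }
})

test_that("the grouped-frequency grid bins values as specified", {
  g <- build_quartile_grid(c(0.05, 0.15, 0.95), n_intervals = 10)
  expect_equal(g$freq, c(1, 1, 0, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(tail(g$cum_freq, 1), 3)

  # value exactly 1.0 falls in the last (closed) interval
  g1 <- build_quartile_grid(c(0.2, 1.0), n_intervals = 5)
  expect_equal(g1$freq, c(0, 1, 0, 0, 1))

  g2 <- build_quartile_grid(c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9),
                            n_intervals = 4)
  expect_equal(g2$freq, c(2, 2, 2, 2))
  expect_equal(g2$delta, 0.25)

  expect_error(build_quartile_grid(c(0.5, 1.2)), "outside")
})

test_that("partition values interpolate within the containing interval", {
  g <- build_quartile_grid(c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9),
                           n_intervals = 4)
  # R_1 = 2 -> interval 1: 0 + (2/2) * 0.25
  expect_equal(partition_value(g, 1), 0.25)
  # R_3 = 6 -> interval 3: 0.5 + ((6-4)/2) * 0.25
  expect_equal(partition_value(g, 3), 0.75)

  # all mass inside one interval: result stays inside it
  g_one <- build_quartile_grid(rep(0.55, 9), n_intervals = 10)
  p <- partition_value(g_one, 2)
  expect_gte(p, 0.5)
  expect_lte(p, 0.6)
})

test_that("partition values are nondecreasing in k and close to sample quantiles", {
  set.seed(21)
  for (rep in 1:200) {
    # monotonicity and range hold for any sample size
    vals <- runif(sample(5:60, 1))
    g <- build_quartile_grid(vals, n_intervals = 10)
    ps <- vapply(1:3, partition_value, 0, grid = g)
    expect_true(all(diff(ps) >= 0))
    expect_true(all(ps >= 0 & ps <= 1))
  }
  for (rep in 1:200) {
    # agreement with sort-based quantiles needs enough values that no
    # class interval around the quartile ranks is empty; 40+ samples
    # (the microarray regime) is comfortably dense for a decile grid
    vals <- runif(sample(40:200, 1))
    g <- build_quartile_grid(vals, n_intervals = 10)
    ps <- vapply(1:3, partition_value, 0, grid = g)
    emp <- quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
    expect_true(all(abs(ps - emp) <= g$delta + 1e-12))
  }
})

test_that("ternarization applies the low-first threshold rule", {
  ds <- expression_dataset(matrix(c(0.1, 0.5, 0.9, 0.25), 1),
                           labels = rep(c("A", "B"), 2))
  tt <- ternarize(ds, th_low = 0.25, th_high = 0.75)
  expect_equal(unname(tt$symbols[1, ]), c(0L, NA, 1L, 0L))
  expect_equal(unname(tt$star_counts), 1)

  # Th_i == Th_f: the <= branch wins on the boundary
  tie <- ternarize(ds, th_low = 0.5, th_high = 0.5)
  expect_equal(unname(tie$symbols[1, 2]), 0L)

  expect_error(ternarize(ds, th_low = 0.8, th_high = 0.2), "Th_i")
})

test_that("ambiguity filtering removes genes at or above the mean star count", {
  sym <- matrix(c(0L, 1L, 0L, 1L,
                  NA, 0L, 1L, NA,
                  NA, NA, NA, NA),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  tt <- mobpso:::new_ternary_table(sym, rep(0.2, 3), rep(0.8, 3), 1:3)
  expect_equal(unname(tt$star_counts), c(0, 2, 4))
  out <- filter_ambiguous(tt)  # Th_a = 2 -> only g1 survives
  expect_equal(out$gene_ids, "g1")
  expect_equal(out$kept_gene_indices, 1L)
  expect_equal(out$log$th_a, 2)

  sym2 <- sym[1:2, ]
  sym2[1, 1] <- NA  # star counts (1, 2)? craft (1, 5) instead below
  tt15 <- mobpso:::new_ternary_table(
    matrix(c(NA, rep(0L, 5), rep(NA, 5), 1L), nrow = 2, byrow = TRUE),
    rep(0.2, 2), rep(0.8, 2), 1:2)
  expect_equal(unname(tt15$star_counts), c(1, 5))
  expect_equal(nrow(filter_ambiguous(tt15)$symbols), 1)  # Th_a = 3

  all_zero <- mobpso:::new_ternary_table(
    matrix(0L, 3, 4), rep(0.2, 3), rep(0.8, 3), 1:3)
  expect_error(filter_ambiguous(all_zero), "n_intervals")
})

test_that("filtering never increases star counts or gene count; singletons pass", {
  sim <- generate_dataset(synthetic_spec(seed = 5, mode = "noisy"))
  norm <- normalize_minmax(sim$dataset)
  tt <- ternarize(norm, 0.25, 0.75)
  out <- filter_ambiguous(tt)
  expect_lte(nrow(out$symbols), nrow(tt$symbols))
  expect_true(all(out$star_counts <= max(tt$star_counts)))

  single <- mobpso:::new_ternary_table(
    matrix(c(0L, NA, 1L), 1), 0.2, 0.8, 1L)
  expect_identical(filter_ambiguous(single), single)
})

test_that("the pipeline is idempotent under re-normalization and keeps planted genes", {
  sim <- generate_dataset(synthetic_spec(seed = 3))
  once <- preprocess_pipeline(sim$dataset)
  renorm <- normalize_minmax(sim$dataset)
  twice <- preprocess_pipeline(renorm)
  expect_equal(once$symbols[once$gene_ids %in% twice$gene_ids, ],
               twice$symbols[twice$gene_ids %in% once$gene_ids, ])

  # planted informative genes survive with zero don't-cares
  expect_true(all(sim$informative %in% once$gene_ids))
  expect_equal(unname(once$star_counts[sim$informative]), rep(0, 3))
})
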