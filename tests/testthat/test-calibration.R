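test_that("the multiplier grid specification parses to 17 unique values", {
  m <- parse_multipliers("0.1-1 by 0.1; 1-6 by 1; 8; 10")
  expect_length(m, 17L)
  expect_equal(m, c(seq(0.1, 1, by = 0.1), 2:6, 8, 10))
  expect_identical(default_multipliers(), m)
  # the overlapping endpoint 1 is deduplicated; en dashes accepted
  expect_length(parse_multipliers("1-3 by 1; 3-5 by 1"), 5L)
  expect_error(parse_multipliers("abc"), "cannot parse")
  expect_error(parse_multipliers(" ; "), "empty")
})

test_that("feature-class combinations enumerate all 31 non-empty subsets", {
  cc <- feature_class_combos()
  expect_length(cc, 31L)
  expect_identical(anyDuplicated(names(cc)), 0L)
  expect_identical(cc[["lq"]], c("linear", "quadratic"))
  expect_identical(sort(nchar(names(cc))), sort(unname(lengths(cc))))
})

test_that("candidate enumeration is a stable cartesian product", {
  combos <- feature_class_combos()
  one <- enumerate_candidates(combos["lq"], default_multipliers(),
                              list(a = "x", b = "y", c = "z"))
  expect_identical(nrow(one), 51L)  # 1 x 17 x 3
  all31 <- enumerate_candidates(combos, default_multipliers(),
                                list(a = "x", b = "y", c = "z"))
  expect_identical(nrow(all31), 1581L)  # 31 x 17 x 3
  expect_identical(all31$candidate_id, seq_len(1581L))
  # ordering: varset varies slowest, multiplier fastest
  expect_identical(unique(all31$varset), c("a", "b", "c"))
  expect_identical(all31$multiplier[1:17], default_multipliers())
  expect_error(enumerate_candidates(list(), 1, list(a = "x")), "non-empty")
})

test_that("partial ROC detects signal and handles degenerate grids", {
  env <- simulate_climate(25, 25, c("x", "y"), smoothness = 3, seed = 71)
  sp <- virtual_species(env, "x", optima = 0.3, breadths = 0.8)
  truth <- as.vector(sp$truth)
  set.seed(72)
  cells <- sample(length(truth), 150, prob = truth, replace = TRUE)
  pr <- partial_roc(truth[cells], truth, E = 0.05, n_boot = 500, seed = 73)
  expect_gt(pr$mean_auc_ratio, 1)
  expect_lt(pr$proc_p, 0.05)
  # a constant grid cannot be ranked: marked non-significant
  flat <- partial_roc(rep(0.5, 20), rep(0.5, 100))
  expect_true(is.na(flat$mean_auc_ratio))
  expect_identical(flat$proc_p, 1)
  # the ratio is defined across the E domain range
  for (E in c(0.05, 0.49)) {
    r <- partial_roc(truth[cells], truth, E = E, n_boot = 50, seed = 1)
    expect_true(is.finite(r$mean_auc_ratio))
  }
  expect_error(partial_roc(truth[cells][1:5], truth), "at least 10")
})

test_that("partial ROC is reproducible under a fixed seed", {
  set.seed(3)
  grid <- runif(400)
  test <- sample(grid, 40)
  a <- partial_roc(test, grid, seed = 11, n_boot = 100)
  b <- partial_roc(test, grid, seed = 11, n_boot = 100)
  expect_identical(a, b)
})

test_that("omission threshold follows the order-statistic rule", {
  cal <- seq(0.1, 1, by = 0.1)
  om <- omission_rate(cal, c(0.05, 0.5), E = 0.05)
  expect_equal(om$threshold, 0.1)  # ceiling(0.05 * 10) = 1st smallest
  expect_equal(om$rate, 0.5)       # 0.05 below, 0.5 retained (not strictly below)
  # evaluating on the calibration data itself cannot exceed E
  self <- omission_rate(cal, cal, E = 0.25)
  expect_lte(self$rate, 0.25)
  # evaluation all above the calibration maximum: zero omission
  expect_equal(omission_rate(cal, c(1.5, 2))$rate, 0)
  # equality with the threshold is retained
  expect_equal(omission_rate(cal, c(0.1, 0.1))$rate, 0)
})

test_that("AICc follows the corrected-likelihood formula", {
  # uniform model (k = 0) on a G-cell grid: lnL = -n log G
  G <- 250
  n <- 12
  uni <- compute_aicc(list(k = 0L), rep(1 / G, n), 1)
  expect_equal(uni$aicc, 2 * n * log(G), tolerance = 1e-12)
  # singular correction at k >= n - 1
  expect_identical(compute_aicc(list(k = 11L), rep(1 / G, n), 1)$aicc, Inf)
  # zero raw score at an occurrence invalidates the likelihood
  expect_message(
    z <- compute_aicc(list(k = 2L), c(0.2, 0, 0.1, 0.3, 0.4), 1), "zero raw")
  expect_identical(z$aicc, Inf)
  # hand-built toy model against a brute-force log-sum oracle
  set.seed(74)
  raw <- runif(5, 0.001, 0.01)
  gsum <- 2.37
  k <- 3L
  got <- compute_aicc(list(k = k), raw, gsum)
  lnl <- sum(log(raw / gsum))
  expect_equal(got$aicc, 2 * k - 2 * lnl + 2 * k * (k + 1) / (5 - k - 1),
               tolerance = 1e-9)
})

test_that("model selection applies the three sequential filters", {
  res <- tibble::tibble(
    candidate_id = 1:6,
    varset = "v", classes = "lq", multiplier = 1,
    proc_p = c(0.001, 0.001, 0.2, 0.001, 0.001, 0.001),
    omission = c(0.01, 0.04, 0.01, 0.10, 0.02, 0.02),
    aicc = c(100, 101.5, 90, 80, 103, 101.5))
  sel <- select_models(res, alpha = 0.05, omission_max = 0.05, delta_max = 2)
  # cand 3 fails significance, cand 4 fails omission, 5 fails delta AICc
  expect_setequal(sel$candidate_id, c(1, 2, 6))
  expect_equal(min(sel$delta_aicc), 0)
  expect_true(all(sel$delta_aicc <= 2))
  # exact AICc ties are both kept
  expect_equal(sort(sel$delta_aicc), c(0, 1.5, 1.5))
  # single surviving candidate selects itself with delta 0
  one <- select_models(res[1, ])
  expect_identical(nrow(one), 1L)
  expect_equal(one$delta_aicc, 0)
  # empty selection is a report, not an error
  expect_message(none <- select_models(res[3:4, ]), "no candidate survives")
  expect_identical(nrow(none), 0L)
})

test_that("selection equals a brute-force filter oracle on random tables", {
  set.seed(75)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    res <- tibble::tibble(
      candidate_id = seq_len(n),
      varset = "v", classes = "x", multiplier = 1,
      proc_p = round(runif(n), 2),
      omission = round(runif(n, 0, 0.2), 2),
      aicc = round(runif(n, 100, 120), 1))
    sel <- suppressMessages(select_models(res, 0.05, 0.05, 2))
    # oracle: three independent passes
    o <- res[res$proc_p < 0.05, ]
    o <- o[o$omission <= 0.05, ]
    keep <- if (nrow(o)) o[o$aicc - min(o$aicc) <= 2, ] else o
    expect_setequal(sel$candidate_id, keep$candidate_id)
    # input order invariance
    perm <- res[sample.int(n), ]
    sel2 <- suppressMessages(select_models(perm, 0.05, 0.05, 2))
    expect_setequal(sel2$candidate_id, sel$candidate_id)
  }
})

test_that("candidate evaluation returns one tidy row per configuration", {
  w <- make_world(n = 20, seed = 77, n_occ = 160)
  env <- w$env
  occ <- suppressMessages(clean_occurrences(w$occ, 10000, 20, seed = 1))
  halves <- split_half(occ, seed = 2)
  bg <- stack_values(env)
  cal <- extract_values(env, halves$calibration)
  ev <- extract_values(env, halves$evaluation)
  combos <- feature_class_combos()[c("l", "lq")]
  varsets <- list(s2 = c("t1", "p1"), s4 = names(env$layers))
  cands <- enumerate_candidates(combos, c(0.5, 2), varsets)
  res <- calibrate_candidates(cands, varsets, combos, cal, ev, bg,
                              n_boot = 100, seed = 5)
  expect_identical(nrow(res), 8L)
  expect_true(all(c("mean_auc_ratio", "proc_p", "omission", "threshold",
                    "k", "aicc", "converged") %in% names(res)))
  expect_true(all(res$omission >= 0 & res$omission <= 1))
  expect_true(all(res$k <= 4 + 4 + 0 + 0 + 10))
  expect_true(all(is.finite(res$aicc) | res$k >= nrow(cal) - 1))
  # determinism: same seed reproduces the table
  res2 <- calibrate_candidates(cands, varsets, combos, cal, ev, bg,
                               n_boot = 100, seed = 5)
  expect_identical(res, res2)
})
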