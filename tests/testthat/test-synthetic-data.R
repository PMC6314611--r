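test_that("simulated climate layers are standardized, autocorrelated and reproducible", {
  env <- simulate_climate(50, 50, c("t1", "t2", "p1", "p2"), smoothness = 5,
                          seed = 1)
  expect_s3_class(env, "env_stack")
  expect_identical(dim(env), c(50L, 50L))
  for (v in names(env$layers)) {
    expect_equal(sd(as.vector(env$layers[[v]])), 1, tolerance = 1e-10)
    expect_equal(mean(env$layers[[v]]), 0, tolerance = 1e-10)
  }
  # spatial autocorrelation: horizontally adjacent cells strongly correlated
  l <- env$layers[["t1"]]
  expect_gt(cor(as.vector(l[, -1]), as.vector(l[, -50])), 0.6)

  env2 <- simulate_climate(50, 50, c("t1", "t2", "p1", "p2"), smoothness = 5,
                           seed = 1)
  expect_identical(env$layers, env2$layers)
  env3 <- simulate_climate(50, 50, c("t1", "t2", "p1", "p2"), smoothness = 5,
                           seed = 2)
  expect_false(identical(env$layers, env3$layers))
})

test_that("very large smoothness approaches the pure latitudinal gradient", {
  env <- simulate_climate(20, 20, c("a", "b"), smoothness = 200, seed = 3)
  l <- env$layers[["a"]]
  # neighbour correlation approaches 1 in both directions
  expect_gt(cor(as.vector(l[-1, ]), as.vector(l[-20, ])), 0.999)
  expect_gt(cor(as.vector(l[, -1]), as.vector(l[, -20])), 0.999)
})

test_that("degenerate grids and bad inputs are rejected", {
  expect_error(simulate_climate(5, 50, c("a", "b"), seed = 1), "at least 10")
  expect_error(simulate_climate(50, 9, c("a", "b"), seed = 1), "at least 10")
  expect_error(simulate_climate(20, 20, "only_one", seed = 1), "two variables")
})

test_that("virtual species truth follows the Gaussian product response", {
  env <- simulate_climate(20, 20, c("x", "y"), smoothness = 3, seed = 7)
  sp <- virtual_species(env, "x", optima = 0.4, breadths = 0.5)
  expect_true(all(sp$truth >= 0 & sp$truth <= 1, na.rm = TRUE))
  expect_equal(max(sp$truth, na.rm = TRUE), 1)
  # closed form per cell: exp(-(x - opt)^2 / (2 b^2)) / max-rescale
  raw <- exp(-(env$layers[["x"]] - 0.4)^2 / (2 * 0.5^2))
  expect_equal(sp$truth, raw / max(raw), tolerance = 1e-12)
  # a cell at distance exactly one breadth scores exp(-1/2) before rescale
  i <- which.min(abs(env$layers[["x"]] - (0.4 + 0.5)))
  expect_equal(sp$truth[i], exp(-(env$layers[["x"]][i] - 0.4)^2 / 0.5) /
                 max(raw), tolerance = 1e-12)
})

test_that("infinite breadth saturates truth at 1 and errors are raised", {
  env <- simulate_climate(15, 15, c("x", "y"), smoothness = 3, seed = 8)
  sp <- virtual_species(env, c("x", "y"), optima = c(0, 0),
                        breadths = c(1e9, 1e9))
  expect_true(all(abs(sp$truth - 1) < 1e-9, na.rm = TRUE))
  expect_error(virtual_species(env, "nope", 0, 1), "unknown variable")
  expect_error(virtual_species(env, "x", 0, -1), "positive")
})

test_that("occurrence sampling is proportional to truth and deterministic", {
  w <- make_world(n = 20, seed = 11, n_occ = 6000)
  occ <- w$occ
  expect_tibble(occ)
  expect_identical(nrow(occ), 6000L)
  # records must fall inside the grid
  expect_true(all(occ$longitude >= w$env$xmin &
                    occ$longitude <= w$env$xmin + 20 * w$env$cellsize))
  # cell frequencies correlate with truth
  cells <- extract_values(w$env, occ)$.cell
  counts <- tabulate(cells, nbins = 400)
  expect_gt(cor(counts, as.vector(w$sp$truth)), 0.9)
  occ2 <- sample_occurrences(w$sp, 6000, seed = 12)
  expect_identical(occ, occ2)
})

test_that("occurrence density converges to the truth distribution", {
  w <- make_world(n = 20, seed = 13, n_occ = 1)
  n <- 10000
  occ <- sample_occurrences(w$sp, n, seed = 99)
  cells <- extract_values(w$env, occ)$.cell
  p <- as.vector(w$sp$truth)
  p <- p / sum(p)
  counts <- tabulate(cells, nbins = 400)
  # chi-square GOF on cells with adequate expected counts
  keep <- n * p >= 5
  chi <- sum((counts[keep] - n * p[keep])^2 / (n * p[keep]))
  pval <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("degenerate truth support concentrates all samples in one cell", {
  env <- simulate_climate(12, 12, c("x", "y"), smoothness = 2, seed = 5)
  sp <- virtual_species(env, "x", optima = 0, breadths = 1)
  sp$truth[] <- 0
  sp$truth[77] <- 1
  occ <- sample_occurrences(sp, 50, seed = 1)
  expect_true(all(extract_values(env, occ)$.cell == 77))
  sp$truth[] <- 0
  expect_error(sample_occurrences(sp, 10, seed = 1), "positive suitability")
})

test_that("uncertainty law straddles the 10 km filter cutoff", {
  set.seed(1)
  u <- default_uncertainty_law(20000)
  expect_lt(abs(median(u) / 5000 - 1), 0.05)
  expect_lt(abs(mean(u > 10000) - 0.1), 0.015)
})

test_that("pseudo-GCM future scenarios shift the present stack coherently", {
  env <- simulate_climate(15, 15, c("a", "b"), smoothness = 3, seed = 21)
  deltas <- list(low = c(a = 0.4, b = -0.1), high = c(a = 1.1, b = -0.4))
  scen <- simulate_futures(env, n_gcm = 4, scenario_deltas = deltas, seed = 5)
  expect_length(scen$futures, 8L)  # 4 GCMs x 2 scenarios
  # stronger scenario shifts every variable strictly more, per GCM
  for (g in 1:4) {
    lo <- scen$futures[[paste0("gcm", g, ".low")]]
    hi <- scen$futures[[paste0("gcm", g, ".high")]]
    expect_gt(mean(hi$layers[["a"]] - env$layers[["a"]]),
              mean(lo$layers[["a"]] - env$layers[["a"]]))
    expect_lt(mean(hi$layers[["b"]] - env$layers[["b"]]),
              mean(lo$layers[["b"]] - env$layers[["b"]]))
  }
  # zero deltas and zero perturbation reproduce the present exactly
  ident <- simulate_futures(env, n_gcm = 2,
                            scenario_deltas = list(s = c(a = 0, b = 0)),
                            perturb_sd = 0, seed = 5)
  for (f in ident$futures) expect_equal(f$layers, env$layers)
  expect_error(
    simulate_futures(env, 2, list(s = c(a = 1))), "every stack variable")
})
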