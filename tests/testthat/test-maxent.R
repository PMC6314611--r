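# small 1-D-friendly dataset builders used across maxent tests
make_linear_world <- function(n_bg = 400, n_pr = 80, slope = 2, seed = 1) {
  set.seed(seed)
  bg <- cbind(x = runif(n_bg))
  p <- exp(slope * bg[, "x"])
  pr <- cbind(x = bg[sample.int(n_bg, n_pr, replace = TRUE, prob = p), "x"])
  list(bg = bg, pr = pr)
}

test_that("feature expansion produces the documented column sets", {
  set.seed(1)
  bg <- matrix(runif(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  pr <- bg[1:30, ]
  spec_l <- build_feature_spec(bg[, 1:2], pr[, 1:2], "linear")
  expect_identical(ncol(expand_features(bg[, 1:2], spec_l)), 2L)
  spec_lqp <- build_feature_spec(bg, pr, c("linear", "quadratic", "product"))
  f <- expand_features(bg, spec_lqp)
  expect_identical(ncol(f), 9L)  # 3 linear + 3 quadratic + 3 pairwise products
  expect_identical(
    as.vector(table(spec_lqp$feat_class)[c("linear", "product", "quadratic")]),
    c(3L, 3L, 3L))
  # hinge: forward + reverse columns at each of 5 knots on one variable
  spec_h <- build_feature_spec(bg[, 1, drop = FALSE], pr[, 1, drop = FALSE],
                               "hinge", n_hinge = 5)
  expect_identical(ncol(expand_features(bg[, 1, drop = FALSE], spec_h)), 10L)
  # thresholds: 10 step functions per variable by default
  spec_t <- build_feature_spec(bg[, 1, drop = FALSE], pr[, 1, drop = FALSE],
                               "threshold")
  expect_identical(ncol(expand_features(bg[, 1, drop = FALSE], spec_t)), 10L)
  # all features live in [0, 1] on the background
  f_all <- expand_features(bg, build_feature_spec(
    bg, pr, c("linear", "quadratic", "product", "threshold", "hinge")))
  expect_true(all(f_all >= 0 & f_all <= 1 + 1e-12))
})

test_that("constant variables are excluded with a warning", {
  bg <- cbind(a = runif(50), flat = rep(1, 50))
  pr <- bg[1:10, ]
  expect_warning(spec <- build_feature_spec(bg, pr, "linear"), "constant")
  expect_identical(spec$vars, "a")
})

test_that("no-signal data shrink coefficients and maximize entropy", {
  set.seed(2)
  bg <- cbind(x = runif(500), y = runif(500))
  pr <- bg[sample.int(500, 100), ]  # presences = uniform draw from background
  fit <- fit_maxent(pr, bg, classes = c("linear", "quadratic"),
                    beta_multiplier = 1)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$lambdas)), 1)
  expect_gt(fit$entropy, 0.995 * log(500))  # near-uniform density
  expect_lt(abs(fit$gain), 0.05)
})

test_that("fitted coefficient matches an independent convex-solver oracle", {
  w <- make_linear_world(seed = 3)
  fit <- fit_maxent(w$pr, w$bg, classes = "linear", beta_multiplier = 1)
  expect_true(fit$converged)
  expect_gt(fit$lambdas[["lin_x"]], 0)  # presences concentrate at high x
  # oracle: generic quasi-Newton on the same penalized likelihood with a
  # smoothed |lambda| (fit_maxent itself never calls optim)
  spec <- fit$spec
  f_pr <- expand_features(w$pr, spec)
  f_bg <- expand_features(w$bg, spec)
  wj <- fit$betas / nrow(f_pr)
  obj <- function(l) {
    eta <- f_bg %*% l
    m <- max(eta)
    -mean(f_pr %*% l) + m + log(sum(exp(eta - m))) +
      sum(wj * sqrt(l^2 + 1e-14))
  }
  orc <- optim(0, obj, method = "BFGS", control = list(reltol = 1e-14))
  expect_lt(abs(fit$lambdas[["lin_x"]] - orc$par), 1e-3)
})

test_that("raw predictions over the background normalize to one", {
  w <- make_world(n = 25, seed = 51, n_occ = 150)
  vals <- extract_values(w$env, w$occ)
  bg <- stack_values(w$env)
  for (classes in list("linear", c("linear", "quadratic", "product"))) {
    fit <- fit_maxent(vals, bg, classes = classes, beta_multiplier = 1)
    raw <- predict(fit, w$env, output = "raw")
    expect_equal(sum(raw$values, na.rm = TRUE), 1, tolerance = 1e-6)
    cl <- predict(fit, w$env, output = "cloglog")
    v <- cl$values[!is.na(cl$values)]
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("the number of active features is non-increasing in the multiplier", {
  # few presences: the class base penalty is large enough that the strongest
  # multipliers actually deactivate features
  w <- make_world(n = 20, seed = 53, n_occ = 40)
  vals <- extract_values(w$env, w$occ)
  bg <- stack_values(w$env)
  spec <- build_feature_spec(bg, vals, c("linear", "quadratic"))
  ks <- vapply(default_multipliers(), function(b) {
    fit_maxent(vals, bg, beta_multiplier = b, spec = spec)$k
  }, numeric(1))
  expect_identical(length(ks), 17L)
  expect_true(all(diff(ks) <= 0))
  expect_lt(ks[17], ks[1])  # the path actually moves
})

test_that("clamping pins out-of-range cells to the boundary prediction", {
  w <- make_world(n = 20, seed = 55, n_occ = 120)
  fit <- fit_maxent(extract_values(w$env, w$occ), stack_values(w$env),
                    classes = c("linear", "quadratic"))
  # prediction on the training stack leaves nothing clamped
  p0 <- predict(fit, w$env)
  expect_identical(sum(p0$clamped, na.rm = TRUE), 0L)
  # push one variable beyond its training maximum in a band of cells
  env2 <- w$env
  hi <- max(w$env$layers$t1) + 5
  env2$layers$t1[1:3, ] <- hi
  p2 <- predict(fit, env2, clamp = TRUE)
  expect_true(all(p2$clamped[1:3, ]))
  expect_identical(sum(p2$clamped[-(1:3), ]), 0L)
  # clamped cells equal the prediction with the variable at the boundary
  env3 <- env2
  env3$layers$t1[1:3, ] <- max(w$env$layers$t1)
  p3 <- predict(env3, object = fit, clamp = FALSE)
  expect_equal(p2$values[1:3, ], p3$values[1:3, ], tolerance = 1e-12)
})

test_that("replicate fits are seeded, optional and non-degenerate", {
  w <- make_world(n = 20, seed = 57, n_occ = 150)
  vals <- extract_values(w$env, w$occ)
  bg <- stack_values(w$env)
  reps <- fit_replicates(vals, bg, classes = "linear", n_rep = 5, seed = 9)
  reps2 <- fit_replicates(vals, bg, classes = "linear", n_rep = 5, seed = 9)
  expect_identical(lapply(reps, `[[`, "lambdas"),
                   lapply(reps2, `[[`, "lambdas"))
  # bootstrap disabled: replicates collapse onto the plain fit
  one <- fit_replicates(vals, bg, classes = "linear", n_rep = 1, seed = 9,
                        bootstrap = FALSE)
  plain <- fit_maxent(vals, bg, classes = "linear")
  expect_equal(one[[1]]$lambdas, plain$lambdas)
  # replicate-to-replicate variation exists on stochastic resamples
  grids <- lapply(reps, predict, env = w$env)
  mr <- median_and_range(grids)
  expect_gt(max(mr$range$values, na.rm = TRUE), 0)
})

test_that("median and range grids follow cellwise arithmetic", {
  tmpl <- structure(list(values = matrix(0.5, 2, 2), scale = "cloglog",
                         clamped = matrix(FALSE, 2, 2),
                         xmin = 0, ymax = 1, cellsize = 0.5),
                    class = "suitability_grid")
  g <- function(v) { t <- tmpl; t$values <- matrix(v, 2, 2); t }
  mr <- median_and_range(list(g(0.2), g(0.4), g(0.9)))
  expect_equal(mr$median$values[1, 1], 0.4)
  expect_equal(mr$range$values[1, 1], 0.7)
  same <- median_and_range(list(g(0.3), g(0.3)))
  expect_true(all(same$range$values == 0))
  # median bounded by min/max cellwise on random stacks
  set.seed(6)
  gs <- lapply(1:7, function(i) g(runif(4)))
  mr2 <- median_and_range(gs)
  arr <- sapply(gs, function(x) as.vector(x$values))
  expect_true(all(mr2$median$values >= matrix(apply(arr, 1, min), 2, 2)))
  expect_true(all(mr2$median$values <= matrix(apply(arr, 1, max), 2, 2)))
  bad <- g(0.1); bad$values <- matrix(0.1, 3, 3)
  expect_error(median_and_range(list(tmpl, bad)), "co-registered")
})

test_that("virtual-species truth is recovered by an lq model", {
  env <- simulate_climate(30, 30, c("t1", "t2", "t3", "p1", "p2", "p3"),
                          smoothness = 4, seed = 61)
  sp <- virtual_species(env, c("t1", "p1"), optima = c(0.4, -0.2),
                        breadths = c(0.8, 1.0))
  occ <- sample_occurrences(sp, 200, seed = 62)
  fit <- fit_maxent(extract_values(env, occ), stack_values(env),
                    classes = c("linear", "quadratic"))
  pred <- predict(fit, env)
  ok <- !is.na(pred$values) & !is.na(sp$truth)
  expect_gte(cor(pred$values[ok], sp$truth[ok], method = "spearman"), 0.8)
})

test_that("models serialize to text and reproduce predictions exactly", {
  w <- make_world(n = 15, seed = 63, n_occ = 80)
  # a stalled fit is fine here: serialization fidelity is what is under test
  fit <- suppressWarnings(
    fit_maxent(extract_values(w$env, w$occ), stack_values(w$env),
               classes = c("linear", "quadratic", "product")))
  path <- withr::local_tempfile(fileext = ".json")
  save_maxent_model(fit, path)
  fit2 <- load_maxent_model(path)
  p1 <- predict(fit, w$env)
  p2 <- predict(fit2, w$env)
  expect_identical(p1$values, p2$values)
})

test_that("tidy and glance summarize a fit", {
  w <- make_linear_world(seed = 65)
  fit <- fit_maxent(w$pr, w$bg, classes = c("linear", "quadratic"))
  td <- tidy(fit)
  expect_tibble(td)
  expect_named(td, c("feature", "class", "lambda", "beta"))
  expect_identical(nrow(td), 2L)
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$k, sum(td$lambda != 0))
})
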