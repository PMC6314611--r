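#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

.maxent_classes <- c("linear", "quadratic", "product", "threshold", "hinge")

as_var_matrix <- function(x, vars = NULL) {
  if (is.data.frame(x)) {
    x <- as.matrix(x[, setdiff(names(x), c(".record", ".cell")), drop = FALSE])
  }
  if (!is.null(vars)) {
    missing_v <- setdiff(vars, colnames(x))
    if (length(missing_v)) {
      stop("missing variable(s): ", paste(missing_v, collapse = ", "), call. = FALSE)
    }
    x <- x[, vars, drop = FALSE]
  }
  storage.mode(x) <- "double"
  x
}

#' Build a feature specification from background and presence data
#'
#' Records, per variable, the background min/max used for \[0, 1\] scaling and
#' for clamping at projection time; hinge knots at presence quantiles and
#' evenly spaced threshold knots, both strictly inside the scaled range; and
#' per-feature background min/max so that every generated feature can itself
#' be rescaled to \[0, 1\]. Variables constant over the background are
#' excluded with a warning.
#'
#' @param background,presence matrices (or tibbles) of raw variable values,
#'   same column names.
#' @param classes subset of `linear`, `quadratic`, `product`, `threshold`,
#'   `hinge`.
#' @param n_hinge hinge knots per variable (forward and reverse hinges are
#'   generated at each knot).
#' @param n_threshold evenly spaced threshold knots per variable.
#' @return object of class `feature_spec`.
#' @export
build_feature_spec <- function(background, presence, classes,
                               n_hinge = 15, n_threshold = 10) {
  classes <- match.arg(classes, .maxent_classes, several.ok = TRUE)
  bg <- as_var_matrix(background)
  pr <- as_var_matrix(presence, colnames(bg))
  vmin <- apply(bg, 2, min)
  vmax <- apply(bg, 2, max)
  const <- vmax - vmin <= 0
  if (any(const)) {
    warning("excluding constant variable(s): ",
            paste(colnames(bg)[const], collapse = ", "), call. = FALSE)
    bg <- bg[, !const, drop = FALSE]
    pr <- pr[, !const, drop = FALSE]
    vmin <- vmin[!const]
    vmax <- vmax[!const]
  }
  if (ncol(bg) == 0L) stop("no non-constant variables left", call. = FALSE)
  vars <- colnames(bg)
  scale01 <- function(x, v) (x - vmin[v]) / (vmax[v] - vmin[v])
  hinge_knots <- threshold_knots <- NULL
  if ("hinge" %in% classes) {
    hinge_knots <- lapply(vars, function(v) {
      z <- scale01(pr[, v], v)
      k <- unique(pmin(pmax(
        stats::quantile(z, probs = seq(0.5, n_hinge - 0.5) / n_hinge,
                        names = FALSE, type = 7), 0.01), 0.99))
      k
    })
    names(hinge_knots) <- vars
  }
  if ("threshold" %in% classes) {
    threshold_knots <- lapply(vars, function(v) {
      seq_len(n_threshold) / (n_threshold + 1)
    })
    names(threshold_knots) <- vars
  }
  spec <- structure(
    list(classes = classes, vars = vars, var_min = vmin, var_max = vmax,
         hinge_knots = hinge_knots, threshold_knots = threshold_knots,
         feat_min = NULL, feat_max = NULL, feat_class = NULL),
    class = "feature_spec"
  )
  f_bg <- expand_raw_features(bg, spec)
  spec$feat_min <- apply(f_bg, 2, min)
  spec$feat_max <- apply(f_bg, 2, max)
  spec$feat_class <- attr(f_bg, "feat_class")
  spec
}

# feature columns before the per-feature [0,1] rescale
expand_raw_features <- function(x, spec) {
  z <- sweep(sweep(x[, spec$vars, drop = FALSE], 2, spec$var_min, "-"),
             2, spec$var_max - spec$var_min, "/")
  cols <- list()
  kls <- character()
  if ("linear" %in% spec$classes) {
    for (v in spec$vars) {
      cols[[paste0("lin_", v)]] <- z[, v]
      kls <- c(kls, "linear")
    }
  }
  if ("quadratic" %in% spec$classes) {
    for (v in spec$vars) {
      cols[[paste0("quad_", v)]] <- z[, v]^2
      kls <- c(kls, "quadratic")
    }
  }
  if ("product" %in% spec$classes && length(spec$vars) >= 2L) {
    for (i in seq_len(length(spec$vars) - 1L)) {
      for (j in (i + 1L):length(spec$vars)) {
        vi <- spec$vars[i]; vj <- spec$vars[j]
        cols[[paste0("prod_", vi, "_", vj)]] <- z[, vi] * z[, vj]
        kls <- c(kls, "product")
      }
    }
  }
  if ("threshold" %in% spec$classes) {
    for (v in spec$vars) {
      for (t in spec$threshold_knots[[v]]) {
        cols[[sprintf("thr_%s_%.4f", v, t)]] <- as.numeric(z[, v] > t)
        kls <- c(kls, "threshold")
      }
    }
  }
  if ("hinge" %in% spec$classes) {
    for (v in spec$vars) {
      for (t in spec$hinge_knots[[v]]) {
        cols[[sprintf("hingef_%s_%.4f", v, t)]] <- pmax(0, z[, v] - t) / (1 - t)
        kls <- c(kls, "hinge")
      }
      for (t in spec$hinge_knots[[v]]) {
        cols[[sprintf("hinger_%s_%.4f", v, t)]] <- pmax(0, t - z[, v]) / t
        kls <- c(kls, "hinge")
      }
    }
  }
  f <- do.call(cbind, cols)
  attr(f, "feat_class") <- stats::setNames(kls, colnames(f))
  f
}

#' Expand raw variable values into the model's design matrix
#'
#' Generates the feature columns for the classes in `spec` (linear `x`,
#' quadratic `x^2`, pairwise products, step thresholds, forward and reverse
#' hinges) on variables scaled to \[0, 1\] by the background range, then
#' rescales each feature to \[0, 1\] using the background feature range
#' stored in the spec.
#'
#' @param x matrix (or tibble) of raw variable values.
#' @param spec a [build_feature_spec()] result.
#' @return numeric design matrix, one named column per feature.
#' @export
expand_features <- function(x, spec) {
  x <- as_var_matrix(x, spec$vars)
  f <- expand_raw_features(x, spec)
  rng <- spec$feat_max - spec$feat_min
  rng[rng <= 0] <- 1
  sweep(sweep(f, 2, spec$feat_min, "-"), 2, rng, "/")
}

# Published default per-class base regularization, interpolated by presence
# count (linear/quadratic/product share one table).
base_penalty <- function(class, n_presence) {
  interp <- function(xs, ys) {
    stats::approx(xs, ys, xout = n_presence, rule = 2)$y
  }
  switch(class,
    linear = ,
    quadratic = ,
    product = interp(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05)),
    threshold = interp(c(0, 100), c(2, 1)),
    hinge = 0.5,
    stop("unknown feature class: ", class)
  )
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit a regularized maximum-entropy presence-background model
#'
#' Maximizes the L1-penalized presence log-likelihood
#' `sum_i log q(x_i) - sum_j beta_j |lambda_j|`, where
#' `q(x) = exp(lambda . f(x)) / Z` and `Z` normalizes over the background.
#' Per-feature penalties are `beta_multiplier` times the published
#' class-specific base penalty (interpolated by presence count) times the
#' feature's presence standard deviation over `sqrt(n_presence)`. The convex
#' objective is solved by a proximal-Newton method: at each outer step the
#' log-partition term is replaced by its local quadratic model and the
#' resulting L1-penalized quadratic is solved by cyclic coordinate descent
#' (soft-thresholding), followed by a backtracking line search on the true
#' objective. Convergence is declared when the KKT conditions hold within
#' `tol`.
#'
#' @param presence,background matrices or tibbles of raw variable values
#'   (same columns); at least 10 presences recommended.
#' @param classes feature classes to use.
#' @param beta_multiplier positive regularization multiplier.
#' @param spec optional precomputed [build_feature_spec()]; built from the
#'   data when `NULL`.
#' @param n_hinge,n_threshold knot counts passed to [build_feature_spec()].
#' @param max_iter iteration cap; non-convergence is reported and flagged on
#'   the returned model, not an error.
#' @param tol KKT tolerance on the per-presence objective scale.
#' @param sd_floor lower bound on the per-feature presence standard deviation
#'   entering the penalty, preventing unpenalized features.
#' @return object of class `maxent_model`: feature spec, sparse coefficient
#'   vector `lambdas`, `linear_predictor_normalizer`, `density_normalizer`
#'   (Z over background), `entropy` (H of the background distribution), and
#'   fit metadata. Raw scores over the background cells sum to 1.
#' @export
fit_maxent <- function(presence, background,
                       classes = c("linear", "quadratic"),
                       beta_multiplier = 1, spec = NULL,
                       n_hinge = 15, n_threshold = 10,
                       max_iter = 100, tol = 1e-5, sd_floor = 0.01) {
  stopifnot(beta_multiplier > 0)
  pr <- as_var_matrix(presence)
  bg <- as_var_matrix(background, colnames(pr))
  if (is.null(spec)) {
    spec <- build_feature_spec(bg, pr, classes, n_hinge, n_threshold)
  }
  f_pr <- expand_features(pr, spec)
  f_bg <- expand_features(bg, spec)
  np <- nrow(f_pr)
  p <- ncol(f_pr)
  s_j <- pmax(apply(f_pr, 2, stats::sd), sd_floor)
  base <- vapply(spec$feat_class, base_penalty, numeric(1), n_presence = np)
  betas <- beta_multiplier * base * s_j / sqrt(np)
  # objective scaled per presence: f(l) = -mean(eta_pr) + lse(eta_bg) + sum(w|l|)
  w <- betas / np
  mean_fpr <- colMeans(f_pr)
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  lam <- numeric(p)
  eta_bg <- numeric(nrow(f_bg))
  converged <- FALSE
  stall <- 0L
  kkt <- function(g) {
    v <- ifelse(lam > 0, abs(g + w),
         ifelse(lam < 0, abs(g - w), pmax(0, abs(g) - w)))
    max(v)
  }
  for (outer in seq_len(max_iter)) {
    q <- exp(eta_bg - max(eta_bg))
    q <- q / sum(q)
    h <- drop(crossprod(f_bg, q))          # E_q f
    g <- -mean_fpr + h                     # gradient of smooth part
    if (kkt(g) <= tol) {
      converged <- TRUE
      break
    }
    # local quadratic model of the log-partition: H = F' diag(q) F - h h'
    hess <- crossprod(f_bg * sqrt(q)) - tcrossprod(h)
    diag(hess) <- diag(hess) + 1e-9
    # coordinate descent on the L1-penalized quadratic subproblem
    z <- lam
    r <- numeric(p)                        # r = H (z - lam)
    hdiag <- diag(hess)
    for (sweep in seq_len(60L)) {
      delta_max <- 0
      for (j in seq_len(p)) {
        u <- z[j]
        d0 <- g[j] + r[j] - hdiag[j] * u   # smooth derivative at z_j = 0
        t_new <- soft(-d0, w[j]) / hdiag[j]
        if (t_new != u) {
          r <- r + hess[, j] * (t_new - u)
          z[j] <- t_new
          delta_max <- max(delta_max, abs(t_new - u))
        }
      }
      if (delta_max < 1e-10) break
    }
    dir <- z - lam
    if (max(abs(dir)) < 1e-12) {
      converged <- kkt(g) <= tol
      break
    }
    # backtracking line search on the true objective
    obj_at <- function(l, eta) -sum(mean_fpr * l) + logsumexp(eta) + sum(w * abs(l))
    obj0 <- obj_at(lam, eta_bg)
    decr <- sum(g * dir) + sum(w * abs(z)) - sum(w * abs(lam))
    eta_dir <- drop(f_bg %*% dir)
    step <- 1
    repeat {
      lam_new <- lam + step * dir
      eta_new <- eta_bg + step * eta_dir
      if (obj_at(lam_new, eta_new) <= obj0 + 1e-4 * step * decr || step < 1e-8) break
      step <- step / 2
    }
    obj_new <- obj_at(lam_new, eta_new)
    lam <- lam_new
    eta_bg <- eta_new
    # near-degenerate feature sets (e.g. adjacent hinge knots) flatten the
    # objective; stop once progress stalls and report the KKT state honestly
    if (obj0 - obj_new < 1e-9 * max(1, abs(obj0))) {
      stall <- stall + 1L
      if (stall >= 3L) break
    } else {
      stall <- 0L
    }
  }
  if (!converged) {
    q <- exp(eta_bg - max(eta_bg)); q <- q / sum(q)
    converged <- kkt(-mean_fpr + drop(crossprod(f_bg, q))) <= tol
  }
  if (!converged) {
    warning("maxent fit did not reach KKT tolerance ", tol,
            " after ", max_iter, " outer iterations", call. = FALSE)
  }
  lam[abs(lam) < 1e-9] <- 0
  eta_bg <- drop(f_bg %*% lam)
  lpn <- max(eta_bg)
  z <- sum(exp(eta_bg - lpn))
  raw_bg <- exp(eta_bg - lpn) / z
  entropy <- -sum(raw_bg * log(raw_bg))
  eta_pr <- drop(f_pr %*% lam)
  loglik <- sum(eta_pr - lpn - log(z))
  structure(
    list(spec = spec,
         lambdas = stats::setNames(lam, colnames(f_pr)),
         betas = stats::setNames(betas, colnames(f_pr)),
         beta_multiplier = beta_multiplier,
         linear_predictor_normalizer = lpn,
         density_normalizer = z,
         entropy = entropy,
         n_presence = np,
         n_background = nrow(f_bg),
         loglik = loglik,
         gain = loglik / np + log(nrow(f_bg)),
         k = sum(lam != 0),
         converged = converged),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> classes {%s}, beta %.3g: %d/%d nonzero features, H = %.3f, gain = %.3f%s\n",
    paste(x$spec$classes, collapse = ","), x$beta_multiplier, x$k,
    length(x$lambdas), x$entropy, x$gain,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @describeIn fit_maxent per-feature coefficients as a tibble.
#' @param x a `maxent_model`.
#' @param ... unused.
#' @export
tidy.maxent_model <- function(x, ...) {
  tibble::tibble(
    feature = names(x$lambdas),
    class = unname(x$spec$feat_class),
    lambda = unname(x$lambdas),
    beta = unname(x$betas)
  )
}

#' @describeIn fit_maxent one-row model summary.
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    n_presence = x$n_presence, n_background = x$n_background,
    n_features = length(x$lambdas), k = x$k, entropy = x$entropy,
    loglik = x$loglik, gain = x$gain,
    beta_multiplier = x$beta_multiplier, converged = x$converged
  )
}

#' Predict suitability over an environmental stack
#'
#' With `clamp = TRUE` (the default, matching standard projection practice)
#' variable values outside the training background range are pinned to the
#' boundary before feature expansion, and the affected cells are flagged in
#' the returned `clamped` mask. Raw output is the background-normalized
#' density (`exp(eta - normalizer) / Z`); cloglog output is
#' `1 - exp(-exp(H) * raw)`.
#'
#' @param object a `maxent_model`.
#' @param env an [env_stack()] supplying every model variable.
#' @param region_mask optional logical matrix restricting prediction.
#' @param clamp pin out-of-range values to the training range?
#' @param output `"cloglog"` (default) or `"raw"`.
#' @param ... unused.
#' @return object of class `suitability_grid`: `values` matrix, `scale`,
#'   logical `clamped` matrix, and grid georeferencing.
#' @export
predict.maxent_model <- function(object, env, region_mask = NULL, clamp = TRUE,
                                 output = c("cloglog", "raw"), ...) {
  output <- match.arg(output)
  vals <- stack_values(env, region_mask)
  cells <- attr(vals, "cells")
  x <- as_var_matrix(vals, object$spec$vars)
  clamped_any <- rep(FALSE, nrow(x))
  if (clamp) {
    for (j in seq_along(object$spec$vars)) {
      lo <- object$spec$var_min[j]
      hi <- object$spec$var_max[j]
      out <- x[, j] < lo | x[, j] > hi
      clamped_any <- clamped_any | out
      x[, j] <- pmin(pmax(x[, j], lo), hi)
    }
  }
  f <- expand_features(x, object$spec)
  eta <- drop(f %*% object$lambdas)
  raw <- exp(eta - object$linear_predictor_normalizer) / object$density_normalizer
  v <- if (output == "cloglog") 1 - exp(-exp(object$entropy) * raw) else raw
  d <- dim(env)
  structure(
    list(values = grid_from_values(v, cells, d),
         scale = output,
         clamped = grid_from_values(as.numeric(clamped_any), cells, d) > 0,
         xmin = env$xmin, ymax = env$ymax, cellsize = env$cellsize),
    class = "suitability_grid"
  )
}

#' @export
print.suitability_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<suitability_grid> %s, %d cells, range [%.4g, %.4g], %d clamped\n",
              x$scale, length(v), min(v), max(v),
              sum(x$clamped, na.rm = TRUE)))
  invisible(x)
}

#' Fit bootstrap replicates of a maxent model
#'
#' Each replicate refits the model on a same-size bootstrap resample of the
#' presences (sampling with replacement); replicate seeds are derived
#' deterministically from `seed`. Individual fit failures are logged and
#' skipped, not fatal.
#'
#' @inheritParams fit_maxent
#' @param n_rep number of replicates (default 10).
#' @param seed master seed.
#' @param bootstrap set `FALSE` to refit on the full presence set each time
#'   (replicates are then identical).
#' @return list of `maxent_model` objects.
#' @export
fit_replicates <- function(presence, background,
                           classes = c("linear", "quadratic"),
                           beta_multiplier = 1, n_rep = 10, seed = 1L,
                           bootstrap = TRUE, ...) {
  stopifnot(n_rep >= 1)
  pr <- as_var_matrix(presence)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max %/% 2L, n_rep)
  models <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    set.seed(rep_seeds[i])
    rows <- if (bootstrap) sample.int(nrow(pr), replace = TRUE) else seq_len(nrow(pr))
    models[[i]] <- tryCatch(
      fit_maxent(pr[rows, , drop = FALSE], background, classes = classes,
                 beta_multiplier = beta_multiplier, ...),
      error = function(e) {
        message("replicate ", i, " failed: ", conditionMessage(e))
        NULL
      })
  }
  models[!vapply(models, is.null, logical(1))]
}

#' Cellwise median and range across replicate suitability grids
#'
#' @param grids list of co-registered `suitability_grid`s.
#' @return list with `median` and `range` (`max - min`) `suitability_grid`s;
#'   the range grid carries scale `"range"`.
#' @export
median_and_range <- function(grids) {
  stopifnot(length(grids) >= 1L)
  d <- dim(grids[[1]]$values)
  for (g in grids[-1]) {
    if (!identical(dim(g$values), d) ||
        !isTRUE(all.equal(c(g$xmin, g$ymax, g$cellsize),
                          c(grids[[1]]$xmin, grids[[1]]$ymax, grids[[1]]$cellsize)))) {
      stop("grids are not co-registered", call. = FALSE)
    }
  }
  arr <- vapply(grids, function(g) g$values, matrix(0, d[1], d[2]))
  dim(arr) <- c(d[1] * d[2], length(grids))
  med <- apply(arr, 1, stats::median)
  rng <- apply(arr, 1, function(r) if (all(is.na(r))) NA_real_ else
    max(r, na.rm = TRUE) - min(r, na.rm = TRUE))
  tmpl <- grids[[1]]
  out_med <- tmpl
  out_med$values <- matrix(med, d[1], d[2])
  out_rng <- tmpl
  out_rng$values <- matrix(rng, d[1], d[2])
  out_rng$scale <- "range"
  list(median = out_med, range = out_rng)
}
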