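#' Parse a regularization-multiplier grid specification
#'
#' Accepts a compact text form such as
#' `"0.1-1 by 0.1; 1-6 by 1; 8; 10"`: semicolon-separated segments, each
#' either a single value or a range `a-b by s`. Values are deduplicated
#' (overlapping endpoints such as the 1 shared by both ranges collapse) and
#' sorted.
#'
#' @param text specification string.
#' @return sorted numeric vector of unique multipliers.
#' @export
parse_multipliers <- function(text) {
  segs <- trimws(strsplit(text, ";")[[1]])
  segs <- segs[nzchar(segs)]
  if (!length(segs)) stop("empty multiplier specification", call. = FALSE)
  vals <- unlist(lapply(segs, function(s) {
    s <- gsub("–", "-", s)  # en dash
    m <- regmatches(s, regexec(
      "^([0-9.]+)\\s*-\\s*([0-9.]+)\\s+by\\s+([0-9.]+)$", s))[[1]]
    if (length(m) == 4L) {
      seq(as.numeric(m[2]), as.numeric(m[3]), by = as.numeric(m[4]))
    } else {
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v)) stop("cannot parse multiplier segment: ", s, call. = FALSE)
      v
    }
  }))
  sort(unique(round(vals, 10)))
}

#' The default 17-value regularization-multiplier grid
#'
#' 0.1 to 1 in steps of 0.1, 1 to 6 in steps of 1, plus 8 and 10.
#' @return numeric vector of 17 multipliers.
#' @export
default_multipliers <- function() {
  parse_multipliers("0.1-1 by 0.1; 1-6 by 1; 8; 10")
}

#' All non-empty combinations of the five feature classes
#'
#' @return named list of 31 character vectors; names are compact codes
#'   (`l`, `q`, `p`, `t`, `h` for linear, quadratic, product, threshold,
#'   hinge), e.g. `"lq"`.
#' @export
feature_class_combos <- function() {
  letters5 <- c(linear = "l", quadratic = "q", product = "p",
                threshold = "t", hinge = "h")
  out <- list()
  for (m in 1:31) {
    sel <- .maxent_classes[bitwAnd(m, c(1L, 2L, 4L, 8L, 16L)) > 0]
    out[[paste(letters5[sel], collapse = "")]] <- sel
  }
  out[order(nchar(names(out)), names(out))]
}

#' Enumerate candidate model configurations
#'
#' Cartesian product of variable sets, feature-class combinations and
#' regularization multipliers, in stable (varset, combo, multiplier) order.
#'
#' @param combos named list of feature-class vectors (see
#'   [feature_class_combos()]).
#' @param multipliers numeric vector of regularization multipliers.
#' @param varsets named list of character vectors of variable names.
#' @return tibble with columns `candidate_id`, `varset`, `classes` (combo
#'   code), `multiplier`.
#' @export
enumerate_candidates <- function(combos, multipliers, varsets) {
  if (!length(combos) || !length(multipliers) || !length(varsets)) {
    stop("combos, multipliers and varsets must all be non-empty", call. = FALSE)
  }
  if (is.null(names(varsets))) names(varsets) <- paste0("set", seq_along(varsets))
  grid <- tidyr::expand_grid(
    varset = names(varsets),
    classes = names(combos),
    multiplier = sort(unique(multipliers))
  )
  dplyr::mutate(grid, candidate_id = dplyr::row_number(), .before = 1)
}

#' Partial-ROC significance test
#'
#' Compares the model's partial AUC, with sensitivity restricted to at least
#' `1 - E`, against the null expectation of a uniformly random classifier
#' over the same sensitivity restriction. For each bootstrap draw of
#' `boot_frac` of the test points (with replacement) the AUC ratio
#' (partial AUC / null partial AUC) is computed; `proc_p` is the fraction of
#' ratios at or below 1.
#'
#' The ROC here is (fraction of grid cells predicted suitable at threshold,
#' fraction of test points predicted suitable), the standard
#' presence-background construction. The integration domain is fixed where
#' the null (diagonal) classifier attains sensitivity at least `1 - E`,
#' i.e. fractional predicted area in `[1 - E, 1]`; the null partial area
#' over that domain is `(1 - (1 - E)^2) / 2`, computed analytically.
#' Fixing the domain keeps the ratio centred at 1 under no signal
#' (restricting by the empirical curve instead inflates it at small test
#' sizes).
#'
#' @param test_suitabilities suitability values at the held-out test points.
#' @param grid_suitabilities suitability values over the prediction grid
#'   cells.
#' @param E acceptable omission (0 < E < 0.5, default 0.05).
#' @param n_boot bootstrap iterations (default 500).
#' @param boot_frac fraction of test points per bootstrap draw (default 0.5).
#' @param seed integer seed.
#' @return list with `mean_auc_ratio`, `proc_p`, and the bootstrap `ratios`.
#'   A degenerate (constant) suitability grid yields `NA` ratio and
#'   `proc_p = 1` (non-significant).
#' @export
partial_roc <- function(test_suitabilities, grid_suitabilities, E = 0.05,
                        n_boot = 500, boot_frac = 0.5, seed = 1L) {
  stopifnot(E > 0, E < 0.5, n_boot >= 1, boot_frac > 0, boot_frac <= 1)
  test <- test_suitabilities[!is.na(test_suitabilities)]
  grid <- grid_suitabilities[!is.na(grid_suitabilities)]
  if (length(test) < 10L) stop("need at least 10 test points", call. = FALSE)
  if (max(grid) - min(grid) <= 0) {
    return(list(mean_auc_ratio = NA_real_, proc_p = 1, ratios = numeric()))
  }
  # threshold ladder from the grid values (capped for speed)
  th <- sort(unique(grid))
  if (length(th) > 500L) {
    th <- unique(stats::quantile(grid, probs = seq(0, 1, length.out = 500),
                                 names = FALSE, type = 7))
  }
  # fraction of grid at or above each threshold (descending in th)
  frac_area <- 1 - (findInterval(th, sort(grid), left.open = TRUE) / length(grid))
  # integration domain fixed where the null (diagonal) classifier attains
  # sensitivity >= 1 - E, i.e. fractional area in [1 - E, 1]; restricting by
  # the empirical model curve instead biases the ratio upward at small test
  # sizes (the high-sensitivity region is then conditioned on the curve)
  x_lo <- 1 - E
  null_pauc <- (1 - x_lo^2) / 2
  pauc_ratio <- function(tt) {
    sens <- 1 - (findInterval(th, sort(tt), left.open = TRUE) / length(tt))
    # points ordered by descending threshold => x (frac_area) ascending
    x <- c(rev(frac_area), 1)
    y <- c(rev(sens), 1)
    keep <- x >= x_lo
    if (!any(keep)) return(NA_real_)
    first <- which(keep)[1]
    if (first > 1L && x[first] > x_lo) {
      # interpolate the curve at the domain edge
      y_lo <- y[first - 1] + (y[first] - y[first - 1]) *
        (x_lo - x[first - 1]) / (x[first] - x[first - 1])
      x <- c(x_lo, x[keep])
      y <- c(y_lo, y[keep])
    } else {
      x <- x[keep]
      y <- y[keep]
    }
    if (length(x) < 2L) return(NA_real_)
    pauc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    pauc / null_pauc
  }
  set.seed(seed)
  m <- max(1L, ceiling(boot_frac * length(test)))
  ratios <- vapply(seq_len(n_boot), function(i) {
    pauc_ratio(test[sample.int(length(test), m, replace = TRUE)])
  }, numeric(1))
  ratios <- ratios[!is.na(ratios)]
  if (!length(ratios)) {
    return(list(mean_auc_ratio = NA_real_, proc_p = 1, ratios = numeric()))
  }
  list(mean_auc_ratio = mean(ratios),
       proc_p = mean(ratios <= 1),
       ratios = ratios)
}

#' Omission rate at an adjusted-training-presence threshold
#'
#' The threshold is the `ceiling(E * n)`-th smallest calibration suitability
#' (the value that excludes the lowest `E` fraction of calibration points);
#' the omission rate is the fraction of evaluation suitabilities strictly
#' below it (ties with the threshold are retained, not omitted).
#'
#' @param cal_suitabilities suitabilities at calibration occurrences.
#' @param eval_suitabilities suitabilities at evaluation occurrences.
#' @param E acceptable omission fraction (default 0.05).
#' @return list with `threshold` and `rate`.
#' @export
omission_rate <- function(cal_suitabilities, eval_suitabilities, E = 0.05) {
  stopifnot(E > 0, E < 1,
            length(cal_suitabilities) >= 1, length(eval_suitabilities) >= 1)
  cal <- sort(cal_suitabilities)
  thr <- cal[max(1L, ceiling(E * length(cal)))]
  list(threshold = thr, rate = mean(eval_suitabilities < thr))
}

#' AICc of a maxent model from raw suitabilities
#'
#' Raw scores are renormalized over the full calibration grid; the
#' log-likelihood is the sum of log normalized scores at the occurrences;
#' `k` is the number of nonzero coefficients. `AICc = 2k - 2 lnL +
#' 2k(k+1)/(n-k-1)`, infinite when `k >= n - 1` or when any occurrence has a
#' zero raw score.
#'
#' @param model a `maxent_model`.
#' @param occurrence_raw raw suitabilities at the occurrence cells.
#' @param grid_raw_sum sum of raw suitabilities over the calibration grid.
#' @return list with `aicc` and `k`.
#' @export
compute_aicc <- function(model, occurrence_raw, grid_raw_sum) {
  k <- model$k
  n <- length(occurrence_raw)
  if (k >= n - 1L) return(list(aicc = Inf, k = k))
  p <- occurrence_raw / grid_raw_sum
  if (any(!is.finite(p)) || any(p <= 0)) {
    message("zero raw score at an occurrence; AICc set to +Inf")
    return(list(aicc = Inf, k = k))
  }
  lnl <- sum(log(p))
  list(aicc = 2 * k - 2 * lnl + 2 * k * (k + 1) / (n - k - 1), k = k)
}

#' Evaluate every candidate configuration
#'
#' Fits one maxent model per candidate row on the calibration occurrences and
#' computes its partial-ROC statistics (on the evaluation half), omission
#' rate at `E`, and AICc, returning one tidy row per candidate.
#'
#' @param candidates tibble from [enumerate_candidates()].
#' @param varsets named list of variable-name vectors.
#' @param combos named list of feature-class vectors.
#' @param cal_values,eval_values tibbles/matrices of variable values at
#'   calibration and evaluation occurrences (all variables).
#' @param background matrix/tibble of background cell values (all variables).
#' @param E acceptable omission (default 0.05).
#' @param n_boot,boot_frac partial-ROC bootstrap settings.
#' @param aicc_occ `"all"` (calibration + evaluation occurrences, the
#'   default) or `"calibration"` for the AICc likelihood.
#' @param seed integer seed (partial-ROC bootstrap).
#' @param verbose print progress every 10 candidates.
#' @return tibble: candidate columns plus `mean_auc_ratio`, `proc_p`,
#'   `omission`, `threshold`, `k`, `aicc`, `converged`.
#' @export
calibrate_candidates <- function(candidates, varsets, combos,
                                 cal_values, eval_values, background,
                                 E = 0.05, n_boot = 500, boot_frac = 0.5,
                                 aicc_occ = c("all", "calibration"),
                                 seed = 1L, verbose = FALSE) {
  aicc_occ <- match.arg(aicc_occ)
  cal_m <- as_var_matrix(cal_values)
  eval_m <- as_var_matrix(eval_values, colnames(cal_m))
  bg_m <- as_var_matrix(background, colnames(cal_m))
  res <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    vars <- varsets[[cand$varset]]
    classes <- combos[[cand$classes]]
    row <- tryCatch({
      fit <- fit_maxent(cal_m[, vars, drop = FALSE], bg_m[, vars, drop = FALSE],
                        classes = classes, beta_multiplier = cand$multiplier)
      su <- function(x) {  # cloglog suitability for point values
        f <- expand_features(clamp_to_spec(x[, fit$spec$vars, drop = FALSE],
                                           fit$spec), fit$spec)
        raw <- exp(drop(f %*% fit$lambdas) - fit$linear_predictor_normalizer) /
          fit$density_normalizer
        list(raw = raw, cloglog = 1 - exp(-exp(fit$entropy) * raw))
      }
      s_cal <- su(cal_m)
      s_eval <- su(eval_m)
      s_bg <- su(bg_m)
      pr <- partial_roc(s_eval$cloglog, s_bg$cloglog, E = E, n_boot = n_boot,
                        boot_frac = boot_frac, seed = seed + i)
      om <- omission_rate(s_cal$cloglog, s_eval$cloglog, E = E)
      occ_raw <- if (aicc_occ == "all") c(s_cal$raw, s_eval$raw) else s_cal$raw
      ai <- compute_aicc(fit, occ_raw, sum(s_bg$raw))
      tibble::tibble(mean_auc_ratio = pr$mean_auc_ratio, proc_p = pr$proc_p,
                     omission = om$rate, threshold = om$threshold,
                     k = ai$k, aicc = ai$aicc, converged = fit$converged)
    }, error = function(e) {
      message("candidate ", cand$candidate_id, " failed: ", conditionMessage(e))
      tibble::tibble(mean_auc_ratio = NA_real_, proc_p = NA_real_,
                     omission = NA_real_, threshold = NA_real_,
                     k = NA_integer_, aicc = NA_real_, converged = FALSE)
    })
    res[[i]] <- dplyr::bind_cols(cand, row)
    if (verbose && i %% 10L == 0L) {
      message("evaluated ", i, "/", nrow(candidates), " candidates")
    }
  }
  dplyr::bind_rows(res)
}

clamp_to_spec <- function(x, spec) {
  for (j in seq_along(spec$vars)) {
    x[, j] <- pmin(pmax(x[, j], spec$var_min[j]), spec$var_max[j])
  }
  x
}

#' Select final models by significance, omission and AICc
#'
#' Three sequential filters: (1) keep candidates with `proc_p < alpha`;
#' (2) keep omission rate `<= omission_max`; (3) among the survivors compute
#' `delta_aicc = aicc - min(aicc)` and keep `delta_aicc <= delta_max` (ties
#' kept). An empty selection at any stage returns an empty tibble with a
#' message, not an error.
#'
#' @param results tibble from [calibrate_candidates()].
#' @param alpha partial-ROC significance level (default 0.05).
#' @param omission_max maximum tolerated omission rate (default 0.05).
#' @param delta_max AICc window above the minimum (default 2).
#' @return tibble of selected rows with `delta_aicc` filled in; attribute
#'   `"stage_counts"` records survivors per stage.
#' @export
select_models <- function(results, alpha = 0.05, omission_max = 0.05,
                          delta_max = 2) {
  stopifnot(nrow(results) >= 1)
  s1 <- dplyr::filter(results, !is.na(.data$proc_p), .data$proc_p < alpha)
  s2 <- dplyr::filter(s1, !is.na(.data$omission), .data$omission <= omission_max)
  counts <- c(input = nrow(results), significant = nrow(s1),
              low_omission = nrow(s2))
  if (nrow(s2) == 0L || all(!is.finite(s2$aicc))) {
    message("no candidate survives the selection filters ",
            "(significant: ", nrow(s1), ", low-omission: ", nrow(s2), ")")
    out <- s2[integer(0), ]
    out$delta_aicc <- numeric(0)
    attr(out, "stage_counts") <- c(counts, selected = 0L)
    return(out)
  }
  s3 <- dplyr::mutate(s2, delta_aicc = .data$aicc - min(.data$aicc, na.rm = TRUE))
  out <- dplyr::arrange(
    dplyr::filter(s3, is.finite(.data$delta_aicc), .data$delta_aicc <= delta_max),
    .data$delta_aicc, .data$candidate_id)
  attr(out, "stage_counts") <- c(counts, selected = nrow(out))
  out
}
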