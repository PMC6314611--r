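#' Leave-one-out jackknife variable contributions
#'
#' The contribution of a variable is the drop in regularized training gain
#' when that variable is omitted and the model refit. Gain is the mean
#' presence log density relative to a uniform background distribution, minus
#' the regularization penalty (`mean(log q) + log(n_background) -
#' sum(beta |lambda|)`), so the uniform model scores 0. A failed
#' leave-one-out fit yields `NA` for that variable.
#'
#' @param presence,background matrices/tibbles of raw variable values.
#' @param variables variables to assess (default: all columns).
#' @param classes feature classes for the assessment fits.
#' @param beta_multiplier regularization multiplier.
#' @param ... further arguments to [fit_maxent()].
#' @return tibble with `variable`, `gain_without`, `contribution`, sorted by
#'   decreasing contribution; attribute `"gain_full"` holds the all-variable
#'   gain.
#' @export
jackknife_contributions <- function(presence, background, variables = NULL,
                                    classes = c("linear", "quadratic"),
                                    beta_multiplier = 1, ...) {
  pr <- as_var_matrix(presence)
  if (is.null(variables)) variables <- colnames(pr)
  if (length(variables) < 2L) stop("need at least 2 variables", call. = FALSE)
  bg <- as_var_matrix(background, colnames(pr))
  reg_gain <- function(vars) {
    fit <- fit_maxent(pr[, vars, drop = FALSE], bg[, vars, drop = FALSE],
                      classes = classes, beta_multiplier = beta_multiplier, ...)
    fit$gain - sum(fit$betas * abs(fit$lambdas)) / fit$n_presence
  }
  g_full <- reg_gain(variables)
  gains <- vapply(variables, function(v) {
    tryCatch(reg_gain(setdiff(variables, v)), error = function(e) {
      message("leave-one-out fit without '", v, "' failed: ",
              conditionMessage(e))
      NA_real_
    })
  }, numeric(1))
  out <- tibble::tibble(
    variable = variables,
    gain_without = unname(gains),
    contribution = g_full - unname(gains)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$contribution))
  attr(out, "gain_full") <- g_full
  out
}

#' Sequential jackknife reduction to nested variable sets
#'
#' Starting from all variables, repeatedly recompute leave-one-out
#' contributions and drop the least-contributing variable until each target
#' size is reached, snapshotting the surviving set at every target. Ties are
#' broken alphabetically by variable name. The resulting sets are strictly
#' nested.
#'
#' @inheritParams jackknife_contributions
#' @param target_sizes strictly decreasing vector of set sizes, each smaller
#'   than the variable count.
#' @return object of class `varset_sequence`: list with `sets` (named list,
#'   full set first), and `steps` (per-removal contribution tables).
#' @export
sequential_reduce <- function(presence, background, variables = NULL,
                              target_sizes, classes = c("linear", "quadratic"),
                              beta_multiplier = 1, ...) {
  pr <- as_var_matrix(presence)
  if (is.null(variables)) variables <- colnames(pr)
  if (any(diff(target_sizes) >= 0) || any(target_sizes < 1) ||
      max(target_sizes) > length(variables)) {
    stop("target_sizes must be strictly decreasing and at most the number ",
         "of variables", call. = FALSE)
  }
  current <- variables
  sets <- list(current)
  names(sets) <- paste0("set", length(current))
  steps <- list()
  for (tgt in target_sizes) {
    while (length(current) > tgt) {
      contrib <- jackknife_contributions(pr, background, current,
                                         classes = classes,
                                         beta_multiplier = beta_multiplier, ...)
      steps[[length(steps) + 1L]] <- contrib
      ranked <- contrib[order(contrib$contribution, contrib$variable), ]
      drop_v <- ranked$variable[1]
      current <- setdiff(current, drop_v)
    }
    sets[[paste0("set", tgt)]] <- current
  }
  structure(list(sets = sets, steps = steps), class = "varset_sequence")
}

#' @export
print.varset_sequence <- function(x, ...) {
  cat("<varset_sequence>\n")
  for (nm in names(x$sets)) {
    cat(sprintf("  %s (%d): %s\n", nm, length(x$sets[[nm]]),
                paste(x$sets[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
tidy.varset_sequence <- function(x, ...) {
  purrr::map_dfr(names(x$sets), function(nm) {
    tibble::tibble(set = nm, size = length(x$sets[[nm]]),
                   variable = x$sets[[nm]])
  })
}
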