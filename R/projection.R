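#' Transfer a fitted model to another scenario or region
#'
#' Identical prediction math to [predict.maxent_model()]; the clamped mask is
#' populated from the scenario values versus the training range, so clamped
#' cells flag where the transfer relies on out-of-range (extrapolated)
#' conditions.
#'
#' @inheritParams predict.maxent_model
#' @param model a `maxent_model`.
#' @param scenario_env target [env_stack()] (future scenario or other
#'   region), supplying every model variable.
#' @return a `suitability_grid`.
#' @export
transfer <- function(model, scenario_env, region_mask = NULL, clamp = TRUE,
                     output = c("cloglog", "raw")) {
  predict(model, scenario_env, region_mask = region_mask, clamp = clamp,
          output = match.arg(output))
}

#' Threshold a suitability surface into a binary map
#'
#' A cell is suitable when its (typically median) suitability is at or above
#' the threshold, usually the adjusted-training-presence threshold from
#' [omission_rate()]. A threshold outside the observed value range produces
#' an all-suitable or all-unsuitable map with a warning.
#'
#' @param grid a `suitability_grid`.
#' @param threshold numeric cutoff on the grid's scale.
#' @return object of class `binary_grid` (logical `values` matrix plus
#'   georeferencing).
#' @export
binarize <- function(grid, threshold) {
  v <- grid$values
  obs <- range(v, na.rm = TRUE)
  if (threshold <= obs[1] || threshold > obs[2]) {
    warning(sprintf(
      "threshold %.4g outside observed suitability range [%.4g, %.4g]",
      threshold, obs[1], obs[2]), call. = FALSE)
  }
  structure(
    list(values = v >= threshold, threshold = threshold,
         xmin = grid$xmin, ymax = grid$ymax, cellsize = grid$cellsize),
    class = "binary_grid"
  )
}

#' GCM-agreement composite of projected change
#'
#' Classifies each cell by cross-GCM agreement on change relative to the
#' present-day binary map: classes 1-4 give the number of GCMs predicting a
#' gain (future suitable where presently unsuitable), classes 5-8 encode 1-4
#' GCMs predicting a loss (future unsuitable where presently suitable), and
#' class 0 means no GCM signals change. A cell with both gain and loss votes
#' (possible only through inconsistent inputs) is classed as gain and the
#' conflict logged.
#'
#' @param present_binary `binary_grid` for the present epoch.
#' @param future_binaries list of 1-4 co-registered `binary_grid`s, one per
#'   GCM, for one emissions scenario.
#' @return object of class `agreement_map` (integer `values` matrix, legend).
#' @export
gcm_agreement <- function(present_binary, future_binaries) {
  n <- length(future_binaries)
  if (n < 1L || n > 4L) {
    stop("between 1 and 4 future binaries are supported by the legend",
         call. = FALSE)
  }
  p <- present_binary$values
  for (fb in future_binaries) {
    if (!identical(dim(fb$values), dim(p))) {
      stop("future binaries are not co-registered with the present map",
           call. = FALSE)
    }
  }
  gain <- loss <- matrix(0L, nrow(p), ncol(p))
  for (fb in future_binaries) {
    f <- fb$values
    g <- f & !p; g[is.na(g)] <- FALSE
    l <- !f & p; l[is.na(l)] <- FALSE
    gain <- gain + g
    loss <- loss + l
  }
  both <- gain > 0 & loss > 0
  if (any(both, na.rm = TRUE)) {
    message(sum(both, na.rm = TRUE),
            " cell(s) with conflicting gain/loss votes; classed as gain")
    loss[both] <- 0L
  }
  cls <- matrix(0L, nrow(p), ncol(p))
  cls[gain > 0] <- gain[gain > 0]
  cls[loss > 0] <- 4L + loss[loss > 0]
  cls[is.na(p)] <- NA_integer_
  legend <- c(
    "0" = "no change signal",
    stats::setNames(paste(1:4, "GCM(s) predict gain"), 1:4),
    stats::setNames(paste(1:4, "GCM(s) predict loss"), 5:8)
  )
  structure(
    list(values = cls, legend = legend, n_gcm = n,
         xmin = present_binary$xmin, ymax = present_binary$ymax,
         cellsize = present_binary$cellsize),
    class = "agreement_map"
  )
}

#' @export
print.agreement_map <- function(x, ...) {
  tab <- table(x$values)
  cat("<agreement_map>", x$n_gcm, "GCM(s); class counts:\n")
  print(tab)
  invisible(x)
}
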