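#' Mobility-oriented parity (MOP) extrapolation-risk analysis
#'
#' Measures, for every projection cell, the environmental distance to the
#' calibration conditions: variables are standardized by the calibration mean
#' and standard deviation, and each projection cell's distance is the mean
#' Euclidean distance to its nearest `ceiling(reference_fraction * n_calib)`
#' calibration cells. Novelty is the excess of that distance over the
#' calibration cloud's own internal scale (the maximum of the same statistic
#' computed for the calibration cells themselves), and similarity is
#' `1 - excess / max(excess)`: conditions no farther from the cloud than the
#' cloud is from itself score 1, so a projection region identical to the
#' calibration region is maximally similar everywhere (a zero maximum excess
#' is handled as similarity 1). Strict extrapolation is flagged wherever any
#' raw (unstandardized) variable falls outside the calibration min-max
#' range.
#'
#' @param calib calibration conditions: matrix/tibble of cell values, or an
#'   [env_stack()] (optionally with `calib_mask`).
#' @param projection projection conditions: matrix/tibble, or an
#'   [env_stack()] (optionally with `projection_mask`); same variables as
#'   `calib`.
#' @param reference_fraction fraction of calibration cells forming the
#'   nearest reference set (0 < f <= 1, default 0.1).
#' @param calib_mask,projection_mask optional logical matrices when stacks
#'   are supplied.
#' @param max_calib calibration clouds larger than this are reduced to a
#'   seeded subsample of this size (default 10,000); set `Inf` for exact
#'   mode.
#' @param seed seed for the optional subsample.
#' @return object of class `mop_result`: `similarity`, `strict`, raw
#'   `distance` and `excess` vectors aligned with the projection cells (plus
#'   the scalar `baseline`); when `projection` is an `env_stack`, also
#'   `similarity_grid` and `strict_grid` matrices.
#' @export
mop <- function(calib, projection, reference_fraction = 0.1,
                calib_mask = NULL, projection_mask = NULL,
                max_calib = 10000, seed = 1L) {
  stopifnot(reference_fraction > 0, reference_fraction <= 1)
  proj_is_stack <- inherits(projection, "env_stack")
  if (inherits(calib, "env_stack")) {
    calib_m <- stack_values(calib, calib_mask)
  } else {
    calib_m <- as_var_matrix(calib)
  }
  if (proj_is_stack) {
    proj_vals <- stack_values(projection, projection_mask)
    proj_cells <- attr(proj_vals, "cells")
    proj_dims <- dim(projection)
    proj_m <- as_var_matrix(proj_vals, colnames(calib_m))
  } else {
    proj_m <- as_var_matrix(projection, colnames(calib_m))
  }
  if (nrow(calib_m) == 0L) stop("empty calibration set", call. = FALSE)
  calib_m <- calib_m[, colnames(calib_m), drop = FALSE]
  nc <- nrow(calib_m)
  if (nc > max_calib) {
    set.seed(seed)
    calib_sub <- calib_m[sample.int(nc, max_calib), , drop = FALSE]
  } else {
    calib_sub <- calib_m
  }
  # strict extrapolation on raw values against the FULL calibration range
  cmin <- apply(calib_m, 2, min)
  cmax <- apply(calib_m, 2, max)
  strict <- rep(FALSE, nrow(proj_m))
  for (j in seq_len(ncol(proj_m))) {
    strict <- strict | proj_m[, j] < cmin[j] | proj_m[, j] > cmax[j]
  }
  # distances on standardized variables
  mu <- colMeans(calib_m)
  sdev <- apply(calib_m, 2, stats::sd)
  sdev[sdev <= 0] <- 1
  cs <- sweep(sweep(calib_sub, 2, mu, "-"), 2, sdev, "/")
  ps <- sweep(sweep(proj_m, 2, mu, "-"), 2, sdev, "/")
  m_ref <- max(1L, ceiling(reference_fraction * nrow(cs)))
  cs_sq <- rowSums(cs^2)
  n_proj <- nrow(ps)
  dist_mean <- numeric(n_proj)
  chunk <- max(1L, floor(4e6 / nrow(cs)))
  for (start in seq(1L, n_proj, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_proj)
    # squared distances projection-chunk x calibration
    d2 <- outer(rowSums(ps[idx, , drop = FALSE]^2), cs_sq, "+") -
      2 * ps[idx, , drop = FALSE] %*% t(cs)
    d2[d2 < 0] <- 0
    d <- sqrt(d2)
    dist_mean[idx] <- apply(d, 1L, function(r) {
      mean(sort.int(r, partial = m_ref)[seq_len(m_ref)])
    })
  }
  # novelty baseline: the same nearest-fraction statistic evaluated for the
  # calibration cells themselves; conditions within the cloud's own scale
  # carry zero excess novelty, so a projection region identical to the
  # calibration region is maximally similar everywhere
  baseline <- numeric(nrow(cs))
  for (start in seq(1L, nrow(cs), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(cs))
    d2 <- outer(cs_sq[idx], cs_sq, "+") - 2 * cs[idx, , drop = FALSE] %*% t(cs)
    d2[d2 < 0] <- 0
    d <- sqrt(d2)
    baseline[idx] <- apply(d, 1L, function(r) {
      mean(sort.int(r, partial = m_ref)[seq_len(m_ref)])
    })
  }
  excess <- pmax(0, dist_mean - max(baseline))
  mx <- max(excess)
  similarity <- if (mx > 0) 1 - excess / mx else rep(1, n_proj)
  out <- list(similarity = similarity, strict = strict, distance = dist_mean,
              excess = excess, baseline = max(baseline),
              reference_fraction = reference_fraction, m_ref = m_ref,
              n_calib = nrow(cs))
  if (proj_is_stack) {
    out$similarity_grid <- grid_from_values(similarity, proj_cells, proj_dims)
    sg <- grid_from_values(as.numeric(strict), proj_cells, proj_dims)
    out$strict_grid <- sg > 0
    out$xmin <- projection$xmin
    out$ymax <- projection$ymax
    out$cellsize <- projection$cellsize
  }
  structure(out, class = "mop_result")
}

#' @export
print.mop_result <- function(x, ...) {
  cat(sprintf(
    "<mop_result> %d projection cells vs %d calibration cells (nearest %d): similarity [%.3f, %.3f], %d strict-extrapolation cell(s)\n",
    length(x$similarity), x$n_calib, x$m_ref, min(x$similarity),
    max(x$similarity), sum(x$strict)))
  invisible(x)
}

#' Cross-GCM agreement of strict extrapolation
#'
#' Counts, per projection cell, how many GCMs flag strict extrapolation.
#'
#' @param mop_results list of co-registered `mop_result`s (one per GCM),
#'   each carrying grids (i.e. built from `env_stack` projections).
#' @return integer matrix of counts (0 to the number of results).
#' @export
mop_agreement <- function(mop_results) {
  stopifnot(length(mop_results) >= 1L)
  grids <- lapply(mop_results, function(m) {
    if (is.null(m$strict_grid)) {
      stop("mop_agreement needs grid-based mop results", call. = FALSE)
    }
    m$strict_grid
  })
  d <- dim(grids[[1]])
  for (g in grids[-1]) {
    if (!identical(dim(g), d)) stop("misaligned mop results", call. = FALSE)
  }
  out <- matrix(0L, d[1], d[2])
  na_all <- Reduce(`&`, lapply(grids, is.na))
  for (g in grids) {
    gi <- g
    gi[is.na(gi)] <- FALSE
    out <- out + gi
  }
  out[na_all] <- NA_integer_
  out
}
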