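#' Simulate spatially autocorrelated climate layers
#'
#' Each layer is Gaussian-smoothed white noise plus a north-south linear
#' gradient, standardized to the requested mean and standard deviation over
#' the grid. `smoothness` is the standard deviation (in cells) of the
#' smoothing kernel and controls the spatial autocorrelation range; as it
#' grows the field approaches the pure gradient. The result is deterministic
#' given `seed`.
#'
#' @param n_rows,n_cols grid dimensions (each at least 10).
#' @param var_names character vector of at least two layer names.
#' @param smoothness positive kernel standard deviation, in cells.
#' @param seed integer seed.
#' @param gradient relative weight of the latitudinal gradient (default 1,
#'   equal weight with the smoothed noise).
#' @param mean,sd target mean and standard deviation of each layer.
#' @param xmin,ymax,cellsize grid georeferencing; the default cell size of
#'   1/6 degree corresponds to a 10-arc-minute climatology grid.
#' @return an [env_stack()].
#' @export
simulate_climate <- function(n_rows, n_cols, var_names, smoothness = 5,
                             seed = 1L, gradient = 1, mean = 0, sd = 1,
                             xmin = -100, ymax = 45, cellsize = 1 / 6) {
  if (n_rows < 10 || n_cols < 10) {
    stop("grid must be at least 10 x 10 cells", call. = FALSE)
  }
  if (length(var_names) < 2L) stop("need at least two variables", call. = FALSE)
  stopifnot(smoothness > 0, sd > 0)
  set.seed(seed)
  grad <- matrix(rep(seq_len(n_rows), n_cols), n_rows, n_cols)
  grad <- (grad - base::mean(grad)) / stats::sd(as.vector(grad))
  layers <- lapply(seq_along(var_names), function(i) {
    noise <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
    sm <- gaussian_blur(noise, smoothness)
    sm <- (sm - base::mean(sm)) / stats::sd(as.vector(sm))
    f <- sm + gradient * grad
    mean + sd * (f - base::mean(f)) / stats::sd(as.vector(f))
  })
  names(layers) <- var_names
  env_stack(layers, xmin = xmin, ymax = ymax, cellsize = cellsize)
}

#' Separable Gaussian blur with reflective edge padding
#' @keywords internal
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur_1d <- function(x) {
    n <- length(x)
    pad <- c(x[pmin(r:1, n)], x, x[pmax(n - (1:r) + 1L, 1L)])
    stats::convolve(pad, rev(k), type = "filter")
  }
  m2 <- apply(m, 2L, blur_1d)
  t(apply(t(m2), 2L, blur_1d))
}

#' Define a virtual species with known suitability
#'
#' Truth suitability is a product of independent Gaussian response curves,
#' one per response variable: `prod(exp(-(x - optimum)^2 / (2 breadth^2)))`,
#' rescaled so its maximum over valid cells is 1. Suitability is therefore
#' maximal where every response variable sits at its optimum.
#'
#' @param env an [env_stack()].
#' @param response_vars names of the variables the species responds to.
#' @param optima numeric vector of optima, one per response variable.
#' @param breadths positive numeric vector of niche breadths (same units as
#'   the variables), one per response variable.
#' @return object of class `virtual_species` with fields `response_vars`,
#'   `optima`, `breadths`, `truth` (matrix in \[0, 1\]) and `env` reference
#'   metadata.
#' @export
virtual_species <- function(env, response_vars, optima, breadths) {
  missing_v <- setdiff(response_vars, names(env$layers))
  if (length(missing_v)) {
    stop("unknown variable(s): ", paste(missing_v, collapse = ", "), call. = FALSE)
  }
  stopifnot(length(optima) == length(response_vars),
            length(breadths) == length(response_vars))
  if (any(breadths <= 0)) stop("breadths must be positive", call. = FALSE)
  d <- dim(env)
  logs <- matrix(0, d[1], d[2])
  for (i in seq_along(response_vars)) {
    x <- env$layers[[response_vars[i]]]
    logs <- logs - (x - optima[i])^2 / (2 * breadths[i]^2)
  }
  truth <- exp(logs)
  truth[!env$mask] <- NA_real_
  mx <- max(truth, na.rm = TRUE)
  if (mx > 0) truth <- truth / mx
  structure(
    list(response_vars = response_vars,
         optima = stats::setNames(optima, response_vars),
         breadths = stats::setNames(breadths, response_vars),
         truth = truth,
         xmin = env$xmin, ymax = env$ymax, cellsize = env$cellsize,
         mask = env$mask),
    class = "virtual_species"
  )
}

#' @export
print.virtual_species <- function(x, ...) {
  cat("<virtual_species> responds to:",
      paste(sprintf("%s (opt %.3g, breadth %.3g)", x$response_vars,
                    x$optima, x$breadths), collapse = "; "), "\n")
  invisible(x)
}

#' Default coordinate-uncertainty law
#'
#' Lognormal with median 5,000 m and 10% of mass above 10,000 m, so that an
#' uncertainty filter at 10 km removes roughly a tenth of simulated records.
#'
#' @param n number of draws.
#' @return numeric vector of uncertainty radii in meters.
#' @export
default_uncertainty_law <- function(n) {
  # sdlog solves P(X > 10000) = 0.1 with medianlog = log(5000)
  stats::rlnorm(n, meanlog = log(5000), sdlog = log(2) / stats::qnorm(0.9))
}

#' Sample occurrence records from a virtual species
#'
#' Cells are drawn with probability proportional to truth suitability;
#' coordinates are jittered uniformly within the chosen cell; each record
#' receives an uncertainty radius drawn from `uncertainty_law`. Deterministic
#' given `seed`.
#'
#' @param species a [virtual_species()].
#' @param n number of records (>= 1).
#' @param uncertainty_law function of `n` returning uncertainty radii in
#'   meters; default [default_uncertainty_law()].
#' @param seed integer seed.
#' @return occurrence tibble with columns `species`, `longitude`, `latitude`,
#'   `uncertainty_m`, `source_id`.
#' @export
sample_occurrences <- function(species, n, uncertainty_law = default_uncertainty_law,
                               seed = 1L) {
  stopifnot(n >= 1)
  p <- as.vector(species$truth)
  p[is.na(p)] <- 0
  if (all(p <= 0)) stop("truth grid has no cell with positive suitability",
                        call. = FALSE)
  set.seed(seed)
  cells <- sample.int(length(p), n, replace = TRUE, prob = p)
  d <- dim(species$truth)
  row <- ((cells - 1L) %% d[1]) + 1L
  col <- ((cells - 1L) %/% d[1]) + 1L
  lon <- species$xmin + (col - 1L + stats::runif(n)) * species$cellsize
  lat <- species$ymax - (row - 1L + stats::runif(n)) * species$cellsize
  tibble::tibble(
    species = "virtual",
    longitude = lon,
    latitude = lat,
    uncertainty_m = uncertainty_law(n),
    source_id = sprintf("sim-%06d", seq_len(n))
  )
}

#' Generate pseudo-GCM future climate scenarios
#'
#' Each future stack is the present stack plus a scenario-wide mean shift per
#' variable (the "delta") plus a pseudo-GCM-specific smooth perturbation
#' field, emulating the regional disagreement between circulation models. A
#' scenario with uniformly larger deltas shifts every variable strictly more
#' than a smaller-delta one.
#'
#' @param env the present-day [env_stack()].
#' @param n_gcm number of pseudo-GCMs (>= 1).
#' @param scenario_deltas named list, one element per scenario, each a named
#'   numeric vector of per-variable mean shifts covering every layer in `env`.
#' @param perturb_sd standard deviation of the GCM-specific smooth
#'   perturbation (0 disables it).
#' @param smoothness kernel sd (cells) for the perturbation fields.
#' @param seed integer seed.
#' @return object of class `scenario_set`: list with `present`, `futures`
#'   (named `gcm<i>.<scenario>` -> `env_stack`) and `deltas`.
#' @export
simulate_futures <- function(env, n_gcm, scenario_deltas, perturb_sd = 0.15,
                             smoothness = 8, seed = 1L) {
  stopifnot(n_gcm >= 1, length(scenario_deltas) >= 1)
  vn <- names(env$layers)
  for (s in names(scenario_deltas)) {
    if (!setequal(names(scenario_deltas[[s]]), vn)) {
      stop("delta vector for scenario '", s,
           "' must name every stack variable", call. = FALSE)
    }
  }
  set.seed(seed)
  d <- dim(env)
  futures <- list()
  for (g in seq_len(n_gcm)) {
    # one smooth perturbation field per GCM x variable, shared across scenarios
    pert <- lapply(vn, function(v) {
      if (perturb_sd <= 0) return(matrix(0, d[1], d[2]))
      f <- gaussian_blur(matrix(stats::rnorm(d[1] * d[2]), d[1], d[2]), smoothness)
      perturb_sd * f / stats::sd(as.vector(f))
    })
    names(pert) <- vn
    for (s in names(scenario_deltas)) {
      delta <- scenario_deltas[[s]]
      layers <- lapply(vn, function(v) env$layers[[v]] + delta[[v]] + pert[[v]])
      names(layers) <- vn
      futures[[paste0("gcm", g, ".", s)]] <-
        env_stack(layers, env$xmin, env$ymax, env$cellsize, mask = env$mask)
    }
  }
  structure(list(present = env, futures = futures, deltas = scenario_deltas),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat(sprintf("<scenario_set> present + %d future stack(s): %s\n",
              length(x$futures), paste(names(x$futures), collapse = ", ")))
  invisible(x)
}
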