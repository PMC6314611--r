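#' Co-registered environmental raster stack
#'
#' An `env_stack` holds one or more named environmental layers on a shared
#' regular lon/lat grid: a named list of numeric matrices (row 1 is the
#' northernmost row), an affine transform (upper-left corner and square cell
#' size in decimal degrees), and a joint validity mask. All layers must share
#' shape, transform and mask, and must be finite on valid cells.
#'
#' @param layers named list of numeric matrices, all the same dimension.
#' @param xmin longitude of the left (west) edge of the grid, decimal degrees.
#' @param ymax latitude of the top (north) edge of the grid, decimal degrees.
#' @param cellsize cell size in decimal degrees (square cells).
#' @param mask optional logical matrix marking valid cells; defaults to cells
#'   finite in every layer.
#'
#' @return an object of class `env_stack`.
#' @export
env_stack <- function(layers, xmin, ymax, cellsize, mask = NULL) {
  if (!is.list(layers) || length(layers) < 1L || is.null(names(layers)) ||
      any(!nzchar(names(layers)))) {
    stop("`layers` must be a non-empty named list of matrices", call. = FALSE)
  }
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all layers must share the same dimensions", call. = FALSE)
  }
  finite <- Reduce(`&`, lapply(layers, is.finite))
  if (is.null(mask)) mask <- finite else mask <- mask & finite
  stopifnot(is.matrix(mask), identical(dim(mask), dim(layers[[1]])))
  structure(
    list(layers = lapply(layers, unname), xmin = xmin, ymax = ymax,
         cellsize = cellsize, mask = mask),
    class = "env_stack"
  )
}

#' @export
print.env_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("<env_stack> %d x %d cells, %.4f deg, %d layer(s): %s\n",
              d[1], d[2], x$cellsize, length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  cat(sprintf("  extent: lon [%.3f, %.3f], lat [%.3f, %.3f]; %d valid cells\n",
              x$xmin, x$xmin + d[2] * x$cellsize,
              x$ymax - d[1] * x$cellsize, x$ymax, sum(x$mask)))
  invisible(x)
}

#' @export
dim.env_stack <- function(x) dim(x$layers[[1]])

#' @export
names.env_stack <- function(x) names(x$layers)

#' Longitude/latitude of cell centers
#'
#' @param env an `env_stack`.
#' @return list with `lon` (length ncol) and `lat` (length nrow) center
#'   coordinates; row 1 / lat[1] is the northernmost row.
#' @keywords internal
cell_centers <- function(env) {
  d <- dim(env)
  list(
    lon = env$xmin + (seq_len(d[2]) - 0.5) * env$cellsize,
    lat = env$ymax - (seq_len(d[1]) - 0.5) * env$cellsize
  )
}

#' Cell values as a tidy matrix
#'
#' Flattens the stack to a cells-by-variables matrix over the cells of `mask`
#' (default: the stack's valid mask). Row order is matrix element order
#' (column-major over the grid), recorded in the `"cells"` attribute.
#'
#' @param env an `env_stack`.
#' @param mask logical matrix selecting cells; intersected with the stack mask.
#' @return numeric matrix, one column per layer; attribute `"cells"` holds the
#'   flat cell indices.
#' @export
stack_values <- function(env, mask = NULL) {
  m <- if (is.null(mask)) env$mask else (mask & env$mask)
  idx <- which(m)
  out <- vapply(env$layers, function(l) l[idx], numeric(length(idx)))
  if (length(idx) == 1L) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(env$layers)))
  attr(out, "cells") <- idx
  out
}

#' Rebuild a grid from per-cell values
#'
#' Inverse of [stack_values()] for a single quantity: places `values` at the
#' flat indices `cells` and `NA` elsewhere.
#' @keywords internal
grid_from_values <- function(values, cells, dims) {
  g <- matrix(NA_real_, dims[1], dims[2])
  g[cells] <- values
  g
}

# ---- ESRI ASCII grid I/O ----------------------------------------------------

#' Read co-registered ESRI ASCII grids into an `env_stack`
#'
#' Layer names are taken from file stems. All files must agree on ncols,
#' nrows, corner and cell size; the joint valid mask is the intersection of
#' the per-layer nodata masks.
#'
#' @param paths character vector of `.asc` file paths.
#' @return an `env_stack`.
#' @export
read_env_ascii <- function(paths) {
  stopifnot(length(paths) >= 1L)
  grids <- lapply(paths, read_one_ascii)
  hdr <- grids[[1]]$header
  for (g in grids[-1]) {
    if (!isTRUE(all.equal(g$header[c("ncols", "nrows", "xll", "yll", "cellsize")],
                          hdr[c("ncols", "nrows", "xll", "yll", "cellsize")],
                          tolerance = 1e-9))) {
      stop("grids are not co-registered (shape/transform mismatch)", call. = FALSE)
    }
  }
  layers <- lapply(grids, `[[`, "values")
  names(layers) <- sub("\\.[^.]*$", "", basename(paths))
  env_stack(layers,
            xmin = hdr[["xll"]],
            ymax = hdr[["yll"]] + hdr[["nrows"]] * hdr[["cellsize"]],
            cellsize = hdr[["cellsize"]])
}

read_one_ascii <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  keys <- tolower(vapply(kv, `[[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% keys)) stop("malformed ESRI ASCII header in ", path, call. = FALSE)
  xll <- if ("xllcorner" %in% keys) vals[["xllcorner"]] else
    vals[["xllcenter"]] - vals[["cellsize"]] / 2
  yll <- if ("yllcorner" %in% keys) vals[["yllcorner"]] else
    vals[["yllcenter"]] - vals[["cellsize"]] / 2
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  n_header <- sum(keys %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                              "xllcenter", "yllcenter", "cellsize", "nodata_value"))
  v <- scan(path, what = numeric(), skip = n_header, quiet = TRUE)
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  if (length(v) != nr * nc) stop("wrong cell count in ", path, call. = FALSE)
  m <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)  # rows north to south
  m[m == nodata] <- NA_real_
  list(header = c(ncols = nc, nrows = nr, xll = xll, yll = yll,
                  cellsize = vals[["cellsize"]]),
       values = m)
}

#' Write an `env_stack` as one ESRI ASCII grid per layer
#'
#' @param env an `env_stack`.
#' @param dir output directory (created if needed).
#' @param digits significant digits written (default 7, ~ float32).
#' @return invisibly, the written file paths.
#' @export
write_env_ascii <- function(env, dir, digits = 7) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(env)
  hdr <- sprintf(
    "ncols %d\nnrows %d\nxllcorner %.10g\nyllcorner %.10g\ncellsize %.10g\nNODATA_value -9999",
    d[2], d[1], env$xmin, env$ymax - d[1] * env$cellsize, env$cellsize)
  paths <- file.path(dir, paste0(names(env$layers), ".asc"))
  for (i in seq_along(env$layers)) {
    m <- env$layers[[i]]
    m[!env$mask] <- NA_real_
    body <- apply(signif(m, digits), 1L, function(r) {
      r[is.na(r)] <- -9999
      paste(format(r, trim = TRUE, scientific = FALSE), collapse = " ")
    })
    writeLines(c(hdr, body), paths[i])
  }
  invisible(paths)
}

# ---- Accessible area (M) and value extraction ------------------------------

#' Build an accessible-area (M) mask around occurrences
#'
#' A cell belongs to M when its center lies within `buffer_deg` degrees of
#' great-circle arc (1 degree ~ 111.32 km) of at least one occurrence. The
#' result is intersected with the stack's valid mask and, optionally, an
#' extra region mask (e.g. a country mask).
#'
#' @param occ occurrence tibble with `longitude` and `latitude` columns.
#' @param env an `env_stack`.
#' @param buffer_deg buffer radius in degrees of arc (default 7).
#' @param region_mask optional logical matrix to intersect with.
#' @return logical matrix aligned with `env`.
#' @export
build_m_mask <- function(occ, env, buffer_deg = 7, region_mask = NULL) {
  stopifnot(buffer_deg > 0, nrow(occ) >= 1L)
  cc <- cell_centers(env)
  d <- dim(env)
  grid_pts <- cbind(lon = rep(cc$lon, each = d[1]), lat = rep(cc$lat, times = d[2]))
  pts <- as.matrix(occ[, c("longitude", "latitude")])
  # central angle (deg) from haversine distance on the sphere
  within <- rep(FALSE, nrow(grid_pts))
  for (i in seq_len(nrow(pts))) {
    dm <- geosphere::distHaversine(pts[i, , drop = TRUE], grid_pts, r = .earth_radius_m)
    ang <- dm / .earth_radius_m * 180 / pi
    within <- within | (ang <= buffer_deg)
  }
  m <- matrix(within, d[1], d[2]) & env$mask
  if (!is.null(region_mask)) m <- m & region_mask
  if (!any(m)) stop("no valid cell falls within the buffer of any occurrence",
                    call. = FALSE)
  m
}

#' Extract per-record environmental values by nearest cell center
#'
#' Cells are addressed with half-open intervals `[edge, edge + cellsize)` from
#' the upper-left corner. Records falling off-grid or on invalid (nodata)
#' cells are excluded with a message giving the count.
#'
#' @param env an `env_stack`.
#' @param occ occurrence tibble with `longitude`, `latitude`.
#' @return tibble with `.record` (row index into `occ`), `.cell` (flat cell
#'   index) and one column per layer.
#' @export
extract_values <- function(env, occ) {
  d <- dim(env)
  col <- floor((occ$longitude - env$xmin) / env$cellsize) + 1L
  row <- floor((env$ymax - occ$latitude) / env$cellsize) + 1L
  on_grid <- col >= 1L & col <= d[2] & row >= 1L & row <= d[1]
  cell <- ifelse(on_grid, (col - 1L) * d[1] + row, NA_integer_)
  valid <- on_grid
  valid[on_grid] <- env$mask[cell[on_grid]]
  n_drop <- sum(!valid)
  if (n_drop == nrow(occ)) stop("all records fall outside the valid grid", call. = FALSE)
  if (n_drop > 0) message(n_drop, " record(s) on invalid or off-grid cells excluded")
  keep <- which(valid)
  vals <- lapply(env$layers, function(l) l[cell[keep]])
  tibble::tibble(.record = keep, .cell = cell[keep], !!!vals)
}

.earth_radius_m <- 6371008.8
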