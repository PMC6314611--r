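#' @importFrom ggplot2 autoplot
NULL

#' @export
ggplot2::autoplot

grid_to_df <- function(values, xmin, ymax, cellsize) {
  d <- dim(values)
  tibble::tibble(
    lon = rep(xmin + (seq_len(d[2]) - 0.5) * cellsize, each = d[1]),
    lat = rep(ymax - (seq_len(d[1]) - 0.5) * cellsize, times = d[2]),
    value = as.vector(values)
  )
}

#' Plot an environmental stack
#'
#' One faceted raster panel per layer; invalid cells are blank.
#'
#' @param object an [env_stack()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.env_stack <- function(object, ...) {
  dfs <- purrr::map_dfr(names(object$layers), function(nm) {
    v <- object$layers[[nm]]
    v[!object$mask] <- NA_real_
    dplyr::mutate(grid_to_df(v, object$xmin, object$ymax, object$cellsize),
                  layer = nm)
  })
  ggplot2::ggplot(dfs, ggplot2::aes(.data$lon, .data$lat, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~layer) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "value")
}

#' Plot a suitability surface
#'
#' @param object a `suitability_grid`.
#' @param occurrences optional occurrence tibble overlaid as points.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.suitability_grid <- function(object, occurrences = NULL, ...) {
  df <- grid_to_df(object$values, object$xmin, object$ymax, object$cellsize)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  limits = if (object$scale == "cloglog")
                                    c(0, 1) else NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  fill = paste0("suitability\n(", object$scale, ")"))
  if (!is.null(occurrences)) {
    p <- p + ggplot2::geom_point(
      data = occurrences,
      ggplot2::aes(.data$longitude, .data$latitude),
      inherit.aes = FALSE, shape = 3, size = 0.8, colour = "red")
  }
  p
}

#' Plot a GCM-agreement composite
#'
#' @param object an `agreement_map`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.agreement_map <- function(object, ...) {
  df <- grid_to_df(object$values, object$xmin, object$ymax, object$cellsize)
  df$class <- factor(df$value, levels = names(object$legend),
                     labels = object$legend)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1,
                               na.value = "grey90", drop = TRUE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "agreement")
}

#' Candidate-evaluation diagnostic plot
#'
#' Omission rate versus AICc for every candidate, coloured by partial-ROC
#' significance, with the selected models highlighted.
#'
#' @param results candidate table from [calibrate_candidates()].
#' @param selected optional selection from [select_models()].
#' @param alpha significance level used for colouring.
#' @return a ggplot.
#' @export
plot_candidates <- function(results, selected = NULL, alpha = 0.05) {
  results$significant <- !is.na(results$proc_p) & results$proc_p < alpha
  p <- ggplot2::ggplot(
    dplyr::filter(results, is.finite(.data$aicc)),
    ggplot2::aes(.data$aicc, .data$omission, colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = 2) +
    ggplot2::labs(x = "AICc", y = "omission rate (E = 5%)",
                  colour = "pROC significant")
  if (!is.null(selected) && nrow(selected)) {
    p <- p + ggplot2::geom_point(data = selected, colour = "red", shape = 1,
                                 size = 3)
  }
  p
}
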