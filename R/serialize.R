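#' Save or load a maxent model as structured text
#'
#' Serializes the feature specification, coefficient vector and normalizers
#' to JSON. Numeric values are written as 17-significant-digit decimal
#' strings, which round-trip IEEE doubles exactly, so a reloaded model
#' reproduces predictions bit for bit.
#'
#' @param model a `maxent_model`.
#' @param path output/input file path.
#' @return `save_maxent_model` returns `path` invisibly; `load_maxent_model`
#'   returns the model.
#' @export
save_maxent_model <- function(model, path) {
  num <- function(x) {
    out <- as.list(sprintf("%.17g", as.numeric(x)))
    names(out) <- names(x)
    out
  }
  payload <- list(
    classes = model$spec$classes,
    vars = model$spec$vars,
    var_min = num(model$spec$var_min),
    var_max = num(model$spec$var_max),
    hinge_knots = lapply(model$spec$hinge_knots, function(k) unname(num(k))),
    threshold_knots = lapply(model$spec$threshold_knots,
                             function(k) unname(num(k))),
    feat_min = num(model$spec$feat_min),
    feat_max = num(model$spec$feat_max),
    feat_class = as.list(model$spec$feat_class),
    lambdas = num(model$lambdas),
    betas = num(model$betas),
    beta_multiplier = sprintf("%.17g", model$beta_multiplier),
    linear_predictor_normalizer = sprintf("%.17g",
                                          model$linear_predictor_normalizer),
    density_normalizer = sprintf("%.17g", model$density_normalizer),
    entropy = sprintf("%.17g", model$entropy),
    n_presence = model$n_presence,
    n_background = model$n_background,
    loglik = sprintf("%.17g", model$loglik),
    gain = sprintf("%.17g", model$gain),
    k = model$k,
    converged = model$converged
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_maxent_model
#' @export
load_maxent_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(x) {
    out <- as.numeric(unlist(x))
    names(out) <- names(x)
    out
  }
  spec <- structure(
    list(classes = p$classes, vars = p$vars,
         var_min = num(p$var_min), var_max = num(p$var_max),
         hinge_knots = if (length(p$hinge_knots))
           lapply(p$hinge_knots, function(k) as.numeric(unlist(k))) else NULL,
         threshold_knots = if (length(p$threshold_knots))
           lapply(p$threshold_knots, function(k) as.numeric(unlist(k))) else NULL,
         feat_min = num(p$feat_min), feat_max = num(p$feat_max),
         feat_class = unlist(p$feat_class)),
    class = "feature_spec"
  )
  structure(
    list(spec = spec,
         lambdas = num(p$lambdas), betas = num(p$betas),
         beta_multiplier = as.numeric(p$beta_multiplier),
         linear_predictor_normalizer = as.numeric(p$linear_predictor_normalizer),
         density_normalizer = as.numeric(p$density_normalizer),
         entropy = as.numeric(p$entropy), n_presence = p$n_presence,
         n_background = p$n_background, loglik = as.numeric(p$loglik),
         gain = as.numeric(p$gain), k = p$k, converged = p$converged),
    class = "maxent_model"
  )
}
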