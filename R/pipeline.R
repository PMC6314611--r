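#' Build a validated pipeline configuration
#'
#' Collects every tunable of the workflow with its standard default:
#' coordinate-uncertainty cutoff 10,000 m; 50 km rarefaction; 7 degree
#' accessible-area buffer; acceptable omission E = 5%; partial-ROC alpha =
#' 0.05 with 500 bootstrap draws of half the evaluation points; AICc window
#' of 2; 10 final-model replicates; the 17-value regularization-multiplier
#' grid; all 31 feature-class combinations; MOP reference fraction 0.1.
#'
#' @param occurrences path to the occurrence CSV.
#' @param env_present directory of present-day `.asc` layers.
#' @param env_futures named list: scenario label (e.g. `gcm1.rcp45`) ->
#'   directory of co-registered future `.asc` layers.
#' @param exclusions optional path to a CSV of `source_id`s to drop.
#' @param max_uncertainty_m,thin_km,buffer_deg,E,alpha,delta_aicc,n_replicates
#'   workflow parameters (see description).
#' @param multipliers regularization multipliers (numeric vector or spec
#'   string for [parse_multipliers()]).
#' @param combos named list of feature-class combinations.
#' @param varset_sizes decreasing target sizes for the jackknife variable
#'   reduction (the full set is always included as the first varset).
#' @param n_boot,boot_frac partial-ROC bootstrap settings.
#' @param mop_fraction MOP reference fraction.
#' @param max_background background sample cap.
#' @param seed master seed; all stage seeds derive from it.
#' @return object of class `run_config` (a validated named list).
#' @export
run_config <- function(occurrences, env_present, env_futures = list(),
                       exclusions = NULL,
                       max_uncertainty_m = 10000, thin_km = 50,
                       buffer_deg = 7, E = 0.05, alpha = 0.05,
                       delta_aicc = 2, n_replicates = 10,
                       multipliers = default_multipliers(),
                       combos = feature_class_combos(),
                       varset_sizes = integer(),
                       n_boot = 500, boot_frac = 0.5,
                       mop_fraction = 0.1, max_background = 10000,
                       seed = 1L) {
  if (is.character(multipliers) && length(multipliers) == 1L) {
    multipliers <- parse_multipliers(multipliers)
  }
  cfg <- list(
    occurrences = occurrences, env_present = env_present,
    env_futures = env_futures, exclusions = exclusions,
    max_uncertainty_m = max_uncertainty_m, thin_km = thin_km,
    buffer_deg = buffer_deg, E = E, alpha = alpha, delta_aicc = delta_aicc,
    n_replicates = n_replicates, multipliers = multipliers, combos = combos,
    varset_sizes = as.integer(varset_sizes), n_boot = n_boot,
    boot_frac = boot_frac, mop_fraction = mop_fraction,
    max_background = max_background, seed = as.integer(seed)
  )
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  chk(cfg$max_uncertainty_m > 0, "max_uncertainty_m must be positive")
  chk(cfg$thin_km > 0, "thin_km must be positive")
  chk(cfg$buffer_deg > 0, "buffer_deg must be positive")
  chk(cfg$E > 0 && cfg$E < 0.5, "E must be in (0, 0.5)")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  chk(cfg$delta_aicc >= 0, "delta_aicc must be non-negative")
  chk(cfg$n_replicates >= 1, "n_replicates must be at least 1")
  chk(length(cfg$multipliers) >= 1 && all(cfg$multipliers > 0),
      "multipliers must be positive")
  chk(length(cfg$combos) >= 1, "need at least one feature-class combination")
  chk(cfg$n_boot >= 1 && cfg$boot_frac > 0 && cfg$boot_frac <= 1,
      "bad partial-ROC bootstrap settings")
  chk(cfg$mop_fraction > 0 && cfg$mop_fraction <= 1,
      "mop_fraction must be in (0, 1]")
  invisible(cfg)
}

#' Write/read a pipeline configuration as YAML
#'
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the validated `run_config` (round-trips losslessly).
#' @export
write_run_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$combos <- lapply(cfg$combos, as.list)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$combos <- lapply(raw$combos, unlist)
  raw$env_futures <- as.list(raw$env_futures)
  do.call(run_config, raw)
}

# deterministic per-stage seed fan-out from the master seed
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101, thin = 211, split = 307, background = 401,
               proc = 503, replicates = 601, mop = 701)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483629)
}

#' Generate a ready-to-run synthetic demonstration setup
#'
#' Materializes a complete synthetic study in `output_dir`: six
#' spatially autocorrelated climate layers, a virtual species responding to
#' two of them, sampled occurrences with uncertainty radii, and 2 pseudo-GCM
#' x 2 scenario future stacks (a moderate and a stronger warming shift),
#' then returns a demonstration-scale [run_config()] (two variable sets,
#' four feature-class combinations, three multipliers).
#'
#' @param output_dir writable directory for the generated inputs.
#' @param seed master seed.
#' @param n_rows,n_cols grid size (default 60 x 60).
#' @param n_occ number of occurrence records sampled (default 800); after the
#'   uncertainty filter and 50-km rarefaction roughly 170 records remain,
#'   mirroring a realistically sized rarefied occurrence compilation.
#' @return the `run_config`, with the truth-holding `virtual_species` in
#'   attribute `"species"` and the scenario set in attribute `"scenarios"`.
#' @export
demo_config <- function(output_dir, seed = 1L, n_rows = 60, n_cols = 60,
                        n_occ = 800) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(output_dir, 2L) != 0L) {
    stop("output directory is not writable: ", output_dir, call. = FALSE)
  }
  sim_seed <- stage_seed(seed, "simulate")
  vars <- c("t1", "t2", "t3", "p1", "p2", "p3")
  env <- simulate_climate(n_rows, n_cols, vars, smoothness = 5,
                          seed = sim_seed)
  sp <- virtual_species(env, c("t1", "p1"), optima = c(0.5, -0.3),
                        breadths = c(0.8, 1.0))
  occ <- sample_occurrences(sp, n_occ, seed = sim_seed + 1L)
  # two emissions scenarios: the stronger one shifts every variable more
  deltas <- list(
    rcp45 = c(t1 = 0.5, t2 = 0.4, t3 = 0.4, p1 = -0.2, p2 = -0.15, p3 = -0.15),
    rcp85 = c(t1 = 1.2, t2 = 1.0, t3 = 1.0, p1 = -0.5, p2 = -0.4, p3 = -0.4)
  )
  scen <- simulate_futures(env, n_gcm = 2, scenario_deltas = deltas,
                           seed = sim_seed + 2L)
  occ_path <- file.path(output_dir, "occurrences.csv")
  readr::write_csv(occ, occ_path)
  present_dir <- file.path(output_dir, "env", "present")
  write_env_ascii(env, present_dir)
  fut_dirs <- list()
  for (nm in names(scen$futures)) {
    d <- file.path(output_dir, "env", nm)
    write_env_ascii(scen$futures[[nm]], d)
    fut_dirs[[nm]] <- d
  }
  cfg <- run_config(
    occurrences = occ_path,
    env_present = present_dir,
    env_futures = fut_dirs,
    combos = feature_class_combos()[c("l", "q", "lq", "lqp")],
    multipliers = c(0.5, 1, 2),
    varset_sizes = 4L,
    seed = seed
  )
  write_run_config(cfg, file.path(output_dir, "config.yml"))
  attr(cfg, "species") <- sp
  attr(cfg, "scenarios") <- scen
  cfg
}

read_stack_dir <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(paths)) stop("no .asc layers found in ", dir, call. = FALSE)
  read_env_ascii(paths)
}

#' Run the full niche-modeling pipeline
#'
#' Executes, in order: occurrence cleaning (exclusions, uncertainty filter,
#' rarefaction), calibration/evaluation split, accessible-area masking,
#' jackknife variable-set reduction, candidate enumeration and evaluation,
#' three-stage model selection, replicate final models with median/range
#' surfaces, thresholding and binary maps, transfers to every future
#' scenario, per-scenario GCM-agreement composites, and MOP extrapolation
#' risk. An empty selection halts cleanly with a diagnostic report. All
#' randomness derives from the config's master seed.
#'
#' @param config a [run_config()] or the path to a YAML config.
#' @param output_dir directory for result files (candidate table, grids,
#'   models, report); `NULL` (default) keeps everything in memory.
#' @param verbose print stage progress.
#' @return object of class `run_report`: stage audit, candidate table,
#'   selection, threshold, grids, MOP results and output paths.
#' @export
run_pipeline <- function(config, output_dir = NULL, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message("[nichecal] ", ...)
  t0 <- Sys.time()
  seed <- config$seed

  say("stage 1/9: occurrences")
  occ0 <- read_occurrences(config$occurrences)
  excl <- if (!is.null(config$exclusions) && file.exists(config$exclusions)) {
    readr::read_csv(config$exclusions, show_col_types = FALSE)$source_id
  } else character()
  occ <- clean_occurrences(occ0, config$max_uncertainty_m, config$thin_km,
                           exclude_ids = excl,
                           seed = stage_seed(seed, "thin"))
  audit <- attr(occ, "audit")

  say("stage 2/9: environmental stack and accessible area")
  env <- read_stack_dir(config$env_present)
  m_mask <- build_m_mask(occ, env, buffer_deg = config$buffer_deg)
  bg_vals <- stack_values(env, m_mask)
  if (nrow(bg_vals) > config$max_background) {
    set.seed(stage_seed(seed, "background"))
    keep <- sort(sample.int(nrow(bg_vals), config$max_background))
    cells <- attr(bg_vals, "cells")[keep]
    bg_vals <- bg_vals[keep, , drop = FALSE]
    attr(bg_vals, "cells") <- cells
  }

  say("stage 3/9: variable sets")
  occ_vals_all <- extract_values(env, occ)
  occ <- occ[occ_vals_all$.record, ]  # keep only records on valid cells
  varsets <- list(set_full = names(env$layers))
  if (length(config$varset_sizes)) {
    seq_red <- sequential_reduce(occ_vals_all, bg_vals,
                                 target_sizes = config$varset_sizes)
    varsets <- seq_red$sets
    names(varsets) <- paste0("set", vapply(varsets, length, integer(1)))
  }

  say("stage 4/9: calibration/evaluation split")
  halves <- split_half(occ, seed = stage_seed(seed, "split"))
  cal_vals <- extract_values(env, halves$calibration)
  eval_vals <- extract_values(env, halves$evaluation)

  say("stage 5/9: candidate evaluation (",
      length(varsets) * length(config$combos) * length(config$multipliers),
      " candidates)")
  candidates <- enumerate_candidates(config$combos, config$multipliers, varsets)
  results <- calibrate_candidates(
    candidates, varsets, config$combos, cal_vals, eval_vals, bg_vals,
    E = config$E, n_boot = config$n_boot, boot_frac = config$boot_frac,
    seed = stage_seed(seed, "proc"), verbose = verbose)

  say("stage 6/9: model selection")
  selected <- select_models(results, alpha = config$alpha,
                            omission_max = config$E,
                            delta_max = config$delta_aicc)
  report <- list(
    config = config, audit = audit, n_calibration = nrow(halves$calibration),
    n_evaluation = nrow(halves$evaluation), varsets = varsets,
    candidates = results, selected = selected,
    stage_counts = attr(selected, "stage_counts"), seeds = seed
  )
  class(report) <- "run_report"
  if (nrow(selected) == 0L) {
    say("empty selection; stopping with diagnostic report")
    report$status <- "empty-selection"
    report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (!is.null(output_dir)) write_report_files(report, output_dir)
    return(report)
  }

  say("stage 7/9: final replicate models")
  models <- list()
  for (i in seq_len(nrow(selected))) {
    sel <- selected[i, ]
    vars <- varsets[[sel$varset]]
    models[[i]] <- fit_replicates(
      cal_vals[, vars], bg_vals[, vars, drop = FALSE],
      classes = config$combos[[sel$classes]],
      beta_multiplier = sel$multiplier, n_rep = config$n_replicates,
      seed = stage_seed(seed, "replicates") + i)
  }
  all_models <- unlist(models, recursive = FALSE)
  pres_grids <- lapply(all_models, predict, env = env, region_mask = m_mask,
                       clamp = TRUE, output = "cloglog")
  pres <- median_and_range(pres_grids)
  med_at <- function(grid, vals) grid$values[vals$.cell]
  thr <- omission_rate(med_at(pres$median, cal_vals),
                       med_at(pres$median, eval_vals), E = config$E)
  pres_bin <- binarize(pres$median, thr$threshold)

  say("stage 8/9: scenario transfers and GCM agreement")
  futures <- lapply(config$env_futures, read_stack_dir)
  fut_median <- list()
  fut_bin <- list()
  for (nm in names(futures)) {
    grids <- lapply(all_models, transfer, scenario_env = futures[[nm]],
                    region_mask = m_mask, clamp = TRUE, output = "cloglog")
    fut_median[[nm]] <- median_and_range(grids)$median
    fut_bin[[nm]] <- binarize(fut_median[[nm]], thr$threshold)
  }
  scenarios <- unique(sub("^[^.]*\\.", "", names(futures)))
  agreement <- list()
  for (sc in scenarios) {
    members <- grep(paste0("\\.", sc, "$"), names(fut_bin), value = TRUE)
    agreement[[sc]] <- gcm_agreement(pres_bin, fut_bin[members])
  }

  say("stage 9/9: MOP extrapolation risk")
  mop_results <- list()
  mop_agree <- list()
  if (length(futures)) {
    for (nm in names(futures)) {
      mop_results[[nm]] <- mop(bg_vals, futures[[nm]],
                               reference_fraction = config$mop_fraction,
                               max_calib = config$max_background,
                               seed = stage_seed(seed, "mop"))
    }
    for (sc in scenarios) {
      members <- grep(paste0("\\.", sc, "$"), names(mop_results), value = TRUE)
      mop_agree[[sc]] <- mop_agreement(mop_results[members])
    }
  }

  report$status <- "ok"
  report$models <- all_models
  report$m_mask <- m_mask
  report$present <- pres
  report$threshold <- thr$threshold
  report$present_binary <- pres_bin
  report$future_median <- fut_median
  report$future_binary <- fut_bin
  report$agreement <- agreement
  report$mop <- mop_results
  report$mop_agreement <- mop_agree
  report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!is.null(output_dir)) write_report_files(report, output_dir)
  report
}

write_grid_asc <- function(values, tmpl, path) {
  v <- values
  if (is.logical(v)) v <- v * 1
  st <- env_stack(list(layer = v), tmpl$xmin, tmpl$ymax, tmpl$cellsize,
                  mask = !is.na(v))
  p <- write_env_ascii(st, dirname(path))
  file.rename(p, path)
  invisible(path)
}

write_report_files <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$candidates, file.path(output_dir, "candidates.csv"))
  if (nrow(report$selected)) {
    readr::write_csv(report$selected, file.path(output_dir, "selected.csv"))
  }
  if (!is.null(report$models)) {
    mdir <- file.path(output_dir, "models")
    dir.create(mdir, showWarnings = FALSE)
    for (i in seq_along(report$models)) {
      save_maxent_model(report$models[[i]],
                        file.path(mdir, sprintf("model_%02d.json", i)))
    }
    gdir <- file.path(output_dir, "grids")
    dir.create(gdir, showWarnings = FALSE)
    tmpl <- report$present$median
    write_grid_asc(tmpl$values, tmpl, file.path(gdir, "present_median.asc"))
    write_grid_asc(report$present$range$values, tmpl,
                   file.path(gdir, "present_range.asc"))
    write_grid_asc(report$present_binary$values, tmpl,
                   file.path(gdir, "present_binary.asc"))
    for (nm in names(report$future_binary)) {
      write_grid_asc(report$future_binary[[nm]]$values, tmpl,
                     file.path(gdir, paste0("binary_", nm, ".asc")))
    }
    for (sc in names(report$agreement)) {
      write_grid_asc(report$agreement[[sc]]$values, tmpl,
                     file.path(gdir, paste0("agreement_", sc, ".asc")))
    }
    for (nm in names(report$mop)) {
      write_grid_asc(report$mop[[nm]]$similarity_grid, tmpl,
                     file.path(gdir, paste0("mop_similarity_", nm, ".asc")))
    }
  }
  summary <- list(
    status = report$status,
    audit = report$audit,
    stage_counts = as.list(report$stage_counts),
    n_selected = nrow(report$selected),
    threshold = report$threshold,
    wall_time_s = report$wall_time_s,
    seed = report$seeds
  )
  jsonlite::write_json(summary, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> status:", x$status, "\n")
  if (!is.null(x$audit)) {
    cat("  occurrence audit:\n")
    print(x$audit)
  }
  cat("  candidates:", nrow(x$candidates),
      "| selected:", nrow(x$selected), "\n")
  if (!is.null(x$threshold)) {
    cat(sprintf("  suitability threshold (E-adjusted): %.4f\n", x$threshold))
  }
  cat(sprintf("  wall time: %.1f s\n", x$wall_time_s))
  invisible(x)
}
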