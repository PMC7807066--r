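#' Default synthetic study configuration
#'
#' The study conditions the pipeline is exercised under when no real data
#' are supplied: a 200 x 200 planar landscape of 10-km cells with five
#' autocorrelated bioclim-style predictors, a known logistic niche driven
#' by three of them (one with a quadratic optimum, two nuisance layers),
#' 500 presence records observed through a nonuniform sampling-effort
#' surface (10% deliberately dirty), 2000 analogue-species sightings
#' sharing that effort surface, and parametric climate-shift scenarios.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size_km cell edge (km).
#' @param layer_names predictor names.
#' @param autocorr_length_km predictor correlation length (km).
#' @param niche a [true_niche()].
#' @param bias_autocorr_km,bias_strength sampling-effort field parameters.
#' @param n_presences,n_analogues record counts.
#' @param dirty_fraction fraction of deliberately rule-violating records.
#' @param scenarios named list of [scenario_shift()]s.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_rows = 200, n_cols = 200, cell_size_km = 5,
                             layer_names = c("bio1", "bio13", "bio15",
                                             "bio18", "bio19"),
                             autocorr_length_km = 100,
                             niche = true_niche(
                               intercept = -1,
                               coefficients = c(bio13 = 4, bio15 = -3,
                                                bio18 = 2),
                               quadratic_coefficients = c(bio13 = -1.5)),
                             bias_autocorr_km = 150, bias_strength = 1.5,
                             n_presences = 500, n_analogues = 2000,
                             dirty_fraction = 0.1,
                             scenarios = list(
                               past = scenario_shift(
                                 additive_delta = c(bio15 = 0.6, bio13 = -0.3)),
                               future = scenario_shift(
                                 additive_delta = c(bio13 = 0.25, bio18 = 0.25)))) {
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 cell_size_km = cell_size_km, layer_names = layer_names,
                 autocorr_length_km = autocorr_length_km, niche = niche,
                 bias_autocorr_km = bias_autocorr_km,
                 bias_strength = bias_strength, n_presences = n_presences,
                 n_analogues = n_analogues, dirty_fraction = dirty_fraction,
                 scenarios = scenarios),
            class = "synthetic_config")
}

#' Pipeline configuration
#'
#' Bundles every stage's settings with the method defaults: 5-km
#' uncertainty cap and 1970 year floor for cleaning, 30-km thinning and
#' pseudo-absence spacing, VIF threshold 10, the nine-algorithm roster with
#' six 70/30 repeats, and inclusion gates TSS >= 0.7 / AUC >= 0.9 /
#' Kappa >= 0.7.
#'
#' @param synthetic a [synthetic_config()] (synthetic mode), or `NULL` to
#'   read `occurrences_csv` / `analogues_csv` / `raster_dir` /
#'   `scenario_dirs` from disk.
#' @param occurrences_csv,analogues_csv,raster_dir,scenario_dirs file-mode
#'   input paths (`scenario_dirs` is a named list of stack directories).
#' @param rules a [cleaning_rules()].
#' @param city_points optional city-centre data frame for the cleaner.
#' @param thin_dist_km presence thinning distance (default 30).
#' @param pa_min_dist_km pseudo-absence spacing (default 30).
#' @param pa_bandwidth_km bias-layer kernel bandwidth (default 30).
#' @param pa_components retained kernel components (`NULL` = 95% variance).
#' @param vif_threshold stepwise VIF cut-off (default 10).
#' @param roster,n_repeats,calib_fraction model roster settings.
#' @param gates named vector `c(tss=, auc=, kappa=)` of inclusion gates.
#' @param out_dir optional directory for all stage artifacts.
#' @param seed global seed; every stage seed is derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            occurrences_csv = NULL, analogues_csv = NULL,
                            raster_dir = NULL, scenario_dirs = list(),
                            rules = cleaning_rules(), city_points = NULL,
                            thin_dist_km = 30, pa_min_dist_km = 30,
                            pa_bandwidth_km = 30, pa_components = NULL,
                            vif_threshold = 10, roster = default_roster(),
                            n_repeats = 6, calib_fraction = 0.7,
                            gates = c(tss = 0.7, auc = 0.9, kappa = 0.7),
                            out_dir = NULL, seed = 1L) {
  if (is.null(synthetic) &&
      (is.null(occurrences_csv) || is.null(raster_dir)))
    stop("either synthetic mode or input paths must be configured")
  if (any(gates < 0) || gates[["auc"]] > 1)
    stop("gates out of legal range")
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config, digits.d = 12)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full ensemble SDM pipeline
#'
#' Executes clean -> thin -> bias layer -> environmental kernel ->
#' pseudo-absences -> extraction -> stepwise VIF -> scale/centre ->
#' multi-algorithm fitting -> gating -> TSS-weighted ensemble -> projection
#' per scenario -> max-TSS binarization -> dispersal-bounded range change
#' -> MESS -> correlation shift. Fully reproducible from `(config, seed)`;
#' every stage draws its own derived seed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: all stage objects plus a
#'   JSON-serialisable `report` with per-stage provenance. Fatal stage
#'   errors carry the stage name in their message.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  report <- list(seed = seed, config_hash = config_hash(config),
                 stages = list())
  res <- list(config = config)
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    report$stages[[name]] <<- TRUE
    out
  }

  if (!is.null(config$synthetic)) {
    sc <- config$synthetic
    res$stack <- stage("simulate", {
      spec <- landscape_spec(sc$n_rows, sc$n_cols, sc$cell_size_km,
                             sc$layer_names, sc$autocorr_length_km,
                             seed = derive_seed(seed, "landscape"))
      generate_predictor_stack(spec)
    })
    res$truth <- true_suitability(res$stack, sc$niche)
    res$true_bias <- generate_bias_surface(res$stack, sc$bias_autocorr_km,
                                           sc$bias_strength,
                                           seed = derive_seed(seed, "bias"))
    occ_raw <- sample_occurrences(res$truth, res$true_bias, sc$n_presences,
                                  seed = derive_seed(seed, "occurrences"),
                                  dirty_fraction = sc$dirty_fraction)
    ana_raw <- generate_analogue_sightings(res$true_bias, sc$n_analogues,
                                           seed = derive_seed(seed, "analogues"))
    scenarios <- lapply(sc$scenarios, function(sh) shift_climate(res$stack, sh))
  } else {
    res$stack <- stage("read", read_stack(config$raster_dir))
    occ_raw <- read_occurrences(config$occurrences_csv)
    ana_raw <- if (!is.null(config$analogues_csv))
      read_occurrences(config$analogues_csv) else NULL
    scenarios <- lapply(config$scenario_dirs, read_stack)
  }

  cl <- stage("clean", clean(occ_raw, config$rules, config$city_points))
  res$cleaning_report <- cl$report
  res$presences <- stage("thin",
    thin(cl$occ, config$thin_dist_km, seed = derive_seed(seed, "thin")))
  report$n_presences_raw <- nrow(occ_raw)
  report$n_presences_clean <- nrow(cl$occ)
  report$n_presences_thinned <- nrow(res$presences)

  res$bias_surface <- stage("bias_layer", {
    if (is.null(ana_raw)) grid_map(matrix(1, res$stack$n_rows, res$stack$n_cols),
                                   res$stack)
    else {
      ana <- clean(ana_raw, config$rules, config$city_points)$occ
      build_bias_surface(ana, res$stack, config$pa_bandwidth_km)
    }
  })
  res$env_kernel <- stage("env_kernel",
    fit_env_kernel(res$presences, res$stack,
                   n_components = config$pa_components,
                   seed = derive_seed(seed, "kernel")))
  res$pseudoabsences <- stage("pseudoabs",
    sample_pseudoabsences(res$env_kernel, res$bias_surface, res$stack,
                          res$presences, config$pa_min_dist_km,
                          seed = derive_seed(seed, "pseudoabs")))
  report$n_pseudoabsences <- nrow(res$pseudoabsences)

  tbl <- stage("extract",
    sample_table(res$stack, res$presences, res$pseudoabsences))
  res$vif_report <- stage("vif", vif_stepwise(tbl, config$vif_threshold))
  tbl <- tbl[c(res$vif_report$retained, "label")]
  std <- stage("scale", scale_centre(tbl))
  res$table <- std$table
  res$params <- std$params
  report$vif_removed <- res$vif_report$removed
  report$vif_retained <- res$vif_report$retained

  res$models <- stage("fit",
    fit_all(res$table, config$roster, config$n_repeats,
            config$calib_fraction, seed = derive_seed(seed, "fit")))
  report$n_candidate_models <- length(res$models)

  sel <- stage("gate",
    select_members(res$models, config$gates[["tss"]], config$gates[["auc"]],
                   config$gates[["kappa"]]))
  res$model_report <- sel$report
  report$n_ensemble_members <- length(sel$members)
  res$ensemble <- stage("ensemble", ensemble_model(sel$members, res$params))
  report$ensemble_weights <- as.numeric(res$ensemble$weights)

  # ensemble skill and binarization threshold on the fitting table
  ens_fit <- ensemble_predict_table(res$ensemble, res$table)
  th <- max_tss_threshold(ens_fit, res$table$label)
  res$threshold <- th$threshold
  report$threshold <- th$threshold
  report$ensemble_fit <- unclass(evaluate_scores(ens_fit, res$table$label))

  res$current_map <- stage("project", ensemble_predict(res$ensemble, res$stack))
  pres_suit <- ens_fit[res$table$label == 1]
  report$boyce <- stage("boyce",
    boyce(as.vector(res$current_map)[!is.na(as.vector(res$current_map))],
          pres_suit))
  res$current_binary <- binarize(res$current_map, res$threshold, "current")

  res$scenarios <- list()
  for (nm in names(scenarios)) {
    sstack <- scenarios[[nm]]
    smap <- stage(paste0("project:", nm), ensemble_predict(res$ensemble, sstack))
    sbin <- binarize(smap, res$threshold, nm)
    rc <- stage(paste0("rangechange:", nm), range_change(res$current_binary, sbin))
    mm <- stage(paste0("mess:", nm), mess_map(res$table, sstack))
    cs <- stage(paste0("corshift:", nm), correlation_shift(res$stack, sstack))
    res$scenarios[[nm]] <- list(stack = sstack, suitability = smap,
                                binary = sbin, range_change = rc,
                                mess = mm, correlation_shift = cs)
    report$scenarios[[nm]] <- list(
      pct_change_unlimited = rc$pct_change_unlimited,
      pct_change_no_dispersal = rc$pct_change_no_dispersal,
      cells_current = rc$cells_current, cells_other = rc$cells_other,
      cells_overlap = rc$cells_overlap,
      mess_fraction_novel = mean(mm$aggregate < 0, na.rm = TRUE),
      max_abs_correlation_shift = max(abs(cs$difference)))
  }

  res$report <- report
  class(res) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_artifacts(res, config$out_dir)
  res
}

#' Write pipeline artifacts to a directory
#'
#' Occurrence CSVs, the predictor/suitability/binary grids as ASCII
#' rasters, the model-selection table as CSV, and the run report as JSON
#' (with config hash and seed for provenance).
#'
#' @param res a `pipeline_result`.
#' @param dir output directory.
#' @export
write_pipeline_artifacts <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(res$stack, file.path(dir, "stack"))
  write_occurrences(res$presences, file.path(dir, "presences.csv"))
  write_occurrences(res$pseudoabsences, file.path(dir, "pseudoabsences.csv"))
  write_ascii_grid(res$current_map, file.path(dir, "suitability_current.asc"))
  utils::write.csv(res$model_report, file.path(dir, "model_selection.csv"),
                   row.names = FALSE)
  for (nm in names(res$scenarios))
    write_ascii_grid(res$scenarios[[nm]]$suitability,
                     file.path(dir, sprintf("suitability_%s.asc", nm)))
  jsonlite::write_json(res$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' Read a pipeline configuration from YAML
#'
#' Scalar keys map onto [pipeline_config()] arguments; `niche`,
#' `scenarios`, and `rules` sub-maps are converted to their constructors.
#' Synthetic mode is used when a `synthetic` map is present.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    sargs <- s[setdiff(names(s), c("niche", "scenarios"))]
    if (!is.null(s$niche))
      sargs$niche <- true_niche(
        intercept = s$niche$intercept,
        coefficients = unlist(s$niche$coefficients),
        quadratic_coefficients = if (!is.null(s$niche$quadratic_coefficients))
          unlist(s$niche$quadratic_coefficients))
    if (!is.null(s$scenarios))
      sargs$scenarios <- lapply(s$scenarios, function(sh)
        scenario_shift(
          additive_delta = if (!is.null(sh$additive_delta)) unlist(sh$additive_delta) else numeric(),
          multiplicative_factor = if (!is.null(sh$multiplicative_factor)) unlist(sh$multiplicative_factor) else numeric()))
    args$synthetic <- do.call(synthetic_config, sargs)
  } else args$synthetic <- NULL
  if (!is.null(y$rules)) args$rules <- do.call(cleaning_rules, y$rules)
  if (!is.null(y$gates)) args$gates <- unlist(y$gates)
  scalar <- intersect(names(y), c("occurrences_csv", "analogues_csv",
                                  "raster_dir", "thin_dist_km",
                                  "pa_min_dist_km", "pa_bandwidth_km",
                                  "pa_components", "vif_threshold", "roster",
                                  "n_repeats", "calib_fraction", "out_dir",
                                  "seed"))
  args <- c(args, y[scalar])
  if (!is.null(y$scenario_dirs)) args$scenario_dirs <- as.list(y$scenario_dirs)
  do.call(pipeline_config, args)
}
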