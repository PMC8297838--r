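# Pipeline orchestration: simulate writes trajectory + metadata CSVs;
# analyze runs segmentation -> properties -> comparison battery -> mixed
# model and writes the report bundle; full chains both. Every run logs the
# package version, a config hash and the seed into the JSON summary.
# Report rounding is centralized: lengths and speeds 3 decimals, counts
# integers, percents nearest integer.

#' Pipeline configuration
#'
#' @param trajectories Directory containing `trajectories_day<d>.csv` files
#'   (analyze mode input; simulate mode output).
#' @param metadata Path of the metadata CSV.
#' @param out Output directory for the report bundle.
#' @param cal A [calibration()] used to read trajectories.
#' @param th A [thresholds()] for segmentation.
#' @param max_gap Largest tracking gap repaired by interpolation (frames).
#' @param family Multiple-testing family handed to [compare_to_control()].
#' @param alpha Significance level.
#' @param design,base,effects Simulation block ([experiment_design()],
#'   [behavior_params()], [effect_model()]).
#' @param seed Integer seed for simulate/full modes.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(trajectories = NULL, metadata = NULL, out = "tagmove_out",
                            cal = calibration(px_per_metre = 1),
                            th = thresholds(), max_gap = 12,
                            family = "run", alpha = 0.05,
                            design = experiment_design(),
                            base = behavior_params(),
                            effects = effect_model(), seed = 1) {
  structure(list(trajectories = trajectories, metadata = metadata, out = out,
                 cal = cal, th = th, max_gap = max_gap, family = family,
                 alpha = alpha, design = design, base = base,
                 effects = effects, seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognised top-level blocks: `paths` (trajectories, metadata, out),
#' `calibration`, `thresholds`, `stats` (family, alpha, max_gap) and
#' `simulation` (design, params, effects, seed); each block's entries are
#' passed to the corresponding constructor, so defaults apply to anything
#' omitted.
#'
#' @param file Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(file) {
  y <- yaml::read_yaml(file)
  args <- list()
  for (k in c("trajectories", "metadata", "out")) args[[k]] <- y$paths[[k]]
  if (!is.null(y$calibration)) args$cal <- do.call(calibration, y$calibration)
  if (!is.null(y$thresholds)) args$th <- do.call(thresholds, y$thresholds)
  for (k in c("family", "alpha", "max_gap")) if (!is.null(y$stats[[k]])) args[[k]] <- y$stats[[k]]
  sim <- y$simulation
  if (!is.null(sim$design)) {
    d <- sim$design
    for (k in c("tag_mass_distributions")) if (!is.null(d[[k]]))
      d[[k]] <- lapply(d[[k]], unlist)
    for (k in c("temperature_levels", "animal_mass_distribution", "arena"))
      if (!is.null(d[[k]])) d[[k]] <- unlist(d[[k]])
    args$design <- do.call(experiment_design, d)
  }
  if (!is.null(sim$params)) args$base <- do.call(behavior_params, sim$params)
  if (!is.null(sim$effects)) {
    e <- sim$effects
    if (!is.null(e$temperature_multipliers))
      e$temperature_multipliers <- lapply(e$temperature_multipliers, unlist)
    args$effects <- do.call(effect_model, e)
  }
  if (!is.null(sim$seed)) args$seed <- sim$seed
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(lapply(unclass(config), unclass), file = tmp)
  unname(tools::md5sum(tmp))
}

round_report <- function(df) {
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) next
    if (grepl("percent", nm)) df[[nm]] <- round(df[[nm]])
    else if (grepl("Frequency|^n_|^day$|^n$", nm)) df[[nm]] <- round(df[[nm]])
    else if (grepl("^p_|p_value|significant", nm)) df[[nm]] <- signif(df[[nm]], 4)
    else df[[nm]] <- round(df[[nm]], 3)
  }
  df
}

write_report_csv <- function(df, out, name) {
  utils::write.csv(round_report(df), file.path(out, name), row.names = FALSE)
}

#' Run the analysis pipeline
#'
#' `mode = "simulate"` writes per-day trajectory CSVs and the metadata CSV
#' into the configured directories. `mode = "analyze"` reads them, repairs
#' short tracking gaps, segments bouts, computes the property table and
#' writes the report bundle: bout table, property table, pooled and
#' stratified comparison results with median tables and significance flags,
#' Discussion-style percent changes, slope results, body-mass tests, the
#' mixed-model coefficient and ANOVA tables, and a machine-readable JSON
#' summary. `mode = "full"` chains both.
#'
#' @param config A [pipeline_config()].
#' @param mode One of "simulate", "analyze", "full".
#' @param seed Optional seed overriding the config's.
#' @return Invisibly, a list with the in-memory results (`properties`,
#'   `comparisons_pooled`, `comparisons_stratified`, `model`, `summary`, ...).
#' @export
run_pipeline <- function(config, mode = c("full", "simulate", "analyze"),
                         seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- seed
  traj_dir <- config$trajectories %||% file.path(config$out, "trajectories")

  if (mode %in% c("simulate", "full")) {
    sim <- simulate_experiment(config$design, config$base, config$effects,
                               seed = config$seed)
    dir.create(traj_dir, recursive = TRUE, showWarnings = FALSE)
    days <- sort(unique(vapply(sim$tracks, function(t) t$day, integer(1))))
    for (d in days) {
      sel <- Filter(function(t) t$day == d, sim$tracks)
      write_tracks(structure(sel, class = "track_set"),
                   file.path(traj_dir, sprintf("trajectories_day%d.csv", d)))
    }
    meta_file <- config$metadata %||% file.path(traj_dir, "metadata.csv")
    write_metadata(sim$metadata, meta_file)
    config$metadata <- meta_file
    if (mode == "simulate")
      return(invisible(list(trajectories = traj_dir, metadata = meta_file)))
  }

  meta_file <- config$metadata %||% file.path(traj_dir, "metadata.csv")
  config$trajectories <- traj_dir
  config$metadata <- meta_file
  if (!dir.exists(traj_dir)) stop(sprintf("run_pipeline: no trajectory directory '%s'", traj_dir))
  files <- list.files(traj_dir, pattern = "^trajectories_day[0-9]+\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0L)
    stop(sprintf("run_pipeline: no trajectory files in '%s'", traj_dir))
  if (!file.exists(meta_file)) stop(sprintf("run_pipeline: no metadata file '%s'", meta_file))
  metadata <- read_metadata(meta_file)

  tracks <- list()
  for (f in files) {
    d <- as.integer(sub("^trajectories_day([0-9]+)\\.csv$", "\\1", basename(f)))
    ts <- read_tracks(f, config$cal, day = d)
    ts <- lapply(ts, fill_gaps, max_gap = config$max_gap)
    # a split track contributes its segments' union; keep longest segment
    ts <- lapply(ts, function(t) if (inherits(t, "cricket_track")) t else
      t[[which.max(vapply(t, function(s) length(s$times), numeric(1)))]])
    tracks <- c(tracks, ts)
  }
  tracks <- structure(tracks, class = "track_set")

  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  props <- properties_table(tracks, metadata, config$th)
  bouts <- bout_table(tracks, config$th)
  cmp_pool <- compare_to_control(props, "pooled", family = config$family,
                                 alpha = config$alpha)
  cmp_strat <- compare_to_control(props, "by_temperature",
                                  family = config$family, alpha = config$alpha)
  med_pool <- median_table(props, by_temperature = FALSE)
  med_strat <- median_table(props, by_temperature = TRUE)
  pct <- cmp_pool[c("property", "day", "weight_category",
                    "median_control", "median_tag")]
  pct$percent_change <- percent_change(pct$median_control, pct$median_tag)
  slopes <- slope_analysis(props, "movementSpeed")
  mass <- body_mass_tests(metadata)
  model <- fit_movement_sum_model(props)

  write_report_csv(props, config$out, "properties.csv")
  write_report_csv(bouts, config$out, "bouts.csv")
  write_report_csv(cmp_pool, config$out, "comparisons_pooled.csv")
  write_report_csv(cmp_strat, config$out, "comparisons_by_temperature.csv")
  write_report_csv(med_pool, config$out, "medians_pooled.csv")
  write_report_csv(med_strat, config$out, "medians_by_temperature.csv")
  write_report_csv(pct, config$out, "percent_changes.csv")
  write_report_csv(slopes$slopes, config$out, "slopes.csv")
  write_report_csv(slopes$tests, config$out, "slope_tests.csv")
  write_report_csv(mass, config$out, "body_mass_tests.csv")
  write_report_csv(model$coefficients, config$out, "model_coefficients.csv")
  write_report_csv(model$anova, config$out, "model_anova.csv")

  summary_json <- list(
    version = as.character(utils::packageVersion("tagmove")),
    seed = config$seed, config_hash = config_hash(config),
    n_tracks = length(tracks), n_individuals = length(unique(props$cricket_id)),
    n_rows = nrow(props),
    pooled_tests = nrow(cmp_pool),
    pooled_significant = sum(cmp_pool$significant),
    stratified_tests = nrow(cmp_strat),
    stratified_significant = sum(cmp_strat$significant),
    reduction_per_100mg_low = distance_reduction_per_100mg(model, "low"),
    reduction_per_100mg_intermediate =
      distance_reduction_per_100mg(model, "intermediate"),
    random_intercept_p = model$ranef_test$p_value)
  jsonlite::write_json(summary_json, file.path(config$out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(properties = props, bouts = bouts,
                 comparisons_pooled = cmp_pool,
                 comparisons_stratified = cmp_strat,
                 medians_pooled = med_pool, medians_stratified = med_strat,
                 percent_changes = pct, slopes = slopes, body_mass = mass,
                 model = model, summary = summary_json))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
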