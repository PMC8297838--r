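# Published summary tables of the cricket tag-load experiment the package's
# defaults emulate, shipped as plain CSV so that worked examples (percent
# changes of group medians, per-100-mg distance reduction) can be recomputed
# from printed inputs without the original trajectories, which were never
# deposited.

#' Reference group medians of the movement properties
#'
#' Group medians of the six movement properties for control, light, medium
#' and heavy tag categories on each of three recording days, from the
#' *Gryllus locorojo* tag-load experiment: pooled across temperatures or
#' stratified by the low/intermediate/high temperature categories.
#'
#' @param stratified If TRUE return the per-temperature table.
#' @return Data frame with columns property, day, (temperature,) control,
#'   light, medium, heavy.
#' @export
reference_medians <- function(stratified = FALSE) {
  f <- if (stratified) "reference_medians_by_temperature.csv" else
    "reference_medians_pooled.csv"
  utils::read.csv(system.file("extdata", f, package = "tagmove"),
                  stringsAsFactors = FALSE)
}

#' Reference mixed-model coefficient table
#'
#' The published fixed-effect coefficients of the distance-travelled mixed
#' model (movementSum in metres, weights in mg, intermediate temperature as
#' reference), in the same layout produced by [fit_movement_sum_model()].
#'
#' @return Data frame with columns term, estimate, std_error, df, t_value,
#'   p_value.
#' @export
reference_coefficients <- function() {
  utils::read.csv(system.file("extdata", "reference_model_coefficients.csv",
                              package = "tagmove"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Discussion-style percent-change summary from a medians table
#'
#' For each tagged category and property, computes the percent change of the
#' tagged median relative to control on each day and reports the day with the
#' largest absolute change — the "up to X%" reading of a cohort report.
#'
#' @param medians A medians table as returned by [reference_medians()] (or
#'   [median_table()] reshaped to the same columns).
#' @param categories Tag categories to summarise.
#' @return Data frame with property, weight_category, day (of the extreme),
#'   percent_change (signed, unrounded) and percent_rounded.
#' @export
percent_change_summary <- function(medians, categories = c("light", "medium", "heavy")) {
  rows <- list()
  for (prop in unique(medians$property)) for (cat in categories) {
    sub <- medians[medians$property == prop, ]
    pc <- percent_change(sub$control, sub[[cat]])
    i <- which.max(abs(pc))
    rows[[length(rows) + 1L]] <- data.frame(
      property = prop, weight_category = cat, day = sub$day[i],
      percent_change = pc[i], percent_rounded = round(pc[i]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
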