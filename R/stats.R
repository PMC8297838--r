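# The comparison battery: Mann-Whitney tests of each tagged group against
# control for every property x day (optionally within temperature strata),
# with Benjamini-Yekutieli FDR adjustment across the whole run; percent
# changes of medians; per-individual day slopes; paired body-mass tests.

PROPERTY_NAMES <- c("movementLength", "movementLengthMax", "movementSum",
                    "movementSpeed", "restingDuration", "restingFrequency")

#' Two-sided Mann-Whitney U test
#'
#' Uses the exact null distribution when the combined sample size is at most
#' 20 and there are no ties, and the tie-corrected normal approximation (with
#' continuity correction) otherwise — the behaviour of any standard
#' implementation at the cohort sizes of a tagging experiment.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with elements `u` (the U statistic of `a`) and `p`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("mann_whitney_u: samples must be non-empty")
  if (max(c(a, b)) == min(c(a, b)))  # all observations tied: no evidence
    return(list(u = length(a) * length(b) / 2, p = 1))
  exact <- (length(a) + length(b) <= 20) && !anyDuplicated(c(a, b))
  w <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(u = unname(w$statistic), p = w$p.value)
}

#' Benjamini-Yekutieli step-up adjustment
#'
#' FDR control under arbitrary dependence: with m tests and the harmonic
#' constant c(m) = sum(1/k), the sorted p-values p(i) are mapped to
#' min over j >= i of min(1, m c(m) p(j) / j), returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_by <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("adjust_by: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

#' Shapiro-Wilk non-normality flag
#'
#' Returns TRUE when the Shapiro-Wilk test rejects normality at the 5% level.
#' In the analysis battery this only documents why the nonparametric branch
#' is used; it never switches tests silently. A zero-variance sample is
#' flagged TRUE (degenerate) with a warning.
#'
#' @param values Numeric sample, n >= 3 (at most 5000 for the test itself).
#' @return Logical flag.
#' @export
normality_check <- function(values) {
  if (length(values) < 3L) stop("normality_check: need at least 3 values")
  if (stats::var(values) == 0) {
    warning("normality_check: zero-variance sample, flagged non-normal")
    return(TRUE)
  }
  stats::shapiro.test(values)$p.value < 0.05
}

#' Compare tagged groups to control across properties and days
#'
#' For every property x day x weight category (and, when stratified, x
#' temperature) runs a two-sided Mann-Whitney test of the tagged sample
#' against the control sample of the same stratum and day. p-values are
#' BY-adjusted within the whole run (the most conservative defensible
#' multiple-testing family: 54 tests pooled, 162 stratified), or within each
#' stratum when `family = "per_stratum"`.
#'
#' @param table A properties table from [properties_table()].
#' @param stratify `"pooled"` (temperature ignored) or `"by_temperature"`.
#' @param properties Property columns to test.
#' @param family `"run"` (adjust across the whole run) or `"per_stratum"`.
#' @param alpha Significance level applied to adjusted p-values.
#' @return Data frame of comparison results (one row per test) with medians,
#'   U statistic, raw and adjusted p-values and a significance flag.
#' @export
compare_to_control <- function(table, stratify = c("pooled", "by_temperature"),
                               properties = PROPERTY_NAMES,
                               family = c("run", "per_stratum"),
                               alpha = 0.05) {
  stratify <- match.arg(stratify)
  family <- match.arg(family)
  strata <- if (stratify == "pooled") "pooled" else unique(table$temperature_category)
  categories <- setdiff(unique(table$weight_category), "control")
  days <- sort(unique(table$day))
  rows <- list()
  for (s in strata) {
    sub <- if (s == "pooled") table else table[table$temperature_category == s, ]
    if (!any(sub$weight_category == "control"))
      stop(sprintf("compare_to_control: no control arm in stratum '%s'", s))
    for (prop in properties) for (d in days) for (cat in categories) {
      ctl <- sub[[prop]][sub$weight_category == "control" & sub$day == d]
      tag <- sub[[prop]][sub$weight_category == cat & sub$day == d]
      if (length(tag) == 0L) next
      mw <- mann_whitney_u(tag, ctl)
      rows[[length(rows) + 1L]] <- data.frame(
        property = prop, day = d, stratum = s, weight_category = cat,
        n_control = length(ctl), n_tag = length(tag),
        median_control = stats::median(ctl), median_tag = stats::median(tag),
        u_statistic = mw$u, p_raw = mw$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (family == "run") adjust_by(out$p_raw) else
    stats::ave(out$p_raw, out$stratum, FUN = adjust_by)
  out$significant <- out$p_adjusted < alpha
  out
}

#' Percent change of a tagged median relative to control
#'
#' @param median_control Control median (non-zero).
#' @param median_tag Tagged-group median.
#' @return Signed percent change; the reporting layer rounds to the nearest
#'   integer.
#' @export
percent_change <- function(median_control, median_tag) {
  if (any(median_control == 0))
    stop("percent_change: control median is zero, change undefined")
  (median_tag - median_control) / median_control * 100
}

#' Median table in the cohort-report layout
#'
#' Rows are day x property, columns are the weight categories (nested within
#' temperature when stratified) — the layout used to report group medians of
#' the six properties.
#'
#' @param table A properties table.
#' @param by_temperature Nest columns within temperature categories?
#' @return Data frame of medians.
#' @export
median_table <- function(table, by_temperature = FALSE) {
  categories <- intersect(c("control", "light", "medium", "heavy"),
                          unique(table$weight_category))
  days <- sort(unique(table$day))
  label <- unlist(lapply(PROPERTY_NAMES, function(p) sprintf("Day %d-%s", days, p)))
  strata <- if (by_temperature) unique(table$temperature_category) else "pooled"
  out <- data.frame(row = label, stringsAsFactors = FALSE)
  for (s in strata) {
    sub <- if (identical(s, "pooled")) table else table[table$temperature_category == s, ]
    for (cat in categories) {
      col <- unlist(lapply(PROPERTY_NAMES, function(p) vapply(days, function(d)
        stats::median(sub[[p]][sub$weight_category == cat & sub$day == d]),
        numeric(1))))
      out[[if (identical(s, "pooled")) cat else paste(s, cat, sep = ".")]] <- col
    }
  }
  out
}

#' Per-individual day slopes and their comparison against control
#'
#' Fits an ordinary least-squares line of the property against day number for
#' every individual with at least two days of data (individuals with fewer
#' are excluded with a warning), then compares each tag category's slope
#' distribution to the control's with a two-sided Wilcoxon rank-sum test.
#'
#' @param table A properties table.
#' @param property Property column to analyse.
#' @return List with `slopes` (cricket_id, weight_category, slope) and
#'   `tests` (weight_category, n, median slopes, p_value).
#' @export
slope_analysis <- function(table, property = "movementSpeed") {
  split_rows <- split(seq_len(nrow(table)), table$cricket_id)
  n_days <- vapply(split_rows, length, integer(1))
  if (any(n_days < 2L)) {
    warning(sprintf("slope_analysis: excluding %d individual(s) with < 2 days",
                    sum(n_days < 2L)))
    split_rows <- split_rows[n_days >= 2L]
  }
  slopes <- do.call(rbind, lapply(split_rows, function(idx) {
    d <- table$day[idx]; v <- table[[property]][idx]
    data.frame(cricket_id = table$cricket_id[idx[1]],
               weight_category = table$weight_category[idx[1]],
               slope = sum((d - mean(d)) * (v - mean(v))) / sum((d - mean(d))^2),
               stringsAsFactors = FALSE)
  }))
  rownames(slopes) <- NULL
  ctl <- slopes$slope[slopes$weight_category == "control"]
  tests <- do.call(rbind, lapply(
    setdiff(unique(slopes$weight_category), "control"), function(cat) {
      sl <- slopes$slope[slopes$weight_category == cat]
      data.frame(weight_category = cat, n_tag = length(sl), n_control = length(ctl),
                 median_slope_tag = stats::median(sl),
                 median_slope_control = stats::median(ctl),
                 p_value = mann_whitney_u(sl, ctl)$p, stringsAsFactors = FALSE)
    }))
  list(slopes = slopes, tests = tests)
}

#' Paired body-mass change tests between consecutive days
#'
#' Two-sided Wilcoxon signed-rank tests of within-individual body-mass
#' changes between consecutive day pairs, across all individuals and within
#' each weight category; reports the median within-individual shift.
#' Individuals lacking either day of a pair are dropped with a warning.
#'
#' @param metadata Experiment metadata (one row per individual-day).
#' @return Data frame with day_pair, scope, n, median_shift_mg, p_value.
#' @export
body_mass_tests <- function(metadata) {
  days <- sort(unique(metadata$day))
  scopes <- c("all", setdiff(unique(metadata$weight_category), character(0)))
  rows <- list()
  for (i in seq_len(length(days) - 1L)) {
    d1 <- days[i]; d2 <- days[i + 1L]
    m1 <- metadata[metadata$day == d1, c("cricket_id", "weight_category", "animal_weight_mg")]
    m2 <- metadata[metadata$day == d2, c("cricket_id", "animal_weight_mg")]
    j <- merge(m1, m2, by = "cricket_id", suffixes = c("_1", "_2"))
    dropped <- length(unique(c(m1$cricket_id, m2$cricket_id))) - nrow(j)
    if (dropped > 0)
      warning(sprintf("body_mass_tests: dropping %d unpaired individual(s) for days %d-%d",
                      dropped, d1, d2))
    for (sc in scopes) {
      sub <- if (sc == "all") j else j[j$weight_category == sc, ]
      if (nrow(sub) == 0L) next
      shift <- sub$animal_weight_mg_2 - sub$animal_weight_mg_1
      p <- if (all(shift == 0)) 1 else
        suppressWarnings(stats::wilcox.test(shift, exact = FALSE, correct = TRUE)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        day_pair = sprintf("%d-%d", d1, d2), scope = sc, n = nrow(sub),
        median_shift_mg = stats::median(shift), p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
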