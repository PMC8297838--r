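# Random-intercept linear mixed model of total distance travelled:
#   movementSum ~ temperature * tag_weight + temperature * animal_weight
#                 + (1 | cricket_id)
# fitted by REML with Satterthwaite degrees of freedom. Temperature is
# categorical with the intermediate level as reference, so the reported
# temperature rows are "high temperature" and "low temperature".

pretty_terms <- function(terms) {
  out <- terms
  out <- gsub("temperature_category(\\w+)", "\\1 temperature", out)
  out <- gsub("tag_weight_mg", "tag weight", out, fixed = TRUE)
  out <- gsub("animal_weight_mg", "animal weight", out, fixed = TRUE)
  out
}

#' Fit the movement-distance mixed model
#'
#' Fits, by REML, a linear mixed model of total distance travelled
#' (movementSum, metres) on temperature category, tag weight (mg), animal
#' weight (mg), the temperature x weight interactions, and a random intercept
#' per cricket capturing the repeated measurements across days. The
#' coefficient table uses Satterthwaite approximate degrees of freedom; an
#' ANOVA-style F table for the five fixed terms is attached, and the random
#' intercept is tested with a REML likelihood-ratio test against the
#' fixed-effects-only model using the boundary-corrected
#' 0.5 chi2(0) + 0.5 chi2(1) null mixture.
#'
#' @param table A properties table with columns movementSum,
#'   temperature_category, tag_weight_mg, animal_weight_mg, cricket_id.
#' @param reference_temperature Reference level for the temperature factor.
#' @return An object of class `movement_lmm` with components `coefficients`
#'   (term, estimate, std_error, df, t_value, p_value), `anova`,
#'   `random_intercept_variance`, `residual_variance`, `ranef_test`
#'   (LRT statistic and p-value), `reference_level`, and the underlying
#'   `lmerModLmerTest` fit as `fit`.
#' @export
fit_movement_sum_model <- function(table, reference_temperature = "intermediate") {
  need <- c("movementSum", "temperature_category", "tag_weight_mg",
            "animal_weight_mg", "cricket_id")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop(sprintf("fit_movement_sum_model: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  dat <- table
  dat$temperature_category <- stats::relevel(factor(dat$temperature_category),
                                             ref = reference_temperature)
  fixed <- movementSum ~ temperature_category * tag_weight_mg +
    temperature_category * animal_weight_mg
  X <- stats::model.matrix(fixed, dat)
  if (qr(X)$rank < ncol(X)) {
    stop(sprintf(
      "fit_movement_sum_model: rank-deficient fixed-effect design (aliased: %s); %s",
      paste(colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]], collapse = ", "),
      "check that every temperature level contains tagged and control individuals"))
  }
  form <- stats::update.formula(fixed, . ~ . + (1 | cricket_id))
  fit <- lmerTest::lmer(form, data = dat, REML = TRUE)

  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = pretty_terms(rownames(sm)),
    estimate = sm[, "Estimate"], std_error = sm[, "Std. Error"],
    df = sm[, "df"], t_value = sm[, "t value"], p_value = sm[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE)

  an <- as.data.frame(stats::anova(fit))
  an_tab <- data.frame(term = pretty_terms(rownames(an)),
                       f_value = an[["F value"]], p_value = an[["Pr(>F)"]],
                       num_df = an[["NumDF"]], den_df = an[["DenDF"]],
                       row.names = NULL, stringsAsFactors = FALSE)

  vc <- as.data.frame(lme4::VarCorr(fit))
  var_id <- vc$vcov[vc$grp == "cricket_id"]
  var_res <- vc$vcov[vc$grp == "Residual"]

  lm0 <- stats::lm(fixed, data = dat)
  lrt <- max(0, 2 * (as.numeric(stats::logLik(fit)) -
                       as.numeric(stats::logLik(lm0, REML = TRUE))))
  p_ranef <- if (lrt == 0) 1 else 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  structure(list(
    fit = fit, coefficients = coefs, anova = an_tab,
    random_intercept_variance = var_id, residual_variance = var_res,
    ranef_test = list(lrt = lrt, p_value = p_ranef),
    reference_level = reference_temperature
  ), class = "movement_lmm")
}

#' @export
print.movement_lmm <- function(x, digits = 4, ...) {
  cat("Linear mixed model of distance travelled (movementSum)\n")
  cat(sprintf("  random intercept per cricket: variance %.4g (residual %.4g)\n",
              x$random_intercept_variance, x$residual_variance))
  cat(sprintf("  random-effect LRT = %.2f, p = %.3g\n",
              x$ranef_test$lrt, x$ranef_test$p_value))
  cat(sprintf("  reference temperature: %s\n\n", x$reference_level))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.movement_lmm <- function(object, ...) {
  print(object)
  cat("\nANOVA (Satterthwaite):\n")
  print(object$anova, row.names = FALSE)
  invisible(object)
}

#' @export
coef.movement_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Distance reduction per 100 mg of tag at a given temperature
#'
#' Combines the tag-weight main effect with its temperature interaction (zero
#' at the reference level) and scales to a 100-mg load:
#' `|beta_tag + beta_temp:tag| * 100` metres per 100 mg per recording.
#'
#' @param coefficients A `movement_lmm` object, or a data frame with columns
#'   `term` and `estimate` using the terms "tag weight" and
#'   "<level> temperature:tag weight".
#' @param temperature Temperature level at which to evaluate the effect.
#' @param reference_level Level carrying no interaction term.
#' @return Metres of distance lost per 100 mg of tag.
#' @export
distance_reduction_per_100mg <- function(coefficients,
                                         temperature = "low",
                                         reference_level = "intermediate") {
  if (inherits(coefficients, "movement_lmm")) {
    reference_level <- coefficients$reference_level
    coefficients <- coefficients$coefficients
  }
  lookup <- function(term) {
    i <- match(term, coefficients$term)
    if (is.na(i)) stop(sprintf("distance_reduction_per_100mg: term '%s' not found", term))
    coefficients$estimate[i]
  }
  beta_tag <- lookup("tag weight")
  beta_int <- if (temperature == reference_level) 0 else
    lookup(sprintf("%s temperature:tag weight", temperature))
  abs(beta_tag + beta_int) * 100
}
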