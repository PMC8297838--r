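test_that("the fitted model has the published coefficient-table shape", {
  fit <- fit_movement_sum_model(sim_lmm_data(1))
  expect_s3_class(fit, "movement_lmm")
  expect_equal(fit$coefficients$term, names(lmm_truth)[c(1, 3, 2, 4, 5, 7, 6, 9, 8)])
  expect_true(all(fit$coefficients$std_error > 0))
  expect_equal(nrow(fit$anova), 5)
  expect_lt(fit$ranef_test$p_value, 0.05)  # sd_id = 3 is well identified
  expect_output(print(fit), "tag weight")
})

test_that("injecting zero cricket-level variance collapses the random intercept", {
  dat <- sim_lmm_data(2, sd_id = 0)
  # remove even the sampling noise in cricket means so the cluster-level
  # variance component is exactly zero by construction
  fit0 <- stats::lm(movementSum ~ temperature_category * tag_weight_mg +
                      temperature_category * animal_weight_mg, dat)
  res <- stats::residuals(fit0)
  dat$movementSum <- stats::fitted(fit0) +
    res - stats::ave(res, dat$cricket_id)
  fit <- fit_movement_sum_model(dat)
  expect_lte(fit$random_intercept_variance, 1e-6 * fit$residual_variance)
})

test_that("tag-load coefficients are stable under balanced row duplication", {
  dat <- sim_lmm_data(3)
  f1 <- fit_movement_sum_model(dat)
  f2 <- fit_movement_sum_model(rbind(dat, dat))
  for (term in c("tag weight", "low temperature:tag weight",
                 "high temperature:tag weight")) {
    e1 <- f1$coefficients$estimate[f1$coefficients$term == term]
    e2 <- f2$coefficients$estimate[f2$coefficients$term == term]
    expect_equal(e2, e1, tolerance = 0.01)
  }
})

test_that("adding a constant to movementSum changes only the intercept", {
  dat <- sim_lmm_data(4)
  f1 <- fit_movement_sum_model(dat)
  dat2 <- dat
  dat2$movementSum <- dat2$movementSum + 100
  f2 <- fit_movement_sum_model(dat2)
  expect_equal(f2$coefficients$estimate[1], f1$coefficients$estimate[1] + 100,
               tolerance = 1e-6)
  expect_equal(f2$coefficients$estimate[-1], f1$coefficients$estimate[-1],
               tolerance = 1e-6)
})

test_that("fixed effects are invariant to relabeling of cricket ids", {
  dat <- sim_lmm_data(5)
  f1 <- fit_movement_sum_model(dat)
  relab <- setNames(sprintf("z%03d", sample(180)), unique(dat$cricket_id))
  dat2 <- dat
  dat2$cricket_id <- unname(relab[dat$cricket_id])
  f2 <- fit_movement_sum_model(dat2)
  expect_equal(f2$coefficients$estimate, f1$coefficients$estimate, tolerance = 1e-8)
})

test_that("with no true tag effect the tag |t| rarely exceeds 2", {
  betas0 <- lmm_truth
  betas0[c("tag weight", "low temperature:tag weight",
           "high temperature:tag weight")] <- 0
  hits <- vapply(1:25, function(s) {
    fit <- fit_movement_sum_model(sim_lmm_data(s + 300, betas = betas0))
    abs(fit$coefficients$t_value[fit$coefficients$term == "tag weight"]) > 2
  }, logical(1))
  expect_lte(sum(hits), ceiling(0.10 * 25))
})

test_that("rank-deficient designs raise an informative error", {
  dat <- sim_lmm_data(6)
  # one temperature level with no tagged animals -> aliased interaction
  dat <- dat[!(dat$temperature_category == "low" & dat$tag_weight_mg > 0), ]
  dat$tag_weight_mg[dat$temperature_category == "low"] <- 0
  expect_error(fit_movement_sum_model(dat), "rank-deficient")
})

test_that("the per-100-mg distance reduction combines main effect and interaction", {
  cf <- reference_coefficients()
  expect_equal(distance_reduction_per_100mg(cf, "low"), 1.4)
  expect_equal(distance_reduction_per_100mg(cf, "intermediate"), 0.77)
  zero <- data.frame(term = cf$term, estimate = 0)
  expect_equal(distance_reduction_per_100mg(zero, "low"), 0)
  expect_error(distance_reduction_per_100mg(cf[cf$term != "tag weight", ], "low"),
               "not found")
  # and the same accessor works on a fitted model object
  fit <- fit_movement_sum_model(sim_lmm_data(7))
  est <- fit$coefficients$estimate
  names(est) <- fit$coefficients$term
  manual <- abs(est[["tag weight"]] + est[["low temperature:tag weight"]]) * 100
  expect_equal(distance_reduction_per_100mg(fit, "low"), manual)
})
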