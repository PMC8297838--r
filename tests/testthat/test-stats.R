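test_that("Mann-Whitney matches exact enumeration and symmetry properties", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p, 0.1)

  r_id <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r_id$p, 1)

  set.seed(1)
  for (i in 1:20) {
    a <- round(runif(sample(3:4, 1), 0, 100), 3)
    b <- round(runif(sample(3:4, 1), 0, 100), 3)
    got <- mann_whitney_u(a, b)
    ref <- mw_enumerate(a, b)
    expect_equal(got$u, ref$u, info = sprintf("case %d", i))
    expect_equal(got$p, ref$p, tolerance = 1e-9, info = sprintf("case %d", i))
    # symmetry and U complement
    got_ba <- mann_whitney_u(b, a)
    expect_equal(got$p, got_ba$p)
    expect_equal(got$u + got_ba$u, length(a) * length(b))
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney type-I error is calibrated at the cohort sample size", {
  set.seed(42)
  rej <- mean(replicate(500, mann_whitney_u(rnorm(15), rnorm(15))$p < 0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("BY adjustment matches the hand-computed step-up", {
  expect_equal(adjust_by(c(0.01, 0.02, 0.9)), c(0.055, 0.055, 1.0))
  expect_equal(adjust_by(0.03), 0.03)  # m = 1, c(1) = 1
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    got <- adjust_by(p)
    expect_equal(got, by_stepup(p), tolerance = 1e-12, info = sprintf("vector %d", i))
    expect_true(all(got >= p))
    o <- order(p)
    expect_true(all(diff(got[o]) >= -1e-12))
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(adjust_by(p[perm]), got[perm])
  }
  expect_error(adjust_by(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the non-normality flag is calibrated and powered", {
  flags_norm <- vapply(1:40, function(s) { set.seed(s); normality_check(rnorm(5000)) },
                       logical(1))
  expect_gte(mean(!flags_norm), 0.95)
  flags_lnorm <- vapply(1:40, function(s) { set.seed(s); normality_check(rlnorm(50, sdlog = 1)) },
                        logical(1))
  expect_gte(mean(flags_lnorm), 0.95)
  expect_warning(flag <- normality_check(rep(1, 10)), "zero-variance")
  expect_true(flag)
  expect_error(normality_check(c(1, 2)), "at least 3")
})

make_props_table <- function(n_per_arm = 6, days = 1:3, temps = "intermediate",
                             seed = 1) {
  set.seed(seed)
  cats <- c("control", "light", "medium", "heavy")
  grid <- expand.grid(i = seq_len(n_per_arm), weight_category = cats,
                      temperature_category = temps, day = days,
                      stringsAsFactors = FALSE)
  grid$cricket_id <- sprintf("x%s_%s_%02d", substr(grid$weight_category, 1, 2),
                             grid$temperature_category, grid$i)
  for (p in c("movementLength", "movementLengthMax", "movementSum",
              "movementSpeed", "restingDuration", "restingFrequency"))
    grid[[p]] <- rnorm(nrow(grid), 10, 2)
  grid
}

test_that("compare_to_control produces the full 54-test family and flags nothing
           when tag arms duplicate control", {
  tab <- make_props_table()
  cmp <- compare_to_control(tab, "pooled")
  expect_equal(nrow(cmp), 6 * 3 * 3)
  expect_true(all(cmp$p_adjusted >= cmp$p_raw - 1e-12))
  expect_true(all(cmp$p_adjusted <= 1))

  # tag rows exactly duplicate control rows -> all adjusted p = 1
  dup <- tab
  for (cat in c("light", "medium", "heavy")) for (d in 1:3) {
    src <- dup$weight_category == "control" & dup$day == d
    dst <- dup$weight_category == cat & dup$day == d
    for (p in c("movementLength", "movementLengthMax", "movementSum",
                "movementSpeed", "restingDuration", "restingFrequency"))
      dup[[p]][dst] <- dup[[p]][src]
  }
  cmp_dup <- compare_to_control(dup, "pooled")
  expect_true(all(cmp_dup$p_adjusted == 1))
  expect_false(any(cmp_dup$significant))

  expect_error(compare_to_control(tab[tab$weight_category != "control", ]),
               "no control arm")
})

test_that("a stratified run on a single temperature equals the pooled run on that subset", {
  tab <- make_props_table(temps = "low", seed = 3)
  pooled <- compare_to_control(tab, "pooled")
  strat <- compare_to_control(tab, "by_temperature")
  expect_equal(strat$p_raw, pooled$p_raw)
  expect_equal(strat$p_adjusted, pooled$p_adjusted)
})

test_that("percent change reproduces median effect sizes and rejects a zero control", {
  expect_equal(round(percent_change(0.066, 0.055)), -17)
  expect_equal(percent_change(1, 1), 0)
  expect_equal(percent_change(1.40, 2.59), 85, tolerance = 1e-9)
  expect_error(percent_change(0, 1), "zero")
})

test_that("median_table has the day-by-property rows and category columns", {
  tab <- make_props_table(seed = 5)
  mt <- median_table(tab)
  expect_equal(nrow(mt), 18)
  expect_named(mt, c("row", "control", "light", "medium", "heavy"))
  expect_equal(mt$control[mt$row == "Day 2-movementSum"],
               median(tab$movementSum[tab$weight_category == "control" & tab$day == 2]))
  mt_s <- median_table(tab, by_temperature = TRUE)
  expect_true("intermediate.heavy" %in% names(mt_s))
})

test_that("day slopes are exact on linear data and flat data gives null tests", {
  tab <- make_props_table(seed = 6)
  tab$movementSpeed <- 10 + 2 * tab$day  # exact line for everyone
  sl <- slope_analysis(tab, "movementSpeed")
  expect_true(all(abs(sl$slopes$slope - 2) < 1e-12))
  expect_true(all(sl$tests$p_value == 1))

  tab$movementSpeed <- 7  # constant
  sl2 <- slope_analysis(tab, "movementSpeed")
  expect_true(all(sl2$slopes$slope == 0))
  expect_true(all(sl2$tests$p_value == 1))

  # individual with a single day is excluded with a warning
  tab3 <- tab[!(tab$cricket_id == tab$cricket_id[1] & tab$day > 1), ]
  expect_warning(sl3 <- slope_analysis(tab3, "movementSpeed"), "excluding 1")
  expect_false(tab$cricket_id[1] %in% sl3$slopes$cricket_id)
})

test_that("a declining heavy arm is detected by the slope comparison", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    days <- 1:3
    mk <- function(n, cat, decline) do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(cricket_id = sprintf("%s%02d", cat, i), weight_category = cat,
                 day = days,
                 movementSpeed = 0.065 * (1 - decline * (days - 1)) + rnorm(3, 0, 0.008))))
    tab <- rbind(mk(45, "control", 0), mk(15, "heavy", 0.2))
    sl <- slope_analysis(tab, "movementSpeed")
    sl$tests$p_value[sl$tests$weight_category == "heavy"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("paired body-mass tests detect the constructed day-2 to day-3 shift", {
  md <- data.frame(cricket_id = rep(sprintf("c%03d", 1:30), each = 3),
                   weight_category = rep(rep(c("control", "heavy"), each = 3), 15),
                   day = rep(1:3, 30), animal_weight_mg = 700)
  res_flat <- body_mass_tests(md)
  all_flat <- res_flat[res_flat$scope == "all", ]
  expect_true(all(all_flat$p_value == 1))
  expect_true(all(all_flat$median_shift_mg == 0))

  md$animal_weight_mg[md$day == 3] <- 722
  res <- body_mass_tests(md)
  r12 <- res[res$day_pair == "1-2" & res$scope == "all", ]
  r23 <- res[res$day_pair == "2-3" & res$scope == "all", ]
  expect_equal(r12$p_value, 1)
  expect_lt(r23$p_value, 0.001)
  expect_equal(r23$median_shift_mg, 22)

  # unpaired individual is dropped with a warning
  md2 <- md[-1, ]
  expect_warning(body_mass_tests(md2), "unpaired")
})

test_that("a +22 mg mean shift at the cohort size is essentially always detected", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    d2 <- rnorm(180, 768, 117)
    d3 <- d2 + rnorm(180, 22, 10)
    md <- data.frame(cricket_id = rep(sprintf("c%03d", 1:180), each = 2),
                     weight_category = "control", day = rep(2:3, 180),
                     animal_weight_mg = as.vector(rbind(d2, d3)))
    res <- body_mass_tests(md)
    res$p_value[res$scope == "all"] < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the percent-change summary picks each category's largest median shift", {
  s <- percent_change_summary(reference_medians())
  pick <- function(prop, cat) s$percent_rounded[s$property == prop & s$weight_category == cat]
  expect_equal(pick("movementSpeed", "medium"), -17)
  expect_equal(pick("movementSum", "heavy"), -41)
  expect_equal(pick("movementLengthMax", "medium"), -28)
  expect_equal(pick("restingDuration", "heavy"), 85)
  expect_equal(pick("restingFrequency", "light"), 17)
})
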