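test_that("a never-moving animal produces a pure rest track with sub-threshold wobble", {
  p <- behavior_params(mean_rest_duration = Inf, position_noise_sd = 0)
  trk <- simulate_track(p, duration = 20, fps = 24, seed = 3)
  expect_length(trk$times, 20 * 24 + 1)
  step <- sqrt(diff(trk$x)^2 + diff(trk$y)^2)
  expect_true(max(step) <= p$rest_jitter_speed / 24 + 1e-12)
  sched <- attr(trk, "schedule")
  expect_true(all(sched$kind == "resting"))
})

test_that("identical seeds give bitwise-identical tracks, different seeds differ", {
  t1 <- simulate_track(behavior_params(), 30, 24, seed = 1)
  t2 <- simulate_track(behavior_params(), 30, 24, seed = 1)
  t3 <- simulate_track(behavior_params(), 30, 24, seed = 2)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
  expect_false(identical(t1$x, t3$x))
})

test_that("generated movement-bout path lengths follow the gamma target mean", {
  # >= 10000 bouts; short rests to pack many bouts per track
  p <- behavior_params(mean_bout_length = 0.1, bout_length_shape = 2,
                       mean_rest_duration = 0.5)
  paths <- unlist(lapply(1:40, function(s) {
    sched <- attr(simulate_track(p, 600, 24, seed = s), "schedule")
    # drop the final segment, truncated by the end of the recording
    sched <- sched[-nrow(sched), ]
    sched$path_length_m[sched$kind == "movement"]
  }))
  expect_gt(length(paths), 10000)
  se <- (0.1 / sqrt(2)) / sqrt(length(paths))
  expect_lt(abs(mean(paths) - 0.1), 3 * se)
})

test_that("tracks never leave the arena rectangle", {
  for (s in 1:5) {
    trk <- simulate_track(behavior_params(), 120, 24, arena = c(1.2, 0.8), seed = s)
    expect_true(all(trk$x >= 0 & trk$x <= 1.2))
    expect_true(all(trk$y >= 0 & trk$y <= 0.8))
  }
})

test_that("invalid generator inputs are rejected", {
  expect_error(simulate_track(behavior_params(), duration = -1), "duration")
  expect_error(simulate_track(behavior_params(), 10, fps = 0), "fps")
  expect_error(behavior_params(mean_bout_speed = -1), "positive")
  expect_error(behavior_params(rest_jitter_speed = 0.02), "resting threshold")
})

test_that("apply_effects scales parameters multiplicatively and log-linearly in tag mass", {
  base <- behavior_params()
  eff <- neutral_effects()
  expect_equal(apply_effects(base, 0, "intermediate", eff), base)

  eff2 <- effect_model(speed_multiplier_per_mg = 0.999,
                       bout_length_multiplier_per_mg = 1,
                       rest_duration_multiplier_per_mg = 1,
                       temperature_multipliers = list(intermediate = c(1, 1, 1)))
  scaled <- apply_effects(base, 100, "intermediate", eff2)
  expect_equal(scaled$mean_bout_speed, base$mean_bout_speed * 0.999^100)
  expect_equal(scaled$mean_bout_length, base$mean_bout_length)

  eff3 <- effect_model(temperature_multipliers = list(a = c(1, 1, 1), b = c(0.8, 1, 1)),
                       speed_multiplier_per_mg = 1,
                       bout_length_multiplier_per_mg = 1,
                       rest_duration_multiplier_per_mg = 1)
  pa <- apply_effects(base, 0, "a", eff3)
  pb <- apply_effects(base, 0, "b", eff3)
  expect_equal(pb$mean_bout_speed / pa$mean_bout_speed, 0.8)
  expect_error(apply_effects(base, 0, "nope", eff3), "unknown temperature category")
})

test_that("a minimal design yields one track per weight category, reproducibly", {
  des <- experiment_design(n_groups_per_temperature = 1, individuals_per_group = 4,
                           days = 1, temperature_levels = c(intermediate = 24),
                           recording_duration = 10, mass_shift_by_day = numeric(0))
  sim1 <- simulate_experiment(des, behavior_params(), neutral_effects(), seed = 5)
  sim2 <- simulate_experiment(des, behavior_params(), neutral_effects(), seed = 5)
  expect_length(sim1$tracks, 4)
  expect_setequal(sim1$metadata$weight_category, c("control", "light", "medium", "heavy"))
  expect_identical(sim1$metadata, sim2$metadata)
  expect_identical(sim1$tracks[[2]]$x, sim2$tracks[[2]]$x)
  # control <=> zero tag weight; masses positive
  expect_true(all((sim1$metadata$weight_category == "control") ==
                    (sim1$metadata$tag_weight_mg == 0)))
  expect_true(all(sim1$metadata$animal_weight_mg > 0))
})

test_that("the default design reproduces the cohort size: 180 individuals, 540 tracks", {
  run <- full_neutral_run()
  expect_length(run$sim$tracks, 540)
  expect_equal(length(unique(run$sim$metadata$cricket_id)), 180)
  expect_equal(nrow(run$sim$metadata), 540)
  # ids stable across days: every id appears on all 3 days
  expect_true(all(table(run$sim$metadata$cricket_id) == 3))
})
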