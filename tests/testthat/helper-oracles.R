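# Independent oracles and shared fixtures for the test suite.

# --- constructed tracks ------------------------------------------------------

# build a track from piecewise-constant-speed segments:
# segs = list(c(speed, duration)); straight-line motion along +x
make_track <- function(segs, fps = 24, id = "t1", day = 1L) {
  dt <- 1 / fps
  dx <- unlist(lapply(segs, function(s) rep(s[1] * dt, round(s[2] * fps))))
  x <- c(0, cumsum(dx))
  tagmove:::new_track(id, times = (seq_along(x) - 1) * dt,
                      x = x, y = rep(0, length(x)), fps = fps, day = day)
}

# random piecewise track alternating stationary and moving segments
random_track <- function(seed, fps = 24, max_frames = 200) {
  set.seed(seed)
  segs <- list()
  total <- 0
  while (total < max_frames / fps) {
    spd <- if (runif(1) < 0.5) runif(1, 0, 0.008) else runif(1, 0.02, 0.1)
    dur <- runif(1, 0.3, 3)
    segs[[length(segs) + 1L]] <- c(spd, dur)
    total <- total + dur
  }
  trk <- make_track(segs, fps = fps)
  n <- min(length(trk$times), max_frames)
  tagmove:::new_track("r", trk$times[1:n], trk$x[1:n], trk$y[1:n], fps, 1L)
}

# --- brute-force bout segmenter ---------------------------------------------

# direct frame-scan reference: naive windowed speeds (explicit loop), frame
# classification, run merging and sub-threshold absorption by sequential scan
brute_segment <- function(track, th = tagmove::thresholds()) {
  n <- length(track$times)
  fps <- track$fps
  step <- numeric(n - 1)
  for (i in seq_len(n - 1))
    step[i] <- sqrt((track$x[i + 1] - track$x[i])^2 + (track$y[i + 1] - track$y[i])^2)
  half <- max(1, round(th$speed_window * fps / 2))
  moving <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    sp <- sum(step[seq(lo, hi - 1)]) / ((hi - lo) / fps)
    moving[i] <- sp > th$resting_speed
  }
  # sequential scan into runs; boundary on the last frame of each run
  runs <- list()
  start <- 1
  for (i in 2:n) {
    if (moving[i] != moving[i - 1]) {
      runs[[length(runs) + 1L]] <- list(moving = moving[start], last = i - 1)
      start <- i
    }
  }
  runs[[length(runs) + 1L]] <- list(moving = moving[start], last = n)
  kind <- character(0); b_start <- numeric(0); b_end <- numeric(0); b_path <- numeric(0)
  prev <- 1
  for (r in runs) {
    path <- if (r$last > prev) sum(step[prev:(r$last - 1)]) else 0
    k <- if (r$moving && path > th$min_movement_length) "movement" else "resting"
    kind <- c(kind, k)
    b_start <- c(b_start, track$times[prev]); b_end <- c(b_end, track$times[r$last])
    b_path <- c(b_path, path)
    prev <- r$last
  }
  keep <- b_end > b_start
  kind <- kind[keep]; b_start <- b_start[keep]; b_end <- b_end[keep]; b_path <- b_path[keep]
  # merge adjacent equal kinds
  i <- 1
  while (i < length(kind)) {
    if (kind[i] == kind[i + 1]) {
      b_end[i] <- b_end[i + 1]; b_path[i] <- b_path[i] + b_path[i + 1]
      kind <- kind[-(i + 1)]; b_start <- b_start[-(i + 1)]
      b_end <- b_end[-(i + 1)]; b_path <- b_path[-(i + 1)]
    } else i <- i + 1
  }
  data.frame(kind = kind, start_time = b_start, end_time = b_end,
             duration = b_end - b_start, path_length = b_path,
             stringsAsFactors = FALSE)
}

# --- exact Mann-Whitney by enumeration --------------------------------------

# two-sided exact p by enumerating all C(n1+n2, n1) group labelings
mw_enumerate <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a); n <- length(pool)
  u_of <- function(idx) {
    x <- pool[idx]; y <- pool[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  us <- apply(utils::combn(n, n1), 2, u_of)
  u_obs <- u_of(seq_len(n1))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# --- hand-coded Benjamini-Yekutieli step-up ---------------------------------

by_stepup <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  q <- m * cm * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# --- memoized full neutral cohort run ---------------------------------------

.tagmove_cache <- new.env(parent = emptyenv())

full_neutral_run <- function() {
  if (is.null(.tagmove_cache$full)) {
    sim <- tagmove::simulate_experiment(effects = tagmove::neutral_effects(),
                                        seed = 7)
    props <- tagmove::properties_table(sim$tracks, sim$metadata)
    bouts <- tagmove::bout_table(sim$tracks)
    .tagmove_cache$full <- list(sim = sim, props = props, bouts = bouts)
  }
  .tagmove_cache$full
}

# simulate one comparison arm (n tracks) with a direct speed multiplier;
# individuals carry persistent log-normal speed traits as in the cohort
# generator so arm comparisons see realistic between-animal variance
simulate_arm <- function(n, speed_mult, seed, category, id_offset = 0) {
  base <- tagmove::behavior_params()
  set.seed(tagmove::derive_seed(seed, c(0L, id_offset)))
  trait <- rlnorm(n, meanlog = -0.08^2 / 2, sdlog = 0.08)
  tracks <- lapply(seq_len(n), function(i) {
    pars <- base
    pars$mean_bout_speed <- base$mean_bout_speed * speed_mult * trait[i]
    class(pars) <- "behavior_params"
    tagmove::simulate_track(pars, 600, 24, seed = tagmove::derive_seed(seed, i + id_offset),
                            cricket_id = sprintf("a%03d", i + id_offset), day = 1L)
  })
  meta <- data.frame(cricket_id = sprintf("a%03d", seq_len(n) + id_offset),
                     temperature_category = "intermediate", temperature_c = 24,
                     day = 1L, weight_category = category,
                     tag_weight_mg = if (category == "control") 0 else 758.6,
                     animal_weight_mg = 768, stringsAsFactors = FALSE)
  list(tracks = tracks, metadata = meta)
}

# one power/type-I replicate: 45 control vs 15 tagged, returns comparison table
arm_comparison <- function(seed, speed_mult) {
  ctl <- simulate_arm(45, 1, seed, "control")
  tag <- simulate_arm(15, speed_mult, seed, "heavy", id_offset = 100)
  tracks <- structure(c(ctl$tracks, tag$tracks), class = "track_set")
  meta <- rbind(ctl$metadata, tag$metadata)
  props <- tagmove::properties_table(tracks, meta)
  tagmove::compare_to_control(props, "pooled")
}

# --- data simulated directly from the mixed-model formula -------------------

lmm_truth <- c("(Intercept)" = 0.8481,
               "low temperature" = 10.8655, "high temperature" = -10.4746,
               "tag weight" = -0.0077, "animal weight" = 0.0217,
               "low temperature:tag weight" = -0.0063,
               "high temperature:tag weight" = 0.0052,
               "low temperature:animal weight" = -0.0109,
               "high temperature:animal weight" = 0.0077)

sim_lmm_data <- function(seed, betas = lmm_truth, sd_id = 3, sd_res = 4,
                         n = 180, days = 3) {
  set.seed(seed)
  cats <- rep(c("control", "light", "medium", "heavy"), each = n / 4)
  tag <- numeric(n)
  tag[cats == "light"] <- rnorm(sum(cats == "light"), 198.7, 2.1)
  tag[cats == "medium"] <- rnorm(sum(cats == "medium"), 549.2, 7.3)
  tag[cats == "heavy"] <- rnorm(sum(cats == "heavy"), 758.6, 6.9)
  temp <- rep(c("low", "intermediate", "high"), length.out = n)
  dat <- do.call(rbind, lapply(seq_len(days), function(d) data.frame(
    cricket_id = sprintf("c%03d", seq_len(n)),
    temperature_category = temp, weight_category = cats,
    tag_weight_mg = tag, day = d,
    animal_weight_mg = rnorm(n, 768, 117), stringsAsFactors = FALSE)))
  f <- factor(dat$temperature_category, levels = c("intermediate", "low", "high"))
  X <- stats::model.matrix(~ f * dat$tag_weight_mg + f * dat$animal_weight_mg)
  bmap <- c("(Intercept)" = "(Intercept)",
            "flow" = "low temperature", "fhigh" = "high temperature",
            "dat$tag_weight_mg" = "tag weight",
            "dat$animal_weight_mg" = "animal weight",
            "flow:dat$tag_weight_mg" = "low temperature:tag weight",
            "fhigh:dat$tag_weight_mg" = "high temperature:tag weight",
            "flow:dat$animal_weight_mg" = "low temperature:animal weight",
            "fhigh:dat$animal_weight_mg" = "high temperature:animal weight")
  b <- betas[bmap[colnames(X)]]
  dat$movementSum <- as.vector(X %*% b) +
    rep(rnorm(n, 0, sd_id), days) + rnorm(n * days, 0, sd_res)
  dat
}

lmm_recovery <- function() {
  if (is.null(.tagmove_cache$recovery)) {
    res <- lapply(1:25, function(s) {
      fit <- tagmove::fit_movement_sum_model(sim_lmm_data(s))
      cf <- fit$coefficients
      truth <- lmm_truth[cf$term]
      data.frame(seed = s, term = cf$term,
                 within_2se = abs(cf$estimate - truth) <= 2 * cf$std_error)
    })
    .tagmove_cache$recovery <- do.call(rbind, res)
  }
  .tagmove_cache$recovery
}
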