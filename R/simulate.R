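# Seeded bout-rest trajectory generator: alternating exponential rests and
# gamma-length movement bouts walked as a correlated random walk with
# reflecting arena walls. All randomness flows from one integer master seed;
# per-track substreams are derived with an LCG mix over (group, id, day).

#' Derive a reproducible substream seed
#'
#' Mixes a master seed with a vector of integer keys through a Lehmer-style
#' multiplicative congruential step modulo 2^31 - 1, so that every
#' (group, individual, day) combination gets its own deterministic stream.
#'
#' @param seed Master integer seed.
#' @param key Integer vector of stream indices.
#' @return A single integer seed below 2^31.
#' @export
derive_seed <- function(seed, key = integer()) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  x <- as.numeric(seed) %% m
  for (k in c(1, as.numeric(key))) x <- (x * 48271 + k) %% m
  as.integer(x)
}

new_track <- function(cricket_id, times, x, y, fps, day = NA_integer_) {
  structure(list(cricket_id = cricket_id, day = day, fps = fps,
                 times = times, x = x, y = y),
            class = "cricket_track")
}

#' @export
print.cricket_track <- function(x, ...) {
  cat(sprintf("<cricket_track> id=%s day=%s: %d frames @ %g fps, %.1f s\n",
              x$cricket_id, x$day, length(x$times), x$fps,
              x$times[length(x$times)] - x$times[1]))
  invisible(x)
}

#' @export
as.data.frame.cricket_track <- function(x, ...) {
  data.frame(frame = round(x$times * x$fps), id = x$cricket_id,
             x = x$x, y = x$y, stringsAsFactors = FALSE)
}

# reflect coordinates into [0, w] (true specular reflection at both walls)
fold_reflect <- function(v, w) {
  m <- v %% (2 * w)
  ifelse(m > w, 2 * w - m, m)
}

#' Simulate one arena trajectory with alternating rests and movement bouts
#'
#' Generates a single individual's 2-D trajectory: resting periods with
#' exponential durations and sub-threshold positional wobble alternate with
#' movement bouts whose path lengths are gamma distributed and which are
#' walked at a per-bout speed (log-normally jittered around
#' `mean_bout_speed`) along a correlated-random-walk heading. Walls reflect.
#' Isotropic Gaussian observation noise is added to every recorded position
#' and positions are clamped to the arena.
#'
#' @param params A [behavior_params()] object.
#' @param duration Recording duration (s), positive.
#' @param fps Frames per second, positive; `duration * fps` frames are
#'   simulated (plus the initial frame).
#' @param arena `c(width, depth)` of the arena (m).
#' @param seed Integer seed; identical seeds give identical tracks.
#' @param cricket_id,day Identifiers stored on the returned track.
#' @return A `cricket_track` with `duration * fps + 1` frames and an attribute
#'   `"schedule"`: the ground-truth segment table (kind, duration_s,
#'   path_length_m) as generated, before any observation noise.
#' @export
simulate_track <- function(params, duration = 600, fps = 24,
                           arena = c(1.2, 0.8), seed = 1,
                           cricket_id = "c001", day = 1L) {
  if (!inherits(params, "behavior_params")) stop("simulate_track: 'params' must be behavior_params")
  if (!is.numeric(duration) || duration <= 0) stop("simulate_track: duration must be positive")
  if (!is.numeric(fps) || fps <= 0) stop("simulate_track: fps must be positive")
  if (length(arena) != 2L || any(arena <= 0)) stop("simulate_track: invalid arena")
  n_steps <- round(duration * fps)
  dt <- 1 / fps

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))

  dx <- numeric(0); dy <- numeric(0)
  kinds <- character(0); seg_frames <- integer(0); seg_path <- numeric(0)
  total <- 0L
  resting <- TRUE  # recordings start after habituation; begin at rest
  while (total < n_steps) {
    if (resting) {
      dur <- if (is.finite(params$mean_rest_duration))
        stats::rexp(1, rate = 1 / params$mean_rest_duration)
      else duration  # mean_rest_duration = Inf: the animal never moves
      n <- max(1L, min(round(dur * fps), n_steps - total))
      mag <- stats::runif(n, 0, params$rest_jitter_speed * dt)
      ang <- stats::runif(n, 0, 2 * pi)
      sdx <- mag * cos(ang); sdy <- mag * sin(ang)
    } else {
      len <- stats::rgamma(1, shape = params$bout_length_shape,
                           scale = params$mean_bout_length / params$bout_length_shape)
      spd <- params$mean_bout_speed * stats::rlnorm(1, meanlog = -0.15^2 / 2, sdlog = 0.15)
      n <- max(1L, min(round(len / spd * fps), n_steps - total))
      step <- spd * dt
      head0 <- stats::runif(1, 0, 2 * pi)
      heads <- head0 + cumsum(stats::rnorm(n, 0, params$turning_sd))
      sdx <- step * cos(heads); sdy <- step * sin(heads)
    }
    dx <- c(dx, sdx); dy <- c(dy, sdy)
    kinds <- c(kinds, if (resting) "resting" else "movement")
    seg_frames <- c(seg_frames, n)
    seg_path <- c(seg_path, sum(sqrt(sdx^2 + sdy^2)))
    total <- total + n
    resting <- !resting
  }

  x0 <- stats::runif(1, 0.05 * arena[1], 0.95 * arena[1])
  y0 <- stats::runif(1, 0.05 * arena[2], 0.95 * arena[2])
  x <- fold_reflect(x0 + c(0, cumsum(dx)), arena[1])
  y <- fold_reflect(y0 + c(0, cumsum(dy)), arena[2])
  if (params$position_noise_sd > 0) {
    x <- x + stats::rnorm(n_steps + 1L, 0, params$position_noise_sd)
    y <- y + stats::rnorm(n_steps + 1L, 0, params$position_noise_sd)
  }
  x <- pmin(pmax(x, 0), arena[1])
  y <- pmin(pmax(y, 0), arena[2])

  trk <- new_track(cricket_id, times = (0:n_steps) * dt, x = x, y = y,
                   fps = fps, day = as.integer(day))
  attr(trk, "schedule") <- data.frame(
    kind = kinds, duration_s = seg_frames * dt, path_length_m = seg_path,
    stringsAsFactors = FALSE)
  trk
}

#' Scale behavioural parameters by tag load and temperature
#'
#' Applies the multiplicative effect model: speed, mean bout length and mean
#' rest duration are multiplied by the temperature-category triple and by the
#' per-mg multipliers raised to the attached tag mass. A 0-mg tag under a
#' neutral (all-ones) category leaves the parameters unchanged.
#'
#' @param params A [behavior_params()] object.
#' @param tag_mass Attached tag mass (mg), non-negative.
#' @param temperature_category Category label known to `effects`.
#' @param effects An [effect_model()].
#' @return A new `behavior_params` object.
#' @export
apply_effects <- function(params, tag_mass, temperature_category, effects) {
  if (!inherits(effects, "effect_model")) stop("apply_effects: 'effects' must be an effect_model")
  if (tag_mass < 0) stop("apply_effects: tag_mass must be non-negative")
  trip <- effects$temperature_multipliers[[temperature_category]]
  if (is.null(trip))
    stop(sprintf("apply_effects: unknown temperature category '%s'", temperature_category))
  out <- unclass(params)
  out$mean_bout_speed <- params$mean_bout_speed *
    effects$speed_multiplier_per_mg^tag_mass * trip[["speed"]]
  out$mean_bout_length <- params$mean_bout_length *
    effects$bout_length_multiplier_per_mg^tag_mass * trip[["bout_length"]]
  out$mean_rest_duration <- params$mean_rest_duration *
    effects$rest_duration_multiplier_per_mg^tag_mass * trip[["rest_duration"]]
  class(out) <- "behavior_params"
  out
}

rnorm_trunc_pos <- function(n, mean, sd) {
  v <- stats::rnorm(n, mean, sd)
  while (any(v <= 0)) v[v <= 0] <- stats::rnorm(sum(v <= 0), mean, sd)
  v
}

#' Simulate a full tag-load experiment
#'
#' Generates one track per individual per day plus the experiment metadata
#' table. Each group holds equal numbers of control, light, medium and heavy
#' individuals; tag masses are drawn once per individual (truncated positive)
#' and body masses evolve across days by the design's median shifts.
#'
#' @param design An [experiment_design()].
#' @param base A [behavior_params()] object for an untagged individual at the
#'   neutral temperature.
#' @param effects An [effect_model()].
#' @param seed Integer master seed.
#' @return A list with components `tracks` (a `track_set`: list of
#'   `cricket_track`s, one per individual-day) and `metadata` (a data frame
#'   with columns cricket_id, group, temperature_category, temperature_c,
#'   day, weight_category, tag_weight_mg, animal_weight_mg).
#' @export
simulate_experiment <- function(design = experiment_design(),
                                base = behavior_params(),
                                effects = effect_model(),
                                seed = 1) {
  stopifnot(inherits(design, "experiment_design"))
  categories <- c("control", names(design$tag_mass_distributions))
  per_cat <- design$individuals_per_group %/% length(categories)
  temps <- names(design$temperature_levels)
  n_groups <- length(temps) * design$n_groups_per_temperature
  n_ind <- n_groups * design$individuals_per_group

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(seed, 0L))

  # individual-level frame: id, group, temperature, category, tag mass
  ind <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    temp <- temps[(g - 1L) %/% design$n_groups_per_temperature + 1L]
    data.frame(
      group = sprintf("%s_g%d", temp,
                      (g - 1L) %% design$n_groups_per_temperature + 1L),
      temperature_category = temp,
      weight_category = rep(categories, each = per_cat),
      stringsAsFactors = FALSE)
  }))
  ind$cricket_id <- sprintf("c%03d", seq_len(n_ind))
  ind$tag_weight_mg <- 0
  for (cat in names(design$tag_mass_distributions)) {
    d <- design$tag_mass_distributions[[cat]]
    sel <- ind$weight_category == cat
    ind$tag_weight_mg[sel] <- rnorm_trunc_pos(sum(sel), d[["mean"]], d[["sd"]])
  }

  # persistent per-individual trait multipliers (mean-preserving log-normal),
  # constant across days so repeated measurements of one animal correlate
  cv <- design$individual_cv
  trait <- vapply(c(speed = "speed", bout_length = "bout_length",
                    rest_duration = "rest_duration"), function(k) {
    s <- cv[[k]]
    if (is.null(s) || s <= 0) rep(1, n_ind) else
      stats::rlnorm(n_ind, meanlog = -s^2 / 2, sdlog = s)
  }, numeric(n_ind))

  # body mass trajectory per individual
  amd <- design$animal_mass_distribution
  mass <- matrix(0, n_ind, design$days)
  mass[, 1] <- rnorm_trunc_pos(n_ind, amd[["mean"]], amd[["sd"]])
  if (design$days > 1) for (d in 2:design$days) {
    mass[, d] <- pmax(mass[, d - 1] + design$mass_shift_by_day[d - 1] +
                        stats::rnorm(n_ind, 0, design$mass_shift_sd), 1)
  }

  metadata <- do.call(rbind, lapply(seq_len(design$days), function(d) {
    data.frame(
      cricket_id = ind$cricket_id, group = ind$group,
      temperature_category = ind$temperature_category,
      temperature_c = unname(design$temperature_levels[ind$temperature_category]),
      day = d, weight_category = ind$weight_category,
      tag_weight_mg = ind$tag_weight_mg, animal_weight_mg = mass[, d],
      stringsAsFactors = FALSE)
  }))
  metadata <- metadata[order(metadata$cricket_id, metadata$day), ]
  rownames(metadata) <- NULL

  tracks <- vector("list", n_ind * design$days)
  k <- 0L
  for (i in seq_len(n_ind)) {
    pars <- apply_effects(base, ind$tag_weight_mg[i],
                          ind$temperature_category[i], effects)
    pars$mean_bout_speed <- pars$mean_bout_speed * trait[i, "speed"]
    pars$mean_bout_length <- pars$mean_bout_length * trait[i, "bout_length"]
    pars$mean_rest_duration <- pars$mean_rest_duration * trait[i, "rest_duration"]
    for (d in seq_len(design$days)) {
      k <- k + 1L
      tracks[[k]] <- simulate_track(
        pars, duration = design$recording_duration, fps = design$fps,
        arena = design$arena, seed = derive_seed(seed, c(i, d)),
        cricket_id = ind$cricket_id[i], day = d)
    }
  }
  list(tracks = structure(tracks, class = "track_set"), metadata = metadata)
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks\n", length(x)))
  invisible(x)
}
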