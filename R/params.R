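#' Behavioural parameters of the bout-rest movement generator
#'
#' Bundles the kinematic parameters of the synthetic cricket: movement bouts
#' have gamma-distributed path lengths walked at a roughly constant speed with
#' correlated-random-walk heading; rests have exponential durations with
#' sub-threshold positional wobble.
#'
#' Defaults are calibrated so that a full synthetic cohort lands near the
#' control medians observed in arena recordings of adult *Gryllus locorojo*
#' females (per-bout speed about 0.065 m/s, resting durations of a few
#' seconds, around a hundred resting periods per 10-min recording).
#'
#' @param mean_bout_length Mean path length of a movement bout (m).
#' @param bout_length_shape Gamma shape of the bout path-length distribution
#'   (dimensionless; 1 = exponential).
#' @param mean_bout_speed Mean walking speed within a movement bout (m/s).
#' @param mean_rest_duration Mean duration of a resting period (s). May be
#'   `Inf`, in which case the animal never moves.
#' @param rest_jitter_speed Maximum apparent speed of the sub-threshold wobble
#'   during rest (m/s). Must stay below the resting-speed threshold (0.01 m/s
#'   by default) so that generated rests are detectable by construction.
#' @param turning_sd Standard deviation of the per-frame heading increment
#'   during a movement bout (radians); smaller values give straighter paths.
#' @param position_noise_sd Standard deviation of isotropic Gaussian
#'   observation noise added to every recorded position (m).
#' @return An object of class `behavior_params`.
#' @seealso [simulate_track()], [apply_effects()]
#' @export
behavior_params <- function(mean_bout_length = 0.12,
                            bout_length_shape = 1.2,
                            mean_bout_speed = 0.076,
                            mean_rest_duration = 2.2,
                            rest_jitter_speed = 0.002,
                            turning_sd = 0.35,
                            position_noise_sd = 1e-4) {
  p <- list(
    mean_bout_length = mean_bout_length,
    bout_length_shape = bout_length_shape,
    mean_bout_speed = mean_bout_speed,
    mean_rest_duration = mean_rest_duration,
    rest_jitter_speed = rest_jitter_speed,
    turning_sd = turning_sd,
    position_noise_sd = position_noise_sd
  )
  for (nm in c("mean_bout_length", "bout_length_shape", "mean_bout_speed",
               "mean_rest_duration", "turning_sd")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop(sprintf("behavior_params: '%s' must be a single positive number", nm))
  }
  for (nm in c("rest_jitter_speed", "position_noise_sd")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop(sprintf("behavior_params: '%s' must be a single non-negative number", nm))
  }
  if (p$rest_jitter_speed >= 0.01)
    stop("behavior_params: 'rest_jitter_speed' must be below the 0.01 m/s resting threshold")
  structure(p, class = "behavior_params")
}

#' Multiplicative treatment-effect model for the synthetic generator
#'
#' Encodes how tag load and ambient temperature scale the behavioural
#' parameters: each per-mg multiplier is raised to the attached tag mass, and
#' each temperature category carries a (speed, bout length, rest duration)
#' multiplier triple. Effects act log-linearly in tag mass, matching the
#' monotone dose-response seen in tag-load experiments. Control animals
#' (0 mg) at the neutral temperature are left unchanged.
#'
#' Defaults reproduce the qualitative pattern of the reference experiment: a
#' heavy (~759 mg) tag slows walking by roughly a quarter, shortens bouts, and
#' nearly doubles resting durations; low temperature lengthens travel while
#' high temperature suppresses it.
#'
#' @param speed_multiplier_per_mg Per-mg multiplier on bout speed.
#' @param bout_length_multiplier_per_mg Per-mg multiplier on mean bout length.
#' @param rest_duration_multiplier_per_mg Per-mg multiplier on mean rest
#'   duration.
#' @param temperature_multipliers Named list mapping temperature category to a
#'   numeric triple `c(speed, bout_length, rest_duration)`.
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(speed_multiplier_per_mg = 0.99966,
                         bout_length_multiplier_per_mg = 0.99945,
                         rest_duration_multiplier_per_mg = 1.00080,
                         temperature_multipliers = list(
                           low          = c(speed = 1.00, bout_length = 1.20, rest_duration = 0.80),
                           intermediate = c(speed = 1.00, bout_length = 1.00, rest_duration = 1.00),
                           high         = c(speed = 1.00, bout_length = 0.75, rest_duration = 1.40)
                         )) {
  for (nm in c("speed_multiplier_per_mg", "bout_length_multiplier_per_mg",
               "rest_duration_multiplier_per_mg")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop(sprintf("effect_model: '%s' must be a single positive number", nm))
  }
  if (!is.list(temperature_multipliers) || is.null(names(temperature_multipliers)))
    stop("effect_model: 'temperature_multipliers' must be a named list")
  for (cat in names(temperature_multipliers)) {
    trip <- temperature_multipliers[[cat]]
    if (!is.numeric(trip) || length(trip) != 3L || any(trip <= 0))
      stop(sprintf("effect_model: multiplier triple for '%s' must be 3 positive numbers", cat))
    names(temperature_multipliers[[cat]]) <- c("speed", "bout_length", "rest_duration")
  }
  structure(list(
    speed_multiplier_per_mg = speed_multiplier_per_mg,
    bout_length_multiplier_per_mg = bout_length_multiplier_per_mg,
    rest_duration_multiplier_per_mg = rest_duration_multiplier_per_mg,
    temperature_multipliers = temperature_multipliers
  ), class = "effect_model")
}

#' Neutral effect model (no tag or temperature influence)
#' @return An `effect_model` whose multipliers are all 1.
#' @export
neutral_effects <- function() {
  effect_model(
    speed_multiplier_per_mg = 1, bout_length_multiplier_per_mg = 1,
    rest_duration_multiplier_per_mg = 1,
    temperature_multipliers = list(
      low = c(1, 1, 1), intermediate = c(1, 1, 1), high = c(1, 1, 1)
    )
  )
}

#' Synthetic experiment design
#'
#' Describes the cohort layout the generator emulates: groups of 20
#' individuals (5 controls and 5 for each tag-weight category) recorded for
#' 10 minutes at 24 fps in a 1.2 x 0.8 m arena, three groups at each of three
#' temperatures, on three consecutive days. Tag and animal masses are drawn
#' from the stated category distributions. Body mass evolves across days with
#' a configurable median shift per day (default: none between days 1 and 2,
#' +22 mg between days 2 and 3).
#'
#' @param n_groups_per_temperature Number of replicate groups per temperature.
#' @param individuals_per_group Individuals in each group; must be divisible
#'   by the four weight categories.
#' @param temperature_levels Named numeric vector of mean arena temperatures
#'   (deg C) for the low/intermediate/high categories.
#' @param days Number of consecutive recording days.
#' @param tag_mass_distributions Named list of `c(mean, sd)` tag-mass
#'   distributions (mg) for the light/medium/heavy categories.
#' @param animal_mass_distribution `c(mean, sd)` of day-1 body mass (mg).
#' @param mass_shift_by_day Numeric vector of median body-mass shifts (mg)
#'   applied between consecutive days (length `days - 1`).
#' @param mass_shift_sd Between-day within-individual body-mass noise SD (mg).
#' @param individual_cv Named numeric `c(speed, bout_length, rest_duration)`
#'   of log-normal coefficients of variation for persistent per-individual
#'   trait multipliers (the "personality" that makes repeated measurements of
#'   one animal correlated across days).
#' @param recording_duration Recording length (s).
#' @param fps Frames per second; `recording_duration * fps` must be integral.
#' @param arena `c(width, depth)` of the arena floor (m).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_groups_per_temperature = 3,
                              individuals_per_group = 20,
                              temperature_levels = c(low = 19.5, intermediate = 24.0, high = 28.3),
                              days = 3,
                              tag_mass_distributions = list(
                                light  = c(mean = 198.7, sd = 2.1),
                                medium = c(mean = 549.2, sd = 7.3),
                                heavy  = c(mean = 758.6, sd = 6.9)
                              ),
                              animal_mass_distribution = c(mean = 768, sd = 117),
                              mass_shift_by_day = c(0, 22),
                              mass_shift_sd = 15,
                              individual_cv = c(speed = 0.08, bout_length = 0.25,
                                                rest_duration = 0.25),
                              recording_duration = 600,
                              fps = 24,
                              arena = c(width = 1.2, depth = 0.8)) {
  n_categories <- length(tag_mass_distributions) + 1L  # + control
  if (individuals_per_group %% n_categories != 0L)
    stop(sprintf("experiment_design: individuals_per_group must be divisible by %d", n_categories))
  if (n_groups_per_temperature < 1 || days < 1)
    stop("experiment_design: counts must be positive")
  if (abs(recording_duration * fps - round(recording_duration * fps)) > 1e-9)
    stop("experiment_design: recording_duration * fps must be an integer frame count")
  if (length(arena) != 2L || any(arena <= 0))
    stop("experiment_design: arena must be two positive dimensions")
  if (length(mass_shift_by_day) != days - 1L)
    mass_shift_by_day <- rep_len(mass_shift_by_day, max(days - 1L, 0L))
  structure(list(
    n_groups_per_temperature = as.integer(n_groups_per_temperature),
    individuals_per_group = as.integer(individuals_per_group),
    temperature_levels = temperature_levels,
    days = as.integer(days),
    tag_mass_distributions = tag_mass_distributions,
    animal_mass_distribution = animal_mass_distribution,
    mass_shift_by_day = mass_shift_by_day,
    mass_shift_sd = mass_shift_sd,
    individual_cv = individual_cv,
    recording_duration = recording_duration,
    fps = fps,
    arena = c(width = unname(arena[1]), depth = unname(arena[2]))
  ), class = "experiment_design")
}

#' Segmentation thresholds
#'
#' The two-state behavioural definition: an animal is *resting* whenever its
#' (smoothed) speed is at or below `resting_speed`, and a run of supra-
#' threshold frames only counts as a *movement* bout if its path length
#' strictly exceeds `min_movement_length`; shorter dashes are treated as noise
#' and absorbed into the surrounding rest.
#'
#' @param min_movement_length Minimum path length of a movement bout (m);
#'   default 0.02 (2 cm).
#' @param resting_speed Speed at or below which a frame is stationary (m/s);
#'   default 0.01 (1 cm/s).
#' @param speed_window Width of the centred smoothing window used to estimate
#'   per-frame speed (s). Must be at least one inter-frame interval.
#' @return An object of class `seg_thresholds`.
#' @export
thresholds <- function(min_movement_length = 0.02,
                       resting_speed = 0.01,
                       speed_window = 0.25) {
  if (min_movement_length <= 0 || resting_speed <= 0 || speed_window <= 0)
    stop("thresholds: all thresholds must be positive")
  structure(list(
    min_movement_length = min_movement_length,
    resting_speed = resting_speed,
    speed_window = speed_window
  ), class = "seg_thresholds")
}

#' Pixel-to-metre calibration
#'
#' Either a single isotropic scale (`px_per_metre`) or four arena-corner pixel
#' coordinates, given in order (origin, +x, +x+y, +y) and fitted per axis by
#' least squares against the known arena size. Image coordinates with y
#' pointing down are flipped to world y-up when `y_axis = "down"`; distances
#' are unaffected by the flip.
#'
#' @param fps Frames per second of the recording.
#' @param px_per_metre Pixels per metre (exclusive with `arena_corner_pixels`).
#' @param arena_corner_pixels 4 x 2 matrix of pixel corner coordinates.
#' @param arena_size `c(width, depth)` of the arena (m).
#' @param y_axis `"up"` (world) or `"down"` (image) orientation of input y.
#' @return An object of class `calibration`.
#' @export
calibration <- function(fps = 24,
                        px_per_metre = NULL,
                        arena_corner_pixels = NULL,
                        arena_size = c(width = 1.2, depth = 0.8),
                        y_axis = c("up", "down")) {
  y_axis <- match.arg(y_axis)
  if (fps <= 0) stop("calibration: fps must be positive")
  if (is.null(px_per_metre) == is.null(arena_corner_pixels))
    stop("calibration: provide exactly one of 'px_per_metre' or 'arena_corner_pixels'")
  if (!is.null(arena_corner_pixels)) {
    arena_corner_pixels <- as.matrix(arena_corner_pixels)
    if (!all(dim(arena_corner_pixels) == c(4L, 2L)))
      stop("calibration: 'arena_corner_pixels' must be a 4 x 2 matrix")
  }
  structure(list(
    fps = fps,
    px_per_metre = px_per_metre,
    arena_corner_pixels = arena_corner_pixels,
    arena_size = c(width = unname(arena_size[1]), depth = unname(arena_size[2])),
    y_axis = y_axis
  ), class = "calibration")
}
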