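# The six per-recording movement properties:
#   movementLength    mean path length of movement bouts (m)
#   movementLengthMax maximum movement-bout path length (m)
#   movementSum       total path length of movement bouts (m)
#   movementSpeed     mean over movement bouts of (path length / duration) (m/s)
#   restingDuration   mean resting-bout duration (s)
#   restingFrequency  number of resting bouts
# movementSpeed is the mean of per-bout speeds, not total distance over total
# moving time; the pooled ratio is kept alongside as movementSpeedPooled for
# sensitivity analyses.

#' Movement properties of one bout sequence
#'
#' @param bouts A `bout_seq` from [segment_bouts()].
#' @return A one-row data frame with the six movement properties, the pooled
#'   speed alternative, and a `no_movement` flag. Individuals that never move
#'   are retained with the four movement fields set to 0 (dropping them would
#'   bias group medians).
#' @export
compute_properties <- function(bouts) {
  stopifnot(inherits(bouts, "bout_seq"))
  mv <- bouts[bouts$kind == "movement", , drop = FALSE]
  rs <- bouts[bouts$kind == "resting", , drop = FALSE]
  no_movement <- nrow(mv) == 0L
  data.frame(
    movementLength = if (no_movement) 0 else mean(mv$path_length),
    movementLengthMax = if (no_movement) 0 else max(mv$path_length),
    movementSum = if (no_movement) 0 else sum(mv$path_length),
    movementSpeed = if (no_movement) 0 else mean(mv$path_length / mv$duration),
    movementSpeedPooled = if (no_movement) 0 else sum(mv$path_length) / sum(mv$duration),
    restingDuration = if (nrow(rs) == 0L) 0 else mean(rs$duration),
    restingFrequency = nrow(rs),
    no_movement = no_movement)
}

#' Cohort movement-property table
#'
#' Segments every track, computes its movement properties, and joins them to
#' the experiment metadata on (cricket_id, day), yielding one row per
#' individual-day in deterministic (cricket_id, day) order.
#'
#' @param tracks A `track_set` whose tracks carry `cricket_id` and `day`.
#' @param metadata Experiment metadata with one row per (cricket_id, day).
#' @param th A [thresholds()] object.
#' @return Data frame combining metadata columns with the property columns.
#' @export
properties_table <- function(tracks, metadata, th = thresholds()) {
  meta_cols <- c("cricket_id", "group", "temperature_category",
                 "temperature_c", "day", "weight_category", "tag_weight_mg",
                 "animal_weight_mg")
  meta_cols <- intersect(meta_cols, names(metadata))
  prop_cols <- c("movementLength", "movementLengthMax", "movementSum",
                 "movementSpeed", "restingDuration", "restingFrequency",
                 "movementSpeedPooled", "no_movement")
  if (length(tracks) == 0L) {
    empty <- metadata[0, meta_cols, drop = FALSE]
    for (p in prop_cols) empty[[p]] <- numeric(0)
    return(empty)
  }
  if (anyDuplicated(metadata[c("cricket_id", "day")]))
    stop("properties_table: metadata has duplicate (cricket_id, day) rows")
  key <- paste(metadata$cricket_id, metadata$day, sep = "\r")
  rows <- lapply(tracks, function(t) {
    i <- match(paste(t$cricket_id, t$day, sep = "\r"), key)
    if (is.na(i))
      stop(sprintf("properties_table: no metadata row for cricket_id=%s day=%s",
                   t$cricket_id, t$day))
    cbind(metadata[i, meta_cols, drop = FALSE],
          compute_properties(segment_bouts(t, th)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cricket_id, out$day), ]
  rownames(out) <- NULL
  out
}
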