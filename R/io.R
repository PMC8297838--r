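# Trajectory CSV dialect: header `frame,id,x,y`, 0-based frames, UTF-8.
# Positions are written in world metres at 6 significant digits; readers
# accept pixel input and calibrate via a scale or four arena corners.

#' Pixel-per-metre scales implied by a calibration
#'
#' For a corner-point calibration the four pixel corners are matched, in
#' order, to world (0,0), (W,0), (W,D), (0,D) and a per-axis linear map is
#' fitted by least squares; the returned scales are the absolute slopes.
#'
#' @param cal A [calibration()] object.
#' @return Named numeric `c(x = , y = )` in pixels per metre.
#' @export
px_scale <- function(cal) {
  stopifnot(inherits(cal, "calibration"))
  if (!is.null(cal$px_per_metre))
    return(c(x = cal$px_per_metre, y = cal$px_per_metre))
  w <- cal$arena_size[["width"]]; d <- cal$arena_size[["depth"]]
  wx <- c(0, w, w, 0); wy <- c(0, 0, d, d)
  px <- cal$arena_corner_pixels
  bx <- stats::cov(px[, 1], wx) / stats::var(wx)
  by <- stats::cov(px[, 2], wy) / stats::var(wy)
  c(x = abs(bx), y = abs(by))
}

# map pixel coordinates to world metres under a calibration
calibrate_xy <- function(x_px, y_px, cal) {
  d <- cal$arena_size[["depth"]]
  if (!is.null(cal$px_per_metre)) {
    x <- x_px / cal$px_per_metre
    y <- y_px / cal$px_per_metre
  } else {
    w <- cal$arena_size[["width"]]
    wx <- c(0, w, w, 0); wy <- c(0, 0, d, d)
    px <- cal$arena_corner_pixels
    fx <- stats::lm.fit(cbind(1, px[, 1]), wx)$coefficients
    fy <- stats::lm.fit(cbind(1, px[, 2]), wy)$coefficients
    x <- fx[1] + fx[2] * x_px
    y <- fy[1] + fy[2] * y_px
  }
  if (cal$y_axis == "down") y <- d - y
  list(x = x, y = y)
}

#' Read a multi-individual trajectory table
#'
#' Reads the `frame,id,x,y` CSV dialect, calibrates pixel positions to world
#' metres, and returns one `cricket_track` per individual with times
#' `frame / fps`. Input rows need not be sorted.
#'
#' @param file Path to the trajectory CSV.
#' @param cal A [calibration()] object.
#' @param day Optional recording day stored on each returned track.
#' @return A `track_set` (list of `cricket_track`s, ordered by id).
#' @export
read_tracks <- function(file, cal, day = NA_integer_) {
  stopifnot(inherits(cal, "calibration"))
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("frame", "id", "x", "y")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop(sprintf("read_tracks: missing column(s): %s", paste(missing_cols, collapse = ", ")))
  if (nrow(tab) == 0L) {
    warning("read_tracks: empty trajectory table")
    return(structure(list(), class = "track_set"))
  }
  if (anyDuplicated(tab[c("id", "frame")]))
    stop("read_tracks: duplicate (id, frame) rows")
  xy <- calibrate_xy(tab$x, tab$y, cal)
  tracks <- lapply(split(seq_len(nrow(tab)), tab$id), function(idx) {
    ord <- idx[order(tab$frame[idx])]
    new_track(cricket_id = as.character(tab$id[ord[1]]),
              times = tab$frame[ord] / cal$fps,
              x = xy$x[ord], y = xy$y[ord], fps = cal$fps, day = day)
  })
  structure(unname(tracks[order(names(tracks))]), class = "track_set")
}

#' Write tracks in the trajectory CSV dialect
#'
#' Writes world-metre positions with 6 significant digits under the header
#' `frame,id,x,y`; reading the file back with a unit calibration reproduces
#' the tracks up to that formatting precision.
#'
#' @param tracks A `track_set` or single `cricket_track`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_tracks <- function(tracks, file) {
  if (inherits(tracks, "cricket_track")) tracks <- list(tracks)
  rows <- do.call(rbind, lapply(tracks, function(t) {
    data.frame(frame = round(t$times * t$fps), id = t$cricket_id,
               x = signif(t$x, 6), y = signif(t$y, 6),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Repair short tracking dropouts by linear interpolation
#'
#' Missing frame indices spanning at most `max_gap` frames are filled by
#' linear interpolation of x and y; longer gaps split the track into
#' segments (returned as a list, with a warning), since inventing long
#' stretches of trajectory would contaminate bout statistics. A gap-free
#' track is returned unchanged.
#'
#' @param track A `cricket_track` (possibly with missing frames).
#' @param max_gap Largest number of consecutive missing frames to fill
#'   (default 12, i.e. 0.5 s at 24 fps).
#' @return A `cricket_track`, or a list of them when the track was split.
#' @export
fill_gaps <- function(track, max_gap = 12) {
  stopifnot(inherits(track, "cricket_track"))
  frames <- round(track$times * track$fps)
  if (length(frames) > 1 && all(diff(frames) == 1L)) return(track)
  # split where a gap exceeds max_gap missing frames
  gap_sizes <- diff(frames) - 1L
  cut_after <- which(gap_sizes > max_gap)
  bounds <- c(0L, cut_after, length(frames))
  segs <- lapply(seq_len(length(bounds) - 1L), function(s) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    f <- frames[idx]
    full <- f[1]:f[length(f)]
    if (length(idx) == 1L) {
      xi <- track$x[idx]; yi <- track$y[idx]
    } else {
      xi <- stats::approx(f, track$x[idx], xout = full)$y
      yi <- stats::approx(f, track$y[idx], xout = full)$y
    }
    new_track(track$cricket_id, times = full / track$fps, x = xi, y = yi,
              fps = track$fps, day = track$day)
  })
  if (length(segs) == 1L) return(segs[[1]])
  warning(sprintf("fill_gaps: track %s split into %d segments (gap > %d frames)",
                  track$cricket_id, length(segs), max_gap))
  segs
}

#' Read or write the experiment metadata table
#'
#' The metadata CSV carries one row per individual per day with columns
#' cricket_id, group, temperature_category, temperature_c, day,
#' weight_category, tag_weight_mg, animal_weight_mg. Reading validates the
#' core invariants: the control category has zero tag weight (and only it),
#' and body masses are positive.
#'
#' @param file Path to the metadata CSV.
#' @return A data frame of experiment records.
#' @export
read_metadata <- function(file) {
  md <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("cricket_id", "temperature_category", "day", "weight_category",
            "tag_weight_mg", "animal_weight_mg")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols))
    stop(sprintf("read_metadata: missing column(s): %s", paste(missing_cols, collapse = ", ")))
  validate_metadata(md)
  md
}

validate_metadata <- function(md) {
  bad <- (md$weight_category == "control") != (md$tag_weight_mg == 0)
  if (any(bad))
    stop(sprintf("metadata: weight_category 'control' must coincide with tag_weight_mg = 0 (rows %s)",
                 paste(utils::head(which(bad), 5), collapse = ", ")))
  if (any(md$animal_weight_mg <= 0)) stop("metadata: animal_weight_mg must be positive")
  invisible(md)
}

#' @rdname read_metadata
#' @param metadata Data frame of experiment records.
#' @export
write_metadata <- function(metadata, file) {
  cols <- c("cricket_id", "group", "temperature_category", "temperature_c",
            "day", "weight_category", "tag_weight_mg", "animal_weight_mg")
  utils::write.csv(metadata[, intersect(cols, names(metadata))], file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}
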