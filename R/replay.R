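#' @title Drive recordings: the replay data model
#' @description A `drive_recording` holds one applicant's assessment drive as
#' an ordered multichannel frame sequence, nominally ~10 Hz after
#' downsampling. Channels per frame: elapsed time `t` (s, strictly
#' increasing), planar position `x`,`y` (m), `heading` (rad), `speed` (m/s,
#' >= 0), `brake` and `throttle` (fraction of full depression in \[0,1\]),
#' `steering` (signed fraction of full rotation in \[-1,1\], negative =
#' left), `lane_offset` (signed m from the lane centerline, positive = right),
#' `turn_signal` (`"none"/"left"/"right"`), `scan_left`/`scan_right`
#' (logical), `posted_limit` (m/s, > 0).
#' @name drive_recording
NULL

.frame_cols <- c("t", "x", "y", "heading", "speed", "brake", "throttle",
                 "steering", "lane_offset", "turn_signal", "scan_left",
                 "scan_right", "posted_limit")

#' Construct a drive recording
#'
#' @param drive_id opaque identifier.
#' @param environment_id environment identifier (1..n_env).
#' @param frames data.frame with the frame columns (see [drive_recording]).
#' @param nominal_rate nominal frame rate in Hz.
#' @param events optional data.frame of simulator event flags with columns
#'   `t`, `s`, `type` (e.g. `"collision_pedestrian"`, `"ran_red_light"`).
#' @return an object of class `drive_recording`.
#' @export
new_drive_recording <- function(drive_id, environment_id, frames,
                                nominal_rate = 10, events = NULL) {
  rec <- structure(
    list(drive_id = as.character(drive_id),
         environment_id = as.integer(environment_id),
         frames = frames,
         nominal_rate = nominal_rate,
         events = events),
    class = "drive_recording")
  validate_drive_recording(rec)
  rec
}

#' Validate drive-recording invariants
#'
#' Checks channel ranges and strict time monotonicity; stops with an
#' informative error on the first violation.
#'
#' @param rec a `drive_recording`.
#' @return `rec`, invisibly.
#' @export
validate_drive_recording <- function(rec) {
  fr <- rec$frames
  missing_cols <- setdiff(.frame_cols, names(fr))
  if (length(missing_cols))
    stop("frames missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(fr) == 0L) stop("recording has no frames")
  if (any(diff(fr$t) <= 0))
    stop("frame times must be strictly increasing (drive ", rec$drive_id, ")")
  if (any(fr$speed < 0)) stop("speed must be >= 0")
  if (any(fr$brake < 0 | fr$brake > 1)) stop("brake must lie in [0,1]")
  if (any(fr$throttle < 0 | fr$throttle > 1)) stop("throttle must lie in [0,1]")
  if (any(fr$steering < -1 | fr$steering > 1)) stop("steering must lie in [-1,1]")
  if (any(fr$posted_limit <= 0)) stop("posted_limit must be > 0")
  if (!all(fr$turn_signal %in% c("none", "left", "right")))
    stop("turn_signal must be one of none/left/right")
  invisible(rec)
}

#' @export
print.drive_recording <- function(x, ...) {
  fr <- x$frames
  cat(sprintf("<drive_recording> %s  env %d  %d frames  %.1f s  (~%.1f Hz)\n",
              x$drive_id, x$environment_id, nrow(fr),
              fr$t[nrow(fr)] - fr$t[1],
              (nrow(fr) - 1) / max(fr$t[nrow(fr)] - fr$t[1], 1e-9)))
  invisible(x)
}

#' Write a recording to a JSONL replay file
#'
#' One JSON object per frame per line, keys `t,x,y,heading,speed,brake,
#' throttle,steering,lane_offset,turn_signal,scan_left,scan_right,
#' posted_limit`. Reals are written with enough digits for a 1e-9 round trip.
#'
#' @param rec a `drive_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_replay()]
#' @export
write_replay <- function(rec, path) {
  fr <- rec$frames
  num <- function(v) {
    out <- sprintf("%.10g", v)
    out[!is.finite(v)] <- "null"
    out
  }
  lines <- sprintf(
    paste0('{"t":%s,"x":%s,"y":%s,"heading":%s,"speed":%s,"brake":%s,',
           '"throttle":%s,"steering":%s,"lane_offset":%s,"turn_signal":"%s",',
           '"scan_left":%s,"scan_right":%s,"posted_limit":%s}'),
    num(fr$t), num(fr$x), num(fr$y), num(fr$heading), num(fr$speed),
    num(fr$brake), num(fr$throttle), num(fr$steering), num(fr$lane_offset),
    fr$turn_signal, ifelse(fr$scan_left, "true", "false"),
    ifelse(fr$scan_right, "true", "false"), num(fr$posted_limit))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSONL replay file
#'
#' Parses one frame per line and validates the recording. A malformed line
#' produces a parse error naming its line number; non-monotone frame times
#' produce a validation error.
#'
#' @param path replay file path.
#' @param drive_id,environment_id identifiers to attach; by default the
#'   drive_id is the file name without extension.
#' @param events optional events data.frame to attach (see
#'   [new_drive_recording()]).
#' @return a `drive_recording`.
#' @export
read_replay <- function(path, drive_id = NULL, environment_id = 1L,
                        events = NULL) {
  if (!file.exists(path)) stop("replay file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("replay file is empty: ", path)
  fr <- tryCatch(
    jsonlite::fromJSON(paste0("[", paste(lines, collapse = ","), "]")),
    error = function(e) {
      # localize the offending line for the error message
      for (i in seq_along(lines)) {
        ok <- tryCatch({jsonlite::fromJSON(lines[i]); TRUE},
                       error = function(e2) FALSE)
        if (!ok) stop("malformed replay line ", i, " in ", path, call. = FALSE)
      }
      stop("malformed replay file: ", path, call. = FALSE)
    })
  fr <- as.data.frame(fr)
  new_drive_recording(
    drive_id = drive_id %||% sub("\\.[^.]*$", "", basename(path)),
    environment_id = environment_id,
    frames = fr[, .frame_cols],
    events = events)
}

#' Downsample a recording by frame subsampling
#'
#' Keeps every `keep_every`-th frame starting at the first; original
#' timestamps are preserved (true elapsed time between retained frames, not
#' resampled). The study's recordings are captured at 60 Hz and stored at
#' ~10 Hz this way.
#'
#' @param rec a `drive_recording`.
#' @param keep_every positive integer subsampling stride (default 6,
#'   60 Hz -> 10 Hz).
#' @return the downsampled `drive_recording`.
#' @export
downsample <- function(rec, keep_every = 6L) {
  if (length(keep_every) != 1L || is.na(keep_every) || keep_every < 1)
    stop("keep_every must be a positive integer")
  keep_every <- as.integer(keep_every)
  idx <- seq(1L, nrow(rec$frames), by = keep_every)
  rec$frames <- rec$frames[idx, , drop = FALSE]
  rownames(rec$frames) <- NULL
  rec$nominal_rate <- rec$nominal_rate / keep_every
  rec
}

#' Truncate a recording at first motion
#'
#' Drops leading frames until the first frame whose speed strictly exceeds
#' `v_min`, aligning replays on a common starting condition. Errors if no
#' frame exceeds `v_min` (the caller should exclude such a drive).
#'
#' @param rec a `drive_recording`.
#' @param v_min motion threshold in m/s (default 0.5).
#' @return the truncated `drive_recording`.
#' @export
truncate_at_motion <- function(rec, v_min = 0.5) {
  i <- which(rec$frames$speed > v_min)
  if (!length(i))
    stop("empty drive: no frame with speed above ", v_min, " m/s (drive ",
         rec$drive_id, ")")
  rec$frames <- rec$frames[i[1L]:nrow(rec$frames), , drop = FALSE]
  rownames(rec$frames) <- NULL
  rec
}
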