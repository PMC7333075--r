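#' Project recorded positions onto the route centerline
#'
#' For each frame, finds the nearest point on the route polyline and returns
#' its arc-length position `s` (m from the route start). The raw projection
#' is then clamped monotone non-decreasing (a briefly reversing vehicle does
#' not rewind route progress). Frames farther than `corridor` from the route
#' raise an off-route warning but are retained with their nearest-point
#' projection.
#'
#' @param env a `vdt_environment`.
#' @param rec a `drive_recording`.
#' @param corridor off-route warning tolerance in m (default 10).
#' @return numeric vector of per-frame arc-length positions.
#' @export
route_progress <- function(env, rec, corridor = 10) {
  px <- rec$frames$x; py <- rec$frames$y
  v <- env$route
  nseg <- nrow(v) - 1L
  best_d2 <- rep(Inf, length(px))
  best_s <- rep(0, length(px))
  for (i in seq_len(nseg)) {
    ax <- v[i, 1]; ay <- v[i, 2]
    dx <- v[i + 1, 1] - ax; dy <- v[i + 1, 2] - ay
    len2 <- dx * dx + dy * dy
    tt <- if (len2 <= 0) rep(0, length(px)) else
      clamp(((px - ax) * dx + (py - ay) * dy) / len2, 0, 1)
    qx <- ax + tt * dx; qy <- ay + tt * dy
    d2 <- (px - qx)^2 + (py - qy)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- env$cum_len[i] + tt[upd] * sqrt(len2)
  }
  if (any(best_d2 > corridor^2))
    warning(sum(best_d2 > corridor^2), " frame(s) off-route (> ", corridor,
            " m from centerline); nearest-point projection retained")
  s <- cummax(pmin(best_s, env$route_length))
  s
}

#' Extract per-zone subintervals from a drive
#'
#' For each event zone, the frames with `entry_s <= s < exit_s` (half-open,
#' first traversal only) form one subinterval carrying the four clustered
#' channels: lane offset, throttle, brake, steering. Zones whose interval
#' would contain fewer than 2 frames are omitted (reported as unvisited).
#'
#' @param rec a `drive_recording`.
#' @param env a `vdt_environment`.
#' @param s optional precomputed [route_progress()] vector.
#' @return named list (by zone id, as `"z<zone_id>"`) of `subinterval`
#'   objects: `zone_id`, `drive_id`, `channels` (n x 4 matrix with columns
#'   lane_offset, throttle, brake, steering), `timestamps`, `collision`
#'   (logical, any collision event flagged in this zone).
#' @export
extract_subintervals <- function(rec, env, s = NULL) {
  if (is.null(s)) s <- route_progress(env, rec)
  fr <- rec$frames
  zones <- env$zones
  out <- list()
  for (i in seq_len(nrow(zones))) {
    inz <- which(s >= zones$entry_s[i] & s < zones$exit_s[i])
    if (length(inz) < 2) next
    # first traversal only: keep the first contiguous run of frames
    brk <- which(diff(inz) > 1)
    if (length(brk)) inz <- inz[seq_len(brk[1])]
    if (length(inz) < 2) next
    ch <- cbind(lane_offset = fr$lane_offset[inz],
                throttle = fr$throttle[inz],
                brake = fr$brake[inz],
                steering = fr$steering[inz])
    collision <- FALSE
    if (!is.null(rec$events) && nrow(rec$events)) {
      collision <- any(rec$events$zone_id == zones$zone_id[i] &
                         grepl("^collision", rec$events$type))
    }
    out[[paste0("z", zones$zone_id[i])]] <-
      structure(list(zone_id = zones$zone_id[i],
                     drive_id = rec$drive_id,
                     channels = ch,
                     timestamps = fr$t[inz],
                     collision = collision),
                class = "subinterval")
  }
  out
}

#' @export
print.subinterval <- function(x, ...) {
  cat(sprintf("<subinterval> drive %s zone %d: %d frames (%.1f s)\n",
              x$drive_id, x$zone_id, nrow(x$channels),
              diff(range(x$timestamps))))
  invisible(x)
}

#' Collect one zone's subintervals across a cohort
#'
#' @param sub_lists list of [extract_subintervals()] results (one per drive).
#' @param zone_id the zone to collect.
#' @return list of `subinterval`s (drives that visited the zone, in input order).
#' @export
collect_zone <- function(sub_lists, zone_id) {
  key <- paste0("z", zone_id)
  out <- lapply(sub_lists, function(sl) sl[[key]])
  out[!vapply(out, is.null, TRUE)]
}
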