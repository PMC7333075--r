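#' The engineered-variables feature catalog
#'
#' The standard comparison representation: 67 named per-drive features
#' summarizing speed management (global and per zone type), posted-limit
#' adherence, infractions, control inputs, signaling, scanning, and drive
#' pacing. The catalog order is fixed; [build_variables()] always emits
#' exactly these names in this order.
#'
#' @return character vector of 67 feature names.
#' @export
variables_catalog <- function() {
  ztypes <- c("crosswalk", "school_zone", "construction_zone",
              "playground_zone", "banking_curve")
  c("vel_max", "vel_mean", "vel_median",
    "ratio_max", "ratio_mean", "ratio_median",
    as.vector(t(outer(ztypes, c("vel_max", "vel_mean", "vel_median",
                                "ratio_max", "ratio_mean", "ratio_median"),
                      paste, sep = "_"))),
    "pct_above_10mph", "pct_above_15mph", "pct_above_20mph",
    "pct_below_10mph", "pct_below_15mph", "pct_below_20mph",
    "collisions_vehicle", "collisions_pedestrian", "red_light_runs",
    "stop_sign_violations", "lane_departures", "missed_yields",
    "steering_reversals", "steering_sd", "steering_max_abs",
    "brake_mean", "brake_max", "hard_brake_count",
    "throttle_mean", "throttle_max", "throttle_sd",
    "lane_offset_mean_abs", "lane_offset_sd", "lane_offset_max_abs",
    "signal_correct_ratio", "signal_missed_count",
    "scan_left_count", "scan_right_count",
    "duration_s", "frac_stopped", "frac_braking")
}

# mph thresholds in m/s
.mph_thresh <- c(`10` = 4.4704, `15` = 6.7056, `20` = 8.9408)

#' Count infraction events in a drive
#'
#' Collisions (vehicle, pedestrian) and red-light runs come from simulator
#' event flags attached to the recording; stop-sign violations (minimum
#' zone speed above 1.5 m/s in a stop-intersection zone), missed crosswalk
#' yields (minimum zone speed above 60% of the zone limit) and lane
#' departures (excursions of |lane offset| beyond 1.2 m) are derived from
#' the channels.
#'
#' @param rec a `drive_recording`.
#' @param env its `vdt_environment`.
#' @param s optional precomputed [route_progress()].
#' @return named integer vector of the six infraction counts.
#' @export
count_infractions <- function(rec, env, s = NULL) {
  if (is.null(s)) s <- route_progress(env, rec)
  fr <- rec$frames
  ev <- rec$events
  n_ev <- function(type) if (is.null(ev)) 0L else sum(ev$type == type)
  zones <- env$zones
  stop_viol <- 0L; missed_yield <- 0L
  for (i in seq_len(nrow(zones))) {
    inz <- s >= zones$entry_s[i] & s < zones$exit_s[i]
    if (sum(inz) < 2) next
    vmin <- min(fr$speed[inz])
    if (zones$zone_type[i] == "intersection_stop" && vmin > 1.5)
      stop_viol <- stop_viol + 1L
    if (zones$zone_type[i] == "crosswalk" && vmin > 0.6 * zones$zone_limit[i])
      missed_yield <- missed_yield + 1L
  }
  dep <- fr$lane_offset
  departed <- abs(dep) > 1.2
  lane_dep <- sum(diff(c(FALSE, departed)) == 1)
  c(collisions_vehicle = n_ev("collision_vehicle"),
    collisions_pedestrian = n_ev("collision_pedestrian"),
    red_light_runs = n_ev("ran_red_light"),
    stop_sign_violations = stop_viol,
    lane_departures = lane_dep,
    missed_yields = missed_yield)
}

#' Build the 67-variable feature vector for one drive
#'
#' The recording should already be preprocessed (downsampled, truncated at
#' first motion). Zone-type statistics are computed over the frames inside
#' zones of that type; a zone type never visited yields `NA` for its six
#' features. Speed-limit adherence uses mph bands converted at 1 mph =
#' 0.44704 m/s.
#'
#' @param rec a `drive_recording`.
#' @param env its `vdt_environment`.
#' @param s optional precomputed [route_progress()].
#' @return named numeric vector of length 67 (order = [variables_catalog()]).
#' @export
build_variables <- function(rec, env, s = NULL) {
  if (nrow(rec$frames) == 0) stop("empty recording")
  if (is.null(s)) s <- route_progress(env, rec)
  fr <- rec$frames
  out <- setNames(numeric(67), variables_catalog())

  ratio <- fr$speed / fr$posted_limit
  out[c("vel_max", "vel_mean", "vel_median")] <-
    c(max(fr$speed), mean(fr$speed), median(fr$speed))
  out[c("ratio_max", "ratio_mean", "ratio_median")] <-
    c(max(ratio), mean(ratio), median(ratio))

  ztypes <- c("crosswalk", "school_zone", "construction_zone",
              "playground_zone", "banking_curve")
  zones <- env$zones
  for (zt in ztypes) {
    zidx <- which(zones$zone_type == zt)
    inz <- rep(FALSE, nrow(fr))
    for (i in zidx)
      inz <- inz | (s >= zones$entry_s[i] & s < zones$exit_s[i])
    cols <- paste0(zt, "_", c("vel_max", "vel_mean", "vel_median",
                              "ratio_max", "ratio_mean", "ratio_median"))
    if (sum(inz) < 2) {
      out[cols] <- NA_real_
    } else {
      out[cols] <- c(max(fr$speed[inz]), mean(fr$speed[inz]),
                     median(fr$speed[inz]),
                     max(ratio[inz]), mean(ratio[inz]), median(ratio[inz]))
    }
  }

  over <- fr$speed - fr$posted_limit
  for (m in names(.mph_thresh)) {
    out[paste0("pct_above_", m, "mph")] <- 100 * mean(over > .mph_thresh[[m]])
    out[paste0("pct_below_", m, "mph")] <- 100 * mean(over < -.mph_thresh[[m]])
  }

  out[names(count_infractions(rec, env, s))] <- count_infractions(rec, env, s)

  st <- fr$steering
  active <- abs(st) > 0.05
  sg <- sign(st[active])
  out["steering_reversals"] <- if (length(sg) > 1) sum(diff(sg) != 0) else 0
  out["steering_sd"] <- sd(st)
  out["steering_max_abs"] <- max(abs(st))

  out["brake_mean"] <- mean(fr$brake)
  out["brake_max"] <- max(fr$brake)
  out["hard_brake_count"] <- sum(diff(c(FALSE, fr$brake > 0.9)) == 1)

  out["throttle_mean"] <- mean(fr$throttle)
  out["throttle_max"] <- max(fr$throttle)
  out["throttle_sd"] <- sd(fr$throttle)

  out["lane_offset_mean_abs"] <- mean(abs(fr$lane_offset))
  out["lane_offset_sd"] <- sd(fr$lane_offset)
  out["lane_offset_max_abs"] <- max(abs(fr$lane_offset))

  turns <- route_turn_angles(env)
  if (length(turns$s)) {
    signaled <- vapply(seq_along(turns$s), function(j) {
      win <- s >= turns$s[j] - 50 & s <= turns$s[j] + 5
      side <- if (turns$angle[j] > 0) "left" else "right"
      any(fr$turn_signal[win] == side)
    }, TRUE)
    out["signal_correct_ratio"] <- mean(signaled)
    out["signal_missed_count"] <- sum(!signaled)
  } else {
    out["signal_correct_ratio"] <- 1
    out["signal_missed_count"] <- 0
  }

  out["scan_left_count"] <- sum(diff(c(FALSE, fr$scan_left)) == 1)
  out["scan_right_count"] <- sum(diff(c(FALSE, fr$scan_right)) == 1)

  out["duration_s"] <- fr$t[nrow(fr)] - fr$t[1]
  out["frac_stopped"] <- mean(fr$speed < 0.5)
  out["frac_braking"] <- mean(fr$brake > 0.1)
  out
}

#' Build the variables feature matrix for a cohort
#'
#' @param recordings list of `drive_recording`s.
#' @param env_bank environment bank; each recording's `environment_id`
#'   selects its environment.
#' @return numeric matrix (drives x 67) with drive ids as row names.
#' @export
build_variables_cohort <- function(recordings, env_bank) {
  X <- t(vapply(recordings, function(rec)
    build_variables(rec, env_bank[[rec$environment_id]]),
    numeric(67)))
  rownames(X) <- vapply(recordings, `[[`, "", "drive_id")
  X
}
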