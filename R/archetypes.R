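#' The planted-behavior archetype library
#'
#' Each event-zone type ships with three prototypical behaviors
#' ("archetypes") spanning compliant to hazardous responses, so that k-way
#' clustering of zone subintervals has recoverable structure. An archetype is
#' a parametric target-speed profile over normalized zone progress (as a
#' multiple of the zone speed limit), an optional lane-offset excursion
#' profile, a non-negative infraction weight feeding the outcome model, and
#' optional simulator event flags (collisions, red-light runs, ...).
#' Brake/throttle channels are not templated directly: they emerge from the
#' acceleration demanded by the target-speed profile, so distinct archetypes
#' produce distinct pedal signatures.
#'
#' @return a named list (by zone type) of lists of archetypes. Each archetype
#'   has fields `name`, `zone_type`, `weight`, `speed_u`/`speed_mult`
#'   (control points), `lane_u`/`lane_off`, `events` (character vector,
#'   possibly empty).
#' @export
archetype_library <- function() {
  a <- function(name, zone_type, weight, su, sm, lu = c(0, 1),
                lo = c(0, 0), events = character()) {
    list(name = name, zone_type = zone_type, weight = weight,
         speed_u = su, speed_mult = sm, lane_u = lu, lane_off = lo,
         events = events)
  }
  u5 <- c(0, 0.25, 0.5, 0.75, 1)
  # stop-type dips are narrow in zone progress: a stop is a brief dwell, not
  # a long crawl, so the deep-speed region spans ~0.1 of the zone
  ustop <- c(0, 0.40, 0.5, 0.60, 1)
  list(
    crosswalk = list(
      a("full_stop",  "crosswalk", 0,   ustop, c(1, 0.50, 0.04, 0.55, 1)),
      a("slow_yield", "crosswalk", 0.5, u5, c(1, 0.75, 0.50, 0.75, 1)),
      a("no_yield",   "crosswalk", 2.5, u5, c(1, 1, 1, 1, 1),
        events = c("missed_yield", "collision_pedestrian"))),
    school_zone = list(
      a("compliant",    "school_zone", 0,   u5, c(1, 1, 1, 1, 1)),
      a("mild_speed",   "school_zone", 0.8, u5, c(1.05, 1.35, 1.35, 1.35, 1.1)),
      a("fast_through", "school_zone", 2,   u5, c(1.2, 1.8, 1.8, 1.8, 1.3))),
    construction_zone = list(
      a("compliant",     "construction_zone", 0, u5, c(1, 1, 1, 1, 1)),
      a("drift",         "construction_zone", 1, u5, c(1, 1, 1, 1, 1),
        lu = c(0, 0.5, 1), lo = c(0, 1.1, 0)),
      a("speed_through", "construction_zone", 2, u5, c(1.1, 1.5, 1.5, 1.5, 1.2))),
    playground_zone = list(
      a("compliant",        "playground_zone", 0,   u5, c(1, 1, 1, 1, 1)),
      a("distracted_drift", "playground_zone", 1,   u5, c(1.05, 1.15, 1.15, 1.15, 1.05),
        lu = c(0, 0.5, 1), lo = c(0, -0.9, 0)),
      a("fast_near_miss",   "playground_zone", 2.5, u5, c(1.2, 1.7, 1.7, 1.7, 1.3),
        events = "collision_pedestrian")),
    banking_curve = list(
      a("smooth",        "banking_curve", 0, u5, c(1, 0.80, 0.75, 0.80, 1)),
      a("wide",          "banking_curve", 1, u5, c(1, 0.92, 0.88, 0.92, 1),
        lu = c(0, 0.5, 1), lo = c(0, 1.2, 0.3)),
      a("overspeed_cut", "banking_curve", 2, u5, c(1.1, 1.15, 1.15, 1.15, 1.1),
        lu = c(0, 0.5, 1), lo = c(0, -1.0, 0))),
    intersection_stop = list(
      a("full_stop",    "intersection_stop", 0, ustop, c(1, 0.45, 0.03, 0.55, 1)),
      a("rolling_stop", "intersection_stop", 1, ustop, c(1, 0.55, 0.28, 0.60, 1),
        events = "ran_stop_sign"),
      a("no_stop",      "intersection_stop", 2, u5, c(1, 0.92, 0.88, 0.92, 1),
        events = "ran_stop_sign")),
    intersection_light = list(
      a("stop_wait",   "intersection_light", 0,   ustop, c(1, 0.45, 0.04, 0.50, 1)),
      a("smooth_pass", "intersection_light", 0.3, u5, c(1, 0.85, 0.80, 0.85, 1)),
      a("run_red",     "intersection_light", 2,   u5, c(1.05, 1.1, 1.1, 1.1, 1.05),
        events = "ran_red_light")),
    rear_end_event = list(
      a("early_brake", "rear_end_event", 0, u5, c(1, 0.55, 0.45, 0.70, 1)),
      a("late_brake",  "rear_end_event", 1, u5, c(1, 1, 0.25, 0.60, 1)),
      a("collision",   "rear_end_event", 3, u5, c(1, 1, 0.90, 0.35, 1),
        events = "collision_vehicle")))
}

#' Zone types recognized by the simulator
#' @export
zone_types <- function() names(archetype_library())

# Evaluate an archetype's target-speed multiplier at normalized progress u.
archetype_speed_mult <- function(arch, u) {
  approx(arch$speed_u, arch$speed_mult, xout = clamp(u, 0, 1),
         rule = 2)$y
}

# Evaluate the lane-offset excursion (m) at normalized progress u.
archetype_lane_off <- function(arch, u) {
  approx(arch$lane_u, arch$lane_off, xout = clamp(u, 0, 1), rule = 2)$y
}

# Archetype selection weights: P(archetype) proportional to (1 - theta)^w,
# with 0^0 := 1. A fully skilled driver (theta = 1) picks only zero-weight
# archetypes; risky-archetype frequency is monotone non-increasing in theta.
archetype_probs <- function(archs, theta) {
  w <- vapply(archs, `[[`, 0, "weight")
  x <- 1 - theta
  p <- ifelse(w == 0, 1, x^w)
  p / sum(p)
}
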