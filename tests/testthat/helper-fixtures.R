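# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# A straight east-west route with explicitly placed zones.
make_straight_env <- function(length = 1000, zones = NULL, base_limit = 13.4,
                              environment_id = 1L) {
  if (is.null(zones))
    zones <- data.frame(zone_id = 1L, zone_type = "crosswalk",
                        entry_s = 300, exit_s = 380, zone_limit = base_limit)
  structure(list(environment_id = environment_id,
                 route = matrix(c(0, 0, length, 0), 2, 2, byrow = TRUE),
                 cum_len = c(0, length),
                 route_length = length,
                 base_limit = base_limit,
                 zones = zones),
            class = "vdt_environment")
}

# A minimal hand-built recording moving at constant speed along +x.
make_recording <- function(n = 100, speed = 13.4, posted = 13.4, dt = 0.1,
                           drive_id = "t1", environment_id = 1L,
                           lane_offset = 0, brake = 0, throttle = 0.5,
                           steering = 0) {
  t <- (seq_len(n) - 1) * dt
  frames <- data.frame(
    t = t, x = t * speed, y = 0, heading = 0,
    speed = rep_len(speed, n), brake = rep_len(brake, n),
    throttle = rep_len(throttle, n), steering = rep_len(steering, n),
    lane_offset = rep_len(lane_offset, n),
    turn_signal = "none", scan_left = FALSE, scan_right = FALSE,
    posted_limit = rep_len(posted, n))
  new_drive_recording(drive_id, environment_id, frames, nominal_rate = 1 / dt)
}

# A random but valid recording for round-trip properties.
make_random_recording <- function(n = 50, seed = 1) {
  set.seed(seed)
  frames <- data.frame(
    t = cumsum(runif(n, 0.05, 0.15)),
    x = cumsum(rnorm(n)), y = cumsum(rnorm(n)),
    heading = runif(n, -pi, pi),
    speed = runif(n, 0, 20),
    brake = runif(n), throttle = runif(n),
    steering = runif(n, -1, 1),
    lane_offset = rnorm(n),
    turn_signal = sample(c("none", "left", "right"), n, replace = TRUE),
    scan_left = runif(n) < 0.1, scan_right = runif(n) < 0.1,
    posted_limit = runif(n, 5, 20))
  new_drive_recording(paste0("r", seed), 1L, frames)
}

# A forced drive plan: every zone executes archetype `idx` (by zone type)
# unless overridden per zone id via `overrides` (named integer vector).
make_forced_plan <- function(env, idx = 1L, overrides = integer(),
                             jitter = 1, theta = 1) {
  lib <- archetype_library()
  zones <- env$zones
  n <- nrow(zones)
  arch_idx <- rep_len(idx, n)
  if (length(overrides))
    arch_idx[match(as.integer(names(overrides)), zones$zone_id)] <-
      unname(overrides)
  arch <- lapply(seq_len(n), function(i) lib[[zones$zone_type[i]]][[arch_idx[i]]])
  turns <- zonescreen:::route_turn_angles(env)
  list(zone_plan = data.frame(
         zone_id = zones$zone_id, arch_idx = arch_idx,
         archetype = vapply(arch, `[[`, "", "name"),
         weight = vapply(arch, `[[`, 0, "weight"),
         jitter = rep_len(jitter, n)),
       zone_events = lapply(arch, `[[`, "events"),
       signals = rep(TRUE, length(turns$s)),
       theta = theta)
}

# Random subinterval channel matrices for DTW/clustering tests.
make_random_channels <- function(n_frames, n_channels = 4, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_frames * n_channels), n_frames, n_channels)
}
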