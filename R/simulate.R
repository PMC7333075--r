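#' Generate a bank of simulated driving environments
#'
#' Each environment is a planned route (a planar polyline traversed once)
#' carrying an ordered, non-overlapping sequence of event zones defined by
#' entry/exit waypoints (arc-length positions along the route centerline).
#' Zone counts are distributed as evenly as possible across environments
#' (16 or 17 each for the default 166 zones over 10 environments); zone ids
#' are globally unique and ascending along each route.
#'
#' @param n_env number of environments (default 10).
#' @param total_zones total event zones across the bank (default 166).
#' @param seed integer seed; the bank is deterministic given the seed.
#' @param route_length route length in m (default 5500, giving ~8-minute
#'   drives at the default cruise limit).
#' @param base_limit posted cruise limit in m/s (default 13.4, ~30 mph).
#' @param zone_len zone length range in m (default 60-100).
#' @return list of `vdt_environment` objects.
#' @export
generate_environment_bank <- function(n_env = 10L, total_zones = 166L, seed = 1L,
                                      route_length = 5500, base_limit = 13.4,
                                      zone_len = c(60, 100)) {
  if (total_zones < n_env)
    stop("total_zones must be at least n_env")
  counts <- rep(total_zones %/% n_env, n_env)
  extra <- total_zones %% n_env
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  next_id <- 1L
  bank <- vector("list", n_env)
  for (e in seq_len(n_env)) {
    env <- generate_environment(environment_id = e,
                                n_zones = counts[e],
                                first_zone_id = next_id,
                                seed = derive_seed(seed, e),
                                route_length = route_length,
                                base_limit = base_limit,
                                zone_len = zone_len)
    next_id <- next_id + counts[e]
    bank[[e]] <- env
  }
  bank
}

# mph -> m/s for posted-limit constants
.mph <- 0.44704

generate_environment <- function(environment_id, n_zones, first_zone_id, seed,
                                 route_length, base_limit,
                                 zone_len = c(60, 100)) {
  set.seed(seed)
  # Route polyline: straight segments joined by turns of +-45/90 degrees.
  n_seg <- max(4L, round(route_length / 700))
  seg_len <- rep(route_length / n_seg, n_seg) * runif(n_seg, 0.7, 1.3)
  seg_len <- seg_len * (route_length / sum(seg_len))
  turns <- sample(c(-pi / 2, -pi / 4, 0, pi / 4, pi / 2), n_seg - 1,
                  replace = TRUE, prob = c(0.2, 0.2, 0.2, 0.2, 0.2))
  headings <- cumsum(c(0, turns))
  verts <- matrix(0, n_seg + 1, 2)
  for (i in seq_len(n_seg))
    verts[i + 1, ] <- verts[i, ] + seg_len[i] * c(cos(headings[i]), sin(headings[i]))
  cum_len <- c(0, cumsum(seg_len))

  # Zones: one per equal arc-length slot, placed randomly inside its slot so
  # order is ascending and no two zones overlap.
  types <- zone_types()
  ztype <- sample(rep_len(types, n_zones))
  slot <- (route_length - 60) / n_zones
  zlen <- pmin(runif(n_zones, zone_len[1], zone_len[2]), slot * 0.6)
  entry <- 30 + (seq_len(n_zones) - 1) * slot + runif(n_zones, 0, slot - zlen - 1)
  limits <- c(crosswalk = base_limit, school_zone = 20 * .mph,
              construction_zone = 25 * .mph, playground_zone = 20 * .mph,
              banking_curve = base_limit, intersection_stop = base_limit,
              intersection_light = base_limit, rear_end_event = base_limit)
  zones <- data.frame(zone_id = first_zone_id + seq_len(n_zones) - 1L,
                      zone_type = ztype,
                      entry_s = entry,
                      exit_s = entry + zlen,
                      zone_limit = unname(limits[ztype]))
  stopifnot(all(zones$entry_s < zones$exit_s),
            all(diff(zones$entry_s) > 0),
            all(zones$exit_s[-n_zones] <= zones$entry_s[-1]))
  structure(list(environment_id = as.integer(environment_id),
                 route = verts, cum_len = cum_len,
                 route_length = route_length,
                 base_limit = base_limit, zones = zones),
            class = "vdt_environment")
}

#' @export
print.vdt_environment <- function(x, ...) {
  cat(sprintf("<vdt_environment> %d: %.0f m route, %d zones, limit %.1f m/s\n",
              x$environment_id, x$route_length, nrow(x$zones), x$base_limit))
  invisible(x)
}

#' Write / read an environment bank as JSON
#'
#' The JSON lists, per environment, the zone table
#' (`zone_id, zone_type, entry_s, exit_s, zone_limit`) together with the
#' route polyline and limits needed to replay or extend the bank.
#'
#' @param bank list of `vdt_environment`s.
#' @param path JSON file path.
#' @export
write_environments <- function(bank, path) {
  out <- lapply(bank, function(env) {
    list(environment_id = env$environment_id,
         route_length = env$route_length,
         base_limit = env$base_limit,
         route = unname(apply(env$route, 1, function(r) c(r[1], r[2]),
                              simplify = FALSE)),
         zones = env$zones)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_environments
#' @export
read_environments <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyMatrix = TRUE)
  lapply(seq_len(nrow(raw)), function(i) {
    verts <- raw$route[[i]]
    seg <- sqrt(rowSums(diff(verts)^2))
    structure(list(environment_id = as.integer(raw$environment_id[i]),
                   route = verts,
                   cum_len = c(0, cumsum(seg)),
                   route_length = raw$route_length[i],
                   base_limit = raw$base_limit[i],
                   zones = as.data.frame(raw$zones[[i]])),
              class = "vdt_environment")
  })
}

#' Construct a driver profile
#'
#' The latent skill `theta` in \[0,1\] links behavior (archetype selection in
#' every zone) to the on-road-exam outcome; `seed` makes the driver's whole
#' drive reproducible.
#'
#' @param theta skill in \[0,1\] (1 = fully skilled).
#' @param seed integer seed.
#' @export
driver_profile <- function(theta, seed) {
  if (is.na(theta) || theta < 0 || theta > 1) stop("theta must lie in [0,1]")
  structure(list(theta = theta, seed = as.integer(seed)),
            class = "driver_profile")
}

#' Plan a drive: archetype draws and signal decisions
#'
#' Draws, reproducibly from the profile seed, the archetype executed in each
#' zone (risky archetypes more likely as skill decreases), a per-zone
#' duration-jitter factor in U(0.8, 1.25) that stretches or compresses the
#' zone transit (so subinterval lengths differ and warping is exercised),
#' and whether each route bend is signaled.
#'
#' @param env a `vdt_environment`.
#' @param profile a `driver_profile`.
#' @return list with `zone_plan` (data.frame: zone_id, archetype index,
#'   name, weight, jitter), `signals` (logical per route bend), and `theta`.
#' @export
plan_drive <- function(env, profile) {
  lib <- archetype_library()
  set.seed(derive_seed(profile$seed, env$environment_id, 1))
  zones <- env$zones
  n <- nrow(zones)
  arch_idx <- integer(n); arch_name <- character(n)
  weight <- numeric(n); events <- vector("list", n)
  for (i in seq_len(n)) {
    archs <- lib[[zones$zone_type[i]]]
    p <- archetype_probs(archs, profile$theta)
    j <- sample.int(length(archs), 1, prob = p)
    arch_idx[i] <- j
    arch_name[i] <- archs[[j]]$name
    weight[i] <- archs[[j]]$weight
    events[[i]] <- archs[[j]]$events
  }
  jitter <- runif(n, 0.8, 1.25)
  turns <- route_turn_angles(env)
  signals <- runif(length(turns$s)) < clamp(0.15 + 0.8 * profile$theta, 0, 1)
  list(zone_plan = data.frame(zone_id = zones$zone_id, arch_idx = arch_idx,
                              archetype = arch_name, weight = weight,
                              jitter = jitter),
       zone_events = events,
       signals = signals, theta = profile$theta)
}

# Bends of the route polyline: arc-length position and signed turn angle of
# each interior vertex with a non-trivial direction change.
route_turn_angles <- function(env, min_angle = 25 * pi / 180) {
  v <- env$route
  n <- nrow(v)
  if (n < 3) return(list(s = numeric(0), angle = numeric(0)))
  h <- atan2(diff(v[, 2]), diff(v[, 1]))
  ang <- diff(h)
  ang <- atan2(sin(ang), cos(ang))
  keep <- abs(ang) >= min_angle
  list(s = env$cum_len[2:(n - 1)][keep], angle = ang[keep])
}

# Map arc-length positions to (x, y, heading) along the route polyline.
route_point <- function(env, s) {
  s <- clamp(s, 0, env$route_length)
  seg <- findInterval(s, env$cum_len, rightmost.closed = TRUE)
  seg <- clamp(seg, 1, nrow(env$route) - 1)
  p0 <- env$route[seg, , drop = FALSE]
  p1 <- env$route[seg + 1, , drop = FALSE]
  len <- env$cum_len[seg + 1] - env$cum_len[seg]
  f <- (s - env$cum_len[seg]) / pmax(len, 1e-12)
  list(x = p0[, 1] + f * (p1[, 1] - p0[, 1]),
       y = p0[, 2] + f * (p1[, 2] - p0[, 2]),
       heading = atan2(p1[, 2] - p0[, 2], p1[, 1] - p0[, 1]))
}

#' Simulate one assessment drive
#'
#' Produces a ~10 Hz `drive_recording` traversing the full route. Inside each
#' event zone the driver executes the archetype drawn in [plan_drive()]; the
#' vehicle tracks the archetype's target-speed profile (scaled by the zone
#' limit and the duration jitter) under bounded acceleration, and the pedal,
#' steering and lane-offset channels are derived from the resulting dynamics
#' plus Gaussian channel noise. Between zones the driver cruises near the
#' posted limit. Deterministic given `env` + `profile`.
#'
#' @param env a `vdt_environment`.
#' @param profile a `driver_profile`.
#' @param noise_sd channel noise SD as a fraction of each channel's range
#'   (default 0.05).
#' @param dt frame period in s (default 0.1).
#' @param plan optionally a precomputed [plan_drive()] result.
#' @param max_frames hard cap on frame count.
#' @return a `drive_recording` with simulator `events` attached.
#' @export
simulate_drive <- function(env, profile, noise_sd = 0.05, dt = 0.1,
                           plan = NULL, max_frames = 60000L) {
  lib <- archetype_library()
  if (is.null(plan)) plan <- plan_drive(env, profile)
  set.seed(derive_seed(profile$seed, env$environment_id, 2))
  zones <- env$zones
  L <- env$route_length

  # Target-speed profile over a fine arc-length grid (2 m): cruise at the
  # base limit, archetype profile inside zones (speed divided by the jitter
  # factor so transit duration scales by it).
  grid <- seq(0, L, by = 2)
  tv <- rep(env$base_limit, length(grid))
  tv0 <- tv  # nominal (unjittered) profile, drives the pedal channels
  lane_target <- rep(0, length(grid))
  for (i in seq_len(nrow(zones))) {
    arch <- lib[[zones$zone_type[i]]][[plan$zone_plan$arch_idx[i]]]
    inz <- grid >= zones$entry_s[i] & grid < zones$exit_s[i]
    if (!any(inz)) next
    u <- (grid[inz] - zones$entry_s[i]) / (zones$exit_s[i] - zones$entry_s[i])
    znom <- zones$zone_limit[i] * archetype_speed_mult(arch, u)
    ztv <- znom / plan$zone_plan$jitter[i]
    # compliant (zero-infraction) archetypes never exceed the posted zone
    # limit; their duration jitter can therefore only stretch the transit
    if (arch$weight == 0) ztv <- pmin(ztv, zones$zone_limit[i])
    tv[inz] <- pmax(0.25, ztv)
    tv0[inz] <- pmax(0.25, znom)
    lane_target[inz] <- archetype_lane_off(arch, u)
  }
  # approach ramps: drivers adjust to a zone's entry speed over the ~40 m
  # before it, so the speed transition (and its pedal transient) happens
  # outside the zone subinterval rather than inside it
  in_zone <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(zones)))
    in_zone <- in_zone | (grid >= zones$entry_s[i] & grid < zones$exit_s[i])
  for (i in seq_len(nrow(zones))) {
    e_idx <- which(grid >= zones$entry_s[i])[1]
    if (is.na(e_idx) || e_idx < 2) next
    r_idx <- which(grid >= zones$entry_s[i] - 40 & grid < zones$entry_s[i])
    r_idx <- r_idx[!in_zone[r_idx]]
    if (!length(r_idx)) next
    frac <- (grid[r_idx] - (zones$entry_s[i] - 40)) / 40
    tv[r_idx] <- tv[r_idx] + frac * (tv[e_idx] - tv[r_idx])
    tv0[r_idx] <- tv0[r_idx] + frac * (tv0[e_idx] - tv0[r_idx])
  }

  # Integrate longitudinal dynamics: bounded accel/decel toward the (noisy)
  # target; look one grid cell ahead so decelerations begin before the zone.
  n_cap <- min(max_frames, ceiling(L / (0.22 * min(tv)) / dt) + 200L)
  v <- numeric(n_cap); s <- numeric(n_cap)
  # slow AR(1) wander around the target speed: drivers drift over seconds,
  # they do not jitter white at frame rate
  wander <- as.numeric(stats::filter(
    rnorm(n_cap, 0, noise_sd * 0.6 * sqrt(1 - 0.9^2)), 0.9,
    method = "recursive"))
  vmult <- 1 + wander
  vi <- 0; si <- 0; n <- 0L
  a_max <- 3.0; d_max <- 6.0; gstep <- grid[2] - grid[1]
  while (si < L && n < n_cap) {
    n <- n + 1L
    v[n] <- vi; s[n] <- si
    gi <- min(length(tv), 1L + as.integer(si / gstep))
    tgt <- min(tv[gi], tv[min(length(tv), gi + 1L)]) * vmult[n]
    vi <- max(0, vi + clamp(tgt - vi, -d_max * dt, a_max * dt))
    if (vi < 0.05 && tgt > 0.2) vi <- 0.2  # creep out of standstill
    si <- si + vi * dt
  }
  v <- v[seq_len(n)]; s <- s[seq_len(n)]
  t <- (seq_len(n) - 1) * dt

  pt <- route_point(env, s)
  hd_un <- cumsum(c(pt$heading[1], atan2(sin(diff(pt$heading)),
                                         cos(diff(pt$heading)))))
  hd_smooth <- as.numeric(stats::filter(hd_un, rep(1 / 15, 15), sides = 2))
  hd_smooth[is.na(hd_smooth)] <- hd_un[is.na(hd_smooth)]
  steering <- clamp(c(diff(hd_smooth) / dt, 0) / 1.5, -1, 1) +
    rnorm(n, 0, noise_sd * 2 * 0.25)
  steering <- clamp(steering, -1, 1)

  acc <- c(diff(v) / dt, 0)
  # pedals respond to the smoothed acceleration demand (~0.5 s), not to
  # frame-rate fluctuations
  acc_s <- as.numeric(stats::filter(acc, rep(1 / 5, 5), sides = 2))
  acc_s[is.na(acc_s)] <- acc[is.na(acc_s)]
  acc <- acc_s
  brake <- clamp(-acc / d_max, 0, 1)
  brake[acc >= -0.2] <- 0
  # drivers hold the brake when (nearly) stopped rather than coasting
  hold <- v < 2 & acc < 0.5
  brake[hold] <- pmax(brake[hold], 0.45)
  brake <- clamp(brake + abs(rnorm(n, 0, noise_sd * 0.3)), 0, 1)
  # throttle holds the effort the nominal profile demands (duration jitter
  # varies how long a behavior takes, not how hard the pedal is pressed)
  gi0 <- clamp(1L + as.integer(s / gstep), 1L, length(grid))
  throttle <- clamp(0.15 + 0.5 * tv0[gi0] / env$base_limit + acc / a_max, 0, 1)
  throttle[brake > 0.05] <- 0
  throttle <- clamp(throttle + rnorm(n, 0, noise_sd * 0.5), 0, 1)

  gi <- clamp(1L + as.integer(s / gstep), 1L, length(grid))
  lo_in <- 0.08 * lane_target[gi] + rnorm(n, 0, noise_sd * 3.6 * 0.25)
  lane_offset <- as.numeric(stats::filter(lo_in, 0.92, method = "recursive"))

  posted <- rep(env$base_limit, n)
  for (i in seq_len(nrow(zones))) {
    inz <- s >= zones$entry_s[i] & s < zones$exit_s[i]
    posted[inz] <- zones$zone_limit[i]
  }

  turn_signal <- rep("none", n)
  turns <- route_turn_angles(env)
  for (j in seq_along(turns$s)) {
    if (!isTRUE(plan$signals[j])) next
    act <- s >= turns$s[j] - 50 & s <= turns$s[j] + 5
    turn_signal[act] <- if (turns$angle[j] > 0) "left" else "right"
  }

  p_scan <- 0.004 + 0.012 * profile$theta
  scan_left <- runif(n) < p_scan
  scan_right <- runif(n) < p_scan

  events <- list()
  for (i in seq_len(nrow(zones))) {
    evs <- plan$zone_events[[i]]
    if (!length(evs)) next
    mid <- (zones$entry_s[i] + zones$exit_s[i]) / 2
    kk <- which(s >= mid)
    if (!length(kk)) next
    events[[length(events) + 1L]] <-
      data.frame(t = t[kk[1]], s = mid, type = evs,
                 zone_id = zones$zone_id[i])
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(t = numeric(0), s = numeric(0), type = character(0),
               zone_id = integer(0))

  frames <- data.frame(t = t, x = pt$x, y = pt$y,
                       heading = atan2(sin(hd_un), cos(hd_un)),
                       speed = v, brake = brake, throttle = throttle,
                       steering = steering, lane_offset = lane_offset,
                       turn_signal = turn_signal,
                       scan_left = scan_left, scan_right = scan_right,
                       posted_limit = posted)
  new_drive_recording(drive_id = paste0("d", profile$seed),
                      environment_id = env$environment_id,
                      frames = frames, nominal_rate = 1 / dt,
                      events = events)
}

#' Assign an on-road-exam score from a driver profile
#'
#' Outcome model: `score = round(max(0, a * (1 - theta) + b * W + e))` with
#' `e ~ Normal(0, sigma_e)` and `W` the summed infraction weights of the
#' archetypes the driver actually executed, so the outcome couples to
#' behavior through both latent skill and realized infractions. Deterministic
#' given the profile seed. With the defaults and `theta ~ Uniform(0,1)` the
#' failure prevalence (score >= 26) is ~25%.
#'
#' @param profile a `driver_profile`.
#' @param a skill coefficient (default 34 score points).
#' @param b infraction-weight coefficient (default 0.05).
#' @param sigma_e score noise SD (default 8).
#' @param infraction_weight_sum realized `W` (from [plan_drive()]; default 0).
#' @return non-negative integer score.
#' @export
assign_ore_score <- function(profile, a = 34, b = 0.05, sigma_e = 8,
                             infraction_weight_sum = 0) {
  if (sigma_e < 0) stop("sigma_e must be >= 0")
  set.seed(derive_seed(profile$seed, 777))
  e <- rnorm(1, 0, sigma_e)
  as.integer(round(max(0, a * (1 - profile$theta) +
                         b * infraction_weight_sum + e)))
}

#' Generate a synthetic cohort
#'
#' Draws `n` drivers with skill `theta ~ Uniform(0,1)`, assigns each an
#' environment uniformly at random, plans and (optionally) simulates their
#' drives, and scores their on-road exams. Fully reproducible from `seed`.
#'
#' @param n number of drivers.
#' @param env_bank list of `vdt_environment`s.
#' @param seed integer master seed.
#' @param a,b,sigma_e outcome-model parameters (see [assign_ore_score()]).
#' @param noise_sd channel noise (see [simulate_drive()]).
#' @param simulate if `FALSE`, skip frame simulation (plans and scores only),
#'   useful for outcome-model calibration at large n.
#' @return list with `recordings` (list of `drive_recording` or `NULL`),
#'   `cohort` (a [cohort_table()]), `plans`, `profiles`, `env_ids`.
#' @export
generate_cohort <- function(n, env_bank, seed = 1L, a = 34, b = 0.05,
                            sigma_e = 8, noise_sd = 0.05, simulate = TRUE) {
  if (n < 1) stop("n must be >= 1")
  set.seed(derive_seed(seed, 0))
  thetas <- runif(n)
  env_ids <- sample.int(length(env_bank), n, replace = TRUE)
  recordings <- if (simulate) vector("list", n) else NULL
  plans <- vector("list", n)
  scores <- integer(n)
  ids <- sprintf("drv%05d", seq_len(n))
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- driver_profile(thetas[i], derive_seed(seed, i))
    profiles[[i]] <- pr
    env <- env_bank[[env_ids[i]]]
    pl <- plan_drive(env, pr)
    plans[[i]] <- pl
    scores[i] <- assign_ore_score(pr, a = a, b = b, sigma_e = sigma_e,
                                  infraction_weight_sum = sum(pl$zone_plan$weight))
    if (simulate) {
      rec <- simulate_drive(env, pr, noise_sd = noise_sd, plan = pl)
      rec$drive_id <- ids[i]
      recordings[[i]] <- rec
    }
  }
  list(recordings = recordings,
       cohort = cohort_table(ids, scores),
       plans = plans, profiles = profiles, env_ids = env_ids)
}
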