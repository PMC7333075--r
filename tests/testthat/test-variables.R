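test_that("the catalog has 67 stable names and build_variables emits them", {
  cat67 <- variables_catalog()
  expect_length(cat67, 67)
  expect_equal(anyDuplicated(cat67), 0)
  env <- make_straight_env()
  v <- build_variables(make_recording(n = 200), env)
  expect_named(v, cat67)
})

test_that("a constant-speed drive at the posted limit has unit speed ratio
           and zero limit-band percentages", {
  env <- make_straight_env(length = 3000)
  rec <- make_recording(n = 200, speed = 13.4, posted = 13.4)
  v <- build_variables(rec, env)
  expect_equal(unname(v["ratio_mean"]), 1.0)
  expect_equal(unname(v["ratio_max"]), 1.0)
  expect_equal(unname(v[grep("^pct_", names(v))]), rep(0, 6))
  expect_equal(unname(v["frac_stopped"]), 0)
})

test_that("limit-band percentages bin speeding frames correctly", {
  env <- make_straight_env(length = 5000)
  rec <- make_recording(n = 100, speed = 13.4, posted = 13.4)
  # 30% of frames at 12 mph over the limit: counts in >10 only
  over <- 12 * 0.44704
  rec$frames$speed[1:30] <- 13.4 + over
  rec$frames$x <- cumsum(c(0, rec$frames$speed[-100] * 0.1))
  v <- build_variables(rec, env)
  expect_equal(unname(v["pct_above_10mph"]), 30)
  expect_equal(unname(v["pct_above_15mph"]), 0)
  expect_equal(unname(v["pct_above_20mph"]), 0)
  expect_equal(unname(v["pct_below_10mph"]), 0)
})

test_that("global speed statistics obey order constraints", {
  bank <- generate_environment_bank(n_env = 1, total_zones = 6, seed = 13,
                                    route_length = 800)
  rec <- simulate_drive(bank[[1]], driver_profile(0.4, 3))
  v <- build_variables(rec, bank[[1]])
  expect_lte(v[["vel_mean"]], v[["vel_max"]])
  expect_lte(v[["vel_median"]], v[["vel_max"]])
  expect_gte(v[["vel_median"]], min(rec$frames$speed))
  # above- and below-limit bands are mutually exclusive per frame
  expect_lte(v[["pct_above_10mph"]] + v[["pct_below_10mph"]], 100)
})

test_that("unvisited zone types yield missing markers for their six features", {
  zones <- data.frame(zone_id = 1L, zone_type = "school_zone",
                      entry_s = 100, exit_s = 200, zone_limit = 8.9408)
  env <- make_straight_env(length = 1000, zones = zones)
  rec <- make_recording(n = 300, speed = 8)
  v <- build_variables(rec, env)
  expect_false(anyNA(v[grep("^school_zone", names(v))]))
  expect_true(all(is.na(v[grep("^crosswalk", names(v))])))
  expect_true(all(is.na(v[grep("^banking_curve", names(v))])))
})

test_that("a skilled noiseless drive accrues zero infractions", {
  bank <- generate_environment_bank(n_env = 1, total_zones = 8, seed = 5,
                                    route_length = 1200)
  rec <- simulate_drive(bank[[1]], driver_profile(1, 42), noise_sd = 0)
  counts <- count_infractions(rec, bank[[1]])
  expect_equal(unname(counts), rep(0L, 6))
})

test_that("a planted no-yield crosswalk archetype is counted as a
           pedestrian collision and missed yield", {
  zones <- data.frame(zone_id = c(1L, 2L),
                      zone_type = c("crosswalk", "school_zone"),
                      entry_s = c(200, 500), exit_s = c(280, 600),
                      zone_limit = c(13.4, 8.9408))
  env <- make_straight_env(length = 1000, zones = zones)
  plan <- make_forced_plan(env, idx = 1L, overrides = c(`1` = 3L))
  rec <- simulate_drive(env, driver_profile(0.5, 7), noise_sd = 0,
                        plan = plan)
  counts <- count_infractions(rec, env)
  expect_equal(unname(counts["collisions_pedestrian"]), 1L)
  expect_equal(unname(counts["missed_yields"]), 1L)
  expect_equal(unname(counts["collisions_vehicle"]), 0L)
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
})

test_that("stop-sign violations are detected from the speed channel", {
  zones <- data.frame(zone_id = 1L, zone_type = "intersection_stop",
                      entry_s = 300, exit_s = 380, zone_limit = 13.4)
  env <- make_straight_env(length = 800, zones = zones)
  run <- simulate_drive(env, driver_profile(0.5, 8), noise_sd = 0,
                        plan = make_forced_plan(env, idx = 3L))  # no_stop
  stopd <- simulate_drive(env, driver_profile(0.5, 8), noise_sd = 0,
                          plan = make_forced_plan(env, idx = 1L))  # full stop
  expect_equal(unname(count_infractions(run, env)["stop_sign_violations"]), 1L)
  expect_equal(unname(count_infractions(stopd, env)["stop_sign_violations"]), 0L)
})
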