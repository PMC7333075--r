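test_that("environment bank has the expected shape and is reproducible", {
  bank <- generate_environment_bank(seed = 7)
  expect_length(bank, 10)
  counts <- vapply(bank, function(e) nrow(e$zones), 0L)
  expect_true(all(counts %in% c(16L, 17L)))
  expect_equal(sum(counts), 166L)
  ids <- unlist(lapply(bank, function(e) e$zones$zone_id))
  expect_equal(sort(ids), 1:166)
  for (e in bank) {
    z <- e$zones
    expect_true(all(z$entry_s < z$exit_s))
    expect_true(all(z$exit_s[-nrow(z)] <= z$entry_s[-1]))  # non-overlapping
  }
  bank2 <- generate_environment_bank(seed = 7)
  expect_identical(bank, bank2)
  expect_error(generate_environment_bank(n_env = 5, total_zones = 3),
               "total_zones")

  one <- generate_environment_bank(n_env = 1, total_zones = 3, seed = 2,
                                   route_length = 900)
  expect_length(one, 1)
  expect_equal(nrow(one[[1]]$zones), 3L)
})

test_that("environments survive a JSON round trip", {
  bank <- generate_environment_bank(n_env = 2, total_zones = 8, seed = 3,
                                    route_length = 900)
  path <- withr::local_tempfile(fileext = ".json")
  write_environments(bank, path)
  back <- read_environments(path)
  expect_equal(back[[1]]$zones, bank[[1]]$zones, tolerance = 1e-9)
  expect_equal(back[[2]]$route, bank[[2]]$route, tolerance = 1e-9)
  expect_equal(back[[2]]$cum_len, bank[[2]]$cum_len, tolerance = 1e-9)
})

test_that("a fully skilled noiseless driver picks only compliant archetypes
           and respects zone limits", {
  bank <- generate_environment_bank(n_env = 1, total_zones = 8, seed = 5,
                                    route_length = 1200)
  env <- bank[[1]]
  pr <- driver_profile(1, 42)
  plan <- plan_drive(env, pr)
  expect_true(all(plan$zone_plan$weight == 0))
  rec <- simulate_drive(env, pr, noise_sd = 0, plan = plan)
  validate_drive_recording(rec)
  s <- route_progress(env, rec)
  # inside the central portion of each zone the speed stays at or below the
  # posted zone limit (entry frames may still be decelerating)
  for (i in seq_len(nrow(env$zones))) {
    zl <- env$zones$zone_limit[i]
    mid <- s >= env$zones$entry_s[i] + 0.3 * (env$zones$exit_s[i] - env$zones$entry_s[i]) &
      s < env$zones$exit_s[i]
    if (sum(mid) < 2) next
    expect_lte(max(rec$frames$speed[mid]), zl * 1.02)
  }
  expect_equal(nrow(rec$events), 0L)
})

test_that("default drives last roughly eight minutes", {
  bank <- generate_environment_bank(seed = 11)
  durs <- vapply(1:3, function(i) {
    rec <- simulate_drive(bank[[i]], driver_profile(0.3 * i, 100 + i))
    rec$frames$t[nrow(rec$frames)] / 60
  }, 0)
  expect_true(all(durs > 8 * 0.8 & durs < 8 * 1.2))
})

test_that("drives are deterministic given environment, profile and seed", {
  bank <- generate_environment_bank(n_env = 1, total_zones = 8, seed = 5,
                                    route_length = 1000)
  r1 <- simulate_drive(bank[[1]], driver_profile(0.4, 9))
  r2 <- simulate_drive(bank[[1]], driver_profile(0.4, 9))
  expect_identical(r1, r2)
})

test_that("risky-archetype frequency decreases with skill", {
  bank <- generate_environment_bank(n_env = 2, total_zones = 20, seed = 6,
                                    route_length = 1500)
  freq <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(th) {
    draws <- unlist(lapply(1:40, function(i) {
      plan_drive(bank[[1 + i %% 2]], driver_profile(th, 1000 + i))$zone_plan$weight
    }))
    mean(draws > 0)
  }, 0)
  expect_true(all(diff(freq) <= 0.02))  # monotone up to sampling noise
  expect_equal(freq[5], 0)              # theta = 1: never risky
})

test_that("outcome model is deterministic and hits its anchor points", {
  expect_equal(assign_ore_score(driver_profile(1, 1), a = 45, b = 0,
                                sigma_e = 0), 0L)
  expect_equal(assign_ore_score(driver_profile(0, 1), a = 45, b = 0,
                                sigma_e = 0), 45L)
  s1 <- assign_ore_score(driver_profile(0.3, 5))
  s2 <- assign_ore_score(driver_profile(0.3, 5))
  expect_identical(s1, s2)
  expect_gte(s1, 0)
})

test_that("default outcome parameters give ~25% failure prevalence", {
  bank <- generate_environment_bank(seed = 7)
  co <- generate_cohort(4000, bank, seed = 21, simulate = FALSE)
  prev <- 100 * mean(co$cohort$ore_score >= 26)
  expect_gt(prev, 25.4 - 3)
  expect_lt(prev, 25.4 + 3)
})

test_that("cohort generation aligns ids and balances environments", {
  bank <- generate_environment_bank(n_env = 2, total_zones = 6, seed = 8,
                                    route_length = 700)
  co <- generate_cohort(30, bank, seed = 4)
  expect_length(co$recordings, 30)
  expect_equal(nrow(co$cohort), 30)
  expect_equal(vapply(co$recordings, `[[`, "", "drive_id"),
               co$cohort$drive_id)
  co2 <- generate_cohort(30, bank, seed = 4)
  expect_identical(co$cohort, co2$cohort)
  expect_identical(co$recordings[[7]]$frames, co2$recordings[[7]]$frames)

  big <- generate_cohort(4000, generate_environment_bank(seed = 7),
                         seed = 13, simulate = FALSE)
  tab <- tabulate(big$env_ids, 10)
  expect_true(all(abs(tab - 400) < 4.5 * sqrt(4000 * 0.1 * 0.9)))
})
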