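test_that("sampled episode conditions stay within the task bounds", {
  set.seed(42)
  cfg <- env_config()
  n <- 10000
  su <- replicate(n, unlist(sample_episode_setup(cfg)))
  expect_true(all(su["target_final_speed", ] >= 10))
  expect_true(all(su["target_final_speed", ] <= 20))
  expect_true(all(su["agent_init_distance", ] >= 25))
  expect_true(all(su["agent_init_distance", ] <= 30))
  expect_true(all(su["change_onset", ] >= 2.5))
  expect_true(all(su["change_onset", ] <= 3.25))
  expect_true(all(su["target_init_speed", ] %in% c(11.25, 9.47, 8.18)))
  # all three initial speeds actually occur
  expect_length(unique(su["target_init_speed", ]), 3)
  # final speeds genuinely spread over the truncated range
  expect_gt(diff(range(su["target_final_speed", ])), 8)
})

test_that("episode sampling and stepping are deterministic under a seed", {
  set.seed(7)
  a <- sample_episode_setup()
  set.seed(7)
  b <- sample_episode_setup()
  expect_identical(a, b)

  set.seed(7)
  tr1 <- simulate_episode(function(obs, st) floor(st$t * 60) %% 6)
  set.seed(7)
  tr2 <- simulate_episode(function(obs, st) floor(st$t * 60) %% 6)
  expect_identical(tr1, tr2)
})

test_that("invalid configurations and invalid stepping are rejected", {
  expect_error(env_config(dt = 0))
  expect_error(env_config(capture_radius = -1))
  expect_error(env_config(change_onset_range = c(3, 20),
                          max_episode_duration = 15),
               "onset")
  r <- env_reset()
  st <- r$state
  st$terminal <- TRUE
  expect_error(env_step(st, 0L, r$setup), "terminal")
  expect_error(env_step(r$state, 6L, r$setup), "range")
})

test_that("the target speed schedule is piecewise linear with a 500 ms ramp", {
  su <- list(target_init_speed = 11.25, target_final_speed = 11.25,
             change_onset = 2.5, ramp_duration = 0.5)
  expect_equal(target_speed_at(su, c(0, 2, 5)), c(11.25, 11.25, 11.25))
  su2 <- list(target_init_speed = 10, target_final_speed = 20,
              change_onset = 2.5, ramp_duration = 0.5)
  expect_equal(target_speed_at(su2, 2.75), 15.0)
  su3 <- list(target_init_speed = 8.18, target_final_speed = 18,
              change_onset = 3.0, ramp_duration = 0.5)
  expect_equal(target_speed_at(su3, 3.5), 18.0)
  expect_error(target_speed_at(su3, -0.1), "non-negative")
})

test_that("pedal lag follows the printed first-order update", {
  expect_equal(pedal_update(0, 14, 0.017), 0.238)
  expect_equal(pedal_update(9.3, 9.3, 0.5), 9.3)        # fixed point
  expect_equal(pedal_update(10, 2, 0.0085), 9.932)      # K = 0.5 K'
  expect_error(pedal_update(1, 2, 0))
})

test_that("holding one pedal follows the closed-form geometric recursion", {
  cfg <- env_config()
  K <- cfg$lag_base
  set.seed(11)
  tr <- simulate_episode(function(obs, st) 5L, cfg)  # constant pedal 14 m/s
  n <- seq_len(nrow(tr))
  closed_form <- 14 + (1 - K)^n * (0 - 14)
  expect_equal(tr$v_s, closed_form, tolerance = 1e-12)
})

test_that("the target's traveled distance matches the schedule integral", {
  set.seed(3)
  for (i in 1:5) {
    tr <- simulate_episode(function(obs, st) sample.int(6, 1) - 1L)
    su <- attr(tr, "setup")
    t_end <- tr$t[nrow(tr)]
    v0 <- su$target_init_speed; v1 <- su$target_final_speed
    on <- su$change_onset; tau <- su$ramp_duration
    # analytic time-integral of the piecewise-linear schedule
    ramp_end <- min(max(t_end - on, 0), tau)
    dist <- v0 * min(t_end, on) +
      (v0 * ramp_end + (v1 - v0) * ramp_end^2 / (2 * tau)) +
      v1 * max(t_end - on - tau, 0)
    traveled <- su$target_init_distance - tr$x_t[nrow(tr)]
    expect_lt(abs(traveled - dist), (1 / 60) * max(v0, v1))
  }
})

test_that("episode termination matches a brute-force stepping oracle", {
  cfg <- env_config()
  # no-change target, slow agent: the episode ends when the target passes
  su <- list(agent_init_distance = 28, target_init_speed = 11.25,
             target_final_speed = 11.25, change_onset = 3.0,
             ramp_duration = 0.5, target_init_distance = 45)
  set.seed(1)
  tr <- simulate_episode(function(obs, st) 0L, cfg, setup = su)
  expect_identical(tr$outcome[nrow(tr)], "miss")
  expected_steps <- ceiling((45 + cfg$capture_radius) / (11.25 / 60))
  expect_lte(abs(nrow(tr) - expected_steps), 1)
  # a required-speed tracking controller on the same schedule intercepts
  tracker <- function(obs, st) {
    d <- abs(pedal_update(obs[["v_s"]], cfg$pedal_speeds,
                          cfg$lag_base) - required_speed(obs))
    which.min(d) - 1L
  }
  set.seed(1)
  tr2 <- simulate_episode(tracker, cfg, setup = su)
  expect_identical(tr2$outcome[nrow(tr2)], "success")
  expect_lte(abs(tr2$x_t[nrow(tr2)]), cfg$capture_radius)
  expect_lte(abs(tr2$x_s[nrow(tr2)]), cfg$capture_radius)
})

test_that("first-order TTC is distance over speed with an infinite sentinel", {
  expect_equal(first_order_ttc(30, 15), 2.0)
  expect_equal(first_order_ttc(25, 11.25), 25 / 11.25)
  expect_identical(first_order_ttc(5, 0), Inf)
  expect_error(first_order_ttc(-1, 2))
})

test_that("ramp-aware TTC matches closed forms and 60 Hz integration", {
  expect_equal(actual_ttc_from_onset(20, 10, 10, 0.5), 2.0)
  expect_equal(actual_ttc_from_onset(30, 10, 20, 0.5), 1.625)
  expect_equal(actual_ttc_from_onset(5, 10, 20, 0.5), (-1 + sqrt(3)) / 2)

  # brute-force oracle: integrate the ramp at 60 Hz (midpoint rule, so the
  # discretization bias stays well below one step) and find the crossing
  simulate_arrival <- function(x, v0, v1, tau, dt = 1 / 60) {
    t <- 0
    repeat {
      tm <- t + dt / 2
      v <- if (tm < tau) v0 + (v1 - v0) * tm / tau else v1
      t <- t + dt
      x <- x - v * dt
      if (x <= 0) return(t)
    }
  }
  set.seed(99)
  for (i in 1:1000) {
    x <- runif(1, 0.5, 50)
    v0 <- runif(1, 5, 15)
    v1 <- runif(1, 5, 25)
    closed <- actual_ttc_from_onset(x, v0, v1, 0.5)
    expect_lt(abs(closed - simulate_arrival(x, v0, v1, 0.5)), 1 / 60 + 1e-9)
  }
})
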