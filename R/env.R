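#' Interception task configuration
#'
#' Builds the configuration of the 60 Hz locomotor interception task. The
#' agent and the target approach a fixed interception point along straight
#' converging paths. The agent starts from rest between 25 and 30 m from the
#' point and controls its speed through a first-order pedal lag
#' (`delta_v = K * (V_p - v_s)` applied once per step, `K = lag_multiplier *
#' lag_base`). The target starts at one of three initial speeds and, between
#' 2.5 and 3.25 s into the episode, ramps linearly over 500 ms to a final
#' speed drawn from a normal distribution with mean 15 m/s and sd 5 m/s,
#' truncated at one sd.
#'
#' The target's initial distance is not part of the task statistics that
#' define the episode schedule; the default of 45 m puts the target's
#' first-order time-to-contact at 4.0--5.5 s across the three initial speeds
#' so that the speed change falls partway through the approach.
#'
#' @param dt simulation step, seconds (60 Hz default).
#' @param lag_base base pedal lag constant `K'` (dimensionless, per step).
#' @param lag_multiplier multiplier on `K'`; the task is studied at 1.0
#'   (responsive vehicle) and 0.5 (sluggish vehicle).
#' @param pedal_speeds the six selectable pedal speeds, m/s.
#' @param agent_init_distance_range uniform range of the agent's initial
#'   distance to the interception point, m.
#' @param target_init_speeds the three target initial speeds, m/s (sampled
#'   uniformly).
#' @param target_init_distance target initial distance, m.
#' @param change_onset_range uniform range of the speed-change onset, s.
#' @param final_speed_mean,final_speed_sd parameters of the final-speed
#'   distribution, m/s. The draw is truncated at mean +/- 1 sd.
#' @param ramp_duration duration of the linear speed ramp, s.
#' @param capture_radius both the agent and the target must be within this
#'   distance of the interception point simultaneously for a success, m.
#' @param max_episode_duration hard episode cutoff, s.
#' @return a list of class `env_config`.
#' @export
env_config <- function(dt = 1 / 60,
                       lag_base = 0.017,
                       lag_multiplier = 1.0,
                       pedal_speeds = c(2, 4, 8, 10, 12, 14),
                       agent_init_distance_range = c(25, 30),
                       target_init_speeds = c(11.25, 9.47, 8.18),
                       target_init_distance = 45,
                       change_onset_range = c(2.5, 3.25),
                       final_speed_mean = 15,
                       final_speed_sd = 5,
                       ramp_duration = 0.5,
                       capture_radius = 1.0,
                       max_episode_duration = 15) {
  stopifnot(dt > 0, lag_base > 0, lag_multiplier > 0,
            lag_base * lag_multiplier <= 1,
            all(pedal_speeds > 0), !is.unsorted(pedal_speeds),
            length(agent_init_distance_range) == 2,
            diff(agent_init_distance_range) >= 0,
            all(target_init_speeds > 0),
            target_init_distance > 0,
            length(change_onset_range) == 2,
            change_onset_range[1] >= 0,
            diff(change_onset_range) >= 0,
            final_speed_sd > 0, ramp_duration > 0,
            capture_radius > 0, max_episode_duration > 0)
  if (change_onset_range[2] > max_episode_duration)
    stop("change onset range must lie within the episode duration")
  cfg <- list(dt = dt, lag_base = lag_base, lag_multiplier = lag_multiplier,
              pedal_speeds = pedal_speeds,
              agent_init_distance_range = agent_init_distance_range,
              target_init_speeds = target_init_speeds,
              target_init_distance = target_init_distance,
              change_onset_range = change_onset_range,
              final_speed_mean = final_speed_mean,
              final_speed_sd = final_speed_sd,
              ramp_duration = ramp_duration,
              capture_radius = capture_radius,
              max_episode_duration = max_episode_duration)
  class(cfg) <- "env_config"
  cfg
}

outcome_labels <- c("ongoing", "success", "miss")

decode_outcome <- function(code) outcome_labels[code + 1L]
phase_labels <- c("pre_change", "ramping", "post_change")
decode_phase <- function(code) phase_labels[code + 1L]

#' Sample the initial conditions of one episode
#'
#' Draws the agent's initial distance, the target's initial and final speed
#' and the speed-change onset from the task distributions. Uses the R random
#' number stream, so `set.seed()` makes the draw reproducible.
#'
#' @param config an [env_config()].
#' @return a list with fields `agent_init_distance`, `target_init_speed`,
#'   `target_final_speed`, `change_onset`, `ramp_duration`,
#'   `target_init_distance`.
#' @export
sample_episode_setup <- function(config = env_config()) {
  stopifnot(inherits(config, "env_config"))
  cpp_sample_setup(unclass(config))
}

#' Start an episode
#'
#' @param config an [env_config()].
#' @return a list with the initial `state`, the initial `observation`
#'   (named vector `x_t, v_t, x_s, v_s`: target distance, target speed,
#'   agent distance, agent speed) and the sampled episode `setup`.
#' @export
env_reset <- function(config = env_config()) {
  stopifnot(inherits(config, "env_config"))
  out <- cpp_env_reset(unclass(config))
  out$state$outcome <- decode_outcome(out$state$outcome)
  out$state$phase <- decode_phase(out$state$phase)
  out
}

#' Advance the episode by one 60 Hz step
#'
#' Applies the pedal lag (`v_s <- v_s + K (V_p - v_s)`), moves both bodies by
#' their updated speed times `dt`, evaluates the target speed schedule, and
#' checks the outcome: a success when agent and target are simultaneously
#' within `capture_radius` of the interception point, a miss when the target
#' has passed beyond the radius or the episode exceeds its maximum duration.
#'
#' @param state the current environment state (from [env_reset()] or a
#'   previous step).
#' @param action pedal index, an integer in `0:5` selecting
#'   `config$pedal_speeds[action + 1]`.
#' @param setup the episode setup returned by [env_reset()].
#' @param config the [env_config()].
#' @return list with the new `state`, `observation`, `reward_fields`
#'   (outcome bookkeeping for reward functions), `terminal` and `outcome`.
#' @export
env_step <- function(state, action, setup, config = env_config()) {
  stopifnot(inherits(config, "env_config"))
  if (is.character(state$outcome))
    state$outcome <- match(state$outcome, outcome_labels) - 1L
  if (is.character(state$phase))
    state$phase <- match(state$phase, phase_labels) - 1L
  out <- cpp_env_step(state, as.integer(action), setup, unclass(config))
  out$outcome <- decode_outcome(out$outcome)
  out$state$outcome <- out$outcome
  out$state$phase <- decode_phase(out$state$phase)
  out$reward_fields <- list(success = identical(out$outcome, "success"),
                            terminal = out$terminal)
  out
}

#' Target speed at a given episode time
#'
#' Piecewise-linear speed schedule: the initial speed before the onset, a
#' linear ramp of `ramp_duration` seconds, the final speed afterwards.
#'
#' @param setup an episode setup (see [sample_episode_setup()]).
#' @param t time since episode start, seconds (vectorized).
#' @return target speed in m/s.
#' @export
target_speed_at <- function(setup, t) {
  if (any(t < 0)) stop("t must be non-negative")
  v0 <- setup$target_init_speed
  v1 <- setup$target_final_speed
  on <- setup$change_onset
  tau <- setup$ramp_duration
  frac <- pmin(pmax((t - on) / tau, 0), 1)
  v0 + (v1 - v0) * frac
}

#' First-order pedal lag update
#'
#' One step of the speed dynamics: `v_s + K * (V_p - v_s)`.
#'
#' @param v_s current agent speed, m/s.
#' @param pedal_speed selected pedal speed `V_p`, m/s.
#' @param K lag coefficient in `(0, 1]`.
#' @return the updated agent speed.
#' @export
pedal_update <- function(v_s, pedal_speed, K) {
  stopifnot(K > 0, K <= 1)
  v_s + K * (pedal_speed - v_s)
}

#' First-order time-to-contact
#'
#' Distance over current speed, assuming the speed stays constant. A
#' stationary object gets an infinite TTC.
#'
#' @param distance distance to the interception point, m (non-negative).
#' @param speed current speed, m/s (non-negative).
#' @return TTC in seconds (`Inf` where `speed == 0`).
#' @export
first_order_ttc <- function(distance, speed) {
  if (any(distance < 0) || any(speed < 0))
    stop("distance and speed must be non-negative")
  ifelse(speed > 0, distance / speed, Inf)
}

#' Time-to-contact through the linear speed ramp
#'
#' Arrival time of a body at distance `x` whose speed ramps linearly from
#' `v0` to `v1` over `tau` seconds starting now. If the ramp itself covers
#' the distance, the quadratic `v0 t + (v1 - v0) t^2 / (2 tau) = x` is
#' solved on `[0, tau]`; otherwise the residual distance is covered at `v1`.
#'
#' @param x distance, m (non-negative).
#' @param v0 speed at the start of the ramp, m/s (positive).
#' @param v1 speed at the end of the ramp, m/s (positive).
#' @param tau ramp duration, s (positive).
#' @return arrival time in seconds.
#' @export
actual_ttc_from_onset <- function(x, v0, v1, tau) {
  stopifnot(all(x >= 0), all(v0 > 0), all(v1 > 0), all(tau > 0))
  n <- max(length(x), length(v0), length(v1), length(tau))
  x <- rep_len(x, n); v0 <- rep_len(v0, n)
  v1 <- rep_len(v1, n); tau <- rep_len(tau, n)
  ramp_dist <- (v0 + v1) * tau / 2
  out <- numeric(n)
  inside <- x <= ramp_dist
  # within the ramp: solve a t^2 + v0 t - x = 0, a = (v1 - v0) / (2 tau)
  a <- (v1 - v0) / (2 * tau)
  for (i in which(inside)) {
    if (abs(a[i]) < 1e-12) {
      out[i] <- x[i] / v0[i]
    } else {
      disc <- v0[i]^2 + 4 * a[i] * x[i]
      if (disc < 0) stop("no real arrival time on the ramp")  # cannot occur
      out[i] <- (-v0[i] + sqrt(disc)) / (2 * a[i])
    }
  }
  out[!inside] <- tau[!inside] + (x[!inside] - ramp_dist[!inside]) / v1[!inside]
  out
}

#' Simulate a full episode under a policy function
#'
#' Convenience driver over [env_reset()]/[env_step()] used for inspection
#' and testing. The policy is an R function `function(observation, state)`
#' returning a pedal index in `0:5`.
#'
#' @param policy policy function (default: always the fastest pedal).
#' @param config an [env_config()].
#' @param setup optional episode setup; sampled if `NULL`.
#' @param max_steps safety cap on the number of steps.
#' @return a data.frame trace with columns `t, x_t, v_t, x_s, v_s, action,
#'   phase, outcome`, one row per step, plus the `setup` as an attribute.
#' @export
simulate_episode <- function(policy = function(obs, state) 5L,
                             config = env_config(), setup = NULL,
                             max_steps = 5000L) {
  r <- env_reset(config)
  if (!is.null(setup)) {
    r$setup <- setup
    r$state$x_t <- setup$target_init_distance
    r$state$v_t <- setup$target_init_speed
    r$state$x_s <- setup$agent_init_distance
  }
  st <- r$state
  rows <- vector("list", max_steps)
  i <- 0L
  while (!st$terminal && i < max_steps) {
    a <- policy(c(x_t = st$x_t, v_t = st$v_t, x_s = st$x_s, v_s = st$v_s), st)
    out <- env_step(st, a, r$setup, config)
    st <- out$state
    i <- i + 1L
    rows[[i]] <- data.frame(t = st$t, x_t = st$x_t, v_t = st$v_t,
                            x_s = st$x_s, v_s = st$v_s, action = a,
                            phase = st$phase, outcome = st$outcome)
  }
  trace <- do.call(rbind, rows[seq_len(i)])
  attr(trace, "setup") <- r$setup
  trace
}
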