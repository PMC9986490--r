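#' Prior preference configuration
#'
#' The prior mapping function collapses the 4-D observation to a single
#' variable, the *speed difference*: the agent's speed minus the speed it
#' would need to arrive at the interception point exactly when the target
#' does under a constant-speed (first-order) extrapolation of the target.
#' The prior preference is a Gaussian over this variable centred at zero:
#' the agent prefers outcomes in which its speed matches the first-order
#' requirement. The instrumental reward is the log-density of the realized
#' speed difference under that prior.
#'
#' The *speed* placed in prior space is configurable. With
#' `speed_source = "pedal"` (the default) an action is represented by its
#' pedal speed — the speed the agent is steering toward — so the six
#' actions spread across the prior axis at their pedal positions and their
#' instrumental values are well separated. With `speed_source = "realized"`
#' the realized (lagged) post-action speed is used instead; one lag step
#' moves the speed by at most `K * 12 = 0.2` m/s, so per-action contrasts
#' are tiny and the mapping describes the state more than the action.
#'
#' @param prior_sd width of the preference distribution, m/s.
#' @param drop_constant drop the Gaussian log-normalizer so the reward is
#'   `-d^2 / (2 prior_sd^2)`, maximal at 0.
#' @param instrumental_scale multiplier on the instrumental reward.
#' @param max_abs_diff clamp on `|speed difference|`, m/s. The required
#'   speed `x_s * v_t / x_t` diverges as the target closes on the
#'   interception point; the clamp keeps the reward bounded below at
#'   `-instrumental_scale * max_abs_diff^2 / (2 prior_sd^2)`.
#' @param speed_source `"pedal"` or `"realized"` (see Details).
#' @return a list of class `prior_config`.
#' @export
prior_config <- function(prior_sd = 1.0, drop_constant = TRUE,
                         instrumental_scale = 1.0, max_abs_diff = 8,
                         speed_source = c("pedal", "realized")) {
  stopifnot(prior_sd > 0, instrumental_scale > 0, max_abs_diff > 0)
  structure(list(prior_sd = prior_sd, drop_constant = drop_constant,
                 instrumental_scale = instrumental_scale,
                 max_abs_diff = max_abs_diff,
                 speed_source = match.arg(speed_source)),
            class = "prior_config")
}

obs_field <- function(obs, name) {
  idx <- c(x_t = 1L, v_t = 2L, x_s = 3L, v_s = 4L)[[name]]
  if (!is.null(names(obs)) && name %in% names(obs)) unname(obs[[name]])
  else unname(obs[[idx]])
}

#' Required speed for first-order interception
#'
#' The agent's distance divided by the target's first-order time-to-contact:
#' `x_s / (x_t / v_t) = x_s * v_t / x_t`. Moving at exactly this speed, the
#' agent arrives at the interception point at the same moment as a target
#' that keeps its current speed.
#'
#' @param obs observation vector `c(x_t, v_t, x_s, v_s)` (names optional).
#' @return required speed in m/s.
#' @export
required_speed <- function(obs) {
  x_t <- obs_field(obs, "x_t"); v_t <- obs_field(obs, "v_t")
  x_s <- obs_field(obs, "x_s")
  if (v_t <= 0) stop("target speed must be positive")
  if (x_t == 0) return(NaN)  # degenerate: target already at the point
  x_s * v_t / x_t
}

#' Speed difference in prior space
#'
#' `agent_speed - required_speed(obs)`; positive when the agent moves faster
#' than the first-order requirement.
#'
#' @param agent_speed agent speed, m/s.
#' @param obs observation vector (see [required_speed()]).
#' @return signed speed difference, m/s.
#' @export
speed_difference <- function(agent_speed, obs) {
  agent_speed - required_speed(obs)
}

#' Instrumental reward of a realized observation
#'
#' Log-likelihood of the post-action speed difference under the prior
#' preference: with the log-normalizer dropped,
#' `-scale * d^2 / (2 * prior_sd^2)` where
#' `d = speed_difference(agent_speed, obs_next)` clamped at `max_abs_diff`.
#' Non-positive, zero exactly at the preferred outcome `d = 0`. By default
#' `agent_speed` is the realized speed carried in the observation; the
#' training loop passes the selected pedal speed when the prior is
#' configured with `speed_source = "pedal"`.
#'
#' @param obs_next the observation realized after the action.
#' @param config a [prior_config()].
#' @param agent_speed the speed placed in prior space; defaults to the
#'   `v_s` field of `obs_next`.
#' @return the instrumental reward (scalar).
#' @export
instrumental_reward <- function(obs_next, config = prior_config(),
                                agent_speed = NULL) {
  stopifnot(inherits(config, "prior_config"))
  if (is.null(agent_speed)) agent_speed <- obs_field(obs_next, "v_s")
  d <- speed_difference(agent_speed, obs_next)
  d <- max(min(d, config$max_abs_diff), -config$max_abs_diff)
  out <- -config$instrumental_scale * d^2 / (2 * config$prior_sd^2)
  if (!config$drop_constant)
    out <- out - config$instrumental_scale * log(config$prior_sd * sqrt(2 * pi))
  out
}

#' Instrumental value of each candidate action
#'
#' Evaluates the instrumental reward every action would earn at the
#' current observation: with `speed_source = "pedal"` each action sits in
#' prior space at its pedal speed; with `"realized"` each action is placed
#' at the speed one pedal-lag step would produce. Used for inspecting the
#' prior space, not in the training loop (the trained G-values subsume it).
#'
#' @param obs current observation `c(x_t, v_t, x_s, v_s)`.
#' @param pedal_speeds the selectable pedal speeds, m/s.
#' @param K pedal lag coefficient (used only for `"realized"`).
#' @param config a [prior_config()].
#' @return named numeric vector of instrumental values, one per action
#'   (names are the pedal speeds).
#' @export
prior_over_actions <- function(obs, pedal_speeds = c(2, 4, 8, 10, 12, 14),
                               K = 0.017, config = prior_config()) {
  v_s <- obs_field(obs, "v_s")
  vals <- vapply(pedal_speeds, function(vp) {
    v_cand <- if (identical(config$speed_source, "pedal")) vp
              else pedal_update(v_s, vp, K)
    instrumental_reward(obs, config, agent_speed = v_cand)
  }, numeric(1))
  names(vals) <- pedal_speeds
  vals
}
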