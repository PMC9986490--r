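`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one trial: a sequence of training (or evaluation) episodes
#'
#' Runs the agent through `n_episodes` sequential episodes of the
#' interception task. During training every transition is stored in the
#' replay buffer and one gradient step is taken per environment step once
#' the warm-up fill is reached. The per-step reward depends on the agent
#' kind: instrumental + weighted epistemic for the active inference agents,
#' the sparse terminal reward for the DQN baseline (which also follows its
#' epsilon-decay schedule). With `train = FALSE` the greedy policy is run
#' without storing or updating.
#'
#' @param agent a [g_agent()] (see [build_agent()]).
#' @param env an [env_config()].
#' @param n_episodes number of episodes.
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first so the whole trial is reproducible.
#' @param train learn online (`TRUE`) or evaluate frozen (`FALSE`).
#' @param prior a [prior_config()] for the instrumental reward.
#' @param record_transitions record the full transition log of this many
#'   initial episodes (attached as attribute `"transitions"`).
#' @return a data.frame with one row per episode: outcome and success flag,
#'   step count, episode return, mean instrumental and epistemic reward,
#'   epsilon, the episode setup (initial distance, initial/final target
#'   speed, onset), the state at speed-change onset, and the
#'   time-to-contact triplet at onset (`agent_ttc`, `target_fo_ttc`,
#'   `target_actual_ttc`).
#' @export
run_trial <- function(agent, env = env_config(), n_episodes = 3000,
                      seed = NULL, train = TRUE, prior = prior_config(),
                      record_transitions = 0) {
  stopifnot(inherits(agent, "g_agent"), inherits(env, "env_config"),
            n_episodes >= 0)
  if (!is.null(seed)) set.seed(seed)
  kind <- agent$kind %||% "aif_full"
  if (!train) {
    eps_s <- 0; eps_e <- 0; dec <- 0L
  } else if (kind == "dqn_sparse") {
    eps_s <- agent$epsilon_start %||% 1.0
    eps_e <- agent$epsilon_end %||% 0.05
    dec <- agent$epsilon_decay_episodes %||% 500L
  } else {
    eps_s <- agent$config$epsilon
    eps_e <- agent$config$epsilon
    dec <- 0L
  }
  run <- list(reward_mode = if (kind == "dqn_sparse") 1L else 0L,
              epistemic_weight = agent$config$epistemic_weight,
              prior_sd = prior$prior_sd,
              instrumental_scale = prior$instrumental_scale,
              max_abs_diff = prior$max_abs_diff,
              speed_source_pedal = identical(prior$speed_source, "pedal"),
              sparse_reward_success = agent$sparse_reward_success %||% 1.0,
              sparse_reward_miss = agent$sparse_reward_miss %||% 0.0,
              epsilon_start = eps_s, epsilon_end = eps_e,
              epsilon_decay_episodes = as.integer(dec),
              train = isTRUE(train), warmup = agent$config$warmup,
              update_every = agent$config$update_every,
              record_transitions = as.integer(record_transitions))
  res <- cpp_run_trial(agent$ptr, unclass(env), as.integer(n_episodes), run)
  tr <- res$transitions
  res$transitions <- NULL
  log <- as.data.frame(res)
  if (n_episodes > 0) {
    log$episode <- seq_len(n_episodes)
    log$outcome <- decode_outcome(log$outcome)
    log$success <- log$success > 0
    ttc <- onset_ttc_triplet(log, env)
    log$agent_ttc <- ttc$agent_ttc
    log$target_fo_ttc <- ttc$target_fo_ttc
    log$target_actual_ttc <- ttc$target_actual_ttc
    log$kind <- kind
    log$gamma <- agent$config$gamma
    log$lag_multiplier <- env$lag_multiplier
  }
  if (!is.null(tr)) attr(log, "transitions") <- tr
  attr(log, "env_config") <- env
  log
}

# vectorized TTC triplet from the logged onset states
onset_ttc_triplet <- function(log, env) {
  agent_ttc <- ifelse(log$onset_v_s > 0, log$onset_x_s / log$onset_v_s, Inf)
  target_fo <- log$onset_x_t / log$target_init_speed
  ok <- !is.na(log$onset_x_t)
  actual <- rep(NA_real_, nrow(log))
  if (any(ok))
    actual[ok] <- actual_ttc_from_onset(pmax(log$onset_x_t[ok], 0),
                                        log$target_init_speed[ok],
                                        log$target_final_speed[ok],
                                        env$ramp_duration)
  list(agent_ttc = agent_ttc, target_fo_ttc = target_fo,
       target_actual_ttc = actual)
}

#' Train a fresh agent for one trial
#'
#' Convenience wrapper: seeds the random stream, initializes an agent of
#' the requested kind and runs [run_trial()]. Identical seeds give
#' identical trials, including weight initialization.
#'
#' @param kind `"aif_full"`, `"aif_instrumental_only"` or `"dqn_sparse"`.
#' @param n_episodes episodes in the trial.
#' @param seed integer seed.
#' @param gamma discount factor (ignored if `agent` is supplied).
#' @param lag_multiplier pedal-lag multiplier (ignored if `env` supplied).
#' @param env optional [env_config()].
#' @param agent optional [agent_config()].
#' @param prior a [prior_config()].
#' @param record_transitions see [run_trial()].
#' @return list with the trained `agent` and the trial `log`.
#' @export
train_trial <- function(kind = c("aif_full", "aif_instrumental_only",
                                 "dqn_sparse"),
                        n_episodes = 3000, seed = 1, gamma = 0.99,
                        lag_multiplier = 1.0, env = NULL, agent = NULL,
                        prior = prior_config(), record_transitions = 0) {
  kind <- match.arg(kind)
  if (is.null(env)) env <- env_config(lag_multiplier = lag_multiplier)
  if (is.null(agent)) agent <- agent_config(gamma = gamma)
  set.seed(seed)
  spec <- switch(kind,
    aif_full = agent,
    aif_instrumental_only = baseline_config("aif_instrumental_only",
                                            agent = agent),
    dqn_sparse = baseline_config("dqn_sparse", agent = agent))
  ag <- build_agent(spec)
  log <- run_trial(ag, env, n_episodes, seed = NULL, train = TRUE,
                   prior = prior, record_transitions = record_transitions)
  if (nrow(log) > 0) log$seed <- seed
  list(agent = ag, log = log)
}

#' Evaluate a trained agent with a frozen greedy policy
#'
#' @param agent a trained [g_agent()].
#' @param env an [env_config()].
#' @param n_episodes fresh evaluation episodes.
#' @param seed optional seed for the evaluation episode stream.
#' @param prior a [prior_config()] (rewards are still logged).
#' @return an episode log as in [run_trial()].
#' @export
evaluate_agent <- function(agent, env = env_config(), n_episodes = 200,
                           seed = NULL, prior = prior_config()) {
  run_trial(agent, env, n_episodes, seed = seed, train = FALSE,
            prior = prior)
}

#' Trailing moving average
#'
#' Average over the trailing `window` values; the leading edge averages
#' over the available prefix.
#'
#' @param series numeric vector.
#' @param window window length (>= 1).
#' @return vector of the same length.
#' @export
windowed_average <- function(series, window) {
  if (length(series) == 0) stop("empty series")
  stopifnot(window >= 1)
  n <- length(series)
  cs <- cumsum(series)
  i <- seq_len(n)
  lag <- pmax(i - window, 0)
  (cs - c(0, cs)[lag + 1]) / (i - lag)
}

#' Success rate over the final episodes of a trial
#'
#' @param log a trial log from [run_trial()].
#' @param last_n number of final episodes to average over (defaults to the
#'   whole log).
#' @return fraction of successes.
#' @export
success_rate <- function(log, last_n = nrow(log)) {
  stopifnot(last_n >= 0, last_n <= nrow(log))
  if (last_n == 0) return(NaN)
  mean(utils::tail(log$success, last_n))
}

#' Time-to-contact triplet at speed-change onset
#'
#' From an episode trace, reads the state at the first step at or after the
#' target's speed-change onset and computes: the agent's first-order TTC
#' (`x_s / v_s`, infinite if the agent is stationary), the target's
#' first-order TTC using the pre-change speed (`x_t / v0`), and the
#' target's actual TTC accounting for the realized ramp
#' ([actual_ttc_from_onset()]).
#'
#' @param trace an episode trace from [simulate_episode()] (columns `t,
#'   x_t, v_t, x_s, v_s`).
#' @param setup the episode setup.
#' @return named list `agent_ttc`, `target_fo_ttc`, `target_actual_ttc`.
#' @export
ttc_at_onset <- function(trace, setup) {
  i <- which(trace$t >= setup$change_onset)[1]
  if (is.na(i)) stop("trace ends before the speed-change onset")
  row <- trace[i, ]
  list(agent_ttc = if (row$v_s > 0) row$x_s / row$v_s else Inf,
       target_fo_ttc = row$x_t / setup$target_init_speed,
       target_actual_ttc = actual_ttc_from_onset(
         max(row$x_t, 0), setup$target_init_speed,
         setup$target_final_speed, setup$ramp_duration))
}

#' Summarize onset TTC distributions by target initial speed
#'
#' Computes, per target-initial-speed group and per TTC type, the boxplot
#' statistics (median, quartiles, Tukey whiskers at 1.5 IQR) over the
#' post-convergence episodes of a trial, plus the *anticipation index*: the
#' position of the agent's median TTC on the segment from the target's
#' first-order median (0, purely reactive) to the target's actual median
#' (1, fully anticipatory).
#'
#' @param log a trial log from [run_trial()], or several row-bound logs.
#' @param cutoff_episode only episodes after this index enter the summary
#'   (training stabilizes well before the default).
#' @param min_group groups with fewer episodes are dropped with a warning.
#' @return a data.frame with one row per group: the group's initial speed,
#'   episode count, `<type>_median`, `<type>_q1`, `<type>_q3`, `<type>_lo`,
#'   `<type>_hi` for types `agent`, `fo`, `actual`, and
#'   `anticipation_index`.
#' @export
summarize_ttc <- function(log, cutoff_episode = 1500, min_group = 5) {
  keep <- log$episode > cutoff_episode & is.finite(log$agent_ttc) &
    !is.na(log$target_actual_ttc)
  d <- log[keep, ]
  if (nrow(d) == 0) stop("no usable episodes after the cutoff")
  groups <- sort(unique(d$target_init_speed), decreasing = TRUE)
  rows <- list()
  for (g in groups) {
    dg <- d[d$target_init_speed == g, ]
    if (nrow(dg) < min_group) {
      warning(sprintf("dropping group v0 = %.2f (only %d episodes)",
                      g, nrow(dg)))
      next
    }
    box <- function(x, prefix) {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      lo <- min(x[x >= q[1] - 1.5 * iqr])
      hi <- max(x[x <= q[3] + 1.5 * iqr])
      stats::setNames(c(q[2], q[1], q[3], lo, hi),
                      paste0(prefix, c("_median", "_q1", "_q3", "_lo", "_hi")))
    }
    st <- c(box(dg$agent_ttc, "agent"), box(dg$target_fo_ttc, "fo"),
            box(dg$target_actual_ttc, "actual"))
    denom <- st[["fo_median"]] - st[["actual_median"]]
    idx <- if (abs(denom) < 1e-12) NA_real_
           else (st[["fo_median"]] - st[["agent_median"]]) / denom
    rows[[length(rows) + 1L]] <-
      data.frame(target_init_speed = g, n = nrow(dg), t(st),
                 anticipation_index = idx)
  }
  do.call(rbind, rows)
}

#' Overall anticipation index
#'
#' Mean of the per-group anticipation indices of [summarize_ttc()]:
#' 0 for a purely reactive agent (its onset TTC matches the target's
#' first-order TTC), 1 for a fully anticipatory one (matching the target's
#' actual TTC under the realized speed ramp).
#'
#' @param x a trial log or the output of [summarize_ttc()].
#' @param ... passed to [summarize_ttc()] when `x` is a log.
#' @return scalar index.
#' @export
anticipation_index <- function(x, ...) {
  if (!"anticipation_index" %in% names(x)) x <- summarize_ttc(x, ...)
  mean(x$anticipation_index, na.rm = TRUE)
}

#' Run a grid of conditions
#'
#' Trains `n_trials` independently seeded agents for every combination of
#' discount factor, pedal-lag multiplier and agent kind, and tabulates the
#' final-window training success rate, a frozen greedy-policy evaluation,
#' and the anticipation index.
#'
#' @param gammas discount factors to sweep.
#' @param lag_multipliers pedal-lag multipliers to sweep.
#' @param kinds agent kinds to sweep.
#' @param n_trials trials per condition.
#' @param n_episodes episodes per trial.
#' @param window final-window length for the training success rate.
#' @param eval_episodes frozen-policy evaluation episodes (0 to skip).
#' @param master_seed base seed; trial `i` in every condition uses
#'   `master_seed + i - 1` (paired across conditions).
#' @param trial_seeds optional explicit per-trial seeds (must be unique).
#' @param cutoff_episode passed to [summarize_ttc()].
#' @param agent base [agent_config()] (gamma is overridden per condition).
#' @return a data.frame with one row per condition: mean and sd of the
#'   final-window and evaluation success rates across trials, and the mean
#'   anticipation index.
#' @export
run_grid <- function(gammas = c(0, 0.99), lag_multipliers = c(1.0, 0.5),
                     kinds = "aif_full", n_trials = 2, n_episodes = 3000,
                     window = 100, eval_episodes = 200, master_seed = 1,
                     trial_seeds = NULL, cutoff_episode = 1500,
                     agent = agent_config()) {
  if (is.null(trial_seeds))
    trial_seeds <- master_seed + seq_len(n_trials) - 1
  if (anyDuplicated(trial_seeds))
    stop("duplicate seeds across trials")
  stopifnot(length(trial_seeds) == n_trials, window <= n_episodes)
  grid <- expand.grid(kind = kinds, gamma = gammas,
                      lag_multiplier = lag_multipliers,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    acfg <- agent
    acfg$gamma <- g$gamma
    final_sr <- eval_sr <- aidx <- numeric(n_trials)
    for (k in seq_len(n_trials)) {
      tr <- train_trial(g$kind, n_episodes = n_episodes,
                        seed = trial_seeds[k], lag_multiplier = g$lag_multiplier,
                        agent = acfg)
      final_sr[k] <- success_rate(tr$log, min(window, n_episodes))
      eval_sr[k] <- if (eval_episodes > 0)
        success_rate(evaluate_agent(tr$agent, attr(tr$log, "env_config"),
                                    eval_episodes)) else NA_real_
      aidx[k] <- tryCatch(anticipation_index(tr$log,
                                             cutoff_episode = cutoff_episode),
                          error = function(e) NA_real_)
    }
    out[[i]] <- data.frame(
      kind = g$kind, gamma = g$gamma, lag_multiplier = g$lag_multiplier,
      n_trials = n_trials, n_episodes = n_episodes,
      success_mean = mean(final_sr), success_sd = stats::sd(final_sr),
      eval_mean = mean(eval_sr), eval_sd = stats::sd(eval_sr),
      anticipation_index = mean(aidx, na.rm = TRUE))
  }
  do.call(rbind, out)
}
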