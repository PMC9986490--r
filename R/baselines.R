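#' Baseline agent configuration
#'
#' The two comparison agents share the joint-model machinery with the full
#' active inference agent:
#'
#' * `"dqn_sparse"` — a deep Q-network trained on the sparse terminal
#'   reward (success/miss) with epsilon-greedy exploration; the
#'   observation head's loss weight is set to 0 so only the action-value
#'   head learns.
#' * `"aif_instrumental_only"` — the active inference agent with the
#'   epistemic reward switched off (`epistemic_weight = 0`); every other
#'   code path is identical to the full agent.
#'
#' @param kind one of `"dqn_sparse"`, `"aif_instrumental_only"`.
#' @param epsilon_start,epsilon_end,epsilon_decay_episodes linear
#'   exploration schedule (DQN only): `epsilon` decays from start to end
#'   over the given number of episodes and stays constant after.
#' @param sparse_reward_success,sparse_reward_miss terminal rewards (DQN
#'   only). With the defaults 1/0 the episode return equals the success
#'   indicator, so windowed mean reward is a windowed success rate.
#' @param agent an [agent_config()] supplying the shared hyperparameters.
#' @return a list of class `baseline_config`.
#' @export
baseline_config <- function(kind = c("dqn_sparse", "aif_instrumental_only"),
                            epsilon_start = 1.0, epsilon_end = 0.05,
                            epsilon_decay_episodes = 500L,
                            sparse_reward_success = 1.0,
                            sparse_reward_miss = 0.0,
                            agent = agent_config()) {
  kind <- match.arg(kind)
  stopifnot(epsilon_start >= epsilon_end, epsilon_end >= 0,
            epsilon_start <= 1, epsilon_decay_episodes >= 0)
  structure(list(kind = kind, epsilon_start = epsilon_start,
                 epsilon_end = epsilon_end,
                 epsilon_decay_episodes = as.integer(epsilon_decay_episodes),
                 sparse_reward_success = sparse_reward_success,
                 sparse_reward_miss = sparse_reward_miss,
                 agent = agent),
            class = "baseline_config")
}

#' Sparse terminal reward
#'
#' The reward signal the DQN baseline learns from: a fixed value at episode
#' end depending on the outcome, zero everywhere else. Calling it on an
#' ongoing outcome is an error; non-terminal steps are zero by definition.
#'
#' @param outcome `"success"` or `"miss"`.
#' @param success_value,miss_value terminal reward values.
#' @return scalar reward.
#' @export
sparse_reward <- function(outcome, success_value = 1.0, miss_value = 0.0) {
  if (identical(outcome, "ongoing"))
    stop("sparse reward is only defined at episode end")
  if (!outcome %in% c("success", "miss")) stop("unknown outcome")
  if (identical(outcome, "success")) success_value else miss_value
}

#' Linear epsilon-decay schedule
#'
#' @param episode_index 0-based episode index (vectorized).
#' @param config a [baseline_config()], or any list with fields
#'   `epsilon_start`, `epsilon_end`, `epsilon_decay_episodes`.
#' @return epsilon in `[0, 1]`.
#' @export
epsilon_schedule <- function(episode_index, config) {
  stopifnot(all(episode_index >= 0))
  n <- config$epsilon_decay_episodes
  if (n <= 0) return(rep(config$epsilon_end, length(episode_index)))
  frac <- pmin(episode_index / n, 1)
  config$epsilon_start + (config$epsilon_end - config$epsilon_start) * frac
}

#' Build an agent from a baseline (or full) specification
#'
#' `"aif_full"` builds the complete active inference agent; the baseline
#' kinds modify only the reward wiring: the instrumental-only ablation sets
#' `epistemic_weight = 0`, the DQN disables the observation head and will be
#' trained on the sparse reward with its epsilon schedule by [run_trial()].
#'
#' @param config a [baseline_config()], or an [agent_config()] for the full
#'   agent.
#' @param params optional explicit initial weights.
#' @return a [g_agent()] whose `kind` field records the variant.
#' @export
build_agent <- function(config, params = NULL) {
  if (inherits(config, "agent_config")) {
    ag <- g_agent(config, params)
    ag$kind <- "aif_full"
    return(ag)
  }
  stopifnot(inherits(config, "baseline_config"))
  acfg <- config$agent
  if (config$kind == "aif_instrumental_only") {
    acfg$epistemic_weight <- 0
    ag <- g_agent(acfg, params)
    ag$kind <- "aif_instrumental_only"
  } else {
    acfg$obs_head_weight <- 0
    acfg$epistemic_weight <- 0
    ag <- g_agent(acfg, params)
    ag$kind <- "dqn_sparse"
    ag$epsilon_start <- config$epsilon_start
    ag$epsilon_end <- config$epsilon_end
    ag$epsilon_decay_episodes <- config$epsilon_decay_episodes
    ag$sparse_reward_success <- config$sparse_reward_success
    ag$sparse_reward_miss <- config$sparse_reward_miss
  }
  ag
}
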