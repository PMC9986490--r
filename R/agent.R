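#' Agent configuration
#'
#' Hyperparameters of the G-learning active inference agent: a two-headed
#' multilayer perceptron (shared ReLU trunk, a linear head estimating the
#' negative expected free energy of each action, and a linear head
#' predicting the next observation), trained by a Q-learning-style bootstrap
#' from a uniform replay buffer with a periodically synchronized target
#' network.
#'
#' Observations are divided elementwise by `obs_norm` before entering the
#' network and the epistemic error norm (distances by 50 m, speeds by
#' 20 m/s by default) so both loss heads operate on O(1) quantities.
#'
#' @param gamma discount factor in `[0, 1)` on bootstrapped future G-values.
#' @param learning_rate Adam step size.
#' @param learning_rate_final,lr_decay_updates optional linear decay of the
#'   step size from `learning_rate` to `learning_rate_final` over this many
#'   gradient updates (0 disables decay).
#' @param batch_size replay minibatch size.
#' @param buffer_capacity replay capacity (FIFO beyond this).
#' @param target_sync_interval gradient steps between target-network copies.
#' @param warmup transitions stored before the first gradient step.
#' @param update_every environment steps per gradient update.
#' @param epistemic_weight multiplier on the epistemic (prediction-error)
#'   reward; 0 gives the instrumental-only ablation.
#' @param hidden_sizes trunk layer widths `c(J1, J2)`.
#' @param sigma_a,sigma_o output standard deviations of the two heads
#'   (unit variance by default).
#' @param obs_head_weight multiplier on the observation-head loss; 0
#'   disables the forward model (used by the DQN baseline).
#' @param epsilon probability of a uniform random action; the active
#'   inference agents act greedily (`epsilon = 0`) and rely on the epistemic
#'   drive plus optimistic zero initialization for exploration.
#' @param obs_norm per-dimension observation normalizers.
#' @param bias include bias terms in all layers (`FALSE` gives the
#'   pure-linear-algebra variant used in exactness tests).
#' @param n_actions,obs_dim head sizes; the interception task uses 6 and 4.
#' @return a list of class `agent_config`.
#' @export
agent_config <- function(gamma = 0.99, learning_rate = 5e-4,
                         learning_rate_final = 1e-4,
                         lr_decay_updates = 4e5, batch_size = 32,
                         buffer_capacity = 1e5, target_sync_interval = 2000,
                         warmup = 1000, update_every = 1,
                         epistemic_weight = 10,
                         hidden_sizes = c(128, 128), sigma_a = 1, sigma_o = 1,
                         obs_head_weight = 1.0, epsilon = 0,
                         obs_norm = c(50, 20, 50, 20), bias = TRUE,
                         n_actions = 6, obs_dim = 4) {
  stopifnot(gamma >= 0, gamma < 1, learning_rate >= 0,
            learning_rate_final >= 0, lr_decay_updates >= 0, batch_size >= 1,
            buffer_capacity >= batch_size, target_sync_interval >= 1,
            warmup >= 0, update_every >= 1, epistemic_weight >= 0,
            length(hidden_sizes) == 2, all(hidden_sizes >= 1),
            sigma_a > 0, sigma_o > 0, obs_head_weight >= 0,
            epsilon >= 0, epsilon <= 1,
            length(obs_norm) == obs_dim, all(obs_norm > 0),
            n_actions >= 1, obs_dim >= 1)
  structure(list(gamma = gamma, learning_rate = learning_rate,
                 learning_rate_final = learning_rate_final,
                 lr_decay_updates = as.numeric(lr_decay_updates),
                 batch_size = as.integer(batch_size),
                 buffer_capacity = as.integer(buffer_capacity),
                 target_sync_interval = as.integer(target_sync_interval),
                 warmup = as.integer(warmup),
                 update_every = as.integer(update_every),
                 epistemic_weight = epistemic_weight,
                 hidden_sizes = as.integer(hidden_sizes),
                 sigma_a = sigma_a, sigma_o = sigma_o,
                 obs_head_weight = obs_head_weight, epsilon = epsilon,
                 obs_norm = obs_norm, bias = bias,
                 n_actions = as.integer(n_actions),
                 obs_dim = as.integer(obs_dim)),
            class = "agent_config")
}

#' Initialize joint-model parameters
#'
#' He-style initialization: trunk weights `N(0, sqrt(2 / fan_in))` (matched
#' to the ReLU trunk), head weights `N(0, sqrt(1 / fan_in))`, biases zero.
#' Draws from the R random stream, so `set.seed()` makes it reproducible.
#'
#' @param hidden_sizes trunk widths `c(J1, J2)`.
#' @param n_actions,obs_dim head sizes.
#' @param bias include (zero-initialized) bias vectors.
#' @return list of weight matrices `W1 (J1 x D)`, `W2 (J2 x J1)`,
#'   `Wa (A x J2)`, `Wo (D x J2)` and bias vectors `b1, b2, ba, bo`.
#' @export
init_params <- function(hidden_sizes = c(128, 128), n_actions = 6,
                        obs_dim = 4, bias = TRUE) {
  stopifnot(length(hidden_sizes) == 2, all(hidden_sizes >= 1),
            n_actions >= 1, obs_dim >= 1)
  j1 <- hidden_sizes[1]; j2 <- hidden_sizes[2]
  he <- function(nout, nin, gain) {
    matrix(stats::rnorm(nout * nin, sd = sqrt(gain / nin)), nout, nin)
  }
  p <- list(W1 = he(j1, obs_dim, 2), W2 = he(j2, j1, 2),
            Wa = he(n_actions, j2, 1), Wo = he(obs_dim, j2, 1),
            b1 = numeric(j1), b2 = numeric(j2),
            ba = numeric(n_actions), bo = numeric(obs_dim))
  attr(p, "bias") <- bias
  p
}

#' Count the free parameters of a joint model
#' @param params a parameter list from [init_params()].
#' @return integer parameter count (biases included when enabled).
#' @export
n_params <- function(params) {
  n <- sum(vapply(params[c("W1", "W2", "Wa", "Wo")], length, numeric(1)))
  if (isTRUE(attr(params, "bias")))
    n <- n + sum(vapply(params[c("b1", "b2", "ba", "bo")], length, numeric(1)))
  as.integer(n)
}

#' Normalize observations for the network
#' @param obs observation vector or matrix with observations in columns.
#' @param obs_norm per-dimension normalizers.
#' @return normalized observations, same shape.
#' @export
normalize_obs <- function(obs, obs_norm = c(50, 20, 50, 20)) {
  if (is.matrix(obs)) obs / obs_norm else unname(obs) / obs_norm
}

#' Joint-model forward pass (reference implementation)
#'
#' Double-precision R implementation of the two-headed network:
#' `z1 = relu(W1 z0 + b1)`, `z2 = relu(W2 z1 + b2)`, linear heads
#' `g = Wa z2 + ba` (negative expected free energy per action) and
#' `pred = Wo z2 + bo` (next-observation prediction). The compiled
#' single-precision path used in training is tested against this function.
#'
#' @param params parameter list (see [init_params()]).
#' @param obs_norm_ed normalized observation vector, or matrix with one
#'   observation per column.
#' @param bias use the bias vectors.
#' @return list with `g` (A x n) and `pred` (D x n) matrices.
#' @export
g_forward <- function(params, obs_norm_ed, bias = TRUE) {
  x <- if (is.matrix(obs_norm_ed)) obs_norm_ed else matrix(obs_norm_ed)
  if (any(!is.finite(x))) stop("observations must be finite")
  z1 <- params$W1 %*% x
  if (bias) z1 <- z1 + params$b1
  z1 <- pmax(z1, 0)
  z2 <- params$W2 %*% z1
  if (bias) z2 <- z2 + params$b2
  z2 <- pmax(z2, 0)
  g <- params$Wa %*% z2
  pred <- params$Wo %*% z2
  if (bias) {
    g <- g + params$ba
    pred <- pred + params$bo
  }
  list(g = g, pred = pred)
}

#' Greedy / epsilon-greedy action selection
#'
#' The greedy action maximizes the estimated negative expected free energy
#' (equivalently, minimizes expected free energy). Ties break to the lowest
#' action index. With probability `epsilon` a uniform random action is
#' taken instead.
#'
#' @param g_values numeric vector of per-action G-values.
#' @param epsilon exploration probability.
#' @return 0-based action index.
#' @export
select_action <- function(g_values, epsilon = 0) {
  if (length(g_values) == 0) stop("empty G-value vector")
  if (any(!is.finite(g_values))) stop("G-values must be finite")
  if (epsilon > 0 && stats::runif(1) < epsilon)
    return(sample.int(length(g_values), 1) - 1L)
  which.max(g_values) - 1L
}

#' Epistemic reward
#'
#' Squared Euclidean distance between the forward model's prediction and the
#' realized next observation (both in normalized units), times a weight.
#' Non-negative; zero only for an exact prediction. Acts as an exploration
#' bonus: poorly modelled transitions look attractive until learned.
#'
#' @param predicted_obs model prediction (normalized units).
#' @param actual_obs realized observation (normalized units).
#' @param weight multiplier (0 disables the term).
#' @return scalar reward.
#' @export
epistemic_reward <- function(predicted_obs, actual_obs, weight = 1) {
  if (length(predicted_obs) != length(actual_obs))
    stop("prediction and observation have different lengths")
  weight * sum((predicted_obs - actual_obs)^2)
}

#' Bootstrap targets for the G head
#'
#' For each transition, the taken action's target is
#' `r + gamma * (1 - terminal) * max_a g_frozen(o')`, evaluated through the
#' frozen target network at the *next* observation; every other action keeps
#' the online network's current estimate at `o`, so only the taken action
#' contributes to the loss.
#'
#' @param batch list with `o` (D x n normalized), `a` (0-based actions),
#'   `r`, `o2` (D x n normalized), `terminal` (0/1).
#' @param online,frozen parameter lists.
#' @param gamma discount factor.
#' @param bias use bias vectors.
#' @return A x n matrix of targets.
#' @export
efe_target <- function(batch, online, frozen, gamma, bias = TRUE) {
  n <- length(batch$a)
  stopifnot(n >= 1)
  tt <- g_forward(online, batch$o, bias)$g
  gmax <- apply(g_forward(frozen, batch$o2, bias)$g, 2, max)
  boot <- batch$r + gamma * ifelse(batch$terminal > 0, 0, gmax)
  tt[cbind(batch$a + 1L, seq_len(n))] <- boot
  tt
}

#' Multi-objective loss of the joint model
#'
#' Batch mean of the two quadratic head losses:
#' `||t - g||^2 / (2 sigma_a^2)` for the G head against (stop-gradient)
#' bootstrap targets and `obs_head_weight * ||o' - pred||^2 / (2 sigma_o^2)`
#' for the transition head against the realized next observation.
#'
#' @param params parameter list.
#' @param batch as in [efe_target()].
#' @param targets A x n target matrix.
#' @param sigma_a,sigma_o head output standard deviations.
#' @param obs_head_weight weight on the transition-head term.
#' @param bias use bias vectors.
#' @return scalar loss.
#' @export
g_loss <- function(params, batch, targets, sigma_a = 1, sigma_o = 1,
                   obs_head_weight = 1, bias = TRUE) {
  fw <- g_forward(params, batch$o, bias)
  n <- ncol(fw$g)
  la <- sum((targets - fw$g)^2) / (2 * sigma_a^2)
  lo <- obs_head_weight * sum((batch$o2 - fw$pred)^2) / (2 * sigma_o^2)
  (la + lo) / n
}

# ---------------------------------------------------------------------------

#' Create a G-learning agent
#'
#' Builds the stateful agent: online and frozen (target) networks, Adam
#' optimizer state and the FIFO replay buffer, all held in compiled code.
#' Weight initialization draws from the R random stream unless explicit
#' parameters are supplied.
#'
#' @param config an [agent_config()].
#' @param params optional parameter list; freshly initialized if `NULL`.
#' @return an object of class `g_agent`.
#' @export
g_agent <- function(config = agent_config(), params = NULL) {
  stopifnot(inherits(config, "agent_config"))
  if (is.null(params))
    params <- init_params(config$hidden_sizes, config$n_actions,
                          config$obs_dim, config$bias)
  ptr <- cpp_agent_new(unclass(config), params)
  structure(list(ptr = ptr, config = config), class = "g_agent")
}

#' @export
print.g_agent <- function(x, ...) {
  st <- cpp_agent_params(x$ptr)
  cat("<g_agent>", "\n",
      "  trunk: ", paste(x$config$hidden_sizes, collapse = " x "),
      ", actions: ", x$config$n_actions,
      ", gamma: ", x$config$gamma, "\n",
      "  updates: ", st$n_updates, ", buffer: ", st$buffer_size, "/",
      x$config$buffer_capacity, "\n", sep = "")
  invisible(x)
}

#' Forward pass of an agent on a raw observation
#' @param agent a [g_agent()].
#' @param obs raw observation vector (normalized internally).
#' @return list with `g` (per-action G-values) and `pred` (next-observation
#'   prediction in normalized units).
#' @export
agent_forward <- function(agent, obs) {
  cpp_agent_forward(agent$ptr, as.numeric(obs))
}

#' Select an action from a raw observation
#' @param agent a [g_agent()].
#' @param obs raw observation vector.
#' @param epsilon exploration probability (defaults to the agent's config).
#' @return 0-based action index.
#' @export
agent_act <- function(agent, obs, epsilon = agent$config$epsilon) {
  cpp_agent_act(agent$ptr, as.numeric(obs), epsilon)
}

#' Store one transition in the replay buffer
#' @param agent a [g_agent()].
#' @param o,o2 raw observations before and after the action.
#' @param a 0-based action index.
#' @param r total reward of the transition.
#' @param terminal logical terminal flag.
#' @export
agent_store <- function(agent, o, a, r, o2, terminal) {
  cpp_agent_store(agent$ptr, as.numeric(o), as.integer(a), r,
                  as.numeric(o2), isTRUE(terminal))
  invisible(agent)
}

#' Number of transitions currently in the replay buffer
#' @param agent a [g_agent()].
#' @return integer buffer fill.
#' @export
agent_buffer_size <- function(agent) cpp_agent_buffer_size(agent$ptr)

#' Sample a batch uniformly (with replacement) from the replay buffer
#' @param agent a [g_agent()].
#' @param n batch size.
#' @return list with `o`, `a`, `r`, `o2`, `terminal` (observations in
#'   columns, raw units).
#' @export
agent_sample <- function(agent, n) cpp_agent_sample(agent$ptr, as.integer(n))

#' One gradient step on a sampled replay batch
#'
#' Samples `batch_size` transitions, forms the bootstrap targets through the
#' frozen network, and applies one Adam update to the online network. The
#' frozen network is refreshed every `target_sync_interval` updates. Errors
#' if the buffer holds fewer transitions than one batch.
#'
#' @param agent a [g_agent()].
#' @return the total number of updates performed, invisibly.
#' @export
agent_train_step <- function(agent) {
  invisible(cpp_agent_train_step(agent$ptr))
}

#' Copy the online network into the frozen target network
#' @param agent a [g_agent()].
#' @export
agent_sync_target <- function(agent) {
  cpp_agent_sync(agent$ptr)
  invisible(agent)
}

#' Extract the agent's parameters and counters
#' @param agent a [g_agent()].
#' @param which `"online"` or `"frozen"`.
#' @return parameter list (double precision copies of the float weights).
#' @export
agent_params <- function(agent, which = c("online", "frozen")) {
  which <- match.arg(which)
  p <- cpp_agent_params(agent$ptr)[[which]]
  attr(p, "bias") <- agent$config$bias
  p
}

#' Overwrite the agent's parameters
#' @param agent a [g_agent()].
#' @param params parameter list.
#' @param also_frozen copy into the target network too.
#' @export
agent_set_params <- function(agent, params, also_frozen = TRUE) {
  cpp_agent_set_params(agent$ptr, params, isTRUE(also_frozen))
  invisible(agent)
}

#' Checkpoint an agent
#'
#' Returns a plain list (config, online and frozen weights, update counter)
#' from which [g_agent_restore()] rebuilds an equivalent agent. Weights
#' round-trip bit-exactly (floats are exactly representable as doubles);
#' optimizer moments and buffer contents are not carried over.
#'
#' @param agent a [g_agent()].
#' @return a checkpoint list.
#' @export
agent_checkpoint <- function(agent) {
  st <- cpp_agent_params(agent$ptr)
  list(config = agent$config, online = st$online, frozen = st$frozen,
       n_updates = st$n_updates)
}

#' Rebuild an agent from a checkpoint
#' @param checkpoint list from [agent_checkpoint()].
#' @return a [g_agent()].
#' @export
g_agent_restore <- function(checkpoint) {
  ag <- g_agent(checkpoint$config, params = checkpoint$online)
  cpp_agent_set_params(ag$ptr, checkpoint$frozen, TRUE)
  cpp_agent_set_params(ag$ptr, checkpoint$online, FALSE)
  ag
}
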