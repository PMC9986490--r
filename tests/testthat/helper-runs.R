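# Trained runs are expensive; train each condition once per test session and
# share it across test files. Keys identify (kind, gamma, lag multiplier,
# episodes, seed).

.run_cache <- new.env(parent = emptyenv())

cached_trial <- function(kind, n_episodes, seed, gamma = 0.99,
                         lag_multiplier = 1.0) {
  key <- paste(kind, n_episodes, seed, gamma, lag_multiplier, sep = "_")
  if (!exists(key, envir = .run_cache)) {
    out <- train_trial(kind, n_episodes = n_episodes, seed = seed,
                       gamma = gamma, lag_multiplier = lag_multiplier)
    assign(key, out, envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# a small agent for fast functional tests (same code paths, narrow trunk)
small_agent_config <- function(hidden_sizes = c(16, 16), warmup = 64,
                               batch_size = 16, buffer_capacity = 1000, ...) {
  agent_config(hidden_sizes = hidden_sizes, warmup = warmup,
               batch_size = batch_size, buffer_capacity = buffer_capacity,
               ...)
}

# deterministic 3-state, 2-action toy MDP used as a G-learning oracle
toy_mdp <- function() {
  list(
    n_states = 3L,
    n_actions = 2L,
    # transition[s, a] -> next state (1-based)
    transition = matrix(c(2L, 3L,
                          3L, 1L,
                          1L, 2L), nrow = 3, byrow = TRUE),
    reward = matrix(c(0.0, 1.0,
                      0.5, -1.0,
                      2.0, 0.0), nrow = 3, byrow = TRUE),
    gamma = 0.9,
    obs = function(s) { o <- numeric(4); o[s] <- 1; o }
  )
}

# independent oracle: value iteration on the toy MDP
toy_mdp_q_star <- function(mdp, iterations = 1000) {
  q <- matrix(0, mdp$n_states, mdp$n_actions)
  for (i in seq_len(iterations)) {
    v <- apply(q, 1, max)
    q <- mdp$reward + mdp$gamma * matrix(v[mdp$transition], mdp$n_states)
  }
  q
}
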