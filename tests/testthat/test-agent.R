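test_that("parameter initialization is seeded and correctly shaped", {
  set.seed(4)
  a <- init_params(c(8, 9), n_actions = 6, obs_dim = 4)
  set.seed(4)
  b <- init_params(c(8, 9), n_actions = 6, obs_dim = 4)
  expect_identical(a, b)
  expect_identical(dim(a$W1), c(8L, 4L))
  expect_identical(dim(a$W2), c(9L, 8L))
  expect_identical(dim(a$Wa), c(6L, 9L))
  expect_identical(dim(a$Wo), c(4L, 9L))
  expect_identical(n_params(a),
                   as.integer(4 * 8 + 8 * 9 + 9 * 6 + 9 * 4 + 8 + 9 + 6 + 4))
  expect_error(init_params(c(0, 4)))
})

test_that("the forward pass matches hand computation", {
  # all-zero weights: both heads are zero everywhere
  p0 <- init_params(c(3, 3))
  for (nm in names(p0)) p0[[nm]][] <- 0
  fw <- g_forward(p0, c(0.5, 0.2, 0.4, 0.1))
  expect_equal(as.numeric(fw$g), rep(0, 6))
  expect_equal(as.numeric(fw$pred), rep(0, 4))

  # single-unit trunk, no biases: g = Wa * relu(W2 * relu(W1 x))
  p <- list(W1 = matrix(c(1, -2, 0.5, 0), 1, 4),
            W2 = matrix(2, 1, 1),
            Wa = matrix(seq(0.1, 0.6, by = 0.1), 6, 1),
            Wo = matrix(c(-1, 0, 1, 2), 4, 1),
            b1 = 0, b2 = 0, ba = numeric(6), bo = numeric(4))
  x <- c(1, 0.25, 2, 3)
  h <- max(0, sum(c(1, -2, 0.5, 0) * x))  # 1.5
  fw <- g_forward(p, x, bias = FALSE)
  expect_equal(as.numeric(fw$g), seq(0.1, 0.6, by = 0.1) * 2 * h)
  expect_equal(as.numeric(fw$pred), c(-1, 0, 1, 2) * 2 * h)

  # negative pre-activation contributes nothing downstream
  x_neg <- c(0, 1, 0, 0)  # W1 x = -2 -> relu 0
  fw2 <- g_forward(p, x_neg, bias = FALSE)
  expect_equal(as.numeric(fw2$g), rep(0, 6))

  expect_error(g_forward(p, c(1, NA, 0, 0), bias = FALSE), "finite")
})

test_that("compiled and reference forward passes agree", {
  set.seed(12)
  p <- init_params(c(24, 17))
  x <- matrix(rnorm(4 * 10), 4, 10)
  ref <- g_forward(p, x, bias = TRUE)
  fast <- cpp_forward(p, x, TRUE)
  expect_equal(fast$g, ref$g, tolerance = 1e-5)
  expect_equal(fast$pred, ref$pred, tolerance = 1e-5)
})

test_that("action selection is greedy on G with documented tie-breaking", {
  expect_identical(select_action(c(0.1, 0.5, 0.2, 0.0, -1, -2)), 1L)
  expect_identical(select_action(rep(0.3, 6)), 0L)
  expect_error(select_action(numeric(0)))
  expect_error(select_action(c(1, NaN)))
  # epsilon = 1: empirically uniform over actions
  set.seed(8)
  draws <- replicate(10000, select_action(c(9, 0, 0, 0, 0, 0), epsilon = 1))
  tab <- table(factor(draws, levels = 0:5))
  expect_gt(chisq.test(tab)$p.value, 1e-3)
})

test_that("epistemic reward is the weighted squared prediction error", {
  expect_equal(epistemic_reward(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  expect_equal(epistemic_reward(c(1, 2, 3, 4), c(1, 3, 3, 4)), 1)
  expect_equal(epistemic_reward(c(0, 0), c(3, 4), weight = 2), 50)
  expect_equal(epistemic_reward(c(5, 5, 5, 5), c(0, 1, 2, 3), weight = 0), 0)
  expect_error(epistemic_reward(c(1, 2), c(1, 2, 3)))
})

test_that("bootstrap targets follow the G-learning rule", {
  set.seed(21)
  online <- init_params(c(6, 5))
  frozen <- init_params(c(6, 5))
  batch <- list(o = matrix(rnorm(4 * 3), 4, 3), a = c(0L, 3L, 5L),
                r = c(1, -2, 0.5), o2 = matrix(rnorm(4 * 3), 4, 3),
                terminal = c(0L, 0L, 1L))
  tt <- efe_target(batch, online, frozen, gamma = 0.99)
  own <- g_forward(online, batch$o)$g
  gmax <- apply(g_forward(frozen, batch$o2)$g, 2, max)
  # taken actions bootstrap through the frozen network
  expect_equal(tt[1, 1], 1 + 0.99 * gmax[1])
  expect_equal(tt[4, 2], -2 + 0.99 * gmax[2])
  # terminal transition: no bootstrap
  expect_equal(tt[6, 3], 0.5)
  # non-taken actions keep the online estimates (zero error contribution)
  mask <- matrix(TRUE, 6, 3); mask[cbind(batch$a + 1, 1:3)] <- FALSE
  expect_equal(tt[mask], own[mask])
  # gamma = 0: myopic targets equal the rewards
  t0 <- efe_target(batch, online, frozen, gamma = 0)
  expect_equal(t0[cbind(batch$a + 1, 1:3)], batch$r)
  # frozen max g = 2, r = 1, gamma 0.99 -> 2.98 (hand-set single-layer net)
  pz <- online
  for (nm in c("W1", "W2", "Wa", "Wo")) pz[[nm]][] <- 0
  pf <- pz
  pf$ba <- c(2, rep(-5, 5))  # frozen net outputs a constant max g of 2
  b1 <- list(o = matrix(0.1, 4, 1), a = 2L, r = 1, o2 = matrix(0.1, 4, 1),
             terminal = 0L)
  expect_equal(efe_target(b1, pz, pf, 0.99)[3, 1], 2.98)
  # compiled target construction agrees with the reference
  fast <- cpp_efe_targets(online, frozen, batch$o, batch$a, batch$r,
                          batch$o2, batch$terminal, 0.99, TRUE)$targets
  expect_equal(fast, tt, tolerance = 1e-5)
})

test_that("the two-headed loss obeys its quadratic identities", {
  set.seed(31)
  p <- init_params(c(6, 5))
  batch <- list(o = matrix(rnorm(4 * 2), 4, 2), a = c(1L, 2L),
                r = c(0, 0), o2 = matrix(rnorm(4 * 2), 4, 2),
                terminal = c(0L, 0L))
  fw <- g_forward(p, batch$o)
  # perfect targets and perfect predictions: zero loss
  expect_equal(g_loss(p, list(o = batch$o, o2 = fw$pred), fw$g), 0)
  # single transition, unit residual on one action coordinate: 1/2 sigma_a^2
  tt <- fw$g[, 1, drop = FALSE]
  tt[1, 1] <- tt[1, 1] + 1
  b1 <- list(o = batch$o[, 1, drop = FALSE], o2 = fw$pred[, 1, drop = FALSE])
  expect_equal(g_loss(p, b1, tt), 0.5)
  expect_equal(g_loss(p, b1, tt, sigma_a = sqrt(2)), 0.25)
  # observation-head residuals scale with 1 / (2 sigma_o^2)
  b2 <- list(o = batch$o[, 1, drop = FALSE],
             o2 = fw$pred[, 1, drop = FALSE] + c(1, 0, 0, 0))
  tt0 <- fw$g[, 1, drop = FALSE]
  expect_equal(g_loss(p, b2, tt0), 0.5)
  expect_equal(g_loss(p, b2, tt0, sigma_o = sqrt(2)), 0.25)
  expect_equal(g_loss(p, b2, tt0, obs_head_weight = 0), 0)
})

test_that("compiled gradients match finite differences of the loss", {
  set.seed(41)
  p <- init_params(c(7, 6))
  n <- 5
  batch <- list(o = matrix(rnorm(4 * n, sd = 0.5), 4, n),
                a = sample(0:5, n, TRUE), r = rnorm(n),
                o2 = matrix(rnorm(4 * n, sd = 0.5), 4, n),
                terminal = rbinom(n, 1, 0.2))
  targets <- efe_target(batch, p, p, gamma = 0.9)
  gr <- cpp_loss_grad(p, batch$o, targets, batch$o2, 1, 1, 1, TRUE)
  h <- 1e-3
  for (nm in c("W1", "W2", "Wa", "Wo", "b1", "ba")) {
    idx <- seq_len(min(10, length(p[[nm]])))
    for (i in idx) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (g_loss(pp, batch, targets) - g_loss(pm, batch, targets)) /
        (2 * h)
      expect_lt(abs(gr[[nm]][i] - num), 2e-3 + 0.05 * abs(num))
    }
  }
})

test_that("training descends on a fixed replayed transition", {
  set.seed(51)
  cfg <- small_agent_config(gamma = 0, learning_rate = 3e-4,
                            learning_rate_final = 3e-4, obs_norm = rep(1, 4))
  ag <- g_agent(cfg)
  o <- c(0.4, 0.3, 0.2, 0.1); o2 <- c(0.35, 0.3, 0.18, 0.12)
  # fill one batch with copies of the same transition: every minibatch
  # then replays exactly this transition
  for (i in seq_len(cfg$batch_size)) agent_store(ag, o, 2L, -1.5, o2, FALSE)
  batch <- list(o = matrix(o), a = 2L, r = -1.5, o2 = matrix(o2),
                terminal = 0L)
  loss_now <- function() {
    p <- agent_params(ag)
    g_loss(p, batch, efe_target(batch, p, p, gamma = 0))
  }
  losses <- numeric(201)
  losses[1] <- loss_now()
  for (i in 1:200) {
    agent_train_step(ag)
    losses[i + 1] <- loss_now()
  }
  expect_gte(mean(diff(losses) < 0), 0.95)
  expect_lt(losses[201], 0.5 * losses[1])
})

test_that("a zero learning rate leaves parameters unchanged", {
  set.seed(52)
  ag <- g_agent(small_agent_config(learning_rate = 0,
                                   learning_rate_final = 0))
  before <- agent_params(ag)
  for (i in 1:20) agent_store(ag, rnorm(4), i %% 6, -1, rnorm(4), FALSE)
  for (i in 1:10) agent_train_step(ag)
  expect_identical(agent_params(ag), before)
})

test_that("training is deterministic under a fixed seed", {
  run <- function() {
    set.seed(53)
    ag <- g_agent(small_agent_config())
    for (i in 1:100) agent_store(ag, rnorm(4), i %% 6, rnorm(1), rnorm(4),
                                 i %% 40 == 0)
    for (i in 1:50) agent_train_step(ag)
    agent_params(ag)
  }
  expect_identical(run(), run())
})

test_that("training requires at least one batch of transitions", {
  set.seed(54)
  ag <- g_agent(small_agent_config(batch_size = 16))
  expect_error(agent_train_step(ag), "fewer")
  for (i in 1:15) agent_store(ag, rnorm(4), 0L, 0, rnorm(4), FALSE)
  expect_error(agent_train_step(ag), "fewer")
  agent_store(ag, rnorm(4), 0L, 0, rnorm(4), FALSE)
  expect_silent(agent_train_step(ag))
})

test_that("the replay buffer is FIFO at capacity and samples uniformly", {
  set.seed(55)
  # FIFO eviction at the default 1e5 capacity
  ag <- g_agent(agent_config(hidden_sizes = c(4, 4), buffer_capacity = 1e5,
                             batch_size = 1))
  for (i in seq_len(1e5 + 1))
    agent_store(ag, c(i, 0, 0, 0), 0L, i, c(i, 0, 0, 0), FALSE)
  expect_identical(agent_buffer_size(ag), as.integer(1e5))
  big <- agent_sample(ag, 3000)
  expect_false(any(big$r == 1))    # the oldest transition was evicted
  expect_true(any(big$r > 1e5 - 3000))

  # degenerate single-item buffer: every sample repeats it
  ag1 <- g_agent(small_agent_config(batch_size = 4))
  expect_error(agent_sample(ag1, 4), "empty")
  agent_store(ag1, c(1, 2, 3, 4), 3L, -7, c(4, 3, 2, 1), TRUE)
  s <- agent_sample(ag1, 64)
  expect_true(all(s$r == -7))
  expect_true(all(s$a == 3L))

  # chi-squared uniformity over a 10-item buffer
  ag2 <- g_agent(small_agent_config())
  for (i in 1:10) agent_store(ag2, rnorm(4), 0L, i, rnorm(4), FALSE)
  s2 <- agent_sample(ag2, 1e5)
  tab <- table(factor(s2$r, levels = 1:10))
  expect_gt(chisq.test(tab)$p.value, 1e-3)
})

test_that("the target network is a frozen copy until synchronized", {
  set.seed(56)
  ag <- g_agent(small_agent_config(target_sync_interval = 10000))
  obs <- rnorm(4)
  p <- cpp_agent_params(ag$ptr)
  expect_identical(p$online, p$frozen)
  for (i in 1:50) agent_store(ag, rnorm(4), i %% 6, rnorm(1), rnorm(4), FALSE)
  for (i in 1:30) agent_train_step(ag)
  p <- cpp_agent_params(ag$ptr)
  expect_false(identical(p$online$W2, p$frozen$W2))  # online moved
  frozen_before <- p$frozen
  agent_sync_target(ag)
  p2 <- cpp_agent_params(ag$ptr)
  expect_identical(p2$frozen, p2$online)
  expect_false(identical(p2$frozen, frozen_before))

  # sync interval 1: the target network never lags
  ag3 <- g_agent(small_agent_config(target_sync_interval = 1))
  for (i in 1:50) agent_store(ag3, rnorm(4), i %% 6, rnorm(1), rnorm(4), FALSE)
  for (i in 1:5) agent_train_step(ag3)
  p3 <- cpp_agent_params(ag3$ptr)
  expect_identical(p3$online, p3$frozen)
})

test_that("checkpoints round-trip bit-exactly", {
  set.seed(57)
  ag <- g_agent(small_agent_config())
  for (i in 1:80) agent_store(ag, rnorm(4), i %% 6, rnorm(1), rnorm(4), FALSE)
  for (i in 1:20) agent_train_step(ag)
  ck <- agent_checkpoint(ag)
  ag2 <- g_agent_restore(ck)
  expect_identical(agent_params(ag2), agent_params(ag))
  obs <- rnorm(4)
  expect_identical(agent_forward(ag2, obs), agent_forward(ag, obs))
})

test_that("G-learning converges to the value-iteration oracle on a toy MDP", {
  mdp <- toy_mdp()
  q_star <- toy_mdp_q_star(mdp)
  set.seed(60)
  cfg <- agent_config(gamma = mdp$gamma, learning_rate = 2e-3,
                      learning_rate_final = 1e-4, lr_decay_updates = 10000,
                      batch_size = 32, buffer_capacity = 512,
                      target_sync_interval = 100, hidden_sizes = c(32, 32),
                      obs_norm = rep(1, 4), n_actions = 2, obs_dim = 4,
                      obs_head_weight = 0)
  ag <- g_agent(cfg)
  for (rep in 1:40) {
    for (s in 1:3) for (a in 1:2) {
      s2 <- mdp$transition[s, a]
      agent_store(ag, mdp$obs(s), a - 1L, mdp$reward[s, a], mdp$obs(s2),
                  FALSE)
    }
  }
  for (i in 1:12000) agent_train_step(ag)
  g_hat <- sapply(1:3, function(s) agent_forward(ag, mdp$obs(s))$g)
  expect_lt(max(abs(as.numeric(g_hat) - as.numeric(t(q_star)))), 1e-2)
  # greedy policy matches the oracle's
  expect_identical(apply(g_hat, 2, which.max), apply(q_star, 1, which.max))
})
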