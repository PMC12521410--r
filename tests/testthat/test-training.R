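test_that("splits are disjoint, exhaustive, floor-rounded, and seeded", {
  pool <- tiny_pool(12)
  ds <- dataset(random_trials(100, 12, 6, seed = 8), pool)
  sp <- split_trials(ds, seed = 4)
  expect_equal(vapply(sp, function(d) length(d$trials), integer(1)),
               c(train = 90L, validation = 5L, test = 5L))
  key <- function(t) paste(c(t$participant, t$session, t$study), collapse = "|")
  keys <- lapply(sp, function(d) vapply(d$trials, key, character(1)))
  expect_length(intersect(keys$train, keys$validation), 0)
  expect_length(intersect(keys$train, keys$test), 0)
  expect_setequal(unlist(keys), vapply(ds$trials, key, character(1)))
  sp2 <- split_trials(ds, seed = 4)
  expect_identical(keys$train, vapply(sp2$train$trials, key, character(1)))
  ds19 <- dataset(random_trials(19, 12, 6, seed = 8), pool)
  expect_error(split_trials(ds19), "too few trials")
})

test_that("episode rewards follow the correct/incorrect/repeat rule", {
  rl <- rl_config(L = 14, N = 30)
  # perfect recall of a 14-item list reaches the reward ceiling of 14
  study <- 2:15
  expect_equal(episode_reward(study, study, rl, ended = TRUE)$total, 14)
  expect_equal(episode_reward(study, integer(0), rl)$total, 0)
  # correct, repeat of it, then an intrusion: 1 - 0.5 - 1
  r <- episode_reward(c(1, 2, 3), c(2, 2, 9), rl_config(L = 3, N = 10))
  expect_equal(r$total, -0.5)
  expect_equal(r$per_step, c(1, -0.5, -1))
  # total reward is at most L, with equality only for perfect recall
  set.seed(6)
  for (i in 1:50) {
    st <- sample(10, 4)
    rec <- sample(10, sample(0:6, 1), replace = TRUE)
    tot <- episode_reward(st, rec, rl_config(L = 4, N = 10))$total
    expect_lte(tot, 4)
    if (tot == 4) expect_setequal(rec, st)
  }
})

test_that("discounted returns and GAE agree with a backward-recursion oracle", {
  set.seed(12)
  for (i in 1:30) {
    T <- sample(1:9, 1)
    rw <- stats::rnorm(T); vals <- stats::rnorm(T)
    g <- stats::runif(1, 0.8, 1); lam <- stats::runif(1)
    got <- gae(rw, vals, g, lam)
    # oracle: explicit per-step sums
    deltas <- rw + g * c(vals[-1], 0) - vals
    adv <- numeric(T)
    for (t in seq_len(T)) {
      s <- 0
      for (j in t:T) s <- s + (g * lam)^(j - t) * deltas[j]
      adv[t] <- s
    }
    expect_equal(got$adv, adv, tolerance = 1e-12)
    # lambda = 1: advantages are discounted returns minus values
    g1 <- gae(rw, vals, g, 1)
    rets <- numeric(T)
    for (t in seq_len(T)) rets[t] <- sum(g^(seq(t, T) - t) * rw[t:T])
    expect_equal(g1$ret, rets, tolerance = 1e-12)
  }
})

test_that("episodes are seeded, bounded, and cover the vocabulary", {
  m <- small_s2s(N = 10, seed = 2)
  rl <- rl_config(L = 4, N = 10, max_steps = 8)
  set.seed(3); e1 <- run_episode(m, rl)
  set.seed(3); e2 <- run_episode(m, rl)
  expect_identical(e1[c("study", "actions", "rewards")],
                   e2[c("study", "actions", "rewards")])
  expect_lte(length(e1$actions), 8)
  expect_equal(length(e1$rewards), length(e1$actions))
  covered <- with_seed(5, {
    unique(unlist(lapply(1:200, function(i) run_episode(m, rl)$study)))
  })
  expect_setequal(covered, 1:10)
})

test_that("analytic policy gradients match finite differences", {
  m <- small_s2s(N = 6, d = 4, seed = 7)
  epi <- list(study = c(2L, 5L, 3L), actions = c(5L, 1L, 3L, 7L),
              adv = c(0.5, -1.2, 0.3, 0.8), ret = c(1, 0.5, 0.2, 0),
              oldlogp = c(-2, -1.5, -2.2, -0.3))
  loss_of <- function(params) {
    memsearch:::s2s_ppo_grad_cpp(params, unclass(m$config), list(epi),
                                 0.2, 0.01, 0.5)$loss
  }
  res <- memsearch:::s2s_ppo_grad_cpp(m$params, unclass(m$config), list(epi),
                                      0.2, 0.01, 0.5)
  set.seed(8)
  for (nm in c("encU", "decW", "Wc", "emb", "out_emb", "eos_w", "val_w")) {
    for (i in sample(length(m$params[[nm]]), 3)) {
      eps <- 1e-6
      p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      numg <- (loss_of(p1) - loss_of(p2)) / (2 * eps)
      expect_equal(res$grads[[nm]][i], numg, tolerance = 1e-4)
    }
  }
})

test_that("PPO ratios are clipped and zero advantages leave only entropy", {
  m <- small_s2s(N = 6, d = 4, seed = 9)
  epi <- list(study = c(1L, 2L, 4L), actions = c(2L, 7L),
              ret = c(0, 0), oldlogp = c(-1, -1))
  # zero advantages: actor surrogate is exactly 0
  epi$adv <- c(0, 0)
  res <- memsearch:::s2s_ppo_grad_cpp(m$params, unclass(m$config), list(epi),
                                      0.2, 0.01, 0.5)
  expect_equal(res$actor_loss, 0)
  expect_gt(res$entropy, 0)
  # extreme old log-probabilities: surrogate bounded by the clip
  epi$adv <- c(1, 1)
  epi$oldlogp <- c(-50, -50)  # ratio astronomically large
  res2 <- memsearch:::s2s_ppo_grad_cpp(m$params, unclass(m$config), list(epi),
                                       0.2, 0.01, 0.5)
  expect_equal(res2$actor_loss, -1.2, tolerance = 1e-9)
})

test_that("PPO solves a two-action bandit", {
  # single-item lists: the policy must learn to recall the studied item
  cfg <- seq2seq_config(hidden_dim = 4, vocab_size = 2, embed_dim = 3, seed = 3)
  m <- build_model(cfg, tiny_pool(2, 3))
  rl <- rl_config(L = 1, N = 2, max_steps = 1, lr = 0.01, seed = 1)
  adam <- NULL
  set.seed(2)
  for (i in 1:150) {
    eps <- lapply(1:4, function(j) run_episode(m, rl))
    upd <- ppo_update(m, eps, rl, adam)
    m <- upd$model; adam <- upd$adam
  }
  tr <- encode_sequence(m, 1L)
  st <- decode_step(m, NULL, tr$h_L, tr)
  p <- output_distribution(m, st$hhat, tr, 1L)
  expect_gt(unname(p["1"]), 0.9)
})

test_that("supervised training overfits a single repeated trial", {
  pool <- tiny_pool(10, 5)
  cfg <- seq2seq_config(hidden_dim = 16, vocab_size = 10, embed_dim = 5,
                        seed = 21)
  m <- build_model(cfg, pool)
  target <- trial(c(3, 7, 1, 9), c(3, 7, 1, 9), N = 10)
  ds <- dataset(rep(list(target), 30), pool)
  sp <- split_trials(ds, fractions = c(0.8, 0.1, 0.1), seed = 1)
  fit <- train_supervised(m, sp, supervised_config(lr = 0.01, batch_size = 8,
                                                   patience = 5, max_epochs = 60,
                                                   seed = 5))
  expect_lt(utils::tail(fit$trajectory$train_loss, 1), 0.1)
  gen <- generate_recall(fit$model, c(3L, 7L, 1L, 9L), mode = "greedy")
  expect_identical(gen$recall, c(3L, 7L, 1L, 9L))
  expect_true(gen$ended)
})

test_that("early stopping fires after the configured patience", {
  pool <- tiny_pool(8, 4)
  cfg <- seq2seq_config(hidden_dim = 6, vocab_size = 8, embed_dim = 4, seed = 2)
  m <- build_model(cfg, pool)
  ds <- dataset(random_trials(40, 8, 4, seed = 31, p_intrusion = 0,
                              p_repeat = 0), tiny_pool(8, 4))
  sp <- split_trials(ds, fractions = c(0.8, 0.1, 0.1), seed = 2)
  # a huge learning rate makes validation loss worsen quickly
  fit <- train_supervised(m, sp, supervised_config(lr = 2, batch_size = 32,
                                                   patience = 3, max_epochs = 50,
                                                   seed = 3))
  expect_true(fit$stopped_early)
  expect_lte(fit$epochs, fit$best_epoch + 3 + 1)
  # determinism: same seed and data give identical fitted parameters
  m2 <- build_model(cfg, pool)
  fit2 <- train_supervised(m2, sp, supervised_config(lr = 2, batch_size = 32,
                                                     patience = 3, max_epochs = 50,
                                                     seed = 3))
  expect_identical(fit$model$params, fit2$model$params)
})

test_that("short PPO runs checkpoint on schedule and resume identically", {
  rl <- rl_config(L = 3, N = 8, iterations = 40, checkpoint_interval = 10,
                  eval_lists = 50, seed = 6, lr = 0.005)
  mc <- seq2seq_config(hidden_dim = 6, vocab_size = 8, embed_dim = 4, seed = 6)
  traj <- train_rl(rl, mc)
  # 40 iterations at interval 10: epoch-0 snapshot plus 4 checkpoints
  expect_equal(length(traj$checkpoints), 5L)
  expect_equal(traj$epochs$iter, c(10, 20, 30, 40))
  # resumption: interrupt after 20 iterations, then continue to 40
  traj_half <- train_rl(rl, mc, until = 20)
  resumed <- train_rl(rl, mc, resume = traj_half)
  expect_equal(resumed$epochs$mean_reward, traj$epochs$mean_reward)
  expect_identical(resumed$model$params, traj$model$params)
})

test_that("scripted policies produce the expected evaluation curves", {
  # a perfect forward-recall oracle: feed recalls as forced actions
  rl <- rl_config(L = 4, N = 9, max_steps = 8)
  lists <- make_study_lists(9, 4, 25, seed = 11)
  trials <- lapply(seq_len(25), function(i) {
    trial(lists[i, ], lists[i, ], N = 9)
  })
  cv <- behavioral_curves(trials)
  expect_equal(cv$spc, rep(1, 4))
  expect_equal(cv$pfr, c(1, 0, 0, 0))
  expect_equal(cv$crp[match(1, cv$lags)], 1)
  # emit-nothing policy: zero reward, all-zero curves
  rewards <- vapply(seq_len(25), function(i) {
    episode_reward(lists[i, ], integer(0), rl, ended = TRUE)$total
  }, numeric(1))
  expect_true(all(rewards == 0))
  empty <- lapply(seq_len(25), function(i) trial(lists[i, ], integer(0), N = 9))
  cve <- behavioral_curves(empty)
  expect_true(all(cve$spc == 0) && all(cve$pfr == 0))
})
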