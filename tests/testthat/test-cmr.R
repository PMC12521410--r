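test_that("context drift has the closed-form mixing scalar and keeps unit norm", {
  cp <- c(1, 0, 0, 0)
  # collinear input: rho = 1 - beta, context unchanged
  expect_equal(drift_context(cp, cp, 0.6), cp)
  # orthogonal input: rho = sqrt(1 - beta^2)
  d <- drift_context(cp, c(0, 2, 0, 0), 0.6)  # also exercises normalization
  expect_equal(d, c(0.8, 0.6, 0, 0))
  expect_equal(drift_context(cp, c(0, 1, 1, 0), 0), cp)
  # random cases stay unit norm
  set.seed(4)
  for (i in 1:100) {
    c0 <- stats::rnorm(6); c0 <- c0 / sqrt(sum(c0^2))
    x <- stats::rnorm(6)
    b <- stats::runif(1)
    expect_lt(abs(sqrt(sum(drift_context(c0, x, b)^2)) - 1), 1e-6)
  }
  expect_error(drift_context(cp, c(0, 0, 0, 0), 0.5), "zero")
  expect_error(drift_context(cp, cp, 1.2), "beta")
})

test_that("encoding stores pre-item contexts in item columns, transposed pair", {
  par <- cmr_params(beta_enc = 0.55)
  st <- encode_list(par, c(2, 1, 3), 5)
  # column of item studied at position i holds c_{i-1}
  expect_equal(st$M_exp_fc[, 2], st$stored_contexts[1, ])
  expect_equal(st$M_exp_fc[, 1], st$stored_contexts[2, ])
  expect_equal(st$M_exp_fc[, 3], st$stored_contexts[3, ])
  expect_identical(st$M_exp_cf, t(st$M_exp_fc))
  # unstudied columns are zero
  expect_true(all(st$M_exp_fc[, c(4, 5)] == 0))
  # no drift: every stored context equals c0
  st0 <- encode_list(cmr_params(beta_enc = 0), c(2, 1, 3), 5)
  expect_true(all(apply(st0$stored_contexts, 1, identical,
                        st0$stored_contexts[1, ])))
  expect_error(encode_list(par, c(2, 2), 5), "repeated")
})

test_that("context reinstatement returns stored contexts bit-exactly", {
  par <- cmr_params(beta_enc = 0.7)
  st <- encode_list(par, c(4, 1, 5, 2), 6)
  expect_identical(reinstate_context(st, 1), st$stored_contexts[2, ])
  expect_identical(reinstate_context(st, 4), st$stored_contexts[1, ])
  expect_error(reinstate_context(st, 3), "not encoded")
})

test_that("recall-context update reduces to pure drift at the gamma extremes", {
  par0 <- cmr_params(beta_rec = 0.45, gamma_fc = 0)
  st <- encode_list(par0, c(3, 1, 4), 6)
  upd <- update_recall_context(st, 1, par0)
  x <- numeric(6); x[1] <- 1
  expect_equal(upd$c, drift_context(st$c, x, 0.45))
  par1 <- cmr_params(beta_rec = 0.45, gamma_fc = 1)
  upd1 <- update_recall_context(st, 1, par1)
  expect_equal(upd1$c, drift_context(st$c, reinstate_context(st, 1), 0.45))
  # beta' = 0: context unchanged
  parz <- cmr_params(beta_rec = 0, gamma_fc = 0.5)
  expect_equal(update_recall_context(st, 1, parz)$c, st$c)
})

test_that("recall probabilities are a studied-only softmax", {
  par <- cmr_params(k = 0)
  st <- encode_list(par, c(2, 5, 3), 6)
  p <- recall_probabilities(st, par)
  expect_equal(p[c(2, 5, 3)], rep(1 / 3, 3))
  expect_true(all(p[c(1, 4, 6)] == 0))
  # hand softmax: similarities (1,0,0), k = 1
  st$stored_contexts <- diag(6)[1:3, ]
  st$c <- c(1, 0, 0, 0, 0, 0)
  p2 <- recall_probabilities(st, cmr_params(k = 1))
  expect_equal(unname(p2[c(2, 5, 3)]),
               c(exp(1), 1, 1) / (exp(1) + 2), tolerance = 1e-12)
  expect_lt(abs(sum(p2) - 1), 1e-9)
  # large k: argmax takes all the mass
  p3 <- recall_probabilities(st, cmr_params(k = 500))
  expect_gt(p3[2], 0.999)
})

test_that("recall simulation is seed-reproducible and matches the batch path", {
  par <- cmr_params(beta_enc = 0.6, beta_rec = 0.5, gamma_fc = 0.4, k = 5)
  study <- c(2, 7, 4, 1, 6)
  set.seed(11); t1 <- simulate_recall(par, study, 8)
  set.seed(11); t2 <- simulate_recall(par, study, 8)
  expect_identical(t1$recall, t2$recall)
  set.seed(11); batch <- cmr_simulate_lists(par, matrix(study, 1), 8)
  expect_identical(batch[[1]], t1$recall)
  # multi-list batch equals trial-by-trial simulation under one stream
  lists <- make_study_lists(8, 5, 6, seed = 3)
  set.seed(21)
  seq_recalls <- lapply(seq_len(6), function(i) simulate_recall(par, lists[i, ], 8)$recall)
  set.seed(21)
  batch2 <- cmr_simulate_lists(par, lists, 8)
  expect_identical(batch2, seq_recalls)
  # max_attempts = 0: empty recall
  par0 <- cmr_params(max_attempts = 0)
  set.seed(1)
  expect_length(simulate_recall(par0, study, 8)$recall, 0)
})

test_that("simulated recall exhibits temporal contiguity", {
  par <- cmr_params(beta_enc = 0.7, beta_rec = 0.6, gamma_fc = 0.5, k = 8)
  lists <- make_study_lists(12, 8, 1000, seed = 5)
  recalls <- with_seed(6, cmr_simulate_lists(par, lists, 12))
  trials <- lapply(seq_len(1000), function(i) trial(lists[i, ], recalls[[i]], N = 12))
  res <- lag_crp(trials)
  expect_gt(res$crp[match(1, res$lags)], res$crp[match(3, res$lags)])
})

test_that("expected reinstatement equals the brute-force weighted sum", {
  set.seed(9)
  for (i in 1:100) {
    N <- sample(4:10, 1); L <- sample(2:min(8, N - 1), 1)
    par <- cmr_params(beta_enc = stats::runif(1), k = stats::runif(1, 0, 10))
    st <- encode_list(par, sample(N, L), N)
    probe <- stats::rnorm(N); probe <- probe / sqrt(sum(probe^2))
    got <- expected_reinstatement(st, probe, par)
    # term-by-term oracle
    sims <- st$stored_contexts %*% probe
    w <- exp(par$k * sims - max(par$k * sims)); w <- w / sum(w)
    want <- numeric(N)
    for (l in seq_len(L)) want <- want + w[l] * st$stored_contexts[l, ]
    expect_equal(got, want, tolerance = 1e-12)
  }
  # k = 0: simple average of stored contexts
  par <- cmr_params(k = 0)
  st <- encode_list(par, c(1, 3, 5), 6)
  expect_equal(expected_reinstatement(st, st$c, par),
               colMeans(st$stored_contexts))
})
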