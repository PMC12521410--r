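test_that("model building is seed-deterministic with shape-driven parameter counts", {
  m1 <- small_s2s(seed = 42)
  m2 <- small_s2s(seed = 42)
  expect_identical(m1$params, m2$params)
  m3 <- small_s2s(seed = 43)
  expect_false(identical(m1$params, m3$params))
  # closed-form parameter count: embeddings (N+2)*de, two GRUs
  # 3d*(de+d) + 3d, mixing d*2d, output N*d, eos d+1, value d+1
  N <- 6; de <- 5; d <- 4
  expect_equal(n_parameters(m1),
               (N + 2) * de + 2 * (3 * d * (de + d) + 3 * d) + d * 2 * d +
                 N * d + (d + 1) + (d + 1))
  # attention off: mixing layer over h alone
  ma <- small_s2s(attention = FALSE)
  expect_equal(dim(ma$params$Wc), c(4L, 4L))
  expect_equal(dim(m1$params$Wc), c(4L, 8L))
  # hidden 32 vs 128 differ by the computed shape difference
  pool <- tiny_pool(6, 5)
  c32 <- build_model(seq2seq_config(32, 6, 5), pool)
  c128 <- build_model(seq2seq_config(128, 6, 5), pool)
  count <- function(d) (6 + 2) * 5 + 2 * (3 * d * (5 + d) + 3 * d) +
    2 * d * d + 6 * d + 2 * (d + 1)
  expect_equal(n_parameters(c32), count(32))
  expect_equal(n_parameters(c128), count(128))
  # pretrained source requires embeddings
  bare <- wordpool(letters[1:6])
  cfgp <- seq2seq_config(4, 6, 5, embedding_source = "pretrained")
  expect_error(build_model(cfgp, bare), "embeddings")
})

test_that("encoding is deterministic, order-sensitive, and length-matched", {
  m <- small_s2s()
  tr <- encode_sequence(m, c(2, 5, 3))
  expect_equal(dim(tr$H), c(3L, 4L))
  expect_equal(tr$H[3, ], tr$h_L)
  expect_identical(tr, encode_sequence(m, c(2, 5, 3)))
  tr2 <- encode_sequence(m, c(3, 5, 2))
  expect_false(isTRUE(all.equal(tr$h_L, tr2$h_L)))
  one <- encode_sequence(m, 4)
  expect_equal(dim(one$H), c(1L, 4L))
  expect_equal(one$H[1, ], one$h_L)
  expect_error(encode_sequence(m, integer(0)), "empty")
  expect_error(encode_sequence(m, 9), "vocabulary")
})

test_that("attention weights live on the simplex with hand-checked values", {
  m <- small_s2s()
  # identical encoder states: uniform weights
  H <- matrix(rep(c(0.3, -0.2, 0.1, 0.4), each = 3), 3, 4)
  at <- attend(c(1, 0, 0, 0), H)
  expect_equal(at$weights, rep(1 / 3, 3))
  # two orthonormal states probed with the first: softmax of (1, 0)
  H2 <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  at2 <- attend(c(1, 0, 0, 0), H2)
  expect_equal(at2$weights, c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(at2$context, at2$weights[1] * H2[1, ] + at2$weights[2] * H2[2, ])
  # random probes: simplex membership
  set.seed(2)
  tr <- encode_sequence(m, c(1, 4, 6, 2))
  for (i in 1:25) {
    w <- attend(stats::rnorm(4), tr$H)$weights
    expect_true(all(w >= 0))
    expect_lt(abs(sum(w) - 1), 1e-9)
  }
})

test_that("decode steps bound the mixed state and respect the ablation", {
  m <- small_s2s()
  tr <- encode_sequence(m, c(2, 5, 3))
  st <- decode_step(m, NULL, tr$h_L, tr)
  expect_true(all(abs(st$hhat) < 1))
  expect_length(st$weights, 3)
  ma <- small_s2s(attention = FALSE)
  tra <- encode_sequence(ma, c(2, 5, 3))
  sta <- decode_step(ma, NULL, tra$h_L, tra)
  expect_length(sta$weights, 0)
  expect_error(decode_step(m, NULL, numeric(3), tr), "dimension")
})

test_that("output distributions sum to one and honour in-list restriction", {
  study <- c(2, 5, 3)
  m_in <- small_s2s(mode = "in_list")
  tr <- encode_sequence(m_in, study)
  st <- decode_step(m_in, NULL, tr$h_L, tr)
  p <- output_distribution(m_in, st$hhat, tr, study)
  expect_length(p, 4)  # three studied + eos
  expect_lt(abs(sum(p) - 1), 1e-9)
  expect_setequal(names(p), c("2", "5", "3", "<eos>"))
  m_full <- small_s2s(mode = "full_vocab")
  trf <- encode_sequence(m_full, study)
  stf <- decode_step(m_full, NULL, trf$h_L, trf)
  pf <- output_distribution(m_full, stf$hhat, trf, study)
  expect_length(pf, 7)
  expect_lt(abs(sum(pf) - 1), 1e-9)
  # all-equal scores give a uniform distribution
  m0 <- m_in
  m0$params$eos_w[] <- 0; m0$params$eos_b <- 0
  tr0 <- tr; tr0$H <- matrix(0, 3, 4)
  p0 <- output_distribution(m0, st$hhat, tr0, study)
  expect_equal(unname(p0), rep(0.25, 4))
})

test_that("generation is reproducible and the R and compiled paths agree", {
  for (attn in c(TRUE, FALSE)) {
    for (mode in c("full_vocab", "in_list")) {
      m <- small_s2s(N = 7, attention = attn, mode = mode, seed = 19)
      study <- c(2L, 6L, 4L)
      g1 <- generate_recall(m, study, mode = "greedy", engine = "r")
      g2 <- generate_recall(m, study, mode = "greedy", engine = "cpp")
      expect_identical(g1$recall, g2$recall)
      expect_equal(g1$logp, g2$logp, tolerance = 1e-10)
      set.seed(33); s1 <- generate_recall(m, study, mode = "sample", engine = "r")
      set.seed(33); s2 <- generate_recall(m, study, mode = "sample", engine = "cpp")
      expect_identical(s1$recall, s2$recall)
      set.seed(33); s3 <- generate_recall(m, study, mode = "sample", engine = "cpp")
      expect_identical(s2$recall, s3$recall)
    }
  }
  m <- small_s2s(seed = 19)
  one <- generate_recall(m, c(2L, 6L, 4L), mode = "greedy", max_steps = 1)
  expect_lte(length(one$recall), 1)
})

test_that("untrained full-vocab models recall studied items near chance", {
  m <- small_s2s(N = 20, seed = 5)
  lists <- make_study_lists(20, 5, 400, seed = 8)
  acts <- with_seed(9, {
    memsearch:::s2s_generate_many_cpp(m$params, unclass(m$config), lists, 1L, 10L)$actions
  })
  hits <- total <- 0
  for (i in seq_len(400)) {
    a <- acts[i, ]; a <- a[a > 0 & a != 21]
    hits <- hits + sum(a %in% lists[i, ])
    total <- total + length(a)
  }
  # chance level: 5 studied of 20 items
  expect_gt(hits / total, 0.25 - 0.08)
  expect_lt(hits / total, 0.25 + 0.08)
})

test_that("attention reproduces expected context reinstatement exactly", {
  set.seed(14)
  worst <- 0
  for (i in 1:100) {
    N <- sample(6:32, 1)
    L <- sample(2:8, 1)
    par <- cmr_params(beta_enc = stats::runif(1))
    st <- encode_list(par, sample(N, L), N)
    for (k in c(0.5, 1, 5)) {
      worst <- max(worst, attention_equivalence_check(st, k))
    }
  }
  expect_lt(worst, 1e-9)
  # k = 0 probe: both sides are the uniform average of stored contexts
  st <- encode_list(cmr_params(), c(1, 4, 2), 6)
  expect_equal(attend(0 * st$c, st$stored_contexts)$context,
               colMeans(st$stored_contexts))
})

test_that("checkpoints round-trip forward passes bit-exactly", {
  m <- small_s2s(seed = 77)
  dir <- withr::local_tempdir()
  save_checkpoint(m, dir, provenance = list(seed = 77, steps = 0))
  m2 <- load_checkpoint(dir)
  expect_identical(m2$params, m$params)
  study <- c(1L, 5L, 3L)
  expect_identical(generate_recall(m, study, mode = "greedy"),
                   generate_recall(m2, study, mode = "greedy"))
})
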