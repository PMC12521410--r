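# shared fixtures, built in code

tiny_pool <- function(N = 5, d_emb = 3, seed = 101) make_wordpool(N, d_emb, seed)

random_trials <- function(n, N, L, seed = 1, p_intrusion = 0.15, p_repeat = 0.15) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      study <- sample.int(N, L)
      n_out <- sample(0:(L + 2L), 1L)
      recall <- integer(0)
      for (j in seq_len(n_out)) {
        u <- stats::runif(1)
        recall <- c(recall, if (u < p_intrusion && length(setdiff(seq_len(N), study))) {
          sample(setdiff(seq_len(N), study), 1L)
        } else if (u < p_intrusion + p_repeat && length(recall)) {
          sample(recall, 1L)
        } else {
          sample(study, 1L)
        })
      }
      trial(study, recall, participant = "px", session = as.character(i), N = N)
    })
  })
}

# independent brute-force lag-CRP oracle: enumerates transitions and
# possible-lag sets explicitly, trial by trial, with no shared code
crp_oracle <- function(trials, L) {
  lags <- c(-(L - 1):-1, 1:(L - 1))
  made <- possible <- stats::setNames(numeric(length(lags)), lags)
  for (tr in trials) {
    study <- unclass(tr$study)
    # clean: keep only first occurrences of studied items
    seen <- c()
    clean <- c()
    for (it in tr$recall) {
      if (it %in% study && !(it %in% seen)) {
        clean <- c(clean, it)
        seen <- c(seen, it)
      }
    }
    pos <- match(clean, study)
    if (length(pos) < 2) next
    for (j in 1:(length(pos) - 1)) {
      from <- pos[j]
      used <- pos[1:j]
      for (p in setdiff(seq_len(L), used)) {
        lg <- as.character(p - from)
        possible[lg] <- possible[lg] + 1
      }
      made[as.character(pos[j + 1] - from)] <- made[as.character(pos[j + 1] - from)] + 1
    }
  }
  ifelse(possible > 0, made / possible, NA_real_)
}

small_s2s <- function(N = 6, L = 3, d = 4, attention = TRUE,
                      mode = "full_vocab", seed = 7) {
  pool <- tiny_pool(N, 5, seed = 3)
  cfg <- seq2seq_config(hidden_dim = d, vocab_size = N, embed_dim = 5,
                        attention = attention, output_mode = mode, seed = seed)
  build_model(cfg, pool)
}
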