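#' Configuration of the seq2seq memory-search model
#'
#' A GRU encoder-decoder with optional dot-product attention whose retrieval
#' rule scores candidate recalls by the match between the current retrieval
#' state and each studied item's stored encoder state (the CMR-aligned rule),
#' with a learned end-of-sequence logit in the same softmax.
#'
#' @param hidden_dim Hidden state dimension `d` (working-memory capacity
#'   analogue; 32/64/128 in the capacity analyses).
#' @param vocab_size Pool size `N`.
#' @param embed_dim Input embedding dimension (default 50; for
#'   `embedding_source = "pretrained"` the native dimension of the pool's
#'   vectors is used).
#' @param attention Logical; `FALSE` gives the ablated model in which the
#'   mixing layer sees only the decoder state.
#' @param embedding_source `"learned"` (trainable rows), `"random"` (fixed
#'   unit-norm random rows), or `"pretrained"` (fixed rows from the pool's
#'   embeddings). Start/end-of-sequence rows are always learned.
#' @param output_mode `"in_list"` restricts the softmax to the studied items
#'   plus end-of-sequence; `"full_vocab"` scores every pool item (unstudied
#'   items via output embeddings) so that incorrect recalls are expressible,
#'   as reinforcement learning and verbatim supervised targets require.
#' @param score_temperature Multiplier on the retrieval scores before the
#'   softmax.
#' @param seed Seed for parameter initialization.
#' @return An object of class `ms_s2s_config`.
#' @export
seq2seq_config <- function(hidden_dim = 128, vocab_size, embed_dim = 50,
                           attention = TRUE,
                           embedding_source = c("learned", "random", "pretrained"),
                           output_mode = c("full_vocab", "in_list"),
                           score_temperature = 1, seed = 1) {
  embedding_source <- match.arg(embedding_source)
  output_mode <- match.arg(output_mode)
  if (hidden_dim < 1) stop("hidden_dim must be >= 1")
  if (vocab_size < 2) stop("vocab_size must be >= 2")
  structure(list(hidden_dim = as.integer(hidden_dim),
                 vocab_size = as.integer(vocab_size),
                 embed_dim = as.integer(embed_dim),
                 attention = isTRUE(attention),
                 embedding_source = embedding_source,
                 output_mode = output_mode,
                 score_temperature = as.numeric(score_temperature),
                 seed = as.integer(seed)),
            class = "ms_s2s_config")
}

#' Build a seq2seq model
#'
#' Initializes all parameters (uniform in `[-1/sqrt(d), 1/sqrt(d)]`), seeded
#' by `config$seed`; identical seeds give identical models. Embedding rows
#' follow `config$embedding_source`; the model stores which parameters are
#' trainable.
#'
#' @param config [seq2seq_config()].
#' @param pool [wordpool()]; must carry embeddings when
#'   `embedding_source = "pretrained"`.
#' @return An object of class `ms_seq2seq` with fields `params` (named list
#'   of matrices/vectors), `config`, `frozen_emb_rows`.
#' @export
build_model <- function(config, pool) {
  stopifnot(inherits(config, "ms_s2s_config"), inherits(pool, "ms_wordpool"))
  if (pool$N != config$vocab_size) stop("pool size does not match vocab_size")
  if (config$embedding_source == "pretrained") {
    if (is.null(pool$embeddings)) stop("pretrained embedding source requires pool embeddings")
    config$embed_dim <- ncol(pool$embeddings)
  }
  d <- config$hidden_dim; de <- config$embed_dim; N <- config$vocab_size
  with_seed(config$seed, {
    a <- 1 / sqrt(d)
    u <- function(nr, nc) matrix(stats::runif(nr * nc, -a, a), nr, nc)
    emb <- u(N + 2L, de)  # rows 1..N items, N+1 start, N+2 end marker
    frozen <- integer(0)
    if (config$embedding_source == "random") {
      fixed <- matrix(stats::rnorm(N * de), N, de)
      emb[seq_len(N), ] <- fixed / sqrt(rowSums(fixed^2))
      frozen <- seq_len(N)
    } else if (config$embedding_source == "pretrained") {
      emb[seq_len(N), ] <- pool$embeddings
      frozen <- seq_len(N)
    }
    params <- list(
      emb = emb,
      encW = u(3L * d, de), encU = u(3L * d, d), encb = stats::runif(3L * d, -a, a),
      decW = u(3L * d, de), decU = u(3L * d, d), decb = stats::runif(3L * d, -a, a),
      Wc = u(d, if (config$attention) 2L * d else d),
      out_emb = u(N, d),
      # the end-of-sequence bias starts strongly negative so that a policy
      # trained from scratch explores recalling before it learns to stop
      # (see the methods vignette on optimistic-recall initialization)
      eos_w = stats::runif(d, -a, a), eos_b = -8,
      val_w = stats::runif(d, -a, a), val_b = 0)
    structure(list(params = params, config = config, frozen_emb_rows = frozen),
              class = "ms_seq2seq")
  })
}

#' @export
print.ms_seq2seq <- function(x, ...) {
  cat(sprintf("<ms_seq2seq> d=%d N=%d d_emb=%d attention=%s mode=%s (%d parameters)\n",
              x$config$hidden_dim, x$config$vocab_size, x$config$embed_dim,
              x$config$attention, x$config$output_mode, n_parameters(x)))
  invisible(x)
}

#' Total number of model parameters
#' @param model An `ms_seq2seq`.
#' @return Integer count over all parameter arrays.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

gru_cell <- function(W, U, b, x, hprev, d) {
  a <- as.numeric(W %*% x) + b
  au <- as.numeric(U %*% hprev)
  z <- sigmoid(a[1:d] + au[1:d])
  r <- sigmoid(a[(d + 1):(2 * d)] + au[(d + 1):(2 * d)])
  n <- tanh(a[(2 * d + 1):(3 * d)] + r * au[(2 * d + 1):(3 * d)])
  (1 - z) * n + z * hprev
}

#' Encode a study list into the encoder trace
#'
#' Runs the encoder GRU over the item embeddings, storing every hidden state;
#' the trace rows are consulted by both the attention mechanism and the
#' retrieval rule.
#'
#' @param model An `ms_seq2seq`.
#' @param study Integer item indices.
#' @return List with `H` (L x d matrix of hidden states) and `h_L`.
#' @export
encode_sequence <- function(model, study) {
  study <- as.integer(study)
  if (!length(study)) stop("empty study list")
  if (min(study) < 1L || max(study) > model$config$vocab_size) {
    stop("item outside vocabulary")
  }
  p <- model$params; d <- model$config$hidden_dim
  H <- matrix(0, length(study), d)
  h <- numeric(d)
  for (i in seq_along(study)) {
    h <- gru_cell(p$encW, p$encU, p$encb, p$emb[study[i], ], h, d)
    H[i, ] <- h
  }
  list(H = H, h_L = h)
}

#' Dot-product attention over stored encoder states
#'
#' Scores each encoder state by its dot product with the decoder state,
#' softmaxes to attention weights, and returns the weighted sum of encoder
#' states.
#'
#' @param h_j Decoder state (length d).
#' @param H Encoder trace matrix (L x d) or the list from
#'   [encode_sequence()].
#' @return List with `weights` (simplex vector over input positions) and
#'   `context`.
#' @export
attend <- function(h_j, H) {
  if (is.list(H)) H <- H$H
  s <- as.numeric(H %*% h_j)
  s <- s - max(s)
  w <- exp(s); w <- w / sum(w)
  list(weights = w, context = as.numeric(crossprod(H, w)))
}

#' One decoder step
#'
#' Advances the decoder GRU on the embedding of the previous output (the
#' start marker on the first step, when the decoder state is initialized with
#' the final encoder state), applies attention if enabled, and mixes decoder
#' state and attention context through the tanh mixing layer.
#'
#' @param model An `ms_seq2seq`.
#' @param prev_item Previous output item index, or `NULL`/`NA` for the start
#'   marker.
#' @param h_prev Previous decoder state (use `trace$h_L` for the first step).
#' @param trace Encoder trace from [encode_sequence()].
#' @return List with `h` (decoder state), `hhat` (retrieval state),
#'   `weights` (attention weights; length 0 when attention is off).
#' @export
decode_step <- function(model, prev_item, h_prev, trace) {
  p <- model$params; d <- model$config$hidden_dim
  if (length(h_prev) != d) stop("decoder state dimension mismatch")
  row <- if (is.null(prev_item) || is.na(prev_item)) {
    model$config$vocab_size + 1L
  } else {
    as.integer(prev_item)
  }
  h <- gru_cell(p$decW, p$decU, p$decb, p$emb[row, ], h_prev, d)
  if (model$config$attention) {
    at <- attend(h, trace)
    hhat <- tanh(as.numeric(p$Wc %*% c(h, at$context)))
    list(h = h, hhat = hhat, weights = at$weights)
  } else {
    hhat <- tanh(as.numeric(p$Wc %*% h))
    list(h = h, hhat = hhat, weights = numeric(0))
  }
}

#' Output distribution of one decoding step
#'
#' Studied items are scored by the dot product between the retrieval state
#' and their stored encoder state; in `"full_vocab"` mode unstudied items are
#' scored against their output embeddings; the end-of-sequence outcome is a
#' learned projection of the retrieval state. One softmax over all scores.
#' In the attention-ablated model the stored encoder states are not
#' consulted at all in `"full_vocab"` mode — every item is scored from the
#' recurrent state via its output embedding, so recall must be generated
#' from working memory alone (`"in_list"` mode keeps encoder-state scores,
#' since positions are the only addressable outcomes there).
#'
#' @param model An `ms_seq2seq`.
#' @param hhat Retrieval state from [decode_step()].
#' @param trace Encoder trace for the current trial.
#' @param study The trial's study list.
#' @return Named probability vector: in `"in_list"` mode over the L studied
#'   items (by position) plus `"<eos>"`; in `"full_vocab"` mode over all N
#'   items plus `"<eos>"`. Sums to 1; in-list mode assigns 0 mass to
#'   unstudied items by construction.
#' @export
output_distribution <- function(model, hhat, trace, study) {
  p <- model$params; cfg <- model$config
  H <- trace$H
  study <- as.integer(study)
  if (cfg$output_mode == "full_vocab") {
    s <- numeric(cfg$vocab_size + 1L)
    pos <- match(seq_len(cfg$vocab_size), study)
    for (it in seq_len(cfg$vocab_size)) {
      s[it] <- if (cfg$attention && !is.na(pos[it])) sum(hhat * H[pos[it], ]) else
        sum(hhat * p$out_emb[it, ])
    }
    nm <- c(as.character(seq_len(cfg$vocab_size)), "<eos>")
  } else {
    s <- numeric(length(study) + 1L)
    for (l in seq_along(study)) s[l] <- sum(hhat * H[l, ])
    nm <- c(as.character(study), "<eos>")
  }
  s[length(s)] <- sum(p$eos_w * hhat) + p$eos_b
  s <- cfg$score_temperature * s
  s <- s - max(s)
  w <- exp(s)
  stats::setNames(w / sum(w), nm)
}

#' Generate a recall sequence from the model
#'
#' Decodes iteratively, feeding each output back as the next input, until the
#' end-of-sequence outcome or `max_steps`. Sampling uses R's RNG (seed with
#' `set.seed()`); greedy mode is deterministic.
#'
#' @param model An `ms_seq2seq`.
#' @param study Study list (item indices).
#' @param mode `"sample"` or `"greedy"`.
#' @param max_steps Maximum outputs (`>= 1`); default `2 * L`.
#' @param engine `"cpp"` (compiled fast path) or `"r"` (pure-R reference);
#'   both produce identical output for identical seeds.
#' @return List with `recall` (item indices, end marker excluded),
#'   `ended` (logical: emitted end-of-sequence), `attention` (steps x L
#'   matrix), `logp`, `value`.
#' @export
generate_recall <- function(model, study, mode = c("sample", "greedy"),
                            max_steps = NULL, engine = c("cpp", "r")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  study <- as.integer(study)
  if (is.null(max_steps)) max_steps <- 2L * length(study)
  if (max_steps < 1) stop("max_steps must be >= 1")
  cfg <- model$config
  if (engine == "cpp") {
    r <- s2s_rollout_cpp(model$params, unclass(cfg), study,
                         if (mode == "sample") 1L else 0L,
                         as.integer(max_steps), integer(0), TRUE)
    acts <- r$actions
    eos_a <- if (cfg$output_mode == "full_vocab") cfg$vocab_size + 1L else length(study) + 1L
    ended <- length(acts) > 0 && acts[length(acts)] == eos_a
    items <- acts[acts != eos_a]
    if (cfg$output_mode == "in_list") items <- study[items]
    keep <- seq_len(length(acts) - as.integer(ended))
    return(list(recall = items, ended = ended,
                attention = if (nrow(r$attention)) r$attention[keep, , drop = FALSE] else r$attention,
                logp = r$logp, value = r$value))
  }
  trace <- encode_sequence(model, study)
  h <- trace$h_L
  prev <- NULL
  items <- integer(0)
  attn <- NULL
  logp <- value <- numeric(0)
  p <- model$params
  for (t in seq_len(max_steps)) {
    st <- decode_step(model, prev, h, trace)
    dist <- output_distribution(model, st$hhat, trace, study)
    a <- if (mode == "greedy") which.max(dist) else {
      u <- stats::runif(1)
      idx <- which(u <= cumsum(dist) + 1e-15)
      if (length(idx)) idx[1L] else length(dist)
    }
    logp <- c(logp, unname(log(dist[a])))
    value <- c(value, sum(p$val_w * st$hhat) + p$val_b)
    if (names(dist)[a] == "<eos>") {
      return(list(recall = items, ended = TRUE, attention = attn,
                  logp = logp, value = value))
    }
    item <- as.integer(names(dist)[a])
    items <- c(items, item)
    if (length(st$weights)) attn <- rbind(attn, st$weights)
    prev <- item
    h <- st$h
  }
  list(recall = items, ended = FALSE, attention = attn, logp = logp,
       value = value)
}

#' Numerical check of the attention / context-reinstatement equivalence
#'
#' Builds an encoder trace whose rows are the stored pre-item contexts of an
#' encoded CMR state and probes it with `k * c_prev`; the attention context
#' then coincides with the expectation of CMR's reinstated context under the
#' recall distribution defined by `c_prev`. Returns the maximum absolute
#' elementwise difference between the two (0 up to floating-point error).
#'
#' @param cmr_state An encoded `ms_cmr_state`.
#' @param k Retrieval inverse temperature used on both sides.
#' @return Maximum absolute discrepancy.
#' @export
attention_equivalence_check <- function(cmr_state, k = 1) {
  H <- cmr_state$stored_contexts
  c_prev <- cmr_state$c
  att <- attend(k * c_prev, H)
  par <- cmr_params(k = k)
  exp_alpha <- expected_reinstatement(cmr_state, c_prev, par)
  max(abs(att$context - exp_alpha))
}

#' Save a model checkpoint
#'
#' Writes the parameter arrays (RDS archive) plus a JSON sidecar with the
#' full configuration and provenance; [load_checkpoint()] restores forward
#' passes bit-exactly.
#'
#' @param model An `ms_seq2seq`.
#' @param dir Checkpoint directory (created if needed).
#' @param provenance Optional named list (seed, step count, ...) stored in
#'   the sidecar.
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(model, dir, provenance = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$params, file.path(dir, "params.rds"))
  side <- c(unclass(model$config),
            list(frozen_emb_rows = model$frozen_emb_rows,
                 provenance = provenance))
  jsonlite::write_json(side, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param dir Checkpoint directory.
#' @return An `ms_seq2seq`.
#' @export
load_checkpoint <- function(dir) {
  params <- readRDS(file.path(dir, "params.rds"))
  side <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg <- seq2seq_config(hidden_dim = side$hidden_dim,
                        vocab_size = side$vocab_size,
                        embed_dim = side$embed_dim,
                        attention = side$attention,
                        embedding_source = side$embedding_source,
                        output_mode = side$output_mode,
                        score_temperature = side$score_temperature,
                        seed = side$seed)
  structure(list(params = params, config = cfg,
                 frozen_emb_rows = as.integer(side$frozen_emb_rows %||% integer(0))),
            class = "ms_seq2seq")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
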