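# run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification for a synthetic free-recall dataset
#'
#' Describes the shape of a fully synthetic experiment: a pool of `N` items
#' with `d_emb`-dimensional embeddings, `n_lists` study lists of length `L`
#' per mock participant, and one ground-truth CMR parameter set per
#' participant. The defaults emulate the shape of a standard immediate
#' free-recall study (16-item lists).
#'
#' @param N Pool size.
#' @param L List length.
#' @param d_emb Embedding dimension.
#' @param n_lists Lists per participant.
#' @param n_participants Number of mock participants.
#' @param cmr_params List of [cmr_params()], one per participant; defaults to
#'   a documented grid over `beta_enc` and `gamma_fc` (recycled to
#'   `n_participants`) so recovery experiments have known spacing.
#' @param seed Integer seed; all generators are pure functions of
#'   (spec, seed).
#' @return An object of class `ms_synthetic_spec`.
#' @export
synthetic_spec <- function(N = 40, L = 16, d_emb = 50, n_lists = 200,
                           n_participants = 4, cmr_params = NULL, seed = 1) {
  if (L > N) stop("L must be <= N")
  if (min(N, L, d_emb, n_lists, n_participants) < 1) stop("all counts must be >= 1")
  if (is.null(cmr_params)) {
    grid <- expand.grid(beta_enc = c(0.3, 0.5, 0.7, 0.9),
                        gamma_fc = c(0.3, 0.7))
    cmr_params <- lapply(seq_len(n_participants), function(i) {
      g <- grid[((i - 1L) %% nrow(grid)) + 1L, ]
      cmr_params(beta_enc = g$beta_enc, gamma_fc = g$gamma_fc)
    })
  }
  if (length(cmr_params) != n_participants) {
    stop("need one CMR parameter set per participant")
  }
  structure(list(N = N, L = L, d_emb = d_emb, n_lists = n_lists,
                 n_participants = n_participants, cmr_params = cmr_params,
                 seed = seed),
            class = "ms_synthetic_spec")
}

#' Generate a synthetic word pool
#'
#' Tokens are zero-padded numerals (`w0001`, ...) with unit-norm random
#' Gaussian embedding rows.
#'
#' @param N Pool size (`>= 2`).
#' @param d_emb Embedding dimension.
#' @param seed Integer seed.
#' @return An [wordpool()] with embeddings attached.
#' @export
make_wordpool <- function(N, d_emb = 50, seed = 1) {
  if (N < 2) stop("N must be >= 2")
  with_seed(seed, {
    emb <- matrix(stats::rnorm(N * d_emb), N, d_emb)
    emb <- emb / sqrt(rowSums(emb^2))
    wordpool(sprintf("w%04d", seq_len(N)), embeddings = emb)
  })
}

#' Sample study lists without replacement from a pool
#'
#' @param N Pool size (or an `ms_wordpool`).
#' @param L List length (`<= N`).
#' @param n_lists Number of lists.
#' @param seed Integer seed.
#' @return Integer matrix `n_lists x L` of item indices.
#' @export
make_study_lists <- function(N, L, n_lists, seed = 1) {
  if (inherits(N, "ms_wordpool")) N <- N$N
  if (L > N) stop("L must be <= N")
  with_seed(seed, {
    t(vapply(seq_len(max(n_lists, 0L)),
             function(i) sample.int(N, L), integer(L)))
  })
}

#' Simulate a dataset of mock participants from ground-truth CMR parameters
#'
#' For each mock participant, generates fresh study lists and CMR-simulated
#' recall sequences under that participant's ground-truth parameters. The
#' returned truth table enables parameter-recovery scoring.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (an `ms_dataset`) and `truth` (data frame of
#'   per-participant ground-truth parameters).
#' @export
simulate_mock_participants <- function(spec) {
  stopifnot(inherits(spec, "ms_synthetic_spec"))
  pool <- make_wordpool(spec$N, spec$d_emb, seed = spec$seed)
  trials <- list()
  truth <- vector("list", spec$n_participants)
  for (p in seq_len(spec$n_participants)) {
    pid <- sprintf("mock%02d", p)
    par <- spec$cmr_params[[p]]
    lists <- make_study_lists(spec$N, spec$L, spec$n_lists,
                              seed = spec$seed + 1000L * p)
    recalls <- with_seed(spec$seed + 1000L * p + 1L,
                         cmr_simulate_lists(par, lists, spec$N))
    for (i in seq_len(nrow(lists))) {
      trials[[length(trials) + 1L]] <-
        trial(lists[i, ], recalls[[i]], participant = pid,
              session = sprintf("s%03d", i), N = spec$N)
    }
    truth[[p]] <- data.frame(participant = pid, beta_enc = par$beta_enc,
                             beta_rec = par$beta_rec, gamma_fc = par$gamma_fc,
                             k = par$k)
  }
  list(dataset = dataset(trials, pool), truth = do.call(rbind, truth))
}

#' Simulate CMR recalls for many study lists (fast path)
#'
#' Batch equivalent of [simulate_recall()]: identical sampling algorithm and
#' RNG stream, implemented in compiled code. With the same seed,
#' `cmr_simulate_lists(par, lists, N)[[i]]` equals the recalls produced by
#' looping [simulate_recall()] over the rows of `lists`.
#'
#' @param params [cmr_params()].
#' @param lists Integer matrix of study lists (rows).
#' @param N Pool size.
#' @return List of integer recall sequences, one per list.
#' @export
cmr_simulate_lists <- function(params, lists, N) {
  lists <- as.matrix(lists)
  storage.mode(lists) <- "integer"
  max_att <- if (is.null(params$max_attempts)) ncol(lists) else params$max_attempts
  m <- cmr_simulate_cpp(lists, as.integer(N), params$beta_enc, params$beta_rec,
                        params$gamma_fc, params$k, as.integer(max_att))
  lapply(seq_len(nrow(m)), function(i) {
    r <- m[i, ]
    r[r > 0L]
  })
}
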