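#' CMR model parameters
#'
#' Free parameters of the Context Maintenance and Retrieval model as used
#' here: the encoding and recall context drift rates, the mix between
#' pre-experimental and experimental context reinstated by a recalled item,
#' and the retrieval noise (inverse temperature) of the softmax recall rule.
#' The normalizing scalars rho and rho' are derived from the drift rates at
#' every step, not free parameters.
#'
#' @param beta_enc Drift rate at encoding, in `[0, 1]`.
#' @param beta_rec Drift rate at recall, in `[0, 1]`.
#' @param gamma_fc Weight of the experimental (stored) context relative to
#'   the pre-experimental context when a recalled item reinstates context, in
#'   `[0, 1]`.
#' @param k Retrieval inverse temperature, `>= 0`; higher is less noisy.
#' @param max_attempts Maximum number of retrieval attempts per recall
#'   simulation; `NULL` means the list length.
#' @return An object of class `ms_cmr_params`.
#' @export
cmr_params <- function(beta_enc = 0.7, beta_rec = 0.6, gamma_fc = 0.5, k = 8,
                       max_attempts = NULL) {
  chk01 <- function(v, nm) {
    if (!is.finite(v) || v < 0 || v > 1) stop(nm, " must be in [0, 1]")
  }
  chk01(beta_enc, "beta_enc"); chk01(beta_rec, "beta_rec"); chk01(gamma_fc, "gamma_fc")
  if (!is.finite(k) || k < 0) stop("k must be finite and >= 0")
  if (!is.null(max_attempts) && max_attempts < 0) stop("max_attempts must be >= 0")
  structure(list(beta_enc = beta_enc, beta_rec = beta_rec,
                 gamma_fc = gamma_fc, k = k, max_attempts = max_attempts),
            class = "ms_cmr_params")
}

#' @export
print.ms_cmr_params <- function(x, ...) {
  cat(sprintf("<ms_cmr_params> beta_enc %.3f beta_rec %.3f gamma_fc %.3f k %.3f\n",
              x$beta_enc, x$beta_rec, x$gamma_fc, x$k))
  invisible(x)
}

#' Drift a unit context vector toward an input
#'
#' `c = rho * c_prev + beta * x`, where `x` is normalized to unit length
#' before mixing and `rho = sqrt(1 + beta^2((c.x)^2 - 1)) - beta (c.x)` is
#' the unique non-negative scalar keeping `c` on the unit sphere.
#'
#' @param c_prev Unit-norm context vector.
#' @param x Non-zero input context vector (normalized internally).
#' @param beta Drift rate in `[0, 1]`.
#' @return The drifted unit-norm context vector.
#' @export
drift_context <- function(c_prev, x, beta) {
  if (!is.finite(beta) || beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  nx <- sqrt(sum(x^2))
  if (nx == 0) stop("drift input vector is zero")
  x <- x / nx
  cx <- sum(c_prev * x)
  rho <- sqrt(1 + beta^2 * (cx^2 - 1)) - beta * cx
  rho * c_prev + beta * x
}

default_start_context <- function(study, N) {
  free <- setdiff(seq_len(N), unclass(study))
  c0 <- numeric(N)
  if (length(free)) {
    c0[free[1L]] <- 1  # reserved start slot: first pool item not on the list
  } else {
    c0[] <- 1 / sqrt(N)  # whole pool studied: fall back to the uniform unit vector
  }
  c0
}

#' Encode a study list into a CMR state
#'
#' For each position `i = 1..L`, the Hebbian outer-product associations are
#' updated with the pre-item context `c_{i-1}` *before* the context drifts
#' toward the item's pre-experimental context (its one-hot identity, since
#' the pre-experimental item-to-context matrix is the identity). After the
#' list, the experimental item-to-context matrix holds `c_{i-1}` in the
#' column of the item studied at `i`, and the context-to-item matrix is its
#' transpose.
#'
#' @param params [cmr_params()].
#' @param study Study list (integer item indices, no repeats).
#' @param N Pool size (context dimension).
#' @param c0 Optional unit-norm initial context; default is the basis vector
#'   of a reserved start slot outside the studied items.
#' @return An object of class `ms_cmr_state` with fields `c` (current
#'   context), `M_exp_fc`, `M_exp_cf` (N x N), `study`, and
#'   `stored_contexts` (L x N matrix of the pre-item contexts `c_{i-1}`).
#' @export
encode_list <- function(params, study, N, c0 = NULL) {
  study <- study_list(study, N)
  L <- length(study)
  if (is.null(c0)) c0 <- default_start_context(study, N)
  if (abs(sqrt(sum(c0^2)) - 1) > 1e-6) stop("c0 must be unit norm")
  cvec <- c0
  M_fc <- matrix(0, N, N)
  stored <- matrix(0, max(L, 0L), N)
  for (i in seq_len(L)) {
    it <- study[i]
    M_fc[, it] <- M_fc[, it] + cvec    # Hebbian update with the pre-item context
    stored[i, ] <- cvec
    x <- numeric(N); x[it] <- 1        # pre-experimental context of the item
    cvec <- drift_context(cvec, x, params$beta_enc)
  }
  structure(list(c = cvec, M_exp_fc = M_fc, M_exp_cf = t(M_fc),
                 study = study, stored_contexts = stored, N = N),
            class = "ms_cmr_state")
}

#' Reinstate the encoding context of a just-recalled item
#'
#' Applies the experimental item-to-context associations to the item's
#' one-hot identity; for an item studied at position `i` this returns the
#' stored pre-item context `c_{i-1}` exactly.
#'
#' @param state An `ms_cmr_state`.
#' @param prev_item Item index; must have been encoded in the current list.
#' @return The reinstated context vector.
#' @export
reinstate_context <- function(state, prev_item) {
  pos <- match(prev_item, unclass(state$study))
  if (is.na(pos)) stop("item ", prev_item, " was not encoded in this list")
  state$M_exp_fc[, prev_item]
}

#' Update the recall-phase context after a recall
#'
#' `c_j = rho' c_{j-1} + beta' [(1 - gamma_fc) x_j + gamma_fc alpha_j]`,
#' where `x_j` is the recalled item's pre-experimental context, `alpha_j` its
#' reinstated experimental context, and `rho'` the same norm-preserving
#' closed form as in [drift_context()] applied to the normalized bracketed
#' input.
#'
#' @inheritParams reinstate_context
#' @param params [cmr_params()].
#' @return The state with its context updated.
#' @export
update_recall_context <- function(state, prev_item, params) {
  alpha <- reinstate_context(state, prev_item)
  x <- numeric(state$N); x[prev_item] <- 1
  input <- (1 - params$gamma_fc) * x + params$gamma_fc * alpha
  state$c <- drift_context(state$c, input, params$beta_rec)
  state
}

#' Recall probabilities under the current context
#'
#' Activation strengths are the dot products between the current context and
#' each studied item's stored pre-item context; probabilities are a softmax
#' with inverse temperature `k` over the studied items only. Unstudied items
#' have probability exactly 0.
#'
#' @param state An `ms_cmr_state` with at least one encoded item.
#' @param params [cmr_params()].
#' @return Numeric vector of length `N` (over pool items) summing to 1.
#' @export
recall_probabilities <- function(state, params) {
  study <- unclass(state$study)
  if (!length(study)) stop("no items encoded")
  sims <- as.numeric(state$stored_contexts %*% state$c)
  z <- params$k * sims
  z <- z - max(z)
  w <- exp(z)
  p <- numeric(state$N)
  p[study] <- w / sum(w)
  p
}

#' Simulate one free-recall trial from CMR
#'
#' Encodes the list, then repeatedly samples an item from
#' [recall_probabilities()] and reinstates its context via
#' [update_recall_context()], stopping after `max_attempts` samples (default
#' `L`) or when the same item is sampled twice in a row (the second sample is
#' recorded before stopping). Sampling uses R's RNG: seed with `set.seed()`
#' for reproducibility.
#'
#' @param params [cmr_params()].
#' @param study Study list.
#' @param N Pool size.
#' @param participant,session Identifiers for the returned trial.
#' @return An `ms_trial` with the simulated recall sequence.
#' @export
simulate_recall <- function(params, study, N, participant = "cmr", session = "sim") {
  state <- encode_list(params, study, N)
  max_att <- if (is.null(params$max_attempts)) length(study) else params$max_attempts
  out <- integer(0)
  for (t in seq_len(max_att)) {
    p <- recall_probabilities(state, params)
    u <- stats::runif(1)
    study_idx <- unclass(state$study)
    cum <- cumsum(p[study_idx])
    item <- study_idx[which(u <= cum + 1e-15)[1L]]
    out <- c(out, item)
    if (t >= 2L && item == out[t - 1L]) break
    state <- update_recall_context(state, item, params)
  }
  trial(study, out, participant = participant, session = session, N = N)
}

#' Expected reinstated context under the recall distribution
#'
#' The expectation of the reinstated context `alpha` when the next recall is
#' drawn from the softmax distribution defined by a probe context:
#' `sum_i softmax_i(k c_{i-1} . c_probe) c_{i-1}`. This is the CMR side of
#' the attention / context-reinstatement equivalence.
#'
#' @param state An encoded `ms_cmr_state`.
#' @param c_prev Probe context vector.
#' @param params [cmr_params()] supplying `k`.
#' @return Context vector of length `N`.
#' @export
expected_reinstatement <- function(state, c_prev, params) {
  sims <- as.numeric(state$stored_contexts %*% c_prev)
  z <- params$k * sims
  z <- z - max(z)
  w <- exp(z); w <- w / sum(w)
  as.numeric(crossprod(state$stored_contexts, w))
}
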