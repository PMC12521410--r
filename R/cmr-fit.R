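# Small Gaussian-process expected-improvement optimizer used by fit_cmr.
# Squared-exponential kernel on the unit hypercube, observation noise, and
# marginal-likelihood selection of the lengthscale over a fixed grid.

gp_fit <- function(X, y, lengthscales = c(0.1, 0.2, 0.35, 0.6), noise = 0.05) {
  y_mu <- mean(y); y_sd <- stats::sd(y); if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  ys <- (y - y_mu) / y_sd
  D2 <- as.matrix(stats::dist(X))^2
  best <- NULL
  for (ell in lengthscales) {
    K <- exp(-D2 / (2 * ell^2)) + diag(noise^2, nrow(X))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    ll <- -0.5 * sum(ys * alpha) - sum(log(diag(ch)))
    if (!is.finite(ll)) next
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, ell = ell, chol = ch, alpha = alpha)
    }
  }
  c(best, list(X = X, y_mu = y_mu, y_sd = y_sd))
}

gp_predict <- function(gp, Xnew) {
  d2 <- outer(rowSums(Xnew^2), rowSums(gp$X^2), "+") - 2 * Xnew %*% t(gp$X)
  Ks <- exp(-pmax(d2, 0) / (2 * gp$ell^2))
  mu <- as.numeric(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$chol), t(Ks))
  var <- pmax(1 - colSums(v^2), 1e-12)
  list(mu = mu * gp$y_sd + gp$y_mu, sd = sqrt(var) * gp$y_sd)
}

expected_improvement <- function(mu, sd, best) {
  imp <- best - mu
  z <- imp / sd
  imp * stats::pnorm(z) + sd * stats::dnorm(z)
}

cmr_from_unit <- function(u, k_max) {
  cmr_params(beta_enc = u[1], beta_rec = u[2], gamma_fc = u[3],
             k = u[4] * k_max)
}

#' Fit CMR parameters to a dataset's behavioural curves
#'
#' Derivative-free global optimization (Gaussian-process expected
#' improvement over a Latin-hypercube initial design) of the CMR parameters
#' `beta_enc`, `beta_rec`, `gamma_fc`, `k`. Each candidate is scored by
#' simulating `n_sim` recall sequences over the dataset's study lists and
#' summing the min-max-scaled RMSEs between the simulated and observed
#' serial position, first-recall, and lag-CRP curves; the scaling constants
#' are the min/max of each curve's RMSE over all evaluations seen so far in
#' this run, so every curve type contributes comparably. All evaluations
#' share one simulation stream (common random numbers), making the
#' objective deterministic in the parameters.
#'
#' @param ds A nonempty fixed-`L` `ms_dataset`.
#' @param budget Total objective evaluations (default 300).
#' @param seed Seed controlling the design, candidate draws, and the
#'   per-evaluation simulation streams.
#' @param n_sim Simulated lists per evaluation (default 600).
#' @param k_max Upper bound of the searched retrieval-noise range.
#' @param n_init Initial Latin-hypercube evaluations.
#' @return List with `params` (best [cmr_params()]), `objective` (its scaled
#'   objective), `trace` (data frame of all evaluations: parameters, raw
#'   per-curve RMSEs, scaled objective), `n_sim`.
#' @export
fit_cmr <- function(ds, budget = 300, seed = 1, n_sim = 600, k_max = 20,
                    n_init = 40) {
  if (!length(ds$trials)) stop("empty dataset")
  L <- check_fixed_L(ds$trials)
  N <- ds$wordpool$N
  target <- behavioral_curves(ds)
  lists_all <- t(vapply(ds$trials, function(t) as.integer(t$study), integer(L)))
  sim_lists <- lists_all[rep_len(seq_len(nrow(lists_all)), n_sim), , drop = FALSE]
  n_init <- min(n_init, budget)

  evaluate <- function(u, eval_id) {
    par <- cmr_from_unit(u, k_max)
    # common random numbers: one fixed simulation stream for every
    # evaluation, so the objective is a deterministic function of the
    # parameters and the optimizer cannot chase per-evaluation noise
    recalls <- with_seed(seed + 1000003L,
                         cmr_simulate_lists(par, sim_lists, N))
    trials <- lapply(seq_len(nrow(sim_lists)), function(i) {
      trial(sim_lists[i, ], recalls[[i]], N = N)
    })
    r <- fit_error(target, behavioral_curves(trials))$rmse
    # degenerate candidates can yield curves with no defined entries (e.g.
    # no transitions at all); probability curves bound the RMSE by 1, so an
    # undefined curve is scored at that bound
    r[!is.finite(r)] <- 1
    r
  }

  X <- matrix(NA_real_, budget, 4)
  R <- matrix(NA_real_, budget, 3)  # raw per-curve RMSEs
  design <- with_seed(seed, lhs::randomLHS(n_init, 4))
  n_done <- 0L
  for (i in seq_len(n_init)) {
    X[i, ] <- design[i, ]
    R[i, ] <- evaluate(design[i, ], i)
    n_done <- i
  }
  scaled_objective <- function(Rm) {
    # min-max scale each curve's RMSE over the evaluations seen so far;
    # degenerate candidates (scored at the RMSE bound of 1) are kept out of
    # the scaling population so they cannot crush real differences, and are
    # capped at a fixed bad value per curve
    out <- matrix(0, nrow(Rm), ncol(Rm))
    for (j in seq_len(ncol(Rm))) {
      ok <- Rm[, j] < 1
      if (!any(ok)) { out[, j] <- 3; next }
      lo <- min(Rm[ok, j]); hi <- max(Rm[ok, j])
      rng <- max(hi - lo, .Machine$double.eps)
      out[, j] <- pmin((Rm[, j] - lo) / rng, 3)
    }
    rowSums(out)
  }
  while (n_done < budget) {
    y <- scaled_objective(R[seq_len(n_done), , drop = FALSE])
    gp <- gp_fit(X[seq_len(n_done), , drop = FALSE], y)
    cand <- with_seed(seed + n_done, {
      base <- matrix(stats::runif(4 * 500), ncol = 4)
      jit <- matrix(stats::rnorm(4 * 100, sd = 0.07), ncol = 4)
      local <- sweep(jit, 2, X[which.min(y), ], "+")
      rbind(base, pmin(pmax(local, 0), 1))
    })
    pr <- gp_predict(gp, cand)
    ei <- expected_improvement(pr$mu, pr$sd, min(y))
    u <- cand[which.max(ei), ]
    n_done <- n_done + 1L
    X[n_done, ] <- u
    R[n_done, ] <- evaluate(u, n_done)
  }
  y <- scaled_objective(R)
  best <- which.min(y)
  trace <- data.frame(beta_enc = X[, 1], beta_rec = X[, 2], gamma_fc = X[, 3],
                      k = X[, 4] * k_max, rmse_spc = R[, 1], rmse_pfr = R[, 2],
                      rmse_crp = R[, 3], objective = y)
  list(params = cmr_from_unit(X[best, ], k_max), objective = y[best],
       trace = trace, n_sim = n_sim)
}
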