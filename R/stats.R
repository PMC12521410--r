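# Exact null distribution of the positive-rank sum W for n untied pairs:
# counts over W = 0..n(n+1)/2 of the 2^n equally likely sign assignments,
# built by the standard convolution over ranks (equivalent to enumeration).
signed_rank_counts <- function(n) {
  maxW <- n * (n + 1L) / 2L
  f <- numeric(maxW + 1L)
  f[1L] <- 1
  for (r in seq_len(n)) {
    g <- f
    g[(r + 1L):(maxW + 1L)] <- g[(r + 1L):(maxW + 1L)] + f[1L:(maxW + 1L - r)]
    f <- g
  }
  f
}

signed_rank_p <- function(W, n, alternative, method, correction = FALSE) {
  maxW <- n * (n + 1) / 2
  if (W < 0 || W > maxW) stop("W out of range [0, ", maxW, "]")
  if (method == "exact") {
    counts <- signed_rank_counts(n)
    total <- 2^n
    p_ge <- sum(counts[(W + 1L):(maxW + 1L)]) / total
    p_le <- sum(counts[1L:(W + 1L)]) / total
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    list(p = p, z = NA_real_)
  } else {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    cc <- if (correction) 0.5 else 0
    z <- switch(alternative,
                greater = (W - mu - cc) / sigma,
                less = (W - mu + cc) / sigma,
                two.sided = (W - mu - sign(W - mu) * cc) / sigma)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
    list(p = p, z = z)
  }
}

#' Wilcoxon signed-rank test
#'
#' Paired signed-rank test with the statistic `W` defined as the sum of the
#' ranks of the positive differences. The exact method computes the null
#' distribution of `W` over all `2^n` sign assignments (by convolution over
#' ranks, which enumerates exactly); the normal method uses
#' `z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24)` with no continuity correction
#' unless requested. Zero differences are dropped with a warning and `n`
#' reduced. Ties among the absolute differences are an error under the exact
#' method (use `method = "normal"`).
#'
#' @param x Numeric vector: either the paired differences (when `y` is NULL)
#'   or the first condition.
#' @param y Optional second condition, paired with `x`.
#' @param alternative One of `"two.sided"`, `"greater"`, `"less"` (direction
#'   refers to `x - y`).
#' @param method `"auto"` (exact when `n <= 25` and there are no ties among
#'   the absolute differences, else normal), `"exact"`, or `"normal"`.
#' @param correction Apply a continuity correction in the normal
#'   approximation (default FALSE).
#' @return List with `W`, `n` (after dropping zeros), `p`, `method` used, and
#'   `z` (NA for exact).
#' @examples
#' # thirteen positive differences of distinct magnitude: p = 1/8192
#' wilcoxon_signed_rank(seq_len(13) / 10, alternative = "greater")$p
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two.sided", "greater", "less"),
                                 method = c("auto", "exact", "normal"),
                                 correction = FALSE) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (!length(d)) stop("no pairs supplied")
  nz <- d != 0
  if (any(!nz)) {
    warning(sum(!nz), " zero difference(s) dropped; n reduced to ", sum(nz))
    d <- d[nz]
  }
  n <- length(d)
  if (n == 0L) stop("all differences are zero: no informative pairs")
  ranks <- rank(abs(d))
  ties <- anyDuplicated(ranks) > 0L
  W <- sum(ranks[d > 0])
  if (method == "auto") method <- if (n <= 25L && !ties) "exact" else "normal"
  if (method == "exact" && ties) {
    stop("ties among absolute differences: exact method unavailable, use method = 'normal'")
  }
  res <- signed_rank_p(W, n, alternative, method, correction)
  list(W = W, n = n, p = res$p, method = method, z = res$z)
}

#' Wilcoxon signed-rank p-value from a printed statistic
#'
#' Recomputes the p-value from a reported `(W, n)` pair, for checking
#' published inferential statistics without the raw differences.
#'
#' @param W Sum of positive ranks.
#' @param n Number of informative (non-zero) pairs.
#' @inheritParams wilcoxon_signed_rank
#' @return List with `W`, `n`, `p`, `method`, `z`.
#' @export
wilcoxon_from_stat <- function(W, n,
                               alternative = c("two.sided", "greater", "less"),
                               method = c("exact", "normal"),
                               correction = FALSE) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  res <- signed_rank_p(W, n, alternative, method, correction)
  list(W = W, n = n, p = res$p, method = method, z = res$z)
}

#' Matched-pairs rank-biserial correlation
#'
#' Effect size for the signed-rank test:
#' `r = (sum of positive ranks - sum of negative ranks) / total rank sum`,
#' i.e. `r = (2W - T) / T` with `T = n(n+1)/2`.
#'
#' @param W Sum of positive ranks.
#' @param n Number of pairs.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' rank_biserial(29, 13)  # about -0.363
#' @export
rank_biserial <- function(W, n) {
  T <- n * (n + 1) / 2
  if (W < 0 || W > T) stop("W out of range [0, ", T, "]")
  (2 * W - T) / T
}

#' Compare two models over paired units
#'
#' Builds the paired comparison (e.g. per-seed mean recall probability or
#' per-participant curve RMSE under two model variants), runs the Wilcoxon
#' signed-rank test (exact when `n <= 25` and untied, else normal) and the
#' rank-biserial effect size.
#'
#' @param results_a,results_b Numeric vectors over the same units (same seeds
#'   or participants), compared as `a - b`.
#' @param alternative Passed to [wilcoxon_signed_rank()].
#' @return List with `n`, `W`, `p`, `method`, `rank_biserial`, `mean_diff`,
#'   or a report with `message = "no informative pairs"` when all differences
#'   are zero.
#' @export
compare_paired_models <- function(results_a, results_b,
                                  alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(results_a) != length(results_b)) stop("mismatched units: lengths differ")
  d <- as.numeric(results_a) - as.numeric(results_b)
  if (all(d == 0)) {
    return(list(n = 0L, W = NA_real_, p = NA_real_, method = NA_character_,
                rank_biserial = NA_real_, mean_diff = 0,
                message = "no informative pairs"))
  }
  wt <- suppressWarnings(wilcoxon_signed_rank(d, alternative = alternative))
  c(wt[c("n", "W", "p", "method")],
    list(rank_biserial = rank_biserial(wt$W, wt$n), mean_diff = mean(d)))
}

#' Average a stack of attention heat-maps across trials
#'
#' Element-wise mean of per-trial attention matrices (rows = decoding steps,
#' columns = input positions). Trials whose recall ended earlier contribute
#' missing rows, which are excluded from the mean for those steps; rows that
#' averaged only simplex rows remain on the simplex.
#'
#' @param stack List of numeric matrices with the same number of columns;
#'   row counts may differ (shorter recalls).
#' @return The mean matrix (`max rows x L`).
#' @export
attention_heatmap <- function(stack) {
  stack <- Filter(function(m) !is.null(m) && nrow(m) > 0, stack)
  if (!length(stack)) stop("empty heat-map stack")
  Lset <- unique(vapply(stack, ncol, integer(1)))
  if (length(Lset) > 1L) stop("attention matrices have differing column counts")
  L <- Lset
  R <- max(vapply(stack, nrow, integer(1)))
  acc <- matrix(0, R, L)
  cnt <- numeric(R)
  for (m in stack) {
    r <- nrow(m)
    acc[seq_len(r), ] <- acc[seq_len(r), ] + m
    cnt[seq_len(r)] <- cnt[seq_len(r)] + 1
  }
  sweep(acc, 1L, cnt, "/")
}
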