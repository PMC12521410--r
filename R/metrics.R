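#' Classify recall events as first correct recalls, repeats, or intrusions
#'
#' Each output is labelled relative to the trial's study list:
#' `correct-first` for the first recall of a studied item, `repeat` for a
#' studied item recalled before, and `intrusion` for an item not on the list.
#'
#' @param trial An `ms_trial` (fields `study`, `recall`).
#' @return Character vector of labels, one per recall output.
#' @examples
#' t <- trial(c(1, 2, 3), c(2, 2, 9), N = 10)
#' classify_recalls(t)  # correct-first, repeat, intrusion
#' @export
classify_recalls <- function(trial) {
  study <- unclass(trial$study)
  out <- trial$recall
  labels <- character(length(out))
  seen <- logical(max(c(study, out, 1L)))
  for (j in seq_along(out)) {
    it <- out[j]
    if (!(it %in% study)) {
      labels[j] <- "intrusion"
    } else if (seen[it]) {
      labels[j] <- "repeat"
    } else {
      labels[j] <- "correct-first"
      seen[it] <- TRUE
    }
  }
  labels
}

ms_trials_of <- function(x) {
  if (inherits(x, "ms_dataset")) x$trials else x
}

check_fixed_L <- function(trials) {
  Ls <- vapply(trials, function(t) length(t$study), integer(1))
  if (!length(Ls)) stop("no trials")
  if (length(unique(Ls)) > 1L) stop("mixed list lengths across trials")
  Ls[1L]
}

# serial positions (1..L) of the correct-first recalls of a trial, in order
correct_first_positions <- function(trial) {
  study <- unclass(trial$study)
  lab <- classify_recalls(trial)
  match(trial$recall[lab == "correct-first"], study)
}

#' Serial position curve
#'
#' For each study position `p`, the fraction of trials in which the item
#' studied at `p` is recalled at least once (repeats are not double-counted).
#'
#' @param trials An `ms_dataset` or list of `ms_trial`.
#' @return Numeric vector of length `L`, serial positions 1..L.
#' @export
serial_position_curve <- function(trials) {
  trials <- ms_trials_of(trials)
  L <- check_fixed_L(trials)
  counts <- numeric(L)
  for (t in trials) {
    counts <- counts + as.numeric(seq_len(L) %in% correct_first_positions(t))
  }
  counts / length(trials)
}

#' Probability of first recall
#'
#' For each study position `p`, the fraction of trials whose first correct
#' (non-intrusion) recall is the item studied at `p`. Trials with no correct
#' recall contribute to no bin, so the curve sums to the fraction of trials
#' with at least one correct recall.
#'
#' @inheritParams serial_position_curve
#' @return Numeric vector of length `L`.
#' @export
probability_first_recall <- function(trials) {
  trials <- ms_trials_of(trials)
  L <- check_fixed_L(trials)
  counts <- numeric(L)
  for (t in trials) {
    pos <- correct_first_positions(t)
    if (length(pos)) counts[pos[1L]] <- counts[pos[1L]] + 1
  }
  counts / length(trials)
}

#' Lag conditional response probability (lag-CRP)
#'
#' The probability of making a recall transition of a given study-position
#' lag, normalized by the number of times that lag was available. Repeats and
#' intrusions are removed before transitions are counted, and at each
#' transition the available lags exclude already-recalled items. Lags with no
#' opportunities are reported as `NA` (missing), never imputed as 0.
#'
#' @inheritParams serial_position_curve
#' @return A list with `lags` (-(L-1)..-1, 1..(L-1)), `crp`, and the raw
#'   `made`/`possible` counts.
#' @export
lag_crp <- function(trials) {
  trials <- ms_trials_of(trials)
  L <- check_fixed_L(trials)
  lags <- c(-(L - 1L):-1L, 1L:(L - 1L))
  made <- possible <- stats::setNames(numeric(length(lags)), lags)
  for (t in trials) {
    pos <- correct_first_positions(t)
    if (length(pos) < 2L) next
    for (j in seq_len(length(pos) - 1L)) {
      cur <- pos[j]
      recalled <- pos[seq_len(j)]
      avail <- setdiff(seq_len(L), recalled)
      poss_lags <- as.character(avail - cur)
      possible[poss_lags] <- possible[poss_lags] + 1
      made[as.character(pos[j + 1L] - cur)] <- made[as.character(pos[j + 1L] - cur)] + 1
    }
  }
  crp <- ifelse(possible > 0, made / possible, NA_real_)
  list(lags = lags, crp = unname(crp), made = unname(made),
       possible = unname(possible))
}

#' Compute all three behavioural curves for a set of trials
#'
#' @inheritParams serial_position_curve
#' @return An object of class `ms_curves` with `L`, `spc`, `pfr`, `lags`,
#'   `crp`.
#' @export
behavioral_curves <- function(trials) {
  trials <- ms_trials_of(trials)
  L <- check_fixed_L(trials)
  cr <- lag_crp(trials)
  structure(list(L = L,
                 spc = serial_position_curve(trials),
                 pfr = probability_first_recall(trials),
                 lags = cr$lags, crp = cr$crp),
            class = "ms_curves")
}

#' @export
print.ms_curves <- function(x, ...) {
  cat("<ms_curves> L =", x$L,
      sprintf("| mean SPC %.3f | PFR mode at %d | CRP(+1) %.3f\n",
              mean(x$spc), which.max(x$pfr),
              x$crp[match(1L, x$lags)]))
  invisible(x)
}

rmse_defined <- function(a, b) {
  keep <- is.finite(a) & is.finite(b)
  if (!any(keep)) return(NA_real_)
  sqrt(mean((a[keep] - b[keep])^2))
}

#' Per-curve RMSE between two sets of behavioural curves
#'
#' Root-mean-square error for each curve type over its defined (non-missing)
#' entries, plus their unweighted sum. Min-max scaling of the three RMSEs for
#' the fitting objective is applied by the optimizer over its own population
#' of evaluations (see [fit_cmr()]); optional `scale` ranges reproduce that
#' scaled aggregate here.
#'
#' @param curves_a,curves_b `ms_curves` objects over the same list length.
#' @param scale Optional list with `min` and `max` numeric vectors of length 3
#'   (spc, pfr, crp order) used to min-max scale each RMSE before summing.
#' @return List with `rmse` (named length-3 vector), `aggregate`.
#' @export
fit_error <- function(curves_a, curves_b, scale = NULL) {
  if (curves_a$L != curves_b$L) stop("curves have different list lengths")
  r <- c(spc = rmse_defined(curves_a$spc, curves_b$spc),
         pfr = rmse_defined(curves_a$pfr, curves_b$pfr),
         crp = rmse_defined(curves_a$crp, curves_b$crp))
  agg <- if (is.null(scale)) {
    sum(r)
  } else {
    rng <- pmax(scale$max - scale$min, .Machine$double.eps)
    sum((r - scale$min) / rng)
  }
  list(rmse = r, aggregate = agg)
}

#' Recall-initiation and backward-transition summaries of a curve set
#'
#' Summaries used to track training trajectories: the probability of
#' initiating recall from the last three or first three list positions and
#' the conditional response probability at lag -1.
#'
#' @param curves An `ms_curves` object with `L >= 3`.
#' @return Named numeric vector `init_last3`, `init_first3`, `crp_minus1`.
#' @export
trajectory_summaries <- function(curves) {
  L <- curves$L
  if (L < 3L) stop("trajectory summaries require L >= 3")
  c(init_last3 = sum(curves$pfr[(L - 2L):L]),
    init_first3 = sum(curves$pfr[1:3]),
    crp_minus1 = curves$crp[match(-1L, curves$lags)])
}

#' Serialize behavioural curves to JSON
#'
#' @param curves An `ms_curves` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  obj <- list(L = curves$L, spc = curves$spc, pfr = curves$pfr,
              crp_lags = curves$lags, crp = curves$crp)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read behavioural curves from JSON written by [write_curves()]
#' @param path Input path.
#' @return An `ms_curves` object.
#' @export
read_curves <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(L = as.integer(obj$L), spc = as.numeric(obj$spc),
                 pfr = as.numeric(obj$pfr), lags = as.integer(obj$crp_lags),
                 crp = as.numeric(obj$crp)),
            class = "ms_curves")
}
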