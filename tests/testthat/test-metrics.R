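test_that("recall events are classified deterministically", {
  t1 <- trial(c(1, 2, 3), c(2, 2, 9), N = 10)
  expect_equal(classify_recalls(t1), c("correct-first", "repeat", "intrusion"))
  expect_equal(classify_recalls(trial(c(1, 2), integer(0), N = 5)), character(0))
  t2 <- trial(c(4, 5, 6), c(6, 4, 5), N = 10)
  expect_equal(classify_recalls(t2), rep("correct-first", 3))
})

test_that("serial position and first-recall curves count correctly", {
  a <- trial(c(1, 2, 3), c(1), N = 5)
  expect_equal(serial_position_curve(list(a)), c(1, 0, 0))
  perfect <- trial(c(1, 2, 3), c(3, 2, 1), N = 5)
  expect_equal(serial_position_curve(list(perfect)), c(1, 1, 1))
  b <- trial(c(1, 2, 3), c(2), N = 5)
  expect_equal(serial_position_curve(list(a, b)), c(0.5, 0.5, 0))
  # pfr: intrusion before first correct does not count; empty contributes nowhere
  c1 <- trial(c(1, 2, 3), c(5, 1), N = 5)
  c2 <- trial(c(1, 2, 3), c(1, 3), N = 5)
  c3 <- trial(c(1, 2, 3), c(2), N = 5)
  c4 <- trial(c(1, 2, 3), integer(0), N = 5)
  expect_equal(probability_first_recall(list(c1, c2, c3, c4)),
               c(0.5, 0.25, 0))
  expect_error(serial_position_curve(list(a, trial(c(1, 2), 1, N = 5))), "mixed")
})

test_that("lag-CRP matches the hand-worked five-item example", {
  tr <- trial(1:5, c(2, 3, 5), N = 8)
  res <- lag_crp(list(tr))
  expect_equal(res$crp[match(1, res$lags)], 0.5)
  expect_equal(res$crp[match(2, res$lags)], 0.5)
  # forward serial recall: crp(+1) = 1, all other defined lags 0
  fwd <- trial(1:5, 1:5, N = 8)
  res2 <- lag_crp(list(fwd))
  expect_equal(res2$crp[match(1, res2$lags)], 1)
  defined <- which(!is.na(res2$crp) & res2$lags != 1)
  expect_true(all(res2$crp[defined] == 0))
  # single-item recalls only: no transitions, all lags missing
  res3 <- lag_crp(list(trial(1:5, 3, N = 8)))
  expect_true(all(is.na(res3$crp)))
})

test_that("lag-CRP agrees with the brute-force transition enumerator", {
  for (L in c(4, 6, 8)) {
    trials <- random_trials(300, L + 3, L, seed = 40 + L)
    res <- lag_crp(trials)
    expect_equal(res$crp, unname(crp_oracle(trials, L)))
  }
})

test_that("curves are invariant to trial order", {
  trials <- random_trials(50, 9, 5, seed = 9)
  shuffled <- with_seed(2, sample(trials))
  expect_equal(behavioral_curves(trials), behavioral_curves(shuffled))
})

test_that("fit_error computes per-curve RMSE and symmetric aggregate", {
  trials <- random_trials(30, 9, 5, seed = 12)
  cv <- behavioral_curves(trials)
  fe <- fit_error(cv, cv)
  expect_equal(unname(fe$rmse), c(0, 0, 0))
  cv2 <- cv
  cv2$spc <- rev(cv$spc)
  cv_a <- behavioral_curves(random_trials(30, 9, 5, seed = 13))
  expect_equal(fit_error(cv, cv_a)$aggregate, fit_error(cv_a, cv)$aggregate)
  # hand value: spc (1,0) vs (0,1) -> RMSE 1
  x <- structure(list(L = 2L, spc = c(1, 0), pfr = c(1, 0), lags = c(-1L, 1L),
                      crp = c(0, 0)), class = "ms_curves")
  y <- structure(list(L = 2L, spc = c(0, 1), pfr = c(1, 0), lags = c(-1L, 1L),
                      crp = c(0, 0)), class = "ms_curves")
  expect_equal(unname(fit_error(x, y)$rmse["spc"]), 1)
})

test_that("trajectory summaries project initiation and backward transitions", {
  trials <- random_trials(40, 20, 16, seed = 3)
  cv <- behavioral_curves(trials)
  s <- trajectory_summaries(cv)
  expect_equal(unname(s["init_first3"]), sum(cv$pfr[1:3]))
  expect_equal(unname(s["crp_minus1"]), cv$crp[match(-1, cv$lags)])
  cv$pfr <- c(1, rep(0, 15))
  s2 <- trajectory_summaries(cv)
  expect_equal(unname(s2[c("init_last3", "init_first3")]), c(0, 1))
  cv$L <- 2L
  expect_error(trajectory_summaries(cv), "L >= 3")
})

test_that("curves serialize to JSON and back with missing lags preserved", {
  trials <- random_trials(10, 8, 4, seed = 77)
  cv <- behavioral_curves(trials)
  path <- withr::local_tempfile(fileext = ".json")
  write_curves(cv, path)
  cv2 <- read_curves(path)
  expect_equal(cv2$spc, cv$spc)
  expect_equal(cv2$crp, cv$crp)
  expect_equal(cv2$lags, cv$lags)
})
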