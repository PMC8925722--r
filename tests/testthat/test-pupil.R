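# Pupil pipeline: filtering, preprocessing, responses, design, regression.

test_that("Butterworth filter matches its analytic magnitude response", {
  fs <- 20
  tt <- seq(0, 200, by = 1 / fs)
  for (f in c(1, 2, 8)) {
    x <- sin(2 * pi * f * tt)
    y <- butter_filtfilt(x, fs, fc = 4)
    mid <- seq(round(length(x) * .25), round(length(x) * .75))
    gain <- sd(y[mid]) / sd(x[mid])
    # two passes square the single-pass magnitude
    expected <- matchpennies:::.butter_gain_sq(f, 4, fs)
    expect_equal(gain, expected, tolerance = 0.02)
  }
  # an 8-Hz sinusoid is crushed well below 10% of its input amplitude
  x8 <- sin(2 * pi * 8 * tt)
  expect_lt(max(abs(butter_filtfilt(x8, fs, 4)[500:3500])), 0.1)
})

test_that("moving statistics agree with naive windowed computation", {
  set.seed(42)
  x <- rnorm(500)
  x[sample(500, 20)] <- NA
  ms <- matchpennies:::.moving_stats(x, 101L)
  for (i in c(1, 37, 250, 490, 500)) {
    w <- x[max(1, i - 50):min(500, i + 50)]
    expect_equal(ms$mean[i], mean(w, na.rm = TRUE))
    expect_equal(ms$sd[i], sd(w[!is.na(w)]))
  }
})

test_that("preprocessing guards degenerate traces and masks MAD outliers", {
  z <- preprocess_trace(rep(3, 15000), fs = 20)$z
  expect_true(all(z == 0))

  set.seed(42)
  x <- rnorm(30000)
  spike_at <- 15000L
  x[spike_at] <- 10 * sd(x)
  tr <- preprocess_trace(x, fs = 20)
  # oracle: apply the MAD arithmetic to the filtered trace directly
  filt <- butter_filtfilt(x, 20, 4)
  bad <- abs(filt - median(filt)) > 3 * mad(filt)
  expect_identical(tr$valid, !bad)
  expect_false(tr$valid[spike_at])
  expect_true(is.na(tr$z[spike_at]))
  expect_false(anyNA(tr$z_filled))

  expect_warning(preprocess_trace(rnorm(1000), fs = 20), "shorter than")
})

test_that("the processing order filter -> mask -> z-score is locked in", {
  set.seed(42)
  x <- rnorm(30000, sd = 1)
  x[2000] <- 40  # large spike
  tr <- preprocess_trace(x, fs = 20)
  # masking operates on the *filtered* trace: the spike is smeared by the
  # lowpass, so several neighbouring frames fall beyond the MAD bound,
  # whereas masking the raw trace would flag exactly one frame
  filt <- butter_filtfilt(x, 20, 4)
  n_masked_filtered <- sum(abs(filt - median(filt)) > 3 * mad(filt))
  n_masked_raw <- sum(abs(x - median(x)) > 3 * mad(x))
  expect_equal(sum(!tr$valid), n_masked_filtered)
  expect_gt(n_masked_filtered, n_masked_raw)
})

test_that("trial responses are baseline-subtracted bin means", {
  fs <- 20
  n <- 20000
  cue <- c(100, 200, 300)
  z <- rep(0, n)
  tt <- (seq_len(n) - 1) / fs
  # boxcar of height 1 on [0, 2] s after the second cue only
  z[tt >= cue[2] & tt < cue[2] + 2] <- 1
  tr <- structure(list(z_filled = z, time = tt, fs = fs, cue_times = cue),
                  class = "pupil_trace")
  resp <- trial_responses(tr)
  centers <- attr(resp, "bin_centers")
  expect_equal(ncol(resp), 80L)
  expect_equal(nrow(resp), 3L)
  expect_true(all(abs(resp[1, ]) < 1e-12))
  on_bins <- centers > 0.05 & centers < 1.95
  expect_true(all(resp[2, on_bins] == 1))
  base_bins <- centers > -1.95 & centers < -1.05
  expect_true(all(resp[2, base_bins] == 0))
  # recomputation is idempotent
  expect_identical(unclass(resp), unclass(trial_responses(tr)))
})

test_that("trials whose window leaves the trace are dropped with a message", {
  fs <- 20
  tr <- structure(list(z_filled = rep(0, 2000), time = (0:1999) / fs,
                       fs = fs, cue_times = c(1, 50, 99.9)),
                  class = "pupil_trace")
  expect_message(resp <- trial_responses(tr), "dropped")
  expect_equal(attr(resp, "trials"), 2L)
  expect_equal(attr(resp, "dropped"), c(1L, 3L))
})

test_that("design matrices implement the documented regressor structure", {
  set.seed(42)
  n <- 40
  ch <- sample(c("L", "R"), n, replace = TRUE)
  out <- sample(0:1, n, replace = TRUE)
  s <- mp_session(ch, out)
  X <- build_design(s, design = "observable")
  expect_equal(nrow(X), n - 3)          # drops first two and last trial
  expect_equal(attr(X, "trials"), 3:(n - 1))
  # dummy coding: 0 = left, 1 = right
  expect_equal(X$c_cur, as.numeric(ch[3:(n - 1)] == "R"))
  expect_equal(X$r_prev2, as.numeric(out[1:(n - 3)]))
  expect_equal(X$cxr_cur, X$c_cur * X$r_cur)
  # r_cum is nondecreasing and reaches 1 on the last rewarded trial
  expect_true(all(diff(X$r_cum) >= 0))
  expect_lte(max(X$r_cum), 1)

  # all-rewarded session: moving average identically 1, r_cum a ramp
  s1 <- mp_session(ch, rep(1, n))
  X1 <- build_design(s1, design = "observable")
  expect_true(all(X1$r_ma == 1))
  expect_equal(X1$r_cum, (3:(n - 1)) / n)
})

test_that("the 20-trial moving average window excludes old rewards as printed", {
  # reward only on trial 2: the window n-19 .. n still contains trial 2 at
  # n = 21 and first excludes it at n = 22
  out <- rep(0, 30); out[2] <- 1
  s <- mp_session(rep("L", 30), out)
  X <- build_design(s, design = "observable")
  tr_idx <- attr(X, "trials")
  expect_equal(X$r_ma[tr_idx == 21], 1 / 20)
  expect_equal(X$r_ma[tr_idx == 22], 0)
  # early trials renormalize over the available history
  expect_equal(X$r_ma[tr_idx == 4], 1 / 4)
  expect_true(attr(X, "early_ma"))
})

test_that("selection and updating designs pull latent variables from the trajectory", {
  set.seed(42)
  p <- default_hybrid_params()
  sim <- simulate_session(p, "matching_pennies", 60)
  X12 <- build_design(sim$session, sim$trajectory, "selection")
  X13 <- build_design(sim$session, sim$trajectory, "updating")
  idx <- attr(X13, "trials")
  expect_equal(X13$rpe, sim$trajectory$rpe[idx])
  expect_equal(X13$cke, sim$trajectory$cke[idx])
  expect_equal(X12$dq, sim$trajectory$dq[attr(X12, "trials")])
  expect_error(build_design(sim$session, NULL, "updating"), "trajectory")
})

test_that("per-bin OLS recovers a noiseless planted response exactly", {
  set.seed(42)
  n <- 120
  s <- mp_session(sample(c("L", "R"), n, replace = TRUE),
                  sample(0:1, n, replace = TRUE))
  X <- build_design(s, design = "observable")
  idx <- attr(X, "trials")
  # plant response = 2 * r_cur on bins 41..70, zero elsewhere, no noise
  Y <- matrix(0, length(idx), 80)
  Y[, 41:70] <- 2 * X$r_cur
  resp <- structure(Y, bin_centers = seq(-3, 5, by = .1)[-1] - .05,
                    trials = idx,
                    class = c("trial_response_matrix", "matrix", "array"))
  rs <- regress_and_summarize(resp, X, n_boot = 0)
  expect_equal(unname(rs$coef["r_cur", 41:70, 1]), rep(2, 30),
               tolerance = 1e-10)
  expect_equal(unname(rs$coef["r_cur", 1:40, 1]), rep(0, 40),
               tolerance = 1e-10)
  expect_true(all(rs$p["r_cur", 41:70, 1] < 1e-10))
  # duplicating the session gives identical per-session coefficients
  rs2 <- regress_and_summarize(list(resp, resp), list(X, X), n_boot = 0)
  expect_equal(rs2$coef[, , 1], rs2$coef[, , 2])
})

test_that("aliased design columns are dropped with a warning", {
  set.seed(42)
  n <- 60
  s <- mp_session(sample(c("L", "R"), n, replace = TRUE), rep(1, n))
  X <- build_design(s, design = "observable")   # all-rewarded: r_* constant
  idx <- attr(X, "trials")
  Y <- matrix(rnorm(length(idx) * 80), length(idx), 80)
  resp <- structure(Y, bin_centers = seq(-3, 5, by = .1)[-1] - .05,
                    trials = idx,
                    class = c("trial_response_matrix", "matrix", "array"))
  expect_warning(rs <- regress_and_summarize(resp, X, n_boot = 0),
                 "rank-deficient")
  expect_true(anyNA(rs$coef[, 1, 1]))
  expect_false(anyNA(rs$coef["c_cur", , 1]))
})

test_that("RPE-sign split partitions rows and flags empty groups", {
  set.seed(42)
  p <- default_hybrid_params()
  sim <- simulate_session(p, "matching_pennies", 400)
  X <- build_design(sim$session, sim$trajectory, "updating")
  idx <- attr(X, "trials")
  Y <- matrix(rnorm(length(idx) * 80, sd = .5), length(idx), 80)
  # plant +1 * RPE into bins 50:70
  Y[, 50:70] <- Y[, 50:70] + 1 * X$rpe
  resp <- structure(Y, bin_centers = seq(-3, 5, by = .1)[-1] - .05,
                    trials = idx,
                    class = c("trial_response_matrix", "matrix", "array"))
  out <- rpe_sign_split(resp, X, n_boot = 0)
  expect_s3_class(out$positive, "regression_summary")
  expect_s3_class(out$negative, "regression_summary")
  # dilation for +RPE and constriction for -RPE: both slopes positive
  expect_gt(mean(out$positive$coef["rpe", 50:70, 1]), 0)
  expect_gt(mean(out$negative$coef["rpe", 50:70, 1]), 0)
  # the partition covers the full design (no zero-RPE rows here)
  n_pos <- sum(X$rpe > 0); n_neg <- sum(X$rpe < 0)
  expect_equal(n_pos + n_neg + sum(X$rpe == 0), nrow(X))

  # all-rewarded synthetic session: negative group absent
  s1 <- mp_session(sim$session$choice, rep(1, 400))
  tr1 <- latent_trajectory(p, s1)
  X1 <- build_design(s1, tr1, "updating")
  i1 <- attr(X1, "trials")
  r1 <- structure(matrix(rnorm(length(i1) * 80), length(i1), 80),
                  bin_centers = seq(-3, 5, by = .1)[-1] - .05, trials = i1,
                  class = c("trial_response_matrix", "matrix", "array"))
  out1 <- suppressWarnings(rpe_sign_split(r1, X1, n_boot = 0))
  expect_null(out1$negative)
  expect_equal(out1$absent$negative, 1L)
})

test_that("eye correlation is exact for copies and sign flips", {
  set.seed(42)
  p <- default_hybrid_params()
  sim <- simulate_session(p, "matching_pennies", 200)
  X <- build_design(sim$session, design = "observable")
  idx <- attr(X, "trials")
  mk <- function(noise_sd) {
    Y <- matrix(rnorm(length(idx) * 80, sd = noise_sd), length(idx), 80)
    # bin-varying shared kernel so coefficient pairs span a range
    for (b in 61:80) Y[, b] <- Y[, b] + X$c_cur * (b - 60) / 20
    structure(Y, bin_centers = seq(-3, 5, by = .1)[-1] - .05, trials = idx,
              class = c("trial_response_matrix", "matrix", "array"))
  }
  left <- regress_and_summarize(list(mk(.3), mk(.3)), list(X, X), n_boot = 0)
  expect_equal(eye_coefficient_correlation(left, left)$r, 1)

  right <- left
  right$coef <- -right$coef
  flip <- eye_coefficient_correlation(left, right)
  expect_equal(flip$r, -1)

  # two eyes sharing a planted signal with independent noise correlate
  set.seed(43)
  eyeL <- regress_and_summarize(list(mk(.5), mk(.5), mk(.5)),
                                list(X, X, X), n_boot = 0)
  eyeR <- regress_and_summarize(list(mk(.5), mk(.5), mk(.5)),
                                list(X, X, X), n_boot = 0)
  shared <- eye_coefficient_correlation(eyeL, eyeR)
  expect_gt(shared$r, 0.6)
})
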