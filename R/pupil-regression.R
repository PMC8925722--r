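#' Build a trial-regressor design matrix for pupil regression
#'
#' Three model specifications are supported, matching the three regression
#' analyses of the pipeline:
#'
#' * `"observable"`: choices `c` (dummy-coded 0 = left, 1 = right) and
#'   outcomes `r` (0/1) for the next, current, previous, and
#'   before-previous trials, their interactions `c*r`, the 20-trial
#'   moving-average reward `r_ma`, and the normalized cumulative reward
#'   `r_cum`.
#' * `"selection"`: current/previous choice, outcome, interaction, plus the
#'   action-value difference `dq = Q_L - Q_R`, chosen value `q_chosen`,
#'   kernel difference `dk = K_L - K_R`, chosen kernel `k_chosen`, `r_ma`,
#'   `r_cum`.
#' * `"updating"`: current/previous choice, previous outcome, `dq`, the
#'   reward prediction error `rpe = r_n - Q_chosen`, `dk`, the
#'   choice-kernel error `cke = 1 - K_chosen`, `r_ma`, `r_cum`.
#'
#' The moving average runs over the 20 most recent trials including the
#' current one (as defined); before trial 20 it is renormalized over the
#' available history (flagged by the `early_ma` attribute). `r_cum` is the
#' cumulative reward divided by the session total, so it is nondecreasing
#' and ends at 1. Trials missing any required lag/lead (the first one or
#' two and, for `"observable"`, the last) and trials adjacent to MISS
#' trials are dropped; kept trial indices are in the `trials` attribute.
#'
#' @param session An [mp_session()].
#' @param trajectory A [latent_trajectory()] from the fitted hybrid model
#'   (required for `"selection"` and `"updating"`).
#' @param design Which regressor set to build.
#' @param ma_window Moving-average window (trials).
#' @return A data.frame of class `pupil_design` with attributes `design`,
#'   `trials`, `early_ma`.
#' @export
build_design <- function(session, trajectory = NULL,
                         design = c("observable", "selection", "updating"),
                         ma_window = 20L) {
  design <- match.arg(design)
  n <- nrow(session)
  if (design != "observable") {
    if (is.null(trajectory)) stop("trajectory required for design '", design, "'")
    if (nrow(trajectory) != n) stop("trajectory/session length mismatch")
  }
  cint <- .choice_to_int(session$choice)
  cc <- 1 - cint          # dummy code: 0 = left, 1 = right (NA for MISS)
  r <- as.numeric(session$outcome)
  r[is.na(cint)] <- NA    # MISS trials excluded from designs

  lag <- function(x, k) {  # x shifted so row n holds x[n - k]
    if (k > 0) c(rep(NA_real_, k), x[seq_len(n - k)])
    else if (k < 0) c(x[(1 - k):n], rep(NA_real_, -k))
    else x
  }
  r_ma <- vapply(seq_len(n), function(i) {
    w <- r[max(1L, i - ma_window + 1L):i]
    mean(w, na.rm = TRUE)
  }, numeric(1))
  tot <- sum(r, na.rm = TRUE)
  r_cum <- if (tot > 0) cumsum(ifelse(is.na(r), 0, r)) / tot else rep(0, n)

  df <- switch(design,
    observable = data.frame(
      c_next = lag(cc, -1L), r_next = lag(r, -1L),
      cxr_next = lag(cc * r, -1L),
      c_cur = cc, r_cur = r, cxr_cur = cc * r,
      c_prev1 = lag(cc, 1L), r_prev1 = lag(r, 1L),
      cxr_prev1 = lag(cc * r, 1L),
      c_prev2 = lag(cc, 2L), r_prev2 = lag(r, 2L),
      cxr_prev2 = lag(cc * r, 2L),
      r_ma = r_ma, r_cum = r_cum),
    selection = data.frame(
      c_cur = cc, r_cur = r, cxr_cur = cc * r,
      c_prev1 = lag(cc, 1L), r_prev1 = lag(r, 1L),
      cxr_prev1 = lag(cc * r, 1L),
      dq = trajectory$dq, q_chosen = trajectory$q_chosen,
      dk = trajectory$dk, k_chosen = trajectory$k_chosen,
      r_ma = r_ma, r_cum = r_cum),
    updating = data.frame(
      c_cur = cc, c_prev1 = lag(cc, 1L), r_prev1 = lag(r, 1L),
      dq = trajectory$dq, rpe = trajectory$rpe,
      dk = trajectory$dk, cke = trajectory$cke,
      r_ma = r_ma, r_cum = r_cum)
  )
  keep <- stats::complete.cases(df)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, design = design, trials = which(keep),
            early_ma = any(which(keep) < ma_window),
            class = c("pupil_design", "data.frame"))
}

# per-session OLS of every time bin on the design; returns coef and p
# matrices (predictors + intercept) x bins, NA for aliased columns
.fit_session_bins <- function(responses, design) {
  rt <- attr(responses, "trials")
  dt <- attr(design, "trials")
  common <- intersect(rt, dt)
  if (length(common) < ncol(design) + 2L) {
    stop("too few usable trials (", length(common), ") for regression")
  }
  Y <- unclass(responses)[match(common, rt), , drop = FALSE]
  X <- cbind(intercept = 1, as.matrix(design[match(common, dt), , drop = FALSE]))
  # drop bins with missing values (should not occur on a full grid)
  qr_x <- qr(X)
  rank <- qr_x$rank
  p_all <- ncol(X)
  used <- qr_x$pivot[seq_len(rank)]
  if (rank < p_all) {
    warning("rank-deficient design: dropping aliased column(s) ",
            paste(colnames(X)[qr_x$pivot[(rank + 1):p_all]], collapse = ", "))
    X <- X[, used, drop = FALSE]
    qr_x <- qr(X)
  }
  nobs <- nrow(X)
  df_res <- nobs - qr_x$rank
  beta <- qr.coef(qr_x, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / df_res
  d_piv <- diag(chol2inv(qr.R(qr_x)))
  d <- numeric(ncol(X))
  d[qr_x$pivot] <- d_piv  # undo any column pivoting
  se <- sqrt(outer(d, sigma2))
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df_res)
  coefs <- matrix(NA_real_, p_all, ncol(Y),
                  dimnames = list(c("intercept", colnames(design)), NULL))
  pvals <- coefs
  coefs[used, ] <- beta
  pvals[used, ] <- pval
  list(coef = coefs, p = pvals, n = nobs)
}

#' Per-bin multiple regression of pupil responses with across-session summary
#'
#' Fits ordinary least squares per 100-ms bin per session (coefficient and
#' two-sided p-value for every predictor), then summarizes across sessions:
#' the fraction of sessions significant at `p_threshold` per predictor per
#' bin, a one-sample proportion chi-squared test (no continuity correction)
#' of that fraction against the `chance` rate, and bootstrap percentile 95%
#' confidence intervals (resampling sessions with replacement) on the mean
#' coefficients. No multiple-comparison correction is applied.
#'
#' @param responses A list of [trial_responses()] matrices (one per
#'   session), or a single matrix.
#' @param designs Matching list of [build_design()] data.frames.
#' @param p_threshold Per-session significance threshold.
#' @param chance Null probability for the chi-squared test.
#' @param n_boot Bootstrap resamples (0 disables the CI).
#' @return A list of class `regression_summary`: `coef` and `p` arrays
#'   (predictor x bin x session), `frac_sig`, `chisq_p`, `mean_coef`,
#'   `ci_lo`, `ci_hi` (predictor x bin), `bin_centers`, `predictors`,
#'   `n_sessions`.
#' @export
regress_and_summarize <- function(responses, designs, p_threshold = 0.01,
                                  chance = 0.01, n_boot = 1000L) {
  if (!is.list(responses)) responses <- list(responses)
  if (is.data.frame(designs)) designs <- list(designs)
  stopifnot(length(responses) == length(designs), length(responses) >= 1L)
  types <- unique(vapply(designs, attr, character(1), "design"))
  if (length(types) != 1L) stop("all designs must share one specification")

  fits <- Map(.fit_session_bins, responses, designs)
  preds <- rownames(fits[[1]]$coef)
  n_bins <- ncol(fits[[1]]$coef)
  n_sess <- length(fits)
  coef_arr <- array(NA_real_, c(length(preds), n_bins, n_sess),
                    dimnames = list(preds, NULL, NULL))
  p_arr <- coef_arr
  for (s in seq_len(n_sess)) {
    coef_arr[, , s] <- fits[[s]]$coef
    p_arr[, , s] <- fits[[s]]$p
  }

  sig <- p_arr < p_threshold
  frac_sig <- apply(sig, c(1, 2), mean, na.rm = TRUE)
  n_ok <- apply(!is.na(p_arr), c(1, 2), sum)
  phat <- frac_sig
  stat <- (phat - chance)^2 * n_ok / (chance * (1 - chance))
  chisq_p <- pchisq(stat, df = 1, lower.tail = FALSE)
  mean_coef <- apply(coef_arr, c(1, 2), mean, na.rm = TRUE)

  ci_lo <- ci_hi <- NULL
  if (n_boot > 0L && n_sess > 1L) {
    flat <- matrix(coef_arr, nrow = length(preds) * n_bins, ncol = n_sess)
    bm <- matrix(NA_real_, n_boot, nrow(flat))
    for (b in seq_len(n_boot)) {
      bm[b, ] <- rowMeans(flat[, sample.int(n_sess, replace = TRUE),
                               drop = FALSE], na.rm = TRUE)
    }
    qs <- apply(bm, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    ci_lo <- matrix(qs[1, ], length(preds), n_bins, dimnames = dimnames(frac_sig))
    ci_hi <- matrix(qs[2, ], length(preds), n_bins, dimnames = dimnames(frac_sig))
  }

  structure(list(coef = coef_arr, p = p_arr, frac_sig = frac_sig,
                 chisq_p = chisq_p, mean_coef = mean_coef,
                 ci_lo = ci_lo, ci_hi = ci_hi,
                 bin_centers = attr(responses[[1]], "bin_centers"),
                 predictors = preds, n_sessions = n_sess,
                 design = types),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat("<regression_summary> design =", x$design, "|", x$n_sessions,
      "session(s),", length(x$predictors), "predictors,",
      ncol(x$frac_sig), "bins\n")
  invisible(x)
}

#' Refit the value-updating regression separately by RPE sign
#'
#' Trials are partitioned by the sign of the reward prediction error and
#' the `"updating"` regression is refit within each group. Because outcome
#' is constant within a group (positive-RPE trials are all rewarded,
#' negative all unrewarded), outcome-confounded columns that become
#' constant are dropped automatically by the rank-deficiency guard.
#' Sessions with an empty group are flagged and omitted from that group's
#' summary; an entirely empty group yields `NULL` with its flag set.
#'
#' @inheritParams regress_and_summarize
#' @return A list with `positive` and `negative` ([regress_and_summarize()]
#'   summaries or `NULL`) and `absent` (list of per-group session indices
#'   that had no trials of that sign).
#' @export
rpe_sign_split <- function(responses, designs, p_threshold = 0.01,
                           chance = 0.01, n_boot = 1000L) {
  if (!is.list(responses)) responses <- list(responses)
  if (is.data.frame(designs)) designs <- list(designs)
  stopifnot(length(responses) == length(designs))
  if (any(vapply(designs, attr, character(1), "design") != "updating")) {
    stop("rpe_sign_split requires 'updating' designs")
  }
  split_one <- function(design, positive) {
    sel <- if (positive) design$rpe > 0 else design$rpe < 0
    sub <- design[sel, , drop = FALSE]
    # drop columns made constant by the split (e.g. outcome-confounded)
    keep_col <- vapply(sub, function(col) length(unique(col)) > 1L, logical(1))
    out <- sub[, keep_col, drop = FALSE]
    structure(out, design = "updating",
              trials = attr(design, "trials")[sel],
              early_ma = attr(design, "early_ma"),
              class = class(design))
  }
  run_group <- function(positive) {
    subs <- lapply(designs, split_one, positive = positive)
    n_rows <- vapply(subs, nrow, integer(1))
    usable <- which(n_rows >= vapply(subs, ncol, integer(1)) + 3L)
    absent <- setdiff(seq_along(designs), usable)
    if (!length(usable)) return(list(summary = NULL, absent = absent))
    list(summary = regress_and_summarize(responses[usable], subs[usable],
                                         p_threshold, chance, n_boot),
         absent = absent)
  }
  pos <- run_group(TRUE)
  neg <- run_group(FALSE)
  list(positive = pos$summary, negative = neg$summary,
       absent = list(positive = pos$absent, negative = neg$absent))
}

#' Correlate one predictor's coefficients between the two eyes
#'
#' Pools the per-session, per-bin regression coefficients of `predictor`
#' within a time window (default 3-5 s after the cue, where pupil responses
#' are largest) from the left- and right-eye summaries of the same sessions
#' and returns their Pearson correlation.
#'
#' @param left,right [regress_and_summarize()] summaries for the two eyes
#'   (same sessions, same bins).
#' @param predictor Predictor name (default current choice).
#' @param window Time window \[s\] relative to cue.
#' @return A list with `r`, `p`, and `n` (number of session x bin pairs).
#' @export
eye_coefficient_correlation <- function(left, right, predictor = "c_cur",
                                        window = c(3, 5)) {
  stopifnot(inherits(left, "regression_summary"),
            inherits(right, "regression_summary"))
  if (!isTRUE(all.equal(left$bin_centers, right$bin_centers)) ||
      left$n_sessions != right$n_sessions) {
    stop("summaries do not share bins/sessions")
  }
  bins <- which(left$bin_centers >= window[1] & left$bin_centers <= window[2])
  a <- as.vector(left$coef[predictor, bins, ])
  b <- as.vector(right$coef[predictor, bins, ])
  ok <- is.finite(a) & is.finite(b)
  ct <- stats::cor.test(a[ok], b[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Write per-bin regression coefficients in long format
#'
#' Columns `session,predictor,bin_start_s,coef,p`.
#'
#' @param summary A [regress_and_summarize()] result.
#' @param path File path.
#' @export
write_regression_long <- function(summary, path) {
  bw <- diff(summary$bin_centers[1:2])
  grid <- expand.grid(predictor = summary$predictors,
                      bin = seq_along(summary$bin_centers),
                      session = seq_len(summary$n_sessions))
  df <- data.frame(session = grid$session,
                   predictor = grid$predictor,
                   bin_start_s = summary$bin_centers[grid$bin] - bw / 2,
                   coef = as.vector(summary$coef),
                   p = as.vector(summary$p))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
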