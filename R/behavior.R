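#' Three-choice entropy of a binary choice sequence
#'
#' Shannon entropy (base 2) of the frequencies of the eight possible
#' patterns of three consecutive choices, counted over all overlapping
#' (stride-1) windows. `0 * log2(0)` is taken as 0. The maximum is 3 bits
#' (all eight patterns equally frequent); a constant sequence scores 0.
#' MISS trials are removed before windowing.
#'
#' @param choices Character vector of `"L"`/`"R"` (optionally `"MISS"`).
#' @return Entropy in bits.
#' @export
three_choice_entropy <- function(choices) {
  p <- three_choice_pattern_freqs(choices)
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' @rdname three_choice_entropy
#' @return `three_choice_pattern_freqs()` returns the named vector of eight
#'   pattern frequencies (summing to 1).
#' @export
three_choice_pattern_freqs <- function(choices) {
  x <- .choice_to_int(choices)
  x <- x[!is.na(x)]
  if (length(x) < 3L) stop("need at least 3 non-MISS choices")
  idx <- 4L * x[1:(length(x) - 2L)] + 2L * x[2:(length(x) - 1L)] +
    x[3:length(x)] + 1L
  counts <- tabulate(idx, nbins = 8L)
  bits <- function(i, b) (i %/% b) %% 2L
  labs <- vapply(0:7, function(i) {
    paste0(c("R", "L")[c(bits(i, 4L), bits(i, 2L), bits(i, 1L)) + 1L],
           collapse = "")
  }, character(1))
  names(counts) <- labs
  counts / sum(counts)
}

#' Running three-choice entropy
#'
#' Entropy of each sliding window of `window` consecutive choices; the
#' value is indexed by the window's last trial.
#'
#' @inheritParams three_choice_entropy
#' @param window Window length in trials.
#' @return Numeric vector of length `length(choices)`, `NA` before the
#'   first full window.
#' @export
running_entropy <- function(choices, window = 30L) {
  n <- length(choices)
  out <- rep(NA_real_, n)
  if (n < window) return(out)
  for (t in window:n) {
    out[t] <- three_choice_entropy(choices[(t - window + 1L):t])
  }
  out
}

# least-squares piecewise-linear fit with at most one slope change:
# candidate breakpoints are scanned, each side fit by OLS independently,
# and the 0- vs 1-breakpoint alternatives are compared by BIC
.piecewise_linear_fit <- function(y, min_seg = 5L) {
  n <- length(y)
  x <- seq_len(n)
  fit_seg <- function(ix) {
    f <- stats::lm.fit(cbind(1, x[ix]), y[ix])
    list(fitted = f$fitted.values, sse = sum(f$residuals^2))
  }
  whole <- fit_seg(seq_len(n))
  best <- list(fitted = whole$fitted, sse = whole$sse, k = 2L, bp = NA_integer_)
  if (n >= 2L * min_seg) {
    sse2 <- Inf
    fitted2 <- NULL
    bp2 <- NA_integer_
    for (bp in min_seg:(n - min_seg)) {
      left <- fit_seg(1:bp)
      right <- fit_seg((bp + 1L):n)
      sse <- left$sse + right$sse
      if (sse < sse2) {
        sse2 <- sse
        fitted2 <- c(left$fitted, right$fitted)
        bp2 <- bp
      }
    }
    # BIC comparison: 2 params vs 5 (two intercepts, two slopes, breakpoint)
    eps <- 1e-12
    bic1 <- n * log(whole$sse / n + eps) + 2L * log(n)
    bic2 <- n * log(sse2 / n + eps) + 5L * log(n)
    if (is.finite(bic2) && bic2 < bic1) {
      best <- list(fitted = fitted2, sse = sse2, k = 5L, bp = bp2)
    }
  }
  best
}

#' Detect the "last trial" of a session from running entropy
#'
#' Toward the end of a session animals tend to repeat one choice before
#' ceasing to respond. The running three-choice entropy of a 30-trial
#' window is fit with a piecewise-linear function (at most one slope
#' change, least squares); the first trial where the fitted function falls
#' below `threshold` is the last trial, and everything after it should be
#' discarded. If the fitted function recovers above the threshold later, or
#' never crosses it, the whole session is kept.
#'
#' @inheritParams running_entropy
#' @param threshold Entropy threshold in bits.
#' @return The last-trial index (equal to `length(choices)` when nothing is
#'   truncated).
#' @export
detect_last_trial <- function(choices, window = 30L, threshold = 1.0) {
  n <- length(choices)
  if (n <= window) return(n)
  e <- running_entropy(choices, window)
  idx <- which(!is.na(e))
  fit <- .piecewise_linear_fit(e[idx])
  fitted <- fit$fitted
  below <- fitted < threshold
  if (!any(below)) return(n)
  first <- which(below)[1]
  if (any(fitted[first:length(fitted)] >= threshold)) return(n)  # recovers
  idx[first]
}

#' Count preference switches
#'
#' The observed choice sequence (L = 1, R = 0, MISS dropped) is smoothed
#' with a Gaussian kernel (sd `sigma` trials, truncated at 4 sd, edge
#' weights renormalized); a preference switch is a crossing of 0.5 by the
#' smoothed running choice average.
#'
#' @inheritParams three_choice_entropy
#' @param sigma Gaussian smoothing width in trials.
#' @return Integer switch count.
#' @export
count_preference_switches <- function(choices, sigma = 5) {
  x <- .choice_to_int(choices)
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(0L)
  half <- ceiling(4 * sigma)
  kern <- exp(-((-half):half)^2 / (2 * sigma^2))
  n <- length(x)
  sm <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    w <- kern[(lo - i + half + 1L):(hi - i + half + 1L)]
    sm[i] <- sum(w * x[lo:hi]) / sum(w)
  }
  side <- sign(sm - 0.5)
  side <- side[side != 0]
  sum(diff(side) != 0)
}

#' Summarize one session
#'
#' Reward rate over non-MISS trials, three-choice entropy and pattern
#' frequencies, the running-entropy last trial, and the preference-switch
#' count.
#'
#' @param session An [mp_session()].
#' @param trajectory Optional [latent_trajectory()] aligned with the
#'   session (currently unused by the summary statistics but kept for
#'   interface symmetry and alignment checking).
#' @param sigma Smoothing width for [count_preference_switches()].
#' @return A list of class `session_summary`.
#' @export
summarize_session <- function(session, trajectory = NULL, sigma = 5) {
  if (!is.null(trajectory) && nrow(trajectory) != nrow(session)) {
    stop("trajectory is not aligned with session")
  }
  responded <- session$choice != "MISS"
  structure(list(
    n_trials = nrow(session),
    reward_rate = mean(session$outcome[responded]),
    entropy = three_choice_entropy(session$choice),
    pattern_freqs = three_choice_pattern_freqs(session$choice),
    last_trial = detect_last_trial(session$choice),
    n_preference_switches = count_preference_switches(session$choice, sigma)
  ), class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf(paste0("<session_summary> %d trials, reward rate %.3f, ",
                     "entropy %.3f bits, last trial %d, %d switches\n"),
              x$n_trials, x$reward_rate, x$entropy, x$last_trial,
              x$n_preference_switches))
  invisible(x)
}

#' Write session summaries to CSV
#'
#' @param summaries A list of `session_summary` objects.
#' @param path File path.
#' @export
write_summaries <- function(summaries, path) {
  df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(n_trials = s$n_trials, reward_rate = s$reward_rate,
               entropy = s$entropy, last_trial = s$last_trial,
               n_preference_switches = s$n_preference_switches)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Psychometric curve over the softmax decision variable
#'
#' Pools trials from one or more sessions, bins them by the weighted sum
#' `beta * (Q_L - Q_R) + beta_k * (K_L - K_R)` from the fitted hybrid
#' model, and reports the observed fraction of left choices per bin next to
#' the softmax prediction at the bin center. Empty bins are dropped.
#'
#' @param sessions An [mp_session()] or list of them.
#' @param trajectories Matching [latent_trajectory()] (or list), produced
#'   with the fitted parameters.
#' @param params The fitted [model_params()] supplying `beta` and `beta_k`.
#' @param n_bins Number of equal-width bins spanning the observed range.
#' @return A data.frame with `center`, `n`, `observed`, `predicted`.
#' @export
psychometric_curve <- function(sessions, trajectories, params, n_bins = 15L) {
  if (is.data.frame(sessions)) sessions <- list(sessions)
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  stopifnot(length(sessions) == length(trajectories))
  bk <- if (params$model == "FQ_RPE_CK") params$beta_k else 0
  w <- unlist(lapply(trajectories, function(tr)
    params$beta * tr$dq + bk * tr$dk))
  ch <- unlist(lapply(sessions, function(s) s$choice))
  keep <- ch != "MISS"
  w <- w[keep]; is_left <- ch[keep] == "L"
  edges <- seq(min(w), max(w), length.out = n_bins + 1L)
  bin <- findInterval(w, edges, rightmost.closed = TRUE)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    if (!any(sel)) return(NULL)
    data.frame(center = (edges[b] + edges[b + 1L]) / 2,
               n = sum(sel), observed = mean(is_left[sel]))
  }))
  out$predicted <- 1 / (1 + exp(-out$center))
  out
}
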