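#' Preprocess a raw pupil-diameter trace
#'
#' The pipeline, in fixed order: (1) zero-phase 4-Hz Butterworth lowpass;
#' (2) frames more than `mad_thresh` scaled median absolute deviations from
#' the whole-trace median are masked as artifacts; (3) conversion to z
#' score with a 10-min centered moving window (masked frames excluded from
#' the window statistics) to absorb slow drift. Masked frames are linearly
#' interpolated in `z_filled` for downstream trial binning only; they stay
#' `NA` in `z` and excluded from all statistics.
#'
#' If the trace is shorter than the z-scoring window, a single-window
#' (global) z score is used with a warning. A constant trace yields z
#' identically 0 (degenerate SDs are guarded).
#'
#' @param raw Numeric vector of pupil diameters.
#' @param fs Sampling rate (Hz, nominal 20).
#' @param cue_times Optional per-trial cue onsets (s from trace start).
#' @param lowpass_hz Lowpass cutoff (Hz).
#' @param mad_thresh Outlier threshold in scaled MADs.
#' @param zscore_window_s Moving-window length (s).
#' @param zscore `"moving"` (moving mean and SD, default), `"moving_mean"`
#'   (subtract moving mean only), `"global"`, or `"none"` (filter and mask
#'   only).
#' @return A list of class `pupil_trace` with elements `raw`, `filtered`,
#'   `z`, `z_filled`, `valid`, `time`, `fs`, `cue_times`.
#' @export
preprocess_trace <- function(raw, fs = 20, cue_times = NULL,
                             lowpass_hz = 4, mad_thresh = 3,
                             zscore_window_s = 600,
                             zscore = c("moving", "moving_mean", "global",
                                        "none")) {
  zscore <- match.arg(zscore)
  stopifnot(is.numeric(raw), all(is.finite(raw)), fs > 0)
  n <- length(raw)
  filtered <- butter_filtfilt(raw, fs, lowpass_hz)

  med <- median(filtered)
  s <- mad(filtered)  # scaled MAD (consistent for normal SD)
  valid <- if (s > 0) abs(filtered - med) <= mad_thresh * s else rep(TRUE, n)

  win <- round(zscore_window_s * fs)
  if (zscore == "moving" || zscore == "moving_mean") {
    if (n < win) {
      warning("trace shorter than z-scoring window; using global statistics")
      zscore <- "global"
    }
  }

  x <- filtered
  x[!valid] <- NA_real_
  z <- switch(zscore,
    moving = {
      ms <- .moving_stats(x, win)
      (x - ms$mean) / ifelse(ms$sd > 1e-10, ms$sd, Inf)
    },
    moving_mean = {
      ms <- .moving_stats(x, win)
      x - ms$mean
    },
    global = {
      mu <- mean(x, na.rm = TRUE)
      sg <- sd(x, na.rm = TRUE)
      if (!is.finite(sg) || sg <= 1e-10) (x - x) else (x - mu) / sg
    },
    none = x
  )
  z[is.nan(z)] <- 0  # 0/Inf guards
  z_filled <- z
  if (anyNA(z_filled)) {
    ok <- which(!is.na(z_filled))
    if (length(ok) >= 2L) {
      z_filled <- approx(ok, z_filled[ok], xout = seq_len(n), rule = 2)$y
    } else {
      z_filled[is.na(z_filled)] <- 0
    }
  }
  structure(list(raw = raw, filtered = filtered, z = z, z_filled = z_filled,
                 valid = valid, time = (seq_len(n) - 1L) / fs, fs = fs,
                 cue_times = cue_times),
            class = "pupil_trace")
}

# centered moving mean/SD over a window of `win` frames, NA-aware, O(n)
.moving_stats <- function(x, win) {
  n <- length(x)
  h <- win %/% 2L
  ok <- !is.na(x)
  x0 <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(x0))          # padded so index lo is always valid
  css <- c(0, cumsum(x0^2))
  cn <- c(0, cumsum(as.numeric(ok)))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  s <- cs[hi + 1L] - cs[lo]
  ss <- css[hi + 1L] - css[lo]
  m <- cn[hi + 1L] - cn[lo]
  mu <- ifelse(m > 0, s / m, NA_real_)
  v <- ifelse(m > 1, pmax((ss - s^2 / pmax(m, 1)) / (m - 1), 0), 0)
  list(mean = mu, sd = sqrt(v), n = m)
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf("<pupil_trace> %d frames at %g Hz (%.1f min), %d masked (%.2f%%)",
              length(x$raw), x$fs, length(x$raw) / x$fs / 60,
              sum(!x$valid), 100 * mean(!x$valid)), "\n")
  if (!is.null(x$cue_times)) cat("  ", length(x$cue_times), "cue times\n")
  invisible(x)
}

#' Read / write a pupil trace CSV (`time_s,diameter`)
#'
#' @param path File path.
#' @return `read_trace()` returns a list with `diameter` and `fs`.
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_s", "diameter") %in% names(df)))
  dt <- diff(df$time_s)
  list(diameter = df$diameter, fs = 1 / median(dt))
}

#' @rdname read_trace
#' @param diameter Numeric trace.
#' @param fs Sampling rate.
#' @export
write_trace <- function(diameter, fs, path) {
  write.csv(data.frame(time_s = (seq_along(diameter) - 1) / fs,
                       diameter = diameter),
            path, row.names = FALSE)
  invisible(path)
}

#' Trial-aligned, baseline-subtracted pupil responses
#'
#' For each trial the baseline is the mean z score over \[-2, -1) s before
#' the cue; the response is the baseline-subtracted z score averaged in
#' `bin_width`-s bins spanning \[`-t_pre`, `t_post`\] s around the cue (80
#' bins of 100 ms on the default \[-3, 5\] s grid). Trials whose window
#' extends beyond the trace are dropped (their indices are recorded in the
#' `dropped` attribute). Masked frames use the interpolated `z_filled`.
#'
#' @param trace A [preprocess_trace()] result with `cue_times` set.
#' @param t_pre,t_post Window extent before/after the cue (s).
#' @param bin_width Bin width (s).
#' @param baseline_window Baseline interval relative to cue (s).
#' @return A matrix of class `trial_response_matrix` (trials x bins) with
#'   attributes `bin_centers`, `trials` (kept trial indices), `dropped`.
#' @export
trial_responses <- function(trace, t_pre = 3, t_post = 5, bin_width = 0.1,
                            baseline_window = c(-2, -1)) {
  stopifnot(inherits(trace, "pupil_trace"), !is.null(trace$cue_times))
  fs <- trace$fs
  n <- length(trace$z_filled)
  n_bins <- round((t_post + t_pre) / bin_width)
  edges <- seq(-t_pre, t_post, by = bin_width)
  centers <- edges[-1] - bin_width / 2
  t_lo <- min(-t_pre, baseline_window[1])

  keep <- list(); rows <- list()
  for (i in seq_along(trace$cue_times)) {
    ct <- trace$cue_times[i]
    i0 <- floor((ct + t_lo) * fs) + 1L
    i1 <- ceiling((ct + t_post) * fs) + 1L
    if (i0 < 1L || i1 > n) next
    idx <- i0:i1
    tau <- trace$time[idx] - ct
    zb <- trace$z_filled[idx]
    base_sel <- tau >= baseline_window[1] & tau < baseline_window[2]
    baseline <- mean(zb[base_sel])
    bin <- floor((tau + t_pre) / bin_width + 1e-9) + 1L
    sel <- bin >= 1L & bin <= n_bins & tau >= -t_pre
    agg <- rowsum(zb[sel], bin[sel])
    cnt <- rowsum(rep(1, sum(sel)), bin[sel])
    vals <- rep(NA_real_, n_bins)
    vals[as.integer(rownames(agg))] <- agg / cnt
    keep[[length(keep) + 1L]] <- i
    rows[[length(rows) + 1L]] <- vals - baseline
  }
  kept <- unlist(keep)
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- matrix(numeric(0), 0, n_bins)
  dropped <- setdiff(seq_along(trace$cue_times), kept)
  if (length(dropped)) {
    message(length(dropped), " trial(s) dropped: window outside trace")
  }
  structure(out, bin_centers = centers, trials = kept, dropped = dropped,
            class = c("trial_response_matrix", "matrix", "array"))
}
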