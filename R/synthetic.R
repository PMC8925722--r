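#' Generate synthetic behavioral sessions with known ground truth
#'
#' Wraps [simulate_session()]: simulates `n_sessions` sessions of a
#' generating agent against the chosen environment and returns the
#' sessions, the implied latent trajectories, and the generating
#' parameters. The default agent is the hybrid model at parameters
#' consistent with the fitted medians of the matching-pennies dataset
#' (alpha = 0.60, alpha_k = 0.13, beta = 0.52, beta_k = 1.63, i.e.
#' alpha_k/alpha = 0.22, beta_k/(beta+beta_k) = 0.76, beta+beta_k = 2.15),
#' which yields sessions with high three-choice entropy (> 2.5 bits) and
#' reward rates a little below the 50% equilibrium, like the animals'.
#'
#' @param params Generating [model_params()].
#' @param env `"matching_pennies"` or `"bandit"`.
#' @param n_sessions,n_trials Dataset size.
#' @param seed Optional RNG seed for reproducibility.
#' @param ... Passed to [simulate_session()].
#' @return A list of class `synthetic_behavior` with `sessions`,
#'   `trajectories`, `params`, `env`.
#' @export
generate_behavior <- function(params = default_hybrid_params(),
                              env = c("matching_pennies", "bandit"),
                              n_sessions = 20L, n_trials = 500L,
                              seed = NULL, ...) {
  env <- match.arg(env)
  if (!is.null(seed)) set.seed(seed)
  sims <- lapply(seq_len(n_sessions), function(i)
    simulate_session(params, env, n_trials, ...))
  structure(list(sessions = lapply(sims, `[[`, "session"),
                 trajectories = lapply(sims, `[[`, "trajectory"),
                 params = params, env = env),
            class = "synthetic_behavior")
}

#' @rdname generate_behavior
#' @export
default_hybrid_params <- function() {
  model_params("FQ_RPE_CK", alpha = 0.60, alpha_k = 0.13,
               beta = 0.52, beta_k = 1.63)
}

#' Planted-coefficient specification for synthetic pupil traces
#'
#' Each row plants one regressor's temporal coefficient kernel: `value` is
#' the coefficient (in z-score units), active between `t_on` and `t_off`
#' seconds relative to the cue, with a raised-cosine-flanked plateau kernel
#' (`ramp`-s cosine ramps, flat top at 1), so interior 100-ms bins carry
#' exactly `value` times the regressor.
#'
#' @param predictor Column names of the target [build_design()] matrix.
#' @param value Planted coefficient values.
#' @param t_on,t_off Active window (s relative to cue onset).
#' @param ramp Cosine ramp duration (s).
#' @return A data.frame of class `pupil_coef_spec`.
#' @export
pupil_coef_spec <- function(predictor, value, t_on, t_off, ramp = 0.5) {
  stopifnot(length(predictor) == length(value),
            length(t_on) %in% c(1L, length(value)),
            length(t_off) %in% c(1L, length(value)))
  out <- data.frame(predictor = predictor, value = value,
                    t_on = t_on, t_off = t_off, ramp = ramp,
                    stringsAsFactors = FALSE)
  class(out) <- c("pupil_coef_spec", "data.frame")
  out
}

# plateau kernel with raised-cosine flanks; 1 on [t_on+ramp, t_off-ramp]
.coef_kernel <- function(tau, t_on, t_off, ramp) {
  k <- numeric(length(tau))
  inside <- tau >= t_on & tau <= t_off
  k[inside] <- 1
  if (ramp > 0) {
    up <- tau >= t_on & tau < t_on + ramp
    k[up] <- 0.5 * (1 - cos(pi * (tau[up] - t_on) / ramp))
    dn <- tau > t_off - ramp & tau <= t_off
    k[dn] <- 0.5 * (1 - cos(pi * (t_off - tau[dn]) / ramp))
  }
  k
}

#' Generate a raw pupil trace with planted regression structure
#'
#' Builds a 20-Hz diameter trace whose preprocessed (z-scored) version
#' contains, per trial, the planted linear combination of design-matrix
#' regressors, superposed on slow sinusoidal drift, band-limited noise, and
#' sparse outlier spikes (to exercise the MAD mask).
#'
#' A 10-min moving z-score is invariant to affine rescaling of the raw
#' trace, so planted coefficients are only recoverable on their stated
#' scale if the z-space signal has unit moving SD. With
#' `noise = "calibrated"` (default) the noise SD is set to
#' `sqrt(1 - var(planted) - var(residual drift))`, which makes the full
#' pipeline (filter, mask, moving z-score, baseline subtraction, per-bin
#' OLS) recover the planted coefficients on their own scale. Passing a
#' numeric `noise` SD instead gives that noise level, in which case
#' recovered coefficients are scaled by 1/SD(z-space signal) when the
#' moving z-score is applied (use `zscore = "none"` in
#' [preprocess_trace()] for exact noiseless recovery).
#'
#' @param session An [mp_session()] with `cue_time` set.
#' @param trajectory Matching [latent_trajectory()] (needed when planted
#'   predictors involve latent variables).
#' @param coef_spec A [pupil_coef_spec()].
#' @param design Design specification the predictors refer to.
#' @param noise `"calibrated"` or a numeric SD (z units).
#' @param drift_amp,drift_period_s Sinusoidal drift amplitude (z units) and
#'   period.
#' @param outlier_rate,outlier_amp Fraction of frames spiked and spike
#'   amplitude in multiples of the trace SD.
#' @param fs Sampling rate (Hz).
#' @param baseline_level,gain Affine map from z-space signal to raw
#'   diameter units.
#' @param tail_s Trace padding after the final cue (s).
#' @return A list of class `synthetic_pupil` with `diameter` (raw trace),
#'   `fs`, `cue_times`, `ground_truth` (the coef spec), `noise_sd`,
#'   `planted_var`.
#' @export
generate_pupil <- function(session, trajectory = NULL,
                           coef_spec = pupil_coef_spec("r_cur", 2, 1, 4),
                           design = c("observable", "selection", "updating"),
                           noise = "calibrated",
                           drift_amp = 0.3, drift_period_s = 1200,
                           outlier_rate = 0.001, outlier_amp = 10,
                           fs = 20, baseline_level = 50, gain = 10,
                           tail_s = 10) {
  design <- match.arg(design)
  stopifnot(inherits(coef_spec, "pupil_coef_spec"))
  X <- build_design(session, trajectory, design)
  missing_pred <- setdiff(coef_spec$predictor, colnames(X))
  if (length(missing_pred)) {
    stop("planted predictor(s) not in design: ",
         paste(missing_pred, collapse = ", "))
  }
  cue <- session$cue_time
  stopifnot(!anyNA(cue))
  n <- ceiling((max(cue) + tail_s) * fs)
  tt <- (seq_len(n) - 1L) / fs

  planted <- numeric(n)
  rows <- attr(X, "trials")
  for (j in seq_len(nrow(coef_spec))) {
    pr <- coef_spec$predictor[j]
    for (k in seq_along(rows)) {
      x_val <- X[[pr]][k]
      if (x_val == 0) next
      ct <- cue[rows[k]]
      i0 <- max(1L, floor((ct + coef_spec$t_on[j]) * fs))
      i1 <- min(n, ceiling((ct + coef_spec$t_off[j]) * fs) + 1L)
      if (i0 > i1) next
      tau <- tt[i0:i1] - ct
      planted[i0:i1] <- planted[i0:i1] +
        coef_spec$value[j] * x_val *
        .coef_kernel(tau, coef_spec$t_on[j], coef_spec$t_off[j],
                     coef_spec$ramp[j])
    }
  }

  drift <- if (drift_amp > 0) {
    drift_amp * sin(2 * pi * tt / drift_period_s + runif(1, 0, 2 * pi))
  } else numeric(n)

  # noise is pre-shaped below the lowpass cutoff so preprocessing leaves
  # its variance intact, then scaled to the requested SD
  make_noise <- function(sd_target) {
    if (sd_target <= 0) return(numeric(n))
    w <- butter_filtfilt(rnorm(n), fs, 3.5)
    w * sd_target / sd(w)
  }
  if (identical(noise, "calibrated")) {
    win <- round(600 * fs)
    resid_drift <- drift - .moving_stats(drift, win)$mean
    resid_planted <- planted - .moving_stats(planted, win)$mean
    v_known <- var(resid_planted) + var(resid_drift)
    if (v_known >= 1) {
      warning("planted + drift variance >= 1; calibrated noise floored")
    }
    noise_sd <- sqrt(max(1 - v_known, 0.0025))
  } else {
    stopifnot(is.numeric(noise), noise >= 0)
    noise_sd <- noise
  }
  eps <- make_noise(noise_sd)

  zsig <- planted + drift + eps
  raw <- baseline_level + gain * zsig
  n_out <- rpois(1, outlier_rate * n)
  if (n_out > 0) {
    at <- sample.int(n, min(n_out, n))
    raw[at] <- raw[at] +
      sample(c(-1, 1), length(at), replace = TRUE) * outlier_amp * sd(raw)
  }
  structure(list(diameter = raw, fs = fs, cue_times = cue,
                 ground_truth = coef_spec, noise_sd = noise_sd,
                 planted_var = var(planted), design = design),
            class = "synthetic_pupil")
}

#' Serialize a synthetic-dataset specification to YAML
#'
#' Round-trips the generating model parameters, environment, dataset size,
#' and seed so a dataset can be regenerated bit-identically.
#'
#' @param spec A named list (e.g. `list(params =, env =, n_sessions =,
#'   n_trials =, seed =)`).
#' @param path File path.
#' @export
write_synth_spec <- function(spec, path) {
  if (inherits(spec$params, "model_params")) {
    p <- unclass(spec$params)
    spec$params <- p[!vapply(p, function(x) is.numeric(x) && is.na(x),
                             logical(1))]
  }
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' @rdname write_synth_spec
#' @export
read_synth_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  if (!is.null(spec$params)) spec$params <- do.call(model_params, spec$params)
  spec
}
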