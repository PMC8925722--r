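#' Trial-timing configuration
#'
#' Defaults follow the task: a 2-s response window, a fixed 3-s consumption
#' period, and an intertrial interval drawn from an exponential distribution
#' with rate 1/3 truncated to \[1, 5\] s. Licks during the ITI append further
#' truncated draws, up to five draws in total, so the post-outcome delay
#' (consumption + ITI) spans 4-8 s on lick-free trials.
#'
#' @param response_window Response window (s).
#' @param consumption Consumption period (s).
#' @param iti_rate Exponential rate of the ITI draw (per s).
#' @param iti_lo,iti_hi Truncation bounds of each ITI draw (s).
#' @param max_draws Maximum number of ITI draws per trial (initial + penalties).
#' @return A list of class `timing_config`.
#' @export
timing_config <- function(response_window = 2, consumption = 3,
                          iti_rate = 1 / 3, iti_lo = 1, iti_hi = 5,
                          max_draws = 5L) {
  stopifnot(iti_lo < iti_hi, max_draws >= 1L, iti_rate > 0)
  structure(list(response_window = response_window, consumption = consumption,
                 iti_rate = iti_rate, iti_lo = iti_lo, iti_hi = iti_hi,
                 max_draws = as.integer(max_draws)),
            class = "timing_config")
}

#' Truncated-exponential draws by inverse CDF
#'
#' Samples from Exp(rate) truncated to \[lo, hi\] via the inverse CDF on the
#' renormalized interval, so results are bit-reproducible given the seed
#' (no rejection loop).
#'
#' @param n Number of draws.
#' @param rate Exponential rate.
#' @param lo,hi Truncation bounds.
#' @return Numeric vector of draws in \[lo, hi\].
#' @export
rtrunc_exp <- function(n, rate = 1 / 3, lo = 1, hi = 5) {
  u <- runif(n)
  e_lo <- exp(-rate * lo)
  e_hi <- exp(-rate * hi)
  -log(e_lo - u * (e_lo - e_hi)) / rate
}

# closed-form mean of the truncated exponential (used as a test oracle)
.trunc_exp_mean <- function(rate = 1 / 3, lo = 1, hi = 5) {
  d <- hi - lo
  lo + 1 / rate - d / (exp(rate * d) - 1)
}

#' Sample the post-outcome delay for one trial
#'
#' One truncated-exponential ITI draw, plus one additional draw per penalty
#' lick, capped at `cfg$max_draws` draws in total. The total post-outcome
#' delay is the consumption period plus the summed ITI.
#'
#' @param cfg A [timing_config()].
#' @param penalty_licks Number of licks emitted during the ITI (>= 0).
#' @return A list with `iti`, `total_delay`, and `n_draws`.
#' @export
sample_trial_timing <- function(cfg = timing_config(), penalty_licks = 0L) {
  stopifnot(inherits(cfg, "timing_config"), penalty_licks >= 0)
  n_draws <- min(1L + as.integer(penalty_licks), cfg$max_draws)
  iti <- sum(rtrunc_exp(n_draws, cfg$iti_rate, cfg$iti_lo, cfg$iti_hi))
  list(iti = iti, total_delay = cfg$consumption + iti, n_draws = n_draws)
}
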