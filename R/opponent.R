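#' Create the matching-pennies computer opponent
#'
#' The opponent keeps the mouse's entire within-session choice and outcome
#' history and, before every trial, estimates nine conditional probabilities
#' that the mouse will choose left: given the preceding N choices
#' (N = 0, ..., 4) and given the preceding N choice-outcome combinations
#' (N = 1, ..., 4). Each estimate is tested against 0.5 with a two-sided
#' exact binomial test. If any test rejects, the opponent counters the
#' significant estimate farthest from 0.5; otherwise it picks a side
#' uniformly at random.
#'
#' @param alpha_test Significance level for the binomial tests. `0` disables
#'   prediction entirely, making the opponent a fair coin.
#' @param counter_mode `"stochastic"` (counter chosen with probability equal
#'   to the deviant estimate, i.e. P(computer = L) = 1 - q*) or
#'   `"deterministic"` (counter side chosen outright).
#' @return An object of class `opponent_state`.
#' @seealso [opponent_predict()], [opponent_choose()], [opponent_observe()]
#' @export
opponent_state <- function(alpha_test = 0.05,
                           counter_mode = c("stochastic", "deterministic")) {
  counter_mode <- match.arg(counter_mode)
  stopifnot(is.numeric(alpha_test), length(alpha_test) == 1L,
            alpha_test >= 0, alpha_test <= 1)
  state <- list(
    alpha_test = alpha_test,
    counter_mode = counter_mode,
    choices = integer(0),   # 1 = L, 0 = R (miss trials are not recorded)
    outcomes = integer(0),
    # suffix-occurrence counts, one table per condition; choice-only
    # patterns are binary-coded, choice-outcome patterns base-4 coded
    occ_c = lapply(0:4, function(N) numeric(2^N)),
    left_c = lapply(0:4, function(N) numeric(2^N)),
    occ_co = lapply(1:4, function(N) numeric(4^N)),
    left_co = lapply(1:4, function(N) numeric(4^N))
  )
  class(state) <- "opponent_state"
  state
}

# pattern index (1-based) of the N most recent choices before position `pos`
# (i.e., choices[pos - N .. pos - 1]); bit i is the choice i+1 steps back
.pat_c <- function(choices, pos, N) {
  if (N == 0L) return(1L)
  idx <- choices[(pos - N):(pos - 1L)]
  sum(idx * 2^((N - 1L):0)) + 1L
}

.pat_co <- function(choices, outcomes, pos, N) {
  sym <- choices[(pos - N):(pos - 1L)] + 2L * outcomes[(pos - N):(pos - 1L)]
  sum(sym * 4^((N - 1L):0)) + 1L
}

#' Record a completed trial in the opponent's history
#'
#' Updates the suffix-count tables incrementally so prediction stays O(1)
#' per trial. MISS trials are not recorded (the opponent's histories track
#' expressed choices only).
#'
#' @param state An `opponent_state`.
#' @param choice `"L"` or `"R"` (or `"MISS"`, ignored).
#' @param outcome 0 or 1.
#' @return The updated `opponent_state`.
#' @export
opponent_observe <- function(state, choice, outcome) {
  stopifnot(inherits(state, "opponent_state"))
  if (identical(choice, "MISS")) return(state)
  c_int <- .choice_to_int(choice)
  stopifnot(outcome %in% c(0, 1))
  state$choices <- c(state$choices, c_int)
  state$outcomes <- c(state$outcomes, as.integer(outcome))
  pos <- length(state$choices)
  is_left <- c_int == 1L
  for (N in 0:4) {
    if (pos - 1L < N) next
    p <- .pat_c(state$choices, pos, N)
    state$occ_c[[N + 1L]][p] <- state$occ_c[[N + 1L]][p] + 1
    if (is_left) state$left_c[[N + 1L]][p] <- state$left_c[[N + 1L]][p] + 1
  }
  for (N in 1:4) {
    if (pos - 1L < N) next
    p <- .pat_co(state$choices, state$outcomes, pos, N)
    state$occ_co[[N]][p] <- state$occ_co[[N]][p] + 1
    if (is_left) state$left_co[[N]][p] <- state$left_co[[N]][p] + 1
  }
  state
}

# two-sided exact binomial p-value against p = 0.5 (symmetric case, so the
# minimal-tail doubling is exact and matches stats::binom.test)
.binom_p_half <- function(k, n) {
  p <- rep(1, length(k))
  pos <- n > 0
  m <- pmin(k[pos], n[pos] - k[pos])
  p[pos] <- pmin(1, 2 * pbinom(m, n[pos], 0.5))
  p
}

#' Nine conditional-probability estimates with exact binomial tests
#'
#' For the current history, returns the estimated probability that the mouse
#' chooses left given the most recent N choices (N = 0-4) and the most
#' recent N choice-outcome pairs (N = 1-4), with the suffix sample size and
#' a two-sided exact binomial p-value against 0.5. Conditions whose suffix
#' has never occurred (including when the history is shorter than N) return
#' estimate 0.5, n = 0, p = 1 and are never treated as significant.
#'
#' @param state An `opponent_state`.
#' @return A data.frame with columns `type` ("choice"/"choice_outcome"),
#'   `N`, `estimate`, `n`, `p_value`, in fixed precedence order (choice
#'   N = 0..4, then choice-outcome N = 1..4).
#' @export
opponent_predict <- function(state) {
  raw <- .opponent_predict_raw(state)
  data.frame(type = c(rep("choice", 5), rep("choice_outcome", 4)),
             N = c(0:4, 1:4), estimate = raw$estimate, n = raw$n,
             p_value = raw$p_value)
}

.opponent_predict_raw <- function(state) {
  stopifnot(inherits(state, "opponent_state"))
  if (length(state$choices) != length(state$outcomes)) {
    stop("invalid opponent state: choice and outcome histories differ in length")
  }
  pos <- length(state$choices) + 1L
  est <- num <- left <- numeric(9)
  Ns <- c(0:4, 1:4)
  for (j in 1:9) {
    N <- Ns[j]
    if (pos - 1L < N) {
      num[j] <- 0
    } else if (j <= 5L) {
      p <- .pat_c(state$choices, pos, N)
      num[j] <- state$occ_c[[N + 1L]][p]
      left[j] <- state$left_c[[N + 1L]][p]
    } else {
      p <- .pat_co(state$choices, state$outcomes, pos, N)
      num[j] <- state$occ_co[[N]][p]
      left[j] <- state$left_co[[N]][p]
    }
    est[j] <- if (num[j] > 0) left[j] / num[j] else 0.5
  }
  list(estimate = est, n = num, p_value = .binom_p_half(left, num))
}

#' Draw the computer's choice for the upcoming trial
#'
#' If no conditional probability is significant at `alpha_test`, the choice
#' is uniform. Otherwise let q* be the significant left-probability estimate
#' farthest from 0.5 (ties broken by fixed table order). In stochastic mode
#' the computer chooses left with probability 1 - q*; in deterministic mode
#' it picks the counter side outright. Uses the ambient R RNG.
#'
#' @param state An `opponent_state`.
#' @return `"L"` or `"R"`.
#' @export
opponent_choose <- function(state) {
  pred <- .opponent_predict_raw(state)
  sig <- pred$n > 0 & pred$p_value < state$alpha_test
  if (!any(sig)) {
    return(if (runif(1) < 0.5) "L" else "R")
  }
  dev <- abs(pred$estimate - 0.5)
  dev[!sig] <- -1
  q_star <- pred$estimate[which.max(dev)]  # which.max keeps first on ties
  if (state$counter_mode == "deterministic") {
    return(if (q_star > 0.5) "R" else "L")
  }
  if (runif(1) < 1 - q_star) "L" else "R"
}

#' @export
print.opponent_state <- function(x, ...) {
  cat("<opponent_state> ", length(x$choices), " trials observed; alpha_test = ",
      x$alpha_test, ", mode = ", x$counter_mode, "\n", sep = "")
  invisible(x)
}
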