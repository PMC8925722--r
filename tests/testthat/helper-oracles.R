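# Independent brute-force oracles used across the test files.

# de Bruijn B(2, 3) cycle over {L, R}, tiled k times with a 2-symbol wrap so
# every overlapping 3-choice window pattern appears exactly k times
debruijn3_sequence <- function(k = 4L) {
  cycle <- c("R", "R", "R", "L", "R", "L", "L", "L")
  c(rep(cycle, k), cycle[1:2])
}

# brute-force conditional probability estimates: count suffix matches by
# direct scanning of the history (the slow road opponent_predict must match)
brute_conditionals <- function(choices, outcomes) {
  stopifnot(length(choices) == length(outcomes))
  n <- length(choices)
  res <- data.frame(type = c(rep("choice", 5), rep("choice_outcome", 4)),
                    N = c(0:4, 1:4), estimate = 0.5, n = 0, p_value = 1)
  for (j in 1:9) {
    N <- res$N[j]
    if (n < N) next
    cur_suffix <- if (N == 0) NULL else {
      if (res$type[j] == "choice") choices[(n - N + 1):n]
      else paste(choices[(n - N + 1):n], outcomes[(n - N + 1):n])
    }
    hits <- 0; lefts <- 0
    for (t in (N + 1):n) {
      prev <- if (N == 0) NULL else {
        if (res$type[j] == "choice") choices[(t - N):(t - 1)]
        else paste(choices[(t - N):(t - 1)], outcomes[(t - N):(t - 1)])
      }
      if (identical(prev, cur_suffix)) {
        hits <- hits + 1
        if (choices[t] == 1) lefts <- lefts + 1
      }
    }
    if (hits > 0) {
      res$estimate[j] <- lefts / hits
      res$n[j] <- hits
      res$p_value[j] <- stats::binom.test(lefts, hits, 0.5)$p.value
    }
  }
  res
}

# feed a choice/outcome history into a fresh opponent state
observe_history <- function(choices_chr, outcomes, ...) {
  st <- opponent_state(...)
  for (i in seq_along(choices_chr)) {
    st <- opponent_observe(st, choices_chr[i], outcomes[i])
  }
  st
}

# plain-R forward-pass NLL via the latent trajectory (independent of the
# C++ likelihood path)
nll_oracle <- function(params, sessions) {
  if (is.data.frame(sessions)) sessions <- list(sessions)
  total <- 0
  for (s in sessions) {
    tr <- latent_trajectory(params, s)
    keep <- s$choice != "MISS"
    p <- ifelse(s$choice[keep] == "L", tr$pL[keep], 1 - tr$pL[keep])
    total <- total - sum(log(pmax(p, 1e-12)))
  }
  total
}

# minimal session constructor for hand-built fixtures
toy_session <- function(choices, outcomes, task = "matching_pennies") {
  mp_session(choices, outcomes, task = task)
}
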