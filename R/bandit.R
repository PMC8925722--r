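#' Create a two-armed bandit environment state
#'
#' Block-structured bandit with reward probabilities 0.7 : 0.1. Within a
#' block, once the agent has chosen the high-probability side ("hit") ten
#' times, every subsequent trial switches the probabilities with probability
#' 1/11 (so the number of trials after the tenth hit is geometric with mean
#' 11). A switch swaps the two probabilities and resets the hit counter.
#'
#' @param p_high,p_low The two reward probabilities.
#' @param first_high Which side starts high: `"L"`, `"R"`, or `"random"`.
#' @param hit_criterion Hits required before switching becomes possible.
#' @param p_switch Per-trial switch probability once armed.
#' @return An object of class `bandit_state`.
#' @export
bandit_state <- function(p_high = 0.7, p_low = 0.1,
                         first_high = c("random", "L", "R"),
                         hit_criterion = 10L, p_switch = 1 / 11) {
  first_high <- match.arg(first_high)
  high_left <- switch(first_high,
                      random = runif(1) < 0.5,
                      L = TRUE,
                      R = FALSE)
  structure(list(
    p_left = if (high_left) p_high else p_low,
    p_right = if (high_left) p_low else p_high,
    p_high = p_high, p_low = p_low,
    hits_in_block = 0L,
    switch_armed = FALSE,
    hit_criterion = as.integer(hit_criterion),
    p_switch = p_switch
  ), class = "bandit_state")
}

#' Advance the bandit by one trial
#'
#' The switch draw happens at the start of the trial (only once the hit
#' criterion has been met), then the outcome is drawn from the chosen side's
#' probability, then the hit counter is updated. MISS choices leave the
#' block state unchanged and yield outcome 0.
#'
#' @param state A [bandit_state()].
#' @param choice `"L"`, `"R"`, or `"MISS"`.
#' @return A list with `outcome` (0/1) and `state` (the updated
#'   `bandit_state`).
#' @export
bandit_step <- function(state, choice) {
  stopifnot(inherits(state, "bandit_state"))
  if (identical(choice, "MISS")) {
    return(list(outcome = 0L, state = state))
  }
  stopifnot(choice %in% c("L", "R"))
  if (state$switch_armed && runif(1) < state$p_switch) {
    tmp <- state$p_left
    state$p_left <- state$p_right
    state$p_right <- tmp
    state$hits_in_block <- 0L
    state$switch_armed <- FALSE
  }
  p <- if (choice == "L") state$p_left else state$p_right
  outcome <- as.integer(runif(1) < p)
  chose_high <- (choice == "L") == (state$p_left >= state$p_right)
  if (chose_high) {
    state$hits_in_block <- state$hits_in_block + 1L
    if (state$hits_in_block >= state$hit_criterion) state$switch_armed <- TRUE
  }
  list(outcome = outcome, state = state)
}
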