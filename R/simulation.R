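#' A fixed-probability agent
#'
#' Chooses left with constant probability `p_left` on every trial,
#' independent of history. `constant_agent(0.5)` is the uniform-random
#' (Nash) player; `constant_agent(1)` always chooses left.
#'
#' @param p_left Probability of choosing left.
#' @return An object of class `constant_agent`.
#' @export
constant_agent <- function(p_left = 0.5) {
  stopifnot(p_left >= 0, p_left <= 1)
  structure(list(p_left = p_left), class = "constant_agent")
}

#' Simulate a closed-loop session
#'
#' Each trial: in matching pennies the computer opponent draws its own
#' choice first (from the history so far), then the agent samples its
#' choice from its policy, the outcome is reward iff the choices match, and
#' both the agent and the opponent update. In the bandit the environment
#' draws the outcome from the chosen side's reward probability and the
#' block state advances. Simulated agents never miss. Cue times accumulate
#' response time + consumption + truncated-exponential ITI per trial, so
#' the session carries a realistic event timeline. Fully reproducible given
#' the RNG seed.
#'
#' @param agent A [model_params()] (learning agent) or [constant_agent()].
#' @param env `"matching_pennies"` or `"bandit"`.
#' @param n_trials Number of trials (>= 1).
#' @param opponent An [opponent_state()] template for matching pennies
#'   (fresh history is used regardless).
#' @param bandit A [bandit_state()] for the bandit environment.
#' @param timing A [timing_config()].
#' @return A list with `session` (an [mp_session()]) and `trajectory` (a
#'   [latent_trajectory()]; `NULL` for constant agents).
#' @export
simulate_session <- function(agent, env = c("matching_pennies", "bandit"),
                             n_trials = 500L,
                             opponent = opponent_state(),
                             bandit = bandit_state(),
                             timing = timing_config()) {
  env <- match.arg(env)
  stopifnot(n_trials >= 1L)
  is_learner <- inherits(agent, "model_params")
  if (!is_learner && !inherits(agent, "constant_agent")) {
    stop("agent must be model_params or constant_agent")
  }
  if (env == "matching_pennies") opponent <- .reset_opponent(opponent)

  choice <- character(n_trials)
  outcome <- integer(n_trials)
  comp <- rep(NA_character_, n_trials)
  cue_time <- numeric(n_trials)
  rt <- numeric(n_trials)
  blocks <- list()

  state <- if (is_learner) agent_state(agent$q0, agent$q0, agent$k0, agent$k0)
  prev_c <- NULL; prev_r <- NULL
  t_now <- 0
  if (env == "bandit") {
    blocks[[1]] <- data.frame(start_trial = 1L, p_left = bandit$p_left,
                              p_right = bandit$p_right)
  }

  for (i in seq_len(n_trials)) {
    cue_time[i] <- t_now
    if (env == "matching_pennies") {
      comp[i] <- opponent_choose(opponent)
    }
    pL <- if (is_learner) {
      action_probability(state, agent, prev_c, prev_r)
    } else {
      agent$p_left
    }
    ch <- if (runif(1) < pL) "L" else "R"
    if (env == "matching_pennies") {
      rw <- as.integer(ch == comp[i])
      opponent <- opponent_observe(opponent, ch, rw)
    } else {
      p_before <- c(bandit$p_left, bandit$p_right)
      step <- bandit_step(bandit, ch)
      rw <- step$outcome
      bandit <- step$state
      if (bandit$p_left != p_before[1]) {
        blocks[[length(blocks) + 1L]] <-
          data.frame(start_trial = i, p_left = bandit$p_left,
                     p_right = bandit$p_right)
      }
    }
    choice[i] <- ch
    outcome[i] <- rw
    if (is_learner) state <- update_state(state, ch, rw, agent)
    prev_c <- ch; prev_r <- rw
    rt[i] <- rlnorm(1, log(0.4), 0.3)  # stereotyped ~0.4-s lick latency
    delay <- sample_trial_timing(timing, penalty_licks = 0L)
    t_now <- t_now + rt[i] + delay$total_delay
  }

  session <- mp_session(choice, outcome,
                        computer_choice = comp, cue_time = cue_time,
                        response_time = rt,
                        task = env,
                        block_schedule = if (length(blocks))
                          do.call(rbind, blocks) else NULL)
  trajectory <- if (is_learner) latent_trajectory(agent, session) else NULL
  list(session = session, trajectory = trajectory)
}

.reset_opponent <- function(template) {
  opponent_state(alpha_test = template$alpha_test,
                 counter_mode = template$counter_mode)
}

#' Reward-rate sweep over the choice-kernel weight
#'
#' Varies the relative choice-kernel weight `w = beta_k / (beta + beta_k)`
#' on a grid while holding the learning rates and the total inverse
#' temperature `beta + beta_k` fixed (at, e.g., the median fitted values),
#' simulating `n_reps` hybrid-agent sessions per grid point and summarizing
#' the reward rate.
#'
#' @param grid Kernel-weight values in \[0, 1\].
#' @param alpha,alpha_k Learning rates held fixed.
#' @param beta_sum Fixed total inverse temperature `beta + beta_k`.
#' @param n_reps Sessions per grid point.
#' @param n_trials Trials per session.
#' @param env,opponent,bandit Environment as in [simulate_session()].
#' @return A data.frame of class `sweep_result` with `w`, `beta`, `beta_k`,
#'   `mean_reward_rate`, `sd_reward_rate`, `se_reward_rate`; the fixed
#'   parameters are stored in attributes.
#' @export
sweep_kernel_weight <- function(grid = seq(0, 1, length.out = 11L),
                                alpha = 0.60, alpha_k = 0.13,
                                beta_sum = 2.15,
                                n_reps = 20L, n_trials = 500L,
                                env = c("matching_pennies", "bandit"),
                                opponent = opponent_state(),
                                bandit = bandit_state()) {
  env <- match.arg(env)
  stopifnot(all(grid >= 0 & grid <= 1))
  grid <- sort(grid)
  rows <- lapply(grid, function(w) {
    params <- model_params("FQ_RPE_CK", alpha = alpha, alpha_k = alpha_k,
                           beta = (1 - w) * beta_sum, beta_k = w * beta_sum)
    rates <- vapply(seq_len(n_reps), function(r) {
      sim <- simulate_session(params, env, n_trials, opponent = opponent,
                              bandit = bandit)
      mean(sim$session$outcome)
    }, numeric(1))
    data.frame(w = w, beta = (1 - w) * beta_sum, beta_k = w * beta_sum,
               mean_reward_rate = mean(rates),
               sd_reward_rate = sd(rates),
               se_reward_rate = sd(rates) / sqrt(n_reps))
  })
  out <- do.call(rbind, rows)
  attr(out, "fixed") <- list(alpha = alpha, alpha_k = alpha_k,
                             beta_sum = beta_sum, env = env,
                             n_reps = n_reps, n_trials = n_trials)
  class(out) <- c("sweep_result", class(out))
  out
}
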