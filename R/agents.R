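#' Decision-model parameters
#'
#' Bundles the parameters of the five trial-by-trial decision models:
#'
#' * `WSLS`: win-stay-lose-switch with adherence probability `p_wsls`.
#' * `Q_RPE`: Q-learning; the chosen value moves toward the outcome at rate
#'   `alpha`, the unchosen value is unchanged; softmax with inverse
#'   temperature `beta`.
#' * `FQ_RPE`: Q-learning with forgetting; as `Q_RPE` but the unchosen value
#'   decays by `(1 - alpha)`.
#' * `DQ_RPE`: differential Q-learning; the chosen value moves toward 1 at
#'   rate `alpha_r` (rewarded) or `alpha_u` (unrewarded). (A documented
#'   variant, `dq_unrewarded_toward_zero = TRUE`, moves unrewarded values
#'   toward 0 instead.)
#' * `FQ_RPE_CK`: the hybrid model; `FQ_RPE` values plus choice kernels that
#'   move toward 1 (chosen) / 0 (unchosen) at rate `alpha_k`, combined in
#'   the softmax as `beta * Q + beta_k * K`.
#'
#' Constraint box: learning rates and `p_wsls` in \[0, 1\]; inverse
#' temperatures positive (capped at 100 during fitting).
#'
#' @param model One of `"WSLS"`, `"Q_RPE"`, `"FQ_RPE"`, `"DQ_RPE"`,
#'   `"FQ_RPE_CK"`.
#' @param alpha,alpha_k,alpha_r,alpha_u Learning rates in \[0, 1\].
#' @param beta,beta_k Inverse temperatures (> 0).
#' @param p_wsls WSLS adherence probability in \[0, 1\].
#' @param q0,k0 Initial action values / choice kernels (default 0, so the
#'   first-trial choice probability is 0.5).
#' @param dq_unrewarded_toward_zero Use the toward-0 unrewarded update for
#'   `DQ_RPE`.
#' @return An object of class `model_params`.
#' @export
model_params <- function(model = c("FQ_RPE_CK", "WSLS", "Q_RPE", "FQ_RPE",
                                   "DQ_RPE"),
                         alpha = NA_real_, alpha_k = NA_real_,
                         alpha_r = NA_real_, alpha_u = NA_real_,
                         beta = NA_real_, beta_k = NA_real_,
                         p_wsls = NA_real_, q0 = 0, k0 = 0,
                         dq_unrewarded_toward_zero = FALSE) {
  model <- match.arg(model)
  need <- .model_free_params(model)
  vals <- list(alpha = alpha, alpha_k = alpha_k, alpha_r = alpha_r,
               alpha_u = alpha_u, beta = beta, beta_k = beta_k,
               p_wsls = p_wsls)
  for (nm in need) {
    v <- vals[[nm]]
    if (is.na(v)) stop("model ", model, " requires parameter ", nm)
    if (nm %in% c("alpha", "alpha_k", "alpha_r", "alpha_u", "p_wsls")) {
      if (v < 0 || v > 1) stop(nm, " must lie in [0, 1]")
    } else if (v < 0) {
      stop(nm, " must be non-negative")
    }
  }
  structure(c(vals, list(model = model, q0 = q0, k0 = k0,
                         dq_unrewarded_toward_zero =
                           isTRUE(dq_unrewarded_toward_zero))),
            class = "model_params")
}

.model_ids <- c(WSLS = 1L, Q_RPE = 2L, FQ_RPE = 3L, DQ_RPE = 4L,
                FQ_RPE_CK = 5L)

.model_free_params <- function(model) {
  switch(model,
         WSLS = "p_wsls",
         Q_RPE = c("alpha", "beta"),
         FQ_RPE = c("alpha", "beta"),
         DQ_RPE = c("alpha_r", "alpha_u", "beta"),
         FQ_RPE_CK = c("alpha", "alpha_k", "beta", "beta_k"))
}

# flat numeric parameter vector consumed by the C++ likelihood
.param_vector <- function(params) {
  g <- function(x) if (is.na(x)) 0 else x
  c(g(params$alpha), g(params$alpha_k), g(params$alpha_r), g(params$alpha_u),
    g(params$beta), g(params$beta_k), g(params$p_wsls),
    as.numeric(params$dq_unrewarded_toward_zero))
}

#' Agent state: action values and choice kernels
#'
#' @param q_left,q_right Action values.
#' @param k_left,k_right Choice kernels.
#' @return A list of class `agent_state`.
#' @export
agent_state <- function(q_left = 0, q_right = 0, k_left = 0, k_right = 0) {
  structure(list(q_left = q_left, q_right = q_right,
                 k_left = k_left, k_right = k_right),
            class = "agent_state")
}

#' One-trial state update
#'
#' Applies the model's learning rule given the trial's choice and outcome.
#' MISS trials return the state unchanged (no choice/outcome pair exists to
#' learn from).
#'
#' @param state An [agent_state()].
#' @param choice `"L"`, `"R"`, or `"MISS"`.
#' @param outcome 0 or 1.
#' @param params A [model_params()].
#' @return The updated `agent_state`.
#' @export
update_state <- function(state, choice, outcome, params) {
  stopifnot(inherits(state, "agent_state"), inherits(params, "model_params"))
  if (identical(choice, "MISS")) return(state)
  stopifnot(choice %in% c("L", "R"), outcome %in% c(0, 1))
  chosen_left <- choice == "L"
  model <- params$model
  qc <- if (chosen_left) state$q_left else state$q_right
  qu <- if (chosen_left) state$q_right else state$q_left

  if (model %in% c("Q_RPE", "FQ_RPE", "FQ_RPE_CK")) {
    qc <- qc + params$alpha * (outcome - qc)
    if (model != "Q_RPE") qu <- (1 - params$alpha) * qu
  } else if (model == "DQ_RPE") {
    rate <- if (outcome == 1) params$alpha_r else params$alpha_u
    target <- if (outcome == 0 && params$dq_unrewarded_toward_zero) 0 else 1
    qc <- qc + rate * (target - qc)
  }
  if (chosen_left) {
    state$q_left <- qc; state$q_right <- qu
  } else {
    state$q_right <- qc; state$q_left <- qu
  }
  if (model == "FQ_RPE_CK") {
    ak <- params$alpha_k
    if (chosen_left) {
      state$k_left <- state$k_left + ak * (1 - state$k_left)
      state$k_right <- (1 - ak) * state$k_right
    } else {
      state$k_right <- state$k_right + ak * (1 - state$k_right)
      state$k_left <- (1 - ak) * state$k_left
    }
  }
  state
}

#' Probability of choosing left on the upcoming trial
#'
#' Softmax over `beta * Q + beta_k * K` (kernels enter for `FQ_RPE_CK`
#' only), computed with max-subtraction for numerical stability. `WSLS`
#' instead returns the stay/switch probability given the previous trial and
#' 0.5 on the first trial (or after a MISS with no earlier history).
#'
#' @inheritParams update_state
#' @param prev_choice,prev_outcome Previous trial's choice/outcome (WSLS
#'   only; `NULL` on the first trial).
#' @return P(choose left), strictly inside (0, 1).
#' @export
action_probability <- function(state, params, prev_choice = NULL,
                               prev_outcome = NULL) {
  stopifnot(inherits(state, "agent_state"), inherits(params, "model_params"))
  if (params$model == "WSLS") {
    if (is.null(prev_choice) || identical(prev_choice, "MISS")) return(0.5)
    p_stay <- if (prev_outcome == 1) params$p_wsls else 1 - params$p_wsls
    return(if (prev_choice == "L") p_stay else 1 - p_stay)
  }
  bk <- if (params$model == "FQ_RPE_CK") params$beta_k else 0
  w_l <- params$beta * state$q_left + bk * state$k_left
  w_r <- params$beta * state$q_right + bk * state$k_right
  m <- max(w_l, w_r)
  e_l <- exp(w_l - m); e_r <- exp(w_r - m)
  e_l / (e_l + e_r)
}

#' Latent-variable trajectory implied by a model on an observed session
#'
#' Forward pass through the session: for each trial the pre-choice action
#' values and choice kernels, the model probability of choosing left, the
#' reward prediction error (RPE, `r_n - Q_chosen`) and the choice-kernel
#' error (CKE, `1 - K_chosen`), plus the value/kernel differences used by
#' the softmax. MISS trials carry the pre-choice state and probability but
#' `NA` RPE/CKE, and trigger no update. Deterministic given its inputs.
#'
#' @param params A [model_params()].
#' @param session An [mp_session()] (or anything with `choice`/`outcome`
#'   columns).
#' @return A data.frame of class `latent_trajectory` with columns `trial`,
#'   `qL`, `qR`, `kL`, `kR`, `pL`, `rpe`, `cke`, `dq`, `dk`, `q_chosen`,
#'   `k_chosen`. The generating `model_params` are stored in the `params`
#'   attribute.
#' @export
latent_trajectory <- function(params, session) {
  stopifnot(inherits(params, "model_params"))
  n <- nrow(session)
  cols <- c("qL", "qR", "kL", "kR", "pL", "rpe", "cke", "dq", "dk",
            "q_chosen", "k_chosen")
  out <- as.data.frame(matrix(NA_real_, n, length(cols)))
  names(out) <- cols
  state <- agent_state(params$q0, params$q0, params$k0, params$k0)
  prev_c <- NULL; prev_r <- NULL
  for (i in seq_len(n)) {
    ch <- session$choice[i]; rw <- session$outcome[i]
    out$qL[i] <- state$q_left; out$qR[i] <- state$q_right
    out$kL[i] <- state$k_left; out$kR[i] <- state$k_right
    out$dq[i] <- state$q_left - state$q_right
    out$dk[i] <- state$k_left - state$k_right
    out$pL[i] <- action_probability(state, params, prev_c, prev_r)
    if (ch != "MISS") {
      qc <- if (ch == "L") state$q_left else state$q_right
      kc <- if (ch == "L") state$k_left else state$k_right
      out$q_chosen[i] <- qc
      out$k_chosen[i] <- kc
      out$rpe[i] <- rw - qc
      out$cke[i] <- 1 - kc
      state <- update_state(state, ch, rw, params)
      prev_c <- ch; prev_r <- rw
    }
  }
  out <- cbind(trial = seq_len(n), out)
  attr(out, "params") <- params
  class(out) <- c("latent_trajectory", class(out))
  out
}

#' Write a latent trajectory to CSV
#'
#' Columns `trial,qL,qR,kL,kR,pL,rpe,cke` for downstream regression.
#'
#' @param trajectory A [latent_trajectory()].
#' @param path File path.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory)[, c("trial", "qL", "qR", "kL", "kR",
                                          "pL", "rpe", "cke")],
            path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore model parameters as YAML
#'
#' @param params A [model_params()].
#' @param path File path.
#' @export
write_params <- function(params, path) {
  lst <- unclass(params)
  lst <- lst[!vapply(lst, function(x) is.numeric(x) && is.na(x), logical(1))]
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(model_params, lst)
}
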