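#' Negative log-likelihood of a model on one or more sessions
#'
#' Sessions are concatenated in the order given; the agent state resets at
#' every session boundary (sessions are separate days). MISS trials
#' contribute no likelihood term and trigger no update. Choice
#' probabilities are floored at 1e-12 before taking logs.
#'
#' @param params A [model_params()].
#' @param sessions An [mp_session()] or a list of them.
#' @return The scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(params, sessions) {
  stopifnot(inherits(params, "model_params"))
  dat <- .stack_sessions(sessions)
  if (sum(!is.na(dat$choice)) == 0L) {
    stop("no non-MISS trials: likelihood undefined")
  }
  nll_forward_cpp(.model_ids[[params$model]], .param_vector(params),
                  dat$choice, dat$outcome, dat$session,
                  params$q0, params$k0)
}

.stack_sessions <- function(sessions) {
  if (is.data.frame(sessions)) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1L)
  choice <- unlist(lapply(sessions, function(s) .choice_to_int(s$choice)))
  outcome <- unlist(lapply(sessions, function(s) as.integer(s$outcome)))
  sess <- rep(seq_along(sessions),
              vapply(sessions, nrow, integer(1)))
  list(choice = as.integer(choice), outcome = outcome,
       session = as.integer(sess))
}

# box used during optimization: rates/p in [0,1], betas log-parameterized
# with an upper cap of 100 (the constraint box only states positivity)
.beta_cap <- 100
.log_beta_lo <- log(1e-4)

.pack_theta <- function(params) {
  nm <- .model_free_params(params$model)
  th <- vapply(nm, function(p) {
    v <- params[[p]]
    if (p %in% c("beta", "beta_k")) log(max(v, 1e-4)) else v
  }, numeric(1))
  names(th) <- nm
  th
}

.unpack_theta <- function(theta, model, ...) {
  nm <- .model_free_params(model)
  args <- list(model = model, ...)
  for (i in seq_along(nm)) {
    v <- theta[i]
    if (nm[i] %in% c("beta", "beta_k")) v <- exp(v)
    args[[nm[i]]] <- unname(v)
  }
  do.call(model_params, args)
}

.theta_bounds <- function(model) {
  nm <- .model_free_params(model)
  lo <- ifelse(nm %in% c("beta", "beta_k"), .log_beta_lo, 0)
  hi <- ifelse(nm %in% c("beta", "beta_k"), log(.beta_cap), 1)
  list(lower = lo, upper = hi, names = nm)
}

.random_start <- function(model) {
  nm <- .model_free_params(model)
  vapply(nm, function(p) {
    if (p %in% c("beta", "beta_k")) log(runif(1, 0.2, 10))
    else runif(1, 0.05, 0.95)
  }, numeric(1))
}

#' Constrained maximum-likelihood fit of one model
#'
#' Box-constrained L-BFGS-B from `n_restarts` random interior starting
#' points (the surface is nonconvex); the best optimum is kept. Learning
#' rates and the WSLS adherence are bounded to \[0, 1\]; inverse
#' temperatures are optimized on the log scale with an upper cap of 100.
#' The BIC uses the number of non-MISS choice observations.
#'
#' @param model Model name (see [model_params()]).
#' @param sessions An [mp_session()] or list of them.
#' @param n_restarts Number of random restarts (>= 1).
#' @param init Optional extra starting `model_params` tried in addition to
#'   the random starts.
#' @return A list of class `fit_result` with elements `params`, `nll`,
#'   `n_obs`, `n_params`, `bic`, `n_restarts_used`, `converged`.
#' @export
fit_model <- function(model, sessions, n_restarts = 10L, init = NULL) {
  stopifnot(n_restarts >= 1L)
  model <- match.arg(model, names(.model_ids))
  dat <- .stack_sessions(sessions)
  n_obs <- sum(!is.na(dat$choice))
  if (n_obs == 0L) stop("no non-MISS trials to fit")
  mid <- .model_ids[[model]]
  bounds <- .theta_bounds(model)

  obj <- function(theta) {
    p <- .unpack_theta(theta, model)
    nll_forward_cpp(mid, .param_vector(p), dat$choice, dat$outcome,
                    dat$session, p$q0, p$k0)
  }

  starts <- replicate(n_restarts, .random_start(model), simplify = FALSE)
  if (!is.null(init)) starts <- c(list(.pack_theta(init)), starts)

  best <- NULL
  any_ok <- FALSE
  for (th0 in starts) {
    fit <- tryCatch(
      optim(th0, obj, method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper,
            control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_ok <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!any_ok) {
    stop("optimizer failed on all ", length(starts), " restarts for model ",
         model)
  }
  k <- length(bounds$names)
  params <- .unpack_theta(best$par, model)
  structure(list(
    params = params,
    nll = best$value,
    n_obs = n_obs,
    n_params = k,
    bic = 2 * best$value + k * log(n_obs),
    n_restarts_used = length(starts),
    converged = best$convergence == 0
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> model =", x$params$model,
      sprintf(" nll = %.3f  BIC = %.3f  (k = %d, n = %d)\n",
              x$nll, x$bic, x$n_params, x$n_obs))
  nm <- .model_free_params(x$params$model)
  vals <- vapply(nm, function(p) x$params[[p]], numeric(1))
  cat("  ", paste(sprintf("%s = %.4f", nm, vals), collapse = ", "), "\n")
  invisible(x)
}

#' Fit all five models and compare by BIC
#'
#' Free-parameter counts: WSLS 1; Q_RPE and FQ_RPE 2; DQ_RPE 3;
#' FQ_RPE_CK 4. The winner attains the minimal BIC. Both the summed BIC
#' and the per-session mean are reported in the comparison table.
#'
#' @inheritParams fit_model
#' @param models Models to include (default: all five).
#' @return A list of class `model_comparison` with elements `fits` (named
#'   list of [fit_model()] results), `table` (data.frame with `model`, `k`,
#'   `nll`, `bic`, `bic_per_session`, `delta_bic`), and `winner`.
#' @export
compare_models <- function(sessions, n_restarts = 10L,
                           models = names(.model_ids)) {
  n_sessions <- if (is.data.frame(sessions)) 1L else length(sessions)
  fits <- lapply(models, function(m) fit_model(m, sessions, n_restarts))
  names(fits) <- models
  tab <- data.frame(
    model = models,
    k = vapply(fits, `[[`, numeric(1), "n_params"),
    nll = vapply(fits, `[[`, numeric(1), "nll"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    stringsAsFactors = FALSE
  )
  tab$bic_per_session <- tab$bic / n_sessions
  tab$delta_bic <- tab$bic - min(tab$bic)
  structure(list(fits = fits, table = tab,
                 winner = models[which.min(tab$bic)]),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> winner by BIC:", x$winner, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
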