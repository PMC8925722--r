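#' Construct a session table
#'
#' A session is a plain data.frame with one row per trial and columns
#' `trial` (1-based, consecutive), `choice` ("L"/"R"/"MISS"), `outcome`
#' (0/1), `computer_choice` ("L"/"R", `NA` for bandit sessions), `cue_time`
#' (s from session start) and `response_time` (s from cue onset, `NA` for
#' MISS trials). The `task` attribute records the environment
#' ("matching_pennies" or "bandit"); bandit sessions may carry a
#' `block_schedule` attribute listing `(start_trial, p_left, p_right)`.
#'
#' @param choice,outcome,computer_choice,cue_time,response_time Per-trial
#'   vectors (recycled NA defaults where absent).
#' @param task Environment identifier.
#' @param block_schedule Optional data.frame of bandit block bounds.
#' @return A data.frame of class `mp_session`.
#' @export
mp_session <- function(choice, outcome, computer_choice = NULL,
                       cue_time = NULL, response_time = NULL,
                       task = c("matching_pennies", "bandit"),
                       block_schedule = NULL) {
  task <- match.arg(task)
  n <- length(choice)
  stopifnot(length(outcome) == n, all(outcome %in% c(0, 1)))
  stopifnot(all(choice %in% c("L", "R", "MISS")))
  if (any(choice == "MISS" & outcome != 0)) {
    stop("MISS trials must carry outcome 0")
  }
  if (is.null(computer_choice)) computer_choice <- rep(NA_character_, n)
  if (task == "matching_pennies" && !anyNA(computer_choice)) {
    ok <- choice == "MISS" |
      (outcome == 1) == (choice == computer_choice)
    if (!all(ok)) stop("outcome must equal 1 iff choice matches computer_choice")
  }
  if (is.null(cue_time)) cue_time <- rep(NA_real_, n)
  if (is.null(response_time)) response_time <- rep(NA_real_, n)
  out <- data.frame(trial = seq_len(n), choice = choice,
                    outcome = as.integer(outcome),
                    computer_choice = computer_choice,
                    cue_time = cue_time, response_time = response_time,
                    stringsAsFactors = FALSE)
  attr(out, "task") <- task
  if (!is.null(block_schedule)) attr(out, "block_schedule") <- block_schedule
  class(out) <- c("mp_session", class(out))
  out
}

#' Read / write a session CSV
#'
#' One row per trial, header required, columns
#' `trial,choice,outcome,computer_choice,cue_time,response_time` with
#' choices encoded `L`/`R`/`MISS`.
#'
#' @param path File path.
#' @param task Environment identifier for the returned session.
#' @return `read_session()` returns an `mp_session`.
#' @export
read_session <- function(path, task = c("matching_pennies", "bandit")) {
  task <- match.arg(task)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "choice", "outcome")
  if (!all(need %in% names(df))) {
    stop("session file must contain columns: ", paste(need, collapse = ", "))
  }
  mp_session(choice = df$choice, outcome = df$outcome,
             computer_choice = if ("computer_choice" %in% names(df))
               df$computer_choice else NULL,
             cue_time = if ("cue_time" %in% names(df)) df$cue_time else NULL,
             response_time = if ("response_time" %in% names(df))
               df$response_time else NULL,
             task = task)
}

#' @rdname read_session
#' @param session An `mp_session`.
#' @export
write_session <- function(session, path) {
  write.csv(as.data.frame(session)[, c("trial", "choice", "outcome",
                                       "computer_choice", "cue_time",
                                       "response_time")],
            path, row.names = FALSE)
  invisible(path)
}
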