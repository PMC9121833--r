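# Behavioral classification of sessions: learning-trial detection,
# piecewise robust regression of the cumulative reward curve, and
# session-level performance summaries.

#' Find the learning trial of an outcome sequence
#'
#' The learning trial is the earliest trial t with three consecutive correct
#' trials (o_t = o_{t+1} = o_{t+2} = 1) followed by performance of at least
#' 80% correct; the 80% window runs from t to the end of the session
#' (including the three-trial run).
#'
#' @param outcomes 0/1 outcome vector, length >= 3.
#' @param criterion Required proportion correct from the learning trial on.
#' @param include_run Include trials t..t+2 in the criterion window (the
#'   default); `FALSE` evaluates the window from t+3 on instead.
#' @return The learning trial index, or `NULL` if no trial qualifies.
#' @export
find_learning_trial <- function(outcomes, criterion = 0.8, include_run = TRUE) {
  Tt <- length(outcomes)
  stopifnot(Tt >= 3, all(outcomes %in% c(0, 1)))
  for (t in seq_len(Tt - 2)) {
    if (all(outcomes[t:(t + 2)] == 1)) {
      win <- if (include_run) outcomes[t:Tt] else outcomes[seq(t + 3, Tt)[seq_len(max(Tt - t - 2, 0))]]
      if (length(win) > 0 && mean(win) >= criterion) return(t)
    }
  }
  NULL
}

robust_slope <- function(y) {
  x <- seq_along(y)
  if (stats::sd(y) == 0) return(0)
  fit <- tryCatch(
    suppressWarnings(MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
                               maxit = 50)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) fit <- stats::lm(y ~ x)
  unname(stats::coef(fit)[2])
}

#' Reward-accumulation rates around a split trial
#'
#' Fits robust regression lines (iteratively reweighted least squares with
#' bisquare weights, tuning constant 4.685, at most 50 iterations) to the
#' cumulative reward curve on trials `[1, split - 1]` and `[split, T]` and
#' returns the two slopes, the per-trial reward-accumulation rates before
#' and after the split.
#'
#' @param outcomes 0/1 outcome vector.
#' @param split Split trial index; both sides need at least 2 trials.
#' @return Named numeric `c(r_before, r_after)`.
#' @export
reward_rates <- function(outcomes, split) {
  Tt <- length(outcomes)
  if (split < 3 || split > Tt - 1)
    stop("each side of the split needs at least 2 trials", call. = FALSE)
  cum <- cumsum(outcomes)
  c(r_before = robust_slope(cum[seq_len(split - 1)]),
    r_after = robust_slope(cum[split:Tt]))
}

#' Classify a session by its behavior
#'
#' A session is `learning` if [find_learning_trial()] succeeds (split at the
#' learning trial); else `rule-change` if the metadata carries a rule-change
#' trial (split there); else `other`, with the split at the trial maximizing
#' the increase in reward-accumulation slope, `r_after - r_before`, over
#' splits with at least `min_side` trials on each side (ties broken by the
#' earliest trial).
#'
#' @param x A `SessionRecording` or a 0/1 outcome vector.
#' @param min_side Minimum trials on each side of a tested split.
#' @param rule_change_trial Rule-change trial (taken from session metadata
#'   when `x` is a session).
#' @return A `LearningAssessment`: list with `class`, `split`, `r_before`,
#'   `r_after`, `delta_r`, `performance`.
#' @export
classify_session <- function(x, min_side = 5, rule_change_trial = NULL) {
  if (inherits(x, "SessionRecording")) {
    rule_change_trial <- rule_change_trial %||% x$metadata$rule_change_trial
    outcomes <- x$trials$outcome
  } else outcomes <- x
  Tt <- length(outcomes)
  lt <- if (Tt >= 3) find_learning_trial(outcomes) else NULL
  mk <- function(class, split) {
    rr <- if (!is.null(split) && split >= 3 && split <= Tt - 1)
      reward_rates(outcomes, split) else c(r_before = NA_real_, r_after = NA_real_)
    structure(list(class = class, split = split,
                   r_before = unname(rr[1]), r_after = unname(rr[2]),
                   delta_r = unname(rr[2] - rr[1]),
                   performance = mean(outcomes)),
              class = "LearningAssessment")
  }
  if (!is.null(lt)) return(mk("learning", lt))
  if (!is.null(rule_change_trial)) return(mk("rule-change", rule_change_trial))
  lo <- min_side + 1; hi <- Tt - min_side
  if (lo > hi) {
    warning("session too short for split search")
    return(mk("other", NULL))
  }
  cand <- lo:hi
  dr <- vapply(cand, function(t) {
    rr <- reward_rates(outcomes, t)
    unname(rr[2] - rr[1])
  }, numeric(1))
  mk("other", cand[which.max(dr)])
}

#' @export
print.LearningAssessment <- function(x, ...) {
  cat(sprintf("LearningAssessment: %s, split trial %s, r_before %.3f, r_after %.3f (delta %.3f)\n",
              x$class, x$split %||% "none", x$r_before, x$r_after, x$delta_r))
  invisible(x)
}

#' Session performance
#'
#' Proportion of correct trials.
#'
#' @param x A `SessionRecording` or 0/1 outcome vector.
#' @return Proportion in `[0, 1]`.
#' @export
session_performance <- function(x) {
  if (inherits(x, "SessionRecording")) x <- x$trials$outcome
  mean(x)
}
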