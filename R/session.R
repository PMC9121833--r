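#' Construct a session recording
#'
#' Bundles the four data streams of one recording session — spike trains,
#' position tracking, the trial event table, and slow-wave-sleep intervals —
#' together with session metadata, and validates all structural invariants.
#'
#' Conventions: all times are in seconds; every interval is half-open
#' `[start, end)` so a spike on a boundary is counted exactly once. Trial
#' `i` is `[t_start, t_armend)`; its intertrial interval (ITI) is
#' `[t_armend, t_iti_end)`. Trials are numbered from 1.
#'
#' @param spikes data.frame with columns `neuron_id` (integer) and
#'   `spike_time_s` (seconds, nondecreasing within each neuron, recorded at
#'   0.1 ms resolution).
#' @param position data.frame with columns `time_s` (strictly increasing),
#'   `x_cm`, `y_cm`; nominal 30 samples/s.
#' @param trials data.frame with columns `trial`, `t_start_s`, `t_armend_s`,
#'   `t_iti_end_s`, `direction` ("left"/"right"), `light` ("left"/"right"),
#'   `outcome` (0/1).
#' @param sleep data.frame with columns `epoch` ("pre"/"post"), `t_start_s`,
#'   `t_end_s`; slow-wave-sleep intervals only, taken as given.
#' @param metadata list with `rat_id`, `rule_name`, `rule_class`
#'   ("direction" or "cue"), optional `rule_change_trial`, and maze geometry
#'   (`arm_length_cm`, default 85; three arms separated by 120 degrees).
#' @return An object of class `SessionRecording`.
#' @export
session_recording <- function(spikes, position, trials, sleep, metadata = list()) {
  metadata$arm_length_cm <- metadata$arm_length_cm %||% 85
  x <- structure(
    list(spikes = as.data.frame(spikes), position = as.data.frame(position),
         trials = as.data.frame(trials), sleep = as.data.frame(sleep),
         metadata = metadata),
    class = "SessionRecording")
  validate_session(x)
  x
}

#' Validate a session recording
#'
#' Checks every structural invariant of the session data model and stops with
#' an error of the form `"invalid session: <violated invariant>"` on the
#' first violation found.
#'
#' @param session A `SessionRecording`.
#' @return The session, invisibly, if valid.
#' @export
validate_session <- function(session) {
  fail <- function(msg) stop("invalid session: ", msg, call. = FALSE)
  sp <- session$spikes; po <- session$position
  tr <- session$trials; sl <- session$sleep

  need <- function(df, cols, what) {
    if (!all(cols %in% names(df))) fail(paste0(what, " missing columns"))
  }
  need(sp, c("neuron_id", "spike_time_s"), "spikes")
  need(po, c("time_s", "x_cm", "y_cm"), "position")
  need(tr, c("trial", "t_start_s", "t_armend_s", "t_iti_end_s",
             "direction", "light", "outcome"), "trials")
  need(sl, c("epoch", "t_start_s", "t_end_s"), "sleep")

  if (nrow(sp) > 0) {
    if (!all(is.finite(sp$spike_time_s)) || any(sp$spike_time_s < 0))
      fail("spike times must be finite and nonnegative")
    if (is.unsorted(order(sp$neuron_id, sp$spike_time_s)) &&
        any(unlist(tapply(sp$spike_time_s, sp$neuron_id,
                          function(t) any(diff(t) < 0)))))
      fail("spike times nondecreasing within each neuron")
  }
  if (length(unique(sp$neuron_id)) < 1) fail("N >= 1 neurons required")

  if (nrow(po) > 0) {
    if (!all(is.finite(po$time_s)) || !all(is.finite(po$x_cm)) ||
        !all(is.finite(po$y_cm)))
      fail("position samples must be finite")
    if (any(diff(po$time_s) <= 0))
      fail("position times strictly increasing")
  }

  if (nrow(tr) < 1) fail("T >= 1 trials required")
  if (any(!(tr$t_start_s < tr$t_armend_s & tr$t_armend_s < tr$t_iti_end_s)))
    fail("t_start < t_armend < t_iti_end for every trial")
  if (nrow(tr) > 1 && any(utils::head(tr$t_iti_end_s, -1) >
                          utils::tail(tr$t_start_s, -1) + 1e-12))
    fail("trials ordered and non-overlapping")
  if (!all(tr$direction %in% c("left", "right")))
    fail("direction must be left/right")
  if (!all(tr$light %in% c("left", "right"))) fail("light must be left/right")
  if (!all(tr$outcome %in% c(0, 1))) fail("outcome must be 0/1")

  if (nrow(sl) > 0) {
    if (!all(sl$epoch %in% c("pre", "post"))) fail("sleep epoch must be pre/post")
    if (any(sl$t_end_s <= sl$t_start_s))
      fail("sleep intervals must have positive duration")
    for (ep in unique(sl$epoch)) {
      s <- sl[sl$epoch == ep, , drop = FALSE]
      if (nrow(s) > 1 && any(utils::head(s$t_end_s, -1) >
                             utils::tail(s$t_start_s, -1) + 1e-12))
        fail("sleep intervals non-overlapping and ordered within an epoch")
    }
    if (any(sl$epoch == "pre") &&
        max(sl$t_end_s[sl$epoch == "pre"]) > min(tr$t_start_s) + 1e-12)
      fail("trial events must follow the pre-sleep epoch")
    if (any(sl$epoch == "post") &&
        min(sl$t_start_s[sl$epoch == "post"]) < max(tr$t_iti_end_s) - 1e-12)
      fail("trial events must precede the post-sleep epoch")
  }
  invisible(session)
}

#' @export
print.SessionRecording <- function(x, ...) {
  cat("SessionRecording:",
      length(unique(x$spikes$neuron_id)), "neurons,",
      nrow(x$trials), "trials,",
      nrow(x$sleep), "sleep intervals\n")
  cat("  rat:", x$metadata$rat_id %||% "?",
      " rule:", x$metadata$rule_name %||% "?",
      paste0("(", x$metadata$rule_class %||% "?", ")"), "\n")
  invisible(x)
}

#' Number of trials in a session
#' @param session A `SessionRecording`.
#' @return Integer trial count.
#' @export
n_trials <- function(session) nrow(session$trials)

bundle_files <- c(spikes = "spikes.tsv", position = "position.tsv",
                  trials = "trials.tsv", sleep = "sleep.tsv",
                  meta = "session.json")

#' Write a session bundle to disk
#'
#' Serializes a session as five plain-text files (`spikes.tsv`,
#' `position.tsv`, `trials.tsv`, `sleep.tsv`, `session.json`). Times are
#' written at 0.1 ms precision (4 decimals, half-even rounding), so a session
#' whose times lie on the recording grid round-trips bit-exactly.
#'
#' @param session A valid `SessionRecording`.
#' @param bundle_path Directory to create/write into.
#' @return `bundle_path`, invisibly.
#' @seealso [load_session()]
#' @export
write_session <- function(session, bundle_path) {
  validate_session(session)
  dir.create(bundle_path, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) sprintf("%.4f", round_time(x))
  wr <- function(df, file) {
    utils::write.table(df, file.path(bundle_path, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  sp <- session$spikes
  sp$spike_time_s <- fmt(sp$spike_time_s)
  wr(sp, "spikes.tsv")
  po <- session$position
  po$time_s <- fmt(po$time_s)
  po$x_cm <- sprintf("%.4f", po$x_cm)
  po$y_cm <- sprintf("%.4f", po$y_cm)
  wr(po, "position.tsv")
  tr <- session$trials
  for (cc in c("t_start_s", "t_armend_s", "t_iti_end_s")) tr[[cc]] <- fmt(tr[[cc]])
  wr(tr, "trials.tsv")
  sl <- session$sleep
  for (cc in c("t_start_s", "t_end_s")) sl[[cc]] <- fmt(sl[[cc]])
  wr(sl, "sleep.tsv")
  jsonlite::write_json(session$metadata, file.path(bundle_path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(bundle_path)
}

#' Load a session bundle from disk
#'
#' Reads a bundle written by [write_session()] and validates it.
#'
#' @param bundle_path Directory containing the five bundle files.
#' @return A validated `SessionRecording`.
#' @export
load_session <- function(bundle_path) {
  paths <- file.path(bundle_path, bundle_files)
  missing <- bundle_files[!file.exists(paths)]
  if (length(missing))
    stop("incomplete bundle: missing ", paste(missing, collapse = ", "),
         call. = FALSE)
  rd <- function(file, classes) {
    utils::read.table(file.path(bundle_path, file), sep = "\t", header = TRUE,
                      colClasses = classes, stringsAsFactors = FALSE)
  }
  spikes <- rd("spikes.tsv", c("integer", "numeric"))
  position <- rd("position.tsv", c("numeric", "numeric", "numeric"))
  trials <- rd("trials.tsv", c("integer", rep("numeric", 3),
                               "character", "character", "integer"))
  sleep <- rd("sleep.tsv", c("character", "numeric", "numeric"))
  meta <- jsonlite::read_json(file.path(bundle_path, "session.json"),
                              simplifyVector = TRUE)
  session_recording(spikes, position, trials, sleep, as.list(meta))
}

#' Half-open phase intervals of a session
#'
#' Returns the per-trial time interval of one task phase. `trial` is
#' `[t_start, t_armend)`, `iti` is `[t_armend, t_iti_end)`; `inbound` and
#' `outbound` split the trial+ITI span at the detected outbound start
#' (heading reversal) instead of the arm end.
#'
#' @param session A `SessionRecording`.
#' @param phase One of `"trial"`, `"iti"`, `"inbound"`, `"outbound"`.
#' @param outbound_starts Optional vector of per-trial outbound start times
#'   (from [detect_outbound_starts()]); computed when needed if omitted.
#' @return data.frame with columns `trial`, `start`, `end`.
#' @export
phase_intervals <- function(session, phase = c("trial", "iti", "inbound", "outbound"),
                            outbound_starts = NULL) {
  phase <- match.arg(phase)
  tr <- session$trials
  if (phase %in% c("inbound", "outbound")) {
    if (is.null(outbound_starts))
      outbound_starts <- detect_outbound_starts(session)$t_outbound_s
    stopifnot(length(outbound_starts) == nrow(tr))
  }
  out <- switch(phase,
    trial = data.frame(trial = tr$trial, start = tr$t_start_s, end = tr$t_armend_s),
    iti = data.frame(trial = tr$trial, start = tr$t_armend_s, end = tr$t_iti_end_s),
    inbound = data.frame(trial = tr$trial, start = tr$t_start_s, end = outbound_starts),
    outbound = data.frame(trial = tr$trial, start = outbound_starts, end = tr$t_iti_end_s))
  out
}
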