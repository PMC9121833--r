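# Building population firing-rate vectors from a session: active-neuron
# selection, per-phase and per-maze-section rate vectors, maze
# linearization, and detection of the outbound (heading-reversal) phase.

#' Select the active neurons of a session
#'
#' A neuron is active if it fired at least one spike in every trial interval
#' `[t_start, t_armend)`. This criterion is applied to trial intervals only.
#'
#' @param session A `SessionRecording`.
#' @return Sorted integer vector of active neuron ids.
#' @export
select_active_neurons <- function(session) {
  tr <- session$trials
  ids <- sort(unique(session$spikes$neuron_id))
  active <- vapply(ids, function(id) {
    st <- session$spikes$spike_time_s[session$spikes$neuron_id == id]
    all(count_in_intervals(st, tr$t_start_s, tr$t_armend_s) >= 1)
  }, logical(1))
  if (!any(active)) stop("no active neurons", call. = FALSE)
  ids[active]
}

#' Per-trial population firing-rate vectors for one phase
#'
#' Rate = spike count in the phase interval / interval duration (Hz); one row
#' per trial, one column per active neuron.
#'
#' @param session A `SessionRecording`.
#' @param phase `"trial"`, `"iti"`, `"inbound"`, or `"outbound"`.
#' @param neurons Neuron ids to use; defaults to [select_active_neurons()].
#' @param outbound_starts Optional precomputed outbound start times.
#' @return A `RateVectorSet`: list with `rates` (T x N matrix), `phase`,
#'   `neuron_ids`, `trial`.
#' @export
phase_rate_vectors <- function(session, phase = c("trial", "iti", "inbound", "outbound"),
                               neurons = NULL, outbound_starts = NULL) {
  phase <- match.arg(phase)
  neurons <- neurons %||% select_active_neurons(session)
  iv <- phase_intervals(session, phase, outbound_starts)
  dur <- iv$end - iv$start
  if (any(dur <= 0)) stop("degenerate interval", call. = FALSE)
  rates <- sapply(neurons, function(id) {
    st <- session$spikes$spike_time_s[session$spikes$neuron_id == id]
    count_in_intervals(st, iv$start, iv$end) / dur
  })
  rates <- matrix(rates, nrow = nrow(iv),
                  dimnames = list(iv$trial, neurons))
  structure(list(rates = rates, phase = phase, neuron_ids = neurons,
                 trial = iv$trial, section = NULL),
            class = "RateVectorSet")
}

#' @export
print.RateVectorSet <- function(x, ...) {
  cat("RateVectorSet:", nrow(x$rates), "trials x", ncol(x$rates),
      "neurons, phase =", x$phase,
      if (!is.null(x$section)) paste0(", section ", x$section) else "", "\n")
  invisible(x)
}

#' Interleaved trial/ITI phase matrix
#'
#' Stacks the trial and ITI rate vectors in temporal order
#' trial(1), ITI(1), ..., trial(T), ITI(T): a 2T x N matrix.
#'
#' @param session A `SessionRecording`.
#' @param neurons Neuron ids (default: active neurons).
#' @param phases Pair of phases to interleave; the default trial/ITI split can
#'   be replaced by the inbound/outbound split.
#' @param outbound_starts Optional precomputed outbound start times.
#' @return A `PhaseMatrix`: list with `X` (2T x N), `phase` (row labels),
#'   `trial` (row trial index).
#' @export
build_phase_matrix <- function(session, neurons = NULL,
                               phases = c("trial", "iti"),
                               outbound_starts = NULL) {
  stopifnot(length(phases) == 2)
  neurons <- neurons %||% select_active_neurons(session)
  a <- phase_rate_vectors(session, phases[1], neurons, outbound_starts)
  b <- phase_rate_vectors(session, phases[2], neurons, outbound_starts)
  if (!identical(a$neuron_ids, b$neuron_ids))
    stop("internal error: mismatched active-neuron sets", call. = FALSE)
  Tt <- nrow(a$rates)
  X <- matrix(NA_real_, 2 * Tt, ncol(a$rates),
              dimnames = list(NULL, colnames(a$rates)))
  X[seq(1, 2 * Tt, 2), ] <- a$rates
  X[seq(2, 2 * Tt, 2), ] <- b$rates
  structure(list(X = X, phase = rep(phases, Tt),
                 trial = rep(a$trial, each = 2), neuron_ids = neurons),
            class = "PhaseMatrix")
}

#' Linearize the maze trajectory
#'
#' Projects each tracking sample onto the two-segment maze skeleton of its
#' trial (start-arm origin -> central platform -> chosen-arm end) and returns
#' the normalized arc-length coordinate (0 at the start-arm origin, 1 at the
#' chosen arm end) and the maze section, one of five equal fifths of the
#' path: sections 1..5 cover [0,0.2), ..., [0.8,1].
#'
#' Samples farther than `tol_cm` from the skeleton are flagged `excluded`.
#' Samples outside any trial or ITI interval get phase `NA`.
#'
#' @param session A `SessionRecording`.
#' @param tol_cm Distance tolerance from the skeleton (cm).
#' @return data.frame with columns `time_s`, `trial`, `phase`, `coord`,
#'   `section`, `dist_cm`, `excluded`.
#' @export
linearize_position <- function(session, tol_cm = 5) {
  po <- session$position
  tr <- session$trials
  L <- session$metadata$arm_length_cm %||% 85
  # assign each sample to a trial span [t_start, t_iti_end)
  idx <- findInterval(po$time_s, tr$t_start_s)
  in_span <- idx >= 1 & po$time_s < c(tr$t_iti_end_s, Inf)[pmax(idx, 1)]
  out <- data.frame(time_s = po$time_s, trial = NA_integer_,
                    phase = NA_character_, coord = NA_real_,
                    section = NA_integer_, dist_cm = NA_real_,
                    excluded = FALSE)
  proj_segment <- function(px, py, ax, ay, bx, by) {
    # project points onto segment a->b; returns t in [0,1] and distance
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- pmin(pmax(((px - ax) * vx + (py - ay) * vy) / len2, 0), 1)
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    list(t = t, d = sqrt(dx^2 + dy^2))
  }
  for (i in seq_len(nrow(tr))) {
    sel <- which(in_span & idx == i)
    if (!length(sel)) next
    px <- po$x_cm[sel]; py <- po$y_cm[sel]
    ang <- if (tr$direction[i] == "right") pi / 6 else 5 * pi / 6
    # segment 1: start origin (0,-L) -> center (0,0); segment 2: center -> arm end
    s1 <- proj_segment(px, py, 0, -L, 0, 0)
    s2 <- proj_segment(px, py, 0, 0, L * cos(ang), L * sin(ang))
    use2 <- s2$d < s1$d
    arc <- ifelse(use2, L + s2$t * L, s1$t * L)
    d <- pmin(s1$d, s2$d)
    coord <- arc / (2 * L)
    out$trial[sel] <- tr$trial[i]
    out$phase[sel] <- ifelse(po$time_s[sel] < tr$t_armend_s[i], "trial", "iti")
    out$coord[sel] <- coord
    out$section[sel] <- pmin(floor(coord / 0.2) + 1L, 5L)
    out$dist_cm[sel] <- d
    out$excluded[sel] <- d > tol_cm
  }
  out
}

#' Per-maze-section population rate vectors
#'
#' Rates are spike counts over the time the animal occupies section `p`
#' within the given phase of each trial, divided by that occupancy time.
#' Trials with zero occupancy of the section in that phase get `NA` rows
#' (flagged missing); downstream analyses drop them pairwise.
#'
#' @param session A `SessionRecording`.
#' @param phase `"trial"` (outbound traversal 1 -> 5) or `"iti"` (return 5 -> 1).
#' @param section Maze section 1..5.
#' @param neurons Neuron ids (default: active neurons).
#' @param linearized Optional precomputed [linearize_position()] table.
#' @return A `RateVectorSet` with attribute `occupancy_s` (per-trial seconds).
#' @export
section_rate_vectors <- function(session, phase = c("trial", "iti"), section,
                                 neurons = NULL, linearized = NULL) {
  phase <- match.arg(phase)
  stopifnot(section %in% 1:5)
  neurons <- neurons %||% select_active_neurons(session)
  lin <- linearized %||% linearize_position(session)
  tr <- session$trials
  # dwell interval of sample k is [t_k, t_{k+1}) clipped to the phase window
  npos <- nrow(lin)
  t_next <- c(lin$time_s[-1], lin$time_s[npos] + 1 / 30)
  sel <- !is.na(lin$phase) & lin$phase == phase & !lin$excluded &
    lin$section == section
  rates <- matrix(NA_real_, nrow(tr), length(neurons),
                  dimnames = list(tr$trial, neurons))
  occ <- numeric(nrow(tr))
  spk <- session$spikes
  spl <- split(spk$spike_time_s, spk$neuron_id)
  for (i in seq_len(nrow(tr))) {
    win <- if (phase == "trial") c(tr$t_start_s[i], tr$t_armend_s[i]) else
      c(tr$t_armend_s[i], tr$t_iti_end_s[i])
    k <- which(sel & lin$trial == tr$trial[i])
    if (!length(k)) next
    s0 <- pmax(lin$time_s[k], win[1])
    s1 <- pmin(t_next[k], win[2])
    ok <- s1 > s0
    s0 <- s0[ok]; s1 <- s1[ok]
    occ[i] <- sum(s1 - s0)
    if (occ[i] <= 0) next
    cnt <- vapply(neurons, function(id) {
      st <- spl[[as.character(id)]]
      if (is.null(st)) 0L else sum(count_in_intervals(st, s0, s1))
    }, integer(1))
    rates[i, ] <- cnt / occ[i]
  }
  if (all(is.na(rates[, 1]))) stop("empty section", call. = FALSE)
  structure(list(rates = rates, phase = phase, neuron_ids = neurons,
                 trial = tr$trial, section = section,
                 occupancy_s = occ),
            class = "RateVectorSet")
}

#' Detect per-trial outbound start times from heading direction
#'
#' Heading is estimated from centered finite differences of the 3-sample
#' moving-average-smoothed trajectory. The outbound start of trial i is the
#' first sample after the arm end beginning a run of at least 400 ms
#' (12 samples at 30 Hz) in which the heading points toward the start-arm
#' origin (angle between heading and the vector to the origin below 90
#' degrees). If no qualifying run exists the ITI end is returned and the
#' trial is flagged degenerate.
#'
#' @param session A `SessionRecording`.
#' @param min_run_s Minimum run duration toward the start (s).
#' @return data.frame with `trial`, `t_outbound_s`, `delay_s` (relative to
#'   the arm end), and `degenerate`.
#' @export
detect_outbound_starts <- function(session, min_run_s = 0.4) {
  po <- session$position
  tr <- session$trials
  L <- session$metadata$arm_length_cm %||% 85
  n <- nrow(po)
  sm <- function(v) {
    if (length(v) < 3) return(v)
    f <- stats::filter(v, rep(1 / 3, 3), sides = 2)
    f[1] <- v[1]; f[length(v)] <- v[length(v)]
    as.numeric(f)
  }
  xs <- sm(po$x_cm); ys <- sm(po$y_cm)
  hx <- c(NA, xs[3:n] - xs[1:(n - 2)], NA)
  hy <- c(NA, ys[3:n] - ys[1:(n - 2)], NA)
  # toward start: heading . (origin - pos) > 0, with nonzero displacement
  tox <- 0 - po$x_cm; toy <- -L - po$y_cm
  moving <- sqrt(hx^2 + hy^2) > 1e-9
  toward <- !is.na(hx) & moving & (hx * tox + hy * toy > 0)
  dt <- stats::median(diff(po$time_s))
  min_run <- max(1L, ceiling(min_run_s / dt))
  out <- data.frame(trial = tr$trial, t_outbound_s = tr$t_iti_end_s,
                    delay_s = tr$t_iti_end_s - tr$t_armend_s,
                    degenerate = TRUE)
  for (i in seq_len(nrow(tr))) {
    k <- which(po$time_s >= tr$t_armend_s[i] & po$time_s < tr$t_iti_end_s[i])
    if (length(k) < min_run) next
    tw <- toward[k]
    tw[is.na(tw)] <- FALSE
    r <- rle(tw)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hit <- which(r$values & r$lengths >= min_run)
    if (!length(hit)) next
    j0 <- starts[hit[1]]
    # The smoothed centered-difference heading responds one to two samples
    # away from the actual reversal; refine the run onset to the earliest
    # contiguous sample whose raw forward displacement points toward the
    # start (extending backward within the ITI, then advancing past any
    # leading zero-displacement dwell samples).
    j1 <- ends[hit[1]]
    raw_toward <- function(kk) {
      dx <- po$x_cm[min(kk + 1, n)] - po$x_cm[kk]
      dy <- po$y_cm[min(kk + 1, n)] - po$y_cm[kk]
      sqrt(dx^2 + dy^2) > 1e-9 && dx * tox[kk] + dy * toy[kk] > 0
    }
    while (j0 > 1 && raw_toward(k[j0 - 1])) j0 <- j0 - 1
    while (j0 < j1 && !raw_toward(k[j0])) j0 <- j0 + 1
    k0 <- k[j0]
    out$t_outbound_s[i] <- po$time_s[k0]
    out$delay_s[i] <- po$time_s[k0] - tr$t_armend_s[i]
    out$degenerate[i] <- FALSE
  }
  out
}

#' Trial vs ITI population-rate rank correlation per trial pair
#'
#' Spearman correlation between the trial rate vector r_t(i) and the ITI
#' rate vector r_I(i) of the same trial, with two-sided p values. Pairs with
#' a constant vector are reported as `NA`.
#'
#' @param session A `SessionRecording`.
#' @param neurons Neuron ids (default: active neurons; at least 3 needed).
#' @return data.frame with `trial`, `rho`, `p`.
#' @export
trial_iti_rate_correlation <- function(session, neurons = NULL) {
  neurons <- neurons %||% select_active_neurons(session)
  if (length(neurons) < 3) stop("need at least 3 neurons", call. = FALSE)
  a <- phase_rate_vectors(session, "trial", neurons)
  b <- phase_rate_vectors(session, "iti", neurons)
  res <- lapply(seq_len(nrow(a$rates)), function(i) {
    x <- a$rates[i, ]; y <- b$rates[i, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(c(rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  data.frame(trial = a$trial, do.call(rbind, res))
}
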