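# Synthetic sessions with implanted ground truth.
#
# The generator emulates the statistical structure the analyses assume:
# two linearly separable phase subspaces (a mean-rate offset between trial
# and ITI activity), binary task-feature coding along per-phase axes with a
# controllable trial<->ITI angle, past-trial coding in the ITI, Poisson
# spiking, a behavioral change point, a piecewise-linear maze trajectory,
# and sleep segments with controllable pre/post reactivation gains.

#' Configuration for the synthetic-session generator
#'
#' Defaults encode the study conditions the analyses target: trials of
#' 6.5 +/- 0.5 s, self-paced intertrial intervals of 55.6 s (5 s per-trial
#' spread), a mean heading-reversal delay of 1.14 s after the arm end,
#' pre/post success probabilities 0.4/0.85 around a learning change point,
#' an 85 cm three-arm maze, and 1 s-granularity sleep reactivation.
#'
#' @param N Neuron count.
#' @param T_trials Trial count.
#' @param baseline_log_mean,baseline_log_sd Per-neuron baseline log-rate is
#'   drawn from N(mean, sd); the baseline firing rate is its softplus (Hz).
#' @param phase_separation Shift `s` (Hz) between trial and ITI mean-rate
#'   vectors: +/- s/2 along a random unit direction.
#' @param feature_gain Named numeric, coding gain beta_f (Hz) per feature
#'   (`direction`, `light`, `outcome`).
#' @param implanted_angle Named numeric, angle alpha_f in `[0, pi]` between
#'   the trial and ITI coding axes of each feature.
#' @param trial_dur_mean,trial_dur_sd,iti_dur_mean,iti_dur_sd Phase duration
#'   distribution (s), truncated below at 1 s.
#' @param outbound_delay Dwell at the arm end before the return run starts (s).
#' @param learning_trial Change-point trial index, or `NULL` for none.
#' @param p_before,p_after Success probabilities before/after the change point.
#' @param lapse Probability that the chosen direction is flipped independently
#'   of the outcome (decouples direction from outcome labels).
#' @param rule_class `"direction"` or `"cue"`; `rule_name` labels the rule.
#' @param rule_name Rule label stored in metadata.
#' @param rule_change_trial Optional rule-switch trial stored in metadata.
#' @param sleep_epoch_s Duration of each sleep epoch (s).
#' @param rho_pre,rho_post Reactivation gains in `[0, 1]`: probability that a
#'   1 s sleep segment in that epoch is a noisy copy of a feature-specific
#'   trial mean vector rather than shuffled baseline activity.
#' @param reactivation_noise_sd SD of the multiplicative lognormal noise on
#'   reactivated vectors.
#' @param arm_length_cm Maze arm length (three arms at 120 degrees).
#' @param tracking_noise_cm SD of Gaussian jitter added to position samples.
#' @param rate_floor Lower bound (Hz) applied to all generative rates.
#' @return A list of class `SynthConfig`.
#' @export
synth_config <- function(N = 12, T_trials = 30,
                         baseline_log_mean = log(5), baseline_log_sd = 0.5,
                         phase_separation = 6,
                         feature_gain = c(direction = 1, light = 1, outcome = 1),
                         implanted_angle = c(direction = pi / 2, light = pi / 2,
                                             outcome = pi / 2),
                         trial_dur_mean = 6.5, trial_dur_sd = 0.5,
                         iti_dur_mean = 55.6, iti_dur_sd = 5,
                         outbound_delay = 1.14,
                         learning_trial = NULL, p_before = 0.4, p_after = 0.85,
                         lapse = 0.05,
                         rule_class = c("cue", "direction"),
                         rule_name = NULL, rule_change_trial = NULL,
                         sleep_epoch_s = 1200, rho_pre = 0.1, rho_post = 0.4,
                         reactivation_noise_sd = 0.3,
                         arm_length_cm = 85, tracking_noise_cm = 0,
                         rate_floor = 0.1) {
  rule_class <- match.arg(rule_class)
  rule_name <- rule_name %||%
    if (rule_class == "cue") "go to the lit arm" else "go to the right arm"
  feats <- c("direction", "light", "outcome")
  named_by_feat <- function(v) {
    out <- rep_len(unname(v), 3)
    names(out) <- feats
    if (!is.null(names(v)) && all(feats %in% names(v))) out[feats] <- v[feats]
    out
  }
  fg <- named_by_feat(feature_gain)
  ia <- named_by_feat(implanted_angle)
  cfg <- list(N = N, T_trials = T_trials,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              phase_separation = phase_separation,
              feature_gain = fg[feats], implanted_angle = ia[feats],
              trial_dur_mean = trial_dur_mean, trial_dur_sd = trial_dur_sd,
              iti_dur_mean = iti_dur_mean, iti_dur_sd = iti_dur_sd,
              outbound_delay = outbound_delay,
              learning_trial = learning_trial,
              p_before = p_before, p_after = p_after, lapse = lapse,
              rule_class = rule_class, rule_name = rule_name,
              rule_change_trial = rule_change_trial,
              sleep_epoch_s = sleep_epoch_s,
              rho_pre = rho_pre, rho_post = rho_post,
              reactivation_noise_sd = reactivation_noise_sd,
              arm_length_cm = arm_length_cm,
              tracking_noise_cm = tracking_noise_cm,
              rate_floor = rate_floor)
  stopifnot(N >= 1, T_trials >= 1,
            phase_separation >= 0, all(cfg$feature_gain >= 0),
            all(cfg$implanted_angle >= 0), all(cfg$implanted_angle <= pi),
            p_before >= 0, p_before <= 1, p_after >= 0, p_after <= 1,
            lapse >= 0, lapse <= 1,
            rho_pre >= 0, rho_pre <= 1, rho_post >= 0, rho_post <= 1)
  structure(cfg, class = "SynthConfig")
}

feature_sign <- function(labels, feature) {
  pos <- switch(feature, direction = "right", light = "right", outcome = 1)
  ifelse(labels == pos, 1, -1)
}

#' Point on the two-segment maze skeleton at a given arc length
#'
#' The skeleton runs from the start-arm origin (arc 0), up the start arm to
#' the central platform (arc = arm length), then along the chosen arm to its
#' end (arc = 2 * arm length). Arms are separated by 120 degrees.
#' @noRd
skeleton_point <- function(arc, direction, arm_length) {
  ang <- ifelse(direction == "right", pi / 6, 5 * pi / 6)  # 30 / 150 deg
  arm_end_x <- arm_length * cos(ang)
  arm_end_y <- arm_length * sin(ang)
  on_start <- arc <= arm_length
  frac2 <- pmax(arc - arm_length, 0) / arm_length
  x <- ifelse(on_start, 0, frac2 * arm_end_x)
  y <- ifelse(on_start, arc - arm_length, frac2 * arm_end_y)
  cbind(x_cm = x, y_cm = y)
}

poisson_spike_block <- function(neuron_ids, rates, starts, ends) {
  # rates: matrix rows = intervals, cols = neurons. Returns data.frame of spikes.
  durs <- ends - starts
  lam <- sweep(rates, 1, durs, `*`)
  counts <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam))
  total <- sum(counts)
  if (total == 0)
    return(data.frame(neuron_id = integer(0), spike_time_s = numeric(0)))
  iv <- rep(rep(seq_len(nrow(counts)), ncol(counts)), as.vector(counts))
  nid <- rep(rep(neuron_ids, each = nrow(counts)), as.vector(counts))
  tt <- starts[iv] + stats::runif(total) * durs[iv]
  data.frame(neuron_id = nid, spike_time_s = tt)
}

#' Generate one synthetic session with ground truth
#'
#' The generative model: (1) trial outcomes are Bernoulli(`p_before`) before
#' the learning trial and Bernoulli(`p_after`) from it on; the lit arm is
#' pseudorandom; the chosen direction is the outcome-consistent arm under the
#' session rule, flipped with probability `lapse`. (2) The mean rate vector
#' of each phase of trial i is softplus(baseline) +/- s/2 along a random
#' phase-offset direction, plus `sum_f beta_f x_f c_f^phase`, where `x_f` is
#' the +/-1 coding of trial i's labels — for the ITI this is the label of the
#' trial the ITI follows (past-trial coding). Rates are floored. (3) Spikes
#' are homogeneous Poisson within each phase. (4) Position runs out and back
#' along the maze skeleton at uniform speed, dwelling at the arm end for
#' `outbound_delay` before the return. (5) Each sleep epoch is tiled with 1 s
#' segments; with probability `rho_epoch` a segment's rate vector is a noisy
#' (multiplicative lognormal) copy of a randomly chosen feature-specific
#' trial mean vector, otherwise a random permutation of the baseline vector.
#'
#' Identical `(config, seed)` yield identical sessions.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return A list with elements `session` (a `SessionRecording`) and
#'   `ground_truth` (implanted parameters: phase-offset direction, per-feature
#'   coding axes per phase, generative per-trial mean-rate matrices,
#'   feature-specific trial mean vectors, learning trial, reactivation gains).
#' @export
generate_session <- function(config, seed) {
  stopifnot(inherits(config, "SynthConfig"))
  with_seed(seed, {
    N <- config$N; Tt <- config$T_trials
    feats <- c("direction", "light", "outcome")
    if (N < 2 && any(config$implanted_angle > 0 & config$feature_gain > 0))
      stop("cannot embed two axes", call. = FALSE)

    base_rate <- softplus(stats::rnorm(N, config$baseline_log_mean,
                                       config$baseline_log_sd))
    u <- runit(N)
    axes <- lapply(feats, function(f) {
      ct <- runit(N)
      ci <- unit_at_angle(ct, config$implanted_angle[[f]])
      list(trial = ct, iti = ci)
    })
    names(axes) <- feats

    # --- behavior ---------------------------------------------------------
    lt <- config$learning_trial
    p <- rep(config$p_before, Tt)
    if (!is.null(lt)) p[seq_len(Tt) >= lt] <- config$p_after
    outcome <- stats::rbinom(Tt, 1, p)
    light <- sample(c("left", "right"), Tt, replace = TRUE)
    correct_arm <- if (config$rule_class == "cue") light else {
      rep(if (grepl("left", config$rule_name)) "left" else "right", Tt)
    }
    other <- function(a) ifelse(a == "left", "right", "left")
    direction <- ifelse(outcome == 1, correct_arm, other(correct_arm))
    flip <- stats::runif(Tt) < config$lapse
    direction[flip] <- other(direction[flip])

    # --- event times ------------------------------------------------------
    dur_t <- pmax(stats::rnorm(Tt, config$trial_dur_mean, config$trial_dur_sd), 1)
    dur_i <- pmax(stats::rnorm(Tt, config$iti_dur_mean, config$iti_dur_sd),
                  config$outbound_delay + 2)
    t0 <- config$sleep_epoch_s + 60
    t_start <- t0 + c(0, cumsum(dur_t + dur_i))[seq_len(Tt)]
    t_armend <- t_start + dur_t
    t_iti_end <- t_armend + dur_i
    t_start <- round_time(t_start); t_armend <- round_time(t_armend)
    t_iti_end <- round_time(t_iti_end)

    # --- per-trial, per-phase mean rates ---------------------------------
    label_sign <- sapply(feats, function(f)
      feature_sign(switch(f, direction = direction, light = light,
                          outcome = outcome), f))  # Tt x 3
    mean_rates <- function(phase) {
      off <- if (phase == "trial") config$phase_separation / 2 else
        -config$phase_separation / 2
      m <- matrix(rep(base_rate + off * u, each = Tt), nrow = Tt)
      for (f in feats)
        m <- m + config$feature_gain[[f]] * outer(label_sign[, f], axes[[f]][[phase]])
      pmax(m, config$rate_floor)
    }
    trial_means <- mean_rates("trial")
    iti_means <- mean_rates("iti")

    spikes <- rbind(
      poisson_spike_block(seq_len(N), trial_means, t_start, t_armend),
      poisson_spike_block(seq_len(N), iti_means, t_armend, t_iti_end))

    # --- feature-specific trial mean vectors (generative) ----------------
    feature_means <- list()
    for (f in feats) {
      for (s in c(-1, 1)) {
        rows <- label_sign[, f] == s
        if (any(rows)) {
          val <- switch(f, outcome = if (s > 0) "1" else "0",
                        if (s > 0) "right" else "left")
          feature_means[[paste(f, val, sep = "_")]] <-
            colMeans(trial_means[rows, , drop = FALSE])
        }
      }
    }

    # --- position ---------------------------------------------------------
    L <- config$arm_length_cm
    pos_list <- vector("list", Tt)
    for (i in seq_len(Tt)) {
      tt <- seq(t_start[i], t_iti_end[i] - 1e-9, by = 1 / 30)
      turn <- t_armend[i] + config$outbound_delay
      arc <- ifelse(tt < t_armend[i],
                    2 * L * (tt - t_start[i]) / (t_armend[i] - t_start[i]),
             ifelse(tt < turn, 2 * L,
                    2 * L * (1 - (tt - turn) / (t_iti_end[i] - turn))))
      arc <- pmin(pmax(arc, 0), 2 * L)
      xy <- skeleton_point(arc, direction[i], L)
      pos_list[[i]] <- data.frame(time_s = tt, x_cm = xy[, 1], y_cm = xy[, 2])
    }
    position <- do.call(rbind, pos_list)
    if (config$tracking_noise_cm > 0) {
      position$x_cm <- position$x_cm + stats::rnorm(nrow(position), 0,
                                                    config$tracking_noise_cm)
      position$y_cm <- position$y_cm + stats::rnorm(nrow(position), 0,
                                                    config$tracking_noise_cm)
    }
    position$time_s <- round_time(position$time_s)
    position$x_cm <- round(position$x_cm, 4)
    position$y_cm <- round(position$y_cm, 4)
    keep <- c(TRUE, diff(position$time_s) > 0)
    position <- position[keep, ]

    # --- sleep ------------------------------------------------------------
    post0 <- max(t_iti_end) + 60
    sleep <- data.frame(
      epoch = rep(c("pre", "post"), each = 2),
      t_start_s = c(0, 0.55 * config$sleep_epoch_s,
                    post0, post0 + 0.55 * config$sleep_epoch_s),
      t_end_s = c(0.45 * config$sleep_epoch_s, config$sleep_epoch_s,
                  post0 + 0.45 * config$sleep_epoch_s,
                  post0 + config$sleep_epoch_s))
    fm <- do.call(rbind, feature_means)
    sleep_spikes <- list()
    for (k in seq_len(nrow(sleep))) {
      rho <- if (sleep$epoch[k] == "pre") config$rho_pre else config$rho_post
      starts <- seq(sleep$t_start_s[k], sleep$t_end_s[k] - 1, by = 1)
      B <- length(starts)
      if (B == 0) next
      react <- stats::runif(B) < rho
      rates <- matrix(0, B, N)
      for (b in seq_len(B)) {
        rates[b, ] <- if (react[b]) {
          fm[sample.int(nrow(fm), 1), ] *
            exp(stats::rnorm(N, 0, config$reactivation_noise_sd))
        } else base_rate[sample.int(N)]
      }
      rates <- pmax(rates, config$rate_floor)
      sleep_spikes[[k]] <- poisson_spike_block(seq_len(N), rates,
                                               starts, starts + 1)
    }
    spikes <- rbind(spikes, do.call(rbind, sleep_spikes))
    spikes$spike_time_s <- round_time(spikes$spike_time_s)
    spikes <- spikes[order(spikes$neuron_id, spikes$spike_time_s), ]
    rownames(spikes) <- NULL

    trials <- data.frame(trial = seq_len(Tt), t_start_s = t_start,
                         t_armend_s = t_armend, t_iti_end_s = t_iti_end,
                         direction = direction, light = light,
                         outcome = outcome)
    metadata <- list(rat_id = "synthetic", rule_name = config$rule_name,
                     rule_class = config$rule_class,
                     rule_change_trial = config$rule_change_trial,
                     arm_length_cm = L, synthetic = TRUE, seed = seed)
    session <- session_recording(spikes, position, trials,
                                 sleep_df_times(sleep), metadata)
    gt <- structure(list(phase_direction = u, axes = axes,
                         base_rate = base_rate,
                         trial_means = trial_means, iti_means = iti_means,
                         feature_means = feature_means,
                         learning_trial = lt,
                         rho_pre = config$rho_pre, rho_post = config$rho_post,
                         seed = seed),
                    class = "GroundTruth")
    list(session = session, ground_truth = gt)
  })
}

sleep_df_times <- function(sl) {
  sl$t_start_s <- round_time(sl$t_start_s)
  sl$t_end_s <- round_time(sl$t_end_s)
  sl
}

#' Generate a cohort of independent synthetic sessions
#'
#' Per-session seeds are derived deterministically from the master seed, so
#' the same `(configs, n_sessions, seed)` always yields the same cohort.
#' `configs` may be a single [synth_config()] (recycled) or a list of
#' configs of length `n_sessions` (mixed cohorts, e.g. learning plus
#' non-learning sessions).
#'
#' @param configs A `SynthConfig` or list of them.
#' @param n_sessions Number of sessions (>= 1).
#' @param seed Master integer seed.
#' @return List of length `n_sessions`; each element as [generate_session()].
#' @export
generate_cohort <- function(configs, n_sessions, seed) {
  stopifnot(n_sessions >= 1)
  if (inherits(configs, "SynthConfig"))
    configs <- rep(list(configs), n_sessions)
  stopifnot(length(configs) == n_sessions)
  seeds <- derive_seeds(seed, n_sessions)
  lapply(seq_len(n_sessions), function(i)
    generate_session(configs[[i]], seeds[i]))
}
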