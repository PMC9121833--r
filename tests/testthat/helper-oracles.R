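# Independent brute-force oracles and small fixture builders, used to check
# the package implementations against a second route.

# Spearman correlation: rank (average ranks on ties) then Pearson by the sum
# formulas, no calls into the package or cor(method = "spearman").
spearman_brute <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Ridge-penalized logistic loss minimized with optim(BFGS) + analytic
# gradient: an optimizer independent of the package's Newton solver.
ridge_logistic_brute <- function(X, y01, C = 1) {
  Xb <- cbind(1, X)
  pen <- c(0, rep(1 / C, ncol(Xb) - 1))
  fn <- function(b) {
    eta <- drop(Xb %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y01 * eta) + sum(pen * b^2) / 2
  }
  gr <- function(b) {
    mu <- 1 / (1 + exp(-drop(Xb %*% b)))
    drop(crossprod(Xb, mu - y01)) + pen * b
  }
  o <- stats::optim(numeric(ncol(Xb)), fn, gr, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-14))
  list(intercept = o$par[1], w = o$par[-1])
}

# Leave-one-out decode by brute-force refit (standardization replicated).
loo_brute <- function(X, labels, C = 1) {
  lv <- sort(unique(labels))
  y <- as.numeric(labels == lv[2])
  pred <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    Xtr <- X[-i, , drop = FALSE]
    mu <- colMeans(Xtr)
    sd <- apply(Xtr, 2, stats::sd); sd[sd == 0] <- 1
    sc <- function(M) sweep(sweep(M, 2, mu), 2, sd, `/`)
    fit <- ridge_logistic_brute(sc(Xtr), y[-i], C)
    eta <- fit$intercept + drop(sc(X[i, , drop = FALSE]) %*% fit$w)
    pred[i] <- if (eta >= 0) lv[2] else lv[1]
  }
  pred
}

# Top-d principal axes by explicit eigendecomposition of the centered
# covariance (eigen(), not svd), with the same sign convention.
pca_brute <- function(X, d) {
  Xc <- sweep(X, 2, colMeans(X))
  eg <- eigen(crossprod(Xc), symmetric = TRUE)
  axes <- eg$vectors[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    k <- which.max(abs(axes[, j]))
    if (axes[k, j] < 0) axes[, j] <- -axes[, j]
  }
  list(axes = axes, projected = Xc %*% axes, eigenvalues = eg$values)
}

# Optimal 1-D two-class threshold error by exhaustive scan (both polarities).
threshold_scan_error <- function(z, labels) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  cuts <- c(sort(unique(z)) - 1e-9, max(z) + 1)
  best <- 1
  for (cc in cuts) for (pol in c(TRUE, FALSE)) {
    pred <- if (pol) ifelse(z > cc, lv[2], lv[1]) else ifelse(z > cc, lv[1], lv[2])
    best <- min(best, mean(pred != labels))
  }
  best
}

# Optimal linear separator in 2-D by grid search over angle and offset.
gridsearch_2d_error <- function(Z, labels) {
  best <- 1
  for (th in seq(0, pi, length.out = 181)) {
    z <- Z[, 1] * cos(th) + Z[, 2] * sin(th)
    best <- min(best, threshold_scan_error(z, labels))
  }
  best
}

# Minimal hand-built session: `rates` is an N x T matrix of trial-phase
# rates realized as evenly spaced spikes (deterministic, exact counts).
make_toy_session <- function(counts_trial, counts_iti = NULL,
                             trial_dur = 2, iti_dur = 4, with_sleep = FALSE) {
  N <- nrow(counts_trial); Tt <- ncol(counts_trial)
  if (is.null(counts_iti)) counts_iti <- counts_trial
  t_start <- 100 + (0:(Tt - 1)) * (trial_dur + iti_dur)
  t_armend <- t_start + trial_dur
  t_iti_end <- t_armend + iti_dur
  spk <- list()
  even_spikes <- function(n, a, b) if (n > 0) a + (b - a) * (seq_len(n) - 0.5) / n else numeric(0)
  for (i in seq_len(Tt)) for (n in seq_len(N)) {
    tt <- c(even_spikes(counts_trial[n, i], t_start[i], t_armend[i]),
            even_spikes(counts_iti[n, i], t_armend[i], t_iti_end[i]))
    spk[[length(spk) + 1]] <- data.frame(neuron_id = rep(n, length(tt)),
                                         spike_time_s = tt)
  }
  spikes <- do.call(rbind, spk)
  spikes$spike_time_s <- round(spikes$spike_time_s, 4)  # recording grid
  spikes <- spikes[order(spikes$neuron_id, spikes$spike_time_s), ]
  rownames(spikes) <- NULL
  tt <- round(seq(t_start[1], t_iti_end[Tt], by = 1 / 30), 4)
  position <- data.frame(time_s = tt, x_cm = 0, y_cm = -85)
  trials <- data.frame(trial = seq_len(Tt), t_start_s = t_start,
                       t_armend_s = t_armend, t_iti_end_s = t_iti_end,
                       direction = rep(c("left", "right"), length.out = Tt),
                       light = rep(c("right", "left"), length.out = Tt),
                       outcome = rep(c(1, 0), length.out = Tt))
  sleep <- if (with_sleep) data.frame(
    epoch = c("pre", "post"), t_start_s = c(0, t_iti_end[Tt] + 10),
    t_end_s = c(90, t_iti_end[Tt] + 100))
  else data.frame(epoch = character(0), t_start_s = numeric(0),
                  t_end_s = numeric(0))
  session_recording(spikes, position, trials, sleep,
                    list(rat_id = "toy", rule_name = "go to the lit arm",
                         rule_class = "cue", arm_length_cm = 85))
}

# Random valid session generator for round-trip property tests (times on the
# 0.1 ms grid by construction).
random_valid_session <- function(seed) {
  set.seed(seed)
  N <- sample(2:5, 1); Tt <- sample(2:5, 1)
  counts_t <- matrix(sample(1:6, N * Tt, replace = TRUE), N, Tt)
  counts_i <- matrix(sample(0:6, N * Tt, replace = TRUE), N, Tt)
  make_toy_session(counts_t, counts_i, with_sleep = TRUE)
}

recovery_config <- function(alpha, T_trials = 40) {
  # High-SNR coding regime used for implanted-axis recovery checks.
  synth_config(T_trials = T_trials, sleep_epoch_s = 120,
               baseline_log_mean = 5, baseline_log_sd = 0.3,
               phase_separation = 4, feature_gain = rep(3, 3),
               implanted_angle = rep(alpha, 3))
}
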