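test_that("active-neuron selection requires a spike on every trial", {
  counts <- matrix(2, 3, 4)
  counts[2, 3] <- 0  # neuron 2 silent in exactly one trial
  s <- make_toy_session(counts)
  expect_equal(select_active_neurons(s), c(1L, 3L))
  s_all <- make_toy_session(matrix(1, 3, 4))
  expect_equal(select_active_neurons(s_all), 1:3)
  # selection is idempotent / order-independent by construction
  expect_equal(select_active_neurons(s), select_active_neurons(s))
  s_none <- make_toy_session(matrix(1, 2, 3))
  s_none$spikes <- s_none$spikes[s_none$spikes$spike_time_s >
                                   s_none$trials$t_armend_s[1], ]
  expect_error(select_active_neurons(s_none), "no active neurons")
})

test_that("phase rates are count over duration", {
  counts <- matrix(0, 2, 2)
  counts[1, 1] <- 3
  s <- make_toy_session(counts, counts_iti = matrix(0, 2, 2),
                        trial_dur = 1.5, iti_dur = 3)
  rv <- phase_rate_vectors(s, "trial", neurons = 1:2)
  expect_equal(rv$rates[1, "1"], 3 / 1.5)  # 3 spikes in 1.5 s -> 2 Hz
  expect_equal(rv$rates[1, "2"], 0)        # empty interval -> 0 Hz
  expect_equal(rv$rates[2, ], c("1" = 0, "2" = 0))
  ri <- phase_rate_vectors(s, "iti", neurons = 1:2)
  expect_true(all(ri$rates == 0))
})

test_that("Poisson neuron mean rate is recovered within 3 SE", {
  set.seed(99)
  Tt <- 200; dur <- 2; rate <- 5
  counts <- matrix(rpois(Tt, rate * dur), 1, Tt)
  counts <- rbind(counts, 1)  # companion neuron keeps the session valid
  s <- make_toy_session(counts, counts_iti = matrix(1, 2, Tt),
                        trial_dur = dur, iti_dur = 1)
  rv <- phase_rate_vectors(s, "trial", neurons = 1:2)
  se <- sqrt(rate / dur / Tt)
  expect_lt(abs(mean(rv$rates[, "1"]) - rate), 3 * se)
})

test_that("phase matrix interleaves trials and ITIs in temporal order", {
  counts_t <- matrix(seq_len(6) * 2, 2, 3)       # distinct per trial
  counts_i <- matrix(seq_len(6) * 2 + 1, 2, 3)
  s <- make_toy_session(counts_t, counts_i, trial_dur = 1, iti_dur = 1)
  pm <- build_phase_matrix(s, neurons = 1:2)
  expect_equal(nrow(pm$X), 6)
  expect_equal(pm$phase, rep(c("trial", "iti"), 3))
  tv <- phase_rate_vectors(s, "trial", neurons = 1:2)
  iv <- phase_rate_vectors(s, "iti", neurons = 1:2)
  for (k in 1:3) {
    expect_equal(pm$X[2 * k - 1, ], tv$rates[k, ])
    expect_equal(pm$X[2 * k, ], iv$rates[k, ])
  }
  expect_equal(ncol(pm$X), 2)
})

test_that("maze linearization maps skeleton landmarks to coordinates", {
  cfg <- synth_config(N = 4, T_trials = 3, sleep_epoch_s = 30)
  s <- generate_session(cfg, 13)$session
  lin <- linearize_position(s)
  keep <- !is.na(lin$coord)
  expect_true(all(lin$coord[keep] >= 0 & lin$coord[keep] <= 1))
  # noiseless trajectory lies on the skeleton up to 0.1 mm coordinate rounding
  expect_true(all(lin$dist_cm[keep] < 0.01))
  # start-arm origin, central platform, arm end
  i_origin <- which(keep & abs(lin$time_s - s$trials$t_start_s[1]) < 1 / 60)[1]
  expect_equal(lin$coord[i_origin], 0, tolerance = 0.02)
  expect_equal(lin$section[i_origin], 1)
  at_end <- which(keep & lin$phase == "trial" &
                    abs(lin$coord - max(lin$coord[keep & lin$phase == "trial"])) < 1e-9)[1]
  expect_gt(lin$coord[at_end], 0.98)
  expect_equal(lin$section[at_end], 5)
  mid <- which(keep & abs(lin$coord - 0.5) < 0.01)[1]
  expect_equal(lin$section[mid], 3)
  # samples far off the maze are flagged
  s2 <- s
  s2$position$x_cm[100] <- 500
  lin2 <- linearize_position(s2)
  expect_true(lin2$excluded[100])
})

test_that("section occupancy conserves traversal time for uniform speed", {
  cfg <- synth_config(N = 4, T_trials = 4, sleep_epoch_s = 30)
  s <- generate_session(cfg, 17)$session
  lin <- linearize_position(s)
  neurons <- select_active_neurons(s)
  occ <- sapply(1:5, function(p)
    section_rate_vectors(s, "trial", p, neurons, lin)$occupancy_s)
  durs <- s$trials$t_armend_s - s$trials$t_start_s
  # each section takes ~1/5 of a uniform-speed traversal
  expect_true(all(abs(occ / durs - 0.2) < 0.05))
  # summed occupancy equals the phase duration up to sampling discreteness
  expect_true(all(abs(rowSums(occ) - durs) < 0.2))
})

test_that("section rates isolate section-specific spiking", {
  cfg <- synth_config(N = 3, T_trials = 3, sleep_epoch_s = 30)
  s <- generate_session(cfg, 19)$session
  lin <- linearize_position(s)
  # rebuild neuron 1's spikes to fire only while the rat is in section 5 (trial)
  sel <- !is.na(lin$phase) & lin$phase == "trial" & lin$section == 5
  new_spk <- data.frame(neuron_id = 1, spike_time_s = lin$time_s[sel] + 1e-3)
  others <- s$spikes[s$spikes$neuron_id != 1, ]
  s$spikes <- rbind(others, new_spk)
  s$spikes <- s$spikes[order(s$spikes$neuron_id, s$spikes$spike_time_s), ]
  rates <- sapply(1:5, function(p)
    mean(section_rate_vectors(s, "trial", p, 1:3, lin)$rates[, "1"], na.rm = TRUE))
  expect_true(all(rates[1:3] < 1e-9))
  expect_gt(rates[5], 1)
})

test_that("outbound start detection matches the implanted reversal delay", {
  cfg <- synth_config(N = 4, T_trials = 10, sleep_epoch_s = 30,
                      outbound_delay = 1.14)
  s <- generate_session(cfg, 23)$session
  ob <- detect_outbound_starts(s)
  expect_false(any(ob$degenerate))
  expect_true(all(abs(ob$delay_s - 1.14) <= 1 / 30 + 1e-9))
  # immediate reversal: delay at most one sample
  cfg0 <- synth_config(N = 4, T_trials = 6, sleep_epoch_s = 30,
                       outbound_delay = 0)
  ob0 <- detect_outbound_starts(generate_session(cfg0, 29)$session)
  expect_true(all(ob0$delay_s <= 1 / 30 + 1e-9))
  # a trajectory that never turns back is flagged degenerate
  counts <- matrix(2, 2, 3)
  toy <- make_toy_session(counts)  # rat parked at the start-arm origin
  obd <- detect_outbound_starts(toy)
  expect_true(all(obd$degenerate))
  expect_equal(obd$t_outbound_s, toy$trials$t_iti_end_s)
})

test_that("trial-ITI rank correlation matches the brute-force oracle", {
  # vectors (1,2,2,4) vs (2,1,3,4): tied ranks exercised
  counts_t <- matrix(c(1, 2, 2, 4), 4, 4)
  counts_i <- matrix(c(2, 1, 3, 4), 4, 4)
  s <- make_toy_session(counts_t, counts_i, trial_dur = 1, iti_dur = 1)
  res <- trial_iti_rate_correlation(s, neurons = 1:4)
  expect_equal(res$rho[1], spearman_brute(c(1, 2, 2, 4), c(2, 1, 3, 4)),
               tolerance = 1e-12)
  # identical vectors -> rho = 1; reversed ranks -> rho = -1
  s2 <- make_toy_session(matrix(1:4, 4, 4), matrix(1:4, 4, 4),
                         trial_dur = 1, iti_dur = 1)
  expect_equal(trial_iti_rate_correlation(s2, neurons = 1:4)$rho,
               rep(1, 4))
  s3 <- make_toy_session(matrix(1:4, 4, 4), matrix(4:1, 4, 4),
                         trial_dur = 1, iti_dur = 1)
  expect_equal(trial_iti_rate_correlation(s3, neurons = 1:4)$rho,
               rep(-1, 4))
  # constant vector -> missing
  s4 <- make_toy_session(matrix(2, 3, 2), matrix(c(1, 2, 3), 3, 2),
                         trial_dur = 1, iti_dur = 1)
  expect_true(all(is.na(trial_iti_rate_correlation(s4, neurons = 1:3)$rho)))
})

test_that("inbound/outbound with zero delay reduces toward the trial/ITI split", {
  cfg <- synth_config(N = 6, T_trials = 10, sleep_epoch_s = 30,
                      outbound_delay = 0, phase_separation = 10)
  s <- generate_session(cfg, 31)$session
  res <- inbound_outbound_separability(s, dims = 1:2)
  # boundaries differ by at most one tracking sample, so errors agree closely
  expect_true(all(abs(res$comparison$difference) <= 0.05))
})
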