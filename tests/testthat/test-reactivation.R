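test_that("feature mean vectors are label-conditional means", {
  X <- rbind(c(1, 1), c(3, 3), c(10, 0))
  labels <- c("left", "left", "right")
  expect_equal(feature_mean_vector(X, labels, "left"), c(2, 2),
               ignore_attr = TRUE)
  expect_equal(feature_mean_vector(X, labels, "right"), c(10, 0),
               ignore_attr = TRUE)
  # count-weighted mean of the two feature vectors is the grand mean
  grand <- (2 * feature_mean_vector(X, labels, "left") +
              1 * feature_mean_vector(X, labels, "right")) / 3
  expect_equal(grand, colMeans(X), ignore_attr = TRUE)
  expect_error(feature_mean_vector(X, labels, "up"), "no rows")
})

test_that("sleep bins tile intervals and drop trailing partial bins", {
  s <- make_toy_session(matrix(2, 3, 3), with_sleep = TRUE)
  # pre epoch is [0, 90): 90 one-second bins
  s$spikes <- rbind(data.frame(neuron_id = rep(1:3, each = 5),
                               spike_time_s = rep(seq(0.5, 85, by = 20), 3)),
                    s$spikes)
  s$spikes <- s$spikes[order(s$spikes$neuron_id, s$spikes$spike_time_s), ]
  sv <- sleep_bin_vectors(s, "pre", bin_s = 1, neurons = 1:3)
  expect_equal(nrow(sv$rates), 90)
  # bin of 2.5 s interval keeps floor(90 / 35) = 2 bins per 35 s etc.
  sv2 <- sleep_bin_vectors(s, "pre", bin_s = 35, neurons = 1:3)
  expect_equal(nrow(sv2$rates), floor(90 / 35))
  # conservation: bins per epoch = sum over intervals of floor(len / bin)
  cfg <- synth_config(N = 4, T_trials = 3, sleep_epoch_s = 100)
  sg <- generate_session(cfg, 3)$session
  for (b in c(0.7, 1, 3.2)) {
    sv3 <- sleep_bin_vectors(sg, "post", b, neurons = 1:4)
    sl <- sg$sleep[sg$sleep$epoch == "post", ]
    expect_equal(nrow(sv3$rates),
                 sum(floor((sl$t_end_s - sl$t_start_s) / b)))
  }
  expect_error(sleep_bin_vectors(sg, "pre", 1e6), "no usable bins")
  # the sweep grid spans 0.1 to 10 s in 67 steps
  expect_length(seq(0.1, 10, by = 0.15), 67)
})

test_that("rank correlation with sleep bins matches the brute-force oracle", {
  set.seed(20)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    v <- sample(1:4, n, replace = TRUE) + 0.5 * rbinom(n, 1, 0.5)  # ties likely
    M <- matrix(sample(1:5, 3 * n, replace = TRUE), 3, n)
    got <- popsubspace:::spearman_with(v, M)
    want <- apply(M, 1, function(row)
      if (sd(rank(row)) == 0) NA_real_ else spearman_brute(v, row))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("reactivation statistic is the median difference and is rank-invariant", {
  cfg <- synth_config(N = 8, T_trials = 10, sleep_epoch_s = 200,
                      rho_pre = 0.1, rho_post = 0.5)
  s <- generate_session(cfg, 51)$session
  neurons <- select_active_neurons(s)
  tv <- phase_rate_vectors(s, "trial", neurons)
  fv <- feature_mean_vector(tv, as.character(s$trials$direction), "right")
  r <- reactivation_distributions(fv, s, bin_s = 1, neurons = neurons)
  expect_equal(r$statistic, median(r$post) - median(r$pre))
  expect_true(all(abs(c(r$pre, r$post)) <= 1))
  expect_true(abs(r$statistic) <= 2)
  # invariant under a monotone transform of the feature vector
  r2 <- reactivation_distributions(exp(fv / max(fv)), s, bin_s = 1,
                                   neurons = neurons)
  expect_equal(r2$statistic, r$statistic)
  expect_equal(r2$pre, r$pre)
  # constant feature vector is an error
  expect_error(reactivation_distributions(rep(1, length(neurons)), s,
                                          neurons = neurons),
               "constant feature vector")
})

test_that("implanted post-training reactivation yields positive statistics", {
  stats <- sapply(1:8, function(sd) {
    cfg <- synth_config(N = 10, T_trials = 12, sleep_epoch_s = 600,
                        rho_pre = 0.1, rho_post = 0.4)
    s <- generate_session(cfg, sd)$session
    median(reactivation_analysis(s, "trial")$statistic)
  })
  expect_true(all(stats > 0))
})

test_that("paired-feature controls are antisymmetric and zero at identity", {
  cfg <- synth_config(N = 8, T_trials = 12, sleep_epoch_s = 200)
  s <- generate_session(cfg, 53)$session
  neurons <- select_active_neurons(s)
  d_pre <- paired_feature_control(s, "direction", "pre", "trial")
  # recompute with values swapped by hand: medians flip sign
  tv <- phase_rate_vectors(s, "trial", neurons)
  labs <- as.character(s$trials$direction)
  sv <- sleep_bin_vectors(s, "pre", 1, neurons)
  med <- sapply(c("left", "right"), function(v) {
    cc <- popsubspace:::spearman_with(feature_mean_vector(tv, labs, v), sv$rates)
    median(cc[!is.na(cc)])
  })
  expect_equal(d_pre, med[["right"]] - med[["left"]])
  # identical mean vectors for the two values -> exactly zero
  s2 <- s
  s2$trials$direction <- rep(c("left", "right"), 6)
  tv2 <- phase_rate_vectors(s2, "trial", neurons)
  same <- feature_mean_vector(tv2, rep("x", 12), "x")
  cc <- popsubspace:::spearman_with(same, sv$rates)
  expect_equal(median(cc[!is.na(cc)]) - median(cc[!is.na(cc)]), 0)
})

test_that("bin-size sweep covers the grid and is stable near the implant scale", {
  cfg <- synth_config(N = 8, T_trials = 10, sleep_epoch_s = 200,
                      rho_pre = 0.05, rho_post = 0.5)
  s <- generate_session(cfg, 55)$session
  sw <- binsize_sweep(s, "trial", features = "direction",
                      grid = c(0.55, 1, 1.45))
  expect_equal(sort(unique(sw$bin_s)), c(0.55, 1, 1.45))
  # reactivation implanted at 1 s: positive at neighboring bin sizes too
  agg <- tapply(sw$statistic, sw$bin_s, median)
  expect_true(all(agg > 0))
})

test_that("cohort-level reactivation correlations detect implanted links", {
  set.seed(21)
  m_pre <- runif(12, -0.1, 0.3)
  m_post <- m_pre + rnorm(12, 0.05, 0.01)
  r <- pre_post_reactivation_correlation(m_pre, m_post)
  expect_gt(r$rho, 0.9)
  expect_error(pre_post_reactivation_correlation(m_pre[1:2], m_post[1:2]),
               "at least 5")
  dr <- runif(12, 0, 1)
  stat <- 0.2 * dr + rnorm(12, sd = 0.01)
  rv <- reactivation_vs_performance(dr, stat)
  expect_gt(rv$rho, 0.8)
  expect_true(is.na(reactivation_vs_performance(rep(0.5, 6), stat[1:6])$rho))
})

test_that("mean activity vectors can align while decoding axes stay apart", {
  counts <- matrix(rpois(60, 8) + 1, 6, 10)
  s <- make_toy_session(counts, counts, trial_dur = 2, iti_dur = 2,
                        with_sleep = TRUE)
  mva <- mean_vector_angles(s, features = "direction", neurons = 1:6)
  expect_true(all(mva$mean_vector_angle >= 0 & mva$mean_vector_angle <= pi))
  # identical trial and ITI rates: mean-vector angles collapse to zero
  expect_true(all(mva$mean_vector_angle < 1e-6))
})
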