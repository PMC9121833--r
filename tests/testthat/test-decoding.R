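test_that("LOO predictions match an independent brute-force refit", {
  set.seed(11)
  for (rep in 1:6) {
    Tt <- sample(6:8, 1); N <- sample(2:4, 1)
    X <- matrix(rnorm(Tt * N), Tt, N)
    labels <- sample(rep(c("left", "right"), length.out = Tt))
    if (min(table(labels)) < 2) next
    X[labels == "right", 1] <- X[labels == "right", 1] + runif(1, 0, 2)
    dec <- loo_decode(X, labels)
    expect_identical(dec$predictions, loo_brute(X, labels))
    expect_equal(dec$accuracy, mean(dec$predictions == labels))
  }
})

test_that("well-separated classes decode perfectly; independent labels at chance", {
  set.seed(12)
  Tt <- 24
  labels <- rep(c("left", "right"), each = Tt / 2)
  X <- matrix(rnorm(Tt * 5, sd = 0.2), Tt, 5)
  X[labels == "right", 2] <- X[labels == "right", 2] + 8
  expect_equal(loo_decode(X, labels)$accuracy, 1)
  # labels independent of activity: accuracy within the empirical null band
  Xn <- matrix(rnorm(Tt * 5), Tt, 5)
  acc <- loo_decode(Xn, labels)$accuracy
  nulls <- shuffled_chance(Xn, labels, reps = 100, seed = 1)
  expect_gte(acc, quantile(nulls, 0.01) - 1e-9)
  expect_lte(acc, quantile(nulls, 0.99) + 1e-9)
})

test_that("shuffled chance is seeded, sized, and centered near 0.5", {
  set.seed(13)
  X <- matrix(rnorm(80), 20, 4)
  labels <- rep(c("a", "b"), 10)
  n1 <- shuffled_chance(X, labels, reps = 50, seed = 42)
  n2 <- shuffled_chance(X, labels, reps = 50, seed = 42)
  expect_identical(n1, n2)
  expect_length(n1, 50)
  expect_lt(abs(mean(n1) - 0.5), 0.12)
  # informative activity beats its own null
  X[labels == "b", ] <- X[labels == "b", ] + 3
  acc <- loo_decode(X, labels)$accuracy
  nulls <- shuffled_chance(X, labels, reps = 50, seed = 7)
  expect_gt(acc, quantile(nulls, 0.975))
})

test_that("decoder axes respect label symmetry and duplication invariance", {
  set.seed(14)
  X <- matrix(rnorm(60), 15, 4)
  labels <- rep(c("left", "right"), length.out = 15)
  X[labels == "right", 3] <- X[labels == "right", 3] + 2
  ax <- fit_decoder_axis(X, labels)
  ax_flip <- fit_decoder_axis(X, ifelse(labels == "left", "zright", "aleft"))
  expect_equal(ax_flip$w, -ax$w, tolerance = 1e-6, ignore_attr = TRUE)
  # duplication doubles the likelihood against a fixed penalty, so the axis
  # direction is only approximately preserved
  ax_dup <- fit_decoder_axis(rbind(X, X), c(labels, labels))
  expect_lt(angle_between(ax$w, ax_dup$w), 0.1)
})

test_that("implanted coding axes are recovered by the axis fit", {
  errs <- sapply(1:5, function(sd) {
    gs <- generate_session(recovery_config(pi / 2, T_trials = 30), sd)
    s <- gs$session; gt <- gs$ground_truth
    an <- select_active_neurons(s)
    iv <- phase_rate_vectors(s, "iti", an)
    w <- fit_decoder_axis(iv, as.character(s$trials$direction))
    c_iti <- gt$axes$direction$iti[an]
    # sign: positive class "right" is the +1 coding by construction
    min(angle_between(w$w, c_iti), angle_between(w$w, -c_iti))
  })
  expect_lt(median(errs), 0.1 * pi)
})

test_that("angle_between satisfies its closed forms and identities", {
  expect_equal(angle_between(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(angle_between(c(1, 0), c(1, 0)), 0)
  expect_equal(angle_between(c(1, 0), c(-1, 0)), pi)
  expect_equal(angle_between(c(1, 0), c(1, 1)), pi / 4)
  expect_error(angle_between(c(0, 0), c(1, 0)), "undefined angle")
  set.seed(15)
  for (rep in 1:20) {
    u <- rnorm(5); v <- rnorm(5)
    expect_equal(angle_between(u, v), angle_between(v, u))
    expect_equal(angle_between(3.7 * u, 0.01 * v), angle_between(u, v))
    expect_equal(angle_between(u, -v), pi - angle_between(u, v))
    expect_true(angle_between(u, v) >= 0 && angle_between(u, v) <= pi)
  }
})

test_that("label shifts for previous/following invert each other", {
  labels <- letters[1:6]
  prev <- shift_labels(labels, "trial", "previous")
  expect_equal(prev$rows, 2:6)
  expect_equal(prev$labels, letters[1:5])
  fol <- shift_labels(labels, "trial", "following")
  expect_equal(fol$rows, 1:5)
  expect_equal(fol$labels, letters[2:6])
  # shifting by previous then following restores the original alignment
  expect_equal(labels[prev$rows - 1], prev$labels)
  expect_equal(labels[fol$rows + 1], fol$labels)
  # ITI rows carry the label of the trial they follow
  iti <- shift_labels(labels, "iti", "previous")
  expect_equal(iti$rows, 1:6)
  expect_equal(iti$labels, labels)
})

test_that("identical data for both phases give near-zero between-phase angles", {
  counts <- matrix(rpois(60, 8) + 1, 6, 10)
  s <- make_toy_session(counts, counts, trial_dur = 2, iti_dur = 2)
  an <- angle_analysis(s, n_shuffle = 0, fold_sd = FALSE, neurons = 1:6)
  expect_true(all(an$between$angle < 0.05 * pi))
})

test_that("cross-decoding on the training set is at least as good as LOO", {
  set.seed(16)
  X <- matrix(rnorm(72), 18, 4)
  labels <- rep(c("a", "b"), 9)
  X[labels == "b", 1] <- X[labels == "b", 1] + 1.2
  full <- cross_decode(X, labels, X, labels, "full")
  loo <- cross_decode(X, labels, X, labels, "loo")
  expect_gte(full$accuracy, loo$accuracy)
  expect_error(cross_decode(X, rep("a", 18), X, labels, "full"),
               "degenerate labels")
})

test_that("decoding-performance correlation detects an implanted link", {
  set.seed(17)
  perf <- runif(20, 0.3, 0.9)
  rel <- 0.5 * perf + rnorm(20, sd = 0.02)
  r <- decoding_vs_performance(perf, rel)
  expect_gt(r$rho, 0.8)
  expect_lt(r$p, 0.05)
  expect_error(decoding_vs_performance(perf[1:2], rel[1:2]), "at least 5")
  r0 <- decoding_vs_performance(perf, rep(0.2, 20))
  expect_true(is.na(r0$rho))
})
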