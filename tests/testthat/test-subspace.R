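test_that("pca_axes matches a brute-force eigendecomposition", {
  set.seed(5)
  for (rep in 1:10) {
    X <- matrix(rnorm(24), 6, 4)
    for (d in 1:3) {
      a <- pca_axes(X, d)
      b <- pca_brute(X, d)
      expect_lt(max(abs(a$axes - b$axes)), 1e-8)
      expect_lt(max(abs(a$projected - b$projected)), 1e-8)
      expect_equal(a$eigenvalues[seq_len(d)], b$eigenvalues[seq_len(d)],
                   tolerance = 1e-8)
    }
  }
})

test_that("pca_axes handles degenerate and isotropic geometry", {
  # data on an exact line: one axis captures all variance
  t <- seq(-2, 2, length.out = 8)
  X <- outer(t, c(1, 2, -1)) + rep(c(5, 0, 3), each = 8)
  pr <- pca_axes(X, 1)
  expect_equal(sum(pr$eigenvalues[1]) / sum(pr$eigenvalues), 1,
               tolerance = 1e-12)
  expect_error(pca_axes(X, 2), "rank deficient")
  # isotropic data: eigenvalues agree within sampling error
  set.seed(6)
  Xi <- matrix(rnorm(4000), 1000, 4)
  pr2 <- pca_axes(Xi, 4)
  expect_lt(max(pr2$eigenvalues) / min(pr2$eigenvalues), 1.3)
})

test_that("separability error is 0 for gapped clouds and 0.5 for identical ones", {
  set.seed(7)
  A <- cbind(rnorm(20, -5), rnorm(20))
  B <- cbind(rnorm(20, 5), rnorm(20))
  expect_equal(separability_error(rbind(A, B), rep(c("a", "b"), each = 20)), 0)
  expect_equal(separability_error(rbind(A, A), rep(c("a", "b"), each = 20)), 0.5)
  expect_error(separability_error(A, rep("a", 20)), "degenerate labels")
})

test_that("separability error tracks the optimal linear separator", {
  set.seed(8)
  for (rep in 1:5) {
    mu <- runif(1, 0.5, 2)
    A <- cbind(rnorm(30, -mu), rnorm(30))
    B <- cbind(rnorm(30, mu), rnorm(30))
    Z <- rbind(A, B); y <- rep(c("a", "b"), each = 30)
    svm_err <- separability_error(Z, y)
    oracle <- gridsearch_2d_error(Z, y)
    expect_lt(svm_err, oracle + 0.05)
    expect_gte(svm_err, oracle)  # no linear rule beats the exhaustive optimum
  }
})

test_that("1-D separability matches an exhaustive threshold scan within 0.02", {
  set.seed(9)
  for (rep in 1:8) {
    z <- matrix(c(rnorm(25, -1), rnorm(25, 1)), ncol = 1)
    y <- rep(c("a", "b"), each = 25)
    expect_lt(abs(separability_error(z, y) - threshold_scan_error(z[, 1], y)),
              0.02 + 1e-9)
  }
})

test_that("separability error is invariant to relabeling and common rescaling", {
  set.seed(10)
  Z <- rbind(cbind(rnorm(15, -1), rnorm(15)), cbind(rnorm(15, 1), rnorm(15)))
  y <- rep(c("a", "b"), each = 15)
  e <- separability_error(Z, y)
  y_flip <- ifelse(y == "a", "b", "a")
  expect_equal(separability_error(Z, y_flip), e)
  expect_equal(separability_error(Z * 1000, y), e)
  expect_equal(separability_error(Z * 1e-4, y), e)
})

test_that("strong phase separation is perfectly separable in low dimension", {
  cfg <- synth_config(N = 8, T_trials = 12, sleep_epoch_s = 30,
                      phase_separation = 15)
  s <- generate_session(cfg, 41)$session
  ps <- phase_separability(s, dims = 1:4)
  expect_equal(ps$errors$error[1], 0)
  expect_equal(ps$chance, 0.5)
  # near-monotonicity: adding dimensions does not hurt much
  expect_true(all(diff(ps$errors$error) <= 0.02 + 1e-9))
})

test_that("section separability maps are symmetric with a transition cross map", {
  cfg <- synth_config(N = 8, T_trials = 12, sleep_epoch_s = 30,
                      phase_separation = 12, feature_gain = c(0, 0, 0))
  s <- generate_session(cfg, 43)$session
  maps <- section_separability(s, d = 2)
  expect_equal(maps$within_trial, t(maps$within_trial))
  expect_equal(maps$within_iti, t(maps$within_iti))
  ok <- !is.na(maps$cross)
  expect_true(all(maps$cross[ok] >= 0 & maps$cross[ok] <= 1))
  # phase offset only: cross-phase pairs separate better than within-phase pairs
  expect_lt(mean(maps$cross, na.rm = TRUE),
            mean(c(maps$within_trial, maps$within_iti), na.rm = TRUE))
})
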