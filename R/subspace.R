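# Linear separability of population activity in low-dimensional
# principal-component projections, between task phases and maze sections.

#' Principal-component axes of a rate matrix
#'
#' Columns are mean-centered (optionally not, for sensitivity analyses), the
#' eigenvectors of X'X are computed, and rows are projected onto the top `d`
#' axes. Axes are ordered by descending eigenvalue with a deterministic sign
#' convention: the largest-magnitude component of each axis is positive.
#'
#' @param x Numeric matrix (rows = rate vectors) or a `PhaseMatrix`.
#' @param d Number of axes, `1 <= d <= rank(X)`.
#' @param center Mean-center columns first (default TRUE).
#' @return List with `axes` (N x d orthonormal), `projected` (rows x d),
#'   `eigenvalues`, `center`.
#' @export
pca_axes <- function(x, d, center = TRUE) {
  X <- if (inherits(x, "PhaseMatrix")) x$X else as.matrix(x)
  stopifnot(d >= 1, nrow(X) > d)
  mu <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  ev <- sv$d^2
  rank <- sum(sv$d > max(sv$d[1], 1e-300) * 1e-10)
  if (d > rank) stop("rank deficient", call. = FALSE)
  axes <- sv$v[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    k <- which.max(abs(axes[, j]))
    if (axes[k, j] < 0) axes[, j] <- -axes[, j]
  }
  list(axes = axes, projected = Xc %*% axes,
       eigenvalues = ev, center = mu)
}

#' Misclassification proportion of a linear maximum-margin classifier
#'
#' Fits a soft-margin linear SVM with a large fixed penalty (effectively a
#' hard margin when the classes are separable) on the projected vectors and
#' returns the training-set misclassification proportion: a measure of
#' geometric separability, not generalization. Because the hinge loss also
#' penalizes margin violations that the misclassification count ignores, the
#' intercept is recalibrated by an exact threshold scan along the SVM's
#' normal direction before the error is counted; on one-dimensional
#' projections this makes the reported error equal to the optimal linear
#' (threshold) error. Projections are rescaled to unit root-mean-square
#' before fitting so the measure is invariant to a common rescaling of all
#' vectors.
#'
#' @param projected Numeric matrix (rows = vectors) of projections.
#' @param labels Binary labels, one per row (factor/character/logical).
#' @param cost Soft-margin penalty.
#' @return Misclassification proportion in `[0, 1]`.
#' @export
separability_error <- function(projected, labels, cost = 1000) {
  Z <- as.matrix(projected)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("degenerate labels", call. = FALSE)
  if (min(table(y)) < 2) stop("degenerate labels", call. = FALSE)
  rms <- sqrt(mean(scale(Z, scale = FALSE)^2))
  if (rms > 0) Z <- Z / rms
  fit <- e1071::svm(Z, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  if (sum(w^2) < 1e-20) return(min(mean(stats::predict(fit, Z) != y),
                                   min(table(y)) / length(y)))
  z <- drop(Z %*% w)
  best_threshold_error(z, y)
}

# exact 0-1-optimal threshold (both polarities) along a 1-D projection
best_threshold_error <- function(z, y) {
  lv <- levels(y)
  o <- order(z)
  zo <- z[o]; yo <- y[o]
  n <- length(z)
  # errors for boundary after position k (0..n), polarity lv[1] below
  below1 <- cumsum(yo != lv[1])
  above2 <- rev(cumsum(rev(yo != lv[2])))
  err1 <- c(above2, 0) + c(0, below1)  # counts for each cut position 0..n
  err2 <- (n - err1)                   # opposite polarity
  # only cuts between distinct values (or outside the data) are realizable
  valid <- c(TRUE, diff(zo) > 0, TRUE)
  min(err1[valid], err2[valid]) / n
}

#' Trial/ITI separability of a session across dimensionalities
#'
#' Builds the interleaved 2T x N phase matrix, projects it onto the top
#' `d` principal axes for each `d`, and reports the linear-classifier
#' misclassification proportion with trial/ITI labels. Chance level is the
#' majority-phase proportion (0.5 for the balanced trial/ITI split).
#'
#' @param session A `SessionRecording`.
#' @param dims Dimensionalities to test.
#' @param phases Phase split (default trial/ITI; use
#'   `c("inbound", "outbound")` for the heading split).
#' @param neurons Neuron ids (default: active neurons).
#' @param center Mean-center before PCA.
#' @param outbound_starts Optional precomputed outbound start times.
#' @return A `SeparabilityResult`: list with `errors` (data.frame of `d`,
#'   `error`), `chance`, `axes` (list per d), `phases`.
#' @export
phase_separability <- function(session, dims = 1:4, phases = c("trial", "iti"),
                               neurons = NULL, center = TRUE,
                               outbound_starts = NULL) {
  pm <- build_phase_matrix(session, neurons, phases, outbound_starts)
  dims <- dims[dims < nrow(pm$X)]
  errs <- numeric(length(dims))
  axes <- vector("list", length(dims))
  for (k in seq_along(dims)) {
    pr <- pca_axes(pm$X, dims[k], center = center)
    errs[k] <- separability_error(pr$projected, pm$phase)
    axes[[k]] <- pr$axes
  }
  structure(list(errors = data.frame(d = dims, error = errs),
                 chance = max(table(pm$phase)) / length(pm$phase),
                 axes = axes, phases = phases),
            class = "SeparabilityResult")
}

#' @export
print.SeparabilityResult <- function(x, ...) {
  cat("SeparabilityResult (", paste(x$phases, collapse = " vs "), "):\n", sep = "")
  print(x$errors, row.names = FALSE)
  invisible(x)
}

#' Pairwise separability of population activity between maze sections
#'
#' For every pair of maze sections, stacks the two sets of section rate
#' vectors, projects onto the top `d` principal axes, and reports the
#' misclassification proportion: within trials (5 x 5, symmetric, diagonal
#' undefined), within ITIs, and across phases (trial section x ITI section;
#' the (5,5) cell is the arm-end transition). Rows missing a section are
#' dropped pairwise; a pair is skipped (NA) if fewer than `min_rows` vectors
#' remain on either side.
#'
#' @param session A `SessionRecording`.
#' @param d Projection dimensionality (default 2).
#' @param neurons Neuron ids (default: active neurons).
#' @param min_rows Minimum vectors per side.
#' @return A `SectionSeparabilityMaps`: list of matrices `within_trial`,
#'   `within_iti`, `cross`.
#' @export
section_separability <- function(session, d = 2, neurons = NULL, min_rows = 3) {
  neurons <- neurons %||% select_active_neurons(session)
  lin <- linearize_position(session)
  vecs <- list(
    trial = lapply(1:5, function(p)
      section_rate_vectors(session, "trial", p, neurons, lin)$rates),
    iti = lapply(1:5, function(p)
      section_rate_vectors(session, "iti", p, neurons, lin)$rates))
  pair_err <- function(A, B) {
    A <- A[stats::complete.cases(A), , drop = FALSE]
    B <- B[stats::complete.cases(B), , drop = FALSE]
    if (nrow(A) < min_rows || nrow(B) < min_rows) return(NA_real_)
    X <- rbind(A, B)
    dd <- min(d, nrow(X) - 1)
    pr <- tryCatch(pca_axes(X, dd), error = function(e) NULL)
    if (is.null(pr)) return(NA_real_)
    separability_error(pr$projected, rep(c("a", "b"), c(nrow(A), nrow(B))))
  }
  within <- function(ph) {
    m <- matrix(NA_real_, 5, 5)
    for (i in 1:4) for (j in (i + 1):5) {
      m[i, j] <- pair_err(vecs[[ph]][[i]], vecs[[ph]][[j]])
      m[j, i] <- m[i, j]
    }
    m
  }
  cross <- matrix(NA_real_, 5, 5,
                  dimnames = list(paste0("trial", 1:5), paste0("iti", 1:5)))
  for (i in 1:5) for (j in 1:5)
    cross[i, j] <- pair_err(vecs$trial[[i]], vecs$iti[[j]])
  structure(list(within_trial = within("trial"), within_iti = within("iti"),
                 cross = cross, d = d),
            class = "SectionSeparabilityMaps")
}

#' Inbound/outbound separability compared with the trial/ITI split
#'
#' Recomputes [phase_separability()] with the inbound/outbound labels
#' (boundary at the detected heading reversal instead of the arm end) and
#' pairs it with the trial/ITI result for each dimensionality, for use in a
#' cohort-level paired signed-rank comparison.
#'
#' @param session A `SessionRecording`.
#' @param dims Dimensionalities to test.
#' @param neurons Neuron ids (default: active neurons).
#' @return List with `trial_iti` and `inbound_outbound`
#'   (`SeparabilityResult`s) and `comparison` (data.frame of `d`,
#'   `error_trial_iti`, `error_inbound_outbound`, `difference`).
#' @export
inbound_outbound_separability <- function(session, dims = 1:4, neurons = NULL) {
  ob <- detect_outbound_starts(session)
  a <- phase_separability(session, dims, c("trial", "iti"), neurons)
  b <- phase_separability(session, dims, c("inbound", "outbound"), neurons,
                          outbound_starts = ob$t_outbound_s)
  cmp <- merge(stats::setNames(a$errors, c("d", "error_trial_iti")),
               stats::setNames(b$errors, c("d", "error_inbound_outbound")),
               by = "d")
  cmp$difference <- cmp$error_inbound_outbound - cmp$error_trial_iti
  list(trial_iti = a, inbound_outbound = b, comparison = cmp)
}
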