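# Leave-one-out decoding of binary task features from population rate
# vectors, label-shuffle chance levels, decoding-axis geometry, cross-phase
# decoding, and position-resolved decoding.
#
# The decoder is an L2-regularized logistic regression (inverse penalty C,
# intercept unpenalized), fit by Newton iterations with step halving.
# Features are standardized with the training rows' mean/SD.

rate_matrix <- function(x) {
  if (inherits(x, "RateVectorSet")) x$rates else as.matrix(x)
}

positive_class <- function(labels) {
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) stop("degenerate labels", call. = FALSE)
  lv[2]
}

ridge_logistic <- function(X, y01, C = 1, max_iter = 100, tol = 1e-10) {
  X <- cbind(1, X)
  p <- ncol(X)
  pen <- c(0, rep(1 / C, p - 1))
  beta <- numeric(p)
  obj <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y01 * eta) +
      sum(pen * b^2) / 2
  }
  f <- obj(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(X, mu - y01)) + pen * beta
    if (max(abs(g)) < tol) break
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X * w, X) + diag(pen, p)
    step <- tryCatch(solve(H + diag(1e-12, p), g), error = function(e) g)
    # backtracking line search keeps Newton stable on separable data
    lam <- 1; accepted <- FALSE
    while (lam >= 1e-8) {
      cand <- beta - lam * step
      fc <- obj(cand)
      if (fc <= f + 1e-12) { accepted <- TRUE; break }
      lam <- lam / 2
    }
    if (!accepted) break
    beta <- cand; f <- fc
  }
  list(intercept = beta[1], w = beta[-1])
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd,
       apply = function(M) sweep(sweep(M, 2, mu), 2, sd, `/`))
}

predict_logit <- function(fit, Xs) {
  eta <- drop(Xs %*% fit$w) + fit$intercept
  # ties at probability exactly 0.5 predict the positive class
  eta >= 0
}

#' Leave-one-out cross-validated decoding of a binary feature
#'
#' For each held-out row, an L2-regularized logistic regression is fit to the
#' remaining rows (features standardized with the training rows' mean/SD) and
#' the held-out label is predicted by the 0.5 probability threshold (ties go
#' to the positive class, the alphabetically/numerically larger label).
#'
#' @param x A `RateVectorSet` or numeric matrix (rows = trials).
#' @param labels Binary labels, one per row; both classes must appear at
#'   least twice and there must be at least 4 rows.
#' @param C Inverse regularization strength.
#' @return List with `accuracy`, `predictions` (character), `labels`,
#'   `positive` (the positive class).
#' @export
loo_decode <- function(x, labels, C = 1) {
  X <- rate_matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  if (nrow(X) < 4) stop("need at least 4 trials", call. = FALSE)
  pos <- positive_class(labels)
  if (min(table(labels)) < 2) stop("degenerate labels", call. = FALSE)
  y <- as.numeric(labels == pos)
  n <- nrow(X)
  pred <- logical(n)
  for (i in seq_len(n)) {
    st <- standardize_fit(X[-i, , drop = FALSE])
    fit <- ridge_logistic(st$apply(X[-i, , drop = FALSE]), y[-i], C)
    pred[i] <- predict_logit(fit, st$apply(X[i, , drop = FALSE]))
  }
  lv <- sort(unique(labels))
  predictions <- ifelse(pred, lv[2], lv[1])
  list(accuracy = mean(predictions == labels), predictions = predictions,
       labels = labels, positive = pos)
}

#' Label-shuffle chance accuracies for leave-one-out decoding
#'
#' Repeats the full leave-one-out decode on `reps` uniform permutations of
#' the labels, seeded for reproducibility. The mean of the shuffle
#' accuracies is the session's chance level for this feature; it accounts
#' for unbalanced label distributions.
#'
#' @inheritParams loo_decode
#' @param reps Number of label permutations (50 in the standard analysis).
#' @param seed Integer seed.
#' @return Numeric vector of length `reps` of shuffle accuracies.
#' @export
shuffled_chance <- function(x, labels, reps = 50, seed = 1, C = 1) {
  X <- rate_matrix(x)
  labels <- as.character(labels)
  with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      loo_decode(X, sample(labels), C)$accuracy
    }, numeric(1))
  })
}

#' Fit a decoding axis on all rows
#'
#' Logistic regression on the full set of rate vectors, with the weight
#' vector in the rate (Hz) coordinate frame so axes from different fits are
#' directly comparable. Rates are not standardized by default: all features
#' share units, and standardizing rescales each neuron's weight by its rate
#' SD, which distorts axis geometry when feature coding dominates a neuron's
#' variance. Set `standardize = TRUE` for the z-scored variant (weights are
#' transformed back to the rate frame).
#'
#' @inheritParams loo_decode
#' @param feature,phase Optional tags stored on the result.
#' @param standardize Z-score rates before fitting (default FALSE).
#' @return A `DecoderAxis`: list with `w` (length-N weights, rate frame),
#'   `intercept`, `positive`, `feature`, `phase`.
#' @export
fit_decoder_axis <- function(x, labels, C = 1, feature = NA, phase = NA,
                             standardize = FALSE) {
  X <- rate_matrix(x)
  labels <- as.character(labels)
  pos <- positive_class(labels)
  y <- as.numeric(labels == pos)
  if (standardize) {
    st <- standardize_fit(X)
    fit <- ridge_logistic(st$apply(X), y, C)
    w <- fit$w / st$sd
    b <- fit$intercept - sum(fit$w * st$mu / st$sd)
  } else {
    fit <- ridge_logistic(X, y, C)
    w <- fit$w
    b <- fit$intercept
  }
  if (all(w == 0)) stop("degenerate axis: all-zero weights", call. = FALSE)
  structure(list(w = stats::setNames(w, colnames(X)), intercept = b,
                 positive = pos, feature = feature, phase = phase),
            class = "DecoderAxis")
}

#' Angle between two weight vectors
#'
#' `theta = acos(u . v / (|u| |v|))` in radians, in `[0, pi]`; the cosine is
#' clipped to `[-1, 1]` before the arccosine.
#'
#' @param u,v Nonzero numeric vectors (or `DecoderAxis` objects).
#' @return Angle in radians.
#' @export
angle_between <- function(u, v) {
  if (inherits(u, "DecoderAxis")) u <- u$w
  if (inherits(v, "DecoderAxis")) v <- v$w
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("undefined angle", call. = FALSE)
  acos(pmin(pmax(sum(u * v) / (nu * nv), -1), 1))
}

#' Align trial-table labels with phase rows
#'
#' Phase rows are indexed by trial: trial row i covers trial i, ITI row i
#' covers the interval after trial i. `reference` selects which trial's
#' label is attached to each row: for trial rows, `current` = trial i,
#' `previous` = trial i-1 (first row dropped), `following` = trial i+1 (last
#' row dropped). For ITI rows the preceding trial is trial i itself, so
#' `previous` (and `current`) attach the label of trial i and `following`
#' the label of trial i+1 (last row dropped).
#'
#' @param labels Per-trial label vector (length T).
#' @param phase `"trial"` or `"iti"`.
#' @param reference `"current"`, `"previous"`, or `"following"`.
#' @return List with `rows` (indices of phase rows kept) and `labels`.
#' @export
shift_labels <- function(labels, phase = c("trial", "iti"),
                         reference = c("current", "previous", "following")) {
  phase <- match.arg(phase)
  reference <- match.arg(reference)
  Tt <- length(labels)
  if (phase == "trial") {
    switch(reference,
      current = list(rows = seq_len(Tt), labels = labels),
      previous = list(rows = 2:Tt, labels = labels[seq_len(Tt - 1)]),
      following = list(rows = seq_len(Tt - 1), labels = labels[2:Tt]))
  } else {
    switch(reference,
      current = ,
      previous = list(rows = seq_len(Tt), labels = labels),
      following = list(rows = seq_len(Tt - 1), labels = labels[2:Tt]))
  }
}

trial_labels <- function(session, feature) {
  tr <- session$trials
  as.character(switch(feature, direction = tr$direction, light = tr$light,
                      outcome = tr$outcome,
                      stop("unknown feature: ", feature, call. = FALSE)))
}

#' Decode one task feature from one phase of a session
#'
#' Convenience wrapper: builds the phase rate vectors, aligns labels per
#' `reference`, runs the leave-one-out decode and the label-shuffle chance
#' level, and reports the relative accuracy (accuracy minus mean shuffle
#' accuracy).
#'
#' @param session A `SessionRecording`.
#' @param feature `"direction"`, `"light"`, or `"outcome"`.
#' @param phase `"trial"` or `"iti"`.
#' @param reference Which trial's label to decode (see [shift_labels()]).
#' @param reps Number of shuffle repetitions.
#' @param seed Integer seed for the shuffles.
#' @param C Inverse regularization strength.
#' @param neurons Neuron ids (default: active neurons).
#' @param vectors Optional precomputed `RateVectorSet` for the phase.
#' @return A `DecodingResult`: list with `feature`, `phase`, `reference`,
#'   `accuracy`, `predictions`, `null_accuracies`, `null_mean`,
#'   `relative_accuracy`.
#' @export
decode_feature <- function(session, feature, phase = c("trial", "iti"),
                           reference = c("current", "previous", "following"),
                           reps = 50, seed = 1, C = 1, neurons = NULL,
                           vectors = NULL) {
  phase <- match.arg(phase)
  reference <- match.arg(reference)
  v <- vectors %||% phase_rate_vectors(session, phase, neurons)
  al <- shift_labels(trial_labels(session, feature), phase, reference)
  X <- v$rates[al$rows, , drop = FALSE]
  dec <- loo_decode(X, al$labels, C)
  nulls <- shuffled_chance(X, al$labels, reps, seed, C)
  structure(list(feature = feature, phase = phase, reference = reference,
                 accuracy = dec$accuracy, predictions = dec$predictions,
                 null_accuracies = nulls, null_mean = mean(nulls),
                 relative_accuracy = dec$accuracy - mean(nulls)),
            class = "DecodingResult")
}

#' @export
print.DecodingResult <- function(x, ...) {
  cat(sprintf("DecodingResult: %s/%s (%s): accuracy %.3f, chance %.3f, relative %+.3f\n",
              x$phase, x$feature, x$reference, x$accuracy, x$null_mean,
              x$relative_accuracy))
  invisible(x)
}

#' Decoding-axis geometry of a session
#'
#' Fits the full-data decoding axis for each feature in each phase (trial
#' axes decode the current trial, ITI axes the preceding trial) and
#' measures: the between-phase angle per feature; the within-phase angle per
#' feature pair; reference angles from axes fit on shuffled labels; and the
#' within-phase fold-axis variability — the SD over leave-one-out folds of
#' the angle between each fold's axis and the full-data axis.
#'
#' @param session A `SessionRecording`.
#' @param features Features to analyze.
#' @param n_shuffle Shuffled-label reference fits per feature.
#' @param seed Integer seed for the shuffles.
#' @param C Inverse regularization strength.
#' @param neurons Neuron ids (default: active neurons).
#' @param fold_sd Compute fold-axis variability (set FALSE to skip the extra
#'   T fits per feature and phase).
#' @return An `AngleSet`: list with `axes`, `between` (data.frame), `within`
#'   (data.frame), `shuffle_ref` (data.frame), `fold_sd` (data.frame).
#' @export
angle_analysis <- function(session, features = c("direction", "light", "outcome"),
                           n_shuffle = 20, seed = 1, C = 1, neurons = NULL,
                           fold_sd = TRUE) {
  neurons <- neurons %||% select_active_neurons(session)
  vecs <- list(trial = phase_rate_vectors(session, "trial", neurons),
               iti = phase_rate_vectors(session, "iti", neurons))
  ref <- c(trial = "current", iti = "previous")
  axes <- list()
  labels <- list()
  for (ph in c("trial", "iti")) for (f in features) {
    al <- shift_labels(trial_labels(session, f), ph, ref[[ph]])
    labels[[paste(ph, f)]] <- al
    axes[[paste(ph, f)]] <- fit_decoder_axis(
      vecs[[ph]]$rates[al$rows, , drop = FALSE], al$labels, C,
      feature = f, phase = ph)
  }
  between <- data.frame(feature = features, angle = vapply(features, function(f)
    angle_between(axes[[paste("trial", f)]], axes[[paste("iti", f)]]),
    numeric(1)))
  within <- if (length(features) < 2) NULL else
    do.call(rbind, lapply(c("trial", "iti"), function(ph) {
      prs <- utils::combn(features, 2)
      data.frame(phase = ph, f1 = prs[1, ], f2 = prs[2, ],
                 angle = apply(prs, 2, function(pr)
                   angle_between(axes[[paste(ph, pr[1])]],
                                 axes[[paste(ph, pr[2])]])))
    }))
  shuffle_ref <- NULL
  if (n_shuffle > 0) {
    shuffle_ref <- with_seed(seed, {
      do.call(rbind, lapply(features, function(f) {
        ang <- vapply(seq_len(n_shuffle), function(r) {
          a <- lapply(c("trial", "iti"), function(ph) {
            al <- labels[[paste(ph, f)]]
            fit_decoder_axis(vecs[[ph]]$rates[al$rows, , drop = FALSE],
                             sample(al$labels), C)
          })
          angle_between(a[[1]], a[[2]])
        }, numeric(1))
        data.frame(feature = f, rep = seq_len(n_shuffle), angle = ang)
      }))
    })
  }
  fold_df <- NULL
  if (fold_sd) {
    fold_df <- do.call(rbind, lapply(c("trial", "iti"), function(ph) {
      data.frame(phase = ph, feature = features,
                 sd = vapply(features, function(f) {
                   al <- labels[[paste(ph, f)]]
                   X <- vecs[[ph]]$rates[al$rows, , drop = FALSE]
                   full <- axes[[paste(ph, f)]]
                   ang <- vapply(seq_len(nrow(X)), function(i) {
                     fold <- tryCatch(
                       fit_decoder_axis(X[-i, , drop = FALSE], al$labels[-i], C),
                       error = function(e) NULL)
                     if (is.null(fold)) NA_real_ else angle_between(fold, full)
                   }, numeric(1))
                   stats::sd(ang, na.rm = TRUE)
                 }, numeric(1)))
    }))
  }
  structure(list(axes = axes, between = between, within = within,
                 shuffle_ref = shuffle_ref, fold_sd = fold_df),
            class = "AngleSet")
}

#' Cross-phase decoding
#'
#' Scores a decoder trained on one phase's vectors on the other phase's
#' vectors. `full` mode fits on all training rows and scores all test rows;
#' `loo` mode leaves out the i-th trial/ITI pair, fits on the remaining
#' training rows, and predicts the i-th test row (rows must be aligned by
#' trial).
#'
#' @param train_x,test_x Rate matrices or `RateVectorSet`s, aligned by row.
#' @param train_labels,test_labels Binary labels per row.
#' @param mode `"full"` or `"loo"`.
#' @param C Inverse regularization strength.
#' @return A `CrossDecodingResult`: list with `accuracy`, `predictions`,
#'   `mode`.
#' @export
cross_decode <- function(train_x, train_labels, test_x, test_labels,
                         mode = c("full", "loo"), C = 1) {
  mode <- match.arg(mode)
  Xtr <- rate_matrix(train_x); Xte <- rate_matrix(test_x)
  train_labels <- as.character(train_labels)
  test_labels <- as.character(test_labels)
  pos <- positive_class(train_labels)
  if (length(unique(test_labels)) < 2) stop("degenerate labels", call. = FALSE)
  y <- as.numeric(train_labels == pos)
  lv <- sort(unique(c(train_labels, test_labels)))
  if (mode == "full") {
    st <- standardize_fit(Xtr)
    fit <- ridge_logistic(st$apply(Xtr), y, C)
    pred <- predict_logit(fit, st$apply(Xte))
  } else {
    stopifnot(nrow(Xtr) == nrow(Xte))
    pred <- logical(nrow(Xte))
    for (i in seq_len(nrow(Xtr))) {
      st <- standardize_fit(Xtr[-i, , drop = FALSE])
      fit <- ridge_logistic(st$apply(Xtr[-i, , drop = FALSE]), y[-i], C)
      pred[i] <- predict_logit(fit, st$apply(Xte[i, , drop = FALSE]))
    }
  }
  predictions <- ifelse(pred, lv[length(lv)], lv[1])
  structure(list(accuracy = mean(predictions == test_labels),
                 predictions = predictions, mode = mode),
            class = "CrossDecodingResult")
}

#' Label-shuffle chance for cross-phase decoding
#'
#' Permutes the shared trial labels (the same permutation applied to the
#' training and test sides, as both are labeled by the same trials) and
#' recomputes the cross-decoding accuracy.
#'
#' @inheritParams cross_decode
#' @param labels Shared per-row labels for both phases.
#' @param reps Number of permutations.
#' @param seed Integer seed.
#' @return Numeric vector of `reps` chance accuracies.
#' @export
cross_decode_chance <- function(train_x, test_x, labels, reps = 50, seed = 1,
                                mode = c("full", "loo"), C = 1) {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      sh <- sample(labels)
      cross_decode(train_x, sh, test_x, sh, mode, C)$accuracy
    }, numeric(1))
  })
}

#' Position-resolved decoding profile
#'
#' Leave-one-out decoding of one feature from the per-maze-section rate
#' vectors of each phase, with a label-shuffle chance level per section and
#' full-mode cross-decoding between matched trial/ITI sections. Sections
#' with fewer than 4 usable rows (after dropping missing-occupancy rows and
#' label alignment) are skipped. Results carry a temporal-order index:
#' trial sections run 1 to 5 and ITI sections 5 back to 1.
#'
#' @param session A `SessionRecording`.
#' @param feature `"direction"`, `"light"`, or `"outcome"`.
#' @param reference Which trial's label to decode (see [shift_labels()]).
#' @param reps Shuffle repetitions per section.
#' @param seed Integer seed.
#' @param C Inverse regularization strength.
#' @param neurons Neuron ids (default: active neurons).
#' @return data.frame with one row per (phase, section): `accuracy`,
#'   `null_mean`, `relative_accuracy`, `null_q975`, `cross_accuracy`
#'   (matched-section, trial-trained on trial rows), `n_used`, `order`.
#' @export
position_decoding_profile <- function(session, feature,
                                      reference = c("current", "previous", "following"),
                                      reps = 50, seed = 1, C = 1,
                                      neurons = NULL) {
  reference <- match.arg(reference)
  neurons <- neurons %||% select_active_neurons(session)
  lin <- linearize_position(session)
  labs <- trial_labels(session, feature)
  sec <- list()
  for (ph in c("trial", "iti")) for (p in 1:5)
    sec[[paste(ph, p)]] <- tryCatch(
      section_rate_vectors(session, ph, p, neurons, lin)$rates,
      error = function(e) NULL)
  out <- list()
  seeds <- derive_seeds(seed, 10)
  k <- 0
  for (ph in c("trial", "iti")) for (p in 1:5) {
    k <- k + 1
    X <- sec[[paste(ph, p)]]
    al <- shift_labels(labs, ph, reference)
    row <- data.frame(phase = ph, section = p,
                      order = if (ph == "trial") p else 11 - p,
                      n_used = 0L, accuracy = NA_real_, null_mean = NA_real_,
                      relative_accuracy = NA_real_, null_q975 = NA_real_,
                      cross_accuracy = NA_real_)
    if (!is.null(X)) {
      Xr <- X[al$rows, , drop = FALSE]
      keep <- stats::complete.cases(Xr)
      Xu <- Xr[keep, , drop = FALSE]
      lu <- al$labels[keep]
      row$n_used <- nrow(Xu)
      if (nrow(Xu) >= 4 && length(unique(lu)) == 2 && min(table(lu)) >= 2) {
        dec <- loo_decode(Xu, lu, C)
        nulls <- shuffled_chance(Xu, lu, reps, seeds[k], C)
        row$accuracy <- dec$accuracy
        row$null_mean <- mean(nulls)
        row$relative_accuracy <- dec$accuracy - mean(nulls)
        row$null_q975 <- stats::quantile(nulls, 0.975, names = FALSE)
      }
    }
    out[[k]] <- row
  }
  out <- do.call(rbind, out)
  # matched-section cross-decoding (train on trial rows, test on ITI rows)
  for (p in 1:5) {
    A <- sec[[paste("trial", p)]]; B <- sec[[paste("iti", p)]]
    if (is.null(A) || is.null(B)) next
    al <- shift_labels(labs, "trial", "current")
    keep <- stats::complete.cases(A[al$rows, , drop = FALSE]) &
      stats::complete.cases(B[al$rows, , drop = FALSE])
    if (sum(keep) < 4) next
    lu <- al$labels[keep]
    if (length(unique(lu)) < 2 || min(table(lu)) < 2) next
    cd <- cross_decode(A[al$rows, , drop = FALSE][keep, , drop = FALSE], lu,
                       B[al$rows, , drop = FALSE][keep, , drop = FALSE], lu,
                       "full", C)
    out$cross_accuracy[out$phase == "iti" & out$section == p] <- cd$accuracy
  }
  out[order(out$order), ]
}

#' Correlation between session performance and decoding accuracy
#'
#' Spearman rank correlation, across sessions, between the proportion of
#' correct trials and the relative decoding accuracy, with a two-sided
#' p value.
#'
#' @param performance Per-session proportion correct (length >= 5).
#' @param relative_accuracy Per-session relative decoding accuracy.
#' @return List with `rho`, `p`, `n`.
#' @export
decoding_vs_performance <- function(performance, relative_accuracy) {
  stopifnot(length(performance) == length(relative_accuracy))
  if (length(performance) < 5)
    stop("need at least 5 sessions", call. = FALSE)
  if (stats::sd(performance) == 0 || stats::sd(relative_accuracy) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(performance)))
  ct <- suppressWarnings(stats::cor.test(performance, relative_accuracy,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(performance))
}
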