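# Reactivation of feature-specific waking activity in slow-wave sleep:
# rank correlation of feature mean vectors with binned sleep population
# vectors, the M_post - M_pre median-difference statistic, within-epoch
# paired-feature controls, and the bin-size sweep.

#' Feature-specific mean activity vector
#'
#' Elementwise mean of the rate vectors of all rows whose label matches
#' `value` (e.g. the mean trial vector of all right-choice trials).
#'
#' @param vectors A `RateVectorSet` or rate matrix.
#' @param labels Per-row labels.
#' @param value The label value to average over.
#' @return Named numeric mean vector (length N).
#' @export
feature_mean_vector <- function(vectors, labels, value) {
  X <- rate_matrix(vectors)
  rows <- which(as.character(labels) == as.character(value))
  if (!length(rows)) stop("no rows with label ", value, call. = FALSE)
  colMeans(X[rows, , drop = FALSE])
}

#' Binned population rate vectors in slow-wave sleep
#'
#' Tiles each slow-wave-sleep interval of the epoch with contiguous bins of
#' `bin_s` seconds anchored at the interval start; the trailing partial bin
#' is dropped so all bins have exactly equal duration. Rates are spike
#' counts divided by `bin_s`, restricted to the session's active neurons.
#'
#' @param session A `SessionRecording`.
#' @param epoch `"pre"` or `"post"`.
#' @param bin_s Bin duration in seconds (> 0).
#' @param neurons Neuron ids (default: active neurons).
#' @return A `SleepVectorSet`: list with `rates` (B x N), `t_start`
#'   (bin start times), `epoch`, `bin_s`, `neuron_ids`.
#' @export
sleep_bin_vectors <- function(session, epoch = c("pre", "post"), bin_s = 1,
                              neurons = NULL) {
  epoch <- match.arg(epoch)
  stopifnot(bin_s > 0)
  neurons <- neurons %||% select_active_neurons(session)
  sl <- session$sleep[session$sleep$epoch == epoch, , drop = FALSE]
  starts <- unlist(lapply(seq_len(nrow(sl)), function(k) {
    nb <- floor((sl$t_end_s[k] - sl$t_start_s[k]) / bin_s)
    if (nb < 1) return(numeric(0))
    sl$t_start_s[k] + bin_s * (seq_len(nb) - 1)
  }))
  if (!length(starts)) stop("no usable bins", call. = FALSE)
  spk <- session$spikes
  rates <- sapply(neurons, function(id) {
    st <- spk$spike_time_s[spk$neuron_id == id]
    count_in_intervals(st, starts, starts + bin_s) / bin_s
  })
  rates <- matrix(rates, nrow = length(starts), dimnames = list(NULL, neurons))
  structure(list(rates = rates, t_start = starts, epoch = epoch,
                 bin_s = bin_s, neuron_ids = neurons),
            class = "SleepVectorSet")
}

spearman_with <- function(v, M) {
  # Spearman correlation of vector v with each row of M; rows with zero
  # variance (e.g. silent bins) return NA and are excluded by callers.
  rv <- rank(v)
  if (stats::sd(rv) == 0) stop("constant feature vector", call. = FALSE)
  apply(M, 1, function(row) {
    rr <- rank(row)
    if (stats::sd(rr) == 0) return(NA_real_)
    stats::cor(rv, rr)
  })
}

#' Pre/post sleep reactivation of a feature-specific activity vector
#'
#' Correlates (Spearman, average ranks on ties) the feature-specific mean
#' vector with the population vector of every sleep bin in the pre- and
#' post-training epochs, and summarizes the shift by the difference of
#' medians `M_post - M_pre`; a positive statistic means the feature vector
#' is preferentially reactivated in post-training sleep. Bins with constant
#' rate vectors (Spearman undefined) are excluded; their counts are
#' reported. The two correlation distributions are also compared with a
#' two-sample Kolmogorov-Smirnov test.
#'
#' @param feature_vector Length-N mean activity vector (see
#'   [feature_mean_vector()]).
#' @param session A `SessionRecording`.
#' @param bin_s Sleep bin duration (s).
#' @param neurons Neuron ids (default: active neurons; at least 3).
#' @param min_bins Minimum usable bins per epoch.
#' @return A `ReactivationResult`: list with `pre`, `post` (correlation
#'   vectors), `statistic` (M_post - M_pre), `m_pre`, `m_post`, `ks_p`,
#'   `n_dropped`, `bin_s`.
#' @export
reactivation_distributions <- function(feature_vector, session, bin_s = 1,
                                       neurons = NULL, min_bins = 5) {
  neurons <- neurons %||% select_active_neurons(session)
  if (length(neurons) < 3) stop("need at least 3 neurons", call. = FALSE)
  stopifnot(length(feature_vector) == length(neurons))
  cors <- lapply(c("pre", "post"), function(ep) {
    sv <- sleep_bin_vectors(session, ep, bin_s, neurons)
    cc <- spearman_with(feature_vector, sv$rates)
    list(keep = cc[!is.na(cc)], dropped = sum(is.na(cc)))
  })
  names(cors) <- c("pre", "post")
  if (length(cors$pre$keep) < min_bins || length(cors$post$keep) < min_bins)
    stop("no usable bins", call. = FALSE)
  m_pre <- stats::median(cors$pre$keep)
  m_post <- stats::median(cors$post$keep)
  ks <- suppressWarnings(stats::ks.test(cors$post$keep, cors$pre$keep))
  structure(list(pre = cors$pre$keep, post = cors$post$keep,
                 statistic = m_post - m_pre, m_pre = m_pre, m_post = m_post,
                 ks_p = ks$p.value,
                 n_dropped = c(pre = cors$pre$dropped, post = cors$post$dropped),
                 bin_s = bin_s),
            class = "ReactivationResult")
}

#' @export
print.ReactivationResult <- function(x, ...) {
  cat(sprintf("ReactivationResult: M_post - M_pre = %+.4f (bin %.2g s, KS p = %.3g)\n",
              x$statistic, x$bin_s, x$ks_p))
  invisible(x)
}

feature_values <- function(feature) {
  if (feature == "outcome") c("0", "1") else c("left", "right")
}

#' Reactivation of every feature value of a phase
#'
#' Convenience loop: for each feature and each of its two values, computes
#' the feature-specific mean vector from the phase rate vectors (trial
#' vectors labeled by the current trial, ITI vectors by the preceding trial)
#' and its pre/post sleep reactivation.
#'
#' @param session A `SessionRecording`.
#' @param source Phase whose mean vectors are reactivated
#'   (`"trial"` or `"iti"`).
#' @param features Features to include.
#' @param bin_s Sleep bin duration (s).
#' @param neurons Neuron ids (default: active neurons).
#' @return data.frame with one row per (feature, value): `statistic`,
#'   `m_pre`, `m_post`, `ks_p`.
#' @export
reactivation_analysis <- function(session, source = c("trial", "iti"),
                                  features = c("direction", "light", "outcome"),
                                  bin_s = 1, neurons = NULL) {
  source <- match.arg(source)
  neurons <- neurons %||% select_active_neurons(session)
  vecs <- phase_rate_vectors(session, source, neurons)
  out <- list()
  for (f in features) for (v in feature_values(f)) {
    labs <- trial_labels(session, f)
    if (!any(labs == v)) next
    fv <- feature_mean_vector(vecs, labs, v)
    r <- tryCatch(reactivation_distributions(fv, session, bin_s, neurons),
                  error = function(e) NULL)
    if (is.null(r)) next
    out[[paste(f, v)]] <- data.frame(
      source = source, feature = f, value = v, bin_s = bin_s,
      statistic = r$statistic, m_pre = r$m_pre, m_post = r$m_post,
      ks_p = r$ks_p)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Within-epoch paired-feature control
#'
#' Difference of median sleep correlations between the two values of one
#' feature within the same sleep epoch (e.g. median correlation with the
#' right-choice trial vector minus with the left-choice vector, both against
#' pre-training sleep). Centered on zero when neither value is
#' preferentially reactivated: a control for artifacts of the reactivation
#' statistic.
#'
#' @param session A `SessionRecording`.
#' @param feature Feature whose two values are compared.
#' @param epoch `"pre"` or `"post"`.
#' @param source Phase of the mean vectors.
#' @param bin_s Sleep bin duration (s).
#' @param neurons Neuron ids (default: active neurons).
#' @return Median difference (value B minus value A, in the order of
#'   [feature_values()]: right minus left, correct minus error).
#' @export
paired_feature_control <- function(session, feature, epoch = c("pre", "post"),
                                   source = c("trial", "iti"), bin_s = 1,
                                   neurons = NULL) {
  epoch <- match.arg(epoch)
  source <- match.arg(source)
  neurons <- neurons %||% select_active_neurons(session)
  vecs <- phase_rate_vectors(session, source, neurons)
  labs <- trial_labels(session, feature)
  vals <- feature_values(feature)
  if (!all(vals %in% labs)) stop("both feature values required", call. = FALSE)
  sv <- sleep_bin_vectors(session, epoch, bin_s, neurons)
  med <- vapply(vals, function(v) {
    cc <- spearman_with(feature_mean_vector(vecs, labs, v), sv$rates)
    stats::median(cc[!is.na(cc)])
  }, numeric(1))
  unname(med[2] - med[1])
}

#' Reactivation bin-size sweep
#'
#' Recomputes the reactivation statistic for every feature value across a
#' grid of sleep bin sizes, 0.1 s to 10 s in steps of 0.15 s (67 sizes),
#' spanning below and above the mean trial duration. Bin sizes with no
#' usable bins are skipped.
#'
#' @param session A `SessionRecording`.
#' @param source Phase of the mean vectors.
#' @param features Features to include.
#' @param grid Bin sizes (s).
#' @param neurons Neuron ids (default: active neurons).
#' @return data.frame as [reactivation_analysis()], one block per bin size.
#' @export
binsize_sweep <- function(session, source = c("trial", "iti"),
                          features = c("direction", "light", "outcome"),
                          grid = seq(0.1, 10, by = 0.15), neurons = NULL) {
  source <- match.arg(source)
  neurons <- neurons %||% select_active_neurons(session)
  out <- lapply(grid, function(b)
    tryCatch(reactivation_analysis(session, source, features, b, neurons),
             error = function(e) NULL))
  do.call(rbind, out)
}

#' Across-session correlation of pre and post reactivation
#'
#' Spearman correlation, across sessions, between the median pre-sleep
#' correlation and the median post-sleep correlation of a feature vector.
#'
#' @param m_pre,m_post Per-session median correlations (length >= 5).
#' @return List with `rho`, `p`, `n` (`NA` for constant input).
#' @export
pre_post_reactivation_correlation <- function(m_pre, m_post) {
  stopifnot(length(m_pre) == length(m_post))
  if (length(m_pre) < 5) stop("need at least 5 sessions", call. = FALSE)
  if (stats::sd(m_pre) == 0 || stats::sd(m_post) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(m_pre)))
  ct <- suppressWarnings(stats::cor.test(m_pre, m_post, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(m_pre))
}

#' Correlation between behavioral change and reactivation
#'
#' Spearman correlation, across sessions, between the change in reward rate
#' (`delta_r` from [classify_session()]) and the reactivation statistic.
#' Sessions with missing `delta_r` are excluded.
#'
#' @param delta_r Per-session change in reward-accumulation rate.
#' @param statistic Per-session reactivation statistic (M_post - M_pre).
#' @return List with `rho`, `p`, `n`.
#' @export
reactivation_vs_performance <- function(delta_r, statistic) {
  stopifnot(length(delta_r) == length(statistic))
  keep <- is.finite(delta_r) & is.finite(statistic)
  delta_r <- delta_r[keep]; statistic <- statistic[keep]
  if (length(delta_r) < 5) stop("need at least 5 sessions", call. = FALSE)
  if (stats::sd(delta_r) == 0 || stats::sd(statistic) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(delta_r)))
  ct <- suppressWarnings(stats::cor.test(delta_r, statistic,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(delta_r))
}

#' Angles between trial and ITI feature mean vectors
#'
#' For each feature value, the angle between the mean trial activity vector
#' and the mean ITI activity vector (ITI vectors labeled by the preceding
#' trial), paired with the corresponding decoding-axis angle: mean activity
#' can stay aligned between phases while the decoding axes rotate to
#' orthogonal.
#'
#' @param session A `SessionRecording`.
#' @param features Features to include.
#' @param neurons Neuron ids (default: active neurons).
#' @param angles Optional precomputed [angle_analysis()] result (computed
#'   without shuffle references if omitted).
#' @return data.frame with `feature`, `value`, `mean_vector_angle`,
#'   `decoding_axis_angle`.
#' @export
mean_vector_angles <- function(session,
                               features = c("direction", "light", "outcome"),
                               neurons = NULL, angles = NULL) {
  neurons <- neurons %||% select_active_neurons(session)
  tv <- phase_rate_vectors(session, "trial", neurons)
  iv <- phase_rate_vectors(session, "iti", neurons)
  angles <- angles %||% angle_analysis(session, features, n_shuffle = 0,
                                       neurons = neurons, fold_sd = FALSE)
  out <- list()
  for (f in features) for (v in feature_values(f)) {
    labs <- trial_labels(session, f)
    if (!any(labs == v)) next
    a <- angle_between(feature_mean_vector(tv, labs, v),
                       feature_mean_vector(iv, labs, v))
    out[[paste(f, v)]] <- data.frame(
      feature = f, value = v, mean_vector_angle = a,
      decoding_axis_angle = angles$between$angle[angles$between$feature == f])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
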