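# Cohort orchestration: run every analysis over a list of sessions,
# aggregate with cohort-level nonparametric tests, and emit a reproducible
# plain-text report (TSV tables + JSON manifest).

#' Run the full analysis pipeline over a cohort
#'
#' For each session: active-neuron selection, trial/ITI separability across
#' dimensionalities, leave-one-out decoding of each feature in each phase
#' (current labels in trials, preceding-trial labels in ITIs) with shuffle
#' chance levels, decoding-axis angles, full-mode cross-decoding with its
#' shuffle chance, behavioral classification, and (when sleep intervals are
#' present) reactivation of trial and ITI feature vectors at the given bin
#' size. Sessions that fail are skipped with the reason recorded in the
#' manifest; the pipeline fails only if every session fails.
#'
#' Cohort aggregation uses paired Wilcoxon signed-rank tests (accuracy vs
#' mean shuffle accuracy per session), one-sample signed-rank tests
#' (relative accuracies and reactivation statistics against zero), reported
#' against alpha levels 0.05, 0.01, and 0.005.
#'
#' Identical sessions + seed reproduce a byte-identical report.
#'
#' @param sessions List of `SessionRecording`s, or a directory containing
#'   session bundles (one subdirectory each).
#' @param out_dir Report directory (created if needed); `NULL` skips writing.
#' @param seed Master integer seed for all shuffles.
#' @param features Features to decode.
#' @param dims Separability dimensionalities.
#' @param reps Shuffle repetitions.
#' @param bin_s Sleep bin size (s).
#' @param alpha Alpha levels annotated in the cohort tables.
#' @return Invisibly, a list with `separability`, `decoding`, `angles`,
#'   `behavior`, `reactivation`, `cohort`, `manifest` (data.frames/lists).
#' @export
run_pipeline <- function(sessions, out_dir = NULL, seed = 1,
                         features = c("direction", "light", "outcome"),
                         dims = 1:4, reps = 50, bin_s = 1,
                         alpha = c(0.05, 0.01, 0.005)) {
  if (is.character(sessions)) {
    dirs <- list.dirs(sessions, recursive = FALSE)
    nm <- basename(dirs)
    sessions <- lapply(dirs, function(d)
      tryCatch(load_session(d), error = function(e) conditionMessage(e)))
    names(sessions) <- nm
  }
  if (is.null(names(sessions)))
    names(sessions) <- sprintf("session%03d", seq_along(sessions))
  seeds <- derive_seeds(seed, length(sessions))
  skipped <- list()
  sep_t <- dec_t <- ang_t <- beh_t <- rea_t <- list()
  for (k in seq_along(sessions)) {
    s <- sessions[[k]]; id <- names(sessions)[k]
    if (!inherits(s, "SessionRecording")) {
      skipped[[id]] <- as.character(s)
      next
    }
    issues <- character(0)
    note <- function(what, e) {
      issues <<- c(issues, paste0(what, ": ", conditionMessage(e)))
      NULL
    }
    res <- tryCatch({
      neurons <- select_active_neurons(s)
      sep <- phase_separability(s, dims, neurons = neurons)
      sep_df <- data.frame(session = id, sep$errors)
      ref <- c(trial = "current", iti = "previous")
      dec_df <- list(); cross_df <- list()
      sseed <- derive_seeds(seeds[k], 2 * length(features) + length(features))
      j <- 0
      vecs <- list(trial = phase_rate_vectors(s, "trial", neurons),
                   iti = phase_rate_vectors(s, "iti", neurons))
      for (ph in c("trial", "iti")) for (f in features) {
        j <- j + 1
        dec_df[[paste(ph, f)]] <- tryCatch({
          d <- decode_feature(s, f, ph, ref[[ph]], reps, sseed[j],
                              neurons = neurons, vectors = vecs[[ph]])
          data.frame(
            session = id, phase = ph, feature = f, reference = ref[[ph]],
            accuracy = d$accuracy, null_mean = d$null_mean,
            relative_accuracy = d$relative_accuracy)
        }, error = function(e) note(paste("decode", ph, f), e))
      }
      for (f in features) {
        j <- j + 1
        cross_df[[f]] <- tryCatch({
          labs <- trial_labels(s, f)
          cd <- cross_decode(vecs$trial, labs, vecs$iti, labs, "full")
          nul <- cross_decode_chance(vecs$trial, vecs$iti, labs,
                                     reps, sseed[j], "full")
          data.frame(
            session = id, phase = "trial_to_iti", feature = f,
            reference = "cross", accuracy = cd$accuracy,
            null_mean = mean(nul),
            relative_accuracy = cd$accuracy - mean(nul))
        }, error = function(e) note(paste("cross-decode", f), e))
      }
      ang_df <- tryCatch({
        ang <- angle_analysis(s, features, n_shuffle = 0, neurons = neurons,
                              fold_sd = FALSE)
        data.frame(session = id, ang$between)
      }, error = function(e) note("angles", e))
      beh <- suppressWarnings(classify_session(s))
      beh_df <- data.frame(session = id, class = beh$class,
                           split = beh$split %||% NA_integer_,
                           r_before = beh$r_before, r_after = beh$r_after,
                           delta_r = beh$delta_r,
                           performance = beh$performance)
      rea_df <- NULL
      if (nrow(s$sleep) > 0) {
        rea_df <- tryCatch({
          r2 <- rbind(reactivation_analysis(s, "trial", features, bin_s, neurons),
                      reactivation_analysis(s, "iti", features, bin_s, neurons))
          if (!is.null(r2) && nrow(r2)) data.frame(session = id, r2) else NULL
        }, error = function(e) note("reactivation", e))
      }
      list(sep = sep_df, dec = do.call(rbind, c(dec_df, cross_df)),
           ang = ang_df, beh = beh_df, rea = rea_df)
    }, error = function(e) conditionMessage(e))
    if (length(issues)) skipped[[paste0(id, ":partial")]] <- issues
    if (is.character(res)) {
      skipped[[id]] <- res
      next
    }
    sep_t[[id]] <- res$sep; dec_t[[id]] <- res$dec; ang_t[[id]] <- res$ang
    beh_t[[id]] <- res$beh; rea_t[[id]] <- res$rea
  }
  if (!length(sep_t))
    stop("all sessions failed: ",
         paste(names(skipped), unlist(skipped), sep = ": ", collapse = "; "),
         call. = FALSE)
  tables <- list(separability = do.call(rbind, sep_t),
                 decoding = do.call(rbind, dec_t),
                 angles = do.call(rbind, ang_t),
                 behavior = do.call(rbind, beh_t),
                 reactivation = if (length(rea_t)) do.call(rbind, rea_t) else NULL)
  for (nm in names(tables))
    if (!is.null(tables[[nm]])) rownames(tables[[nm]]) <- NULL

  tables$cohort <- cohort_tests(tables, alpha)
  tables$manifest <- list(
    package = "popsubspace",
    version = as.character(utils::packageVersion("popsubspace")),
    seed = seed, reps = reps, bin_s = bin_s, dims = dims,
    features = features, alpha = alpha,
    n_sessions = length(sep_t), skipped = skipped)
  if (!is.null(out_dir)) write_report(tables, out_dir)
  invisible(tables)
}

cohort_tests <- function(tables, alpha) {
  out <- list()
  dec <- tables$decoding
  if (is.null(dec)) dec <- data.frame(phase = character(0), feature = character(0))
  for (key in unique(paste(dec$phase, dec$feature))) {
    d <- dec[paste(dec$phase, dec$feature) == key, , drop = FALSE]
    if (nrow(d) < 2 || stats::sd(d$accuracy - d$null_mean) == 0) next
    wp <- suppressWarnings(
      stats::wilcox.test(d$accuracy, d$null_mean, paired = TRUE)$p.value)
    wz <- suppressWarnings(
      stats::wilcox.test(d$relative_accuracy, mu = 0)$p.value)
    out[[key]] <- data.frame(
      analysis = "decoding", group = key, n = nrow(d),
      mean_relative = mean(d$relative_accuracy),
      p_paired = wp, p_vs_zero = wz,
      signif = paste(alpha[wz < alpha], collapse = ","))
  }
  rea <- tables$reactivation
  if (!is.null(rea)) {
    for (key in unique(paste(rea$source, rea$feature, rea$value))) {
      r <- rea[paste(rea$source, rea$feature, rea$value) == key, , drop = FALSE]
      if (nrow(r) < 2 || stats::sd(r$statistic) == 0) next
      wz <- suppressWarnings(stats::wilcox.test(r$statistic, mu = 0)$p.value)
      out[[paste("rea", key)]] <- data.frame(
        analysis = "reactivation", group = key, n = nrow(r),
        mean_relative = mean(r$statistic), p_paired = NA_real_,
        p_vs_zero = wz, signif = paste(alpha[wz < alpha], collapse = ","))
    }
  }
  df <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  df
}

write_report <- function(tables, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  num_fmt <- function(df) {
    for (cc in names(df))
      if (is.numeric(df[[cc]])) df[[cc]] <- sprintf("%.10g", df[[cc]])
    df
  }
  for (nm in c("separability", "decoding", "angles", "behavior",
               "reactivation", "cohort")) {
    if (is.null(tables[[nm]])) next
    utils::write.table(num_fmt(tables[[nm]]),
                       file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(tables$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}
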