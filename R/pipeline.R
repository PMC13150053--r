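# cheap, dependency-free fingerprint of a configuration list
config_fingerprint <- function(config) {
  s <- paste(names(unlist(config)), format(unlist(config), digits = 15),
             collapse = ";")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 251)) %% 4294967291)
}

#' Preprocess one subject's recording into scored LRP latencies
#'
#' Runs the reduction chain in fixed order: mastoid re-reference,
#' band-pass, notch, segmentation of correct trials (stimulus- and
#' response-locked), ocular correction, baseline correction, four-rule
#' artifact rejection, then LRP derivation and onset scoring.
#'
#' @param recording An \code{\link{eeg_recording}}.
#' @param trials The subject's trial table.
#' @param filter Apply the band-pass and notch filters (default TRUE).
#' @param reject Apply artifact rejection (default TRUE).
#' @param reject_criteria Thresholds passed to
#'   \code{\link{reject_artifacts}}.
#' @param min_trials_per_hand Minimum retained correct trials per hand
#'   for a usable subject.
#' @return List: the \code{\link{score_subject}} output plus
#'   \code{s_rejection}/\code{r_rejection} reports and \code{usable};
#'   when unusable, \code{reason} says why.
#' @export
preprocess_and_score <- function(recording, trials, filter = TRUE,
                                 reject = TRUE,
                                 reject_criteria = list(),
                                 min_trials_per_hand = 20) {
  rec <- rereference(recording, c("M1", "M2"))
  if (filter) {
    rec <- bandpass_filter(rec, 0.1, 30, order = 2)
    rec <- notch_filter(rec, 60)
  }
  s_ep <- segment_epochs(rec, trials, "stimulus")
  r_ep <- segment_epochs(rec, trials, "response")
  s_ep <- ocular_correct(s_ep)
  r_ep <- ocular_correct(r_ep)
  s_ep <- baseline_correct(s_ep)
  r_ep <- baseline_correct(r_ep)
  s_rep <- r_rep <- NULL
  if (reject) {
    s_rj <- reject_artifacts(s_ep, criteria = reject_criteria)
    r_rj <- reject_artifacts(r_ep, criteria = reject_criteria)
    s_ep <- s_rj$epochs; r_ep <- r_rj$epochs
    s_rep <- s_rj$report; r_rep <- r_rj$report
  }
  hand_counts <- function(ep) {
    c(left = sum(ep$trial_meta$hand == "left"),
      right = sum(ep$trial_meta$hand == "right"))
  }
  hc <- pmin(hand_counts(s_ep), hand_counts(r_ep))
  if (any(hc < min_trials_per_hand)) {
    return(list(usable = FALSE,
                reason = sprintf(
                  "retained %d left / %d right trials; need %d per hand",
                  hc["left"], hc["right"], min_trials_per_hand),
                s_rejection = s_rep, r_rejection = r_rep))
  }
  score <- score_subject(s_ep, r_ep)
  c(score, list(usable = TRUE, reason = NA_character_,
                s_rejection = s_rep, r_rejection = r_rep))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' One call from simulation to inference: simulate subject ground truth
#' and trials, render and preprocess each subject's EEG, score S-LRP and
#' R-LRP latencies, clean the behavioral data, assemble and winsorize
#' the cohort table, compute the correlation matrix and commonality
#' decompositions, fit the dual-mediator path model, and estimate Monte
#' Carlo power for both indirect effects. Deterministic given the
#' config seed; every written artifact is stamped with the seed and a
#' configuration fingerprint.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param out_dir Optional directory; when given, writes
#'   \code{cohort.tsv}, \code{scores.tsv}, \code{summaries.tsv}, a
#'   \code{results.json} bundle, and (optionally) BrainVision triplets.
#' @param filter,reject Stage toggles, passed to
#'   \code{\link{preprocess_and_score}}.
#' @param reject_criteria Rejection thresholds override.
#' @param min_trials_per_hand Usability floor per response hand.
#' @param power_reps Replicates for the power stage (0 skips it).
#' @param write_eeg Also write each subject's BrainVision triplet
#'   (large; default FALSE).
#' @param verbose Print per-stage progress.
#' @return List: \code{subjects}, \code{trials}, \code{scores},
#'   \code{summaries}, \code{cohort} (the analysis table),
#'   \code{correlations}, \code{commonality_rt}, \code{commonality_age},
#'   \code{path_model}, \code{power}, \code{seed}, \code{fingerprint}.
#' @export
run_pipeline <- function(config, out_dir = NULL, filter = TRUE,
                         reject = TRUE, reject_criteria = list(),
                         min_trials_per_hand = 20, power_reps = 1000,
                         write_eeg = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  fp <- config_fingerprint(config)

  say("simulating %d subjects x %d trials (seed %d)",
      config$n_subjects, config$n_trials, config$seed)
  sim <- simulate_cohort(config)
  subjects <- sim$subjects; trials <- sim$trials

  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  say("rendering + preprocessing + scoring EEG")
  scores <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    sub <- subjects[i, ]
    tr <- trials[trials$subject_id == sub$subject_id, ]
    rec <- render_eeg(tr, sub, config)
    if (write_eeg && !is.null(out_dir))
      write_brainvision(rec, file.path(out_dir, sub$subject_id))
    res <- preprocess_and_score(rec, tr, filter = filter,
                                reject = reject,
                                reject_criteria = reject_criteria,
                                min_trials_per_hand = min_trials_per_hand)
    scores[[i]] <- data.frame(
      subject_id = sub$subject_id,
      usable = res$usable,
      s_lrp_ms = if (res$usable) res$s_latency_ms else NA_real_,
      r_lrp_ms = if (res$usable) res$r_latency_ms else NA_real_,
      s_peak_uv = if (res$usable) res$s_peak_uv else NA_real_,
      r_peak_uv = if (res$usable) res$r_peak_uv else NA_real_,
      frac_rejected = if (reject && !is.null(res$s_rejection))
        attr(res$s_rejection, "fraction_rejected") else 0,
      stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, scores)

  say("behavioral cleaning")
  cleaned <- clean_rts(trials)
  summaries <- summarize_subjects(cleaned$table, trials)
  thr <- as.numeric(binomial_chance_threshold(config$n_trials))
  summaries <- exclude_subjects(summaries, thr)

  cohort <- merge(merge(subjects, summaries, by = "subject_id"),
                  scores, by = "subject_id")
  cohort <- cohort[!cohort$excluded & cohort$usable &
                     !is.na(cohort$s_lrp_ms), ]
  say("cohort: %d of %d subjects usable", nrow(cohort), nrow(subjects))

  cohort$mean_rt_ms <- winsorize(cohort$mean_rt_ms)
  cohort$s_lrp_ms <- winsorize(cohort$s_lrp_ms)
  cohort$r_lrp_ms <- winsorize(cohort$r_lrp_ms)

  corrs <- commonality_rt <- commonality_age <- path_model <- power <- NULL
  if (nrow(cohort) >= 8) {
    corrs <- pearson_matrix(cohort[, c("age_years", "sex", "mean_rt_ms",
                                       "accuracy", "s_lrp_ms",
                                       "r_lrp_ms")])
    commonality_rt <- commonality_two_predictor(
      cohort$mean_rt_ms, cohort$s_lrp_ms, cohort$r_lrp_ms)
    commonality_age <- commonality_two_predictor(
      cohort$age_years, cohort$s_lrp_ms, cohort$r_lrp_ms)
    path_model <- fit_path_model(cohort)
    if (power_reps > 0) {
      pe <- path_model$paths$estimate
      names(pe) <- rownames(path_model$paths)
      power <- monte_carlo_power(
        list(a_S = pe["a_S"], a_R = pe["a_R"], b_S = pe["b_S"],
             b_R = pe["b_R"], c_direct = pe["c_direct"],
             rho_med = path_model$psi, beta_sex = pe["beta_sex"]),
        n = nrow(cohort), n_reps = power_reps,
        seed = config$seed + 1L)
    }
  } else {
    warning("fewer than 8 usable subjects; inference stages skipped")
  }

  result <- list(subjects = subjects, trials = trials, scores = scores,
                 summaries = summaries, cohort = cohort,
                 correlations = corrs,
                 commonality_rt = commonality_rt,
                 commonality_age = commonality_age,
                 path_model = path_model, power = power,
                 seed = config$seed, fingerprint = fp)

  if (!is.null(out_dir)) {
    wtsv <- function(d, f) utils::write.table(
      d, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wtsv(trials[, c("subject_id", "trial", "hand", "compatibility",
                    "correct", "rt_ms")], "trials.tsv")
    wtsv(scores, "scores.tsv")
    wtsv(summaries, "summaries.tsv")
    wtsv(cohort, "cohort.tsv")
    bundle <- list(seed = config$seed, fingerprint = fp,
                   n_usable = nrow(cohort))
    if (!is.null(path_model)) {
      bundle$paths <- as.list(path_model$paths$estimate)
      names(bundle$paths) <- rownames(path_model$paths)
      bundle$psi <- path_model$psi
      bundle$indirect_S <- path_model$indirect_S$estimate
      bundle$indirect_R <- path_model$indirect_R$estimate
      bundle$total <- path_model$total$estimate
      bundle$fit <- path_model$fit
    }
    if (!is.null(power)) {
      bundle$power_S <- power$power_S
      bundle$power_R <- power$power_R
    }
    jsonlite::write_json(bundle, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
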