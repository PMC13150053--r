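#' Clean reaction times per subject
#'
#' Removal order, per subject: (1) error trials; (2) anticipations with
#' RT below \code{fast_cutoff} ms; (3) slow outliers with RT at or above
#' the subject's mean plus \code{sd_cutoff} standard deviations, where
#' mean and SD are computed once on the trials surviving steps 1-2 (no
#' re-iteration) and the fence is upper-tail only. When the surviving
#' RTs have zero spread the SD fence is vacuous and removes nothing.
#'
#' @param table Trial table with \code{subject_id}, \code{rt_ms},
#'   \code{correct}.
#' @param fast_cutoff Fast cutoff, ms.
#' @param sd_cutoff SD multiplier for the slow fence.
#' @return List with \code{table} (retained trials) and \code{report}
#'   (per subject: counts removed per rule, n retained, and a flag for
#'   subjects left with fewer than 2 trials).
#' @export
clean_rts <- function(table, fast_cutoff = 100, sd_cutoff = 3) {
  stopifnot(all(c("subject_id", "rt_ms", "correct") %in% names(table)))
  keep <- logical(nrow(table))
  ids <- unique(table$subject_id)
  rep_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- which(table$subject_id == ids[i])
    sub <- table[rows, ]
    ok <- sub$correct                        # (1) errors out
    n_err <- sum(!ok)
    fast <- ok & sub$rt_ms < fast_cutoff     # (2) anticipations
    n_fast <- sum(fast)
    ok <- ok & !fast
    n_slow <- 0L
    if (sum(ok) > 1) {
      m <- mean(sub$rt_ms[ok]); s <- stats::sd(sub$rt_ms[ok])
      if (s > 0) {                           # (3) upper fence, one pass
        slow <- ok & sub$rt_ms >= m + sd_cutoff * s
        n_slow <- sum(slow)
        ok <- ok & !slow
      }
    }
    keep[rows] <- ok
    rep_rows[[i]] <- data.frame(subject_id = ids[i],
                                n_error = n_err, n_fast = n_fast,
                                n_slow = n_slow, n_retained = sum(ok),
                                too_few = sum(ok) < 2,
                                stringsAsFactors = FALSE)
  }
  list(table = table[keep, , drop = FALSE],
       report = do.call(rbind, rep_rows))
}

#' Summarize subjects after cleaning
#'
#' Mean RT is taken over the retained correct trials; accuracy is the
#' number of correct responses divided by all administered trials (the
#' pre-cleaning denominator). Subjects with no retained trials are
#' flagged excluded with reason \code{"no_trials"}.
#'
#' @param clean_table Retained trials from \code{\link{clean_rts}}.
#' @param full_table The original (pre-cleaning) trial table.
#' @return Data frame: \code{subject_id}, \code{mean_rt_ms},
#'   \code{accuracy}, \code{n_retained}, \code{excluded}, \code{reason}.
#' @export
summarize_subjects <- function(clean_table, full_table) {
  ids <- unique(full_table$subject_id)
  out <- lapply(ids, function(id) {
    all_sub <- full_table[full_table$subject_id == id, ]
    ret <- clean_table[clean_table$subject_id == id, ]
    acc <- mean(all_sub$correct)
    if (nrow(ret) == 0)
      data.frame(subject_id = id, mean_rt_ms = NA_real_, accuracy = acc,
                 n_retained = 0L, excluded = TRUE, reason = "no_trials",
                 stringsAsFactors = FALSE)
    else
      data.frame(subject_id = id, mean_rt_ms = mean(ret$rt_ms),
                 accuracy = acc, n_retained = nrow(ret),
                 excluded = FALSE, reason = NA_character_,
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Exact binomial threshold for above-chance accuracy
#'
#' Smallest accuracy proportion k*/n such that the exact upper binomial
#' tail P(X >= k*) under chance responding is at or below \code{alpha}.
#'
#' @param n_trials Number of trials.
#' @param p_chance Chance success probability.
#' @param alpha Significance level.
#' @return The minimal passing accuracy proportion (k*/n), with the
#'   integer count as attribute \code{"k"}.
#' @export
#' @examples
#' binomial_chance_threshold(300, 0.5, 0.01)  # 0.57 (171/300)
binomial_chance_threshold <- function(n_trials, p_chance = 0.5,
                                      alpha = 0.01) {
  stopifnot(n_trials > 0, alpha > 0, alpha < 1,
            p_chance > 0, p_chance < 1)
  ks <- 0:n_trials
  tail <- stats::pbinom(ks - 1, n_trials, p_chance, lower.tail = FALSE)
  k_star <- ks[which(tail <= alpha)[1]]
  structure(k_star / n_trials, k = k_star)
}

#' Flag subjects below the chance-performance criterion
#'
#' @param summaries Output of \code{\link{summarize_subjects}}.
#' @param threshold Minimal passing accuracy (the threshold value itself
#'   passes); defaults to the exact binomial threshold at alpha = 0.01
#'   for the modal trial count.
#' @return The summaries with \code{excluded}/\code{reason} updated.
#' @export
exclude_subjects <- function(summaries, threshold = NULL) {
  if (is.null(threshold)) {
    n_admin <- 300L
    threshold <- as.numeric(binomial_chance_threshold(n_admin))
  }
  low <- !summaries$excluded & summaries$accuracy < threshold
  summaries$excluded[low] <- TRUE
  summaries$reason[low] <- "below_chance"
  summaries
}

#' Winsorize outlying values to the furthest non-outlying value
#'
#' Values at or beyond \code{k_sd} standard deviations from the sample
#' mean (mean and SD of the original vector, single pass, two-sided) are
#' replaced by the most extreme value on the same side that is not
#' outlying. Length and order are preserved; a zero-SD vector is
#' returned unchanged.
#'
#' @param values Numeric vector.
#' @param k_sd SD multiplier for the fences.
#' @return The winsorized vector.
#' @export
winsorize <- function(values, k_sd = 3) {
  m <- mean(values); s <- stats::sd(values)
  if (is.na(s) || s == 0) return(values)
  out <- abs(values - m) >= k_sd * s
  if (!any(out) || all(out)) return(values)
  inside <- values[!out]
  hi <- out & values > m
  lo <- out & values < m
  values[hi] <- max(inside)
  values[lo] <- min(inside)
  values
}
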