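#' Re-reference a recording to the average of two mastoids
#'
#' Subtracts the samplewise mean of the two reference channels from every
#' other channel; the reference channels themselves are retained
#' unmodified.
#'
#' @param recording An \code{\link{eeg_recording}}.
#' @param reference_labels Labels of the two mastoid channels.
#' @return The re-referenced recording.
#' @export
rereference <- function(recording, reference_labels = c("M1", "M2")) {
  stopifnot(inherits(recording, "eeg_recording"))
  missing <- setdiff(reference_labels, recording$channel_labels)
  if (length(missing) > 0)
    stop("reference channel not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ref <- colMeans(recording$data[reference_labels, , drop = FALSE])
  others <- setdiff(recording$channel_labels, reference_labels)
  recording$data[others, ] <-
    sweep(recording$data[others, , drop = FALSE], 2, ref)
  recording
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass of the given design order in a
#' forward-backward (zero-phase) pass to every channel, so the effective
#' attenuation is the squared magnitude response and group delay is nil.
#'
#' @param recording An \code{\link{eeg_recording}}.
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Filter design order (the bidirectional pass doubles the
#'   effective order).
#' @return The filtered recording.
#' @export
bandpass_filter <- function(recording, low_hz = 0.1, high_hz = 30,
                            order = 2) {
  stopifnot(inherits(recording, "eeg_recording"))
  nyq <- recording$sampling_rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist", call. = FALSE)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  for (i in seq_len(nrow(recording$data)))
    recording$data[i, ] <- signal::filtfilt(bf, recording$data[i, ])
  recording
}

# RBJ biquad notch design: unit gain away from f0, zero at f0
design_notch <- function(freq_hz, fs, Q = 30) {
  w0 <- 2 * pi * freq_hz / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Zero-phase IIR notch filter
#'
#' Second-order (biquad) notch applied forward-backward. The default
#' quality factor 30 gives a ~2 Hz wide notch at 60 Hz, sparing the 30 Hz
#' band-pass edge.
#'
#' @param recording An \code{\link{eeg_recording}}.
#' @param freq_hz Notch center frequency in Hz.
#' @param Q Quality factor (center frequency / -3 dB bandwidth).
#' @return The filtered recording.
#' @export
notch_filter <- function(recording, freq_hz = 60, Q = 30) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (freq_hz >= recording$sampling_rate / 2)
    stop("notch frequency must lie below Nyquist", call. = FALSE)
  flt <- design_notch(freq_hz, recording$sampling_rate, Q)
  for (i in seq_len(nrow(recording$data)))
    recording$data[i, ] <- signal::filtfilt(
      signal::Arma(b = flt$b, a = flt$a), recording$data[i, ])
  recording
}

#' Segment a recording into stimulus- or response-locked epochs
#'
#' Cuts one epoch per correct trial around the requested marker kind.
#' Incorrect trials are excluded before segmentation. Time-to-sample
#' conversion rounds half away from zero and the window is half-open
#' \code{[start, end)}, so an 800 ms window at 500 Hz is exactly 400
#' samples. Epochs that would overlap a recording edge are dropped and
#' counted in a warning.
#'
#' @param recording An \code{\link{eeg_recording}}.
#' @param trial_table Data frame with at least \code{trial} and
#'   \code{correct} columns (plus any metadata to carry along).
#' @param lock \code{"stimulus"} or \code{"response"}.
#' @param window_ms Two-element window relative to the lock event, ms.
#' @param baseline_ms Two-element baseline interval, ms (stored; applied
#'   by \code{\link{baseline_correct}}).
#' @return An object of class \code{epoch_set}: trials x channels x
#'   samples array plus metadata.
#' @export
segment_epochs <- function(recording, trial_table,
                           lock = c("stimulus", "response"),
                           window_ms = if (match.arg(lock) == "stimulus")
                             c(-200, 600) else c(-1000, 200),
                           baseline_ms = if (match.arg(lock) == "stimulus")
                             c(-200, 0) else c(-1000, -800)) {
  stopifnot(inherits(recording, "eeg_recording"))
  lock <- match.arg(lock)
  fs <- recording$sampling_rate
  mk <- recording$markers
  sel <- if (lock == "stimulus") mk$kind == "stimulus"
         else mk$kind %in% c("response_left", "response_right")
  mk <- mk[sel, , drop = FALSE]
  if (nrow(mk) == 0)
    stop("no markers of kind '", lock, "' in recording", call. = FALSE)

  correct_trials <- trial_table$trial[trial_table$correct]
  mk <- mk[mk$trial %in% correct_trials, , drop = FALSE]
  if (nrow(mk) == 0) {
    warning("no correct trials to segment; returning empty epoch set")
    empty <- array(numeric(0),
                   dim = c(0, nrow(recording$data), 0))
    return(structure(list(data = empty, time_ms = numeric(0), lock = lock,
                          window_ms = window_ms, baseline_ms = baseline_ms,
                          sampling_rate = fs,
                          channel_labels = recording$channel_labels,
                          trial_meta = trial_table[0, , drop = FALSE],
                          n_dropped_edges = 0L),
                     class = "epoch_set"))
  }

  a <- ms_to_samples(window_ms[1], fs)
  b <- ms_to_samples(window_ms[2], fs) - 1L   # half-open [start, end)
  nsmp <- b - a + 1L
  total <- ncol(recording$data)
  first <- mk$sample + a
  last <- mk$sample + b
  ok <- first >= 1L & last <= total
  dropped <- sum(!ok)
  if (dropped > 0)
    warning(sprintf("%d epoch(s) overlap the recording edges; dropped",
                    dropped))
  mk <- mk[ok, , drop = FALSE]

  nchan <- nrow(recording$data)
  dat <- array(NA_real_, dim = c(nrow(mk), nchan, nsmp))
  for (i in seq_len(nrow(mk))) {
    idx <- (mk$sample[i] + a):(mk$sample[i] + b)
    dat[i, , ] <- recording$data[, idx]
  }
  meta <- trial_table[match(mk$trial, trial_table$trial), , drop = FALSE]
  rownames(meta) <- NULL

  structure(list(data = dat,
                 time_ms = (a:b) / fs * 1000,
                 lock = lock,
                 window_ms = window_ms,
                 baseline_ms = baseline_ms,
                 sampling_rate = fs,
                 channel_labels = recording$channel_labels,
                 trial_meta = meta,
                 n_dropped_edges = dropped),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("%s-locked epochs: %d trials x %d channels x %d samples @ %g Hz\n",
              x$lock, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$sampling_rate))
  cat(sprintf("  window [%g, %g) ms, baseline [%g, %g] ms\n",
              x$window_ms[1], x$window_ms[2],
              x$baseline_ms[1], x$baseline_ms[2]))
  invisible(x)
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per trial and channel, the mean over the baseline interval.
#'
#' @param epochs An \code{epoch_set}.
#' @param baseline_ms Baseline interval; defaults to the one stored at
#'   segmentation.
#' @return The corrected epoch set.
#' @export
baseline_correct <- function(epochs, baseline_ms = epochs$baseline_ms) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (dim(epochs$data)[1] == 0) return(epochs)
  bsel <- epochs$time_ms >= baseline_ms[1] & epochs$time_ms < baseline_ms[2]
  if (!any(bsel))
    stop("baseline interval lies outside the epoch window", call. = FALSE)
  bl <- apply(epochs$data[, , bsel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - array(bl, dim = dim(epochs$data))
  epochs
}

#' Regression-based ocular artifact correction
#'
#' Estimates EOG-to-EEG propagation factors on event-related-average
#' subtracted data, then removes the scaled raw EOG from the raw EEG:
#' (1) the per-condition average (conditions formed from hand and, when
#' present, compatibility) is subtracted from every trial, for EEG and EOG
#' alike, so event-related activity cannot leak into the factors;
#' (2) per EEG channel, the residual EEG is regressed on residual VEOG and
#' HEOG pooled over trials and samples; (3) \code{factor x raw EOG} is
#' subtracted from the raw EEG. The averages are used only for estimation.
#'
#' @param epochs An \code{epoch_set} containing the EOG channels.
#' @param veog_label,heog_label Names of the ocular channels.
#' @return The corrected epoch set, with the estimated factors attached as
#'   attribute \code{"propagation"} (channels x 2 matrix).
#' @export
ocular_correct <- function(epochs, veog_label = "VEOG",
                           heog_label = "HEOG") {
  stopifnot(inherits(epochs, "epoch_set"))
  labs <- epochs$channel_labels
  for (l in c(veog_label, heog_label))
    if (!l %in% labs)
      stop("EOG channel not found: ", l, call. = FALSE)
  n_tr <- dim(epochs$data)[1]
  if (n_tr == 0) return(epochs)
  iv <- match(veog_label, labs); ih <- match(heog_label, labs)
  eeg_idx <- setdiff(seq_along(labs), c(iv, ih))

  meta <- epochs$trial_meta
  cond <- if (!is.null(meta$hand) && !is.null(meta$compatibility))
    interaction(meta$hand, meta$compatibility, drop = TRUE)
  else if (!is.null(meta$hand)) factor(meta$hand)
  else factor(rep(1L, n_tr))

  resid <- epochs$data
  for (lev in levels(cond)) {
    tr <- which(cond == lev)
    avg <- apply(epochs$data[tr, , , drop = FALSE], c(2, 3), mean)
    resid[tr, , ] <- sweep(epochs$data[tr, , , drop = FALSE],
                           c(2, 3), avg)
  }

  rv <- as.vector(resid[, iv, ]); rh <- as.vector(resid[, ih, ])
  X <- cbind(rv, rh)
  keepcol <- apply(X, 2, stats::sd) > 0
  prop <- matrix(0, length(eeg_idx), 2,
                 dimnames = list(labs[eeg_idx], c("VEOG", "HEOG")))
  if (!all(keepcol))
    warning("zero-variance EOG channel; its propagation factor set to 0")
  if (any(keepcol)) {
    Xk <- X[, keepcol, drop = FALSE]
    XtX <- crossprod(Xk)
    for (j in seq_along(eeg_idx)) {
      y <- as.vector(resid[, eeg_idx[j], ])
      prop[j, keepcol] <- solve(XtX, crossprod(Xk, y))
    }
  }
  for (j in seq_along(eeg_idx)) {
    epochs$data[, eeg_idx[j], ] <- epochs$data[, eeg_idx[j], ] -
      prop[j, 1] * epochs$data[, iv, ] - prop[j, 2] * epochs$data[, ih, ]
  }
  attr(epochs, "propagation") <- prop
  epochs
}

# moving-window range (max - min) over windows of w samples;
# pmax/pmin over the lagged columns beats apply() by an order of magnitude
roll_range <- function(x, w) {
  n <- length(x)
  if (n < w) return(max(x) - min(x))
  lags <- lapply(seq_len(w), function(k) x[k:(n - w + k)])
  do.call(pmax, lags) - do.call(pmin, lags)
}

#' Four-rule artifact rejection
#'
#' Flags a trial when any scanned channel violates any of:
#' (1) absolute voltage above \code{abs_uv} at any sample;
#' (2) peak-to-peak range above \code{p2p_uv} within a moving 100-ms
#' window; (3) an adjacent-sample step above \code{step_uv_ms}
#' (expressed in microvolts per millisecond); (4) low activity, range
#' below \code{flat_uv} within a moving 100-ms window. Windows advance one
#' sample at a time. Flagged trials are removed from the returned set.
#'
#' @param epochs An \code{epoch_set}.
#' @param criteria Named list of thresholds: \code{abs_uv} (100),
#'   \code{p2p_uv} (175), \code{step_uv_ms} (30), \code{flat_uv} (0.5).
#'   Set an entry to \code{NA} to disable that rule.
#' @param channels Channels to scan; default all channels except VEOG and
#'   HEOG.
#' @param window_ms Moving-window width for rules (2) and (4).
#' @return List with \code{epochs} (retained trials) and \code{report}
#'   (per-trial flag, first criterion fired, channel, and the rejected
#'   fraction as attribute \code{"fraction_rejected"}).
#' @export
reject_artifacts <- function(epochs,
                             criteria = list(abs_uv = 100, p2p_uv = 175,
                                             step_uv_ms = 30,
                                             flat_uv = 0.5),
                             channels = NULL,
                             window_ms = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  defaults <- list(abs_uv = 100, p2p_uv = 175, step_uv_ms = 30,
                   flat_uv = 0.5)
  defaults[names(criteria)] <- criteria
  criteria <- defaults
  fs <- epochs$sampling_rate
  w <- max(2L, as.integer(round_half_up(window_ms * fs / 1000)))
  if (dim(epochs$data)[3] < w)
    stop("epochs shorter than the moving window", call. = FALSE)
  if (is.null(channels))
    channels <- setdiff(epochs$channel_labels, c("VEOG", "HEOG"))
  chan_idx <- match(channels, epochs$channel_labels)
  if (anyNA(chan_idx))
    stop("unknown channel in 'channels'", call. = FALSE)

  n_tr <- dim(epochs$data)[1]
  crit <- rep("none", n_tr)
  chan_hit <- rep(NA_character_, n_tr)
  step_thr <- if (is.na(criteria$step_uv_ms)) NA else
    criteria$step_uv_ms * 1000 / fs    # uV per sample
  for (i in seq_len(n_tr)) {
    for (k in seq_along(chan_idx)) {
      x <- epochs$data[i, chan_idx[k], ]
      hit <- if (!is.na(criteria$abs_uv) &&
                 any(abs(x) > criteria$abs_uv)) "abs_amp"
      else {
        rr <- roll_range(x, w)
        if (!is.na(criteria$p2p_uv) && any(rr > criteria$p2p_uv)) "p2p"
        else if (!is.na(step_thr) && any(abs(diff(x)) > step_thr)) "step"
        else if (!is.na(criteria$flat_uv) &&
                 any(rr < criteria$flat_uv)) "low_activity"
        else NULL
      }
      if (!is.null(hit)) {
        crit[i] <- hit
        chan_hit[i] <- channels[k]
        break
      }
    }
  }
  flagged <- crit != "none"
  report <- data.frame(trial = if (!is.null(epochs$trial_meta$trial))
                         epochs$trial_meta$trial else seq_len(n_tr),
                       rejected = flagged,
                       criterion = crit,
                       channel = chan_hit,
                       stringsAsFactors = FALSE)
  attr(report, "fraction_rejected") <- mean(flagged)

  keep <- which(!flagged)
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$trial_meta <- epochs$trial_meta[keep, , drop = FALSE]
  rownames(epochs$trial_meta) <- NULL
  list(epochs = epochs, report = report)
}
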