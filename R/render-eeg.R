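#' Constructor for a continuous EEG recording
#'
#' @param data Numeric matrix, channels x samples, microvolts.
#' @param channel_labels Character vector, one label per row of \code{data}.
#' @param sampling_rate Sampling rate in Hz.
#' @param markers Data frame with columns \code{sample} (1-based sample
#'   index), \code{kind} (\code{"stimulus"}, \code{"response_left"},
#'   \code{"response_right"}) and \code{trial}.
#' @return An \code{eeg_recording} object.
#' @export
eeg_recording <- function(data, channel_labels, sampling_rate, markers) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_labels),
            sampling_rate > 0)
  if (nrow(markers) > 1 && any(diff(markers$sample) <= 0))
    stop("marker sample indices must be strictly increasing", call. = FALSE)
  structure(list(data = data,
                 channel_labels = as.character(channel_labels),
                 sampling_rate = sampling_rate,
                 markers = markers),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s), %d markers\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate, nrow(x$markers)))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

# band-limited (low-passed) Gaussian noise, scaled back to the target sd
bandlimited_noise <- function(n, sd, fs, cutoff = 30) {
  if (sd <= 0 || n == 0) return(numeric(n))
  w <- stats::rnorm(n)
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  y <- signal::filtfilt(bf, w)
  y * sd / stats::sd(y)
}

# raised-cosine blink template, width_ms wide, unit peak
blink_template <- function(width_ms, fs) {
  n <- max(3L, round(width_ms * fs / 1000))
  0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n)))
}

#' Render a synthetic continuous EEG recording for one subject
#'
#' Inverts the LRP double subtraction: on each trial a lateralized ramp
#' begins \code{premotor_ms} after the stimulus marker, peaks at the
#' response marker with half the configured LRP amplitude per channel
#' (opposite signs on C3 and C4, contralateral negative), then decays
#' linearly over 300 ms. A hand-independent bilateral stimulus-evoked
#' component and band-limited Gaussian noise are superimposed identically
#' or independently per channel; mastoids carry reference noise; VEOG and
#' HEOG carry raised-cosine blink templates that propagate to the scalp
#' channels with fixed factors (0.15 VEOG, 0.08 HEOG to C3/C4) so that
#' regression-based ocular correction has something real to estimate.
#' Stimulus onset asynchrony is 250 ms stimulus duration plus an
#' inter-trial interval drawn from \{1080, 1100, 1130\} ms.
#'
#' @param trials Trial table from \code{\link{simulate_trials}}.
#' @param subject The matching row from \code{\link{simulate_subjects}}.
#' @param config A \code{\link{cohort_config}}.
#' @param seed Optional integer; defaults to a stream derived from the
#'   config seed and subject index.
#' @return An \code{\link{eeg_recording}} with channels
#'   C3, C4, M1, M2, VEOG, HEOG.
#' @export
render_eeg <- function(trials, subject, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!all(c("premotor_ms", "motor_ms", "rt_ms") %in% names(trials)))
    stop("trials must carry premotor/motor durations", call. = FALSE)
  fs <- config$sampling_rate
  if (fs < 100)
    stop("sampling rate too low to place sub-sample onsets", call. = FALSE)
  if (is.null(seed)) {
    idx <- as.integer(sub("^S", "", subject$subject_id))
    seed <- (config$seed + 20011L * idx) %% .Machine$integer.max
  }
  set.seed(seed)

  n_tr <- nrow(trials)
  ms2smp <- function(ms) as.integer(round_half_up(ms * fs / 1000))

  iti <- sample(c(1080, 1100, 1130), n_tr, replace = TRUE)
  # stimulus onsets: 250 ms stimulus duration + ITI between trials
  stim_ms <- 1500 + cumsum(c(0, (250 + iti)[-n_tr]))
  resp_ms <- stim_ms + trials$rt_ms
  total_samples <- ms2smp(resp_ms[n_tr] + 1500)

  chans <- c("C3", "C4", "M1", "M2", "VEOG", "HEOG")
  dat <- matrix(0, length(chans), total_samples,
                dimnames = list(chans, NULL))

  t_ms <- (seq_len(total_samples) - 1) / fs * 1000
  lat <- numeric(total_samples)    # lateralized component (C3 +, C4 -)
  bil <- numeric(total_samples)    # bilateral component

  # the double subtraction sums four half-waves, so a per-channel
  # deflection of A/4 yields a derived LRP of amplitude A
  half <- config$lrp_amplitude / 4
  decay_ms <- 300
  for (k in seq_len(n_tr)) {
    onset <- stim_ms[k] + trials$premotor_ms[k]
    peak <- resp_ms[k]
    i0 <- ms2smp(onset) + 1L; i1 <- ms2smp(peak) + 1L
    i2 <- min(ms2smp(peak + decay_ms) + 1L, total_samples)
    sgn <- if (trials$hand[k] == "left") 1 else -1
    if (i1 > i0) {
      ramp <- seq(0, 1, length.out = i1 - i0 + 1L)
      lat[i0:i1] <- lat[i0:i1] + sgn * half * ramp
    }
    if (i2 > i1) {
      fall <- seq(1, 0, length.out = i2 - i1 + 1L)
      ii <- (i1 + 1L):i2
      lat[ii] <- lat[ii] + sgn * half * fall[-1]
    }
    # bilateral stimulus-evoked bump, identical over both motor sites
    j0 <- ms2smp(stim_ms[k]) + 1L
    j1 <- min(ms2smp(stim_ms[k] + 600) + 1L, total_samples)
    tt <- t_ms[j0:j1] - stim_ms[k]
    bil[j0:j1] <- bil[j0:j1] + 5 * exp(-0.5 * ((tt - 300) / 80)^2)
  }

  dat["C3", ] <- lat + bil
  dat["C4", ] <- -lat + bil
  if (config$eeg_noise_sd > 0) {
    for (ch in c("C3", "C4", "M1", "M2"))
      dat[ch, ] <- dat[ch, ] +
        bandlimited_noise(total_samples, config$eeg_noise_sd, fs)
  }

  # ocular channels: blinks plus a little measurement noise
  if (config$blink_rate > 0) {
    n_blinks <- stats::rpois(1, config$blink_rate * total_samples / fs)
    if (n_blinks > 0) {
      tpl <- blink_template(200, fs)
      starts <- sort(sample.int(max(1L, total_samples - length(tpl)),
                                n_blinks, replace = TRUE))
      for (s in starts) {
        ii <- s:(s + length(tpl) - 1L)
        dat["VEOG", ii] <- dat["VEOG", ii] + 150 * tpl
        dat["HEOG", ii] <- dat["HEOG", ii] + 40 * tpl
      }
    }
  }
  if (config$eeg_noise_sd > 0) {
    dat["VEOG", ] <- dat["VEOG", ] +
      bandlimited_noise(total_samples, config$eeg_noise_sd / 2, fs)
    dat["HEOG", ] <- dat["HEOG", ] +
      bandlimited_noise(total_samples, config$eeg_noise_sd / 2, fs)
  }
  # fixed scalp propagation of ocular activity
  dat["C3", ] <- dat["C3", ] + 0.15 * dat["VEOG", ] + 0.08 * dat["HEOG", ]
  dat["C4", ] <- dat["C4", ] + 0.15 * dat["VEOG", ] - 0.08 * dat["HEOG", ]

  # markers: pressed hand equals instructed hand on correct trials,
  # the opposite hand on errors
  pressed <- ifelse(trials$correct, trials$hand,
                    ifelse(trials$hand == "left", "right", "left"))
  markers <- rbind(
    data.frame(sample = ms2smp(stim_ms) + 1L, kind = "stimulus",
               trial = trials$trial),
    data.frame(sample = ms2smp(resp_ms) + 1L,
               kind = paste0("response_", pressed),
               trial = trials$trial))
  markers <- markers[order(markers$sample), ]
  rownames(markers) <- NULL

  eeg_recording(dat, chans, fs, markers)
}

#' Inject constructed artifact exemplars into a recording
#'
#' Plants minimal offenders for the four rejection rules into the
#' stimulus-locked epoch windows of randomly chosen distinct trials:
#' \describe{
#'   \item{abs}{a single excursion beyond +/-100 microvolts}
#'   \item{p2p}{a peak-to-peak swing above 175 microvolts inside 100 ms}
#'   \item{step}{an adjacent-sample step above 30 microvolts/ms}
#'   \item{flat}{a 150-ms span clamped constant (range below 0.5 microvolts)}
#' }
#'
#' @param recording An \code{\link{eeg_recording}}.
#' @param artifact_spec Data frame with columns \code{class} (one of
#'   \code{"abs"}, \code{"p2p"}, \code{"step"}, \code{"flat"}),
#'   \code{count}, and optionally \code{channel} (default \code{"C3"}).
#' @param seed Integer seed for trial selection.
#' @param window_ms Epoch window (relative to stimulus) inside which the
#'   offender is placed; default \code{c(-200, 600)}.
#' @return List with elements \code{recording} (modified) and
#'   \code{injected} (data frame: trial, class, channel).
#' @export
inject_artifacts <- function(recording, artifact_spec, seed = 1L,
                             window_ms = c(-200, 600)) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (is.null(artifact_spec$channel)) artifact_spec$channel <- "C3"
  set.seed(seed)
  fs <- recording$sampling_rate
  stim <- recording$markers[recording$markers$kind == "stimulus", ]
  n_need <- sum(artifact_spec$count)
  if (n_need > nrow(stim))
    stop("more artifacts requested than trials available", call. = FALSE)
  victims <- sample(stim$trial, n_need)
  dat <- recording$data
  out <- vector("list", n_need)
  pos <- 1L
  for (r in seq_len(nrow(artifact_spec))) {
    cls <- artifact_spec$class[r]
    ch <- artifact_spec$channel[r]
    if (!ch %in% recording$channel_labels)
      stop("unknown channel: ", ch, call. = FALSE)
    for (j in seq_len(artifact_spec$count[r])) {
      tr <- victims[pos]
      m <- stim$sample[stim$trial == tr]
      # place the offender in the middle of the epoch window
      a <- m + round_half_up(window_ms[1] * fs / 1000)
      b <- m + round_half_up(window_ms[2] * fs / 1000) - 1L
      mid <- (a + b) %/% 2L
      w100 <- max(3L, round(100 * fs / 1000))
      if (cls == "abs") {
        dat[ch, mid] <- 120
      } else if (cls == "p2p") {
        # +/-90 uV swing well inside one 100-ms window, gentle slope,
        # |amplitude| < 100: fires (2) but neither (1) nor (3)
        k <- max(3L, w100 %/% 3L)
        v <- c(seq(0, 90, length.out = k), seq(90, -90, length.out = k),
               seq(-90, 0, length.out = k))
        ii <- mid:(mid + length(v) - 1L)
        dat[ch, ii] <- dat[ch, ii] + v
      } else if (cls == "step") {
        # sustained offset: adjacent samples differ by 35 uV/ms, but the
        # absolute level stays below the 100 uV rule at typical rates
        jump <- 35 * (1000 / fs)
        dat[ch, mid:(mid + 10L)] <- dat[ch, mid:(mid + 10L)] + jump
      } else if (cls == "flat") {
        span <- mid:(mid + round(150 * fs / 1000))
        # clamp relative to the mastoid mean where present, so the span
        # stays flat after average-mastoid re-referencing
        refs <- intersect(c("M1", "M2"), recording$channel_labels)
        refm <- if (length(refs) > 0)
          colMeans(dat[refs, span, drop = FALSE]) else 0
        dat[ch, span] <- dat[ch, span[1]] + refm - refm[1]
      } else stop("unknown artifact class: ", cls, call. = FALSE)
      out[[pos]] <- data.frame(trial = tr, class = cls, channel = ch)
      pos <- pos + 1L
    }
  }
  recording$data <- dat
  list(recording = recording, injected = do.call(rbind, out))
}
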