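#' Derive the lateralized readiness potential by double subtraction
#'
#' Computes the mean C3 - C4 difference over left-hand trials minus the
#' mean C3 - C4 difference over right-hand trials, using the retained
#' (correct, artifact-free) trials of the epoch set. With this subtraction
#' order the contralateral motor negativity yields a positive-going LRP,
#' so peaks are maxima. Any activity common to both channels or both
#' hands cancels exactly.
#'
#' @param epochs An \code{epoch_set} whose \code{trial_meta} carries a
#'   \code{hand} column.
#' @param channel_left,channel_right Channel labels over left and right
#'   motor cortex.
#' @return An object of class \code{lrp_waveform}: \code{time_ms},
#'   \code{amplitude_uv}, lock, and the left/right trial counts.
#' @export
derive_lrp <- function(epochs, channel_left = "C3", channel_right = "C4") {
  stopifnot(inherits(epochs, "epoch_set"))
  il <- match(channel_left, epochs$channel_labels)
  ir <- match(channel_right, epochs$channel_labels)
  if (anyNA(c(il, ir)))
    stop("LRP channels not found in epoch set", call. = FALSE)
  hand <- epochs$trial_meta$hand
  nl <- sum(hand == "left"); nr <- sum(hand == "right")
  if (nl == 0 || nr == 0)
    stop("need retained trials for both hands (left: ", nl,
         ", right: ", nr, ")", call. = FALSE)
  diffw <- epochs$data[, il, ] - epochs$data[, ir, ]
  left_avg <- colMeans(diffw[hand == "left", , drop = FALSE])
  right_avg <- colMeans(diffw[hand == "right", , drop = FALSE])
  structure(list(time_ms = epochs$time_ms,
                 amplitude_uv = left_avg - right_avg,
                 lock = epochs$lock,
                 n_left_trials = nl,
                 n_right_trials = nr),
            class = "lrp_waveform")
}

#' @export
print.lrp_waveform <- function(x, ...) {
  cat(sprintf("%s-locked LRP: [%g, %g] ms, %d left / %d right trials, peak %.2f uV\n",
              x$lock, min(x$time_ms), max(x$time_ms),
              x$n_left_trials, x$n_right_trials, max(x$amplitude_uv)))
  invisible(x)
}

#' Find the LRP peak inside a latency window
#'
#' Returns the extremum of the configured polarity inside the closed
#' window; ties are broken by the earliest time point.
#'
#' @param waveform An \code{lrp_waveform} (or any list with
#'   \code{time_ms} and \code{amplitude_uv}).
#' @param window_ms Closed search window, ms.
#' @param polarity \code{"positive"} (maxima; the default under this
#'   package's subtraction order) or \code{"negative"}.
#' @return List with \code{peak_ms} and \code{peak_uv}.
#' @export
find_peak <- function(waveform, window_ms,
                      polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  sel <- which(waveform$time_ms >= window_ms[1] &
               waveform$time_ms <= window_ms[2])
  if (length(sel) == 0)
    stop("peak window contains no samples", call. = FALSE)
  amp <- waveform$amplitude_uv[sel]
  i <- if (polarity == "positive") which.max(amp) else which.min(amp)
  # which.max already returns the first (earliest) index on ties
  list(peak_ms = waveform$time_ms[sel[i]], peak_uv = amp[i])
}

#' Segmented-regression onset latency estimate
#'
#' Fits, for every candidate breakpoint tau on the sample grid, the
#' continuous piecewise model \code{y(t) = c} for \code{t <= tau} and
#' \code{y(t) = c + s (t - tau)} for \code{t > tau} by least squares over
#' the search interval, and returns the tau minimizing the residual sum
#' of squares (ties broken by the earliest tau). The pre-onset segment is
#' a flat line (slope fixed at zero) sharing its level with the rising
#' segment, so the breakpoint is the only structural parameter beyond the
#' two line coefficients.
#'
#' @param waveform An \code{lrp_waveform}-like list.
#' @param interval_ms Search interval \code{[start, peak]}, ms.
#' @return An object of class \code{latency_estimate}: \code{onset_ms},
#'   \code{level_uv} (c), \code{slope_uv_ms} (s), \code{sse},
#'   \code{search_interval_ms}, and \code{degenerate} (TRUE when the
#'   waveform is constant over the interval and the onset is undefined).
#' @export
estimate_onset <- function(waveform, interval_ms) {
  sel <- which(waveform$time_ms >= interval_ms[1] &
               waveform$time_ms <= interval_ms[2])
  if (length(sel) < 4)
    stop("onset search interval must contain at least 4 samples",
         call. = FALSE)
  t <- waveform$time_ms[sel]
  y <- waveform$amplitude_uv[sel]
  if (stats::sd(y) == 0) {
    return(structure(list(onset_ms = NA_real_, level_uv = y[1],
                          slope_uv_ms = 0, sse = 0,
                          search_interval_ms = interval_ms,
                          degenerate = TRUE),
                     class = "latency_estimate"))
  }
  n <- length(t)
  best <- list(sse = Inf, tau = NA_real_, c = NA_real_, s = NA_real_)
  for (j in 2:(n - 1)) {
    tau <- t[j]
    x <- pmax(t - tau, 0)
    # closed-form least squares for y ~ 1 + x
    mx <- mean(x); my <- mean(y)
    sxx <- sum((x - mx)^2)
    s <- if (sxx > 0) sum((x - mx) * (y - my)) / sxx else 0
    cc <- my - s * mx
    sse <- sum((y - cc - s * x)^2)
    if (sse < best$sse - 1e-12) best <- list(sse = sse, tau = tau,
                                             c = cc, s = s)
  }
  structure(list(onset_ms = best$tau, level_uv = best$c,
                 slope_uv_ms = best$s, sse = best$sse,
                 search_interval_ms = interval_ms,
                 degenerate = FALSE),
            class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  if (x$degenerate) cat("Onset undefined (constant waveform)\n")
  else cat(sprintf("Onset %.1f ms (level %.2f uV, slope %.4f uV/ms, SSE %.3f)\n",
                   x$onset_ms, x$level_uv, x$slope_uv_ms, x$sse))
  invisible(x)
}

#' Score one subject's S-LRP and R-LRP latencies
#'
#' Derives the stimulus- and response-locked LRPs, detects peaks inside
#' the configured windows (defaults: 200-500 ms post-stimulus;
#' -200-100 ms around the response), then estimates each onset with the
#' segmented-regression procedure over the interval from the baseline
#' start to the identified peak. The premotor (S-LRP) latency is the
#' stimulus-locked onset; the motor (R-LRP) latency is the negated
#' response-locked onset, i.e. a positive duration before the response.
#'
#' @param s_epochs,r_epochs Stimulus- and response-locked epoch sets.
#' @param s_peak_window,r_peak_window Peak search windows, ms.
#' @param s_search_start,r_search_start Start of the onset search
#'   interval, ms (defaults: the baseline starts).
#' @return List: \code{s_latency_ms}, \code{r_latency_ms},
#'   \code{s_peak_uv}, \code{r_peak_uv}, \code{s_lrp}, \code{r_lrp}
#'   (the waveforms), \code{n_s_trials}, \code{n_r_trials}.
#' @export
score_subject <- function(s_epochs, r_epochs,
                          s_peak_window = c(200, 500),
                          r_peak_window = c(-200, 100),
                          s_search_start = -200,
                          r_search_start = -1000) {
  s_lrp <- derive_lrp(s_epochs)
  r_lrp <- derive_lrp(r_epochs)
  s_peak <- find_peak(s_lrp, s_peak_window)
  r_peak <- find_peak(r_lrp, r_peak_window)
  s_on <- estimate_onset(s_lrp, c(s_search_start, s_peak$peak_ms))
  r_on <- estimate_onset(r_lrp, c(r_search_start, r_peak$peak_ms))
  list(s_latency_ms = s_on$onset_ms,
       r_latency_ms = -r_on$onset_ms,
       s_peak_uv = s_peak$peak_uv,
       r_peak_uv = r_peak$peak_uv,
       s_onset = s_on, r_onset = r_on,
       s_lrp = s_lrp, r_lrp = r_lrp,
       n_s_trials = s_lrp$n_left_trials + s_lrp$n_right_trials,
       n_r_trials = r_lrp$n_left_trials + r_lrp$n_right_trials)
}
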