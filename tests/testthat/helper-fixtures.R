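# Build an epoch_set directly from an array, for tests that need exact
# control over the data (bypassing rendering/segmentation).
make_epochs <- function(data, fs = 500, lock = "stimulus",
                        window_ms = NULL, baseline_ms = NULL,
                        channel_labels = NULL, meta = NULL) {
  stopifnot(length(dim(data)) == 3)
  n_tr <- dim(data)[1]; n_ch <- dim(data)[2]; n_sm <- dim(data)[3]
  if (is.null(window_ms))
    window_ms <- c(0, n_sm * 1000 / fs)
  if (is.null(baseline_ms))
    baseline_ms <- c(window_ms[1], window_ms[1] + 100)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(n_ch))
  if (is.null(meta))
    meta <- data.frame(trial = seq_len(n_tr),
                       hand = rep(c("left", "right"), length.out = n_tr),
                       correct = TRUE)
  a <- lrpfrac:::ms_to_samples(window_ms[1], fs)
  structure(list(data = data,
                 time_ms = (a:(a + n_sm - 1)) / fs * 1000,
                 lock = lock, window_ms = window_ms,
                 baseline_ms = baseline_ms, sampling_rate = fs,
                 channel_labels = channel_labels, trial_meta = meta,
                 n_dropped_edges = 0L),
            class = "epoch_set")
}

# A flat / rising / decaying piecewise-linear waveform on a ms grid
# (the shape class the onset estimator assumes, with a post-peak decay
# so peak detection lands on the true peak).
make_ramp_waveform <- function(onset_ms, peak_ms, peak_uv,
                               t_start = -200, t_end = 600, fs = 500,
                               noise_sd = 0, decay_ms = 200) {
  t <- seq(t_start, t_end, by = 1000 / fs)
  rise <- (t - onset_ms) / (peak_ms - onset_ms)
  fall <- 1 - (t - peak_ms) / decay_ms
  amp <- peak_uv * pmax(0, pmin(rise, fall, 1))
  if (noise_sd > 0) amp <- amp + rnorm(length(t), 0, noise_sd)
  list(time_ms = t, amplitude_uv = amp, lock = "stimulus",
       n_left_trials = 1L, n_right_trials = 1L)
}

# Independent brute-force segmented-regression oracle built on lm():
# exhaustively scans every interior breakpoint and refits with lm.
brute_force_onset <- function(time_ms, amp, interval_ms) {
  sel <- which(time_ms >= interval_ms[1] & time_ms <= interval_ms[2])
  t <- time_ms[sel]; y <- amp[sel]
  n <- length(t)
  sses <- sapply(2:(n - 1), function(j) {
    x <- pmax(t - t[j], 0)
    sum(resid(lm(y ~ x))^2)
  })
  t[(2:(n - 1))[which.min(sses)]]
}

# Small deterministic cohort table drawn from the standardized path model.
draw_cohort_table <- function(n, params, seed) {
  Sigma <- lrpfrac:::implied_path_cov(
    params$a_S, params$a_R, params$b_S, params$b_R,
    params$c_direct, params$beta_sex, params$rho_med)
  set.seed(seed)
  X <- MASS::mvrnorm(n, rep(0, 5), Sigma)
  data.frame(age = X[, 1], sex = X[, 2], s_lrp = X[, 3],
             r_lrp = X[, 4], rt = X[, 5])
}

paper_path_params <- function() {
  list(a_S = -0.09 / 0.41, a_R = 0.02 / 0.23, b_S = 0.41, b_R = 0.23,
       c_direct = -0.08, rho_med = -0.12, beta_sex = 0.221)
}
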