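make_rec <- function(data, labels, fs = 500) {
  eeg_recording(data, labels, fs,
                data.frame(sample = 1L, kind = "stimulus", trial = 1L))
}

test_that("mastoid re-referencing subtracts the mastoid mean and keeps references", {
  n <- 1000
  dat <- rbind(C3 = rnorm(n), C4 = rnorm(n), M1 = 0, M2 = 0)
  rec <- make_rec(dat, rownames(dat))
  expect_equal(rereference(rec)$data, dat)

  dat2 <- rbind(C3 = rep(10, n), C4 = rep(-5, n),
                M1 = rep(2, n), M2 = rep(4, n))
  out <- rereference(make_rec(dat2, rownames(dat2)))$data
  expect_equal(out["C3", ], rep(10 - 3, n))
  expect_equal(out["C4", ], rep(-5 - 3, n))
  expect_equal(out["M1", ], rep(2, n))

  # difference invariance: C3 = C4 before implies C3 = C4 after
  x <- rnorm(n)
  dat3 <- rbind(C3 = x, C4 = x, M1 = rnorm(n), M2 = rnorm(n))
  out3 <- rereference(make_rec(dat3, rownames(dat3)))$data
  expect_equal(out3["C3", ], out3["C4", ])

  expect_error(rereference(make_rec(dat2[1:2, ], c("C3", "C4"))), "M1")
})

test_that("band-pass filter removes DC, passes 10 Hz with no delay, attenuates 60 Hz", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  rec_dc <- make_rec(matrix(50, 1, length(t)), "C3", fs)
  out_dc <- bandpass_filter(rec_dc)$data[1, ]
  mid <- out_dc[1000:4000]
  expect_lt(mean(abs(mid)), 0.05 * 50)

  s10 <- sin(2 * pi * 10 * t)
  out10 <- bandpass_filter(make_rec(matrix(s10, 1), "C3", fs))$data[1, ]
  core <- 500:4500
  expect_lt(abs(max(out10[core]) - 1), 0.05)
  # zero phase: cross-correlation peaks at lag < 1 sample
  lags <- -3:3
  cc <- sapply(lags, function(l)
    cor(s10[core], out10[core + l]))
  expect_equal(lags[which.max(cc)], 0)

  # 60 Hz attenuated by the analytic squared Butterworth magnitude ratio
  s60 <- sin(2 * pi * 60 * t)
  out60 <- bandpass_filter(make_rec(matrix(s60, 1), "C3", fs))$data[1, ]
  amp60 <- max(abs(out60[core]))
  amp10 <- max(abs(out10[core]))
  bf <- signal::butter(2, c(0.1, 30) / (fs / 2), type = "pass")
  # squared magnitude (forward-backward pass) from the polynomials
  H <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    abs(sum(bf$b * z^(seq_along(bf$b) - 1)) /
          sum(bf$a * z^(seq_along(bf$a) - 1)))^2
  }
  expect_equal(amp60 / amp10, H(60) / H(10), tolerance = 0.1)
  expect_lt(amp60, 0.2 * amp10)

  expect_error(bandpass_filter(rec_dc, low_hz = 30, high_hz = 10), "band")
  expect_error(bandpass_filter(rec_dc, high_hz = 300), "band")
})

test_that("notch filter suppresses 60 Hz, spares 10 Hz, fixes nothing on silence", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  core <- 300:1500
  s60 <- sin(2 * pi * 60 * t)
  out <- notch_filter(make_rec(matrix(s60, 1), "C3", fs))$data[1, ]
  expect_lt(rms(out[core]), 0.1 * rms(s60[core]))

  s10 <- sin(2 * pi * 10 * t)
  out10 <- notch_filter(make_rec(matrix(s10, 1), "C3", fs))$data[1, ]
  expect_lt(abs(rms(out10[core]) / rms(s10[core]) - 1), 0.05)

  z <- make_rec(matrix(0, 1, 500), "C3", fs)
  expect_equal(notch_filter(z)$data, z$data)
  expect_error(notch_filter(z, freq_hz = 300), "Nyquist")
})

test_that("segmentation windows, index arithmetic and degenerate cases behave", {
  fs <- 500
  dat <- matrix(seq_len(4000), 1, dimnames = list("C3", NULL))
  mk <- data.frame(sample = c(1000L, 2500L),
                   kind = "stimulus", trial = 1:2)
  rec <- eeg_recording(dat, "C3", fs, mk)
  tt <- data.frame(trial = 1:2, correct = c(TRUE, TRUE), hand = "left")
  ep <- segment_epochs(rec, tt, "stimulus", window_ms = c(-200, 600),
                       baseline_ms = c(-200, 0))
  expect_equal(dim(ep$data), c(2, 1, 400))      # 800 ms at 500 Hz
  # window start -200 ms: epoch begins 100 samples before the marker
  expect_equal(ep$data[1, 1, 1], unname(dat[1, 900]))
  expect_equal(ep$time_ms[1], -200)

  # all trials incorrect: empty set with a warning
  tt_bad <- data.frame(trial = 1:2, correct = FALSE, hand = "left")
  expect_warning(ep0 <- segment_epochs(rec, tt_bad, "stimulus"),
                 "no correct trials")
  expect_equal(dim(ep0$data)[1], 0)

  expect_error(segment_epochs(rec, tt, "response"), "response")

  # epochs that would run off the edge are dropped with a warning
  mk2 <- data.frame(sample = c(50L, 2000L), kind = "stimulus",
                    trial = 1:2)
  rec2 <- eeg_recording(dat, "C3", fs, mk2)
  expect_warning(ep2 <- segment_epochs(rec2, tt, "stimulus"), "edge")
  expect_equal(dim(ep2$data)[1], 1)
})

test_that("baseline correction zeroes the baseline mean and is idempotent", {
  ep <- make_epochs(array(7, c(1, 1, 400)), window_ms = c(-200, 600),
                    baseline_ms = c(-200, 0))
  out <- baseline_correct(ep)
  expect_equal(out$data, array(0, c(1, 1, 400)))

  ramp <- array(seq(0, 10, length.out = 400), c(1, 1, 400))
  epr <- make_epochs(ramp, window_ms = c(-200, 600),
                     baseline_ms = c(-200, 0))
  outr <- baseline_correct(epr)
  bmean <- mean(ramp[1, 1, epr$time_ms < 0])
  expect_equal(outr$data[1, 1, ], ramp[1, 1, ] - bmean)
  expect_equal(baseline_correct(outr)$data, outr$data)

  expect_error(baseline_correct(ep, baseline_ms = c(-900, -800)),
               "outside")
})

test_that("ocular correction recovers a known propagation factor and leaves clean data alone", {
  set.seed(5)
  n_tr <- 30; n_sm <- 200
  blink <- array(0, c(n_tr, n_sm))
  for (i in 1:n_tr) blink[i, ] <- cumsum(rnorm(n_sm, 0, 3))
  signal_erp <- sin(seq(0, pi, length.out = n_sm)) * 2
  dat <- array(0, c(n_tr, 3, n_sm))
  for (i in 1:n_tr) {
    dat[i, 2, ] <- blink[i, ]                       # VEOG
    dat[i, 1, ] <- signal_erp + 0.5 * blink[i, ] + rnorm(n_sm, 0, 0.1)
  }
  ep <- make_epochs(dat, channel_labels = c("C3", "VEOG", "HEOG"))
  expect_warning(out <- ocular_correct(ep), "zero-variance")
  prop <- attr(out, "propagation")
  expect_lt(abs(prop["C3", "VEOG"] - 0.5), 0.01)
  recovered <- apply(out$data[, 1, ], 2, mean)
  expect_lt(max(abs(recovered - signal_erp)), 0.15)

  # both EOG silent: data unchanged
  dat0 <- array(rnorm(10 * 3 * 50), c(10, 3, 50))
  dat0[, 2, ] <- 0; dat0[, 3, ] <- 0
  ep0 <- make_epochs(dat0, channel_labels = c("C3", "VEOG", "HEOG"))
  expect_warning(out0 <- ocular_correct(ep0), "zero-variance")
  expect_equal(out0$data, dat0)

  expect_error(ocular_correct(make_epochs(dat0,
    channel_labels = c("C3", "Fz", "Pz"))), "VEOG")
})

test_that("subtracting the event-related average prevents signal leakage into the factors", {
  # VEOG carries an event-locked component correlated with the EEG's own
  # ERP but NOT propagated; the naive (no subtraction) regression
  # overestimates the factor, the average-subtracted one does not.
  set.seed(6)
  n_tr <- 40; n_sm <- 200
  erp <- sin(seq(0, pi, length.out = n_sm)) * 5
  true_b <- 0.3
  dat <- array(0, c(n_tr, 3, n_sm))
  for (i in 1:n_tr) {
    blink <- cumsum(rnorm(n_sm, 0, 2))
    dat[i, 2, ] <- blink + 4 * erp          # EOG with event-locked part
    dat[i, 1, ] <- erp + true_b * blink + rnorm(n_sm, 0, 0.1)
  }
  ep <- make_epochs(dat, channel_labels = c("C3", "VEOG", "HEOG"),
                    meta = data.frame(trial = 1:n_tr, hand = "left",
                                      correct = TRUE))
  expect_warning(out <- ocular_correct(ep), "zero-variance")
  b_corrected <- attr(out, "propagation")["C3", "VEOG"]

  naive_b <- coef(lm(as.vector(dat[, 1, ]) ~ as.vector(dat[, 2, ])))[2]
  expect_lt(abs(b_corrected - true_b), abs(naive_b - true_b))
  expect_lt(abs(b_corrected - true_b), 0.02)
})

test_that("each rejection rule fires on its minimal offender and unit conversion is honored", {
  base <- function() {
    set.seed(7)
    array(rnorm(400, 0, 2), c(1, 1, 400))
  }
  ep <- function(d) make_epochs(d, channel_labels = "C3",
                                window_ms = c(-200, 600))
  # (1) threshold + 1
  d <- base(); d[1, 1, 200] <- 101
  r <- reject_artifacts(ep(d))
  expect_true(r$report$rejected)
  expect_equal(r$report$criterion, "abs_amp")
  expect_equal(dim(r$epochs$data)[1], 0)

  # (2) 176 uV swing inside 100 ms, |amplitude| kept below the abs rule
  d <- base(); d[1, 1, 200:249] <- seq(-88, 88, length.out = 50)
  r <- reject_artifacts(ep(d))
  expect_equal(r$report$criterion, "p2p")

  # (3) 31 uV adjacent-sample step at 500 Hz is 15.5 uV/ms: below threshold
  d <- base(); d[1, 1, 200] <- d[1, 1, 199] + 31
  expect_false(reject_artifacts(ep(d))$report$rejected)
  #     61 uV is 30.5 uV/ms: above
  d <- base(); d[1, 1, 200] <- d[1, 1, 199] + 61
  expect_equal(reject_artifacts(ep(d))$report$criterion, "step")

  # (4) constant epoch
  d <- array(3, c(1, 1, 400))
  r <- reject_artifacts(ep(d))
  expect_equal(r$report$criterion, "low_activity")

  # clean background passes all four rules
  r <- reject_artifacts(ep(base()))
  expect_false(r$report$rejected)
  expect_equal(attr(r$report, "fraction_rejected"), 0)
})

test_that("flagging one trial never changes another trial's flag", {
  set.seed(8)
  d <- array(rnorm(5 * 1 * 400, 0, 2), c(5, 1, 400))
  ep <- make_epochs(d, channel_labels = "C3",
                    meta = data.frame(trial = 1:5, hand = "left",
                                      correct = TRUE))
  before <- reject_artifacts(ep)$report
  d2 <- d; d2[3, 1, 100] <- 150
  ep2 <- make_epochs(d2, channel_labels = "C3",
                     meta = ep$trial_meta)
  after <- reject_artifacts(ep2)$report
  expect_equal(before$rejected[-3], after$rejected[-3])
  expect_true(after$rejected[3])
})
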