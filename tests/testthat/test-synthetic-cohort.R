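test_that("RT is exactly the sum of premotor and motor durations on correct trials", {
  cfg <- cohort_config(n_subjects = 5, n_trials = 80, seed = 11)
  sim <- simulate_cohort(cfg)
  ok <- sim$trials$correct
  expect_true(all(sim$trials$rt_ms[ok] ==
                    sim$trials$premotor_ms[ok] + sim$trials$motor_ms[ok]))
  expect_true(all(sim$trials$premotor_ms > 0))
  expect_true(all(sim$trials$motor_ms > 0))
})

test_that("identical seeds give bit-identical ground truth", {
  cfg <- cohort_config(n_subjects = 4, n_trials = 50, seed = 42)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$subjects, s2$subjects)
  expect_identical(s1$trials, s2$trials)
})

test_that("trial counts, hand balance and error flags follow the configuration", {
  cfg <- cohort_config(n_subjects = 1, n_trials = 300, seed = 5,
                       error_rate = 0)
  sub <- simulate_subjects(cfg)
  tr <- simulate_trials(sub[1, ], cfg)
  expect_equal(nrow(tr), 300)
  # hands equiprobable: binomial 3.5-sigma band around 150
  expect_lt(abs(sum(tr$hand == "left") - 150), 3.5 * sqrt(300 * 0.25))
  expect_true(all(tr$correct))

  cfg2 <- cohort_config(n_subjects = 1, n_trials = 200, seed = 5,
                        error_rate = 0.5)
  tr2 <- simulate_trials(sub[1, ], cfg2)
  expect_gt(sum(!tr2$correct), 0)
})

test_that("degenerate noise collapses every RT onto the latent means", {
  cfg <- cohort_config(n_subjects = 2, n_trials = 30, seed = 9,
                       trial_noise = list(mu = 0, sigma = 0, tau = 0),
                       compat_effect_ms = 0, error_rate = 0)
  sim <- simulate_cohort(cfg)
  for (id in sim$subjects$subject_id) {
    sub <- sim$subjects[sim$subjects$subject_id == id, ]
    tr <- sim$trials[sim$trials$subject_id == id, ]
    expect_equal(tr$rt_ms,
                 rep(sub$premotor_mean_ms + sub$motor_mean_ms, nrow(tr)))
  }
})

test_that("generative structure is recovered at large n (a_S, null case, rho_med)", {
  # oracle: the generating value, within 2 Monte Carlo SEs (2/sqrt(n))
  n <- 5000
  tol <- 2 / sqrt(n)
  cfg <- cohort_config(n_subjects = n, seed = 101,
                       path_params = list(a_S = -0.22, a_R = 0.087,
                                          rho_med = -0.12))
  sub <- simulate_subjects(cfg)
  r_pre <- cor(sub$age_z, sub$premotor_mean_ms)
  expect_lt(abs(r_pre - (-0.22)), tol)

  # residual mediator correlation after partialling out age
  res_pre <- resid(lm(premotor_mean_ms ~ age_z, data = sub))
  res_mot <- resid(lm(motor_mean_ms ~ age_z, data = sub))
  expect_lt(abs(cor(res_pre, res_mot) - (-0.12)), tol)

  cfg0 <- cohort_config(n_subjects = 500, seed = 77,
                        path_params = list(a_S = 0, a_R = 0))
  sub0 <- simulate_subjects(cfg0)
  expect_lt(abs(cor(sub0$age_z, sub0$premotor_mean_ms)), 2 / sqrt(500))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(path_params = list(rho_med = 1)), "rho_med")
  expect_error(cohort_config(path_params = list(a_S = 1.2)), "residual")
  expect_error(cohort_config(error_rate = 1.5))
  expect_error(cohort_config(n_trials = 0))
})

test_that("rendered recordings place markers with the three printed ITIs", {
  cfg <- cohort_config(n_subjects = 1, n_trials = 40, seed = 3,
                       eeg_noise_sd = 0, blink_rate = 0, error_rate = 0)
  sim <- simulate_cohort(cfg)
  tr <- sim$trials
  rec <- render_eeg(tr, sim$subjects[1, ], cfg)
  stim <- rec$markers[rec$markers$kind == "stimulus", ]
  # stimulus onset asynchrony = 250 ms stimulus + ITI
  soa_ms <- diff(stim$sample) / rec$sampling_rate * 1000
  expect_true(all(soa_ms %in% (250 + c(1080, 1100, 1130))))
  # every stimulus of a correct trial is followed by exactly one response
  resp <- rec$markers[rec$markers$kind != "stimulus", ]
  expect_equal(resp$trial, stim$trial)
  expect_true(all(diff(rec$markers$sample) > 0))
})

test_that("a zero-amplitude LRP renders as a statistically flat waveform", {
  cfg <- cohort_config(n_subjects = 1, n_trials = 120, seed = 21,
                       lrp_amplitude = 0, eeg_noise_sd = 6,
                       blink_rate = 0, error_rate = 0)
  sim <- simulate_cohort(cfg)
  tr <- sim$trials
  rec <- render_eeg(tr, sim$subjects[1, ], cfg)
  rec <- rereference(rec)
  ep <- baseline_correct(segment_epochs(rec, tr, "stimulus"))
  w <- derive_lrp(ep)
  post <- w$amplitude_uv[w$time_ms > 0]
  se <- sd(post) / sqrt(length(post))
  expect_lt(abs(mean(post)), 3 * sd(post))
})

test_that("injected offenders are flagged by the matching criterion and clean background is not", {
  cfg <- cohort_config(n_subjects = 1, n_trials = 60, seed = 31,
                       eeg_noise_sd = 3, blink_rate = 0, error_rate = 0)
  sim <- simulate_cohort(cfg)
  tr <- sim$trials
  rec <- render_eeg(tr, sim$subjects[1, ], cfg)

  # clean background: nothing flagged
  ep0 <- baseline_correct(segment_epochs(rereference(rec), tr, "stimulus"))
  r0 <- reject_artifacts(ep0, channels = c("C3", "C4"))
  expect_equal(sum(r0$report$rejected), 0)

  spec <- data.frame(class = c("flat", "abs", "p2p", "step"),
                     count = c(10, 3, 3, 3), channel = "C3")
  inj <- inject_artifacts(rec, spec, seed = 8)
  ep <- baseline_correct(segment_epochs(rereference(inj$recording), tr,
                                        "stimulus"))
  rr <- reject_artifacts(ep, channels = c("C3", "C4"))
  rep <- rr$report

  # exactly the offending trials are flagged
  expect_setequal(rep$trial[rep$rejected], inj$injected$trial)
  # the ten flatline offenders all fall under the low-activity rule
  flat_trials <- inj$injected$trial[inj$injected$class == "flat"]
  expect_gte(sum(rep$criterion[rep$trial %in% flat_trials] ==
                   "low_activity"), 10)
  # step offenders are step violations, not absolute-amplitude ones
  step_trials <- inj$injected$trial[inj$injected$class == "step"]
  expect_true(all(rep$criterion[rep$trial %in% step_trials] == "step"))
})

test_that("requesting more artifacts than trials errors", {
  cfg <- cohort_config(n_subjects = 1, n_trials = 10, seed = 3,
                       eeg_noise_sd = 1, blink_rate = 0, error_rate = 0)
  sim <- simulate_cohort(cfg)
  rec <- render_eeg(sim$trials, sim$subjects[1, ], cfg)
  expect_error(
    inject_artifacts(rec, data.frame(class = "abs", count = 11)),
    "more artifacts")
})
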