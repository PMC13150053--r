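#' Configuration for a synthetic flanker-task EEG cohort
#'
#' Bundles every parameter of the synthetic cohort generator: sample size,
#' age range, trial counts, the standardized path coefficients that induce
#' age-graded premotor (but not motor) processing speed, trial-level noise,
#' and EEG rendering parameters.
#'
#' The generative model mirrors the dual-mediator path structure the
#' downstream analysis estimates: standardized age drives each subject's
#' latent premotor and motor mean durations through \code{a_S} and
#' \code{a_R}; the two mediator disturbances are correlated \code{rho_med};
#' per-trial durations scatter around the subject means; reaction time is
#' the exact sum of the premotor and motor durations on correct trials.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Two-element numeric, years; ages are drawn uniformly.
#' @param n_trials Critical trials per subject.
#' @param sampling_rate EEG sampling rate in Hz.
#' @param path_params Named list of standardized coefficients:
#'   \code{a_S} (age to premotor mean), \code{a_R} (age to motor mean),
#'   \code{b_S}, \code{b_R} (mediator to RT; used by the closed-form
#'   cohort simulator, implicit in trial rendering), \code{c_direct}
#'   (direct age to RT), \code{rho_med} (residual mediator correlation),
#'   \code{beta_sex} (sex to RT).
#' @param premotor_mean_ms,premotor_sd_ms Cohort mean and between-subject
#'   SD of the latent premotor duration (ms).
#' @param motor_mean_ms,motor_sd_ms Same for the motor duration.
#' @param trial_noise Named list \code{list(mu, sigma, tau)} of ex-Gaussian
#'   within-subject trial noise (ms): \code{sigma} is the Gaussian SD,
#'   \code{tau} the exponential (right-skew) mean, \code{mu} a constant
#'   shift (kept 0 so subject means stay interpretable).
#' @param compat_effect_ms Flanker interference effect: incompatible
#'   trials lengthen the premotor stage by half this value, compatible
#'   trials shorten it by the same amount.
#' @param eeg_noise_sd Band-limited background EEG noise SD in microvolts.
#' @param lrp_amplitude Peak amplitude of the lateralized ramp (microvolts)
#'   in the derived LRP (the per-channel deflection is half, with opposite
#'   sign over the two motor sites).
#' @param blink_rate Expected blinks per second on the ocular channels.
#' @param error_rate Probability a trial is an error.
#' @param prop_female Probability a subject is female (sex affects RT only,
#'   through \code{beta_sex}).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#'
#' @return An object of class \code{cohort_config} (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 4, n_trials = 20, seed = 1)
#' cfg$path_params$a_S
cohort_config <- function(n_subjects = 194,
                          age_range = c(14, 19),
                          n_trials = 300,
                          sampling_rate = 500,
                          path_params = list(
                            a_S = -0.22, a_R = 0.087,
                            b_S = 0.41, b_R = 0.23,
                            c_direct = -0.08, rho_med = -0.12,
                            beta_sex = 0.221),
                          premotor_mean_ms = 191,
                          premotor_sd_ms = 40,
                          motor_mean_ms = 152,
                          motor_sd_ms = 36,
                          trial_noise = list(mu = 0, sigma = 35, tau = 45),
                          compat_effect_ms = 36.5,
                          eeg_noise_sd = 8,
                          lrp_amplitude = 3,
                          blink_rate = 0.1,
                          error_rate = 0.12,
                          prop_female = 0.686,
                          seed = 1L) {
  defaults <- list(a_S = -0.22, a_R = 0.087, b_S = 0.41, b_R = 0.23,
                   c_direct = -0.08, rho_med = -0.12, beta_sex = 0.221)
  defaults[names(path_params)] <- path_params
  path_params <- defaults

  stopifnot(n_subjects >= 1, n_trials > 0, sampling_rate > 0,
            length(age_range) == 2, age_range[1] < age_range[2],
            error_rate >= 0, error_rate <= 1,
            prop_female >= 0, prop_female <= 1,
            premotor_mean_ms > 0, motor_mean_ms > 0,
            premotor_sd_ms >= 0, motor_sd_ms >= 0,
            eeg_noise_sd >= 0, blink_rate >= 0)
  if (abs(path_params$rho_med) >= 1)
    stop("rho_med must lie strictly inside (-1, 1)", call. = FALSE)
  for (nm in c("a_S", "a_R")) {
    if (abs(path_params[[nm]]) >= 1)
      stop(sprintf(
        "|%s| >= 1 leaves no residual variance for the mediator", nm),
        call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         age_range = as.numeric(age_range),
         n_trials = as.integer(n_trials),
         sampling_rate = sampling_rate,
         path_params = path_params,
         premotor_mean_ms = premotor_mean_ms,
         premotor_sd_ms = premotor_sd_ms,
         motor_mean_ms = motor_mean_ms,
         motor_sd_ms = motor_sd_ms,
         trial_noise = trial_noise,
         compat_effect_ms = compat_effect_ms,
         eeg_noise_sd = eeg_noise_sd,
         lrp_amplitude = lrp_amplitude,
         blink_rate = blink_rate,
         error_rate = error_rate,
         prop_female = prop_female,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic flanker cohort configuration\n")
  cat(sprintf("  %d subjects, ages %.0f-%.0f, %d trials each @ %g Hz\n",
              x$n_subjects, x$age_range[1], x$age_range[2],
              x$n_trials, x$sampling_rate))
  pp <- x$path_params
  cat(sprintf("  paths: a_S=%.3f a_R=%.3f b_S=%.2f b_R=%.2f c'=%.2f rho=%.2f sex=%.3f\n",
              pp$a_S, pp$a_R, pp$b_S, pp$b_R, pp$c_direct, pp$rho_med,
              pp$beta_sex))
  cat(sprintf("  premotor %g (%g) ms, motor %g (%g) ms, error rate %g\n",
              x$premotor_mean_ms, x$premotor_sd_ms,
              x$motor_mean_ms, x$motor_sd_ms, x$error_rate))
  invisible(x)
}
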