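#' Draw subject-level ground truth for a synthetic cohort
#'
#' Samples age, sex, and latent premotor/motor mean durations. Age is
#' uniform on the configured range and standardized; the standardized age
#' score drives the premotor mean through \code{a_S} and the motor mean
#' through \code{a_R}; the two mediator disturbances are drawn with
#' correlation \code{rho_med}. Latent means are expressed in ms on the
#' configured premotor/motor scales.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return A data frame with one row per subject: \code{subject_id},
#'   \code{age_years}, \code{age_z}, \code{sex} (0 male / 1 female),
#'   \code{premotor_mean_ms}, \code{motor_mean_ms}.
#' @export
simulate_subjects <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  pp <- config$path_params

  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  age_z <- as.numeric(scale(age))
  if (n == 1) age_z <- 0
  sex <- stats::rbinom(n, 1, config$prop_female)

  # correlated standardized mediator disturbances
  e <- matrix(stats::rnorm(2 * n), n, 2)
  rho <- pp$rho_med
  e2 <- rho * e[, 1] + sqrt(1 - rho^2) * e[, 2]
  z_pre <- pp$a_S * age_z + sqrt(1 - pp$a_S^2) * e[, 1]
  z_mot <- pp$a_R * age_z + sqrt(1 - pp$a_R^2) * e2

  pre <- config$premotor_mean_ms + config$premotor_sd_ms * z_pre
  mot <- config$motor_mean_ms + config$motor_sd_ms * z_mot
  # latent durations must stay physiologically positive
  pre <- pmax(pre, 40)
  mot <- pmax(mot, 40)

  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             age_years = age,
             age_z = age_z,
             sex = sex,
             premotor_mean_ms = pre,
             motor_mean_ms = mot,
             stringsAsFactors = FALSE)
}

# ex-Gaussian deviate centred on zero: Gaussian(0, sigma) + Exp(tau) - tau
rexgauss0 <- function(n, mu, sigma, tau) {
  g <- if (sigma > 0) stats::rnorm(n, mu, sigma) else rep(mu, n)
  e <- if (tau > 0) stats::rexp(n, rate = 1 / tau) - tau else 0
  g + e
}

#' Simulate flanker trials for one subject
#'
#' Draws per-trial premotor and motor durations around the subject's latent
#' means. The premotor component carries the right-skewed (ex-Gaussian)
#' share of trial noise, the motor component a Gaussian share, so the EEG
#' onset implied by the premotor duration stays consistent with the
#' behavioral RT: on every correct trial \code{rt_ms} is exactly
#' \code{premotor_ms + motor_ms}. Hands and flanker compatibilities are
#' equiprobable; errors are flagged with the configured rate.
#'
#' @param subject One row of the data frame from
#'   \code{\link{simulate_subjects}}.
#' @param config A \code{\link{cohort_config}}.
#' @param seed Optional integer; defaults to a stream derived from the
#'   config seed and the subject index so subjects are independent.
#' @return Data frame of trials: \code{subject_id}, \code{trial},
#'   \code{hand}, \code{compatibility}, \code{premotor_ms},
#'   \code{motor_ms}, \code{rt_ms}, \code{correct}.
#' @export
simulate_trials <- function(subject, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), nrow(subject) == 1)
  if (subject$premotor_mean_ms <= 0 || subject$motor_mean_ms <= 0)
    stop("subject latent means must be positive", call. = FALSE)
  if (is.null(seed)) {
    idx <- as.integer(sub("^S", "", subject$subject_id))
    seed <- (config$seed + 10007L * idx) %% .Machine$integer.max
  }
  set.seed(seed)
  n <- config$n_trials
  tn <- config$trial_noise

  hand <- sample(c("left", "right"), n, replace = TRUE)
  compat <- sample(c("compatible", "incompatible"), n, replace = TRUE)

  pre <- subject$premotor_mean_ms +
    rexgauss0(n, tn$mu, tn$sigma, tn$tau)
  mot <- subject$motor_mean_ms +
    (if (tn$sigma > 0) stats::rnorm(n, 0, tn$sigma / 2) else 0)
  # flanker interference lengthens the premotor stage only
  shift <- config$compat_effect_ms / 2
  pre <- pre + ifelse(compat == "incompatible", shift, -shift)
  pre <- pmax(pre, 30)
  mot <- pmax(mot, 30)

  correct <- stats::runif(n) >= config$error_rate

  data.frame(subject_id = subject$subject_id,
             trial = seq_len(n),
             hand = hand,
             compatibility = compat,
             premotor_ms = pre,
             motor_ms = mot,
             rt_ms = pre + mot,
             correct = correct,
             stringsAsFactors = FALSE)
}

#' Simulate a complete cohort trial table
#'
#' Convenience wrapper: \code{\link{simulate_subjects}} then
#' \code{\link{simulate_trials}} for each subject.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return List with elements \code{subjects} and \code{trials}.
#' @export
simulate_cohort <- function(config) {
  subjects <- simulate_subjects(config)
  trials <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i)
    simulate_trials(subjects[i, ], config)))
  rownames(trials) <- NULL
  list(subjects = subjects, trials = trials)
}
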