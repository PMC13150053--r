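# Model-implied covariance of (age, sex, S, R, RT) for the recursive
# dual-mediator path model, all variables standardized. exo_cov is the
# 2x2 covariance of the exogenous block (age, sex).
implied_path_cov <- function(a_S, a_R, b_S, b_R, c_direct, beta_sex,
                             rho_med,
                             exo_cov = diag(2),
                             v_S = NULL, v_R = NULL, v_RT = NULL) {
  if (is.null(v_S)) v_S <- 1 - a_S^2
  if (is.null(v_R)) v_R <- 1 - a_R^2
  psi_cov <- rho_med * sqrt(v_S * v_R)
  # inputs u = (age, sex, eS, eR, eRT); observed = T u
  cov_SR_exo <- matrix(c(exo_cov[1, 1], exo_cov[1, 2],
                         exo_cov[2, 1], exo_cov[2, 2]), 2, 2)
  if (is.null(v_RT)) {
    # choose the RT disturbance so var(RT) = 1
    S_age <- a_S * exo_cov[1, 1]
    R_age <- a_R * exo_cov[1, 1]
    covSR <- a_S * a_R * exo_cov[1, 1] + psi_cov
    explained <- c_direct^2 * exo_cov[1, 1] + beta_sex^2 * exo_cov[2, 2] +
      b_S^2 * (a_S^2 * exo_cov[1, 1] + v_S) +
      b_R^2 * (a_R^2 * exo_cov[1, 1] + v_R) +
      2 * c_direct * beta_sex * exo_cov[1, 2] +
      2 * c_direct * (b_S * S_age + b_R * R_age) +
      2 * beta_sex * (b_S * a_S + b_R * a_R) * exo_cov[1, 2] +
      2 * b_S * b_R * covSR
    v_RT <- 1 - explained
    if (v_RT <= 0)
      stop("path parameterization implies non-positive RT residual ",
           "variance; implied covariance is not positive definite",
           call. = FALSE)
  }
  Tm <- matrix(0, 5, 5,
               dimnames = list(c("age", "sex", "S", "R", "RT"), NULL))
  Tm[1, 1] <- 1
  Tm[2, 2] <- 1
  Tm[3, ] <- c(a_S, 0, 1, 0, 0)
  Tm[4, ] <- c(a_R, 0, 0, 1, 0)
  # RT = c age + beta_sex sex + b_S S + b_R R + eRT, substituted
  Tm[5, ] <- c(c_direct + b_S * a_S + b_R * a_R, beta_sex,
               b_S, b_R, 1)
  U <- matrix(0, 5, 5)
  U[1:2, 1:2] <- cov_SR_exo
  U[3, 3] <- v_S; U[4, 4] <- v_R
  U[3, 4] <- U[4, 3] <- psi_cov
  U[5, 5] <- v_RT
  Sigma <- Tm %*% U %*% t(Tm)
  dimnames(Sigma) <- list(rownames(Tm), rownames(Tm))
  Sigma
}

#' Maximum-likelihood fit indices for a covariance structure
#'
#' Computes the ML discrepancy chi-square and the usual absolute and
#' incremental fit indices for a fitted covariance structure:
#' chi2 = (n-1) F_ML with F_ML = ln|Sigma| - ln|S| + tr(S Sigma^-1) - p;
#' RMSEA = sqrt(max(chi2 - df, 0) / (df (n-1))) (defined as 0 when
#' df = 0); SRMR = root mean square of the standardized residual moments
#' over the p(p+1)/2 unique entries; CFI and TLI are computed against
#' the independence baseline (diagonal of the sample covariance).
#'
#' @param sample_cov Sample covariance matrix.
#' @param implied_cov Model-implied covariance matrix, same order.
#' @param df Model degrees of freedom.
#' @param n Sample size.
#' @param baseline_cov Baseline (independence) covariance; defaults to
#'   \code{diag(diag(sample_cov))}.
#' @return List: \code{chi2}, \code{df}, \code{p_value}, \code{rmsea},
#'   \code{srmr}, \code{cfi}, \code{tli}.
#' @export
fit_indices <- function(sample_cov, implied_cov, df, n,
                        baseline_cov = NULL) {
  S <- as.matrix(sample_cov); Sg <- as.matrix(implied_cov)
  p <- nrow(S)
  stopifnot(nrow(Sg) == p, df >= 0, n > p)
  ev <- eigen(Sg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 ||
      min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("covariance matrices must be positive definite", call. = FALSE)
  fml <- function(S, Sg) {
    as.numeric(determinant(Sg, logarithm = TRUE)$modulus -
               determinant(S, logarithm = TRUE)$modulus +
               sum(diag(S %*% solve(Sg))) - nrow(S))
  }
  chi2 <- (n - 1) * fml(S, Sg)
  chi2 <- max(chi2, 0)
  p_value <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
             else NA_real_
  rmsea <- if (df == 0) 0 else sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  d <- sqrt(diag(S))
  resid <- (S - Sg) / tcrossprod(d)
  srmr <- sqrt(mean(resid[upper.tri(resid, diag = TRUE)]^2))
  if (is.null(baseline_cov)) baseline_cov <- diag(diag(S))
  df_b <- p * (p - 1) / 2
  chi2_b <- (n - 1) * fml(S, baseline_cov)
  cfi <- 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)
  tli <- if (df > 0 && chi2_b > df_b)
    ((chi2_b / df_b) - (chi2 / df)) / ((chi2_b / df_b) - 1)
  else NA_real_
  list(chi2 = chi2, df = df, p_value = p_value, rmsea = rmsea,
       srmr = srmr, cfi = cfi, tli = tli)
}

#' Fit the dual-mediator path model of age effects on RT
#'
#' Estimates the recursive path model in which standardized age predicts
#' the two mediators (S-LRP and R-LRP latency: a-paths), both mediators
#' and age predict mean RT (b-paths and the direct c'-path), sex enters
#' as an independent influence on RT, and the mediator disturbances are
#' allowed to covary. For this recursive structure the maximum-likelihood
#' point estimates coincide with two-stage OLS (each mediator on age; RT
#' on age, both mediators, sex), which is how they are computed: fully
#' closed form, no optimizer. Indirect effects are products of the
#' corresponding a- and b-paths with delta-method standard errors
#' \code{SE(ab) = sqrt(a^2 SE_b^2 + b^2 SE_a^2)}; the total effect is the
#' direct effect plus both indirect effects, exactly. Fit indices are
#' computed from the implied covariance of the five observed variables,
#' whose only over-identifying restrictions are the omitted sex-to-
#' mediator paths (df = 2).
#'
#' @param cohort Data frame with columns \code{age}, \code{sex},
#'   \code{s_lrp}, \code{r_lrp}, \code{rt} (or the cohort-table names
#'   \code{age_years}, \code{mean_rt_ms}, \code{s_lrp_ms},
#'   \code{r_lrp_ms}).
#' @param standardize If TRUE (default) all five variables are z-scored
#'   and the reported solution is fully standardized. If FALSE the
#'   mediators and RT are mean-centered only and age is standardized, so
#'   paths carry ms units.
#' @return Object of class \code{path_model_result}: \code{paths} (data
#'   frame of estimate, se, z, p for a_S, a_R, b_S, b_R, c_direct,
#'   beta_sex), \code{psi} (residual mediator correlation),
#'   \code{indirect_S}, \code{indirect_R}, \code{total} (each with
#'   estimate, se, z, p), \code{fit} (see \code{\link{fit_indices}}),
#'   \code{n}.
#' @export
fit_path_model <- function(cohort, standardize = TRUE) {
  nm <- names(cohort)
  pick <- function(...) {
    for (cand in c(...)) if (cand %in% nm) return(cohort[[cand]])
    stop("cohort lacks a required column (tried: ",
         paste(c(...), collapse = ", "), ")", call. = FALSE)
  }
  age <- pick("age", "age_years")
  sex <- pick("sex")
  S <- pick("s_lrp", "s_lrp_ms")
  R <- pick("r_lrp", "r_lrp_ms")
  RT <- pick("rt", "mean_rt_ms")
  d <- data.frame(age, sex, S, R, RT)
  if (anyNA(d)) stop("cohort rows must be complete", call. = FALSE)
  n <- nrow(d)
  stopifnot(n > 6)
  if (any(vapply(d, stats::sd, numeric(1)) == 0))
    stop("singular design: a modeled column has zero variance",
         call. = FALSE)
  if (standardize) {
    d[] <- lapply(d, function(x) as.numeric(scale(x)))
  } else {
    d$age <- as.numeric(scale(d$age))
    d$S <- d$S - mean(d$S); d$R <- d$R - mean(d$R)
    d$RT <- d$RT - mean(d$RT)
    d$sex <- d$sex - mean(d$sex)
  }

  fS <- stats::lm(S ~ age, data = d)
  fR <- stats::lm(R ~ age, data = d)
  fY <- stats::lm(RT ~ age + S + R + sex, data = d)
  grab <- function(fit, term) {
    sm <- summary(fit)$coefficients
    c(est = sm[term, 1], se = sm[term, 2])
  }
  est <- rbind(a_S = grab(fS, "age"),
               a_R = grab(fR, "age"),
               b_S = grab(fY, "S"),
               b_R = grab(fY, "R"),
               c_direct = grab(fY, "age"),
               beta_sex = grab(fY, "sex"))
  paths <- data.frame(estimate = est[, "est"], se = est[, "se"])
  paths$z <- paths$estimate / paths$se
  paths$p <- 2 * stats::pnorm(abs(paths$z), lower.tail = FALSE)

  psi <- stats::cor(stats::resid(fS), stats::resid(fR))

  delta_prod <- function(a, sa, b, sb) {
    ab <- a * b
    se <- sqrt(a^2 * sb^2 + b^2 * sa^2)
    z <- ab / se
    list(estimate = ab, se = se, z = z,
         p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  }
  ind_S <- delta_prod(est["a_S", "est"], est["a_S", "se"],
                      est["b_S", "est"], est["b_S", "se"])
  ind_R <- delta_prod(est["a_R", "est"], est["a_R", "se"],
                      est["b_R", "est"], est["b_R", "se"])
  total_est <- est["c_direct", "est"] + ind_S$estimate + ind_R$estimate
  # z for the total from the OLS of RT on age and sex alone would need
  # its own model; report the delta-method composite instead
  se_total <- sqrt(est["c_direct", "se"]^2 + ind_S$se^2 + ind_R$se^2)
  total <- list(estimate = total_est, se = se_total,
                z = total_est / se_total,
                p = 2 * stats::pnorm(abs(total_est / se_total),
                                     lower.tail = FALSE))

  Sc <- stats::cov(d)
  v_S_hat <- Sc["S", "S"] - est["a_S", "est"]^2 * Sc["age", "age"]
  v_R_hat <- Sc["R", "R"] - est["a_R", "est"]^2 * Sc["age", "age"]
  rho_hat <- psi
  implied <- implied_path_cov(
    a_S = est["a_S", "est"], a_R = est["a_R", "est"],
    b_S = est["b_S", "est"], b_R = est["b_R", "est"],
    c_direct = est["c_direct", "est"], beta_sex = est["beta_sex", "est"],
    rho_med = rho_hat,
    exo_cov = Sc[c("age", "sex"), c("age", "sex")],
    v_S = v_S_hat, v_R = v_R_hat,
    v_RT = stats::var(stats::resid(fY)))
  fit <- fit_indices(Sc, implied, df = 2, n = n)

  structure(list(paths = paths, psi = rho_hat,
                 indirect_S = ind_S, indirect_R = ind_R, total = total,
                 fit = fit, n = n, standardized = standardize),
            class = "path_model_result")
}

#' @export
print.path_model_result <- function(x, ...) {
  cat(sprintf("Dual-mediator path model (n = %d, %s solution)\n", x$n,
              if (x$standardized) "standardized" else "unstandardized"))
  print(round(x$paths, 4))
  cat(sprintf("residual mediator correlation psi = %.3f\n", x$psi))
  cat(sprintf("indirect via S-LRP: %.3f (se %.3f, z %.2f, p %.4f)\n",
              x$indirect_S$estimate, x$indirect_S$se, x$indirect_S$z,
              x$indirect_S$p))
  cat(sprintf("indirect via R-LRP: %.3f (se %.3f, z %.2f, p %.4f)\n",
              x$indirect_R$estimate, x$indirect_R$se, x$indirect_R$z,
              x$indirect_R$p))
  cat(sprintf("total effect of age: %.3f\n", x$total$estimate))
  with(x$fit, cat(sprintf(
    "fit: chi2(%d) = %.3f, p = %.3f, RMSEA %.3f, SRMR %.3f, CFI %.3f, TLI %.3f\n",
    df, chi2, p_value, rmsea, srmr, cfi, tli)))
  invisible(x)
}

# internal fast refit used by the power simulation: standardized data in,
# delta-method z statistics for both indirect effects out
path_indirect_z <- function(X) {
  n <- nrow(X)
  age <- X[, 1]; sex <- X[, 2]; S <- X[, 3]; R <- X[, 4]; RT <- X[, 5]
  za <- sum(age^2)
  aS <- sum(age * S) / za
  aR <- sum(age * R) / za
  se_aS <- sqrt(sum((S - aS * age)^2) / (n - 2) / za)
  se_aR <- sqrt(sum((R - aR * age)^2) / (n - 2) / za)
  Xm <- cbind(1, age, S, R, sex)
  XtX <- crossprod(Xm)
  bhat <- solve(XtX, crossprod(Xm, RT))
  res <- RT - Xm %*% bhat
  s2 <- sum(res^2) / (n - 5)
  vb <- s2 * diag(solve(XtX))
  bS <- bhat[3]; bR <- bhat[4]
  se_bS <- sqrt(vb[3]); se_bR <- sqrt(vb[4])
  c(z_S = (aS * bS) / sqrt(aS^2 * se_bS^2 + bS^2 * se_aS^2),
    z_R = (aR * bR) / sqrt(aR^2 * se_bR^2 + bR^2 * se_aR^2))
}

#' Monte Carlo power for the mediation paths
#'
#' Draws replicate cohorts of size \code{n} from the multivariate normal
#' distribution implied by the standardized dual-mediator path model,
#' refits the model per replicate, and reports the proportion of
#' replicates in which each indirect effect's delta-method z exceeds the
#' two-sided critical value at \code{alpha}.
#'
#' @param path_params Named list: \code{a_S}, \code{a_R}, \code{b_S},
#'   \code{b_R}, \code{c_direct}, \code{rho_med}, \code{beta_sex}
#'   (standardized).
#' @param n Cohort size per replicate.
#' @param n_reps Number of replicates.
#' @param alpha Two-sided significance level.
#' @param seed Integer seed; results are deterministic given it.
#' @param include_sex Whether the sex covariate is part of the
#'   data-generating model (it is always part of the fitted model).
#' @param standardize_each Re-standardize every replicate before fitting
#'   (the default, matching the standardized fitting procedure).
#' @return Object of class \code{power_result}: \code{power_S},
#'   \code{power_R}, \code{n}, \code{n_reps}, \code{alpha},
#'   \code{n_failed} (non-finite refits, excluded from the denominator),
#'   \code{seed}.
#' @export
monte_carlo_power <- function(path_params, n, n_reps = 5000,
                              alpha = 0.05, seed = 1L,
                              include_sex = TRUE,
                              standardize_each = TRUE) {
  pp <- path_params
  beta_sex <- if (include_sex) pp$beta_sex else 0
  Sigma <- implied_path_cov(pp$a_S, pp$a_R, pp$b_S, pp$b_R,
                            pp$c_direct, beta_sex, pp$rho_med)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("implied covariance is not positive definite", call. = FALSE)
  L <- chol(Sigma)
  set.seed(seed)
  crit <- stats::qnorm(1 - alpha / 2)
  hit_S <- hit_R <- 0L
  failed <- 0L
  for (r in seq_len(n_reps)) {
    X <- matrix(stats::rnorm(n * 5), n, 5) %*% L
    if (standardize_each) X <- scale(X)
    z <- tryCatch(path_indirect_z(X), error = function(e) c(NA, NA))
    if (anyNA(z) || any(!is.finite(z))) {
      failed <- failed + 1L
      next
    }
    hit_S <- hit_S + (abs(z[1]) > crit)
    hit_R <- hit_R + (abs(z[2]) > crit)
  }
  done <- n_reps - failed
  structure(list(power_S = hit_S / done, power_R = hit_R / done,
                 n = n, n_reps = n_reps, alpha = alpha,
                 n_failed = failed, seed = seed),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo mediation power (n = %d, %d reps, alpha = %g):\n",
    x$n, x$n_reps, x$alpha))
  cat(sprintf("  S-LRP indirect: %.1f%%\n", 100 * x$power_S))
  cat(sprintf("  R-LRP indirect: %.1f%%\n", 100 * x$power_R))
  if (x$n_failed > 0)
    cat(sprintf("  (%d failed replicates excluded)\n", x$n_failed))
  invisible(x)
}
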