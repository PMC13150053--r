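#' Pearson correlation matrix with t-based p-values
#'
#' Pairwise Pearson correlations over complete columns, with two-sided
#' p-values from t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom.
#'
#' @param data Data frame or matrix of numeric columns.
#' @return List with matrices \code{r}, \code{p}, and \code{n}. Columns
#'   with zero variance yield \code{NA} entries and a warning.
#' @export
pearson_matrix <- function(data) {
  X <- as.matrix(data)
  stopifnot(is.numeric(X), nrow(X) >= 3)
  n <- nrow(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "),
            "; correlations undefined")
  r <- suppressWarnings(stats::cor(X))
  r[, sds == 0] <- NA; r[sds == 0, ] <- NA
  diag(r) <- ifelse(sds == 0, NA, 1)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA
  list(r = r, p = p, n = n)
}

#' Compare two dependent, overlapping correlations
#'
#' Tests whether the correlation of variable j with k differs from that
#' of j with h when k and h are measured on the same sample (correlations
#' share variable j and overlap through r_kh). The default is the
#' Meng-Rosenthal-Rubin z for overlapping dependent correlations:
#' \deqn{z = (z_{jk} - z_{jh}) \sqrt{(n-3) / (2 (1 - r_{kh}) h)}}
#' with \eqn{h = (1 - f \bar r^2)/(1 - \bar r^2)},
#' \eqn{f = \min(1, (1 - r_{kh}) / (2 (1 - \bar r^2)))} and
#' \eqn{\bar r^2 = (r_{jk}^2 + r_{jh}^2)/2}; \eqn{z_{\cdot}} are Fisher
#' transforms. The \code{"independent"} method treats the two
#' correlations as coming from independent samples of size n.
#'
#' @param r_jk,r_jh The two correlations sharing variable j.
#' @param r_kh Correlation between the two non-shared variables (ignored
#'   by the independent method).
#' @param n Sample size.
#' @param method \code{"meng"} (default) or \code{"independent"}.
#' @return List with \code{z} and two-sided \code{p}.
#' @export
compare_dependent_correlations <- function(r_jk, r_jh, r_kh, n,
                                           method = c("meng",
                                                      "independent")) {
  method <- match.arg(method)
  if (any(abs(c(r_jk, r_jh)) >= 1))
    stop("|r| = 1 has an infinite Fisher transform", call. = FALSE)
  stopifnot(n > 3, abs(r_kh) <= 1)
  zf <- function(r) atanh(r)
  if (method == "independent") {
    z <- (zf(r_jk) - zf(r_jh)) / sqrt(2 / (n - 3))
  } else {
    rbar2 <- (r_jk^2 + r_jh^2) / 2
    f <- min(1, (1 - r_kh) / (2 * (1 - rbar2)))
    h <- (1 - f * rbar2) / (1 - rbar2)
    z <- (zf(r_jk) - zf(r_jh)) * sqrt((n - 3) / (2 * (1 - r_kh) * h))
  }
  list(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Two-predictor commonality decomposition of R-squared
#'
#' Partitions the R-squared of \code{y ~ x1 + x2} into the variance
#' unique to each predictor and the variance they share, from the three
#' hierarchical regressions:
#' unique_1 = R2(y~x1,x2) - R2(y~x2); unique_2 = R2(y~x1,x2) - R2(y~x1);
#' common = R2(y~x1) + R2(y~x2) - R2(y~x1,x2). The common component can
#' legitimately be negative (a suppression signature). Components sum to
#' the total by construction.
#'
#' @param y,x1,x2 Numeric vectors of equal length.
#' @return Object of class \code{commonality_result}: \code{unique_1},
#'   \code{unique_2}, \code{common}, \code{total}, and
#'   \code{pct_of_total} for each component.
#' @export
commonality_two_predictor <- function(y, x1, x2) {
  stopifnot(length(y) == length(x1), length(y) == length(x2),
            length(y) > 3)
  if (abs(stats::cor(x1, x2)) > 1 - 1e-12)
    stop("predictors are collinear", call. = FALSE)
  r2 <- function(fit) summary(fit)$r.squared
  r2_full <- r2(stats::lm(y ~ x1 + x2))
  r2_1 <- r2(stats::lm(y ~ x1))
  r2_2 <- r2(stats::lm(y ~ x2))
  u1 <- r2_full - r2_2
  u2 <- r2_full - r2_1
  com <- r2_1 + r2_2 - r2_full
  structure(list(unique_1 = u1, unique_2 = u2, common = com,
                 total = r2_full,
                 pct_of_total = 100 * c(unique_1 = u1, unique_2 = u2,
                                        common = com) / r2_full),
            class = "commonality_result")
}

#' @export
print.commonality_result <- function(x, ...) {
  tab <- data.frame(
    component = c("unique_1", "unique_2", "common", "total"),
    proportion_variance = c(x$unique_1, x$unique_2, x$common, x$total),
    pct_of_total = c(x$pct_of_total, 100))
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Trial-level linear mixed model of the flanker effect
#'
#' Fits RT (or trial-level accuracy, as a linear probability model) on
#' standardized age, compatibility (+0.5 compatible / -0.5 incompatible)
#' and centered sex with all interactions, plus by-subject random
#' intercepts and random compatibility slopes. Variance-explained
#' summaries follow the marginal/conditional decomposition (fixed-effect
#' variance over total; fixed plus random over total).
#'
#' @param trials Trial table (\code{subject_id}, \code{rt_ms},
#'   \code{correct}, \code{compatibility}).
#' @param subjects Subject table (\code{subject_id}, \code{age_years} or
#'   \code{age_z}, \code{sex}).
#' @param outcome \code{"rt"} (correct trials only) or
#'   \code{"accuracy"} (all trials, correctness as 0/1).
#' @return List: \code{fixed} (beta, SE, df, t, p per fixed effect),
#'   \code{r2_marginal}, \code{r2_conditional}, \code{converged},
#'   \code{model} (the \code{lmerMod} fit).
#' @export
fit_trial_lme <- function(trials, subjects, outcome = c("rt", "accuracy")) {
  outcome <- match.arg(outcome)
  d <- merge(trials, subjects, by = "subject_id")
  d$compat <- ifelse(d$compatibility == "compatible", 0.5, -0.5)
  d$age_std <- if (!is.null(d$age_z)) d$age_z
               else as.numeric(scale(d$age_years))
  d$sex_c <- d$sex - mean(d$sex)
  if (outcome == "rt") {
    d <- d[d$correct, ]
    d$y <- d$rt_ms
  } else {
    d$y <- as.numeric(d$correct)
  }
  fit <- lmerTest::lmer(
    y ~ age_std * compat * sex_c + (1 + compat | subject_id),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("beta", "se", "df", "t", "p")
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_rand <- sum(vc$vcov[is.na(vc$var2) & vc$grp != "Residual"])
  var_res <- vc$vcov[vc$grp == "Residual"]
  var_fix <- stats::var(as.vector(
    stats::model.matrix(fit) %*% lme4::fixef(fit)))
  tot <- var_fix + var_rand + var_res
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  if (!conv)
    warning("mixed model convergence messages: ",
            paste(fit@optinfo$conv$lme4$messages, collapse = "; "))
  list(fixed = co,
       r2_marginal = var_fix / tot,
       r2_conditional = (var_fix + var_rand) / tot,
       converged = conv,
       model = fit)
}
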