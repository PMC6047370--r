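# Closed-form instrument-strength and confounding-level calculators, and
# the first-stage instrument-exclusion statistic.

#' Correlation between the binary treatment and a binary instrument
#'
#' Closed form for `Corr(T, Z)` when `Z ~ Bernoulli(p)` and the other
#' covariates and the confounder are frozen at their means: with
#' `A_j = exp(-(alpha0 + j*alpha_z + mu1*alpha1 + mu2*alpha2 + mu_u))`,
#' \deqn{Corr(T,Z) = \frac{(1/(1+A_1) - 1/(1+A_0))\sqrt{p(1-p)}}
#'   {\sqrt{q(1-q)}}, \quad q = p/(1+A_1) + (1-p)/(1+A_0).}
#'
#' @param alpha length-4 vector `(alpha0, alpha_z, alpha1, alpha2)`.
#' @param p Bernoulli probability of the instrument, in (0, 1).
#' @param mu1,mu2 covariate means.
#' @param mu_u mean of the confounder (0 for the mean-zero confounder).
#' @return The correlation.
#' @export
corr_TZ <- function(alpha, p, mu1 = -2, mu2 = -3, mu_u = 0) {
  stopifnot(length(alpha) == 4L)
  if (p <= 0 || p >= 1) stop("`p` must lie in (0, 1)", call. = FALSE)
  A <- function(z) exp(-(alpha[[1]] + z * alpha[[2]] + mu1 * alpha[[3]] +
                           mu2 * alpha[[4]] + mu_u))
  e1 <- 1 / (1 + A(1)); e0 <- 1 / (1 + A(0))
  q <- p * e1 + (1 - p) * e0
  (e1 - e0) * sqrt(p * (1 - p)) / sqrt(q * (1 - q))
}

#' Correlation between the latent treatment index and the instrument
#'
#' Closed form for `Corr(Z, T*)` with
#' `T* = alpha0 + Z*alpha_z + X1*alpha1 + X2*alpha2 + Xu` and
#' `Z ~ Bernoulli(p)`:
#' \deqn{Corr(Z, T^*) = \frac{\alpha_z\sqrt{p(1-p)}}
#'   {(\alpha_z^2 p(1-p) + \alpha_1^2\sigma_1^2 + \alpha_2^2\sigma_2^2 +
#'   \sigma_u^2)^{1/2}}.}
#' This is the scenario-defining measure of instrument strength.
#'
#' @inheritParams corr_TZ
#' @param sigma1,sigma2 covariate standard deviations (> 0).
#' @param sigma_u confounder standard deviation (>= 0).
#' @export
corr_Tstar_Z <- function(alpha, p, sigma1 = 1, sigma2 = 1, sigma_u = 1) {
  stopifnot(length(alpha) == 4L)
  if (p <= 0 || p >= 1) stop("`p` must lie in (0, 1)", call. = FALSE)
  if (sigma1 <= 0 || sigma2 <= 0)
    stop("covariate variances must be positive", call. = FALSE)
  az <- alpha[[2]]
  az * sqrt(p * (1 - p)) /
    sqrt(az^2 * p * (1 - p) + alpha[[3]]^2 * sigma1^2 +
           alpha[[4]]^2 * sigma2^2 + sigma_u^2)
}

#' Confounding level: correlation between confounder and latent index
#'
#' Closed form for `Corr(Xu, T*)`:
#' \deqn{Corr(X_u, T^*) = \frac{\sigma_u}
#'   {(\alpha_z^2 p(1-p) + \alpha_1^2\sigma_1^2 + \alpha_2^2\sigma_2^2 +
#'   \sigma_u^2)^{1/2}}.}
#'
#' @inheritParams corr_Tstar_Z
#' @export
confounding_level <- function(alpha, p, sigma1 = 1, sigma2 = 1,
                              sigma_u = 1) {
  stopifnot(length(alpha) == 4L)
  if (p <= 0 || p >= 1) stop("`p` must lie in (0, 1)", call. = FALSE)
  if (sigma1 <= 0 || sigma2 <= 0)
    stop("covariate variances must be positive", call. = FALSE)
  az <- alpha[[2]]
  sigma_u / sqrt(az^2 * p * (1 - p) + alpha[[3]]^2 * sigma1^2 +
                   alpha[[4]]^2 * sigma2^2 + sigma_u^2)
}

#' First-stage instrument-exclusion statistic
#'
#' Analogue of the first-stage F-statistic of linear IV regression for the
#' logistic treatment model: by default the squared Wald z-statistic of
#' the instrument coefficient in the logistic regression of `T` on
#' `(1, instrument, X1, X2)` (one instrument, so the Wald chi-square on
#' 1 df divided by the number of instruments). A likelihood-ratio variant
#' (`type = "lr"`, twice the log-likelihood drop when the instrument is
#' excluded) is available. This Wald-z-squared definition is the
#' package's own, stated here because the linear-regression analogue has
#' no unique nonlinear counterpart.
#'
#' @param cohort a cohort with proxies attached.
#' @param instrument `"pr"` or `"zstar"`.
#' @param type `"wald"` (default) or `"lr"`.
#' @return The statistic; `NA` with a warning when the first-stage fit
#'   does not converge.
#' @export
first_stage_F <- function(cohort, instrument = c("pr", "zstar"),
                          type = c("wald", "lr")) {
  instrument <- match.arg(instrument)
  type <- match.arg(type)
  fs <- fit_first_stage(cohort, instrument, loss = "ml")
  if (!fs$converged) {
    warning("first-stage fit did not converge; F-equivalent undefined",
            call. = FALSE)
    return(NA_real_)
  }
  if (type == "wald") {
    z <- fs$coef[[instrument]] / sqrt(fs$vcov[instrument, instrument])
    return(z^2)
  }
  d <- estimation_sample(cohort)
  w0 <- cbind(`(Intercept)` = rep(1, nrow(d)), X1 = d$X1, X2 = d$X2)
  f0 <- fit_logistic_ml(d$T, w0)
  ll <- function(mu, y) sum(y * log(mu) + (1 - y) * log1p(-mu))
  2 * (ll(fs$fitted, d$T) - ll(f0$fitted, d$T))
}

#' Closed-form diagnostics for a scenario configuration
#'
#' Convenience wrapper returning the instrument strength measured on the
#' treatment scale (`corr_TZ`), on the latent-index scale
#' (`corr_Tstar_Z`) and the confounding level (`corr_Tstar_Xu`), all from
#' the closed forms. When a cohort with proxies is supplied, the
#' first-stage instrument-exclusion statistic is added.
#'
#' @param config an [scenario_config()].
#' @param cohort optional cohort with proxies for the F-equivalent.
#' @param instrument proxy used for the F-equivalent.
#' @return A named list of class `iv_diagnostics`.
#' @export
diagnose_scenario <- function(config, cohort = NULL, instrument = "pr") {
  stopifnot(inherits(config, "iv_scenario_config"))
  out <- list(
    corr_TZ = corr_TZ(config$alpha, config$p_pp, config$mu1, config$mu2, 0),
    corr_Tstar_Z = corr_Tstar_Z(config$alpha, config$p_pp, config$sigma1,
                                config$sigma2, config$sigma_u),
    corr_Tstar_Xu = confounding_level(config$alpha, config$p_pp,
                                      config$sigma1, config$sigma2,
                                      config$sigma_u),
    f_stat = if (!is.null(cohort))
      first_stage_F(cohort, instrument) else NA_real_
  )
  class(out) <- "iv_diagnostics"
  out
}

#' @export
print.iv_diagnostics <- function(x, ...) {
  cat("Instrument strength Corr(T, Z):   ", sprintf("%.4f", x$corr_TZ), "\n")
  cat("Instrument strength Corr(Z, T*):  ", sprintf("%.4f", x$corr_Tstar_Z),
      "\n")
  cat("Confounding level Corr(Xu, T*):   ", sprintf("%.4f", x$corr_Tstar_Xu),
      "\n")
  if (!is.na(x$f_stat))
    cat("First-stage F-equivalent:         ", sprintf("%.2f", x$f_stat), "\n")
  invisible(x)
}
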