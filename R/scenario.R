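#' Scenario configuration for the cohort simulator
#'
#' Bundles every generative parameter of the physician-clustered cohort
#' model: patients are nested under physicians, a binary physician-level
#' prescribing preference `PP ~ Bernoulli(p_pp)` drives treatment choice
#' through a logistic index, and a normal unmeasured confounder `Xu` enters
#' both the treatment and the outcome index.
#'
#' The treatment model is
#' `P(T=1) = expit(alpha0 + PP*alpha_z + X1*alpha1 + X2*alpha2 + Xu)`
#' and the outcome model is
#' `P(Y=1) = expit(beta0 + T*beta_t + X1*beta1 + X2*beta2 + Xu*beta_u)`.
#'
#' @param n total number of patients; must be a positive multiple of `m`.
#' @param m patients per physician (default 100).
#' @param alpha numeric length-4 vector `(alpha0, alpha_z, alpha1, alpha2)`
#'   of treatment-model coefficients. The confounder enters with a fixed
#'   unit coefficient.
#' @param beta numeric length-5 vector
#'   `(beta0, beta_t, beta1, beta2, beta_u)` of outcome-model coefficients.
#' @param sigma_u standard deviation of the confounder `Xu` (>= 0). Values
#'   0.5, 1 and 1.5 correspond to low, medium and high confounding.
#' @param p_pp Bernoulli probability that a physician prefers the treatment
#'   of interest (default 0.7).
#' @param mu1,mu2 means of the covariates `X1` and `X2` (defaults -2, -3).
#' @param sigma1,sigma2 standard deviations of `X1`, `X2` (defaults 1, 1).
#' @param ns number of Monte-Carlo replications for study runs.
#' @param seed default RNG seed used by [simulate_cohort()] and
#'   [run_scenario()] when no seed is passed explicitly.
#'
#' @return An object of class `iv_scenario_config` (a named list).
#' @seealso [scenario_preset()] for the named strength/confounding grid.
#' @export
scenario_config <- function(n, m = 100L,
                            alpha = c(0.2, 2, 2, 1.2),
                            beta = c(-0.6, 3, 1, 1, 1),
                            sigma_u = 1,
                            p_pp = 0.7,
                            mu1 = -2, mu2 = -3,
                            sigma1 = 1, sigma2 = 1,
                            ns = 200L, seed = 1L) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || n <= 0L || is.na(m) || m <= 0L)
    stop("`n` and `m` must be positive integers", call. = FALSE)
  if (n %% m != 0L)
    stop("`n` must be divisible by `m` (patients per physician)", call. = FALSE)
  if (length(alpha) != 4L || anyNA(alpha) || !all(is.finite(alpha)))
    stop("`alpha` must be 4 finite values (alpha0, alpha_z, alpha1, alpha2)",
         call. = FALSE)
  if (length(beta) != 5L || anyNA(beta) || !all(is.finite(beta)))
    stop("`beta` must be 5 finite values (beta0, beta_t, beta1, beta2, beta_u)",
         call. = FALSE)
  if (sigma_u < 0) stop("`sigma_u` must be >= 0", call. = FALSE)
  if (p_pp <= 0 || p_pp >= 1) stop("`p_pp` must lie in (0, 1)", call. = FALSE)
  if (sigma1 <= 0 || sigma2 <= 0)
    stop("covariate standard deviations must be > 0", call. = FALSE)
  cfg <- list(
    n = n, m = m,
    alpha = stats::setNames(as.numeric(alpha),
                            c("alpha0", "alpha_z", "alpha1", "alpha2")),
    beta = stats::setNames(as.numeric(beta),
                           c("beta0", "beta_t", "beta1", "beta2", "beta_u")),
    sigma_u = sigma_u, p_pp = p_pp,
    mu1 = mu1, mu2 = mu2, sigma1 = sigma1, sigma2 = sigma2,
    ns = as.integer(ns), seed = as.integer(seed)
  )
  class(cfg) <- "iv_scenario_config"
  cfg
}

#' Named scenario presets on the strength-by-confounding grid
#'
#' The study design varies the instrument coefficient `alpha_z` over
#' \{1, 2, 3\} (weak, moderate, strong instrument) and the confounder
#' standard deviation `sigma_u` over \{0.5, 1, 1.5\} (low, medium, high
#' confounding), keeping all other parameters fixed. Two exposure regimes
#' are provided: `"rare"` (`alpha0 = 0.2`, `beta0 = -0.6`; exposure
#' prevalence roughly 2--6\% and event prevalence below 5\%) and
#' `"balanced"` (`alpha0 = 5`, `beta0 = -2.3`; exposure 26--45\%).
#'
#' @param strength instrument strength, one of `"weak"`, `"moderate"`,
#'   `"strong"` (`alpha_z` = 1, 2, 3).
#' @param confounding one of `"low"`, `"medium"`, `"high"`
#'   (`sigma_u` = 0.5, 1, 1.5).
#' @param n cohort size (default 30000).
#' @param regime `"rare"` or `"balanced"` exposure regime.
#' @param ... further arguments passed to [scenario_config()]
#'   (e.g. `ns`, `seed`, `m`).
#' @return An `iv_scenario_config`.
#' @export
scenario_preset <- function(strength = c("weak", "moderate", "strong"),
                            confounding = c("low", "medium", "high"),
                            n = 30000L,
                            regime = c("rare", "balanced"), ...) {
  strength <- match.arg(strength)
  confounding <- match.arg(confounding)
  regime <- match.arg(regime)
  alpha_z <- c(weak = 1, moderate = 2, strong = 3)[[strength]]
  sigma_u <- c(low = 0.5, medium = 1, high = 1.5)[[confounding]]
  alpha0 <- if (regime == "rare") 0.2 else 5
  beta0 <- if (regime == "rare") -0.6 else -2.3
  scenario_config(n = n,
                  alpha = c(alpha0, alpha_z, 2, 1.2),
                  beta = c(beta0, 3, 1, 1, 1),
                  sigma_u = sigma_u, ...)
}

#' Read a scenario grid from a YAML or JSON file
#'
#' The file holds a list of entries, each with fields `strength`
#' (`weak`/`moderate`/`strong`, abbreviation `mod` accepted), `confounding`
#' (`low`/`medium`/`high`, abbreviation `med` accepted) and `n`, plus
#' optional overrides (`regime`, `ns`, `seed`, `m`).
#'
#' @param path file path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return A named list of `iv_scenario_config` objects, keyed
#'   `strength_confounding_n`.
#' @export
read_scenario_grid <- function(path) {
  entries <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!length(entries)) stop("empty scenario grid file", call. = FALSE)
  out <- lapply(entries, function(e) {
    # a bare `n:` key is YAML shorthand for boolean false; undo that
    if (!"n" %in% names(e) && "FALSE" %in% names(e))
      names(e)[names(e) == "FALSE"] <- "n"
    strength <- switch(tolower(e$strength),
                       weak = "weak", mod = "moderate", moderate = "moderate",
                       strong = "strong",
                       stop("unknown strength: ", e$strength, call. = FALSE))
    confounding <- switch(tolower(e$confounding),
                          low = "low", med = "medium", medium = "medium",
                          high = "high",
                          stop("unknown confounding: ", e$confounding,
                               call. = FALSE))
    extra <- e[intersect(names(e), c("ns", "seed", "m"))]
    do.call(scenario_preset,
            c(list(strength = strength, confounding = confounding,
                   n = e$n %||% 30000L,
                   regime = e$regime %||% "rare"),
              extra))
  })
  names(out) <- vapply(out, function(cfg) {
    paste(scenario_labels(cfg)$strength, scenario_labels(cfg)$confounding,
          cfg$n, sep = "_")
  }, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Map a config back to grid labels; "custom" when off the canonical grid.
scenario_labels <- function(config) {
  az <- config$alpha[["alpha_z"]]
  su <- config$sigma_u
  strength <- if (isTRUE(all.equal(az, 1))) "weak"
  else if (isTRUE(all.equal(az, 2))) "moderate"
  else if (isTRUE(all.equal(az, 3))) "strong"
  else "custom"
  confounding <- if (isTRUE(all.equal(su, 0.5))) "low"
  else if (isTRUE(all.equal(su, 1))) "medium"
  else if (isTRUE(all.equal(su, 1.5))) "high"
  else "custom"
  regime <- if (isTRUE(all.equal(config$alpha[["alpha0"]], 5))) "balanced"
  else "rare"
  list(strength = strength, confounding = confounding, regime = regime)
}

#' @export
print.iv_scenario_config <- function(x, ...) {
  lab <- scenario_labels(x)
  cat("Scenario configuration (", lab$regime, " exposure regime)\n", sep = "")
  cat("  n =", x$n, " patients,", x$n %/% x$m, "physicians x", x$m,
      "patients\n")
  cat("  instrument strength:", lab$strength,
      sprintf("(alpha_z = %g)", x$alpha[["alpha_z"]]), "\n")
  cat("  confounding:", lab$confounding,
      sprintf("(sigma_u = %g)", x$sigma_u), "\n")
  cat("  alpha:", paste(sprintf("%s=%g", names(x$alpha), x$alpha),
                        collapse = ", "), "\n")
  cat("  beta: ", paste(sprintf("%s=%g", names(x$beta), x$beta),
                        collapse = ", "), "\n")
  cat("  X1 ~ N(", x$mu1, ",", x$sigma1^2, "), X2 ~ N(", x$mu2, ",",
      x$sigma2^2, "), Xu ~ N(0,", x$sigma_u^2, "), PP ~ Bern(",
      x$p_pp, ")\n", sep = "")
  cat("  ns =", x$ns, " replications, seed =", x$seed, "\n")
  invisible(x)
}
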