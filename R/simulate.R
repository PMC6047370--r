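# Sub-stream seeds: one root seed per cohort, one deterministic sub-seed per
# variable (and per replication in study runs), so that adding a variable to
# the generator never perturbs the draws of earlier variables.
sub_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 1103515 + as.double(k) * 12820163
  as.integer(s %% 2147483647 + 1)
}

# Draw order (documented contract, one RNG sub-stream each):
#   1 PP (one Bernoulli per physician), 2 X1, 3 X2, 4 Xu, 5 T, 6 Y.
.substream <- c(PP = 1L, X1 = 2L, X2 = 3L, Xu = 4L, T = 5L, Y = 6L)

#' Simulate a physician-clustered cohort
#'
#' Generates `n` patients nested in `n/m` physicians. Physician preference
#' `PP` is one Bernoulli(`p_pp`) draw per physician, shared by all of that
#' physician's patients. Covariates `X1 ~ N(mu1, sigma1^2)`,
#' `X2 ~ N(mu2, sigma2^2)` and the confounder `Xu ~ N(0, sigma_u^2)` are
#' independent across patients. Treatment and outcome are Bernoulli draws
#' from the logistic indices
#' `expit(alpha0 + PP*alpha_z + X1*alpha1 + X2*alpha2 + Xu)` and
#' `expit(beta0 + T*beta_t + X1*beta1 + X2*beta2 + Xu*beta_u)`.
#'
#' Each variable is drawn from its own RNG sub-stream derived
#' deterministically from `seed`, in the fixed order PP, X1, X2, Xu, T, Y;
#' cohorts are therefore bit-reproducible for a given seed.
#'
#' @param config an [scenario_config()] object.
#' @param seed integer root seed; defaults to `config$seed`.
#' @return A `data.frame` of class `iv_cohort` with columns
#'   `physician_id`, `order` (within-physician generation order), `X1`,
#'   `X2`, `Xu`, `PP`, `T`, `Y`. The configuration is kept in
#'   `attr(, "config")`. Use [attach_proxies()] to add the instrument
#'   proxies.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "iv_scenario_config"))
  n <- config$n; m <- config$m
  n_phys <- n %/% m
  a <- config$alpha; b <- config$beta

  with_seed <- function(var, expr) {
    set.seed(sub_seed(seed, .substream[[var]]))
    expr
  }
  PP_phys <- with_seed("PP", stats::rbinom(n_phys, 1L, config$p_pp))
  PP <- rep(PP_phys, each = m)
  X1 <- with_seed("X1", stats::rnorm(n, config$mu1, config$sigma1))
  X2 <- with_seed("X2", stats::rnorm(n, config$mu2, config$sigma2))
  Xu <- if (config$sigma_u > 0) {
    with_seed("Xu", stats::rnorm(n, 0, config$sigma_u))
  } else {
    numeric(n)
  }
  pT <- stats::plogis(a[["alpha0"]] + PP * a[["alpha_z"]] +
                        X1 * a[["alpha1"]] + X2 * a[["alpha2"]] + Xu)
  T <- with_seed("T", stats::rbinom(n, 1L, pT))
  pY <- stats::plogis(b[["beta0"]] + T * b[["beta_t"]] +
                        X1 * b[["beta1"]] + X2 * b[["beta2"]] +
                        Xu * b[["beta_u"]])
  Y <- with_seed("Y", stats::rbinom(n, 1L, pY))

  cohort <- data.frame(
    physician_id = rep(seq_len(n_phys), each = m),
    order = rep(seq_len(m), times = n_phys),
    X1 = X1, X2 = X2, Xu = Xu, PP = PP, T = T, Y = Y
  )
  attr(cohort, "config") <- config
  class(cohort) <- c("iv_cohort", "data.frame")
  cohort
}

#' Attach physician-preference proxy instruments to a cohort
#'
#' Builds the two proxies of the latent physician preference from observed
#' prescribing history: `Zstar`, the treatment prescribed to the
#' immediately preceding patient of the same physician, and `pr`, the
#' proportion of all earlier patients of the same physician who received
#' the treatment of interest. Both are undefined for each physician's first
#' patient; those rows get `valid_proxy = FALSE` (and `NA` proxies) and are
#' excluded from estimation samples.
#'
#' @param cohort a data frame with columns `physician_id`, `order`, `T`,
#'   sorted by `(physician_id, order)` without duplicates.
#' @return The cohort with columns `Zstar`, `pr` and `valid_proxy` added.
#' @export
attach_proxies <- function(cohort) {
  req <- c("physician_id", "order", "T")
  if (!all(req %in% names(cohort)))
    stop("cohort must have columns physician_id, order, T", call. = FALSE)
  key <- order(cohort$physician_id, cohort$order)
  if (!identical(key, seq_len(nrow(cohort))))
    stop("cohort must be sorted by (physician_id, order)", call. = FALSE)
  if (anyDuplicated(cohort[c("physician_id", "order")]))
    stop("duplicated (physician_id, order) pairs", call. = FALSE)

  pid <- cohort$physician_id
  tr <- cohort$T
  # within-physician running index and cumulative treated count
  idx <- stats::ave(rep(1, nrow(cohort)), pid, FUN = cumsum)
  ctr <- stats::ave(tr, pid, FUN = cumsum)
  first <- idx == 1
  prev_idx <- seq_along(tr) - 1L
  prev_idx[first] <- NA_integer_
  prev <- tr[prev_idx]   # NA index keeps T's storage type
  pr <- (ctr - tr) / (idx - 1)
  pr[first] <- NA_real_
  cohort$Zstar <- prev
  cohort$pr <- pr
  cohort$valid_proxy <- !first
  cohort
}

# Rows used for estimation: proxy-valid patients when proxies are attached,
# otherwise the whole cohort.
estimation_sample <- function(cohort) {
  if ("valid_proxy" %in% names(cohort)) cohort[cohort$valid_proxy, , drop = FALSE]
  else cohort
}

#' Check equivalence of the latent-index and Bernoulli outcome generators
#'
#' The binary outcome can be generated either as
#' `Y = 1(Y* - eps > 0)` with `Y*` the linear index and `eps` standard
#' logistic, or directly as `Y ~ Bernoulli(expit(Y*))`. The two
#' constructions are distributionally identical; this routine simulates
#' both on a common set of linear predictors and tests whether the two
#' outcome prevalences agree within three Monte-Carlo standard errors.
#'
#' @param config an [scenario_config()] object supplying the index model.
#' @param seed integer seed.
#' @param n_mc number of patients to simulate.
#' @return `TRUE`/`FALSE`; the two prevalences and the tolerance are
#'   attached as attributes.
#' @export
index_function_equivalence_check <- function(config, seed = 1L,
                                             n_mc = 100000L) {
  stopifnot(inherits(config, "iv_scenario_config"))
  b <- config$beta
  n_mc <- as.integer(n_mc)
  if (n_mc <= 0L) stop("`n_mc` must be positive", call. = FALSE)

  set.seed(sub_seed(seed, 101L))
  X1 <- stats::rnorm(n_mc, config$mu1, config$sigma1)
  X2 <- stats::rnorm(n_mc, config$mu2, config$sigma2)
  Xu <- stats::rnorm(n_mc, 0, config$sigma_u)
  PP <- stats::rbinom(n_mc, 1L, config$p_pp)
  a <- config$alpha
  T <- stats::rbinom(n_mc, 1L, stats::plogis(
    a[["alpha0"]] + PP * a[["alpha_z"]] + X1 * a[["alpha1"]] +
      X2 * a[["alpha2"]] + Xu))
  ystar <- b[["beta0"]] + T * b[["beta_t"]] + X1 * b[["beta1"]] +
    X2 * b[["beta2"]] + Xu * b[["beta_u"]]

  set.seed(sub_seed(seed, 102L))
  y_bern <- stats::rbinom(n_mc, 1L, stats::plogis(ystar))
  set.seed(sub_seed(seed, 103L))
  y_index <- as.integer(ystar - stats::rlogis(n_mc) > 0)

  p1 <- mean(y_bern); p2 <- mean(y_index)
  pbar <- (p1 + p2) / 2
  tol <- 3 * sqrt(2 * pbar * (1 - pbar) / n_mc)
  ok <- abs(p1 - p2) <= tol
  structure(ok, prevalence_bernoulli = p1, prevalence_index = p2,
            tolerance = tol)
}

#' Write / read a cohort as headered CSV
#'
#' The on-disk format has columns `physician_id, order, X1, X2, Xu, PP, T,
#' Y, Zstar, pr, valid_proxy`. On read, `Xu` and `PP` may be absent (user
#' data where the confounder and latent preference are unobserved), as may
#' the proxy columns (recomputable with [attach_proxies()]).
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   an `iv_cohort` data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path)
  req <- c("physician_id", "order", "T", "Y", "X1", "X2")
  miss <- setdiff(req, names(cohort))
  if (length(miss))
    stop("cohort file missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if ("valid_proxy" %in% names(cohort))
    cohort$valid_proxy <- as.logical(cohort$valid_proxy)
  class(cohort) <- c("iv_cohort", "data.frame")
  cohort
}
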