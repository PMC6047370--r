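# Internal fitting engines shared by all estimators, plus the iv_fit class.

expit <- stats::plogis

new_iv_fit <- function(method, coef, vcov, converged, n_used,
                       level = 0.95, status = if (converged) "ok" else "nonconverged",
                       notes = character(), ...) {
  k <- length(coef)
  if (is.null(vcov)) vcov <- matrix(NA_real_, k, k)
  dimnames(vcov) <- list(names(coef), names(coef))
  fit <- list(method = method, coef = coef, vcov = vcov,
              converged = converged, status = status, n_used = n_used,
              level = level, notes = notes, ...)
  fit$ci <- wald_ci(coef, vcov, level)
  class(fit) <- "iv_fit"
  fit
}

wald_ci <- function(coef, vcov, level) {
  se <- sqrt(pmax(diag(vcov), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(lower = coef - z * se, upper = coef + z * se)
}

# Maximum-likelihood logistic fit on an explicit design matrix.
# Flags quasi-complete separation (fitted probabilities pinned at 0/1 with
# runaway coefficients) as non-convergence.
fit_logistic_ml <- function(y, X) {
  if (qr(X)$rank < ncol(X))
    stop("singular design matrix in logistic fit", call. = FALSE)
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  coef <- fit$coefficients
  mu <- fit$fitted.values
  separation <- any(mu < 1e-10 | mu > 1 - 1e-10) && max(abs(coef)) > 15
  converged <- isTRUE(fit$converged) && !separation && all(is.finite(coef))
  w <- mu * (1 - mu)
  info <- crossprod(X, w * X)
  vcov <- tryCatch(solve(info), error = function(e) {
    converged <<- FALSE
    matrix(NA_real_, ncol(X), ncol(X))
  })
  list(coef = coef, vcov = vcov, fitted = mu, residuals = y - mu,
       converged = converged)
}

# Nonlinear least-squares logistic fit: minimizes sum (y - expit(X b))^2
# by Levenberg-Marquardt with analytic Jacobian, started at the ML
# solution (or zero when ML itself fails).
fit_logistic_nls <- function(y, X, start = NULL) {
  if (is.null(start)) {
    ml <- tryCatch(fit_logistic_ml(y, X), error = function(e) NULL)
    start <- if (!is.null(ml) && all(is.finite(ml$coef))) ml$coef
    else numeric(ncol(X))
  }
  resid_fn <- function(b) y - as.vector(expit(X %*% b))
  jac_fn <- function(b) {
    mu <- as.vector(expit(X %*% b))
    -(mu * (1 - mu)) * X
  }
  out <- minpack.lm::nls.lm(par = start, fn = resid_fn, jac = jac_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  coef <- stats::setNames(out$par, colnames(X))
  mu <- as.vector(expit(X %*% coef))
  converged <- out$info %in% 1:4 && all(is.finite(coef))
  list(coef = coef, fitted = mu, residuals = y - mu, converged = converged,
       info = out$info)
}

# One-step sandwich M^-1 S M^-1 / n for an NLS logistic stage; used as the
# standalone vcov of a single stage (the 2SRI sandwich supersedes it for
# the corrected second stage).
nls_stage_vcov <- function(X, fitted, residuals) {
  w <- fitted * (1 - fitted)
  M <- crossprod(w * X) / nrow(X)
  S <- crossprod(w * residuals * X) / nrow(X)
  Mi <- solve(M)
  (Mi %*% S %*% t(Mi)) / nrow(X)
}

design_outcome <- function(data, include_xu = FALSE, resid_col = NULL) {
  cols <- list(`(Intercept)` = rep(1, nrow(data)), T = data$T,
               X1 = data$X1, X2 = data$X2)
  if (include_xu) cols$Xu <- data$Xu
  if (!is.null(resid_col)) cols$residual <- resid_col
  do.call(cbind, cols)
}

design_treatment <- function(data, instrument) {
  Z <- data[[instrument]]
  if (is.null(Z)) stop("instrument column `", instrument, "` not found",
                       call. = FALSE)
  if (anyNA(Z)) stop("instrument has missing values on the estimation sample",
                     call. = FALSE)
  if (stats::var(Z) == 0)
    stop("singular design: instrument `", instrument, "` is constant",
         call. = FALSE)
  X <- cbind(`(Intercept)` = rep(1, nrow(data)), Z, data$X1, data$X2)
  colnames(X) <- c("(Intercept)", instrument, "X1", "X2")
  X
}

#' Benchmark logistic fit of the outcome model with the confounder observed
#'
#' Maximum-likelihood logistic regression of `Y` on
#' `(1, T, X1, X2, Xu)`. Only possible on simulated data where the
#' confounder `Xu` is recorded; serves as the oracle benchmark against
#' which the IV estimators are judged.
#'
#' @param cohort a cohort data frame (proxy-valid patients are used when
#'   proxies are attached, so all methods share one estimation sample).
#' @param level nominal confidence level for Wald intervals.
#' @return An `iv_fit` object.
#' @export
fit_true <- function(cohort, level = 0.95) {
  if (!"Xu" %in% names(cohort) || all(is.na(cohort$Xu)))
    stop("fit_true needs the confounder column `Xu` (simulated data only)",
         call. = FALSE)
  d <- estimation_sample(cohort)
  X <- design_outcome(d, include_xu = TRUE)
  fit <- fit_logistic_ml(d$Y, X)
  new_iv_fit("true", stats::setNames(fit$coef, colnames(X)), fit$vcov,
             fit$converged, nrow(d), level,
             fitted = fit$fitted, residuals = fit$residuals)
}

#' Conventional logistic fit ignoring the unmeasured confounder
#'
#' Maximum-likelihood logistic regression of `Y` on `(1, T, X1, X2)`,
#' i.e. the analysis a practitioner without access to `Xu` would run.
#' Its treatment coefficient is biased when the confounder is active.
#'
#' @inheritParams fit_true
#' @return An `iv_fit` object.
#' @export
fit_conventional <- function(cohort, level = 0.95) {
  d <- estimation_sample(cohort)
  X <- design_outcome(d)
  fit <- fit_logistic_ml(d$Y, X)
  new_iv_fit("conventional", stats::setNames(fit$coef, colnames(X)),
             fit$vcov, fit$converged, nrow(d), level,
             fitted = fit$fitted, residuals = fit$residuals)
}

#' First-stage treatment model on a preference proxy
#'
#' Regression of the binary treatment on `(1, proxy, X1, X2)` over the
#' proxy-valid patients, by logistic maximum likelihood (default) or
#' nonlinear least squares. The raw residuals `T - expit(w'alpha_hat)` are
#' stored; they become the extra regressor of the 2SRI second stage.
#'
#' @param cohort a cohort with proxies attached (see [attach_proxies()]).
#' @param instrument `"pr"` (running proportion treated) or `"zstar"`
#'   (previous patient's treatment).
#' @param loss `"ml"` or `"nls"`.
#' @param level nominal confidence level.
#' @return An `iv_fit` with elements `residuals`, `fitted` and the design
#'   matrix `w`.
#' @export
fit_first_stage <- function(cohort, instrument = c("pr", "zstar"),
                            loss = c("ml", "nls"), level = 0.95) {
  instrument <- match.arg(instrument)
  loss <- match.arg(loss)
  col <- c(pr = "pr", zstar = "Zstar")[[instrument]]
  if (!col %in% names(cohort))
    stop("proxies not attached; run attach_proxies() first", call. = FALSE)
  d <- estimation_sample(cohort)
  w <- design_treatment(d, col)
  colnames(w)[2] <- instrument
  fit <- if (loss == "ml") fit_logistic_ml(d$T, w)
  else fit_logistic_nls(d$T, w)
  vcov <- if (loss == "ml") fit$vcov
  else nls_stage_vcov(w, fit$fitted, fit$residuals)
  new_iv_fit("first_stage", stats::setNames(fit$coef, colnames(w)), vcov,
             fit$converged, nrow(d), level, status = if (fit$converged)
               "ok" else "nonconverged",
             loss = loss, instrument = instrument,
             fitted = fit$fitted, residuals = fit$residuals, w = w)
}

#' Fit an instrumental-variable (or benchmark) estimator
#'
#' Single front door to the four estimators compared in the package:
#' the benchmark logistic fit with the confounder observed (`"true"`),
#' the conventional logistic fit omitting it (`"conventional"`),
#' two-stage residual inclusion (`"2sri"`, see [fit_2sri()]) and the
#' nonlinear IV-GMM (`"gmm"`, see [fit_gmm()]).
#'
#' @param cohort a cohort data frame; for the IV methods, proxies must be
#'   attached with [attach_proxies()].
#' @param method estimator to fit.
#' @param instrument preference proxy used by the IV methods: `"pr"` or
#'   `"zstar"`.
#' @param level nominal confidence level for Wald intervals.
#' @param ... further arguments passed to the method-specific fitter
#'   (e.g. `stage_loss` for 2SRI, `weight_scheme` for GMM).
#' @return An object of class `iv_fit` with `print`, `summary`, `coef`,
#'   `vcov`, `confint`, `residuals` and `predict` methods.
#' @examples
#' cfg <- scenario_preset("strong", "high", n = 5000, ns = 1, seed = 7)
#' coh <- attach_proxies(simulate_cohort(cfg))
#' fit <- iv_fit(coh, "2sri", instrument = "pr")
#' summary(fit)
#' @export
iv_fit <- function(cohort, method = c("true", "conventional", "2sri", "gmm"),
                   instrument = c("pr", "zstar"), level = 0.95, ...) {
  method <- match.arg(method)
  instrument <- match.arg(instrument)
  switch(method,
         true = fit_true(cohort, level = level),
         conventional = fit_conventional(cohort, level = level),
         `2sri` = fit_2sri(cohort, instrument = instrument, level = level,
                           ...),
         gmm = fit_gmm(cohort, instrument = instrument, level = level, ...))
}

#' @export
coef.iv_fit <- function(object, ...) object$coef

#' @export
vcov.iv_fit <- function(object, ...) object$vcov

#' @export
confint.iv_fit <- function(object, parm, level = NULL, ...) {
  level <- level %||% object$level
  ci <- wald_ci(object$coef, object$vcov, level)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
residuals.iv_fit <- function(object, ...) object$residuals

#' @export
predict.iv_fit <- function(object, newdata = NULL,
                           type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$fitted))
      stop("fitted values not stored for this method", call. = FALSE)
    return(if (type == "response") object$fitted
           else stats::qlogis(object$fitted))
  }
  nm <- names(object$coef)
  vars <- setdiff(nm, c("(Intercept)", "residual"))
  miss <- setdiff(vars, names(newdata))
  if (length(miss))
    stop("newdata lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- cbind(1, as.matrix(newdata[vars]))
  b <- object$coef[c("(Intercept)", vars)]
  eta <- as.vector(X %*% b)
  if ("residual" %in% nm)
    warning("linear predictor omits the residual term for new data",
            call. = FALSE)
  if (type == "response") expit(eta) else eta
}

#' @export
print.iv_fit <- function(x, ...) {
  cat("IV fit, method =", x$method,
      if (!is.null(x$instrument)) paste0("(instrument: ", x$instrument, ")"),
      "\n")
  cat("n =", x$n_used, "; converged:", x$converged,
      if (!identical(x$status, "ok")) paste0("[", x$status, "]"), "\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' @export
summary.iv_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  z <- object$coef / se
  tab <- cbind(Estimate = object$coef, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)),
               object$ci)
  out <- list(method = object$method, instrument = object$instrument,
              table = tab, converged = object$converged,
              status = object$status, n_used = object$n_used,
              level = object$level)
  class(out) <- "summary.iv_fit"
  out
}

#' @export
print.summary.iv_fit <- function(x, ...) {
  cat("Method:", x$method,
      if (!is.null(x$instrument)) paste0("(instrument: ", x$instrument, ")"),
      "\n")
  cat("Observations used:", x$n_used, "; converged:", x$converged, "\n\n")
  stats::printCoefmat(x$table[, 1:4, drop = FALSE], signif.stars = FALSE)
  cat(sprintf("\n%.0f%% Wald confidence intervals:\n", 100 * x$level))
  print(round(x$table[, 5:6, drop = FALSE], 4))
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Writes method label, named coefficients, row-major covariance,
#' confidence intervals, convergence flag and sample size.
#'
#' @param fit an `iv_fit`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @export
write_fit_json <- function(fit, path = NULL) {
  obj <- list(method = fit$method,
              coef = as.list(fit$coef),
              vcov = as.vector(t(fit$vcov)),
              ci = list(lower = unname(fit$ci[, "lower"]),
                        upper = unname(fit$ci[, "upper"])),
              converged = fit$converged,
              status = fit$status,
              n_used = fit$n_used)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
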