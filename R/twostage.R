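#' Two-stage residual inclusion estimator
#'
#' First stage: regression of the binary treatment on
#' `(1, proxy, X1, X2)`. Second stage: regression of the outcome on
#' `(1, T, X1, X2, U_alpha)` where `U_alpha = T - expit(w'alpha_hat)` is
#' the raw first-stage residual; the residual column stands in for the
#' unmeasured confounder, and its coefficient plays the role of
#' `beta_u`. Both stages use nonlinear least squares by default
#' (`stage_loss = "nls"`), which is the loss under which the two-step
#' sandwich covariance of [sandwich_covariance_2sri()] is derived;
#' `stage_loss = "ml"` fits both stages by logistic maximum likelihood
#' instead.
#'
#' @param cohort a cohort with proxies attached.
#' @param instrument `"pr"` or `"zstar"`.
#' @param stage_loss `"nls"` (default) or `"ml"`, applied to both stages.
#' @param residual optional numeric vector overriding the first-stage
#'   residual column (length = estimation sample); used for validation,
#'   e.g. supplying the true confounder shows the second stage then
#'   reproduces the benchmark fit.
#' @param level nominal confidence level.
#' @return An object of class `c("iv_fit_2sri", "iv_fit")`. `coef`/`vcov`
#'   refer to the corrected second stage; the first-stage `iv_fit` is in
#'   `$first`.
#' @export
fit_2sri <- function(cohort, instrument = c("pr", "zstar"),
                     stage_loss = c("nls", "ml"), residual = NULL,
                     level = 0.95) {
  instrument <- match.arg(instrument)
  stage_loss <- match.arg(stage_loss)
  first <- fit_first_stage(cohort, instrument, loss = stage_loss,
                           level = level)
  if (!first$converged) {
    k <- 5L
    fit <- new_iv_fit("2sri", stats::setNames(rep(NA_real_, k),
                                              c("(Intercept)", "T", "X1", "X2",
                                                "residual")),
                      NULL, FALSE, first$n_used, level,
                      status = "nonconverged", instrument = instrument,
                      stage_loss = stage_loss, first = first)
    class(fit) <- c("iv_fit_2sri", "iv_fit")
    return(fit)
  }
  d <- estimation_sample(cohort)
  Ua <- if (is.null(residual)) first$residuals else {
    stopifnot(length(residual) == nrow(d))
    residual
  }
  X <- design_outcome(d, resid_col = Ua)
  second <- if (stage_loss == "ml") fit_logistic_ml(d$Y, X)
  else fit_logistic_nls(d$Y, X)
  coef <- stats::setNames(second$coef, colnames(X))
  converged <- second$converged
  parts <- list(w = first$w, X = X,
                Pa = first$fitted, Pb = second$fitted,
                Ua = Ua, Ub = second$residuals,
                beta_u = unname(coef["residual"]))
  vcov <- if (converged)
    tryCatch(sandwich_covariance_2sri(parts),
             error = function(e) {
               converged <<- FALSE
               NULL
             })
  else NULL
  fit <- new_iv_fit("2sri", coef, vcov, converged, nrow(d), level,
                    status = if (converged) "ok" else "nonconverged",
                    instrument = instrument, stage_loss = stage_loss,
                    first = first, fitted = second$fitted,
                    residuals = second$residuals, sandwich_parts = parts)
  class(fit) <- c("iv_fit_2sri", "iv_fit")
  fit
}

#' Plug-in blocks of the 2SRI two-step sandwich covariance
#'
#' Computes the six plug-in matrices entering the two-step covariance:
#' with `w` the first-stage design, `X` the second-stage design (residual
#' column last), `Pa`, `Pb` the stage fitted probabilities and `Ua`, `Ub`
#' the stage residuals,
#' \deqn{A11 = [Pa(1-Pa)w]'[Pa(1-Pa)w]/n,\quad
#'       A22 = [Pb(1-Pb)X]'[Pb(1-Pb)X]/n,}
#' \deqn{A21 = -(b_u/n) [Pb^2(1-Pb)^2 X]'[Pa(1-Pa)w],}
#' \deqn{S1 = [Pa(1-Pa)Ua w]'[Pa(1-Pa)Ua w]/n,\quad
#'       S2 = [Pb(1-Pb)Ub X]'[Pb(1-Pb)Ub X]/n,}
#' \deqn{S21 = [Pb(1-Pb)Ub X]'[Pa(1-Pa)Ua w]/n.}
#' The sign of `A21` follows the chain rule applied to the second-stage
#' index: the residual column differentiates to `-b_u r'(w'alpha) w` with
#' respect to the first-stage parameters.
#'
#' @param parts a list with elements `w`, `X`, `Pa`, `Pb`, `Ua`, `Ub`,
#'   `beta_u` (see [fit_2sri()], element `sandwich_parts`), or an
#'   `iv_fit_2sri` object.
#' @return A list of matrices `A11`, `A21`, `A22`, `S1`, `S2`, `S21`.
#' @export
sandwich_blocks_2sri <- function(parts) {
  if (inherits(parts, "iv_fit_2sri")) parts <- parts$sandwich_parts
  n <- nrow(parts$w)
  wa <- parts$Pa * (1 - parts$Pa)      # r'(eta_alpha)
  wb <- parts$Pb * (1 - parts$Pb)      # F'(eta_beta)
  Gw <- wa * parts$w
  GX <- wb * parts$X
  list(
    A11 = crossprod(Gw) / n,
    A21 = -(parts$beta_u / n) * crossprod(wb^2 * parts$X, Gw),
    A22 = crossprod(GX) / n,
    S1 = crossprod(parts$Ua * Gw) / n,
    S2 = crossprod(parts$Ub * GX) / n,
    S21 = crossprod(parts$Ub * GX, parts$Ua * Gw) / n
  )
}

#' Two-step sandwich covariance of the 2SRI estimator
#'
#' Assembles the three-term covariance
#' \deqn{Var(\hat\beta) = (A22^{-1} S2 A22^{-1'} +
#'   A22^{-1} A21 A11^{-1} S1 A11^{-1'} A21' A22^{-1'} -
#'   A22^{-1} S21 A11^{-1'} A21' A22^{-1'})/n}
#' from the plug-in blocks of [sandwich_blocks_2sri()], accounting for the
#' estimation of the first-stage parameters inside the residual column.
#' The result is symmetrized as `(V + V')/2`. With the cross matrices
#' `A21` and `S21` zeroed the expression collapses to the one-step
#' sandwich `A22^{-1} S2 A22^{-1'}/n` that ignores first-stage
#' uncertainty.
#'
#' @param parts as in [sandwich_blocks_2sri()].
#' @param drop_cross logical; force `A21 = 0` and `S21 = 0` (one-step
#'   sandwich).
#' @return The covariance matrix of the second-stage coefficients.
#' @export
sandwich_covariance_2sri <- function(parts, drop_cross = FALSE) {
  if (inherits(parts, "iv_fit_2sri")) parts <- parts$sandwich_parts
  n <- nrow(parts$w)
  bl <- sandwich_blocks_2sri(parts)
  rc <- function(M) {
    kappa <- tryCatch(kappa(M, exact = FALSE), error = function(e) Inf)
    if (!is.finite(kappa) || kappa > 1e12)
      stop(sprintf("singular block in sandwich covariance (condition number %.3g)",
                   kappa), call. = FALSE)
    solve(M)
  }
  A22i <- rc(bl$A22)
  if (drop_cross) {
    V <- A22i %*% bl$S2 %*% t(A22i) / n
  } else {
    A11i <- rc(bl$A11)
    core <- bl$A21 %*% A11i %*% bl$S1 %*% t(A11i) %*% t(bl$A21)
    cross <- bl$S21 %*% t(A11i) %*% t(bl$A21)
    V <- (A22i %*% (bl$S2 + core - cross) %*% t(A22i)) / n
  }
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(parts$X), colnames(parts$X))
  V
}

#' @export
print.iv_fit_2sri <- function(x, ...) {
  NextMethod()
  if (!is.null(x$first) && x$first$converged) {
    cat("First stage (", x$stage_loss, "), instrument coefficient: ",
        sprintf("%.4f", x$first$coef[[x$instrument]]), "\n", sep = "")
  }
  invisible(x)
}
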