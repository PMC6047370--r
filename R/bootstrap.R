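#' Nonparametric bootstrap covariance of a fitted estimator
#'
#' Resamples the estimation sample with replacement, refits, and returns
#' the empirical covariance of the refitted coefficients. The default
#' resampling unit is the patient; `unit = "physician"` resamples whole
#' physician panels (block bootstrap respecting the clustering);
#' `unit = "none"` refits the unresampled data `B` times (degenerate
#' case, zero covariance -- useful for validation).
#'
#' @param cohort a cohort (proxies attached if `fitter` needs them).
#' @param fitter a function `cohort -> iv_fit`, e.g.
#'   `function(d) fit_2sri(d, "pr")`.
#' @param B number of bootstrap resamples (>= 2).
#' @param seed integer seed.
#' @param unit `"patient"`, `"physician"` or `"none"`.
#' @return Covariance matrix of the coefficients over successful
#'   resamples, with attributes `n_failed` and `B`. Errors if more than
#'   20\% of resample fits fail.
#' @export
bootstrap_variance <- function(cohort, fitter, B, seed = 1L,
                               unit = c("patient", "physician", "none")) {
  unit <- match.arg(unit)
  B <- as.integer(B)
  if (B < 2L) stop("`B` must be at least 2", call. = FALSE)
  d <- estimation_sample(cohort)
  set.seed(sub_seed(seed, 901L))
  draws <- vector("list", B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- switch(unit,
      patient = sample.int(nrow(d), replace = TRUE),
      physician = {
        ids <- unique(d$physician_id)
        picked <- sample(ids, length(ids), replace = TRUE)
        unlist(lapply(picked, function(p) which(d$physician_id == p)),
               use.names = FALSE)
      },
      none = seq_len(nrow(d)))
    res <- d[idx, , drop = FALSE]
    fit <- tryCatch(fitter(res), error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) {
      n_failed <- n_failed + 1L
      next
    }
    draws[[b]] <- fit$coef
  }
  if (n_failed > 0.2 * B)
    stop(sprintf("bootstrap unstable: %d of %d resample fits failed",
                 n_failed, B), call. = FALSE)
  mat <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  V <- stats::cov(mat)
  attr(V, "n_failed") <- n_failed
  attr(V, "B") <- B
  V
}
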