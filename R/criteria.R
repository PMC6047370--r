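# Monte-Carlo evaluation criteria. Each is the literal textbook formula so
# that summaries can be re-derived exactly from stored per-replication
# estimates.

#' Percentage relative bias of the treatment coefficient
#'
#' `rB = 100 * mean(estimates / beta_t - 1)`.
#'
#' @param estimates per-replication treatment-coefficient estimates.
#' @param beta_t true treatment coefficient (nonzero).
#' @export
relative_bias <- function(estimates, beta_t) {
  if (!length(estimates)) stop("no estimates supplied", call. = FALSE)
  if (beta_t == 0)
    stop("relative bias is undefined for beta_t = 0", call. = FALSE)
  100 * mean(estimates / beta_t - 1)
}

#' Monte-Carlo variance and mean asymptotic variance
#'
#' `mc_variance` is the empirical variance of the estimates with the
#' `ns - 1` denominator; `mean_asymptotic_variance` averages the
#' per-replication asymptotic variance estimates.
#'
#' @param estimates per-replication point estimates (>= 2 for
#'   `mc_variance`).
#' @param variances per-replication asymptotic variance estimates.
#' @export
mc_variance <- function(estimates) {
  if (length(estimates) < 2L)
    stop("at least two estimates needed for the Monte-Carlo variance",
         call. = FALSE)
  stats::var(estimates)
}

#' @rdname mc_variance
#' @export
mean_asymptotic_variance <- function(variances) {
  if (!length(variances)) stop("no variances supplied", call. = FALSE)
  mean(variances)
}

#' Root mean squared error of the treatment coefficient
#'
#' `rMSE = sqrt(mean((estimates - beta_t)^2))`.
#'
#' @inheritParams relative_bias
#' @export
rmse <- function(estimates, beta_t) {
  if (!length(estimates)) stop("no estimates supplied", call. = FALSE)
  sqrt(mean((estimates - beta_t)^2))
}

#' Lower and upper non-coverage percentages
#'
#' `Er_inf` is the percentage of replications whose confidence interval
#' lies entirely above the truth (`beta_t < lower`), `Er_sup` the
#' percentage lying entirely below (`beta_t > upper`); strict
#' inequalities, so a degenerate interval at the truth covers.
#'
#' @param cis two-column matrix (lower, upper), one row per replication.
#' @param beta_t true treatment coefficient.
#' @return Named numeric `c(Er_inf, Er_sup)`, in percent.
#' @export
noncoverage <- function(cis, beta_t) {
  cis <- as.matrix(cis)
  if (ncol(cis) != 2L) stop("`cis` must have two columns", call. = FALSE)
  if (any(cis[, 1] > cis[, 2], na.rm = TRUE))
    stop("malformed interval: lower bound exceeds upper bound",
         call. = FALSE)
  c(Er_inf = 100 * mean(beta_t < cis[, 1]),
    Er_sup = 100 * mean(beta_t > cis[, 2]))
}

#' Replication filtering: convergence failures and outliers
#'
#' Applies the study's two filtering rules to a long table of
#' per-replication, per-method results (columns `rep`, `method`, `est`,
#' `var`, `status`):
#' \enumerate{
#'   \item GMM convergence failures (status `nonconverged` or `singular`)
#'     remove that replication for \emph{all} methods
#'     (status `dropped_gmm`).
#'   \item A surviving replication is a method-specific outlier when its
#'     absolute relative bias exceeds 100\% (`|est/beta_t - 1| > 1`) or
#'     its variance estimate is non-finite (status `outlier`).
#' }
#' Non-GMM convergence failures drop only that method's replication.
#'
#' @param results data frame with columns `rep`, `method`, `est`, `var`,
#'   `status` (`"ok"`, `"nonconverged"` or `"singular"`).
#' @param beta_t true treatment coefficient.
#' @return The table with updated `status` plus a `retained` logical
#'   column; per-method counts are attached as attribute `counts`.
#' @export
outlier_filter <- function(results, beta_t) {
  req <- c("rep", "method", "est", "var", "status")
  if (!all(req %in% names(results)))
    stop("`results` must have columns rep, method, est, var, status",
         call. = FALSE)
  res <- results
  gmm_bad <- unique(res$rep[res$method == "gmm" &
                              res$status %in% c("nonconverged", "singular")])
  drop <- res$rep %in% gmm_bad & res$status == "ok"
  res$status[drop] <- "dropped_gmm"
  ok <- res$status == "ok"
  out <- ok & (!is.finite(res$est) | !is.finite(res$var) |
                 abs(res$est / beta_t - 1) > 1)
  res$status[out] <- "outlier"
  res$retained <- res$status == "ok"
  counts <- do.call(rbind, lapply(split(res, res$method), function(g) {
    data.frame(method = g$method[1],
               n_retained = sum(g$retained),
               n_outliers = sum(g$status == "outlier"),
               n_failed = sum(g$status %in% c("nonconverged", "singular")),
               n_dropped_gmm = sum(g$status == "dropped_gmm"))
  }))
  rownames(counts) <- NULL
  attr(res, "counts") <- counts
  res
}
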