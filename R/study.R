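#' Run a Monte-Carlo scenario
#'
#' Simulates `config$ns` cohorts, attaches the preference proxies, fits
#' the requested estimators on each replication, applies the filtering
#' rules (GMM failures drop the replication for all methods; outliers
#' with |relative bias| > 100\% or non-finite variance are dropped
#' per-method) and computes the evaluation criteria per method: relative
#' bias (\%), Monte-Carlo standard deviation, mean asymptotic standard
#' deviation, root mean squared error and lower/upper non-coverage.
#' The first-stage instrument-exclusion statistic is recorded on every
#' replication.
#'
#' Per-replication seeds are derived from `(seed, replication index)`, so
#' results do not depend on evaluation order and are reproducible.
#'
#' @param config an [scenario_config()]; `config$ns` replications of size
#'   `config$n`.
#' @param instrument `"pr"` or `"zstar"`.
#' @param methods subset of `c("true", "conventional", "2sri", "gmm")`;
#'   may be empty (`character(0)`) to collect only first-stage
#'   statistics.
#' @param seed root seed (default `config$seed`).
#' @param level nominal confidence level.
#' @param stage_loss passed to [fit_2sri()].
#' @return An object of class `iv_scenario_summary`: a data frame with one
#'   row per method and columns `rB`, `sd_mc`, `sd_asym`, `rMSE`,
#'   `Er_inf`, `Er_sup` (percent), `pval` (their sum as a proportion),
#'   `n_outliers`, `n_failed`, `n_retained`, plus attributes `raw` (the
#'   filtered long per-replication table), `f_stats`, `config`,
#'   `instrument` and `labels`.
#' @export
run_scenario <- function(config,
                         instrument = c("pr", "zstar"),
                         methods = c("true", "conventional", "2sri", "gmm"),
                         seed = config$seed, level = 0.95,
                         stage_loss = "nls") {
  stopifnot(inherits(config, "iv_scenario_config"))
  instrument <- match.arg(instrument)
  if (length(methods))
    methods <- match.arg(methods, several.ok = TRUE)
  ns <- config$ns
  beta_t <- config$beta[["beta_t"]]

  rows <- vector("list", ns * max(1L, length(methods)))
  f_stats <- rep(NA_real_, ns)
  ri <- 0L
  for (j in seq_len(ns)) {
    rep_seed <- sub_seed(seed, 10000L + j)
    cohort <- attach_proxies(simulate_cohort(config, rep_seed))
    f_stats[j] <- suppressWarnings(first_stage_F(cohort, instrument))
    for (meth in methods) {
      fit <- tryCatch(
        if (meth == "2sri")
          fit_2sri(cohort, instrument = instrument, level = level,
                   stage_loss = stage_loss)
        else iv_fit(cohort, meth, instrument = instrument, level = level),
        error = function(e) NULL)
      ri <- ri + 1L
      rows[[ri]] <- if (is.null(fit)) {
        data.frame(rep = j, method = meth, est = NA_real_, var = NA_real_,
                   lo = NA_real_, hi = NA_real_, status = "nonconverged")
      } else {
        data.frame(rep = j, method = meth,
                   est = unname(fit$coef["T"]),
                   var = if (all(is.na(fit$vcov))) NA_real_
                   else unname(fit$vcov["T", "T"]),
                   lo = unname(fit$ci["T", "lower"]),
                   hi = unname(fit$ci["T", "upper"]),
                   status = fit$status)
      }
    }
  }
  raw <- if (length(methods)) do.call(rbind, rows[seq_len(ri)])
  else data.frame(rep = integer(), method = character(), est = numeric(),
                  var = numeric(), lo = numeric(), hi = numeric(),
                  status = character())
  raw <- outlier_filter(raw, beta_t)

  summarize_method <- function(meth) {
    g <- raw[raw$method == meth, , drop = FALSE]
    r <- g[g$retained, , drop = FALSE]
    cnt <- attr(raw, "counts")
    cnt <- cnt[cnt$method == meth, ]
    usable <- nrow(r) >= 2L
    data.frame(
      method = meth,
      rB = if (nrow(r)) relative_bias(r$est, beta_t) else NA_real_,
      sd_mc = if (usable) sqrt(mc_variance(r$est)) else NA_real_,
      sd_asym = if (nrow(r)) sqrt(mean_asymptotic_variance(r$var))
      else NA_real_,
      rMSE = if (nrow(r)) rmse(r$est, beta_t) else NA_real_,
      Er_inf = if (nrow(r)) noncoverage(r[c("lo", "hi")], beta_t)[["Er_inf"]]
      else NA_real_,
      Er_sup = if (nrow(r)) noncoverage(r[c("lo", "hi")], beta_t)[["Er_sup"]]
      else NA_real_,
      n_outliers = cnt$n_outliers,
      n_failed = cnt$n_failed + cnt$n_dropped_gmm,
      n_retained = cnt$n_retained,
      unusable = cnt$n_retained < 0.5 * ns
    )
  }
  summ <- if (length(methods))
    do.call(rbind, lapply(methods, summarize_method))
  else data.frame()
  if (nrow(summ)) {
    summ$pval <- (summ$Er_inf + summ$Er_sup) / 100
    rownames(summ) <- NULL
    if (any(summ$unusable))
      warning("scenario unusable for method(s): ",
              paste(summ$method[summ$unusable], collapse = ", "),
              " (more than half the replications dropped)", call. = FALSE)
  }
  structure(summ,
            raw = raw, f_stats = f_stats, config = config,
            instrument = instrument, labels = scenario_labels(config),
            seed = seed,
            class = c("iv_scenario_summary", "data.frame"))
}

#' Monte-Carlo mean of the first-stage F-equivalent
#'
#' @param summary an `iv_scenario_summary`.
#' @return Mean of the per-replication instrument-exclusion statistics.
#' @export
mean_first_stage_F <- function(summary) {
  mean(attr(summary, "f_stats"), na.rm = TRUE)
}

#' @export
print.iv_scenario_summary <- function(x, digits = 3, ...) {
  lab <- attr(x, "labels")
  cfg <- attr(x, "config")
  cat(sprintf("Scenario: %s instrument, %s confounding, n = %d, ns = %d (%s regime, instrument %s)\n",
              lab$strength, lab$confounding, cfg$n, cfg$ns, lab$regime,
              attr(x, "instrument")))
  cat(sprintf("Mean first-stage F-equivalent: %.2f\n\n",
              mean_first_stage_F(x)))
  if (nrow(x)) {
    df <- as.data.frame(x)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits)
    print(df[setdiff(names(df), "unusable")], row.names = FALSE)
  }
  invisible(x)
}

#' Boxplot of per-replication relative bias by method
#'
#' @param x an `iv_scenario_summary`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.iv_scenario_summary <- function(x, ...) {
  raw <- attr(x, "raw")
  raw <- raw[raw$retained, , drop = FALSE]
  if (!nrow(raw)) stop("no retained replications to plot", call. = FALSE)
  beta_t <- attr(x, "config")$beta[["beta_t"]]
  rb <- 100 * (raw$est / beta_t - 1)
  graphics::boxplot(rb ~ raw$method, xlab = "method",
                    ylab = "relative bias (%)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Assemble study tables from scenario summaries
#'
#' Lays out a list of scenario summaries in the study's reporting shape:
#' `performance` has one row per (n, confounding, method) and a
#' four-column block (rB, sd, rMSE, pval) per instrument strength;
#' `outliers` counts dropped replications per cell; `f_stats` holds the
#' Monte-Carlo mean first-stage F-equivalents. Cells absent from the
#' input are rendered as `"-"`.
#'
#' @param summaries list of `iv_scenario_summary` objects (at least one).
#' @param dir optional directory; when given, `performance.csv`,
#'   `outliers.csv` and `f_stats.csv` are written there.
#' @return A named list of data frames, invisibly when `dir` is given.
#' @export
report_tables <- function(summaries, dir = NULL) {
  if (!length(summaries)) stop("no summaries supplied", call. = FALSE)
  if (inherits(summaries, "iv_scenario_summary"))
    summaries <- list(summaries)
  meta <- lapply(summaries, function(s) {
    lab <- attr(s, "labels"); cfg <- attr(s, "config")
    list(strength = lab$strength, confounding = lab$confounding, n = cfg$n,
         summary = s)
  })
  strengths <- c("weak", "moderate", "strong")
  ns_sizes <- sort(unique(vapply(meta, function(m) m$n, numeric(1))),
                   decreasing = TRUE)
  confs <- c("high", "medium", "low")
  confs <- confs[confs %in% vapply(meta, function(m) m$confounding,
                                   character(1))]
  methods <- unique(unlist(lapply(meta, function(m) m$summary$method)))

  cell <- function(n, conf, str) {
    hit <- Filter(function(m) m$n == n && m$confounding == conf &&
                    m$strength == str, meta)
    if (length(hit)) hit[[1]]$summary else NULL
  }
  fmt <- function(x, d = 2) ifelse(is.na(x), "-", formatC(x, digits = d,
                                                          format = "f"))
  perf <- do.call(rbind, lapply(ns_sizes, function(n) {
    do.call(rbind, lapply(confs, function(conf) {
      do.call(rbind, lapply(methods, function(meth) {
        row <- data.frame(n = n, confounding = conf, method = meth)
        for (str in strengths) {
          s <- cell(n, conf, str)
          vals <- if (!is.null(s) && meth %in% s$method) {
            r <- s[s$method == meth, ]
            c(fmt(r$rB), fmt(r$sd_mc), fmt(r$rMSE), fmt(r$pval))
          } else rep("-", 4)
          row[paste0(str, "_", c("rB", "sd", "rMSE", "pval"))] <- vals
        }
        row
      }))
    }))
  }))
  outl <- do.call(rbind, lapply(ns_sizes, function(n) {
    do.call(rbind, lapply(confs, function(conf) {
      row <- data.frame(n = n, confounding = conf)
      for (str in strengths) {
        s <- cell(n, conf, str)
        row[[str]] <- if (!is.null(s) && "gmm" %in% s$method)
          s$n_outliers[s$method == "gmm"] else NA
      }
      row
    }))
  }))
  fst <- do.call(rbind, lapply(ns_sizes, function(n) {
    do.call(rbind, lapply(confs, function(conf) {
      row <- data.frame(n = n, confounding = conf)
      for (str in strengths) {
        s <- cell(n, conf, str)
        row[[str]] <- if (!is.null(s))
          round(mean_first_stage_F(s), 2) else NA
      }
      row
    }))
  }))
  out <- list(performance = perf, outliers = outl, f_stats = fst)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(out))
      utils::write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
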