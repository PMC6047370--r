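test_that("scenario runs are deterministic and self-consistent", {
  cfg <- toy_config(n = 1000, m = 20, ns = 6, seed = 33)
  s1 <- run_scenario(cfg, "pr", methods = c("true", "conventional", "2sri"))
  s2 <- run_scenario(cfg, "pr", methods = c("true", "conventional", "2sri"))
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_identical(attr(s1, "raw"), attr(s2, "raw"))

  # summary criteria re-derivable exactly from the stored raw table
  raw <- attr(s1, "raw")
  bt <- cfg$beta[["beta_t"]]
  for (meth in unique(raw$method)) {
    r <- raw[raw$method == meth & raw$retained, ]
    row <- s1[s1$method == meth, ]
    expect_gte(nrow(r), 2)
    expect_identical(row$rB, relative_bias(r$est, bt))
    expect_identical(row$sd_mc, sqrt(mc_variance(r$est)))
    expect_identical(row$rMSE, rmse(r$est, bt))
    nc <- noncoverage(r[c("lo", "hi")], bt)
    expect_identical(row$Er_inf, nc[["Er_inf"]])
    expect_identical(row$pval, (nc[["Er_inf"]] + nc[["Er_sup"]]) / 100)
    expect_identical(row$n_retained + row$n_failed +
                       row$n_outliers, cfg$ns)
  }
  expect_true(is.finite(mean_first_stage_F(s1)))
})

test_that("a single replication leaves the Monte-Carlo sd undefined", {
  cfg <- toy_config(n = 500, m = 10, ns = 1, seed = 2)
  s <- run_scenario(cfg, "pr", methods = "conventional")
  expect_true(is.na(s$sd_mc))
  expect_false(is.na(s$rB))
})

test_that("F-only runs collect the exclusion statistic without fits", {
  cfg <- toy_config(n = 500, m = 10, ns = 3, seed = 8)
  s <- run_scenario(cfg, "pr", methods = character(0))
  expect_equal(nrow(s), 0)
  expect_length(attr(s, "f_stats"), 3)
  expect_true(all(is.finite(attr(s, "f_stats"))))
})

test_that("report tables take the study layout with dashes for missing cells", {
  cfgs <- list(toy_config(n = 400, m = 10, ns = 3, seed = 1),
               toy_config(n = 400, m = 10, ns = 3, seed = 2))
  cfgs[[1]]$alpha[["alpha_z"]] <- 1
  cfgs[[2]]$alpha[["alpha_z"]] <- 3
  ss <- lapply(cfgs, run_scenario, instrument = "pr",
               methods = c("true", "conventional"))
  tabs <- report_tables(ss)
  expect_named(tabs, c("performance", "outliers", "f_stats"))
  perf <- tabs$performance
  expect_equal(nrow(perf), 2)  # one confounding level x two methods
  expect_true(all(c("weak_rB", "moderate_rB", "strong_rB") %in% names(perf)))
  expect_true(all(perf$moderate_rB == "-"))  # moderate cell not run
  expect_true(all(perf$weak_rB != "-"))
  expect_error(report_tables(list()), "no summaries")

  dir <- withr::local_tempdir()
  report_tables(ss, dir = dir)
  expect_true(all(file.exists(file.path(dir, c("performance.csv",
                                               "outliers.csv",
                                               "f_stats.csv")))))
})

test_that("plot and print methods run on a scenario summary", {
  cfg <- toy_config(n = 400, m = 10, ns = 4, seed = 12)
  s <- run_scenario(cfg, "pr", methods = c("true", "conventional"))
  expect_output(print(s), "Mean first-stage F-equivalent")
  pdf(NULL)
  on.exit(dev.off())
  expect_no_error(plot(s))
})
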