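test_that("cohorts are bit-reproducible and respect the clustering design", {
  cfg <- scenario_preset("moderate", "medium", n = 2000, m = 20, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)

  # PP is a physician-level quantity: constant within physician
  within_var <- tapply(a$PP, a$physician_id, function(v) length(unique(v)))
  expect_true(all(within_var == 1L))
  expect_equal(nrow(a), 2000L)
  expect_equal(length(unique(a$physician_id)), 100L)
  expect_true(all(a$T %in% 0:1) && all(a$Y %in% 0:1))

  # degenerate confounder
  cfg0 <- scenario_config(n = 400, m = 20, sigma_u = 0, seed = 3)
  expect_true(all(simulate_cohort(cfg0)$Xu == 0))
})

test_that("configuration errors are caught", {
  expect_error(scenario_config(n = 0), "positive")
  expect_error(scenario_config(n = 150, m = 100), "divisible")
  expect_error(scenario_config(n = 100, m = 10, p_pp = 1), "p_pp")
  expect_error(scenario_config(n = 100, m = 10, sigma_u = -1), "sigma_u")
  expect_error(scenario_config(n = 100, m = 10, beta = c(0, Inf, 0, 0, 0)),
               "finite")
})

test_that("proxies are the previous treatment and running treated proportion", {
  coh <- attach_proxies(cohort_from_history(list(c(1, 0, 1, 1), c(1, 1, 1))))
  # fourth patient of physician 1: previous T = 1, 2 of 3 earlier treated
  expect_equal(coh$Zstar[4], 1)
  expect_equal(coh$pr[4], 2 / 3)
  expect_equal(coh$pr[3], 1 / 2)
  # all previous treated -> pr = 1, Zstar = 1
  expect_equal(coh$pr[7], 1)
  expect_equal(coh$Zstar[7], 1)
  # first patient of each physician has no proxy
  firsts <- coh$order == 1
  expect_true(all(!coh$valid_proxy[firsts]))
  expect_true(all(is.na(coh$pr[firsts])) && all(is.na(coh$Zstar[firsts])))
  expect_true(all(coh$valid_proxy[!firsts]))
})

test_that("stored proxies equal recomputation from scratch on simulated data", {
  coh <- toy_cohort(n = 600, m = 12, seed = 5)
  for (p in unique(coh$physician_id)) {
    tr <- coh$T[coh$physician_id == p]
    pr <- coh$pr[coh$physician_id == p]
    zs <- coh$Zstar[coh$physician_id == p]
    for (i in seq_along(tr)[-1]) {
      expect_identical(pr[i], mean(tr[seq_len(i - 1)]))
      expect_identical(zs[i], tr[i - 1])
    }
  }
})

test_that("attach_proxies rejects unsorted or duplicated panels", {
  coh <- cohort_from_history(list(c(1, 0, 1)))
  expect_error(attach_proxies(coh[c(2, 1, 3), ]), "sorted")
  dup <- rbind(coh, coh[1, ])
  expect_error(attach_proxies(dup[order(dup$physician_id, dup$order), ]),
               "duplicated")
  expect_error(attach_proxies(coh[, c("physician_id", "order")]), "columns")
})

test_that("latent-index and Bernoulli outcome generators are equivalent", {
  cfg <- scenario_preset("moderate", "medium", n = 100, m = 10)
  ok <- index_function_equivalence_check(cfg, seed = 4, n_mc = 100000)
  expect_true(ok)
  p1 <- attr(ok, "prevalence_bernoulli")
  p2 <- attr(ok, "prevalence_index")
  expect_lt(abs(p1 - p2), attr(ok, "tolerance"))
  expect_error(index_function_equivalence_check(cfg, n_mc = 0), "positive")
  bad <- cfg; bad$beta[["beta_t"]] <- Inf
  expect_error(scenario_config(n = 100, m = 10,
                               beta = c(-0.6, Inf, 1, 1, 1)), "finite")
  expect_true(index_function_equivalence_check(toy_config(), seed = 2,
                                               n_mc = 50000))
})

test_that("cohort CSV round-trips and tolerates missing latent columns", {
  coh <- toy_cohort(n = 100, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back)[names(coh)], as.data.frame(coh),
               tolerance = 1e-12, ignore_attr = TRUE)
  # user data without Xu / PP still reads
  pub <- as.data.frame(coh)[setdiff(names(coh), c("Xu", "PP"))]
  utils::write.csv(pub, path, row.names = FALSE)
  expect_s3_class(read_cohort(path), "iv_cohort")
  utils::write.csv(pub[setdiff(names(pub), "Y")], path, row.names = FALSE)
  expect_error(read_cohort(path), "missing required")
})

test_that("scenario presets map the named grid onto parameter values", {
  cfg <- scenario_preset("strong", "high", n = 1000, m = 10)
  expect_equal(cfg$alpha[["alpha_z"]], 3)
  expect_equal(cfg$sigma_u, 1.5)
  expect_equal(cfg$alpha[["alpha0"]], 0.2)
  bal <- scenario_preset("weak", "low", n = 1000, m = 10,
                         regime = "balanced")
  expect_equal(bal$alpha[["alpha0"]], 5)
  expect_equal(bal$beta[["beta0"]], -2.3)
  expect_equal(bal$alpha[["alpha_z"]], 1)
  expect_equal(bal$sigma_u, 0.5)

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- strength: weak",
               "  confounding: med",
               "  n: 1000",
               "  m: 10",
               "- strength: strong",
               "  confounding: high",
               "  n: 2000",
               "  m: 10",
               "  regime: balanced"), path)
  grid <- read_scenario_grid(path)
  expect_named(grid, c("weak_medium_1000", "strong_high_2000"))
  expect_equal(grid[[2]]$alpha[["alpha0"]], 5)
})
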