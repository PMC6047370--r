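test_that("benchmark fit recovers the generating coefficients", {
  cfg <- scenario_preset("moderate", "high", n = 10000, m = 100, seed = 21)
  truth <- cfg$beta
  ests <- t(sapply(1:25, function(j) {
    coh <- attach_proxies(simulate_cohort(cfg, seed = 700 + j))
    coef(fit_true(coh))
  }))
  m <- colMeans(ests)
  se <- apply(ests, 2, stats::sd) / sqrt(nrow(ests))
  expect_true(all(abs(m - truth) < 3 * se + 1e-8),
              info = paste(round(m, 3), collapse = ", "))
})

test_that("iv_fit dispatches and methods expose the fit", {
  coh <- toy_cohort(n = 1000, m = 20, seed = 2)
  fit <- iv_fit(coh, "conventional")
  expect_s3_class(fit, "iv_fit")
  expect_named(coef(fit), c("(Intercept)", "T", "X1", "X2"))
  expect_equal(dim(vcov(fit)), c(4, 4))
  expect_true(isSymmetric(vcov(fit)))
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= coef(fit) & coef(fit) <= ci[, 2]))
  expect_equal(unname(confint(fit, "T", level = 0.99)[, 2] -
                        confint(fit, "T", level = 0.99)[, 1]),
               2 * qnorm(0.995) * sqrt(vcov(fit)["T", "T"]))
  expect_length(residuals(fit), fit$n_used)
  expect_equal(predict(fit),
               plogis(qlogis(predict(fit, type = "response"))))
  nd <- data.frame(T = c(0, 1), X1 = 0, X2 = 0)
  p <- predict(fit, nd)
  expect_true(all(p > 0 & p < 1) && p[2] > p[1])
  expect_output(print(summary(fit)), "conventional")
  expect_error(fit_true(coh[setdiff(names(coh), "Xu")]), "Xu")
})

test_that("quasi-complete separation is flagged as non-convergence", {
  d <- data.frame(physician_id = rep(1:2, each = 20), order = rep(1:20, 2),
                  X1 = rnorm(40), X2 = rnorm(40), Xu = 0,
                  PP = 0L, T = rep(0:1, 20))
  d$Y <- d$T
  fit <- fit_conventional(d)
  expect_false(fit$converged)
  expect_identical(fit$status, "nonconverged")
})

test_that("first-stage residuals satisfy the ML score equation", {
  coh <- toy_cohort(n = 1000, m = 20, seed = 4)
  fs <- fit_first_stage(coh, "pr", loss = "ml")
  expect_lt(abs(sum(fs$residuals)), 1e-6)
  expect_gt(fs$coef[["pr"]], 0)
  # nls stage solves its own normal equations
  fsn <- fit_first_stage(coh, "pr", loss = "nls")
  w <- fsn$w
  mu <- fsn$fitted
  grad <- crossprod(w, mu * (1 - mu) * fsn$residuals)
  expect_lt(max(abs(grad)) / nrow(w), 1e-8)
})

test_that("supplying the confounder as the residual reproduces the benchmark", {
  coh <- toy_cohort(n = 2000, m = 20, seed = 7)
  d <- coh[coh$valid_proxy, ]
  oracle <- fit_2sri(coh, "pr", stage_loss = "ml", residual = d$Xu)
  bench <- fit_true(coh)
  expect_equal(unname(coef(oracle)[c("(Intercept)", "T", "X1", "X2",
                                     "residual")]),
               unname(coef(bench)), tolerance = 1e-6)
})

test_that("two-step sandwich collapses to one step without cross terms and is permutation-stable", {
  coh <- toy_cohort(n = 400, m = 10, seed = 11)
  fit <- fit_2sri(coh, "pr")
  expect_true(fit$converged)
  V <- vcov(fit)
  expect_true(isSymmetric(V))
  expect_true(all(diag(V) >= 0))

  parts <- fit$sandwich_parts
  V1 <- sandwich_covariance_2sri(parts, drop_cross = TRUE)
  bl <- sandwich_blocks_2sri(parts)
  A22i <- solve(bl$A22)
  expect_equal(V1, (A22i %*% bl$S2 %*% t(A22i)) / nrow(parts$w),
               tolerance = 1e-10, ignore_attr = TRUE)

  # swapping the roles of X1 and X2 permutes coefficients and covariance
  coh2 <- coh
  coh2$X1 <- coh$X2; coh2$X2 <- coh$X1
  fit2 <- fit_2sri(coh2, "pr")
  perm <- c(1, 2, 4, 3, 5)
  expect_equal(unname(coef(fit2)), unname(coef(fit))[perm],
               tolerance = 1e-6)
  expect_equal(unname(vcov(fit2)), unname(vcov(fit))[perm, perm],
               tolerance = 1e-5)
})

test_that("asymptotic 2SRI standard error tracks the Monte-Carlo sd", {
  cfg <- toy_config(n = 2000, m = 20, seed = 31)
  est <- se <- numeric(30)
  for (j in 1:30) {
    coh <- attach_proxies(simulate_cohort(cfg, seed = 600 + j))
    f <- fit_2sri(coh, "pr")
    est[j] <- coef(f)[["T"]]
    se[j] <- sqrt(vcov(f)["T", "T"])
  }
  expect_lt(abs(mean(se) - sd(est)) / sd(est), 0.5)
})

test_that("GMM drives the sample moments to zero and flags broken problems", {
  coh <- toy_cohort(n = 1000, m = 20, seed = 13)
  fit <- fit_gmm(coh, "pr")
  expect_true(fit$converged)
  expect_lt(max(abs(fit$moments)), 1e-8)
  # minimizer property: objective at the solution below truth
  expect_lte(fit$objective,
             gmm_objective(fit, coh, c(0, 1, 0.5, 0.5)) + 1e-12)
  # identity weighting leaves the exactly identified estimate unchanged
  fit_id <- fit_gmm(coh, "pr", weight_scheme = "identity")
  expect_equal(coef(fit_id), coef(fit), tolerance = 1e-7)
  # constant proxy is a singular design
  bad <- coh; bad$pr[bad$valid_proxy] <- 0.3
  expect_error(fit_gmm(bad, "pr"), "constant")
})

test_that("GMM agrees with an independent root-finding oracle on small cohorts", {
  skip_if_not_installed("pracma")
  for (s in c(1, 2, 3)) {
    coh <- toy_cohort(n = 50, seed = 100 + s)
    fit <- fit_gmm(coh, "pr")
    if (!fit$converged) next
    d <- coh[coh$valid_proxy, ]
    w <- cbind(1, d$pr, d$X1, d$X2)
    X <- cbind(1, d$T, d$X1, d$X2)
    mom <- function(b) colMeans((d$Y - plogis(as.vector(X %*% b))) * w)
    root <- pracma::fsolve(mom, x0 = c(0, 1, 0.5, 0.5), tol = 1e-12)$x
    expect_equal(unname(coef(fit)), unname(root), tolerance = 1e-5)
  }
})

test_that("bootstrap covariance behaves across resampling units", {
  coh <- toy_cohort(n = 400, m = 10, seed = 19)
  fitter <- function(d) fit_conventional(d)
  V0 <- bootstrap_variance(coh, fitter, B = 5, seed = 1, unit = "none")
  expect_equal(max(abs(V0)), 0)
  V <- bootstrap_variance(coh, fitter, B = 60, seed = 1)
  glm_se <- sqrt(vcov(fit_conventional(coh))["T", "T"])
  expect_lt(abs(sqrt(V["T", "T"]) - glm_se) / glm_se, 0.5)
  # doubling B leaves the estimate stable up to bootstrap noise
  V2 <- bootstrap_variance(coh, fitter, B = 120, seed = 2)
  expect_lt(abs(sqrt(V2["T", "T"]) - sqrt(V["T", "T"])) / sqrt(V["T", "T"]),
            0.5)
  Vb <- bootstrap_variance(coh, fitter, B = 30, seed = 3,
                           unit = "physician")
  expect_true(all(diag(Vb) > 0))
  expect_error(bootstrap_variance(coh, fitter, B = 1), "at least 2")
})

test_that("fits serialize to JSON and back", {
  coh <- toy_cohort(n = 200, seed = 23)
  fit <- fit_conventional(coh)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$method, "conventional")
  expect_equal(unlist(back$coef), coef(fit), tolerance = 1e-12)
  expect_equal(matrix(unlist(back$vcov), 4, byrow = TRUE),
               unname(vcov(fit)), tolerance = 1e-12)
  expect_true(back$converged)
})
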