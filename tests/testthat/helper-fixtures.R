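# Shared fixtures and independent oracles for the test suite.

# Small well-conditioned configuration (non-rare events, modest n) for
# oracle comparisons where the rare-event design would be degenerate.
toy_config <- function(n = 200L, m = 10L, seed = 42L, ns = 1L) {
  scenario_config(n = n, m = m,
                  alpha = c(0, 2, 0.5, 0.5),
                  beta = c(0, 1, 0.5, 0.5, 1),
                  sigma_u = 1, p_pp = 0.5,
                  mu1 = 0, mu2 = 0, sigma1 = 1, sigma2 = 1,
                  ns = ns, seed = seed)
}

toy_cohort <- function(n = 200L, seed = 42L, ...) {
  attach_proxies(simulate_cohort(toy_config(n = n, seed = seed, ...)))
}

# Hand-built cohort from an explicit treatment history per physician.
cohort_from_history <- function(histories) {
  do.call(rbind, lapply(seq_along(histories), function(p) {
    tr <- histories[[p]]
    data.frame(physician_id = p, order = seq_along(tr),
               X1 = 0, X2 = 0, Xu = 0, PP = 0L, T = tr,
               Y = 0L)
  }))
}

# Finite-difference oracle for the two-step sandwich blocks: evaluates the
# defining sums with every derivative (logistic density, d eta/d alpha,
# d eta/d beta) obtained by central differences instead of the closed
# forms used by the implementation.
fd_sandwich_blocks <- function(d, alpha_hat, beta_hat, instrument = "pr",
                               h = 1e-5) {
  w <- cbind(1, d[[instrument]], d$X1, d$X2)
  n <- nrow(w)
  ka <- length(alpha_hat); kb <- length(beta_hat)
  Xmat <- function(a) cbind(1, d$T, d$X1, d$X2,
                            d$T - plogis(as.vector(w %*% a)))
  eta_b <- function(a, b) as.vector(Xmat(a) %*% b)
  eta_a <- function(a) as.vector(w %*% a)
  fd1 <- function(x) (plogis(x + h) - plogis(x - h)) / (2 * h)

  # n x ka and n x kb derivative matrices by central differences
  DA_beta <- sapply(seq_len(ka), function(j) {
    e <- numeric(ka); e[j] <- h
    (eta_b(alpha_hat + e, beta_hat) - eta_b(alpha_hat - e, beta_hat)) / (2 * h)
  })
  DB_beta <- sapply(seq_len(kb), function(j) {
    e <- numeric(kb); e[j] <- h
    (eta_b(alpha_hat, beta_hat + e) - eta_b(alpha_hat, beta_hat - e)) / (2 * h)
  })
  DA_alpha <- sapply(seq_len(ka), function(j) {
    e <- numeric(ka); e[j] <- h
    (eta_a(alpha_hat + e) - eta_a(alpha_hat - e)) / (2 * h)
  })

  rp <- fd1(eta_a(alpha_hat))                  # r'(eta_alpha)
  Fp <- fd1(eta_b(alpha_hat, beta_hat))        # F'(eta_beta)
  Pa <- plogis(eta_a(alpha_hat))
  Pb <- plogis(eta_b(alpha_hat, beta_hat))
  Ua <- d$T - Pa
  Ub <- d$Y - Pb

  list(A11 = crossprod(rp * DA_alpha) / n,
       A21 = crossprod(Fp * DB_beta, Fp * DA_beta) / n,
       A22 = crossprod(Fp * DB_beta) / n,
       S1 = crossprod(rp * Ua * DA_alpha) / n,
       S2 = crossprod(Fp * Ub * DB_beta) / n,
       S21 = crossprod(Fp * Ub * DB_beta, rp * Ua * DA_alpha) / n)
}

rel_err <- function(a, b) {
  a <- unname(as.matrix(a)); b <- unname(as.matrix(b))
  norm(a - b, "F") / max(norm(b, "F"), .Machine$double.eps)
}
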