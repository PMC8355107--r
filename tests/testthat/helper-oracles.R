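# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately brute-force implementations, kept separate from the package's
# computational paths.

# dense-grid marginal likelihood for a one-specific-factor bifactor toy:
# 2-D trapezoid-style Riemann sum over (thetaG, thetaS)
dense_bifactor_loglik <- function(x, a_g, a_s, cc, n_grid = 2001, lim = 8) {
  g <- seq(-lim, lim, length.out = n_grid)
  dg <- g[2] - g[1]
  wG <- dnorm(g); wS <- dnorm(g)
  P <- matrix(1, n_grid, n_grid)             # rows thetaG, cols thetaS
  for (j in seq_along(x)) {
    pj <- plogis(outer(a_g[j] * g, a_s[j] * g, "+") + cc[j])
    if (is.na(x[j])) next
    P <- P * (if (x[j] == 1) pj else 1 - pj)
  }
  log(sum(P * outer(wG, wS)) * dg^2)
}

# dense-grid unidimensional posterior mean (EAP oracle)
dense_eap <- function(x, a, cc, n_grid = 2001, lim = 8) {
  g <- seq(-lim, lim, length.out = n_grid)
  lik <- dnorm(g)
  for (j in seq_along(x)) {
    pj <- plogis(cc[j] + a[j] * g)
    if (is.na(x[j])) next
    lik <- lik * (if (x[j] == 1) pj else 1 - pj)
  }
  sum(g * lik) / sum(lik)
}

# Hudson-type Fst estimator over SNPs for two populations
hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# exhaustive greedy clumping oracle on a full correlation matrix
clump_oracle <- function(snp, chr, pos, p, G, r2_max, window_kb) {
  ord <- order(p, pos, snp)
  C2 <- suppressWarnings(cor(G))^2
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (chr[i] == chr[j] && abs(pos[i] - pos[j]) <= window_kb * 1000 &&
          !is.na(C2[i, j]) && C2[i, j] > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(snp[kept])
}

# brute-force BH step-up discovery set: largest k with p_(k) <= k q / m
bh_oracle_discoveries <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k_star <- 0L
  for (k in seq_len(m)) if (p[ord[k]] <= k * q / m) k_star <- k
  sort(ord[seq_len(k_star)])
}

# tetrachoric correlation by bisection on the bivariate-normal orthant mass
tetrachoric_oracle <- function(x, y) {
  p1 <- mean(x); p2 <- mean(y); p11 <- mean(x == 1 & y == 1)
  h <- qnorm(1 - p1); k <- qnorm(1 - p2)
  orthant <- function(rho) {
    f <- function(t) dnorm(t) * pnorm((rho * t - k) / sqrt(1 - rho^2))
    stats::integrate(f, h, Inf, rel.tol = 1e-9)$value
  }
  lo <- -0.999; hi <- 0.999
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (orthant(mid) < p11) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# adjusted Rand index between two partitions
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab)); si <- sum(comb2(rowSums(tab))); sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
zscore <- function(x) (x - mean(x)) / sd(x)

# lazily built shared fixtures (expensive fits reused across tests)
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

small_cohort <- function() {
  fixture("small_cohort", function() {
    simulate_cohort(cohort_config(n_study = 700L, n_snps = 400L, n_causal = 60L,
                                  ld_blocks = list(n = 20L, size = 2L, refresh = 0.05)),
                    seed = 2024)
  })
}

# a 23-item bifactor fit on a moderately sized cohort, shared across tests
fixture_bifactor_fit <- function() {
  fixture("bifactor_fit", function() {
    ch <- small_cohort()
    it <- filter_items(ch$items)
    fit <- fit_item_model(it, bifactor_spec(attr(it, "item_map"), "bifactor"))
    list(cohort = ch, items = it, fit = fit)
  })
}
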