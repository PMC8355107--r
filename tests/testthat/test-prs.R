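# Allele matching, clumping against an exhaustive oracle, score algebra,
# Nagelkerke incremental R2 and permutation empirical p-values.

toy_panel <- function(G, chr = NULL, pos = NULL, a1 = NULL, a2 = NULL) {
  m <- ncol(G)
  genotype_panel(G,
                 tibble::tibble(snp = colnames(G),
                                chr = chr %||% rep(1L, m),
                                pos = pos %||% as.integer(seq_len(m) * 1e6),
                                a1 = a1 %||% rep("A", m), a2 = a2 %||% rep("G", m)),
                 tibble::tibble(id = paste0("p", seq_len(nrow(G)))))
}

test_that("allele matching orients, flips and drops as specified", {
  G <- matrix(0L, 4, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  panel <- toy_panel(G, a1 = c("A", "C", "A"), a2 = c("G", "T", "T"))
  ss <- tibble::tibble(snp = c("s1", "s2", "s3", "s9"),
                       a1 = c("A", "T", "A", "A"), a2 = c("G", "C", "T", "G"),
                       beta = c(0.1, 0.1, 0.2, 0.3), se = 0.01,
                       p = c(1e-4, 1e-3, 1e-2, 1e-5))
  m <- match_alleles(ss, panel)
  rep_ <- attr(m, "match_report")
  # s1 same orientation, s2 flipped (panel counts C, sumstats effect is T)
  expect_equal(m$beta[m$snp == "s1"], 0.1)
  expect_equal(m$beta[m$snp == "s2"], -0.1)
  expect_equal(m$orientation[m$snp == "s2"], "flipped")
  # s3 is A/T strand-ambiguous -> dropped and counted; s9 unmatched
  expect_false("s3" %in% m$snp)
  expect_equal(rep_$n_ambiguous, 1L)
  expect_equal(rep_$n_unmatched, 1L)

  ss_or <- ss[1, ]; ss_or$beta <- NULL; ss_or$or <- exp(0.1)
  m_or <- match_alleles(ss_or, panel)
  expect_equal(m_or$beta, 0.1)

  expect_error(match_alleles(ss[4, ], panel), "overlap")
})

test_that("clumping keeps independent SNPs and prunes correlated ones", {
  set.seed(1)
  n <- 200
  base <- rbinom(n, 2L, 0.4)
  G <- cbind(s1 = base, s2 = base,                 # duplicated pair
             s3 = rbinom(n, 2L, 0.3), s4 = rbinom(n, 2L, 0.5))
  panel <- toy_panel(G, pos = c(1e6, 1.05e6, 5e6, 9e6) |> as.integer())
  ss <- tibble::tibble(snp = colnames(G), chr = 1L, pos = panel$map$pos,
                       a1 = "A", a2 = "G", beta = 0.1, se = 0.01,
                       p = c(1e-4, 1e-8, 0.02, 0.5))
  kept <- clump(ss, panel)
  # only the more significant duplicate survives; uncorrelated SNPs retained
  expect_true("s2" %in% kept)
  expect_false("s1" %in% kept)
  expect_true(all(c("s3", "s4") %in% kept))
})

test_that("clumping equals the exhaustive greedy oracle on block structure", {
  set.seed(2)
  n <- 300
  blocks <- lapply(1:3, function(b) {
    base <- rbinom(n, 2L, runif(1, 0.2, 0.8))
    sapply(1:4, function(k) {
      redraw <- runif(n) < 0.08
      col <- base
      col[redraw] <- rbinom(sum(redraw), 2L, 0.5)
      col
    })
  })
  G <- do.call(cbind, c(blocks, list(matrix(rbinom(n * 8, 2L, 0.5), n, 8))))
  colnames(G) <- sprintf("v%02d", seq_len(ncol(G)))
  pos <- as.integer(c(outer(1:4 * 1e4, (0:2) * 1e6, "+"), 1e7 + 1:8 * 1e6))
  panel <- toy_panel(G, pos = pos)
  set.seed(3)
  ss <- tibble::tibble(snp = colnames(G), chr = 1L, pos = pos, a1 = "A",
                       a2 = "G", beta = 0.1, se = 0.01,
                       p = runif(ncol(G), 1e-8, 0.9))
  for (r2 in c(0.1, 0.5)) {
    kept <- clump(ss, panel, r2_max = r2, window_kb = 250)
    want <- clump_oracle(ss$snp, ss$chr, ss$pos, ss$p, G, r2, 250)
    expect_equal(sort(kept), want)
  }
})

test_that("scores follow the thresholded linear form and standardization is exact", {
  G <- matrix(c(1L, 2L, 0L, 1L,
                2L, 0L, 1L, 1L), 4, 2,
              dimnames = list(NULL, c("s1", "s2")))
  panel <- toy_panel(G)
  ss <- tibble::tibble(snp = c("s1", "s2"), chr = 1L, pos = panel$map$pos,
                       a1 = "A", a2 = "G", beta = c(0.1, -0.2), se = 0.01,
                       p = c(0.001, 0.06), orientation = "same")
  prof <- score_prs(panel, ss, thresholds = c(1e-4, 0.05, 1))
  # person 1: only s1 passes at 0.05 -> 0.1; both at 1 -> 0.1*1 - 0.2*2 = -0.3
  expect_equal(prof$score_0.05[1], 0.1)
  expect_equal(prof$score_1[1], 0.1 * 1 - 0.2 * 2)
  expect_equal(unname(attr(prof, "n_snps")), c(0L, 1L, 2L))
  # empty threshold -> all-zero scores, flagged NA standardization
  expect_true(all(prof$score_0.0001 == 0))
  expect_true(all(is.na(prof$`score_0.0001_z`)))
  # standardization exactness
  expect_lt(abs(mean(prof$score_1_z)), 1e-10)
  expect_lt(abs(sd(prof$score_1_z) - 1), 1e-8)
  expect_error(score_prs(panel, ss, thresholds = numeric(0)), "empty")
})

test_that("score sets are monotone in the threshold and linear in the weights", {
  ch <- small_cohort()
  m <- match_alleles(ch$sumstats, ch$study)
  prof <- score_prs(ch$study, m)
  ns <- attr(prof, "n_snps")
  expect_true(all(diff(ns) >= 0))
  # linearity: splitting the weights reproduces the sum
  m1 <- m; m1$beta <- m$beta * 0.3
  m2 <- m; m2$beta <- m$beta * 0.7
  p1 <- score_prs(ch$study, m1, thresholds = 0.5)
  p2 <- score_prs(ch$study, m2, thresholds = 0.5)
  expect_equal(p1$score_0.5 + p2$score_0.5, prof$score_0.5, tolerance = 1e-12)
})

test_that("missing dosages are mean-imputed in scoring", {
  G <- matrix(c(0L, 2L, NA, 2L), 4, 1, dimnames = list(NULL, "s1"))
  panel <- toy_panel(G)
  ss <- tibble::tibble(snp = "s1", chr = 1L, pos = 1e6L, a1 = "A", a2 = "G",
                       beta = 1, se = 0.01, p = 0.01)
  prof <- score_prs(panel, ss, thresholds = 1)
  expect_equal(prof$score_1[3], 2 * mean(c(0, 2, 2)) / 2)
})

test_that("incremental Nagelkerke R2 matches hand-enumerated Bernoulli likelihoods", {
  # toy structure: binary PRS group, outcome frequencies differ by group
  y <- c(rep(1, 8), rep(0, 2), rep(1, 3), rep(0, 7))
  z <- c(rep(1, 10), rep(0, 10))
  prof <- tibble::tibble(id = paste0("p", 1:20), score_1 = z,
                         score_1_z = (z - mean(z)) / sd(z))
  attr(prof, "thresholds") <- 1
  attr(prof, "n_snps") <- c("1" = 1L)
  class(prof) <- c("prs_profile", class(prof))
  pheno <- tibble::tibble(id = paste0("p", 1:20), case = y)
  ev <- nagelkerke_eval(prof, pheno)
  # closed-form saturated-by-group likelihoods
  l1 <- 0.8^8 * 0.2^2 * 0.3^3 * 0.7^7
  l0 <- 0.55^11 * 0.45^9
  want <- (1 - (l0 / l1)^(2 / 20)) / (1 - l0^(2 / 20))
  expect_equal(ev$delta_r2, want, tolerance = 1e-6)
  expect_equal(ev$ll0, log(l0), tolerance = 1e-8)
  expect_equal(ev$ll1, log(l1), tolerance = 1e-8)
})

test_that("a pure-noise PRS explains almost nothing", {
  set.seed(4)
  n <- 2000
  z <- rnorm(n)
  prof <- tibble::tibble(id = paste0("p", 1:n), score_1 = z, score_1_z = zscore(z))
  attr(prof, "thresholds") <- 1
  attr(prof, "n_snps") <- c("1" = 10L)
  class(prof) <- c("prs_profile", class(prof))
  pheno <- tibble::tibble(id = paste0("p", 1:n), case = rbinom(n, 1, 0.5))
  ev <- nagelkerke_eval(prof, pheno)
  expect_lt(ev$delta_r2, 0.005)
})

test_that("permutation empirical p has the add-one floor and is seed-stable", {
  ch <- small_cohort()
  m <- match_alleles(ch$sumstats, ch$study)
  kept <- clump(m, ch$study)
  prof <- score_prs(ch$study, m[m$snp %in% kept, ],
                    thresholds = c(0.01, 0.05, 0.5))
  pheno <- ch$phenotypes[c("id", "case", "sex", "age")]
  pp <- permutation_empirical_p(prof, pheno, covariates = c("sex", "age"),
                                n_perm = 150, seed = 5)
  pp2 <- permutation_empirical_p(prof, pheno, covariates = c("sex", "age"),
                                 n_perm = 150, seed = 5)
  expect_identical(pp$empirical_p, pp2$empirical_p)
  # strong true signal: observed best p beats every permutation
  expect_equal(pp$empirical_p, 1 / 151)
  expect_equal(pp$n_perm, 150)
  expect_warning(
    permutation_empirical_p(prof, pheno, covariates = c("sex", "age"),
                            n_perm = 20, seed = 1), "coarse")
})

test_that("the empirical p is never anti-conservative against the naive best p", {
  set.seed(6)
  n <- 250
  G <- matrix(rbinom(n * 40, 2L, 0.4), n, 40,
              dimnames = list(NULL, sprintf("s%02d", 1:40)))
  panel <- toy_panel(G, pos = as.integer(1:40 * 1e6))
  for (rep_ in 1:3) {
    ss <- tibble::tibble(snp = colnames(G), chr = 1L, pos = panel$map$pos,
                         a1 = "A", a2 = "G", beta = rnorm(40, 0, 0.05),
                         se = 0.01, p = runif(40), orientation = "same")
    prof <- score_prs(panel, ss, thresholds = c(0.05, 0.2, 1))
    pheno <- tibble::tibble(id = paste0("p", 1:n), case = rbinom(n, 1, 0.5))
    pp <- permutation_empirical_p(prof, pheno, n_perm = 199, seed = rep_)
    mc_slack <- 2 * sqrt(pp$best_p_obs * (1 - pp$best_p_obs) / 199)
    expect_gte(pp$empirical_p, pp$best_p_obs - mc_slack)
  }
})
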