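# Standardized PCA, reference k-means assignment, iterative-pruning
# substructure search and cluster screening.

two_pop_panel <- function() {
  fixture("two_pop_panel", function() {
    simulate_populations(population_model(c(0.1, 0.1), c(250, 250)),
                         1000, seed = 101)
  })
}

test_that("PC1 separates two diverged populations by sign", {
  p <- two_pop_panel()
  pcs <- standardized_pca(p, n_pcs = 5)
  lab <- p$samples$population
  s <- sign(pcs$scores$PC1)
  acc <- max(mean((s > 0) == (lab == "pop1")), mean((s > 0) == (lab == "pop2")))
  expect_gte(acc, 0.99)
  # scores centered, components orthogonal
  expect_lt(max(abs(colMeans(as.matrix(pcs$scores[-1])))), 1e-8)
  cp <- crossprod(as.matrix(pcs$scores[-1]))
  expect_lt(max(abs(cp[upper.tri(cp)])) / max(diag(cp)), 1e-8)
})

test_that("a homogeneous panel has no dominant component relative to a permuted null", {
  p <- simulate_populations(population_model(0.02, 300), 500, seed = 102)
  freq <- colMeans(p$dosage) / 2
  keep <- freq > 0 & freq < 1
  Z <- prsdims:::scale_dosage(p$dosage[, keep], freq[keep])
  obs <- max(prsdims:::top_pcs(Z, 1)$eigenvalues)
  set.seed(103)
  perm <- replicate(20, {
    Zp <- apply(Z, 2, sample)
    max(prsdims:::top_pcs(Zp, 1)$eigenvalues)
  })
  expect_lt(obs, max(perm) * 1.1)
})

test_that("duplicated individuals receive identical PC scores", {
  p <- two_pop_panel()
  samples <- p$samples[c(1:60, 1), ]
  samples$id[61] <- "copy"
  dup <- genotype_panel(p$dosage[c(1:60, 1), ], p$map, samples)
  pcs <- standardized_pca(dup, n_pcs = 3)
  expect_equal(unlist(pcs$scores[61, -1]), unlist(pcs$scores[1, -1]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("exclusion regions and the informative-SNP guard are honored", {
  p <- two_pop_panel()
  # exclude every SNP on chromosome 1 via one covering interval
  excl <- tibble::tibble(chr = 1L, start = 0, end = 3e9)
  pcs <- standardized_pca(p, exclude_regions = excl, n_pcs = 3)
  expect_lt(pcs$n_snps_used, sum(p$map$chr != 1) + 1)
  expect_error(standardized_pca(panel_subset(p, 1:40), n_pcs = 50),
               "individuals")
})

test_that("reference k-means assignment recovers labels and is order-invariant", {
  p <- simulate_populations(population_model(c(0.1, 0.1, 0.1), c(120, 120, 120),
                                             labels = c("EUR", "AFR", "EAS")),
                            1500, seed = 104)
  pcs <- standardized_pca(p, n_pcs = 4)
  ref <- tibble::tibble(id = p$samples$id, label = p$samples$population)
  asg <- assign_reference_clusters(pcs, ref, k = 3, seed = 7)
  expect_gte(mean(asg$label == ref$label), 0.95)

  # permuting individual order leaves assignments unchanged (seeded)
  set.seed(42)
  perm <- sample(nrow(pcs$scores))
  asg <- suppressWarnings(assign_reference_clusters(pcs, ref, k = 3, seed = 7))
  pcs2 <- pcs
  pcs2$scores <- pcs$scores[perm, ]
  asg2 <- suppressWarnings(assign_reference_clusters(pcs2, ref, k = 3, seed = 7))
  merged <- dplyr::inner_join(asg, asg2, by = "id")
  expect_true(all(merged$label.x == merged$label.y))

  # k = 1: everyone shares one label
  asg1 <- assign_reference_clusters(pcs, ref, k = 1, seed = 7)
  expect_equal(length(unique(asg1$label)), 1L)
  expect_warning(assign_reference_clusters(pcs, ref, k = 2, seed = 7),
                 "smaller than")
})

test_that("sign-flipped components leave the clustering unchanged", {
  p <- two_pop_panel()
  pcs <- standardized_pca(p, n_pcs = 4)
  ref <- tibble::tibble(id = p$samples$id[1:100],
                        label = p$samples$population[1:100])
  asg <- assign_reference_clusters(pcs, ref, k = 2, seed = 3)
  flipped <- pcs
  flipped$scores$PC1 <- -flipped$scores$PC1
  asg_f <- assign_reference_clusters(flipped, ref, k = 2, seed = 3)
  expect_equal(asg$label, asg_f$label)
})

test_that("ipPCA keeps a homogeneous sample intact and splits true structure", {
  # null calibration: one population -> one leaf
  leaves <- vapply(1:5, function(s) {
    p <- simulate_populations(population_model(0.02, 400), 500, seed = 200 + s)
    length(unique(ippca_partition(p, seed = s)$assignment$leaf))
  }, numeric(1))
  expect_gte(mean(leaves == 1), 0.8)

  # three populations recovered with high adjusted Rand index
  p3 <- simulate_populations(population_model(c(0.1, 0.1, 0.1), c(300, 300, 300)),
                             1500, seed = 210)
  tr <- ippca_partition(p3, seed = 11)
  expect_gte(adjusted_rand(tr$assignment$leaf, p3$samples$population), 0.9)
  # leaves partition the sample exactly
  expect_equal(sort(tr$assignment$id), sort(p3$samples$id))
  expect_true(all(!is.na(tr$assignment$leaf)))
  expect_true(all(table(tr$nodes$parent[!is.na(tr$nodes$parent)]) == 2))

  # a min_cluster above n/2 forces a single leaf without testing
  p <- simulate_populations(population_model(c(0.1, 0.1), c(60, 60)), 300, seed = 220)
  tr1 <- ippca_partition(p, min_cluster = 100, seed = 1)
  expect_equal(unique(tr1$nodes$decision), "terminal_small")
})

test_that("cluster screening keeps discriminative leaves and drops degenerate ones", {
  set.seed(31)
  n <- 400
  prs <- rnorm(n)
  case <- rbinom(n, 1, plogis(0.2 + 0.8 * prs))       # informative leaf
  tree <- list(assignment = tibble::tibble(id = paste0("p", 1:n), leaf = 1L))
  pheno <- tibble::tibble(id = paste0("p", 1:n), case = case,
                          sex = sample(c("male", "female"), n, TRUE),
                          age = rnorm(n, 35, 10))
  scr <- screen_clusters(tree, tibble::tibble(id = pheno$id, score = prs), pheno)
  expect_true(scr$keep[1])
  expect_equal(attr(scr, "analysis_ids"), pheno$id)

  # all-case leaf is non-informative
  pheno2 <- pheno; pheno2$case <- 1L
  scr2 <- screen_clusters(tree, tibble::tibble(id = pheno$id, score = prs), pheno2)
  expect_false(scr2$keep[1])
  expect_equal(scr2$reason[1], "non-informative")

  # no covariates: estimate equals a direct unadjusted logistic fit
  scr3 <- screen_clusters(tree, tibble::tibble(id = pheno$id, score = prs),
                          pheno, covariates = character())
  direct <- glm(case ~ prs, family = binomial())
  expect_equal(scr3$estimate[1], unname(coef(direct)["prs"]), tolerance = 1e-8)

  # ancestry requirement: mismatched label drops the leaf
  labs <- tibble::tibble(id = pheno$id, label = "AFR")
  scr4 <- screen_clusters(tree, tibble::tibble(id = pheno$id, score = prs),
                          pheno, cluster_labels = labs, target_ancestry = "EUR")
  expect_false(scr4$keep[1])
  expect_equal(scr4$reason[1], "ancestry not confirmed")
})

test_that("a pure-noise PRS keeps a leaf at roughly half the nominal rate", {
  set.seed(41)
  keeps <- replicate(300, {
    n <- 150
    prs <- rnorm(n)
    case <- rbinom(n, 1, 0.5)
    tree <- list(assignment = tibble::tibble(id = paste0("p", 1:n), leaf = 1L))
    pheno <- tibble::tibble(id = paste0("p", 1:n), case = case)
    scr <- screen_clusters(tree, tibble::tibble(id = pheno$id, score = prs),
                           pheno, covariates = character())
    scr$keep[1]
  })
  # one-sided positivity at two-sided p < 0.05: keep probability ~ 0.025
  expect_lt(abs(mean(keeps) - 0.025), 0.025)
})

test_that("a liability-coupled leaf is kept with high power", {
  kept <- vapply(1:10, function(s) {
    set.seed(500 + s)
    n <- 400
    prs <- rnorm(n)
    case <- rbinom(n, 1, plogis(0.6 * prs))
    tree <- list(assignment = tibble::tibble(id = paste0("p", 1:n), leaf = 1L))
    pheno <- tibble::tibble(id = paste0("p", 1:n), case = case)
    screen_clusters(tree, tibble::tibble(id = pheno$id, score = prs), pheno,
                    covariates = character())$keep[1]
  }, logical(1))
  expect_gte(mean(kept), 0.9)
})

test_that("ipPCA is deterministic under a fixed seed", {
  p <- two_pop_panel()
  t1 <- ippca_partition(p, seed = 9)
  t2 <- ippca_partition(p, seed = 9)
  expect_identical(t1$assignment, t2$assignment)
  expect_identical(t1$nodes, t2$nodes)
})
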