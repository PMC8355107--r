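# Balding-Nichols genotype simulation: per-population allele frequencies are
# Beta-distributed around a shared ancestral frequency, with divergence F.

#' Describe a multi-population Balding-Nichols model
#'
#' @param fst divergence parameter F per population, each in (0, 1).
#' @param cluster_sizes individuals per population (same length as `fst`).
#' @param labels optional population labels (default `pop1`, `pop2`, ...).
#' @param p_anc optional per-SNP ancestral allele frequencies in `[0.05, 0.95]`;
#'   if `NULL` they are drawn uniformly at simulation time.
#' @return A `population_model` list used by [simulate_populations()].
#' @export
population_model <- function(fst, cluster_sizes, labels = NULL, p_anc = NULL) {
  assert_that(length(fst) == length(cluster_sizes),
              "fst and cluster_sizes must have the same length")
  assert_that(all(fst > 0 & fst < 1),
              "all divergence parameters F must lie strictly in (0, 1)")
  assert_that(all(cluster_sizes >= 0) && sum(cluster_sizes) > 0,
              "cluster sizes must be non-negative with at least one individual")
  if (!is.null(p_anc)) {
    assert_that(all(p_anc >= 0.05 & p_anc <= 0.95),
                "ancestral frequencies must lie in [0.05, 0.95]")
  }
  labels <- labels %||% paste0("pop", seq_along(fst))
  structure(list(n_populations = length(fst), fst = fst,
                 cluster_sizes = as.integer(cluster_sizes),
                 labels = labels, p_anc = p_anc),
            class = "population_model")
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' For population `k` and SNP `j` the population frequency is drawn
#' `Beta(p(1 - F_k) / F_k, (1 - p)(1 - F_k) / F_k)` around the ancestral
#' frequency `p`, and genotypes are `Binomial(2, p_pop)` allele counts.
#' Optional LD blocks create runs of adjacent, highly correlated SNPs so that
#' clumping has structure to act on: block members start as copies of the
#' block seed SNP and each individual's genotype is independently refreshed
#' from the population frequency with probability `refresh`.
#'
#' @param model a [population_model()].
#' @param n_snps number of SNPs (>= 1).
#' @param seed integer seed (required; the draw is bit-reproducible).
#' @param ld_blocks `NULL` for exchangeable SNPs, or
#'   `list(n =, size =, refresh =)` describing `n` blocks of `size` adjacent
#'   SNPs with per-entry refresh probability `refresh`.
#' @param id_prefix prefix for generated sample ids.
#' @return A [genotype_panel()] with population labels in `$samples` and the
#'   generating per-population frequencies in `attr(, "pop_freq")`.
#' @export
simulate_populations <- function(model, n_snps, seed, ld_blocks = NULL,
                                 id_prefix = "ind") {
  assert_that(inherits(model, "population_model"), "model must be a population_model")
  assert_that(n_snps >= 1, "n_snps must be >= 1")
  assert_that(!missing(seed) && !is.null(seed), "a seed is required")
  with_substream(seed, "genotypes", {
    n_pop <- model$n_populations
    p_anc <- model$p_anc %||% runif(n_snps, 0.05, 0.95)
    assert_that(length(p_anc) == n_snps, "p_anc must have one entry per SNP")

    # block layout: block members are adjacent; independent SNPs are spaced
    # 500 kb apart so they never share a clumping window, block members 10 kb
    block_of <- rep(NA_integer_, n_snps)
    if (!is.null(ld_blocks)) {
      size <- ld_blocks$size
      n_b <- ld_blocks$n
      assert_that(size >= 2 && n_b >= 1, "ld_blocks needs n >= 1 and size >= 2")
      assert_that(n_b * size <= n_snps, "ld blocks exceed n_snps")
      block_of[seq_len(n_b * size)] <- rep(seq_len(n_b), each = size)
      p_anc[seq_len(n_b * size)] <- rep(p_anc[seq(1L, n_b * size, by = size)],
                                        each = size)
    }

    pop_freq <- matrix(NA_real_, n_pop, n_snps)
    for (k in seq_len(n_pop)) {
      f <- model$fst[k]
      a <- p_anc * (1 - f) / f
      b <- (1 - p_anc) * (1 - f) / f
      pop_freq[k, ] <- rbeta(n_snps, a, b)
      if (!is.null(ld_blocks)) {
        # block members share the seed SNP's population frequency
        idx <- which(!is.na(block_of))
        seed_idx <- idx - (idx - 1L) %% ld_blocks$size
        pop_freq[k, idx] <- pop_freq[k, seed_idx]
      }
    }

    n_total <- sum(model$cluster_sizes)
    pop_id <- rep(seq_len(n_pop), times = model$cluster_sizes)
    dosage <- matrix(NA_integer_, n_total, n_snps)
    for (k in seq_len(n_pop)) {
      rows <- which(pop_id == k)
      if (!length(rows)) next
      dosage[rows, ] <- matrix(
        rbinom(length(rows) * n_snps, 2L,
               rep(pop_freq[k, ], each = length(rows))),
        nrow = length(rows))
    }
    if (!is.null(ld_blocks)) {
      refresh <- ld_blocks$refresh
      for (j in which(!is.na(block_of))) {
        seed_j <- j - (j - 1L) %% ld_blocks$size
        if (seed_j == j) next
        redraw <- runif(n_total) < refresh
        col <- dosage[, seed_j]
        col[redraw] <- rbinom(sum(redraw), 2L, pop_freq[pop_id[redraw], j])
        dosage[, j] <- col
      }
    }

    alleles <- non_ambiguous_alleles(n_snps)
    step <- rep(500000L, n_snps)
    if (!is.null(ld_blocks) && n_snps > 1L) {
      same_block <- !is.na(block_of[-1L]) & !is.na(block_of[-n_snps]) &
        block_of[-1L] == block_of[-n_snps]
      step[-1L][same_block] <- 10000L
    }
    step[1L] <- 0L
    map <- tibble(
      snp = sprintf("rs%06d", seq_len(n_snps)),
      chr = 1L + as.integer((seq_len(n_snps) - 1L) %/% max(1, ceiling(n_snps / 22))),
      pos = 0L, a1 = alleles$a1, a2 = alleles$a2)
    map$pos <- stats::ave(cumsum(as.numeric(step)), map$chr,
                          FUN = function(x) x - min(x) + 1e6)
    map$pos <- as.integer(map$pos)

    samples <- tibble(id = sprintf("%s%05d", id_prefix, seq_len(n_total)),
                      population = model$labels[pop_id])
    out <- genotype_panel(dosage, map, samples)
    attr(out, "pop_freq") <- pop_freq
    attr(out, "ld_block") <- block_of
    out
  })
}

# draw A1/A2 pairs avoiding strand-ambiguous (A/T, C/G) combinations
non_ambiguous_alleles <- function(n) {
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  pick <- sample.int(4L, n, replace = TRUE)
  flip <- runif(n) < 0.5
  a1 <- ifelse(flip, pairs[pick, 2], pairs[pick, 1])
  a2 <- ifelse(flip, pairs[pick, 1], pairs[pick, 2])
  list(a1 = a1, a2 = a2)
}
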