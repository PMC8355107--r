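# Synthetic discovery-GWAS summary statistics: true log-odds effects observed
# with sampling noise matching an effective discovery sample size.

#' Declare the true effect structure of a synthetic cohort
#'
#' @param causal_snp_ids SNP ids carrying non-zero liability effects.
#' @param true_beta log-odds effect per causal SNP (same length).
#' @param gwas_n effective discovery-GWAS sample size (controls the sampling
#'   noise of the observed summary statistics).
#' @param dim_slopes tibble with columns `dimension`, `b_prs`, `b_cannabis`:
#'   standardized structural slopes of the latent symptom dimensions on the
#'   (standardized) true genetic score and on the cannabis indicator.
#' @param cannabis_logit_params `list(intercept =, case_shift =)` for the
#'   logistic model of cannabis use probability.
#' @return A `true_effects` list.
#' @export
true_effects <- function(causal_snp_ids, true_beta, gwas_n, dim_slopes,
                         cannabis_logit_params = list(intercept = -1.6,
                                                      case_shift = 1.0)) {
  assert_that(length(causal_snp_ids) == length(true_beta),
              "one true beta per causal SNP required")
  assert_that(all(is.finite(true_beta)), "true betas must be finite")
  dim_slopes <- as_tibble(dim_slopes)
  assert_that(all(c("dimension", "b_prs", "b_cannabis") %in% names(dim_slopes)),
              "dim_slopes needs columns dimension, b_prs, b_cannabis")
  assert_that(all(is.finite(dim_slopes$b_prs)) && all(is.finite(dim_slopes$b_cannabis)),
              "dimension slopes must be finite")
  structure(list(causal_snp_ids = causal_snp_ids, true_beta = true_beta,
                 gwas_n = gwas_n, dim_slopes = dim_slopes,
                 cannabis_logit_params = cannabis_logit_params),
            class = "true_effects")
}

# per-SNP true beta vector aligned to a panel's map (0 for non-causal)
true_beta_vector <- function(effects, panel) {
  beta <- setNames(rep(0, ncol(panel$dosage)), panel$map$snp)
  idx <- match(effects$causal_snp_ids, panel$map$snp)
  assert_that(!anyNA(idx), "causal SNP ids must be a subset of panel SNPs")
  beta[idx] <- effects$true_beta
  beta
}

#' Simulate GWAS summary statistics for a panel's variants
#'
#' Observed effects are `beta_hat = beta_true + N(0, se^2)` with
#' `se = 1 / sqrt(2 p (1 - p) N)` where `p` is the panel effect-allele
#' frequency and `N` the effective GWAS sample size; two-sided Wald p-values
#' and an odds-ratio column `exp(beta_hat)` are attached. Monomorphic SNPs
#' (frequency 0 or 1) are excluded; their count is recorded in
#' `attr(, "n_monomorphic")` and messaged.
#'
#' @param effects a [true_effects()] object.
#' @param panel a [genotype_panel()].
#' @param seed integer seed.
#' @return A tibble with columns `snp`, `chr`, `pos`, `a1`, `a2`, `beta`,
#'   `or`, `se`, `p` (summary-statistics layout used by the PRS stage).
#' @export
simulate_gwas_sumstats <- function(effects, panel, seed) {
  beta_true <- true_beta_vector(effects, panel)
  with_substream(seed, "sumstats", {
    p <- panel_freq(panel)
    mono <- p <= 0 | p >= 1
    if (any(mono)) {
      message(sprintf("excluding %d monomorphic SNPs from summary statistics",
                      sum(mono)))
    }
    keep <- which(!mono)
    se <- 1 / sqrt(2 * p[keep] * (1 - p[keep]) * effects$gwas_n)
    beta_hat <- beta_true[keep] + rnorm(length(keep), 0, se)
    out <- tibble(
      snp = panel$map$snp[keep], chr = panel$map$chr[keep],
      pos = panel$map$pos[keep], a1 = panel$map$a1[keep],
      a2 = panel$map$a2[keep],
      beta = unname(beta_hat), or = unname(exp(beta_hat)), se = unname(se),
      p = unname(wald_p(beta_hat, se)))
    attr(out, "n_monomorphic") <- sum(mono)
    out
  })
}
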