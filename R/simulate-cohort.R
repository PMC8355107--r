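# One-call synthetic cohort generation: genotypes for study + reference,
# discovery summary statistics, phenotypes, latent dimensions and item
# responses, all from a single master seed with named substreams.

#' Configuration of the synthetic case-control cohort
#'
#' Defaults define the canonical study conditions used throughout the test
#' suite: 2500 study individuals drawn from a homogeneous European-like
#' population (with a three-population reference panel for ancestry
#' assignment), 1000 SNPs of which 100 are causal, a discovery GWAS of
#' effective size 75,000, a liability slope calibrated so the true-effect PRS
#' explains a Nagelkerke delta-R2 of about 0.1, structural slopes of 0.2
#' (PRS, positive and negative dimensions) and 0.3 (cannabis, positive
#' dimension), and the fixed 23-item bi-factor bank.
#'
#' @param ... named overrides of the defaults (unknown names are an error).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(...) {
  defaults <- list(
    n_study = 2500L,
    study_cluster_sizes = NULL,   # default: all study individuals from pop 1
    n_reference = c(EUR = 150L, AFR = 100L, EAS = 100L),
    fst = c(0.01, 0.05, 0.1),
    population_labels = c("EUR", "AFR", "EAS"),
    n_snps = 1000L,
    n_causal = 100L,
    beta_sd = 0.05,
    gwas_n = 75000,
    ld_blocks = list(n = 50L, size = 2L, refresh = 0.05),
    liability = list(intercept = 0.45, slope = 0.6),
    cannabis = list(intercept = -1.6, case_shift = 1.0),
    dim_slopes = tibble(
      dimension = c("general", "positive", "negative", "disorganization",
                    "mania", "depression"),
      b_prs = c(0, 0.2, 0.2, 0, 0, 0),
      b_cannabis = c(0, 0.3, 0, 0, 0, 0)),
    sds_loadings = c(avolition = 0.75, emotional_expressivity = 0.85),
    covariates = list(age_mean = 33, age_sd = 12, age_range = c(18, 64),
                      p_male = 0.53),
    missing_rate = 0.05,
    item_bank = default_item_bank(),
    sds_bank = sds_item_bank()
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  assert_that(length(unknown) == 0,
              paste("unknown cohort_config keys:", paste(unknown, collapse = ", ")))
  modifyList(defaults, overrides)
}

#' Simulate a complete synthetic case-control cohort
#'
#' @param config a [cohort_config()].
#' @param seed master integer seed; every stage draws from a named substream
#'   of it, so runs are bit-reproducible.
#' @return A `prs_cohort` list: `study` and `reference` [genotype_panel()]s,
#'   `sumstats`, `effects`, `phenotypes`, `items` (+ `sds_items`), `bank`,
#'   `sds_bank`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed) {
  assert_that(!missing(seed), "a master seed is required")
  labels <- config$population_labels
  study_sizes <- config$study_cluster_sizes %||%
    c(config$n_study, rep(0L, length(labels) - 1L))
  assert_that(length(study_sizes) == length(labels),
              "study_cluster_sizes must match population_labels")
  ref_sizes <- as.integer(config$n_reference[labels])
  ref_sizes[is.na(ref_sizes)] <- 0L

  model <- population_model(config$fst, study_sizes + ref_sizes, labels = labels)
  panel <- simulate_populations(model, config$n_snps, seed,
                                ld_blocks = config$ld_blocks)

  # split combined panel into study and reference, preserving population freqs
  pop <- panel$samples$population
  role <- character(nrow(panel$dosage))
  for (k in seq_along(labels)) {
    rows <- which(pop == labels[k])
    role[rows] <- rep(c("study", "reference"),
                      times = c(study_sizes[k], ref_sizes[k]))
  }
  study <- panel_subset(panel, role == "study")
  study$samples$id <- sprintf("subj%05d", seq_len(nrow(study$dosage)))
  rownames(study$dosage) <- study$samples$id
  reference <- panel_subset(panel, role == "reference")
  reference$samples$id <- sprintf("ref%05d", seq_len(nrow(reference$dosage)))
  rownames(reference$dosage) <- reference$samples$id

  effects <- with_substream(seed, "effects", {
    causal <- sort(sample(panel$map$snp, config$n_causal))
    true_effects(causal, rnorm(config$n_causal, 0, config$beta_sd),
                 gwas_n = config$gwas_n, dim_slopes = config$dim_slopes,
                 cannabis_logit_params = config$cannabis)
  })

  sumstats <- simulate_gwas_sumstats(effects, study, seed)
  phenotypes <- simulate_phenotypes(
    study, effects,
    covariate_config = c(list(liability = config$liability), config$covariates),
    seed = seed)

  # SDS-like latents: two correlated negative-symptom facets driven by the
  # negative dimension (their correlation is the product of the loadings)
  phenotypes <- with_substream(seed, "sds_latents", {
    for (f in names(config$sds_loadings)) {
      lam <- config$sds_loadings[[f]]
      phenotypes[[paste0("theta_", f)]] <-
        lam * phenotypes$theta_negative + rnorm(nrow(phenotypes), 0, sqrt(1 - lam^2))
    }
    phenotypes
  })

  items <- simulate_item_responses(phenotypes, config$item_bank,
                                   missing_rate = config$missing_rate, seed = seed)
  sds_items <- simulate_item_responses(phenotypes, config$sds_bank,
                                       missing_rate = config$missing_rate,
                                       seed = substream_seed(seed, "sds_items"))

  structure(list(study = study, reference = reference, sumstats = sumstats,
                 effects = effects, phenotypes = phenotypes, items = items,
                 sds_items = sds_items, bank = config$item_bank,
                 sds_bank = config$sds_bank, config = config, seed = seed),
            class = "prs_cohort")
}

#' @export
print.prs_cohort <- function(x, ...) {
  cat(sprintf("<prs_cohort> %d study individuals (%d cases), %d reference, %d SNPs, %d items\n",
              nrow(x$study$dosage), sum(x$phenotypes$case),
              nrow(x$reference$dosage), ncol(x$study$dosage),
              nrow(x$bank)))
  invisible(x)
}
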