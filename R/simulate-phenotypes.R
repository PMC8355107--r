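# Phenotype and latent-dimension simulation: a standardized true genetic
# score drives case status through a logistic liability model; latent symptom
# dimensions receive additive genetic and cannabis effects.

#' Simulate case status, covariates, cannabis use and latent dimensions
#'
#' The true score is `S_i = sum_j beta_true_j G_ij`, standardized over the
#' cohort. Case status is `Bernoulli(plogis(alpha + lambda * S_i))`; cannabis
#' use is `Bernoulli(plogis(c0 + c1 * case_i))`; each latent dimension is
#' `theta = b_prs * S + b_cannabis * C + e`, with `e` scaled so the simulated
#' dimension has unit variance. Age is truncated-normal, sex Bernoulli, and a
#' five-level categorical research diagnosis is drawn for cases only.
#'
#' @param panel a [genotype_panel()] (the study individuals).
#' @param effects a [true_effects()] object.
#' @param covariate_config list of covariate and liability settings; see
#'   [cohort_config()] for the defaults.
#' @param seed integer seed.
#' @return A tibble with one row per individual: `id`, `population`, `case`,
#'   `sex`, `age`, `diagnosis`, `cannabis`, `true_score`, and one
#'   `theta_<dimension>` column per row of `effects$dim_slopes`.
#' @export
simulate_phenotypes <- function(panel, effects, covariate_config = list(), seed) {
  cfg <- modifyList(list(
    liability = list(intercept = 0.45, slope = 0.6),
    age_mean = 33, age_sd = 12, age_range = c(18, 64),
    p_male = 0.53,
    diagnosis_levels = c("bipolar", "depression_psychotic", "schizophrenia",
                         "schizoaffective", "unspecified"),
    diagnosis_probs = c(0.05, 0.05, 0.35, 0.38, 0.17)
  ), covariate_config)

  beta <- true_beta_vector(effects, panel)
  raw <- as.vector(panel$dosage %*% beta)
  s <- standardize(raw)
  n <- length(s)

  with_substream(seed, "phenotypes", {
    case <- rbinom(n, 1L, plogis(cfg$liability$intercept + cfg$liability$slope * s))
    cl <- effects$cannabis_logit_params
    cannabis <- rbinom(n, 1L, plogis(cl$intercept + cl$case_shift * case))
    sex <- ifelse(rbinom(n, 1L, cfg$p_male) == 1L, "male", "female")
    age <- rnorm(n, cfg$age_mean, cfg$age_sd)
    while (any(bad <- age < cfg$age_range[1] | age > cfg$age_range[2])) {
      age[bad] <- rnorm(sum(bad), cfg$age_mean, cfg$age_sd)
    }
    diagnosis <- rep(NA_character_, n)
    diagnosis[case == 1L] <- sample(cfg$diagnosis_levels, sum(case), replace = TRUE,
                                    prob = cfg$diagnosis_probs)

    out <- tibble(id = panel$samples$id,
                  population = panel$samples$population %||% NA_character_,
                  case = case, sex = sex, age = age, diagnosis = diagnosis,
                  cannabis = cannabis, true_score = s)
    for (d in seq_len(nrow(effects$dim_slopes))) {
      row <- effects$dim_slopes[d, ]
      systematic <- row$b_prs * s + row$b_cannabis * cannabis
      v <- var(systematic)
      assert_that(v < 1,
                  sprintf("dimension '%s': structural slopes explain variance >= 1",
                          row$dimension))
      theta <- systematic + rnorm(n, 0, sqrt(1 - v))
      out[[paste0("theta_", row$dimension)]] <- theta
    }
    out
  })
}
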