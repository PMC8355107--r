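# Polygenic risk scoring: allele matching, greedy LD clumping, thresholded
# weighted dosage sums, Nagelkerke incremental pseudo-R2 evaluation and
# permutation empirical p-values.

#' Match summary-statistic alleles to a genotype panel
#'
#' SNPs are matched by id. When the panel's counted allele equals the summary
#' A2, the effect sign is flipped and the orientation recorded.
#' Strand-ambiguous (A/T, C/G) SNPs are dropped by default, as are SNPs whose
#' alleles cannot be reconciled and SNPs absent from the panel.
#'
#' @param sumstats tibble with `snp`, `a1`, `a2`, `beta` (or `or`), `se`, `p`.
#' @param panel a [genotype_panel()].
#' @param drop_ambiguous drop A/T and C/G SNPs (default `TRUE`).
#' @return Matched sumstats tibble (effect `beta` oriented to the panel's
#'   counted allele, `orientation` column `"same"`/`"flipped"`), with counts
#'   of dropped SNPs in `attr(, "match_report")`.
#' @export
match_alleles <- function(sumstats, panel, drop_ambiguous = TRUE) {
  ss <- as_tibble(sumstats)
  if (!"beta" %in% names(ss) && "or" %in% names(ss)) ss$beta <- log(ss$or)
  assert_that(all(c("snp", "a1", "a2", "beta", "p") %in% names(ss)),
              "sumstats needs columns snp, a1, a2, beta (or or), p")
  ambiguous <- (ss$a1 == "A" & ss$a2 == "T") | (ss$a1 == "T" & ss$a2 == "A") |
    (ss$a1 == "C" & ss$a2 == "G") | (ss$a1 == "G" & ss$a2 == "C")
  n_ambiguous <- if (drop_ambiguous) sum(ambiguous) else 0L
  if (drop_ambiguous) ss <- ss[!ambiguous, ]

  idx <- match(ss$snp, panel$map$snp)
  n_unmatched <- sum(is.na(idx))
  ss <- ss[!is.na(idx), ]; idx <- idx[!is.na(idx)]
  same <- ss$a1 == panel$map$a1[idx] & ss$a2 == panel$map$a2[idx]
  flipped <- ss$a1 == panel$map$a2[idx] & ss$a2 == panel$map$a1[idx]
  n_mismatch <- sum(!same & !flipped)
  keep <- same | flipped
  ss <- ss[keep, ]
  assert_that(nrow(ss) > 0, "no summary-statistic SNPs overlap the panel")
  ss$orientation <- ifelse(same[keep], "same", "flipped")
  ss$beta <- ifelse(ss$orientation == "flipped", -ss$beta, ss$beta)
  if ("or" %in% names(ss)) ss$or <- exp(ss$beta)
  attr(ss, "match_report") <- list(n_matched = nrow(ss),
                                   n_ambiguous = n_ambiguous,
                                   n_unmatched = n_unmatched,
                                   n_allele_mismatch = n_mismatch)
  ss
}

#' Greedy LD clumping
#'
#' Iterates SNPs by ascending p-value (ties broken by p, then position, then
#' id) and retains a SNP unless it lies within `window_kb` of an
#' already-retained SNP on the same chromosome with squared dosage
#' correlation above `r2_max`.
#'
#' @param sumstats matched sumstats (needs `snp`, `chr`, `pos`, `p`).
#' @param panel the [genotype_panel()] supplying dosages for r2.
#' @param r2_max squared-correlation threshold (default 0.1).
#' @param window_kb window in kilobases (default 250).
#' @return Character vector of retained SNP ids. SNPs with missing positions
#'   are excluded with a warning.
#' @export
clump <- function(sumstats, panel, r2_max = 0.1, window_kb = 250) {
  ss <- as_tibble(sumstats)
  no_pos <- is.na(ss$pos) | is.na(ss$chr)
  if (any(no_pos)) {
    warn(sprintf("%d SNPs without positions excluded from clumping", sum(no_pos)))
    ss <- ss[!no_pos, ]
  }
  ord <- order(ss$p, ss$pos, ss$snp)
  ss <- ss[ord, ]
  G <- panel$dosage[, ss$snp, drop = FALSE]
  window <- window_kb * 1000
  retained <- integer(0)
  for (i in seq_len(nrow(ss))) {
    near <- retained[ss$chr[retained] == ss$chr[i] &
                       abs(ss$pos[retained] - ss$pos[i]) <= window]
    blocked <- FALSE
    for (j in near) {
      r <- suppressWarnings(cor(G[, i], G[, j], use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_max) { blocked <- TRUE; break }
    }
    if (!blocked) retained <- c(retained, i)
  }
  ss$snp[retained]
}

#' Thresholded polygenic scores
#'
#' `S_i(P_T) = sum over SNPs with p <= P_T of beta_j G_ij`; missing dosages
#' are imputed as twice the effect-allele frequency of the analysis sample.
#' Raw scores and within-sample standardized scores (`_z` columns) are both
#' returned.
#'
#' @param panel a [genotype_panel()].
#' @param matched_sumstats output of [match_alleles()], usually restricted to
#'   a clumped SNP set.
#' @param thresholds p-value threshold grid (default the PRSice-style grid;
#'   0.05 is the conventional a-priori primary threshold).
#' @return A `prs_profile` tibble: `id`, `score_<P_T>`, `score_<P_T>_z`, with
#'   SNP counts per threshold in `attr(, "n_snps")`.
#' @export
score_prs <- function(panel, matched_sumstats,
                      thresholds = c(5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.5, 1)) {
  assert_that(length(thresholds) > 0, "threshold grid must not be empty")
  thresholds <- sort(thresholds)
  ss <- matched_sumstats[matched_sumstats$snp %in% panel$map$snp, ]
  G <- panel$dosage[, ss$snp, drop = FALSE]
  freq <- colMeans(G, na.rm = TRUE) / 2
  for (j in seq_len(ncol(G))) {
    miss <- is.na(G[, j])
    if (any(miss)) G[miss, j] <- 2 * freq[j]
  }
  out <- tibble(id = panel$samples$id)
  n_snps <- integer(length(thresholds))
  for (t in seq_along(thresholds)) {
    inc <- ss$p <= thresholds[t]
    n_snps[t] <- sum(inc)
    s <- as.vector(G[, inc, drop = FALSE] %*% ss$beta[inc])
    out[[paste0("score_", thr_label(thresholds[t]))]] <- s
    z <- if (sum(inc) > 0 && sd(s) > 0) standardize(s) else rep(NA_real_, length(s))
    out[[paste0("score_", thr_label(thresholds[t]), "_z")]] <- z
  }
  attr(out, "thresholds") <- thresholds
  attr(out, "n_snps") <- setNames(n_snps, thr_label(thresholds))
  class(out) <- c("prs_profile", class(out))
  out
}

# incremental Nagelkerke pseudo-R2 from covariate-only and full log-likelihoods
nagelkerke_r2 <- function(ll0, ll1, n) {
  (1 - exp((2 / n) * (ll0 - ll1))) / (1 - exp((2 / n) * ll0))
}

#' Evaluate PRS case-control discrimination across thresholds
#'
#' Per threshold, fits the covariate-only and covariate + PRS logistic models
#' by maximum likelihood and reports the incremental Nagelkerke
#' `R2 = [1 - (L0/L1)^(2/N)] / [1 - L0^(2/N)]` (likelihoods, not logs),
#' together with the PRS coefficient and its Wald p. Thresholds with
#' separation (`|coef| > 15`) are flagged unreliable.
#'
#' @param profile a `prs_profile` from [score_prs()].
#' @param phenotype tibble with `id`, `case` and covariate columns.
#' @param covariates covariate column names (may be empty).
#' @return A `prs_eval` tibble, one row per threshold (`threshold`, `n_snps`,
#'   `estimate`, `se`, `p`, `ll0`, `ll1`, `delta_r2`, `reliable`), with the
#'   best threshold (max `delta_r2`) in `attr(, "best")`.
#' @export
nagelkerke_eval <- function(profile, phenotype, covariates = character()) {
  thresholds <- attr(profile, "thresholds")
  n_snps <- attr(profile, "n_snps")
  dat <- dplyr::inner_join(profile, phenotype, by = "id")
  assert_that(all(dat$case %in% 0:1), "phenotype must be binary 0/1")
  covs <- covariates[covariates %in% names(dat)]
  cc <- complete.cases(dat[c("case", covs)])
  dat <- dat[cc, ]
  n <- nrow(dat)
  f0 <- stats::as.formula(paste("case ~", if (length(covs))
    paste(covs, collapse = " + ") else "1"))
  m0 <- glm(f0, family = binomial(), data = dat)
  ll0 <- as.numeric(logLik(m0))
  rows <- lapply(seq_along(thresholds), function(t) {
    zcol <- paste0("score_", thr_label(thresholds[t]), "_z")
    base <- tibble(threshold = thresholds[t], n_snps = unname(n_snps[t]))
    if (all(is.na(dat[[zcol]]))) {
      return(dplyr::mutate(base, estimate = NA_real_, se = NA_real_,
                           p = NA_real_, ll0 = ll0, ll1 = NA_real_,
                           delta_r2 = NA_real_, reliable = FALSE))
    }
    d1 <- dat; d1$prs <- d1[[zcol]]
    f1 <- stats::as.formula(paste("case ~ prs +", if (length(covs))
      paste(covs, collapse = " + ") else "1"))
    m1 <- glm(f1, family = binomial(), data = d1)
    ll1 <- as.numeric(logLik(m1))
    est <- coef(summary(m1))["prs", ]
    dplyr::mutate(base, estimate = est[["Estimate"]], se = est[["Std. Error"]],
                  p = est[["Pr(>|z|)"]], ll0 = ll0, ll1 = ll1,
                  delta_r2 = nagelkerke_r2(ll0, ll1, n),
                  reliable = abs(est[["Estimate"]]) <= 15)
  })
  out <- dplyr::bind_rows(rows)
  best <- out$threshold[which.max(ifelse(out$reliable, out$delta_r2, -Inf))]
  attr(out, "best") <- best
  attr(out, "n") <- n
  class(out) <- c("prs_eval", class(out))
  out
}

#' Permutation empirical p-value for the best-threshold association
#'
#' Re-runs the full threshold sweep on phenotypes shuffled across individuals
#' (covariates stay attached to their individuals), recording each
#' permutation's best (minimum) PRS association p; the empirical p is
#' `(1 + #(best_p_perm <= best_p_obs)) / (n_perm + 1)`.
#'
#' @param profile a `prs_profile`.
#' @param phenotype tibble with `id`, `case`, covariates.
#' @param covariates covariate column names.
#' @param n_perm number of permutations (default 5000; fewer than 100 draws a
#'   granularity warning).
#' @param seed integer seed.
#' @return List: `empirical_p`, `best_p_obs`, `best_threshold`, `n_perm`,
#'   `perm_best_p` (the permuted null distribution).
#' @export
permutation_empirical_p <- function(profile, phenotype,
                                    covariates = character(), n_perm = 5000,
                                    seed = 1) {
  if (n_perm < 100) warn("fewer than 100 permutations: empirical p is coarse")
  obs <- nagelkerke_eval(profile, phenotype, covariates)
  best_p_obs <- min(obs$p, na.rm = TRUE)

  thresholds <- attr(profile, "thresholds")
  dat <- dplyr::inner_join(profile, phenotype, by = "id")
  covs <- covariates[covariates %in% names(dat)]
  dat <- dat[complete.cases(dat[c("case", covs)]), ]
  zcols <- paste0("score_", thr_label(thresholds), "_z")
  zcols <- zcols[vapply(zcols, function(zc) !all(is.na(dat[[zc]])), logical(1))]
  Xcov <- stats::model.matrix(
    stats::as.formula(paste("~", if (length(covs)) paste(covs, collapse = "+") else "1")),
    data = dat)
  y <- dat$case
  best_perm_p <- with_substream(seed, "prs_permutation", {
    vapply(seq_len(n_perm), function(b) {
      yp <- sample(y)
      min(vapply(zcols, function(zc) {
        fit <- suppressWarnings(
          glm.fit(cbind(Xcov, prs = dat[[zc]]), yp, family = binomial()))
        est <- coef(fit)[["prs"]]
        # Wald p from the final IRLS weights
        XW <- cbind(Xcov, prs = dat[[zc]]) * sqrt(fit$weights)
        se <- sqrt(tryCatch(solve(crossprod(XW))["prs", "prs"],
                            error = function(e) NA_real_))
        wald_p(est, se)
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
  })
  list(empirical_p = (1 + sum(best_perm_p <= best_p_obs)) / (n_perm + 1),
       best_p_obs = best_p_obs,
       best_threshold = attr(obs, "best"),
       n_perm = n_perm,
       perm_best_p = best_perm_p)
}

#' Plot the PRS evaluation across thresholds
#'
#' @param object a `prs_eval`.
#' @param ... unused.
#' @return A ggplot bar chart of incremental Nagelkerke R2 per threshold.
#' @method autoplot prs_eval
#' @export
autoplot.prs_eval <- function(object, ...) {
  d <- as_tibble(object)
  d$threshold <- factor(thr_label(d$threshold),
                        levels = thr_label(sort(unique(d$threshold))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$delta_r2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(P[T]), y = expression(Delta * R[Nagelkerke]^2)) +
    ggplot2::theme_minimal()
}
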