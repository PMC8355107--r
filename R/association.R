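# Association stage: linear regression of dimension scores on PRS and
# cannabis use, nested-model likelihood-ratio tests, Benjamini-Hochberg FDR,
# and cohort-comparison statistics recomputable from printed summary tables.

#' Regress dimension scores on a standardized PRS
#'
#' Ordinary least squares per outcome with Wald 95% confidence intervals
#' (normal critical value 1.96) and two-sided p-values, on complete cases.
#'
#' @param scores tibble `id` + one column per dimension score.
#' @param prs_z tibble `id`, `prs` (standardized polygenic score).
#' @param covariates tibble `id` + covariate columns (all are adjusted for);
#'   `NULL` for unadjusted fits.
#' @param outcomes which score columns to test (default: all non-`id`,
#'   non-`sd_` columns).
#' @return An `assoc_result` tibble: `outcome`, `predictor`, `estimate`
#'   (unstandardised slope B), `se`, `conf.low`, `conf.high`, `p`, `loglik`,
#'   `n`.
#' @export
dimension_regression <- function(scores, prs_z, covariates = NULL,
                                 outcomes = NULL) {
  outcomes <- outcomes %||%
    setdiff(names(scores), c("id", grep("^sd_", names(scores), value = TRUE)))
  dat <- dplyr::inner_join(as_tibble(scores), as_tibble(prs_z), by = "id")
  cov_cols <- character()
  if (!is.null(covariates)) {
    dat <- dplyr::inner_join(dat, as_tibble(covariates), by = "id")
    cov_cols <- setdiff(names(covariates), "id")
  }
  rows <- lapply(outcomes, function(oc) {
    d <- dat[complete.cases(dat[c(oc, "prs", cov_cols)]), ]
    rhs <- paste(c("prs", cov_cols), collapse = " + ")
    fit <- lm(stats::as.formula(paste0("`", oc, "` ~ ", rhs)), data = d)
    check_full_rank(fit)
    est <- coef(summary(fit))["prs", ]
    tibble(outcome = oc, predictor = "prs",
           estimate = est[["Estimate"]], se = est[["Std. Error"]],
           conf.low = est[["Estimate"]] - 1.96 * est[["Std. Error"]],
           conf.high = est[["Estimate"]] + 1.96 * est[["Std. Error"]],
           p = wald_p(est[["Estimate"]], est[["Std. Error"]]),
           loglik = as.numeric(logLik(fit)), n = nrow(d))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("assoc_result", class(out))
  out
}

check_full_rank <- function(fit) {
  if (anyNA(coef(fit))) {
    abort(paste("rank-deficient design; collinear column(s):",
                paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  invisible(fit)
}

#' Joint PRS + cannabis model with a likelihood-ratio test
#'
#' Fits the reduced model (PRS + covariates) and the full model (+ cannabis)
#' by maximum likelihood on the same rows and reports both adjusted slopes
#' plus the LR test `chi2 = 2 (LL_full - LL_reduced)` on 1 df.
#'
#' @param scores tibble `id` + score columns.
#' @param prs_z tibble `id`, `prs`.
#' @param cannabis tibble `id`, `cannabis` (binary 0/1).
#' @param covariates optional tibble `id` + covariates.
#' @param outcome which score column to model (default `"positive"`).
#' @return List with `results` (an `assoc_result` tibble, PRS and cannabis
#'   rows) and `lr_test` (tibble `chi2`, `df`, `p`).
#' @export
joint_cannabis_model <- function(scores, prs_z, cannabis, covariates = NULL,
                                 outcome = "positive") {
  dat <- dplyr::inner_join(as_tibble(scores), as_tibble(prs_z), by = "id") |>
    dplyr::inner_join(as_tibble(cannabis), by = "id")
  cov_cols <- character()
  if (!is.null(covariates)) {
    dat <- dplyr::inner_join(dat, as_tibble(covariates), by = "id")
    cov_cols <- setdiff(names(covariates), "id")
  }
  assert_that(all(dat$cannabis %in% 0:1), "cannabis indicator must be binary 0/1")
  d <- dat[complete.cases(dat[c(outcome, "prs", "cannabis", cov_cols)]), ]
  assert_that(length(unique(d$cannabis)) == 2,
              "cannabis indicator is degenerate (single level) in the analysis rows")
  rhs0 <- paste(c("prs", cov_cols), collapse = " + ")
  f0 <- stats::as.formula(paste0("`", outcome, "` ~ ", rhs0))
  f1 <- stats::as.formula(paste0("`", outcome, "` ~ cannabis + ", rhs0))
  m0 <- lm(f0, data = d); m1 <- lm(f1, data = d)
  check_full_rank(m1)
  assert_that(stats::nobs(m0) == stats::nobs(m1),
              "nested fits use differing case counts; nesting violated")
  chi2 <- 2 * (as.numeric(logLik(m1)) - as.numeric(logLik(m0)))
  row_of <- function(fit, term, label) {
    est <- coef(summary(fit))[term, ]
    tibble(outcome = outcome, predictor = label,
           estimate = est[["Estimate"]], se = est[["Std. Error"]],
           conf.low = est[["Estimate"]] - 1.96 * est[["Std. Error"]],
           conf.high = est[["Estimate"]] + 1.96 * est[["Std. Error"]],
           p = wald_p(est[["Estimate"]], est[["Std. Error"]]),
           loglik = as.numeric(logLik(fit)), n = nrow(d))
  }
  results <- dplyr::bind_rows(row_of(m1, "prs", "prs"),
                              row_of(m1, "cannabis", "cannabis"))
  class(results) <- c("assoc_result", class(results))
  list(results = results,
       lr_test = tibble(chi2 = chi2, df = 1L,
                        p = pchisq(chi2, df = 1, lower.tail = FALSE)))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Two adjusted-value variants over one p-value family: `raw` is the
#' rank-wise quotient `p_(k) * m / k` without monotonization (the quantity
#' printed in many applied reports), and `step_up_monotone` is the standard
#' step-up adjusted value (cumulative minimum from the largest rank, capped
#' at 1; equals `stats::p.adjust(method = "BH")`). Discovery flags always
#' come from the classical largest-k step-up rule at level `q`.
#'
#' @param pvals numeric p-values in (0, 1].
#' @param labels optional test labels.
#' @param q tolerated false discovery rate (default 0.10).
#' @return An `fdr_report` tibble: `label`, `p`, `rank`, `p_adj_raw`,
#'   `p_adj_monotone`, `discovery`.
#' @export
bh_adjust <- function(pvals, labels = NULL, q = 0.10) {
  assert_that(length(pvals) > 0, "empty p-value family")
  assert_that(all(pvals > 0 & pvals <= 1), "p-values must lie in (0, 1]")
  m <- length(pvals)
  labels <- labels %||% paste0("test", seq_len(m))
  ord <- order(pvals)                       # stable: ties keep input order
  rank_of <- integer(m); rank_of[ord] <- seq_len(m)
  p_adj_raw <- pvals * m / rank_of
  p_adj_monotone <- p.adjust(pvals, method = "BH")
  # classical step-up: reject the k smallest p-values, k the largest rank
  # with p_(k) <= k q / m
  sorted <- pvals[ord]
  ok <- which(sorted <= seq_len(m) * q / m)
  k_star <- if (length(ok)) max(ok) else 0L
  discovery <- rank_of <= k_star
  out <- tibble(label = labels, p = pvals, rank = rank_of,
                p_adj_raw = p_adj_raw, p_adj_monotone = p_adj_monotone,
                discovery = discovery)
  attr(out, "q") <- q
  class(out) <- c("fdr_report", class(out))
  out
}

#' Pearson chi-squared test for an r x c contingency table
#'
#' `sum (O - E)^2 / E` with expected counts from the margin products, no
#' continuity correction, `df = (r - 1)(c - 1)`.
#'
#' @param counts matrix (or table) of non-negative integer counts with all
#'   margins positive.
#' @return One-row tibble `chi2`, `df`, `p`.
#' @export
chi2_rxc <- function(counts) {
  counts <- as.matrix(counts)
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "counts must be non-negative integers")
  assert_that(all(rowSums(counts) > 0) && all(colSums(counts) > 0),
              "contingency table has a zero margin")
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble(chi2 = unname(ht$statistic), df = unname(ht$parameter),
         p = unname(ht$p.value))
}

#' Pooled two-sample t statistic from summary moments
#'
#' Student's t with pooled variance
#' `sp^2 = ((n1 - 1) sd1^2 + (n2 - 1) sd2^2) / (n1 + n2 - 2)`,
#' `t = (mean2 - mean1) / (sp sqrt(1/n1 + 1/n2))`, `df = n1 + n2 - 2`.
#'
#' @param mean1,sd1,n1 first group's mean, SD and size (`n1 >= 2`, `sd1 > 0`).
#' @param mean2,sd2,n2 second group's summaries.
#' @return One-row tibble `t`, `df`, `p` (two-sided).
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  assert_that(n1 >= 2 && n2 >= 2, "both groups need n >= 2")
  assert_that(sd1 > 0 && sd2 > 0, "both SDs must be positive")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  tt <- (mean2 - mean1) / (sp * sqrt(1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  tibble(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' Forest plot of association results
#'
#' @param object an `assoc_result` tibble.
#' @param ... unused.
#' @return A ggplot of slopes with 95% CIs per outcome/predictor.
#' @method autoplot assoc_result
#' @export
autoplot.assoc_result <- function(object, ...) {
  d <- as_tibble(object)
  d$label <- paste(d$outcome, d$predictor, sep = " ~ ")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "unstandardised slope B (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
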