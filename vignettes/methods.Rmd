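---
title: "Models and methods: polygenic scores, cannabis use and transdiagnostic symptom dimensions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

prsdims implements, as one tested chain, the analysis that links a
schizophrenia polygenic risk score (SZ-PRS) and cannabis use to
transdiagnostic dimensions of psychotic symptoms and experiences. This
vignette is the package's own account of each model, the choices that were
genuinely open, and what the synthetic cohort does and does not establish.

## The measurement model

Symptom checklists (observer-rated psychosis items in patients, self-rated
psychotic experiences in controls, a deficit-syndrome schedule for negative
symptoms) are dichotomised to present/absent. For a person with latent traits
$\theta$ the probability of endorsing item $j$ is the two-parameter logistic

$$P(X_{ij}=1\mid\theta_i) = \mathrm{logit}^{-1}\!\big(c_j + a_{G,j}\,
\theta_{G,i} + a_{S,j}\,\theta_{s(j),i}\big),$$

with one general factor $\theta_G$ loading on every item and orthogonal
specific factors (positive, negative, disorganization, mania, depression)
loading on item subsets. Four model kinds are estimable on the same data:

* `unidimensional` — a single factor ($a_S \equiv 0$);
* `bifactor` — general plus orthogonal specific factors;
* `second_order` — items load on first-order factors which in turn load on
  one higher-order factor with loadings $\gamma_s$ (the "hierarchical"
  competitor; marginally this is a correlated-factor model whose correlation
  matrix has one-factor structure $\gamma\gamma'$);
* `correlated` — per-factor loadings with a freely estimated factor
  correlation matrix, supported for up to three factors (tensor-product
  quadrature); with more factors the second-order kind is the tractable
  multidimensional competitor. The two-factor negative-symptom model
  (avolition and lack of emotional expressivity, `fit_sds_two_factor()`)
  is the correlated kind with $K=2$.

Estimation is marginal maximum likelihood by EM (Bock–Aitkin expected counts).
The bi-factor likelihood uses the dimension-reduction identity: conditional
on $\theta_G$ the specific factors are independent, so the $(1+K)$-dimensional
integral collapses to an outer one-dimensional Gauss–Hermite quadrature over
$\theta_G$ of per-factor one-dimensional inner quadratures. Missing responses
are skipped from the person product (missing at random, direct ML). Persons
sharing a response pattern on a factor's items are collapsed before the
E-step, which makes the per-iteration cost nearly independent of the sample
size.

Numerical choices: 21 Gauss–Hermite points per dimension (the log-likelihood
changes by less than $10^{-3}$ at 41 points on the canonical 23-item
fixture); EM stops when the largest absolute parameter change falls below
$10^{-4}$ (at most 500 iterations; non-convergence is flagged, never silently
returned); discriminations are capped at $|a| \le 8$ and flagged when the cap
binds (Heywood guard); sign indeterminacy is resolved deterministically by
reflecting each factor so its first item's discrimination is positive. Item
log-probabilities are evaluated on the log scale so extreme quadrature nodes
cannot underflow.

Model comparison uses $-2\mathrm{LL}$ penalised as AIC ($2k$), BIC
($k\ln N$) and the sample-size-adjusted BIC ($k\ln\frac{N+2}{24}$).
Reliability of the bi-factor solution is summarised by McDonald's
$\omega$, $\omega_H$ and the per-factor construct replicability $H$, after
converting logistic discriminations to standardized loadings with the
$D = 1.702$ rescaling, $\lambda = (a/D)/\sqrt{1 + \sum (a/D)^2}$.

### Item and person filters

Before fitting, persons with more than 20 missing ratings are dropped, then
items whose valid frequency of *present* falls below 10% are dropped — in
that order, which is recorded in the filter report. The person rule is
applied first so that item prevalences are computed on the analysable
persons; the operation is idempotent.

## Dimension scores and the attenuation correction

Per-person scores are expected a-posteriori (EAP) means with posterior SDs.
EAP scores shrink multiplicatively toward zero and, in bi-factor models,
leak across dimensions (the posterior mean of one specific factor borrows
from the general factor and, negatively, from its rivals). Used naively as
regression outcomes they therefore attenuate and distort slopes.

`rescale_scores(method = "disattenuate")` corrects this multivariately.
Under a normal approximation the EAP vector satisfies
$E[\hat\theta\mid\theta] = A\theta$ with $A = I - \bar V R^{-1}$, where
$\bar V$ is the average posterior covariance (including cross-trait terms)
and $R$ the prior covariance. One direction of $A$ — the contrast between
the general factor and the sum of the specifics — is weakly identified
(smallest eigenvalue of order $10^{-2}$ at the canonical conditions), and
inverting it would amplify score noise roughly forty-fold. The package
therefore floors the singular values of $A^{-1}$ at `min_shrinkage`
(default 0.3, i.e. at most a ~3.3-fold amplification) and renormalises so
each trait's own shrinkage is corrected exactly
($\mathrm{diag}(WA) = 1$). The residual price is bounded cross-dimension
leakage: at the canonical conditions, dimensions simulated with zero
genetic slope show mean spurious slopes of about $\pm 0.07$ across
replicate cohorts, and individual cohorts can exceed that (slopes of
$\pm 0.15$ on a weakly measured dimension are possible). This is a
fundamental limit of scoring five specific factors from 4–6 items each, not
of the implementation; interpreting small slopes on weakly measured
dimensions requires care, in real data as much as here.

## Ancestry analysis

`standardized_pca()` centers dosages and scales them by
$\sqrt{2\hat p(1-\hat p)}$, removing monomorphic SNPs and SNPs inside
long-range high-LD intervals (a canonical hg19 region list ships in
`inst/extdata`, replaceable; BED intervals are 0-based half-open,
converted in exactly one place). Study and reference individuals are
projected in one PC space; seeded k-means (Lloyd, order-invariant restarts)
transfers the majority reference superpopulation label to each cluster.

`ippca_partition()` searches for fine-scale substructure by recursive
pruning: each node's leading eigenvalue is compared with a permutation null
in which every SNP column is permuted independently within the node, and
significant nodes are split by 2-means on their top two PCs. Because column
permutation destroys linkage disequilibrium, the node's SNPs are LD-pruned
first (greedy, $r^2 > 0.2$ within 250 kb) — without this, LD alone mimics
substructure. The test statistic uses a seeded subsample of at most 500 SNPs
and a fixed-length power iteration applied identically to observed and
permuted matrices, so the comparison is calibrated by construction. With the
default 50 permutations an empirical p cannot reach the default
$\alpha = 10^{-3}$, so the tail probability is taken from the permuted
null's moments (Gaussian tail); with enough permutations the empirical p is
used directly. Splits require both children to have at least `min_cluster`
(50) members.

`screen_clusters()` then fits `case ~ PRS + sex + age` per leaf and keeps
leaves where the PRS coefficient is positive with two-sided $p < 0.05$
(one-sided positivity: "discriminative value" has an expected direction)
and, when reference labels are available, the leaf's majority ancestry
matches the configured target. The union of kept leaves is the analysis
sample.

## Polygenic scoring

Summary statistics are matched to the panel by SNP id; effects are flipped
when the panel counts the other allele, and strand-ambiguous (A/T, C/G)
SNPs are dropped with a count. Clumping is greedy by ascending p-value
(ties: p, position, id) with defaults $r^2 = 0.1$ within 250 kb — PRSice-1
era defaults, exposed as arguments. Scores are raw weighted sums
$S_i(P_T) = \sum_{p_j \le P_T}\hat\beta_j G_{ij}$ over the threshold grid
$\{5\times10^{-8}, 10^{-5}, 10^{-3}, 0.01, 0.05, 0.1, 0.2, 0.5, 1\}$, with
0.05 the a-priori primary threshold; missing dosages are imputed as twice
the within-sample allele frequency, and within-sample standardized `_z`
columns put regression slopes on the per-SD scale.

Discrimination is the incremental Nagelkerke pseudo-$R^2$,
$$R^2_N = \frac{1 - (L_0/L_1)^{2/N}}{1 - L_0^{2/N}},$$
with $L_0$ the covariate-only and $L_1$ the covariate-plus-PRS likelihood.
The family-wise sensitivity analysis repeats the full threshold sweep on
5000 phenotype permutations (covariates stay attached to individuals) and
reports the add-one empirical p,
$(1 + \#\{p^{perm}_{best} \le p^{obs}_{best}\})/(B+1)$.

## Association stage

Dimension scores are regressed on the standardized PRS by OLS with Wald 95%
intervals ($\pm 1.96\,\mathrm{SE}$), on complete cases; case models adjust
for sex, age, 10 ancestry PCs and categorical diagnosis, control models for
sex, age and 10 PCs. The joint cannabis model adds the use indicator to the
PRS model on identical rows and compares fits with a likelihood-ratio test,
$\chi^2 = 2\Delta\mathrm{LL}$ on 1 df. The false-discovery family is the ten
PRS–dimension tests (six in cases, four in controls) at $q = 0.10$; both the
raw rank-wise BH quotient $p_{(k)}m/k$ (the quantity printed in many applied
reports; it can invert the p-value ordering) and the monotone step-up
adjusted value are always reported, with discovery flags from the classical
largest-$k$ rule. Cohort-description utilities (`chi2_rxc()`,
`t_from_summary()`) recompute contingency and pooled-t statistics directly
from printed counts and summary moments.

## The synthetic cohort

`simulate_cohort()` generates everything downstream of recruitment:

* **Genotypes** under the Balding–Nichols model — per population $k$ and
  SNP $j$, $p_{kj}\sim\mathrm{Beta}(p(1-F_k)/F_k,\,(1-p)(1-F_k)/F_k)$ with
  ancestral frequencies uniform on $[0.05, 0.95]$ and genotypes
  $\mathrm{Binomial}(2, p_{kj})$. Defaults: three populations with
  $F = (0.01, 0.05, 0.1)$; the study sample (2500 individuals, matching the
  1500/1000 case/control conditions) is drawn from the first, with a
  three-population reference panel (150/100/100) for label transfer. Fifty
  two-SNP LD blocks ($r^2\approx0.9$, members 10 kb apart; independent SNPs
  500 kb apart) give clumping structure to act on.
* **Summary statistics** for an effective discovery GWAS of 75,000: 100 of
  1000 SNPs causal with $\beta\sim N(0, 0.05^2)$, observed with
  $\mathrm{se} = 1/\sqrt{2p(1-p)N}$ noise, two-sided Wald p-values and an
  odds-ratio column.
* **Phenotypes**: the standardized true score $S_i=\sum_j\beta_jG_{ij}$
  drives case status through a logistic liability,
  $\Pr(\mathrm{case}) = \mathrm{logit}^{-1}(0.45 + 0.6\,S_i)$; the slope was
  calibrated once so the true-effect PRS explains an incremental Nagelkerke
  $R^2\approx 0.1$, the order of the reported case–control discrimination.
  Cannabis use is $\mathrm{logit}^{-1}(-1.6 + 1.0\,\mathrm{case})$
  (≈17% in controls, ≈35% in cases). Age is normal (33, 12) truncated to
  18–64, sex Bernoulli(0.53), and cases receive a five-level research
  diagnosis with realistic frequencies (no effect on the dimensions).
* **Latent dimensions**: $\theta_d = b_{prs}S + b_{cannabis}C +
  \varepsilon$, with $\varepsilon$ scaled so each simulated dimension has
  unit variance. Defaults: $b_{prs}=0.2$ on the positive and negative
  dimensions, $b_{cannabis}=0.3$ on the positive dimension, zero elsewhere.
  Two negative-symptom facets (avolition, emotional expressivity; loadings
  0.75 and 0.85 on the negative dimension) drive the SDS-like items.
* **Item responses** from the fixed 23-item bank (six positive, five
  negative, four each disorganization/mania/depression; marginal endorsement
  15–55%), masked missing completely at random at 5% — MCAR is the testable
  special case of the MAR assumption under which estimation is valid.

All randomness flows from one master seed through named substreams, so runs
are bit-reproducible and stages can be regenerated independently.

What passing tests show — and do not. The generator matches the study's
*statistical skeleton*: population structure, sampling noise in external
summary statistics, liability-scale case ascertainment, additive latent
effects of realistic size, 2PL response behaviour, MCAR gaps. It does not
emulate realistic linkage disequilibrium (SNPs are exchangeable apart from
the synthetic blocks), haplotype phase, imputation artefacts, rater effects,
site heterogeneity, or selection into genotyping. Recovery of the
generating slopes here therefore validates the machinery, not the clinical
conclusions one would draw from real data.

## Problem sizes used by the shipped checks

The canonical recovery study runs 20 replicate cohorts of 2500 individuals,
1000 SNPs and 23 items; null calibration of the dimension regression uses
500 replicate phenotype draws on a fixed 400-individual panel; permutation
uniformity uses 100 replicates of a 99-permutation sweep. These sizes give
Monte-Carlo error comfortably inside the tolerances they are checked
against.

## Known limitations

* Cross-dimension leakage of corrected bi-factor scores (above) bounds how
  precisely small slopes on weakly measured dimensions can be interpreted.
* The correlated kind is limited to three factors; richer correlated
  structures must go through the second-order parameterisation.
* The ipPCA stopping rule is a calibrated permutation/moment test, declared
  here as this package's rule rather than a reconstruction of any
  particular published variant.
* Logistic link only; probit parameters can be converted via $D=1.702$ but
  probit estimation itself is not implemented.
* Hard-call dosages only; dosage-probability input is out of scope.
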