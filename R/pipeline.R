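# End-to-end orchestration: ancestry screen -> analysis-sample selection ->
# PRS sweep (+ optional permutation) -> item filtering and model fits (cases
# and controls separately, plus the SDS-style two-factor fit) -> dimension
# scores -> regressions, LR tests, FDR.

stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
  })
}

#' Analysis settings for the cohort pipeline
#'
#' @param ... named overrides; see defaults in the function body. The
#'   defaults mirror the per-stage ledger defaults: 10 PCs, k-means over the
#'   reference superpopulations, ipPCA with 50 permutations at alpha 1e-3,
#'   clumping at r2 0.1 / 250 kb, the PRSice-style threshold grid with 0.05
#'   as the primary threshold, EAP scoring with attenuation correction, and
#'   the 10-test PRS FDR family at q = 0.10.
#' @return A named list of settings.
#' @export
analysis_settings <- function(...) {
  defaults <- list(
    n_pcs = 10,
    kmeans_k = NULL,            # default: number of reference labels
    target_ancestry = "EUR",
    ippca = list(min_cluster = 50, alpha = 1e-3, n_perm = 50, test_snps = 500),
    screen_p_cut = 0.05,
    clump_r2 = 0.1, clump_window_kb = 250,
    thresholds = c(5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.5, 1),
    primary_threshold = 0.05,
    n_perm = 0,                 # PRS permutation sweep (0 = skip)
    min_prevalence = 0.10, max_person_missing = 20,
    quadrature_points = 21,
    control_factors = c("positive", "negative", "depression"),
    score_rescale = "disattenuate",
    fit_controls = TRUE, fit_sds = TRUE, compare_models = FALSE,
    fdr_q = 0.10, fdr_family = "prs",
    seed = 1)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  assert_that(length(unknown) == 0,
              paste("unknown analysis settings:", paste(unknown, collapse = ", ")))
  modifyList(defaults, overrides)
}

#' Run the full analysis chain on in-memory cohort data
#'
#' @param study a [genotype_panel()] of study individuals.
#' @param sumstats summary-statistics tibble (internal column names, see
#'   [read_sumstats()]).
#' @param phenotypes tibble `id`, `case`, `sex`, `age`, `diagnosis`,
#'   `cannabis`.
#' @param items item response tibble with an `item_map` attribute.
#' @param reference optional reference [genotype_panel()] with population
#'   labels (enables ancestry assignment).
#' @param sds_items optional SDS-style item tibble (two-factor fit).
#' @param exclude_regions optional high-LD exclusion intervals.
#' @param settings an [analysis_settings()] list.
#' @return A `pipeline_result` list with per-stage outputs: `pca`,
#'   `ancestry_labels`, `tree`, `screen`, `analysis_ids`, `prs_eval`,
#'   `permutation`, `fits`, `scores`, `associations`, `lr_tests`, `fdr`,
#'   `match_report`, `timings`.
#' @export
analyze_cohort <- function(study, sumstats, phenotypes, items,
                           reference = NULL, sds_items = NULL,
                           exclude_regions = NULL,
                           settings = analysis_settings()) {
  s <- settings
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  # ---- ancestry -----------------------------------------------------------
  res <- list()
  res$ancestry_labels <- NULL
  stage("ancestry", {
    if (!is.null(reference)) {
      joint <- panel_rbind(study, reference)
      res$pca_joint <- standardized_pca(joint, exclude_regions, s$n_pcs)
      ref_labels <- tibble(id = reference$samples$id,
                           label = reference$samples$population)
      k <- s$kmeans_k %||% length(unique(ref_labels$label))
      res$ancestry_labels <- assign_reference_clusters(
        res$pca_joint, ref_labels, k = k, seed = s$seed)
    }
    res$tree <- ippca_partition(study, min_cluster = s$ippca$min_cluster,
                                alpha = s$ippca$alpha, n_perm = s$ippca$n_perm,
                                test_snps = s$ippca$test_snps, seed = s$seed)
  })
  timings$ancestry <- tic() - t0; t0 <- tic()

  # ---- PRS construction and cluster screen --------------------------------
  stage("prs", {
    matched <- match_alleles(sumstats, study)
    res$match_report <- attr(matched, "match_report")
    kept_snps <- clump(matched, study, r2_max = s$clump_r2,
                       window_kb = s$clump_window_kb)
    matched <- matched[matched$snp %in% kept_snps, ]
    res$clumped_snps <- kept_snps
    profile_all <- score_prs(study, matched, thresholds = s$thresholds)
    zc <- paste0("score_", thr_label(s$primary_threshold), "_z")
    screen_scores <- tibble(id = profile_all$id, score = profile_all[[zc]])
    res$screen <- screen_clusters(
      res$tree, screen_scores, phenotypes, covariates = c("sex", "age"),
      p_cut = s$screen_p_cut, cluster_labels = res$ancestry_labels,
      target_ancestry = if (is.null(res$ancestry_labels)) NULL else s$target_ancestry)
    res$analysis_ids <- attr(res$screen, "analysis_ids")
    assert_that(length(res$analysis_ids) > 0,
                "no cluster passed the PRS discrimination / ancestry screen")

    analysis_panel <- panel_subset(study, res$analysis_ids)
    res$pca <- standardized_pca(analysis_panel, exclude_regions, s$n_pcs)
    res$profile <- score_prs(analysis_panel, matched, thresholds = s$thresholds)
    pc_cols <- paste0("PC", seq_len(s$n_pcs))
    covar <- dplyr::inner_join(phenotypes[c("id", "case", "sex", "age",
                                            "diagnosis", "cannabis")],
                               res$pca$scores, by = "id")
    res$covariates <- covar
    res$prs_eval <- nagelkerke_eval(res$profile, covar,
                                    covariates = c("sex", "age", pc_cols))
    res$permutation <- if (s$n_perm > 0) {
      permutation_empirical_p(res$profile, covar,
                              covariates = c("sex", "age", pc_cols),
                              n_perm = s$n_perm, seed = s$seed)
    }
  })
  timings$prs <- tic() - t0; t0 <- tic()

  # ---- item models and dimension scores -----------------------------------
  stage("dimensions", {
    map <- attr(items, "item_map")
    assert_that(!is.null(map), "items need an item_map attribute")
    in_analysis <- items$id %in% res$analysis_ids
    case_ids <- phenotypes$id[phenotypes$case == 1]
    res$fits <- list(); res$scores <- list()

    fit_group <- function(tbl, factors) {
      sub_map <- map[map$factor %in% factors, ]
      tbl <- tbl[c("id", sub_map$item)]
      attr(tbl, "item_map") <- sub_map
      filtered <- filter_items(tbl, s$min_prevalence, s$max_person_missing)
      spec <- bifactor_spec(attr(filtered, "item_map"), model_kind = "bifactor")
      fit <- fit_item_model(filtered, spec,
                            quadrature_points = s$quadrature_points)
      sc <- rescale_scores(eap_scores(fit, filtered), s$score_rescale)
      list(fit = fit, scores = sc, filtered = filtered)
    }

    cases_tbl <- items[in_analysis & items$id %in% case_ids, ]
    g <- fit_group(cases_tbl, unique(map$factor))
    res$fits$cases <- g$fit; res$scores$cases <- g$scores
    res$filtered_cases <- g$filtered

    if (s$fit_controls) {
      ctrl_tbl <- items[in_analysis & !items$id %in% case_ids, ]
      g <- fit_group(ctrl_tbl, s$control_factors)
      res$fits$controls <- g$fit; res$scores$controls <- g$scores
    }

    if (s$fit_sds && !is.null(sds_items)) {
      sds_tbl <- sds_items[sds_items$id %in% res$scores$cases$id, ]
      filtered <- filter_items(sds_tbl, s$min_prevalence, s$max_person_missing)
      res$fits$sds <- fit_sds_two_factor(filtered,
                                         quadrature_points = s$quadrature_points)
      res$scores$sds <- rescale_scores(eap_scores(res$fits$sds, filtered),
                                       s$score_rescale)
    }

    if (s$compare_models) {
      res$model_comparison <- compare_item_models(res$filtered_cases,
                                                  quadrature_points = s$quadrature_points)
    }
  })
  timings$dimensions <- tic() - t0; t0 <- tic()

  # ---- association, LR tests, FDR -----------------------------------------
  stage("association", {
    pc_cols <- paste0("PC", seq_len(s$n_pcs))
    zc <- paste0("score_", thr_label(s$primary_threshold), "_z")
    prs_tbl <- tibble(id = res$profile$id, prs = res$profile[[zc]])
    covar <- res$covariates
    covar$diagnosis_cov <- ifelse(covar$case == 1, covar$diagnosis, "control")

    assoc <- list()
    case_cov <- covar[covar$case == 1, c("id", "sex", "age", pc_cols, "diagnosis_cov")]
    names(case_cov)[names(case_cov) == "diagnosis_cov"] <- "diagnosis"
    assoc$cases <- dimension_regression(res$scores$cases, prs_tbl, case_cov) |>
      dplyr::mutate(group = "cases", .before = 1)
    if (!is.null(res$scores$controls)) {
      ctrl_cov <- covar[covar$case == 0, c("id", "sex", "age", pc_cols)]
      assoc$controls <- dimension_regression(res$scores$controls, prs_tbl,
                                             ctrl_cov) |>
        dplyr::mutate(group = "controls", .before = 1)
    }
    if (!is.null(res$scores$sds)) {
      assoc$sds <- dimension_regression(res$scores$sds, prs_tbl, case_cov) |>
        dplyr::mutate(group = "cases_sds", .before = 1)
    }
    res$associations <- dplyr::bind_rows(assoc)

    cannabis_tbl <- covar[c("id", "cannabis")]
    res$lr_tests <- list(
      cases = joint_cannabis_model(res$scores$cases, prs_tbl, cannabis_tbl,
                                   case_cov, outcome = "positive"))
    if (!is.null(res$scores$controls)) {
      res$lr_tests$controls <- joint_cannabis_model(
        res$scores$controls, prs_tbl, cannabis_tbl,
        covar[covar$case == 0, c("id", "sex", "age", pc_cols)],
        outcome = "positive")
    }

    fam <- res$associations
    if (s$fdr_family == "prs") fam <- fam[fam$group %in% c("cases", "controls"), ]
    res$fdr <- bh_adjust(fam$p, paste(fam$group, fam$outcome, sep = ":"),
                         q = s$fdr_q)
  })
  timings$association <- tic() - t0
  res$timings <- timings
  res$settings <- s
  structure(res, class = "pipeline_result")
}

#' Fit and compare the four competing dimensional models
#'
#' Unidimensional, correlated (when the factor count allows an unstructured
#' correlation matrix), second-order and bi-factor fits on one filtered item
#' table, summarized by LL / AIC / BIC / SABIC.
#'
#' @param filtered a filtered item table with its `item_map` attribute.
#' @param quadrature_points quadrature points per dimension.
#' @return List with `fits` (named `irt_fit`s) and `table` (one row per
#'   model, ranked by BIC).
#' @export
compare_item_models <- function(filtered, quadrature_points = 21) {
  map <- attr(filtered, "item_map")
  kinds <- c("unidimensional", "second_order", "bifactor")
  if (length(unique(map$factor)) <= 3) kinds <- c(kinds, "correlated")
  fits <- lapply(kinds, function(k) {
    fit_item_model(filtered, bifactor_spec(map, model_kind = k),
                   quadrature_points = quadrature_points)
  })
  names(fits) <- kinds
  table <- dplyr::bind_rows(lapply(fits, function(f) {
    suppressWarnings(fit_indices(f))
  }), .id = "model") |> dplyr::arrange(.data$BIC)
  list(fits = fits, table = table)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> analysis sample n = %d; %d association tests\n",
              length(x$analysis_ids), nrow(x$associations)))
  invisible(x)
}

#' Parameter-recovery study on the canonical synthetic cohort
#'
#' Repeatedly simulates the canonical cohort, runs the full analysis chain
#' (ancestry screen, PRS construction, bi-factor fitting, attenuation-
#' corrected scores, case regressions), and compares the estimated slopes
#' with the generating values: PRS on the positive and negative dimensions
#' and cannabis on the positive dimension, plus the bi-factor discrimination
#' RMSE against the generating item bank.
#'
#' @param n_seeds number of replicate cohorts.
#' @param seed base seed; replicate `i` uses `seed * 1000 + i`.
#' @param config a [cohort_config()].
#' @param settings an [analysis_settings()]; the recovery study skips the
#'   control-group fit, the SDS fit and permutations by default.
#' @return Tibble, one row per seed: `prs_positive`, `prs_negative`,
#'   `cannabis_positive`, `rmse_a`, `delta_r2`, `lr_chi2`, `n_analysis`, with
#'   the generating slopes in `attr(, "truth")`.
#' @export
slope_recovery <- function(n_seeds = 20, seed = 1, config = cohort_config(),
                           settings = NULL) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    s_i <- (seed * 1000 + i) %% .Machine$integer.max
    ch <- simulate_cohort(config, seed = s_i)
    st <- settings %||% analysis_settings(fit_controls = FALSE, fit_sds = FALSE,
                                          n_perm = 0, seed = s_i)
    res <- analyze_cohort(ch$study, ch$sumstats, ch$phenotypes, ch$items,
                          reference = ch$reference, settings = st)
    a <- res$associations[res$associations$group == "cases", ]
    jm <- res$lr_tests$cases
    # discrimination recovery is evaluated on the full-cohort measurement
    # fit (the canonical n), while the association slopes come from the
    # group-specific fits that mirror the instrument administration
    full_items <- ch$items[ch$items$id %in% res$analysis_ids, ]
    attr(full_items, "item_map") <- attr(ch$items, "item_map")
    filtered <- filter_items(full_items, st$min_prevalence,
                             st$max_person_missing)
    full_fit <- fit_item_model(filtered,
                               bifactor_spec(attr(filtered, "item_map"),
                                             "bifactor"),
                               quadrature_points = st$quadrature_points)
    cmp <- dplyr::inner_join(full_fit$params, ch$bank,
                             by = "item", suffix = c("_est", "_true"))
    pe <- res$prs_eval
    tibble(seed = s_i,
           prs_positive = a$estimate[a$outcome == "positive"],
           prs_negative = a$estimate[a$outcome == "negative"],
           cannabis_positive = jm$results$estimate[jm$results$predictor == "cannabis"],
           rmse_a = sqrt(mean(c((cmp$a_g_est - cmp$a_g_true)^2,
                                (cmp$a_s_est - cmp$a_s_true)^2))),
           delta_r2 = pe$delta_r2[pe$threshold == st$primary_threshold],
           lr_chi2 = jm$lr_test$chi2,
           n_analysis = length(res$analysis_ids))
  })
  out <- dplyr::bind_rows(rows)
  truth <- config$dim_slopes
  attr(out, "truth") <- c(
    prs_positive = truth$b_prs[truth$dimension == "positive"],
    prs_negative = truth$b_prs[truth$dimension == "negative"],
    cannabis_positive = truth$b_cannabis[truth$dimension == "positive"])
  out
}

#' Run the pipeline from files
#'
#' Reads every input named in the configuration, runs [analyze_cohort()],
#' and writes the declared outputs plus a machine-readable run manifest. Any
#' stage failure halts with a stage-named error; outputs of earlier stages
#' remain on disk.
#'
#' @param config a YAML file path or an equivalent named list with sections
#'   `paths` (genotypes, genotype_format, sumstats, phenotypes, items,
#'   optional sds_items / reference / reference_format / exclude_bed),
#'   `settings` (passed to [analysis_settings()]), `seed` and `out_dir`.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  assert_that(all(c("paths", "out_dir") %in% names(config)),
              "config needs 'paths' and 'out_dir'")
  known <- c("paths", "settings", "seed", "out_dir")
  unknown <- setdiff(names(config), known)
  assert_that(length(unknown) == 0,
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
  p <- config$paths
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  started <- Sys.time()

  inputs <- stage("read_inputs", {
    list(
      study = read_genotypes(p$genotypes, p$genotype_format %||% "plink-bed"),
      sumstats = read_sumstats(p$sumstats),
      phenotypes = readr::read_csv(p$phenotypes, show_col_types = FALSE,
                                   progress = FALSE),
      items = read_items(p$items),
      sds_items = if (!is.null(p$sds_items)) read_items(p$sds_items),
      reference = if (!is.null(p$reference)) {
        ref <- read_genotypes(p$reference, p$reference_format %||% "plink-bed")
        labels <- readr::read_tsv(p$reference_labels,
                                  col_names = c("id", "label"),
                                  col_types = "cc", progress = FALSE)
        ref$samples$population <- labels$label[match(ref$samples$id, labels$id)]
        ref
      },
      exclude_regions = if (!is.null(p$exclude_bed)) read_bed_regions(p$exclude_bed))
  })

  settings <- do.call(analysis_settings,
                      c(config$settings %||% list(),
                        if (!is.null(config$seed)) list(seed = config$seed)))
  res <- analyze_cohort(inputs$study, inputs$sumstats, inputs$phenotypes,
                        inputs$items, reference = inputs$reference,
                        sds_items = inputs$sds_items,
                        exclude_regions = inputs$exclude_regions,
                        settings = settings)

  stage("write_outputs", {
    w <- function(x, name) readr::write_tsv(x, file.path(out_dir, name))
    w(res$pca$scores, "pc_scores.tsv")
    if (!is.null(res$ancestry_labels)) w(res$ancestry_labels, "ancestry_clusters.tsv")
    w(res$tree$nodes, "ippca_nodes.tsv")
    w(res$tree$assignment, "ippca_assignment.tsv")
    jsonlite::write_json(res$screen, file.path(out_dir, "cluster_screen.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    w(as_tibble(res$profile), "prs_scores.tsv")
    w(as_tibble(res$prs_eval), "prs_eval.tsv")
    for (g in names(res$fits)) {
      write_irt_fit(res$fits[[g]], file.path(out_dir, paste0("fit_", g, ".json")))
      if (!is.null(res$scores[[g]])) {
        w(as_tibble(res$scores[[g]]), paste0("scores_", g, ".tsv"))
      }
    }
    w(res$associations, "associations.tsv")
    lr <- dplyr::bind_rows(lapply(res$lr_tests, function(x) x$lr_test),
                           .id = "group")
    w(lr, "lr_tests.tsv")
    w(as_tibble(res$fdr), "fdr.tsv")
    if (!is.null(res$permutation)) {
      jsonlite::write_json(res$permutation[c("empirical_p", "best_p_obs",
                                             "best_threshold", "n_perm")],
                           file.path(out_dir, "permutation.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    yaml::write_yaml(list(paths = p, settings = settings,
                          seed = settings$seed, out_dir = out_dir),
                     file.path(out_dir, "config_resolved.yaml"))
    manifest <- list(package = "prsdims",
                     version = as.character(packageVersion("prsdims")),
                     started = format(started), finished = format(Sys.time()),
                     seed = settings$seed, inputs = p,
                     n_study = nrow(inputs$study$dosage),
                     n_analysis = length(res$analysis_ids),
                     stage_timings_sec = lapply(res$timings, round, 2))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  invisible(out_dir)
}
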