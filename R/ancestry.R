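# Ancestry analysis: standardized genotype PCA, reference-panel k-means
# assignment, iterative-pruning substructure search, and per-cluster PRS
# screening that selects the analysis sample.

#' Standardized genotype principal components
#'
#' Dosages are mean-centered and scaled by `sqrt(2 p (1 - p))` per SNP
#' (missing entries contribute zero after centering); monomorphic SNPs and
#' SNPs inside exclusion intervals (long-range high-LD regions) are removed
#' before decomposition.
#'
#' @param panel a [genotype_panel()].
#' @param exclude_regions `NULL` or a tibble with `chr`, `start`, `end`
#'   (0-based half-open, BED convention).
#' @param n_pcs number of components to keep (default 10).
#' @return An `ancestry_pca`: `$scores` tibble (`id`, `PC1..PCk`),
#'   `$eigenvalues`, `$snp_weights`, `$n_snps_used`.
#' @export
standardized_pca <- function(panel, exclude_regions = NULL, n_pcs = 10) {
  assert_that(nrow(panel$dosage) >= n_pcs + 1,
              "panel needs at least n_pcs + 1 individuals")
  keep <- rep(TRUE, ncol(panel$dosage))
  if (!is.null(exclude_regions)) {
    for (r in seq_len(nrow(exclude_regions))) {
      hit <- panel$map$chr == exclude_regions$chr[r] &
        panel$map$pos > exclude_regions$start[r] &
        panel$map$pos <= exclude_regions$end[r]
      keep <- keep & !hit
    }
  }
  p <- panel_freq(panel)
  keep <- keep & p > 0 & p < 1
  assert_that(sum(keep) >= n_pcs,
              sprintf("only %d informative SNPs for %d requested PCs",
                      sum(keep), n_pcs))
  Z <- scale_dosage(panel$dosage[, keep, drop = FALSE], p[keep])
  dec <- top_pcs(Z, n_pcs)
  scores <- as_tibble(as.data.frame(dec$scores))
  names(scores) <- paste0("PC", seq_len(n_pcs))
  structure(list(scores = dplyr::bind_cols(tibble(id = panel$samples$id), scores),
                 eigenvalues = dec$eigenvalues,
                 snp_weights = tibble(snp = panel$map$snp[keep]) |>
                   dplyr::bind_cols(as_tibble(as.data.frame(dec$weights),
                                              .name_repair = ~ paste0("PC", seq_len(n_pcs)))),
                 n_snps_used = sum(keep)),
            class = "ancestry_pca")
}

# center/scale a dosage matrix at given frequencies; missing -> 0
scale_dosage <- function(G, p) {
  Z <- sweep(G, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(pmax(2 * p * (1 - p), 1e-12)), "/")
  Z[is.na(Z)] <- 0
  Z
}

# top principal components via the smaller-side eigendecomposition
top_pcs <- function(Z, n_pcs) {
  n <- nrow(Z); m <- ncol(Z)
  if (m <= n) {
    C <- crossprod(Z) / (n - 1)
    e <- eigen(C, symmetric = TRUE)
    w <- e$vectors[, seq_len(n_pcs), drop = FALSE]
    list(scores = Z %*% w, eigenvalues = e$values[seq_len(n_pcs)], weights = w)
  } else {
    C <- tcrossprod(Z) / (n - 1)
    e <- eigen(C, symmetric = TRUE)
    u <- e$vectors[, seq_len(n_pcs), drop = FALSE]
    lam <- e$values[seq_len(n_pcs)]
    scores <- u %*% diag(sqrt(pmax(lam * (n - 1), 0)), n_pcs)
    w <- crossprod(Z, u)
    w <- sweep(w, 2, sqrt(colSums(w^2)), "/")
    list(scores = scores, eigenvalues = lam, weights = w)
  }
}

#' @export
print.ancestry_pca <- function(x, ...) {
  cat(sprintf("<ancestry_pca> %d individuals, %d SNPs used, %d PCs\n",
              nrow(x$scores), x$n_snps_used, length(x$eigenvalues)))
  invisible(x)
}

#' Assign reference-panel ancestry labels by k-means on joint PCs
#'
#' Seeded k-means (Lloyd, with `n_start` deterministic restarts whose initial
#' centers are drawn order-invariantly) on the joint PC scores of study and
#' reference individuals; each cluster inherits the majority label of its
#' reference members, clusters without reference members are `"unassigned"`.
#'
#' @param pcs an `ancestry_pca` over study + reference individuals (or its
#'   `$scores` tibble).
#' @param reference_labels tibble `id`, `label` for the reference individuals.
#' @param k number of clusters (default 5, continental convention).
#' @param seed integer seed.
#' @param n_start restarts.
#' @return Tibble `id`, `cluster`, `label`.
#' @export
assign_reference_clusters <- function(pcs, reference_labels, k = 5, seed = 1,
                                      n_start = 10) {
  scores <- if (inherits(pcs, "ancestry_pca")) pcs$scores else pcs
  if (k < length(unique(reference_labels$label))) {
    warn(sprintf("k = %d is smaller than the %d distinct reference labels",
                 k, length(unique(reference_labels$label))))
  }
  M <- as.matrix(scores[setdiff(names(scores), "id")])
  ord <- order(scores$id)                 # order-invariant sampling frame
  fit <- with_substream(seed, "kmeans", {
    best <- NULL
    for (r in seq_len(n_start)) {
      centers <- M[ord[sample.int(length(ord), k)], , drop = FALSE]
      km <- suppressWarnings(
        kmeans(M, centers = centers, algorithm = "Lloyd", iter.max = 100))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  cl <- fit$cluster
  lab_by_cluster <- vapply(seq_len(k), function(g) {
    ref <- reference_labels$label[match(scores$id[cl == g], reference_labels$id)]
    ref <- ref[!is.na(ref)]
    if (!length(ref)) "unassigned" else names(sort(table(ref), decreasing = TRUE))[1]
  }, character(1))
  tibble(id = scores$id, cluster = cl, label = lab_by_cluster[cl])
}

#' Iterative-pruning PCA substructure search
#'
#' Recursively tests each node for population substructure: the leading
#' eigenvalue of the node's standardized genotypes (estimated by fixed-length
#' power iteration on a seeded SNP subsample) is compared with a permutation
#' null in which every SNP column is independently permuted within the node.
#' If significant at `alpha` and both prospective children have at least
#' `min_cluster` members, the node is split by 2-means on its top two PCs and
#' the children are recursed; otherwise it is terminal. The permutation p is
#' empirical when enough permutations are available (`n_perm + 1 >=
#' 10 / alpha`), and otherwise a Gaussian tail probability from the permuted
#' null's moments.
#'
#' @param panel a [genotype_panel()].
#' @param min_cluster smallest admissible cluster (nodes below `2 *
#'   min_cluster` are terminal without testing).
#' @param alpha significance level of the substructure test.
#' @param n_perm permutations per node.
#' @param test_snps maximum SNPs used by the permutation test statistic.
#' @param prune_r2,prune_window_kb LD pruning applied before testing: the
#'   permutation null permutes SNP columns independently, which destroys LD,
#'   so correlated SNPs would mimic substructure; pruning (greedy, by
#'   position) restores calibration.
#' @param seed integer seed.
#' @return An `ippca_tree`: `$nodes` tibble (`node`, `parent`, `n`, `stat`,
#'   `p`, `decision`) and `$assignment` tibble (`id`, `leaf`).
#' @export
ippca_partition <- function(panel, min_cluster = 50, alpha = 1e-3,
                            n_perm = 50, test_snps = 500, prune_r2 = 0.2,
                            prune_window_kb = 250, seed = 1) {
  if (!is.null(prune_r2)) {
    panel <- panel_subset(panel, snps = ld_prune(panel, prune_r2, prune_window_kb))
  }
  ids <- panel$samples$id
  nodes <- list()
  assignment <- setNames(rep(NA_integer_, length(ids)), ids)
  node_counter <- 0L

  recurse <- function(members, parent) {
    node_counter <<- node_counter + 1L
    node_id <- node_counter
    n <- length(members)
    if (n < 2 * min_cluster) {
      nodes[[length(nodes) + 1L]] <<- tibble(
        node = node_id, parent = parent, n = n, stat = NA_real_, p = NA_real_,
        decision = "terminal_small")
      assignment[members] <<- node_id
      return(invisible(NULL))
    }
    G <- panel$dosage[members, , drop = FALSE]
    p_node <- colMeans(G, na.rm = TRUE) / 2
    poly <- p_node > 0 & p_node < 1
    Z <- scale_dosage(G[, poly, drop = FALSE], p_node[poly])
    test <- with_substream(seed, paste0("ippca_node", node_id), {
      sub <- if (ncol(Z) > test_snps) sort(sample.int(ncol(Z), test_snps)) else seq_len(ncol(Z))
      Zs <- Z[, sub, drop = FALSE]
      v0 <- rnorm(ncol(Zs))
      obs <- leading_eigenvalue(Zs, v0)
      perm <- vapply(seq_len(n_perm), function(b) {
        Zp <- apply(Zs, 2, sample)
        leading_eigenvalue(Zp, v0)
      }, numeric(1))
      p_val <- if (n_perm + 1 >= 10 / alpha) {
        (1 + sum(perm >= obs)) / (n_perm + 1)
      } else {
        pnorm((obs - mean(perm)) / sd(perm), lower.tail = FALSE)
      }
      list(stat = obs, p = p_val)
    })
    if (test$p >= alpha) {
      nodes[[length(nodes) + 1L]] <<- tibble(
        node = node_id, parent = parent, n = n, stat = test$stat, p = test$p,
        decision = "terminal_homogeneous")
      assignment[members] <<- node_id
      return(invisible(NULL))
    }
    pcs <- top_pcs(Z, 2)$scores
    centers <- pcs[c(which.min(pcs[, 1]), which.max(pcs[, 1])), , drop = FALSE]
    km <- suppressWarnings(kmeans(pcs, centers = centers, algorithm = "Lloyd",
                                  iter.max = 100))
    sizes <- table(km$cluster)
    if (length(sizes) < 2 || any(sizes < min_cluster)) {
      nodes[[length(nodes) + 1L]] <<- tibble(
        node = node_id, parent = parent, n = n, stat = test$stat, p = test$p,
        decision = "terminal_split_too_small")
      assignment[members] <<- node_id
      return(invisible(NULL))
    }
    nodes[[length(nodes) + 1L]] <<- tibble(
      node = node_id, parent = parent, n = n, stat = test$stat, p = test$p,
      decision = "split")
    recurse(members[km$cluster == 1], node_id)
    recurse(members[km$cluster == 2], node_id)
  }

  recurse(ids, NA_integer_)
  nodes <- dplyr::bind_rows(nodes)
  structure(list(nodes = nodes,
                 assignment = tibble(id = ids, leaf = unname(assignment[ids]))),
            class = "ippca_tree")
}

#' Greedy LD pruning by position
#'
#' Walks SNPs in map order and drops a SNP when its squared dosage
#' correlation with an already-kept SNP within `window_kb` on the same
#' chromosome exceeds `r2_max`.
#'
#' @param panel a [genotype_panel()].
#' @param r2_max squared-correlation ceiling (default 0.2).
#' @param window_kb window in kilobases.
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(panel, r2_max = 0.2, window_kb = 250) {
  map <- panel$map
  G <- panel$dosage
  window <- window_kb * 1000
  kept <- integer(0)
  for (i in seq_len(nrow(map))) {
    near <- kept[map$chr[kept] == map$chr[i] &
                   abs(map$pos[kept] - map$pos[i]) <= window]
    blocked <- FALSE
    for (j in near) {
      r <- suppressWarnings(cor(G[, i], G[, j], use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_max) { blocked <- TRUE; break }
    }
    if (!blocked) kept <- c(kept, i)
  }
  map$snp[kept]
}

# leading eigenvalue of Z'Z/(n-1) by fixed-length power iteration (identical
# procedure for observed and permuted matrices keeps the comparison calibrated)
leading_eigenvalue <- function(Z, v0, iters = 20) {
  v <- v0 / sqrt(sum(v0^2))
  for (i in seq_len(iters)) {
    u <- as.vector(Z %*% v)
    v <- as.vector(crossprod(Z, u))
    v <- v / sqrt(sum(v^2))
  }
  sum(as.vector(Z %*% v)^2) / (nrow(Z) - 1)
}

#' @export
print.ippca_tree <- function(x, ...) {
  n_leaves <- sum(!x$nodes$decision %in% "split")
  cat(sprintf("<ippca_tree> %d nodes, %d leaves\n", nrow(x$nodes), n_leaves))
  invisible(x)
}

#' Screen ancestry clusters by PRS case-control discrimination
#'
#' Per leaf, fits `case ~ PRS (+ covariates)` by logistic regression and keeps
#' the leaf when the PRS coefficient is positive with two-sided `p < p_cut`
#' and, if `cluster_labels` are given, the leaf's majority ancestry label
#' equals `target_ancestry`. Leaves with no cases or no controls are dropped
#' as non-informative. The union of kept leaves is the analysis sample.
#'
#' @param tree an `ippca_tree`.
#' @param prs_scores tibble `id`, `score`.
#' @param phenotype tibble with `id`, `case` and any covariate columns.
#' @param covariates names of covariate columns (default sex and age).
#' @param p_cut discrimination threshold (default 0.05).
#' @param cluster_labels optional tibble `id`, `label` (from
#'   [assign_reference_clusters()]).
#' @param target_ancestry required label (e.g. `"EUR"`); ignored when
#'   `cluster_labels` is `NULL`.
#' @return A `cluster_screen` tibble, one row per leaf, with the kept/dropped
#'   decision and reasons; kept individuals' ids in `attr(, "analysis_ids")`.
#' @export
screen_clusters <- function(tree, prs_scores, phenotype,
                            covariates = c("sex", "age"), p_cut = 0.05,
                            cluster_labels = NULL, target_ancestry = NULL) {
  leaves <- sort(unique(tree$assignment$leaf))
  dat <- dplyr::left_join(tree$assignment, prs_scores, by = "id") |>
    dplyr::left_join(phenotype, by = "id")
  assert_that(!anyNA(dat$score) && !anyNA(dat$case),
              "every individual needs a PRS and a case status")
  if (!is.null(cluster_labels)) {
    dat <- dplyr::left_join(dat, cluster_labels[c("id", "label")], by = "id")
  }
  rows <- lapply(leaves, function(lf) {
    d <- dat[dat$leaf == lf, ]
    n_cases <- sum(d$case == 1); n_controls <- sum(d$case == 0)
    label <- if (!is.null(cluster_labels)) {
      names(sort(table(d$label), decreasing = TRUE))[1]
    } else NA_character_
    base <- tibble(leaf = lf, n = nrow(d), n_cases = n_cases,
                   n_controls = n_controls, label = label)
    if (n_cases == 0 || n_controls == 0) {
      return(dplyr::mutate(base, estimate = NA_real_, p = NA_real_,
                           delta_r2 = NA_real_, keep = FALSE,
                           reason = "non-informative"))
    }
    covs <- covariates[covariates %in% names(d)]
    f0 <- stats::as.formula(paste("case ~", if (length(covs))
      paste(covs, collapse = " + ") else "1"))
    f1 <- stats::as.formula(paste("case ~ score +", if (length(covs))
      paste(covs, collapse = " + ") else "1"))
    m0 <- glm(f0, family = binomial(), data = d)
    m1 <- glm(f1, family = binomial(), data = d)
    est <- coef(summary(m1))["score", ]
    r2 <- nagelkerke_r2(as.numeric(logLik(m0)), as.numeric(logLik(m1)), nrow(d))
    discriminates <- est["Estimate"] > 0 && est["Pr(>|z|)"] < p_cut
    ancestry_ok <- is.null(cluster_labels) || is.null(target_ancestry) ||
      identical(label, target_ancestry)
    dplyr::mutate(base, estimate = est[["Estimate"]], p = est[["Pr(>|z|)"]],
                  delta_r2 = r2, keep = discriminates && ancestry_ok,
                  reason = dplyr::case_when(
                    !discriminates ~ "PRS not discriminative",
                    !ancestry_ok ~ "ancestry not confirmed",
                    TRUE ~ "kept"))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cluster_screen", class(out))
  attr(out, "analysis_ids") <- dat$id[dat$leaf %in% out$leaf[out$keep]]
  out
}
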