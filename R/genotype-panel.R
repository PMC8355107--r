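#' Genotype panel container
#'
#' A light container for hard-call dosages: an `n x m` integer matrix of
#' effect-allele counts (0/1/2, `NA` = missing), a variant map and a sample
#' table. Dosages count copies of the `a1` allele of each variant.
#'
#' @param dosage integer matrix, individuals in rows, SNPs in columns;
#'   `rownames` are sample ids and `colnames` SNP ids.
#' @param map tibble with columns `snp`, `chr`, `pos`, `a1`, `a2` (one row per
#'   column of `dosage`).
#' @param samples tibble with columns `id` and optionally `population`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, map, samples) {
  dosage <- as.matrix(dosage)
  map <- as_tibble(map)
  samples <- as_tibble(samples)
  assert_that(ncol(dosage) == nrow(map), "map must have one row per SNP column")
  assert_that(nrow(dosage) == nrow(samples), "samples must have one row per individual")
  assert_that(!anyDuplicated(map$snp), "SNP ids must be unique")
  assert_that(!anyDuplicated(samples$id), "sample ids must be unique")
  rownames(dosage) <- samples$id
  colnames(dosage) <- map$snp
  structure(list(dosage = dosage, map = map, samples = samples),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  if ("population" %in% names(x$samples)) {
    tab <- table(x$samples$population)
    cat("populations:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Subset a genotype panel
#'
#' @param panel a [genotype_panel()].
#' @param ids sample ids (or logical/integer index) to keep.
#' @param snps optional SNP ids to keep.
#' @return A `genotype_panel` restricted to the requested rows/columns.
#' @export
panel_subset <- function(panel, ids = NULL, snps = NULL) {
  keep_i <- if (is.null(ids)) seq_len(nrow(panel$dosage)) else {
    if (is.character(ids)) match(ids, panel$samples$id) else seq_len(nrow(panel$dosage))[ids]
  }
  assert_that(!anyNA(keep_i), "unknown sample ids in panel subset")
  keep_j <- if (is.null(snps)) seq_len(ncol(panel$dosage)) else match(snps, panel$map$snp)
  assert_that(!anyNA(keep_j), "unknown SNP ids in panel subset")
  genotype_panel(panel$dosage[keep_i, keep_j, drop = FALSE],
                 panel$map[keep_j, , drop = FALSE],
                 panel$samples[keep_i, , drop = FALSE])
}

#' Combine two panels over the same variants
#'
#' Used to merge a study panel with a reference panel before joint PCA.
#' @param x,y `genotype_panel`s with identical variant maps.
#' @return A row-bound `genotype_panel`.
#' @export
panel_rbind <- function(x, y) {
  assert_that(identical(x$map$snp, y$map$snp) &&
                identical(x$map$a1, y$map$a1),
              "panels must share an identical variant map")
  samples <- dplyr::bind_rows(x$samples, y$samples)
  genotype_panel(rbind(x$dosage, y$dosage), x$map, samples)
}

# Per-SNP effect-allele frequency, missing-aware.
panel_freq <- function(panel) {
  colMeans(panel$dosage, na.rm = TRUE) / 2
}
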