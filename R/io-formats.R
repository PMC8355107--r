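# Readers/writers for the standard interchange formats: PLINK bed/bim/fam,
# VCF 4.2, summary-statistics TSV, phenotype/item CSV, fitted-model JSON.
# Coordinate conventions: bim/VCF positions are 1-based; BED exclusion
# intervals are 0-based half-open (converted in exactly one place,
# read_bed_regions).

#' Write a genotype panel as PLINK bed/bim/fam
#'
#' SNP-major bed with the standard 2-bit encoding; the panel's counted allele
#' `a1` is written as the bim allele-1, so a round trip preserves dosages.
#'
#' @param panel a [genotype_panel()].
#' @param prefix path prefix (writes `<prefix>.bed`, `.bim`, `.fam`).
#' @return The prefix, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  G <- panel$dosage
  n <- nrow(G); m <- ncol(G)
  # two-bit codes indexed by dosage of allele-1: 0 -> 11, 1 -> 10, 2 -> 00, NA -> 01
  code <- c(3L, 2L, 0L)
  bpi <- ceiling(n / 4)
  bytes <- raw(bpi * m)
  pad <- 4L * bpi - n
  for (j in seq_len(m)) {
    g <- G[, j]
    cd <- ifelse(is.na(g), 1L, code[g + 1L])
    if (pad > 0) cd <- c(cd, rep(0L, pad))
    quads <- matrix(cd, nrow = 4)
    bytes[(j - 1L) * bpi + seq_len(bpi)] <-
      as.raw(quads[1, ] + quads[2, ] * 4L + quads[3, ] * 16L + quads[4, ] * 64L)
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  readr::write_tsv(
    tibble(chr = panel$map$chr, snp = panel$map$snp, cm = 0,
           pos = panel$map$pos, a1 = panel$map$a1, a2 = panel$map$a2),
    paste0(prefix, ".bim"), col_names = FALSE)
  readr::write_tsv(
    tibble(fid = panel$samples$id, iid = panel$samples$id, father = 0,
           mother = 0, sex = 0, pheno = -9),
    paste0(prefix, ".fam"), col_names = FALSE)
  invisible(prefix)
}

#' Read PLINK bed/bim/fam genotypes
#'
#' @param prefix path prefix of the fileset.
#' @return A [genotype_panel()]; dosages count the bim allele-1.
#' @export
read_plink <- function(prefix) {
  bim <- readr::read_tsv(paste0(prefix, ".bim"),
                         col_names = c("chr", "snp", "cm", "pos", "a1", "a2"),
                         col_types = "icdicc", progress = FALSE)
  fam <- readr::read_tsv(paste0(prefix, ".fam"),
                         col_names = c("fid", "iid", "father", "mother", "sex", "pheno"),
                         col_types = "cccccc", progress = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw_all <- readBin(paste0(prefix, ".bed"), what = "raw",
                     n = file.size(paste0(prefix, ".bed")))
  assert_that(length(raw_all) >= 3 &&
                identical(raw_all[1:2], as.raw(c(0x6c, 0x1b))),
              "not a PLINK bed file (bad magic bytes)")
  assert_that(raw_all[3] == as.raw(0x01), "only SNP-major bed files are supported")
  bpi <- ceiling(n / 4)
  body <- raw_all[-(1:3)]
  assert_that(length(body) == bpi * m,
              sprintf("bed size (%d bytes) disagrees with bim/fam (%d SNPs x %d samples)",
                      length(body), m, n))
  # decode via a 256 x 4 lookup of allele-1 dosages
  two_bits <- cbind(bitwAnd(0:255, 3L), bitwAnd(bitwShiftR(0:255, 2L), 3L),
                    bitwAnd(bitwShiftR(0:255, 4L), 3L), bitwAnd(bitwShiftR(0:255, 6L), 3L))
  decode <- matrix(c(2L, NA_integer_, 1L, 0L)[two_bits + 1L], nrow = 256)
  geno <- decode[as.integer(body) + 1L, ]
  # rows of `geno` follow bytes in file order (SNP-major); expand per SNP
  G <- matrix(NA_integer_, n, m)
  idx <- seq_len(n)
  for (j in seq_len(m)) {
    block <- geno[(j - 1L) * bpi + seq_len(bpi), , drop = FALSE]
    G[, j] <- as.integer(t(block))[idx]
  }
  genotype_panel(G, bim[c("chr", "snp", "pos", "a1", "a2")][c("snp", "chr", "pos", "a1", "a2")],
                 tibble(id = fam$iid))
}

#' Write a genotype panel as VCF 4.2
#'
#' REF is the panel's `a2`, ALT its counted allele `a1`, so GT alt-allele
#' counts equal the panel dosages; missing dosages become `./.`.
#'
#' @param panel a [genotype_panel()].
#' @param path output `.vcf` path (uncompressed).
#' @return The path, invisibly.
#' @export
write_vcf <- function(panel, path) {
  gt <- c("0/0", "0/1", "1/1")
  G <- panel$dosage
  lines <- c("##fileformat=VCFv4.2",
             "##source=prsdims",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$samples$id), collapse = "\t"))
  body <- vapply(seq_len(ncol(G)), function(j) {
    calls <- ifelse(is.na(G[, j]), "./.", gt[G[, j] + 1L])
    paste(c(panel$map$chr[j], panel$map$pos[j], panel$map$snp[j],
            panel$map$a2[j], panel$map$a1[j], ".", "PASS", ".", "GT", calls),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' @param path a VCF file (plain or bgzipped; parsed with vcfR).
#' @return A [genotype_panel()] whose counted allele `a1` is the ALT allele.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
             "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  flat <- as.vector(gt)
  bad <- !is.na(flat) & !(flat %in% c(names(known), "./.", ".|."))
  if (any(bad)) {
    first <- which(bad)[1]
    abort(sprintf("malformed VCF genotype '%s' (variant %s, sample %s)",
                  flat[first], rownames(gt)[(first - 1) %% nrow(gt) + 1],
                  colnames(gt)[(first - 1) %/% nrow(gt) + 1]))
  }
  dos <- matrix(unname(known[flat]), nrow = nrow(gt))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  map <- tibble(snp = fix$ID, chr = as.integer(fix$CHROM),
                pos = as.integer(fix$POS), a1 = fix$ALT, a2 = fix$REF)
  genotype_panel(t(dos), map, tibble(id = colnames(gt)))
}

#' Read genotypes in either supported format
#'
#' @param path PLINK prefix (for `"plink-bed"`) or VCF path (for `"vcf"`).
#' @param format `"plink-bed"` or `"vcf"`.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("plink-bed", "vcf")) {
  format <- match.arg(format)
  if (format == "plink-bed") read_plink(path) else read_vcf(path)
}

#' Write / read GWAS summary statistics
#'
#' Tab-delimited with header `SNP CHR BP A1 A2 OR SE P`. On reading, an `OR`
#' column is converted to `beta = log(OR)`; a `BETA` column is used directly.
#'
#' @param sumstats tibble with `snp`, `chr`, `pos`, `a1`, `a2`, `beta` or
#'   `or`, `se`, `p`.
#' @param path file path.
#' @return `write_sumstats`: the path, invisibly. `read_sumstats`: a tibble
#'   with internal column names (`snp`, `chr`, `pos`, `a1`, `a2`, `beta`,
#'   `se`, `p`).
#' @export
write_sumstats <- function(sumstats, path) {
  out <- tibble(SNP = sumstats$snp, CHR = sumstats$chr, BP = sumstats$pos,
                A1 = sumstats$a1, A2 = sumstats$a2,
                OR = sumstats$or %||% exp(sumstats$beta),
                SE = sumstats$se, P = sumstats$p)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  raw <- readr::read_table(path, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_guess()))
  names(raw) <- toupper(names(raw))
  assert_that(all(c("SNP", "A1", "A2", "P") %in% names(raw)) &&
                any(c("OR", "BETA") %in% names(raw)),
              "sumstats need SNP, A1, A2, P and OR or BETA columns")
  beta <- if ("BETA" %in% names(raw)) raw$BETA else log(raw$OR)
  tibble(snp = raw$SNP,
         chr = if ("CHR" %in% names(raw)) raw$CHR else NA_integer_,
         pos = if ("BP" %in% names(raw)) raw$BP else NA_integer_,
         a1 = raw$A1, a2 = raw$A2, beta = beta, or = exp(beta),
         se = if ("SE" %in% names(raw)) raw$SE else NA_real_,
         p = raw$P)
}

#' Read exclusion regions from a BED file
#'
#' Standard 0-based half-open BED intervals (chrom, chromStart, chromEnd);
#' a leading `chr` prefix is tolerated.
#'
#' @param path BED file path.
#' @return Tibble `chr`, `start`, `end` as used by [standardized_pca()].
#' @export
read_bed_regions <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_guess()),
                         progress = FALSE)
  assert_that(ncol(bed) >= 3, "BED file needs at least 3 columns")
  tibble(chr = as.integer(sub("^chr", "", as.character(bed[[1]]))),
         start = as.numeric(bed[[2]]), end = as.numeric(bed[[3]]))
}

#' Write / read an item response table
#'
#' Persons by items CSV, header row of item ids, empty cells for missing.
#' The item-to-factor map travels as a second CSV (`item`, `factor`).
#'
#' @param items item response tibble (`id` + item columns).
#' @param path CSV path; the map, when present, is written beside it as
#'   `<path>.map.csv`.
#' @return Paths invisibly; `read_items` returns the tibble with its
#'   `item_map` attribute restored when the map file exists.
#' @export
write_items <- function(items, path) {
  readr::write_csv(items, path, na = "")
  map <- attr(items, "item_map")
  if (!is.null(map)) readr::write_csv(map, paste0(path, ".map.csv"))
  invisible(path)
}

#' @rdname write_items
#' @export
read_items <- function(path) {
  out <- readr::read_csv(path, na = "", progress = FALSE,
                         col_types = readr::cols(id = readr::col_character(),
                                                 .default = readr::col_integer()))
  map_path <- paste0(path, ".map.csv")
  if (file.exists(map_path)) {
    attr(out, "item_map") <- readr::read_csv(map_path, col_types = "cc",
                                             progress = FALSE)
  }
  out
}

#' Serialize a fitted item response model to JSON
#'
#' @param fit an `irt_fit`.
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_irt_fit <- function(fit, path) {
  payload <- list(kind = fit$kind, link = fit$link, loglik = fit$loglik,
                  n_params = fit$n_params, n_persons = fit$n_persons,
                  params = fit$params,
                  factor_cor = fit$factor_cor, gamma = as.list(fit$gamma %||% list()),
                  convergence = fit$convergence[c("converged", "iterations",
                                                  "final_change")])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
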