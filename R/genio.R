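#' Read genotypes from VCF or a dosage table
#'
#' Loads biallelic SNPs into a [geno_matrix()]. For VCF input only the GT
#' field is used; dosage is the count of the alternate allele (0/1/2),
#' missing calls are preserved as `NA`. Records that are not biallelic SNPs
#' are skipped and their count reported via a message and the
#' `skipped_non_biallelic` attribute.
#'
#' The dosage-table dialect is tab-delimited with a header row of locus ids
#' of the form `chrom_pos` and the accession id in the first column, as
#' written by [write_dosage_table()].
#'
#' @param path path to the file.
#' @param format `"vcf"` or `"dosage_table"`.
#' @return a [geno_matrix()]; attribute `skipped_non_biallelic` counts the
#'   skipped records (VCF only).
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_data("genotype file not found: %s", path)
  if (format == "vcf") read_vcf_genotypes(path) else read_dosage_table(path)
}

read_vcf_genotypes <- function(path) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop_data("cannot parse VCF '%s': %s", path, conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!biallelic)
  if (n_skip > 0) {
    inform(sprintf("read_genotypes: skipped %d non-biallelic record(s)", n_skip))
  }
  if (!any(biallelic)) stop_data("no biallelic SNP records in '%s'", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  # count alternate alleles in the GT string; any missing allele -> NA
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean == "1/1"] <- 2
  dos[clean == "0"] <- 0   # haploid calls
  dos[clean == "1"] <- 2
  pos <- unname(as.integer(fix[, "POS"]))
  chrom <- unname(fix[, "CHROM"])
  id <- unname(fix[, "ID"])
  loci <- tibble(
    locus_id = ifelse(is.na(id) | id == ".", paste(chrom, pos, sep = "_"), id),
    chrom = chrom, pos_bp = pos, ref = unname(ref[biallelic]),
    alt = unname(alt[biallelic]))
  g <- geno_matrix(t(dos), loci)
  attr(g, "skipped_non_biallelic") <- n_skip
  g
}

read_dosage_table <- function(path) {
  tab <- tryCatch(
    read.delim(path, check.names = FALSE, row.names = 1),
    error = function(e) stop_data("cannot parse dosage table '%s': %s",
                                  path, conditionMessage(e)))
  if (ncol(tab) == 0) stop_data("no loci in dosage table '%s'", path)
  mat <- as.matrix(tab)
  storage.mode(mat) <- "double"
  ids <- colnames(mat)
  parts <- regmatches(ids, regexpr("_[0-9]+$", ids))
  if (length(parts) != length(ids)) {
    stop_data("dosage table header ids must look like '<chrom>_<pos>'")
  }
  pos <- as.integer(sub("^_", "", parts))
  chrom <- sub("_[0-9]+$", "", ids)
  geno_matrix(mat, tibble(locus_id = ids, chrom = chrom, pos_bp = pos))
}

#' Write a genotype matrix as a tab-delimited dosage table
#'
#' @param g a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_table <- function(g, path) {
  df <- data.frame(accession = accessions(g), g$dosage, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as VCF 4.2 (GT only)
#'
#' Fractional (imputed) dosages are rounded to the nearest genotype call.
#'
#' @inheritParams write_dosage_table
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", accessions(g)), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  dos <- round(t(g$dosage))
  gt <- matrix("./.", nrow(dos), ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gt_code[pmin(pmax(dos[ok], 0), 2) + 1]
  lines <- paste(g$loci$chrom, g$loci$pos_bp, g$loci$locus_id, g$loci$ref,
                 g$loci$alt, ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Per-locus allele statistics
#'
#' Computes, for every locus, the alternate-allele frequency and minor
#' allele frequency over non-missing calls, the heterozygosity (fraction of
#' dosage-1 calls among non-missing calls) and the missing-call rate over
#' all accessions. Loci with zero non-missing calls get `NA` frequency
#' statistics and are flagged.
#'
#' @param g a [geno_matrix()].
#' @return a tibble with columns `locus_id`, `chrom`, `pos_bp`, `n_called`,
#'   `alt_freq`, `maf`, `het_rate`, `missing_rate`, `all_missing`.
#' @examples
#' g <- geno_matrix(matrix(c(0, 0, 1, 2), 4, 1,
#'                         dimnames = list(NULL, "1_100")),
#'                  data.frame(locus_id = "1_100", chrom = "1", pos_bp = 100))
#' locus_stats(g)  # maf 0.375, het 0.25
#' @export
locus_stats <- function(g) {
  d <- g$dosage
  n <- nrow(d)
  called <- colSums(!is.na(d))
  alt_freq <- colSums(d, na.rm = TRUE) / (2 * pmax(called, 1L))
  alt_freq[called == 0] <- NA_real_
  het <- colSums(d == 1, na.rm = TRUE) / pmax(called, 1L)
  het[called == 0] <- NA_real_
  tibble(
    locus_id = g$loci$locus_id, chrom = g$loci$chrom, pos_bp = g$loci$pos_bp,
    n_called = unname(called),
    alt_freq = unname(alt_freq),
    maf = unname(pmin(alt_freq, 1 - alt_freq)),
    het_rate = unname(het),
    missing_rate = unname(1 - called / n),
    all_missing = unname(called == 0L))
}

#' Filter loci on missingness, MAF and heterozygosity
#'
#' Retains exactly the loci with `missing_rate <= max_missing`, `maf >=
#' min_maf` and `het_rate <= max_het` (all bounds inclusive), preserving
#' genomic order. The defaults are the standard quality thresholds for a
#' rice diversity panel: at most 20% missing calls, MAF at least 2%, at
#' most 5% heterozygous calls.
#'
#' @param g a [geno_matrix()].
#' @param max_missing,min_maf,max_het thresholds in `[0, 1]`.
#' @return the filtered [geno_matrix()], with attribute `filter_log`
#'   (retained/removed counts).
#' @export
filter_loci <- function(g, max_missing = 0.20, min_maf = 0.02, max_het = 0.05) {
  for (th in c(max_missing, min_maf, max_het)) {
    if (!is_scalar_prob(th)) stop_config("filter thresholds must lie in [0, 1]")
  }
  st <- locus_stats(g)
  keep <- !st$all_missing &
    st$missing_rate <= max_missing & st$maf >= min_maf & st$het_rate <= max_het
  if (!any(keep)) stop_data("all %d loci removed by the filters", nrow(st))
  inform(sprintf("filter_loci: retained %d / %d loci", sum(keep), length(keep)))
  out <- subset_geno(g, loci = which(keep))
  attr(out, "filter_log") <- list(retained = sum(keep),
                                  removed = sum(!keep),
                                  thresholds = c(max_missing = max_missing,
                                                 min_maf = min_maf,
                                                 max_het = max_het))
  out
}

#' Impute missing dosages per locus
#'
#' `mean` replaces missing calls with the locus mean dosage (fractional in
#' `[0, 2]`); `mode` with the most frequent observed dosage (ties broken
#' toward the smaller dosage). Observed calls are never altered.
#'
#' @param g a [geno_matrix()] with no all-missing locus.
#' @param method `"mean"` or `"mode"`.
#' @return an imputed [geno_matrix()] with no missing values.
#' @export
impute_missing <- function(g, method = c("mean", "mode")) {
  method <- match.arg(method)
  d <- g$dosage
  if (!anyNA(d)) return(g)
  called <- colSums(!is.na(d))
  if (any(called == 0)) {
    stop_data("%d locus/loci are entirely missing; filter first", sum(called == 0))
  }
  if (method == "mean") {
    fill <- colMeans(d, na.rm = TRUE)
  } else {
    fill <- apply(d, 2, function(col) {
      tab <- tabulate(col + 1L, nbins = 3L)
      as.numeric(which.max(tab) - 1L)
    })
  }
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- fill[idx[, 2]]
  g$dosage <- d
  g
}
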