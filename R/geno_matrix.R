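#' Accession-by-locus dosage matrix
#'
#' `geno_matrix()` bundles a numeric dosage matrix (accessions in rows, loci
#' in columns, values 0/1/2 counting the alternate allele, `NA` for missing
#' calls) with per-locus metadata: chromosome, 1-based physical position and
#' the reference/alternate alleles. Loci must be sorted by chromosome and
#' strictly increasing position within chromosome, as in a VCF.
#'
#' @param dosage numeric matrix, accessions x loci; rownames are accession
#'   ids, colnames are locus ids.
#' @param loci a data frame with one row per locus and columns `locus_id`,
#'   `chrom`, `pos_bp` and optionally `ref`, `alt`.
#' @return an object of class `geno_matrix`.
#' @examples
#' g <- geno_matrix(
#'   matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
#'          dimnames = list(c("a1", "a2", "a3"), c("c1_100", "c1_200"))),
#'   loci = data.frame(locus_id = c("c1_100", "c1_200"),
#'                     chrom = "c1", pos_bp = c(100L, 200L)))
#' g
#' @export
geno_matrix <- function(dosage, loci) {
  if (!is.matrix(dosage) || !is.numeric(dosage)) {
    stop_data("`dosage` must be a numeric matrix")
  }
  storage.mode(dosage) <- "double"
  loci <- as_tibble(loci)
  required <- c("locus_id", "chrom", "pos_bp")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols)) {
    stop_data("`loci` lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(loci) != ncol(dosage)) {
    stop_data("`loci` has %d rows but `dosage` has %d columns",
              nrow(loci), ncol(dosage))
  }
  if (!("ref" %in% names(loci))) loci$ref <- "A"
  if (!("alt" %in% names(loci))) loci$alt <- "T"
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("acc", seq_len(nrow(dosage)))
  }
  if (anyDuplicated(rownames(dosage))) {
    stop_data("accession ids must be unique")
  }
  colnames(dosage) <- loci$locus_id
  # enforce (chrom, pos) sort order, strictly increasing within chromosome
  ord <- order(match(loci$chrom, unique(loci$chrom)), loci$pos_bp)
  if (!all(ord == seq_along(ord))) {
    loci <- loci[ord, ]
    dosage <- dosage[, ord, drop = FALSE]
  }
  dup <- unlist(lapply(split(loci$pos_bp, loci$chrom), function(p) any(duplicated(p))))
  if (any(dup)) {
    stop_data("positions must be strictly increasing within chromosome")
  }
  structure(list(dosage = dosage, loci = loci), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d accessions x %d loci on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$loci$chrom))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Accession ids of a genotype matrix
#' @param g a [geno_matrix()].
#' @return character vector of accession ids.
#' @export
accessions <- function(g) rownames(g$dosage)

#' Subset a genotype matrix by accession and/or locus
#'
#' @param g a [geno_matrix()].
#' @param accessions,loci character ids (or logical/integer indices) to keep.
#' @return a [geno_matrix()].
#' @export
subset_geno <- function(g, accessions = NULL, loci = NULL) {
  d <- g$dosage
  if (!is.null(accessions)) d <- d[accessions, , drop = FALSE]
  li <- g$loci
  if (!is.null(loci)) {
    idx <- if (is.character(loci)) match(loci, li$locus_id) else which_idx(loci, nrow(li))
    if (anyNA(idx)) stop_data("unknown locus id(s) in `loci`")
    # keep genomic order regardless of the order requested
    idx <- sort(idx)
    d <- d[, idx, drop = FALSE]
    li <- li[idx, ]
  }
  geno_matrix(d, li)
}

which_idx <- function(i, n) {
  if (is.logical(i)) which(i) else as.integer(i)
}
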