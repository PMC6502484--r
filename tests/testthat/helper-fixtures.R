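# Shared fixtures for the suite. Everything is generated in code; nothing
# is read from disk except files the tests themselves write to tempdirs.

# small clean genotype panel (no missing/het unless asked)
quick_geno <- function(n = 60, n_chrom = 2, loci = 40, seed = 1, ...) {
  args <- list(n_accessions = n, n_chrom = n_chrom, loci_per_chrom = loci,
               missing_rate = 0, het_rate = 0, n_qtl = min(20, n_chrom * loci),
               seed = seed)
  args <- utils::modifyList(args, list(...))
  simulate_genotypes(do.call(sim_config, args))$geno
}

# build a geno_matrix from a bare dosage matrix on one chromosome
toy_geno <- function(dosage, chrom = "1", spacing = 100L) {
  L <- ncol(dosage)
  pos <- seq_len(L) * spacing
  colnames(dosage) <- paste(chrom, pos, sep = "_")
  geno_matrix(dosage, tibble::tibble(
    locus_id = colnames(dosage), chrom = chrom, pos_bp = pos))
}

# draw u ~ N(0, s2 * K) for a kernel with accession names
draw_gv <- function(K, s2) {
  Km <- if (inherits(K, "gs_kernel")) unclass(K) else K
  L <- chol(Km + diag(1e-8 * mean(diag(Km)), nrow(Km)))
  setNames(drop(t(L) %*% rnorm(nrow(Km))) * sqrt(s2), rownames(Km))
}

# mean r^2 at a given locus lag on one chromosome
mean_lag_r2 <- function(g, chrom, lag) {
  r2 <- pairwise_r2(g, chrom)$r2
  L <- nrow(r2)
  mean(r2[cbind(seq_len(L - lag), seq_len(L - lag) + lag)])
}
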