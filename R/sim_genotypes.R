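#' Simulate rice-like SNP genotypes
#'
#' Generates an accession x locus dosage matrix with subpopulation
#' structure, admixture, and tunable LD decay. Each subpopulation carries a
#' pool of founder haplotypes whose allele frequencies drift from shared
#' ancestral frequencies (Balding-Nichols model); every accession's
#' chromosome is a Markov mosaic over founder haplotypes, continuing the
#' current founder at each next locus with probability `ld_copy_prob` and
#' otherwise re-drawing a founder according to the accession's ancestry
#' proportions. Accessions are fully inbred (dosage = twice the haplotype
#' allele); heterozygous and missing calls are then injected completely at
#' random at the configured rates.
#'
#' With `ld_copy_prob = 0` founder indices at different loci are
#' independent, so inter-locus r² collapses to its sampling floor (~1/n);
#' larger values create geometrically decaying LD along each chromosome.
#'
#' @param config a [sim_config()].
#' @return a list with elements `geno` (a [geno_matrix()]) and `truth`
#'   (a partial `sim_truth`: ancestry proportions, subpopulation labels and
#'   the complete pre-missingness dosage matrix; QTL fields are filled in by
#'   [simulate_phenotypes()]).
#' @examples
#' sim <- simulate_genotypes(sim_config(n_accessions = 40, n_chrom = 2,
#'                                      loci_per_chrom = 50, seed = 7))
#' sim$geno
#' @export
simulate_genotypes <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_local_seed(config$seed, simulate_genotypes_impl(config))
}

simulate_genotypes_impl <- function(config) {
  n <- config$n_accessions
  S <- config$n_subpops
  L <- config$loci_per_chrom
  m <- config$n_founders
  fst <- config$fst
  cpy <- config$ld_copy_prob

  acc_ids <- sprintf("acc%03d", seq_len(n))

  # ancestry proportions: symmetric Dirichlet(admixture_conc); small
  # concentrations give nearly pure ancestries, large ones heavy admixture.
  # The subpopulation label is the majority ancestry component.
  ancestry <- matrix(0, n, S, dimnames = list(acc_ids, paste0("pop", seq_len(S))))
  for (i in seq_len(n)) {
    gam <- rgamma(S, shape = config$admixture_conc, rate = 1)
    if (sum(gam) <= 0) gam[(i - 1L) %% S + 1L] <- 1
    ancestry[i, ] <- gam / sum(gam)
  }
  primary <- max.col(ancestry)

  # ancestral allele frequencies: U-shaped, clamped away from fixation so the
  # realized MAF spectrum respects maf_floor for the vast majority of loci
  lo <- max(config$maf_floor + 0.04, 0.05)
  chrom_ids <- as.character(seq_len(config$n_chrom))
  founder_of_pop <- rep(seq_len(S), each = m)

  hap <- matrix(0L, n, 0L)
  loci <- vector("list", config$n_chrom)
  for (ci in seq_len(config$n_chrom)) {
    p0 <- pmin(pmax(rbeta(L, 0.5, 0.5), lo), 1 - lo)
    # Balding-Nichols drift per subpopulation
    a <- p0 * (1 - fst) / fst
    b <- (1 - p0) * (1 - fst) / fst
    psub <- matrix(rbeta(S * L, rep(a, each = S), rep(b, each = S)), nrow = S)
    # founder haplotypes: m per subpopulation. Alleles along a founder are
    # correlated through a latent AR(1) Gaussian (coefficient ld_copy_prob)
    # thresholded at the subpopulation allele frequency — a Gaussian copula
    # that preserves every per-locus marginal exactly (keeping the MAF
    # spectrum intact) while making nearby loci associated across the pool,
    # the source of population-level LD that mosaic copying then propagates
    founders <- matrix(0L, S * m, L)
    for (s in seq_len(S)) {
      z <- matrix(0, m, L)
      z[, 1] <- rnorm(m)
      if (L > 1 && cpy > 0) {
        innov_sd <- sqrt(1 - cpy^2)
        for (l in 2:L) z[, l] <- cpy * z[, l - 1] + innov_sd * rnorm(m)
      } else if (L > 1) {
        z[, 2:L] <- rnorm(m * (L - 1))
      }
      thr <- stats::qnorm(psub[s, ])
      founders[founder_of_pop == s, ] <-
        (z < matrix(thr, m, L, byrow = TRUE)) * 1L
    }
    hap_c <- matrix(0L, n, L)
    for (i in seq_len(n)) {
      keep <- c(FALSE, runif(L - 1) < cpy)
      seg <- cumsum(!keep)             # segment index per locus
      n_seg <- seg[L]
      pop_seg <- sample.int(S, n_seg, replace = TRUE, prob = ancestry[i, ])
      fnd_seg <- (pop_seg - 1L) * m + sample.int(m, n_seg, replace = TRUE)
      fnd <- fnd_seg[seg]
      hap_c[i, ] <- founders[cbind(fnd, seq_len(L))]
    }
    hap <- cbind(hap, hap_c)
    pos <- as.integer(round(seq_len(L) * config$locus_spacing_kb * 1000))
    loci[[ci]] <- tibble(
      locus_id = paste(chrom_ids[ci], pos, sep = "_"),
      chrom = chrom_ids[ci], pos_bp = pos, ref = "A", alt = "T")
  }
  loci <- dplyr::bind_rows(loci)

  dosage <- 2L * hap
  rownames(dosage) <- acc_ids

  # heterozygous calls (inbred lines retain ~1% residual heterozygosity)
  if (config$het_rate > 0) {
    het <- which(runif(length(dosage)) < config$het_rate)
    dosage[het] <- 1L
  }
  complete <- dosage
  if (config$missing_rate > 0) {
    miss <- which(runif(length(dosage)) < config$missing_rate)
    dosage[miss] <- NA_integer_
  }

  geno <- geno_matrix(dosage, loci)
  truth <- structure(list(
    ancestry = ancestry,
    subpop_of = setNames(primary, acc_ids),
    complete_dosage = complete,
    qtl_indices = NULL, qtl_effects = NULL, true_bv = NULL,
    check_values = NULL
  ), class = "sim_truth")
  list(geno = geno, truth = truth)
}
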