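#' Configuration for the rice-like trial simulator
#'
#' Bundles every knob of the synthetic genotype/phenotype generator and
#' validates the combination. Defaults describe the study conditions the
#' package is designed around: a diversity panel of 280 inbred accessions in
#' five admixed subpopulations, 12 chromosomes carrying 250 SNP loci each
#' (a ~3,000-marker panel at one locus per 13.7 kb), low LD decaying over a
#' few hundred kb, a rare-allele-skewed MAF spectrum, ~4% missing calls and
#' ~1% heterozygous calls, and three environments (one favourable, two
#' drought-stressed) whose genetic correlations follow the flowering-time
#' pattern: high between the favourable and stress trials.
#'
#' @param n_accessions number of test accessions.
#' @param n_subpops number of ancestral subpopulations.
#' @param admixture_conc positive symmetric-Dirichlet concentration for
#'   individual ancestry proportions; small values give nearly pure
#'   single-subpopulation ancestries, values near or above 1 heavy
#'   admixture. The subpopulation label of an accession is its majority
#'   ancestry component.
#' @param n_chrom,loci_per_chrom chromosome count and loci per chromosome.
#' @param locus_spacing_kb physical distance between adjacent loci (kb).
#' @param ld_copy_prob probability in `[0, 1)` that the founder haplotype
#'   being copied continues at the next locus; controls LD decay (r² between
#'   loci at lag L decays roughly as `ld_copy_prob^(2 L)`).
#' @param maf_floor target lower bound for realized minor allele frequency.
#' @param missing_rate,het_rate per-call rates of missing and heterozygous
#'   calls injected completely at random.
#' @param n_qtl number of causal loci.
#' @param env_labels character vector of environment names.
#' @param h2_target per-environment broad-sense heritability in `(0, 1]`
#'   (recycled if scalar).
#' @param genetic_corr environment x environment genetic correlation matrix
#'   (symmetric, unit diagonal, positive semi-definite).
#' @param genetic_var per-environment genetic variance among accessions, in
#'   squared trait units (recycled if scalar).
#' @param block_var per-environment variance of random block effects.
#' @param trait_mean per-environment trait mean.
#' @param trait_name trait label written into the field book.
#' @param design named list (one element per environment) of field-design
#'   descriptors, each `list(type = "augmented"|"alpha_lattice", n_blocks,
#'   n_checks)`; augmented designs place each accession once, alpha-lattice
#'   designs twice (2 replicates), and all checks appear in every block.
#' @param n_founders founder haplotypes per subpopulation (haplotype pool
#'   the Markov copying process draws from).
#' @param fst Balding-Nichols differentiation of subpopulation allele
#'   frequencies from the shared ancestral frequencies.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return a validated `sim_config` list.
#' @seealso [simulate_genotypes()], [simulate_phenotypes()]
#' @export
sim_config <- function(n_accessions = 280,
                       n_subpops = 5,
                       admixture_conc = 0.2,
                       n_chrom = 12,
                       loci_per_chrom = 250,
                       locus_spacing_kb = 13.7,
                       ld_copy_prob = 0.99,
                       maf_floor = 0.01,
                       missing_rate = 0.04,
                       het_rate = 0.01,
                       n_qtl = 100,
                       env_labels = c("E1", "E2", "E3"),
                       h2_target = c(0.75, 0.76, 0.84),
                       genetic_corr = NULL,
                       genetic_var = 100,
                       block_var = 10,
                       trait_mean = 90,
                       trait_name = "trait",
                       design = NULL,
                       n_founders = 24,
                       fst = 0.1,
                       seed = 1L) {
  check_field <- function(ok, field, what) {
    if (!ok) stop_config("invalid `%s`: %s", field, what)
  }
  check_field(is_count(n_accessions), "n_accessions", "must be a positive integer")
  check_field(is_count(n_subpops), "n_subpops", "must be a positive integer")
  check_field(is_scalar_prob(admixture_conc, 1e-8, Inf), "admixture_conc",
              "must be a positive real")
  check_field(is_count(n_chrom), "n_chrom", "must be a positive integer")
  check_field(is_count(loci_per_chrom), "loci_per_chrom", "must be a positive integer")
  check_field(is_scalar_prob(locus_spacing_kb, 1e-8, Inf), "locus_spacing_kb",
              "must be a positive real")
  check_field(is_scalar_prob(ld_copy_prob, 0, 1 - 1e-12), "ld_copy_prob",
              "must lie in [0, 1)")
  check_field(is_scalar_prob(maf_floor, 0, 0.5), "maf_floor", "must lie in [0, 0.5]")
  check_field(is_scalar_prob(missing_rate), "missing_rate", "must lie in [0, 1]")
  check_field(is_scalar_prob(het_rate), "het_rate", "must lie in [0, 1]")
  check_field(is_count(n_qtl), "n_qtl", "must be a positive integer")
  check_field(n_qtl <= n_chrom * loci_per_chrom, "n_qtl",
              "cannot exceed n_chrom * loci_per_chrom")
  check_field(is.character(env_labels) && length(env_labels) >= 1 &&
                !anyDuplicated(env_labels), "env_labels",
              "must be distinct environment names")
  n_env <- length(env_labels)

  h2_target <- rep_len(h2_target, n_env)
  check_field(all(h2_target > 0 & h2_target <= 1), "h2_target",
              "entries must lie in (0, 1]")
  genetic_var <- rep_len(genetic_var, n_env)
  check_field(all(genetic_var > 0), "genetic_var", "entries must be positive")
  block_var <- rep_len(block_var, n_env)
  check_field(all(block_var >= 0), "block_var", "entries must be non-negative")
  trait_mean <- rep_len(trait_mean, n_env)

  if (is.null(genetic_corr)) {
    genetic_corr <- default_genetic_corr(env_labels)
  }
  genetic_corr <- as.matrix(genetic_corr)
  check_field(nrow(genetic_corr) == n_env && ncol(genetic_corr) == n_env,
              "genetic_corr", "must be env x env")
  check_field(max(abs(genetic_corr - t(genetic_corr))) < 1e-10, "genetic_corr",
              "must be symmetric")
  check_field(max(abs(diag(genetic_corr) - 1)) < 1e-10, "genetic_corr",
              "must have unit diagonal")
  ev <- eigen(genetic_corr, symmetric = TRUE, only.values = TRUE)$values
  check_field(min(ev) > -1e-8, "genetic_corr", "must be positive semi-definite")
  dimnames(genetic_corr) <- list(env_labels, env_labels)

  if (is.null(design)) {
    design <- default_designs(env_labels)
  }
  check_field(is.list(design) && all(env_labels %in% names(design)), "design",
              "must provide a descriptor for every environment")
  for (e in env_labels) {
    d <- design[[e]]
    ok <- is.list(d) && d$type %in% c("augmented", "alpha_lattice") &&
      is_count(d$n_blocks) && is_count(d$n_checks)
    check_field(ok, "design",
                sprintf("descriptor for %s needs type/n_blocks/n_checks", e))
    design[[e]]$n_blocks <- as.integer(d$n_blocks)
    design[[e]]$n_checks <- as.integer(d$n_checks)
  }
  check_field(is_count(n_founders) && n_founders >= 2, "n_founders",
              "must be an integer >= 2")
  check_field(is_scalar_prob(fst, 1e-6, 0.99), "fst", "must lie in (0, 1)")
  check_field(length(seed) == 1 && is.finite(seed), "seed", "must be an integer")

  structure(list(
    n_accessions = as.integer(n_accessions), n_subpops = as.integer(n_subpops),
    admixture_conc = admixture_conc, n_chrom = as.integer(n_chrom),
    loci_per_chrom = as.integer(loci_per_chrom),
    locus_spacing_kb = locus_spacing_kb, ld_copy_prob = ld_copy_prob,
    maf_floor = maf_floor, missing_rate = missing_rate, het_rate = het_rate,
    n_qtl = as.integer(n_qtl), env_labels = env_labels,
    h2_target = setNames(h2_target, env_labels),
    genetic_corr = genetic_corr,
    genetic_var = setNames(genetic_var, env_labels),
    block_var = setNames(block_var, env_labels),
    trait_mean = setNames(trait_mean, env_labels),
    trait_name = trait_name, design = design[env_labels],
    n_founders = as.integer(n_founders), fst = fst, seed = as.integer(seed)
  ), class = "sim_config")
}

# Genetic correlations defaulting to the flowering-time pattern of a
# favourable trial vs two drought trials: high everywhere.
default_genetic_corr <- function(env_labels) {
  n <- length(env_labels)
  r <- diag(n)
  if (n >= 2) r[1, 2] <- r[2, 1] <- 0.71
  if (n >= 3) {
    r[2, 3] <- r[3, 2] <- 0.58
    r[1, 3] <- r[3, 1] <- 0.68
  }
  if (n > 3) {
    extra <- upper.tri(r) & r == 0
    r[extra] <- 0.5
    r[lower.tri(r)] <- t(r)[lower.tri(r)]
  }
  dimnames(r) <- list(env_labels, env_labels)
  r
}

# First environment: augmented design, 1 rep; later ones alpha-lattice, 2 reps.
default_designs <- function(env_labels) {
  out <- lapply(seq_along(env_labels), function(i) {
    if (i == 1) {
      list(type = "augmented", n_blocks = 14L, n_checks = 16L)
    } else {
      list(type = "alpha_lattice", n_blocks = 14L, n_checks = 16L)
    }
  })
  names(out) <- env_labels
  out
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d accessions, %d subpops, %d chrom x %d loci, %d envs (%s)\n",
    x$n_accessions, x$n_subpops, x$n_chrom, x$loci_per_chrom,
    length(x$env_labels), paste(x$env_labels, collapse = ", ")))
  invisible(x)
}
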