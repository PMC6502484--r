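#' Simulate multi-environment field-book phenotypes
#'
#' Draws additive QTL effects for each environment from a multivariate
#' normal whose covariance encodes the configured between-environment
#' genetic correlations, recalibrates them so the in-sample correlation and
#' variance of the true breeding values match the targets exactly, and lays
#' the resulting genetic values out in plot-level field designs: an
#' augmented design (each accession once, replicated checks in every block)
#' or an alpha-lattice with two replicates. Residual variance is set from
#' the per-environment heritability target via
#' `sigma2_e = sigma2_g (1 - H2) / H2`.
#'
#' @param g a [geno_matrix()] from [simulate_genotypes()].
#' @param truth the partial `sim_truth` from the same call.
#' @param config the [sim_config()] used to generate `g`.
#' @return a list with `fieldbook` (tibble with columns `env`, `entry_id`,
#'   `is_check`, `rep`, `block`, `trait`, `value`) and `truth` (completed
#'   `sim_truth` with `qtl_indices`, `qtl_effects` (env x QTL), `true_bv`
#'   (accession x env) and per-environment check values).
#' @export
simulate_phenotypes <- function(g, truth, config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  for (e in config$env_labels) {
    if (is.null(config$design[[e]])) {
      stop_config("environment '%s' has no field-design descriptor", e)
    }
  }
  # derived seed so phenotype randomness is independent of the genotype stream
  with_local_seed(config$seed + 77003L, simulate_phenotypes_impl(g, truth, config))
}

simulate_phenotypes_impl <- function(g, truth, config) {
  envs <- config$env_labels
  J <- length(envs)
  n <- nrow(g$dosage)
  acc_ids <- accessions(g)

  X <- truth$complete_dosage
  if (is.null(X)) X <- g$dosage
  # QTL drawn among loci polymorphic in the complete matrix
  poly <- which(apply(X, 2, function(col) var(col, na.rm = TRUE) > 0))
  if (length(poly) < config$n_qtl) {
    stop_config("n_qtl = %d exceeds the %d polymorphic loci available",
                config$n_qtl, length(poly))
  }
  qtl <- sort(sample(poly, config$n_qtl))
  Xq <- X[, qtl, drop = FALSE]

  R <- config$genetic_corr
  target_sd <- sqrt(config$genetic_var)
  sigma_t <- diag(target_sd, J) %*% R %*% diag(target_sd, J)

  # raw effects ~ MVN(0, R) per QTL, then recolored so that the sample
  # covariance of the breeding values equals sigma_t exactly
  cr <- chol(R + diag(1e-10, J))
  beta <- matrix(rnorm(config$n_qtl * J), config$n_qtl, J) %*% cr
  bv0 <- Xq %*% beta
  c0 <- cov(bv0)
  M <- solve(chol(c0 + diag(1e-12 * mean(diag(c0)), J)),
             chol(sigma_t + diag(1e-10, J)))
  beta <- beta %*% M
  bv <- Xq %*% beta
  dimnames(bv) <- list(acc_ids, envs)

  # checks: fixed genotypes with their own genetic values, shared covariance
  n_checks <- max(vapply(config$design, function(d) as.integer(d$n_checks), 0L))
  check_ids <- sprintf("check%02d", seq_len(n_checks))
  check_vals <- matrix(rnorm(n_checks * J), n_checks, J) %*%
    chol(sigma_t + diag(1e-10, J))
  dimnames(check_vals) <- list(check_ids, envs)

  fb <- vector("list", J)
  for (j in seq_len(J)) {
    e <- envs[j]
    d <- config$design[[e]]
    s2g <- config$genetic_var[j]
    h2 <- config$h2_target[j]
    s2e <- s2g * (1 - h2) / h2
    mu <- config$trait_mean[j]
    n_reps <- if (d$type == "alpha_lattice") 2L else 1L
    rows <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      blk_eff <- rnorm(d$n_blocks, 0, sqrt(config$block_var[j]))
      blk_of <- sample(rep_len(seq_len(d$n_blocks), n))
      ids <- c(acc_ids, rep(check_ids[seq_len(d$n_checks)], d$n_blocks))
      blks <- c(blk_of, rep(seq_len(d$n_blocks), each = d$n_checks))
      is_chk <- c(rep(FALSE, n), rep(TRUE, d$n_blocks * d$n_checks))
      gval <- c(bv[, j], rep(check_vals[seq_len(d$n_checks), j], d$n_blocks))
      val <- mu + gval + blk_eff[blks] +
        if (s2e > 0) rnorm(length(ids), 0, sqrt(s2e)) else 0
      rows[[r]] <- tibble(
        env = e, entry_id = ids, is_check = is_chk, rep = r,
        block = sprintf("r%d_b%02d", r, blks),
        trait = config$trait_name, value = unname(val))
    }
    fb[[j]] <- dplyr::bind_rows(rows)
  }

  truth$qtl_indices <- g$loci$locus_id[qtl]
  truth$qtl_effects <- t(beta)
  dimnames(truth$qtl_effects) <- list(envs, truth$qtl_indices)
  truth$true_bv <- bv
  truth$check_values <- check_vals
  list(fieldbook = dplyr::bind_rows(fb), truth = truth)
}

#' One-call simulation of genotypes and phenotypes
#'
#' Convenience wrapper running [simulate_genotypes()] then
#' [simulate_phenotypes()] on one [sim_config()].
#'
#' @param config a [sim_config()].
#' @return list with `geno`, `fieldbook`, `truth`.
#' @export
simulate_trial <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  sg <- simulate_genotypes(config)
  sp <- simulate_phenotypes(sg$geno, sg$truth, config)
  list(geno = sg$geno, fieldbook = sp$fieldbook, truth = sp$truth)
}
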