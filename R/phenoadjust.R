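#' Fit the plot-level adjustment model for one environment and trait
#'
#' Fits the check-augmented mixed model
#' `Y = mu + C_j + beta_k + N_i alpha_i + e` by EM-REML, where `C_j` are
#' fixed check effects, `beta_k` random block effects (one level per block
#' within replicate), `alpha_i` random accession effects switched on only
#' for non-check plots (the covariate `N_i` is 1 for accessions, 0 for
#' checks, so check plots inform the mean, check and block effects but
#' carry no accession effect), and `e` the residual. Block effects are
#' anchored by the checks replicated in every block.
#'
#' @param fb a field book: data frame with columns `env`, `entry_id`,
#'   `is_check`, `rep`, `block`, `trait`, `value` (see
#'   [simulate_phenotypes()]).
#' @param env,trait which environment and trait to fit.
#' @param max_iter,tol EM-REML iteration cap and convergence tolerance on
#'   the restricted log-likelihood.
#' @return a `gs_varcomp`: genetic, block and residual variance components,
#'   fixed effects (`mu`, per-check offsets), accession BLUPs, restricted
#'   log-likelihood trace and convergence flag.
#' @seealso [adjusted_means()], [broad_sense_h2()]
#' @export
fit_adjustment_model <- function(fb, env, trait, max_iter = 1000L, tol = 1e-8) {
  fb <- as_tibble(fb)
  need <- c("env", "entry_id", "is_check", "block", "trait", "value")
  missing_cols <- setdiff(need, names(fb))
  if (length(missing_cols)) {
    stop_data("field book lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!("rep" %in% names(fb))) fb$rep <- 1L
  dat <- fb[fb$env == env & fb$trait == trait & !is.na(fb$value), ]
  if (nrow(dat) == 0) stop_data("no records for env '%s', trait '%s'", env, trait)

  blk <- factor(paste(dat$rep, dat$block, sep = ":"))
  if (nlevels(blk) < 2) stop_data("need at least 2 blocks")
  has_check <- tapply(dat$is_check, blk, any)
  if (!all(has_check)) {
    stop_data("every block needs at least one check record (%d lack one)",
              sum(!has_check))
  }

  y <- dat$value
  checks <- sort(unique(dat$entry_id[dat$is_check]))
  X <- matrix(1, nrow(dat), 1, dimnames = list(NULL, "mu"))
  if (length(checks)) {
    Xc <- outer(dat$entry_id, checks, "==") * 1
    colnames(Xc) <- checks
    X <- cbind(X, Xc)
  }
  Zb <- outer(as.character(blk), levels(blk), "==") * 1
  colnames(Zb) <- levels(blk)
  acc <- sort(unique(dat$entry_id[!dat$is_check]))
  Za <- outer(dat$entry_id, acc, "==") * (!dat$is_check)
  colnames(Za) <- acc

  res <- em_reml_terms(y, X, list(block = Zb, accession = Za),
                       tol = tol, max_iter = max_iter)
  structure(list(
    sigma2_g = unname(res$sigma2["accession"]),
    sigma2_block = unname(res$sigma2["block"]),
    sigma2_e = res$sigma2_e,
    fixed_effects = setNames(res$beta, colnames(X)),
    blup_accession = res$u$accession,
    blup_block = res$u$block,
    loglik_trace = res$loglik_trace,
    converged = res$converged,
    env = env, trait = trait, n_plots = nrow(dat),
    data = dat
  ), class = "gs_varcomp")
}

#' @export
print.gs_varcomp <- function(x, ...) {
  cat(sprintf(
    "<gs_varcomp> %s / %s: sigma2_g = %.4g, sigma2_block = %.4g, sigma2_e = %.4g, H2 = %.3f%s\n",
    x$trait, x$env, x$sigma2_g, x$sigma2_block, x$sigma2_e,
    broad_sense_h2(x$sigma2_g, x$sigma2_e),
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @method tidy gs_varcomp
#' @export
tidy.gs_varcomp <- function(x, ...) {
  tibble(term = c("sigma2_g", "sigma2_block", "sigma2_e", names(x$fixed_effects)),
         type = c(rep("variance", 3), rep("fixed", length(x$fixed_effects))),
         estimate = c(x$sigma2_g, x$sigma2_block, x$sigma2_e,
                      unname(x$fixed_effects)))
}

#' @method glance gs_varcomp
#' @export
glance.gs_varcomp <- function(x, ...) {
  tibble(env = x$env, trait = x$trait, n_plots = x$n_plots,
         sigma2_g = x$sigma2_g, sigma2_block = x$sigma2_block,
         sigma2_e = x$sigma2_e,
         H2 = broad_sense_h2(x$sigma2_g, x$sigma2_e),
         loglik_restricted = utils::tail(x$loglik_trace, 1),
         converged = x$converged)
}

#' Adjusted accession means
#'
#' Extracts one adjusted phenotype per phenotyped accession from a fitted
#' adjustment model. The default (`method = "blup"`) is `mu + BLUP(alpha_i)`
#' — the shrunken accession value consistent with the mixed model.
#' `method = "block_corrected"` instead averages the raw plot values after
#' subtracting the estimated block effects (no shrinkage).
#'
#' @param fit a `gs_varcomp` from [fit_adjustment_model()].
#' @param method `"blup"` or `"block_corrected"`.
#' @return tibble with columns `accession`, `env`, `trait`, `y_adj`.
#' @export
adjusted_means <- function(fit, method = c("blup", "block_corrected")) {
  method <- match.arg(method)
  if (!fit$converged) {
    warn("adjustment model had not converged; adjusted means use the last iterate")
  }
  mu <- fit$fixed_effects[["mu"]]
  if (method == "blup") {
    out <- tibble(accession = names(fit$blup_accession),
                  y_adj = mu + unname(fit$blup_accession))
  } else {
    dat <- fit$data[!fit$data$is_check, ]
    blk <- paste(dat$rep, dat$block, sep = ":")
    corrected <- dat$value - unname(fit$blup_block[blk])
    out <- tibble(accession = dat$entry_id, v = corrected) |>
      dplyr::group_by(.data$accession) |>
      dplyr::summarise(y_adj = mean(.data$v), .groups = "drop")
  }
  out$env <- fit$env
  out$trait <- fit$trait
  out[, c("accession", "env", "trait", "y_adj")]
}

#' Broad-sense heritability
#'
#' `H2 = sigma2_g / (sigma2_g + sigma2_e)`: the genotypic share of the
#' phenotypic variance, the residual being the only other component counted
#' in the phenotypic variance of the single-environment analysis.
#'
#' @param sigma2_g,sigma2_e non-negative genotypic and residual variance
#'   components (vectorized; recycled to common length).
#' @return heritability value(s) in `[0, 1]`.
#' @examples
#' broad_sense_h2(70.27, 23)    # 0.75 to two decimals
#' broad_sense_h2(469.94, 21.71) # 0.96
#' @export
broad_sense_h2 <- function(sigma2_g, sigma2_e) {
  if (any(sigma2_g < 0) || any(sigma2_e < 0)) {
    stop_config("variance components must be non-negative")
  }
  tot <- sigma2_g + sigma2_e
  if (any(tot == 0)) stop_config("sigma2_g and sigma2_e cannot both be zero")
  sigma2_g / tot
}
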