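#' Population-structure covariates from principal components
#'
#' Returns the first `k_subpops - 1` principal components of the centered
#' dosage matrix, mean-centered — the standard structure correction for a
#' mixed-linear-model GWAS (for a panel with K subpopulations, K - 1
#' ancestry dimensions are identifiable).
#'
#' @param g an imputed [geno_matrix()].
#' @param k_subpops assumed number of subpopulations (>= 2).
#' @return numeric matrix, accessions x (k_subpops - 1), mean-centered
#'   columns; attribute `method = "pca"`.
#' @export
structure_covariates <- function(g, k_subpops) {
  if (!is_count(k_subpops) || k_subpops < 2) {
    stop_config("`k_subpops` must be an integer >= 2")
  }
  M <- if (inherits(g, "geno_matrix")) g$dosage else g
  if (k_subpops > nrow(M)) {
    stop_config("`k_subpops` (%d) exceeds the number of accessions (%d)",
                k_subpops, nrow(M))
  }
  if (anyNA(M)) stop_data("dosages contain missing values; impute first")
  pc <- prcomp(M, center = TRUE, scale. = FALSE, rank. = k_subpops - 1)
  q <- pc$x[, seq_len(k_subpops - 1), drop = FALSE]
  q <- sweep(q, 2, colMeans(q))
  rownames(q) <- rownames(M)
  attr(q, "method") <- "pca"
  q
}

#' Mixed-linear-model GWAS with kinship and structure covariates
#'
#' Single-marker association scan under `y = X b + m a + u + e`,
#' `u ~ N(0, sigma2_u K)`, with `X = [1, Q]`. Variance components are
#' estimated once under the marker-free null by EM-REML on the
#' eigendecomposition of `K` and then held fixed for every marker (the
#' P3D/EMMAX approximation used by standard MLM implementations); each
#' marker is tested by generalized least squares, with a two-sided p-value
#' from the t statistic of the marker coefficient on `n - p` degrees of
#' freedom. Markers collinear with the covariates are flagged and assigned
#' p = 1.
#'
#' @param y_adj adjusted phenotypes: data frame with columns `accession`
#'   and `y_adj`, or a named numeric vector.
#' @param g an imputed [geno_matrix()] carrying the markers to test.
#' @param K kinship matrix (default [grm()] of `g`).
#' @param Q structure covariates (accessions x c matrix, e.g. from
#'   [structure_covariates()]); `NULL` for none.
#' @return a `gs_gwas` tibble: `locus_id`, `chrom`, `pos_bp`, `beta`, `se`,
#'   `statistic`, `p_value`, `aliased`; attributes record n and the null
#'   variance components.
#' @export
mlm_gwas <- function(y_adj, g, K = NULL, Q = NULL) {
  yv <- as_named_response(y_adj)
  ids <- names(yv)
  missing_acc <- setdiff(ids, accessions(g))
  if (length(missing_acc)) {
    stop_data("genotypes lack accession(s): %s",
              paste(head(missing_acc, 5), collapse = ", "))
  }
  M <- g$dosage[ids, , drop = FALSE]
  if (anyNA(M)) stop_data("dosages contain missing values; impute first")
  if (is.null(K)) K <- grm(g)
  Km <- as_kernel_matrix(K)[ids, ids]
  X0 <- matrix(1, length(ids), 1)
  if (!is.null(Q)) {
    Qm <- as.matrix(Q)
    if (!is.null(rownames(Qm))) Qm <- Qm[ids, , drop = FALSE]
    X0 <- cbind(X0, Qm)
  }

  null_fit <- em_reml_kernel(yv, X0, Km, tol = 1e-6)
  d <- null_fit$eigen$values
  U <- null_fit$eigen$vectors
  sw <- sqrt(1 / (null_fit$sigma2_u * d + null_fit$sigma2_e))

  # whitened data: OLS in this basis is GLS in the original one
  yw <- sw * drop(crossprod(U, yv))
  Xw <- sw * crossprod(U, X0)
  Mw <- sw * crossprod(U, M)
  qrX <- qr(Xw)
  yr <- qr.resid(qrX, yw)
  Mr <- qr.resid(qrX, Mw)

  mm <- colSums(Mr^2)
  my <- drop(crossprod(Mr, yr))
  aliased <- mm < 1e-10 * length(ids)
  beta <- ifelse(aliased, NA_real_, my / mm)
  # variance-component shape is fixed (P3D); the residual scale is
  # re-estimated per marker, so with K = I the test reduces exactly to OLS
  df <- length(ids) - ncol(X0) - 1
  rss <- pmax(sum(yr^2) - my^2 / mm, 0)
  se <- ifelse(aliased, NA_real_, sqrt(rss / df / mm))
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  p[aliased] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  out <- tibble(
    locus_id = g$loci$locus_id, chrom = g$loci$chrom, pos_bp = g$loci$pos_bp,
    beta = unname(beta), se = unname(se), statistic = unname(tstat),
    p_value = unname(p), aliased = unname(aliased))
  attr(out, "n") <- length(ids)
  attr(out, "sigma2_u") <- null_fit$sigma2_u
  attr(out, "sigma2_e") <- null_fit$sigma2_e
  attr(out, "n_covariates") <- ncol(X0) - 1
  class(out) <- c("gs_gwas", class(out))
  out
}

#' Select the top-k markers by association p-value
#'
#' Returns the `k` loci with the smallest p-values; ties at the boundary
#' are broken by genomic order (chromosome, then position). The returned
#' ids are sorted genomically.
#'
#' @param res a `gs_gwas` result.
#' @param k number of markers to keep (`1 <= k <=` number tested).
#' @return character vector of locus ids in genomic order.
#' @export
select_top_k <- function(res, k) {
  if (!is_count(k)) stop_config("`k` must be a positive integer")
  if (k > nrow(res)) {
    stop_config("`k` (%d) exceeds the %d tested loci", k, nrow(res))
  }
  ord <- order(res$p_value, match(res$chrom, unique(res$chrom)), res$pos_bp)
  sel <- sort(ord[seq_len(k)])
  res$locus_id[sel]
}
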