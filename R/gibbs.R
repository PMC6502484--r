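# Internal Gibbs machinery for the multi-environment kernel models.
#
# Every kernel random term u = Z a, a ~ N(0, sigma2 K), is reparameterised
# through the truncated eigendecomposition K = G L G' as u_obs = W b with
# W = Z G L^{1/2} and b ~ N(0, sigma2 I_r). A one-time SVD W = U S V' makes
# the full conditional of b diagonal in the V basis:
#   c = V'b,  prec(c_j) = S_j^2 / sigma2_e + 1 / sigma2.
# Components of b orthogonal to the row space of W are touched only by the
# prior; their sum of squares (needed for the variance update) is drawn as
# sigma2 * chisq(r - m) without ever forming them, and they contribute
# nothing to the posterior mean of u. Each iteration therefore costs a few
# matrix-vector products.

kernel_eigen <- function(K, tol = 1e-8) {
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  keep <- eg$values > tol * max(eg$values)
  list(vectors = eg$vectors[, keep, drop = FALSE],
       values = eg$values[keep],
       rank = sum(keep))
}

# obs_acc: for each observation, the row index of its accession in K's eigen
make_gibbs_term <- function(eig, obs_acc) {
  W <- eig$vectors[obs_acc, , drop = FALSE] %*% diag(sqrt(eig$values),
                                                     eig$rank)
  sv <- svd(W)
  keep <- sv$d > 1e-10 * max(sv$d, 1)
  list(U = sv$u[, keep, drop = FALSE],
       S = sv$d[keep],
       V = sv$v[, keep, drop = FALSE],
       m = sum(keep), r = eig$rank, n_obs = length(obs_acc))
}

# One Gibbs update of a kernel term. ystar = residual with this term's
# current fit added back. Returns the new fitted values on the observations,
# the coefficient draw c (V basis) and the quadratic form b'b for the
# variance update.
update_gibbs_term <- function(term, ystar, s2_term, s2e) {
  a <- drop(crossprod(term$U, ystar))
  prec <- term$S^2 / s2e + 1 / s2_term
  cmean <- (term$S * a / s2e) / prec
  cdraw <- cmean + rnorm(term$m) / sqrt(prec)
  ss_perp <- if (term$r > term$m) s2_term * rchisq(1, term$r - term$m) else 0
  list(fitted = drop(term$U %*% (term$S * cdraw)),
       c = cdraw,
       ss = sum(cdraw^2) + ss_perp)
}

# scaled-inverse-chi-squared draw
rinvchisq <- function(df, scale_sum) scale_sum / rchisq(1, df)

# posterior-mean genetic values per accession from the accumulated mean of c
term_posterior_u <- function(term, eig, c_mean) {
  b_mean <- drop(term$V %*% c_mean)
  drop(eig$vectors %*% (sqrt(eig$values) * b_mean))
}
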