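# EM-REML solvers for Gaussian mixed models.
#
# Two specialisations of the same monotone EM update
#   sigma2_k <- sigma2_k + (sigma2_k^2 / q_k) * (y'P A_k P y - tr(P A_k))
# (A_k the covariance structure of term k, P the REML projection matrix):
#  * a single dense kernel term (GBLUP / RKHS), solved in the eigenbasis of
#    the kernel so each iteration is O(n p^2);
#  * any number of identity-covariance terms (blocks, accessions), solved
#    with the Woodbury identity so the per-iteration cost is governed by the
#    number of random levels, not the number of plots.
# The restricted log-likelihood is tracked each iteration; EM guarantees it
# is non-decreasing, which the test suite asserts.

VAR_FLOOR <- 1e-10

# ---- single kernel term ----------------------------------------------------

em_reml_kernel <- function(y, X, K, tol = 1e-8, max_iter = 1000L,
                           init = NULL, fix_sigma2_e = NULL) {
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  if (qr(X)$rank < ncol(X)) stop_data("singular fixed-effect design")
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  if (min(eg$values) < -1e-6 * max(abs(eg$values))) {
    stop_data("kernel is not positive semi-definite")
  }
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  p <- ncol(X)

  vy <- var(y)
  if (vy <= 0) vy <- 1
  s2u <- if (is.null(init)) vy / (2 * max(mean(d), 1e-12)) else init[1]
  s2e <- if (is.null(init)) vy / 2 else init[2]
  if (!is.null(fix_sigma2_e)) s2e <- max(fix_sigma2_e, VAR_FLOOR)

  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- 1 / (s2u * d + s2e)
    WX <- Xt * w
    C <- crossprod(Xt, WX)
    B <- solve(C)
    beta <- drop(B %*% crossprod(WX, yt))
    r <- yt - drop(Xt %*% beta)
    py <- w * r

    ll <- -0.5 * (sum(log(s2u * d + s2e)) +
                    determinant(C, logarithm = TRUE)$modulus +
                    sum(r * py))
    trace <- c(trace, as.numeric(ll))
    if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }

    tr_pd <- sum(w * d) - sum(B * crossprod(WX, d * WX))
    tr_p <- sum(w) - sum(B * crossprod(WX, WX))
    ypdpy <- sum(d * py^2)
    yppy <- sum(py^2)
    s2u <- max(VAR_FLOOR, s2u + (s2u^2 / n) * (ypdpy - tr_pd))
    if (is.null(fix_sigma2_e)) {
      s2e <- max(VAR_FLOOR, s2e + (s2e^2 / n) * (yppy - tr_p))
    }
  }
  if (!converged) {
    warn(sprintf("EM-REML did not converge in %d iterations (last delta %.3g)",
                 max_iter, abs(diff(utils::tail(trace, 2)))))
  }
  # back to original coordinates
  w <- 1 / (s2u * d + s2e)
  WX <- Xt * w
  B <- solve(crossprod(Xt, WX))
  beta <- drop(B %*% crossprod(WX, yt))
  r <- yt - drop(Xt %*% beta)
  py_orig <- drop(U %*% (w * r))
  u_hat <- s2u * drop(U %*% (d * (w * r)))

  list(sigma2_u = s2u, sigma2_e = s2e, beta = beta, u_hat = u_hat,
       py = py_orig, loglik_trace = trace, converged = converged,
       eigen = list(values = d, vectors = U))
}

# ---- multiple identity-covariance terms ------------------------------------

# terms: named list of design matrices Z_k (n x q_k), each u_k ~ N(0, s2_k I)
em_reml_terms <- function(y, X, terms, tol = 1e-8, max_iter = 1000L) {
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < ncol(X)) stop_data("singular fixed-effect design")
  Z <- do.call(cbind, terms)
  qk <- vapply(terms, ncol, 0L)
  q <- sum(qk)
  blk <- rep(seq_along(terms), qk)

  ZtZ <- crossprod(Z)
  p <- ncol(X)
  vy <- var(y)
  if (vy <= 0) vy <- 1
  s2 <- rep(vy / (2 * length(terms)), length(terms))
  s2e <- vy / 2

  trace <- numeric(0)
  converged <- FALSE
  res <- NULL
  for (it in seq_len(max_iter)) {
    gvec <- s2[blk]
    A <- ZtZ + diag(s2e / gvec, q)
    cA <- chol(A)
    Ainv_mult <- function(B) backsolve(cA, forwardsolve(t(cA), B))
    VinvX <- (X - Z %*% Ainv_mult(crossprod(Z, X))) / s2e
    Vinvy <- drop(y - Z %*% Ainv_mult(crossprod(Z, y))) / s2e
    C <- crossprod(X, VinvX)
    Cinv <- solve(C)
    beta <- drop(Cinv %*% crossprod(VinvX, y))
    py <- Vinvy - drop(VinvX %*% beta)
    resid <- y - drop(X %*% beta)
    ypy <- sum(resid * py)

    logdetV <- (n - q) * log(s2e) + sum(log(gvec)) +
      2 * sum(log(diag(cA)))
    ll <- -0.5 * (logdetV + determinant(C, logarithm = TRUE)$modulus + ypy)
    trace <- c(trace, as.numeric(ll))
    if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }

    # diagonals of Z'PZ per block, and tr(P)
    VinvZ <- (Z - Z %*% Ainv_mult(ZtZ)) / s2e
    dZVZ <- colSums(Z * VinvZ)
    ZtVinvX <- crossprod(Z, VinvX)
    dZVX <- rowSums((ZtVinvX %*% Cinv) * ZtVinvX)
    dZPZ <- dZVZ - dZVX
    trVinv <- (n - sum(diag(Ainv_mult(ZtZ)))) / s2e
    tr_p <- trVinv - sum(Cinv * crossprod(VinvX))

    Ztpy <- drop(crossprod(Z, py))
    for (k in seq_along(terms)) {
      sel <- blk == k
      ypapy <- sum(Ztpy[sel]^2)
      s2[k] <- max(VAR_FLOOR, s2[k] + (s2[k]^2 / qk[k]) * (ypapy - sum(dZPZ[sel])))
    }
    s2e <- max(VAR_FLOOR, s2e + (s2e^2 / n) * (sum(py^2) - tr_p))
  }
  if (!converged) {
    warn(sprintf("EM-REML did not converge in %d iterations (last delta %.3g)",
                 max_iter, abs(diff(utils::tail(trace, 2)))))
  }
  gvec <- s2[blk]
  A <- ZtZ + diag(s2e / gvec, q)
  cA <- chol(A)
  Ainv_mult <- function(B) backsolve(cA, forwardsolve(t(cA), B))
  VinvX <- (X - Z %*% Ainv_mult(crossprod(Z, X))) / s2e
  C <- crossprod(X, VinvX)
  Cinv <- solve(C)
  beta <- drop(Cinv %*% crossprod(VinvX, y))
  Vinvy <- drop(y - Z %*% Ainv_mult(crossprod(Z, y))) / s2e
  py <- Vinvy - drop(VinvX %*% beta)
  Ztpy <- drop(crossprod(Z, py))
  u <- lapply(seq_along(terms), function(k) {
    bk <- s2[k] * Ztpy[blk == k]
    names(bk) <- colnames(terms[[k]])
    bk
  })
  names(u) <- names(terms)
  names(s2) <- names(terms)

  list(sigma2 = s2, sigma2_e = s2e, beta = beta, u = u,
       loglik_trace = trace, converged = converged, py = py)
}
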