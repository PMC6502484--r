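# shared medium panel for the model tests
panel <- local({
  g <- quick_geno(n = 120, n_chrom = 3, loci = 60, seed = 51)
  list(geno = g, K = grm(g), Kg = gaussian_kernel(g))
})

test_that("gaussian kernel matches direct evaluation and its limits", {
  M <- matrix(c(0, 0, 2,
                0, 0, 2,
                2, 2, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  Kg <- gaussian_kernel(M, h = 0.5)
  d2_ac <- sum((M[1, ] - M[3, ])^2) / 3
  expect_equal(Kg[1, 2], 1)          # identical rows
  expect_equal(Kg[1, 3], exp(-0.5 * d2_ac))
  expect_equal(diag(Kg), rep(1, 3), ignore_attr = TRUE)
  # h -> 0: all entries approach 1
  K0 <- gaussian_kernel(panel$geno, h = 1e-12)
  expect_lt(max(abs(unclass(K0) - 1)), 1e-9)
  # default bandwidth is the reciprocal median off-diagonal squared distance
  Kd <- gaussian_kernel(panel$geno)
  M2 <- panel$geno$dosage
  sq <- rowSums(M2^2)
  d2 <- (outer(sq, sq, "+") - 2 * tcrossprod(M2)) / ncol(M2)
  expect_equal(attr(Kd, "h"), 1 / median(d2[upper.tri(d2)]))
  expect_error(gaussian_kernel(panel$geno, h = -1), class = "gsrice_config_error")
})

test_that("GBLUP equals an independent ridge-regression solution", {
  g <- quick_geno(n = 30, n_chrom = 2, loci = 50, seed = 21)
  M <- scale(g$dosage, center = TRUE, scale = FALSE)
  K <- tcrossprod(M)
  dimnames(K) <- list(accessions(g), accessions(g))
  set.seed(1)
  y <- setNames(drop(M %*% rnorm(100, 0, 0.2)) + rnorm(30), accessions(g))
  fit <- fit_gblup(y, K)
  lambda <- fit$sigma2_e / fit$sigma2_u
  beta <- solve(crossprod(M) + diag(lambda, ncol(M)), crossprod(M, y - fit$mu))
  expect_lt(max(abs(drop(M %*% beta) - fit$u_hat)), 1e-6)
})

test_that("with residual variance pinned near zero the fit interpolates", {
  g <- quick_geno(n = 25, n_chrom = 1, loci = 80, seed = 22)
  K <- unclass(grm(g)) + diag(0.05, 25)  # full rank
  dimnames(K) <- list(accessions(g), accessions(g))
  set.seed(2)
  y <- setNames(drop(chol(K) %*% rnorm(25)) * 3 + 10, accessions(g))
  fit <- suppressWarnings(fit_gblup(y, K, fix_sigma2_e = 1e-10))
  expect_lt(max(abs(fit$mu + fit$u_hat[names(y)] - y)), 1e-6)
})

test_that("heritability is recovered on average at h2 = 0.5", {
  h2_hat <- vapply(1:5, function(s) {
    g <- quick_geno(n = 200, n_chrom = 3, loci = 60, seed = 800 + s)
    K <- grm(g)
    set.seed(900 + s)
    u <- draw_gv(K, 50)
    y <- u + rnorm(200, 0, sqrt(50))
    fit <- fit_gblup(y, K)
    fit$sigma2_u / (fit$sigma2_u + fit$sigma2_e)
  }, 0)
  expect_lt(abs(mean(h2_hat) - 0.5), 0.1)
})

test_that("RKHS with a linear kernel is exactly GBLUP", {
  set.seed(3)
  y <- setNames(draw_gv(panel$K, 40) + rnorm(120, 0, 5), accessions(panel$geno))
  f1 <- fit_gblup(y, panel$K)
  f2 <- fit_rkhs(y, panel$K)
  expect_equal(f2$u_hat, f1$u_hat, tolerance = 1e-12)
  expect_equal(f2$sigma2_u, f1$sigma2_u)
  expect_equal(f2$model, "rkhs")
})

test_that("RKHS captures epistatic signal at least as well as GBLUP", {
  pa <- sapply(1:6, function(s) {
    g <- quick_geno(n = 200, n_chrom = 2, loci = 50, seed = 1000 + s)
    set.seed(1100 + s)
    qtl <- sample(ncol(g$dosage), 10)
    # purely epistatic genetic values: products of centered QTL dosages,
    # orthogonal to any additive signal a linear kernel could capture
    X <- scale(g$dosage[, qtl], scale = FALSE)
    pairs <- utils::combn(10, 2)
    epi <- sapply(seq_len(ncol(pairs)), function(k) {
      X[, pairs[1, k]] * X[, pairs[2, k]]
    })
    gv <- drop(scale(epi %*% rnorm(ncol(pairs))))
    y <- setNames(gv + rnorm(200, 0, 0.5), accessions(g))
    train <- accessions(g)[1:150]
    test <- accessions(g)[151:200]
    fg <- suppressWarnings(fit_gblup(y[train], grm(g)))
    fr <- suppressWarnings(fit_rkhs(y[train], gaussian_kernel(g)))
    c(gblup = cor(predict(fg, test)$gebv, y[test]),
      rkhs = cor(predict(fr, test)$gebv, y[test]))
  })
  expect_true(all(pa["rkhs", ] - pa["gblup", ] > 0))
  expect_gt(mean(pa["rkhs", ] - pa["gblup", ]), 0.05)
  # additive architecture: the two methods are near-equivalent
  pa_add <- sapply(1:4, function(s) {
    g <- quick_geno(n = 150, n_chrom = 2, loci = 50, seed = 1200 + s)
    set.seed(1300 + s)
    y <- setNames(draw_gv(grm(g), 30) + rnorm(150, 0, sqrt(30)), accessions(g))
    train <- accessions(g)[1:110]
    test <- accessions(g)[111:150]
    fg <- fit_gblup(y[train], grm(g))
    fr <- fit_rkhs(y[train], gaussian_kernel(g))
    c(cor(predict(fg, test)$gebv, y[test]), cor(predict(fr, test)$gebv, y[test]))
  })
  expect_lt(abs(mean(pa_add[1, ]) - mean(pa_add[2, ])), 0.05)
})

test_that("single-environment reduction of the MxE sampler matches GBLUP", {
  set.seed(4)
  y <- draw_gv(panel$K, 40) + rnorm(120, 0, sqrt(20))
  dat <- tibble::tibble(accession = accessions(panel$geno), env = "E1",
                        y_adj = unname(y))
  fit <- fit_mxe_gblup(dat, panel$K, iters = 2500, burnin = 500, seed = 13)
  gb <- fit_gblup(setNames(dat$y_adj, dat$accession), panel$K)
  expect_gt(cor(fit$u0 + fit$u_env[, 1], gb$u_hat), 0.99)
})

test_that("the MxE sampler is deterministic under a fixed seed", {
  set.seed(5)
  dat <- tibble::tibble(
    accession = rep(accessions(panel$geno), 2),
    env = rep(c("E1", "E2"), each = 120),
    y_adj = rnorm(240))
  f1 <- fit_mxe_gblup(dat, panel$K, iters = 600, burnin = 100, seed = 42)
  f2 <- fit_mxe_gblup(dat, panel$K, iters = 600, burnin = 100, seed = 42)
  expect_identical(f1$u_env, f2$u_env)
  expect_identical(f1$sigma2_0, f2$sigma2_0)
})

test_that("MxE recovers the implied between-environment genetic correlation", {
  est <- vapply(1:4, function(s) {
    g <- quick_geno(n = 150, n_chrom = 3, loci = 80, seed = 1400 + s)
    K <- grm(g)
    set.seed(1500 + s)
    u0 <- draw_gv(K, 40)
    u1 <- draw_gv(K, 40)
    u2 <- draw_gv(K, 40)
    acc <- accessions(g)
    dat <- tibble::tibble(
      accession = rep(acc, 2), env = rep(c("E1", "E2"), each = 150),
      y_adj = c(u0 + u1, u0 + u2) + rnorm(300, 0, sqrt(20)))
    fit <- fit_mxe_gblup(dat, K, iters = 3000, burnin = 1000, seed = 1600 + s)
    fit$env_cor[1, 2]
  }, 0)
  expect_lt(abs(mean(est) - 0.5), 0.15)
})

test_that("GxE RKHS with a linear kernel matches the MxE model, and reduces to RKHS", {
  set.seed(6)
  u0 <- draw_gv(panel$K, 40)
  dat <- tibble::tibble(
    accession = rep(accessions(panel$geno), 2),
    env = rep(c("E1", "E2"), each = 120),
    y_adj = rep(unname(u0), 2) + rnorm(240, 0, 4))
  f_mxe <- fit_mxe_gblup(dat, panel$K, iters = 2000, burnin = 500, seed = 7)
  f_gxe <- fit_gxe_rkhs(dat, panel$K, iters = 2000, burnin = 500, seed = 7)
  expect_identical(f_gxe$model, "gxe_rkhs")
  expect_identical(f_mxe$u_env, f_gxe$u_env)  # same kernel, same seed
  d1 <- dat[dat$env == "E1", ]
  f_one <- fit_gxe_rkhs(d1, panel$Kg, iters = 2500, burnin = 500, seed = 8)
  rk <- fit_rkhs(setNames(d1$y_adj, d1$accession), panel$Kg)
  expect_gt(cor(f_one$u0 + f_one$u_env[, 1], rk$u_hat), 0.98)
})

test_that("the Kronecker model recovers genetic correlation and its null", {
  est <- vapply(1:3, function(s) {
    g <- quick_geno(n = 150, n_chrom = 3, loci = 80, seed = 1700 + s)
    K <- grm(g)
    Km <- unclass(K)
    set.seed(1800 + s)
    Sg <- matrix(c(50, 35, 35, 50), 2)
    U <- t(chol(Km + diag(1e-6, 150))) %*% (matrix(rnorm(300), 150, 2) %*% chol(Sg))
    Y <- U + matrix(rnorm(300, 0, sqrt(15)), 150, 2)
    dimnames(Y) <- list(rownames(Km), c("E1", "E2"))
    fit_kron_multitrait(Y, K, iters = 4000, burnin = 1000, seed = 1900 + s)$env_cor[1, 2]
  }, 0)
  expect_lt(abs(mean(est) - 0.7), 0.15)

  # independent environments: posterior correlation near zero
  est0 <- vapply(1:3, function(s) {
    g <- quick_geno(n = 150, n_chrom = 3, loci = 80, seed = 2000 + s)
    K <- grm(g)
    set.seed(2100 + s)
    Y <- cbind(draw_gv(K, 50), draw_gv(K, 50)) + matrix(rnorm(300, 0, sqrt(15)), 150, 2)
    colnames(Y) <- c("E1", "E2")
    fit_kron_multitrait(Y, K, iters = 4000, burnin = 1000, seed = 2200 + s)$env_cor[1, 2]
  }, 0)
  expect_lt(abs(mean(est0)), 0.15)

  # degenerate single-environment call is rejected
  Y1 <- matrix(rnorm(120), 120, 1, dimnames = list(accessions(panel$geno), "E1"))
  expect_error(fit_kron_multitrait(Y1, panel$K), "2 environments",
               class = "gsrice_data_error")
})

test_that("predictions are consistent, duplicate-safe and equivariant", {
  set.seed(9)
  y <- setNames(draw_gv(panel$K, 40) + rnorm(120, 0, 4), accessions(panel$geno))
  fit <- fit_gblup(y, panel$K)
  pr <- predict(fit, names(y))
  expect_equal(pr$gebv, unname(fit$mu + fit$u_hat[names(y)]))
  expect_equal(nrow(predict(fit, character(0))), 0L)
  expect_error(predict(fit, "nobody"), "nobody", class = "gsrice_data_error")

  # duplicate genotypes, one phenotyped and one not, get near-equal GEBVs
  g <- quick_geno(n = 40, n_chrom = 1, loci = 60, seed = 23)
  d <- g$dosage
  d[40, ] <- d[1, ]
  K <- grm(d)
  set.seed(10)
  y2 <- setNames(draw_gv(K, 30) + rnorm(40, 0, 3), rownames(d))[1:39]
  f2 <- fit_gblup(y2, K)
  pr2 <- predict(f2, rownames(d)[c(1, 40)])
  expect_lt(abs(diff(pr2$gebv)), 1e-6)

  # relabeling accessions relabels predictions
  perm <- sample(names(y))
  fitp <- fit_gblup(y[perm], panel$K[perm, perm])
  expect_equal(predict(fitp, perm)$gebv, predict(fit, perm)$gebv,
               tolerance = 1e-6)
})
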