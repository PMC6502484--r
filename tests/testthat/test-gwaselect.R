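test_that("raw relationship matrix equals the hand cross-product", {
  M <- matrix(c(0, 1, 2, 2, 0, 1), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("l1", "l2")))
  G <- grm(M, "raw")
  expect_equal(unclass(G)[1:3, 1:3], tcrossprod(M), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("identical genotypes give identical relationship rows and top diagonals", {
  g <- quick_geno(n = 20, n_chrom = 1, loci = 50, seed = 3)
  d <- g$dosage
  d[2, ] <- d[1, ]  # duplicate accession
  G <- grm(d, "vanraden")
  expect_equal(G[1, ], G[2, ], tolerance = 1e-12)
  expect_equal(G[1, 2], G[1, 1], tolerance = 1e-12)
  expect_gte(min(eigen(unclass(G), symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
})

test_that("vanraden scaling centers the diagonal near 1 for outbred data", {
  set.seed(4)
  p <- runif(400, 0.1, 0.9)
  M <- sapply(p, function(pp) rbinom(120, 2, pp))
  rownames(M) <- sprintf("a%03d", 1:120)
  G <- grm(M, "vanraden")
  expect_gt(mean(diag(G)), 0.8)
  expect_lt(mean(diag(G)), 1.2)
})

test_that("principal-component covariates separate simulated subpopulations", {
  g <- quick_geno(n = 120, n_chrom = 2, loci = 150, n_subpops = 2,
                  admixture_conc = 0.1, fst = 0.3, seed = 9)
  q <- structure_covariates(g, k_subpops = 2)
  expect_equal(ncol(q), 1L)
  expect_equal(colMeans(q), 0, tolerance = 1e-10, ignore_attr = TRUE)
  # recover the generating labels from the simulator
  truth <- simulate_genotypes(sim_config(
    n_accessions = 120, n_chrom = 2, loci_per_chrom = 150, n_subpops = 2,
    admixture_conc = 0.1, fst = 0.3, missing_rate = 0, het_rate = 0,
    n_qtl = 20, seed = 9))$truth
  r_pb <- cor(q[, 1], as.numeric(truth$subpop_of == 1))
  expect_gt(abs(r_pb), 0.9)
  expect_error(structure_covariates(g, 1), class = "gsrice_config_error")
  expect_error(structure_covariates(g, 500), class = "gsrice_config_error")
})

test_that("permuting accessions permutes the covariate rows identically", {
  g <- quick_geno(n = 40, n_chrom = 1, loci = 60, seed = 12)
  q1 <- structure_covariates(g, 3)
  perm <- sample(accessions(g))
  q2 <- structure_covariates(subset_geno(g, accessions = perm), 3)
  expect_equal(abs(q2), abs(q1[perm, , drop = FALSE]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("marker tests match an exact GLS oracle with the null variance components", {
  g <- quick_geno(n = 12, n_chrom = 1, loci = 5, n_qtl = 2, seed = 31)
  set.seed(2)
  yv <- setNames(rnorm(12, sd = 2) + g$dosage[, 2], accessions(g))
  K <- grm(g)
  res <- suppressWarnings(mlm_gwas(yv, g, K = K))
  V <- attr(res, "sigma2_u") * unclass(K)[1:12, 1:12] +
    attr(res, "sigma2_e") * diag(12)
  Vi <- solve(V)
  for (j in 1:5) {
    X <- cbind(1, g$dosage[, j])
    C <- solve(t(X) %*% Vi %*% X)
    b <- drop(C %*% t(X) %*% Vi %*% yv)
    r <- yv - X %*% b
    s2 <- drop(t(r) %*% Vi %*% r) / (12 - 2)
    p <- 2 * pt(-abs(b[2] / sqrt(s2 * C[2, 2])), 12 - 2)
    expect_equal(res$p_value[j], p, tolerance = 1e-8)
  }
})

test_that("with identity kinship and no covariates the MLM reduces to OLS", {
  g <- quick_geno(n = 50, n_chrom = 1, loci = 20, seed = 41)
  set.seed(3)
  yv <- setNames(rnorm(50), accessions(g))
  K <- diag(50)
  dimnames(K) <- list(accessions(g), accessions(g))
  res <- suppressWarnings(mlm_gwas(yv, g, K = K))
  p_ols <- apply(g$dosage, 2, function(m) {
    if (var(m) == 0) return(1)
    summary(lm(yv ~ m))$coefficients[2, 4]
  })
  expect_lt(max(abs(res$p_value - p_ols)), 1e-10)
})

test_that("the null MLM is calibrated at the nominal type-I level", {
  hits <- 0L
  total <- 0L
  for (s in 1:10) {
    g <- quick_geno(n = 100, n_chrom = 1, loci = 300, n_subpops = 1,
                    ld_copy_prob = 0, seed = 400 + s)
    g <- suppressMessages(filter_loci(g, min_maf = 0.05, max_het = 1))
    set.seed(500 + s)
    yv <- setNames(rnorm(100), accessions(g))
    K <- diag(100)
    dimnames(K) <- list(accessions(g), accessions(g))
    res <- suppressWarnings(mlm_gwas(yv, g, K = K))
    hits <- hits + sum(res$p_value < 0.05)
    total <- total + nrow(res)
  }
  rate <- hits / total
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / total)
  expect_lt(abs(rate - 0.05), ci_half + 0.01)
})

test_that("a strong single QTL is ranked first by the scan", {
  found <- vapply(1:8, function(s) {
    g <- quick_geno(n = 150, n_chrom = 2, loci = 100, ld_copy_prob = 0.5,
                    seed = 600 + s)
    st <- locus_stats(g)
    qtl <- which.min(abs(st$maf - 0.4))
    x <- g$dosage[, qtl]
    set.seed(700 + s)
    # QTL explains ~30% of phenotypic variance
    b <- sqrt(0.3 / (0.7 * var(x)))
    yv <- setNames(b * x + rnorm(150), accessions(g))
    res <- mlm_gwas(yv, g, K = grm(g), Q = structure_covariates(g, 3))
    which.min(res$p_value) == qtl
  }, NA)
  expect_gte(sum(found), 7)
})

test_that("top-k selection is deterministic, nested, and genomically tie-broken", {
  res <- tibble::tibble(
    locus_id = c("1_100", "1_200", "2_100", "2_200", "3_100"),
    chrom = c("1", "1", "2", "2", "3"),
    pos_bp = c(100, 200, 100, 200, 100),
    p_value = c(0.5, 0.01, 0.2, 0.2, 0.9))
  expect_equal(select_top_k(res, 1), "1_200")
  # ties at rank 2/3: the earlier genomic position wins
  expect_equal(select_top_k(res, 2), c("1_200", "2_100"))
  expect_equal(select_top_k(res, 5), res$locus_id)
  for (k1 in 1:4) {
    expect_true(all(select_top_k(res, k1) %in% select_top_k(res, k1 + 1)))
  }
  expect_error(select_top_k(res, 0), class = "gsrice_config_error")
  expect_error(select_top_k(res, 6), class = "gsrice_config_error")
})

test_that("GWAS results are invariant to accession relabeling", {
  g <- quick_geno(n = 60, n_chrom = 1, loci = 40, seed = 77)
  set.seed(8)
  yv <- setNames(g$dosage[, 5] + rnorm(60, sd = 2), accessions(g))
  K <- grm(g)
  Q <- structure_covariates(g, 3)
  res1 <- mlm_gwas(yv, g, K = K, Q = Q)
  perm <- sample(accessions(g))
  gp <- subset_geno(g, accessions = perm)
  res2 <- mlm_gwas(yv[perm], gp, K = grm(gp), Q = structure_covariates(gp, 3))
  expect_equal(res2$p_value, res1$p_value, tolerance = 1e-6)
})
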