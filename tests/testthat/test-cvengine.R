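test_that("partition sizes reproduce the 80/20 rule at the reference panel sizes", {
  p280 <- make_partitions(sprintf("a%03d", 1:280), 0.8, n_reps = 3, seed = 1)
  expect_length(p280$partitions[[1]]$train, 224L)
  expect_length(p280$partitions[[1]]$validation, 56L)
  p204 <- make_partitions(sprintf("a%03d", 1:204), 0.8, n_reps = 3, seed = 1)
  expect_length(p204$partitions[[1]]$train, 163L)
  expect_length(p204$partitions[[1]]$validation, 41L)
  # partition property: train and validation tile the id set, every replicate
  for (part in p280$partitions) {
    expect_identical(sort(c(part$train, part$validation)),
                     sort(p280$ids))
    expect_length(intersect(part$train, part$validation), 0L)
  }
  # reproducible and reusable across traits/models
  expect_identical(make_partitions(p280$ids, 0.8, 3, seed = 1)$partitions,
                   p280$partitions)
  expect_error(make_partitions(letters[1:10], n_reps = 0),
               class = "gsrice_config_error")
  expect_error(make_partitions(letters[1:3], n_reps = 2),
               class = "gsrice_config_error")
})

test_that("the Fisher transform is exact and invertible", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_lt(max(abs(inverse_fisher_z(fisher_z(r)) - r)), 1e-12)
  expect_error(fisher_z(1), class = "gsrice_config_error")
  expect_error(fisher_z(-1.2), class = "gsrice_config_error")
})

test_that("predictive ability is the sample Pearson correlation", {
  expect_equal(predictive_ability(1:5, 1:5), 1)
  expect_equal(predictive_ability(1:5, -(1:5)), -1)
  pred <- c(1, 2, 3, 4)
  obs <- c(1, 2, 2, 4)
  num <- sum((pred - mean(pred)) * (obs - mean(obs)))
  den <- sqrt(sum((pred - mean(pred))^2) * sum((obs - mean(obs))^2))
  expect_equal(predictive_ability(pred, obs), num / den)
  expect_warning(r0 <- predictive_ability(rep(1, 4), 1:4), "zero variance")
  expect_true(is.na(r0))
  expect_error(predictive_ability(1:3, 1:4), class = "gsrice_data_error")
})

test_that("ANOVA on Z: constant response, t-squared identity, orthogonal main effects", {
  # constant response: factor sums of squares are zero
  pa_const <- tibble::tibble(r = rep(0.4, 12), f = rep(c("a", "b"), 6))
  az <- suppressWarnings(anova_z(pa_const, "f"))
  expect_equal(az$sumsq[az$term == "f"], 0, tolerance = 1e-20)

  # one balanced two-level factor: F equals the squared two-sample t
  set.seed(1)
  pa <- tibble::tibble(r = runif(40, 0.2, 0.7),
                       f = rep(c("a", "b"), each = 20))
  az2 <- anova_z(pa, "f")
  z <- fisher_z(pa$r)
  tt <- t.test(z ~ pa$f, var.equal = TRUE)$statistic
  expect_equal(az2$statistic[az2$term == "f"], unname(tt^2), tolerance = 1e-10)

  # balanced two-factor design: sequential main-effect SS identical with and
  # without the interaction term
  set.seed(2)
  des <- tidyr::expand_grid(f1 = c("a", "b"), f2 = c("x", "y", "z"),
                            rep = 1:5)
  des$r <- runif(nrow(des), 0.1, 0.8)
  a_main <- anova_z(des, c("f1", "f2"), "none")
  a_int <- anova_z(des, c("f1", "f2"), "first_order")
  for (f in c("f1", "f2")) {
    expect_equal(a_main$sumsq[a_main$term == f], a_int$sumsq[a_int$term == f],
                 tolerance = 1e-10)
  }
  expect_true("f1:f2" %in% a_int$term)
  # factor df + error df = total df
  expect_equal(sum(a_int$df), nrow(des) - 1)
})

# a small two-environment dataset with strong genetic correlation
cv_world <- local({
  g <- quick_geno(n = 120, n_chrom = 2, loci = 80, seed = 71)
  K <- grm(g)
  set.seed(72)
  u0 <- draw_gv(K, 45)
  u1 <- draw_gv(K, 5)
  u2 <- draw_gv(K, 5)
  acc <- accessions(g)
  y_adj <- tibble::tibble(
    accession = rep(acc, 2),
    env = rep(c("E1", "E2"), each = 120),
    trait = "trait",
    y_adj = c(u0 + u1 + rnorm(120, 0, sqrt(25)),
              2 + u0 + u2 + rnorm(120, 0, sqrt(25))))
  list(geno = g, K = K, y_adj = y_adj, acc = acc)
})

test_that("CV2 with no helper environments reduces exactly to CV1", {
  plan <- make_partitions(cv_world$acc, 0.8, n_reps = 3, seed = 5)
  sc1 <- cv_scenario("CV1", "E1", model = "gblup")
  sc2 <- cv_scenario("CV2", "E1", helper_envs = character(), model = "gblup")
  r1 <- run_cv(sc1, plan, cv_world$y_adj, cv_world$geno)
  r2 <- run_cv(sc2, plan, cv_world$y_adj, cv_world$geno)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
})

test_that("no validation phenotype can leak into CV1 training or GWAS selection", {
  plan <- make_partitions(cv_world$acc, 0.8, n_reps = 1, seed = 6)
  sc <- cv_scenario("CV1", "E1", model = "gblup", marker_mode = "gwas_derived",
                    top_k = 40, k_subpops = 3)
  base <- suppressWarnings(run_cv(sc, plan, cv_world$y_adj, cv_world$geno,
                                  keep_predictions = TRUE))
  # corrupt the replicate's validation phenotypes in every environment;
  # neither the GWAS selection nor the fit may see them, so predictions of
  # the validation accessions must not move
  poisoned <- cv_world$y_adj
  bad <- poisoned$accession %in% plan$partitions[[1]]$validation
  poisoned$y_adj[bad] <- poisoned$y_adj[bad] + 1e3
  pois <- suppressWarnings(run_cv(sc, plan, poisoned, cv_world$geno,
                                  keep_predictions = TRUE))
  expect_equal(attr(pois, "predictions")$predicted,
               attr(base, "predictions")$predicted, tolerance = 1e-10)
})

test_that("a pure-noise phenotype has predictive ability centred at zero", {
  set.seed(7)
  noise <- cv_world$y_adj
  noise$y_adj <- rnorm(nrow(noise))
  plan <- make_partitions(cv_world$acc, 0.8, n_reps = 25, seed = 8)
  sc <- cv_scenario("CV1", "E1", model = "gblup")
  pa <- suppressWarnings(run_cv(sc, plan, noise, cv_world$geno))
  s <- glance(pa)
  expect_lt(abs(s$mean_r), 3 * s$se_r + 0.02)
})

test_that("predictive ability respects the heritability ceiling", {
  plan <- make_partitions(cv_world$acc, 0.8, n_reps = 8, seed = 9)
  sc <- cv_scenario("CV1", "E1", model = "gblup")
  pa <- run_cv(sc, plan, cv_world$y_adj, cv_world$geno)
  h2 <- 50 / 75
  expect_lte(glance(pa)$mean_r, sqrt(h2) + 0.05)
})

test_that("multi-environment CV runs end to end and CV2 uses helper records", {
  plan <- make_partitions(cv_world$acc, 0.8, n_reps = 2, seed = 10)
  sc_cv2 <- cv_scenario("CV2", "E2", helper_envs = "E1", model = "mxe_gblup")
  pa2 <- run_cv(sc_cv2, plan, cv_world$y_adj, cv_world$geno,
                iters = 800, burnin = 200)
  expect_equal(nrow(pa2), 2L)
  expect_true(all(is.finite(pa2$r)))
  expect_true(all(pa2$env == "E2"))
  # determinism of the whole CV pipeline under a fixed plan seed
  pa2b <- run_cv(sc_cv2, plan, cv_world$y_adj, cv_world$geno,
                 iters = 800, burnin = 200)
  expect_identical(pa2$r, pa2b$r)
})

test_that("scenario validation rejects inconsistent configurations", {
  expect_error(cv_scenario("CV2", "E1", helper_envs = "E1", model = "mxe_gblup"),
               class = "gsrice_config_error")
  expect_error(cv_scenario("CV1", "E1", model = "gblup",
                           marker_mode = "gwas_derived"),
               "top_k", class = "gsrice_config_error")
})
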