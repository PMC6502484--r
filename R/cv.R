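#' Random train/validation partitions
#'
#' Draws `n_reps` random partitions of the accession ids into a training
#' fraction and its complement (e.g. 280 accessions at 0.8 give 224/56;
#' 204 give 163/41). Every replicate's randomness derives from
#' `seed + replicate`, so the same plan is reproducible and reusable across
#' traits and models.
#'
#' @param ids character vector of accession ids (n >= 5).
#' @param train_frac training fraction in (0, 1); the training size is
#'   `round(train_frac * n)`.
#' @param n_reps number of replicates.
#' @param seed master integer seed.
#' @return a `gs_cv_plan`: list of per-replicate `train` / `validation` id
#'   vectors plus the plan parameters.
#' @export
make_partitions <- function(ids, train_frac = 0.8, n_reps = 100L, seed = 1L) {
  if (!is_count(n_reps)) stop_config("`n_reps` must be a positive integer")
  if (!is_scalar_prob(train_frac, 1e-12, 1 - 1e-12)) {
    stop_config("`train_frac` must lie strictly between 0 and 1")
  }
  ids <- as.character(ids)
  n <- length(ids)
  if (n < 5) stop_config("need at least 5 ids to partition")
  if (anyDuplicated(ids)) stop_config("`ids` must be unique")
  n_train <- round(train_frac * n)
  parts <- lapply(seq_len(n_reps), function(i) {
    with_local_seed(seed + i, {
      tr <- sort(sample(ids, n_train))
      list(train = tr, validation = sort(setdiff(ids, tr)))
    })
  })
  structure(list(partitions = parts, ids = ids, train_frac = train_frac,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "gs_cv_plan")
}

#' @export
print.gs_cv_plan <- function(x, ...) {
  cat(sprintf("<gs_cv_plan> %d replicates, %d ids -> train %d / validation %d (seed %d)\n",
              x$n_reps, length(x$ids), length(x$partitions[[1]]$train),
              length(x$partitions[[1]]$validation), x$seed))
  invisible(x)
}

#' Describe a cross-validation scenario
#'
#' CV1 masks every phenotype of the validation accessions; CV2 additionally
#' appends the validation accessions' records in the helper environment(s)
#' to the training data, so prediction in the target environment can borrow
#' their observed performance elsewhere. Marker input is either a fixed
#' LD-derived subset or a trait/environment-specific top-k set re-selected
#' by GWAS inside every training fold.
#'
#' @param scheme `"CV1"` or `"CV2"`.
#' @param target_env environment whose phenotypes are predicted.
#' @param helper_envs helper environments contributing training records
#'   (required non-empty for CV2 with multi-environment models).
#' @param model one of `"gblup"`, `"rkhs"`, `"mxe_gblup"`, `"gxe_rkhs"`,
#'   `"kron_multitrait"`.
#' @param marker_mode `"ld_derived"` (fixed subset) or `"gwas_derived"`
#'   (top-k re-selected per fold).
#' @param marker_set locus ids for `ld_derived` (`NULL` = all loci).
#' @param top_k subset size for `gwas_derived`.
#' @param k_subpops subpopulation count for the structure covariates used
#'   by the within-fold GWAS.
#' @return a `gs_cv_scenario` list.
#' @export
cv_scenario <- function(scheme = c("CV1", "CV2"), target_env,
                        helper_envs = character(),
                        model = c("gblup", "rkhs", "mxe_gblup", "gxe_rkhs",
                                  "kron_multitrait"),
                        marker_mode = c("ld_derived", "gwas_derived"),
                        marker_set = NULL, top_k = NULL, k_subpops = 5L) {
  scheme <- match.arg(scheme)
  model <- match.arg(model)
  marker_mode <- match.arg(marker_mode)
  if (target_env %in% helper_envs) {
    stop_config("`helper_envs` must not contain the target environment")
  }
  if (marker_mode == "gwas_derived" && is.null(top_k)) {
    stop_config("`top_k` is required for gwas_derived marker selection")
  }
  structure(list(scheme = scheme, target_env = target_env,
                 helper_envs = helper_envs, model = model,
                 marker_mode = marker_mode, marker_set = marker_set,
                 top_k = top_k, k_subpops = as.integer(k_subpops)),
            class = "gs_cv_scenario")
}

#' Run a cross-validation scenario
#'
#' For every replicate of the plan: (1) select markers — for
#' `gwas_derived`, run [mlm_gwas()] on the training fold only (kinship and
#' principal components recomputed on the training accessions, so no
#' validation information leaks into the selection) and keep the
#' [select_top_k()] loci; (2) build the model's kernel (linear relationship
#' matrix for GBLUP-type models, Gaussian for RKHS-type) on the selected
#' markers over all accessions; (3) assemble the training records per the
#' scheme; (4) fit; (5) predict the validation accessions in the target
#' environment and correlate with their observed adjusted means.
#'
#' @param scenario a [cv_scenario()].
#' @param plan a [make_partitions()] plan over the accession ids.
#' @param y_adj adjusted means: tibble with columns `accession`, `env`,
#'   `y_adj` covering the target and helper environments.
#' @param geno an imputed [geno_matrix()] over (at least) the plan's ids.
#' @param premiss pre-imputation [locus_stats()] (unused here, accepted for
#'   pipeline symmetry).
#' @param iters,burnin Gibbs chain settings for the multi-environment
#'   models.
#' @param keep_predictions if `TRUE`, attach per-replicate prediction
#'   tables as the `predictions` attribute.
#' @return a `gs_pa` tibble: `replicate`, `env`, `r`, `n_valid`; use
#'   [glance()] for the mean/SE summary.
#' @export
run_cv <- function(scenario, plan, y_adj, geno, premiss = NULL,
                   iters = 1500L, burnin = 500L, keep_predictions = FALSE) {
  stopifnot(inherits(scenario, "gs_cv_scenario"), inherits(plan, "gs_cv_plan"))
  y_adj <- as_tibble(y_adj)
  need_env <- c(scenario$target_env, scenario$helper_envs)
  missing_env <- setdiff(need_env, unique(y_adj$env))
  if (length(missing_env)) {
    stop_data("`y_adj` lacks environment(s): %s", paste(missing_env, collapse = ", "))
  }
  missing_geno <- setdiff(plan$ids, accessions(geno))
  if (length(missing_geno)) {
    stop_data("genotypes lack plan accession(s): %s",
              paste(head(missing_geno, 5), collapse = ", "))
  }
  multi <- scenario$model %in% c("mxe_gblup", "gxe_rkhs", "kron_multitrait")
  g_plan <- subset_geno(geno, accessions = plan$ids)
  target_y <- y_adj[y_adj$env == scenario$target_env, ]
  yt_all <- setNames(target_y$y_adj, target_y$accession)

  results <- vector("list", plan$n_reps)
  preds <- vector("list", plan$n_reps)
  for (i in seq_len(plan$n_reps)) {
    part <- plan$partitions[[i]]
    train_ids <- part$train
    valid_ids <- part$validation
    obs_valid <- yt_all[intersect(valid_ids, names(yt_all))]
    obs_valid <- obs_valid[!is.na(obs_valid)]
    if (length(obs_valid) < 3) {
      warn(sprintf("replicate %d: fewer than 3 phenotyped validation accessions; skipped", i))
      results[[i]] <- tibble(replicate = i, env = scenario$target_env,
                             r = NA_real_, n_valid = length(obs_valid))
      next
    }

    sel <- select_markers(scenario, g_plan, train_ids, yt_all, i)
    g_sel <- subset_geno(g_plan, loci = sel)
    Ksel <- if (scenario$model %in% c("gblup", "mxe_gblup", "kron_multitrait")) {
      grm(g_sel)
    } else {
      gaussian_kernel(g_sel)
    }

    rep_seed <- plan$seed + 7919L * i
    if (!multi) {
      ytr <- yt_all[intersect(train_ids, names(yt_all))]
      fit <- if (scenario$model == "gblup") {
        fit_gblup(ytr, Ksel)
      } else {
        fit_rkhs(ytr, Ksel)
      }
      pr <- predict(fit, names(obs_valid))
      pred <- setNames(pr$gebv, pr$accession)
    } else {
      envs_used <- c(scenario$target_env, scenario$helper_envs)
      recs <- y_adj[y_adj$env %in% envs_used & y_adj$accession %in% train_ids, ]
      if (scenario$scheme == "CV2" && length(scenario$helper_envs)) {
        helper_recs <- y_adj[y_adj$env %in% scenario$helper_envs &
                               y_adj$accession %in% valid_ids, ]
        recs <- dplyr::bind_rows(recs, helper_recs)
      }
      fit <- switch(scenario$model,
        mxe_gblup = fit_mxe_gblup(recs, Ksel, iters = iters, burnin = burnin,
                                  seed = rep_seed),
        gxe_rkhs = fit_gxe_rkhs(recs, Ksel, iters = iters, burnin = burnin,
                                seed = rep_seed),
        kron_multitrait = fit_kron_multitrait(recs, Ksel, iters = iters,
                                              burnin = burnin, seed = rep_seed))
      pr <- predict(fit, tibble(accession = names(obs_valid),
                                env = scenario$target_env))
      pred <- setNames(pr$gebv, pr$accession)
    }

    r <- predictive_ability(pred[names(obs_valid)], obs_valid)
    results[[i]] <- tibble(replicate = i, env = scenario$target_env,
                           r = r, n_valid = length(obs_valid))
    if (keep_predictions) {
      preds[[i]] <- tibble(replicate = i, accession = names(obs_valid),
                           predicted = unname(pred[names(obs_valid)]),
                           observed = unname(obs_valid))
    }
  }
  out <- dplyr::bind_rows(results)
  attr(out, "scenario") <- scenario
  if (keep_predictions) attr(out, "predictions") <- dplyr::bind_rows(preds)
  class(out) <- c("gs_pa", class(out))
  out
}

# within-fold marker selection (training accessions only for gwas_derived)
select_markers <- function(scenario, g_plan, train_ids, yt_all, replicate) {
  if (scenario$marker_mode == "ld_derived") {
    return(scenario$marker_set %||% g_plan$loci$locus_id)
  }
  ytr <- yt_all[intersect(train_ids, names(yt_all))]
  ytr <- ytr[!is.na(ytr)]
  g_tr <- subset_geno(g_plan, accessions = names(ytr))
  Ktr <- grm(g_tr)
  Qtr <- structure_covariates(g_tr, scenario$k_subpops)
  res <- mlm_gwas(ytr, g_tr, K = Ktr, Q = Qtr)
  select_top_k(res, min(scenario$top_k, nrow(res)))
}

#' @method glance gs_pa
#' @export
glance.gs_pa <- function(x, ...) {
  ok <- x[!is.na(x$r), ]
  z <- fisher_z(pmin(pmax(ok$r, -0.999999), 0.999999))
  tibble(n_reps = nrow(ok),
         mean_r = mean(ok$r),
         se_r = sd(ok$r) / sqrt(nrow(ok)),
         mean_r_backtransformed = inverse_fisher_z(mean(z)),
         n_skipped = sum(is.na(x$r)))
}

#' Predictive ability
#'
#' Sample Pearson correlation between predicted and observed values of the
#' validation set.
#'
#' @param pred,obs numeric vectors of equal length (>= 3).
#' @return the correlation, or `NA` with a warning when either vector has
#'   zero variance.
#' @export
predictive_ability <- function(pred, obs) {
  if (length(pred) != length(obs)) stop_data("`pred` and `obs` lengths differ")
  if (length(pred) < 3) stop_data("need at least 3 pairs")
  if (sd(pred) == 0 || sd(obs) == 0) {
    warn("zero variance in predictions or observations; predictive ability undefined")
    return(NA_real_)
  }
  cor(pred, obs)
}

#' Fisher Z transform and its inverse
#'
#' `Z = 0.5 (ln(1 + r) - ln(1 - r))`; the inverse is `tanh(z)`. Correlations
#' on the Z scale are approximately normal with variance independent of the
#' true correlation, which is why ANOVA of predictive abilities is run on Z.
#'
#' @param r correlation(s) with `|r| < 1`.
#' @param z Fisher Z value(s).
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop_config("`r` must satisfy |r| < 1")
  0.5 * (log(1 + r) - log(1 - r))
}

#' @rdname fisher_z
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Fixed-effects ANOVA of Fisher-Z-transformed predictive ability
#'
#' Transforms the correlations to the Z scale and fits a fixed-effects
#' linear model with sequential (Type I) sums of squares in the supplied
#' factor order, optionally with all first-order interactions; F statistics
#' are tested against the error mean square. Aliased terms are reported
#' with 0 degrees of freedom.
#'
#' @param pa a data frame with a correlation column `r` plus factor columns.
#' @param factors character vector naming the factor columns, in the order
#'   the sequential decomposition should use.
#' @param interactions `"none"` or `"first_order"`.
#' @param response name of the correlation column.
#' @return a `gs_zanova` tibble: `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p_value`.
#' @export
anova_z <- function(pa, factors, interactions = c("none", "first_order"),
                    response = "r") {
  interactions <- match.arg(interactions)
  pa <- as_tibble(pa)
  missing_cols <- setdiff(c(response, factors), names(pa))
  if (length(missing_cols)) {
    stop_data("`pa` lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  dat <- pa[!is.na(pa[[response]]), ]
  for (f in factors) {
    dat[[f]] <- factor(dat[[f]])
    if (nlevels(dat[[f]]) < 2) {
      stop_data("factor '%s' needs at least 2 levels", f)
    }
  }
  dat$.z <- fisher_z(pmin(pmax(dat[[response]], -0.999999), 0.999999))
  rhs <- paste(factors, collapse = " + ")
  if (interactions == "first_order" && length(factors) > 1) {
    pairs <- utils::combn(factors, 2, FUN = function(p) paste(p, collapse = ":"))
    rhs <- paste(c(factors, pairs), collapse = " + ")
  }
  fit <- lm(stats::as.formula(paste(".z ~", rhs)), data = dat)
  a <- anova(fit)
  out <- tibble(term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`,
                meansq = a$`Mean Sq`, statistic = a$`F value`,
                p_value = a$`Pr(>F)`)
  # aliased terms never make it into the table; report them with 0 df
  wanted <- attr(stats::terms(fit), "term.labels")
  dropped <- setdiff(wanted, out$term)
  if (length(dropped)) {
    out <- dplyr::bind_rows(out, tibble(term = dropped, df = 0L, sumsq = 0,
                                        meansq = NA_real_,
                                        statistic = NA_real_,
                                        p_value = NA_real_))
  }
  class(out) <- c("gs_zanova", class(out))
  out
}
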