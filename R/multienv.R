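#' Multi-environment kernel models fitted by Gibbs sampling
#'
#' `fit_mxe_gblup()` fits the marker-by-environment decomposition on a
#' linear relationship matrix: stacked records
#' `y = mu_env + u0 + u_env + e`, where `u0 ~ N(0, sigma2_0 K)` is a
#' genetic main effect shared across environments and each
#' `u_env ~ N(0, sigma2_env K)` is an environment-specific deviation. The
#' implied genetic correlation between environments j and k is
#' `sigma2_0 / sqrt((sigma2_0 + sigma2_j)(sigma2_0 + sigma2_k))`.
#' `fit_gxe_rkhs()` is the same decomposition with a Gaussian kernel — the
#' empirical-Bayes genotype-by-environment RKHS model. Variance components
#' carry scaled-inverse-chi-squared priors (default df 5, scales set from
#' the sample variance with an R-squared split of 0.5) and are sampled by
#' Gibbs; posterior means are reported after burn-in.
#'
#' @param data stacked records: data frame with columns `accession`, `env`
#'   and `y_adj` (at most one record per accession-environment cell).
#' @param K kernel over all accessions of interest (training and
#'   prediction targets); rownames required.
#' @param iters,burnin Gibbs chain length and burn-in (the defaults follow
#'   common practice for these samplers; tests use shorter chains).
#' @param seed integer seed making the chain reproducible; `NULL` uses the
#'   current RNG state.
#' @param df_prior,r2_prior prior degrees of freedom and variance split.
#' @return a `gs_multi_fit` with posterior means of the environment
#'   intercepts, the genetic values (`u0`, `u_env`), the variance
#'   components, the implied between-environment genetic-correlation matrix
#'   `env_cor`, and sampler diagnostics.
#' @export
fit_mxe_gblup <- function(data, K, iters = 25000L, burnin = 5000L,
                          seed = NULL, df_prior = 5, r2_prior = 0.5) {
  fit_env_decomp(data, K, iters, burnin, seed, df_prior, r2_prior,
                 model = "mxe_gblup")
}

#' @rdname fit_mxe_gblup
#' @export
fit_gxe_rkhs <- function(data, K, iters = 25000L, burnin = 5000L,
                         seed = NULL, df_prior = 5, r2_prior = 0.5) {
  fit_env_decomp(data, K, iters, burnin, seed, df_prior, r2_prior,
                 model = "gxe_rkhs")
}

fit_env_decomp <- function(data, K, iters, burnin, seed, df_prior, r2_prior,
                           model) {
  dat <- check_multienv_data(data, min_env = 1L)
  Km <- as_kernel_matrix(K)
  acc_all <- rownames(Km)
  missing_acc <- setdiff(dat$accession, acc_all)
  if (length(missing_acc)) {
    stop_data("kernel lacks accession(s): %s",
              paste(head(missing_acc, 5), collapse = ", "))
  }
  envs <- unique(dat$env)
  J <- length(envs)
  n_obs <- nrow(dat)
  y <- dat$y_adj
  obs_acc <- match(dat$accession, acc_all)
  obs_env <- match(dat$env, envs)

  eig <- kernel_eigen(Km)
  term_main <- make_gibbs_term(eig, obs_acc)
  term_env <- lapply(seq_len(J), function(j) {
    idx <- which(obs_env == j)
    c(make_gibbs_term(eig, obs_acc[idx]), list(idx = idx))
  })

  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  mdiag <- mean(diag(Km))
  Se0 <- vy * (1 - r2_prior) * (df_prior + 2)
  Su0 <- vy * r2_prior * (df_prior + 2) / (2 * mdiag)
  Sj0 <- vy * r2_prior * (df_prior + 2) / (2 * mdiag)

  with_local_seed(seed, {
    s2e <- vy / 2
    s2_0 <- vy * r2_prior / (2 * mdiag)
    s2_j <- rep(vy * r2_prior / (2 * mdiag), J)
    mu <- tapply(y, obs_env, mean)[as.character(seq_len(J))]
    mu <- as.numeric(mu)
    fit_main <- numeric(n_obs)
    fit_env <- numeric(n_obs)
    c_main <- numeric(term_main$m)

    n_keep <- iters - burnin
    if (n_keep <= 0) stop_config("`iters` must exceed `burnin`")
    acc_c_main <- numeric(term_main$m)
    acc_c_env <- lapply(term_env, function(t) numeric(t$m))
    acc_mu <- numeric(J)
    samp_var <- matrix(NA_real_, n_keep, 2 + J,
                       dimnames = list(NULL, c("sigma2_0", paste0("sigma2_", envs),
                                               "sigma2_e")))
    kept <- 0L

    for (it in seq_len(iters)) {
      # environment intercepts (flat prior)
      resid <- y - fit_main - fit_env
      for (j in seq_len(J)) {
        idx <- term_env[[j]]$idx
        nj <- length(idx)
        mu[j] <- mean(resid[idx]) + rnorm(1) * sqrt(s2e / nj)
      }
      resid <- resid - mu[obs_env]

      # main genetic effect
      up <- update_gibbs_term(term_main, resid + fit_main, s2_0, s2e)
      fit_main <- up$fitted
      c_main <- up$c
      s2_0 <- rinvchisq(df_prior + term_main$r, Su0 + up$ss)

      # environment-specific deviations
      ss_env <- numeric(J)
      c_env <- vector("list", J)
      for (j in seq_len(J)) {
        tj <- term_env[[j]]
        idx <- tj$idx
        ystar_j <- y[idx] - mu[j] - fit_main[idx]
        upj <- update_gibbs_term(tj, ystar_j, s2_j[j], s2e)
        fit_env[idx] <- upj$fitted
        c_env[[j]] <- upj$c
        s2_j[j] <- rinvchisq(df_prior + tj$r, Sj0 + upj$ss)
      }

      # residual variance
      e <- y - mu[obs_env] - fit_main - fit_env
      s2e <- rinvchisq(df_prior + n_obs, Se0 + sum(e^2))

      if (it > burnin) {
        kept <- kept + 1L
        acc_c_main <- acc_c_main + c_main
        for (j in seq_len(J)) acc_c_env[[j]] <- acc_c_env[[j]] + c_env[[j]]
        acc_mu <- acc_mu + mu
        samp_var[kept, ] <- c(s2_0, s2_j, s2e)
      }
    }

    u0 <- term_posterior_u(term_main, eig, acc_c_main / kept)
    names(u0) <- acc_all
    u_env <- vapply(seq_len(J), function(j) {
      term_posterior_u(term_env[[j]], eig, acc_c_env[[j]] / kept)
    }, numeric(length(acc_all)))
    dimnames(u_env) <- list(acc_all, envs)

    # implied genetic correlation, averaged over posterior draws
    env_cor <- diag(1, J)
    dimnames(env_cor) <- list(envs, envs)
    if (J >= 2) {
      for (j in seq_len(J - 1)) {
        for (k in seq(j + 1, J)) {
          rho <- samp_var[, 1] /
            sqrt((samp_var[, 1] + samp_var[, 1 + j]) *
                   (samp_var[, 1] + samp_var[, 1 + k]))
          env_cor[j, k] <- env_cor[k, j] <- mean(rho)
        }
      }
    }

    structure(list(
      model = model, envs = envs,
      mu = setNames(acc_mu / kept, envs),
      u0 = u0, u_env = u_env,
      sigma2_0 = mean(samp_var[, 1]),
      sigma2_env = setNames(colMeans(samp_var)[1 + seq_len(J)], envs),
      sigma2_e = mean(samp_var[, 2 + J]),
      env_cor = env_cor,
      var_samples = samp_var,
      diagnostics = list(iters = iters, burnin = burnin, seed = seed,
                         n_obs = n_obs, kernel_kind = attr(K, "kind") %||% "user")
    ), class = "gs_multi_fit")
  })
}

check_multienv_data <- function(data, min_env = 2L) {
  dat <- as_tibble(data)
  col <- intersect(c("y_adj", "value", "y"), names(dat))
  if (!all(c("accession", "env") %in% names(dat)) || !length(col)) {
    stop_data("`data` needs columns `accession`, `env` and `y_adj`")
  }
  dat <- dat[!is.na(dat[[col[1]]]), c("accession", "env", col[1])]
  names(dat)[3] <- "y_adj"
  if (anyDuplicated(dat[, c("accession", "env")])) {
    stop_data("at most one record per accession-environment cell")
  }
  envs <- unique(dat$env)
  if (length(envs) < min_env) {
    stop_data("need at least %d environment(s), got %d", min_env, length(envs))
  }
  n_per_env <- table(dat$env)
  if (any(n_per_env < 2)) {
    stop_data("environment(s) with fewer than 2 records: %s",
              paste(names(n_per_env)[n_per_env < 2], collapse = ", "))
  }
  dat
}

#' Kronecker multi-trait (multi-environment) genomic model
#'
#' Treats the environments as correlated traits: `Y = 1 mu' + U + E` with
#' `vec(U) ~ N(0, Sigma_G %x% K)` for an unstructured environment-level
#' genetic covariance `Sigma_G` (inverse-Wishart prior, df J + 2,
#' identity-proportional scale) and independent per-environment residual
#' variances. Missing cells — including accessions never phenotyped — are
#' handled by data augmentation, so predictions for unphenotyped accessions
#' borrow strength through both `K` and `Sigma_G`. Fitted by Gibbs; the
#' sampler works in the eigenbasis of `K` where the rows of the rotated
#' genetic matrix are independent, and simultaneously diagonalizes the
#' residual and genetic precisions per iteration so each row update is a
#' vectorized scalar draw.
#'
#' @inheritParams fit_mxe_gblup
#' @param data records as in [fit_mxe_gblup()] (>= 2 environments), or an
#'   accession x environment matrix with `NA` for missing cells.
#' @return a `gs_multi_fit` with posterior means of `mu`, the genetic
#'   values `u_env` (accession x environment), `Sigma_G` and its
#'   correlation form `env_cor`, residual variances, and diagnostics.
#' @export
fit_kron_multitrait <- function(data, K, iters = 25000L, burnin = 5000L,
                                seed = NULL, df_prior = 5, r2_prior = 0.5) {
  Km <- as_kernel_matrix(K)
  acc_all <- rownames(Km)
  if (is.matrix(data) && !is.data.frame(data)) {
    Y0 <- data
    envs <- colnames(Y0) %||% paste0("E", seq_len(ncol(Y0)))
  } else {
    dat <- check_multienv_data(data, min_env = 2L)
    envs <- unique(dat$env)
    Y0 <- matrix(NA_real_, length(acc_all), length(envs),
                 dimnames = list(acc_all, envs))
    Y0[cbind(match(dat$accession, acc_all), match(dat$env, envs))] <- dat$y_adj
  }
  J <- ncol(Y0)
  if (J < 2) stop_data("need at least 2 environments")
  if (any(colSums(!is.na(Y0)) == 0)) {
    stop_data("environment(s) with no observed records: %s",
              paste(envs[colSums(!is.na(Y0)) == 0], collapse = ", "))
  }
  missing_acc <- setdiff(rownames(Y0), acc_all)
  if (length(missing_acc)) {
    stop_data("kernel lacks accession(s): %s",
              paste(head(missing_acc, 5), collapse = ", "))
  }
  Y0 <- Y0[match(acc_all, rownames(Y0)), , drop = FALSE]
  rownames(Y0) <- acc_all
  n <- nrow(Y0)

  eig <- kernel_eigen(Km)
  G <- eig$vectors
  lam <- eig$values
  r <- eig$rank

  obs <- !is.na(Y0)
  vyj <- apply(Y0, 2, var, na.rm = TRUE)
  vyj[!is.finite(vyj) | vyj <= 0] <- 1
  mdiag <- mean(diag(Km))
  df_e <- df_prior
  Se0 <- vyj * (1 - r2_prior) * (df_e + 2)
  df_g <- J + 2
  # prior mean of Sigma_G proportional to identity on the trait scale
  S0 <- diag(vyj * r2_prior / mdiag, J) * (df_g - J - 1)

  with_local_seed(seed, {
    mu <- colMeans(Y0, na.rm = TRUE)
    s2e <- vyj / 2
    Sigma_G <- diag(vyj * r2_prior / mdiag, J)
    Y <- Y0
    for (j in seq_len(J)) Y[!obs[, j], j] <- mu[j]
    U <- matrix(0, n, J)

    n_keep <- iters - burnin
    if (n_keep <= 0) stop_config("`iters` must exceed `burnin`")
    acc_U <- matrix(0, n, J)
    acc_mu <- numeric(J)
    acc_Sigma <- matrix(0, J, J)
    acc_cor <- matrix(0, J, J)
    acc_s2e <- numeric(J)
    kept <- 0L

    for (it in seq_len(iters)) {
      # simultaneous diagonalization of residual and genetic precision
      rsd_half <- sqrt(s2e)
      B <- diag(1 / rsd_half, J) %*% Sigma_G %*% diag(1 / rsd_half, J)
      eB <- eigen((B + t(B)) / 2, symmetric = TRUE)
      phi <- 1 / pmax(eB$values, 1e-12)
      Tm <- diag(rsd_half, J) %*% eB$vectors      # T'R^-1 T = I, T'Sg^-1 T = diag(phi)

      Yc <- sweep(Y, 2, mu)
      Ystar <- crossprod(G, Yc)                   # r x J
      A <- Ystar %*% (diag(1 / s2e, J) %*% Tm)    # T' R^-1 y*, transposed layout
      Sc <- 1 / (1 + outer(1 / lam, phi))         # r x J conditional variances
      Cdraw <- A * Sc + matrix(rnorm(r * J), r, J) * sqrt(Sc)
      Ustar <- Cdraw %*% t(Tm)
      U <- G %*% Ustar

      # Sigma_G | U
      Spost <- S0 + crossprod(Ustar / sqrt(lam))
      Sigma_G <- solve(rWishart_one(df_g + r, solve(Spost)))

      # residual variances and intercepts
      for (j in seq_len(J)) {
        e <- Y[, j] - mu[j] - U[, j]
        s2e[j] <- rinvchisq(df_e + n, Se0[j] + sum(e^2))
        mu[j] <- mean(Y[, j] - U[, j]) + rnorm(1) * sqrt(s2e[j] / n)
      }

      # data augmentation for missing cells
      for (j in seq_len(J)) {
        mis <- !obs[, j]
        if (any(mis)) {
          Y[mis, j] <- mu[j] + U[mis, j] + rnorm(sum(mis)) * sqrt(s2e[j])
        }
      }

      if (it > burnin) {
        kept <- kept + 1L
        acc_U <- acc_U + U
        acc_mu <- acc_mu + mu
        acc_Sigma <- acc_Sigma + Sigma_G
        acc_cor <- acc_cor + stats::cov2cor(Sigma_G)
        acc_s2e <- acc_s2e + s2e
      }
    }

    u_env <- acc_U / kept
    dimnames(u_env) <- list(acc_all, envs)
    Sigma_mean <- acc_Sigma / kept
    env_cor <- acc_cor / kept
    dimnames(Sigma_mean) <- dimnames(env_cor) <- list(envs, envs)

    structure(list(
      model = "kron_multitrait", envs = envs,
      mu = setNames(acc_mu / kept, envs),
      u0 = NULL, u_env = u_env,
      Sigma_G = Sigma_mean, env_cor = env_cor,
      sigma2_e = setNames(acc_s2e / kept, envs),
      diagnostics = list(iters = iters, burnin = burnin, seed = seed,
                         n_obs = sum(obs), kernel_kind = attr(K, "kind") %||% "user")
    ), class = "gs_multi_fit")
  })
}

# one Wishart draw (stats::rWishart returns an array)
rWishart_one <- function(df, S) {
  stats::rWishart(1, df, S)[, , 1]
}

#' @export
print.gs_multi_fit <- function(x, ...) {
  cat(sprintf("<gs_multi_fit> %s over %d environments (%s); chain %d/%d\n",
              x$model, length(x$envs), paste(x$envs, collapse = ", "),
              x$diagnostics$iters, x$diagnostics$burnin))
  invisible(x)
}

#' @method tidy gs_multi_fit
#' @export
tidy.gs_multi_fit <- function(x, ...) {
  if (x$model == "kron_multitrait") {
    tibble(term = c(paste0("mu_", x$envs), paste0("sigma2_e_", x$envs),
                    paste0("sigma2_g_", x$envs)),
           estimate = c(unname(x$mu), unname(x$sigma2_e), diag(x$Sigma_G)))
  } else {
    tibble(term = c(paste0("mu_", x$envs), "sigma2_0",
                    paste0("sigma2_", x$envs), "sigma2_e"),
           estimate = c(unname(x$mu), x$sigma2_0, unname(x$sigma2_env),
                        x$sigma2_e))
  }
}

#' @method glance gs_multi_fit
#' @export
glance.gs_multi_fit <- function(x, ...) {
  tibble(model = x$model, n_env = length(x$envs),
         n_obs = x$diagnostics$n_obs,
         iters = x$diagnostics$iters, burnin = x$diagnostics$burnin,
         mean_env_cor = mean(x$env_cor[upper.tri(x$env_cor)]))
}

#' Predict genetic values from a multi-environment fit
#'
#' @param object a `gs_multi_fit`.
#' @param targets data frame with columns `accession` and `env`; defaults
#'   to every accession x environment combination of the fit.
#' @param ... unused.
#' @return tibble with columns `accession`, `env`, `gebv` (posterior-mean
#'   genetic value plus environment intercept).
#' @export
predict.gs_multi_fit <- function(object, targets = NULL, ...) {
  if (is.null(targets)) {
    targets <- tidyr::expand_grid(accession = rownames(object$u_env),
                                  env = object$envs)
  }
  targets <- as_tibble(targets)
  if (nrow(targets) == 0) {
    return(tibble(accession = character(), env = character(), gebv = numeric()))
  }
  unknown <- setdiff(targets$accession, rownames(object$u_env))
  if (length(unknown)) {
    stop_data("accession(s) not covered by the fitted kernel: %s",
              paste(unique(unknown), collapse = ", "))
  }
  bad_env <- setdiff(targets$env, object$envs)
  if (length(bad_env)) {
    stop_data("environment(s) not in the fit: %s", paste(bad_env, collapse = ", "))
  }
  ai <- match(targets$accession, rownames(object$u_env))
  ei <- match(targets$env, object$envs)
  g <- object$u_env[cbind(ai, ei)]
  if (!is.null(object$u0)) g <- g + object$u0[ai]
  tibble(accession = targets$accession, env = targets$env,
         gebv = unname(object$mu[ei] + g))
}
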