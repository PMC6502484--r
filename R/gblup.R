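#' Single-environment kernel prediction (GBLUP / RKHS)
#'
#' Fits `y = mu + u + e` with `u ~ N(0, sigma2_u K)` by EM-REML on the
#' training accessions, then extends the genetic values to every accession
#' covered by the kernel through the conditional expectation
#' `u_target = sigma2_u K[target, train] V^{-1} (y - mu)`. With a linear
#' relationship matrix this is GBLUP; [fit_rkhs()] is the same machinery
#' with a Gaussian kernel and captures non-additive genetic signal.
#'
#' @param y training phenotypes: a data frame with columns `accession` and
#'   `y_adj` (adjusted means), or a named numeric vector.
#' @param K kernel matrix (from [grm()] or [gaussian_kernel()]) whose
#'   rownames cover the union of training and prediction accessions.
#' @param tol,max_iter EM-REML convergence tolerance on the restricted
#'   log-likelihood, and iteration cap.
#' @param fix_sigma2_e optionally hold the residual variance fixed at this
#'   value (e.g. near zero for interpolation) and estimate only the genetic
#'   variance.
#' @return a `gs_single_fit` with intercept `mu`, per-accession genetic
#'   values `u_hat` (over all kernel accessions), variance components,
#'   restricted log-likelihood trace and convergence flag.
#' @examples
#' sim <- simulate_trial(sim_config(n_accessions = 60, n_chrom = 2,
#'                                  loci_per_chrom = 60, env_labels = "E1",
#'                                  missing_rate = 0, seed = 3))
#' y <- tibble::tibble(accession = accessions(sim$geno),
#'                     y_adj = sim$truth$true_bv[, 1] + rnorm(60, 0, 5))
#' fit <- fit_gblup(y, grm(sim$geno))
#' glance(fit)
#' @export
fit_gblup <- function(y, K, tol = 1e-8, max_iter = 1000L,
                      fix_sigma2_e = NULL) {
  fit_single_kernel(y, K, tol, max_iter, fix_sigma2_e, label = "gblup")
}

#' @rdname fit_gblup
#' @export
fit_rkhs <- function(y, K, tol = 1e-8, max_iter = 1000L,
                     fix_sigma2_e = NULL) {
  fit_single_kernel(y, K, tol, max_iter, fix_sigma2_e, label = "rkhs")
}

fit_single_kernel <- function(y, K, tol, max_iter, fix_sigma2_e = NULL,
                              label) {
  yv <- as_named_response(y)
  Km <- as_kernel_matrix(K)
  train <- names(yv)
  missing_acc <- setdiff(train, rownames(Km))
  if (length(missing_acc)) {
    stop_data("kernel lacks training accession(s): %s",
              paste(head(missing_acc, 5), collapse = ", "))
  }
  Kt <- Km[train, train]
  res <- em_reml_kernel(yv, matrix(1, length(yv), 1), Kt,
                        tol = tol, max_iter = max_iter,
                        fix_sigma2_e = fix_sigma2_e)
  # conditional-expectation extension to every kernel accession
  u_all <- drop(res$sigma2_u * Km[, train, drop = FALSE] %*% res$py)
  names(u_all) <- rownames(Km)
  structure(list(
    mu = unname(res$beta[1]),
    u_hat = u_all,
    sigma2_u = res$sigma2_u, sigma2_e = res$sigma2_e,
    loglik_trace = res$loglik_trace, converged = res$converged,
    kernel_kind = attr(K, "kind") %||% "user",
    model = label, train_ids = train
  ), class = "gs_single_fit")
}

as_named_response <- function(y) {
  if (is.data.frame(y)) {
    col <- intersect(c("y_adj", "value", "y"), names(y))
    if (!("accession" %in% names(y)) || !length(col)) {
      stop_data("`y` needs columns `accession` and `y_adj`")
    }
    yv <- setNames(y[[col[1]]], y$accession)
  } else {
    yv <- y
  }
  if (is.null(names(yv))) stop_data("`y` must carry accession names")
  yv <- yv[!is.na(yv)]
  if (length(yv) < 3) stop_data("need at least 3 training phenotypes")
  if (anyDuplicated(names(yv))) stop_data("duplicate accessions in `y`")
  yv
}

#' @export
print.gs_single_fit <- function(x, ...) {
  cat(sprintf("<gs_single_fit> %s: n_train = %d, sigma2_u = %.4g, sigma2_e = %.4g (h2 = %.3f)%s\n",
              x$model, length(x$train_ids), x$sigma2_u, x$sigma2_e,
              x$sigma2_u / (x$sigma2_u + x$sigma2_e),
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Predict genomic estimated breeding values
#'
#' @param object a `gs_single_fit`.
#' @param accessions character vector of accessions to predict (must be
#'   covered by the kernel the model was fitted with); defaults to all.
#' @param ... unused.
#' @return tibble with columns `accession`, `gebv`.
#' @export
predict.gs_single_fit <- function(object, accessions = NULL, ...) {
  accessions <- accessions %||% names(object$u_hat)
  if (length(accessions) == 0) {
    return(tibble(accession = character(), gebv = numeric()))
  }
  unknown <- setdiff(accessions, names(object$u_hat))
  if (length(unknown)) {
    stop_data("accession(s) not covered by the fitted kernel: %s",
              paste(unknown, collapse = ", "))
  }
  tibble(accession = accessions,
         gebv = object$mu + unname(object$u_hat[accessions]))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy gs_single_fit
#' @export
tidy.gs_single_fit <- function(x, ...) {
  tibble(term = c("sigma2_u", "sigma2_e", "mu"),
         estimate = c(x$sigma2_u, x$sigma2_e, x$mu))
}

#' @method glance gs_single_fit
#' @export
glance.gs_single_fit <- function(x, ...) {
  tibble(model = x$model, n_train = length(x$train_ids),
         sigma2_u = x$sigma2_u, sigma2_e = x$sigma2_e,
         h2 = x$sigma2_u / (x$sigma2_u + x$sigma2_e),
         loglik_restricted = utils::tail(x$loglik_trace, 1),
         n_iter = length(x$loglik_trace), converged = x$converged)
}
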