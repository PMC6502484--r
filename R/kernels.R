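#' Genomic relationship matrix
#'
#' Builds the linear kernel over accessions from an imputed dosage matrix.
#' `centering = "vanraden"` (default) centers each locus by twice its allele
#' frequency and scales by `2 * sum(p (1 - p))`, giving a matrix with mean
#' diagonal near 1; `"raw"` is the plain cross-product `M M'` of the dosages
#' as-is. A jitter of 1e-8 is added to the diagonal if needed to make the
#' result numerically positive semi-definite.
#'
#' @param g an imputed [geno_matrix()], or a bare numeric dosage matrix with
#'   accession rownames.
#' @param centering `"vanraden"` or `"raw"`.
#' @return an accession x accession `gs_kernel` matrix.
#' @export
grm <- function(g, centering = c("vanraden", "raw")) {
  centering <- match.arg(centering)
  M <- if (inherits(g, "geno_matrix")) g$dosage else g
  if (ncol(M) == 0) stop_data("zero loci: cannot build a relationship matrix")
  if (anyNA(M)) stop_data("dosages contain missing values; impute first")
  if (centering == "vanraden") {
    p <- colMeans(M) / 2
    W <- sweep(M, 2, 2 * p)
    denom <- 2 * sum(p * (1 - p))
    if (denom <= 0) stop_data("all loci monomorphic: relationship matrix undefined")
    G <- tcrossprod(W) / denom
  } else {
    G <- tcrossprod(M)
  }
  new_kernel(G, kind = "linear_grm", centering = centering)
}

#' Gaussian (RKHS) kernel
#'
#' `K[i, j] = exp(-h * d2[i, j])` where `d2` is the squared Euclidean
#' distance between dosage rows divided by the locus count. The default
#' bandwidth is the reciprocal of the median off-diagonal `d2`, placing the
#' kernel in its informative range regardless of marker density.
#'
#' @param g an imputed [geno_matrix()] or bare dosage matrix.
#' @param h positive bandwidth; `NULL` for the reciprocal-median rule.
#' @return an accession x accession `gs_kernel` matrix with unit diagonal;
#'   attribute `h` records the bandwidth used.
#' @export
gaussian_kernel <- function(g, h = NULL) {
  M <- if (inherits(g, "geno_matrix")) g$dosage else g
  if (anyNA(M)) stop_data("dosages contain missing values; impute first")
  if (!is.null(h) && (!is.numeric(h) || length(h) != 1 || h <= 0)) {
    stop_config("`h` must be a positive real")
  }
  sq <- rowSums(M^2)
  d2 <- (outer(sq, sq, "+") - 2 * tcrossprod(M)) / ncol(M)
  d2[d2 < 0] <- 0
  if (is.null(h)) {
    med <- median(d2[upper.tri(d2)])
    if (!is.finite(med) || med <= 0) med <- 1
    h <- 1 / med
  }
  K <- exp(-h * d2)
  diag(K) <- 1
  out <- new_kernel(K, kind = "gaussian")
  attr(out, "h") <- h
  out
}

new_kernel <- function(G, kind, centering = NULL) {
  G <- (G + t(G)) / 2
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(1, max(abs(diag(G))))) {
    G <- G + diag(1e-8 - ev_min, nrow(G))
  }
  structure(G, class = c("gs_kernel", "matrix"),
            kind = kind, centering = centering)
}

#' @export
print.gs_kernel <- function(x, ...) {
  cat(sprintf("<gs_kernel> %s, %d accessions, mean diagonal %.3f\n",
              attr(x, "kind"), nrow(x), mean(diag(x))))
  invisible(x)
}

# accept gs_kernel or plain matrix, return plain symmetric matrix + names
as_kernel_matrix <- function(K) {
  if (is.null(rownames(K))) stop_data("kernel must carry accession rownames")
  m <- unclass(K)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  m
}
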