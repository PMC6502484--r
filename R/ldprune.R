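#' Pairwise LD (r-squared) within one chromosome
#'
#' Computes the composite (Rogers-Huff style) r² for unphased dosage data:
#' the squared Pearson correlation between the two dosage columns. Requires
#' imputed (missing-free) dosages. Monomorphic loci are defined to have
#' r² = 0 against every other locus.
#'
#' @param g an imputed [geno_matrix()].
#' @param chrom chromosome id.
#' @return an `ld_matrix`: list with `chrom`, `locus_ids` and the symmetric
#'   `r2` matrix (unit diagonal).
#' @export
pairwise_r2 <- function(g, chrom) {
  idx <- which(g$loci$chrom == chrom)
  if (length(idx) == 0) stop_data("no loci on chromosome '%s'", chrom)
  d <- g$dosage[, idx, drop = FALSE]
  if (anyNA(d)) stop_data("dosages contain missing values; impute first")
  if (length(idx) == 1) {
    warn(sprintf("chromosome '%s' has a single locus; empty LD matrix", chrom))
    r2 <- matrix(1, 1, 1, dimnames = list(colnames(d), colnames(d)))
  } else {
    sds <- apply(d, 2, sd)
    mono <- sds == 0
    r <- suppressWarnings(cor(d))
    r[mono, ] <- 0
    r[, mono] <- 0
    r2 <- r^2
    diag(r2) <- 1
  }
  structure(list(chrom = chrom, locus_ids = colnames(d), r2 = r2),
            class = "ld_matrix")
}

#' Prune loci by pairwise LD with representative selection
#'
#' Per chromosome, loci are grouped into clusters: connected components of
#' the graph whose edges join pairs with r² strictly above `r2_max`.
#' Singleton clusters are kept as-is; from every multi-locus cluster the one
#' representative with the fewest missing calls before imputation is kept,
#' ties broken by the highest MAF and remaining ties uniformly at random
#' under `seed`. Finally, kept loci with MAF below `min_maf` are dropped.
#' The construction guarantees that every retained pair on a chromosome has
#' r² <= r2_max.
#'
#' @param g an imputed [geno_matrix()].
#' @param r2_max LD threshold in `(0, 1]`; pairs above it are clustered.
#' @param min_maf minimum MAF applied to the kept set.
#' @param premiss pre-imputation [locus_stats()] (for the missing-data and
#'   MAF criteria); defaults to stats of `g` itself.
#' @param seed integer seed for random tie-breaking.
#' @return a `prune_result`: list with `kept_locus_ids`, the full
#'   `clusters` tibble (`locus_id`, `chrom`, `cluster`, `kept`) and the
#'   thresholds used.
#' @export
prune_by_ld <- function(g, r2_max, min_maf = 0, premiss = NULL, seed = 1L) {
  if (!is_scalar_prob(r2_max, 1e-12, 1)) {
    stop_config("`r2_max` must lie in (0, 1]")
  }
  if (is.null(premiss)) premiss <- locus_stats(g)
  premiss <- premiss[match(g$loci$locus_id, premiss$locus_id), ]
  if (anyNA(premiss$locus_id)) {
    stop_data("`premiss` does not cover every locus of `g`")
  }
  with_local_seed(seed, {
    res <- lapply(unique(g$loci$chrom), function(ch) {
      prune_chrom(g, ch, r2_max, premiss)
    })
    clusters <- dplyr::bind_rows(res)
    st <- locus_stats(g)
    maf <- st$maf[match(clusters$locus_id, st$locus_id)]
    clusters$kept <- clusters$kept & maf >= min_maf
    structure(list(
      kept_locus_ids = clusters$locus_id[clusters$kept],
      clusters = clusters,
      thresholds = c(r2_max = r2_max, min_maf = min_maf)
    ), class = "prune_result")
  })
}

prune_chrom <- function(g, ch, r2_max, premiss) {
  ld <- pairwise_r2(g, ch)
  r2 <- ld$r2
  n <- nrow(r2)
  adj <- (r2 > r2_max)
  diag(adj) <- FALSE
  comp <- if (n == 1) {
    list(membership = 1L)
  } else {
    igraph::components(igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
  }
  member <- comp$membership
  ids <- ld$locus_ids
  pm <- premiss[match(ids, premiss$locus_id), ]
  kept <- logical(n)
  for (cl in unique(member)) {
    in_cl <- which(member == cl)
    if (length(in_cl) == 1) {
      kept[in_cl] <- TRUE
    } else {
      sc_miss <- pm$missing_rate[in_cl]
      best <- in_cl[sc_miss == min(sc_miss)]
      if (length(best) > 1) {
        sc_maf <- pm$maf[best]
        best <- best[sc_maf == max(sc_maf)]
      }
      if (length(best) > 1) best <- sample(best, 1L)
      kept[best[1]] <- TRUE
    }
  }
  tibble(locus_id = ids, chrom = ch,
         cluster = paste0(ch, "_c", member), kept = kept)
}

#' Grid of LD x MAF pruning thresholds
#'
#' Runs [prune_by_ld()] for every combination of LD and MAF thresholds and
#' tabulates the subset sizes, the usual first step when trading marker
#' density against panel size (e.g. r² thresholds 0.25/0.5/0.75/0.9/1
#' crossed with MAF 2/5/25%).
#'
#' @param g an imputed [geno_matrix()].
#' @param r2_levels,maf_levels numeric vectors of thresholds.
#' @param premiss pre-imputation [locus_stats()].
#' @param seed integer seed.
#' @return a tibble with columns `r2_max`, `min_maf`, `n_kept` and a
#'   list-column `result` of `prune_result`s.
#' @export
threshold_grid <- function(g, r2_levels = c(0.25, 0.5, 0.75, 0.9, 1),
                           maf_levels = c(0.02, 0.05, 0.25),
                           premiss = NULL, seed = 1L) {
  if (!length(r2_levels) || !length(maf_levels)) {
    stop_config("`r2_levels` and `maf_levels` must be non-empty")
  }
  combos <- tidyr::expand_grid(r2_max = sort(r2_levels), min_maf = sort(maf_levels))
  res <- purrr::pmap(combos, function(r2_max, min_maf) {
    prune_by_ld(g, r2_max = r2_max, min_maf = min_maf, premiss = premiss,
                seed = seed)
  })
  combos$n_kept <- vapply(res, function(x) length(x$kept_locus_ids), 0L)
  combos$result <- res
  combos
}

#' LD decay against physical distance
#'
#' Bins all within-chromosome locus pairs by physical distance and reports
#' mean and SD of r² per bin, along with the distance at which the mean r²
#' first falls below half its first-bin value (attribute
#' `half_decay_kb`, the midpoint of that bin; `NA` when no bin decays that
#' far).
#'
#' @param g an imputed [geno_matrix()].
#' @param bin_width_kb,max_dist_kb bin width and maximum pair distance (kb).
#' @return tibble with `bin_start_kb`, `bin_end_kb`, `mean_r2`, `sd_r2`,
#'   `n_pairs`; class `ld_decay`.
#' @export
ld_decay_curve <- function(g, bin_width_kb = 25, max_dist_kb = 500) {
  pairs <- lapply(unique(g$loci$chrom), function(ch) {
    idx <- which(g$loci$chrom == ch)
    if (length(idx) < 2) return(NULL)
    ld <- pairwise_r2(g, ch)
    pos <- g$loci$pos_bp[idx] / 1000
    dmat <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(dmat)
    ok <- ut & dmat <= max_dist_kb
    if (!any(ok)) return(NULL)
    tibble(dist_kb = dmat[ok], r2 = ld$r2[ok])
  })
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0) {
    warn("no locus pairs within `max_dist_kb`; empty decay curve")
    out <- tibble(bin_start_kb = numeric(), bin_end_kb = numeric(),
                  mean_r2 = numeric(), sd_r2 = numeric(), n_pairs = integer())
    attr(out, "half_decay_kb") <- NA_real_
    class(out) <- c("ld_decay", class(out))
    return(out)
  }
  bin <- pmin(floor(pairs$dist_kb / bin_width_kb),
              ceiling(max_dist_kb / bin_width_kb) - 1)
  out <- pairs |>
    dplyr::mutate(bin = bin) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), sd_r2 = sd(.data$r2),
                     n_pairs = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(bin_start_kb = .data$bin * bin_width_kb,
                  bin_end_kb = (.data$bin + 1) * bin_width_kb) |>
    dplyr::select("bin_start_kb", "bin_end_kb", "mean_r2", "sd_r2", "n_pairs")
  half <- out$mean_r2[1] / 2
  below <- which(out$mean_r2 < half)
  attr(out, "half_decay_kb") <- if (length(below)) {
    (out$bin_start_kb[below[1]] + out$bin_end_kb[below[1]]) / 2
  } else {
    NA_real_
  }
  class(out) <- c("ld_decay", class(out))
  out
}
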