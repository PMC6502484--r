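#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_boxplot labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot an LD decay curve
#'
#' @param object an `ld_decay` from [ld_decay_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ld_decay
#' @export
autoplot.ld_decay <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$bin_start_kb + df$bin_end_kb) / 2
  ggplot(df, aes(x = .data$mid, y = .data$mean_r2)) +
    geom_ribbon(aes(ymin = pmax(.data$mean_r2 - .data$sd_r2, 0),
                    ymax = .data$mean_r2 + .data$sd_r2), alpha = 0.2) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "distance (kb)", y = expression(mean ~ r^2),
         title = "LD decay") +
    theme_minimal()
}

#' Manhattan-style plot of a GWAS scan
#'
#' @param object a `gs_gwas` from [mlm_gwas()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot gs_gwas
#' @export
autoplot.gs_gwas <- function(object, ...) {
  df <- as_tibble(object)
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))
  ggplot(df, aes(x = .data$pos_bp / 1e6, y = -log10(.data$p_value),
                 colour = .data$chrom)) +
    geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    labs(x = "position (Mb)", y = expression(-log[10](p))) +
    theme_minimal()
}

#' Boxplot of per-replicate predictive abilities
#'
#' @param object a `gs_pa` from [run_cv()], or several row-bound together
#'   (facet columns such as `model`/`scheme` are used if present).
#' @param by optional column name to group boxes by.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot gs_pa
#' @export
autoplot.gs_pa <- function(object, by = NULL, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$r), ]
  xvar <- by %||% "env"
  ggplot(df, aes(x = .data[[xvar]], y = .data$r)) +
    geom_boxplot() +
    labs(x = xvar, y = "predictive ability (r)") +
    theme_minimal()
}
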