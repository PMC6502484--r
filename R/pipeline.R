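#' Run the full genomic-selection pipeline
#'
#' Orchestrates the stages end to end: simulate (or read) genotypes and
#' field books, quality-control and impute the markers, prune by LD,
#' fit the plot-level adjustment model per environment, run the configured
#' cross-validation scenarios and the Fisher-Z ANOVA. Every stage writes
#' its artifact (plain-text CSV/TSV/JSON) under `out_dir` together with a
#' run manifest, and logs its input/output shapes.
#'
#' @param config a nested list, or the path to a YAML file with the same
#'   structure. Recognised blocks: `out_dir`, `seed`, `simulate` (arguments
#'   of [sim_config()]) *or* `input` (`genotypes` = list(path, format),
#'   `fieldbook` = path), `qc` (`max_missing`, `min_maf`, `max_het`,
#'   `impute_method`), `prune` (`r2_max`, `min_maf`, optional `grid` with
#'   `r2_levels`/`maf_levels`), `cv` (`train_frac`, `n_reps`, `iters`,
#'   `burnin`, and a list of `scenarios`, each with the [cv_scenario()]
#'   fields), `anova` (`factors`, `interactions`).
#' @param dry_run if `TRUE`, validate the config, print the stage plan and
#'   write nothing.
#' @return invisibly, a list of artifact paths (empty for a dry run).
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_config("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_pipeline_config(config)

  stages <- c("simulate/read", "qc", "prune", "adjust",
              if (length(cfg$cv$scenarios)) "cv", if (!is.null(cfg$anova)) "anova")
  if (dry_run) {
    inform(paste0("pipeline plan: ", paste(stages, collapse = " -> ")))
    return(invisible(list()))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  log_stage <- function(stage, msg) inform(sprintf("[%s] %s", stage, msg))

  # --- stage 1: data ---------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim <- simulate_trial(do.call(sim_config, cfg$simulate))
    geno_raw <- sim$geno
    fieldbook <- sim$fieldbook
    artifacts$genotypes <- file.path(cfg$out_dir, "genotypes.tsv")
    write_dosage_table(geno_raw, artifacts$genotypes)
    artifacts$fieldbook <- file.path(cfg$out_dir, "fieldbook.csv")
    write.csv(fieldbook, artifacts$fieldbook, row.names = FALSE)
    artifacts$true_bv <- file.path(cfg$out_dir, "true_breeding_values.csv")
    write.csv(data.frame(accession = rownames(sim$truth$true_bv),
                         sim$truth$true_bv, check.names = FALSE),
              artifacts$true_bv, row.names = FALSE)
    log_stage("simulate", sprintf("%d accessions x %d loci; %d field-book rows",
                                  nrow(geno_raw$dosage), ncol(geno_raw$dosage),
                                  nrow(fieldbook)))
  } else {
    geno_raw <- read_genotypes(cfg$input$genotypes$path,
                               cfg$input$genotypes$format %||% "vcf")
    fieldbook <- as_tibble(utils::read.csv(cfg$input$fieldbook))
    log_stage("read", sprintf("%d accessions x %d loci; %d field-book rows",
                              nrow(geno_raw$dosage), ncol(geno_raw$dosage),
                              nrow(fieldbook)))
  }

  # --- stage 2: qc -----------------------------------------------------------
  premiss <- locus_stats(geno_raw)
  geno_f <- filter_loci(geno_raw,
                        max_missing = cfg$qc$max_missing %||% 0.20,
                        min_maf = cfg$qc$min_maf %||% 0.02,
                        max_het = cfg$qc$max_het %||% 0.05)
  geno <- impute_missing(geno_f, method = cfg$qc$impute_method %||% "mean")
  artifacts$qc_stats <- file.path(cfg$out_dir, "locus_stats.csv")
  write.csv(premiss, artifacts$qc_stats, row.names = FALSE)
  log_stage("qc", sprintf("retained %d / %d loci", ncol(geno$dosage),
                          ncol(geno_raw$dosage)))

  # --- stage 3: prune --------------------------------------------------------
  marker_set <- NULL
  if (!is.null(cfg$prune)) {
    if (!is.null(cfg$prune$grid)) {
      grid <- threshold_grid(geno, r2_levels = cfg$prune$grid$r2_levels,
                             maf_levels = cfg$prune$grid$maf_levels,
                             premiss = premiss, seed = cfg$seed)
      artifacts$prune_grid <- file.path(cfg$out_dir, "prune_grid.csv")
      write.csv(grid[, c("r2_max", "min_maf", "n_kept")],
                artifacts$prune_grid, row.names = FALSE)
    }
    pr <- prune_by_ld(geno, r2_max = cfg$prune$r2_max %||% 0.5,
                      min_maf = cfg$prune$min_maf %||% 0.05,
                      premiss = premiss, seed = cfg$seed)
    marker_set <- pr$kept_locus_ids
    artifacts$kept_loci <- file.path(cfg$out_dir, "kept_loci.txt")
    writeLines(marker_set, artifacts$kept_loci)
    log_stage("prune", sprintf("kept %d loci at r2 <= %.2f, MAF >= %.2f",
                               length(marker_set), cfg$prune$r2_max %||% 0.5,
                               cfg$prune$min_maf %||% 0.05))
  }

  # --- stage 4: adjust -------------------------------------------------------
  combos <- unique(fieldbook[, c("env", "trait")])
  fits <- purrr::pmap(combos, function(env, trait) {
    fit_adjustment_model(fieldbook, env, trait)
  })
  y_adj <- dplyr::bind_rows(lapply(fits, adjusted_means))
  varcomp <- dplyr::bind_rows(lapply(fits, glance))
  artifacts$y_adj <- file.path(cfg$out_dir, "adjusted_means.csv")
  write.csv(y_adj, artifacts$y_adj, row.names = FALSE)
  artifacts$varcomp <- file.path(cfg$out_dir, "variance_components.json")
  jsonlite::write_json(varcomp, artifacts$varcomp, digits = NA)
  log_stage("adjust", sprintf("%d env x trait fits; H2 range %.2f-%.2f",
                              nrow(varcomp), min(varcomp$H2), max(varcomp$H2)))

  # --- stage 5: cv -----------------------------------------------------------
  if (length(cfg$cv$scenarios)) {
    traits <- unique(y_adj$trait)
    pa_all <- list()
    for (sc_cfg in cfg$cv$scenarios) {
      sc <- cv_scenario(
        scheme = sc_cfg$scheme, target_env = sc_cfg$target_env,
        helper_envs = sc_cfg$helper_envs %||% character(),
        model = sc_cfg$model,
        marker_mode = sc_cfg$marker_mode %||% "ld_derived",
        marker_set = marker_set, top_k = sc_cfg$top_k,
        k_subpops = sc_cfg$k_subpops %||% 5L)
      for (tr in traits) {
        ya <- y_adj[y_adj$trait == tr, ]
        plan <- make_partitions(sort(unique(ya$accession[ya$env == sc$target_env])),
                                train_frac = cfg$cv$train_frac %||% 0.8,
                                n_reps = sc_cfg$n_reps %||% cfg$cv$n_reps %||% 10L,
                                seed = cfg$seed)
        pa <- run_cv(sc, plan, ya, geno,
                     iters = cfg$cv$iters %||% 1500L,
                     burnin = cfg$cv$burnin %||% 500L)
        pa$trait <- tr
        pa$model <- sc$model
        pa$scheme <- sc$scheme
        pa$marker_mode <- sc$marker_mode
        pa_all <- c(pa_all, list(as_tibble(pa)))
        log_stage("cv", sprintf("%s %s %s %s: mean r = %.3f",
                                tr, sc$model, sc$scheme, sc$target_env,
                                mean(pa$r, na.rm = TRUE)))
      }
    }
    pa_tbl <- dplyr::bind_rows(pa_all)
    artifacts$cv_results <- file.path(cfg$out_dir, "cv_results.csv")
    write.csv(pa_tbl, artifacts$cv_results, row.names = FALSE)
    summary_tbl <- pa_tbl |>
      dplyr::filter(!is.na(.data$r)) |>
      dplyr::group_by(.data$trait, .data$model, .data$scheme, .data$env,
                      .data$marker_mode) |>
      dplyr::summarise(mean_r = mean(.data$r),
                       se_r = sd(.data$r) / sqrt(dplyr::n()),
                       .groups = "drop")
    artifacts$cv_summary <- file.path(cfg$out_dir, "cv_summary.csv")
    write.csv(summary_tbl, artifacts$cv_summary, row.names = FALSE)

    # --- stage 6: anova ------------------------------------------------------
    if (!is.null(cfg$anova)) {
      az <- anova_z(pa_tbl, factors = cfg$anova$factors,
                    interactions = cfg$anova$interactions %||% "none")
      artifacts$anova <- file.path(cfg$out_dir, "anova_z.csv")
      write.csv(az, artifacts$anova, row.names = FALSE)
      log_stage("anova", sprintf("%d terms", nrow(az)))
    }
  }

  manifest <- list(package_version = as.character(utils::packageVersion("gsrice")),
                   seed = cfg$seed, stages = stages,
                   artifacts = lapply(artifacts, basename),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  artifacts$manifest <- file.path(cfg$out_dir, "manifest.json")
  invisible(artifacts)
}

# validate everything up front so all config errors are reported at once
validate_pipeline_config <- function(cfg) {
  errs <- character()
  if (is.null(cfg$out_dir)) errs <- c(errs, "`out_dir` is required")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$simulate) && is.null(cfg$input)) {
    errs <- c(errs, "either `simulate` or `input` must be given")
  }
  if (!is.null(cfg$input)) {
    gp <- cfg$input$genotypes$path
    if (is.null(gp)) {
      errs <- c(errs, "`input$genotypes$path` is required")
    } else if (!file.exists(gp)) {
      errs <- c(errs, sprintf("genotype path does not exist: %s", gp))
    }
    fp <- cfg$input$fieldbook
    if (is.null(fp)) {
      errs <- c(errs, "`input$fieldbook` is required")
    } else if (!file.exists(fp)) {
      errs <- c(errs, sprintf("fieldbook path does not exist: %s", fp))
    }
  }
  for (sc in cfg$cv$scenarios) {
    if (is.null(sc$scheme) || is.null(sc$target_env) || is.null(sc$model)) {
      errs <- c(errs, "every cv scenario needs `scheme`, `target_env` and `model`")
    }
  }
  if (length(errs)) {
    stop_config("invalid pipeline config:\n%s",
                paste(paste0("  - ", errs), collapse = "\n"))
  }
  cfg
}
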