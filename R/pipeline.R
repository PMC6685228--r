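#' Run the full TMB analysis pipeline from a config
#'
#' Orchestrates the stages — synthesize (or load) a cohort, per-sample TMB,
#' per-cancer-type metric reports, outlier-robustness analyses, and the
#' random virtual-panel design experiment — and writes each output as a TSV
#' into `out_dir`. Every output file embeds the master seed and an MD5 hash
#' of the effective config in a leading `#` comment line, and the effective
#' config itself is echoed to `config_echo.yaml`, so a run can be re-executed
#' to byte-identical reports. A stage that fails is logged and skipped;
#' completed outputs are kept.
#'
#' @param config Path to a YAML run config, or an equivalent named list.
#'   Recognized blocks: `synthesize` (with `universe` and `cancer_types`
#'   sub-blocks) or `input` (`maf`, `type_map`, optionally `gene_lengths`);
#'   `panels` (a list of inline panel mappings or paths to panel YAMLs);
#'   `stages` (subset of `tmb`, `metrics`, `robustness`, `design`; default
#'   all applicable); and scalars `seed`, `exome_mb`, `mode`,
#'   `cutpoint_fraction`, `removal_fractions`, plus a `designer` block
#'   (`sizes`, `n_draws`, `target`).
#' @param out_dir Output directory, created if needed.
#' @param seed Optional master seed overriding the config's.
#' @return Invisibly, a named list of the paths written.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML path or a named list")
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) stop("config must provide a master seed")
  if (is.null(cfg$synthesize) && is.null(cfg$input)) {
    stop("config needs either a 'synthesize' or an 'input' block")
  }
  cfg$exome_mb <- cfg$exome_mb %||% 38
  cfg$mode <- cfg$mode %||% "value_transfer"
  cfg$cutpoint_fraction <- cfg$cutpoint_fraction %||% 0.2
  cfg$removal_fractions <- unlist(cfg$removal_fractions %||%
                                    c(0.01, 0.02, 0.03, 0.04, 0.05))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  log <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stamp <- config_stamp(cfg)
  written <- list()
  emit <- function(tbl, name) {
    path <- file.path(out_dir, name)
    writeLines(stamp, path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
    written[[name]] <<- path
    log("wrote ", name, " (", nrow(tbl), " rows)")
    path
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log("stage '", name, "' failed: ", conditionMessage(e))
      NULL
    })
  }

  # --- cohort -------------------------------------------------------------
  gene_lengths <- NULL
  if (!is.null(cfg$synthesize)) {
    uni_spec <- do.call(gene_universe_spec, cfg$synthesize$universe %||% list())
    universe <- generate_gene_universe(uni_spec, seed = cfg$seed)
    specs <- lapply(cfg$synthesize$cancer_types,
                    function(x) do.call(cancer_type_spec, x))
    cohort <- generate_cohort(specs, universe, seed = cfg$seed + 1,
                              exome_mb = cfg$exome_mb)
    if (!is.null(cfg$synthesize$outlier)) {
      ob <- cfg$synthesize$outlier
      for (ct in ob$cancer_types %||% unique(cohort$samples$cancer_type)) {
        cohort <- inject_outlier(cohort, ct, ob$multiplier, universe,
                                 seed = cfg$seed + 2 + match(
                                   ct, unique(cohort$samples$cancer_type)))
      }
    }
    gene_lengths <- universe
    emit(universe, "gene_lengths.tsv")
    log("synthesized cohort: ", nrow(cohort$samples), " samples, ",
        length(specs), " cancer type(s), seed ", cfg$seed)
  } else {
    records <- read_maf(cfg$input$maf)
    type_map <- read_type_map(cfg$input$type_map)
    cohort <- build_cohort(records, type_map,
                           unmapped = cfg$input$unmapped %||% "error")
    if (!is.null(cfg$input$gene_lengths)) {
      gene_lengths <- read_gene_lengths(cfg$input$gene_lengths)
    }
    log("loaded cohort: ", nrow(cohort$samples), " samples")
  }
  for (ct in sort(unique(cohort$samples$cancer_type))) {
    log("  n(", ct, ") = ", sum(cohort$samples$cancer_type == ct))
  }
  emit(cohort$samples[, c("sample", "cancer_type", "n_nonsyn", "n_syn")],
       "tally.tsv")

  panels <- load_config_panels(cfg)
  stages <- cfg$stages %||% c("tmb", "metrics", "robustness", "design")

  # --- stages -------------------------------------------------------------
  tmb_table <- NULL
  if (any(c("tmb", "metrics", "robustness") %in% stages) &&
      length(panels) > 0) {
    tmb_table <- run_stage("tmb", {
      tt <- build_tmb_table(cohort, panels, exome_mb = cfg$exome_mb)
      if ("tmb" %in% stages) emit(tt, "tmb_table.tsv")
      tt
    })
  }
  if ("metrics" %in% stages && !is.null(tmb_table)) {
    run_stage("metrics", {
      log("classification mode: ", cfg$mode, ", cutpoint top ",
          cfg$cutpoint_fraction * 100, "%")
      emit(metric_report(tmb_table, cutpoint_fraction = cfg$cutpoint_fraction,
                         mode = cfg$mode), "metrics.tsv")
    })
  }
  if ("robustness" %in% stages && !is.null(tmb_table)) {
    run_stage("robustness", {
      sweeps <- purrr::map_dfr(panels, function(p) {
        removal_sweep(tmb_table, p$name, fractions = cfg$removal_fractions,
                      cutpoint_fraction = cfg$cutpoint_fraction,
                      mode = cfg$mode)
      })
      emit(sweeps, "removal_sweep.tsv")
      subs <- purrr::map_dfr(panels, function(p) {
        subgroup_correlations(tmb_table, p$name)
      })
      emit(subs, "subgroups.tsv")
    })
  }
  if ("design" %in% stages) {
    run_stage("design", {
      if (is.null(gene_lengths)) {
        stop("design stage needs a gene length table ",
             "(synthesize block or input$gene_lengths)")
      }
      dz <- cfg$designer %||% list()
      design <- minimal_panel_size(
        cohort, gene_lengths,
        sizes = unlist(dz$sizes %||% seq(150, 1000, by = 50)),
        target = dz$target %||% 0.90,
        n_draws = dz$n_draws %||% 1000,
        cutpoint_fraction = cfg$cutpoint_fraction,
        mode = dz$mode %||% "quantile",
        include_synonymous = isTRUE(dz$include_synonymous),
        exome_mb = cfg$exome_mb,
        seed = cfg$seed + 1000)
      emit(design$accuracy, "design_accuracy.tsv")
      emit(design$summary, "design_summary.tsv")
    })
  }

  yaml::write_yaml(cfg, file.path(out_dir, "config_echo.yaml"))
  writeLines(log_lines, log_path)
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_stamp <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  paste0("# tmbpanel seed=", cfg$seed, " config_md5=",
         unname(tools::md5sum(tmp)))
}

load_config_panels <- function(cfg) {
  lapply(cfg$panels %||% list(), function(p) {
    if (is.character(p)) return(load_panel(p))
    genes <- p$genes
    if (is.character(genes) && length(genes) == 1 && file.exists(genes)) {
      genes <- readLines(genes)
      genes <- genes[nzchar(trimws(genes))]
    } else {
      genes <- unlist(genes, use.names = FALSE)
    }
    panel_definition(p$name, genes, p$size_mb, isTRUE(p$include_synonymous))
  })
}

#' Plot the pipeline's report families
#'
#' Cosmetic companions to the TSV reports: per-cancer-type metric bars,
#' removal-sweep trajectories of R-squared versus accuracy, subgroup
#' R-squared bars, and designer accuracy-versus-size curves. Figures carry
#' no information the TSVs do not; they are excluded from numerical testing.
#'
#' @param out_dir A directory written by [run_pipeline()].
#' @param families Report families to plot; any subset of `"metrics"`,
#'   `"removal_sweep"`, `"subgroups"`, `"design"`.
#' @return Invisibly, the figure paths written.
#' @export
plot_reports <- function(out_dir,
                         families = c("metrics", "removal_sweep",
                                      "subgroups", "design")) {
  families <- match.arg(families, several.ok = TRUE)
  sources <- c(metrics = "metrics.tsv", removal_sweep = "removal_sweep.tsv",
               subgroups = "subgroups.tsv", design = "design_accuracy.tsv")
  needed <- sources[families]
  missing <- needed[!file.exists(file.path(out_dir, needed))]
  if (length(missing) > 0) {
    stop("missing report file(s) in ", out_dir, ": ",
         paste(missing, collapse = ", "))
  }
  read_report <- function(name) {
    readr::read_tsv(file.path(out_dir, name), comment = "#",
                    show_col_types = FALSE, progress = FALSE)
  }
  paths <- character()
  save_fig <- function(plot, name, width = 7, height = 5) {
    path <- file.path(out_dir, name)
    ggplot2::ggsave(path, plot, width = width, height = height)
    paths <<- c(paths, path)
  }
  if ("metrics" %in% families) {
    m <- read_report("metrics.tsv") |>
      tidyr::pivot_longer(dplyr::all_of(c("accuracy", "fpr", "fnr")),
                          names_to = "metric", values_to = "value")
    save_fig(
      ggplot2::ggplot(m, ggplot2::aes(x = .data$cancer_type, y = .data$value,
                                      fill = .data$metric)) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::facet_wrap(~panel) +
        ggplot2::labs(x = NULL, y = "proportion of cases",
                      title = "Dichotomous classification per cancer type") +
        ggplot2::theme_minimal(),
      "fig_metrics.pdf")
  }
  if ("removal_sweep" %in% families) {
    s <- read_report("removal_sweep.tsv") |>
      tidyr::pivot_longer(dplyr::all_of(c("r_squared", "accuracy")),
                          names_to = "metric", values_to = "value")
    save_fig(
      ggplot2::ggplot(s, ggplot2::aes(x = .data$removal_fraction,
                                      y = .data$value,
                                      colour = .data$metric)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::facet_grid(panel ~ cancer_type) +
        ggplot2::labs(x = "fraction of top-TMB cases removed", y = NULL,
                      title = "Correlation vs accuracy under outlier removal") +
        ggplot2::theme_minimal(),
      "fig_removal_sweep.pdf")
  }
  if ("subgroups" %in% families) {
    g <- read_report("subgroups.tsv")
    save_fig(
      ggplot2::ggplot(g, ggplot2::aes(x = .data$cancer_type,
                                      y = .data$r_squared,
                                      fill = .data$subgroup)) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::facet_wrap(~panel) +
        ggplot2::labs(x = NULL, y = expression(R^2),
                      title = "Correlation within TMB subgroups") +
        ggplot2::theme_minimal(),
      "fig_subgroups.pdf")
  }
  if ("design" %in% families) {
    d <- read_report("design_accuracy.tsv")
    save_fig(
      ggplot2::ggplot(d, ggplot2::aes(x = .data$size, y = .data$mean_accuracy,
                                      colour = .data$cancer_type)) +
        ggplot2::geom_line() +
        ggplot2::geom_ribbon(ggplot2::aes(
          ymin = .data$mean_accuracy - .data$sd_accuracy,
          ymax = .data$mean_accuracy + .data$sd_accuracy,
          fill = .data$cancer_type), alpha = 0.15, colour = NA) +
        ggplot2::geom_hline(yintercept = 0.9, linetype = "dashed") +
        ggplot2::labs(x = "panel size (genes)", y = "mean accuracy",
                      title = "Random virtual-panel accuracy vs panel size") +
        ggplot2::theme_minimal(),
      "fig_design.pdf")
  }
  invisible(paths)
}
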