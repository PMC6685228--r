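#' Whole-exome TMB per sample
#'
#' WES-based TMB is the count of non-synonymous somatic coding mutations
#' (base substitutions and indels) per megabase of exome; 38 Mb is the
#' conventional whole-exome size. Synonymous mutations never enter the WES
#' gold standard, even when a panel's counting rule includes them; both
#' tallies are kept on the cohort so the choice stays auditable.
#'
#' @param cohort A `tmb_cohort`.
#' @param exome_mb Exome size in megabases; default 38.
#' @return Tibble `sample`, `cancer_type`, `tmb_wes` (Mut/Mb).
#' @export
tmb_wes <- function(cohort, exome_mb = 38) {
  if (!is.numeric(exome_mb) || exome_mb <= 0) stop("exome_mb must be > 0")
  dplyr::transmute(cohort$samples,
                   sample = .data$sample,
                   cancer_type = .data$cancer_type,
                   tmb_wes = .data$n_nonsyn / exome_mb)
}

#' In-silico panel TMB per sample
#'
#' Panel TMB divides the number of somatic mutations falling in the panel's
#' genes (non-synonymous, plus synonymous iff the panel's counting rule says
#' so) by the panel's captured-region size in Mb. Membership is by gene
#' symbol; no interval intersection is attempted.
#'
#' @param cohort A `tmb_cohort`.
#' @param panel A `panel_definition`.
#' @return Tibble `sample`, `tmb_panel` (Mut/Mb), aligned with
#'   `cohort$samples`.
#' @export
tmb_panel <- function(cohort, panel) {
  stopifnot(inherits(panel, "panel_definition"))
  in_panel <- cohort$gene_counts[cohort$gene_counts$gene %in% panel$genes, ,
                                 drop = FALSE]
  hits <- in_panel |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(count = sum(.data$n_nonsyn) +
                       if (panel$include_synonymous) sum(.data$n_syn) else 0L,
                     .groups = "drop")
  counts <- stats::setNames(rep(0, nrow(cohort$samples)),
                            cohort$samples$sample)
  counts[hits$sample] <- hits$count
  tibble::tibble(sample = cohort$samples$sample,
                 tmb_panel = unname(counts) / panel$size_mb)
}

#' Per-sample TMB table across panels
#'
#' One row per sample with the WES TMB and one `tmb_<panel>` column per
#' evaluated panel. TMB values are unrounded Mut/Mb floats; rounding, if
#' any, happens at report time.
#'
#' @param cohort A `tmb_cohort`.
#' @param panels A list of `panel_definition`s (or a single one).
#' @param exome_mb Exome size in megabases; default 38.
#' @return Tibble `sample`, `cancer_type`, `tmb_wes`, `tmb_<name>`...
#' @export
build_tmb_table <- function(cohort, panels, exome_mb = 38) {
  if (inherits(panels, "panel_definition")) panels <- list(panels)
  if (length(panels) == 0) stop("at least one panel is required")
  out <- tmb_wes(cohort, exome_mb)
  for (panel in panels) {
    col <- paste0("tmb_", panel$name)
    out[[col]] <- tmb_panel(cohort, panel)$tmb_panel
  }
  out
}

# Sparse gene x sample count matrices; the fast path for the random-panel
# experiment, where thousands of gene subsets are summed per cohort.
cohort_matrices <- function(cohort, gene_universe = NULL) {
  gc <- cohort$gene_counts
  genes <- if (is.null(gene_universe)) sort(unique(gc$gene)) else gene_universe
  samples <- cohort$samples$sample
  gc <- gc[gc$gene %in% genes, , drop = FALSE]
  i <- match(gc$gene, genes)
  j <- match(gc$sample, samples)
  dims <- c(length(genes), length(samples))
  list(
    nonsyn = Matrix::sparseMatrix(i = i, j = j, x = gc$n_nonsyn, dims = dims,
                                  dimnames = list(genes, samples)),
    syn = Matrix::sparseMatrix(i = i, j = j, x = gc$n_syn, dims = dims,
                               dimnames = list(genes, samples)),
    genes = genes, samples = samples
  )
}
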