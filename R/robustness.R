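#' Successive removal of top-ranked-TMB cases
#'
#' For each cancer type and each removal fraction `f`, the top
#' `floor(f * n)` samples by WES TMB rank (descending, barcode tie-break —
#' the same rank convention as [quantile_cutpoint()], so "top 5%" names the
#' same set everywhere) are dropped and both R-squared and the full
#' agreement metric suite are recomputed on the remainder. The quantile
#' cutpoint is recomputed on the reduced set by default, because "top f%"
#' labels are statements about the analyzed cohort; `freeze_cutpoint = TRUE`
#' keeps the baseline cutpoint for sensitivity analysis. Delta columns
#' compare each row to the no-removal baseline.
#'
#' @param tmb_table Tibble from [build_tmb_table()].
#' @param panel Panel name (one `tmb_<panel>` column).
#' @param fractions Removal fractions in `[0, 0.5)`; default 1% to 5%.
#'   `floor(f * n) = 0` removes nothing and reproduces the baseline.
#' @param cutpoint_fraction Top fraction defining TMB-high; default 0.20.
#' @param mode Classification mode, see [classify_panel()].
#' @param freeze_cutpoint Keep the baseline cutpoint after removal instead of
#'   recomputing it; default `FALSE`.
#' @param min_n Minimum remaining samples; below it the row is emitted with
#'   missing metrics and a warning. Default 10.
#' @return Long tibble: `cancer_type`, `panel`, `removal_fraction`,
#'   `cutpoint_fraction`, `mode`, `n_removed`, `n_remaining`, `r_squared`,
#'   `accuracy`, `fpr`, `fnr`, `ppa`, `npa`, `delta_r_squared`,
#'   `delta_accuracy`. A `removal_fraction = 0` baseline row leads each
#'   cancer type.
#' @export
removal_sweep <- function(tmb_table, panel,
                          fractions = c(0.01, 0.02, 0.03, 0.04, 0.05),
                          cutpoint_fraction = 0.2,
                          mode = c("value_transfer", "quantile"),
                          freeze_cutpoint = FALSE, min_n = 10) {
  mode <- match.arg(mode)
  panel <- resolve_panel_names(tmb_table, panel)
  stopifnot(all(fractions >= 0 & fractions < 0.5))
  fractions <- sort(unique(c(0, fractions)))
  col <- paste0("tmb_", panel)
  purrr::map_dfr(unique(tmb_table$cancer_type), function(ct) {
    sub <- tmb_table[tmb_table$cancer_type == ct, , drop = FALSE]
    base_cut <- quantile_cutpoint(sub$tmb_wes, sub$sample, cutpoint_fraction)
    ord <- order(-sub$tmb_wes, sub$sample)
    rows <- purrr::map_dfr(fractions, function(f) {
      k <- floor(f * nrow(sub))
      kept <- if (k > 0) sub[-ord[seq_len(k)], , drop = FALSE] else sub
      if (nrow(kept) < min_n) {
        warning("removal of top ", f * 100, "% leaves ", nrow(kept),
                " sample(s) in ", ct, "; metrics reported missing",
                call. = FALSE)
        return(tibble::tibble(
          cancer_type = ct, panel = panel, removal_fraction = f,
          cutpoint_fraction = cutpoint_fraction, mode = mode,
          n_removed = k, n_remaining = nrow(kept),
          r_squared = NA_real_, accuracy = NA_real_, fpr = NA_real_,
          fnr = NA_real_, ppa = NA_real_, npa = NA_real_
        ))
      }
      cut <- if (freeze_cutpoint) base_cut else
        quantile_cutpoint(kept$tmb_wes, kept$sample, cutpoint_fraction)
      truth <- if (freeze_cutpoint) {
        kept$tmb_wes > cut$wes_value |
          (kept$tmb_wes == cut$wes_value & kept$sample <= cut$cut_sample)
      } else {
        kept$sample %in% cut$high_samples
      }
      pred <- classify_panel(kept[[col]], kept$sample, cut, mode)
      metrics <- metric_suite(confusion(truth, unname(pred)))
      tibble::tibble(
        cancer_type = ct, panel = panel, removal_fraction = f,
        cutpoint_fraction = cutpoint_fraction, mode = mode,
        n_removed = k, n_remaining = nrow(kept),
        r_squared = suppressWarnings(r_squared(kept$tmb_wes, kept[[col]])),
        accuracy = metrics$accuracy, fpr = metrics$fpr, fnr = metrics$fnr,
        ppa = metrics$ppa, npa = metrics$npa
      )
    })
    base <- rows[rows$removal_fraction == 0, , drop = FALSE]
    rows$delta_r_squared <- rows$r_squared - base$r_squared
    rows$delta_accuracy <- rows$accuracy - base$accuracy
    rows
  })
}

#' Correlation within TMB subgroups
#'
#' Samples of each cancer type are partitioned by WES TMB rank into the top
#' 5% (`floor(0.05 n)` samples), the top 5-20% (the next
#' `floor(0.20 n) - floor(0.05 n)`), and the bottom 80% (the remainder) —
#' disjoint and exhaustive — and R-squared between panel and WES TMB is
#' computed within each subgroup and over all samples. Subgroups with fewer
#' than 3 samples are reported missing.
#'
#' @param tmb_table Tibble from [build_tmb_table()].
#' @param panel Panel name.
#' @return Long tibble: `cancer_type`, `panel`, `subgroup` (one of
#'   `"top_5"`, `"top_5_20"`, `"bottom_80"`, `"all"`), `n`, `r_squared`.
#' @export
subgroup_correlations <- function(tmb_table, panel) {
  panel <- resolve_panel_names(tmb_table, panel)
  col <- paste0("tmb_", panel)
  purrr::map_dfr(unique(tmb_table$cancer_type), function(ct) {
    sub <- tmb_table[tmb_table$cancer_type == ct, , drop = FALSE]
    n <- nrow(sub)
    ord <- order(-sub$tmb_wes, sub$sample)
    k5 <- floor(0.05 * n)
    k20 <- floor(0.20 * n)
    idx <- list(
      top_5 = ord[seq_len(k5)],
      top_5_20 = ord[setdiff(seq_len(k20), seq_len(k5))],
      bottom_80 = ord[setdiff(seq_len(n), seq_len(k20))],
      all = seq_len(n)
    )
    purrr::imap_dfr(idx, function(rows, name) {
      tibble::tibble(
        cancer_type = ct, panel = panel, subgroup = name, n = length(rows),
        r_squared = if (length(rows) < 3) NA_real_ else
          suppressWarnings(r_squared(sub$tmb_wes[rows], sub[[col]][rows]))
      )
    })
  })
}
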