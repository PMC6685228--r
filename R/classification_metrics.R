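#' Per-cancer-type quantile cutpoint on WES TMB
#'
#' "Top f%" is read as a rank statement: samples are sorted by WES TMB
#' descending with deterministic tie-breaking by sample barcode, and the top
#' `k = floor(f * n)` samples (at least 1) are TMB-high by WES truth. The
#' cutpoint value is the WES TMB of the k-th ranked sample. An interpolated
#' percentile is deliberately not used — interpolation schemes differ across
#' software and "top 20%" does not name one.
#'
#' @param values Numeric WES TMB values.
#' @param samples Sample barcodes aligned with `values` (used for the
#'   deterministic tie-break and for the returned high-set).
#' @param fraction Top fraction in (0, 1), e.g. 0.20.
#' @return A `tmb_cutpoint`: list with `fraction`, `k`, `wes_value`,
#'   `high_samples`, `n`.
#' @export
quantile_cutpoint <- function(values, samples, fraction) {
  n <- length(values)
  if (n < 2) stop("need at least 2 samples to place a cutpoint")
  if (length(samples) != n) stop("values and samples must align")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must lie in (0, 1)")
  }
  if (length(unique(values)) == 1) {
    warning("all TMB values identical; high set resolved by barcode order",
            call. = FALSE)
  }
  ord <- order(-values, samples)
  k <- max(1L, floor(fraction * n))
  structure(
    list(fraction = fraction, k = k, wes_value = values[ord[k]],
         cut_sample = samples[ord[k]],
         high_samples = samples[ord[seq_len(k)]], n = n),
    class = "tmb_cutpoint"
  )
}

#' Dichotomize panel TMB against a cutpoint
#'
#' Two candidate rules are implemented because the thresholding of the
#' panel-side TMB is a genuine modelling choice:
#' * `value_transfer` (default): a sample is predicted TMB-high iff its panel
#'   TMB is at or above the WES-derived cutpoint value. This reproduces the
#'   false-positive asymmetry seen when cancer-gene panels overestimate TMB.
#'   A panel TMB exactly equal to the cutpoint value is resolved by the same
#'   barcode order that ranked the cutpoint itself, so the one deterministic
#'   total order (TMB descending, barcode ascending) governs every stage and
#'   a panel identical to WES reproduces the truth labels exactly even when
#'   integer-derived TMB values tie at the threshold.
#' * `quantile`: the sample is predicted high iff it ranks in the top
#'   fraction of panel TMB within the cancer type (same rank rule as
#'   [quantile_cutpoint()]). By construction the predicted and true high sets
#'   have equal size, forcing fp = fn.
#'
#' @param values Numeric panel TMB values.
#' @param samples Sample barcodes aligned with `values`.
#' @param cutpoint A `tmb_cutpoint` from the same cancer type.
#' @param mode `"value_transfer"` or `"quantile"`.
#' @return Named logical vector: `TRUE` = predicted TMB-high.
#' @export
classify_panel <- function(values, samples, cutpoint,
                           mode = c("value_transfer", "quantile")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cutpoint, "tmb_cutpoint"),
            length(values) == length(samples))
  if (mode == "value_transfer") {
    pred <- values > cutpoint$wes_value |
      (values == cutpoint$wes_value & samples <= cutpoint$cut_sample)
  } else {
    ord <- order(-values, samples)
    k <- max(1L, floor(cutpoint$fraction * length(values)))
    pred <- rep(FALSE, length(values))
    pred[ord[seq_len(k)]] <- TRUE
  }
  stats::setNames(pred, samples)
}

#' Confusion counts between WES truth and panel prediction
#'
#' @param truth Logical vector: `TRUE` = TMB-high by WES.
#' @param pred Logical vector aligned by sample: `TRUE` = predicted high.
#' @return List with `tp`, `fp`, `fn`, `tn` (non-negative integers summing
#'   to `length(truth)`).
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("truth and prediction differ in length")
  }
  list(tp = sum(truth & pred), fp = sum(!truth & pred),
       fn = sum(truth & !pred), tn = sum(!truth & !pred))
}

#' Agreement metrics from confusion counts
#'
#' Accuracy is the proportion of correctly classified cases, the false
#' positive rate the proportion misclassified as TMB-high, the false
#' negative rate the proportion misclassified as TMB-low (so accuracy + FPR
#' + FNR = 1). Positive percentage agreement is tp / (tp + fn) and negative
#' percentage agreement tn / (tn + fp); either is reported as `NA` (missing,
#' never 0) when its denominator is empty.
#'
#' @param counts Confusion counts from [confusion()].
#' @return Tibble with columns `n`, `accuracy`, `fpr`, `fnr`, `ppa`, `npa`.
#' @export
metric_suite <- function(counts) {
  n <- counts$tp + counts$fp + counts$fn + counts$tn
  if (n == 0) stop("no classified samples")
  accuracy <- (counts$tp + counts$tn) / n
  fpr <- counts$fp / n
  tibble::tibble(
    n = n,
    accuracy = accuracy,
    fpr = fpr,
    # fn/n written as the complement so accuracy + fpr + fnr is exactly 1
    # in floating point as well as algebraically
    fnr = 1 - (accuracy + fpr),
    ppa = if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn)
          else NA_real_,
    npa = if (counts$tn + counts$fp > 0) counts$tn / (counts$tn + counts$fp)
          else NA_real_
  )
}

#' Squared Pearson correlation of raw TMB values
#'
#' Computed on untransformed Mut/Mb values: the sensitivity of R-squared to
#' ultra-high-TMB outliers — the phenomenon this package interrogates — only
#' exists on the raw scale. Returns `NA` with a warning (instead of halting)
#' when either argument has zero variance.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return The squared Pearson correlation, or `NA`.
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; R-squared undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' Per-cancer-type metric report for one or more panels
#'
#' For every (cancer type, panel) pair: Pearson R-squared between panel and
#' WES TMB, the quantile cutpoint at `cutpoint_fraction`, the panel-side
#' classification under `mode`, and the full agreement metric suite with
#' confusion counts.
#'
#' @param tmb_table Tibble from [build_tmb_table()].
#' @param panels Panel name(s); default: every `tmb_<name>` column present.
#' @param cutpoint_fraction Top fraction defining TMB-high; default 0.20.
#' @param mode Classification mode, see [classify_panel()].
#' @return Tibble, one row per (cancer_type, panel): `cancer_type`, `panel`,
#'   `n`, `cutpoint_fraction`, `cutpoint_value`, `mode`, `r_squared`,
#'   `accuracy`, `fpr`, `fnr`, `ppa`, `npa`, `tp`, `fp`, `fn`, `tn`.
#' @export
metric_report <- function(tmb_table, panels = NULL, cutpoint_fraction = 0.2,
                          mode = c("value_transfer", "quantile")) {
  mode <- match.arg(mode)
  panels <- resolve_panel_names(tmb_table, panels)
  grid <- expand.grid(cancer_type = unique(tmb_table$cancer_type),
                      panel = panels, stringsAsFactors = FALSE)
  purrr::pmap_dfr(grid, function(cancer_type, panel) {
    sub <- tmb_table[tmb_table$cancer_type == cancer_type, , drop = FALSE]
    single_report(sub, panel, cutpoint_fraction, mode)
  })
}

single_report <- function(sub, panel, cutpoint_fraction, mode) {
  col <- paste0("tmb_", panel)
  if (!col %in% names(sub)) stop("TMB table has no column ", col)
  cut <- quantile_cutpoint(sub$tmb_wes, sub$sample, cutpoint_fraction)
  truth <- sub$sample %in% cut$high_samples
  pred <- classify_panel(sub[[col]], sub$sample, cut, mode)
  cc <- confusion(truth, unname(pred))
  metrics <- metric_suite(cc)
  tibble::tibble(
    cancer_type = sub$cancer_type[1], panel = panel, n = metrics$n,
    cutpoint_fraction = cutpoint_fraction, cutpoint_value = cut$wes_value,
    mode = mode,
    r_squared = suppressWarnings(r_squared(sub$tmb_wes, sub[[col]])),
    accuracy = metrics$accuracy, fpr = metrics$fpr, fnr = metrics$fnr,
    ppa = metrics$ppa, npa = metrics$npa,
    tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn
  )
}

resolve_panel_names <- function(tmb_table, panels) {
  available <- sub("^tmb_", "", grep("^tmb_", names(tmb_table), value = TRUE))
  available <- setdiff(available, "wes")
  if (is.null(panels)) {
    if (length(available) == 0) stop("TMB table has no panel columns")
    return(available)
  }
  missing <- setdiff(panels, available)
  if (length(missing) > 0) {
    stop("TMB table has no column for panel(s): ",
         paste(missing, collapse = ", "))
  }
  panels
}
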