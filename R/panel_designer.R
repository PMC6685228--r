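#' Accuracy of random virtual panels of a fixed gene count
#'
#' Draws `n_draws` panels of `size` genes uniformly without replacement from
#' the gene universe of the length table, builds each as a virtual panel
#' (captured Mb from summed coding lengths), computes per-cancer-type
#' accuracy at the stated quantile cutpoint, and summarises the draws. Each
#' draw re-seeds from `seed + draw index`, so results are deterministic for
#' a given seed and independent of how draws are batched.
#'
#' @param cohort A `tmb_cohort`.
#' @param gene_lengths Length table (tibble `gene`, `coding_length_bases` or
#'   named numeric vector); its genes are the sampling universe.
#' @param size Panel gene count (<= universe size).
#' @param n_draws Number of random panels; default 1000.
#' @param cutpoint_fraction Top fraction defining TMB-high; default 0.20.
#' @param mode Classification mode, see [classify_panel()]. The designer
#'   defaults to `"quantile"`: a random in-silico panel carries no externally
#'   calibrated threshold to transfer, and rank-based dichotomization is free
#'   of the value-quantization artifact of very small panels, whose TMB scale
#'   is so granular (one captured mutation can exceed the transferred
#'   threshold) that value-transfer accuracy is not even approximately
#'   monotone in panel size.
#' @param include_synonymous Counting rule for the virtual panels; default
#'   `FALSE`.
#' @param exome_mb Exome size for the WES reference; default 38.
#' @param seed Integer seed.
#' @return Tibble `cancer_type`, `size`, `n_draws`, `mean_accuracy`,
#'   `sd_accuracy`.
#' @export
random_panel_accuracy <- function(cohort, gene_lengths, size, n_draws = 1000,
                                  cutpoint_fraction = 0.2,
                                  mode = c("quantile", "value_transfer"),
                                  include_synonymous = FALSE, exome_mb = 38,
                                  seed = 1) {
  mode <- match.arg(mode)
  lengths <- as_length_vector(gene_lengths)
  ctx <- designer_context(cohort, lengths, cutpoint_fraction, exome_mb)
  acc <- draw_accuracies(ctx, size, n_draws, mode, include_synonymous, seed)
  tibble::tibble(
    cancer_type = ctx$types,
    size = size,
    n_draws = n_draws,
    mean_accuracy = colMeans(acc),
    sd_accuracy = apply(acc, 2, stats::sd)
  )
}

#' Minimal panel size per cancer type for a target mean accuracy
#'
#' Grid search over panel sizes (the paper-style design grid spans 150 to
#' 1000 genes): for each size, `n_draws` random panels are scored and the
#' minimal size is the first grid point whose mean accuracy reaches
#' `target`. Cancer types never reaching the target are truncated at the
#' largest grid size and flagged `reached = FALSE`. A grid with
#' first-crossing is used rather than bisection because accuracy is a
#' stochastic, only approximately monotone function of size.
#'
#' @inheritParams random_panel_accuracy
#' @param sizes Ascending gene-count grid; default `seq(150, 1000, 50)`.
#' @param target Target mean accuracy; default 0.90.
#' @return A `tmb_design` list: `accuracy` (tibble `cancer_type`, `size`,
#'   `n_draws`, `mean_accuracy`, `sd_accuracy`) and `summary` (tibble
#'   `cancer_type`, `minimal_size`, `reached`, `target`).
#' @export
minimal_panel_size <- function(cohort, gene_lengths,
                               sizes = seq(150, 1000, by = 50),
                               target = 0.90, n_draws = 1000,
                               cutpoint_fraction = 0.2,
                               mode = c("quantile", "value_transfer"),
                               include_synonymous = FALSE, exome_mb = 38,
                               seed = 1) {
  mode <- match.arg(mode)
  if (length(sizes) == 0) stop("sizes grid is empty")
  if (is.unsorted(sizes, strictly = TRUE)) {
    stop("sizes must be strictly ascending")
  }
  lengths <- as_length_vector(gene_lengths)
  ctx <- designer_context(cohort, lengths, cutpoint_fraction, exome_mb)
  accuracy <- purrr::imap_dfr(sizes, function(size, i) {
    acc <- draw_accuracies(ctx, size, n_draws, mode, include_synonymous,
                           seed + (i - 1) * (n_draws + 1))
    tibble::tibble(cancer_type = ctx$types, size = size, n_draws = n_draws,
                   mean_accuracy = colMeans(acc),
                   sd_accuracy = apply(acc, 2, stats::sd))
  })
  summary <- accuracy |>
    dplyr::group_by(.data$cancer_type) |>
    dplyr::arrange(.data$size, .by_group = TRUE) |>
    dplyr::summarise(
      minimal_size = if (any(.data$mean_accuracy >= target))
        .data$size[which(.data$mean_accuracy >= target)[1]] else max(.data$size),
      reached = any(.data$mean_accuracy >= target),
      .groups = "drop"
    ) |>
    dplyr::mutate(target = target)
  structure(list(accuracy = accuracy, summary = summary),
            class = "tmb_design")
}

#' @export
print.tmb_design <- function(x, ...) {
  cat("<tmb_design> grid of", length(unique(x$accuracy$size)),
      "panel sizes over", nrow(x$summary), "cancer type(s)\n")
  print(x$summary)
  invisible(x)
}

# Precompute everything draw-independent: sparse count matrices over the
# sampling universe, WES truth labels and cutpoint values per cancer type.
designer_context <- function(cohort, lengths, cutpoint_fraction, exome_mb) {
  universe <- names(lengths)
  mats <- cohort_matrices(cohort, gene_universe = universe)
  wes <- cohort$samples$n_nonsyn / exome_mb
  samples <- cohort$samples$sample
  types <- sort(unique(cohort$samples$cancer_type))
  per_type <- lapply(types, function(ct) {
    idx <- which(cohort$samples$cancer_type == ct)
    cut <- quantile_cutpoint(wes[idx], samples[idx], cutpoint_fraction)
    list(idx = idx, cutval = cut$wes_value, cut_sample = cut$cut_sample,
         truth = samples[idx] %in% cut$high_samples,
         fraction = cutpoint_fraction)
  })
  list(mats = mats, lengths = lengths, universe = universe,
       samples = samples, types = types, per_type = per_type)
}

draw_accuracies <- function(ctx, size, n_draws, mode, include_synonymous,
                            seed) {
  n_genes <- length(ctx$universe)
  if (size > n_genes) {
    stop("panel size ", size, " exceeds the gene universe (", n_genes, ")")
  }
  if (n_draws < 1) stop("n_draws must be >= 1")
  acc <- matrix(NA_real_, nrow = n_draws, ncol = length(ctx$types))
  for (d in seq_len(n_draws)) {
    set.seed((seed + d) %% .Machine$integer.max)
    idx_g <- sample.int(n_genes, size)
    size_mb <- sum(ctx$lengths[idx_g]) / 1e6
    counts <- Matrix::colSums(ctx$mats$nonsyn[idx_g, , drop = FALSE])
    if (include_synonymous) {
      counts <- counts + Matrix::colSums(ctx$mats$syn[idx_g, , drop = FALSE])
    }
    tmbv <- counts / size_mb
    for (t in seq_along(ctx$types)) {
      pt <- ctx$per_type[[t]]
      if (mode == "value_transfer") {
        v <- tmbv[pt$idx]
        pred <- v > pt$cutval |
          (v == pt$cutval & ctx$samples[pt$idx] <= pt$cut_sample)
      } else {
        ord <- order(-tmbv[pt$idx], ctx$samples[pt$idx])
        k <- max(1L, floor(pt$fraction * length(pt$idx)))
        pred <- rep(FALSE, length(pt$idx))
        pred[ord[seq_len(k)]] <- TRUE
      }
      acc[d, t] <- mean(pred == pt$truth)
    }
  }
  acc
}
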