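#' Specification of one synthetic cancer type
#'
#' The generator models each cancer type's WES TMB as a right-skewed
#' log-normal body plus a small multiplicative "hypermutator" tail: with
#' probability `hyper_fraction` a sample's TMB is scaled by
#' `hyper_multiplier`, emulating the relatively ultra-high-TMB cases (POLE /
#' MSI-like biology) present in most cancer types, the very outliers that
#' inflate Pearson correlation.
#'
#' @param code Cancer-type study code (e.g. `"PAAD"`).
#' @param n_samples Number of samples (>= 10).
#' @param tmb_log_mean,tmb_log_sd Log-scale mean and sd (> 0) of the
#'   log-normal TMB body, in Mut/Mb.
#' @param hyper_fraction Fraction of hypermutator samples in `[0, 0.1]`.
#' @param hyper_multiplier TMB scaling factor for hypermutators (> 5).
#' @param syn_ratio Expected synonymous:nonsynonymous count ratio (>= 0).
#' @return A `cancer_type_spec` list.
#' @export
cancer_type_spec <- function(code, n_samples, tmb_log_mean, tmb_log_sd,
                             hyper_fraction = 0.02, hyper_multiplier = 20,
                             syn_ratio = 0.45) {
  stopifnot(is.character(code), nzchar(code))
  if (n_samples < 10) stop("n_samples must be >= 10")
  if (tmb_log_sd <= 0) stop("tmb_log_sd must be > 0")
  if (hyper_fraction < 0 || hyper_fraction > 0.1) {
    stop("hyper_fraction must lie in [0, 0.1]")
  }
  if (hyper_multiplier <= 5) stop("hyper_multiplier must be > 5")
  if (syn_ratio < 0) stop("syn_ratio must be >= 0")
  structure(
    list(code = code, n_samples = as.integer(n_samples),
         tmb_log_mean = tmb_log_mean, tmb_log_sd = tmb_log_sd,
         hyper_fraction = hyper_fraction, hyper_multiplier = hyper_multiplier,
         syn_ratio = syn_ratio),
    class = "cancer_type_spec"
  )
}

#' Specification of a synthetic gene universe
#'
#' Coding lengths are drawn log-normally (human CDS lengths are right-skewed
#' around 1.5-2 kb). The defaults — 20,000 genes averaging about 1.9 kb —
#' make the universe's summed coding length come out near the 38 Mb exome,
#' so that mutations spread over the whole universe reproduce exome-wide
#' mutation density and a random sub-panel's TMB is an approximately
#' unbiased estimate of WES TMB. A configurable fraction of "hotspot" genes
#' receives an elevated per-base mutation rate, emulating the cancer-gene
#' enrichment bias through which real targeted panels overestimate TMB — the
#' mechanism behind false-positive-dominated misclassification under
#' value-transfer dichotomization.
#'
#' @param n_genes Number of genes (>= 200).
#' @param length_log_mean,length_log_sd Log-scale parameters of the coding
#'   length distribution (bases).
#' @param hotspot_fraction Fraction of genes flagged as hotspots, in `[0, 1]`.
#' @param hotspot_enrichment Per-base rate multiplier for hotspot genes
#'   (>= 1).
#' @return A `gene_universe_spec` list.
#' @export
gene_universe_spec <- function(n_genes = 20000, length_log_mean = log(1600),
                               length_log_sd = 0.6, hotspot_fraction = 0,
                               hotspot_enrichment = 1) {
  if (n_genes < 200) stop("n_genes must be >= 200")
  if (length_log_sd <= 0) stop("length_log_sd must be > 0")
  if (hotspot_fraction < 0 || hotspot_fraction > 1) {
    stop("hotspot_fraction must lie in [0, 1]")
  }
  if (hotspot_enrichment < 1) stop("hotspot_enrichment must be >= 1")
  structure(
    list(n_genes = as.integer(n_genes), length_log_mean = length_log_mean,
         length_log_sd = length_log_sd, hotspot_fraction = hotspot_fraction,
         hotspot_enrichment = hotspot_enrichment),
    class = "gene_universe_spec"
  )
}

#' Generate a synthetic gene universe
#'
#' @param spec A [gene_universe_spec()].
#' @param seed Integer seed; the result is deterministic given it.
#' @return Tibble `gene` (synthetic symbols `G00001`...),
#'   `coding_length_bases`, `hotspot` (logical), `enrichment` (numeric,
#'   1 for non-hotspot genes).
#' @export
generate_gene_universe <- function(spec, seed) {
  stopifnot(inherits(spec, "gene_universe_spec"))
  set.seed(seed)
  n <- spec$n_genes
  lengths <- pmax(90, round(stats::rlnorm(n, spec$length_log_mean,
                                          spec$length_log_sd)))
  hotspot <- rep(FALSE, n)
  n_hot <- floor(spec$hotspot_fraction * n)
  if (n_hot > 0) hotspot[sample.int(n, n_hot)] <- TRUE
  tibble::tibble(
    gene = sprintf("G%05d", seq_len(n)),
    coding_length_bases = lengths,
    hotspot = hotspot,
    enrichment = ifelse(hotspot, spec$hotspot_enrichment, 1)
  )
}

#' Generate a synthetic multi-cancer cohort
#'
#' Per sample: WES TMB is drawn from the log-normal body, promoted to
#' hypermutator with probability `hyper_fraction` (TMB scaled by
#' `hyper_multiplier`); the non-synonymous count is `round(TMB * exome_mb)`
#' so [tmb_wes()] inverts the generator exactly up to rounding; the
#' synonymous count is Poisson with mean `syn_ratio` times the
#' non-synonymous count; and every mutation is assigned to a gene with
#' probability proportional to coding length times enrichment. The cohort is
#' emitted together with a MAF-style record table (`Missense_Mutation` /
#' `Silent` rows) that round-trips through [read_maf()] and
#' [build_cohort()] to identical tallies.
#'
#' @param specs A [cancer_type_spec()] or list of them.
#' @param universe Gene universe tibble from [generate_gene_universe()].
#' @param seed Integer seed; the cohort is deterministic given it.
#' @param maf_path Optional path: when given, the MAF-style table is also
#'   written there as a TSV.
#' @param exome_mb Exome size used to convert TMB to counts; default 38.
#' @return A `tmb_cohort` with an additional `maf` element (the record
#'   tibble) and a `specs` element retaining the configuration.
#' @export
generate_cohort <- function(specs, universe, seed, maf_path = NULL,
                            exome_mb = 38) {
  if (inherits(specs, "cancer_type_spec")) specs <- list(specs)
  stopifnot(length(specs) > 0,
            all(vapply(specs, inherits, TRUE, "cancer_type_spec")))
  codes <- vapply(specs, `[[`, "", "code")
  if (anyDuplicated(codes) > 0) stop("duplicated cancer-type codes in specs")
  set.seed(seed)
  weights <- universe$coding_length_bases * universe$enrichment
  pieces <- lapply(specs, function(sp) {
    n <- sp$n_samples
    barcodes <- sprintf("%s-S%04d", sp$code, seq_len(n))
    tmb <- stats::rlnorm(n, sp$tmb_log_mean, sp$tmb_log_sd)
    hyper <- stats::runif(n) < sp$hyper_fraction
    tmb[hyper] <- tmb[hyper] * sp$hyper_multiplier
    n_nonsyn <- as.integer(round(tmb * exome_mb))
    n_syn <- as.integer(stats::rpois(n, sp$syn_ratio * n_nonsyn))
    maf <- tibble::tibble(
      gene = universe$gene[c(
        sample.int(nrow(universe), sum(n_nonsyn), replace = TRUE,
                   prob = weights),
        sample.int(nrow(universe), sum(n_syn), replace = TRUE,
                   prob = weights))],
      classification = rep(c("Missense_Mutation", "Silent"),
                           c(sum(n_nonsyn), sum(n_syn))),
      sample = c(rep(barcodes, n_nonsyn), rep(barcodes, n_syn))
    )
    list(samples = tibble::tibble(sample = barcodes, cancer_type = sp$code,
                                  hypermutator = hyper),
         maf = maf)
  })
  maf <- dplyr::bind_rows(lapply(pieces, `[[`, "maf"))
  maf$class <- ifelse(maf$classification == "Silent", "synonymous",
                      "nonsynonymous")
  type_map <- dplyr::bind_rows(lapply(pieces, `[[`, "samples"))
  cohort <- build_cohort(maf, type_map[, c("sample", "cancer_type")])
  cohort$samples <- dplyr::left_join(
    cohort$samples, type_map[, c("sample", "hypermutator")], by = "sample")
  cohort$maf <- maf[, c("gene", "classification", "sample")]
  cohort$specs <- specs
  if (!is.null(maf_path)) write_maf(cohort$maf, maf_path)
  cohort
}

#' Scale one sample's mutation burden to create an outlier
#'
#' Picks one sample of the stated cancer type uniformly at random and
#' multiplies its mutation counts; the added mutations are re-assigned to
#' genes with the universe's length-times-enrichment weights. Emulates a
#' single relatively ultra-hypermutated case, whose presence props up the
#' all-samples Pearson correlation.
#'
#' @param cohort A `tmb_cohort`.
#' @param cancer_type Cancer-type code present in the cohort.
#' @param multiplier Count scaling factor (>= 1); `1` leaves the cohort
#'   unchanged.
#' @param universe Gene universe tibble (weights for the added mutations).
#' @param seed Integer seed.
#' @return The modified `tmb_cohort`; the chosen barcode is recorded in the
#'   `outlier_sample` element.
#' @export
inject_outlier <- function(cohort, cancer_type, multiplier, universe, seed) {
  in_type <- cohort$samples$sample[cohort$samples$cancer_type == cancer_type]
  if (length(in_type) == 0) {
    stop("cancer type not present in cohort: ", cancer_type)
  }
  if (multiplier < 1) stop("multiplier must be >= 1")
  set.seed(seed)
  target <- in_type[sample.int(length(in_type), 1)]
  row <- which(cohort$samples$sample == target)
  add_nonsyn <- as.integer(round(cohort$samples$n_nonsyn[row] * multiplier)) -
    cohort$samples$n_nonsyn[row]
  add_syn <- as.integer(round(cohort$samples$n_syn[row] * multiplier)) -
    cohort$samples$n_syn[row]
  if (add_nonsyn == 0 && add_syn == 0) return(cohort)
  weights <- universe$coding_length_bases * universe$enrichment
  extra <- tibble::tibble(
    gene = universe$gene[sample.int(nrow(universe), add_nonsyn + add_syn,
                                    replace = TRUE, prob = weights)],
    classification = rep(c("Missense_Mutation", "Silent"),
                         c(add_nonsyn, add_syn)),
    sample = target
  )
  extra_counts <- extra |>
    dplyr::count(.data$sample, .data$gene,
                 syn = .data$classification == "Silent") |>
    dplyr::transmute(sample = .data$sample, gene = .data$gene,
                     n_nonsyn = ifelse(.data$syn, 0L, .data$n),
                     n_syn = ifelse(.data$syn, .data$n, 0L))
  cohort$gene_counts <- dplyr::bind_rows(cohort$gene_counts, extra_counts) |>
    dplyr::group_by(.data$sample, .data$gene) |>
    dplyr::summarise(n_nonsyn = as.integer(sum(.data$n_nonsyn)),
                     n_syn = as.integer(sum(.data$n_syn)),
                     .groups = "drop") |>
    dplyr::arrange(.data$sample, .data$gene)
  cohort$samples$n_nonsyn[row] <- cohort$samples$n_nonsyn[row] + add_nonsyn
  cohort$samples$n_syn[row] <- cohort$samples$n_syn[row] + add_syn
  if (!is.null(cohort$maf)) {
    cohort$maf <- dplyr::bind_rows(cohort$maf, extra)
  }
  cohort$outlier_sample <- target
  cohort
}

#' Load cancer-type specs from a YAML file
#'
#' The file holds a list of mappings, each with the fields of
#' [cancer_type_spec()] (`code`, `n_samples`, `tmb_log_mean`, `tmb_log_sd`,
#' and optionally `hyper_fraction`, `hyper_multiplier`, `syn_ratio`).
#'
#' @param path YAML file path.
#' @return List of `cancer_type_spec` objects.
#' @export
read_cohort_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$cancer_types)) raw <- raw$cancer_types
  lapply(raw, function(x) do.call(cancer_type_spec, x))
}
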