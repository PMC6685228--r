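#' Variant classification partition table
#'
#' The mapping from MAF `Variant_Classification` terms to the three counting
#' classes used throughout the package: `nonsynonymous` (missense, nonsense,
#' nonstop, frame-shift and in-frame indels, translation start site, splice
#' site), `synonymous` (silent), and `excluded` (non-coding categories such as
#' UTRs, flanks, introns, RNA and intergenic calls). The default table ships
#' as an editable TSV in `inst/extdata/variant_classes.tsv` so the partition
#' can be audited or overridden; indels sit in the nonsynonymous bucket
#' because the WES TMB definition counts base substitutions and indels alike.
#'
#' @param path Optional path to a two-column TSV (`classification`, `class`)
#'   overriding the packaged default.
#' @return A tibble with columns `classification` and `class`.
#' @export
#' @examples
#' variant_vocabulary()
variant_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "variant_classes.tsv", package = "tmbpanel")
  }
  vocab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  stopifnot(all(c("classification", "class") %in% names(vocab)))
  bad <- setdiff(unique(vocab$class),
                 c("nonsynonymous", "synonymous", "excluded"))
  if (length(bad) > 0) {
    stop("unknown counting class in vocabulary: ", paste(bad, collapse = ", "))
  }
  vocab
}

#' Classify MAF variant classifications into counting classes
#'
#' Deterministic, total mapping of `Variant_Classification` strings to
#' `nonsynonymous`, `synonymous` or `excluded`. Terms absent from the
#' vocabulary are never counted: they map to `excluded` and a warning lists
#' them, so an unrecognized dialect surfaces instead of silently inflating
#' tallies.
#'
#' @param classification Character vector of MAF classification terms.
#' @param vocab Vocabulary tibble, see [variant_vocabulary()].
#' @return Character vector, same length, values in
#'   `c("nonsynonymous", "synonymous", "excluded")`.
#' @export
#' @examples
#' classify_variant(c("Missense_Mutation", "Silent", "3'UTR"))
classify_variant <- function(classification, vocab = variant_vocabulary()) {
  map <- stats::setNames(vocab$class, vocab$classification)
  out <- unname(map[classification])
  unknown <- is.na(out) & !is.na(classification)
  if (any(unknown)) {
    warning("unrecognized Variant_Classification term(s) treated as excluded: ",
            paste(sort(unique(classification[unknown])), collapse = ", "),
            call. = FALSE)
  }
  out[is.na(out)] <- "excluded"
  out
}

#' Read a MAF-style somatic mutation table
#'
#' Reads a tab-separated MAF dialect: `#` comment lines are skipped, a header
#' row is required, and at least `Hugo_Symbol`, `Variant_Classification` and
#' `Tumor_Sample_Barcode` must be present (extra columns are ignored, column
#' order is irrelevant). Classifications are preserved verbatim; a `class`
#' column carries the counting class and `recognized` flags whether the term
#' was in the vocabulary.
#'
#' @param path Path to the MAF-style TSV.
#' @param vocab Vocabulary tibble, see [variant_vocabulary()].
#' @return A tibble of variant records with columns `gene`, `classification`,
#'   `sample`, `class`, `recognized`, one row per MAF data row (no
#'   deduplication).
#' @export
read_maf <- function(path, vocab = variant_vocabulary()) {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  raw <- readr::read_tsv(path, comment = "#",
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("Hugo_Symbol", "Variant_Classification", "Tumor_Sample_Barcode")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("MAF is missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) stop("MAF file has no data rows: ", path)
  cls <- suppressWarnings(classify_variant(raw$Variant_Classification, vocab))
  recognized <- raw$Variant_Classification %in% vocab$classification
  if (any(!recognized)) {
    warning(sum(!recognized), " MAF row(s) carry unrecognized ",
            "Variant_Classification terms; retained but flagged",
            call. = FALSE)
  }
  tibble::tibble(
    gene = raw$Hugo_Symbol,
    classification = raw$Variant_Classification,
    sample = raw$Tumor_Sample_Barcode,
    class = cls,
    recognized = recognized
  )
}

#' Read a sample to cancer-type mapping table
#'
#' @param path Two-column TSV with header `sample`, `cancer_type`.
#' @return A tibble with columns `sample` and `cancer_type`.
#' @export
read_type_map <- function(path) {
  tm <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  missing <- setdiff(c("sample", "cancer_type"), names(tm))
  if (length(missing) > 0) {
    stop("type map is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tm$sample) > 0) {
    stop("type map lists duplicated sample barcode(s): ",
         paste(unique(tm$sample[duplicated(tm$sample)]), collapse = ", "))
  }
  tm[, c("sample", "cancer_type")]
}

#' Assemble a cohort from variant records and a cancer-type map
#'
#' Tallies non-synonymous and synonymous coding mutations per sample and per
#' gene under the [classify_variant()] partition (`excluded` rows contribute
#' nothing). Samples present in the type map but absent from the records are
#' kept with zero counts — a tumor with no called mutations still has TMB 0,
#' and dropping it would bias quantile cutpoints.
#'
#' @param records Variant-record tibble from [read_maf()] (or any tibble with
#'   columns `gene`, `sample` and either `class` or `classification`).
#' @param type_map Tibble with columns `sample`, `cancer_type`.
#' @param unmapped Policy for record samples missing from `type_map`:
#'   `"error"` (default) fails listing the barcodes; `"drop"` removes them
#'   with a warning.
#' @return A `tmb_cohort`: a list with `samples` (tibble `sample`,
#'   `cancer_type`, `n_nonsyn`, `n_syn`) and `gene_counts` (tibble `sample`,
#'   `gene`, `n_nonsyn`, `n_syn`).
#' @export
build_cohort <- function(records, type_map, unmapped = c("error", "drop")) {
  unmapped <- match.arg(unmapped)
  if (!"class" %in% names(records)) {
    records$class <- classify_variant(records$classification)
  }
  stray <- setdiff(unique(records$sample), type_map$sample)
  if (length(stray) > 0) {
    if (unmapped == "error") {
      stop("sample barcode(s) absent from the cancer-type map: ",
           paste(sort(stray), collapse = ", "))
    }
    warning("dropping ", length(stray),
            " sample(s) absent from the cancer-type map", call. = FALSE)
    records <- records[!records$sample %in% stray, , drop = FALSE]
  }
  counted <- records[records$class != "excluded", , drop = FALSE]
  gene_counts <- counted |>
    dplyr::count(.data$sample, .data$gene, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (col in c("nonsynonymous", "synonymous")) {
    if (!col %in% names(gene_counts)) gene_counts[[col]] <- 0L
  }
  gene_counts <- gene_counts |>
    dplyr::transmute(sample = .data$sample, gene = .data$gene,
                     n_nonsyn = as.integer(.data$nonsynonymous),
                     n_syn = as.integer(.data$synonymous)) |>
    dplyr::arrange(.data$sample, .data$gene)
  samples <- gene_counts |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_nonsyn = sum(.data$n_nonsyn),
                     n_syn = sum(.data$n_syn), .groups = "drop")
  samples <- type_map |>
    dplyr::left_join(samples, by = "sample") |>
    dplyr::mutate(n_nonsyn = as.integer(dplyr::coalesce(.data$n_nonsyn, 0L)),
                  n_syn = as.integer(dplyr::coalesce(.data$n_syn, 0L))) |>
    dplyr::arrange(.data$sample)
  new_tmb_cohort(samples, gene_counts)
}

new_tmb_cohort <- function(samples, gene_counts, maf = NULL) {
  stopifnot(anyDuplicated(samples$sample) == 0)
  out <- list(samples = samples, gene_counts = gene_counts)
  if (!is.null(maf)) out$maf <- maf
  structure(out, class = "tmb_cohort")
}

#' @export
print.tmb_cohort <- function(x, ...) {
  cat("<tmb_cohort> ", nrow(x$samples), " samples, ",
      length(unique(x$samples$cancer_type)), " cancer type(s), ",
      sum(x$samples$n_nonsyn), " nonsynonymous / ",
      sum(x$samples$n_syn), " synonymous mutations\n", sep = "")
  invisible(x)
}

#' Write / read the per-sample tally table
#'
#' The tally table (`sample`, `cancer_type`, `n_nonsyn`, `n_syn`) is the
#' cohort's sample-level summary; writing and re-reading it reproduces the
#' counts exactly.
#'
#' @param cohort A `tmb_cohort`.
#' @param path Output TSV path.
#' @return `write_tally_table()` returns `path` invisibly;
#'   `read_tally_table()` returns the tally tibble.
#' @export
write_tally_table <- function(cohort, path) {
  readr::write_tsv(
    cohort$samples[, c("sample", "cancer_type", "n_nonsyn", "n_syn")],
    path, progress = FALSE)
  invisible(path)
}

#' @rdname write_tally_table
#' @export
read_tally_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample = "c", cancer_type = "c", n_nonsyn = "i", n_syn = "i"
  ), progress = FALSE)
}

#' Write a variant-record table as a MAF-style TSV
#'
#' @param records Tibble with columns `gene`, `classification`, `sample`.
#' @param path Output path.
#' @export
write_maf <- function(records, path) {
  out <- tibble::tibble(
    Hugo_Symbol = records$gene,
    Variant_Classification = records$classification,
    Tumor_Sample_Barcode = records$sample
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
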