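# Programmatic fixtures shared across the suite. Everything is generated at
# test time; nothing binary is stored.

# Write a MAF-style TSV and return its path.
write_fixture_maf <- function(rows, path = tempfile(fileext = ".maf"),
                              comments = character()) {
  header <- "Hugo_Symbol\tVariant_Classification\tTumor_Sample_Barcode"
  writeLines(c(comments, header, rows), path)
  path
}

maf_row <- function(gene, classification, sample) {
  paste(gene, classification, sample, sep = "\t")
}

# A cohort built by hand (not via the generator): counts are explicit so
# oracles can recount them independently.
manual_cohort <- function(counts) {
  # counts: data.frame sample, cancer_type, gene, n_nonsyn, n_syn
  gene_counts <- tibble::as_tibble(counts[order(counts$sample, counts$gene),
                                          c("sample", "gene", "n_nonsyn", "n_syn")])
  samples <- tibble::as_tibble(unique(counts[, c("sample", "cancer_type")]))
  agg_ns <- tapply(counts$n_nonsyn, counts$sample, sum)
  agg_s <- tapply(counts$n_syn, counts$sample, sum)
  samples$n_nonsyn <- as.integer(agg_ns[samples$sample])
  samples$n_syn <- as.integer(agg_s[samples$sample])
  samples <- samples[order(samples$sample), ]
  tmbpanel:::new_tmb_cohort(samples, gene_counts)
}

# Small calibrated universe + two-type cohort used by several suites.
small_universe <- function(seed = 7, n_genes = 2000) {
  generate_gene_universe(gene_universe_spec(n_genes = n_genes), seed = seed)
}

two_type_cohort <- function(universe, seed = 11, n = 60) {
  specs <- list(
    cancer_type_spec("AA", n, tmb_log_mean = log(2), tmb_log_sd = 0.5,
                     hyper_fraction = 0),
    cancer_type_spec("BB", n, tmb_log_mean = log(8), tmb_log_sd = 0.5,
                     hyper_fraction = 0)
  )
  generate_cohort(specs, universe, seed = seed)
}

# Ten seeded replicate cohorts with a weakly concordant random panel and one
# injected extreme outlier each; cached so multiple test blocks share one
# computation.
.outlier_cache <- new.env(parent = emptyenv())
outlier_replicates <- function(n_reps = 10) {
  key <- paste0("reps", n_reps)
  if (!is.null(.outlier_cache[[key]])) return(.outlier_cache[[key]])
  universe <- generate_gene_universe(gene_universe_spec(), seed = 2024)
  reps <- lapply(seq_len(n_reps), function(r) {
    spec <- cancer_type_spec("SYN", 150, tmb_log_mean = log(2),
                             tmb_log_sd = 0.5, hyper_fraction = 0)
    cohort <- generate_cohort(spec, universe, seed = 100 + r)
    wes <- cohort$samples$n_nonsyn / 38
    # scale so the injected case lands >= 20x the cohort maximum whichever
    # sample is chosen
    mult <- ceiling(25 * max(wes) / max(min(wes), 1 / 38))
    cohort <- inject_outlier(cohort, "SYN", mult, universe, seed = 500 + r)
    set.seed(900 + r)
    panel <- make_virtual_panel(sample(universe$gene, 300), universe,
                                name = "rand300")
    build_tmb_table(cohort, panel)
  })
  .outlier_cache[[key]] <- reps
  reps
}
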