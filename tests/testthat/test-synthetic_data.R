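test_that("gene universe generation is deterministic and honours its spec", {
  spec <- gene_universe_spec(n_genes = 500, hotspot_fraction = 0.1,
                             hotspot_enrichment = 4)
  a <- generate_gene_universe(spec, seed = 6)
  b <- generate_gene_universe(spec, seed = 6)
  expect_identical(a, b)
  expect_equal(nrow(a), 500)
  expect_equal(sum(a$hotspot), 50)
  expect_true(all(a$enrichment[a$hotspot] == 4))
  expect_true(all(a$enrichment[!a$hotspot] == 1))

  no_hot <- generate_gene_universe(gene_universe_spec(n_genes = 500), 6)
  expect_true(all(no_hot$enrichment == 1))
  expect_error(gene_universe_spec(n_genes = 50), ">= 200")
  expect_error(gene_universe_spec(hotspot_enrichment = 0.5), ">= 1")
})

test_that("empirical mean coding length matches the configured distribution", {
  mu <- log(1500); sdl <- 0.5
  uni <- generate_gene_universe(
    gene_universe_spec(n_genes = 5000, length_log_mean = mu,
                       length_log_sd = sdl), seed = 17)
  expected_mean <- exp(mu + sdl^2 / 2)                 # log-normal closed form
  expected_sd <- expected_mean * sqrt(exp(sdl^2) - 1)
  se <- expected_sd / sqrt(5000)
  expect_lt(abs(mean(uni$coding_length_bases) - expected_mean), 3 * se)
})

test_that("cohort generation is deterministic and conserves counts", {
  uni <- small_universe(n_genes = 400)
  spec <- cancer_type_spec("AA", 30, log(2), 0.5)
  a <- generate_cohort(spec, uni, seed = 9)
  b <- generate_cohort(spec, uni, seed = 9)
  expect_identical(a$samples, b$samples)
  expect_identical(a$gene_counts, b$gene_counts)
  c <- generate_cohort(spec, uni, seed = 10)
  expect_false(identical(a$samples$n_nonsyn, c$samples$n_nonsyn))

  # conservation: per-gene counts sum to the drawn per-sample totals
  by_sample_ns <- tapply(a$gene_counts$n_nonsyn, a$gene_counts$sample, sum)
  by_sample_s <- tapply(a$gene_counts$n_syn, a$gene_counts$sample, sum)
  expect_equal(as.vector(by_sample_ns[a$samples$sample]),
               a$samples$n_nonsyn)
  expect_equal(as.vector(by_sample_s[a$samples$sample]), a$samples$n_syn)
})

test_that("a narrow body recovers its configured median TMB", {
  uni <- small_universe(n_genes = 400)
  cohort <- generate_cohort(
    cancer_type_spec("AA", 2000, tmb_log_mean = log(1.0), tmb_log_sd = 0.2,
                     hyper_fraction = 0),
    uni, seed = 23)
  med <- median(cohort$samples$n_nonsyn / 38)
  # log-normal median exp(mu) = 1.0; allow Monte-Carlo + count-rounding slack
  expect_lt(abs(med - 1.0), 0.05)
})

test_that("generated MAF files round-trip to identical tallies", {
  uni <- small_universe(n_genes = 400)
  path <- tempfile(fileext = ".maf")
  cohort <- generate_cohort(cancer_type_spec("AA", 20, log(2), 0.5), uni,
                            seed = 31, maf_path = path)
  reread <- build_cohort(read_maf(path),
                         cohort$samples[, c("sample", "cancer_type")])
  expect_equal(reread$samples$n_nonsyn, cohort$samples$n_nonsyn)
  expect_equal(reread$samples$n_syn, cohort$samples$n_syn)
  expect_equal(reread$gene_counts, cohort$gene_counts)
})

test_that("log-TMB parameters and hypermutator fraction are recoverable", {
  uni <- small_universe(n_genes = 400)
  mu <- log(3); sdl <- 0.5; hf <- 0.03
  cohort <- generate_cohort(
    cancer_type_spec("AA", 2000, mu, sdl, hyper_fraction = hf,
                     hyper_multiplier = 30),
    uni, seed = 41)
  body <- cohort$samples[!cohort$samples$hypermutator, ]
  log_tmb <- log(body$n_nonsyn / 38)
  n <- nrow(body)
  expect_lt(abs(mean(log_tmb) - mu), 3 * sdl / sqrt(n))
  expect_lt(abs(sd(log_tmb) - sdl), 3 * sdl / sqrt(2 * n))
  expect_lt(abs(mean(cohort$samples$hypermutator) - hf),
            3 * sqrt(hf * (1 - hf) / 2000))
})

test_that("outlier injection is deterministic, bounded and directional", {
  uni <- small_universe(n_genes = 400)
  cohort <- generate_cohort(cancer_type_spec("AA", 40, log(2), 0.4), uni,
                            seed = 51)
  a <- inject_outlier(cohort, "AA", 50, uni, seed = 3)
  b <- inject_outlier(cohort, "AA", 50, uni, seed = 3)
  expect_identical(a$samples, b$samples)
  expect_error(inject_outlier(cohort, "ZZ", 50, uni, seed = 3),
               "not present")
  # multiplier 1 leaves the cohort untouched
  same <- inject_outlier(cohort, "AA", 1, uni, seed = 3)
  expect_identical(same$samples, cohort$samples)

  # downstream direction: the injected case props up the all-samples R^2
  set.seed(4)
  panel <- make_virtual_panel(sample(uni$gene, 40), uni, name = "p")
  tt <- build_tmb_table(a, panel)
  out_sample <- a$outlier_sample
  with_out <- r_squared(tt$tmb_wes, tt$tmb_p)
  without <- r_squared(tt$tmb_wes[tt$sample != out_sample],
                       tt$tmb_p[tt$sample != out_sample])
  expect_gt(with_out, without)
})

test_that("hotspot enrichment makes hotspot panels overestimate TMB", {
  # exome-calibrated universe so the comparison probes the enrichment bias,
  # not a denominator mismatch
  uni <- generate_gene_universe(
    gene_universe_spec(hotspot_fraction = 0.1, hotspot_enrichment = 6),
    seed = 61)
  cohort <- generate_cohort(cancer_type_spec("AA", 80, log(3), 0.4), uni,
                            seed = 62)
  hot_panel <- make_virtual_panel(uni$gene[uni$hotspot], uni, name = "hot")
  tt <- build_tmb_table(cohort, hot_panel)
  expect_gt(mean(tt$tmb_hot), mean(tt$tmb_wes))
})

test_that("spec constructors validate their invariants", {
  expect_error(cancer_type_spec("A", 5, 0, 0.5), "n_samples")
  expect_error(cancer_type_spec("A", 20, 0, 0), "tmb_log_sd")
  expect_error(cancer_type_spec("A", 20, 0, 0.5, hyper_fraction = 0.2),
               "hyper_fraction")
  expect_error(cancer_type_spec("A", 20, 0, 0.5, hyper_multiplier = 2),
               "hyper_multiplier")
  specs <- read_cohort_specs(system.file("extdata", "specs", "paad_like.yaml",
                                         package = "tmbpanel"))
  expect_length(specs, 1)
  expect_equal(specs[[1]]$code, "PAAD")
  expect_equal(specs[[1]]$n_samples, 177L)
})
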