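test_that("quantile cutpoint follows the rank rule with barcode tie-breaks", {
  cut <- quantile_cutpoint(c(5, 4, 3, 2, 1), paste0("S", 1:5), 0.20)
  expect_equal(cut$k, 1L)
  expect_equal(cut$wes_value, 5)
  expect_equal(cut$high_samples, "S1")

  # degenerate all-equal values: resolved by barcode order, with a warning
  expect_warning(
    tied <- quantile_cutpoint(rep(2, 10), paste0("S", sprintf("%02d", 1:10)),
                              0.20),
    "identical")
  expect_equal(tied$k, 2L)
  expect_equal(tied$high_samples, c("S01", "S02"))

  expect_error(quantile_cutpoint(1, "S1", 0.2), "at least 2")
  expect_error(quantile_cutpoint(c(1, 2), c("a", "b"), 1.2), "\\(0, 1\\)")
})

test_that("the top-k high set matches an independent sort-and-slice oracle", {
  set.seed(177)
  n <- 177  # a PAAD-sized cohort
  values <- round(rlnorm(n, 0, 0.6), 4)
  samples <- sprintf("S%03d", sample(n))
  cut <- quantile_cutpoint(values, samples, 0.20)
  expect_equal(cut$k, 35L)  # floor(0.2 * 177)
  oracle <- data.frame(v = values, s = samples)
  oracle <- oracle[order(-oracle$v, oracle$s), ]
  expect_equal(sort(cut$high_samples), sort(oracle$s[1:35]))
  expect_equal(cut$wes_value, oracle$v[35])
})

test_that("panel classification implements both thresholding rules", {
  cut <- quantile_cutpoint(c(9, 5, 1, 0.5), paste0("S", 1:4), 0.25)
  expect_equal(unname(classify_panel(c(10, 0.5), c("S1", "S2"), cut,
                                     "value_transfer")),
               c(TRUE, FALSE))
  # identical panel and WES TMB: predictions equal truth under either mode
  vals <- c(9, 5, 1, 0.5)
  truth <- paste0("S", 1:4) %in% cut$high_samples
  for (mode in c("value_transfer", "quantile")) {
    pred <- classify_panel(vals, paste0("S", 1:4), cut, mode)
    expect_equal(unname(pred), truth, label = mode)
  }
  # quantile mode always predicts floor(f*n) highs, whatever the values
  set.seed(8)
  vals200 <- rlnorm(200)
  cut200 <- quantile_cutpoint(rlnorm(200), sprintf("T%03d", 1:200), 0.20)
  pred200 <- classify_panel(vals200, sprintf("T%03d", 1:200), cut200,
                            "quantile")
  expect_equal(sum(pred200), 40)
})

test_that("confusion counts enumerate all four cells and check alignment", {
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  pred <- c(TRUE, FALSE, TRUE, FALSE)
  cc <- confusion(truth, pred)
  expect_equal(cc, list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  perfect <- confusion(truth, truth)
  expect_equal(perfect$fp + perfect$fn, 0L)
  expect_error(confusion(truth, pred[1:3]), "length")

  # 500 random label pairs vs an independent pairwise count
  set.seed(99)
  t2 <- runif(500) < 0.3
  p2 <- runif(500) < 0.4
  cc2 <- confusion(t2, p2)
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_len(500)) {
    if (t2[i] && p2[i]) tp <- tp + 1L
    else if (!t2[i] && p2[i]) fp <- fp + 1L
    else if (t2[i] && !p2[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  expect_equal(cc2, list(tp = tp, fp = fp, fn = fn, tn = tn))
})

test_that("the agreement metric suite follows its defining formulas", {
  m <- metric_suite(list(tp = 8, fp = 20, fn = 2, tn = 70))
  expect_equal(m$accuracy, 0.78)
  expect_equal(m$fpr, 0.20)
  expect_equal(m$fnr, 0.02)
  expect_equal(m$ppa, 0.80)
  expect_equal(m$npa, 70 / 90)

  perfect <- metric_suite(list(tp = 3, fp = 0, fn = 0, tn = 7))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$ppa, 1)
  expect_equal(perfect$npa, 1)

  # empty positive class: PPA is missing, never coerced to 0
  degenerate <- metric_suite(list(tp = 0, fp = 1, fn = 0, tn = 9))
  expect_true(is.na(degenerate$ppa))
  expect_false(is.na(degenerate$npa))
  expect_error(metric_suite(list(tp = 0, fp = 0, fn = 0, tn = 0)),
               "no classified samples")
})

test_that("R-squared matches the textbook formula and handles degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(r_squared(x, 2 * x + 1), 1.0)
  # independent covariance/variance oracle
  x3 <- c(1, 2, 3); y3 <- c(3, 1, 2)
  cov_xy <- sum((x3 - mean(x3)) * (y3 - mean(y3))) / 2
  oracle <- (cov_xy / (sqrt(sum((x3 - mean(x3))^2) / 2) *
                         sqrt(sum((y3 - mean(y3))^2) / 2)))^2
  expect_equal(r_squared(x3, y3), oracle)
  expect_warning(out <- r_squared(x3, c(2, 2, 2)), "zero variance")
  expect_true(is.na(out))
  expect_error(r_squared(1:2, 1:2), "at least 3")
})

test_that("R-squared is invariant to positive affine transforms", {
  set.seed(12)
  for (i in 1:20) {
    x <- rlnorm(30); y <- x + rnorm(30, sd = 0.3)
    a <- runif(1, 0.1, 5); b <- runif(1, -2, 2)
    expect_equal(r_squared(a * x + b, y), r_squared(x, y))
    expect_equal(r_squared(x, a * y + b), r_squared(x, y))
  }
})

test_that("accuracy + FPR + FNR is exactly 1 and quantile mode forces fp = fn", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    samples <- sprintf("S%03d", 1:n)
    wes <- rlnorm(n)
    panel <- wes * exp(rnorm(n, sd = 0.5))
    cut <- quantile_cutpoint(wes, samples, runif(1, 0.1, 0.5))
    truth <- samples %in% cut$high_samples
    for (mode in c("value_transfer", "quantile")) {
      pred <- classify_panel(panel, samples, cut, mode)
      m <- metric_suite(confusion(truth, unname(pred)))
      expect_identical(m$accuracy + m$fpr + m$fnr, 1)
      if (mode == "quantile") {
        cc <- confusion(truth, unname(pred))
        expect_equal(cc$fp, cc$fn)  # equal-sized predicted and true high sets
      }
    }
  }
})

test_that("metric_report assembles per-cancer-type rows with all fields", {
  universe <- small_universe(n_genes = 500)
  cohort <- two_type_cohort(universe, n = 30)
  pseudo <- panel_definition("exome", universe$gene, 38)
  tt <- build_tmb_table(cohort, pseudo)
  rep <- metric_report(tt, cutpoint_fraction = 0.25)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$accuracy, c(1, 1))
  expect_equal(rep$tp + rep$fp + rep$fn + rep$tn, rep$n)
  expect_equal(rep$cutpoint_fraction, c(0.25, 0.25))
  expect_error(metric_report(tt, panels = "nope"), "nope")
})
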