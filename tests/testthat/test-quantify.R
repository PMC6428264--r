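test_that("peptide_ratio implements both platform conventions", {
  # median over per-transition ratios
  expect_equal(peptide_ratio(c(4, 5, 9), c(10, 10, 10),
                             "median_of_transitions"), 0.5)
  # summed-area ratio
  expect_equal(peptide_ratio(c(100, 300), c(200, 600),
                             "all_product_ions"), 0.5)
  # a zero light ion still counts in the sums
  expect_equal(peptide_ratio(c(100, 0), c(200, 600),
                             "all_product_ions"), 100 / 800)
  # missing pairs are dropped; nothing usable -> NA
  expect_equal(peptide_ratio(c(100, NA), c(200, 600),
                             "all_product_ions"), 0.5)
  expect_true(is.na(peptide_ratio(NA_real_, 200, "all_product_ions")))
  expect_warning(r <- peptide_ratio(10, 0, "all_product_ions"), "heavy")
  expect_true(is.na(r))
  expect_warning(r2 <- peptide_ratio(10, 0, "median_of_transitions"),
                 "heavy")
  expect_true(is.na(r2))
})

test_that("ratio methods agree when transitions share one ratio and obey scale/label symmetry", {
  for (s in 1:20) {
    set.seed(s)
    heavy <- runif(4, 100, 1000)
    r <- runif(1, 0.05, 5)
    light <- heavy * r
    expect_equal(peptide_ratio(light, heavy, "median_of_transitions"),
                 peptide_ratio(light, heavy, "all_product_ions"))
    # scale equivariance in the light channel
    k <- runif(1, 0.1, 10)
    for (m in c("median_of_transitions", "all_product_ions")) {
      expect_equal(peptide_ratio(light * k, heavy, m),
                   k * peptide_ratio(light, heavy, m))
    }
    # label symmetry for a single transition: r -> 1/r
    expect_equal(peptide_ratio(heavy[1], light[1], "median_of_transitions"),
                 1 / peptide_ratio(light[1], heavy[1],
                                   "median_of_transitions"))
  }
})

test_that("ratio-to-concentration conversion uses spike and lysate amounts", {
  expect_equal(peptide_concentration(0.5, 5, 1), 2500)
  expect_equal(peptide_concentration(0, 50, 2), 0)
  expect_equal(peptide_concentration(0.02, 5, 1), 100)
  expect_error(peptide_concentration(0.5, 0, 1), "spike_fmol")
  expect_error(peptide_concentration(0.5, 5, -1), "lysate_ug")
})

test_that("replicate summarization is a robust median with CV", {
  expect_equal(summarize_replicates(c(10, 12, 14))$concentration, 12)
  expect_equal(summarize_replicates(7)$concentration, 7)
  expect_true(is.na(summarize_replicates(7)$cv_pct))
  # median resists a single aberrant replicate (mean would be 74)
  expect_equal(summarize_replicates(c(10, 12, 200))$concentration, 12)
})

test_that("protein roll-up is a median over detected peptides, permutation invariant", {
  r <- rollup_protein(c(90, 100, 110))
  expect_equal(r$concentration, 100)
  expect_equal(r$inter_peptide_cv, 10)
  expect_equal(rollup_protein(50),
               list(concentration = 50, n_peptides_detected = 1L,
                    inter_peptide_cv = NA_real_))
  none <- rollup_protein(c(NA_real_, NA_real_))
  expect_true(is.na(none$concentration))
  expect_equal(none$n_peptides_detected, 0L)
  set.seed(1)
  x <- runif(5, 10, 100)
  expect_equal(rollup_protein(x), rollup_protein(sample(x)))
})

test_that("quantify_samples matches the single-measurement primitives", {
  tr <- dplyr::bind_rows(
    toy_transitions(c(100, 300), c(200, 600), replicate = 1L),
    toy_transitions(c(150, 250), c(250, 550), replicate = 2L)
  )
  sheet <- toy_sample_sheet()
  q <- quantify_samples(tr, sheet, method = "all_product_ions")
  expect_equal(q$peptides$ratio, c(400 / 800, 400 / 800))
  expect_equal(q$peptides$concentration, c(2500, 2500))
  expect_equal(q$matrix$OAT, 2500)
  # median method on the same table
  qm <- quantify_samples(tr, sheet, method = "median_of_transitions")
  expect_equal(qm$peptides$ratio[1], median(c(100 / 200, 300 / 600)))
  # platform default: ffpe -> all_product_ions
  expect_equal(quantify_samples(tr, sheet)$peptides$ratio,
               q$peptides$ratio)
})

test_that("LLOQ gating flags computable-but-censored peptides as not detected", {
  tr <- toy_transitions(c(100, 300), c(200, 600))  # ratio 0.5 -> 2500
  sheet <- toy_sample_sheet()
  q <- quantify_samples(tr, sheet, lloq = c(LVDFSGNR = 5000))
  expect_true(q$peptides$below_lloq)
  expect_false(q$peptides$detected)
  expect_equal(q$peptides$concentration, 2500)  # value kept for audit
  expect_true(is.na(q$matrix$OAT))
  expect_error(quantify_samples(tr, sheet, lloq = c(OTHER = 1)), "lloq")
})

test_that("peptide-consistency QC reports median CV and minimum correlation", {
  # two peptides identical across samples: r = 1, CVs = 0
  tab <- tidyr::expand_grid(sample_id = sprintf("S%d", 1:5),
                            peptide = c("A", "B"))
  tab$protein <- "P"
  tab$concentration <- rep(c(10, 20, 30, 40, 50), each = 2)
  qc <- qc_peptide_consistency(tab)
  expect_equal(qc$min_pairwise_r, 1)
  expect_equal(qc$median_cv_pct, 0)

  # peptide2 = 2 * peptide1: r = 1, per-sample CV = 100*sd(x,2x)/mean
  tab2 <- tab
  tab2$concentration <- ifelse(tab2$peptide == "B",
                               2 * tab2$concentration, tab2$concentration)
  qc2 <- qc_peptide_consistency(tab2)
  expect_equal(qc2$min_pairwise_r, 1)
  expect_equal(qc2$median_cv_pct, 100 * sd(c(1, 2)) / 1.5, tolerance = 1e-12)

  # constant peptide profile: correlation undefined
  tab3 <- tab
  tab3$concentration[tab3$peptide == "B"] <- 7
  expect_true(is.na(qc_peptide_consistency(tab3)$min_pairwise_r))
})

test_that("inter-peptide CV tracks the replicate noise of the generator", {
  # independent simulation oracle for the expected per-sample CV of
  # peptide medians under 10% replicate noise (median-of-3 shrinkage)
  set.seed(42)
  sdlog <- sqrt(log1p(0.1^2))
  sim_cv <- replicate(4000, {
    peps <- apply(matrix(exp(rnorm(9, 0, sdlog)), 3), 2, median)
    100 * sd(peps) / mean(peps)
  })
  oracle <- median(sim_cv)

  co <- generate_cohort(cohort_design(replicate_cv = 0.10, lloq = 1e-6,
                                      seed = 8))
  q <- quantify_samples(co$transitions, co$samples)
  qc <- qc_peptide_consistency(q$peptide_summary)
  med_cv <- median(qc$median_cv_pct[qc$n_peptides == 3])
  expect_lt(abs(med_cv - oracle), 2)
  # and peptide profiles of one protein are strongly correlated
  expect_gte(min(qc$min_pairwise_r), 0.9)
})

test_that("cross-platform correlation fits an OLS line", {
  x <- c(1, 2, 3, 4, 5)
  fit <- correlate_platforms(x, 2 * x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r, 1)
  expect_equal(fit$n, 5)
  expect_error(correlate_platforms(c(1, 2), c(1, 2)), "3")
  expect_error(correlate_platforms(rep(1, 5), x), "constant")
  # permutation null: unrelated vectors decorrelate
  null_ok <- vapply(1:40, function(s) {
    set.seed(s)
    x <- rnorm(100)
    abs(correlate_platforms(x, sample(x))$r) < 0.3
  }, logical(1))
  expect_gte(mean(null_ok), 0.95)
})
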