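five_mat <- function(...) {
  vals <- list(...)
  tibble::tibble(sample_id = sprintf("S%d", seq_along(vals[[1]])),
                 CLIC3 = vals$CLIC3, GM2A = vals$GM2A, OAT = vals$OAT,
                 PADI3 = vals$PADI3, DPYSL2 = vals$DPYSL2)
}

test_that("combined scores are the signed concentration sums", {
  mat <- five_mat(CLIC3 = 1, GM2A = 2, OAT = 3, PADI3 = 4, DPYSL2 = 5)
  expect_equal(combined_score(mat)$score, 1 + 2 + 3 + 4 - 5)
  # all proteins equal c: weight sum is 3
  matc <- five_mat(CLIC3 = 7, GM2A = 7, OAT = 7, PADI3 = 7, DPYSL2 = 7)
  expect_equal(combined_score(matc)$score, 21)
  expect_equal(
    combined_score(mat, signature_definition("three_protein"))$score,
    2 + 3 - 5
  )
  three0 <- tibble::tibble(sample_id = "S1", GM2A = 2, OAT = 3, DPYSL2 = 5)
  expect_equal(
    combined_score(three0, signature_definition("three_protein"))$score, 0
  )
})

test_that("scores are linear and DPYSL2 enters with weight -1", {
  set.seed(4)
  base <- five_mat(CLIC3 = runif(5), GM2A = runif(5), OAT = runif(5),
                   PADI3 = runif(5), DPYSL2 = runif(5))
  s0 <- combined_score(base)$score
  shifted <- base
  shifted$DPYSL2 <- shifted$DPYSL2 + 3
  expect_equal(combined_score(shifted)$score, s0 - 3)
  shifted2 <- base
  shifted2$OAT <- shifted2$OAT + 2
  expect_equal(combined_score(shifted2)$score, s0 + 2)
})

test_that("scoring requires a complete matrix", {
  mat <- five_mat(CLIC3 = NA_real_, GM2A = 2, OAT = 3, PADI3 = 4,
                  DPYSL2 = 5)
  expect_error(combined_score(mat), "impute")
  expect_error(combined_score(mat[-2]), "CLIC3")
})

test_that("threshold calibration: median midpoint and Youden", {
  scores <- c(10, 12, 2, 4)
  labels <- rep(c("responder", "non-responder"), each = 2)
  expect_equal(calibrate_threshold(scores, labels), 7)
  # identical class medians -> that common median
  expect_equal(calibrate_threshold(c(5, 5), c("responder", "non-responder")),
               5)
  # Youden on perfectly separated classes: midpoint of the gap
  expect_equal(calibrate_threshold(c(1, 2, 8, 9),
                                   rep(c("non-responder", "responder"),
                                       each = 2), method = "youden"),
               5)
  expect_error(calibrate_threshold(c(1, 2), c("responder", "responder")),
               "both classes")
})

test_that("classification is strict-greater with a conservative tie rule", {
  expect_identical(classify_samples(7.1, 7), "responder")
  expect_identical(classify_samples(7, 7), "non-responder")
  expect_identical(classify_samples(c(-5, 0, 5), -Inf),
                   rep("responder", 3))
})

test_that("training-set classification is at least as good as any constant rule", {
  for (s in 1:25) {
    co <- generate_cohort(cohort_design(n_responders = 6,
                                        n_nonresponders = 9, seed = s))
    def <- signature_definition()
    scores <- as.numeric(as.matrix(co$truth[names(def)]) %*% def)
    labels <- response_class(co$samples$cohort_label)
    for (m in c("median_midpoint", "youden")) {
      thr <- calibrate_threshold(scores, labels, m)
      perf <- performance_report(classify_samples(scores, thr), labels)
      # a constant classifier has sensitivity + specificity = 100
      expect_gte(perf$sensitivity + perf$specificity, 100)
    }
  }
})

test_that("performance counts and rates recompute exactly", {
  pred <- rep(c("responder", "non-responder", "non-responder", "responder"),
              c(8, 2, 16, 3))
  truth <- rep(c("responder", "non-responder"), c(10, 19))
  perf <- performance_report(pred, truth)
  expect_equal(perf[c("tp", "fn", "tn", "fp")],
               tibble::tibble(tp = 8L, fn = 2L, tn = 16L, fp = 3L),
               ignore_attr = TRUE)
  expect_equal(perf$sensitivity, 80)
  expect_equal(perf$specificity, 100 * 16 / 19)  # 84.2, prints as 84
  expect_equal(perf$n, 29)
  # order invariance
  set.seed(1)
  o <- sample(length(pred))
  expect_equal(performance_report(pred[o], truth[o]), perf)
  # perfect prediction
  perfect <- performance_report(truth, truth)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "ppv",
                                "npv", "accuracy")]),
               c(sensitivity = 100, specificity = 100, ppv = 100,
                 npv = 100, accuracy = 100))
  # 10 true positives against 1 false positive: PPV 90.9, prints as 91
  p2 <- performance_report(rep("responder", 11),
                           rep(c("responder", "non-responder"), c(10, 1)))
  expect_equal(p2$ppv, 100 * 10 / 11)
  expect_error(performance_report(character(), character()), "empty")
})

test_that("cross-validation separates a separated cohort and errors on bad k", {
  mat <- tibble::tibble(sample_id = sprintf("S%d", 1:10),
                        GM2A = c(rep(100, 5), rep(10, 5)),
                        OAT = c(rep(90, 5), rep(12, 5)),
                        DPYSL2 = c(rep(10, 5), rep(80, 5)))
  labels <- rep(c("responder", "non-responder"), each = 5)
  cv <- cross_validate(mat, labels, signature_definition("three_protein"),
                       k = "loo", seed = 1)
  expect_equal(cv$mean_accuracy, 100)
  expect_equal(cv$n_folds_evaluated, 10)
  expect_error(cross_validate(mat, labels, k = 11), "k")
  expect_error(cross_validate(mat[1:3, ], labels[1:3]), "4")
})

test_that("cross-validation imputes training folds and blinds held-out folds", {
  set.seed(9)
  mat <- tibble::tibble(sample_id = sprintf("S%d", 1:12),
                        GM2A = c(rep(100, 6), rep(10, 6)) + rnorm(12),
                        OAT = c(rep(90, 6), rep(12, 6)) + rnorm(12),
                        DPYSL2 = c(rep(10, 6), rep(80, 6)) + rnorm(12))
  mat$GM2A[c(2, 8)] <- NA
  labels <- rep(c("responder", "non-responder"), each = 6)
  cv <- cross_validate(mat, labels, signature_definition("three_protein"),
                       k = 4, seed = 2)
  expect_equal(cv$n_folds_evaluated, 4)
  expect_gte(cv$mean_accuracy, 75)
})

test_that("the full pipeline recovers a well-separated synthetic cohort", {
  co <- generate_cohort(cohort_design(n_responders = 5,
                                      n_nonresponders = 8, seed = 21))
  res <- run_signature_pipeline(co, impute_seed = 21)
  expect_gte(res$performance$sensitivity, 60)
  expect_gte(res$performance$specificity, 60)
  expect_identical(res$scores$predicted,
                   classify_samples(res$scores$score, res$threshold))
  # three-protein variant runs on the same cohort
  res3 <- run_signature_pipeline(co, variant = "three_protein",
                                 impute_seed = 21)
  expect_equal(nrow(res3$scores), 13)
})
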