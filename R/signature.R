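# Combined-measure signature: weighted sums of protein concentrations,
# threshold calibration, classification and performance reporting.

#' Signature definitions: the 5- and 3-protein combined measures
#'
#' The combined measure sums protein concentrations with unit weights,
#' DPYSL2 entering with weight -1 because it moves in the opposite
#' direction in responders:
#' * `five_protein`: CLIC3 + GM2A + OAT + PADI3 - DPYSL2
#' * `three_protein`: GM2A + OAT - DPYSL2 (the three consistently
#'   quantified proteins)
#'
#' Externally derived linear weights (e.g., an SVM solution) can be
#' passed anywhere a definition is accepted, as any named numeric
#' vector.
#'
#' @param variant `"five_protein"` or `"three_protein"`.
#' @return A named numeric vector of per-protein weights.
#' @examples
#' signature_definition("three_protein")
#' @export
signature_definition <- function(variant = c("five_protein",
                                             "three_protein")) {
  variant <- match.arg(variant)
  if (variant == "five_protein") {
    c(CLIC3 = 1, GM2A = 1, OAT = 1, PADI3 = 1, DPYSL2 = -1)
  } else {
    c(GM2A = 1, OAT = 1, DPYSL2 = -1)
  }
}

#' Combined signature score per sample
#'
#' `score = sum_p weight_p * concentration_p` over the definition's
#' proteins, on the raw amol/ug scale. Every protein in the definition
#' must be present and complete — run imputation first.
#'
#' @param mat Samples x proteins tibble with a `sample_id` column
#'   (post-imputation).
#' @param definition Named weight vector (see [signature_definition()]).
#' @return A tibble with `sample_id` and `score`.
#' @examples
#' mat <- tibble::tibble(sample_id = "S1", CLIC3 = 1, GM2A = 2, OAT = 3,
#'                       PADI3 = 4, DPYSL2 = 5)
#' combined_score(mat, signature_definition("five_protein"))$score # 5
#' @export
combined_score <- function(mat, definition = signature_definition()) {
  mat <- check_matrix(mat)
  if (is.null(names(definition)) || !is.numeric(definition)) {
    stop("`definition` must be a named numeric weight vector", call. = FALSE)
  }
  absent <- setdiff(names(definition), names(mat))
  if (length(absent)) {
    stop(sprintf("matrix lacks signature protein(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  sub <- as.matrix(mat[names(definition)])
  if (anyNA(sub)) {
    stop("signature proteins contain missing values; impute before scoring",
         call. = FALSE)
  }
  tibble::tibble(
    sample_id = mat$sample_id,
    score = as.numeric(sub %*% definition)
  )
}

#' Calibrate a classification threshold on labelled training scores
#'
#' Default rule: the midpoint of the two class medians — robust at the
#' small cohort sizes typical of this setting. Alternative `"youden"`:
#' the cut maximizing sensitivity + specificity over the training
#' scores, evaluated at midpoints between consecutive distinct scores
#' (plus one candidate below all scores and one above); ties resolve to
#' the lowest threshold. On perfectly separated classes Youden returns
#' the midpoint of the gap.
#'
#' @param scores Numeric training scores.
#' @param labels `"responder"`/`"non-responder"` per score; both classes
#'   must be present.
#' @param method `"median_midpoint"` (default) or `"youden"`.
#' @return A single threshold on the score scale.
#' @examples
#' calibrate_threshold(c(10, 12, 2, 4),
#'                     c("responder", "responder",
#'                       "non-responder", "non-responder")) # 7
#' @export
calibrate_threshold <- function(scores, labels,
                                method = c("median_midpoint", "youden")) {
  method <- match.arg(method)
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  resp <- scores[labels == "responder"]
  nonresp <- scores[labels == "non-responder"]
  if (!length(resp) || !length(nonresp)) {
    stop("both classes must be present to calibrate a threshold",
         call. = FALSE)
  }
  if (method == "median_midpoint") {
    return((stats::median(resp) + stats::median(nonresp)) / 2)
  }
  s <- sort(unique(scores))
  gaps <- if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2 else numeric()
  span <- max(s) - min(s)
  pad <- if (span > 0) span / 2 else 1
  candidates <- c(min(s) - pad, gaps, max(s) + pad)
  j <- vapply(candidates, function(thr) {
    mean(resp > thr) + mean(nonresp <= thr) - 1
  }, numeric(1))
  candidates[which.max(j)]  # which.max takes the first (lowest) maximizer
}

#' Classify samples against a signature threshold
#'
#' A sample is called a responder iff its score strictly exceeds the
#' threshold; scores at the threshold are called non-responders
#' (conservative: avoid overcalling response).
#'
#' @param scores Numeric scores.
#' @param threshold Numeric threshold (may be infinite: `-Inf` calls
#'   every sample a responder).
#' @return Character vector of `"responder"`/`"non-responder"`.
#' @export
classify_samples <- function(scores, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold)) {
    stop("`threshold` must be a single non-missing number", call. = FALSE)
  }
  ifelse(scores > threshold, "responder", "non-responder")
}

#' Classification performance against true response labels
#'
#' Confusion counts (responder = positive class) and the derived rates
#' as percentages: sensitivity 100*TP/(TP+FN), specificity
#' 100*TN/(TN+FP), PPV 100*TP/(TP+FP), NPV 100*TN/(TN+FN), accuracy
#' 100*(TP+TN)/n. Rates with an empty denominator are `NA`.
#'
#' @param predicted,truth Aligned character vectors of
#'   `"responder"`/`"non-responder"`.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`, `n`.
#' @examples
#' # 8/10 responders and 16/19 non-responders called correctly:
#' pred <- rep(c("responder", "non-responder", "non-responder", "responder"),
#'             c(8, 2, 16, 3))
#' truth <- rep(c("responder", "non-responder"), c(10, 19))
#' performance_report(pred, truth)[c("sensitivity", "specificity")]
#' @export
performance_report <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  if (!length(predicted)) stop("empty input", call. = FALSE)
  ok_levels <- c("responder", "non-responder")
  stopifnot(all(predicted %in% ok_levels), all(truth %in% ok_levels))
  tp <- sum(predicted == "responder" & truth == "responder")
  fp <- sum(predicted == "responder" & truth == "non-responder")
  tn <- sum(predicted == "non-responder" & truth == "non-responder")
  fn <- sum(predicted == "non-responder" & truth == "responder")
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    accuracy = rate(tp + tn, tp + fp + tn + fn),
    n = tp + fp + tn + fn
  )
}

#' Cross-validated signature performance
#'
#' Stratified k-fold (or leave-one-out with `k = "loo"`)
#' cross-validation of the combined-measure classifier. Per fold: when
#' the matrix has missing values, training rows are completed with
#' [impute_group_median()] and held-out rows with [impute_blinded()]
#' using the training group medians; the threshold is calibrated on the
#' training scores and applied to the held-out scores. Folds whose
#' training part lacks a class are skipped with a warning.
#'
#' @param mat Samples x proteins tibble with `sample_id`.
#' @param labels `"responder"`/`"non-responder"` per row of `mat`.
#' @param definition Signature weights (see [signature_definition()]).
#' @param k Number of folds (2 <= k <= n), or `"loo"`.
#' @param seed Integer seed for the fold shuffle.
#' @param threshold_method Passed to [calibrate_threshold()].
#' @return A list with `fold_accuracy` (per evaluated fold, %),
#'   `mean_accuracy` (%), `pooled` (a [performance_report()] over all
#'   held-out predictions) and `n_folds_evaluated`.
#' @export
cross_validate <- function(mat, labels, definition = signature_definition(),
                           k = 5, seed = 1L,
                           threshold_method = "median_midpoint") {
  mat <- check_matrix(mat)
  n <- nrow(mat)
  stopifnot(length(labels) == n)
  if (n < 4L) stop("at least 4 samples are required", call. = FALSE)
  if (identical(k, "loo")) k <- n
  k <- check_count(k, "k")
  if (k < 2L || k > n) {
    stop(sprintf("`k` must be between 2 and n = %d", n), call. = FALSE)
  }

  fold_of <- withr::with_seed(seed, {
    f <- integer(n)
    offset <- 0L
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      f[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
    f
  })

  needs_imputation <- anyNA(as.matrix(mat[setdiff(names(mat), "sample_id")]))
  fold_accuracy <- numeric()
  pred_all <- truth_all <- character()
  for (fold in seq_len(k)) {
    test_idx <- which(fold_of == fold)
    train_idx <- setdiff(seq_len(n), test_idx)
    if (length(unique(labels[train_idx])) < 2L || !length(test_idx)) {
      warning(sprintf("fold %d skipped: training part lacks a class", fold),
              call. = FALSE)
      next
    }
    train <- mat[train_idx, ]
    test <- mat[test_idx, ]
    if (needs_imputation) {
      med <- group_medians(train, labels[train_idx])
      train <- impute_group_median(train, labels[train_idx])
      test <- impute_blinded(test, med)
    }
    thr <- calibrate_threshold(combined_score(train, definition)$score,
                               labels[train_idx], threshold_method)
    pred <- classify_samples(combined_score(test, definition)$score, thr)
    fold_accuracy <- c(fold_accuracy,
                       100 * mean(pred == labels[test_idx]))
    pred_all <- c(pred_all, pred)
    truth_all <- c(truth_all, labels[test_idx])
  }
  if (!length(fold_accuracy)) {
    stop("no fold could be evaluated", call. = FALSE)
  }
  list(
    fold_accuracy = fold_accuracy,
    mean_accuracy = mean(fold_accuracy),
    pooled = performance_report(pred_all, truth_all),
    n_folds_evaluated = length(fold_accuracy)
  )
}
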