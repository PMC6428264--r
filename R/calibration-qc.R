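# Assay qualification from dilution series: back-calculation, per-level
# CV/accuracy diagnostics, LOD/LLOQ under two rule sets, and a
# diagnostic log-log linearity fit.
#
# Rule sets:
#   ffpe          per-level %CV < 20 and %accuracy-error < 20
#                 (recovery within 80-120%); LLOQ = the level
#                 immediately above the LOD.
#   fresh_frozen  per-level %CV < 25 and %accuracy-error < 25;
#                 LLOQ = 3 x LOD (not snapped to a level).
# In both, the LOD is the lowest level from which every level upward
# passes (contiguity: the LOD starts the quantifiable range).

rule_threshold <- function(rule_set) {
  switch(rule_set, ffpe = 20, fresh_frozen = 25)
}

#' Back-calculate spiked amounts from a calibration series
#'
#' With identical-sequence isotope standards the relative response is
#' unity, so each replicate's estimated amount is simply its measured
#' varied/fixed ratio times the fixed counterpart amount. The fitted
#' curve ([fit_curve()]) is diagnostic only and plays no part here.
#'
#' @param series A [calibration_series()].
#' @return The series with an `estimate_fmol` column added.
#' @export
back_calculate <- function(series) {
  stopifnot(inherits(series, "calibration_series"))
  fixed <- attr(series, "fixed_counterpart_amount")
  out <- series
  out$estimate_fmol <- out$ratio * fixed
  out
}

#' Per-level calibration diagnostics
#'
#' For every dilution level: mean back-calculated amount, replicate %CV
#' (100 * sd/mean; undefined with a single replicate) and %accuracy
#' error (100 * |mean estimate - nominal| / nominal).
#'
#' @param series A [calibration_series()].
#' @return A tibble with one row per level: `level`, `nominal_fmol`,
#'   `n_replicates`, `mean_estimate_fmol`, `cv_pct`,
#'   `accuracy_error_pct`.
#' @examples
#' s <- calibration_series(
#'   data.frame(nominal_fmol = rep(2^(0:5), each = 2),
#'              ratio = rep(2^(0:5), each = 2) / 5),
#'   fixed_counterpart_amount = 5, varied_label = "light")
#' level_diagnostics(s)
#' @export
level_diagnostics <- function(series) {
  est <- back_calculate(series)
  dplyr::summarise(
    tibble::as_tibble(est),
    n_replicates = dplyr::n(),
    mean_estimate_fmol = mean(.data$estimate_fmol),
    cv_pct = percent_cv(.data$estimate_fmol),
    accuracy_error_pct = 100 *
      abs(mean(.data$estimate_fmol) - .data$nominal_fmol[1]) /
      .data$nominal_fmol[1],
    .by = c("level", "nominal_fmol")
  )
}

level_passes <- function(diagnostics, rule_set) {
  thr <- rule_threshold(rule_set)
  !is.na(diagnostics$cv_pct) & diagnostics$cv_pct < thr &
    diagnostics$accuracy_error_pct < thr
}

#' Determine the limit of detection from a dilution series
#'
#' The LOD is the nominal amount of the lowest level whose replicate
#' %CV and %accuracy error both beat the rule set's threshold (20% for
#' `ffpe`, 25% for `fresh_frozen`) *and* from which every higher level
#' also passes, so the LOD marks the start of a contiguous quantifiable
#' range. A level with a single replicate has no CV and fails by
#' policy.
#'
#' @param series A [calibration_series()], or a precomputed
#'   [level_diagnostics()] table.
#' @param rule_set `"ffpe"` or `"fresh_frozen"`.
#' @return The LOD in fmol, or `NA` (assay not quantifiable) when no
#'   level starts a passing run.
#' @export
determine_lod <- function(series, rule_set = c("ffpe", "fresh_frozen")) {
  rule_set <- match.arg(rule_set)
  diagnostics <- if (inherits(series, "calibration_series")) {
    level_diagnostics(series)
  } else {
    tibble::as_tibble(series)
  }
  diagnostics <- diagnostics[order(diagnostics$nominal_fmol), ]
  pass <- level_passes(diagnostics, rule_set)
  # start of the passing run that reaches the top level
  run_top <- rev(cumprod(rev(pass))) > 0
  if (!any(run_top)) return(NA_real_)
  diagnostics$nominal_fmol[which(run_top)[1]]
}

#' Determine the lower limit of quantification
#'
#' Under `ffpe` rules the LLOQ is the nominal amount of the calibration
#' level immediately above the LOD (undefined when the LOD already sits
#' at the top level); under `fresh_frozen` rules the LLOQ is 3 x LOD,
#' not snapped to a level.
#'
#' @param lod LOD in fmol (as returned by [determine_lod()]).
#' @param rule_set `"ffpe"` or `"fresh_frozen"`.
#' @param levels Nominal level amounts of the series (required for
#'   `ffpe`).
#' @return The LLOQ in fmol, or `NA` when the LOD is undefined or (ffpe)
#'   no level lies above it.
#' @export
determine_lloq <- function(lod, rule_set = c("ffpe", "fresh_frozen"),
                           levels = NULL) {
  rule_set <- match.arg(rule_set)
  if (is.na(lod)) return(NA_real_)
  if (rule_set == "fresh_frozen") return(3 * lod)
  if (is.null(levels)) {
    stop("`levels` is required for the ffpe rule set", call. = FALSE)
  }
  levels <- sort(levels)
  above <- levels[levels > lod]
  if (!length(above)) return(NA_real_)
  above[1]
}

#' Diagnostic log-log linearity fit of a calibration series
#'
#' Least squares of log10(back-calculated amount) on log10(nominal
#' amount) over the replicates of the passing levels (or of all levels
#' when `rule_set` is `NULL`). A slope near 1 indicates linear response
#' across the calibrated range.
#'
#' @param series A [calibration_series()].
#' @param rule_set Optional rule set used to restrict the fit to
#'   passing levels.
#' @return A list with `slope`, `intercept`, `r_squared`, `n_levels`.
#' @export
fit_curve <- function(series, rule_set = NULL) {
  diagnostics <- level_diagnostics(series)
  keep_levels <- if (is.null(rule_set)) {
    diagnostics$level
  } else {
    diagnostics$level[level_passes(diagnostics, match.arg(rule_set,
                                                          c("ffpe", "fresh_frozen")))]
  }
  est <- back_calculate(series)
  est <- est[est$level %in% keep_levels & est$estimate_fmol > 0, ]
  if (length(unique(est$level)) < 3L) {
    stop("at least 3 (passing) levels are required for the curve fit",
         call. = FALSE)
  }
  fit <- stats::lm(log10(estimate_fmol) ~ log10(nominal_fmol), data = est)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    n_levels = length(unique(est$level))
  )
}

#' Qualify one peptide assay from its dilution series
#'
#' Runs [level_diagnostics()], [determine_lod()], [determine_lloq()] and
#' [fit_curve()] and assembles the per-peptide qualification: LOD/LLOQ
#' in fmol spiked, a `qualified` flag, per-level diagnostics and the
#' log-log curve.
#'
#' @param series A [calibration_series()].
#' @param rule_set `"ffpe"` or `"fresh_frozen"`.
#' @return An object of class `assay_qualification`: a list with
#'   `peptide`, `rule_set`, `lod_fmol`, `lloq_fmol`, `qualified`,
#'   `diagnostics` (tibble) and `curve` (list, `NULL` when too few
#'   passing levels).
#' @export
qualify_assay <- function(series, rule_set = c("ffpe", "fresh_frozen")) {
  rule_set <- match.arg(rule_set)
  diagnostics <- level_diagnostics(series)
  lod <- determine_lod(diagnostics, rule_set)
  lloq <- determine_lloq(lod, rule_set, levels = diagnostics$nominal_fmol)
  curve <- tryCatch(fit_curve(series, rule_set), error = function(e) NULL)
  structure(
    list(
      peptide = attr(series, "peptide"),
      rule_set = rule_set,
      lod_fmol = lod,
      lloq_fmol = lloq,
      qualified = !is.na(lod) && !is.na(lloq),
      diagnostics = diagnostics,
      curve = curve
    ),
    class = "assay_qualification"
  )
}

#' @export
print.assay_qualification <- function(x, ...) {
  cat(sprintf("<assay_qualification> %s [%s]\n", x$peptide, x$rule_set))
  if (x$qualified) {
    cat(sprintf("  LOD %.4g fmol, LLOQ %.4g fmol\n", x$lod_fmol, x$lloq_fmol))
  } else {
    cat("  not quantifiable under this rule set\n")
  }
  if (!is.null(x$curve)) {
    cat(sprintf("  log-log curve: slope %.3f, R^2 %.4f (%d levels)\n",
                x$curve$slope, x$curve$r_squared, x$curve$n_levels))
  }
  invisible(x)
}

#' Qualify several assays and summarize as a table
#'
#' @param series_list A list of [calibration_series()] objects.
#' @param rule_set `"ffpe"` or `"fresh_frozen"`.
#' @return A tibble with one row per peptide (`peptide`, `rule_set`,
#'   `lod_fmol`, `lloq_fmol`, `qualified`, `slope`, `intercept`,
#'   `r_squared`), suitable for [write_qualification()].
#' @export
qualify_assays <- function(series_list, rule_set = c("ffpe", "fresh_frozen")) {
  rule_set <- match.arg(rule_set)
  rows <- lapply(series_list, function(s) {
    q <- qualify_assay(s, rule_set)
    tibble::tibble(
      peptide = q$peptide, rule_set = q$rule_set,
      lod_fmol = q$lod_fmol, lloq_fmol = q$lloq_fmol,
      qualified = q$qualified,
      slope = q$curve$slope %||% NA_real_,
      intercept = q$curve$intercept %||% NA_real_,
      r_squared = q$curve$r_squared %||% NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Convert qualification LLOQs to concentration units
#'
#' LOD/LLOQ are determined in fmol spiked on column; applying them to a
#' sample converts through the lysate amount analyzed:
#' `fmol * 1000 / lysate_ug` = amol per ug lysate.
#'
#' @param qualification A [qualify_assays()] summary tibble (or a single
#'   `assay_qualification`).
#' @param lysate_ug Lysate amount analyzed, ug.
#' @return A named vector of per-peptide LLOQs in amol/ug, as accepted
#'   by [quantify_samples()] and [impute_below_lloq()].
#' @export
lloq_amol_per_ug <- function(qualification, lysate_ug) {
  check_scalar_number(lysate_ug, "lysate_ug", positive = TRUE)
  if (inherits(qualification, "assay_qualification")) {
    qualification <- tibble::tibble(peptide = qualification$peptide,
                                    lloq_fmol = qualification$lloq_fmol)
  }
  stats::setNames(qualification$lloq_fmol * 1000 / lysate_ug,
                  qualification$peptide)
}
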