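# Transition areas -> peptide ratios -> concentrations -> protein
# roll-up, with replicate summarization and peptide-consistency QC.

#' Light/heavy ratio for one peptide measurement
#'
#' Computes the endogenous-to-standard ratio from matched transition
#' peak areas under either platform convention:
#' `median_of_transitions` (fresh-frozen: median over per-transition
#' light/heavy ratios) or `all_product_ions` (FFPE: sum of light areas
#' over sum of heavy areas, so a zero ion still counts in the sums).
#'
#' `light` and `heavy` must be aligned: element i of each is the same
#' product ion. Transitions where either area is missing are dropped
#' before either rule is applied; for the median rule, transitions with
#' a zero heavy area are also dropped. If nothing usable remains the
#' ratio is missing (`NA`), with a warning when the cause is a zero
#' heavy signal.
#'
#' @param light,heavy Numeric vectors of peak areas for matched product
#'   ions (may contain `NA`).
#' @param method `"median_of_transitions"` or `"all_product_ions"`.
#' @return A single ratio, or `NA` when no matched pair is usable.
#' @examples
#' peptide_ratio(c(100, 300), c(200, 600), "all_product_ions") # 0.5
#' peptide_ratio(c(0.4, 0.5, 0.9) * 10, c(10, 10, 10),
#'               "median_of_transitions") # 0.5
#' @export
peptide_ratio <- function(light, heavy,
                          method = c("median_of_transitions",
                                     "all_product_ions")) {
  method <- match.arg(method)
  if (length(light) != length(heavy)) {
    stop("`light` and `heavy` must be matched vectors of equal length",
         call. = FALSE)
  }
  ok <- !is.na(light) & !is.na(heavy)
  if (!any(ok)) return(NA_real_)
  light <- light[ok]
  heavy <- heavy[ok]
  if (method == "all_product_ions") {
    hsum <- sum(heavy)
    if (hsum == 0) {
      warning("total heavy area is zero; ratio is missing", call. = FALSE)
      return(NA_real_)
    }
    sum(light) / hsum
  } else {
    usable <- heavy > 0
    if (!any(usable)) {
      warning("all heavy areas are zero; ratio is missing", call. = FALSE)
      return(NA_real_)
    }
    stats::median(light[usable] / heavy[usable])
  }
}

#' Convert a light/heavy ratio to a concentration
#'
#' With a heavy standard of known amount spiked into a known amount of
#' lysate, the dimensionless light/heavy ratio becomes an absolute
#' endogenous concentration:
#' `ratio * spike_fmol * 1000 / lysate_ug` amol per ug lysate.
#'
#' @param ratio Light/heavy ratio (>= 0, may be `NA`).
#' @param spike_fmol Heavy standard spiked, fmol (> 0).
#' @param lysate_ug Lysate digested and analyzed, ug (> 0).
#' @return Concentration in amol/ug lysate.
#' @examples
#' peptide_concentration(0.5, 5, 1) # 2500 amol/ug
#' @export
peptide_concentration <- function(ratio, spike_fmol, lysate_ug) {
  check_numeric_vec(spike_fmol, "spike_fmol", positive = TRUE)
  check_numeric_vec(lysate_ug, "lysate_ug", positive = TRUE)
  ratio * spike_fmol * 1000 / lysate_ug
}

#' Summarize technical replicates of one peptide in one sample
#'
#' The per-sample peptide concentration is the median across replicate
#' injections (robust to a single aberrant run); the replicate %CV is
#' reported alongside.
#'
#' @param x Numeric vector of per-replicate concentrations (`NA`
#'   replicates are dropped).
#' @return A list with `concentration` (median; `NA` if no replicate is
#'   present), `cv_pct` (`NA` with < 2 replicates) and `n_replicates`.
#' @export
summarize_replicates <- function(x) {
  x <- x[!is.na(x)]
  list(
    concentration = if (length(x)) stats::median(x) else NA_real_,
    cv_pct = percent_cv(x),
    n_replicates = length(x)
  )
}

#' Roll peptide concentrations up to one protein value
#'
#' The protein concentration is the median of its detected peptides'
#' concentrations; the inter-peptide %CV (100 * sd/mean, needing >= 2
#' detected peptides) is the per-sample consistency metric. With zero
#' detected peptides the protein is missing.
#'
#' @param x Numeric vector of per-sample peptide concentrations (`NA` =
#'   not detected).
#' @return A list with `concentration`, `n_peptides_detected`,
#'   `inter_peptide_cv`.
#' @examples
#' rollup_protein(c(90, 100, 110)) # 100, CV 10%
#' @export
rollup_protein <- function(x) {
  x <- x[!is.na(x)]
  list(
    concentration = if (length(x)) stats::median(x) else NA_real_,
    n_peptides_detected = length(x),
    inter_peptide_cv = percent_cv(x)
  )
}

# Match light and heavy rows of each (sample, replicate, peptide) by
# the rank of product_mz within each label: the isotope shift moves
# every product ion by the same mass, so rank order is preserved.
match_label_pairs <- function(transitions) {
  tr <- dplyr::mutate(
    transitions,
    ion_rank = rank(.data$product_mz, ties.method = "first"),
    .by = c("sample_id", "replicate", "peptide", "label")
  )
  wide <- tidyr::pivot_wider(
    dplyr::select(tr, "sample_id", "replicate", "protein", "peptide",
                  "label", "ion_rank", "peak_area"),
    names_from = "label", values_from = "peak_area"
  )
  for (lab in c("light", "heavy")) {
    if (!lab %in% names(wide)) wide[[lab]] <- NA_real_
  }
  wide
}

#' Quantify a cohort: transitions to peptide and protein concentrations
#'
#' Runs the full quantification for every (sample, replicate, peptide):
#' light/heavy ratio under the chosen platform convention, conversion to
#' amol/ug using each sample's spike and lysate amounts, optional
#' LLOQ-based detection gating, median summarization over replicates,
#' and median roll-up of detected peptides to protein level.
#'
#' When `lloq` is supplied, a peptide replicate whose computable
#' concentration falls below its LLOQ is flagged `below_lloq` and
#' treated as not detected (its value is retained for audit but excluded
#' from roll-up; [impute_below_lloq()] fills such cells).
#'
#' @param transitions Transition table (see [read_transition_table()]).
#' @param samples Sample sheet (see [read_sample_sheet()]).
#' @param method Ratio rule; defaults to the sample platform's
#'   convention (`all_product_ions` for ffpe, `median_of_transitions`
#'   for fresh_frozen) when `NULL`.
#' @param lloq Optional per-peptide LLOQ in amol/ug lysate: a single
#'   number or a named vector (names = peptides).
#' @return A list of tibbles:
#'   * `peptides`: per (sample, replicate, peptide) ratio,
#'     concentration, `below_lloq` and `detected`;
#'   * `peptide_summary`: per (sample, peptide) median concentration
#'     over detected replicates plus replicate %CV;
#'   * `proteins`: per (sample, protein) concentration,
#'     `n_peptides_detected`, `inter_peptide_cv`, `source`;
#'   * `matrix`: wide samples x proteins concentration tibble.
#' @export
quantify_samples <- function(transitions, samples, method = NULL,
                             lloq = NULL) {
  transitions <- validate_transitions(transitions[transition_cols])
  samples <- validate_sample_sheet(tibble::as_tibble(samples))
  if (is.null(method)) {
    platforms <- unique(samples$platform)
    method <- if (identical(platforms, "fresh_frozen")) {
      "median_of_transitions"
    } else {
      "all_product_ions"
    }
  }
  method <- match.arg(method, c("median_of_transitions", "all_product_ions"))

  unknown <- setdiff(unique(transitions$sample_id), samples$sample_id)
  if (length(unknown)) {
    stop(sprintf("transition table references samples missing from the sample sheet: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }

  wide <- match_label_pairs(transitions)
  wide$pair_ok <- !is.na(wide$light) & !is.na(wide$heavy)
  if (method == "all_product_ions") {
    peptides <- dplyr::summarise(
      wide,
      ratio = {
        hs <- sum(.data$heavy[.data$pair_ok])
        if (!any(.data$pair_ok) || hs == 0) {
          NA_real_
        } else {
          sum(.data$light[.data$pair_ok]) / hs
        }
      },
      .by = c("sample_id", "replicate", "protein", "peptide")
    )
  } else {
    peptides <- dplyr::summarise(
      wide,
      ratio = {
        u <- .data$pair_ok & .data$heavy > 0
        if (!any(u)) NA_real_ else stats::median(.data$light[u] / .data$heavy[u])
      },
      .by = c("sample_id", "replicate", "protein", "peptide")
    )
  }
  peptides <- dplyr::left_join(
    peptides,
    dplyr::select(samples, "sample_id", "lysate_amount", "spike_amount"),
    by = "sample_id"
  )
  peptides$concentration <- peptides$ratio * peptides$spike_amount * 1000 /
    peptides$lysate_amount

  if (!is.null(lloq)) {
    check_numeric_vec(lloq, "lloq", positive = TRUE)
    if (length(lloq) == 1L && is.null(names(lloq))) {
      lloq_vec <- rep(lloq, nrow(peptides))
    } else {
      lloq_vec <- unname(lloq[peptides$peptide])
      if (anyNA(lloq_vec)) {
        stop("`lloq` must name every peptide in the transition table",
             call. = FALSE)
      }
    }
    peptides$lloq <- lloq_vec
    peptides$below_lloq <- !is.na(peptides$concentration) &
      peptides$concentration < lloq_vec
  } else {
    peptides$lloq <- NA_real_
    peptides$below_lloq <- FALSE
  }
  peptides$detected <- !is.na(peptides$concentration) & !peptides$below_lloq
  peptides <- dplyr::select(
    peptides, "sample_id", "replicate", "protein", "peptide",
    "ratio", "concentration", "lloq", "below_lloq", "detected"
  )

  summarize_quant(peptides, samples)
}

# replicate summarization + protein roll-up of a per-replicate peptide
# table (shared by quantify_samples and the post-imputation path)
summarize_quant <- function(peptides, samples) {
  if (!"imputed" %in% names(peptides)) peptides$imputed <- FALSE
  peptide_summary <- dplyr::summarise(
    peptides,
    concentration = if (any(.data$detected)) {
      stats::median(.data$concentration[.data$detected])
    } else {
      NA_real_
    },
    replicate_cv_pct = percent_cv(.data$concentration[.data$detected]),
    n_replicates_detected = sum(.data$detected),
    imputed = any(.data$detected & .data$imputed),
    .by = c("sample_id", "protein", "peptide")
  )

  proteins <- dplyr::summarise(
    peptide_summary,
    n_peptides_detected = sum(!is.na(.data$concentration)),
    inter_peptide_cv = percent_cv(.data$concentration),
    source = if (any(.data$imputed)) "imputed" else "measured",
    concentration = if (any(!is.na(.data$concentration))) {
      stats::median(.data$concentration, na.rm = TRUE)
    } else {
      NA_real_
    },
    .by = c("sample_id", "protein")
  )
  proteins <- dplyr::select(
    proteins, "sample_id", "protein", "concentration",
    "n_peptides_detected", "inter_peptide_cv", "source"
  )

  mat <- tidyr::pivot_wider(
    dplyr::select(proteins, "sample_id", "protein", "concentration"),
    names_from = "protein", values_from = "concentration"
  )
  mat <- mat[match(samples$sample_id, mat$sample_id), ]

  list(peptides = peptides, peptide_summary = peptide_summary,
       proteins = proteins, matrix = mat)
}

#' Peptide-consistency QC for a quantified cohort
#'
#' For each protein, reports (i) the median over samples of the
#' per-sample inter-peptide %CV and (ii) the minimum pairwise Pearson
#' correlation between its peptides' concentration profiles across
#' samples. Concordant peptides (low CV, high correlation) indicate the
#' peptide level is a valid surrogate for protein concentration.
#'
#' @param peptide_summary Per (sample, peptide) concentration table with
#'   columns `sample_id`, `protein`, `peptide`, `concentration` (as
#'   produced by [quantify_samples()]).
#' @return A tibble with one row per protein: `n_peptides`,
#'   `median_cv_pct`, `min_pairwise_r` (NA when a peptide profile is
#'   constant or fewer than 3 complete sample pairs exist).
#' @export
qc_peptide_consistency <- function(peptide_summary) {
  peptide_summary <- tibble::as_tibble(peptide_summary)
  per_sample_cv <- dplyr::summarise(
    peptide_summary,
    cv = percent_cv(.data$concentration),
    .by = c("protein", "sample_id")
  )
  cv_tab <- dplyr::summarise(
    per_sample_cv,
    median_cv_pct = stats::median(.data$cv, na.rm = TRUE),
    .by = "protein"
  )

  cor_tab <- dplyr::summarise(
    peptide_summary,
    {
      wide <- tidyr::pivot_wider(
        dplyr::pick(dplyr::everything()),
        id_cols = "sample_id", names_from = "peptide",
        values_from = "concentration"
      )
      m <- as.matrix(wide[-1])
      tibble::tibble(
        n_peptides = ncol(m),
        min_pairwise_r = min_pairwise_cor(m)
      )
    },
    .by = "protein"
  )
  dplyr::left_join(cor_tab, cv_tab, by = "protein")
}

min_pairwise_cor <- function(m) {
  if (ncol(m) < 2L) return(NA_real_)
  rs <- c()
  for (i in seq_len(ncol(m) - 1L)) {
    for (j in seq(i + 1L, ncol(m))) {
      ok <- stats::complete.cases(m[, i], m[, j])
      if (sum(ok) < 3L) {
        rs <- c(rs, NA_real_)
      } else if (stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0) {
        rs <- c(rs, NA_real_)  # constant profile: correlation undefined
      } else {
        rs <- c(rs, stats::cor(m[ok, i], m[ok, j]))
      }
    }
  }
  if (all(is.na(rs))) NA_real_ else min(rs, na.rm = TRUE)
}

#' Linear cross-platform correlation
#'
#' Ordinary least-squares fit and Pearson correlation between two
#' per-sample measurements of the same analyte (e.g., SRM concentration
#' against an IHC immune-reactivity score, or two SRM analytes).
#'
#' @param x,y Paired numeric vectors; pairs with a missing value are
#'   dropped.
#' @return A tibble with `slope`, `intercept`, `r`, `n`.
#' @export
correlate_platforms <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) {
    stop("at least 3 paired non-missing values are required", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("`x` is constant; a linear fit is undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = stats::cor(x, y),
    n = length(x)
  )
}
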