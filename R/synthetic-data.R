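# Synthetic-data generators: seeded cohorts and calibration series with
# the statistical structure the downstream analysis assumes, so every
# stage is testable without measured data.

# Default five-protein panel. Base concentrations are non-responder
# medians in amol/ug lysate; effect_size is the responder/non-responder
# fold ratio and effect_direction its sign (-1: lower in responders).
# Values sit in the reported 1.07-1.92 effect-size range, with the two
# low-abundance proteins (CLIC3, PADI3) placed below the ~100 amol/ug
# LLOQ so that left-censoring is common, as seen in FFPE cohorts.
default_panel <- function() {
  tibble::tibble(
    protein = c("DPYSL2", "OAT", "CLIC3", "GM2A", "PADI3"),
    n_peptides = c(3L, 3L, 2L, 3L, 3L),
    base_concentration = c(1200, 900, 70, 600, 70),
    effect_size = c(1.55, 1.92, 1.78, 1.50, 1.07),
    effect_direction = c(-1, 1, 1, 1, 1)
  )
}

# Invented proteotypic peptide sequences (synthetic placeholders, not
# from any published transition list). Deterministic per protein.
panel_peptides <- function(protein, n) {
  known <- list(
    DPYSL2 = c("AGVEELLR", "TIGDLVQK", "SDLELGVR"),
    OAT    = c("LVDFSGNR", "TIQGPPTEK", "AVELDSITK"),
    CLIC3  = c("GFTVPEAFR", "ADLSLLGK"),
    GM2A   = c("SPLGELLK", "VESVLSSR", "TGLFDAEK"),
    PADI3  = c("NLPEVASR", "GQLDVFEK", "SVLGEAIK")
  )
  if (protein %in% names(known) && n <= length(known[[protein]])) {
    return(known[[protein]][seq_len(n)])
  }
  # fall back to a deterministic sequence derived from the protein name
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  offset <- sum(utf8ToInt(protein))
  vapply(seq_len(n), function(i) {
    idx <- ((offset + i * seq_len(7) * 13L) %% length(aa)) + 1L
    paste0(paste(aa[idx], collapse = ""), if (i %% 2L) "K" else "R")
  }, character(1))
}

#' Design a synthetic responder/non-responder SRM cohort
#'
#' Captures everything [generate_cohort()] needs: cohort sizes, the
#' protein panel with per-protein abundance and effect size, noise
#' levels, censoring limits and the spike/lysate amounts that link
#' light/heavy ratios to concentrations.
#'
#' Biological (between-sample) and technical (replicate) variability are
#' both multiplicative log-normal; `biological_cv` and `replicate_cv`
#' are fractional CVs. Censoring is applied to the per-replicate peptide
#' concentration: values below `lloq` are emitted as absent light
#' transitions (informative missingness), never as zeros.
#'
#' @param n_responders,n_nonresponders Cohort sizes (default 10 and 19).
#' @param panel Data frame with columns `protein`, `n_peptides`,
#'   `base_concentration` (non-responder median, amol/ug),
#'   `effect_size` (responder/non-responder fold ratio, > 0) and
#'   `effect_direction` (+1 or -1). Defaults to the five-protein
#'   DPYSL2/OAT/CLIC3/GM2A/PADI3 panel with DPYSL2 inverted.
#' @param replicate_cv Fractional CV of technical replicates (default
#'   0.10, matching a ~10% inter-replicate spread).
#' @param biological_cv Fractional between-sample CV (default 0.25).
#' @param lloq Censoring limit in amol/ug lysate; a single number
#'   applied to every peptide or a named per-peptide vector. Default 100.
#' @param n_replicates Technical replicates per sample (default 3).
#' @param n_transitions Transitions monitored per peptide (default 3).
#' @param lysate_amount Digest analyzed per injection, ug (default 1).
#' @param spike_amount Heavy standard spiked per peptide, fmol
#'   (default 5).
#' @param seed Integer seed; all generator output is a pure function of
#'   the design including this seed.
#' @return An object of class `cohort_design`.
#' @seealso [generate_cohort()]
#' @export
cohort_design <- function(n_responders = 10, n_nonresponders = 19,
                          panel = default_panel(),
                          replicate_cv = 0.10, biological_cv = 0.25,
                          lloq = 100, n_replicates = 3, n_transitions = 3,
                          lysate_amount = 1, spike_amount = 5, seed = 1L) {
  n_responders <- check_count(n_responders, "n_responders")
  n_nonresponders <- check_count(n_nonresponders, "n_nonresponders")
  n_replicates <- check_count(n_replicates, "n_replicates")
  n_transitions <- check_count(n_transitions, "n_transitions")
  check_scalar_number(replicate_cv, "replicate_cv", nonneg = TRUE)
  check_scalar_number(biological_cv, "biological_cv", nonneg = TRUE)
  check_scalar_number(lysate_amount, "lysate_amount", positive = TRUE)
  check_scalar_number(spike_amount, "spike_amount", positive = TRUE)
  seed <- check_count(seed, "seed")
  panel <- tibble::as_tibble(panel)
  needed <- c("protein", "n_peptides", "base_concentration",
              "effect_size", "effect_direction")
  if (!all(needed %in% names(panel))) {
    stop_bad_arg("panel", paste("must have columns",
                                paste(needed, collapse = ", ")))
  }
  check_numeric_vec(panel$base_concentration, "panel$base_concentration",
                    positive = TRUE)
  check_numeric_vec(panel$effect_size, "panel$effect_size", positive = TRUE)
  if (!all(panel$effect_direction %in% c(-1, 1))) {
    stop_bad_arg("panel$effect_direction", "must be +1 or -1")
  }
  check_numeric_vec(lloq, "lloq", positive = TRUE)

  peptides <- dplyr::bind_rows(lapply(seq_len(nrow(panel)), function(i) {
    tibble::tibble(
      protein = panel$protein[i],
      peptide = panel_peptides(panel$protein[i], panel$n_peptides[i])
    )
  }))
  if (length(lloq) == 1L) {
    lloq <- stats::setNames(rep(lloq, nrow(peptides)), peptides$peptide)
  } else if (is.null(names(lloq)) || !all(peptides$peptide %in% names(lloq))) {
    stop_bad_arg("lloq", "must be a single number or named for every peptide")
  }

  structure(
    list(
      n_responders = n_responders, n_nonresponders = n_nonresponders,
      panel = panel, peptides = peptides,
      replicate_cv = replicate_cv, biological_cv = biological_cv,
      lloq = lloq, n_replicates = n_replicates,
      n_transitions = n_transitions,
      lysate_amount = lysate_amount, spike_amount = spike_amount,
      seed = seed
    ),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    "<cohort_design> %d responders / %d non-responders, %d proteins, %d replicates, seed %d\n",
    x$n_responders, x$n_nonresponders, nrow(x$panel), x$n_replicates, x$seed
  ))
  print(x$panel)
  invisible(x)
}

# deterministic (noise-free) transition geometry: relative intensities
# and m/z bookkeeping for n transitions of peptide k
transition_geometry <- function(pep_index, n_transitions) {
  rel <- 0.55^(seq_len(n_transitions) - 1)
  prec <- 420 + 13.7 * pep_index
  prod <- prec + 110 + 57 * seq_len(n_transitions)
  list(rel = rel, precursor = prec, product = prod)
}

#' Generate a synthetic cohort of transition-level SRM measurements
#'
#' Draws per-sample true protein concentrations log-normally around the
#' group-specific median (`base_concentration`, scaled by
#' `effect_size^effect_direction` for responders), propagates them to
#' peptide/replicate level with multiplicative technical noise, censors
#' replicate concentrations below the peptide's LLOQ (light transitions
#' absent), and renders the remainder as light/heavy transition peak
#' areas consistent with the spike and lysate amounts.
#'
#' @param design A [cohort_design()].
#' @return A list with components
#'   * `transitions`: long transition table (one row per sample,
#'     replicate, peptide, label, transition) as read/written by
#'     [read_transition_table()];
#'   * `samples`: sample sheet with `cohort_label` ground truth;
#'   * `truth`: wide tibble of true per-sample protein concentrations
#'     (amol/ug), before technical noise and censoring.
#' @examples
#' cohort <- generate_cohort(cohort_design(n_responders = 3,
#'                                         n_nonresponders = 3, seed = 7))
#' dplyr::count(cohort$transitions, label)
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  withr::with_seed(design$seed, generate_cohort_impl(design))
}

generate_cohort_impl <- function(design) {
  n_total <- design$n_responders + design$n_nonresponders
  samples <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n_total)),
    cohort_label = rep(c("responder", "non-responder"),
                       c(design$n_responders, design$n_nonresponders)),
    lysate_amount = design$lysate_amount,
    spike_amount = design$spike_amount,
    platform = "ffpe"
  )

  panel <- design$panel
  resp_median <- panel$base_concentration *
    panel$effect_size^panel$effect_direction

  # true per-sample protein concentrations (biological level)
  sdlog_bio <- cv_to_sdlog(design$biological_cv)
  truth_long <- tidyr::expand_grid(
    sample_id = samples$sample_id,
    protein = panel$protein
  )
  truth_long <- dplyr::left_join(
    truth_long,
    dplyr::select(samples, "sample_id", "cohort_label"),
    by = "sample_id"
  )
  med <- ifelse(truth_long$cohort_label == "responder",
                resp_median[match(truth_long$protein, panel$protein)],
                panel$base_concentration[match(truth_long$protein,
                                               panel$protein)])
  truth_long$concentration <-
    med * exp(stats::rnorm(nrow(truth_long), 0, sdlog_bio))

  truth <- tidyr::pivot_wider(
    dplyr::select(truth_long, "sample_id", "protein", "concentration"),
    names_from = "protein", values_from = "concentration"
  )

  # peptide x replicate concentrations with technical noise
  sdlog_rep <- cv_to_sdlog(design$replicate_cv)
  meas <- tidyr::expand_grid(
    sample_id = samples$sample_id,
    peptide = design$peptides$peptide,
    replicate = seq_len(design$n_replicates)
  )
  meas$protein <- design$peptides$protein[match(meas$peptide,
                                                design$peptides$peptide)]
  meas <- dplyr::left_join(
    meas,
    dplyr::select(truth_long, "sample_id", "protein", true = "concentration"),
    by = c("sample_id", "protein")
  )
  meas$concentration <- meas$true * exp(stats::rnorm(nrow(meas), 0, sdlog_rep))
  meas$censored <- meas$concentration < design$lloq[meas$peptide]

  # render transitions: heavy always present, light absent when censored
  pep_index <- match(meas$peptide, design$peptides$peptide)
  rows <- lapply(seq_len(design$n_transitions), function(j) {
    geom_rel <- 0.55^(j - 1)
    prec <- 420 + 13.7 * pep_index
    prod <- prec + 110 + 57 * j
    heavy_area <- design$spike_amount * 2e4 * geom_rel
    light_area <- heavy_area * meas$concentration * design$lysate_amount /
      (1000 * design$spike_amount)
    heavy <- tibble::tibble(
      sample_id = meas$sample_id, replicate = meas$replicate,
      protein = meas$protein, peptide = meas$peptide,
      label = "heavy", precursor_mz = prec + 4, product_mz = prod + 8,
      peak_area = heavy_area
    )
    light <- tibble::tibble(
      sample_id = meas$sample_id, replicate = meas$replicate,
      protein = meas$protein, peptide = meas$peptide,
      label = "light", precursor_mz = prec, product_mz = prod,
      peak_area = light_area
    )[!meas$censored, ]
    dplyr::bind_rows(heavy, light)
  })
  transitions <- dplyr::arrange(
    dplyr::bind_rows(rows),
    .data$sample_id, .data$replicate, .data$protein, .data$peptide,
    .data$label, .data$product_mz
  )

  list(transitions = transitions, samples = samples, truth = truth)
}

#' Design a synthetic calibration (dilution) series
#'
#' Presets follow the two qualification formats: `"ffpe"` titrates the
#' light peptide over 25 amol to 25 fmol in 14 points against a fixed
#' 5 fmol heavy spike (forward curve); `"fresh_frozen"` titrates the
#' heavy peptide over 1.5 amol to 100 fmol in 12 points against a fixed
#' 50 fmol light amount (reversed curve). Levels are geometrically
#' spaced between the endpoints.
#'
#' @param platform `"ffpe"` or `"fresh_frozen"`; sets default levels,
#'   fixed counterpart amount and varied label.
#' @param levels Nominal spiked amounts (fmol), strictly increasing;
#'   overrides the preset.
#' @param fixed_counterpart_amount Fixed spike of the other label, fmol.
#' @param n_replicates Replicate injections per level (default 3; at
#'   least 2 are needed for a CV).
#' @param noise_cv Fractional multiplicative CV on each replicate ratio.
#' @param noise_floor Additive amount-scale noise (fmol): each replicate
#'   estimate gains `noise_floor * |N(0,1)|`, which dominates (and fails)
#'   the lowest levels when sized near their nominal amounts.
#' @param varied_label Which label is titrated; defaults to the preset.
#' @param seed Integer seed.
#' @return An object of class `calibration_design`.
#' @seealso [generate_calibration()], [qualify_assay()]
#' @export
calibration_design <- function(platform = c("ffpe", "fresh_frozen"),
                               levels = NULL,
                               fixed_counterpart_amount = NULL,
                               n_replicates = 3,
                               noise_cv = 0.08, noise_floor = 0,
                               varied_label = NULL, seed = 1L) {
  platform <- match.arg(platform)
  if (is.null(levels)) {
    levels <- if (platform == "ffpe") {
      exp(seq(log(0.025), log(25), length.out = 14))
    } else {
      exp(seq(log(0.0015), log(100), length.out = 12))
    }
  }
  check_numeric_vec(levels, "levels", positive = TRUE)
  if (is.unsorted(levels, strictly = TRUE)) {
    stop_bad_arg("levels", "must be strictly increasing")
  }
  fixed_counterpart_amount <- fixed_counterpart_amount %||%
    (if (platform == "ffpe") 5 else 50)
  check_scalar_number(fixed_counterpart_amount, "fixed_counterpart_amount",
                      positive = TRUE)
  varied_label <- varied_label %||%
    (if (platform == "ffpe") "light" else "heavy")
  stopifnot(varied_label %in% c("light", "heavy"))
  n_replicates <- check_count(n_replicates, "n_replicates")
  check_scalar_number(noise_cv, "noise_cv", nonneg = TRUE)
  check_scalar_number(noise_floor, "noise_floor", nonneg = TRUE)
  seed <- check_count(seed, "seed")

  structure(
    list(platform = platform, levels = levels,
         fixed_counterpart_amount = fixed_counterpart_amount,
         n_replicates = n_replicates, noise_cv = noise_cv,
         noise_floor = noise_floor, varied_label = varied_label,
         seed = seed),
    class = "calibration_design"
  )
}

#' @export
print.calibration_design <- function(x, ...) {
  cat(sprintf(
    "<calibration_design> %s: %d levels (%.4g-%.4g fmol), fixed %s %.4g fmol, %d replicates\n",
    x$platform, length(x$levels), min(x$levels), max(x$levels),
    setdiff(c("light", "heavy"), x$varied_label), x$fixed_counterpart_amount,
    x$n_replicates
  ))
  invisible(x)
}

#' Construct a calibration series from measured ratios
#'
#' Wraps a long table of per-level replicate ratios (varied label over
#' fixed counterpart) with the metadata qualification needs.
#'
#' @param data Data frame with columns `nominal_fmol` and `ratio`
#'   (optionally `replicate`).
#' @param fixed_counterpart_amount Fixed spike of the counterpart label,
#'   fmol.
#' @param varied_label `"light"` or `"heavy"`.
#' @param peptide Peptide identifier carried into reports.
#' @return A tibble of class `calibration_series` with attributes
#'   `fixed_counterpart_amount`, `varied_label`, `peptide`.
#' @export
calibration_series <- function(data, fixed_counterpart_amount,
                               varied_label = c("light", "heavy"),
                               peptide = "peptide") {
  varied_label <- match.arg(varied_label)
  check_scalar_number(fixed_counterpart_amount, "fixed_counterpart_amount",
                      positive = TRUE)
  data <- tibble::as_tibble(data)
  stopifnot(all(c("nominal_fmol", "ratio") %in% names(data)))
  check_numeric_vec(data$nominal_fmol, "nominal_fmol", positive = TRUE)
  check_numeric_vec(data$ratio, "ratio", nonneg = TRUE)
  lv <- sort(unique(data$nominal_fmol))
  if (length(lv) < 6L) {
    stop_bad_arg("data", "must contain at least 6 dilution levels")
  }
  if (!"replicate" %in% names(data)) {
    data <- dplyr::mutate(data, replicate = dplyr::row_number(),
                          .by = "nominal_fmol")
  }
  data$level <- match(data$nominal_fmol, lv)
  data <- data[order(data$level, data$replicate),
               c("level", "nominal_fmol", "replicate", "ratio")]
  structure(data,
            fixed_counterpart_amount = fixed_counterpart_amount,
            varied_label = varied_label, peptide = peptide,
            class = c("calibration_series", class(data)))
}

#' Generate a synthetic calibration series
#'
#' Replicate ratios at each level are `nominal / fixed_counterpart`
#' perturbed by multiplicative log-normal noise (`noise_cv`) plus an
#' additive amount-scale floor (`noise_floor * |N(0,1)| /
#' fixed_counterpart`) that distorts the lowest levels, emulating
#' chemical background at the bottom of the curve.
#'
#' @param design A [calibration_design()].
#' @param peptide Peptide identifier attached to the series.
#' @return A `calibration_series` (see [calibration_series()]).
#' @examples
#' series <- generate_calibration(calibration_design("ffpe", seed = 3))
#' length(unique(series$nominal_fmol))
#' @export
generate_calibration <- function(design, peptide = "peptide") {
  stopifnot(inherits(design, "calibration_design"))
  withr::with_seed(design$seed, {
    grid <- tidyr::expand_grid(
      nominal_fmol = design$levels,
      replicate = seq_len(design$n_replicates)
    )
    sdlog <- cv_to_sdlog(design$noise_cv)
    est <- grid$nominal_fmol * exp(stats::rnorm(nrow(grid), 0, sdlog)) +
      design$noise_floor * abs(stats::rnorm(nrow(grid)))
    grid$ratio <- est / design$fixed_counterpart_amount
    calibration_series(grid, design$fixed_counterpart_amount,
                       design$varied_label, peptide)
  })
}
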