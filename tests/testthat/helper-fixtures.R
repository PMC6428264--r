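# Small in-code fixtures shared across the suite.

# A minimal transition table: one sample, one replicate, one peptide,
# n matched light/heavy transitions with the given areas.
toy_transitions <- function(light, heavy, sample_id = "S1", replicate = 1L,
                            protein = "OAT", peptide = "LVDFSGNR") {
  n <- length(heavy)
  light_rows <- tibble::tibble(
    sample_id = sample_id, replicate = replicate, protein = protein,
    peptide = peptide, label = "light",
    precursor_mz = 500, product_mz = 600 + 10 * seq_len(n),
    peak_area = light
  )
  heavy_rows <- tibble::tibble(
    sample_id = sample_id, replicate = replicate, protein = protein,
    peptide = peptide, label = "heavy",
    precursor_mz = 504, product_mz = 608 + 10 * seq_len(n),
    peak_area = heavy
  )
  dplyr::bind_rows(light_rows, heavy_rows)
}

toy_sample_sheet <- function(sample_id = "S1", cohort_label = "responder",
                             lysate_amount = 1, spike_amount = 5,
                             platform = "ffpe") {
  tibble::tibble(sample_id = sample_id, cohort_label = cohort_label,
                 lysate_amount = lysate_amount, spike_amount = spike_amount,
                 platform = platform)
}

# A calibration series built from explicit per-replicate estimates
# (fmol); ratios are derived from the fixed counterpart amount.
series_from_estimates <- function(estimates_by_level, nominal, fixed = 5,
                                  varied_label = "light") {
  stopifnot(length(estimates_by_level) == length(nominal))
  data <- dplyr::bind_rows(lapply(seq_along(nominal), function(i) {
    tibble::tibble(nominal_fmol = nominal[i],
                   ratio = estimates_by_level[[i]] / fixed)
  }))
  calibration_series(data, fixed_counterpart_amount = fixed,
                     varied_label = varied_label)
}

# Literal per-level LOD scan used as an independent oracle: recompute
# CV and accuracy error per level from scratch and walk the levels.
brute_force_lod <- function(series, rule_set) {
  thr <- if (rule_set == "ffpe") 20 else 25
  fixed <- attr(series, "fixed_counterpart_amount")
  nominal <- sort(unique(series$nominal_fmol))
  pass <- logical(length(nominal))
  for (i in seq_along(nominal)) {
    est <- series$ratio[series$nominal_fmol == nominal[i]] * fixed
    cv <- if (length(est) < 2) NA_real_ else 100 * sd(est) / mean(est)
    acc <- 100 * abs(mean(est) - nominal[i]) / nominal[i]
    pass[i] <- !is.na(cv) && cv < thr && acc < thr
  }
  for (i in seq_along(nominal)) {
    if (all(pass[i:length(nominal)])) return(nominal[i])
  }
  NA_real_
}

# default design with all effect sizes forced to 1 (null cohort)
null_cohort_design <- function(n_responders, n_nonresponders, seed, ...) {
  p <- srmsig:::default_panel()
  p$effect_size[] <- 1
  cohort_design(n_responders = n_responders,
                n_nonresponders = n_nonresponders,
                panel = p, seed = seed, ...)
}
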