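# Reading and writing the pipeline's tabular artifacts. All files are
# plain CSV/TSV with documented headers; missing peak areas are empty
# cells (zero is a legal measured value, distinct from missing).

transition_cols <- c("sample_id", "replicate", "protein", "peptide",
                     "label", "precursor_mz", "product_mz", "peak_area")
sample_sheet_cols <- c("sample_id", "cohort_label", "lysate_amount",
                       "spike_amount", "platform")
cohort_labels_ok <- c("responder", "non-responder",
                      "PD", "SD", "PR", "CR", "unknown")

delim_for <- function(dialect) switch(dialect, csv = ",", tsv = "\t")

read_delim_quiet <- function(path, dialect, col_types) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  readr::read_delim(path, delim = delim_for(dialect), col_types = col_types,
                    na = c("", "NA"), progress = FALSE,
                    show_col_types = FALSE)
}

#' Read or write a long-format transition table
#'
#' One row per measured transition: `sample_id`, `replicate` (>= 1),
#' `protein`, `peptide` (uppercase sequence), `label` (`light` or
#' `heavy`), `precursor_mz`, `product_mz` (Th) and `peak_area`
#' (intensity >= 0, empty cell when not measured). Reading validates the
#' schema and fails on unknown labels or duplicated
#' (sample, replicate, peptide, label, product_mz) keys, naming the
#' offending row.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `read_transition_table()` returns a tibble of transition
#'   records; `write_transition_table()` returns `path` invisibly.
#' @export
read_transition_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  x <- read_delim_quiet(path, dialect, readr::cols(
    sample_id = readr::col_character(),
    replicate = readr::col_integer(),
    protein = readr::col_character(),
    peptide = readr::col_character(),
    label = readr::col_character(),
    precursor_mz = readr::col_double(),
    product_mz = readr::col_double(),
    peak_area = readr::col_double()
  ))
  missing_cols <- setdiff(transition_cols, names(x))
  if (length(missing_cols)) {
    stop(sprintf("transition table lacks columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  validate_transitions(x[transition_cols])
}

validate_transitions <- function(x) {
  x <- tibble::as_tibble(x)
  bad_label <- which(!x$label %in% c("light", "heavy"))
  if (length(bad_label)) {
    stop(sprintf("unknown label %s in transition row %d",
                 dQuote(x$label[bad_label[1]]), bad_label[1]),
         call. = FALSE)
  }
  if (any(is.na(x$peptide)) || any(x$peptide == "") ||
      any(grepl("[^A-Z]", x$peptide))) {
    stop("peptide sequences must be non-empty uppercase strings",
         call. = FALSE)
  }
  if (any(!is.na(x$peak_area) & x$peak_area < 0)) {
    stop("peak_area must be >= 0 when present", call. = FALSE)
  }
  if (any(is.na(x$replicate) | x$replicate < 1)) {
    stop("replicate must be an index >= 1", call. = FALSE)
  }
  key <- paste(x$sample_id, x$replicate, x$peptide, x$label, x$product_mz,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf(
      "duplicate transition (sample %s, replicate %s, peptide %s, %s, product m/z %s) at row %d",
      x$sample_id[dup[1]], x$replicate[dup[1]], x$peptide[dup[1]],
      x$label[dup[1]], format(x$product_mz[dup[1]]), dup[1]
    ), call. = FALSE)
  }
  x
}

#' @rdname read_transition_table
#' @param x Tibble of transition records.
#' @export
write_transition_table <- function(x, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  x <- validate_transitions(x[transition_cols])
  readr::write_delim(x, path, delim = delim_for(dialect), na = "")
  invisible(path)
}

#' Read or write a sample sheet
#'
#' One row per sample: `sample_id`, `cohort_label` (one of `responder`,
#' `non-responder`, the RECIST codes `PD`/`SD`/`PR`/`CR`, or `unknown`),
#' `lysate_amount` (ug, > 0), `spike_amount` (fmol heavy standard per
#' peptide, > 0) and `platform` (`fresh_frozen` or `ffpe`).
#'
#' @param path File path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return A tibble of sample records.
#' @export
read_sample_sheet <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  x <- read_delim_quiet(path, dialect, readr::cols(
    sample_id = readr::col_character(),
    cohort_label = readr::col_character(),
    lysate_amount = readr::col_double(),
    spike_amount = readr::col_double(),
    platform = readr::col_character()
  ))
  missing_cols <- setdiff(sample_sheet_cols, names(x))
  if (length(missing_cols)) {
    stop(sprintf("sample sheet lacks columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  validate_sample_sheet(x[sample_sheet_cols])
}

validate_sample_sheet <- function(x) {
  x <- tibble::as_tibble(x)
  bad <- which(!is.na(x$cohort_label) & !x$cohort_label %in% cohort_labels_ok)
  if (length(bad)) {
    stop(sprintf("unknown cohort label %s in sample-sheet row %d (allowed: %s)",
                 dQuote(x$cohort_label[bad[1]]), bad[1],
                 paste(cohort_labels_ok, collapse = ", ")), call. = FALSE)
  }
  if (any(is.na(x$lysate_amount) | x$lysate_amount <= 0)) {
    stop("lysate_amount must be > 0", call. = FALSE)
  }
  if (any(is.na(x$spike_amount) | x$spike_amount <= 0)) {
    stop("spike_amount must be > 0", call. = FALSE)
  }
  bad_platform <- which(!is.na(x$platform) &
                          !x$platform %in% c("fresh_frozen", "ffpe"))
  if (length(bad_platform)) {
    stop(sprintf("unknown platform %s in sample-sheet row %d",
                 dQuote(x$platform[bad_platform[1]]), bad_platform[1]),
         call. = FALSE)
  }
  if (anyDuplicated(x$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  x
}

#' @rdname read_sample_sheet
#' @param x Tibble of sample records.
#' @export
write_sample_sheet <- function(x, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  x <- validate_sample_sheet(x[sample_sheet_cols])
  readr::write_delim(x, path, delim = delim_for(dialect), na = "")
  invisible(path)
}

#' Expand RECIST codes to clinical response classes
#'
#' Maps RECIST categories onto the binary response labels the signature
#' is calibrated against: `PR` and `CR` are responders, `PD` and `SD`
#' non-responders; `responder`/`non-responder` pass through and
#' `unknown` becomes `NA`.
#'
#' @param cohort_label Character vector of cohort labels.
#' @return Character vector of `"responder"`/`"non-responder"`/`NA`.
#' @export
response_class <- function(cohort_label) {
  out <- dplyr::case_match(
    cohort_label,
    c("PR", "CR", "responder") ~ "responder",
    c("PD", "SD", "non-responder") ~ "non-responder",
    .default = NA_character_
  )
  bad <- !is.na(cohort_label) & is.na(out) & cohort_label != "unknown"
  if (any(bad)) {
    stop(sprintf("unknown cohort label %s", dQuote(cohort_label[bad][1])),
         call. = FALSE)
  }
  out
}

#' Read or write an assay-qualification summary
#'
#' One row per peptide: `peptide`, `rule_set`, `lod_fmol`, `lloq_fmol`,
#' `qualified`, `slope`, `intercept`, `r_squared`.
#'
#' @param path File path.
#' @param x Qualification summary tibble (as produced by
#'   [qualify_assays()]).
#' @return A tibble (reading) or `path` invisibly (writing).
#' @export
read_qualification <- function(path) {
  read_delim_quiet(path, "csv", readr::cols(
    peptide = readr::col_character(),
    rule_set = readr::col_character(),
    lod_fmol = readr::col_double(),
    lloq_fmol = readr::col_double(),
    qualified = readr::col_logical(),
    slope = readr::col_double(),
    intercept = readr::col_double(),
    r_squared = readr::col_double()
  ))
}

#' @rdname read_qualification
#' @export
write_qualification <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, na = "")
  invisible(path)
}
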