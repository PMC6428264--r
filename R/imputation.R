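# Below-LLOQ imputation: left-censored peptide values get a stochastic
# draw under the LLOQ; two deterministic group-median variants support
# classifier training and blinded application.

#' Impute left-censored (below-LLOQ) peptide values
#'
#' Every missing or below-LLOQ peptide value in a per-replicate peptide
#' table receives a draw `u ~ Uniform(0, LLOQ)` for its peptide's LLOQ.
#' When more than one peptide of the *same protein* is missing within
#' one (sample, replicate) measurement, each such cell's final value is
#' a second draw from `Normal(mean = its u, sd = cv_second_draw * u)`,
#' adding the extra spread expected of concentrations this low.
#' Non-positive second draws are resampled (at CV 0.25 the probability
#' of a non-positive draw is ~3e-5, so resampling leaves the
#' distribution essentially untouched). Measured cells are never
#' modified.
#'
#' @param peptides Per-replicate peptide table with columns `sample_id`,
#'   `replicate`, `protein`, `peptide`, `concentration` and (optionally)
#'   `below_lloq`/`detected` flags, as produced by
#'   [quantify_samples()]. A cell is imputed when its concentration is
#'   missing or flagged below LLOQ.
#' @param lloq Per-peptide LLOQ in amol/ug: a single number or a named
#'   vector covering every imputed peptide. Defaults to the table's own
#'   `lloq` column when present.
#' @param cv_second_draw Fractional CV of the conditional second draw
#'   (default 0.25).
#' @param seed Optional integer seed; with a seed the result is a pure
#'   function of its inputs.
#' @return A list:
#'   * `peptides`: the completed table, imputed cells marked
#'     `imputed = TRUE` (and `detected = TRUE`, `below_lloq = FALSE`);
#'   * `audit`: one row per imputed cell with the uniform draw `u`,
#'     the final `value` and whether a `second_draw` occurred.
#' @examples
#' tab <- tibble::tibble(sample_id = "S1", replicate = 1,
#'                       protein = "CLIC3",
#'                       peptide = c("GFTVPEAFR", "ADLSLLGK"),
#'                       concentration = c(NA, 250))
#' impute_below_lloq(tab, lloq = 100, seed = 1)$audit
#' @export
impute_below_lloq <- function(peptides, lloq = NULL, cv_second_draw = 0.25,
                              seed = NULL) {
  peptides <- tibble::as_tibble(peptides)
  check_scalar_number(cv_second_draw, "cv_second_draw", nonneg = TRUE)
  need <- c("sample_id", "replicate", "protein", "peptide", "concentration")
  stopifnot(all(need %in% names(peptides)))

  missing_cell <- is.na(peptides$concentration)
  if ("below_lloq" %in% names(peptides)) {
    missing_cell <- missing_cell |
      (!is.na(peptides$below_lloq) & peptides$below_lloq)
  }

  if (is.null(lloq)) {
    if (!"lloq" %in% names(peptides)) {
      stop("supply `lloq` or include an `lloq` column", call. = FALSE)
    }
    lloq_vec <- peptides$lloq
  } else {
    check_numeric_vec(lloq, "lloq", positive = TRUE)
    if (length(lloq) == 1L && is.null(names(lloq))) {
      lloq_vec <- rep(lloq, nrow(peptides))
    } else {
      lloq_vec <- unname(lloq[peptides$peptide])
    }
  }
  if (any(missing_cell & (is.na(lloq_vec) | lloq_vec <= 0))) {
    bad <- peptides$peptide[missing_cell & (is.na(lloq_vec) | lloq_vec <= 0)]
    stop(sprintf("no LLOQ available for missing peptide(s): %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }

  draw <- function() {
    idx <- which(missing_cell)
    # deterministic draw order: table order within the missing set
    u <- stats::runif(length(idx), 0, lloq_vec[idx])
    value <- u
    # count missing peptides per (sample, replicate, protein) measurement
    key <- paste(peptides$sample_id[idx], peptides$replicate[idx],
                 peptides$protein[idx], sep = "\r")
    multi <- stats::ave(rep(1L, length(idx)), key, FUN = sum) > 1L
    second <- which(multi)
    for (i in second) {
      repeat {
        v <- stats::rnorm(1, mean = u[i], sd = cv_second_draw * u[i])
        if (v > 0 || cv_second_draw == 0) break
      }
      value[i] <- v
    }
    list(idx = idx, u = u, value = value, second = multi)
  }
  d <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  out <- peptides
  out$concentration[d$idx] <- d$value
  if (!"imputed" %in% names(out)) out$imputed <- FALSE
  out$imputed[d$idx] <- TRUE
  if ("below_lloq" %in% names(out)) out$below_lloq[d$idx] <- FALSE
  if ("detected" %in% names(out)) out$detected[d$idx] <- TRUE

  audit <- tibble::tibble(
    sample_id = peptides$sample_id[d$idx],
    replicate = peptides$replicate[d$idx],
    protein = peptides$protein[d$idx],
    peptide = peptides$peptide[d$idx],
    lloq = lloq_vec[d$idx],
    u = d$u,
    value = d$value,
    second_draw = d$second
  )
  list(peptides = out, audit = audit)
}

check_matrix <- function(mat) {
  mat <- tibble::as_tibble(mat)
  stopifnot("sample_id" %in% names(mat))
  if (!all(vapply(mat[-match("sample_id", names(mat))], is.numeric,
                  logical(1)))) {
    stop("protein columns must be numeric", call. = FALSE)
  }
  mat
}

#' Per-protein medians of the observed values in each response group
#'
#' @param mat Samples x proteins tibble with a `sample_id` column.
#' @param labels `"responder"`/`"non-responder"` per sample (aligned
#'   with the rows of `mat`).
#' @return A tibble with `protein`, `responder_median`,
#'   `nonresponder_median`.
#' @export
group_medians <- function(mat, labels) {
  mat <- check_matrix(mat)
  stopifnot(length(labels) == nrow(mat))
  proteins <- setdiff(names(mat), "sample_id")
  med <- function(p, grp) {
    v <- mat[[p]][labels == grp]
    stats::median(v[!is.na(v)])
  }
  tibble::tibble(
    protein = proteins,
    responder_median = vapply(proteins, med, numeric(1), "responder",
                              USE.NAMES = FALSE),
    nonresponder_median = vapply(proteins, med, numeric(1), "non-responder",
                                 USE.NAMES = FALSE)
  )
}

#' Impute missing protein values to their response-group median
#'
#' Training-time variant: a missing (sample, protein) cell is set to the
#' median of that protein's observed values within the sample's own
#' response group. Requires at least one observed value per protein per
#' group.
#'
#' @inheritParams group_medians
#' @return The completed matrix.
#' @export
impute_group_median <- function(mat, labels) {
  mat <- check_matrix(mat)
  stopifnot(length(labels) == nrow(mat))
  med <- group_medians(mat, labels)
  for (p in med$protein) {
    miss <- is.na(mat[[p]])
    if (!any(miss)) next
    fill <- ifelse(labels == "responder",
                   med$responder_median[med$protein == p],
                   med$nonresponder_median[med$protein == p])
    if (anyNA(fill[miss])) {
      stop(sprintf("no observed values of %s in some response group", p),
           call. = FALSE)
    }
    mat[[p]][miss] <- fill[miss]
  }
  mat
}

#' Impute missing protein values blinded to group membership
#'
#' Blinded-application variant: a missing cell is set to the average of
#' the two training-set group medians for its protein, so no response
#' information about the new sample is used.
#'
#' @param mat Samples x proteins tibble with a `sample_id` column.
#' @param medians Training medians from [group_medians()].
#' @return The completed matrix.
#' @export
impute_blinded <- function(mat, medians) {
  mat <- check_matrix(mat)
  medians <- tibble::as_tibble(medians)
  for (p in setdiff(names(mat), "sample_id")) {
    miss <- is.na(mat[[p]])
    if (!any(miss)) next
    row <- medians[medians$protein == p, ]
    if (nrow(row) != 1L || is.na(row$responder_median) ||
        is.na(row$nonresponder_median)) {
      stop(sprintf("no training medians available for %s", p),
           call. = FALSE)
    }
    mat[[p]][miss] <- (row$responder_median + row$nonresponder_median) / 2
  }
  mat
}
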