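#' Cohort inclusion rules
#'
#' Encodes the inclusion criteria applied to an EHR extract: at least two
#' RA-related ICD-9 diagnosis codes (714.0, 714.1, 714.2) spaced a minimum of
#' 30 days apart, at least one DMARD prescription, at least two CDAI scores,
#' and at least one inflammation lab (ESR or CRP). An optional minimum care
#' span (off by default) additionally requires the first and last CDAI to be
#' at least `min_span_days` apart.
#'
#' @param qualifying_icd9 character vector of qualifying diagnosis codes.
#' @param min_code_spacing_days minimum days between two qualifying codes.
#' @param min_dmard_count minimum number of DMARD-class medication events.
#' @param min_cdai_count minimum number of CDAI records.
#' @param required_labs lab names of which at least one record is required.
#' @param min_span_days optional minimum days between first and last CDAI
#'   (`NULL` disables; the care-span requirement is otherwise implied by the
#'   other criteria).
#' @return an object of class `inclusion_rules`.
#' @export
#' @examples
#' inclusion_rules()
inclusion_rules <- function(qualifying_icd9 = QUALIFYING_ICD9,
                            min_code_spacing_days = 30,
                            min_dmard_count = 1L,
                            min_cdai_count = 2L,
                            required_labs = c("ESR", "CRP"),
                            min_span_days = NULL) {
  stopifnot(min_code_spacing_days >= 0, min_dmard_count >= 1, min_cdai_count >= 1)
  structure(list(qualifying_icd9 = qualifying_icd9,
                 min_code_spacing_days = min_code_spacing_days,
                 min_dmard_count = as.integer(min_dmard_count),
                 min_cdai_count = as.integer(min_cdai_count),
                 required_labs = required_labs,
                 min_span_days = min_span_days),
            class = "inclusion_rules")
}

check_tables <- function(tables) {
  needed <- c("demographics", "diagnoses", "cdai", "labs", "meds")
  missing <- setdiff(needed, names(tables))
  if (length(missing)) stop("missing EHR table(s): ", paste(missing, collapse = ", "))
  invisible(tables)
}

#' Apply the cohort inclusion criteria
#'
#' A patient is included iff they have (a) at least two qualifying diagnosis
#' codes on dates at least `min_code_spacing_days` apart, (b) at least
#' `min_dmard_count` DMARD-class medication events (conventional synthetic,
#' biologic, or tofacitinib — corticosteroids do not count), (c) at least
#' `min_cdai_count` CDAI records, and (d) at least one record of a required
#' lab.
#'
#' @param tables EHR tables list.
#' @param rules an [inclusion_rules()].
#' @return character vector of included patient ids, sorted.
#' @export
apply_inclusion <- function(tables, rules = inclusion_rules()) {
  check_tables(tables)
  dx <- tables$diagnoses
  dxq <- dx[dx$icd9_code %in% rules$qualifying_icd9, , drop = FALSE]
  # two codes >= spacing days apart <=> at least 2 codes and max spread >= spacing
  n_codes <- table(dxq$patient_id)
  spread <- tapply(as.numeric(dxq$date), dxq$patient_id, function(d) diff(range(d)))
  ok_dx <- names(spread)[spread >= rules$min_code_spacing_days]
  ok_dx <- intersect(ok_dx, names(n_codes)[n_codes >= 2])

  med <- tables$meds
  dmard <- med[med$med_class %in% DMARD_CLASSES, , drop = FALSE]
  n_dmard <- table(dmard$patient_id)
  ok_med <- names(n_dmard)[n_dmard >= rules$min_dmard_count]

  n_cdai <- table(tables$cdai$patient_id)
  ok_cdai <- names(n_cdai)[n_cdai >= rules$min_cdai_count]

  labs <- tables$labs
  ok_lab <- unique(labs$patient_id[labs$lab_name %in% rules$required_labs])

  ids <- Reduce(intersect, list(ok_dx, ok_med, ok_cdai, ok_lab))

  if (!is.null(rules$min_span_days)) {
    cd <- tables$cdai[tables$cdai$patient_id %in% ids, ]
    span <- tapply(as.numeric(cd$date), cd$patient_id, function(d) diff(range(d)))
    ids <- intersect(ids, names(span)[span >= rules$min_span_days])
  }
  sort(intersect(ids, tables$demographics$patient_id))
}

#' Bin a CDAI score into the four disease-activity categories
#'
#' Remission is CDAI <= 2.8; low activity (2.8, 10\]; moderate (10, 22\];
#' high > 22.
#'
#' @param score numeric vector of CDAI scores in \[0, 72\].
#' @return character vector in `{"remission","low","moderate","high"}`.
#' @export
#' @examples
#' bin_cdai(c(0, 2.8, 10, 22, 22.01))
bin_cdai <- function(score) {
  if (any(!is.finite(score)) || any(score < 0 | score > 72))
    stop("CDAI score outside [0, 72]")
  ifelse(score <= 2.8, "remission",
         ifelse(score <= 10, "low",
                ifelse(score <= 22, "moderate", "high")))
}

#' Binary disease-activity state from a CDAI score
#'
#' Controlled (remission or low activity) is CDAI <= 10; uncontrolled
#' (moderate or high) is CDAI > 10. Consistent with [bin_cdai()] by
#' construction.
#'
#' @param score numeric vector of CDAI scores in \[0, 72\].
#' @return character vector in `{"controlled","uncontrolled"}`.
#' @export
#' @examples
#' label_binary(c(10, 10.1, 72))
label_binary <- function(score) {
  if (any(!is.finite(score)) || any(score < 0 | score > 72))
    stop("CDAI score outside [0, 72]")
  ifelse(score <= 10, "controlled", "uncontrolled")
}

#' Build the forecasting cohort
#'
#' Applies the inclusion criteria, then for each included patient takes the
#' chronologically last CDAI visit as the index visit (the prediction target)
#' and the penultimate CDAI visit as the source of the prior outcome. Two CDAI
#' records on the same date are resolved by keeping the last in table order
#' (with a warning).
#'
#' @param tables EHR tables list.
#' @param rules an [inclusion_rules()].
#' @return data.frame with one row per patient: `patient_id`, `index_date`,
#'   `index_cdai`, `prior_date`, `prior_cdai`, `outcome_binary`,
#'   `outcome_category`, `prior_outcome_binary`.
#' @export
build_cohort <- function(tables, rules = inclusion_rules()) {
  ids <- apply_inclusion(tables, rules)
  if (!length(ids)) stop("no patients satisfy the inclusion criteria")
  cd <- tables$cdai[tables$cdai$patient_id %in% ids, , drop = FALSE]
  # stable sort by (patient, date) keeps table order within a date
  cd <- cd[order(cd$patient_id, cd$date), , drop = FALSE]
  dup <- duplicated(cd[, c("patient_id", "date")])
  if (any(dup)) {
    warning(sum(dup), " duplicate same-date CDAI record(s); keeping the last by table order")
    cd <- cd[is_last_in_group(paste(cd$patient_id, cd$date)), , drop = FALSE]
    # a patient may drop below the minimum CDAI count after deduplication
    n_left <- table(cd$patient_id)
    keep <- names(n_left)[n_left >= rules$min_cdai_count]
    cd <- cd[cd$patient_id %in% keep, , drop = FALSE]
    ids <- intersect(ids, keep)
  }
  idx <- which(is_last_in_group(cd$patient_id))
  prior <- idx - 1L
  if (any(cd$patient_id[prior] != cd$patient_id[idx]))
    stop("internal consistency error: included patient with fewer than 2 CDAI records")
  data.frame(
    patient_id = cd$patient_id[idx],
    index_date = cd$date[idx],
    index_cdai = cd$cdai_score[idx],
    prior_date = cd$date[prior],
    prior_cdai = cd$cdai_score[prior],
    outcome_binary = label_binary(cd$cdai_score[idx]),
    outcome_category = bin_cdai(cd$cdai_score[idx]),
    prior_outcome_binary = label_binary(cd$cdai_score[prior]),
    stringsAsFactors = FALSE
  )
}

#' Write / read a cohort table as CSV
#'
#' @param cohort a [build_cohort()] data.frame.
#' @param file path to a CSV file.
#' @return the file path (write) or the cohort data.frame (read).
#' @export
write_cohort <- function(cohort, file) {
  utils::write.csv(cohort, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  x$index_date <- as.Date(x$index_date)
  x$prior_date <- as.Date(x$prior_date)
  x
}
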