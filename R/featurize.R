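#' Fixed-interval window configuration
#'
#' History before each patient's index date is cut into `n_windows` contiguous
#' fixed-length windows counting backward from the index date; window
#' `n_windows` is the most recent ("current") window. Events older than
#' `lookback_cap_days` are discarded. Index-day events are excluded by default
#' as a leakage guard: the forecast must precede the visit it predicts.
#' Missing continuous values are filled with `missing_sentinel` (default 0, a
#' value chosen to never represent an observed measurement under the package's
#' conventions; note CDAI 0 is clinically attainable — see the package
#' vignette for why zero is nevertheless used).
#'
#' @param n_windows number of windows (default 4).
#' @param window_days days per window (default 120).
#' @param lookback_cap_days maximum history depth; default
#'   `n_windows * window_days` (4 full windows). Set to 365 to cap at one
#'   calendar year.
#' @param include_index_day should events dated on the index day enter the
#'   most recent window? Default `FALSE`.
#' @param missing_sentinel fill value for empty continuous cells.
#' @param carry_forward_meds if `TRUE`, a medication's indicator stays 1 in
#'   every window after its first occurrence (default `FALSE`:
#'   first-occurrence window only).
#' @return an object of class `window_config`.
#' @export
#' @examples
#' window_config()
window_config <- function(n_windows = 4L, window_days = 120,
                          lookback_cap_days = n_windows * window_days,
                          include_index_day = FALSE, missing_sentinel = 0,
                          carry_forward_meds = FALSE) {
  stopifnot(n_windows >= 1, window_days > 0, lookback_cap_days > 0)
  structure(list(n_windows = as.integer(n_windows), window_days = window_days,
                 lookback_cap_days = lookback_cap_days,
                 include_index_day = isTRUE(include_index_day),
                 missing_sentinel = missing_sentinel,
                 carry_forward_meds = isTRUE(carry_forward_meds)),
            class = "window_config")
}

#' Feature schema: variable ordering and grouping
#'
#' The time-varying block holds, per window, one 0/1 indicator per medication
#' code (29 DMARDs, 8 corticosteroids) followed by the CDAI, ESR and CRP
#' values — 40 variables per window. The static block is age at index, sex,
#' race, rheumatoid factor and anti-CCP (5 variables). With the default 4
#' windows the flattened feature vector has 4 x 40 + 5 = 165 columns. The
#' group map sends each time-varying variable to its column indices across
#' windows, for grouped permutation importance.
#'
#' @param cfg a [window_config()].
#' @return an object of class `feature_schema` with elements `tv_vars`,
#'   `static_vars`, `n_windows`, `total_dim`, `flat_names`, `group_map`.
#' @export
#' @examples
#' feature_schema(window_config())$total_dim
feature_schema <- function(cfg = window_config()) {
  vocab <- medication_codes()
  tv_vars <- c(vocab$med_code, "cdai", "esr", "crp")
  static_vars <- c("age", "sex", "race", "rf_positive", "ccp_positive")
  p <- length(tv_vars); Tn <- cfg$n_windows
  flat_names <- c(as.vector(outer(tv_vars, seq_len(Tn),
                                  function(v, w) paste0(v, "@w", w))),
                  static_vars)
  group_map <- lapply(seq_len(p), function(v) v + (seq_len(Tn) - 1L) * p)
  names(group_map) <- tv_vars
  structure(list(tv_vars = tv_vars, static_vars = static_vars,
                 n_windows = Tn, n_tv = p,
                 total_dim = Tn * p + length(static_vars),
                 flat_names = flat_names, group_map = group_map,
                 med_classes = stats::setNames(vocab$med_class, vocab$med_code)),
            class = "feature_schema")
}

#' Assign an event to a lookback window
#'
#' With windows numbered 1 (oldest) to `n_windows` (most recent), an event
#' `d` days before the index date falls in window
#' `n_windows - floor(d / window_days)` when `d < lookback_cap_days`; events
#' at or beyond the cap are discarded (`NA`). An event on the index day
#' (`d = 0`) is discarded unless `include_index_day` is set.
#'
#' @param event_date,index_date `Date` vectors (recycled).
#' @param cfg a [window_config()].
#' @return integer window index, or `NA` for discarded events. Events dated
#'   after the index raise an error (leakage guard).
#' @export
#' @examples
#' idx <- as.Date("2015-06-01")
#' assign_window(idx - c(10, 130, 480), idx, window_config())
assign_window <- function(event_date, index_date, cfg = window_config()) {
  d <- as.numeric(as.Date(index_date) - as.Date(event_date))
  if (any(d < 0)) stop("event after index date: leakage guard")
  w <- cfg$n_windows - floor(d / cfg$window_days)
  w[d >= cfg$lookback_cap_days] <- NA_integer_
  if (!cfg$include_index_day) w[d == 0] <- NA_integer_
  as.integer(w)
}

#' Reduce a window's dated values to the most recent one
#'
#' @param values numeric values sharing one variable and window.
#' @param dates matching `Date` vector; ties on the latest date are broken by
#'   keeping the last value in input order.
#' @return the most recent value, or `NA` if none.
#' @export
reduce_window <- function(values, dates) {
  if (!length(values)) return(NA_real_)
  i <- which(dates == max(dates))
  values[i[length(i)]]
}

#' Per-window first-occurrence medication indicators
#'
#' Only the chronologically first event of each medication code is considered
#' (treatment stop dates are unreliable in EHRs, so later re-prescriptions
#' carry no information about the start of therapy). The indicator is 1 in the
#' first event's window and 0 elsewhere; with `carry_forward_meds` it stays 1
#' in all later windows.
#'
#' @param med_events data.frame with columns `date`, `med_code` for one
#'   patient, all dated on or before `index_date`.
#' @param index_date the patient's index date.
#' @param cfg a [window_config()].
#' @param schema a [feature_schema()].
#' @return integer matrix `n_windows x n_med_codes` of 0/1 indicators.
#' @export
encode_medications <- function(med_events, index_date, cfg = window_config(),
                               schema = feature_schema(cfg)) {
  codes <- names(schema$med_classes)
  out <- matrix(0L, cfg$n_windows, length(codes), dimnames = list(NULL, codes))
  if (!nrow(med_events)) return(out)
  ev <- med_events[order(med_events$date), , drop = FALSE]
  first <- ev[!duplicated(ev$med_code), , drop = FALSE]
  w <- assign_window(first$date, index_date, cfg)
  keep <- !is.na(w) & first$med_code %in% codes
  for (k in which(keep)) {
    ws <- if (cfg$carry_forward_meds) w[k]:cfg$n_windows else w[k]
    out[ws, first$med_code[k]] <- 1L
  }
  out
}

race_code <- function(race) match(race, RACE_LEVELS)
sex_code <- function(sex) as.integer(sex == "female")

#' Assemble one patient's feature sample
#'
#' Builds the windowed tensor for a single cohort member: CDAI, ESR and CRP
#' per window via [assign_window()] + [reduce_window()] (missing cells take
#' the sentinel), medication indicators via [encode_medications()], and the
#' static vector (age at index in integer years, sex, race code, RF,
#' anti-CCP). The index visit's own CDAI — the prediction target — never
#' enters the features.
#'
#' @param member one row of a [build_cohort()] data.frame.
#' @param tables EHR tables (may be pre-filtered to the patient).
#' @param cfg a [window_config()].
#' @param schema a [feature_schema()].
#' @return list with `patient_id`, `tv` (`n_windows x n_tv` matrix), `static`,
#'   `label`, `label_category`.
#' @export
assemble <- function(member, tables, cfg = window_config(),
                     schema = feature_schema(cfg)) {
  pid <- member$patient_id
  idx <- member$index_date
  tv <- matrix(cfg$missing_sentinel, cfg$n_windows, schema$n_tv,
               dimnames = list(NULL, schema$tv_vars))

  fill <- function(var, dates, values) {
    keep <- dates <= idx
    dates <- dates[keep]; values <- values[keep]
    w <- assign_window(dates, idx, cfg)
    for (ww in unique(w[!is.na(w)])) {
      sel <- !is.na(w) & w == ww
      tv[ww, var] <<- reduce_window(values[sel], dates[sel])
    }
  }
  cd <- tables$cdai[tables$cdai$patient_id == pid, , drop = FALSE]
  fill("cdai", cd$date, cd$cdai_score)
  lb <- tables$labs[tables$labs$patient_id == pid, , drop = FALSE]
  esr <- lb[lb$lab_name == "ESR", , drop = FALSE]
  crp <- lb[lb$lab_name == "CRP", , drop = FALSE]
  fill("esr", esr$date, esr$value)
  fill("crp", crp$date, crp$value)

  me <- tables$meds[tables$meds$patient_id == pid & tables$meds$date <= idx, , drop = FALSE]
  tv[, names(schema$med_classes)] <- encode_medications(me, idx, cfg, schema)

  dm <- tables$demographics[tables$demographics$patient_id == pid, , drop = FALSE]
  static <- c(age = as.integer(format(idx, "%Y")) - dm$birth_year,
              sex = sex_code(dm$sex), race = race_code(dm$race),
              rf_positive = dm$rf_positive, ccp_positive = dm$ccp_positive)
  names(static) <- schema$static_vars
  list(patient_id = pid, tv = tv, static = static,
       label = member$outcome_binary, label_category = member$outcome_category)
}

#' Featurize an entire cohort
#'
#' Applies [assemble()] to every cohort member and stacks the results into a
#' sample container used by the models: a 3-D array of time-varying features,
#' a static matrix, a flattened design matrix, and the labels.
#'
#' @param cohort a [build_cohort()] data.frame.
#' @param tables EHR tables list.
#' @param cfg a [window_config()].
#' @return an object of class `ra_features` with elements `x`
#'   (`n x n_windows x n_tv` array), `static` (`n x 5`), `flat`
#'   (`n x total_dim`, columns named `<var>@w<window>` then statics), `y`
#'   (1 = uncontrolled), `label`, `category`, `patient_id`, `schema`, `cfg`.
#' @export
featurize_cohort <- function(cohort, tables, cfg = window_config()) {
  schema <- feature_schema(cfg)
  n <- nrow(cohort)
  Tn <- cfg$n_windows; p <- schema$n_tv
  x <- array(cfg$missing_sentinel, c(n, Tn, p),
             dimnames = list(NULL, NULL, schema$tv_vars))
  static <- matrix(0, n, length(schema$static_vars),
                   dimnames = list(NULL, schema$static_vars))
  # pre-split tables by patient to avoid repeated full-table scans
  sub <- function(tab) split(seq_len(nrow(tab)), tab$patient_id)
  si <- list(cdai = sub(tables$cdai), labs = sub(tables$labs),
             meds = sub(tables$meds), demographics = sub(tables$demographics))
  for (i in seq_len(n)) {
    pid <- cohort$patient_id[i]
    mini <- list(
      cdai = tables$cdai[si$cdai[[pid]], , drop = FALSE],
      labs = tables$labs[si$labs[[pid]] %||% integer(0), , drop = FALSE],
      meds = tables$meds[si$meds[[pid]] %||% integer(0), , drop = FALSE],
      demographics = tables$demographics[si$demographics[[pid]], , drop = FALSE])
    s <- assemble(cohort[i, ], mini, cfg, schema)
    x[i, , ] <- s$tv
    static[i, ] <- s$static
  }
  # window-major blocks: all variables of window 1, then window 2, ...
  flat <- do.call(cbind, lapply(seq_len(Tn), function(w)
    matrix(x[, w, ], nrow = n)))
  flat <- cbind(flat, static)
  colnames(flat) <- schema$flat_names
  structure(list(x = x, static = static, flat = flat,
                 y = as.integer(cohort$outcome_binary == "uncontrolled"),
                 label = cohort$outcome_binary,
                 category = cohort$outcome_category,
                 prior_outcome = cohort$prior_outcome_binary,
                 patient_id = cohort$patient_id,
                 schema = schema, cfg = cfg),
            class = "ra_features")
}

#' @export
print.ra_features <- function(x, ...) {
  cat(sprintf("<ra_features: %d samples, %d windows x %d vars + %d static (%d total)>\n",
              length(x$y), x$cfg$n_windows, x$schema$n_tv,
              length(x$schema$static_vars), x$schema$total_dim))
  invisible(x)
}

#' Subset a feature container by sample index or patient id
#'
#' @param x an `ra_features` object.
#' @param i integer/logical index, or character patient ids.
#' @param ... unused.
#' @return an `ra_features` object with the selected samples.
#' @export
`[.ra_features` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$patient_id)
  out <- x
  out$x <- x$x[i, , , drop = FALSE]
  out$static <- x$static[i, , drop = FALSE]
  out$flat <- x$flat[i, , drop = FALSE]
  for (f in c("y", "label", "category", "prior_outcome", "patient_id"))
    out[[f]] <- x[[f]][i]
  out
}

n_samples <- function(x) length(x$y)

#' Stratified train/validation/test split
#'
#' Partitions patients into three disjoint sets, stratified by binary outcome.
#' Global set sizes are `round(fraction * n)` for test and validation (train
#' takes the remainder), matching e.g. a test set of 116 from 578 patients at
#' 20%; strata are allocated by largest remainder so the global sizes are hit
#' exactly.
#'
#' @param cohort a [build_cohort()] data.frame (or any data.frame with
#'   `patient_id` and `outcome_binary`).
#' @param fractions numeric of length 3 (train, validation, test) summing
#'   to 1.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return list of character vectors `train`, `validation`, `test`.
#' @export
split_cohort <- function(cohort, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-9)
  n <- nrow(cohort)
  if (n < 3) stop("need at least 3 cohort members to split")
  n_test <- round(fractions[3] * n)
  n_val <- round(fractions[2] * n)
  strata <- split(cohort$patient_id, cohort$outcome_binary)
  alloc <- function(sizes, k) {
    # largest-remainder apportionment of k across strata of given sizes
    quota <- sizes * k / sum(sizes)
    base <- floor(quota)
    extra <- k - sum(base)
    if (extra > 0) {
      ord <- order(quota - base, decreasing = TRUE)
      base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
    }
    base
  }
  sizes <- vapply(strata, length, integer(1))
  k_test <- alloc(sizes, n_test)
  k_val <- alloc(sizes - k_test, n_val)
  set.seed(as.integer(seed))
  test <- character(0); val <- character(0); train <- character(0)
  for (s in seq_along(strata)) {
    ids <- sample(strata[[s]])
    test <- c(test, ids[seq_len(k_test[s])])
    val <- c(val, ids[k_test[s] + seq_len(k_val[s])])
    train <- c(train, ids[-(seq_len(k_test[s] + k_val[s]))])
  }
  list(train = sort(train), validation = sort(val), test = sort(test))
}

#' Write features as a flat CSV plus a JSON schema
#'
#' @param features an `ra_features` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_features <- function(features, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(features$flat)
  df$label <- features$label
  df$category <- features$category
  df <- cbind(patient_id = features$patient_id, df)
  utils::write.csv(df, file.path(dir, "features.csv"), row.names = FALSE)
  sc <- features$schema
  jsonlite::write_json(list(tv_vars = sc$tv_vars, static_vars = sc$static_vars,
                            n_windows = sc$n_windows, total_dim = sc$total_dim,
                            flat_names = sc$flat_names,
                            window_days = features$cfg$window_days),
                       file.path(dir, "schema.json"), auto_unbox = TRUE)
  invisible(dir)
}
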