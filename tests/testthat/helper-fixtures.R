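# Shared fixtures, all generated in code.

# A hand-built five-table extract for one or more patients, default fully
# qualifying: 2 codes 30 days apart, 1 csDMARD, 2 CDAI scores, 1 ESR.
make_patient_tables <- function(patient_id = "P1",
                                dx_days = c(0, 30),
                                dx_codes = c("714.0", "714.0"),
                                med_days = 5, med_codes = "DMARD_01",
                                med_classes = "csDMARD",
                                cdai_days = c(10, 200),
                                cdai_scores = c(4, 15),
                                lab_days = 10, lab_names = "ESR",
                                lab_values = 20,
                                birth_year = 1960L, sex = "female",
                                race = "white", rf = 1L, ccp = 0L,
                                origin = as.Date("2014-01-01")) {
  list(
    demographics = data.frame(patient_id = patient_id, birth_year = birth_year,
                              sex = sex, race = race, rf_positive = rf,
                              ccp_positive = ccp, stringsAsFactors = FALSE),
    diagnoses = data.frame(patient_id = patient_id, date = origin + dx_days,
                           icd9_code = dx_codes, stringsAsFactors = FALSE),
    cdai = data.frame(patient_id = patient_id, date = origin + cdai_days,
                      cdai_score = cdai_scores, stringsAsFactors = FALSE),
    labs = data.frame(patient_id = patient_id, date = origin + lab_days,
                      lab_name = lab_names, value = lab_values,
                      stringsAsFactors = FALSE),
    meds = data.frame(patient_id = patient_id, date = origin + med_days,
                      med_code = med_codes, med_class = med_classes,
                      stringsAsFactors = FALSE)
  )
}

bind_tables <- function(...) {
  parts <- list(...)
  out <- lapply(names(parts[[1]]), function(nm)
    do.call(rbind, lapply(parts, `[[`, nm)))
  names(out) <- names(parts[[1]])
  out
}

# Build an ra_features object directly from arrays (bypassing the EHR path),
# for toy-model tests. Label = 1 (uncontrolled) decided by the caller.
make_toy_features <- function(x, static, y, cfg = window_config()) {
  schema <- feature_schema(cfg)
  n <- dim(x)[1]
  stopifnot(dim(x)[2] == cfg$n_windows, dim(x)[3] == schema$n_tv)
  dimnames(x) <- list(NULL, NULL, schema$tv_vars)
  colnames(static) <- schema$static_vars
  flat <- do.call(cbind, lapply(seq_len(cfg$n_windows), function(w)
    matrix(x[, w, ], nrow = n)))
  flat <- cbind(flat, static)
  colnames(flat) <- schema$flat_names
  structure(list(x = x, static = static, flat = flat, y = as.integer(y),
                 label = ifelse(y == 1, "uncontrolled", "controlled"),
                 category = ifelse(y == 1, "moderate", "low"),
                 prior_outcome = ifelse(y == 1, "uncontrolled", "controlled"),
                 patient_id = sprintf("T%04d", seq_len(n)),
                 schema = schema, cfg = cfg),
            class = "ra_features")
}

# Linearly separable toy set: the most recent window's CDAI carries the label.
make_separable_features <- function(n = 20, seed = 1) {
  set.seed(seed)
  cfg <- window_config()
  schema <- feature_schema(cfg)
  x <- array(0, c(n, cfg$n_windows, schema$n_tv))
  y <- rep_len(c(0L, 1L), n)
  cdai_slot <- which(schema$tv_vars == "cdai")
  x[, 4, cdai_slot] <- ifelse(y == 1, 25, 4) + stats::rnorm(n, sd = 0.5)
  x[, 3, cdai_slot] <- stats::rnorm(n, 10, 3)
  static <- cbind(stats::rnorm(n, 57, 10), stats::rbinom(n, 1, 0.8),
                  sample(1:5, n, TRUE), stats::rbinom(n, 1, 0.7),
                  stats::rbinom(n, 1, 0.6))
  make_toy_features(x, static, y, cfg)
}

fast_hp <- function(...) {
  args <- utils::modifyList(
    list(td_units = 8L, gru_units = c(8L), dropout = 0, l2_penalty = 1e-5,
         learning_rate = 1e-2, max_epochs = 60L, patience = 60L,
         batch_size = 8L, seed = 1L), list(...))
  do.call(hyperparams, args)
}

# Lazily built medium synthetic cohort shared across model tests.
.fixture_env <- new.env(parent = emptyenv())
medium_cohort <- function() {
  if (is.null(.fixture_env$medium)) {
    p <- hospital_profile("university", n_patients = 400, seed = 7)
    sim <- generate_ehr(p)
    cohort <- build_cohort(sim$tables)
    fx <- featurize_cohort(cohort, sim$tables)
    sp <- split_cohort(cohort, seed = 7)
    .fixture_env$medium <- list(profile = p, sim = sim, cohort = cohort,
                                features = fx, split = sp,
                                train = fx[sp$train], validation = fx[sp$validation],
                                test = fx[sp$test])
  }
  .fixture_env$medium
}

# Independent brute-force featurizer: loops over every raw event row and
# recomputes window assignment by date arithmetic, never calling the package's
# vectorized path. Used as the oracle for assemble()/featurize_cohort().
brute_force_features <- function(member, tables, cfg = window_config()) {
  schema <- feature_schema(cfg)
  Tn <- cfg$n_windows
  tv <- matrix(cfg$missing_sentinel, Tn, schema$n_tv,
               dimnames = list(NULL, schema$tv_vars))
  idx <- member$index_date
  win_of <- function(d) {
    if (d < 0) stop("event after index")
    if (d >= cfg$lookback_cap_days) return(NA_integer_)
    if (d == 0 && !cfg$include_index_day) return(NA_integer_)
    Tn - floor(d / cfg$window_days)
  }
  # continuous variables: most recent value per window, table order on ties
  for (spec in list(list(var = "cdai", tab = tables$cdai, val = "cdai_score",
                         filt = TRUE),
                    list(var = "esr", tab = tables$labs, val = "value",
                         filt = tables$labs$lab_name == "ESR"),
                    list(var = "crp", tab = tables$labs, val = "value",
                         filt = tables$labs$lab_name == "CRP"))) {
    tab <- spec$tab[spec$tab$patient_id == member$patient_id & spec$filt, , drop = FALSE]
    best_date <- rep(as.Date(NA), Tn)
    for (r in seq_len(nrow(tab))) {
      if (tab$date[r] > idx) next
      w <- win_of(as.numeric(idx - tab$date[r]))
      if (is.na(w)) next
      if (is.na(best_date[w]) || tab$date[r] >= best_date[w]) {
        best_date[w] <- tab$date[r]
        tv[w, spec$var] <- tab[[spec$val]][r]
      }
    }
  }
  meds <- tables$meds[tables$meds$patient_id == member$patient_id, , drop = FALSE]
  meds <- meds[meds$date <= idx, , drop = FALSE]
  for (code in unique(meds$med_code)) {
    ev <- meds[meds$med_code == code, , drop = FALSE]
    first_date <- min(ev$date)
    w <- win_of(as.numeric(idx - first_date))
    if (!is.na(w)) {
      ws <- if (cfg$carry_forward_meds) w:Tn else w
      tv[ws, code] <- 1
    }
  }
  dm <- tables$demographics[tables$demographics$patient_id == member$patient_id, ]
  static <- c(as.integer(format(idx, "%Y")) - dm$birth_year,
              as.integer(dm$sex == "female"),
              match(dm$race, c("white", "african_american", "hispanic",
                               "asian", "other")),
              dm$rf_positive, dm$ccp_positive)
  names(static) <- schema$static_vars
  list(tv = tv, static = static)
}

# Large strong-signal cohort shared by the signal-recovery, transfer and
# learning-curve checks (built once per test run).
strong_cohort <- function() {
  if (is.null(.fixture_env$strong)) {
    p <- hospital_profile("university", n_patients = 2000, seed = 11)
    sim <- generate_ehr(p)
    cohort <- build_cohort(sim$tables)
    fx <- featurize_cohort(cohort, sim$tables)
    sp <- split_cohort(cohort, seed = 2)
    hp <- hyperparams(seed = 3)
    model <- train_forecaster(fx[sp$train], fx[sp$validation], hp)
    .fixture_env$strong <- list(
      profile = p, sim = sim, cohort = cohort, features = fx, split = sp,
      train = fx[sp$train], validation = fx[sp$validation], test = fx[sp$test],
      hp = hp, model = model)
  }
  .fixture_env$strong
}
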