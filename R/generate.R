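empty_ehr_tables <- function() {
  list(
    demographics = data.frame(patient_id = character(), birth_year = integer(),
                              sex = character(), race = character(),
                              rf_positive = integer(), ccp_positive = integer(),
                              stringsAsFactors = FALSE),
    diagnoses = data.frame(patient_id = character(), date = as.Date(character()),
                           icd9_code = character(), stringsAsFactors = FALSE),
    cdai = data.frame(patient_id = character(), date = as.Date(character()),
                      cdai_score = numeric(), stringsAsFactors = FALSE),
    labs = data.frame(patient_id = character(), date = as.Date(character()),
                      lab_name = character(), value = numeric(), stringsAsFactors = FALSE),
    meds = data.frame(patient_id = character(), date = as.Date(character()),
                      med_code = character(), med_class = character(), stringsAsFactors = FALSE)
  )
}

#' Generate synthetic EHR event tables for one hospital
#'
#' Simulates a rheumatology clinic's relational EHR extract with the
#' statistical structure the downstream forecasting pipeline assumes:
#' autocorrelated CDAI trajectories on the 0-72 scale driven by a latent AR(1)
#' severity process, inflammation labs (ESR, CRP) that rise monotonically with
#' severity and are missing at random, medication start events whose hazard
#' increases with severity and whose class mix follows the profile, qualifying
#' ICD-9 diagnosis codes (714.0/714.1/714.2), and static demographics and
#' serologies. A configurable fraction of patients deliberately fails one
#' inclusion criterion each (a single diagnosis code, codes under 30 days
#' apart, no DMARD, or fewer than 2 CDAI scores) so the cohort filter can be
#' exercised.
#'
#' The intercept and severity weighting of the CDAI map are calibrated (see
#' [solve_latent_calibration()]) so that the stationary fraction of controlled
#' visits and the visit-to-visit outcome switch rate match the profile's
#' `controlled_target` and `switch_target`. The full latent state is returned
#' as ground truth so that parameter- and signal-recovery tests are possible.
#'
#' @param profile a [hospital_profile()].
#' @param seed integer; defaults to `profile$seed`.
#' @return a list with class `ehr_simulation`:
#'   * `tables`: list of data.frames `demographics`, `diagnoses`, `cdai`,
#'     `labs`, `meds` (the `EHRTables` contract);
#'   * `truth`: per-visit latent state (`z` standardized severity,
#'     `treat_reduction`, `u` latent index, `outcome`, `is_index`), generator
#'     parameters, and realized controlled fraction / switch rate.
#' @export
#' @examples
#' sim <- generate_ehr(hospital_profile("university", n_patients = 50, seed = 3))
#' head(sim$tables$cdai)
#' sim$truth$realized_controlled
generate_ehr <- function(profile, seed = profile$seed) {
  validate_profile(profile)
  p <- profile
  n <- as.integer(p$n_patients)
  cal <- solve_latent_calibration(p$controlled_target, p$switch_target, p$ar_phi)
  w <- cal$w
  noise_sd <- sqrt(max(0, 1 - w^2))
  sd_stat <- if (p$ar_phi < 1) p$ar_sigma / sqrt(1 - p$ar_phi^2) else 0

  if (n == 0L) {
    truth <- list(visits = data.frame(patient_id = character(), visit = integer(),
                                      date = as.Date(character()), z = numeric(),
                                      treat_reduction = numeric(), u = numeric(),
                                      cdai = numeric(), outcome = character(),
                                      is_index = logical(), stringsAsFactors = FALSE),
                  params = c(cal, list(ar_phi = p$ar_phi, t_star = NA_real_,
                                       cdai_scale = p$cdai_scale, profile = unclass(p))),
                  realized_controlled = NA_real_, realized_switch = NA_real_)
    return(structure(list(tables = empty_ehr_tables(), truth = truth),
                     class = "ehr_simulation"))
  }

  set.seed(as.integer(seed))
  meds_vocab <- medication_codes()
  ids <- sprintf("P%05d", seq_len(n))

  # which patients deliberately fail an inclusion criterion, and how
  n_nq <- floor(p$nonqualifying_frac * n)
  modes <- rep("qualifying", n)
  if (n_nq > 0) {
    nq_idx <- sample.int(n, n_nq)
    modes[nq_idx] <- rep(c("single_code", "codes_too_close", "no_dmard", "one_cdai"),
                         length.out = n_nq)
  }

  demo <- vector("list", n); dx <- vector("list", n)
  med <- vector("list", n); vis <- vector("list", n)

  origin <- as.Date("2012-01-01")
  for (i in seq_len(n)) {
    # accumulate plain vectors; data.frames are assembled once after the loop
    nv <- 2L + stats::rpois(1L, p$n_visits_mean)
    gaps <- pmax(1, round(exp(log(p$visit_gap_median_days) +
                                p$visit_gap_dispersion * stats::rnorm(nv - 1L))))
    start <- sample.int(1461L, 1L) - 1L          # day offset from origin
    dates <- start + cumsum(c(0, gaps))

    # standardized latent severity, stationary AR(1)
    z <- numeric(nv)
    z[1] <- stats::rnorm(1L)
    innov_sd <- sqrt(max(0, 1 - p$ar_phi^2))
    for (t in seq_len(nv - 1L)) z[t + 1L] <- p$ar_phi * z[t] + stats::rnorm(1L, sd = innov_sd)
    if (sd_stat == 0) z[] <- 0   # degenerate limit: severity frozen at its mean

    # medication events: per class, ever-prescribed probability rises with the
    # patient's mean severity; the start visit is chosen with weight exp(z)
    zbar <- mean(z)
    med_date <- integer(0); med_code <- character(0); med_class <- character(0)
    bio_start_visit <- NA_integer_
    for (cl in MED_CLASSES) {
      prop <- clip(p$med_propensity[[cl]], 1e-9, 1 - 1e-9)
      ever <- stats::runif(1L) < stats::plogis(stats::qlogis(prop) + 0.35 * zbar)
      if (!ever) next
      sv <- sample.int(nv, 1L, prob = exp(z))
      code <- sample(meds_vocab$med_code[meds_vocab$med_class == cl], 1L)
      med_date <- c(med_date, dates[sv]); med_code <- c(med_code, code)
      med_class <- c(med_class, cl)
      # occasional repeat prescription of the same drug at a later visit
      if (sv < nv && stats::runif(1L) < 0.5) {
        rv <- sv + sample.int(nv - sv, 1L)
        med_date <- c(med_date, dates[rv]); med_code <- c(med_code, code)
        med_class <- c(med_class, cl)
      }
      if (cl == "biologic") bio_start_visit <- sv
    }
    if (modes[i] == "no_dmard" && length(med_class)) {
      keep <- !(med_class %in% DMARD_CLASSES)
      med_date <- med_date[keep]; med_code <- med_code[keep]; med_class <- med_class[keep]
    }

    # a biologic start lowers severity from the next visit onward
    d <- numeric(nv)
    if (!is.na(bio_start_visit) && bio_start_visit < nv)
      d[(bio_start_visit + 1L):nv] <- p$treatment_effect

    # diagnosis events
    if (modes[i] == "single_code") {
      dx_date <- dates[1]; dx_code <- sample(QUALIFYING_ICD9, 1L)
    } else if (modes[i] == "codes_too_close") {
      dx_date <- c(dates[1], dates[1] + 20L)
      dx_code <- sample(QUALIFYING_ICD9, 2L, replace = TRUE)
    } else {
      dx_date <- c(dates[1], max(dates[2], dates[1] + 30L))
      dx_code <- sample(QUALIFYING_ICD9, 2L, replace = TRUE)
    }

    age <- clip(round(stats::rnorm(1L, p$age_mean_sd[1], p$age_mean_sd[2])), 18, 95)
    demo[[i]] <- list(
      birth_year = as.integer(as.integer(format(origin + dates[nv], "%Y")) - age),
      sex = if (stats::runif(1L) < p$sex_female_prob) "female" else "male",
      race = sample(RACE_LEVELS, 1L, prob = p$race_probs),
      rf_positive = as.integer(stats::runif(1L) < stats::plogis(0.8 + 0.4 * zbar)),
      ccp_positive = as.integer(stats::runif(1L) < stats::plogis(0.6 + 0.4 * zbar)))
    dx[[i]] <- list(date = dx_date, code = dx_code)
    med[[i]] <- list(date = med_date, code = med_code, class = med_class)
    vis[[i]] <- list(
      nv = nv, date = dates, z = z, treat_reduction = d, s_adj = z - d,
      eps = stats::rnorm(nv),
      esr_noise = stats::rnorm(nv), crp_noise = stats::rnorm(nv),
      esr_miss = stats::runif(nv) < p$lab_missing_prob[["ESR"]],
      crp_miss = stats::runif(nv) < p$lab_missing_prob[["CRP"]])
  }

  nv_all <- vapply(vis, `[[`, integer(1), "nv")
  pull <- function(lst, fld) unlist(lapply(lst, `[[`, fld), use.names = FALSE)
  visits <- data.frame(
    patient_id = rep(ids, nv_all),
    visit = unlist(lapply(nv_all, seq_len), use.names = FALSE),
    date = origin + pull(vis, "date"),
    z = pull(vis, "z"), treat_reduction = pull(vis, "treat_reduction"),
    s_adj = pull(vis, "s_adj"), eps = pull(vis, "eps"),
    esr_noise = pull(vis, "esr_noise"), crp_noise = pull(vis, "crp_noise"),
    esr_miss = pull(vis, "esr_miss"), crp_miss = pull(vis, "crp_miss"),
    mode = rep(modes, nv_all), stringsAsFactors = FALSE)

  # calibrate the controlled threshold against the realized systematic part:
  # expected controlled fraction equals the target exactly, including any
  # shift introduced by treatment effects
  m <- w * visits$s_adj
  t_star <- if (noise_sd < 1e-6) {
    as.numeric(stats::quantile(m, p$controlled_target, type = 1))
  } else {
    f <- function(t) mean(stats::pnorm((t - m) / noise_sd)) - p$controlled_target
    stats::uniroot(f, c(min(m) - 8 * noise_sd - 1, max(m) + 8 * noise_sd + 1),
                   tol = 1e-10)$root
  }

  visits$u <- m + noise_sd * visits$eps
  visits$cdai <- clip(10 + p$cdai_scale * (visits$u - t_star), 0, 72)
  visits$outcome <- ifelse(visits$cdai <= 10, "controlled", "uncontrolled")
  last <- is_last_in_group(visits$patient_id)
  visits$is_index <- last

  # one CDAI row per visit; patients in the 'one_cdai' failure mode keep only
  # their index visit's score
  keep_cdai <- visits$mode != "one_cdai" | visits$is_index
  cdai_tab <- data.frame(patient_id = visits$patient_id[keep_cdai],
                         date = visits$date[keep_cdai],
                         cdai_score = round(visits$cdai[keep_cdai], 1),
                         stringsAsFactors = FALSE)

  esr_val <- clip(round(exp(3.0 + 0.55 * visits$s_adj + 0.35 * visits$esr_noise)), 1, 140)
  crp_val <- clip(round(exp(1.2 + 0.80 * visits$s_adj + 0.50 * visits$crp_noise), 1), 0.1, 200)
  labs_tab <- rbind(
    data.frame(patient_id = visits$patient_id[!visits$esr_miss],
               date = visits$date[!visits$esr_miss], lab_name = "ESR",
               value = esr_val[!visits$esr_miss], stringsAsFactors = FALSE),
    data.frame(patient_id = visits$patient_id[!visits$crp_miss],
               date = visits$date[!visits$crp_miss], lab_name = "CRP",
               value = crp_val[!visits$crp_miss], stringsAsFactors = FALSE))
  labs_tab <- labs_tab[order(labs_tab$patient_id, labs_tab$date), ]
  rownames(labs_tab) <- NULL

  n_dx <- vapply(dx, function(e) length(e$date), integer(1))
  n_med <- vapply(med, function(e) length(e$date), integer(1))
  tables <- list(
    demographics = data.frame(
      patient_id = ids,
      birth_year = vapply(demo, `[[`, integer(1), "birth_year"),
      sex = vapply(demo, `[[`, character(1), "sex"),
      race = vapply(demo, `[[`, character(1), "race"),
      rf_positive = vapply(demo, `[[`, integer(1), "rf_positive"),
      ccp_positive = vapply(demo, `[[`, integer(1), "ccp_positive"),
      stringsAsFactors = FALSE),
    diagnoses = data.frame(
      patient_id = rep(ids, n_dx),
      date = origin + pull(dx, "date"),
      icd9_code = pull(dx, "code"), stringsAsFactors = FALSE),
    cdai = cdai_tab,
    labs = labs_tab,
    meds = data.frame(
      patient_id = rep(ids, n_med),
      date = origin + pull(med, "date"),
      med_code = pull(med, "code"),
      med_class = pull(med, "class"), stringsAsFactors = FALSE)
  )

  # realized calibration over the whole latent trajectory set
  same_patient <- visits$patient_id[-1] == visits$patient_id[-nrow(visits)]
  sw <- (visits$outcome[-1] != visits$outcome[-nrow(visits)])[same_patient]
  truth <- list(
    visits = visits[, c("patient_id", "visit", "date", "z", "treat_reduction",
                        "s_adj", "u", "cdai", "outcome", "is_index", "mode")],
    params = list(c0 = cal$c0, r_star = cal$r_star, w = w, ar_phi = p$ar_phi,
                  t_star = t_star, cdai_scale = p$cdai_scale, profile = unclass(p)),
    realized_controlled = mean(visits$outcome == "controlled"),
    realized_switch = if (length(sw)) mean(sw) else NA_real_
  )
  structure(list(tables = tables, truth = truth), class = "ehr_simulation")
}

#' @export
print.ehr_simulation <- function(x, ...) {
  cat(sprintf("<ehr_simulation: %d patients, %d visits>\n",
              nrow(x$tables$demographics), nrow(x$truth$visits)))
  cat(sprintf("  realized controlled fraction: %.3f | switch rate: %.3f\n",
              x$truth$realized_controlled, x$truth$realized_switch))
  invisible(x)
}

#' Check a generated extract's marginals against its profile targets
#'
#' Recomputes, from the event tables alone, the realized controlled fraction,
#' visit-to-visit switch rate, median inter-visit gap, and per-class
#' medication prevalence, and flags each against the profile target at a
#' stated tolerance.
#'
#' @param tables the `tables` element of [generate_ehr()] output (or a real
#'   extract in the same shape).
#' @param targets the [hospital_profile()] the data should match.
#' @param tol named list of tolerances: `frac` (controlled/switch, default
#'   0.03), `gap_days` (default 15), `med` (default 0.06).
#' @return data.frame with columns `metric`, `target`, `realized`, `tol`,
#'   `pass`.
#' @export
check_marginals <- function(tables, targets,
                            tol = list(frac = 0.03, gap_days = 15, med = 0.06)) {
  if (nrow(tables$cdai) == 0) stop("empty tables: no CDAI records to check")
  validate_profile(targets)
  cd <- tables$cdai[order(tables$cdai$patient_id, tables$cdai$date), ]
  controlled <- cd$cdai_score <= 10
  same <- cd$patient_id[-1] == cd$patient_id[-nrow(cd)]
  switch_rate <- mean((controlled[-1] != controlled[-nrow(cd)])[same])
  gaps <- as.numeric(diff(cd$date))[same]
  med_prev <- vapply(MED_CLASSES, function(cl) {
    with_cl <- unique(tables$meds$patient_id[tables$meds$med_class == cl])
    length(with_cl) / nrow(tables$demographics)
  }, numeric(1))

  out <- data.frame(
    metric = c("controlled_fraction", "switch_rate", "median_visit_gap_days",
               paste0("med_prevalence_", MED_CLASSES)),
    target = c(targets$controlled_target, targets$switch_target,
               targets$visit_gap_median_days, unname(targets$med_propensity[MED_CLASSES])),
    realized = c(mean(controlled), switch_rate, stats::median(gaps), unname(med_prev)),
    tol = c(tol$frac, tol$frac, tol$gap_days, rep(tol$med, 4)),
    stringsAsFactors = FALSE
  )
  out$pass <- abs(out$realized - out$target) <= out$tol
  out
}

#' Write EHR tables (and optional ground truth) to a directory of CSV files
#'
#' Files are `demographics.csv`, `diagnoses.csv`, `cdai.csv`, `labs.csv`,
#' `meds.csv` with the canonical headers; dates are ISO-8601. When `truth` is
#' supplied, `ground_truth.csv` and `profile.json` are written alongside.
#'
#' @param tables EHR tables list.
#' @param dir output directory (created if needed).
#' @param truth optional ground-truth element from [generate_ehr()].
#' @return `dir`, invisibly.
#' @export
write_ehr <- function(tables, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(empty_ehr_tables())) {
    tab <- tables[[nm]]
    utils::write.csv(tab, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  if (!is.null(truth)) {
    utils::write.csv(truth$visits, file.path(dir, "ground_truth.csv"), row.names = FALSE)
    par <- truth$params
    jsonlite::write_json(par[setdiff(names(par), "profile")],
                         file.path(dir, "calibration.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(par$profile, file.path(dir, "profile.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read EHR tables from a directory of CSV files
#'
#' Inverse of [write_ehr()]; dates are parsed as `Date`.
#'
#' @param dir directory containing the five canonical CSVs.
#' @return EHR tables list.
#' @export
read_ehr <- function(dir) {
  tmpl <- empty_ehr_tables()
  out <- list()
  for (nm in names(tmpl)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("missing table file: ", f)
    tab <- utils::read.csv(f, stringsAsFactors = FALSE,
                           colClasses = vapply(tmpl[[nm]], function(col)
                             class(col)[1], character(1)))
    if ("date" %in% names(tab)) tab$date <- as.Date(tab$date)
    if ("cdai_score" %in% names(tab)) tab$cdai_score <- as.numeric(tab$cdai_score)
    out[[nm]] <- tab
  }
  out
}
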