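#' Hospital generating profile for the synthetic EHR generator
#'
#' A profile bundles every parameter of the synthetic cohort: demographics,
#' visit cadence, medication propensities, the latent AR(1) disease-severity
#' process, and the two calibration targets the generator is solved against —
#' the marginal probability that a visit is controlled (CDAI <= 10) and the
#' probability that the binary outcome switches between consecutive visits.
#'
#' Two named presets are provided. `"university"` emulates a university
#' hospital rheumatology clinic: median 100 days between visits, median 6 CDAI
#' scores per patient, broad DMARD use (csDMARD 92%, biologic 63%, tofacitinib
#' 5%), 60% controlled visits and a 25% visit-to-visit switch rate.
#' `"safety_net"` emulates a safety-net clinic: median 180-day gaps, median 4
#' CDAI scores, narrower treatment (csDMARD 79%, biologic 29%, no
#' tofacitinib) and a different race/ethnicity mix.
#'
#' @param name `"university"`, `"safety_net"`, or `"custom"` (all defaults
#'   from `"university"`).
#' @param ... named overrides of any profile field, e.g. `n_patients = 500`.
#' @return an object of class `hospital_profile` (a named list).
#'
#' @details Severity follows a stationary AR(1) process with mean `ar_mu`,
#' autoregressive coefficient `ar_phi` and innovation sd `ar_sigma`, indexed
#' by visit. CDAI is a linear map of a noisy copy of standardized severity,
#' clipped to \[0, 72\]; the intercept and the severity/noise weighting are
#' solved in closed form so that the stationary controlled fraction and the
#' consecutive-visit switch rate hit `controlled_target` and `switch_target`
#' (see [solve_latent_calibration()]). A biologic start lowers subsequent
#' severity by `treatment_effect` stationary standard deviations.
#'
#' @export
#' @examples
#' p <- hospital_profile("university", n_patients = 100, seed = 7)
#' p$visit_gap_median_days
hospital_profile <- function(name = c("university", "safety_net", "custom"), ...) {
  name <- match.arg(name)
  base <- list(
    name = "university",
    n_patients = 578L,
    visit_gap_median_days = 100,
    visit_gap_dispersion = 0.45,
    n_visits_mean = 4,              # extra visits beyond the minimum of 2; median total ~ 6
    age_mean_sd = c(57, 15),
    sex_female_prob = 0.825,
    race_probs = c(white = 0.512, african_american = 0.057, hispanic = 0.168,
                   asian = 0.175, other = 0.088),
    med_propensity = c(csDMARD = 0.924, biologic = 0.630, tofacitinib = 0.050,
                       corticosteroid = 0.600),
    controlled_target = 0.60,
    switch_target = 0.25,
    lab_missing_prob = c(ESR = 0.30, CRP = 0.35),
    ar_mu = 0,
    ar_phi = 0.92,
    ar_sigma = sqrt(1 - 0.92^2),    # unit stationary variance
    treatment_effect = 0.30,        # severity drop (stationary sd units) after a biologic start
    cdai_scale = 9,                 # CDAI points per unit of the latent index
    nonqualifying_frac = 0.10,
    seed = 1L
  )
  if (name == "safety_net") {
    base$name <- "safety_net"
    base$n_patients <- 242L
    base$visit_gap_median_days <- 180
    base$n_visits_mean <- 2
    base$age_mean_sd <- c(60, 15)
    base$sex_female_prob <- 0.806
    base$race_probs <- c(white = 0.124, african_american = 0.079,
                         hispanic = 0.368, asian = 0.289, other = 0.140)
    base$med_propensity <- c(csDMARD = 0.789, biologic = 0.289,
                             tofacitinib = 0, corticosteroid = 0.500)
    base$lab_missing_prob <- c(ESR = 0.35, CRP = 0.40)
  }
  if (name == "custom") base$name <- "custom"
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown)) stop("unknown profile field(s): ", paste(unknown, collapse = ", "))
  base[names(dots)] <- dots
  profile <- structure(base, class = "hospital_profile")
  validate_profile(profile)
  profile
}

#' Validate a hospital profile
#'
#' Checks every invariant of the generating profile and raises an error
#' naming the offending field.
#'
#' @param profile a [hospital_profile()].
#' @return the profile, invisibly.
#' @export
validate_profile <- function(profile) {
  if (!inherits(profile, "hospital_profile")) stop("not a hospital_profile")
  p <- profile
  stop_field(is.numeric(p$n_patients) && p$n_patients >= 0 &&
               p$n_patients == round(p$n_patients), "n_patients", "must be a nonnegative integer")
  stop_field(p$visit_gap_median_days > 0, "visit_gap_median_days", "must be > 0")
  stop_field(p$visit_gap_dispersion > 0, "visit_gap_dispersion", "must be > 0")
  stop_field(p$n_visits_mean >= 0, "n_visits_mean", "must be >= 0")
  stop_field(p$sex_female_prob >= 0 && p$sex_female_prob <= 1, "sex_female_prob", "probability in [0,1]")
  stop_field(length(p$race_probs) == 5 && all(p$race_probs >= 0) &&
               abs(sum(p$race_probs) - 1) < 1e-9, "race_probs",
             "5 nonnegative probabilities summing to 1")
  stop_field(all(p$med_propensity >= 0 & p$med_propensity <= 1) &&
               setequal(names(p$med_propensity), MED_CLASSES), "med_propensity",
             "named probabilities for csDMARD, biologic, tofacitinib, corticosteroid")
  stop_field(p$controlled_target > 0 && p$controlled_target < 1, "controlled_target", "in (0,1)")
  stop_field(p$switch_target >= 0 && p$switch_target < 1, "switch_target", "in [0,1)")
  stop_field(all(p$lab_missing_prob >= 0 & p$lab_missing_prob <= 1) &&
               setequal(names(p$lab_missing_prob), c("ESR", "CRP")), "lab_missing_prob",
             "named probabilities for ESR and CRP")
  stop_field(p$ar_phi >= 0 && p$ar_phi < 1, "ar_phi", "in [0,1)")
  stop_field(p$ar_sigma >= 0, "ar_sigma", "must be >= 0")
  stop_field(p$treatment_effect >= 0, "treatment_effect", "must be >= 0")
  stop_field(p$cdai_scale > 0, "cdai_scale", "must be > 0")
  stop_field(p$nonqualifying_frac >= 0 && p$nonqualifying_frac < 1, "nonqualifying_frac", "in [0,1)")
  invisible(profile)
}

# P(X <= c, Y <= c) for standard bivariate normal with correlation r,
# by 1-D quadrature of the conditional normal CDF.
binorm_lower <- function(c0, r) {
  if (abs(r) < 1e-12) return(stats::pnorm(c0)^2)
  f <- function(x) stats::dnorm(x) * stats::pnorm((c0 - r * x) / sqrt(1 - r^2))
  stats::integrate(f, -Inf, c0, rel.tol = 1e-10)$value
}

#' Solve the latent-index calibration of the synthetic generator
#'
#' The generator represents each visit's disease state through a standardized
#' latent index `u = w * s + sqrt(1 - w^2) * e`, where `s` is the standardized
#' AR(1) severity (visit-to-visit correlation `ar_phi`) and `e` independent
#' measurement noise; the visit is controlled when `u <= c0`. Consecutive
#' visits' indices then correlate at `r = w^2 * ar_phi`, and the switch
#' probability is `2 * (pnorm(c0) - P(u1 <= c0, u2 <= c0; r))`. This function
#' inverts that relation: it sets `c0 = qnorm(controlled_target)`, solves the
#' bivariate-normal equation for the pair correlation `r*` that yields
#' `switch_target`, and returns the severity weight `w = sqrt(r*/ar_phi)`.
#'
#' @param controlled_target stationary probability that a visit is controlled.
#' @param switch_target probability that consecutive visits differ in binary
#'   outcome.
#' @param ar_phi AR(1) coefficient of the latent severity; must exceed the
#'   required pair correlation, otherwise no noise weighting can reach the
#'   target and an error is raised.
#' @return list with `c0`, `r_star`, `w`.
#' @export
#' @examples
#' solve_latent_calibration(0.60, 0.25, 0.85)
solve_latent_calibration <- function(controlled_target, switch_target, ar_phi) {
  c0 <- stats::qnorm(controlled_target)
  swr <- function(r) 2 * (stats::pnorm(c0) - binorm_lower(c0, r)) - switch_target
  # switch rate is decreasing in r; r = 0 gives the independence maximum
  max_switch <- 2 * (stats::pnorm(c0) - stats::pnorm(c0)^2)
  if (switch_target > max_switch + 1e-12)
    stop(sprintf("switch_target %.3f unattainable (max %.3f at independence)",
                 switch_target, max_switch))
  r_star <- if (switch_target <= 0) 1 - 1e-9 else
    stats::uniroot(swr, c(1e-9, 1 - 1e-9), tol = 1e-10)$root
  if (ar_phi < r_star - 1e-9)
    stop(sprintf(
      "ar_phi = %.3f is below the pair correlation r* = %.3f required by switch_target; increase ar_phi",
      ar_phi, r_star))
  w <- sqrt(min(1, r_star / max(ar_phi, 1e-12)))
  list(c0 = c0, r_star = r_star, w = w)
}

#' Bayes-optimal forecasting AUROC of a synthetic cohort
#'
#' Computes, by direct use of the generator's ground truth, the AUROC of the
#' best possible forecaster of the final visit's binary outcome: the score
#' that knows the true latent severity at the penultimate visit and the
#' patient's treatment state at the index visit, i.e. the conditional mean of
#' the index visit's latent outcome index. Any model trained on the observed
#' tables is bounded above by this value (up to Monte-Carlo noise), so it
#' quantifies how much forecastable signal a profile generates.
#'
#' @param truth a `ground truth` object returned by [generate_ehr()].
#' @return the Bayes-optimal AUROC (a number in \[0.5, 1\]).
#' @export
bayes_optimal_auroc <- function(truth) {
  v <- truth$visits
  par <- truth$params
  idx <- which(v$is_index)
  prev <- idx - 1L
  ok <- v$patient_id[idx] == v$patient_id[prev]
  idx <- idx[ok]; prev <- prev[ok]
  # conditional mean of the index latent index given the previous visit's
  # true severity and the (known) treatment reduction at the index visit
  score <- par$w * (par$ar_phi * (v$z[prev]) - v$treat_reduction[idx])
  y <- v$outcome[idx] == "uncontrolled"
  auroc(score, y)
}

#' @export
print.hospital_profile <- function(x, ...) {
  cat(sprintf("<hospital_profile '%s'>\n", x$name))
  cat(sprintf("  patients: %d | visit gap median: %g d | visits: 2 + Pois(%g)\n",
              x$n_patients, x$visit_gap_median_days, x$n_visits_mean))
  cat(sprintf("  targets: controlled %.2f, switch %.2f | ar_phi %.2f\n",
              x$controlled_target, x$switch_target, x$ar_phi))
  invisible(x)
}
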