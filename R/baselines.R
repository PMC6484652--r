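#' Outcome-posterior baseline classifier
#'
#' Uses only the training cohort's outcome prevalence: each test patient is
#' independently predicted "controlled" with probability equal to the training
#' fraction of controlled outcomes (e.g. 60% of the time for a 60:40 cohort).
#' The AUROC score of a prediction is 1 if uncontrolled, else 0. Because the
#' predictions are independent of the truth, the expected AUROC is exactly
#' 0.5; the baseline quantifies how much a forecaster gains over prevalence
#' alone.
#'
#' @param train_labels training outcome labels (see [auroc()] for accepted
#'   encodings).
#' @return an object of class `outcome_posterior` with element `p_controlled`.
#' @export
#' @examples
#' m <- fit_outcome_posterior(rep(c("controlled", "uncontrolled"), c(6, 4)))
#' m$p_controlled
fit_outcome_posterior <- function(train_labels) {
  if (!length(train_labels)) stop("empty training labels")
  y <- as_binary_label(train_labels)  # TRUE = uncontrolled
  structure(list(p_controlled = mean(!y)), class = "outcome_posterior")
}

#' @rdname fit_outcome_posterior
#' @param model a fitted `outcome_posterior`.
#' @param n_samples number of predictions to draw.
#' @param seed integer seed (sampled predictions are deterministic given it).
#' @param analytic if `TRUE`, return the constant analytic score
#'   `1 - p_controlled` for every sample instead of sampled labels (a variant;
#'   the sampled form matches the baseline's definition).
#' @return for `predict_outcome_posterior`: numeric 0/1 scores (1 =
#'   uncontrolled), or a constant probability vector when `analytic`.
#' @export
predict_outcome_posterior <- function(model, n_samples, seed = 1L,
                                      analytic = FALSE) {
  stopifnot(inherits(model, "outcome_posterior"), n_samples >= 1)
  if (analytic) return(rep(1 - model$p_controlled, n_samples))
  set.seed(as.integer(seed))
  as.numeric(stats::runif(n_samples) >= model$p_controlled)
}

#' Change-posterior baseline classifier
#'
#' Uses two pieces of prior knowledge: each patient's previously recorded
#' outcome, and the training cohort's probability of switching outcome class
#' between consecutive visits. Each patient's forecast equals their prior
#' outcome, flipped independently with the switch probability (e.g. 30% of
#' patients change class, 70% keep it).
#'
#' @param prior_outcomes training patients' outcome at the penultimate visit.
#' @param index_outcomes training patients' outcome at the index visit.
#' @return an object of class `change_posterior` with element `p_switch`.
#' @export
#' @examples
#' m <- fit_change_posterior(c("controlled", "controlled", "uncontrolled", "controlled"),
#'                           c("controlled", "uncontrolled", "uncontrolled", "controlled"))
#' m$p_switch
fit_change_posterior <- function(prior_outcomes, index_outcomes) {
  if (!length(prior_outcomes)) stop("empty training transitions")
  stopifnot(length(prior_outcomes) == length(index_outcomes))
  p <- as_binary_label(prior_outcomes); y <- as_binary_label(index_outcomes)
  structure(list(p_switch = mean(p != y)), class = "change_posterior")
}

#' @rdname fit_change_posterior
#' @param model a fitted `change_posterior`.
#' @param prior_outcomes the test patients' prior outcomes.
#' @param seed integer seed.
#' @param analytic if `TRUE`, return each patient's analytic probability of
#'   being uncontrolled (`1 - p_switch` if previously uncontrolled, `p_switch`
#'   otherwise) instead of sampled labels.
#' @return for `predict_change_posterior`: numeric 0/1 scores (1 =
#'   uncontrolled), or analytic probabilities when `analytic`.
#' @export
predict_change_posterior <- function(model, prior_outcomes, seed = 1L,
                                     analytic = FALSE) {
  stopifnot(inherits(model, "change_posterior"))
  if (!length(prior_outcomes)) stop("missing prior outcomes")
  if (anyNA(prior_outcomes)) stop("missing prior outcome for some samples")
  prior_unc <- as_binary_label(prior_outcomes)
  p_unc <- ifelse(prior_unc, 1 - model$p_switch, model$p_switch)
  if (analytic) return(p_unc)
  set.seed(as.integer(seed))
  flip <- stats::runif(length(prior_unc)) < model$p_switch
  as.numeric(xor(prior_unc, flip))
}
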