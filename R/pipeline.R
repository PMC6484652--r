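#' Declarative configuration for an end-to-end forecasting experiment
#'
#' Bundles everything [run_experiment()] needs: the source- and target-site
#' generating profiles (or directories of real extracts), cohort rules, window
#' configuration, hyperparameters, split fractions, evaluation options and the
#' global seed, which is fanned out deterministically to every stage via
#' [derive_seed()].
#'
#' @param source_profile [hospital_profile()] for the source (large) site.
#' @param target_profile optional [hospital_profile()] for the transfer
#'   target; `NULL` runs a single-site experiment.
#' @param rules an [inclusion_rules()].
#' @param window a [window_config()].
#' @param hp a [hyperparams()].
#' @param split_fractions train/validation/test fractions, summing to 1.
#' @param evaluation list of options: `pis` (compute permutation importance),
#'   `pis_repeats`, `pis_windows` (`"combined"`, `"per"`, `"both"`),
#'   `learning_curve`, `lc_sizes`, `lc_repeats`, `tsne`, `confident_low`,
#'   `confident_high`.
#' @param out_dir optional directory for all artifacts.
#' @param seed global integer seed.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(source_profile = hospital_profile("university"),
                              target_profile = hospital_profile("safety_net"),
                              rules = inclusion_rules(),
                              window = window_config(),
                              hp = hyperparams(),
                              split_fractions = c(0.6, 0.2, 0.2),
                              evaluation = list(),
                              out_dir = NULL, seed = 1L) {
  ev <- utils::modifyList(list(pis = TRUE, pis_repeats = 100L,
                               pis_windows = "combined",
                               learning_curve = FALSE,
                               lc_sizes = NULL, lc_repeats = 3L,
                               tsne = FALSE,
                               confident_low = 0.2, confident_high = 0.8),
                          evaluation)
  validate_profile(source_profile)
  if (!is.null(target_profile)) validate_profile(target_profile)
  stopifnot(abs(sum(split_fractions) - 1) < 1e-9)
  structure(list(source_profile = source_profile, target_profile = target_profile,
                 rules = rules, window = window, hp = hp,
                 split_fractions = split_fractions, evaluation = ev,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Recognized top-level keys: `seed`, `out_dir`, `split_fractions`,
#' `source_profile`, `target_profile` (each a mapping of
#' [hospital_profile()] fields plus an optional `preset`), `rules`, `window`,
#' `hyperparams`, `evaluation`.
#'
#' @param file path to a YAML file.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(file) {
  y <- yaml::read_yaml(file)
  prof <- function(spec) {
    if (is.null(spec)) return(NULL)
    preset <- spec$preset %||% "university"
    spec$preset <- NULL
    for (nm in c("race_probs", "med_propensity", "lab_missing_prob", "age_mean_sd"))
      if (!is.null(spec[[nm]])) spec[[nm]] <- unlist(spec[[nm]])
    do.call(hospital_profile, c(list(name = preset), spec))
  }
  experiment_config(
    source_profile = prof(y$source_profile) %||% hospital_profile("university"),
    target_profile = prof(y$target_profile),
    rules = do.call(inclusion_rules, y$rules %||% list()),
    window = do.call(window_config, y$window %||% list()),
    hp = do.call(hyperparams, y$hyperparams %||% list()),
    split_fractions = y$split_fractions %||% c(0.6, 0.2, 0.2),
    evaluation = y$evaluation %||% list(),
    out_dir = y$out_dir, seed = y$seed %||% 1L
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
}

prepare_site <- function(profile, cfg, label) {
  sim <- stage(paste0("generate_", label),
               generate_ehr(profile, seed = derive_seed(cfg$seed, paste0("generate_", label))))
  cohort <- stage(paste0("cohort_", label), build_cohort(sim$tables, cfg$rules))
  fx <- stage(paste0("featurize_", label),
              featurize_cohort(cohort, sim$tables, cfg$window))
  sp <- stage(paste0("split_", label),
              split_cohort(cohort, cfg$split_fractions,
                           seed = derive_seed(cfg$seed, paste0("split_", label))))
  list(sim = sim, cohort = cohort, features = fx, split = sp,
       train = fx[sp$train], validation = fx[sp$validation], test = fx[sp$test])
}

eval_arm <- function(scores, test) {
  list(result = delong_ci(scores, test$y == 1L), scores = scores)
}

#' Run an end-to-end forecasting experiment
#'
#' Executes every stage from synthetic generation through evaluation:
#' generate source (and target) EHR tables, apply the cohort criteria,
#' featurize, split, train the recurrent forecaster, the dense surrogate and
#' both posterior baselines on the source training set, and evaluate all four
#' on the source test set with DeLong CIs, a confident-and-wrong summary, a
#' subgroup table and (optionally) permutation importance, a learning curve
#' and a t-SNE confusion plot. When a target profile is present, the three
#' cross-site strategies are run: a native model trained only on the target
#' training set, the source model applied directly to the target test set,
#' and the source model fine-tuned on the target training set.
#'
#' Record counts are logged after every stage so cohort attrition is
#' auditable; all artifacts are written under `cfg$out_dir` when set.
#'
#' @param cfg an [experiment_config()].
#' @param quiet suppress stage logging.
#' @return an object of class `ra_experiment`: per-arm [delong_ci()] results,
#'   PIS table, subgroup and confident-wrong summaries, transfer results, and
#'   a manifest (seeds, sizes, package version).
#' @export
run_experiment <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  src <- prepare_site(cfg$source_profile, cfg, "source")
  say("source: %d patients generated, %d in cohort, split %d/%d/%d",
      cfg$source_profile$n_patients, nrow(src$cohort),
      n_samples(src$train), n_samples(src$validation), n_samples(src$test))

  hp <- cfg$hp; hp$seed <- derive_seed(cfg$seed, "train_recurrent")
  recurrent <- stage("train_recurrent", train_forecaster(src$train, src$validation, hp))
  hp_d <- cfg$hp; hp_d$seed <- derive_seed(cfg$seed, "train_dense")
  dense <- stage("train_dense", train_dense_surrogate(src$train, src$validation, hp_d))
  say("source models trained: recurrent best val AUROC %.3f (epoch %d), dense %.3f",
      recurrent$best_val_auroc, recurrent$best_epoch, dense$best_val_auroc)

  op <- fit_outcome_posterior(src$train$label)
  chp <- fit_change_posterior(src$train$prior_outcome, src$train$label)

  n_test <- n_samples(src$test)
  arms <- list(
    recurrent = eval_arm(stats::predict(recurrent, src$test), src$test),
    dense = eval_arm(stats::predict(dense, src$test), src$test),
    outcome_posterior = eval_arm(
      predict_outcome_posterior(op, n_test, seed = derive_seed(cfg$seed, "op_pred")),
      src$test),
    change_posterior = eval_arm(
      predict_change_posterior(chp, src$test$prior_outcome,
                               seed = derive_seed(cfg$seed, "cp_pred")),
      src$test))
  say("source test AUROCs: recurrent %.3f, dense %.3f, outcome posterior %.3f, change posterior %.3f",
      arms$recurrent$result$auc, arms$dense$result$auc,
      arms$outcome_posterior$result$auc, arms$change_posterior$result$auc)

  ev <- cfg$evaluation
  prob <- arms$recurrent$scores
  idx_cdai <- src$cohort$index_cdai[match(src$test$patient_id, src$cohort$patient_id)]
  cw <- confident_wrong(prob, src$test$y, ev$confident_low, ev$confident_high,
                        cdai = idx_cdai)
  subgroups <- subgroup_performance(prob, src$test$y, src$test$category)

  pis <- NULL
  if (isTRUE(ev$pis)) {
    pis <- stage("permutation_importance",
                 permutation_importance(recurrent, src$test,
                                        windows = ev$pis_windows,
                                        n_repeats = ev$pis_repeats,
                                        seed = derive_seed(cfg$seed, "pis")))
    say("permutation importance computed (%d entries)", nrow(pis))
  }
  lc <- NULL
  if (isTRUE(ev$learning_curve)) {
    sizes <- ev$lc_sizes %||% unique(pmin(n_samples(src$train),
                                          c(50, 100, 200, 400, n_samples(src$train))))
    lc <- stage("learning_curve",
                learning_curve(src$train, src$validation, src$test, sizes,
                               repeats = ev$lc_repeats, hp = cfg$hp,
                               seed = derive_seed(cfg$seed, "lc")))
  }
  tsne <- NULL
  if (isTRUE(ev$tsne)) {
    emb <- extract_embedding(recurrent, src$test)
    tsne <- confusion_plot(emb, src$test$y, seed = derive_seed(cfg$seed, "tsne"),
                           file = if (!is.null(cfg$out_dir))
                             file.path(cfg$out_dir, "confusion_plot.png") else NULL)
  }

  transfer <- NULL
  if (!is.null(cfg$target_profile)) {
    tgt <- prepare_site(cfg$target_profile, cfg, "target")
    say("target: %d in cohort, split %d/%d/%d", nrow(tgt$cohort),
        n_samples(tgt$train), n_samples(tgt$validation), n_samples(tgt$test))
    hp_t <- cfg$hp; hp_t$seed <- derive_seed(cfg$seed, "train_native")
    native <- stage("train_native", train_forecaster(tgt$train, tgt$validation, hp_t))
    tuned <- stage("fine_tune",
                   fine_tune(recurrent, tgt$train, tgt$validation,
                             seed = derive_seed(cfg$seed, "fine_tune")))
    t_op <- fit_outcome_posterior(tgt$train$label)
    t_chp <- fit_change_posterior(tgt$train$prior_outcome, tgt$train$label)
    nt <- n_samples(tgt$test)
    transfer <- list(
      native = eval_arm(stats::predict(native, tgt$test), tgt$test),
      direct = eval_arm(stats::predict(recurrent, tgt$test), tgt$test),
      finetuned = eval_arm(stats::predict(tuned, tgt$test), tgt$test),
      outcome_posterior = eval_arm(
        predict_outcome_posterior(t_op, nt, seed = derive_seed(cfg$seed, "t_op_pred")),
        tgt$test),
      change_posterior = eval_arm(
        predict_change_posterior(t_chp, tgt$test$prior_outcome,
                                 seed = derive_seed(cfg$seed, "t_cp_pred")),
        tgt$test),
      sizes = c(train = n_samples(tgt$train), validation = n_samples(tgt$validation),
                test = n_samples(tgt$test)))
    say("target test AUROCs: native %.3f, direct transfer %.3f, fine-tuned %.3f",
        transfer$native$result$auc, transfer$direct$result$auc,
        transfer$finetuned$result$auc)
  }

  manifest <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("raforecast")),
    r_version = R.version.string,
    source_cohort = nrow(src$cohort),
    split_sizes = c(train = n_samples(src$train),
                    validation = n_samples(src$validation),
                    test = n_samples(src$test)),
    feature_dim = src$features$schema$total_dim,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  report <- structure(list(arms = arms, confident_wrong = cw,
                           subgroups = subgroups, pis = pis,
                           learning_curve = lc, tsne = tsne,
                           transfer = transfer, manifest = manifest,
                           models = list(recurrent = recurrent, dense = dense),
                           source = src[c("cohort", "features", "split", "train",
                                          "validation", "test")],
                           config = cfg),
                      class = "ra_experiment")
  if (!is.null(cfg$out_dir)) write_experiment(report, cfg$out_dir)
  report
}

#' Write an experiment report's artifacts to a directory
#'
#' Emits a machine-readable `report.json` (all AUROCs with CIs, the
#' confident-wrong summary, manifest), `predictions_*.csv` per arm,
#' `pis.csv`, `subgroups.csv`, `learning_curve.csv` and the saved recurrent
#' model.
#'
#' @param report an `ra_experiment`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arm_json <- function(a) list(auc = a$result$auc, ci_low = a$result$ci_low,
                               ci_high = a$result$ci_high,
                               n_pos = a$result$n_pos, n_neg = a$result$n_neg)
  j <- list(
    source = lapply(report$arms, arm_json),
    transfer = if (!is.null(report$transfer))
      lapply(report$transfer[setdiff(names(report$transfer), "sizes")], arm_json),
    confident_wrong = report$confident_wrong[c("n", "n_confident",
                                               "n_confident_wrong", "rate")],
    manifest = report$manifest)
  jsonlite::write_json(j, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  test <- report$source$test
  for (nm in names(report$arms))
    utils::write.csv(data.frame(patient_id = test$patient_id,
                                probability = report$arms[[nm]]$scores,
                                label = test$label, category = test$category),
                     file.path(dir, sprintf("predictions_%s.csv", nm)),
                     row.names = FALSE)
  if (!is.null(report$pis))
    utils::write.csv(report$pis, file.path(dir, "pis.csv"), row.names = FALSE)
  utils::write.csv(report$subgroups, file.path(dir, "subgroups.csv"), row.names = FALSE)
  if (!is.null(report$learning_curve))
    utils::write.csv(report$learning_curve, file.path(dir, "learning_curve.csv"),
                     row.names = FALSE)
  if (!is.null(report$tsne))
    utils::write.csv(report$tsne, file.path(dir, "tsne_coordinates.csv"),
                     row.names = FALSE)
  save_forecaster(report$models$recurrent, file.path(dir, "model_recurrent"))
  invisible(dir)
}

#' @export
print.ra_experiment <- function(x, ...) {
  cat("<ra_experiment>\n")
  fmt <- function(nm, a) sprintf("  %-18s AUROC %.3f (%.3f-%.3f)\n", nm,
                                 a$result$auc, a$result$ci_low, a$result$ci_high)
  cat("source test set:\n")
  for (nm in names(x$arms)) cat(fmt(nm, x$arms[[nm]]))
  if (!is.null(x$transfer)) {
    cat("target test set:\n")
    for (nm in setdiff(names(x$transfer), "sizes")) cat(fmt(nm, x$transfer[[nm]]))
  }
  cw <- x$confident_wrong
  cat(sprintf("confident-and-wrong: %d of %d (%.1f%%)\n",
              cw$n_confident_wrong, cw$n, 100 * cw$rate))
  invisible(x)
}
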