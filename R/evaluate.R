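as_binary_label <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("controlled", "uncontrolled")))
    stop("labels must be controlled/uncontrolled, 0/1 or logical")
  labels == "uncontrolled"
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Equals the probability that a random positive (uncontrolled) sample is
#' scored above a random negative one, with ties counted half:
#' (concordant pairs + ties/2) / (n_pos * n_neg).
#'
#' @param scores numeric scores; larger means more likely uncontrolled.
#' @param labels the true labels: logical, 0/1, or
#'   `"controlled"`/`"uncontrolled"` (uncontrolled is the positive class).
#' @return the AUROC in \[0, 1\].
#' @export
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
auroc <- function(scores, labels) {
  y <- as_binary_label(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("AUROC undefined: only one class present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' AUROC with a DeLong confidence interval
#'
#' Nonparametric variance of the AUROC from DeLong's structural components:
#' the placement value of each positive (its mean score dominance over all
#' negatives) and of each negative, whose variances combine as
#' `var = S10/n_pos + S01/n_neg`. The Wald interval
#' `auc +/- z_(1-alpha/2) * sqrt(var)` is truncated to \[0, 1\].
#'
#' @param scores numeric scores (larger = more likely uncontrolled).
#' @param labels true labels, see [auroc()].
#' @param alpha interval miss probability (default 0.05 for a 95% CI).
#' @return an object of class `auroc_result`: list with `auc`, `ci_low`,
#'   `ci_high`, `se`, `alpha`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' set.seed(1)
#' delong_ci(rnorm(100) + rep(0:1, 50), rep(0:1, 50))
delong_ci <- function(scores, labels, alpha = 0.05) {
  y <- as_binary_label(labels)
  pos <- scores[y]; neg <- scores[!y]
  n1 <- length(pos); n0 <- length(neg)
  if (n1 < 2 || n0 < 2) stop("DeLong CI requires at least 2 samples per class")
  # placement via midranks, O((n1+n0) log(n1+n0))
  all_r <- rank(c(pos, neg))
  r_pos <- rank(pos); r_neg <- rank(neg)
  v10 <- (all_r[seq_len(n1)] - r_pos) / n0            # per-positive placements
  v01 <- 1 - (all_r[n1 + seq_len(n0)] - r_neg) / n1   # per-negative placements
  auc <- mean(v10)
  v <- stats::var(v10) / n1 + stats::var(v01) / n0
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(auc = auc, ci_low = max(0, auc - z * sqrt(v)),
                 ci_high = min(1, auc + z * sqrt(v)), se = sqrt(v),
                 alpha = alpha, n_pos = n1, n_neg = n0),
            class = "auroc_result")
}

#' @export
print.auroc_result <- function(x, ...) {
  cat(sprintf("AUROC %.3f (%d%% CI %.3f-%.3f; n+=%d, n-=%d)\n",
              x$auc, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Grouped permutation importance scores (PIS)
#'
#' Measures each variable group's contribution to forecasting AUROC by
#' permuting its values across test samples and recording the drop. The score
#' is reported in percentage points: `pis = 100 * (baseline AUROC - permuted
#' AUROC)`, averaged over `n_repeats` permutations, with a percentile CI. An
#' entry is significant when its permuted-AUROC interval excludes the baseline
#' AUROC (equivalently, the PIS interval excludes 0).
#'
#' Besides per-window entries, `"combined"` permutes all windows of a group
#' jointly (not a sum of per-window scores, which would double-count
#' correlated windows), and the special `"time"` group permutes the window
#' order within each sample, destroying temporal ordering while preserving
#' content. Static variables are permuted individually (window `"static"`).
#'
#' @param model a trained forecaster (anything with a [predict()] method
#'   returning uncontrolled probabilities for an `ra_features` object).
#' @param features test-set `ra_features`.
#' @param groups character vector of time-varying variable names to assess
#'   (default: all in the schema).
#' @param windows `"combined"`, `"per"` or `"both"`: which entries to compute.
#' @param include_time,include_static include the `"time"` and static entries.
#' @param n_repeats permutations per entry (>= 2; default 100).
#' @param seed integer seed.
#' @param alpha percentile-interval miss probability (default 0.05).
#' @return data.frame of class `pis_table`: `group`, `window`, `pis`,
#'   `ci_low`, `ci_high`, `significant`, plus the baseline AUROC as attribute
#'   `baseline_auc`.
#' @export
permutation_importance <- function(model, features, groups = NULL,
                                   windows = c("both", "combined", "per"),
                                   include_time = TRUE, include_static = TRUE,
                                   n_repeats = 100L, seed = 1L, alpha = 0.05) {
  windows <- match.arg(windows)
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  schema <- features$schema
  groups <- groups %||% schema$tv_vars
  unknown <- setdiff(groups, schema$tv_vars)
  if (length(unknown)) stop("unknown group(s): ", paste(unknown, collapse = ", "))
  n <- n_samples(features)
  Tn <- features$cfg$n_windows
  y <- features$y == 1L
  base_auc <- auroc(stats::predict(model, features), y)

  set.seed(as.integer(seed))
  perms <- lapply(seq_len(n_repeats), function(r) sample.int(n))
  time_perms <- lapply(seq_len(n_repeats), function(r)
    t(vapply(seq_len(n), function(i) sample.int(Tn), integer(Tn))))

  drop_for <- function(mutate) {
    vapply(seq_len(n_repeats), function(r) {
      fx <- mutate(features, perms[[r]], time_perms[[r]])
      base_auc - auroc(stats::predict(model, fx), y)
    }, numeric(1))
  }
  q <- c(alpha / 2, 1 - alpha / 2)
  rows <- list()
  add <- function(group, window, drops) {
    ci <- stats::quantile(100 * drops, q, names = FALSE, type = 7)
    rows[[length(rows) + 1L]] <<- data.frame(
      group = group, window = window, pis = mean(100 * drops),
      ci_low = ci[1], ci_high = ci[2],
      significant = ci[1] > 0 | ci[2] < 0, stringsAsFactors = FALSE)
  }

  for (gname in groups) {
    if (windows %in% c("both", "per")) {
      for (w in seq_len(Tn)) {
        add(gname, as.character(w), drop_for(function(fx, pm, tp) {
          fx$x[, w, gname] <- fx$x[pm, w, gname]
          fx
        }))
      }
    }
    if (windows %in% c("both", "combined")) {
      add(gname, "combined", drop_for(function(fx, pm, tp) {
        fx$x[, , gname] <- fx$x[pm, , gname]
        fx
      }))
    }
  }
  if (include_static) {
    for (sv in schema$static_vars) {
      add(sv, "static", drop_for(function(fx, pm, tp) {
        fx$static[, sv] <- fx$static[pm, sv]
        fx
      }))
    }
  }
  if (include_time) {
    add("time", "combined", drop_for(function(fx, pm, tp) {
      for (i in seq_len(n)) fx$x[i, , ] <- fx$x[i, tp[i, ], ]
      fx
    }))
  }
  out <- do.call(rbind, rows)
  attr(out, "baseline_auc") <- base_auc
  class(out) <- c("pis_table", "data.frame")
  out
}

#' Confident-and-wrong analysis
#'
#' A forecast is confident when its predicted probability of uncontrolled
#' disease lies above `high` or below `low`; it is wrong when the prediction
#' thresholded at 0.5 mislabels the visit. Reports how often the model is
#' both, and (when the future CDAI values are supplied) which scores those
#' errors fall on — in practice they concentrate near the controlled/
#' uncontrolled boundary at CDAI 10.
#'
#' @param probabilities predicted probabilities of uncontrolled.
#' @param labels true labels, see [auroc()].
#' @param low,high confidence band edges (defaults 0.2 and 0.8).
#' @param cdai optional future-visit CDAI scores of the same samples.
#' @return list: `n`, `n_confident`, `n_confident_wrong`, `rate` (of all
#'   samples), `cdai_confident_wrong`.
#' @export
confident_wrong <- function(probabilities, labels, low = 0.2, high = 0.8,
                            cdai = NULL) {
  stopifnot(low < high, low >= 0, high <= 1)
  y <- as_binary_label(labels)
  conf <- probabilities > high | probabilities < low
  wrong <- (probabilities > 0.5) != y
  cw <- conf & wrong
  list(n = length(y), n_confident = sum(conf), n_confident_wrong = sum(cw),
       rate = mean(cw),
       cdai_confident_wrong = if (!is.null(cdai)) cdai[cw] else NULL)
}

#' Forecasting accuracy by future disease-activity category
#'
#' Thresholded accuracy (at 0.5) and mean predicted probability within each
#' future-CDAI category. Empty categories are reported as absent.
#'
#' @param probabilities predicted probabilities of uncontrolled.
#' @param labels true binary labels.
#' @param categories the future visit's [bin_cdai()] category per sample.
#' @return data.frame: `category`, `n`, `accuracy`, `mean_prob`.
#' @export
subgroup_performance <- function(probabilities, labels, categories) {
  y <- as_binary_label(labels)
  correct <- (probabilities > 0.5) == y
  lev <- c("remission", "low", "moderate", "high")
  present <- lev[lev %in% categories]
  out <- do.call(rbind, lapply(present, function(cat) {
    i <- categories == cat
    data.frame(category = cat, n = sum(i), accuracy = mean(correct[i]),
               mean_prob = mean(probabilities[i]), stringsAsFactors = FALSE)
  }))
  out
}

#' Learning curve: test AUROC as a function of training-set size
#'
#' For each size, subsamples the training pool without replacement (repeats
#' times, different subsample seeds), trains a forecaster with the given
#' hyperparameters, and records its test AUROC.
#'
#' @param train,validation,test `ra_features` sets.
#' @param sizes training-set sizes (each <= pool size).
#' @param repeats subsample repeats per size.
#' @param hp [hyperparams()] used for every run.
#' @param seed integer seed fanned out per run.
#' @param trainer the fitting function (default [train_forecaster()]).
#' @return data.frame: `n_train`, `mean_auc`, `sd_auc`; per-run AUROCs in
#'   attribute `runs`.
#' @export
learning_curve <- function(train, validation, test, sizes, repeats = 3L,
                           hp = hyperparams(), seed = 1L,
                           trainer = train_forecaster) {
  n <- n_samples(train)
  if (any(sizes > n)) stop("size exceeds training pool")
  runs <- expand.grid(size = sizes, rep = seq_len(repeats))
  runs$auc <- NA_real_
  for (k in seq_len(nrow(runs))) {
    s <- derive_seed(seed, sprintf("lc_%d_%d", runs$size[k], runs$rep[k]))
    set.seed(s)
    idx <- if (runs$size[k] == n) seq_len(n) else sample.int(n, runs$size[k])
    hp_k <- hp; hp_k$seed <- s
    m <- trainer(train[idx], validation, hp_k)
    runs$auc[k] <- auroc(stats::predict(m, test), test$y == 1L)
  }
  agg <- do.call(rbind, lapply(sort(unique(runs$size)), function(s) {
    a <- runs$auc[runs$size == s]
    data.frame(n_train = s, mean_auc = mean(a),
               sd_auc = if (length(a) > 1) stats::sd(a) else 0)
  }))
  attr(agg, "runs") <- runs
  agg
}
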