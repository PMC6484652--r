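test_that("AUROC equals the pair-counting definition on canonical cases", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auroc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3)), 1.0)
  expect_error(auroc(1:4, rep(1, 4)), "one class")
})

test_that("AUROC matches the brute-force pair-counting oracle exactly", {
  pair_oracle <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(11)
  for (rep in 1:300) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- if (runif(1) < 0.3) sample(1:5, n, TRUE) else round(rnorm(n), 2)
    expect_identical(auroc(s, y), pair_oracle(s, y))
  }
})

test_that("DeLong CI collapses under perfect separation and tracks pROC", {
  skip_if_not_installed("pROC")
  r <- delong_ci(c(1, 2, 3, 11, 12, 13), rep(c(0, 1), each = 3))
  expect_equal(r$auc, 1)
  expect_equal(r$ci_low, 1)
  expect_equal(r$ci_high, 1)

  set.seed(21)
  for (rep in 1:20) {
    n <- sample(20:80, 1)
    y <- c(0, 0, 1, 1, rbinom(n - 4, 1, 0.5))
    s <- rnorm(n) + y
    ours <- delong_ci(s, y)
    ref <- suppressMessages(pROC::ci.auc(pROC::roc(y, s, quiet = TRUE),
                                         method = "delong"))
    expect_equal(ours$ci_low, as.numeric(ref[1]), tolerance = 1e-8)
    expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-8)
    expect_equal(ours$ci_high, as.numeric(ref[3]), tolerance = 1e-8)
  }
  expect_error(delong_ci(c(1, 2, 3), c(1, 0, 0)), "at least 2")
})

test_that("DeLong CI agrees with a stratified bootstrap on small instances", {
  set.seed(31)
  for (rep in 1:8) {
    n1 <- sample(15:30, 1); n0 <- sample(15:30, 1)
    pos <- rnorm(n1, 1); neg <- rnorm(n0)
    s <- c(pos, neg); y <- rep(c(1, 0), c(n1, n0))
    ours <- delong_ci(s, y)
    boots <- replicate(2000, {
      auroc(c(sample(pos, n1, TRUE), sample(neg, n0, TRUE)), y)
    })
    bci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    expect_lt(abs(ours$ci_low - bci[1]), 0.05)
    expect_lt(abs(ours$ci_high - bci[2]), 0.05)
  }
})

test_that("permutation importance flags signal variables and not constant ones", {
  fx <- make_separable_features(60, seed = 6)
  m <- train_forecaster(fx, fx, fast_hp(max_epochs = 40))
  pis <- permutation_importance(m, fx, groups = c("cdai", "DMARD_05", "esr"),
                                windows = "combined", include_time = FALSE,
                                include_static = FALSE, n_repeats = 30, seed = 2)
  cdai <- pis[pis$group == "cdai", ]
  expect_true(cdai$significant)
  expect_gt(cdai$pis, 10)
  # DMARD_05 and esr are all-constant in this toy set: never significant
  for (g in c("DMARD_05", "esr")) {
    row <- pis[pis$group == g, ]
    expect_false(row$significant)
    expect_equal(row$pis, 0)
  }
  expect_error(permutation_importance(m, fx, groups = "nonexistent"), "unknown")
  expect_error(permutation_importance(m, fx, n_repeats = 1), "n_repeats")
})

test_that("permuting window order measures the value of time", {
  fx <- make_separable_features(60, seed = 8)
  m <- train_forecaster(fx, fx, fast_hp(max_epochs = 40))
  pis <- permutation_importance(m, fx, groups = "cdai", windows = "combined",
                                include_time = TRUE, include_static = FALSE,
                                n_repeats = 30, seed = 3)
  expect_true("time" %in% pis$group)
  # the toy signal lives in the most recent window, so destroying order hurts
  expect_gt(pis$pis[pis$group == "time"], 0)
})

test_that("confident-and-wrong counts follow the band and threshold rules", {
  cw <- confident_wrong(c(0.9, 0.55, 0.1, 0.85), c(1, 1, 1, 0),
                        cdai = c(30, 12, 11, 4))
  # 0.9/label 1 correct; 0.55 not confident; 0.1/label 1 confident wrong;
  # 0.85/label 0 confident wrong
  expect_identical(cw$n_confident, 3L)
  expect_identical(cw$n_confident_wrong, 2L)
  expect_equal(cw$rate, 0.5)
  expect_identical(cw$cdai_confident_wrong, c(11, 4))
  none <- confident_wrong(c(0.4, 0.6, 0.5), c(0, 1, 1))
  expect_identical(none$n_confident_wrong, 0L)
})

test_that("subgroup accuracy is 1 when all correct and near base rate under shuffling", {
  probs <- c(0.1, 0.2, 0.9, 0.8)
  labels <- c(0, 0, 1, 1)
  cats <- c("remission", "low", "moderate", "high")
  tab <- subgroup_performance(probs, labels, cats)
  expect_true(all(tab$accuracy == 1))
  expect_identical(tab$category, cats)

  set.seed(41)
  y <- rbinom(4000, 1, 0.5)
  p <- runif(4000)
  cats2 <- sample(c("remission", "low", "moderate", "high"), 4000, TRUE)
  tab2 <- subgroup_performance(p, y, cats2)
  expect_true(all(abs(tab2$accuracy - 0.5) < 0.06))

  absent <- subgroup_performance(probs[1:2], labels[1:2], c("low", "low"))
  expect_identical(absent$category, "low")
})

test_that("learning curve at full pool equals a direct train/evaluate run", {
  m <- medium_cohort()
  hp <- fast_hp(max_epochs = 6)
  lc <- learning_curve(m$train, m$validation, m$test,
                       sizes = raforecast:::n_samples(m$train),
                       repeats = 1, hp = hp, seed = 3)
  s <- derive_seed(3, sprintf("lc_%d_%d", raforecast:::n_samples(m$train), 1))
  hp2 <- hp; hp2$seed <- s
  direct <- train_forecaster(m$train, m$validation, hp2)
  expect_equal(lc$mean_auc, auroc(predict(direct, m$test), m$test$y))
  expect_error(learning_curve(m$train, m$validation, m$test, sizes = 1e6,
                              hp = hp), "exceeds")
})
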