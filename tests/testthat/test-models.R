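test_that("backpropagated gradients match finite differences (recurrent)", {
  set.seed(42)
  hp <- hyperparams(td_units = 5, gru_units = c(4, 3), dropout = 0,
                    l2_penalty = 0, seed = 1)
  B <- 7; Tn <- 4; d <- 6
  X <- array(rnorm(B * Tn * d), c(B, Tn, d))
  y <- rbinom(B, 1, 0.5)
  par <- raforecast:::nn_init_recurrent(d, hp)
  # randomize biases away from 0 so no ReLU sits exactly on its kink
  par <- lapply(par, function(m) m + matrix(rnorm(length(m), sd = 0.1), nrow(m)))
  fwd <- raforecast:::nn_forward_recurrent(par, X, hp)
  g <- raforecast:::nn_backward_recurrent(par, fwd, X, y, hp)
  eps <- 1e-6
  for (nm in names(par)) {
    ks <- seq_len(min(length(par[[nm]]), 5))
    for (k in ks) {
      p2 <- par; p2[[nm]][k] <- p2[[nm]][k] + eps
      l1 <- raforecast:::bce_loss(raforecast:::nn_forward_recurrent(p2, X, hp)$p, y)
      p2[[nm]][k] <- p2[[nm]][k] - 2 * eps
      l0 <- raforecast:::bce_loss(raforecast:::nn_forward_recurrent(p2, X, hp)$p, y)
      num <- (l1 - l0) / (2 * eps)
      expect_lt(abs(num - g[[nm]][k]) / max(1e-7, abs(num) + abs(g[[nm]][k])),
                1e-4)
    }
  }
})

test_that("backpropagated gradients match finite differences (dense)", {
  set.seed(43)
  hp <- hyperparams(td_units = 5, gru_units = c(4, 3), dropout = 0,
                    l2_penalty = 0, seed = 1)
  B <- 7
  X <- matrix(rnorm(B * 10), B)
  y <- rbinom(B, 1, 0.5)
  par <- raforecast:::nn_init_dense(10, hp)
  par <- lapply(par, function(m) m + matrix(rnorm(length(m), sd = 0.1), nrow(m)))
  fwd <- raforecast:::nn_forward_dense(par, X, hp)
  g <- raforecast:::nn_backward_dense(par, fwd, X, y, hp)
  eps <- 1e-6
  for (nm in names(par)) for (k in seq_len(min(length(par[[nm]]), 5))) {
    p2 <- par; p2[[nm]][k] <- p2[[nm]][k] + eps
    l1 <- raforecast:::bce_loss(raforecast:::nn_forward_dense(p2, X, hp)$p, y)
    p2[[nm]][k] <- p2[[nm]][k] - 2 * eps
    l0 <- raforecast:::bce_loss(raforecast:::nn_forward_dense(p2, X, hp)$p, y)
    num <- (l1 - l0) / (2 * eps)
    expect_lt(abs(num - g[[nm]][k]) / max(1e-7, abs(num) + abs(g[[nm]][k])), 1e-4)
  }
})

test_that("both architectures separate a linearly separable toy set", {
  fx <- make_separable_features(20, seed = 2)
  hp <- fast_hp(max_epochs = 80)
  m <- train_forecaster(fx, fx, hp)
  expect_equal(auroc(predict(m, fx), fx$y), 1.0)
  md <- train_dense_surrogate(fx, fx, fast_hp(max_epochs = 80, seed = 2))
  expect_equal(auroc(predict(md, fx), fx$y), 1.0)
})

test_that("training is deterministic given the seed", {
  m <- medium_cohort()
  hp <- fast_hp(max_epochs = 8, dropout = 0.3, seed = 5)
  a <- train_forecaster(m$train, m$validation, hp)
  b <- train_forecaster(m$train, m$validation, hp)
  expect_identical(a$history, b$history)
  expect_identical(predict(a, m$test), predict(b, m$test))
  c <- train_forecaster(m$train, m$validation, fast_hp(max_epochs = 8,
                                                       dropout = 0.3, seed = 6))
  expect_false(identical(a$history$val_auroc, c$history$val_auroc))
})

test_that("degenerate inputs are rejected", {
  fx <- make_separable_features(10)
  allpos <- fx[which(fx$y == 1)]
  expect_error(train_forecaster(allpos, fx, fast_hp()), "single class")
  m <- train_forecaster(fx, fx, fast_hp(max_epochs = 2))
  other <- make_separable_features(6, seed = 3)
  other$schema$flat_names <- rev(other$schema$flat_names)
  expect_error(predict(m, other), "schema")
  expect_error(extract_embedding(structure(list(), class = "lm"), fx),
               "ra_forecaster")
})

test_that("prediction maps empty to empty and duplicates to identical values", {
  fx <- make_separable_features(12)
  m <- train_forecaster(fx, fx, fast_hp(max_epochs = 5))
  expect_identical(predict(m, fx[integer(0)]), numeric(0))
  dup <- fx[c(3, 3, 7)]
  pr <- predict(m, dup)
  expect_identical(pr[1], pr[2])
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("embeddings have the configured width and respect duplicates", {
  fx <- make_separable_features(14)
  hp <- fast_hp(max_epochs = 5, gru_units = c(8L, 6L))
  m <- train_forecaster(fx, fx, hp)
  emb <- extract_embedding(m, fx)
  expect_identical(dim(emb), c(14L, 6L))
  dup <- extract_embedding(m, fx[c(2, 2)])
  expect_identical(dup[1, ], dup[2, ])
  md <- train_dense_surrogate(fx, fx, hp)
  expect_identical(ncol(extract_embedding(md, fx)), 6L)
})

test_that("training AUROC on its own data stays above chance", {
  m <- medium_cohort()
  fit <- train_forecaster(m$train, m$validation, fast_hp(max_epochs = 15))
  expect_gt(auroc(predict(fit, m$train), m$train$y), 0.5)
})

test_that("outcome-posterior baseline learns the prevalence and is uninformative", {
  labels <- rep(c("controlled", "uncontrolled"), c(60, 40))
  op <- fit_outcome_posterior(labels)
  expect_equal(op$p_controlled, 0.60)
  expect_error(fit_outcome_posterior(character(0)), "empty")

  all_ctrl <- fit_outcome_posterior(rep("controlled", 5))
  expect_true(all(predict_outcome_posterior(all_ctrl, 50, seed = 1) == 0))

  # predictions independent of truth: AUROC -> 0.5 for any label vector
  set.seed(99)
  y <- rbinom(1e5, 1, 0.37)
  sc <- predict_outcome_posterior(op, 1e5, seed = 2)
  expect_lt(abs(auroc(sc, y) - 0.5), 0.02)
})

test_that("change-posterior baseline matches its closed-form AUROC on a known chain", {
  # symmetric two-state chain with persistence 0.75
  set.seed(7)
  n <- 1e5
  prior <- rbinom(n, 1, 0.5)
  y <- ifelse(runif(n) < 0.75, prior, 1 - prior)
  cp <- fit_change_posterior(prior, y)
  expect_lt(abs(cp$p_switch - 0.25), 0.01)
  sc <- predict_change_posterior(cp, prior, seed = 8)

  # closed form from the transition matrix and the fitted flip rate
  q <- cp$p_switch
  p11 <- 0.75 * (1 - q) + 0.25 * q      # P(score=1 | y=1)
  p10 <- 0.25 * (1 - q) + 0.75 * q      # P(score=1 | y=0)
  closed <- p11 * (1 - p10) + 0.5 * (p11 * p10 + (1 - p11) * (1 - p10))
  expect_lt(abs(auroc(sc, y) - closed), 0.02)

  expect_true(all(predict_change_posterior(fit_change_posterior(prior, prior),
                                           prior, seed = 1) == prior))
  expect_error(predict_change_posterior(cp, c(1, NA)), "missing")
  expect_error(fit_change_posterior(integer(0), integer(0)), "empty")
})

test_that("fine-tuning with zero epochs is the identity", {
  m <- medium_cohort()
  fit <- train_forecaster(m$train, m$validation, fast_hp(max_epochs = 6))
  same <- fine_tune(fit, m$train, m$validation, max_epochs = 0)
  expect_identical(predict(same, m$test), predict(fit, m$test))
})

test_that("fine-tuning on the source's own data never degrades validation AUROC", {
  m <- medium_cohort()
  fit <- train_forecaster(m$train, m$validation, fast_hp(max_epochs = 15))
  base_val <- auroc(predict(fit, m$validation), m$validation$y)
  tuned <- fine_tune(fit, m$train, m$validation, max_epochs = 5, patience = 5)
  tuned_val <- auroc(predict(tuned, m$validation), m$validation$y)
  expect_gte(tuned_val, base_val - 0.02)
})

test_that("model save/load round-trips predictions exactly", {
  m <- medium_cohort()
  fit <- train_forecaster(m$train, m$validation, fast_hp(max_epochs = 4))
  dir <- withr::local_tempdir()
  save_forecaster(fit, dir)
  back <- load_forecaster(dir)
  expect_equal(predict(back, m$test), predict(fit, m$test), tolerance = 1e-12)
})

test_that("random-search hook returns the best validation configuration", {
  fx <- make_separable_features(24, seed = 4)
  space <- list(td_units = c(4L, 8L), gru_units = list(c(4L)),
                dropout = c(0), l2_penalty = c(1e-5), learning_rate = c(1e-2))
  rs <- random_search(fx, fx, space, n_draws = 2, seed = 1,
                      trainer = function(tr, va, hp) {
                        hp$max_epochs <- 10L
                        train_forecaster(tr, va, hp)
                      })
  expect_identical(nrow(rs$results), 2L)
  expect_equal(rs$model$best_val_auroc, max(rs$results$val_auroc))
})
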