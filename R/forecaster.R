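#' Hyperparameters for the forecasting networks
#'
#' The forecaster is deliberately small and highly regularized: the training
#' cohorts number in the hundreds of patients, so capacity is kept low and
#' dropout high. Defaults: a 32-unit time-distributed input transform, GRU
#' stack of 32 and 16 units, dropout 0.5, L2 penalty 1e-4, Adam at 1e-3,
#' batches of 32, up to 200 epochs with early stopping after 20 epochs without
#' validation-AUROC improvement. [random_search()] provides a search hook over
#' a declared space.
#'
#' @param td_units width of the time-distributed input layer.
#' @param gru_units integer vector of GRU layer widths (hidden widths of the
#'   dense surrogate).
#' @param dropout dropout rate in \[0, 1).
#' @param l2_penalty L2 coefficient on weight matrices.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation-AUROC
#'   improvement).
#' @param seed integer seed controlling initialization, shuffling and dropout.
#' @return an object of class `hyperparams`.
#' @export
hyperparams <- function(td_units = 32L, gru_units = c(32L, 16L), dropout = 0.5,
                        l2_penalty = 1e-4, learning_rate = 1e-3,
                        batch_size = 32L, max_epochs = 200L, patience = 20L,
                        seed = 1L) {
  stopifnot(td_units >= 1, all(gru_units >= 1), dropout >= 0, dropout < 1,
            l2_penalty >= 0, learning_rate > 0, batch_size >= 1,
            max_epochs >= 0, patience >= 1)
  structure(list(td_units = as.integer(td_units), gru_units = as.integer(gru_units),
                 dropout = dropout, l2_penalty = l2_penalty,
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "hyperparams")
}

# model input: statics are broadcast onto every window so the time-distributed
# layer is the sole input transform; columns are standardized with
# training-set moments stored in the model.
build_input_recurrent <- function(features, scaler = NULL) {
  n <- n_samples(features); Tn <- features$cfg$n_windows
  p <- features$schema$n_tv; s <- length(features$schema$static_vars)
  X <- array(0, c(n, Tn, p + s))
  for (t in seq_len(Tn)) X[, t, ] <- cbind(matrix(features$x[, t, ], nrow = n),
                                           features$static)
  if (!is.null(scaler)) {
    for (t in seq_len(Tn))
      X[, t, ] <- sweep(sweep(matrix(X[, t, ], nrow = n), 2, scaler$center), 2,
                        scaler$scale, `/`)
  }
  X
}

build_input_dense <- function(features, scaler = NULL) {
  X <- features$flat
  if (!is.null(scaler))
    X <- sweep(sweep(X, 2, scaler$center), 2, scaler$scale, `/`)
  X
}

fit_scaler <- function(X) {
  M <- if (length(dim(X)) == 3) do.call(rbind, lapply(seq_len(dim(X)[2]),
                                                      function(t) matrix(X[, t, ], nrow = dim(X)[1])))
       else X
  center <- colMeans(M)
  scale <- apply(M, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

check_schema <- function(model, features) {
  if (!identical(model$schema$flat_names, features$schema$flat_names))
    stop("schema mismatch between model and features")
}

#' Train the recurrent disease-activity forecaster
#'
#' Fits the longitudinal model: a dense transform applied identically to each
#' time window (statics broadcast onto every window), a stack of gated
#' recurrent unit layers, and a single sigmoid output giving the probability
#' of uncontrolled disease activity at the index visit. Training minimizes
#' binary cross-entropy with equal class weights by Adam, with minibatch
#' shuffling each epoch and early stopping on validation AUROC; the best
#' validation-epoch weights are kept. The run is deterministic given
#' `hp$seed`.
#'
#' @param train,validation `ra_features` objects sharing one schema; the
#'   training labels must contain both classes.
#' @param hp a [hyperparams()] object.
#' @return an object of class `ra_forecaster` with the learned parameters,
#'   input scaler, schema, training history and seed.
#' @seealso [predict.ra_forecaster()], [extract_embedding()], [fine_tune()],
#'   [train_dense_surrogate()]
#' @export
train_forecaster <- function(train, validation, hp = hyperparams()) {
  if (length(unique(train$y)) < 2) stop("training labels contain a single class")
  if (!identical(train$schema$flat_names, validation$schema$flat_names))
    stop("schema mismatch between train and validation")
  X <- build_input_recurrent(train)
  scaler <- fit_scaler(X)
  X <- build_input_recurrent(train, scaler)
  Xval <- build_input_recurrent(validation, scaler)
  fit <- nn_train(X, train$y, Xval, validation$y, hp, arch = "recurrent")
  structure(list(par = fit$par, arch = "recurrent", hp = hp, scaler = scaler,
                 schema = train$schema, cfg = train$cfg,
                 history = fit$history, best_epoch = fit$best_epoch,
                 best_val_auroc = fit$best_val_auroc, n_train = n_samples(train)),
            class = "ra_forecaster")
}

#' Train the fully dense surrogate
#'
#' Same training protocol as [train_forecaster()] but on the flattened
#' 165-column design matrix with ordinary dense hidden layers (widths
#' `c(td_units, gru_units)`) and no recurrence. Serves as the multilayer-
#' perceptron comparator, which cannot exploit the window ordering.
#'
#' @inheritParams train_forecaster
#' @return an `ra_forecaster` object with `arch = "dense"`.
#' @export
train_dense_surrogate <- function(train, validation, hp = hyperparams()) {
  if (length(unique(train$y)) < 2) stop("training labels contain a single class")
  if (!identical(train$schema$flat_names, validation$schema$flat_names))
    stop("schema mismatch between train and validation")
  X <- build_input_dense(train)
  scaler <- fit_scaler(X)
  X <- build_input_dense(train, scaler)
  Xval <- build_input_dense(validation, scaler)
  fit <- nn_train(X, train$y, Xval, validation$y, hp, arch = "dense")
  structure(list(par = fit$par, arch = "dense", hp = hp, scaler = scaler,
                 schema = train$schema, cfg = train$cfg,
                 history = fit$history, best_epoch = fit$best_epoch,
                 best_val_auroc = fit$best_val_auroc, n_train = n_samples(train)),
            class = "ra_forecaster")
}

#' Predict uncontrolled-disease probabilities
#'
#' @param object a trained `ra_forecaster`.
#' @param newdata an `ra_features` object with the model's schema.
#' @param ... unused.
#' @return numeric vector of probabilities of uncontrolled disease activity at
#'   the index visit, one per sample (deterministic; dropout is inactive at
#'   prediction time).
#' @export
predict.ra_forecaster <- function(object, newdata, ...) {
  check_schema(object, newdata)
  if (n_samples(newdata) == 0) return(numeric(0))
  if (object$arch == "recurrent") {
    X <- build_input_recurrent(newdata, object$scaler)
    nn_forward_recurrent(object$par, X, object$hp)$p
  } else {
    X <- build_input_dense(newdata, object$scaler)
    nn_forward_dense(object$par, X, object$hp)$p
  }
}

#' Extract the final pre-output representation per patient
#'
#' Returns the activations feeding the output unit — the last GRU layer's
#' final hidden state (or the last dense hidden layer for the surrogate) —
#' the learned patient trajectory vector visualized in the confusion plot.
#'
#' @param model a trained `ra_forecaster`.
#' @param features an `ra_features` object.
#' @return numeric matrix, one row per sample; width equals the final layer
#'   size.
#' @export
extract_embedding <- function(model, features) {
  if (!inherits(model, "ra_forecaster")) stop("not a trained ra_forecaster")
  check_schema(model, features)
  if (model$arch == "recurrent") {
    X <- build_input_recurrent(features, model$scaler)
    nn_forward_recurrent(model$par, X, model$hp)$cache$hT
  } else {
    X <- build_input_dense(features, model$scaler)
    nn_forward_dense(model$par, X, model$hp)$cache$hT
  }
}

#' Fine-tune a trained forecaster on a new cohort
#'
#' Two-phase transfer learning: (1) continue training only the output layer at
#' a tenth of the original learning rate; (2) unfreeze all parameters and
#' train at the same reduced rate. Early stopping on the target validation
#' AUROC as in [train_forecaster()]; since the starting weights count as the
#' epoch-0 candidate, fine-tuning can never return a model worse on the target
#' validation set than the source model. The source model is not modified.
#' With `max_epochs = 0` the result's predictions are identical to the
#' source's.
#'
#' @param model a trained `ra_forecaster`.
#' @param train,validation target-site `ra_features` (schema must match the
#'   source).
#' @param max_epochs,patience early-stopping settings per phase (defaults:
#'   the source model's).
#' @param lr_factor learning-rate reduction (default 0.1).
#' @param seed integer seed for the fine-tuning run.
#' @return a new `ra_forecaster`.
#' @export
fine_tune <- function(model, train, validation,
                      max_epochs = model$hp$max_epochs,
                      patience = model$hp$patience, lr_factor = 0.1,
                      seed = model$hp$seed + 1L) {
  check_schema(model, train); check_schema(model, validation)
  out <- model
  if (max_epochs == 0) return(out)
  hp <- model$hp
  hp$max_epochs <- as.integer(max_epochs)
  hp$patience <- as.integer(patience)
  hp$seed <- as.integer(seed)
  lr <- model$hp$learning_rate * lr_factor
  build <- if (model$arch == "recurrent") build_input_recurrent else build_input_dense
  X <- build(train, model$scaler); Xval <- build(validation, model$scaler)
  head_only <- c("out.W", "out.b")
  ph1 <- nn_train(X, train$y, Xval, validation$y, hp, arch = model$arch,
                  init = model$par, trainable = head_only, lr = lr)
  hp2 <- hp; hp2$seed <- hp$seed + 1L
  ph2 <- nn_train(X, train$y, Xval, validation$y, hp2, arch = model$arch,
                  init = ph1$par, trainable = NULL, lr = lr)
  out$par <- ph2$par
  out$history <- rbind(cbind(ph1$history, phase = "head"),
                       cbind(ph2$history, phase = "full"))
  out$best_val_auroc <- ph2$best_val_auroc
  out$finetuned <- TRUE
  out
}

#' Random search over a declared hyperparameter space
#'
#' A lightweight model-selection hook: draws `n_draws` configurations
#' uniformly from the given space, trains each, and returns the one with the
#' best validation AUROC.
#'
#' @param train,validation `ra_features` sets.
#' @param space named list; each element a vector of candidate values (for
#'   `gru_units`, a list of integer vectors).
#' @param n_draws number of sampled configurations.
#' @param seed integer seed.
#' @param trainer fitting function (default [train_forecaster()]).
#' @return list: `model` (best), `results` (data.frame of draws and their
#'   validation AUROCs).
#' @export
random_search <- function(train, validation,
                          space = list(td_units = c(16L, 32L, 64L),
                                       gru_units = list(c(16L), c(32L, 16L), c(64L, 32L)),
                                       dropout = c(0.3, 0.5),
                                       l2_penalty = c(1e-5, 1e-4, 1e-3),
                                       learning_rate = c(3e-4, 1e-3, 3e-3)),
                          n_draws = 5L, seed = 1L, trainer = train_forecaster) {
  set.seed(as.integer(seed))
  draws <- lapply(seq_len(n_draws), function(k)
    lapply(space, function(v) v[[sample.int(length(v), 1L)]]))
  best <- NULL; rows <- list()
  for (k in seq_along(draws)) {
    hp <- do.call(hyperparams, c(draws[[k]], list(seed = derive_seed(seed, paste0("draw", k)))))
    m <- trainer(train, validation, hp)
    rows[[k]] <- data.frame(draw = k, val_auroc = m$best_val_auroc,
                            td_units = hp$td_units,
                            gru_units = paste(hp$gru_units, collapse = "-"),
                            dropout = hp$dropout, l2_penalty = hp$l2_penalty,
                            learning_rate = hp$learning_rate)
    if (is.null(best) || m$best_val_auroc > best$best_val_auroc) best <- m
  }
  list(model = best, results = do.call(rbind, rows))
}

#' @export
print.ra_forecaster <- function(x, ...) {
  cat(sprintf("<ra_forecaster (%s): %s>\n", x$arch,
              if (x$arch == "recurrent")
                sprintf("TD(%d) -> GRU(%s) -> sigmoid", x$hp$td_units,
                        paste(x$hp$gru_units, collapse = ",")) else
                sprintf("dense(%s) -> sigmoid",
                        paste(c(x$hp$td_units, x$hp$gru_units), collapse = ","))))
  cat(sprintf("  trained on %d samples; best val AUROC %.3f at epoch %d%s\n",
              x$n_train, x$best_val_auroc, x$best_epoch,
              if (isTRUE(x$finetuned)) " (fine-tuned)" else ""))
  invisible(x)
}

#' @export
summary.ra_forecaster <- function(object, ...) {
  print(object)
  h <- object$history
  cat(sprintf("  epochs run: %d | final train loss: %.4f\n",
              max(h$epoch), utils::tail(stats::na.omit(h$train_loss), 1)))
  cat(sprintf("  parameters: %d\n",
              sum(vapply(object$par, length, integer(1)))))
  invisible(object)
}

#' Plot a forecaster's training history
#'
#' Training loss and validation AUROC per epoch, with the early-stopping
#' optimum marked.
#'
#' @param x a trained `ra_forecaster`.
#' @param ... passed to [plot()].
#' @export
plot.ra_forecaster <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$epoch[-1], h$train_loss[-1], type = "l", xlab = "epoch",
       ylab = "training loss", main = "loss", ...)
  plot(h$epoch, h$val_auroc, type = "l", xlab = "epoch",
       ylab = "validation AUROC", main = "early stopping", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' Save / load a forecaster as a directory of plain-text artifacts
#'
#' Parameters go to one CSV per matrix, the schema and configuration to JSON,
#' and the training history to CSV.
#'
#' @param model a trained `ra_forecaster`.
#' @param dir directory path.
#' @return `dir` invisibly (save); the model (load).
#' @export
save_forecaster <- function(model, dir) {
  dir.create(file.path(dir, "par"), showWarnings = FALSE, recursive = TRUE)
  for (nm in names(model$par))
    utils::write.csv(model$par[[nm]], file.path(dir, "par", paste0(nm, ".csv")),
                     row.names = FALSE)
  utils::write.csv(model$history, file.path(dir, "history.csv"), row.names = FALSE)
  meta <- list(arch = model$arch, hp = unclass(model$hp),
               scaler = model$scaler, best_epoch = model$best_epoch,
               best_val_auroc = model$best_val_auroc, n_train = model$n_train,
               flat_names = model$schema$flat_names,
               cfg = unclass(model$cfg), par_names = names(model$par))
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_forecaster
#' @export
load_forecaster <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  par <- lapply(meta$par_names, function(nm)
    as.matrix(utils::read.csv(file.path(dir, "par", paste0(nm, ".csv")))))
  par <- lapply(par, function(m) {dimnames(m) <- NULL; m})
  names(par) <- meta$par_names
  cfg <- do.call(window_config, meta$cfg[c("n_windows", "window_days",
                                           "lookback_cap_days", "include_index_day",
                                           "missing_sentinel", "carry_forward_meds")])
  schema <- feature_schema(cfg)
  if (!identical(schema$flat_names, meta$flat_names))
    stop("saved schema does not match this package's feature schema")
  hp <- do.call(hyperparams, meta$hp)
  structure(list(par = par, arch = meta$arch, hp = hp,
                 scaler = list(center = meta$scaler$center, scale = meta$scaler$scale),
                 schema = schema, cfg = cfg,
                 history = utils::read.csv(file.path(dir, "history.csv")),
                 best_epoch = meta$best_epoch, best_val_auroc = meta$best_val_auroc,
                 n_train = meta$n_train),
            class = "ra_forecaster")
}
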