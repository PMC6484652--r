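# Exact t-distributed stochastic neighbor embedding (no Barnes-Hut
# approximation). Adequate for the few hundred patient representations a
# confusion plot visualizes; O(n^2) memory and time per iteration.

tsne_p_matrix <- function(X, perplexity) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D2[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP < 1e-300) sumP <- 1e-300
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { betamin <- beta; beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2 }
      else { betamax <- beta; beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2 }
    }
    P[i, -i] <- Pi / sumP
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' 2-D t-SNE embedding
#'
#' Exact t-SNE with perplexity-calibrated Gaussian input affinities and a
#' Student-t low-dimensional kernel, optimized by gradient descent with
#' momentum and early exaggeration. Deterministic given `seed`.
#'
#' @param X numeric matrix (n x d), n >= 5.
#' @param perplexity effective neighborhood size; capped at `(n - 1) / 3`.
#' @param n_iter gradient-descent iterations.
#' @param seed integer seed (controls the random initialization).
#' @return n x 2 matrix of coordinates.
#' @export
tsne_embed <- function(X, perplexity = 30, n_iter = 400L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 5) stop("t-SNE needs at least 5 points")
  perplexity <- min(perplexity, (n - 1) / 3)
  P <- tsne_p_matrix(X, perplexity)
  set.seed(as.integer(seed))
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  lr <- 100; exaggeration <- 12; stop_exag <- 100L
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= stop_exag) P * exaggeration else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (it < 250) 0.5 else 0.8
    dY <- momentum * dY - lr * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Confusion plot of the learned patient representations
#'
#' Embeds the model's final per-patient representations (see
#' [extract_embedding()]) into 2-D with t-SNE and colors each point by the
#' true next-visit outcome, to assess whether the learned representation
#' separates controlled from uncontrolled patients.
#'
#' @param embeddings numeric matrix of per-sample representations (n >= 5).
#' @param labels true outcomes (see [auroc()] for encodings).
#' @param seed integer seed for the t-SNE initialization.
#' @param perplexity t-SNE perplexity.
#' @param file optional PNG path; when given, the figure is written there.
#' @return data.frame `x`, `y`, `label` (invisibly when plotting to file).
#' @export
confusion_plot <- function(embeddings, labels, seed = 1L, perplexity = 30,
                           file = NULL) {
  y <- as_binary_label(labels)
  coords <- tsne_embed(embeddings, perplexity = perplexity, seed = seed)
  out <- data.frame(x = coords[, 1], y = coords[, 2],
                    label = ifelse(y, "uncontrolled", "controlled"),
                    stringsAsFactors = FALSE)
  draw <- function() {
    plot(out$x, out$y, col = ifelse(y, "#D55E00", "#0072B2"),
         pch = 19, cex = 0.7, xlab = "t-SNE 1", ylab = "t-SNE 2",
         main = "Confusion plot: learned patient representations")
    graphics::legend("topright", legend = c("controlled", "uncontrolled"),
                     col = c("#0072B2", "#D55E00"), pch = 19, bty = "n")
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 700, res = 120)
    draw()
    grDevices::dev.off()
    return(invisible(out))
  }
  draw()
  invisible(out)
}
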