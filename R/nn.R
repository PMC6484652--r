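# Minimal neural-network engine: a time-distributed dense input transform,
# stacked gated recurrent unit (GRU) layers and a sigmoid output head, plus a
# fully dense variant, trained by Adam on binary cross-entropy with manual
# backpropagation. Parameters live in a flat named list of matrices so that
# optimizer state, L2 penalties, layer freezing and finite-difference gradient
# checks all operate uniformly.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

nn_init_recurrent <- function(d_in, hp) {
  par <- list()
  par[["td.W"]] <- glorot(d_in, hp$td_units)
  par[["td.b"]] <- matrix(0, 1, hp$td_units)
  sizes <- c(hp$td_units, hp$gru_units)
  for (l in seq_along(hp$gru_units)) {
    din <- sizes[l]; u <- sizes[l + 1]
    pre <- sprintf("gru%d.", l)
    for (g in c("Wz", "Wr", "Wh")) par[[paste0(pre, g)]] <- glorot(din, u)
    for (g in c("Uz", "Ur", "Uh")) par[[paste0(pre, g)]] <- glorot(u, u)
    for (g in c("bz", "br", "bh")) par[[paste0(pre, g)]] <- matrix(0, 1, u)
  }
  u_last <- utils::tail(hp$gru_units, 1)
  par[["out.W"]] <- glorot(u_last, 1)
  par[["out.b"]] <- matrix(0, 1, 1)
  par
}

nn_init_dense <- function(d_in, hp) {
  par <- list()
  sizes <- c(d_in, hp$td_units, hp$gru_units)
  for (l in seq_len(length(sizes) - 1)) {
    par[[sprintf("dense%d.W", l)]] <- glorot(sizes[l], sizes[l + 1])
    par[[sprintf("dense%d.b", l)]] <- matrix(0, 1, sizes[l + 1])
  }
  par[["out.W"]] <- glorot(utils::tail(sizes, 1), 1)
  par[["out.b"]] <- matrix(0, 1, 1)
  par
}

addb <- function(m, b) sweep(m, 2, b, `+`)  # add a 1 x k bias row

# Forward pass for the recurrent architecture.
# X: B x T x d array. masks: optional dropout masks (training only).
nn_forward_recurrent <- function(par, X, hp, masks = NULL) {
  B <- dim(X)[1]; Tn <- dim(X)[2]
  L <- length(hp$gru_units)
  cache <- list(A = vector("list", Tn), relu = vector("list", Tn),
                gru = lapply(seq_len(L), function(l) vector("list", Tn)),
                H = lapply(seq_len(L), function(l) vector("list", Tn)))
  # time-distributed dense + relu (+ dropout), identical weights at every step
  for (t in seq_len(Tn)) {
    Zt <- addb(matrix(X[, t, ], nrow = B) %*% par[["td.W"]], par[["td.b"]])
    At <- pmax(Zt, 0)
    cache$relu[[t]] <- Zt > 0
    if (!is.null(masks)) At <- At * masks$td[[t]]
    cache$A[[t]] <- At
  }
  inp <- cache$A
  for (l in seq_len(L)) {
    pre <- sprintf("gru%d.", l)
    u <- hp$gru_units[l]
    h <- matrix(0, B, u)
    for (t in seq_len(Tn)) {
      xt <- inp[[t]]
      z <- sigmoid(addb(xt %*% par[[paste0(pre, "Wz")]] + h %*% par[[paste0(pre, "Uz")]],
                        par[[paste0(pre, "bz")]]))
      r <- sigmoid(addb(xt %*% par[[paste0(pre, "Wr")]] + h %*% par[[paste0(pre, "Ur")]],
                        par[[paste0(pre, "br")]]))
      hh <- tanh(addb(xt %*% par[[paste0(pre, "Wh")]] + (r * h) %*% par[[paste0(pre, "Uh")]],
                      par[[paste0(pre, "bh")]]))
      hnew <- (1 - z) * h + z * hh
      cache$gru[[l]][[t]] <- list(x = xt, h_prev = h, z = z, r = r, hh = hh)
      h <- hnew
      cache$H[[l]][[t]] <- h
    }
    inp <- cache$H[[l]]
  }
  hT <- cache$H[[L]][[Tn]]
  if (!is.null(masks)) hT <- hT * masks$head
  cache$hT <- hT
  p <- sigmoid(addb(hT %*% par[["out.W"]], par[["out.b"]]))
  list(p = as.vector(p), cache = cache)
}

nn_backward_recurrent <- function(par, fwd, X, y, hp, masks = NULL) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; L <- length(hp$gru_units)
  cache <- fwd$cache
  g <- lapply(par, function(m) m * 0)
  dlogit <- matrix((fwd$p - y) / B, B, 1)
  g[["out.W"]] <- t(cache$hT) %*% dlogit
  g[["out.b"]] <- matrix(colSums(dlogit), 1)
  dhT <- dlogit %*% t(par[["out.W"]])
  if (!is.null(masks)) dhT <- dhT * masks$head

  # gradient w.r.t. each layer's output sequence, top layer first
  dseq <- lapply(seq_len(Tn), function(t) matrix(0, B, hp$gru_units[L]))
  dseq[[Tn]] <- dhT
  for (l in rev(seq_len(L))) {
    pre <- sprintf("gru%d.", l)
    u <- hp$gru_units[l]
    din <- if (l == 1) hp$td_units else hp$gru_units[l - 1]
    dx_seq <- lapply(seq_len(Tn), function(t) matrix(0, B, din))
    dh_next <- matrix(0, B, u)
    for (t in rev(seq_len(Tn))) {
      cc <- cache$gru[[l]][[t]]
      dh <- dseq[[t]] + dh_next
      dz <- dh * (cc$hh - cc$h_prev)
      dhh <- dh * cc$z
      dh_prev <- dh * (1 - cc$z)
      da_h <- dhh * (1 - cc$hh^2)
      g[[paste0(pre, "Wh")]] <- g[[paste0(pre, "Wh")]] + t(cc$x) %*% da_h
      g[[paste0(pre, "Uh")]] <- g[[paste0(pre, "Uh")]] + t(cc$r * cc$h_prev) %*% da_h
      g[[paste0(pre, "bh")]] <- g[[paste0(pre, "bh")]] + matrix(colSums(da_h), 1)
      drh <- da_h %*% t(par[[paste0(pre, "Uh")]])
      dr <- drh * cc$h_prev
      dh_prev <- dh_prev + drh * cc$r
      da_z <- dz * cc$z * (1 - cc$z)
      g[[paste0(pre, "Wz")]] <- g[[paste0(pre, "Wz")]] + t(cc$x) %*% da_z
      g[[paste0(pre, "Uz")]] <- g[[paste0(pre, "Uz")]] + t(cc$h_prev) %*% da_z
      g[[paste0(pre, "bz")]] <- g[[paste0(pre, "bz")]] + matrix(colSums(da_z), 1)
      dh_prev <- dh_prev + da_z %*% t(par[[paste0(pre, "Uz")]])
      da_r <- dr * cc$r * (1 - cc$r)
      g[[paste0(pre, "Wr")]] <- g[[paste0(pre, "Wr")]] + t(cc$x) %*% da_r
      g[[paste0(pre, "Ur")]] <- g[[paste0(pre, "Ur")]] + t(cc$h_prev) %*% da_r
      g[[paste0(pre, "br")]] <- g[[paste0(pre, "br")]] + matrix(colSums(da_r), 1)
      dh_prev <- dh_prev + da_r %*% t(par[[paste0(pre, "Ur")]])
      dx_seq[[t]] <- da_z %*% t(par[[paste0(pre, "Wz")]]) +
        da_r %*% t(par[[paste0(pre, "Wr")]]) +
        da_h %*% t(par[[paste0(pre, "Wh")]])
      dh_next <- dh_prev
    }
    dseq <- dx_seq
  }
  # time-distributed layer
  for (t in seq_len(Tn)) {
    dA <- dseq[[t]]
    if (!is.null(masks)) dA <- dA * masks$td[[t]]
    dZ <- dA * cache$relu[[t]]
    g[["td.W"]] <- g[["td.W"]] + t(matrix(X[, t, ], nrow = B)) %*% dZ
    g[["td.b"]] <- g[["td.b"]] + matrix(colSums(dZ), 1)
  }
  g
}

nn_forward_dense <- function(par, X, hp, masks = NULL) {
  L <- length(hp$gru_units) + 1L
  A <- X; acts <- vector("list", L); relus <- vector("list", L)
  for (l in seq_len(L)) {
    Z <- addb(A %*% par[[sprintf("dense%d.W", l)]], par[[sprintf("dense%d.b", l)]])
    A <- pmax(Z, 0)
    relus[[l]] <- Z > 0
    if (!is.null(masks)) A <- A * masks$dense[[l]]
    acts[[l]] <- A
  }
  p <- sigmoid(addb(A %*% par[["out.W"]], par[["out.b"]]))
  list(p = as.vector(p), cache = list(acts = acts, relus = relus, hT = A))
}

nn_backward_dense <- function(par, fwd, X, y, hp, masks = NULL) {
  L <- length(hp$gru_units) + 1L
  B <- nrow(X)
  g <- lapply(par, function(m) m * 0)
  dlogit <- matrix((fwd$p - y) / B, B, 1)
  g[["out.W"]] <- t(fwd$cache$hT) %*% dlogit
  g[["out.b"]] <- matrix(colSums(dlogit), 1)
  dA <- dlogit %*% t(par[["out.W"]])
  for (l in rev(seq_len(L))) {
    if (!is.null(masks)) dA <- dA * masks$dense[[l]]
    dZ <- dA * fwd$cache$relus[[l]]
    Ain <- if (l == 1) X else fwd$cache$acts[[l - 1]]
    g[[sprintf("dense%d.W", l)]] <- t(Ain) %*% dZ
    g[[sprintf("dense%d.b", l)]] <- matrix(colSums(dZ), 1)
    dA <- dZ %*% t(par[[sprintf("dense%d.W", l)]])
  }
  g
}

nn_dropout_masks <- function(arch, B, Tn, hp) {
  rate <- hp$dropout
  if (rate <= 0) return(NULL)
  keep <- function(nr, nc) matrix(stats::rbinom(nr * nc, 1, 1 - rate), nr, nc) / (1 - rate)
  if (arch == "recurrent") {
    list(td = lapply(seq_len(Tn), function(t) keep(B, hp$td_units)),
         head = keep(B, utils::tail(hp$gru_units, 1)))
  } else {
    widths <- c(hp$td_units, hp$gru_units)
    list(dense = lapply(widths, function(u) keep(B, u)))
  }
}

bce_loss <- function(p, y) {
  p <- clip(p, 1e-12, 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Adam step restricted to trainable parameter names; weight matrices (not
# biases) carry the L2 penalty.
nn_adam_step <- function(par, g, state, lr, l2, trainable,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in trainable) {
    gr <- g[[nm]]
    if (l2 > 0 && grepl("\\.W|\\.U", nm)) gr <- gr + 2 * l2 * par[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

# Core training loop shared by the recurrent and dense architectures.
# Early stopping tracks the best validation AUROC (the starting parameters
# count as epoch 0, so continued training can never hand back a worse model).
nn_train <- function(X, y, Xval, yval, hp, arch = c("recurrent", "dense"),
                     init = NULL, trainable = NULL, lr = hp$learning_rate) {
  arch <- match.arg(arch)
  set.seed(as.integer(hp$seed))
  n <- if (arch == "recurrent") dim(X)[1] else nrow(X)
  d <- if (arch == "recurrent") dim(X)[3] else ncol(X)
  Tn <- if (arch == "recurrent") dim(X)[2] else NA_integer_
  par <- init %||% (if (arch == "recurrent") nn_init_recurrent(d, hp) else nn_init_dense(d, hp))
  trainable <- trainable %||% names(par)
  fwd_fun <- if (arch == "recurrent") nn_forward_recurrent else nn_forward_dense
  bwd_fun <- if (arch == "recurrent") nn_backward_recurrent else nn_backward_dense
  state <- list(m = lapply(par, function(m) m * 0),
                v = lapply(par, function(m) m * 0), t = 0)

  val_score <- function(p) auroc(fwd_fun(p, Xval, hp)$p, yval == 1L)
  best <- list(par = par, auc = val_score(par), epoch = 0L)
  history <- data.frame(epoch = 0L, train_loss = NA_real_, val_auroc = best$auc)
  wait <- 0L
  if (hp$max_epochs >= 1) for (epoch in seq_len(hp$max_epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (b in split(ord, ceiling(seq_along(ord) / hp$batch_size))) {
      Xb <- if (arch == "recurrent") X[b, , , drop = FALSE] else X[b, , drop = FALSE]
      yb <- y[b]
      masks <- nn_dropout_masks(arch, length(b), Tn, hp)
      fwd <- fwd_fun(par, Xb, hp, masks)
      g <- bwd_fun(par, fwd, Xb, yb, hp, masks)
      upd <- nn_adam_step(par, g, state, lr, hp$l2_penalty, trainable)
      par <- upd$par; state <- upd$state
      losses <- c(losses, bce_loss(fwd$p, yb))
    }
    auc <- val_score(par)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = mean(losses),
                                         val_auroc = auc))
    if (auc > best$auc + 1e-9) {
      best <- list(par = par, auc = auc, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= hp$patience) break
    }
  }
  list(par = best$par, history = history, best_epoch = best$epoch,
       best_val_auroc = best$auc, arch = arch)
}
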