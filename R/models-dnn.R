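# A small feed-forward neural network regressor written in base matrix
# algebra: ReLU hidden layers, full-batch Adam, early stopping on a
# validation split, and a small architecture grid.

dnn_default_grid <- function() {
  c(lapply(c(16L, 32L, 64L), function(w) w),
    lapply(c(16L, 32L, 64L), function(w) c(w, w)))
}

mlp_init <- function(p, hidden) {
  dims <- c(p, hidden, 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1)) {
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1], 0, sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X, dropout = 0, train = FALSE) {
  L <- length(par$W)
  A <- list(X)
  Z <- list()
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    if (l < L) {
      H <- pmax(Z[[l]], 0)
      if (train && dropout > 0) {
        mask <- matrix(runif(length(H)) > dropout, nrow(H), ncol(H)) / (1 - dropout)
        H <- H * mask
      }
      A[[l + 1]] <- H
    }
  }
  list(A = A, Z = Z, yhat = as.vector(Z[[L]]))
}

mlp_grad <- function(par, fw, y) {
  L <- length(par$W)
  n <- length(y)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- matrix(2 * (fw$yhat - y) / n, ncol = 1)
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fw$A[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(par$W[[l]])) * (fw$Z[[l - 1]] > 0)
    }
  }
  list(dW = dW, db = db)
}

mlp_train <- function(X, y, hidden, epochs, lr, patience, val_idx,
                      dropout = 0) {
  par <- mlp_init(ncol(X), hidden)
  L <- length(par$W)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8
  Xtr <- X[-val_idx, , drop = FALSE]; ytr <- y[-val_idx]
  Xva <- X[val_idx, , drop = FALSE]; yva <- y[val_idx]
  best <- list(par = par, val = Inf, epoch = 0L)
  wait <- 0L
  for (ep in seq_len(epochs)) {
    fw <- mlp_forward(par, Xtr, dropout = dropout, train = TRUE)
    gr <- mlp_grad(par, fw, ytr)
    for (l in seq_len(L)) {
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gr$dW[[l]]
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gr$dW[[l]]^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gr$db[[l]]
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gr$db[[l]]^2
      mhW <- mW[[l]] / (1 - b1^ep); vhW <- vW[[l]] / (1 - b2^ep)
      mhb <- mb[[l]] / (1 - b1^ep); vhb <- vb[[l]] / (1 - b2^ep)
      par$W[[l]] <- par$W[[l]] - lr * mhW / (sqrt(vhW) + epsa)
      par$b[[l]] <- par$b[[l]] - lr * mhb / (sqrt(vhb) + epsa)
    }
    val <- mean((mlp_forward(par, Xva)$yhat - yva)^2)
    if (val < best$val - 1e-10) {
      best <- list(par = par, val = val, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  best
}

#' Fit a feed-forward neural network regressor
#'
#' A fully connected network with one or two ReLU hidden layers, trained
#' full-batch with Adam on standardized inputs and outcome, with early
#' stopping on a held-out validation split. When `hidden` is `NULL` a small
#' architecture grid ({1, 2} layers x {16, 32, 64} units) is searched and
#' the architecture with the lowest validation MSE is kept. Training refuses
#' to run below 100 observations — with samples that small (e.g. a
#' 77-tract city) the validation split cannot support reliable model
#' selection.
#'
#' @param design Data frame of predictors.
#' @param outcome Numeric outcome.
#' @param hidden Integer vector of hidden-layer widths, or `NULL` to search
#'   the default grid.
#' @param epochs Maximum training epochs.
#' @param learning_rate Adam step size.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param val_frac Fraction of rows held out for validation.
#' @param dropout Dropout rate on hidden activations during training
#'   (default 0, keeping fits fully reproducible for a given seed).
#' @param seed Integer seed for initialization, the validation split, and
#'   any dropout draws.
#' @return A `mob_dnn` model object; metrics include in-sample `r2`/`rmse`
#'   and the selected architecture's validation R².
#' @export
fit_dnn <- function(design, outcome, hidden = NULL, epochs = 300,
                    learning_rate = 0.01, patience = 25, val_frac = 0.2,
                    dropout = 0, seed = 1L) {
  X <- as.matrix(as.data.frame(design))
  n <- nrow(X)
  if (n < 100) {
    abort(sprintf("sample-size: the network cannot be trained on n = %d (< 100) records", n),
          class = "mobesity_sample_size_error")
  }
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  y_ctr <- mean(outcome); y_scl <- stats::sd(outcome)
  if (y_scl == 0) y_scl <- 1
  ys <- (outcome - y_ctr) / y_scl

  grid <- if (is.null(hidden)) dnn_default_grid() else list(as.integer(hidden))
  withr::with_seed(seed, {
    val_idx <- sample.int(n, max(2L, round(val_frac * n)))
    fits <- lapply(grid, function(h) {
      mlp_train(Xs, ys, h, epochs = epochs, lr = learning_rate,
                patience = patience, val_idx = val_idx, dropout = dropout)
    })
    best_i <- which.min(vapply(fits, function(f) f$val, numeric(1)))
    best <- fits[[best_i]]
    arch <- grid[[best_i]]

    yhat <- mlp_forward(best$par, Xs)$yhat * y_scl + y_ctr
    res <- outcome - yhat
    tss <- sum((outcome - mean(outcome))^2)
    yva <- outcome[val_idx]
    vhat <- yhat[val_idx]
    val_r2 <- 1 - sum((yva - vhat)^2) / sum((yva - mean(yva))^2)
    metrics <- list(r2 = 1 - sum(res^2) / tss, rmse = sqrt(mean(res^2)),
                    val_r2 = val_r2)
    new_model_result("dnn", fitted = yhat, residuals = res, metrics = metrics,
                     par = best$par, hidden = arch,
                     x_center = ctr, x_scale = scl,
                     y_center = y_ctr, y_scale = y_scl,
                     best_epoch = best$epoch, val_idx = val_idx)
  })
}

#' @export
predict.mob_dnn <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata))[, names(object$x_center), drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  mlp_forward(object$par, Xs)$yhat * object$y_scale + object$y_center
}

#' Fit any of the five obesity-estimation models by name
#'
#' Dispatcher used by the cross-validation and comparison machinery.
#'
#' @param kind One of `"ols"`, `"gwr"`, `"rf"`, `"dnn"`, `"grf"`.
#' @param design Data frame of predictors.
#' @param outcome Numeric outcome.
#' @param coords Planar coordinates (required for `gwr` and `grf`).
#' @param spec Named list of model-specific hyperparameters forwarded to the
#'   underlying `fit_*` function.
#' @param seed Seed forwarded to the stochastic fitters.
#' @return A `mob_model` object.
#' @export
fit_model <- function(kind, design, outcome, coords = NULL, spec = list(),
                      seed = 1L) {
  kind <- match.arg(kind, c("ols", "gwr", "rf", "dnn", "grf"))
  switch(kind,
    ols = fit_ols(design, outcome),
    gwr = do.call(fit_gwr, c(list(design = design, outcome = outcome,
                                  coords = coords), spec)),
    rf = do.call(fit_rf, c(list(design = design, outcome = outcome,
                                seed = seed), spec)),
    dnn = do.call(fit_dnn, c(list(design = design, outcome = outcome,
                                  seed = seed), spec)),
    grf = do.call(fit_grf, c(list(design = design, outcome = outcome,
                                  coords = coords, seed = seed), spec)))
}

# Predict with the right signature per model kind.
predict_model <- function(object, newdata, newcoords = NULL) {
  if (inherits(object, "mob_gwr") || inherits(object, "mob_grf")) {
    predict(object, newdata, newcoords)
  } else {
    predict(object, newdata)
  }
}
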