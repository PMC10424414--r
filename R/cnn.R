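# Small convolutional network over taxonomy images.
#
# Two convolution layers (ReLU, max-pool over width after the first), a dense
# hidden layer with dropout, and a linear (regression) or sigmoid (binary)
# output. The dense hidden layer uses a leaky ReLU so that inputs far from
# the training distribution (e.g., candidate profiles explored by the genetic
# algorithm) cannot saturate every unit at once and collapse to a constant
# prediction. Covariates are concatenated to the flattened convolutional features
# before the dense layers. Convolutions are computed as im2col gathers
# followed by matrix products, with all gather/scatter indices precomputed
# from the image geometry, so training is a sequence of BLAS calls. Optimizer
# is Adam with minibatches; early stopping monitors a validation split.

cnn_config <- function(channels = c(8L, 16L), kernel = c(2L, 3L), pool_w = 2L,
                       hidden = 32L, dropout = 0.2, lr = 1e-3, batch_size = 32L,
                       epochs = 150L, patience = 20L, leak = 0.01,
                       loss = c("mse", "bce")) {
  loss <- match.arg(loss)
  list(channels = as.integer(channels), kernel = as.integer(kernel),
       pool_w = as.integer(pool_w), hidden = as.integer(hidden),
       dropout = dropout, lr = lr, batch_size = as.integer(batch_size),
       epochs = as.integer(epochs), patience = as.integer(patience),
       leak = leak, loss = loss)
}

# flat column-major index of cell (i, j) on an h x w grid
.flat_idx <- function(i, j, h) (j - 1L) * h + i

.conv_indices <- function(h, w, kh, kw) {
  h1 <- h - kh + 1L; w1 <- w - kw + 1L
  if (h1 < 1L || w1 < 1L)
    stop("image ", h, "x", w, " too small for kernel ", kh, "x", kw, call. = FALSE)
  pos_i <- rep(seq_len(h1), w1)
  pos_j <- rep(seq_len(w1), each = h1)
  idx <- matrix(0L, h1 * w1, kh * kw)
  k <- 0L
  for (dj in 0:(kw - 1L)) for (di in 0:(kh - 1L)) {
    k <- k + 1L
    idx[, k] <- .flat_idx(pos_i + di, pos_j + dj, h)
  }
  list(idx = idx, h = h1, w = w1)
}

.pool_indices <- function(h, w, pw) {
  wp <- w %/% pw
  if (wp < 1L) stop("feature map too narrow for pooling", call. = FALSE)
  pos_i <- rep(seq_len(h), wp)
  pos_j <- rep(seq_len(wp), each = h)
  a <- .flat_idx(pos_i, pw * (pos_j - 1L) + 1L, h)
  b <- .flat_idx(pos_i, pw * (pos_j - 1L) + 2L, h)
  list(a = a, b = b, h = h, w = wp)
}

cnn_geometry <- function(height, width, config) {
  kh <- config$kernel[1L]; kw <- config$kernel[2L]
  c1 <- .conv_indices(height, width, kh, kw)
  p1 <- .pool_indices(c1$h, c1$w, config$pool_w)
  c2 <- .conv_indices(p1$h, p1$w, kh, kw)
  list(height = height, width = width,
       c1 = c1, p1 = p1, c2 = c2,
       P1 = nrow(c1$idx), P1p = length(p1$a), P2 = nrow(c2$idx),
       flat = nrow(c2$idx) * config$channels[2L])
}

cnn_init <- function(geom, n_cov, config, seed) {
  kk <- nrow(geom$c1$idx) * 0L + ncol(geom$c1$idx)  # kernel cells
  ch1 <- config$channels[1L]; ch2 <- config$channels[2L]
  with_seed(seed, {
    he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
    list(W1 = he(kk, ch1), b1 = numeric(ch1),
         W2 = he(kk * ch1, ch2), b2 = numeric(ch2),
         Wd1 = he(geom$flat + n_cov, config$hidden), bd1 = numeric(config$hidden),
         Wd2 = he(config$hidden, 1L), bd2 = numeric(1L))
  })
}

# gather row indices: for each out position, the n rows of that position's
# source, sample-fastest ((pos - 1) * n + 1:n)
.gather_rows <- function(pos, n) {
  as.vector(outer(seq_len(n), (pos - 1L) * n, `+`))
}

.cnn_forward <- function(w, geom, config, X, C, train = FALSE, drop_mask = NULL) {
  n <- nrow(X)
  M1 <- matrix(X[, as.vector(geom$c1$idx)], nrow = n * geom$P1)
  Z1 <- sweep(M1 %*% w$W1, 2L, w$b1, "+")
  A1 <- pmax(Z1, 0)
  ia <- .gather_rows(geom$p1$a, n); ib <- .gather_rows(geom$p1$b, n)
  Aa <- A1[ia, , drop = FALSE]; Ab <- A1[ib, , drop = FALSE]
  maskA <- Aa >= Ab
  Ap <- pmax(Aa, Ab)
  blocks <- vector("list", ncol(geom$c2$idx))
  rows2 <- vector("list", ncol(geom$c2$idx))
  for (k in seq_len(ncol(geom$c2$idx))) {
    rows2[[k]] <- .gather_rows(geom$c2$idx[, k], n)
    blocks[[k]] <- Ap[rows2[[k]], , drop = FALSE]
  }
  M2 <- do.call(cbind, blocks)
  Z2 <- sweep(M2 %*% w$W2, 2L, w$b2, "+")
  A2 <- pmax(Z2, 0)
  F_ <- matrix(as.vector(A2), nrow = n)
  Fc <- if (ncol(C)) cbind(F_, C) else F_
  H1p <- sweep(Fc %*% w$Wd1, 2L, w$bd1, "+")
  H1 <- pmax(H1p, 0) + config$leak * pmin(H1p, 0)
  H1d <- if (train && config$dropout > 0) H1 * drop_mask else H1
  out <- sweep(H1d %*% w$Wd2, 2L, w$bd2, "+")
  list(n = n, M1 = M1, Z1 = Z1, ia = ia, ib = ib, maskA = maskA, Ap = Ap,
       rows2 = rows2, M2 = M2, Z2 = Z2, Fc = Fc, H1p = H1p, H1d = H1d,
       out = out)
}

.cnn_loss_grad <- function(out, y, loss) {
  n <- length(y)
  if (identical(loss, "mse")) {
    d <- out - y
    list(loss = mean(d^2), dout = matrix(2 * d / n, ncol = 1L))
  } else {
    p <- stats::plogis(out)
    eps <- 1e-12
    list(loss = -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps)),
         dout = matrix((p - y) / n, ncol = 1L))
  }
}

.scatter_mats <- function(geom, n, cache) {
  key <- as.character(n)
  if (!is.null(cache[[key]])) return(cache[[key]])
  mats <- lapply(seq_len(ncol(geom$c2$idx)), function(k) {
    Matrix::sparseMatrix(i = .gather_rows(geom$c2$idx[, k], n),
                         j = seq_len(n * geom$P2), x = 1,
                         dims = c(n * geom$P1p, n * geom$P2))
  })
  cache[[key]] <- mats
  mats
}

.cnn_backward <- function(w, geom, config, fw, dout, drop_mask, scat_cache) {
  n <- fw$n
  kk <- ncol(geom$c1$idx)
  ch1 <- config$channels[1L]
  dWd2 <- crossprod(fw$H1d, dout); dbd2 <- colSums(dout)
  dH1d <- dout %*% t(w$Wd2)
  dH1 <- if (config$dropout > 0 && !is.null(drop_mask)) dH1d * drop_mask else dH1d
  dH1p <- dH1 * ((fw$H1p > 0) + config$leak * (fw$H1p <= 0))
  dWd1 <- crossprod(fw$Fc, dH1p); dbd1 <- colSums(dH1p)
  dFc <- dH1p %*% t(w$Wd1)
  dF <- dFc[, seq_len(geom$flat), drop = FALSE]
  dA2 <- matrix(as.vector(dF), nrow = n * geom$P2)
  dZ2 <- dA2 * (fw$Z2 > 0)
  dW2 <- crossprod(fw$M2, dZ2); db2 <- colSums(dZ2)
  dM2 <- dZ2 %*% t(w$W2)
  scat <- .scatter_mats(geom, n, scat_cache)
  dAp <- matrix(0, n * geom$P1p, ch1)
  for (k in seq_along(scat)) {
    cols <- ((k - 1L) * ch1 + 1L):(k * ch1)
    dAp <- dAp + as.matrix(scat[[k]] %*% dM2[, cols, drop = FALSE])
  }
  dA1 <- matrix(0, n * geom$P1, ch1)
  dA1[fw$ia, ] <- dAp * fw$maskA
  dA1[fw$ib, ] <- dA1[fw$ib, , drop = FALSE] + dAp * (!fw$maskA)
  dZ1 <- dA1 * (fw$Z1 > 0)
  dW1 <- crossprod(fw$M1, dZ1); db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       Wd1 = dWd1, bd1 = dbd1, Wd2 = dWd2, bd2 = dbd2)
}

.adam_state <- function(w) {
  list(m = lapply(w, function(p) p * 0), v = lapply(w, function(p) p * 0), t = 0L)
}

.adam_step <- function(w, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(w)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, st = st)
}

# X: n x (height*width) flattened images; C: n x n_cov; y: numeric (0/1 for bce)
# val: integer indices of the validation rows (early stopping); NULL = none
cnn_train <- function(X, C, y, geom, config, seed, val = NULL) {
  n <- nrow(X)
  tr <- if (is.null(val)) seq_len(n) else setdiff(seq_len(n), val)
  xmu <- colMeans(X[tr, , drop = FALSE])
  xsd <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
  xsd[!is.finite(xsd) | xsd < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2L, xmu, "-"), 2L, xsd, "/")
  if (identical(config$loss, "mse")) {
    ymu <- mean(y[tr]); ysd <- stats::sd(y[tr]); if (!is.finite(ysd) || ysd < 1e-8) ysd <- 1
    ys <- (y - ymu) / ysd
  } else {
    ymu <- 0; ysd <- 1; ys <- y
  }
  w <- cnn_init(geom, ncol(C), config, seed)
  st <- .adam_state(w)
  scat_cache <- new.env(parent = emptyenv())
  best <- list(w = w, loss = Inf, epoch = 0L)
  with_seed(seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(tr)
      nb <- ceiling(length(ord) / config$batch_size)
      for (b in seq_len(nb)) {
        take <- ord[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, length(ord))]
        Xb <- Xs[take, , drop = FALSE]; Cb <- C[take, , drop = FALSE]
        dm <- if (config$dropout > 0) {
          matrix((stats::runif(length(take) * config$hidden) > config$dropout) /
                   (1 - config$dropout), length(take), config$hidden)
        } else NULL
        fw <- .cnn_forward(w, geom, config, Xb, Cb, train = TRUE, drop_mask = dm)
        lg <- .cnn_loss_grad(fw$out, ys[take], config$loss)
        g <- .cnn_backward(w, geom, config, fw, lg$dout, dm, scat_cache)
        up <- .adam_step(w, g, st, config$lr)
        w <- up$w; st <- up$st
      }
      monitor <- if (is.null(val)) tr else val
      fwm <- .cnn_forward(w, geom, config, Xs[monitor, , drop = FALSE],
                          C[monitor, , drop = FALSE], train = FALSE)
      ml <- .cnn_loss_grad(fwm$out, ys[monitor], config$loss)$loss
      if (ml < best$loss - 1e-6) {
        best <- list(w = w, loss = ml, epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) {
        break
      }
    }
  })
  list(w = best$w, geom = geom, config = config,
       xmu = xmu, xsd = xsd, ymu = ymu, ysd = ysd,
       best_epoch = best$epoch, val_loss = best$loss)
}

cnn_predict_raw <- function(model, X, C) {
  Xs <- sweep(sweep(X, 2L, model$xmu, "-"), 2L, model$xsd, "/")
  fw <- .cnn_forward(model$w, model$geom, model$config, Xs, C, train = FALSE)
  out <- as.numeric(fw$out)
  if (identical(model$config$loss, "mse")) {
    out * model$ysd + model$ymu
  } else {
    stats::plogis(out)
  }
}
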