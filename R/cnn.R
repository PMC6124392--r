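# Compact CNN trainer for binary patch verification.
#
# Convolutions are 3x3 with same-padding, each followed by ReLU and 2x2
# max-pooling (floor semantics; pooling is skipped once a spatial side
# reaches 1). A convolution is evaluated as nine shifted BLAS matrix
# multiplies (one per kernel tap), which keeps all heavy lifting in BLAS
# without materializing im2col matrices. Activations are carried as
# (H, W, N, C) arrays so tap slices flatten into matmul-ready matrices
# with no transposition. The head is three fully-connected layers ending
# in a 2-way softmax; training is Adam on the cross-entropy,
# deterministic given the seed (no dropout, single RNG stream).

cnn_widths <- function(depth) pmin(16 * 2^(seq_len(depth) - 1), 128)

cnn_layer_dims <- function(input_size, depth) {
  dims <- list(); H <- input_size; W <- input_size; C <- 3L
  widths <- cnn_widths(depth)
  for (l in seq_len(depth)) {
    dims[[l]] <- list(H = H, W = W, Cin = C, Cout = widths[l],
                      pool = H >= 2 && W >= 2)
    C <- widths[l]
    if (dims[[l]]$pool) { H <- H %/% 2L; W <- W %/% 2L }
  }
  list(conv = dims, flat = H * W * C)
}

# Initialize an untrained model (He init; caller seeds the RNG).
cnn_init <- function(input_size, conv_depth, fc_widths = c(256, 64)) {
  geom <- cnn_layer_dims(input_size, conv_depth)
  conv <- lapply(geom$conv, function(g) {
    K <- 9L * g$Cin
    list(W = array(stats::rnorm(K * g$Cout, 0, sqrt(2 / K)),
                   c(3, 3, g$Cin, g$Cout)),
         b = numeric(g$Cout), g = g)
  })
  sizes <- c(geom$flat, fc_widths, 2L)
  fc <- lapply(seq_len(length(sizes) - 1L), function(i) {
    list(W = matrix(stats::rnorm(sizes[i + 1] * sizes[i], 0,
                                 sqrt(2 / sizes[i])),
                    sizes[i + 1], sizes[i]),
         b = numeric(sizes[i + 1]))
  })
  structure(list(conv = conv, fc = fc, input_size = input_size,
                 conv_depth = conv_depth), class = "cnn_model")
}

# Zero-pad the two spatial dims of an (H, W, N, C) array by 1.
pad1 <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  xp[2:(d[1] + 1), 2:(d[2] + 1), , ] <- x
  xp
}

# Slice of a padded stack for kernel tap (u, v), flattened to a
# ((H*W*N) x C) matrix ready for BLAS.
tap_slice <- function(xp, u, v, H, W) {
  s <- xp[u:(u + H - 1L), v:(v + W - 1L), , , drop = FALSE]
  dim(s) <- c(H * W * dim(xp)[3], dim(xp)[4])
  s
}

# x: (H, W, N, Cin) -> list(z (H, W, N, Cout), xp (padded input))
conv_fwd <- function(layer, x) {
  g <- layer$g
  N <- dim(x)[3]
  hwn <- g$H * g$W * N
  xp <- pad1(x)
  zm <- matrix(rep(layer$b, each = hwn), hwn, g$Cout)
  for (u in 1:3) for (v in 1:3)
    zm <- zm + tap_slice(xp, u, v, g$H, g$W) %*% layer$W[u, v, , ]
  dim(zm) <- c(g$H, g$W, N, g$Cout)
  list(z = zm, xp = xp)
}

# Gradients of a conv layer; the input gradient (skipped for the first
# layer) is the correlation of the padded output gradient with the
# flipped kernels.
conv_bwd <- function(layer, dz, xp, need_dx = TRUE) {
  g <- layer$g
  N <- dim(dz)[3]
  hwn <- g$H * g$W * N
  dW <- array(0, dim(layer$W))
  dzm <- dz; dim(dzm) <- c(hwn, g$Cout)
  db <- colSums(dzm)
  for (u in 1:3) for (v in 1:3)
    dW[u, v, , ] <- crossprod(tap_slice(xp, u, v, g$H, g$W), dzm)
  dx <- NULL
  if (need_dx) {
    dzp <- pad1(dz)
    dxm <- matrix(0, hwn, g$Cin)
    for (u in 1:3) for (v in 1:3)
      dxm <- dxm + tap_slice(dzp, u, v, g$H, g$W) %*%
        t(layer$W[4L - u, 4L - v, , ])
    dim(dxm) <- c(g$H, g$W, N, g$Cin)
    dx <- dxm
  }
  list(dx = dx, dW = dW, db = db)
}

# 2x2 max-pool over the first two dims of a 4-d array (floor semantics).
pool_fwd <- function(x) {
  d <- dim(x); H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  xc <- x[seq_len(2L * H2), seq_len(2L * W2), , , drop = FALSE]
  dim(xc) <- c(2L, H2, 2L, W2, d[3], d[4])
  s1 <- xc[1, , 1, , , ]; s2 <- xc[2, , 1, , , ]
  s3 <- xc[1, , 2, , , ]; s4 <- xc[2, , 2, , , ]
  dms <- c(H2, W2, d[3], d[4])
  dim(s1) <- dms; dim(s2) <- dms; dim(s3) <- dms; dim(s4) <- dms
  out <- pmax(s1, s2, s3, s4)
  a1 <- s1 == out; a2 <- (s2 == out) & !a1
  a3 <- (s3 == out) & !a1 & !a2; a4 <- (s4 == out) & !a1 & !a2 & !a3
  list(z = out, masks = list(a1, a2, a3, a4), in_dim = d)
}

pool_bwd <- function(dz, cache) {
  d <- cache$in_dim; H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  dx6 <- array(0, c(2L, H2, 2L, W2, d[3], d[4]))
  dx6[1, , 1, , , ] <- dz * cache$masks[[1]]
  dx6[2, , 1, , , ] <- dz * cache$masks[[2]]
  dx6[1, , 2, , , ] <- dz * cache$masks[[3]]
  dx6[2, , 2, , , ] <- dz * cache$masks[[4]]
  dim(dx6) <- c(2L * H2, 2L * W2, d[3], d[4])
  if (2L * H2 == d[1] && 2L * W2 == d[2]) return(dx6)
  dx <- array(0, d)
  dx[seq_len(2L * H2), seq_len(2L * W2), , ] <- dx6
  dx
}

# x enters as (S, S, 3, N) and is re-laid-out to (H, W, N, C) internally.
cnn_forward <- function(model, x, keep_cache = FALSE) {
  x <- aperm(x, c(1, 2, 4, 3))
  caches <- if (keep_cache) vector("list", model$conv_depth) else NULL
  for (l in seq_len(model$conv_depth)) {
    cf <- conv_fwd(model$conv[[l]], x)
    relu_mask <- cf$z > 0
    a <- cf$z * relu_mask
    pf <- if (model$conv[[l]]$g$pool) pool_fwd(a) else NULL
    if (keep_cache)
      caches[[l]] <- list(xp = cf$xp, relu = relu_mask, pool = pf)
    x <- if (is.null(pf)) a else pf$z
  }
  N <- dim(x)[3]
  a <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = N)  # features x N
  fc_caches <- if (keep_cache) vector("list", length(model$fc)) else NULL
  for (j in seq_along(model$fc)) {
    z <- model$fc[[j]]$W %*% a + model$fc[[j]]$b
    if (keep_cache) fc_caches[[j]] <- list(a_in = a, z = z)
    a <- if (j < length(model$fc)) z * (z > 0) else z
  }
  zs <- sweep(a, 2, apply(a, 2, max))  # stabilized softmax
  ez <- exp(zs)
  probs <- sweep(ez, 2, colSums(ez), "/")
  list(probs = probs, caches = caches, fc_caches = fc_caches)
}

cnn_backward <- function(model, fwd, y) {
  N <- length(y)
  Y <- matrix(0, 2, N); Y[cbind(y + 1L, seq_len(N))] <- 1
  dz <- (fwd$probs - Y) / N
  grads <- list(conv = vector("list", model$conv_depth),
                fc = vector("list", length(model$fc)))
  for (j in rev(seq_along(model$fc))) {
    cache <- fwd$fc_caches[[j]]
    if (j < length(model$fc)) dz <- dz * (cache$z > 0)
    grads$fc[[j]] <- list(dW = tcrossprod(dz, cache$a_in), db = rowSums(dz))
    dz <- crossprod(model$fc[[j]]$W, dz)
  }
  lastc <- fwd$caches[[model$conv_depth]]
  out_dim <- if (!is.null(lastc$pool)) dim(lastc$pool$z) else dim(lastc$relu)
  # un-flatten: (flat x N) -> (H, W, C, N) -> (H, W, N, C)
  dx <- array(dz, c(out_dim[1], out_dim[2], out_dim[4], out_dim[3]))
  dx <- aperm(dx, c(1, 2, 4, 3))
  for (l in rev(seq_len(model$conv_depth))) {
    cache <- fwd$caches[[l]]
    if (!is.null(cache$pool)) dx <- pool_bwd(dx, cache$pool)
    dx <- dx * cache$relu
    cb <- conv_bwd(model$conv[[l]], dx, cache$xp, need_dx = l > 1L)
    grads$conv[[l]] <- list(dW = cb$dW, db = cb$db)
    dx <- cb$dx
  }
  grads
}

adam_state <- function(model) {
  zero_like <- function(p) list(W = p$W * 0, b = p$b * 0)
  list(conv = lapply(model$conv, zero_like),
       fc = lapply(model$fc, zero_like), t = 0L)
}

adam_step <- function(model, grads, mstate, vstate, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  t <- mstate$t + 1L
  upd <- function(p, g, m, v) {
    m$W <- beta1 * m$W + (1 - beta1) * g$dW
    m$b <- beta1 * m$b + (1 - beta1) * g$db
    v$W <- beta2 * v$W + (1 - beta2) * g$dW^2
    v$b <- beta2 * v$b + (1 - beta2) * g$db^2
    corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
    p$W <- p$W - lr * (m$W / corr1) / (sqrt(v$W / corr2) + eps)
    p$b <- p$b - lr * (m$b / corr1) / (sqrt(v$b / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  for (l in seq_along(model$conv)) {
    r <- upd(model$conv[[l]], grads$conv[[l]],
             mstate$conv[[l]], vstate$conv[[l]])
    r$p$g <- model$conv[[l]]$g
    model$conv[[l]] <- r$p; mstate$conv[[l]] <- r$m; vstate$conv[[l]] <- r$v
  }
  for (j in seq_along(model$fc)) {
    r <- upd(model$fc[[j]], grads$fc[[j]], mstate$fc[[j]], vstate$fc[[j]])
    model$fc[[j]] <- r$p; mstate$fc[[j]] <- r$m; vstate$fc[[j]] <- r$v
  }
  mstate$t <- t
  list(model = model, m = mstate, v = vstate)
}

# Probability of the positive class for a stack of inputs, in chunks to
# bound memory.
cnn_predict <- function(model, x, chunk = 64L) {
  N <- dim(x)[4]
  out <- numeric(N)
  for (s in seq(1L, N, by = chunk)) {
    e <- min(s + chunk - 1L, N)
    fwd <- cnn_forward(model, x[, , , s:e, drop = FALSE])
    out[s:e] <- fwd$probs[2, ]
  }
  out
}

cnn_loss <- function(probs, y) {
  p <- ifelse(y == 1L, probs, 1 - probs)
  -mean(log(pmax(p, 1e-12)))
}

# One full training run; x is (S, S, 3, N), y in {0, 1}.
cnn_train <- function(model, x, y, epochs, batch_size, lr,
                      x_val = NULL, y_val = NULL) {
  N <- dim(x)[4]
  ms <- adam_state(model); vs <- adam_state(model)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_accuracy = numeric())
  for (ep in seq_len(epochs)) {
    perm <- sample.int(N)
    losses <- numeric(0)
    for (s in seq(1L, N, by = batch_size)) {
      take <- perm[s:min(s + batch_size - 1L, N)]
      xb <- x[, , , take, drop = FALSE]; yb <- y[take]
      fwd <- cnn_forward(model, xb, keep_cache = TRUE)
      loss <- cnn_loss(fwd$probs[2, ], yb)
      if (!is.finite(loss)) stop("non-finite training loss at epoch ", ep)
      grads <- cnn_backward(model, fwd, yb)
      st <- adam_step(model, grads, ms, vs, lr)
      model <- st$model; ms <- st$m; vs <- st$v
      losses <- c(losses, loss)
    }
    vl <- NA_real_; va <- NA_real_
    if (!is.null(x_val)) {
      pv <- cnn_predict(model, x_val)
      vl <- cnn_loss(pv, y_val)
      va <- mean((pv >= 0.5) == (y_val == 1L))
    }
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(losses),
                                         val_loss = vl, val_accuracy = va))
  }
  list(model = model, history = history)
}
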