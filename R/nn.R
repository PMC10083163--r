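# Minimal functional neural-network substrate for the patch classifier.
#
# Activations travel as "tensors": list(x = array(HW, C, N), h, w), i.e. the
# spatial grid flattened column-major in the first dimension, channels
# second, batch third. After global pooling the activation is a plain
# (features x batch) matrix. Convolutions are expressed as im2col gathers
# followed by BLAS matrix multiplication; the backward pass scatters with
# rowsum(). Everything is functional: forward returns (possibly updated)
# modules so batch-norm running statistics stay reproducible.

as_nn_tensor <- function(patches) {
  # patches: array (side, side, N) or matrix (side, side)
  if (is.matrix(patches)) patches <- array(patches, dim = c(dim(patches), 1L))
  d <- dim(patches)
  list(x = array(patches, dim = c(d[1] * d[2], 1L, d[3])), h = d[1], w = d[2])
}

# ---- convolution geometry (memoized per shape) -----------------------------

.geom_cache <- new.env(parent = emptyenv())

conv_geom <- function(h, w, k, s, p) {
  key <- paste(h, w, k, s, p, sep = ",")
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  ph <- h + 2L * p; pw <- w + 2L * p
  outh <- (ph - k) %/% s + 1L; outw <- (pw - k) %/% s + 1L
  if (outh < 1L || outw < 1L)
    stop(sprintf("feature map %dx%d too small for kernel %d stride %d", h, w, k, s))
  off <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * ph, "+"))
  orig <- as.vector(outer((0:(outh - 1L)) * s, (0:(outw - 1L)) * s * ph, "+"))
  gather <- outer(off, orig, "+") + 1L               # k2 x outHW
  gi_vec <- as.vector(gather)
  ug <- sort(unique(gi_vec))
  pad_idx <- as.vector(outer((0:(h - 1L)) + p, ((0:(w - 1L)) + p) * ph, "+")) + 1L
  g <- list(k = k, k2 = k * k, s = s, p = p, h = h, w = w,
            ph = ph, pw = pw, phw = ph * pw,
            outh = outh, outw = outw, outHW = outh * outw,
            gather = gather, gi_vec = gi_vec, ug = ug, pad_idx = pad_idx)
  .geom_cache[[key]] <- g
  g
}

pad_channels <- function(Xm, g) {
  if (g$p == 0L) return(Xm)
  Xp <- matrix(0, g$phw, ncol(Xm))
  Xp[g$pad_idx, ] <- Xm
  Xp
}

unpad_channels <- function(dXp, g) {
  if (g$p == 0L) dXp else dXp[g$pad_idx, , drop = FALSE]
}

gather_cols <- function(t, g) {
  C <- dim(t$x)[2]; N <- dim(t$x)[3]
  Xp <- pad_channels(matrix(t$x, nrow = t$h * t$w, ncol = C * N), g)
  cols <- Xp[g$gi_vec, , drop = FALSE]               # (k2*outHW, C*N)
  dim(cols) <- c(g$k2, g$outHW, C, N)
  cols
}

scatter_cols <- function(dcols_mat, g, ncolums) {
  # dcols_mat: (k2*outHW, C*N); accumulate into the padded grid
  acc <- rowsum(dcols_mat, group = g$gi_vec, reorder = TRUE)
  dXp <- matrix(0, g$phw, ncolums)
  dXp[g$ug, ] <- acc
  dXp
}

# ---- leaf modules ----------------------------------------------------------

nn_conv <- function(in_ch, out_ch, kernel, stride = 1L, pad = 0L) {
  fan_in <- kernel * kernel * in_ch
  W <- matrix(rnorm(out_ch * fan_in, 0, sqrt(2 / fan_in)), out_ch, fan_in)
  list(kind = "conv", in_ch = in_ch, out_ch = out_ch,
       kernel = as.integer(kernel), stride = as.integer(stride),
       pad = as.integer(pad), params = list(W = W))
}

nn_bn <- function(ch, eps = 1e-5, momentum = 0.1) {
  list(kind = "bn", ch = ch, eps = eps, momentum = momentum,
       params = list(gamma = rep(1, ch), beta = rep(0, ch)),
       buffers = list(rm = rep(0, ch), rv = rep(1, ch)))
}

nn_relu <- function() list(kind = "relu", params = list())

nn_maxpool <- function(kernel = 3L, stride = 2L, pad = 1L)
  list(kind = "maxpool", kernel = as.integer(kernel),
       stride = as.integer(stride), pad = as.integer(pad), params = list())

nn_avgpool <- function(kernel = 2L, stride = 2L)
  list(kind = "avgpool", kernel = as.integer(kernel),
       stride = as.integer(stride), pad = 0L, params = list())

nn_gap <- function() list(kind = "gap", params = list())

nn_linear <- function(in_f, out_f) {
  bound <- 1 / sqrt(in_f)
  list(kind = "linear", in_f = in_f, out_f = out_f,
       params = list(W = matrix(runif(out_f * in_f, -bound, bound), out_f, in_f),
                     b = runif(out_f, -bound, bound)))
}

nn_seq <- function(children) list(kind = "seq", children = children, params = list())

# Bottlenecked dense layer: BN-ReLU-1x1 conv-BN-ReLU-3x3 conv, output
# concatenated onto the input along channels.
nn_dense_layer <- function(in_ch, growth, bn_size = 4L) {
  inter <- bn_size * growth
  list(kind = "dense_layer", in_ch = in_ch, growth = growth,
       children = list(nn_bn(in_ch), nn_relu(), nn_conv(in_ch, inter, 1L),
                       nn_bn(inter), nn_relu(), nn_conv(inter, growth, 3L, pad = 1L)),
       params = list())
}

nn_dense_block <- function(in_ch, n_layers, growth, bn_size = 4L) {
  ch <- in_ch
  layers <- vector("list", n_layers)
  for (i in seq_len(n_layers)) {
    layers[[i]] <- nn_dense_layer(ch, growth, bn_size)
    ch <- ch + growth
  }
  list(kind = "seq", children = layers, params = list(), out_ch = ch)
}

nn_transition <- function(in_ch, out_ch) {
  nn_seq(list(nn_bn(in_ch), nn_relu(), nn_conv(in_ch, out_ch, 1L), nn_avgpool()))
}

# ---- forward / backward ----------------------------------------------------

nn_forward <- function(m, t, training = FALSE) {
  switch(m$kind,
    conv = {
      g <- conv_geom(t$h, t$w, m$kernel, m$stride, m$pad)
      C <- dim(t$x)[2]; N <- dim(t$x)[3]
      cols <- gather_cols(t, g)
      cols <- aperm(cols, c(1, 3, 2, 4))
      dim(cols) <- c(g$k2 * C, g$outHW * N)
      Y <- m$params$W %*% cols
      dim(Y) <- c(m$out_ch, g$outHW, N)
      list(y = list(x = aperm(Y, c(2, 1, 3)), h = g$outh, w = g$outw),
           cache = list(cols = cols, g = g, C = C, N = N), m = m)
    },
    bn = {
      d <- dim(t$x); HW <- d[1]; C <- d[2]; N <- d[3]
      xr <- matrix(aperm(t$x, c(1, 3, 2)), HW * N, C)
      if (training) {
        mu <- colMeans(xr)
        v <- colMeans(xr^2) - mu^2
        mom <- m$momentum
        m$buffers$rm <- (1 - mom) * m$buffers$rm + mom * mu
        m$buffers$rv <- (1 - mom) * m$buffers$rv + mom * v
      } else {
        mu <- m$buffers$rm; v <- m$buffers$rv
      }
      invstd <- 1 / sqrt(v + m$eps)
      n <- HW * N
      xhat <- (xr - rep(mu, each = n)) * rep(invstd, each = n)
      yr <- xhat * rep(m$params$gamma, each = n) + rep(m$params$beta, each = n)
      y <- aperm(array(yr, dim = c(HW, N, C)), c(1, 3, 2))
      list(y = list(x = y, h = t$h, w = t$w),
           cache = list(xhat = xhat, invstd = invstd, HW = HW, C = C, N = N,
                        training = training),
           m = m)
    },
    relu = {
      mask <- t$x > 0
      list(y = list(x = t$x * mask, h = t$h, w = t$w),
           cache = list(mask = mask), m = m)
    },
    maxpool = {
      g <- conv_geom(t$h, t$w, m$kernel, m$stride, m$pad)
      C <- dim(t$x)[2]; N <- dim(t$x)[3]
      cols <- gather_cols(t, g)                     # (k2, outHW, C, N)
      V <- matrix(cols, nrow = g$k2)
      a <- max.col(t(V), ties.method = "first")
      vals <- V[(seq_along(a) - 1L) * g$k2 + a]
      y <- array(vals, dim = c(g$outHW, C, N))
      list(y = list(x = y, h = g$outh, w = g$outw),
           cache = list(g = g, argmax = array(a, dim = c(g$outHW, C, N)),
                        C = C, N = N), m = m)
    },
    avgpool = {
      g <- conv_geom(t$h, t$w, m$kernel, m$stride, m$pad)
      C <- dim(t$x)[2]; N <- dim(t$x)[3]
      cols <- gather_cols(t, g)
      V <- matrix(cols, nrow = g$k2)
      y <- array(.colMeans(V, g$k2, ncol(V)), dim = c(g$outHW, C, N))
      list(y = list(x = y, h = g$outh, w = g$outw),
           cache = list(g = g, C = C, N = N), m = m)
    },
    gap = {
      d <- dim(t$x); HW <- d[1]; C <- d[2]; N <- d[3]
      xm <- matrix(t$x, HW, C * N)
      y <- matrix(.colMeans(xm, HW, C * N), C, N)
      list(y = y, cache = list(HW = HW, C = C, N = N), m = m)
    },
    linear = {
      y <- m$params$W %*% t + m$params$b
      list(y = y, cache = list(x = t), m = m)
    },
    seq = {
      caches <- vector("list", length(m$children))
      cur <- t
      for (i in seq_along(m$children)) {
        r <- nn_forward(m$children[[i]], cur, training)
        caches[[i]] <- r$cache
        m$children[[i]] <- r$m
        cur <- r$y
      }
      list(y = cur, cache = caches, m = m)
    },
    dense_layer = {
      C <- dim(t$x)[2]; N <- dim(t$x)[3]
      caches <- vector("list", length(m$children))
      cur <- t
      for (i in seq_along(m$children)) {
        r <- nn_forward(m$children[[i]], cur, training)
        caches[[i]] <- r$cache
        m$children[[i]] <- r$m
        cur <- r$y
      }
      G <- dim(cur$x)[2]
      y <- array(0, dim = c(t$h * t$w, C + G, N))
      y[, seq_len(C), ] <- t$x
      y[, C + seq_len(G), ] <- cur$x
      list(y = list(x = y, h = t$h, w = t$w),
           cache = list(chain = caches, C = C, G = G), m = m)
    },
    stop("unknown module kind: ", m$kind)
  )
}

nn_backward <- function(m, cache, dy) {
  switch(m$kind,
    conv = {
      g <- cache$g; C <- cache$C; N <- cache$N
      dYm <- matrix(aperm(dy$x, c(2, 1, 3)), m$out_ch, g$outHW * N)
      dW <- dYm %*% t(cache$cols)
      dcols <- crossprod(m$params$W, dYm)
      dim(dcols) <- c(g$k2, C, g$outHW, N)
      dcols <- aperm(dcols, c(1, 3, 2, 4))
      dim(dcols) <- c(g$k2 * g$outHW, C * N)
      dXm <- unpad_channels(scatter_cols(dcols, g, C * N), g)
      list(dx = list(x = array(dXm, dim = c(g$h * g$w, C, N)), h = g$h, w = g$w),
           grads = list(W = dW))
    },
    bn = {
      HW <- cache$HW; C <- cache$C; N <- cache$N; n <- HW * N
      dyr <- matrix(aperm(dy$x, c(1, 3, 2)), n, C)
      xhat <- cache$xhat
      dgamma <- colSums(dyr * xhat)
      dbeta <- colSums(dyr)
      dxhat <- dyr * rep(m$params$gamma, each = n)
      if (cache$training) {
        s1 <- colSums(dxhat); s2 <- colSums(dxhat * xhat)
        dxr <- rep(cache$invstd / n, each = n) *
          (n * dxhat - rep(s1, each = n) - xhat * rep(s2, each = n))
      } else {
        dxr <- dxhat * rep(cache$invstd, each = n)
      }
      dx <- aperm(array(dxr, dim = c(HW, N, C)), c(1, 3, 2))
      list(dx = list(x = dx, h = dy$h, w = dy$w),
           grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = {
      list(dx = list(x = dy$x * cache$mask, h = dy$h, w = dy$w), grads = list())
    },
    maxpool = {
      g <- cache$g; C <- cache$C; N <- cache$N
      dymat <- matrix(dy$x, g$outHW, C * N)
      Amat <- matrix(cache$argmax, g$outHW, C * N)
      dXp <- matrix(0, g$phw, C * N)
      for (a in seq_len(g$k2)) {
        rows <- g$gather[a, ]
        dXp[rows, ] <- dXp[rows, ] + dymat * (Amat == a)
      }
      dXm <- unpad_channels(dXp, g)
      list(dx = list(x = array(dXm, dim = c(g$h * g$w, C, N)), h = g$h, w = g$w),
           grads = list())
    },
    avgpool = {
      g <- cache$g; C <- cache$C; N <- cache$N
      dymat <- matrix(dy$x, g$outHW, C * N) / g$k2
      dXp <- matrix(0, g$phw, C * N)
      for (a in seq_len(g$k2)) {
        rows <- g$gather[a, ]
        dXp[rows, ] <- dXp[rows, ] + dymat
      }
      dXm <- unpad_channels(dXp, g)
      list(dx = list(x = array(dXm, dim = c(g$h * g$w, C, N)), h = g$h, w = g$w),
           grads = list())
    },
    gap = {
      HW <- cache$HW; C <- cache$C; N <- cache$N
      dXm <- matrix(rep(as.numeric(dy), each = HW) / HW, HW, C * N)
      list(dx = list(x = array(dXm, dim = c(HW, C, N)), h = NA, w = NA),
           grads = list())
    },
    linear = {
      list(dx = crossprod(m$params$W, dy),
           grads = list(W = dy %*% t(cache$x), b = rowSums(dy)))
    },
    seq = {
      grads <- vector("list", length(m$children))
      cur <- dy
      for (i in rev(seq_along(m$children))) {
        r <- nn_backward(m$children[[i]], cache[[i]], cur)
        grads[[i]] <- r$grads
        cur <- r$dx
      }
      list(dx = cur, grads = grads)
    },
    dense_layer = {
      C <- cache$C; G <- cache$G
      dx_direct <- dy$x[, seq_len(C), , drop = FALSE]
      dg <- list(x = dy$x[, C + seq_len(G), , drop = FALSE], h = dy$h, w = dy$w)
      grads <- vector("list", length(m$children))
      cur <- dg
      for (i in rev(seq_along(m$children))) {
        r <- nn_backward(m$children[[i]], cache$chain[[i]], cur)
        grads[[i]] <- r$grads
        cur <- r$dx
      }
      list(dx = list(x = cur$x + dx_direct, h = dy$h, w = dy$w), grads = grads)
    },
    stop("unknown module kind: ", m$kind)
  )
}

# ---- parameter plumbing ----------------------------------------------------

nn_flatten <- function(node) {
  if (!is.null(node$children))
    unlist(lapply(node$children, nn_flatten), recursive = FALSE, use.names = FALSE)
  else if (length(node$params)) unname(node$params)
  else list()
}

nn_flatten_grads <- function(m, grads) {
  if (!is.null(m$children)) {
    unlist(lapply(seq_along(m$children),
                  function(i) nn_flatten_grads(m$children[[i]], grads[[i]])),
           recursive = FALSE, use.names = FALSE)
  } else if (length(m$params)) unname(grads)
  else list()
}

nn_set_params <- function(m, flat, pos = new.env()) {
  if (is.null(pos$i)) pos$i <- 0L
  if (!is.null(m$children)) {
    m$children <- lapply(m$children, nn_set_params, flat = flat, pos = pos)
  } else if (length(m$params)) {
    for (nm in names(m$params)) {
      pos$i <- pos$i + 1L
      p <- flat[[pos$i]]
      dim(p) <- dim(m$params[[nm]])
      m$params[[nm]] <- p
    }
  }
  m
}

# ---- AdamW with AMSGrad ----------------------------------------------------

adamw_init <- function(flat_params) {
  zeros <- lapply(flat_params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(step = 0L, m = zeros, v = zeros, vmax = zeros)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamw_step <- function(flat_params, flat_grads, state, lr, weight_decay,
                       betas = c(0.9, 0.999), eps = 1e-8, amsgrad = TRUE) {
  state$step <- state$step + 1L
  b1 <- betas[1]; b2 <- betas[2]
  bc1 <- 1 - b1^state$step; bc2 <- 1 - b2^state$step
  for (i in seq_along(flat_params)) {
    g <- flat_grads[[i]]
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g * g
    if (amsgrad) {
      state$vmax[[i]] <- pmax(state$vmax[[i]], state$v[[i]])
      denom <- sqrt(state$vmax[[i]] / bc2) + eps
    } else {
      denom <- sqrt(state$v[[i]] / bc2) + eps
    }
    flat_params[[i]] <- flat_params[[i]] -
      lr * ((state$m[[i]] / bc1) / denom) - lr * weight_decay * flat_params[[i]]
  }
  list(params = flat_params, state = state)
}

# ---- softmax / weighted cross-entropy --------------------------------------

softmax_cols <- function(z) {
  mx <- apply(z, 2, max)
  e <- exp(z - rep(mx, each = nrow(z)))
  e / rep(colSums(e), each = nrow(z))
}

# logits: (K x N); y_idx: integer class indices 1..K; w: per-sample weights.
weighted_ce_loss <- function(logits, y_idx, w) {
  N <- ncol(logits); K <- nrow(logits)
  mx <- apply(logits, 2, max)
  zs <- logits - rep(mx, each = K)
  lse <- log(colSums(exp(zs)))
  logp <- zs - rep(lse, each = K)
  sel <- cbind(y_idx, seq_len(N))
  wsum <- sum(w)
  loss <- -sum(w * logp[sel]) / wsum
  p <- exp(logp)
  onehot <- matrix(0, K, N)
  onehot[sel] <- 1
  dlogits <- (p - onehot) * rep(w / wsum, each = K)
  list(loss = loss, dlogits = dlogits)
}
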