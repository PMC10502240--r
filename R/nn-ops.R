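# Minimal neural-network primitives with explicit reverse-mode gradients.
#
# Batches of sequence feature maps are 3D arrays (n, L, C): sample, position,
# channel. R's column-major layout makes (n, Lslice, C) slices contiguous in
# (sample, position) so they reshape to (n*Lslice, C) matrices for BLAS
# matrix products without copying semantics surprises.
#
# Every *_fwd returns list(out, cache); the matching *_bwd consumes the cache
# and the upstream gradient and returns gradients for inputs and parameters.
# Correctness is pinned by finite-difference tests.

# ---- initializers -----------------------------------------------------------

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# ---- dense ------------------------------------------------------------------

dense_init <- function(in_dim, out_dim) {
  list(W = he_init(c(in_dim, out_dim), in_dim), b = numeric(out_dim))
}

dense_fwd <- function(X, p) {
  out <- X %*% p$W
  out <- sweep(out, 2, p$b, "+")
  list(out = out, cache = X)
}

dense_bwd <- function(dY, cache, p) {
  list(dX = dY %*% t(p$W),
       grads = list(W = crossprod(cache, dY), b = colSums(dY)))
}

# ---- 1D convolution (valid, stride 1) --------------------------------------

conv1d_init <- function(k, in_ch, out_ch) {
  list(W = he_init(c(k, in_ch, out_ch), k * in_ch), b = numeric(out_ch))
}

conv1d_fwd <- function(X, p) {
  d <- dim(X); n <- d[1]; L <- d[2]; cin <- d[3]
  k <- dim(p$W)[1]; cout <- dim(p$W)[3]
  lout <- L - k + 1L
  if (lout < 1) stop(sprintf("conv input length %d shorter than kernel %d",
                             L, k))
  Y <- matrix(rep(p$b, each = n * lout), n * lout, cout)
  for (j in seq_len(k)) {
    Xs <- X[, j:(j + lout - 1L), , drop = FALSE]
    dim(Xs) <- c(n * lout, cin)
    Y <- Y + Xs %*% matrix(p$W[j, , ], cin, cout)
  }
  dim(Y) <- c(n, lout, cout)
  list(out = Y, cache = X)
}

conv1d_bwd <- function(dY, cache, p, need_dx = TRUE) {
  X <- cache
  d <- dim(X); n <- d[1]; L <- d[2]; cin <- d[3]
  k <- dim(p$W)[1]; cout <- dim(p$W)[3]
  lout <- dim(dY)[2]
  dYm <- dY; dim(dYm) <- c(n * lout, cout)
  dW <- array(0, dim(p$W))
  dX <- if (need_dx) array(0, dim(X))
  for (j in seq_len(k)) {
    idx <- j:(j + lout - 1L)
    Xs <- X[, idx, , drop = FALSE]
    dim(Xs) <- c(n * lout, cin)
    dW[j, , ] <- crossprod(Xs, dYm)
    if (need_dx) {
      dXs <- dYm %*% t(matrix(p$W[j, , ], cin, cout))
      dim(dXs) <- c(n, lout, cin)
      dX[, idx, ] <- dX[, idx, , drop = FALSE] + dXs
    }
  }
  list(dX = dX, grads = list(W = dW, b = colSums(dYm)))
}

# ---- max pooling (non-overlapping) -----------------------------------------

maxpool1d_fwd <- function(X, pool) {
  d <- dim(X); n <- d[1]; L <- d[2]; ch <- d[3]
  lout <- L %/% pool
  if (lout < 1) stop("pool window longer than input")
  cols1 <- seq(1L, by = pool, length.out = lout)
  out <- X[, cols1, , drop = FALSE]
  argmax <- array(1L, dim = c(n, lout, ch))
  if (pool > 1) for (j in 2:pool) {
    s <- X[, cols1 + (j - 1L), , drop = FALSE]
    m <- s > out
    out[m] <- s[m]
    argmax[m] <- j
  }
  list(out = out, cache = list(argmax = argmax, pool = pool, dims = d))
}

maxpool1d_bwd <- function(dY, cache) {
  d <- cache$dims; pool <- cache$pool
  lout <- dim(dY)[2]
  dX <- array(0, dim = d)
  cols1 <- seq(1L, by = pool, length.out = lout)
  for (j in seq_len(pool)) {
    m <- cache$argmax == j
    tmp <- array(0, dim = dim(dY))
    tmp[m] <- dY[m]
    dX[, cols1 + (j - 1L), ] <- tmp
  }
  dX
}

# ---- activations / dropout --------------------------------------------------

relu_fwd <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_bwd <- function(dY, cache) dY * cache

sigmoid <- function(z) 1 / (1 + exp(-z))

dropout_fwd <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(out = X, cache = NULL))
  mask <- array((stats::runif(length(X)) >= rate) / (1 - rate), dim = dim(X))
  list(out = X * mask, cache = mask)
}

dropout_bwd <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

# ---- LSTM -------------------------------------------------------------------

# Gate layout in the 4h-wide weight blocks: input, forget, cell, output.

lstm_init <- function(in_ch, h) {
  list(Wx = he_init(c(in_ch, 4L * h), in_ch),
       Wh = he_init(c(h, 4L * h), h),
       b = c(numeric(h), rep(1, h), numeric(2L * h)))  # forget bias 1
}

lstm_fwd <- function(X, p, reverse = FALSE) {
  d <- dim(X); n <- d[1]; Tn <- d[2]; cin <- d[3]
  h <- nrow(p$Wh)
  times <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  H <- array(0, dim = c(n, Tn, h))
  hs <- matrix(0, n, h); cs <- matrix(0, n, h)
  steps <- vector("list", Tn)
  for (s in seq_len(Tn)) {
    t <- times[s]
    Xt <- X[, t, ]; dim(Xt) <- c(n, cin)
    z <- Xt %*% p$Wx + hs %*% p$Wh +
      matrix(p$b, n, 4L * h, byrow = TRUE)
    ig <- sigmoid(z[, 1:h, drop = FALSE])
    fg <- sigmoid(z[, (h + 1):(2 * h), drop = FALSE])
    gg <- tanh(z[, (2 * h + 1):(3 * h), drop = FALSE])
    og <- sigmoid(z[, (3 * h + 1):(4 * h), drop = FALSE])
    c_prev <- cs
    cs <- fg * c_prev + ig * gg
    tc <- tanh(cs)
    h_prev <- hs
    hs <- og * tc
    H[, t, ] <- hs
    steps[[s]] <- list(Xt = Xt, ig = ig, fg = fg, gg = gg, og = og,
                       c_prev = c_prev, cs = cs, tc = tc, h_prev = h_prev)
  }
  list(out = H, cache = list(steps = steps, times = times, n = n,
                             cin = cin, h = h, Tn = Tn))
}

lstm_bwd <- function(dH, cache, p) {
  n <- cache$n; cin <- cache$cin; h <- cache$h; Tn <- cache$Tn
  dWx <- array(0, dim = dim(p$Wx)); dWh <- array(0, dim = dim(p$Wh))
  db <- numeric(4L * h)
  dX <- array(0, dim = c(n, Tn, cin))
  dh_next <- matrix(0, n, h); dc_next <- matrix(0, n, h)
  for (s in rev(seq_len(Tn))) {
    t <- cache$times[s]
    st <- cache$steps[[s]]
    dh <- dH[, t, ]; dim(dh) <- c(n, h)
    dh <- dh + dh_next
    dc <- dc_next + dh * st$og * (1 - st$tc^2)
    d_og <- dh * st$tc * st$og * (1 - st$og)
    d_ig <- dc * st$gg * st$ig * (1 - st$ig)
    d_fg <- dc * st$c_prev * st$fg * (1 - st$fg)
    d_gg <- dc * st$ig * (1 - st$gg^2)
    dz <- cbind(d_ig, d_fg, d_gg, d_og)
    dWx <- dWx + crossprod(st$Xt, dz)
    dWh <- dWh + crossprod(st$h_prev, dz)
    db <- db + colSums(dz)
    dX[, t, ] <- dz %*% t(p$Wx)
    dh_next <- dz %*% t(p$Wh)
    dc_next <- dc * st$fg
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

bilstm_init <- function(in_ch, h) {
  list(fw = lstm_init(in_ch, h), bw = lstm_init(in_ch, h))
}

bilstm_fwd <- function(X, p) {
  f <- lstm_fwd(X, p$fw, reverse = FALSE)
  b <- lstm_fwd(X, p$bw, reverse = TRUE)
  d <- dim(f$out)
  out <- array(0, dim = c(d[1], d[2], 2L * d[3]))
  out[, , seq_len(d[3])] <- f$out
  out[, , d[3] + seq_len(d[3])] <- b$out
  list(out = out, cache = list(f = f$cache, b = b$cache, h = d[3]))
}

bilstm_bwd <- function(dY, cache, p) {
  h <- cache$h
  df <- lstm_bwd(dY[, , seq_len(h), drop = FALSE], cache$f, p$fw)
  db <- lstm_bwd(dY[, , h + seq_len(h), drop = FALSE], cache$b, p$bw)
  list(dX = df$dX + db$dX, grads = list(fw = df$grads, bw = db$grads))
}

# ---- parameter-tree utilities ----------------------------------------------

#' @keywords internal
params_walk <- function(p, f, path = "") {
  if (is.list(p)) {
    for (nm in names(p)) params_walk(p[[nm]], f, paste0(path, "/", nm))
  } else {
    f(p, path)
  }
  invisible(NULL)
}

params_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- stats::setNames(
      lapply(names(a), function(nm) params_map2(a[[nm]], b[[nm]], f)),
      names(a))
    return(out)
  }
  f(a, b)
}

params_zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, params_zero_like))
  array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
}

params_add <- function(a, b) params_map2(a, b, `+`)

# Sum of f(leaf) over weight leaves; leaves named 'b' (biases) are skipped
# when penalize_bias is FALSE.
params_penalty <- function(p, f, penalize_bias = FALSE) {
  total <- 0
  rec <- function(q, nm) {
    if (is.list(q)) {
      for (k in names(q)) rec(q[[k]], k)
    } else if (penalize_bias || nm != "b") {
      total <<- total + f(q)
    }
  }
  rec(p, "")
  total
}

# Add regularization gradient in place: d/dW (l1|W| + l2 W^2).
params_reg_grad <- function(grads, params, l1, l2) {
  rec <- function(g, p, nm) {
    if (is.list(g)) {
      return(stats::setNames(
        lapply(names(g), function(k) rec(g[[k]], p[[k]], k)), names(g)))
    }
    if (nm == "b") return(g)
    g + l1 * sign(p) + 2 * l2 * p
  }
  rec(grads, params, "")
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = params_zero_like(params), v = params_zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- params_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- params_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- params_map2(state$m, state$v, function(m, v)
    (m / bc1) / (sqrt(v / bc2) + eps))
  params <- params_map2(params, mhat, function(p, u) p - lr * u)
  list(params = params, state = state)
}
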