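# Minimal neural-network primitives with explicit backpropagation.
#
# All image-like activations use NHWC layout: dim(x) = c(N, H, W, C).
# Convolutions are evaluated as im2col + matrix multiply so the heavy
# lifting is done by BLAS; the backward passes return exact gradients
# (verified by finite differences in the test suite).

# ---- initialisers -----------------------------------------------------

glorot_init <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

orthogonal_init <- function(n_in, n_out) {
  a <- matrix(rnorm(max(n_in, n_out)^2), max(n_in, n_out))
  q <- qr.Q(qr(a))
  q[seq_len(n_in), seq_len(n_out), drop = FALSE]
}

# ---- zero padding -----------------------------------------------------

pad_nhwc <- function(x, pt, pb, pl, pr) {
  d <- dim(x)
  out <- array(0, dim = c(d[1L], d[2L] + pt + pb, d[3L] + pl + pr, d[4L]))
  out[, pt + seq_len(d[2L]), pl + seq_len(d[3L]), ] <- x
  out
}

# same-padding amounts for kernel k (left/top gets the smaller share,
# matching the usual zero-filling convention for even kernels)
same_pad <- function(k) {
  p <- k - 1L
  c(lo = p %/% 2L, hi = p - p %/% 2L)
}

# ---- 2-D convolution (stride 1, same padding) -------------------------

# Linear gather indices into the padded NHWC array for im2col, memoised
# per shape: batch shapes recur every iteration, so the index matrix is
# built once and the per-call work is a single vector gather.
.im2col_idx <- new.env(parent = emptyenv())

im2col_indices <- function(n, hp, wp, cc, kh, kw, out_h, out_w) {
  key <- paste(n, hp, wp, cc, kh, kw, out_h, out_w, sep = "x")
  cached <- .im2col_idx[[key]]
  if (!is.null(cached)) return(cached)
  r_n <- rep(seq_len(n), times = out_h * out_w)
  r_i <- rep(rep(seq_len(out_h), each = n), times = out_w)
  r_j <- rep(seq_len(out_w), each = n * out_h)
  chan_off <- (seq_len(cc) - 1L) * (n * hp * wp)
  blocks <- vector("list", kh * kw)
  b <- 0L
  for (dj in seq_len(kw)) {
    for (di in seq_len(kh)) {
      pos <- r_n + n * ((r_i + di - 2L) + hp * (r_j + dj - 2L))
      b <- b + 1L
      blocks[[b]] <- outer(pos, chan_off, "+")
    }
  }
  idx <- do.call(cbind, blocks)
  storage.mode(idx) <- "integer"
  # stored as a flat vector so indexing is always linear (a matrix
  # subscript whose column count equals the array rank would be read
  # as coordinates)
  out <- list(idx = as.vector(idx), nr = nrow(idx), nc = ncol(idx))
  .im2col_idx[[key]] <- out
  out
}

im2col <- function(xp, kh, kw, out_h, out_w) {
  d <- dim(xp)                       # N, Hp, Wp, C
  ix <- im2col_indices(d[1L], d[2L], d[3L], d[4L], kh, kw, out_h, out_w)
  cols <- gather_idx(xp, ix$idx)
  dim(cols) <- c(ix$nr, ix$nc)
  cols
}

# Scatter-accumulate column gradients back onto the padded input
# (sequential accumulation in storage order, matching the forward
# gather's block order).
col2im <- function(dcols, n, hp, wp, cc, kh, kw, out_h, out_w) {
  ix <- im2col_indices(n, hp, wp, cc, kh, kw, out_h, out_w)
  dxp <- scatter_add(dcols, ix$idx, n * hp * wp * cc)
  dim(dxp) <- c(n, hp, wp, cc)
  dxp
}

conv2d_forward <- function(x, w, b) {
  # x: N,H,W,Cin ; w: kh*kw*Cin x Cout (kernel-position-major, see im2col)
  d <- dim(x)
  kh <- attr(w, "kh"); kw <- attr(w, "kw")
  ph <- same_pad(kh); pw <- same_pad(kw)
  xp <- pad_nhwc(x, ph[1L], ph[2L], pw[1L], pw[2L])
  cols <- im2col(xp, kh, kw, d[2L], d[3L])
  out <- sweep(cols %*% w, 2L, b, "+")
  list(out = array(out, dim = c(d[1L], d[2L], d[3L], ncol(w))),
       cache = list(cols = cols, dim_in = d, kh = kh, kw = kw,
                    ph = ph, pw = pw))
}

conv2d_backward <- function(dout, w, cache, need_dx = TRUE) {
  d <- cache$dim_in
  dmat <- matrix(dout, nrow = d[1L] * d[2L] * d[3L])
  dw <- crossprod(cache$cols, dmat)
  attr(dw, "kh") <- cache$kh; attr(dw, "kw") <- cache$kw
  db <- colSums(dmat)
  if (!need_dx) {
    return(list(dx = NULL, dw = dw, db = db))
  }
  dcols <- tcrossprod(dmat, w)
  hp <- d[2L] + sum(cache$ph); wp <- d[3L] + sum(cache$pw)
  dxp <- col2im(dcols, d[1L], hp, wp, d[4L], cache$kh, cache$kw,
                d[2L], d[3L])
  dx <- dxp[, cache$ph[1L] + seq_len(d[2L]), cache$pw[1L] + seq_len(d[3L]), ,
            drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

conv2d_weights <- function(kh, kw, c_in, c_out) {
  w <- glorot_init(kh * kw * c_in, c_out, dims = c(kh * kw * c_in, c_out))
  attr(w, "kh") <- as.integer(kh); attr(w, "kw") <- as.integer(kw)
  w
}

# ---- 2x2 stride-2 max pooling ----------------------------------------

maxpool2_forward <- function(x) {
  d <- dim(x)
  oh <- d[2L] %/% 2L; ow <- d[3L] %/% 2L
  i1 <- 2L * seq_len(oh) - 1L; j1 <- 2L * seq_len(ow) - 1L
  cand <- array(0, dim = c(d[1L], oh, ow, d[4L], 4L))
  cand[, , , , 1L] <- x[, i1, j1, , drop = FALSE]
  cand[, , , , 2L] <- x[, i1 + 1L, j1, , drop = FALSE]
  cand[, , , , 3L] <- x[, i1, j1 + 1L, , drop = FALSE]
  cand[, , , , 4L] <- x[, i1 + 1L, j1 + 1L, , drop = FALSE]
  cm <- matrix(cand, ncol = 4L)
  which_max <- max.col(cm, ties.method = "first")
  out <- cm[cbind(seq_len(nrow(cm)), which_max)]
  list(out = array(out, dim = c(d[1L], oh, ow, d[4L])),
       cache = list(dim_in = d, oh = oh, ow = ow, which_max = which_max))
}

maxpool2_backward <- function(dout, cache) {
  d <- cache$dim_in; oh <- cache$oh; ow <- cache$ow
  i1 <- 2L * seq_len(oh) - 1L; j1 <- 2L * seq_len(ow) - 1L
  dcand <- matrix(0, nrow = d[1L] * oh * ow * d[4L], ncol = 4L)
  dcand[cbind(seq_len(nrow(dcand)), cache$which_max)] <- as.vector(dout)
  dcand <- array(dcand, dim = c(d[1L], oh, ow, d[4L], 4L))
  dx <- array(0, dim = d)
  dx[, i1, j1, ] <- dcand[, , , , 1L]
  dx[, i1 + 1L, j1, ] <- dcand[, , , , 2L]
  dx[, i1, j1 + 1L, ] <- dcand[, , , , 3L]
  dx[, i1 + 1L, j1 + 1L, ] <- dcand[, , , , 4L]
  dx
}

# ---- dense layer ------------------------------------------------------

linear_forward <- function(x, w, b) {
  list(out = sweep(x %*% w, 2L, b, "+"), cache = x)
}

linear_backward <- function(dout, w, cache) {
  list(dx = tcrossprod(dout, w), dw = crossprod(cache, dout),
       db = colSums(dout))
}

relu_forward <- function(x) {
  out <- x
  out[out < 0] <- 0
  list(out = out, cache = x > 0)
}

relu_backward <- function(dout, cache) dout * cache

# ---- dilated 1-D convolution over time (same padding) -----------------
# x: N x T x C array; w: k*Cin x Cout with taps at offsets
# (-(k%/%2), ..) * dilation

conv1d_forward <- function(x, w, b, dilation = 1L) {
  d <- dim(x)
  k <- attr(w, "k")
  half <- (k - 1L) %/% 2L
  offs <- (seq_len(k) - 1L - half) * dilation
  cc <- d[3L]
  cols <- matrix(0, nrow = d[1L] * d[2L], ncol = k * cc)
  tpos <- seq_len(d[2L])
  for (j in seq_len(k)) {
    src <- tpos + offs[j]
    ok <- src >= 1L & src <= d[2L]
    blk <- array(0, dim = c(d[1L], d[2L], cc))
    blk[, ok, ] <- x[, src[ok], , drop = FALSE]
    cols[, (j - 1L) * cc + seq_len(cc)] <- matrix(blk, nrow = d[1L] * d[2L])
  }
  out <- sweep(cols %*% w, 2L, b, "+")
  list(out = array(out, dim = c(d[1L], d[2L], ncol(w))),
       cache = list(cols = cols, dim_in = d, k = k, offs = offs))
}

conv1d_backward <- function(dout, w, cache) {
  d <- cache$dim_in
  dmat <- matrix(dout, nrow = d[1L] * d[2L])
  dw <- crossprod(cache$cols, dmat)
  attr(dw, "k") <- cache$k
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, w)
  dx <- array(0, dim = d)
  cc <- d[3L]
  tpos <- seq_len(d[2L])
  for (j in seq_len(cache$k)) {
    src <- tpos + cache$offs[j]
    ok <- src >= 1L & src <= d[2L]
    blk <- array(dcols[, (j - 1L) * cc + seq_len(cc)],
                 dim = c(d[1L], d[2L], cc))
    dx[, src[ok], ] <- dx[, src[ok], , drop = FALSE] + blk[, ok, , drop = FALSE]
  }
  list(dx = dx, dw = dw, db = db)
}

conv1d_weights <- function(k, c_in, c_out) {
  w <- glorot_init(k * c_in, c_out, dims = c(k * c_in, c_out))
  attr(w, "k") <- as.integer(k)
  w
}

# ---- batch-style per-channel normalisation over (N, T) ----------------
# x: N x T x C; training mode uses batch statistics and updates running
# moments; inference uses the stored running moments.

batchnorm_forward <- function(x, gamma, beta, state, training, momentum = 0.9,
                              eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, ncol = d[3L])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2L, mu)^2)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2L, mu), 2L, inv, "*")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = array(out, dim = d), state = state,
       cache = list(xhat = xhat, inv = inv, dim = d, training = training))
}

batchnorm_backward <- function(dout, gamma, cache) {
  d <- cache$dim
  dm <- matrix(dout, ncol = d[3L])
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  n <- nrow(dm)
  dxhat <- sweep(dm, 2L, gamma, "*")
  if (cache$training) {
    dx <- sweep(dxhat - rep(colMeans(dxhat), each = n) -
                  cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n),
                2L, cache$inv, "*")
  } else {
    dx <- sweep(dxhat, 2L, cache$inv, "*")
  }
  list(dx = array(dx, dim = d), dgamma = dgamma, dbeta = dbeta)
}

# ---- dropout ----------------------------------------------------------

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = x, cache = NULL))
  }
  mask <- array(rbinom(length(x), 1L, 1 - rate), dim = dim(x)) / (1 - rate)
  list(out = x * mask, cache = mask)
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

# ---- softmax cross-entropy -------------------------------------------

# probs: N x K; y: integer class in 1..K. Returns mean loss and dlogits.
softmax_xent <- function(logits, y, prob_floor = 1e-12) {
  p <- softmax(logits)
  n <- nrow(p)
  picked <- pmax(p[cbind(seq_len(n), y)], prob_floor)
  loss <- -mean(log(picked))
  dlogits <- p
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}

# ---- Adam optimiser ---------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}
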