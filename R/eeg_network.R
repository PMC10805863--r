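# The EEG branch: per-slice band attention, a four-layer CNN with max
# pooling and a 512-unit dense layer, a two-layer peephole LSTM (hidden
# 128), additive self-attention over time steps, and a softmax
# classifier. Widths are configurable; the defaults are the reference
# architecture (conv channels 64/128/256/128, FC 512, hidden 128).

#' Construct an EEG emotion-recognition network
#'
#' Builds the parameter set for the EEG branch. Convolutions use zero
#' filling and ReLU; the 2 x 2 stride-2 max pool follows the conv stack;
#' the dense layer feeds a stacked peephole LSTM whose top-layer hidden
#' states pass through self-attention into the classifier. Convolutional
#' and dense weights use uniform Glorot initialisation, recurrent maps an
#' orthogonal initialisation; peephole gates see the cell state
#' elementwise.
#'
#' @param T Time slices per sample.
#' @param B Input channel count of the first conv (number of bands, or
#'   samples-per-slice for the raw-input ablation).
#' @param H,W Spatial grid size (default 9 x 9).
#' @param conv_channels Output channels of the four conv layers.
#' @param kernels Square kernel sizes of the four conv layers.
#' @param fc_dim Dense layer width feeding the LSTM.
#' @param hidden LSTM hidden size (also the feature dimension used for
#'   distillation).
#' @param lstm_layers Number of stacked LSTM layers.
#' @param n_class Number of output classes.
#' @param use_band_attention,use_self_attention Ablation switches.
#' @param seed Integer seed for initialisation.
#' @return Object of class `"eeg_net"`.
#' @export
eeg_net <- function(T = 4L, B = 4L, H = 9L, W = 9L,
                    conv_channels = c(64L, 128L, 256L, 128L),
                    kernels = c(5L, 4L, 3L, 1L),
                    fc_dim = 512L, hidden = 128L, lstm_layers = 2L,
                    n_class = 2L, use_band_attention = TRUE,
                    use_self_attention = TRUE, seed = 1L) {
  stop_if(length(conv_channels) != 4L || length(kernels) != 4L,
          "conv stack must have 4 layers")
  cfg <- list(T = as.integer(T), B = as.integer(B), H = as.integer(H),
              W = as.integer(W), conv_channels = as.integer(conv_channels),
              kernels = as.integer(kernels), fc_dim = as.integer(fc_dim),
              hidden = as.integer(hidden),
              lstm_layers = as.integer(lstm_layers),
              n_class = as.integer(n_class),
              use_band_attention = isTRUE(use_band_attention),
              use_self_attention = isTRUE(use_self_attention),
              seed = as.integer(seed))
  params <- with_seed(seed, init_eeg_params(cfg))
  structure(list(config = cfg, params = params), class = "eeg_net")
}

init_eeg_params <- function(cfg) {
  p <- list()
  c_in <- cfg$B
  for (l in 1:4) {
    k <- cfg$kernels[l]
    c_out <- cfg$conv_channels[l]
    p[[paste0("conv", l, "_w")]] <- conv2d_weights(k, k, c_in, c_out)
    p[[paste0("conv", l, "_b")]] <- numeric(c_out)
    c_in <- c_out
  }
  flat <- (cfg$H %/% 2L) * (cfg$W %/% 2L) * c_in
  p$fc_w <- glorot_init(flat, cfg$fc_dim)
  p$fc_b <- numeric(cfg$fc_dim)
  m <- cfg$fc_dim
  for (l in seq_len(cfg$lstm_layers)) {
    h <- cfg$hidden
    for (g in c("i", "f", "c", "o")) {
      p[[paste0("l", l, "_Wy", g)]] <- glorot_init(m, h)
      p[[paste0("l", l, "_Wh", g)]] <- orthogonal_init(h, h)
      p[[paste0("l", l, "_b", g)]] <- numeric(h)
    }
    for (g in c("i", "f", "o")) {
      p[[paste0("l", l, "_p", g)]] <- numeric(h)   # diagonal peepholes
    }
    m <- h
  }
  if (cfg$use_band_attention) {
    bg <- with_seed(cfg$seed + 101L, band_gate_params(cfg$B))
    p$gate_w <- bg$w
  }
  if (cfg$use_self_attention) {
    sa <- self_attention_params(cfg$hidden)
    for (nm in names(sa)) p[[paste0("attn_", nm)]] <- sa[[nm]]
  }
  p$head_w <- glorot_init(cfg$hidden, cfg$n_class)
  p$head_b <- numeric(cfg$n_class)
  p
}

#' @export
print.eeg_net <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat("EEG branch: input", cfg$T, "x", cfg$B, "x", cfg$H, "x", cfg$W,
      "-> conv", paste(cfg$conv_channels, collapse = "/"),
      "-> fc", cfg$fc_dim, "->", cfg$lstm_layers, "x LSTM(", cfg$hidden,
      ")\n")
  cat("  band attention:", cfg$use_band_attention,
      "| self-attention:", cfg$use_self_attention,
      "|", format(n_par, big.mark = ","), "parameters\n")
  invisible(x)
}

# ---- CNN over merged (N*T) slices ------------------------------------

eeg_cnn_forward <- function(x_nhwc, params) {
  caches <- list()
  h <- x_nhwc
  for (l in 1:4) {
    cv <- conv2d_forward(h, params[[paste0("conv", l, "_w")]],
                         params[[paste0("conv", l, "_b")]])
    rl <- relu_forward(cv$out)
    caches[[paste0("conv", l)]] <- cv$cache
    caches[[paste0("relu", l)]] <- rl$cache
    h <- rl$out
  }
  mp <- maxpool2_forward(h)
  caches$pool <- mp$cache
  d <- dim(mp$out)
  flat <- matrix(mp$out, nrow = d[1L])
  fc <- linear_forward(flat, params$fc_w, params$fc_b)
  caches$fc <- fc$cache
  caches$pool_dim <- d
  list(out = fc$out, caches = caches)
}

eeg_cnn_backward <- function(dout, params, caches, need_dx = TRUE) {
  grads <- list()
  lb <- linear_backward(dout, params$fc_w, caches$fc)
  grads$fc_w <- lb$dw; grads$fc_b <- lb$db
  dpool <- array(lb$dx, dim = caches$pool_dim)
  dh <- maxpool2_backward(dpool, caches$pool)
  for (l in 4:1) {
    dh <- relu_backward(dh, caches[[paste0("relu", l)]])
    cb <- conv2d_backward(dh, params[[paste0("conv", l, "_w")]],
                          caches[[paste0("conv", l)]],
                          need_dx = l > 1L || need_dx)
    grads[[paste0("conv", l, "_w")]] <- cb$dw
    grads[[paste0("conv", l, "_b")]] <- cb$db
    dh <- cb$dx
  }
  list(dx = dh, grads = grads)
}

#' CNN stage of the EEG branch for a single time slice
#'
#' Four same-padded ReLU convolutions, 2 x 2 stride-2 max pooling,
#' flatten, and a dense layer.
#'
#' @param slice `B x H x W` numeric array.
#' @param net An [eeg_net()].
#' @return Numeric vector of length `fc_dim` (512 by default).
#' @export
cnn_forward <- function(slice, net) {
  d <- dim(slice)
  cfg <- net$config
  stop_if(length(d) != 3L || d[1L] != cfg$B || d[2L] != cfg$H ||
            d[3L] != cfg$W, "slice must be B x H x W matching the net")
  x <- array(aperm(array(slice, dim = c(1L, d)), c(1L, 3L, 4L, 2L)),
             dim = c(1L, d[2L], d[3L], d[1L]))
  as.numeric(eeg_cnn_forward(x, net$params)$out)
}

# ---- peephole LSTM ----------------------------------------------------

lstm_layer_forward <- function(y, params, prefix) {
  d <- dim(y)                              # N, T, m
  n <- d[1L]; TT <- d[2L]
  hdim <- length(params[[paste0(prefix, "_bi")]])
  hs <- array(0, dim = c(n, TT, hdim))
  h <- matrix(0, n, hdim); cc <- matrix(0, n, hdim)
  steps <- vector("list", TT)
  for (t in seq_len(TT)) {
    yt <- matrix(y[, t, ], nrow = n)
    i <- sigmoid(sweep(yt %*% params[[paste0(prefix, "_Wyi")]] +
                         h %*% params[[paste0(prefix, "_Whi")]] +
                         sweep(cc, 2L, params[[paste0(prefix, "_pi")]], "*"),
                       2L, params[[paste0(prefix, "_bi")]], "+"))
    f <- sigmoid(sweep(yt %*% params[[paste0(prefix, "_Wyf")]] +
                         h %*% params[[paste0(prefix, "_Whf")]] +
                         sweep(cc, 2L, params[[paste0(prefix, "_pf")]], "*"),
                       2L, params[[paste0(prefix, "_bf")]], "+"))
    g <- tanh(sweep(yt %*% params[[paste0(prefix, "_Wyc")]] +
                      h %*% params[[paste0(prefix, "_Whc")]],
                    2L, params[[paste0(prefix, "_bc")]], "+"))
    c_new <- f * cc + i * g
    o <- sigmoid(sweep(yt %*% params[[paste0(prefix, "_Wyo")]] +
                         h %*% params[[paste0(prefix, "_Who")]] +
                         sweep(c_new, 2L, params[[paste0(prefix, "_po")]],
                               "*"),
                       2L, params[[paste0(prefix, "_bo")]], "+"))
    tc <- tanh(c_new)
    h_new <- o * tc
    steps[[t]] <- list(yt = yt, h_prev = h, c_prev = cc, i = i, f = f,
                       g = g, o = o, c = c_new, tc = tc)
    h <- h_new; cc <- c_new
    hs[, t, ] <- h
  }
  list(out = hs, cache = steps)
}

lstm_layer_backward <- function(dhs, params, cache, prefix) {
  TT <- length(cache)
  n <- nrow(cache[[1L]]$yt)
  m <- ncol(cache[[1L]]$yt)
  hdim <- ncol(cache[[1L]]$i)
  g0 <- function(r, c) matrix(0, r, c)
  gr <- list()
  for (g in c("i", "f", "c", "o")) {
    gr[[paste0(prefix, "_Wy", g)]] <- g0(m, hdim)
    gr[[paste0(prefix, "_Wh", g)]] <- g0(hdim, hdim)
    gr[[paste0(prefix, "_b", g)]] <- numeric(hdim)
  }
  for (g in c("i", "f", "o")) gr[[paste0(prefix, "_p", g)]] <- numeric(hdim)
  dy <- array(0, dim = c(n, TT, m))
  dh_next <- g0(n, hdim); dc_next <- g0(n, hdim)
  for (t in rev(seq_len(TT))) {
    st <- cache[[t]]
    dh <- matrix(dhs[, t, ], nrow = n) + dh_next
    do <- dh * st$tc * st$o * (1 - st$o)
    dc <- dh * st$o * (1 - st$tc^2) + dc_next +
      sweep(do, 2L, params[[paste0(prefix, "_po")]], "*")
    di <- dc * st$g * st$i * (1 - st$i)
    df <- dc * st$c_prev * st$f * (1 - st$f)
    dg <- dc * st$i * (1 - st$g^2)
    dc_prev <- dc * st$f +
      sweep(di, 2L, params[[paste0(prefix, "_pi")]], "*") +
      sweep(df, 2L, params[[paste0(prefix, "_pf")]], "*")
    dyt <- g0(n, m); dh_prev <- g0(n, hdim)
    for (gset in list(list(d = di, g = "i"), list(d = df, g = "f"),
                      list(d = dg, g = "c"), list(d = do, g = "o"))) {
      dd <- gset$d; gg <- gset$g
      gr[[paste0(prefix, "_Wy", gg)]] <-
        gr[[paste0(prefix, "_Wy", gg)]] + crossprod(st$yt, dd)
      gr[[paste0(prefix, "_Wh", gg)]] <-
        gr[[paste0(prefix, "_Wh", gg)]] + crossprod(st$h_prev, dd)
      gr[[paste0(prefix, "_b", gg)]] <-
        gr[[paste0(prefix, "_b", gg)]] + colSums(dd)
      dyt <- dyt + tcrossprod(dd, params[[paste0(prefix, "_Wy", gg)]])
      dh_prev <- dh_prev + tcrossprod(dd, params[[paste0(prefix, "_Wh", gg)]])
    }
    gr[[paste0(prefix, "_pi")]] <- gr[[paste0(prefix, "_pi")]] +
      colSums(di * st$c_prev)
    gr[[paste0(prefix, "_pf")]] <- gr[[paste0(prefix, "_pf")]] +
      colSums(df * st$c_prev)
    gr[[paste0(prefix, "_po")]] <- gr[[paste0(prefix, "_po")]] +
      colSums(do * st$c)
    dy[, t, ] <- dyt
    dh_next <- dh_prev
    dc_next <- dc_prev
  }
  list(dy = dy, grads = gr)
}

#' LSTM stage of the EEG branch
#'
#' Runs the stacked peephole LSTM over a `T x fc_dim` feature sequence
#' from zero initial state and returns all top-layer hidden states.
#'
#' @param y `T x fc_dim` matrix (one sample's CNN outputs in time order).
#' @param net An [eeg_net()].
#' @return `T x hidden` matrix of top-layer hidden states.
#' @export
lstm_forward <- function(y, net) {
  stop_if(ncol(y) != net$config$fc_dim, "input width must be fc_dim")
  h <- array(y, dim = c(1L, nrow(y), ncol(y)))
  for (l in seq_len(net$config$lstm_layers)) {
    h <- lstm_layer_forward(h, net$params, paste0("l", l))$out
  }
  matrix(h[1L, , ], nrow = dim(h)[2L])
}

#' Classify attention-weighted features
#'
#' Sums the reweighted hidden states over time, applies the dense head
#' and a softmax.
#'
#' @param A `T x hidden` matrix of attention-weighted features.
#' @param net An [eeg_net()].
#' @return Length-`n_class` probability vector.
#' @export
classify <- function(A, net) {
  pooled <- matrix(colSums(A), nrow = 1L)
  logits <- linear_forward(pooled, net$params$head_w, net$params$head_b)$out
  as.numeric(softmax(logits))
}

# ---- full branch ------------------------------------------------------

# X: N x T x B x H x W. Returns probs (N x K), Vs (N x T x hidden),
# band weights (N x T x B or NULL), logits, caches for backward.
eeg_forward <- function(net, X, keep_cache = FALSE) {
  cfg <- net$config
  p <- net$params
  d <- dim(X)
  stop_if(length(d) != 5L || !all(d[-1L] == c(cfg$T, cfg$B, cfg$H, cfg$W)),
          "input must be N x T x B x H x W matching the net config")
  n <- d[1L]; TT <- d[2L]
  m <- n * TT
  slices <- array(X, dim = c(m, cfg$B, cfg$H, cfg$W))
  gate_cache <- NULL
  band_w <- NULL
  if (cfg$use_band_attention) {
    ba <- band_attention_forward(slices, list(w = p$gate_w))
    band_w <- array(ba$weights, dim = c(n, TT, cfg$B))
    slices <- ba$out
    gate_cache <- ba$cache
  }
  x_nhwc <- aperm(slices, c(1L, 3L, 4L, 2L))
  cnn <- eeg_cnn_forward(x_nhwc, p)
  y <- array(cnn$out, dim = c(n, TT, cfg$fc_dim))
  hcur <- y
  lstm_caches <- vector("list", cfg$lstm_layers)
  for (l in seq_len(cfg$lstm_layers)) {
    lf <- lstm_layer_forward(hcur, p, paste0("l", l))
    lstm_caches[[l]] <- lf$cache
    hcur <- lf$out
  }
  Htop <- hcur                                       # N x T x hidden
  attn_caches <- NULL
  if (cfg$use_self_attention) {
    attn_caches <- vector("list", n)
    A <- array(0, dim = dim(Htop))
    Pmat <- matrix(0, n, TT)
    sa_par <- attn_params(p)
    for (i in seq_len(n)) {
      fw <- self_attention_forward(matrix(Htop[i, , ], nrow = TT), sa_par)
      A[i, , ] <- fw$A
      Pmat[i, ] <- fw$P
      attn_caches[[i]] <- fw$cache
    }
  } else {
    A <- Htop / TT
    Pmat <- matrix(1 / TT, n, TT)
  }
  pooled <- apply(A, c(1L, 3L), sum)
  if (is.null(dim(pooled))) pooled <- matrix(pooled, nrow = n)
  head <- linear_forward(pooled, p$head_w, p$head_b)
  probs <- softmax(head$out)
  res <- list(probs = probs, logits = head$out, Vs = A, P = Pmat,
              band_weights = band_w)
  if (keep_cache) {
    res$cache <- list(gate = gate_cache, cnn = cnn$caches,
                      lstm = lstm_caches, attn = attn_caches,
                      head_x = head$cache, n = n, TT = TT, Htop = Htop)
  }
  res
}

attn_params <- function(p) {
  list(Wd = p$attn_Wd, W1 = p$attn_W1, W2 = p$attn_W2, Wt = p$attn_Wt,
       b1 = p$attn_b1, b2 = p$attn_b2)
}

# dlogits: N x K; dVs: N x T x hidden (or NULL). Returns grads list.
eeg_backward <- function(net, fw, dlogits, dVs = NULL) {
  cfg <- net$config
  p <- net$params
  ca <- fw$cache
  n <- ca$n; TT <- ca$TT
  grads <- list()
  hb <- linear_backward(dlogits, p$head_w, ca$head_x)
  grads$head_w <- hb$dw; grads$head_b <- hb$db
  dpooled <- hb$dx                                   # N x hidden
  dA <- array(0, dim = c(n, TT, cfg$hidden))
  for (t in seq_len(TT)) dA[, t, ] <- dpooled
  if (!is.null(dVs)) dA <- dA + dVs
  dH <- array(0, dim = c(n, TT, cfg$hidden))
  if (cfg$use_self_attention) {
    sa_par <- attn_params(p)
    sa_g <- NULL
    for (i in seq_len(n)) {
      bk <- self_attention_backward(matrix(dA[i, , ], nrow = TT),
                                    params = sa_par, cache = ca$attn[[i]])
      dH[i, , ] <- bk$dH
      if (is.null(sa_g)) sa_g <- bk$grads else {
        for (nm in names(sa_g)) sa_g[[nm]] <- sa_g[[nm]] + bk$grads[[nm]]
      }
    }
    for (nm in names(sa_g)) grads[[paste0("attn_", nm)]] <- sa_g[[nm]]
  } else {
    dH <- dA / TT
  }
  dcur <- dH
  for (l in rev(seq_len(cfg$lstm_layers))) {
    lb <- lstm_layer_backward(dcur, p, ca$lstm[[l]], paste0("l", l))
    grads <- c(grads, lb$grads)
    dcur <- lb$dy
  }
  dy_mat <- matrix(dcur, nrow = n * TT)
  cb <- eeg_cnn_backward(dy_mat, p, ca$cnn,
                         need_dx = cfg$use_band_attention)
  grads <- c(grads, cb$grads)
  if (cfg$use_band_attention) {
    dslices <- aperm(cb$dx, c(1L, 4L, 2L, 3L))
    gb <- band_attention_backward(dslices, list(w = p$gate_w), ca$gate)
    grads$gate_w <- gb$dw
  }
  grads
}

#' Predict class probabilities from feature tensors
#'
#' @param object An [eeg_net()].
#' @param tensors `N x T x B x H x W` array (or a single
#'   `T x B x H x W` tensor).
#' @param ... Unused.
#' @return `N x n_class` matrix of probabilities.
#' @export
predict.eeg_net <- function(object, tensors, ...) {
  if (length(dim(tensors)) == 4L) {
    tensors <- array(tensors, dim = c(1L, dim(tensors)))
  }
  eeg_forward(object, tensors)$probs
}
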