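# The visual branch: a per-frame CNN (two conv+pool stages and a dense
# layer to 512), a temporal convolutional network of two parameter-shared
# dilated-convolution modules with residual connections, batch-style
# normalisation and dropout, then a per-step dense softmax head. The TCN
# output (T x 128) is the teacher feature sequence for distillation.

#' Construct the visual CNN-TCN network
#'
#' @param T Frames per clip.
#' @param height,width Frame size (48 x 48 by default).
#' @param cnn_channels Channels of the two spatial conv layers.
#' @param spatial_dim Per-frame feature width (default 512).
#' @param tcn_dim TCN channel width / output feature dimension
#'   (default 128).
#' @param n_class Number of classes.
#' @param dropout Dropout rate after each normalisation (default 0.5).
#' @param seed Integer seed for initialisation.
#' @return Object of class `"visual_net"`.
#' @export
visual_net <- function(T = 8L, height = 48L, width = 48L,
                       cnn_channels = c(32L, 64L), spatial_dim = 512L,
                       tcn_dim = 128L, n_class = 2L, dropout = 0.5,
                       seed = 1L) {
  cfg <- list(T = as.integer(T), height = as.integer(height),
              width = as.integer(width),
              cnn_channels = as.integer(cnn_channels),
              spatial_dim = as.integer(spatial_dim),
              tcn_dim = as.integer(tcn_dim), n_class = as.integer(n_class),
              dropout = dropout, seed = as.integer(seed))
  params <- with_seed(seed, init_visual_params(cfg))
  state <- init_visual_state(cfg)
  structure(list(config = cfg, params = params, state = state),
            class = "visual_net")
}

init_visual_params <- function(cfg) {
  p <- list()
  p$conv1_w <- conv2d_weights(3L, 3L, 3L, cfg$cnn_channels[1L])
  p$conv1_b <- numeric(cfg$cnn_channels[1L])
  p$conv2_w <- conv2d_weights(3L, 3L, cfg$cnn_channels[1L],
                              cfg$cnn_channels[2L])
  p$conv2_b <- numeric(cfg$cnn_channels[2L])
  flat <- (cfg$height %/% 4L) * (cfg$width %/% 4L) * cfg$cnn_channels[2L]
  p$fc_w <- glorot_init(flat, cfg$spatial_dim)
  p$fc_b <- numeric(cfg$spatial_dim)
  d <- cfg$tcn_dim
  p$proj_w <- conv1d_weights(1L, cfg$spatial_dim, d)
  p$proj_b <- numeric(d)
  # one parameter set, applied by both temporal-conv modules
  p$tcn_c1_w <- conv1d_weights(3L, d, d); p$tcn_c1_b <- numeric(d)
  p$tcn_c2_w <- conv1d_weights(3L, d, d); p$tcn_c2_b <- numeric(d)
  p$tcn_c3_w <- conv1d_weights(3L, d, d); p$tcn_c3_b <- numeric(d)
  p$tcn_res_w <- conv1d_weights(1L, d, d); p$tcn_res_b <- numeric(d)
  for (j in 1:3) {
    p[[paste0("tcn_g", j)]] <- rep(1, d)
    p[[paste0("tcn_be", j)]] <- numeric(d)
  }
  p$head_w <- glorot_init(d, cfg$n_class)
  p$head_b <- numeric(cfg$n_class)
  p
}

init_visual_state <- function(cfg) {
  d <- cfg$tcn_dim
  st <- list()
  for (m in 1:2) {
    for (j in 1:3) {
      st[[paste0("bn_m", m, "_", j)]] <- list(mean = numeric(d),
                                              var = rep(1, d))
    }
  }
  st
}

#' @export
print.visual_net <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat("Visual branch:", cfg$height, "x", cfg$width,
      "x3 frames -> CNN", paste(cfg$cnn_channels, collapse = "/"),
      "-> fc", cfg$spatial_dim, "-> shared TCN(", cfg$tcn_dim,
      ") x2 ->", cfg$n_class, "classes;",
      format(n_par, big.mark = ","), "parameters\n")
  invisible(x)
}

# ---- per-frame CNN ----------------------------------------------------

# frames: M x H x W x 3 (merged N*T); returns M x spatial_dim
visual_cnn_core <- function(frames, p) {
  cv1 <- conv2d_forward(frames, p$conv1_w, p$conv1_b)
  r1 <- relu_forward(cv1$out)
  mp1 <- maxpool2_forward(r1$out)
  cv2 <- conv2d_forward(mp1$out, p$conv2_w, p$conv2_b)
  r2 <- relu_forward(cv2$out)
  mp2 <- maxpool2_forward(r2$out)
  d <- dim(mp2$out)
  flat <- matrix(mp2$out, nrow = d[1L])
  fc <- linear_forward(flat, p$fc_w, p$fc_b)
  list(out = fc$out,
       cache = list(cv1 = cv1$cache, r1 = r1$cache, mp1 = mp1$cache,
                    cv2 = cv2$cache, r2 = r2$cache, mp2 = mp2$cache,
                    fc = fc$cache, pool_dim = d))
}

visual_cnn_core_backward <- function(dout, p, ca) {
  g <- list()
  lb <- linear_backward(dout, p$fc_w, ca$fc)
  g$fc_w <- lb$dw; g$fc_b <- lb$db
  dh <- maxpool2_backward(array(lb$dx, dim = ca$pool_dim), ca$mp2)
  dh <- relu_backward(dh, ca$r2)
  cb2 <- conv2d_backward(dh, p$conv2_w, ca$cv2)
  g$conv2_w <- cb2$dw; g$conv2_b <- cb2$db
  dh <- maxpool2_backward(cb2$dx, ca$mp1)
  dh <- relu_backward(dh, ca$r1)
  cb1 <- conv2d_backward(dh, p$conv1_w, ca$cv1)
  g$conv1_w <- cb1$dw; g$conv1_b <- cb1$db
  g
}

#' Per-frame spatial features of a clip
#'
#' Each frame is processed independently: conv, pool, conv, pool,
#' flatten, dense layer.
#'
#' @param frames `T x height x width x 3` array (values in `[0, 1]`).
#' @param net A [visual_net()].
#' @return `T x spatial_dim` matrix.
#' @export
visual_cnn_forward <- function(frames, net) {
  d <- dim(frames)
  cfg <- net$config
  stop_if(length(d) != 4L || d[2L] != cfg$height || d[3L] != cfg$width ||
            d[4L] != 3L, "frames must be T x %d x %d x 3",
          cfg$height, cfg$width)
  visual_cnn_core(frames, net$params)$out
}

# ---- temporal-conv module (shared parameters) -------------------------

tcn_module_forward <- function(x, p, state, m, training) {
  ca <- list()
  run <- function(cv_w, cv_b, dilation, bn_idx, h) {
    cv <- conv1d_forward(h, cv_w, cv_b, dilation)
    rl <- relu_forward(cv$out)
    bn <- batchnorm_forward(rl$out, p[[paste0("tcn_g", bn_idx)]],
                            p[[paste0("tcn_be", bn_idx)]],
                            state[[paste0("bn_m", m, "_", bn_idx)]],
                            training)
    state[[paste0("bn_m", m, "_", bn_idx)]] <<- bn$state
    dp <- dropout_forward(bn$out, if (training) netdrop else 0, training)
    list(out = dp$out, cache = list(cv = cv$cache, rl = rl$cache,
                                    bn = bn$cache, dp = dp$cache))
  }
  netdrop <- attr(state, "dropout") %||% 0.5
  s1 <- run(p$tcn_c1_w, p$tcn_c1_b, 1L, 1L, x); ca$s1 <- s1$cache
  s2 <- run(p$tcn_c2_w, p$tcn_c2_b, 2L, 2L, s1$out); ca$s2 <- s2$cache
  s3 <- run(p$tcn_c3_w, p$tcn_c3_b, 2L, 3L, s2$out); ca$s3 <- s3$cache
  res <- conv1d_forward(x, p$tcn_res_w, p$tcn_res_b, 1L)
  ca$res <- res$cache
  list(out = s3$out + res$out, cache = ca, state = state)
}

tcn_module_backward <- function(dout, p, ca) {
  g <- list()
  rb <- conv1d_backward(dout, p$tcn_res_w, ca$res)
  g$tcn_res_w <- rb$dw; g$tcn_res_b <- rb$db
  dx <- rb$dx
  back <- function(dh, cvw_name, bn_idx, cache) {
    dh <- dropout_backward(dh, cache$dp)
    bb <- batchnorm_backward(dh, p[[paste0("tcn_g", bn_idx)]], cache$bn)
    g[[paste0("tcn_g", bn_idx)]] <<-
      (g[[paste0("tcn_g", bn_idx)]] %||% 0) + bb$dgamma
    g[[paste0("tcn_be", bn_idx)]] <<-
      (g[[paste0("tcn_be", bn_idx)]] %||% 0) + bb$dbeta
    dh <- relu_backward(bb$dx, cache$rl)
    cb <- conv1d_backward(dh, p[[cvw_name]], cache$cv)
    g[[cvw_name]] <<- (g[[cvw_name]] %||% 0) + cb$dw
    bname <- sub("_w$", "_b", cvw_name)
    g[[bname]] <<- (g[[bname]] %||% 0) + cb$db
    cb$dx
  }
  dh <- back(dout, "tcn_c3_w", 3L, ca$s3)
  dh <- back(dh, "tcn_c2_w", 2L, ca$s2)
  dh <- back(dh, "tcn_c1_w", 1L, ca$s1)
  list(dx = dx + dh, grads = g)
}

# spatial: N x T x spatial_dim -> N x T x tcn_dim
tcn_core_forward <- function(spatial, p, state, training, dropout) {
  attr(state, "dropout") <- dropout
  pj <- conv1d_forward(spatial, p$proj_w, p$proj_b, 1L)
  m1 <- tcn_module_forward(pj$out, p, state, 1L, training)
  m2 <- tcn_module_forward(m1$out, p, m1$state, 2L, training)
  # temporal average pooling, kernel 2 stride 1, same padding:
  # out_t = (x_t + x_{t+1}) / 2, last step padded with zero
  x <- m2$out
  d <- dim(x)
  xs <- array(0, dim = d)
  if (d[2L] > 1L) xs[, seq_len(d[2L] - 1L), ] <- x[, 2:d[2L], , drop = FALSE]
  out <- (x + xs) / 2
  list(out = out, state = m2$state,
       cache = list(pj = pj$cache, m1 = m1$cache, m2 = m2$cache, d = d))
}

tcn_core_backward <- function(dout, p, ca) {
  d <- ca$d
  dx <- dout / 2
  if (d[2L] > 1L) {
    dx[, 2:d[2L], ] <- dx[, 2:d[2L], , drop = FALSE] +
      dout[, seq_len(d[2L] - 1L), , drop = FALSE] / 2
  }
  b2 <- tcn_module_backward(dx, p, ca$m2)
  b1 <- tcn_module_backward(b2$dx, p, ca$m1)
  g <- b2$grads
  for (nm in names(b1$grads)) g[[nm]] <- (g[[nm]] %||% 0) + b1$grads[[nm]]
  pb <- conv1d_backward(b1$dx, p$proj_w, ca$pj)
  g$proj_w <- pb$dw; g$proj_b <- pb$db
  list(dx = pb$dx, grads = g)
}

#' Temporal convolutional stage of the visual branch
#'
#' Projects per-frame features to the TCN width, applies two
#' parameter-shared temporal-convolution modules (conv k3 d1 plus two
#' dilated convs k3 d2, each with ReLU, normalisation and dropout, and a
#' 1 x 1-conv residual path), then a kernel-2 stride-1 average pool over
#' time. Sequence length is preserved (same padding).
#'
#' @param spatial `T x spatial_dim` matrix.
#' @param net A [visual_net()].
#' @param training Logical; enables batch statistics and dropout.
#' @return `T x tcn_dim` matrix.
#' @export
tcn_forward <- function(spatial, net, training = FALSE) {
  x <- array(spatial, dim = c(1L, nrow(spatial), ncol(spatial)))
  out <- tcn_core_forward(x, net$params, net$state, training,
                          net$config$dropout)$out
  matrix(out[1L, , ], nrow = nrow(spatial))
}

#' Receptive field of one temporal-convolution module
#'
#' Kernel-3 dilation-1 plus two kernel-3 dilation-2 layers: each layer
#' adds `(k - 1) * dilation` steps to the single-step base.
#'
#' @return Integer receptive field in time steps.
#' @export
tcn_receptive_field <- function() {
  layers <- data.frame(k = c(3L, 3L, 3L), d = c(1L, 2L, 2L))
  1L + sum((layers$k - 1L) * layers$d)
}

#' Per-step classification of spatio-temporal features
#'
#' Dense layer to `n_class` logits at every time step, softmax per row.
#'
#' @param Vt `T x tcn_dim` matrix.
#' @param net A [visual_net()].
#' @return `T x n_class` matrix; each row sums to 1.
#' @export
visual_classify <- function(Vt, net) {
  logits <- sweep(Vt %*% net$params$head_w, 2L, net$params$head_b, "+")
  softmax(logits)
}

# full forward over a batch of clips: clips N x T x H x W x 3
visual_forward <- function(net, clips, training = FALSE,
                           keep_cache = FALSE) {
  cfg <- net$config
  d <- dim(clips)
  stop_if(length(d) != 5L, "clips must be N x T x H x W x 3")
  n <- d[1L]; TT <- d[2L]
  frames <- array(clips, dim = c(n * TT, d[3L], d[4L], d[5L]))
  cnn <- visual_cnn_core(frames, net$params)
  spatial <- array(cnn$out, dim = c(n, TT, cfg$spatial_dim))
  tc <- tcn_core_forward(spatial, net$params, net$state, training,
                         cfg$dropout)
  vt <- tc$out                                       # N x T x tcn_dim
  vm <- matrix(vt, nrow = n * TT)
  logits <- sweep(vm %*% net$params$head_w, 2L, net$params$head_b, "+")
  res <- list(Vt = vt, logits = logits, state = tc$state)
  if (keep_cache) {
    res$cache <- list(cnn = cnn$cache, tcn = tc$cache, vm = vm,
                      n = n, TT = TT)
  }
  res
}

# dlogits: (N*T) x K aligned with rows of vm; dVt extra gradient on the
# TCN output (N x T x tcn_dim) or NULL
visual_backward <- function(net, fw, dlogits, dVt = NULL) {
  p <- net$params
  ca <- fw$cache
  g <- list()
  g$head_w <- crossprod(ca$vm, dlogits)
  g$head_b <- colSums(dlogits)
  dvm <- tcrossprod(dlogits, p$head_w)
  dvt <- array(dvm, dim = c(ca$n, ca$TT, ncol(dvm)))
  if (!is.null(dVt)) dvt <- dvt + dVt
  tb <- tcn_core_backward(dvt, p, ca$tcn)
  for (nm in names(tb$grads)) g[[nm]] <- tb$grads[[nm]]
  dsp <- matrix(tb$dx, nrow = ca$n * ca$TT)
  cg <- visual_cnn_core_backward(dsp, p, ca$cnn)
  for (nm in names(cg)) g[[nm]] <- cg[[nm]]
  g
}

#' Extract teacher feature sequences from a trained visual network
#'
#' Runs the clip through the CNN and TCN in inference mode (dropout off,
#' running normalisation statistics), returning the `T x tcn_dim`
#' spatio-temporal feature sequence used as the distillation target.
#'
#' @param clip `T x height x width x 3` array.
#' @param net A trained [visual_net()].
#' @return `T x tcn_dim` matrix.
#' @export
extract_visual_features <- function(clip, net) {
  spatial <- visual_cnn_forward(clip, net)
  tcn_forward(spatial, net, training = FALSE)
}

#' Predict clip-level class probabilities
#'
#' Averages the per-step softmax outputs over time.
#'
#' @param object A [visual_net()].
#' @param clips `N x T x H x W x 3` array (or one clip).
#' @param ... Unused.
#' @return `N x n_class` matrix of probabilities.
#' @export
predict.visual_net <- function(object, clips, ...) {
  if (length(dim(clips)) == 4L) {
    clips <- array(clips, dim = c(1L, dim(clips)))
  }
  fw <- visual_forward(object, clips, training = FALSE)
  n <- dim(clips)[1L]; TT <- dim(clips)[2L]
  pr <- softmax(fw$logits)
  parr <- array(pr, dim = c(n, TT, ncol(pr)))
  apply(parr, c(1L, 3L), mean)
}
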