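# Attention components: an efficient-channel-style frequency-band gate
# (global average pooling -> 1-D conv across bands -> sigmoid -> per-band
# rescaling) and an additive self-attention over LSTM time steps.

#' Adaptive 1-D convolution kernel size for the band gate
#'
#' `t = log2(c)/gamma + b/gamma`, rounded to the nearest odd integer
#' (ties toward the smaller odd value), with a minimum of 1.
#'
#' @param c Number of channels (here: frequency bands).
#' @param gamma,b Mapping constants (defaults 2 and 1).
#' @return Odd positive integer kernel size.
#' @export
adaptive_kernel_size <- function(c, gamma = 2, b = 1) {
  stop_if(c < 1, "c must be >= 1")
  t <- log2(c) / gamma + b / gamma
  lower <- max(1, 2 * floor((t - 1) / 2) + 1)    # largest odd <= t (>= 1)
  upper <- lower + 2
  k <- if (t - lower <= upper - t) lower else upper
  as.integer(max(1, k))
}

# The gate conv starts mildly amplifying (small positive taps) rather
# than random-signed: with one shared coefficient the amplify and
# attenuate directions are equally expressive per sample, so a
# random-signed start would leave the sign of the trained gate -- and
# hence the ordering of the reported mean band weights -- to
# initialisation noise instead of to the data.
band_gate_params <- function(n_bands, gamma = 2, b = 1) {
  k <- adaptive_kernel_size(n_bands, gamma, b)
  w <- conv1d_weights(k, 1L, 1L)
  w[] <- 0.25 / k
  list(w = w)
}

# Band attention over a batch of slices.
# x: N x B x H x W array (or one B x H x W slice); conv weight shared.
band_attention_forward <- function(x, params) {
  single <- length(dim(x)) == 3L
  if (single) x <- array(x, dim = c(1L, dim(x)))
  d <- dim(x)                              # N B H W
  g <- apply(x, c(1L, 2L), mean)           # N x B pooled descriptors
  if (is.null(dim(g))) g <- matrix(g, nrow = d[1L])
  gc <- array(g, dim = c(d[1L], d[2L], 1L))
  cv <- conv1d_forward(gc, params$w, 0)
  s <- matrix(cv$out, nrow = d[1L])        # N x B pre-activation
  wts <- sigmoid(s)                        # N x B weights in (0,1)
  wx <- array(wts, dim = d) * 0            # broadcast weights over H, W
  wx <- x * array(rep(wts, times = d[3L] * d[4L]), dim = d)
  list(weights = wts, out = if (single) array(wx, dim = d[-1L]) else wx,
       cache = list(x = x, wts = wts, conv = cv, dim = d, single = single))
}

band_attention_backward <- function(dout, params, cache) {
  d <- cache$dim
  if (cache$single) dout <- array(dout, dim = d)
  wts_full <- array(rep(cache$wts, times = d[3L] * d[4L]), dim = d)
  dx_direct <- dout * wts_full
  dwts <- apply(dout * cache$x, c(1L, 2L), sum)          # N x B
  if (is.null(dim(dwts))) dwts <- matrix(dwts, nrow = d[1L])
  ds <- dwts * cache$wts * (1 - cache$wts)
  bw <- conv1d_backward(array(ds, dim = c(d[1L], d[2L], 1L)),
                        params$w, cache$conv$cache)
  # pooled-descriptor gradient spread uniformly back over the H x W cells
  dg <- matrix(bw$dx, nrow = d[1L]) / (d[3L] * d[4L])
  dx <- dx_direct + array(rep(dg, times = d[3L] * d[4L]), dim = d)
  list(dx = if (cache$single) array(dx, dim = d[-1L]) else dx,
       dw = bw$dw)
}

#' Frequency-band attention gate
#'
#' Pools each band of a `B x H x W` feature slice to a scalar descriptor,
#' passes the descriptor vector through a 1-D convolution across bands
#' (kernel size from [adaptive_kernel_size()]), applies a sigmoid, and
#' rescales each band of the input by its weight.
#'
#' @param slice `B x H x W` numeric array.
#' @param params Optional gate parameters (a list with conv weight `w`);
#'   freshly initialised when omitted.
#' @return List with `weights` (length-B vector in (0,1)) and `weighted`
#'   (`B x H x W` array).
#' @export
band_attention <- function(slice, params = NULL) {
  d <- dim(slice)
  stop_if(length(d) != 3L, "slice must be a B x H x W array")
  if (is.null(params)) params <- band_gate_params(d[1L])
  fw <- band_attention_forward(slice, params)
  list(weights = as.numeric(fw$weights), weighted = fw$out)
}

# ---- self-attention over time steps ----------------------------------

self_attention_params <- function(d) {
  list(Wd = glorot_init(d, d), W1 = glorot_init(d, d),
       W2 = glorot_init(d, d), Wt = glorot_init(d, d),
       b1 = numeric(d), b2 = numeric(d))
}

#' Per-step self-attention scores
#'
#' For each hidden state `h_t`, an alignment vector `d_t = Wd h_t` is
#' formed by a bias-free linear map of the same dimension, and the score
#' vector is `S_t = Wt ReLU(W1 h_t + W2 d_t + b1) + b2`.
#'
#' @param H `T x d` matrix of hidden states.
#' @param params List with `Wd`, `W1`, `W2`, `Wt` (`d x d`) and `b1`,
#'   `b2` (length `d`).
#' @return `T x d` matrix of scores.
#' @export
self_attention_scores <- function(H, params) {
  stop_if(ncol(H) != nrow(params$W1), "hidden dimension mismatch")
  fw <- self_attention_forward(H, params)
  fw$S
}

self_attention_forward <- function(H, params) {
  D <- H %*% params$Wd
  Z <- sweep(H %*% params$W1 + D %*% params$W2, 2L, params$b1, "+")
  R <- relu_forward(Z)
  S <- sweep(R$out %*% params$Wt, 2L, params$b2, "+")
  N <- rowSums(S * H)
  P <- as.numeric(softmax(matrix(N, nrow = 1L)))
  A <- H * P
  list(S = S, N = N, P = P, A = A,
       cache = list(H = H, D = D, relu = R$cache, R = R$out, S = S,
                    N = N, P = P))
}

self_attention_backward <- function(dA, dP_extra = NULL, params, cache) {
  H <- cache$H; P <- cache$P
  dH <- dA * P
  dP <- rowSums(dA * H)
  if (!is.null(dP_extra)) dP <- dP + dP_extra
  # softmax backward: dN_t = P_t (dP_t - sum_j P_j dP_j)
  dN <- P * (dP - sum(P * dP))
  dS <- dN * H
  dH <- dH + cache$S * dN
  dR <- dS %*% t(params$Wt)
  dWt <- crossprod(cache$R, dS)
  db2 <- colSums(dS)
  dZ <- relu_backward(dR, cache$relu)
  db1 <- colSums(dZ)
  dW1 <- crossprod(H, dZ)
  dW2 <- crossprod(cache$D, dZ)
  dD <- dZ %*% t(params$W2)
  dWd <- crossprod(H, dD)
  dH <- dH + dZ %*% t(params$W1) + dD %*% t(params$Wd)
  list(dH = dH, grads = list(Wd = dWd, W1 = dW1, W2 = dW2, Wt = dWt,
                             b1 = db1, b2 = db2))
}

#' Attention probabilities over time steps
#'
#' Per-step similarity `N_t = S_t' h_t` softmaxed over `t`.
#'
#' @param S `T x d` score matrix.
#' @param H `T x d` hidden-state matrix.
#' @return List with `N` (length-T similarities) and `P` (length-T
#'   probabilities summing to 1).
#' @export
self_attention_probs <- function(S, H) {
  stop_if(!all(dim(S) == dim(H)), "S and H must have the same shape")
  N <- rowSums(S * H)
  P <- as.numeric(softmax(matrix(N, nrow = 1L)))
  list(N = N, P = P)
}

#' Reweight hidden states by attention probabilities
#'
#' `A_t = P_t h_t`.
#'
#' @param H `T x d` hidden-state matrix.
#' @param P Length-T probability vector.
#' @return `T x d` matrix.
#' @export
apply_attention <- function(H, P) {
  stop_if(length(P) != nrow(H), "length(P) must equal nrow(H)")
  H * P
}
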