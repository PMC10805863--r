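# The EEG branch: shape contracts at reference widths, algebraic limits,
# hand-rolled step oracles, and an exact finite-difference check of the
# full backward pass.

test_that("reference-width CNN emits 512 features per slice", {
  net <- eeg_net(T = 4, B = 4, seed = 1)     # 64/128/256/128, fc 512
  slice <- array(rnorm(4 * 81), dim = c(4, 9, 9))
  y <- cnn_forward(slice, net)
  expect_length(y, 512L)
  # 9x9 -> 4x4 after the 2x2 stride-2 pool; flatten is 4*4*128 = 2048
  expect_equal(dim(net$params$fc_w), c(2048L, 512L))
  expect_error(cnn_forward(array(0, dim = c(3, 9, 9)), net), "B x H x W")
})

test_that("zero input with zero biases maps to zero through the CNN", {
  net <- eeg_net(T = 2, B = 4, conv_channels = c(3, 4, 5, 4), fc_dim = 8,
                 hidden = 6, seed = 2)
  y <- cnn_forward(array(0, dim = c(4, 9, 9)), net)
  expect_true(all(y == 0))
})

test_that("LSTM returns T x 128 top-layer states at reference width", {
  net <- eeg_net(T = 4, B = 4, seed = 3)
  for (TT in c(1L, 3L, 6L)) {
    y <- matrix(rnorm(TT * 512), TT, 512)
    H <- lstm_forward(y, net)
    expect_equal(dim(H), c(TT, 128L))
  }
})

test_that("a single LSTM step matches the printed gate equations", {
  net <- eeg_net(T = 1, B = 4, conv_channels = c(2, 2, 2, 2), fc_dim = 5,
                 hidden = 4, lstm_layers = 1, seed = 4)
  y <- matrix(rnorm(5), 1, 5)
  H <- lstm_forward(y, net)
  p <- net$params
  sig <- function(x) 1 / (1 + exp(-x))
  # zero initial state: peephole terms on i/f vanish, o sees c_t
  i <- sig(as.numeric(y %*% p$l1_Wyi) + p$l1_bi)
  f <- sig(as.numeric(y %*% p$l1_Wyf) + p$l1_bf)
  g <- tanh(as.numeric(y %*% p$l1_Wyc) + p$l1_bc)
  cc <- i * g
  o <- sig(as.numeric(y %*% p$l1_Wyo) + p$l1_po * cc + p$l1_bo)
  expect_equal(as.numeric(H), o * tanh(cc), tolerance = 1e-12)
})

test_that("zero gate weights and biases give zero hidden states", {
  net <- eeg_net(T = 3, B = 4, conv_channels = c(2, 2, 2, 2), fc_dim = 5,
                 hidden = 4, seed = 5)
  net$params[grep("^l[0-9]_", names(net$params))] <-
    lapply(net$params[grep("^l[0-9]_", names(net$params))],
           function(p) p * 0)
  H <- lstm_forward(matrix(rnorm(15), 3, 5), net)
  expect_true(all(H == 0))
})

test_that("the classifier head is a softmax over pooled features", {
  net <- eeg_net(T = 2, B = 4, conv_channels = c(2, 2, 2, 2), fc_dim = 5,
                 hidden = 4, seed = 6)
  # equal logits from zero features -> (0.5, 0.5)
  net$params$head_b <- c(0, 0)
  expect_equal(classify(matrix(0, 2, 4), net), c(0.5, 0.5))
  # logits (ln 3, 0) -> (0.75, 0.25)
  net$params$head_w <- matrix(0, 4, 2)
  net$params$head_b <- c(log(3), 0)
  expect_equal(classify(matrix(rnorm(8), 2, 4), net), c(0.75, 0.25),
               tolerance = 1e-12)
  set.seed(6)
  pr <- classify(matrix(rnorm(8), 2, 4), eeg_net(
    T = 2, B = 4, conv_channels = c(2, 2, 2, 2), fc_dim = 5, hidden = 4,
    seed = 7))
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_true(all(pr >= 0))
})

test_that("the full branch is deterministic with reference feature shapes", {
  net <- eeg_net(T = 4, B = 4, conv_channels = c(4, 5, 6, 5), fc_dim = 16,
                 hidden = 128, seed = 8)
  X <- array(rnorm(2 * 4 * 4 * 81), dim = c(2, 4, 4, 9, 9))
  p1 <- predict(net, X)
  p2 <- predict(net, X)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), c(1, 1), tolerance = 1e-12)
  fw <- asNamespace("deeframe")$eeg_forward(net, X)
  expect_equal(dim(fw$Vs), c(2L, 4L, 128L))   # T x 128 feature sequences
  expect_equal(rowSums(fw$P), c(1, 1), tolerance = 1e-9)
})

test_that("logits are invariant to a band permutation mirrored in conv1", {
  net <- eeg_net(T = 2, B = 4, conv_channels = c(3, 4, 5, 4), fc_dim = 8,
                 hidden = 6, seed = 9)
  X <- array(rnorm(2 * 2 * 4 * 81), dim = c(2, 2, 4, 9, 9))
  perm <- c(3L, 1L, 4L, 2L)
  Xp <- X[, , perm, , , drop = FALSE]
  net_p <- net
  # conv1 weight rows are kernel-position blocks of B input channels
  w <- net$params$conv1_w
  idx <- as.vector(vapply(seq_len(nrow(w) / 4) - 1L,
                          function(kpos) kpos * 4L + perm, integer(4)))
  wp <- w[idx, , drop = FALSE]
  attr(wp, "kh") <- attr(w, "kh"); attr(wp, "kw") <- attr(w, "kw")
  net_p$params$conv1_w <- wp
  env <- asNamespace("deeframe")
  l0 <- env$eeg_forward(net, X)$logits
  lp <- env$eeg_forward(net_p, Xp)$logits
  expect_equal(lp, l0, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences", {
  env <- asNamespace("deeframe")
  set.seed(30)
  net <- eeg_net(T = 3, B = 4, conv_channels = c(3, 4, 5, 4), fc_dim = 10,
                 hidden = 6, seed = 31)
  X <- array(rnorm(2 * 3 * 4 * 81), dim = c(2, 3, 4, 9, 9))
  y <- c(1L, 2L)
  vt <- array(0.3, dim = c(2, 3, 6))
  loss_of <- function(net) {
    fw <- env$eeg_forward(net, X, keep_cache = TRUE)
    sx <- env$softmax_xent(fw$logits, y)
    list(loss = sx$loss + 0.5 * mean(abs(fw$Vs - vt)), fw = fw, sx = sx)
  }
  l0 <- loss_of(net)
  dVs <- 0.5 * sign(l0$fw$Vs - vt) / length(vt)
  gr <- env$eeg_backward(net, l0$fw, l0$sx$dlogits, dVs)
  eps <- 1e-5
  set.seed(32)
  for (nm in names(net$params)) {
    p <- net$params[[nm]]
    for (j in sample(seq_along(p), min(3L, length(p)))) {
      n2 <- net
      n2$params[[nm]][j] <- p[j] + eps
      lp <- loss_of(n2)$loss
      n2$params[[nm]][j] <- p[j] - eps
      lm <- loss_of(n2)$loss
      expect_equal(gr[[nm]][j], (lp - lm) / (2 * eps), tolerance = 1e-4,
                   label = paste("grad", nm, j))
    }
  }
})

test_that("ablation switches change the parameter set", {
  full <- eeg_net(T = 2, B = 4, conv_channels = c(2, 2, 2, 2), fc_dim = 4,
                  hidden = 4, seed = 10)
  none <- eeg_net(T = 2, B = 4, conv_channels = c(2, 2, 2, 2), fc_dim = 4,
                  hidden = 4, seed = 10, use_band_attention = FALSE,
                  use_self_attention = FALSE)
  expect_true("gate_w" %in% names(full$params))
  expect_false("gate_w" %in% names(none$params))
  expect_false(any(grepl("^attn_", names(none$params))))
  expect_gt(sum(vapply(full$params, length, numeric(1))),
            sum(vapply(none$params, length, numeric(1))))
})
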