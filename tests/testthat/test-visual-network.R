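# The visual CNN-TCN branch: shape contracts at reference widths,
# per-frame independence, residual and sharing contracts, dilation
# arithmetic, and an exact gradient check.

small_vnet <- function(seed = 1, dropout = 0, T = 4) {
  visual_net(T = T, height = 8, width = 8, cnn_channels = c(2, 3),
             spatial_dim = 10, tcn_dim = 5, dropout = dropout, seed = seed)
}

test_that("reference-width CNN emits 512 features per frame", {
  net <- visual_net(T = 2, seed = 1)
  clip <- array(runif(2 * 48 * 48 * 3), dim = c(2, 48, 48, 3))
  sp <- visual_cnn_forward(clip, net)
  expect_equal(dim(sp), c(2L, 512L))
  expect_error(visual_cnn_forward(array(0, dim = c(2, 24, 24, 3)), net),
               "frames must be")
})

test_that("frames are processed independently", {
  net <- small_vnet()
  clip <- array(runif(4 * 8 * 8 * 3), dim = c(4, 8, 8, 3))
  clip[3, , , ] <- clip[1, , , ]             # duplicate a frame
  sp <- visual_cnn_forward(clip, net)
  expect_equal(sp[3, ], sp[1, ])
  # zero frames and zero biases give zero features
  sp0 <- visual_cnn_forward(array(0, dim = c(4, 8, 8, 3)), net)
  expect_true(all(sp0 == 0))
})

test_that("TCN preserves sequence length at reference width", {
  net <- visual_net(T = 6, seed = 2)
  for (TT in c(1L, 4L, 6L)) {
    sp <- matrix(rnorm(TT * 512), TT, 512)
    vt <- tcn_forward(sp, net)
    expect_equal(dim(vt), c(TT, 128L))
  }
})

test_that("one temporal-conv module spans 11 time steps", {
  # kernel 3 d1 adds 2; each kernel-3 d2 conv adds 4: 1 + 2 + 4 + 4
  expect_identical(tcn_receptive_field(), 11L)
})

test_that("zeroing the conv branch reduces a module to its residual", {
  net <- small_vnet()
  for (nm in c("tcn_c1_w", "tcn_c1_b", "tcn_c2_w", "tcn_c2_b",
               "tcn_c3_w", "tcn_c3_b")) {
    net$params[[nm]] <- net$params[[nm]] * 0
  }
  env <- asNamespace("deeframe")
  x <- array(rnorm(1 * 4 * 5), dim = c(1, 4, 5))
  m <- env$tcn_module_forward(x, net$params, net$state, 1L, FALSE)
  res <- env$conv1d_forward(x, net$params$tcn_res_w, net$params$tcn_res_b,
                            1L)
  expect_equal(m$out, res$out, tolerance = 1e-12)
})

test_that("both temporal-conv modules share one parameter set", {
  net <- small_vnet()
  env <- asNamespace("deeframe")
  x <- array(rnorm(1 * 5 * 5), dim = c(1, 5, 5))
  # composition oracle: applying the module twice with the same params
  # reproduces the cascade inside the TCN (pre-pooling)
  m1 <- env$tcn_module_forward(x, net$params, net$state, 1L, FALSE)
  m2 <- env$tcn_module_forward(m1$out, net$params, m1$state, 2L, FALSE)
  # there is exactly one temporal-conv parameter set
  expect_length(grep("^tcn_c[0-9]_w$", names(net$params)), 3L)
  # mutating the shared weights changes both applications
  net2 <- net
  net2$params$tcn_c1_w <- net2$params$tcn_c1_w + 0.1
  m1b <- env$tcn_module_forward(x, net2$params, net2$state, 1L, FALSE)
  m2b <- env$tcn_module_forward(m1$out, net2$params, m1$state, 2L, FALSE)
  expect_false(isTRUE(all.equal(m1$out, m1b$out)))
  expect_false(isTRUE(all.equal(m2$out, m2b$out)))
})

test_that("per-step classification is a row-wise softmax to T x 2", {
  net <- small_vnet()
  vt <- matrix(rnorm(4 * 5), 4, 5)
  pr <- visual_classify(vt, net)
  expect_equal(dim(pr), c(4L, 2L))
  expect_equal(rowSums(pr), rep(1, 4), tolerance = 1e-12)
  net$params$head_w <- net$params$head_w * 0
  net$params$head_b <- c(0, 0)
  expect_true(all(visual_classify(vt, net) == 0.5))
})

test_that("feature extraction is deterministic and compositional", {
  net <- small_vnet(dropout = 0.5)           # dropout must be inert here
  clip <- array(runif(4 * 8 * 8 * 3), dim = c(4, 8, 8, 3))
  f1 <- extract_visual_features(clip, net)
  f2 <- extract_visual_features(clip, net)
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(4L, 5L))
  expect_equal(f1, tcn_forward(visual_cnn_forward(clip, net), net))
})

test_that("visual gradients match finite differences", {
  env <- asNamespace("deeframe")
  set.seed(40)
  net <- small_vnet(seed = 41)
  clips <- array(runif(2 * 4 * 8 * 8 * 3), dim = c(2, 4, 8, 8, 3))
  y <- rep(c(1L, 2L), times = 4)
  vt0 <- array(0.2, dim = c(2, 4, 5))
  loss_of <- function(net) {
    fw <- env$visual_forward(net, clips, training = TRUE,
                             keep_cache = TRUE)
    sx <- env$softmax_xent(fw$logits, y)
    list(loss = sx$loss + 0.3 * mean(abs(fw$Vt - vt0)), fw = fw, sx = sx)
  }
  l0 <- loss_of(net)
  dVt <- 0.3 * sign(l0$fw$Vt - vt0) / length(vt0)
  gr <- env$visual_backward(net, l0$fw, l0$sx$dlogits, dVt)
  eps <- 1e-5
  set.seed(42)
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

test_that("dropout is active only in training mode", {
  net <- small_vnet(dropout = 0.5, seed = 43)
  env <- asNamespace("deeframe")
  clips <- array(runif(1 * 4 * 8 * 8 * 3), dim = c(1, 4, 8, 8, 3))
  set.seed(1)
  a <- env$visual_forward(net, clips, training = TRUE)$logits
  set.seed(2)
  b <- env$visual_forward(net, clips, training = TRUE)$logits
  expect_false(isTRUE(all.equal(a, b)))
  c1 <- env$visual_forward(net, clips, training = FALSE)$logits
  c2 <- env$visual_forward(net, clips, training = FALSE)$logits
  expect_identical(c1, c2)
})
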