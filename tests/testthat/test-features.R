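# Band decomposition, differential entropy, topographic projection and
# the 3D feature tensor.

test_that("a pure 40 Hz tone lands in the gamma band only", {
  fs <- 128
  tone <- matrix(sin(2 * pi * 40 * (0:255) / fs), nrow = 1)
  rownames(tone) <- "x"
  bands <- bandpass_decompose(tone, fs)
  ratio <- vapply(bands, function(m) {
    stats::var(as.numeric(m)) / stats::var(as.numeric(tone))
  }, numeric(1))
  expect_gte(ratio[["gamma"]], 0.9)
  expect_true(all(ratio[c("theta", "alpha", "beta")] <= 0.05))
})

test_that("zero input filters to zero and band energies are bounded", {
  z <- matrix(0, 2, 128)
  rownames(z) <- c("a", "b")
  expect_true(all(vapply(bandpass_decompose(z, 128),
                         function(m) all(m == 0), logical(1))))
  set.seed(8)
  wn <- matrix(rnorm(256), nrow = 1)
  rownames(wn) <- "w"
  bands <- bandpass_decompose(wn, 128)
  expect_lte(sum(vapply(bands, function(m) stats::var(as.numeric(m)),
                        numeric(1))),
             stats::var(as.numeric(wn)) * 1.05)
})

test_that("band edges at or above Nyquist are rejected", {
  bad <- data.frame(name = "x", low = 10, high = 70)
  expect_error(bandpass_decompose(matrix(0, 1, 64), 128, bad), "Nyquist")
})

test_that("differential entropy matches the Gaussian closed form", {
  x <- matrix(rnorm(10), nrow = 1)
  x <- (x - mean(x)) / stats::sd(x)          # exact unit sample variance
  expect_equal(differential_entropy(x)[[1]], 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-12)
  # doubling sigma adds ln 2
  expect_equal(differential_entropy(2 * x)[[1]] -
                 differential_entropy(x)[[1]], log(2), tolerance = 1e-12)
})

test_that("differential entropy converges on Monte-Carlo Gaussian draws", {
  set.seed(13)
  draws <- matrix(rnorm(1e5, sd = 2), nrow = 1)
  closed_form <- 0.5 * log(2 * pi * exp(1) * 4)
  expect_equal(closed_form, 2.1121, tolerance = 1e-4)
  expect_lt(abs(differential_entropy(draws)[[1]] - closed_form), 0.02)
})

test_that("zero-variance input falls back to the variance floor", {
  flat <- matrix(1, 2, 50)
  de <- differential_entropy(flat, var_floor = 1e-12)
  expect_true(all(is.finite(de)))
  expect_equal(de[[1]], 0.5 * log(2 * pi * exp(1) * 1e-12))
})

test_that("projection places channels injectively and zero-fills", {
  m <- load_montage()
  vals <- stats::setNames(rep(1, 32), names(m$mapping))
  grid <- project_to_grid(vals, m)
  expect_equal(sum(grid == 1), 32)
  expect_equal(sum(grid == 0), 81 - 32)
  # distinct values are recoverable bijectively
  vals2 <- stats::setNames(seq_len(32), names(m$mapping))
  grid2 <- project_to_grid(vals2, m)
  back <- vapply(names(vals2), function(ch) {
    rc <- m$mapping[[ch]]
    grid2[rc[1], rc[2]]
  }, numeric(1))
  expect_equal(back, vals2)
  expect_error(project_to_grid(c(bogus = 1), m), "not in montage")
})

test_that("montages with duplicate cells are rejected at load", {
  bad <- tempfile(fileext = ".json")
  writeLines('{"H": 9, "W": 9, "mapping": {"a": [0,0], "b": [0,0]}}', bad)
  expect_error(load_montage(bad), "one cell")
  oob <- tempfile(fileext = ".json")
  writeLines('{"H": 9, "W": 9, "mapping": {"a": [9,0]}}', oob)
  expect_error(load_montage(oob), "grid")
})

test_that("feature tensor has shape T x B x 9 x 9 with zero-filled cells", {
  spec <- synth_spec(n_subjects = 1, n_trials_per_subject = 2,
                     trial_duration = 2, baseline_duration = 1, seed = 4)
  ds <- generate_eeg(spec)
  win <- ds$records[[1]]$trials[[1]]$signal    # 2 s at 128 Hz
  tensor <- build_feature_tensor(win, 128, T = 4)
  expect_equal(dim(tensor), c(4L, 4L, 9L, 9L))
  m <- load_montage()
  occupied <- matrix(FALSE, 9, 9)
  for (rc in m$mapping) occupied[rc[1], rc[2]] <- TRUE
  flat <- matrix(tensor, nrow = 4 * 4)      # columns are grid cells
  expect_true(all(flat[, !as.vector(occupied)] == 0))
  expect_true(all(flat[, as.vector(occupied)] != 0))
  expect_error(build_feature_tensor(win, 128, T = 7), "divisible")
})

test_that("degenerate T = 1 equals the per-band DE grids", {
  set.seed(9)
  win <- matrix(rnorm(32 * 64), nrow = 32)
  rownames(win) <- names(load_montage()$mapping)
  tensor <- build_feature_tensor(win, 128, T = 1)
  bands <- bandpass_decompose(win, 128)
  m <- load_montage()
  for (b in 1:4) {
    expect_equal(tensor[1, b, , ],
                 project_to_grid(differential_entropy(bands[[b]]), m))
  }
})

test_that("an all-zero window hits the variance floor on occupied cells", {
  win <- matrix(0, 32, 64)
  rownames(win) <- names(load_montage()$mapping)
  tensor <- build_feature_tensor(win, 128, T = 2)
  m <- load_montage()
  occupied <- matrix(FALSE, 9, 9)
  for (rc in m$mapping) occupied[rc[1], rc[2]] <- TRUE
  floor_de <- 0.5 * log(2 * pi * exp(1) * 1e-12)
  flat <- matrix(tensor, nrow = 2 * 4)
  expect_true(all(flat[, as.vector(occupied)] == floor_de))
  expect_true(all(flat[, !as.vector(occupied)] == 0))
})

test_that("tensor construction is equivariant to channel relabeling", {
  set.seed(10)
  m <- load_montage()
  chn <- names(m$mapping)
  win <- matrix(rnorm(32 * 64), nrow = 32, dimnames = list(chn, NULL))
  perm <- sample(32)
  win_p <- win[perm, , drop = FALSE]       # same channels, new row order
  expect_equal(build_feature_tensor(win_p, 128, T = 2),
               build_feature_tensor(win, 128, T = 2))
})

test_that("raw point tensors carry sampling points without a DE stage", {
  m <- load_montage()
  win <- matrix(seq_len(32 * 8), nrow = 32,
                dimnames = list(names(m$mapping), NULL))
  rt <- raw_point_tensor(win, T = 2, montage = m)
  expect_equal(dim(rt), c(2L, 4L, 9L, 9L))
  rc <- m$mapping[["Cz"]]
  expect_equal(rt[1, 1, rc[1], rc[2]], unname(win["Cz", 1]))
  expect_equal(rt[2, 1, rc[1], rc[2]], unname(win["Cz", 5]))
})
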