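# Losses, fold construction, grid search, cross-validation mechanics and
# training behaviour on small benches.

test_that("L1 feature loss matches a brute-force double-loop oracle", {
  set.seed(20)
  U <- matrix(rnorm(12), 4, 3)
  V <- matrix(rnorm(12), 4, 3)
  acc <- 0
  for (i in 1:4) for (j in 1:3) acc <- acc + abs(U[i, j] - V[i, j])
  expect_equal(l1_feature_loss(U, V, w_star = 0.7), 0.7 * acc / 12,
               tolerance = 1e-12)
  expect_equal(l1_feature_loss(U, U, 1), 0)
  # constant difference c gives |c|
  expect_equal(l1_feature_loss(U, U - 0.3, 1), 0.3, tolerance = 1e-12)
  expect_error(l1_feature_loss(U, V[1:2, ]), "identical shape")
})

test_that("multitask loss reduces to its components at the limits", {
  set.seed(21)
  P <- softmax(matrix(rnorm(10), 5, 2))
  Y <- sample(1:2, 5, replace = TRUE)
  V1 <- matrix(rnorm(20), 4, 5)
  V2 <- matrix(rnorm(20), 4, 5)
  ce <- -mean(log(P[cbind(1:5, Y)]))
  # rho = 1: exactly cross-entropy, teacher ignored
  expect_identical(multitask_loss(P, Y, V1, V2, rho = 1, w_star = 3), ce)
  # perfect predictions and matched features: zero
  P_perfect <- matrix(0, 5, 2)
  P_perfect[cbind(1:5, Y)] <- 1
  expect_equal(multitask_loss(P_perfect, Y, V1, V1, rho = 0.8), 0,
               tolerance = 1e-9)
  # stated combination: CE = 1, L1 term = 0.5, rho = 0.8 -> 0.9
  P_e <- matrix(0, 2, 2)
  P_e[cbind(1:2, c(1L, 2L))] <- exp(-1)
  Vt <- matrix(0.5, 3, 4)
  Vs <- matrix(0, 3, 4)
  expect_equal(multitask_loss(P_e, c(1L, 2L), Vt, Vs, rho = 0.8,
                              w_star = 1), 0.8 * 1 + 0.2 * 0.5,
               tolerance = 1e-12)
})

test_that("stratified folds partition each class evenly", {
  labels <- rep(c(0L, 1L), times = c(30, 20))
  fold <- make_stratified_folds(labels, 10, seed = 3)
  expect_true(all(fold %in% 1:10))
  expect_length(fold, 50L)
  # every sample in exactly one fold; class counts balanced across folds
  for (k in 1:10) {
    expect_equal(sum(fold == k & labels == 0L), 3L)
    expect_equal(sum(fold == k & labels == 1L), 2L)
  }
})

cheap_features <- function(n_per_subject = 40, seed = 50,
                           n_subjects = 1L) {
  # tiny tensors whose first cell carries the class signal
  with_seed(seed, {
    n <- n_per_subject * n_subjects
    label <- rep_len(c(0L, 1L), n)
    tensors <- array(rnorm(n * 2 * 2 * 3 * 3, sd = 0.1),
                     dim = c(n, 2, 2, 3, 3))
    tensors[, , , 1, 1] <- tensors[, , , 1, 1] + 2 * label
    list(tensors = tensors, label = label,
         subject = rep(sprintf("s%02d", seq_len(n_subjects)),
                       each = n_per_subject),
         trial = rep(seq_len(n_per_subject), times = n_subjects))
  })
}

threshold_fit <- function(x, y) {
  # oracle-free cheap classifier: threshold on the informative cell
  m0 <- mean(x[y == 0L, , , 1, 1])
  m1 <- mean(x[y == 1L, , , 1, 1])
  list(cut = (m0 + m1) / 2, flip = m1 < m0)
}
threshold_predict <- function(fit, x) {
  v <- apply(x[, , , 1, 1, drop = FALSE], 1, mean)
  as.integer(xor(v > fit$cut, fit$flip))
}

test_that("cross-validation runs 5 x 10 exhaustive disjoint folds", {
  feats <- cheap_features()
  cfg <- distill_config(cv_repeats = 5, cv_folds = 10, seed = 4)
  n_fits <- 0L
  res <- cross_validate(feats, cfg,
                        fit_fun = function(x, y) {
                          n_fits <<- n_fits + 1L
                          threshold_fit(x, y)
                        },
                        predict_fun = threshold_predict)
  expect_equal(n_fits, 50L)                     # 5 repeats x 10 folds
  expect_equal(nrow(res$folds), 50L)
  # each repetition tests every sample exactly once
  counts <- tapply(res$folds$accuracy, res$folds$rep, length)
  expect_true(all(counts == 10L))
  expect_gt(res$mean_accuracy, 0.95)            # separable by construction
})

test_that("a perfect classifier scores 100% on every metric", {
  feats <- cheap_features(20)
  cfg <- distill_config(cv_repeats = 1, cv_folds = 4, seed = 5)
  res <- cross_validate(feats, cfg,
                        fit_fun = function(x, y) NULL,
                        predict_fun = function(fit, x) {
                          as.integer(apply(x[, , , 1, 1, drop = FALSE], 1,
                                           mean) > 1)
                        })
  expect_equal(res$mean_accuracy, 1)
  expect_true(all(res$folds$precision == 1))
  expect_true(all(res$folds$recall == 1))
  expect_true(all(res$folds$f1 == 1))
})

test_that("metrics keep the F1 harmonic-mean identity", {
  feats <- cheap_features(40, seed = 51)
  cfg <- distill_config(cv_repeats = 2, cv_folds = 5, seed = 6)
  res <- cross_validate(feats, cfg,
                        fit_fun = threshold_fit,
                        predict_fun = function(fit, x) {
                          p <- threshold_predict(fit, x)
                          p[1] <- 1L - p[1]     # inject errors
                          p
                        })
  ok <- with(res$folds, !is.na(precision) & !is.na(recall) &
               (precision + recall) > 0)
  expect_true(any(ok))
  expect_equal(res$folds$f1[ok],
               with(res$folds[ok, ],
                    2 * precision * recall / (precision + recall)))
})

test_that("single-class subjects are skipped with a warning", {
  feats <- cheap_features(20, n_subjects = 2L)
  feats$label[feats$subject == "s01"] <- 0L
  cfg <- distill_config(cv_repeats = 1, cv_folds = 4, seed = 7)
  expect_warning(
    res <- cross_validate(feats, cfg, fit_fun = threshold_fit,
                          predict_fun = threshold_predict),
    "single class")
  expect_equal(unique(res$folds$subject), "s02")
})

test_that("the default w grid has 11 candidates from 0.5 to 1.5", {
  cfg <- distill_config()
  expect_length(cfg$w_grid, 11L)
  expect_equal(cfg$w_grid, seq(0.5, 1.5, by = 0.1))
  expect_equal(cfg$rho, 0.8)
  expect_error(distill_config(rho = 1.2), "rho")
  expect_error(distill_config(w_grid = numeric()), "non-empty")
})

test_that("rho = 1 training is bit-identical with and without a teacher", {
  feats <- cheap_features(16)
  teacher <- generate_visual_features(feats$label, T = 2, F = 4, snr = 5,
                                      seed = 9)
  cfg <- distill_config(rho = 1, seed = 10)
  net <- eeg_net(T = 2, B = 2, H = 3, W = 3,
                 conv_channels = c(2, 2, 2, 2), fc_dim = 6, hidden = 4,
                 seed = 11)
  a <- train_eeg(net, feats$tensors, feats$label, cfg, epochs = 2,
                 lr = 1e-3)
  b <- train_eeg(net, feats$tensors, feats$label, cfg,
                 visual_features = teacher, epochs = 2, lr = 1e-3)
  expect_identical(a$params, b$params)
})

test_that("training loss decreases on separable synthetic tensors", {
  feats <- cheap_features(32, seed = 52)
  cfg <- distill_config(rho = 1, seed = 12)
  net <- eeg_net(T = 2, B = 2, H = 3, W = 3,
                 conv_channels = c(3, 3, 3, 3), fc_dim = 8, hidden = 6,
                 seed = 13)
  fit <- train_eeg(net, feats$tensors, feats$label, cfg, epochs = 8,
                   lr = 3e-3)
  expect_lt(mean(tail(fit$history$loss, 2)),
            mean(head(fit$history$loss, 2)))
})

test_that("distillation misalignment and missing teachers are errors", {
  feats <- cheap_features(8)
  cfg <- distill_config(rho = 0.8, seed = 14)
  net <- eeg_net(T = 2, B = 2, H = 3, W = 3,
                 conv_channels = c(2, 2, 2, 2), fc_dim = 6, hidden = 4,
                 seed = 15)
  expect_error(train_eeg(net, feats$tensors, feats$label, cfg),
               "visual_features required")
  short_teacher <- generate_visual_features(feats$label[1:4], T = 2,
                                            F = 4, snr = 1, seed = 16)
  expect_error(train_eeg_distilled(net, feats$tensors, feats$label,
                                   short_teacher, cfg), "misaligned")
})

test_that("grid search returns the accuracy-maximising w", {
  feats <- cheap_features(24, seed = 53)
  teacher <- generate_visual_features(feats$label, T = 2, F = 4, snr = 5,
                                      seed = 17)
  cfg <- distill_config(rho = 0.8, w_grid = c(0.5, 1.0, 1.5), seed = 18)
  net <- eeg_net(T = 2, B = 2, H = 3, W = 3,
                 conv_channels = c(2, 2, 2, 2), fc_dim = 6, hidden = 4,
                 seed = 19)
  gs <- grid_search_w(net, feats$tensors, feats$label, teacher, cfg,
                      epochs = 2, lr = 2e-3)
  expect_equal(nrow(gs$scores), 3L)
  expect_equal(gs$best_w,
               gs$scores$w[which.max(gs$scores$accuracy)])
  # degenerate single-candidate grid returns the candidate
  cfg1 <- distill_config(rho = 0.8, w_grid = 0.7, seed = 18)
  gs1 <- grid_search_w(net, feats$tensors, feats$label, teacher, cfg1,
                       epochs = 1, lr = 2e-3)
  expect_equal(gs1$best_w, 0.7)
})

test_that("visual training descends and checkpoints reproduce outputs", {
  labels <- rep_len(c(0L, 1L), 24L)
  clips <- generate_frame_clips(labels, T = 4, height = 48, width = 48,
                                seed = 60)
  clip_arr <- array(0, dim = c(24, 4, 48, 48, 3))
  for (i in 1:24) clip_arr[i, , , , ] <- clips[[i]]
  net <- visual_net(T = 4, cnn_channels = c(3, 4), spatial_dim = 16,
                    tcn_dim = 8, dropout = 0.2, seed = 61)
  cfg <- distill_config(seed = 62, batch_size = 8)
  fit <- train_visual(net, clip_arr, labels, cfg, epochs = 6, lr = 2e-3)
  expect_gte(nrow(fit$history), 6L)
  expect_lt(mean(tail(fit$history$loss, 2)),
            mean(head(fit$history$loss, 2)))
  # checkpoint round trip reproduces evaluation outputs exactly
  ck <- tempfile(fileext = ".json")
  write_checkpoint(fit, ck)
  back <- read_checkpoint(ck, visual_net(T = 4, cnn_channels = c(3, 4),
                                         spatial_dim = 16, tcn_dim = 8,
                                         dropout = 0.2, seed = 1))
  expect_equal(predict(back, clip_arr[1:2, , , , , drop = FALSE]),
               predict(fit, clip_arr[1:2, , , , , drop = FALSE]),
               tolerance = 1e-12)
  expect_error(train_visual(net, clip_arr[0, , , , , drop = FALSE],
                            integer(0), cfg), "empty")
})

test_that("band-attention report needs the gate and stays in [0,1]", {
  feats <- cheap_features(8)
  net <- eeg_net(T = 2, B = 2, H = 3, W = 3,
                 conv_channels = c(2, 2, 2, 2), fc_dim = 6, hidden = 4,
                 seed = 20)
  bw <- report_band_attention(net, feats$tensors)
  expect_length(bw, 2L)
  expect_true(all(bw > 0 & bw < 1))
  off <- eeg_net(T = 2, B = 2, H = 3, W = 3,
                 conv_channels = c(2, 2, 2, 2), fc_dim = 6, hidden = 4,
                 seed = 20, use_band_attention = FALSE)
  expect_error(report_band_attention(off, feats$tensors), "disabled")
})
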