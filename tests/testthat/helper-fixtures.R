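# Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

featurize_bench <- function(effect, data_seed) {
  spec <- synth_spec(n_subjects = 2, n_trials_per_subject = 40,
                     trial_duration = 6, baseline_duration = 2,
                     effect_size = effect, seed = data_seed)
  prep <- preprocess_dataset(generate_eeg(spec), window_seconds = 2)
  featurize_windows(prep, T = 4)
}

# strong gamma effect: band-attention recovery bench
easy_features <- function() {
  fixture("easy_features", function() featurize_bench(3, 21))
}

# weak effect: attention-ablation bench (accuracy well off ceiling)
hard_features <- function() {
  fixture("hard_features", function() featurize_bench(1.3, 22))
}

# moderate effect: distillation bench (signal present, not saturated)
moderate_features <- function() {
  fixture("moderate_features", function() featurize_bench(1.8, 23))
}

reduced_net <- function(seed, ...) {
  eeg_net(T = 4L, B = 4L, conv_channels = c(8L, 12L, 16L, 12L),
          fc_dim = 48L, hidden = 24L, seed = seed, ...)
}

# train a reduced-width EEG net on a 75/25 split and report held-out
# accuracy plus the fitted model
train_bench <- function(feats, seed, rho = 1, teacher = NULL,
                        epochs = 35L, lr = 2e-3, ...) {
  n <- dim(feats$tensors)[1L]
  te <- seq(1L, n, by = 4L)
  tr <- setdiff(seq_len(n), te)
  net <- reduced_net(seed, ...)
  cfg <- distill_config(rho = rho, seed = seed)
  fit <- train_eeg(net, feats$tensors[tr, , , , , drop = FALSE],
                   feats$label[tr], cfg,
                   visual_features = if (!is.null(teacher)) teacher[tr],
                   epochs = epochs, lr = lr)
  pr <- predict(fit, feats$tensors[te, , , , , drop = FALSE])
  acc <- mean(max.col(pr, ties.method = "first") - 1L ==
                feats$label[te])
  list(fit = fit, accuracy = acc)
}

# clean low-amplitude teacher in the student feature range
bench_teacher <- function(labels) {
  generate_visual_features(labels, T = 4L, F = 24L, snr = 30, seed = 99,
                           scale = 0.02)
}

# memoised multi-seed experiment arms shared by the acceptance tests
recovery_runs <- function(seeds = 1:5) {
  fixture("recovery_runs", function() {
    feats <- easy_features()
    lapply(seeds, function(s) {
      r <- train_bench(feats, seed = s, epochs = 30L)
      list(accuracy = r$accuracy,
           band_weights = report_band_attention(r$fit, feats$tensors))
    })
  })
}

hard_full_runs <- function(seeds = 1:5) {
  fixture("hard_full_runs", function() {
    feats <- hard_features()
    vapply(seeds, function(s) train_bench(feats, seed = s)$accuracy,
           numeric(1))
  })
}

no_attention_runs <- function(seeds = 1:5) {
  fixture("no_attention_runs", function() {
    feats <- hard_features()
    vapply(seeds, function(s) {
      train_bench(feats, seed = s, use_band_attention = FALSE,
                  use_self_attention = FALSE)$accuracy
    }, numeric(1))
  })
}

moderate_baseline_runs <- function(seeds = 1:5) {
  fixture("moderate_baseline_runs", function() {
    feats <- moderate_features()
    vapply(seeds, function(s) {
      train_bench(feats, seed = s, epochs = 40L)$accuracy
    }, numeric(1))
  })
}

distilled_runs <- function(seeds = 1:5) {
  fixture("distilled_runs", function() {
    feats <- moderate_features()
    teacher <- bench_teacher(feats$label)
    vapply(seeds, function(s) {
      train_bench(feats, seed = s, rho = 0.8, teacher = teacher,
                  epochs = 40L)$accuracy
    }, numeric(1))
  })
}
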