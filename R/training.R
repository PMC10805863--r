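# Training: the weighted multitask loss (cross-entropy plus an L1
# feature-matching term between visual teacher and EEG student), Adam
# training loops for both branches, grid search over the L1 weight w*,
# repeated stratified cross-validation per subject, ablation variants,
# and the trained band-attention report.

#' Distillation / training configuration
#'
#' Defaults follow the reference protocol: cross-entropy weight
#' `rho = 0.8`, L1-weight grid 0.5-1.5 in steps of 0.1, learning rates
#' 1e-6 (EEG) and 1e-5 (visual), 100 epochs, batch size 128, and
#' five-times-repeated tenfold cross-validation per subject.
#'
#' @param rho Weight of the cross-entropy term in `[0, 1]`.
#' @param w_grid Candidate values for the L1 weight `w*`.
#' @param learning_rate_eeg,learning_rate_visual Adam learning rates.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param cv_repeats,cv_folds Cross-validation protocol.
#' @param w_star L1 weight used when not grid searching.
#' @param seed Integer seed.
#' @return Object of class `"distill_config"`.
#' @export
distill_config <- function(rho = 0.8, w_grid = seq(0.5, 1.5, by = 0.1),
                           learning_rate_eeg = 1e-6,
                           learning_rate_visual = 1e-5, epochs = 100L,
                           batch_size = 128L, cv_repeats = 5L,
                           cv_folds = 10L, w_star = 1.0, seed = 1L) {
  stop_if(rho < 0 || rho > 1, "rho must be in [0, 1]")
  stop_if(length(w_grid) == 0L, "w_grid must be non-empty")
  stop_if(cv_folds < 2L, "cv_folds must be >= 2")
  structure(list(rho = rho, w_grid = w_grid,
                 learning_rate_eeg = learning_rate_eeg,
                 learning_rate_visual = learning_rate_visual,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 cv_repeats = as.integer(cv_repeats),
                 cv_folds = as.integer(cv_folds), w_star = w_star,
                 seed = as.integer(seed)),
            class = "distill_config")
}

#' Weighted L1 feature-matching loss
#'
#' `w_star * mean(|U - V|)` over all `T x F` entries: the auxiliary loss
#' pulling student features toward the teacher's.
#'
#' @param U,V `T x F` matrices (teacher and student feature sequences).
#' @param w_star Scalar weight.
#' @return Scalar loss.
#' @export
l1_feature_loss <- function(U, V, w_star = 1.0) {
  stop_if(is.null(dim(U)) || is.null(dim(V)) || !all(dim(U) == dim(V)),
          "U and V must be matrices of identical shape")
  w_star * mean(abs(U - V))
}

#' Multitask distillation loss
#'
#' `rho * CE + (1 - rho) * l1_feature_loss(Vt, Vs, w_star)`, where CE is
#' the mean cross-entropy of the predicted probabilities against the
#' labels (probabilities floored at 1e-12 before the log).
#'
#' @param P `N x K` matrix of predicted class probabilities.
#' @param Y Integer class labels in `1..K`.
#' @param Vt,Vs Teacher and student feature arrays of identical shape.
#' @param rho Cross-entropy weight in `[0, 1]`.
#' @param w_star L1 weight.
#' @return Scalar loss.
#' @export
multitask_loss <- function(P, Y, Vt, Vs, rho = 0.8, w_star = 1.0) {
  stop_if(rho < 0 || rho > 1, "rho must be in [0, 1]")
  ce <- -mean(log(pmax(P[cbind(seq_len(nrow(P)), Y)], 1e-12)))
  l1 <- if (rho < 1) {
    stop_if(!all(dim(Vt) == dim(Vs)), "Vt and Vs must have the same shape")
    mean(abs(Vt - Vs)) * w_star
  } else 0
  rho * ce + (1 - rho) * l1
}

# ---- stratified folds -------------------------------------------------

#' Stratified k-fold partition
#'
#' Assigns each sample to exactly one of `k` folds, keeping the class
#' proportions of `labels` approximately equal across folds.
#'
#' @param labels Binary (0/1) integer labels.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Integer fold assignment in `1..k`, one per sample.
#' @export
make_stratified_folds <- function(labels, k, seed = 1L) {
  stop_if(k < 2L, "k must be >= 2")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# ---- EEG training -----------------------------------------------------

#' Train the EEG branch, optionally with a visual teacher
#'
#' Minimises the multitask loss with Adam. When `rho = 1` the teacher is
#' ignored entirely (the run is bit-identical to a no-distillation run
#' under the same seed); otherwise `visual_features` must supply one
#' `T x hidden` teacher sequence per training sample, held fixed
#' (offline distillation).
#'
#' @param net An [eeg_net()].
#' @param tensors `N x T x B x H x W` feature array.
#' @param labels Binary (0/1) labels, length N.
#' @param config A [distill_config()].
#' @param visual_features Optional list of `T x hidden` teacher matrices
#'   (length N), required when `rho < 1`.
#' @param epochs,lr Optional overrides of the config values.
#' @param verbose Print per-epoch loss.
#' @return The trained `"eeg_net"` with a `history` data frame attached.
#' @export
train_eeg <- function(net, tensors, labels, config = distill_config(),
                      visual_features = NULL, epochs = NULL, lr = NULL,
                      verbose = FALSE) {
  n <- dim(tensors)[1L]
  stop_if(length(labels) != n, "labels must match sample count")
  distill <- config$rho < 1
  if (distill) {
    stop_if(is.null(visual_features),
            "visual_features required when rho < 1")
    stop_if(length(visual_features) != n,
            "need one teacher sequence per training sample")
    vt_all <- array(0, dim = c(n, net$config$T, net$config$hidden))
    for (i in seq_len(n)) {
      stop_if(!all(dim(visual_features[[i]]) ==
                     c(net$config$T, net$config$hidden)),
              "teacher sequence %d has the wrong shape", i)
      vt_all[i, , ] <- visual_features[[i]]
    }
  }
  epochs <- epochs %||% config$epochs
  lr <- lr %||% config$learning_rate_eeg
  y <- as.integer(labels) + 1L
  params <- net$params
  opt <- adam_init(params)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     accuracy = numeric())
  with_seed(config$seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        net$params <- params
        fw <- eeg_forward(net, tensors[idx, , , , , drop = FALSE],
                          keep_cache = TRUE)
        sx <- softmax_xent(fw$logits, y[idx])
        dlogits <- sx$dlogits * config$rho
        dVs <- NULL
        loss <- config$rho * sx$loss
        if (distill) {
          vt <- vt_all[idx, , , drop = FALSE]
          diffs <- fw$Vs - vt
          l1 <- mean(abs(diffs)) * config$w_star
          loss <- loss + (1 - config$rho) * l1
          dVs <- (1 - config$rho) * config$w_star *
            sign(diffs) / length(diffs)
        }
        grads <- eeg_backward(net, fw, dlogits, dVs)
        st <- adam_step(params, grads, opt, lr)
        params <- st$params; opt <- st$state
        ep_loss <- ep_loss + loss * length(idx)
        ep_correct <- ep_correct +
          sum(max.col(fw$probs, ties.method = "first") == y[idx])
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n,
                                     accuracy = ep_correct / n))
      if (verbose) {
        message(sprintf("epoch %d  loss %.4f  acc %.3f", ep,
                        ep_loss / n, ep_correct / n))
      }
    }
  })
  net$params <- params
  net$history <- hist
  net
}

#' Train the EEG branch with offline visual distillation
#'
#' Convenience wrapper around [train_eeg()] that requires the teacher
#' features and checks their alignment with the EEG samples.
#'
#' @inheritParams train_eeg
#' @return Trained `"eeg_net"`.
#' @export
train_eeg_distilled <- function(net, tensors, labels, visual_features,
                                config = distill_config(), epochs = NULL,
                                lr = NULL, verbose = FALSE) {
  stop_if(length(visual_features) != dim(tensors)[1L],
          "visual features misaligned with EEG samples (%d vs %d)",
          length(visual_features), dim(tensors)[1L])
  train_eeg(net, tensors, labels, config, visual_features, epochs, lr,
            verbose)
}

# ---- visual training --------------------------------------------------

#' Train the visual branch on labelled clips
#'
#' Per-step cross-entropy against the clip label, Adam updates, and
#' best-validation checkpoint retention: after every epoch the model is
#' evaluated on the validation split and the best parameter set so far
#' is kept.
#'
#' @param net A [visual_net()].
#' @param clips `N x T x H x W x 3` array.
#' @param labels Binary (0/1) labels, length N.
#' @param config A [distill_config()].
#' @param val_fraction Fraction of clips held out for checkpoint
#'   selection.
#' @param epochs,lr Optional overrides.
#' @param verbose Print per-epoch loss.
#' @return The trained `"visual_net"` with `history` attached.
#' @export
train_visual <- function(net, clips, labels, config = distill_config(),
                         val_fraction = 0.2, epochs = NULL, lr = NULL,
                         verbose = FALSE) {
  n <- dim(clips)[1L]
  stop_if(n == 0L, "empty clip set")
  stop_if(length(labels) != n, "labels must match clip count")
  epochs <- epochs %||% config$epochs
  lr <- lr %||% config$learning_rate_visual
  y <- as.integer(labels) + 1L
  params <- net$params
  opt <- adam_init(params)
  best <- list(acc = -Inf, params = params, state = net$state)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     val_accuracy = numeric())
  with_seed(config$seed, {
    n_val <- max(1L, round(val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(tr_idx) == 0L) tr_idx <- val_idx
    for (ep in seq_len(epochs)) {
      ord <- tr_idx[sample.int(length(tr_idx))]
      ep_loss <- 0
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        net$params <- params
        fw <- visual_forward(net, clips[idx, , , , , drop = FALSE],
                             training = TRUE, keep_cache = TRUE)
        net$state <- fw$state
        y_rep <- rep(y[idx], times = dim(clips)[2L])
        sx <- softmax_xent(fw$logits, y_rep)
        grads <- visual_backward(net, fw, sx$dlogits)
        st <- adam_step(params, grads, opt, lr)
        params <- st$params; opt <- st$state
        ep_loss <- ep_loss + sx$loss * length(idx)
      }
      net$params <- params
      pr <- predict(net, clips[val_idx, , , , , drop = FALSE])
      val_acc <- mean(max.col(pr, ties.method = "first") == y[val_idx])
      if (val_acc >= best$acc) {
        best <- list(acc = val_acc, params = params, state = net$state)
      }
      hist <- rbind(hist, data.frame(epoch = ep,
                                     loss = ep_loss / length(ord),
                                     val_accuracy = val_acc))
      if (verbose) {
        message(sprintf("epoch %d  loss %.4f  val acc %.3f", ep,
                        ep_loss / length(ord), val_acc))
      }
    }
  })
  net$params <- best$params
  net$state <- best$state
  net$history <- hist
  net
}

# ---- grid search ------------------------------------------------------

#' Grid search over the L1 weight w*
#'
#' Trains one distilled model per candidate `w*` on the training split
#' and evaluates accuracy on a held-out validation split; returns the
#' accuracy-maximising `w*` (ties broken toward the smaller value).
#'
#' @param net An [eeg_net()] template (re-initialised per candidate).
#' @param tensors,labels,visual_features Training data.
#' @param config A [distill_config()]; `w_grid` supplies the candidates.
#' @param val_fraction Held-out fraction for scoring.
#' @param epochs,lr Optional overrides.
#' @return List with `best_w` and `scores` (data frame of w, accuracy).
#' @export
grid_search_w <- function(net, tensors, labels, visual_features,
                          config = distill_config(), val_fraction = 0.25,
                          epochs = NULL, lr = NULL) {
  stop_if(length(config$w_grid) == 0L, "empty w grid")
  n <- dim(tensors)[1L]
  val_idx <- with_seed(config$seed + 17L,
                       sample.int(n, max(1L, round(val_fraction * n))))
  tr_idx <- setdiff(seq_len(n), val_idx)
  scores <- data.frame(w = config$w_grid, accuracy = NA_real_)
  for (j in seq_along(config$w_grid)) {
    cfg_j <- config
    cfg_j$w_star <- config$w_grid[j]
    fit <- train_eeg(net, tensors[tr_idx, , , , , drop = FALSE],
                     labels[tr_idx], cfg_j,
                     visual_features = visual_features[tr_idx],
                     epochs = epochs, lr = lr)
    pr <- predict(fit, tensors[val_idx, , , , , drop = FALSE])
    scores$accuracy[j] <- mean(max.col(pr, ties.method = "first") - 1L ==
                                 labels[val_idx])
  }
  best <- scores$w[which.max(scores$accuracy)]   # first max = smallest w
  list(best_w = best, scores = scores)
}

# ---- cross-validation -------------------------------------------------

#' Repeated stratified cross-validation per subject
#'
#' For each subject: stratified `cv_folds`-fold partition, repeated
#' `cv_repeats` times with reshuffling; a model is fitted on each
#' training fold and scored on the held-out fold. Per-subject means are
#' aggregated into mean and standard deviation across subjects.
#' Subjects with only one class are skipped with a warning.
#'
#' @param features List with `tensors`, `label`, `subject` (as from
#'   [featurize_windows()]).
#' @param config A [distill_config()].
#' @param fit_fun `function(tensors, labels)` returning a fitted object;
#'   defaults to a reduced-width EEG network fit.
#' @param predict_fun `function(fit, tensors)` returning predicted 0/1
#'   labels.
#' @return Object of class `"cv_result"`: per-fold metric table plus
#'   across-subject summary.
#' @export
cross_validate <- function(features, config = distill_config(),
                           fit_fun = NULL, predict_fun = NULL) {
  if (is.null(fit_fun)) {
    fit_fun <- function(x, y) {
      net <- eeg_net(T = dim(x)[2L], B = dim(x)[3L], H = dim(x)[4L],
                     W = dim(x)[5L], conv_channels = c(8L, 12L, 16L, 12L),
                     fc_dim = 48L, hidden = 24L, seed = config$seed)
      train_eeg(net, x, y, config)
    }
    predict_fun <- function(fit, x) {
      max.col(predict(fit, x), ties.method = "first") - 1L
    }
  }
  rows <- list()
  for (subj in unique(features$subject)) {
    s_idx <- which(features$subject == subj)
    y <- features$label[s_idx]
    if (length(unique(y)) < 2L) {
      warning("subject ", subj, " has a single class; skipped")
      next
    }
    stop_if(length(s_idx) < config$cv_folds,
            "subject %s has fewer samples than folds", subj)
    for (rep in seq_len(config$cv_repeats)) {
      fold <- make_stratified_folds(y, config$cv_folds,
                                    seed = config$seed + 1000L * rep)
      for (k in seq_len(config$cv_folds)) {
        te <- s_idx[fold == k]
        tr <- s_idx[fold != k]
        fit <- fit_fun(features$tensors[tr, , , , , drop = FALSE],
                       features$label[tr])
        pred <- predict_fun(fit,
                            features$tensors[te, , , , , drop = FALSE])
        m <- classification_metrics(features$label[te], pred)
        rows[[length(rows) + 1L]] <-
          data.frame(subject = subj, rep = rep, fold = k,
                     accuracy = m[["accuracy"]],
                     precision = m[["precision"]], recall = m[["recall"]],
                     f1 = m[["f1"]])
      }
    }
  }
  stop_if(length(rows) == 0L, "no subject had both classes")
  folds <- do.call(rbind, rows)
  per_subject <- stats::aggregate(accuracy ~ subject, folds, mean)
  res <- list(folds = folds, per_subject = per_subject,
              mean_accuracy = mean(per_subject$accuracy),
              sd_accuracy = stats::sd(per_subject$accuracy),
              config = config)
  class(res) <- "cv_result"
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation: %d subjects, %d x %d-fold\n",
              nrow(x$per_subject), x$config$cv_repeats, x$config$cv_folds))
  cat(sprintf("  accuracy %.2f +/- %.2f %%\n", 100 * x$mean_accuracy,
              100 * (x$sd_accuracy %||% 0)))
  invisible(x)
}

# ---- ablations --------------------------------------------------------

#' Ablation suite over attention, 3D input and distillation variants
#'
#' Trains and evaluates the four attention variants (both, band-only,
#' self-only, none), a raw-input variant (sampling points projected to
#' the grid, no DE and no band gate), and, when teacher features are
#' supplied, the distilled model against its `rho = 1` baseline.
#'
#' @param features Output of [featurize_windows()] (DE tensors).
#' @param raw_features Optional output of the raw-point pipeline (same
#'   list shape) for the raw-input variant.
#' @param visual_features Optional teacher sequences for the
#'   distillation pair.
#' @param config A [distill_config()].
#' @param holdout_fraction Test fraction for the shared split.
#' @param net_args List of width arguments passed to [eeg_net()].
#' @param epochs,lr Training overrides.
#' @return Data frame: variant, accuracy, n_parameters.
#' @export
ablation_suite <- function(features, raw_features = NULL,
                           visual_features = NULL,
                           config = distill_config(),
                           holdout_fraction = 0.25,
                           net_args = list(conv_channels = c(8L, 12L, 16L,
                                                             12L),
                                           fc_dim = 48L, hidden = 24L),
                           epochs = NULL, lr = NULL) {
  n <- dim(features$tensors)[1L]
  te <- with_seed(config$seed + 31L,
                  sample.int(n, max(1L, round(holdout_fraction * n))))
  tr <- setdiff(seq_len(n), te)
  fit_variant <- function(x, band, self, cfg, vf = NULL) {
    dims <- dim(x)
    net <- do.call(eeg_net, c(list(T = dims[2L], B = dims[3L],
                                   H = dims[4L], W = dims[5L],
                                   use_band_attention = band,
                                   use_self_attention = self,
                                   seed = cfg$seed), net_args))
    n_par <- sum(vapply(net$params, length, numeric(1)))
    fit <- train_eeg(net, x[tr, , , , , drop = FALSE],
                     features$label[tr], cfg,
                     visual_features = if (!is.null(vf)) vf[tr],
                     epochs = epochs, lr = lr)
    pr <- predict(fit, x[te, , , , , drop = FALSE])
    acc <- mean(max.col(pr, ties.method = "first") - 1L ==
                  features$label[te])
    list(accuracy = acc, n_parameters = n_par)
  }
  base_cfg <- config
  base_cfg$rho <- 1
  out <- list()
  variants <- list(full = c(TRUE, TRUE), band_only = c(TRUE, FALSE),
                   self_only = c(FALSE, TRUE), none = c(FALSE, FALSE))
  for (nm in names(variants)) {
    v <- fit_variant(features$tensors, variants[[nm]][1L],
                     variants[[nm]][2L], base_cfg)
    out[[length(out) + 1L]] <- data.frame(variant = nm,
                                          accuracy = v$accuracy,
                                          n_parameters = v$n_parameters)
  }
  if (!is.null(raw_features)) {
    v <- fit_variant(raw_features$tensors, FALSE, TRUE, base_cfg)
    out[[length(out) + 1L]] <- data.frame(variant = "raw_input",
                                          accuracy = v$accuracy,
                                          n_parameters = v$n_parameters)
  }
  if (!is.null(visual_features)) {
    v <- fit_variant(features$tensors, TRUE, TRUE, config,
                     vf = visual_features)
    out[[length(out) + 1L]] <- data.frame(variant = "distilled",
                                          accuracy = v$accuracy,
                                          n_parameters = v$n_parameters)
  }
  do.call(rbind, out)
}

# ---- band-attention report --------------------------------------------

#' Mean trained band-attention weights
#'
#' Runs the trained network over the samples and averages the sigmoid
#' band weights over all samples and time slices.
#'
#' @param net A trained [eeg_net()] with band attention enabled.
#' @param tensors `N x T x B x H x W` feature array.
#' @return Named numeric vector of per-band mean weights in `[0, 1]`.
#' @export
report_band_attention <- function(net, tensors) {
  stop_if(!net$config$use_band_attention,
          "band attention is disabled in this model")
  fw <- eeg_forward(net, tensors)
  w <- apply(fw$band_weights, 3L, mean)
  names(w) <- band_definitions()$name[seq_along(w)]
  w
}
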