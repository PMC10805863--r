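# Synthetic multimodal emotion data with known ground truth.
#
# EEG background per channel = one narrowband oscillator per frequency band
# (random frequency within the band, random phase per channel x trial)
# plus 1/f^a pink noise. Oscillator amplitudes are calibrated so that the
# total background power inside each band is identical across the four
# bands; the class-1 effect then raises the informative band's power on
# the informative channels to exactly effect_size times the class-0 band
# power, which is the only systematic band asymmetry in the data.

EEG_BANDS <- data.frame(
  name = c("theta", "alpha", "beta", "gamma"),
  low = c(4, 8, 14, 31),
  high = c(7, 13, 30, 50),
  stringsAsFactors = FALSE
)

DEAP_CHANNELS <- c(
  "Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1",
  "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4",
  "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8",
  "PO4", "O2"
)

# posterior electrodes carrying the class-dependent gamma effect
POSTERIOR_CHANNELS <- c(11L, 12L, 13L, 14L, 15L, 16L, 29L, 30L, 31L, 32L)

#' Specification of a synthetic EEG emotion dataset
#'
#' Collects the generator's parameters: trial structure, sampling, the
#' band and channels that carry the class-dependent power difference, the
#' effect size (class-1 / class-0 band-power ratio), and the pink-noise
#' slope. Identical specs (including seed) generate bit-identical data.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials_per_subject Trials per subject; class labels are
#'   balanced within each subject to within one trial.
#' @param trial_duration Experimental segment length in seconds.
#' @param baseline_duration Pre-stimulus baseline length in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param n_channels Electrode count (default 32, the standard montage).
#' @param informative_band One of `"theta"`, `"alpha"`, `"beta"`,
#'   `"gamma"`: the band whose power differs between classes.
#' @param informative_channels Integer channel indices carrying the
#'   effect; defaults to ten posterior electrodes.
#' @param effect_size Ratio of class-1 to class-0 band power on the
#'   informative channels (must be positive; 1 = no effect).
#' @param noise_exponent Spectral slope a of the 1/f^a background.
#' @param noise_fraction Fraction of per-channel background variance
#'   carried by the pink noise (the rest is split over the four band
#'   oscillators).
#' @param seed Integer seed; fixes the whole dataset.
#' @return An object of class `"synth_spec"`.
#' @export
synth_spec <- function(n_subjects = 4,
                       n_trials_per_subject = 40,
                       trial_duration = 8,
                       baseline_duration = 3,
                       sampling_rate = 128,
                       n_channels = 32,
                       informative_band = "gamma",
                       informative_channels = POSTERIOR_CHANNELS,
                       effect_size = 3,
                       noise_exponent = 1,
                       noise_fraction = 0.3,
                       seed = 1L) {
  spec <- list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_subject = as.integer(n_trials_per_subject),
    trial_duration = trial_duration,
    baseline_duration = baseline_duration,
    sampling_rate = sampling_rate,
    n_channels = as.integer(n_channels),
    informative_band = informative_band,
    informative_channels = as.integer(informative_channels),
    effect_size = effect_size,
    noise_exponent = noise_exponent,
    noise_fraction = noise_fraction,
    seed = as.integer(seed)
  )
  class(spec) <- "synth_spec"
  validate_synth_spec(spec)
  spec
}

validate_synth_spec <- function(spec) {
  stop_if(spec$n_subjects < 1L, "n_subjects must be >= 1")
  stop_if(spec$n_trials_per_subject < 1L, "n_trials_per_subject must be >= 1")
  stop_if(spec$trial_duration <= 0, "trial_duration must be positive")
  stop_if(spec$baseline_duration <= 0, "baseline_duration must be positive")
  stop_if(spec$sampling_rate <= 0, "sampling_rate must be positive")
  stop_if(spec$n_channels < 1L, "n_channels must be >= 1")
  stop_if(!spec$informative_band %in% EEG_BANDS$name,
          "informative_band must be one of theta/alpha/beta/gamma")
  stop_if(length(spec$informative_channels) == 0L,
          "informative_channels must be non-empty")
  stop_if(any(spec$informative_channels < 1L |
                spec$informative_channels > spec$n_channels),
          "informative_channels out of range")
  stop_if(spec$effect_size <= 0, "effect_size must be positive")
  stop_if(spec$noise_fraction < 0 || spec$noise_fraction >= 1,
          "noise_fraction must be in [0, 1)")
  invisible(spec)
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("Synthetic EEG spec:", x$n_subjects, "subjects x",
      x$n_trials_per_subject, "trials,", x$trial_duration, "s +",
      x$baseline_duration, "s baseline @", x$sampling_rate, "Hz,",
      x$n_channels, "channels\n")
  cat("  effect:", x$informative_band, "power x", x$effect_size, "on",
      length(x$informative_channels), "channels; 1/f^",
      x$noise_exponent, " noise; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# 1/f^a noise of unit variance via spectral shaping of white noise
pink_noise <- function(n, exponent) {
  white <- rnorm(n)
  if (exponent == 0) {
    return(white)
  }
  spec <- fft(white)
  f <- c(1, seq_len(n - 1))           # DC handled separately
  f <- pmin(f, n - f + 1)             # fold to two-sided frequency index
  scale <- f^(-exponent / 2)
  scale[1] <- 0                       # drop DC
  x <- Re(fft(spec * scale, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Expected share of unit-variance pink noise falling inside [lo, hi] Hz,
# for slope a over the generated range [f_min, nyquist].
pink_band_fraction <- function(lo, hi, exponent, f_min, nyquist) {
  integ <- function(a, b) {
    if (exponent == 1) log(b / a) else
      (b^(1 - exponent) - a^(1 - exponent)) / (1 - exponent)
  }
  integ(max(lo, f_min), min(hi, nyquist)) / integ(f_min, nyquist)
}

# per-band oscillator variances so each band's background power equals
# `band_power` after adding the pink-noise share
oscillator_variances <- function(spec, band_power = 1) {
  nyq <- spec$sampling_rate / 2
  noise_share <- vapply(seq_len(nrow(EEG_BANDS)), function(b) {
    pink_band_fraction(EEG_BANDS$low[b], EEG_BANDS$high[b],
                       spec$noise_exponent, 1, nyq)
  }, numeric(1)) * spec$noise_fraction
  v <- band_power - noise_share
  stop_if(any(v <= 0),
          "noise_fraction too large to equalise band powers")
  names(v) <- EEG_BANDS$name
  v
}

# one channels x samples background segment (oscillators + pink noise)
background_segment <- function(spec, n_samples, osc_var, boost_band = NULL,
                               boost_var = NULL, boost_channels = integer()) {
  fs <- spec$sampling_rate
  tt <- (seq_len(n_samples) - 1) / fs
  sig <- matrix(0, nrow = spec$n_channels, ncol = n_samples)
  for (ch in seq_len(spec$n_channels)) {
    acc <- numeric(n_samples)
    for (b in seq_len(nrow(EEG_BANDS))) {
      f <- runif(1, EEG_BANDS$low[b], EEG_BANDS$high[b])
      phase <- runif(1, 0, 2 * pi)
      v <- osc_var[b]
      if (!is.null(boost_band) && EEG_BANDS$name[b] == boost_band &&
          ch %in% boost_channels) {
        v <- boost_var
      }
      acc <- acc + sqrt(2 * v) * sin(2 * pi * f * tt + phase)
    }
    acc <- acc + sqrt(spec$noise_fraction) *
      pink_noise(n_samples, spec$noise_exponent)
    sig[ch, ] <- acc
  }
  sig
}

#' Generate a synthetic EEG emotion dataset
#'
#' Produces per-subject trial recordings (baseline + experimental
#' segment), integer 1-9 ratings consistent with a balanced binary
#' high/low class, and the ground-truth spec. Class-1 trials carry
#' `effect_size` times the class-0 band power in the informative band on
#' the informative channels; baselines carry no class signal.
#'
#' @param spec A [synth_spec()].
#' @return A list of class `"synth_dataset"` with elements `records`
#'   (one per subject: `subject_id`, `trials`, `sampling_rate`,
#'   `channel_names`), `labels` (data frame: subject, trial, class,
#'   rating_valence, rating_arousal), `visual_features` (NULL until
#'   [generate_visual_features()] is attached) and `truth` (the
#'   generating [synth_spec()]).
#' @export
generate_eeg <- function(spec) {
  validate_synth_spec(spec)
  with_seed(spec$seed, {
    fs <- spec$sampling_rate
    n_trial <- round(spec$trial_duration * fs)
    n_base <- round(spec$baseline_duration * fs)
    osc_var <- oscillator_variances(spec)
    inf_idx <- match(spec$informative_band, EEG_BANDS$name)
    nyq <- fs / 2
    noise_in_band <- spec$noise_fraction *
      pink_band_fraction(EEG_BANDS$low[inf_idx], EEG_BANDS$high[inf_idx],
                         spec$noise_exponent, 1, nyq)
    # class-1 oscillator variance chosen so total in-band power is
    # effect_size x the class-0 in-band power (oscillator + noise share)
    band_power <- 1
    boost_var <- spec$effect_size * band_power - noise_in_band
    stop_if(boost_var <= 0, "effect_size too small for the noise floor")
    ch_names <- if (spec$n_channels == 32L) DEAP_CHANNELS else
      paste0("ch", seq_len(spec$n_channels))

    records <- vector("list", spec$n_subjects)
    lab_rows <- vector("list", spec$n_subjects)
    for (s in seq_len(spec$n_subjects)) {
      classes <- rep_len(c(0L, 1L), spec$n_trials_per_subject)
      classes <- classes[sample.int(length(classes))]
      trials <- vector("list", spec$n_trials_per_subject)
      for (tr in seq_len(spec$n_trials_per_subject)) {
        cls <- classes[tr]
        baseline <- background_segment(spec, n_base, osc_var)
        signal <- if (cls == 1L) {
          background_segment(spec, n_trial, osc_var,
                             boost_band = spec$informative_band,
                             boost_var = boost_var,
                             boost_channels = spec$informative_channels)
        } else {
          background_segment(spec, n_trial, osc_var)
        }
        rating_v <- if (cls == 1L) sample(6:9, 1) else sample(1:4, 1)
        rating_a <- if (cls == 1L) sample(6:9, 1) else sample(1:4, 1)
        rownames(signal) <- ch_names
        rownames(baseline) <- ch_names
        trials[[tr]] <- list(signal = signal, baseline = baseline,
                             ratings = c(valence = rating_v,
                                         arousal = rating_a),
                             class = cls)
      }
      records[[s]] <- list(subject_id = sprintf("s%02d", s), trials = trials,
                           sampling_rate = fs, channel_names = ch_names)
      lab_rows[[s]] <- data.frame(
        subject = sprintf("s%02d", s),
        trial = seq_len(spec$n_trials_per_subject),
        class = classes,
        rating_valence = vapply(trials, function(x) x$ratings[["valence"]],
                                numeric(1)),
        rating_arousal = vapply(trials, function(x) x$ratings[["arousal"]],
                                numeric(1)),
        stringsAsFactors = FALSE
      )
    }
    ds <- list(records = records, labels = do.call(rbind, lab_rows),
               visual_features = NULL, truth = spec)
    class(ds) <- "synth_dataset"
    ds
  })
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("Synthetic EEG dataset:", length(x$records), "subjects,",
      nrow(x$labels), "trials (", sum(x$labels$class == 1L), "high /",
      sum(x$labels$class == 0L), "low )\n")
  invisible(x)
}

#' Generate label-correlated visual feature sequences
#'
#' Stand-in for features extracted by a trained visual network: each trial
#' gets a T x F sequence whose class-conditional mean vectors are
#' separated by `snr` (in units of the unit per-entry noise standard
#' deviation); `snr = 0` gives label-independent sequences.
#'
#' @param labels Integer vector of binary classes (0/1), one per trial.
#' @param T Time steps per sequence.
#' @param F Feature dimension.
#' @param snr Euclidean distance between the class mean vectors, in
#'   units of the per-entry noise standard deviation.
#' @param seed Integer seed.
#' @param scale Overall amplitude of the sequences (per-entry noise
#'   standard deviation). Separability depends only on `snr`; `scale`
#'   matters when the sequences serve as distillation targets, where
#'   they should live in the student feature range.
#' @return List of T x F matrices, one per label.
#' @export
generate_visual_features <- function(labels, T, F, snr, seed = 1L,
                                     scale = 1) {
  stop_if(T < 1L || F < 1L, "T and F must be >= 1")
  stop_if(snr < 0, "snr must be >= 0")
  stop_if(length(labels) == 0L, "labels must be non-empty")
  stop_if(!all(labels %in% c(0L, 1L)), "labels must be binary 0/1")
  stop_if(scale <= 0, "scale must be positive")
  with_seed(seed, {
    u <- rnorm(F)
    u <- u / sqrt(sum(u^2))
    delta <- snr * u
    lapply(labels, function(cls) {
      mu <- if (cls == 1L) delta else rep(0, F)
      scale * (matrix(rnorm(T * F), nrow = T, ncol = F) +
                 matrix(mu, nrow = T, ncol = F, byrow = TRUE))
    })
  })
}

#' Generate synthetic facial frame clips
#'
#' Each clip is T frames of 48 x 48 x 3 values in [0, 1] showing a
#' Gaussian blob drifting across the frame; the per-frame drift speed
#' depends on the class, giving the visual network a learnable
#' motion cue.
#'
#' @param labels Integer vector of binary classes (0/1), one per clip.
#' @param T Frames per clip.
#' @param height,width Frame size (default 48 x 48).
#' @param speed0,speed1 Drift speed in pixels/frame for class 0 / class 1.
#' @param blob_sigma Gaussian radius of the blob in pixels.
#' @param seed Integer seed.
#' @return List of T x height x width x 3 arrays.
#' @export
generate_frame_clips <- function(labels, T, height = 48L, width = 48L,
                                 speed0 = 1, speed1 = 3, blob_sigma = 4,
                                 seed = 1L) {
  stop_if(T < 1L, "T must be >= 1")
  stop_if(length(labels) == 0L, "labels must be non-empty")
  with_seed(seed, {
    xs <- seq_len(width)
    ys <- seq_len(height)
    lapply(labels, function(cls) {
      speed <- if (cls == 1L) speed1 else speed0
      ang <- runif(1, 0, 2 * pi)
      vel <- speed * c(cos(ang), sin(ang))
      pos <- c(runif(1, width * 0.3, width * 0.7),
               runif(1, height * 0.3, height * 0.7))
      hue <- runif(3, 0.4, 1)
      clip <- array(0, dim = c(T, height, width, 3L))
      for (t in seq_len(T)) {
        # reflect at borders
        for (k in 1:2) {
          lim <- if (k == 1) width else height
          if (pos[k] < 1 || pos[k] > lim) {
            vel[k] <- -vel[k]
            pos[k] <- min(max(pos[k], 1), lim)
          }
        }
        blob <- outer(exp(-(ys - pos[2])^2 / (2 * blob_sigma^2)),
                      exp(-(xs - pos[1])^2 / (2 * blob_sigma^2)))
        for (c in 1:3) {
          clip[t, , , c] <- pmin(1, hue[c] * blob +
                                   0.02 * abs(rnorm(height * width)))
        }
        pos <- pos + vel
      }
      clip
    })
  })
}

#' Mean frame-to-frame blob displacement of a clip
#'
#' Recovers the drift speed from generated frames by tracking the
#' intensity centroid; used to verify the class-dependent motion cue.
#'
#' @param clip A T x H x W x 3 array.
#' @return Mean centroid displacement in pixels/frame.
#' @export
clip_displacement <- function(clip) {
  d <- dim(clip)
  lum <- apply(clip, c(1, 2, 3), sum)
  cent <- t(vapply(seq_len(d[1]), function(t) {
    fr <- lum[t, , ]
    fr <- pmax(fr - stats::median(fr), 0)
    w <- sum(fr)
    c(sum(row(fr) * fr) / w, sum(col(fr) * fr) / w)
  }, numeric(2)))
  if (d[1] < 2L) return(0)
  mean(sqrt(rowSums(diff(cent)^2)))
}
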