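# 3D feature construction: Butterworth band decomposition, per-channel
# differential entropy under the Gaussian closed form, topographic
# projection of electrodes onto a sparse 9 x 9 grid, and stacking into a
# T x B x 9 x 9 tensor.

#' Default EEG frequency-band definitions
#'
#' theta 4-7 Hz, alpha 8-13 Hz, beta 14-30 Hz, gamma 31-50 Hz.
#'
#' @return Data frame with columns `name`, `low`, `high`.
#' @export
band_definitions <- function() EEG_BANDS

#' Decompose a window into frequency-band signals
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass filter of
#' the given order per band and channel, so band signals stay time-aligned
#' with the input.
#'
#' @param window Channels x samples matrix.
#' @param sampling_rate Sampling rate in Hz.
#' @param bands Band definition data frame (default [band_definitions()]).
#' @param order Butterworth order (default 4).
#' @return Named list (by band) of channels x samples matrices.
#' @export
bandpass_decompose <- function(window, sampling_rate,
                               bands = band_definitions(), order = 4L) {
  nyq <- sampling_rate / 2
  stop_if(any(bands$high >= nyq),
          "band edge at or above Nyquist (%g Hz)", nyq)
  stop_if(any(bands$low <= 0) || any(bands$low >= bands$high),
          "band edges must satisfy 0 < low < high")
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (b in seq_len(nrow(bands))) {
    bf <- signal::butter(order, c(bands$low[b], bands$high[b]) / nyq,
                         type = "pass")
    filt <- t(apply(window, 1L, function(ch) {
      signal::filtfilt(bf, ch)
    }))
    if (ncol(window) == 1L) filt <- matrix(filt, nrow = nrow(window))
    dimnames(filt) <- dimnames(window)
    out[[b]] <- filt
  }
  out
}

#' Differential entropy of band-limited signals (Gaussian closed form)
#'
#' For a Gaussian signal the differential entropy is
#' `0.5 * log(2 * pi * e * sigma^2)` nats; the per-channel sample
#' variance (unbiased) estimates `sigma^2`. A variance floor keeps the
#' value finite on degenerate (constant) slices.
#'
#' @param band_signal Channels x samples matrix (or a vector, one
#'   channel).
#' @param var_floor Lower bound applied to the variance estimate.
#' @return Numeric vector of per-channel DE values in nats.
#' @export
differential_entropy <- function(band_signal, var_floor = 1e-12) {
  if (is.null(dim(band_signal))) {
    band_signal <- matrix(band_signal, nrow = 1L)
  }
  stop_if(ncol(band_signal) < 2L, "need at least 2 samples per channel")
  v <- pmax(apply(band_signal, 1L, stats::var), var_floor)
  de <- 0.5 * log(2 * pi * exp(1) * v)
  names(de) <- rownames(band_signal)
  de
}

#' Load an electrode-to-grid montage from JSON
#'
#' The montage file maps channel names to `[row, col]` cells (0-based,
#' row-major) of an `H x W` grid. Mappings must be injective and within
#' the grid.
#'
#' @param path Path to a montage JSON file; the default is the packaged
#'   32-channel 10-20 layout on a 9 x 9 grid.
#' @return Object of class `"montage"`: list with `mapping` (named list
#'   of 1-based `c(row, col)`), `H`, `W`.
#' @export
load_montage <- function(path = system.file("extdata", "montage_32_9x9.json",
                                            package = "deeframe")) {
  raw <- jsonlite::fromJSON(path)
  h <- as.integer(raw$H)
  w <- as.integer(raw$W)
  mapping <- lapply(raw$mapping, function(rc) as.integer(rc) + 1L)
  cells <- vapply(mapping, function(rc) (rc[1] - 1L) * w + rc[2], numeric(1))
  stop_if(anyDuplicated(cells) > 0L, "montage maps two channels to one cell")
  rc_ok <- vapply(mapping, function(rc) {
    length(rc) == 2L && all(rc >= 1L) && rc[1] <= h && rc[2] <= w
  }, logical(1))
  stop_if(!all(rc_ok), "montage cell out of grid")
  structure(list(mapping = mapping, H = h, W = w), class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("Montage:", length(x$mapping), "channels on a", x$H, "x", x$W,
      "grid\n")
  invisible(x)
}

#' Project per-channel values onto the topographic grid
#'
#' Places each channel's value at its montage cell; cells without an
#' electrode are exactly zero.
#'
#' @param values Named numeric vector (names = channel names).
#' @param montage A [load_montage()] object.
#' @return `H x W` numeric matrix.
#' @export
project_to_grid <- function(values, montage) {
  stop_if(is.null(names(values)), "values must be named by channel")
  unknown <- setdiff(names(values), names(montage$mapping))
  stop_if(length(unknown) > 0L, "channel(s) not in montage: %s",
          paste(unknown, collapse = ", "))
  grid <- matrix(0, nrow = montage$H, ncol = montage$W)
  for (ch in names(values)) {
    rc <- montage$mapping[[ch]]
    grid[rc[1], rc[2]] <- values[[ch]]
  }
  grid
}

#' Build the 3D differential-entropy feature tensor for one window
#'
#' The window is band-pass decomposed once (zero-phase, so band signals
#' stay aligned), split into `T` equal non-overlapping sub-slices, and
#' for each sub-slice and band the per-channel DE values are projected
#' onto the grid. The result is a `T x B x H x W` array.
#'
#' @param window Channels x samples matrix with channel rownames.
#' @param sampling_rate Sampling rate in Hz.
#' @param T Number of sub-slices; must divide the sample count.
#' @param bands Band definitions.
#' @param montage Electrode montage.
#' @param var_floor Variance floor for degenerate slices.
#' @return `T x B x H x W` numeric array.
#' @export
build_feature_tensor <- function(window, sampling_rate, T = 4L,
                                 bands = band_definitions(),
                                 montage = load_montage(),
                                 var_floor = 1e-12) {
  n <- ncol(window)
  stop_if(n %% T != 0L, "window length %d not divisible by T = %d", n, T)
  slice_len <- n %/% T
  band_sigs <- bandpass_decompose(window, sampling_rate, bands)
  out <- array(0, dim = c(T, nrow(bands), montage$H, montage$W))
  for (t in seq_len(T)) {
    cols <- (t - 1L) * slice_len + seq_len(slice_len)
    for (b in seq_len(nrow(bands))) {
      de <- differential_entropy(band_sigs[[b]][, cols, drop = FALSE],
                                 var_floor = var_floor)
      out[t, b, , ] <- project_to_grid(de, montage)
    }
  }
  out
}

#' Project raw sampling points onto the grid (no DE stage)
#'
#' Ablation input: every sampling point of the window becomes one grid
#' map; the points are grouped into `T` sub-slices so the result is
#' `T x (samples/T) x H x W`, consumed by the network in place of the
#' band axis.
#'
#' @inheritParams build_feature_tensor
#' @return `T x (samples/T) x H x W` numeric array.
#' @export
raw_point_tensor <- function(window, T = 4L, montage = load_montage()) {
  n <- ncol(window)
  stop_if(n %% T != 0L, "window length %d not divisible by T = %d", n, T)
  slice_len <- n %/% T
  out <- array(0, dim = c(T, slice_len, montage$H, montage$W))
  for (t in seq_len(T)) {
    cols <- (t - 1L) * slice_len + seq_len(slice_len)
    for (j in seq_len(slice_len)) {
      out[t, j, , ] <- project_to_grid(window[, cols[j]], montage)
    }
  }
  out
}

#' Build feature tensors for a whole set of windows
#'
#' @param prep Output of [preprocess_dataset()].
#' @param T Sub-slices per window.
#' @param bands,montage,var_floor Passed to [build_feature_tensor()].
#' @return List with `tensors` (N x T x B x H x W array), `label`,
#'   `subject`, `trial`.
#' @export
featurize_windows <- function(prep, T = 4L, bands = band_definitions(),
                              montage = load_montage(), var_floor = 1e-12) {
  n <- length(prep$windows)
  stop_if(n == 0L, "no windows to featurize")
  first <- build_feature_tensor(prep$windows[[1]], prep$sampling_rate, T,
                                bands, montage, var_floor)
  tensors <- array(0, dim = c(n, dim(first)))
  tensors[1, , , , ] <- first
  if (n > 1L) {
    for (i in 2:n) {
      tensors[i, , , , ] <- build_feature_tensor(
        prep$windows[[i]], prep$sampling_rate, T, bands, montage, var_floor)
    }
  }
  list(tensors = tensors, label = prep$label, subject = prep$subject,
       trial = prep$trial)
}
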