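# Preprocessing: baseline removal with a non-overlapping window template,
# non-overlapping segmentation, middle-segment selection, and rating
# binarization at the conventional threshold of 5.

#' Remove the pre-stimulus baseline from an experimental EEG segment
#'
#' The baseline is cut into non-overlapping windows of `window_seconds`;
#' their per-channel elementwise mean forms a template window, which is
#' subtracted from every (non-overlapping) window of the experimental
#' signal. A trailing partial window has the leading part of the template
#' subtracted, so the output length equals the input length.
#'
#' @param trial_signal Channels x samples matrix (experimental segment).
#' @param baseline_signal Channels x samples matrix (pre-stimulus
#'   segment); must span at least one window.
#' @param window_seconds Window length in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @return Corrected channels x samples matrix.
#' @export
remove_baseline <- function(trial_signal, baseline_signal, window_seconds,
                            sampling_rate) {
  stop_if(nrow(trial_signal) != nrow(baseline_signal),
          "trial and baseline must have the same channel count")
  wlen <- window_seconds * sampling_rate
  stop_if(abs(wlen - round(wlen)) > 1e-9,
          "window_seconds x sampling_rate must be an integer")
  wlen <- as.integer(round(wlen))
  n_base_win <- ncol(baseline_signal) %/% wlen
  stop_if(n_base_win < 1L, "baseline shorter than one window")
  template <- matrix(0, nrow = nrow(baseline_signal), ncol = wlen)
  for (w in seq_len(n_base_win)) {
    template <- template +
      baseline_signal[, (w - 1L) * wlen + seq_len(wlen), drop = FALSE]
  }
  template <- template / n_base_win
  out <- trial_signal
  n <- ncol(trial_signal)
  start <- 1L
  while (start <= n) {
    len <- min(wlen, n - start + 1L)
    out[, start:(start + len - 1L)] <-
      out[, start:(start + len - 1L), drop = FALSE] -
      template[, seq_len(len), drop = FALSE]
    start <- start + wlen
  }
  out
}

#' Segment a signal into non-overlapping windows
#'
#' Cuts consecutive, non-overlapping windows of `window_seconds`; a
#' trailing remainder that does not fill a window is discarded. A window
#' longer than the signal yields an empty list.
#'
#' @param signal Channels x samples matrix.
#' @param window_seconds Window length in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @return List of channels x samples matrices.
#' @export
segment_windows <- function(signal, window_seconds, sampling_rate) {
  wlen <- window_seconds * sampling_rate
  stop_if(abs(wlen - round(wlen)) > 1e-9 || wlen <= 0,
          "window_seconds x sampling_rate must be a positive integer")
  wlen <- as.integer(round(wlen))
  n_win <- ncol(signal) %/% wlen
  if (n_win == 0L) return(list())
  lapply(seq_len(n_win), function(w) {
    signal[, (w - 1L) * wlen + seq_len(wlen), drop = FALSE]
  })
}

#' Select the centred segment of a signal
#'
#' Keeps the middle `keep_seconds` of the signal. When the number of
#' trimmed samples is odd, the extra sample is trimmed from the head.
#'
#' @param signal Channels x samples matrix.
#' @param keep_seconds Duration to keep, in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @return Channels x samples matrix of `keep_seconds * sampling_rate`
#'   samples.
#' @export
select_middle_segment <- function(signal, keep_seconds, sampling_rate) {
  keep <- as.integer(round(keep_seconds * sampling_rate))
  n <- ncol(signal)
  stop_if(n < keep, "signal shorter than keep_seconds")
  rem <- n - keep
  head_trim <- rem %/% 2L + rem %% 2L
  signal[, head_trim + seq_len(keep), drop = FALSE]
}

#' Binarize a 1-9 emotion rating at threshold 5
#'
#' Ratings above 5 map to `"high"`, ratings of 5 or below to `"low"`
#' (vectorised).
#'
#' @param rating Integer rating(s) in 1..9.
#' @return Character vector of `"low"` / `"high"`.
#' @export
binarize_rating <- function(rating) {
  stop_if(any(rating < 1 | rating > 9 | rating != round(rating)),
          "ratings must be integers in 1..9")
  ifelse(rating > 5, "high", "low")
}

#' Preprocess a synthetic dataset into labelled windows
#'
#' Applies baseline removal and non-overlapping segmentation to every
#' trial of every subject, carrying the binary label of the requested
#' rating dimension onto each window.
#'
#' @param dataset A `"synth_dataset"` (or any list of records in the same
#'   shape).
#' @param window_seconds Window length in seconds.
#' @param dimension `"valence"` or `"arousal"`.
#' @param middle_seconds Optional: keep only the centred span of this
#'   duration before windowing (used for variable-length trials).
#' @return A list with `windows` (list of channels x samples matrices),
#'   and parallel vectors `label` (0 = low, 1 = high), `subject`,
#'   `trial`.
#' @export
preprocess_dataset <- function(dataset, window_seconds = 2,
                               dimension = c("valence", "arousal"),
                               middle_seconds = NULL) {
  dimension <- match.arg(dimension)
  windows <- list()
  label <- integer()
  subject <- character()
  trial <- integer()
  for (rec in dataset$records) {
    fs <- rec$sampling_rate
    for (tr in seq_along(rec$trials)) {
      x <- rec$trials[[tr]]
      sig <- x$signal
      if (!is.null(middle_seconds)) {
        sig <- select_middle_segment(sig, middle_seconds, fs)
      }
      sig <- remove_baseline(sig, x$baseline, window_seconds, fs)
      wins <- segment_windows(sig, window_seconds, fs)
      if (length(wins) == 0L) next
      rating <- x$ratings[[dimension]]
      lab <- as.integer(binarize_rating(rating) == "high")
      windows <- c(windows, wins)
      label <- c(label, rep(lab, length(wins)))
      subject <- c(subject, rep(rec$subject_id, length(wins)))
      trial <- c(trial, rep(tr, length(wins)))
    }
  }
  list(windows = windows, label = label, subject = subject, trial = trial,
       sampling_rate = dataset$records[[1]]$sampling_rate,
       window_seconds = window_seconds)
}
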