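# I/O: a plain-text array container for synthetic datasets (CSV signals
# + JSON metadata), minimal readers for 16-bit EDF and uncompressed
# MATLAB v5 numeric arrays, metrics/feature writers, and the end-to-end
# pipeline driver.

fmt_num <- function(x) sprintf("%.17g", x)

write_matrix_csv <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(mat) %||% paste0("V", seq_len(ncol(mat))),
                   collapse = ","), con)
  apply(mat, 1L, function(r) writeLines(paste(fmt_num(r), collapse = ","),
                                        con))
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' One signals file per subject (plain CSV: trial, segment, channel,
#' then samples at full precision), a trial table (ratings, classes) and
#' a JSON copy of the generating spec. The container round-trips
#' bit-exactly through [read_synthetic_dataset()].
#'
#' @param dataset A `"synth_dataset"`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- dataset$truth
  jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(dataset$labels, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  for (rec in dataset$records) {
    con <- file(file.path(dir, paste0(rec$subject_id, "_signals.csv")),
                "w")
    writeLines("trial,segment,channel,samples...", con)
    for (tr in seq_along(rec$trials)) {
      for (seg in c("signal", "baseline")) {
        m <- rec$trials[[tr]][[seg]]
        for (ch in seq_len(nrow(m))) {
          writeLines(paste(c(tr, seg, rec$channel_names[ch],
                             fmt_num(m[ch, ])), collapse = ","), con)
        }
      }
    }
    close(con)
  }
  invisible(dir)
}

#' Read a synthetic dataset written by [write_synthetic_dataset()]
#'
#' @param dir Directory containing `spec.json`, `trials.csv` and
#'   per-subject signal files.
#' @return A `"synth_dataset"`.
#' @export
read_synthetic_dataset <- function(dir) {
  spec_l <- jsonlite::fromJSON(file.path(dir, "spec.json"))
  spec <- do.call(synth_spec, spec_l[setdiff(names(spec_l), character())])
  labels <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  files <- sort(list.files(dir, pattern = "_signals\\.csv$",
                           full.names = TRUE))
  records <- lapply(files, function(f) {
    subject_id <- sub("_signals\\.csv$", "", basename(f))
    lines <- readLines(f)[-1L]
    parts <- strsplit(lines, ",", fixed = TRUE)
    trial_no <- vapply(parts, function(p) as.integer(p[1L]), integer(1))
    seg <- vapply(parts, function(p) p[2L], character(1))
    chan <- vapply(parts, function(p) p[3L], character(1))
    ch_names <- unique(chan)
    trials <- lapply(sort(unique(trial_no)), function(tr) {
      get_seg <- function(s) {
        rows <- which(trial_no == tr & seg == s)
        m <- do.call(rbind, lapply(parts[rows], function(p) {
          as.numeric(p[-(1:3)])
        }))
        rownames(m) <- chan[rows]
        m[ch_names, , drop = FALSE]
      }
      lr <- labels[labels$subject == subject_id & labels$trial == tr, ]
      list(signal = get_seg("signal"), baseline = get_seg("baseline"),
           ratings = c(valence = lr$rating_valence,
                       arousal = lr$rating_arousal),
           class = lr$class)
    })
    list(subject_id = subject_id, trials = trials,
         sampling_rate = spec$sampling_rate, channel_names = ch_names)
  })
  ds <- list(records = records, labels = labels, visual_features = NULL,
             truth = spec)
  class(ds) <- "synth_dataset"
  ds
}

# ---- feature container ------------------------------------------------

#' Write a feature set (tensors + labels) to a directory
#'
#' `features.csv` holds one flattened tensor per row at full precision;
#' `meta.json` records the array dimensions and sample metadata.
#'
#' @param features Output of [featurize_windows()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_features <- function(features, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(features$tensors)
  n <- d[1L]
  flat <- matrix(features$tensors, nrow = n)
  con <- file(file.path(dir, "features.csv"), "w")
  for (i in seq_len(n)) {
    writeLines(paste(fmt_num(flat[i, ]), collapse = ","), con)
  }
  close(con)
  jsonlite::write_json(list(dim = d, label = features$label,
                            subject = features$subject,
                            trial = features$trial),
                       file.path(dir, "meta.json"), digits = NA)
  invisible(dir)
}

#' Read a feature set written by [write_features()]
#'
#' @param dir Directory containing `features.csv` and `meta.json`.
#' @return List with `tensors`, `label`, `subject`, `trial`.
#' @export
read_features <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  lines <- readLines(file.path(dir, "features.csv"))
  flat <- do.call(rbind, lapply(strsplit(lines, ",", fixed = TRUE),
                                as.numeric))
  list(tensors = array(flat, dim = meta$dim), label = meta$label,
       subject = meta$subject, trial = meta$trial)
}

#' Write evaluation metrics as JSON
#'
#' Adds the seed and a hash of the configuration so runs are
#' attributable.
#'
#' @param metrics Named list or vector of numbers.
#' @param path Output file.
#' @param config Optional configuration list recorded alongside.
#' @param seed Optional seed recorded alongside.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, config = NULL, seed = NULL) {
  payload <- list(metrics = as.list(metrics))
  if (!is.null(config)) {
    cfg <- unclass(config)
    payload$config <- cfg
    payload$config_hash <- config_hash(cfg)
  }
  if (!is.null(seed)) payload$seed <- seed
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # small deterministic polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Save / load network parameters as a JSON checkpoint
#'
#' Stores every parameter array with its dimensions at full precision;
#' reloading reproduces forward outputs exactly.
#'
#' @param net An `"eeg_net"` or `"visual_net"`.
#' @param path Checkpoint file.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(net, path) {
  ser <- lapply(net$params, function(p) {
    list(dim = dim(p) %||% length(p), data = as.numeric(p),
         kh = attr(p, "kh"), kw = attr(p, "kw"), k = attr(p, "k"))
  })
  payload <- list(class = class(net)[1L], config = net$config,
                  params = ser, config_hash = config_hash(net$config))
  if (!is.null(net$state)) {
    payload$state <- net$state
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_checkpoint
#' @param template A network of the matching class whose configuration
#'   the checkpoint must match.
#' @export
read_checkpoint <- function(path, template) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  stop_if(raw$class != class(template)[1L],
          "checkpoint class %s does not match template", raw$class)
  params <- lapply(raw$params, function(p) {
    a <- array(p$data, dim = unlist(p$dim))
    if (length(dim(a)) == 1L) a <- as.numeric(a)
    if (!is.null(p$kh)) {
      attr(a, "kh") <- as.integer(p$kh)
      attr(a, "kw") <- as.integer(p$kw)
    }
    if (!is.null(p$k)) attr(a, "k") <- as.integer(p$k)
    a
  })
  template$params <- params[names(template$params)]
  if (!is.null(raw$state)) {
    template$state <- lapply(raw$state, function(s) {
      list(mean = as.numeric(s$mean), var = as.numeric(s$var))
    })
  }
  template
}

# ---- EDF reader (16-bit, no annotations) ------------------------------

#' Read a 16-bit EDF recording
#'
#' Minimal reader for continuous EDF files: parses the ASCII header,
#' applies the per-channel physical scaling, and concatenates data
#' records into a channels x samples matrix. Annotation channels are
#' not supported.
#'
#' @param path EDF file.
#' @return List with `signal` (channels x samples, physical units),
#'   `sampling_rate`, `channel_names`, `duration` (seconds).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr(8)                                   # version
  hdr(80); hdr(80)                         # patient / recording id
  hdr(8); hdr(8)                           # date / time
  header_bytes <- as.integer(hdr(8))
  hdr(44)                                  # reserved
  n_records <- as.integer(hdr(8))
  record_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  labels <- vapply(seq_len(ns), function(i) hdr(16), character(1))
  for (i in seq_len(ns)) hdr(80)           # transducer
  for (i in seq_len(ns)) hdr(8)            # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(hdr(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(hdr(8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(hdr(8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(hdr(8)), numeric(1))
  for (i in seq_len(ns)) hdr(80)           # prefiltering
  nsamp <- vapply(seq_len(ns), function(i) as.integer(hdr(8)), integer(1))
  for (i in seq_len(ns)) hdr(32)           # reserved
  stop_if(header_bytes != 256L + 256L * ns, "corrupt EDF header")
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  offset <- pmin_ - gain * dmin_
  sig <- lapply(seq_len(ns), function(i) numeric(0))
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[i], size = 2L,
                     endian = "little")
      sig[[i]] <- c(sig[[i]], gain[i] * dig + offset[i])
    }
  }
  signal <- do.call(rbind, sig)
  rownames(signal) <- labels
  list(signal = signal, sampling_rate = nsamp[1L] / record_dur,
       channel_names = labels, duration = n_records * record_dur)
}

#' Write a 16-bit EDF recording
#'
#' Companion writer used to exercise [read_edf()] and export synthetic
#' recordings; values are scaled to the per-channel min/max range.
#'
#' @param signal Channels x samples matrix with channel rownames.
#' @param sampling_rate Sampling rate in Hz.
#' @param path Output file.
#' @param record_seconds Data-record duration (default 1 s).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signal, sampling_rate, path, record_seconds = 1) {
  ns <- nrow(signal)
  spr <- as.integer(round(sampling_rate * record_seconds))
  n_records <- ncol(signal) %/% spr
  stop_if(n_records < 1L, "signal shorter than one data record")
  signal <- signal[, seq_len(n_records * spr), drop = FALSE]
  pmin_ <- apply(signal, 1L, min)
  pmax_ <- apply(signal, 1L, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, n) {
    s <- substr(format(x, width = n), 1L, n)
    writeChar(formatC(s, width = n, flag = "-"), con, eos = NULL)
  }
  pad("0", 8)
  pad("synthetic patient", 80); pad("synthetic recording", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(as.character(256L + 256L * ns), 8)
  pad("", 44)
  pad(as.character(n_records), 8)
  pad(format(record_seconds), 8)
  pad(as.character(ns), 4)
  labs <- rownames(signal) %||% paste0("ch", seq_len(ns))
  for (l in labs) pad(l, 16)
  for (i in seq_len(ns)) pad("synthetic", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) pad(format(pmin_[i], digits = 6), 8)
  for (i in seq_len(ns)) pad(format(pmax_[i], digits = 6), 8)
  for (i in seq_len(ns)) pad("-32768", 8)
  for (i in seq_len(ns)) pad("32767", 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(as.character(spr), 8)
  for (i in seq_len(ns)) pad("", 32)
  gain <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      x <- signal[i, (r - 1L) * spr + seq_len(spr)]
      dig <- as.integer(round((x - pmin_[i]) / gain[i]) - 32768)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

# ---- MATLAB v5 reader/writer (uncompressed double arrays) ------------

#' Read numeric arrays from an uncompressed MATLAB v5 file
#'
#' Supports double-precision real arrays (the layout of per-trial
#' channels x samples exports); compressed or cell/struct elements are
#' rejected.
#'
#' @param path `.mat` file.
#' @return Named list of numeric arrays.
#' @export
read_mat <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 124)                 # text header
  version <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  endian <- rawToChar(readBin(con, "raw", 2))
  stop_if(endian != "IM", "big-endian MAT files not supported")
  stop_if(version != 256L, "not a MAT v5 file")
  out <- list()
  repeat {
    tag <- readBin(con, "integer", 2L, size = 4L, endian = "little")
    if (length(tag) < 2L) break
    stop_if(tag[1L] == 15L, "compressed MAT elements not supported")
    stop_if(tag[1L] != 14L, "unsupported MAT element type %d", tag[1L])
    el <- readBin(con, "raw", tag[2L])
    parsed <- parse_mat_matrix(el)
    out[[parsed$name]] <- parsed$value
  }
  out
}

parse_mat_matrix <- function(bytes) {
  pos <- 1L
  rd_tag <- function() {
    t <- readBin(bytes[pos:(pos + 7L)], "integer", 2L, size = 4L,
                 endian = "little")
    small <- bitwAnd(t[1L], -65536L) != 0L
    if (small) {
      list(type = bitwAnd(t[1L], 65535L),
           nbytes = bitwShiftR(bitwAnd(t[1L], -65536L), 16L), small = TRUE)
    } else {
      list(type = t[1L], nbytes = t[2L], small = FALSE)
    }
  }
  rd_element <- function(what, size) {
    tg <- rd_tag()
    if (tg$small) {
      data <- bytes[(pos + 4L):(pos + 4L + tg$nbytes - 1L)]
      pos <<- pos + 8L
    } else {
      data <- bytes[(pos + 8L):(pos + 8L + tg$nbytes - 1L)]
      adv <- 8L + tg$nbytes
      if (adv %% 8L != 0L) adv <- adv + (8L - adv %% 8L)
      pos <<- pos + adv
    }
    readBin(data, what, n = length(data) %/% size, size = size,
            endian = "little")
  }
  flags <- rd_element("integer", 4L)
  cls <- bitwAnd(flags[1L], 255L)
  stop_if(cls != 6L, "only double arrays supported (class %d)", cls)
  dims <- rd_element("integer", 4L)
  name <- rawToChar(as.raw(rd_element("integer", 1L)))
  value <- rd_element("numeric", 8L)
  if (length(dims) > 1L) value <- array(value, dim = dims)
  list(name = name, value = value)
}

#' Write numeric arrays to an uncompressed MATLAB v5 file
#'
#' @param arrays Named list of numeric vectors/matrices/arrays.
#' @param path Output `.mat` file.
#' @return `path`, invisibly.
#' @export
write_mat <- function(arrays, path) {
  stop_if(is.null(names(arrays)) || any(names(arrays) == ""),
          "arrays must be a named list")
  con <- file(path, "wb")
  on.exit(close(con))
  txt <- sprintf("MATLAB 5.0 MAT-file, created by deeframe")
  hdr <- charToRaw(formatC(txt, width = 124, flag = "-"))
  writeBin(hdr[1:124], con)
  writeBin(c(256L), con, size = 2L, endian = "little")
  writeChar("IM", con, eos = NULL)
  pad8 <- function(n) if (n %% 8L == 0L) 0L else 8L - n %% 8L
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    dims <- dim(a) %||% c(1L, length(a))
    if (length(dims) == 1L) dims <- c(1L, dims)
    name_raw <- charToRaw(nm)
    sub_len <- function(payload) 8L + payload + pad8(payload)
    total <- sub_len(8L) + sub_len(4L * length(dims)) +
      sub_len(length(name_raw)) + sub_len(8L * length(a))
    writeBin(c(14L, total), con, size = 4L, endian = "little")
    writeBin(c(6L, 8L), con, size = 4L, endian = "little")   # flags tag
    writeBin(c(6L, 0L), con, size = 4L, endian = "little")   # mxDOUBLE
    writeBin(c(5L, 4L * length(dims)), con, size = 4L, endian = "little")
    writeBin(as.integer(dims), con, size = 4L, endian = "little")
    writeBin(as.raw(rep(0, pad8(4L * length(dims)))), con)
    writeBin(c(1L, length(name_raw)), con, size = 4L, endian = "little")
    writeBin(name_raw, con)
    writeBin(as.raw(rep(0, pad8(length(name_raw)))), con)
    writeBin(c(9L, 8L * length(a)), con, size = 4L, endian = "little")
    writeBin(as.numeric(a), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read an EEG recording from any supported container
#'
#' Dispatches on the file extension: `.edf` via [read_edf()], `.mat`
#' via [read_mat()] (expects one channels x samples array per trial),
#' or a synthetic-container directory via [read_synthetic_dataset()].
#'
#' @param path File or directory.
#' @param sampling_rate Required for `.mat` input.
#' @return For files, a list with `signal`/`sampling_rate`/
#'   `channel_names`; for directories, a `"synth_dataset"`.
#' @export
read_eeg <- function(path, sampling_rate = NULL) {
  stop_if(!file.exists(path), "no such file: %s", path)
  if (dir.exists(path)) return(read_synthetic_dataset(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") return(read_edf(path))
  if (ext == "mat") {
    stop_if(is.null(sampling_rate), "sampling_rate required for .mat")
    arrays <- read_mat(path)
    return(list(signal = arrays[[1L]], sampling_rate = sampling_rate,
                channel_names = rownames(arrays[[1L]]) %||%
                  paste0("ch", seq_len(nrow(arrays[[1L]])))))
  }
  stop("unsupported EEG container: ", path, call. = FALSE)
}

# ---- pipeline ---------------------------------------------------------

#' Run the full synthetic pipeline end to end
#'
#' Generates (or loads) a synthetic dataset, preprocesses and
#' featurizes it, attaches teacher features, trains the distilled EEG
#' network on a training split, and evaluates on the held-out split,
#' writing metrics, the band-attention report and a checkpoint to
#' `out_dir`.
#'
#' @param spec A [synth_spec()].
#' @param out_dir Output directory (artifacts are written when given).
#' @param config A [distill_config()].
#' @param T Sub-slices per window.
#' @param window_seconds Window length in seconds.
#' @param net_args Width arguments for [eeg_net()].
#' @param teacher_snr Class separation of the synthetic teacher
#'   features.
#' @param epochs,lr Training overrides.
#' @param holdout_fraction Held-out test fraction.
#' @return List with `metrics`, `band_weights`, `net`, `history`.
#' @export
run_pipeline <- function(spec = synth_spec(), out_dir = NULL,
                         config = distill_config(), T = 4L,
                         window_seconds = 2,
                         net_args = list(conv_channels = c(8L, 12L, 16L,
                                                           12L),
                                         fc_dim = 48L, hidden = 24L),
                         teacher_snr = 6, epochs = 10L, lr = 1e-3,
                         holdout_fraction = 0.25) {
  ds <- generate_eeg(spec)
  prep <- preprocess_dataset(ds, window_seconds = window_seconds)
  feats <- featurize_windows(prep, T = T)
  hidden <- net_args$hidden %||% 128L
  vf <- generate_visual_features(feats$label, T = T, F = hidden,
                                 snr = teacher_snr,
                                 seed = spec$seed + 7L)
  n <- dim(feats$tensors)[1L]
  te <- with_seed(config$seed + 31L,
                  sample.int(n, max(1L, round(holdout_fraction * n))))
  tr <- setdiff(seq_len(n), te)
  dims <- dim(feats$tensors)
  net <- do.call(eeg_net, c(list(T = dims[2L], B = dims[3L], H = dims[4L],
                                 W = dims[5L], seed = config$seed),
                            net_args))
  fit <- train_eeg(net, feats$tensors[tr, , , , , drop = FALSE],
                   feats$label[tr], config, visual_features = vf[tr],
                   epochs = epochs, lr = lr)
  pr <- predict(fit, feats$tensors[te, , , , , drop = FALSE])
  pred <- max.col(pr, ties.method = "first") - 1L
  metrics <- classification_metrics(feats$label[te], pred)
  bw <- report_band_attention(fit, feats$tensors)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_metrics(metrics, file.path(out_dir, "metrics.json"),
                  config = config, seed = spec$seed)
    utils::write.csv(data.frame(band = names(bw), mean_weight = bw),
                     file.path(out_dir, "band_attention.csv"),
                     row.names = FALSE)
    write_checkpoint(fit, file.path(out_dir, "checkpoint.json"))
  }
  list(metrics = metrics, band_weights = bw, net = fit,
       history = fit$history)
}
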