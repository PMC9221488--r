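#' Labelled multichannel EEG/EMG series
#'
#' A `channel_matrix` bundles a channels-by-samples numeric matrix with
#' channel identifiers, per-channel modality labels (`"EEG"` or `"EMG"`)
#' and the sampling rate.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param channel_ids character vector of channel names, one per row.
#' @param modalities character vector of `"EEG"`/`"EMG"` labels, one per row.
#' @param fs sampling rate in Hz.
#' @return An object of class `channel_matrix`.
#' @export
channel_matrix <- function(data, channel_ids, modalities, fs) {
  data <- as.matrix(data)
  if (length(channel_ids) != nrow(data))
    stop("channel_ids must have one entry per data row")
  if (length(modalities) != nrow(data))
    stop("modalities must have one entry per data row")
  modalities <- toupper(as.character(modalities))
  bad <- setdiff(unique(modalities), c("EEG", "EMG"))
  if (length(bad))
    stop("unknown modality label(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  rownames(data) <- channel_ids
  structure(
    list(data = data, channel_ids = as.character(channel_ids),
         modalities = modalities, fs = fs),
    class = "channel_matrix"
  )
}

#' @export
print.channel_matrix <- function(x, ...) {
  cat(sprintf("<channel_matrix> %d channels x %d samples @ %g Hz (%d EEG, %d EMG)\n",
              nrow(x$data), ncol(x$data), x$fs,
              sum(x$modalities == "EEG"), sum(x$modalities == "EMG")))
  invisible(x)
}

#' @export
dim.channel_matrix <- function(x) dim(x$data)

#' Read a multichannel recording with a channel manifest
#'
#' Reads a CSV/TSV file with one column per channel and a header row of
#' channel names, plus a manifest mapping channel name to modality.
#' Channels are returned in manifest order.
#'
#' @param path path to a CSV or TSV file (one column per channel).
#' @param manifest either a named character vector / named list mapping
#'   channel id to `"EEG"`/`"EMG"`, or the path to a YAML file with that
#'   mapping.
#' @param fs sampling rate in Hz.
#' @return A [channel_matrix()].
#' @export
load_signals <- function(path, manifest, fs = 1000) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(manifest) && length(manifest) == 1L && file.exists(manifest))
    manifest <- unlist(yaml::read_yaml(manifest))
  manifest <- unlist(manifest)
  if (is.null(names(manifest)) || any(names(manifest) == ""))
    stop("manifest must map channel names to modalities")
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(names(manifest), names(df))
  if (length(missing))
    stop("channel(s) named in manifest but absent from file: ",
         paste(missing, collapse = ", "))
  dat <- t(as.matrix(df[, names(manifest), drop = FALSE]))
  if (!is.numeric(dat)) stop("non-numeric data in ", path)
  channel_matrix(dat, names(manifest), unname(manifest), fs)
}

# RBJ biquad notch coefficients at f0 Hz with quality factor q.
notch_coefs <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + alpha),
       a = c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha)))
}

#' Filter, notch and rectify a multichannel recording
#'
#' Applies zero-phase (forward-backward) order-4 Butterworth bandpass
#' filters per modality, a quality-factor-30 biquad notch at the mains
#' frequency to every channel, and full-wave rectification of EMG rows.
#' Filtering precedes rectification.
#'
#' @param cm a [channel_matrix()].
#' @param eeg_band,emg_band numeric length-2 band edges in Hz.
#' @param notch mains frequency in Hz, or `NULL` to disable.
#' @param notch_q notch quality factor.
#' @param rectify_emg replace EMG rows by their absolute value.
#' @return A filtered [channel_matrix()].
#' @export
preprocess <- function(cm, eeg_band = c(0.05, 100), emg_band = c(30, 200),
                       notch = 50, notch_q = 30, rectify_emg = TRUE) {
  stopifnot(inherits(cm, "channel_matrix"))
  if (!all(is.finite(cm$data))) stop("non-finite values in input signal")
  nyq <- cm$fs / 2
  for (band in list(eeg_band, emg_band)) {
    if (!is.null(band) && (length(band) != 2 || any(band <= 0) ||
                           band[1] >= band[2] || band[2] >= nyq))
      stop("band edges must satisfy 0 < lo < hi < fs/2")
  }
  out <- cm$data
  filt_rows <- function(rows, bf) {
    for (i in rows) out[i, ] <<- signal::filtfilt(bf, out[i, ])
  }
  eeg <- which(cm$modalities == "EEG")
  emg <- which(cm$modalities == "EMG")
  if (!is.null(eeg_band) && length(eeg))
    filt_rows(eeg, signal::butter(4, eeg_band / nyq, type = "pass"))
  if (!is.null(emg_band) && length(emg))
    filt_rows(emg, signal::butter(4, emg_band / nyq, type = "pass"))
  if (!is.null(notch)) {
    if (notch >= nyq) stop("notch frequency must be below fs/2")
    nc <- notch_coefs(notch, cm$fs, notch_q)
    for (i in seq_len(nrow(out)))
      out[i, ] <- signal::filtfilt(filt = nc$b, a = nc$a, x = out[i, ])
  }
  if (rectify_emg && length(emg)) out[emg, ] <- abs(out[emg, ])
  if (!all(is.finite(out))) stop("filtering produced non-finite values")
  channel_matrix(out, cm$channel_ids, cm$modalities, cm$fs)
}

#' Cut a recording into fixed-length epochs
#'
#' @param cm a [channel_matrix()].
#' @param onsets integer vector of 1-based start samples.
#' @param length epoch length in samples.
#' @return A list of [channel_matrix()] objects, one per onset.
#' @export
epoch_trials <- function(cm, onsets, length) {
  stopifnot(inherits(cm, "channel_matrix"))
  if (length <= 0) stop("epoch length must be positive")
  n <- ncol(cm$data)
  lapply(onsets, function(on) {
    if (on < 1 || on + length - 1 > n)
      stop(sprintf("onset %d with length %d exceeds the %d available samples",
                   on, length, n))
    channel_matrix(cm$data[, on:(on + length - 1), drop = FALSE],
                   cm$channel_ids, cm$modalities, cm$fs)
  })
}
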