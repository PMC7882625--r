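#' Raw multi-channel EEG container
#'
#' Holds artifact-cleaned EEG voltages as a channel-by-sample matrix together
#' with the sampling rate and 10-20 montage labels.  Preprocessing (bad-channel
#' rejection, line-noise removal, re-referencing) is assumed to have been done
#' upstream; this container only validates shape and rate.
#'
#' @param samples Numeric matrix, channels in rows, samples in columns (microvolts).
#'   `NA` entries mark masked (artifact-dropped) samples.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Unique channel names (10-20 montage, e.g. `"C3"`).
#' @param start_time Offset of the first sample in seconds (default 0).
#' @param max_bin_hz Highest analysis bin the recording must support (default 40);
#'   `fs` must be at least twice this.
#' @return An object of class `raw_eeg`.
#' @export
raw_eeg <- function(samples, fs, channel_labels = rownames(samples),
                    start_time = 0, max_bin_hz = 40) {
  samples <- as.matrix(samples)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_labels) != nrow(samples)) {
    stop_neurodyn("channel_labels length must match the number of rows",
                  class = "neurodyn_config_error")
  }
  if (anyDuplicated(channel_labels)) {
    stop_neurodyn("channel labels must be unique", class = "neurodyn_config_error")
  }
  if (fs < 2 * max_bin_hz) {
    stop_neurodyn(sprintf("sampling rate %g Hz too low for %g Hz analysis (need >= %g)",
                          fs, max_bin_hz, 2 * max_bin_hz),
                  class = "neurodyn_config_error")
  }
  rownames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs, channel_labels = channel_labels,
                 start_time = start_time),
            class = "raw_eeg")
}

#' @export
print.raw_eeg <- function(x, ...) {
  cat(sprintf("<raw_eeg> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  invisible(x)
}

make_taper <- function(name, n) {
  switch(name,
    hann = if (n == 1) 1 else 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1))),
    hamming = if (n == 1) 1 else 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
    boxcar = ,
    rectangular = rep(1, n),
    stop_neurodyn("unknown taper '", name, "'", class = "neurodyn_config_error"))
}

# One-sided Welch PSD (density, unit^2/Hz) of vector x at rate fs, with
# segments of nseg samples, fractional overlap, and the named taper.
# Returns list(freq, density).
welch_segments <- function(x, fs, nseg, overlap, taper) {
  n <- length(x)
  nseg <- min(nseg, n)
  w <- make_taper(taper, nseg)
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq.int(1L, n - nseg + 1L, by = step)
  u <- sum(w^2)                         # taper power normalization
  nfreq <- nseg %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- seg - mean(seg)              # detrend by segment mean (DC removal)
    ft <- stats::fft(seg * w)
    pxx <- (Mod(ft[seq_len(nfreq)])^2) / (fs * u)
    # double everything except DC and (for even nseg) Nyquist: one-sided density
    two <- rep(2, nfreq)
    two[1] <- 1
    if (nseg %% 2 == 0) two[nfreq] <- 1
    acc <- acc + pxx * two
  }
  list(freq = (seq_len(nfreq) - 1L) * fs / nseg, density = acc / length(starts))
}

#' Per-second PSD tensor via Welch's method
#'
#' Estimates the power spectral density of each channel on a fixed epoch
#' cadence (default 1 s) and integrates the density over 1-Hz bands to give a
#' `time x channel x bin` band-power tensor in microvolts squared (density
#' times 1 Hz).  With the default single 1-s segment per epoch, Welch's
#' estimator degenerates to a modified (tapered) periodogram; longer segments
#' with overlap reduce variance at the cost of temporal smearing.
#'
#' @param raw A [raw_eeg()] object.
#' @param epoch_length Output cadence in seconds (default 1).
#' @param segment_length Welch segment length in seconds
#'   (default `epoch_length`); must not exceed `epoch_length`.
#' @param overlap Fractional overlap between Welch segments in `[0, 1)`.
#' @param window_taper `"hann"` (default), `"hamming"` or `"boxcar"`.
#' @param bins Integer band centers in Hz (default `1:40`); each bin integrates
#'   density over `[f - 0.5, f + 0.5)` Hz.
#'
#' @details Epochs containing any masked (`NA`) sample yield a masked PSD row
#'   which propagates to masked symbols downstream, preserving time alignment
#'   rather than shortening the record.
#'
#' @return A `psd_tensor`: numeric array `[epoch, channel, bin]` with
#'   attributes `bins`, `epoch_length`, `channel_labels`, `start_time`.
#' @examples
#' fs <- 128
#' t <- seq(0, 10 - 1 / fs, by = 1 / fs)
#' eeg <- raw_eeg(rbind(sin(2 * pi * 10 * t)), fs, "C3")
#' psd <- welch_psd(eeg, window_taper = "boxcar")
#' which.max(psd[1, 1, ])  # all band power lands in the 10 Hz bin
#' @export
welch_psd <- function(raw, epoch_length = 1, segment_length = epoch_length,
                      overlap = 0.5, window_taper = "hann", bins = 1:40) {
  stopifnot(inherits(raw, "raw_eeg"))
  if (segment_length > epoch_length) {
    stop_neurodyn("segment_length must not exceed epoch_length",
                  class = "neurodyn_config_error")
  }
  fs <- raw$fs
  if (fs < 2 * max(bins)) {
    stop_neurodyn("sampling rate too low for the requested bins",
                  class = "neurodyn_config_error")
  }
  nseg <- as.integer(round(segment_length * fs))
  nepoch_samp <- as.integer(round(epoch_length * fs))
  n_epochs <- ncol(raw$samples) %/% nepoch_samp
  if (n_epochs < 1) {
    stop_neurodyn("recording shorter than one epoch", class = "neurodyn_config_error")
  }
  # frequency resolution must resolve the requested 1-Hz bands
  if (fs / nseg > 1 + 1e-9) {
    stop_neurodyn("segment too short to resolve 1-Hz bins (need >= 1 s)",
                  class = "neurodyn_config_error")
  }
  nch <- nrow(raw$samples)
  out <- array(NA_real_, dim = c(n_epochs, nch, length(bins)),
               dimnames = list(NULL, raw$channel_labels, paste0(bins, "Hz")))
  freq <- NULL
  for (e in seq_len(n_epochs)) {
    idx <- ((e - 1L) * nepoch_samp + 1L):(e * nepoch_samp)
    for (ch in seq_len(nch)) {
      x <- raw$samples[ch, idx]
      if (anyNA(x)) next                     # masked epoch row
      w <- welch_segments(x, fs, nseg, overlap, window_taper)
      if (is.null(freq)) freq <- w$freq
      df <- fs / nseg
      for (b in seq_along(bins)) {
        sel <- w$freq >= bins[b] - 0.5 & w$freq < bins[b] + 0.5
        out[e, ch, b] <- sum(w$density[sel]) * df
      }
    }
  }
  structure(out, bins = as.numeric(bins), epoch_length = epoch_length,
            channel_labels = raw$channel_labels, start_time = raw$start_time,
            class = c("psd_tensor", "array"))
}

#' @export
print.psd_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<psd_tensor> %d epoch(s) x %d channel(s) x %d bin(s), %g s cadence\n",
              d[1], d[2], d[3], attr(x, "epoch_length")))
  invisible(x)
}

#' Read / write PSD tensors as long-format delimited tables
#'
#' Long format columns: `time`, `channel`, `bin_hz`, `power` (microvolts
#' squared per bin).  Masked entries are written as empty fields and read back
#' as `NA`.
#'
#' @param psd A `psd_tensor`.
#' @param file Path to a delimited text file.
#' @param sep Field separator (default comma).
#' @return `read_psd_table()` returns a `psd_tensor`; `write_psd_table()`
#'   returns `file` invisibly.
#' @export
write_psd_table <- function(psd, file, sep = ",") {
  bins <- attr(psd, "bins")
  chs <- attr(psd, "channel_labels")
  d <- dim(psd)
  df <- expand.grid(time = seq_len(d[1]), channel = chs, bin_hz = bins,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$power <- as.vector(psd)
  utils::write.table(df, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_psd_table
#' @export
read_psd_table <- function(file, sep = ",") {
  df <- utils::read.table(file, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("time", "channel", "bin_hz", "power")
  if (!all(need %in% names(df))) {
    stop_neurodyn("PSD table needs columns time, channel, bin_hz, power",
                  class = "neurodyn_io_error")
  }
  times <- sort(unique(df$time))
  chs <- unique(df$channel)
  bins <- sort(unique(df$bin_hz))
  arr <- array(NA_real_, dim = c(length(times), length(chs), length(bins)),
               dimnames = list(NULL, chs, paste0(bins, "Hz")))
  arr[cbind(match(df$time, times), match(df$channel, chs), match(df$bin_hz, bins))] <-
    df$power
  structure(arr, bins = bins, epoch_length = if (length(times) > 1) min(diff(times)) else 1,
            channel_labels = chs, start_time = min(times) - 1,
            class = c("psd_tensor", "array"))
}

#' Read raw EEG from a delimited channels-by-samples table
#'
#' Expects one row per channel with the channel label in the first column and
#' voltage samples in the remaining columns.
#'
#' @param file Path to the table.
#' @param fs Sampling rate in Hz (not stored in the table).
#' @param sep Field separator.
#' @inheritParams raw_eeg
#' @return A [raw_eeg()] object.
#' @export
read_raw_table <- function(file, fs, sep = ",", start_time = 0, max_bin_hz = 40) {
  df <- utils::read.table(file, header = FALSE, sep = sep, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  raw_eeg(mat, fs, labels, start_time = start_time, max_bin_hz = max_bin_hz)
}
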