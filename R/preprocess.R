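# Waveform denoising and mel-spectrogram image construction.
#
# Pipeline: 4th-order low-pass Butterworth IIR (600 Hz cutoff) ->
# Hann-window STFT (n_fft 1024, hop 256, centred frames) -> 40-band mel
# projection -> dB with a -40 dB floor (matched to the recordings'
# background noise level) -> per-image min-max normalization
# -> bilinear resize to 224x224.  Row 224 (image bottom) is the lowest mel
# band; columns map linearly to time.

#' Preprocessing configuration
#'
#' @param filter_order Butterworth order.
#' @param cutoff low-pass cutoff in Hz (must be below Nyquist).
#' @param n_fft STFT window length (Hann).
#' @param hop STFT hop length in samples.
#' @param n_mels number of mel bands.
#' @param out_size output image size `c(rows, cols)`.
#' @param db_floor dynamic-range floor in dB below the per-image maximum.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(filter_order = 4, cutoff = 600,
                              n_fft = 1024, hop = 256, n_mels = 40,
                              out_size = c(224, 224), db_floor = -40) {
  stopifnot(hop <= n_fft, all(out_size >= 1), db_floor < 0)
  structure(list(filter_order = filter_order, cutoff = cutoff,
                 n_fft = n_fft, hop = hop, n_mels = n_mels,
                 out_size = out_size, db_floor = db_floor),
            class = "preprocess_config")
}

#' Low-pass Butterworth denoising
#'
#' Single-pass causal IIR filtering (order and cutoff from `config`).
#' The digital design places the half-power (-3.01 dB) point exactly at the
#' cutoff; away from the cutoff it tracks the analog magnitude
#' `|H(f)|^2 = 1 / (1 + (f/fc)^(2n))` increasingly closely as the sampling
#' rate grows relative to the cutoff.
#'
#' @param waveform numeric samples.
#' @param sampling_rate Hz; must exceed twice the cutoff.
#' @param config a [preprocess_config()].
#' @return filtered waveform, same length as the input.
#' @export
butterworth_lowpass <- function(waveform, sampling_rate,
                                config = preprocess_config()) {
  if (config$cutoff >= sampling_rate / 2) {
    stop("cutoff must be below the Nyquist frequency")
  }
  bf <- signal::butter(config$filter_order,
                       config$cutoff / (sampling_rate / 2), type = "low")
  as.numeric(signal::filter(bf, waveform))
}

# HTK mel scale
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' @param n_mels number of bands.
#' @param n_fft FFT length (filters span `n_fft/2 + 1` bins).
#' @param sampling_rate Hz.
#' @param fmin,fmax band-edge limits in Hz (`fmax` defaults to Nyquist).
#' @return list with `weights` (`n_mels` x `n_fft/2+1` matrix of unit-peak
#'   triangles) and `centers` (band centre frequencies in Hz).
#' @export
mel_filterbank <- function(n_mels, n_fft, sampling_rate, fmin = 0,
                           fmax = sampling_rate / 2) {
  n_bins <- n_fft %/% 2 + 1
  freqs <- (seq_len(n_bins) - 1) * sampling_rate / n_fft
  mpts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2)
  fpts <- mel_to_hz(mpts)
  W <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- fpts[m]; ce <- fpts[m + 1]; hi <- fpts[m + 2]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    W[m, ] <- pmax(0, pmin(up, down))
  }
  list(weights = W, centers = fpts[2:(n_mels + 1)])
}

# Power spectrogram: Hann window, centred frames (zero padding n_fft/2 at
# both ends), frame k (0-based) centred at sample k*hop.
stft_power <- function(waveform, n_fft, hop) {
  n <- length(waveform)
  pad <- n_fft %/% 2
  x <- c(numeric(pad), waveform, numeric(pad + n_fft)) # generous tail pad
  n_frames <- 1L + n %/% hop
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_fft) - 1) / n_fft)
  frames <- matrix(0, n_fft, n_frames)
  for (k in seq_len(n_frames)) {
    s <- (k - 1L) * hop + 1L
    frames[, k] <- x[s:(s + n_fft - 1L)] * win
  }
  sp <- stats::mvfft(frames)
  n_bins <- n_fft %/% 2 + 1
  abs(sp[seq_len(n_bins), , drop = FALSE])^2
}

#' Convert a waveform to a fixed-size mel-spectrogram image
#'
#' Signals shorter than one window are centre-padded with zeros.  Images
#' with zero dynamic range (e.g. an all-zero waveform) map to all-zero
#' pixels.
#'
#' @param waveform numeric samples (non-empty).
#' @param sampling_rate Hz.
#' @param config a [preprocess_config()].
#' @return object of class `mel_image`: `pixels` (rows x cols matrix in
#'   `[0,1]`, row 1 = top = highest mel band), `duration_s`, and `geometry`
#'   (the parameters needed to map seconds to pixel columns and mel bands to
#'   rows).
#' @export
mel_spectrogram <- function(waveform, sampling_rate,
                            config = preprocess_config()) {
  if (length(waveform) == 0) stop("waveform must be non-empty")
  duration <- length(waveform) / sampling_rate
  wf <- waveform
  if (length(wf) < config$n_fft) {
    deficit <- config$n_fft - length(wf)
    wf <- c(numeric(deficit %/% 2), wf, numeric(deficit - deficit %/% 2))
  }
  P <- stft_power(wf, config$n_fft, config$hop)
  fb <- mel_filterbank(config$n_mels, config$n_fft, sampling_rate)
  M <- fb$weights %*% P # n_mels x n_frames
  db <- 10 * log10(pmax(M, 1e-30))
  db <- db - max(db)
  db <- pmax(db, config$db_floor)
  rng <- range(db)
  if (diff(rng) == 0) {
    norm <- matrix(0, nrow(db), ncol(db))
  } else {
    norm <- (db - rng[1]) / diff(rng)
  }
  # flip so low frequencies sit at the bottom row of the image
  flipped <- norm[rev(seq_len(nrow(norm))), , drop = FALSE]
  px <- resize_bilinear(flipped, config$out_size[1], config$out_size[2])
  px <- clamp(px, 0, 1)
  geometry <- list(n_rows = config$out_size[1], n_cols = config$out_size[2],
                   duration_s = duration, n_mels = config$n_mels,
                   mel_centers_hz = fb$centers,
                   sampling_rate = sampling_rate,
                   n_fft = config$n_fft, hop = config$hop)
  structure(list(pixels = px, duration_s = duration, geometry = geometry),
            class = "mel_image")
}

#' @export
print.mel_image <- function(x, ...) {
  cat(sprintf("<mel_image> %dx%d, %.3f s, %d mel bands @ %g Hz\n",
              x$geometry$n_rows, x$geometry$n_cols, x$duration_s,
              x$geometry$n_mels, x$geometry$sampling_rate))
  invisible(x)
}

#' Map a time (seconds) to a 0-based pixel column
#'
#' `column = floor(t / duration * n_cols)`, clamped to `[0, n_cols - 1]`.
#'
#' @param t_s time in seconds, within `[0, duration_s]`.
#' @param geometry the `geometry` field of a [mel_spectrogram()] image.
#' @return integer 0-based column index.
#' @export
time_to_column <- function(t_s, geometry) {
  if (any(t_s < 0 | t_s > geometry$duration_s + 1e-12)) {
    stop("t_s outside [0, duration]")
  }
  col <- floor(t_s / geometry$duration_s * geometry$n_cols)
  as.integer(clamp(col, 0, geometry$n_cols - 1))
}

#' Map a 0-based pixel column back to the time of its centre
#'
#' @param col 0-based column index.
#' @param geometry the `geometry` field of a [mel_spectrogram()] image.
#' @return time in seconds of the column midpoint.
#' @export
column_to_time <- function(col, geometry) {
  (col + 0.5) / geometry$n_cols * geometry$duration_s
}

# Row range (1-based, R indexing) covering a frequency band, for optional
# band-restricted ground-truth boxes.  Row 1 is the top (highest band).
band_to_rows <- function(band_hz, geometry) {
  cen <- geometry$mel_centers_hz
  sel <- which(cen >= band_hz[1] & cen <= band_hz[2])
  if (!length(sel)) sel <- which.min(abs(cen - mean(band_hz)))
  n_mels <- geometry$n_mels
  rows_per_band <- geometry$n_rows / n_mels
  # mel band b occupies (flipped) rows [(n_mels-b)*rpb, (n_mels-b+1)*rpb)
  top_band <- max(sel); bottom_band <- min(sel)
  r0 <- floor((n_mels - top_band) * rows_per_band) + 1
  r1 <- ceiling((n_mels - bottom_band + 1) * rows_per_band)
  c(r0, min(r1, geometry$n_rows))
}

#' Export a mel image (or any `[0,1]` matrix) as an 8-bit grayscale PNG
#'
#' @param image a `mel_image` or numeric matrix in `[0,1]`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mel_png <- function(image, path) {
  px <- if (inherits(image, "mel_image")) image$pixels else image
  png::writePNG(clamp(px, 0, 1), path)
  invisible(path)
}
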