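# steady-state amplitude of a filtered sinusoid, by least squares on a
# sin/cos basis over the tail of the signal
steady_gain_db <- function(freq, fs, config = preprocess_config()) {
  t <- seq(0, 0.5, by = 1 / fs)
  x <- sin(2 * pi * freq * t)
  y <- butterworth_lowpass(x, fs, config)
  i <- seq(floor(length(t) * 0.4), length(t))
  B <- cbind(sin(2 * pi * freq * t[i]), cos(2 * pi * freq * t[i]))
  cf <- stats::coef(stats::lm(y[i] ~ B - 1))
  20 * log10(sqrt(sum(cf^2)))
}

test_that("Butterworth low-pass has the textbook frequency response", {
  fs <- 44100
  # DC: unit gain after the transient
  dc <- butterworth_lowpass(rep(1, 4000), fs)
  expect_equal(tail(dc, 1), 1, tolerance = 1e-6)
  # half-power point at the cutoff
  expect_equal(steady_gain_db(600, fs), -3.0103, tolerance = 0.1)
  # analog magnitude at one octave above: 10*log10(1/(1+2^8))
  expect_equal(steady_gain_db(1200, fs), 10 * log10(1 / 257),
               tolerance = 0.3)
  expect_error(butterworth_lowpass(rnorm(10), 1000), "Nyquist")
})

test_that("mel images are deterministic, normalized and degenerate-safe", {
  cy <- small_cycles()[[2]]
  a <- mel_spectrogram(cy$waveform, cy$sampling_rate)
  b <- mel_spectrogram(cy$waveform, cy$sampling_rate)
  expect_identical(a$pixels, b$pixels)
  expect_equal(dim(a$pixels), c(224, 224))
  expect_true(all(a$pixels >= 0 & a$pixels <= 1))
  # config echoed in geometry
  expect_equal(a$geometry$n_fft, 1024)
  expect_equal(a$geometry$hop, 256)
  expect_equal(a$geometry$n_mels, 40)
  expect_equal(c(a$geometry$n_rows, a$geometry$n_cols), c(224, 224))
  # all-zero waveform maps to an all-zero image
  z <- mel_spectrogram(numeric(2000), 4000)
  expect_true(all(z$pixels == 0))
  # shorter than one window: padded, never a crash
  s <- mel_spectrogram(rnorm(100), 4000)
  expect_equal(dim(s$pixels), c(224, 224))
  expect_error(mel_spectrogram(numeric(0), 4000), "non-empty")
})

test_that("a pure tone lights up the mel band nearest its frequency", {
  fs <- 4000
  tone <- sin(2 * pi * 200 * seq(0, 0.8, by = 1 / fs))
  img <- mel_spectrogram(tone, fs)
  fb <- mel_filterbank(40, 1024, fs)
  # mean intensity of each band's row block (image rows are flipped: band 1
  # = lowest frequency = bottom rows)
  rows_per_band <- 224 / 40
  band_mean <- vapply(seq_len(40), function(b) {
    r1 <- floor((40 - b) * rows_per_band) + 1
    r2 <- ceiling((40 - b + 1) * rows_per_band)
    mean(img$pixels[r1:r2, ])
  }, 0)
  expect_equal(which.max(band_mean), which.min(abs(fb$centers - 200)))
})

test_that("time/column maps agree with the floor convention and clamp", {
  geo <- list(n_cols = 224, n_rows = 224, duration_s = 0.8)
  expect_equal(time_to_column(0, geo), 0L)
  expect_equal(time_to_column(0.4, geo), 112L)
  expect_equal(time_to_column(0.8, geo), 223L) # clamp at the end
  expect_error(time_to_column(0.9, geo), "duration")
  # monotone in t
  ts <- seq(0, 0.8, length.out = 101)
  expect_true(all(diff(time_to_column(ts, geo)) >= 0))
  # inverse maps column midpoints back within one column width
  for (col in c(0L, 57L, 223L)) {
    t_mid <- column_to_time(col, geo)
    expect_equal(time_to_column(t_mid, geo), col)
    expect_lt(abs(t_mid - col / 224 * 0.8), 0.8 / 224)
  }
})

test_that("systolic murmur energy is localized in the systolic columns", {
  p <- cycle_params("systolic", murmur_snr_db = 15)
  cy <- generate_cycle(p, seed = 13)
  img <- mel_spectrogram(butterworth_lowpass(cy$waveform, 4000), 4000)
  rows <- heartcam:::band_to_rows(p$murmur_band, img$geometry)
  cols_of <- function(iv) {
    (time_to_column(iv[1], img$geometry) + 1):
      max(1, floor(iv[2] / img$duration_s * 224))
  }
  sys_mean <- mean(img$pixels[rows[1]:rows[2], cols_of(cy$phases$systole)])
  dia_mean <- mean(img$pixels[rows[1]:rows[2], cols_of(cy$phases$diastole)])
  expect_gt(sys_mean, dia_mean)
})

test_that("mel image exports to PNG", {
  cy <- small_cycles()[[1]]
  img <- mel_spectrogram(cy$waveform, cy$sampling_rate)
  f <- withr::local_tempfile(fileext = ".png")
  write_mel_png(img, f)
  expect_true(file.exists(f))
  expect_equal(dim(png::readPNG(f)), c(224, 224))
})
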