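test_that("cycle generation is deterministic and phase-partitioned", {
  p <- cycle_params("abnormal", murmur_snr_db = 12)
  a <- generate_cycle(p, seed = 5)
  b <- generate_cycle(p, seed = 5)
  expect_identical(a$waveform, b$waveform)
  expect_false(identical(a$waveform, generate_cycle(p, seed = 6)$waveform))

  # phases tile [0, duration) contiguously from 0
  bounds <- unlist(a$phases)
  expect_equal(a$phases$S1[1], 0)
  expect_equal(a$phases$S1[2], a$phases$systole[1])
  expect_equal(a$phases$systole[2], a$phases$S2[1])
  expect_equal(a$phases$S2[2], a$phases$diastole[1])
  expect_equal(a$phases$diastole[2],
               length(a$waveform) / a$sampling_rate, tolerance = 1e-6)
  expect_lte(max(abs(a$waveform)), 1)
})

test_that("murmur band power is calibrated to the requested SNR", {
  p <- cycle_params("systolic", murmur_snr_db = 10)
  cy <- generate_cycle(p, seed = 7)
  d_sys <- band_power_db(cy$waveform, cy$sampling_rate, cy$phases$systole,
                         p$murmur_band)
  d_dia <- band_power_db(cy$waveform, cy$sampling_rate, cy$phases$diastole,
                         p$murmur_band)
  expect_equal(d_sys - d_dia, 10, tolerance = 2)

  # normal cycles put no murmur energy anywhere: systole and diastole band
  # power agree to within 1 dB
  pn <- cycle_params("normal")
  cn <- generate_cycle(pn, seed = 7)
  n_sys <- band_power_db(cn$waveform, cn$sampling_rate, cn$phases$systole,
                         pn$murmur_band)
  n_dia <- band_power_db(cn$waveform, cn$sampling_rate, cn$phases$diastole,
                         pn$murmur_band)
  expect_lt(abs(n_sys - n_dia), 1)
})

test_that("abnormal cycles carry murmur energy in both intervals", {
  snr <- 12
  pa <- cycle_params("abnormal", murmur_snr_db = snr)
  pn <- cycle_params("normal", murmur_snr_db = snr)
  ca <- generate_cycle(pa, seed = 31)
  cn <- generate_cycle(pn, seed = 31)
  # peak normalization differs between the two cycles; compare in-cycle
  # murmur band power against the cycle's own S1-free background: the
  # abnormal cycle must exceed the matched normal cycle by >= snr - 3 dB
  # after aligning their background levels
  bg_a <- band_power_db(ca$waveform, 4000, c(0, ca$phases$S1[2]),
                        pa$murmur_band)
  bg_n <- band_power_db(cn$waveform, 4000, c(0, cn$phases$S1[2]),
                        pn$murmur_band)
  for (ph in c("systole", "diastole")) {
    pw_a <- band_power_db(ca$waveform, 4000, ca$phases[[ph]], pa$murmur_band)
    pw_n <- band_power_db(cn$waveform, 4000, cn$phases[[ph]], pn$murmur_band)
    expect_gte((pw_a - bg_a) - (pw_n - bg_n), snr - 3)
  }
})

test_that("dataset generation honours class counts and derived seeds", {
  spec <- dataset_spec(counts = c(normal = 1, systolic = 1, diastolic = 1,
                                  abnormal = 1), seed = 2)
  cycles <- generate_dataset(spec)
  expect_length(cycles, 4)
  expect_setequal(vapply(cycles, `[[`, "", "class_label"),
                  c("normal", "systolic", "diastolic", "abnormal"))
  # regenerating the dataset reproduces it exactly
  cycles2 <- generate_dataset(spec)
  expect_identical(lapply(cycles, `[[`, "waveform"),
                   lapply(cycles2, `[[`, "waveform"))
  # presets
  expect_equal(unname(balanced_spec()$counts), rep(237, 4))
  expect_equal(unname(imbalanced_spec()$counts), c(2000, 1500, 237, 1000))
  expect_error(dataset_spec(counts = c(normal = 0, systolic = 1,
                                       diastolic = 1, abnormal = 1)),
               "counts")
})

test_that("cycle WAV+JSON round trip preserves phases and waveform", {
  cy <- small_cycles()[[3]]
  wav <- withr::local_tempfile(fileext = ".wav")
  ann <- withr::local_tempfile(fileext = ".json")
  write_cycle(cy, wav, ann)
  back <- read_cycle(wav, ann)
  for (ph in names(cy$phases)) {
    expect_equal(back$phases[[ph]], unname(cy$phases[[ph]]),
                 tolerance = 1e-9)
  }
  expect_equal(back$class_label, cy$class_label)
  # 16-bit quantization bound
  expect_lte(max(abs(back$waveform - cy$waveform)), 2^-15)
  # float32 round trip is tighter
  write_cycle(cy, wav, ann, format = "float32")
  expect_lte(max(abs(read_cycle(wav, ann)$waveform - cy$waveform)), 1e-7)
})

test_that("malformed annotations are rejected", {
  cy <- small_cycles()[[1]]
  wav <- withr::local_tempfile(fileext = ".wav")
  ann <- withr::local_tempfile(fileext = ".json")
  write_cycle(cy, wav, ann)
  j <- jsonlite::read_json(ann)
  j$phases$systole <- NULL
  jsonlite::write_json(j, ann, auto_unbox = TRUE)
  expect_error(read_cycle(wav, ann), "phases")
  j2 <- jsonlite::read_json(ann)
  j2$phases$systole <- c(0.1, 0.3)
  j2$sampling_rate <- 8000
  jsonlite::write_json(j2, ann, auto_unbox = TRUE)
  expect_error(read_cycle(wav, ann), "mismatch")
  expect_error(cycle_params(murmur_band = c(100, 3000)), "murmur_band")
  expect_error(cycle_params("flutter"), "arg")
})

test_that("write_dataset produces a complete manifest", {
  dir <- withr::local_tempdir()
  man <- write_dataset(small_cycles()[1:4], dir)
  expect_equal(nrow(man), 4)
  expect_true(all(file.exists(man$path)))
  expect_true(all(file.exists(man$annotation_path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
})
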