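# Synthetic annotated single-cycle phonocardiograms.
#
# Each simulated heartbeat cycle is a mono waveform with four contiguous
# annotated phases (S1, systole, S2, diastole) and a class label driven by
# murmur timing: "normal" (no murmur), "systolic", "diastolic", or
# "abnormal" (murmur in both intervals).  S1/S2 are Gaussian-enveloped
# low-frequency transients; murmurs are band-limited Gaussian noise with a
# raised-cosine envelope confined strictly inside the labelled interval.

PCG_CLASSES <- c("normal", "systolic", "diastolic", "abnormal")
PCG_PHASES <- c("S1", "systole", "S2", "diastole")

#' Parameters of one simulated heartbeat cycle
#'
#' Defaults model low-frequency valve-closure transients (S1 about 80 Hz and
#' 90 ms, S2 about 110 Hz and 70 ms) and murmurs as 100-400 Hz band-limited
#' noise.  Phase durations default to physiological proportions of a 0.8 s
#' cycle: S1 10%, systole 30%, S2 8%, diastole 52%.
#'
#' @param class_label one of `"normal"`, `"systolic"`, `"diastolic"`,
#'   `"abnormal"`.
#' @param sampling_rate Hz.
#' @param phase_durations named numeric vector of seconds for
#'   `S1, systole, S2, diastole`; their sum is the cycle duration.
#' @param s1_freq,s2_freq centre frequency (Hz) of the S1/S2 transients.
#' @param murmur_band numeric length-2, murmur band edges in Hz (must lie
#'   inside `(0, sampling_rate/2)`).
#' @param murmur_snr_db murmur band-power above the background level, in dB,
#'   measured inside the murmur interval.
#' @param noise_floor_db background white-noise RMS in dB relative to unit
#'   amplitude.
#' @return an object of class `cycle_params`.
#' @export
cycle_params <- function(class_label = "normal",
                         sampling_rate = 4000,
                         phase_durations = c(S1 = 0.08, systole = 0.24,
                                             S2 = 0.064, diastole = 0.416),
                         s1_freq = 80, s2_freq = 110,
                         murmur_band = c(100, 400),
                         murmur_snr_db = 12,
                         noise_floor_db = -40) {
  class_label <- match.arg(class_label, PCG_CLASSES)
  if (!all(PCG_PHASES %in% names(phase_durations))) {
    stop("phase_durations must be named S1, systole, S2, diastole")
  }
  phase_durations <- phase_durations[PCG_PHASES]
  if (any(phase_durations <= 0)) stop("all phase durations must be > 0")
  if (length(murmur_band) != 2 || murmur_band[1] <= 0 ||
      murmur_band[2] <= murmur_band[1] ||
      murmur_band[2] >= sampling_rate / 2) {
    stop("murmur_band must lie within (0, sampling_rate/2)")
  }
  structure(list(class_label = class_label,
                 sampling_rate = sampling_rate,
                 phase_durations = phase_durations,
                 s1_freq = s1_freq, s2_freq = s2_freq,
                 murmur_band = murmur_band,
                 murmur_snr_db = murmur_snr_db,
                 noise_floor_db = noise_floor_db),
            class = "cycle_params")
}

gaussian_transient <- function(t, centre, width, freq) {
  env <- exp(-0.5 * ((t - centre) / (width / 6))^2)
  env * sin(2 * pi * freq * (t - centre))
}

# Raised-cosine window over [a, b) with ramps covering `frac` of the
# interval at each end; zero outside.
raised_cosine_window <- function(t, a, b, frac = 0.1) {
  w <- numeric(length(t))
  len <- b - a
  ramp <- frac * len
  inside <- t >= a & t < b
  u <- t[inside]
  v <- rep(1, length(u))
  lo <- u < a + ramp
  v[lo] <- 0.5 * (1 - cos(pi * (u[lo] - a) / ramp))
  hi <- u >= b - ramp
  v[hi] <- 0.5 * (1 - cos(pi * (b - u[hi]) / ramp))
  w[inside] <- v
  w
}

#' Generate one annotated heartbeat cycle
#'
#' Deterministic in `(params, seed)`.  The murmur amplitude is calibrated so
#' that the waveform's band power inside the murmur band during a murmur
#' interval sits `murmur_snr_db` above the background band power; for class
#' `"normal"` the murmur amplitude is exactly zero.
#'
#' @param params a [cycle_params()] object.
#' @param seed integer seed.
#' @return an object of class `annotated_cycle` with fields `waveform`,
#'   `sampling_rate`, `phases` (named list of `c(start, end)` half-open
#'   intervals in seconds, contiguous from 0) and `class_label`.
#' @export
generate_cycle <- function(params, seed = 1L) {
  stopifnot(inherits(params, "cycle_params"))
  fs <- params$sampling_rate
  d <- params$phase_durations
  bounds <- cumsum(c(0, d))
  duration <- bounds[length(bounds)]
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  phases <- stats::setNames(
    lapply(seq_along(PCG_PHASES),
           function(i) unname(c(bounds[i], bounds[i + 1]))),
    PCG_PHASES)

  sigma_n <- 10^(params$noise_floor_db / 20)
  with_seed(seed, {
    x <- stats::rnorm(n, sd = sigma_n) # background

    # S1 / S2 transients centred in their intervals
    x <- x + gaussian_transient(t, mean(phases$S1), d[["S1"]], params$s1_freq)
    x <- x + 0.8 * gaussian_transient(t, mean(phases$S2), d[["S2"]],
                                      params$s2_freq)

    murmur_in <- switch(params$class_label,
                        normal = character(0),
                        systolic = "systole",
                        diastolic = "diastole",
                        abnormal = c("systole", "diastole"))
    if (length(murmur_in)) {
      band <- params$murmur_band
      bw_fraction <- (band[2] - band[1]) / (fs / 2)
      bg_band_power <- sigma_n^2 * bw_fraction
      target_power <- bg_band_power * 10^(params$murmur_snr_db / 10)
      bf <- signal::butter(4, band / (fs / 2), type = "pass")
      for (ph in murmur_in) {
        iv <- phases[[ph]]
        raw <- stats::rnorm(n)
        bl <- as.numeric(signal::filter(bf, raw))
        # calibrate on the interval itself (steady-state portion)
        idx <- which(t >= iv[1] & t < iv[2])
        bl_rms <- sqrt(mean(bl[idx]^2))
        scale <- sqrt(target_power) / bl_rms
        x <- x + scale * bl * raised_cosine_window(t, iv[1], iv[2])
      }
    }
    peak <- max(abs(x))
    if (peak > 0) x <- x / peak
    structure(list(waveform = x, sampling_rate = fs, phases = phases,
                   class_label = params$class_label,
                   params = params, seed = as.integer(seed)),
              class = "annotated_cycle")
  })
}

#' @export
print.annotated_cycle <- function(x, ...) {
  cat(sprintf("<annotated_cycle> class=%s, %.3f s @ %g Hz\n",
              x$class_label, length(x$waveform) / x$sampling_rate,
              x$sampling_rate))
  for (ph in names(x$phases)) {
    cat(sprintf("  %-8s [%.3f, %.3f)\n", ph, x$phases[[ph]][1],
                x$phases[[ph]][2]))
  }
  invisible(x)
}

#' Specification of a synthetic dataset
#'
#' Per-cycle parameters are drawn uniformly from the stated ranges; cycle
#' duration is drawn from `duration_range` and split into phases around the
#' default proportions with `proportion_jitter` relative jitter.
#'
#' @param counts named integer vector of cycles per class
#'   (`normal, systolic, diastolic, abnormal`).
#' @param seed integer; per-cycle seeds are derived deterministically from it.
#' @param duration_range cycle duration range in seconds.
#' @param snr_range murmur SNR range in dB.
#' @param proportion_jitter relative jitter applied to the default phase
#'   proportions (0.10/0.30/0.08/0.52), renormalized to the drawn duration.
#' @param sampling_rate,murmur_band,noise_floor_db passed to [cycle_params()].
#' @return an object of class `dataset_spec`.
#' @seealso [balanced_spec()], [imbalanced_spec()] for the study presets.
#' @export
dataset_spec <- function(counts = c(normal = 10, systolic = 10,
                                    diastolic = 10, abnormal = 10),
                         seed = 1L,
                         duration_range = c(0.6, 1.0),
                         snr_range = c(6, 18),
                         proportion_jitter = 0.15,
                         sampling_rate = 4000,
                         murmur_band = c(100, 400),
                         noise_floor_db = -40) {
  if (!all(PCG_CLASSES %in% names(counts))) {
    stop("counts must be named normal, systolic, diastolic, abnormal")
  }
  counts <- counts[PCG_CLASSES]
  if (any(counts < 1)) stop("all class counts must be >= 1")
  structure(list(counts = counts, seed = as.integer(seed),
                 duration_range = duration_range, snr_range = snr_range,
                 proportion_jitter = proportion_jitter,
                 sampling_rate = sampling_rate, murmur_band = murmur_band,
                 noise_floor_db = noise_floor_db),
            class = "dataset_spec")
}

#' Balanced study preset: 237 cycles per class (948 total)
#' @param seed integer seed.
#' @param ... passed on to [dataset_spec()].
#' @export
balanced_spec <- function(seed = 1L, ...) {
  dataset_spec(counts = c(normal = 237, systolic = 237, diastolic = 237,
                          abnormal = 237), seed = seed, ...)
}

#' Imbalanced study preset: 2000/1500/237/1000 cycles
#' @param seed integer seed.
#' @param scale divide all counts by this factor (rounded, min 1) for
#'   scaled-down runs.
#' @param ... passed on to [dataset_spec()].
#' @export
imbalanced_spec <- function(seed = 1L, scale = 1, ...) {
  counts <- c(normal = 2000, systolic = 1500, diastolic = 237,
              abnormal = 1000)
  counts <- pmax(round(counts / scale), 1)
  dataset_spec(counts = counts, seed = seed, ...)
}

draw_cycle_params <- function(spec, class_label, seed) {
  with_seed(seed, {
    dur <- stats::runif(1, spec$duration_range[1], spec$duration_range[2])
    prop <- c(S1 = 0.10, systole = 0.30, S2 = 0.08, diastole = 0.52)
    jit <- stats::runif(4, 1 - spec$proportion_jitter,
                        1 + spec$proportion_jitter)
    prop <- prop * jit / sum(prop * jit)
    snr <- stats::runif(1, spec$snr_range[1], spec$snr_range[2])
    cycle_params(class_label = class_label,
                 sampling_rate = spec$sampling_rate,
                 phase_durations = prop * dur,
                 murmur_band = spec$murmur_band,
                 murmur_snr_db = snr,
                 noise_floor_db = spec$noise_floor_db)
  })
}

#' Generate a full annotated dataset
#'
#' @param spec a [dataset_spec()].
#' @return list of `annotated_cycle` objects (classes in order, exactly
#'   `spec$counts` per class); each cycle is regenerable in isolation from
#'   its derived seed.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  out <- vector("list", sum(spec$counts))
  k <- 0L
  for (cl in PCG_CLASSES) {
    for (i in seq_len(spec$counts[[cl]])) {
      s_par <- derive_seed(spec$seed, "params", cl, i)
      s_wav <- derive_seed(spec$seed, "waveform", cl, i)
      par <- draw_cycle_params(spec, cl, s_par)
      k <- k + 1L
      out[[k]] <- generate_cycle(par, s_wav)
    }
  }
  out
}

#' Write a cycle as WAV audio plus a JSON phase annotation
#'
#' The annotation schema is
#' `{"label":..., "sampling_rate":..., "phases":{"S1":[t0,t1], ...}}` with
#' half-open intervals in seconds.
#'
#' @param cycle an `annotated_cycle`.
#' @param audio_path,annotation_path output file paths.
#' @param format WAV sample format, see [write_wav()].
#' @return invisibly, a list of the two paths.
#' @export
write_cycle <- function(cycle, audio_path, annotation_path,
                        format = "pcm16") {
  stopifnot(inherits(cycle, "annotated_cycle"))
  write_wav(cycle$waveform, audio_path, cycle$sampling_rate, format = format)
  ann <- list(label = cycle$class_label,
              sampling_rate = cycle$sampling_rate,
              phases = cycle$phases)
  jsonlite::write_json(ann, annotation_path, auto_unbox = TRUE, digits = NA)
  invisible(list(audio = audio_path, annotation = annotation_path))
}

#' Read a cycle from WAV audio plus a JSON phase annotation
#'
#' @param audio_path,annotation_path files written by [write_cycle()] (or
#'   user-supplied data in the same schema).
#' @return an `annotated_cycle`.
#' @export
read_cycle <- function(audio_path, annotation_path) {
  wav <- read_wav(audio_path)
  ann <- jsonlite::read_json(annotation_path, simplifyVector = TRUE)
  if (is.null(ann$phases) || !setequal(names(ann$phases), PCG_PHASES)) {
    stop("annotation must define exactly the phases S1, systole, S2, diastole")
  }
  if (is.null(ann$label) || !(ann$label %in% PCG_CLASSES)) {
    stop("annotation label must be one of ", paste(PCG_CLASSES, collapse = ", "))
  }
  if (!is.null(ann$sampling_rate) &&
      abs(ann$sampling_rate - wav$sampling_rate) > 1e-9) {
    stop("sampling-rate mismatch between WAV and annotation")
  }
  phases <- lapply(ann$phases[PCG_PHASES], as.numeric)
  structure(list(waveform = wav$waveform, sampling_rate = wav$sampling_rate,
                 phases = phases, class_label = ann$label),
            class = "annotated_cycle")
}

#' Write a dataset to disk with a CSV manifest
#'
#' @param cycles list of `annotated_cycle`s.
#' @param dir output directory (created if missing).
#' @param split optional character vector of split names per cycle.
#' @return data.frame manifest with columns
#'   `path, annotation_path, label, split`.
#' @export
write_dataset <- function(cycles, dir, split = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(cycles)
  if (is.null(split)) split <- rep("all", n)
  man <- data.frame(path = character(n), annotation_path = character(n),
                    label = character(n), split = split,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    base <- sprintf("cycle_%04d_%s", i, cycles[[i]]$class_label)
    man$path[i] <- file.path(dir, paste0(base, ".wav"))
    man$annotation_path[i] <- file.path(dir, paste0(base, ".json"))
    man$label[i] <- cycles[[i]]$class_label
    write_cycle(cycles[[i]], man$path[i], man$annotation_path[i])
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  man
}

#' Welch band power of a waveform segment, in dB
#'
#' Diagnostic used to verify murmur calibration: average periodogram power
#' inside `band` over the samples of `interval`.
#'
#' @param waveform numeric samples.
#' @param sampling_rate Hz.
#' @param interval `c(start, end)` seconds.
#' @param band `c(low, high)` Hz.
#' @param seg_len Welch segment length (samples).
#' @return band power in dB (10*log10 of mean power in band).
#' @export
band_power_db <- function(waveform, sampling_rate, interval, band,
                          seg_len = 256) {
  n <- length(waveform)
  t <- (seq_len(n) - 1) / sampling_rate
  idx <- which(t >= interval[1] & t < interval[2])
  x <- waveform[idx]
  if (length(x) < seg_len) seg_len <- 2^floor(log2(length(x)))
  hop <- seg_len %/% 2
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  starts <- seq(1, length(x) - seg_len + 1, by = hop)
  freqs <- (seq_len(seg_len %/% 2 + 1) - 1) * sampling_rate / seg_len
  keep <- freqs >= band[1] & freqs <= band[2]
  p <- 0
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)] * win
    sp <- abs(stats::fft(seg))^2 / sum(win^2)
    p <- p + mean(sp[seq_len(seg_len %/% 2 + 1)][keep])
  }
  10 * log10(p / length(starts))
}
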