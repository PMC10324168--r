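#' Synthetic EEG generator configuration
#'
#' The stated world of the package's fixtures: 22-channel, 10-20-positioned,
#' 256 Hz EEG trials of T = 5 one-second slices, in two classes. Background
#' trials are 1/f ("pink") noise with a superimposed 10 Hz alpha rhythm.
#' Seizure trials add a high-amplitude ~3 Hz spike-and-wave discharge on a
#' focal subset of electrodes (a left fronto-temporal focus by default),
#' phase-continuous across slices -- the classic generalized spike-wave
#' morphology at the canonical absence-seizure rate, whose energy falls in
#' the delta band. Every channel of every trial is z-scored.
#'
#' @param n_per_class Trials per class.
#' @param t_slices,n_channels,samples_per_slice Trial geometry (5 x 22 x 256).
#' @param sample_rate Hz; must equal `samples_per_slice` for 1-second slices.
#' @param seed RNG seed.
#' @param seizure_freq Spike-wave repetition rate, Hz.
#' @param seizure_amp Median discharge amplitude relative to the background
#'   standard deviation. Per-trial severity is drawn from
#'   `seizure_amp * runif(amp_range)`, so weak discharges genuinely overlap
#'   the background class: victims trained on this world plateau near the
#'   low-90s accuracy regime reported for real scalp EEG rather than
#'   memorizing a separable toy task.
#' @param amp_range Lower/upper bounds of the per-trial severity multiplier.
#' @param background_exponent Spectral exponent of the 1/f^a background.
#' @param alpha_amp Amplitude of the 10 Hz background rhythm.
#' @param spatial_focus Electrode labels carrying the discharge.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_class = 100L, t_slices = 5L,
                             n_channels = 22L, samples_per_slice = 256L,
                             sample_rate = 256, seed = 1L,
                             seizure_freq = 3, seizure_amp = 1.5,
                             amp_range = c(0.2, 1.7),
                             background_exponent = 1, alpha_amp = 1,
                             spatial_focus = c("FP1", "F7", "F3", "FT9",
                                               "T7", "C3", "P7", "O1")) {
  stopifnot(sample_rate == samples_per_slice, n_per_class >= 1)
  structure(
    list(n_per_class = as.integer(n_per_class), t_slices = as.integer(t_slices),
         n_channels = as.integer(n_channels),
         samples_per_slice = as.integer(samples_per_slice),
         sample_rate = sample_rate, seed = as.integer(seed),
         seizure_freq = seizure_freq, seizure_amp = seizure_amp,
         amp_range = amp_range,
         background_exponent = background_exponent, alpha_amp = alpha_amp,
         spatial_focus = spatial_focus),
    class = "synthetic_config"
  )
}

# one channel of 1/f background + alpha rhythm, length n at fs Hz
pink_channel <- function(n, fs, exponent, alpha_amp) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))                 # avoid DC blow-up
  f <- pmin(f, n - f + 1) * fs / n
  spec <- spec * f^(-exponent / 2)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x / stats::sd(x)
  tt <- (seq_len(n) - 1) / fs
  x + alpha_amp * sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi)) *
    (0.7 + 0.3 * sin(2 * pi * 0.3 * tt + stats::runif(1, 0, 2 * pi)))
}

# spike-and-wave discharge: sharp spike + slow wave per cycle, length n
spike_wave <- function(n, fs, freq, phase) {
  tt <- (seq_len(n) - 1) / fs
  cyc <- (tt * freq + phase) %% 1
  wave <- sin(2 * pi * cyc - pi / 2)
  spike <- exp(-0.5 * ((cyc - 0.15) / 0.03)^2) * 2
  wave + spike
}

#' Generate a labeled synthetic EEG dataset
#'
#' @param config A [synthetic_config()].
#' @return List with `x` (array N x T x C x S), `y` (factor with levels
#'   `background`, `seizure`), `channels` (electrode labels) and `config`.
#'   Balanced: the first `n_per_class` samples are background, the rest
#'   seizure.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  Tn <- config$t_slices; C <- config$n_channels; S <- config$samples_per_slice
  fs <- config$sample_rate
  channels <- chbmit_channels()[seq_len(C)]
  focus <- match(toupper(config$spatial_focus), channels)
  focus <- focus[!is.na(focus)]
  N <- 2L * config$n_per_class
  n <- Tn * S
  x <- array(0, c(N, Tn, C, S))
  with_local_seed(config$seed, {
    for (i in seq_len(N)) {
      seiz <- i > config$n_per_class
      trial <- matrix(0, C, n)
      for (c in seq_len(C)) {
        trial[c, ] <- pink_channel(n, fs, config$background_exponent,
                                   config$alpha_amp)
      }
      if (seiz) {
        ph <- stats::runif(1)
        severity <- config$seizure_amp *
          stats::runif(1, config$amp_range[1], config$amp_range[2])
        for (c in focus) {
          amp <- severity * stats::runif(1, 0.8, 1.2)
          trial[c, ] <- trial[c, ] + amp * spike_wave(n, fs,
                                                      config$seizure_freq, ph)
        }
      }
      trial <- (trial - rowMeans(trial)) /
        apply(trial, 1, stats::sd)            # per-channel z-score
      x[i, , , ] <- aperm(array(t(trial), c(S, Tn, C)), c(2, 3, 1))
    }
  })
  y <- factor(rep(c("background", "seizure"), each = config$n_per_class),
              levels = c("background", "seizure"))
  list(x = x, y = y, channels = channels, config = config)
}

#' Segment a continuous recording into labeled trials
#'
#' Cuts 5-second windows from a continuous multichannel recording: inside
#' seizure intervals windows start every 3 s (consecutive windows share 2 s);
#' outside them windows start every 5 s (non-overlapping). Non-seizure
#' windows are then subsampled to the seizure count so the classes balance.
#'
#' @param recording C x n numeric matrix at `sample_rate` Hz.
#' @param seizure_intervals Two-column matrix (or list of length-2 vectors)
#'   of seizure start/end times in seconds.
#' @param window_s Window length in seconds.
#' @param sample_rate Hz (must be 256 for the downstream pipeline).
#' @param max_abs Amplitude rejection threshold: windows with any sample
#'   beyond it are dropped as bad data.
#' @param flat_sd Flatline rejection: windows with any channel whose standard
#'   deviation falls below it are dropped.
#' @param seed Seed for the balancing subsample.
#' @return As [generate_dataset()]: `x` (N x T x C x S), `y`, plus the kept
#'   window start times.
#' @export
segment_recording <- function(recording, seizure_intervals, window_s = 5,
                              sample_rate = 256, max_abs = Inf,
                              flat_sd = 1e-12, seed = 1L) {
  C <- nrow(recording); n <- ncol(recording)
  dur <- n / sample_rate
  if (dur < window_s) stop("recording shorter than one window")
  if (is.list(seizure_intervals)) {
    seizure_intervals <- do.call(rbind, seizure_intervals)
  }
  if (is.null(seizure_intervals)) seizure_intervals <- matrix(0, 0, 2)
  seiz_starts <- numeric(0)
  for (k in seq_len(nrow(seizure_intervals))) {
    a <- seizure_intervals[k, 1]; b <- seizure_intervals[k, 2]
    if (b - a >= window_s) {
      seiz_starts <- c(seiz_starts, seq(a, b - window_s, by = window_s - 2))
    }
  }
  in_seizure <- function(s) {
    nrow(seizure_intervals) > 0 &&
      any(s < seizure_intervals[, 2] & (s + window_s) > seizure_intervals[, 1])
  }
  bg_starts <- seq(0, dur - window_s, by = window_s)
  bg_starts <- bg_starts[!vapply(bg_starts, in_seizure, logical(1))]
  cut_window <- function(s) {
    i0 <- round(s * sample_rate)
    recording[, (i0 + 1):(i0 + window_s * sample_rate), drop = FALSE]
  }
  ok_window <- function(w) {
    all(is.finite(w)) && max(abs(w)) <= max_abs &&
      all(apply(w, 1, stats::sd) > flat_sd)
  }
  seiz_w <- Filter(ok_window, lapply(seiz_starts, cut_window))
  bg_w <- Filter(ok_window, lapply(bg_starts, cut_window))
  keep_seiz <- seiz_starts[seq_along(seiz_w)]
  n_keep <- min(length(seiz_w), length(bg_w))
  bg_pick <- if (length(seiz_w) > 0 && length(bg_w) > n_keep) {
    with_local_seed(seed, sort(sample(seq_along(bg_w), n_keep)))
  } else seq_along(bg_w)
  seiz_pick <- seq_len(if (length(bg_w) > 0) n_keep else length(seiz_w))
  windows <- c(bg_w[bg_pick], seiz_w[seiz_pick])
  keep_seiz <- keep_seiz[seiz_pick]
  labels <- c(rep("background", length(bg_pick)), rep("seizure", length(seiz_pick)))
  Tn <- as.integer(window_s); S <- as.integer(sample_rate)
  N <- length(windows)
  x <- array(0, c(N, Tn, C, S))
  for (i in seq_len(N)) {
    x[i, , , ] <- aperm(array(t(windows[[i]]), c(S, Tn, C)), c(2, 3, 1))
  }
  list(x = x, y = factor(labels, levels = c("background", "seizure")),
       starts = c(bg_starts[bg_pick], keep_seiz))
}

#' Read a (plain) EDF recording
#'
#' Minimal reader for European Data Format files: fixed-layout ASCII header
#' plus little-endian int16 data records, rescaled to physical units. The
#' sampling rate must be 256 Hz, and channels are reordered according to a
#' channel-to-electrode mapping (the shipped CHB-MIT default, or any
#' two-column `chbmit`/`electrode` table).
#'
#' @param path EDF file path.
#' @param montage_mapping `NULL` for the shipped default, a data frame, or
#'   the path of a TSV with columns `chbmit`, `electrode`.
#' @return List with `data` (C x n matrix, rows named by electrode), `fs`,
#'   `labels` (electrode labels), `n_records`, `duration` (seconds).
#' @export
read_edf <- function(path, montage_mapping = NULL) {
  mapping <- default_mapping(montage_mapping)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(rawToChar(readBin(con, "raw", nc)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                     # header length
  rd(44)
  ndr <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")   # transducer
  vapply(seq_len(ns), function(i) rd(8), "")    # unit
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")   # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  fs <- spr / dur
  if (any(fs != 256)) {
    stop("format error: sampling rate ", paste(unique(fs), collapse = "/"),
         " Hz, expected 256 Hz")
  }
  data <- matrix(0, ns, ndr * spr[1])
  for (r in seq_len(ndr)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      phys <- (raw - dmin_[s]) * (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s]) +
        pmin_[s]
      data[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <- phys
    }
  }
  labels_norm <- toupper(gsub("\\s+", "", labels))
  want <- toupper(gsub("\\s+", "", mapping$chbmit))
  idx <- match(want, labels_norm)
  if (anyNA(idx)) {
    stop("mapping error: channel(s) not present in file: ",
         paste(mapping$chbmit[is.na(idx)], collapse = ", "))
  }
  out <- data[idx, , drop = FALSE]
  rownames(out) <- mapping$electrode
  list(data = out, fs = 256, labels = mapping$electrode, n_records = ndr,
       duration = ndr * dur)
}

default_mapping <- function(montage_mapping) {
  if (is.null(montage_mapping)) {
    montage_mapping <- system.file("extdata", "chbmit_1020_mapping.tsv",
                                   package = "beamattack")
  }
  if (is.character(montage_mapping)) {
    montage_mapping <- utils::read.table(montage_mapping, sep = "\t",
                                         header = TRUE,
                                         stringsAsFactors = FALSE,
                                         comment.char = "#")
  }
  stopifnot(all(c("chbmit", "electrode") %in% names(montage_mapping)))
  montage_mapping
}
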