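#' Decompose an EEG sample into rhythms, spectra and powers
#'
#' Runs the full per-slice, per-electrode transform chain on a T x C x S
#' sample: level-8 Haar wavelet-packet decomposition, band filtering into the
#' four rhythms, time-domain rhythm reconstruction, forward DFT, and
#' mean-absolute rhythm power. This is the EEG-side half of the BEAM
#' pipeline.
#'
#' @param sample Numeric array T x C x S (time slices x electrodes x samples
#'   per slice).
#' @param sample_rate Sampling rate in Hz (S samples = 1 second at 256 Hz).
#' @param level WPT depth.
#' @param bands Band table, see [rhythm_bands()].
#' @return List with elements
#'   \describe{
#'     \item{coeffs}{T x C x S array of frequency-ordered WPT leaves.}
#'     \item{rhythms}{T x B x C x S array of time-domain rhythms.}
#'     \item{freq}{complex T x B x C x S array of rhythm spectra.}
#'     \item{power}{T x B x C rhythm power array, all entries >= 0.}
#'     \item{bands, sample_rate, level}{echoed configuration.}
#'   }
#' @export
decompose_sample <- function(sample, sample_rate = 256, level = 8L,
                             bands = rhythm_bands()) {
  d <- dim(sample)
  if (length(d) != 3L) stop("shape mismatch: sample must be a T x C x S array")
  Tn <- d[1]; C <- d[2]; S <- d[3]
  B <- nrow(bands)
  W <- wpt_matrix(S, level)
  # slices as columns: S x (T*C); column index = (slice, electrode) pair
  flat <- matrix(aperm(sample, c(3, 1, 2)), nrow = S)
  leaves <- W %*% flat
  coeffs <- aperm(array(leaves, c(S, Tn, C)), c(2, 3, 1))
  rhythms <- array(0, c(Tn, B, C, S))
  freq <- array(complex(real = 0), c(Tn, B, C, S))
  power <- array(0, c(Tn, B, C))
  for (b in seq_len(B)) {
    keep <- band_leaf_indices(bands$band[b], sample_rate, level, bands)
    lb <- matrix(0, S, Tn * C)
    lb[keep, ] <- leaves[keep, , drop = FALSE]
    rb <- crossprod(W, lb)                        # inverse WPT, all slices at once
    fb <- stats::mvfft(rb)
    rhythms[, b, , ] <- aperm(array(rb, c(S, Tn, C)), c(2, 3, 1))
    freq[, b, , ] <- aperm(array(fb, c(S, Tn, C)), c(2, 3, 1))
    power[, b, ] <- matrix(colMeans(Mod(fb)), Tn, C)
  }
  dimnames(power) <- list(NULL, bands$band, NULL)
  list(coeffs = coeffs, rhythms = rhythms, freq = freq, power = power,
       bands = bands, sample_rate = sample_rate, level = as.integer(level))
}

#' Rebuild one slice with replaced rhythm coefficients
#'
#' Splices externally supplied per-band wavelet-packet leaves into the
#' decomposition of `original`: leaves inside each band's index set are taken
#' from `band_coeffs`, leaves outside every band (DC and > 30 Hz) survive
#' from the original, then the slice is reconstructed by the inverse WPT.
#'
#' @param original Numeric vector, the raw slice.
#' @param band_coeffs Named list (one entry per band) of `wpt_coefficients`
#'   or plain numeric leaf vectors in frequency order.
#' @param sample_rate Sampling rate in Hz.
#' @param level WPT depth.
#' @param bands Band table.
#' @return Numeric vector, same length as `original`.
#' @export
reconstruct_slice <- function(original, band_coeffs, sample_rate = 256,
                              level = 8L, bands = rhythm_bands()) {
  co <- wpt_decompose(original, level = level)
  for (b in bands$band) {
    if (is.null(band_coeffs[[b]])) stop("band_coeffs is missing band: ", b)
    idx <- band_leaf_indices(b, sample_rate, level, bands)
    repl <- band_coeffs[[b]]
    leaves <- if (inherits(repl, "wpt_coefficients")) as.numeric(repl$leaves) else as.numeric(repl)
    co$leaves[, idx] <- leaves[idx]
  }
  wpt_reconstruct(co)
}
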