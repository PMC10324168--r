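#' Rhythm band table
#'
#' The four canonical EEG rhythms as half-open frequency intervals in Hz:
#' delta (0.5-4), theta (4-8), alpha (8-13), beta (13-30). The 0-0.5 Hz DC
#' leaf belongs to no band.
#'
#' @return A tibble with columns `band`, `f_lo`, `f_hi`.
#' @export
rhythm_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta"),
    f_lo = c(0.5, 4, 8, 13),
    f_hi = c(4, 8, 13, 30)
  )
}

gray_code <- function(k) bitwXor(k, k %/% 2L)

#' Full wavelet-packet decomposition (orthonormal Haar)
#'
#' Decomposes a signal of length S into the 2^level leaves of the full
#' wavelet-packet tree with the db1 (Haar) filter pair in the orthonormal
#' convention, so that energy is conserved exactly. Leaves are returned in
#' frequency (sequency) order: leaf k nominally covers
#' \[k fs / 2^(level+1), (k+1) fs / 2^(level+1)) Hz. The tree's natural
#' (filter-bank) order is mapped to frequency order by the binary-reflected
#' Gray code, which accounts for the spectral folding in every highpass
#' branch.
#'
#' @param signal Numeric vector, length divisible by 2^level.
#' @param wavelet Wavelet identifier; only "db1" is implemented.
#' @param level Decomposition depth; 8 for 1-second 256-sample slices.
#' @return Object of class `wpt_coefficients`: list with `leaves` (leaf_len x
#'   2^level matrix, columns in frequency order), `wavelet`, `level`, `S`.
#' @export
wpt_decompose <- function(signal, wavelet = "db1", level = 8L) {
  if (!identical(wavelet, "db1")) stop("only the db1 (Haar) wavelet is supported")
  S <- length(signal)
  n_leaves <- 2L^level
  if (S %% n_leaves != 0L) {
    stop("shape error: signal length ", S, " not divisible by 2^level = ", n_leaves)
  }
  x <- matrix(as.numeric(signal), ncol = 1L)
  s2 <- sqrt(2)
  for (l in seq_len(level)) {
    len <- nrow(x)
    odd <- x[seq(1L, len, 2L), , drop = FALSE]
    even <- x[seq(2L, len, 2L), , drop = FALSE]
    a <- (odd + even) / s2
    d <- (odd - even) / s2
    # interleave children: block j -> (approx_j, detail_j), natural order
    nb <- ncol(x)
    nxt <- matrix(0, nrow = len / 2L, ncol = 2L * nb)
    nxt[, seq(1L, 2L * nb, 2L)] <- a
    nxt[, seq(2L, 2L * nb, 2L)] <- d
    x <- nxt
  }
  perm <- gray_code(seq_len(n_leaves) - 1L) + 1L   # freq position -> natural index
  structure(
    list(leaves = x[, perm, drop = FALSE], wavelet = wavelet,
         level = as.integer(level), S = S),
    class = "wpt_coefficients"
  )
}

#' Inverse full wavelet-packet transform
#'
#' Exact inverse of [wpt_decompose()] (the Haar filter bank is orthonormal).
#'
#' @param coeffs A `wpt_coefficients` object.
#' @return Numeric vector of length `coeffs$S`.
#' @export
wpt_reconstruct <- function(coeffs) {
  stopifnot(inherits(coeffs, "wpt_coefficients"))
  n_leaves <- 2L^coeffs$level
  perm <- gray_code(seq_len(n_leaves) - 1L) + 1L
  x <- matrix(0, nrow = nrow(coeffs$leaves), ncol = n_leaves)
  x[, perm] <- coeffs$leaves                       # back to natural order
  s2 <- sqrt(2)
  for (l in seq_len(coeffs$level)) {
    nb <- ncol(x) / 2L
    a <- x[, seq(1L, 2L * nb, 2L), drop = FALSE]
    d <- x[, seq(2L, 2L * nb, 2L), drop = FALSE]
    len <- 2L * nrow(x)
    nxt <- matrix(0, nrow = len, ncol = nb)
    nxt[seq(1L, len, 2L), ] <- (a + d) / s2
    nxt[seq(2L, len, 2L), ] <- (a - d) / s2
    x <- nxt
  }
  as.numeric(x)
}

# Cached S x S orthogonal matrix of the level-8 Haar packet transform in
# frequency order; lets whole T x C slice stacks be transformed with one GEMM.
.wpt_cache <- new.env(parent = emptyenv())

wpt_matrix <- function(S = 256L, level = 8L) {
  key <- paste0("W_", S, "_", level)
  if (!is.null(.wpt_cache[[key]])) return(.wpt_cache[[key]])
  W <- vapply(seq_len(S), function(i) {
    e <- numeric(S); e[i] <- 1
    as.numeric(wpt_decompose(e, level = level)$leaves)
  }, numeric(S))
  .wpt_cache[[key]] <- W
  W
}

#' Leaf indices covering a rhythm band
#'
#' Returns the (1-based, frequency-ordered) wavelet-packet leaf indices whose
#' nominal frequency interval \[k fs / 2^(level+1), (k+1) fs / 2^(level+1))
#' intersects the half-open band \[f_lo, f_hi).
#'
#' @param band Band name present in `bands`.
#' @param sample_rate Sampling rate in Hz.
#' @param level WPT depth.
#' @param bands Band table, see [rhythm_bands()].
#' @return Integer vector of leaf indices.
#' @export
band_leaf_indices <- function(band, sample_rate = 256, level = 8L,
                              bands = rhythm_bands()) {
  row <- bands[bands$band == band, ]
  if (nrow(row) != 1L) stop("unknown band name: ", band)
  n_leaves <- 2L^level
  bw <- sample_rate / 2 / n_leaves
  k <- seq_len(n_leaves) - 1L
  lo <- k * bw; hi <- (k + 1L) * bw
  which(pmax(lo, row$f_lo) < pmin(hi, row$f_hi))
}

#' Zero all leaves outside a rhythm band
#'
#' @param coeffs A `wpt_coefficients` object.
#' @param band Band name.
#' @param sample_rate Sampling rate in Hz.
#' @param bands Band table.
#' @return A `wpt_coefficients` object with out-of-band leaves zeroed
#'   (idempotent).
#' @export
filter_band <- function(coeffs, band, sample_rate = 256,
                        bands = rhythm_bands()) {
  stopifnot(inherits(coeffs, "wpt_coefficients"))
  keep <- band_leaf_indices(band, sample_rate, coeffs$level, bands)
  out <- coeffs
  drop <- setdiff(seq_len(ncol(out$leaves)), keep)
  out$leaves[, drop] <- 0
  out
}

#' Extract a time-domain rhythm from one slice
#'
#' WPT-filters the slice to the requested band and inverts: the band-limited
#' time series carrying that rhythm. Summing the four rhythms plus the
#' out-of-band remainder reproduces the slice (the leaves partition).
#'
#' @param slice Numeric vector (one 1-second slice of one electrode).
#' @param band Band name.
#' @param sample_rate Sampling rate in Hz.
#' @param level WPT depth.
#' @param bands Band table.
#' @return Numeric vector, same length as `slice`.
#' @export
extract_time_rhythm <- function(slice, band, sample_rate = 256, level = 8L,
                                bands = rhythm_bands()) {
  wpt_reconstruct(filter_band(wpt_decompose(slice, level = level), band,
                              sample_rate, bands))
}

#' Forward DFT of a rhythm
#'
#' Standard unnormalized forward discrete Fourier transform (the package-wide
#' convention; the inverse is 1/S-scaled).
#'
#' @param rhythm Numeric (or complex) vector.
#' @return Complex vector of the same length.
#' @export
fft_rhythm <- function(rhythm) stats::fft(rhythm)

ifft <- function(spectrum) stats::fft(spectrum, inverse = TRUE) / length(spectrum)

#' Mean-absolute spectral power of a rhythm
#'
#' Power of a rhythm = the mean of the absolute values of its spectrum,
#' (1/S) * sum_i |F(i)|.
#'
#' @param spectrum Complex vector.
#' @return Non-negative scalar.
#' @export
rhythm_power <- function(spectrum) {
  if (length(spectrum) < 1L) stop("empty spectrum")
  mean(Mod(spectrum))
}
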