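test_that("level-8 Haar decomposition has the closed-form constants", {
  # all-ones slice: only the approximation leaf survives, scaled by 2^(L/2)
  co <- wpt_decompose(rep(1, 256), level = 8)
  leaves <- as.numeric(co$leaves)
  expect_equal(leaves[1], 16)
  expect_equal(leaves[-1], rep(0, 255))
  # zero signal
  expect_equal(as.numeric(wpt_decompose(numeric(256))$leaves), rep(0, 256))
})

test_that("the transform is orthonormal and exactly invertible", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(256)
    co <- wpt_decompose(x)
    # Parseval
    expect_equal(sum(co$leaves^2), sum(x^2), tolerance = 1e-8)
    # perfect reconstruction
    expect_lt(max(abs(wpt_reconstruct(co) - x)), 1e-10)
  }
  expect_error(wpt_decompose(rnorm(100), level = 8), "shape error")
  expect_error(wpt_decompose(rnorm(256), wavelet = "db4"), "db1")
})

test_that("frequency-ordered leaves match the sequency Walsh-Hadamard oracle", {
  # independent derivation: the depth-L Haar packet at leaf length 1 is the
  # Walsh-Hadamard transform; sequency order = bit-reversal of the Gray code
  L <- 6L; S <- 2L^L
  H <- matrix(1, 1, 1)
  for (i in seq_len(L)) H <- rbind(cbind(H, H), cbind(H, -H))
  revbits <- function(k, n) {
    b <- as.integer(intToBits(k))[1:n]
    sum(b * 2^((n - 1):0))
  }
  grayenc <- function(k) bitwXor(k, bitwShiftR(k, 1))
  perm <- vapply(0:(S - 1), function(k) revbits(grayenc(k), L), 1) + 1
  Wal <- H[perm, ] / 2^(L / 2)
  set.seed(4)
  x <- rnorm(S)
  expect_equal(as.numeric(wpt_decompose(x, level = L)$leaves),
               as.numeric(Wal %*% x), tolerance = 1e-12)
  # sequency sanity: analysis functions have 0, 1, 2, ... sign changes
  basis <- diag(S)
  leaves <- vapply(seq_len(S), function(i)
    as.numeric(wpt_decompose(basis[, i], level = L)$leaves), numeric(S))
  changes <- apply(leaves, 1, function(r) sum(diff(sign(r)) != 0))
  expect_equal(changes, 0:(S - 1))
})

test_that("band leaf indices map the rhythm boundaries at 0.5 Hz per leaf", {
  # delta 0.5-4 Hz -> leaves 2..8 (1-based; the DC leaf belongs to no band)
  expect_equal(band_leaf_indices("delta"), 2:8)
  expect_equal(band_leaf_indices("theta"), 9:16)
  expect_equal(band_leaf_indices("alpha"), 17:26)
  expect_equal(band_leaf_indices("beta"), 27:60)
  expect_error(band_leaf_indices("gamma"), "unknown band")
  # pairwise disjoint
  idx <- lapply(rhythm_bands()$band, band_leaf_indices)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_length(intersect(idx[[i]], idx[[j]]), 0)
  }
})

test_that("band filtering is idempotent and partitions the leaves", {
  set.seed(5)
  x <- rnorm(256)
  co <- wpt_decompose(x)
  bands <- rhythm_bands()$band
  f1 <- filter_band(co, "alpha")
  expect_equal(filter_band(f1, "alpha"), f1)
  expect_equal(as.numeric(filter_band(wpt_decompose(numeric(256)),
                                      "delta")$leaves),
               rep(0, 256))
  # the four band rhythms plus the out-of-band remainder reproduce the slice
  rhythms <- vapply(bands, function(b) extract_time_rhythm(x, b), numeric(256))
  inband <- sort(unlist(lapply(bands, band_leaf_indices)))
  rem <- co
  rem$leaves[, inband] <- 0
  total <- rowSums(rhythms) + wpt_reconstruct(rem)
  expect_lt(max(abs(total - x)), 1e-8)
})

test_that("extracted rhythms are dominated by the matching band", {
  # Haar packets leak (the transform is the Walsh transform, best-case
  # concentration 8/pi^2), so the honest check is dominance, not purity
  fs <- 256
  tt <- (0:255) / fs
  cases <- list(c(2, "delta"), c(6, "theta"), c(10, "alpha"), c(20, "beta"))
  for (cs in cases) {
    f <- as.numeric(cs[1]); band <- cs[2]
    x <- sin(2 * pi * f * tt)
    energies <- vapply(rhythm_bands()$band, function(b)
      sum(extract_time_rhythm(x, b)^2), 1)
    expect_equal(names(which.max(energies)), band)
    expect_gt(energies[band] / sum(x^2), 0.4)
  }
  expect_equal(extract_time_rhythm(numeric(256), "alpha"), numeric(256))
})

test_that("rhythm power is the mean absolute spectrum value", {
  expect_equal(rhythm_power(complex(real = numeric(16))), 0)
  expect_equal(rhythm_power(complex(modulus = rep(2, 10),
                                    argument = runif(10))), 2)
  # on-bin unit sinusoid: two bins of magnitude S/2 -> power 1
  x <- sin(2 * pi * 10 * (0:255) / 256)
  expect_equal(rhythm_power(fft_rhythm(x)), 1, tolerance = 1e-10)
  expect_error(rhythm_power(complex(0)), "empty")
  # 1-Lipschitz in the mean-absolute metric
  set.seed(6)
  a <- complex(real = rnorm(64), imaginary = rnorm(64))
  b <- complex(real = rnorm(64), imaginary = rnorm(64))
  expect_lte(abs(rhythm_power(a) - rhythm_power(b)), mean(Mod(a - b)) + 1e-12)
})

test_that("fft_rhythm follows the unnormalized forward convention", {
  expect_equal(fft_rhythm(numeric(8)), complex(real = numeric(8)))
  f <- fft_rhythm(rep(3, 8))
  expect_equal(Mod(f[1]), 24)
  expect_lt(max(Mod(f[-1])), 1e-12)
  set.seed(7)
  x <- rnorm(64)
  expect_lt(max(abs(Re(fft(fft_rhythm(x), inverse = TRUE)) / 64 - x)), 1e-10)
})

test_that("reconstruct_slice splices exactly the in-band leaves", {
  set.seed(8)
  x <- rnorm(256)
  bands <- rhythm_bands()$band
  own <- lapply(bands, function(b) filter_band(wpt_decompose(x), b))
  names(own) <- bands
  # identity replacement
  expect_lt(max(abs(reconstruct_slice(x, own) - x)), 1e-6)
  # all-zero band coefficients: original minus its four rhythms
  zeros <- lapply(bands, function(b) numeric(256))
  names(zeros) <- bands
  rhysum <- rowSums(vapply(bands, function(b) extract_time_rhythm(x, b),
                           numeric(256)))
  expect_lt(max(abs(reconstruct_slice(x, zeros) - (x - rhysum))), 1e-8)
  # replacement touches only in-band leaves
  set.seed(9)
  rnd <- lapply(bands, function(b) rnorm(256))
  names(rnd) <- bands
  out <- wpt_decompose(reconstruct_slice(x, rnd))
  orig <- wpt_decompose(x)
  outside <- setdiff(1:256, unlist(lapply(bands, band_leaf_indices)))
  expect_equal(out$leaves[, outside], orig$leaves[, outside],
               tolerance = 1e-10)
  expect_error(reconstruct_slice(x, rnd[1:3]), "missing band")
})

test_that("decompose_sample produces shape-consistent products", {
  set.seed(10)
  x <- array(rnorm(2 * 3 * 256), c(2, 3, 256))
  d <- decompose_sample(x)
  expect_equal(dim(d$power), c(2, 4, 3))
  expect_equal(dim(d$rhythms), c(2, 4, 3, 256))
  expect_equal(dim(d$freq), c(2, 4, 3, 256))
  expect_true(all(d$power >= 0))
  # agreement with the per-slice scalar path
  p11 <- rhythm_power(fft_rhythm(extract_time_rhythm(x[1, 2, ], "alpha")))
  expect_equal(d$power[1, "alpha", 2], p11, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(decompose_sample(array(0, c(2, 3, 256)))$power,
               array(0, c(2, 4, 3)), ignore_attr = TRUE)
  expect_error(decompose_sample(matrix(0, 3, 256)), "shape")
})
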