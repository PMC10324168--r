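# Thin-plate spline machinery.
#
# The topographic interpolant is the 2-D thin-plate spline, the minimizer of
# the bending energy integral among all interpolants -- i.e. literally the
# "smoothness and minimum curvature" criterion quoted for cubic spline
# interpolation of scalp maps. It is exact at the nodes, reproduces constants
# and planes exactly, and is *linear* in the data, so both directions of the
# electrode <-> grid mapping collapse to precomputed matrices.

tps_kernel <- function(r2) {
  # U(r) = r^2 log r, with U(0) = 0; r2 is squared distance
  out <- ifelse(r2 > 0, 0.5 * r2 * log(r2), 0)
  out
}

cross_dist2 <- function(a, b) {
  # squared euclidean distances, rows of a x rows of b
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
}

# m x n linear operator: data at src points -> TPS interpolant at dst points
tps_operator <- function(src, dst) {
  n <- nrow(src)
  K <- tps_kernel(pmax(cross_dist2(src, src), 0))
  P <- cbind(1, src)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  B <- cbind(tps_kernel(pmax(cross_dist2(dst, src), 0)), 1, dst)
  sol <- tryCatch(solve(A), error = function(e) {
    stop("invalid-geometry: degenerate node configuration for interpolation")
  })
  B %*% sol[, seq_len(n), drop = FALSE]
}

beam_operators <- function(montage, grid, method = "consistent") {
  key <- paste0("ops_", method, "_",
                paste(signif(as.numeric(montage$coords2d), 12), collapse = ","))
  if (!is.null(grid$cache[[key]])) return(grid$cache[[key]])
  elec <- unname(montage$coords2d)
  fwd <- tps_operator(elec, grid$centers)          # HW x C
  back <- switch(method,
    consistent = {
      # exact left inverse of fwd: the electrode values whose topographic map
      # best matches (and, for maps built by build_beams, exactly matches)
      # the given grid image
      qr.solve(qr(fwd), diag(nrow(grid$centers)))
    },
    tps = tps_operator(grid$centers, elec),        # C x HW
    stop("unknown sampling method: ", method)
  )
  ops <- list(fwd = fwd, back = back)
  grid$cache[[key]] <- ops
  ops
}

#' Interpolate one topographic power map
#'
#' Evaluates the minimum-curvature (thin-plate spline) interpolant of the C
#' electrode powers at every grid cell centre. Exact at electrode locations.
#'
#' @param powers Numeric vector of length C.
#' @param montage A `beam_montage`.
#' @param grid A `beam_grid` from [build_grid()].
#' @return H x W numeric matrix.
#' @export
interpolate_beam <- function(powers, montage, grid) {
  stopifnot(length(powers) == length(montage$names))
  ops <- beam_operators(montage, grid)
  matrix(ops$fwd %*% as.numeric(powers), grid$H, grid$W)
}

#' Build the BEAM tensor from a rhythm power array
#'
#' Interpolates every (time slice, rhythm) power vector onto the topographic
#' grid, giving the T x B x H x W brain electrical activity mapping tensor
#' that the BEAM-related victim models consume.
#'
#' @param P Numeric array T x B x C (rhythm power array).
#' @param montage A `beam_montage`.
#' @param grid A `beam_grid`.
#' @return Object of class `beam_tensor`: list with `values` (T x B x H x W)
#'   and `grid`.
#' @export
build_beams <- function(P, montage, grid) {
  d <- dim(P)
  if (length(d) != 3L || d[3] != length(montage$names)) {
    stop("shape mismatch: P must be T x B x C with C matching the montage")
  }
  ops <- beam_operators(montage, grid)
  Pm <- matrix(aperm(P, c(3, 1, 2)), nrow = d[3])          # C x (T*B)
  V <- ops$fwd %*% Pm                                      # HW x (T*B)
  vals <- aperm(array(V, c(grid$H, grid$W, d[1], d[2])), c(3, 4, 1, 2))
  structure(list(values = vals, grid = grid), class = "beam_tensor")
}

#' @export
print.beam_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("<beam_tensor> ", paste(d, collapse = " x "),
      " (T x B x H x W)\n", sep = "")
  invisible(x)
}

#' Sample a BEAM-space perturbation back to the electrodes
#'
#' Converts a perturbation image stack on the topographic grid into a
#' perturbation on the rhythm power array by resampling each H x W image at
#' the 2-D electrode locations.
#'
#' Two resampling schemes are provided. `"consistent"` (default) applies the
#' exact linear left-inverse of the electrodes-to-grid interpolation
#' operator, so the round trip powers -> map -> powers is exact to machine
#' precision; for images that are not exact topographic maps it returns the
#' electrode values whose map is closest in least squares. `"tps"` is the
#' literal reading: an independent thin-plate interpolation of the grid
#' values evaluated at the electrodes.
#'
#' @param eta_beam A `beam_tensor` (or plain T x B x H x W array).
#' @param montage A `beam_montage`.
#' @param grid A `beam_grid`; must match `eta_beam`.
#' @param method `"consistent"` or `"tps"`.
#' @return Numeric array T x B x C.
#' @export
sample_perturbation <- function(eta_beam, montage, grid,
                                method = c("consistent", "tps")) {
  method <- match.arg(method)
  vals <- if (inherits(eta_beam, "beam_tensor")) eta_beam$values else eta_beam
  d <- dim(vals)
  if (length(d) != 4L || d[3] != grid$H || d[4] != grid$W) {
    stop("geometry error: eta_beam does not match the grid (", grid$H, " x ",
         grid$W, ")")
  }
  xy <- montage$coords2d
  b <- grid$bounds
  out_of_bounds <- xy[, 1] < b["xmin"] - 1e-12 | xy[, 1] > b["xmax"] + 1e-12 |
    xy[, 2] < b["ymin"] - 1e-12 | xy[, 2] > b["ymax"] + 1e-12
  if (any(out_of_bounds)) {
    stop("geometry error: electrode(s) outside grid bounds: ",
         paste(montage$names[out_of_bounds], collapse = ", "))
  }
  ops <- beam_operators(montage, grid, method)
  Vm <- matrix(aperm(vals, c(3, 4, 1, 2)), nrow = grid$H * grid$W)  # HW x (T*B)
  E <- ops$back %*% Vm                                              # C x (T*B)
  aperm(array(E, c(nrow(xy), d[1], d[2])), c(2, 3, 1))
}
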