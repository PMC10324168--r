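#' Spherical 10-20 electrode positions
#'
#' Builds the 3-D positions of standard 10-20 (and a few 10-10) scalp
#' electrodes on a spherical head model of radius `radius` metres. Positions
#' follow the textbook construction: the vertex electrode Cz sits at the top
#' of the sphere, midline and rim electrodes are placed at 20% arcs
#' (36 degrees) along the nasion-inion and circumferential lines, and the
#' lateral parasagittal electrodes (F3/F4, P3/P4) are spherical midpoints of
#' their midline and rim neighbours, which is how they are defined on a real
#' head.
#'
#' Coordinate convention: +x towards the right ear, +y towards the nasion,
#' +z up; all in metres.
#'
#' @param radius Sphere radius in metres. The default 0.095 m is the standard
#'   adult head model.
#' @return A tibble with columns `label`, `x`, `y`, `z`.
#' @export
electrode_positions_1020 <- function(radius = 0.095) {
  deg <- pi / 180
  # label, inclination from vertex (deg), azimuth from nasion (deg, + = right)
  ang <- list(
    CZ  = c(0, 0),
    FCZ = c(18, 0),
    FZ  = c(36, 0),    PZ  = c(36, 180),
    C3  = c(36, -90),  C4  = c(36, 90),
    FPZ = c(72, 0),    OZ  = c(72, 180),
    FP1 = c(72, -18),  FP2 = c(72, 18),
    F7  = c(72, -54),  F8  = c(72, 54),
    T7  = c(72, -90),  T8  = c(72, 90),
    P7  = c(72, -126), P8  = c(72, 126),
    O1  = c(72, -162), O2  = c(72, 162),
    FT9 = c(90, -72),  FT10 = c(90, 72)
  )
  unit <- function(a) {
    th <- a[1] * deg; ph <- a[2] * deg
    c(sin(th) * sin(ph), sin(th) * cos(ph), cos(th))
  }
  pts <- t(vapply(ang, unit, numeric(3)))
  # spherical midpoint (slerp at t = 0.5) of two unit vectors
  smid <- function(a, b) {
    m <- (pts[a, ] + pts[b, ]) / 2
    m / sqrt(sum(m^2))
  }
  mids <- rbind(
    F3 = smid("FZ", "F7"), F4 = smid("FZ", "F8"),
    P3 = smid("PZ", "P7"), P4 = smid("PZ", "P8")
  )
  pts <- rbind(pts, mids)
  tibble::tibble(
    label = rownames(pts),
    x = pts[, 1] * radius,
    y = pts[, 2] * radius,
    z = pts[, 3] * radius
  )
}

#' Default 22-electrode channel set
#'
#' The 22 scalp electrodes used for the topographic pipeline: the 19 standard
#' 10-20 electrodes plus FT9, FT10 and FCZ. CHB-MIT recordings carry 23
#' bipolar channels whose names reference exactly this electrode set; the
#' shipped mapping file (`system.file("extdata", "chbmit_1020_mapping.tsv",
#' package = "beamattack")`) spells out one editable default assignment.
#'
#' @return Character vector of 22 electrode labels.
#' @export
chbmit_channels <- function() {
  c("FP1", "FP2", "F7", "F3", "FZ", "F4", "F8",
    "FT9", "T7", "C3", "CZ", "C4", "T8", "FT10",
    "P7", "P3", "PZ", "P4", "P8", "O1", "O2", "FCZ")
}

#' Azimuthal equidistant projection of sphere points
#'
#' Projects points on a sphere of radius `radius` to the plane through the
#' projection centre at the top of the sphere (0, 0, radius), preserving both
#' the great-circle distance and the direction (azimuth) from the centre:
#' a point at arc distance d from the vertex lands at planar distance d from
#' the origin, along its original azimuth.
#'
#' @param points3d Numeric matrix with columns x, y, z (metres), rows on the
#'   sphere.
#' @param radius Sphere radius in metres.
#' @param tol On-sphere tolerance (relative to `radius`).
#' @return Numeric matrix with columns x, y (metres).
#' @export
project_equidistant_azimuthal <- function(points3d, radius, tol = 1e-6) {
  points3d <- rbind(points3d)
  stopifnot(ncol(points3d) == 3, radius > 0)
  rr <- sqrt(rowSums(points3d^2))
  off <- abs(rr - radius) > tol * radius
  if (any(off)) {
    stop("invalid-geometry: point(s) off the sphere of radius ", radius,
         " at row(s) ", paste(which(off), collapse = ", "))
  }
  z <- pmin(pmax(points3d[, 3] / radius, -1), 1)
  alpha <- acos(z)                       # arc distance from apex / radius
  if (any(alpha > pi - 1e-9)) {
    stop("ambiguous-azimuth: antipodal point (0, 0, -r) has no defined azimuth")
  }
  hyp <- sqrt(points3d[, 1]^2 + points3d[, 2]^2)
  ux <- ifelse(hyp > 0, points3d[, 1] / hyp, 0)
  uy <- ifelse(hyp > 0, points3d[, 2] / hyp, 0)
  cbind(x = radius * alpha * ux, y = radius * alpha * uy)
}

#' Build an electrode montage
#'
#' Resolves 10-20 electrode labels to 3-D positions on the spherical head
#' model and projects them to the 2-D plane with
#' [project_equidistant_azimuthal()].
#'
#' @param standard Montage family; only `"1020"` is supported.
#' @param channels Electrode labels; defaults to [chbmit_channels()]. The old
#'   temporal names T3/T4/T5/T6 are accepted as aliases of T7/T8/P7/P8.
#' @param radius Head sphere radius in metres.
#' @return An object of class `beam_montage`: list with `names`, `coords3d`
#'   (C x 3), `coords2d` (C x 2), `radius`.
#' @export
build_montage <- function(standard = "1020", channels = chbmit_channels(),
                          radius = 0.095) {
  if (!identical(standard, "1020")) {
    stop("unsupported montage standard: ", standard)
  }
  channels <- toupper(channels)
  alias <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")
  hit <- channels %in% names(alias)
  channels[hit] <- alias[channels[hit]]
  if (anyDuplicated(channels)) {
    stop("duplicate electrode labels: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "))
  }
  tab <- electrode_positions_1020(radius)
  missing <- setdiff(channels, tab$label)
  if (length(missing) > 0) {
    stop("missing-electrode: unknown label(s): ",
         paste(missing, collapse = ", "))
  }
  idx <- match(channels, tab$label)
  coords3d <- as.matrix(tab[idx, c("x", "y", "z")])
  rownames(coords3d) <- channels
  coords2d <- project_equidistant_azimuthal(coords3d, radius)
  rownames(coords2d) <- channels
  structure(
    list(names = channels, coords3d = coords3d, coords2d = coords2d,
         radius = radius),
    class = "beam_montage"
  )
}

#' @export
print.beam_montage <- function(x, ...) {
  cat("<beam_montage> ", length(x$names), " electrodes on r = ",
      x$radius, " m sphere\n", sep = "")
  cat(" ", paste(x$names, collapse = " "), "\n")
  invisible(x)
}

#' Build the topographic interpolation grid
#'
#' Meshes the minimum bounding rectangle of the projected 2-D electrode
#' positions with an H x W grid of equal cells and records the cell centres.
#' Cells are square when the rectangle's aspect ratio matches H/W; the grid
#' always uses constant spacing along each axis.
#'
#' @param montage A `beam_montage`.
#' @param H,W Grid rows (y axis) and columns (x axis); reference BEAMs use
#'   22 x 22.
#' @return Object of class `beam_grid`: `H`, `W`, `xs`, `ys` (centre
#'   coordinates, metres; `ys` descending so row 1 is the front of the head),
#'   `centers` (H*W x 2, column-major over the image), `bounds`, `inside_hull`
#'   (logical H*W), and a `cache` environment for interpolation operators.
#' @export
build_grid <- function(montage, H = 22L, W = 22L) {
  stopifnot(inherits(montage, "beam_montage"), H >= 2, W >= 2)
  xy <- montage$coords2d
  rngx <- range(xy[, 1]); rngy <- range(xy[, 2])
  if (diff(rngx) <= 0 || diff(rngy) <= 0 || qr(scale(xy, scale = FALSE))$rank < 2) {
    stop("invalid-geometry: electrode positions are degenerate (collinear)")
  }
  dx <- diff(rngx) / W
  dy <- diff(rngy) / H
  xs <- rngx[1] + (seq_len(W) - 0.5) * dx
  ys <- rngy[2] - (seq_len(H) - 0.5) * dy   # row 1 = front (max y)
  # column-major over the H x W image so matrix(vals, H, W) lines up directly
  centers <- cbind(x = rep(xs, each = H), y = rep(ys, times = W))
  hull <- grDevices::chull(xy)
  inside <- in_convex_hull(centers, xy[hull, , drop = FALSE])
  structure(
    list(H = as.integer(H), W = as.integer(W), xs = xs, ys = ys,
         centers = centers, bounds = c(xmin = rngx[1], xmax = rngx[2],
                                       ymin = rngy[1], ymax = rngy[2]),
         inside_hull = inside, cache = new.env(parent = emptyenv())),
    class = "beam_grid"
  )
}

# point-in-convex-polygon test (hull vertices in counter-clockwise order)
in_convex_hull <- function(pts, hull, tol = 1e-12) {
  n <- nrow(hull)
  # ensure counter-clockwise orientation
  area2 <- sum(hull[, 1] * hull[c(2:n, 1), 2] - hull[c(2:n, 1), 1] * hull[, 2])
  if (area2 < 0) hull <- hull[n:1, , drop = FALSE]
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- hull[j, 1] - hull[i, 1]; ey <- hull[j, 2] - hull[i, 2]
    cross <- ex * (pts[, 2] - hull[i, 2]) - ey * (pts[, 1] - hull[i, 1])
    inside <- inside & (cross >= -tol)
  }
  inside
}

#' @export
print.beam_grid <- function(x, ...) {
  cat("<beam_grid> ", x$H, " x ", x$W, " cells over [",
      signif(x$bounds["xmin"], 4), ", ", signif(x$bounds["xmax"], 4), "] x [",
      signif(x$bounds["ymin"], 4), ", ", signif(x$bounds["ymax"], 4), "] m\n",
      sep = "")
  invisible(x)
}

#' Write / read a montage as TSV
#'
#' Columns: label, x3d, y3d, z3d, x2d, y2d (metres).
#'
#' @param montage A `beam_montage`.
#' @param path File path.
#' @return `write_montage` returns `path` invisibly; `read_montage` returns a
#'   `beam_montage`.
#' @export
write_montage <- function(montage, path) {
  df <- data.frame(label = montage$names,
                   x3d = montage$coords3d[, 1], y3d = montage$coords3d[, 2],
                   z3d = montage$coords3d[, 3],
                   x2d = montage$coords2d[, 1], y2d = montage$coords2d[, 2])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @param radius Sphere radius recorded on the returned montage.
#' @export
read_montage <- function(path, radius = 0.095) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  coords3d <- as.matrix(df[, c("x3d", "y3d", "z3d")])
  coords2d <- as.matrix(df[, c("x2d", "y2d")])
  rownames(coords3d) <- rownames(coords2d) <- df$label
  colnames(coords3d) <- c("x", "y", "z")
  colnames(coords2d) <- c("x", "y")
  structure(
    list(names = df$label, coords3d = coords3d, coords2d = coords2d,
         radius = radius),
    class = "beam_montage"
  )
}
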