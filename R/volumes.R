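#' Annotated 3D volume
#'
#' A plain numeric 3D array (x, y, z order) carrying its voxel spacing and
#' world origin in micrometres. World coordinate of voxel (i, j, k),
#' 1-based, is origin + (i-1, j-1, k-1) * voxel.
#'
#' @param a 3D numeric array, dimensions (nx, ny, nz).
#' @param voxel_um length-3 voxel spacing (dx, dy, dz), um.
#' @param origin_um length-3 world coordinate of voxel (1,1,1), um.
#' @return the array with class \code{vol3d} and attributes set.
#' @export
vol3d <- function(a, voxel_um = c(1, 1, 1), origin_um = c(0, 0, 0)) {
  stopifnot(length(dim(a)) == 3L, length(voxel_um) == 3L,
            all(voxel_um > 0), length(origin_um) == 3L)
  attr(a, "voxel_um") <- as.numeric(voxel_um)
  attr(a, "origin_um") <- as.numeric(origin_um)
  class(a) <- c("vol3d", class(a))
  a
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x)
  v <- attr(x, "voxel_um"); o <- attr(x, "origin_um")
  cat(sprintf("vol3d %d x %d x %d voxels, %.3g x %.3g x %.3g um/voxel, origin (%g, %g, %g) um\n",
              d[1], d[2], d[3], v[1], v[2], v[3], o[1], o[2], o[3]))
  cat(sprintf("  intensity range [%g, %g]\n", min(x), max(x)))
  invisible(x)
}

voxel_of <- function(v) attr(v, "voxel_um") %||% c(1, 1, 1)
origin_of <- function(v) attr(v, "origin_um") %||% c(0, 0, 0)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trilinear interpolation of a 3D array at world points
#'
#' @param vol a \code{\link{vol3d}} (or bare 3D array, unit voxels at
#'   origin 0).
#' @param pts n x 3 matrix of world um coordinates.
#' @param outside value returned for points outside the volume.
#' @return numeric vector of interpolated values.
#' @export
interp_trilinear <- function(vol, pts, outside = 0) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  d <- dim(vol)
  vx <- voxel_of(vol); or <- origin_of(vol)
  # fractional 0-based voxel coordinates
  fx <- (pts[, 1] - or[1]) / vx[1]
  fy <- (pts[, 2] - or[2]) / vx[2]
  fz <- (pts[, 3] - or[3]) / vx[3]
  out <- rep(outside, nrow(pts))
  ok <- fx >= 0 & fx <= d[1] - 1 & fy >= 0 & fy <= d[2] - 1 &
        fz >= 0 & fz <= d[3] - 1
  if (!any(ok)) return(out)
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  x0 <- pmin(floor(fx), d[1] - 2); y0 <- pmin(floor(fy), d[2] - 2)
  z0 <- pmin(floor(fz), d[3] - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  tx <- fx - x0; ty <- fy - y0; tz <- fz - z0
  idx <- function(i, j, k) 1 + i + d[1] * (j + d[2] * k)
  v <- as.vector(vol)
  c000 <- v[idx(x0, y0, z0)];     c100 <- v[idx(x0 + 1, y0, z0)]
  c010 <- v[idx(x0, y0 + 1, z0)]; c110 <- v[idx(x0 + 1, y0 + 1, z0)]
  c001 <- v[idx(x0, y0, z0 + 1)]; c101 <- v[idx(x0 + 1, y0, z0 + 1)]
  c011 <- v[idx(x0, y0 + 1, z0 + 1)]; c111 <- v[idx(x0 + 1, y0 + 1, z0 + 1)]
  val <- (c000 * (1 - tx) + c100 * tx) * (1 - ty) * (1 - tz) +
         (c010 * (1 - tx) + c110 * tx) * ty * (1 - tz) +
         (c001 * (1 - tx) + c101 * tx) * (1 - ty) * tz +
         (c011 * (1 - tx) + c111 * tx) * ty * tz
  out[ok] <- val
  out
}

#' Bilinear interpolation of a matrix at fractional (0-based) coordinates
#'
#' @param img numeric matrix.
#' @param x,y equal-length fractional 0-based row/column coordinates.
#' @param outside fill value outside the image.
#' @return numeric vector.
#' @export
interp_bilinear <- function(img, x, y, outside = 0) {
  d <- dim(img)
  out <- rep(outside, length(x))
  ok <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1
  if (!any(ok)) return(out)
  xs <- x[ok]; ys <- y[ok]
  x0 <- pmax(pmin(floor(xs), d[1] - 2), 0)
  y0 <- pmax(pmin(floor(ys), d[2] - 2), 0)
  tx <- xs - x0; ty <- ys - y0
  v <- as.vector(img)
  idx <- function(i, j) 1 + i + d[1] * j
  val <- v[idx(x0, y0)] * (1 - tx) * (1 - ty) +
         v[idx(x0 + 1, y0)] * tx * (1 - ty) +
         v[idx(x0, y0 + 1)] * (1 - tx) * ty +
         v[idx(x0 + 1, y0 + 1)] * tx * ty
  out[ok] <- val
  out
}

#' Block-mean downsampling of a matrix
#'
#' Averages non-overlapping f x f blocks; trailing rows/columns that do
#' not fill a block are dropped.
#'
#' @param img numeric matrix.
#' @param f integer downsampling factor.
#' @return downsampled matrix.
#' @export
block_mean <- function(img, f = 4L) {
  f <- as.integer(f)
  stopifnot(f >= 1L)
  if (f == 1L) return(img)
  d <- dim(img)
  nr <- d[1] %/% f; nc <- d[2] %/% f
  stopifnot(nr >= 1L, nc >= 1L)
  img <- img[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  a <- array(img, dim = c(f, nr, f, nc))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

#' Block-mean downscaling of a volume to isotropic spacing
#'
#' Downscales a \code{\link{vol3d}} to an isotropic target spacing (25 um
#' by default, the spacing used for atlas registration) by averaging
#' whole blocks of voxels.
#'
#' @param vol a \code{\link{vol3d}}.
#' @param target_um target isotropic voxel size, um.
#' @return a \code{\link{vol3d}} at the target spacing.
#' @export
downscale_for_atlas <- function(vol, target_um = 25) {
  vx <- voxel_of(vol)
  f <- pmax(1L, as.integer(round(target_um / vx)))
  d <- dim(vol)
  n <- d %/% f
  stopifnot(all(n >= 1L))
  a <- unclass(vol)[seq_len(n[1] * f[1]), seq_len(n[2] * f[2]),
                    seq_len(n[3] * f[3]), drop = FALSE]
  dim(a) <- c(f[1], n[1], f[2], n[2], f[3], n[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(prod(f), prod(n))
  out <- array(colMeans(a), dim = n)
  vol3d(out, voxel_um = vx * f, origin_um = origin_of(vol) + (f - 1) * vx / 2)
}
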