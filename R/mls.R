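#' Similarity moving-least-squares transform of 2D points
#'
#' Deformation interpolating control-point displacements with
#' distance-decaying weights w_i = 1 / |v - p_i|^(2*alpha). For each
#' evaluation point the weighted-best similarity transform (rotation +
#' isotropic scale + translation) of the control points is applied, which
#' makes the warp reproduce any global similarity transform exactly and
#' keeps local shapes undistorted. With a single control point the warp
#' degenerates to the pure translation by its displacement. Points
#' coinciding with a control point map exactly to its target.
#'
#' @param v n x 2 matrix of points to transform, um.
#' @param p m x 2 matrix of control points, um.
#' @param q m x 2 matrix of control-point targets (p + displacement), um.
#' @param alpha weight falloff exponent (default 1).
#' @return n x 2 matrix of transformed points.
#' @references Schaefer, McPhail & Warren-style similarity MLS image
#'   deformation.
#' @export
mls_transform <- function(v, p, q, alpha = 1) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 2)
  p <- matrix(as.numeric(as.matrix(p)), ncol = 2)
  q <- matrix(as.numeric(as.matrix(q)), ncol = 2)
  m <- nrow(p)
  if (m < 1) stop("need at least one control point")
  dup <- duplicated(p) | duplicated(p, fromLast = TRUE)
  if (any(dup)) {
    grp <- interaction(p[, 1], p[, 2], drop = TRUE)
    for (g in levels(grp)) {
      sel <- grp == g
      if (sum(sel) > 1 &&
          (max(q[sel, 1]) - min(q[sel, 1]) > 1e-9 ||
           max(q[sel, 2]) - min(q[sel, 2]) > 1e-9))
        stop("coincident control points with conflicting displacements")
    }
    keep <- !duplicated(p)
    p <- p[keep, , drop = FALSE]; q <- q[keep, , drop = FALSE]
    m <- nrow(p)
  }
  if (m == 1)
    return(sweep(v, 2, q[1, ] - p[1, ], "+"))
  # complex formulation: similarity = complex-linear map
  pc <- complex(real = p[, 1], imaginary = p[, 2])
  qc <- complex(real = q[, 1], imaginary = q[, 2])
  vc <- complex(real = v[, 1], imaginary = v[, 2])
  out <- vc
  d2 <- outer(vc, pc, function(a, b) Mod(a - b)^2)   # n x m
  exact <- d2 < 1e-18
  w <- 1 / pmax(d2, 1e-18)^alpha
  sw <- rowSums(w)
  pstar <- as.vector(w %*% pc) / sw
  qstar <- as.vector(w %*% qc) / sw
  # M = sum w q^ conj(p^) / sum w |p^|^2  (complex-linear similarity fit)
  ph <- outer(pstar, pc, function(a, b) b - a)   # n x m: pc - pstar per row
  qh <- outer(qstar, qc, function(a, b) b - a)
  num <- rowSums(w * qh * Conj(ph))
  den <- rowSums(w * Mod(ph)^2)
  M <- num / den
  out <- M * (vc - pstar) + qstar
  # points exactly on a control point map to its target
  if (any(exact)) {
    hit <- which(exact, arr.ind = TRUE)
    out[hit[, 1]] <- qc[hit[, 2]]
  }
  cbind(Re(out), Im(out))
}

#' Warp an image by similarity moving least squares
#'
#' Content at control point \code{p[i,]} moves to \code{p[i,] + d[i,]}.
#' Implemented by inverse-mapped resampling: the backward MLS transform
#' (targets back to sources) is evaluated on a coarse grid, bilinearly
#' interpolated to every pixel, and the input is sampled there. Zero
#' displacements give the identity image.
#'
#' @param img numeric matrix; rows = x, cols = y, pixel spacing
#'   \code{voxel_xy} um.
#' @param p m x 2 control points, um.
#' @param d m x 2 displacements, um.
#' @param alpha weight falloff exponent.
#' @param voxel_xy pixel spacing (dx, dy), um.
#' @param grid_step field evaluation stride, pixels.
#' @return warped matrix of the same size.
#' @export
mls_warp <- function(img, p, d, alpha = 1, voxel_xy = c(1, 1),
                     grid_step = 4L) {
  if (all(abs(d) < 1e-15)) return(img)
  nx <- nrow(img); ny <- ncol(img)
  gx <- unique(c(seq(1, nx, by = grid_step), nx))
  gy <- unique(c(seq(1, ny, by = grid_step), ny))
  gpts <- cbind(rep((gx - 1) * voxel_xy[1], times = length(gy)),
                rep((gy - 1) * voxel_xy[2], each = length(gx)))
  src <- mls_transform(gpts, p + d, p, alpha = alpha)  # backward map
  sx <- matrix(src[, 1], length(gx), length(gy))
  sy <- matrix(src[, 2], length(gx), length(gy))
  # interpolate field to all pixels (in grid index space)
  px <- (seq_len(nx) - 1) * voxel_xy[1]
  py <- (seq_len(ny) - 1) * voxel_xy[2]
  gi <- stats::approx(x = (gx - 1) * voxel_xy[1], y = seq_along(gx) - 1,
                      xout = px)$y
  gj <- stats::approx(x = (gy - 1) * voxel_xy[2], y = seq_along(gy) - 1,
                      xout = py)$y
  I <- outer(gi, rep(1, ny)); J <- outer(rep(1, nx), gj)
  fx <- matrix(interp_bilinear(sx, as.vector(I), as.vector(J)), nx, ny)
  fy <- matrix(interp_bilinear(sy, as.vector(I), as.vector(J)), nx, ny)
  matrix(interp_bilinear(img, as.vector(fx / voxel_xy[1]),
                         as.vector(fy / voxel_xy[2])), nx, ny)
}
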