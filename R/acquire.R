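#' Simulate oblique on-the-fly acquisition of a volume
#'
#' Samples oblique imaging planes from a world-coordinate volume through
#' the inverse of \code{\link{oblique_to_world}} with trilinear
#' interpolation, producing the frame streams ("columns") a stage-scanned
#' oblique light-sheet system would record. Adjacent columns tile the
#' volume along y with a configurable fractional overlap (default 10%).
#'
#' In \code{"synchronized"} mode each voxel is exposed only while the
#' scanning beam passes it, so frames are sharp samples of the oblique
#' plane. In \code{"unsynchronized"} mode the whole frame period is
#' exposed while the stage moves, which smears each frame along x by the
#' inter-frame stage travel (a box kernel of length stage_speed /
#' scan_rate) - the classic on-the-fly light-sheet motion blur.
#'
#' @param vol a \code{\link{vol3d}} (x, y, z world axes, um).
#' @param g an \code{\link{acquisition_geometry}}; its
#'   \code{column_origin_um} is recomputed per column.
#' @param mode "synchronized" or "unsynchronized".
#' @param overlap fractional y-overlap between adjacent columns.
#' @param noise list(poisson =, read_sigma =) applied per frame; default
#'   noiseless.
#' @param frame_step_um optional override of the stage travel per frame
#'   (e.g. 0 to emulate a stationary stage); defaults to the geometry's
#'   \code{voxel_grid} value.
#' @param n_frames optional fixed number of frames per column.
#' @return list of \code{image_column} objects: \code{frames} (array
#'   frame x row x col), \code{geometry}, \code{column_id},
#'   \code{nominal_origin_um}, and a \code{truncated} flag set when the
#'   frame footprint leaves the volume.
#' @export
simulate_acquisition <- function(vol, g,
                                 mode = c("synchronized", "unsynchronized"),
                                 overlap = 0.10,
                                 noise = list(poisson = FALSE, read_sigma = 0),
                                 frame_step_um = NULL, n_frames = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "acquisition_geometry"))
  vg <- voxel_grid(g)
  fs <- frame_step_um %||% vg$frame_step_um
  th <- g$tilt_angle_deg * pi / 180
  d <- dim(vol); vx <- voxel_of(vol); or <- origin_of(vol)
  ext <- (d - 1) * vx
  R <- g$frame_shape[1]; C <- g$frame_shape[2]
  z_top <- or[3] + ext[3]
  # frame pixel lattice (0-based indices)
  rows <- seq_len(R) - 1; cols <- seq_len(C) - 1
  x_off_row <- rows * vg$pixel_um * cos(th)   # x offset of each row
  z_row <- z_top - rows * vg$pixel_um * sin(th)
  col_width <- (C - 1) * vg$pixel_um
  stride <- col_width * (1 - overlap)
  n_cols <- max(1L, ceiling((ext[2] - col_width) / stride) + 1L)
  # stage lead-in: deep rows trail the shallow ones by up to
  # (R-1) * pixel * cos(tilt) in x, so sweeping must start early
  lead <- (R - 1) * vg$pixel_um * cos(th)
  x_start <- or[1] - lead
  if (is.null(n_frames)) {
    n_frames <- if (fs > 0) floor((ext[1] + lead) / fs) + 1L else 1L
  }
  columns <- vector("list", n_cols)
  for (ci in seq_len(n_cols)) {
    oy <- or[2] + (ci - 1) * stride
    origin <- c(x_start, oy, z_top)
    gc <- g
    gc$column_origin_um <- origin
    y_col <- oy + cols * vg$pixel_um
    frames <- array(0, dim = c(n_frames, R, C))
    truncated <- FALSE
    # sub-steps emulating exposure during stage motion
    subs <- if (mode == "unsynchronized" && fs > 0)
      seq(0, fs, length.out = max(3L, ceiling(fs / vg$pixel_um)) + 1L)[-1] - fs /
        (2 * max(3L, ceiling(fs / vg$pixel_um))) else 0
    ptsY <- rep(y_col, each = R)
    ptsZ <- rep(z_row, times = C)
    baseX <- rep(x_off_row, times = C)
    for (f in seq_len(n_frames)) {
      x0 <- x_start + (f - 1) * fs
      acc <- 0
      for (u in subs) {
        pts <- cbind(baseX + x0 + u, ptsY, ptsZ)
        acc <- acc + interp_trilinear(vol, pts)
      }
      img <- acc / length(subs)
      if (!truncated &&
          (x0 + max(x_off_row) > or[1] + ext[1] + 1e-9 ||
           min(z_row) < or[3] - 1e-9 || max(y_col) > or[2] + ext[2] + 1e-9))
        truncated <- TRUE
      if (isTRUE(noise$poisson)) img <- stats::rpois(length(img), pmax(img, 0))
      rs <- noise$read_sigma %||% 0
      if (rs > 0) img <- img + stats::rnorm(length(img), 0, rs)
      frames[f, , ] <- img
    }
    columns[[ci]] <- structure(list(frames = frames, geometry = gc,
                                    column_id = ci,
                                    nominal_origin_um = origin,
                                    truncated = truncated),
                               class = "image_column")
  }
  columns
}

#' @export
print.image_column <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_column %s: %d frames of %d x %d px, origin (%g, %g, %g) um%s\n",
              x$column_id, d[1], d[2], d[3],
              x$nominal_origin_um[1], x$nominal_origin_um[2],
              x$nominal_origin_um[3],
              if (isTRUE(x$truncated)) " [truncated]" else ""))
  invisible(x)
}

# smooth random in-plane displacement field: sum of <= n_modes
# random-phase sinusoids, jointly rescaled to the requested amplitude
random_sin_field <- function(nx, ny, voxel_xy, amplitude_um, n_modes = 5) {
  X <- outer((seq_len(nx) - 1) * voxel_xy[1], rep(1, ny))
  Y <- outer(rep(1, nx), (seq_len(ny) - 1) * voxel_xy[2])
  # wavelengths at or above the slice extent: slice-handling distortions
  # are large-scale bends with small local strain
  L <- max(nx * voxel_xy[1], ny * voxel_xy[2])
  fx <- matrix(0, nx, ny); fy <- matrix(0, nx, ny)
  for (m in seq_len(n_modes)) {
    lam <- stats::runif(1, L, 2 * L)
    k <- 2 * pi / lam
    thk <- stats::runif(1, 0, 2 * pi)
    ph <- stats::runif(2, 0, 2 * pi)
    w <- stats::runif(2, 0.3, 1)
    arg <- k * (cos(thk) * X + sin(thk) * Y)
    fx <- fx + w[1] * sin(arg + ph[1])
    fy <- fy + w[2] * sin(arg + ph[2])
  }
  mag <- sqrt(fx^2 + fy^2)
  s <- if (max(mag) > 0) amplitude_um / max(mag) else 0
  list(fx = fx * s, fy = fy * s, voxel_xy = voxel_xy)
}

# backward-warp one z-plane: out(i,j) = in(i + fx/dx, j + fy/dy)
warp_plane <- function(img, field) {
  nx <- nrow(img); ny <- ncol(img)
  ii <- outer(seq_len(nx) - 1, rep(1, ny))
  jj <- outer(rep(1, nx), seq_len(ny) - 1)
  x <- ii + field$fx / field$voxel_xy[1]
  y <- jj + field$fy / field$voxel_xy[2]
  matrix(interp_bilinear(img, as.vector(x), as.vector(y)), nx, ny)
}

#' Evaluate a recorded backward displacement field at world points
#'
#' @param field field as stored by \code{\link{cut_and_deform_slices}}
#'   (matrices \code{fx}, \code{fy} in um on the slice pixel grid).
#' @param xy n x 2 matrix of in-plane um coordinates.
#' @return n x 2 matrix of (dx, dy) um.
#' @export
eval_field <- function(field, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  i <- xy[, 1] / field$voxel_xy[1]
  j <- xy[, 2] / field$voxel_xy[2]
  cbind(interp_bilinear(field$fx, i, j), interp_bilinear(field$fy, i, j))
}

#' Forward-deform points under a recorded backward field
#'
#' The image warp is backward (output at q samples input at q + b(q)), so
#' a material point at p appears at the q solving q + b(q) = p; this is
#' found by fixed-point iteration, which converges for the smooth,
#' small-amplitude fields the generator produces.
#'
#' @param field recorded field (see \code{\link{eval_field}}).
#' @param xy n x 2 original in-plane positions, um.
#' @param tol convergence tolerance, um.
#' @return n x 2 deformed positions, um.
#' @export
deform_points <- function(field, xy, tol = 1e-6) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  q <- xy
  for (it in 1:50) {
    b <- eval_field(field, q)
    qn <- xy - b
    if (max(abs(qn - q)) < tol) { q <- qn; break }
    q <- qn
  }
  q
}

#' Undo a recorded deformation on observed positions
#'
#' Exact inverse of \code{\link{deform_points}} by construction:
#' p = q + b(q).
#'
#' @inheritParams deform_points
#' @param xy n x 2 observed (deformed) positions, um.
#' @return n x 2 original positions, um.
#' @export
undeform_points <- function(field, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  xy + eval_field(field, xy)
}

#' Cut a volume into thick slices and apply per-slice deformations
#'
#' Splits a volume along z into slabs of the given thickness (a thickness
#' exceeding the volume depth yields a single slice), then applies to
#' each slab an independent smooth low-frequency in-plane deformation
#' (sum of at most \code{n_modes} random-phase sinusoids, peak magnitude
#' \code{deform_amplitude_um}) and, optionally, a small planar surface
#' tilt. Every applied field and tilt is recorded so downstream
#' alignment can be scored against ground truth.
#'
#' @param vol a \code{\link{vol3d}}.
#' @param truth optional truth list from \code{\link{render_phantom}};
#'   when present, deformed per-slice cell positions are recorded.
#' @param slice_thickness_um slab thickness, um (default 300, matching
#'   the vibratome sectioning the imaging geometry is built around).
#' @param deform_amplitude_um peak in-plane displacement, um.
#' @param tilt_amplitude max |plane slope| of the surface tilt
#'   (dimensionless dz/dxy); 0 disables tilt.
#' @param n_modes sinusoid count per field.
#' @param seed RNG seed.
#' @return list of class \code{sliced_phantom}: \code{slices} (list of
#'   \code{\link{vol3d}}, origins preserving global z), \code{fields},
#'   \code{tilts}, \code{z_ranges}, and \code{cells_deformed} when truth
#'   was given.
#' @export
cut_and_deform_slices <- function(vol, truth = NULL,
                                  slice_thickness_um = 300,
                                  deform_amplitude_um = 5,
                                  tilt_amplitude = 0, n_modes = 5,
                                  seed = 0L) {
  stopifnot(slice_thickness_um > 0)
  set.seed(seed)
  d <- dim(vol); vx <- voxel_of(vol); or <- origin_of(vol)
  k <- max(1L, round(slice_thickness_um / vx[3]))
  starts <- seq(1L, d[3], by = k)
  n_s <- length(starts)
  slices <- vector("list", n_s); fields <- vector("list", n_s)
  tilts <- vector("list", n_s); zr <- matrix(0, n_s, 2)
  cells_def <- NULL
  for (s in seq_len(n_s)) {
    zi <- starts[s]:min(d[3], starts[s] + k - 1L)
    slab <- unclass(vol)[, , zi, drop = FALSE]
    fld <- random_sin_field(d[1], d[2], vx[1:2], deform_amplitude_um, n_modes)
    tilt <- if (tilt_amplitude > 0)
      stats::runif(2, -tilt_amplitude, tilt_amplitude) else c(0, 0)
    if (deform_amplitude_um > 0) {
      for (p in seq_along(zi)) slab[, , p] <- warp_plane(slab[, , p], fld)
    }
    if (any(tilt != 0)) {
      # shift content in z by t(x,y) = a*x + b*y (um), per (x,y) column
      tmap <- outer((seq_len(d[1]) - 1) * vx[1] * tilt[1], rep(1, d[2])) +
              outer(rep(1, d[1]), (seq_len(d[2]) - 1) * vx[2] * tilt[2])
      nz <- length(zi)
      old <- slab
      for (p in seq_len(nz)) {
        # sample input at z index p - t/dz (backward shift)
        zq <- p - tmap / vx[3]
        z0 <- floor(zq)
        z0c <- pmin(pmax(z0, 1), nz - 1)
        w <- pmin(pmax(zq - z0c, 0), 1)
        lin <- function(kk) {
          m <- matrix(0, d[1], d[2])
          sel <- kk >= 1 & kk <= nz
          if (any(sel)) {
            idx <- cbind(which(sel, arr.ind = TRUE), kk[sel])
            m[sel] <- old[idx]
          }
          m
        }
        a0 <- lin(z0c); a1 <- lin(z0c + 1L)
        out <- a0 * (1 - w) + a1 * w
        out[zq < 0.5 | zq > nz + 0.5] <- 0
        slab[, , p] <- out
      }
    }
    z0_um <- or[3] + (zi[1] - 1L) * vx[3]
    slices[[s]] <- vol3d(slab, voxel_um = vx, origin_um = c(or[1:2], z0_um))
    fields[[s]] <- fld; tilts[[s]] <- tilt
    zr[s, ] <- c(z0_um, or[3] + (zi[length(zi)] - 1L) * vx[3])
    if (!is.null(truth) && nrow(truth$cells)) {
      inz <- truth$cells$z_um >= zr[s, 1] - vx[3] / 2 &
             truth$cells$z_um <= zr[s, 2] + vx[3] / 2
      if (any(inz)) {
        cc <- truth$cells[inz, , drop = FALSE]
        q <- deform_points(fld, as.matrix(cc[, c("x_um", "y_um")]))
        cells_def <- rbind(cells_def,
          data.frame(id = cc$id, slice = s, channel = cc$channel,
                     x_um = q[, 1], y_um = q[, 2], z_um = cc$z_um))
      }
    }
  }
  structure(list(slices = slices, fields = fields, tilts = tilts,
                 z_ranges = zr, cells_deformed = cells_def,
                 voxel_um = vx),
            class = "sliced_phantom")
}
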