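#' Acquisition geometry for oblique on-the-fly light-sheet imaging
#'
#' Bundles every scan/optics parameter needed to map camera frame pixels
#' acquired at a tilt to the sample surface onto world micrometre
#' coordinates. The stage moves continuously along world x while oblique
#' frames are read out at \code{scan_rate_hz}; the imaging plane is tilted
#' \code{tilt_angle_deg} to the sample surface.
#'
#' Coordinate convention used throughout the package: right-handed world
#' frame in micrometres; x = stage travel direction, y = illumination beam
#' width (frame columns), z = depth, decreasing into the tissue. Pixel and
#' frame indices are 0-based with half-open ranges.
#'
#' @param tilt_angle_deg angle between imaging plane and sample surface,
#'   degrees, in (0, 90). Default 45.
#' @param objective_mag nominal objective magnification (dimensionless).
#' @param tube_focal_mm tube lens focal length, mm.
#' @param reference_tube_mm reference tube length of the objective's
#'   manufacturer convention, mm (default 180, Olympus).
#' @param camera_pixel_um physical camera pixel pitch, micrometres
#'   (default 6.5, typical sCMOS).
#' @param scan_rate_hz frame (beam-scan) rate, frames per second.
#' @param stage_speed_um_s stage speed, micrometres per second.
#' @param frame_shape integer c(rows, cols) of one acquired frame.
#' @param exposure_per_voxel_s effective excitation time per voxel in
#'   synchronized-scan mode, seconds.
#' @param column_origin_um world (x, y, z) of frame 0, pixel (0, 0).
#' @return an object of class \code{acquisition_geometry} (a list).
#' @examples
#' g <- acquisition_geometry(scan_rate_hz = 200, stage_speed_um_s = 1000)
#' effective_magnification(g)   # 13.33
#' voxel_grid(g)
#' @export
acquisition_geometry <- function(tilt_angle_deg = 45,
                                 objective_mag = 20,
                                 tube_focal_mm = 120,
                                 reference_tube_mm = 180,
                                 camera_pixel_um = 6.5,
                                 scan_rate_hz = 200,
                                 stage_speed_um_s = 1000,
                                 frame_shape = c(1000L, 2000L),
                                 exposure_per_voxel_s = 100e-6,
                                 column_origin_um = c(0, 0, 0)) {
  if (!is.numeric(tilt_angle_deg) || tilt_angle_deg <= 0 || tilt_angle_deg >= 90)
    stop("tilt_angle_deg must lie in (0, 90)")
  pos <- c(objective_mag = objective_mag, tube_focal_mm = tube_focal_mm,
           reference_tube_mm = reference_tube_mm,
           camera_pixel_um = camera_pixel_um, scan_rate_hz = scan_rate_hz,
           stage_speed_um_s = stage_speed_um_s,
           exposure_per_voxel_s = exposure_per_voxel_s)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) stop("parameters must be strictly positive: ",
                        paste(bad, collapse = ", "))
  frame_shape <- as.integer(frame_shape)
  if (length(frame_shape) != 2L || any(frame_shape < 1L))
    stop("frame_shape must be two positive integers (rows, cols)")
  stopifnot(length(column_origin_um) == 3L, is.numeric(column_origin_um))
  structure(list(
    tilt_angle_deg = tilt_angle_deg,
    objective_mag = objective_mag,
    tube_focal_mm = tube_focal_mm,
    reference_tube_mm = reference_tube_mm,
    camera_pixel_um = camera_pixel_um,
    scan_rate_hz = scan_rate_hz,
    stage_speed_um_s = stage_speed_um_s,
    frame_shape = frame_shape,
    exposure_per_voxel_s = exposure_per_voxel_s,
    column_origin_um = as.numeric(column_origin_um)
  ), class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat("Oblique acquisition geometry\n")
  cat(sprintf("  tilt %.1f deg; objective %gx, tube %g/%g mm -> %.2fx effective\n",
              x$tilt_angle_deg, x$objective_mag, x$tube_focal_mm,
              x$reference_tube_mm, effective_magnification(x)))
  vg <- voxel_grid(x)
  cat(sprintf("  stage %g um/s, scan %g Hz; voxel %.3f x %.3f um in-plane, %.3f um frame step (%.3f um axial)\n",
              x$stage_speed_um_s, x$scan_rate_hz, vg$pixel_um, vg$pixel_um,
              vg$frame_step_um, vg$axial_step_um))
  cat(sprintf("  frame %d x %d px, origin (%g, %g, %g) um\n",
              x$frame_shape[1], x$frame_shape[2],
              x$column_origin_um[1], x$column_origin_um[2], x$column_origin_um[3]))
  invisible(x)
}

#' Effective magnification of the imaging path
#'
#' Nominal objective magnification rescaled by the actual tube lens:
#' M_eff = M_obj * f_tube / f_reference. A 20x objective with a 120 mm tube
#' lens on a 180 mm reference convention gives 13.3x.
#'
#' @param g an \code{\link{acquisition_geometry}}.
#' @return effective magnification (dimensionless).
#' @export
effective_magnification <- function(g) {
  stopifnot(inherits(g, "acquisition_geometry"))
  if (g$tube_focal_mm <= 0 || g$reference_tube_mm <= 0)
    stop("focal lengths must be positive")
  g$objective_mag * g$tube_focal_mm / g$reference_tube_mm
}

#' Voxel grid implied by a geometry
#'
#' In-plane pixel size is the camera pitch divided by the effective
#' magnification; the frame step is stage travel per scan period; the axial
#' step (perpendicular to the oblique imaging plane) is the frame step
#' times sin(tilt). At 200 Hz / 1 mm/s / 45 deg this is the ~0.5 x 0.5 x
#' 3.5 um^3 sampling regime.
#'
#' @param g an \code{\link{acquisition_geometry}}.
#' @return list with \code{pixel_um}, \code{frame_step_um},
#'   \code{axial_step_um}, class \code{voxel_grid}.
#' @export
voxel_grid <- function(g) {
  stopifnot(inherits(g, "acquisition_geometry"))
  if (g$scan_rate_hz <= 0) stop("scan_rate_hz must be positive")
  px <- g$camera_pixel_um / effective_magnification(g)
  fs <- g$stage_speed_um_s / g$scan_rate_hz
  structure(list(pixel_um = px,
                 frame_step_um = fs,
                 axial_step_um = fs * sin(g$tilt_angle_deg * pi / 180)),
            class = "voxel_grid")
}

#' Vertical depth imaged by an oblique field
#'
#' An oblique section of length \code{oblique_field_um} along the imaging
#' plane spans a vertical depth of field * sin(tilt): a ~420 um oblique
#' field at 45 deg reaches ~297 um into the sample, which is what caps the
#' usable slice thickness near 300 um.
#'
#' @param oblique_field_um field extent along the oblique plane, um.
#' @param tilt_angle_deg tilt angle, degrees.
#' @return vertical depth, um.
#' @export
imageable_depth <- function(oblique_field_um, tilt_angle_deg = 45) {
  if (any(oblique_field_um <= 0)) stop("field length must be positive")
  if (any(tilt_angle_deg <= 0 | tilt_angle_deg > 90))
    stop("tilt_angle_deg must lie in (0, 90]")
  oblique_field_um * sin(tilt_angle_deg * pi / 180)
}

#' Lateral motion blur of on-the-fly acquisition
#'
#' Smear accumulated while a voxel is being exposed on a moving stage:
#' blur = stage speed * effective exposure. With a synchronized scanning
#' beam the effective exposure per voxel is ~100 us (blur < 0.05 um at
#' 0.5 mm/s); without synchronization the whole frame period is exposed
#' and the blur is the full inter-frame travel.
#'
#' @param stage_speed_um_s stage speed, um/s (>= 0).
#' @param effective_exposure_s effective exposure, s (>= 0). Ignored when
#'   \code{g} is supplied.
#' @param g optional \code{\link{acquisition_geometry}} from which the
#'   exposure is taken according to \code{mode}.
#' @param mode "synchronized" uses \code{exposure_per_voxel_s};
#'   "unsynchronized" uses the full frame period 1/scan_rate.
#' @return blur extent, um.
#' @export
motion_blur_extent <- function(stage_speed_um_s, effective_exposure_s = NULL,
                               g = NULL,
                               mode = c("synchronized", "unsynchronized")) {
  if (!is.null(g)) {
    stopifnot(inherits(g, "acquisition_geometry"))
    mode <- match.arg(mode)
    if (missing(stage_speed_um_s)) stage_speed_um_s <- g$stage_speed_um_s
    effective_exposure_s <- switch(mode,
      synchronized = g$exposure_per_voxel_s,
      unsynchronized = 1 / g$scan_rate_hz)
  }
  if (any(stage_speed_um_s < 0) || any(effective_exposure_s < 0))
    stop("speed and exposure must be nonnegative")
  stage_speed_um_s * effective_exposure_s
}

#' Voxel throughput at a given volume rate
#'
#' Converts a volumetric acquisition rate (um^3/s) into voxels per second
#' for a voxel grid; useful to check a configuration against the camera
#' data-rate ceiling (400 Mvoxel/s for the reference system).
#'
#' @param volume_rate_um3_s acquired volume per second, um^3/s (>= 0).
#' @param voxel a \code{voxel_grid} (or list with \code{pixel_um} and
#'   \code{axial_step_um}).
#' @return voxels per second.
#' @export
voxel_throughput <- function(volume_rate_um3_s, voxel) {
  vv <- voxel$pixel_um^2 * voxel$axial_step_um
  if (!is.finite(vv) || vv <= 0) stop("voxel volume must be positive")
  if (any(volume_rate_um3_s < 0)) stop("volume rate must be nonnegative")
  volume_rate_um3_s / vv
}

#' Map oblique frame pixels to world coordinates
#'
#' THE coordinate convention of this package. Frame \code{f}, pixel row
#' \code{r}, column \code{c} (all 0-based) map to world micrometres as a
#' shear along the stage direction:
#' \deqn{x = ox + f \cdot s_f + r \cdot p \cos\theta,\quad
#'       y = oy + c \cdot p,\quad z = oz - r \cdot p \sin\theta}
#' with p the in-plane pixel size, s_f the stage travel per frame and
#' theta the tilt. Rows advance down into the tissue (z decreases);
#' columns advance across the beam (y).
#'
#' @param g an \code{\link{acquisition_geometry}}.
#' @param frame_index,pixel_row,pixel_col equal-length numeric vectors of
#'   (possibly fractional) 0-based indices.
#' @param check when TRUE, integer indices outside \code{frame_shape}
#'   raise an error.
#' @return n x 3 matrix of world (x, y, z) in um.
#' @seealso \code{\link{world_to_oblique}} for the inverse.
#' @export
oblique_to_world <- function(g, frame_index, pixel_row, pixel_col,
                             check = TRUE) {
  stopifnot(inherits(g, "acquisition_geometry"))
  vg <- voxel_grid(g)
  th <- g$tilt_angle_deg * pi / 180
  if (check) {
    if (any(pixel_row < 0 | pixel_row > g$frame_shape[1] - 1L) ||
        any(pixel_col < 0 | pixel_col > g$frame_shape[2] - 1L) ||
        any(frame_index < 0))
      stop("pixel/frame index out of range for frame_shape")
  }
  o <- g$column_origin_um
  cbind(x = o[1] + frame_index * vg$frame_step_um + pixel_row * vg$pixel_um * cos(th),
        y = o[2] + pixel_col * vg$pixel_um,
        z = o[3] - pixel_row * vg$pixel_um * sin(th))
}

#' Map world coordinates back to fractional frame/pixel indices
#'
#' Exact inverse of \code{\link{oblique_to_world}}; returns fractional
#' indices (no rounding), suitable for interpolation.
#'
#' @param g an \code{\link{acquisition_geometry}}.
#' @param xyz n x 3 matrix (or length-3 vector) of world um coordinates.
#' @return n x 3 matrix with columns frame_index, pixel_row, pixel_col.
#' @export
world_to_oblique <- function(g, xyz) {
  stopifnot(inherits(g, "acquisition_geometry"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  vg <- voxel_grid(g)
  th <- g$tilt_angle_deg * pi / 180
  o <- g$column_origin_um
  row <- (o[3] - xyz[, 3]) / (vg$pixel_um * sin(th))
  col <- (xyz[, 2] - o[2]) / vg$pixel_um
  fr  <- (xyz[, 1] - o[1] - row * vg$pixel_um * cos(th)) / vg$frame_step_um
  cbind(frame_index = fr, pixel_row = row, pixel_col = col)
}

#' Read or write an acquisition-geometry JSON sidecar
#'
#' The sidecar ("geometry.json") stores every field of the geometry so a
#' frame stack on disk is self-describing.
#'
#' @param g an \code{\link{acquisition_geometry}}.
#' @param path file path.
#' @return \code{read_geometry} returns an \code{acquisition_geometry};
#'   \code{write_geometry} returns \code{path} invisibly.
#' @export
write_geometry <- function(g, path) {
  stopifnot(inherits(g, "acquisition_geometry"))
  jsonlite::write_json(unclass(g), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(acquisition_geometry, x)
}
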