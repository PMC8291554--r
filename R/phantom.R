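#' Specify a ground-truthed two-channel phantom
#'
#' Describes a 3D test object emulating cleared-tissue fluorescence data:
#' ellipsoidal somata/nuclei rendered as truncated anisotropic Gaussians
#' (sigma = radius/2, truncated at 3 sigma, so a band-pass blob detector
#' peaks at the soma centre), optional tubular dendrites along polylines,
#' a constant tissue background, and sCMOS-like Poisson shot noise plus
#' Gaussian read noise. All randomness is fixed by \code{seed}.
#'
#' @param volume_um length-3 physical extent (x, y, z), um.
#' @param voxel_um length-3 voxel spacing, um (default c(1, 1, 3),
#'   in-plane-fine / axially-coarse like the native acquisition grid).
#' @param cells data.frame with columns \code{x_um, y_um, z_um,
#'   radius_um, peak, channel} ("red" or "green") and optionally
#'   \code{partner} (id of a colabelled cell in the other channel) and
#'   \code{region}. May be empty.
#' @param dendrites list of tubes, each \code{list(path = n x 3 matrix of
#'   um points, radius_um, intensity, channel)}.
#' @param background_level constant background, counts.
#' @param noise list(poisson = TRUE/FALSE, read_sigma = counts).
#' @param seed integer RNG seed fixing all randomness of the renderer.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(volume_um, voxel_um = c(1, 1, 3),
                         cells = NULL, dendrites = list(),
                         background_level = 100,
                         noise = list(poisson = TRUE, read_sigma = 2),
                         seed = 0L) {
  stopifnot(length(volume_um) == 3L, all(volume_um > 0),
            length(voxel_um) == 3L, all(voxel_um > 0),
            background_level >= 0)
  if (is.null(cells)) {
    cells <- data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                        radius_um = numeric(), peak = numeric(),
                        channel = character(), partner = integer())
  }
  cells <- as.data.frame(cells)
  if (nrow(cells)) {
    req <- c("x_um", "y_um", "z_um", "radius_um", "peak", "channel")
    if (!all(req %in% names(cells)))
      stop("cells must have columns ", paste(req, collapse = ", "))
    inside <- cells$x_um >= 0 & cells$x_um <= volume_um[1] &
              cells$y_um >= 0 & cells$y_um <= volume_um[2] &
              cells$z_um >= 0 & cells$z_um <= volume_um[3]
    if (!all(inside)) stop(sum(!inside), " cell centre(s) outside the volume")
    if (any(cells$radius_um <= 0)) stop("cell radii must be positive")
    if (any(cells$peak < 0)) stop("cell intensities must be nonnegative")
    if (is.null(cells$partner)) cells$partner <- NA_integer_
    if (is.null(cells$id)) cells$id <- seq_len(nrow(cells))
  } else {
    cells$id <- integer()
  }
  structure(list(volume_um = as.numeric(volume_um),
                 voxel_um = as.numeric(voxel_um),
                 cells = cells, dendrites = dendrites,
                 background_level = background_level,
                 noise = noise, seed = as.integer(seed)),
            class = "phantom_spec")
}

# truncated separable Gaussian blob and its target index ranges; the
# caller adds it in place (avoids copying the full volume per cell)
blob_patch <- function(d, centre_vox, sigma_vox, peak, trunc = 3) {
  lo <- pmax(1L, as.integer(ceiling(centre_vox - trunc * sigma_vox + 1)))
  hi <- pmin(d, as.integer(floor(centre_vox + trunc * sigma_vox + 1)))
  if (any(lo > hi)) return(NULL)
  gx <- exp(-((lo[1]:hi[1]) - 1 - centre_vox[1])^2 / (2 * sigma_vox[1]^2))
  gy <- exp(-((lo[2]:hi[2]) - 1 - centre_vox[2])^2 / (2 * sigma_vox[2]^2))
  gz <- exp(-((lo[3]:hi[3]) - 1 - centre_vox[3])^2 / (2 * sigma_vox[3]^2))
  list(ix = lo[1]:hi[1], iy = lo[2]:hi[2], iz = lo[3]:hi[3],
       patch = peak * outer(outer(gx, gy), gz))
}

#' Render a phantom specification into two-channel volumes plus truth
#'
#' Deterministic given \code{spec$seed}. Somata are additive truncated
#' Gaussians; dendrites are rendered as chains of small Gaussian profiles
#' along their polylines; Poisson shot noise is applied to the noiseless
#' signal, then Gaussian read noise, then the result is rounded and
#' clipped to the 16-bit range.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list of class \code{visor_phantom} with elements
#'   \code{channels} (named list of \code{\link{vol3d}}) and \code{truth}
#'   (cell table, per-region counts if a \code{region} column is present,
#'   volume/voxel bookkeeping).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dims <- pmax(2L, as.integer(round(spec$volume_um / spec$voxel_um)))
  chans <- unique(c("red", "green", as.character(spec$cells$channel)))
  out <- list()
  for (ch in chans) {
    a <- array(spec$background_level, dim = dims)
    cc <- spec$cells[spec$cells$channel == ch, , drop = FALSE]
    if (nrow(cc)) for (i in seq_len(nrow(cc))) {
      ctr <- c(cc$x_um[i], cc$y_um[i], cc$z_um[i]) / spec$voxel_um
      sig <- (cc$radius_um[i] / 2) / spec$voxel_um
      b <- blob_patch(dims, ctr, sig, cc$peak[i])
      if (!is.null(b))
        a[b$ix, b$iy, b$iz] <- a[b$ix, b$iy, b$iz] + b$patch
    }
    for (tube in spec$dendrites) {
      if (!identical(tube$channel %||% "red", ch)) next
      for (b in tube_patches(dim(a), tube, spec$voxel_um))
        a[b$ix, b$iy, b$iz] <- a[b$ix, b$iy, b$iz] + b$patch
    }
    if (isTRUE(spec$noise$poisson)) {
      a[] <- stats::rpois(length(a), lambda = pmax(a, 0))
    }
    rs <- spec$noise$read_sigma %||% 0
    if (rs > 0) a[] <- a + stats::rnorm(length(a), 0, rs)
    a[] <- pmin(pmax(round(a), 0), 65535)
    out[[ch]] <- vol3d(a, voxel_um = spec$voxel_um)
  }
  truth <- list(cells = spec$cells,
                volume_um = spec$volume_um, voxel_um = spec$voxel_um,
                seed = spec$seed)
  if (!is.null(spec$cells$region) && nrow(spec$cells))
    truth$region_counts <- as.data.frame(table(region = spec$cells$region,
                                               channel = spec$cells$channel),
                                         responseName = "count")
  structure(list(channels = out, truth = truth), class = "visor_phantom")
}

tube_patches <- function(d, tube, voxel_um) {
  path <- tube$path
  if (is.null(dim(path))) path <- matrix(path, ncol = 3, byrow = TRUE)
  sig <- (tube$radius_um / 2)
  step <- min(voxel_um) / 2
  out <- list()
  for (s in seq_len(nrow(path) - 1L)) {
    p0 <- path[s, ]; p1 <- path[s + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    n <- max(2L, ceiling(len / step))
    t <- seq(0, 1, length.out = n)
    # scale so the summed profile along the axis has roughly the target
    # peak intensity regardless of sampling density
    peak <- tube$intensity * step / (sqrt(2 * pi) * sig)
    for (i in seq_len(n)) {
      ctr <- (p0 + t[i] * (p1 - p0)) / voxel_um
      b <- blob_patch(d, ctr, rep(sig, 3) / voxel_um, peak, trunc = 2.5)
      if (!is.null(b)) out[[length(out) + 1L]] <- b
    }
  }
  out
}

#' @export
print.visor_phantom <- function(x, ...) {
  cat(sprintf("visor_phantom: %d channel(s), %d ground-truth cells\n",
              length(x$channels), nrow(x$truth$cells)))
  for (ch in names(x$channels)) {
    d <- dim(x$channels[[ch]])
    cat(sprintf("  %-6s %d x %d x %d voxels, %d cells\n", ch,
                d[1], d[2], d[3], sum(x$truth$cells$channel == ch)))
  }
  invisible(x)
}

#' Place cell centres on a jittered lattice with a guaranteed separation
#'
#' Samples \code{n} sites from a cubic lattice of the given pitch
#' restricted to a box (optionally to an inscribed ellipsoid, for
#' cluster-like nuclei), then jitters each by at most \code{jitter_um}.
#' Any two centres are at least \code{pitch_um - 2 * jitter_um} apart,
#' which keeps phantoms resolvable by a blob detector of matched scale.
#'
#' @param n number of centres.
#' @param lo_um,hi_um length-3 corners of the placement box, um.
#' @param pitch_um lattice pitch, um.
#' @param jitter_um maximum absolute jitter per axis, um.
#' @param ellipsoid if TRUE restrict sites to the ellipsoid inscribed in
#'   the box (a dense-cluster layout).
#' @return n x 3 matrix of centres (um). Errors if the lattice holds
#'   fewer than \code{n} sites.
#' @export
place_cells_lattice <- function(n, lo_um, hi_um, pitch_um = 22,
                                jitter_um = 2, ellipsoid = FALSE) {
  gx <- seq(lo_um[1] + pitch_um / 2, hi_um[1] - pitch_um / 2, by = pitch_um)
  gy <- seq(lo_um[2] + pitch_um / 2, hi_um[2] - pitch_um / 2, by = pitch_um)
  gz <- seq(lo_um[3] + pitch_um / 2, hi_um[3] - pitch_um / 2, by = pitch_um)
  sites <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  if (ellipsoid) {
    c0 <- (lo_um + hi_um) / 2
    ax <- (hi_um - lo_um) / 2
    r2 <- ((sites[, 1] - c0[1]) / ax[1])^2 + ((sites[, 2] - c0[2]) / ax[2])^2 +
          ((sites[, 3] - c0[3]) / ax[3])^2
    sites <- sites[r2 <= 1, , drop = FALSE]
  }
  if (nrow(sites) < n)
    stop("lattice holds only ", nrow(sites), " sites; need ", n)
  pick <- sites[sample.int(nrow(sites), n), , drop = FALSE]
  pick + matrix(stats::runif(3 * n, -jitter_um, jitter_um), ncol = 3)
}
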