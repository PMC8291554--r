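#' Built-in phantom presets
#'
#' Ready-made ground-truthed phantoms emulating the package's reference
#' experiments. All sizes in um; cells are placed on a jittered lattice
#' (pitch 22, jitter 2) so any two same-channel centres are >= 18 um
#' apart, above the resolution limit of the default matched-scale blob
#' detector; colabelled nuclei sit exactly at their partner soma centre.
#'
#' \describe{
#'   \item{\code{pvn_phantom}}{Dense cluster of red (CRH-like) somata in
#'   an ellipsoid, a printed fraction of which carry a green (c-Fos-like)
#'   nucleus. Defaults: 834 somata, 430 colabelled, all green cells
#'   colabelled.}
#'   \item{\code{mea_phantom}}{Dispersed somata with a near-orthogonal
#'   green population. Defaults: 1018 red, 569 green of which 104
#'   colabelled.}
#'   \item{\code{soma_phantom}}{Single-channel noiseless phantom (200
#'   somata) for detector precision/recall scoring.}
#' }
#'
#' @param n_red,n_green,n_double class totals (green includes the
#'   colabelled cells).
#' @param n_cells soma count of the single-channel phantom.
#' @param seed RNG seed fixing placement and noise.
#' @param noise noise spec passed to \code{\link{phantom_spec}}.
#' @return a \code{\link{phantom_spec}}.
#' @name phantom_presets
NULL

two_channel_spec <- function(centres, n_red, n_green, n_double, volume_um,
                             radius_red = 5, radius_green = 4.5,
                             peak = c(900, 1500), seed = 0L,
                             noise = list(poisson = TRUE, read_sigma = 2)) {
  n_sites <- n_red + (n_green - n_double)
  stopifnot(nrow(centres) >= n_sites)
  red_idx <- seq_len(n_red)
  dbl_idx <- seq_len(n_double)                 # first doubles host a nucleus
  grn_only <- n_red + seq_len(n_green - n_double)
  pk <- function(n) stats::runif(n, peak[1], peak[2])
  red <- data.frame(x_um = centres[red_idx, 1], y_um = centres[red_idx, 2],
                    z_um = centres[red_idx, 3], radius_um = radius_red,
                    peak = pk(n_red), channel = "red",
                    partner = NA_integer_)
  grn_at <- c(dbl_idx, grn_only)
  grn <- data.frame(x_um = centres[grn_at, 1], y_um = centres[grn_at, 2],
                    z_um = centres[grn_at, 3], radius_um = radius_green,
                    peak = pk(n_green), channel = "green",
                    partner = c(dbl_idx, rep(NA_integer_, n_green - n_double)))
  cells <- rbind(red, grn)
  cells$id <- seq_len(nrow(cells))
  phantom_spec(volume_um = volume_um, voxel_um = c(1, 1, 3), cells = cells,
               background_level = 100, noise = noise, seed = seed)
}

#' @rdname phantom_presets
#' @export
pvn_phantom <- function(n_red = 834, n_green = 430, n_double = 430,
                        seed = 0L,
                        noise = list(poisson = TRUE, read_sigma = 2)) {
  set.seed(seed)
  # dense nucleus (ellipsoidal cluster) inside a darker surrounding field,
  # as a hypothalamic nucleus appears in a coronal section
  vol <- c(640, 640, 162)
  n_sites <- n_red + (n_green - n_double)
  centres <- place_cells_lattice(n_sites, lo_um = c(90, 90, 15),
                                 hi_um = vol - c(90, 90, 15),
                                 pitch_um = 22, jitter_um = 2,
                                 ellipsoid = TRUE)
  two_channel_spec(centres, n_red, n_green, n_double, vol, seed = seed,
                   noise = noise)
}

#' @rdname phantom_presets
#' @export
mea_phantom <- function(n_red = 1018, n_green = 569, n_double = 104,
                        seed = 0L,
                        noise = list(poisson = TRUE, read_sigma = 2)) {
  set.seed(seed)
  vol <- c(560, 560, 162)
  n_sites <- n_red + (n_green - n_double)
  centres <- place_cells_lattice(n_sites, lo_um = c(25, 25, 15),
                                 hi_um = vol - c(25, 25, 15),
                                 pitch_um = 22, jitter_um = 2,
                                 ellipsoid = FALSE)
  two_channel_spec(centres, n_red, n_green, n_double, vol, seed = seed,
                   noise = noise)
}

#' @rdname phantom_presets
#' @export
soma_phantom <- function(n_cells = 200, seed = 0L,
                         noise = list(poisson = FALSE, read_sigma = 0)) {
  set.seed(seed)
  vol <- c(300, 300, 126)
  centres <- place_cells_lattice(n_cells, lo_um = c(20, 20, 12),
                                 hi_um = vol - c(20, 20, 12),
                                 pitch_um = 22, jitter_um = 2)
  cells <- data.frame(x_um = centres[, 1], y_um = centres[, 2],
                      z_um = centres[, 3], radius_um = 5,
                      peak = stats::runif(n_cells, 900, 1500),
                      channel = "red", partner = NA_integer_)
  phantom_spec(volume_um = vol, voxel_um = c(1, 1, 3), cells = cells,
               background_level = 100, noise = noise, seed = seed)
}

#' @rdname phantom_presets
#' @param n_cells soma count.
#' @param volume_um phantom extent.
#' @export
texture_phantom <- function(n_cells = 1100, volume_um = c(240, 240, 120),
                            seed = 0L,
                            noise = list(poisson = FALSE, read_sigma = 0)) {
  set.seed(seed)
  cells <- data.frame(
    x_um = stats::runif(n_cells, 12, volume_um[1] - 12),
    y_um = stats::runif(n_cells, 12, volume_um[2] - 12),
    z_um = stats::runif(n_cells, 6, volume_um[3] - 6),
    radius_um = stats::runif(n_cells, 5, 10),
    peak = stats::runif(n_cells, 300, 1500),
    channel = "red", partner = NA_integer_)
  phantom_spec(volume_um = volume_um, voxel_um = c(1, 1, 3), cells = cells,
               background_level = 100, noise = noise, seed = seed)
}

#' Dual-channel detection and colocalization on a rendered phantom
#'
#' Detects cells independently in the red and green channels and pairs
#' them by mutual nearest neighbours, reporting per-class and
#' double-positive counts.
#'
#' @param phantom a rendered \code{visor_phantom} (or a
#'   \code{\link{phantom_spec}}, rendered on the fly).
#' @param cfg a \code{\link{detector_config}}.
#' @param radius_um colocalization radius, um (default = default cell
#'   radius).
#' @return list: \code{n_red}, \code{n_green}, \code{n_double},
#'   \code{records} (both channels' tables), \code{coloc}.
#' @export
dual_channel_recovery <- function(phantom, cfg = detector_config(),
                                  radius_um = 5) {
  if (inherits(phantom, "phantom_spec")) phantom <- render_phantom(phantom)
  red <- detect_cells(phantom$channels$red, cfg, channel = "red")
  grn <- detect_cells(phantom$channels$green, cfg, channel = "green")
  cl <- colocalize(red, grn, radius_um = radius_um)
  list(n_red = cl$n_a, n_green = cl$n_b, n_double = cl$n_double,
       records = rbind(red, grn), coloc = cl)
}
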