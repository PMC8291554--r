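#' Tone-mapping configuration
#'
#' Parameters of the progressive HDR tone mapper. Processing happens in
#' the log domain: the log image is split by an edge-preserving bilateral
#' filter into a smooth base layer (large-scale brightness) and a detail
#' layer (local contrast); only the base is compressed, step by step,
#' before recombination, so somata and fibre bundles tens of thousands of
#' counts bright and spines a few hundred counts dim both stay visible in
#' 8 bits.
#'
#' @param spatial_sigma_px spatial sigma of the bilateral filter, px.
#' @param range_sigma range sigma in log-intensity units; NULL (default)
#'   selects it adaptively as \code{0.4 * (p95 - p5)} of the local
#'   log-gradient magnitudes of the image.
#' @param n_steps number of progressive compression steps (>= 1).
#' @param factor per-step base dynamic-range multiplier in (0, 1].
#' @param output_bits output bit depth (8).
#' @return list of class \code{tonemap_config}.
#' @export
tonemap_config <- function(spatial_sigma_px = 6, range_sigma = NULL,
                           n_steps = 3L, factor = 0.6, output_bits = 8L) {
  stopifnot(spatial_sigma_px > 0, n_steps >= 1, factor > 0, factor <= 1)
  if (!is.null(range_sigma)) stopifnot(range_sigma > 0)
  structure(list(spatial_sigma_px = spatial_sigma_px,
                 range_sigma = range_sigma, n_steps = as.integer(n_steps),
                 factor = factor, output_bits = as.integer(output_bits)),
            class = "tonemap_config")
}

# brute-force shift-and-accumulate bilateral filter (edge-preserving)
bilateral_filter <- function(img, spatial_sigma, range_sigma) {
  r <- max(1L, ceiling(2 * spatial_sigma))
  nx <- nrow(img); ny <- ncol(img)
  acc <- matrix(0, nx, ny); wacc <- matrix(0, nx, ny)
  for (di in -r:r) for (dj in -r:r) {
    ws <- exp(-(di^2 + dj^2) / (2 * spatial_sigma^2))
    if (ws < 1e-4) next
    xi <- seq_len(nx) + di; yj <- seq_len(ny) + dj
    okx <- xi >= 1 & xi <= nx; oky <- yj >= 1 & yj <= ny
    sh <- matrix(NA_real_, nx, ny)
    sh[okx, oky] <- img[xi[okx], yj[oky]]
    wr <- exp(-(sh - img)^2 / (2 * range_sigma^2)) * ws
    wr[is.na(sh)] <- 0; sh[is.na(sh)] <- 0
    acc <- acc + wr * sh
    wacc <- wacc + wr
  }
  acc / wacc
}

adaptive_range_sigma <- function(logimg) {
  g <- grad_mag(logimg)
  qs <- stats::quantile(g, c(0.05, 0.95), names = FALSE)
  max(0.4 * (qs[2] - qs[1]), 1e-3)
}

#' Decompose a 16-bit image into bilateral base and detail layers
#'
#' base = bilateral filter of log(1 + image); detail = log(1 + image) -
#' base. The decomposition is exact by construction: base + detail
#' reconstructs the log input to machine precision.
#'
#' @param image16 numeric matrix of nonnegative intensities.
#' @param cfg a \code{\link{tonemap_config}}.
#' @return list(base, detail, range_sigma) of matrices in log units.
#' @export
bilateral_decompose <- function(image16, cfg = tonemap_config()) {
  stopifnot(length(image16) > 0, all(image16 >= 0))
  L <- log1p(image16)
  rs <- cfg$range_sigma %||% adaptive_range_sigma(L)
  base <- bilateral_filter(L, cfg$spatial_sigma_px, rs)
  list(base = base, detail = L - base, range_sigma = rs)
}

#' Progressively compress the dynamic range of a base layer
#'
#' Applies \code{n_steps} global range scalings about the current base
#' midpoint; each step multiplies the base dynamic range by
#' \code{factor}, so k steps scale it by factor^k. The adaptive range
#' sigma is recomputed from the current base after every step and
#' recorded (it parameterizes any subsequent decomposition of the
#' compressed base).
#'
#' @param base base-layer matrix (log units).
#' @param cfg a \code{\link{tonemap_config}}.
#' @return compressed base with attribute \code{range_sigmas}.
#' @export
progressive_compress <- function(base, cfg = tonemap_config()) {
  rs <- numeric(cfg$n_steps)
  for (s in seq_len(cfg$n_steps)) {
    mid <- mean(range(base))
    base <- mid + cfg$factor * (base - mid)
    rs[s] <- adaptive_range_sigma(base)
  }
  attr(base, "range_sigmas") <- rs
  base
}

#' Tone-map a 16-bit image to 8 bits
#'
#' Bilateral base/detail decomposition in the log domain, progressive
#' base compression, recombination with the uncompressed detail layer,
#' exponentiation and affine rescaling to [0, 255]. Rescaling anchors
#' default to the recombined image's own range (\code{anchors} lets a
#' caller impose per-volume anchors so that all planes of a brain share
#' one mapping).
#'
#' @param image16 numeric matrix of nonnegative intensities.
#' @param cfg a \code{\link{tonemap_config}}.
#' @param anchors optional c(lo, hi) recombined-log-domain anchors.
#' @return integer matrix in [0, 255].
#' @export
tonemap <- function(image16, cfg = tonemap_config(), anchors = NULL) {
  if (max(image16) <= 0) return(matrix(0L, nrow(image16), ncol(image16)))
  dec <- bilateral_decompose(image16, cfg)
  comp <- progressive_compress(dec$base, cfg)
  rec <- comp + dec$detail
  if (is.null(anchors)) anchors <- range(rec)
  span <- max(anchors[2] - anchors[1], 1e-6)
  out <- (rec - anchors[1]) / span
  matrix(as.integer(pmin(pmax(round(out * (2^cfg$output_bits - 1)), 0),
                         2^cfg$output_bits - 1)),
         nrow(image16), ncol(image16))
}
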