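#' Detector configuration
#'
#' Parameters of the three-step soma/nucleus detector: difference-of-
#' Gaussian maxima on 4x-downsized 2D planes, local patch thresholding
#' with seeded watershed splitting, then 3D linking of per-plane segments
#' across neighbouring planes. Detection is 2D-then-link rather than 3D
#' blob detection, which is what the anisotropic native sampling (fine
#' in-plane, coarse axially) calls for.
#'
#' DoG sigmas derive from the predefined cell size: sigma1 =
#' cell_size_px / (4 * sqrt(2)) at the downsampled scale, sigma2 =
#' 2 * sigma1.
#'
#' @param cell_size_um predefined cell diameter, um.
#' @param downsample integer downsizing factor for the DoG stage.
#' @param volume_range_um3 (min, max) accepted 3D volume.
#' @param eccentricity_range accepted moment-ellipsoid eccentricity.
#' @param intensity_range accepted mean intensity, counts.
#' @param link_max_dist_um max centroid distance for linking segments in
#'   adjacent planes; default half the cell size.
#' @param link_min_overlap minimum area IoU for linking.
#' @param min_sections minimum number of linked planes (shorter chains
#'   are still returned but fail validation via the volume range).
#' @param noise_k local-maxima floor: median + noise_k * MAD of the DoG.
#' @return list of class \code{detector_config}.
#' @export
detector_config <- function(cell_size_um = 10, downsample = 4L,
                            volume_range_um3 = c(100, 4000),
                            eccentricity_range = c(0, 0.95),
                            intensity_range = c(0, Inf),
                            link_max_dist_um = cell_size_um / 2,
                            link_min_overlap = 0.2,
                            min_sections = 2L, noise_k = 3) {
  stopifnot(cell_size_um > 0, downsample >= 1,
            volume_range_um3[1] < volume_range_um3[2],
            eccentricity_range[1] <= eccentricity_range[2],
            intensity_range[1] <= intensity_range[2])
  structure(list(cell_size_um = cell_size_um,
                 downsample = as.integer(downsample),
                 volume_range_um3 = volume_range_um3,
                 eccentricity_range = eccentricity_range,
                 intensity_range = intensity_range,
                 link_max_dist_um = link_max_dist_um,
                 link_min_overlap = link_min_overlap,
                 min_sections = as.integer(min_sections),
                 noise_k = noise_k),
            class = "detector_config")
}

#' DoG local maxima of a 2D plane
#'
#' Downsizes by block averaging, computes the difference of two Gaussians
#' (sigma2 = 2 * sigma1), and returns strict 8-neighbourhood local maxima
#' above a robust noise floor (median + noise_k * MAD), with coordinates
#' mapped back to full resolution.
#'
#' @param image numeric matrix (full-resolution plane).
#' @param cfg a \code{\link{detector_config}}.
#' @param pixel_um in-plane pixel size, um.
#' @return data.frame (i, j) of full-resolution 1-based pixel indices
#'   plus the DoG response.
#' @export
dog_maxima <- function(image, cfg = detector_config(), pixel_um = 1) {
  f <- cfg$downsample
  cell_px <- cfg$cell_size_um / pixel_um
  s1 <- cell_px / (4 * sqrt(2))          # at the downsampled scale
  s2 <- 2 * s1
  ds <- block_mean(image, f)
  # gblur needs the image to exceed its kernel (2*ceiling(3*sigma)+1)
  pad <- ceiling(3 * max(s2, 0.6)) + 1L
  if (any(dim(ds) < 2L * pad + 1L)) {
    # reflect-pad tiny images so the Gaussian kernel fits
    ds <- pad_reflect(ds, pad)
    padded <- TRUE
  } else padded <- FALSE
  g1 <- EBImage::gblur(ds, sigma = max(s1, 0.3))
  g2 <- EBImage::gblur(ds, sigma = max(s2, 0.6))
  dog <- g1 - g2
  if (padded) dog <- dog[(pad + 1):(nrow(dog) - pad),
                         (pad + 1):(ncol(dog) - pad), drop = FALSE]
  floor_ <- stats::median(dog) + cfg$noise_k * stats::mad(dog)
  mx <- local_maxima8(dog)
  sel <- which(mx & dog > floor_, arr.ind = TRUE)
  if (!nrow(sel))
    return(data.frame(i = integer(), j = integer(), response = numeric()))
  data.frame(i = (sel[, 1] - 1L) * f + (f + 1L) %/% 2L,
             j = (sel[, 2] - 1L) * f + (f + 1L) %/% 2L,
             response = dog[sel])
}

pad_reflect <- function(m, p) {
  ri <- c(pmin(p:1 + 1L, nrow(m)), seq_len(nrow(m)),
          pmax(nrow(m) - (1:p), 1L))
  ci <- c(pmin(p:1 + 1L, ncol(m)), seq_len(ncol(m)),
          pmax(ncol(m) - (1:p), 1L))
  m[ri, ci, drop = FALSE]
}

local_maxima8 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(TRUE, nx, ny)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    sh <- matrix(-Inf, nx, ny)
    xi <- seq_len(nx) + di; yj <- seq_len(ny) + dj
    okx <- xi >= 1 & xi <= nx; oky <- yj >= 1 & yj <= ny
    sh[okx, oky] <- m[xi[okx], yj[oky]]
    out <- out & (m > sh)
  }
  out
}

#' Patch threshold around a detected peak
#'
#' Extracts the square patch of side 3 x cell size centred on the peak
#' and thresholds it at the average of the peak value and the mean of the
#' one-pixel patch border. Patches clipped by the image edge are flagged.
#'
#' @param image numeric matrix.
#' @param peak c(i, j) 1-based pixel indices.
#' @param cfg a \code{\link{detector_config}}.
#' @param pixel_um in-plane pixel size, um.
#' @return list: \code{mask} (logical matrix), \code{threshold},
#'   \code{rows}, \code{cols} (patch index ranges), \code{clipped},
#'   \code{degenerate} (TRUE when the peak does not rise above the
#'   border).
#' @export
patch_threshold <- function(image, peak, cfg = detector_config(),
                            pixel_um = 1) {
  side <- max(5L, round(3 * cfg$cell_size_um / pixel_um))
  h <- side %/% 2L
  ri <- (peak[1] - h):(peak[1] + h)
  ci <- (peak[2] - h):(peak[2] + h)
  clipped <- min(ri) < 1 || max(ri) > nrow(image) ||
             min(ci) < 1 || max(ci) > ncol(image)
  ri <- ri[ri >= 1 & ri <= nrow(image)]
  ci <- ci[ci >= 1 & ci <= ncol(image)]
  patch <- image[ri, ci, drop = FALSE]
  border <- c(patch[1, ], patch[nrow(patch), ],
              patch[-c(1, nrow(patch)), 1], patch[-c(1, nrow(patch)), ncol(patch)])
  thr <- (image[peak[1], peak[2]] + mean(border)) / 2
  mask <- patch >= thr
  list(mask = mask, threshold = thr, rows = ri, cols = ci,
       clipped = clipped,
       degenerate = image[peak[1], peak[2]] <= mean(border) + 1e-12)
}

#' Seeded watershed split of a thresholded patch
#'
#' Splits a binary patch among seed points along the intensity valleys
#' using gradient-weighted seeded region growing (EBImage::propagate)
#' restricted to the mask; one label per seed. Seeds falling outside the
#' mask get empty segments.
#'
#' @param patch numeric intensity patch.
#' @param mask logical matrix, same size.
#' @param seeds n x 2 matrix of seed (row, col) indices within the patch.
#' @return integer label matrix (0 = background, k = seed k).
#' @export
watershed_segment <- function(patch, mask, seeds) {
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 2)
  lab <- matrix(0L, nrow(patch), ncol(patch))
  inside <- mask[seeds]
  seed_img <- matrix(0L, nrow(patch), ncol(patch))
  for (s in seq_len(nrow(seeds)))
    if (inside[s]) seed_img[seeds[s, 1], seeds[s, 2]] <- s
  if (all(seed_img == 0L)) return(lab)
  rng <- range(patch)
  x <- if (diff(rng) > 0) (patch - rng[1]) / diff(rng) else patch * 0
  out <- EBImage::propagate(EBImage::Image(x), EBImage::Image(seed_img),
                            mask = EBImage::Image(mask))
  matrix(as.integer(EBImage::imageData(out)), nrow(patch), ncol(patch))
}

# detect 2D segments in one plane; returns list of segments
detect_plane <- function(image, cfg, pixel_um, plane_index) {
  pk <- dog_maxima(image, cfg, pixel_um)
  if (!nrow(pk)) return(list())
  # refine each peak at full resolution within the downsample window
  f <- cfg$downsample
  for (r in seq_len(nrow(pk))) {
    ri <- max(1L, pk$i[r] - f):min(nrow(image), pk$i[r] + f)
    ci <- max(1L, pk$j[r] - f):min(ncol(image), pk$j[r] + f)
    w <- which.max(image[ri, ci])
    pk$i[r] <- ri[(w - 1L) %% length(ri) + 1L]
    pk$j[r] <- ci[(w - 1L) %/% length(ri) + 1L]
  }
  # deduplicate refined peaks closer than half a cell
  min_d <- (cfg$cell_size_um / pixel_um) / 2
  ord <- order(-pk$response)
  keep <- logical(nrow(pk))
  for (r in ord) {
    if (any(keep & abs(pk$i - pk$i[r]) < min_d & abs(pk$j - pk$j[r]) < min_d))
      next
    keep[r] <- TRUE
  }
  pk <- pk[keep, , drop = FALSE]
  segs <- list()
  for (r in seq_len(nrow(pk))) {
    pt <- patch_threshold(image, c(pk$i[r], pk$j[r]), cfg, pixel_um)
    if (pt$degenerate) next
    patch <- image[pt$rows, pt$cols, drop = FALSE]
    # seeds: this peak plus any other surviving peak inside the patch
    in_patch <- pk$i >= min(pt$rows) & pk$i <= max(pt$rows) &
                pk$j >= min(pt$cols) & pk$j <= max(pt$cols)
    seeds <- cbind(pk$i[in_patch] - min(pt$rows) + 1L,
                   pk$j[in_patch] - min(pt$cols) + 1L)
    self <- which(which(in_patch) == r)
    lab <- if (nrow(seeds) > 1L) watershed_segment(patch, pt$mask, seeds)
           else {
             cc <- EBImage::bwlabel(pt$mask)
             sl <- cc[pk$i[r] - min(pt$rows) + 1L, pk$j[r] - min(pt$cols) + 1L]
             m <- matrix(0L, nrow(patch), ncol(patch))
             if (sl > 0) m[cc == sl] <- 1L
             `attr<-`(m, "self", 1L)
           }
    self_lab <- attr(lab, "self") %||% self
    px <- which(lab == self_lab, arr.ind = TRUE)
    if (!nrow(px)) next
    gi <- px[, 1] + min(pt$rows) - 1L
    gj <- px[, 2] + min(pt$cols) - 1L
    ints <- image[cbind(gi, gj)]
    segs[[length(segs) + 1L]] <- list(
      plane = plane_index,
      cx = sum(gi * ints) / sum(ints), cy = sum(gj * ints) / sum(ints),
      area_px = nrow(px), mean_int = mean(ints),
      pix = (gj - 1L) * nrow(image) + gi,   # linear indices in the plane
      clipped = pt$clipped)
  }
  segs
}

#' Link per-plane 2D segments into 3D cell records
#'
#' Greedy chain linking: segments in adjacent planes are linked when
#' their centroid distance is below \code{link_max_dist_um} and their
#' area IoU exceeds \code{link_min_overlap}; many-to-one candidates are
#' resolved by maximum IoU, ties by minimum centroid distance. Volume is
#' the summed segment area times the plane spacing; eccentricity is
#' sqrt(1 - lambda_min/lambda_max) of the intensity-weighted 3D
#' second-moment ellipsoid.
#'
#' @param segments list of per-plane segment lists (as built internally
#'   by \code{\link{detect_cells}}).
#' @param voxel_um length-3 voxel size, um.
#' @param cfg a \code{\link{detector_config}}.
#' @return data.frame of cell records.
#' @export
link_3d <- function(segments, voxel_um, cfg = detector_config()) {
  segs <- do.call(c, segments)
  n <- length(segs)
  if (!n)
    return(empty_cell_table())
  plane <- vapply(segs, `[[`, 1, "plane")
  cx <- vapply(segs, `[[`, 1, "cx"); cy <- vapply(segs, `[[`, 1, "cy")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  max_d_px <- cfg$link_max_dist_um / voxel_um[1]
  for (p in sort(unique(plane))) {
    a_idx <- which(plane == p); b_idx <- which(plane == p + 1L)
    if (!length(a_idx) || !length(b_idx)) next
    cand <- NULL
    for (ai in a_idx) {
      d <- sqrt((cx[b_idx] - cx[ai])^2 + (cy[b_idx] - cy[ai])^2)
      near <- which(d < max_d_px)
      for (bi in near) {
        iou <- length(intersect(segs[[ai]]$pix, segs[[b_idx[bi]]]$pix)) /
               length(union(segs[[ai]]$pix, segs[[b_idx[bi]]]$pix))
        if (iou > cfg$link_min_overlap)
          cand <- rbind(cand, c(ai, b_idx[bi], iou, d[bi]))
      }
    }
    if (is.null(cand)) next
    cand <- cand[order(-cand[, 3], cand[, 4]), , drop = FALSE]
    used_a <- used_b <- integer(0)
    for (r in seq_len(nrow(cand))) {
      ai <- as.integer(cand[r, 1]); bi <- as.integer(cand[r, 2])
      if (ai %in% used_a || bi %in% used_b) next
      ra <- find(ai); rb <- find(bi)
      if (ra != rb) parent[rb] <- ra
      used_a <- c(used_a, ai); used_b <- c(used_b, bi)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  groups <- split(seq_len(n), roots)
  recs <- lapply(seq_along(groups), function(gidx) {
    g <- groups[[gidx]]
    ar <- vapply(segs[g], `[[`, 1, "area_px")
    mi <- vapply(segs[g], `[[`, 1, "mean_int")
    w <- ar * mi
    px_area <- voxel_um[1] * voxel_um[2]
    pos <- c(sum(w * cx[g]) / sum(w) - 1, sum(w * cy[g]) / sum(w) - 1,
             sum(w * (plane[g] - 1)) / sum(w)) * voxel_um
    # second moments from segment centroids/areas (plane-wise)
    xs <- (cx[g] - 1) * voxel_um[1]; ys <- (cy[g] - 1) * voxel_um[2]
    zs <- (plane[g] - 1) * voxel_um[3]
    r_eq <- sqrt(ar * px_area / pi)       # per-plane disc radius
    mu <- pos
    cxx <- sum(w * ((xs - mu[1])^2 + r_eq^2 / 4)) / sum(w)
    cyy <- sum(w * ((ys - mu[2])^2 + r_eq^2 / 4)) / sum(w)
    czz <- sum(w * ((zs - mu[3])^2 + voxel_um[3]^2 / 12)) / sum(w)
    cxy <- sum(w * (xs - mu[1]) * (ys - mu[2])) / sum(w)
    M <- matrix(c(cxx, cxy, 0, cxy, cyy, 0, 0, 0, czz), 3)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    ecc <- if (max(ev) > 0) sqrt(max(0, 1 - min(ev) / max(ev))) else 0
    data.frame(id = gidx,
               x_um = pos[1], y_um = pos[2], z_um = pos[3],
               volume_um3 = sum(ar) * px_area * voxel_um[3],
               eccentricity = ecc,
               intensity = sum(w) / sum(ar),
               n_sections = length(g),
               clipped = any(vapply(segs[g], `[[`, TRUE, "clipped")))
  })
  do.call(rbind, recs)
}

empty_cell_table <- function() {
  data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
             z_um = numeric(), volume_um3 = numeric(),
             eccentricity = numeric(), intensity = numeric(),
             n_sections = integer(), clipped = logical())
}

#' Validate cell records against predefined feature ranges
#'
#' A record is valid iff its volume, eccentricity and mean intensity all
#' fall inside the configured ranges.
#'
#' @param records cell record data.frame (see \code{\link{link_3d}}).
#' @param cfg a \code{\link{detector_config}}.
#' @return records with a logical \code{valid} column.
#' @export
validate_cells <- function(records, cfg = detector_config()) {
  if (!nrow(records)) { records$valid <- logical(0); return(records) }
  records$valid <-
    records$volume_um3 >= cfg$volume_range_um3[1] &
    records$volume_um3 <= cfg$volume_range_um3[2] &
    records$eccentricity >= cfg$eccentricity_range[1] &
    records$eccentricity <= cfg$eccentricity_range[2] &
    records$intensity >= cfg$intensity_range[1] &
    records$intensity <= cfg$intensity_range[2]
  records
}

#' Detect cells in a 3D volume
#'
#' Runs the full three-step detector plane by plane (DoG maxima on
#' 4x-downsized planes, patch thresholding with watershed splitting,
#' 3D linking), then validates the records.
#'
#' @param vol a \code{\link{vol3d}} (or bare array with 1 um voxels).
#' @param cfg a \code{\link{detector_config}}.
#' @param channel label stored in the output.
#' @return data.frame of validated cell records (world um coordinates,
#'   volume, eccentricity, intensity, n_sections, valid).
#' @export
detect_cells <- function(vol, cfg = detector_config(), channel = NA_character_) {
  vx <- voxel_of(vol); or <- origin_of(vol)
  d <- dim(vol)
  segments <- vector("list", d[3])
  a <- unclass(vol)
  for (k in seq_len(d[3]))
    segments[[k]] <- detect_plane(a[, , k], cfg, vx[1], k)
  recs <- link_3d(segments, vx, cfg)
  if (nrow(recs)) {
    recs$x_um <- recs$x_um + or[1]
    recs$y_um <- recs$y_um + or[2]
    recs$z_um <- recs$z_um + or[3]
    recs$channel <- channel
  } else recs$channel <- character(0)
  validate_cells(recs, cfg)
}

#' Pair detections across two channels (colocalization)
#'
#' Mutual-nearest-neighbour pairing within a radius: a pair (a, b) is
#' double-positive iff b is a's nearest neighbour, a is b's, and their
#' distance is below \code{radius_um}.
#'
#' @param a,b cell record data.frames (only valid records are used when
#'   a \code{valid} column is present).
#' @param radius_um pairing radius, um; a cell radius is a sensible
#'   default.
#' @return list: \code{n_a}, \code{n_b}, \code{n_double}, \code{pairs}
#'   (indices into the filtered tables plus distance).
#' @export
colocalize <- function(a, b, radius_um = 5) {
  if (!is.null(a$valid)) a <- a[a$valid, , drop = FALSE]
  if (!is.null(b$valid)) b <- b[b$valid, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  if (!na || !nb)
    return(list(n_a = na, n_b = nb, n_double = 0L,
                pairs = data.frame(i = integer(), j = integer(),
                                   dist_um = numeric())))
  A <- as.matrix(a[, c("x_um", "y_um", "z_um")])
  B <- as.matrix(b[, c("x_um", "y_um", "z_um")])
  nn_ab <- integer(na); d_ab <- numeric(na)
  for (i in seq_len(na)) {
    d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 + (B[, 3] - A[i, 3])^2
    nn_ab[i] <- which.min(d2); d_ab[i] <- sqrt(min(d2))
  }
  nn_ba <- integer(nb)
  for (j in seq_len(nb)) {
    d2 <- (A[, 1] - B[j, 1])^2 + (A[, 2] - B[j, 2])^2 + (A[, 3] - B[j, 3])^2
    nn_ba[j] <- which.min(d2)
  }
  mutual <- which(d_ab <= radius_um & nn_ba[nn_ab] == seq_len(na))
  list(n_a = na, n_b = nb, n_double = length(mutual),
       pairs = data.frame(i = mutual, j = nn_ab[mutual],
                          dist_um = d_ab[mutual]))
}

#' Apply an affine transform to cell record coordinates
#'
#' Used to carry detections into atlas space once an external
#' registration supplies the transform. The matrix is 3x4 (linear part
#' and translation) or 4x4 homogeneous; it must be non-singular.
#'
#' @param records cell record data.frame.
#' @param matrix affine matrix.
#' @return records with transformed coordinates.
#' @export
apply_affine <- function(records, matrix) {
  if (all(dim(matrix) == c(4, 4))) matrix <- matrix[1:3, , drop = FALSE]
  stopifnot(all(dim(matrix) == c(3, 4)))
  if (abs(det(matrix[, 1:3])) < 1e-12) stop("singular affine matrix")
  if (!nrow(records)) return(records)
  X <- t(cbind(as.matrix(records[, c("x_um", "y_um", "z_um")]), 1))
  Y <- t(matrix %*% X)
  records$x_um <- Y[, 1]; records$y_um <- Y[, 2]; records$z_um <- Y[, 3]
  records
}

#' Match detections to ground truth
#'
#' Greedy nearest pairing within a radius; reports precision/recall.
#'
#' @param records detected records (valid only if flagged).
#' @param truth_xyz n x 3 matrix of true positions, um.
#' @param radius_um match radius.
#' @return list(n_true, n_det, n_matched, precision, recall).
#' @export
match_to_truth <- function(records, truth_xyz, radius_um = 5) {
  if (!is.null(records$valid)) records <- records[records$valid, , drop = FALSE]
  nd <- nrow(records); nt <- nrow(truth_xyz)
  if (!nd || !nt)
    return(list(n_true = nt, n_det = nd, n_matched = 0L,
                precision = 0, recall = 0))
  D <- as.matrix(records[, c("x_um", "y_um", "z_um")])
  used <- logical(nd); matched <- 0L
  for (t in seq_len(nt)) {
    d2 <- (D[, 1] - truth_xyz[t, 1])^2 + (D[, 2] - truth_xyz[t, 2])^2 +
          (D[, 3] - truth_xyz[t, 3])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (sqrt(d2[j]) <= radius_um) { used[j] <- TRUE; matched <- matched + 1L }
  }
  list(n_true = nt, n_det = nd, n_matched = matched,
       precision = matched / nd, recall = matched / nt)
}
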