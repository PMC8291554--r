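#' Deskew an oblique frame stream onto a world-axis-aligned grid
#'
#' Resamples an \code{image_column} (frames acquired at a tilt while the
#' stage moved) onto an axis-aligned micrometre grid by inverting the
#' shear mapping of \code{\link{oblique_to_world}} with trilinear
#' interpolation in (frame, row, col) index space. Output in-plane
#' spacing is the camera pixel size; axial spacing defaults to the native
#' frame axial step (anisotropic voxels are kept, not isotropized).
#'
#' @param col an \code{image_column} from
#'   \code{\link{simulate_acquisition}} (or built from files).
#' @param axial_step_um output z spacing, um; default the geometry's
#'   axial step.
#' @return a \code{\link{vol3d}} in world coordinates.
#' @export
stack_column <- function(col, axial_step_um = NULL) {
  if (is.null(col$geometry)) stop("image column carries no geometry")
  g <- col$geometry
  vg <- voxel_grid(g)
  th <- g$tilt_angle_deg * pi / 180
  dz <- axial_step_um %||% vg$axial_step_um
  fdim <- dim(col$frames)                     # (frame, row, col)
  o <- g$column_origin_um
  fs <- vg$frame_step_um
  x_max <- o[1] + (fdim[1] - 1) * fs + (fdim[2] - 1) * vg$pixel_um * cos(th)
  xs <- seq(o[1], x_max, by = vg$pixel_um)
  ys <- seq(o[2], o[2] + (fdim[3] - 1) * vg$pixel_um, by = vg$pixel_um)
  zs <- seq(o[3], o[3] - (fdim[2] - 1) * vg$pixel_um * sin(th), by = -dz)
  out <- array(0, dim = c(length(xs), length(ys), length(zs)))
  fvol <- vol3d(col$frames, voxel_um = c(1, 1, 1))  # index space
  for (k in seq_along(zs)) {
    pts <- cbind(rep(xs, times = length(ys)),
                 rep(ys, each = length(xs)),
                 zs[k])
    frc <- world_to_oblique(g, pts)
    out[, , k] <- interp_trilinear(fvol, frc)
  }
  vol3d(out, voxel_um = c(vg$pixel_um, vg$pixel_um, dz),
        origin_um = c(o[1], o[2], zs[length(zs)]))[, , rev(seq_along(zs)),
                                                   drop = FALSE] -> a
  # store with z increasing (origin at deepest plane)
  vol3d(a, voxel_um = c(vg$pixel_um, vg$pixel_um, dz),
        origin_um = c(o[1], o[2], min(zs)))
}

phase_correlate <- function(a, b) {
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  cp <- Fa * Conj(Fb)
  m <- Mod(cp); m[m < 1e-12] <- 1e-12
  r <- Re(stats::fft(cp / m, inverse = TRUE))
  pk <- which.max(r)
  d <- dim(a)
  idx <- arrayInd(pk, d) - 1L
  # wrap to signed shifts
  ifelse(idx > d / 2, idx - d, idx)
}

ncc3 <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den < 1e-12) return(0)
  sum(a * b) / den
}

# NCC of b shifted by s against a (overlapping part only)
ncc_shift <- function(a, b, s) {
  d <- dim(a)
  ia <- lapply(1:3, function(k) {
    lo <- max(1L, 1L + s[k]); hi <- min(d[k], d[k] + s[k])
    if (lo > hi) return(NULL)
    lo:hi
  })
  if (any(vapply(ia, is.null, TRUE))) return(-Inf)
  ib <- lapply(1:3, function(k) ia[[k]] - s[k])
  av <- a[ia[[1]], ia[[2]], ia[[3]], drop = FALSE]
  bv <- b[ib[[1]], ib[[2]], ib[[3]], drop = FALSE]
  if (length(av) < 8) return(-Inf)
  ncc3(av, bv)
}

#' Estimate the offset between two overlapping subvolumes
#'
#' Background-subtracted normalized cross-correlation restricted to the
#' nominal overlap region, initialized by FFT phase correlation and
#' refined over a small integer-voxel neighbourhood. When the nominal
#' overlap is thinner than 16 voxels in any axis, or the correlation
#' score falls below \code{min_score}, the edge is flagged low-confidence
#' and the nominal (stage-coordinate) offset is returned.
#'
#' @param a,b \code{\link{vol3d}} subvolumes with identical voxel spacing
#'   and world origins (their nominal placement).
#' @param min_score NCC below which the estimate falls back to nominal.
#' @param refine half-width (voxels) of the NCC refinement search around
#'   the phase-correlation peak.
#' @return list: \code{offset_um} (measured origin_b - origin_a),
#'   \code{offset_vox}, \code{score}, \code{fallback}.
#' @export
estimate_pair_offset <- function(a, b, min_score = 0.3, refine = 2L) {
  vx <- voxel_of(a)
  stopifnot(all(abs(vx - voxel_of(b)) < 1e-9))
  oa <- origin_of(a); ob <- origin_of(b)
  nominal_um <- ob - oa
  # nominal overlap window in world coordinates
  lo <- pmax(oa, ob)
  hi <- pmin(oa + (dim(a) - 1) * vx, ob + (dim(b) - 1) * vx)
  n_ov <- floor((hi - lo) / vx) + 1
  if (any(n_ov < 16)) {
    return(list(offset_um = nominal_um, offset_vox = round(nominal_um / vx),
                score = 0, fallback = TRUE))
  }
  ia <- lapply(1:3, function(k) {
    s <- round((lo[k] - oa[k]) / vx[k]) + 1L; s:(s + n_ov[k] - 1L)
  })
  ib <- lapply(1:3, function(k) {
    s <- round((lo[k] - ob[k]) / vx[k]) + 1L; s:(s + n_ov[k] - 1L)
  })
  ca <- unclass(a)[ia[[1]], ia[[2]], ia[[3]], drop = FALSE]
  cb <- unclass(b)[ib[[1]], ib[[2]], ib[[3]], drop = FALSE]
  ca <- ca - mean(ca); cb <- cb - mean(cb)
  s0 <- phase_correlate(ca, cb)
  cand <- as.matrix(expand.grid(dx = -refine:refine, dy = -refine:refine,
                                dz = -refine:refine))
  cand <- sweep(cand, 2, as.numeric(s0), "+")
  scores <- apply(cand, 1, function(s) ncc_shift(ca, cb, as.integer(s)))
  best <- which.max(scores)
  s_best <- as.integer(cand[best, ])
  score <- scores[best]
  if (!is.finite(score) || score < min_score) {
    return(list(offset_um = nominal_um, offset_vox = round(nominal_um / vx),
                score = max(score, 0), fallback = TRUE))
  }
  # b appears shifted by s_best inside the nominal overlap: measured
  # origin correction is -s_best voxels applied to b
  off_um <- nominal_um + s_best * vx
  list(offset_um = off_um, offset_vox = round(off_um / vx),
       score = score, fallback = FALSE)
}

#' Solve global column origins from pairwise offsets
#'
#' Weighted least squares over the pairwise offset edges (weights =
#' correlation scores), with the first column of every connected
#' component anchored at its nominal origin. Disconnected components are
#' each anchored at nominal coordinates with a warning.
#'
#' @param edges data.frame with columns \code{i, j, dx, dy, dz, score}
#'   (offset_um = origin_j - origin_i).
#' @param nominal n x 3 matrix of nominal origins, um.
#' @return list: \code{origins} (n x 3 um), \code{residuals} per edge.
#' @export
solve_global_offsets <- function(edges, nominal) {
  n <- nrow(nominal)
  if (n == 1L || is.null(edges) || nrow(edges) == 0L)
    return(list(origins = nominal, residuals = numeric(0)))
  # connected components by BFS
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (e in seq_len(nrow(edges))) {
    i <- edges$i[e]; j <- edges$j[e]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  comp <- rep(NA_integer_, n); nc <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    nc <- nc + 1L; queue <- s; comp[s] <- nc
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]][is.na(comp[adj[[v]]])]
      comp[nb] <- nc; queue <- c(queue, nb)
    }
  }
  if (nc > 1L)
    warning(nc, " disconnected components; each anchored at nominal origin")
  origins <- nominal
  offs <- as.matrix(edges[, c("dx", "dy", "dz")])
  # quadratic weight = score^2: near-perfect correlations dominate and
  # low-confidence edges contribute little
  w <- pmax(edges$score, 1e-3)
  for (cmp in seq_len(nc)) {
    nodes <- which(comp == cmp)
    if (length(nodes) == 1L) next
    anchor <- nodes[1]
    sel <- which(edges$i %in% nodes & edges$j %in% nodes)
    idx <- match(seq_len(n), nodes)     # node -> position in component
    A <- matrix(0, length(sel) + 1L, length(nodes))
    A[cbind(seq_along(sel), idx[edges$i[sel]])] <- -w[sel]
    A[cbind(seq_along(sel), idx[edges$j[sel]])] <- w[sel]
    A[length(sel) + 1L, idx[anchor]] <- 1
    for (ax in 1:3) {
      bvec <- c(w[sel] * offs[sel, ax], nominal[anchor, ax])
      fit <- qr.solve(A, bvec)
      origins[nodes, ax] <- fit
    }
  }
  res <- origins[edges$j, , drop = FALSE] - origins[edges$i, , drop = FALSE] - offs
  list(origins = origins, residuals = sqrt(rowSums(res^2)))
}

#' Build the pairwise offset graph over a set of columns
#'
#' Runs \code{\link{estimate_pair_offset}} for every pair of subvolumes
#' whose nominal bounding boxes overlap.
#'
#' @param vols list of \code{\link{vol3d}} (deskewed columns).
#' @return edge data.frame (i, j, dx, dy, dz, score, fallback).
#' @export
offset_graph <- function(vols) {
  n <- length(vols)
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    oa <- origin_of(vols[[i]]); ob <- origin_of(vols[[j]])
    vx <- voxel_of(vols[[i]])
    lo <- pmax(oa, ob)
    hi <- pmin(oa + (dim(vols[[i]]) - 1) * vx, ob + (dim(vols[[j]]) - 1) * vx)
    if (any(hi < lo)) next
    e <- estimate_pair_offset(vols[[i]], vols[[j]])
    edges <- rbind(edges, data.frame(i = i, j = j, dx = e$offset_um[1],
                                     dy = e$offset_um[2], dz = e$offset_um[3],
                                     score = e$score, fallback = e$fallback))
  }
  edges
}

#' Fuse columns into one volume with linear feather blending
#'
#' Places each subvolume at its solved origin (rounded to the common
#' voxel grid) and blends overlaps with separable linear feather weights
#' spanning the full overlap, so the output is a convex combination of
#' the inputs.
#'
#' @param vols list of \code{\link{vol3d}} with identical voxel spacing.
#' @param origins n x 3 matrix of solved world origins, um; defaults to
#'   each volume's own origin.
#' @return fused \code{\link{vol3d}}.
#' @export
fuse_columns <- function(vols, origins = NULL) {
  vx <- voxel_of(vols[[1]])
  if (is.null(origins))
    origins <- do.call(rbind, lapply(vols, origin_of))
  lo <- apply(origins, 2, min)
  hi <- sapply(1:3, function(k)
    max(origins[, k] + (vapply(vols, function(v) dim(v)[k], 1L) - 1) * vx[k]))
  nd <- as.integer(round((hi - lo) / vx)) + 1L
  acc <- array(0, nd); wacc <- array(0, nd)
  for (m in seq_along(vols)) {
    d <- dim(vols[[m]])
    start <- as.integer(round((origins[m, ] - lo) / vx)) + 1L
    fw <- lapply(1:3, function(k) {
      i <- seq_len(d[k]); pmin(i, d[k] + 1L - i) / ((d[k] + 1) / 2)
    })
    w <- outer(outer(fw[[1]], fw[[2]]), fw[[3]])
    ix <- start[1]:(start[1] + d[1] - 1L)
    iy <- start[2]:(start[2] + d[2] - 1L)
    iz <- start[3]:(start[3] + d[3] - 1L)
    acc[ix, iy, iz] <- acc[ix, iy, iz] + unclass(vols[[m]]) * w
    wacc[ix, iy, iz] <- wacc[ix, iy, iz] + w
  }
  out <- acc
  nz <- wacc > 0
  out[nz] <- acc[nz] / wacc[nz]
  vol3d(out, voxel_um = vx, origin_um = lo)
}

#' Stitch a set of image columns into one slice volume
#'
#' Convenience composition: deskew every column
#' (\code{\link{stack_column}}), estimate pairwise offsets in the overlap
#' regions, solve global origins and fuse.
#'
#' @param columns list of \code{image_column}.
#' @param axial_step_um passed to \code{\link{stack_column}}.
#' @return list: \code{volume} (fused \code{\link{vol3d}}),
#'   \code{origins}, \code{edges}, \code{residuals}.
#' @export
stitch_columns <- function(columns, axial_step_um = NULL) {
  vols <- lapply(columns, stack_column, axial_step_um = axial_step_um)
  nominal <- do.call(rbind, lapply(vols, origin_of))
  edges <- offset_graph(vols)
  sol <- solve_global_offsets(edges, nominal)
  list(volume = fuse_columns(vols, sol$origins), origins = sol$origins,
       edges = edges, residuals = sol$residuals)
}
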