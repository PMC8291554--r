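#' Fit a flattened surface plane to one face of a thick slice
#'
#' The face height map is extracted as the first voxel crossing an
#' intensity threshold (Otsu by default) along z for every (x, y) column,
#' median-filtered 3 x 3, and fitted with a least-squares plane
#' z = a*x + b*y + c over unmasked support points. Masked regions (e.g.
#' ventricles) are excluded from the fit and their heights interpolated
#' from the plane.
#'
#' @param slice a \code{\link{vol3d}} slab.
#' @param face "high" (largest-z face, nearest the surface) or "low".
#' @param mask optional logical matrix (nx x ny), TRUE = exclude.
#' @param threshold intensity threshold; default Otsu on the slab.
#' @return list of class \code{surface_model}: \code{coef} (a, b, c; um
#'   units), \code{height_um} (filled height map), \code{residual_map},
#'   \code{face}, \code{threshold}.
#' @export
fit_surface <- function(slice, face = c("high", "low"), mask = NULL,
                        threshold = NULL) {
  face <- match.arg(face)
  d <- dim(slice); vx <- voxel_of(slice); or <- origin_of(slice)
  a <- unclass(slice)
  if (is.null(threshold)) {
    rng <- range(a)
    threshold <- if (diff(rng) <= 0) rng[1] else
      EBImage::otsu(EBImage::Image(matrix((a - rng[1]) / diff(rng),
                                          ncol = 1L))) * diff(rng) + rng[1]
  }
  nz <- d[3]
  h <- matrix(NA_real_, d[1], d[2])
  ks <- if (face == "high") nz:1 else 1:nz
  found <- matrix(FALSE, d[1], d[2])
  for (k in ks) {
    hit <- !found & (a[, , k] >= threshold)
    h[hit] <- k
    found <- found | hit
  }
  h <- median_filter3(h)
  sup <- !is.na(h) & !(if (is.null(mask)) FALSE else mask)
  if (sum(sup) < 3) stop("fewer than 3 unmasked support points for surface fit")
  xu <- (row(h) - 1) * vx[1] + or[1]
  yu <- (col(h) - 1) * vx[2] + or[2]
  zu <- (h - 1) * vx[3] + or[3]
  fit <- stats::lsfit(cbind(xu[sup], yu[sup]), zu[sup])
  cf <- c(a = unname(fit$coefficients[2]), b = unname(fit$coefficients[3]),
          c = unname(fit$coefficients[1]))
  pred <- cf[1] * xu + cf[2] * yu + cf[3]
  res <- zu - pred
  zu[!sup] <- pred[!sup]
  structure(list(coef = cf, height_um = zu, residual_map = res,
                 face = face, threshold = threshold),
            class = "surface_model")
}

# 3x3 median filter, NA-tolerant, edges use available neighbours
median_filter3 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  sh <- function(di, dj) {
    out <- matrix(NA_real_, nx, ny)
    xi <- seq_len(nx) + di; yj <- seq_len(ny) + dj
    okx <- xi >= 1 & xi <= nx; oky <- yj >= 1 & yj <= ny
    out[okx, oky] <- m[xi[okx], yj[oky]]
    out
  }
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1))
  arr <- array(NA_real_, c(nx * ny, nrow(offs)))
  for (r in seq_len(nrow(offs))) arr[, r] <- as.vector(sh(offs[r, 1], offs[r, 2]))
  matrix(apply(arr, 1, stats::median, na.rm = TRUE), nx, ny)
}

#' Flatten a slice so its faces become constant-z planes
#'
#' Resamples every (x, y) column in z so the fitted top and bottom
#' surfaces map to their mean levels, with the interior interpolated
#' linearly between the faces. With a single model the slab is shifted
#' rigidly in z per column (faces assumed parallel).
#'
#' @param slice a \code{\link{vol3d}}.
#' @param high \code{surface_model} of the largest-z face.
#' @param low optional \code{surface_model} of the other face.
#' @return flattened \code{\link{vol3d}} of identical dimensions.
#' @export
flatten_slice <- function(slice, high, low = NULL) {
  d <- dim(slice); vx <- voxel_of(slice); or <- origin_of(slice)
  a <- unclass(slice)
  hk <- (high$height_um - or[3]) / vx[3] + 1          # face index map
  hbar <- mean(hk)
  if (is.null(low)) {
    src_at <- function(k) k + (hk - hbar)
  } else {
    lk <- (low$height_um - or[3]) / vx[3] + 1
    lbar <- mean(lk)
    scale <- (hk - lk) / max(hbar - lbar, 1e-9)
    src_at <- function(k) lk + (k - lbar) * scale
  }
  out <- array(0, d)
  for (k in seq_len(d[3])) {
    zq <- src_at(k)
    z0 <- floor(zq)
    z0 <- pmin(pmax(z0, 1L), d[3] - 1L)
    w <- pmin(pmax(zq - z0, 0), 1)
    g <- function(kk) {
      m <- matrix(0, d[1], d[2])
      sel <- kk >= 1 & kk <= d[3]
      if (any(sel)) m[sel] <- a[cbind(which(sel, arr.ind = TRUE), kk[sel])]
      m
    }
    plane <- g(z0) * (1 - w) + g(z0 + 1L) * w
    plane[zq < 1 | zq > d[3]] <- 0
    out[, , k] <- plane
  }
  vol3d(out, voxel_um = vx, origin_um = or)
}

grad_mag <- function(img) {
  nx <- nrow(img); ny <- ncol(img)
  gx <- img * 0; gy <- img * 0
  gx[2:(nx - 1), ] <- (img[3:nx, ] - img[1:(nx - 2), ]) / 2
  gy[, 2:(ny - 1)] <- (img[, 3:ny] - img[, 1:(ny - 2)]) / 2
  sqrt(gx^2 + gy^2)
}

ncc2 <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den < 1e-12) return(0)
  sum(a * b) / den
}

match_point <- function(ga, gb, i, j, disp0, patch, search, subpixel = TRUE) {
  nx <- nrow(ga); ny <- ncol(ga)
  pi_ <- (i - patch):(i + patch); pj <- (j - patch):(j + patch)
  if (min(pi_) < 1 || max(pi_) > nx || min(pj) < 1 || max(pj) > ny)
    return(NULL)
  pa <- ga[pi_, pj]
  sc <- matrix(-Inf, 2 * search + 1, 2 * search + 1)
  for (du in -search:search) for (dv in -search:search) {
    qi <- pi_ + disp0[1] + du; qj <- pj + disp0[2] + dv
    if (min(qi) < 1 || max(qi) > nrow(gb) || min(qj) < 1 || max(qj) > ncol(gb))
      next
    sc[du + search + 1, dv + search + 1] <- ncc2(pa, gb[qi, qj])
  }
  bi <- which.max(sc)
  best_s <- sc[bi]
  if (!is.finite(best_s)) return(NULL)
  bu <- (bi - 1) %% nrow(sc) + 1; bv <- (bi - 1) %/% nrow(sc) + 1
  best <- c(bu - search - 1, bv - search - 1)
  # parabolic subpixel refinement along each axis
  sub <- c(0, 0)
  if (subpixel) {
    if (bu > 1 && bu < nrow(sc) && all(is.finite(sc[(bu - 1):(bu + 1), bv]))) {
      den <- sc[bu - 1, bv] - 2 * sc[bu, bv] + sc[bu + 1, bv]
      if (den < -1e-12)
        sub[1] <- max(-0.5, min(0.5, 0.5 * (sc[bu - 1, bv] - sc[bu + 1, bv]) / den))
    }
    if (bv > 1 && bv < ncol(sc) && all(is.finite(sc[bu, (bv - 1):(bv + 1)]))) {
      den <- sc[bu, bv - 1] - 2 * sc[bu, bv] + sc[bu, bv + 1]
      if (den < -1e-12)
        sub[2] <- max(-0.5, min(0.5, 0.5 * (sc[bu, bv - 1] - sc[bu, bv + 1]) / den))
    }
  }
  c(disp0 + best + sub, best_s)
}

#' Extract dense correspondences between two opposing slice faces
#'
#' Pluggable dense-correspondence stage. The default backend matches
#' edges and textures: coarse-to-fine block matching on
#' gradient-magnitude images (4x coarse pass initializing a full-
#' resolution refinement), sampled on a regular grid restricted to
#' high-texture locations, with local normalized cross-correlation as
#' confidence. Exactness of the flow backend is deliberately not load-
#' bearing; any function with the same signature can be substituted.
#'
#' @param face_a,face_b numeric matrices (same extent), pixel spacing
#'   \code{voxel_xy} um; a = reference face, b = moving face.
#' @param voxel_xy pixel spacing, um.
#' @param grid_step_um correspondence grid pitch, um.
#' @param patch_um half-width of the matching patch, um.
#' @param search_um maximum displacement searched, um.
#' @param texture_quantile keep grid points whose local gradient energy
#'   exceeds this quantile of the image.
#' @param backend optional replacement
#'   \code{function(face_a, face_b, pts_px, voxel_xy)} returning a
#'   matrix (dx_px, dy_px, confidence).
#' @return data.frame (xa, ya, xb, yb, confidence), um; zero rows (with
#'   a warning) when the faces are textureless.
#' @export
extract_correspondences <- function(face_a, face_b, voxel_xy = c(1, 1),
                                    grid_step_um = 24, patch_um = 10,
                                    search_um = 12, texture_quantile = 0.5,
                                    backend = NULL) {
  stopifnot(all(dim(face_a) == dim(face_b)))
  ga <- grad_mag(face_a); gb <- grad_mag(face_b)
  if (max(ga) < 1e-9) {
    warning("textureless face: no correspondences")
    return(data.frame(xa = numeric(), ya = numeric(), xb = numeric(),
                      yb = numeric(), confidence = numeric()))
  }
  step <- max(2L, round(grid_step_um / voxel_xy[1]))
  patch <- max(3L, round(patch_um / voxel_xy[1]))
  search <- max(1L, round(search_um / voxel_xy[1]))
  gi <- seq(patch + search + 1L, nrow(ga) - patch - search, by = step)
  gj <- seq(patch + search + 1L, ncol(ga) - patch - search, by = step)
  if (!length(gi) || !length(gj)) {
    warning("faces too small for the matching patch")
    return(data.frame(xa = numeric(), ya = numeric(), xb = numeric(),
                      yb = numeric(), confidence = numeric()))
  }
  pts <- as.matrix(expand.grid(i = gi, j = gj))
  # texture selection: local gradient energy (patch sum)
  energy <- apply(pts, 1, function(p)
    sum(ga[(p[1] - patch):(p[1] + patch), (p[2] - patch):(p[2] + patch)]^2))
  keep <- energy >= stats::quantile(energy, texture_quantile) & energy > 0
  pts <- pts[keep, , drop = FALSE]
  if (!nrow(pts)) {
    warning("no textured grid points")
    return(data.frame(xa = numeric(), ya = numeric(), xb = numeric(),
                      yb = numeric(), confidence = numeric()))
  }
  if (!is.null(backend)) {
    res <- backend(face_a, face_b, pts, voxel_xy)
  } else {
    # coarse pass at 4x on gradients of the downsampled faces, with a
    # patch twice the fine context so large displacements are resolved
    # unambiguously before local refinement
    f <- 4L
    ca <- grad_mag(block_mean(face_a, f)); cb <- grad_mag(block_mean(face_b, f))
    pc <- max(3L, as.integer(ceiling(2 * patch / f)))
    res <- t(apply(pts, 1, function(p) {
      ci <- min(max(pc + 1L, round(p[1] / f)), nrow(ca) - pc)
      cj <- min(max(pc + 1L, round(p[2] / f)), ncol(ca) - pc)
      coarse <- match_point(ca, cb, ci, cj, c(0L, 0L), patch = pc,
                            search = max(1L, ceiling(search / f)),
                            subpixel = FALSE)
      init <- if (is.null(coarse)) c(0L, 0L) else as.integer(round(coarse[1:2] * f))
      fine <- match_point(ga, gb, p[1], p[2], init, patch, search = f + 1L)
      if (is.null(fine)) c(NA, NA, NA) else fine
    }))
  }
  ok <- is.finite(res[, 3])
  pts <- pts[ok, , drop = FALSE]; res <- res[ok, , drop = FALSE]
  data.frame(xa = (pts[, 1] - 1) * voxel_xy[1],
             ya = (pts[, 2] - 1) * voxel_xy[2],
             xb = (pts[, 1] - 1 + res[, 1]) * voxel_xy[1],
             yb = (pts[, 2] - 1 + res[, 2]) * voxel_xy[2],
             confidence = pmax(0, pmin(1, res[, 3])))
}

#' Globally adjust correspondence displacements across a slice stack
#'
#' Minimizes \eqn{\sum_i \|d_i - \hat d_i\|^2 + \lambda_{smooth}
#' \sum_{(i,j) \in N} \|\hat d_i - \hat d_j\|^2 + \lambda_{small} \sum_i
#' \|\hat d_i\|^2} jointly over all interfaces (sparse linear solve, one
#' system per component). Neighbourhoods are k-nearest in-plane within an
#' interface plus nearest-point links across consecutive interfaces,
#' which limits error accumulation through the stack under the
#' smoothness / small-deformation assumptions.
#'
#' @param sets list of correspondence data.frames (see
#'   \code{\link{extract_correspondences}}), ordered along the stack.
#' @param lambda_smooth,lambda_small penalty weights.
#' @param k in-plane neighbours per point.
#' @return list of data.frames with adjusted \code{xb, yb} (and raw
#'   displacements kept as \code{dx_raw, dy_raw}).
#' @export
adjust_correspondences <- function(sets, lambda_smooth = 1, lambda_small = 0.1,
                                   k = 8L) {
  if (is.data.frame(sets)) sets <- list(sets)
  stopifnot(length(sets) >= 1)
  ns <- vapply(sets, nrow, 1L)
  tot <- sum(ns)
  if (tot == 0L) return(sets)
  off <- cumsum(c(0L, ns))
  P <- do.call(rbind, lapply(sets, function(s) cbind(s$xa, s$ya)))
  D <- do.call(rbind, lapply(sets, function(s) cbind(s$xb - s$xa, s$yb - s$ya)))
  ii <- integer(0); jj <- integer(0); dd <- numeric(0)
  for (s in seq_along(sets)) {
    n <- ns[s]
    if (n >= 2) {
      pp <- P[(off[s] + 1):(off[s] + n), , drop = FALSE]
      dm <- as.matrix(stats::dist(pp))
      kk <- min(k, n - 1L)
      for (a in seq_len(n)) {
        nb <- order(dm[a, ])[2:(kk + 1L)]
        ii <- c(ii, rep(off[s] + a, kk)); jj <- c(jj, off[s] + nb)
        dd <- c(dd, dm[a, nb])
      }
    }
    if (s < length(sets) && ns[s] > 0 && ns[s + 1] > 0) {
      # link each point to its nearest in the next interface
      pa <- P[(off[s] + 1):(off[s] + ns[s]), , drop = FALSE]
      pb <- P[(off[s + 1] + 1):(off[s + 1] + ns[s + 1]), , drop = FALSE]
      for (a in seq_len(ns[s])) {
        d2 <- (pb[, 1] - pa[a, 1])^2 + (pb[, 2] - pa[a, 2])^2
        ii <- c(ii, off[s] + a); jj <- c(jj, off[s + 1] + which.min(d2))
        dd <- c(dd, sqrt(min(d2)))
      }
    }
  }
  if (length(ii)) {
    # Gaussian distance kernel at the median neighbour spacing, then
    # degree normalization: lambda_smooth = 1 blends an outlier about
    # halfway to its neighbourhood mean while leaving smooth fields
    # nearly untouched (the penalty approximates a first-difference
    # seminorm, not an absolute shrinkage)
    h <- max(stats::median(dd), 1e-6)
    wgt <- exp(-dd^2 / (2 * h^2)) + 1e-9
    W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii),
                              x = c(wgt, wgt) / 2, dims = c(tot, tot))
    deg <- Matrix::rowSums(W)
    W <- Matrix::Diagonal(x = 1 / pmax(deg, 1e-12)) %*% W
    W <- (W + Matrix::t(W)) / 2
    L <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  } else {
    L <- Matrix::Diagonal(tot, 0)
  }
  A <- Matrix::Diagonal(tot, 1 + lambda_small) + lambda_smooth * L
  Dhat <- as.matrix(Matrix::solve(A, D))
  if (any(!is.finite(Dhat))) stop("adjustment solve did not converge")
  out <- vector("list", length(sets))
  for (s in seq_along(sets)) {
    sel <- if (ns[s] > 0) (off[s] + 1):(off[s] + ns[s]) else integer(0)
    o <- sets[[s]]
    if (length(sel)) {
      o$dx_raw <- D[sel, 1]; o$dy_raw <- D[sel, 2]
      o$xb <- o$xa + Dhat[sel, 1]; o$yb <- o$ya + Dhat[sel, 2]
    }
    out[[s]] <- o
  }
  out
}

#' Four-step reconstruction of a stack of thick slices
#'
#' Composes the whole-slice alignment pipeline: (i) fit and flatten the
#' top/bottom surface of every slice; (ii) extract correspondences
#' between the opposing faces of each adjacent slice pair; (iii) adjust
#' all displacements jointly under smoothness and small-displacement
#' penalties; (iv) warp each slice by similarity moving least squares.
#' Per-slice warps are solved on a coarse node grid by a chain
#' least-squares along the stack (so corrections stay small everywhere
#' instead of accumulating), then applied in-plane to every z-plane.
#'
#' @param slices list of \code{\link{vol3d}} slabs, ordered in z, or a
#'   \code{sliced_phantom}.
#' @param lambda_smooth,lambda_small adjustment weights.
#' @param face_planes number of z-planes max-projected to form a face
#'   image (1 = the plane adjacent to the cut).
#' @param grid_nodes nodes per axis of the per-slice warp grid.
#' @param flatten run the surface flattening step.
#' @param mu ridge weight of the chain solve.
#' @param min_confidence correspondences below this NCC confidence are
#'   discarded before adjustment.
#' @param outlier_tol_um correspondences deviating more than this from
#'   the median displacement of their 8 nearest neighbours are discarded
#'   (flow outlier rejection); NULL disables.
#' @param min_warp_um slices whose solved node corrections all stay
#'   below this are left unwarped.
#' @param ... passed to \code{\link{extract_correspondences}}.
#' @return list of class \code{brain_reconstruction}: \code{volume}
#'   (stacked aligned \code{\link{vol3d}}), \code{slices}, \code{warps}
#'   (per slice: nodes \code{p}, displacements \code{d}),
#'   \code{interfaces} (adjusted sets), \code{residuals} (per-interface
#'   mean |displacement| before and after).
#' @export
reconstruct_brain <- function(slices, lambda_smooth = 0.3,
                              lambda_small = 0.03,
                              face_planes = 1L, grid_nodes = 13L,
                              flatten = FALSE, mu = 0.01,
                              min_confidence = 0.7,
                              outlier_tol_um = 3, min_warp_um = 0.5,
                              ...) {
  if (inherits(slices, "sliced_phantom")) slices <- slices$slices
  S <- length(slices)
  stopifnot(S >= 1)
  vx <- voxel_of(slices[[1]])
  if (flatten) {
    slices <- lapply(slices, function(sl)
      flatten_slice(sl, fit_surface(sl, "high"), fit_surface(sl, "low")))
  }
  if (S == 1L) {
    return(structure(list(volume = slices[[1]], slices = slices,
                          warps = list(NULL), interfaces = list(),
                          residuals = NULL),
                     class = "brain_reconstruction"))
  }
  face_img <- function(sl, side) {
    a <- unclass(sl); nz <- dim(a)[3]
    ks <- if (side == "high") max(1L, nz - face_planes + 1L):nz
          else seq_len(min(face_planes, nz))
    apply(a[, , ks, drop = FALSE], c(1, 2), max)
  }
  sets <- vector("list", S - 1L)
  for (s in seq_len(S - 1L)) {
    fa <- face_img(slices[[s]], "high")
    fb <- face_img(slices[[s + 1L]], "low")
    st <- extract_correspondences(fa, fb, voxel_xy = vx[1:2], ...)
    st <- st[st$confidence >= min_confidence, , drop = FALSE]
    if (!is.null(outlier_tol_um) && nrow(st) > 9) {
      dx <- st$xb - st$xa; dy <- st$yb - st$ya
      keep <- vapply(seq_len(nrow(st)), function(i) {
        d2 <- (st$xa - st$xa[i])^2 + (st$ya - st$ya[i])^2
        nb <- order(d2)[2:9]
        sqrt((dx[i] - stats::median(dx[nb]))^2 +
             (dy[i] - stats::median(dy[nb]))^2) < outlier_tol_um
      }, TRUE)
      st <- st[keep, , drop = FALSE]
    }
    sets[[s]] <- st
  }
  adj <- adjust_correspondences(sets, lambda_smooth, lambda_small)
  # chain solve on a regular node grid covering the correspondence hull
  # (no extrapolation beyond measured support)
  d1 <- dim(slices[[1]])
  allp <- do.call(rbind, lapply(adj, function(s) cbind(s$xa, s$ya)))
  if (is.null(allp) || nrow(allp) < 4) {
    hull <- rbind(c(0, 0), (d1[1:2] - 1) * vx[1:2])
  } else {
    hull <- rbind(apply(allp, 2, min), apply(allp, 2, max))
  }
  xs <- seq(hull[1, 1], hull[2, 1], length.out = grid_nodes)
  ys <- seq(hull[1, 2], hull[2, 2], length.out = grid_nodes)
  nodes <- as.matrix(expand.grid(x = xs, y = ys))
  dgrid <- lapply(adj, fit_field_nodes, nodes = nodes)
  # per node & component: minimize sum_s (u_{s+1}-u_s + d_s)^2 + mu sum u^2
  A <- diag(mu, S)
  for (s in seq_len(S - 1L)) {
    A[s, s] <- A[s, s] + 1; A[s + 1L, s + 1L] <- A[s + 1L, s + 1L] + 1
    A[s, s + 1L] <- A[s, s + 1L] - 1; A[s + 1L, s] <- A[s + 1L, s] - 1
  }
  warps <- lapply(seq_len(S), function(s)
    list(p = nodes, d = matrix(0, nrow(nodes), 2), xs = xs, ys = ys))
  for (g in seq_len(nrow(nodes))) for (comp in 1:2) {
    bvec <- numeric(S)
    for (s in seq_len(S - 1L)) {
      ds <- dgrid[[s]][g, comp]
      bvec[s] <- bvec[s] + ds; bvec[s + 1L] <- bvec[s + 1L] - ds
    }
    u <- solve(A, bvec)
    for (s in seq_len(S)) warps[[s]]$d[g, comp] <- u[s]
  }
  # corrections below half an in-plane pixel are measurement noise on
  # already-aligned slices: skip them (keeps the identity on undeformed
  # stacks, consistent with the voxel-scale goals downstream)
  for (s in seq_len(S))
    if (max(abs(warps[[s]]$d)) < min_warp_um)
      warps[[s]]$d[] <- 0
  aligned <- vector("list", S)
  for (s in seq_len(S)) {
    a <- unclass(slices[[s]])
    if (max(abs(warps[[s]]$d)) > 1e-12) {
      for (k in seq_len(dim(a)[3]))
        a[, , k] <- mls_warp(a[, , k], warps[[s]]$p, warps[[s]]$d,
                             voxel_xy = vx[1:2])
    }
    aligned[[s]] <- vol3d(a, voxel_um = vx, origin_um = origin_of(slices[[s]]))
  }
  big <- array(0, c(d1[1], d1[2], sum(vapply(aligned, function(x) dim(x)[3], 1L))))
  k0 <- 0L
  for (s in seq_len(S)) {
    nz <- dim(aligned[[s]])[3]
    big[, , (k0 + 1L):(k0 + nz)] <- unclass(aligned[[s]])
    k0 <- k0 + nz
  }
  resid <- data.frame(
    interface = seq_len(S - 1L),
    before_um = vapply(sets, function(s)
      if (nrow(s)) mean(sqrt((s$xb - s$xa)^2 + (s$yb - s$ya)^2)) else NA_real_, 1),
    after_um = vapply(seq_len(S - 1L), function(s) {
      st <- adj[[s]]
      if (!nrow(st)) return(NA_real_)
      pa <- apply_slice_warp(warps[[s]], cbind(st$xa, st$ya))
      pb <- apply_slice_warp(warps[[s + 1L]], cbind(st$xa + st$dx_raw,
                                                    st$ya + st$dy_raw))
      mean(sqrt(rowSums((pb - pa)^2)))
    }, 1))
  structure(list(volume = vol3d(big, voxel_um = vx,
                                origin_um = origin_of(slices[[1]])),
                 slices = aligned, warps = warps, interfaces = adj,
                 residuals = resid),
            class = "brain_reconstruction")
}

# local confidence/distance-weighted linear fit of the displacement
# field at each node (first-order, so smooth fields keep gradient and
# amplitude; k-nearest support, no extrapolation blowup)
fit_field_nodes <- function(set, nodes, k = 10L) {
  if (nrow(set) == 0) return(matrix(0, nrow(nodes), 2))
  P <- cbind(set$xa, set$ya)
  D <- cbind(set$xb - set$xa, set$yb - set$ya)
  k <- min(k, nrow(set))
  out <- matrix(0, nrow(nodes), 2)
  for (g in seq_len(nrow(nodes))) {
    r2 <- (P[, 1] - nodes[g, 1])^2 + (P[, 2] - nodes[g, 2])^2
    nb <- order(r2)[seq_len(k)]
    w <- set$confidence[nb] / (r2[nb] + 4)
    if (k >= 4) {
      X <- cbind(1, P[nb, 1] - nodes[g, 1], P[nb, 2] - nodes[g, 2])
      XtW <- t(X * w)
      fit <- try(solve(XtW %*% X, XtW %*% D[nb, , drop = FALSE]),
                 silent = TRUE)
      if (!inherits(fit, "try-error") && all(is.finite(fit[1, ]))) {
        out[g, ] <- fit[1, ]
        next
      }
    }
    out[g, ] <- colSums(w * D[nb, , drop = FALSE]) / sum(w)
  }
  out
}

#' Apply a per-slice node warp to in-plane points
#'
#' Bilinear interpolation of the node displacement field (clamped to the
#' node-grid hull) added to the input positions.
#'
#' @param warp list(p, d, xs, ys) as stored by
#'   \code{\link{reconstruct_brain}}.
#' @param xy n x 2 points, um.
#' @return n x 2 warped points, um.
#' @export
apply_slice_warp <- function(warp, xy) {
  if (is.null(warp) || max(abs(warp$d)) < 1e-15) return(xy)
  nx <- length(warp$xs); ny <- length(warp$ys)
  ux <- matrix(warp$d[, 1], nx, ny)
  uy <- matrix(warp$d[, 2], nx, ny)
  # fractional grid coordinates, clamped (constant extension outside)
  gi <- (xy[, 1] - warp$xs[1]) / (warp$xs[2] - warp$xs[1])
  gj <- (xy[, 2] - warp$ys[1]) / (warp$ys[2] - warp$ys[1])
  gi <- pmin(pmax(gi, 0), nx - 1)
  gj <- pmin(pmax(gj, 0), ny - 1)
  xy + cbind(interp_bilinear(ux, gi, gj), interp_bilinear(uy, gi, gj))
}

#' Ground-truth cross-interface mismatch of a reconstructed stack
#'
#' For a marker grid in the interior of each interface, compares the
#' positions a material point takes in the two adjacent deformed slices
#' (using the generator's recorded fields) before and after applying the
#' reconstruction's per-slice warps.
#'
#' @param sliced a \code{sliced_phantom} from
#'   \code{\link{cut_and_deform_slices}}.
#' @param recon a \code{brain_reconstruction} of the same slices (NULL
#'   gives the unaligned baseline only).
#' @param step_um marker grid pitch.
#' @param margin_um margin excluded at the slice border.
#' @return data.frame (interface, before_um, after_um).
#' @export
interface_mismatch <- function(sliced, recon = NULL, step_um = 15,
                               margin_um = 30) {
  stopifnot(inherits(sliced, "sliced_phantom"))
  d <- dim(sliced$slices[[1]]); vx <- sliced$voxel_um
  mk <- as.matrix(expand.grid(
    x = seq(margin_um, (d[1] - 1) * vx[1] - margin_um, by = step_um),
    y = seq(margin_um, (d[2] - 1) * vx[2] - margin_um, by = step_um)))
  S <- length(sliced$slices)
  out <- data.frame(interface = seq_len(S - 1L), before_um = NA_real_,
                    after_um = NA_real_)
  for (s in seq_len(S - 1L)) {
    qa <- deform_points(sliced$fields[[s]], mk)
    qb <- deform_points(sliced$fields[[s + 1L]], mk)
    out$before_um[s] <- mean(sqrt(rowSums((qa - qb)^2)))
    if (!is.null(recon)) {
      wa <- apply_slice_warp(recon$warps[[s]], qa)
      wb <- apply_slice_warp(recon$warps[[s + 1L]], qb)
      out$after_um[s] <- mean(sqrt(rowSums((wa - wb)^2)))
    }
  }
  out
}

#' @export
print.brain_reconstruction <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("brain_reconstruction: %d slices -> %d x %d x %d voxels\n",
              length(x$slices), d[1], d[2], d[3]))
  if (!is.null(x$residuals)) {
    cat("per-interface mean in-plane mismatch (um):\n")
    print(x$residuals, row.names = FALSE)
  }
  invisible(x)
}
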