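# shared fixture builders (everything generated in code at test time)

# volume of smooth Gaussian beads on a constant background
bead_volume <- function(dims = c(120, 80, 60), n_beads = 12, sigma2 = 18,
                        peak = 1000, background = 50, seed = 1,
                        margin = 10) {
  set.seed(seed)
  a <- array(0, dims)
  r <- ceiling(sqrt(sigma2) * 3)
  centres <- cbind(sample((margin + r):(dims[1] - margin - r), n_beads, TRUE),
                   sample((margin + r):(dims[2] - margin - r), n_beads, TRUE),
                   sample((margin + r):(dims[3] - margin - r), n_beads, TRUE))
  for (b in seq_len(n_beads)) {
    ix <- (centres[b, 1] - r):(centres[b, 1] + r)
    iy <- (centres[b, 2] - r):(centres[b, 2] + r)
    iz <- (centres[b, 3] - r):(centres[b, 3] + r)
    gx <- exp(-((ix - centres[b, 1])^2) / sigma2)
    gy <- exp(-((iy - centres[b, 2])^2) / sigma2)
    gz <- exp(-((iz - centres[b, 3])^2) / sigma2)
    a[ix, iy, iz] <- a[ix, iy, iz] + peak * outer(outer(gx, gy), gz)
  }
  list(vol = vol3d(a + background, c(1, 1, 1)), centres = centres)
}

# hard (uniform-intensity) sphere in a small volume, anisotropic voxels
hard_sphere_volume <- function(radius_um = 7, voxel = c(1, 1, 3.5),
                               peak = 1000, background = 100,
                               extent_um = c(60, 60, 56)) {
  dims <- round(extent_um / voxel)
  ctr <- (dims - 1) / 2 * voxel
  a <- array(background, dims)
  for (k in seq_len(dims[3])) {
    z <- (k - 1) * voxel[3]
    xs <- ((seq_len(dims[1]) - 1) * voxel[1] - ctr[1])
    ys <- ((seq_len(dims[2]) - 1) * voxel[2] - ctr[2])
    r2 <- outer(xs^2, ys^2, "+") + (z - ctr[3])^2
    a[, , k] <- a[, , k] + peak * (r2 <= radius_um^2)
  }
  list(vol = vol3d(a, voxel), centre = ctr, radius = radius_um)
}

# default geometry with round numbers: pixel 0.5 um, frame step 1 um
test_geometry <- function(frame_shape = c(180L, 170L),
                          stage_speed_um_s = 200) {
  acquisition_geometry(objective_mag = 20, tube_focal_mm = 117,
                       reference_tube_mm = 180, camera_pixel_um = 6.5,
                       scan_rate_hz = 200,
                       stage_speed_um_s = stage_speed_um_s,
                       frame_shape = frame_shape)
}
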