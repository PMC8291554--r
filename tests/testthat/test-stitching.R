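test_that("deskewed bead positions match the geometry mapping", {
  # single bright bead; its world position after stacking must agree
  # with oblique_to_world applied to the brightest frame pixel
  bv <- bead_volume(dims = c(100, 60, 50), n_beads = 1, sigma2 = 8,
                    peak = 5000, background = 0, seed = 9)
  g <- test_geometry(frame_shape = c(150L, 110L))
  col <- simulate_acquisition(bv$vol, g)[[1]]
  pk <- arrayInd(which.max(col$frames), dim(col$frames))
  w <- drop(oblique_to_world(col$geometry, pk[1] - 1, pk[2] - 1, pk[3] - 1))
  v <- stack_column(col, axial_step_um = 1)
  pv <- arrayInd(which.max(unclass(v)), dim(v))
  wv <- origin_of(v) + (pv - 1) * voxel_of(v)
  expect_lt(max(abs(wv - w)), 1.01)                  # within one voxel
  expect_lt(max(abs(wv - (bv$centres[1, ] - 1))), 1.5)  # near the true bead
})

test_that("two beads keep their spacing through deskew", {
  a <- array(0, c(120, 50, 40))
  put <- function(a, c0) {
    for (dx in -6:6) for (dy in -6:6) for (dz in -6:6)
      a[c0[1] + dx, c0[2] + dy, c0[3] + dz] <-
        a[c0[1] + dx, c0[2] + dy, c0[3] + dz] + 3000 * exp(-(dx^2 + dy^2 + dz^2) / 8)
    a
  }
  a <- put(a, c(30, 25, 20)); a <- put(a, c(80, 25, 20))
  vol <- vol3d(a, c(1, 1, 1))
  g <- test_geometry(frame_shape = c(120L, 90L))
  v <- stack_column(simulate_acquisition(vol, g)[[1]], axial_step_um = 1)
  av <- unclass(v)
  p1 <- arrayInd(which.max(av), dim(av))
  av2 <- av
  av2[max(1, p1[1] - 20):min(dim(av)[1], p1[1] + 20), , ] <- 0
  p2 <- arrayInd(which.max(av2), dim(av2))
  d <- sqrt(sum(((p2 - p1) * voxel_of(v))^2))
  expect_lt(abs(d - 50) / 50, 0.02)
})

test_that("pair offsets are recovered from constructed shifts", {
  set.seed(2)
  base <- array(stats::rnorm(70 * 70 * 40, 100, 15), c(70, 70, 40))
  base <- base + 400 * array(
    exp(-((slice.index(base, 1) - 35)^2 + (slice.index(base, 2) - 35)^2 +
            (slice.index(base, 3) - 20)^2) / 150), dim(base))
  a <- vol3d(base[1:55, 1:55, 1:32], c(1, 1, 1), origin_um = c(0, 0, 0))
  # content shifted by (7, -3, 0) but declared at the same origin
  b <- vol3d(base[(1:55) + 7, (1:55) - 3 + 5, 1:32], c(1, 1, 1),
             origin_um = c(0, 2, 0))
  e <- estimate_pair_offset(a, b)
  expect_false(e$fallback)
  expect_equal(unname(e$offset_um), c(7, 2, 0))
  expect_gt(e$score, 0.99)

  # identical volumes: zero offset, perfect score
  e0 <- estimate_pair_offset(a, vol3d(unclass(a), c(1, 1, 1)))
  expect_equal(unname(e0$offset_um), c(0, 0, 0))
  expect_equal(e0$score, 1, tolerance = 1e-9)

  # uncorrelated noise: fallback to nominal with near-zero score
  n1 <- vol3d(array(stats::rnorm(48^2 * 20), c(48, 48, 20)), c(1, 1, 1))
  n2 <- vol3d(array(stats::rnorm(48^2 * 20), c(48, 48, 20)), c(1, 1, 1))
  en <- estimate_pair_offset(n1, n2)
  expect_true(en$fallback)
  expect_lt(abs(en$score), 0.3)

  # overlap thinner than 16 voxels: low-confidence fallback
  thin <- vol3d(unclass(a), c(1, 1, 1), origin_um = c(45, 0, 0))
  et <- estimate_pair_offset(a, thin)
  expect_true(et$fallback)
})

test_that("global solve handles chains, loops and singletons", {
  # chain of exact offsets -> cumulative sums
  nominal <- rbind(c(0, 0, 0), c(90, 0, 0), c(180, 0, 0))
  edges <- data.frame(i = c(1, 2), j = c(2, 3), dx = c(92, 88),
                      dy = c(1, -1), dz = c(0, 0), score = 1)
  sol <- solve_global_offsets(edges, nominal)
  expect_equal(sol$origins[2, ], c(92, 1, 0), tolerance = 1e-9)
  expect_equal(sol$origins[3, ], c(180, 0, 0), tolerance = 1e-9)

  # redundant loop with one corrupted edge: solution within 1 voxel
  nominal4 <- rbind(c(0, 0, 0), c(100, 0, 0), c(100, 100, 0), c(0, 100, 0))
  truth <- nominal4
  edges4 <- data.frame(
    i = c(1, 2, 3, 4, 1), j = c(2, 3, 4, 1, 3),
    dx = c(100, 0, -100, 0, 100 + 8),   # edge 5 corrupted by 8 um
    dy = c(0, 100, 0, -100, 100),
    dz = 0, score = c(1, 1, 1, 1, 0.2))
  sol4 <- solve_global_offsets(edges4, nominal4)
  expect_lt(max(abs(sol4$origins - truth)), 1)

  # single column: nominal returned
  s1 <- solve_global_offsets(NULL, matrix(c(5, 6, 7), 1))
  expect_equal(s1$origins, matrix(c(5, 6, 7), 1))

  # disconnected graph: warning, both anchored at nominal
  edges_d <- data.frame(i = 1, j = 2, dx = 10, dy = 0, dz = 0, score = 1)
  expect_warning(
    sol_d <- solve_global_offsets(edges_d, rbind(c(0, 0, 0), c(10, 0, 0),
                                                 c(500, 0, 0))),
    "disconnected")
  expect_equal(sol_d$origins[3, ], c(500, 0, 0))
})

test_that("feather fusion is a convex combination", {
  # two identical overlapping constants fuse to the same constant
  c1 <- vol3d(array(7, c(30, 30, 10)), c(1, 1, 1), origin_um = c(0, 0, 0))
  c2 <- vol3d(array(7, c(30, 30, 10)), c(1, 1, 1), origin_um = c(20, 0, 0))
  f <- fuse_columns(list(c1, c2))
  expect_true(all(abs(unclass(f) - 7) < 1e-9))
  # bounded by input range
  set.seed(3)
  r1 <- vol3d(array(runif(30 * 30 * 10, 2, 9), c(30, 30, 10)), c(1, 1, 1))
  r2 <- vol3d(array(runif(30 * 30 * 10, 2, 9), c(30, 30, 10)), c(1, 1, 1),
              origin_um = c(18, 0, 0))
  f2 <- fuse_columns(list(r1, r2))
  expect_gte(min(f2), 2 - 1e-9)
  expect_lte(max(f2), 9 + 1e-9)
  # non-overlapping -> simple mosaic
  m2 <- vol3d(array(3, c(10, 10, 5)), c(1, 1, 1), origin_um = c(30, 0, 0))
  m1 <- vol3d(array(5, c(10, 10, 5)), c(1, 1, 1))
  fm <- fuse_columns(list(m1, m2))
  expect_equal(fm[1, 1, 1], 5)
  expect_equal(fm[dim(fm)[1], 1, 1], 3)
})

test_that("stitching simulated columns recovers truth at integer voxels", {
  bv <- bead_volume(dims = c(100, 150, 50), n_beads = 14, sigma2 = 10,
                    peak = 2000, background = 50, seed = 11)
  g <- test_geometry(frame_shape = c(150L, 220L))
  cols <- simulate_acquisition(bv$vol, g, overlap = 0.10,
                               noise = list(poisson = FALSE, read_sigma = 2))
  expect_gte(length(cols), 2)
  st <- stitch_columns(cols, axial_step_um = 1)
  # solved origins equal the (known-correct) nominal origins exactly
  nominal <- do.call(rbind, lapply(cols, function(cc) {
    v <- stack_column(cc, axial_step_um = 1); origin_of(v)
  }))
  expect_lt(max(abs(st$origins - nominal)), 0.51)   # integer-voxel agreement
  adjacent <- st$edges$j == st$edges$i + 1
  expect_true(all(!st$edges$fallback[adjacent]))
  # fused volume reproduces bead positions within a voxel
  fused <- st$volume
  fo <- origin_of(fused); fv <- voxel_of(fused)
  truth <- bv$centres - 1          # helper centres are 1-based indices
  for (b in seq_len(nrow(truth))) {
    ci <- round((truth[b, ] - fo) / fv) + 1
    lo <- pmax(ci - 8, 1); hi <- pmin(ci + 8, dim(fused))
    sub <- unclass(fused)[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] - 50
    sub[sub < 0.2 * max(sub)] <- 0
    idx <- which(sub > 0)
    ai <- arrayInd(idx, dim(sub)); wgt <- sub[idx]
    w <- fo + (colSums(ai * wgt) / sum(wgt) + lo - 2) * fv
    expect_lte(max(abs(w - truth[b, ])), 1.5)
  }
})
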