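test_that("NIfTI round-trip preserves data and grid metadata", {
  set.seed(1)
  vol <- image_volume(array(rnorm(10 * 12 * 14), c(10, 12, 14)),
                      spacing = c(0.5, 0.5, 1.0), origin = c(3, -2, 7))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_equal(max(abs(back$data - vol$data)), 0)
  expect_equal(back$spacing, vol$spacing)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)

  lab <- label_volume(array(rbinom(10 * 12 * 14, 1, 0.3), c(10, 12, 14)),
                      spacing = c(0.5, 0.5, 1.0), origin = c(3, -2, 7))
  fl <- tempfile(fileext = ".nii.gz")
  write_volume(lab, fl)
  backl <- read_volume(fl, label = TRUE)
  expect_identical(backl$data, lab$data)
})

test_that("invalid grids are rejected with explicit errors", {
  expect_error(image_volume(array(0, c(4, 4, 4)), spacing = c(0, 1, 1)),
               "spacing")
  expect_error(image_volume(array(0, c(4, 4, 4)), spacing = c(-1, 1, 1)),
               "spacing")
  expect_error(image_volume(matrix(0, 3, 3)), "3D")
  expect_error(label_volume(array(2, c(3, 3, 3))), "0 or 1")
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
})

test_that("phantom volume written to disk has world bounds matching its spec", {
  ph <- phantom_full()
  f <- tempfile(fileext = ".nii.gz")
  write_volume(ph$image, f)
  back <- read_volume(f)
  spec <- ph$spec
  # grid extent derived from the generator's analytic margins
  expect_equal(vol_dim(back), vol_dim(ph$image))
  expect_equal(back$origin, ph$image$origin, tolerance = 1e-5)
  w <- spec$arch_width_mm
  xs_max <- back$origin[1] + (vol_dim(back)[1] - 1) * back$spacing[1]
  expect_gte(xs_max, w / 2)          # arch fits inside the written volume
  expect_lte(back$origin[1], -w / 2)
})

test_that("resampling preserves constants and world extent", {
  vol <- image_volume(array(3.5, c(8, 10, 6)), spacing = c(1, 2, 3))
  out <- resample(vol, c(5, 5, 5))
  expect_true(all(abs(out$data - 3.5) < 1e-12))
  # extent conservation arithmetic: 288x144x72 at (0.5,1,2) mm -> 144^3 at 1mm
  vol2 <- image_volume(array(0, c(288, 144, 72)), spacing = c(0.5, 1, 2))
  out2 <- resample(vol2, c(144, 144, 144))
  expect_equal(out2$spacing, c(1, 1, 1))
})

test_that("label resampling keeps labels binary and round-trips a ball", {
  # exact 2x down/up: centers aligned between the grids
  n <- 24L; nc <- 12L; r <- 10
  ball <- ball_mask(n, r)
  down <- resample(ball, rep(nc, 3))
  up <- resample(down, rep(n, 3))
  expect_true(all(up$data %in% c(0L, 1L)))
  # independent nearest-neighbour oracle on the analytic ball indicator:
  # voxel centers of the coarse grid snapped to the nearest source center
  ctr <- (n + 1) / 2
  oracle_coarse <- array(0L, rep(nc, 3))
  for (k in 1:nc) for (j in 1:nc) for (i in 1:nc) {
    wc <- (c(i, j, k) - 1) * (n / nc) + (n / nc + 1) / 2  # 1-based src coords
    nn <- round(wc)
    oracle_coarse[i, j, k] <- as.integer(sum((nn - ctr)^2) <= r^2)
  }
  d_oracle <- 2 * sum(oracle_coarse & down$data) /
    (sum(oracle_coarse) + sum(down$data))
  expect_gte(d_oracle, 0.95)
  d <- dice(up, ball)
  expect_gte(d, 0.9)
  expect_error(resample(ball, rep(nc, 3), mode = "trilinear"), "binary")
})

test_that("world_bounds matches definition and a brute-force oracle", {
  a <- array(0L, c(9, 9, 9)); a[3, 4, 5] <- 1L
  m <- label_volume(a)
  b <- world_bounds(m)
  expect_equal(b$min_corner, c(2, 3, 4))
  expect_equal(b$max_corner, c(2, 3, 4))
  full <- label_volume(array(1L, c(4, 5, 6)), spacing = c(2, 1, 1),
                       origin = c(10, 0, 0))
  bf <- world_bounds(full)
  expect_equal(bf$min_corner, c(10, 0, 0))
  expect_equal(bf$max_corner, c(10 + 3 * 2, 4, 5))
  set.seed(42)
  for (rep in 1:3) {
    r <- array(rbinom(7 * 8 * 9, 1, 0.05), c(7, 8, 9))
    if (sum(r) == 0) next
    lv <- label_volume(r, spacing = c(0.7, 1.1, 2.3), origin = c(-4, 2, 1))
    bb <- world_bounds(lv)
    idx <- which(r == 1L, arr.ind = TRUE)
    pts <- index_to_world(lv, idx)   # brute force over all foreground voxels
    expect_equal(bb$min_corner, unname(apply(pts, 2, min)))
    expect_equal(bb$max_corner, unname(apply(pts, 2, max)))
  }
  expect_error(world_bounds(label_volume(array(0L, c(3, 3, 3)))), "empty")
})

test_that("pad_box arithmetic including degenerate boxes", {
  b <- world_box(c(10, 10, 10), c(50, 50, 50))
  p <- pad_box(b, 5)
  expect_equal(p$min_corner, c(5, 5, 5))
  expect_equal(p$max_corner, c(55, 55, 55))
  expect_equal(pad_box(b, 0), b)
  dg <- pad_box(world_box(c(1, 2, 3), c(1, 2, 3)), 5)
  expect_equal(dg$max_corner - dg$min_corner, rep(10, 3))
  expect_error(pad_box(b, -1), ">= 0")
})

test_that("crop_world keeps world coordinates and clips to the volume", {
  set.seed(2)
  vol <- image_volume(array(rnorm(20^3), c(20, 20, 20)),
                      spacing = c(1, 1, 2), origin = c(0, 0, 0))
  # identity crop
  whole <- crop_world(vol, world_box(c(-5, -5, -5), c(100, 100, 100)))
  expect_identical(whole$data, vol$data)
  expect_equal(whole$origin, vol$origin)
  # coordinate conservation for an interior crop
  cr <- crop_world(vol, world_box(c(3, 3, 6), c(10, 10, 20)))
  expect_equal(cr$data[1, 1, 1],
               vol$data[4, 4, 4])
  expect_equal(index_to_world(cr, c(1, 1, 1)), c(3, 3, 6))
  # partial overlap clips, inventing no voxels: x in [-5, 4.2] keeps
  # centers 0..4 -> 5 voxels
  part <- crop_world(vol, world_box(c(-5, 0, 0), c(4.2, 100, 100)))
  expect_equal(vol_dim(part), c(5, 20, 20))
  expect_error(crop_world(vol, world_box(c(500, 0, 0), c(600, 5, 5))),
               "overlap")
})

test_that("crop/pad/bounds composition never loses mask voxels", {
  ph <- phantom_partial()
  m <- ph$gt_original
  box <- pad_box(world_bounds(m), 5)
  cr <- crop_world(m, box)
  expect_equal(sum(cr$data), sum(m$data))
})
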