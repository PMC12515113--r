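cube_label <- function(lo, hi, n = 20) {
  a <- array(0L, c(n, n, n))
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  label_volume(a)
}

test_that("voxel Dice: identity, disjoint, half-overlap, containment formula", {
  a <- cube_label(c(3, 3, 3), c(10, 10, 10))
  expect_equal(dice(a, a), 1.0)
  b <- cube_label(c(12, 12, 12), c(18, 18, 18))
  expect_equal(dice(a, b), 0.0)
  # two 8x8x8 cubes overlapping in half their volume
  c1 <- cube_label(c(1, 1, 1), c(8, 8, 8))
  c2 <- cube_label(c(5, 1, 1), c(12, 8, 8))
  expect_equal(dice(c1, c2), 0.5)
  # containment bound: A inside B with volumes v, V -> 2v/(v+V) exactly
  inner <- cube_label(c(4, 4, 4), c(9, 9, 9))     # 6^3
  outer <- cube_label(c(2, 2, 2), c(11, 11, 11))  # 10^3
  expect_equal(dice(inner, outer), 2 * 216 / (216 + 1000))
  expect_true(abs(dice(inner, outer) - dice(outer, inner)) < 1e-15)
  expect_error(dice(a, label_volume(array(0L, c(5, 5, 5)))), "grid|empty")
})

test_that("mesh-mode Dice via enclosed volumes matches closed forms", {
  # unit cubes overlapping half their volume
  m1 <- box_mesh(c(0, 0, 0), c(10, 10, 10))
  m2 <- box_mesh(c(5, 0, 0), c(15, 10, 10))
  expect_equal(dice(m1, m2, pitch = 0.25), 0.5, tolerance = 0.02)
  expect_equal(dice(m1, m1, pitch = 0.25), 1.0, tolerance = 1e-6)
})

test_that("mesh-mode and voxel-mode Dice agree on a phantom", {
  ph <- phantom_full()
  pred <- ph$gt_cl3
  gt <- ph$gt_original
  d_vox <- dice(pred, gt)
  d_mesh <- dice(extract_mesh(pred), extract_mesh(gt), pitch = 0.7)
  expect_lt(abs(d_mesh - d_vox), 0.01)
})

test_that("ASD: identical meshes, concentric spheres, parallel sheets", {
  sph <- icosphere(radius = 20, subdiv = 3)
  expect_equal(asd(sph, sph)$asd_mm, 0)
  sph2 <- icosphere(radius = 21, subdiv = 3)
  r <- asd(sph, sph2)
  expect_equal(r$asd_mm, 1.0, tolerance = 0.02)
  expect_equal(r$asd_mm, (r$dasd_ab_mm + r$dasd_ba_mm) / 2)
  # large parallel sheets 2 mm apart: ASD -> 2.0 as extent/separation -> inf
  grid_sheet <- function(z, n = 101, w = 200) {
    xy <- seq(-w / 2, w / 2, length.out = n)
    v <- as.matrix(expand.grid(x = xy, y = xy, z = z))
    f <- matrix(0L, 0, 3)
    id <- function(i, j) (j - 1L) * n + i
    for (j in 1:(n - 1)) for (i in 1:(n - 1)) {
      f <- rbind(f, c(id(i, j), id(i + 1, j), id(i, j + 1)),
                 c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
    }
    surface_mesh(v, f)
  }
  s0 <- grid_sheet(0); s2 <- grid_sheet(2)
  expect_equal(asd(s0, s2)$asd_mm, 2.0, tolerance = 0.04)
  # brute-force oracle on a small random point set
  set.seed(1)
  P <- matrix(rnorm(15, sd = 30), 5, 3)
  fast <- mandseg:::.point_mesh_dist(P, sph$vertices, sph$triangles)
  slow <- sapply(seq_len(nrow(P)), function(i) {
    min(sapply(seq_len(nrow(sph$triangles)), function(t) {
      tri <- sph$vertices[sph$triangles[t, ], ]
      # distance from point to triangle via quadratic programming over
      # barycentric coordinates (coarse grid refinement)
      uv <- expand.grid(u = seq(0, 1, 0.05), v = seq(0, 1, 0.05))
      uv <- uv[uv$u + uv$v <= 1, ]
      pts <- outer(1 - uv$u - uv$v, tri[1, ]) + outer(uv$u, tri[2, ]) +
        outer(uv$v, tri[3, ])
      sqrt(min(rowSums(sweep(pts, 2, P[i, ])^2)))
    }))
  })
  expect_equal(fast, slow, tolerance = 0.02)
})

test_that("curve distances: identity, rigid offset, brute-force oracle", {
  set.seed(3)
  t <- seq(0, 1, length.out = 40)
  # planar arc, so a z-offset is exactly perpendicular everywhere
  pts <- cbind(10 * cos(pi * t), 10 * sin(pi * t), 0)
  c1 <- curve_polyline(pts, "dental")
  expect_equal(curve_distance(c1, c1), 0)
  shifted <- curve_polyline(sweep(pts, 2, c(0, 0, 3), "+"), "dental")
  expect_equal(curve_distance(c1, shifted), 3.0, tolerance = 1e-9)
  expect_error(curve_distance(c1, curve_polyline(pts, "caudolateral")),
               "different kinds")
  # random polylines vs brute-force all-pairs closest-segment oracle
  p2 <- cbind(pts[, 1], pts[, 2], sin(7 * t)) +
    matrix(rnorm(length(pts), sd = 0.5), ncol = 3)
  c2 <- curve_polyline(p2, "dental")
  d_pkg <- curve_distance(c1, c2, n_stations = 40)
  seg_dist <- function(p, A, B) {
    ab <- B - A
    tt <- pmin(pmax(sum((p - A) * ab) / sum(ab^2), 0), 1)
    sqrt(sum((A + tt * ab - p)^2))
  }
  dir_mean <- function(P, Q) {
    mean(sapply(seq_len(nrow(P)), function(i) {
      min(sapply(seq_len(nrow(Q) - 1), function(s)
        seg_dist(P[i, ], Q[s, ], Q[s + 1, ])))
    }))
  }
  # same stations as the implementation (arch parameters match, n = rows)
  d_oracle <- (dir_mean(pts, p2) + dir_mean(p2, pts)) / 2
  expect_equal(d_pkg, d_oracle, tolerance = 1e-6)
})

test_that("extracted curves are translation-equivariant and need a U-shape", {
  ph <- phantom_full()
  mesh <- extract_mesh(ph$gt_original)
  for (kind in c("caudolateral", "dental")) {
    c0 <- extract_curve(mesh, kind)
    moved <- mesh
    moved$vertices <- sweep(mesh$vertices, 2, c(5, 5, 5), "+")
    c1 <- extract_curve(moved, kind)
    expect_equal(c1$points, sweep(c0$points, 2, c(5, 5, 5), "+"),
                 tolerance = 1e-9)
    expect_gte(nrow(c0$points), 10)
    expect_true(all(diff(c0$arch_parameter) > 0))
  }
  expect_error(extract_curve(icosphere(radius = 8), "dental"),
               "arch detection failed")
})

test_that("phantom curve metrics reproduce the expected anatomy", {
  ph <- phantom_partial()
  mo <- gt_mesh(ph, "O"); m3 <- gt_mesh(ph, "cl3"); m5 <- gt_mesh(ph, "cl5")
  # caudolateral: basal contour unchanged by ridge reduction
  cau <- curve_distance(extract_curve(mo, "caudolateral"),
                        extract_curve(m5, "caudolateral"))
  expect_lt(cau, 0.3)
  # dental: O -> Cl.III < O -> Cl.V, and the O/Cl.V height gap matches the
  # generator's analytic expectation within half a voxel
  dodo <- extract_curve(mo, "dental")
  d3 <- extract_curve(m3, "dental")
  d5 <- extract_curve(m5, "dental")
  expect_lt(curve_distance(dodo, d3), curve_distance(dodo, d5))
  gap <- mean(dodo$points[, 3]) - mean(d5$points[, 3])
  half_voxel <- max(ph$spec$spacing_mm) / 2
  expect_lt(abs(gap - ph$analytic_curves$dental_gap_o_cl5_mm), half_voxel)
})

test_that("evaluate_pair bundles Dice, ASD and curve metrics", {
  ph <- phantom_edentulous()
  r <- evaluate_pair(ph$gt_cl3, ph$gt_original, curves = TRUE,
                     taubin_iterations = 10)
  expect_true(r$dsc > 0.8 && r$dsc < 1)
  expect_gt(r$asd_mm, 0)
  expect_equal(r$asd_mm, (r$dasd_ab_mm + r$dasd_ba_mm) / 2)
  expect_lt(r$caudolateral_mm, 1)
  expect_gt(r$dental_mm, 0.5)
})
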