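test_that("extracted ball volume is accurate and converges with resolution", {
  ball <- ball_mask(25, 10)               # radius 10 mm at 1 mm spacing
  v_true <- 4 / 3 * pi * 10^3
  m1 <- extract_mesh(ball)
  err1 <- abs(mesh_volume(m1) - v_true) / v_true
  expect_lt(err1, 0.05)
  ball_fine <- ball_mask(49, 20, spacing = c(0.5, 0.5, 0.5))  # same sphere
  m2 <- extract_mesh(ball_fine)
  err2 <- abs(mesh_volume(m2) - v_true) / v_true
  expect_lt(err2, err1)                   # strictly decreasing error
})

test_that("single-voxel masks give closed meshes bounded by the voxel", {
  a <- array(0L, c(5, 5, 5)); a[3, 3, 3] <- 1L
  m <- extract_mesh(label_volume(a, spacing = c(1, 1, 2)))
  v <- mesh_volume(m)
  expect_gt(v, 0)
  expect_lte(v, 1 * 1 * 2)
  expect_error(extract_mesh(label_volume(array(0L, c(4, 4, 4)))), "empty")
})

test_that("anisotropic spacing yields the analytic ellipsoid volume", {
  n <- 25; ctr <- 13
  idx <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  inside <- (idx$i - ctr)^2 + (idx$j - ctr)^2 + (idx$k - ctr)^2 <= 100
  ball <- label_volume(array(as.integer(inside), c(n, n, n)),
                       spacing = c(1, 1, 2))
  # world-space shape: ellipsoid with semi-axes 10, 10, 20 mm
  v_true <- 4 / 3 * pi * 10 * 10 * 20
  expect_lt(abs(mesh_volume(extract_mesh(ball)) - v_true) / v_true, 0.05)
})

test_that("Taubin smoothing preserves volume where Laplacian shrinks", {
  ball <- ball_mask(25, 10)
  m <- extract_mesh(ball)
  v0 <- mesh_volume(m)
  expect_identical(taubin_smooth(m, iterations = 0), m)
  mt <- taubin_smooth(m, lambda = 0.5, nu = 0.5, iterations = 100)
  ml <- laplacian_smooth(m, lambda = 0.5, iterations = 100)
  expect_identical(mt$triangles, m$triangles)   # topology untouched
  expect_equal(nrow(mt$vertices), nrow(m$vertices))
  dv_t <- abs(mesh_volume(mt) - v0) / v0
  dv_l <- abs(mesh_volume(ml) - v0) / v0
  expect_lt(dv_t, 0.05)
  expect_lt(dv_t, dv_l)
  expect_error(taubin_smooth(m, nu = -0.5), "positive magnitude")
})

test_that("Taubin denoises a jittered sphere (radial RMS halved)", {
  sph <- icosphere(radius = 20, subdiv = 3)
  set.seed(99)
  noisy <- sph
  noisy$vertices <- noisy$vertices + matrix(rnorm(length(sph$vertices),
                                                  sd = 0.3),
                                            ncol = 3)
  rms_r <- function(m) {
    r <- sqrt(rowSums(m$vertices^2))
    sqrt(mean((r - 20)^2))
  }
  before <- rms_r(noisy)
  after <- rms_r(taubin_smooth(noisy, iterations = 100))
  expect_lt(after, before * 0.5)
})

test_that("largest_component matches a flood-fill oracle", {
  a <- array(0L, c(30, 30, 30))
  idx <- expand.grid(i = 1:30, j = 1:30, k = 1:30)
  b1 <- (idx$i - 9)^2 + (idx$j - 9)^2 + (idx$k - 9)^2 <= 25
  b2 <- (idx$i - 22)^2 + (idx$j - 22)^2 + (idx$k - 22)^2 <= 9
  a[b1 | b2] <- 1L
  lv <- label_volume(a)
  keep <- largest_component(lv)
  expect_identical(keep$data, array(as.integer(b1), c(30, 30, 30)))
  # single component -> identity
  solo <- label_volume(array(as.integer(b1), c(30, 30, 30)))
  expect_identical(largest_component(solo)$data, solo$data)
  # independent flood-fill oracle for component sizes (6/26-connectivity
  # agree for these well-separated balls)
  oracle_sizes <- local({
    seen <- array(FALSE, dim(a))
    sizes <- integer(0)
    for (s in which(a == 1L)) {
      if (seen[s]) next
      queue <- s; seen[s] <- TRUE; n <- 0L
      dims <- dim(a)
      while (length(queue)) {
        cur <- queue[length(queue)]; queue <- queue[-length(queue)]
        n <- n + 1L
        ci <- arrayInd(cur, dims)
        for (d in 1:3) for (dd in c(-1L, 1L)) {
          nb <- ci; nb[d] <- nb[d] + dd
          if (nb[d] < 1L || nb[d] > dims[d]) next
          lin <- nb[1] + dims[1] * (nb[2] - 1L + dims[2] * (nb[3] - 1L))
          if (a[lin] == 1L && !seen[lin]) {
            seen[lin] <- TRUE
            queue <- c(queue, lin)
          }
        }
      }
      sizes <- c(sizes, n)
    }
    sort(sizes)
  })
  lab <- mandseg:::.label_components26(a, dim(a))
  expect_equal(sort(tabulate(lab[lab > 0])), oracle_sizes)
  expect_error(largest_component(label_volume(array(0L, c(3, 3, 3)))),
               "empty")
})
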