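aug_fixture <- function(n = 24, r = 7) {
  ball <- ball_mask(n, r)
  img <- image_volume(array(as.double(ball$data) * 1000 - 500, c(n, n, n)))
  list(img = img, lab = ball)
}

test_that("zero probability is a bit-identical passthrough", {
  fx <- aug_fixture()
  cfg <- augment_config(per_transform_probability = 0)
  out <- augment_pair(fx$img, fx$lab, cfg, seed = 3)
  expect_identical(out$image$data, fx$img$data)
  expect_identical(out$labels$data, fx$lab$data)
})

test_that("mirroring is an exact involution", {
  fx <- aug_fixture()
  # make the volume asymmetric so mirroring is visible
  img <- fx$img; img$data[1:5, , ] <- 77
  lab <- fx$lab; lab$data[1:3, 1:3, 1:3] <- 1L
  cfg <- augment_config(per_transform_probability = c(1, 0, 0, 0, 0))
  once <- augment_pair(img, lab, cfg, seed = 1)
  expect_false(identical(once$image$data, img$data))
  twice <- augment_pair(once$image, once$labels, cfg, seed = 2)
  expect_equal(twice$image$data, img$data, tolerance = 1e-12)
  expect_identical(twice$labels$data, lab$data)
})

test_that("opposite rotations almost cancel on a centered ball", {
  fx <- aug_fixture(n = 32, r = 11)
  rot_only <- function(deg) {
    augment_config(rotation_deg_range = c(deg, deg),
                   per_transform_probability = c(0, 1, 0, 0, 0))
  }
  a <- augment_pair(fx$img, fx$lab, rot_only(20), seed = 1)
  b <- augment_pair(a$image, a$labels, rot_only(-20), seed = 2)
  d <- dice(b$labels, fx$lab)
  expect_gte(d, 0.95)  # interpolation loss only
})

test_that("image and labels stay co-registered under the full transform set", {
  fx <- aug_fixture()
  cfg <- augment_config(per_transform_probability = 1,
                        translation_voxels_range = c(-4, 4))
  for (seed in 1:4) {
    out <- augment_pair(fx$img, fx$lab, cfg, seed = seed)
    expect_true(all(out$labels$data %in% c(0L, 1L)))
    if (sum(out$labels$data) == 0) next
    # centroid of warped label vs centroid of bright image voxels
    ci <- which(out$labels$data == 1L, arr.ind = TRUE)
    bright <- which(out$image$data > 0, arr.ind = TRUE)
    expect_lt(max(abs(colMeans(ci) - colMeans(bright))), 1.0)
  }
})

test_that("same seed reproduces the same augmentation", {
  fx <- aug_fixture()
  cfg <- augment_config(per_transform_probability = 0.5)
  a <- augment_pair(fx$img, fx$lab, cfg, seed = 42)
  b <- augment_pair(fx$img, fx$lab, cfg, seed = 42)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$labels$data, b$labels$data)
})

test_that("mismatched grids are rejected and noise/blur stay unavailable", {
  fx <- aug_fixture()
  other <- label_volume(array(0L, c(10, 10, 10)))
  other$data[5, 5, 5] <- 1L
  cfg <- augment_config()
  expect_error(augment_pair(fx$img, other, cfg), "share a grid")
  # the configuration surface has no intensity-noise switch to enable
  expect_false(any(grepl("noise|blur", names(cfg), ignore.case = TRUE)))
  expect_error(augment_config(per_transform_probability = 2), "\\[0, 1\\]")
  expect_error(augment_config(scale_range = c(2, 1)), "ordered")
})
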