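tiny_cfg <- function(out_channels = 1L) {
  net_config(c(16L, 16L, 16L), depth = 2L, base_channels = 4L,
             out_channels = out_channels)
}

test_that("network config invariants are checked before allocation", {
  expect_error(net_config(c(50, 48, 48), depth = 3), "divisible")
  expect_error(net_config(out_channels = 2), "1 or 3")
  expect_error(net_config(depth = 1), "depth")
  cfg <- net_config_desk()
  expect_equal(cfg$input_shape, c(48L, 48L, 48L))
})

test_that("parameter count is a pure function of config; heads differ only in the final layer", {
  set.seed(1); n1 <- build_net(tiny_cfg(1L))
  set.seed(2); n1b <- build_net(tiny_cfg(1L))
  expect_equal(n_params(n1), n_params(n1b))
  set.seed(3); n3 <- build_net(tiny_cfg(3L))
  # trunk parameter counts identical; only the 1x1x1 head grows 3x
  head1 <- length(n1$final$w) + length(n1$final$b)
  head3 <- length(n3$final$w) + length(n3$final$b)
  expect_equal(n_params(n3) - head3, n_params(n1) - head1)
  expect_equal(head3, 3L * head1)
})

test_that("forward pass maps input shape to per-channel probabilities", {
  set.seed(5)
  net <- build_net(tiny_cfg(3L))
  x <- array(0, c(16, 16, 16))
  p <- mandseg:::net_forward(net, x)$prob
  expect_equal(dim(p), c(16L, 16L, 16L, 3L))
  expect_true(all(is.finite(p)))
  expect_true(all(p > 0 & p < 1))
})

test_that("prediction binarizes per channel and copies grid metadata", {
  set.seed(6)
  net <- build_net(tiny_cfg(1L))
  img <- image_volume(array(0.5, c(16, 16, 16)), spacing = c(2, 2, 2),
                      origin = c(1, 2, 3))
  full <- predict_volume(net, img, threshold = 0)
  expect_equal(sum(full$data), prod(vol_dim(img)))
  expect_equal(full$spacing, img$spacing)
  expect_equal(full$origin, img$origin)
  # probabilities all below a high threshold -> empty mask (the pipeline's
  # empty-detection input)
  empty <- predict_volume(net, img, threshold = 1)
  expect_equal(sum(empty$data), 0)
  bad <- image_volume(array(0, c(8, 8, 8)))
  expect_error(predict_volume(net, bad), "shape")
})

test_that("multi-label head uses independent sigmoids (channel independence)", {
  set.seed(7)
  net <- build_net(tiny_cfg(3L))
  x <- array(rnorm(16^3), c(16, 16, 16))
  p0 <- mandseg:::net_forward(net, x)$prob
  # probabilities are not softmax-coupled: voxelwise channel sums differ from 1
  sums <- apply(p0, 1:3, sum)
  expect_gt(max(abs(sums - 1)), 0.1)
  # perturbing one channel's head weights leaves the other channels unchanged
  net2 <- net
  net2$final$w[, 2] <- net2$final$w[, 2] + 1
  p1 <- mandseg:::net_forward(net2, x)$prob
  expect_identical(p1[, , , 1], p0[, , , 1])
  expect_identical(p1[, , , 3], p0[, , , 3])
  expect_gt(max(abs(p1[, , , 2] - p0[, , , 2])), 1e-4)
})

test_that("backward pass matches finite differences through the full net", {
  set.seed(8)
  cfg <- net_config(c(8L, 8L, 8L), depth = 2L, base_channels = 2L,
                    out_channels = 1L)
  net <- build_net(cfg)
  x <- array(rnorm(8^3), c(8, 8, 8, 1))
  target <- array(as.double(ball_mask(8, 3)$data), c(8, 8, 8, 1))
  fw <- mandseg:::net_forward(net, x, keep_cache = TRUE)
  lg <- mandseg:::dice_bce_loss(fw$prob, target)
  grads <- mandseg:::net_backward(net, fw$cache, lg$glogits)
  params <- mandseg:::flatten_params(net)
  loss_at <- function(params) {
    n2 <- mandseg:::set_params(net, params)
    f <- mandseg:::net_forward(n2, x)
    mandseg:::dice_bce_loss(f$prob, target)$loss
  }
  eps <- 1e-4
  set.seed(9)
  for (nm in c("enc1.1.w", "dec1.2.w", "final.w")) {
    i <- sample(length(params[[nm]]), 1)
    p2 <- params
    p2[[nm]][i] <- p2[[nm]][i] + eps
    fd <- (loss_at(p2) - loss_at(params)) / eps
    expect_equal(grads[[nm]][i], fd, tolerance = 5e-2)
  }
})

test_that("checkpoints round-trip predictions exactly at double precision", {
  set.seed(10)
  net <- build_net(tiny_cfg(1L))
  f <- tempfile(fileext = ".txt")
  save_net(net, f)
  back <- load_net(f)
  x <- array(rnorm(16^3), c(16, 16, 16))
  expect_equal(mandseg:::net_forward(back, x)$prob,
               mandseg:::net_forward(net, x)$prob, tolerance = 1e-12)
})

test_that("seeded training is deterministic", {
  co <- list(phantom_full(), phantom_partial(), phantom_edentulous())
  split <- c("train", "train", "validation")
  cfg <- net_config(c(16L, 16L, 16L), depth = 2L, base_channels = 2L)
  tc <- train_config(epochs = 2L)
  r1 <- train_stage(co, split, "first", config = cfg, tc = tc, seed = 5)
  r2 <- train_stage(co, split, "first", config = cfg, tc = tc, seed = 5)
  expect_equal(r1$history, r2$history)
  expect_identical(mandseg:::flatten_params(r1$net),
                   mandseg:::flatten_params(r2$net))
})
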