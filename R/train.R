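#' Training configuration
#'
#' Optimization settings for [train_stage()]. The loss is soft-Dice plus
#' binary cross-entropy, averaged over output channels; optimization is Adam.
#' Training stops early once the validation Dice reaches `stop_target` or has
#' not improved for `patience` epochs; the best-validation weights are kept.
#'
#' @param epochs maximum number of epochs.
#' @param lr Adam learning rate.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param patience early-stopping patience in epochs.
#' @param stop_target validation Dice at which training stops early.
#' @param threshold binarization threshold for validation Dice.
#' @param hu_window intensity normalization window (HU).
#' @param roi_pad_mm padding around the ground-truth bounding box used to
#'   build second-stage training crops.
#' @param augment logical; apply the spatial augmentation pipeline to
#'   training samples each epoch (default TRUE — in particular the scaling
#'   and translation transforms make the second stage robust to the
#'   region-of-interest size variation it meets at inference time).
#' @return a `TrainConfig` list.
#' @export
train_config <- function(epochs = 15L, lr = 2e-3, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, patience = 4L, stop_target = 0.90,
                         threshold = 0.5, hu_window = c(-200, 2500),
                         roi_pad_mm = 5, augment = TRUE) {
  structure(list(epochs = as.integer(epochs), lr = lr, beta1 = beta1,
                 beta2 = beta2, adam_eps = adam_eps,
                 patience = as.integer(patience), stop_target = stop_target,
                 threshold = threshold, hu_window = hu_window,
                 roi_pad_mm = roi_pad_mm, augment = isTRUE(augment)),
            class = "TrainConfig")
}

# soft-Dice + BCE loss and its gradient w.r.t. logits; prob/target are
# (D,H,W,C) arrays.
dice_bce_loss <- function(prob, target, eps = 1e-6) {
  nc <- dim(prob)[4]
  nvox <- prod(dim(prob)[1:3])
  glog <- array(0, dim(prob))
  loss <- 0
  for (c in seq_len(nc)) {
    p <- prob[, , , c]
    t <- target[, , , c]
    pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    bce <- -mean(t * log(pc) + (1 - t) * log(1 - pc))
    spt <- sum(p * t)
    num <- 2 * spt + eps
    den <- sum(p) + sum(t) + eps
    dice_loss <- 1 - num / den
    g_bce <- (pc - t) / nvox
    g_dice <- -(2 * t * den - num) / den^2 * (p * (1 - p))
    glog[, , , c] <- (g_bce + g_dice) / nc
    loss <- loss + (bce + dice_loss) / nc
  }
  list(loss = loss, glogits = glog)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  corr1 <- 1 - cfg$beta1^state$t
  corr2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - cfg$lr * mhat / (sqrt(vhat) + cfg$adam_eps)
  }
  list(params = params, state = state)
}

variant_label <- function(case, variant) {
  switch(variant,
         O = case$gt_original,
         cl3 = case$gt_cl3,
         cl5 = case$gt_cl5,
         multi = {
           d <- dim(case$gt_original$data)
           arr <- array(0L, c(d, 3L))
           arr[, , , 1] <- case$gt_original$data
           arr[, , , 2] <- case$gt_cl3$data
           arr[, , , 3] <- case$gt_cl5$data
           label_volume(arr, spacing = case$gt_original$spacing,
                        origin = case$gt_original$origin,
                        channel_names = c("O", "Cl.III", "Cl.V"))
         },
         stop("unknown variant: ", variant))
}

# Build one (input tensor, target tensor) training sample on the network grid.
prepare_sample <- function(case, stage, variant, shape, tc) {
  img <- case$image
  lab <- variant_label(case, variant)
  if (stage == "second") {
    box <- pad_box(world_bounds(case$gt_original), tc$roi_pad_mm)
    img <- crop_world(img, box)
    lab <- crop_world(lab, box)
  }
  img <- resample(normalize_intensity(img, tc$hu_window), shape,
                  mode = "trilinear")
  lab <- resample(lab, shape, mode = "nearest")
  x <- img$data
  dim(x) <- c(dim(x), 1L)
  t <- array(as.double(lab$data), c(shape, n_channels(lab)))
  list(x = x, target = t, image = img, label = lab)
}

#' Train one pipeline stage
#'
#' The first stage learns to localize the mandible on the whole field of view
#' (always trained against the original ground truth); second-stage models
#' are trained on crops around the padded ground-truth bounding box against
#' the requested variant (`"O"`, `"cl3"`, `"cl5"`, or `"multi"` for the
#' three-channel combined model). Per-epoch validation Dice drives early
#' stopping and best-checkpoint selection.
#'
#' @param cases list of phantom cases (or any objects with `image`,
#'   `gt_original`, `gt_cl3`, `gt_cl5` fields).
#' @param split a `SplitAssignment` from [stratified_split()], or a character
#'   vector (`"train"`/`"validation"`/`"test"`) parallel to `cases`.
#' @param stage `"first"` or `"second"`.
#' @param variant `"O"`, `"cl3"`, `"cl5"`, or `"multi"`; the first stage
#'   always uses `"O"`.
#' @param config a `NetConfig`.
#' @param tc a [train_config()].
#' @param ac an optional [augment_config()] used when `tc$augment` is TRUE.
#' @param seed integer seed controlling initialization, shuffling and
#'   augmentation.
#' @return list with elements `net` (best-validation `UNet3D`) and `history`
#'   (data.frame of epoch, train_loss, val_dice).
#' @export
train_stage <- function(cases, split, stage = c("first", "second"),
                        variant = "O", config = net_config_desk(),
                        tc = train_config(), ac = NULL, seed = 1L) {
  stage <- match.arg(stage)
  if (stage == "first") variant <- "O"
  if (variant == "multi" && config$out_channels != 3L)
    stop("multi-label training needs out_channels = 3")
  if (variant != "multi" && config$out_channels != 1L)
    stop("single-label training needs out_channels = 1")
  memb <- if (is.data.frame(split)) {
    split$split[match(seq_along(cases), split$case)]
  } else split
  tr_idx <- which(memb == "train")
  va_idx <- which(memb == "validation")
  if (length(tr_idx) == 0L) stop("empty training split")
  if (length(va_idx) == 0L) stop("empty validation split")
  if (tc$augment && is.null(ac))
    ac <- if (stage == "first") augment_config() else augment_config_stage2()
  set.seed(seed)
  net <- build_net(config)
  shape <- config$input_shape
  tr <- lapply(cases[tr_idx], prepare_sample, stage = stage,
               variant = variant, shape = shape, tc = tc)
  va <- lapply(cases[va_idx], prepare_sample, stage = stage,
               variant = variant, shape = shape, tc = tc)
  params <- flatten_params(net)
  st <- adam_init(params)
  best <- list(dice = -Inf, params = params)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_dice = numeric())
  stall <- 0L
  for (ep in seq_len(tc$epochs)) {
    ord <- sample(length(tr))
    ep_loss <- 0
    for (ii in ord) {
      s <- tr[[ii]]
      x <- s$x
      target <- s$target
      if (tc$augment && !is.null(ac)) {
        aug <- augment_tensor(s, ac, seed = seed * 10000L + ep * 100L + ii)
        x <- aug$x
        target <- aug$target
      }
      net <- set_params(net, params)
      fw <- net_forward(net, x, keep_cache = TRUE)
      lg <- dice_bce_loss(fw$prob, target)
      if (!is.finite(lg$loss))
        stop("NaN/Inf training loss at epoch ", ep,
             "; check intensity normalization and learning rate")
      ep_loss <- ep_loss + lg$loss
      grads <- net_backward(net, fw$cache, lg$glogits)
      upd <- adam_step(params, grads, st, tc)
      params <- upd$params
      st <- upd$state
    }
    net <- set_params(net, params)
    vd <- vapply(va, function(s) {
      pr <- net_forward(net, s$x)$prob
      channel_dice(pr >= tc$threshold, s$target)
    }, numeric(1))
    val_dice <- mean(vd)
    hist <- rbind(hist, data.frame(epoch = ep,
                                   train_loss = ep_loss / length(tr),
                                   val_dice = val_dice))
    if (val_dice > best$dice + 1e-4) {
      best <- list(dice = val_dice, params = params)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (val_dice >= tc$stop_target || stall >= tc$patience) break
  }
  net <- set_params(net, best$params)
  list(net = net, history = hist, best_val_dice = best$dice)
}

# mean Dice over channels of binary arrays
channel_dice <- function(pred, target) {
  nc <- dim(target)[4]
  d <- numeric(nc)
  for (c in seq_len(nc)) {
    p <- pred[, , , c]
    t <- target[, , , c]
    d[c] <- (2 * sum(p & (t > 0))) / max(sum(p) + sum(t), 1)
  }
  mean(d)
}

# apply spatial augmentation to a prepared sample (tensor form)
augment_tensor <- function(s, ac, seed) {
  res <- augment_pair(s$image, s$label, ac, seed = seed)
  x <- res[[1]]$data
  dim(x) <- c(dim(x), 1L)
  t <- array(as.double(res[[2]]$data),
             c(dim(res[[2]]$data)[1:3], n_channels(res[[2]])))
  list(x = x, target = t)
}
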