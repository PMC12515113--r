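#' U-Net configuration
#'
#' Describes a 3D U-Net with `depth` encoder levels, `base_channels` features
#' at the top level (doubled per level), two 3x3x3 conv + ReLU blocks per
#' level, 2x max-pooling, nearest-neighbour upsampling with skip
#' concatenation, and a 1x1x1 output head with an independent sigmoid per
#' channel. `out_channels` is 1 (single-label) or 3 (the multi-label head
#' with one channel each for the original, Class III and Class V variants —
#' sigmoids, not softmax, because the three targets overlap spatially).
#'
#' The scan-scale configuration uses `input_shape = c(144, 144, 144)`; a
#' desk-scale configuration (48^3, base 8) trains in minutes on one CPU.
#'
#' @param input_shape integer length-3; each entry divisible by
#'   `2^(depth-1)`.
#' @param depth number of resolution levels (>= 2).
#' @param base_channels features at the first level.
#' @param out_channels 1 or 3.
#' @param convs_per_block 2 (the classic double-conv block) or 1 (slim
#'   blocks, used by the desk-scale configuration to cut CPU cost roughly in
#'   half).
#' @return a `NetConfig` list.
#' @export
net_config <- function(input_shape = c(144L, 144L, 144L), depth = 3L,
                       base_channels = 16L, out_channels = 1L,
                       convs_per_block = 2L) {
  input_shape <- as.integer(input_shape)
  depth <- as.integer(depth)
  if (!out_channels %in% c(1L, 3L))
    stop("out_channels must be 1 or 3")
  if (depth < 2L) stop("depth must be >= 2")
  if (length(input_shape) != 3L || any(input_shape <= 0L))
    stop("input_shape must be 3 positive integers")
  if (any(input_shape %% 2L^(depth - 1L) != 0L))
    stop("input_shape must be divisible by 2^(depth-1) = ",
         2L^(depth - 1L))
  if (!convs_per_block %in% c(1L, 2L))
    stop("convs_per_block must be 1 or 2")
  structure(list(input_shape = input_shape, depth = depth,
                 base_channels = as.integer(base_channels),
                 out_channels = as.integer(out_channels),
                 convs_per_block = as.integer(convs_per_block),
                 final_activation = "sigmoid"),
            class = "NetConfig")
}

#' Desk-scale network configuration
#'
#' 48^3 input, 8 base channels, depth 3 — small enough to train on one CPU
#' core in minutes while exercising the full two-stage pipeline.
#'
#' @inheritParams net_config
#' @export
net_config_desk <- function(out_channels = 1L) {
  net_config(input_shape = c(48L, 48L, 48L), depth = 3L, base_channels = 8L,
             out_channels = out_channels, convs_per_block = 1L)
}

new_conv <- function(cin, cout, ksize, rng_sd = NULL) {
  nin <- cin * ksize^3
  if (is.null(rng_sd)) rng_sd <- sqrt(2 / nin)  # He initialization
  list(w = matrix(stats::rnorm(nin * cout, sd = rng_sd), nin, cout),
       b = rep(0, cout), ksize = as.integer(ksize), cin = cin, cout = cout)
}

#' Build a 3D U-Net
#'
#' Allocates and initializes all network weights for a [net_config()]. The
#' parameter count is a pure function of the configuration; initialization
#' uses the current RNG state (seed it for reproducible nets).
#'
#' @param config a `NetConfig`.
#' @return a `UNet3D` object (list of conv blocks).
#' @export
build_net <- function(config) {
  stopifnot(inherits(config, "NetConfig"))
  ch <- config$base_channels * 2L^(seq_len(config$depth) - 1L)
  two <- config$convs_per_block == 2L
  enc <- list()
  cin <- 1L
  for (l in seq_len(config$depth)) {
    enc[[l]] <- list(conv1 = new_conv(cin, ch[l], 3L),
                     conv2 = if (two) new_conv(ch[l], ch[l], 3L))
    cin <- ch[l]
  }
  dec <- list()
  for (l in rev(seq_len(config$depth - 1L))) {
    cat_in <- ch[l + 1L] + ch[l]  # upsampled deep + skip
    dec[[as.character(l)]] <- list(conv1 = new_conv(cat_in, ch[l], 3L),
                                   conv2 = if (two) new_conv(ch[l], ch[l], 3L))
  }
  final <- new_conv(ch[1L], config$out_channels, 1L, rng_sd = 0.01)
  # start the head near the foreground prior (~10%) so early epochs are not
  # spent escaping the all-background regime
  final$b <- rep(-2, config$out_channels)
  structure(list(config = config, enc = enc, dec = dec, final = final),
            class = "UNet3D")
}

#' @export
print.UNet3D <- function(x, ...) {
  cat(sprintf("UNet3D: input %s, depth %d, base %d, out_channels %d, %d parameters\n",
              paste(x$config$input_shape, collapse = "x"), x$config$depth,
              x$config$base_channels, x$config$out_channels, n_params(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param net a `UNet3D`.
#' @export
n_params <- function(net) {
  sum(vapply(flatten_params(net), length, numeric(1)))
}

flatten_params <- function(net) {
  out <- list()
  grab <- function(cv, tag) {
    if (is.null(cv)) return(invisible(NULL))
    out[[paste0(tag, ".w")]] <<- cv$w
    out[[paste0(tag, ".b")]] <<- cv$b
  }
  for (l in seq_along(net$enc)) {
    grab(net$enc[[l]]$conv1, paste0("enc", l, ".1"))
    grab(net$enc[[l]]$conv2, paste0("enc", l, ".2"))
  }
  for (nm in names(net$dec)) {
    grab(net$dec[[nm]]$conv1, paste0("dec", nm, ".1"))
    grab(net$dec[[nm]]$conv2, paste0("dec", nm, ".2"))
  }
  grab(net$final, "final")
  out
}

set_params <- function(net, params) {
  put <- function(cv, tag) {
    if (is.null(cv)) return(NULL)
    cv$w[] <- params[[paste0(tag, ".w")]]
    cv$b[] <- params[[paste0(tag, ".b")]]
    cv
  }
  for (l in seq_along(net$enc)) {
    net$enc[[l]]$conv1 <- put(net$enc[[l]]$conv1, paste0("enc", l, ".1"))
    net$enc[[l]]$conv2 <- put(net$enc[[l]]$conv2, paste0("enc", l, ".2"))
  }
  for (nm in names(net$dec)) {
    net$dec[[nm]]$conv1 <- put(net$dec[[nm]]$conv1, paste0("dec", nm, ".1"))
    net$dec[[nm]]$conv2 <- put(net$dec[[nm]]$conv2, paste0("dec", nm, ".2"))
  }
  net$final <- put(net$final, "final")
  net
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

conv_fwd <- function(cv, x) .conv3_forward(x, dim(x), cv$w, cv$b, cv$ksize)

cat4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# Forward pass; returns sigmoid probabilities and (optionally) every
# intermediate needed for the backward pass.
net_forward <- function(net, x, keep_cache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  depth <- net$config$depth
  cache <- list(x = x)
  a <- x
  skips <- list()
  block_fwd <- function(blk, a) {
    a1 <- relu_fwd(conv_fwd(blk$conv1, a))
    a2 <- if (is.null(blk$conv2)) a1 else relu_fwd(conv_fwd(blk$conv2, a1))
    list(a1 = a1, a2 = a2)
  }
  for (l in seq_len(depth)) {
    bf <- block_fwd(net$enc[[l]], a)
    cache[[paste0("enc", l)]] <- c(list(in_ = a), bf)
    skips[[l]] <- bf$a2
    if (l < depth) {
      mp <- .maxpool2_forward(bf$a2, dim(bf$a2))
      cache[[paste0("pool", l)]] <- mp$idx
      a <- mp$y
    } else {
      a <- bf$a2
    }
  }
  for (l in rev(seq_len(depth - 1L))) {
    up <- .upsample2_forward(a, dim(a))
    ct <- cat4(up, skips[[l]])
    blk <- net$dec[[as.character(l)]]
    bf <- block_fwd(blk, ct)
    cache[[paste0("dec", l)]] <- c(list(in_ = ct, up_dim = dim(a)), bf)
    a <- bf$a2
  }
  logits <- conv_fwd(net$final, a)
  prob <- 1 / (1 + exp(-logits))
  cache$head_in <- a
  cache$logits <- logits
  if (!keep_cache) cache <- NULL
  list(prob = prob, cache = cache)
}

# Backward pass from dLoss/dlogits; returns gradient list parallel to
# flatten_params().
net_backward <- function(net, cache, glogits) {
  grads <- list()
  depth <- net$config$depth
  bk <- .conv3_backward(cache$head_in, dim(cache$head_in), net$final$w,
                        glogits, net$final$ksize)
  grads[["final.w"]] <- bk$gw; grads[["final.b"]] <- bk$gb
  g <- bk$gx
  for (l in seq_len(depth - 1L)) {
    cc <- cache[[paste0("dec", l)]]
    blk <- net$dec[[as.character(l)]]
    if (!is.null(blk$conv2)) {
      g <- g * (cc$a2 > 0)
      bk <- .conv3_backward(cc$a1, dim(cc$a1), blk$conv2$w, g, 3L)
      grads[[paste0("dec", l, ".2.w")]] <- bk$gw
      grads[[paste0("dec", l, ".2.b")]] <- bk$gb
      g <- bk$gx
    }
    g <- g * (cc$a1 > 0)
    bk <- .conv3_backward(cc$in_, dim(cc$in_), blk$conv1$w, g, 3L)
    grads[[paste0("dec", l, ".1.w")]] <- bk$gw
    grads[[paste0("dec", l, ".1.b")]] <- bk$gb
    # split concat gradient: first channels -> upsampled path, rest -> skip
    cup <- cc$up_dim[4]
    gup <- bk$gx[, , , seq_len(cup), drop = FALSE]
    cache[[paste0("skipgrad", l)]] <-
      bk$gx[, , , cup + seq_len(dim(bk$gx)[4] - cup), drop = FALSE]
    g <- .upsample2_backward(gup, cc$up_dim)
  }
  # encoder, deepest first; g currently flows into enc[depth] output
  for (l in rev(seq_len(depth))) {
    cc <- cache[[paste0("enc", l)]]
    if (l < depth) {
      gpool <- .maxpool2_backward(g, cache[[paste0("pool", l)]], dim(cc$a2))
      g <- gpool + cache[[paste0("skipgrad", l)]]
    }
    blk <- net$enc[[l]]
    if (!is.null(blk$conv2)) {
      g <- g * (cc$a2 > 0)
      bk <- .conv3_backward(cc$a1, dim(cc$a1), blk$conv2$w, g, 3L)
      grads[[paste0("enc", l, ".2.w")]] <- bk$gw
      grads[[paste0("enc", l, ".2.b")]] <- bk$gb
      g <- bk$gx
    }
    g <- g * (cc$a1 > 0)
    bk <- .conv3_backward(cc$in_, dim(cc$in_), blk$conv1$w, g, 3L)
    grads[[paste0("enc", l, ".1.w")]] <- bk$gw
    grads[[paste0("enc", l, ".1.b")]] <- bk$gb
    g <- bk$gx
  }
  grads
}

#' Run a network on an image and binarize the prediction
#'
#' The image must already be on the network grid (see [normalize_intensity()]
#' and [resample()]); each output channel is thresholded independently.
#'
#' @param net a `UNet3D`.
#' @param image an `ImageVolume` whose grid matches `net$config$input_shape`.
#' @param threshold binarization threshold in (0, 1); probabilities strictly
#'   greater than `threshold` become foreground (so `threshold = 0` marks
#'   everything foreground).
#' @return a `LabelVolume` (multi-channel when `out_channels = 3`) on the
#'   image's grid.
#' @export
predict_volume <- function(net, image, threshold = 0.5) {
  stopifnot(inherits(net, "UNet3D"))
  if (!all(vol_dim(image) == net$config$input_shape))
    stop("image shape ", paste(vol_dim(image), collapse = "x"),
         " does not match network input shape ",
         paste(net$config$input_shape, collapse = "x"))
  prob <- net_forward(net, image$data)$prob
  mask <- array(0L, dim(prob))
  mask[prob >= threshold] <- 1L
  if (dim(mask)[4] == 1L) dim(mask) <- dim(mask)[1:3]
  nm <- if (net$config$out_channels == 3L) c("O", "Cl.III", "Cl.V") else NULL
  label_volume(mask, spacing = image$spacing, origin = image$origin,
               channel_names = nm)
}

#' Clip-and-rescale CT intensity normalization
#'
#' Clips intensities to a Hounsfield window and rescales linearly to
#' \[0, 1\]. Default window (-200, 2500) HU spans air through tooth enamel.
#'
#' @param image an `ImageVolume`.
#' @param window length-2 HU window.
#' @return an `ImageVolume` with values in \[0, 1\].
#' @export
normalize_intensity <- function(image, window = c(-200, 2500)) {
  d <- pmin(pmax(image$data, window[1]), window[2])
  d <- (d - window[1]) / (window[2] - window[1])
  image_volume(d, spacing = image$spacing, origin = image$origin)
}

#' Save / load network weights
#'
#' Checkpoints are plain text: a one-line header with the architecture
#' followed by one named, flattened weight vector per conv block. Round-trips
#' at full double precision.
#'
#' @param net a `UNet3D`.
#' @param path file path.
#' @export
save_net <- function(net, path) {
  params <- flatten_params(net)
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- net$config
  writeLines(sprintf("mandseg-unet3d 1 %d %d %d %d %d %d %d",
                     cfg$input_shape[1], cfg$input_shape[2],
                     cfg$input_shape[3], cfg$depth, cfg$base_channels,
                     cfg$out_channels, cfg$convs_per_block), con)
  for (nm in names(params)) {
    v <- params[[nm]]
    writeLines(sprintf("%s %d", nm, length(v)), con)
    writeLines(paste(sprintf("%.17g", as.vector(v)), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname save_net
#' @export
load_net <- function(path) {
  lines <- readLines(path)
  hd <- strsplit(lines[1], " ")[[1]]
  if (hd[1] != "mandseg-unet3d") stop("not a mandseg network checkpoint")
  cfg <- net_config(input_shape = as.integer(hd[3:5]),
                    depth = as.integer(hd[6]),
                    base_channels = as.integer(hd[7]),
                    out_channels = as.integer(hd[8]),
                    convs_per_block = as.integer(hd[9]))
  net <- build_net(cfg)
  params <- flatten_params(net)
  i <- 2L
  while (i < length(lines)) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    nm <- kv[1]
    vals <- as.numeric(strsplit(trimws(lines[i + 1L]), "\\s+")[[1]])
    stopifnot(length(vals) == as.integer(kv[2]))
    params[[nm]][] <- vals
    i <- i + 2L
  }
  set_params(net, params)
}
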