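#' Augmentation configuration
#'
#' Spatial training-time augmentation: elastic deformation, random rotation,
#' translation, isotropic scaling, and left-right mirroring, each applied
#' independently with `per_transform_probability`. Intensity noise/blur are
#' deliberately absent from the pipeline and cannot be enabled here.
#'
#' Elastic parameter semantics (this package's convention, exposed because
#' conventions differ between libraries): control points are placed every
#' `sigma` voxels (sigma drawn uniformly from `elastic_sigma_range`), each
#' with an independent offset drawn uniformly from
#' `magnitude * 0.004` voxels, where magnitude is drawn from
#' `elastic_magnitude_range`; the coarse field is trilinearly upsampled to a
#' dense displacement. A magnitude of 250 therefore corresponds to typical
#' displacements of about one voxel, 2500 to about ten.
#'
#' @param elastic_magnitude_range elastic offset magnitude range; the
#'   first-stage default is c(250, 1000), second-stage models use
#'   c(1000, 2500).
#' @param elastic_sigma_range control-point spacing range in voxels.
#' @param rotation_deg_range rotation per axis, degrees.
#' @param translation_voxels_range translation per axis, voxels (applied on
#'   the network-resolution grid).
#' @param scale_range isotropic scale factor range.
#' @param mirror_axis axis index mirrored (1 = left-right in the internal
#'   axis convention).
#' @param per_transform_probability probability each transform is applied;
#'   either a scalar shared by all five transforms or a length-5 vector in
#'   the order (mirror, rotation, scaling, translation, elastic), which
#'   allows single-transform configurations for testing.
#' @param fill_value image fill for regions mapped from outside the grid;
#'   `NULL` (default) uses the image minimum, i.e. air-equivalent intensity.
#'   Labels always fill with 0.
#' @return an `AugmentConfig`.
#' @export
augment_config <- function(elastic_magnitude_range = c(250, 1000),
                           elastic_sigma_range = c(10, 13),
                           rotation_deg_range = c(-20, 20),
                           translation_voxels_range = c(-30, 30),
                           scale_range = c(0.75, 1.25),
                           mirror_axis = 1L,
                           per_transform_probability = 0.5,
                           fill_value = NULL) {
  chk <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2]) stop(nm, " must be an ordered pair")
  }
  chk(elastic_magnitude_range, "elastic_magnitude_range")
  chk(elastic_sigma_range, "elastic_sigma_range")
  chk(rotation_deg_range, "rotation_deg_range")
  chk(translation_voxels_range, "translation_voxels_range")
  chk(scale_range, "scale_range")
  if (!length(per_transform_probability) %in% c(1L, 5L) ||
      any(per_transform_probability < 0) || any(per_transform_probability > 1))
    stop("per_transform_probability must be in [0, 1] (scalar or length 5)")
  if (length(per_transform_probability) == 1L)
    per_transform_probability <- rep(per_transform_probability, 5L)
  names(per_transform_probability) <-
    c("mirror", "rotation", "scale", "translation", "elastic")
  structure(list(elastic_magnitude_range = elastic_magnitude_range,
                 elastic_sigma_range = elastic_sigma_range,
                 rotation_deg_range = rotation_deg_range,
                 translation_voxels_range = translation_voxels_range,
                 scale_range = scale_range, mirror_axis = as.integer(mirror_axis),
                 per_transform_probability = per_transform_probability,
                 fill_value = fill_value),
            class = "AugmentConfig")
}

#' Second-stage augmentation defaults
#'
#' Same as [augment_config()] but with the stronger elastic magnitude range
#' used for the region-of-interest models.
#' @param ... overrides passed to [augment_config()].
#' @export
augment_config_stage2 <- function(...) {
  augment_config(elastic_magnitude_range = c(1000, 2500), ...)
}

rot_mat <- function(deg, axis) {
  th <- deg * pi / 180
  R <- diag(3)
  ax <- setdiff(1:3, axis)
  R[ax[1], ax[1]] <- cos(th); R[ax[2], ax[2]] <- cos(th)
  R[ax[1], ax[2]] <- -sin(th); R[ax[2], ax[1]] <- sin(th)
  R
}

# Draw the sampled transform for a seed: a 3x4 output-index -> source-index
# affine (about the volume center) plus an optional dense displacement field.
sample_transform <- function(cfg, dims, seed) {
  set.seed(seed)
  p <- cfg$per_transform_probability
  R <- diag(3)
  use <- stats::runif(5) < p  # (mirror, rotation, scale, translation, elastic)
  if (use[1]) {
    M <- diag(3)
    M[cfg$mirror_axis, cfg$mirror_axis] <- -1
    R <- R %*% M
  }
  if (use[2]) {
    angs <- stats::runif(3, cfg$rotation_deg_range[1], cfg$rotation_deg_range[2])
    R <- R %*% rot_mat(angs[1], 1) %*% rot_mat(angs[2], 2) %*% rot_mat(angs[3], 3)
  }
  if (use[3]) {
    s <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
    R <- R * (1 / s)  # output scaled by s means sampling source at 1/s
  }
  tr <- c(0, 0, 0)
  if (use[4])
    tr <- stats::runif(3, cfg$translation_voxels_range[1],
                       cfg$translation_voxels_range[2])
  ctr <- (dims - 1) / 2
  # src = R (o - ctr) + ctr - tr
  A <- cbind(R, ctr - R %*% ctr - tr)
  disp <- NULL
  if (use[5]) {
    mag <- stats::runif(1, cfg$elastic_magnitude_range[1],
                        cfg$elastic_magnitude_range[2])
    sig <- stats::runif(1, cfg$elastic_sigma_range[1],
                        cfg$elastic_sigma_range[2])
    ng <- pmax(2L, as.integer(ceiling(dims / sig)) + 1L)
    amp <- mag * 0.004
    disp <- array(0, c(dims, 3L))
    for (ax in 1:3) {
      coarse <- array(stats::runif(prod(ng), -amp, amp), ng)
      # trilinear upsample of the control grid to the dense grid
      scl <- (ng - 1) / pmax(dims - 1, 1)
      Au <- cbind(diag(scl), c(0, 0, 0))
      disp[, , , ax] <- .warp_volume(coarse, ng, dims, Au, NULL, 1L, 0)
    }
  }
  list(A = A, disp = disp, used = use)
}

#' Apply one random spatial augmentation to an image/label pair
#'
#' Image and labels receive the identical spatial transform; images are
#' sampled trilinearly, labels nearest-neighbour (so they stay binary). With
#' `per_transform_probability = 0` the pair passes through bit-identically.
#' The same seed always produces the same transform.
#'
#' @param image an `ImageVolume`.
#' @param labels a `LabelVolume` on the same grid.
#' @param cfg an [augment_config()].
#' @param seed integer seed for this draw.
#' @return list of the transformed `(image, labels)`.
#' @export
augment_pair <- function(image, labels, cfg, seed = 1L) {
  if (!all(vol_dim(image) == vol_dim(labels)) ||
      max(abs(image$spacing - labels$spacing)) > 1e-9 ||
      max(abs(image$origin - labels$origin)) > 1e-9)
    stop("image and labels must share a grid")
  dims <- vol_dim(image)
  tf <- sample_transform(cfg, dims, seed)
  if (!any(tf$used)) return(list(image = image, labels = labels))
  fill <- if (is.null(cfg$fill_value)) min(image$data) else cfg$fill_value
  dv <- if (is.null(tf$disp)) NULL else as.vector(tf$disp)
  img_out <- .warp_volume(image$data, dims, dims, tf$A, dv, 1L, fill)
  warp_lab <- function(a) {
    storage.mode(a) <- "double"
    .warp_volume(a, dims, dims, tf$A, dv, 0L, 0)
  }
  nc <- n_channels(labels)
  if (nc == 1L) {
    lab_out <- warp_lab(labels$data)
  } else {
    lab_out <- array(0, c(dims, nc))
    for (ch in seq_len(nc)) lab_out[, , , ch] <- warp_lab(labels$data[, , , ch])
  }
  list(image = image_volume(img_out, image$spacing, image$origin),
       labels = label_volume(lab_out, labels$spacing, labels$origin,
                             channel_names = labels$channel_names))
}
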