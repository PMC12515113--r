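#' @useDynLib mandseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Image volumes with world-coordinate metadata
#'
#' An `ImageVolume` is a 3D scalar grid (CT-like intensities in Hounsfield
#' units) together with the metadata that defines the voxel-to-world map:
#' per-axis voxel spacing in mm and the world position (mm) of the center of
#' voxel `(1,1,1)`. Axes are held internally in a fixed right-handed RAS-like
#' order; files with other axis-aligned orientations are normalized on read.
#' World coordinates are voxel-center based:
#' `world = origin + (index - 1) * spacing`.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel size per axis in mm (all > 0).
#' @param origin numeric length-3, world mm position of the first voxel center.
#' @return An object of class `ImageVolume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L || any(dim(data) <= 0L))
    stop("data must be a 3D array with positive dimensions")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 orientation = "RAS"),
            class = "ImageVolume")
}

#' Binary label volumes
#'
#' A `LabelVolume` shares an [image_volume()] grid and stores one or more
#' binary channels (e.g. the three ground-truth variants original / Class III
#' / Class V). Channels are independent and may overlap spatially; every
#' value must be exactly 0 or 1. Single-channel data is a 3D array,
#' multi-channel data a 4D array with channels last.
#'
#' @param data 3D (single channel) or 4D (channels last) array of 0/1 values.
#' @param spacing,origin grid metadata, as for [image_volume()].
#' @param channel_names optional character vector naming the channels.
#' @return An object of class `LabelVolume`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         channel_names = NULL) {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop("label data must be a 3D or 4D array")
  if (!all(data %in% c(0, 1))) stop("label values must be exactly 0 or 1")
  storage.mode(data) <- "integer"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (any(spacing <= 0)) stop("spacing must be positive (mm)")
  nchan <- if (nd == 3L) 1L else dim(data)[4]
  if (!is.null(channel_names) && length(channel_names) != nchan)
    stop("channel_names length must match the number of channels")
  structure(list(data = data, spacing = spacing, origin = origin,
                 orientation = "RAS", channel_names = channel_names),
            class = "LabelVolume")
}

is_label <- function(vol) inherits(vol, "LabelVolume")

n_channels <- function(vol) {
  if (length(dim(vol$data)) == 4L) dim(vol$data)[4] else 1L
}

#' Grid dimensions of a volume
#' @param vol an `ImageVolume` or `LabelVolume`.
#' @return integer length-3 spatial dimensions.
#' @export
vol_dim <- function(vol) dim(vol$data)[1:3]

#' Voxel index to world coordinates
#'
#' Maps 1-based (possibly fractional) voxel indices to world mm via the
#' affine `world = origin + (index - 1) * spacing`; [world_to_index()] is its
#' exact inverse.
#'
#' @param vol a volume.
#' @param index numeric length-3 or an n x 3 matrix of 1-based indices.
#' @return world coordinates, same shape as `index`.
#' @export
index_to_world <- function(vol, index) {
  if (is.matrix(index))
    sweep(sweep(index - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  else vol$origin + (index - 1) * vol$spacing
}

#' @rdname index_to_world
#' @param world world mm coordinates (length-3 or n x 3 matrix).
#' @export
world_to_index <- function(vol, world) {
  if (is.matrix(world))
    sweep(sweep(world, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
  else (world - vol$origin) / vol$spacing + 1
}

#' @export
print.ImageVolume <- function(x, ...) {
  cat(sprintf("ImageVolume %s, spacing (%s) mm, origin (%s) mm\n",
              paste(vol_dim(x), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
print.LabelVolume <- function(x, ...) {
  cat(sprintf("LabelVolume %s, %d channel(s), %d foreground voxel(s)\n",
              paste(vol_dim(x), collapse = "x"), n_channels(x),
              sum(x$data)))
  invisible(x)
}

nifti_affine <- function(vol) {
  rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
}

#' Read / write volumes as NIfTI-1
#'
#' Volumes are stored as NIfTI-1 (`.nii` / `.nii.gz`) with the voxel-to-world
#' map in the qform/sform. On read, axis-aligned orientations are normalized
#' to the internal RAS convention; oblique (sheared/rotated) affines are
#' rejected with an explicit error, as are non-positive spacings. Image data
#' round-trips losslessly (`double` on disk); labels are written as `uint8`.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param label logical; read as a [label_volume()]? 4D files are always read
#'   as multi-channel labels.
#' @return an `ImageVolume` or `LabelVolume`.
#' @export
read_volume <- function(path, label = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) == 4L) label <- TRUE
  if (!length(dm) %in% c(3L, 4L)) stop("expected a 3D or 4D NIfTI volume")
  if (length(dm) == 4L && dm[4] == 1L) dm <- dm[1:3]
  try_orient <- try({
    RNifti::orientation(img) <- "RAS"
  }, silent = TRUE)
  if (inherits(try_orient, "try-error"))
    stop("unreadable orientation metadata (qform/sform) in ", path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  sp <- sqrt(colSums(rot^2))
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing (pixdim) in NIfTI header of ", path)
  if (max(abs(rot - diag(sp))) > 1e-4 * max(sp))
    stop("oblique orientation (non-axis-aligned qform/sform) is not supported: ",
         path)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  origin <- aff[1:3, 4]
  if (label) {
    if (!all(a %in% c(0, 1)))
      stop("label volume contains values other than 0/1: ", path)
    label_volume(a, spacing = sp, origin = origin)
  } else {
    storage.mode(a) <- "double"
    image_volume(a, spacing = sp, origin = origin)
  }
}

#' @rdname read_volume
#' @param vol volume to write.
#' @export
write_volume <- function(vol, path) {
  dtype <- if (is_label(vol)) "uint8" else "double"
  pd <- c(-1, vol$spacing, rep(0, 4))
  img <- RNifti::asNifti(vol$data, reference = list(pixdim = pd),
                         datatype = dtype)
  aff <- nifti_affine(vol)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Resample a volume to a target grid shape
#'
#' The world extent of the sampled region (voxel edge to voxel edge) is
#' preserved, so the output spacing is `extent / target_shape`. Intensities
#' use trilinear interpolation; labels must use nearest-neighbour so they
#' stay binary.
#'
#' @param vol an `ImageVolume` or `LabelVolume`.
#' @param target_shape integer length-3 of positive grid dimensions.
#' @param mode `"trilinear"` or `"nearest"`; labels require `"nearest"`.
#' @param fill value used outside the source grid (default: edge behaviour
#'   never triggers it since the target covers the same extent).
#' @return a volume of the same class on the new grid.
#' @export
resample <- function(vol, target_shape,
                     mode = if (is_label(vol)) "nearest" else "trilinear",
                     fill = 0) {
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape <= 0L))
    stop("target_shape must be 3 positive integers")
  mode <- match.arg(mode, c("trilinear", "nearest"))
  if (is_label(vol) && mode != "nearest")
    stop("labels must be resampled with mode='nearest' to stay binary")
  sdim <- vol_dim(vol)
  extent <- sdim * vol$spacing
  new_spacing <- extent / target_shape
  # voxel-edge-aligned grids: first new center sits at edge + new_spacing/2
  edge_min <- vol$origin - vol$spacing / 2
  new_origin <- edge_min + new_spacing / 2
  # source index (0-based) of target voxel o: diag scale + offset
  scale <- new_spacing / vol$spacing
  off <- (new_origin - vol$origin) / vol$spacing
  A <- cbind(diag(scale), off)
  m <- if (mode == "nearest") 0L else 1L
  resamp1 <- function(a) {
    storage.mode(a) <- "double"
    .warp_volume(a, sdim, target_shape, A, NULL, m, fill)
  }
  if (is_label(vol)) {
    nc <- n_channels(vol)
    if (nc == 1L) {
      out <- resamp1(vol$data)
    } else {
      out <- array(0, c(target_shape, nc))
      for (ch in seq_len(nc)) out[, , , ch] <- resamp1(vol$data[, , , ch])
    }
    label_volume(out, spacing = new_spacing, origin = new_origin,
                 channel_names = vol$channel_names)
  } else {
    image_volume(resamp1(vol$data), spacing = new_spacing, origin = new_origin)
  }
}

#' Axis-aligned world-space boxes
#'
#' A `WorldBox` is a closed axis-aligned box in world mm. [world_bounds()]
#' returns the tightest box containing all foreground voxel centers of a
#' mask; [pad_box()] moves the corners outward by a margin (no clipping —
#' clipping to the image extent happens at crop time).
#'
#' @param min_corner,max_corner numeric length-3 mm, componentwise
#'   `max_corner >= min_corner`.
#' @return a `WorldBox`.
#' @export
world_box <- function(min_corner, max_corner) {
  min_corner <- as.numeric(min_corner)
  max_corner <- as.numeric(max_corner)
  if (length(min_corner) != 3L || length(max_corner) != 3L)
    stop("box corners must be length-3")
  if (any(max_corner < min_corner))
    stop("max_corner must be >= min_corner componentwise")
  structure(list(min_corner = min_corner, max_corner = max_corner),
            class = "WorldBox")
}

#' @export
print.WorldBox <- function(x, ...) {
  cat(sprintf("WorldBox (%s) - (%s) mm\n",
              paste(format(x$min_corner), collapse = ", "),
              paste(format(x$max_corner), collapse = ", ")))
  invisible(x)
}

#' @rdname world_box
#' @param mask a non-empty `LabelVolume` (any channel counts as foreground).
#' @export
world_bounds <- function(mask) {
  stopifnot(is_label(mask))
  d <- mask$data
  if (length(dim(d)) == 4L) d <- apply(d, 1:3, max)
  idx <- which(d != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("empty mask: no foreground voxels detected", call. = FALSE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  world_box(index_to_world(mask, lo), index_to_world(mask, hi))
}

#' @rdname world_box
#' @param box a `WorldBox`.
#' @param margin_mm non-negative padding in mm applied on every side.
#' @export
pad_box <- function(box, margin_mm) {
  if (length(margin_mm) == 1L) margin_mm <- rep(margin_mm, 3)
  if (any(margin_mm < 0)) stop("margin_mm must be >= 0")
  world_box(box$min_corner - margin_mm, box$max_corner + margin_mm)
}

#' Crop a volume to a world-space box
#'
#' Keeps every voxel whose center lies inside `box` intersected with the
#' image extent; the origin is updated so retained voxels keep their world
#' coordinates exactly. No padding voxels are invented for box parts outside
#' the volume.
#'
#' @param vol a volume.
#' @param box a `WorldBox` intersecting the volume's world extent.
#' @return a volume of the same class.
#' @export
crop_world <- function(vol, box) {
  d <- vol_dim(vol)
  lo_idx <- pmax(1L, as.integer(ceiling(world_to_index(vol, box$min_corner) - 1e-9)))
  hi_idx <- pmin(d, as.integer(floor(world_to_index(vol, box$max_corner) + 1e-9)))
  if (any(lo_idx > hi_idx))
    stop("crop box does not overlap the volume's world extent")
  i <- lo_idx[1]:hi_idx[1]; j <- lo_idx[2]:hi_idx[2]; k <- lo_idx[3]:hi_idx[3]
  new_origin <- index_to_world(vol, lo_idx)
  if (is_label(vol)) {
    if (length(dim(vol$data)) == 4L) {
      out <- vol$data[i, j, k, , drop = FALSE]
    } else {
      out <- vol$data[i, j, k, drop = FALSE]
    }
    label_volume(out, spacing = vol$spacing, origin = new_origin,
                 channel_names = vol$channel_names)
  } else {
    image_volume(vol$data[i, j, k, drop = FALSE], spacing = vol$spacing,
                 origin = new_origin)
  }
}

#' Extract one channel of a multi-channel label volume
#' @param mask a `LabelVolume`.
#' @param channel channel index or name.
#' @return a single-channel `LabelVolume`.
#' @export
label_channel <- function(mask, channel) {
  stopifnot(is_label(mask))
  if (length(dim(mask$data)) == 3L) {
    if (!identical(channel, 1L) && !identical(channel, 1))
      stopifnot(channel %in% c(mask$channel_names, 1))
    return(mask)
  }
  if (is.character(channel)) channel <- match(channel, mask$channel_names)
  label_volume(mask$data[, , , channel, drop = TRUE], spacing = mask$spacing,
               origin = mask$origin,
               channel_names = mask$channel_names[channel])
}

#' Paste a (cropped / resampled) label onto a reference grid
#'
#' Samples the label nearest-neighbour at every voxel center of the reference
#' grid; voxels outside the label's extent become background. Used to bring
#' network-resolution predictions back to the native resolution of the
#' original scan.
#'
#' @param label a `LabelVolume`.
#' @param ref a volume defining the target grid.
#' @return a `LabelVolume` on `ref`'s grid.
#' @export
resample_to_grid <- function(label, ref) {
  stopifnot(is_label(label))
  sdim <- vol_dim(label)
  tdim <- vol_dim(ref)
  scale <- ref$spacing / label$spacing
  off <- (ref$origin - label$origin) / label$spacing
  A <- cbind(diag(scale), off)
  samp1 <- function(a) {
    storage.mode(a) <- "double"
    .warp_volume(a, sdim, tdim, A, NULL, 0L, 0)
  }
  nc <- n_channels(label)
  if (nc == 1L) {
    out <- samp1(label$data)
  } else {
    out <- array(0, c(tdim, nc))
    for (ch in seq_len(nc)) out[, , , ch] <- samp1(label$data[, , , ch])
  }
  label_volume(out, spacing = ref$spacing, origin = ref$origin,
               channel_names = label$channel_names)
}
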