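#' Extract an iso-surface mesh from a binary mask
#'
#' Converts a voxel mask into a closed triangulated surface in world mm.
#' Extraction is done with marching tetrahedra: each grid cell (corners at
#' voxel centers) is split into the Kuhn six-tetrahedra decomposition and the
#' iso-surface at `level` is triangulated per tetrahedron. This table-free
#' member of the marching-cubes family yields watertight, consistently
#' outward-oriented surfaces; the volume is padded with one background layer
#' so surfaces touching the grid border still close.
#'
#' @param mask a non-empty single-channel `LabelVolume` (or an `ImageVolume`
#'   holding a scalar field to be iso-surfaced).
#' @param level iso level (default 0.5 for binary masks).
#' @return a `SurfaceMesh` in world mm.
#' @export
extract_mesh <- function(mask, level = 0.5) {
  d <- mask$data
  if (length(dim(d)) == 4L) {
    if (dim(d)[4] != 1L)
      stop("extract_mesh needs a single-channel mask; use label_channel()")
    d <- d[, , , 1, drop = TRUE]
  }
  if (sum(d > level) == 0L) stop("empty mask: nothing to mesh", call. = FALSE)
  storage.mode(d) <- "double"
  res <- .marching_tets(d, dim(d), level, mask$spacing, mask$origin)
  mesh <- surface_mesh(res$vertices, res$triangles)
  if (mesh_volume(mesh) < 0)  # enforce outward orientation globally
    mesh$triangles <- mesh$triangles[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Taubin mesh smoothing
#'
#' Two-step smoothing per iteration: an umbrella-Laplacian shrink step with
#' factor `lambda`, then an inflation step with a negative factor whose
#' magnitude is `nu`. The alternating signs make the filter a band-pass in
#' mesh frequency and avoid the systematic volume shrinkage of plain
#' Laplacian smoothing. `nu` is the magnitude of the negative second step;
#' supplying `mu` directly (e.g. `mu = -0.53`, the convention where
#' `|mu| > lambda`) overrides it. Vertex count and triangle connectivity are
#' unchanged.
#'
#' @param mesh a `SurfaceMesh`.
#' @param lambda positive shrink factor (default 0.5).
#' @param nu positive magnitude of the inflate step (default 0.5); the
#'   applied factor is `-nu`.
#' @param iterations number of shrink/inflate iterations (>= 0).
#' @param mu optional explicit (negative) inflate factor overriding `nu`.
#' @return the smoothed `SurfaceMesh` (same topology).
#' @export
taubin_smooth <- function(mesh, lambda = 0.5, nu = 0.5, iterations = 100,
                          mu = NULL) {
  stopifnot(inherits(mesh, "SurfaceMesh"))
  if (iterations < 0) stop("iterations must be >= 0")
  if (is.null(mu)) {
    if (nu <= 0)
      stop("nu must be a positive magnitude; the inflate step applies -nu")
    mu <- -nu
  }
  if (mu >= 0) stop("mu must be negative (inflate step)")
  if (lambda <= 0) stop("lambda must be positive")
  if (iterations == 0) return(mesh)
  v <- .smooth_mesh_cpp(mesh$vertices, mesh$triangles, lambda, mu,
                        as.integer(iterations))
  surface_mesh(v, mesh$triangles)
}

#' Plain Laplacian smoothing (reference / comparison)
#'
#' Umbrella-operator Laplacian smoothing with factor `lambda` only. Shrinks
#' closed surfaces; provided as the baseline against which the anti-shrink
#' property of [taubin_smooth()] is assessed.
#'
#' @inheritParams taubin_smooth
#' @export
laplacian_smooth <- function(mesh, lambda = 0.5, iterations = 100) {
  stopifnot(inherits(mesh, "SurfaceMesh"))
  if (iterations == 0) return(mesh)
  v <- .smooth_mesh_cpp(mesh$vertices, mesh$triangles, lambda, 0,
                        as.integer(iterations))
  surface_mesh(v, mesh$triangles)
}

#' Keep the largest 26-connected foreground component
#'
#' @param mask a non-empty single-channel `LabelVolume`.
#' @return a `LabelVolume` with only the largest component retained.
#' @export
largest_component <- function(mask) {
  stopifnot(is_label(mask))
  d <- mask$data
  if (length(dim(d)) == 4L) d <- d[, , , 1, drop = TRUE]
  if (sum(d) == 0L) stop("empty mask", call. = FALSE)
  lab <- .label_components26(d, dim(d))
  tab <- tabulate(lab[lab > 0L])
  keep <- which.max(tab)
  out <- array(0L, dim(d))
  out[lab == keep] <- 1L
  label_volume(out, spacing = mask$spacing, origin = mask$origin)
}

#' Voxel prediction to smoothed surface, in one call
#'
#' The standard post-processing chain: optionally keep the largest
#' component, extract the iso-surface at native resolution, and Taubin-smooth
#' it (lambda = 0.5, nu = 0.5, 100 iterations by default).
#'
#' @param mask a single-channel `LabelVolume` at native resolution.
#' @param keep_largest drop all but the largest 26-connected component first.
#' @param taubin_iterations smoothing iterations (0 disables smoothing).
#' @param lambda,nu,mu smoothing parameters, see [taubin_smooth()].
#' @return a `SurfaceMesh`.
#' @export
postprocess_mask <- function(mask, keep_largest = TRUE,
                             taubin_iterations = 100, lambda = 0.5, nu = 0.5,
                             mu = NULL) {
  if (keep_largest) mask <- largest_component(mask)
  mesh <- extract_mesh(mask)
  if (taubin_iterations > 0)
    mesh <- taubin_smooth(mesh, lambda = lambda, nu = nu,
                          iterations = taubin_iterations, mu = mu)
  mesh
}
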