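#' Ordered anatomical curve polylines
#'
#' A `CurvePolyline` is an ordered sequence of 3D points along the mandibular
#' arch with a strictly increasing arch parameter in \[0, 1\]: either the
#' caudolateral curve (inferior/basal border, expected invariant under ridge
#' modification) or the dental curve (tooth cusps or, when edentulous, the
#' alveolar crest top).
#'
#' @param points K x 3 matrix of world mm points (K >= 10).
#' @param kind `"caudolateral"` or `"dental"`.
#' @param arch_parameter strictly increasing scalar per point in \[0, 1\];
#'   defaults to uniform.
#' @return a `CurvePolyline`.
#' @export
curve_polyline <- function(points, kind = c("caudolateral", "dental"),
                           arch_parameter = NULL) {
  kind <- match.arg(kind)
  points <- as.matrix(points)
  colnames(points) <- NULL
  if (nrow(points) < 10L) stop("curve needs at least 10 points")
  if (ncol(points) != 3L) stop("points must be K x 3")
  if (is.null(arch_parameter))
    arch_parameter <- seq(0, 1, length.out = nrow(points))
  if (any(diff(arch_parameter) <= 0))
    stop("arch_parameter must be strictly increasing")
  structure(list(points = points, kind = kind,
                 arch_parameter = as.numeric(arch_parameter)),
            class = "CurvePolyline")
}

#' @export
print.CurvePolyline <- function(x, ...) {
  cat(sprintf("CurvePolyline (%s): %d stations\n", x$kind, nrow(x$points)))
  invisible(x)
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`. For label volumes (same grid) the
#' measure is voxel counts; for meshes it is enclosed volume, computed by
#' voxelizing both meshes on a common fine grid and intersecting the
#' resulting solids. In both modes the numerator is the Boolean
#' *intersection* of the two solids.
#'
#' @param a,b two `LabelVolume`s on one grid, or two closed `SurfaceMesh`es.
#' @param pitch voxelization pitch (mm) for mesh mode; default resolves the
#'   smaller mesh bounding-box extent into about 150 cells.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b, pitch = NULL) {
  if (is_label(a) && is_label(b)) {
    if (!all(vol_dim(a) == vol_dim(b)) ||
        max(abs(a$spacing - b$spacing)) > 1e-9 ||
        max(abs(a$origin - b$origin)) > 1e-9)
      stop("voxel-mode dice needs both labels on the same grid")
    da <- a$data > 0; db <- b$data > 0
    sa <- sum(da); sb <- sum(db)
    if (sa == 0 || sb == 0) stop("dice inputs must be non-empty")
    return(2 * sum(da & db) / (sa + sb))
  }
  if (inherits(a, "SurfaceMesh") && inherits(b, "SurfaceMesh")) {
    va <- voxelize(a, b, pitch)
    ia <- va$a > 0; ib <- va$b > 0
    if (!sum(ia) || !sum(ib)) stop("dice inputs must be non-empty")
    return(2 * sum(ia & ib) / (sum(ia) + sum(ib)))
  }
  stop("dice needs two LabelVolumes or two SurfaceMeshes")
}

# voxelize two meshes on one grid spanning their union bbox
voxelize <- function(a, b, pitch = NULL) {
  lo <- pmin(apply(a$vertices, 2, min), apply(b$vertices, 2, min))
  hi <- pmax(apply(a$vertices, 2, max), apply(b$vertices, 2, max))
  if (is.null(pitch)) {
    ext <- min(apply(a$vertices, 2, function(v) diff(range(v))))
    pitch <- max(ext / 150, 1e-6)
  }
  origin <- lo - pitch / 2
  dims <- as.integer(ceiling((hi - origin) / pitch)) + 1L
  list(a = .voxelize_mesh(a$vertices, a$triangles, origin, rep(pitch, 3), dims),
       b = .voxelize_mesh(b$vertices, b$triangles, origin, rep(pitch, 3), dims),
       origin = origin, pitch = pitch, dims = dims)
}

#' Symmetric average surface distance (ASD)
#'
#' `ASD(A,B) = (dASD(A,B) + dASD(B,A)) / 2`, where the directed term
#' `dASD(A,B)` averages, over the vertex set of A, the unsigned minimum
#' distance from each vertex to the *surface* (not the vertices) of B.
#'
#' @param a,b two `SurfaceMesh`es.
#' @return list with `asd_mm`, `dasd_ab_mm`, `dasd_ba_mm`; `asd_mm` is
#'   exactly the mean of the directed terms.
#' @export
asd <- function(a, b) {
  stopifnot(inherits(a, "SurfaceMesh"), inherits(b, "SurfaceMesh"))
  if (nrow(a$triangles) == 0L || nrow(b$triangles) == 0L)
    stop("degenerate mesh: no triangles")
  dab <- mean(.point_mesh_dist(a$vertices, b$vertices, b$triangles))
  dba <- mean(.point_mesh_dist(b$vertices, a$vertices, a$triangles))
  list(asd_mm = (dab + dba) / 2, dasd_ab_mm = dab, dasd_ba_mm = dba)
}

#' Automatic anatomical curve extraction
#'
#' Operationalization of the mandibular curve metrics: the mesh is assumed to
#' be in the package's anatomical axis convention (x left-right, y posterior
#' to anterior, z inferior to superior). Vertices are binned into stations by
#' the angle around a reference point behind the posterior opening of the
#' U-shaped arch; per station the caudolateral curve takes the inferior-most
#' surface point over the whole arch, and the dental curve the superior-most
#' point over the central arch window (stations 0.12-0.88 of the arc, which
#' excludes the ascending rami). Deterministic for a fixed mesh.
#'
#' @param mesh a mandible-like `SurfaceMesh`.
#' @param kind `"caudolateral"` or `"dental"`.
#' @param n_stations number of arch stations.
#' @param dental_extent_frac fraction of the left-right extent (centered)
#'   traced by the dental curve; the default 0.62 keeps stations on the
#'   alveolar band and off the ascending rami.
#' @return a `CurvePolyline`.
#' @export
extract_curve <- function(mesh, kind = c("caudolateral", "dental"),
                          n_stations = 100L,
                          dental_extent_frac = 0.62) {
  kind <- match.arg(kind)
  v <- mesh$vertices
  cx <- mean(range(v[, 1]))
  cy <- min(v[, 2]) - 10
  # U-shape sanity: the arch must subtend a wide angle around a reference
  # point behind its posterior opening
  th <- atan2(v[, 2] - cy, v[, 1] - cx)
  span <- diff(range(th))
  if (span < 100 * pi / 180 || span > 179 * pi / 180)
    stop("arch detection failed: vertex angular span is not U-shaped")
  # The mandibular arch is single-valued over the left-right axis, so the
  # arch parameter is normalized x within the traced window.
  if (kind == "dental") {
    # central arch only: the alveolar band, excluding the ascending rami
    half <- diff(range(v[, 1])) / 2
    keep <- abs(v[, 1] - cx) <= dental_extent_frac * half
  } else {
    # basal border only: the inferior quarter of the height range, so
    # stations never land on condyle or coronoid undersides
    zr <- range(v[, 3])
    keep <- v[, 3] <= zr[1] + 0.25 * diff(zr)
  }
  xk <- range(v[keep, 1])
  u <- (v[, 1] - xk[1]) / diff(xk)
  edges <- seq(0, 1, length.out = n_stations + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  pts <- matrix(NA_real_, n_stations, 3)
  # caudolateral station point = centroid of near-minimal vertices (stable
  # against ties across the flat basal surface); dental station point = the
  # superior-most vertex (cusps are unique maxima)
  band <- 0.8
  for (q in seq_len(n_stations)) {
    sel <- which(keep & u >= edges[q] & u <= edges[q + 1L])
    if (length(sel) == 0L) next
    zz <- v[sel, 3]
    if (kind == "caudolateral") {
      near <- zz <= min(zz) + band
      pts[q, ] <- colMeans(v[sel[near], , drop = FALSE])
    } else {
      pts[q, ] <- v[sel[which.max(zz)], ]
    }
  }
  ok <- stats::complete.cases(pts)
  if (mean(ok) < 0.5)
    stop("arch detection failed: too many empty stations")
  # fill sparsely sampled stations by interpolating along the curve
  if (any(!ok))
    for (j in 1:3)
      pts[!ok, j] <- stats::approx(centers[ok], pts[ok, j],
                                   xout = centers[!ok], rule = 2)$y
  curve_polyline(pts, kind = kind, arch_parameter = centers)
}

# distance from each point to the nearest segment of a polyline
pt_polyline_dist <- function(P, Q) {
  A <- Q[-nrow(Q), , drop = FALSE]
  B <- Q[-1, , drop = FALSE]
  AB <- B - A
  len2 <- rowSums(AB^2)
  len2[len2 == 0] <- 1e-300
  vapply(seq_len(nrow(P)), function(i) {
    p <- P[i, ]
    AP <- sweep(A, 2, p, "-")
    tt <- pmin(pmax(-rowSums(AP * AB) / len2, 0), 1)
    Cst <- A + AB * tt
    sqrt(min(rowSums(sweep(Cst, 2, p, "-")^2)))
  }, numeric(1))
}

resample_curve <- function(curve, u) {
  sapply(1:3, function(j)
    stats::approx(curve$arch_parameter, curve$points[, j], xout = u,
                  rule = 2)$y)
}

#' Distance between two anatomical curves
#'
#' Both curves (same kind) are resampled to matched arch-parameter stations;
#' the reported value is the mean distance from each resampled point of one
#' curve to the other resampled polyline, averaged over both directions.
#'
#' @param c1,c2 `CurvePolyline`s of the same kind.
#' @param n_stations number of matched stations.
#' @return mean symmetric curve distance in mm.
#' @export
curve_distance <- function(c1, c2, n_stations = 100L) {
  stopifnot(inherits(c1, "CurvePolyline"), inherits(c2, "CurvePolyline"))
  if (c1$kind != c2$kind)
    stop("cannot compare curves of different kinds (", c1$kind, " vs ",
         c2$kind, ")")
  lo <- max(min(c1$arch_parameter), min(c2$arch_parameter))
  hi <- min(max(c1$arch_parameter), max(c2$arch_parameter))
  u <- seq(lo, hi, length.out = n_stations)
  P1 <- resample_curve(c1, u)
  P2 <- resample_curve(c2, u)
  (mean(pt_polyline_dist(P1, P2)) + mean(pt_polyline_dist(P2, P1))) / 2
}

#' Full metric evaluation of a prediction against a ground truth
#'
#' Computes voxel Dice at native resolution plus, after converting both masks
#' to post-processed surfaces, the symmetric ASD and the two anatomical
#' curve distances.
#'
#' @param pred,gt single-channel `LabelVolume`s on the same grid.
#' @param curves also extract and compare anatomical curves (requires
#'   mandible-like masks).
#' @param taubin_iterations smoothing iterations used for both surfaces.
#' @return list with `dsc`, `asd_mm`, `dasd_ab_mm`, `dasd_ba_mm` and (when
#'   `curves`) `caudolateral_mm`, `dental_mm`.
#' @export
evaluate_pair <- function(pred, gt, curves = TRUE, taubin_iterations = 100) {
  out <- list(dsc = dice(pred, gt))
  mp <- postprocess_mask(pred, taubin_iterations = taubin_iterations)
  mg <- postprocess_mask(gt, taubin_iterations = taubin_iterations)
  out <- c(out, asd(mp, mg))
  if (curves) {
    out$caudolateral_mm <- curve_distance(
      extract_curve(mp, "caudolateral"), extract_curve(mg, "caudolateral"))
    out$dental_mm <- curve_distance(
      extract_curve(mp, "dental"), extract_curve(mg, "dental"))
  }
  out
}
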