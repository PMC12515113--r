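#' Parametric mandible phantom specification
#'
#' Describes one synthetic case: a horseshoe-shaped mandibular body (parabolic
#' arch centerline with an elliptical-tube cross-section), posterior ascending
#' rami with condylar and coronoid bumps, an alveolar ridge band on top of the
#' body, and optional teeth (truncated cones seated on the ridge). Three
#' ground-truth variants are derived from one geometry: the original (O,
#' including any dentition), a Class III variant (teeth removed, alveolar
#' crest lowered by `cl3_reduction_mm` — moderate ridge atrophy), and a Class
#' V variant (crest lowered by the larger `cl5_reduction_mm` — severe
#' atrophy). Reduction only removes material from the ridge band, so the
#' basal body, rami and condyles are bit-identical across variants.
#'
#' For `dentition_status = "edentulous"` the original geometry itself carries
#' a partly resorbed ridge (80 percent of the Class III reduction) and no
#' teeth, so its Class III variant differs from O only marginally — matching
#' the clinical situation where an already toothless mandible needs no
#' significant alteration.
#'
#' @param arch_width_mm,arch_depth_mm horseshoe outer extents (left-right,
#'   antero-posterior).
#' @param body_height_mm basal body height above the inferior border.
#' @param ridge_height_mm alveolar band height above the body.
#' @param tooth_count number of tooth sites along the arch.
#' @param tooth_height_mm tooth cone height above the crest.
#' @param dentition_status `"full"`, `"partial"` or `"edentulous"`.
#' @param present_teeth logical vector (length `tooth_count`) of present
#'   sites; defaults to all present (full), a random 60 percent (partial) or
#'   none (edentulous).
#' @param cl3_reduction_mm,cl5_reduction_mm crest lowering of the two atrophy
#'   variants; must satisfy `cl5 > cl3 > 0` and
#'   `ridge_height_mm >= cl5_reduction_mm` (Class V never cuts the basal
#'   body).
#' @param spacing_mm per-axis voxel size.
#' @param noise_sd_HU additive Gaussian intensity noise.
#' @param include_distractors add a cranium-like bone slab and a hyoid-like
#'   blob so first-stage localization is not trivial.
#' @param seed integer; same seed, same phantom, bit for bit.
#' @return a `PhantomSpec`.
#' @export
phantom_spec <- function(arch_width_mm = 92, arch_depth_mm = 68,
                         body_height_mm = 18, ridge_height_mm = 12,
                         tooth_count = 14L, tooth_height_mm = 8,
                         dentition_status = c("full", "partial", "edentulous"),
                         present_teeth = NULL,
                         cl3_reduction_mm = 4, cl5_reduction_mm = 8,
                         spacing_mm = c(2, 2, 2), noise_sd_HU = 25,
                         include_distractors = TRUE, seed = 1L) {
  dentition_status <- match.arg(dentition_status)
  if (!(cl5_reduction_mm > cl3_reduction_mm && cl3_reduction_mm > 0))
    stop("invariant violated: need cl5_reduction_mm > cl3_reduction_mm > 0")
  if (ridge_height_mm < cl5_reduction_mm)
    stop("invariant violated: ridge_height_mm must be >= cl5_reduction_mm ",
         "(Class V must not cut into the basal body)")
  if (dentition_status == "edentulous") {
    tooth_count <- 0L
    present_teeth <- logical(0)
  }
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3)
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive")
  structure(list(arch_width_mm = arch_width_mm, arch_depth_mm = arch_depth_mm,
                 body_height_mm = body_height_mm,
                 ridge_height_mm = ridge_height_mm,
                 tooth_count = as.integer(tooth_count),
                 tooth_height_mm = tooth_height_mm,
                 dentition_status = dentition_status,
                 present_teeth = present_teeth,
                 cl3_reduction_mm = cl3_reduction_mm,
                 cl5_reduction_mm = cl5_reduction_mm,
                 spacing_mm = as.numeric(spacing_mm),
                 noise_sd_HU = noise_sd_HU,
                 include_distractors = isTRUE(include_distractors),
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

# fixed secondary geometry (mm), shared by rasterizer and analytic curves
phantom_geom <- function(spec) {
  list(a = 7,          # body tube half-width
       ar = 5,         # ridge band half-width
       rb = 3,         # rounding depth of the inferior border
       rt = 2,         # rounding of the crest across the band
       ridge_t = c(0.10, 0.90),   # arch-parameter window of the ridge band
       curve_t = c(0.12, 0.88),   # station window of the dental curve
       ramus_h = 46,   # ramus top above the inferior border
       ramus_rx = 6, ramus_ry = 8,
       tooth_base_r = 3.2, tooth_top_r = 2.2,
       socket_r = 2,
       socket_depth = min(2, 0.6 * spec$cl3_reduction_mm),
       margin_xy = 16, margin_z_lo = 24, margin_z_hi = 26,
       tooth_t = c(0.15, 0.85))   # tooth sites within this arch window
}

arch_xy <- function(t, spec) {
  cbind(x = (t - 0.5) * spec$arch_width_mm,
        y = spec$arch_depth_mm * (1 - (2 * (t - 0.5))^2))
}

# arc-length parameterization of the arch centerline
arch_arclen <- function(spec, nt = 1024L) {
  t <- seq(0, 1, length.out = nt)
  p <- arch_xy(t, spec)
  seg <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  list(t = t, s = c(0, cumsum(seg)))
}

# tooth site centers, equally spaced in arc length inside the tooth window
tooth_sites <- function(spec) {
  if (spec$tooth_count == 0L) return(numeric(0))
  g <- phantom_geom(spec)
  al <- arch_arclen(spec)
  swin <- stats::approx(al$t, al$s, xout = g$tooth_t)$y
  sc <- seq(swin[1], swin[2], length.out = spec$tooth_count)
  stats::approx(al$s, al$t, xout = sc)$y
}

# original-variant crest reduction (mm): edentulous originals already carry a
# partly resorbed ridge
original_reduction <- function(spec) {
  if (spec$dentition_status == "edentulous") 0.8 * spec$cl3_reduction_mm else 0
}

#' Generate one synthetic phantom case
#'
#' Rasterizes the phantom geometry into a CT-like `ImageVolume`
#' (air about -1000 HU, soft tissue about 60 HU, bone about 1200 HU, teeth
#' about 2200 HU, plus Gaussian noise) and the three paired binary ground
#' truths. The three label volumes satisfy, by construction,
#' `gt_cl5` within `gt_cl3` within `gt_original` (for dentate cases) and are
#' identical outside the alveolar ridge band.
#'
#' @param spec a [phantom_spec()].
#' @return a `PhantomCase`: list with `image`, `gt_original`, `gt_cl3`,
#'   `gt_cl5`, `spec`, and `analytic_curves` (ground-truth caudolateral and
#'   dental polylines plus the expected mean dental-curve height gap between
#'   the O and Class V variants, `dental_gap_o_cl5_mm`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  set.seed(spec$seed)
  present <- resolve_dentition(spec)
  f <- phantom_fields(spec)
  sp <- spec$spacing_mm
  g <- f$g

  gt_o <- phantom_occupancy(spec, f, present, original_reduction(spec),
                            with_teeth = TRUE) >= 0.5
  gt_3 <- phantom_occupancy(spec, f, present, spec$cl3_reduction_mm,
                            with_teeth = FALSE) >= 0.5
  gt_5 <- phantom_occupancy(spec, f, present, spec$cl5_reduction_mm,
                            with_teeth = FALSE) >= 0.5

  # CT-like image from the original geometry (+ optional distractors)
  dims <- f$dims
  img <- array(-1000, dims)
  w <- spec$arch_width_mm; dep <- spec$arch_depth_mm
  head_xy <- (f$X / (w / 2 + 14))^2 + ((f$Y - dep / 2) / (dep / 2 + 20))^2
  zsc <- ((f$zs - 22) / 62)^2
  for (k in seq_len(dims[3])) {
    sl <- img[, , k]
    sl[head_xy + zsc[k] <= 1] <- 60
    img[, , k] <- sl
  }
  img[gt_o] <- 1200
  teeth <- phantom_teeth_mask(spec, f, present)
  if (!is.null(teeth)) img[teeth & gt_o] <- 2200
  if (spec$include_distractors) {
    for (k in seq_len(dims[3])) {
      z <- f$zs[k]
      sl <- img[, , k]
      if (z >= g$ramus_h + 8 && z <= g$ramus_h + 20)
        sl[(f$X / (w / 2 + 8))^2 +
             ((f$Y - dep / 2) / (dep / 2 + 10))^2 <= 1] <- 1200
      sl[(f$X / 10)^2 + ((f$Y - 0.35 * dep) / 6)^2 +
           ((z + 12) / 4)^2 <= 1] <- 1200
      img[, , k] <- sl
    }
  }
  img <- img + stats::rnorm(length(img), 0, spec$noise_sd_HU)

  to_label <- function(a) {
    label_volume(array(as.integer(a), dims), spacing = sp, origin = f$origin)
  }
  structure(list(
    image = image_volume(img, spacing = sp, origin = f$origin),
    gt_original = to_label(gt_o),
    gt_cl3 = to_label(gt_3),
    gt_cl5 = to_label(gt_5),
    spec = spec,
    present_teeth = present,
    analytic_curves = analytic_curves(spec, present)
  ), class = "PhantomCase")
}

resolve_dentition <- function(spec) {
  present <- spec$present_teeth
  if (!is.null(present)) return(present)
  nteeth <- spec$tooth_count
  switch(spec$dentition_status,
         full = rep(TRUE, nteeth),
         partial = {
           pr <- stats::runif(nteeth) < 0.6
           if (all(pr)) pr[sample(nteeth, 1)] <- FALSE
           if (!any(pr)) pr[sample(nteeth, 1)] <- TRUE
           pr
         },
         edentulous = logical(0))
}

# deterministic geometry fields shared by the rasterizer, the soft-occupancy
# mesher and the analytic curves: grid, per-column arch distance/parameter,
# height profiles, rami footprint and bump ellipsoids
phantom_fields <- function(spec) {
  g <- phantom_geom(spec)
  sp <- spec$spacing_mm
  w <- spec$arch_width_mm; dep <- spec$arch_depth_mm
  xr <- c(-(w / 2 + g$margin_xy), w / 2 + g$margin_xy)
  yr <- c(-g$margin_xy - 8, dep + g$margin_xy)
  zr <- c(-g$margin_z_lo, g$ramus_h + g$margin_z_hi)
  dims <- as.integer(ceiling(c(diff(xr), diff(yr), diff(zr)) / sp))
  origin <- c(xr[1], yr[1], zr[1]) + sp / 2
  xs <- origin[1] + (seq_len(dims[1]) - 1) * sp[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * sp[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * sp[3]
  nt <- 512L
  tt <- seq(0, 1, length.out = nt)
  ct <- arch_xy(tt, spec)
  X <- matrix(xs, dims[1], dims[2])
  Y <- matrix(ys, dims[1], dims[2], byrow = TRUE)
  dmin2 <- matrix(Inf, dims[1], dims[2])
  tmin <- matrix(0, dims[1], dims[2])
  for (q in seq_len(nt)) {
    d2 <- (X - ct[q, 1])^2 + (Y - ct[q, 2])^2
    upd <- d2 < dmin2
    dmin2[upd] <- d2[upd]
    tmin[upd] <- tt[q]
  }
  dmin <- sqrt(dmin2)
  crest0 <- spec$body_height_mm + spec$ridge_height_mm
  z_bot <- g$rb * (dmin / g$a)^2
  crest_col <- crest0 - g$rt * (pmin(dmin, g$ar) / g$ar)^2
  in_band <- dmin <= g$ar & tmin >= g$ridge_t[1] & tmin <= g$ridge_t[2]
  # signed lateral distances (positive inside)
  lat_tube <- g$a - dmin
  lat_band <- g$ar - dmin
  lat_band[!in_band] <- -Inf
  ram_lat <- matrix(-Inf, dims[1], dims[2])
  bump <- vector("list", 0)
  for (s in c(-1, 1)) {
    cx <- s * w / 2
    e <- sqrt(((X - cx) / g$ramus_rx)^2 + ((Y - 2) / g$ramus_ry)^2)
    ram_lat <- pmax(ram_lat, (1 - e) * min(g$ramus_rx, g$ramus_ry))
    bump <- c(bump, list(c(cx, -3, g$ramus_h + 2, 6, 7, 6),    # condyle
                         c(cx, 9, g$ramus_h - 2, 4, 5.5, 6)))  # coronoid
  }
  sites_t <- tooth_sites(spec)
  sites_xy <- if (length(sites_t)) arch_xy(sites_t, spec) else matrix(0, 0, 2)
  list(g = g, dims = dims, origin = origin, xs = xs, ys = ys, zs = zs,
       X = X, Y = Y, dmin = dmin, tmin = tmin, z_bot = z_bot,
       crest_col = crest_col, crest0 = crest0, lat_tube = lat_tube,
       lat_band = lat_band, ram_lat = ram_lat, bump = bump,
       sites_xy = sites_xy)
}

# Occupancy field of one ground-truth variant, in [0, 1], linear across
# surfaces (value 0.5 exactly on the analytic boundary). Thresholding at 0.5
# gives the binary ground truth; iso-surfacing at 0.5 gives a sub-voxel
# ground-truth mesh.
phantom_occupancy <- function(spec, f, present, reduction, with_teeth) {
  g <- f$g
  sp <- spec$spacing_mm
  rxy <- 2 * mean(sp[1:2])   # linear ramp widths
  rz <- 2 * sp[3]
  clampf <- function(d, ramp) pmin(pmax(d / ramp + 0.5, 0), 1)
  bh <- spec$body_height_mm
  dims <- f$dims
  top_band <- f$crest_col - reduction
  top_band[f$lat_band == -Inf] <- -Inf
  lat_low <- clampf(f$lat_tube, rxy)
  lat_high <- clampf(f$lat_band, rxy)
  lat_ram <- clampf(f$ram_lat, rxy)
  occ <- array(0, dims)
  sdep <- g$socket_depth
  th <- spec$tooth_height_mm
  base_z <- f$crest0 - original_reduction(spec) - 1
  for (k in seq_len(dims[3])) {
    z <- f$zs[k]
    o_low <- pmin(clampf(bh - z, rz), clampf(z - f$z_bot, rz), lat_low)
    o_high <- pmin(clampf(top_band - z, rz), clampf(z - (bh - rz), rz),
                   lat_high)
    sl <- pmax(o_low, o_high,
               pmin(lat_ram, clampf(g$ramus_h - z, rz), clampf(z, rz)))
    for (b in f$bump) {
      e <- sqrt(((f$X - b[1]) / b[4])^2 + ((f$Y - b[2]) / b[5])^2 +
                  ((z - b[3]) / b[6])^2)
      sl <- pmax(sl, clampf((1 - e) * min(b[4:6]), rxy))
    }
    if (with_teeth && length(present) && any(!present)) {
      for (i in which(!present)) {
        rho <- sqrt((f$X - f$sites_xy[i, 1])^2 + (f$Y - f$sites_xy[i, 2])^2)
        o_s <- pmin(clampf(g$socket_r - rho, rxy),
                    clampf(z - (f$crest0 - sdep), rz))
        sl <- pmin(sl, 1 - o_s)
      }
    }
    if (with_teeth && length(present) && any(present)) {
      if (z >= base_z - rz && z <= base_z + 1 + th + rz) {
        h <- max(0, z - (base_z + 1))
        r <- g$tooth_base_r - (g$tooth_base_r - g$tooth_top_r) * h / th
        for (i in which(present)) {
          rho <- sqrt((f$X - f$sites_xy[i, 1])^2 +
                        (f$Y - f$sites_xy[i, 2])^2)
          o_t <- pmin(clampf(r - rho, rxy),
                      clampf(base_z + 1 + th - z, rz),
                      clampf(z - (base_z - 1), rz))
          sl <- pmax(sl, o_t)
        }
      }
    }
    occ[, , k] <- sl
  }
  occ
}

phantom_teeth_mask <- function(spec, f, present) {
  if (!length(present) || !any(present)) return(NULL)
  g <- f$g
  th <- spec$tooth_height_mm
  base_z <- f$crest0 - original_reduction(spec) - 1
  dims <- f$dims
  m <- array(FALSE, dims)
  for (k in which(f$zs >= base_z & f$zs <= base_z + 1 + th)) {
    z <- f$zs[k]
    h <- max(0, z - (base_z + 1))
    r <- g$tooth_base_r - (g$tooth_base_r - g$tooth_top_r) * h / th
    sl <- m[, , k]
    for (i in which(present))
      sl <- sl | ((f$X - f$sites_xy[i, 1])^2 +
                    (f$Y - f$sites_xy[i, 2])^2 <= r^2)
    m[, , k] <- sl
  }
  m
}

#' Sub-voxel ground-truth surface of a phantom variant
#'
#' Iso-surfaces the phantom's continuous occupancy field at 0.5, which places
#' surface vertices on the analytic geometry to sub-voxel accuracy — the
#' phantom counterpart of a smooth, manually curated STL ground truth. The
#' binary label volumes are this same field thresholded at 0.5.
#'
#' @param case a `PhantomCase`.
#' @param variant `"O"`, `"cl3"` or `"cl5"`.
#' @return a `SurfaceMesh`.
#' @export
gt_mesh <- function(case, variant = c("O", "cl3", "cl5")) {
  variant <- match.arg(variant)
  spec <- case$spec
  f <- phantom_fields(spec)
  red <- switch(variant, O = original_reduction(spec),
                cl3 = spec$cl3_reduction_mm, cl5 = spec$cl5_reduction_mm)
  occ <- phantom_occupancy(spec, f, case$present_teeth, red,
                           with_teeth = variant == "O")
  extract_mesh(image_volume(occ, spacing = spec$spacing_mm,
                            origin = f$origin), level = 0.5)
}

# Ground-truth curves from the generative model: stations equally spaced in
# arc length within the dental-curve window.
analytic_curves <- function(spec, present, n_stations = 100L) {
  g <- phantom_geom(spec)
  al <- arch_arclen(spec)
  # dental-curve window: the central fraction of the left-right extent (the
  # same convention extract_curve() uses), converted to arch parameter t
  extent <- spec$arch_width_mm + 2 * g$ramus_rx + mean(spec$spacing_mm)
  xw <- 0.62 * extent / 2
  tw <- min(0.45, xw / spec$arch_width_mm)
  curve_t <- c(0.5 - tw, 0.5 + tw)
  # stations uniform in t (equivalently in x, the arch parameter the curve
  # extractor uses); sc tracks the corresponding arc-length positions
  tc <- seq(curve_t[1], curve_t[2], length.out = n_stations)
  sc <- stats::approx(al$t, al$s, xout = tc)$y
  xy <- arch_xy(tc, spec)
  crest0 <- spec$body_height_mm + spec$ridge_height_mm
  caudo <- cbind(xy, z = 0)

  # Station height of a variant's dental curve. A station is the planar cut
  # x = x_q across the arch, so tooth/socket footprints act through their
  # left-right (x) distance to the station, which is what a surface tracer
  # sees.
  dental_z <- function(reduction, with_teeth) {
    z <- rep(crest0 - reduction, n_stations)
    # a surface tracer maximizes over a station bin of this half-width, so
    # distances to tooth axes act reduced by it
    halfbin <- abs(diff(range(xy[, 1]))) / (2 * n_stations)
    if (with_teeth && spec$tooth_count > 0L) {
      sites_t <- tooth_sites(spec)
      sites_x <- arch_xy(sites_t, spec)[, 1]
      base_z <- crest0 - reduction - 1
      for (q in seq_len(n_stations)) {
        dist_x <- pmax(0, abs(xy[q, 1] - sites_x) - halfbin)
        i <- which.min(dist_x)
        if (dist_x[i] < g$tooth_base_r) {
          if (present[i]) {
            lift <- min(spec$tooth_height_mm,
                        spec$tooth_height_mm * (g$tooth_base_r - dist_x[i]) /
                          (g$tooth_base_r - g$tooth_top_r))
            z[q] <- base_z + 1 + lift
          } else if (dist_x[i] < g$socket_r) {
            # the station plane clips the socket rim: the nearest intact
            # crest sits at band offset sqrt(socket_r^2 - dx^2)
            doff2 <- g$socket_r^2 - dist_x[i]^2
            z[q] <- crest0 - g$rt * doff2 / g$ar^2
          }
        }
      }
    }
    z
  }
  r_o <- original_reduction(spec)
  zo <- dental_z(r_o, TRUE)
  z3 <- dental_z(spec$cl3_reduction_mm, FALSE)
  z5 <- dental_z(spec$cl5_reduction_mm, FALSE)
  list(
    caudolateral = curve_polyline(caudo, kind = "caudolateral"),
    dental_original = curve_polyline(cbind(xy, z = zo), kind = "dental"),
    dental_cl3 = curve_polyline(cbind(xy, z = z3), kind = "dental"),
    dental_cl5 = curve_polyline(cbind(xy, z = z5), kind = "dental"),
    dental_gap_o_cl5_mm = mean(zo) - mean(z5),
    dental_gap_o_cl3_mm = mean(zo) - mean(z3)
  )
}

#' @export
print.PhantomCase <- function(x, ...) {
  cat(sprintf(
    "PhantomCase (%s, seed %d): grid %s, fg voxels O/III/V = %d/%d/%d\n",
    x$spec$dentition_status, x$spec$seed,
    paste(vol_dim(x$image), collapse = "x"),
    sum(x$gt_original$data), sum(x$gt_cl3$data), sum(x$gt_cl5$data)))
  invisible(x)
}

#' Generate a cohort of phantoms
#'
#' Draws per-case specs reproducibly from parameter ranges and assigns dental
#' statuses to match the requested fractions (fully dentate and edentulous
#' counts are rounded to the nearest integer, partial takes the remainder).
#'
#' @param n number of cases (>= 3 when all three fractions are positive).
#' @param status_fractions length-3 fractions (full, partial, edentulous)
#'   summing to 1; the cohort default (0.22, 0.56, 0.22) mirrors a clinical
#'   case mix of 55/136/55.
#' @param spec_ranges named list of length-2 ranges overriding the defaults
#'   for `arch_width_mm`, `arch_depth_mm`, `body_height_mm`,
#'   `ridge_height_mm`, `tooth_height_mm`, `cl3_reduction_mm`,
#'   `cl5_reduction_mm`, `noise_sd_HU`.
#' @param seed cohort seed.
#' @param spacing_mm,include_distractors passed through to every case.
#' @return list with `cases` (list of `PhantomCase`) and `metadata`
#'   (data.frame of the sampled parameters).
#' @export
make_cohort <- function(n, status_fractions = c(0.22, 0.56, 0.22),
                        spec_ranges = list(), seed = 1L,
                        spacing_mm = c(2, 2, 2), include_distractors = TRUE) {
  if (abs(sum(status_fractions) - 1) > 1e-6)
    stop("status_fractions must sum to 1")
  n <- as.integer(n)
  n_full <- as.integer(round(status_fractions[1] * n))
  n_eden <- as.integer(round(status_fractions[3] * n))
  n_part <- n - n_full - n_eden
  counts <- c(full = n_full, partial = n_part, edentulous = n_eden)
  want <- status_fractions > 0
  if (any(counts[want] < 1L) || n_part < 0L)
    stop("n = ", n, " too small to realize all requested dental statuses")
  rng <- function(nm, default) {
    r <- if (!is.null(spec_ranges[[nm]])) spec_ranges[[nm]] else default
    stats::runif(1, r[1], r[2])
  }
  statuses <- rep(names(counts), counts)
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n)
  cases <- vector("list", n)
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(case_seeds[i])
    sp <- phantom_spec(
      arch_width_mm = rng("arch_width_mm", c(85, 100)),
      arch_depth_mm = rng("arch_depth_mm", c(60, 75)),
      body_height_mm = rng("body_height_mm", c(16, 20)),
      ridge_height_mm = rng("ridge_height_mm", c(10, 14)),
      tooth_height_mm = rng("tooth_height_mm", c(7, 9)),
      cl3_reduction_mm = rng("cl3_reduction_mm", c(3.5, 4.5)),
      cl5_reduction_mm = rng("cl5_reduction_mm", c(7, 9)),
      noise_sd_HU = rng("noise_sd_HU", c(20, 30)),
      dentition_status = statuses[i],
      spacing_mm = spacing_mm,
      include_distractors = include_distractors,
      seed = case_seeds[i])
    cases[[i]] <- make_phantom(sp)
    meta[[i]] <- data.frame(case = i, status = statuses[i],
                            seed = case_seeds[i],
                            arch_width_mm = sp$arch_width_mm,
                            arch_depth_mm = sp$arch_depth_mm,
                            body_height_mm = sp$body_height_mm,
                            ridge_height_mm = sp$ridge_height_mm,
                            tooth_height_mm = sp$tooth_height_mm,
                            cl3_reduction_mm = sp$cl3_reduction_mm,
                            cl5_reduction_mm = sp$cl5_reduction_mm,
                            noise_sd_HU = sp$noise_sd_HU)
  }
  list(cases = cases, metadata = do.call(rbind, meta))
}

#' Write a phantom case to disk
#'
#' Writes the CT-like volume, the three ground-truth label volumes (NIfTI)
#' and their surface meshes (binary STL) into a directory.
#'
#' @param case a `PhantomCase`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param meshes also write ground-truth STL meshes.
#' @return the directory, invisibly.
#' @export
write_phantom_case <- function(case, dir, prefix = "case", meshes = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(case$image, file.path(dir, paste0(prefix, "_image.nii.gz")))
  write_volume(case$gt_original, file.path(dir, paste0(prefix, "_gt_O.nii.gz")))
  write_volume(case$gt_cl3, file.path(dir, paste0(prefix, "_gt_cl3.nii.gz")))
  write_volume(case$gt_cl5, file.path(dir, paste0(prefix, "_gt_cl5.nii.gz")))
  if (meshes) {
    write_mesh(extract_mesh(case$gt_original),
               file.path(dir, paste0(prefix, "_gt_O.stl")))
    write_mesh(extract_mesh(case$gt_cl3),
               file.path(dir, paste0(prefix, "_gt_cl3.stl")))
    write_mesh(extract_mesh(case$gt_cl5),
               file.path(dir, paste0(prefix, "_gt_cl5.stl")))
  }
  invisible(dir)
}
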