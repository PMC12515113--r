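# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

phantom_full <- function() fixture("phantom_full", function() {
  make_phantom(phantom_spec(seed = 7))
})

phantom_partial <- function() fixture("phantom_partial", function() {
  make_phantom(phantom_spec(dentition_status = "partial", seed = 3))
})

phantom_edentulous <- function() fixture("phantom_edentulous", function() {
  make_phantom(phantom_spec(dentition_status = "edentulous", seed = 4))
})

# binary voxel ball (indicator of an analytic sphere) as a LabelVolume
ball_mask <- function(n, r_vox, spacing = c(1, 1, 1), center = NULL) {
  if (is.null(center)) center <- rep((n + 1) / 2, 3)
  idx <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  inside <- (idx$i - center[1])^2 + (idx$j - center[2])^2 +
    (idx$k - center[3])^2 <= r_vox^2
  label_volume(array(as.integer(inside), c(n, n, n)), spacing = spacing)
}

# geodesic icosphere (subdivided icosahedron) of given radius
icosphere <- function(radius = 1, subdiv = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(parent = emptyenv())
    nf <- matrix(0L, 0, 3)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      m <- mid_cache[[key]]
      if (!is.null(m)) return(m)
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, "+")
  surface_mesh(v, f)
}

# axis-aligned box mesh (12 triangles, outward normals)
box_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # corner order: x fastest
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),     # z = lo
    c(5, 6, 7), c(6, 8, 7),     # z = hi
    c(1, 2, 5), c(2, 6, 5),     # y = lo
    c(3, 7, 4), c(4, 7, 8),     # y = hi
    c(1, 5, 3), c(3, 5, 7),     # x = lo
    c(2, 4, 6), c(4, 8, 6))     # x = hi
  m <- surface_mesh(v, f)
  if (mesh_volume(m) < 0) m$triangles <- m$triangles[, c(1, 3, 2)]
  m
}

# small mixed-status cohort reused by the phantom-consistency and curve suites
accept_cohort <- function() fixture("accept_cohort", function() {
  make_cohort(8, seed = 505)
})
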