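#' Triangulated surface meshes
#'
#' A `SurfaceMesh` holds vertices in world mm and 1-based triangle indices.
#' The vertex set is the `V_A` over which directed average surface distances
#' are taken.
#'
#' @param vertices numeric n x 3 matrix (mm).
#' @param triangles integer m x 3 matrix of vertex indices (1-based).
#' @return an object of class `SurfaceMesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L || ncol(triangles) != 3L)
    stop("vertices and triangles must have 3 columns")
  if (nrow(triangles) < 1L) stop("mesh must have at least one triangle")
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles),
            class = "SurfaceMesh")
}

#' @export
print.SurfaceMesh <- function(x, ...) {
  cat(sprintf("SurfaceMesh: %d vertices, %d triangles, volume %.2f mm^3\n",
              nrow(x$vertices), nrow(x$triangles), mesh_volume(x)))
  invisible(x)
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem volume; positive when triangle normals point outward.
#'
#' @param mesh a `SurfaceMesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  .mesh_volume_cpp(mesh$vertices, mesh$triangles)
}

tri_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$triangles
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Read and write STL surface files
#'
#' Binary STL is the default dialect; ASCII STL is detected automatically on
#' read and available on write via `ascii = TRUE`. STL stores single
#' precision, so coordinates round-trip to within about 1e-5 mm at
#' anatomical scales. Duplicated per-facet vertices are merged on read.
#'
#' @param mesh a `SurfaceMesh` with at least one triangle.
#' @param path file path.
#' @param ascii write ASCII instead of binary STL.
#' @return `read_mesh` returns a `SurfaceMesh`; `write_mesh` its path,
#'   invisibly.
#' @export
write_mesh <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "SurfaceMesh"))
  v <- mesh$vertices; f <- mesh$triangles
  n <- tri_normals(mesh)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  m <- nrow(f)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mandseg", con)
    tri <- cbind(n, v[f[, 1], ], v[f[, 2], ], v[f[, 3], ])
    txt <- sprintf(paste0(
      "facet normal %.9g %.9g %.9g\n outer loop\n",
      "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
      "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
      tri[, 1], tri[, 2], tri[, 3], tri[, 4], tri[, 5], tri[, 6],
      tri[, 7], tri[, 8], tri[, 9], tri[, 10], tri[, 11], tri[, 12])
    writeLines(txt, con)
    writeLines("endsolid mandseg", con)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "mandseg binary STL"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(m), con, size = 4, endian = "little")
  # 50 bytes per facet: 12 float32 + uint16 attribute
  vals <- t(cbind(n, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                  v[f[, 3], , drop = FALSE]))  # 12 x m
  fl <- writeBin(as.vector(vals), raw(), size = 4, endian = "little")
  fl <- matrix(fl, nrow = 48L)
  block <- rbind(fl, matrix(as.raw(0), nrow = 2L, ncol = m))
  writeBin(as.vector(block), con)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.size(path)
  if (sz < 84) stop("malformed STL: file too short")
  head_raw <- readBin(path, "raw", n = min(sz, 1024))
  printable <- head_raw[head_raw > as.raw(8) & head_raw < as.raw(127)]
  head_txt <- rawToChar(printable)
  is_ascii <- grepl("^\\s*solid", head_txt) && grepl("facet", head_txt) &&
    grepl("vertex", head_txt)
  if (is_ascii) {
    tri <- read_stl_ascii(path)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    m <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (m < 1L || sz < 84 + 50 * as.double(m))
      stop("malformed STL header: facet count inconsistent with file size")
    block <- matrix(readBin(con, "raw", n = 50 * m), nrow = 50L)
    fl <- readBin(as.vector(block[1:48, , drop = FALSE]), "numeric",
                  n = 12 * m, size = 4, endian = "little")
    tri <- matrix(fl, nrow = 12L)[4:12, , drop = FALSE]  # drop normals
  }
  m <- ncol(tri)
  pts <- matrix(as.vector(tri), ncol = 3, byrow = TRUE)  # 3m x 3 vertices
  key <- paste(pts[, 1], pts[, 2], pts[, 3], sep = "|")
  uid <- match(key, unique(key))
  verts <- pts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3 != 0)
    stop("malformed ASCII STL: vertex count not a multiple of 3")
  nums <- vapply(strsplit(trimws(vl), "\\s+"),
                 function(p) as.numeric(p[2:4]), numeric(3))  # 3 x 3m
  if (any(!is.finite(nums))) stop("malformed ASCII STL: non-numeric vertex")
  matrix(nums, nrow = 9L)  # 9 x m, (v1 v2 v3) per column
}
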