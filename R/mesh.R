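#' Triangle mesh objects
#'
#' A `triangle_mesh` is a closed, orientable triangulated surface:
#' `vertices` (n x 3, metres), `faces` (m x 3 integer, 1-based, wound
#' counter-clockwise seen from outside) and `normals` (n x 3 outward unit
#' vectors).
#'
#' @param vertices n x 3 numeric matrix of coordinates in metres.
#' @param faces m x 3 integer matrix of vertex indices.
#' @param normals optional n x 3 matrix of outward unit normals; computed by
#'   area weighting of incident face normals when omitted.
#' @param validate check closure/orientability and normal lengths.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range")
  }
  if (is.null(normals)) {
    normals <- vertex_normals(vertices, faces)
  } else {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    stopifnot(nrow(normals) == nrow(vertices), ncol(normals) == 3L)
  }
  mesh <- structure(list(vertices = vertices, faces = faces,
                         normals = normals),
                    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces (Euler characteristic %d)\n",
              nrow(x$vertices), nrow(x$faces), mesh_euler(x)))
  invisible(x)
}

row_norms <- function(m) sqrt(rowSums(m * m))

cross3 <- function(a, b) {
  # row-wise cross product of n x 3 matrices (recycled if one has 1 row)
  if (is.null(dim(a))) a <- matrix(a, 1L)
  if (is.null(dim(b))) b <- matrix(b, 1L)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

# Area-weighted per-vertex outward normals.
vertex_normals <- function(vertices, faces) {
  v1 <- vertices[faces[, 1L], , drop = FALSE]
  fn <- cross3(vertices[faces[, 2L], , drop = FALSE] - v1,
               vertices[faces[, 3L], , drop = FALSE] - v1)  # 2 * area * n
  idx <- c(faces[, 1L], faces[, 2L], faces[, 3L])
  s <- rowsum(rbind(fn, fn, fn), idx)
  acc <- matrix(0, nrow(vertices), 3L)
  acc[as.integer(rownames(s)), ] <- s
  acc / pmax(row_norms(acc), .Machine$double.xmin)
}

# faces with every edge shared by exactly two faces, consistently wound
mesh_edge_counts <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  table(key)
}

#' Validate a triangle mesh
#'
#' Checks the invariants required of head-model surfaces: every edge shared
#' by exactly two faces (closed, orientable), unit normals (1e-9), and no
#' zero-area faces.
#'
#' @param mesh a [triangle_mesh()].
#' @param tol tolerance on unit-normal length.
#' @return `mesh`, invisibly; stops on violation.
#' @export
validate_mesh <- function(mesh, tol = 1e-9) {
  counts <- mesh_edge_counts(mesh$faces)
  if (any(counts != 2L)) {
    stop("mesh is not closed: ", sum(counts != 2L),
         " edge(s) not shared by exactly 2 faces")
  }
  v1 <- mesh$vertices[mesh$faces[, 1L], , drop = FALSE]
  areas <- 0.5 * row_norms(cross3(mesh$vertices[mesh$faces[, 2L], , drop = FALSE] - v1,
                                  mesh$vertices[mesh$faces[, 3L], , drop = FALSE] - v1))
  if (any(areas <= 0)) stop("mesh has degenerate (zero-area) faces")
  if (any(abs(row_norms(mesh$normals) - 1) > tol)) {
    stop("mesh normals are not unit length within ", tol)
  }
  invisible(mesh)
}

#' Euler characteristic of a mesh
#'
#' V - E + F; equals 2 for a closed surface of sphere topology.
#'
#' @param mesh a [triangle_mesh()].
#' @return integer Euler characteristic.
#' @export
mesh_euler <- function(mesh) {
  n_e <- length(mesh_edge_counts(mesh$faces))
  nrow(mesh$vertices) - n_e + nrow(mesh$faces)
}

#' Geodesic sphere from a subdivided octahedron
#'
#' Subdivides each octahedron face into `freq^2` triangles and projects to
#' the unit sphere, giving `4 * freq^2 + 2` vertices. The octahedron is used
#' (rather than an icosahedron) so that the six axis poles are mesh
#' vertices, which lets ellipsoidal head surfaces match prescribed axis
#' extents exactly.
#'
#' @param freq subdivision frequency (>= 1).
#' @return a [triangle_mesh()] on the unit sphere (normals = vertices).
#' @export
octasphere <- function(freq) {
  m <- as.integer(freq)
  stopifnot(m >= 1L)
  octants <- expand.grid(sx = c(1L, -1L), sy = c(1L, -1L), sz = c(1L, -1L))

  # barycentric integer grid on one face: corners X=(m,0,0), Y=(0,m,0), Z=(0,0,m)
  ab <- expand.grid(a = 0:m, b = 0:m)
  ab <- ab[ab$a + ab$b <= m, ]
  ab <- ab[order(ab$a, ab$b), ]
  npts <- nrow(ab)                      # (m+1)(m+2)/2
  # local index of (a, b), row-major in a then b
  loc_idx <- function(a, b) {
    a * (m + 1L) - (a * (a - 1L)) %/% 2L + b + 1L
  }
  base_int <- cbind(m - ab$a - ab$b, ab$a, ab$b)  # (x, y, z) integer coords

  # local face list (1-based into the local grid)
  up <- expand.grid(a = 0:(m - 1L), b = 0:(m - 1L))
  up <- up[up$a + up$b <= m - 1L, ]
  f_up <- cbind(loc_idx(up$a, up$b), loc_idx(up$a + 1L, up$b),
                loc_idx(up$a, up$b + 1L))
  f_dn <- NULL
  if (m >= 2L) {
    dn <- expand.grid(a = 0:(m - 2L), b = 0:(m - 2L))
    dn <- dn[dn$a + dn$b <= m - 2L, ]
    f_dn <- cbind(loc_idx(dn$a + 1L, dn$b), loc_idx(dn$a + 1L, dn$b + 1L),
                  loc_idx(dn$a, dn$b + 1L))
  }
  f_local <- rbind(f_up, f_dn)

  all_int <- vector("list", 8L)
  all_faces <- vector("list", 8L)
  for (o in seq_len(8L)) {
    s <- unlist(octants[o, ])
    pts <- sweep(base_int, 2L, s, `*`)
    fl <- f_local
    if (prod(s) < 0L) fl <- fl[, c(1L, 3L, 2L)]  # keep outward winding
    all_int[[o]] <- pts
    all_faces[[o]] <- fl + (o - 1L) * npts
  }
  pts <- do.call(rbind, all_int)
  faces <- do.call(rbind, all_faces)

  key <- paste(pts[, 1L], pts[, 2L], pts[, 3L])
  first <- !duplicated(key)
  remap <- match(key, key[first])
  verts_int <- pts[first, , drop = FALSE]
  faces <- matrix(remap[faces], ncol = 3L)
  # every triangle's centroid lies strictly inside its octant, so no face is
  # duplicated across octants; only boundary vertices are welded

  v <- verts_int / m
  v <- v / row_norms(v)
  triangle_mesh(v, faces, normals = v, validate = FALSE)
}

#' Read or write meshes in ASCII OFF/PLY/STL
#'
#' Minimal readers/writers for the common ASCII mesh dialects; coordinates
#' are taken to be metres. STL does not share vertices, so reading STL welds
#' coincident vertices exactly.
#'
#' @param path file path; format from extension (.off, .ply, .stl).
#' @param mesh a [triangle_mesh()] (for writing).
#' @return `read_mesh` returns a [triangle_mesh()]; `write_mesh` returns
#'   `path` invisibly.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "off") {
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    stopifnot(toupper(trimws(lines[1L])) == "OFF")
    hdr <- scan(text = lines[2L], quiet = TRUE)
    nv <- hdr[1L]; nf <- hdr[2L]
    v <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE), ncol = 3L,
                byrow = TRUE)
    fraw <- lapply(lines[(3 + nv):(2 + nv + nf)],
                   function(l) scan(text = l, quiet = TRUE))
    f <- t(vapply(fraw, function(x) x[2:4] + 1, numeric(3L)))
  } else if (ext == "ply") {
    end_hdr <- which(trimws(lines) == "end_header")[1L]
    hdr <- lines[seq_len(end_hdr)]
    nv <- as.integer(sub(".*element vertex +(\\d+).*", "\\1",
                         grep("element vertex", hdr, value = TRUE)[1L]))
    nf <- as.integer(sub(".*element face +(\\d+).*", "\\1",
                         grep("element face", hdr, value = TRUE)[1L]))
    body <- lines[(end_hdr + 1L):length(lines)]
    v <- t(vapply(body[seq_len(nv)],
                  function(l) scan(text = l, quiet = TRUE)[1:3], numeric(3L)))
    f <- t(vapply(body[nv + seq_len(nf)],
                  function(l) scan(text = l, quiet = TRUE)[2:4] + 1,
                  numeric(3L)))
    dimnames(v) <- NULL
  } else if (ext == "stl") {
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- matrix(unlist(lapply(vl, function(l) {
      scan(text = sub("^\\s*vertex", "", l), quiet = TRUE)
    })), ncol = 3L, byrow = TRUE)
    key <- paste(coords[, 1L], coords[, 2L], coords[, 3L])
    first <- !duplicated(key)
    v <- coords[first, , drop = FALSE]
    f <- matrix(match(key, key[first]), ncol = 3L, byrow = TRUE)
  } else {
    stop("unsupported mesh format: ", ext)
  }
  triangle_mesh(v, f)
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  if (ext == "off") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("OFF", sprintf("%d %d 0", nrow(v), nrow(f))), con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L),
               con)
  } else if (ext == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L),
               con)
  } else if (ext == "stl") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid mesh", con)
    v1 <- v[f[, 1L], , drop = FALSE]
    fn <- cross3(v[f[, 2L], , drop = FALSE] - v1, v[f[, 3L], , drop = FALSE] - v1)
    fn <- fn / pmax(row_norms(fn), .Machine$double.xmin)
    for (i in seq_len(nrow(f))) {
      writeLines(c(sprintf("facet normal %.17g %.17g %.17g",
                           fn[i, 1L], fn[i, 2L], fn[i, 3L]),
                   "  outer loop",
                   sprintf("    vertex %.17g %.17g %.17g",
                           v[f[i, ], 1L], v[f[i, ], 2L], v[f[i, ], 3L]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else {
    stop("unsupported mesh format: ", ext)
  }
  invisible(path)
}
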