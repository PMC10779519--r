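#' Triangular surface mesh
#'
#' A `tri_mesh` stores the vertices (points in space, in ångströms) and the
#' explicitly defined triangular facets of an unstructured surface mesh.
#' Facets are expected to list their three vertices counter-clockwise when the
#' mesh is viewed from its exterior, so that the signed volume of a closed
#' mesh is positive. Facet indices are 1-based internally; the OBJ and MSMS
#' readers convert from the file formats' conventions at the I/O boundary.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z coordinates, Å).
#' @param facets integer matrix with 3 columns of 1-based vertex indices.
#' @return an object of class `tri_mesh` with elements `vertices` and `facets`.
#' @examples
#' m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'               rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
#' mesh_volume(m)
#' @export
tri_mesh <- function(vertices, facets) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = NULL)
  if (length(facets) == 0) {
    facets <- matrix(integer(0), ncol = 3)
  } else {
    facets <- matrix(as.integer(facets), ncol = 3, dimnames = NULL)
  }
  if (any(!is.finite(vertices))) {
    stop("tri_mesh: vertex coordinates must be finite")
  }
  if (nrow(facets) > 0) {
    if (any(facets < 1L) || any(facets > nrow(vertices))) {
      stop("tri_mesh: facet index out of range (1..", nrow(vertices), ")")
    }
    if (any(facets[, 1] == facets[, 2] | facets[, 1] == facets[, 3] |
            facets[, 2] == facets[, 3])) {
      stop("tri_mesh: facets must reference 3 distinct vertices")
    }
  }
  structure(list(vertices = vertices, facets = facets), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d facets, signed volume %.4f\n",
              nrow(x$vertices), nrow(x$facets), mesh_volume(x)))
  invisible(x)
}

#' Read a Wavefront OBJ mesh
#'
#' Parses `v` and `f` records of a Wavefront OBJ file; all other record types
#' are ignored. Facet vertex references may carry `/`-suffixed texture/normal
#' indices (`f 1/1/1 2/2/2 3/3/3`), of which only the leading vertex index is
#' used. OBJ indices are 1-based and map directly onto the internal 1-based
#' representation. Polygons with more than three vertices are rejected rather
#' than fan-triangulated, because silent triangulation could flip facet
#' orientations.
#'
#' @param path path to an OBJ file.
#' @return a [tri_mesh].
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) stop("read_obj: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  verts <- list()
  faces <- list()
  for (ln in seq_along(toks)) {
    tk <- toks[[ln]]
    if (length(tk) == 0 || tk[1] == "") next
    if (tk[1] == "v") {
      xyz <- suppressWarnings(as.numeric(tk[2:4]))
      if (length(tk) < 4 || any(is.na(xyz))) {
        stop("read_obj: malformed vertex record at line ", ln)
      }
      verts[[length(verts) + 1L]] <- xyz
    } else if (tk[1] == "f") {
      ref <- tk[-1]
      if (length(ref) != 3) {
        stop("read_obj: facet with ", length(ref),
             " vertices at line ", ln, " (only triangles are supported)")
      }
      idx <- suppressWarnings(
        as.integer(vapply(strsplit(ref, "/", fixed = TRUE), `[`, "", 1L)))
      if (any(is.na(idx))) {
        stop("read_obj: malformed facet record at line ", ln)
      }
      faces[[length(faces) + 1L]] <- idx
    }
  }
  v <- if (length(verts)) do.call(rbind, verts) else matrix(numeric(0), ncol = 3)
  f <- if (length(faces)) do.call(rbind, faces) else matrix(integer(0), ncol = 3)
  if (nrow(f) > 0 && (any(f < 1L) || any(f > nrow(v)))) {
    stop("read_obj: facet index out of range")
  }
  tri_mesh(v, f)
}

#' Write a Wavefront OBJ mesh
#'
#' Coordinates are written with enough decimal places that a write/read round
#' trip reproduces them within 1e-9.
#'
#' @param mesh a [tri_mesh].
#' @param path output file path.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- sprintf("v %.10f %.10f %.10f",
               mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  f <- if (nrow(mesh$facets) > 0) {
    sprintf("f %d %d %d", mesh$facets[, 1], mesh$facets[, 2], mesh$facets[, 3])
  } else character(0)
  ok <- tryCatch({
    writeLines(c(v, f), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("write_obj: cannot write to ", path)
  invisible(NULL)
}

# First integer on the third header line of an MSMS output file.
msms_declared_count <- function(lines, what) {
  if (length(lines) < 3) stop("read_msms_surface: truncated ", what, " file")
  n <- suppressWarnings(as.integer(strsplit(trimws(lines[3]),
                                            "[[:space:]]+")[[1]][1]))
  if (is.na(n)) stop("read_msms_surface: malformed ", what, " header")
  n
}

#' Read an MSMS .vert/.face mesh pair
#'
#' MSMS writes the vertex and facet arrays of its triangulated molecular
#' surfaces as a pair of text files, each with three header lines; the third
#' header line declares the record count. Vertex records carry coordinates
#' plus normals (`x y z nx ny nz ...`); facet records carry three 1-based
#' vertex indices plus type columns (`i j k type face-of`). Normals and
#' trailing columns are parsed and discarded.
#'
#' @param vert_path path to the `.vert` file.
#' @param face_path path to the `.face` file.
#' @return a [tri_mesh].
#' @export
read_msms_surface <- function(vert_path, face_path) {
  vl <- readLines(vert_path, warn = FALSE)
  fl <- readLines(face_path, warn = FALSE)
  nv <- msms_declared_count(vl, ".vert")
  nf <- msms_declared_count(fl, ".face")
  vrec <- vl[-(1:3)]
  frec <- fl[-(1:3)]
  vrec <- vrec[nzchar(trimws(vrec))]
  frec <- frec[nzchar(trimws(frec))]
  if (length(vrec) != nv) {
    stop("read_msms_surface: .vert declares ", nv, " records but has ",
         length(vrec))
  }
  if (length(frec) != nf) {
    stop("read_msms_surface: .face declares ", nf, " records but has ",
         length(frec))
  }
  vtk <- strsplit(trimws(vrec), "[[:space:]]+")
  ftk <- strsplit(trimws(frec), "[[:space:]]+")
  if (any(vapply(vtk, length, 0L) < 3)) {
    stop("read_msms_surface: malformed .vert record")
  }
  if (any(vapply(ftk, length, 0L) < 3)) {
    stop("read_msms_surface: non-triangle .face record")
  }
  v <- t(vapply(vtk, function(tk) as.numeric(tk[1:3]), numeric(3)))
  f <- t(vapply(ftk, function(tk) as.integer(tk[1:3]), integer(3)))
  if (any(is.na(v))) stop("read_msms_surface: malformed .vert coordinates")
  if (any(is.na(f))) stop("read_msms_surface: malformed .face indices")
  tri_mesh(v, f)
}

#' Signed volume of a triangular mesh
#'
#' Sum over facets of the signed volume of the tetrahedron spanned between
#' the origin and the facet, `det[v1 v2 v3] / 6`. For a closed mesh with
#' counter-clockwise facets this equals the enclosed volume and is invariant
#' to where the mesh sits relative to the origin; for an open mesh the signed
#' contributions simply sum.
#'
#' @param mesh a [tri_mesh].
#' @return signed volume in cubic ångströms.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (nrow(mesh$facets) == 0) return(0)
  a <- mesh$vertices[mesh$facets[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$facets[, 2], , drop = FALSE]
  c <- mesh$vertices[mesh$facets[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
         a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
         a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(det) / 6
}

#' Center a mesh and scale it into the unit ball
#'
#' Vertices are shifted by `center` (default: their mean) and divided by the
#' unit-ball scale factor. If the requested factor is smaller than the largest
#' centered vertex distance rmax, it is increased to rmax so that every vertex
#' lies inside the closed unit ball.
#'
#' @param mesh a [tri_mesh].
#' @param scale_factor requested unit-ball scale factor (Å, > 0).
#' @param center either the string `"vertex-mean"` or a numeric length-3
#'   centering origin. The retrieval pipeline overrides the default with the
#'   guide effective-atom centroid so mesh and atom features share one frame.
#' @return a [tri_mesh] inside the unit ball, with attributes `center` and
#'   `effective_factor` recording the transform actually applied.
#' @export
center_and_scale <- function(mesh, scale_factor, center = "vertex-mean") {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (!is.numeric(scale_factor) || length(scale_factor) != 1 ||
      scale_factor <= 0) {
    stop("center_and_scale: scale_factor must be a positive length")
  }
  if (identical(center, "vertex-mean")) {
    center <- colMeans(mesh$vertices)
  }
  center <- as.numeric(center)
  stopifnot(length(center) == 3)
  shifted <- sweep(mesh$vertices, 2, center)
  rmax <- sqrt(max(rowSums(shifted^2)))
  if (rmax == 0) stop("center_and_scale: degenerate mesh (all vertices coincide)")
  eff <- max(scale_factor, rmax)
  out <- tri_mesh(shifted / eff, mesh$facets)
  attr(out, "center") <- center
  attr(out, "effective_factor") <- eff
  out
}

# Unit icosahedron vertex/facet arrays with outward (CCW) facets.
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

#' Generate an icosphere mesh
#'
#' Subdivided icosahedron with vertices projected onto the sphere of the given
#' radius. The result is closed and counter-clockwise oriented; the facet
#' count is `20 * 4^subdivisions`. As an inscribed polyhedron its volume is
#' positive and strictly below `4 * pi * radius^3 / 3`, converging to it as
#' the subdivision level grows.
#'
#' @param radius sphere radius (Å, > 0).
#' @param subdivisions number of 4-way facet subdivisions (>= 0).
#' @return a [tri_mesh].
#' @export
generate_sphere_mesh <- function(radius, subdivisions = 3) {
  stopifnot(radius > 0, subdivisions >= 0)
  ico <- icosahedron()
  v <- ico$v
  f <- ico$f
  if (subdivisions > 0) {
    for (s in seq_len(subdivisions)) {
      nv <- nrow(v)
      midpoint_id <- new.env(hash = TRUE)
      vlist <- list(v)
      next_id <- nv
      get_mid <- function(i, j) {
        key <- paste(min(i, j), max(i, j))
        id <- midpoint_id[[key]]
        if (is.null(id)) {
          m <- (v[i, ] + v[j, ]) / 2
          m <- m / sqrt(sum(m^2))
          next_id <<- next_id + 1L
          vlist[[length(vlist) + 1L]] <<- m
          id <- next_id
          midpoint_id[[key]] <- id
        }
        id
      }
      newf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
      for (t in seq_len(nrow(f))) {
        a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
        ab <- get_mid(a, b); bc <- get_mid(b, cc); ca <- get_mid(cc, a)
        newf[4 * t - 3, ] <- c(a, ab, ca)
        newf[4 * t - 2, ] <- c(b, bc, ab)
        newf[4 * t - 1, ] <- c(cc, ca, bc)
        newf[4 * t, ] <- c(ab, bc, ca)
      }
      v <- do.call(rbind, vlist)
      f <- newf
    }
  }
  tri_mesh(v * radius, f)
}

#' Generate an axis-aligned box mesh
#'
#' Closed 12-facet box centered at the origin with the given half-extents,
#' counter-clockwise oriented.
#'
#' @param half_extents numeric length-3 vector of positive half-extents (Å).
#' @return a [tri_mesh]; its volume is `8 * prod(half_extents)`.
#' @export
generate_box_mesh <- function(half_extents = c(1, 1, 1)) {
  h <- as.numeric(half_extents)
  stopifnot(length(h) == 3, all(h > 0))
  v <- as.matrix(expand.grid(x = c(-1, 1) * h[1],
                             y = c(-1, 1) * h[2],
                             z = c(-1, 1) * h[3]))
  dimnames(v) <- NULL
  # vertex order: index = 1 + (x>0) + 2*(y>0) + 4*(z>0)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = -h (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = +h (normal +z)
    c(1, 2, 5), c(2, 6, 5),   # y = -h (normal -y)
    c(3, 7, 4), c(4, 7, 8),   # y = +h (normal +y)
    c(1, 5, 3), c(3, 5, 7),   # x = -h (normal -x)
    c(2, 4, 6), c(4, 8, 6))   # x = +h (normal +x)
  tri_mesh(v, f)
}
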