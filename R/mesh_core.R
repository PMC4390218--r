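#' Tetrahedral mesh with named surface patches
#'
#' `tet_mesh()` builds the central data structure of biteFEM: a tetrahedral
#' volume mesh (linear 4-node or quadratic 10-node elements) together with
#' named sets of boundary triangular faces ("patches") that carry the
#' biomechanical roles — muscle insertion areas, prehension (bite) contacts,
#' jaw-joint and occipital-condyle constraint sites.
#'
#' Coordinates are in millimetres and the package works in the consistent
#' mm–MPa–N unit system (1 MPa acting on 1 mm\eqn{^2} gives 1 N). The
#' skull coordinate convention is +x anterior, +y dorsal, +z left lateral.
#'
#' Element node ordering follows the VTK convention: corners 1–4 with
#' positive signed volume, then (for quadratic elements) mid-edge nodes on
#' edges (1,2), (2,3), (3,1), (1,4), (2,4), (3,4). Elements with negative
#' signed volume are repaired at construction by a vertex swap; the number
#' of repairs is reported via a message.
#'
#' @param nodes numeric matrix, one row per node, columns x, y, z (mm).
#' @param elems integer matrix of node indices, 4 columns (linear) or 10
#'   (quadratic), one row per tetrahedron.
#' @param patches named list of integer face matrices (3 columns for linear
#'   meshes, 6 for quadratic: corners then mid-edge nodes). Every face must
#'   be a boundary face of the volume mesh.
#' @param node_sets named list of integer node-index vectors.
#' @param metadata list; recognised entries are `label` (specimen label) and
#'   `units` (must be `"mm-MPa-N"` when present — units are validated, never
#'   converted).
#' @param validate logical; run [validate_mesh()] on the result.
#' @return an object of class `tet_mesh`.
#' @seealso [mesh_volume()], [mesh_surface_area()], [patch_area()],
#'   [patch_centroid()], [read_mesh()], [make_skull()]
#' @export
tet_mesh <- function(nodes, elems, patches = list(), node_sets = list(),
                     metadata = list(), validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3L) stop("`nodes` must have 3 columns (x, y, z)")
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  if (!ncol(elems) %in% c(4L, 10L))
    stop("`elems` must have 4 (linear) or 10 (quadratic) columns")
  order <- if (ncol(elems) == 4L) 1L else 2L
  if (nrow(elems) == 0L) stop("mesh has no elements")
  if (any(elems < 1L) || any(elems > nrow(nodes)))
    stop("element connectivity references nodes outside the node table")
  if (!is.null(metadata$units) && !identical(metadata$units, "mm-MPa-N"))
    stop("unsupported units tag '", metadata$units,
         "': biteFEM works in the consistent mm-MPa-N system")

  mesh <- structure(
    list(nodes = nodes, elems = elems, order = order,
         patches = patches, node_sets = node_sets, metadata = metadata),
    class = "tet_mesh")

  vols <- element_volumes(mesh)
  bad <- which(vols < 0)
  if (length(bad)) {
    # repair inverted elements: swap corners 2,3 (and re-map mid-edge nodes)
    perm <- if (order == 1L) c(1L, 3L, 2L, 4L) else
      c(1L, 3L, 2L, 4L, 7L, 6L, 5L, 8L, 10L, 9L)
    mesh$elems[bad, ] <- mesh$elems[bad, perm, drop = FALSE]
    message(length(bad), " inverted element(s) repaired by vertex swap")
  }
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d %s tetrahedra\n",
              nrow(x$nodes), nrow(x$elems),
              if (x$order == 1L) "linear (4-node)" else "quadratic (10-node)"))
  if (!is.null(x$metadata$label)) cat("  label:", x$metadata$label, "\n")
  if (length(x$patches))
    cat("  patches:", paste(names(x$patches), collapse = ", "), "\n")
  invisible(x)
}

# local corner triples of the 4 outward-oriented faces, and the local
# mid-edge node of each face edge for quadratic elements
.tet_face_corners <- rbind(c(1L, 3L, 2L), c(1L, 2L, 4L),
                           c(2L, 3L, 4L), c(1L, 4L, 3L))
.tet_face_mids    <- rbind(c(7L, 6L, 5L), c(5L, 9L, 8L),
                           c(6L, 10L, 9L), c(8L, 10L, 7L))

# collision-free numeric key for an unordered corner triple
.face_key <- function(tri, n_nodes) {
  s <- cbind(pmin(tri[, 1L], tri[, 2L], tri[, 3L]),
             tri[, 1L] + tri[, 2L] + tri[, 3L] -
               pmin(tri[, 1L], tri[, 2L], tri[, 3L]) -
               pmax(tri[, 1L], tri[, 2L], tri[, 3L]),
             pmax(tri[, 1L], tri[, 2L], tri[, 3L]))
  base <- as.double(n_nodes) + 1
  if (base^3 > 2^53) stop("mesh too large for face keying")
  (as.double(s[, 1L]) * base + s[, 2L]) * base + s[, 3L]
}

#' Boundary faces of a tetrahedral mesh
#'
#' Enumerates the faces that belong to exactly one tetrahedron, oriented
#' outward. For quadratic meshes each face carries its three mid-edge nodes.
#'
#' @param mesh a [tet_mesh()].
#' @return integer matrix of faces (3 or 6 columns).
#' @export
boundary_faces <- function(mesh) {
  ne <- nrow(mesh$elems)
  fc <- .tet_face_corners
  faces <- matrix(0L, nrow = 4L * ne, ncol = if (mesh$order == 1L) 3L else 6L)
  for (f in 1:4) {
    idx <- seq.int(f, by = 4L, length.out = ne)
    faces[idx, 1:3] <- mesh$elems[, fc[f, ], drop = FALSE]
    if (mesh$order == 2L)
      faces[idx, 4:6] <- mesh$elems[, .tet_face_mids[f, ], drop = FALSE]
  }
  key <- .face_key(faces[, 1:3, drop = FALSE], nrow(mesh$nodes))
  tab <- table(key)
  once <- as.numeric(names(tab)[tab == 1L])
  faces[key %in% once, , drop = FALSE]
}

#' Signed volumes of all elements
#'
#' Volumes from the corner-node determinant formula; mid-edge nodes do not
#' enter (biteFEM quadratic elements have straight edges by construction).
#'
#' @param mesh a [tet_mesh()].
#' @return numeric vector of signed element volumes (mm^3).
#' @export
element_volumes <- function(mesh) {
  n <- mesh$nodes
  e <- mesh$elems
  a <- n[e[, 2L], , drop = FALSE] - n[e[, 1L], , drop = FALSE]
  b <- n[e[, 3L], , drop = FALSE] - n[e[, 1L], , drop = FALSE]
  d <- n[e[, 4L], , drop = FALSE] - n[e[, 1L], , drop = FALSE]
  (a[, 1L] * (b[, 2L] * d[, 3L] - b[, 3L] * d[, 2L]) +
   a[, 2L] * (b[, 3L] * d[, 1L] - b[, 1L] * d[, 3L]) +
   a[, 3L] * (b[, 1L] * d[, 2L] - b[, 2L] * d[, 1L])) / 6
}

#' Total mesh volume
#'
#' @param mesh a [tet_mesh()].
#' @return total volume V in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- element_volumes(mesh)
  bad <- which(v <= 0)
  if (length(bad))
    stop("inverted or degenerate element(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  sum(v)
}

.tri_areas <- function(nodes, faces) {
  p1 <- nodes[faces[, 1L], , drop = FALSE]
  u <- nodes[faces[, 2L], , drop = FALSE] - p1
  v <- nodes[faces[, 3L], , drop = FALSE] - p1
  cx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  cy <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  cz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total boundary surface area
#'
#' Area of the enclosing surface S used by the area scaling law.
#'
#' @param mesh a [tet_mesh()].
#' @return total boundary area in mm^2.
#' @export
mesh_surface_area <- function(mesh) {
  sum(.tri_areas(mesh$nodes, boundary_faces(mesh)))
}

.get_patch <- function(mesh, patch) {
  if (!patch %in% names(mesh$patches))
    stop("unknown patch '", patch, "'; available: ",
         paste(names(mesh$patches), collapse = ", "))
  mesh$patches[[patch]]
}

#' Area of a named surface patch
#'
#' The muscular insertion area SM when the patch is a muscle origin.
#'
#' @param mesh a [tet_mesh()].
#' @param patch patch name.
#' @return patch area in mm^2 (0 with a warning for an empty patch).
#' @export
patch_area <- function(mesh, patch) {
  f <- .get_patch(mesh, patch)
  if (nrow(f) == 0L) {
    warning("patch '", patch, "' is empty")
    return(0)
  }
  sum(.tri_areas(mesh$nodes, f))
}

#' Area-weighted centroid of a named surface patch
#'
#' @param mesh a [tet_mesh()].
#' @param patch patch name.
#' @return length-3 numeric vector (mm).
#' @export
patch_centroid <- function(mesh, patch) {
  f <- .get_patch(mesh, patch)
  if (nrow(f) == 0L) stop("patch '", patch, "' is empty")
  a <- .tri_areas(mesh$nodes, f)
  cen <- (mesh$nodes[f[, 1L], , drop = FALSE] +
          mesh$nodes[f[, 2L], , drop = FALSE] +
          mesh$nodes[f[, 3L], , drop = FALSE]) / 3
  unname(colSums(cen * a) / sum(a))
}

#' Unique node indices of a patch
#'
#' All nodes (corner and mid-edge) lying on the faces of a patch; the node
#' set used when a patch acts as a constraint site.
#'
#' @param mesh a [tet_mesh()].
#' @param patch patch name.
#' @return sorted integer vector of node indices.
#' @export
patch_nodes <- function(mesh, patch) {
  sort(unique(as.integer(.get_patch(mesh, patch))))
}

#' Validate mesh invariants
#'
#' Checks: strictly positive element volumes; unique patch names; every
#' patch face a boundary face with valid node indices; for quadratic meshes,
#' mid-edge nodes at edge midpoints (construction-time geometry).
#'
#' @param mesh a [tet_mesh()].
#' @param check_midpoints logical; verify the mid-edge node positions
#'   (construction-time invariant — disable for deformed geometry).
#' @return invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_mesh <- function(mesh, check_midpoints = TRUE) {
  v <- element_volumes(mesh)
  if (any(v <= 0))
    stop("element(s) with non-positive volume: ",
         paste(utils::head(which(v <= 0), 5L), collapse = ", "))
  if (length(mesh$patches)) {
    if (anyDuplicated(names(mesh$patches)))
      stop("duplicate patch names")
    bkey <- .face_key(boundary_faces(mesh)[, 1:3, drop = FALSE],
                      nrow(mesh$nodes))
    for (nm in names(mesh$patches)) {
      f <- mesh$patches[[nm]]
      if (nrow(f) == 0L) next
      if (any(f < 1L) || any(f > nrow(mesh$nodes)))
        stop("patch '", nm, "' references invalid node indices")
      pk <- .face_key(f[, 1:3, drop = FALSE], nrow(mesh$nodes))
      if (!all(pk %in% bkey))
        stop("patch '", nm, "' contains non-boundary faces")
    }
  }
  if (mesh$order == 2L && check_midpoints) {
    edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L),
                   c(1L, 4L), c(2L, 4L), c(3L, 4L))
    for (k in 1:6) {
      mid <- mesh$nodes[mesh$elems[, 4L + k], , drop = FALSE]
      exp <- (mesh$nodes[mesh$elems[, edges[k, 1L]], , drop = FALSE] +
              mesh$nodes[mesh$elems[, edges[k, 2L]], , drop = FALSE]) / 2
      if (max(abs(mid - exp)) > 1e-8 * max(1, max(abs(mesh$nodes))))
        stop("mid-edge nodes off edge midpoints (edge slot ", k, ")")
    }
  }
  invisible(TRUE)
}

#' Linear-elastic material
#'
#' Isotropic, linear, homogeneous material in MPa. The skull default (used
#' throughout the worked examples) is cortical-bone-like: E = 6650 MPa,
#' nu = 0.35.
#'
#' @param E Young's modulus, MPa (> 0).
#' @param nu Poisson's ratio, dimensionless (-1 < nu < 0.5).
#' @return object of class `fem_material`.
#' @export
material <- function(E = 6650, nu = 0.35) {
  stopifnot(is.numeric(E), length(E) == 1L, is.finite(E),
            is.numeric(nu), length(nu) == 1L, is.finite(nu))
  if (E <= 0) stop("Young's modulus must be positive")
  if (nu <= -1 || nu >= 0.5) stop("Poisson's ratio must lie in (-1, 0.5)")
  structure(list(E = E, nu = nu), class = "fem_material")
}
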