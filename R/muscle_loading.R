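#' Jaw-adductor muscle definition
#'
#' A muscle is modelled as a uniform contraction pressure P (MPa, force per
#' unit area under the constant-PCSA assumption) acting over its insertion
#' patch on the skull, directed along the line joining the patch centroid
#' to the muscle's insertion point on the mandible.
#'
#' @param name muscle label, e.g. `"AME_left"`.
#' @param patch name of the insertion patch on the skull mesh.
#' @param pressure contraction pressure P, MPa (>= 0).
#' @param jaw_point length-3 point (mm): insertion location on the mandible.
#' @param side `"left"` or `"right"`.
#' @return object of class `muscle_definition`.
#' @export
muscle_definition <- function(name, patch, pressure, jaw_point,
                              side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(is.character(name), is.character(patch),
            is.numeric(pressure), length(pressure) == 1L,
            is.numeric(jaw_point), length(jaw_point) == 3L,
            all(is.finite(jaw_point)))
  if (pressure < 0) stop("contraction pressure must be non-negative")
  structure(list(name = name, patch = patch, pressure = pressure,
                 jaw_point = as.numeric(jaw_point), side = side),
            class = "muscle_definition")
}

#' Gape specification
#'
#' Gape at the moment of biting is the sum of skull elevation and mandible
#' depression. Elevation rigidly rotates the whole loaded skull frame and
#' leaves the elastic problem unchanged (constraints are expressed in the
#' skull frame), so only the mandible depression modifies the muscle force
#' directions; the elevation is carried in provenance. The two study
#' conditions are 6°/0° (gape 6°) and 6°/15° (gape 21°).
#'
#' @param skull_elevation_deg skull elevation, degrees (>= 0).
#' @param mandible_depression_deg mandible depression, degrees (>= 0).
#' @return object of class `gape_spec` with a `total_deg` field.
#' @export
gape_spec <- function(skull_elevation_deg = 6,
                      mandible_depression_deg = 0) {
  stopifnot(skull_elevation_deg >= 0, mandible_depression_deg >= 0)
  structure(list(skull_elevation_deg = skull_elevation_deg,
                 mandible_depression_deg = mandible_depression_deg,
                 total_deg = skull_elevation_deg + mandible_depression_deg),
            class = "gape_spec")
}

#' Muscle traction direction
#'
#' Unit vector from the insertion-patch centroid toward the mandibular
#' insertion point, rotated by the mandible depression angle about the
#' mediolateral (+z) axis in the opening sense (anterior tips ventrally).
#' Being a free direction vector, the rotation is independent of the axis
#' anchor point (the jaw joint).
#'
#' @param mesh a [tet_mesh()].
#' @param muscle a [muscle_definition()].
#' @param gape a [gape_spec()].
#' @return unit length-3 vector.
#' @export
muscle_direction <- function(mesh, muscle, gape = gape_spec()) {
  cen <- patch_centroid(mesh, muscle$patch)
  d <- muscle$jaw_point - cen
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12)
    stop("muscle '", muscle$name,
         "' has zero-length direction (jaw point at patch centroid)")
  d <- d / nd
  th <- -gape$mandible_depression_deg * pi / 180  # opening rotation about +z
  R <- rbind(c(cos(th), -sin(th), 0),
             c(sin(th),  cos(th), 0),
             c(0, 0, 1))
  as.numeric(R %*% d)
}

#' Nodal forces equivalent to a uniform traction on a patch
#'
#' Converts a uniform traction vector (MPa) over a patch into consistent
#' nodal forces: equal thirds per corner for linear faces; for quadratic
#' (straight-edge) faces the consistent lumping puts one third of each face
#' load on each mid-edge node and none on the corners. The resultant equals
#' `traction * patch area` exactly.
#'
#' @param mesh a [tet_mesh()].
#' @param patch patch name.
#' @param traction length-3 traction vector, MPa.
#' @return data.frame with columns `node`, `fx`, `fy`, `fz` (N), one row
#'   per loaded node.
#' @export
apply_traction <- function(mesh, patch, traction) {
  stopifnot(is.numeric(traction), length(traction) == 3L,
            all(is.finite(traction)))
  f <- .get_patch(mesh, patch)
  if (nrow(f) == 0L) stop("patch '", patch, "' is empty")
  if (any(!is.finite(mesh$nodes[unique(as.integer(f)), ])))
    stop("patch '", patch, "' has non-finite node coordinates")
  areas <- .tri_areas(mesh$nodes, f)
  loaded <- if (mesh$order == 1L) f[, 1:3, drop = FALSE]
            else f[, 4:6, drop = FALSE]
  node <- as.integer(loaded)
  w <- rep(areas / 3, 3L)
  agg <- rowsum(cbind(w * traction[1], w * traction[2], w * traction[3]),
                group = node)
  data.frame(node = as.integer(rownames(agg)),
             fx = agg[, 1], fy = agg[, 2], fz = agg[, 3])
}

#' Muscle tractions as nodal forces
#'
#' Applies the uniform traction `t = P d` (contraction pressure times the
#' centroid-to-jaw direction from [muscle_direction()]) over the muscle's
#' insertion patch. The total applied load is `P * SM * d` where SM is the
#' insertion area.
#'
#' @param mesh a [tet_mesh()].
#' @param muscle a [muscle_definition()].
#' @param gape a [gape_spec()].
#' @return data.frame as in [apply_traction()].
#' @export
build_tractions <- function(mesh, muscle, gape = gape_spec()) {
  d <- muscle_direction(mesh, muscle, gape)
  apply_traction(mesh, muscle$patch, muscle$pressure * d)
}

#' Assemble the global nodal load vector for a muscle set
#'
#' Sums the per-muscle nodal forces into a global degree-of-freedom vector
#' (length 3 * node count, dof order x1 y1 z1 x2 ...). Overlapping insertion
#' patches are allowed — forces add — but are reported via a message.
#'
#' @param mesh a [tet_mesh()].
#' @param muscles list of [muscle_definition()].
#' @param gape a [gape_spec()].
#' @return numeric load vector, N.
#' @export
assemble_load_vector <- function(mesh, muscles, gape = gape_spec()) {
  f <- numeric(3L * nrow(mesh$nodes))
  seen <- character(0)
  for (m in muscles) {
    if (m$patch %in% seen)
      message("patch '", m$patch, "' loaded by more than one muscle; ",
              "forces add")
    seen <- c(seen, m$patch)
    tb <- build_tractions(mesh, m, gape)
    idx <- 3L * (tb$node - 1L)
    f[idx + 1L] <- f[idx + 1L] + tb$fx
    f[idx + 2L] <- f[idx + 2L] + tb$fy
    f[idx + 3L] <- f[idx + 3L] + tb$fz
  }
  f
}
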