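#' @title Deterministic verification and skull-like fixtures
#' @description Generators for the meshes used to verify the solver (patch
#'   cube, cantilever beam) and for parametric skull-like specimens standing
#'   in for CT-derived geometry. All generators are pure functions of their
#'   parameters: two calls with identical arguments give identical meshes.
#' @name synthetic_specimens
NULL

# 6-tet decomposition of a hexahedron (corner ids in the order
# (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),(0,1,1)).
# All six share the 1-7 diagonal; conforming across a structured grid.
.hex_tets <- rbind(c(1L, 2L, 3L, 7L), c(1L, 3L, 4L, 7L), c(1L, 4L, 8L, 7L),
                   c(1L, 8L, 5L, 7L), c(1L, 5L, 6L, 7L), c(1L, 6L, 2L, 7L))

# Upgrade a linear mesh to quadratic by inserting mid-edge nodes.
.to_quadratic <- function(mesh) {
  if (mesh$order == 2L) return(mesh)
  edges_loc <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L),
                     c(1L, 4L), c(2L, 4L), c(3L, 4L))
  ne <- nrow(mesh$elems)
  n0 <- nrow(mesh$nodes)
  ea <- eb <- matrix(0L, ne, 6L)
  for (k in 1:6) {
    a <- mesh$elems[, edges_loc[k, 1L]]
    b <- mesh$elems[, edges_loc[k, 2L]]
    ea[, k] <- pmin(a, b); eb[, k] <- pmax(a, b)
  }
  key <- as.double(ea) * (n0 + 1) + as.double(eb)
  ukey <- sort(unique(key))
  mid_id <- match(key, ukey) + n0
  ua <- floor((ukey - 1e-9) / (n0 + 1))
  ub <- ukey - ua * (n0 + 1)
  mids <- (mesh$nodes[ua, , drop = FALSE] + mesh$nodes[ub, , drop = FALSE]) / 2
  elems10 <- cbind(mesh$elems, matrix(mid_id, ne, 6L))
  lookup_mid <- function(a, b) {
    k <- as.double(pmin(a, b)) * (n0 + 1) + as.double(pmax(a, b))
    as.integer(match(k, ukey) + n0)
  }
  patches <- lapply(mesh$patches, function(f) {
    if (nrow(f) == 0L) return(matrix(0L, 0L, 6L))
    cbind(f, lookup_mid(f[, 1L], f[, 2L]),
          lookup_mid(f[, 2L], f[, 3L]),
          lookup_mid(f[, 3L], f[, 1L]))
  })
  tet_mesh(rbind(mesh$nodes, mids), elems10, patches,
           node_sets = mesh$node_sets, metadata = mesh$metadata,
           validate = FALSE)
}

# Structured box of nx*ny*nz hexahedra split into tets; returns a linear
# mesh without patches (callers select and name faces).
.box_mesh <- function(origin, lengths, nx, ny, nz) {
  xs <- origin[1] + lengths[1] * (0:nx) / nx
  ys <- origin[2] + lengths[2] * (0:ny) / ny
  zs <- origin[3] + lengths[3] * (0:nz) / nz
  nid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs,
                                 KEEP.OUT.ATTRS = FALSE))
  cells <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  corn <- cbind(nid(cells$i,      cells$j,      cells$k),
                nid(cells$i + 1L, cells$j,      cells$k),
                nid(cells$i + 1L, cells$j + 1L, cells$k),
                nid(cells$i,      cells$j + 1L, cells$k),
                nid(cells$i,      cells$j,      cells$k + 1L),
                nid(cells$i + 1L, cells$j,      cells$k + 1L),
                nid(cells$i + 1L, cells$j + 1L, cells$k + 1L),
                nid(cells$i,      cells$j + 1L, cells$k + 1L))
  elems <- matrix(0L, 6L * nrow(corn), 4L)
  for (t in 1:6)
    elems[seq.int(t, by = 6L, length.out = nrow(corn)), ] <-
      corn[, .hex_tets[t, ], drop = FALSE]
  tet_mesh(nodes, elems, validate = FALSE)
}

# Select boundary faces whose centroid satisfies a predicate.
.select_faces <- function(mesh, bnd, pred) {
  cen <- (mesh$nodes[bnd[, 1L], , drop = FALSE] +
          mesh$nodes[bnd[, 2L], , drop = FALSE] +
          mesh$nodes[bnd[, 3L], , drop = FALSE]) / 3
  bnd[pred(cen), , drop = FALSE]
}

#' Cube fixture with six named face patches
#'
#' The classic solver-verification geometry: a cube meshed into `6 n^3`
#' tetrahedra with face patches `xmin`, `xmax`, `ymin`, `ymax`, `zmin`,
#' `zmax`, used for the uniaxial patch test.
#'
#' @param edge edge length, mm.
#' @param n number of divisions per side (>= 1).
#' @param order element order, 1 (linear) or 2 (quadratic).
#' @return a [tet_mesh()].
#' @export
make_patch_cube <- function(edge = 1, n = 1, order = 1) {
  stopifnot(edge > 0, n >= 1)
  mesh <- .box_mesh(c(0, 0, 0), rep(edge, 3), n, n, n)
  bnd <- boundary_faces(mesh)
  tol <- 1e-9 * edge
  mesh$patches <- list(
    xmin = .select_faces(mesh, bnd, function(c) abs(c[, 1]) < tol),
    xmax = .select_faces(mesh, bnd, function(c) abs(c[, 1] - edge) < tol),
    ymin = .select_faces(mesh, bnd, function(c) abs(c[, 2]) < tol),
    ymax = .select_faces(mesh, bnd, function(c) abs(c[, 2] - edge) < tol),
    zmin = .select_faces(mesh, bnd, function(c) abs(c[, 3]) < tol),
    zmax = .select_faces(mesh, bnd, function(c) abs(c[, 3] - edge) < tol))
  mesh$metadata <- list(label = "patch_cube", units = "mm-MPa-N")
  if (order == 2) mesh <- .to_quadratic(mesh)
  validate_mesh(mesh)
  mesh
}

#' Cantilever beam fixture
#'
#' A structured beam along +x with patches `fixed_end` (x = 0) and `tip`
#' (x = length), the geometry for the Timoshenko tip-deflection benchmark.
#'
#' @param length,width,height beam dimensions, mm (x, z, y extents).
#' @param nx,ny,nz divisions along length, height and width.
#' @param order element order, 1 or 2.
#' @return a [tet_mesh()].
#' @export
make_cantilever <- function(length = 20, width = 2, height = 2,
                            nx = 10, ny = 2, nz = 2, order = 1) {
  stopifnot(length > 0, width > 0, height > 0, nx >= 1, ny >= 1, nz >= 1)
  mesh <- .box_mesh(c(0, -height / 2, -width / 2),
                    c(length, height, width), nx, ny, nz)
  bnd <- boundary_faces(mesh)
  tol <- 1e-9 * length
  mesh$patches <- list(
    fixed_end = .select_faces(mesh, bnd, function(c) abs(c[, 1]) < tol),
    tip = .select_faces(mesh, bnd, function(c) abs(c[, 1] - length) < tol))
  mesh$metadata <- list(label = "cantilever", units = "mm-MPa-N")
  if (order == 2) mesh <- .to_quadratic(mesh)
  validate_mesh(mesh)
  mesh
}

#' Homothetic (uniform) scaling of a mesh
#'
#' Multiplies node coordinates by the linear ratio `alpha` about the origin;
#' connectivity, patches and node sets are unchanged. Volume scales as
#' `alpha^3` and all areas as `alpha^2`.
#'
#' @param mesh a [tet_mesh()].
#' @param alpha linear scaling ratio (> 0).
#' @return the scaled [tet_mesh()].
#' @export
homothety <- function(mesh, alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha <= 0) stop("homothety ratio must be positive")
  mesh$nodes <- mesh$nodes * alpha
  mesh
}

#' Parameters for the skull-like fixture
#'
#' The fixture is a dorsoventrally flattened dome shell over an elliptical
#' footprint, open ventrally, with a posteromedial opening (emulating the
#' interpterygoid vacuities) that leaves the posterolateral rim as a
#' suspended maxilla-like strip anchored at its anterior end. It carries
#' the full complement of labelled patches: paired adductor insertion
#' areas on the dorsal roof (`AME_*` anterolateral, `AMI_*` medial),
#' paired anterior and posterior prehension sites on the ventral rim
#' (the posterior pair on the strip), paired jaw-joint (`quadrate_*`) and
#' occipital (`condyle_*`) constraint sites, plus a dorsal `preorbital`
#' reporting region. With `lateral_gap = TRUE` the strip's posterior
#' connection to the quadrate region is removed, reproducing the absence
#' of a bony bridge between the posterior maxilla and the
#' quadrato-squamosal region that characterises extant giant-salamander
#' skulls; with `lateral_gap = FALSE` that bridge is present.
#'
#' Default proportions follow a "flat and broad" caricature
#' (length:width:height = 2:2:0.6); they are a biomechanical stand-in, not
#' a claim about real skull geometry.
#'
#' @param length anteroposterior extent, mm (adult default 180, a
#'   giant-salamander-scale skull).
#' @param width mediolateral extent, mm.
#' @param height dorsoventral extent (dome apex), mm.
#' @param shell_thickness shell thickness, mm (< height / 2).
#' @param resolution target element edge length, mm; at least two element
#'   layers are always placed through the shell.
#' @param element_order 1 or 2 (quadratic is the default used in analyses).
#' @param lateral_gap logical; omit the posterolateral bony bridge.
#' @param seed integer seed for optional interior-node jitter.
#' @param jitter jitter amplitude as a fraction of `resolution` (applied to
#'   interior nodes only, so patch geometry is reproducible); default 0.
#' @return a list of class `skull_params`.
#' @export
skull_params <- function(length = 180, width = 180, height = 54,
                         shell_thickness = 9, resolution = 9,
                         element_order = 2, lateral_gap = TRUE,
                         seed = 0L, jitter = 0) {
  stopifnot(length > 0, width > 0, height > 0, shell_thickness > 0,
            resolution > 0, element_order %in% c(1, 2), jitter >= 0)
  if (shell_thickness >= height / 2)
    stop("shell_thickness must be less than height / 2")
  structure(list(length = length, width = width, height = height,
                 shell_thickness = shell_thickness, resolution = resolution,
                 element_order = as.integer(element_order),
                 lateral_gap = isTRUE(lateral_gap),
                 seed = as.integer(seed), jitter = jitter),
            class = "skull_params")
}

# footprint-band definitions of the skull patches and openings, in
# normalised disc coordinates (rho = radial position, psi = polar angle
# from anterior in units of pi). The posteromedial vacuity makes the
# posterolateral rim a suspended maxilla-like strip anchored anteriorly;
# lateral_gap controls whether its posterior end bridges to the quadrate
# region. Patch bands are chosen so the default AME/AMI insertion-area
# ratio is close to the adult value 559.23/2333.
.skull_patch_spec <- function() {
  list(ami_rho = 0.60, ami_pmin = -0.65,
       ame_rho = c(0.60, 0.90), ame_psi = c(0.15, 0.25),
       vac_psi = c(0.30, 0.80), vac_rho = c(0.50, 0.78),
       rim_rho = 0.75,
       preh_ant_psi = c(0.03, 0.18), preh_post_psi = c(0.55, 0.68),
       gap_psi = c(0.70, 0.80), gap_rho = 0.55,
       quad_psi = c(0.81, 0.90), cond_psi = c(0.92, 1.001),
       preorb_pmin = 0.35)
}

#' Generate the skull-like shell fixture
#'
#' Builds a bilaterally mirror-symmetric (about z = 0) tetrahedral shell
#' mesh per [skull_params()]. The mesh and its patches are exactly
#' symmetric under z -> -z: elements on the right side are mirrored copies
#' of the left side, so bilateral load cases produce mirror-symmetric
#' solutions to solver round-off.
#'
#' Coordinates: +x anterior, +y dorsal, +z left lateral; the ventral rim
#' lies in y in [0, shell_thickness] and the dome apex at y = height.
#'
#' @param params a [skull_params()].
#' @return a [tet_mesh()] with patches `AME_left/right`, `AMI_left/right`,
#'   `prehension_anterior_left/right`, `prehension_posterior_left/right`,
#'   `quadrate_left/right`, `condyle_left/right`, and `preorbital`.
#' @export
make_skull <- function(params = skull_params()) {
  stopifnot(inherits(params, "skull_params"))
  ps <- .skull_patch_spec()
  a <- params$length / 2
  c_ <- params$width / 2
  t <- params$shell_thickness
  hd <- params$height - t
  nx <- max(10L, as.integer(ceiling(params$length / params$resolution)))
  nzh <- max(5L, as.integer(ceiling(params$width / params$resolution / 2)))
  nt <- max(2L, as.integer(round(t / params$resolution)))

  # full symmetric node grid over the parametric square [-1,1]^2
  xi  <- (0:nx) * 2 / nx - 1
  eta <- c(rev(-(1:nzh)), 0:nzh) / nzh               # symmetric in 0
  nj <- length(eta)
  grid <- expand.grid(i = 0:nx, j = 0:(nj - 1L), k = 0:nt)
  gxi <- xi[grid$i + 1L]
  geta <- eta[grid$j + 1L]
  p <- gxi * sqrt(pmax(0, 1 - geta^2 / 2))
  q <- geta * sqrt(pmax(0, 1 - gxi^2 / 2))
  rho2 <- p^2 + q^2
  ybase <- hd * (1 - rho2)
  nodes <- cbind(a * p, ybase + t * grid$k / nt, c_ * q)
  nid <- function(i, j, k) 1L + i + (nx + 1L) * (j + nj * k)

  # cells of the left half (eta >= 0), mirrored to the right
  jmid <- nzh  # index of eta = 0 in 0-based j
  cells <- expand.grid(i = 0:(nx - 1L), j = jmid:(nj - 2L), k = 0:(nt - 1L))
  # parametric centre of each footprint cell
  cxi <- (xi[cells$i + 1L] + xi[cells$i + 2L]) / 2
  ceta <- (eta[cells$j + 1L] + eta[cells$j + 2L]) / 2
  cp <- cxi * sqrt(pmax(0, 1 - ceta^2 / 2))
  cq <- ceta * sqrt(pmax(0, 1 - cxi^2 / 2))
  crho <- sqrt(cp^2 + cq^2)
  cpsi <- atan2(abs(cq), cp) / pi
  # posteromedial vacuity (always open): leaves the posterolateral rim as a
  # maxilla-like strip attached to the shell only at its anterior end ...
  drop <- crho > ps$vac_rho[1] & crho < ps$vac_rho[2] &
    cpsi > ps$vac_psi[1] & cpsi < ps$vac_psi[2]
  # ... and, without a lateral bridge, open between the posterior
  # prehension region and the quadrate region
  if (params$lateral_gap)
    drop <- drop |
      (crho > ps$gap_rho & cpsi > ps$gap_psi[1] & cpsi < ps$gap_psi[2])
  cells <- cells[!drop, , drop = FALSE]
  corn <- cbind(nid(cells$i,      cells$j,      cells$k),
                nid(cells$i + 1L, cells$j,      cells$k),
                nid(cells$i + 1L, cells$j + 1L, cells$k),
                nid(cells$i,      cells$j + 1L, cells$k),
                nid(cells$i,      cells$j,      cells$k + 1L),
                nid(cells$i + 1L, cells$j,      cells$k + 1L),
                nid(cells$i + 1L, cells$j + 1L, cells$k + 1L),
                nid(cells$i,      cells$j + 1L, cells$k + 1L))
  nc <- nrow(corn)
  elems_half0 <- matrix(0L, 6L * nc, 4L)
  for (s in 1:6)
    elems_half0[seq.int(s, by = 6L, length.out = nc), ] <-
      corn[, .hex_tets[s, ], drop = FALSE]
  # grid axes map to (x, z, y): a left-handed assignment, so the canonical
  # hex split needs one vertex swap for positive volumes; the mirrored half
  # (z -> -z) then needs none
  elems_half <- elems_half0[, c(1L, 3L, 2L, 4L)]
  mirror_node <- function(id) {
    id0 <- id - 1L
    i <- id0 %% (nx + 1L)
    rest <- id0 %/% (nx + 1L)
    j <- rest %% nj
    k <- rest %/% nj
    nid(i, 2L * jmid - j, k)
  }
  elems_mirror <- matrix(mirror_node(elems_half0), ncol = 4L)
  elems <- rbind(elems_half, elems_mirror)

  # drop unused nodes, remap
  used <- sort(unique(as.integer(elems)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  elems <- matrix(remap[elems], ncol = 4L)
  nodes <- nodes[used, , drop = FALSE]

  # layer index per node (for dorsal/ventral face classification)
  layer <- ((used - 1L) %/% ((nx + 1L) * nj))

  mesh <- tet_mesh(nodes, elems, validate = FALSE,
                   metadata = list(label = "synthetic_skull",
                                   units = "mm-MPa-N"))
  bnd <- boundary_faces(mesh)
  top <- apply(matrix(layer[bnd[, 1:3]], ncol = 3L) == nt, 1L, all)
  bot <- apply(matrix(layer[bnd[, 1:3]], ncol = 3L) == 0L, 1L, all)
  cen <- (nodes[bnd[, 1L], , drop = FALSE] + nodes[bnd[, 2L], , drop = FALSE] +
          nodes[bnd[, 3L], , drop = FALSE]) / 3
  fp <- cen[, 1] / a; fq <- cen[, 3] / c_
  frho <- sqrt(fp^2 + fq^2)
  fpsi <- atan2(abs(fq), fp) / pi
  # a face is "left" only if entirely in z > 0 (and vice versa), so paired
  # patches never share midline nodes and per-side reactions are disjoint
  ztol <- 1e-9 * params$width
  zc <- matrix(nodes[bnd[, 1:3], 3L], ncol = 3L)
  left <- zc[, 1] > ztol & zc[, 2] > ztol & zc[, 3] > ztol
  right <- zc[, 1] < -ztol & zc[, 2] < -ztol & zc[, 3] < -ztol

  pick <- function(sel) bnd[sel, , drop = FALSE]
  band <- function(v, b) v > b[1] & v < b[2]
  patches <- list(
    AME_left  = pick(top & left  & band(frho, ps$ame_rho) & band(fpsi, ps$ame_psi)),
    AME_right = pick(top & right & band(frho, ps$ame_rho) & band(fpsi, ps$ame_psi)),
    AMI_left  = pick(top & left  & frho < ps$ami_rho & fp > ps$ami_pmin),
    AMI_right = pick(top & right & frho < ps$ami_rho & fp > ps$ami_pmin),
    prehension_anterior_left   = pick(bot & left  & frho > ps$rim_rho & band(fpsi, ps$preh_ant_psi)),
    prehension_anterior_right  = pick(bot & right & frho > ps$rim_rho & band(fpsi, ps$preh_ant_psi)),
    prehension_posterior_left  = pick(bot & left  & frho > ps$rim_rho & band(fpsi, ps$preh_post_psi)),
    prehension_posterior_right = pick(bot & right & frho > ps$rim_rho & band(fpsi, ps$preh_post_psi)),
    quadrate_left  = pick(bot & left  & frho > ps$rim_rho & band(fpsi, ps$quad_psi)),
    quadrate_right = pick(bot & right & frho > ps$rim_rho & band(fpsi, ps$quad_psi)),
    condyle_left   = pick(bot & left  & frho > ps$rim_rho & band(fpsi, ps$cond_psi)),
    condyle_right  = pick(bot & right & frho > ps$rim_rho & band(fpsi, ps$cond_psi)),
    preorbital = pick(top & fp > ps$preorb_pmin))
  small <- names(patches)[vapply(patches, nrow, 1L) < 3L]
  if (length(small))
    stop("patch(es) captured fewer than 3 faces at this resolution: ",
         paste(small, collapse = ", "), "; refine `resolution`")
  mesh$patches <- patches

  if (params$jitter > 0) {
    bn <- unique(as.integer(bnd))
    interior <- setdiff(seq_len(nrow(mesh$nodes)), bn)
    if (length(interior)) {
      set.seed(params$seed)
      mesh$nodes[interior, ] <- mesh$nodes[interior, , drop = FALSE] +
        matrix(stats::runif(3L * length(interior), -1, 1),
               ncol = 3L) * params$jitter * params$resolution * 0.25
    }
  }
  if (params$element_order == 2L) mesh <- .to_quadratic(mesh)
  validate_mesh(mesh)
  mesh
}

#' Default adductor muscle set for the skull fixture
#'
#' Builds the four jaw-closing muscle definitions (left/right AME and AMI)
#' with mandibular insertion points placed ventral and slightly lateral to
#' each origin centroid, so the traction pulls the skull roof toward the
#' lower jaw.
#'
#' @param mesh a skull fixture from [make_skull()].
#' @param pressure contraction pressure, MPa (single value or named vector
#'   with entries `AME` and `AMI`).
#' @return list of [muscle_definition()] objects.
#' @export
skull_muscles <- function(mesh, pressure = 0.3) {
  pr <- function(which) {
    if (length(pressure) == 1L && is.null(names(pressure))) return(pressure)
    unname(pressure[[which]])
  }
  height <- max(mesh$nodes[, 2])
  zhalf <- max(abs(mesh$nodes[, 3]))
  mk <- function(name, patch, which, side) {
    cen <- patch_centroid(mesh, patch)
    jp <- c(cen[1], -0.3 * height,
            sign(cen[3]) * max(abs(cen[3]), 0.8 * zhalf))
    muscle_definition(name, patch, pr(which), jp, side)
  }
  list(mk("AME_left", "AME_left", "AME", "left"),
       mk("AME_right", "AME_right", "AME", "right"),
       mk("AMI_left", "AMI_left", "AMI", "left"),
       mk("AMI_right", "AMI_right", "AMI", "right"))
}
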