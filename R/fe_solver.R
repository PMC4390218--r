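#' Isotropic elasticity matrix in Voigt form
#'
#' 6x6 constitutive matrix relating Voigt stress (s11, s22, s33, s23, s13,
#' s12) to Voigt strain with engineering shear strains, for a linear,
#' homogeneous, isotropic material.
#'
#' @param mat a [material()].
#' @return 6x6 numeric matrix, MPa.
#' @export
elasticity_matrix <- function(mat) {
  stopifnot(inherits(mat, "fem_material"))
  if (abs(mat$nu - 0.5) < 1e-6)
    stop("Poisson's ratio at the incompressible limit; no linear-elastic ",
         "constitutive matrix exists")
  lam <- mat$E * mat$nu / ((1 + mat$nu) * (1 - 2 * mat$nu))
  mu <- mat$E / (2 * (1 + mat$nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

.lame <- function(mat)
  list(lambda = mat$E * mat$nu / ((1 + mat$nu) * (1 - 2 * mat$nu)),
       mu = mat$E / (2 * (1 + mat$nu)))

# 4-point Gauss rule on the tetrahedron (barycentric), exact to degree 2
.tet_gauss <- local({
  a <- (5 + 3 * sqrt(5)) / 20
  b <- (5 - sqrt(5)) / 20
  rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
})

# local edge endpoints of the VTK mid-node slots 5..10
.tet10_edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L),
                      c(1L, 4L), c(2L, 4L), c(3L, 4L))

# corner barycentric gradient matrix (4x3) and element volume
.corner_grads <- function(coords) {
  C <- t(coords[2:4, , drop = FALSE]) - coords[1, ]
  detC <- det(C)
  if (abs(detC) < .Machine$double.xmin * 1e6 || detC <= 0)
    stop("degenerate or inverted element")
  Ci <- solve(C)
  list(gL = rbind(-colSums(Ci), Ci), V = detC / 6)
}

# shape-function gradient matrices (nn x 3), one per quadrature point,
# and matching weights. Quadratic elements are affine (straight edges,
# mid-edge nodes at midpoints), so corner gradients are constant.
.shape_grads <- function(coords, order) {
  cg <- .corner_grads(coords)
  if (order == 1L)
    return(list(G = list(cg$gL), w = cg$V))
  G <- vector("list", 4L)
  for (g in 1:4) {
    L <- .tet_gauss[g, ]
    Gn <- matrix(0, 10L, 3L)
    Gn[1:4, ] <- (4 * L - 1) * cg$gL
    for (k in 1:6) {
      i <- .tet10_edges[k, 1L]; j <- .tet10_edges[k, 2L]
      Gn[4L + k, ] <- 4 * (L[i] * cg$gL[j, ] + L[j] * cg$gL[i, ])
    }
    G[[g]] <- Gn
  }
  list(G = G, w = rep(cg$V / 4, 4))
}

.element_K <- function(coords, lambda, mu, order) {
  sg <- .shape_grads(coords, order)
  nn <- nrow(coords)
  K <- matrix(0, 3L * nn, 3L * nn)
  ia <- lapply(1:3, function(a) seq.int(a, 3L * nn, by = 3L))
  for (g in seq_along(sg$G)) {
    Gn <- sg$G[[g]]
    w <- sg$w[g]
    A <- tcrossprod(Gn)
    for (a in 1:3) for (b in 1:3) {
      blk <- lambda * outer(Gn[, a], Gn[, b]) + mu * outer(Gn[, b], Gn[, a])
      if (a == b) blk <- blk + mu * A
      K[ia[[a]], ia[[b]]] <- K[ia[[a]], ia[[b]]] + w * blk
    }
  }
  K
}

#' Element stiffness matrix
#'
#' Stiffness of a single tetrahedron (constant-strain closed form for
#' linear elements; 4-point Gauss quadrature for quadratic elements, exact
#' for their affine geometry). Degrees of freedom are interleaved
#' (x1, y1, z1, x2, ...). The matrix is symmetric positive-semidefinite
#' with exactly the six rigid-body zero-energy modes.
#'
#' @param coords 4x3 or 10x3 node coordinate matrix (mm); node ordering as
#'   in [tet_mesh()].
#' @param mat a [material()].
#' @return 12x12 or 30x30 stiffness matrix (N/mm).
#' @export
element_stiffness <- function(coords, mat) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) %in% c(4L, 10L), ncol(coords) == 3L,
            inherits(mat, "fem_material"))
  lm <- .lame(mat)
  .element_K(coords, lm$lambda, lm$mu, if (nrow(coords) == 4L) 1L else 2L)
}

#' Assemble the global stiffness matrix
#'
#' Sparse symmetric global stiffness, dimension 3 x node count, built by
#' standard scatter of element matrices.
#'
#' @param mesh a [tet_mesh()].
#' @param mat a [material()].
#' @return a `dgCMatrix` sparse matrix.
#' @export
assemble <- function(mesh, mat) {
  lm <- .lame(mat)
  nn_el <- if (mesh$order == 1L) 4L else 10L
  nd_el <- 3L * nn_el
  ne <- nrow(mesh$elems)
  nent <- nd_el * nd_el
  ii <- integer(nent * ne); jj <- integer(nent * ne); xx <- numeric(nent * ne)
  rep_i <- rep(seq_len(nd_el), times = nd_el)
  rep_j <- rep(seq_len(nd_el), each = nd_el)
  axes <- rep(1:3, nn_el)
  for (e in seq_len(ne)) {
    en <- mesh$elems[e, ]
    Ke <- .element_K(mesh$nodes[en, , drop = FALSE], lm$lambda, lm$mu,
                     mesh$order)
    dof <- 3L * rep(en - 1L, each = 3L) + axes
    at <- (e - 1L) * nent
    ii[at + seq_len(nent)] <- dof[rep_i]
    jj[at + seq_len(nent)] <- dof[rep_j]
    xx[at + seq_len(nent)] <- Ke
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = rep(3L * nrow(mesh$nodes), 2L))
}

#' Dirichlet constraint set
#'
#' Zero-displacement constraints by role: in the bite model the prehension
#' (bite contact) patches are fixed in all three directions, the jaw-joint
#' (quadrate) patches in y (dorsoventral), and the occipital condyles in x
#' (anteroposterior). Duplicate (node, axis) pairs across entries are
#' merged — homogeneous constraints cannot conflict.
#'
#' @param mesh a [tet_mesh()].
#' @param entries list; each element a list with `axes` (subset of
#'   "x","y","z") and either `patch` (patch name) or `nodes` (node indices),
#'   optionally `role` (label used in reaction breakdowns).
#' @return object of class `constraint_set`: resolved entries plus the
#'   vector of fixed global dofs.
#' @export
constraint_set <- function(mesh, entries) {
  ax_id <- c(x = 1L, y = 2L, z = 3L)
  res <- lapply(entries, function(en) {
    nodes <- if (!is.null(en$patch)) patch_nodes(mesh, en$patch)
             else sort(unique(as.integer(en$nodes)))
    if (length(nodes) == 0L) stop("constraint entry resolves to no nodes")
    if (any(nodes < 1L | nodes > nrow(mesh$nodes)))
      stop("constraint node indices out of range")
    axes <- ax_id[match.arg(en$axes, c("x", "y", "z"), several.ok = TRUE)]
    list(role = if (!is.null(en$role)) en$role
                else if (!is.null(en$patch)) en$patch else "nodes",
         patch = en$patch, nodes = nodes, axes = unname(axes))
  })
  dofs <- sort(unique(unlist(lapply(res, function(en)
    as.integer(outer(3L * (en$nodes - 1L), en$axes, `+`))))))
  if (length(dofs) < 6L)
    stop("constraints remove fewer than 6 degrees of freedom; ",
         "rigid-body modes remain")
  structure(list(entries = res, dofs = dofs, n_dof = 3L * nrow(mesh$nodes)),
            class = "constraint_set")
}

#' Solve the constrained linear-elastic static problem
#'
#' Constraints are imposed by elimination (reduction of the system to the
#' free degrees of freedom), so constraint reactions are exact by
#' back-substitution: `r = K[c, ] u - f[c]`. This matters because the bite
#' force is itself a reaction. The reduced system is solved by sparse
#' Cholesky factorization.
#'
#' @param K global stiffness from [assemble()].
#' @param loads global load vector (N), e.g. from [assemble_load_vector()].
#' @param constraints a [constraint_set()].
#' @return object of class `fem_solution` with fields `u` (n x 3 nodal
#'   displacements, mm), `reactions` (n x 3, N, nonzero only at constrained
#'   dofs), `fixed` (n x 3 logical), `constraints`, and
#'   `equilibrium_residual` (relative).
#' @export
solve_static <- function(K, loads, constraints) {
  stopifnot(inherits(constraints, "constraint_set"))
  nd <- nrow(K)
  if (length(loads) != nd || constraints$n_dof != nd)
    stop("dimension mismatch between stiffness, loads and constraints")
  fixed <- constraints$dofs
  free <- setdiff(seq_len(nd), fixed)
  Kff <- K[free, free, drop = FALSE]
  sing <- function(msg)
    stop("singular stiffness after constraint elimination: ",
         "unconstrained rigid-body modes remain (", msg, ")", call. = FALSE)
  ch <- withCallingHandlers(
    tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE),
             error = function(e) sing(conditionMessage(e))),
    warning = function(w) {
      if (grepl("not positive definite", conditionMessage(w)))
        sing(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  uf <- as.numeric(Matrix::solve(ch, loads[free]))
  res <- max(abs(Kff %*% uf - loads[free]))
  scl <- max(abs(loads[free]), 1e-300)
  if (!is.finite(res) || res > 1e-6 * max(scl, 1))
    stop("static solve did not reach equilibrium on free dofs (residual ",
         format(res), ")")
  u <- numeric(nd)
  u[free] <- uf
  r <- numeric(nd)
  r[fixed] <- as.numeric(K[fixed, , drop = FALSE] %*% u) - loads[fixed]
  fsum <- colSums(matrix(loads + r, ncol = 3L, byrow = TRUE))
  fscale <- max(sum(abs(loads)), 1e-300)
  structure(list(
    u = matrix(u, ncol = 3L, byrow = TRUE),
    reactions = matrix(r, ncol = 3L, byrow = TRUE),
    fixed = matrix(seq_len(nd) %in% fixed, ncol = 3L, byrow = TRUE),
    constraints = constraints,
    equilibrium_residual = max(abs(fsum)) / fscale),
    class = "fem_solution")
}

#' @export
print.fem_solution <- function(x, ...) {
  cat(sprintf("fem_solution: %d nodes, max |u| = %.4g mm, equilibrium residual %.2e\n",
              nrow(x$u), max(abs(x$u)), x$equilibrium_residual))
  invisible(x)
}

#' Recover stresses from a displacement field
#'
#' Per-element Voigt stress (s11, s22, s33, s23, s13, s12) sampled at the
#' quadrature points and averaged per element, plus a nodal field obtained
#' by volume-weighted averaging of the adjacent element stresses. Von Mises
#' equivalents are computed for both.
#'
#' @param mesh a [tet_mesh()].
#' @param mat a [material()].
#' @param u n x 3 nodal displacement matrix (mm).
#' @return list with `stress_elem` (m x 6, MPa), `vm_elem`, `stress_node`
#'   (n x 6), `vm_node`.
#' @export
recover_stresses <- function(mesh, mat, u) {
  stopifnot(nrow(u) == nrow(mesh$nodes), ncol(u) == 3L)
  lm <- .lame(mat)
  ne <- nrow(mesh$elems)
  sig <- matrix(0, ne, 6L)
  for (e in seq_len(ne)) {
    en <- mesh$elems[e, ]
    sg <- .shape_grads(mesh$nodes[en, , drop = FALSE], mesh$order)
    U <- u[en, , drop = FALSE]
    acc <- numeric(6L)
    for (g in seq_along(sg$G)) {
      gr <- crossprod(U, sg$G[[g]])       # grad u, 3x3
      eps <- (gr + t(gr)) / 2
      s <- 2 * lm$mu * eps + diag(lm$lambda * sum(diag(eps)), 3L)
      acc <- acc + c(s[1, 1], s[2, 2], s[3, 3], s[2, 3], s[1, 3], s[1, 2])
    }
    sig[e, ] <- acc / length(sg$G)
  }
  vols <- element_volumes(mesh)
  nn_el <- ncol(mesh$elems)
  nodes_of <- as.integer(mesh$elems)
  wts <- rep(vols, times = nn_el)
  num <- rowsum(sig[rep(seq_len(ne), times = nn_el), , drop = FALSE] * wts,
                group = nodes_of)
  den <- rowsum(wts, group = nodes_of)
  stress_node <- matrix(0, nrow(mesh$nodes), 6L)
  idx <- as.integer(rownames(num))
  stress_node[idx, ] <- num / as.numeric(den)
  list(stress_elem = sig, vm_elem = von_mises(sig),
       stress_node = stress_node, vm_node = von_mises(stress_node))
}

#' Von Mises equivalent stress
#'
#' `sqrt(0.5 * ((s11-s22)^2 + (s22-s33)^2 + (s33-s11)^2) + 3 * (s23^2 +
#' s13^2 + s12^2))` — the deviatoric second-invariant criterion used for
#' ductile yield prediction.
#'
#' @param sigma numeric length-6 Voigt stress (s11, s22, s33, s23, s13,
#'   s12) or a matrix with 6 columns.
#' @return scalar or vector of Von Mises stresses, MPa.
#' @export
von_mises <- function(sigma) {
  if (is.null(dim(sigma))) sigma <- matrix(sigma, ncol = 6L)
  stopifnot(ncol(sigma) == 6L)
  sqrt(0.5 * ((sigma[, 1] - sigma[, 2])^2 + (sigma[, 2] - sigma[, 3])^2 +
              (sigma[, 3] - sigma[, 1])^2) +
       3 * (sigma[, 4]^2 + sigma[, 5]^2 + sigma[, 6]^2))
}

#' Bite force from prehension reactions
#'
#' The estimated bite force acting on the prey is the resultant of the
#' reaction forces at the fully fixed prehension (bite contact) nodes.
#'
#' @param solution a `fem_solution` from [solve_static()].
#' @param nodes integer node indices of the prehension set; must be fixed
#'   in all three directions.
#' @return list with `force` (length-3 resultant, N) and `magnitude` (N).
#' @export
bite_force <- function(solution, nodes) {
  stopifnot(inherits(solution, "fem_solution"))
  nodes <- sort(unique(as.integer(nodes)))
  if (length(nodes) == 0L) stop("empty prehension node set")
  if (!all(solution$fixed[nodes, ]))
    stop("prehension nodes are not fully constrained in all three axes")
  f <- colSums(solution$reactions[nodes, , drop = FALSE])
  list(force = f, magnitude = sqrt(sum(f^2)))
}

#' Assemble, solve and recover in one call
#'
#' Convenience wrapper: [assemble()] (or a pre-assembled stiffness),
#' [solve_static()] and [recover_stresses()].
#'
#' @param mesh a [tet_mesh()].
#' @param mat a [material()].
#' @param loads global load vector.
#' @param constraints a [constraint_set()].
#' @param K optional pre-assembled stiffness.
#' @return `fem_solution` with a `stress` field attached.
#' @export
solve_mesh <- function(mesh, mat, loads, constraints, K = NULL) {
  if (is.null(K)) K <- assemble(mesh, mat)
  sol <- solve_static(K, loads, constraints)
  sol$stress <- recover_stresses(mesh, mat, sol$u)
  sol
}
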