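# shared fixtures and independent oracles, built in code at test time

# reference tetrahedron (unit right tet at the origin)
single_tet <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1))
}

# scatter a nodal force table into a global dof vector
loads_from_table <- function(mesh, tb) {
  f <- numeric(3L * nrow(mesh$nodes))
  idx <- 3L * (tb$node - 1L)
  f[idx + 1L] <- tb$fx; f[idx + 2L] <- tb$fy; f[idx + 3L] <- tb$fz
  f
}

# uniaxial patch-test boundary conditions: traction p on xmax, rollers on
# xmin, minimal extra fixities to remove the remaining rigid modes
uniaxial_setup <- function(mesh, p, edge = 1) {
  tb <- apply_traction(mesh, "xmax", c(p, 0, 0))
  origin <- which(rowSums(abs(mesh$nodes)) < 1e-9 * edge)
  up_z <- which(abs(mesh$nodes[, 1]) < 1e-9 & abs(mesh$nodes[, 2]) < 1e-9 &
                  abs(mesh$nodes[, 3] - edge) < 1e-9 * edge)
  cs <- constraint_set(mesh, list(
    list(patch = "xmin", axes = "x"),
    list(nodes = origin, axes = c("y", "z")),
    list(nodes = up_z, axes = "y")))
  list(loads = loads_from_table(mesh, tb), constraints = cs)
}

rotation_matrix <- function(th) {
  Rx <- rbind(c(1, 0, 0),
              c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])),
              c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0),
              c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# independent element-stiffness oracle: explicit B-matrix route
# K = sum_g w_g B^T D B with B built from shape-function gradients
oracle_element_K <- function(coords, mat) {
  D <- elasticity_matrix(mat)
  X <- coords[1:4, , drop = FALSE]
  C <- cbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ])
  V <- det(C) / 6
  Ci <- solve(C)
  gL <- rbind(-colSums(Ci), Ci)
  nn <- nrow(coords)
  bmat <- function(G) {
    B <- matrix(0, 6, 3 * nn)
    for (a in seq_len(nn)) {
      c0 <- 3 * (a - 1)
      B[1, c0 + 1] <- G[a, 1]
      B[2, c0 + 2] <- G[a, 2]
      B[3, c0 + 3] <- G[a, 3]
      B[4, c0 + 2] <- G[a, 3]; B[4, c0 + 3] <- G[a, 2]   # gamma_yz
      B[5, c0 + 1] <- G[a, 3]; B[5, c0 + 3] <- G[a, 1]   # gamma_xz
      B[6, c0 + 1] <- G[a, 2]; B[6, c0 + 2] <- G[a, 1]   # gamma_xy
    }
    B
  }
  if (nn == 4L) {
    B <- bmat(gL)
    return(V * t(B) %*% D %*% B)
  }
  a <- (5 + 3 * sqrt(5)) / 20; b <- (5 - sqrt(5)) / 20
  gp <- rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
  edges <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  K <- matrix(0, 30, 30)
  for (g in 1:4) {
    L <- gp[g, ]
    G <- matrix(0, 10, 3)
    G[1:4, ] <- (4 * L - 1) * gL
    for (k in 1:6)
      G[4 + k, ] <- 4 * (L[edges[k, 1]] * gL[edges[k, 2], ] +
                         L[edges[k, 2]] * gL[edges[k, 1], ])
    B <- bmat(G)
    K <- K + (V / 4) * t(B) %*% D %*% B
  }
  K
}

# small skull fixtures, memoised across tests within a run
.fixture_cache <- new.env(parent = emptyenv())
test_skull <- function(order = 1, lateral_gap = TRUE, resolution = 12) {
  key <- paste0("sk_", order, "_", lateral_gap, "_", resolution)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_skull(skull_params(
      resolution = resolution, element_order = order,
      lateral_gap = lateral_gap))
  .fixture_cache[[key]]
}

# the study-condition case matrix on quadratic fixtures (adult + isometric
# subadult), computed once and reused by the acceptance tests
acceptance_matrix <- function() {
  if (is.null(.fixture_cache$acc)) {
    adult <- make_skull(skull_params(resolution = 9))
    sub <- make_skull(skull_params(length = 90, width = 90, height = 27,
                                   shell_thickness = 4.5, resolution = 4.5))
    res <- suppressMessages(
      run_matrix(adult, sub, list(material = material(), pressure = 0.3,
                                  gape = gape_spec(6, 0))))
    .fixture_cache$acc <- list(adult = adult, sub = sub, results = res)
  }
  .fixture_cache$acc
}
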