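test_that("elasticity matrix matches the Lame-constant closed form", {
  D0 <- elasticity_matrix(material(1, 0))
  expect_equal(D0, diag(c(1, 1, 1, 0.5, 0.5, 0.5)), tolerance = 1e-15)
  D <- elasticity_matrix(material(6650, 0.35))
  expect_equal(D, t(D), tolerance = 1e-15)
  lam <- 6650 * 0.35 / ((1 + 0.35) * (1 - 0.7))
  mu <- 6650 / (2 * 1.35)
  Dref <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  Dref[1:3, 1:3] <- Dref[1:3, 1:3] + lam
  expect_equal(D, Dref, tolerance = 1e-12)
  expect_error(elasticity_matrix(material(1, 0.4999999)), "incompressible")
})

test_that("element stiffness is symmetric with exactly six rigid modes", {
  mat <- material(6650, 0.35)
  set.seed(3)
  for (order in 1:2) {
    coords4 <- rbind(c(0, 0, 0), c(1.2, 0.1, 0), c(0.2, 1, 0.1),
                     c(0.1, 0.2, 0.9))
    coords <- if (order == 1) coords4 else {
      edges <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
      rbind(coords4, (coords4[edges[, 1], ] + coords4[edges[, 2], ]) / 2)
    }
    K <- element_stiffness(coords, mat)
    expect_lt(max(abs(K - t(K))), 1e-12 * max(abs(K)))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_identical(sum(ev < 1e-8 * max(ev)), 6L)
    # rigid translations produce no force
    for (ax in 1:3) {
      u <- rep(0, 3 * nrow(coords)); u[seq(ax, length(u), by = 3)] <- 1
      expect_lt(max(abs(K %*% u)), 1e-9 * max(abs(K)))
    }
  }
  expect_error(element_stiffness(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                       c(1, 1, 0)), mat), "degenerate")
})

test_that("element stiffness matches the B-matrix oracle", {
  mat <- material(6650, 0.35)
  coords4 <- rbind(c(0, 0, 0), c(1.1, 0, 0.05), c(0, 0.9, 0.1),
                   c(0.2, 0.1, 1))
  expect_equal(element_stiffness(coords4, mat),
               oracle_element_K(coords4, mat), tolerance = 1e-10)
  edges <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  coords10 <- rbind(coords4,
                    (coords4[edges[, 1], ] + coords4[edges[, 2], ]) / 2)
  expect_equal(element_stiffness(coords10, mat),
               oracle_element_K(coords10, mat), tolerance = 1e-10)
})

test_that("assembly matches dense summation on small meshes", {
  mat <- material(100, 0.3)
  # one element: global equals element matrix
  tet <- single_tet()
  K1 <- as.matrix(assemble(tet, mat))
  expect_equal(K1, unname(element_stiffness(tet$nodes, mat)),
               tolerance = 1e-12)
  # multi-element mesh vs dense scatter oracle
  mesh <- make_patch_cube(1, 2, order = 1)  # 48 elements
  Ks <- as.matrix(assemble(mesh, mat))
  nd <- 3 * nrow(mesh$nodes)
  Kd <- matrix(0, nd, nd)
  for (e in seq_len(nrow(mesh$elems))) {
    en <- mesh$elems[e, ]
    Ke <- oracle_element_K(mesh$nodes[en, ], mat)
    dof <- as.integer(t(outer(3 * (en - 1), 1:3, `+`)))
    Kd[dof, dof] <- Kd[dof, dof] + Ke
  }
  expect_lt(max(abs(Ks - Kd)), 1e-10 * max(abs(Kd)))
  # two disconnected elements give a block structure
  two <- tet_mesh(rbind(single_tet()$nodes, single_tet()$nodes + 5),
                  rbind(1:4, 5:8))
  K2 <- as.matrix(assemble(two, mat))
  expect_true(all(K2[1:12, 13:24] == 0))
})

test_that("uniaxial patch test is exact for linear and quadratic elements", {
  mat <- material(6650, 0.35)
  p <- 2.5
  for (order in 1:2) {
    mesh <- make_patch_cube(1, 2, order = order)
    setup <- uniaxial_setup(mesh, p)
    sol <- solve_mesh(mesh, mat, setup$loads, setup$constraints)
    s <- sol$stress$stress_elem
    expect_lt(max(abs(s[, 1] - p)), 1e-9)
    expect_lt(max(abs(s[, 2:6])), 1e-9)
    expect_lt(sol$equilibrium_residual, 1e-8)
    # doubling the load doubles the displacements
    sol2 <- solve_mesh(mesh, mat, 2 * setup$loads, setup$constraints)
    expect_equal(sol2$u, 2 * sol$u, tolerance = 1e-10)
  }
})

test_that("zero load gives zero displacement and zero reactions", {
  mesh <- make_patch_cube(1, 2)
  cs <- constraint_set(mesh, list(list(patch = "xmin",
                                       axes = c("x", "y", "z"))))
  sol <- solve_mesh(mesh, material(), numeric(3 * nrow(mesh$nodes)), cs)
  expect_true(all(sol$u == 0))
  expect_true(all(sol$reactions == 0))
})

test_that("under-constrained systems report rigid-body modes", {
  mesh <- make_patch_cube(1, 1)
  n1 <- patch_nodes(mesh, "xmin")[1]
  expect_error(constraint_set(mesh, list(list(nodes = n1, axes = "x"))),
               "fewer than 6")
  # six dofs on collinear nodes still leave translation and spin free
  mesh2 <- make_patch_cube(1, 2)
  edge <- which(abs(mesh2$nodes[, 2]) < 1e-9 & abs(mesh2$nodes[, 3]) < 1e-9)
  cs <- constraint_set(mesh2, list(list(nodes = edge, axes = c("y", "z"))))
  K <- assemble(mesh2, material())
  f <- numeric(nrow(K)); f[1] <- 1
  expect_error(solve_static(K, f, cs))
})

test_that("stress recovery reproduces closed-form fields", {
  mat <- material(6650, 0.35)
  mu <- 6650 / (2 * 1.35)
  mesh <- make_patch_cube(1, 2, order = 2)
  # rigid motion (translation + small rotation) produces zero stress
  th <- 1e-4
  u_rigid <- cbind(0.3 - th * mesh$nodes[, 2], th * mesh$nodes[, 1] - 0.1,
                   mesh$nodes[, 3] * 0 + 0.2)
  st <- recover_stresses(mesh, mat, u_rigid)
  expect_lt(max(abs(st$stress_elem)), 1e-9 * 6650)
  # pure shear u_x = g*y: sigma_xy = 2 mu eps_xy = mu g
  g <- 1e-3
  u_shear <- cbind(g * mesh$nodes[, 2], 0 * mesh$nodes[, 1],
                   0 * mesh$nodes[, 1])
  st2 <- recover_stresses(mesh, mat, u_shear)
  expect_equal(st2$stress_elem[, 6], rep(mu * g, nrow(mesh$elems)),
               tolerance = 1e-9)
  expect_lt(max(abs(st2$stress_elem[, c(1:5)])), 1e-9)
  expect_equal(st2$vm_node, rep(sqrt(3) * mu * g, nrow(mesh$nodes)),
               tolerance = 1e-9)
})

test_that("Von Mises matches the principal-stress eigenvalue oracle", {
  expect_equal(von_mises(c(5, 5, 5, 0, 0, 0)), 0)
  expect_equal(von_mises(c(7, 0, 0, 0, 0, 0)), 7)
  set.seed(11)
  sig <- matrix(rnorm(6000, sd = 40), ncol = 6)
  vm <- von_mises(sig)
  vm_oracle <- apply(sig, 1, function(s) {
    S <- rbind(c(s[1], s[6], s[5]), c(s[6], s[2], s[4]),
               c(s[5], s[4], s[3]))
    pr <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    sqrt(0.5 * ((pr[1] - pr[2])^2 + (pr[2] - pr[3])^2 + (pr[3] - pr[1])^2))
  })
  expect_lt(max(abs(vm - vm_oracle) / pmax(vm_oracle, 1)), 1e-12)
  expect_true(all(vm >= 0))
})

test_that("Von Mises fields are invariant under rigid rotations", {
  mat <- material()
  cube <- make_patch_cube(1, 2, 1)
  tb <- apply_traction(cube, "xmax", c(1, 0.3, 0))
  loads <- loads_from_table(cube, tb)
  cs <- constraint_set(cube, list(list(patch = "xmin",
                                       axes = c("x", "y", "z"))))
  s0 <- solve_mesh(cube, mat, loads, cs)
  set.seed(1)
  for (k in 1:3) {
    R <- rotation_matrix(runif(3, 0, 2 * pi))
    rot <- cube; rot$nodes <- cube$nodes %*% t(R)
    lrot <- as.numeric(t(matrix(loads, ncol = 3, byrow = TRUE) %*% t(R)))
    csr <- constraint_set(rot, list(list(patch = "xmin",
                                         axes = c("x", "y", "z"))))
    s1 <- solve_mesh(rot, mat, lrot, csr)
    expect_lt(max(abs(s1$stress$vm_elem - s0$stress$vm_elem)),
              1e-9 * max(s0$stress$vm_elem))
  }
})

test_that("cantilever deflection converges to the Timoshenko closed form", {
  mat <- material(6650, 0.35)
  E <- 6650; nu <- 0.35; G <- E / (2 * (1 + nu))
  L <- 20; h <- 2; w <- 2; P <- 10
  I <- w * h^3 / 12; A <- w * h
  kap <- 10 * (1 + nu) / (12 + 11 * nu)
  delta <- P * L^3 / (3 * E * I) + P * L / (kap * G * A)
  tip_deflection <- function(nx, ny, nz, order) {
    m <- make_cantilever(L, w, h, nx, ny, nz, order)
    tb <- apply_traction(m, "tip", c(0, -P / (w * h), 0))
    cs <- constraint_set(m, list(list(patch = "fixed_end",
                                      axes = c("x", "y", "z"))))
    sol <- solve_mesh(m, mat, loads_from_table(m, tb), cs)
    -mean(sol$u[patch_nodes(m, "tip"), 2])
  }
  # linear elements: error decreases monotonically under refinement
  err4 <- vapply(list(c(5, 1, 1), c(10, 2, 2), c(20, 4, 4)), function(cf)
    abs(tip_deflection(cf[1], cf[2], cf[3], 1) - delta) / delta, numeric(1))
  expect_true(all(diff(err4) < 0))
  # quadratic elements: within 2% at 4 elements through the thickness
  err10 <- abs(tip_deflection(20, 4, 4, 2) - delta) / delta
  expect_lt(err10, 0.02)
})

test_that("bite force equals the applied load in a determinate toy", {
  mat <- material()
  mesh <- make_patch_cube(1, 1, order = 1)
  # press straight down on the top face; the bottom is the fixed support
  tb <- apply_traction(mesh, "ymax", c(0, -3, 0))
  cs <- constraint_set(mesh, list(list(patch = "ymin",
                                       axes = c("x", "y", "z"))))
  sol <- solve_mesh(mesh, mat, loads_from_table(mesh, tb), cs)
  bf <- bite_force(sol, patch_nodes(mesh, "ymin"))
  expect_equal(bf$force, c(0, 3, 0), tolerance = 1e-9)
  expect_equal(bf$magnitude, 3, tolerance = 1e-9)
  # reaction extraction requires full constraint
  expect_error(bite_force(sol, patch_nodes(mesh, "ymax")),
               "not fully constrained")
  expect_error(bite_force(sol, integer(0)), "empty")
})
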