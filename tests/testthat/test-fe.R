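test_that("material validation enforces physical bounds", {
  expect_error(material_props(-1, 0.2), "moduli")
  expect_error(material_props(1000, 0.5), "Poisson")
  expect_error(material_props(1000, 0), "Poisson")
  # 0.49 sutures are legal (strictly below incompressibility)
  expect_s3_class(material_props(1000, 0.3, 16, 0.49), "material_props")
})

test_that("assembled stiffness is symmetric with the rigid-body null space", {
  mesh <- unit_cube_mesh() # no fixed nodes
  sys <- assemble_system(mesh, material_props(1, 1e-9), enhance = FALSE)
  K <- as.matrix(sys$K)
  expect_lt(max(abs(K - t(K))), 1e-9 * max(abs(K)))
  # 24 DOF - 6 rigid body modes = rank 18
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev < 1e-8 * max(ev)), 6)
  expect_equal(qr(K, tol = 1e-10)$rank, 18)
  # enhanced (incompatible-modes) element keeps the same null space
  Ke <- as.matrix(assemble_system(mesh, material_props(1, 1e-9))$K)
  expect_lt(max(abs(Ke - t(Ke))), 1e-9 * max(abs(Ke)))
  expect_equal(qr(Ke, tol = 1e-10)$rank, 18)
})

test_that("single-element uniaxial patch test matches Hooke's law exactly", {
  E <- 7.3
  # unit cube, back face (x=0) fixed in x, pulled with unit traction on x=1
  nodes <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
  )
  mesh <- hex_mesh(nodes, matrix(1:8, 1), "parietal_bone",
                   node_sets = list(base_fixed = integer(0)))
  for (enhance in c(FALSE, TRUE)) {
    sys <- assemble_system(mesh, material_props(E, nu_bone = 1e-9), enhance)
    K <- as.matrix(sys$K)
    # constrain: x on back face, y on y=0 face, z on z=0 face (nu = 0)
    fixed <- c(3 * c(1, 4, 5, 8) - 2, 3 * c(1, 2, 5, 6) - 1, 3 * c(1, 2, 3, 4))
    f <- numeric(24)
    f[3 * c(2, 3, 6, 7) - 2] <- 0.25 # unit traction, consistent corner loads
    free <- setdiff(1:24, fixed)
    u <- numeric(24)
    u[free] <- solve(K[free, free], f[free])
    ux <- u[3 * c(2, 3, 6, 7) - 2]
    expect_equal(ux, rep(1 / E, 4), tolerance = 1e-8)
  }
})

test_that("sparse solve matches a dense reference on a small strip", {
  mesh <- bar_mesh(2)
  sys <- assemble_system(mesh, material_props(100, 0.3))
  f <- matrix(0, sys$n_nodes, 3)
  f[9:12, 3] <- 0.25 # tip shear load
  u <- solve_system(sys, f)
  # dense brute-force oracle on the same constrained system
  K <- as.matrix(sys$K)
  fv <- as.numeric(t(f))
  ud <- numeric(length(fv))
  ud[sys$free_dofs] <- solve(K[sys$free_dofs, sys$free_dofs],
                             fv[sys$free_dofs])
  expect_equal(as.numeric(t(u)), ud, tolerance = 1e-10)
  expect_lt(attr(u, "residual"), 1e-8)
})

test_that("zero force gives zero displacement and forces scale linearly", {
  sys <- coarse_cut()$system
  f0 <- matrix(0, sys$n_nodes, 3)
  expect_equal(max(abs(solve_system(sys, f0))), 0)
  f <- craniospring:::spring_load(sys, coarse_cut()$anchors, c(2, 2))
  u1 <- solve_system(sys, f)
  u2 <- solve_system(sys, 2 * f)
  expect_equal(2 * u1, u2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("reactions balance applied loads", {
  sys <- coarse_cut()$system
  f <- craniospring:::spring_load(sys, coarse_cut()$anchors, c(3, 3))
  u <- solve_system(sys, f)
  r <- reaction_forces(sys, u)
  resultant <- colSums(f) + colSums(r)
  expect_lt(max(abs(resultant)) / max(abs(f)), 1e-6)
})

test_that("post-op metrics follow the deformed geometry", {
  mesh <- coarse_mesh()
  n <- nrow(mesh$nodes)
  u0 <- matrix(0, n, 3)
  pm <- compute_postop_metrics(mesh, u0)
  expect_equal(pm$post_op_ci, mesh_metrics(mesh)$ci)
  expect_equal(pm$max_displacement, 0)
  # uniform translation leaves extents unchanged
  ut <- matrix(rep(c(3, -2, 1), each = n), n, 3)
  pt <- compute_postop_metrics(mesh, ut)
  expect_equal(pt$post_op_width, pm$post_op_width)
  expect_equal(pt$post_op_length, pm$post_op_length)
  # pure symmetric widening: width grows by exactly 2 delta
  delta <- 0.7
  uw <- matrix(0, n, 3)
  uw[, 2] <- delta * sign(mesh$nodes[, 2])
  pw <- compute_postop_metrics(mesh, uw)
  expect_equal(pw$post_op_width, pm$post_op_width + 2 * delta)
})

test_that("an under-constrained model is reported as singular", {
  mesh <- unit_cube_mesh(fixed = integer(0))
  sys <- assemble_system(mesh, material_props(10, 0.3))
  f <- matrix(0, 8, 3)
  f[5:8, 3] <- 1
  expect_error(solve_system(sys, f), "singular|under-constrained")
})

test_that("degenerate element geometry is rejected with the element named", {
  nodes <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0) # zero-height element
  )
  mesh <- hex_mesh(nodes, matrix(1:8, 1), "parietal_bone")
  expect_error(assemble_system(mesh, material_props(10, 0.3)),
               "element 1")
})
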