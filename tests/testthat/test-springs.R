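test_that("spring force law hits its defining points and is monotone", {
  ch <- spring_characteristic(1.2, F0 = 8, opening_max = 12)
  expect_equal(spring_force(ch, 0), 8)
  expect_equal(spring_force(ch, 12), 0)
  expect_equal(spring_force(ch, 6), 4) # linear law midpoint
  expect_equal(spring_force(ch, 20), 0) # beyond max
  o <- seq(0, 15, by = 0.1)
  expect_true(all(diff(spring_force(ch, o)) <= 1e-12))
  expect_error(spring_force(ch, -1), ">= 0")
})

test_that("catalog covers the three wire diameters with stiffness-ordered F0", {
  cat <- spring_catalog()
  expect_equal(cat$d_wire, c(1.0, 1.2, 1.4))
  expect_true(all(diff(cat$F0) > 0)) # F0 grows with wire diameter (~d^4)
  expect_equal(cat$F0[3] / cat$F0[2], (1.4 / 1.2)^4, tolerance = 1e-9)
  expect_error(spring_characteristic(9.9), "no catalogued")
})

test_that("tabulated force laws interpolate and must be non-increasing", {
  pts <- data.frame(opening = c(0, 5, 10), force = c(6, 3, 0))
  ch <- spring_characteristic(1.2, points = pts)
  expect_equal(spring_force(ch, 2.5), 4.5)
  expect_equal(spring_force(ch, 10), 0)
  expect_error(
    spring_characteristic(1.2, points = data.frame(opening = c(0, 5),
                                                   force = c(1, 2))),
    "non-increasing"
  )
})

test_that("rigid-limit equilibrium keeps openings near zero and forces near F0", {
  cut <- coarse_cut()$mesh
  anc <- coarse_cut()$anchors
  stiff <- assemble_system(cut, material_props(2e6, 0.22))
  ch <- spring_characteristic(1.2)
  eq <- equilibrate(stiff, anc, ch)
  expect_true(eq$converged)
  expect_lt(max(eq$springs$opening), 0.05)
  expect_gt(min(eq$springs$force), 0.995 * ch$F0)
})

test_that("converged state satisfies the spring law self-consistently", {
  eq <- equilibrate(coarse_cut()$system, coarse_cut()$anchors,
                    spring_characteristic(1.2), tol = 1e-5, max_iter = 200)
  expect_true(eq$converged)
  ch <- spring_characteristic(1.2)
  expect_equal(eq$springs$force, spring_force(ch, eq$springs$opening),
               tolerance = 1e-3)
  expect_lt(sum(eq$springs$force), nrow(eq$springs) * ch$F0 + 1e-9)
})

test_that("equilibrium matches the closed-form series-stiffness solution", {
  # the structure is linear, so opening = compliance * force; with the
  # linear spring law F = F0 (1 - o/omax) the converged force has the
  # closed form F* = F0 / (1 + c F0 / omax). Measure c independently with
  # a unit-force solve, then check equilibrate() against the formula.
  cutinfo <- coarse_cut()
  sys <- cutinfo$system
  anc <- cutinfo$anchors[1, ] # single soft spring
  f_unit <- craniospring:::spring_load(sys, anc, 1)
  u_unit <- solve_system(sys, f_unit)
  c_struct <- craniospring:::spring_openings(sys, anc, u_unit)
  ch <- spring_characteristic(1.2, F0 = 2, opening_max = 30)
  eq <- equilibrate(sys, anc, ch, tol = 1e-6, max_iter = 200)
  f_closed <- ch$F0 / (1 + c_struct * ch$F0 / ch$opening_max)
  expect_equal(eq$springs$force, f_closed, tolerance = 1e-3)
})

test_that("symmetric springs on a fully symmetric mesh converge to equal forces", {
  # equal anterior/posterior curvature makes the skull x-mirror symmetric,
  # so the two springs see identical structures
  p <- calvarial_params(160, 114, 99, 2, resolution = 9,
                        element_order = "hex8",
                        curvature_anterior = 2, curvature_posterior = 2)
  m <- build_calvarium(p)
  cut <- apply_osteotomy(m, validation_plan())
  # uniform bone everywhere: the anterior fontanelle patch would otherwise
  # break the front/back symmetry
  cut$suture_fraction[] <- 0
  anc <- locate_spring_anchors(cut, validation_plan())
  sys <- assemble_system(cut, soft_materials())
  eq <- equilibrate(sys, anc, spring_characteristic(1.2), tol = 1e-6,
                    max_iter = 200)
  expect_equal(eq$springs$force[1], eq$springs$force[2], tolerance = 1e-3)
  expect_equal(eq$springs$opening[1], eq$springs$opening[2], tolerance = 1e-3)
})

test_that("converged displacement grows with spring preload", {
  sys <- coarse_cut()$system
  anc <- coarse_cut()$anchors
  disp <- vapply(c(2, 4, 6), function(f0) {
    eq <- equilibrate(sys, anc,
                      spring_characteristic(1.2, F0 = f0, opening_max = 10))
    compute_postop_metrics(coarse_cut()$mesh, eq$u)$max_displacement
  }, 0)
  expect_true(all(diff(disp) > 0))
})

test_that("non-convergence raises a condition carrying the iteration history", {
  sys <- coarse_cut()$system
  anc <- coarse_cut()$anchors
  cnd <- tryCatch(
    equilibrate(sys, anc, spring_characteristic(1.2), max_iter = 1),
    craniospring_no_convergence = function(c) c
  )
  expect_s3_class(cnd, "craniospring_no_convergence")
  expect_true(is.data.frame(cnd$history))
  expect_equal(max(cnd$history$iter), 1)
})
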