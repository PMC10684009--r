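# Shared fixtures: coarse meshes are expensive enough to build once.

coarse_params <- function(...) {
  calvarial_params(160, 114, 99, t_skull = 2, resolution = 9,
                   element_order = "hex8", ...)
}

validation_plan <- function(...) {
  surgical_plan(w_ost = 20, l_ost = 0, n_spring = 2, x_spring = 34,
                d_wire = 1.2, ...)
}

soft_materials <- function() material_props(41, 0.22)

fixture_env <- new.env(parent = emptyenv())

# memoised coarse validation-geometry mesh (uncut)
coarse_mesh <- function() {
  if (is.null(fixture_env$mesh)) {
    fixture_env$mesh <- build_calvarium(coarse_params())
  }
  fixture_env$mesh
}

# memoised cut mesh + anchors + assembled soft-bone system
coarse_cut <- function() {
  if (is.null(fixture_env$cut)) {
    cut <- apply_osteotomy(coarse_mesh(), validation_plan())
    fixture_env$cut <- list(
      mesh = cut,
      anchors = locate_spring_anchors(cut, validation_plan()),
      system = assemble_system(cut, soft_materials())
    )
  }
  fixture_env$cut
}

# single unit-cube element mesh (8-node), base face optionally fixed
unit_cube_mesh <- function(fixed = integer(0)) {
  nodes <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
  )
  hex_mesh(nodes, matrix(1:8, 1), "parietal_bone",
           node_sets = list(base_fixed = fixed))
}

# small bar of nx x 1 x 1 unit-cube elements along x, face x=0 fixed
bar_mesh <- function(nx = 2) {
  xs <- 0:nx
  nodes <- do.call(rbind, lapply(xs, function(x) {
    cbind(x, c(0, 1, 1, 0), c(0, 0, 1, 1))
  }))
  elems <- t(vapply(seq_len(nx), function(i) {
    a <- (i - 1) * 4
    # VTK ordering: bottom face (z=0) ccw viewed from above, then top face
    c(a + 1, a + 5, a + 6, a + 2, a + 4, a + 8, a + 7, a + 3)
  }, numeric(8)))
  hex_mesh(nodes, elems, "parietal_bone",
           node_sets = list(base_fixed = 1:4))
}
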