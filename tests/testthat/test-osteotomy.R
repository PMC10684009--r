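test_that("surgical plan validation enforces the clinical constraints", {
  expect_error(surgical_plan(n_spring = 4), "2 or 3")
  expect_error(surgical_plan(w_ost = 0), "w_ost")
  expect_error(surgical_plan(l_ost = -1), "l_ost")
  expect_error(surgical_plan(l_ost = 30, x_spring = 20), "within the cut")
})

test_that("suture-to-suture cut on the validation geometry is about 97 mm", {
  cut <- coarse_cut()$mesh
  expect_gt(cut$removed$count, 0)
  expect_equal(cut$removed$cut_length, 96, tolerance = 0.05)
  # element conservation: before = after + removed
  expect_equal(cut$removed$total_before,
               nrow(cut$elems) + cut$removed$count)
})

test_that("a cut consuming the whole inter-suture span is rejected", {
  m <- coarse_mesh()
  half_span <- 0.3 * 160
  expect_error(
    apply_osteotomy(m, surgical_plan(w_ost = 20, l_ost = half_span,
                                     x_spring = half_span)),
    "degenerate"
  )
})

test_that("doubling the osteotomy width doubles the physical gap", {
  # the cut boundary snaps to the exact plan width, so the edge node sets
  # sit at +/- w_ost/2 for any width; on a mesh fine enough to resolve both
  # strips the removed-element count roughly doubles too
  m6 <- build_calvarium(calvarial_params(160, 114, 99, 2, resolution = 6,
                                         element_order = "hex8"))
  c10 <- apply_osteotomy(m6, surgical_plan(w_ost = 10))
  c20 <- apply_osteotomy(m6, surgical_plan(w_ost = 20))
  gap <- function(cut) {
    # lateral faces are projected onto the exact planes; staircase corner
    # nodes at ring transitions stay off-plane, so the representative gap
    # is the median edge-node separation
    el <- cut$node_sets$osteotomy_edge_left
    er <- cut$node_sets$osteotomy_edge_right
    stats::median(cut$nodes[er, "y"]) - stats::median(cut$nodes[el, "y"])
  }
  expect_equal(gap(c10), 10, tolerance = 1e-9)
  expect_equal(gap(c20), 20, tolerance = 1e-9)
  expect_gt(c20$removed$count / c10$removed$count, 1.4)
  expect_lt(c20$removed$count / c10$removed$count, 3)
})

test_that("cut edge node sets are disjoint, equal-sized and on the cut planes", {
  cut <- coarse_cut()$mesh
  left <- cut$node_sets$osteotomy_edge_left
  right <- cut$node_sets$osteotomy_edge_right
  expect_gt(length(left), 0)
  expect_equal(length(left), length(right))
  expect_length(intersect(left, right), 0)
  expect_true(all(cut$nodes[left, "y"] < 0))
  expect_true(all(cut$nodes[right, "y"] > 0))
})

test_that("spring anchors sit at the planned distances from the sutures", {
  plan <- validation_plan()
  anc <- coarse_cut()$anchors
  expect_equal(nrow(anc), 2L)
  # outer springs 34 mm from the sutures at +/- 48 mm
  expect_equal(sort(anc$x_target), c(-14, 14))
  expect_true(all(abs(anc$x_actual - anc$x_target) <= 9))
  # per-side weights are convex combinations
  for (k in seq_len(nrow(anc))) {
    expect_equal(sum(anc$left_weights[[k]]), 1, tolerance = 1e-9)
    expect_equal(sum(anc$right_weights[[k]]), 1, tolerance = 1e-9)
  }
})

test_that("three springs put the middle spring at the cut midpoint", {
  m <- coarse_mesh()
  plan <- surgical_plan(w_ost = 20, l_ost = 0, n_spring = 3, x_spring = 34)
  cut <- apply_osteotomy(m, plan)
  anc <- locate_spring_anchors(cut, plan)
  expect_equal(nrow(anc), 3L)
  expect_equal(sort(anc$x_target), c(-14, 0, 14))
})

test_that("anchor pairs are mirror-symmetric about the midsagittal plane", {
  anc <- coarse_cut()$anchors
  cut <- coarse_cut()$mesh
  for (k in seq_len(nrow(anc))) {
    pl <- colSums(cut$nodes[anc$left_nodes[[k]], , drop = FALSE] *
                    anc$left_weights[[k]])
    pr <- colSums(cut$nodes[anc$right_nodes[[k]], , drop = FALSE] *
                    anc$right_weights[[k]])
    expect_equal(pl[["y"]], -pr[["y"]], tolerance = 1e-6)
    expect_equal(pl[["x"]], pr[["x"]], tolerance = 1e-6)
    expect_equal(pl[["z"]], pr[["z"]], tolerance = 1e-6)
  }
})

test_that("springs outside the cut are rejected", {
  m <- build_calvarium(calvarial_params(160, 114, 99, 2, resolution = 9,
                                        element_order = "hex8",
                                        coronal_offset_frac = 0.15,
                                        lambdoid_offset_frac = 0.15))
  plan <- surgical_plan(w_ost = 20, l_ost = 0, n_spring = 2, x_spring = 40)
  cut <- apply_osteotomy(m, plan)
  expect_error(locate_spring_anchors(cut, plan), "outside|cross")
})
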