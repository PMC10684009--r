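#' Run one spring-assisted cranioplasty simulation
#'
#' Convenience pipeline: build the calvarial mesh, apply the osteotomy,
#' locate the spring anchors, assemble the elastic system, equilibrate the
#' springs against the skull, and post-process the deformed shape into
#' post-operative metrics.
#'
#' @param params A [calvarial_params()] (or a list coercible to one).
#' @param plan A [surgical_plan()].
#' @param materials A [material_props()].
#' @param characteristic Spring characteristic; defaults to the catalog
#'   entry for `plan$d_wire`.
#' @param tol,max_iter,relax Passed to [equilibrate()].
#' @return A `sac_simulation`: the cut mesh, displacement field, spring
#'   states and a one-row `metrics` tibble (pre/post-op CI, extents, max
#'   displacement, iteration count).
#' @export
simulate_case <- function(params, plan, materials,
                          characteristic = NULL,
                          tol = 1e-4, max_iter = 50, relax = 0.5) {
  if (!inherits(params, "calvarial_params")) {
    params <- do.call(calvarial_params, as.list(params))
  }
  if (!inherits(plan, "surgical_plan")) plan <- do.call(surgical_plan, as.list(plan))
  if (is.null(characteristic)) {
    characteristic <- spring_characteristic(plan$d_wire)
  }
  mesh <- build_calvarium(params)
  pre <- mesh_metrics(mesh)
  cut <- apply_osteotomy(mesh, plan)
  anchors <- locate_spring_anchors(cut, plan)
  system <- assemble_system(cut, materials)
  eq <- equilibrate(system, anchors, characteristic,
                    tol = tol, max_iter = max_iter, relax = relax)
  post <- compute_postop_metrics(cut, eq$u)
  metrics <- dplyr::bind_cols(
    tibble::tibble(pre_op_ci = pre$ci),
    post,
    tibble::tibble(
      delta_ci_pp = 100 * (post$post_op_ci - pre$ci),
      iterations = eq$iterations
    )
  )
  structure(
    list(
      params = params, plan = plan, materials = materials,
      characteristic = characteristic,
      mesh = cut, anchors = anchors, equilibrium = eq,
      u = eq$u, metrics = metrics,
      n_elements = nrow(cut$elems), n_nodes = nrow(cut$nodes)
    ),
    class = "sac_simulation"
  )
}

#' @export
print.sac_simulation <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<sac_simulation> %d %s elements (%d nodes)\n",
    x$n_elements, x$mesh$element_order, x$n_nodes
  ))
  cat(sprintf(
    "  pre-op CI %.3f -> post-op CI %.3f (+%.2f pp), max displacement %.2f mm\n",
    m$pre_op_ci, m$post_op_ci, m$delta_ci_pp, m$max_displacement
  ))
  invisible(x)
}
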