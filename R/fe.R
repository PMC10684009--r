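#' Material properties for bone and suture regions
#'
#' Small-strain isotropic linear elasticity, with one (E, nu) pair for the
#' bony regions (parietal, frontal, occipital) and one for the compliant
#' regions (coronal/lambdoid sutures, anterior fontanelle). The suture
#' default (16 MPa, 0.49) reflects unfused fibrous tissue, near
#' incompressibility included.
#'
#' @param E_bone Elastic modulus of bone, MPa (> 0).
#' @param nu_bone Poisson's ratio of bone, in (0, 0.5).
#' @param E_suture Elastic modulus of sutures/fontanelle, MPa.
#' @param nu_suture Poisson's ratio of sutures/fontanelle, in (0, 0.5);
#'   0.49 is allowed (strictly below the incompressible limit).
#' @return A `material_props` object.
#' @export
material_props <- function(E_bone, nu_bone, E_suture = 16, nu_suture = 0.49) {
  for (nm in c("E_bone", "nu_bone", "E_suture", "nu_suture")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  if (E_bone <= 0 || E_suture <= 0) abort("elastic moduli must be > 0.")
  if (nu_bone <= 0 || nu_bone >= 0.5 || nu_suture <= 0 || nu_suture >= 0.5) {
    abort("Poisson's ratios must lie strictly in (0, 0.5).")
  }
  structure(
    list(E_bone = E_bone, nu_bone = nu_bone,
         E_suture = E_suture, nu_suture = nu_suture),
    class = "material_props"
  )
}

#' Assemble the sparse linear-elastic stiffness system
#'
#' Element stiffness matrices use full Gauss quadrature (2x2x2 for 8-node,
#' 3x3x3 for 20-node hexahedra); the per-element region label selects the
#' (E, nu) pair. The `base_fixed` node set supplies the homogeneous
#' Dirichlet constraints.
#'
#' For 8-node bricks the element is enhanced with the classical incompatible
#' bending modes (nine internal DOFs, centroid-Jacobian corrected, statically
#' condensed per element), the same cure commercial linear bricks apply:
#' without it a one-element-thick trilinear shell locks in shear and is far
#' too stiff in bending. Set `enhance = FALSE` for the plain trilinear
#' element (useful in verification studies).
#'
#' @param mesh A `calvarial_mesh` (any labelled hex mesh from [hex_mesh()]
#'   works, e.g. fixture meshes in verification tests).
#' @param materials A [material_props()] object.
#' @param enhance Use incompatible bending modes for 8-node bricks
#'   (default TRUE; ignored for 20-node elements).
#' @return An `fe_system`: the symmetric stiffness matrix `K`
#'   (3 n_nodes x 3 n_nodes, dgCMatrix), fixed/free DOF bookkeeping and a
#'   cached Cholesky factorisation (computed lazily by [solve_system()]).
#' @export
assemble_system <- function(mesh, materials, enhance = TRUE) {
  stopifnot(inherits(mesh, "calvarial_mesh"))
  if (!inherits(materials, "material_props")) {
    materials <- do.call(material_props, as.list(materials))
  }
  # suture/fontanelle compliance: where the mesh carries per-element overlap
  # fractions (parametric calvaria), blend bone and suture properties by the
  # series rule of mixtures so the compliant band's width is the anatomical
  # one, not one element. Fixture meshes without fractions use the label.
  is_suture <- as.character(mesh$label) %in% suture_labels()
  f <- mesh$suture_fraction
  if (is.null(f)) f <- as.numeric(is_suture)
  Evec <- 1 / (f / materials$E_suture + (1 - f) / materials$E_bone)
  nuvec <- f * materials$nu_suture + (1 - f) * materials$nu_bone

  trip <- .hex_assemble(mesh$nodes, mesh$elems, Evec, nuvec, enhance)
  if (any(trip$min_detJ <= 0)) {
    bad <- which(trip$min_detJ <= 0)[1]
    abort(sprintf(
      "element %d has a non-positive Jacobian (min detJ = %.3g); the mesh is degenerate.",
      bad, trip$min_detJ[bad]
    ))
  }
  n_dof <- 3L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(
    i = trip$i, j = trip$j, x = trip$x, dims = c(n_dof, n_dof)
  )

  fixed_nodes <- mesh$node_sets$base_fixed
  fixed_dofs <- if (length(fixed_nodes)) {
    as.integer(rbind(3L * fixed_nodes - 2L, 3L * fixed_nodes - 1L,
                     3L * fixed_nodes))
  } else {
    integer(0)
  }
  structure(
    list(
      K = K,
      mesh = mesh,
      materials = materials,
      n_nodes = nrow(mesh$nodes),
      fixed_dofs = fixed_dofs,
      free_dofs = setdiff(seq_len(n_dof), fixed_dofs),
      min_detJ = min(trip$min_detJ),
      cache = new.env(parent = emptyenv())
    ),
    class = "fe_system"
  )
}

#' @export
print.fe_system <- function(x, ...) {
  cat(sprintf(
    "<fe_system> %d nodes (%d DOF, %d fixed), E_bone = %g MPa, E_suture = %g MPa\n",
    x$n_nodes, 3L * x$n_nodes, length(x$fixed_dofs),
    x$materials$E_bone, x$materials$E_suture
  ))
  invisible(x)
}

fe_factor <- function(system) {
  if (is.null(system$cache$chol)) {
    Kff <- system$K[system$free_dofs, system$free_dofs, drop = FALSE]
    system$cache$Kff <- Kff
    system$cache$chol <- tryCatch(
      Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE),
      error = function(e) abort(paste0(
        "constrained stiffness system is singular (under-constrained model): ",
        conditionMessage(e)
      ))
    )
  }
  system$cache$chol
}

#' Solve the constrained equilibrium for nodal forces
#'
#' Direct sparse Cholesky factorisation of the free-DOF block (factor cached
#' on the system, so repeated solves with new load vectors — as in the
#' spring fixed-point iteration — only back-substitute). The relative
#' residual on the free DOFs is checked against 1e-8.
#'
#' @param system An [assemble_system()] result.
#' @param forces Numeric n_nodes x 3 matrix of nodal forces, N. Zero rows
#'   for unloaded nodes.
#' @return n_nodes x 3 displacement matrix (mm), zero at fixed nodes, with
#'   attribute `residual` (relative equilibrium residual).
#' @export
solve_system <- function(system, forces) {
  stopifnot(inherits(system, "fe_system"))
  forces <- as.matrix(forces)
  if (!all(dim(forces) == c(system$n_nodes, 3L))) {
    abort("`forces` must be an n_nodes x 3 matrix.")
  }
  if (any(!is.finite(forces))) abort("forces must be finite.")
  f <- as.numeric(t(forces)) # dof order x1 y1 z1 x2 ...
  ff <- f[system$free_dofs]
  u <- numeric(3L * system$n_nodes)
  if (any(ff != 0)) {
    ch <- fe_factor(system)
    uf <- tryCatch(
      as.numeric(Matrix::solve(ch, ff)),
      error = function(e) abort(paste0(
        "constrained stiffness system is singular (under-constrained model): ",
        conditionMessage(e)
      ))
    )
    if (any(!is.finite(uf))) {
      abort("constrained stiffness system is singular (under-constrained model).")
    }
    u[system$free_dofs] <- uf
    res <- sqrt(sum((as.numeric(system$cache$Kff %*% uf) - ff)^2)) /
      sqrt(sum(ff^2))
    if (res > 1e-8) {
      warn(sprintf("equilibrium residual %.2e exceeds 1e-8.", res))
    }
  } else {
    res <- 0
  }
  out <- matrix(u, ncol = 3L, byrow = TRUE,
                dimnames = list(NULL, c("ux", "uy", "uz")))
  attr(out, "residual") <- res
  out
}

#' Reaction forces at the fixed DOFs
#'
#' @param system An `fe_system`.
#' @param u Displacement matrix from [solve_system()].
#' @return n_nodes x 3 matrix of reaction forces (non-zero only at fixed
#'   nodes).
#' @export
reaction_forces <- function(system, u) {
  f <- as.numeric(system$K %*% as.numeric(t(u)))
  r <- numeric(length(f))
  r[system$fixed_dofs] <- f[system$fixed_dofs]
  matrix(r, ncol = 3L, byrow = TRUE,
         dimnames = list(NULL, c("rx", "ry", "rz")))
}

#' Post-operative skull metrics from a displacement field
#'
#' Deformed coordinates are `nodes + u`; post-operative length and width are
#' the axis-aligned extents (max - min, the caliper definition behind the
#' cephalic index) of the deformed node cloud along x and y.
#'
#' @param mesh The (cut) mesh the displacements belong to.
#' @param u n_nodes x 3 displacement matrix, mm.
#' @return One-row tibble: `post_op_length`, `post_op_width`, `post_op_ci`,
#'   `max_displacement` (all mm except the CI ratio).
#' @export
compute_postop_metrics <- function(mesh, u) {
  stopifnot(inherits(mesh, "calvarial_mesh"))
  u <- as.matrix(u)
  def <- mesh$nodes + u
  len <- max(def[, 1]) - min(def[, 1])
  wid <- max(def[, 2]) - min(def[, 2])
  tibble::tibble(
    post_op_length = len,
    post_op_width = wid,
    post_op_ci = compute_cephalic_index(wid, len),
    max_displacement = sqrt(max(rowSums(u^2)))
  )
}

#' Mesh sensitivity study
#'
#' Re-runs one spring-assisted simulation across a ladder of resolutions and
#' element orders, reporting element/node counts, maximal displacement and
#' post-operative CI per level, plus the coarsest level whose maximal
#' displacement is within `band` of the finest (per element order).
#'
#' @param params A [calvarial_params()]; its `resolution`/`element_order`
#'   are overridden level by level.
#' @param plan A [surgical_plan()].
#' @param materials A [material_props()]; defaults to the validation-case
#'   bone (E = 41 MPa, nu = 0.22) with standard sutures.
#' @param characteristic Spring characteristic, see [spring_characteristic()].
#' @param levels Numeric vector of >= 3 resolutions, mm (any order; sorted
#'   coarse to fine).
#' @param orders Element orders to test.
#' @param band Relative convergence band on max displacement (default 2%).
#' @return A `mesh_sensitivity` tibble; `attr(, "converged")` names the
#'   coarsest converged resolution per order.
#' @export
mesh_sensitivity <- function(params, plan,
                             materials = material_props(41, 0.22),
                             characteristic = NULL,
                             levels = c(12, 9, 6, 4.5),
                             orders = c("hex8", "hex20"),
                             band = 0.02) {
  if (length(levels) < 3) abort("supply at least 3 resolution levels.")
  levels <- sort(unique(levels), decreasing = TRUE)
  if (is.null(characteristic)) {
    characteristic <- spring_characteristic(plan$d_wire)
  }
  grid <- tidyr::expand_grid(order = orders, resolution = levels)
  rows <- purrr::pmap(grid, function(order, resolution) {
    p <- params
    p$resolution <- resolution
    p$element_order <- order
    sim <- simulate_case(p, plan, materials, characteristic)
    dplyr::bind_cols(
      tibble::tibble(element_order = order, resolution = resolution,
                     n_elements = sim$n_elements, n_nodes = sim$n_nodes),
      sim$metrics[, c("max_displacement", "post_op_ci")]
    )
  })
  out <- dplyr::bind_rows(rows)
  converged <- vapply(unique(out$element_order), function(ord) {
    sub <- out[out$element_order == ord, ]
    finest <- sub$max_displacement[which.min(sub$resolution)]
    ok <- abs(sub$max_displacement - finest) / finest <= band
    max(sub$resolution[ok])
  }, 0)
  names(converged) <- unique(out$element_order)
  attr(out, "converged") <- converged
  class(out) <- c("mesh_sensitivity", class(out))
  out
}

#' @rdname mesh_sensitivity
#' @param object,x A `mesh_sensitivity` table.
#' @param ... Ignored.
#' @export
autoplot.mesh_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$n_elements, y = .data$max_displacement,
    colour = .data$element_order
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "elements", y = "max displacement [mm]", colour = "element order",
      title = "Mesh sensitivity of the spring-assisted simulation"
    )
}
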