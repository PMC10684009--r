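#' Default spring catalog
#'
#' Three compressed-spring characteristics, one per wire diameter. Each is a
#' linear force-versus-opening law: force `F0` at zero opening, decaying to
#' zero at `opening_max`. Published descriptions of these implants report
#' the wire diameters but not the force magnitudes, so the `F0` defaults are
#' calibrated configuration: the 1.2 mm value is set once so that the
#' reference validation scenario (160/114/99 mm skull, 2 mm thick, 41 MPa
#' bone, suture-to-suture 20 mm osteotomy, two springs at 34 mm) lands at
#' the expected immediate post-operative cephalic index, and the other two
#' scale with the torsional wire stiffness, i.e. as `d_wire^4`.
#'
#' @return Tibble with columns `d_wire` (mm), `F0` (N), `opening_max` (mm).
#' @export
spring_catalog <- function() {
  f0_12 <- 6.711 # calibrated, see the methods vignette
  tibble::tibble(
    d_wire = c(1.0, 1.2, 1.4),
    F0 = f0_12 * (c(1.0, 1.2, 1.4) / 1.2)^4,
    opening_max = 10
  )
}

#' Spring force characteristic
#'
#' A monotone non-increasing mapping from spring opening (the increase in
#' distance between the two anchor columns, mm) to axial force (N). The
#' default is the linear law from [spring_catalog()] for the requested wire
#' diameter; custom `F0`/`opening_max` or a tabulated `points` data frame
#' (columns `opening`, `force`, interpolated piecewise linearly) override it.
#'
#' @param d_wire Wire diameter, mm; matched against the catalog.
#' @param F0 Force at zero opening, N (> 0).
#' @param opening_max Opening at which the force reaches zero, mm (> 0).
#' @param points Optional data frame of tabulated (opening, force) pairs.
#' @return A `spring_characteristic` object.
#' @export
spring_characteristic <- function(d_wire = 1.2, F0 = NULL, opening_max = NULL,
                                  points = NULL) {
  cat_row <- spring_catalog()[match(d_wire, spring_catalog()$d_wire), ]
  if (is.null(F0)) {
    if (is.na(cat_row$F0) && is.null(points)) {
      abort(sprintf("no catalogued spring characteristic for d_wire = %g mm.",
                    d_wire))
    }
    F0 <- cat_row$F0
  }
  if (is.null(opening_max)) opening_max <- cat_row$opening_max
  if (is.null(points)) {
    if (!is.finite(F0) || F0 <= 0) abort("`F0` must be > 0.")
    if (!is.finite(opening_max) || opening_max <= 0) {
      abort("`opening_max` must be > 0.")
    }
  } else {
    points <- as.data.frame(points)
    if (!all(c("opening", "force") %in% names(points))) {
      abort("`points` needs columns `opening` and `force`.")
    }
    points <- points[order(points$opening), ]
    if (any(diff(points$force) > 1e-9)) {
      abort("tabulated spring law must be non-increasing in opening.")
    }
    if (any(points$opening < 0) || any(points$force < 0)) {
      abort("tabulated openings and forces must be non-negative.")
    }
    F0 <- points$force[1]
    opening_max <- max(points$opening)
  }
  structure(
    list(d_wire = d_wire, F0 = F0, opening_max = opening_max,
         points = points),
    class = "spring_characteristic"
  )
}

#' @export
print.spring_characteristic <- function(x, ...) {
  cat(sprintf(
    "<spring_characteristic> d_wire = %g mm, F0 = %.2f N, opening_max = %g mm%s\n",
    x$d_wire, x$F0, x$opening_max,
    if (is.null(x$points)) " (linear law)" else
      sprintf(" (%d tabulated points)", nrow(x$points))
  ))
  invisible(x)
}

#' Evaluate a spring force law
#'
#' @param characteristic A [spring_characteristic()].
#' @param opening Opening distance(s), mm; must be >= 0. Forces are zero for
#'   openings at or beyond `opening_max`.
#' @return Axial force(s), N (non-increasing, continuous in `opening`).
#' @export
spring_force <- function(characteristic, opening) {
  stopifnot(inherits(characteristic, "spring_characteristic"))
  if (any(!is.finite(opening)) || any(opening < 0)) {
    abort("`opening` must be finite and >= 0.")
  }
  if (is.null(characteristic$points)) {
    pmax(0, characteristic$F0 * (1 - opening / characteristic$opening_max))
  } else {
    stats::approx(
      characteristic$points$opening, characteristic$points$force,
      xout = pmin(opening, characteristic$opening_max),
      rule = 2
    )$y
  }
}

# Weighted anchor-foot position (node weights sum to 1 per side).
anchor_point <- function(mesh, nodes, weights, u = NULL) {
  p <- colSums(mesh$nodes[nodes, , drop = FALSE] * weights)
  if (!is.null(u)) p <- p + colSums(u[nodes, , drop = FALSE] * weights)
  p
}

# Build the nodal force matrix for the current spring forces. Each spring's
# force is distributed over its weighted anchor-foot nodes (through-thickness
# column(s) on each cut edge), applied as an action-reaction pair along the
# unit vector between the two feet.
spring_load <- function(system, anchors, forces, u = NULL) {
  F <- matrix(0, system$n_nodes, 3)
  mesh <- system$mesh
  for (k in seq_len(nrow(anchors))) {
    ln <- anchors$left_nodes[[k]]; lw <- anchors$left_weights[[k]]
    rn <- anchors$right_nodes[[k]]; rw <- anchors$right_weights[[k]]
    pl <- anchor_point(mesh, ln, lw, u)
    pr <- anchor_point(mesh, rn, rw, u)
    dir <- (pr - pl) / sqrt(sum((pr - pl)^2))
    F[rn, ] <- F[rn, ] + forces[k] * rw %o% dir
    F[ln, ] <- F[ln, ] - forces[k] * lw %o% dir
  }
  F
}

spring_openings <- function(system, anchors, u) {
  mesh <- system$mesh
  vapply(seq_len(nrow(anchors)), function(k) {
    ln <- anchors$left_nodes[[k]]; lw <- anchors$left_weights[[k]]
    rn <- anchors$right_nodes[[k]]; rw <- anchors$right_weights[[k]]
    pl0 <- anchor_point(mesh, ln, lw)
    pr0 <- anchor_point(mesh, rn, rw)
    pl <- anchor_point(mesh, ln, lw, u)
    pr <- anchor_point(mesh, rn, rw, u)
    sqrt(sum((pr - pl)^2)) - sqrt(sum((pr0 - pl0)^2))
  }, 0)
}

#' Self-consistent spring/skull equilibrium
#'
#' The spring force depends on how far the cut has opened, and the opening
#' depends on the applied spring forces. A damped fixed-point iteration
#' resolves the coupling: apply the current forces, solve the elastic
#' system, recompute each spring's opening from the deformed anchor
#' positions, re-evaluate the force law, and under-relax the force update
#' until the largest force change (relative to `F0`) drops below `tol`.
#' The stiffness factorisation is reused across iterations, so each step
#' costs one sparse back-substitution.
#'
#' @param system An [assemble_system()] result for the cut mesh.
#' @param anchors A [locate_spring_anchors()] result.
#' @param characteristic A [spring_characteristic()].
#' @param tol Convergence tolerance on the relative force change
#'   (default 1e-4).
#' @param max_iter Maximum fixed-point iterations (default 50).
#' @param relax Under-relaxation factor in (0, 1]; 0.5 guards against
#'   oscillation on very soft skulls.
#' @return A `spring_equilibrium`: displacement field `u`, per-spring state
#'   tibble `springs` (`opening` mm, `force` N), iteration history, and the
#'   converged flag.
#' @export
equilibrate <- function(system, anchors, characteristic,
                        tol = 1e-4, max_iter = 50, relax = 0.5) {
  stopifnot(inherits(system, "fe_system"),
            inherits(characteristic, "spring_characteristic"))
  if (nrow(anchors) == 0) abort("no spring anchors supplied.")
  F0 <- characteristic$F0
  forces <- rep(spring_force(characteristic, 0), nrow(anchors))
  u <- matrix(0, system$n_nodes, 3)
  history <- vector("list", max_iter)
  converged <- FALSE
  it <- 0L
  delta_prev <- Inf
  for (it in seq_len(max_iter)) {
    loads <- spring_load(system, anchors, forces, u = NULL)
    u <- solve_system(system, loads)
    openings <- pmax(0, spring_openings(system, anchors, u))
    target <- spring_force(characteristic, openings)
    new_forces <- (1 - relax) * forces + relax * target
    delta <- max(abs(new_forces - forces)) / F0
    # steep force laws on very compliant skulls make the plain iteration
    # oscillate; damp the relaxation whenever the update stops contracting
    if (delta > 0.9 * delta_prev) relax <- max(relax / 2, 0.02)
    delta_prev <- delta
    history[[it]] <- tibble::tibble(
      iter = it, spring = seq_along(forces),
      force = new_forces, opening = openings, delta = delta
    )
    forces <- new_forces
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  history <- dplyr::bind_rows(history[seq_len(it)])
  if (!converged) {
    cnd <- rlang::error_cnd(
      "craniospring_no_convergence",
      message = sprintf(
        "spring equilibrium did not converge in %d iterations (last delta %.3g).",
        max_iter, history$delta[nrow(history)]
      ),
      history = history
    )
    rlang::cnd_signal(cnd)
  }
  # final solve at the converged forces
  loads <- spring_load(system, anchors, forces, u = NULL)
  u <- solve_system(system, loads)
  openings <- pmax(0, spring_openings(system, anchors, u))
  structure(
    list(
      u = u,
      springs = tibble::tibble(
        spring = seq_along(forces),
        x = anchors$x_actual,
        opening = openings,
        force = forces
      ),
      loads = loads,
      iterations = it,
      converged = converged,
      history = history,
      characteristic = characteristic
    ),
    class = "spring_equilibrium"
  )
}

#' @export
print.spring_equilibrium <- function(x, ...) {
  cat(sprintf(
    "<spring_equilibrium> %d springs, converged in %d iterations\n",
    nrow(x$springs), x$iterations
  ))
  print(x$springs)
  invisible(x)
}
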