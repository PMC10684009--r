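#' Surgical plan: osteotomy and spring placement
#'
#' Describes the parasagittal osteotomy and the implanted expansion springs.
#' The osteotomy is a midline strip of width `w_ost` running between the
#' coronal and lambdoid sutures, stopped `l_ost` short of each suture.
#' Springs sit across the cut: one at `x_spring` from the coronal end, one at
#' `x_spring` from the lambdoid end, and (for three springs) one at the cut
#' midpoint.
#'
#' @param w_ost Osteotomy width, mm (> 0).
#' @param l_ost Offset of the osteotomy ends from the coronal and lambdoid
#'   sutures, mm (>= 0; symmetric at both ends).
#' @param n_spring Number of springs, 2 or 3.
#' @param x_spring Distance of the outer springs from the sutures, mm.
#'   Must satisfy `x_spring >= l_ost` so the springs lie within the cut.
#' @param d_wire Spring wire diameter, mm; one of the catalogued
#'   characteristics (1.0, 1.2 or 1.4 by default, see [spring_catalog()]).
#' @return A validated `surgical_plan` object.
#' @export
surgical_plan <- function(w_ost = 20, l_ost = 0, n_spring = 2,
                          x_spring = 34, d_wire = 1.2) {
  for (nm in c("w_ost", "l_ost", "n_spring", "x_spring", "d_wire")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  if (!n_spring %in% c(2, 3)) abort("`n_spring` must be 2 or 3.")
  if (w_ost <= 0) abort("`w_ost` must be > 0.")
  if (x_spring <= 0) abort("`x_spring` must be > 0.")
  if (l_ost < 0) abort("`l_ost` must be >= 0.")
  if (x_spring < l_ost) {
    abort("`x_spring` must be >= `l_ost` (springs must lie within the cut).")
  }
  structure(
    list(w_ost = w_ost, l_ost = l_ost, n_spring = as.integer(n_spring),
         x_spring = x_spring, d_wire = d_wire),
    class = "surgical_plan"
  )
}

#' @export
print.surgical_plan <- function(x, ...) {
  cat(sprintf(
    "<surgical_plan> osteotomy %g mm wide, suture offset %g mm; %d springs (d = %g mm) at %g mm from the sutures\n",
    x$w_ost, x$l_ost, x$n_spring, x$d_wire, x$x_spring
  ))
  invisible(x)
}

#' Apply the parasagittal osteotomy to a calvarial mesh
#'
#' Removes every element whose centroid lies in the midline strip
#' `|y| <= w_ost/2`, `x` between (lambdoid suture + `l_ost`) and (coronal
#' suture - `l_ost`), drops the orphaned nodes, and records the two cut-edge
#' node sets (`osteotomy_edge_left` for y < 0, `osteotomy_edge_right` for
#' y > 0: nodes shared between removed and remaining elements).
#'
#' @param mesh A `calvarial_mesh` from [build_calvarium()].
#' @param plan A [surgical_plan()].
#' @return The cut mesh, with `node_sets$osteotomy_edge_left/right` populated
#'   and a `removed` field recording counts, the axial cut range and the cut
#'   length (x-extent of the removed elements).
#' @export
apply_osteotomy <- function(mesh, plan) {
  stopifnot(inherits(mesh, "calvarial_mesh"))
  if (!inherits(plan, "surgical_plan")) plan <- do.call(surgical_plan, as.list(plan))
  if (!is.null(mesh$removed)) abort("mesh already has an osteotomy applied.")
  if (is.null(mesh$suture_x)) {
    abort("mesh carries no suture positions; build it with build_calvarium().")
  }
  x_cor <- mesh$suture_x[["coronal"]]
  x_lam <- mesh$suture_x[["lambdoid"]]
  cut_lo <- x_lam + plan$l_ost
  cut_hi <- x_cor - plan$l_ost
  if (cut_hi - cut_lo <= 0) {
    abort(sprintf(
      "degenerate osteotomy: l_ost = %g mm leaves a cut of length %.1f mm.",
      plan$l_ost, cut_hi - cut_lo
    ))
  }

  corner_x <- matrix(mesh$nodes[mesh$elems[, 1:8], "x"], ncol = 8)
  corner_y <- matrix(mesh$nodes[mesh$elems[, 1:8], "y"], ncol = 8)
  cx <- rowMeans(corner_x)
  cy <- rowMeans(corner_y)

  # an element belongs to the cut when, for each bounding plane, its far
  # face is no closer to the plane than its near face: the resulting cut
  # boundary is the grid face nearest each plane, so the later projection of
  # boundary nodes onto the exact planes never moves a node by more than
  # about half an element and never leaves sliver elements along the edge
  f_ya <- abs(rowMeans(corner_y[, c(1, 2, 5, 6), drop = FALSE]))
  f_yb <- abs(rowMeans(corner_y[, c(3, 4, 7, 8), drop = FALSE]))
  y_near <- pmin(f_ya, f_yb); y_far <- pmax(f_ya, f_yb)
  f_xa <- rowMeans(corner_x[, c(1, 4, 5, 8), drop = FALSE])
  f_xb <- rowMeans(corner_x[, c(2, 3, 6, 7), drop = FALSE])
  x_lo_f <- pmin(f_xa, f_xb); x_hi_f <- pmax(f_xa, f_xb)
  hw <- plan$w_ost / 2
  inside_y <- abs(y_far - hw) <= abs(y_near - hw)
  inside_hi <- abs(x_lo_f - cut_hi) >= abs(x_hi_f - cut_hi)
  inside_lo <- abs(x_hi_f - cut_lo) >= abs(x_lo_f - cut_lo)
  removed <- which(inside_y & inside_hi & inside_lo)
  if (length(removed) == 0) {
    # cut narrower than one element row: remove the innermost row pair
    in_x <- cx >= cut_lo & cx <= cut_hi
    if (!any(in_x)) {
      abort("osteotomy strip contains no elements at this resolution.")
    }
    hw_y <- max(hw, min(abs(cy[in_x])) + 1e-9)
    removed <- which(in_x & abs(cy) <= hw_y)
  }
  if (length(removed) == 0) abort("osteotomy removed no elements.")

  removed_nodes <- unique(as.integer(mesh$elems[removed, ]))
  kept_elems <- mesh$elems[-removed, , drop = FALSE]
  kept_label <- mesh$label[-removed]
  kept_cells <- mesh$cell_index[-removed, , drop = FALSE]
  kept_fraction <- mesh$suture_fraction[-removed]
  kept_nodes_idx <- sort(unique(as.integer(kept_elems)))

  shared <- intersect(removed_nodes, kept_nodes_idx)
  ys <- mesh$nodes[shared, "y"]
  edge_left_old <- shared[ys < -1e-8]
  edge_right_old <- shared[ys > 1e-8]

  # Snap the cut boundary to the exact plan geometry: nodes on a face between
  # a removed element and its kept neighbour across the cut (a y-neighbour in
  # the structured grid) are projected onto y = +/- w_ost/2. Removal by
  # element centroid alone leaves a staircase boundary whose effective width
  # jitters by half an element per resolution level; projecting the lateral
  # face nodes makes the gap width exact at any resolution (the mesh
  # convergence study depends on this). End-cap faces are left untouched.
  nodes2 <- mesh$nodes
  nu <- mesh$grid[["nu"]]
  nv <- mesh$grid[["nv"]]
  lateral <- integer(0)
  endcap <- integer(0)
  for (e in removed) {
    ci <- mesh$cell_index[e, "ci"]; cj <- mesh$cell_index[e, "cj"]
    for (dj in c(-1L, 1L)) {
      if (cj + dj < 1L || cj + dj > nv) next
      nb <- ci + (cj + dj - 1L) * nu
      if (nb %in% removed) next
      lateral <- c(lateral, intersect(mesh$elems[e, ], mesh$elems[nb, ]))
    }
    for (di in c(-1L, 1L)) {
      if (ci + di < 1L || ci + di > nu) next
      nb <- ci + di + (cj - 1L) * nu
      if (nb %in% removed) next
      endcap <- c(endcap, intersect(mesh$elems[e, ], mesh$elems[nb, ]))
    }
  }
  lateral <- setdiff(unique(lateral), unique(endcap))
  endcap <- unique(endcap)
  # only nodes already within an element of the nominal cut boundary move;
  # faces that surface near the midline at staircase transitions stay put
  move <- abs(plan$w_ost / 2 - abs(nodes2[lateral, "y"]))
  lateral <- lateral[move <= 0.9 * mesh$resolution &
                       abs(nodes2[lateral, "y"]) > plan$w_ost / 4]
  nodes2[lateral, "y"] <- sign(nodes2[lateral, "y"]) * (plan$w_ost / 2)
  if (length(endcap)) {
    xe <- nodes2[endcap, "x"]
    x_end <- ifelse(abs(xe - cut_hi) < abs(xe - cut_lo), cut_hi, cut_lo)
    ok <- abs(x_end - xe) <= 0.9 * mesh$resolution
    endcap <- endcap[ok]
    nodes2[endcap, "x"] <- x_end[ok]
  }
  moved <- c(lateral, endcap)
  if (length(moved) && ncol(mesh$elems) == 20L) {
    # straighten quadratic edges touching moved nodes, otherwise the
    # projected corner and the untouched mid-edge node can fold the element
    hex20_edges <- cbind(
      c(1, 2, 3, 4, 5, 6, 7, 8, 1, 2, 3, 4),
      c(2, 3, 4, 1, 6, 7, 8, 5, 5, 6, 7, 8),
      9:20
    )
    affected <- which(rowSums(matrix(kept_elems %in% moved,
                                     nrow = nrow(kept_elems))) > 0)
    for (e in affected) {
      en <- kept_elems[e, ]
      for (r in seq_len(12)) {
        nodes2[en[hex20_edges[r, 3]], ] <-
          (nodes2[en[hex20_edges[r, 1]], ] + nodes2[en[hex20_edges[r, 2]], ]) / 2
      }
    }
  }

  # reindex nodes
  remap <- integer(nrow(mesh$nodes))
  remap[kept_nodes_idx] <- seq_along(kept_nodes_idx)
  new_elems <- matrix(remap[kept_elems], nrow = nrow(kept_elems))
  storage.mode(new_elems) <- "integer"
  new_nodes <- nodes2[kept_nodes_idx, , drop = FALSE]
  new_meta <- mesh$node_meta[kept_nodes_idx, , drop = FALSE]
  node_sets <- lapply(mesh$node_sets, function(s) {
    s <- intersect(s, kept_nodes_idx)
    as.integer(remap[s])
  })
  node_sets$osteotomy_edge_left <- as.integer(remap[edge_left_old])
  node_sets$osteotomy_edge_right <- as.integer(remap[edge_right_old])

  out <- hex_mesh(
    new_nodes, new_elems, as.character(kept_label),
    node_sets = node_sets,
    params = mesh$params,
    resolution = mesh$resolution,
    node_meta = new_meta,
    cell_index = kept_cells,
    suture_x = mesh$suture_x,
    grid = mesh$grid,
    suture_fraction = kept_fraction,
    plan = plan,
    removed = list(
      count = length(removed),
      x_range = c(cut_lo, cut_hi),
      cut_length = cut_hi - cut_lo,
      total_before = nrow(mesh$elems)
    )
  )
  out
}

# Group cut-edge nodes into through-thickness columns keyed by the fine-grid
# (gi, gj) surface position; returns a tibble of columns with mean coords.
edge_columns <- function(mesh, side = c("left", "right")) {
  side <- match.arg(side)
  set <- mesh$node_sets[[paste0("osteotomy_edge_", side)]]
  if (is.null(set) || length(set) == 0) {
    abort("mesh has no osteotomy edge node sets; apply the osteotomy first.")
  }
  meta <- mesh$node_meta[set, , drop = FALSE]
  key <- paste(meta[, "gi"], meta[, "gj"], sep = "_")
  split_idx <- split(set, key)
  cols <- tibble::tibble(
    nodes = unname(split_idx),
    x = vapply(split_idx, function(i) mean(mesh$nodes[i, "x"]), 0),
    y = vapply(split_idx, function(i) mean(mesh$nodes[i, "y"]), 0),
    z = vapply(split_idx, function(i) mean(mesh$nodes[i, "z"]), 0)
  )
  # keep lateral-face columns (|y| near the side maximum), not cut-end caps
  cols[abs(cols$y) >= 0.75 * max(abs(cols$y)), , drop = FALSE]
}

#' Locate spring anchor node pairs along the osteotomy
#'
#' Anchors are through-thickness node columns on the two cut edges. The
#' outer springs sit `x_spring` from the coronal and lambdoid sutures; a
#' third spring (if present) sits at the cut midpoint. Each target position
#' snaps to the nearest edge-node column (lower index wins on exact ties).
#'
#' @param mesh A cut `calvarial_mesh` (after [apply_osteotomy()]).
#' @param plan The [surgical_plan()] used for the cut.
#' @param foot_width Physical axial extent of a spring foot on the cut edge,
#'   mm; the spring force is spread over the edge columns it covers.
#' @return A `spring_anchor_set`: tibble with one row per spring
#'   (`x_target`, `x_actual`, node and weight list-columns per side).
#' @export
locate_spring_anchors <- function(mesh, plan = mesh$plan, foot_width = 6) {
  stopifnot(inherits(mesh, "calvarial_mesh"))
  if (is.null(mesh$removed)) abort("apply the osteotomy before locating anchors.")
  if (is.null(plan)) abort("no surgical plan supplied.")
  x_cor <- mesh$suture_x[["coronal"]]
  x_lam <- mesh$suture_x[["lambdoid"]]
  cut <- mesh$removed$x_range

  if (x_cor - plan$x_spring < x_lam + plan$x_spring - 1e-9) {
    abort("spring positions cross: x_spring too large for this cut.")
  }
  targets <- c(x_cor - plan$x_spring, x_lam + plan$x_spring)
  if (plan$n_spring == 3L) targets <- c(targets, mean(cut))
  targets <- sort(targets, decreasing = TRUE)
  if (any(targets < cut[1] - mesh$resolution) ||
      any(targets > cut[2] + mesh$resolution)) {
    abort("spring positions fall outside the osteotomy cut.")
  }

  left <- edge_columns(mesh, "left")
  right <- edge_columns(mesh, "right")
  # A spring foot has a finite footprint on the cut edge: its force is
  # spread over the edge-node columns within half a footprint of the target
  # position with tent (hat) weights. This keeps both the load position and
  # the loaded physical width fixed while the mesh refines; snapping the
  # whole force to the single nearest node would make the local shell
  # indentation (and hence the spring opening) resolution-dependent. On
  # meshes coarser than the footprint the foot falls back to the two
  # bracketing columns, linearly weighted.
  pick <- function(cols, x_t) {
    ord <- order(cols$x)
    xs <- cols$x[ord]
    hw <- foot_width / 2
    inside <- which(abs(xs - x_t) < hw)
    if (length(inside) >= 2) {
      sel <- ord[inside]
      w <- 1 - abs(xs[inside] - x_t) / hw
      w <- w / sum(w)
    } else if (x_t <= xs[1]) {
      sel <- ord[1]; w <- 1
    } else if (x_t >= xs[length(xs)]) {
      sel <- ord[length(xs)]; w <- 1
    } else {
      j <- findInterval(x_t, xs)
      sel <- ord[c(j, j + 1)]
      w2 <- (x_t - xs[j]) / (xs[j + 1] - xs[j])
      w <- c(1 - w2, w2)
      keep <- w > 1e-9
      sel <- sel[keep]; w <- w[keep]
    }
    nodes <- unlist(cols$nodes[sel])
    nw <- rep(w / lengths(cols$nodes[sel]), lengths(cols$nodes[sel]))
    list(nodes = nodes, weights = nw, x = sum(w * cols$x[sel]))
  }
  la <- lapply(targets, function(x_t) pick(left, x_t))
  ra <- lapply(targets, function(x_t) pick(right, x_t))

  out <- tibble::tibble(
    spring = seq_along(targets),
    x_target = targets,
    x_actual = (vapply(la, `[[`, 0, "x") + vapply(ra, `[[`, 0, "x")) / 2,
    left_nodes = lapply(la, `[[`, "nodes"),
    left_weights = lapply(la, `[[`, "weights"),
    right_nodes = lapply(ra, `[[`, "nodes"),
    right_weights = lapply(ra, `[[`, "weights")
  )
  if (any(abs(out$x_actual - out$x_target) > mesh$resolution + 1e-9)) {
    warn("an anchor lies more than one element edge from its target position.")
  }
  class(out) <- c("spring_anchor_set", class(out))
  out
}
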