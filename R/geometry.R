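#' Parametric calvarial geometry specification
#'
#' Describes the infant calvarium as a superellipsoid-like half shell: a
#' curved shell of uniform thickness, truncated at a horizontal base plane,
#' with separate anterior and posterior plan-view exponents so frontal and
#' occipital rounding can differ. The coordinate convention is
#' x = anteroposterior (length, +x anterior), y = mediolateral (width),
#' z = vertical, origin at the shell centroid on the base plane.
#'
#' Suture layout: coronal and lambdoid sutures are transverse compliant
#' strips centred at `+coronal_offset_frac * l_skull` and
#' `-lambdoid_offset_frac * l_skull`; with the 0.30/0.30 defaults the
#' inter-suture distance is 0.6 `l_skull` (about 96 mm on a 160 mm skull,
#' matching the reported suture-to-suture cut length). The anterior
#' fontanelle is a diamond patch at the coronal/midline junction.
#'
#' @param l_skull,w_skull,h_skull Skull length, width, height, mm
#'   (`l_skull > w_skull > 0`, `h_skull > 0`).
#' @param t_skull Shell thickness, mm; must satisfy `0 < t_skull < h_skull/5`.
#' @param curvature_anterior,curvature_posterior Dimensionless plan-view
#'   superellipse exponents (2 = elliptical; larger = fuller/boxier) for the
#'   anterior and posterior halves.
#' @param resolution Target element edge length, mm.
#' @param element_order `"hex20"` (20-node quadratic serendipity, default) or
#'   `"hex8"` (8-node trilinear).
#' @param base_angle_deg Colatitude (degrees, measured from the apex) at
#'   which the shell is truncated by the base plane. Values above 90 place
#'   the widest section above the base so the measured width can respond to
#'   lateral expansion, as in a parietal eminence.
#' @param suture_width Width of the coronal/lambdoid suture strips, mm.
#' @param coronal_offset_frac,lambdoid_offset_frac Suture centre positions as
#'   fractions of `l_skull` anterior/posterior of the centroid.
#' @param fontanelle_length,fontanelle_width Full extents of the diamond
#'   anterior-fontanelle patch along x and y, mm.
#' @param grid_n Optional explicit grid size `c(nu, nv)` (cells along the two
#'   parametric directions, both even), overriding the size derived from
#'   `resolution`. Used by the mesh-sensitivity study to refine by exact
#'   nesting so that discretisation features subdivide coherently.
#' @return A validated `calvarial_params` object.
#' @export
calvarial_params <- function(l_skull, w_skull, h_skull, t_skull,
                             curvature_anterior = 2.0,
                             curvature_posterior = 2.2,
                             resolution = 6,
                             element_order = c("hex20", "hex8"),
                             base_angle_deg = 110,
                             suture_width = 3,
                             coronal_offset_frac = 0.30,
                             lambdoid_offset_frac = 0.30,
                             fontanelle_length = 30,
                             fontanelle_width = 25,
                             grid_n = NULL) {
  element_order <- match.arg(element_order)
  if (!is.null(grid_n)) {
    if (length(grid_n) != 2 || any(grid_n < 6) || any(grid_n %% 2 != 0)) {
      abort("`grid_n` must be two even cell counts >= 6.")
    }
    grid_n <- as.integer(grid_n)
  }
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
    x
  }
  for (nm in c("l_skull", "w_skull", "h_skull", "t_skull", "resolution",
               "curvature_anterior", "curvature_posterior", "base_angle_deg",
               "suture_width", "coronal_offset_frac", "lambdoid_offset_frac",
               "fontanelle_length", "fontanelle_width")) {
    num1(get(nm), nm)
  }
  if (!(l_skull > w_skull && w_skull > 0)) {
    abort("invalid calvarial parameters: need l_skull > w_skull > 0.")
  }
  if (h_skull <= 0) abort("invalid calvarial parameters: h_skull must be > 0.")
  if (!(t_skull > 0 && t_skull < h_skull / 5)) {
    abort("invalid calvarial parameters: need 0 < t_skull < h_skull/5.")
  }
  if (resolution <= 0) abort("invalid calvarial parameters: resolution must be > 0.")
  if (curvature_anterior < 1 || curvature_posterior < 1) {
    abort("curvature exponents must be >= 1.")
  }
  if (base_angle_deg <= 90 || base_angle_deg >= 150) {
    abort("`base_angle_deg` must lie in (90, 150).")
  }
  structure(
    list(
      l_skull = l_skull, w_skull = w_skull, h_skull = h_skull,
      t_skull = t_skull,
      curvature_anterior = curvature_anterior,
      curvature_posterior = curvature_posterior,
      resolution = resolution, element_order = element_order,
      base_angle_deg = base_angle_deg, suture_width = suture_width,
      coronal_offset_frac = coronal_offset_frac,
      lambdoid_offset_frac = lambdoid_offset_frac,
      fontanelle_length = fontanelle_length,
      fontanelle_width = fontanelle_width,
      grid_n = grid_n
    ),
    class = "calvarial_params"
  )
}

#' @export
print.calvarial_params <- function(x, ...) {
  cat(sprintf(
    "<calvarial_params> %g x %g x %g mm, t = %g mm, CI = %.3f, %s @ %g mm\n",
    x$l_skull, x$w_skull, x$h_skull, x$t_skull,
    compute_cephalic_index(x$w_skull, x$l_skull), x$element_order,
    x$resolution
  ))
  invisible(x)
}

# Default cell counts for a skull of the given size at a target resolution.
default_grid <- function(l_skull, w_skull, h_skull, resolution,
                         base_angle_deg = 110) {
  phi_base <- base_angle_deg * pi / 180
  c_e <- h_skull / (1 - cos(phi_base))
  arc_u <- phi_base * (l_skull / 2 + c_e) / 2
  arc_v <- phi_base * (w_skull / 2 + c_e) / 2
  c(2L * max(4L, as.integer(ceiling(arc_u / resolution))),
    2L * max(3L, as.integer(ceiling(arc_v / resolution))))
}

# Outer-surface parametric map: square (s,t) in [-1,1]^2 -> dome point (mm).
# Returns a list of matrices x, y, z matching dim(s).
calvarial_surface <- function(s, t, params) {
  a <- params$l_skull / 2
  b <- params$w_skull / 2
  phi_base <- params$base_angle_deg * pi / 180
  c_e <- params$h_skull / (1 - cos(phi_base))
  z_c <- -c_e * cos(phi_base)

  # square -> unit disc by the concentric map: square rings go to circles
  # (max-norm radius, square angular coordinate). Non-degenerate everywhere
  # except the apex point itself, so no inverted cells at the square corners.
  rho <- pmax(abs(s), abs(t))
  lam <- atan2(t, s)
  lam[rho == 0] <- 0

  phi <- rho * phi_base
  wa <- (1 + cos(lam)) / 2
  p <- wa * params$curvature_anterior + (1 - wa) * params$curvature_posterior
  R <- ((abs(cos(lam)) / a)^p + (abs(sin(lam)) / b)^p)^(-1 / p)
  R[rho == 0] <- a

  list(
    x = sin(phi) * R * cos(lam),
    y = sin(phi) * R * sin(lam),
    z = z_c + c_e * cos(phi)
  )
}

# Outward unit normal of the outer surface by central differences in (s,t).
calvarial_normal <- function(s, t, params) {
  h <- 1e-4
  p1 <- calvarial_surface(s + h, t, params)
  p2 <- calvarial_surface(s - h, t, params)
  q1 <- calvarial_surface(s, t + h, params)
  q2 <- calvarial_surface(s, t - h, params)
  ex <- (p1$x - p2$x); ey <- (p1$y - p2$y); ez <- (p1$z - p2$z)
  fx <- (q1$x - q2$x); fy <- (q1$y - q2$y); fz <- (q1$z - q2$z)
  nx <- ey * fz - ez * fy
  ny <- ez * fx - ex * fz
  nz <- ex * fy - ey * fx
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  list(x = nx / nn, y = ny / nn, z = nz / nn)
}

#' Construct a labelled hexahedral mesh from raw arrays
#'
#' Low-level constructor used by [build_calvarium()] and handy for building
#' small fixture meshes in tests and verification studies (patch tests,
#' dense-solver cross-checks).
#'
#' @param nodes Numeric matrix, one row per node, columns x/y/z (mm).
#' @param elems Integer matrix of 1-based node indices, 8 or 20 columns
#'   (VTK hexahedron ordering).
#' @param label Per-element region label; character or factor with levels
#'   among the calvarial regions.
#' @param node_sets Named list of integer node-index vectors.
#' @param ... Further fields stored on the object.
#' @return A `calvarial_mesh` object.
#' @export
hex_mesh <- function(nodes, elems, label, node_sets = list(), ...) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  if (ncol(nodes) != 3) abort("`nodes` must have 3 columns.")
  if (!ncol(elems) %in% c(8L, 20L)) {
    abort("`elems` must have 8 or 20 columns (VTK hexahedron ordering).")
  }
  if (length(label) == 1) label <- rep(label, nrow(elems))
  if (length(label) != nrow(elems)) {
    abort("`label` must have one entry per element.")
  }
  if (max(elems) > nrow(nodes) || min(elems) < 1L) {
    abort("element connectivity references a missing node.")
  }
  structure(
    c(
      list(
        nodes = nodes, elems = elems,
        label = factor(label, levels = region_levels()),
        node_sets = node_sets,
        element_order = if (ncol(elems) == 8L) "hex8" else "hex20"
      ),
      list(...)
    ),
    class = "calvarial_mesh"
  )
}

region_levels <- function() {
  c("parietal_bone", "frontal_bone", "occipital_bone",
    "coronal_suture", "lambdoid_suture", "anterior_fontanelle")
}

suture_labels <- function() {
  c("coronal_suture", "lambdoid_suture", "anterior_fontanelle")
}

#' Build the parametric calvarial finite-element mesh
#'
#' Generates a one-element-thick (through the thickness) curved shell of
#' hexahedra on the parametric dome described by `params`, labels the
#' coronal and lambdoid suture strips and the anterior fontanelle, and
#' records the `base_fixed` node set (all nodes within half an element of
#' the base plane, where the model is clamped).
#'
#' The mesh bounding box matches (`l_skull`, `w_skull`, `h_skull`) exactly:
#' after meshing, the node cloud is affinely rescaled per axis so the
#' discretised extents equal the requested dimensions at any resolution.
#'
#' @param params A [calvarial_params()] object.
#' @return A `calvarial_mesh` with fields `nodes` (n x 3, mm), `elems`
#'   (m x 8 or m x 20, 1-based), `label` (per-element region factor),
#'   `node_sets` (`base_fixed`), plus grid bookkeeping used by
#'   [apply_osteotomy()] and [locate_spring_anchors()].
#' @export
build_calvarium <- function(params) {
  if (!inherits(params, "calvarial_params")) {
    params <- do.call(calvarial_params, as.list(params))
  }
  res <- params$resolution
  # grid sized by meridian arc length (apex to base), so `resolution` is the
  # element edge target on the curved surface, not in plan view
  phi_base <- params$base_angle_deg * pi / 180
  c_e <- params$h_skull / (1 - cos(phi_base))
  arc_u <- phi_base * (params$l_skull / 2 + c_e) / 2
  arc_v <- phi_base * (params$w_skull / 2 + c_e) / 2
  if (is.null(params$grid_n)) {
    gn <- default_grid(params$l_skull, params$w_skull, params$h_skull, res,
                       params$base_angle_deg)
    nu <- gn[1]
    nv <- gn[2]
  } else {
    nu <- params$grid_n[1]
    nv <- params$grid_n[2]
    res <- arc_u / (nu / 2) # effective edge length, for snapping guards
  }

  # fine parametric grid at half steps (used directly by hex20; hex8 uses
  # the odd rows/cols)
  s2 <- seq(-1, 1, length.out = 2L * nu + 1L)
  t2 <- seq(-1, 1, length.out = 2L * nv + 1L)
  S <- matrix(s2, nrow = length(s2), ncol = length(t2))
  T <- matrix(t2, nrow = length(s2), ncol = length(t2), byrow = TRUE)
  P <- calvarial_surface(S, T, params)
  N <- calvarial_normal(S, T, params)

  out_x <- P$x; out_y <- P$y; out_z <- P$z
  in_x <- out_x - params$t_skull * N$x
  in_y <- out_y - params$t_skull * N$y
  in_z <- pmax(out_z - params$t_skull * N$z, 0)
  out_z <- pmax(out_z, 0)

  ni <- 2L * nu + 1L
  nj <- 2L * nv + 1L
  corner <- outer(seq_len(ni) %% 2L == 1L, seq_len(nj) %% 2L == 1L, "&")
  centre <- outer(seq_len(ni) %% 2L == 0L, seq_len(nj) %% 2L == 0L, "&")

  if (params$element_order == "hex8") {
    keep_surface <- corner
  } else {
    keep_surface <- !centre
  }

  id_in <- matrix(NA_integer_, ni, nj)
  id_out <- matrix(NA_integer_, ni, nj)
  id_mid <- matrix(NA_integer_, ni, nj)
  n_in <- sum(keep_surface)
  id_in[keep_surface] <- seq_len(n_in)
  id_out[keep_surface] <- n_in + seq_len(n_in)
  use_mid <- params$element_order == "hex20"
  if (use_mid) {
    id_mid[corner] <- 2L * n_in + seq_len(sum(corner))
  }

  take <- function(m, keep) m[keep]
  nodes <- rbind(
    cbind(take(in_x, keep_surface), take(in_y, keep_surface),
          take(in_z, keep_surface)),
    cbind(take(out_x, keep_surface), take(out_y, keep_surface),
          take(out_z, keep_surface))
  )
  meta <- rbind(
    cbind(which(keep_surface, arr.ind = TRUE), layer = 0L),
    cbind(which(keep_surface, arr.ind = TRUE), layer = 2L)
  )
  if (use_mid) {
    nodes <- rbind(nodes, cbind(
      (take(in_x, corner) + take(out_x, corner)) / 2,
      (take(in_y, corner) + take(out_y, corner)) / 2,
      (take(in_z, corner) + take(out_z, corner)) / 2
    ))
    meta <- rbind(meta, cbind(which(corner, arr.ind = TRUE), layer = 1L))
  }
  colnames(nodes) <- c("x", "y", "z")
  colnames(meta) <- c("gi", "gj", "layer")

  # per-axis rescale: exact bounding box at every resolution
  nodes[, "x"] <- nodes[, "x"] * (params$l_skull / 2) / max(nodes[, "x"])
  nodes[, "y"] <- nodes[, "y"] * (params$w_skull / 2) / max(nodes[, "y"])
  nodes[, "z"] <- nodes[, "z"] * params$h_skull / max(nodes[, "z"])

  cells <- expand.grid(ci = seq_len(nu), cj = seq_len(nv))
  i2a <- 2L * cells$ci - 1L; i2b <- i2a + 2L; i2m <- i2a + 1L
  j2a <- 2L * cells$cj - 1L; j2b <- j2a + 2L; j2m <- j2a + 1L
  idx <- function(m, i, j) m[cbind(i, j)]
  corners_in <- cbind(idx(id_in, i2a, j2a), idx(id_in, i2b, j2a),
                      idx(id_in, i2b, j2b), idx(id_in, i2a, j2b))
  corners_out <- cbind(idx(id_out, i2a, j2a), idx(id_out, i2b, j2a),
                       idx(id_out, i2b, j2b), idx(id_out, i2a, j2b))
  if (params$element_order == "hex8") {
    elems <- cbind(corners_in, corners_out)
  } else {
    mids_in <- cbind(idx(id_in, i2m, j2a), idx(id_in, i2b, j2m),
                     idx(id_in, i2m, j2b), idx(id_in, i2a, j2m))
    mids_out <- cbind(idx(id_out, i2m, j2a), idx(id_out, i2b, j2m),
                      idx(id_out, i2m, j2b), idx(id_out, i2a, j2m))
    mids_vert <- cbind(idx(id_mid, i2a, j2a), idx(id_mid, i2b, j2a),
                       idx(id_mid, i2b, j2b), idx(id_mid, i2a, j2b))
    elems <- cbind(corners_in, corners_out, mids_in, mids_out, mids_vert)
  }
  storage.mode(elems) <- "integer"

  # element centroids from the 8 corners
  cx <- rowMeans(matrix(nodes[elems[, 1:8], "x"], ncol = 8))
  cy <- rowMeans(matrix(nodes[elems[, 1:8], "y"], ncol = 8))

  x_cor <- params$coronal_offset_frac * params$l_skull
  x_lam <- -params$lambdoid_offset_frac * params$l_skull
  xmat <- matrix(nodes[elems[, 1:8], "x"], ncol = 8)
  ymat <- matrix(nodes[elems[, 1:8], "y"], ncol = 8)
  x_lo <- apply(xmat, 1, min); x_hi <- apply(xmat, 1, max)

  # Suture strips are thinner than one element at practical resolutions, so
  # each suture stores a per-element overlap fraction; assembly turns the
  # fraction into an effective modulus (series rule of mixtures), keeping
  # through-suture compliance resolution-independent.
  overlap_frac <- function(x_s) {
    lo <- x_s - params$suture_width / 2
    hi <- x_s + params$suture_width / 2
    pmax(0, pmin(hi, x_hi) - pmax(lo, x_lo)) / pmax(x_hi - x_lo, 1e-12)
  }
  f_cor <- overlap_frac(x_cor)
  f_lam <- overlap_frac(x_lam)
  suture_fraction <- pmax(f_cor, f_lam)

  label <- rep("parietal_bone", nrow(elems))
  label[cx > x_cor] <- "frontal_bone"
  label[cx < x_lam] <- "occipital_bone"
  main_band <- function(f) f > 0 & f >= 0.5 * max(f)
  label[main_band(f_cor)] <- "coronal_suture"
  label[main_band(f_lam)] <- "lambdoid_suture"

  # anterior fontanelle: diamond patch at the coronal/midline junction;
  # fraction = area coverage of the element footprint, by 7x7 subsampling
  font_cover <- function(ex_lo, ex_hi, ey_lo, ey_hi) {
    qs <- (seq_len(7) * 2 - 1) / 14
    pts_x <- outer(ex_lo, qs, function(l, q) l) +
      outer(ex_hi - ex_lo, qs, `*`)
    frac <- numeric(length(ex_lo))
    for (iy in qs) {
      py <- ey_lo + iy * (ey_hi - ey_lo)
      for (ix in seq_along(qs)) {
        inside <- abs(pts_x[, ix] - x_cor) / (params$fontanelle_length / 2) +
          abs(py) / (params$fontanelle_width / 2) <= 1
        frac <- frac + inside
      }
    }
    frac / 49
  }
  y_lo <- apply(ymat, 1, min); y_hi <- apply(ymat, 1, max)
  f_font <- font_cover(x_lo, x_hi, y_lo, y_hi)
  if (!any(f_font > 0)) {
    f_font[which.min((cx - x_cor)^2 + cy^2)] <- 1
  }
  in_font <- f_font > 0 & f_font >= 0.5 * max(f_font)
  label[in_font] <- "anterior_fontanelle"
  suture_fraction <- pmax(suture_fraction, f_font)

  # clamp the rim: every node column on the truncation boundary (the shell's
  # bottom edge face, a resolution-independent physical set on the base plane)
  base_fixed <- which(meta[, "gi"] == 1L | meta[, "gi"] == ni |
                        meta[, "gj"] == 1L | meta[, "gj"] == nj)

  hex_mesh(
    nodes, elems, label,
    node_sets = list(base_fixed = as.integer(base_fixed)),
    params = params,
    resolution = res,
    node_meta = meta,
    cell_index = as.matrix(cells),
    suture_x = c(coronal = x_cor, lambdoid = x_lam),
    grid = c(nu = nu, nv = nv),
    suture_fraction = suture_fraction
  )
}

#' @export
print.calvarial_mesh <- function(x, ...) {
  bb <- apply(x$nodes, 2, range)
  cat(sprintf(
    "<calvarial_mesh> %d nodes, %d %s elements\n",
    nrow(x$nodes), nrow(x$elems), x$element_order
  ))
  cat(sprintf(
    "  bounding box %.1f x %.1f x %.1f mm, CI = %.3f\n",
    diff(bb[, 1]), diff(bb[, 2]), diff(bb[, 3]),
    compute_cephalic_index(diff(bb[, 2]), diff(bb[, 1]))
  ))
  tab <- table(x$label)
  cat("  regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (!is.null(x$removed)) {
    cat(sprintf(
      "  osteotomy: %d elements removed, cut length %.1f mm\n",
      x$removed$count, x$removed$cut_length
    ))
  }
  invisible(x)
}

#' Mesh summary metrics
#'
#' @param mesh A `calvarial_mesh`.
#' @return A one-row tibble with node/element counts, bounding box and CI.
#' @export
mesh_metrics <- function(mesh) {
  bb <- apply(mesh$nodes, 2, range)
  tibble::tibble(
    n_nodes = nrow(mesh$nodes),
    n_elements = nrow(mesh$elems),
    element_order = mesh$element_order,
    length = diff(bb[, 1]),
    width = diff(bb[, 2]),
    height = diff(bb[, 3]),
    ci = compute_cephalic_index(diff(bb[, 2]), diff(bb[, 1]))
  )
}
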