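#' Export a mesh (and optional fields) as a legacy-ASCII VTK file
#'
#' Writes an unstructured-grid VTK file readable by ParaView and meshio:
#' hexahedral cells (VTK types 12/25), the region label as cell data, node
#' sets as 0/1 point-data masks, and any displacement field as a point-data
#' vector.
#'
#' @param mesh A `calvarial_mesh`.
#' @param path Output file path (conventionally `.vtk`).
#' @param displacement Optional n_nodes x 3 matrix written as the point-data
#'   vector `displacement`.
#' @param cell_data Optional named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, displacement = NULL, cell_data = list()) {
  stopifnot(inherits(mesh, "calvarial_mesh"))
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elems)
  k <- ncol(mesh$elems)
  vtk_type <- if (k == 8L) 12L else 25L
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("craniospring calvarial mesh")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", n))
  writeLines(apply(format(mesh$nodes, digits = 10, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  wl(sprintf("CELLS %d %d", m, m * (k + 1L)))
  writeLines(apply(cbind(k, mesh$elems - 1L), 1, paste, collapse = " "), con)
  wl(sprintf("CELL_TYPES %d", m))
  writeLines(as.character(rep(vtk_type, m)), con)

  wl(sprintf("CELL_DATA %d", m))
  wl("SCALARS region int 1")
  wl("LOOKUP_TABLE default")
  writeLines(as.character(as.integer(mesh$label)), con)
  for (nm in names(cell_data)) {
    wl(sprintf("SCALARS %s double 1", nm))
    wl("LOOKUP_TABLE default")
    writeLines(format(cell_data[[nm]], digits = 10, trim = TRUE), con)
  }

  wl(sprintf("POINT_DATA %d", n))
  for (nm in names(mesh$node_sets)) {
    mask <- integer(n)
    mask[mesh$node_sets[[nm]]] <- 1L
    wl(sprintf("SCALARS %s int 1", nm))
    wl("LOOKUP_TABLE default")
    writeLines(as.character(mask), con)
  }
  if (!is.null(displacement)) {
    wl("VECTORS displacement double")
    writeLines(apply(format(as.matrix(displacement), digits = 10,
                            trim = TRUE, scientific = FALSE),
                     1, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Read a simulation/campaign configuration file
#'
#' YAML (or JSON) configuration with optional blocks `geometry`, `plan`,
#' `materials`, `campaign` and `springs`; unknown fields are rejected so
#' typos fail loudly. Every field defaults to the package defaults.
#'
#' @param path Path to a YAML or JSON file.
#' @return A named list of constructor-ready argument lists.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found.", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("config must be a mapping.")
  known <- c("geometry", "plan", "materials", "campaign", "springs")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    abort(paste0("unknown config block(s): ", paste(extra, collapse = ", ")))
  }
  check_args <- function(block, fn) {
    bad <- setdiff(names(cfg[[block]]), names(formals(fn)))
    if (length(bad)) {
      abort(sprintf("unknown field(s) in `%s`: %s", block,
                    paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(cfg$geometry)) check_args("geometry", calvarial_params)
  if (!is.null(cfg$plan)) check_args("plan", surgical_plan)
  if (!is.null(cfg$materials)) check_args("materials", material_props)
  if (!is.null(cfg$campaign)) check_args("campaign", campaign_config)
  if (!is.null(cfg$springs)) check_args("springs", spring_characteristic)
  cfg
}
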