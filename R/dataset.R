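#' Sampling ranges for the simulation campaign
#'
#' Default ranges for the simulated surgical, material and geometric
#' parameters: bone modulus 100-3000 MPa (the range actually swept in the
#' reference simulations; the infant-bone literature range 1000-4500 MPa is
#' available by argument), bone Poisson's ratio 0.2-0.3, thickness 2-4 mm,
#' osteotomy width 10-20 mm, suture offset 0-40 mm, skull length 153-170 mm,
#' skull width 107-120 mm, spring distance 10-40 mm, two or three springs,
#' and the three catalogued wire diameters.
#'
#' @param E_bone,nu_bone,t_skull,w_ost,l_ost,l_skull,w_skull,x_spring
#'   Length-2 numeric `(min, max)` ranges.
#' @param n_spring,d_wire Discrete value sets.
#' @return A `parameter_ranges` object.
#' @export
parameter_ranges <- function(E_bone = c(100, 3000), nu_bone = c(0.2, 0.3),
                             t_skull = c(2, 4), w_ost = c(10, 20),
                             l_ost = c(0, 40), l_skull = c(153, 170),
                             w_skull = c(107, 120), x_spring = c(10, 40),
                             n_spring = c(2L, 3L),
                             d_wire = spring_catalog()$d_wire) {
  cont <- list(E_bone = E_bone, nu_bone = nu_bone, t_skull = t_skull,
               w_ost = w_ost, l_ost = l_ost, l_skull = l_skull,
               w_skull = w_skull, x_spring = x_spring)
  for (nm in names(cont)) {
    v <- cont[[nm]]
    if (length(v) != 2 || !all(is.finite(v)) || v[1] >= v[2]) {
      abort(sprintf("`%s` must be a (min, max) range with min < max.", nm))
    }
  }
  structure(
    c(cont, list(n_spring = as.integer(n_spring), d_wire = d_wire)),
    class = "parameter_ranges"
  )
}

#' Sample simulation parameter sets
#'
#' Continuous parameters are drawn independently and uniformly within their
#' ranges; the spring count and wire diameter uniformly over their discrete
#' sets. Two couplings apply by default:
#'
#' * `scaling = "uniform"` draws one scale factor per sample and scales the
#'   165/116/87 mm base skull by it (so `l_skull` spans its full range and
#'   `w_skull`, `h_skull` follow proportionally): the campaign then varies
#'   calvaria *size* at fixed pre-operative proportions, matching how the
#'   reference simulations were generated. `scaling = "independent"` samples
#'   length and width separately and sets the height from their geometric
#'   mean.
#' * `(l_ost, x_spring)` pairs violating `x_spring >= l_ost` (spring outside
#'   the cut) are rejected and redrawn, i.e. the pair is uniform on the
#'   feasible region.
#'
#' @param ranges A [parameter_ranges()] object.
#' @param n Number of parameter sets (default 212, the campaign size).
#' @param seed Integer seed; same seed, same samples.
#' @param scaling `"uniform"` (single scale factor, default) or
#'   `"independent"`.
#' @return Tibble with `id`, the ten sampled parameters and the derived
#'   `h_skull`.
#' @export
sample_parameters <- function(ranges = parameter_ranges(), n = 212,
                              seed = 1, scaling = c("uniform", "independent")) {
  stopifnot(inherits(ranges, "parameter_ranges"))
  scaling <- match.arg(scaling)
  if (n <= 0) abort("`n` must be positive.")
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    code
  }
  withr_seed({
    draw <- function(r) runif(n, r[1], r[2])
    E_bone <- draw(ranges$E_bone)
    nu_bone <- draw(ranges$nu_bone)
    t_skull <- draw(ranges$t_skull)
    w_ost <- draw(ranges$w_ost)
    l_ost <- draw(ranges$l_ost)
    x_spring <- draw(ranges$x_spring)
    # rejection step: springs must lie within the cut
    bad <- which(x_spring < l_ost)
    while (length(bad)) {
      l_ost[bad] <- runif(length(bad), ranges$l_ost[1], ranges$l_ost[2])
      x_spring[bad] <- runif(length(bad), ranges$x_spring[1], ranges$x_spring[2])
      bad <- bad[x_spring[bad] < l_ost[bad]]
    }
    if (scaling == "uniform") {
      s <- runif(n, ranges$l_skull[1] / 165, ranges$l_skull[2] / 165)
      l_skull <- 165 * s
      w_skull <- 116 * s
      h_skull <- 87 * s
    } else {
      l_skull <- draw(ranges$l_skull)
      w_skull <- draw(ranges$w_skull)
      h_skull <- 87 * sqrt((l_skull / 165) * (w_skull / 116))
    }
    n_spring <- sample(ranges$n_spring, n, replace = TRUE)
    d_wire <- sample(ranges$d_wire, n, replace = TRUE)
    tibble::tibble(
      id = seq_len(n),
      E_bone = E_bone, nu_bone = nu_bone, t_skull = t_skull,
      w_ost = w_ost, l_ost = l_ost,
      l_skull = l_skull, w_skull = w_skull, h_skull = h_skull,
      x_spring = x_spring, n_spring = as.integer(n_spring), d_wire = d_wire
    )
  })
}

#' Campaign configuration
#'
#' Solver and mesh settings shared by every simulation of a campaign. The
#' default resolution (9 mm, quadratic elements) is the desk-scale campaign
#' preset; single-case studies default to finer meshes.
#'
#' @param resolution Element edge length, mm.
#' @param element_order `"hex20"` or `"hex8"`.
#' @param fixed_grid Use one grid topology for every run, sized for the
#'   165/116/87 mm base skull at `resolution` (default TRUE). The sampled
#'   calvaria are affine-scaled copies of the base shape, so a common grid
#'   keeps the discretisation identical across runs and the campaign
#'   response smooth in the skull-size parameters; per-run `ceil()` grid
#'   sizing would inject step noise the surrogates cannot learn.
#' @param E_suture,nu_suture Suture/fontanelle material, fixed across the
#'   campaign.
#' @param tol,max_iter,relax Spring fixed-point settings, see [equilibrate()].
#' @param characteristic Optional [spring_characteristic()] override applied
#'   to every run regardless of `d_wire` (used e.g. for zero-force controls);
#'   `NULL` selects the catalog law per sample.
#' @param cache_dir Optional directory of per-run CSV results; reruns skip
#'   ids already present, making a campaign resumable.
#' @param quiet Suppress per-run progress messages.
#' @return A `campaign_config` list.
#' @export
campaign_config <- function(resolution = 9, element_order = "hex8",
                            fixed_grid = TRUE,
                            E_suture = 16, nu_suture = 0.49,
                            tol = 1e-4, max_iter = 100, relax = 0.5,
                            characteristic = NULL, cache_dir = NULL,
                            quiet = TRUE) {
  structure(
    list(resolution = resolution, element_order = element_order,
         fixed_grid = fixed_grid,
         E_suture = E_suture, nu_suture = nu_suture,
         tol = tol, max_iter = max_iter, relax = relax,
         characteristic = characteristic, cache_dir = cache_dir,
         quiet = quiet),
    class = "campaign_config"
  )
}

record_cols <- function() {
  c("id", "E_bone", "nu_bone", "t_skull", "w_ost", "l_ost", "l_skull",
    "w_skull", "h_skull", "x_spring", "n_spring", "d_wire",
    "pre_op_ci", "post_op_ci", "post_op_ci_pct", "max_displacement",
    "n_elements", "n_nodes", "iterations", "converged", "error")
}

run_one_sample <- function(row, config) {
  grid_n <- if (isTRUE(config$fixed_grid)) {
    default_grid(165, 116, 87, config$resolution)
  }
  params <- calvarial_params(
    l_skull = row$l_skull, w_skull = row$w_skull, h_skull = row$h_skull,
    t_skull = row$t_skull, resolution = config$resolution,
    element_order = config$element_order, grid_n = grid_n
  )
  plan <- surgical_plan(
    w_ost = row$w_ost, l_ost = row$l_ost, n_spring = row$n_spring,
    x_spring = row$x_spring, d_wire = row$d_wire
  )
  materials <- material_props(row$E_bone, row$nu_bone,
                              config$E_suture, config$nu_suture)
  characteristic <- config$characteristic %||%
    spring_characteristic(row$d_wire)
  sim <- simulate_case(params, plan, materials, characteristic,
                       tol = config$tol, max_iter = config$max_iter,
                       relax = config$relax)
  tibble::tibble(
    id = row$id,
    E_bone = row$E_bone, nu_bone = row$nu_bone, t_skull = row$t_skull,
    w_ost = row$w_ost, l_ost = row$l_ost,
    l_skull = row$l_skull, w_skull = row$w_skull, h_skull = row$h_skull,
    x_spring = row$x_spring, n_spring = row$n_spring, d_wire = row$d_wire,
    pre_op_ci = sim$metrics$pre_op_ci,
    post_op_ci = sim$metrics$post_op_ci,
    post_op_ci_pct = 100 * sim$metrics$post_op_ci,
    max_displacement = sim$metrics$max_displacement,
    n_elements = sim$n_elements, n_nodes = sim$n_nodes,
    iterations = sim$metrics$iterations,
    converged = TRUE, error = NA_character_
  )
}

failed_record <- function(row, msg) {
  tibble::tibble(
    id = row$id,
    E_bone = row$E_bone, nu_bone = row$nu_bone, t_skull = row$t_skull,
    w_ost = row$w_ost, l_ost = row$l_ost,
    l_skull = row$l_skull, w_skull = row$w_skull, h_skull = row$h_skull,
    x_spring = row$x_spring, n_spring = row$n_spring, d_wire = row$d_wire,
    pre_op_ci = NA_real_, post_op_ci = NA_real_, post_op_ci_pct = NA_real_,
    max_displacement = NA_real_,
    n_elements = NA_integer_, n_nodes = NA_integer_,
    iterations = NA_integer_, converged = FALSE, error = msg
  )
}

#' Run the finite-element simulation campaign
#'
#' One simulation per sampled parameter set. A failing or non-converging run
#' is flagged (`converged = FALSE`, reason in `error`) rather than aborting
#' the campaign; flagged rows carry NA outcomes and are excluded by
#' [split_dataset()]. With `config$cache_dir` set, finished runs are written
#' as per-id CSV files and skipped on resume.
#'
#' @param samples Tibble from [sample_parameters()].
#' @param config A [campaign_config()].
#' @return Tibble of simulation records: the sampled parameters, pre/post-op
#'   CI (ratio and percent), max displacement (mm), mesh sizes and
#'   convergence bookkeeping.
#' @export
run_campaign <- function(samples, config = campaign_config()) {
  stopifnot(is.data.frame(samples))
  if (!is.null(config$cache_dir) && !dir.exists(config$cache_dir)) {
    dir.create(config$cache_dir, recursive = TRUE)
  }
  rows <- purrr::map(seq_len(nrow(samples)), function(i) {
    row <- samples[i, ]
    cache_file <- if (!is.null(config$cache_dir)) {
      file.path(config$cache_dir, sprintf("record_%04d.csv", row$id))
    }
    if (!is.null(cache_file) && file.exists(cache_file)) {
      rec <- tibble::as_tibble(read.csv(cache_file))
      rec$error <- as.character(rec$error)
      return(rec)
    }
    rec <- tryCatch(
      run_one_sample(row, config),
      error = function(e) {
        if (!config$quiet) {
          message(sprintf("run %d failed: %s", row$id, conditionMessage(e)))
        }
        failed_record(row, conditionMessage(e))
      }
    )
    if (!config$quiet) message(sprintf("run %d/%d done", i, nrow(samples)))
    if (!is.null(cache_file)) write.csv(rec, cache_file, row.names = FALSE)
    rec
  })
  dplyr::bind_rows(rows)
}

#' Split campaign records into train and test sets
#'
#' Converged records only; random disjoint subsets of the requested sizes,
#' reproducible by seed. The 170/42 default mirrors the 212-simulation
#' campaign split used to train and test the surrogates.
#'
#' @param records Tibble from [run_campaign()].
#' @param n_train,n_test Subset sizes.
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_dataset <- function(records, n_train = 170, n_test = 42, seed = 1) {
  ok <- records[!is.na(records$post_op_ci) & records$converged, ]
  if (nrow(ok) < n_train + n_test) {
    abort(sprintf(
      "need %d converged records for a %d/%d split, have %d.",
      n_train + n_test, n_train, n_test, nrow(ok)
    ))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  idx <- sample(nrow(ok), n_train + n_test)
  list(
    train = ok[idx[seq_len(n_train)], ],
    test = ok[idx[n_train + seq_len(n_test)], ]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
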