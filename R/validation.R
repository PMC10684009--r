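#' The reference validation scenario
#'
#' The held-out test case used to check surrogate predictions against a
#' full finite-element simulation: an average sagittal-craniosynostosis
#' calvarium of a 5-month-old (160 x 114 x 99 mm, pre-operative CI 0.71,
#' 2 mm thick; bone E = 41 MPa, nu = 0.22; sutures 16 MPa, 0.49) treated
#' with a 20 mm wide suture-to-suture osteotomy (about 96 mm long) and two
#' 1.2 mm wire springs placed 34 mm from the sutures.
#'
#' The cohort-average skull shape itself is not redistributable; this case
#' uses the package's parametric calvarium as a synthetic stand-in with the
#' published overall dimensions, and is labelled as such in reports.
#'
#' Note the bone modulus lies far below the campaign sampling range, so
#' surrogate predictions for this case are extrapolations; [run_validation()]
#' surfaces the out-of-range warning prominently.
#'
#' @param resolution,element_order Mesh preset for the validation FE run
#'   (default 6 mm quadratic bricks, inside the mesh-converged band).
#' @return A `validation_case` list with `params`, `plan`, `materials`.
#' @export
validation_case <- function(resolution = 6, element_order = "hex20") {
  structure(
    list(
      params = calvarial_params(
        l_skull = 160, w_skull = 114, h_skull = 99, t_skull = 2,
        resolution = resolution, element_order = element_order
      ),
      plan = surgical_plan(w_ost = 20, l_ost = 0, n_spring = 2,
                           x_spring = 34, d_wire = 1.2),
      materials = material_props(E_bone = 41, nu_bone = 0.22,
                                 E_suture = 16, nu_suture = 0.49),
      label = "synthetic parametric stand-in for the cohort-average skull"
    ),
    class = "validation_case"
  )
}

#' Features of a case for surrogate prediction
#'
#' @param case A [validation_case()] (or compatible list).
#' @param pre_op_ci Pre-operative CI (ratio); defaults to width/length of
#'   the case parameters.
#' @return One-row tibble with the surrogate feature columns.
#' @export
case_features <- function(case, pre_op_ci = NULL) {
  p <- case$params
  pl <- case$plan
  if (is.null(pre_op_ci)) {
    pre_op_ci <- compute_cephalic_index(p$w_skull, p$l_skull)
  }
  tibble::tibble(
    E_bone = case$materials$E_bone, nu_bone = case$materials$nu_bone,
    t_skull = p$t_skull, w_ost = pl$w_ost, l_ost = pl$l_ost,
    l_skull = p$l_skull, w_skull = p$w_skull,
    x_spring = pl$x_spring, n_spring = as.numeric(pl$n_spring),
    d_wire = pl$d_wire, pre_op_ci = pre_op_ci
  )
}

#' Run the validation scenario and compare surrogates against the FE result
#'
#' Simulates the case with the finite-element pipeline, queries every tuned
#' surrogate for the same feature vector, and reports per-model percent
#' error against the simulated post-operative CI
#' (`|predicted - simulated| / simulated x 100`).
#'
#' @param models Named list of `tuned_model`s (e.g. `compare_models()$models`).
#' @param case A [validation_case()].
#' @param characteristic Optional spring-characteristic override (e.g. a
#'   zero-force control); default is the catalog law for the plan's wire.
#' @return A `validation_report`: `fe` (one-row tibble with pre/post-op CI,
#'   CI change in percentage points, max displacement), `predictions`
#'   (per-model tibble), and the case. Printed reports flag extrapolation.
#' @export
run_validation <- function(models, case = validation_case(),
                           characteristic = NULL) {
  if (inherits(models, "model_comparison")) models <- models$models
  if (inherits(models, "tuned_model")) models <- list(models)
  if (length(models) == 0) abort("no trained models supplied.")
  sim <- simulate_case(case$params, case$plan, case$materials,
                       characteristic = characteristic)
  fe <- dplyr::bind_cols(
    sim$metrics[, c("pre_op_ci", "post_op_ci", "delta_ci_pp",
                    "max_displacement")],
    tibble::tibble(post_op_ci_pct = 100 * sim$metrics$post_op_ci,
                   n_elements = sim$n_elements)
  )
  feats <- case_features(case)
  preds <- lapply(models, function(m) {
    pr <- withCallingHandlers(
      predict_ci(m, feats),
      warning = function(w) invokeRestart("muffleWarning")
    )
    tibble::tibble(
      algorithm = m$algorithm,
      predicted_ci_pct = pr$.pred,
      out_of_range = pr$.out_of_range
    )
  })
  predictions <- dplyr::bind_rows(preds)
  predictions$percent_error <-
    abs(predictions$predicted_ci_pct - fe$post_op_ci_pct) /
    fe$post_op_ci_pct * 100
  predictions <- dplyr::arrange(predictions, .data$percent_error)
  structure(
    list(fe = fe, predictions = predictions, case = case, simulation = sim),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", x$case$label, "\n")
  cat(sprintf(
    "  FE: pre-op CI %.4f -> post-op CI %.4f (+%.2f pp), max displacement %.2f mm\n",
    x$fe$pre_op_ci, x$fe$post_op_ci, x$fe$delta_ci_pp, x$fe$max_displacement
  ))
  oor <- unique(stats::na.omit(x$predictions$out_of_range))
  if (length(oor)) {
    cat("  WARNING: surrogates are extrapolating - feature(s) outside the",
        "training range:", paste(oor, collapse = "; "), "\n")
  }
  print(as.data.frame(
    x$predictions[, c("algorithm", "predicted_ci_pct", "percent_error")]
  ), digits = 4)
  invisible(x)
}

#' @rdname run_validation
#' @param x A `validation_report`.
#' @param ... Ignored.
#' @export
tidy.validation_report <- function(x, ...) x$predictions

#' @rdname run_validation
#' @export
glance.validation_report <- function(x, ...) {
  dplyr::bind_cols(
    x$fe,
    tibble::tibble(
      best_algorithm = x$predictions$algorithm[1],
      best_percent_error = x$predictions$percent_error[1]
    )
  )
}
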