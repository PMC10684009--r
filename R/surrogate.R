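surrogate_algorithms <- function() {
  c("linear_regression", "svr", "decision_tree", "random_forest",
    "gradient_boosting", "xgboost")
}

surrogate_features <- function() {
  c("E_bone", "nu_bone", "t_skull", "w_ost", "l_ost", "l_skull", "w_skull",
    "x_spring", "n_spring", "d_wire", "pre_op_ci")
}

#' Default hyperparameter search spaces
#'
#' Standard-practice spaces per algorithm: tree depth 2-12, learning rate
#' 0.01-0.3 (log scale), 50-500 boosting rounds / forest trees, SVR
#' C/gamma/epsilon log-uniform with an RBF kernel. Linear regression has no
#' hyperparameters (tuning is a no-op fit).
#'
#' @param algorithm One of `linear_regression`, `svr`, `decision_tree`,
#'   `random_forest`, `gradient_boosting`, `xgboost`.
#' @return Named list of search-space definitions (see [p_uniform()]).
#' @export
default_search_space <- function(algorithm) {
  switch(algorithm,
    linear_regression = list(),
    svr = list(
      cost = p_loguniform(1e-1, 1e3),
      gamma = p_loguniform(1e-3, 10),
      epsilon = p_loguniform(1e-3, 1)
    ),
    decision_tree = list(
      maxdepth = p_quniform(2, 12),
      cp = p_loguniform(1e-5, 1e-1),
      minsplit = p_quniform(2, 20)
    ),
    random_forest = list(
      num.trees = p_quniform(50, 500),
      mtry = p_quniform(2, length(surrogate_features())),
      min.node.size = p_quniform(1, 10)
    ),
    gradient_boosting = list(
      nrounds = p_quniform(50, 500),
      eta = p_loguniform(0.01, 0.3),
      max_depth = p_quniform(2, 12),
      subsample = p_uniform(0.5, 1)
    ),
    xgboost = list(
      nrounds = p_quniform(50, 500),
      eta = p_loguniform(0.01, 0.3),
      max_depth = p_quniform(2, 12),
      subsample = p_uniform(0.5, 1),
      colsample_bytree = p_uniform(0.5, 1),
      min_child_weight = p_quniform(1, 10),
      lambda = p_loguniform(1e-3, 10),
      alpha = p_loguniform(1e-3, 10)
    ),
    abort(sprintf("unknown algorithm '%s'.", algorithm))
  )
}

#' Surrogate model specification
#'
#' @param algorithm Regression algorithm id; see [default_search_space()].
#' @param search_space Hyperparameter space (default per algorithm).
#' @param budget Tuning trials for the TPE optimiser.
#' @param seed Integer seed controlling fold assignment and tuning.
#' @return A `model_spec` object.
#' @export
model_spec <- function(algorithm = surrogate_algorithms(),
                       search_space = NULL, budget = 100, seed = 1) {
  algorithm <- match.arg(algorithm)
  if (is.null(search_space)) search_space <- default_search_space(algorithm)
  if (budget < 1) abort("`budget` must be >= 1.")
  structure(
    list(algorithm = algorithm, search_space = search_space,
         budget = as.integer(budget), seed = as.integer(seed)),
    class = "model_spec"
  )
}

# ---- fitting backends -------------------------------------------------------
# LR and SVR consume standardised features (constant columns dropped);
# tree ensembles consume raw features.

scale_info <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  keep <- is.finite(scl) & scl > 1e-12
  list(center = ctr, scale = scl, keep = keep)
}

apply_scale <- function(X, si) {
  Xs <- sweep(X[, si$keep, drop = FALSE], 2, si$center[si$keep])
  sweep(Xs, 2, si$scale[si$keep], "/")
}

fit_backend <- function(algorithm, X, y, params, seed) {
  switch(algorithm,
    linear_regression = {
      si <- scale_info(X)
      df <- as.data.frame(apply_scale(X, si))
      df$.y <- y
      list(fit = lm(.y ~ ., data = df), scale = si)
    },
    svr = {
      si <- scale_info(X)
      fit <- e1071::svm(
        x = apply_scale(X, si), y = y, type = "eps-regression",
        kernel = "radial", scale = FALSE,
        cost = params$cost %||% 1,
        gamma = params$gamma %||% (1 / sum(si$keep)),
        epsilon = params$epsilon %||% 0.1
      )
      list(fit = fit, scale = si)
    },
    decision_tree = {
      df <- as.data.frame(X)
      df$.y <- y
      list(fit = rpart::rpart(
        .y ~ ., data = df, method = "anova",
        control = rpart::rpart.control(
          maxdepth = params$maxdepth %||% 8,
          cp = params$cp %||% 0.01,
          minsplit = params$minsplit %||% 5,
          xval = 0
        )
      ))
    },
    random_forest = {
      df <- as.data.frame(X)
      df$.y <- y
      list(fit = ranger::ranger(
        .y ~ ., data = df,
        num.trees = params$num.trees %||% 500,
        mtry = min(params$mtry %||% max(1, floor(ncol(X) / 3)), ncol(X)),
        min.node.size = params$min.node.size %||% 5,
        seed = seed, num.threads = 1
      ))
    },
    gradient_boosting = ,
    xgboost = {
      xparams <- list(
        objective = "reg:squarederror",
        eta = params$eta %||% 0.1,
        max_depth = params$max_depth %||% 4,
        subsample = params$subsample %||% 1,
        nthread = 1, seed = seed
      )
      if (algorithm == "gradient_boosting") {
        # classic gradient-boosted trees: regularisation terms off
        xparams$lambda <- 0
        xparams$alpha <- 0
      } else {
        xparams$colsample_bytree <- params$colsample_bytree %||% 1
        xparams$min_child_weight <- params$min_child_weight %||% 1
        xparams$lambda <- params$lambda %||% 1
        xparams$alpha <- params$alpha %||% 0
      }
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      list(fit = xgboost::xgb.train(
        params = xparams, data = dtrain,
        nrounds = params$nrounds %||% 200, verbose = 0
      ))
    },
    abort(sprintf("unknown algorithm '%s'.", algorithm))
  )
}

predict_backend <- function(algorithm, model, X) {
  switch(algorithm,
    linear_regression = {
      df <- as.data.frame(apply_scale(X, model$scale))
      unname(predict(model$fit, newdata = df))
    },
    svr = unname(predict(model$fit, apply_scale(X, model$scale))),
    decision_tree = unname(predict(model$fit, newdata = as.data.frame(X))),
    random_forest = unname(predict(model$fit, data = as.data.frame(X),
                                   num.threads = 1)$predictions),
    gradient_boosting = ,
    xgboost = unname(predict(model$fit,
                             xgboost::xgb.DMatrix(X, nthread = 1)))
  )
}

feature_matrix <- function(data, features) {
  miss <- setdiff(features, names(data))
  if (length(miss)) {
    abort(paste0("missing feature column(s): ", paste(miss, collapse = ", ")))
  }
  X <- as.matrix(data[, features, drop = FALSE])
  if (any(!is.finite(X))) abort("features contain non-finite values.")
  storage.mode(X) <- "double"
  X
}

cv_folds <- function(n, k, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Tune a surrogate on campaign records
#'
#' Sequential model-based optimisation ([tpe_optimize()]) over the spec's
#' search space, minimising the k-fold cross-validated RMSE of the
#' post-operative CI (percent scale); the best configuration is refitted on
#' the full training set. Algorithms without hyperparameters are fitted
#' directly. Reproducible given the spec seed.
#'
#' @param train Training records (tibble from [split_dataset()]).
#' @param spec A [model_spec()].
#' @param folds Cross-validation folds (default 5).
#' @param features Feature column names; defaults to the ten sampled
#'   simulation parameters plus the pre-operative CI.
#' @param target Target column; defaults to `post_op_ci_pct`.
#' @return A `tuned_model` (predict with [predict_ci()]; inspect with
#'   [tidy()]/[glance()]).
#' @export
tune_model <- function(train, spec, folds = 5,
                       features = surrogate_features(),
                       target = "post_op_ci_pct") {
  stopifnot(is.data.frame(train), inherits(spec, "model_spec"))
  if (nrow(train) == 0) abort("empty training set.")
  X <- feature_matrix(train, features)
  y <- train[[target]]
  if (is.null(y)) abort(sprintf("no target column `%s`.", target))

  fold_id <- cv_folds(nrow(X), folds, spec$seed)
  objective <- function(params) {
    errs <- vapply(seq_len(max(fold_id)), function(k) {
      tr <- fold_id != k
      fit <- fit_backend(spec$algorithm, X[tr, , drop = FALSE], y[tr],
                         params, seed = spec$seed)
      pred <- predict_backend(spec$algorithm, fit, X[!tr, , drop = FALSE])
      mean((pred - y[!tr])^2)
    }, 0)
    sqrt(mean(errs))
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed + 1L)
  opt <- tpe_optimize(spec$search_space, objective, spec$budget)

  fit <- fit_backend(spec$algorithm, X, y, opt$best_params, seed = spec$seed)
  structure(
    list(
      algorithm = spec$algorithm,
      spec = spec,
      best_params = opt$best_params,
      cv_rmse = opt$best_loss,
      trials = opt$trials,
      fit = fit,
      features = features,
      target = target,
      feature_range = apply(X, 2, range),
      n_train = nrow(X)
    ),
    class = "tuned_model"
  )
}

#' @export
print.tuned_model <- function(x, ...) {
  cat(sprintf(
    "<tuned_model> %s, %d training rows, cv RMSE %.4f (%d trials)\n",
    x$algorithm, x$n_train, x$cv_rmse, nrow(x$trials)
  ))
  if (length(x$best_params)) {
    cat("  best:", paste(names(x$best_params),
                         vapply(x$best_params, format, "", digits = 4),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname tune_model
#' @param x,object A `tuned_model`.
#' @param ... Ignored.
#' @export
tidy.tuned_model <- function(x, ...) {
  if (length(x$best_params) == 0) {
    return(tibble::tibble(term = character(), value = numeric()))
  }
  tibble::tibble(
    term = names(x$best_params),
    value = vapply(x$best_params, function(v) as.numeric(v)[1], 0)
  )
}

#' @rdname tune_model
#' @export
glance.tuned_model <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm, cv_rmse = x$cv_rmse,
    n_trials = nrow(x$trials), n_train = x$n_train,
    seed = x$spec$seed
  )
}

#' Predict post-operative CI for new cases
#'
#' @param model A [tune_model()] result.
#' @param new_data Data frame with the model's feature columns.
#' @return Tibble with `.pred` (post-operative CI, percent scale) and
#'   `.out_of_range` (comma-separated features outside the training bounds,
#'   `NA` when none). A warning is raised when extrapolating — e.g. a bone
#'   modulus below the sampled campaign range.
#' @export
predict_ci <- function(model, new_data) {
  stopifnot(inherits(model, "tuned_model"))
  X <- feature_matrix(new_data, model$features)
  pred <- predict_backend(model$algorithm, model$fit, X)
  oor <- apply(X, 1, function(row) {
    bad <- model$features[row < model$feature_range[1, ] |
                            row > model$feature_range[2, ]]
    if (length(bad)) paste(bad, collapse = ", ") else NA_character_
  })
  if (any(!is.na(oor))) {
    warn(paste0(
      "prediction requested outside the training range (",
      paste(unique(stats::na.omit(oor)), collapse = "; "),
      "): the surrogate is extrapolating."
    ))
  }
  tibble::tibble(.pred = pred, .out_of_range = oor)
}

#' Evaluate a tuned surrogate on held-out records
#'
#' RMSE on the percent-CI scale and the coefficient of determination
#' R^2 = 1 - SS_res/SS_tot. A zero-variance test target makes R^2
#' undefined; it is reported as `NA` with a message.
#'
#' @param test Held-out records.
#' @param model A `tuned_model`.
#' @param features,target As in [tune_model()]; defaults from the model.
#' @return One-row tibble: `algorithm`, `rmse`, `r2`, `n`.
#' @export
evaluate_model <- function(test, model,
                           features = model$features,
                           target = model$target) {
  stopifnot(is.data.frame(test), inherits(model, "tuned_model"))
  if (nrow(test) == 0) abort("empty test set.")
  X <- feature_matrix(test, features)
  y <- test[[target]]
  pred <- predict_backend(model$algorithm, model$fit, X)
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot <= 0) {
    message("zero-variance test target: R^2 is undefined (reported as NA).")
    NA_real_
  } else {
    1 - ss_res / ss_tot
  }
  tibble::tibble(
    algorithm = model$algorithm,
    rmse = sqrt(mean((y - pred)^2)),
    r2 = r2,
    n = nrow(X)
  )
}

#' Train, tune and compare the six surrogate algorithms
#'
#' Tunes every spec on the training set, evaluates on the held-out test set
#' and (optionally) predicts the validation case, reporting per-algorithm
#' RMSE, R^2 and validation percent error, ranked by R^2.
#'
#' @param train,test Campaign record tibbles from [split_dataset()].
#' @param specs List of [model_spec()]s (default: all six algorithms with
#'   shared `budget` and `seed`).
#' @param validation Optional one-row data frame of validation-case features
#'   plus a `post_op_ci_pct` column holding the finite-element result; the
#'   per-model percent error `|predicted - simulated| / simulated * 100` is
#'   then included.
#' @param folds,budget,seed Tuning controls used when `specs` is NULL.
#' @return A `model_comparison`: `metrics` tibble (ranked), `scatter` tibble
#'   of predicted-vs-simulated test points, and the fitted `models` list.
#' @export
compare_models <- function(train, test, specs = NULL, validation = NULL,
                           folds = 5, budget = 100, seed = 1) {
  if (is.null(specs)) {
    specs <- lapply(surrogate_algorithms(), model_spec,
                    budget = budget, seed = seed)
  }
  if (length(specs) < 2) abort("supply at least two model specs.")
  models <- lapply(specs, function(sp) tune_model(train, sp, folds = folds))
  names(models) <- vapply(models, `[[`, "", "algorithm")

  metrics <- dplyr::bind_rows(lapply(models, function(m) {
    evaluate_model(test, m)
  }))
  metrics$cv_rmse <- vapply(models, `[[`, 0, "cv_rmse")

  scatter <- dplyr::bind_rows(lapply(models, function(m) {
    tibble::tibble(
      algorithm = m$algorithm,
      simulated = test[[m$target]],
      predicted = predict_backend(m$algorithm, m$fit,
                                  feature_matrix(test, m$features))
    )
  }))

  if (!is.null(validation)) {
    fe <- validation$post_op_ci_pct
    preds <- vapply(models, function(m) {
      suppressWarnings(predict_ci(m, validation)$.pred)
    }, 0)
    metrics$validation_pred <- preds[metrics$algorithm]
    metrics$percent_error <-
      abs(metrics$validation_pred - fe) / fe * 100
  }
  metrics <- dplyr::arrange(metrics, dplyr::desc(.data$r2))
  metrics$rank <- seq_len(nrow(metrics))

  structure(
    list(metrics = metrics, scatter = scatter, models = models,
         validation = validation),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(as.data.frame(x$metrics), digits = 4)
  invisible(x)
}

#' @rdname compare_models
#' @param x,object A `model_comparison`.
#' @param ... Ignored.
#' @export
tidy.model_comparison <- function(x, ...) x$metrics

#' @rdname compare_models
#' @export
glance.model_comparison <- function(x, ...) {
  best <- x$metrics[1, ]
  tibble::tibble(
    n_models = nrow(x$metrics),
    best_algorithm = best$algorithm,
    best_r2 = best$r2,
    best_rmse = best$rmse
  )
}

#' @rdname compare_models
#' @export
autoplot.model_comparison <- function(object, ...) {
  lab <- object$metrics
  lab$label <- sprintf("RMSE %.2f, R² %.2f", lab$rmse, lab$r2)
  ggplot2::ggplot(object$scatter,
                  ggplot2::aes(x = .data$simulated, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_text(
      data = lab, inherit.aes = FALSE,
      ggplot2::aes(x = -Inf, y = Inf, label = .data$label),
      hjust = -0.05, vjust = 1.5, size = 3
    ) +
    ggplot2::facet_wrap(~algorithm) +
    ggplot2::labs(
      x = "simulated post-op CI [%]", y = "predicted post-op CI [%]",
      title = "Surrogate predictions vs finite-element simulations"
    )
}
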