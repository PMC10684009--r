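#' Hyperparameter search-space primitives
#'
#' Declare one dimension of a search space: continuous (`p_uniform`,
#' `p_loguniform`), integer-quantised (`p_quniform`) or categorical
#' (`p_choice`).
#'
#' @param low,high Range bounds (inclusive; `p_loguniform` bounds are on the
#'   natural scale and must be positive).
#' @param values Candidate values for `p_choice`.
#' @return A parameter definition used in a search-space list.
#' @name search-space
NULL

#' @rdname search-space
#' @export
p_uniform <- function(low, high) {
  stopifnot(is.finite(low), is.finite(high), low < high)
  list(type = "uniform", low = low, high = high)
}

#' @rdname search-space
#' @export
p_loguniform <- function(low, high) {
  stopifnot(is.finite(low), is.finite(high), 0 < low, low < high)
  list(type = "loguniform", low = low, high = high)
}

#' @rdname search-space
#' @export
p_quniform <- function(low, high) {
  stopifnot(is.finite(low), is.finite(high), low < high)
  list(type = "quniform", low = low, high = high)
}

#' @rdname search-space
#' @export
p_choice <- function(values) {
  stopifnot(length(values) >= 1)
  list(type = "choice", values = values)
}

# draw one random configuration from the prior
tpe_sample_prior <- function(space) {
  lapply(space, function(def) {
    switch(def$type,
      uniform = runif(1, def$low, def$high),
      loguniform = exp(runif(1, log(def$low), log(def$high))),
      quniform = as.integer(round(runif(1, def$low, def$high))),
      choice = def$values[[sample.int(length(def$values), 1)]]
    )
  })
}

# transform an observed value to the modelling scale
tpe_transform <- function(def, x) {
  switch(def$type,
    uniform = as.numeric(x),
    loguniform = log(as.numeric(x)),
    quniform = as.numeric(x),
    choice = match(x, def$values)
  )
}

tpe_back <- function(def, z) {
  switch(def$type,
    uniform = min(max(z, def$low), def$high),
    loguniform = exp(min(max(z, log(def$low)), log(def$high))),
    quniform = as.integer(min(max(round(z), def$low), def$high)),
    choice = def$values[[z]]
  )
}

# Parzen estimator for one continuous dimension: mixture of Gaussians at the
# observations plus a uniform prior component over the range.
tpe_parzen <- function(obs, lo, hi) {
  n <- length(obs)
  bw <- max(1.06 * stats::sd(obs) * n^(-1 / 5), (hi - lo) / 50)
  if (!is.finite(bw) || bw <= 0) bw <- (hi - lo) / 10
  list(obs = obs, bw = bw, lo = lo, hi = hi, w_prior = 1 / (n + 1))
}

tpe_parzen_sample <- function(pz) {
  if (runif(1) < pz$w_prior) {
    runif(1, pz$lo, pz$hi)
  } else {
    i <- sample.int(length(pz$obs), 1)
    min(max(rnorm(1, pz$obs[i], pz$bw), pz$lo), pz$hi)
  }
}

tpe_parzen_density <- function(pz, x) {
  d <- mean(dnorm(x, pz$obs, pz$bw))
  pz$w_prior / (pz$hi - pz$lo) + (1 - pz$w_prior) * d
}

#' Sequential model-based optimisation with a tree of Parzen estimators
#'
#' Minimises a black-box objective over a declared search space. The first
#' `n_startup` trials are drawn from the prior; afterwards the observed
#' trials are split at the `gamma` loss quantile into a "good" and a "bad"
#' set, each modelled per dimension by a Parzen (kernel-density) estimator
#' with a uniform prior component (categorical dimensions use smoothed
#' frequencies). Candidates are drawn from the good-set density and the one
#' maximising the good/bad density ratio — the expected-improvement proxy —
#' is evaluated next.
#'
#' Deterministic given the R random seed: with the same seed the first `b`
#' trials of a longer run coincide with a budget-`b` run, so the best loss
#' is non-increasing in budget.
#'
#' @param space Named list of [p_uniform()]/[p_loguniform()]/[p_quniform()]/
#'   [p_choice()] definitions. May be empty (the objective is evaluated once
#'   with no parameters).
#' @param objective `function(params)` returning a finite scalar loss
#'   (smaller is better). Trials whose objective throws are recorded with
#'   loss `Inf` and skipped.
#' @param budget Number of trials.
#' @param n_startup Random-search warm-up trials before the Parzen model is
#'   used.
#' @param gamma Quantile defining the good set.
#' @param n_candidates Candidates scored per TPE step.
#' @return List: `best_params`, `best_loss`, and the trial log `trials`
#'   (tibble with `trial`, `loss`, and a `params` list-column).
#' @export
tpe_optimize <- function(space, objective, budget,
                         n_startup = 10, gamma = 0.25, n_candidates = 24) {
  stopifnot(budget >= 1)
  if (length(space) == 0) {
    loss <- objective(list())
    return(list(
      best_params = list(), best_loss = loss,
      trials = tibble::tibble(trial = 1L, loss = loss, params = list(list()))
    ))
  }
  losses <- numeric(budget)
  configs <- vector("list", budget)
  for (i in seq_len(budget)) {
    done <- which(is.finite(losses[seq_len(i - 1)]))
    if (i <= n_startup || length(done) < max(4, n_startup / 2)) {
      cand <- tpe_sample_prior(space)
    } else {
      ord <- done[order(losses[done])]
      n_good <- max(2L, ceiling(gamma * length(ord)))
      good <- ord[seq_len(n_good)]
      bad <- ord[-seq_len(n_good)]
      if (length(bad) < 2) bad <- ord
      models <- lapply(names(space), function(nm) {
        def <- space[[nm]]
        g_obs <- vapply(configs[good], function(cc) tpe_transform(def, cc[[nm]]), 0)
        b_obs <- vapply(configs[bad], function(cc) tpe_transform(def, cc[[nm]]), 0)
        if (def$type == "choice") {
          k <- length(def$values)
          pg <- (tabulate(g_obs, k) + 1) / (length(g_obs) + k)
          pb <- (tabulate(b_obs, k) + 1) / (length(b_obs) + k)
          list(type = "choice", pg = pg, pb = pb)
        } else {
          lo <- if (def$type == "loguniform") log(def$low) else def$low
          hi <- if (def$type == "loguniform") log(def$high) else def$high
          list(type = "cont",
               g = tpe_parzen(g_obs, lo, hi),
               b = tpe_parzen(b_obs, lo, hi))
        }
      })
      names(models) <- names(space)
      best_score <- -Inf
      cand <- NULL
      for (k in seq_len(n_candidates)) {
        trial_cand <- list()
        score <- 0
        for (nm in names(space)) {
          def <- space[[nm]]
          mod <- models[[nm]]
          if (mod$type == "choice") {
            z <- sample.int(length(def$values), 1, prob = mod$pg)
            score <- score + log(mod$pg[z]) - log(mod$pb[z])
          } else {
            z <- tpe_parzen_sample(mod$g)
            score <- score + log(tpe_parzen_density(mod$g, z)) -
              log(tpe_parzen_density(mod$b, z))
          }
          trial_cand[[nm]] <- tpe_back(def, z)
        }
        if (score > best_score) {
          best_score <- score
          cand <- trial_cand
        }
      }
    }
    configs[[i]] <- cand
    losses[i] <- tryCatch({
      v <- objective(cand)
      if (!is.numeric(v) || length(v) != 1 || is.na(v)) Inf else v
    }, error = function(e) Inf)
  }
  if (all(!is.finite(losses))) {
    abort(
      "all tuning trials failed.",
      trials = tibble::tibble(
        trial = seq_len(budget), loss = losses, params = configs
      )
    )
  }
  best <- which.min(losses)
  list(
    best_params = configs[[best]],
    best_loss = losses[best],
    trials = tibble::tibble(
      trial = seq_len(budget), loss = losses, params = configs
    )
  )
}
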