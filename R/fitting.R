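# Two-stage ensemble inference: embedded linear scale fit, log-scale loss,
# global random seed search, Nelder-Mead refinement, percentile summaries.

#' Default search bounds for the global seed search
#'
#' Uniform sampling ranges for the six coordinates
#' `(log10_k1, m, log10_k2, n, log10_kA, log10_kB)`.  The defaults envelope
#' the full span of ensemble fit results observed across the four LuxR
#' variants (log10 kB reaching 15 on one side and -5.5 on the other) with
#' margin: log10 k1, log10 k2 in [-6, 8]; log10 kA, log10 kB in [-6, 16];
#' m, n in [0.05, 4].
#'
#' @param log10_k1,log10_k2,log10_kA,log10_kB,m,n length-2 `c(low, high)`
#'   ranges.
#' @return A 2 x 6 matrix with rows `low`, `high` and the canonical
#'   coordinate order as columns.
#' @export
search_bounds <- function(log10_k1 = c(-6, 8), m = c(0.05, 4),
                          log10_k2 = c(-6, 8), n = c(0.05, 4),
                          log10_kA = c(-6, 16), log10_kB = c(-6, 16)) {
  b <- cbind(log10_k1 = log10_k1, m = m, log10_k2 = log10_k2, n = n,
             log10_kA = log10_kA, log10_kB = log10_kB)
  rownames(b) <- c("low", "high")
  if (any(b["low", ] >= b["high", ]))
    stop("each bound must satisfy low < high", call. = FALSE)
  if (b["low", "m"] <= 0 || b["low", "n"] <= 0)
    stop("Hill coefficient bounds must be positive", call. = FALSE)
  b
}

#' Fitting options
#'
#' @param max_iter Nelder-Mead iteration cap.
#' @param reltol relative convergence tolerance on the loss spread of the
#'   simplex.
#' @param eps_sqrt floor on model sqrt-luminescence, see [luminescence()].
#' @param closure conservation closure, see [solve_free_luxr()].
#' @param hill_floor hard lower limit on `m`, `n` inside the optimizer;
#'   non-positive Hill exponents are meaningless and are repelled by a
#'   penalty.
#' @return A list of class `"fit_options"`.
#' @export
fit_options <- function(max_iter = 2000L, reltol = 1e-8, eps_sqrt = 1e-3,
                        closure = "stoichiometric", hill_floor = 0.01) {
  structure(list(max_iter = as.integer(max_iter), reltol = reltol,
                 eps_sqrt = eps_sqrt, closure = closure,
                 hill_floor = hill_floor),
            class = "fit_options")
}

degenerate_fit_error <- function(msg) {
  stop(errorCondition(msg, class = c("luxrfit_degenerate_fit", "error")))
}

#' Linear scale fit of model occupancy to measured luminescence
#'
#' Given occupancies `P` over the plate and the measured luminescence, finds
#' the baseline and gain `(a0, a1)` minimizing
#' `sum((sqrt(L_data) - (a0 + a1 * P))^2)` over non-missing wells — an
#' ordinary unconstrained linear least squares in the square-root domain.
#'
#' @param P occupancy matrix or vector over the plate wells.
#' @param L_data measured specific luminescence, same shape; `NA` wells are
#'   excluded.
#' @return A [scale_params()] object.
#' @section Errors: if fewer than two wells remain or all their occupancies
#'   coincide, the normal equations are singular and a condition of class
#'   `"luxrfit_degenerate_fit"` is signalled.
#' @export
fit_scale <- function(P, L_data) {
  if (length(P) != length(L_data))
    stop("P and L_data must have the same shape", call. = FALSE)
  ok <- !is.na(L_data)
  x <- as.numeric(P)[ok]
  y <- sqrt(as.numeric(L_data)[ok])
  if (length(x) < 2L)
    degenerate_fit_error("fewer than two usable wells")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= .Machine$double.eps * length(x) * max(1, mean(x)^2))
    degenerate_fit_error("all occupancies equal: scale fit is singular")
  a1 <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a0 <- mean(y) - a1 * mean(x)
  scale_params(a0, a1)
}

#' Log-scale sum-of-squares loss
#'
#' The loss compared during fitting is
#' `sum((log10(L_data) - log10(L_model))^2)` over non-missing wells: the
#' luminescence spans several decades and its uncertainty is closer to
#' proportional than absolute, so residuals are taken on a logarithmic scale.
#' Both matrices are floored at `floor` before logging so that
#' zero-luminescence wells contribute finitely instead of being discarded.
#'
#' @param L_model predicted luminescence matrix.
#' @param L_data measured luminescence matrix, same shape.
#' @param floor positive floor applied before `log10`; defaults to
#'   `1e-6 * max(L_data)`.
#' @return Non-negative scalar loss; 0 iff the floored matrices agree.
#' @export
log_sse <- function(L_model, L_data, floor = NULL) {
  if (length(L_model) != length(L_data))
    stop("model and data matrices must have the same shape", call. = FALSE)
  if (is.null(floor)) floor <- 1e-6 * max(L_data, na.rm = TRUE)
  if (!is.finite(floor) || floor <= 0) floor <- 1e-12
  ok <- !is.na(L_data)
  d <- log10(pmax(as.numeric(L_data)[ok], floor)) -
       log10(pmax(as.numeric(L_model)[ok], floor))
  sum(d^2)
}

#' Fitting objective: loss of one parameter set against one plate
#'
#' One evaluation of the model-to-data discrepancy: computes occupancy over
#' the plate's concentration grid, finds the optimal `(a0, a1)` by the
#' embedded linear scale fit, forms the predicted luminescence and returns
#' the log-scale loss together with the embedded scale.
#'
#' @param params a [kinetic_params()] object.
#' @param data a [plate_grid()].
#' @param options a [fit_options()] list.
#' @return List with elements `loss` and `scale`.
#' @export
objective <- function(params, data, options = fit_options()) {
  stopifnot(inherits(data, "plate_grid"))
  P <- occupancy_grid(data$c8_levels, data$c6_levels, params,
                      closure = options$closure)
  sc <- fit_scale(P, data$L)
  L_model <- luminescence(P, sc, eps_sqrt = options$eps_sqrt)
  list(loss = log_sse(L_model, data$L), scale = sc)
}

# Penalized objective value for the optimizer: finite everywhere, repels
# non-positive Hill exponents, maps degenerate scale fits to a large value.
objective_value <- function(par, data, options) {
  if (par[2L] <= options$hill_floor || par[4L] <= options$hill_floor)
    return(1e10 * (1 + abs(min(par[2L], par[4L]))))
  v <- tryCatch(objective(as_kinetic_params(par), data, options)$loss,
                error = function(e) Inf)
  if (!is.finite(v)) 1e10 else v
}

#' Refine one seed by Nelder-Mead simplex search
#'
#' Runs an unconstrained Nelder-Mead search (via [stats::optim()]) in the six
#' coordinates from the given seed, with the scale parameters re-fit linearly
#' inside every objective evaluation.  The returned loss never exceeds the
#' seed's own objective (the best simplex vertex is monotone).
#'
#' @param seed starting [kinetic_params()] (or 6-vector).
#' @param data a [plate_grid()].
#' @param options a [fit_options()] list.
#' @param seed_index,dataset_id labels carried into the result for ensemble
#'   bookkeeping.
#' @return A list of class `"fit_result"` with elements `params`, `scale`,
#'   `loss`, `seed_loss`, `converged`, `iterations`, `seed_index`,
#'   `dataset_id`.
#' @export
local_fit <- function(seed, data, options = fit_options(),
                      seed_index = NA_integer_, dataset_id = NA_character_) {
  seed <- as_kinetic_params(seed)
  seed_loss <- objective_value(as.numeric(seed), data, options)
  if (!is.finite(seed_loss))
    stop("objective is not finite at the seed", call. = FALSE)
  opt <- stats::optim(as.numeric(seed), objective_value,
                      data = data, options = options,
                      method = "Nelder-Mead",
                      control = list(maxit = options$max_iter,
                                     reltol = options$reltol))
  params <- as_kinetic_params(opt$par)
  sc <- tryCatch(objective(params, data, options)$scale,
                 error = function(e) NULL)
  structure(list(params = params, scale = sc,
                 loss = min(opt$value, seed_loss),
                 seed_loss = seed_loss,
                 converged = opt$convergence == 0L,
                 iterations = unname(opt$counts["function"]),
                 seed_index = seed_index, dataset_id = dataset_id),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit result (loss %.4g, %s, %d evaluations)\n", x$loss,
              if (x$converged) "converged" else "iteration cap hit",
              x$iterations))
  print(x$params)
  if (!is.null(x$scale)) print(x$scale)
  invisible(x)
}

#' Global random seed search
#'
#' Samples `n_points` parameter sets uniformly over the search bounds
#' (uniform in log10 for the four dissociation constants, linear in the Hill
#' coefficients), evaluates the fitting objective at each, and keeps the
#' `n_keep` best as seeds for local refinement.  The reference procedure
#' draws 30,000 points and retains the best 50.
#'
#' @param data a [plate_grid()] the objective is evaluated against.
#' @param n_points number of random points.
#' @param n_keep number of best points retained (`<= n_points`).
#' @param bounds a [search_bounds()] matrix.
#' @param rng_seed integer seed making the draw reproducible; `NULL` leaves
#'   the RNG state untouched.
#' @param options a [fit_options()] list.
#' @return A data frame of class `"luxr_seeds"`: the six parameter columns
#'   plus `loss`, sorted by ascending loss.
#' @export
global_seed_search <- function(data, n_points = 30000L, n_keep = 50L,
                               bounds = search_bounds(), rng_seed = NULL,
                               options = fit_options()) {
  if (n_keep > n_points)
    stop("n_keep must not exceed n_points", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  draws <- vapply(param_names(), function(pn) {
    stats::runif(n_points, bounds["low", pn], bounds["high", pn])
  }, numeric(n_points))
  draws <- matrix(draws, nrow = n_points,
                  dimnames = list(NULL, param_names()))
  losses <- apply(draws, 1L, objective_value, data = data, options = options)
  keep <- order(losses)[seq_len(n_keep)]
  out <- data.frame(draws[keep, , drop = FALSE], loss = losses[keep])
  class(out) <- c("luxr_seeds", "data.frame")
  out
}

seed_params <- function(seeds, i) {
  as_kinetic_params(as.numeric(seeds[i, param_names()]))
}

#' Ensemble fit: every seed against every replicate dataset
#'
#' Runs [local_fit()] for each (seed, dataset) pair, giving
#' `n_keep * n_datasets` independent optimizations per strain (50 seeds x 3
#' replicate plates = 150 in the reference procedure).  Replicate plates are
#' fit separately, never averaged.
#'
#' @param datasets a [plate_grid()] or list of them; list names become
#'   `dataset_id` labels (defaults `plate1`, `plate2`, ...).
#' @param seeds a `"luxr_seeds"` data frame from [global_seed_search()], or a
#'   list of [kinetic_params()].
#' @param options a [fit_options()] list.
#' @return A list of `"fit_result"` objects with class `"luxr_ensemble"`;
#'   see [as.data.frame.luxr_ensemble()].
#' @export
ensemble_fit <- function(datasets, seeds, options = fit_options()) {
  if (inherits(datasets, "plate_grid")) datasets <- list(datasets)
  if (length(datasets) < 1L) stop("need at least one dataset", call. = FALSE)
  ids <- names(datasets)
  if (is.null(ids)) ids <- paste0("plate", seq_along(datasets))
  if (inherits(seeds, "luxr_seeds")) {
    seed_list <- lapply(seq_len(nrow(seeds)), seed_params, seeds = seeds)
  } else if (inherits(seeds, "kinetic_params")) {
    seed_list <- list(seeds)
  } else {
    seed_list <- lapply(seeds, as_kinetic_params)
  }
  if (length(seed_list) < 1L) stop("need at least one seed", call. = FALSE)
  fits <- vector("list", length(seed_list) * length(datasets))
  k <- 0L
  for (d in seq_along(datasets)) {
    for (s in seq_along(seed_list)) {
      k <- k + 1L
      fits[[k]] <- local_fit(seed_list[[s]], datasets[[d]], options,
                             seed_index = s, dataset_id = ids[d])
    }
  }
  structure(fits, class = "luxr_ensemble")
}

#' Flatten an ensemble of fits to a data frame
#'
#' @param x a `"luxr_ensemble"` list from [ensemble_fit()].
#' @param ... unused.
#' @return One row per fit: labels, the six parameters, `a0`, `a1`, `loss`,
#'   `seed_loss`, `converged`, `iterations`.
#' @export
as.data.frame.luxr_ensemble <- function(x, ...) {
  rows <- lapply(x, function(f) {
    p <- as.numeric(f$params)
    data.frame(seed_index = f$seed_index, dataset_id = f$dataset_id,
               log10_k1 = p[1L], m = p[2L], log10_k2 = p[3L], n = p[4L],
               log10_kA = p[5L], log10_kB = p[6L],
               a0 = if (is.null(f$scale)) NA_real_ else f$scale$a0,
               a1 = if (is.null(f$scale)) NA_real_ else f$scale$a1,
               loss = f$loss, seed_loss = f$seed_loss,
               converged = f$converged, iterations = f$iterations)
  })
  do.call(rbind, rows)
}

#' Percentile summary of an ensemble of fits
#'
#' Per-parameter median and 20th/25th/75th/80th percentiles over all fits in
#' the ensemble, using the linear-interpolation quantile convention
#' ([stats::quantile()] type 7).  The 20-80 band is the uncertainty range
#' reported for each parameter; the 25-75 band matches the histogram boxes.
#'
#' @param results a `"luxr_ensemble"` list or its data-frame form.
#' @return Data frame of class `"ensemble_summary"`, one row per parameter,
#'   columns `parameter`, `median`, `p20`, `p25`, `p75`, `p80`; the number of
#'   fits is in attribute `n_fits`.
#' @export
summarize_ensemble <- function(results) {
  df <- if (is.data.frame(results)) results else as.data.frame(results)
  if (nrow(df) < 1L) stop("no fit results to summarize", call. = FALSE)
  qs <- t(vapply(param_names(), function(pn) {
    stats::quantile(df[[pn]], c(0.5, 0.2, 0.25, 0.75, 0.8),
                    names = FALSE, type = 7)
  }, numeric(5)))
  out <- data.frame(parameter = param_names(),
                    median = qs[, 1L], p20 = qs[, 2L], p25 = qs[, 3L],
                    p75 = qs[, 4L], p80 = qs[, 5L], row.names = NULL)
  attr(out, "n_fits") <- nrow(df)
  class(out) <- c("ensemble_summary", "data.frame")
  out
}

#' Extract the per-parameter medians of a summary as kinetic parameters
#'
#' @param summary an `"ensemble_summary"` data frame.
#' @return A [kinetic_params()] built from the medians.
#' @export
summary_medians <- function(summary) {
  as_kinetic_params(summary$median[match(param_names(), summary$parameter)])
}
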