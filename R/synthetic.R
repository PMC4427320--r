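# Synthetic well-plate generator: strain presets, multiplicative lognormal
# noise, and a parameter-recovery harness for the full pipeline.

#' Standard two-signal concentration design
#'
#' The 8 x 8 factorial design used on the well plates: final concentrations
#' of 0, 12.5, 25, 100, 400, 800, 1600 and 3200 nM for C8-HSL along one axis
#' and the same levels for 3OC6-HSL along the other, 64 wells in total.
#'
#' @return List with elements `c8` and `c6`, each the 8-level nM vector.
#' @export
default_grid <- function() {
  lv <- c(0, 12.5, 25, 100, 400, 800, 1600, 3200)
  list(c8 = lv, c6 = lv)
}

# Median ensemble-fit parameter estimates for the four LuxR variants
# (log10_k1, m, log10_k2, n, log10_kA, log10_kB).
preset_table <- list(
  MJ1   = c(0.46, 0.27, 5.3, 1.51, 3.2, -4.5),
  ES114 = c(1.3, 0.61, 2.7, 1.3, 2.4, -1.7),
  A     = c(2.6, 1.23, 2.63, 1.15, 0.27, 0.41),
  B     = c(3.5, 1.6, 2.2, 0.34, -1.8, 5.3)
)

#' Canned LuxR variant presets
#'
#' Median ensemble-fit parameters for the four LuxR variants studied with
#' this model: the wild-type receptors `"MJ1"` and `"ES114"` (strongly
#' 3OC6-HSL-preferring), the near-neutral `"A"`, and `"B"` whose preferences
#' are reversed toward C8-HSL.  The default luminescence scale is
#' `a0 = 10, a1 = 550`, typical of the experimental datasets.
#'
#' @param name one of `"MJ1"`, `"ES114"`, `"A"`, `"B"`.
#' @return List of class `"strain_preset"` with elements `name`, `params`
#'   (a [kinetic_params()]) and `scale` (a [scale_params()]).
#' @export
#' @examples
#' strain_preset("A")$params
strain_preset <- function(name = c("MJ1", "ES114", "A", "B")) {
  name <- match.arg(name)
  structure(list(name = name,
                 params = as_kinetic_params(preset_table[[name]]),
                 scale = scale_params(10, 550)),
            class = "strain_preset")
}

#' Multiplicative measurement-noise model
#'
#' Well-level proportional noise: each well's luminescence is multiplied by
#' an i.i.d. lognormal factor with mean 1 and coefficient of variation `cv`
#' (`sdlog = sqrt(log(1 + cv^2))`, `meanlog = -sdlog^2 / 2`).  Proportional
#' rather than additive noise matches the use of a log-scale fitting loss.
#' `cv = 0` reproduces the deterministic surface exactly.
#'
#' @param cv coefficient of variation, >= 0; default 0.15.
#' @param rng_seed integer seed for reproducible draws; `NULL` leaves the
#'   RNG state untouched.
#' @return List of class `"noise_model"`.
#' @export
noise_model <- function(cv = 0.15, rng_seed = NULL) {
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  structure(list(cv = cv, distribution = "lognormal", rng_seed = rng_seed),
            class = "noise_model")
}

#' Simulate one well plate from the forward model
#'
#' Evaluates the deterministic response surface at the given parameters and
#' applies multiplicative lognormal noise well by well.
#'
#' @param params a [kinetic_params()] object.
#' @param scale a [scale_params()] object.
#' @param grid concentration design, as from [default_grid()].
#' @param noise a [noise_model()].
#' @param meta named list attached to the plate.
#' @inheritParams solve_free_luxr
#' @return A [plate_grid()] of noisy specific luminescence.
#' @export
simulate_plate <- function(params, scale = scale_params(10, 550),
                           grid = default_grid(), noise = noise_model(),
                           meta = list(),
                           closure = c("stoichiometric", "unweighted")) {
  closure <- match.arg(closure)
  surf <- response_surface(grid$c8, grid$c6, params, scale, closure = closure)
  if (noise$cv > 0) {
    if (!is.null(noise$rng_seed)) set.seed(noise$rng_seed)
    sdlog <- sqrt(log1p(noise$cv^2))
    eps <- stats::rlnorm(length(surf), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    surf <- surf * matrix(eps, nrow = nrow(surf))
  }
  plate_grid(grid$c8, grid$c6, surf, meta)
}

#' Simulate replicate plates
#'
#' Convenience wrapper producing `n_replicates` independent plates; when the
#' noise model carries a seed, replicate `i` uses `rng_seed + i - 1` so
#' replicates differ but the set is reproducible.
#'
#' @inheritParams simulate_plate
#' @param n_replicates number of plates.
#' @return Named list of [plate_grid()] objects (`rep1`, `rep2`, ...).
#' @export
simulate_replicates <- function(params, scale = scale_params(10, 550),
                                n_replicates = 3L, grid = default_grid(),
                                noise = noise_model(), meta = list(),
                                closure = "stoichiometric") {
  plates <- lapply(seq_len(n_replicates), function(i) {
    nm <- noise
    if (!is.null(nm$rng_seed)) nm$rng_seed <- nm$rng_seed + i - 1L
    simulate_plate(params, scale, grid, nm,
                   meta = c(meta, list(replicate = i)), closure = closure)
  })
  names(plates) <- paste0("rep", seq_len(n_replicates))
  plates
}

#' Parameter-recovery experiment on synthetic plates
#'
#' End-to-end check of the inference pipeline: simulate replicate plates from
#' known parameters, run the global seed search on the first plate, refine
#' every retained seed against every plate, summarize the ensemble, and
#' compare the per-parameter medians and 20-80 percentile intervals with the
#' truth.
#'
#' @param truth a [strain_preset()], or a list with elements `params` and
#'   `scale`.
#' @param n_replicates number of simulated replicate plates.
#' @param noise a [noise_model()]; its seed (offset per replicate) controls
#'   the simulated data.
#' @param n_points,n_keep global-search settings (see [global_seed_search()]).
#' @param bounds a [search_bounds()] matrix.
#' @param rng_seed seed for the global search draw.
#' @param options a [fit_options()] list.
#' @param grid concentration design.
#' @return List of class `"recovery_report"` with elements `report` (data
#'   frame: `parameter`, `truth`, `median`, `p20`, `p80`, `abs_error`,
#'   `covered`), `summary`, `ensemble` and `plates`.
#' @export
recovery_experiment <- function(truth, n_replicates = 3L,
                                noise = noise_model(cv = 0.10, rng_seed = 1L),
                                n_points = 3000L, n_keep = 10L,
                                bounds = search_bounds(), rng_seed = 1L,
                                options = fit_options(),
                                grid = default_grid()) {
  if (n_replicates < 1L) stop("need at least one replicate", call. = FALSE)
  params <- as_kinetic_params(truth$params)
  scale <- truth$scale
  plates <- simulate_replicates(params, scale, n_replicates, grid, noise,
                                closure = options$closure)
  seeds <- global_seed_search(plates[[1L]], n_points = n_points,
                              n_keep = n_keep, bounds = bounds,
                              rng_seed = rng_seed, options = options)
  ens <- ensemble_fit(plates, seeds, options)
  summ <- summarize_ensemble(ens)
  tv <- as.numeric(params)[match(summ$parameter, param_names())]
  report <- data.frame(parameter = summ$parameter, truth = tv,
                       median = summ$median, p20 = summ$p20, p80 = summ$p80,
                       abs_error = abs(summ$median - tv),
                       covered = summ$p20 <= tv & tv <= summ$p80,
                       row.names = NULL)
  structure(list(report = report, summary = summ, ensemble = ens,
                 plates = plates),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d fits:\n",
              attr(x$summary, "n_fits")))
  print(x$report, digits = 4)
  invisible(x)
}
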