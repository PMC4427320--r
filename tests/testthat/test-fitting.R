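# Scale fit, log-scale loss, objective, local refinement, seed search,
# ensemble bookkeeping and percentile summaries.

test_that("embedded scale fit recovers the linear map on sqrt luminescence", {
  # noiseless recovery over a realistic occupancy spread
  P <- seq(0, 0.8, length.out = 20)
  L <- (10 + 550 * P)^2
  sc <- fit_scale(P, L)
  expect_equal(sc$a0, 10, tolerance = 1e-10)
  expect_equal(sc$a1, 550, tolerance = 1e-10)

  # two wells: exact interpolation
  sc2 <- fit_scale(c(0, 1), c(100, 400))
  expect_equal(sc2$a0, 10)
  expect_equal(sc2$a1, 10)

  # NA wells are excluded, not propagated
  L3 <- L; L3[5] <- NA
  sc3 <- fit_scale(P, L3)
  expect_equal(sc3$a1, 550, tolerance = 1e-10)

  # constant occupancy makes the normal equations singular
  expect_error(fit_scale(rep(0.3, 10), L[1:10]),
               class = "luxrfit_degenerate_fit")
})

test_that("log-scale loss sums squared decade discrepancies over usable wells", {
  L <- matrix(c(100, 1000, 50, 2), 2, 2)
  expect_equal(log_sse(L, L), 0)
  expect_equal(log_sse(100, 1000), 1)          # one decade
  expect_equal(log_sse(c(100, 100), c(1000, 10)), 2)  # symmetric in ratio
  Lna <- L; Lna[2, 2] <- NA
  expect_equal(log_sse(L + 0, Lna), 0)
  expect_error(log_sse(L, L[1, ]), "shape")
})

test_that("objective composes occupancy, scale fit and log loss", {
  pr <- strain_preset("A")
  plate <- noiseless_plate("A")
  ob <- objective(pr$params, plate)
  expect_lte(ob$loss, 1e-12)
  expect_equal(ob$scale$a0, 10, tolerance = 1e-6)
  expect_equal(ob$scale$a1, 550, tolerance = 1e-6)

  # perturbing a sensitive parameter must cost something
  shifted <- as.numeric(pr$params); shifted[1] <- shifted[1] + 0.5
  expect_gt(objective(as_kinetic_params(shifted), plate)$loss, 1e-4)

  # hand-composed pipeline on a small grid equals the packaged objective
  p <- kinetic_params(2, 1, 2, 1, 1, 1)
  grid <- list(c8 = c(0, 100), c6 = c(0, 100))
  Pm <- rbind(occupancy(c(0, 100), 0, p), occupancy(c(0, 100), 100, p))
  Pm <- t(Pm)  # rows = c8, cols = c6
  L_data <- (10 + 550 * Pm)^2 * 1.1  # 10% over the model everywhere
  plate2 <- plate_grid(grid$c8, grid$c6, L_data)
  sc <- fit_scale(Pm, L_data)
  by_hand <- log_sse(luminescence(Pm, sc), L_data)
  expect_equal(objective(p, plate2)$loss, by_hand, tolerance = 1e-12)
})

test_that("objective is invariant under signal-role swap plus data transpose", {
  set.seed(21)
  pr <- strain_preset("ES114")
  plate <- simulate_plate(pr$params, pr$scale,
                          noise = noise_model(0.1, rng_seed = 7))
  p <- random_params()
  swapped <- kinetic_params(p[["log10_k2"]], p[["n"]], p[["log10_k1"]],
                            p[["m"]], p[["log10_kB"]], p[["log10_kA"]])
  plate_t <- plate_grid(plate$c6_levels, plate$c8_levels, t(plate$L))
  expect_equal(objective(p, plate)$loss, objective(swapped, plate_t)$loss,
               tolerance = 1e-10)
})

test_that("local refinement descends from its seed and recovers a shifted parameter", {
  pr <- strain_preset("A")
  plate <- noiseless_plate("A")

  # seed at the truth: already at the optimum
  fit0 <- local_fit(pr$params, plate)
  expect_lte(fit0$loss, 1e-10)
  expect_equal(as.numeric(fit0$params), as.numeric(pr$params),
               tolerance = 0.01)

  # seed with log10_k1 shifted +0.5: Nelder-Mead pulls it back
  shifted <- as.numeric(pr$params); shifted[1] <- shifted[1] + 0.5
  fit1 <- local_fit(shifted, plate)
  expect_lte(fit1$loss, fit1$seed_loss)
  expect_equal(fit1$params[["log10_k1"]], pr$params[["log10_k1"]],
               tolerance = 0.05)

  # iteration cap is honored and flagged
  fit2 <- local_fit(shifted, plate, fit_options(max_iter = 1))
  expect_false(fit2$converged)
  expect_lte(fit2$loss, fit2$seed_loss)

  # descent holds from arbitrary finite seeds too
  set.seed(22)
  for (i in 1:3) {
    s <- random_params()
    f <- local_fit(s, plate, fit_options(max_iter = 150))
    expect_lte(f$loss, f$seed_loss)
  }
})

test_that("global seed search is uniform-in-bounds, sorted and reproducible", {
  plate <- noiseless_plate("A")
  b <- search_bounds()
  s1 <- global_seed_search(plate, n_points = 150, n_keep = 20,
                           bounds = b, rng_seed = 5)
  expect_equal(nrow(s1), 20)
  expect_false(is.unsorted(s1$loss))
  for (pn in colnames(b)) {
    expect_true(all(s1[[pn]] >= b["low", pn] & s1[[pn]] <= b["high", pn]))
  }
  # determinism contract
  s2 <- global_seed_search(plate, n_points = 150, n_keep = 20,
                           bounds = b, rng_seed = 5)
  expect_identical(s1, s2)
  # n_keep = n_points returns the whole sample; over-asking errors
  s3 <- global_seed_search(plate, n_points = 30, n_keep = 30, rng_seed = 5)
  expect_equal(nrow(s3), 30)
  expect_error(global_seed_search(plate, n_points = 10, n_keep = 11),
               "n_keep")
})

test_that("ensemble fit labels every seed-dataset pair exactly once", {
  pr <- strain_preset("A")
  plates <- simulate_replicates(pr$params, pr$scale, n_replicates = 2,
                                noise = noise_model(0.1, rng_seed = 3))
  seeds <- list(pr$params,
                as_kinetic_params(as.numeric(pr$params) + 0.1))
  ens <- ensemble_fit(plates, seeds, fit_options(max_iter = 5))
  df <- as.data.frame(ens)
  expect_equal(nrow(df), 4)
  expect_equal(nrow(unique(df[, c("seed_index", "dataset_id")])), 4)
  expect_setequal(unique(df$dataset_id), c("rep1", "rep2"))

  ens1 <- ensemble_fit(plates[[1]], list(pr$params),
                       fit_options(max_iter = 5))
  expect_length(ens1, 1)
})

test_that("ensemble summaries use linear-interpolation percentiles", {
  # one parameter varying, others constant, to probe the quantile rule
  mk <- function(vals) {
    data.frame(log10_k1 = vals, m = 1, log10_k2 = vals, n = 1,
               log10_kA = 1, log10_kB = 1)
  }
  s <- summarize_ensemble(mk(c(1, 2, 3, 4, 5)))
  expect_equal(s$median[s$parameter == "log10_k1"], 3)
  expect_equal(attr(s, "n_fits"), 5)

  s100 <- summarize_ensemble(mk(1:100))
  expect_equal(s100$p20[s100$parameter == "log10_k1"], 20.8)
  expect_equal(s100$p80[s100$parameter == "log10_k1"], 80.2)
  expect_true(all(s100$p20 <= s100$p25 & s100$p25 <= s100$median &
                  s100$median <= s100$p75 & s100$p75 <= s100$p80))

  sconst <- summarize_ensemble(mk(rep(2, 7)))
  row <- sconst[sconst$parameter == "log10_k1", ]
  expect_true(all(row[, c("median", "p20", "p25", "p75", "p80")] == 2))

  expect_error(summarize_ensemble(data.frame()), "summarize")
})
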