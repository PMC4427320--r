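# Plate container, raw preprocessing, CSV dialects, CLI round trip.

test_that("plate grid validates shape, ordering and sign", {
  L <- matrix(1:4, 2, 2)
  expect_s3_class(plate_grid(c(0, 10), c(0, 20), L), "plate_grid")
  expect_error(plate_grid(c(0, 10, 20), c(0, 20), L), "shape")
  expect_error(plate_grid(c(10, 0), c(0, 20), L), "ascending")
  expect_error(plate_grid(c(0, 10), c(0, 20), -L), "non-negative")
})

test_that("raw plates normalize to specific luminescence via the path-corrected OD", {
  raw <- raw_plate(od600 = matrix(c(0.46, 0.23, 0.46, 0.92), 2, 2),
                   lum = matrix(500, 2, 2),
                   c8_levels = c(0, 10), c6_levels = c(0, 10))
  plate <- preprocess_raw(raw)
  expect_equal(unname(plate$L),
               matrix(c(500, 1000, 500, 250), 2, 2))
  # a dead well (OD <= 0) is masked, not divided by
  raw$od600[1, 1] <- 0
  expect_warning(plate2 <- preprocess_raw(raw), "missing")
  expect_true(is.na(plate2$L[1, 1]))
  expect_equal(plate2$L[2, 1], 1000)
})

test_that("matrix-CSV write/read round trip is the identity", {
  pr <- strain_preset("A")
  plate <- simulate_plate(pr$params, pr$scale,
                          noise = noise_model(0.1, rng_seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate(plate, path)
  back <- read_plate(path)
  expect_equal(back$c8_levels, plate$c8_levels)
  expect_equal(back$c6_levels, plate$c6_levels)
  expect_equal(unname(back$L), unname(plate$L), tolerance = 1e-12)
})

test_that("both CSV dialects and shuffled rows canonicalize identically", {
  dir <- withr::local_tempdir()
  mpath <- file.path(dir, "m.csv")
  lpath <- file.path(dir, "l.csv")
  writeLines(c("c8_nM,0,50", "100,7,8", "0,5,6"), mpath)  # rows out of order
  g <- expand.grid(c8_nM = c(0, 100), c6_nM = c(0, 50))
  g$luminescence <- c(5, 7, 6, 8)
  set.seed(1)
  utils::write.csv(g[sample(nrow(g)), ], lpath, row.names = FALSE)
  pm <- read_plate(mpath)
  pl <- read_plate(lpath)
  expect_equal(pm$c8_levels, c(0, 100))
  expect_equal(unname(pm$L), unname(pl$L))
  expect_equal(unname(pm$L), matrix(c(5, 7, 6, 8), 2, 2))
})

test_that("blank cells become missing wells; duplicate labels are rejected", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "blank.csv")
  writeLines(c("c8_nM,0,50", "0,5,", "100,7,8"), p1)
  plate <- read_plate(p1)
  expect_equal(sum(is.na(plate$L)), 1)
  expect_true(is.na(plate$L[1, 2]))
  p2 <- file.path(dir, "dup.csv")
  writeLines(c("c8_nM,0,0", "0,5,6", "100,7,8"), p2)
  expect_error(read_plate(p2), "duplicate")
})

test_that("CLI pipeline simulate -> fit -> summarize -> convert -> surface exits 0", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "simA")
  suppressMessages({
    expect_equal(luxr_cli(c("simulate", "--preset", "A", "--cv", "0.05",
                            "--seed", "1", "--replicates", "2",
                            "--out-prefix", prefix)), 0L)
    plates <- sprintf("%s_rep%d.csv", prefix, 1:2)
    expect_true(all(file.exists(plates)))
    fits_json <- file.path(dir, "fits.json")
    fits_csv <- file.path(dir, "fits.csv")
    expect_equal(luxr_cli(c("fit", "--plates", paste(plates, collapse = ","),
                            "--n-points", "80", "--n-keep", "2",
                            "--seed", "1", "--max-iter", "60",
                            "--out", fits_json, "--out-csv", fits_csv)), 0L)
    summ_csv <- file.path(dir, "summary.csv")
    expect_equal(luxr_cli(c("summarize", "--fits", fits_json,
                            "--out", summ_csv)), 0L)
    abs_csv <- file.path(dir, "abs.csv")
    expect_equal(luxr_cli(c("convert", "--summary", summ_csv,
                            "--luxr0", "33", "--strain", "A",
                            "--out", abs_csv)), 0L)
    surf_csv <- file.path(dir, "surface.csv")
    expect_equal(luxr_cli(c("surface", "--preset", "A",
                            "--out", surf_csv)), 0L)
  })
  fits <- utils::read.csv(fits_csv)
  expect_equal(nrow(fits), 4)  # 2 seeds x 2 plates
  summ <- utils::read.csv(summ_csv)
  expect_equal(nrow(summ), 6)
  abs_tab <- utils::read.csv(abs_csv)
  expect_equal(abs_tab$strain, "A")
  expect_true(all(abs_tab[, c("K1_nM", "K2_nM", "KA_nM", "KB_nM")] > 0))
  surf <- read_plate(surf_csv)
  expect_equal(length(surf$c8_levels), 8)
})

test_that("CLI rejects unknown subcommands and flags with nonzero status", {
  suppressMessages({
    expect_equal(luxr_cli(character(0)), 2L)
    expect_equal(luxr_cli("frobnicate"), 2L)
    expect_equal(luxr_cli(c("simulate", "--bogus", "1")), 1L)
    expect_equal(luxr_cli(c("fit", "--plates")), 1L)
  })
})
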