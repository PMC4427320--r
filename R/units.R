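# Conversion between scaled (per-total-LuxR) and absolute dissociation
# constants.  The fitted constants are nondimensionalized by the total
# intracellular LuxR concentration [LuxR0], which the luminescence data
# cannot determine; converting to absolute nanomolar constants requires an
# assumed [LuxR0].  The default, 33 nM, follows the literature estimate for
# the homologous receptor TraR (about 20 protomers per cell).

#' Absolute dissociation constants
#'
#' @param K1,K2 complex dissociation constants, nM.
#' @param KA,KB lux-box dissociation constants, nM.
#' @param luxr0 total intracellular LuxR concentration (nM) used in the
#'   conversion.
#' @return List of class `"absolute_params"`.
#' @export
absolute_params <- function(K1, K2, KA, KB, luxr0 = 33) {
  v <- c(K1 = K1, K2 = K2, KA = KA, KB = KB, luxr0 = luxr0)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("absolute constants and luxr0 must be positive and finite",
         call. = FALSE)
  structure(as.list(v), class = "absolute_params")
}

#' @export
print.absolute_params <- function(x, ...) {
  cat(sprintf(
    "Absolute dissociation constants at [LuxR0] = %g nM:\n  K1 = %.4g nM, K2 = %.4g nM, KA = %.4g nM, KB = %.4g nM\n",
    x$luxr0, x$K1, x$K2, x$KA, x$KB))
  invisible(x)
}

check_hill_exponents <- function(m, n, tol = 0.05) {
  for (h in c(m = m, n = n)) {
    if (abs(2 * h - 1) == 0)
      stop("Hill coefficient of exactly 0.5 makes the absolute constant underdetermined (exponent 2m - 1 = 0)",
           call. = FALSE)
  }
  fragile <- abs(2 * c(m, n) - 1) < tol
  if (any(fragile))
    warning("Hill coefficient near 0.5: absolute complex dissociation constant is numerically fragile",
            call. = FALSE)
  fragile
}

#' Convert scaled fit parameters to absolute dissociation constants
#'
#' The scaled constants relate to absolute ones through the total LuxR
#' concentration: `kA = KA / luxr0`, `kB = KB / luxr0`, and
#' `k1^m = K1^(2m-1) / luxr0^(m-1)` (similarly for `k2` with `n`).  Inverting
#' gives `KA = kA * luxr0`, `KB = kB * luxr0`,
#' `K1 = (k1^m * luxr0^(m-1))^(1/(2m-1))` and
#' `K2 = (k2^n * luxr0^(n-1))^(1/(2n-1))`, evaluated in log10 space.
#' A Hill coefficient of exactly 0.5 makes the exponent `2m - 1` vanish and
#' the absolute constant underdetermined (error); values within 0.05 of 0.5
#' are flagged with a warning as numerically fragile.
#'
#' @param params a [kinetic_params()] object.
#' @param luxr0 assumed total intracellular LuxR concentration, nM.
#' @return An [absolute_params()] object, with a logical attribute
#'   `"fragile"` marking near-singular exponents (order `K1`, `K2`).
#' @export
#' @examples
#' scaled_to_absolute(kinetic_params(2, 1, 2, 1, 0, 0), luxr0 = 33)
scaled_to_absolute <- function(params, luxr0 = 33) {
  p <- as_kinetic_params(params)
  if (luxr0 <= 0) stop("luxr0 must be positive", call. = FALSE)
  m <- p[["m"]]; n <- p[["n"]]
  fragile <- check_hill_exponents(m, n)
  l0 <- log10(luxr0)
  log10_K1 <- (m * p[["log10_k1"]] + (m - 1) * l0) / (2 * m - 1)
  log10_K2 <- (n * p[["log10_k2"]] + (n - 1) * l0) / (2 * n - 1)
  out <- absolute_params(K1 = 10^log10_K1, K2 = 10^log10_K2,
                         KA = 10^(p[["log10_kA"]] + l0),
                         KB = 10^(p[["log10_kB"]] + l0),
                         luxr0 = luxr0)
  attr(out, "fragile") <- fragile
  out
}

#' Convert absolute dissociation constants back to scaled fit parameters
#'
#' Exact inverse of [scaled_to_absolute()] at the same Hill coefficients.
#'
#' @param abs_params an [absolute_params()] object.
#' @param m,n Hill coefficients of the two complexes.
#' @return A [kinetic_params()] object.
#' @export
absolute_to_scaled <- function(abs_params, m, n) {
  stopifnot(inherits(abs_params, "absolute_params"))
  check_hill_exponents(m, n)
  l0 <- log10(abs_params$luxr0)
  log10_k1 <- ((2 * m - 1) * log10(abs_params$K1) - (m - 1) * l0) / m
  log10_k2 <- ((2 * n - 1) * log10(abs_params$K2) - (n - 1) * l0) / n
  kinetic_params(log10_k1, m, log10_k2, n,
                 log10(abs_params$KA) - l0, log10(abs_params$KB) - l0)
}

#' Tabulate absolute constants for several parameter sets
#'
#' Builds a strain-by-constant conversion table (one row per named parameter
#' set) ready to be written as CSV.
#'
#' @param params_list named list of [kinetic_params()] objects.
#' @param luxr0 assumed total LuxR concentration, nM.
#' @return Data frame with columns `strain`, `K1_nM`, `K2_nM`, `KA_nM`,
#'   `KB_nM`, `luxr0_nM`.
#' @export
absolute_table <- function(params_list, luxr0 = 33) {
  rows <- lapply(names(params_list), function(nm) {
    a <- scaled_to_absolute(params_list[[nm]], luxr0)
    data.frame(strain = nm, K1_nM = a$K1, K2_nM = a$K2,
               KA_nM = a$KA, KB_nM = a$KB, luxr0_nM = luxr0)
  })
  do.call(rbind, rows)
}
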