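#' Kinetic interaction parameters for one LuxR variant
#'
#' Bundles the six parameters of the competitive two-signal activation model:
#' the scaled dissociation constants for the C8-HSL and 3OC6-HSL complexes of
#' LuxR (`k1`, `k2`, both nM, stored as log10), the Hill coefficients of
#' cooperative complex formation (`m`, `n`), and the scaled lux-box
#' dissociation constants of the two complexes (`kA`, `kB`, dimensionless
#' because they are expressed relative to total intracellular LuxR, stored as
#' log10).
#'
#' @param log10_k1 log10 of the scaled C8-HSL complex dissociation constant (nM).
#' @param m Hill coefficient of the LuxR/C8-HSL complex; must be > 0.
#' @param log10_k2 log10 of the scaled 3OC6-HSL complex dissociation constant (nM).
#' @param n Hill coefficient of the LuxR/3OC6-HSL complex; must be > 0.
#' @param log10_kA log10 of the scaled lux-box dissociation constant of the
#'   C8-HSL complex.
#' @param log10_kB log10 of the scaled lux-box dissociation constant of the
#'   3OC6-HSL complex.
#' @return A named numeric vector of class `"kinetic_params"` in the canonical
#'   coordinate order `(log10_k1, m, log10_k2, n, log10_kA, log10_kB)` used by
#'   the optimizer and seed search.
#' @seealso [solve_free_luxr()], [occupancy()], [strain_preset()]
#' @export
#' @examples
#' kinetic_params(2, 1, 2, 1, 1, 1)
kinetic_params <- function(log10_k1, m, log10_k2, n, log10_kA, log10_kB) {
  x <- c(log10_k1 = log10_k1, m = m, log10_k2 = log10_k2, n = n,
         log10_kA = log10_kA, log10_kB = log10_kB)
  validate_kinetic_params(x)
  structure(x, class = "kinetic_params")
}

#' @rdname kinetic_params
#' @param x a numeric vector of length 6 in canonical coordinate order, or an
#'   object already of class `"kinetic_params"`.
#' @export
as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  x <- as.numeric(x)
  if (length(x) != 6L)
    stop("kinetic parameters require exactly 6 values", call. = FALSE)
  kinetic_params(x[1L], x[2L], x[3L], x[4L], x[5L], x[6L])
}

param_names <- function() {
  c("log10_k1", "m", "log10_k2", "n", "log10_kA", "log10_kB")
}

validate_kinetic_params <- function(x) {
  if (any(!is.finite(x)))
    stop("all kinetic parameters must be finite", call. = FALSE)
  if (x[["m"]] <= 0 || x[["n"]] <= 0)
    stop("Hill coefficients m and n must be positive", call. = FALSE)
  invisible(x)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (log10 scale for dissociation constants):\n")
  print(stats::setNames(as.numeric(x), param_names()))
  invisible(x)
}

#' Luminescence scale parameters
#'
#' The measured specific luminescence is modeled through its square root:
#' `sqrt(L) = a0 + a1 * P`, where `P` is the lux-box occupancy.  `a0` is the
#' baseline (uninduced) square-root luminescence and `a1` the gain.  The
#' square-root link reflects luciferase acting as a dimer, so light output
#' scales as the square of lux transcription.
#'
#' @param a0 baseline, in square-root specific-luminescence units.
#' @param a1 gain, in square-root specific-luminescence units.
#' @return An object of class `"scale_params"`.
#' @export
#' @examples
#' scale_params(10, 550)
scale_params <- function(a0, a1) {
  if (!is.finite(a0) || !is.finite(a1))
    stop("scale parameters must be finite", call. = FALSE)
  structure(list(a0 = a0, a1 = a1), class = "scale_params")
}

#' @export
print.scale_params <- function(x, ...) {
  cat(sprintf("Luminescence scale: a0 = %g, a1 = %g  (sqrt(L) = a0 + a1 P)\n",
              x$a0, x$a1))
  invisible(x)
}
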