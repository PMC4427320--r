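# Forward equilibrium model: free-LuxR partitioning under conservation of
# total LuxR, competitive lux-box occupancy, and the predicted luminescence
# surface.

# exp() with the argument capped so that extreme parameter draws (log10 k
# spanning tens of decades) give a large finite value instead of Inf; keeps
# the bisection residual finite and sign-correct.
exp_capped <- function(x) exp(pmin(x, 700))

# Vectorized solve of the free-LuxR balance in u = log(r):
#   exp(u) + w_m * exp(la + m*u) + w_n * exp(lb + n*u) = 1
# where la = m*log(c8/k1), lb = n*log(c6/k2) and w_m, w_n are the LuxR
# stoichiometry weights (m, n for the stoichiometric closure; 1, 1 for the
# unweighted closure).  The left-hand side is strictly increasing in u, is
# < 1 as u -> -Inf and >= 1 at u = 0, so bisection on [-745, 0] is globally
# convergent; 90 halvings take the bracket far below double precision.
solve_r_log <- function(log_a, log_b, m, n, w_m, w_n, iters = 90L) {
  stopifnot(length(log_a) == length(log_b))
  k <- length(log_a)
  # no-ligand wells: both complex terms vanish identically, r = 1 exactly
  free <- (log_a == -Inf) & (log_b == -Inf)
  lo <- rep(-745, k)
  hi <- rep(0, k)
  f <- function(u) {
    exp(u) + w_m * exp_capped(log_a + m * u) + w_n * exp_capped(log_b + n * u) - 1
  }
  for (i in seq_len(iters)) {
    mid <- 0.5 * (lo + hi)
    pos <- f(mid) >= 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  u <- 0.5 * (lo + hi)
  u[free] <- 0
  u
}

# Shared setup: log-space ligand terms for a concentration vector pair.
# 0^m is taken as 0 for all m > 0 (log term -Inf), covering the
# zero-concentration wells of the standard plate design.
ligand_log_terms <- function(c8, c6, params) {
  p <- as_kinetic_params(params)
  ln10 <- log(10)
  list(
    log_a = p[["m"]] * (log(c8) - ln10 * p[["log10_k1"]]),
    log_b = p[["n"]] * (log(c6) - ln10 * p[["log10_k2"]]),
    p = p
  )
}

#' Solve the free-LuxR equilibrium at given signal concentrations
#'
#' Partitions the total intracellular LuxR pool between free LuxR and the two
#' homomultimeric LuxR-HSL complexes.  In scaled variables (`r` = free LuxR /
#' total LuxR, `rc8` and `rc6` = complex concentrations / total LuxR) the
#' complexes obey `rc8 = (c8/k1)^m * r^m` and `rc6 = (c6/k2)^n * r^n`, and the
#' conservation balance closes the system.  With the default stoichiometric
#' closure each complex sequesters `m` (or `n`) LuxR protomers:
#' `r + m*rc8 + n*rc6 = 1`.  The alternative `"unweighted"` closure counts
#' complexes singly: `r + rc8 + rc6 = 1`.
#'
#' The balance is solved by bisection on `log(r)` with all powers evaluated in
#' log space, so extreme dissociation constants cannot overflow.  The lux-box
#' occupancy follows from the probability ratios `PA = rc8/kA`,
#' `PB = rc6/kB`, `P = (PA+PB)/(1+PA+PB)`.
#'
#' @param c8 C8-HSL concentration(s), nM, >= 0.
#' @param c6 3OC6-HSL concentration(s), nM, >= 0.  Recycled against `c8`.
#' @param params a [kinetic_params()] object (or 6-vector in canonical order).
#' @param tol maximum tolerated residual of the conservation balance.
#' @param closure conservation closure: `"stoichiometric"` (default) or
#'   `"unweighted"`.
#' @return A data frame with one row per concentration pair and columns
#'   `c8`, `c6`, `r`, `rc8`, `rc6`, `PA`, `PB`, `P`.
#' @export
#' @examples
#' p <- kinetic_params(2, 1, 2, 1, 1, 1)
#' solve_free_luxr(c(0, 100), 0, p)
solve_free_luxr <- function(c8, c6, params, tol = 1e-10,
                            closure = c("stoichiometric", "unweighted")) {
  closure <- match.arg(closure)
  if (any(c8 < 0) || any(c6 < 0))
    stop("HSL concentrations must be non-negative", call. = FALSE)
  nn <- max(length(c8), length(c6))
  c8 <- rep_len(c8, nn)
  c6 <- rep_len(c6, nn)
  lt <- ligand_log_terms(c8, c6, params)
  p <- lt$p
  m <- p[["m"]]; n <- p[["n"]]
  w_m <- if (closure == "stoichiometric") m else 1
  w_n <- if (closure == "stoichiometric") n else 1
  u <- solve_r_log(lt$log_a, lt$log_b, m, n, w_m, w_n)
  r <- exp(u)
  rc8 <- exp_capped(lt$log_a + m * u)
  rc6 <- exp_capped(lt$log_b + n * u)
  resid <- abs(r + w_m * rc8 + w_n * rc6 - 1)
  if (any(resid > tol))
    stop(sprintf("conservation residual %.3g exceeds tol %.3g", max(resid), tol),
         call. = FALSE)
  PA <- rc8 * 10^(-p[["log10_kA"]])
  PB <- rc6 * 10^(-p[["log10_kB"]])
  data.frame(c8 = c8, c6 = c6, r = r, rc8 = rc8, rc6 = rc6,
             PA = PA, PB = PB, P = (PA + PB) / (1 + PA + PB))
}

#' Lux-box occupancy probability
#'
#' Probability that the lux operator is bound by either LuxR-HSL complex,
#' `P = (PA + PB) / (1 + PA + PB)`, at the equilibrium free-LuxR partition.
#' `P` is zero with no signal, strictly increasing in each signal alone, and
#' saturates below 1 because complex formation is limited by the total
#' intracellular LuxR pool.
#'
#' @inheritParams solve_free_luxr
#' @return Numeric vector of occupancies in `[0, 1)`.
#' @export
occupancy <- function(c8, c6, params,
                      closure = c("stoichiometric", "unweighted")) {
  solve_free_luxr(c8, c6, params, closure = match.arg(closure))$P
}

#' Predicted specific luminescence from occupancy
#'
#' Applies the square-root link `sqrt(L) = a0 + a1 * P` and squares.  The
#' square-root value is floored at `eps_sqrt` so that predicted luminescence
#' is always positive (a negative `a0 + a1*P` can arise transiently during
#' fitting) and the log-scale loss stays defined.
#'
#' @param P occupancy value(s) in `[0, 1)`.
#' @param scale a [scale_params()] object.
#' @param eps_sqrt positive floor applied to `a0 + a1*P` before squaring.
#' @return Specific luminescence value(s).
#' @export
#' @examples
#' luminescence(0.5, scale_params(10, 550))  # (10 + 275)^2
luminescence <- function(P, scale, eps_sqrt = 1e-3) {
  pmax(scale$a0 + scale$a1 * P, eps_sqrt)^2
}

#' Predicted luminescence response surface over a concentration grid
#'
#' Evaluates the forward model over the full factorial grid of C8-HSL and
#' 3OC6-HSL levels, the in-silico analogue of one well plate.
#'
#' @param c8_levels C8-HSL concentrations (nM), one per plate row.
#' @param c6_levels 3OC6-HSL concentrations (nM), one per plate column.
#' @inheritParams solve_free_luxr
#' @inheritParams luminescence
#' @return Matrix of predicted specific luminescence, rows indexed by
#'   `c8_levels`, columns by `c6_levels`.
#' @export
response_surface <- function(c8_levels, c6_levels, params,
                             scale = scale_params(10, 550), eps_sqrt = 1e-3,
                             closure = c("stoichiometric", "unweighted")) {
  if (length(c8_levels) == 0L || length(c6_levels) == 0L)
    stop("concentration axes must be non-empty", call. = FALSE)
  P <- occupancy_grid(c8_levels, c6_levels, params, match.arg(closure))
  L <- luminescence(P, scale, eps_sqrt)
  dimnames(L) <- list(c8 = format(c8_levels, trim = TRUE),
                      c6 = format(c6_levels, trim = TRUE))
  L
}

# Occupancy over the factorial grid, as a |c8| x |c6| matrix.
occupancy_grid <- function(c8_levels, c6_levels, params,
                           closure = "stoichiometric") {
  g <- expand.grid(c8 = c8_levels, c6 = c6_levels)
  P <- occupancy(g$c8, g$c6, params, closure = closure)
  matrix(P, nrow = length(c8_levels), ncol = length(c6_levels))
}

#' Maximum fractional suppression along one signal axis
#'
#' Quantifies the non-monotonic "competitive suppression" phenotype: along a
#' slice where one HSL increases while the other is held fixed, luminescence
#' can peak and then fall, because the added signal builds complexes with a
#' weaker lux-box affinity that displace the stronger activator from the
#' shared LuxR pool.  For each slice the index is
#' `(peak - min beyond the peak) / peak`; the function returns the maximum
#' over all slices, or 0 when every slice is non-decreasing.
#'
#' @param surface positive luminescence matrix (rows = C8-HSL levels,
#'   columns = 3OC6-HSL levels, both ascending).
#' @param axis which signal is being increased along the slice: `"C8"` scans
#'   down the rows at each fixed 3OC6-HSL column, `"3OC6"` scans across the
#'   columns at each fixed C8-HSL row.
#' @return Maximum fractional decrease, in `[0, 1)`.
#' @export
suppression_index <- function(surface, axis = c("C8", "3OC6")) {
  axis <- match.arg(axis)
  slices <- if (axis == "C8") {
    lapply(seq_len(ncol(surface)), function(j) surface[, j])
  } else {
    lapply(seq_len(nrow(surface)), function(i) surface[i, ])
  }
  drop_frac <- vapply(slices, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(0)
    imax <- which.max(x)
    if (imax == length(x)) return(0)
    (x[imax] - min(x[(imax + 1L):length(x)])) / x[imax]
  }, numeric(1))
  max(0, drop_frac)
}
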