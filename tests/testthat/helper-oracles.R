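# Independent oracles and random-case generators shared across tests.

# Brute-force bisection for the free-LuxR balance, in linear r on (0, 1],
# down to a fixed resolution.  Written independently of the production
# solver: plain powers, no log-space tricks, so only usable where
# (c/k)^m stays finite.
oracle_solve_r <- function(c8, c6, params, closure = "stoichiometric",
                           res = 1e-8) {
  p <- as_kinetic_params(params)
  m <- p[["m"]]; n <- p[["n"]]
  A <- (c8 / 10^p[["log10_k1"]])^m
  B <- (c6 / 10^p[["log10_k2"]])^n
  w_m <- if (closure == "stoichiometric") m else 1
  w_n <- if (closure == "stoichiometric") n else 1
  f <- function(r) r + w_m * A * r^m + w_n * B * r^n - 1
  lo <- 0; hi <- 1
  while (hi - lo > res) {
    mid <- 0.5 * (lo + hi)
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  0.5 * (lo + hi)
}

# Random but physically plausible kinetic parameters.  Ranges are kept
# inside the default search bounds while avoiding the extreme tails where
# the plain-power oracle itself overflows.
random_params <- function() {
  kinetic_params(stats::runif(1, -2, 5), stats::runif(1, 0.1, 4),
                 stats::runif(1, -2, 5), stats::runif(1, 0.1, 4),
                 stats::runif(1, -4, 4), stats::runif(1, -4, 4))
}

# Random concentration from the plate's dynamic range, zero included.
random_conc <- function(n = 1) {
  out <- 10^stats::runif(n, -1, 3.6)
  out[stats::runif(n) < 0.15] <- 0
  out
}

# One standard noiseless plate for fitting tests.
noiseless_plate <- function(preset = "A") {
  pr <- strain_preset(preset)
  simulate_plate(pr$params, pr$scale, noise = noise_model(cv = 0))
}
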