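# Independent oracles used across the test files. These deliberately
# re-transcribe the printed formulas in a separate code path from the
# package implementation.

# straight transcription of the series base cases and recursion
oracle_coeffs <- function(x, k_in, k_aSx, k_Sx, p_C, n) {
  u <- numeric(n + 1)
  w <- numeric(n + 1)
  B <- k_aSx + k_Sx * x
  u[0 + 1] <- k_Sx * (k_in + x * B)
  u[1 + 1] <- -(k_in * (k_aSx + 2 * k_Sx * x) + x * B * (k_aSx + 3 * k_Sx * x))
  u[2 + 1] <- x^2 * (k_aSx + 2 * k_Sx * x) * B
  u[3 + 1] <- -p_C * x * B^2 * u[1 + 1]
  w[0 + 1] <- -k_Sx * x
  w[1 + 1] <- (k_aSx + 2 * k_Sx * x) * x
  w[2 + 1] <- 0
  w[3 + 1] <- -p_C * x * B^2 * w[1 + 1]
  if (n >= 4) {
    for (i in 4:n) {
      u[i + 1] <- p_C * x * B^2 * ((i - 3) * x * u[i - 3 + 1] - (i - 2) * u[i - 2 + 1])
      w[i + 1] <- p_C * x * B^2 * ((i - 3) * x * w[i - 3 + 1] - (i - 2) * w[i - 2 + 1])
    }
  }
  list(u = u, w = w)
}

# brute-force root scan of the stationarity residual: dense linear grid,
# sign changes refined by bisection
brute_force_roots <- function(C, D, params, n_grid = 1e5, x_lo = NULL,
                              x_hi = NULL) {
  if (is.null(x_lo)) x_lo <- 1e-6 * C
  if (is.null(x_hi)) x_hi <- 2 * C
  xs <- seq(x_lo, x_hi, length.out = n_grid)
  gv <- stationarity_residual(xs, C, D, params)
  idx <- which(gv[-1] * gv[-length(gv)] < 0)
  vapply(idx, function(i) {
    stats::uniroot(function(x) stationarity_residual(x, C, D, params),
                   lower = xs[i], upper = xs[i + 1], tol = 1e-12)$root
  }, numeric(1))
}

# minimal synthetic trajectory container understood by the regimes module
make_traj <- function(times, x, C = NULL, D = NULL) {
  list(times = times,
       states = data.frame(t = times, x = x,
                           C = if (is.null(C)) rep(1, length(x)) else C,
                           D = if (is.null(D)) rep(0, length(x)) else D))
}

# random valid parameter draw used by the property suites
random_params <- function() {
  eco_params(
    k_in = stats::runif(1, 0, 2),
    k_aSx = stats::runif(1, 0, 2),
    k_Sx = stats::runif(1, 0.1, 3),
    k_d = stats::runif(1, 0.2, 2),
    K_D = exp(stats::runif(1, log(0.01), log(10))),
    K_E = exp(stats::runif(1, log(0.05), log(10))),
    p_C = stats::runif(1, 0, 0.01),
    p_D = stats::runif(1, 0, 0.1))
}

random_state <- function() {
  eco_state(x = stats::runif(1, 0.05, 30), C = stats::runif(1, 5, 80),
            D = stats::runif(1, 0, 10))
}
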