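#' Reproduction, mortality and crowding laws with their partial derivatives
#'
#' Evaluates, at a given state, the specific self-reproduction rate
#' `W = (k_aSx + k_Sx x)(1 - x/C)` (which is also the fitness functional of
#' the model), the specific mortality rate `Y = k_d + D H`, the crowding
#' function `H = k_d x r / (K_D + x r)` with auto-aggression factor
#' `r = exp(x/K_E - 1)`, and the partial derivatives `W_x`, `W_C`, `W_CC`,
#' `W_xC` and `H_x` that enter the parameter-evolution equations.
#'
#' The exponential `r` overflows double precision for moderate `x/K_E`; `H`
#' and `H_x` are therefore evaluated in an algebraically rearranged form in
#' which only `exp(-(x/K_E - 1))` appears when the exponent is positive, so
#' both remain finite for all `x >= 0`. The reported `r` itself is capped at
#' `exp(700)`.
#'
#' @param state an [eco_state()].
#' @param params an [eco_params()].
#' @return An object of class `eco_rates`: a list with components `W`, `Y`,
#'   `H`, `r`, `W_x`, `W_C`, `W_CC`, `W_xC`, `H_x`.
#' @examples
#' p <- eco_params(k_Sx = 1, K_D = 0.5, K_E = 2)
#' compute_rates(eco_state(x = 2, C = 30, D = 3.5), p)
#' @export
compute_rates <- function(state, params) {
  stopifnot(inherits(state, "eco_state"), inherits(params, "eco_params"))
  x <- state$x; C <- state$C; D <- state$D
  ka <- params$k_aSx; ks <- params$k_Sx; kd <- params$k_d
  KD <- params$K_D; KE <- params$K_E

  z <- x / KE - 1
  r <- exp(min(z, 700))
  if (x == 0) {
    H <- 0
    H_x <- kd * exp(-1) / KD
  } else if (z >= 0) {
    # multiply numerator and denominator by exp(-z) (and exp(-2 z) for H_x)
    emz <- exp(-min(z, 700))
    H <- kd * x / (KD * emz + x)
    H_x <- kd * KD * (1 + x / KE) * emz / (KD * emz + x)^2
  } else {
    ez <- exp(z)
    H <- kd * x * ez / (KD + x * ez)
    H_x <- kd * KD * (1 + x / KE) * ez / (KD + x * ez)^2
  }

  structure(list(
    W    = (ka + ks * x) * (1 - x / C),
    Y    = kd + D * H,
    H    = H,
    r    = r,
    W_x  = ks - (ka + 2 * ks * x) / C,
    W_C  = (ka + ks * x) * x / C^2,
    W_CC = -2 * (ka + ks * x) * x / C^3,
    W_xC = (ka + 2 * ks * x) / C^2,
    H_x  = H_x
  ), class = "eco_rates")
}

#' @export
print.eco_rates <- function(x, ...) {
  cat(sprintf("<eco_rates> W = %g, Y = %g, H = %g\n", x$W, x$Y, x$H))
  cat(sprintf("  W_x = %g, W_C = %g, W_CC = %g, W_xC = %g, H_x = %g\n",
              x$W_x, x$W_C, x$W_CC, x$W_xC, x$H_x))
  invisible(x)
}

#' Coefficients of the parameter-evolution series
#'
#' Computes the coefficient sequences `u_i` and `w_i`, `i = 0..max_order`, of
#' the two power series in `1/C` that express the evolution rates of the
#' carrying capacity and the mortality coefficient. Indices 0 to 3 follow the
#' printed closed forms; indices `i >= 4` follow the recursion
#' `u_i = A ((i-3) x u_{i-3} - (i-2) u_{i-2})` (and likewise for `w_i`) with
#' recursion factor `A = p_C x (k_aSx + k_Sx x)^2`. The closed forms for
#' `u_3`, `w_3` coincide with the recursion evaluated at `i = 3`, whose
#' `(i-3)` term vanishes.
#'
#' @param state an [eco_state()].
#' @param params an [eco_params()].
#' @param max_order highest coefficient index to compute; must be at least 3.
#' @return A list with numeric vectors `u` and `w` of length
#'   `max_order + 1`; element `i + 1` holds the coefficient of index `i`.
#' @examples
#' p <- eco_params(k_in = 0.01, k_Sx = 1, p_C = 0.0015)
#' series_coefficients(eco_state(x = 2, C = 30, D = 0), p, max_order = 5)
#' @export
series_coefficients <- function(state, params, max_order = 60L) {
  stopifnot(inherits(state, "eco_state"), inherits(params, "eco_params"))
  if (max_order < 3)
    stop("series_coefficients: max_order must be at least 3", call. = FALSE)
  x <- state$x
  kin <- params$k_in; ka <- params$k_aSx; ks <- params$k_Sx
  pC <- params$p_C
  N <- as.integer(max_order)

  u <- numeric(N + 1)
  w <- numeric(N + 1)
  u[1] <- ks * (kin + x * (ka + ks * x))
  u[2] <- -(kin * (ka + 2 * ks * x) + x * (ka + ks * x) * (ka + 3 * ks * x))
  u[3] <- x^2 * (ka + 2 * ks * x) * (ka + ks * x)
  A <- pC * x * (ka + ks * x)^2
  u[4] <- -A * u[2]
  w[1] <- -ks * x
  w[2] <- (ka + 2 * ks * x) * x
  w[3] <- 0
  w[4] <- -A * w[2]
  if (N >= 4) {
    for (i in 5:(N + 1)) {
      k <- i - 1  # coefficient index
      u[i] <- A * ((k - 3) * x * u[i - 3] - (k - 2) * u[i - 2])
      w[i] <- A * ((k - 3) * x * w[i - 3] - (k - 2) * w[i - 2])
    }
  }
  list(u = u, w = w)
}

#' Truncation policy for the evolution series
#'
#' The model writes the evolution rates of `C` and `D` as infinite series
#' whose coefficients eventually grow (the recursion multiplies by
#' `(i - 2) A / C^2`-like factors), so the series are treated as asymptotic:
#' terms are accumulated while they shrink, and summation stops either when
#' the adaptive relative-tolerance rule fires or, if term magnitudes start
#' growing first, at the smallest-magnitude term (optimal truncation).
#'
#' @param max_order hard cap on the highest series index retained.
#' @param rtol_series relative tolerance of the stopping rule: summation
#'   stops at the first index `i >= 4` for which the current and previous
#'   term are both below `rtol_series` relative to the running partial sums.
#' @return A list of class `eco_trunc_policy`.
#' @export
trunc_policy <- function(max_order = 60L, rtol_series = 1e-12) {
  stopifnot(max_order >= 3, rtol_series > 0)
  structure(list(max_order = as.integer(max_order),
                 rtol_series = rtol_series),
            class = "eco_trunc_policy")
}

#' Truncated sums of the evolution series
#'
#' Accumulates the two series `S_C = sum_{i>=1} i (u_i + Y w_i) / C^i` and
#' `S_D = sum_{i>=0} w_i / C^i` in increasing `i`, applying the adaptive
#' stopping rule of [trunc_policy()]. If the term magnitudes start growing
#' before the rule fires (asymptotic-series behaviour) the sums are truncated
#' at the smallest-magnitude term and `converged` is set to `FALSE`.
#'
#' @param u,w coefficient vectors as returned by [series_coefficients()]
#'   (element `i + 1` holds index `i`); must have equal length.
#' @param Y specific mortality rate at the state of interest, multiplying
#'   `w_i` inside the first series.
#' @param C positive carrying capacity.
#' @param policy an [trunc_policy()]; its `max_order` is further limited by
#'   the length of `u`.
#' @return An object of class `eco_series`: list with `u`, `w`, `N` (the
#'   truncation order actually used), `S_C`, `S_D`, `converged`, and
#'   `smallest_term_index` (optimal-truncation diagnostic: the index of the
#'   smallest retained term magnitude).
#' @examples
#' p <- eco_params(k_in = 0.01, k_Sx = 1, p_C = 0.0015)
#' s <- eco_state(x = 2, C = 30, D = 0)
#' cf <- series_coefficients(s, p, 60)
#' truncate_sums(cf$u, cf$w, Y = compute_rates(s, p)$Y, C = s$C)
#' @export
truncate_sums <- function(u, w, Y, C, policy = trunc_policy()) {
  if (length(u) != length(w))
    stop("truncate_sums: u and w must have identical length", call. = FALSE)
  if (!is.finite(C) || C <= 0)
    stop("truncate_sums: C must be positive and finite", call. = FALSE)
  N <- min(length(u) - 1L, policy$max_order)

  ii <- seq_len(N)
  cp <- cumprod(rep(1 / C, N))
  tC <- c(0, ii * (u[ii + 1] + Y * w[ii + 1]) * cp)  # index 0 slot unused
  tD <- c(w[1], w[ii + 1] * cp)
  m <- pmax(abs(tC[-1]), abs(tD[-1]))                # term magnitudes, i >= 1
  SCp <- cumsum(tC)                                  # SCp[i + 1] = partial sum to i
  SDp <- cumsum(tD)

  n_used <- N
  converged <- FALSE
  if (max(m) == 0) {
    n_used <- min(3L, N)
    converged <- TRUE
  } else if (N >= 4) {
    tiny <- 1e-300
    for (i in 4:N) {
      rel  <- m[i] / max(abs(SCp[i + 1]), abs(SDp[i + 1]), tiny)
      relp <- m[i - 1] / max(abs(SCp[i]), abs(SDp[i]), tiny)
      if (rel < policy$rtol_series && relp < policy$rtol_series) {
        n_used <- i; converged <- TRUE; break
      }
      if (i >= 6 && m[i] > m[i - 1] && m[i - 1] > m[i - 2]) {
        n_used <- which.min(m[seq_len(i - 2)]); converged <- FALSE; break
      }
    }
  }

  structure(list(
    u = u[seq_len(N + 1)], w = w[seq_len(N + 1)],
    N = as.integer(n_used),
    S_C = SCp[n_used + 1], S_D = SDp[n_used + 1],
    converged = converged,
    smallest_term_index = which.min(m[seq_len(n_used)])
  ), class = "eco_series")
}

#' @export
print.eco_series <- function(x, ...) {
  cat(sprintf("<eco_series> N = %d, S_C = %g, S_D = %g, converged = %s\n",
              x$N, x$S_C, x$S_D, x$converged))
  invisible(x)
}

#' Right-hand side of the three-variable evolution system
#'
#' Evaluates the full evolution system at one state: the density equation
#' `x_t = k_in + x (W - Y)`, and the parameter-evolution equations
#' `C_t = -p_C W S_C` and `D_t = p_D W D H S_D` with the truncated series
#' sums from [truncate_sums()]. The mortality rate `Y` inside the first
#' series is the instantaneous value at the state.
#'
#' @param state an [eco_state()].
#' @param params an [eco_params()].
#' @param policy an [trunc_policy()].
#' @param compiled use the compiled core (identical arithmetic, much faster)
#'   instead of the R reference path.
#' @return A list with `x_t`, `C_t`, `D_t`, plus diagnostics `n_used` and
#'   `converged` from the series truncation.
#' @examples
#' p <- eco_params(k_in = 1.29, k_Sx = 1.23, K_D = 0.26, K_E = 0.007,
#'                 p_C = 0.0015, p_D = 0.02111)
#' eco_rhs(eco_state(x = 0.31, C = 30.08, D = 3.5), p)
#' @export
eco_rhs <- function(state, params, policy = trunc_policy(), compiled = FALSE) {
  stopifnot(inherits(state, "eco_state"), inherits(params, "eco_params"))
  if (compiled) {
    v <- eco_rhs_core(state$x, state$C, state$D, param_vector(params),
                      policy$max_order, policy$rtol_series)
    return(list(x_t = v[1], C_t = v[2], D_t = v[3],
                n_used = as.integer(v[4]), converged = v[5] == 1))
  }
  rates <- compute_rates(state, params)
  cf <- series_coefficients(state, params, policy$max_order)
  s <- truncate_sums(cf$u, cf$w, rates$Y, state$C, policy)
  list(
    x_t = params$k_in + state$x * (rates$W - rates$Y),
    C_t = -params$p_C * rates$W * s$S_C,
    D_t = params$p_D * rates$W * state$D * rates$H * s$S_D,
    n_used = s$N, converged = s$converged
  )
}
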