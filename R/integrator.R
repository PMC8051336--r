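#' Solver options for the ecosystem integrator
#'
#' @param method a [deSolve::ode()] method; the default `"lsoda"` switches
#'   automatically between stiff and non-stiff integration, which matters
#'   because the collapse phase of the punctuated cycle is fast relative to
#'   the stasis phase.
#' @param rtol,atol relative and absolute integration tolerances.
#' @param blowup_guard magnitude of `x`, `C` or `D` beyond which the run is
#'   aborted as diverged.
#' @param compiled evaluate the right-hand side through the compiled core.
#' @return A list of class `eco_solver_opts`.
#' @export
solver_opts <- function(method = "lsoda", rtol = 1e-8, atol = 1e-10,
                        blowup_guard = 1e12, compiled = TRUE) {
  structure(list(method = method, rtol = rtol, atol = atol,
                 blowup_guard = blowup_guard, compiled = compiled),
            class = "eco_solver_opts")
}

#' Integrate the three-variable evolution system
#'
#' Solves the coupled equations for biota density, carrying capacity and
#' mortality coefficient over a supplied output grid, using an adaptive
#' stiffness-switching integrator. After integration the right-hand side is
#' re-evaluated at every output row to record the series-truncation
#' diagnostics (truncation order used, convergence flag) and the rate laws
#' `W`, `Y`, `H` along the trajectory.
#'
#' Non-negativity of `x` is enforced by error rather than clipping: with
#' `k_in > 0` the flow cannot cross `x = 0`, so a sampled `x` below `-atol`
#' indicates solver failure and aborts with the last valid time in the
#' message.
#'
#' @param params an [eco_params()].
#' @param init an [eco_state()]; its `t` is ignored in favour of `t_grid[1]`.
#' @param t_grid strictly increasing numeric vector of output times.
#' @param opts an [solver_opts()].
#' @param policy an [trunc_policy()].
#' @return An object of class `eco_trajectory`: list with `times`, `states`
#'   (data frame `t`, `x`, `C`, `D`), `diagnostics` (data frame `W`, `Y`,
#'   `H`, `trunc_order`, `converged`), `params`, `init`, `opts`, `policy`.
#' @examples
#' p <- eco_params(k_aSx = 2, k_Sx = 0, k_d = 1, K_D = 1e12)
#' tr <- simulate_ecosystem(p, eco_state(x = 1, C = 10, D = 0),
#'                          t_grid = seq(0, 40, by = 1))
#' tail(as.data.frame(tr), 2)  # settles at C (1 - k_d / k_aSx) = 5
#' @export
simulate_ecosystem <- function(params, init, t_grid,
                               opts = solver_opts(),
                               policy = trunc_policy()) {
  stopifnot(inherits(params, "eco_params"), inherits(init, "eco_state"))
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0))
    stop("simulate_ecosystem: t_grid must be strictly increasing",
         call. = FALSE)

  pv <- param_vector(params)
  n_max <- policy$max_order
  rtol_s <- policy$rtol_series
  guard <- opts$blowup_guard
  C_floor <- init$C_floor

  deriv <- if (opts$compiled) {
    function(t, y, parms) {
      if (!all(is.finite(y)))
        stop("integration failure: non-finite state at t = ", t, call. = FALSE)
      if (max(abs(y)) > guard)
        stop("integration failure: state blow-up at t = ", t, call. = FALSE)
      if (y[2] < C_floor)
        stop("integration failure: carrying capacity below C_floor at t = ",
             t, call. = FALSE)
      v <- eco_rhs_core(y[1], y[2], y[3], pv, n_max, rtol_s)
      list(v[1:3])
    }
  } else {
    function(t, y, parms) {
      if (!all(is.finite(y)))
        stop("integration failure: non-finite state at t = ", t, call. = FALSE)
      if (max(abs(y)) > guard)
        stop("integration failure: state blow-up at t = ", t, call. = FALSE)
      if (y[2] < C_floor)
        stop("integration failure: carrying capacity below C_floor at t = ",
             t, call. = FALSE)
      # bypass eco_state() validation: the solver may probe slightly
      # negative x transiently; the formulas are well defined there
      st <- structure(list(t = t, x = y[1], C = y[2], D = y[3],
                           C_floor = C_floor), class = "eco_state")
      d <- eco_rhs(st, params, policy)
      list(c(d$x_t, d$C_t, d$D_t))
    }
  }

  sol <- deSolve::ode(y = c(x = init$x, C = init$C, D = init$D),
                      times = t_grid, func = deriv, parms = NULL,
                      method = opts$method, rtol = opts$rtol,
                      atol = opts$atol, maxsteps = 100000)
  sol <- as.data.frame(sol)
  names(sol)[1] <- "t"
  if (nrow(sol) < length(t_grid))
    stop(sprintf("integration failure: solver stopped at t = %g (of %g)",
                 max(sol$t), max(t_grid)), call. = FALSE)
  if (any(sol$x < -opts$atol))
    stop(sprintf("integration failure: x < -atol first at t = %g",
                 sol$t[which(sol$x < -opts$atol)[1]]), call. = FALSE)

  diag <- t(vapply(seq_len(nrow(sol)), function(i) {
    eco_rhs_core(sol$x[i], sol$C[i], sol$D[i], pv, n_max, rtol_s)
  }, numeric(8)))
  diagnostics <- data.frame(W = diag[, 6], Y = diag[, 7], H = diag[, 8],
                            trunc_order = as.integer(diag[, 4]),
                            converged = diag[, 5] == 1)

  structure(list(times = sol$t,
                 states = sol[, c("t", "x", "C", "D")],
                 diagnostics = diagnostics,
                 params = params, init = init,
                 opts = opts, policy = policy),
            class = "eco_trajectory")
}

#' @export
print.eco_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<eco_trajectory> %d samples, t in [%g, %g]\n",
              n, x$times[1], x$times[n]))
  cat(sprintf("  x in [%.4g, %.4g], C in [%.4g, %.4g], D in [%.4g, %.4g]\n",
              min(x$states$x), max(x$states$x),
              min(x$states$C), max(x$states$C),
              min(x$states$D), max(x$states$D)))
  nc <- sum(!x$diagnostics$converged)
  if (nc > 0)
    cat(sprintf("  %d sampled states with non-converged series truncation\n", nc))
  invisible(x)
}

#' @export
as.data.frame.eco_trajectory <- function(x, ...) {
  cbind(x$states, x$diagnostics)
}

#' Summarise trajectory diagnostics
#'
#' @param traj an [simulate_ecosystem()] trajectory.
#' @return A list with the count of sampled states whose series truncation
#'   did not converge, ranges of the state variables, and a `clean` flag that
#'   is `TRUE` when every sampled evaluation converged.
#' @export
check_trajectory <- function(traj) {
  stopifnot(inherits(traj, "eco_trajectory"))
  if (length(traj$times) == 0 || nrow(traj$diagnostics) == 0)
    stop("check_trajectory: empty trajectory", call. = FALSE)
  nonconv <- sum(!traj$diagnostics$converged)
  list(
    n_samples = length(traj$times),
    n_nonconverged = nonconv,
    clean = nonconv == 0,
    x_range = range(traj$states$x),
    C_range = range(traj$states$C),
    D_range = range(traj$states$D)
  )
}
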