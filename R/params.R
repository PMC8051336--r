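#' Model parameters of the ecosystem evolution system
#'
#' Bundles the eight fixed rate constants of the three-variable evolution
#' system. All values are in conventional (dimensionless) units.
#'
#' @param k_in nonnegative influx rate of biota from outside the modelling
#'   area.
#' @param k_aSx nonnegative rate constant for asexual reproduction.
#' @param k_Sx nonnegative rate constant for sexual reproduction (the density
#'   factor of the reproduction law).
#' @param k_d positive baseline specific mortality rate. Also scales the
#'   crowding function, so the equilibrium structure is invariant under a
#'   common rescaling of `k_in`, `k_aSx`, `k_Sx`, `k_d`; `k_d = 1` is the
#'   conventional normalisation used by [fit_parameters()].
#' @param K_D positive half-saturation-like constant of the crowding
#'   function.
#' @param K_E positive density scale of the auto-aggression factor
#'   `exp(x / K_E - 1)`.
#' @param p_C nonnegative mutation-rate constant for the evolving carrying
#'   capacity `C`.
#' @param p_D nonnegative mutation-rate constant for the evolving mortality
#'   coefficient `D`.
#'
#' @return An object of class `eco_params` (a named list of the eight
#'   constants).
#' @seealso [eco_state()], [eco_rhs()], [eco_profile()]
#' @examples
#' eco_params(k_in = 0.01, k_Sx = 1, p_C = 0.0015, p_D = 0.02111)
#' @export
eco_params <- function(k_in = 0, k_aSx = 0, k_Sx = 1, k_d = 1,
                       K_D = 1, K_E = 1, p_C = 0, p_D = 0) {
  p <- list(k_in = k_in, k_aSx = k_aSx, k_Sx = k_Sx, k_d = k_d,
            K_D = K_D, K_E = K_E, p_C = p_C, p_D = p_D)
  vals <- unlist(p)
  if (!all(is.finite(vals)))
    stop("eco_params: all parameters must be finite", call. = FALSE)
  if (k_d <= 0 || K_D <= 0 || K_E <= 0)
    stop("eco_params: k_d, K_D and K_E must be strictly positive",
         call. = FALSE)
  if (any(c(k_in, k_aSx, k_Sx, p_C, p_D) < 0))
    stop("eco_params: rate constants must be nonnegative", call. = FALSE)
  if (k_aSx == 0 && k_Sx == 0)
    stop("eco_params: at least one of k_aSx, k_Sx must be positive",
         call. = FALSE)
  structure(p, class = "eco_params")
}

#' @export
print.eco_params <- function(x, ...) {
  cat("<eco_params>\n")
  cat(sprintf("  reproduction: k_aSx = %g, k_Sx = %g  (influx k_in = %g)\n",
              x$k_aSx, x$k_Sx, x$k_in))
  cat(sprintf("  mortality:    k_d = %g, K_D = %g, K_E = %g\n",
              x$k_d, x$K_D, x$K_E))
  cat(sprintf("  mutation:     p_C = %g, p_D = %g\n", x$p_C, x$p_D))
  invisible(x)
}

# parameter vector in the fixed order expected by the compiled core
param_vector <- function(params) {
  unlist(params[c("k_in", "k_aSx", "k_Sx", "k_d", "K_D", "K_E", "p_C", "p_D")])
}

#' State of the ecosystem
#'
#' The dynamical variables of the model: biota density `x`, evolving maximum
#' biota density (carrying capacity) `C`, and evolving mortality coefficient
#' `D`, at time `t`.
#'
#' @param x nonnegative biota density.
#' @param C positive carrying capacity; must exceed `C_floor`.
#' @param D nonnegative mortality coefficient.
#' @param t time in conventional units.
#' @param C_floor smallest admissible carrying capacity; states with
#'   `C <= C_floor` are rejected as degenerate.
#'
#' @return An object of class `eco_state`.
#' @examples
#' eco_state(x = 0.31, C = 30.08, D = 3.5)
#' @export
eco_state <- function(x, C, D, t = 0, C_floor = 1e-9) {
  if (!all(is.finite(c(x, C, D, t))))
    stop("eco_state: non-finite state", call. = FALSE)
  if (x < 0)
    stop("eco_state: biota density x must be nonnegative", call. = FALSE)
  if (C <= C_floor)
    stop(sprintf("eco_state: degenerate state, C = %g is at or below C_floor = %g",
                 C, C_floor), call. = FALSE)
  if (D < 0)
    stop("eco_state: mortality coefficient D must be nonnegative",
         call. = FALSE)
  structure(list(t = t, x = x, C = C, D = D, C_floor = C_floor),
            class = "eco_state")
}

#' @export
print.eco_state <- function(x, ...) {
  cat(sprintf("<eco_state> t = %g: x = %g, C = %g, D = %g\n",
              x$t, x$x, x$C, x$D))
  invisible(x)
}
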