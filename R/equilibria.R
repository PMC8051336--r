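#' Residual of the frozen density equation
#'
#' The stationarity condition of the density equation at frozen `(C, D)` is
#' `g(x) = k_in + x (W(x) - Y(x)) = 0`; this function evaluates `g`
#' (vectorised over `x`).
#'
#' @param x positive density (may be a vector).
#' @param C frozen carrying capacity.
#' @param D frozen mortality coefficient.
#' @param params an [eco_params()].
#' @return Numeric vector of residual values.
#' @export
stationarity_residual <- function(x, C, D, params) {
  stopifnot(inherits(params, "eco_params"))
  ka <- params$k_aSx; ks <- params$k_Sx; kd <- params$k_d
  KD <- params$K_D; KE <- params$K_E
  z <- x / KE - 1
  H <- ifelse(z >= 0,
              kd * x / (KD * exp(-pmin(z, 700)) + x),
              kd * x * exp(z) / (KD + x * exp(z)))
  H[x == 0] <- 0
  W <- (ka + ks * x) * (1 - x / C)
  params$k_in + x * (W - (kd + D * H))
}

# derivative of the residual: g'(x) = (W - Y) + x (W_x - D H_x)
stationarity_dgdx <- function(x, C, D, params) {
  r <- compute_rates(structure(list(t = 0, x = x, C = C, D = D,
                                    C_floor = 1e-300),
                               class = "eco_state"), params)
  (r$W - r$Y) + x * (r$W_x - D * r$H_x)
}

#' Search settings for the equilibrium finder
#'
#' @param x_lo,x_hi search range as fractions of `C` (defaults `1e-6 C` to
#'   `2 C`: the reproduction law is negative beyond `C`, so for small influx
#'   no root exists above `2 C`).
#' @param n_grid number of bracketing grid points. The grid is log-spaced
#'   below `x_break` and linear above, because the lower equilibria are
#'   typically two orders of magnitude smaller than the upper one.
#' @param x_break switchover density between the log and linear grid
#'   sections; `NULL` picks `max(K_E, C / 60)`.
#' @param root_rtol relative tolerance to which each bracketed root is
#'   polished.
#' @param marginal_tol threshold on `|dg/dx|` below which a root is labelled
#'   marginal (fold point) rather than stable or unstable.
#' @return A list of class `eco_search`.
#' @export
equilibrium_search <- function(x_lo = 1e-6, x_hi = 2, n_grid = 4000L,
                               x_break = NULL, root_rtol = 1e-10,
                               marginal_tol = 1e-8) {
  structure(list(x_lo = x_lo, x_hi = x_hi, n_grid = as.integer(n_grid),
                 x_break = x_break, root_rtol = root_rtol,
                 marginal_tol = marginal_tol),
            class = "eco_search")
}

#' Equilibria of the frozen density equation
#'
#' Finds all simple roots of the stationarity residual on the search range,
#' classifies their stability from the sign of `dg/dx` (negative means
#' stable), and labels them. With three roots the structure is always
#' stable/unstable/stable and the labels are `x_min`, `x_mdl`, `x_max` in
#' increasing order; a single root is labelled `x_max` when it lies above
#' `C/2` and `x_min` otherwise; with two roots (a fold) the unstable one is
#' labelled `x_mdl` and the stable one by its position.
#'
#' More than three roots would violate the model's intersection structure
#' (the reproduction and mortality curves can cross at most three times) and
#' raise an anomaly error carrying the offending root set.
#'
#' @param C frozen carrying capacity.
#' @param D frozen mortality coefficient.
#' @param params an [eco_params()].
#' @param search an [equilibrium_search()].
#' @return An object of class `eco_equilibria`: list with `C`, `D`, `roots`
#'   (data frame `x`, `dgdx`, `stable`, `label`) sorted by increasing `x`,
#'   and `n_roots`.
#' @examples
#' p <- eco_params(k_in = 1.294, k_Sx = 1.229, K_D = 0.257, K_E = 0.00703)
#' find_equilibria(C = 30.082, D = 3.5, p)
#' @export
find_equilibria <- function(C, D, params, search = equilibrium_search()) {
  stopifnot(inherits(params, "eco_params"), C > 0, D >= 0)
  x_lo <- search$x_lo * C
  x_hi <- search$x_hi * C
  x_break <- if (is.null(search$x_break)) max(params$K_E, C / 60) else search$x_break
  x_break <- min(max(x_break, x_lo * 1.01), x_hi * 0.99)
  n_log <- search$n_grid %/% 2
  xs <- sort(unique(c(
    exp(seq(log(x_lo), log(x_break), length.out = n_log)),
    seq(x_break, x_hi, length.out = search$n_grid - n_log)
  )))
  gv <- stationarity_residual(xs, C, D, params)
  flips <- which(gv[-1] * gv[-length(gv)] < 0)
  exact <- which(gv == 0)

  roots <- vapply(flips, function(i) {
    stats::uniroot(function(x) stationarity_residual(x, C, D, params),
                   lower = xs[i], upper = xs[i + 1],
                   tol = search$root_rtol * xs[i + 1])$root
  }, numeric(1))
  roots <- sort(unique(c(roots, xs[exact])))

  dg <- vapply(roots, stationarity_dgdx, numeric(1), C = C, D = D,
               params = params)
  stable <- dg < 0
  n <- length(roots)
  if (n > 3) {
    cond <- structure(
      class = c("eco_anomaly_error", "error", "condition"),
      list(message = sprintf(
        "find_equilibria: %d roots found at C = %g, D = %g; the model admits at most three",
        n, C, D),
        call = sys.call(-1), roots = roots))
    stop(cond)
  }
  label <- rep(NA_character_, n)
  if (n == 3) {
    label <- c("x_min", "x_mdl", "x_max")
  } else if (n == 1) {
    label <- if (roots > C / 2) "x_max" else "x_min"
  } else if (n == 2) {
    label[!stable] <- "x_mdl"
    label[stable] <- if (any(roots[stable] > C / 2)) "x_max" else "x_min"
  }
  marginal <- abs(dg) < search$marginal_tol
  structure(list(
    C = C, D = D,
    roots = data.frame(x = roots, dgdx = dg, stable = stable,
                       marginal = marginal, label = label,
                       stringsAsFactors = FALSE),
    n_roots = n
  ), class = "eco_equilibria")
}

#' @export
print.eco_equilibria <- function(x, ...) {
  cat(sprintf("<eco_equilibria> C = %g, D = %g: %d root(s)\n",
              x$C, x$D, x$n_roots))
  if (x$n_roots > 0) print(x$roots, row.names = FALSE)
  invisible(x)
}

#' Manifested stationary state
#'
#' Given the current density and an equilibrium set, returns the stable
#' stationary state whose basin of attraction contains the current density:
#' with three roots, the lower state if `x < x_mdl` and the upper state
#' otherwise; with a single stable root, that root regardless of `x`.
#'
#' @param x current positive density.
#' @param eq an [find_equilibria()] result with at least one stable root.
#' @return A list with `label` (`"x_min"` or `"x_max"`), `x_value` (the
#'   manifested equilibrium density) and `boundary` (the basin boundary
#'   `x_mdl`, or `NA` when there is no middle root).
#' @export
manifested_state <- function(x, eq) {
  stopifnot(inherits(eq, "eco_equilibria"))
  st <- eq$roots[eq$roots$stable, , drop = FALSE]
  if (nrow(st) == 0)
    stop(structure(
      class = c("eco_anomaly_error", "error", "condition"),
      list(message = "manifested_state: equilibrium set has no stable root",
           call = sys.call())))
  if (nrow(st) == 1) {
    lab <- st$label
    if (is.na(lab)) lab <- if (st$x > eq$C / 2) "x_max" else "x_min"
    bnd <- eq$roots$x[eq$roots$label == "x_mdl"]
    return(list(label = lab, x_value = st$x,
                boundary = if (length(bnd)) bnd[1] else NA_real_))
  }
  mdl <- eq$roots$x[eq$roots$label == "x_mdl"]
  if (x < mdl[1])
    list(label = "x_min", x_value = min(st$x), boundary = mdl[1])
  else
    list(label = "x_max", x_value = max(st$x), boundary = mdl[1])
}

#' Bistability map over a (C, D) grid
#'
#' Evaluates [find_equilibria()] on a rectangular grid of frozen `(C, D)`
#' values and tabulates root counts and labelled root positions. Cells where
#' the finder raises an anomaly (more than three roots) are recorded with
#' their actual root count and `NA` labels rather than aborting the map.
#'
#' @param params an [eco_params()].
#' @param C_range,D_range length-2 positive ranges.
#' @param n_C,n_D grid sizes.
#' @param search an [equilibrium_search()].
#' @return A data frame of class `eco_bistability_map` with columns `C`,
#'   `D`, `root_count`, `x_min`, `x_mdl`, `x_max`, and attribute `summary`
#'   (cell counts and area fractions per root count).
#' @export
bistability_map <- function(params, C_range, D_range, n_C = 25L, n_D = 25L,
                            search = equilibrium_search()) {
  stopifnot(length(C_range) == 2, length(D_range) == 2,
            all(C_range > 0), all(D_range >= 0))
  grid <- expand.grid(C = seq(C_range[1], C_range[2], length.out = n_C),
                      D = seq(D_range[1], D_range[2], length.out = n_D))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    eq <- tryCatch(find_equilibria(grid$C[i], grid$D[i], params, search),
                   eco_anomaly_error = function(e) e)
    if (inherits(eq, "eco_anomaly_error"))
      return(data.frame(root_count = length(eq$roots), x_min = NA_real_,
                        x_mdl = NA_real_, x_max = NA_real_))
    pick <- function(lab) {
      v <- eq$roots$x[!is.na(eq$roots$label) & eq$roots$label == lab]
      if (length(v)) v[1] else NA_real_
    }
    data.frame(root_count = eq$n_roots, x_min = pick("x_min"),
               x_mdl = pick("x_mdl"), x_max = pick("x_max"))
  })
  out <- cbind(grid, do.call(rbind, res))
  tab <- table(out$root_count)
  attr(out, "summary") <- data.frame(
    root_count = as.integer(names(tab)),
    n_cells = as.integer(tab),
    area_fraction = as.numeric(tab) / nrow(out))
  class(out) <- c("eco_bistability_map", class(out))
  out
}

#' Saddle-node events along a trajectory
#'
#' Tracks the root count of the frozen density equation along `(C(t), D(t))`
#' of a trajectory and brackets every change by bisection in time (linearly
#' interpolating `C` and `D` between samples). A decrease by two is
#' classified as a merge of the vanishing pair: `lower-pair-merge` when the
#' lower stable root and the middle root disappear (the upper state
#' survives), `upper-pair-merge` when the upper pair disappears;
#' an increase by two is a `pair-birth`.
#'
#' @param traj an [simulate_ecosystem()] trajectory.
#' @param params an [eco_params()]; defaults to the trajectory's own.
#' @param dt_tol bracket width at which bisection stops; `NULL` picks
#'   `1e-3` times the median sampling step.
#' @param search an [equilibrium_search()].
#' @return A data frame of events with columns `t_lo`, `t_hi`, `kind`,
#'   `merged_x`, `count_before`, `count_after` (zero rows when the root
#'   count never changes).
#' @export
saddle_node_scan <- function(traj, params = traj$params, dt_tol = NULL,
                             search = equilibrium_search()) {
  stopifnot(inherits(traj, "eco_trajectory"))
  tt <- traj$times
  if (is.null(dt_tol)) dt_tol <- 1e-3 * stats::median(diff(tt))
  Cf <- stats::approxfun(tt, traj$states$C)
  Df <- stats::approxfun(tt, traj$states$D)
  count_at <- function(t) {
    eq <- tryCatch(find_equilibria(Cf(t), max(Df(t), 0), params, search),
                   eco_anomaly_error = function(e) NULL)
    if (is.null(eq)) return(NA_integer_)
    eq$n_roots
  }
  counts <- vapply(tt, count_at, integer(1))
  ch <- which(diff(counts) != 0 & !is.na(diff(counts)))
  if (length(ch) == 0) {
    return(data.frame(t_lo = numeric(0), t_hi = numeric(0),
                      kind = character(0), merged_x = numeric(0),
                      count_before = integer(0), count_after = integer(0)))
  }
  events <- lapply(ch, function(i) {
    lo <- tt[i]; hi <- tt[i + 1]
    c_lo <- counts[i]; c_hi <- counts[i + 1]
    while (hi - lo > dt_tol) {
      mid <- (lo + hi) / 2
      cm <- count_at(mid)
      if (is.na(cm)) break
      if (cm == c_lo) lo <- mid else { hi <- mid; c_hi <- cm }
    }
    richer_t <- if (c_lo > c_hi) lo else hi
    eq_rich <- find_equilibria(Cf(richer_t), max(Df(richer_t), 0), params,
                               search)
    eq_poor_t <- if (c_lo > c_hi) hi else lo
    eq_poor <- find_equilibria(Cf(eq_poor_t), max(Df(eq_poor_t), 0), params,
                               search)
    kind <- if (c_hi > c_lo) "pair-birth" else "count-change"
    merged_x <- NA_real_
    if (abs(c_lo - c_hi) == 2 && eq_rich$n_roots >= 3) {
      # the vanishing pair is the pair of rich-side roots farthest from any
      # surviving root
      dist_to_surv <- vapply(eq_rich$roots$x, function(r)
        min(abs(r - eq_poor$roots$x)), numeric(1))
      pair <- order(dist_to_surv, decreasing = TRUE)[1:2]
      merged_x <- mean(eq_rich$roots$x[sort(pair)])
      lower_pair <- all(sort(pair) == c(1, 2))
      if (c_lo > c_hi) {
        kind <- if (lower_pair) "lower-pair-merge" else "upper-pair-merge"
      } else {
        kind <- "pair-birth"
      }
    }
    data.frame(t_lo = lo, t_hi = hi, kind = kind, merged_x = merged_x,
               count_before = c_lo, count_after = c_hi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, events)
}

#' Reproduction/mortality diagram table
#'
#' Tabulates the reproduction law `W`, the mortality law `Y` and the
#' density-dependent mortality component `D H` on a density grid at frozen
#' `(C, D)`, for redrawing the intersection diagrams whose crossings are the
#' stationary states. `Y - D H` is the constant baseline mortality `k_d`.
#'
#' @param C,D frozen parameter values.
#' @param params an [eco_params()].
#' @param x_grid positive increasing density grid; `NULL` picks 400 points
#'   on `(0, 1.2 C]`.
#' @return A data frame with columns `x`, `W`, `Y`, `DH`.
#' @export
wy_table <- function(C, D, params, x_grid = NULL) {
  stopifnot(inherits(params, "eco_params"))
  if (is.null(x_grid)) x_grid <- seq(1e-3 * C, 1.2 * C, length.out = 400)
  if (any(diff(x_grid) <= 0) || any(x_grid <= 0))
    stop("wy_table: x_grid must be positive and increasing", call. = FALSE)
  rows <- lapply(x_grid, function(x) {
    r <- compute_rates(structure(list(t = 0, x = x, C = C, D = D,
                                      C_floor = 1e-300),
                                 class = "eco_state"), params)
    data.frame(x = x, W = r$W, Y = r$Y, DH = D * r$H)
  })
  do.call(rbind, rows)
}
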