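# ---- peak/trough utilities ------------------------------------------------

# local maxima of a series with topographic prominence above `min_prom`.
# prominence of a peak: height above the higher of the two deepest valleys
# separating it from higher terrain (or the series ends).
local_peaks <- function(y, min_prom = 0) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  keep <- vapply(cand, function(i) {
    h <- y[i]
    j <- i
    left_min <- h
    while (j > 1 && y[j] <= h) { j <- j - 1; left_min <- min(left_min, y[j]) }
    if (y[j] <= h) left_min <- min(y[1:i])
    j <- i
    right_min <- h
    while (j < n && y[j] <= h) { j <- j + 1; right_min <- min(right_min, y[j]) }
    if (y[j] <= h) right_min <- min(y[i:n])
    (h - max(left_min, right_min)) >= min_prom
  }, logical(1))
  cand[keep]
}

local_troughs <- function(y, min_prom = 0) local_peaks(-y, min_prom)

cv <- function(v) stats::sd(v) / mean(v)

# ---- regime classification ------------------------------------------------

#' Settings for long-run regime classification
#'
#' @param transient_fraction fraction of the trajectory discarded before
#'   classification (the initial conditions of the system are essentially
#'   arbitrary, so half the run is treated as transient).
#' @param cv_tol coefficient of variation of the post-transient density
#'   below which the run is called stationary.
#' @param periodic_cv_tol maximum coefficient of variation of both
#'   peak-to-peak intervals and peak amplitudes for a periodic label.
#' @param min_cycles minimum number of putative cycles required after the
#'   transient; fewer yields the label `undetermined`.
#' @param peak_prom_frac prominence threshold for oscillation peaks, as a
#'   fraction of the post-transient range of `x`.
#' @param lyapunov optional precomputed largest Lyapunov exponent; when
#'   `NULL` one is estimated (see [classify_regime()]).
#' @param lyap_tol positive threshold above which the Lyapunov estimate
#'   counts as chaotic.
#' @param lyap_settings settings passed to [lyapunov_exponent()] when a
#'   model-based estimate is needed.
#' @return A list of class `eco_regime_settings`.
#' @export
regime_settings <- function(transient_fraction = 0.5, cv_tol = 1e-3,
                            periodic_cv_tol = 0.05, min_cycles = 10,
                            peak_prom_frac = 0.25, lyapunov = NULL,
                            lyap_tol = 1e-3, lyap_settings = NULL) {
  structure(list(transient_fraction = transient_fraction, cv_tol = cv_tol,
                 periodic_cv_tol = periodic_cv_tol, min_cycles = min_cycles,
                 peak_prom_frac = peak_prom_frac, lyapunov = lyapunov,
                 lyap_tol = lyap_tol, lyap_settings = lyap_settings),
            class = "eco_regime_settings")
}

#' Classify the long-run dynamical regime of a trajectory
#'
#' After discarding the transient, labels the run `stationary` (negligible
#' variation of the density), `periodic` (regular peak spacing and
#' amplitude), `chaotic` (sustained aperiodic oscillation together with a
#' positive largest Lyapunov exponent) or `undetermined`.
#'
#' Requiring both aperiodicity and a positive Lyapunov estimate for the
#' chaotic label avoids misclassifying long transients. The Lyapunov value
#' is taken from `settings$lyapunov` if supplied; otherwise, for
#' trajectories carrying model parameters a two-trajectory estimate on the
#' flow is computed from the post-transient state, and for synthetic
#' trajectories a divergence-rate estimate from the sampled series is used
#' ([lyapunov_series()]).
#'
#' @param traj an `eco_trajectory`, or any list with components `times` and
#'   `states$x` (synthetic fixtures).
#' @param settings an [regime_settings()].
#' @return An object of class `eco_regime`: list with `label`,
#'   `period_estimate`, `amplitude`, `lyapunov`,
#'   `transient_fraction_discarded`, `n_peaks`.
#' @export
classify_regime <- function(traj, settings = regime_settings()) {
  if (is.null(traj$times) || length(traj$times) == 0)
    stop("classify_regime: empty trajectory", call. = FALSE)
  tt <- traj$times
  xx <- traj$states$x
  keep <- tt >= tt[1] + settings$transient_fraction * (tt[length(tt)] - tt[1])
  t2 <- tt[keep]; x2 <- xx[keep]

  rep0 <- list(label = "undetermined", period_estimate = NA_real_,
               amplitude = max(x2) - min(x2), lyapunov = NA_real_,
               transient_fraction_discarded = settings$transient_fraction,
               n_peaks = 0L)

  if (mean(x2) > 0 && cv(x2) < settings$cv_tol) {
    rep0$label <- "stationary"
    return(structure(rep0, class = "eco_regime"))
  }

  prom <- settings$peak_prom_frac * (max(x2) - min(x2))
  pk <- local_peaks(x2, min_prom = prom)
  rep0$n_peaks <- length(pk)
  if (length(pk) >= 2) {
    intervals <- diff(t2[pk])
    amps <- x2[pk]
    rep0$period_estimate <- mean(intervals)
    rep0$amplitude <- mean(amps) - min(x2)
    if (length(pk) - 1 >= settings$min_cycles &&
        cv(intervals) < settings$periodic_cv_tol &&
        cv(amps) < settings$periodic_cv_tol) {
      rep0$label <- "periodic"
      return(structure(rep0, class = "eco_regime"))
    }
  }
  if (length(pk) < settings$min_cycles) {
    return(structure(rep0, class = "eco_regime"))
  }

  # sustained aperiodic oscillation: decide chaos by the Lyapunov exponent
  lam <- settings$lyapunov
  if (is.null(lam)) {
    lam <- if (inherits(traj, "eco_trajectory")) {
      st <- structure(list(t = t2[1], x = x2[1], C = traj$states$C[keep][1],
                           D = traj$states$D[keep][1], C_floor = 1e-9),
                      class = "eco_state")
      ls <- settings$lyap_settings
      if (is.null(ls)) ls <- lyapunov_settings()
      lyapunov_exponent(traj$params, st, ls)
    } else {
      lyapunov_series(x2, dt = stats::median(diff(t2)))
    }
  }
  rep0$lyapunov <- lam
  rep0$label <- if (is.finite(lam) && lam > settings$lyap_tol) "chaotic"
                else "undetermined"
  structure(rep0, class = "eco_regime")
}

#' @export
print.eco_regime <- function(x, ...) {
  cat(sprintf("<eco_regime> %s", x$label))
  if (!is.na(x$period_estimate))
    cat(sprintf(", period ~ %.4g", x$period_estimate))
  if (!is.na(x$lyapunov))
    cat(sprintf(", lyapunov ~ %.4g", x$lyapunov))
  cat(sprintf(", amplitude ~ %.4g\n", x$amplitude))
  invisible(x)
}

# ---- Lyapunov estimation --------------------------------------------------

#' Settings for the two-trajectory Lyapunov estimator
#'
#' @param delta0 initial separation of the two trajectories.
#' @param tau renormalisation interval (time units).
#' @param horizon total integration time of the estimate.
#' @param settle time integrated before the estimate starts, letting the
#'   reference trajectory reach its attractor and the perturbation align
#'   with the leading direction.
#' @param discard_fraction fraction of the earliest renormalisation
#'   intervals excluded from the average.
#' @return A list of class `eco_lyap_settings`.
#' @export
lyapunov_settings <- function(delta0 = 1e-8, tau = 2, horizon = 2000,
                              settle = 500, discard_fraction = 0.2) {
  structure(list(delta0 = delta0, tau = tau, horizon = horizon,
                 settle = settle, discard_fraction = discard_fraction),
            class = "eco_lyap_settings")
}

#' Largest Lyapunov exponent of a flow
#'
#' Two-trajectory renormalisation estimate: a reference and a perturbed copy
#' are integrated jointly; every `tau` time units the log separation growth
#' is recorded and the perturbation is rescaled back to `delta0`. The
#' estimate is the mean log growth rate over the retained intervals, in
#' units of inverse conventional time.
#'
#' @param sys an [eco_params()] (the ecosystem flow is used) or a function
#'   `f(t, y)` returning the derivative of an arbitrary flow.
#' @param init an [eco_state()] for the ecosystem flow, or a numeric state
#'   vector for a custom flow.
#' @param settings an [lyapunov_settings()].
#' @param opts an [solver_opts()] for the ecosystem flow.
#' @param policy an [trunc_policy()] for the ecosystem flow.
#' @return The estimated largest Lyapunov exponent (numeric scalar).
#' @examples
#' # stable spiral: contraction at rate -0.1
#' f <- function(t, y) c(-0.1 * y[1] - y[2], y[1] - 0.1 * y[2])
#' lyapunov_exponent(f, c(1, 0),
#'                   lyapunov_settings(horizon = 200, settle = 50))
#' @export
lyapunov_exponent <- function(sys, init, settings = lyapunov_settings(),
                              opts = solver_opts(), policy = trunc_policy()) {
  if (inherits(sys, "eco_params")) {
    pv <- param_vector(sys)
    n_max <- policy$max_order; rtol_s <- policy$rtol_series
    f <- function(t, y) {
      v <- eco_rhs_core(y[1], y[2], y[3], pv, n_max, rtol_s)
      v[1:3]
    }
    y0 <- c(init$x, init$C, init$D)
  } else {
    stopifnot(is.function(sys))
    f <- sys
    y0 <- as.numeric(init)
  }
  d <- length(y0)
  fun2 <- function(t, y, parms) {
    list(c(f(t, y[1:d]), f(t, y[(d + 1):(2 * d)])))
  }
  run <- function(y, t0, t1) {
    sol <- deSolve::ode(y = y, times = c(t0, t1), func = fun2, parms = NULL,
                        method = opts$method, rtol = opts$rtol,
                        atol = opts$atol, maxsteps = 100000)
    as.numeric(sol[nrow(sol), -1])
  }
  # settle the reference, then attach the perturbed copy
  if (settings$settle > 0) {
    solr <- deSolve::ode(y = y0, times = c(0, settings$settle),
                         func = function(t, y, p) list(f(t, y)), parms = NULL,
                         method = opts$method, rtol = opts$rtol,
                         atol = opts$atol, maxsteps = 100000)
    y0 <- as.numeric(solr[nrow(solr), -1])
  }
  delta0 <- settings$delta0
  pert <- y0 + delta0 * rep(1 / sqrt(d), d)
  y <- c(y0, pert)
  n_int <- max(2L, floor(settings$horizon / settings$tau))
  s <- numeric(n_int)
  t_cur <- settings$settle
  for (k in seq_len(n_int)) {
    y <- run(y, t_cur, t_cur + settings$tau)
    t_cur <- t_cur + settings$tau
    d_now <- sqrt(sum((y[1:d] - y[(d + 1):(2 * d)])^2))
    if (!is.finite(d_now) || d_now == 0) {
      s[k] <- NA
      y[(d + 1):(2 * d)] <- y[1:d] + delta0 * rep(1 / sqrt(d), d)
      next
    }
    s[k] <- log(d_now / delta0)
    y[(d + 1):(2 * d)] <- y[1:d] + (delta0 / d_now) * (y[(d + 1):(2 * d)] - y[1:d])
  }
  drop_n <- floor(settings$discard_fraction * n_int)
  s_keep <- s[(drop_n + 1):n_int]
  mean(s_keep, na.rm = TRUE) / settings$tau
}

#' Largest Lyapunov exponent from a sampled series
#'
#' Divergence-rate estimate in the style of Rosenstein et al.: the series is
#' delay-embedded, each point is paired with its nearest neighbour outside a
#' Theiler window, the mean log distance between the pairs is tracked over
#' `k_steps` forward steps, and the exponent is the slope of that curve by
#' least squares.
#'
#' @param x numeric series, sampled at a constant step.
#' @param dt sampling step.
#' @param emb_dim embedding dimension.
#' @param delay embedding delay in samples.
#' @param theiler minimum temporal separation (samples) between neighbour
#'   pairs.
#' @param k_steps number of forward steps over which divergence is tracked.
#' @return Estimated exponent in units of `1/dt`.
#' @export
lyapunov_series <- function(x, dt = 1, emb_dim = 3, delay = 1, theiler = 10,
                            k_steps = 6) {
  n <- length(x) - (emb_dim - 1) * delay
  if (n < 4 * (theiler + k_steps))
    stop("lyapunov_series: series too short", call. = FALSE)
  emb <- sapply(seq_len(emb_dim), function(j) x[(1 + (j - 1) * delay):(n + (j - 1) * delay)])
  emb <- matrix(emb, nrow = n)
  n_use <- n - k_steps
  idx <- seq_len(n_use)
  # nearest neighbour outside the Theiler window
  nn <- vapply(idx, function(i) {
    d2 <- rowSums((emb[idx, , drop = FALSE] -
                     matrix(emb[i, ], n_use, emb_dim, byrow = TRUE))^2)
    d2[abs(idx - i) <= theiler] <- Inf
    which.min(d2)
  }, integer(1))
  dist_k <- vapply(0:k_steps, function(k) {
    dk <- sqrt(rowSums((emb[idx + k, , drop = FALSE] -
                          emb[nn + k, , drop = FALSE])^2))
    mean(log(dk[dk > 0]))
  }, numeric(1))
  ks <- 0:k_steps
  stats::coef(stats::lm(dist_k ~ ks))[["ks"]] / dt
}

# ---- cycles, phases, extinction events ------------------------------------

#' Detect oscillation cycles
#'
#' Cycle boundaries are the successive deep minima of the density,
#' prominence-filtered so that the shallow dips of local catastrophes inside
#' the stasis phase are not counted as cycle boundaries.
#'
#' Because the explosive-growth phase rings with large-amplitude dips, deep
#' minima can cluster around one collapse; minima closer together than
#' `min_gap_frac` of the trajectory span are merged, keeping the deepest, so
#' one boundary is reported per collapse.
#'
#' @param traj an `eco_trajectory` or a list with `times` and `states$x`.
#' @param prom_frac prominence threshold as a fraction of the range of `x`.
#' @param min_gap_frac minimum boundary separation as a fraction of the
#'   trajectory span.
#' @return Numeric vector of boundary times (deep minima); length below two
#'   means no full cycle was found.
#' @export
detect_cycles <- function(traj, prom_frac = 0.5, min_gap_frac = 0.1) {
  tt <- traj$times; xx <- traj$states$x
  prom <- prom_frac * (max(xx) - min(xx))
  if (prom <= 0) return(numeric(0))
  tr <- local_troughs(xx, min_prom = prom)
  if (length(tr) < 2) return(tt[tr])
  gap <- min_gap_frac * (tt[length(tt)] - tt[1])
  cluster <- cumsum(c(1, diff(tt[tr]) > gap))
  keep <- vapply(split(tr, cluster), function(ix) ix[which.min(xx[ix])],
                 integer(1))
  tt[sort(keep)]
}

#' Phase thresholds for cycle segmentation
#'
#' All thresholds are relative to the running cycle maximum `M` of the
#' density, since the phases of the punctuated cycle are defined only
#' qualitatively.
#'
#' @param q_low fraction of `M` below which the system is in the
#'   low-density phase.
#' @param q_high fraction of `M` above which the system is in the
#'   high-density (stasis) regime.
#' @param dip_frac relative drop from the running maximum that qualifies a
#'   stasis-phase dip as a local catastrophe.
#' @return A list of class `eco_phase_thresholds`.
#' @export
phase_thresholds <- function(q_low = 0.1, q_high = 0.5, dip_frac = 0.25) {
  structure(list(q_low = q_low, q_high = q_high, dip_frac = dip_frac),
            class = "eco_phase_thresholds")
}

#' Segment one oscillation cycle into evolutionary phases
#'
#' Splits a cycle of the punctuated dynamics into the collapse phase `f1`
#' (fast fall from above `q_high * M` to below `q_low * M`), the low-density
#' phase `f2` (the maximal interval below `q_low * M`), the explosive-growth
#' phase `f3` (rise until the density first exceeds `q_high * M`), and the
#' stasis phase `f4`, itself divided into slow-growth stretches `f4s` and
#' local-catastrophe dips `f4n` (drops of more than `dip_frac` from the
#' running stasis maximum whose minima remain above `q_low * M`). A cycle
#' with no excursion below `q_low * M` is returned as a single `f4` segment
#' (mild evolution).
#'
#' @param traj an `eco_trajectory` or list with `times` and `states$x`.
#' @param cycle length-2 numeric: cycle start and end times.
#' @param thresholds an [phase_thresholds()].
#' @return An object of class `eco_phases`: list with `segments` (data frame
#'   `t_start`, `t_end`, `label`) tiling the cycle, and `cycle_bounds`.
#' @export
segment_phases <- function(traj, cycle, thresholds = phase_thresholds()) {
  stopifnot(length(cycle) == 2, cycle[1] < cycle[2])
  keep <- traj$times >= cycle[1] & traj$times <= cycle[2]
  tt <- traj$times[keep]; xx <- traj$states$x[keep]
  if (length(tt) < 3)
    stop("segment_phases: cycle contains too few samples", call. = FALSE)
  M <- max(xx)
  lo <- thresholds$q_low * M
  hi <- thresholds$q_high * M
  n <- length(tt)

  below <- xx < lo
  if (!any(below)) {
    seg <- subdivide_f4(tt, xx, 1L, n, thresholds, lo)
    return(structure(list(segments = seg, cycle_bounds = cycle),
                     class = "eco_phases"))
  }
  # maximal (longest) run below q_low: the f2 phase
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  f2_i <- c(starts[best], ends[best])

  # f1: collapse immediately before f2, from the last time x >= q_high * M
  f1_i <- NULL
  if (f2_i[1] > 1) {
    pre <- which(xx[seq_len(f2_i[1] - 1)] >= hi)
    if (length(pre)) f1_i <- c(max(pre), f2_i[1])
  }
  # f3: rise after f2 until x first exceeds q_high * M
  f3_i <- NULL
  if (f2_i[2] < n) {
    post <- which(xx[(f2_i[2] + 1):n] >= hi)
    if (length(post)) f3_i <- c(f2_i[2], f2_i[2] + min(post))
  }

  segs <- list()
  if (!is.null(f1_i) && f1_i[1] > 1)
    segs <- c(segs, list(subdivide_f4(tt, xx, 1L, f1_i[1], thresholds, lo)))
  if (!is.null(f1_i))
    segs <- c(segs, list(data.frame(t_start = tt[f1_i[1]], t_end = tt[f2_i[1]],
                                    label = "f1", stringsAsFactors = FALSE)))
  f2_start <- if (is.null(f1_i)) tt[1] else tt[f2_i[1]]
  f2_end <- if (is.null(f3_i)) tt[n] else tt[f3_i[1]]
  segs <- c(segs, list(data.frame(t_start = f2_start, t_end = f2_end,
                                  label = "f2", stringsAsFactors = FALSE)))
  if (!is.null(f3_i)) {
    segs <- c(segs, list(data.frame(t_start = tt[f3_i[1]], t_end = tt[f3_i[2]],
                                    label = "f3", stringsAsFactors = FALSE)))
    if (f3_i[2] < n)
      segs <- c(segs, list(subdivide_f4(tt, xx, f3_i[2], n, thresholds, lo)))
  }
  segments <- do.call(rbind, segs)
  segments <- segments[segments$t_end > segments$t_start, , drop = FALSE]
  rownames(segments) <- NULL
  structure(list(segments = segments, cycle_bounds = cycle),
            class = "eco_phases")
}

# split a stasis stretch [i0, i1] into f4s runs and f4n dips: a dip opens
# when x falls below (1 - dip_frac) of the running maximum and closes when
# it recovers above that level; dips reaching below q_low*M belong to f1/f2
# logic and are not expected here.
subdivide_f4 <- function(tt, xx, i0, i1, thresholds, lo) {
  idx <- i0:i1
  x <- xx[idx]
  runmax <- cummax(x)
  level <- (1 - thresholds$dip_frac) * runmax
  in_dip <- x < level & x >= lo
  if (!any(in_dip)) {
    return(data.frame(t_start = tt[i0], t_end = tt[i1], label = "f4s",
                      stringsAsFactors = FALSE))
  }
  r <- rle(in_dip)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- lapply(seq_along(r$lengths), function(k) {
    data.frame(t_start = tt[idx[starts[k]]],
               t_end = tt[idx[min(ends[k] + 1L, length(idx))]],
               label = if (r$values[k]) "f4n" else "f4s",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  out[out$t_end > out$t_start, , drop = FALSE]
}

#' @export
print.eco_phases <- function(x, ...) {
  cat(sprintf("<eco_phases> cycle [%g, %g]\n",
              x$cycle_bounds[1], x$cycle_bounds[2]))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Catalogue extinction events along a trajectory
#'
#' Prominence-filtered minima of the density are classified as `global`
#' extinction analogues when the minimum falls below `q_low` times the
#' running maximum since the previous event (the collapse reaches near-zero
#' density) and as `local` catastrophes otherwise.
#'
#' @param traj an `eco_trajectory` or list with `times` and `states$x`.
#' @param thresholds an [phase_thresholds()]; `q_low` sets the global/local
#'   boundary.
#' @param prom_frac prominence threshold for candidate minima, as a fraction
#'   of the range of `x`.
#' @return A data frame with columns `t`, `depth` (density at the minimum)
#'   and `kind`.
#' @export
extinction_events <- function(traj, thresholds = phase_thresholds(),
                              prom_frac = 0.1) {
  tt <- traj$times; xx <- traj$states$x
  rng <- max(xx) - min(xx)
  if (rng <= 0)
    return(data.frame(t = numeric(0), depth = numeric(0),
                      kind = character(0)))
  tr <- local_troughs(xx, min_prom = prom_frac * rng)
  if (!length(tr))
    return(data.frame(t = numeric(0), depth = numeric(0),
                      kind = character(0)))
  prev <- 1L
  rows <- lapply(tr, function(i) {
    runmax <- max(xx[prev:i])
    kind <- if (xx[i] < thresholds$q_low * runmax) "global" else "local"
    prev <<- i
    data.frame(t = tt[i], depth = xx[i], kind = kind,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
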