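#' Published equilibrium triples
#'
#' Returns the eleven equilibrium records transcribed from the published
#' intersection diagrams: frozen `(C, D)` values with the labelled
#' stationary densities `x_min`, `x_mdl`, `x_max` (absent entries are `NA`),
#' plus the instantaneous density `x_current` and time `t`, which are
#' informational only and never fitted. Eight records trace the passage
#' through the collapse/regrowth transition, three the stasis phase; two of
#' the eleven are partial (a single printed root) and two are near-fold
#' (middle and upper root nearly equal), which makes them highly sensitive
#' validation points.
#'
#' @return A data frame with columns `source`, `t`, `C`, `D`, `x_min`,
#'   `x_mdl`, `x_max`, `x_current`.
#' @export
caption_dataset <- function() {
  path <- system.file("extdata", "caption_equilibria.csv",
                      package = "ecoevolve", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Sources of the six complete fit records
#'
#' The six records of [caption_dataset()] with full triples from the
#' collapse/regrowth transition sequence, used as the default calibration
#' fit set; the partial, near-fold and stasis-phase records are reserved for
#' held-out validation.
#'
#' @return Character vector of record sources.
#' @export
complete_fit_sources <- function() {
  c("Fig3B", "Fig3C", "Fig3E", "Fig3F", "Fig3H", "Fig3I")
}

#' Assemble full model parameters from calibration free parameters
#'
#' The calibration conventions are `k_aSx = 0` (the published equilibrium
#' diagrams come from sexual-reproduction runs) and `k_d = 1` (the
#' equilibrium structure is invariant under a common rescaling of `k_in`,
#' `k_aSx`, `k_Sx`, `k_d`, so the baseline mortality is a free
#' normalisation, not an assumption).
#'
#' @param theta named numeric vector with elements `k_in`, `k_Sx`, `K_D`,
#'   `K_E`.
#' @param p_C,p_D mutation-rate constants to attach (irrelevant for
#'   equilibria, which depend only on the frozen density equation).
#' @return An [eco_params()].
#' @export
theta_to_params <- function(theta, p_C = 0, p_D = 0) {
  eco_params(k_in = theta[["k_in"]], k_aSx = 0, k_Sx = theta[["k_Sx"]],
             k_d = 1, K_D = theta[["K_D"]], K_E = theta[["K_E"]],
             p_C = p_C, p_D = p_D)
}

#' Predict labelled equilibria at frozen (C, D)
#'
#' Forward map of the calibration inverse problem: assembles full model
#' parameters from the free parameters via [theta_to_params()] and runs the
#' equilibrium finder.
#'
#' @param theta named numeric vector (`k_in`, `k_Sx`, `K_D`, `K_E`).
#' @param C,D frozen parameter values.
#' @param search an [equilibrium_search()].
#' @return A one-row data frame with columns `x_min`, `x_mdl`, `x_max`
#'   (absent labels `NA`) and `n_roots`.
#' @export
predict_roots <- function(theta, C, D, search = equilibrium_search()) {
  eq <- find_equilibria(C, D, theta_to_params(theta), search)
  pick <- function(lab) {
    v <- eq$roots$x[!is.na(eq$roots$label) & eq$roots$label == lab]
    if (length(v)) v[1] else NA_real_
  }
  data.frame(x_min = pick("x_min"), x_mdl = pick("x_mdl"),
             x_max = pick("x_max"), n_roots = eq$n_roots)
}

#' Options for the calibration fit
#'
#' @param starts data frame of multistart values for `k_Sx`, `K_D`, `K_E`;
#'   the default is the full 27-point log-spaced grid
#'   `k_Sx in (0.3, 1, 3) x K_D in (0.01, 0.3, 10) x K_E in (0.05, 0.5, 5)`.
#' @param k_in_start common starting value for the influx rate (started
#'   near zero: whether the published runs used a strictly positive influx
#'   is unknown).
#' @param lower,upper named positive bounds of the search box (log-scale
#'   optimisation inside).
#' @param miss_penalty loss added for every printed root label the model
#'   fails to produce, and for every spurious extra root.
#' @param search an [equilibrium_search()] used inside the loss; a coarser
#'   bracketing grid than the finder default is sufficient here because
#'   every root is polished by bisection anyway.
#' @return A list of class `eco_calib_options`.
#' @export
calib_options <- function(starts = NULL, k_in_start = 1e-4,
                          lower = c(k_in = 1e-10, k_Sx = 1e-3,
                                    K_D = 1e-6, K_E = 1e-3),
                          upper = c(k_in = 50, k_Sx = 100,
                                    K_D = 1e6, K_E = 1e4),
                          miss_penalty = 10,
                          search = equilibrium_search(n_grid = 2000L)) {
  if (is.null(starts))
    starts <- expand.grid(k_Sx = c(0.3, 1, 3), K_D = c(0.01, 0.3, 10),
                          K_E = c(0.05, 0.5, 5))
  structure(list(starts = starts, k_in_start = k_in_start,
                 lower = lower, upper = upper,
                 miss_penalty = miss_penalty, search = search),
            class = "eco_calib_options")
}

# loss of one record: squared log differences between predicted and printed
# roots matched by label; a missing predicted label (or an extra root) costs
# miss_penalty
record_loss <- function(theta, rec, opts) {
  eq <- tryCatch(find_equilibria(rec$C, rec$D, theta_to_params(theta),
                                 opts$search),
                 eco_anomaly_error = function(e)
                   list(n_roots = length(e$roots), roots = NULL),
                 error = function(e) NULL)
  printed <- c(x_min = rec$x_min, x_mdl = rec$x_mdl, x_max = rec$x_max)
  printed <- printed[!is.na(printed)]
  if (is.null(eq)) return(opts$miss_penalty * (length(printed) + 1))
  if (is.null(eq$roots))   # anomaly: more than three roots
    return(opts$miss_penalty * (eq$n_roots - 3) +
             opts$miss_penalty * length(printed))
  pred <- structure(eq$roots$x, names = eq$roots$label)
  loss <- 0
  for (lab in names(printed)) {
    if (lab %in% names(pred)) {
      loss <- loss + (log(pred[[lab]]) - log(printed[[lab]]))^2
    } else if (eq$n_roots > 0) {
      # no predicted root carries this label: penalty plus pull toward the
      # nearest root so the objective stays informative
      loss <- loss + opts$miss_penalty +
        min((log(eq$roots$x) - log(printed[[lab]]))^2)
    } else {
      loss <- loss + opts$miss_penalty
    }
  }
  loss
}

calibration_loss <- function(log_theta, records, opts) {
  theta <- exp(log_theta)
  names(theta) <- c("k_in", "k_Sx", "K_D", "K_E")
  tot <- 0
  for (i in seq_len(nrow(records)))
    tot <- tot + record_loss(theta, records[i, ], opts)
  tot
}

#' Fit the base rate constants to printed equilibrium triples
#'
#' Solves the inverse problem: recover the free parameters `k_in`, `k_Sx`,
#' `K_D`, `K_E` (conventions `k_aSx = 0`, `k_d = 1`) from records of frozen
#' `(C, D)` with printed stationary densities, by minimising the summed
#' squared differences of log predicted and log printed roots, matched by
#' label. The log scale is used because the roots span two orders of
#' magnitude. Optimisation is bounded quasi-Newton in log-parameter space
#' from a deterministic multistart grid; the best converged start wins, and
#' the full multistart log is returned.
#'
#' @param records data frame with columns `C`, `D`, `x_min`, `x_mdl`,
#'   `x_max` (absent roots `NA`), e.g. from [caption_dataset()]; at least
#'   four records with at least two printed roots each are required.
#' @param opts an [calib_options()].
#' @return An object of class `eco_calibration`: list with `theta_hat`
#'   (named vector), `loss`, `per_record` (predicted vs printed roots and
#'   relative errors), `multistart_log` (one row per start), `records` and
#'   `opts`.
#' @examples
#' \donttest{
#' recs <- caption_dataset()
#' fit <- fit_parameters(recs[recs$source %in% complete_fit_sources(), ])
#' fit$theta_hat
#' }
#' @export
fit_parameters <- function(records, opts = calib_options()) {
  n_roots_per <- rowSums(!is.na(records[, c("x_min", "x_mdl", "x_max")]))
  if (sum(n_roots_per >= 2) < 4)
    stop("fit_parameters: need at least 4 records with at least 2 printed roots",
         call. = FALSE)

  lower <- log(opts$lower[c("k_in", "k_Sx", "K_D", "K_E")])
  upper <- log(opts$upper[c("k_in", "k_Sx", "K_D", "K_E")])
  log_rows <- list()
  best <- NULL
  for (i in seq_len(nrow(opts$starts))) {
    st <- log(c(opts$k_in_start, opts$starts$k_Sx[i], opts$starts$K_D[i],
                opts$starts$K_E[i]))
    fit <- tryCatch(
      stats::nlminb(st, calibration_loss, records = records, opts = opts,
                    lower = lower, upper = upper,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    ok <- !is.null(fit) && is.finite(fit$objective)
    log_rows[[i]] <- data.frame(
      start_k_Sx = opts$starts$k_Sx[i], start_K_D = opts$starts$K_D[i],
      start_K_E = opts$starts$K_E[i],
      loss = if (ok) fit$objective else NA_real_,
      converged = ok && fit$convergence == 0)
    if (ok && (is.null(best) || fit$objective < best$objective)) best <- fit
  }
  if (is.null(best))
    stop("fit_parameters: all multistart optimisations failed", call. = FALSE)

  theta_hat <- exp(best$par)
  names(theta_hat) <- c("k_in", "k_Sx", "K_D", "K_E")
  per_record <- prediction_table(theta_hat, records)
  structure(list(theta_hat = theta_hat, loss = best$objective,
                 per_record = per_record,
                 multistart_log = do.call(rbind, log_rows),
                 records = records, opts = opts),
            class = "eco_calibration")
}

#' @export
print.eco_calibration <- function(x, ...) {
  cat("<eco_calibration>\n  theta_hat:",
      paste(sprintf("%s = %.6g", names(x$theta_hat), x$theta_hat),
            collapse = ", "),
      sprintf("\n  loss = %.6g over %d records\n", x$loss, nrow(x$records)))
  invisible(x)
}

# predicted vs printed roots for a set of records
prediction_table <- function(theta, records) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    pred <- tryCatch(predict_roots(theta, rec$C, rec$D),
                     error = function(e)
                       data.frame(x_min = NA_real_, x_mdl = NA_real_,
                                  x_max = NA_real_, n_roots = NA_integer_))
    out <- data.frame(source = if ("source" %in% names(rec)) rec$source else NA,
                      C = rec$C, D = rec$D)
    for (lab in c("x_min", "x_mdl", "x_max")) {
      out[[paste0(lab, "_printed")]] <- rec[[lab]]
      out[[paste0(lab, "_pred")]] <- pred[[lab]]
      out[[paste0(lab, "_relerr")]] <-
        (pred[[lab]] - rec[[lab]]) / rec[[lab]]
    }
    out$n_roots_pred <- pred$n_roots
    out
  })
  do.call(rbind, rows)
}

#' Validate a calibration on held-out records
#'
#' @param result an [fit_parameters()] result.
#' @param records held-out records in [caption_dataset()] layout.
#' @return A data frame (one row per record) with predicted roots, relative
#'   errors per printed label, and a `count_agrees` flag comparing the
#'   predicted root count with the number of printed labels.
#' @export
holdout_validate <- function(result, records) {
  stopifnot(inherits(result, "eco_calibration"))
  tab <- prediction_table(result$theta_hat, records)
  printed_n <- rowSums(!is.na(records[, c("x_min", "x_mdl", "x_max")]))
  tab$count_agrees <- !is.na(tab$n_roots_pred) & tab$n_roots_pred == printed_n
  tab
}

#' Generate synthetic equilibrium records
#'
#' Forward-simulates labelled equilibria at supplied `(C, D)` values from
#' known parameters, optionally applying multiplicative log-normal noise and
#' dropping labels, for calibration recovery experiments.
#'
#' @param theta named free-parameter vector (`k_in`, `k_Sx`, `K_D`, `K_E`).
#' @param CD data frame with columns `C` and `D`.
#' @param noise standard deviation of the log-normal multiplicative noise
#'   (0 gives exact forward roots).
#' @param seed integer seed fixing the noise stream.
#' @param drop optional list (one element per record) of label names to
#'   remove, emulating partially printed records.
#' @return A data frame in [caption_dataset()] layout (without `t` and
#'   `x_current`).
#' @export
synthesize_equilibrium_data <- function(theta, CD, noise = 0, seed = 1,
                                        drop = NULL) {
  stopifnot(is.data.frame(CD), all(c("C", "D") %in% names(CD)))
  set.seed(seed)
  rows <- lapply(seq_len(nrow(CD)), function(i) {
    pred <- predict_roots(theta, CD$C[i], CD$D[i])
    out <- data.frame(source = sprintf("synthetic%02d", i),
                      C = CD$C[i], D = CD$D[i],
                      x_min = pred$x_min, x_mdl = pred$x_mdl,
                      x_max = pred$x_max)
    for (lab in c("x_min", "x_mdl", "x_max")) {
      if (!is.na(out[[lab]]) && noise > 0)
        out[[lab]] <- out[[lab]] * exp(stats::rnorm(1, 0, noise))
      if (!is.null(drop) && lab %in% drop[[i]]) out[[lab]] <- NA_real_
    }
    out
  })
  do.call(rbind, rows)
}

#' Shipped parameter profiles
#'
#' `"reduced"` switches off parameter evolution (`p_C = p_D = 0`), leaving
#' the single density equation at frozen `(C, D)` — the closed-form testbed.
#' `"paper-like"` is the calibrated profile: the free parameters obtained by
#' [fit_parameters()] on the six complete records of [caption_dataset()]
#' (conventions `k_aSx = 0`, `k_d = 1`), with the published mutation-rate
#' pair `p_C = 0.0015`, `p_D = 0.02111` and an initial state taken from the
#' earliest printed record (low density inside the low-density phase).
#' `"fixtures"` is a small, fast, well-behaved parameter set for synthetic
#' tests.
#'
#' @param name profile name.
#' @param refit recompute the calibrated free parameters from
#'   [caption_dataset()] instead of using the stored values (slower,
#'   identical by determinism of the fit).
#' @return A list with components `params` ([eco_params()]), `init`
#'   ([eco_state()]) and `t_span` (suggested simulation span).
#' @export
eco_profile <- function(name = c("paper-like", "reduced", "fixtures"),
                        refit = FALSE) {
  name <- match.arg(name)
  switch(name,
    "paper-like" = {
      theta <- c(k_in = 1.2943800, k_Sx = 1.2294600,
                 K_D = 0.2569890, K_E = 0.0070317)
      if (refit) {
        recs <- caption_dataset()
        theta <- fit_parameters(
          recs[recs$source %in% complete_fit_sources(), ])$theta_hat
      }
      list(params = theta_to_params(theta, p_C = 0.0015, p_D = 0.02111),
           init = eco_state(x = 0.3096, C = 30.0820, D = 3.5),
           t_span = c(0, 12000))
    },
    "reduced" = list(
      params = eco_params(k_in = 0, k_aSx = 2, k_Sx = 0, k_d = 1,
                          K_D = 1e12, K_E = 1, p_C = 0, p_D = 0),
      init = eco_state(x = 0.5, C = 10, D = 0),
      t_span = c(0, 50)),
    "fixtures" = list(
      params = eco_params(k_in = 0.05, k_aSx = 0, k_Sx = 1.2, k_d = 1,
                          K_D = 0.3, K_E = 0.01, p_C = 0.0015, p_D = 0.021),
      init = eco_state(x = 0.3, C = 30, D = 3.5),
      t_span = c(0, 2000))
  )
}
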