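test_that("stationarity residual behaves at the boundaries and at roots", {
  p <- eco_params(k_in = 0, k_aSx = 0.3, k_Sx = 1, k_d = 1,
                  K_D = 0.5, K_E = 1)
  # without influx the residual vanishes with the density factor
  expect_equal(stationarity_residual(1e-12, 20, 2, p), 0, tolerance = 1e-10)

  p2 <- eco_params(k_in = 1.294, k_aSx = 0, k_Sx = 1.229, k_d = 1,
                   K_D = 0.257, K_E = 0.00703)
  eq <- find_equilibria(30.082, 3.5, p2)
  g_at_roots <- stationarity_residual(eq$roots$x, 30.082, 3.5, p2)
  expect_lt(max(abs(g_at_roots)), 1e-6)

  # the sign flips across each simple root (dense scan oracle)
  for (i in seq_len(eq$n_roots)) {
    r <- eq$roots$x[i]
    eps <- 1e-4 * r
    expect_lt(stationarity_residual(r - eps, 30.082, 3.5, p2) *
                stationarity_residual(r + eps, 30.082, 3.5, p2), 0)
  }
})

test_that("finder recovers closed-form roots when crowding is disabled", {
  # K_D huge makes H ~ 0, so with k_in = 0, k_aSx = 0 the nonzero roots
  # solve k_Sx x (1 - x/C) = k_d: a quadratic
  ks <- 2; kd <- 1; C <- 12
  p <- eco_params(k_in = 0, k_aSx = 0, k_Sx = ks, k_d = kd,
                  K_D = 1e15, K_E = 1)
  disc <- sqrt(C^2 - 4 * C * kd / ks)
  expected <- sort(c((C - disc) / 2, (C + disc) / 2))
  eq <- find_equilibria(C, 0.01, p)
  expect_identical(eq$n_roots, 2L)
  expect_equal(eq$roots$x, expected, tolerance = 1e-9)
  # lower crossing unstable, upper stable
  expect_identical(eq$roots$stable, c(FALSE, TRUE))
  expect_identical(eq$roots$label, c("x_mdl", "x_max"))
})

test_that("finder agrees with a brute-force scan on random instances", {
  set.seed(505)
  n_checked <- 0
  for (k in 1:100) {
    p <- eco_params(k_in = stats::runif(1, 0.01, 2), k_aSx = 0,
                    k_Sx = stats::runif(1, 0.5, 3), k_d = 1,
                    K_D = exp(stats::runif(1, log(0.05), log(5))),
                    K_E = exp(stats::runif(1, log(0.01), log(5))))
    C <- stats::runif(1, 10, 50)
    D <- stats::runif(1, 0, 10)
    oracle <- brute_force_roots(C, D, p, n_grid = 1e4)
    eq <- tryCatch(find_equilibria(C, D, p),
                   eco_anomaly_error = function(e) e)
    if (inherits(eq, "eco_anomaly_error")) {
      expect_gt(length(oracle), 3)
      next
    }
    expect_identical(eq$n_roots, length(oracle))
    if (eq$n_roots > 0)
      expect_equal(eq$roots$x, oracle, tolerance = 1e-6)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 90)
})

test_that("three-root sets follow the stable/unstable/stable pattern", {
  p <- eco_params(k_in = 1.294, k_aSx = 0, k_Sx = 1.229, k_d = 1,
                  K_D = 0.257, K_E = 0.00703)
  eq <- find_equilibria(30.082, 3.5, p)
  expect_identical(eq$n_roots, 3L)
  expect_identical(eq$roots$stable, c(TRUE, FALSE, TRUE))
  expect_identical(eq$roots$label, c("x_min", "x_mdl", "x_max"))
  expect_true(all(diff(eq$roots$x) > 0))
})

test_that("manifested state is piecewise constant with its jump at the middle root", {
  p <- eco_params(k_in = 1.294, k_aSx = 0, k_Sx = 1.229, k_d = 1,
                  K_D = 0.257, K_E = 0.00703)
  eq <- find_equilibria(30.082, 3.5, p)
  mdl <- eq$roots$x[2]
  below <- manifested_state(mdl * 0.99, eq)
  above <- manifested_state(mdl * 1.01, eq)
  expect_identical(below$label, "x_min")
  expect_identical(above$label, "x_max")
  expect_equal(below$boundary, mdl)

  # label is constant across each basin
  labs <- vapply(seq(0.01, 29, length.out = 40), function(x)
    manifested_state(x, eq)$label, character(1))
  expect_identical(labs, ifelse(seq(0.01, 29, length.out = 40) < mdl,
                                "x_min", "x_max"))

  # a single-root set is returned regardless of the density
  eq1 <- find_equilibria(30.1132, 1.4357, p)
  expect_identical(eq1$n_roots, 1L)
  expect_identical(manifested_state(0.01, eq1)$x_value,
                   manifested_state(29, eq1)$x_value)
})

test_that("bistability map reports root counts and fold crossings", {
  p <- eco_params(k_in = 1.294, k_aSx = 0, k_Sx = 1.229, k_d = 1,
                  K_D = 0.257, K_E = 0.00703)
  m <- bistability_map(p, C_range = c(30.082, 30.1132),
                       D_range = c(1.4357, 3.5), n_C = 2, n_D = 8)
  cell_bi <- m[abs(m$C - 30.082) < 1e-9 & abs(m$D - 3.5) < 1e-9, ]
  cell_mono <- m[abs(m$C - 30.1132) < 1e-9 & abs(m$D - 1.4357) < 1e-9, ]
  expect_identical(cell_bi$root_count, 3L)
  expect_identical(cell_mono$root_count, 1L)
  expect_true(all(m$root_count %in% c(1L, 3L)))

  # along a D-line the count changes by exactly two across the fold
  counts <- m$root_count[abs(m$C - 30.082) < 1e-9]
  jumps <- diff(counts[order(m$D[abs(m$C - 30.082) < 1e-9])])
  expect_true(all(jumps %in% c(-2L, 0L, 2L)))
  expect_s3_class(attr(m, "summary"), "data.frame")
})

test_that("saddle-node scan finds a single constructed fold crossing", {
  p <- eco_params(k_in = 1.294, k_aSx = 0, k_Sx = 1.229, k_d = 1,
                  K_D = 0.257, K_E = 0.00703)
  # frozen parameters: no events
  frozen <- make_traj(0:50, x = rep(1, 51), C = rep(30.082, 51),
                      D = rep(3.5, 51))
  frozen$params <- p
  class(frozen) <- "eco_trajectory"
  expect_identical(nrow(saddle_node_scan(frozen, p)), 0L)

  # D ramped down through the lower fold at fixed C: exactly one merge of
  # the lower pair (the upper state survives)
  tt <- seq(0, 100, by = 1)
  ramp <- make_traj(tt, x = rep(1, length(tt)), C = rep(30.082, length(tt)),
                    D = seq(3.5, 1.0, length.out = length(tt)))
  ramp$params <- p
  class(ramp) <- "eco_trajectory"
  ev <- saddle_node_scan(ramp, p)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "lower-pair-merge")
  expect_identical(ev$count_before, 3L)
  expect_identical(ev$count_after, 1L)
  expect_lt(ev$t_hi - ev$t_lo, 1e-2)
  # the merged pair vanishes near the lower roots, far below the survivor
  expect_lt(ev$merged_x, 10)
})

test_that("diagram table is consistent with the rate laws and the finder", {
  p <- eco_params(k_in = 1.294, k_aSx = 0, k_Sx = 1.229, k_d = 1,
                  K_D = 0.257, K_E = 0.00703)
  C <- 30.082; D <- 3.5
  tab <- wy_table(C, D, p, x_grid = seq(0.01, 1.2 * C, length.out = 600))
  expect_named(tab, c("x", "W", "Y", "DH"))
  # W vanishes at the carrying capacity
  expect_lt(abs(tab$W[which.min(abs(tab$x - C))]), 0.05)
  # the baseline mortality is the constant gap between Y and D H
  expect_equal(tab$Y - tab$DH, rep(p$k_d, nrow(tab)), tolerance = 1e-12)
  # sign changes of the residual along the grid match the finder's count
  g <- p$k_in + tab$x * (tab$W - tab$Y)
  n_flips <- sum(diff(sign(g)) != 0)
  expect_identical(n_flips, find_equilibria(C, D, p)$n_roots)
})
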