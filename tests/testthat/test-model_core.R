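test_that("rate laws obey their closed forms and limits", {
  p <- eco_params(k_in = 0.1, k_aSx = 0.5, k_Sx = 1.2, k_d = 0.8,
                  K_D = 0.4, K_E = 2)

  # no aggression at zero density
  r0 <- compute_rates(eco_state(x = 0, C = 10, D = 3), p)
  expect_identical(r0$H, 0)
  expect_equal(r0$Y, p$k_d)

  # unit auto-aggression at x = K_E
  rK <- compute_rates(eco_state(x = p$K_E, C = 10, D = 3), p)
  expect_equal(rK$r, 1)
  expect_equal(rK$H, p$k_d * p$K_E / (p$K_D + p$K_E))

  # reproduction vanishes at carrying capacity
  rC <- compute_rates(eco_state(x = 10, C = 10, D = 3), p)
  expect_equal(rC$W, 0)

  # crowding saturates at k_d, and stays finite far beyond overflow range
  rBig <- compute_rates(eco_state(x = 1e5 * p$K_E, C = 1e6, D = 3), p)
  expect_equal(rBig$H, p$k_d, tolerance = 1e-10)
  expect_true(is.finite(rBig$H) && is.finite(rBig$H_x) && rBig$H_x >= 0)

  # degenerate and invalid states are rejected
  expect_error(eco_state(x = 1, C = 1e-12, D = 0), "degenerate")
  expect_error(eco_state(x = NaN, C = 10, D = 0), "non-finite")
})

test_that("printed partial derivatives match central finite differences", {
  set.seed(101)
  h1 <- sqrt(.Machine$double.eps)
  # relative agreement at 1e-5 wherever the quantity is resolvable; an
  # absolute floor of 1e-7 absorbs the roundoff noise of the central
  # difference itself (eps * f / h), which dominates where H saturates and
  # H_x underflows toward zero
  agree <- function(a, b) abs(a - b) <= 1e-5 * pmax(abs(a), abs(b)) + 1e-7
  all_ok <- TRUE
  for (k in 1:200) {
    p <- random_params()
    s <- random_state()
    x <- s$x; C <- s$C
    at <- function(x_, C_)
      compute_rates(eco_state(x = x_, C = C_, D = s$D), p)
    W_of <- function(x_, C_)
      (p$k_aSx + p$k_Sx * x_) * (1 - x_ / C_)
    r <- at(x, C)

    hx <- h1 * max(abs(x), 1)
    hC <- h1 * max(abs(C), 1)
    fd <- c(
      # first-order partials against central differences of W and H
      W_x  = (W_of(x + hx, C) - W_of(x - hx, C)) / (2 * hx),
      W_C  = (W_of(x, C + hC) - W_of(x, C - hC)) / (2 * hC),
      H_x  = (at(x + hx, C)$H - at(x - hx, C)$H) / (2 * hx),
      # second-order partials against differences of the verified
      # first-order formulas (a plain second difference of W drowns in
      # roundoff when x is small, because W_CC is proportional to x)
      W_CC = (at(x, C + hC)$W_C - at(x, C - hC)$W_C) / (2 * hC),
      W_xC = (at(x, C + hC)$W_x - at(x, C - hC)$W_x) / (2 * hC))
    an <- c(r$W_x, r$W_C, r$H_x, r$W_CC, r$W_xC)
    all_ok <- all_ok && all(agree(an, fd))
  }
  expect_true(all_ok)
})

test_that("series base cases hold and the recursion reproduces index 3", {
  set.seed(202)
  for (k in 1:100) {
    p <- random_params()
    s <- random_state()
    cf <- series_coefficients(s, p, max_order = 6)
    expect_identical(cf$w[3], 0)  # w_2 = 0 exactly

    # recursion at i = 3: the (i-3) term vanishes, leaving -A * (u_1, w_1)
    A <- p$p_C * s$x * (p$k_aSx + p$k_Sx * s$x)^2
    expect_equal(cf$u[4], -A * cf$u[2], tolerance = 1e-15)
    expect_equal(cf$w[4], -A * cf$w[2], tolerance = 1e-15)
  }

  # purely asexual reproduction: w_0 = 0
  pa <- eco_params(k_aSx = 1, k_Sx = 0, k_d = 1, K_D = 1, K_E = 1)
  cfa <- series_coefficients(eco_state(x = 3, C = 10, D = 1), pa, 4)
  expect_identical(cfa$w[1], 0)

  expect_error(series_coefficients(eco_state(x = 1, C = 10, D = 0),
                                   pa, max_order = 2), "max_order")
})

test_that("coefficients match an independent expansion at a fixed state", {
  p <- eco_params(k_in = 0.01, k_aSx = 0, k_Sx = 1, k_d = 1,
                  K_D = 1, K_E = 1, p_C = 0.0015)
  s <- eco_state(x = 2, C = 30, D = 0)
  cf <- series_coefficients(s, p, max_order = 5)
  orc <- oracle_coeffs(x = 2, k_in = 0.01, k_aSx = 0, k_Sx = 1,
                       p_C = 0.0015, n = 5)
  expect_equal(cf$u, orc$u, tolerance = 1e-13)
  expect_equal(cf$w, orc$w, tolerance = 1e-13)
})

test_that("truncated sums handle zero, geometric and growing-term fixtures", {
  # all-zero coefficients: empty sums, trivially converged
  z <- truncate_sums(rep(0, 41), rep(0, 41), Y = 2, C = 5)
  expect_identical(z$S_C, 0)
  expect_identical(z$S_D, 0)
  expect_true(z$converged)

  # geometric decay: u_i = w_i = a (C/2)^i gives terms ratio 1/2 and
  # closed-form sums S_D = a sum (1/2)^i = 2 a, S_C = a (1+Y) sum i/2^i = 2 a (1+Y)
  C <- 8; a <- 3; Y <- 1.7
  i <- 0:60
  g <- a * (C / 2)^i
  sg <- truncate_sums(g, g, Y = Y, C = C)
  expect_true(sg$converged)
  expect_equal(sg$S_D, 2 * a, tolerance = 1e-10)
  expect_equal(sg$S_C, 2 * a * (1 + Y), tolerance = 1e-10)

  # shrink-then-grow magnitudes: optimal truncation at the smallest term
  v <- ifelse(i <= 8, 2^(-i), 2^(i - 16))
  w <- v * C^i
  sf <- truncate_sums(u = rep(0, length(w)), w = w, Y = 0, C = C)
  expect_false(sf$converged)
  expect_identical(sf$smallest_term_index, 8L)
  expect_equal(sf$N, 8L)
  expect_equal(sf$S_D, sum(v[i <= 8]))  # direct scan of the constructed terms
})

test_that("truncation is order-stable once the stopping rule fires", {
  p <- eco_params(k_in = 0.5, k_aSx = 0, k_Sx = 1.2, k_d = 1,
                  K_D = 0.3, K_E = 1, p_C = 0.0015)
  s <- eco_state(x = 0.4, C = 30, D = 3)
  r <- compute_rates(s, p)
  cf60 <- series_coefficients(s, p, 60)
  cf90 <- series_coefficients(s, p, 90)
  s60 <- truncate_sums(cf60$u, cf60$w, r$Y, s$C, trunc_policy(60))
  s90 <- truncate_sums(cf90$u, cf90$w, r$Y, s$C, trunc_policy(90))
  expect_true(s60$converged)
  expect_identical(s60$S_C, s90$S_C)
  expect_identical(s60$S_D, s90$S_D)
})

test_that("right-hand side reduces correctly and matches hand evaluation", {
  # frozen parameter evolution: only the density equation remains
  p0 <- eco_params(k_in = 0.3, k_aSx = 0.2, k_Sx = 1, k_d = 1,
                   K_D = 0.5, K_E = 1, p_C = 0, p_D = 0)
  d0 <- eco_rhs(eco_state(x = 2, C = 10, D = 1.5), p0)
  expect_identical(d0$C_t, 0)
  expect_identical(d0$D_t, 0)

  # extinction boundary: influx only
  p1 <- eco_params(k_in = 0.7, k_aSx = 0.2, k_Sx = 1, k_d = 1,
                   K_D = 0.5, K_E = 1, p_C = 0.002, p_D = 0.05)
  d1 <- eco_rhs(eco_state(x = 0, C = 10, D = 1.5), p1)
  expect_identical(d1$D_t, 0)
  expect_equal(d1$x_t, p1$k_in)

  # term-by-term hand evaluation truncated at order 6 (fast-decaying case)
  p2 <- eco_params(k_in = 0.01, k_aSx = 0, k_Sx = 1, k_d = 1,
                   K_D = 1, K_E = 1, p_C = 0.0015, p_D = 0.02)
  s2 <- eco_state(x = 2, C = 100, D = 1.2)
  r2 <- compute_rates(s2, p2)
  orc <- oracle_coeffs(2, 0.01, 0, 1, 0.0015, 6)
  ii <- 1:6
  S_C <- sum(ii * (orc$u[ii + 1] + r2$Y * orc$w[ii + 1]) / s2$C^ii)
  S_D <- sum(orc$w / s2$C^(0:6))
  hand <- c(p2$k_in + s2$x * (r2$W - r2$Y),
            -p2$p_C * r2$W * S_C,
            p2$p_D * r2$W * s2$D * r2$H * S_D)
  got <- eco_rhs(s2, p2, trunc_policy(max_order = 6))
  expect_equal(unlist(got[c("x_t", "C_t", "D_t")]), hand,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("density growth rate scales linearly with a common rate rescaling", {
  set.seed(303)
  for (k in 1:20) {
    p <- random_params()
    s <- random_state()
    lam <- stats::runif(1, 0.2, 5)
    p2 <- eco_params(k_in = lam * p$k_in, k_aSx = lam * p$k_aSx,
                     k_Sx = lam * p$k_Sx, k_d = lam * p$k_d,
                     K_D = p$K_D, K_E = p$K_E, p_C = p$p_C, p_D = p$p_D)
    expect_equal(eco_rhs(s, p2)$x_t, lam * eco_rhs(s, p)$x_t,
                 tolerance = 1e-12)
  }
})

test_that("crowding is strictly increasing in density and bounded by k_d", {
  p <- eco_params(k_Sx = 1, k_d = 1.4, K_D = 0.7, K_E = 3)
  xs <- seq(0.01, 50, length.out = 300)
  H <- vapply(xs, function(x)
    compute_rates(eco_state(x = x, C = 1000, D = 1), p)$H, numeric(1))
  expect_true(all(diff(H) > 0))
  expect_true(all(H < p$k_d))
})

test_that("compiled and reference right-hand sides agree", {
  set.seed(404)
  for (k in 1:50) {
    p <- random_params()
    s <- random_state()
    a <- eco_rhs(s, p, compiled = FALSE)
    b <- eco_rhs(s, p, compiled = TRUE)
    expect_equal(unlist(a[1:3]), unlist(b[1:3]), tolerance = 1e-13)
    expect_identical(a$n_used, b$n_used)
    expect_identical(a$converged, b$converged)
  }
})
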