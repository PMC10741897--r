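test_that("gamma_ratio follows the power-function integration rule", {
  expect_equal(gamma_ratio(0, 1), 1)
  expect_equal(gamma_ratio(1, 1), 0.5)
  # high-precision Gamma evaluation oracle
  expect_equal(gamma_ratio(1, 0.478), gamma(1.478) / gamma(1.956),
               tolerance = 1e-12)
  expect_equal(gamma_ratio(1, 0.478), 0.9017798, tolerance = 1e-6)
  expect_error(gamma_ratio(1, 0), "q")
  expect_error(gamma_ratio(1, 1.2), "q")
  expect_error(gamma_ratio(-1, 0.5), "non-negative")
})

test_that("series products match a brute-force convolution", {
  q <- 0.478
  one <- tau_from_plain_coefs(c(1, 0, 0, 0, 0, 0), q)
  v <- tau_from_plain_coefs(c(0.3, -1.2, 0.5, 2, -0.7, 0.1), q)
  expect_equal(series_product(one, v)$coeffs, v$coeffs, tolerance = 1e-14)
  # (1 + s)^2 = 1 + 2s + s^2
  u <- tau_from_plain_coefs(c(1, 1, 0), q)
  expect_equal(plain_coefs(series_product(u, u, M = 2)), c(1, 2, 1),
               tolerance = 1e-14)
  set.seed(11)
  for (rep in 1:5) {
    a <- stats::runif(6, -1, 1)
    b <- stats::runif(6, -1, 1)
    got <- plain_coefs(series_product(tau_from_plain_coefs(a, q),
                                      tau_from_plain_coefs(b, q), M = 5))
    expect_equal(got, oracle_convolve(a, b, 5), tolerance = 1e-13)
  }
  expect_error(series_product(tau_from_plain_coefs(1:2, 0.5),
                              tau_from_plain_coefs(1:2, 0.6)),
               "shared q")
})

test_that("tanh composition reproduces the Adomian polynomials", {
  q <- 0.7
  # constant series
  cst <- series_tanh(tau_from_plain_coefs(c(0.8, 0, 0), q))
  expect_equal(plain_coefs(cst), c(tanh(0.8), 0, 0), tolerance = 1e-14)
  # Maclaurin series of tanh
  id <- tau_from_plain_coefs(c(0, 1, 0, 0), q)
  expect_equal(plain_coefs(series_tanh(id, M = 3)), c(0, 1, 0, -1 / 3),
               tolerance = 1e-13)
  # order-0/1 closed forms and the quadrature oracle on random series
  set.seed(22)
  for (rep in 1:20) {
    a <- stats::runif(5, -1, 1)
    got <- plain_coefs(series_tanh(tau_from_plain_coefs(a, q), M = 4))
    expect_equal(got[1], tanh(a[1]), tolerance = 1e-14)
    expect_equal(got[2], a[2] * (1 - tanh(a[1])^2), tolerance = 1e-13)
    want <- oracle_compose_coefs(tanh, a, 4)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("the Adomian recursion starts from the vector field and vanishes at equilibria", {
  sys <- hnn_system(order = 0.478)
  # order-1 coefficients equal the field, machine-exactly
  set.seed(33)
  for (rep in 1:10) {
    s <- rand_state()
    co <- adm_coefficients(sys, s, M = 3)
    c1 <- vapply(co, function(ts) ts$coeffs[2], numeric(1))
    expect_equal(c1, hnn_vector_field(s, sys$params), tolerance = 1e-14)
  }
  # the origin is an equilibrium: all higher coefficients are zero
  co <- adm_coefficients(sys, rep(0, 5), M = 4)
  for (ts in co) expect_identical(ts$coeffs[-1], rep(0, 4))
  # closed-form first coefficient of the first component at (1,1,-1,0,0)
  co <- adm_coefficients(sys, c(1, 1, -1, 0, 0), M = 1)
  expect_equal(co[[1]]$coeffs[2], -1 + 2.5 * tanh(1) + 1.5 * tanh(1),
               tolerance = 1e-14)
  expect_error(adm_coefficients(sys, rep(0, 5), M = 0), "at least 1")
})

test_that("D^q x = x yields the truncated Mittag-Leffler coefficients exactly", {
  for (q in c(0.3, 0.5, 1)) {
    sys <- caputo_system(matrix(1), list(), order = q)
    co <- adm_coefficients(sys, 2.5, M = 8)[[1]]
    # Gamma-scaled coefficients are all equal to the initial value
    expect_equal(co$coeffs, rep(2.5, 9), tolerance = 1e-13)
  }
  # one series step agrees with the full Mittag-Leffler function
  sys <- caputo_system(matrix(1), list(), order = 0.5)
  x1 <- adm_step(sys, 1, h = 1e-3, M = 6)
  expect_equal(x1, oracle_mittag_leffler(1e-3^0.5, 0.5), tolerance = 1e-9)
})

test_that("equilibria are exact fixed points of the series step", {
  sys <- hnn_system(order = 0.478)
  for (M in c(1, 2, 3, 5))
    for (h in c(1e-6, 1e-3, 0.1))
      expect_identical(adm_step(sys, rep(0, 5), h = h, M = M), rep(0, 5))
})

test_that("the q = 1 limit is classical Taylor stepping", {
  A <- matrix(c(-0.5, 1, -1, -0.2), 2, 2)
  sys <- caputo_system(A, list(), order = 1)
  x0 <- c(1, -0.5)
  h <- 0.05
  for (M in c(1, 2, 3, 4)) {
    taylor <- x0
    Ak <- diag(2)
    for (i in 1:M) {
      Ak <- Ak %*% A
      taylor <- taylor + drop(Ak %*% x0) * h^i / factorial(i)
    }
    expect_equal(adm_step(sys, x0, h = h, M = M), taylor, tolerance = 1e-13)
  }
  # global error on D^1 x = -x scales as h^M
  sysd <- caputo_system(matrix(-1), list(), order = 1)
  err <- function(h, M) {
    n <- round(1 / h)
    traj <- adm_integrate(sysd, 1, h = h, n_steps = n, M = M)
    abs(traj$states[n + 1, 1] - exp(-1))
  }
  for (M in c(2, 3)) {
    ratio <- err(0.02, M) / err(0.01, M)
    expect_gt(ratio, 2^M * 0.8)
    expect_lt(ratio, 2^M * 1.25)
  }
})

test_that("successive truncation orders differ by the expected power of h", {
  sys <- hnn_system(order = 0.478)
  s <- c(1, 1, -1, 0, 0)
  gap <- function(h) max(abs(adm_step(sys, s, h, M = 3) -
                             adm_step(sys, s, h, M = 2)))
  # |step_M3 - step_M2| = |a_3| h^(3q): halving h scales it by 2^(-3q)
  ratio <- gap(1e-4) / gap(5e-5)
  expect_equal(log2(ratio), 3 * 0.478, tolerance = 0.02)
})

test_that("integration matches closed forms and records divergence", {
  # D^1 x = -x against exp(-t)
  sys <- caputo_system(matrix(-1), list(), order = 1)
  traj <- adm_integrate(sys, 1, h = 1e-3, n_steps = 5000, M = 3)
  expect_lt(max(abs(traj$states[, 1] - exp(-traj$t))), 1e-6)
  expect_true(is.na(traj$diverged_at))
  # D^1 x = x^2 blows up in finite time and trips the guard
  sysq <- caputo_system(matrix(0), list(list(row = 1, type = "prod",
                                             args = c(1, 1), coef = 1)),
                        order = 1)
  trajq <- adm_integrate(sysq, 10, h = 0.05, n_steps = 200, M = 3)
  expect_false(is.na(trajq$diverged_at))
  expect_true(all(is.na(trajq$states[(trajq$diverged_at + 2):201, 1])))
})

test_that("trajectory objects carry their metadata and methods work", {
  sys <- hnn_system(order = 0.478)
  traj <- adm_integrate(sys, c(1, 1, -1, 0, 0), h = 1e-3, n_steps = 50,
                        M = 3, n_discard = 10)
  expect_identical(dim(traj$states), c(51L, 5L))
  expect_identical(colnames(traj$states), c("x", "y", "z", "u", "w"))
  expect_identical(traj$n_discard, 10L)
  df <- as.data.frame(traj)
  expect_identical(names(df), c("t", "x", "y", "z", "u", "w"))
  expect_output(print(traj), "ADM trajectory")
  sim <- simulate(sys, nsim = 20)
  expect_identical(nrow(sim$states), 21L)
})
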