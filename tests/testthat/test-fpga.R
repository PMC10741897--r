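test_that("the two-term update reproduces the printed one-iteration values", {
  s <- two_term_step(c(1, 1, -1, 0, 0), hnn_params(), q = 0.478, h = 1e-6)
  expect_equal(s[1:4], c(1.0031310, 0.9988223, -0.9975377, 0.0061760),
               tolerance = 1e-5)
  # fifth component closed form: p * y0 * h^q / Gamma(q+1); the printed
  # 0.0045901 carries a decimal-shift typo (correct digits, wrong magnitude)
  expect_equal(s[5], 0.3 * 1e-6^0.478 / gamma(1.478), tolerance = 1e-12)
  expect_equal(s[5], 4.59014e-4, tolerance = 1e-6)
  expect_identical(two_term_step(rep(0, 5), hnn_params(), 0.478, 1e-6),
                   rep(0, 5))
})

test_that("the two-term step equals the one-term series step", {
  sys <- hnn_system(order = 0.478)
  set.seed(29)
  for (rep in 1:100) {
    s <- rand_state()
    expect_equal(two_term_step(s, sys$params, 0.478, 1e-4),
                 adm_step(sys, s, h = 1e-4, M = 1), tolerance = 1e-12)
  }
})

test_that("fixed-point formats validate and quantise with saturation", {
  expect_error(fixed_point_format(32, 0), "frac_bits")
  expect_error(fixed_point_format(32, 32), "frac_bits")
  fmt <- fixed_point_format(8, 4)
  expect_equal(fp_quantize(0.3, fmt), 0.3125, tolerance = 1e-12)
  expect_equal(fp_quantize(100, fmt), fmt$max) # saturates at ~7.94
  expect_equal(fp_quantize(-100, fmt), -fmt$max)
  tfmt <- fixed_point_format(8, 4, rounding = "truncate")
  expect_equal(fp_quantize(0.99, tfmt), 0.9375, tolerance = 1e-12)
})

test_that("one emulated step tracks the floating datapath", {
  p <- hnn_params()
  s0 <- c(1, 1, -1, 0, 0)
  float <- two_term_step(s0, p, 0.478, 1e-6)
  fixed <- as.numeric(fixed_point_step(s0, p, 0.478, 1e-6,
                                       fixed_point_format(32, 26)))
  expect_lt(max(abs(float - fixed)), 2^-20)
  # at 64/52 the quantisation noise itself is below 1e-9: compare against
  # a floating evaluation that shares the tanh lookup path
  fmt <- fixed_point_format(64, 52)
  th <- fohnn:::fp_tanh(s0[1:4], fmt)
  f <- c(drop(p$W %*% th) - s0[1:4], 0)
  f[2] <- f[2] + p$k * s0[2] * (p$a + p$b * s0[5])
  f[5] <- p$p * s0[2] - p$g * s0[5]
  ref <- s0 + f * 1e-6^0.478 / gamma(1.478)
  expect_lt(max(abs(ref - as.numeric(fixed_point_step(s0, p, 0.478, 1e-6,
                                                      fmt)))), 1e-9)
})

test_that("widening the word monotonically reduces the drift", {
  p <- hnn_params()
  drift <- vapply(c(12, 18, 24), function(fb) {
    fmt <- fixed_point_format(32, fb)
    sf <- c(1, 1, -1, 0, 0)
    sx <- sf
    dev <- 0
    for (k in 1:400) {
      sf <- two_term_step(sf, p, 0.478, 1e-3)
      sx <- as.numeric(fixed_point_step(sx, p, 0.478, 1e-3, fmt))
      dev <- max(dev, max(abs(sf - sx)))
    }
    dev
  }, numeric(1))
  expect_true(all(diff(drift) < 0))
})

test_that("the truncation audit bounds the discarded term and scales as h^2q", {
  aud <- truncation_audit(hnn_params(), q = 0.478, h = 1e-6, n_steps = 200)
  expect_true(all(aud$max_abs_second < 1e-4))
  expect_true(is.na(aud$diverged_at))
  aud10 <- truncation_audit(hnn_params(), q = 0.478, h = 1e-5, n_steps = 200)
  # over a short window the states barely move, so the ratio of the audited
  # maxima across a tenfold step change estimates the h^(2q) slope
  slope <- unname(log10(aud10$max_abs_second[1] / aud$max_abs_second[1]))
  expect_equal(slope, 2 * 0.478, tolerance = 0.1)
})

test_that("the audit reproduces the multiscroll regime inside its window", {
  for (bv in c(-1.2, 1.2)) {
    aud <- truncation_audit(hnn_params(b = bv, p = 2.6, g = 2.5),
                            q = 0.478, h = 1e-6, n_steps = 2e5)
    expect_true(is.na(aud$diverged_at))
    expect_true(all(aud$max_abs_second <= 1e-4))
  }
})

test_that("fixed-point drift grows at most linearly in step count", {
  p <- hnn_params()
  fmt <- fixed_point_format(24, 18)
  sf <- c(1, 1, -1, 0, 0)
  sx <- sf
  dev <- numeric(1000)
  for (k in 1:1000) {
    sf <- two_term_step(sf, p, 0.478, 1e-5)
    sx <- as.numeric(fixed_point_step(sx, p, 0.478, 1e-5, fmt))
    dev[k] <- max(abs(sf - sx))
  }
  # per-step increments bounded: max deviation within a constant factor of
  # a linear envelope fitted on the first tenth
  rate <- max(dev[1:100]) / 100
  expect_lt(max(dev), rate * 1000 * 5)
})
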