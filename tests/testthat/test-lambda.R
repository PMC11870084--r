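# Space-constant estimation: weight function, convolution, fitting, and
# the power-law relation between input resistance and space constant.

test_that("weight function has the stated value, decay and integral", {
  expect_equal(weight_g(0, 2), 1 / 2)
  expect_lt(weight_g(50, 1), 1e-12)
  # closed-form integral over the positive half-line = 3/2
  for (lam in c(0.5, 1, 1.12))
    expect_equal(integrate(function(u) weight_g(u, lam), 0, Inf)$value,
                 1.5, tolerance = 1e-8)
  # printed variant goes negative left of -lambda log(2); symmetric
  # variant stays positive
  expect_lt(weight_g(-2, 1, "printed"), 0)
  expect_gt(weight_g(-2, 1, "symmetric"), 0)
  expect_error(weight_g(0, -1), "lambda")
})

test_that("illumination indicator matches the printed branches", {
  expect_equal(light_f(0.5, b = 1), 1)
  expect_equal(light_f(1.5, b = 1), 0)     # x > b branch
  # half-line mode: any x <= b illuminated
  expect_equal(light_f(-100, b = 1), 1)
  # interval mode
  expect_equal(light_f(-3, b = 1, far_edge = -2), 0)
  expect_equal(light_f(-1, b = 1, far_edge = -2), 1)
})

test_that("closed-form convolution equals adaptive quadrature to 1e-6", {
  for (variant in c("printed", "symmetric"))
    for (lam in c(0.1, 0.56, 1.12, 3))
      for (b in c(-1.5, -0.3, 0.2, 1))
        for (fe in c(-Inf, -3)) {
          cf <- convolve_fg(0, b, fe, lam, variant)
          q <- integrate(function(tau) weight_g(-tau, lam, variant),
                         lower = if (is.finite(fe)) fe else -60 * lam,
                         upper = b, rel.tol = 1e-10,
                         subdivisions = 400L)$value
          expect_equal(cf, q, tolerance = 1e-6)
        }
})

test_that("larger space constants give a more gradual spatial decay", {
  b <- seq(-3, 0, by = 0.25)
  r1 <- convolve_fg(0, b, -Inf, 1)     # lambda = 1 mm
  r05 <- convolve_fg(0, b, -Inf, 0.5)  # lambda = 0.5 mm
  # normalized responses: the small-lambda curve decays faster
  n1 <- r1 / max(r1); n05 <- r05 / max(r05)
  expect_true(all(n05[b < -0.25] < n1[b < -0.25]))
  # response vanishes far from the light
  expect_lt(convolve_fg(0, -30, -Inf, 1), 1e-10)
  # monotone non-decreasing in illumination extent
  expect_true(all(diff(convolve_fg(0, seq(-4, 0, 0.1), -Inf, 1)) > 0))
  expect_true(all(diff(convolve_fg(0, seq(-4, 0, 0.1), -Inf, 0.56,
                                   "symmetric")) > 0))
})

test_that("lambda fit recovers generator truth and flags pure noise", {
  s1 <- gen_lambda_series(1.12, amplitude = 3, noise_sd = 0)
  f1 <- fit_lambda(s1)
  expect_equal(f1$lambda_mm, 1.12, tolerance = 1e-3)
  expect_true(f1$accepted)
  expect_equal(f1$amplitude_mV, 3, tolerance = 1e-6)
  s2 <- gen_lambda_series(0.56, amplitude = 3, noise_sd = 0,
                          direction = "transverse")
  f2 <- fit_lambda(s2)
  expect_equal(f2$lambda_mm, 0.56, tolerance = 1e-3)
  expect_equal(f2$direction, "transverse")
  # symmetric-variant round trip
  s3 <- gen_lambda_series(1.12, noise_sd = 0, variant = "symmetric")
  expect_equal(fit_lambda(s3, variant = "symmetric")$lambda_mm, 1.12,
               tolerance = 1e-3)
  # pure noise: fit not accepted
  noise <- optoclamp:::with_seed(13, abs(rnorm(8, 0, 1)) + 0.05)
  sn <- illumination_series(seq(-2, 0.3, length.out = 8), noise)
  fn <- fit_lambda(sn)
  expect_false(fn$accepted)
  expect_gt(fn$mse, 0.3)
})

test_that("median recovered lambda is within 5% of truth at 5%-of-max noise", {
  b <- seq(-2, 0.3, length.out = 8)
  mx <- max(3 * convolve_fg(0, b, -Inf, 1.12))
  est <- vapply(1:100, function(seed) {
    s <- gen_lambda_series(1.12, amplitude = 3, b = b,
                           noise_sd = 0.05 * mx, seed = seed)
    fit_lambda(s)$lambda_mm
  }, numeric(1))
  expect_equal(median(est), 1.12, tolerance = 0.05)
  # per-replicate scatter sits at the information limit for this design
  expect_lt(median(abs(est / 1.12 - 1)), 0.10)
})

test_that("power-law fit is exact on exact data and profiles sensible CIs", {
  x <- c(1, 1.3, 1.6, 2, 2.5)
  f_sqrt <- fit_power_relation(x, sqrt(x))
  expect_equal(f_sqrt$a, 1, tolerance = 1e-8)
  expect_equal(f_sqrt$b, 0.5, tolerance = 1e-8)
  expect_equal(f_sqrt$ci_b[1], f_sqrt$ci_b[2], tolerance = 1e-6)
  f_lin <- fit_power_relation(x, x)
  expect_equal(f_lin$b, 1, tolerance = 1e-8)
  # noisy sqrt-law data: CI covers 0.5
  p <- gen_rm_lambda_pairs(0.5, n = 20, noise = 0.1, seed = 3)
  fp <- fit_power_relation(p$x, p$y)
  expect_true(fp$ci_b[1] <= 0.5 && 0.5 <= fp$ci_b[2])
  expect_error(fit_power_relation(c(1, 2), c(1, 2)), "at least 5")
  expect_error(fit_power_relation(x, -sqrt(x)), "positive")
})

test_that("area-to-edge geometry presets", {
  expect_equal(area_to_edge(11.2, "square"), sqrt(11.2))
  expect_equal(area_to_edge(1, "square"), 1)
  expect_equal(area_to_edge(6.2, "circle"), 2 * sqrt(6.2 / pi))
})

test_that("illumination series round-trips through delimited text", {
  s <- gen_lambda_series(1.12, noise_sd = 0.1, seed = 2,
                         direction = "transverse")
  path <- tempfile(fileext = ".tsv")
  write_illumination_series(s, path)
  back <- read_illumination_series(path)
  expect_equal(back$delta_e, s$delta_e, tolerance = 1e-12)
  expect_equal(back$direction, "transverse")
  expect_identical(back$far_edge, -Inf)
  unlink(path)
})
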