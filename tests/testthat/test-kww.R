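test_that("kww_loss matches the high-precision oracle to 1e-6 relative", {
  for (b in unique(kww_oracle$beta)) {
    sub <- kww_oracle[kww_oracle$beta == b, ]
    got <- kww_loss(sub$x, beta = b, tau = 1)
    expect_equal(got, sub$phi, tolerance = 1e-6,
                 label = sprintf("Phi(x, beta = %g)", b))
    expect_lt(max(abs(got - sub$phi) / sub$phi), 1e-6)
  }
})

test_that("the beta = 1 limit equals the Debye closed form everywhere", {
  x <- 10^seq(-5, 5, length.out = 101)
  expect_equal(kww_loss(x, beta = 1, tau = 1), x / (1 + x^2),
               tolerance = 1e-6)
  # tau and amplitude scaling
  expect_equal(kww_loss(2, beta = 1, tau = 0.5, amplitude = 3),
               3 * 1 / (1 + 1), tolerance = 1e-12)
})

test_that("kww_loss validates its domain", {
  expect_error(kww_loss(1, beta = 0, tau = 1), class = "amorphkit_domain_error")
  expect_error(kww_loss(1, beta = 1.1, tau = 1), class = "amorphkit_domain_error")
  expect_error(kww_loss(-1, beta = 0.5, tau = 1), class = "amorphkit_domain_error")
  expect_error(kww_loss(1, beta = 0.5, tau = 0), class = "amorphkit_domain_error")
})

test_that("the sum rule integral over ln(omega) equals (pi/2) * amplitude", {
  for (b in c(0.3, 0.62, 1.0)) {
    val <- integrate_loss_dlnw(function(w) kww_loss(w, beta = b, tau = 1))
    expect_equal(val, pi / 2, tolerance = 1e-3,
                 label = sprintf("sum rule, beta = %g", b))
  }
})

test_that("the loss curve is positive, unimodal, and shifts with 1/tau", {
  x <- 10^seq(-4, 4, length.out = 400)
  for (b in c(0.3, 0.62, 0.9)) {
    y <- kww_loss(x, beta = b, tau = 1)
    expect_true(all(y > 0))
    i <- which.max(y)
    expect_true(all(diff(y[seq_len(i)]) > 0))
    expect_true(all(diff(y[i:length(y)]) < 0))
    # peak position scales as 1/tau at fixed beta
    y10 <- kww_loss(x, beta = b, tau = 10)
    expect_equal(x[which.max(y10)] * 10, x[i], tolerance = 0.05)
  }
})

test_that("decreasing beta broadens the peak (numeric FWHM oracle)", {
  x <- 10^seq(-6, 6, length.out = 4000)
  fwhm <- vapply(c(0.9, 0.7, 0.5, 0.3), function(b) {
    y <- kww_loss(x, beta = b, tau = 1)
    above <- which(y >= max(y) / 2)
    log10(x[max(above)] / x[min(above)])
  }, 0.0)
  expect_true(all(diff(fwhm) > 0))
})

test_that("a noiseless KWW peak is recovered with the generating exponent", {
  f <- 10^seq(-1, 6, by = 0.1)
  sp <- loss_spectrum(360, f, kww_loss(2 * pi * f, 0.62, 1e-2, 7.8))
  fit <- fit_kww(sp)
  expect_lt(abs(coef(fit)[["beta"]] - 0.62), 0.005)
  expect_equal(coef(fit)[["tau_kww"]], 1e-2, tolerance = 0.01)
  expect_equal(coef(fit)[["amplitude"]], 7.8, tolerance = 0.01)
})

test_that("a Debye peak is recovered with beta near 1", {
  f <- 10^seq(-1, 6, by = 0.1)
  sp <- loss_spectrum(360, f, kww_loss(2 * pi * f, 1, 1e-2, 3))
  fit <- fit_kww(sp)
  expect_lt(abs(coef(fit)[["beta"]] - 1), 1e-3)
})

test_that("fitting an HN-shaped peak agrees with a grid-search oracle", {
  f <- 10^seq(-1, 6, by = 0.1)
  sp <- loss_spectrum(360, f, eval_hn_loss(2 * pi * f, 1, 1e-2, 0.8, 0.6))
  fit <- fit_kww(sp)

  # exhaustive (beta, tau) grid with the amplitude profiled out analytically
  peak <- 10^(-log10(2 * pi * 1e-2))
  inwin <- abs(log10(f) - log10(fit$f_max)) <= 2
  w <- 2 * pi * f[inwin]
  ylog <- log10(sp$loss[inwin])
  grid <- expand.grid(beta = seq(0.35, 0.95, by = 0.015),
                      ltau = seq(-3.2, -0.8, by = 0.1))
  rss <- mapply(function(b, lt) {
    m <- log10(kww_loss(w, b, 10^lt))
    r <- ylog - m
    sum((r - mean(r))^2)   # optimal log-amplitude removed
  }, grid$beta, grid$ltau)
  beta_oracle <- grid$beta[which.min(rss)]
  expect_lt(abs(coef(fit)[["beta"]] - beta_oracle), 0.03)
  # interconversion sanity band: beta ~ (a*b)^(1/1.23) ~ 0.55
  expect_gt(coef(fit)[["beta"]], 0.50)
  expect_lt(coef(fit)[["beta"]], 0.60)
})

test_that("fit_kww refuses spectra without an in-window maximum", {
  f <- 10^seq(-1, 6, by = 0.25)
  flank <- loss_spectrum(340, f, 0.5 * (f / 0.1)^-0.5)
  expect_error(fit_kww(flank), class = "amorphkit_not_fittable")
})

test_that("shape invariance holds on a fixed-shape ladder and fails when broken", {
  ladder <- make_kww_ladder(beta = 0.62)
  inv <- shape_invariance_check(ladder, sigma_over_eps0 = 0)
  expect_lt(inv$spread, 0.01)
  expect_true(inv$pass)

  # two very different shapes must fail at the default threshold
  f <- 10^seq(-1, 6, by = 1 / 8)
  broken <- spectrum_set(list(
    loss_spectrum(360, f, kww_loss(2 * pi * f, 0.5, 1e-2, 5)),
    loss_spectrum(362, f, kww_loss(2 * pi * f, 0.9, 1e-3, 5))))
  inv2 <- shape_invariance_check(broken, sigma_over_eps0 = 0)
  expect_false(inv2$pass)
  expect_gt(inv2$spread, 0.05)

  # a single fittable spectrum is insufficient
  single <- spectrum_set(list(
    loss_spectrum(360, f, kww_loss(2 * pi * f, 0.5, 1e-2, 5))))
  expect_error(shape_invariance_check(single, sigma_over_eps0 = 0),
               class = "amorphkit_insufficient_data")
})

test_that("conductivity subtraction recovers the underlying peak shape", {
  f <- 10^seq(-1, 6, by = 0.1)
  sig <- 30
  sp <- loss_spectrum(360, f,
                      kww_loss(2 * pi * f, 0.62, 1e-2, 7.8) +
                        sig / (2 * pi * f))
  fit <- fit_kww(sp, sigma_over_eps0 = sig)
  expect_lt(abs(coef(fit)[["beta"]] - 0.62), 0.01)
  # masking-only mode works when the conductivity leaves the peak visible
  sp2 <- loss_spectrum(360, f,
                       kww_loss(2 * pi * f, 0.62, 1e-2, 7.8) +
                         2 / (2 * pi * f))
  fit2 <- fit_kww(sp2, mask_conductivity = TRUE)
  expect_lt(abs(coef(fit2)[["beta"]] - 0.62), 0.05)
  # a conductivity strong enough to bury the peak is reported as unfittable
  expect_error(fit_kww(sp, mask_conductivity = TRUE),
               class = "amorphkit_not_fittable")
})
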