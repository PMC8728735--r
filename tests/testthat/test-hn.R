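test_that("eval_hn_loss reproduces closed-form special cases", {
  # Debye peak value: delta_eps / 2 at omega * tau = 1
  expect_equal(eval_hn_loss(1, delta_eps = 1, tau_hn = 1, a = 1, b = 1), 0.5)
  # pure conductivity: sigma / (eps0 * omega)
  expect_equal(eval_hn_loss(10, delta_eps = 0, tau_hn = 1, a = 1, b = 1,
                            sigma_over_eps0 = 1), 0.1)
  # high-precision complex-arithmetic oracle for broadened exponents
  expect_equal(eval_hn_loss(1, delta_eps = 1, tau_hn = 1, a = 0.8, b = 0.6),
               hn_oracle_08_06, tolerance = 1e-14)
})

test_that("eval_hn_loss validates its domain", {
  expect_error(eval_hn_loss(c(1, -1), 1, 1, 1, 1),
               class = "amorphkit_domain_error")
  expect_error(eval_hn_loss(0, 1, 1, 1, 1), class = "amorphkit_domain_error")
  expect_error(eval_hn_loss(1, 1, 1, a = 1.2, b = 1),
               class = "amorphkit_domain_error")
  expect_error(eval_hn_loss(1, 1, tau_hn = -1, a = 1, b = 1),
               class = "amorphkit_domain_error")
})

test_that("hn_peak_frequency matches the numeric argmax of the loss curve", {
  # Debye closed form
  expect_equal(hn_peak_frequency(1, 1, 1), 1 / (2 * pi), tolerance = 1e-12)
  for (ab in list(c(0.8, 0.6), c(0.95, 0.4), c(0.5, 1), c(0.7, 0.85))) {
    fmax <- hn_peak_frequency(1, ab[1], ab[2])
    lf <- seq(log10(fmax) - 3, log10(fmax) + 3, length.out = 1e6)
    loss <- eval_hn_loss(2 * pi * 10^lf, 1, 1, ab[1], ab[2])
    f_argmax <- 10^lf[which.max(loss)]
    expect_equal(fmax, f_argmax, tolerance = 1e-4)
  }
})

test_that("f_max * tau decreases monotonically in b at fixed a", {
  for (a in c(0.5, 0.8, 1)) {
    fm <- vapply(seq(0.05, 1, by = 0.05), function(b) {
      hn_peak_frequency(1, a, b)
    }, 0.0)
    expect_true(all(diff(fm) < 0))
  }
})

test_that("tau_alpha_from_hn is consistent with the peak frequency", {
  # Debye: both sine factors cancel
  expect_equal(tau_alpha_from_hn(1, 1, 1), 1)
  # homogeneity in tau_hn
  expect_equal(tau_alpha_from_hn(7.3, 0.8, 0.6),
               7.3 * tau_alpha_from_hn(1, 0.8, 0.6))
  # reciprocal angular peak frequency, across a shape grid
  for (a in c(0.5, 0.7, 0.9, 1)) {
    for (b in c(0.4, 0.6, 0.8, 1)) {
      expect_equal(tau_alpha_from_hn(1, a, b),
                   1 / (2 * pi * hn_peak_frequency(1, a, b)),
                   tolerance = 1e-8)
    }
  }
})

test_that("noiseless HN spectra are recovered to high accuracy", {
  truth <- c(delta_eps = 7.8, tau_hn = 2e-3, a = 0.85, b = 0.55,
             sigma_over_eps0 = 50)
  fit <- fit_hn(make_hn_spectrum())
  expect_true(fit$converged)
  expect_equal(coef(fit), truth, tolerance = 1e-3)
  rel <- abs(coef(fit) - truth) / truth
  expect_lt(max(rel), 1e-3)
})

test_that("a noiseless Debye spectrum recovers a = b = 1", {
  fit <- fit_hn(make_hn_spectrum(delta_eps = 3, tau_hn = 1e-3, a = 1, b = 1,
                                 sigma_over_eps0 = 0))
  expect_lt(abs(coef(fit)[["a"]] - 1), 1e-3)
  expect_lt(abs(coef(fit)[["b"]] - 1), 1e-3)
})

test_that("2 % multiplicative noise leaves the main parameters well determined", {
  truth <- c(delta_eps = 7.8, tau_hn = 2e-3, a = 0.85, b = 0.55,
             sigma_over_eps0 = 50)
  fit <- fit_hn(make_hn_spectrum(noise_cv = 0.02, seed = 7))
  p <- coef(fit)
  expect_lt(abs(p[["delta_eps"]] - truth[["delta_eps"]]) / truth[["delta_eps"]], 0.05)
  expect_lt(abs(p[["tau_hn"]] - truth[["tau_hn"]]) / truth[["tau_hn"]], 0.05)
  expect_lt(abs(p[["a"]] - truth[["a"]]), 0.05)
  expect_lt(abs(p[["b"]] - truth[["b"]]), 0.05)
  expect_true(all(fit$se[c("delta_eps", "tau_hn")] > 0))
})

test_that("refitting from the fitted parameters is idempotent", {
  sp <- make_hn_spectrum(noise_cv = 0.02, seed = 3)
  fit1 <- fit_hn(sp)
  fit2 <- fit_hn(sp, options = hn_fit_options(n_starts = 2,
                                              start = coef(fit1)))
  expect_lt(abs(fit2$resid_norm - fit1$resid_norm) / fit1$resid_norm, 1e-10)
})

test_that("multi-start beats a random-search oracle on a small instance", {
  sp <- make_hn_spectrum(points_per_decade = 5, noise_cv = 0.03, seed = 11)
  fit <- fit_hn(sp)
  w <- 2 * pi * sp$frequency
  ylog <- log10(sp$loss)
  set.seed(101)
  best_random <- Inf
  for (i in seq_len(1e4)) {
    p <- c(10^runif(1, -2, 2), 10^runif(1, -8, 1), runif(1, 0.05, 1),
           runif(1, 0.05, 1), 10^runif(1, -6, 4))
    r <- sqrt(mean((log10(eval_hn_loss(w, p[1], p[2], p[3], p[4], p[5])) -
                      ylog)^2))
    if (r < best_random) best_random <- r
  }
  expect_lte(fit$resid_norm, best_random)
})

test_that("fitting demands eligibility and a visible peak", {
  # too few points
  sp_small <- loss_spectrum(360, 10^seq(0, 4, length.out = 5), rep(1, 5))
  expect_error(fit_hn(sp_small), class = "amorphkit_not_fittable")
  # monotone flank only
  f <- 10^seq(-1, 6, by = 0.25)
  flank <- loss_spectrum(340, f, 0.5 * (f / 0.1)^-0.5)
  expect_error(fit_hn(flank), class = "amorphkit_not_fittable")
  # same flank is fittable when the peak requirement is lifted
  expect_s3_class(fit_hn(flank, options = hn_fit_options(require_peak = FALSE)),
                  "hnfit")
})

test_that("low-frequency log-log slope approaches -1 with conductivity", {
  w <- 10^seq(-6, -5, length.out = 10)
  loss <- eval_hn_loss(w, 7.8, 2e-3, 0.85, 0.55, sigma_over_eps0 = 50)
  slopes <- diff(log10(loss)) / diff(log10(w))
  expect_equal(slopes, rep(-1, 9), tolerance = 1e-3)
})

test_that("predict and residuals methods are mutually consistent", {
  sp <- make_hn_spectrum(noise_cv = 0.02, seed = 5)
  fit <- fit_hn(sp)
  expect_equal(residuals(fit), log10(sp$loss) - log10(predict(fit)))
  expect_equal(predict(fit, newdata = sp$frequency[3]),
               predict(fit)[3])
})
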