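test_that("an exactly linear profile gives the exact IDR with zero spread", {
  tt <- seq(0, 120, by = 5)
  prof <- dissolution_profile(tt, cbind(0.01 * tt, 0.01 * tt, 0.01 * tt),
                              volume = 500, disc_area = 0.5)
  res <- estimate_idr(prof, c(0, 120))
  expect_equal(res$idr_mean, 10, tolerance = 1e-12)
  expect_equal(res$idr_sd, 0, tolerance = 1e-12)
  expect_equal(res$n_replicates, 3)
})

test_that("the early-window slope of the saturating model recovers k * Cs", {
  cfg <- dissolution_sim_config(k = 0.096, c_s = 2, noise_cv = 0)
  prof <- simulate_dissolution(cfg)
  res <- estimate_idr(prof, c(0, 15))
  expect_equal(res$idr_mean, 0.096 * 2, tolerance = 0.01)
})

test_that("seeded triplicate noise keeps the mean accurate with positive spread", {
  cfg <- dissolution_sim_config(k = 0.096, c_s = 2, noise_cv = 0.05, seed = 9)
  prof <- simulate_dissolution(cfg)
  res <- estimate_idr(prof, c(0, 15))
  expect_equal(res$idr_mean, 0.192, tolerance = 0.03)
  expect_gt(res$idr_sd, 0)
})

test_that("IDR is invariant to replicate order and scales with V and 1/S", {
  tt <- seq(0, 60, by = 5)
  set.seed(4)
  conc <- cbind(0.01 * tt, 0.011 * tt, 0.009 * tt) +
    matrix(rnorm(3 * length(tt), 0, 1e-4), ncol = 3)
  conc <- pmax(conc, 0)
  p1 <- dissolution_profile(tt, conc, 500, 0.5)
  p2 <- dissolution_profile(tt, conc[, 3:1], 500, 0.5)
  expect_equal(estimate_idr(p1, c(0, 60))$idr_mean,
               estimate_idr(p2, c(0, 60))$idr_mean)
  expect_equal(estimate_idr(p1, c(0, 60))$idr_sd,
               estimate_idr(p2, c(0, 60))$idr_sd)

  p3 <- dissolution_profile(tt, conc, 1000, 0.5)
  p4 <- dissolution_profile(tt, conc, 500, 0.25)
  expect_equal(estimate_idr(p3, c(0, 60))$idr_mean,
               2 * estimate_idr(p1, c(0, 60))$idr_mean)
  expect_equal(estimate_idr(p4, c(0, 60))$idr_mean,
               2 * estimate_idr(p1, c(0, 60))$idr_mean)
})

test_that("later windows on the saturating model give smaller IDRs", {
  cfg <- dissolution_sim_config(k = 0.5, c_s = 0.5, noise_cv = 0,
                                times = seq(0, 120, by = 5))
  prof <- simulate_dissolution(cfg)
  wins <- list(c(0, 30), c(30, 60), c(60, 90), c(90, 120))
  idrs <- vapply(wins, function(w) estimate_idr(prof, w)$idr_mean, 0.0)
  expect_true(all(diff(idrs) < 0))
})

test_that("windows with too few points are rejected", {
  tt <- seq(0, 120, by = 5)
  prof <- dissolution_profile(tt, 0.01 * tt, 500, 0.5)
  expect_error(estimate_idr(prof, c(0, 6)),
               class = "amorphkit_insufficient_data")
  expect_error(estimate_idr(prof, c(10, 5)), class = "amorphkit_domain_error")
})

test_that("fold-changes reproduce the conventional rounding", {
  expect_equal(fold_change(0.192, 0.016), 12)     # nearest integer above 10
  expect_equal(fold_change(0.043, 0.016), 2.7)    # one decimal below 10
  expect_equal(fold_change(0.5, 0.5), 1.0)
  expect_equal(fold_change(0.192, 0.016, rounding = "none"), 12,
               tolerance = 1e-12)
  expect_error(fold_change(0.1, 0), class = "amorphkit_domain_error")
  expect_error(fold_change(0.1, -2), class = "amorphkit_domain_error")
})

test_that("fold_change accepts idr_result objects", {
  tt <- seq(0, 120, by = 5)
  fast <- dissolution_profile(tt, 0.02 * tt, 500, 0.5)
  slow <- dissolution_profile(tt, 0.001 * tt, 500, 0.5)
  fc <- fold_change(estimate_idr(fast, c(0, 120)),
                    estimate_idr(slow, c(0, 120)))
  expect_equal(fc, 20)
})

test_that("a single-slope profile yields no regime change", {
  tt <- seq(0, 120, by = 5)
  prof <- dissolution_profile(tt, 0.01 * tt, 500, 0.5)
  rc <- detect_regime_change(prof)
  expect_false(rc$changed)
  expect_true(is.na(rc$breakpoint))
})

test_that("a kinetic break is located within one sampling interval", {
  tt <- seq(0, 120, by = 5)
  cc <- ifelse(tt <= 45, 0.19 * tt / 500 * 0.5,
               (0.19 * 45 + 0.02 * (tt - 45)) / 500 * 0.5)
  set.seed(12)
  conc <- vapply(1:3, function(r) cc * exp(rnorm(length(cc), 0, 0.02)),
                 numeric(length(cc)))
  prof <- dissolution_profile(tt, conc, 500, 0.5)
  rc <- detect_regime_change(prof)
  expect_true(rc$changed)
  expect_lte(abs(rc$breakpoint - 45), 5)
  expect_gt(rc$slope_before, rc$slope_after)
})

test_that("breakpoint search equals exhaustive enumeration", {
  tt <- seq(0, 120, by = 5)
  set.seed(3)
  cc <- ifelse(tt <= 60, 0.002 * tt, 0.12 + 0.0005 * (tt - 60)) +
    rnorm(length(tt), 0, 1e-3)
  cc <- pmax(cc, 0)
  prof <- dissolution_profile(tt, cc, 500, 0.5)
  rc <- detect_regime_change(prof)

  # independent naive enumeration over all interior time points
  best <- Inf; best_bp <- NA
  for (i in 3:(length(tt) - 2)) {
    s1 <- sum(residuals(lm(cc[1:i] ~ tt[1:i]))^2)
    s2 <- sum(residuals(lm(cc[(i + 1):length(tt)] ~ tt[(i + 1):length(tt)]))^2)
    if (s1 + s2 < best) { best <- s1 + s2; best_bp <- tt[i] }
  }
  expect_equal(rc$sse_two, best, tolerance = 1e-12)
  expect_equal(rc$breakpoint, best_bp)
})

test_that("regime detection needs at least 8 points", {
  tt <- seq(0, 30, by = 5)
  prof <- dissolution_profile(tt, 0.01 * tt, 500, 0.5)
  expect_error(detect_regime_change(prof),
               class = "amorphkit_insufficient_data")
})

test_that("the nonlinear dissolution fit recovers k and Cs", {
  cfg <- dissolution_sim_config(k = 0.3, c_s = 0.8, noise_cv = 0,
                                times = seq(0, 600, by = 10), replicates = 1)
  prof <- simulate_dissolution(cfg)
  fit <- fit_dissolution(prof)
  expect_equal(fit$k, 0.3, tolerance = 1e-4)
  expect_equal(fit$c_s, 0.8, tolerance = 1e-4)
  expect_equal(fit$idr, 0.24, tolerance = 1e-4)
})
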