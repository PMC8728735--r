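#' Havriliak-Negami dielectric loss with a dc-conductivity term
#'
#' Evaluates the imaginary part of the Havriliak-Negami (HN) permittivity
#' plus the dc-conductivity contribution:
#' \deqn{\varepsilon''(\omega) = \frac{\sigma_{DC}}{\varepsilon_0 \omega}
#'   - \mathrm{Im}\!\left[\frac{\Delta\varepsilon}
#'   {\left(1 + (i\omega\tau_{HN})^a\right)^b}\right]}
#' The exponents `a` and `b` control the symmetric and asymmetric broadening
#' of the alpha-relaxation peak; `a = b = 1` is the Debye limit.
#'
#' @param omega Angular frequencies in rad/s, all positive.
#' @param delta_eps Dielectric strength (relaxation amplitude), `> 0`
#'   for a visible peak (0 gives the pure conductivity term).
#' @param tau_hn HN relaxation time in seconds, `> 0`.
#' @param a Symmetric broadening exponent, `0 < a <= 1`.
#' @param b Asymmetric broadening exponent, `0 < b <= 1`.
#' @param sigma_over_eps0 dc conductivity divided by the vacuum permittivity,
#'   in 1/s, `>= 0`.
#' @return Loss values, same length as `omega`.
#' @examples
#' # Debye peak: loss at omega*tau = 1 equals delta_eps / 2
#' eval_hn_loss(1, delta_eps = 1, tau_hn = 1, a = 1, b = 1)
#' @seealso [fit_hn()], [hn_peak_frequency()]
#' @export
eval_hn_loss <- function(omega, delta_eps, tau_hn, a, b, sigma_over_eps0 = 0) {
  if (any(!is.finite(omega)) || any(omega <= 0)) {
    amk_domain_error("`omega` must be positive and finite")
  }
  check_scalar(delta_eps, "delta_eps", lower = 0)
  check_scalar(tau_hn, "tau_hn", lower = 0, open_lower = TRUE)
  check_scalar(a, "a", lower = 0, upper = 1, open_lower = TRUE)
  check_scalar(b, "b", lower = 0, upper = 1, open_lower = TRUE)
  check_scalar(sigma_over_eps0, "sigma_over_eps0", lower = 0)
  hn <- -Im(delta_eps / (1 + (1i * omega * tau_hn)^a)^b)
  sigma_over_eps0 / omega + hn
}

#' Frequency of the Havriliak-Negami loss maximum
#'
#' Closed-form position of the alpha-loss peak:
#' \deqn{f_{max} = \frac{1}{2\pi\tau_{HN}}
#'   \left[\frac{\sin\left(\frac{\pi a}{2+2b}\right)}
#'              {\sin\left(\frac{\pi a b}{2+2b}\right)}\right]^{1/a}}
#'
#' @inheritParams eval_hn_loss
#' @return Peak frequency in Hz.
#' @export
hn_peak_frequency <- function(tau_hn, a, b) {
  check_scalar(tau_hn, "tau_hn", lower = 0, open_lower = TRUE)
  check_scalar(a, "a", lower = 0, upper = 1, open_lower = TRUE)
  check_scalar(b, "b", lower = 0, upper = 1, open_lower = TRUE)
  (1 / (2 * pi * tau_hn)) *
    (sin(pi * a / (2 + 2 * b)) / sin(pi * a * b / (2 + 2 * b)))^(1 / a)
}

#' Structural relaxation time from Havriliak-Negami parameters
#'
#' Converts the HN time to the alpha-relaxation time (the reciprocal angular
#' frequency of the loss maximum):
#' \deqn{\tau_\alpha = \tau_{HN}
#'   \left[\sin\left(\frac{\pi a}{2+2b}\right)\right]^{-1/a}
#'   \left[\sin\left(\frac{\pi a b}{2+2b}\right)\right]^{1/a}}
#' For `a = b = 1` (Debye), `tau_alpha = tau_hn`.
#'
#' @param tau_hn HN relaxation time in seconds, or an object returned by
#'   [fit_hn()] (in which case the remaining arguments are ignored).
#' @inheritParams eval_hn_loss
#' @return Alpha-relaxation time in seconds.
#' @export
tau_alpha_from_hn <- function(tau_hn, a, b) {
  if (inherits(tau_hn, "hnfit")) {
    p <- coef(tau_hn)
    return(tau_alpha_from_hn(p[["tau_hn"]], p[["a"]], p[["b"]]))
  }
  check_scalar(tau_hn, "tau_hn", lower = 0, open_lower = TRUE)
  check_scalar(a, "a", lower = 0, upper = 1, open_lower = TRUE)
  check_scalar(b, "b", lower = 0, upper = 1, open_lower = TRUE)
  tau_hn * sin(pi * a / (2 + 2 * b))^(-1 / a) *
    sin(pi * a * b / (2 + 2 * b))^(1 / a)
}

#' Options for the Havriliak-Negami fit
#'
#' @param n_starts Number of multi-start initializations (default 16).
#' @param require_peak Demand an interior loss maximum before fitting; if
#'   none is found a "not fittable" error is raised.  Set to `FALSE` to fit
#'   flank-only spectra.
#' @param seed Seed controlling the log-uniform draw of starting relaxation
#'   times (default 0, so fits are reproducible).
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param start Optional extra starting point: named vector with
#'   `delta_eps`, `tau_hn`, `a`, `b`, `sigma_over_eps0` on the natural
#'   scale (e.g. the `par` of a previous fit).
#' @return A list of class `"hn_fit_options"`.
#' @export
hn_fit_options <- function(n_starts = 16L, require_peak = TRUE, seed = 0L,
                           maxiter = 200L, start = NULL) {
  structure(list(n_starts = as.integer(n_starts),
                 require_peak = isTRUE(require_peak),
                 seed = as.integer(seed),
                 maxiter = as.integer(maxiter),
                 start = start),
            class = "hn_fit_options")
}

#' Fit the Havriliak-Negami function (with conductivity) to a loss spectrum
#'
#' Least-squares fit of [eval_hn_loss()] to one spectrum, with residuals
#' taken in `log10(loss)` so that the decades-spanning peak and the
#' conductivity tail are weighted evenly.  The fit is multi-started over a
#' grid of shape exponents and log-uniform relaxation-time initializations;
#' the best start by residual norm (ties broken by smaller `tau_hn`) is
#' returned.  Bounds are `0.001 <= a, b <= 1` and `sigma_over_eps0 >= 0`
#' (the conductivity exponent is fixed at 1, i.e. pure dc conduction).
#'
#' @param spectrum A [loss_spectrum()] with at least 8 points spanning at
#'   least 2 decades.
#' @param options An [hn_fit_options()] list.
#' @return An object of class `"hnfit"` with components `par` (named vector:
#'   `delta_eps`, `tau_hn`, `a`, `b`, `sigma_over_eps0`), `se` (standard
#'   errors, same names), `resid_norm` (RMS of the log10 residuals),
#'   `converged`, `n_starts`, `start_diagnostics`, `spectrum`, plus
#'   `f_max` and `tau_alpha` derived from the parameters.  Supports
#'   `coef()`, `print()`, `summary()`, `predict()`, `residuals()`, `plot()`.
#' @export
fit_hn <- function(spectrum, options = hn_fit_options()) {
  stopifnot(inherits(spectrum, "loss_spectrum"))
  if (!is_fit_eligible(spectrum)) {
    amk_not_fittable("spectrum has too few points or too little frequency span")
  }
  if (options$require_peak && is.null(find_loss_peak(spectrum))) {
    amk_not_fittable(sprintf(
      "no interior loss maximum at T = %g K; alpha peak outside the window",
      spectrum$temperature))
  }
  f <- spectrum$frequency
  w <- 2 * pi * f
  ylog <- log10(pmax(spectrum$loss, .Machine$double.xmin))

  # parameterization: log10(delta_eps), log10(tau_hn), a, b, log10(sigma')
  model_resid <- function(p) {
    val <- eval_hn_loss(w, 10^p[1], 10^p[2], p[3], p[4], 10^p[5])
    log10(pmax(val, .Machine$double.xmin)) - ylog
  }

  peak <- find_loss_peak(spectrum)
  de0 <- if (!is.null(peak)) 2 * peak$loss else 2 * max(spectrum$loss)
  # conductivity guess from the lowest-frequency point if the local log-log
  # slope is close to -1 there, else negligible
  lslope <- diff(ylog[1:2]) / diff(log10(f[1:2]))
  sig_est <- if (is.finite(lslope) && lslope < -0.8) {
    spectrum$loss[1] * w[1]
  } else {
    1e-10 * w[1]
  }

  shape_grid <- expand.grid(a = c(1.0, 0.8, 0.6, 0.4), b = c(1.0, 0.6))
  lo <- c(-6, log10(1 / (2 * pi * max(f))) - 4, 1e-3, 1e-3, -30)
  hi <- c(6, log10(1 / (2 * pi * min(f))) + 4, 1, 1, 30)

  starts <- with_seed(options$seed, {
    tau0 <- 10^runif(options$n_starts,
                     log10(1 / (2 * pi * max(f))),
                     log10(1 / (2 * pi * min(f))))
    lapply(seq_len(options$n_starts), function(i) {
      g <- shape_grid[((i - 1) %% nrow(shape_grid)) + 1, ]
      c(log10(de0), log10(tau0[i]), g$a, g$b,
        log10(if (i %% 2 == 0) sig_est else 1e-12 * w[1]))
    })
  })
  if (!is.null(options$start)) {
    s <- options$start
    starts <- c(starts, list(c(
      log10(s[["delta_eps"]]), log10(s[["tau_hn"]]), s[["a"]], s[["b"]],
      log10(max(s[["sigma_over_eps0"]], 1e-30)))))
  }

  runs <- lapply(starts, function(p0) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(p0, lo), hi), fn = model_resid,
                         lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(
                           maxiter = options$maxiter,
                           ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) return(list(ok = FALSE, resid_norm = Inf, start = p0))
    list(ok = fit$info %in% 1:4, fit = fit, start = p0,
         resid_norm = sqrt(fit$deviance / length(ylog)),
         tau = 10^fit$par[2])
  })

  ok <- vapply(runs, `[[`, TRUE, "ok")
  if (!any(ok)) {
    amk_fit_failure("no Havriliak-Negami start converged",
                    diagnostics = runs)
  }
  rn <- vapply(runs, `[[`, 0.0, "resid_norm")
  taus <- vapply(runs, function(r) if (r$ok) r$tau else Inf, 0.0)
  rn[!ok] <- Inf
  best <- order(rn, taus)[1]
  fit <- runs[[best]]$fit

  par <- c(delta_eps = 10^fit$par[1], tau_hn = 10^fit$par[2],
           a = fit$par[3], b = fit$par[4], sigma_over_eps0 = 10^fit$par[5])
  se <- hn_param_se(fit, par)

  structure(
    list(par = par, se = se,
         resid_norm = sqrt(fit$deviance / length(ylog)),
         deviance = fit$deviance,
         converged = fit$info %in% 1:4,
         n_starts = options$n_starts,
         start_diagnostics = data.frame(
           start = seq_along(runs), converged = ok, resid_norm = rn),
         spectrum = spectrum,
         f_max = hn_peak_frequency(par[["tau_hn"]], par[["a"]], par[["b"]]),
         tau_alpha = tau_alpha_from_hn(par[["tau_hn"]], par[["a"]], par[["b"]])),
    class = "hnfit"
  )
}

# Delta-method standard errors on the natural scale from the internal
# (log10 delta_eps, log10 tau, a, b, log10 sigma') covariance.
hn_param_se <- function(fit, par) {
  se_int <- rep(NA_real_, 5)
  vc <- tryCatch({
    n <- length(fit$fvec); p <- 5
    resvar <- fit$deviance / max(n - p, 1)
    resvar * chol2inv(chol(fit$hessian))
  }, error = function(e) NULL)
  if (!is.null(vc)) se_int <- sqrt(pmax(diag(vc), 0))
  ln10 <- log(10)
  se <- c(delta_eps = se_int[1] * ln10 * par[["delta_eps"]],
          tau_hn = se_int[2] * ln10 * par[["tau_hn"]],
          a = se_int[3], b = se_int[4],
          sigma_over_eps0 = se_int[5] * ln10 * par[["sigma_over_eps0"]])
  se
}

#' @export
coef.hnfit <- function(object, ...) object$par

#' @export
print.hnfit <- function(x, ...) {
  p <- x$par
  cat(sprintf("<hnfit> T = %.2f K%s\n", x$spectrum$temperature,
              if (x$converged) "" else "  (NOT converged)"))
  cat(sprintf("  delta_eps = %.4g, tau_hn = %.4g s, a = %.4g, b = %.4g, sigma/eps0 = %.4g 1/s\n",
              p[["delta_eps"]], p[["tau_hn"]], p[["a"]], p[["b"]],
              p[["sigma_over_eps0"]]))
  cat(sprintf("  f_max = %.4g Hz, tau_alpha = %.4g s, rms(log10) resid = %.3g\n",
              x$f_max, x$tau_alpha, x$resid_norm))
  invisible(x)
}

#' @export
summary.hnfit <- function(object, ...) {
  out <- data.frame(estimate = object$par, std_error = object$se)
  attr(out, "resid_norm") <- object$resid_norm
  attr(out, "converged") <- object$converged
  out
}

#' @export
predict.hnfit <- function(object, newdata = NULL, ...) {
  f <- if (is.null(newdata)) {
    object$spectrum$frequency
  } else if (is.list(newdata) && !is.null(newdata$frequency)) {
    newdata$frequency
  } else {
    as.numeric(newdata)
  }
  p <- object$par
  eval_hn_loss(2 * pi * f, p[["delta_eps"]], p[["tau_hn"]], p[["a"]],
               p[["b"]], p[["sigma_over_eps0"]])
}

#' @export
residuals.hnfit <- function(object, ...) {
  log10(object$spectrum$loss) - log10(predict(object))
}

#' @export
plot.hnfit <- function(x, ...) {
  sp <- x$spectrum
  plot(sp$frequency, sp$loss, log = "xy", xlab = "frequency (Hz)",
       ylab = "dielectric loss", main = sprintf("HN fit, T = %.1f K",
                                                sp$temperature), ...)
  fgrid <- 10^seq(log10(min(sp$frequency)), log10(max(sp$frequency)),
                  length.out = 200)
  lines(fgrid, predict(x, fgrid), col = "forestgreen", lwd = 2)
  abline(v = x$f_max, lty = 3)
  invisible(x)
}
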