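#' Fit the Vogel-Fulcher-Tammann law to a relaxation map
#'
#' Parameterizes the super-Arrhenius temperature dependence of structural
#' relaxation times in the supercooled liquid,
#' \deqn{\tau_\alpha(T) = \tau_\infty \exp\!\left(\frac{B}{T - T_0}\right),}
#' by least squares on `log10(tau_alpha)` versus `T`.  The fit is
#' multi-started over an 11-value grid of `T0` from 0 K to `min(T) - 5` K;
#' ties are broken by residual norm, then smaller `T0`.  The Arrhenius case
#' is the `T0 = 0` limit.
#'
#' @param points A data frame with columns `temperature` (K) and
#'   `log10_tau_alpha` (log10 seconds), e.g. the `source == "hn_fit"` rows
#'   of a relaxation map; or a [relaxation_map()]-style data frame, in which
#'   case only its `hn_fit` rows are used.
#' @param weights Optional fitting weights (default equal).
#' @return An object of class `"vftfit"`: `par` (named: `tau_inf` in s,
#'   `B` in K, `T0` in K), `se`, `cov` (covariance of
#'   `(log10_tau_inf, B, T0)`), `resid_norm`, `converged`, `data`.
#'   Supports `coef()`, `print()`, `predict()`, `residuals()`, `plot()`.
#' @seealso [tg_from_vft()], [tau_alpha_from_hn()]
#' @export
fit_vft <- function(points, weights = NULL) {
  df <- as.data.frame(points)
  if ("source" %in% names(df)) df <- df[df$source == "hn_fit", , drop = FALSE]
  if (!all(c("temperature", "log10_tau_alpha") %in% names(df))) {
    amk_format_error("`points` needs columns temperature and log10_tau_alpha")
  }
  tt <- df$temperature
  lt <- df$log10_tau_alpha
  if (nrow(df) < 4) {
    amk_insufficient_data("VFT fit needs at least 4 relaxation-time points")
  }
  if (diff(range(lt)) < 2) {
    amk_insufficient_data("relaxation times must span at least 2 decades")
  }
  wts <- if (is.null(weights)) rep(1, length(tt)) else weights

  ln10 <- log(10)
  model_resid <- function(p) {
    # p = (log10_tau_inf, B, T0)
    sqrt(wts) * (p[1] + p[2] / (ln10 * (tt - p[3])) - lt)
  }
  lo <- c(-30, 1, 0)
  hi <- c(10, 1e6, min(tt) - 1)

  t0_grid <- seq(0, min(tt) - 5, length.out = 11)
  runs <- lapply(t0_grid, function(t0) {
    # initial slope/intercept from an Arrhenius-like regression at this T0
    xr <- 1 / (ln10 * (tt - t0))
    cf <- unname(stats::coef(stats::lm(lt ~ xr)))
    p0 <- c(cf[1], max(min(cf[2], hi[2]), lo[2]), t0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(p0, lo), hi), fn = model_resid,
                         lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) return(list(ok = FALSE, resid_norm = Inf, t0 = t0))
    list(ok = fit$info %in% 1:4, fit = fit,
         resid_norm = sqrt(fit$deviance / length(lt)), t0 = fit$par[3])
  })
  ok <- vapply(runs, `[[`, TRUE, "ok")
  if (!any(ok)) amk_fit_failure("no VFT start converged")
  rn <- vapply(runs, `[[`, 0.0, "resid_norm")
  t0s <- vapply(runs, `[[`, 0.0, "t0")
  rn[!ok] <- Inf
  best <- order(rn, t0s)[1]
  fit <- runs[[best]]$fit

  vc <- tryCatch({
    resvar <- fit$deviance / max(length(lt) - 3, 1)
    resvar * chol2inv(chol(fit$hessian))
  }, error = function(e) matrix(NA_real_, 3, 3))
  dimnames(vc) <- list(c("log10_tau_inf", "B", "T0"),
                       c("log10_tau_inf", "B", "T0"))

  par <- c(tau_inf = 10^fit$par[1], B = fit$par[2], T0 = fit$par[3])
  se_int <- sqrt(pmax(diag(vc), 0))
  se <- c(tau_inf = se_int[1] * ln10 * par[["tau_inf"]],
          B = se_int[2], T0 = se_int[3])

  structure(
    list(par = par, se = se, cov = vc,
         resid_norm = sqrt(fit$deviance / length(lt)),
         deviance = fit$deviance,
         converged = fit$info %in% 1:4,
         data = data.frame(temperature = tt, log10_tau_alpha = lt)),
    class = "vftfit"
  )
}

#' @export
coef.vftfit <- function(object, ...) object$par

#' @export
print.vftfit <- function(x, ...) {
  cat(sprintf("<vftfit> tau_inf = %.4g s, B = %.4g K, T0 = %.4g K  (rms resid %.3g, n = %d)\n",
              x$par[["tau_inf"]], x$par[["B"]], x$par[["T0"]],
              x$resid_norm, nrow(x$data)))
  invisible(x)
}

#' Predict relaxation times from a VFT fit
#'
#' @param object A [fit_vft()] result.
#' @param newdata Temperatures in kelvin (vector, or list/data frame with a
#'   `temperature` element); defaults to the fitted temperatures.
#' @param what `"log10_tau"` (default) or `"tau"` (seconds).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.vftfit <- function(object, newdata = NULL,
                           what = c("log10_tau", "tau"), ...) {
  what <- match.arg(what)
  tt <- if (is.null(newdata)) {
    object$data$temperature
  } else if (is.list(newdata) && !is.null(newdata$temperature)) {
    newdata$temperature
  } else {
    as.numeric(newdata)
  }
  p <- object$par
  if (any(tt <= p[["T0"]])) {
    amk_domain_error("temperatures at or below T0 have undefined VFT times")
  }
  lt <- log10(p[["tau_inf"]]) + p[["B"]] / (log(10) * (tt - p[["T0"]]))
  if (what == "tau") 10^lt else lt
}

#' @export
residuals.vftfit <- function(object, ...) {
  object$data$log10_tau_alpha - predict(object)
}

#' @export
plot.vftfit <- function(x, ...) {
  d <- x$data
  plot(1000 / d$temperature, d$log10_tau_alpha,
       xlab = "1000/T (1/K)", ylab = "log10 tau_alpha (s)",
       main = "Relaxation map", ...)
  tg <- seq(min(d$temperature) - 5, max(d$temperature) + 5, length.out = 200)
  tg <- tg[tg > x$par[["T0"]] + 1]
  lines(1000 / tg, predict(x, tg), col = "grey40", lwd = 2)
  invisible(x)
}

#' Glass-transition temperature from a VFT fit
#'
#' Applies the convention Tg = T at which `tau_alpha` reaches a reference
#' value (100 s by default):
#' \deqn{T_g = T_0 + \frac{B}{\ln(\tau_{ref}/\tau_\infty)}}
#' The uncertainty is first-order propagation of the fit covariance.
#'
#' @param params A [fit_vft()] result.
#' @param tau_ref Reference relaxation time in seconds (default 100).
#' @return An object of class `"tg_estimate"`: `tg` (K), `se` (K),
#'   `tau_ref`.
#' @export
tg_from_vft <- function(params, tau_ref = 100) {
  stopifnot(inherits(params, "vftfit"))
  check_scalar(tau_ref, "tau_ref", lower = 0, open_lower = TRUE)
  p <- params$par
  if (tau_ref <= p[["tau_inf"]]) {
    amk_domain_error("tau_ref must exceed tau_inf for a finite Tg")
  }
  L <- log(tau_ref / p[["tau_inf"]])
  tg <- p[["T0"]] + p[["B"]] / L
  # gradient wrt internal (log10_tau_inf, B, T0)
  g <- c(log(10) * p[["B"]] / L^2, 1 / L, 1)
  se <- if (all(is.finite(params$cov))) {
    sqrt(max(drop(t(g) %*% params$cov %*% g), 0))
  } else NA_real_
  structure(list(tg = tg, se = se, tau_ref = tau_ref, vft = params),
            class = "tg_estimate")
}

#' @export
print.tg_estimate <- function(x, ...) {
  cat(sprintf("<tg_estimate> Tg(tau = %g s) = %.2f +/- %.2f K\n",
              x$tau_ref, x$tg, x$se))
  invisible(x)
}

#' Kinetic fragility index from a VFT fit
#'
#' Steepness index `m = d log10(tau) / d(Tg/T)` at `T = Tg`:
#' `m = B * Tg / (ln(10) * (Tg - T0)^2)`.
#'
#' @param params A [fit_vft()] result.
#' @param tg A [tg_from_vft()] result (computed at `tau_ref = 100` s if
#'   omitted).
#' @return The fragility index (dimensionless).
#' @export
vft_fragility <- function(params, tg = NULL) {
  stopifnot(inherits(params, "vftfit"))
  if (is.null(tg)) tg <- tg_from_vft(params)
  p <- params$par
  p[["B"]] * tg$tg / (log(10) * (tg$tg - p[["T0"]])^2)
}

#' Assemble a relaxation map
#'
#' A relaxation map is the set of (temperature, log10 tau_alpha) points the
#' VFT analysis consumes, each flagged by provenance: `"hn_fit"` for points
#' measured directly by Havriliak-Negami fitting, `"master_shift"` for
#' points predicted by master-curve shifting of sub-Tg spectra.
#'
#' @param temperature Temperatures in kelvin.
#' @param log10_tau_alpha log10 relaxation times (seconds).
#' @param source `"hn_fit"` or `"master_shift"` (recycled).
#' @param uncertainty Uncertainties in log10 seconds, `>= 0` (recycled).
#' @return A data frame of class `"relaxation_map"`.
#' @export
relaxation_map <- function(temperature, log10_tau_alpha,
                           source = "hn_fit", uncertainty = 0) {
  source <- rep_len(source, length(temperature))
  uncertainty <- rep_len(uncertainty, length(temperature))
  if (!all(source %in% c("hn_fit", "master_shift"))) {
    amk_domain_error("`source` must be 'hn_fit' or 'master_shift'")
  }
  if (any(!is.finite(uncertainty)) || any(uncertainty < 0)) {
    amk_domain_error("`uncertainty` must be finite and >= 0")
  }
  df <- data.frame(temperature = as.numeric(temperature),
                   log10_tau_alpha = as.numeric(log10_tau_alpha),
                   source = source, uncertainty = uncertainty)
  df <- df[order(df$temperature), ]
  rownames(df) <- NULL
  class(df) <- c("relaxation_map", "data.frame")
  df
}
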