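#' One-sided Fourier transform of the stretched-exponential (KWW) function
#'
#' Dielectric loss of a Kohlrausch-Williams-Watts relaxation,
#' \deqn{\varepsilon''(\omega) = A \int_0^\infty
#'   \left(-\frac{d\phi}{dt}\right) \sin(\omega t)\, dt, \qquad
#'   \phi(t) = \exp\left[-(t/\tau)^{\beta}\right],}
#' evaluated to better than 1e-6 relative accuracy across at least six
#' decades of \eqn{\omega\tau}.  For `beta = 1` this reduces to the Debye
#' loss \eqn{A\,\omega\tau/(1+\omega^2\tau^2)}.
#'
#' The oscillatory integral is computed, after the substitution
#' \eqn{v = (t/\tau)^\beta}, by panel Gauss-Legendre quadrature between
#' consecutive zeros of the sine factor; when the integrand's slow
#' \eqn{e^{-v}} decay leaves a long alternating tail of lobes, the partial
#' sums are accelerated by repeated averaging (Euler-van Wijngaarden).
#' For \eqn{\omega\tau \ge 3} the convergent high-frequency series
#' \eqn{\sum_k (-1)^{k-1}\,\Gamma(k\beta+1)/k!\,\sin(\pi k\beta/2)
#' (\omega\tau)^{-k\beta}} is used instead.
#'
#' @param omega Angular frequencies in rad/s, all positive.
#' @param beta Stretching exponent, `0 < beta <= 1`.
#' @param tau KWW relaxation time in seconds, `> 0`.
#' @param amplitude Dielectric strength scale `A`, `> 0`.
#' @return Loss values, same length as `omega`.
#' @examples
#' kww_loss(1, beta = 1, tau = 1)        # Debye: 0.5 at omega*tau = 1
#' @seealso [fit_kww()], [eval_hn_loss()]
#' @export
kww_loss <- function(omega, beta, tau, amplitude = 1) {
  if (any(!is.finite(omega)) || any(omega <= 0)) {
    amk_domain_error("`omega` must be positive and finite")
  }
  check_scalar(beta, "beta", lower = 0, upper = 1, open_lower = TRUE)
  check_scalar(tau, "tau", lower = 0, open_lower = TRUE)
  check_scalar(amplitude, "amplitude", lower = 0, open_lower = TRUE)
  amplitude * vapply(omega * tau, kww_phi, 0.0, beta = beta)
}

# Phi(x, beta) = int_0^inf beta u^(beta-1) exp(-u^beta) sin(x u) du
#             = int_0^inf exp(-v) sin(x v^(1/beta)) dv        (v = u^beta)
kww_phi <- function(x, beta) {
  if (beta == 1) return(x / (1 + x^2))
  if (x >= 3) return(kww_phi_series(x, beta))

  f <- function(v) exp(-v) * sin(x * v^(1 / beta))
  vmax <- 50                      # exp(-50) ~ 2e-22: tail negligible
  max_lobes <- 200L

  # sine-zero lobe boundaries in v, truncated at vmax
  k <- 0:max_lobes
  vlo <- (k * pi / x)^beta
  nl <- which(vlo > vmax)[1]
  capped <- is.na(nl)
  nl <- if (capped) max_lobes else nl - 1L  # lobes fully below vmax boundary
  bounds <- vlo[seq_len(nl + 1L)]
  bounds[nl + 1L] <- min(bounds[nl + 1L], vmax + 8)

  lobes <- gl_panel_lobes(f, bounds)
  if (!capped || nl < 16L) return(sum(lobes))
  # remaining alternating tail: accelerate by repeated averaging
  j0 <- max(1L, nl %/% 2L)
  S <- cumsum(lobes[j0:nl])
  while (length(S) > 1) S <- (S[-1] + S[-length(S)]) / 2
  sum(lobes[seq_len(j0 - 1L)]) + S
}

# Integrate f over each interval [bounds[i], bounds[i+1]] with 15-point
# Gauss-Legendre, splitting wide intervals into panels of width <= 2 so the
# exp(-v) factor is always well resolved.  The first lobe starts at v = 0,
# where sin(x v^(1/beta)) has only finitely many bounded derivatives for
# beta < 1; a geometrically graded mesh near zero restores full accuracy
# there.  Fully vectorized.
gl_panel_lobes <- function(f, bounds) {
  nl <- length(bounds) - 1L
  lob_id <- integer(0); plo <- numeric(0); phi_ <- numeric(0)
  for (i in seq_len(nl)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    if (lo == 0) {
      geo <- pmin(2 * 2^-(40:0), hi)
      edges <- sort(unique(c(0, geo, seq2_cap(2, hi, 2), hi)))
    } else {
      np <- max(1L, ceiling((hi - lo) / 2))
      edges <- seq(lo, hi, length.out = np + 1L)
    }
    np <- length(edges) - 1L
    lob_id <- c(lob_id, rep.int(i, np))
    plo <- c(plo, edges[-(np + 1L)])
    phi_ <- c(phi_, edges[-1L])
  }
  keep <- phi_ > plo
  lob_id <- lob_id[keep]; plo <- plo[keep]; phi_ <- phi_[keep]
  half <- (phi_ - plo) / 2
  mid <- (phi_ + plo) / 2
  # nodes: matrix panels x 15
  vv <- outer(half, gl15$nodes) + mid
  fv <- matrix(f(as.numeric(vv)), nrow = length(half))
  panel_vals <- (fv %*% gl15$weights) * half
  as.numeric(rowsum(as.numeric(panel_vals), lob_id))
}

# seq(from, to, by) that returns empty when from > to
seq2_cap <- function(from, to, by) {
  if (from > to) numeric(0) else seq(from, to, by = by)
}

# Convergent large-x series (exact for beta < 1; terms decay
# superexponentially).  Stop on term magnitude, ignoring sin() zeros.
kww_phi_series <- function(x, beta) {
  s <- 0
  for (k in 1:1000) {
    m <- exp(lgamma(k * beta + 1) - lgamma(k + 1) - k * beta * log(x))
    s <- s + (-1)^(k - 1) * m * sin(pi * k * beta / 2)
    if (m < 1e-17 * abs(s) && k > 4) break
  }
  s
}

#' Options for the KWW peak-shape fit
#'
#' @param beta_starts Multi-start grid of stretching exponents.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return A list of class `"kww_fit_options"`.
#' @export
kww_fit_options <- function(beta_starts = seq(0.3, 1.0, by = 0.1),
                            maxiter = 100L) {
  structure(list(beta_starts = beta_starts, maxiter = as.integer(maxiter)),
            class = "kww_fit_options")
}

#' Fit the KWW peak shape to an alpha-loss peak
#'
#' Least-squares fit of [kww_loss()] to the region around the loss maximum
#' (default +/- 2 decades in frequency), with residuals in `log10(loss)`.
#' Any dc-conductivity contribution should be removed first: pass the
#' `sigma_over_eps0` from a prior [fit_hn()] to have it subtracted
#' (default), or set `mask_conductivity = TRUE` to instead drop
#' low-frequency points whose local log-log slope is steeper than -0.95.
#'
#' @param spectrum A [loss_spectrum()] containing an in-window maximum.
#' @param window_decades Half-width of the fit window around the peak, in
#'   decades of frequency (default 2).
#' @param sigma_over_eps0 dc conductivity over vacuum permittivity (1/s) to
#'   subtract before fitting; 0 for none.
#' @param mask_conductivity If `TRUE`, exclude conductivity-dominated
#'   points instead of subtracting.
#' @param options A [kww_fit_options()] list.
#' @return An object of class `"kwwfit"` with `par` (`beta`, `tau_kww`,
#'   `amplitude`), `se`, `resid_norm`, `converged`, `f_max`, `window`, and
#'   the corrected spectrum used.  Supports `coef()`, `print()`,
#'   `predict()`, `residuals()`.
#' @export
fit_kww <- function(spectrum, window_decades = 2, sigma_over_eps0 = 0,
                    mask_conductivity = FALSE, options = kww_fit_options()) {
  stopifnot(inherits(spectrum, "loss_spectrum"))
  f <- spectrum$frequency
  loss <- spectrum$loss
  if (mask_conductivity) {
    # upper bound on sigma/eps0 from the lower envelope of loss * omega
    # (for a dc tail plus a relaxation peak the minimum sits at the
    # low-frequency end and approaches sigma/eps0 from above); points where
    # that conductivity could exceed 10 % of the loss are dropped
    w_all <- 2 * pi * f
    sig_hat <- min(loss * w_all)
    keep <- !conductivity_dominated(f, loss) &
      sig_hat / w_all < 0.1 * loss
    f <- f[keep]; loss <- loss[keep]
  } else if (sigma_over_eps0 > 0) {
    loss <- loss - sigma_over_eps0 / (2 * pi * f)
    keep <- loss > 0
    f <- f[keep]; loss <- loss[keep]
  }
  if (length(f) < 5) amk_not_fittable("too few points after conductivity handling")
  corrected <- loss_spectrum(spectrum$temperature, f, loss,
                             label = spectrum$label)
  peak <- find_loss_peak(corrected)
  if (is.null(peak)) {
    amk_not_fittable(sprintf("no in-window loss maximum at T = %g K",
                             spectrum$temperature))
  }
  inwin <- abs(log10(f / peak$frequency)) <= window_decades
  fw <- f[inwin]; lw <- loss[inwin]
  w <- 2 * pi * fw
  ylog <- log10(pmax(lw, .Machine$double.xmin))

  # parameterization: beta, log10(tau), log10(amplitude)
  model_resid <- function(p) {
    val <- kww_loss(w, p[1], 10^p[2], 10^p[3])
    log10(pmax(val, .Machine$double.xmin)) - ylog
  }
  lo <- c(1e-3, log10(1 / (2 * pi * max(fw))) - 3, -6)
  hi <- c(1, log10(1 / (2 * pi * min(fw))) + 3, 6)

  runs <- lapply(options$beta_starts, function(b0) {
    p0 <- c(b0, log10(1 / (2 * pi * peak$frequency)), log10(2 * peak$loss))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(p0, lo), hi), fn = model_resid,
                         lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(
                           maxiter = options$maxiter,
                           ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(fit)) return(list(ok = FALSE, resid_norm = Inf))
    list(ok = fit$info %in% 1:4, fit = fit,
         resid_norm = sqrt(fit$deviance / length(ylog)))
  })
  ok <- vapply(runs, `[[`, TRUE, "ok")
  if (!any(ok)) amk_fit_failure("no KWW start converged")
  rn <- vapply(runs, `[[`, 0.0, "resid_norm")
  rn[!ok] <- Inf
  fit <- runs[[which.min(rn)]]$fit

  par <- c(beta = fit$par[1], tau_kww = 10^fit$par[2],
           amplitude = 10^fit$par[3])
  se_int <- tryCatch({
    resvar <- fit$deviance / max(length(ylog) - 3, 1)
    sqrt(pmax(diag(resvar * chol2inv(chol(fit$hessian))), 0))
  }, error = function(e) rep(NA_real_, 3))
  ln10 <- log(10)
  se <- c(beta = se_int[1], tau_kww = se_int[2] * ln10 * par[["tau_kww"]],
          amplitude = se_int[3] * ln10 * par[["amplitude"]])

  structure(
    list(par = par, se = se,
         resid_norm = sqrt(fit$deviance / length(ylog)),
         converged = fit$info %in% 1:4,
         f_max = peak$frequency,
         window = range(fw),
         spectrum = corrected),
    class = "kwwfit"
  )
}

#' @export
coef.kwwfit <- function(object, ...) object$par

#' @export
print.kwwfit <- function(x, ...) {
  cat(sprintf("<kwwfit> T = %.2f K: beta = %.3f, tau_kww = %.4g s, amplitude = %.4g%s\n",
              x$spectrum$temperature, x$par[["beta"]], x$par[["tau_kww"]],
              x$par[["amplitude"]], if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
predict.kwwfit <- function(object, newdata = NULL, ...) {
  f <- if (is.null(newdata)) object$spectrum$frequency else as.numeric(newdata)
  p <- object$par
  kww_loss(2 * pi * f, p[["beta"]], p[["tau_kww"]], p[["amplitude"]])
}

#' @export
residuals.kwwfit <- function(object, ...) {
  log10(object$spectrum$loss) - log10(predict(object))
}

#' Temperature invariance of the alpha-peak shape
#'
#' Fits the KWW stretching exponent at every peak-bearing temperature of a
#' spectrum set and reports the spread.  Shape invariance (time-temperature
#' superposition) is the assumption behind master-curve shifting of sub-Tg
#' spectra, so this check should pass before [estimate_shift()] is used.
#'
#' @param set A [spectrum_set()] with at least two peak-bearing spectra.
#' @param threshold Maximum acceptable `max(beta) - min(beta)` spread
#'   (default 0.05).
#' @param sigma_over_eps0 Optional vector (recycled) of conductivity values
#'   to subtract per spectrum; by default each spectrum gets an HN pre-fit
#'   and its fitted conductivity is used.
#' @param options A [kww_fit_options()] list.
#' @return A list of class `"shape_invariance"`: data frame `beta_by_T`
#'   (temperature, beta, se), `spread`, `threshold`, and logical `pass`.
#' @export
shape_invariance_check <- function(set, threshold = 0.05,
                                   sigma_over_eps0 = NULL,
                                   options = kww_fit_options()) {
  stopifnot(inherits(set, "spectrum_set"))
  peaked <- Filter(function(sp) !is.null(find_loss_peak(sp)), set$spectra)
  if (length(peaked) < 2) {
    amk_insufficient_data("need at least 2 peak-bearing spectra")
  }
  if (!is.null(sigma_over_eps0)) {
    sig <- rep_len(sigma_over_eps0, length(peaked))
  } else {
    sig <- vapply(peaked, function(sp) {
      hn <- tryCatch(fit_hn(sp), error = function(e) NULL)
      if (is.null(hn)) 0 else coef(hn)[["sigma_over_eps0"]]
    }, 0.0)
  }
  fits <- Map(function(sp, s) {
    tryCatch(fit_kww(sp, sigma_over_eps0 = s, options = options),
             error = function(e) NULL)
  }, peaked, sig)
  keep <- !vapply(fits, is.null, TRUE)
  fits <- fits[keep]
  if (length(fits) < 2) {
    amk_insufficient_data("fewer than 2 spectra produced a KWW fit")
  }
  df <- data.frame(
    temperature = vapply(fits, function(fi) fi$spectrum$temperature, 0.0),
    beta = vapply(fits, function(fi) fi$par[["beta"]], 0.0),
    se = vapply(fits, function(fi) fi$se[["beta"]], 0.0))
  spread <- max(df$beta) - min(df$beta)
  structure(list(beta_by_T = df, spread = spread, threshold = threshold,
                 pass = spread <= threshold),
            class = "shape_invariance")
}

#' @export
print.shape_invariance <- function(x, ...) {
  cat(sprintf("<shape_invariance> %d temperatures, beta spread = %.4f (threshold %.3f): %s\n",
              nrow(x$beta_by_T), x$spread, x$threshold,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

# Points dominated by dc conduction: local log-log slope <= -0.95 on the
# low-frequency side of the curve.
conductivity_dominated <- function(f, loss) {
  n <- length(f)
  lf <- log10(f); ll <- log10(pmax(loss, .Machine$double.xmin))
  slope <- rep(NA_real_, n)
  if (n >= 2) {
    s <- diff(ll) / diff(lf)
    slope[1] <- s[1]; slope[n] <- s[n - 1]
    if (n > 2) slope[2:(n - 1)] <- (s[-1] + s[-(n - 1)]) / 2
  }
  dom <- slope <= -0.95
  # only flag the contiguous low-frequency run
  if (any(!dom)) dom & (cumsum(!dom) == 0) else dom
}
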