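#' Intrinsic dissolution rate from windowed slopes
#'
#' For each replicate, fits an ordinary least-squares line to concentration
#' versus time inside the window and converts the slope to an intrinsic
#' dissolution rate, `IDR = (V / S) * dC/dt` (mg min^-1 cm^-2).  This is
#' the early-time behavior of the stationary-disc dissolution model
#' `C(t) = Cs * (1 - exp(-k S t / V))`, whose initial slope gives
#' `IDR = k * Cs`.
#'
#' @param profile A [dissolution_profile()].
#' @param window Numeric pair `(t_start, t_end)` in minutes; at least three
#'   time points per replicate must fall inside (inclusive).
#' @return An object of class `"idr_result"`: `window`, `idr_mean`,
#'   `idr_sd` (across replicates), `n_replicates`, `slopes` (per-replicate
#'   IDR values, mg min^-1 cm^-2), `label`.
#' @seealso [fold_change()], [detect_regime_change()], [fit_dissolution()]
#' @export
estimate_idr <- function(profile, window) {
  stopifnot(inherits(profile, "dissolution_profile"))
  if (length(window) != 2 || window[2] <= window[1]) {
    amk_domain_error("`window` must be (t_start, t_end) with t_end > t_start")
  }
  inwin <- profile$times >= window[1] & profile$times <= window[2]
  if (sum(inwin) < 3) {
    amk_insufficient_data(sprintf(
      "window [%g, %g] min contains %d time point(s); need >= 3",
      window[1], window[2], sum(inwin)))
  }
  tt <- profile$times[inwin]
  scale <- profile$volume / profile$disc_area
  slopes <- apply(profile$concentration[inwin, , drop = FALSE], 2,
                  function(cc) unname(coef(lm(cc ~ tt))[2]) * scale)
  structure(
    list(window = as.numeric(window),
         idr_mean = mean(slopes),
         idr_sd = if (length(slopes) > 1) stats::sd(slopes) else 0,
         n_replicates = length(slopes),
         slopes = slopes,
         label = profile$label),
    class = "idr_result"
  )
}

#' @export
print.idr_result <- function(x, ...) {
  cat(sprintf(
    "<idr_result>%s window %g-%g min: IDR = %.4g +/- %.4g mg min^-1 cm^-2 (n = %d)\n",
    if (nzchar(x$label)) paste0(" ", x$label, ",") else "",
    x$window[1], x$window[2], x$idr_mean, x$idr_sd, x$n_replicates))
  invisible(x)
}

#' Fold-change between two intrinsic dissolution rates
#'
#' Ratio of mean IDRs, reported with the conventional rounding of
#' dissolution studies: nearest integer for ratios of 10 or more, one
#' decimal below 10 (`rounding = "auto"`, the default); `"none"` returns
#' the raw ratio.
#'
#' @param idr_test,idr_reference [estimate_idr()] results (or bare positive
#'   numbers).
#' @param rounding `"auto"` or `"none"`.
#' @return The fold-change (test over reference).
#' @export
fold_change <- function(idr_test, idr_reference, rounding = c("auto", "none")) {
  rounding <- match.arg(rounding)
  num <- if (inherits(idr_test, "idr_result")) idr_test$idr_mean else idr_test
  den <- if (inherits(idr_reference, "idr_result")) {
    idr_reference$idr_mean
  } else {
    idr_reference
  }
  check_scalar(num, "idr_test")
  if (!is_scalar_number(den) || den <= 0) {
    amk_domain_error("reference IDR must be a positive number")
  }
  ratio <- num / den
  if (rounding == "none") return(ratio)
  if (ratio >= 10) round(ratio) else round(ratio, 1)
}

#' Detect a change in dissolution kinetics
#'
#' Two-segment piecewise-linear fit of the replicate-mean concentration
#' curve over a grid of candidate breakpoints (every interior time point
#' with at least three points on each side).  The breakpoint minimizing the
#' total squared error is returned, together with the two slopes converted
#' to IDR units.  If the best two-segment fit improves the single-line
#' residual by less than `min_improvement` (default 20 %), the profile is
#' flagged as having no kinetic change.
#'
#' @param profile A [dissolution_profile()] with at least 8 time points.
#' @param min_improvement Minimum fractional reduction of the residual sum
#'   of squares required to declare a regime change (default 0.2).
#' @return An object of class `"regime_change"`: `changed` (logical),
#'   `breakpoint` (minutes, `NA` if unchanged), `slope_before`,
#'   `slope_after` (mg min^-1 cm^-2), `sse_one`, `sse_two`.
#' @export
detect_regime_change <- function(profile, min_improvement = 0.2) {
  stopifnot(inherits(profile, "dissolution_profile"))
  tt <- profile$times
  if (length(tt) < 8) {
    amk_insufficient_data("regime detection needs at least 8 time points")
  }
  cc <- rowMeans(profile$concentration)
  scale <- profile$volume / profile$disc_area

  sse_line <- function(idx) {
    if (length(idx) < 2) return(c(sse = 0, slope = NA_real_))
    fit <- lm(cc[idx] ~ tt[idx])
    c(sse = sum(residuals(fit)^2), slope = unname(coef(fit)[2]))
  }
  one <- sse_line(seq_along(tt))

  cand <- which(seq_along(tt) >= 3 & seq_along(tt) <= length(tt) - 2)
  fits <- lapply(cand, function(i) {
    left <- sse_line(1:i)
    right <- sse_line((i + 1):length(tt))
    list(bp = tt[i], sse = left[["sse"]] + right[["sse"]],
         slope_before = left[["slope"]], slope_after = right[["slope"]])
  })
  sses <- vapply(fits, `[[`, 0.0, "sse")
  best <- fits[[which.min(sses)]]

  # an essentially exact single line (relative to the data scale) cannot
  # meaningfully be improved by a second segment
  floor_sse <- 1e-20 * max(sum(cc^2), .Machine$double.xmin)
  improved <- one[["sse"]] > floor_sse &&
    (one[["sse"]] - best$sse) / one[["sse"]] >= min_improvement
  structure(
    list(changed = improved,
         breakpoint = if (improved) best$bp else NA_real_,
         slope_before = best$slope_before * scale,
         slope_after = best$slope_after * scale,
         sse_one = one[["sse"]], sse_two = best$sse,
         label = profile$label),
    class = "regime_change"
  )
}

#' @export
print.regime_change <- function(x, ...) {
  if (x$changed) {
    cat(sprintf(
      "<regime_change> kinetics change at t = %g min: IDR %.4g -> %.4g mg min^-1 cm^-2\n",
      x$breakpoint, x$slope_before, x$slope_after))
  } else {
    cat("<regime_change> no kinetic regime change detected\n")
  }
  invisible(x)
}

#' Fit the stationary-disc dissolution model
#'
#' Nonlinear least-squares fit of `C(t) = Cs * (1 - exp(-k S t / V))` to
#' the replicate-mean concentration curve, an alternative to windowed
#' slopes when the profile shows saturation.
#'
#' @param profile A [dissolution_profile()].
#' @param start Optional named starting values `c(k = , c_s = )`.
#' @return A list of class `"dissolution_fit"`: `k` (cm/min), `c_s`
#'   (mg/mL), `idr` (`k * c_s`, mg min^-1 cm^-2), `resid_norm`.
#' @export
fit_dissolution <- function(profile, start = NULL) {
  stopifnot(inherits(profile, "dissolution_profile"))
  tt <- profile$times
  cc <- rowMeans(profile$concentration)
  V <- profile$volume; S <- profile$disc_area
  if (is.null(start)) {
    cs0 <- max(cc) * 1.5 + 1e-9
    early <- seq_len(max(3, min(5, length(tt))))
    sl <- unname(coef(lm(cc[early] ~ tt[early]))[2])
    start <- c(k = max(sl, 1e-12) * V / (S * cs0), c_s = cs0)
  }
  fit <- minpack.lm::nls.lm(
    par = log(start), lower = log(c(1e-12, 1e-9)), upper = log(c(1e6, 1e6)),
    fn = function(p) cc - exp(p[2]) * (1 - exp(-exp(p[1]) * S * tt / V)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  k <- unname(exp(fit$par[1])); cs <- unname(exp(fit$par[2]))
  structure(list(k = k, c_s = cs, idr = k * cs,
                 resid_norm = sqrt(fit$deviance / length(tt))),
            class = "dissolution_fit")
}

#' @export
print.dissolution_fit <- function(x, ...) {
  cat(sprintf(
    "<dissolution_fit> k = %.4g cm/min, Cs = %.4g mg/mL, IDR = k*Cs = %.4g mg min^-1 cm^-2\n",
    x$k, x$c_s, x$idr))
  invisible(x)
}
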