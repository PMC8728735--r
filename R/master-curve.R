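#' Options for master-curve shift estimation
#'
#' @param search Signed search range for the shift, in decades.
#' @param prescan_step Step of the coarse pre-scan grid (decades).
#' @param min_overlap Minimum number of overlapping points required.
#' @param noise_floor Loss values at or below this are excluded.
#' @param exclude_conductivity Drop points whose local log-log slope is
#'   steeper than -0.95 (dc-conduction dominated).
#' @return A list of class `"shift_options"`.
#' @export
shift_options <- function(search = c(-8, 8), prescan_step = 0.1,
                          min_overlap = 5L, noise_floor = 0,
                          exclude_conductivity = TRUE) {
  structure(list(search = search, prescan_step = prescan_step,
                 min_overlap = as.integer(min_overlap),
                 noise_floor = noise_floor,
                 exclude_conductivity = isTRUE(exclude_conductivity)),
            class = "shift_options")
}

#' Horizontal shift superposing a spectrum onto a reference
#'
#' Time-temperature superposition: finds the log10-frequency shift `s`
#' minimizing the mean squared difference between the reference loss curve
#' evaluated at `10^(x + s)` and the target curve at `10^x`, over their
#' overlap (interpolation linear in log-log space; horizontal shift only,
#' no vertical scaling).  With this sign convention
#' `s = log10(tau_target / tau_ref)`: a slower (glassy) target gives a
#' positive shift.  The peak shapes are assumed temperature-invariant,
#' which [shape_invariance_check()] verifies upstream.
#'
#' A coarse pre-scan over the search range avoids local minima; the
#' minimum is then refined by bracketed scalar minimization.  The shift
#' uncertainty is estimated from the curvature of the objective.
#'
#' @param reference A peak-bearing [loss_spectrum()] (conductivity removed
#'   or negligible).
#' @param target The [loss_spectrum()] to superpose (typically a flank-only
#'   sub-Tg spectrum).
#' @param options A [shift_options()] list.
#' @return An object of class `"shift_result"`: `temperature` (target's),
#'   `log10_shift`, `se`, `overlap_points`, `objective` (mean squared
#'   log10 residual at the optimum), `vertical_offset` (diagnostic: mean
#'   residual remaining, decades), and `boundary` (`TRUE` when the solution
#'   sits at the edge of the feasible shift range with minimal overlap and
#'   should be treated with caution).
#' @export
estimate_shift <- function(reference, target, options = shift_options()) {
  stopifnot(inherits(reference, "loss_spectrum"),
            inherits(target, "loss_spectrum"))
  ref <- shift_mask(reference, options)
  tgt <- shift_mask(target, options)
  if (length(ref$x) < options$min_overlap || length(tgt$x) < options$min_overlap) {
    amk_insufficient_data("too few usable points after masking")
  }

  penalty <- 1e10   # finite so optimize() stays quiet in infeasible regions
  objective <- function(s, with_n = FALSE) {
    yr <- approx(ref$x, ref$y, xout = tgt$x + s, rule = 1)$y
    keep <- !is.na(yr)
    n <- sum(keep)
    if (n < options$min_overlap) {
      return(if (with_n) list(value = penalty, n = n) else penalty)
    }
    val <- mean((yr[keep] - tgt$y[keep])^2)
    if (with_n) list(value = val, n = n) else val
  }

  grid <- seq(options$search[1], options$search[2], by = options$prescan_step)
  vals <- vapply(grid, objective, 0.0)
  feasible <- vals < penalty
  if (!any(feasible)) {
    amk_stop("amorphkit_insufficient_overlap",
             "no shift in the search range gives sufficient overlap")
  }
  s0 <- grid[which.min(vals)]
  opt <- optimize(objective, interval = s0 + c(-1.5, 1.5) * options$prescan_step,
                  tol = 1e-9)
  s_hat <- opt$minimum
  at <- objective(s_hat, with_n = TRUE)

  # curvature-based 1-sigma uncertainty on s
  h <- 0.02
  curv <- (objective(s_hat + h) + objective(s_hat - h) - 2 * at$value) / h^2
  se <- if (is.finite(curv) && curv > 0 && at$n > 2) {
    sqrt(2 * at$value / (at$n * curv) * at$n / max(at$n - 2, 1))
  } else NA_real_

  yr <- approx(ref$x, ref$y, xout = tgt$x + s_hat, rule = 1)$y
  keep <- !is.na(yr)
  # a solution pressed against the edge of the feasible shift range (minimum
  # possible overlap) may be clamped rather than converged - flag it
  feas_range <- range(grid[feasible])
  boundary <- at$n <= options$min_overlap &&
    (s_hat >= feas_range[2] - options$prescan_step ||
       s_hat <= feas_range[1] + options$prescan_step)
  structure(
    list(temperature = target$temperature,
         log10_shift = s_hat, se = se,
         overlap_points = at$n,
         objective = at$value,
         vertical_offset = mean(yr[keep] - tgt$y[keep]),
         boundary = boundary),
    class = "shift_result"
  )
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf(
    "<shift_result> T = %.2f K: s = %+.4f decades (se %.3g), overlap %d pts, obj %.3g\n",
    x$temperature, x$log10_shift, x$se, x$overlap_points, x$objective))
  invisible(x)
}

# log-log representation of a spectrum with noise floor and conductivity
# masking applied.
shift_mask <- function(spectrum, options) {
  f <- spectrum$frequency; loss <- spectrum$loss
  keep <- loss > options$noise_floor
  if (options$exclude_conductivity) {
    keep <- keep & !conductivity_dominated(f, loss)
  }
  list(x = log10(f[keep]), y = log10(loss[keep]))
}

#' Predict glassy-state relaxation times from master-curve shifts
#'
#' Converts horizontal shifts of sub-Tg spectra into predicted
#' alpha-relaxation times: `log10 tau_alpha(T) = log10 tau_ref + s(T)`
#' under the sign convention of [estimate_shift()].
#'
#' @param reference_tau_alpha Alpha-relaxation time at the reference
#'   temperature, in seconds (from an HN fit).
#' @param shifts A list of [estimate_shift()] results (a single result is
#'   also accepted).
#' @return A [relaxation_map()] data frame with `source = "master_shift"`;
#'   uncertainties are the shift standard errors.
#' @export
predict_glassy_tau <- function(reference_tau_alpha, shifts) {
  check_scalar(reference_tau_alpha, "reference_tau_alpha",
               lower = 0, open_lower = TRUE)
  if (inherits(shifts, "shift_result")) shifts <- list(shifts)
  stopifnot(all(vapply(shifts, inherits, TRUE, "shift_result")))
  relaxation_map(
    temperature = vapply(shifts, `[[`, 0.0, "temperature"),
    log10_tau_alpha = log10(reference_tau_alpha) +
      vapply(shifts, `[[`, 0.0, "log10_shift"),
    source = "master_shift",
    uncertainty = vapply(shifts, function(s) {
      if (is.finite(s$se)) s$se else 0
    }, 0.0))
}

#' Deviation of predicted relaxation times from a VFT extrapolation
#'
#' Compares master-curve-predicted glassy relaxation times against the
#' extrapolated supercooled-liquid VFT law.  Positive deviations mean the
#' predicted times are slower than the extrapolation - the signature of a
#' more aged (lower-enthalpy) glass.
#'
#' @param predicted A [relaxation_map()] (any source).
#' @param vft A [fit_vft()] result.
#' @return A data frame with `temperature`, `log10_tau_alpha`,
#'   `vft_log10_tau`, `deviation_decades`, plus attributes
#'   `mean_deviation` and `max_abs_deviation`.
#' @export
compare_to_vft <- function(predicted, vft) {
  stopifnot(inherits(vft, "vftfit"))
  df <- as.data.frame(predicted)
  stopifnot(all(c("temperature", "log10_tau_alpha") %in% names(df)))
  vlt <- predict(vft, df$temperature)
  out <- data.frame(temperature = df$temperature,
                    log10_tau_alpha = df$log10_tau_alpha,
                    vft_log10_tau = vlt,
                    deviation_decades = df$log10_tau_alpha - vlt)
  attr(out, "mean_deviation") <- mean(out$deviation_decades)
  attr(out, "max_abs_deviation") <- max(abs(out$deviation_decades))
  out
}
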