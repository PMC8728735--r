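#' Run the full dielectric analysis pipeline
#'
#' Orchestrates the dielectric workflow on a set of loss spectra:
#' \enumerate{
#'   \item classify spectra as peak-bearing (supercooled liquid) or
#'     flank-only (glassy);
#'   \item Havriliak-Negami + conductivity fit per peak-bearing temperature;
#'   \item KWW peak-shape fits and the shape-invariance check;
#'   \item alpha-relaxation times and the measured relaxation map;
#'   \item VFT fit and Tg at `tau_alpha = tau_ref` (100 s);
#'   \item master-curve shifts of the flank-only spectra onto the
#'     lowest-temperature peak-bearing reference, predicted glassy
#'     relaxation times, and their deviation from the VFT extrapolation.
#' }
#' All stage outputs can be written as delimited-text tables plus one JSON
#' run-metadata file.  The run is deterministic under the seed.
#'
#' @param spectra A [spectrum_set()] or path readable by
#'   [read_spectrum_set()].
#' @param out_dir Optional output directory for stage artifacts.
#' @param seed Seed passed to the seeded fit stages.
#' @param tau_ref Relaxation time defining Tg, seconds (default 100).
#' @param shape_threshold Spread threshold for [shape_invariance_check()].
#' @param kww_options,shift_options Stage option lists.
#' @param run_kww If `FALSE`, skip the KWW stage (shape check included).
#' @return A list of class `"dielectric_report"`: `hn_table`, `kww`
#'   (`beta_by_T`, `spread`, `pass`), `relaxation_map`, `vft`, `tg`,
#'   `shifts`, `vft_deviation`, `reference_temperature`, `seed`.
#' @export
run_dielectric_pipeline <- function(spectra, out_dir = NULL, seed = 1L,
                                    tau_ref = 100, shape_threshold = 0.05,
                                    kww_options = kww_fit_options(),
                                    shift_options = amorphkit::shift_options(),
                                    run_kww = TRUE) {
  if (is.character(spectra)) spectra <- read_spectrum_set(spectra)
  stopifnot(inherits(spectra, "spectrum_set"))

  has_peak <- vapply(spectra$spectra,
                     function(sp) !is.null(find_loss_peak(sp)), TRUE)
  if (!any(has_peak)) {
    amk_not_fittable("stage hn_fit: no spectrum shows an in-window alpha peak")
  }
  liquid <- spectra$spectra[has_peak]
  glassy <- spectra$spectra[!has_peak]

  # -- HN fits ---------------------------------------------------------
  hn_fits <- lapply(liquid, function(sp) {
    tryCatch(fit_hn(sp, options = hn_fit_options(seed = seed)),
             error = function(e) {
               amk_fit_failure(sprintf("stage hn_fit failed at T = %g K: %s",
                                       sp$temperature, conditionMessage(e)))
             })
  })
  hn_table <- do.call(rbind, lapply(hn_fits, function(fit) {
    data.frame(temperature = fit$spectrum$temperature,
               t(fit$par), resid_norm = fit$resid_norm,
               f_max = fit$f_max, tau_alpha = fit$tau_alpha,
               converged = fit$converged)
  }))

  # -- KWW shape -------------------------------------------------------
  kww <- NULL
  if (run_kww) {
    sig <- vapply(hn_fits, function(fit) fit$par[["sigma_over_eps0"]], 0.0)
    kww <- tryCatch(
      shape_invariance_check(spectrum_set(liquid),
                             threshold = shape_threshold,
                             sigma_over_eps0 = sig, options = kww_options),
      error = function(e) {
        amk_fit_failure(sprintf("stage kww failed: %s", conditionMessage(e)))
      })
  }

  # -- relaxation map + VFT -------------------------------------------
  rmap <- relaxation_map(
    temperature = hn_table$temperature,
    log10_tau_alpha = log10(hn_table$tau_alpha),
    source = "hn_fit")
  vft <- tryCatch(fit_vft(rmap), error = function(e) {
    amk_fit_failure(sprintf("stage vft failed: %s", conditionMessage(e)))
  })
  tg <- tg_from_vft(vft, tau_ref = tau_ref)

  # -- master curve ----------------------------------------------------
  shifts <- NULL; predicted <- NULL; deviation <- NULL
  if (length(glassy) > 0) {
    iref <- which.min(vapply(liquid, `[[`, 0.0, "temperature"))
    ref_spectrum <- liquid[[iref]]
    ref_tau <- hn_fits[[iref]]$tau_alpha
    shifts <- lapply(glassy, function(sp) {
      tryCatch(estimate_shift(ref_spectrum, sp, options = shift_options),
               error = function(e) {
                 amk_fit_failure(sprintf(
                   "stage master_curve failed at T = %g K: %s",
                   sp$temperature, conditionMessage(e)))
               })
    })
    predicted <- predict_glassy_tau(ref_tau, shifts)
    deviation <- compare_to_vft(predicted, vft)
    rmap <- rbind(rmap, predicted)
    class(rmap) <- c("relaxation_map", "data.frame")
  }

  report <- structure(
    list(hn_table = hn_table, kww = kww, relaxation_map = rmap,
         vft = vft, tg = tg, shifts = shifts, vft_deviation = deviation,
         reference_temperature = if (length(glassy) > 0) {
           ref_spectrum$temperature
         } else NA_real_,
         seed = seed, tau_ref = tau_ref),
    class = "dielectric_report")

  if (!is.null(out_dir)) write_dielectric_report(report, out_dir)
  report
}

#' @export
print.dielectric_report <- function(x, ...) {
  cat("<dielectric_report>\n")
  cat(sprintf("  HN fits: %d temperatures (%.1f-%.1f K)\n",
              nrow(x$hn_table), min(x$hn_table$temperature),
              max(x$hn_table$temperature)))
  if (!is.null(x$kww)) {
    cat(sprintf("  KWW beta: %.3f-%.3f (spread %.4f, %s)\n",
                min(x$kww$beta_by_T$beta), max(x$kww$beta_by_T$beta),
                x$kww$spread, if (x$kww$pass) "shape-invariant" else "NOT invariant"))
  }
  p <- x$vft$par
  cat(sprintf("  VFT: tau_inf = %.3g s, B = %.4g K, T0 = %.2f K\n",
              p[["tau_inf"]], p[["B"]], p[["T0"]]))
  cat(sprintf("  Tg(tau = %g s) = %.2f +/- %.2f K\n",
              x$tau_ref, x$tg$tg, x$tg$se))
  if (!is.null(x$vft_deviation)) {
    cat(sprintf("  master curve: %d glassy spectra, max |dev from VFT| = %.3f decades\n",
                nrow(x$vft_deviation),
                attr(x$vft_deviation, "max_abs_deviation")))
  }
  invisible(x)
}

write_dielectric_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
                file.path(out_dir, name),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wt(report$hn_table, "hn_parameters.tsv")
  if (!is.null(report$kww)) wt(report$kww$beta_by_T, "kww_beta.tsv")
  wt(as.data.frame(report$relaxation_map), "relaxation_map.tsv")
  vft_df <- data.frame(parameter = names(report$vft$par),
                       estimate = report$vft$par, std_error = report$vft$se)
  wt(vft_df, "vft_parameters.tsv")
  if (!is.null(report$vft_deviation)) {
    wt(report$vft_deviation, "vft_deviation.tsv")
  }
  meta <- list(seed = report$seed, tau_ref = report$tau_ref,
               tg_K = report$tg$tg, tg_se_K = report$tg$se,
               reference_temperature_K = report$reference_temperature,
               shape_spread = if (!is.null(report$kww)) report$kww$spread,
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' Run the dissolution analysis pipeline
#'
#' Computes windowed intrinsic dissolution rates for every sample, a
#' fold-change table against a named reference sample, and kinetic
#' regime-change flags.
#'
#' @param profiles Named list of [dissolution_profile()] objects (or file
#'   paths readable by [read_dissolution()]).
#' @param windows Named list of `(t_start, t_end)` windows in minutes.
#'   Windows not containing enough points for a sample are skipped with a
#'   warning.
#' @param reference Name of the reference sample for fold-changes (its
#'   first applicable window is the denominator), or `NULL` to skip
#'   fold-changes.
#' @param fold_window Name of the window used for fold-changes (default:
#'   first window).
#' @param out_dir Optional output directory for stage artifacts.
#' @return A list of class `"dissolution_report"`: `idr_table`,
#'   `fold_changes`, `regime_changes`.
#' @export
run_dissolution_pipeline <- function(profiles,
                                     windows = list(early = c(0, 15),
                                                    late = c(60, 120),
                                                    full = c(0, 120)),
                                     reference = NULL,
                                     fold_window = names(windows)[1],
                                     out_dir = NULL) {
  if (length(profiles) == 0) amk_format_error("no dissolution profiles given")
  profiles <- lapply(profiles, function(p) {
    if (is.character(p)) read_dissolution(p) else p
  })
  stopifnot(all(vapply(profiles, inherits, TRUE, "dissolution_profile")))
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    names(profiles) <- vapply(seq_along(profiles), function(i) {
      lab <- profiles[[i]]$label
      if (nzchar(lab)) lab else paste0("sample", i)
    }, "")
  }

  idr <- list()
  rows <- list()
  for (sample in names(profiles)) {
    for (win in names(windows)) {
      res <- tryCatch(estimate_idr(profiles[[sample]], windows[[win]]),
                      error = function(e) {
                        warning(sprintf("sample %s, window %s: %s", sample,
                                        win, conditionMessage(e)),
                                call. = FALSE)
                        NULL
                      })
      if (!is.null(res)) {
        idr[[paste(sample, win, sep = ".")]] <- res
        rows[[length(rows) + 1]] <- data.frame(
          sample = sample, window = win,
          t_start = res$window[1], t_end = res$window[2],
          idr_mean = res$idr_mean, idr_sd = res$idr_sd,
          n_replicates = res$n_replicates)
      }
    }
  }
  idr_table <- do.call(rbind, rows)

  fold_changes <- NULL
  if (!is.null(reference)) {
    if (!reference %in% names(profiles)) {
      amk_format_error(sprintf("reference sample `%s` not found", reference))
    }
    ref_idr <- idr[[paste(reference, fold_window, sep = ".")]]
    if (is.null(ref_idr)) {
      warning("reference IDR unavailable; fold-change section omitted",
              call. = FALSE)
    } else {
      fold_changes <- do.call(rbind, lapply(names(profiles), function(sample) {
        res <- idr[[paste(sample, fold_window, sep = ".")]]
        if (is.null(res)) return(NULL)
        data.frame(sample = sample, reference = reference,
                   window = fold_window,
                   fold = fold_change(res, ref_idr),
                   fold_raw = fold_change(res, ref_idr, rounding = "none"))
      }))
    }
  } else if (length(profiles) > 1) {
    warning("no reference sample configured; fold-change section omitted",
            call. = FALSE)
  }

  regimes <- lapply(profiles, function(p) {
    tryCatch(detect_regime_change(p), error = function(e) NULL)
  })

  report <- structure(
    list(idr_table = idr_table, fold_changes = fold_changes,
         regime_changes = regimes, idr = idr),
    class = "dissolution_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(idr_table, file.path(out_dir, "idr_table.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(fold_changes)) {
      write.table(fold_changes, file.path(out_dir, "fold_changes.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  report
}

#' @export
print.dissolution_report <- function(x, ...) {
  cat("<dissolution_report>\n")
  print(x$idr_table, row.names = FALSE)
  if (!is.null(x$fold_changes)) {
    cat("fold-changes:\n")
    print(x$fold_changes, row.names = FALSE)
  }
  for (nm in names(x$regime_changes)) {
    rc <- x$regime_changes[[nm]]
    if (!is.null(rc) && rc$changed) {
      cat(sprintf("  %s: kinetics change at t = %g min\n", nm, rc$breakpoint))
    }
  }
  invisible(x)
}
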