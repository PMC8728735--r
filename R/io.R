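#' Read a set of dielectric loss spectra from a delimited text file
#'
#' Expects one long table with columns for temperature (K), frequency (Hz)
#' and dielectric loss.  The delimiter (comma or tab) is auto-detected.
#' Rows with non-positive frequency or non-finite loss are dropped with a
#' warning reporting the count; structural problems (missing columns, empty
#' file) raise a format error.  Units are fixed (K, Hz); no unit inference
#' is attempted.
#'
#' @param path Path to the file.
#' @param dialect Named list mapping the logical columns to file column
#'   names: `temperature`, `frequency`, `loss`, and optionally `label`.
#' @return A [spectrum_set()] sorted by temperature.
#' @seealso [write_spectrum_set()]
#' @export
read_spectrum_set <- function(path,
                              dialect = list(temperature = "temperature_K",
                                             frequency = "frequency_Hz",
                                             loss = "eps_loss")) {
  df <- read_delimited(path)
  for (col in c("temperature", "frequency", "loss")) {
    nm <- dialect[[col]]
    if (is.null(nm) || !nm %in% names(df)) {
      amk_format_error(sprintf("missing column `%s` (%s) in %s",
                               if (is.null(nm)) col else nm, col, path))
    }
  }
  tt <- as.numeric(df[[dialect$temperature]])
  ff <- as.numeric(df[[dialect$frequency]])
  ll <- as.numeric(df[[dialect$loss]])
  lab <- if (!is.null(dialect$label) && dialect$label %in% names(df)) {
    as.character(df[[dialect$label]])
  } else rep("", nrow(df))

  keep <- is.finite(tt) & is.finite(ff) & ff > 0 & is.finite(ll)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warning(sprintf("dropped %d row(s) with non-positive frequency or non-finite values",
                    n_dropped), call. = FALSE)
  }
  if (!any(keep)) amk_format_error(sprintf("no valid rows in %s", path))
  tt <- tt[keep]; ff <- ff[keep]; ll <- ll[keep]; lab <- lab[keep]

  spectra <- lapply(split(seq_along(tt), tt), function(idx) {
    o <- idx[order(ff[idx])]
    loss_spectrum(tt[o[1]], ff[o], ll[o], label = lab[o[1]])
  })
  spectrum_set(unname(spectra))
}

#' Write a spectrum set to a delimited text file
#'
#' Writes the long format read by [read_spectrum_set()], with 15 significant
#' digits so that a write/read round trip preserves values.
#'
#' @param set A [spectrum_set()].
#' @param path Output file path.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_spectrum_set <- function(set, path, sep = ",") {
  stopifnot(inherits(set, "spectrum_set"))
  rows <- lapply(set$spectra, function(sp) {
    data.frame(temperature_K = rep(sp$temperature, length(sp$frequency)),
               frequency_Hz = sp$frequency,
               eps_loss = sp$loss,
               label = rep(sp$label, length(sp$frequency)))
  })
  df <- do.call(rbind, rows)
  for (col in c("temperature_K", "frequency_Hz", "eps_loss")) {
    df[[col]] <- sprintf("%.15g", df[[col]])
  }
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dissolution profile from a stationary-disc test
#'
#' Replicate concentration-time series under fixed hydrodynamics, plus the
#' geometry needed to convert slopes into intrinsic dissolution rates.
#'
#' @param times Sampling times in minutes, strictly increasing, `>= 0`.
#' @param concentration Concentrations in mg/mL: a numeric vector (one
#'   replicate) or a matrix with one column per replicate, rows matching
#'   `times`.
#' @param volume Volume of the dissolution medium in mL.
#' @param disc_area Exposed disc surface area in cm^2.
#' @param label Free-text sample label.
#' @return An object of class `"dissolution_profile"`.
#' @export
dissolution_profile <- function(times, concentration, volume, disc_area,
                                label = "") {
  check_scalar(volume, "volume", lower = 0, open_lower = TRUE)
  check_scalar(disc_area, "disc_area", lower = 0, open_lower = TRUE)
  conc <- as.matrix(concentration)
  if (length(times) != nrow(conc)) {
    amk_format_error("`times` length must match rows of `concentration`")
  }
  if (any(!is.finite(times)) || any(times < 0) || any(diff(times) <= 0)) {
    amk_format_error("`times` must be non-negative and strictly increasing")
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    amk_domain_error("concentrations must be finite and non-negative")
  }
  if (is.null(colnames(conc))) {
    colnames(conc) <- paste0("rep", seq_len(ncol(conc)))
  }
  structure(
    list(times = as.numeric(times), concentration = conc,
         volume = as.numeric(volume), disc_area = as.numeric(disc_area),
         label = as.character(label)[1]),
    class = "dissolution_profile"
  )
}

#' @export
print.dissolution_profile <- function(x, ...) {
  cat(sprintf(
    "<dissolution_profile> %d time points (%g-%g min), %d replicate(s), V = %g mL, S = %g cm^2%s\n",
    length(x$times), min(x$times), max(x$times), ncol(x$concentration),
    x$volume, x$disc_area,
    if (nzchar(x$label)) paste0(", label: ", x$label) else ""))
  invisible(x)
}

#' Read a dissolution profile from a delimited text file
#'
#' Expects a column `time_min` plus one `conc_rep<i>` column per replicate
#' (mg/mL).  The medium volume and disc area are taken from
#' `# volume_mL:` and `# disc_area_cm2:` header comment lines, or can be
#' supplied explicitly (arguments override the header).
#'
#' @param path Path to the file.
#' @param volume,disc_area Optional overrides (mL, cm^2).
#' @return A [dissolution_profile()].
#' @seealso [write_dissolution()]
#' @export
read_dissolution <- function(path, volume = NULL, disc_area = NULL) {
  header <- parse_header_values(path)
  if (is.null(volume)) volume <- header[["volume_mL"]]
  if (is.null(disc_area)) disc_area <- header[["disc_area_cm2"]]
  if (is.null(volume) || is.null(disc_area)) {
    amk_format_error(
      "volume and disc_area must be given in header comments or arguments")
  }
  df <- read_delimited(path)
  if (!"time_min" %in% names(df)) {
    amk_format_error(sprintf("missing column `time_min` in %s", path))
  }
  rep_cols <- grep("^conc_rep", names(df), value = TRUE)
  if (length(rep_cols) == 0) {
    amk_format_error(sprintf("no `conc_rep*` columns in %s", path))
  }
  times <- as.numeric(df$time_min)
  if (any(diff(times) <= 0)) {
    amk_format_error("`time_min` must be strictly increasing")
  }
  conc <- as.matrix(df[rep_cols])
  lab <- header[["label"]]
  dissolution_profile(times, conc, volume, disc_area,
                      label = if (is.null(lab)) "" else lab)
}

#' Write a dissolution profile to a delimited text file
#'
#' @param profile A [dissolution_profile()].
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_dissolution <- function(profile, path, sep = ",") {
  stopifnot(inherits(profile, "dissolution_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# volume_mL: %.15g", profile$volume), con)
  writeLines(sprintf("# disc_area_cm2: %.15g", profile$disc_area), con)
  if (nzchar(profile$label)) {
    writeLines(sprintf("# label: %s", profile$label), con)
  }
  conc <- profile$concentration
  df <- data.frame(time_min = sprintf("%.15g", profile$times))
  for (j in seq_len(ncol(conc))) {
    df[[paste0("conc_rep", j)]] <- sprintf("%.15g", conc[, j])
  }
  write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# -- internal ---------------------------------------------------------------

# Read a comma- or tab-delimited table, skipping '#' comments.
read_delimited <- function(path) {
  if (!file.exists(path)) amk_format_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) amk_format_error(sprintf("empty input file: %s", path))
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  read.table(text = lines, sep = sep, header = TRUE,
             stringsAsFactors = FALSE, check.names = FALSE)
}

parse_header_values <- function(path) {
  if (!file.exists(path)) amk_format_error(sprintf("file not found: %s", path))
  lines <- grep("^\\s*#", readLines(path, warn = FALSE), value = TRUE)
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.+?)\\s*$", ln))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      out[[m[2]]] <- if (is.na(val)) m[3] else val
    }
  }
  out
}
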