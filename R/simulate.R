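#' Configuration for simulating a ladder of alpha-loss spectra
#'
#' Defines the generating law of a synthetic broadband-dielectric
#' measurement: alpha-relaxation times follow a Vogel-Fulcher-Tammann law,
#' every temperature shares one Havriliak-Negami peak shape (so
#' time-temperature superposition holds exactly), and a dc-conductivity
#' tail is tied to the structural relaxation rate through one coupling
#' constant, `sigma_over_eps0(T) = sigma_ratio / tau_alpha(T)`.
#'
#' The defaults emulate a supercooled-liquid heating run on an amorphous
#' small-molecule drug: 0.1 Hz-1 MHz window, spectra every 2 K from 359 to
#' 381 K, dielectric strength 7.8, and a generating VFT law calibrated so
#' that Tg (tau_alpha = 100 s) is 351.0 K with an attempt time of 1e-14 s
#' and a kinetic fragility of about 110, typical of van der Waals
#' pharmaceutical glass formers.  The default shape exponents (`a = 0.88`,
#' `b = 0.631`) give an alpha peak whose KWW stretching exponent is 0.62.
#'
#' @param vft Named list or vector with `tau_inf` (s), `B` (K), `T0` (K):
#'   the generating VFT law.
#' @param shape Named list or vector with HN exponents `a`, `b` (each in
#'   (0, 1]), shared by all temperatures.
#' @param delta_eps Dielectric strength, `> 0`.
#' @param sigma_ratio Dimensionless dc-conductivity coupling:
#'   `sigma_over_eps0 = sigma_ratio / tau_alpha`.
#' @param temperatures Spectrum temperatures in kelvin.
#' @param freq_decades Window `(min, max)` in log10 Hz.
#' @param points_per_decade Grid density, `>= 5`.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise applied pointwise (`0` = noiseless).
#' @param seed Integer RNG seed.
#' @return A list of class `"spectrum_sim_config"`.
#' @export
spectrum_sim_config <- function(
    vft = list(tau_inf = 1e-14,
               B = (351 - 300) * log(100 / 1e-14),
               T0 = 300),
    shape = list(a = 0.88, b = 0.631),
    delta_eps = 7.8,
    sigma_ratio = 0.05,
    temperatures = seq(359, 381, by = 2),
    freq_decades = c(-1, 6),
    points_per_decade = 8L,
    noise_cv = 0.02,
    seed = 1L) {
  vft <- as.list(vft); shape <- as.list(shape)
  check_scalar(vft$tau_inf, "vft$tau_inf", lower = 0, open_lower = TRUE)
  check_scalar(vft$B, "vft$B", lower = 0, open_lower = TRUE)
  check_scalar(vft$T0, "vft$T0", lower = 0)
  check_scalar(shape$a, "shape$a", lower = 0, upper = 1, open_lower = TRUE)
  check_scalar(shape$b, "shape$b", lower = 0, upper = 1, open_lower = TRUE)
  check_scalar(delta_eps, "delta_eps", lower = 0, open_lower = TRUE)
  check_scalar(sigma_ratio, "sigma_ratio", lower = 0)
  check_scalar(noise_cv, "noise_cv", lower = 0)
  if (points_per_decade < 5) {
    amk_domain_error("`points_per_decade` must be at least 5")
  }
  structure(
    list(vft = vft, shape = shape, delta_eps = delta_eps,
         sigma_ratio = sigma_ratio,
         temperatures = as.numeric(temperatures),
         freq_decades = as.numeric(freq_decades),
         points_per_decade = as.integer(points_per_decade),
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "spectrum_sim_config"
  )
}

# tau_alpha under the generating VFT law; errors below T0.
sim_tau_alpha <- function(config, temperature) {
  with(config$vft, {
    if (any(temperature <= T0)) {
      amk_domain_error("temperatures at or below the generating T0 have undefined tau")
    }
    tau_inf * exp(B / (temperature - T0))
  })
}

# HN time whose loss peak sits at 1/(2 pi tau_alpha).
sim_tau_hn <- function(config, tau_alpha) {
  a <- config$shape$a; b <- config$shape$b
  tau_alpha * sin(pi * a / (2 + 2 * b))^(1 / a) *
    sin(pi * a * b / (2 + 2 * b))^(-1 / a)
}

sim_freq_grid <- function(config) {
  10^seq(config$freq_decades[1], config$freq_decades[2],
         by = 1 / config$points_per_decade)
}

sim_one_spectrum <- function(config, temperature, label) {
  tau_a <- sim_tau_alpha(config, temperature)
  tau_hn <- sim_tau_hn(config, tau_a)
  f <- sim_freq_grid(config)
  w <- 2 * pi * f
  loss <- eval_hn_loss(w, config$delta_eps, tau_hn, config$shape$a,
                       config$shape$b,
                       sigma_over_eps0 = config$sigma_ratio / tau_a)
  loss <- loss * lognormal_factors(length(loss), config$noise_cv)
  loss_spectrum(temperature, f, loss, label = label)
}

#' Simulate a ladder of supercooled-liquid loss spectra
#'
#' Generates one loss spectrum per configured temperature from the
#' closed-form Havriliak-Negami model with conductivity, alpha-peak
#' positions following the generating VFT law, shared peak shape, and
#' multiplicative log-normal noise.  Deterministic under the config seed.
#'
#' @param config A [spectrum_sim_config()].
#' @return A [spectrum_set()]; its `metadata` records the config.
#' @seealso [simulate_glassy_flanks()], [run_dielectric_pipeline()]
#' @export
simulate_spectrum_set <- function(config = spectrum_sim_config()) {
  stopifnot(inherits(config, "spectrum_sim_config"))
  with_seed(config$seed, {
    spectra <- lapply(config$temperatures, function(tt) {
      sim_one_spectrum(config, tt, label = "simulated")
    })
    spectrum_set(spectra, metadata = list(sim_config = config))
  })
}

#' Simulate flank-only glassy loss spectra
#'
#' Generates sub-Tg spectra whose alpha peak lies below the frequency
#' window, so only the high-frequency flank is observable - the input of
#' the master-curve method.  Temperatures whose peak would fall inside the
#' window are rejected.
#'
#' @param config A [spectrum_sim_config()] (the same generating law as the
#'   supercooled ladder).
#' @param temperatures_below_tg Temperatures in kelvin, each low enough
#'   that `f_max < ` the window minimum.
#' @return A [spectrum_set()].
#' @export
simulate_glassy_flanks <- function(config, temperatures_below_tg) {
  stopifnot(inherits(config, "spectrum_sim_config"))
  f_min <- 10^config$freq_decades[1]
  for (tt in temperatures_below_tg) {
    tau_a <- sim_tau_alpha(config, tt)
    tau_hn <- sim_tau_hn(config, tau_a)
    fm <- hn_peak_frequency(tau_hn, config$shape$a, config$shape$b)
    if (fm >= f_min) {
      amk_domain_error(sprintf(
        "T = %g K puts the alpha peak at %.3g Hz, inside the window (not a glassy flank)",
        tt, fm))
    }
  }
  with_seed(config$seed + 1L, {
    spectra <- lapply(temperatures_below_tg, function(tt) {
      sim_one_spectrum(config, tt, label = "glassy")
    })
    spectrum_set(spectra, metadata = list(sim_config = config))
  })
}

#' Configuration for simulating stationary-disc dissolution profiles
#'
#' The noiseless truth is the closed-form solution of the stationary-disc
#' model, `C(t) = c_s * (1 - exp(-k S t / V))`; replicates receive
#' multiplicative log-normal noise.  Defaults mirror a typical paddle
#' apparatus run: 500 mL medium, an 8 mm diameter disc
#' (S = pi * 0.4^2 ~ 0.5027 cm^2), samples every 5 min for 120 min,
#' triplicate.
#'
#' @param k Intrinsic dissolution rate constant in cm/min, `> 0`.
#' @param c_s Saturation solubility in mg/mL, `> 0`.
#' @param volume Medium volume in mL.
#' @param disc_area Disc surface area in cm^2.
#' @param times Sampling times in minutes.
#' @param replicates Number of replicates, `>= 1`.
#' @param noise_cv Replicate noise coefficient of variation.
#' @param seed Integer RNG seed.
#' @return A list of class `"dissolution_sim_config"`.
#' @export
dissolution_sim_config <- function(k = 0.096, c_s = 2, volume = 500,
                                   disc_area = pi * 0.4^2,
                                   times = seq(0, 120, by = 5),
                                   replicates = 3L, noise_cv = 0.05,
                                   seed = 1L) {
  check_scalar(k, "k", lower = 0, open_lower = TRUE)
  check_scalar(c_s, "c_s", lower = 0, open_lower = TRUE)
  check_scalar(volume, "volume", lower = 0, open_lower = TRUE)
  check_scalar(disc_area, "disc_area", lower = 0, open_lower = TRUE)
  check_scalar(noise_cv, "noise_cv", lower = 0)
  if (replicates < 1) amk_domain_error("`replicates` must be >= 1")
  structure(
    list(k = k, c_s = c_s, volume = volume, disc_area = disc_area,
         times = as.numeric(times), replicates = as.integer(replicates),
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "dissolution_sim_config"
  )
}

#' Simulate a stationary-disc dissolution profile
#'
#' @param config A [dissolution_sim_config()].
#' @param label Sample label recorded in the profile.
#' @return A [dissolution_profile()] with `replicates` columns.
#' @export
simulate_dissolution <- function(config = dissolution_sim_config(),
                                 label = "simulated") {
  stopifnot(inherits(config, "dissolution_sim_config"))
  truth <- config$c_s *
    (1 - exp(-config$k * config$disc_area * config$times / config$volume))
  with_seed(config$seed, {
    conc <- vapply(seq_len(config$replicates), function(r) {
      truth * lognormal_factors(length(truth), config$noise_cv)
    }, numeric(length(truth)))
    dissolution_profile(config$times, conc, config$volume, config$disc_area,
                        label = label)
  })
}
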