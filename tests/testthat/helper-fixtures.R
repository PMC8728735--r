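# Shared fixtures and frozen oracle values.

# High-precision reference values for the one-sided Fourier transform of the
# stretched exponential, Phi(x, beta) = int_0^infty beta u^(beta-1)
# exp(-u^beta) sin(x u) du.  Computed independently at 40+ significant
# digits with arbitrary-precision arithmetic (tanh-sinh quadrature split at
# the sine zeros where the oscillation count is moderate, and the exact
# convergent power series with precision scaled to the largest term
# elsewhere; the two routes agree to 1e-25 where both apply).
kww_oracle <- data.frame(
  beta = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.62, 0.62, 0.62, 0.62, 0.62, 0.62, 0.62, 0.62, 0.62, 0.62, 0.62, 0.62, 0.62, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
  x = c(1.0000000000e-03, 3.1622776602e-03, 1.0000000000e-02, 3.1622776602e-02, 1.0000000000e-01, 3.1622776602e-01, 1.0000000000e+00, 3.1622776602e+00, 1.0000000000e+01, 3.1622776602e+01, 1.0000000000e+02, 3.1622776602e+02, 1.0000000000e+03, 1.0000000000e-03, 3.1622776602e-03, 1.0000000000e-02, 3.1622776602e-02, 1.0000000000e-01, 3.1622776602e-01, 1.0000000000e+00, 3.1622776602e+00, 1.0000000000e+01, 3.1622776602e+01, 1.0000000000e+02, 3.1622776602e+02, 1.0000000000e+03, 1.0000000000e-03, 3.1622776602e-03, 1.0000000000e-02, 3.1622776602e-02, 1.0000000000e-01, 3.1622776602e-01, 1.0000000000e+00, 3.1622776602e+00, 1.0000000000e+01, 3.1622776602e+01, 1.0000000000e+02, 3.1622776602e+02, 1.0000000000e+03, 1.0000000000e-03, 3.1622776602e-03, 1.0000000000e-02, 3.1622776602e-02, 1.0000000000e-01, 3.1622776602e-01, 1.0000000000e+00, 3.1622776602e+00, 1.0000000000e+01, 3.1622776602e+01, 1.0000000000e+02, 3.1622776602e+02, 1.0000000000e+03, 1.0000000000e-03, 3.1622776602e-03, 1.0000000000e-02, 3.1622776602e-02, 1.0000000000e-01, 3.1622776602e-01, 1.0000000000e+00, 3.1622776602e+00, 1.0000000000e+01, 3.1622776602e+01, 1.0000000000e+02, 3.1622776602e+02, 1.0000000000e+03),
  phi = c(0.0088996783847658314515,
          0.024581876696227380336,
          0.055784824777578408128,
          0.099277703184249221913,
          0.14048226183445627901,
          0.16483365989904533166,
          0.1677480768342602957,
          0.15380699343346265762,
          0.13082953147999712429,
          0.10548689609425580815,
          0.081883163580051460118,
          0.061873227642812694826,
          0.045870873543761681024,
          0.0019998800302227204805,
          0.0063207700957226206628,
          0.019882866355392575519,
          0.060105469300932148902,
          0.14967665990567466383,
          0.24804610123930148635,
          0.27051358016221416225,
          0.22127431358830834673,
          0.15306641719911578958,
          0.096503507802966834173,
          0.057822183472845622987,
          0.033686226345137161575,
          0.019321590036163901333,
          0.001443587187890968274,
          0.0045645903265985835612,
          0.014420837625607115309,
          0.045180981489264887552,
          0.13194238746887682057,
          0.27802164126127132393,
          0.32938309536327564642,
          0.2487354176552646623,
          0.14876645045786696109,
          0.079951069761658374868,
          0.040919142357627225071,
          0.020469729799136787002,
          0.010129039958614421621,
          0.0011330003319612179553,
          0.0035827829664528275562,
          0.011327267557843214568,
          0.035741589994889258475,
          0.11062830191902295329,
          0.29249501153409002141,
          0.41420717168260456909,
          0.27496912342646345762,
          0.12886535329918019643,
          0.054148946503219462512,
          0.021980648007354781914,
          0.0088156814561520368406,
          0.0035197503857485757522,
          0.00099999900000100018158,
          0.0031622460377080021526,
          0.0099990000999900015971,
          0.031591185416267528185,
          0.099009900990099014573,
          0.28747978728803447179,
          0.5,
          0.28747978728803447179,
          0.099009900990099014573,
          0.031591185416267528185,
          0.0099990000999900015971,
          0.0031622460377080021526,
          0.00099999900000099996474))

# Independent complex-arithmetic value of the Havriliak-Negami loss at
# omega = tau = 1, a = 0.8, b = 0.6, delta_eps = 1, sigma = 0, i.e.
# -Im[(1 + i^0.8)^(-0.6)], evaluated at 40 significant digits.
hn_oracle_08_06 <- 0.27580504136452372903

# Noiseless Havriliak-Negami spectrum on the standard 0.1 Hz - 1 MHz grid.
make_hn_spectrum <- function(delta_eps = 7.8, tau_hn = 2e-3, a = 0.85,
                             b = 0.55, sigma_over_eps0 = 50,
                             temperature = 369, points_per_decade = 10,
                             noise_cv = 0, seed = 1) {
  f <- 10^seq(-1, 6, by = 1 / points_per_decade)
  loss <- eval_hn_loss(2 * pi * f, delta_eps, tau_hn, a, b, sigma_over_eps0)
  if (noise_cv > 0) {
    set.seed(seed)
    loss <- loss * exp(rnorm(length(loss), -log(1 + noise_cv^2) / 2,
                             sqrt(log(1 + noise_cv^2))))
  }
  loss_spectrum(temperature, f, loss)
}

# Ladder of KWW-shaped peaks with a shared stretching exponent.
make_kww_ladder <- function(beta = 0.62, taus = 10^seq(-1, -4, length.out = 5),
                            amplitude = 7.8, temperatures = NULL) {
  f <- 10^seq(-1, 6, by = 1 / 8)
  if (is.null(temperatures)) temperatures <- 360 + 2 * seq_along(taus)
  spectrum_set(Map(function(tau, tt) {
    loss_spectrum(tt, f, kww_loss(2 * pi * f, beta, tau, amplitude))
  }, taus, temperatures))
}

# Trapezoid integral of a loss curve over ln(omega) on a wide log grid,
# used for sum-rule checks.
integrate_loss_dlnw <- function(loss_fun, lx_lo = -12, lx_hi = 15, n = 5000) {
  lx <- seq(lx_lo, lx_hi, length.out = n)
  y <- loss_fun(10^lx)
  sum((y[-1] + y[-n]) / 2 * diff(lx)) * log(10)
}
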