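# Solution biophysics: DLS autocorrelation fitting via the Siegert
# relation, Stokes-Einstein size and empirical mass calibration, CD mean
# residue ellipticity conversion, and electrospray charge-ladder mass
# deconvolution.

KB <- 1.380649e-23  # J/K

#' Magnitude of the DLS scattering vector
#'
#' q = 4 pi n0 sin(theta / 2) / lambda.
#'
#' @param n0 solvent refractive index (water: 1.331).
#' @param lambda laser wavelength in meters (He-Ne: 632.8e-9).
#' @param theta_deg scattering angle in degrees, in (0, 180).
#' @return q in m^-1.
#' @export
scattering_vector <- function(n0 = 1.331, lambda = 632.8e-9,
                              theta_deg = 90) {
  stopifnot(theta_deg > 0, theta_deg < 180)
  4 * pi * n0 * sin(theta_deg * pi / 360) / lambda
}

#' Viscosity of water (Vogel equation)
#'
#' eta(T) = 2.414e-5 * 10^(247.8 / (T - 140)) Pa s, valid 273-373 K.
#' Buffers are treated as water.
#'
#' @param temperature_k temperature in Kelvin.
#' @return dynamic viscosity in Pa s.
#' @export
water_viscosity <- function(temperature_k) {
  stopifnot(temperature_k > 273, temperature_k < 373)
  2.414e-5 * 10^(247.8 / (temperature_k - 140))
}

#' Build a correlogram object
#' @param tau delay times in seconds, strictly increasing.
#' @param g2 intensity autocorrelation values.
#' @param temperature_k sample temperature, K.
#' @param theta_deg scattering angle, degrees.
#' @param lambda laser wavelength, m.
#' @param n0 refractive index.
#' @export
correlogram <- function(tau, g2, temperature_k = 293,
                        theta_deg = 90, lambda = 632.8e-9, n0 = 1.331) {
  stopifnot(length(tau) == length(g2), all(is.finite(g2)),
            !is.unsorted(tau, strictly = TRUE))
  structure(list(tau = tau, g2 = g2, temperature_k = temperature_k,
                 theta_deg = theta_deg, lambda = lambda, n0 = n0),
            class = "correlogram")
}

# model: g2(tau) = B * (1 + beta * g1(tau)^2), g1 = sum_i a_i exp(-G_i tau)
g2_model <- function(tau, B, beta, amps, gammas) {
  g1 <- rowSums(vapply(seq_along(amps),
                       function(i) amps[i] * exp(-gammas[i] * tau),
                       numeric(length(tau))))
  B * (1 + beta * g1^2)
}

softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

#' Fit a correlogram with the Siegert relation
#'
#' Least-squares fit of g2(tau) = B (1 + beta |g1(tau)|^2) with
#' g1 = sum a_i exp(-Gamma_i tau), a_i >= 0, sum a_i = 1 (amplitudes
#' parameterized through a softmax so the constraints hold by
#' construction). Three fixed multi-starts on the decay rates guard
#' against local minima. Each component is converted to a diffusion
#' coefficient D = Gamma / q^2 and a hydrodynamic radius via
#' Stokes-Einstein, R_h = kB T / (6 pi eta(T) D).
#'
#' @param c a `correlogram`.
#' @param n_components 1 or 2 exponentials.
#' @param collapse_below amplitude below which a component is dropped
#'   (refitting with fewer components), default 0.01.
#' @return list with `B`, `beta`, `components` (data frame `amplitude`,
#'   `gamma_s` (s^-1), `d_m2s`, `rh_m`, `fraction`), `converged`, `note`.
#' @export
fit_correlogram <- function(c, n_components = 2, collapse_below = 0.01) {
  stopifnot(inherits(c, "correlogram"), n_components %in% 1:2)
  if (length(c$tau) < 20) stop("need >= 20 delay points")
  tau <- c$tau; g2 <- c$g2
  B0 <- mean(g2[tau >= stats::quantile(tau, 0.9)])
  if (max(g2) - B0 < 1e-8 * max(abs(g2), 1))
    stop("no decay in correlogram (g2 is flat)")
  beta0 <- max(g2) / B0 - 1
  # decay-time scale guess: tau where half the decay has happened
  target <- B0 * (1 + beta0 / 4)
  t_half <- tau[which.min(abs(g2 - target))]
  g0 <- log(2) / max(t_half, min(tau))
  starts <- list(c(1, 1), c(0.1, 10), c(0.02, 2)) # multipliers on g0
  best <- NULL
  for (s in starts) {
    par0 <- if (n_components == 2)
      c(log(B0), log(beta0), log(g0 * s[1]), log(g0 * s[2]), 0)
    else c(log(B0), log(beta0), log(g0 * s[1]))
    fn <- function(p) {
      B <- exp(p[1]); beta <- exp(p[2])
      if (n_components == 2) {
        gam <- exp(p[3:4]); amps <- softmax(c(p[5], 0))
      } else { gam <- exp(p[3]); amps <- 1 }
      g2_model(tau, B, beta, amps, gam) - g2
    }
    fit <- tryCatch(minpack.lm::nls.lm(par0, fn = fn,
             control = minpack.lm::nls.lm.control(maxiter = 300)),
             error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) stop("correlogram fit did not converge")
  p <- best$par
  B <- exp(p[1]); beta <- exp(p[2])
  if (n_components == 2) {
    gam <- exp(p[3:4]); amps <- softmax(c(p[5], 0))
  } else { gam <- exp(p[3]); amps <- 1 }
  note <- ""
  if (n_components == 2 && min(amps) < collapse_below) {
    sub <- fit_correlogram(c, n_components = 1)
    sub$note <- sprintf(
      "component with amplitude %.3g below %.2g collapsed to 1-component fit",
      min(amps), collapse_below)
    return(sub)
  }
  ord <- order(gam, decreasing = TRUE)
  gam <- gam[ord]; amps <- amps[ord]
  q <- scattering_vector(c$n0, c$lambda, c$theta_deg)
  D <- gam / q^2
  eta <- water_viscosity(c$temperature_k)
  rh <- KB * c$temperature_k / (6 * pi * eta * D)
  list(B = B, beta = beta,
       components = data.frame(amplitude = amps, gamma_s = gam,
                               d_m2s = D, rh_m = rh, fraction = amps),
       converged = best$info %in% 1:4, note = note)
}

#' Intensity-weighted size histogram from a DLS fit
#' @param fit output of [fit_correlogram()].
#' @param n_bins number of log-spaced radius bins.
#' @param range_nm radius range of the histogram in nm.
#' @return data frame `rh_nm_lo`, `rh_nm_hi`, `fraction`.
#' @export
dls_size_histogram <- function(fit, n_bins = 40, range_nm = c(0.5, 500)) {
  edges <- exp(seq(log(range_nm[1]), log(range_nm[2]),
                   length.out = n_bins + 1))
  rh_nm <- fit$components$rh_m * 1e9
  frac <- numeric(n_bins)
  for (i in seq_along(rh_nm)) {
    b <- findInterval(rh_nm[i], edges, all.inside = TRUE)
    frac[b] <- frac[b] + fit$components$fraction[i]
  }
  data.frame(rh_nm_lo = edges[-length(edges)], rh_nm_hi = edges[-1],
             fraction = frac)
}

# empirical globular-protein DLS calibration R_h(nm) = A * M(kDa)^B
RH_CAL_A <- 0.7429
RH_CAL_B <- 0.3599

#' Molecular weight from hydrodynamic radius (globular calibration)
#'
#' Inverts the empirical calibration R_h(nm) = 0.7429 * M(kDa)^0.3599.
#'
#' @param rh_nm hydrodynamic radius in nm (globular regime 0.5-10 nm;
#'   a warning is emitted outside it).
#' @param a,b calibration constants.
#' @return list `mw_kda` (full precision) and `mw_kda_2sf` (2 significant
#'   figures, the reporting convention).
#' @export
mw_from_rh <- function(rh_nm, a = RH_CAL_A, b = RH_CAL_B) {
  if (rh_nm < 0.5 || rh_nm > 10)
    warning("R_h outside the globular-protein calibration regime")
  mw <- (rh_nm / a)^(1 / b)
  list(mw_kda = mw, mw_kda_2sf = signif(mw, 2))
}

#' Hydrodynamic radius from molecular weight (forward calibration)
#' @param mw_kda mass in kDa.
#' @inheritParams mw_from_rh
#' @return R_h in nm.
#' @export
rh_from_mw <- function(mw_kda, a = RH_CAL_A, b = RH_CAL_B) a * mw_kda^b

#' Convert a raw CD spectrum to mean residue ellipticity
#'
#' Applies [theta] = theta * Mw / (N * c * l) pointwise, with theta the
#' raw signal converted from millidegrees to degrees, Mw the molecular
#' weight (Da), N the number of residues, c the mass concentration in
#' g/ml and l the path length in cm.
#'
#' @param wavelength_nm wavelengths.
#' @param mdeg raw ellipticity in millidegrees.
#' @param mw_da molecular weight, Da.
#' @param n_residues number of amino-acid residues.
#' @param conc_g_ml mass concentration, g/ml.
#' @param path_cm optical path length, cm.
#' @return data frame `wavelength_nm`, `mre` (deg cm^2 dmol^-1).
#' @export
mean_residue_ellipticity <- function(wavelength_nm, mdeg, mw_da,
                                     n_residues, conc_g_ml, path_cm) {
  if (any(!is.finite(c(mw_da, n_residues, conc_g_ml, path_cm))) ||
      any(c(mw_da, n_residues, conc_g_ml, path_cm) <= 0))
    stop("metadata (Mw, N, c, l) must all be set and positive")
  theta_deg <- mdeg / 1000
  mre <- theta_deg * mw_da / (n_residues * conc_g_ml * path_cm)
  data.frame(wavelength_nm = wavelength_nm, mre = mre)
}

PROTON_MASS <- 1.00728  # Da

#' Deconvolute an electrospray charge ladder
#'
#' Adjacent peaks of one ladder (sorted by descending m/z) carry charges
#' z and z + 1; the charge follows from
#' z = round((m2 - m_p) / (m1 - m2)) and each peak then yields a mass
#' M = z * (m/z - m_p). The ladder is consistent when the per-pair charge
#' estimates increase by exactly one and the per-peak masses agree.
#'
#' @param mz m/z values of consecutive ladder peaks (>= 2), any order.
#' @param known_z optional charge of the single supplied peak (then one
#'   peak suffices).
#' @param tol relative mass agreement required across peaks.
#' @return list `mass_da` (mean), `mass_sd`, `charges`.
#' @export
deconvolve_charge_ladder <- function(mz, known_z = NULL, tol = 1e-3) {
  if (!is.null(known_z)) {
    stopifnot(length(mz) == length(known_z))
    masses <- known_z * (mz - PROTON_MASS)
    return(list(mass_da = mean(masses),
                mass_sd = if (length(masses) > 1) stats::sd(masses) else 0,
                charges = known_z))
  }
  if (length(mz) < 2) stop("need >= 2 ladder peaks (or known_z)")
  mz <- sort(mz, decreasing = TRUE)
  z_pair <- round((mz[-1] - PROTON_MASS) / (mz[-length(mz)] - mz[-1]))
  z <- c(z_pair[1], z_pair[1] + seq_along(mz[-1]))
  # consistency: every adjacent pair must imply the expected charge
  implied <- z_pair
  expected <- z[-length(z)]
  masses <- z * (mz - PROTON_MASS)
  bad <- which(implied != expected |
                 abs(masses[-1] - masses[-length(masses)]) >
                   tol * mean(masses))
  if (length(bad))
    stop("inconsistent charge ladder at peak pair(s): ",
         paste(sprintf("(%.4f, %.4f)", mz[bad], mz[bad + 1]),
               collapse = ", "))
  list(mass_da = mean(masses), mass_sd = stats::sd(masses), charges = z)
}
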