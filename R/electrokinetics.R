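#' Vacuum permittivity (F/m)
#' @export
EPS0 <- 8.8541878128e-12

#' Cell/medium dielectric parameters
#'
#' Bundles the single-shell dielectric description of a cell suspended in a
#' liquid medium: cytoplasm permittivity/conductivity, medium
#' permittivity/conductivity, and the membrane capacitance, plus the cell
#' radius. Relaxation times derived from them drive the frequency response
#' of the Clausius-Mossotti factor: `tau_c = eps_c / sigma_c`,
#' `tau_1 = eps_m / sigma_m`, `tau_2 = C_mem * R / sigma_c`,
#' `tau_2p = C_mem * R / sigma_m`.
#'
#' Defaults describe a ~12 um lymphoblast-like cell in a low-conductivity
#' isotonic sucrose buffer (medium conductivity 1.5e-2 S/m): cytoplasm
#' 60 eps0 / 0.5 S/m, medium 78 eps0, membrane capacitance 1e-2 F/m^2.
#'
#' @param cell_radius Cell radius in metres.
#' @param eps_c,eps_m Cytoplasm and medium permittivity, F/m (absolute).
#' @param sigma_c,sigma_m Cytoplasm and medium conductivity, S/m.
#' @param C_mem Specific membrane capacitance, F/m^2.
#' @return An object of class `cell_medium_params` including the derived
#'   relaxation times.
#' @export
cell_medium_params <- function(cell_radius = 6e-6,
                               eps_c = 60 * EPS0, sigma_c = 0.5,
                               eps_m = 78 * EPS0, sigma_m = 1.5e-2,
                               C_mem = 1e-2) {
  vals <- c(cell_radius, eps_c, sigma_c, eps_m, sigma_m, C_mem)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all dielectric parameters must be positive and finite",
         call. = FALSE)
  structure(list(cell_radius = cell_radius, eps_c = eps_c, sigma_c = sigma_c,
                 eps_m = eps_m, sigma_m = sigma_m, C_mem = C_mem,
                 tau_c = eps_c / sigma_c,
                 tau_1 = eps_m / sigma_m,
                 tau_2 = C_mem * cell_radius / sigma_c,
                 tau_2p = C_mem * cell_radius / sigma_m),
            class = "cell_medium_params")
}

#' Real part of the Clausius-Mossotti factor for a shelled cell
#'
#' Evaluates, with genuine complex arithmetic, the rational frequency
#' response of the single-shell cell model:
#' \deqn{Re[K(\omega)] = Re\left[\frac{-\omega^2(\tau_1\tau_2 -
#'   \tau_c\tau_2') + j\omega(\tau_2' - \tau_1 - \tau_2) - 1}
#'   {\omega^2(\tau_c\tau_2' + 2\tau_1\tau_2) - j\omega(\tau_2' + 2\tau_1 +
#'   \tau_2) - 2}\right]}
#' The DC limit is exactly 0.5 (numerator -1 over denominator -2); the
#' high-frequency limit is
#' `-(tau_1 tau_2 - tau_c tau_2p) / (tau_c tau_2p + 2 tau_1 tau_2)`. The
#' sign of `Re[K]` sets the direction of the dielectrophoretic force.
#'
#' @param params A [cell_medium_params()].
#' @param omega Angular frequency in rad/s (vectorized, each >= 0).
#' @return `Re[K(omega)]`, same length as `omega`.
#' @export
cm_real <- function(params, omega) {
  stopifnot(inherits(params, "cell_medium_params"), all(omega >= 0))
  tc <- params$tau_c; t1 <- params$tau_1
  t2 <- params$tau_2; t2p <- params$tau_2p
  num <- -omega^2 * (t1 * t2 - tc * t2p) + 1i * omega * (t2p - t1 - t2) - 1
  den <- omega^2 * (tc * t2p + 2 * t1 * t2) -
    1i * omega * (t2p + 2 * t1 + t2) - 2
  Re(num / den)
}

#' Time-averaged dielectrophoretic force magnitude
#'
#' `<F_DEP> = 2 pi R^3 eps_m Re[K] grad|E_rms|^2` for a spherical particle
#' of radius `R` in a medium of permittivity `eps_m`. The result is signed:
#' negative values mean the particle is pushed away from the high-field
#' region (negative DEP).
#'
#' @param cell_radius Particle radius, m.
#' @param eps_m Medium permittivity, F/m.
#' @param ReK Real part of the Clausius-Mossotti factor.
#' @param grad_E2 Gradient of the squared rms field, V^2/m^3.
#' @return Force in newtons.
#' @export
dep_force_magnitude <- function(cell_radius, eps_m, ReK, grad_E2) {
  stopifnot(cell_radius > 0)
  2 * pi * cell_radius^3 * eps_m * ReK * grad_E2
}

#' Self-rotation torque in a linearly polarized AC field
#'
#' Torque on a polarizable sphere that spins in a non-rotational
#' (linearly polarized) AC field:
#' \deqn{T = \frac{9}{4} V \varepsilon_1 E_0^2
#'   \frac{\varepsilon_r - \sigma_r}{(\varepsilon_r+2)(\sigma_r+2)}
#'   \left(\frac{X + X_0}{(X+X_0)^2 + 1} +
#'         \frac{X - X_0}{(X-X_0)^2 + 1}\right)}
#' with `eps_r = eps_p/eps_m`, `sigma_r = sigma_p/sigma_m`,
#' `X = omega * tau`, `X_0 = omega_0 * tau`, and
#' `tau = (eps_p + 2 eps_m) / (sigma_p + 2 sigma_m)` the Maxwell-Wagner
#' relaxation time. The torque vanishes at `X = 0` (odd symmetry of the
#' bracket) and whenever `eps_r = sigma_r` (no loss contrast), and is an
#' odd, bounded function of `X` when `X_0 = 0`.
#'
#' @param X Dimensionless field frequency `omega * tau` (vectorized).
#' @param X0 Dimensionless rotation frequency `omega_0 * tau`.
#' @param eps_r Particle/medium permittivity ratio.
#' @param sigma_r Particle/medium conductivity ratio.
#' @param volume Cell volume, m^3.
#' @param eps1 Medium permittivity entering the prefactor, F/m.
#' @param E0 Field amplitude, V/m.
#' @return Torque in newton-metres, same length as `X`.
#' @export
rotation_torque <- function(X, X0 = 0, eps_r, sigma_r,
                            volume = 4 / 3 * pi * (6e-6)^3,
                            eps1 = 78 * EPS0, E0 = 1e4) {
  stopifnot(volume > 0, eps1 > 0)
  bracket <- (X + X0) / ((X + X0)^2 + 1) + (X - X0) / ((X - X0)^2 + 1)
  9 / 4 * volume * eps1 * E0^2 *
    (eps_r - sigma_r) / ((eps_r + 2) * (sigma_r + 2)) * bracket
}

#' Frequency spectrum of the Clausius-Mossotti factor
#'
#' Tabulates `Re[K]` over a grid of applied-field frequencies — the table a
#' practitioner scans to pick the operating frequency (where `Re[K]` and
#' hence the electrokinetic response peaks or changes sign).
#'
#' @param params A [cell_medium_params()].
#' @param freq_hz Frequencies in Hz (default: log-spaced 1 kHz -- 100 MHz).
#' @return A data frame with columns `freq_hz`, `omega`, `re_k`.
#' @export
cm_spectrum <- function(params,
                        freq_hz = 10^seq(3, 8, length.out = 201)) {
  omega <- 2 * pi * freq_hz
  data.frame(freq_hz = freq_hz, omega = omega,
             re_k = cm_real(params, omega))
}
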