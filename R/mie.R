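#' Optical configuration for a single-sphere scattering problem
#'
#' @param wavelength_nm Vacuum wavelength of the illumination in nm.
#' @param diameter_um Sphere diameter in micrometres.
#' @param n_medium Refractive index of the host medium (real, >= 1).
#' @param n_sphere Refractive index of the sphere (real; absorbing spheres
#'   with complex index are rejected — the suspensions modelled here are
#'   non-absorbing polystyrene in water).
#' @return An object of class `optical_config`.
#' @examples
#' optical_config(635, 1.04, 1.33, 1.59)
#' @export
optical_config <- function(wavelength_nm, diameter_um, n_medium, n_sphere) {
  if (is.complex(n_sphere) || is.complex(n_medium)) {
    stop("complex refractive indices (absorbing spheres) are not supported")
  }
  vals <- c(wavelength_nm, diameter_um, n_medium, n_sphere)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all optical parameters must be finite and strictly positive")
  }
  if (n_medium < 1) stop("n_medium must be >= 1")
  structure(list(wavelength_nm = wavelength_nm, diameter_um = diameter_um,
                 n_medium = n_medium, n_sphere = n_sphere),
            class = "optical_config")
}

# Mie expansion coefficients a_n, b_n (Bohren & Huffman), with the
# logarithmic derivative computed by downward recurrence.  Truncation uses
# the Wiscombe criterion N = x + 4 x^(1/3) + 2.
mie_coefficients <- function(m, x) {
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  nmx <- max(nmax, ceiling(abs(m * x))) + 16
  D <- complex(nmx + 1)
  mx <- m * x
  for (n in nmx:1) D[n] <- n / mx - 1 / (D[n + 1] + n / mx)
  # Riccati-Bessel psi_n, chi_n by upward recurrence
  psi <- numeric(nmax + 1); chi <- numeric(nmax + 1)
  psi[1] <- sin(x); chi[1] <- cos(x)
  ppsi <- cos(x); pchi <- -sin(x)          # psi_{-1}, chi_{-1}
  for (k in seq_len(nmax)) {
    psi[k + 1] <- (2 * k - 1) / x * psi[k] - ppsi
    chi[k + 1] <- (2 * k - 1) / x * chi[k] - pchi
    ppsi <- psi[k]; pchi <- chi[k]
  }
  xi <- psi - 1i * chi
  n <- seq_len(nmax)
  da <- D[n + 1] / m + n / x
  db <- D[n + 1] * m + n / x
  an <- (da * psi[n + 1] - psi[n]) / (da * xi[n + 1] - xi[n])
  bn <- (db * psi[n + 1] - psi[n]) / (db * xi[n + 1] - xi[n])
  list(an = an, bn = bn, nmax = nmax)
}

# Complex scattering amplitudes S1, S2 at cos(theta) = mu (vectorized),
# using the pi_n / tau_n angular-function recurrence.
mie_amplitudes <- function(coef, mu) {
  an <- coef$an; bn <- coef$bn; nmax <- coef$nmax
  S1 <- complex(length(mu)); S2 <- complex(length(mu))
  pi0 <- numeric(length(mu)); pi1 <- rep(1, length(mu))
  for (k in seq_len(nmax)) {
    tau <- k * mu * pi1 - (k + 1) * pi0
    f <- (2 * k + 1) / (k * (k + 1))
    S1 <- S1 + f * (an[k] * pi1 + bn[k] * tau)
    S2 <- S2 + f * (an[k] * tau + bn[k] * pi1)
    pi2 <- ((2 * k + 1) * mu * pi1 - (k + 1) * pi0) / k
    pi0 <- pi1; pi1 <- pi2
  }
  list(S1 = S1, S2 = S2)
}

#' Solve the Mie scattering problem for one sphere
#'
#' Computes the four independent Mueller-matrix elements of a homogeneous
#' sphere versus scattering angle, together with the (unpolarized)
#' scattering efficiency Q and anisotropy factor g. The sphere Mueller
#' matrix is block-diagonal:
#' \deqn{M(\theta) = \begin{pmatrix} M_{11} & M_{12} & 0 & 0 \\
#'   M_{12} & M_{11} & 0 & 0 \\ 0 & 0 & M_{33} & M_{34} \\
#'   0 & 0 & -M_{34} & M_{33} \end{pmatrix}}
#' with \eqn{M_{11} = (|S_1|^2+|S_2|^2)/2}, \eqn{M_{12} = (|S_2|^2-|S_1|^2)/2},
#' \eqn{M_{33} = \mathrm{Re}(S_2 S_1^*)}, \eqn{M_{34} = \mathrm{Im}(S_2 S_1^*)}.
#'
#' @param config An [optical_config()].
#' @param angle_step_deg Angular resolution of the returned grid (degrees).
#' @return An object of class `mie_solution` with elements `theta_deg`,
#'   `m11`, `m12`, `m33`, `m34`, `efficiency_Q`, `anisotropy_g`,
#'   `size_parameter`, `relative_index`, `n_terms` and the `config`.
#' @examples
#' sol <- solve_mie(optical_config(635, 1.04, 1.33, 1.59))
#' round(sol$efficiency_Q, 2)  # 2.71
#' round(sol$anisotropy_g, 2)  # 0.92
#' @export
solve_mie <- function(config, angle_step_deg = 0.1) {
  stopifnot(inherits(config, "optical_config"))
  if (angle_step_deg <= 0 || angle_step_deg > 90) {
    stop("angle_step_deg must be in (0, 90]")
  }
  x <- pi * config$diameter_um * config$n_medium /
    (config$wavelength_nm / 1000)
  m <- config$n_sphere / config$n_medium
  coef <- mie_coefficients(m, x)
  an <- coef$an; bn <- coef$bn
  n <- seq_along(an)
  Q <- 2 / x^2 * sum((2 * n + 1) * (Mod(an)^2 + Mod(bn)^2))
  g1 <- if (length(an) > 1) {
    k <- seq_len(length(an) - 1)
    sum(k * (k + 2) / (k + 1) *
          Re(an[k] * Conj(an[k + 1]) + bn[k] * Conj(bn[k + 1])))
  } else 0
  g2 <- sum((2 * n + 1) / (n * (n + 1)) * Re(an * Conj(bn)))
  g <- 4 / (x^2 * Q) * (g1 + g2)

  theta_deg <- seq(0, 180, by = angle_step_deg)
  if (theta_deg[length(theta_deg)] < 180) theta_deg <- c(theta_deg, 180)
  amp <- mie_amplitudes(coef, cos(theta_deg * pi / 180))
  m11 <- 0.5 * (Mod(amp$S1)^2 + Mod(amp$S2)^2)
  m12 <- 0.5 * (Mod(amp$S2)^2 - Mod(amp$S1)^2)
  cross <- amp$S2 * Conj(amp$S1)
  structure(list(theta_deg = theta_deg, m11 = m11, m12 = m12,
                 m33 = Re(cross), m34 = Im(cross),
                 efficiency_Q = Q, anisotropy_g = g,
                 size_parameter = x, relative_index = m,
                 n_terms = coef$nmax, config = config),
            class = "mie_solution")
}

#' @export
print.mie_solution <- function(x, ...) {
  cat(sprintf(paste0("<mie_solution> d=%.3g um, lambda=%.4g nm | X=%.4g ",
                     "M=%.4g | Q=%.4f g=%.4f (%d terms, %d angles)\n"),
              x$config$diameter_um, x$config$wavelength_nm,
              x$size_parameter, x$relative_index,
              x$efficiency_Q, x$anisotropy_g, x$n_terms,
              length(x$theta_deg)))
  invisible(x)
}

# Exact Mueller elements at arbitrary angles (not grid-interpolated).
mueller_at <- function(solution, theta_deg) {
  cfg <- solution$config
  x <- solution$size_parameter
  m <- solution$relative_index
  amp <- mie_amplitudes(mie_coefficients(m, x), cos(theta_deg * pi / 180))
  cross <- amp$S2 * Conj(amp$S1)
  list(m11 = 0.5 * (Mod(amp$S1)^2 + Mod(amp$S2)^2),
       m12 = 0.5 * (Mod(amp$S2)^2 - Mod(amp$S1)^2),
       m33 = Re(cross), m34 = Im(cross))
}

#' Scatter a Stokes vector off a single sphere
#'
#' Applies the block-diagonal sphere Mueller matrix at scattering angle
#' `theta_deg` to an incident Stokes vector (both expressed in the
#' scattering-plane frame).
#'
#' @param solution A [solve_mie()] result.
#' @param incident A [stokes()] vector.
#' @param theta_deg Scattering angle in degrees, in `[0, 180]`.
#' @return The scattered `stokes` vector (unnormalized intensity).
#' @export
scatter_stokes <- function(solution, incident, theta_deg) {
  stopifnot(inherits(solution, "mie_solution"), inherits(incident, "stokes"))
  if (length(theta_deg) != 1 || !is.finite(theta_deg) ||
      theta_deg < 0 || theta_deg > 180) {
    stop("theta_deg must be a single angle in [0, 180]")
  }
  el <- mueller_at(solution, theta_deg)
  I <- el$m11 * incident[["I"]] + el$m12 * incident[["Q"]]
  Q <- el$m12 * incident[["I"]] + el$m11 * incident[["Q"]]
  U <- el$m33 * incident[["U"]] + el$m34 * incident[["V"]]
  V <- -el$m34 * incident[["U"]] + el$m33 * incident[["V"]]
  stokes(I, Q, U, V, tol = 1e-6)
}

#' Signed degree of circular polarization
#'
#' The DOCP of the scattered state, given a negative sign when the
#' scattered and incident V components have opposite signs (helicity flip)
#' and a positive sign when they agree (helicity preservation):
#' `CP = V_s/I_s * V_i/|V_i|`.
#'
#' @param scattered,incident `stokes` vectors; `incident` must carry a
#'   definite helicity (`V != 0`) and `scattered` must have `I > 0`.
#' @return Signed fraction in `[-1, 1]`.
#' @export
signed_docp <- function(scattered, incident) {
  stopifnot(inherits(scattered, "stokes"), inherits(incident, "stokes"))
  if (incident[["V"]] == 0) {
    stop("incident state has V = 0: helicity undefined")
  }
  if (scattered[["I"]] <= 0) stop("scattered state has no intensity")
  (scattered[["V"]] / scattered[["I"]]) *
    sign(incident[["V"]])
}

# Signed DOCP curve for circular incidence.  For a block-diagonal sphere
# matrix and pure circular input this reduces to M33/M11, independent of
# the handedness convention.
signed_docp_curve <- function(solution) solution$m33 / solution$m11

#' Onset angle of the backward helicity-flipping lobe
#'
#' Sweeps the signed DOCP over scattering angle for circular incidence and
#' returns the smallest angle above which it stays negative through 180
#' degrees (the boundary of the contiguous flipping lobe containing exact
#' backscatter). The zero crossing is refined by bisection on the exact
#' Mie amplitudes.
#'
#' @param solution A [solve_mie()] result.
#' @param incident Circularly polarized incident `stokes` state.
#' @param refine_deg Bisection refinement tolerance in degrees.
#' @return A list with `onset_deg` (NA if no flipping occurs anywhere) and
#'   logical `no_flip`.
#' @export
flip_onset_angle <- function(solution, incident = stokes_circular("left"),
                             refine_deg = 0.01) {
  stopifnot(inherits(solution, "mie_solution"))
  if (docp(incident) < 1 - 1e-9) {
    stop("incident state must be purely circular")
  }
  cp <- signed_docp_curve(solution)
  th <- solution$theta_deg
  if (all(cp >= 0)) {
    return(list(onset_deg = NA_real_, no_flip = TRUE))
  }
  neg <- cp < 0
  i <- length(th)
  while (i > 1 && neg[i - 1]) i <- i - 1
  if (i == 1) return(list(onset_deg = 0, no_flip = FALSE))
  # bisect between th[i-1] (cp >= 0) and th[i] (cp < 0)
  lo <- th[i - 1]; hi <- th[i]
  f <- function(t) {
    el <- mueller_at(solution, t)
    el$m33 / el$m11
  }
  while (hi - lo > refine_deg) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) hi <- mid else lo <- mid
  }
  list(onset_deg = (lo + hi) / 2, no_flip = FALSE)
}

#' Polar map of signed single-scattering intensity
#'
#' Builds the per-angle signed intensity curves used for polar (log-scale)
#' visualization of helicity flipping versus preservation across sphere
#' sizes. Each configuration's angular shape (M11 normalized to unit
#' angular integral) is scaled by the ratio of its scattering efficiency
#' to `normalization_Q`, and the sign of the signed DOCP for circular
#' incidence is attached.
#'
#' @param configs A list of [optical_config()] objects.
#' @param normalization_Q Reference scattering efficiency (> 0).
#' @param angle_step_deg Angular grid resolution.
#' @return A data.frame with columns `diameter_um`, `theta_deg`,
#'   `intensity`, `signed_docp`, `signed_intensity`, `relative_magnitude`.
#' @export
polar_docp_map <- function(configs, normalization_Q,
                           angle_step_deg = 0.1) {
  if (inherits(configs, "optical_config")) configs <- list(configs)
  if (!is.numeric(normalization_Q) || normalization_Q <= 0) {
    stop("normalization_Q must be > 0")
  }
  out <- lapply(configs, function(cfg) {
    sol <- solve_mie(cfg, angle_step_deg)
    th <- sol$theta_deg
    shape <- sol$m11 /
      sum(sol$m11 * sin(th * pi / 180)) / (angle_step_deg * pi / 180)
    rel <- sol$efficiency_Q / normalization_Q
    cp <- signed_docp_curve(sol)
    data.frame(diameter_um = cfg$diameter_um, theta_deg = th,
               intensity = rel * shape, signed_docp = cp,
               signed_intensity = sign(cp) * rel * shape,
               relative_magnitude = rel)
  })
  do.call(rbind, out)
}
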