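#' Scattering medium specification
#'
#' A non-absorbing suspension of monodisperse spheres in a box geometry:
#' photons enter through the top face (z = 0), and the cuvette walls
#' terminate (tally) photons that reach them. The entry face is treated as
#' refractive-index matched (no Fresnel step), consistent with rejecting
#' specular reflections at detection.
#'
#' @param mu_s_cm Scattering coefficient in cm^-1 (> 0); the mean free
#'   path is `10 / mu_s_cm` mm.
#' @param optics An [optical_config()] describing the spheres.
#' @param depth_cm,lateral_cm Cuvette depth and lateral width in cm.
#' @return An object of class `medium_spec`.
#' @export
medium_spec <- function(mu_s_cm, optics, depth_cm = 2.2, lateral_cm = 2.2) {
  stopifnot(inherits(optics, "optical_config"))
  if (!is.finite(mu_s_cm) || mu_s_cm <= 0) stop("mu_s_cm must be > 0")
  if (depth_cm <= 0 || lateral_cm <= 0) stop("cuvette dimensions must be > 0")
  structure(list(mu_s_cm = mu_s_cm, optics = optics,
                 depth_cm = depth_cm, lateral_cm = lateral_cm,
                 mfp_mm = 10 / mu_s_cm),
            class = "medium_spec")
}

#' Incident beam specification
#'
#' @param fwhm_mm Full width at half maximum of the Gaussian beam (mm).
#' @param incident A pure circular [stokes()] state (`|V| = I`).
#' @param center Beam center on the entry face, mm.
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(fwhm_mm = 3, incident = stokes_circular("left"),
                      center = c(0, 0)) {
  if (!is.finite(fwhm_mm) || fwhm_mm <= 0) stop("fwhm_mm must be > 0")
  stopifnot(inherits(incident, "stokes"))
  if (abs(docp(incident) - 1) > 1e-9) {
    stop("incident beam must be purely circularly polarized")
  }
  structure(list(fwhm_mm = fwhm_mm, incident = incident,
                 center = center,
                 sigma_mm = fwhm_mm / (2 * sqrt(2 * log(2)))),
            class = "beam_spec")
}

#' Detector geometry
#'
#' @param n_pixels Pixels per side of the square detector grid.
#' @param pitch_um Pixel pitch in micrometres. The default 53 um puts the
#'   15-pixel central averaging disk at ~0.8 mm and gives a ~21 mm field
#'   with 400 pixels.
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(n_pixels = 400, pitch_um = 53) {
  if (n_pixels < 2 || pitch_um <= 0) stop("invalid detector geometry")
  structure(list(n_pixels = as.integer(n_pixels), pitch_um = pitch_um,
                 pitch_mm = pitch_um / 1000,
                 field_mm = n_pixels * pitch_um / 1000),
            class = "detector_spec")
}

#' Full simulation configuration
#'
#' @param medium A [medium_spec()].
#' @param beam A [beam_spec()].
#' @param detector A [detector_spec()].
#' @param n_photons Number of photon packets to launch.
#' @param seed Integer RNG seed; every photon derives an independent
#'   substream from `(seed, photon index)`, so results are bit-identical
#'   for a given seed regardless of execution order.
#' @param max_events Hard cap on scattering events per photon. Photons
#'   reaching the cap are tallied as truncated; the run manifest warns if
#'   the truncated fraction exceeds 1%.
#' @param polarized_sampling If `TRUE` (default), scattering angles are
#'   drawn from the polarization-dependent phase function by rejection;
#'   if `FALSE`, from the unpolarized M11 phase function with an intensity
#'   weight correction (cross-validation mode).
#' @param angle_step_deg Resolution of the tabulated Mueller elements.
#' @param highn_threshold Event count above which detected photons are
#'   tallied into the depolarization-limit diagnostic. The default 400 is
#'   several multiples of the ~70-event 1/e helicity attenuation of the
#'   1.04 um reference spheres, so tallied photons are fully circularly
#'   depolarized.
#' @param acceptance_cone_deg Optional half-angle (degrees, from the
#'   surface normal) of a detection acceptance cone emulating the finite
#'   collection aperture of an imaging system. The default `NULL` records
#'   every photon exiting the entry face regardless of exit angle.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(medium, beam = beam_spec(),
                              detector = detector_spec(),
                              n_photons = 1e5, seed = 1,
                              max_events = 10000,
                              polarized_sampling = TRUE,
                              angle_step_deg = 0.1,
                              highn_threshold = 400,
                              acceptance_cone_deg = NULL) {
  stopifnot(inherits(medium, "medium_spec"), inherits(beam, "beam_spec"),
            inherits(detector, "detector_spec"))
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (max_events < 1) stop("max_events must be >= 1")
  if (!is.null(acceptance_cone_deg) &&
      (acceptance_cone_deg <= 0 || acceptance_cone_deg > 90)) {
    stop("acceptance_cone_deg must be in (0, 90] or NULL")
  }
  structure(list(medium = medium, beam = beam, detector = detector,
                 n_photons = n_photons, seed = as.integer(seed),
                 max_events = as.integer(max_events),
                 polarized_sampling = isTRUE(polarized_sampling),
                 angle_step_deg = angle_step_deg,
                 highn_threshold = as.integer(highn_threshold),
                 acceptance_cone_deg = acceptance_cone_deg),
            class = "simulation_config")
}

#' Launch a photon packet
#'
#' Samples an entry position from the 2-D Gaussian beam profile and
#' initializes a packet travelling along +z with the incident Stokes
#' state, unit weight and zero event count. Uses R's RNG (seed with
#' [set.seed()]); the compiled engine uses its own per-photon substreams.
#'
#' @param beam A [beam_spec()].
#' @return A `photon_packet` list.
#' @export
launch_photon <- function(beam) {
  stopifnot(inherits(beam, "beam_spec"))
  xy <- stats::rnorm(2, mean = beam$center, sd = beam$sigma_mm)
  structure(list(position = c(xy[1], xy[2], 0),
                 direction = c(0, 0, 1),
                 frame_m = c(1, 0, 0), frame_n = c(0, 1, 0),
                 stokes = beam$incident / beam$incident[["I"]],
                 weight = 1, n_events = 0L, theta_sum = 0, cos_sum = 0),
            class = "photon_packet")
}

#' Sample scattering free paths
#'
#' @param mu_s_cm Scattering coefficient (cm^-1).
#' @param n Number of draws.
#' @return Path lengths in mm, exponential with mean `10 / mu_s_cm`.
#' @export
sample_free_path <- function(mu_s_cm, n = 1) {
  if (mu_s_cm <= 0) stop("mu_s_cm must be > 0")
  stats::rexp(n, rate = mu_s_cm / 10)
}

# Tabulated phase-function CDF for inverse sampling of theta ~ M11 sin(theta)
theta_cdf_table <- function(solution) {
  th <- solution$theta_deg * pi / 180
  w <- solution$m11 * sin(th)
  mids <- (w[-1] + w[-length(w)]) / 2 * diff(th)
  cdf <- c(0, cumsum(mids))
  cdf / cdf[length(cdf)]
}

#' Sample scattering angles from the polarized phase function
#'
#' Draws `(theta, phi)` pairs from the single-scattering probability
#' proportional to `M11(theta) I + M12(theta) (Q cos 2phi + U sin 2phi)`
#' by rejection against the envelope `M11 (I + sqrt(Q^2+U^2))`, with theta
#' proposed by inverse-CDF sampling of the M11 phase function and phi
#' uniform. Uses R's RNG.
#'
#' @param solution A [solve_mie()] result.
#' @param stokes_state The current [stokes()] state of the packet.
#' @param n Number of draws.
#' @return A data.frame with columns `theta` and `phi` (radians).
#' @export
sample_scattering <- function(solution, stokes_state, n = 1) {
  stopifnot(inherits(solution, "mie_solution"),
            inherits(stokes_state, "stokes"))
  th_grid <- solution$theta_deg * pi / 180
  cdf <- theta_cdf_table(solution)
  r12 <- solution$m12 / solution$m11
  I <- stokes_state[["I"]]
  Qn <- stokes_state[["Q"]] / I; Un <- stokes_state[["U"]] / I
  A <- sqrt(Qn^2 + Un^2)
  draw_theta <- function(k) {
    stats::approx(cdf, th_grid, xout = stats::runif(k), ties = "ordered")$y
  }
  theta <- numeric(n); phi <- numeric(n)
  filled <- 0; guard <- 0
  while (filled < n) {
    k <- (n - filled) * 2 + 16
    tt <- draw_theta(k)
    pp <- stats::runif(k, 0, 2 * pi)
    r <- stats::approx(th_grid, r12, xout = tt)$y
    pacc <- (1 + r * (Qn * cos(2 * pp) + Un * sin(2 * pp))) / (1 + A)
    keep <- which(stats::runif(k) < pacc)
    take <- utils::head(keep, n - filled)
    idx <- filled + seq_along(take)
    theta[idx] <- tt[take]; phi[idx] <- pp[take]
    filled <- filled + length(take)
    if ((guard <- guard + 1) > 10000) {
      stop("rejection sampler failed to accept (broken envelope)")
    }
  }
  data.frame(theta = theta, phi = phi)
}

rotate_about <- function(v, axis, angle) {
  # Rodrigues rotation
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) + pracma_cross(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Apply one scattering event to a photon packet
#'
#' Rotates the Stokes reference frame into the scattering plane (azimuth
#' `phi` about the propagation direction), applies the sphere Mueller
#' matrix at `theta`, renormalizes intensity into the packet weight, and
#' updates the direction and polarization reference frame.
#'
#' @param packet A `photon_packet` from [launch_photon()].
#' @param solution A [solve_mie()] result.
#' @param theta,phi Scattering and azimuthal angles in radians.
#' @return The updated `photon_packet`.
#' @export
apply_scattering <- function(packet, solution, theta, phi) {
  stopifnot(inherits(packet, "photon_packet"))
  el <- mueller_at(solution, theta * 180 / pi)
  s <- packet$stokes
  c2p <- cos(2 * phi); s2p <- sin(2 * phi)
  Qr <- s[["Q"]] * c2p + s[["U"]] * s2p
  Ur <- -s[["Q"]] * s2p + s[["U"]] * c2p
  I2 <- el$m11 * s[["I"]] + el$m12 * Qr
  Q2 <- el$m12 * s[["I"]] + el$m11 * Qr
  U2 <- el$m33 * Ur + el$m34 * s[["V"]]
  V2 <- -el$m34 * Ur + el$m33 * s[["V"]]
  d <- packet$direction; m <- packet$frame_m; n <- packet$frame_n
  mphi <- cos(phi) * m + sin(phi) * n
  nphi <- -sin(phi) * m + cos(phi) * n
  dnew <- cos(theta) * d + sin(theta) * mphi
  mnew <- cos(theta) * mphi - sin(theta) * d
  dnew <- dnew / sqrt(sum(dnew^2))
  mnew <- mnew - sum(mnew * dnew) * dnew
  mnew <- mnew / sqrt(sum(mnew^2))
  packet$direction <- dnew
  packet$frame_m <- mnew
  packet$frame_n <- pracma_cross(dnew, mnew)
  packet$stokes <- stokes(1, Q2 / I2, U2 / I2, V2 / I2, tol = 1e-6)
  packet$n_events <- packet$n_events + 1L
  packet$theta_sum <- packet$theta_sum + theta
  packet$cos_sum <- packet$cos_sum + cos(theta)
  packet
}

#' Empty detector accumulator grid
#'
#' @param detector A [detector_spec()].
#' @return A `detector_grid` holding the per-channel accumulators.
#' @export
detector_grid <- function(detector = detector_spec()) {
  np <- detector$n_pixels
  z <- function() matrix(0, np, np)
  structure(list(detector = detector,
                 flipped = z(), preserved = z(),
                 nsum_flipped = z(), nsum_preserved = z(),
                 anglesum_flipped = z(), anglesum_preserved = z(),
                 cossum_flipped = z(), cossum_preserved = z(),
                 count_flipped = z(), count_preserved = z(),
                 overflow = 0),
            class = "detector_grid")
}

#' Record a photon exiting the entry face
#'
#' Splits the packet intensity into helicity channels (for left-circular
#' incidence: preserved = (I - V)/2, flipped = (I + V)/2 under the
#' V = R - L convention), bins it at the exit position, and accumulates
#' the per-channel event-count and angle-sum statistics weighted by that
#' channel's intensity. Exits outside the grid go to the overflow tally.
#'
#' @param packet A `photon_packet` positioned on the entry face with an
#'   outward direction.
#' @param grid A [detector_grid()].
#' @param incident_V Sign of the incident V component (default -1,
#'   left-circular).
#' @return The updated `detector_grid`.
#' @export
detect_exit <- function(packet, grid, incident_V = -1) {
  stopifnot(inherits(packet, "photon_packet"), inherits(grid, "detector_grid"))
  if (abs(packet$position[3]) > 1e-9 || packet$direction[3] >= 0) {
    stop("packet is not exiting through the entry face")
  }
  s <- packet$stokes; w <- packet$weight
  Vn <- s[["V"]] / s[["I"]]
  if (incident_V < 0) {
    wf <- 0.5 * w * (1 + Vn); wp <- 0.5 * w * (1 - Vn)
  } else {
    wf <- 0.5 * w * (1 - Vn); wp <- 0.5 * w * (1 + Vn)
  }
  det <- grid$detector
  half <- det$field_mm / 2
  ix <- floor((packet$position[1] + half) / det$pitch_mm) + 1
  iy <- floor((packet$position[2] + half) / det$pitch_mm) + 1
  if (ix < 1 || ix > det$n_pixels || iy < 1 || iy > det$n_pixels) {
    grid$overflow <- grid$overflow + w
    return(grid)
  }
  nev <- packet$n_events
  amean <- if (nev > 0) packet$theta_sum / nev else 0
  cmean <- if (nev > 0) packet$cos_sum / nev else 1
  grid$flipped[iy, ix] <- grid$flipped[iy, ix] + wf
  grid$preserved[iy, ix] <- grid$preserved[iy, ix] + wp
  grid$nsum_flipped[iy, ix] <- grid$nsum_flipped[iy, ix] + wf * nev
  grid$nsum_preserved[iy, ix] <- grid$nsum_preserved[iy, ix] + wp * nev
  grid$anglesum_flipped[iy, ix] <- grid$anglesum_flipped[iy, ix] + wf * amean
  grid$anglesum_preserved[iy, ix] <- grid$anglesum_preserved[iy, ix] + wp * amean
  grid$cossum_flipped[iy, ix] <- grid$cossum_flipped[iy, ix] + wf * cmean
  grid$cossum_preserved[iy, ix] <- grid$cossum_preserved[iy, ix] + wp * cmean
  if (wf > 0) grid$count_flipped[iy, ix] <- grid$count_flipped[iy, ix] + 1
  if (wp > 0) grid$count_preserved[iy, ix] <- grid$count_preserved[iy, ix] + 1
  grid
}

#' Run the Stokes-vector Monte Carlo simulation
#'
#' Transports `n_photons` circularly polarized packets through the
#' suspension with the compiled engine and returns co-registered
#' helicity-flipped/preserved backscattered images, per-pixel scattering
#' statistics, an exit-angle histogram, and a run manifest with the full
#' photon accounting.
#'
#' @param config A [simulation_config()].
#' @return An object of class `helicity_run` containing `pair` (a
#'   [helicity_image_pair()] with stats grids), `exit_hist`, `manifest`
#'   and the `config`.
#' @examples
#' \donttest{
#' opt <- optical_config(635, 1.04, 1.33, 1.59)
#' cfg <- simulation_config(medium_spec(50, opt), n_photons = 2e4, seed = 7)
#' run <- run_simulation(cfg)
#' run$manifest$w_detected
#' }
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  med <- config$medium; det <- config$detector; beam <- config$beam
  sol <- solve_mie(med$optics, config$angle_step_deg)
  th <- sol$theta_deg * pi / 180
  t0 <- proc.time()[["elapsed"]]
  res <- .polmc_run(th, sol$m12 / sol$m11, sol$m33 / sol$m11,
                    sol$m34 / sol$m11, theta_cdf_table(sol),
                    mu_s = med$mu_s_cm / 10,
                    depth = med$depth_cm * 10,
                    half = med$lateral_cm * 10 / 2,
                    beam_sigma = beam$sigma_mm,
                    inc_V = sign(beam$incident[["V"]]),
                    n_pixels = det$n_pixels, pitch = det$pitch_mm,
                    n_photons = config$n_photons,
                    max_events = config$max_events,
                    seed = config$seed %% 2^31,
                    polarized_sampling = config$polarized_sampling,
                    highn_threshold = config$highn_threshold,
                    cone_cos = if (is.null(config$acceptance_cone_deg)) 0
                               else cos(config$acceptance_cone_deg * pi / 180))
  elapsed <- proc.time()[["elapsed"]] - t0
  center_px <- (det$n_pixels + 1) / 2
  pair <- helicity_image_pair(res$flipped, res$preserved,
                              pixel_pitch_um = det$pitch_um,
                              beam_center = c(center_px, center_px),
                              stats = res[c(
                                "nsum_flipped", "nsum_preserved",
                                "anglesum_flipped", "anglesum_preserved",
                                "cossum_flipped", "cossum_preserved",
                                "count_flipped", "count_preserved",
                                "class_flipped", "class_preserved",
                                "class_nsum_flipped", "class_nsum_preserved",
                                "class_anglesum_flipped",
                                "class_anglesum_preserved",
                                "class_cossum_flipped",
                                "class_cossum_preserved")])
  trunc_frac <- res$w_truncated / config$n_photons
  manifest <- list(
    n_photons = config$n_photons, seed = config$seed,
    w_detected = res$w_detected, w_overflow = res$w_overflow,
    w_side = res$w_side, w_truncated = res$w_truncated,
    w_outside_cone = res$w_outside_cone,
    truncated_fraction = trunc_frac,
    truncation_warning = trunc_frac > 0.01,
    highn = as.list(res$highn),
    highn_threshold = config$highn_threshold,
    mie = list(Q = sol$efficiency_Q, g = sol$anisotropy_g,
               X = sol$size_parameter, M = sol$relative_index),
    elapsed_s = elapsed)
  if (manifest$truncation_warning) {
    warning(sprintf("event-cap truncation fraction %.2f%% exceeds 1%%",
                    100 * trunc_frac))
  }
  nab <- length(res$exit_hist_flipped)
  exit_hist <- data.frame(
    theta_deg = 90 + (seq_len(nab) - 0.5) * 90 / nab,
    flipped = res$exit_hist_flipped,
    preserved = res$exit_hist_preserved)
  structure(list(pair = pair, exit_hist = exit_hist,
                 manifest = manifest, config = config),
            class = "helicity_run")
}

#' @export
print.helicity_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<helicity_run> %g photons | detected %.1f%% ",
                     "side %.1f%% truncated %.2f%% | %.1f s\n"),
              m$n_photons, 100 * m$w_detected / m$n_photons,
              100 * m$w_side / m$n_photons,
              100 * m$truncated_fraction, m$elapsed_s))
  invisible(x)
}
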