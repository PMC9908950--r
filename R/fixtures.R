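#' Specification for a synthetic helicity image pair
#'
#' Describes a pair of radially symmetric analytic images emulating
#' backscattered helicity images: a central plateau of controllable peak
#' intensity, an exponential tail of controllable decay length per
#' channel, an optional additive noise floor and optional Poisson-like
#' shot noise. This gives closed-form control over I_in, I_out and R_out
#' for every analysis and metric operation without running the Monte
#' Carlo.
#'
#' @param peak_flipped,peak_preserved Channel peak intensities.
#' @param plateau_mm Radius of the flat central plateau (mm).
#' @param decay_flipped_mm,decay_preserved_mm Exponential decay lengths of
#'   the tails (mm).
#' @param noise_floor Constant additive background level.
#' @param shot_noise If `TRUE`, pixel values are Poisson-perturbed
#'   (variance = mean, Gaussian approximation).
#' @param pitch_um Pixel pitch (um).
#' @param n_pixels Pixels per side.
#' @return An object of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(peak_flipped = 1000,
                                 peak_preserved = 1000,
                                 plateau_mm = 1.5,
                                 decay_flipped_mm = 1.5,
                                 decay_preserved_mm = 2.0,
                                 noise_floor = 0,
                                 shot_noise = FALSE,
                                 pitch_um = 53, n_pixels = 400) {
  stopifnot(peak_flipped > 0, peak_preserved > 0, plateau_mm > 0,
            decay_flipped_mm > 0, decay_preserved_mm > 0,
            noise_floor >= 0, pitch_um > 0, n_pixels >= 16)
  structure(as.list(environment()), class = "synthetic_image_spec")
}

#' Synthetic profile in closed form
#'
#' The analytic radial law of the generator:
#' `v(r) = peak` for `r <= plateau`, `peak * exp(-(r - plateau)/decay)`
#' beyond, plus the noise floor. Used as the integration oracle in tests.
#'
#' @param spec A [synthetic_image_spec()].
#' @param r_mm Radii (mm).
#' @param channel `"flipped"` or `"preserved"`.
#' @return Intensity values.
#' @export
synthetic_profile <- function(spec, r_mm,
                              channel = c("flipped", "preserved")) {
  channel <- match.arg(channel)
  peak <- if (channel == "flipped") spec$peak_flipped else spec$peak_preserved
  decay <- if (channel == "flipped") spec$decay_flipped_mm
           else spec$decay_preserved_mm
  peak * exp(-pmax(r_mm - spec$plateau_mm, 0) / decay) + spec$noise_floor
}

#' Generate a synthetic helicity image pair
#'
#' @param spec A [synthetic_image_spec()].
#' @param seed Optional seed for the shot noise (ignored when
#'   `shot_noise = FALSE`, in which case the pair is deterministic).
#' @return A [helicity_image_pair()] centered on the grid.
#' @export
generate_synthetic_pair <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  np <- spec$n_pixels
  ctr <- (np + 1) / 2
  r_mm <- sqrt((col(matrix(0, np, np)) - ctr)^2 +
                 (row(matrix(0, np, np)) - ctr)^2) * spec$pitch_um / 1000
  mk <- function(channel) {
    v <- synthetic_profile(spec, r_mm, channel)
    if (spec$shot_noise) {
      if (!is.null(seed)) set.seed(seed + (channel == "preserved"))
      v <- pmax(0, v + stats::rnorm(length(v), 0, sqrt(pmax(v, 0))))
      v <- matrix(v, np, np)
    }
    v
  }
  helicity_image_pair(mk("flipped"), mk("preserved"),
                      pixel_pitch_um = spec$pitch_um,
                      beam_center = c(ctr, ctr))
}
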