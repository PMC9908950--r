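#!/usr/bin/env Rscript
# Regenerates the package's standard figures from fresh computation:
#   fig_polar_docp.pdf     signed single-scattering intensity, polar, 3 sizes
#   fig_profiles_mu*.pdf   flipped/preserved radial profiles
#   fig_events_mu*.pdf     mean scattering-event count vs radius
#   fig_angles_mu*.pdf     mean scattering angle vs radius
#   fig_response_surface.pdf  normalized SHRM over (diameter, mu_s)
#
# Usage: Rscript scripts/figures.R [--out-dir scratch/figures]
#                                  [--photons 100000] [--seed 1]

suppressPackageStartupMessages({
  library(heliscat)
  library(ggplot2)
})

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
out_dir <- get_opt("--out-dir", "scratch/figures")
n_photons <- as.numeric(get_opt("--photons", "1e5"))
seed <- as.integer(get_opt("--seed", "1"))
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
save_fig <- function(p, name, w = 7, h = 5) {
  ggsave(file.path(out_dir, name), p, width = w, height = h)
}

diameters <- c(0.20, 0.58, 1.04)
optics <- lapply(diameters, function(d) optical_config(635, d, 1.33, 1.59))
names(optics) <- diameters

## polar maps of signed single-scattering intensity
q_ref <- solve_mie(optics[["1.04"]])$efficiency_Q
map <- polar_docp_map(optics, normalization_Q = q_ref, angle_step_deg = 0.25)
save_fig(plot_polar_docp(map), "fig_polar_docp.pdf", w = 10, h = 4)

## simulations for the reference spheres at low and high turbidity
for (mu in c(50, 200)) {
  run <- suppressWarnings(run_simulation(simulation_config(
    medium_spec(mu, optics[["1.04"]]), n_photons = n_photons, seed = seed)))
  pair <- run$pair
  pf <- radial_profile(pair$flipped, pair$beam_center, pair$pixel_pitch_um)
  pp <- radial_profile(pair$preserved, pair$beam_center, pair$pixel_pitch_um)
  save_fig(plot_profiles(pf, pp) +
             ggtitle(sprintf("1.04 um, mu_s = %d cm^-1", mu)),
           sprintf("fig_profiles_mu%d.pdf", mu))
  save_fig(plot_statistics_profiles(
    event_count_profile(pair, "flipped"),
    event_count_profile(pair, "preserved"), r_max_mm = 10) +
      ggtitle(sprintf("mean N, mu_s = %d cm^-1", mu)),
    sprintf("fig_events_mu%d.pdf", mu))
  save_fig(plot_statistics_profiles(
    mean_angle_profile(pair, "flipped"),
    mean_angle_profile(pair, "preserved"),
    ylab = "mean scattering angle (deg)", r_max_mm = 10) +
      ggtitle(sprintf("mean angle, mu_s = %d cm^-1", mu)),
    sprintf("fig_angles_mu%d.pdf", mu))
}

## SHRM response surface over the 3 x 4 sample design
grid <- expand.grid(diameter_um = diameters,
                    mu_s_cm = c(50, 100, 150, 200))
grid$shrm <- mapply(function(d, mu) {
  run <- suppressWarnings(run_simulation(simulation_config(
    medium_spec(mu, optics[[as.character(d)]]),
    n_photons = n_photons / 2, seed = seed)))
  compute_shrm(run$pair, zero_frac = 0.02)$shrm
}, grid$diameter_um, grid$mu_s_cm)
surf <- build_response_surface(normalize_set(grid))
save_fig(plot_response_surface(surf), "fig_response_surface.pdf")

cat("figures written to", out_dir, "\n")
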