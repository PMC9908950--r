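# Shared Monte Carlo runs, computed once per test session.  Sizes are
# chosen so that the stochastic acceptance statistics (convergence radii,
# in-region g-factors) have seed-to-seed scatter well inside their
# tolerance bands while the whole suite stays fast.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, maker) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- maker()
  .run_cache[[key]]
}

reference_run <- function(mu_s_cm, diameter_um = 1.04) {
  n <- switch(as.character(mu_s_cm),
              "50" = 3e5, "200" = 1.2e5, 6e4)
  key <- sprintf("d%g_mu%g", diameter_um, mu_s_cm)
  cached_run(key, function() {
    suppressWarnings(run_simulation(simulation_config(
      medium_spec(mu_s_cm, paper_optics(diameter_um)),
      n_photons = n, seed = 1904)))
  })
}

run_profiles <- function(run) {
  p <- run$pair
  list(flipped = radial_profile(p$flipped, p$beam_center, p$pixel_pitch_um),
       preserved = radial_profile(p$preserved, p$beam_center,
                                  p$pixel_pitch_um))
}

# radius enclosing a given fraction of total detected image intensity
enclosing_radius <- function(run, frac = 0.9) {
  p <- run$pair
  tot <- p$flipped + p$preserved
  r <- sqrt((col(tot) - p$beam_center[1])^2 +
              (row(tot) - p$beam_center[2])^2) * p$pixel_pitch_um / 1000
  o <- order(r)
  cum <- cumsum(tot[o]) / sum(tot)
  r[o][which(cum >= frac)[1]]
}
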