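test_that("free paths are exponential with mean 1/mu_s", {
  set.seed(11)
  expect_error(sample_free_path(-1), "mu_s_cm")
  s50 <- sample_free_path(50, 2e5)
  expect_equal(mean(s50), 0.2, tolerance = 0.01)
  s200 <- sample_free_path(200, 2e5)
  expect_equal(mean(s200), 0.05, tolerance = 0.01)
  expect_equal(mean(s50) / mean(s200), 4, tolerance = 0.03)
})

test_that("launched packets reproduce the beam and incident state", {
  set.seed(12)
  beam <- beam_spec(fwhm_mm = 3)
  pk <- replicate(5000, launch_photon(beam), simplify = FALSE)
  xs <- vapply(pk, function(p) p$position[1], numeric(1))
  ys <- vapply(pk, function(p) p$position[2], numeric(1))
  fwhm_hat <- 2 * sqrt(2 * log(2)) * sqrt((stats::var(xs) + stats::var(ys)) / 2)
  expect_equal(fwhm_hat, 3, tolerance = 0.05)
  expect_true(all(vapply(pk, function(p) {
    signed_docp(p$stokes, beam$incident) == 1
  }, logical(1))))
  expect_equal(pk[[1]]$weight, 1)
  expect_equal(pk[[1]]$n_events, 0L)
})

test_that("sampled scattering angles follow the phase function", {
  sol <- solve_mie(paper_optics(), angle_step_deg = 0.2)
  set.seed(13)
  # unpolarized: empirical mean cosine equals the Mie anisotropy
  draws <- sample_scattering(sol, stokes(1), n = 1e5)
  expect_equal(mean(cos(draws$theta)), 0.92, tolerance = 0.01)
  # circular state: azimuth uniform
  circ <- sample_scattering(sol, stokes_circular("left"), n = 2e4)
  cs <- chisq.test(table(cut(circ$phi, seq(0, 2 * pi, length.out = 17))))
  expect_gt(cs$p.value, 0.001)
  # linear state: theta marginal unchanged (phi-average kills the M12 term)
  lin <- sample_scattering(sol, stokes(1, 0.9, 0, 0), n = 2e4)
  ks <- suppressWarnings(ks.test(lin$theta, draws$theta[1:2e4]))
  expect_gt(ks$p.value, 0.01)
})

test_that("applying a scattering event preserves physics invariants", {
  sol <- solve_mie(paper_optics(), angle_step_deg = 0.2)
  beam <- beam_spec()
  set.seed(14)
  pk <- launch_photon(beam)
  # forward scattering is the identity on direction and helicity
  fwd <- apply_scattering(pk, sol, 0, 1.3)
  expect_equal(fwd$direction, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fwd$stokes[["V"]], -1, tolerance = 1e-9)
  # exact backscatter flips the V sign
  back <- apply_scattering(pk, sol, pi, 0.4)
  expect_gt(back$stokes[["V"]], 0)
  expect_equal(back$direction, c(0, 0, -1), tolerance = 1e-12)
  # random sequences keep the state realizable and the frame orthonormal
  pk2 <- launch_photon(beam)
  for (i in 1:300) {
    draw <- sample_scattering(sol, pk2$stokes, 1)
    pk2 <- apply_scattering(pk2, sol, draw$theta, draw$phi)
    s <- pk2$stokes
    expect_true(s[["I"]] + 1e-9 >=
                  sqrt(s[["Q"]]^2 + s[["U"]]^2 + s[["V"]]^2))
  }
  expect_equal(sum(pk2$direction^2), 1, tolerance = 1e-9)
  expect_equal(sum(pk2$direction * pk2$frame_m), 0, tolerance = 1e-9)
  expect_equal(pk2$n_events, 300L)
})

test_that("detect_exit splits intensity into helicity channels", {
  grid <- detector_grid(detector_spec(n_pixels = 20, pitch_um = 500))
  beam <- beam_spec()
  set.seed(15)
  pk <- launch_photon(beam)
  pk$position <- c(0, 0, 0); pk$direction <- c(0, 0, -1)
  # pure preserved state deposits nothing in the flipped channel
  pk$stokes <- stokes(1, 0, 0, -1)
  g1 <- detect_exit(pk, grid)
  expect_equal(sum(g1$flipped), 0)
  expect_equal(sum(g1$preserved), 1)
  # fully depolarized packet splits evenly
  pk$stokes <- stokes(1, 0, 0, 0)
  g2 <- detect_exit(pk, grid)
  expect_equal(sum(g2$flipped), 0.5)
  # off-grid exit goes to the overflow tally
  pk$position <- c(100, 0, 0)
  g3 <- detect_exit(pk, g2)
  expect_equal(g3$overflow, 1)
  pk$direction <- c(0, 0, 1)
  expect_error(detect_exit(pk, g3), "entry face")
})

test_that("the engine conserves launched weight exactly and is reproducible", {
  opt <- paper_optics()
  cfg <- simulation_config(medium_spec(50, opt), n_photons = 5000, seed = 77)
  run1 <- run_simulation(cfg)
  m <- run1$manifest
  total <- m$w_detected + m$w_overflow + m$w_side + m$w_truncated +
    m$w_outside_cone
  expect_equal(total, 5000, tolerance = 1e-12)
  expect_equal(sum(run1$pair$flipped) + sum(run1$pair$preserved),
               m$w_detected, tolerance = 1e-12)
  run2 <- run_simulation(cfg)
  expect_identical(run1$pair$flipped, run2$pair$flipped)
  expect_identical(run1$pair$preserved, run2$pair$preserved)
  run3 <- run_simulation(simulation_config(medium_spec(50, opt),
                                           n_photons = 5000, seed = 78))
  expect_false(identical(run1$pair$flipped, run3$pair$flipped))
})

test_that("single-scatter transport reproduces the Mie signed-DOCP curve", {
  opt <- paper_optics()
  run <- suppressWarnings(run_simulation(simulation_config(
    medium_spec(50, opt), n_photons = 8e5, seed = 21, max_events = 1)))
  h <- run$exit_hist
  sol <- solve_mie(opt)
  cp_mc <- (h$preserved - h$flipped) / (h$preserved + h$flipped)
  cp_th <- stats::approx(sol$theta_deg, sol$m33 / sol$m11,
                         xout = h$theta_deg)$y
  sel <- h$flipped + h$preserved > 20
  dev <- sqrt(stats::weighted.mean((cp_mc[sel] - cp_th[sel])^2,
                                   (h$flipped + h$preserved)[sel]))
  expect_lt(dev, 0.05)
})

test_that("unpolarized-sampling mode cross-validates the polarized sampler", {
  opt <- paper_optics()
  med <- medium_spec(50, opt)
  rp <- run_simulation(simulation_config(med, n_photons = 4e4, seed = 31,
                                         polarized_sampling = TRUE))
  ru <- run_simulation(simulation_config(med, n_photons = 4e4, seed = 32,
                                         polarized_sampling = FALSE))
  expect_equal(ru$manifest$w_detected / rp$manifest$w_detected, 1,
               tolerance = 0.02)
  expect_equal(sum(ru$pair$flipped) / sum(rp$pair$flipped), 1,
               tolerance = 0.05)
})

test_that("tighter turbidity confines the backscattered image", {
  r50 <- reference_run(50)
  r200 <- reference_run(200)
  expect_lt(enclosing_radius(r200, 0.9), enclosing_radius(r50, 0.9))
})

test_that("the preserved image is wider than the flipped one at low turbidity", {
  pr <- run_profiles(reference_run(50))
  # radius where each (peak-normalized) profile falls to 20% of its peak
  r20 <- function(prof) {
    v <- prof$value / max(prof$value, na.rm = TRUE)
    prof$radius_mm[which(v < 0.2 & prof$radius_mm > 1)[1]]
  }
  expect_gt(r20(pr$preserved), r20(pr$flipped))
})
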