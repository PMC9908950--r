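make_profile <- function(radius_mm, value, pitch_um = 53,
                         n_pixels = rep(100, length(value))) {
  structure(data.frame(radius_mm = radius_mm, value = value,
                       n_pixels = n_pixels),
            class = c("radial_profile", "data.frame"),
            pixel_pitch_um = pitch_um,
            central_plateau_radius_mm = 0)
}

test_that("image pair constructor validates geometry and intensities", {
  m <- matrix(1, 50, 50)
  expect_s3_class(helicity_image_pair(m, m, 53), "helicity_image_pair")
  expect_error(helicity_image_pair(m, matrix(1, 40, 50), 53), "shape")
  expect_error(helicity_image_pair(-m, m, 53), "non-negative")
  expect_error(helicity_image_pair(m, m, 0), "pixel_pitch")
  expect_error(helicity_image_pair(m, m, 53, beam_center = c(99, 1)),
               "inside")
})

test_that("illuminated region recovery on a synthetic beam", {
  np <- 201; pitch <- 53
  ctr <- (np + 1) / 2
  r_mm <- sqrt((col(matrix(0, np, np)) - ctr)^2 +
                 (row(matrix(0, np, np)) - ctr)^2) * pitch / 1000
  sigma <- 3 / (2 * sqrt(2 * log(2)))
  beam <- exp(-r_mm^2 / (2 * sigma^2))
  ir <- locate_illuminated_region(beam, pitch)
  expect_equal(ir$fwhm_mm, 3, tolerance = 0.02)
  expect_equal(ir$edge_radius_mm, ir$fwhm_mm / 2)
  expect_equal(ir$center, c(ctr, ctr), tolerance = 1e-6)
  # translation equivariance
  shifted <- beam * 0
  shifted[, 11:np] <- beam[, 1:(np - 10)]
  ir2 <- locate_illuminated_region(shifted, pitch)
  expect_equal(ir2$center[1] - ir$center[1], 10, tolerance = 0.05)
  # flat and two-peak images are rejected
  expect_error(locate_illuminated_region(matrix(1, 20, 20), 53), "no beam")
  two <- matrix(0, 60, 60)
  two[15, 15] <- 1; two[45, 45] <- 1
  expect_error(locate_illuminated_region(two, 53), "single dominant peak")
})

test_that("radial profile matches a brute-force per-pixel oracle", {
  np <- 121; pitch <- 100; ctr <- 61
  rpx <- sqrt((col(matrix(0, np, np)) - ctr)^2 +
                (row(matrix(0, np, np)) - ctr)^2)
  img <- exp(-rpx * pitch / 1000)
  for (cpx in c(0, 15)) {
    prof <- radial_profile(img, c(ctr, ctr), pitch, central_px = cpx)
    # naive oracle: same binning rule, independent loop
    bins <- round(rpx)
    if (cpx > 0) bins[bins <= cpx] <- 0
    for (k in unique(sort(bins))[1:30]) {
      row <- which.min(abs(prof$radius_mm - k * pitch / 1000))
      expect_equal(prof$value[row], mean(img[bins == k]),
                   tolerance = 1e-12, label = sprintf("bin %d cpx %d", k, cpx))
    }
  }
})

test_that("radial profile plateau, constancy and linearity", {
  np <- 101; ctr <- 51
  u <- matrix(4.2, np, np)
  prof <- radial_profile(u, c(ctr, ctr), 53)
  expect_true(all(abs(prof$value - 4.2) < 1e-12))
  # plateau covers radii out to ~0.8 mm at 53 um pitch with 15 px
  expect_equal(attr(prof, "central_plateau_radius_mm"), 15 * 0.053)
  expect_equal(length(unique(prof$value[prof$radius_mm <= 15 * 0.053])), 1)
  # linearity: profile of a sum is the sum of profiles
  set.seed(4)
  a <- matrix(runif(np^2), np, np); b <- matrix(runif(np^2), np, np)
  pa <- radial_profile(a, c(ctr, ctr), 53)
  pb <- radial_profile(b, c(ctr, ctr), 53)
  pab <- radial_profile(a + b, c(ctr, ctr), 53)
  expect_equal(pab$value, pa$value + pb$value, tolerance = 1e-12)
  expect_error(radial_profile(a, c(500, 50), 53), "inside")
})

test_that("profiles of a radially symmetric kernel match the analytic law", {
  spec <- synthetic_image_spec(peak_flipped = 100, peak_preserved = 100,
                               plateau_mm = 1, decay_flipped_mm = 2,
                               decay_preserved_mm = 2, n_pixels = 201)
  pair <- generate_synthetic_pair(spec)
  prof <- radial_profile(pair$flipped, pair$beam_center,
                         pair$pixel_pitch_um, central_px = 0)
  sel <- prof$radius_mm > 1.2 & prof$radius_mm < 4
  expected <- synthetic_profile(spec, prof$radius_mm[sel], "flipped")
  expect_equal(prof$value[sel], expected, tolerance = 0.02)
})

test_that("convergence distance detects where channels become identical", {
  r <- seq(0, 12, by = 0.053)
  base <- exp(-r / 3)
  same <- make_profile(r, base)
  expect_equal(convergence_distance(same, same), 0)
  expect_equal(convergence_distance(same, same, mode = "relative"), 0)
  # constructed divergence below 5 mm only
  stepped <- make_profile(r, base * (1 + 0.5 * (r < 5)))
  expect_equal(convergence_distance(stepped, same, smooth_bins = 1), 5,
               tolerance = 0.06)
  expect_equal(convergence_distance(stepped, same, mode = "relative"), 5,
               tolerance = 0.06)
  # exact scale invariance
  s10 <- make_profile(r, 10 * base * (1 + 0.5 * (r < 5)))
  b10 <- make_profile(r, 10 * base)
  expect_identical(convergence_distance(stepped, same, smooth_bins = 1),
                   convergence_distance(s10, b10, smooth_bins = 1))
  # profiles that never converge yield the sentinel
  res <- convergence_distance(make_profile(r, rep(1, length(r))),
                              make_profile(r, rep(0.5, length(r))))
  expect_true(is.na(res))
  expect_true(attr(res, "no_convergence"))
  expect_error(convergence_distance(same, make_profile(r[-1], base[-1])),
               "radius grid")
})

test_that("statistics profiles recover constant per-photon statistics", {
  np <- 101; ctr <- 51
  I <- matrix(runif(np^2) + 0.5, np, np)
  k <- 7; theta0 <- 60 * pi / 180
  stats <- list(nsum_flipped = k * I, anglesum_flipped = theta0 * I,
                cossum_flipped = cos(theta0) * I)
  pair <- helicity_image_pair(I, I, 53, stats = stats)
  nprof <- event_count_profile(pair, "flipped")
  expect_true(all(abs(nprof$value - k) < 1e-9))
  aprof <- mean_angle_profile(pair, "flipped")
  expect_true(all(abs(aprof$value - 60) < 1e-9))
  expect_true(all(abs(aprof$g - cos(theta0)) < 1e-9))
  expect_true(all(abs(aprof$g_of_mean_angle - cos(theta0)) < 1e-9))
  # measured pairs carry no statistics
  bare <- helicity_image_pair(I, I, 53)
  expect_error(event_count_profile(bare, "flipped"), "no photon statistics")
})

test_that("event counts grow with radius and g relaxes to the Mie value", {
  run <- reference_run(50)
  pair <- run$pair
  nf <- event_count_profile(pair, "flipped")
  inner <- mean(nf$value[nf$radius_mm <= 1], na.rm = TRUE)
  outer <- mean(nf$value[nf$radius_mm >= 6 & nf$radius_mm <= 8],
                na.rm = TRUE)
  expect_gt(outer, inner)
  gp <- mean_angle_profile(pair, "preserved")
  far <- gp$radius_mm >= 8 & gp$radius_mm <= 10
  expect_equal(mean(gp$g[far], na.rm = TRUE), 0.92, tolerance = 0.02)
})

test_that("the pathway-mixture g-factor reproduces the worked example", {
  comps <- data.frame(
    n_forward = c(19, 0), g_forward = c(0.92, NA),
    n_backward = c(1, 1), backward_angle_deg = c(180, 180),
    fraction = c(0.9, 0.1))
  expect_equal(round(pathway_g_mixture(comps), 2), 0.64)
  # single all-forward component returns its own g
  one <- data.frame(n_forward = 10, g_forward = 0.7, n_backward = 0,
                    backward_angle_deg = 180, fraction = 1)
  expect_equal(pathway_g_mixture(one), 0.7)
  # a singly backscattered population has g = cos(180) = -1
  single <- data.frame(n_forward = 0, g_forward = NA, n_backward = 1,
                       backward_angle_deg = 180, fraction = 1)
  expect_equal(pathway_g_mixture(single), -1)
  bad <- comps; bad$fraction <- c(0.6, 0.1)
  expect_error(pathway_g_mixture(bad), "sum to 1")
})
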