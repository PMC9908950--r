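unit_profile <- function(values, dr = 1, pitch_um = 1000 * dr) {
  structure(data.frame(radius_mm = seq(0, by = dr,
                                       length.out = length(values)),
                       value = values, n_pixels = rep(1, length(values))),
            class = c("radial_profile", "data.frame"),
            pixel_pitch_um = pitch_um, central_plateau_radius_mm = 0)
}

test_that("compute_triple reproduces constructed arithmetic", {
  # all intensity inside the 3 mm bound
  p1 <- unit_profile(c(1, 1, 1, 1, 0, 0, 0, 0))
  t1 <- compute_triple(p1)
  expect_equal(t1$I_in, 4)
  expect_equal(t1$R_out_mm, 1)   # one empty bin closes the region
  expect_equal(t1$I_out, 0)
  # 2 on [0,3], 1 on (3,6], 0 beyond, unit bins
  p2 <- unit_profile(c(2, 2, 2, 2, 1, 1, 1, 0, 0, 0))
  t2 <- compute_triple(p2)
  expect_equal(t2$I_in, 8)
  expect_equal(t2$I_out, 3)
  expect_equal(t2$I_in / t2$I_out, 8 / 3)
  expect_equal(t2$R_out_mm, 4)
  expect_false(t2$truncated_at_field_edge)
  # profile that never reaches the threshold is truncated with a flag
  p3 <- unit_profile(rep(1, 10))
  expect_true(compute_triple(p3)$truncated_at_field_edge)
  expect_error(compute_triple(unit_profile(c(1, 1))), "inner bound")
})

test_that("compute_triple equals a direct summation oracle", {
  set.seed(8)
  spec <- synthetic_image_spec(peak_flipped = 800, peak_preserved = 500,
                               plateau_mm = 1.5, decay_flipped_mm = 1.2,
                               decay_preserved_mm = 2.1)
  pair <- generate_synthetic_pair(spec)
  prof <- radial_profile(pair$flipped, pair$beam_center,
                         pair$pixel_pitch_um)
  tr <- compute_triple(prof, inner_mm = 3, zero_frac = 0.005)
  # oracle: explicit sums over the same profile bins
  r <- prof$radius_mm; v <- prof$value
  expect_equal(tr$I_in, sum(v[r <= 3]))
  thr <- 0.005 * max(v)
  outs <- which(r > 3)
  below <- v[outs] <= thr
  rz <- r[outs[which(rev(cumprod(rev(below))) > 0)[1]]]
  expect_equal(tr$R_out_mm, rz - 3)
  expect_equal(tr$I_out, sum(v[r > 3 & r <= rz]))
})

test_that("triples of the analytic generator match closed-form integration", {
  spec <- synthetic_image_spec(peak_flipped = 1000, peak_preserved = 1000,
                               plateau_mm = 1.5, decay_flipped_mm = 1.0,
                               decay_preserved_mm = 1.0)
  pair <- generate_synthetic_pair(spec)
  prof <- radial_profile(pair$flipped, pair$beam_center,
                         pair$pixel_pitch_um, central_px = 0)
  tr <- compute_triple(prof, zero_frac = 0.005)
  dr <- pair$pixel_pitch_um / 1000
  rr <- prof$radius_mm
  expect_equal(tr$I_in, sum(synthetic_profile(spec, rr[rr <= 3], "flipped")),
               tolerance = 0.01)
  # analytic zero crossing: peak * exp(-(r - plateau)/decay) = 0.005 peak
  r_zero <- 1.5 + 1.0 * log(1 / 0.005)
  expect_equal(tr$R_out_mm, r_zero - 3, tolerance = 0.05)
})

test_that("SHRM follows the composite-product arithmetic exactly", {
  t1 <- structure(list(I_in = 2, I_out = 1, R_out_mm = 3,
                       truncated_at_field_edge = FALSE),
                  class = "helicity_triple")
  res <- shrm(t1, t1)
  expect_equal(res$shrm, 36)
  expect_equal(res$ratio_flipped, 2)
  expect_equal(res$shrm,
               res$ratio_flipped * res$flipped$R_out_mm *
                 res$ratio_preserved * res$preserved$R_out_mm)
  # scaling intensities leaves the metric unchanged
  t10 <- structure(list(I_in = 20, I_out = 10, R_out_mm = 3,
                        truncated_at_field_edge = FALSE),
                   class = "helicity_triple")
  expect_equal(shrm(t10, t10)$shrm, 36)
  t0 <- structure(list(I_in = 1, I_out = 0, R_out_mm = 0,
                       truncated_at_field_edge = FALSE),
                  class = "helicity_triple")
  expect_error(shrm(t0, t1), "I_out")
})

test_that("SHRM is invariant to uniform image rescaling", {
  spec <- synthetic_image_spec(peak_flipped = 300, peak_preserved = 700,
                               decay_flipped_mm = 1.1,
                               decay_preserved_mm = 1.9)
  pair <- generate_synthetic_pair(spec)
  scaled <- helicity_image_pair(17 * pair$flipped, 17 * pair$preserved,
                                pair$pixel_pitch_um, pair$beam_center)
  expect_equal(compute_shrm(pair)$shrm, compute_shrm(scaled)$shrm,
               tolerance = 1e-12)
})

test_that("normalization maps the reference sample to exactly 1", {
  df <- expand.grid(diameter_um = c(0.20, 0.58, 1.04),
                    mu_s_cm = c(50, 100, 150, 200))
  set.seed(9)
  df$shrm <- 5 + df$diameter_um * 10 + runif(nrow(df))
  out <- normalize_set(df)
  ref <- out$shrm_norm[out$diameter_um == 0.20 & out$mu_s_cm == 200]
  expect_identical(ref, 1)
  out2 <- normalize_set(transform(df, shrm = shrm * 3.7))
  expect_equal(out2$shrm_norm, out$shrm_norm, tolerance = 1e-12)
  expect_error(normalize_set(df[!(df$diameter_um == 0.20 &
                                    df$mu_s_cm == 200), ]), "reference")
})

test_that("the response surface interpolates its nodes bilinearly", {
  df <- expand.grid(diameter_um = c(0.20, 0.58, 1.04),
                    mu_s_cm = c(50, 100, 150, 200))
  df$shrm <- with(df, diameter_um * 2 + mu_s_cm / 100)
  surf <- build_response_surface(normalize_set(df))
  expect_equal(dim(surf$values), c(3, 4))
  # node identity
  for (i in seq_len(nrow(df))) {
    expect_equal(surface_query(surf, df$diameter_um[i], df$mu_s_cm[i]),
                 df$shrm[i] / df$shrm[df$diameter_um == 0.20 &
                                        df$mu_s_cm == 200],
                 tolerance = 1e-12)
  }
  # midpoint of two nodes is their mean
  mid <- surface_query(surf, 0.39, 50)
  v1 <- surface_query(surf, 0.20, 50); v2 <- surface_query(surf, 0.58, 50)
  expect_equal(mid, (v1 + v2) / 2, tolerance = 1e-12)
  expect_error(build_response_surface(normalize_set(df)[-2, ]),
               "missing cells")
})

test_that("surface inversion finds loci and flags ambiguity", {
  # a saddle-free monotone surface: unique locus
  df <- expand.grid(diameter_um = c(0.2, 0.6, 1.0),
                    mu_s_cm = c(50, 100, 150, 200))
  df$shrm <- with(df, diameter_um * 10)
  df$shrm_norm <- df$shrm / df$shrm[1]
  surf <- build_response_surface(df)
  res <- surface_query(surf, 0.6, 100)
  inv <- invert_surface(surf, res)
  expect_true(inv$in_range)
  expect_false(inv$ambiguous)
  expect_true(all(abs(inv$candidates$diameter_um - 0.6) < 0.05))
  # a folded surface: two disjoint loci at the same level
  df2 <- df
  df2$shrm_norm <- with(df2, abs(diameter_um - 0.6) + 1e-3 * mu_s_cm)
  surf2 <- build_response_surface(df2)
  inv2 <- invert_surface(surf2, 0.3)
  expect_true(inv2$ambiguous)
  expect_gt(length(unique(inv2$candidates$locus)), 1)
  # out-of-range value
  expect_false(invert_surface(surf, 99)$in_range)
})
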