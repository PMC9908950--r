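#' Co-registered helicity-flipped / helicity-preserved image pair
#'
#' @param flipped,preserved Non-negative numeric matrices of equal shape.
#' @param pixel_pitch_um Pixel pitch in micrometres.
#' @param beam_center Beam center in pixel coordinates `c(col, row)`;
#'   defaults to the grid center.
#' @param stats Optional list of per-helicity statistics grids (event-count
#'   sums, angle sums, photon counts) as produced by [run_simulation()].
#'   Measured image pairs carry no photon statistics.
#' @return An object of class `helicity_image_pair`.
#' @export
helicity_image_pair <- function(flipped, preserved, pixel_pitch_um,
                                beam_center = NULL, stats = NULL) {
  flipped <- as.matrix(flipped); preserved <- as.matrix(preserved)
  if (!identical(dim(flipped), dim(preserved))) {
    stop("flipped and preserved grids must have identical shape")
  }
  if (any(flipped < 0, na.rm = TRUE) || any(preserved < 0, na.rm = TRUE)) {
    stop("intensity grids must be non-negative")
  }
  if (!is.finite(pixel_pitch_um) || pixel_pitch_um <= 0) {
    stop("pixel_pitch_um must be > 0")
  }
  if (is.null(beam_center)) {
    beam_center <- (dim(flipped)[2:1] + 1) / 2
  }
  if (beam_center[1] < 1 || beam_center[1] > ncol(flipped) ||
      beam_center[2] < 1 || beam_center[2] > nrow(flipped)) {
    stop("beam_center must lie inside the grid")
  }
  structure(list(flipped = flipped, preserved = preserved,
                 pixel_pitch_um = pixel_pitch_um,
                 beam_center = beam_center, stats = stats),
            class = "helicity_image_pair")
}

#' @export
print.helicity_image_pair <- function(x, ...) {
  cat(sprintf("<helicity_image_pair> %dx%d px @ %.3g um | flip/pres totals %.4g / %.4g\n",
              nrow(x$flipped), ncol(x$flipped), x$pixel_pitch_um,
              sum(x$flipped), sum(x$preserved)))
  invisible(x)
}

# 4-connected component count of a logical mask (tiny BFS labeller).
n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  ncomp <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    lab[start] <- ncomp
    nr <- nrow(mask)
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L; cc <- (cur - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; c2 <- cc + d[2]
        if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= ncol(mask)) {
          j <- (c2 - 1L) * nr + rr
          if (mask[j] && lab[j] == 0L) { lab[j] <- ncomp; queue <- c(queue, j) }
        }
      }
    }
  }
  ncomp
}

#' Locate the illuminated region from a beam image
#'
#' Finds the beam center as the intensity centroid and the beam width as
#' the FWHM of the azimuthally averaged radial profile. The IR edge radius
#' is FWHM/2. The image must contain a single dominant peak (one
#' connected region above half maximum).
#'
#' @param beam_image 2-D non-negative intensity grid of the bare beam.
#' @param pixel_pitch_um Pixel pitch in micrometres.
#' @return A list with `center` (pixel `c(col, row)`), `fwhm_mm`,
#'   `edge_radius_mm`, of class `illuminated_region`.
#' @export
locate_illuminated_region <- function(beam_image, pixel_pitch_um) {
  img <- as.matrix(beam_image)
  rng <- range(img)
  if (!all(is.finite(rng)) || rng[2] <= rng[1] || rng[2] <= 0) {
    stop("no beam found: image is flat or empty")
  }
  if (n_components(img > rng[2] / 2) != 1) {
    stop("no beam found: image does not contain a single dominant peak")
  }
  tot <- sum(img)
  cols <- col(img); rows <- row(img)
  cx <- sum(cols * img) / tot
  cy <- sum(rows * img) / tot
  prof <- radial_profile(img, center = c(cx, cy),
                         pixel_pitch_um = pixel_pitch_um, central_px = 0)
  v <- prof$value; r <- prof$radius_mm
  half <- max(v) / 2
  below <- which(v < half & r > r[which.max(v)])
  if (!length(below)) stop("no beam found: profile never falls below half maximum")
  i <- below[1]
  # linear interpolation of the half-max crossing
  r_half <- r[i - 1] + (half - v[i - 1]) / (v[i] - v[i - 1]) * (r[i] - r[i - 1])
  structure(list(center = c(cx, cy), fwhm_mm = 2 * r_half,
                 edge_radius_mm = r_half),
            class = "illuminated_region")
}

#' Azimuthally averaged radial profile of an image
#'
#' Pixels are assigned to 1-pixel-wide annuli by the rounded distance of
#' their centers from `center`. All pixels within the central
#' `central_px`-radius disk are averaged together and that common value is
#' reported as a constant plateau over those radii (with a 53 um pitch and
#' the default 15 pixels this plateau extends to ~0.8 mm), which
#' suppresses the choppiness of the innermost annuli.
#'
#' @param image 2-D numeric grid.
#' @param center Center in pixel coordinates `c(col, row)`.
#' @param pixel_pitch_um Pixel pitch in micrometres.
#' @param central_px Radius (pixels) of the central averaging disk; 0
#'   disables the plateau.
#' @param weights Optional matrix of the same shape; when given, the
#'   profile is the weighted annulus mean `sum(image)/sum(weights)`
#'   (used for ratio statistics such as mean event counts).
#' @return An object of class `radial_profile`: data.frame with columns
#'   `radius_mm`, `value`, `n_pixels`, and attributes `pixel_pitch_um`,
#'   `central_plateau_radius_mm`.
#' @export
radial_profile <- function(image, center, pixel_pitch_um, central_px = 15,
                           weights = NULL) {
  img <- as.matrix(image)
  if (center[1] < 1 || center[1] > ncol(img) ||
      center[2] < 1 || center[2] > nrow(img)) {
    stop("center must lie inside the grid")
  }
  r_px <- sqrt((col(img) - center[1])^2 + (row(img) - center[2])^2)
  bin <- round(r_px)
  if (central_px > 0) bin[bin <= central_px] <- 0L
  f <- factor(bin, levels = sort(unique(as.vector(bin))))
  num <- tapply(img, f, sum)
  den <- if (is.null(weights)) tapply(rep(1, length(img)), f, sum)
         else tapply(as.matrix(weights), f, sum)
  val <- as.numeric(num) / as.numeric(den)
  val[!is.finite(val)] <- NA_real_
  k <- as.numeric(levels(f))
  pitch_mm <- pixel_pitch_um / 1000
  if (central_px > 0 && k[1] == 0) {
    # expand the plateau over every radius it covers
    kk <- c(0:central_px, k[k > central_px])
    vv <- c(rep(val[1], central_px + 1), val[-1])
    nn <- c(as.numeric(den)[1], rep(NA, central_px), as.numeric(den)[-1])
    k <- kk; val <- vv; den <- nn
  }
  out <- data.frame(radius_mm = k * pitch_mm, value = val,
                    n_pixels = as.numeric(den))
  # largest radius whose annulus lies fully inside the grid
  field_mm <- (min(center[1] - 1, ncol(img) - center[1],
                   center[2] - 1, nrow(img) - center[2]) - 0.5) * pitch_mm
  structure(out, class = c("radial_profile", "data.frame"),
            pixel_pitch_um = pixel_pitch_um,
            central_plateau_radius_mm = central_px * pitch_mm,
            field_radius_mm = max(field_mm, 0))
}

#' Radial convergence distance of two helicity profiles
#'
#' The smallest radius beyond which the flipped and preserved profiles are
#' indistinguishable at every larger radius. Convergence of the two
#' channels marks complete circular depolarization: helicity has been
#' randomized into equal flip/preserve odds. The statistic is invariant
#' under common intensity rescaling in both modes.
#'
#' Two notions of "indistinguishable" are offered. The default
#' (`mode = "peak"`) declares the curves converged where their absolute
#' difference stays below `tol` (1%) of the peak of the summed profile —
#' the level below which two curves drawn on a common peak-normalized
#' linear plot cannot be told apart, matching how convergence is read off
#' plotted profiles. `mode = "relative"` instead bounds the normalized
#' difference `|f - p| / (f + p)` by `tol` (default 5% in that mode) at
#' radii carrying non-negligible intensity; it is far more stringent in
#' the dim outer tail, where a tiny residual helicity imbalance persists
#' long after the curves are visually identical.
#'
#' @param flipped,preserved `radial_profile` objects on a common radius
#'   grid.
#' @param tol Convergence tolerance; interpreted per `mode`. Default 0.01
#'   for `"peak"`, 0.05 for `"relative"`.
#' @param mode `"peak"` or `"relative"` (see Description).
#' @param floor_frac Intensity floor as a fraction of the peak of
#'   `flipped + preserved`, below which radii are ignored in
#'   `"relative"` mode (guards against noise-floor false convergence).
#' @param smooth_bins Width (annuli) of the centered moving average
#'   applied to the difference curve in `"peak"` mode before
#'   thresholding; damps Monte Carlo shot noise in sparse outer annuli.
#'   1 disables smoothing.
#' @return Convergence radius in mm, or `NA` with attribute
#'   `no_convergence = TRUE` if the profiles never converge in the field.
#' @export
convergence_distance <- function(flipped, preserved, tol = NULL,
                                 mode = c("peak", "relative"),
                                 floor_frac = 0.001, smooth_bins = 5) {
  stopifnot(inherits(flipped, "radial_profile"),
            inherits(preserved, "radial_profile"))
  mode <- match.arg(mode)
  if (is.null(tol)) tol <- if (mode == "peak") 0.01 else 0.05
  if (!isTRUE(all.equal(flipped$radius_mm, preserved$radius_mm))) {
    stop("profiles must share the same radius grid")
  }
  f <- flipped$value; p <- preserved$value
  tot <- f + p
  # restrict the scan to annuli fully inside the detector field: partial
  # corner annuli carry a handful of pixels and pure shot noise
  fr <- attr(flipped, "field_radius_mm")
  if (!is.null(fr)) {
    inside <- flipped$radius_mm <= fr
    f <- f[inside]; p <- p[inside]; tot <- tot[inside]
    flipped <- flipped[inside, , drop = FALSE]
  }
  if (mode == "peak") {
    d <- abs(f - p) / max(tot, na.rm = TRUE)
    if (smooth_bins > 1) {
      k <- rep(1 / smooth_bins, smooth_bins)
      dd <- d; dd[!is.finite(dd)] <- 0
      wts <- as.numeric(is.finite(d))
      num <- stats::filter(dd, k, sides = 2)
      den <- stats::filter(wts, k, sides = 2)
      sm <- as.numeric(num) / as.numeric(den)
      d <- ifelse(is.finite(sm), sm, d)
    }
    keep <- is.finite(d)
    ok <- !keep | d < tol
  } else {
    keep <- is.finite(tot) & tot > floor_frac * max(tot, na.rm = TRUE)
    d <- abs(f - p) / tot
    ok <- !keep | (is.finite(d) & d < tol)
  }
  idx <- which(keep)
  if (!length(idx)) return(structure(NA_real_, no_convergence = TRUE))
  run_ok <- rev(cumprod(rev(ok))) > 0
  cand <- which(run_ok & keep)
  if (!length(cand)) return(structure(NA_real_, no_convergence = TRUE))
  first <- cand[1]
  if (first == idx[1] && all(ok[keep])) return(0)
  flipped$radius_mm[first]
}

# shared helper: per-annulus intensity-weighted mean of a per-photon
# statistic, under either channel bookkeeping
stats_profile <- function(pair, channel = c("flipped", "preserved"),
                          which_stat = c("events", "angle", "cos"),
                          central_px = 15,
                          weighting = c("intensity", "class")) {
  channel <- match.arg(channel); which_stat <- match.arg(which_stat)
  weighting <- match.arg(weighting)
  if (is.null(pair$stats)) {
    stop("image pair carries no photon statistics grids ",
         "(measured images cannot provide event counts)")
  }
  st <- pair$stats
  prefix <- if (weighting == "class") "class_" else ""
  num <- st[[paste0(prefix, switch(which_stat, events = "nsum_",
                                   angle = "anglesum_",
                                   cos = "cossum_"), channel)]]
  den <- if (weighting == "class") st[[paste0("class_", channel)]]
         else pair[[channel]]
  radial_profile(num, center = pair$beam_center,
                 pixel_pitch_um = pair$pixel_pitch_um,
                 central_px = central_px, weights = den)
}

#' Mean scattering-event-count profile
#'
#' Mean number of scattering events N of the photons in one helicity
#' channel, per annulus. Under `weighting = "intensity"` (the default)
#' each photon contributes to both channels in proportion to the
#' helicity-analyzed intensity it deposits there, which is how an
#' image-forming detector mixes sub-populations; under
#' `weighting = "class"` each photon is assigned wholly to the channel
#' matching the sign of its exit V.
#'
#' @param pair A [helicity_image_pair()] carrying simulation stats grids.
#' @param channel `"flipped"` or `"preserved"`.
#' @param central_px Central averaging-disk radius in pixels.
#' @param weighting `"intensity"` or `"class"` (see Details).
#' @return A `radial_profile` of mean N.
#' @export
event_count_profile <- function(pair, channel = c("flipped", "preserved"),
                                central_px = 15,
                                weighting = c("intensity", "class")) {
  stats_profile(pair, channel, "events", central_px, weighting)
}

#' Mean scattering-angle profile and its g-factor
#'
#' Per-annulus averages of the per-photon mean scattering angle and the
#' per-photon mean of cos(theta) for one helicity channel. The `g` column
#' is the channel's photon-path anisotropy — the weighted average over
#' photons of each photon's own mean event cosine — whose fully
#' depolarized limit is the Mie asymmetry parameter of the spheres
#' (0.92 for the 1.04 um reference configuration). `g_of_mean_angle`
#' (= cos of the mean angle) is also reported.
#'
#' @inheritParams event_count_profile
#' @return A `radial_profile` with columns `value` (mean angle, degrees),
#'   `g` and `g_of_mean_angle`.
#' @export
mean_angle_profile <- function(pair, channel = c("flipped", "preserved"),
                               central_px = 15,
                               weighting = c("intensity", "class")) {
  prof <- stats_profile(pair, channel, "angle", central_px, weighting)
  gprof <- stats_profile(pair, channel, "cos", central_px, weighting)
  prof$value <- prof$value * 180 / pi
  prof$g <- gprof$value
  prof$g_of_mean_angle <- cos(prof$value * pi / 180)
  prof
}

#' Aggregate photon statistics within a disk
#'
#' Pools the per-pixel statistics of both helicity channels over all
#' pixels within `radius_mm` of the beam center (e.g. the illuminated
#' region) and returns per-channel intensity, mean event count, mean
#' scattering angle and g = cos(mean angle).
#'
#' @param pair A [helicity_image_pair()] with stats grids.
#' @param radius_mm Disk radius in mm (default 1.5 mm = FWHM/2 of the 3 mm
#'   beam).
#' @param weighting `"intensity"` or `"class"` channel bookkeeping (see
#'   [event_count_profile()]).
#' @return A data.frame with one row per channel: channel intensity, mean
#'   event count, mean scattering angle (degrees) and the photon-path
#'   anisotropy g (average of per-photon mean event cosines).
#' @export
region_statistics <- function(pair, radius_mm = 1.5,
                              weighting = c("intensity", "class")) {
  if (is.null(pair$stats)) stop("image pair carries no photon statistics grids")
  weighting <- match.arg(weighting)
  prefix <- if (weighting == "class") "class_" else ""
  r_px <- sqrt((col(pair$flipped) - pair$beam_center[1])^2 +
                 (row(pair$flipped) - pair$beam_center[2])^2)
  inside <- r_px * pair$pixel_pitch_um / 1000 <= radius_mm
  one <- function(channel) {
    I <- if (weighting == "class") {
      sum(pair$stats[[paste0("class_", channel)]][inside])
    } else sum(pair[[channel]][inside])
    nsum <- sum(pair$stats[[paste0(prefix, "nsum_", channel)]][inside])
    asum <- sum(pair$stats[[paste0(prefix, "anglesum_", channel)]][inside])
    csum <- sum(pair$stats[[paste0(prefix, "cossum_", channel)]][inside])
    data.frame(channel = channel, intensity = I, mean_events = nsum / I,
               mean_angle_deg = asum / I * 180 / pi, g = csum / I)
  }
  rbind(one("flipped"), one("preserved"))
}

#' Pathway-mixture g-factor
#'
#' Illustrative decomposition of a photon population's g-factor into
#' pathway types: each component contributes the event-weighted mean of
#' cosines of its near-forward (`g_forward` per event) and backward
#' (`cos(backward_angle)` per event) scatterings, and components are
#' combined by their population fractions.
#'
#' @param components A data.frame (or list of lists) with columns
#'   `n_forward`, `g_forward`, `n_backward`, `backward_angle_deg`,
#'   `fraction`. Fractions must sum to 1.
#' @return The mixture g-factor.
#' @examples
#' pathway_g_mixture(data.frame(
#'   n_forward = c(19, 0), g_forward = c(0.92, NA),
#'   n_backward = c(1, 1), backward_angle_deg = c(180, 180),
#'   fraction = c(0.9, 0.1)))  # 0.64
#' @export
pathway_g_mixture <- function(components) {
  comp <- if (is.data.frame(components)) components
          else do.call(rbind, lapply(components, as.data.frame))
  if (abs(sum(comp$fraction) - 1) > 1e-8) {
    stop("component fractions must sum to 1")
  }
  g_comp <- mapply(function(nf, gf, nb, ang, frac) {
    if (nf + nb <= 0) stop("component must contain at least one event")
    fwd <- if (nf > 0) nf * gf else 0
    (fwd + nb * cos(ang * pi / 180)) / (nf + nb)
  }, comp$n_forward, comp$g_forward, comp$n_backward,
     comp$backward_angle_deg, comp$fraction)
  sum(comp$fraction * g_comp)
}
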