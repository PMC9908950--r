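#' In-region / out-of-region intensity triple of one helicity profile
#'
#' Summarizes a radial intensity profile by three quantities: `I_in`, the
#' sum of the profile values from R = 0 to the inner bound (3 mm); `R_out`,
#' the distance from the inner bound to the radius at which the intensity
#' falls to "zero" (a sustained drop to or below `zero_frac` of the profile
#' peak); and `I_out`, the profile sum over the `R_out` region. Sums are
#' over the 1-D annulus-mean profile values (a pixel-weighted variant is
#' available via `pixel_weighted = TRUE`).
#'
#' @param profile A [radial_profile()].
#' @param inner_mm Inner bound separating the in/out regions (mm).
#' @param zero_frac "Reaches zero" threshold as a fraction of the profile
#'   peak. The default 0.5% suits noiseless simulation profiles; for
#'   measured images pass a background-derived threshold via
#'   `zero_level`.
#' @param zero_level Optional absolute intensity threshold overriding
#'   `zero_frac` (e.g. mean + 2 SD of a background region).
#' @param pixel_weighted If `TRUE`, weight each annulus by its pixel count
#'   (area weighting) instead of summing plain annulus means.
#' @return An object of class `helicity_triple`: list with `I_in`,
#'   `I_out`, `R_out_mm` and logical `truncated_at_field_edge`.
#' @export
compute_triple <- function(profile, inner_mm = 3, zero_frac = 0.005,
                           zero_level = NULL, pixel_weighted = FALSE) {
  stopifnot(inherits(profile, "radial_profile"))
  r <- profile$radius_mm; v <- profile$value
  ok <- is.finite(v)
  r <- r[ok]; v <- v[ok]
  w <- if (pixel_weighted) profile$n_pixels[ok] else rep(1, length(v))
  w[!is.finite(w)] <- 1
  if (max(r) <= inner_mm) stop("profile does not extend beyond the inner bound")
  thr <- if (!is.null(zero_level)) zero_level else zero_frac * max(v)
  I_in <- sum((w * v)[r <= inner_mm])
  outer <- which(r > inner_mm)
  # first outer radius from which the intensity stays at/below threshold
  below <- v[outer] <= thr
  stays <- rev(cumprod(rev(below))) > 0
  truncated <- FALSE
  if (any(stays)) {
    r_zero <- r[outer[which(stays)[1]]]
  } else {
    r_zero <- max(r)
    truncated <- TRUE
  }
  R_out <- max(0, r_zero - inner_mm)
  sel <- r > inner_mm & r <= inner_mm + R_out
  I_out <- sum((w * v)[sel])
  structure(list(I_in = I_in, I_out = I_out, R_out_mm = R_out,
                 truncated_at_field_edge = truncated),
            class = "helicity_triple")
}

#' Spatial helicity response metric (SHRM)
#'
#' The composite product
#' `SHRM = (I_in/I_out * R_out)_flipped * (I_in/I_out * R_out)_preserved`.
#' The intensity ratios make the metric invariant to uniform rescaling of
#' the images (camera gain), while `R_out` carries the spatial spread.
#' SHRM rises with turbidity and falls with scatterer size, and jointly
#' the two factors separate the (diameter, mu_s) plane.
#'
#' @param flipped,preserved `helicity_triple` objects for the two
#'   channels.
#' @return An object of class `shrm_result` with the two triples, the two
#'   `I_in/I_out` ratios, and `shrm` (units mm^2).
#' @export
shrm <- function(flipped, preserved) {
  stopifnot(inherits(flipped, "helicity_triple"),
            inherits(preserved, "helicity_triple"))
  if (flipped$I_out <= 0 || preserved$I_out <= 0) {
    stop("degenerate profile: I_out is zero, SHRM undefined")
  }
  rf <- flipped$I_in / flipped$I_out
  rp <- preserved$I_in / preserved$I_out
  structure(list(flipped = flipped, preserved = preserved,
                 ratio_flipped = rf, ratio_preserved = rp,
                 shrm = rf * flipped$R_out_mm * rp * preserved$R_out_mm,
                 normalization_reference = "none"),
            class = "shrm_result")
}

#' @export
print.shrm_result <- function(x, ...) {
  cat(sprintf(paste0("<shrm_result> SHRM=%.4g mm^2 | flipped: Iin/Iout=%.3g ",
                     "Rout=%.3g mm | preserved: Iin/Iout=%.3g Rout=%.3g mm\n"),
              x$shrm, x$ratio_flipped, x$flipped$R_out_mm,
              x$ratio_preserved, x$preserved$R_out_mm))
  invisible(x)
}

#' SHRM straight from an image pair
#'
#' Convenience wrapper: radial profiles of both channels, triples, SHRM.
#'
#' @param pair A [helicity_image_pair()].
#' @param central_px Central averaging-disk radius (pixels).
#' @param ... Passed to [compute_triple()].
#' @return An `shrm_result`.
#' @export
compute_shrm <- function(pair, central_px = 15, ...) {
  stopifnot(inherits(pair, "helicity_image_pair"))
  pf <- radial_profile(pair$flipped, pair$beam_center, pair$pixel_pitch_um,
                       central_px = central_px)
  pp <- radial_profile(pair$preserved, pair$beam_center, pair$pixel_pitch_um,
                       central_px = central_px)
  shrm(compute_triple(pf, ...), compute_triple(pp, ...))
}

#' Normalize a set of SHRM results by a reference sample
#'
#' @param results A data.frame with columns `diameter_um`, `mu_s_cm`,
#'   `shrm` (one row per sample).
#' @param reference Named vector `c(diameter_um = ..., mu_s_cm = ...)`
#'   identifying the reference sample (default: smallest spheres at the
#'   highest standard turbidity, 0.20 um at 200 cm^-1).
#' @return The data.frame with an added `shrm_norm` column; the reference
#'   row has `shrm_norm` exactly 1.
#' @export
normalize_set <- function(results,
                          reference = c(diameter_um = 0.20, mu_s_cm = 200)) {
  stopifnot(is.data.frame(results),
            all(c("diameter_um", "mu_s_cm", "shrm") %in% names(results)))
  hit <- which(abs(results$diameter_um - reference[["diameter_um"]]) < 1e-9 &
                 abs(results$mu_s_cm - reference[["mu_s_cm"]]) < 1e-9)
  if (length(hit) != 1) stop("reference sample not found (or not unique)")
  results$shrm_norm <- results$shrm / results$shrm[hit]
  results
}

#' Build a (diameter, mu_s) response surface of normalized SHRM
#'
#' @param normalized A data.frame from [normalize_set()] covering a full
#'   rectangular grid of at least 2 diameters x 2 turbidities.
#' @return An object of class `response_surface` with sorted axes and the
#'   value matrix (rows = diameters, cols = turbidities). Queries between
#'   nodes use bilinear interpolation ([surface_query()]).
#' @export
build_response_surface <- function(normalized) {
  stopifnot(is.data.frame(normalized), "shrm_norm" %in% names(normalized))
  ds <- sort(unique(normalized$diameter_um))
  ms <- sort(unique(normalized$mu_s_cm))
  if (length(ds) < 2 || length(ms) < 2) {
    stop("need at least 2 diameters and 2 turbidities")
  }
  vals <- matrix(NA_real_, length(ds), length(ms),
                 dimnames = list(ds, ms))
  for (i in seq_len(nrow(normalized))) {
    vals[match(normalized$diameter_um[i], ds),
         match(normalized$mu_s_cm[i], ms)] <- normalized$shrm_norm[i]
  }
  if (anyNA(vals)) {
    miss <- which(is.na(vals), arr.ind = TRUE)
    stop("incomplete grid; missing cells: ",
         paste(sprintf("(d=%s, mu_s=%s)", ds[miss[, 1]], ms[miss[, 2]]),
               collapse = ", "))
  }
  structure(list(diameters_um = ds, mu_s_cm = ms, values = vals),
            class = "response_surface")
}

#' Query a response surface by bilinear interpolation
#'
#' @param surface A [build_response_surface()] result.
#' @param diameter_um,mu_s_cm Query coordinates (vectors of equal length
#'   or length 1), inside the grid hull.
#' @return Interpolated normalized SHRM values.
#' @export
surface_query <- function(surface, diameter_um, mu_s_cm) {
  stopifnot(inherits(surface, "response_surface"))
  ds <- surface$diameters_um; ms <- surface$mu_s_cm
  n <- max(length(diameter_um), length(mu_s_cm))
  diameter_um <- rep_len(diameter_um, n); mu_s_cm <- rep_len(mu_s_cm, n)
  vapply(seq_len(n), function(k) {
    d <- diameter_um[k]; m <- mu_s_cm[k]
    if (d < ds[1] || d > ds[length(ds)] || m < ms[1] || m > ms[length(ms)]) {
      return(NA_real_)
    }
    i <- max(1, min(length(ds) - 1, findInterval(d, ds)))
    j <- max(1, min(length(ms) - 1, findInterval(m, ms)))
    fd <- (d - ds[i]) / (ds[i + 1] - ds[i])
    fm <- (m - ms[j]) / (ms[j + 1] - ms[j])
    (1 - fd) * (1 - fm) * surface$values[i, j] +
      fd * (1 - fm) * surface$values[i + 1, j] +
      (1 - fd) * fm * surface$values[i, j + 1] +
      fd * fm * surface$values[i + 1, j + 1]
  }, numeric(1))
}

#' Invert the response surface for a measured SHRM value
#'
#' Finds the iso-SHRM loci on the bilinear surface: all (diameter, mu_s)
#' grid cells whose interpolated value crosses `shrm_value`, grouped into
#' connected components. Multiple disjoint loci flag the low-turbidity
#' ambiguity; an optional turbidity restriction (e.g. mu_s > 100 cm^-1,
#' typical of mammalian tissue) can disambiguate.
#'
#' @param surface A [build_response_surface()] result.
#' @param shrm_value Normalized SHRM value to invert.
#' @param mu_s_min Optional lower bound on mu_s (cm^-1) applied before the
#'   search.
#' @param n_grid Resolution of the fine evaluation grid per axis.
#' @return A list with `candidates` (data.frame `diameter_um`, `mu_s_cm`,
#'   `locus`), `ambiguous` (more than one disjoint locus), and
#'   `in_range`.
#' @export
invert_surface <- function(surface, shrm_value, mu_s_min = NULL,
                           n_grid = 121) {
  stopifnot(inherits(surface, "response_surface"))
  ds <- surface$diameters_um; ms <- surface$mu_s_cm
  m_lo <- if (is.null(mu_s_min)) ms[1] else max(ms[1], mu_s_min)
  if (m_lo >= ms[length(ms)]) stop("mu_s_min excludes the whole surface")
  dq <- seq(ds[1], ds[length(ds)], length.out = n_grid)
  mq <- seq(m_lo, ms[length(ms)], length.out = n_grid)
  vals <- outer(dq, mq, function(a, b) surface_query(surface, a, b))
  if (shrm_value < min(vals) || shrm_value > max(vals)) {
    return(list(candidates = data.frame(), ambiguous = FALSE,
                in_range = FALSE))
  }
  # cells whose corner values bracket the iso level
  lo <- vals[-n_grid, -n_grid]; r1 <- vals[-1, -n_grid]
  c1 <- vals[-n_grid, -1]; d1 <- vals[-1, -1]
  cmin <- pmin(lo, r1, c1, d1); cmax <- pmax(lo, r1, c1, d1)
  hit <- cmin <= shrm_value & cmax >= shrm_value
  if (!any(hit)) {
    return(list(candidates = data.frame(), ambiguous = FALSE,
                in_range = TRUE))
  }
  lab <- matrix(0L, nrow(hit), ncol(hit))
  ncomp <- 0L
  for (start in which(hit)) {
    if (lab[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start; lab[start] <- ncomp
    nr <- nrow(hit)
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      rr <- (cur - 1L) %% nr + 1L; cc <- (cur - 1L) %/% nr + 1L
      for (dd in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                      c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))) {
        r2 <- rr + dd[1]; c2 <- cc + dd[2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= ncol(hit)) {
          j <- (c2 - 1L) * nr + r2
          if (hit[j] && lab[j] == 0L) { lab[j] <- ncomp; queue <- c(queue, j) }
        }
      }
    }
  }
  idx <- which(hit, arr.ind = TRUE)
  cand <- data.frame(
    diameter_um = (dq[idx[, 1]] + dq[idx[, 1] + 1]) / 2,
    mu_s_cm = (mq[idx[, 2]] + mq[idx[, 2] + 1]) / 2,
    locus = lab[which(hit)])
  list(candidates = cand, ambiguous = ncomp > 1, in_range = TRUE)
}
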