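#' Read a flat TOML-style configuration file
#'
#' Minimal reader for the package's plain-text configs: `[section]`
#' headers, `key = value` pairs, `#` comments. Values are parsed as
#' numbers when possible, otherwise kept as (optionally quoted) strings.
#'
#' @param path Path to the config file.
#' @return A nested named list (one element per section; top-level keys
#'   before any section go into `$global`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list(); section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[section]][[key]] <- if (!is.na(num)) num else val
  }
  out
}

write_sidecar <- function(path, pair, grid_scales = NULL) {
  jsonlite::write_json(
    list(pixel_pitch_um = pair$pixel_pitch_um,
         beam_center = pair$beam_center,
         n_pixels = dim(pair$flipped),
         grid_scales = grid_scales),
    path, auto_unbox = TRUE, digits = NA)
}

write_csv_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(grid, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = ",")
  }), con)
}

#' Write a helicity image pair to disk
#'
#' Writes the flipped and preserved grids (and any statistics grids) as
#' 32-bit float grayscale TIFF or plain CSV, plus a JSON sidecar carrying
#' the pixel pitch, beam center and (for TIFF) the per-grid intensity
#' scales. TIFF storage is max-normalized 32-bit float (round trip exact
#' to single precision); CSV storage is full double precision (bit-exact
#' round trip).
#'
#' @param pair A [helicity_image_pair()].
#' @param dir Output directory (created if missing).
#' @param format `"tiff"` or `"csv"`.
#' @param prefix Filename prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_helicity_images <- function(pair, dir, format = c("tiff", "csv"),
                                  prefix = "helicity") {
  stopifnot(inherits(pair, "helicity_image_pair"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grids <- c(list(flipped = pair$flipped, preserved = pair$preserved),
             pair$stats)
  files <- character(0)
  scales <- list()
  for (nm in names(grids)) {
    f <- file.path(dir, sprintf("%s_%s.%s", prefix, nm,
                                if (format == "tiff") "tif" else "csv"))
    if (format == "tiff") {
      sc <- max(grids[[nm]], 1e-300)
      scales[[nm]] <- sc
      suppressWarnings(tiff::writeTIFF(grids[[nm]] / sc, f,
                                       bits.per.sample = 32L,
                                       reduce = FALSE))
    } else {
      write_csv_grid(grids[[nm]], f)
    }
    files <- c(files, f)
  }
  sc_path <- file.path(dir, paste0(prefix, "_sidecar.json"))
  write_sidecar(sc_path, pair,
                grid_scales = if (format == "tiff") scales else NULL)
  invisible(c(files, sc_path))
}

#' Read a helicity image pair from disk
#'
#' Counterpart of [write_helicity_images()]; restores the pair (and any
#' statistics grids found alongside). A missing sidecar falls back to
#' defaults (53 um pitch, grid-center beam) with a warning.
#'
#' @param dir Directory containing the files.
#' @param format `"tiff"` or `"csv"`.
#' @param prefix Filename prefix used at write time.
#' @return A [helicity_image_pair()].
#' @export
read_helicity_images <- function(dir, format = c("tiff", "csv"),
                                 prefix = "helicity") {
  format <- match.arg(format)
  ext <- if (format == "tiff") "tif" else "csv"
  sc_path <- file.path(dir, paste0(prefix, "_sidecar.json"))
  scales <- NULL
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    pitch <- sc$pixel_pitch_um; center <- sc$beam_center
    scales <- sc$grid_scales
  } else {
    warning("sidecar not found; assuming 53 um pitch and centered beam")
    pitch <- 53; center <- NULL
  }
  rd <- function(nm) {
    f <- file.path(dir, sprintf("%s_%s.%s", prefix, nm, ext))
    if (!file.exists(f)) return(NULL)
    if (format == "tiff") {
      m <- tiff::readTIFF(f, as.is = FALSE)
      sc <- if (!is.null(scales[[nm]])) scales[[nm]] else 1
      matrix(as.numeric(m) * sc, nrow(m), ncol(m))
    } else {
      m <- as.matrix(utils::read.table(f, sep = ",", header = FALSE,
                                       colClasses = "numeric"))
      dimnames(m) <- NULL
      m
    }
  }
  flipped <- rd("flipped"); preserved <- rd("preserved")
  if (is.null(flipped) || is.null(preserved)) {
    stop("missing flipped/preserved image files in ", dir)
  }
  stats_names <- c("nsum_flipped", "nsum_preserved", "anglesum_flipped",
                   "anglesum_preserved", "cossum_flipped", "cossum_preserved",
                   "count_flipped", "count_preserved",
                   "class_flipped", "class_preserved",
                   "class_nsum_flipped", "class_nsum_preserved",
                   "class_anglesum_flipped", "class_anglesum_preserved",
                   "class_cossum_flipped", "class_cossum_preserved")
  stats <- Filter(Negate(is.null), stats::setNames(
    lapply(stats_names, rd), stats_names))
  if (!length(stats)) stats <- NULL
  helicity_image_pair(flipped, preserved, pixel_pitch_um = pitch,
                      beam_center = center, stats = stats)
}

#' Write a radial profile as CSV
#'
#' @param profile A [radial_profile()].
#' @param path Output file (columns `radius_mm`, `value`, ...).
#' @return Invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Assemble a run manifest
#'
#' @param run A `helicity_run`.
#' @param files Optional character vector of output files to checksum.
#' @return A list suitable for JSON serialization (tool version, config
#'   echo, seed, photon accounting, checksums).
#' @export
run_manifest <- function(run, files = character(0)) {
  stopifnot(inherits(run, "helicity_run"))
  cfg <- run$config
  list(tool = "heliscat",
       version = as.character(utils::packageVersion("heliscat")),
       seed = cfg$seed,
       config = list(
         mu_s_cm = cfg$medium$mu_s_cm,
         depth_cm = cfg$medium$depth_cm,
         lateral_cm = cfg$medium$lateral_cm,
         diameter_um = cfg$medium$optics$diameter_um,
         wavelength_nm = cfg$medium$optics$wavelength_nm,
         n_medium = cfg$medium$optics$n_medium,
         n_sphere = cfg$medium$optics$n_sphere,
         fwhm_mm = cfg$beam$fwhm_mm,
         n_pixels = cfg$detector$n_pixels,
         pitch_um = cfg$detector$pitch_um,
         n_photons = cfg$n_photons,
         max_events = cfg$max_events),
       accounting = run$manifest[c("w_detected", "w_overflow", "w_side",
                                   "w_truncated", "truncated_fraction",
                                   "truncation_warning")],
       outputs = if (length(files)) {
         list(files = files, md5 = unname(tools::md5sum(files)))
       } else NULL)
}
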