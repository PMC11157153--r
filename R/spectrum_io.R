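#' Construct a raw profile spectrum
#'
#' Container for a profile mass spectrum on a true-mass axis (Da). Points are
#' sorted by mass; intensities must be finite and non-negative.
#'
#' @param masses Numeric vector of mass positions in Da.
#' @param intensities Numeric vector of intensities (same length).
#' @param normalization_factor Positive scalar; 1 when unnormalized. After
#'   [select_and_normalize()] it stores the original maximum so intensities
#'   can be rescaled back to raw units.
#' @param source_id Sample label.
#' @return An object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(masses, intensities, normalization_factor = 1,
                         source_id = "sample") {
  if (length(masses) != length(intensities)) {
    stop("masses and intensities must have equal length")
  }
  if (length(masses) == 0) stop("no data points")
  bad <- which(!is.finite(masses) | !is.finite(intensities))
  if (length(bad) > 0) {
    stop("non-finite value at index ", bad[1])
  }
  if (any(intensities < 0)) stop("negative intensity")
  ord <- order(masses)
  masses <- masses[ord]; intensities <- intensities[ord]
  if (anyDuplicated(masses)) {
    keep <- !duplicated(masses)
    masses <- masses[keep]; intensities <- intensities[keep]
  }
  structure(list(masses = masses, intensities = intensities,
                 normalization_factor = normalization_factor,
                 source_id = source_id),
            class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("Profile spectrum '%s': %d points, %.2f-%.2f Da, factor %.4g\n",
              x$source_id, length(x$masses), min(x$masses), max(x$masses),
              x$normalization_factor))
  invisible(x)
}

#' Load a profile spectrum
#'
#' Reads a profile mass spectrum with masses in Da. Two formats are
#' supported: mzML (read through mzR; the first spectrum in the file is
#' used) and a plain two-column TSV dialect (mass<TAB>intensity, `#`
#' comments allowed, no header required) convenient for fixtures.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"mzml"` or `"tsv"`.
#' @param source_id Sample label; defaults to the file name without extension.
#' @return A [raw_spectrum()] with `normalization_factor = 1`.
#' @export
load_spectrum <- function(path, format = c("auto", "mzml", "tsv"),
                          source_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read spectrum file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "tsv"
  }
  if (is.null(source_id)) {
    source_id <- sub("\\.[^.]*$", "", basename(path))
    source_id <- sub("\\.profile$", "", source_id)
  }
  if (format == "mzml") {
    handle <- mzR::openMSfile(path)
    on.exit(mzR::close(handle), add = TRUE)
    if (length(handle) < 1) stop("no data points in ", path)
    pts <- mzR::peaks(handle, 1)
    if (NROW(pts) == 0) stop("no data points in ", path)
    raw_spectrum(pts[, 1], pts[, 2], source_id = source_id)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (length(lines) == 0) stop("no data points in ", path)
    parts <- strsplit(lines, "[\t ]+")
    m <- suppressWarnings(vapply(parts, function(p) as.numeric(p[1]), 0))
    i <- suppressWarnings(vapply(parts, function(p) as.numeric(p[2]), 0))
    bad <- which(is.na(m) | is.na(i))
    if (length(bad) > 0) stop("non-numeric value at line ", bad[1])
    raw_spectrum(m, i, source_id = source_id)
  }
}

#' Write a spectrum as TSV
#'
#' @param spec A [raw_spectrum()].
#' @param path Output path.
#' @export
write_spectrum_tsv <- function(spec, path) {
  utils::write.table(
    data.frame(mass = spec$masses, intensity = spec$intensities),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict to a mass range and normalize
#'
#' Keeps only points with `lo <= mass <= hi` and divides intensities by the
#' window maximum so the highest point is exactly 1. The original maximum is
#' stored in `normalization_factor` so abundances can be rescaled to raw
#' units after the analysis.
#'
#' @param spec A [raw_spectrum()].
#' @param lo,hi Mass range bounds in Da (`lo < hi`).
#' @return A normalized [raw_spectrum()] restricted to the range.
#' @export
select_and_normalize <- function(spec, lo, hi) {
  stopifnot(lo < hi)
  keep <- spec$masses >= lo & spec$masses <= hi
  if (!any(keep) || max(spec$intensities[keep]) <= 0) {
    stop("no signal in mass range [", lo, ", ", hi, "]")
  }
  m <- spec$masses[keep]; i <- spec$intensities[keep]
  top <- max(i)
  raw_spectrum(m, i / top, normalization_factor = spec$normalization_factor * top,
               source_id = spec$source_id)
}

#' Centroid a profile spectrum
#'
#' Reduces the profile to its local maxima, retaining only the apex
#' (mass, intensity) of each peak. A point is a peak when it is strictly
#' greater than both neighbours; a flat plateau flanked by lower points
#' contributes a single centroid at its midpoint mass. Boundary points are
#' never peaks.
#'
#' @param spec A [raw_spectrum()] with at least 3 points.
#' @return A `centroid_peaks` object: `peak_masses`, `peak_intensities`,
#'   `noise_level` (0 until [estimate_noise_level()] is applied) and the
#'   parent's `normalization_factor` and `source_id`.
#' @export
centroid_profile <- function(spec) {
  n <- length(spec$masses)
  if (n < 3) stop("profile too short to centroid (need >= 3 points)")
  y <- spec$intensities
  pm <- numeric(0); pi_ <- numeric(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      # walk over a possible plateau starting at i
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) {
        pm <- c(pm, (spec$masses[i] + spec$masses[j]) / 2)
        pi_ <- c(pi_, y[i])
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  structure(list(peak_masses = pm, peak_intensities = pi_,
                 noise_level = 0,
                 normalization_factor = spec$normalization_factor,
                 source_id = spec$source_id),
            class = "centroid_peaks")
}

#' @export
print.centroid_peaks <- function(x, ...) {
  cat(sprintf("Centroided peaks '%s': %d peaks, noise level %.4g\n",
              x$source_id, length(x$peak_masses), x$noise_level))
  invisible(x)
}

#' Estimate the noise threshold of a spectrum
#'
#' The signal/noise threshold is one-half of the standard deviation of all
#' profile intensities within the analysis mass range. Peaks at or below
#' this level are treated as background downstream. The population flavour
#' (divide by n) is the default since the window's intensities are treated
#' as the complete population.
#'
#' @param spec A [raw_spectrum()] already restricted to the analysis range.
#' @param flavor `"population"` (default) or `"sample"` standard deviation.
#' @return Intensity threshold (>= 0).
#' @export
estimate_noise_level <- function(spec, flavor = c("population", "sample")) {
  flavor <- match.arg(flavor)
  y <- spec$intensities
  if (length(y) < 2) stop("cannot estimate dispersion from a single point")
  s2 <- stats::var(y)
  if (flavor == "population") s2 <- s2 * (length(y) - 1) / length(y)
  0.5 * sqrt(s2)
}

#' Attach a noise level to a centroided peak list
#'
#' @param peaks A `centroid_peaks` object.
#' @param noise_level Intensity threshold.
#' @return The peak list with `noise_level` set.
#' @export
set_noise_level <- function(peaks, noise_level) {
  stopifnot(noise_level >= 0)
  peaks$noise_level <- noise_level
  peaks
}
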