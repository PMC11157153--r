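#' Detection configuration
#'
#' Settings of the sliding-window Gaussian detector. The defaults follow the
#' recommended practice: the window spans the upper third of the reference
#' envelope (floored at 6 Da so at least five 1 Da-spaced isotopologue peaks
#' fit), the step is 1 Da, and two accepted envelope means must be at least
#' two-thirds of a window apart.
#'
#' @param window_size Sliding-window width in Da (> 5).
#' @param step_size Window advance per step in Da.
#' @param min_peak_distance Minimum distance between accepted means in Da;
#'   defaults to two-thirds of the window size.
#' @param pvalue_threshold Significance level; window fits with a chi-square
#'   goodness-of-fit p-value below it are discarded.
#' @param noise_level Intensity threshold separating signal from background.
#' @param min_signal_peaks Minimum number of signal peaks required in a
#'   window for a fit (the chi-square test needs at least 5 points).
#' @param count_scale Ion-count scale of the normalized spectrum: the
#'   approximate number of ions behind the tallest peak. The chi-square
#'   statistic is computed on estimated counts (`count_scale *` normalized
#'   intensity), which gives the goodness-of-fit filter real power: without
#'   it the statistic shrinks with the intensity unit and the p-value is
#'   always ~1. Set to `NULL` for the scale-free statistic.
#' @param refine Jointly refit the accepted means and amplitudes as a sum of
#'   constant-sigma Gaussians after overlap resolution (default `TRUE`).
#'   Single-window fits are biased toward a neighbouring envelope whose
#'   flank leaks into the window; the joint refit removes that
#'   contamination. Components whose refined amplitude drops to the noise
#'   floor are discarded. No new components are introduced, so species
#'   below the resolvable separation remain merged.
#' @return A `detection_config` list.
#' @export
detection_config <- function(window_size = NULL, step_size = 1,
                             min_peak_distance = NULL,
                             pvalue_threshold = 0.05,
                             noise_level = 0,
                             min_signal_peaks = 5,
                             count_scale = 1000,
                             refine = TRUE) {
  if (is.null(window_size)) stop("window_size is required (see default_detection_config)")
  if (window_size <= 5) stop("window_size must exceed 5 Da")
  if (is.null(min_peak_distance)) min_peak_distance <- 2 / 3 * window_size
  if (min_peak_distance < 2 / 3 * window_size) {
    stop("min_peak_distance must be at least two-thirds of the window size")
  }
  stopifnot(step_size > 0, pvalue_threshold > 0, pvalue_threshold < 1,
            noise_level >= 0, min_signal_peaks >= 5)
  structure(list(window_size = window_size, step_size = step_size,
                 min_peak_distance = min_peak_distance,
                 pvalue_threshold = pvalue_threshold,
                 noise_level = noise_level,
                 min_signal_peaks = min_signal_peaks,
                 count_scale = count_scale,
                 refine = isTRUE(refine)),
            class = "detection_config")
}

#' Default detection configuration for a protein
#'
#' Derives the window size from the reference envelope: the width of the
#' peaks with abundance at least 2/3 of the apex, floored at 6 Da.
#'
#' @param ref A [protein_reference()].
#' @param noise_level Intensity threshold (see [estimate_noise_level()]).
#' @param ... Overrides passed to [detection_config()].
#' @return A `detection_config`.
#' @export
default_detection_config <- function(ref, noise_level = 0, ...) {
  w <- max(upper_envelope_width(ref), 6 + 1e-9)
  args <- list(...)
  args$window_size <- if (is.null(args$window_size)) w else args$window_size
  args$noise_level <- noise_level
  do.call(detection_config, args)
}

# Optimal amplitude for a fixed mean/sigma (linear least squares, >= 0).
.amp_for_mean <- function(mu, x, y, sigma) {
  w <- exp(-(x - mu)^2 / (2 * sigma^2))
  a <- sum(w * y) / sum(w * w)
  max(a, 0)
}

.sse_for_mean <- function(mu, x, y, sigma) {
  a <- .amp_for_mean(mu, x, y, sigma)
  sum((y - a * exp(-(x - mu)^2 / (2 * sigma^2)))^2)
}

#' Fit a constant-width Gaussian inside one window
#'
#' Two-parameter least-squares fit (mean, amplitude) of a Gaussian with the
#' protein's fixed sigma to the signal peaks inside the window
#' `[window_start, window_start + window_size]`. Only peaks strictly above
#' the noise level enter the fit; fewer than `min_signal_peaks` of them
#' means no fit is attempted. The mean is constrained to the window. The fit
#' profiles out the amplitude (closed form for a fixed mean) and minimizes
#' over the mean by a coarse grid followed by golden-section refinement,
#' which is deterministic and robust to local minima.
#'
#' @param peaks A `centroid_peaks` list.
#' @param window_start Window lower edge in Da.
#' @param config A [detection_config()].
#' @param sigma Constant Gaussian width from the protein reference.
#' @return A `gaussian_fit` (fields `mean`, `amplitude`, `sigma`,
#'   `chi_square`, `pvalue`, `window_start`, `n_peaks`) or `NULL`.
#' @export
fit_window_gaussian <- function(peaks, window_start, config, sigma) {
  hi <- window_start + config$window_size
  sel <- peaks$peak_masses >= window_start & peaks$peak_masses <= hi &
    peaks$peak_intensities > config$noise_level
  if (sum(sel) < config$min_signal_peaks) return(NULL)
  x <- peaks$peak_masses[sel]; y <- peaks$peak_intensities[sel]
  # coarse deterministic grid over candidate means, then local refinement
  grid <- seq(window_start, hi, by = 0.25)
  sse <- vapply(grid, .sse_for_mean, 0, x = x, y = y, sigma = sigma)
  k <- which.min(sse)
  lo_b <- grid[max(1, k - 1)]; hi_b <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(.sse_for_mean, c(lo_b, hi_b), x = x, y = y,
                         sigma = sigma, tol = 1e-8)
  mu <- opt$minimum
  # a mean pinned to the window boundary means the optimum lies outside the
  # window (typical for windows covering only an envelope flank); the same
  # envelope is captured by a better-positioned window, so drop the candidate
  if (mu - window_start < 0.1 || hi - mu < 0.1) return(NULL)
  a <- .amp_for_mean(mu, x, y, sigma)
  expected <- a * exp(-(x - mu)^2 / (2 * sigma^2))
  gof <- tryCatch(
    chi_square_goodness(y, expected, count_scale = config$count_scale),
    error = function(e) NULL)
  if (is.null(gof)) return(NULL)
  structure(list(mean = mu, amplitude = a, sigma = sigma,
                 chi_square = gof$statistic, pvalue = gof$pvalue,
                 window_start = window_start, n_peaks = length(x)),
            class = "gaussian_fit")
}

#' Chi-square goodness of fit
#'
#' Pearson statistic `sum((obs - exp)^2 / exp)` comparing observed peak
#' intensities with the fitted Gaussian values, with the upper-tail p-value
#' at `n - npar - 1` degrees of freedom (two fitted parameters by default).
#' Under the null the fitted model describes the data, so a high p-value
#' reflects a good fit. Points with an expected value of zero are excluded
#' with a warning.
#'
#' @param observed,expected Numeric vectors of equal length (>= 5 usable
#'   points; expected > 0).
#' @param npar Number of fitted parameters absorbed into the degrees of
#'   freedom (default 2: mean and amplitude).
#' @param count_scale Optional ion-count scale: intensities are multiplied
#'   by it before forming the statistic, making the test sensitive at the
#'   level of counting statistics. `NULL` uses the intensities as given.
#' @return List with `statistic`, `pvalue` and `df`.
#' @export
chi_square_goodness <- function(observed, expected, npar = 2,
                                count_scale = NULL) {
  stopifnot(length(observed) == length(expected))
  usable <- expected > 0
  if (any(!usable)) {
    warning(sum(!usable), " point(s) with zero expected value excluded")
    observed <- observed[usable]; expected <- expected[usable]
  }
  n <- length(observed)
  if (n < 5) stop("fewer than 5 usable points for the chi-square test")
  if (!is.null(count_scale)) {
    observed <- observed * count_scale
    expected <- expected * count_scale
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- max(n - npar - 1, 1)
  list(statistic = stat,
       pvalue = stats::pchisq(stat, df = df, lower.tail = FALSE),
       df = df)
}

#' Scan a spectrum for envelope fits
#'
#' Slides a fixed-size window across the centroided spectrum (step
#' `step_size`, default 1 Da), fits a constant-sigma Gaussian in each
#' window, drops fits with a goodness-of-fit p-value below the significance
#' level, and resolves overlapping candidates so no two surviving means are
#' closer than the allowed overlap.
#'
#' @param peaks A `centroid_peaks` list with `noise_level` set (or supplied
#'   via `config`).
#' @param ref A [protein_reference()] providing sigma.
#' @param config A [detection_config()].
#' @return List of `gaussian_fit` objects sorted by mean (possibly empty).
#' @export
scan_spectrum <- function(peaks, ref, config) {
  if (length(peaks$peak_masses) == 0) return(list())
  if (config$noise_level == 0 && peaks$noise_level > 0) {
    config$noise_level <- peaks$noise_level
  }
  lo <- min(peaks$peak_masses); hi <- max(peaks$peak_masses)
  starts <- seq(lo, max(lo, hi - config$window_size), by = config$step_size)
  fits <- vector("list", length(starts))
  nfit <- 0L
  for (s in starts) {
    f <- fit_window_gaussian(peaks, s, config, ref$sigma)
    if (!is.null(f) && f$pvalue >= config$pvalue_threshold) {
      nfit <- nfit + 1L
      fits[[nfit]] <- f
    }
  }
  fits <- fits[seq_len(nfit)]
  fits <- resolve_overlaps(fits, config)
  if (config$refine) fits <- refine_fits(fits, peaks, config, ref$sigma)
  fits
}

#' Joint refinement of accepted envelope fits
#'
#' Refits all accepted components simultaneously as a sum of constant-sigma
#' Gaussians (one mean and one amplitude per component) against the signal
#' peaks, starting from the window-scan solution. Each mean may move at most
#' 1 Da: the refit is a local correction for neighbour-flank contamination,
#' and near the resolvable-separation limit the joint mean/amplitude
#' trade-off is ill-conditioned, so a wider trust region lets components
#' wander outward. Amplitudes stay non-negative, and components whose
#' refined amplitude does not exceed the noise level are dropped. The
#' per-window chi-square p-values are retained.
#'
#' @param fits Accepted `gaussian_fit` list (output of
#'   [resolve_overlaps()]).
#' @param peaks A `centroid_peaks` list.
#' @param config A [detection_config()].
#' @param sigma Constant Gaussian width.
#' @return Refined list of `gaussian_fit` objects sorted by mean.
#' @export
refine_fits <- function(fits, peaks, config, sigma) {
  k <- length(fits)
  if (k == 0) return(fits)
  mu0 <- vapply(fits, `[[`, 0, "mean")
  a0 <- vapply(fits, `[[`, 0, "amplitude")
  sel <- peaks$peak_intensities > config$noise_level &
    peaks$peak_masses >= min(mu0) - config$window_size &
    peaks$peak_masses <= max(mu0) + config$window_size
  x <- peaks$peak_masses[sel]; y <- peaks$peak_intensities[sel]
  if (length(x) < 2 * k) return(fits)
  obj <- function(par) {
    mu <- par[seq_len(k)]; a <- par[k + seq_len(k)]
    pred <- numeric(length(x))
    for (j in seq_len(k)) {
      pred <- pred + a[j] * exp(-(x - mu[j])^2 / (2 * sigma^2))
    }
    sum((y - pred)^2)
  }
  res <- stats::optim(c(mu0, a0), obj, method = "L-BFGS-B",
                      lower = c(mu0 - 1, rep(0, k)),
                      upper = c(mu0 + 1, rep(Inf, k)),
                      control = list(maxit = 500))
  mu <- res$par[seq_len(k)]; a <- res$par[k + seq_len(k)]
  keep <- which(a > config$noise_level)
  out <- lapply(keep, function(j) {
    f <- fits[[j]]
    f$mean <- mu[j]; f$amplitude <- a[j]
    f
  })
  out[order(vapply(out, `[[`, 0, "mean"))]
}

#' Resolve overlapping candidate fits
#'
#' Greedy best-first selection: candidates are ordered by decreasing
#' p-value (ties broken by larger amplitude, then lower mean) and accepted
#' only when their mean is at least `min_peak_distance` away from every
#' already accepted mean, so within each conflict the better-supported fit
#' survives. The result does not depend on the input order.
#'
#' @param fits List of `gaussian_fit` objects.
#' @param config A [detection_config()].
#' @return Accepted fits sorted by mean.
#' @export
resolve_overlaps <- function(fits, config) {
  if (length(fits) <= 1) return(fits)
  pv <- vapply(fits, `[[`, 0, "pvalue")
  amp <- vapply(fits, `[[`, 0, "amplitude")
  mu <- vapply(fits, `[[`, 0, "mean")
  ord <- order(-pv, -amp, mu)
  accepted_mu <- numeric(0)
  accepted <- integer(0)
  for (i in ord) {
    if (all(abs(mu[i] - accepted_mu) >= config$min_peak_distance)) {
      accepted <- c(accepted, i)
      accepted_mu <- c(accepted_mu, mu[i])
    }
  }
  fits[accepted[order(mu[accepted])]]
}

#' Convert accepted fits to quantified mass shifts
#'
#' The shift of an envelope is its fitted mean minus the protein's reference
#' mass. Its abundance is the area under the fitted Gaussian,
#' `amplitude * sigma * sqrt(2*pi)`, rescaled to raw units with the
#' spectrum's normalization factor; relative abundances are shares of the
#' total detected abundance in the sample.
#'
#' @param fits List of `gaussian_fit` objects.
#' @param ref A [protein_reference()].
#' @param normalization_factor Factor stored by [select_and_normalize()].
#' @param sample_id Sample label.
#' @return A data.frame (class `mass_shift_table`) with columns `sample_id`,
#'   `mean`, `shift`, `pvalue`, `abundance`, `relative_abundance`.
#' @export
quantify_and_shift <- function(fits, ref, normalization_factor = 1,
                               sample_id = "sample") {
  if (length(fits) == 0) {
    out <- data.frame(sample_id = character(0), mean = numeric(0),
                      shift = numeric(0), pvalue = numeric(0),
                      abundance = numeric(0), relative_abundance = numeric(0))
    class(out) <- c("mass_shift_table", "data.frame")
    return(out)
  }
  mu <- vapply(fits, `[[`, 0, "mean")
  amp <- vapply(fits, `[[`, 0, "amplitude")
  pv <- vapply(fits, `[[`, 0, "pvalue")
  sig <- vapply(fits, `[[`, 0, "sigma")
  area <- amp * sig * sqrt(2 * pi) * normalization_factor
  out <- data.frame(sample_id = sample_id, mean = mu,
                    shift = mu - ref$reference_mass, pvalue = pv,
                    abundance = area,
                    relative_abundance = area / sum(area))
  out <- out[order(out$mean), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mass_shift_table", "data.frame")
  out
}

#' Detect mass shifts in one profile spectrum
#'
#' Convenience wrapper running the full per-sample chain: range restriction
#' and normalization, centroiding, noise estimation, window scan, overlap
#' resolution and quantification.
#'
#' @param spec A [raw_spectrum()].
#' @param ref A [protein_reference()].
#' @param lo,hi Analysis mass range in Da.
#' @param config Optional [detection_config()]; defaults to
#'   [default_detection_config()] with the estimated noise level.
#' @return A `mass_shift_table` data.frame (see [quantify_and_shift()]).
#' @export
detect_mass_shifts <- function(spec, ref, lo, hi, config = NULL) {
  spec <- select_and_normalize(spec, lo, hi)
  noise <- estimate_noise_level(spec)
  peaks <- set_noise_level(centroid_profile(spec), noise)
  if (is.null(config)) {
    config <- default_detection_config(ref, noise_level = noise)
  } else if (config$noise_level == 0) {
    config$noise_level <- noise
  }
  fits <- scan_spectrum(peaks, ref, config)
  quantify_and_shift(fits, ref, spec$normalization_factor, spec$source_id)
}
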