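#' Modform (PTM-pattern) mixture specification
#'
#' Describes the ground truth of a simulated spectrum: a set of PTM count
#' vectors on a protein of interest with their relative abundances.
#'
#' @param counts Integer matrix, one row per species, columns named after
#'   the PTM types of `table` (a single species may be given as a vector).
#' @param abundances Positive relative abundances, one per species;
#'   normalized to sum to 1.
#' @param protein A [protein_reference()].
#' @param table A `ptm_table` supplying the PTM masses (defaults to
#'   [default_ptm_table()]).
#' @return A `modform_spec` with fields `counts`, `abundances`, `shifts`
#'   (the mass shift `m . p` of each species), `protein`, `table`.
#' @export
modform_spec <- function(counts, abundances, protein,
                         table = default_ptm_table()) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(counts)))
  stopifnot(!is.null(colnames(counts)),
            all(colnames(counts) %in% table$name),
            nrow(counts) == length(abundances), all(abundances > 0))
  abundances <- abundances / sum(abundances)
  masses <- table$mass[match(colnames(counts), table$name)]
  shifts <- as.numeric(counts %*% masses)
  if (anyDuplicated(round(shifts, 6))) {
    stop("species must have distinct mass shifts")
  }
  structure(list(counts = counts, abundances = abundances, shifts = shifts,
                 protein = protein, table = table),
            class = "modform_spec")
}

#' @export
print.modform_spec <- function(x, ...) {
  cat(sprintf("Modform spec: %d species, shifts %.1f-%.1f Da\n",
              nrow(x$counts), min(x$shifts), max(x$shifts)))
  invisible(x)
}

# Render a stick peak list (mass, height) as a profile on a regular grid.
.render_profile <- function(peak_masses, peak_heights, lo, hi,
                            grid_step = 0.02, peak_sigma = 0.05) {
  grid <- seq(lo, hi, by = grid_step)
  y <- numeric(length(grid))
  half_width <- 4 * peak_sigma
  for (i in seq_along(peak_masses)) {
    m <- peak_masses[i]
    if (m < lo - half_width || m > hi + half_width) next
    a <- max(1L, ceiling((m - half_width - lo) / grid_step) + 1L)
    b <- min(length(grid), floor((m + half_width - lo) / grid_step) + 1L)
    if (a > b) next
    idx <- a:b
    y[idx] <- y[idx] +
      peak_heights[i] * exp(-(grid[idx] - m)^2 / (2 * peak_sigma^2))
  }
  list(grid = grid, intensity = y)
}

#' Build the theoretical (noise-free) spectrum of a modform mixture
#'
#' Each species contributes the protein's reference isotopic distribution
#' shifted by its total modification mass `m . p` and scaled by its
#' abundance; isotopologue sticks (~1 Da apart) from all species are
#' rendered as narrow Gaussian profile peaks on a common mass grid. The
#' underlying stick list is kept in the attribute `signal_peaks` so noise
#' can be injected at the peak level.
#'
#' @param spec A [modform_spec()].
#' @param grid_step Profile grid spacing in Da.
#' @param peak_sigma Rendered width of a single isotopologue peak in Da.
#' @param pad Margin added on both sides of the outermost isotopologues, Da.
#' @return A [raw_spectrum()] with attributes `signal_peaks` (data.frame
#'   `mass`, `height`, `species`) and `render` (grid parameters).
#' @export
build_theoretical_spectrum <- function(spec, grid_step = 0.02,
                                       peak_sigma = 0.05, pad = 30) {
  dist <- spec$protein$isotopic_distribution
  pm <- numeric(0); ph <- numeric(0); ps <- integer(0)
  for (s in seq_along(spec$shifts)) {
    pm <- c(pm, dist$masses + spec$shifts[s])
    ph <- c(ph, dist$abundances * spec$abundances[s])
    ps <- c(ps, rep(s, length(dist$masses)))
  }
  lo <- min(pm) - pad; hi <- max(pm) + pad
  prof <- .render_profile(pm, ph, lo, hi, grid_step, peak_sigma)
  out <- raw_spectrum(prof$grid, prof$intensity, source_id = "simulated")
  attr(out, "signal_peaks") <- data.frame(mass = pm, height = ph, species = ps)
  attr(out, "render") <- list(grid_step = grid_step, peak_sigma = peak_sigma,
                              lo = lo, hi = hi)
  out
}

#' Noise model for simulated spectra
#'
#' Three independent channels, each drawn from a shifted/scaled beta
#' distribution `loc + scale * Beta(shape1, shape2)`:
#' \describe{
#'   \item{basal}{background peaks added across the whole range at ~1 Da
#'     spacing; the draw is the peak intensity (on the normalized scale
#'     where the tallest signal is 1).}
#'   \item{vertical}{peak-height error: each signal peak's intensity is
#'     multiplied by the drawn ratio (mean 1).}
#'   \item{horizontal}{spacing error: the gap between consecutive
#'     isotopologues of a species deviates from its ideal value by the
#'     draw, applied cumulatively along the envelope (mean 0 Da).}
#' }
#' A channel with `scale = 0` is off (ratio 1, deviation 0, no basal
#' peaks). The same seed always reproduces the same spectrum.
#'
#' @param basal,vertical,horizontal Lists with `shape1`, `shape2`, `scale`,
#'   `loc`.
#' @param seed Integer RNG seed.
#' @return A `noise_model` list.
#' @export
noise_model <- function(basal = list(shape1 = 2, shape2 = 10, scale = 0.05, loc = 0),
                        vertical = list(shape1 = 4, shape2 = 4, scale = 0.2, loc = 0.9),
                        horizontal = list(shape1 = 5, shape2 = 5, scale = 0.04, loc = -0.02),
                        seed = 1L) {
  for (ch in list(basal, vertical, horizontal)) {
    stopifnot(ch$shape1 > 0, ch$shape2 > 0, ch$scale >= 0)
  }
  structure(list(basal = basal, vertical = vertical, horizontal = horizontal,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Default noise model
#'
#' Channel magnitudes chosen to emulate individual-ion spectra: a sparse
#' background floor up to 5% of the tallest signal (mean ~0.8%), peak-height
#' ratios with mean 1 and standard deviation 0.03 (the order of ion-counting
#' statistics for peaks built from hundreds of ions), and spacing deviations
#' with standard deviation 6 mDa per gap, applied cumulatively. The
#' magnitudes were calibrated so that detection on simulated overlapping
#' envelopes reproduces the separability characteristics measured on real
#' individual-ion data (see the methods vignette).
#'
#' @param seed Integer RNG seed.
#' @return A `noise_model`.
#' @export
default_noise_model <- function(seed = 1L) noise_model(seed = seed)

#' Noise-free model
#'
#' All three channel scales set to zero; [apply_noise()] returns its input
#' unchanged.
#'
#' @param seed Integer RNG seed (kept for interface symmetry).
#' @return A `noise_model`.
#' @export
zero_noise_model <- function(seed = 1L) {
  noise_model(basal = list(shape1 = 1, shape2 = 1, scale = 0, loc = 0),
              vertical = list(shape1 = 1, shape2 = 1, scale = 0, loc = 1),
              horizontal = list(shape1 = 1, shape2 = 1, scale = 0, loc = 0),
              seed = seed)
}

.draw_channel <- function(ch, n) ch$loc + ch$scale * stats::rbeta(n, ch$shape1, ch$shape2)

#' Add noise and error to a simulated spectrum
#'
#' Perturbs the stick peaks underlying a spectrum built by
#' [build_theoretical_spectrum()] with the three channels of a
#' [noise_model()] and re-renders the profile on the same grid. With all
#' channel scales zero the input is returned unchanged (bit-identical).
#'
#' @param spec A [raw_spectrum()] carrying the `signal_peaks` attribute.
#' @param model A [noise_model()].
#' @param seed Seed used for this draw; defaults to `model$seed`.
#' @return A [raw_spectrum()] with the same grid.
#' @export
apply_noise <- function(spec, model, seed = model$seed) {
  if (model$basal$scale == 0 && model$vertical$scale == 0 &&
      model$horizontal$scale == 0) {
    return(spec)
  }
  peaks <- attr(spec, "signal_peaks")
  render <- attr(spec, "render")
  if (is.null(peaks) || is.null(render)) {
    stop("spectrum does not carry signal peaks; build it with build_theoretical_spectrum()")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  m <- peaks$mass; h <- peaks$height; sp <- peaks$species
  # horizontal: cumulative spacing deviations within each species' envelope
  if (model$horizontal$scale > 0) {
    for (s in unique(sp)) {
      idx <- which(sp == s)
      if (length(idx) < 2) next
      dev <- .draw_channel(model$horizontal, length(idx) - 1)
      m[idx] <- m[idx][1] + c(0, cumsum(diff(m[idx]) + dev))
    }
  }
  # vertical: multiplicative peak-height error
  if (model$vertical$scale > 0) {
    h <- h * .draw_channel(model$vertical, length(h))
  }
  # basal: background peaks at ~1 Da spacing across the full range
  if (model$basal$scale > 0) {
    start <- render$lo + stats::runif(1)
    bm <- seq(start, render$hi, by = 1)
    bh <- .draw_channel(model$basal, length(bm)) * max(peaks$height)
    m <- c(m, bm); h <- c(h, bh)
  }
  prof <- .render_profile(m, pmax(h, 0), render$lo, render$hi,
                          render$grid_step, render$peak_sigma)
  out <- raw_spectrum(prof$grid, prof$intensity, source_id = spec$source_id)
  attr(out, "render") <- render
  out
}

#' Simulate one noisy modform spectrum
#'
#' @param spec A [modform_spec()].
#' @param model A [noise_model()].
#' @param seed Seed for the noise draw.
#' @param ... Passed to [build_theoretical_spectrum()].
#' @return A [raw_spectrum()].
#' @export
simulate_modform_spectrum <- function(spec, model = default_noise_model(),
                                      seed = model$seed, ...) {
  apply_noise(build_theoretical_spectrum(spec, ...), model, seed = seed)
}
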