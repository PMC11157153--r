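test_that("window fit recovers exact Gaussian peaks and honors the 5-peak rule", {
  sigma <- 3.2
  x <- seq(100, 112, by = 1)
  y <- 0.9 * exp(-(x - 106.3)^2 / (2 * sigma^2))
  pk <- structure(list(peak_masses = x, peak_intensities = y, noise_level = 0),
                  class = "centroid_peaks")
  cfg <- detection_config(window_size = 12, noise_level = 0)
  f <- fit_window_gaussian(pk, 100, cfg, sigma)
  expect_equal(f$mean, 106.3, tolerance = 1e-6)
  expect_equal(f$amplitude, 0.9, tolerance = 1e-6)
  expect_equal(f$pvalue, 1)

  # four signal peaks -> no fit
  pk4 <- structure(list(peak_masses = x[1:4], peak_intensities = y[1:4],
                        noise_level = 0), class = "centroid_peaks")
  expect_null(fit_window_gaussian(pk4, 100, cfg, sigma))

  # peaks below the noise floor carry no signal
  cfg_hi <- detection_config(window_size = 12, noise_level = 1)
  expect_null(fit_window_gaussian(pk, 100, cfg_hi, sigma))
})

test_that("chi-square goodness matches its definition and tail table", {
  obs <- c(1, 2, 3, 2, 1)
  gof <- chi_square_goodness(obs, obs)
  expect_equal(gof$statistic, 0)
  expect_equal(gof$pvalue, 1)

  expected <- c(0.5, 1, 2, 1, 0.5)
  gof <- chi_square_goodness(2 * expected, expected)
  expect_equal(gof$statistic, sum(expected))

  # chi-square upper tail: stat 11.07 at 5 df sits at p ~ 0.05
  expect_equal(stats::pchisq(11.07, 5, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)
  expect_error(chi_square_goodness(1:4, 1:4), "fewer than 5")
  expect_warning(chi_square_goodness(c(1, 2, 3, 2, 1, 9),
                                     c(1, 2, 3, 2, 1, 0)),
                 "zero expected value")
})

test_that("count scaling multiplies the statistic without changing zero fits", {
  obs <- c(1, 2, 3, 2, 1) / 10
  expd <- c(1.1, 1.9, 3.2, 2, 0.9) / 10
  plain <- chi_square_goodness(obs, expd)
  scaled <- chi_square_goodness(obs, expd, count_scale = 500)
  expect_equal(scaled$statistic, 500 * plain$statistic)
  expect_lt(scaled$pvalue, plain$pvalue)
  expect_equal(chi_square_goodness(obs, obs, count_scale = 500)$pvalue, 1)
})

test_that("overlap resolution is greedy, deterministic and order independent", {
  mk <- function(mean, pvalue, amplitude = 1) {
    structure(list(mean = mean, amplitude = amplitude, sigma = 1,
                   chi_square = 0, pvalue = pvalue, window_start = mean - 3),
              class = "gaussian_fit")
  }
  cfg <- detection_config(window_size = 9, min_peak_distance = 6)

  out <- resolve_overlaps(list(mk(100, 0.2), mk(100.5, 0.9)), cfg)
  expect_equal(vapply(out, `[[`, 0, "mean"), 100.5)

  out <- resolve_overlaps(list(mk(100, 0.2), mk(120, 0.9)), cfg)
  expect_length(out, 2)

  # chain: middle fit has the best p-value and expels both neighbours
  chain <- list(mk(0, 0.9), mk(4, 0.95), mk(8, 0.9))
  out <- resolve_overlaps(chain, cfg)
  expect_equal(vapply(out, `[[`, 0, "mean"), 4)

  # survivor set is invariant under input permutation
  set.seed(3)
  fits <- lapply(1:12, function(i) mk(stats::runif(1, 0, 40),
                                      stats::runif(1), stats::runif(1)))
  ref_means <- vapply(resolve_overlaps(fits, cfg), `[[`, 0, "mean")
  for (r in 1:5) {
    perm <- sample(fits)
    expect_equal(vapply(resolve_overlaps(perm, cfg), `[[`, 0, "mean"),
                 ref_means)
  }
})

test_that("quantification uses the Gaussian area and normalizes shares", {
  ref <- list(reference_mass = 1000, sigma = 3)
  class(ref) <- "protein_reference"
  mk <- function(mean, amplitude, sigma) {
    structure(list(mean = mean, amplitude = amplitude, sigma = sigma,
                   chi_square = 0, pvalue = 1, window_start = 0),
              class = "gaussian_fit")
  }
  # numerical quadrature oracle for the area under a Gaussian
  quad <- function(a, s) {
    stats::integrate(function(x) a * exp(-x^2 / (2 * s^2)), -Inf, Inf)$value
  }
  out <- quantify_and_shift(list(mk(1010, 2, 3)), ref, 1)
  expect_equal(out$abundance, quad(2, 3), tolerance = 1e-9)
  expect_equal(out$abundance, 2 * 3 * sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(out$shift, 10)
  expect_equal(out$relative_abundance, 1)

  out1 <- quantify_and_shift(list(mk(1010, 1, 1)), ref, 1)
  expect_equal(out1$abundance, sqrt(2 * pi), tolerance = 1e-9)
  expect_equal(out1$abundance, quad(1, 1), tolerance = 1e-9)

  # rescaling by the normalization factor propagates linearly
  out5 <- quantify_and_shift(list(mk(1010, 2, 3)), ref, 5)
  expect_equal(out5$abundance, 5 * quad(2, 3), tolerance = 1e-8)
})

test_that("noiseless single species yields exactly one accurate shift", {
  ref <- small_ref()
  spec <- modform_spec(matrix(1L, 1, 1, dimnames = list(NULL, "Ph")),
                       1, ref)
  clean <- build_theoretical_spectrum(spec)
  sh <- detect_mass_shifts(clean, ref, min(clean$masses), max(clean$masses))
  expect_equal(nrow(sh), 1)
  expect_lt(abs(sh$mean - (ref$reference_mass + spec$shifts)),
            20e-6 * ref$reference_mass)
  expect_equal(sh$relative_abundance, 1)
})

test_that("well-separated species recover counts and abundance ratios", {
  ref <- small_ref()
  counts <- matrix(c(0L, 2L, 5L), ncol = 1, dimnames = list(NULL, "Ph"))
  spec <- modform_spec(counts, c(0.5, 0.3, 0.2), ref)
  clean <- build_theoretical_spectrum(spec)
  sh <- detect_mass_shifts(clean, ref, min(clean$masses), max(clean$masses))
  expect_equal(nrow(sh), 3)
  expect_equal(sh$shift, spec$shifts, tolerance = 0.3, ignore_attr = TRUE)
  r2 <- 1 - sum((sh$relative_abundance - spec$abundances)^2) /
    sum((spec$abundances - mean(spec$abundances))^2)
  expect_gt(r2, 0.99)
})

test_that("fit p-values degrade as vertical noise grows", {
  ref <- small_ref()
  spec <- modform_spec(matrix(1L, 1, 1, dimnames = list(NULL, "Ph")), 1, ref)
  clean <- build_theoretical_spectrum(spec)
  mean_p <- vapply(c(0.1, 0.45), function(vs) {
    model <- noise_model(
      basal = list(shape1 = 1, shape2 = 1, scale = 0, loc = 0),
      vertical = list(shape1 = 4, shape2 = 4, scale = vs, loc = 1 - vs / 2),
      horizontal = list(shape1 = 1, shape2 = 1, scale = 0, loc = 0),
      seed = 1)
    ps <- vapply(1:40, function(r) {
      noisy <- apply_noise(clean, model, seed = 100 + r)
      sh <- detect_mass_shifts(noisy, ref, min(noisy$masses),
                               max(noisy$masses))
      if (nrow(sh) == 0) 0 else max(sh$pvalue)
    }, 0)
    mean(ps)
  }, 0)
  expect_gt(mean_p[1], mean_p[2])
})
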