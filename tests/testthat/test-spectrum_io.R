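test_that("TSV spectra parse, sort, and reject bad input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "100.0\t5.0", "101.0\t10.0"), f)
  sp <- load_spectrum(f)
  expect_equal(sp$masses, c(100, 101))
  expect_equal(sp$intensities, c(5, 10))
  expect_identical(sp$normalization_factor, 1)

  writeLines(c("101.0\t1.0", "100.0\t2.0"), f)
  sp <- load_spectrum(f)
  expect_equal(sp$masses, c(100, 101))
  expect_equal(sp$intensities, c(2, 1))

  writeLines(character(0), f)
  expect_error(load_spectrum(f), "no data points")
  writeLines(c("100.0\tNaN"), f)
  expect_error(raw_spectrum(100, NaN), "non-finite value at index 1")
  expect_error(load_spectrum("/nonexistent/spectrum.tsv"), "cannot read")
})

test_that("mzML profile spectra round-trip through mzR", {
  masses <- seq(1000, 1006, by = 1)
  intens <- c(1, 4, 9, 10, 8, 3, 0.5)
  f <- withr::local_tempfile(fileext = ".mzML")
  hdr <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = length(masses), totIonCurrent = sum(intens),
    retentionTime = 0, basePeakMZ = masses[which.max(intens)],
    basePeakIntensity = max(intens), collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = min(masses), highMZ = max(masses), precursorScanNum = 0L,
    precursorMZ = 0, precursorCharge = 0L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0, filterString = NA_character_,
    spectrumId = "scan=1", centroided = FALSE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(list(cbind(masses, intens)), f, header = hdr)
  sp <- load_spectrum(f, format = "mzml")
  expect_equal(sp$masses, masses, tolerance = 1e-9)
  expect_equal(sp$intensities, intens, tolerance = 1e-9)
  expect_length(sp$masses, 7)
})

test_that("range selection and normalization invert exactly", {
  sp <- raw_spectrum(c(99, 100, 101, 102, 110), c(1, 2, 4, 8, 50))
  nm <- select_and_normalize(sp, 100, 102)
  expect_equal(nm$intensities, c(0.25, 0.5, 1))
  expect_identical(nm$normalization_factor, 8)
  # all-equal intensities normalize to 1 with the max as factor
  eq <- select_and_normalize(raw_spectrum(c(1, 2), c(3, 3)), 0, 3)
  expect_equal(eq$intensities, c(1, 1))
  expect_identical(eq$normalization_factor, 3)
  # round trip is bit-exact
  expect_identical(nm$intensities * nm$normalization_factor, c(2, 4, 8))
  expect_error(select_and_normalize(sp, 200, 300), "no signal in mass range")
})

test_that("centroiding retains exactly the strict local maxima", {
  sp <- raw_spectrum(c(100, 100.5, 101), c(0.2, 1, 0.3))
  pk <- centroid_profile(sp)
  expect_equal(pk$peak_masses, 100.5)
  expect_equal(pk$peak_intensities, 1)

  mono <- raw_spectrum(seq(5), 1:5)
  expect_length(centroid_profile(mono)$peak_masses, 0)

  # two Gaussian bumps sampled at 0.2 Da -> exactly the two apex samples
  x <- seq(90, 110, by = 0.2)
  y <- exp(-(x - 95)^2 / 0.5) + 0.6 * exp(-(x - 105)^2 / 0.5)
  pk <- centroid_profile(raw_spectrum(x, y))
  expect_equal(pk$peak_masses, c(95, 105))

  expect_error(centroid_profile(raw_spectrum(c(1, 2), c(1, 2))),
               "too short to centroid")
})

test_that("centroid count equals brute-force local-maximum count", {
  set.seed(11)
  for (rep in 1:20) {
    y <- stats::runif(60)
    x <- seq_along(y)
    pk <- centroid_profile(raw_spectrum(x, y))
    brute <- sum(vapply(2:(length(y) - 1), function(i) {
      y[i] > y[i - 1] && y[i] > y[i + 1]
    }, TRUE))
    expect_length(pk$peak_masses, brute)
  }
})

test_that("plateau peaks centroid once at the midpoint", {
  sp <- raw_spectrum(c(1, 2, 3, 4, 5), c(0.1, 0.8, 0.8, 0.8, 0.1))
  pk <- centroid_profile(sp)
  expect_equal(pk$peak_masses, 3)
  expect_equal(pk$peak_intensities, 0.8)
})

test_that("noise level is half the population SD and scales homogeneously", {
  expect_equal(estimate_noise_level(raw_spectrum(1:3, rep(0.1, 3))), 0)
  # population SD of (0, 2) is 1
  expect_equal(estimate_noise_level(raw_spectrum(1:2, c(0, 2))), 0.5)
  expect_equal(estimate_noise_level(raw_spectrum(1:2, c(0, 2)), "sample"),
               0.5 * sd(c(0, 2)))
  y <- stats::runif(50)
  a <- estimate_noise_level(raw_spectrum(seq_along(y), y))
  b <- estimate_noise_level(raw_spectrum(seq_along(y), 7.3 * y))
  expect_equal(b, 7.3 * a)
  expect_error(estimate_noise_level(raw_spectrum(1, 5)), "single point")
})

test_that("noise threshold on a realistic spectrum clears the basal floor", {
  ref <- small_ref()
  spec <- modform_spec(matrix(c(0L, 1L), 2, 1, dimnames = list(NULL, "Ph")),
                       c(0.6, 0.4), ref)
  model <- default_noise_model(seed = 7)
  noisy <- apply_noise(build_theoretical_spectrum(spec), model)
  nm <- select_and_normalize(noisy, min(noisy$masses), max(noisy$masses))
  thr <- estimate_noise_level(nm)
  # 10,000 draws from the basal channel, on the same normalized scale
  set.seed(7)
  basal <- model$basal$loc +
    model$basal$scale * stats::rbeta(10000, model$basal$shape1, model$basal$shape2)
  expect_gt(mean(thr > basal), 0.99)
})
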