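#' Assemble a pipeline run configuration
#'
#' A flat key-value configuration (also readable from a YAML file with
#' [read_run_config()]). Required: `spectra` (paths), `fasta`, `mass_range`
#' (length-2 numeric). Everything else has defaults mirroring the
#' recommended analysis settings.
#'
#' @param spectra Character vector of spectrum paths (mzML or TSV).
#' @param fasta FASTA path of the protein of interest.
#' @param mass_range Numeric `c(lo, hi)` in Da.
#' @param sample_ids Labels; default file stems.
#' @param ptm_table_path Optional CSV/TSV path; default nine-type table.
#' @param mass_tolerance_ppm Tolerance for pattern inference (and bin size).
#' @param objectives Objectives to report.
#' @param laps Number of patterns per shift and objective.
#' @param pvalue_threshold Significance level of the fit filter.
#' @param window_size,step_size,min_peak_distance Detector overrides.
#' @param bin_size Cross-sample bin width in Da; `NULL` derives it from the
#'   tolerance (floored at 0.5 Da).
#' @param output_dir Directory for result files.
#' @return A `run_config` list.
#' @export
run_config <- function(spectra, fasta, mass_range, sample_ids = NULL,
                       ptm_table_path = NULL, mass_tolerance_ppm = 20,
                       objectives = c("min_both", "min_ptm"), laps = 1,
                       pvalue_threshold = 0.05, window_size = NULL,
                       step_size = 1, min_peak_distance = NULL,
                       bin_size = NULL, output_dir = "massshift_results") {
  stopifnot(length(mass_range) == 2, mass_range[1] < mass_range[2])
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.[^.]*$", "", basename(spectra))
  }
  structure(list(spectra = spectra, fasta = fasta, mass_range = mass_range,
                 sample_ids = sample_ids, ptm_table_path = ptm_table_path,
                 mass_tolerance_ppm = mass_tolerance_ppm,
                 objectives = objectives, laps = laps,
                 pvalue_threshold = pvalue_threshold,
                 window_size = window_size, step_size = step_size,
                 min_peak_distance = min_peak_distance, bin_size = bin_size,
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full detection + inference pipeline
#'
#' For every sample: load, restrict/normalize, centroid, estimate the noise
#' level, scan for envelope fits, quantify mass shifts; then bin shifts
#' across samples and infer PTM patterns for each binned shift under the
#' requested objectives. Writes `mass_shifts.csv` (per-sample detections),
#' `aligned_shifts.csv` (one row per species with per-sample relative
#' abundances), `ptm_patterns.csv` (top-k patterns per shift and objective)
#' and `run.log` (per-stage counts and every default in effect).
#'
#' @param config A [run_config()] or path to a YAML file.
#' @return Invisibly, a list with `shifts`, `aligned`, `report`, `patterns`,
#'   `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, log_con)
    message(msg)
  }

  ref <- protein_reference(fasta = config$fasta)
  say("protein: %d aa, reference mass %.3f Da, sigma %.3f Da",
      nchar(ref$sequence), ref$reference_mass, ref$sigma)
  table <- if (is.null(config$ptm_table_path)) {
    default_ptm_table()
  } else {
    read_ptm_table(config$ptm_table_path)
  }
  say("ptm table: %d types (%s)", nrow(table),
      paste(table$name, collapse = ", "))

  all_shifts <- list()
  for (i in seq_along(config$spectra)) {
    id <- config$sample_ids[i]
    spec <- load_spectrum(config$spectra[i], source_id = id)
    spec <- select_and_normalize(spec, config$mass_range[1],
                                 config$mass_range[2])
    noise <- estimate_noise_level(spec)
    peaks <- set_noise_level(centroid_profile(spec), noise)
    det <- default_detection_config(
      ref, noise_level = noise,
      window_size = config$window_size,
      step_size = config$step_size,
      min_peak_distance = config$min_peak_distance,
      pvalue_threshold = config$pvalue_threshold)
    fits <- scan_spectrum(peaks, ref, det)
    shifts <- quantify_and_shift(fits, ref, spec$normalization_factor, id)
    say(paste0("sample %s: %d profile points, %d peaks (%d above noise ",
               "%.4g), window %.2f Da (step %.2f, min distance %.2f, ",
               "p >= %.3g), %d mass shifts"),
        id, length(spec$masses), length(peaks$peak_masses),
        sum(peaks$peak_intensities > noise), noise, det$window_size,
        det$step_size, det$min_peak_distance, det$pvalue_threshold,
        nrow(shifts))
    if (nrow(shifts) == 0) warning("no mass shifts detected in sample ", id)
    all_shifts[[id]] <- shifts
  }

  bin_size <- if (is.null(config$bin_size)) {
    default_bin_size(config$mass_tolerance_ppm, ref$reference_mass)
  } else {
    config$bin_size
  }
  aligned <- bin_mass_shifts(all_shifts, bin_size = bin_size)
  say("alignment: bin size %.3f Da, %d species across %d samples",
      bin_size, nrow(aligned), length(all_shifts))
  report <- build_mass_shift_table(aligned)

  inf_cfg <- inference_config(mass_tolerance_ppm = config$mass_tolerance_ppm,
                              reference_mass = ref$reference_mass,
                              laps = config$laps)
  patterns <- infer_patterns(aligned$average_shift, table, inf_cfg,
                             objectives = config$objectives)
  say("inference: tolerance %.1f ppm (eps_max %.4f Da), objectives %s, laps %d",
      config$mass_tolerance_ppm, inf_cfg$eps_max,
      paste(config$objectives, collapse = "/"), config$laps)

  # Table-style report: first-lap pattern per objective joined to abundances
  for (obj in config$objectives) {
    first <- patterns[patterns$objective == obj & patterns$lap == 1, ]
    report[[paste0("pattern.", obj)]] <-
      first$pattern[match(round(report$average_shift, 6),
                          round(first$shift, 6))]
  }

  files <- c(shifts = file.path(config$output_dir, "mass_shifts.csv"),
             aligned = file.path(config$output_dir, "aligned_shifts.csv"),
             patterns = file.path(config$output_dir, "ptm_patterns.csv"))
  utils::write.csv(do.call(rbind, all_shifts), files["shifts"],
                   row.names = FALSE)
  utils::write.csv(report, files["aligned"], row.names = FALSE, na = "")
  utils::write.csv(patterns, files["patterns"], row.names = FALSE)
  say("wrote %s", paste(files, collapse = ", "))
  invisible(list(shifts = all_shifts, aligned = aligned, report = report,
                 patterns = patterns, files = files, reference = ref))
}

#' Run a named simulation benchmark
#'
#' Fixtures: `"overlap_ladder"` (pairs of envelopes at separations 2-16 Da),
#' `"phospho_ladder"` (seven phosphorylation states) and
#' `"complex_landscape"` (eighteen species, four PTM types). Results are
#' written as CSV under `output_dir`.
#'
#' @param fixture Fixture name or a [modform_spec()].
#' @param protein A [protein_reference()]; default the bundled p53.
#' @param n Simulations per evaluation.
#' @param seed RNG seed for the noise model.
#' @param mass_tolerance_ppm Tolerance for inference-based fixtures.
#' @param laps Lap depths to evaluate.
#' @param output_dir Output directory (`NULL` to skip writing).
#' @return The benchmark result object, invisibly when writing.
#' @export
simulate_benchmark <- function(fixture, protein = NULL, n = 100, seed = 1L,
                               mass_tolerance_ppm = 20, laps = c(1, 3),
                               output_dir = "massshift_benchmarks") {
  if (is.null(protein)) {
    protein <- protein_reference(fasta = p53_fasta_path())
  }
  model <- default_noise_model(seed = seed)
  if (is.character(fixture)) {
    known <- c("overlap_ladder", "phospho_ladder", "complex_landscape")
    if (!fixture %in% known) {
      stop("unknown fixture '", fixture, "'; available: ",
           paste(known, collapse = ", "))
    }
  }
  if (identical(fixture, "overlap_ladder")) {
    res <- run_overlap_ladder(seq(2, 16, by = 2), protein, model, n = n)
    out <- res
  } else {
    spec <- if (identical(fixture, "phospho_ladder")) {
      phospho_ladder_spec(protein)
    } else if (identical(fixture, "complex_landscape")) {
      complex_landscape_spec(protein)
    } else {
      fixture
    }
    inf <- inference_config(mass_tolerance_ppm = mass_tolerance_ppm,
                            reference_mass = protein$reference_mass)
    res <- run_pattern_benchmark(spec, model, n = n, inference = inf,
                                 laps = laps)
    out <- res$per_species
    out$abundance_r2 <- res$abundance_r2
    out$n_simulations <- res$n_simulations
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    name <- if (is.character(fixture)) fixture else "custom"
    utils::write.csv(out, file.path(output_dir, paste0(name, ".csv")),
                     row.names = FALSE)
    return(invisible(res))
  }
  res
}

#' Path of the bundled p53 FASTA
#'
#' Canonical human p53 sequence (UniProt P04637, 393 residues, average mass
#' ~43,653 Da), the default protein of interest for simulations.
#'
#' @return File path inside the installed package.
#' @export
p53_fasta_path <- function() {
  system.file("extdata", "P04637_p53_human.fasta", package = "massShiftR",
              mustWork = TRUE)
}
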