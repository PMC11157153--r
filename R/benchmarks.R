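#' Two-species overlap spec at a given separation
#'
#' Two equal-abundance copies of the protein's envelope whose means differ
#' by `separation` Da (the first species is unmodified). Used to probe the
#' resolvable-separation limit of the detector.
#'
#' @param separation Mean separation in Da.
#' @param protein A [protein_reference()].
#' @return A `modform_spec`-like object (direct shifts, no PTM counts).
#' @keywords internal
.overlap_pair_spec <- function(separation, protein) {
  structure(list(counts = NULL, abundances = c(0.5, 0.5),
                 shifts = c(0, separation), protein = protein,
                 table = NULL),
            class = "modform_spec")
}

#' Overlap-separation ladder benchmark
#'
#' For each separation, simulates two equal-abundance envelopes that far
#' apart, adds noise, and runs mass-shift detection `n` times. A replicate
#' counts as separated when both true means are each recovered by a
#' detected mean within the relative mass tolerance.
#'
#' @param separations Numeric vector of mean separations in Da.
#' @param protein A [protein_reference()].
#' @param model A [noise_model()]; replicate seeds are derived from its
#'   seed.
#' @param n Number of simulations per separation.
#' @param config Optional [detection_config()] (noise level is estimated
#'   per replicate when 0).
#' @param tolerance_ppm Recovery tolerance in ppm of the true mean.
#' @return data.frame (class `benchmark_result`) with one row per
#'   separation: `separation`, `separated_fraction`, `n_simulations`.
#' @export
run_overlap_ladder <- function(separations, protein,
                               model = default_noise_model(), n = 100,
                               config = NULL, tolerance_ppm = 20) {
  stopifnot(n >= 1, all(separations > 0))
  rows <- lapply(seq_along(separations), function(si) {
    sep <- separations[si]
    spec <- .overlap_pair_spec(sep, protein)
    clean <- build_theoretical_spectrum(spec)
    true_means <- protein$reference_mass + spec$shifts
    ok <- 0L
    for (r in seq_len(n)) {
      seed <- model$seed + 7919L * si + r
      noisy <- apply_noise(clean, model, seed = seed)
      shifts <- detect_mass_shifts(noisy, protein,
                                   lo = min(noisy$masses),
                                   hi = max(noisy$masses), config = config)
      hit <- vapply(true_means, function(tm) {
        any(abs(shifts$mean - tm) <= tolerance_ppm * 1e-6 * tm)
      }, TRUE)
      if (all(hit)) ok <- ok + 1L
    }
    data.frame(separation = sep, separated_fraction = ok / n,
               n_simulations = n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_result", "data.frame")
  out
}

#' Smallest reliably resolved separation
#'
#' @param ladder Result of [run_overlap_ladder()].
#' @param threshold Success-fraction threshold (default 0.75: resolved in
#'   more than 75% of simulations).
#' @return Separation in Da (`NA` when none qualifies).
#' @export
resolution_limit <- function(ladder, threshold = 0.75) {
  ok <- ladder$separation[ladder$separated_fraction > threshold]
  if (length(ok) == 0) NA_real_ else min(ok)
}

#' End-to-end benchmark on a known modform mixture
#'
#' Simulates the spectrum of a modform mixture `n` times, runs detection
#' and PTM-pattern inference on each replicate, and scores per species:
#' the fraction of replicates in which its mass shift is detected (within
#' the inference tolerance `eps_max`), and — for every requested objective
#' and lap depth — the fraction of replicates in which the true count
#' vector appears among the top-k inferred patterns. A species or pattern
#' is conventionally called reliable when its fraction exceeds 0.75.
#'
#' @param spec A [modform_spec()] with known ground truth.
#' @param model A [noise_model()].
#' @param n Number of simulations.
#' @param inference An [inference_config()] (its `eps_max` defines both the
#'   detection-match tolerance and the solver tolerance).
#' @param table `ptm_table` used for inference (may contain more types than
#'   the ground truth; defaults to [default_ptm_table()]).
#' @param objectives Objectives to evaluate.
#' @param laps Integer vector of lap depths to evaluate (e.g. `c(1, 3)`).
#' @param detection Optional [detection_config()].
#' @return List of class `pattern_benchmark`: `per_species` data.frame
#'   (`shift`, `true_pattern`, `detection_rate`, one
#'   `accuracy.<objective>.k<laps>` column per combination),
#'   `abundance_r2` (mean over replicates), `n_simulations`.
#' @export
run_pattern_benchmark <- function(spec, model = default_noise_model(),
                                  n = 100, inference = NULL,
                                  table = default_ptm_table(),
                                  objectives = c("min_ptm", "min_both"),
                                  laps = c(1, 3), detection = NULL) {
  protein <- spec$protein
  if (is.null(inference)) {
    inference <- inference_config(mass_tolerance_ppm = 20,
                                  reference_mass = protein$reference_mass)
  }
  eps <- inference$eps_max
  n_species <- length(spec$shifts)
  # ground-truth count vectors on the inference table's name space
  truth <- matrix(0L, n_species, nrow(table),
                  dimnames = list(NULL, table$name))
  if (!is.null(spec$counts)) {
    truth[, colnames(spec$counts)] <- spec$counts
  }
  clean <- build_theoretical_spectrum(spec)
  true_means <- protein$reference_mass + spec$shifts
  max_laps <- max(laps)
  detected <- matrix(0L, n_species, n)
  correct <- array(0L, c(n_species, length(objectives), length(laps)),
                   dimnames = list(NULL, objectives, paste0("k", laps)))
  r2 <- numeric(n)
  for (r in seq_len(n)) {
    noisy <- apply_noise(clean, model, seed = model$seed + r)
    shifts <- detect_mass_shifts(noisy, protein, lo = min(noisy$masses),
                                 hi = max(noisy$masses), config = detection)
    est_ab <- numeric(n_species)
    for (s in seq_len(n_species)) {
      d <- abs(shifts$mean - true_means[s])
      if (length(d) == 0 || min(d) > eps) next
      hit <- which.min(d)
      detected[s, r] <- 1L
      est_ab[s] <- shifts$relative_abundance[hit]
      obs <- shifts$shift[hit]
      for (oi in seq_along(objectives)) {
        cfg <- inference
        cfg$objective <- objectives[oi]
        cfg$laps <- max_laps
        sols <- enumerate_k_solutions(obs, table, cfg)
        for (li in seq_along(laps)) {
          top <- sols[seq_len(min(laps[li], length(sols)))]
          good <- any(vapply(top, function(p) {
            all(p$counts[table$name] == truth[s, ])
          }, TRUE))
          if (good) correct[s, oi, li] <- correct[s, oi, li] + 1L
        }
      }
    }
    sst <- sum((spec$abundances - mean(spec$abundances))^2)
    r2[r] <- 1 - sum((spec$abundances - est_ab)^2) / sst
  }
  per_species <- data.frame(
    shift = spec$shifts,
    true_pattern = apply(truth, 1, function(ct) {
      format_pattern(structure(list(counts = ct), class = "ptm_pattern"))
    }),
    detection_rate = rowMeans(detected))
  for (oi in seq_along(objectives)) {
    for (li in seq_along(laps)) {
      per_species[[paste0("accuracy.", objectives[oi], ".k", laps[li])]] <-
        correct[, oi, li] / n
    }
  }
  structure(list(per_species = per_species, abundance_r2 = mean(r2),
                 n_simulations = n),
            class = "pattern_benchmark")
}

#' @export
print.pattern_benchmark <- function(x, ...) {
  cat(sprintf("Pattern benchmark: %d species, %d simulations, abundance R2 %.3f\n",
              nrow(x$per_species), x$n_simulations, x$abundance_r2))
  print(x$per_species, digits = 3)
  invisible(x)
}

#' Phosphorylation-ladder fixture
#'
#' Seven species carrying 0-6 phosphorylations (mass shifts 0-480 Da) with
#' gently decreasing abundances; the simple benchmark mixture for studying
#' the impact of the individual noise channels.
#'
#' @param protein A [protein_reference()].
#' @return A [modform_spec()].
#' @export
phospho_ladder_spec <- function(protein) {
  counts <- matrix(0:6, ncol = 1, dimnames = list(NULL, "Ph"))
  modform_spec(counts, c(0.25, 0.20, 0.16, 0.12, 0.10, 0.09, 0.08), protein)
}

#' Complex PTM-landscape fixture
#'
#' Eighteen species built from four PTM types (Ph, Ac, Cys, Ox) spanning
#' mass shifts from 16 to ~458 Da with all pairwise gaps >= 12 Da, emulating
#' a crowded modform landscape. The truth set is deliberately graded for
#' inference over the full nine-type candidate table: the three lowest
#' shifts are the unique minimal-count explanation of their mass, while
#' higher shifts have fewer-count impostors or near-degenerate alternatives
#' (Ac vs Me3 differ by only ~0.04 Da; multi-oxidation masses mimic other
#' adduct sums), so count minimization alone succeeds only on the lowest
#' shifts, the combined objective recovers several more, and deeper
#' solution-space laps add further correct patterns. This fixture is a
#' synthetic approximation, not a published pattern list.
#'
#' @param protein A [protein_reference()].
#' @return A [modform_spec()].
#' @export
complex_landscape_spec <- function(protein) {
  counts <- rbind(
    c(0, 0, 0, 1),  # Ox             ~16
    c(0, 1, 0, 0),  # Ac             ~42
    c(1, 0, 0, 0),  # Ph             ~80
    c(1, 0, 0, 2),  # Ph+2Ox         ~112
    c(0, 0, 1, 1),  # Cys+Ox         ~135
    c(0, 1, 1, 0),  # Ac+Cys         ~161
    c(0, 1, 1, 1),  # Ac+Cys+Ox      ~177
    c(0, 1, 1, 2),  # Ac+Cys+2Ox     ~193
    c(0, 2, 1, 1),  # 2Ac+Cys+Ox     ~219
    c(3, 0, 0, 0),  # 3Ph            ~240
    c(3, 0, 0, 1),  # 3Ph+Ox         ~256
    c(1, 2, 1, 0),  # Ph+2Ac+Cys     ~283
    c(1, 2, 1, 1),  # Ph+2Ac+Cys+Ox  ~299
    c(2, 1, 1, 0),  # 2Ph+Ac+Cys     ~321
    c(3, 0, 1, 0),  # 3Ph+Cys        ~359
    c(3, 0, 1, 1),  # 3Ph+Cys+Ox     ~375
    c(2, 2, 1, 2),  # 2Ph+2Ac+Cys+2Ox ~395
    c(3, 1, 1, 2))  # 3Ph+Ac+Cys+2Ox ~433
  colnames(counts) <- c("Ph", "Ac", "Cys", "Ox")
  modform_spec(counts, seq(0.09, 0.03, length.out = 18), protein)
}
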