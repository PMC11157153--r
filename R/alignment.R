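#' Bin mass shifts across samples
#'
#' Envelope means detected in different samples (conditions and replicates)
#' that differ by less than the bin size are assumed to represent the same
#' species and are binned together; each bin's species mass is the
#' arithmetic mean of its member means. Binning is a greedy left-to-right
#' pass over the sorted means: a mean starts a new bin when it lies
#' `bin_size` or more above the current bin's running average. This
#' prevents the unbounded chaining plain single linkage allows, and makes
#' binning idempotent: a new bin opens only once the candidate is at least
#' `bin_size` above the running average, so the averages of adjacent rows
#' always end up at least `bin_size` apart and re-binning a binned table
#' changes nothing.
#'
#' @param shifts A `mass_shift_table` data.frame (rows from one or more
#'   samples, see [quantify_and_shift()]), or a list of such tables.
#' @param bin_size Bin width in Da (default 0.5; see
#'   [default_bin_size()] for the tolerance-derived choice).
#' @return An `aligned_shift_table` data.frame with one row per binned
#'   species: `average_mass`, `average_shift`, `n_members`, and the member
#'   rows in the attribute `members` (keyed by `bin`).
#' @export
bin_mass_shifts <- function(shifts, bin_size = 0.5) {
  stopifnot(bin_size > 0)
  if (is.list(shifts) && !is.data.frame(shifts)) {
    shifts <- do.call(rbind, shifts)
  }
  if (is.null(shifts) || nrow(shifts) == 0) {
    out <- data.frame(bin = integer(0), average_mass = numeric(0),
                      average_shift = numeric(0), n_members = integer(0))
    attr(out, "members") <- cbind(shifts, bin = integer(0))
    class(out) <- c("aligned_shift_table", "data.frame")
    return(out)
  }
  shifts <- shifts[order(shifts$mean), , drop = FALSE]
  bin <- integer(nrow(shifts))
  current <- 1L
  run_sum <- shifts$mean[1]; run_n <- 1L
  bin[1] <- current
  for (i in seq_len(nrow(shifts))[-1]) {
    m <- shifts$mean[i]
    if (m - run_sum / run_n >= bin_size) {
      current <- current + 1L
      run_sum <- 0; run_n <- 0L
    }
    bin[i] <- current
    run_sum <- run_sum + m
    run_n <- run_n + 1L
  }
  shifts$bin <- bin
  avg <- tapply(shifts$mean, bin, mean)
  avg_shift <- tapply(shifts$shift, bin, mean)
  out <- data.frame(bin = as.integer(names(avg)),
                    average_mass = as.numeric(avg),
                    average_shift = as.numeric(avg_shift),
                    n_members = as.integer(table(bin)))
  out <- out[order(out$average_mass), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "members") <- shifts
  class(out) <- c("aligned_shift_table", "data.frame")
  out
}

#' Default bin size from the mass tolerance
#'
#' The bin width is tied to the mass tolerance used for pattern inference:
#' `ppm * reference_mass`, but never below 0.5 Da. Larger tolerances widen
#' the bins and (deliberately) admit more candidate patterns.
#'
#' @param mass_tolerance_ppm Tolerance in parts per million.
#' @param reference_mass Protein reference mass in Da.
#' @return Bin size in Da.
#' @export
default_bin_size <- function(mass_tolerance_ppm, reference_mass) {
  max(mass_tolerance_ppm * 1e-6 * reference_mass, 0.5)
}

#' Wide per-sample report of binned mass shifts
#'
#' One row per binned species with its average shift and the relative
#' abundance observed in each sample; samples where the species was not
#' detected are left `NA` (rendered blank in CSV output). Rows ascend by
#' shift.
#'
#' @param aligned An `aligned_shift_table` from [bin_mass_shifts()].
#' @return A data.frame with columns `average_shift`, `average_mass`, and
#'   one `rel_abundance.<sample_id>` column per sample.
#' @export
build_mass_shift_table <- function(aligned) {
  members <- attr(aligned, "members")
  samples <- unique(members$sample_id)
  out <- aligned[, c("average_shift", "average_mass"), drop = FALSE]
  for (s in samples) {
    col <- rep(NA_real_, nrow(out))
    sub <- members[members$sample_id == s, , drop = FALSE]
    # a sample may contribute several members to one bin; sum their shares
    if (nrow(sub) > 0) {
      agg <- tapply(sub$relative_abundance, sub$bin, sum)
      col[match(as.integer(names(agg)), aligned$bin)] <- as.numeric(agg)
    }
    out[[paste0("rel_abundance.", s)]] <- col
  }
  out <- out[order(out$average_shift), , drop = FALSE]
  rownames(out) <- NULL
  out
}
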