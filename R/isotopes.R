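# IUPAC 2021 isotopic compositions and masses for the elements occurring in
# unmodified proteins plus the adduct elements used by the default PTM table.
# Each entry: matrix with columns mass (Da) and abundance, rows ordered by
# increasing neutron count starting at the lightest isotope.
.isotope_table <- list(
  C = cbind(mass = c(12.0000000, 13.0033548), abundance = c(0.9893, 0.0107)),
  H = cbind(mass = c(1.0078250, 2.0141018), abundance = c(0.999885, 0.000115)),
  N = cbind(mass = c(14.0030740, 15.0001089), abundance = c(0.99636, 0.00364)),
  O = cbind(mass = c(15.9949146, 16.9991317, 17.9991596),
            abundance = c(0.99757, 0.00038, 0.00205)),
  S = cbind(mass = c(31.9720712, 32.9714589, 33.9678670, 34.9690323, 35.9670812),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0000, 0.0001)),
  P = cbind(mass = 30.9737616, abundance = 1),
  Na = cbind(mass = 22.9897693, abundance = 1)
)

# Amino-acid residue formulas (chain residue = amino acid minus water).
.residue_formulas <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

#' Average atomic mass of an element
#'
#' Abundance-weighted mean over the naturally occurring isotopes.
#'
#' @param element Element symbol (e.g. `"C"`).
#' @return Average mass in Da.
#' @keywords internal
average_atomic_mass <- function(element) {
  tab <- .isotope_table[[element]]
  if (is.null(tab)) stop("no isotope data for element '", element, "'")
  sum(tab[, "mass"] * tab[, "abundance"])
}

#' Elemental composition of a protein sequence
#'
#' Sums the residue formulas of the chain and adds one water for the peptide
#' termini, so the composition is that of the free (unmodified) polypeptide.
#' An empty sequence yields the composition of water.
#'
#' @param sequence Amino-acid string using the 20 standard one-letter codes.
#' @return Named integer vector of element counts (class `composition`).
#' @examples
#' elemental_composition("GG")  # C4 H8 N2 O3
#' @export
elemental_composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  letters <- strsplit(sequence, "")[[1]]
  bad <- which(!letters %in% names(.residue_formulas))
  if (length(bad) > 0) {
    stop("unknown amino-acid letter '", letters[bad[1]], "' at position ", bad[1])
  }
  comp <- c(C = 0, H = 2, N = 0, O = 1, S = 0)  # water
  for (aa in letters) {
    f <- .residue_formulas[[aa]]
    comp[names(f)] <- comp[names(f)] + f
  }
  comp <- comp[comp != 0 | names(comp) %in% c("H", "O")]
  storage.mode(comp) <- "integer"
  class(comp) <- "composition"
  comp
}

#' Average (chemical) mass of a composition
#'
#' @param composition Named vector of element counts.
#' @return Mass in Da using abundance-weighted atomic masses.
#' @export
composition_mass <- function(composition) {
  sum(vapply(names(composition), average_atomic_mass, numeric(1)) *
        as.numeric(composition))
}

#' Monoisotopic mass of a composition
#'
#' @param composition Named vector of element counts.
#' @return Mass in Da using the lightest isotope of each element.
#' @export
composition_monoisotopic_mass <- function(composition) {
  sum(vapply(names(composition), function(el) .isotope_table[[el]][1, "mass"],
             numeric(1)) * as.numeric(composition))
}

# Convolve two aggregated distributions given as lists with elements
# prob (abundance per neutron-offset bin) and wmass (abundance-weighted mass
# per bin). Offsets are implicit 0,1,2,... from the first bin.
.conv_agg <- function(a, b, prune = 1e-15) {
  np <- convolve(a$prob, rev(b$prob), type = "open")
  # weighted mass of the sum: E[p1 p2 (m1 + m2)] per bin
  nw <- convolve(a$wmass, rev(b$prob), type = "open") +
    convolve(a$prob, rev(b$wmass), type = "open")
  np[np < 0] <- 0
  keep <- which(np > prune)
  if (length(keep) == 0) keep <- which.max(np)
  lo <- min(keep); hi <- max(keep)
  list(prob = np[lo:hi], wmass = nw[lo:hi],
       offset = a$offset + b$offset + lo - 1L)
}

# n-fold self-convolution by exponentiation-by-squaring.
.pow_agg <- function(base, n, prune = 1e-15) {
  result <- NULL
  while (n > 0) {
    if (n %% 2 == 1) {
      result <- if (is.null(result)) base else .conv_agg(result, base, prune)
    }
    n <- n %/% 2
    if (n > 0) base <- .conv_agg(base, base, prune)
  }
  result
}

.element_agg <- function(element) {
  tab <- .isotope_table[[element]]
  if (is.null(tab)) stop("no isotope data for element '", element, "'")
  p <- tab[, "abundance"]
  list(prob = p, wmass = p * tab[, "mass"], offset = 0L)
}

#' Aggregated isotopic distribution of a molecule
#'
#' Computes the isotopologue distribution of a composition by convolving the
#' per-element isotope distributions, binning fine structure by nominal
#' neutron count so consecutive peaks are spaced ~1 Da apart (each bin's mass
#' is the abundance-weighted centroid of its isotopologues). Peaks below
#' `min_abundance` are pruned and the remainder renormalized to sum to 1.
#'
#' @param composition Named vector of element counts (non-negative).
#' @param min_abundance Relative abundance below which peaks are dropped.
#' @return An `isotopic_distribution`: list with `masses` (Da, increasing,
#'   ~1 Da spacing) and `abundances` (sum to 1).
#' @examples
#' d <- isotopic_distribution(elemental_composition("G"))
#' sum(d$abundances)  # 1
#' @export
isotopic_distribution <- function(composition, min_abundance = 1e-5) {
  composition <- composition[as.numeric(composition) != 0]
  if (length(composition) == 0) stop("empty composition")
  if (any(as.numeric(composition) < 0)) {
    stop("negative element counts are not supported for isotope convolution")
  }
  agg <- NULL
  for (el in names(composition)) {
    e <- .pow_agg(.element_agg(el), as.integer(composition[[el]]))
    agg <- if (is.null(agg)) e else .conv_agg(agg, e)
  }
  masses <- agg$wmass / agg$prob
  keep <- agg$prob / max(agg$prob) >= 0 & agg$prob > 0
  masses <- masses[keep]; prob <- agg$prob[keep]
  rel <- prob / sum(prob)
  keep <- rel >= min_abundance
  masses <- masses[keep]; rel <- rel[keep]
  rel <- rel / sum(rel)
  structure(list(masses = masses, abundances = rel),
            class = "isotopic_distribution")
}

#' @export
print.isotopic_distribution <- function(x, ...) {
  cat(sprintf("Isotopic distribution: %d peaks, %.4f-%.4f Da\n",
              length(x$masses), min(x$masses), max(x$masses)))
  invisible(x)
}
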