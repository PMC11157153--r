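---
title: "Detecting mass shifts and inferring PTM patterns from true mass spectra"
author: "massShiftR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mass shifts and inferring PTM patterns from true mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(massShiftR)
```

# The measurement model

Individual ion mass spectrometry measures the mass of intact protein ions
directly, producing a profile spectrum on a Dalton axis with no charge-state
deconvolution. A protein of interest appears as a cluster of isotopologue
peaks spaced ~1 Da apart — its isotopic envelope — and every modified form
of the protein appears as a copy of that envelope displaced by the summed
modification mass. Two assumptions underpin the whole analysis:

1. **The envelope is approximately Gaussian.** For proteins above roughly
   14 kDa the isotopic distribution is the convolution of thousands of
   per-atom isotope distributions and is well described by a Gaussian in
   shape; the approximation error is a skew of a few tenths of a Dalton,
   which is handled explicitly (see *Reference mass* below).
2. **The envelope width is constant across modification states.** Adding a
   modification of tens to hundreds of Daltons changes the elemental
   composition by a few atoms out of thousands, so the standard deviation
   σ of the envelope is treated as a property of the protein, fitted once
   on the unmodified theoretical distribution and reused for every fit.
   For the bundled p53 sequence (393 aa, average mass 43,652.8 Da) the
   fitted σ is ≈ 5.6 Da, which matches the exact second moment of the
   computed isotopic distribution (≈ 5.60 Da) to within 0.4%.

The theoretical distribution itself is computed by exact polynomial
convolution of IUPAC per-element isotope distributions, aggregated by
nominal neutron count so that each retained peak is the abundance-weighted
centroid of its fine structure. This yields the ~1 Da spacing the
simulation and detection stages assume; sub-Dalton fine structure is
deliberately not modelled.

## Reference mass

The reference mass — the point from which every shift is measured — is
*not* taken from the Gaussian fit to the full distribution. Because the
true envelope is slightly skewed, a Gaussian fitted to all peaks and a
Gaussian fitted to only the top of the envelope (as the sliding-window
detector does) disagree by ~0.3 Da for p53 (~7 ppm). If the full-fit mean
were used as reference, that model mismatch would contaminate every
reported shift. Instead the same windowed, σ-fixed, refinement-corrected
fit that measures experimental envelopes is applied once to the
theoretical distribution, so an unmodified envelope reports a shift of
zero by construction. The full-distribution fit remains available
(`fit_reference_sigma()`, and the `full_fit_mean` field).

# Mass-shift detection

The detector follows a scan–filter–resolve–refine sequence.

**Preprocessing.** The spectrum is restricted to the user's mass range and
normalized to its maximum. Centroiding keeps strict local maxima (a flat
plateau contributes its midpoint once; boundary points are never peaks).
The signal threshold is one half of the standard deviation of all profile
intensities in the range — the population flavour (divide by *n*), since
the window's intensities are treated as the complete population, not a
sample. Peaks at or below the threshold are background.

**Window scan.** A window of fixed size slides in 1 Da steps. The default
window size is the mass width of the reference peaks with abundance at
least 2/3 of the apex (the "upper third" of the envelope), floored at
6 Da; for proteins above ~14 kDa this guarantees the five points the
chi-square test requires. In each window a Gaussian with fixed σ is fitted
to the signal peaks by least squares. The amplitude is profiled out in
closed form, and the mean is found by a coarse 0.25 Da grid followed by
golden-section refinement — deterministic, and robust against the local
minima a free 2-parameter optimizer can fall into. Fits whose mean lands
on the window boundary (within 0.1 Da) are discarded: a boundary-pinned
optimum means the window covers only an envelope flank, and the same
envelope is captured by a better-positioned window. Without this rule,
flank fits form a continuum of spurious high-quality candidates.

**Chi-square filter.** Each fit is scored with the Pearson statistic
`Σ (obs − exp)² / exp` at `n − 3` degrees of freedom (two fitted
parameters). Intensities are first multiplied by a *count scale*
(default 1000), the approximate number of ions behind the tallest peak.
This matters: the raw statistic is homogeneous of degree one in the
intensity unit, so on normalized intensities it shrinks toward zero and
every fit — including a Gaussian laid over the blended top of two merged
envelopes — passes any significance level. On the ion-count scale the test
regains its intended power: systematic misfits a few percent of peak
height are rejected at the 0.05 default significance level, while
fluctuations at the counting-statistics level pass. Users with spectra in
true ion counts should set `count_scale = NULL` and supply counts.

**Overlap resolution.** Candidates are ordered by decreasing p-value (ties:
larger amplitude, then lower mean) and accepted greedily when at least
`min_peak_distance` (default 2/3 of the window) from every accepted mean.
This is deterministic and independent of input order.

**Joint refinement.** Finally all accepted components are refitted
simultaneously as a sum of σ-fixed Gaussians against the signal peaks.
A single-window fit of one envelope is biased toward a neighbour whose
flank leaks into the window; the joint model accounts for that overlap.
Each mean may move at most 1 Da — the refit is a local correction, and
near the resolvable-separation limit the joint mean/amplitude trade-off
becomes ill-conditioned, so a wider trust region lets components wander.
Components whose refined amplitude falls to the noise floor are dropped
(this also removes the occasional mid-point fit between two well-separated
envelopes). No components are ever added, so species below the resolvable
separation stay merged.

**Quantification.** Each surviving envelope contributes
`A = α·σ·√(2π)`, rescaled to raw units by the stored normalization factor;
relative abundances are shares of the summed area. (The Gaussian integral
is `α·σ·√(2π)`; relative abundances are invariant to the constant.)

## Resolvability

Two equal envelopes merge into a unimodal profile when their means are
closer than about 2σ. For a p53-sized protein (σ ≈ 5.6 Da) the package's
benchmark (`run_overlap_ladder()`, and the acceptance script) measures the
smallest separation recovered within 20 ppm in >75% of noisy simulations
as 10 Da, with separations of 8 Da and below succeeding only in a small
minority of runs. This limit is structural — it follows from σ — not a
tunable of the detector.

# Cross-sample alignment

Envelope means from all samples are sorted and binned greedily: a mean
starts a new bin when it lies `bin_size` or more above the current bin's
running average. The rule prevents the unbounded chaining of plain single
linkage, and it makes binning idempotent: adjacent row averages always end
up at least `bin_size` apart, so re-binning a binned table changes
nothing. The default bin size is the inference mass tolerance
(`ppm × reference mass`) floored at 0.5 Da; wider bins admit more
candidate patterns downstream, which is the documented trade-off of
raising the tolerance. Each species' mass is the arithmetic mean of its
member means, computed once per bin.

# PTM pattern inference

For an observed shift `obs` and a PTM table with masses `m` and per-type
upper bounds `ub`, feasible patterns are integer vectors
`0 ≤ p ≤ ub` with `|m·p − obs| ≤ ε_max`. Three objectives are offered:

- `min_ptm`: minimize `P = Σ pᵢ` (fastest; prefers parsimony);
- `min_error`: minimize `ε = |m·p − obs|` (sensible only on very clean
  data — with noise it chases coincidental near-exact masses);
- `min_both`: minimize `ε/ε_max + P/P_max` (the recommended compromise).

Because the unknowns are integer counts, these are bounded integer
programs; they are solved exactly by depth-first branch-and-bound over the
count vector (heaviest modification first), pruning on the reachable-mass
interval and on an objective lower bound against the incumbent. A separate
flat enumeration of the feasible set serves as the test oracle; on
hundreds of random instances the two agree exactly.

The *k* best patterns ("laps") are enumerated by re-solving with a
strict-improvement constraint: `P ≥ P_prev + 1`, `ε ≥ ε_prev + δ`
(δ = 10⁻⁴ Da), or `f ≥ f_prev + 10⁻⁶`. A consequence, faithful to the
constraints as stated, is that alternatives *tying* the previous optimum
are skipped; an optional `tie_mode = "nogood"` instead excludes only the
previously returned vectors and therefore walks through ties (an
extension, off by default).

Decisions where the method description leaves latitude, and how they were
fixed here:

- **Tolerance base.** `ε_max = ppm × reference mass` of the protein, not of
  the shift. Observed shifts are differences of envelope means near the
  protein mass, so their absolute error scales with the protein mass; and
  only on this reading are the published example decompositions (e.g. one
  cysteinylation, error ≈ 1.56 Da, at a 120.7 Da shift under 36 ppm)
  feasible at all.
- **`P_max`.** The combined objective needs a normalizer for the count
  term. Using the sum of all upper bounds (often 50+) shrinks the count
  term until `min_both` degenerates into `min_error` and high-count
  patterns with accidentally tiny error win (at 120.7 Da, seven
  methylations plus a sodium adduct would displace the phosphate + sodium
  explanation). The default is `min(Σ ub, 10)`: ten simultaneously
  occupied sites is a generous ceiling for one molecule, and the resulting
  rankings reproduce the published example decompositions.
- **PTM masses.** Average masses by default (a fitted envelope mean tracks
  the average mass); monoisotopic selectable. Masses are derived from
  elemental compositions where given; negative element counts are allowed
  so adducts like sodium (Na − H) are expressible.
- **Upper bounds.** Entries without an explicit bound get
  `floor((obs + ε_max)/mass)` capped at 10.

Pattern inference is deliberately not biologically weighted: objectives
rank the solution space, nothing more. Site localization is impossible
from intact mass alone and out of scope.

# The synthetic-spectrum generator

`build_theoretical_spectrum()` renders each species as the reference
isotopologue sticks displaced by `m·p`, scaled by its abundance, drawn as
narrow Gaussian profile peaks (width 0.05 Da) on a 0.02 Da grid — fine
enough that centroiding recovers apex positions to under 0.02 Da.
`apply_noise()` perturbs the underlying stick list with three channels,
each drawn from a shifted, scaled beta distribution
(`loc + scale·Beta(a, b)`), then re-renders:

- **basal**: background peaks at ~1 Da spacing across the whole range,
  intensity up to 5% of the tallest signal (mean ≈ 0.8%);
- **vertical**: each signal peak's height multiplied by a ratio with mean
  1 and standard deviation 0.03 — the order of ion-counting statistics for
  peaks assembled from hundreds of individual ions, and coherent with the
  detector's default count scale of 1000 (`sd ≈ 1/√N`);
- **horizontal**: each isotopologue gap deviates from its ideal value by a
  draw with mean 0 and standard deviation 6 mDa, applied cumulatively
  along the envelope (spacing error, not i.i.d. jitter).

A channel with `scale = 0` is off, and a zero-noise model returns the
input unchanged. All draws derive from a single seed; the same seed
reproduces a spectrum bit for bit, and benchmark replicates use seeds
derived from the base seed.

The exact parameters of the noise measured on real instruments are not
published, so the shipped defaults were calibrated once against the
published operating characteristics of detection on such data — the 10 Da
separability limit with high success from 12 Da upward, failure at 6 Da
and below, and the observation that basal noise alone does not change
detection — and then frozen. Within that calibration the marginal split
rate exactly at 8 Da is the least constrained quantity; the test suite
asserts only that it is a clear minority (10–50%).

What the generator does *not* emulate: detector-specific individual-ion
statistics (ion survival, charge assignment), contaminant species,
sub-Dalton fine structure, and intensity-dependent mass error. Passing
benchmarks on simulated data therefore demonstrate correct behaviour of
the algorithmic chain under controlled noise, not instrument-level
validity on real spectra — contaminant peaks above the noise level, for
instance, will be reported as modforms of the protein of interest, an
acknowledged behaviour of the method.

## Benchmark fixtures

Three fixtures mirror the study designs used to characterize the method:
`overlap_ladder` (two equal envelopes at 2–16 Da separations),
`phospho_ladder` (seven phosphorylation states, 0–480 Da), and
`complex_landscape` (eighteen species over Ph/Ac/Cys/Ox spanning 16–433 Da
with gaps ≥ 16 Da). The landscape's truth set is graded by construction:
the lowest shifts are the unique minimal-count explanation of their mass;
higher shifts collide with fewer-count impostors or near-degenerate
alternatives (acetylation vs tri-methylation differ by 0.043 Da — far
below any realistic tolerance), so pure count minimization fails on most
species, the combined objective recovers more, and deeper laps more
still. It is a synthetic approximation of that design, not a published
pattern list, and the tests assert the qualitative ordering (combined ≥
count-only, k = 3 ≥ k = 1, all 18 detected) rather than exact counts.

# Problem sizes and runtimes

The shipped tests and the acceptance script run the ladder at 100
simulations per separation (≈ 15 s on one core), the complex landscape at
25 simulations (≈ 2 min including inference at two objectives × three
laps), and the solver/oracle comparison at 200 random instances (seconds).
These sizes keep every stochastic estimate's Monte-Carlo error well below
the decision thresholds they feed (e.g. a binomial standard error of ~4
percentage points against the 75% reliability threshold).

# Known limitations

- Species closer than the ~2σ merge limit are reported as one envelope
  with an intermediate mass; no mixture deconvolution below that limit is
  attempted.
- Mass shifts beyond ~400 Da admit thousands of feasible patterns at
  realistic tolerances; rankings there are unreliable under every
  objective, and enumerating more laps mainly adds incorrect candidates.
- The chi-square filter's power depends on the count scale; if it is set
  far from the true ion statistics the filter becomes either toothless
  (too small) or rejects genuine envelopes whose windows are contaminated
  by neighbours (too large).
- Binning can, in principle, assign two true species of one sample to a
  single row when their means fall within one bin; the bin size should
  stay at or below the detector's overlap distance.
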