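---
title: "Ion-mobility-aware validation of DSBU cross-links: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ion-mobility-aware validation of DSBU cross-links}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlpasef)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and their defaults, what the synthetic
data generator does and does not emulate, and the choices made where the
design was genuinely open.

## The problem

DSBU cross-linking covalently bridges lysine (and, less efficiently,
serine, threonine and tyrosine) side chains, or a protein N-terminus, that
are spatially close. After tryptic digestion, a cross-linked peptide pair
is identified from its fragment spectrum. Two features make
timsTOF DDA-PASEF data attractive and awkward at once: each precursor
carries an inverse reduced ion mobility (1/K0, V·s/cm²) that sharpens
extraction and matching, and the serial-fragmentation scheme produces
many mobility-resolved MS/MS scans of the same eluting compound that must
be merged before searching. Downstream, DDA's stochastic precursor
selection means the absence of a spectrum match in a replicate is weak
evidence of absence of the molecule — which motivates the peptide-centric
validation implemented here.

## Chemistry

Masses are computed from hard-coded IUPAC monoisotopic atomic masses
(proton 1.00727646 Da). Peptide mass is the sum of residue masses plus one
water; carbamidomethylation of Cys (+57.02146 Da, fixed) and Met oxidation
(+15.99491 Da, variable) are built in, and arbitrary deltas can be
supplied per residue or position. A cross-link's neutral mass is
`mass(alpha) + mass(beta) + intact linker`, where the DSBU intact mass is
*defined* as the sum of its two cleavage fragments Bu (C₄H₇NO,
85.05276 Da) and BuUr (C₅H₅NO₂, 111.03203 Da) — conservation across the
cleavable urea bond is enforced at construction to 1e-4 Da.

`fragment_ions()` enumerates a/b/y ions of both peptides. A fragment that
does not span the link site is a plain linear fragment; one that does is
emitted in three variants: with the intact linker plus the complete
partner peptide, or retaining only Bu or only BuUr — the diagnostic
doublet. Isotope spacing uses the averagine convention (1.0033548 Da/z);
fine-structure envelopes, internal and immonium ions are out of scope.
a-ions are generated for search-support purposes but excluded from EIC
validation by default. Zero-mass-shift ("dead-end") fragment semantics
are deliberately not guessed at and not generated.

## Consensus spectra

Scans are grouped into compounds by greedy seeded clustering: records are
ranked by descending precursor intensity (ties: ascending m/z, then scan
id); the top unassigned record seeds a cluster and absorbs every
unassigned record within *all three* tolerances of the seed (0.75 min,
0.015 Th absolute, 0.025 V·s/cm²). Measuring membership against the seed,
not transitively, bounds within-cluster spread at the stated tolerances
and makes the partition order-invariant; on small instances it is verified
against a brute-force restatement of the same rule. The merged spectrum
pools fragment peaks and bins them at 0.02 Th (intensity-weighted mean
m/z, summed intensity); the consensus 1/K0 is the intensity-weighted mean
of member precursors — the ion-mobilogram centre — and the apex RT is the
RT of the strongest member. Peak binning assumes centroided input;
profile-mode peak picking is not attempted. The MGF dialect writes 1/K0
into the scan title (`compound=<id> run=<id> 1/K0=<x.xxxx>`) so it
survives through search engines that ignore unknown headers.

## FDR

Merged XSM tables are scored by target-decoy competition. At a score
threshold t the estimated FDR is `#decoys(>= t) / #targets(>= t)` (1 when
no targets remain); a record's q-value is the minimum estimated FDR over
all thresholds at or below its score, giving monotone q. The
decoys/targets form (rather than decoys/(targets+decoys)) follows common
XL-MS practice; the choice is configurable in spirit — the estimator is a
single documented function — and the streaming implementation is tested
against an O(n²) threshold scan. Defaults follow the workflow's printed
settings: global q ≤ 0.05 and minimum score 15. Any per-search pre-filter
applied upstream by the search engine is treated as part of the input.

## Ion-mobility library and iRT calibration

Per precursor — the unordered pair of (sequence, link position) halves
plus charge — the library stores the arithmetic mean 1/K0 and the observed
range over all contributing XSMs. The extraction window defaults to the
observed range floored at 0.05 V·s/cm² total width (±0.025, matching the
merge tolerance), so single-observation precursors still get a usable
window; whether the original analysis used the range as a window or only
reported it is unknowable from the outside, so both are exposed.

Retention-time calibration is ordinary least squares of reference iRT on
observed RT, per run. Linear is the minimal faithful model for a short
spiked standard set; LOWESS/spline alignment is a non-goal. An optional
robustness rule removes the single worst standard when n ≥ 6 and its
residual exceeds 3 residual SDs — note that with the plain SD in the
denominator a gross outlier partially masks itself, so the rule only
fires when the panel is large enough (about a dozen standards for a
5 min RT error); this is a documented limitation, not a bug. Predicted
RT windows are `max(3 * residual SD / slope, 0.5 min)` half-width: the
floor keeps perfectly calibrated runs from degenerating to zero-width
windows.

## Peptide-centric validation

For every FDR-surviving precursor, the first three isotopes are extracted
at 10 ppm from each run's MS1 peaks, inside the run-local RT window
(consensus iRT projected through that run's calibration) and the library
mobility window. The theoretical monoisotopic m/z is recomputed from the
sequences rather than taken from the (measurement-jittered) XSM row.
The EIC grid is the union of MS1 scan times in the window — no
resampling; isotope traces are aligned on the common grid. A peak is
called at the summed-trace maximum, with boundaries descending to 5% of
apex or a local minimum; noise is 1.4826 × MAD of the off-peak region;
the coelution score is the minimum pairwise Pearson correlation of the
three isotope traces inside the boundaries. Detection requires
S/N ≥ 3 and coelution ≥ 0.8. These two thresholds are the package's own
defaults — the underlying criteria list (apex RT, peak shape, isotope
coelution) is qualitative — and both are arguments everywhere they
matter.

The verdict is the three-criterion conjunction: **validated** iff q ≤ α
and a peak is detected in *all* sample replicates and *no* peak is
detected in any negative control at the matching iRT/mobility
coordinates. Rejection reasons are reported with the fixed precedence
FDR → control → replicates (a reporting convention for determinism, not a
scientific claim); a precursor with no peak anywhere is `not_detected`.
"All sample replicates" counts only runs labelled as replicates of the
same condition; runs at other collision-energy profiles would be reported
but not required. Replicate overlap of XSM-level identifications is
summarised as exclusive UpSet counts, and `match_between_runs()`
classifies each (precursor, run) as identification-plus-peak, peak-only
(transferred identification) or no-peak.

## The synthetic-study generator

`generate_study()` emulates the structure of the benchmark experiment the
workflow targets: four technical replicates at one collision-energy
profile plus one cross-linker-free negative control; DSBU cross-links of
a tryptic digest; iRT standards in every run. Its defaults are the study
conditions and are not tuned per test:

* Protein: a deterministic synthetic 300-residue sequence with
  tryptic-like K/R content (a stand-in, not a real protein). Digestion is
  fully specific after K/R with no proline exception, ≤3 missed
  cleavages, lengths 5–50.
* Cross-links: 20 true + 20 reversed-sequence decoys; a linked lysine is
  never the peptide C-terminus (a linked K is not cleavable, the standard
  XL-MS convention).
* Per precursor: charge 3–4; 1/K0 = 0.45 + 0.05·z + 0.5·(m/z)/1000,
  clamped to the instrument's 0.73–1.60 V·s/cm² mobility range, plus
  0.005 jitter — only the range is knowable, so the affine form is a
  plausible invention; true iRT uniform on 10–90; lognormal abundance.
* Runs: per-run affine RT calibrations (slope ≈ 5 iRT/min, intercept
  ≈ −50), MS1 scans every 0.05 min on one shared grid per run (as on a
  real instrument cycle), Gaussian elution peaks of SD 0.06 min with
  isotope ratios 1/0.85/0.55, per-scan MS1 m/z jitter 2 ppm (TOF-typical,
  and deliberately small against the 10 ppm extraction window; the MGF
  fragment jitter is a separate 5 ppm parameter), 1000 random matrix
  peaks.
* XSMs: each true cross-link is identified in each replicate with
  probability p = 0.5 (DDA stochasticity), with one run guaranteed so
  every planted cross-link is assessable — this leaves the
  all-four-replicates probability p⁴ unchanged. Scores are Normal(40, 8)
  for targets and Normal(18, 6) for decoys, truncated at zero — chosen so
  both the minimum-score-15 and the 5% global FDR cuts are genuinely
  exercised; these distributions are an invention of the generator, not a
  measured property.
* Controls carry matrix peaks, standards, and the MS1 signal of 2
  designated contaminant cross-links — which must end up
  `rejected_control`.

What the generator does *not* emulate: raw TIMS frames and PASEF
scheduling, profile-mode peaks, collision-energy-dependent fragmentation
efficiency, chimeric spectra, intensity-dependent score correlation, and
real chromatographic tailing. Passing tests therefore demonstrate the
correctness and calibration of the pipeline's logic under clean,
well-separated signals — not its behaviour on noisy biological matrices.

## Numerical choices and degenerate inputs

Zero-variance traces get coelution 0 (not NA); an all-zero off-peak
region gives infinite S/N, which counts as detected only if coelution
also passes. Empty clusters, empty MGF blocks, decoy-free FDR input
(loud warning, q = 0), missing mobility values (skipped with a warning)
and missing library entries (`not_detected` verdict, warning) are all
defined rather than errors where a partial result is scientifically
meaningful. Ties in clustering are broken by m/z then scan id; tied FDR
scores share one threshold. All tabular outputs are UTF-8 CSV; MGF
round-trips byte-identically through its own reader.

## Problem sizes

The bundled tests and the acceptance script run the full pipeline on
studies of 20 true cross-links, 4+1 runs and ~1000 matrix peaks per run
(a few seconds per study), with smaller instances for property tests
across many seeds; these sizes were chosen to make the statistical
checks (binomial sampling counts, mobility recovery within
3·SD/√n, 1% slope recovery) well-powered while keeping the suite quick
to iterate on.

## Known limitations

* The FDR estimator and decoy construction are fixed conventions;
  search-engine-specific refinements (per-search pre-filters,
  score recalibration) are passed through, not modelled.
* Linear iRT calibration cannot absorb nonlinear gradient distortion.
* The ProXL export covers the subset of the schema needed for
  cross-link import (linker, search program, reported peptides, PSMs),
  not the full format.
* Only two-fragment cleavable NHS-ester linkers are modelled; other
  linker chemistries fit the `linker_spec()` container but are untested.
* DIA acquisition and Bruker raw-file reading are out of scope; inputs
  are centroided, calibrated peak lists.
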