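---
title: "Screening fragmented bone assemblages with zoomscreen: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening fragmented bone assemblages with zoomscreen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoomscreen)
```

## The problem

Palaeolithic faunal assemblages are often so fragmented that only a few
percent of bone specimens can be identified morphologically. Zooarchaeology
by Mass Spectrometry (ZooMS) screens the rest: collagen type I survives for
tens of millennia, its tryptic peptides carry taxon-specific mass
differences, and a MALDI-ToF peptide mass fingerprint over 700--3500 m/z can
place a splinter of bone in a species, genus or family. The same spectra
carry a preservation signal: the extent of glutamine deamidation (%Gln),
read from the shape of a peptide's isotope envelope.

`zoomscreen` implements this screening workflow end to end: spectral
processing, marker-based taxonomic assignment with explicit ambiguity
handling, %Gln quantification by envelope deconvolution, and the
zooarchaeological bookkeeping (NISP tables, screening success rates) needed
to fold molecular determinations back into a site report. A synthetic
generator supplies spectra and assemblages with known ground truth, so every
stage is testable without instrument data.

## Spectral processing

Spectra are modelled as singly charged profiles. Processing follows the
standard ZooMS chain, with each step's parameters exposed in
`preprocess_config()`:

* **Resampling** to a uniform axis (default step 0.02 Th, far below the
  ~1 Th isotope spacing) by linear interpolation. Replicate acquisitions of
  one sample are averaged pointwise on this grid before peak picking; a
  per-replicate picking path was considered and rejected in favour of the
  simpler average-first convention, which matches how duplicate MALDI spots
  are usually combined.
* **Smoothing**: Savitzky-Golay, polynomial order 2, window 0.2 Th. The
  cycle count may be fractional: 1.5 cycles means the average of the
  one-pass and two-pass outputs; in general the fractional part is a convex
  blend between the flanking integer passes. This gives a continuous,
  testable meaning to a fractional setting that processing GUIs expose
  without defining.
* **Baseline**: the axis is cut into 100 equal segments ("precision 100");
  each segment anchors the baseline at its intensity minimum, optionally
  shifted up by a fraction of the segment's intensity range ("relative
  offset", default 0); the anchors are joined piecewise-linearly and the
  baseline subtracted with clamping at zero.
* **Peak picking**: local maxima with signal-to-noise at least 3.5 and
  height at least 0.5% of the base peak. Noise is 1.4826 times the windowed
  median absolute deviation (windows of 100 Th), estimated on the profile
  *before* smoothing: smoothing shrinks the noise floor, and an estimate
  taken after it would let thousands of smoothed noise maxima through the
  gate. Centroids are intensity-weighted means of the contiguous points
  above 80% of the apex ("picking height 80%").
* **Deisotoping**: peaks spaced 1.00235 Th apart (the average peptide
  isotopologue spacing, charge 1) are chained greedily from low m/z; each
  chain is reported as one monoisotopic peak carrying its envelope. A chain
  is split where intensity rises again after the third isotope, the
  signature of a second overlapping envelope.

Degenerate inputs are handled explicitly: an all-zero spectrum yields an
empty peak list (not an error), non-uniform axes are rejected before
smoothing, and a spectrum with fewer points than baseline segments is a
parameter error.

## Marker matching and assignment rules

Identification is always relative to a user-supplied marker table (taxon,
marker series A--G or named peptide, monoisotopic m/z, diagnostic flag) plus
a table of named ambiguity groups — sets of taxa the available markers
cannot separate. The package ships an *illustrative, synthetic* example pair
(`example_marker_db()`) whose masses are placeholders; curated reference
masses live in the literature and must be supplied for real work. This was a
deliberate choice: the published working marker lists are assembled from
several sources and are not reproducible from any single table, so encoding
one as scientific truth would be misleading.

Matching uses a tolerance of 0.2 Th by default (configurable; no tolerance
is standard in the field, and 0.2 Th is comfortably wider than the centroid
error of a calibrated ToF while narrower than any marker separation in the
example table). Assignment then proceeds by counting matched diagnostic
markers per candidate taxon:

1. a unique taxon with at least `min_diagnostic` (default 2) diagnostic
   matches that strictly dominates all rivals is called at species level;
2. tied taxa escalate to the smallest registered ambiguity group covering
   them (Bos/Bison, Caprinae/Cervidae, Ursus sp./Lynx lynx, ...) — ties are
   never broken by intensity, because in practice they are broken by
   re-examining the bone, which is outside the software;
3. when the only evidence is a single diagnostic peptide shared across taxa
   (the classic 1453.7-class peptide common to several carnivores, hare and
   wild boar), the group registered for that peptide is assigned and
   `needs_morphological_review` is set;
4. matches that resolve nothing beyond order-wide ungulate peptides give
   "Ungulata"; anything less is "undetermined".

`min_diagnostic = 2` encodes the observed practice that one shared peptide
never supports a species call. The screening **success rate** is the
percentage of samples assigned anything other than "undetermined", rounded
to the nearest integer — the determined/tested convention used in screening
reports. (Published summary tables sometimes print success figures computed
on another, unexplained basis; this package implements the determined/tested
definition throughout.)

A chimeric peak list containing the complete fingerprints of two unrelated
taxa (say, an aurochs and a bear) can defeat assignment, since no registered
group covers both; single-specimen samples cannot produce this, and the
monotonicity tests therefore add only same-taxon or non-marker peaks.

## Deamidation (%Gln) by envelope deconvolution

Glutamine deamidation converts a side-chain amide to a carboxyl; the residue
loses NH and gains O, shifting the peptide by
+0.98402 Da (computed in `deamidation_mass_shift()` from standard
monoisotopic atomic masses). Because the shift is close to, but not exactly,
one isotope spacing, a partially deamidated peptide's envelope is a
superposition: the observed intensities at positions
$m_0 + j \cdot 1.00235$, $j = 0 \dots k$, are modelled as

$$ y_j = c\,[\alpha E_0(j) + (1-\alpha) E_1(j)] + b $$

where $E_0$ is the theoretical envelope of the native peptide, $E_1$ the
same envelope displaced by +0.98402 Da (one position at ToF resolution), and
$\alpha \in [0,1]$ is the undeamidated fraction, reported as %Gln (1 =
intact, 0 = fully deamidated). The default targets are the two standard
collagen screening peptides at m/z 1105.6 and 1706.7, with $k = 5$ isotope
positions.

Numerical choices:

* **Envelopes** come from exact convolution of elemental isotope
  distributions, using a supplied elemental composition when known and an
  averagine composition scaled to the neutral mass otherwise. The
  convolution is verified in the tests against an independent
  direct-enumeration oracle.
* **Fitting** is non-negative least squares on the two component vectors
  plus a non-negative flat background term $b$; $\alpha$ is the ratio
  $a_0/(a_0+a_1)$ of the fitted weights, clipped to $[0,1]$. NNLS replaces
  the stochastic optimisers sometimes used for this deconvolution: it is
  deterministic, exact in the noiseless limit, and a 0.001-step grid search
  oracle in the test suite guards the equivalence. Residuals are unweighted;
  intensity weighting was considered and rejected for lack of a defensible
  per-peak variance model on centroided data.
* **Missing positions are missing, not zero.** A deisotoped peak list
  censors everything below the picking threshold; forcing unobserved tail
  positions to zero systematically penalises the longer shifted envelope
  and biases $\alpha$ upward by ~0.02 at realistic noise. Positions with no
  observation within tolerance are therefore dropped from the fit, and a
  fit needs at least three observed positions.
* A single deamidation event is modelled even for peptides with several
  glutamines — the two-component model is what the 0--1 %Gln scale implies;
  site-resolved multi-event modelling is out of scope.
* The result is flagged `usable = FALSE` when the native monoisotopic peak
  is below S/N 3.5 (a fully deamidated sample trips this gate legitimately:
  its native monoisotopic peak does not exist).

Site-level reports give n, mean, median and 2 SE ($2\,\mathrm{sd}/\sqrt{n}$)
per site and peptide, never pooling the two peptides. The extraction
protocol (acid demineralisation vs ammonium-bicarbonate only) is carried as
a per-batch flag and reported alongside the statistics, because acid
demineralisation is known to inflate deamidation; no correction is applied,
and %Gln is treated as a preservation proxy, not a dating method.

## Zooarchaeological bookkeeping

`select_for_zooms()` applies the five sampling criteria used to choose
unidentified fragments for destructive analysis: size above 2 cm, visible
trabeculae, scarce taphonomic alteration (combustion, manganese,
concretion; the tolerated number of alterations is a configuration, since
"scarce" has no published cutoff), known excavation position, and adequate
cortical bone.

`tally_counts()` implements the NISP conventions of published site tables:
the determinate percentage uses the whole assemblage as denominator;
order-group percentages (Lagomorpha / Carnivora / Ungulata) use the site's
total NISP; per-taxon percentages use the taxon's order-group NISP. This
two-level denominator convention was reverse-engineered from worked
examples (112 of 509 ungulates = 22%; 44 of 55 carnivores = 80%) and is
enforced consistently, with half-up rounding to one decimal and whole
numbers printed bare. The tests enforce the conservation identities
(statuses partition the assemblage; group NISP sums to site NISP; taxon
NISP sums to group NISP; percentages normalise within rounding slack) —
published tables occasionally violate these identities internally, and the
package treats that as a property of the source data, not a convention to
replicate.

`integrate_zooms_nisp()` adds molecular determinations (including
group-level categories) beside the morphological NISP without double
counting: a specimen already determined morphologically keeps its
morphological identity and the conflict is warned about.

## The synthetic generator

`simulate_spectrum()` renders, on the 700--3500 m/z grid: Gaussian peaks
(constant width, sigma 0.08 Th) with theoretical isotope envelopes at every
marker of one taxon; the two deamidation targets as the
$\alpha$-mixture of native and shifted envelopes; a decaying polynomial
baseline plus a constant chemical-noise floor (four noise standard
deviations, so the non-negativity clamp does not truncate the noise
distribution); and additive Gaussian noise. Degradation is modelled as
independent marker dropout — each collagen peptide, targets included,
survives with probability $1 - p_{\text{dropout}}$ — plus whatever noise
level the configuration sets. This is the simplest mechanism that
reproduces the empirical link between collagen preservation, screening
success and deamidation; it does not model ionisation suppression,
mass-dependent resolution, calibration drift, or real chemical noise
structure, so passing tests demonstrate correctness of the pipeline's
logic, not instrument-level realism.

Default conditions: peak S/N 20, noise 5% of the reference peak height,
baseline amplitude 20%, peak width 0.08 Th. Everything is reproducible from
the seed alone; per-sample seeds in `simulate_assemblage()` derive from the
master seed.

## Problem sizes in the test suite

The packaged checks use, as the package's own choices: noiseless recovery
on 100-sample single-site assemblages; preservation-gradient ordering on
paired 50-sample sites (dropout 0.7 vs 0.05) over 20 seeded runs; %Gln
recovery at 2% multiplicative envelope noise with 50 fits per mixture
level; and oracle equivalence of marker matching on 1,000-row random
tables. The reproduction script (`scripts/acceptance.R`) repeats the same
computations with 10 seeded pairs for the ordering benchmark.

## Known limitations

* Identification quality is bounded by the supplied marker table; the
  packaged table is synthetic and illustrative only.
* Charge deconvolution, recalibration and vendor raw formats are out of
  scope (mzML and two-column text are supported; profile data assumed).
* MNI estimation and morphological identification are outside the package:
  the former needs element/side/age conventions the screening data do not
  carry, the latter is human expertise that the software only flags for
  (`needs_morphological_review`).
* %Gln is reported per peptide as a relative preservation proxy within an
  assemblage; cross-study comparison is confounded by extraction protocol
  and burial environment.
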