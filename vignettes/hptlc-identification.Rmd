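---
title: "Identifying phenolic compounds from HPTLC band signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying phenolic compounds from HPTLC band signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hptlcID)
```

## The identification problem

High-performance thin-layer chromatography separates the non-sugar
constituents of a honey extract into bands on a silica plate. Unlike
column-based techniques, a single HPTLC run yields several independent
descriptors per band: the retention factor (Rf, the band's migration
distance relative to the solvent front), the band's colour under 254 nm and
366 nm illumination, its colour again after spraying with a derivatisation
reagent (NP-PEG, the natural-product reagent with polyethylene glycol, read
at 366 nm; or vanillin-sulfuric acid, VSA, read at 366 nm and in white
light), and full UV-Vis and fluorescence spectra from a densitometer before
and after derivatisation. No single descriptor identifies a compound -
dozens of phenolics share any given Rf window - but their conjunction is
highly discriminating.

`hptlcID` implements this conjunction as a transparent, auditable pipeline:
a reference library of 107 standards, a cascade of tolerance filters that
shortlists candidate identities, an overlay scorer that compares full
spectra, and consolidation of results across derivatisations and mobile
phases.

## The reference library

Each standard is recorded under two mobile phases - MPA
(toluene:ethyl acetate:formic acid 2:8:1 *v/v/v*) and the less polar MPB
(6:5:1) - giving the four database views 1A (MPA, NP-PEG), 1B (MPA, VSA),
2A (MPB, NP-PEG) and 2B (MPB, VSA). Colour is stored as a hue angle,

$$H^\circ = \frac{180}{\pi}\,\mathrm{atan2}\!\big(\sqrt{3}\,(G-B),\; 2R-G-B\big)
\quad (+360 \text{ if negative}),$$

which collapses an RGB reading into one comparable number; saturation and
lightness are discarded as they vary with application volume and
illumination far more than hue does. Achromatic pixels (R = G = B) have no
hue; the conversion raises a typed error rather than returning 0°, because
a silent 0 would spuriously match red-hued standards. Hues are binned into
twelve contiguous 30° colour families; bins are half-open
$[\ell, \ell + 30)$ so printed two-decimal bounds such as "0.00-29.99"
leave no gaps.

Spectra are summarised by the wavelengths of their extrema: fluorescence
λmax and λmin and one to three UV-Vis λmax values before derivatisation,
and single fluorescence/UV-Vis λmax values after. Absent peaks are encoded
as absence - a printed 0 placeholder is never stored as a wavelength, since
0 nm is physically meaningless and would corrupt the tolerance filters.
The library TSV round-trips field-for-field through
`load_library()`/`write_library()` and is validated on load (unique
contiguous codes, Rf in [0, 1], hues in [0, 360), wavelengths in
[190, 900] nm, ascending peak lists).

```{r summary}
summary(hptlc_library())
```

## The filter cascade

`run_cascade()` applies the view's stage sequence in order - Rf, hues,
fluorescence λmax/λmin, UV-Vis λmax, UV-Vis peak count, post-derivatisation
fluorescence and UV-Vis λmax - keeping at each stage only the candidates
within tolerance. The tunable tolerances, with their defaults:

| parameter     | default | unit | rationale                                  |
|---------------|---------|------|--------------------------------------------|
| `rf_tol`      | 0.05    | Rf   | inter-run Rf drift (humidity, plate batch) |
| `hue_tol`     | 60      | °    | colour drift across runs and reagent age   |
| `lambda_tol`  | 15      | nm   | scanner λmax repeatability (≈ ±2%)         |
| `uv_post_tol` | 60      | nm   | derivatisation shifts λmax far more        |

Numerical choices worth stating explicitly:

* **All bounds are inclusive** (`|Δ| ≤ tol`). The packaged validation data
  contain candidates that survive at exactly 15 nm and at exactly 60°, so
  a strict inequality would visibly change recorded outcomes.
* **Hue comparison is circular by default**: the distance between 36° and
  345° is 51°, not 309°. The white-light hue of VSA-derivatised bands
  straddles the red/scarlet boundary at 0°/360° routinely, and a recorded
  validation run retains a 345° standard against a 36° query - only the
  circular reading is consistent with that. A non-circular mode
  (`wrap_hue = FALSE`) is kept as a sensitivity switch.
* **UV peak matching is positional on ascending lists with equal length
  required.** The validated behaviour for one-peak queries is count-based
  elimination; requiring positional agreement within `lambda_tol`
  generalises it to multi-peak queries and reproduces the recorded
  two-peak (kaempferol/isorhamnetin) outcomes. The first-λmax filter and
  the peak-count filter are separate stages, mirroring how the validation
  traces tabulate them.
* **Post-derivatisation comparisons use λmax only** - the library stores no
  post-derivatisation fluorescence λmin, so no such stage exists.
* **A band attribute that was not measured skips its stage with a warning**
  rather than failing all candidates: honey bands are routinely evaluable
  under only a subset of conditions. A candidate lacking a value for a
  stage the band does supply fails that stage, since the match cannot be
  confirmed.
* **Resuming from a recorded Rf-survivor list.** Rf varies run to run; the
  library stores reference-run values, and a specific plate run's Rf stage
  may retain candidates whose reference Rf sits just outside ±0.05 of the
  query. Recorded validation observations therefore carry their own
  Rf-survivor lists, and `run_cascade(stages = ...)` can start at the
  254 nm hue stage over that list. Full-sequence runs (e.g. the self-match
  and jitter-recovery properties) use all stages.

Because the stages are independent conjunctive predicates, the final
survivor set is order-invariant (the intermediate counts are not); the test
suite verifies this against a brute-force oracle that evaluates the
conjunction per candidate directly.

## Spectral overlay and decision rules

`score_overlay()` clips both spectra to a comparison window, normalises
each to its **windowed** maximum (the comparison is explicitly windowed, so
the window maximum - not the global λmax - is the meaningful reference
point), linearly interpolates the standard onto the unknown's wavelength
grid, and reports two statistics: the Pearson correlation of the paired
normalised intensities, and the percentage of the **unknown's** grid points
(the natural denominator: the question is how much of the unknown's trace
the standard explains) lying within ±0.125 normalised AU of the standard.
Correlation is scale-invariant, so whether it is computed on raw or
normalised clipped intensities is immaterial; it is computed on the
normalised pairs. A constant (zero-variance) clipped spectrum has no
defined correlation and raises an error rather than returning `NA`.

Default windows: UV-Vis 250-500 nm before derivatisation and after NP-PEG
(mobile-phase solvents absorb below 250 nm), 230-600 nm after VSA, and
210-270 nm for fluorescence. Recorded practice shows both 230 and 250 nm
as the lower VSA bound in different places; the methods-grade value of
230 nm is the default and the window is configurable everywhere.

`decide_scores()` walks the state sequence UV-pre → UV-NP-PEG → UV-VSA →
fluorescence (fluorescence only ever arbitrates what UV-Vis could not).
At each state the top candidate wins only if it leads the runner-up by
**strictly more than** 0.100 in correlation or, failing that, by strictly
more than 10 percentage points in percent-within - correlation is consulted
first, percent as the tiebreak, matching how the validated discriminations
were argued. Gaps of exactly 0.100 or exactly 10 points escalate. Absolute
floors (defaults r ≥ 0.8 and percent ≥ 50 on the decisive state) reject
bands whose *best* candidate still overlays poorly - this reproduces the
negative-control rejection (best r 0.922 at only 41.8% within band) while
passing the positive controls. No recorded floor value exists, so the
floors are explicitly configurable and may be disabled (`floors = NULL`).
If no state separates the candidates the full set is returned as
ambiguous; a final visual inspection of the overlays remains good practice,
and borderline verdicts should not be over-interpreted.

```{r decide}
decide_scores(data.frame(
  candidate = c("methyl syringate", "syringic acid"),
  state = "uv_np", pearson_r = c(0.939, 0.986),
  percent_within = c(78.9, 100.0)))
```

## Consolidation

Within a mobile phase a credible identity must survive both derivatisation
cascades: `consolidate_pair()` is a strict intersection. Across mobile
phases, `cross_solvent_report()` reports compounds found in both sets as
double-identified but **retains** single-set finds: a band well resolved in
one solvent system may co-migrate with others in the second, so absence
there is weak evidence. Interpretation of single identifications is left
to the analyst.

## The synthetic generator

`make_spectrum()` builds spectra as sums of Gaussian peaks on a regular
grid with seeded Gaussian noise, and `jitter_band()` re-measures a library
standard in silico by shifting every attribute uniformly within a chosen
fraction of its filtering tolerance (hues wrap around the circle). These
emulate exactly what the scoring and matching contracts depend on - smooth
unimodal absorbance features and bounded measurement drift - and nothing
more: no real chromophore band shapes, no baseline drift, no derivatisation
chemistry, no correlated channel noise. Passing tests therefore demonstrate
the correctness of the filtering/scoring logic under the stated drift
model, not instrument-level robustness; the recorded spiked-honey
validation traces carry that burden.

## Problem sizes and test design

The property suite runs, per execution: 1,000 random-band cascades checked
against the brute-force conjunction oracle, self-match of all 107 standards
in all four views, jitter-recovery of all standards at 20 seeds below half
of each tolerance, and 100 random spectrum pairs checked against a
direct-summation overlay oracle - sizes chosen to exercise every stage
combination across the hue circle and peak-count classes while keeping the
whole suite fast enough to run on every change. All randomness is seeded;
reruns are deterministic.

## Known limitations

* The library stores one reference signature per standard; concentration
  dependence of hue and of minor λmax values is not modelled.
* Overlay verdicts for genuinely dissimilar chemistry can still correlate
  highly over a narrow window; the percent-within statistic and the floors
  mitigate but do not eliminate this, and the recorded honey-band verdicts
  show that visual inspection contributed to accept/reject calls that no
  single floor reproduces.
* Peak picking from raw chromatograms, plate-image colour extraction and
  quantification are out of scope; inputs are the already-tabulated band
  attributes and exported two-column spectra.
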