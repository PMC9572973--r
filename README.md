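# hptlcID

Identification of phenolic compounds in complex natural-product matrices
(typically honey extracts) from high-performance thin-layer chromatography
(HPTLC) band signatures.

HPTLC plates yield unusually rich per-band data: the retention factor
(Rf), the band's colour under several imaging conditions, and full UV-Vis
and fluorescence spectra recorded by a densitometer, each before and after
chemical derivatisation (NP-PEG, i.e. natural-product reagent with
polyethylene glycol, and VSA, vanillin-sulfuric acid). `hptlcID` turns those
measurements into compound identifications in three steps:

1. **Reference library.** A packaged library of 107 standards (flavonoids,
   hydroxybenzoic/hydroxycinnamic acid derivatives, simple phenols and a few
   non-phenolic honey constituents) stores, per compound: Rf in two mobile
   phases (MPA = toluene:ethyl acetate:formic acid 2:8:1; MPB = 6:5:1), hue
   angles H° under five imaging conditions, fluorescence λmax/λmin and
   UV-Vis λmax values before derivatisation, and fluorescence/UV-Vis λmax
   after each derivatisation. Band colours are reduced to a single hue angle

   H° = atan2(√3·(G − B), 2R − G − B) · 180/π  (mapped into [0°, 360°)),

   binned into twelve 30° colour families (Red, Orange, ..., Scarlet).
   The library is consulted through four views - 1A (MPA, NP-PEG),
   1B (MPA, VSA), 2A (MPB, NP-PEG), 2B (MPB, VSA).

2. **Cascade filtering.** An unknown band is compared against a view by an
   ordered sequence of inclusive tolerance filters: Rf ± 0.05, each hue
   ± 60° (circularly), fluorescence λmax and λmin ± 15 nm, UV-Vis λmax
   ± 15 nm plus an exact peak-count match, then post-derivatisation
   fluorescence λmax ± 15 nm and UV-Vis λmax ± 60 nm (derivatisation
   causes larger bathochromic/hypsochromic shifts). Each stage keeps only
   the candidates passing it; the full audit trace of survivor counts is
   returned.

3. **Spectral overlay.** Shortlisted candidates are confirmed by overlaying
   spectra: both curves are clipped to a comparison window (UV-Vis 250-500 nm
   before derivatisation and after NP-PEG, 230-600 nm after VSA;
   fluorescence 210-270 nm), normalised to their windowed maxima, and scored
   by Pearson correlation r and the percentage of the unknown's points lying
   within ± 0.125 normalised absorbance units of the candidate's curve.
   Among close candidates, the winner must lead by more than 0.100 in r or,
   failing that, by more than 10 percentage points in percent-within;
   otherwise the next spectrum state in the sequence (UV pre → UV NP-PEG →
   UV VSA → fluorescence) is consulted. Optional absolute floors
   (r ≥ 0.8, percent ≥ 50 by default) reject bands whose best candidate
   still overlays poorly. Matches surviving both derivatisation views of a
   mobile phase are "consolidated"; compounds found in both mobile-phase
   sets are "double-identified".

## Worked example

A band of an artificial honey spiked with syringic acid, measured in MPA
with NP-PEG derivatisation (Rf 0.608, hues 139.3°/180°/209.2°, fluorescence
λmax/λmin 225/258 nm, one UV-Vis maximum at 276 nm, post-derivatisation
fluorescence 239 nm and UV-Vis 288 nm), matched against view 1A restricted
to that run's 42 Rf-stage survivors:

```r
library(hptlcID)
lib <- hptlc_library()
fx  <- yaml::read_yaml(system.file("extdata", "validation_bands.yaml",
                                   package = "hptlcID"))$compound_a$mpa_np
band <- do.call(band_observation, lapply(fx$band, \(v) as.numeric(unlist(v))))
view <- select_view(lib, "1A", codes = unlist(fx$rf_candidates))
trace <- run_cascade(band, view, stages = setdiff(stage_sequence("1A"), "rf"))
print(trace)
#> Cascade trace (view 1A):
#>   hue_dev254     (tol 60):  42 candidate(s)
#>   hue_dev366     (tol 60):  40 candidate(s)
#>   hue_np366      (tol 60):  31 candidate(s)
#>   fl_pre_max     (tol 15):  31 candidate(s)
#>   fl_pre_min     (tol 15):  25 candidate(s)
#>   uv_pre_lambda  (tol 15):  11 candidate(s)
#>   uv_pre_peaks   (tol peak count):   6 candidate(s)
#>   fl_np_max      (tol 15):   5 candidate(s)
#>   uv_np_max      (tol 60):   5 candidate(s)
#>   potential matches: 36, 43, 48, 58, 67
```

The cascade narrows 42 candidates to five: 2,3,4-trihydroxybenzoic acid
(36), eudesmic acid (43), methyl syringate (48), syringic acid (58) and
m-coumaric acid (67). The companion VSA view (1B) narrows its 32 candidates
to just methyl syringate and syringic acid, so the consolidated shortlist is
the syringate pair. The overlay decision rules then discriminate them: on
the post-NP-PEG UV-Vis overlay the correlations (0.939 vs 0.986) are too
close to call, but 100.0% of the band's points fall within ±0.125 AU of
syringic acid against 78.9% for methyl syringate - a gap above the
10-point threshold:

```r
scores <- data.frame(candidate = c("methyl syringate", "syringic acid"),
                     state = "uv_np", pearson_r = c(0.939, 0.986),
                     percent_within = c(78.9, 100.0))
decide_scores(scores)
#> Decision: matched candidate syringic acid on state uv_np
```

A shell front-end with the same functionality ships in `inst/cli/hptlc-id`
(subcommands `summary`, `match`, `overlay`, `consolidate`, `synth`).

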