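---
title: "Methods: lipophagy screening statistics and the nested case-control pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipophagy screening statistics and the nested case-control pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`liposcreen` implements the computational core of an image-based
high-content screen for lipophagy activators together with its companion
nested case-control analysis, and ships a synthetic-data layer so that
every downstream stage is testable against known ground truth without any
external download. This vignette is the package's own account of the
models, parameter choices and numerical conventions; it states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

# The reporter and the per-well score

The screen images HepG2 hepatocytes carrying a tandem GFP–mCherry reporter
anchored to lipid droplets, plus nuclear TagBFP. GFP is quenched at
lysosomal pH while mCherry persists, so droplets delivered to
autolysosomes lose GFP but keep mCherry. The per-well readout is the
**lipophagy score**

$$ s \;=\; \frac{F_{\mathrm{mCherry}} - F_{\mathrm{GFP}}}{N_{\mathrm{cells}}}, $$

where both fluorescence totals are integrated over the mCherry-positive
area and \(N_{\mathrm{cells}}\) is the TagBFP nucleus count. The score can
legitimately be negative. A well with an empty mCherry mask scores 0 and
is flagged `EMPTY_MASK` (a compound that abolishes droplets is a
biological result); a well with zero nuclei is an assay failure and is
flagged `NO_CELLS` (the scalar scoring function raises an error instead of
fabricating a 0).

## Segmentation conventions

The vendor software parameters behind the original quantification are not
published, so this package adopts an explicit, robust convention:

* channels are smoothed with a Gaussian (sigma `smoothing_radius`, default
  1 px);
* the threshold is `median + k * max(MAD, mad_floor)` over the whole
  smoothed raster, with `k_nuc = 6` (BFP) and `k_mch = 4` (mCherry).
  Robust statistics were preferred over Otsu because most wells are
  sparse-signal: the background dominates, and median/MAD are insensitive
  to the signal fraction;
* the MAD is the Gaussian-consistent `stats::mad()` (constant 1.4826).
  `mad_floor` (default 2 counts) exists because on a noiseless or blank
  raster the MAD collapses to 0 and a bare-median threshold would select
  arbitrarily faint Gaussian tails; the floor pins the noiseless threshold
  at the quantisation scale. When a noiseless render serves as the
  ground-truth mask for a noisy measurement, the two must be thresholded
  at matched levels: the noiseless MAD is floored at the analytically
  expected smoothed-noise scale `noise_sd / (2 sigma sqrt(pi))`
  (`expected_smoothed_noise_sd()`). A residual ~7% area deficit remains
  because droplet pixels inflate the measured MAD at ~20% signal
  coverage; this is a property of whole-raster robust thresholds, sits
  well inside the 10% acceptance band, and is documented rather than
  hidden;
* connected components are 8-connected, components below
  `min_blob_area_px = 4` are discarded; pixels are atomic (a pixel is in
  or out), indexing is row-major with the origin at the top left.

Nucleus count equals the number of surviving BFP components; the
paper-level identification of TagBFP dots with cell number is taken over
as-is.

# The synthetic world

The generator is a stated world, not a tuning dial; its defaults were
fixed before the acceptance battery was run.

* **Plate geometry.** 384-well plates (16 × 24); compound plates carry 352
  compound wells and 32 vehicle (DMSO) control wells placed by stratified
  sampling over the row-major order so they sample the positional field;
  a separate all-DMSO plate provides the position correction, matching the
  screen design (~3500 compounds, ≈10 plates).
* **Cells.** 120 cells per well at 256 × 256 px (scaled fixtures use 25
  cells at 128 × 128). Counts are truncated-normal with CV 5%, the
  well-to-well repeatability of an automated dispenser; Poisson counting
  noise would overstate the variation of a dispensed suspension.
* **Geometry.** Nuclei are isotropic Gaussian blobs (sigma = 0.4 × radius,
  radius 3 px) on a jittered grid with pitch six radii and jitter ± one
  radius, guaranteeing ≥ 4 radii separation so connected-component
  counting is well posed — the generator's contract with the counter, not
  a claim about confluent monolayers. Droplets (radius 1.5 px, ~3 per
  cell, Poisson) sit in an annulus of 1–2 nucleus radii around their
  parent nucleus and are rendered identically in GFP and mCherry except
  for the quench factor `1 - quench_fraction` on GFP.
* **Noise and gain.** Gaussian read noise (SD 8 counts on a background of
  100) by default; Poisson shot noise is available but off, so fixed seeds
  give bit-identical rasters. Each channel's per-well gain is lognormal
  with CV 5%. This gain term is the dominant null variation of the score:
  GFP and mCherry share droplet geometry exactly, so without it the null
  score spread would collapse to read noise and hit calling would be
  unrealistically easy. With it, a fully quenched active (quench 0.9)
  sits at an expected robust Z of roughly 8–9 — strong, as in the original
  screen, but not trivial.
* **Toxicity.** Spiked toxic wells have viability factor 0.5, well below
  the 80% exclusion boundary.
* **Position artifact.** An additive per-well offset, linear in plate row
  and column, applied to chosen channels. With equal amplitudes on GFP and
  mCherry the offset cancels inside the score (the robust threshold shifts
  with the median and the two integrals shift equally); with
  channel-specific amplitudes cancellation happens at the DMSO-conversion
  step instead. The exact-cancellation identity of subtract-mode
  conversion is exercised directly by injecting a gradient into the
  per-well scores of both plates.
* **What the generator does not emulate.** Optical PSFs, 3D structure,
  cell-shape variation, droplet size distributions beyond a lognormal
  brightness factor, plate-to-plate batch effects, or edge evaporation.
  A green spike-in test therefore establishes that the statistics recover
  a stated effect under the stated noise — not that the segmentation
  would survive arbitrary real-world imagery.

# Screening statistics

**DMSO conversion.** The paper converts raw scores "according to the
value of the DMSO-treated plate for all wells" without naming the
operation. Default is positional subtraction
(`converted(w) = raw(w) - dmso(w)`), because scores may be ≤ 0 and
division is unstable near zero; `divide` mode is retained for sensitivity
analysis and refuses near-zero denominators.

**Robust Z.** `Z_i = (x_i - median(x)) / (1.4826 * MAD(x))`. The paper's
"converted robust standard deviation" names no estimator; 1.4826 × MAD is
the Gaussian-consistent convention. Pooling is across all compound wells
of the run ("all sample"); per-plate pooling is a config option since the
paper does not state which was used. A zero MAD is a degenerate-scale
error, never a silent division.

**Toxicity gate.** Toxic ⇔ `cell_count < 0.80 * reference`, strict, with
the reference being the median cell count of the DMSO control wells of
the same run — the paper prints "<80%" but not the denominator; the DMSO
median is this package's convention. A well at exactly 80% is retained.

**Hits.** Hit ⇔ `Z > 3` (strict, "3<") and not toxic; exclusion precedes
calling, so a toxic well is never a hit regardless of Z. The hit list is
sorted by descending Z with ties broken by well address.

**Fold change** is a ratio of group medians; a non-positive control
median yields `NA` flagged `UNDEFINED_FOLD`.

# Flow-cytometry gating

Event tables are plain data frames (CSV on disk; FCS parsing is out of
scope). Gates are conjunctions of per-channel `above` (≥) / `below` (<)
predicates on raw or `log10(x+1)` intensities. The original gates were
drawn interactively in vendor software, so thresholds here are explicit
parameters; the one objective default is the surface-marker rule: the
positivity threshold is the 99th percentile of a negative-control (e.g.
knockout) sample, giving a ~1% false-positive anchor.

# Nested case-control pipeline

**Filters.** Exclusion if any required field is missing, NYHA class
II–IV heart failure, or age outside 20–80 (inclusive). Reason counts are
booked with precedence missing → heart failure → age; the precedence is
bookkeeping only — total exclusions are precedence-independent. Duplicate
subjects keep the most recent ultrasound record when a date exists.

**Matching.** The source states the criteria (age, sex, BMI, AF; 1:1) but
no algorithm. This package uses greedy nearest-neighbour matching without
replacement: exact on sex and AF; eligibility within calipers of ± 2
years and ± 1 kg/m²; distance `|Δage|/2 + |Δbmi|/1`; cases with the
fewest eligible controls are matched first (scarcity-first), ties go to
the lowest control id, and unmatched cases are dropped and reported.
Optimal matching is a non-goal. The procedure is fully deterministic; the
seed argument is reserved.

**Tests.** The 2 × 2 chi-square is the closed form
`n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with optional Yates correction. The
Mantel–Haenszel test pools sex × AF strata (the matching cells) by
default — the original stratification behind the printed P = 0.025 is not
stated, so that P is flagged as non-reproducible without subject-level
data rather than imitated. The common OR is `Σ(ad/n) / Σ(bc/n)` with a
Robins–Breslow–Greenland standard error; continuous covariates are
compared by Welch's t-test (equal-variance optional), with p = 1 by
convention when both groups are degenerate with equal means.

**Registry generator.** Digoxin is prescribed preferentially to AF and
older subjects (the confounding that motivates matching); fatty liver
follows a logistic model whose digoxin coefficient is the stated
conditional odds ratio (default 0.58, protective). With
`confounding = 0` the crude 2 × 2 odds ratio is consistent for the
conditional one, which is how the generator is validated against itself.
With confounding on, the matched-cohort MH estimate recovers the
generating OR within Monte-Carlo error; a small residual attenuation
toward the null (odds-ratio non-collapsibility over the within-caliper
covariate spread) is expected and is well inside the 3-SE acceptance
band at n = 10^5. Numbers echo the study's frame: baseline fatty-liver
prevalence 23.8%, exposure ~2%, BMI ~22.5 (lean East-Asian cohort), ages
centred at 62 with tails outside the 20–80 window so the filters have
work.

# Assay conversions

Closed forms as printed in the source protocols:
insulin µIU/mL = 26 × ng/ml; HOMA-IR = insulin × glucose / 405;
FAO IU/l = 12.96 × (OD492 reaction − control), with negative net OD
clamped to 0 and flagged (negative enzyme activity is non-physical; the
kit sheet is silent).

# Numerical and I/O decisions

* All randomness flows from integer seeds through per-call substreams;
  nothing touches the global RNG state. Scene and noise use separate
  substreams so a noiseless rerun reproduces the identical scene.
* Pixels are clipped to `[0, 2^bit - 1]` and rounded; 16-bit default.
* Images travel as uncompressed little-endian multi-page TIFF (one page
  per channel, order BFP/GFP/mCherry) via a minimal built-in reader and
  writer, because the target R stack ships no TIFF package; the subset is
  round-trip tested.
* Run configs are JSON rather than YAML (no YAML parser in the target
  stack); plate maps, registries, event tables are CSV; quantifications
  and screen results are TSV; run summaries are JSON stamped with the
  seed and an FNV-1a config hash.
* CLI exit codes: 0 success, 2 input error, 3 degenerate-statistics
  error, mapped from typed R conditions.

# Known limitations

* Segmentation is validated against the package's own synthetic renders,
  not against vendor-software output on real images.
* The greedy matcher is order-dependent by construction; scarcity-first
  ordering mitigates but does not optimise.
* The MH stratification (sex × AF) is a convention; the printed P = 0.025
  of the source table is deliberately not an acceptance value.
* Acceptance image runs are scaled (one full 256 × 256 screen, the rest at
  128 × 128) to stay inside runtime budgets; scaling changes runtime only,
  never thresholds or tolerances.
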