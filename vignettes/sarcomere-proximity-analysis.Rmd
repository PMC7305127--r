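---
title: "Methods: proximity-labeling analysis of the sarcomere"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proximity-labeling analysis of the sarcomere}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcoprox)
```

`sarcoprox` analyzes in vivo BioID experiments in which a promiscuous
biotin ligase is knocked into a sarcomeric protein and biotinylates
lysines within its reach. This vignette is the package's own account of
the underlying models, the parameters that matter, the numerical
conventions, and what the synthetic-data tests do and do not demonstrate.

## The spatial model

### Contour-length geometry

Sequence separation is converted to physical length with two constants:

* `folded_domain_length_nm = 4.0` — a folded Ig-like domain spans ~40 Å
  end to end, essentially independent of its residue count;
* `unstructured_nm_per_residue = 0.4` — an extended unstructured region
  contributes ~4 Å per amino acid.

`residue_distance()` sums these along the chain. Two conventions deserve
note:

1. **Partially spanned folded domains count in full.** Intra-domain
   geometry is not resolvable from sequence, and a rigid domain moves as a
   unit, so any traversal into a folded domain adds its full 4.0 nm.
   Concretely, a unit step between consecutive residues contributes
   0.4 nm whenever either endpoint is unstructured, and each folded
   domain traversed by at least one fully interior step contributes one
   flat 4.0 nm. This makes the distance symmetric, zero only on identical
   positions, and monotone in sequence separation. Exact additivity fails
   only when a path is split *inside* a folded domain (the flat term
   would be counted twice); the triangle inequality always holds.
2. **Distances are contour lengths**, i.e. maximal reach along the chain,
   not through-space Euclidean distances. The radius-of-action estimate
   is therefore an upper bound on the ligase's reach, which matches how a
   "range of activity" is interpreted when mapping labeled sites onto a
   domain diagram.

`estimate_radius()` reports the min–max contour distance from the
insertion residue to the member sites of the primary hotspot, excluding
sites at the insertion residue itself.

### Hotspots and dwell time

Filtered sites are clustered single-linkage along the residue axis:
consecutive sites are merged while their contour gap is at most
`merge_gap_nm = 30`. The default is twice the ~15 nm outer labeling
radius — two sites reachable from a single tether position belong to the
same hotspot. Each hotspot's aggregate intensity is the **sum of
per-site medians across knock-in replicates**, with missing values
(intensity 0) excluded; the median is robust to the left-censored dropout
typical of label-free MS. A mean aggregate is available via the
`aggregate` argument. Ties in the primary ranking are broken by smaller
span, then lower start residue, so results are deterministic.

The dwell model assumes the amount of biotinylation is proportional to
the duration of colocalization. The secondary/primary intensity ratio is
then itself the fraction of the contraction cycle the two regions spend
within labeling range, and

\[ t_\text{dwell} = f \times T_\text{cycle}, \qquad T_\text{cycle} = 0.15\ \text{s (murine heart)}. \]

Ratios are legitimate data summaries and may exceed 1; clipping to [0, 1]
happens at the `dwell_fraction()` step (with a warning), not at
`hotspot_ratio()`. No alternative (non-proportional) model is
implemented; disabling the proportionality flag raises an error rather
than silently changing the model.

## Site filtering

A biotinylation site is called knock-in-specific when it has at least
`min_valid_knockin = 3` valid values (intensity > 0) in the knock-in
group **and** at least `min_excess_over_wildtype = 2` more valid values
than in the wild-type group. Both inequalities are weak. Note that at
parameters (0, 0) the excess rule still requires at least as many
knock-in as wild-type valid values; the filter is the identity only on
tables where that holds.

Contaminants and reverse-database hits are recognized both by id prefix
(`CON__`, `REV__`) and by `+` marker columns, whichever the file dialect
provides. Intensity 0 and an empty cell both mean missing; negative
intensities are format errors, as are missing sample columns.

## Enrichment statistics

The protein-level pipeline mirrors the Perseus label-free workflow:

1. **Valid-value filter**: keep proteins with ≥ 3 valid values in *at
   least one* genotype group. The alternative strict reading (≥ 3 in
   *every* group) is available via `scope = "each"`; the "at least one
   group" semantics is the common default for enrichment designs where
   controls are expected to be empty.
2. **log2 transform**, zeros to `NA`.
3. **Down-shifted imputation**: each missing cell is drawn from
   `Normal(μ_obs − 1.8 σ_obs, (0.3 σ_obs)²)`. Statistics are computed per
   sample column by default (`per_column = TRUE`); whole-matrix statistics
   are available, since both conventions are in circulation and the
   choice is not derivable from the workflow description alone.
4. **Two-sample Student's t-test** (equal variance, two-sided); Welch is
   available by flag. A zero-variance row with equal means is defined as
   `t = 0, p = 1`, not an error.
5. **Permutation FDR**: genotype labels are reassigned
   (`n_permutations = 250` by default; when fewer distinct reassignments
   exist — e.g. 69 for 4 vs 4 excluding the observed labeling — all are
   enumerated and the count recorded). For protein \(i\),
   \[ q_i = \frac{\frac{1}{B}\#\{(b,j): |t'_{bj}| \ge |t_i|\}}{\#\{j: |t_j| \ge |t_i|\}} \]
   clipped to [0, 1] and made monotone non-increasing in \(|t|\) by
   step-up enforcement (each q may not exceed the q of any less
   significant protein). An SAM-style moderation constant `s0` is
   supported but defaults to 0, since the workflow being reproduced
   states none.
6. **Call**: significant ⇔ `q < 0.05` ∧ `peptides ≥ 3` ∧ `log2FC > 0`
   (enrichment in the knock-in direction only). No fold-change floor is
   applied beyond the sign constraint.

## Profile quantification

Profiles are uniformly sampled multi-channel 1D traces. All fractional
thresholds operate on the min–max-normalized channel over the analysis
window, which makes every measurement invariant to channel gain; the
normalization window is the analysis box, not the full image line.
Numerical conventions:

* **Threshold crossings** (75% edges, 25% presence, half maximum) are
  located by linear interpolation between adjacent samples, giving
  deterministic sub-pixel positions.
* **Overlap intervals** are the maximal intervals where the pointwise
  minimum of the two normalized channels exceeds the presence fraction —
  equivalent to "both channels above threshold" on the sampled grid.
* **Peaks** are strict local maxima after 3-point moving-average
  smoothing, kept if the unsmoothed normalized value reaches the presence
  fraction and the topographic prominence on the smoothed curve reaches
  `min_prominence = 0.1`. The prominence filter exists because additive
  noise on the shoulder of a bright band otherwise produces spurious
  "secondary" peaks adjacent to the primary one.
* **Sarcomere length** is the mean spacing of consecutive α-actinin
  peaks; **Z-disc width** is the FWHM of the central actinin band.
* **Hotspot displacement** takes the global biotin maximum as the primary
  band, then the highest remaining peak at or outside the Z-disc edge
  interval as the secondary hotspot, and reports its distance to the
  nearer edge (0 at the edge, `NA` when no secondary peak exists — an
  absent value is distinguishable from a true zero).
* **Averaging** registers each replicate by translating its dominant
  actinin peak to position 0, then averages pointwise on the common
  lattice, reporting mean, SEM = sd/√n and the per-position n. Because
  sarcomeres are periodic, registration may align different Z-discs
  across replicates; the common-coverage region shrinks accordingly and
  the per-position n makes this explicit.
* An optional constant-background subtraction is deliberately **not**
  applied by default: soluble protein contributes background whose
  treatment upstream is acquisition-specific.

## The synthetic-data generator

The generator emulates the data structure of a knock-in vs wild-type
proximity-labeling study with known ground truth.

* **Distance decay.** No quantitative decay law for labeling efficiency
  vs distance is established; the generator uses a half-Gaussian in
  contour distance with scale equal to `labeling_radius_nm`, truncated at
  that radius (the radius is the maximal reach). This is a smooth,
  single-parameter stand-in, flagged as such.
* **Secondary hotspot.** Candidate lysines around the secondary residue
  receive expected intensities scaled so that the *expected* secondary
  aggregate equals `dwell_fraction` × the primary aggregate, whatever the
  local domain architecture — a "labeling budget" formulation that makes
  the conservation property exact at the level of expected intensities.
* **Noise.** MS intensities are multiplicative log-normal
  (`intensity_cv = 0.25`); imaging profiles carry additive Gaussian noise
  clipped at zero. These are the standard noise families for the two
  modalities.
* **MNAR dropout.** Missingness is logistic in log2 intensity with slope
  1 per log2 unit and midpoint 8 log2 units below the peak-site median —
  dropout confined to the low-abundance tail, at overall rates typical of
  label-free data. A midpoint of −∞ disables missingness.
* **Wild-type background** appears at rate 0.05 per cell at 1% of the
  knock-in intensity scale.
* **Profiles** place Gaussian Z-disc bands (FWHM = `zdisc_width_nm`,
  default 100 nm) spaced by the sarcomere length (default 2.0 µm), biotin
  bands at each Z-disc edge plus a weaker band `hotspot_offset_nm`
  (default 200 nm) outward, and an erf-edged myosin plateau of
  half-length 800 nm centered mid-sarcomere, all convolved analytically
  with a Gaussian PSF (`psf_sigma_nm = 30`, STED-like) and sampled at
  15 nm/pixel.

What the generator does **not** emulate: peptide-level effects
(digestion, fragmentation, match-between-runs), isoform complexity,
correlated replicate structure, 2D/3D image formation, or curved/bent
myofibrils. Passing parameter-recovery tests therefore demonstrates the
estimators' correctness under the stated generative assumptions, not
their robustness to every artifact of real acquisitions.

One estimator property worth knowing: because hotspot aggregation uses
the median of *valid* (non-missing) values, preferential dropout of low
draws inflates the dimmer cluster's aggregate slightly, biasing the
recovered dwell fraction upward by well under 1% relative at default
settings. The package's recovery studies disable dropout to isolate the
clustering/ratio estimator; the conservation property itself is exact in
expectation and tested exactly against the generator truth.

## Problem sizes and determinism

All randomness flows through explicit integer seeds (`withr::with_seed`),
and identical configuration + seed reproduces outputs bit-for-bit,
including the JSON pipeline reports (which embed the seed and a config
hash). The test suite exercises: imputation moments at 10⁵ cells;
permutation-FDR control on 50 global-null tables of 500 proteins (4 vs 4
replicates); dwell-fraction recovery over 200 simulations per setting
with 50 knock-in replicates; profile-geometry recovery over 9 replicate
traces; and brute-force oracle equivalence on 1,000 random instances per
primitive (site filter, min-valid filter, single-linkage clustering,
overlap intervals). These sizes give Monte-Carlo standard errors small
enough that 3-SE acceptance bands are meaningful while the full suite
runs in well under a minute.

## Known limitations

* The radius-of-action interval is a contour-length (maximal-reach)
  estimate; through-space distances can only be shorter.
* The dwell model is strictly proportional; saturation of biotinylation
  or variable biotin availability would break the linear readout.
* Permutation FDR with few replicates has a coarse permutation lattice
  (69 distinct reassignments for 4 vs 4), so attainable q values are
  quantized.
* The profile pipeline assumes well-separated, roughly periodic bands;
  heavily overlapping bands (e.g. secondary offsets below the PSF width)
  merge and are reported as a single band.
* JSON is the supported configuration format for the orchestration layer
  (`run_sites()`, `run_enrichment()`, `run_profiles()`).
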