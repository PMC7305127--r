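# sarcoprox

Analysis of in vivo **BioID proximity-labeling** experiments on striated
muscle. When a promiscuous biotin ligase is knocked into a sarcomeric
protein (e.g. at titin's Z-disc/I-band transition), the positions and
intensities of the biotinylated lysines it leaves behind encode spatial
information: which residues lie within the ligase's reach, how far that
reach extends in nanometers, and — because labeling accumulates with
contact time — what fraction of the contraction cycle two regions spend
juxtaposed. `sarcoprox` turns MaxQuant-style site and protein-group tables
and 1D super-resolution line profiles into those quantities.

It is aimed at proteomics and muscle-biology groups running knock-in
proximity-labeling studies with wild-type controls.

## What it computes

**Knock-in-specific site calling.** A site is ligase-specific when it has
at least 3 valid values (intensity > 0) in the knock-in group and at least
2 more valid values than in the wild-type group:

```
keep  ⇔  n_valid(KI) ≥ 3  ∧  n_valid(KI) ≥ n_valid(WT) + 2
```

**Sequence → physical distance.** Contour lengths along the annotated
chain: a folded Ig-like domain counts a fixed 4.0 nm (~40 Å) regardless of
residue count, unstructured regions 0.4 nm (4 Å) per residue. The ligase's
radius of action is the min–max contour distance from the insertion
residue to the sites of the primary hotspot.

**Hotspots and dwell times.** Sites are clustered single-linkage along the
residue axis (merge gap 30 nm by default); each hotspot's aggregate
intensity is the sum of per-site medians across knock-in replicates. Under
the assumption that biotinylation is proportional to colocalization time,

```
dwell fraction = I(secondary) / I(primary),   dwell time = fraction × T_cycle
```

with `T_cycle = 0.15 s` (murine cardiac cycle) by default.

**Enrichment statistics (Perseus-style).** Protein groups are filtered to
≥ 3 valid values in at least one genotype group, log2-transformed, missing
values imputed from `Normal(μ_obs − 1.8·σ_obs, (0.3·σ_obs)²)` per sample
column, tested with a two-sample Student's t-test, and controlled by
permutation-based FDR; a protein is called ligase-associated when
`q < 0.05`, `peptides ≥ 3`, and `log2FC > 0`.

**Profile quantification.** For two-channel sarcomere line profiles:
band peaks and FWHM, filament edges at 75% of the normalized signal,
channel-overlap intervals where both signals exceed 25%, the displacement
of the secondary biotin hotspot from the Z-disc edge, sarcomere length
from α-actinin peak spacing, and mean ± SEM trace averaging after
registration.

**Synthetic data.** `sim_config()` / `simulate_site_table()` /
`simulate_proteingroups()` / `simulate_profiles()` generate all inputs
with known ground truth — distance-decay labeling around the insertion,
a secondary hotspot carrying a configurable dwell fraction, log-normal
intensities with intensity-dependent (MNAR) dropout, wild-type background,
and noisy periodic two-channel profiles — so every stage is testable
without any external download.

## Worked example

```r
library(sarcoprox)

ann <- sim_annotation()                      # titin-like Z-disc architecture
cfg <- sim_config(seed = 7, insertion_residue = 300,
                  secondary_site_residue = 1200,
                  dwell_fraction = 0.075, n_knockin = 8)
tb   <- simulate_site_table(cfg, ann)        # 35 sites, 8 KI + 4 WT samples
kept <- filter_specific_sites(tb)            # knock-in-specificity rule
hs   <- detect_hotspots(annotate_sites(kept, ann), ann)
hs
#>   rank_label    center span_min span_max n_sites aggregate_intensity
#> 1    primary  300.6815      275      325      11             9097164
#> 2  secondary 1238.2712     1180     1295      24              719448

hotspot_ratio(hotspot_by_rank(hs, "secondary"), hotspot_by_rank(hs, "primary"))
#> [1] 0.0791
estimate_radius(ann, 300, hotspot_by_rank(hs, "primary"))
#> min_nm max_nm
#>      2     10
signif(dwell_time(dwell_fraction(0.0791)), 3)
#> [1] 0.0119
```

Reading: the primary hotspot sits around the insertion residue (center
~301), the secondary one at the far cluster (~1238). Its relative
intensity, 0.0791, recovers the simulated dwell fraction of 0.075; the
maximal contour distance of primary-hotspot sites from the insertion
recovers the simulated 10 nm labeling radius; and at a 0.15 s cycle the
secondary contact lasts ~0.012 s per beat.

The same stages run end-to-end from a JSON config via `run_sites()`,
`run_enrichment()` and `run_profiles()`, which write TSV/CSV tables and
JSON reports stamped with the seed and config hash.

## Package layout

- `R/` — site tables, geometry model, hotspots/dwell, enrichment
  statistics, profile quantification, simulation, pipeline orchestration
- `tests/testthat/` — unit, property and end-to-end acceptance tests with
  brute-force oracles
- `vignettes/sarcomere-proximity-analysis.Rmd` — the methods vignette:
  model assumptions, parameter choices, numerical conventions, limitations
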