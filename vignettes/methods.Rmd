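---
title: "Models and methods behind phosphoTMT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phosphoTMT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoTMT)
```

phosphoTMT implements the post-search computation for a six-group TMT
experiment — untransfected β-cells (CON), scrambled-siRNA controls (SC)
and DMT1-silenced cells (DMT1-KD), each with and without IL-1β exposure —
in three biological replicates, one 6-channel plex per replicate. This
vignette explains the quantification model, the statistical decisions,
the synthetic-data generator used for validation, and the limits of what
passing tests demonstrate.

## Quantification model

The quantification unit is the PSM (peptide-spectrum match) with one
reporter intensity per TMT channel. Two assumptions drive roll-up:

* **Unique-peptide rule.** Only peptides mapping to a single protein
  accession contribute. Shared peptides are ambiguous evidence and are
  excluded from both layers rather than fractionally assigned.
* **Layer separation.** Phosphorylated PSMs never enter the protein
  layer, so protein abundance is the *non-phosphorylated* abundance. This
  matters because the phosphopeptide layer is normalized with factors
  computed from that non-phosphorylated layer; a phosphorylation shift
  then cannot contaminate its own normalization anchor.

Protein abundance per sample is the plain sum of contributing PSM
intensities; sums skip missing cells, and a cell is missing (never zero)
when no PSM contributes. Zero is retained as a legal measurement.
Phosphopeptide features are keyed by sequence plus the sorted site set,
so `...S5...` and `...S5,T7...` of the same sequence are distinct
features — the site-set identity is what downstream reversion calls refer
to. Samples are identified by (group, replicate) across plexes; no
reference-channel bridging is applied because the design carries no
bridge channel.

### Normalization

Per-sample factors are `f_s = mean(totals) / total_s`, computed on the
totals of non-missing cells and applied multiplicatively; they are the
per-sample loading corrections that land in roughly [0.9, 1.1] for
well-balanced channels. We read the loading-correction factors as
multiplicative total-intensity equalizers rather than as a
standardization of per-sample variances: the alternative (scaling by the
SD of log-intensities) would not equalize loading and is not
implemented. Applying the procedure twice is a no-op (all follow-up
factors are 1), and the factors are recorded on the matrix for
provenance. Equalizing to the *mean* total makes the target depend
weakly on all samples, so multiplying one sample by k rescales that
sample's factor by 1/k up to the shift of the common target — relative
abundances are invariant, absolute values only up to the common scale.

Total-intensity normalization assumes regulation is roughly balanced;
strongly one-sided regulation (many up, few down) compresses the
apparent effect size by the shift it induces in the totals. The
generator's recovery scenarios keep the regulated fraction small
(≤ 10 %) for this reason, and the effect-convergence check on the
generator itself uses identity channel bias on the raw matrix, because
with random biases the per-sample loading offset is shared by every
feature's ratio until normalization removes it.

### Phosphosite filtering

A phospho-PSM is accepted iff *every* reported site probability is
≥ 0.75 (inclusive); accepted sites with probability strictly > 0.99 are
additionally classed "distinct". The strict all-sites rule is a
deliberate choice for the ambiguous case of one confident plus one
sub-threshold site: dropping the PSM is conservative and keeps the
feature key (sequence + site set) trustworthy, at the cost of some
sensitivity. The alternative — keeping the PSM with a reduced site set —
would merge it into a different feature and blur site-level claims.

## Differential analysis

For a comparison (numerator group vs denominator group) the replicate
log2 ratio pairs the two samples within each biological replicate.
Missing or zero values exclude that replicate only (no pseudocounts);
features with fewer than all replicates are flagged.

The test standardizes each feature's mean ratio against a robust
empirical null built from all features of the comparison: location is
the median, scale is 1.4826 × MAD. The robust moments keep the small
regulated minority from inflating the null scale; with mean/SD moments a
strong regulated tail would shrink every z. The cost is a breakdown
point, not bias: if more than half of all features were regulated in one
direction the null location itself would drift — none of the scenarios
here approach that. Two-sided p-values come from the standard normal,
and Benjamini–Hochberg adjustment is applied separately per comparison
and per layer (protein vs phosphopeptide), since each layer's calls are
reported as its own family. At least 20 features are required before the
null is estimated at all.

A significant call additionally requires:

* **Direction consistency** — all available replicate ratios strictly
  positive or strictly negative; a zero ratio breaks consistency (it is
  neither), and fewer than two available replicates is inconsistent by
  convention.
* **Transfection filter** — |mean log2(CON/SC)| ≤ 0.2 for unchallenged
  comparisons, |mean log2(CON-IL/SC-IL)| ≤ 0.2 for IL-1β comparisons.
  The window is read on the log2 scale, consistent with the ratio–ratio
  usage elsewhere in the analysis (the linear reading [0.8, 1.2] was
  considered and rejected: it is asymmetric in log space). For a
  comparison spanning both conditions (SC-IL vs SC) a feature passing
  *either* window is accepted; requiring a specific single window for a
  spanning comparison would make the filter depend on an arbitrary
  choice of which condition "owns" it. The filter runs before testing,
  but acceptance flags enter only the final conjunction, so the BH
  family size m is the full tested set and is logged.

Phosphopeptide ratios can additionally be adjusted by subtracting the
parent protein's replicate ratio, isolating occupancy change from
expression change; features without a quantified parent keep raw ratios
and carry an `adjusted = FALSE` flag rather than being dropped.

### Reversion classification

A feature is `reverted` when (i) it is significant in SC-IL vs SC,
(ii) significant with opposite sign in DMT1-KD-IL vs SC-IL, and (iii) its
replicate-mean *linear* fraction DMT1-KD-IL/SC-IL lies in [0.5, 0.7]
(reciprocal band for features down in SC-IL) — the knock-down pulls the
feature 30–50 % back from the IL-1β level. The band is applied to the
replicate-mean fraction, not per replicate: the band describes where the
feature settles, and per-replicate banding would multiply the noise
sensitivity of a boundary feature by the number of replicates. The band
is evaluated on the normalized abundances (the same matrix the
significance calls are computed from). Features significant only in
DMT1-KD-IL vs SC-IL are `protective-up`/`protective-down`.

## Multivariate QC

Group profiles are per-feature percentage shares: replicate-averaged
group abundance divided by the feature's six-group total, × 100. PCA runs
on the 6 × features share matrix with per-feature centering and *no*
scaling — shares are already on a common percentage scale, and scaling
would up-weight near-constant features; the decomposition uses singular
values, scores are reported for the first two components with their
variance fractions, and each component's sign is fixed so its
largest-magnitude loading is positive (a deterministic convention, since
singular vectors are sign-ambiguous). PCA is computed on the six group
means rather than the 18 samples because the profiles are defined as
replicate averages; a sample-level PCA can be obtained by passing a
profile built from an un-averaged matrix.

## PRM quantification

Transition chromatograms are integrated trapezoidally inside the
scheduled retention-time window, with no baseline subtraction or
smoothing (the synthetic baselines are zero; real baselines would need a
pre-processing step this package does not provide). The light/heavy
ratio is the ratio of summed fragment areas — not the mean of
per-fragment ratios — which weights fragments by signal and is robust to
weak transitions. Identity is scored by the normalized dot product
between measured areas and reference fragment intensities, computed on
the heavy standard (and reported for the light channel too), with an
inclusive acceptance threshold of 0.95. Co-elution is checked by
correlating light and heavy apex retention times across the peptide
panel; apexes on a window boundary are flagged as truncated, and pairs
more than 0.2 min apart are flagged individually. The dot product is
computed per peptide aggregate (one score per peptide and channel), not
per charge state; the simulated data carry a single charge state per
peptide.

## The synthetic-data generator

`simulate_psm_dataset()` emulates exactly the structure the analysis
assumes:

* log-normal peptide base intensities (natural-log mean `log(1e6)`,
  SD 1.2 — a broad but desk-sized dynamic range);
* per-sample multiplicative channel biases drawn uniformly from
  [0.9, 1.1], the loading-correction range expected for balanced
  channels;
* planted log2 group effects (default magnitude 1) for IL-1β-regulated,
  knock-down-regulated and reverted feature classes; reverted features
  place the DMT1-KD-IL mean at SC-IL × u, u ~ U(0.5, 0.7) (reciprocal
  for down-features), directly encoding the 30–50 % pull-back;
* biological noise per feature × sample (log2 SD 0.2) shared by all the
  feature's PSMs, plus measurement noise per PSM × channel (log2 SD
  0.1). Separating the two keeps feature-level ratio variance
  homogeneous — which is what makes the empirical-null z-test calibrated —
  while still letting roll-up average the measurement component down;
* a localization-probability mixture: confident sites ~ Beta(200, 1)
  (85 % of sites; P(> 0.99) ≈ 0.87, matching the reported fraction of
  distinctly localized sites) and ambiguous sites ~ Beta(8, 8) centered
  at 0.5, so both the 0.75 and the 0.99 cutoffs are exercised;
* 5 % shared (non-unique) peptides, 2 % missing cells (written as empty
  fields, never zeros), and 5 % phospho-only proteins. With the default
  per-peptide phospho rate of 0.3 this yields a proteome/phosphoproteome
  overlap of ≈ 0.76 at a few thousand proteins, the value observed in
  the study this design emulates; the emergent overlap is below
  1 − frac_phospho_only because a single-peptide phosphoprotein cannot
  also appear in the non-phospho layer.

The missingness rate and dynamic range are placeholders — the deposited
raw data they would have to be calibrated against is out of scope — so
recovery results quantify algorithmic correctness, not expected
performance on any particular instrument. The generator also omits,
deliberately: isotope-impurity cross-talk between channels, chimeric
PSMs, intensity-dependent missingness, and search-engine FDR structure.
Passing tests therefore show the pipeline recovers what it assumes; they
do not show robustness to violations of those assumptions.

`simulate_prm_dataset()` produces co-eluting Gaussian light/heavy
elution profiles (σ = 0.1 min) on a shared grid (10 ms sampling) inside
a 3-min scheduled window, fragment amplitudes proportional to the
reference intensities, light = heavy × true ratio, and a configurable
light-vs-heavy apex jitter (default 0.01 min) and additive noise.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen so each scenario's
sampling error is well below the property it checks: 2,000 features for
null calibration (the fraction of raw p < 0.05 is then estimated to
± 0.005); 2,100 features with 100 planted 1-log2FC effects for
sensitivity/FDR; 6,000 features for channel-bias recovery (the relative
error of a total-intensity estimate scales with the effective number of
peptides, heavy-tailed weights included); 1,000 features with 50 planted
reverted features at low noise (log2 SD 0.02, fully unique peptides so
every planted feature is quantifiable) for exact reversion-set recovery.
Reruns of the full pipeline on identical inputs are byte-identical: all
randomness lives in the generator behind a single seed, result tables
are written at fixed precision with no timestamps, and outputs are
staged and published only on success, so a failed run leaves no partial
tables.

Tie-breaks and degenerate inputs: a z-test on fewer than 20 features, a
constant ratio distribution (MAD 0), a sample with zero total intensity,
an all-zero dot-product vector, a heavy area of zero, and a window with
fewer than two chromatogram points are all hard errors, not silent
results.

## Known limitations

* The robust-null z-test assumes most features are unregulated; it is
  not a per-feature variance model (no moderated t / limma-style
  shrinkage), so features with atypically noisy replicates can reach
  significance on a lucky mean.
* The unique-peptide rule discards shared-peptide evidence entirely;
  proteins quantified only by shared peptides are invisible.
* No imputation: features missing in a replicate simply lose that
  replicate, and features missing a whole group drop out of profiles.
* PRM processing starts from extracted chromatograms; raw-file
  extraction, transition optimization and LOQ/LOD calibration are out of
  scope.
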