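---
title: "Case-control morphometry effect maps and imaging-transcriptomic null models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control morphometry effect maps and imaging-transcriptomic null models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package computes

`morphogene` implements the analysis chain of a case-control neuroimaging
genetics study of a monogenic syndrome with two genotype subgroups (a
larger one, n = 30, and a smaller one, n = 10) against matched controls
(n = 40):

1. **Regional effect-size maps.** For each of the 34 Desikan-Killiany
   cortical regions per hemisphere and each morphometric measure — gray
   matter volume (GMV, mm³), surface area (SA, mm²), cortical thickness
   (CT, mm) — plus subcortical volumes, the patient-minus-control Cohen's d
   after adjustment for the measure's global counterpart (total brain
   volume TBV, total surface area TSA, or weighted mean thickness WMT).
   Inference uses an ANCOVA route for the larger subgroup (diagnosis +
   age + sex + global covariate; error df = n − 5) and a
   residualize-then-t route for the small subgroup, with
   Benjamini-Hochberg FDR within each measure family (68 cortical
   regions, or the 8 subcortical volumes).
2. **Subgroup convergence.** Pearson correlation between the two
   genotypes' d maps, tested against a genetic-status permutation null.
3. **Gene-brain association.** An atlas-style transcriptome (multi-donor,
   probe-level, spatially located samples) is collapsed to one expression
   value per region; the region vector is correlated with a d map and
   tested against three nulls: a spatial spin, random gene sets, and
   brain-expressed gene sets.
4. **Brain-behavior decoupling.** Within-group Pearson correlations
   between striatal composites (caudate + putamen + pallidum per side)
   and behavior scores, compared between groups with Fisher r-to-z tests
   and FDR over the tested pairs.

Every stage runs on synthetic data with programmed ground truth, so
recovery, calibration and power are testable without restricted MRI data
or the full atlas download.

# The synthetic-data generators

## Cohort

Each subject receives demographics (group-specific age and sex
distributions), a cumulative Euler number (surface-reconstruction quality
index; group-specific means so quality-confound analyses are
non-trivial), three global measures, 204 cortical regional values and 8
subcortical volumes. The generative model for a regional value is

    region = baseline × (global / global_mean)
             + d × sigma_region × 1[patient] + noise,

with `noise ~ N(0, sigma_region)` and `sigma_region` a fixed fraction of
the regional baseline (defaults: 12% for volumes and areas, 5% for
thickness). Three properties follow by construction:

* regional values are positively coupled to the subject's global measure,
  so global adjustment is consequential, not cosmetic;
* the programmed `d` is expressed on the *globally residualized* scale —
  it is what `effect_size_map()` should recover;
* regional measures are conditionally independent given the global
  measure. This is an assumption: real cortical measures have richer
  covariance (neighboring regions co-vary beyond their shared global
  factor), which is why passing recovery tests here do not certify
  behavior under strong local covariance.

Global deficits default to the study conditions (larger subgroup:
d = −0.98 TBV, −0.55 TSA, −1.04 WMT; smaller: −0.49, −0.44, −0.70), and
`demo_effect_map()` programs the printed subcortical pattern (bilateral
caudate/putamen/pallidum deficits, right hippocampus) plus a shared
smooth cortical pattern so the two genotype maps genuinely converge.

## Sphere, transcriptome, behavior

The parcellation stand-in places a Fibonacci lattice (default 2000
vertices per hemisphere) on the unit sphere and partitions it into
spherical Voronoi cells of randomly drawn seeds (34 per hemisphere by
default, labeled with the Desikan-Killiany names). The right hemisphere
is the x-negated mirror of the left, the standard convention for
bilateral atlases and the property the mirrored spin relies on.

Transcriptome samples sit on sphere vertices, per donor (default 6 donors
x 100 samples; right-hemisphere samples only for 2 donors, mirroring the
incomplete right-hemisphere coverage of the public atlas). Each gene has
a smooth latent field (kernel-weighted sum of random bumps,
length-scale 0.4 rad), evaluated homotopically (right-hemisphere samples
are evaluated at their mirrored position). Probe values add a per-probe
offset and noise on a log2-intensity-like scale. A designated target gene
can instead be programmed with a region-level correlation `rho` to a
supplied map; its field is piecewise constant within parcels
(`rho·z(map) + sqrt(1−rho²)·z(noise)` across regions), which trades
spatial realism for an exactly interpretable ground truth.

Behavior scores use the conditional Gaussian construction
`score = mean + sd·(r·z_striatum + sqrt(1−r²)·z)` against the bilateral
striatal composite, so one latent draw drives both sides and left/right
realized correlations are close, as in the emulated study's report.
Missing scores are assigned at random per group with the per-test counts
of the emulated demographic table.

# Statistical conventions

* All parametric p-values are two-sided; the printed values of the
  emulated study (e.g. t = 2.244, df = 78 → p = 0.028) match that
  convention.
* Cohen's d uses the pooled-SD formula without small-sample correction,
  signed patient minus control so deficits are negative.
* Welch degrees of freedom are kept fractional.
* Residualization for d uses the global covariate only, fit on both
  contrast groups pooled without a group term: including a group term (or
  fitting per group) would absorb part of the group difference and bias d
  toward zero.
* The small-subgroup t route uses the pooled-variance t on residuals,
  which makes the F = t² identity with the covariate-free ANCOVA exact
  and the two routes' p-values converge on large balanced cohorts.
* Degenerate regions (zero variance after adjustment) are reported as
  missing with a warning, never silently dropped.
* Empirical p-values always use the add-one rule
  (1 + #extreme)/(B + 1), so p > 0 and the attainable floor at B
  permutations is 1/(B + 1) — 0.0005 at the study scale of 2000.

# The convergence permutation scope

`convergence_test()` permutes genetic status across **all** subjects,
patients and controls, preserving group sizes, and recomputes both
residual-route d maps against the pseudo-reference per permutation. The
alternative of reshuffling labels only within the patient pool (exposed
as `permute = "patients_only"`) is *not* a convergence test: each
pseudo-subgroup is then a mixture of both genotypes, and a mixture map
correlates with another mixture map at least as strongly as the two
unmixed maps do (at sizes 30/10 the mixture-correlation is
0.625 + 0.375·rho for true map correlation rho, which exceeds rho
whenever rho < 1). Under that scheme the observed correlation can
essentially never exceed the null, whatever the data; it is a test of
subgroup *difference*. The all-subjects scheme instead asks whether maps
computed from informative labels cohere more than maps computed from
uninformative ones, which is the question a convergence claim answers,
and it is exactly calibrated when labels carry no information (all
groups drawn from one process). When the genotypes carry independent
non-zero maps the permutation p is conservative (rejection below
nominal), which the test suite asserts as a one-sided bound.

The statistic inside the loop uses the residual d route for both
pseudo-subgroups, keeping it exchangeable under relabeling; per-measure
runs use independent seeded streams.

# Gene-brain null models

* **Spin null.** A uniform SO(3) rotation (QR of a Gaussian matrix with
  sign correction) is applied to the labeled left-hemisphere sphere; the
  right hemisphere uses the mirrored operator `M R M`, `M = diag(−1,1,1)`,
  preserving homotopy. Samples are reassigned to the rotated parcels by
  nearest vertex and the full probe-to-region chain is re-run; the
  identity rotation therefore reproduces the observed correlation
  exactly, which is regression-tested. Parcels left without samples are
  handled by pairwise deletion; rotations leaving fewer than 3 complete
  regions are redrawn and counted.
* **Gene nulls.** Same-sized gene sets are drawn without replacement from
  the full pool or its brain-expressed subset, the target gene excluded
  by default (including it only dilutes the null toward the observed
  value). Region vectors are built once per gene and cached, making the
  published 10,000 draws cheap.
* **Sidedness.** The default is one-sided in the direction of the
  observed correlation, the reading closest to "does the observed
  positive correlation exceed null expectations". This choice doubles the
  type-I rate relative to a pre-registered direction: under a symmetric
  null the directional p is uniform on (0, ½]. Calibration checks in the
  test suite therefore fix `sided = "greater"`, the pre-registered
  direction; users testing an a-priori direction should do the same.

## Aggregation-chain order

The atlas-style chain is mean-within-donor-and-region, then median
across donors. Published descriptions of such chains mix "mean" and
"median" for the within-donor stage; the within-donor statistic is
exposed (`within_donor = "mean"` or `"median"`) rather than hidden, with
the mean as default. No inter-donor normalization is applied; sample
assignment uses nearest vertex with an optional distance threshold
(default: none), with ties broken deterministically toward the lowest
vertex index.

# Brain-behavior analysis

TBV adjustment applies to the brain variable only, within group; scores
are never adjusted. Both adjusted and unadjusted variants are first-class
outputs, reported side by side. The FDR family is exactly the pairs
tested in one call — re-running on a subset changes q values, which is
intended and regression-tested. The default hypothesis-driven pair set is
striatal composites × attention/inhibition plus hippocampal volumes ×
memory scores.

# Problem sizes used by the test suite

The statistical acceptance tests run at sizes chosen to keep the full
suite in the tens of minutes on one core while leaving the Monte-Carlo
error well inside the asserted bands: effect-recovery at the study's
30/40 with 100 repeats; convergence calibration over 200 datasets at 500
permutations; spin calibration over 200 datasets at 500 rotations on a
2000-vertex-per-hemisphere sphere with 6 × 30 samples; gene-null
calibration and power over 100 repeats at 200 and 1000 draws. The
acceptance script (`scripts/acceptance.R`) runs the pipeline itself at
the published scales (2000 label permutations, 1000 rotations, 10,000
gene draws).

# Known limitations

* Conditional independence of regions given the global measure (above).
* The target gene's programmed field is region-piecewise-constant, not
  smooth; spin-null specificity against *purely* smoothness-induced
  correlation is exercised by the smooth non-target genes instead.
* The parcellation stand-in has quasi-uniform parcel sizes; real
  parcellations have heavier size imbalance, which mainly affects how
  often rotations empty a parcel.
* No vertex-wise analysis, no longitudinal models, no probe filtering or
  differential-stability probe selection, and no surrogate-map null other
  than the spin.
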