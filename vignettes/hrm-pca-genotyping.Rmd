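---
title: "Methods: HRM curve genotyping with PCA and model-based clustering"
author: "hrmpca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HRM curve genotyping with PCA and model-based clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrmpca)
```

# The measurement and its model

High-resolution melting (HRM) genotyping records the fluorescence of a
saturating dsDNA dye while a PCR amplicon is heated through its
denaturation transition. A homozygote's product is a single homoduplex
whose melt curve is, to good approximation, a two-state transition: the
double-stranded fraction follows a sigmoid in temperature centred at the
duplex Tm. A heterozygote's PCR product re-anneals into four duplex
species in roughly equal proportions — the two matched homoduplexes and
two mismatched heteroduplexes whose single-base mismatch depresses their
melting stability — so its curve is a four-component mixture with an
early-melting shoulder. Genotype information is therefore carried by
curve *shape*, and calling genotypes reduces to clustering curves.

The pipeline implemented here makes that clustering statistical rather
than heuristic:

1. **Clip** each plate to the marker's active melt region
   $[T_{lo}, T_{hi}]$ (the packaged panel table carries these per
   marker).
2. **Normalize** each curve. The default is per-curve min–max scaling
   within the clipped region, which is the scheme the calling pipeline
   itself uses: it requires only the two region limits, and is invariant
   to the per-well amplitude and offset differences that dominate raw
   plates. The classic two-baseline scheme (least-squares lines fitted to
   pre- and post-melt windows, curve rescaled to the band between them
   and clipped to $[-0.05, 1.05]$) is provided as an alternative mode,
   mainly for difference plots in the style of instrument software.
3. **Embed** samples by PCA, treating each sample's normalized curve as
   one *variable* observed over the temperature grid. The sample
   coordinates are then the entries of the top-$k$ eigenvectors of the
   sample-by-sample covariance — the "rotation" of a PCA whose variables
   are curves. With two or three variants per marker, two or three
   components capture the genotype structure; $k$ is the smallest of
   $\{2, 3\}$ whose cumulative explained variance reaches 0.90,
   defaulting to 3.
4. **Cluster** the coordinates with a $G$-component Gaussian mixture
   with full per-component covariances, fitted by EM. The default
   $G = 3$ matches the biallelic expectation (two homozygotes plus the
   heterozygote); `G = "auto"` compares $G \in \{1,2,3\}$ by BIC for
   markers where a variant class is absent.
5. **Label** each cluster by the majority genotype among its
   Sanger-sequenced anchor samples; all members inherit the label.
   Accuracy against a Sanger truth set is reported as
   `consistent/sequenced` with the percentage rounded to one decimal,
   half away from zero.

## Assumptions

* One marker per plate, one amplicon per well; multi-domain melting and
  probe chemistries are out of scope.
* Genotype classes are separable in the leading PCs after normalization
  — true when the allele ΔTm or the heteroduplex shoulder is resolvable
  at the instrument's noise level.
* Anchors are correct: Sanger labels are treated as ground truth, and a
  cluster's disagreeing anchors are resolved by majority with a raised
  conflict flag (an exact tie leaves the cluster undetermined). This
  retains the information that drives accuracy audits instead of hiding
  it.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `lower`/`upper` melt-region limits | per marker (panel table) | °C | bound the informative transition; closed interval, compared with 1e-9 °C tolerance so printed limits on grid points are kept |
| `choose_k` threshold | 0.90 | fraction | smallest $k \in \{2,3\}$ reaching this cumulative explained variance; capped at 3 |
| `G` | 3 | components | two homozygotes + heterozygote; `"auto"` scans 1–3 by BIC |
| EM restarts | 10 | — | k-means++ initializations; best final log-likelihood kept |
| EM tolerance | 1e-8 | log-lik units | convergence on log-likelihood gain |
| covariance ridge | $10^{-6}\,\mathrm{tr}(S)/d$ | coord. units² | keeps small clusters' covariances invertible |
| haplotype EM tolerance | 1e-8 | frequency | max $|\Delta f|$ per iteration; cap 10,000 iterations |
| haplotype EM restarts | uniform + 5 random | — | detects likelihood ridges (non-identifiability) |

# The simulator: what it emulates, what it does not

`simulate_plate()` generates plates from the two-state model directly:
each duplex species contributes $w_i\,\sigma((T_{m,i} - T)/w)$ with
$\sigma$ the logistic function; heterozygotes get the equimolar
four-species mixture with heteroduplex Tms depressed by
`heteroduplex_shift`. On top of the mixture curve it adds per-curve
amplitude jitter (CV 5 %), a linear baseline drift (0.005 fluorescence
per °C), and i.i.d. Gaussian read noise. Defaults — ref Tm 78 °C, allele
ΔTm 0.5 °C, heteroduplex shift 1.0 °C, transition width 0.4 °C, grid
70–90 °C in 0.1 °C steps, 9/9/9 samples (a 27-sample plate the size of
the cultivar panel), noise 0.3 % of amplitude — describe a typical
instrument resolution and a clearly resolvable SNP.

The simulator deliberately omits: sequence-dependent (nearest-neighbour)
thermodynamics, multi-domain melting, well-position and edge effects,
correlated drift within a ramp, and failed or contaminated wells beyond
constant curves. Passing tests on simulated plates therefore demonstrate
that the *pipeline machinery* recovers cluster structure the two-state
model generates at realistic noise; they do not certify performance on
amplicons whose melt behaviour departs from two-state, which is exactly
the regime where anchors and conflict flags matter on real data.

# Numerical choices

* **Clipping** uses a closed interval with 1e-9 °C tolerance; fewer than
  5 retained reads is an error naming the marker and limits.
* **Constant curves** (failed wells) are excluded from min–max
  normalization with a warning rather than failing the plate; an
  all-constant plate is an error.
* **PCA sign convention**: each component is flipped so its
  largest-magnitude entry is positive, making coordinates reproducible
  across LAPACK implementations. `k` beyond the matrix rank is truncated
  with a warning; a plate of identical curves is a degeneracy error.
* **GMM determinism**: k-means++ seeding and EM run under the caller's
  seed; clusters are relabelled in increasing order of the component
  mean on the first coordinate. The covariance ridge makes the M-step
  fractionally inexact, so a sub-tolerance dip in log-likelihood is
  treated as convergence while a material drop (> 1e-6 relative) is an
  internal error. Empty components abort a restart; if all 10 restarts
  fail, the fit errors.
* **Derivative Tm** uses central finite differences with ties broken to
  the lower temperature; a never-descending curve has no transition and
  errors.
* **Chi-square association** follows the plain Pearson formula with no
  continuity correction and no exact-test substitution, matching the
  spreadsheet CHITEST convention the panel's published significance was
  computed with; expected cells below 5 warn. Zero-margin rows/columns
  are dropped before computing degrees of freedom, and df = 0 is an
  error.
* **Haplotype EM** enumerates haplotypes explicitly (loci capped at 6,
  i.e. 64 haplotypes; the panel's sets use 2–3 SNPs), marginalizes
  missing single-locus codes in the E-step instead of dropping
  cultivars, asserts a non-decreasing likelihood every iteration, and
  flags the estimate non-identifiable when a restart ties the best
  log-likelihood (within 1e-6) at a frequency vector differing by more
  than 1e-4 — the signature of a phase ridge, e.g. a sample of pure
  double heterozygotes. Output haplotypes are ordered lexicographically.

# Design choices that were genuinely open

* **Which normalization the calling pipeline uses.** The calling
  interface takes only the two melt-region limits, so no baseline
  windows are available to it; per-curve min–max within the clipped
  region is the only scheme consistent with that interface and is the
  default. Whether curves should instead be scaled jointly across the
  plate is a real alternative; per-curve scaling was chosen because it
  removes per-well amplitude variation, which is the dominant nuisance.
* **Covariance model.** Rather than searching a large family of
  constrained covariance models, one expressive model (full, per
  component, ridge-regularized) is fitted with deterministic
  initialization — reproducibility across platforms was valued over
  marginal BIC gains from model search. The widely used `mclust` package
  serves as an independent cross-check in the test suite, not as the
  implementation.
* **Association denominators.** All 27 classified cultivars enter the
  association by default, because the class label (low/high) exists for
  every cultivar even where published chilling hours do not;
  `only_phenotyped = TRUE` restricts to the 20 cultivars with hours.
* **Anchor disagreements** resolve by majority with a conflict flag
  rather than erroring, preserving the audit trail.
* **CHAPLIN-style haplotype analysis** is implemented as the canonical
  HWE genotype-to-haplotype EM with multistart, and reports per-group
  frequencies only; the 'general'-model likelihood-ratio case/control
  test is intentionally out of scope.

# Problem sizes used by the test suite

The suite exercises the pipeline at the scale the method is designed
for: 24–27-sample plates over a 201-point grid, 20 simulation seeds per
noise level for the accuracy sweep, 2,000 replicates for the chi-square
type-I calibration (expected cells ≥ 5 throughout), n = 500 individuals
for haplotype-frequency recovery, and 30-individual instances for the
EM-versus-grid likelihood comparison at 0.005 simplex resolution. A
0.005 grid can only undershoot the continuous optimum, so that
comparison is one-sided: the EM optimum must not be beaten by the grid
by more than 1e-4.

# Known limitations

* Fluorescence curves from real instruments were not published for the
  reference panel, so the packaged genotype table is the panel's ground
  truth and plate-level behaviour is validated on simulated data; the
  printed per-marker accuracies of the original study are properties of
  its unpublished raw fluorescence and are not reproduction targets.
* The two-baseline scheme shares the limits table with clipping; for a
  few panel markers the tuned limits lie outside the baseline windows,
  which the loader flags with a warning rather than failing.
* The haplotype EM assumes Hardy–Weinberg random union of gametes within
  each analysed group; cultivar collections are not random-mating
  populations, so stratified frequencies should be read as descriptive
  summaries, not population estimates.
* Chi-square p-values on 27 cultivars involve small expected cells for
  some genotype categories; the implementation warns but still reports
  the asymptotic p-value, by design matching the published convention.
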