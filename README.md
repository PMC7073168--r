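# hrmpca

SNP genotyping from high-resolution melting (HRM) curves, with
principal-component embedding and model-based clustering, plus the
downstream marker–trait statistics a breeding panel needs.

## The problem

HRM is a cheap, gel-free way to genotype SNPs: after PCR in the presence
of a saturating dsDNA dye, fluorescence is recorded while the amplicon
melts, and the shape of the melt curve discriminates sequence variants —
homozygotes differ through the Tm shift of their homoduplexes, while
heterozygotes re-anneal into a four-species homoduplex/heteroduplex
mixture whose early-melting shoulder deforms the curve. Commercial HRM
software clusters curves by shape heuristics and can misassign samples
when curves spread widely. `hrmpca` implements the statistical
alternative: normalize each curve over its marker-specific active melt
region, embed the curves with PCA, cluster the sample coordinates with a
Gaussian mixture fitted by EM, and label each cluster with the genotype of
Sanger-sequenced anchor samples.

For sample $j$ with raw fluorescence $F_j(T)$ clipped to the melt region
$[T_{lo}, T_{hi}]$, the pipeline's normalization is per-curve min–max,
$F'_j = (F_j - \min F_j)/(\max F_j - \min F_j)$ (a two-baseline scheme
fitting least-squares lines to the pre- and post-melt windows is also
provided). Treating each normalized curve as one variable observed over
the temperature grid, the sample coordinates are the top-$k$ ($k \in
\{2,3\}$, chosen by explained variance) eigenvectors of the
sample-by-sample covariance. A $G$-component Gaussian mixture with full
covariances (default $G = 3$, or BIC selection over $G \in \{1,2,3\}$) is
fitted to those coordinates by EM from k-means++ starts, and a marker's
genotyping accuracy is reported as calls consistent with Sanger
sequencing over samples sequenced.

The package ships the 22-marker peach (*Prunus persica*) chilling
requirement (CR) panel as reference data: per-marker melt-region limits
and baseline windows, and the genotypes of 27 cultivars (15 low-chill, 12
high-chill) at the 11 markers linked to major-effect CR QTLs. On that
table it computes the contingency chi-square marker–trait association
(genotype categories × CR classes, no continuity correction), putative
low-chill alleles, and case/control haplotype frequencies estimated from
unphased 0/1/2 genotype codes by the standard EM under Hardy–Weinberg
random gamete union. A two-state logistic melting simulator generates
plates with known genotypes so the whole pipeline is testable end to end.

## Worked example

Simulate a 27-sample plate (9 per genotype, ΔTm 0.5 °C, heteroduplex
shift 1 °C, 0.3 % read noise), call it with one anchor per genotype, and
score against the simulator's truth:

```r
library(hrmpca)
cfg   <- simulation_config(n_per_genotype = c(9, 9, 9), noise_sd = 0.003, seed = 7)
plate <- simulate_plate(cfg)
fit   <- run_hrm_pca_pipeline(plate$dataset,
                              anchors = plate$truth[c("ref_hom_01", "het_01", "alt_hom_01")],
                              lower = 74, upper = 82.5, seed = 7)
fit
#> <hrm_call> simulated
#>   k = 2 PCs, 3 clusters
#> <cluster_call_result> G = 3  loglik = 279.414
#>        genotype
#> cluster A/A A/G G/G
#>       1   0   9   0
#>       2   0   0   9
#>       3   9   0   0
genotyping_accuracy(fit$genotype, plate$truth)
#> accuracy: 27/27; 100.0%
```

Two principal components explain enough variance here; the three mixture
components separate the heterozygote (earliest-melting, cluster 1), alt
homozygote and ref homozygote, and every call matches the simulated
truth. On the packaged cultivar panel, the association table reproduces
the published significance pattern (all 11 major-effect markers p < 0.05,
seven of them p < 0.001):

```r
tab <- association_table(load_genotype_fixture())
head(tab[order(tab$p_value), ], 4)
#>            marker statistic df  p_value stars low_chill_allele
#> 1  SNP_IGA_122351      23.3  2 8.89e-06   ***                G
#> 11 SNP_IGA_427604      19.9  2 4.89e-05   ***                G
#> 7  SNP_IGA_780662      18.4  2 1.01e-04   ***                C
#> 3  SNP_IGA_779222      16.4  2 2.75e-04   ***                C
```

and haplotype frequencies stratified by CR class come from the EM
estimator (low CR = case, high CR = control):

```r
mg <- encode_genotypes(load_genotype_fixture(),
                       c("SNP_IGA_122351", "SNP_IGA_134905"))
case_control_haplotype_freqs(mg, seed = 1)
#> <case_control_haplotypes> SNP_IGA_122351-SNP_IGA_134905
#>    overall   case control
#> AA  0.4974 0.1534  0.9167
#> AG  0.0952 0.1133  0.0833
#> GA  0.1878 0.3466  0.0000
#> GG  0.2196 0.3867  0.0000
```

The AA haplotype dominates high-chill cultivars while G-bearing
haplotypes are confined to the low-chill group, mirroring the single-SNP
association.

A thin shell front end (`inst/cli/hrmpca`) exposes the same operations as
subcommands (`simulate`, `normalize`, `call`, `assoc`, `haplo`,
`run-all`); `run_end_to_end()` drives a whole configured run and writes
CSV/JSON artifacts plus a seeded run log.

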