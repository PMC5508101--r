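---
title: "Multiple QTL-seq: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple QTL-seq: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqtlseq)
```

## The method

QTL-seq maps quantitative trait loci by sequencing two pooled DNA bulks
drawn from the phenotypic extremes of a segregating population — here,
early- and late-flowering recombinant inbred lines (RILs) from a
biparental chickpea-style cross, selfed to F9 by single seed descent. At
a SNP differentiating the two parents, the **SNP-index** of a bulk is the
fraction of its reads carrying the allele that differs from the reference
parent's assembly,

$$\mathrm{index} = \frac{d_{alt}}{d_{ref} + d_{alt}},$$

and the **Δ(SNP-index)** is the difference of the two bulks' indices. Far
from any causal locus the bulks are random samples of the population and
Δ fluctuates around 0; at a locus co-segregating with the trait the bulks
are fixed for opposite parental alleles and Δ approaches ±1. *Multiple*
QTL-seq runs this analysis in two (or more) populations that share one
parent and intersects the called intervals, which narrows each QTL to the
region supported in every genetic background.

Because the early parent is the reference assembly, a QTL fixed in the
bulks gives index ≈ 0 in the early bulk and ≈ 1 in the late bulk, i.e.
Δ = early − late ≈ −1. Published descriptions of the method vary in which
bulk is subtracted from which; `delta_snp_index()` therefore exposes the
orientation as an argument (default `early_minus_late`), and
`call_qtls()` is deliberately sign-agnostic: it works on |Δ| plus the
per-bulk index criteria, so either orientation yields identical calls.

## Pipeline stages and their parameters

1. **Filtering** (`filter_snps()`): total depth ≥ 10 in both bulks, mean
   base quality ≥ 20, parents homozygous-differentiated (parental indices
   rounding to 0 and 1 at 0.1/0.9 cut-offs), and removal of SNPs whose
   index is < 0.3 in *both* bulks. The last rule follows the original
   QTL-seq recommendation — such SNPs are typically alignment or calling
   artefacts — and can be disabled (`low_index_floor = 0`) since it is a
   protocol convention rather than a statistical necessity.
2. **Windowing** (`sliding_window_profile()`): unweighted means of the
   per-SNP indices over sliding windows of width `W` advanced by `s`,
   anchored at position 1. The genome-scale protocol uses W = 10 Mb with a
   1-kb increment; both are free parameters here because on a synthetic
   desk-scale chromosome (tens of Mb) a 10-Mb window would span half the
   chromosome. The unweighted (not depth-weighted) mean matches the
   method's "mean distribution of Δ(SNP-index)" convention. The final
   partial window is retained, flagged, when it contains SNPs.
3. **Null bands** (`null_bands()`, `simulate_null_delta()`): the null
   distribution of Δ is simulated by drawing, per bulk, `bulk_size`
   genotypes from the F-generation RIL distribution — residual
   heterozygote frequency $h = (1/2)^{g-1}$, the two homozygote classes at
   $(1-h)/2$ each — then binomial read sampling at each grid depth
   (default grid 10–150×, 10,000 replicates, two-sided 95/99/99.9%
   quantiles). Bounds at observed depths are linearly interpolated;
   depths below the grid fall back to the nearest grid value with a
   warning rather than extrapolating. Per window the bound is the mean of
   member-SNP bounds — standard QTL-seq practice. This is conservative
   for windows containing many SNPs, because window-averaging removes the
   read-sampling component of the per-SNP null while the bound retains
   it; the observed null exceedance of tiled windows at the 99% band is
   therefore at or below the nominal 1% (the calibration tests check it
   stays within 1% ± 1%). An exact windowed null is a possible extension.
4. **Calling** (`call_qtls()`): runs of ≥ `min_windows` (default 2, to
   suppress single-window spikes) consecutive non-empty windows where
   |mean Δ| exceeds the band at the chosen level *and* |mean Δ| >
   `min_delta` (default 0.5) *and* the high/low bulk index means pass
   0.8/0.2. Interval endpoints snap to the outermost SNPs inside the run,
   so printed flanking-SNP positions are reproducible; interval length is
   reported as `end − start`, the convention that reproduces the printed
   kb/Mb sizes from printed flanking positions. The method's sources cite
   both a 99% level and P < 0.001; both bands are computed and the level
   is a parameter rather than a resolved choice.
5. **Consensus narrowing** (`intersect_qtls()`): overlapping calls from
   two populations, same chromosome and same Δ sign (so QTLs of opposite
   parental contribution never merge), intersect to
   `[max(starts), min(ends)]`. Whether "consensus" means strict
   intersection or simply the shorter of two nested calls is ambiguous in
   the method's descriptions; strict intersection is implemented, and for
   nested pairs the two readings coincide.
6. **Candidates and annotation** (`delineate_candidates()`,
   `classify_location()`, `coding_effect()`): SNPs at the interval's
   maximal |Δ| are mapped to genes; positions classify as CDS > intron >
   URR > DRR > intergenic, with 2-kb regulatory windows by default — the
   URR/DRR window length is a convention (no standard exists), so it is
   exposed and reported URR/DRR proportions should be read as
   window-dependent. UTRs are not modelled: gene span minus CDS is
   "intron", matching the category set this analysis reports. Coding
   effects use the standard genetic code only.
7. **Diversity scan** (`diversity_windows()`, `diversity_ratio()`):
   windowed θπ (frequency form, equal to the mean pairwise Hamming
   distance; the $n/(n-1)$ factor makes it unbiased), Watterson's θ and
   Tajima's D with the standard constants, in 100-kb non-overlapping
   windows. Inbred accessions genotyped as 0/1/2 dosages expand to two
   haplotypes per individual (`dosage_to_haplotypes()`). The
   cultivated/wild ratio 100·θπ_C/θπ_W quantifies domestication-related
   diversity loss.

## What the synthetic generator emulates — and what it does not

`simulate_ril_population()` performs one meiosis per generation per line
(Poisson crossover counts under the Haldane, interference-free model;
crossover positions uniform) followed by selfing to F9, so residual
heterozygosity decays as $(1/2)^{g-1}$ and two-point recombination
converges to the RIL map expansion $R = 2r/(1+2r)$. Phenotypes are
additive (QTL effects in days, `effect × (dosage − 1)`) plus environment,
G×E and residual terms; with $v = \sigma^2_g(1-h^2)/h^2$ the non-genetic
variance splits as $\sigma^2_{ge} = 0.25\,vE$ and
$\sigma^2_e = 0.75\,vER$, chosen once so the expected entry-mean
broad-sense heritability equals the target (the 25/75 split is a
realistic ratio for replicated multi-location trials; any split summing
to $v$ gives the same entry-mean H²). Bulks take the `bulk_size` = 10
lowest/highest trait means among individuals homozygous across declared
QTL regions (± 1 Mb), ties broken by line ID; reads are
Poisson-total/binomial-allele samples at 30× mean depth. Defaults follow
the emulated study design: F9, populations of a few hundred lines, a
55-Mb chromosome-4-like pseudomolecule, two planted QTLs whose summed
effects reproduce a ~42-day parental divergence and a ~15-day RIL
standard deviation, 3 cM/Mb.

The generator does **not** emulate: dominance or epistasis, segregation
distortion, crossover interference, mapping/alignment artefacts, depth
heterogeneity along the genome, or genotyping error. Passing tests
therefore demonstrate the statistical machinery under the model's own
assumptions, not robustness to the artefacts of real resequencing data.

For the diversity panels, wild haplotypes carry unlinked sites whose
derived-allele counts follow the neutral folded site-frequency spectrum
(P(count = i) ∝ 1/i), which centres Tajima's D near zero by construction
— a uniform allele-frequency draw would not (it overloads intermediate
frequencies and pushes D strongly positive, ≈ +2.5 at n = 100). The
cultivated panel is a founder bottleneck (resampling from 25 founder
haplotypes) with additional per-site fixation inside the declared sweep
region, calibrated so the realized in-region θπ ratio equals
1 − `reduction` in expectation after accounting for the bottleneck factor
$1 - 1/n_f$. This is a caricature of domestication — no linkage, no
demography — sufficient to test the estimators, not a coalescent
simulation.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere; BED export
  (`write_intervals()`) is the only 0-based surface, converting as
  `start − 1`.
* Windows with no SNPs carry `NA` means and never enter calling; a window
  wider than the chromosome clamps to one window with a warning.
* Zero-depth SNPs have undefined index and are dropped when building
  index records.
* Negative ANOVA variance components truncate to zero (flagged), keeping
  H² in [0, 100]; unbalanced genotype × environment designs are refused
  rather than approximated.
* Tajima's D is `NA` for S = 0 and is not computed below n = 4
  haplotypes.
* All generators are pure functions of `(config, seed)`; the pipeline
  runner derives per-stage seeds from the run seed, and reruns are
  byte-identical.

## Problem sizes used by the test-suite simulations

The calibration and recovery checks run at desk scale, chosen once as
realistic miniatures of the emulated design: no-QTL calibration on
10-Mb chromosomes (10-kb marker spacing, 60 RILs, 10 + 10 bulks, 30×,
0.5-Mb tiles, 20 seeds); planted-QTL recovery on 25-Mb chromosomes
(80 RILs, one 15-day QTL at 8 Mb, 2-Mb windows, 20 seeds); heritability
recovery at the trial design scale (260 RILs, 2 environments × 2
replicates, 20 seeds); diversity recovery on 2,000-site, 50 + 50
haplotype panels. Heterozygosity checks use one marker on each of ten
chromosomes across 2,000 lines so the plain binomial standard error
applies to independent loci.

## Known limitations

* The windowed null band is conservative (see above); reported
  significance levels are upper bounds on the false-positive rate.
* `single_marker_pve()` is a plain one-way R² — no kinship, structure or
  multiple-testing control — and is intended as a quick effect-size
  screen, not association mapping.
* Missing genotype handling in diversity scans assumes data are complete
  after upstream filtering; per-site pairwise-complete estimation is not
  implemented.
* Interval endpoints depend on marker density: with sparse markers the
  snapped flanking SNPs can sit well inside the true supported region.
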