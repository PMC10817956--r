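---
title: "Selection-signature scanning with sweepscan: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection-signature scanning with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## What the package computes

`sweepscan` scans multi-population diploid SNP panels for selective sweeps:
genomic regions where recent positive selection has driven an allele toward
fixation, depressing local diversity and extending haplotype homozygosity.
Three complementary window statistics are computed on a sliding grid
(20 kb windows, 10 kb step, by default):

* **Pooled heterozygosity (Hp)** on a pooled set of populations presumed to
  share the selective pressure. For a window with per-SNP major and minor
  observed allele counts, `Hp = 2 * sum(n_maj) * sum(n_min) /
  (sum(n_maj) + sum(n_min))^2`, algebraically bounded in `[0, 0.5]`.
  Major/minor orientation is decided per SNP within the pool, not inherited
  from VCF REF/ALT. Window values are standardized genome-wide to ZHp;
  windows at `ZHp <= -4` are candidates.
* **Windowed weighted Fst** between two groups, from the Weir–Cockerham
  (1984) variance components `a` (among populations), `b` (among
  individuals) and `c` (within individuals): the window value is the ratio
  of sums `sum(a) / sum(a + b + c)` over usable sites, not the mean of
  per-site ratios. Standardized genome-wide to ZFst; candidates need
  `ZFst > 3.7` and empirical `P < 0.01`.
* **XP-EHH** per SNP between the same two groups:
  `ln(iHH_A / iHH_B)`, where iHH is the trapezoidal integral over physical
  distance of the extended-haplotype-homozygosity curve on both sides of
  the core, truncated below an EHH of 0.05 or past 1 Mb. Scores are
  standardized genome-wide, then averaged within windows (both the signed
  mean and the mean of absolute values). Candidates need mean
  `|XP-EHH_std| > 2.6`, empirical `P < 0.01`, and every scored SNP in the
  window sharing one raw sign; the common sign gives the selection
  direction (positive = first-listed group).

Putative sweep regions from the group comparison are windows or regions
detected by **both** the Fst and XP-EHH scans: each scan's candidate
windows are merged (bedtools semantics, book-ended windows merge) and the
overlaps of the two region sets are reported, with the direction carried
from the XP-EHH side. Regions are annotated against gene models (BED or
GFF3) by overlap and by proximity within a 30 kb flank — the default flank
reflects the largest gene-to-region distance the package is designed to
report as "nearby".

### Thresholds

Two threshold sets circulate for this family of scans (`ZFst > 5` with
`|XP-EHH_std| > 3.5`, and `ZFst > 3.7` with `|XP-EHH_std| > 2.6`). The
package defaults to 3.7 / 2.6 — the set consistent with the candidate
regions this pipeline is designed to reproduce — and exposes both knobs in
`scan_config()`. The empirical P-value is rank-based within the run
(`p_i = #{x_j >= x_i} / N`, ties sharing the larger value), so with `N`
scored windows no window can have `P < 1/N`; small window grids therefore
admit only the top `floor(0.01 N)`-ish ranks at `P < 0.01`. This is a
property of the empirical-P construction, not of the implementation.

## Filters

Genotype-level masking happens first: a genotype is kept iff `GQ > 15` and
`DP > 3` (strict readings of the thresholds). Site-level drops follow in a
fixed order — non-biallelic records, missingness `>= 20%`, `MAF <= 0.05`
(union sample, called alleles only), Hardy–Weinberg exact-test
`P < 1e-7` — and finally one member of any sample pair with Yang
relatedness (Ajk) above 0.9 is removed (the member with the higher
missingness; ties keep the earlier sample ID). The order matters:
masking changes missingness and MAF, and every stage's kept + dropped
counts must reconcile with its input, which the filter report records.

The HWE test is the two-sided conditional exact test on the heterozygote
count given the allele counts, computed in the union of all samples, since
joint genotyping is the natural context for this filter.

A caveat on the Ajk relatedness estimator: its familiar calibration
(≈1 for duplicates, ≈0 for unrelated pairs) assumes a large panel of
mutually unrelated individuals with well-estimated allele frequencies. On
small panels drawn from a single tiny population — including this
package's own simulations — all pairs are related and the estimator
shrinks markedly (a duplicated sample can score ~0.55–0.75). Duplicates
remain the most-related pair and are still detectable by rank, but the
fixed 0.9 cutoff is only meaningful at realistic panel sizes.

## The simulator and what the tests can show

`wf_simulate()` is a discrete-generation Wright–Fisher model: an ancestral
population evolved for `10 Ne` generations of burn-in (mutation–drift
equilibrium), an instantaneous split into `n_pops` copies, independent
drift with optional symmetric migration, and an optional additive sweep
(fitnesses 1, 1+s, 1+2s). Mutation is infinite-sites (every site stays
biallelic, matching the biallelic filter); recombination is Poisson
crossovers with uniform breakpoints; positions are integers drawn by
rejection. A sweep lost to drift is re-injected up to a budget and
otherwise reported as lost in the truth record rather than failing the
run. Everything is deterministic given the seed.

Scaled-down study conditions (all configurable):

* **Neutral calibration panels**: 2 populations × 10 diploids, `Ne = 50`,
  split 25 generations before present, 1 Mb, `mu = 5e-6`,
  `rec = 1e-6` per bp per generation. The per-bp rates are scaled up so a
  1 Mb desk-scale panel carries a post-filter SNP density (≈2–3 per kb)
  comparable to a dense WGS panel; the population-scaled parameters
  (`4 Ne mu`, `4 Ne rec` per bp) stay in a realistic range for chicken.
* **Sweep-recovery panels**: 4 populations × 5 diploids — two populations
  per comparison group, mirroring a two-ecotype design with 4–10 samples
  per population — `Ne = 50`, split 8 generations before present, 5 Mb,
  `mu = 2.5e-6`, `rec = 5e-6`, and an additive `s = 6` sweep planted at
  the split in both group-A populations. At the split the populations are
  identical copies, so a group-wide sweep is planted on the same haplotype
  background in each; this emulates selection on standing ancestral
  variation shared by the group. The strong `s` makes the sweep complete
  within the short split time, which keeps the background differentiation
  low — the regime in which fixed Z thresholds tuned on genome-scale data
  remain meaningful on a 5 Mb desk-scale genome.

What passing tests do show: the formula-level statistics agree with
independent oracles to near machine precision; the combined caller is
conservative on neutral data (mean combined call fraction at or below the
nominal 1%); and completed planted sweeps are detected: the focal window
shows positive standardized XP-EHH essentially always, and a common
Fst/XP-EHH region with the correct direction covers it in well over half
of seeded replicates. The strictest check -- the focal 20 kb window
attaining the exact genome-wide ZHp minimum -- holds in only about 60% of
replicates at this scale: the sweep footprint spans many overlapping
windows whose Hp values nearly tie, so the argmin often lands one or two
grid steps from the planted position, and a 5 Mb Ne = 50 genome also
carries occasional naturally diversity-free windows that compete for the
minimum. Genome-scale panels with hundreds of pooled chromosomes sharpen
the focal depression far beyond what a 20-haplotype pool can. What they do not show: behaviour
on real sequencing data with genotyping error, phasing error, variable
depth, demographic complexity (bottlenecks, admixture, gene flow) or
reference bias — none of which the generator emulates. The `degrade()`
operation injects missingness and low-GQ calls to exercise the filter
chain, not to model a sequencing error process.

## Numerical choices

* EHH curves are evaluated on the SNP grid: the value changes only at
  sites, curves start at 1 at distance zero, the core site's own
  refinement sits at distance zero, and integration is trapezoidal between
  consecutive evaluated sites with truncation at the first point below the
  cutoff, flat extension to the 1 Mb bound or contig end otherwise. The
  genome scan uses an algebraically equivalent pair-based formulation
  (a haplotype pair stops contributing at its first mismatch away from the
  core), asserted equal to the site-by-site route in the tests.
* Standardization is a single genome-wide pool over scored windows (or
  SNPs for XP-EHH) per analysis. Windows below `min_snps = 10` scored
  SNPs are excluded from both standardization and candidacy, not
  zero-filled. A constant score vector (e.g. XP-EHH of identical panels)
  standardizes to zero rather than 0/0.
* Nucleotide diversity uses the full window span as denominator, so a
  window's pi halves when its span doubles at fixed variant content; this
  matches the windowed-pi convention of common VCF tooling and is flagged
  in the output metadata.
* LD r2 is haplotype-based (`D^2 / (p1 q1 p2 q2)`) when phase is
  available and squared dosage correlation otherwise; the mode is recorded
  in the output. Pruning removes the later-positioned SNP of an offending
  pair, scanning 50-SNP windows advancing by 5.
* PCA uses Patterson scaling (centre by `2p`, divide by `sqrt(p(1-p))`,
  missing to 0 after centring, monomorphic columns dropped).
* Empirical-P ties share the larger P; the ZHp boundary is inclusive
  (`<= -4` is a candidate); merging is direction-aware (opposite-direction
  regions never merge).
* Internal coordinates are 0-based half-open everywhere; conversion to and
  from the 1-based VCF/GFF3 conventions is confined to the I/O layer.

## Known limitations

* Unphased input supports all dosage-based statistics but not XP-EHH; the
  pipeline refuses the scan rather than silently imputing phase.
* The empirical-P floor of `1/N` makes `P < 0.01` unattainable on grids of
  100 windows or fewer; use longer genomes or more contigs.
* The Ajk caveat above: the 0.9 relatedness cutoff is not meaningful on
  very small related panels.
* The simulator models neither variable recombination maps nor gene
  conversion; EHH distances are physical bp (an optional genetic map is a
  possible extension, not implemented).
* On desk-scale panels the ZHp argmin localizes a completed sweep only to
  within a window or two of the true position (see above); treat merged
  regions, not single windows, as the unit of localization.

## Reproducibility

Every pipeline run writes a manifest (configuration echo, input checksums,
thresholds, standardization constants, filter accounting). Reruns from the
same inputs and configuration are byte-identical, which the test suite
asserts file by file.
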