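---
title: "Two-locus mutual information scans for breed-discriminative SNPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-locus mutual information scans for breed-discriminative SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmiscan)
```

## The problem

Two intensively selected populations — the motivating case is a beef
breed and a dairy breed of cattle — differ at a small set of genomic
positions whose genotypes essentially *determine* which population an
individual belongs to, against a large background of shared
polymorphism.  `cmiscan` scans a genome of biallelic SNP genotypes for
such positions using an information-theoretic score that needs no model
of allele-frequency change or haplotype structure: it asks directly how
much information the genotypes at two adjacent loci carry about the
population label.

## The score

Let $y$ be the population label (two levels) and let $x_1, x_2$ be the
genotype classes of two adjacent SNPs.  Genotypes are the ten unordered
base pairs AA, TT, GG, CC, AT, AG, AC, TG, TC, GC; heterozygote
orientation is collapsed, so `0/1` and `1/0` encode the same class.
All estimators are plug-in (maximum-likelihood) with natural logarithms,
so values are in nats, and $0 \log 0 = 0$ throughout.

The per-pair score is the mutual information between the label and the
*composite* two-locus genotype,

$$CI(y; x_1, x_2) \;=\; \sum_{y,s_1,s_2} p(y,s_1,s_2)
  \log \frac{p(y,s_1,s_2)}{p(y)\,p(s_1,s_2)},$$

which by the chain rule decomposes as
$CI(y;x_1,x_2) = CI(y;x_1\mid x_2) + I(y;x_2)$, where

$$CI(y;x_1 \mid x_2) = \sum_{y,s_1,s_2} p(y,s_1,s_2)
  \log \frac{p(s_2)\, p(y,s_1,s_2)}{p(y,s_2)\, p(s_1,s_2)}$$

is the conditional mutual information: what the first locus adds beyond
the second.  The score is zero iff the label is independent of the
locus pair, and is bounded by $H(y)$.  For a balanced two-population
sample $H(y) = \ln 2 \approx 0.6931$, which motivates the default
flagging threshold $\theta = 0.693$: a pair at the threshold *fully
determines* the population.  The comparison is closed
(`score >= theta`) because the interesting scores *attain* the bound.
No bias correction (Miller–Madow, shrinkage) is applied — a corrected
estimator would change the meaning of $\theta$, which is only
interpretable for the raw plug-in sums.

`entropy()`, `mutual_information()`, `conditional_mi()` and
`mi_extractor()` expose the estimators on count tables;
`joint_counts()` builds the tables from observation vectors.

```{r extractor}
y  <- rep(c("breed1", "breed2"), each = 10)
x1 <- rep(c("AA", "GG"), each = 10)   # perfectly discriminative locus
x2 <- rep("TT", 20)                   # monomorphic partner
mi_extractor(joint_counts(y, x1, x2))
```

## Significance by label permutation

How an extractor score should be converted into a p-value is a design
choice here: we use a label-permutation null, which is distribution-free
and respects the genotype structure.  Labels are permuted while both
genotype vectors stay fixed; the Monte-Carlo estimate uses the add-one
form $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\mathrm{perm}})$,
which is a valid p-value and never zero.  For small samples an exact
mode enumerates all $\binom{n}{n_A}$ balanced relabellings and returns
the exact tail fraction.  Because the add-one minimum is
$1/(n_{\mathrm{perm}}+1)$, flagging at $p < 10^{-3}$ requires more than
1000 permutations; the scan default is 10,000.  Ties are counted in the
tail (scores within $10^{-12}$ of the observed value count as
exceedances), which makes the test conservative on heavily tied genotype
data — the test suite checks that the realised type-I rate at 0.05
stays inside binomial 99% bounds over 500 null replicates.

## The genome scan

`cmi_scan()` scores every consecutive same-chromosome SNP pair in
coordinate order — "adjacent" means consecutive in the coordinate-sorted
site list, with no physical-distance cap — and projects pair scores onto
SNPs by taking each SNP's maximum over the (at most two) pairs
containing it, recording the partner.  This projection preserves the
discriminative potential of a SNP whichever neighbour realises it.  Two
consequences are worth keeping in mind:

* every coordinate neighbour of a perfectly discriminative SNP also
  reaches $\ln 2$ (the pair containing the discriminative locus
  determines the label regardless of the partner), so flagged sets come
  in runs of planted loci plus their immediate partners; and
* a pair can reach the threshold although neither locus is marginally
  informative — two loci whose *joint* genotype (e.g. allele parity)
  encodes the population.  This is exactly the case where the two-locus
  extractor beats single-site mutual information, and the simulator can
  plant such pairs (see below).

Permutation p-values are computed lazily, only for SNPs whose score
reaches $\theta$: sub-threshold SNPs can never be flagged, so they are
reported with $p = 1$ unevaluated.  No multiple-testing correction is
applied by default (the flagging rule is a strict raw threshold
$p < 10^{-3}$); a Bonferroni option exists.  Chromosomes with a single
SNP cannot form a pair; such SNPs are reported unscored with a warning
count.

Downstream summaries: `genotype_class_distribution()` tabulates, per
chromosome, each population's *majority* genotype class at every flagged
SNP (the reduction from individuals to one class per SNP per population
is a reporting choice; ties resolve by the canonical class order);
`heterozygosity_table()` computes per-population mean heterozygote
counts over flagged loci, partitioned on whether the *other* population
is all-homozygous — empty partitions are reported `NA`, deliberately
distinct from 0; `genotype_profile()` gives the per-site class counts
inside a gene; `mito_summary()` reports the flagged percentage on the
mitochondrial contig (default name `"MT"`) to one decimal.

## XP-EHH for method comparison

As an orthogonal, haplotype-based detector of population-specific
selection the package implements cross-population extended haplotype
homozygosity from scratch on phased matrices.  `ehh()` computes
site-EHH with both core alleles pooled: at each successive SNP outward
from the core, haplotypes are grouped by their allele string over the
flanking window (the core site itself is excluded, so the curve starts
at exactly 1), and $EHH(d) = \sum_h \binom{c_h}{2} / \binom{n}{2}$.
`ihh()` integrates the curve trapezoidally over physical distance —
only physical coordinates are available from a VCF, so no genetic map
is used — in both directions, truncating at the *first sample point*
below the truncation level (default 0.05); that point's trapezoid is
included and no interpolation of the crossing is attempted, keeping the
rule deterministic.  Curves that never reach the truncation before the
chromosome end are integrated to the end and flagged `edge_warning`.

`xpehh_scan()` forms $\ln(iHH_A/iHH_B)$ per site, drops sites where
either area is below `min_ihh` (default $10^{-8}$; log-ratios of
near-zero areas are unstable — a floor, not a pseudocount, so no bias
is introduced), and standardises the retained scores genome-wide to
mean 0, variance 1.  Positive standardised scores indicate longer
haplotype homozygosity in population A.  `select_extremes()` takes the
top and bottom `floor(n * quantile)` sites (default quantile 0.01) as
candidates for the two populations, annotated to their closest genes;
candidates are selected per SNP, not per 50-kb window.  A degenerate
all-equal score distribution yields z = 0 with a warning and empty
candidate sets.

One resolution caveat is inherent to iHH statistics: the EHH windows of
neighbouring SNPs overlap almost completely, so the *ordering* of
scores within a swept tract is essentially exchangeable noise.  The
meaningful statement at sweep scale is that the maximal score falls
inside (or immediately flanking) the swept tract, and that is what the
tests assert — not that the literal core SNP outranks its neighbours.

## Gene-set enrichment

`enrich()` performs the one-sided hypergeometric over-representation
test (upper tail $P(X \ge k)$, via `stats::phyper`) of a candidate gene
list against a literature catalog.  The gene universe is a required
explicit argument: reported p-values are meaningless without knowing
$N$, so the package never defaults it.  Symbols match
case-insensitively after whitespace stripping; query or catalog genes
outside the universe are dropped with a warning.

## Coordinates and I/O conventions

SNP positions are 1-based (VCF) everywhere; gene intervals are
normalised to 0-based half-open on read (`read_gene_annotation()`
accepts BED4+ natively and converts GFF3 `gene` features, taking names
from `Name=`, then `gene_id=`, then `ID=`).  Nearest-gene assignment
(`assign_snps_to_genes()`) maps a site inside a gene to that gene,
otherwise to the nearest gene on the chromosome within
`max_distance_bp`, breaking exact ties by the smaller gene start;
unassigned is a valid outcome.  There is no principled default for
`max_distance_bp` — inside-gene-only (0) is the conservative default.
Strand is kept but unused: the ten-class genotype scheme is strandless.

Missing genotypes are a hard error, not imputed or skipped: entropy
estimates on partial counts are ill-defined without an imputation
model, and imputation belongs upstream (e.g. BEAGLE) of this package.
Multiallelic and indel records are dropped with counts, not decomposed,
because the ten-class scheme is defined on biallelic SNPs.

## The simulator: what it emulates and what it does not

`simulate_breeds()` generates a phased two-population cohort with
truth-tagged structure.  Background loci draw a shared allele frequency
per site (uniform on [0.05, 0.95]) and independent Hardy–Weinberg
genotypes in both populations, so background genotypes are
label-independent *by construction* — the correct null for the scan.
On top of that it plants:

* **fixed differences** — population 1 fixed for one homozygous class,
  population 2 for another; perfectly discriminative, score $\ln 2$;
* **breed-exclusive heterozygosity loci** — the owner population mixes
  heterozygotes and reference homozygotes while the other population is
  fixed for the alternate homozygote; these reproduce the
  heterozygosity-pattern table structure (the conditional mean
  heterozygote count of the other population is exactly zero);
* **epistatic pairs** — two adjacent loci whose allele parity encodes
  the population while each marginal genotype distribution is
  label-balanced; flagged as a pair with no spill-over onto
  neighbours;
* **a haplotype sweep** — a carrier fraction (default 0.9) of
  population A's haplotypes has the segment of the configured length
  (default 200 kb) around the core replaced by one shared haplotype,
  per the rectangular-tract reading of a near-fixed sweep.

Defaults mirror a balanced 10 + 10 design.  The mitochondrial contig
(33 SNPs over ~16.3 kb, haploid-like homozygous genotypes) carries four
epistatic pairs by default, so the default scan flags exactly 8 of 33
mitochondrial SNPs (24.2%).  Epistatic pairs rather than fixed
differences are used there because a fixed difference necessarily
drags its coordinate neighbours over the threshold, making an exact
8-SNP flagged set unrealisable.

What the simulator does **not** emulate: linkage disequilibrium outside
the injected sweep (background loci are independent), recombination
maps, mutation-rate heterogeneity, demography, or genotyping error.
Tests passing on this generator therefore demonstrate correctness of
the estimators and the planted-structure logic, not performance under
realistic background LD — on real data, adjacent-pair scores are
correlated along the genome and flagged runs will be longer.

## Numerical choices

* Natural logarithms everywhere; $\theta = 0.693$ is meaningful only in
  nats.
* Plug-in CMI is clamped to zero when round-off produces values in
  $(-10^{-12}, 0)$; the chain-rule identity is exact to $10^{-12}$.
* Permutation tail comparisons use a $10^{-12}$ tolerance so that
  bitwise-equal maximal scores count as ties.
* Trapezoidal iHH truncates at the first sub-threshold sample point
  (included), resolving the boundary deterministically.
* z-standardisation uses the sample standard deviation; mean 0 and
  variance 1 hold to $10^{-9}$.

## Problem sizes

The shipped tests and the acceptance script run the scan on simulated
cohorts of 2 autosomes x 200 SNPs plus the 33-SNP mitochondrial contig,
20 samples, with 2000 permutations per tested pair; calibration uses
500 null replicates at 399 permutations, recovery 20 seeds, and sweep
detection 10 seeds.  These sizes were chosen as the smallest at which
every planted-structure statement is exact rather than approximate; the
scan itself is linear in pairs and has been run comfortably at two
orders of magnitude more sites.

## Known limitations

* Two populations only; the extractor generalises to $k$ labels and
  more loci, but thresholds and the permutation design here assume
  binary balanced labels (unbalanced labels lower $H(y)$ and hence the
  attainable maximum — set `theta` accordingly).
* Per-SNP max projection reports partners of discriminative SNPs as
  discriminative; interpret flagged runs, not isolated flags.
* XP-EHH requires fully phased input and localises sweeps to tract
  resolution, not SNP resolution.
* The enrichment test inherits the usual caveats of gene-universe
  choice; it implements only the hypergeometric tail, not GO/KEGG
  retrieval or term grouping.
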