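---
title: "Comparative SNP and haplotype diversity and LD decay: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative SNP and haplotype diversity and LD decay: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodiv)
```

haplodiv compares genetic diversity and linkage disequilibrium (LD) between
germplasm sets of inbred lines — the classic tropical-versus-temperate maize
contrast — using biallelic SNPs and the multi-allelic haplotypes built from
them. This vignette is the package's account of the statistics it computes,
the windowing and filtering rules it applies, the synthetic data generator it
ships for testing, and the design decisions taken where reasonable
alternatives existed.

## Data model

Genotypes are held in a `genotype_matrix`: samples × SNPs, each call coded as
the dosage of the alternate (B) allele — 0 (hom A), 1 (het), 2 (hom B) or
`NA` (missing). The panel is assumed to consist of (mostly homozygous) inbred
lines; heterozygous calls are retained as first-class data because genotyping
pipelines report residual heterozygosity, but several downstream steps treat
them specially (below). SNPs are canonically ordered by (chromosome,
position), 1-based with closed intervals throughout, matching VCF and GFF3
conventions; positions must be strictly increasing within a chromosome.
Strand is read from gene models but deliberately ignored by classification
and windowing: all rules here operate on physical position only.

## Region classification and marker sets

A SNP inside any exon interval of its gene is *exonic*; inside the gene span
but no exon, *intronic*; outside every gene span, *intergenic*
(`classify_snp()`). Exon intervals are the gene-level union over transcripts,
merged where overlapping; a UTR exon counts as exonic (no finer subclass is
used). When gene spans overlap, the SNP is assigned to the gene whose span
starts first, with ties broken by the lexicographically smaller gene id —
the rule is arbitrary but deterministic, which matters because gene-window
haplotype loci inherit it. Marker sets for comparison are `all`,
`intergenic`, `intragenic`, `intronic` and `exonic`, and satisfy the obvious
set algebra (`intragenic = intronic ∪ exonic`, disjoint from `intergenic`).

## Haplotype windowing

Three locus types turn runs of SNPs into multi-allelic markers:

* **gene windows** — all genic SNPs sharing a gene id, in genomic order.
  Single-SNP gene loci exist but only loci with ≥ 2 SNPs are informative as
  haplotypes; both are returned.
* **3-SNP sliding windows** — per chromosome, consecutive *disjoint* triples
  starting at the first SNP; each SNP belongs to at most one window and the
  trailing `n mod 3` SNPs stay unassigned. (The windows slide along the map
  but do not overlap.)
* **10 kb windows** — a SNP whose nearest same-chromosome neighbour is more
  than 10 kb away is excluded as unlinked; the remaining SNPs chain
  transitively, adjacent SNPs ≤ 10 kb apart joining one locus. Chaining, not
  a 10 kb cap on the total span, is used: it is the reading under which every
  retained SNP ends up in a ≥ 2-SNP locus, which is how the counts of the
  motivating maize study are self-consistent. The threshold is a parameter,
  so a cumulative-span variant can be emulated by post-filtering if wanted.

A sample's haplotype allele at a locus is the concatenation of its
homozygous calls (`"ABA"`, one letter per member SNP). The missing rule is
all-or-nothing: any missing member call makes the whole locus missing for
that sample. A heterozygous member call does too — phase would be needed to
resolve it, no phasing model is fitted, and at the residual-heterozygosity
levels of inbred panels the loss is negligible.

## Diversity statistics

For marker $i$ with allele frequencies $P_{ij}$, the polymorphic information
content is

$$\mathrm{PIC}_i = 1 - \sum_j P_{ij}^2 - \sum_{j<k} 2 P_{ij}^2 P_{ik}^2,$$

computed through the identity
$\sum_{j<k} 2 P_{ij}^2 P_{ik}^2 = (\sum_j P_{ij}^2)^2 - \sum_j P_{ij}^4$
(the test suite checks the closed form against the literal double loop). A
monomorphic marker has PIC 0; a biallelic marker peaks at
`pic(c(0.5, 0.5))` = 0.375.

SNP allele frequencies count two alleles per homozygote and one per allele
for a heterozygote (the genotyping platform's convention for residual hets
is unknowable from the data, and at simulated rates the choice is
negligible); haplotype alleles count once per non-missing sample.
Heterozygosity is the HET fraction of non-missing calls; haplotype loci have
heterozygosity 0 by construction. MAF of a multi-allelic locus is the
frequency of the second most frequent allele. `summarize_diversity()`
recomputes allele frequencies *within* each germplasm set before averaging
(rather than reusing whole-panel frequencies — the alternative reading);
loci monomorphic within a subset are retained with PIC 0, and loci with no
non-missing call in a subset are dropped from that subset's mean with a
reported count.

## Population structure

The Rogers distance between two lines averages, over loci where both have
calls, $\sqrt{\tfrac12 \sum_a (p_a - q_a)^2}$ with within-individual allele
frequencies (homozygote 1, het ½ each); for biallelic SNPs this is
|dosage difference|/2, and the pairwise-complete handling of missing data
divides by the number of loci actually compared. Neighbor-joining follows
the classical Saitou–Nei agglomeration with two numerical conventions: ties
in the Q-matrix minimum are broken by the smallest (i, j) index pair, making
runs reproducible, and negative limb lengths are clamped to zero after
computation, as distance-based tree software commonly does. The tree is
unrooted with a trifurcating final join; `write_newick()` emits branch
lengths at 6 decimals and quotes labels containing whitespace.

`deepest_split()` operationalizes "the two major groups": among internal
edges it maximizes branch length × (tips on one side) × (tips on the other),
i.e. the edge contributing most to the total tip-to-tip path length. The raw
longest internal edge is *not* used — in practice it tends to be the stalk
of a cherry of two outlier lines, whereas the size-weighted criterion finds
the central divergence.

## Linkage disequilibrium

Because the panel is inbred, two-locus phase is directly observable:
haplotype counts for a SNP pair are taken from samples homozygous and
non-missing at both SNPs. With B-allele frequencies $p_i, p_j$ and joint
frequency $p_{ij}$ among those samples, $D = p_{ij} - p_i p_j$ and

$$R^2 = \frac{D^2}{p_i(1-p_i)\,p_j(1-p_j)},$$

identically the squared Pearson correlation of the 0/1-coded alleles.
Significance is a two-sided Fisher exact test on the 2 × 2 haplotype count
table, computed by hypergeometric summation (the sum of table probabilities
not exceeding the observed one, with the same 1e-7 relative tolerance as
`stats::fisher.test`, which it reproduces; the in-package implementation
exists because a genome's worth of pairs means hundreds of thousands of
tests per run). Pairs need at least 10 informative samples (configurable)
and both SNPs polymorphic among them; only within-chromosome pairs are
computed. SNPs enter LD analysis after a strict `MAF > 0.05` filter,
applied within the sample subset being analysed.

Per-chromosome summaries report the percentage of pairs significant at
α = 0.01 and the percentage with $R^2 > 0.1$ under *both* denominators in
circulation — all pairs, and significant pairs only — because comparative
studies quote both and silently choosing one invites misreading.

The decay curve bins pairs by distance into half-open geometric bins
(0–1, 1–2, 2–5, 5–10, 10–20, 20–50, 50–100, 100–1000 kb, > 1 Mb by
default — the resolution at which decay distances are conventionally
quoted) and averages $R^2$ per bin. The decay distance is where the mean
first falls below 0.1, linearly interpolated between the centers of the
last bin at/above and the first bin below the threshold, skipping empty
bins; the unbounded last bin uses its lower edge as center. If the first
occupied bin is already below threshold the estimate is censored low
(`decay_distance()` maps it to 0: decay completed below the binning
resolution); if no bin falls below, censored high (`Inf`).

## The synthetic data generator

No genotype matrix is bundled with the package's motivating studies, so
`simulate_genotypes()` provides a self-contained substrate with two
independently tunable knobs: founder-pool size (diversity) and a
recombination intensity (LD decay). Per subpopulation and chromosome,
`n_founders` founder haplotypes are drawn SNP-by-SNP (allele B with that
SNP's founder frequency, itself uniform on [0.1, 0.5] so that most SNPs
survive the MAF filter). Each line is a single gamete built by copying a
founder and switching to a uniformly chosen founder after each inter-SNP
gap with probability $1 - e^{-r \cdot \mathrm{gap} \cdot G}$, then doubled
to a homozygous genotype; residual heterozygosity (0.5%) and missing calls
(2%) are applied as independent per-call corruption afterwards. This
copying model was chosen over coalescent machinery deliberately: it is
O(samples × SNPs), exactly reproducible from a seed, and realizes the two
contrasts the analyses need.

Defaults describe a two-set panel of 300 "tropical" and 150 "temperate"
lines at 2000 SNPs on 10 chromosomes of 2 Mb: tropical lines draw from 8
founders with switch intensity 4 × 10⁻⁶ per bp per meiosis-equivalent over
10 generations, temperate from 4 founders at 1.5 × 10⁻⁶. Two properties of
the model informed these numbers. First, founder haplotypes are drawn in
linkage equilibrium, so the expected $R^2$ between fully linked SNPs is
only about $1/(K-1)$ for a $K$-founder pool — with dozens of founders the
0.1 decay threshold would never be crossed at any distance, so founder
counts must stay single-digit for decay distances to be measurable.
Second, with those caps (≈ 0.14 and ≈ 0.33) the chosen switch intensities
put the mean-$R^2$ crossing of 0.1 at roughly 4–5 kb (tropical) and ≈ 50 kb
(temperate), the contrast reported for real tropical and temperate maize.
The generator emulates: biallelic SNPs on mostly-homozygous lines, a
diversity gap between sets, subpopulation divergence through founder-pool
sampling drift, distance-dependent LD, missingness and residual
heterozygosity. It does not emulate: real maize demography, selection,
ascertainment bias of genotyping chips, mutation, or gene/intergenic
structure (simulated SNPs carry `region_class = "unknown"`; classification
is exercised against gene-model fixtures instead). Passing
parameter-recovery tests therefore show that the *analyses* recover known
generating contrasts — not that real maize has those parameters.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds; identical configuration
and seed reproduce byte-identical outputs, including the pipeline's staged
TSVs and run report. The test suite exercises the full default simulation
(450 × 2000, ten seeds) for parameter recovery, smaller two-chromosome
panels (100 × 200) for module behaviour, 1000 random annotation fixtures
for the windowing invariants, and exhaustive oracles where feasible: PIC
against the double loop up to 23 alleles, Fisher p against complete table
enumeration for totals ≤ 30, and neighbor-joining against an exhaustive
topology search with least-squares branch fitting for 4–8 taxa — sizes
chosen so the whole suite completes in a few minutes.

## Known limitations

* Founder pools in linkage equilibrium cap attainable $R^2$ (above); the
  simulator cannot produce strong long-range LD together with large founder
  numbers.
* Heterozygous calls are discarded from haplotype calling and LD counting
  rather than phased; for panels with appreciable heterozygosity a phasing
  model would be required.
* No algorithmic subgroup-cutting rule is provided beyond the deepest
  split; finer subgroup structure is the analyst's call on the exported
  tree.
* Inter-chromosomal LD, D′, haplotype-block calling, F-statistics and
  model-based admixture inference are out of scope.
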