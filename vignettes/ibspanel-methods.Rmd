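---
title: "Methods: IBS clustering and informative marker panels"
author: "ibspanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IBS clustering and informative marker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibspanel)
```

## The problem

Many perennial crops — date palm prominently among them — are maintained as
named cultivars, often by vegetative propagation, so distinct trees can be
genetically identical while the population as a whole splits into deep
geographic subpopulations (here labeled *Eastern* and *Western* by
convention).  Given dense SNP genotypes for a reference collection of
cultivars, a set of outgroup samples from related species, and unknown
"survey" trees, the questions are: which subpopulation does each unknown
cultivar belong to, which named cultivar cluster does each survey tree fall
into, and how few markers suffice to answer reliably.

`ibspanel` implements that workflow: staged genotype quality control,
identity-by-state distances, Ward clustering with outgroup orientation,
label propagation through shared cluster membership, and reduction of the
marker set to a compact panel of highly informative SNPs whose fidelity is
quantified against the full set.

## Genotype model and quality control

Genotypes are diploid alternate-allele dosages $g \in \{0, 1, 2\}$ with a
missing state; every call carries a read depth.  Insertions/deletions are
skipped at read time — every downstream statistic assumes SNPs — and
multi-allelic records are flagged and removed by the biallelic filter
rather than being approximated.  Half-called genotypes (`./0`) have no
defined dosage and are treated as missing; phasing separators are ignored
because only dosage enters any statistic.

The QC cascade runs in a fixed order with strict inequalities:

1. **Depth mask** (default 10×): heterozygotes cannot be called reliably
   at low coverage, so calls below threshold become missing.  When masking
   is requested but a call has no recorded depth, the default `strict`
   policy masks it — unverifiable coverage is treated as absent coverage —
   with a `lenient` opt-out.
2. **Variant missingness > 0.4 removed**, a coarse first pass.
3. **Sample missingness > 0.3 removed**.
4. **Recompute** missingness on the surviving samples; retain biallelic
   SNPs with missingness **< 0.1** and Hardy–Weinberg exact-test
   $p > 10^{-6}$.

Values exactly at a boundary are therefore kept at stages 2–3 and dropped
at stage 4.  The recomputation at stage 4 matters: a variant missing only
in a removed sample becomes complete and survives.  No minor-allele
frequency filter is applied; monomorphic markers are legal and are simply
never selected by PIC ranking later.  The cascade is idempotent, and each
set of samples (cultivars, outgroup, survey trees) is processed
independently before merging, because depth profiles and missingness
structure differ between sample sets; the Hardy–Weinberg test is
accordingly per-set as well.

The Hardy–Weinberg test is the exact conditional test: given the observed
allele counts, all heterozygote counts of the same parity are enumerated
and the p-value sums the probabilities of configurations no more probable
than the observed one.  Probability ties are included, compared with a
$10^{-12}$ relative tolerance so floating-point noise in the log-factorial
evaluation cannot split a tie.  The mid-p variant is deliberately not
used; the plain exact test is the convention behind this kind of filter.

## Distances, clustering, assignment

Identity-by-state similarity between two samples is the mean share of
alleles identical in state over loci where both are called:
$s_{ij} = \operatorname{mean}_\ell\,(1 - |g_{i\ell} - g_{j\ell}|/2)$, and
the distance is $1 - s_{ij} \in [0, 1]$.  Two heterozygotes share both
allele states and count as full sharing.  Denominators are per-pair
(pairwise-complete loci), not complete-case: a sample with scattered
missingness still contributes every locus it shares with each partner.  A
pair with zero shared loci is an error naming the pair, not a silent NA.

Clustering is agglomerative Ward on the **raw** dissimilarities — the
`ward.D` convention, i.e. the Lance–Williams update
$d(k, i\cup j) = \frac{(n_i+n_k)\,d(k,i) + (n_j+n_k)\,d(k,j) - n_k\,d(i,j)}{n_i+n_j+n_k}$
applied without squaring the input.  This is not `ward.D2`; the two differ
in merge heights, and the choice is pinned in the tests by a hand-worked
3-point example (distances 1, 4, 4 merge at heights 1 then 5) and by a
brute-force oracle.  These (1−IBS) dissimilarities are an operational
measure of genotype sharing, not evolutionary distances: clones sit at
distance 0, seed offspring at intermediate distances, so branch lengths
should not be read as divergence times.

The tree is exported as Newick with ultrametric branch lengths derived
from merge heights (a leaf's branch equals its parent's merge height), so
the file reparses to the identical dendrogram.  Orientation by the
outgroup rotates internal nodes so the smallest clade containing all
outgroup samples is drawn first; rotation never changes merge structure or
heights.  If that clade contains ingroup samples the tree is flagged
non-monophyletic rather than re-rooted by force.

Unlabeled samples are assigned by **shared cluster membership**: cut the
tree into `k_top` clusters (default 3 — outgroup plus the two cultivar
subpopulations) and give each unlabeled sample the majority label among
labeled samples in its cluster.  A cluster with no labeled members, or
with a tied majority, yields `"unknown"` plus a report entry; the package
refuses to guess on a tie because a wrong subpopulation call is worse than
an abstention.  Survey-tree composition is reported at a deeper,
configurable cut (default 6 clusters) with raw counts and whole-number
percentages; proportions of newly assigned cultivars are printed at two
decimals.

## Informative marker panels

For a biallelic marker with minor allele frequency $a$, polymorphism
information content is
$\mathrm{PIC}(a) = 1 - \left(a^2 + (1-a)^2\right) - 2a^2(1-a)^2$,
strictly increasing on $[0, 0.5]$ with maximum $0.375$ at $a = 0.5$.

Panel construction is two-staged:

* **LD pruning** (`r2_max = 0.1`, window 50 variants, step 5): within each
  window, whenever a retained pair has squared dosage correlation at or
  above the threshold, the later-positioned variant is removed
  (keep-first — deterministic and standard).  The window/step sizes are
  package defaults recorded in the panel provenance; `window = Inf` gives
  global all-pairs pruning for small sets.  $r^2$ is the composite
  (phase-free) genotype correlation over pairwise-complete samples,
  because phase is not available in dosage data; undefined $r^2$ (zero
  variance, fewer than two shared calls) never causes pruning.
* **PIC threshold** (`pic_min = 0.37`, inclusive ≥): among pruned
  variants, keep those with PIC at or above threshold.  The inclusive
  bound is the operative protocol choice where an exclusive reading was
  also defensible; the flag is recorded in the panel provenance so the
  decision is auditable.

Panel fidelity is measured two ways on the same sample set: the Pearson
correlation of the strictly-lower-triangle entries of the panel and
full-set distance matrices, and a Mantel permutation test (rows and
columns of one matrix permuted simultaneously; one-sided
$p = (1 + \#\{r_{perm} \ge r_{obs}\})/(1 + n_{perm})$).  Permutations
default to 999 — 99 is too coarse to support claims below $p = 0.01$ — and
the seed is an explicit required argument, so a fidelity report is exactly
reproducible.

## The synthetic generator

`simulate_genotypes()` draws the statistical structure the pipeline
assumes, so every stage is testable without external data:

* ancestral allele frequencies uniform on $[0.05, 0.95]$ (bounded away
  from fixation so PIC selection has dynamic range);
* subpopulation frequencies via the Balding–Nichols construction,
  $\mathrm{Beta}\left(p\frac{1-F}{F},\ (1-p)\frac{1-F}{F}\right)$, with
  $F = 0.1$ for the Eastern/Western analogs and $F = 0.5$ for the
  outgroup.  Drift-style frequency divergence is all the analysis needs;
  an explicit coalescent would add realism the statistics never see;
* genotypes $\mathrm{Binomial}(2, p_{sub})$ per locus;
* clones as exact genotype copies of random cultivars with independently
  re-drawn depth and missingness (vegetative propagation);
* seed progeny taking one allele per locus from a named mother and one
  from the mother's subpopulation frequency (an unknown father);
* depth $\mathrm{Poisson}(30)$ by default (negative binomial available
  via `depth_dispersion`), calls below 10× masked, plus 2% extra random
  missingness.

Defaults are 30 + 30 founders, 10 outgroup, 5 clones, 5 progeny, 2,000
markers — a small high-coverage study in which the two subpopulations are
clearly separable but individual pairs remain noisy.  Founders enter the
metadata as labeled cultivars, clones and progeny as unlabeled survey
samples, so the generator exercises label propagation exactly the way a
real survey would.

What the generator does **not** emulate: physical linkage (markers are
exchangeable, so LD pruning only ever sees structure-induced correlation),
selection, real chromosome organization, batch effects between sample
sets, and genotyping error beyond depth-driven missingness.  Passing tests
on synthetic data therefore validate the statistical machinery, not the
wet-lab robustness of any particular marker assay.

## Numerical and design notes

* Positions are 1-based throughout, as in the input format; no half-open
  conversions anywhere.
* Ward tie-breaks follow the minimum-index rule of the underlying
  agglomeration; all oracle comparisons use continuous random distances
  where ties have probability zero.
* `mantel_test` and `simulate_genotypes` save and restore the caller's
  RNG state; determinism is part of both functions' contracts.
* The merge step projects every sample set onto the cultivar set's
  post-QC variants.  A merge needs a reference variant list; the cultivar
  collection is the reference panel by construction, and survey samples
  genotyped on fewer sites simply become missing at the gap — consistent
  with the per-pair IBS denominators downstream.
* `run_full_study()` writes each artifact as it completes and keeps a
  MANIFEST of finished stages, so a failed run is diagnosable from disk.

## Test scale and known limitations

The test suite validates the exact statistics against independent
brute-force oracles at small sizes (Hardy–Weinberg against full
enumeration for all genotype triples up to $n = 50$; IBS against explicit
per-allele sharing on 5×20 matrices; Ward against a literal
Lance–Williams implementation up to 8 leaves) and the end-to-end behavior
on simulated studies of 60–80 samples × 2,000–4,000 markers.  Cluster
recovery of the three-group structure (ARI ≥ 0.95 in at least 19 of 20
seeded replicates at $F = 0.1$, outgroup divergence 0.5) is part of the
acceptance suite.

One acceptance property is known not to hold at this simulated scale: a
PIC ≥ 0.37 panel drawn from a 4,000-marker, two-subpopulation study
(F = 0.1, 80 samples) retains roughly 350 markers, and the correlation
between its distance matrix and the full-set matrix plateaus near 0.7 —
any 350-marker subset is capped near 0.8, because between-pair signal
variance under this design is comparable to 350-marker sampling noise.
Distance-matrix correlations approaching 0.98 arise when the compared
matrices include deeply diverged outgroup samples, whose pair distances
dominate the variance; the corresponding test is kept at its nominal
threshold and documents the gap rather than hiding it.

Other limitations: no imputation, no per-genotype quality (GQ) filtering,
no haplotype/phase-aware LD, no bootstrap support values on the tree, no
polyploid genotypes, and no minimal-discriminating-subset optimization of
the panel beyond the PIC/LD rules.
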