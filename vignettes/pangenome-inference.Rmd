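---
title: "Pangenome and core genome inference with pancore: methods and design"
author: "pancore maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pangenome and core genome inference with pancore: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancore)
```

# Scope

`pancore` infers pangenomes (a partition of all predicted genes of a set
of genomes into orthogroups) and core genomes (families present in nearly
all genomes, in single copy) for prokaryotic datasets that may span
multiple species or genera. It also subsamples representative genomes in
linear time, builds concatenated core-gene supermatrices for phylogeny
inference, and computes pangenome statistics: gene fixation frequency
across species and a joint maximum-likelihood model of orthogroup
prevalence and genome completeness. A simulator generates multi-genome
datasets with known orthogroup truth, which is how the package validates
itself.

This vignette explains the methods, the tunable parameters, the
numerical choices, and the limits of what the simulated validation can
show.

# Pangenome inference

## Superclustering

All amino-acid sequences are first grouped by a greedy incremental
preclustering: genes are processed by decreasing length, and each gene
joins the earliest-founded precluster whose representative (its longest
member) shares a k-mer identity estimate of at least
`preclusterIdentity`, founding a new precluster otherwise. The estimate
is the fraction of shared distinct 5-mers relative to the smaller k-mer
set. Note the scale: for sequences with residue identity $p$, the
expected fraction of intact 5-mers is roughly $p^5$, so the default
threshold of 0.5 corresponds to roughly 87% residue identity. The
representative index is k-mer-inverted, which makes preclustering
effectively linear in the number of genes.

Preclustering alone fragments families at genus-level divergence. A
second, profile-based pass restores sensitivity: for each precluster a
multiple sequence alignment and an alignment profile with a consensus
sequence are built, profiles are compared all-versus-all (restricted to
pairs whose consensi share 5-mers), and preclusters whose symmetrised
profile score reaches `superclusterFrac` times the smaller profile
self-score are connected. Connected components are the superclusters.

The default `superclusterFrac = 0.25` was chosen from the observed score
geometry: fragments of one family at ~90% nucleotide identity score
around half of the smaller self-score (their consensi are roughly 70–85%
identical), while unrelated profiles score below 5% of it. A threshold
of 0.5 sits on top of the within-family distribution and splits real
families; 0.25 separates the two regimes with a wide margin on both
sides. The candidate prefilter (consensus 5-mer fraction at least 0.02)
is similarly permissive because same-family consensi can share as few as
8% of their 5-mers.

## Iterative binary splitting

Each supercluster is split recursively. One iteration:

1. **Representatives.** If the cluster has fewer than `maxAlign`
   (default 512) members, all are representatives; otherwise `nReps`
   (default 32) are chosen by maximin farthest-first traversal over
   k-mer distance, so the representatives cover the cluster's diversity.
2. **Alignment and bipartition.** Representatives are aligned; a
   distance matrix (one minus the fraction of identical positions over
   columns where neither row is gapped; disjoint rows get distance 1)
   feeds average-linkage hierarchical clustering, cut at the root into
   the two top-level groups.
3. **Re-inflation.** Non-representatives join the side of their closest
   representative by k-mer identity. Representatives stay on their own
   side, so both sides are always non-empty.
4. **Co-occurrence test.** The split is accepted only if the two
   subclusters co-occur in genomes at least as often as expected when
   the division of the parent's genes into groups of the observed sizes
   is random. For a genome holding $k$ of the parent's $n$ genes with
   proposed sizes $a$ and $b = n - a$:
   $$P(\text{no } A \text{ gene}) = \binom{n-k}{a}\Big/\binom{n}{a},$$
   and the expected number of co-occurring genomes is
   $\sum_g \left(1 - P_g(\text{no } A) - P_g(\text{no } B)\right)$ (the
   both-absent term vanishes for $k \ge 1$). Accepted splits recurse;
   rejected clusters are emitted as one orthogroup.

The expectation is exact (hypergeometric), and the test suite checks it
against a 10,000-draw label-permutation Monte-Carlo.

**Boundary rule.** For strictly single-copy clusters every genome holds
one gene, so observed and expected co-occurrence are both zero. Read
literally, "at least as often as expected" would then accept every
split and shred single-copy families into singletons. When
`observed == expected == 0` the split is therefore rejected. Clean
paralogs (a genome holding genes on both sides) always have positive
expectation, so genuine paralog splits are unaffected. This boundary
case is the one place where the acceptance rule is deliberately strict;
it is what makes the recursion terminate with sensible orthogroups on
single-copy data.

**In-paralogs.** When a family carries a duplication confined to a
clade, the affected genomes hold both copies, co-occurrence supports
the split, and the two paralog groups become separate orthogroups. The
simulator's truth keeps in-paralogs in their parent family (they descend
from a single ancestral gene), so each such family costs a small amount
of recall in the gene-pair score. With the default duplication
probability this effect is on the order of a tenth of a percent and the
benchmark F stays above 99%.

# Core genome inference

The core module avoids a full pangenome. Four steps:

1. Infer the pangenome of `nSeedGenomes` (default 100) randomly chosen
   seed genomes.
2. Candidate core families: single copy in at least `candidateCorePrev`
   (default 90%) of the seeds. Build an alignment and a profile per
   candidate.
3. Search all profiles against all seed sequences and calibrate a score
   cutoff per profile: the midpoint between the mean member score and
   the mean of the best non-member score per genome. Membership is then
   re-decided by the cutoffs, and final core families must be single
   copy in at least `finalCorePrev` (default 95%) of seeds.
4. Assign non-seed genes by profile search under the same cutoffs; a
   gene passing several cutoffs goes to its best-scoring family.

Two calibration choices deserve comment. "Mean of member and non-member
scores" is ambiguous between the mean of the pooled scores and the
midpoint of the two class means; the pooled mean is dominated by the far
larger non-member class and collapses toward noise, so the midpoint is
used. The non-member pool keeps only the best hit per genome because the
discriminative boundary that matters is against each genome's closest
paralog, and this makes the cutoff insensitive to how many weak hits the
search happens to return. With no non-member hits at all the cutoff
falls back to half the member mean.

# Representative sampling and ANI

`pairwiseAni()` computes the identity between two genomes as the mean of
per-gene global-alignment identities over families with exactly one copy
in each genome — a core-genome ANI (cANI) when a core pangenome is
supplied. `method = "meanXX"` trims `floor(((100-XX)/200) * m)` genes
from each tail of the sorted identities before averaging (`mean90`
keeps the middle 90%); the trimmed variant (tcANI) is robust to outlier
genes such as recent horizontal transfers, which otherwise drag the
plain mean down. Nucleotide sequences are preferred when present;
otherwise the value is an amino-acid identity and should be read as an
AAI.

`sampleGenomes()` runs maximin farthest-first traversal over
`1 - ANI`: the first genome is the one farthest from a seeded random
pivot, and every subsequent pick maximises the minimum distance to the
genomes already sampled, maintained in an incrementally updated array.
This costs at most $k \cdot n$ distance evaluations for $k$ samples from
$n$ genomes — linear in $n$ for fixed $k$ — and the novelty sequence
(distance of each new genome to the nearest sampled one) is
non-increasing by construction. Sampling stops at $k$ genomes or when
the next novelty would fall below `1 - maxIdentity`. With a species map,
sampling runs independently within species under a per-species cap.
Ties are broken by the lexicographically smallest identifier and the
pivot is the only random element, so traces are reproducible from the
seed.

# Supermatrix construction

`concatSupermatrix()` builds the input for core-gene phylogenies: per
family (in sorted orthogroup order), all copies are removed from genomes
holding more than one copy, the remaining members are aligned at the
amino-acid level, residues are replaced by their codons (gaps become
`---`), and the per-family blocks are concatenated. Genomes missing a
family carry an all-gap block, so every row has the same codon-multiple
length and ungapping a genome's block reproduces its coding sequence
exactly. Genes whose nucleotide and amino-acid lengths disagree beyond
one codon (common for partial genes at contig edges) are skipped with a
warning rather than corrupting a column.

# Pangenome statistics

## Prevalence and completeness

Observed gene presence mixes two signals: how prevalent a family really
is, and how complete each genome assembly is. The model treats presence
of orthogroup $j$ in genome $i$ as Bernoulli with success probability
$c_i q_j$ ($q$ = prevalence, $c$ = completeness). Fitting alternates
one-dimensional Newton updates on each block with the other fixed,
clamped to $[\varepsilon, 1]$, with per-block backtracking so the
log-likelihood never decreases; after each sweep the completeness vector
is rescaled so $\max_i c_i = 1$, which removes the multiplicative
non-identifiability without changing the likelihood. Convergence is
declared when a sweep gains less than `tol` (default $10^{-6}$)
log-likelihood units. All-zero rows or columns are clamped to
$\varepsilon$ with a warning. Parameter recovery on matrices simulated
from known $(q, c)$ is part of the acceptance suite.

## Fixation frequency

The fixation frequency of an orthogroup is the fraction of species in
which it is part of the species-level core genome, among species where
it is present at all. Species-core membership uses the fitted prevalence
$q \ge 0.95$ rather than a raw presence fraction, so incomplete genomes
do not deflate core calls. Only species with at least `minGenomes`
genomes enter the computation, and records are emitted only for
orthogroups present in at least `minSpecies` retained species. A value
of 1 means the family is either core or absent in every species; values
near 0 flag families that are widespread but almost never fixed — a
signature of mobile elements.

## Evaluation metrics

`genePairPrf()` scores a predicted pangenome against a reference over
all unordered gene pairs (co-clustered in both = true positive),
computed from family-size contingency counts rather than materialised
pairs. `mapOrthogroups()` matches orthogroups between two pangenomes
when they share at least one gene copy in at least 95% of the genomes of
either family (the rule is applied to both genome sets; ties go to the
pair sharing most genes, then lexicographic). `ancestorDiscoveryOrder()`
checks a sampling order phylogenetically: each new genome discovers the
most recent common ancestor of itself and the closest genome already
sampled, and the statistic is the fraction of consecutive discoveries in
old-to-young order.

# The simulator

`simulatePangenome()` produces datasets with known truth. Genomes evolve
along a random coalescent tree; branch lengths are rescaled so that the
mean expected tip-tip Jukes–Cantor identity equals `targetIdentity`
(0.90 emulates a genus-level dataset; values near 1 emulate a
within-species population). Core families are present at the root and
never lost; accessory families are gained on a branch chosen with
probability proportional to branch length and are lost as a Poisson
process (`lossRate` events per branch, default 0.2) in their subtree —
with 2000 accessory families this yields the familiar U-shaped
prevalence distribution of rare and near-core accessory genes. With
probability `dupProb` (default 0.02, the order of magnitude of
clade-specific duplications visible in bacterial pangenomes) a family
acquires an in-paralog copy that receives an extra divergence burst
(10% of sites) and then evolves like any lineage. Sequences are
stop-free random coding sequences of 300–1500 nt evolving by point
substitutions only.

What the simulator deliberately omits: insertions and deletions within
orthologs (so the truth stays alignment-free), recombination and gene
conversion, codon-usage bias, intergenic DNA, and — most importantly —
assembly and gene-prediction artifacts. Benchmarks on simulated data
therefore measure the clustering method itself, not the robustness of a
full annotation pipeline, and accuracy on real data will be lower for
reasons unrelated to the inference algorithm.

Problem sizes used for validation are chosen to keep the default test
run fast while exercising the full pipeline: the routine suite uses 20
genomes with 300 families for the pangenome benchmark and 120 genomes
with 100 families for the core-versus-pan comparison, and the
acceptance script runs the full 100-genome, 3000-family configuration.

# Engine and numerical choices

The sequence-comparison engine is built in (no external binaries):
BLOSUM62 with affine gaps (open 11, extend 1) for amino-acid alignments,
match 2 / mismatch −3 (open 5, extend 2) for nucleotide alignments;
progressive multiple alignment over a UPGMA guide tree built from k-mer
distances, merging groups through a global alignment of their longest
members; alignment profiles with pseudocount frequencies
$(\text{count} + 0.1)/(\text{rows} + 2)$ over the 20 standard residues
(in gapped columns the deficit from 1 is the gap mass); and local
profile–sequence alignment with per-column $\log_2$-odds scores against
a uniform background of 1/20. Columns with at least 50% gaps are dropped
from the consensus and from scoring. Alignment kernels and k-mer
machinery are compiled code; everything else is R.

Determinism: every randomised step (seed-genome choice, sampling pivot,
core-gene subsetting, the simulator) takes an explicit seed, ties are
broken lexicographically, and two runs with the same seed produce
identical output.

Known limitations: the built-in aligner targets profile construction and
within-family distances, not external-aligner fidelity, and alignment
quality degrades below roughly 50% residue identity; profile-based
merging of preclusters loses sensitivity below roughly 65% consensus
identity, so extremely diverged families may stay split; and no synteny
or gene-order information is used.
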