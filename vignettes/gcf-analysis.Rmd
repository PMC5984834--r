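---
title: "Gene cluster families, domain networks and genome location: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene cluster families, domain networks and genome location: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcfkit)
```

This vignette is the package's account of its methods: the models and
rules it implements, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the underlying procedures were originally
manual or underspecified.

## The analysis problem

Actinomycete genomes carry many biosynthetic gene clusters (BGCs), and a
genus-scale comparison asks four questions. Which BGCs across strains are
variants of one pathway — one *gene cluster family* (GCF)? How does the
family inventory relate to the strain phylogeny? How fast does family
richness grow with the number of strains sampled? And where do clusters
sit on the chromosome relative to the replication origin? `gcfkit`
answers each with an explicit, testable procedure.

## Family membership criteria

Membership of two clusters in the same family is decided by four
conjunctive criteria, evaluated symmetrically (the smaller cluster — by
gene count, ties broken by id — always supplies the denominator):

* **I, architecture.** Same product class (PKS, NRPS, PKS/NRPS-hybrid,
  RiPP, Terpene, Other) and multiset Jaccard of gene-role composition at
  or above `architecture_role_jaccard_min` (default 0.5). Architecture
  comparison is traditionally done by eye; class match plus role-content
  overlap is our operationalization, and the floor is configurable.
* **II, function.** Strictly more than `majority_fraction` (default 0.5)
  of the smaller cluster's genes have a role present in the other
  cluster, irrespective of gene order.
* **III, identity.** Strictly more than half of the smaller cluster's
  genes have a protein match in the other cluster at
  `gene_identity_min = 0.50` identity and `gene_coverage_min = 0.80`
  coverage. A gene qualifies when *some* hit satisfies both thresholds
  simultaneously.
* **IV, module positions.** For modular classes only, KS and C domains
  are paired by modular position (index 1 with 1, 2 with 2, ... up to the
  shorter module list); the majority of compared pairs must reach
  `module_domain_identity_min = 0.80` identity. Extra modules on the
  longer side do not veto membership — the rule speaks only about
  positions present in both clusters. A modular cluster with no module
  annotation makes criterion IV "not applicable" (with a warning) rather
  than a veto.

"Majority" is interpreted as strictly greater than 50% everywhere;
using the smaller cluster's gene count as denominator makes every
criterion symmetric by construction.

Sequence comparison uses deterministic Smith–Waterman alignment (BLOSUM62,
gap open 10, extension 0.5, via `Biostrings`), with identity = matches /
aligned columns and coverage = aligned span of the shorter sequence over
its length. A precomputed hit table (e.g. from an external BLAST run) can
be supplied instead, reproducing a search-tool-based workflow without
making an external binary part of the test path.

Pairwise membership is not transitive, so families are defined as
connected components (single linkage) of the pairwise relation — the same
closure a similarity network applies. `assign_gcfs()` exploits this:
candidate pairs (within one product class; cross-class pairs fail
criterion I by definition) are visited in order of decreasing
domain-content similarity under a union–find structure, and a pair whose
members are already connected is skipped. A skipped pair's verdict cannot
change connectivity, so the resulting partition is provably identical to
exhaustive all-vs-all evaluation while avoiding most alignment work; the
test suite checks invariance under input permutation.

Families are categorized by strain frequency: `common` (four or more
strains), `rare` (2–3), `unique` (one strain — by strain count, so two
copies in one strain are still unique).

## Domain-content similarity network

Independently of the criteria, clusters are compared by Pfam-domain
content. With domain-type sets $D_a, D_b$ and copy numbers $a_d, b_d$:

$$J = \frac{|D_a \cap D_b|}{|D_a \cup D_b|}, \qquad
  \mathrm{DDI} = 1 - \frac{\sum_d |a_d - b_d|}{\sum_d \max(a_d, b_d)},
  \qquad S = w_J\,J + w_D\,\mathrm{DDI}.$$

The literature combining these metrics prints no closed formula for the
duplication component; the form above is chosen because it satisfies the
qualitative contract — 1 for identical copy-number vectors, 0 for
disjoint clusters, symmetric, monotone — and is oracle-testable. Weights
default to $w_J = 0.36, w_D = 0.64$, the customary Jaccard/duplication
mix; the one number we treat as fixed by practice on actinomycete data is
the edge threshold $S \ge 0.65$, which best reflects manually curated
families (published alternatives of 0.5 and 0.8 under- and over-split).
Two clusters that both lack domain annotation get similarity 0, not 1: an
empty annotation carries no evidence of relatedness. Components of the
thresholded graph are the network's families; when reference clusters
(e.g. a MIBiG-like catalogue, same TSV schema with `source=reference`)
are included, components are classified as own-only / reference-only /
mixed, with own-only singletons counted separately — the accounting used
to argue how much of a genus' repertoire is unknown.

`build_network()` computes all pairwise scores by linear algebra on the
cluster-by-domain count matrix; the scalar definitions remain the
reference implementation and the tests hold both to a brute-force
enumeration oracle at $10^{-12}$.

## Presence/absence profiling

The strain × family binary matrix (1 = family has a member in the strain)
orders columns by class and then descending abundance. Strain profiles
are compared with the Dice coefficient $2|A \cap B|/(|A|+|B|)$; two empty
profiles score 0 by the same no-evidence convention. The dendrogram is
UPGMA on distance $1 - \mathrm{Dice}$ (the distance transform is not
dictated by the original PAST-based workflow; $1-s$ is the simplest and
is config-exposed). UPGMA is implemented in the package rather than
delegated to `hclust` because exact ties are common on binary-profile
distances and we require a documented, deterministic tie-break (lowest
index pair); node height is half the merge distance, so the tree is
ultrametric with leaves at height 0. The implementation is tested against
a naive recompute-all-averages oracle and against `phangorn::upgma` on
tie-free random matrices.

## Rarefaction

Family richness per phylogenetic group uses analytic sample-based
(Mao–Tau-type) rarefaction: with $n$ strains in the group and family $j$
present in $n_j$ of them,

$$\tilde S(k) = S_{obs} - \sum_j \binom{n-n_j}{k} \Big/ \binom{n}{k},$$

the exact expectation of richness over random $k$-subsets (computed with
`lchoose` for stability). The original workflow used an external
estimator program without naming its settings; the analytic form is the
standard default and a Monte-Carlo mode (mean and SE over random subsets)
is provided for cross-checking. Curves are monotone non-decreasing and
concave, and extrapolation beyond $n$ (Chao-type) is deliberately not
attempted.

## Genome location relative to oriC

Circular chromosomes are linearized using the dnaA gene as the start
(oriC lies immediately upstream of dnaA). A cluster is represented by its
interval midpoint, computed circularly when the cluster wraps the origin.
With genome length $L$ and dnaA at $d$ on the plus strand,
$p = ((m - d) \bmod L)/L$; a minus-strand dnaA mirrors the coordinate
frame first, giving $p = ((d - m) \bmod L)/L$ — the analogue of aligning
the reverse-complement sequence. The midpoint (rather than the cluster
start) is used because it is robust to boundary trimming. Densities are
counted over `n_bins = 8` equal regions (`floor(p * n_bins)`), per class
and in total.

A family is *positionally conserved* within a clade when the maximum
pairwise circular distance ($\min(|\Delta p|, 1-|\Delta p|)$) among its
members is at most `tolerance = 0.05` of the genome length. The original
assessment of "same location" was visual; the tolerance formalizes it
and is config-exposed. A cluster counts as *hypervariable* when more than
half of its span lies outside the genome's conserved (core-alignment)
intervals, which this package consumes as BED input rather than
computing. Multi-replicon strains are out of scope: one chromosome per
genome, with inputs assumed on a single coordinate system.

## POCP genus delimitation

The percentage of conserved proteins between genomes $A$ and $B$ is
$(C_A + C_B)/(T_A + T_B) \times 100$, where $C_A$ counts proteins of $A$
with at least one hit in $B$ at e-value $\le 10^{-5}$, identity
$\ge 40\%$ and aligned fraction $\ge 50\%$ of the query. These cutoffs
come from the originally proposed POCP procedure, not from any single
study's text, and are config-exposed. Strains with POCP $\ge 50\%$ are
called the same genus. `pocp_from_sequences()` generates the hit tables
by all-vs-all alignment for desk-scale proteomes; no e-value is fabricated
in that mode (the e-value filter applies only to externally supplied hit
tables), and larger inputs are refused with a pointer to the hit-table
path.

## The synthetic-data generator

`generate_dataset()` emulates a genus-scale study: 4 clades × 5 strains
plus 2 outlier strains on 1 Mb circular chromosomes; 5 core families
present in every strain, 8 clade families vertical within each clade, 10
rare families in 2–3 random strains, and Poisson(6) unique families per
strain — which makes roughly 70–75% of families unique, the hallmark of
strain-level diversification (field surveys report on the order of 6–7
novel clusters per new species and two thirds of families unique).
Within-family instances diverge from a family archetype by domain
gain/loss (probability 0.05 per domain type), copy-number jitter (0.1),
protein substitution at 0.15 substitutions/site, and occasional local
gene-order shuffles (membership criteria are order-insensitive). Between
families, archetypes draw independent roles, domains (300-type alphabet)
and random proteins, keeping cross-family identity far below the
criteria thresholds.

Design choices worth recording:

* **Substitution model.** Uniform substitution over the 20 residues, no
  indels by default: each site mutates with probability $1-e^{-d}$ to one
  of the 19 other residues, so expected identity to the seed is exactly
  $e^{-d}$ — analytically predictable, which is what the generator's own
  tests verify by simulation.
* **Conserved module genes.** Genes carrying KS/C module domains evolve
  at `module_gene_conservation = 0.25` times the protein divergence.
  At the full default divergence two instances sit near 74% identity and
  criterion IV's 80% module-identity rule would reject genuine modular
  family members wholesale; slow-evolving assembly-line domains are also
  the biological reality (they are usable phylogenetic markers). The
  multiplier is a parameter, so the stringent regime remains reachable.
* **Positions.** Core and clade families occupy fixed relative positions
  outside the variable region (noise ±0.02, below the 0.05 conservation
  tolerance so planted structure is recoverable by design); rare and
  unique (HGT-tier) clusters land uniformly in the variable region
  `[0.3, 0.7]` opposite oriC. Each genome's conserved intervals — the
  complement of the variable region mapped through its own dnaA anchor
  and strand — are emitted as BED.
* **Clade tree.** A star of polytomous cherries (one per clade, outliers
  at the root); no branch-length realism is claimed. Outlier strains
  carry core and unique families only and receive the label
  `"singleton"`; when judging clade recovery from profile dendrograms the
  tree is cut into 4 groups and only clade-labelled strains are scored,
  since outliers carry no clade claim.

What the generator does **not** emulate: nucleotide sequence, intergenic
DNA, realistic Pfam grammar per cluster class, indels, unequal clade
sizes, or genome rearrangements. Passing the recovery tests therefore
shows that the pipeline's rules recover exactly the kind of structure
they define, under controlled divergence — not that real annotation
noise, fragmented assemblies, or atypical cluster architectures are
handled; on real data the alignment thresholds and the 0.65 network
threshold remain the user's responsibility to validate.

## Numerical choices and degenerate inputs

Empty-vs-empty domain sets and all-zero profile pairs score 0 (no
evidence ≠ similarity). A non-positive optimal alignment score yields
identity 0 and coverage 0. UPGMA refuses NaN distances; ties merge the
lowest-index pair. Rarefaction uses `lchoose` differences to avoid
overflow; `k` beyond the group size is a domain error rather than an
extrapolation. Positions are guarded against `p = 1` from floating-point
roundoff. The pipeline records its seed in every summary and writes an
MD5 manifest; identical config + seed reproduce byte-identical outputs.

## Problem sizes used in the tests

The default study conditions (22 genomes, ≈ 440 BGCs, ≈ 190 families) are
used for all recovery checks: family-assignment agreement with truth over
a 10-seed sweep, clade recovery over 20 seeds, and positional enrichment
over 10 seeds. Metric and position oracles run on 1,000 random cases,
UPGMA on 200 random 4–8 taxon matrices, and rarefaction is checked
exhaustively up to 6 strains and by 10,000-draw Monte-Carlo at 20
strains. Smaller simulated datasets (2 clades × 2–3 strains) exercise
round-trips, determinism and the pipeline plumbing.

## Known limitations

Criterion I's "similar architecture" reduces a visual judgement to class
+ role-content overlap; synteny is deliberately not scored. The pairs
evaluated are all pairs within a product class — a hybrid cluster
misclassified upstream will never be compared with its true relatives.
The exact duplication-index variant and weights used by earlier network
analyses are not recoverable from the literature; ours is documented and
configurable, with only the 0.65 threshold treated as anchored. POCP on
real genomes requires full proteomes; the in-package alignment mode is a
desk-scale convenience, not a replacement for a proper search tool.
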