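---
title: "Methods: pangenome, core-SNP phylogeny and pseudogene-aware gene-trait matching"
author: "lactopan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome, core-SNP phylogeny and pseudogene-aware gene-trait matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures behind each stage of the
package, the parameters that matter, and the design decisions taken where
several reasonable options existed. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The setting

*Lactococcus lactis*-style strain collections pose four linked questions:
how large are the pan- and core-genome; how do the strains relate
phylogenetically; which gene content is plasmid-borne; and which orthologous
groups (OGs) predict a binary strain trait such as subspecies genotype or
dairy/non-dairy isolation niche. Dairy starter strains complicate all four
through genome erosion: many genes survive only as pseudogenes, which are
neither cleanly present nor cleanly absent. The package therefore carries a
tri-state presence matrix (absent / pseudogene / present) through every
downstream computation.

## Orthology

**Alignment.** Protein pairs are scored by exact Smith–Waterman local
alignment with BLOSUM62 and affine gaps; a gap of length $L$ costs
$\mathrm{open} + L\cdot\mathrm{extend}$, default 11/1 (the classic protein
search setting). Exact dynamic programming replaces a heuristic search
engine deliberately: at a few hundred to a few thousand genes per analysis
it is affordable, has no seeds or E-value model to configure, and is fully
deterministic. A shared-k-mer prescreen (k = 4, ≥ 1 shared k-mer by
default) skips pairs that cannot pass the edge thresholds; it is a speed
device only, since every surviving pair is still scored exactly.

**Edge weights.** The score is normalized by the smaller self-score,
$w(a,b) = S(a,b)/\min(S(a,a), S(b,b))$, giving a scale-free weight in
$(0,1]$ with $w = 1$ for identical sequences. Edges require $w \ge 0.4$
and alignment coverage of at least half the shorter sequence — coverage is
measured on the *shorter* sequence on purpose, so that a pseudogene
fragment still connects to its full-length orthologs. An E-value-based
weight was rejected because it needs a database-size model that a
deterministic desk pipeline does not have.

**Markov clustering.** MCL is implemented directly on a sparse
column-stochastic matrix: add self-loops (maximum incident weight, floor
$10^{-6}$), normalize columns, then alternate expansion ($M \gets M M$) and
inflation (entry-wise power $r$, pruning entries below $10^{-5}$, column
renormalization) until the largest entry change falls below $10^{-6}$ or
100 iterations pass (the current partition is then returned with a
warning). Clusters are the weakly connected components of the converged
non-zero structure, so the output is always a partition and disconnected
components can never merge. Inflation defaults to 1.5, the long-standing
ortholog-clustering default; higher values fragment clusters. The
ortholog/in-paralog edge re-weighting found in some ortholog pipelines is
not reproduced: downstream analyses consume only the final OG membership
matrix.

## Pangenome and rarefaction

Pseudogenes count as *non-absent* for pan/core membership: OG counting
reflects gene content before intactness filtering, and an
intact-only switch (`require_intact`) is exposed where coreness should be
strict. Rarefaction draws `n_permutations` (default 500) random strain
orderings under a mandatory seed; for up to 8 strains all $N!$ orderings
can be enumerated exactly, which the tests exploit as a brute-force oracle.
The "leveling-off" of the pan curve is reported descriptively as the first
$k$ whose mean increment drops below 0.5% of the total OG count — it is a
description, not a test statistic.

## Core-SNP supermatrix and phylogeny

Single-copy core OGs (exactly one member in every strain, intact or
pseudogene — a truncated member still records the locus) are scanned
per aligned block; columns with ≥ 2 distinct residues are concatenated in
(sorted OG id, column index) order. Columns containing gaps or non-ACGT
symbols are dropped entirely: real alignments leave several defensible
treatments of gapped columns, simulated data is ungapped, and dropping is
the only choice that is deterministic for both.

Distances are p-distances — the fraction of supermatrix columns that
differ. Restricting to variable columns scales all pairwise distances by
the same factor (invariant columns contribute no mismatches), so tree
topology is unaffected; a Jukes–Cantor correction
($-\tfrac34\log(1-\tfrac43 p)$) is available as a model switch. Triangle
inequality violations are possible for p-distances and are permitted.

Neighbor joining is implemented in the package rather than delegated so
its numerical conventions are pinned down: ties on the Q-criterion go to
the lexicographically smallest pair of cluster representatives (each
cluster represented by its smallest leaf label), and a negative branch
length is clamped to zero with the deficit moved to the sister branch,
preserving the joined path length. NJ is exact on additive matrices, which
the tests verify against noiseless patristic distances, with `ape::nj` as
an independent topology cross-check. Approximate maximum likelihood is
deliberately out of scope: the claims the pipeline supports (clade
membership, outgroup position) are recoverable by distance methods at the
divergences involved.

Re-rooting requires the outgroup to form one side of a split of the
unrooted tree; the root bisects that edge. A non-monophyletic outgroup is
refused with an error rather than silently resolved.

## Plasmid calling

The chromosomal depth baseline is the *length-weighted median* of a
strain's contig depths: plasmid contigs are short and deep, so an
unweighted mean (or median over contigs) could be dragged upward in
plasmid-rich strains, while the weighted median essentially always lands on
chromosomal sequence. Calls use ratio ≥ 1.5 (typical lactococcal plasmid
copy numbers are ≥ 2) and length ≥ 2 kb (short contigs are repeat-prone).
Repeat-flagged contigs — the stand-in for manual curation of rRNA operons,
IS elements and prophages — are set aside as `unclassified`, never called
either way. OG-level assignment is majority vote over member genes with
ties going to plasmid; the tie direction is a convention, recorded in the
call output.

## Gene–trait matching

The discrimination score formalizes "pseudogenes are an intermediate
state": a pseudogene cell is compatible with both presence and absence, so
it contributes no error in either orientation and is excluded from the
denominator. For orientation "presence predicts class A", the errors are
present-in-B plus absent-in-A strains; the score is
$1 - \min_\text{orientation}(\text{errors})/n_\text{scored}$. This
replaces a Random-Forest importance ranking: the use case is marker
identification with perfect or near-perfect splits, which the error count
captures deterministically and testably, whereas forest hyperparameters
would be unrecoverable.

Significance comes from a permutation null: labels are permuted jointly
across all OGs per replicate (preserving between-OG correlation), and
$p = (1 + \#\{\text{permutation score} \ge \text{observed}\})/(n_{perm}+1)$,
the standard add-one estimator that can never report zero.
Benjamini–Hochberg q-values are computed across OGs. One consequence worth
knowing: a perfect marker attains the minimum attainable p-value
$1/(n_{perm}+1)$ only when no permuted labeling reproduces its split, which
requires the label-permutation space (${n \choose n_A}$) to dwarf
$n_{perm}$. Validation fixtures therefore use 24-strain collections; with
a dozen strains and 999 permutations, collisions are routine and the
reported p is honestly larger.

Two further conventions: the heatmap distance encoding maps
absent/pseudogene/present to 0/0.5/1 (the intermediate state sits between
its neighbors, used *only* for distances, never for scoring), and the
"most discriminating" display set is all perfect-score OGs when any exist,
else the top 50 by rank. Leave-one-out prediction refits each OG's
orientation on the training strains; pseudogene cells abstain from voting,
and vote ties default to the alphabetically first class.

One subtlety of the neutral-cell rule: because pseudogene cells leave the
denominator as well as the error count, converting a *correctly matching*
cell to a pseudogene can lower a non-perfect OG's score slightly; only
converting an *error* cell is guaranteed never to hurt. The tests assert
the guaranteed direction.

## The simulator

`simulate_dataset()` generates the structures the analyses are meant to
find, with these defaults as the standard validation scenario:

| parameter | default | meaning |
|---|---|---|
| `n_strains` | 12 | collection size |
| `n_core_ogs` × `gene_length_bp` | 30 × 300 bp | 9 kb core, ~1.2 kb of variable sites at default divergence |
| `subst_rate` | 0.05 | expected substitutions/site over the unit tree depth |
| `n_clade_markers`, `n_niche_markers` | 3 + 3 | accessory OGs equal to the clade / dairy indicator |
| `pseudo_fraction` | 0.3 | fraction of (subclade strain, core OG) pairs truncated |
| `niche_crossover` | 0.25 | fraction of non-subclade strains labeled dairy anyway |
| `n_plasmid_ogs`, `coverage_multiplier` | 5 at 5× | plasmid contig content and relative depth |
| `depth_noise` | 0 | multiplicative depth noise (sd/mean) |

The phylogeny is a pure-birth (Yule) topology. Branch lengths are drawn as
$0.25 + \mathrm{Exp}(1)$ and rescaled to unit maximum root-to-tip depth:
the floor guarantees that every internal edge leaves a detectable sequence
footprint at the default rate (~9+ expected substitutions over the core),
because an arbitrarily short internal edge is statistically unidentifiable
regardless of inference method and would make topology-recovery validation
meaningless. For the same reason the first split is conditioned (by
resampling) on both clades holding ≥ 2 strains — a one-strain "subspecies"
cannot be scored by the trait matcher. Sequences evolve by Jukes–Cantor:
per branch of length $d$, each site substitutes with probability
$\tfrac34(1 - e^{-4\,d\,\mathrm{rate}/3})$, uniformly to one of the other
three bases; this is the exact JC transition kernel, so leaf-pair
divergence follows the closed form at total separation, which the tests
check at 30 kb against a 3-Monte-Carlo-SE band. Substitutions that would
create an in-frame stop codon are resampled (the resample is still a
substitution, so divergence statistics are unaffected).

Pseudogenes are realized as protein truncations to a uniform 30–70%
prefix while the nucleotide gene is kept full length. This matches how
draft-genome pseudogenes actually surface (an incomplete protein product),
keeps the per-OG nucleotide blocks equal-length — the generator emits
ungapped alignments by construction — and exercises the length-based
pseudogene caller (`call_pseudogenes`: member shorter than 0.8× the median
intact length of an OG with ≥ 3 members, or carrying an internal stop).
Accessory marker and plasmid gene sequences are drawn unrelated (random
stop-free coding sequence, identical across carriers), so the similarity
graph separates them from core OGs without threshold tuning.

What the simulator does *not* emulate — and what passing tests therefore
do not certify about real data: recombination and horizontal transfer
within core genes, rate heterogeneity across sites and lineages, gene
order/synteny, IS-element dynamics, fragmented draft assemblies, and
annotation noise (miscalled starts, split genes). Real collections also
require externally aligned per-OG blocks; the pipeline never aligns.

## Numerical conventions and degenerate inputs

* Reported table means use commercial (half-up) rounding; base R's
  round-half-even would print 2.485 → 2.48.
* The weighted median is the lower weighted median (smallest value whose
  cumulative weight reaches half the total).
* A zero depth baseline leaves all of a strain's contigs `unclassified`.
* All-pseudogene label vectors score 1 with `n_scored = 0` (no scorable
  evidence against the marker).
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; pipeline outputs are written atomically and reruns
  are byte-identical, which the tests assert via checksums.
* Problem sizes in the validation suite (12–24 strains, 30 core genes,
  ≤ 999 permutations, 10–20 seeds per property) were chosen as the
  smallest sizes at which each property is informative; they are the
  package's standard validation scenario, not a statement about the scale
  the code can handle.

## Known limitations

* Orthology is similarity-only: no synteny, no explicit in-paralog
  resolution beyond MCL granularity; deep paralog families may need a
  higher inflation.
* p-distance NJ is a point estimate; no bootstrap support is computed.
* The plasmid caller needs a coverage table from a read mapper and cannot
  see integrated elements at chromosomal copy number.
* The trait score targets clean presence/absence markers; graded or
  epistatic genotype-phenotype relations are out of scope.
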