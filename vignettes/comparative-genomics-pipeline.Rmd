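---
title: "Methods: comparative genomics across the prokaryotic domain divide"
author: "prokphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics across the prokaryotic domain divide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prokphylo)
```

This vignette is the package's own account of the models and procedures it
implements, of the parameters that matter, and of the design choices made
where the underlying survey methods are not fully specified in the
literature the analyses come from.

## 1. The motif census

Proteins that ligate a [4Fe-4S] cluster through a ferredoxin-like cysteine
arrangement carry the pattern C-x$_i$-C-x$_j$-C-x$_k$-C, with the general
form at spacers $(i, j, k) = (2, 2, 3)$. `scan_protein()` reports every
start position at which the four fixed positions hold cysteine, *including
overlapping occurrences* (implemented as a zero-width lookahead, and checked
in the tests against a naive position-by-position oracle). At the genome
level a protein counts **once** per pattern however many occurrences it
contains, matching the "number of proteins containing the motif" reading;
the per-genome proportion is taken over all proteins in the genome file.

Decisions worth stating explicitly:

* **Variant spacer triples.** Surveys of this kind also count "additional"
  motifs with different numbers of bridging residues without enumerating
  them. The defaults here — (2,2,2), (2,3,3), (3,2,3), (2,2,4) — are
  documented placeholders, fully configurable via `motif_pattern()`.
* **Ambiguity codes.** `X` (and the other extended IUPAC letters) match at
  spacer positions and never match a fixed cysteine position. Characters
  outside the IUPAC alphabet are an input error naming the record, not a
  silent skip.
* **Marker flags.** "At least one of them" is read leniently: a single
  retained hit to any subunit of HdrABC or QmoABC flags the taxon. The
  strict alternative (a complete complex within one genome) is available
  via `flag_markers(strict = TRUE)`.

## 2. Pathway presence calling

Hits are filtered with **inclusive** bounds: $E \le 10^{-10}$ ("E values
better than" is taken as $\le$) and identity $\ge 25\%$. Each pathway is an
ordered list of *slots*; slash pairs in the canonical gene lists (ubiD/ubiX,
HemF/HemN, HemY/HemG, UbiE/MenG) form one slot satisfiable by either member,
so they are not double-counted in the denominator. Completeness is the
fraction of slots with at least one retained hit, compared **exactly**
(no rounding) against the 0.70 threshold, with at-threshold completeness
called present; whether 5/8 = 0.625 should round up is a genuine ambiguity,
and the package resolves it by exact fraction comparison.

The haem-d1 rule: the alternative haem pathway shares enzymes with haem d1
biosynthesis, so a passing haem-alternative call in a genome that also has a
retained hit to cd1 nitrite reductase (the only haem d1 enzyme) is recorded
as `present = FALSE, d1_reassigned = TRUE`. cd1 presence uses the same
global thresholds as everything else. Organisms with unusual quinone
chemistry (e.g. benzothiophene derivatives) simply score low on all defined
pathways; no special-case scoring is applied.

## 3. The stringency grid

The identity criterion "roughly 30% identical in all comparisons" is
operationalised as a hard, inclusive **all-pairs** cutoff: a family is
retained iff every pairwise member identity is $\ge 30\%$ (single-member
families pass trivially). Identity comes from a global Needleman–Wunsch
alignment with BLOSUM62 scoring and affine gaps (open 11, extend 1); the
denominator is the number of alignment columns after trimming terminal-gap
columns — the literature gives no definition, so this choice is stated and
configurable (`denominator = "shorter"` divides by the shorter sequence
instead). The all-pairs cost is quadratic, so `max_family_size` errors on
oversized families rather than silently subsampling.

Group presence counts *groups, not genomes*: a family is present in a group
if at least one member genome belongs to it. Cell $(a, b)$ of the grid then
counts families present in $\ge a$ of the archaebacterial and $\ge b$ of the
eubacterial groups. Monotonicity along both axes is structural and asserted
on every run; per-cell family id lists feed the annotation report
(`grid_cell_report()`), where COG-style annotation is passthrough text —
no functional classification is computed.

## 4. Taxon sampling

Balanced sampling works from all-vs-all identities of a single marker
protein (ribosomal protein L3 in the motivating survey), converted to
distances $1 - \mathrm{id}/100$. The published procedure says only
"a hierarchical clustering algorithm", so three choices had to be made and
are documented as such:

* **Domains are clustered separately**, guaranteeing the even split
  (e.g. 50 + 50) by construction.
* **Linkage** defaults to average (UPGMA-style); single and complete are
  available.
* **Representatives** are cluster medoids — the member minimising the summed
  within-cluster distance — with ties broken by lexicographically smallest
  genome id, making the selection deterministic and independent of input
  order (a property the tests verify by permutation, and by exhaustive
  enumeration of medoids on small instances).

## 5. Trees and node frequencies

The comparison statistic — for each internal node (bipartition) of the
concatenated tree, the fraction of single-gene trees containing the
identical bipartition — is method-agnostic; externally built Newick trees
are accepted. For a self-contained pipeline the package builds trees
deterministically by **neighbor joining on Poisson-corrected distances**:
$p$ is the proportion of differing sites among pairwise-ungapped sites
(pairwise deletion), $d = -\ln(1 - p)$, capped at `d_max = 10` as
$p \to 1$. The NJ implementation breaks Q-criterion ties by the smallest
index pair, clamps negative branch-length estimates to zero, and on additive
input recovers the generating topology and all path distances exactly
(verified to $10^{-9}$ in the tests).

Bipartitions are canonicalised as the sorted leaf set on the side *not*
containing the lexicographically smallest leaf, so the two orientations of a
split compare equal; matching is exact identity on identical leaf sets
(partial-leaf-set compatibility matching is out of scope — the universal
genes cover every taxon by construction). Rooted input is unrooted on read.
Support is exported as Newick node labels at 4 decimal places; a viewer can
map frequency to branch opacity linearly.

## 6. The synthetic-data generator

The generator exists so that every downstream stage can be tested against
known ground truth. What it emulates, and what it deliberately does not:

* **Taxonomy and species tree.** Two domains split into taxonomic groups
  (defaults 11 archaebacterial, 30 eubacterial — the group structure of the
  motivating gene-family survey), random binary group and backbone
  topologies, and a single inter-domain edge of configurable length
  (default 1.0 expected substitutions/site). Within-group and backbone edges
  default to 0.1 and 0.2 — realistic protein-divergence scales chosen once,
  large enough that tree reconstruction at the simulated alignment lengths
  is reliable, and small enough that distances stay far from saturation.
* **Gene trees.** Each of the `n_universal_genes` (default 48) receives,
  with probability $p$, exactly **one nearest-neighbour interchange** at a
  uniformly chosen internal edge, excluding the inter-domain edge by
  default. An NNI changes only the chosen edge's bipartition, so the
  expected gene-tree frequency of each eligible node is analytic,
  $1 - p/E$ with $E$ the number of eligible edges — the quantitative hook
  the acceptance checks use. Coalescent discordance, transfers and losses
  are *not* modelled.
* **Sequences.** Site-independent evolution: root residues drawn with a
  configurable cysteine frequency (default 0.014, near proteome-wide
  averages), per-branch substitution probability $1 - e^{-t}$, replacements
  uniform over the other 19 residues. No exchangeability matrix, no rate
  heterogeneity, no indels — alignments are ungapped by construction, so
  passing tests say nothing about alignment-error robustness.
* **Proteomes.** Background proteins of fixed length; with probability
  `motif_rate` a motif instance overwrites a random window (length
  preserved), its spacers drawn from the 19 non-cysteine letters so a
  planting cannot create a nested second match by itself. With background
  cysteine frequency 0 the planted set equals the detected set exactly.
* **Families.** Presence per group is Bernoulli with configurable
  probabilities; members descend from a family ancestor (length 120) at one
  of two divergence levels — conserved (site mutation rate 0.08, pairwise
  identity ≈ 85%, intended to survive the 30% filter) or diverged (rate
  0.75, identity ≈ 10%, intended to fail it). The margins are wide enough
  that the intended and realised filter outcomes coincide. This family
  model is a stand-in, not a reconstruction of any real clustering
  procedure.
* **Hit tables.** For each genome × pathway, passing hits are emitted for
  exactly the configured completeness fraction (which must be a multiple of
  $1/\mathrm{slots}$), plus decoys that each fail exactly one filter; the
  full pipeline round-trips the configured truth exactly.

All randomness flows from one configured seed; stages draw in a fixed,
documented order (taxonomy, gene trees, proteomes, families, hits), each
from its own derived seed, so `run_simulation()` is byte-identical across
runs with equal seeds — asserted at file level (md5) in the tests.

## 7. Problem sizes and numerical choices

The test and acceptance runs use desk-scale sizes chosen to exercise every
code path with comfortable statistical margins: 10,000 random sequences for
the scanner/oracle comparison; 100 random additive matrices ($n \le 12$)
for tree recovery; 1000 synthetic families for the grid recount; and, for
discordance-parameter recovery, 20 genomes per domain, 48 genes × 2000
sites at $p = 0.25$ — at these branch lengths and alignment sizes gene
trees are recovered essentially exactly, so the observed mean node support
sits within three binomial standard errors of $1 - p/E$. Numerical
tie-breaks (NJ index pairs, medoid ids), clamping (negative branch lengths,
the $d_{\max}$ distance cap) and degenerate-input behaviour (empty
proteomes, zero comparable sites, oversized families) are all specified
above and are errors, never silent fallbacks.

## 8. Known limitations

* The substitution model is deliberately minimal; trees from real,
  rate-heterogeneous, indel-rich protein data will be noisier than the
  generator suggests.
* One NNI per discordant gene is the smallest useful discordance model; it
  does not emulate the correlated, deep discordance of real prokaryote
  genomes, where lateral transfer can dominate.
* The identity filter's alignment parameters (BLOSUM62, 11/1) are fixed
  conventions, not fitted; percent identity is denominator-sensitive and
  both offered denominators are approximations of unstated practice.
* Pathway calling sees only gene names in hit tables; it cannot distinguish
  orthologs from paralogs, and decoy realism is limited to threshold
  behaviour.
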