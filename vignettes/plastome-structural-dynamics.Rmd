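---
title: "Models and methods for plastome structural dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for plastome structural dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidyn)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical conventions chosen where several were
defensible, and what the synthetic-data generator does and does not emulate.

## The biological setting

Most land-plant plastomes are quadripartite: a large single-copy region
(LSC) and a small single-copy region (SSC) separated by two copies of a
large repeat, usually inverted (IR~A~/IR~B~).  In spikemosses
(Selaginellaceae) the two copies are co-oriented in many species — a direct
repeat (DR) arrangement — and a handful of species additionally carry a
second, smaller repeat pair (the *psbK–trnQ* region analog, roughly 1.8–2.7
kb) with one copy in each single-copy region.  Large repeats mediate
frequent reciprocal homologous recombination, so the orientation pattern of
the repeat pairs determines which alternative genome configurations a
plastome population can reach.  The package quantifies three linked aspects
of this system: how far gene orders have diverged (rearrangement
distances), which repeats exist (repeat detection), and which molecule
forms recombination can generate (the state-graph model), plus the
comparative statistics used around them (pairwise dN/dS contrasts, Mk
ancestral-state reconstruction, PIC correlations).

## Signed permutations and rearrangement distances

Gene orders are compared after encoding both genomes over their shared
genes: genes present once in each genome are taken in the first genome's
coordinate order and greedily merged into maximal blocks that are
contiguous and co-oriented in both genomes (`encode_lcb_permutations()`).
This is a gene-order-resolution stand-in for nucleotide-level collinear
block detection; it deliberately ignores genes missing from either genome,
since blocks are only meaningful on shared content.

Two distances are computed on the resulting signed permutations, both under
the **linear capped convention** (caps 0 and *n*+1).  The breakpoint
distance counts adjacencies of one permutation absent from the other,
orientation respected — with the caps and signs, the adjacency (x, y) is
conserved exactly when y = x + 1 after composing one permutation with the
other's inverse.  The inversion distance is the exact minimum number of
signed reversals, computed from the breakpoint graph as
*d* = (*n* + 1) − *c* + *h* + *f*: cycles *c*, hurdles *h* (unoriented
components whose positions are consecutive on the circular reading of
unoriented-component positions), and the fortress correction *f* (an odd
number of hurdles, all of them superhurdles).  Both distances are computed
on the composition q⁻¹∘p against the identity, so one code path serves all
pairs.

Because hurdle/fortress bookkeeping is notoriously easy to get subtly
wrong, the package ships an independent exact oracle:
`inversion_distance_bfs()` performs breadth-first search over the full
signed-permutation state space (cached per size, feasible through n = 7).
During development the formula was checked against the oracle exhaustively
for **all** 645,120 signed permutations of size ≤ 7 with zero mismatches;
the shipped test suite re-verifies n ≤ 5 exhaustively plus 500 random n = 7
instances.  No fortress exists at n ≤ 7, so the fortress branch cannot be
exercised against the oracle; the exhaustive agreement does show it never
fires spuriously at these sizes.  `sorting_scenario()` produces an explicit
minimum-length reversal script by repeatedly applying the lowest-index
reversal that decreases the formula distance by one; its success on every
random instance is itself a check that the formula never underestimates.

A note on one convention-dependent reproduction: the bundled published
distance table (`lycophyte_distance_table()`, 105 lower-triangle BP/IV
cells over 15 lycophyte plastomes) yields a Pearson correlation of 0.930
between the two distances, as recomputed by `scripts/acceptance.R`.  The
correlation reported alongside that table in the literature (0.977) is only
recovered from Selaginella-restricted readings of the table (for example,
the 13 Selaginella species' pairs plus the zero diagonal give 0.9772), and
the table's *Isoetes* column increments its inversion distances perfectly
by one across largely syntenic species, which suggests a printing artifact.
The package reports the faithful computation and documents the discrepancy
rather than tuning to the published value.

## Repeat detection

`find_repeats()` reports **all maximal exact repeated pairs** longer than a
threshold (default 15 bp, strict), in both orientations, with circular wrap
handled by doubling the sequence and deduplicating by position modulo the
genome length.  Detection is seed-and-extend on shared (min_len + 1)-mers
grouped by diagonal (anti-diagonal for inverted matches): a maximal repeat
of length L contributes exactly L − k + 1 consecutive seeds on one
diagonal, so merged runs *are* the maximal matches, and maximality needs no
separate extension step.  Matching is exact (identity 1.0): the reference
tools in this area allow mismatches with unstated parameters, so exact
matching was chosen for determinism; consequently repeat counts on real
genomes are not comparable to published counts at fixed thresholds.
Overlapping-copy matches are collapsed into tandem arrays reported as one
unit length plus copy count; palindromic self-hits at a single locus are
excluded; and `repeat_summary()` excludes pairs of at least 1 kb by default,
mirroring the practice of removing one DR/IR copy before counting dispersed
repeats.

## The recombination state-graph model

The model works at **segment resolution**: a molecule form is a circular
sequence of oriented segment tokens delimited by repeat-copy boundaries,
with both copies of a pair carrying the same token.  Nucleotide detail adds
nothing here — the events only rearrange segments.  Two forms are the same
molecule exactly when their token circles agree up to rotation and
reflection (reading the other strand), which the canonical key captures
(lexicographically minimal rendering over all rotations of the form and its
reflection).

Two events are modeled.  A **flip** at an inverted pair reverses, with
orientations negated, the arc strictly between the two copies; the two
possible arcs give reflection-equivalent circles, so the canonical child is
unique.  A **split** at a direct pair excises two circular subgenomic
molecules, each retaining one full repeat copy and one arc; the segment
multiset is conserved.  `enumerate_forms()` closes the master chromosome
under these events breadth-first, deduplicating by canonical key.
Subgenomic molecules are terminal: intermolecular recombination, concatemer
formation and linear/branched replication intermediates are outside the
model.  Stoichiometry over full-length isomers is reported as uniform — the
equilibrium assumption for highly efficient reciprocal recombination — and
no kinetic rates are modeled.

For an IR master carrying a small inverted pair (one copy per single-copy
region), the closure is the documented three-isomer chain: flipping at the
large IR turns the small pair direct (isomer I), flipping at the small pair
turns the large pair direct (isomer II), and each direct-pair-bearing
isomer splits into two subgenomic molecules.  A geometric fact worth
recording: the two subgenomes excised from isomer I are the *same circular
molecules*, after rotation and reflection, as the two excised from isomer
II, so the deduplicated graph holds 3 full-length forms, 4 split children
across events, and 2 distinct subgenomic molecules.  The DR-only master
gives 1 full-length form and 2 subgenomes; an IR-only master gives 2
isomers and none.

On the orientation of the small *psbK–trnQ*-like pair in the IR-carrying
master: descriptions of this pair disagree between sources (direct vs
inverted).  The package's reference fixtures use **inverted in the master
form**, because only that geometry produces the two-isomer chain just
described; with a direct small pair the master itself would split and no
isomer II would exist.

## Pairwise dN/dS

`ml_pairwise_rates()` maximizes the pairwise codon likelihood under a
GY94-type 61×61 rate matrix (translation table 11, the plastid bacterial
code; its sense-codon set and stops coincide with the standard code) with
F3×4 codon frequencies computed per pair from the union of the two
sequences.  The matrix is scaled to one expected substitution per codon per
unit time, so *t* is in substitutions/codon.  Optimization is bounded
L-BFGS-B over log(t) ∈ [log 1e−6, log 50], log(κ) ∈ [log 0.01, log 100],
log(ω) ∈ [log 1e−4, log 20], started from a proportion-difference guess
with optional random restarts; codons containing a gap or ambiguity in
either sequence are deleted pairwise.  dS and dN partition *t* by flux:
with ρ~S~ the fitted synonymous flux proportion and p~S~ the synonymous
flux proportion at ω = 1 (the synonymous site fraction),
dS = t·ρ~S~/(3 p~S~) and dN = t·ρ~N~/(3 (1 − p~S~)), which makes
dN/dS = ω exactly.  Estimates with dS > 5 are flagged saturated.

`ng86_rates()` is the independent counting route: per-codon synonymous
site fractions, equal-path weighting over substitution orders for multi-hit
codons (paths through stop codons excluded), and Jukes–Cantor correction.
The two routes agree in the weak-divergence limit **when the generating
process has no transition bias** (κ = 1), which is how the agreement test
is parameterized; with κ > 1 the unweighted NG86 site counts are known to
overestimate dS by roughly the 15–20% seen in simulation, so that setting
is not used for the agreement check.  Group contrasts
(`compare_rate_groups()`) pool per-gene within-class pairwise estimates and
use Wilcoxon rank-sum tests — exact by enumeration for pooled samples of at
most 20 without ties, otherwise the tie- and continuity-corrected normal
approximation.  Only within-class species pairs enter a class's pool;
cross-class pairs are simply not labeled.

## Mk ancestral states and independent contrasts

The DR/IR character is modeled by the 2-state symmetric Mk model: a single
rate, change probability (1 − e^(−2·rate·b))/2 on a branch of length b, and
the flat root prior (½, ½) that the symmetric model forces.  The rate is
ML-optimized per tree (one rate per tree in multi-tree summaries, matching
per-tree reconstruction practice); likelihoods use Felsenstein pruning,
verified against brute-force enumeration over all interior-state
assignments on small trees, and marginal ancestral probabilities combine
downward partials with the likelihood of the rest of the tree.  When all
tips share one state the rate is returned as the 0 boundary with a note.
`summarize_asr_over_trees()` matches clades across trees by tip
bipartition and reports, per clade, the fraction of trees containing it,
mean marginals, and the fraction of trees in which a "change" is
reconstructed on its stem branch — operationalized as differing
most-probable marginal states at the branch's two ends, since the summary
this mirrors is not formally defined elsewhere.

Independent contrasts follow Felsenstein's recursion (contrast
(x₁ − x₂)/√(v₁ + v₂), weighted ancestral values, parent branch lengthened
by v₁v₂/(v₁ + v₂)).  Polytomies are rejected rather than zero-resolved, to
avoid silently inflating the contrast count.  The PIC correlation is
computed through the origin with n − 1 degrees of freedom, the standard
treatment for contrasts.

## The synthetic-data generator

`simulate_architecture()` emulates exactly the features the pipeline is
sensitive to: total sizes around 110–147 kb, a large repeat pair of 7–17 kb
in either orientation separating LSC from SSC, an optional small pair with
one copy per single-copy region, and GC content near 0.51–0.56 (achieved
within ±0.01 at ≥ 100 kb by i.i.d. sampling with P(G) = P(C) = GC/2).  The
flanking bases of planted repeat copies are adjusted so that chance
extension cannot occur, making planted pairs recoverable at exactly their
planted coordinates.  Every generator takes an explicit seed and is
bit-reproducible given it.  The reference architectures
(`fixture_figure5()`) use fixed seeds and sizes modeled on the three
canonical layouts (DR-only ~121 kb; IR + 2.7-kb inverted pair ~144 kb;
DR + 1.8-kb inverted pair ~140 kb).

What the generator does **not** emulate: real gene sequences or codon-usage
bias beyond F3×4, indels, degenerate (non-identical) repeat families,
tandem-array evolution, and nucleotide-level rearrangement breakpoints.
Tests passing on synthetic data therefore demonstrate correctness of the
algorithms under the stated models, not robustness to annotation error or
approximate repeats in real genomes.

## Numerical choices and problem sizes

Coordinates are 0-based half-open internally, 1-based inclusive in GFF3 on
disk; origin-wrapping features are stored as two sub-intervals sharing an
id.  Gene names are normalized (lower-case, copy suffixes stripped) before
presence/absence and block encoding.  N bases are excluded from the GC
denominator.  Pseudogenes are excluded from distinct-gene counts.  Ties in
`sorting_scenario()` break to the lowest index; canonical keys break ties
lexicographically.  The test suite sizes its simulations to run in a few
minutes on one CPU: the BFS oracle table at n = 7 (645,120 states, built
once and cached), 50 replicates × 500 codons for ω recovery, 2,000 null
rank-sum simulations, 200 trees × 20 tips for contrast calibration, and
random-sequence false-positive screens at 20 kb × 20 seeds; the vignette
states these as the package's chosen study sizes.

## Known limitations

* The inversion-distance fortress branch is theory-faithful but cannot be
  validated against the exhaustive oracle (no fortress exists at n ≤ 7).
* Repeat detection is exact-match only; approximate repeat families are out
  of scope.
* The recombination model is combinatorial: no rates, no intermolecular
  events, no linear or branched intermediates.
* Pairwise dN/dS assumes in-frame, stop-free alignments (gaps as whole
  codons) and does not implement branch or site models.
* The Mk machinery is strictly two-state and symmetric; asymmetric-rate or
  multi-state characters are not supported.
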