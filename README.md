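# plastidyn

Tools for studying the structural evolution of plastid genomes (plastomes)
whose two single-copy regions are separated by a pair of large repeats — the
canonical **inverted repeat (IR)** of most land plants, or the unusual
**direct repeat (DR)** arrangement found in spikemosses (Selaginellaceae).
The package is aimed at comparative organelle genomicists who want to
quantify gene-order rearrangement, detect the repeats that mediate it, and
model the recombination behavior those repeats allow.

## What it computes

* **Rearrangement distances.** Gene orders shared between two annotated
  genomes are merged into signed collinear blocks
  (`encode_lcb_permutations()`); the package computes the breakpoint
  distance (number of broken signed adjacencies, with linear caps) and the
  exact minimum inversion distance via the Hannenhalli–Pevzner
  breakpoint-graph formula
  *d = (n + 1) − c + h + f* (cycles *c*, hurdles *h*, fortress *f*),
  validated against an exhaustive breadth-first-search oracle
  (`inversion_distance()`, `inversion_distance_bfs()`,
  `sorting_scenario()`, `pairwise_distance_matrix()`).
* **Repeat detection.** All maximal exact repeat pairs above a length
  threshold, direct and inverted, with circular wrap and tandem-array
  collapsing (`find_repeats()`, `repeat_summary()`, `large_repeat_pair()`).
* **Recombination model.** At segment resolution, homologous recombination
  between an *inverted* pair flips the arc between the copies (an isomer);
  recombination between a *direct* pair splits the circle into two
  subgenomic molecules.  `enumerate_forms()` closes the master chromosome
  under these events and classifies the genome as `DR_only`, `IR_only` or
  `IRDR_coexisting` (`classify_dynamic()`), with equal stoichiometry assumed
  over full-length isomers (`stoichiometry()`).
* **Substitution rates.** Pairwise maximum-likelihood *dN*/*dS* under a
  GY94-type codon model with F3×4 frequencies (`ml_pairwise_rates()`),
  Nei–Gojobori counting as an independent check (`ng86_rates()`), and
  Wilcoxon rank-sum contrasts between structural classes
  (`compare_rate_groups()`).
* **Character and trait analysis.** Two-state Mk ancestral-state
  reconstruction of the DR/IR character with per-tree summaries over tree
  samples (`mk_fit()`, `summarize_asr_over_trees()`), and correlation of
  repeat counts with rearrangement distances by Pearson tests and
  phylogenetically independent contrasts (`pearson()`, `pic_contrasts()`,
  `pic_correlation()`).
* **Synthetic data.** Every input the pipeline consumes can be generated
  in-package: plastome architectures with planted repeat pairs
  (`simulate_architecture()`, `fixture_figure5()`), inversion histories,
  codon alignments with known (t, κ, ω), Yule trees, Mk characters and
  Brownian tip values.

## Worked example

```r
library(plastidyn)

fx <- fixture_figure5()           # three reference architectures
g  <- enumerate_forms(fx$IRDR_uncinata)
g
#> recombination state graph: 3 full-length form(s), 2 distinct subgenomic
#> molecule(s), 6 event(s)
form_counts(g)$full_length        #> 3   (master + isomer I + isomer II)
classify_dynamic(g)               #> "IRDR_coexisting"
stoichiometry(g)                  # 1/3 per full-length isomer

rp <- find_repeats(fx$IRDR_uncinata, min_len = 15)
rp[rp$length > 1000, c("length", "orientation")]
#>   length orientation
#> 1  12800    inverted     (the IR itself)
#> 2   2700    inverted     (the psbK–trnQ-like pair)

inversion_distance(c(1, -2, 3), c(1, 2, 3))   #> 1
inversion_distance(c(2, 1),     c(1, 2))      #> 3 (the minimal hurdle)
```

The state graph above is the flip-flop chain of an IR-carrying master with a
small inverted pair, one copy in each single-copy region: flipping at the
large IR makes the small pair direct (isomer I), flipping at the small pair
makes the large pair direct (isomer II), and each direct-pair-bearing isomer
splits into two subgenomic circles.

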