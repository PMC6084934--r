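---
title: "Measuring the optimality of the standard genetic code with an evolutionary algorithm"
author: "codonEvolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the optimality of the standard genetic code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonEvolve)
```

## The question

The standard genetic code (SGC) maps 61 sense codons to 20 amino acids and
reserves TAA, TAG and TGA as stops.  A long-standing question in molecular
evolution is whether this particular mapping is *adaptive*: does it arrange
amino acids so that single-nucleotide mutations and mistranslations tend to
exchange chemically similar amino acids?  `codonEvolve` quantifies this by
searching the space of alternative codes for the ones that are best and
worst at damping the chemical consequences of point mutations, and then
placing the SGC between those two extremes.  Because the three codon
positions play very different roles (the second position is the least
redundant, the third the most), the cost is resolved by position.

## The cost function

For a code $c$ and the set $D$ of unordered pairs of sense codons
$\langle i, j\rangle$ differing at exactly one position,

$$F(c) = \sum_{\langle i,j\rangle \in D} \left[p(i) - p(j)\right]^2,$$

where $p(i)$ is the polarity of the amino acid that $c$ assigns to codon
$i$.  Restricting $D$ to pairs differing at position $k$ gives the
per-position costs $F_1, F_2, F_3$; the total is $F_T = F_1 + F_2 + F_3$.
The bundled polarity scale is the Woese *polar requirement*, transcribed
from the AAindex entry WOEC730101.  Published transcriptions of that index
differ slightly for Cys, Trp and Tyr; the scale is therefore a plain
20-value table that can be replaced via `polarityScale()` or
`readPolarityScale()` to probe that sensitivity.

Two conventions are fixed here and matter for reproducibility:

* **Stop codons are excluded from $D$.**  Polarity is undefined for the
  stop signal, so any pair containing TAA, TAG or TGA is dropped.  This
  leaves $|D| = 263$ pairs, split 87/88/88 across the three positions
  (without the exclusion there would be $64 \cdot 9 / 2 = 288$).
* **Each unordered pair is counted once**, and `polarityCost(code,
  position = "all")` is *defined* as the sum of the three per-position
  costs, so the identity $F_T = F_1 + F_2 + F_3$ holds bit-exactly rather
  than only up to floating-point reassociation.

Because the measures built on $F$ (below) are ratios or differences, a
double-counting convention would cancel out of them; the single-count
convention fixes the raw $F$ values that the package reports.

## Four models of code variation

All models keep the three standard stop codons fixed and require every
amino acid to be encoded at least once.  They differ in how much of the
SGC's structure they preserve, which determines the size of the search
space (`spaceSize()` computes these exactly with big-integer arithmetic):

| model | preserves                                   | operators act on | space size |
|-------|---------------------------------------------|------------------|-----------:|
| DEG   | synonymous blocks *and* degeneracy classes  | whole blocks     | 5.225e8    |
| BLO   | synonymous blocks                           | whole blocks     | 2.433e18   |
| NUM   | per-amino-acid codon counts                 | single codons    | 5.559e64   |
| GEN   | nothing beyond surjectivity                 | single codons    | 8.788e78   |

A "codon block" here is the full synonymous codon set of one amino acid,
giving 20 blocks.  This reading is pinned down by the space sizes: the BLO
count is exactly $20!$ and the DEG count is exactly
$3!\,5!\,1!\,9!\,2! = 522{,}547{,}200$, the product of factorials of the
degeneracy-class sizes (three 6-fold, five 4-fold, one 3-fold, nine
2-fold and two 1-fold amino acids).  Conventional code tables are
sometimes described with more blocks by splitting the serine, leucine and
arginine codons into contiguous groups; that convention is *not* used by
any operator in this package.  `totalSpaceSize()` additionally counts all
codes with variable stop placement (surjections of 64 codons onto 21
labels, about 1.51e84), which is the usual headline figure for the size
of code space.

Model-specific operators (all closed over their constraint sets):

* **Generation** — DEG: permute amino acids uniformly within each
  degeneracy class; BLO: permute all 20; NUM: deal the 61 codons uniformly
  into classes of the standard sizes; GEN: assign each codon a uniform
  amino acid and reject non-surjective draws (rejection is cheap: about
  38% of draws over 61 codons already hit all 20 amino acids).  The GEN
  generator intentionally produces *nearly uniform* codon counts (mean
  3.05 codons per amino acid); that is a property of this randomization,
  not of code space itself, and it is why random-code baselines are a
  poor stand-in for true extremes.
* **Mutation** — DEG/BLO: swap the blocks of two distinct amino acids
  (same degeneracy class under DEG), drawn uniformly over admissible
  pairs; NUM/GEN: pick two distinct amino acids, one codon of each
  uniformly, and exchange the two assignments.  Exactly one exchange is
  applied per selected individual; the per-individual mutation
  probability gates whether an individual is touched at all.
* **Crossover** — DEG/BLO: a position-based crossover on block
  permutations.  Each amino acid is independently retained with
  probability 0.5 on its own-parent block; the remaining blocks are
  filled with the unused amino acids of the other parent *in that
  parent's block order* (the description "according to the amino acid
  order in the parental code" is read as donor block order; an
  alphabetical fill would be an equally consistent reading and is easy to
  substitute, but the choice is immaterial to the optima, only to the
  path taken).  Under DEG the fill is class-matched.  NUM/GEN: a
  codon-reassignment crossover.  A random amino acid $a_1$ is chosen;
  codons of $a_1$ private to one parent are exchanged pairwise between
  the two offspring; surplus private codons are then moved to $a_1$ from
  a donor amino acid in one offspring and away from $a_1$ in the other.
  An amino acid is never stripped of its last codon, so offspring stay
  surjective.  Under NUM every move is replaced by a two-codon swap,
  which preserves the standard count profile exactly.  Donor and
  recipient amino acids are drawn uniformly among the eligible ones;
  the underlying description leaves this choice open.

## The evolutionary algorithm

`runEA()` is a single-objective, archive-based elitist EA.  Per
generation: parents and archive are pooled and evaluated on the chosen
criterion ($F_1$, $F_2$, $F_3$ or $F_T$, minimized or maximized); the
best 700 form the new archive (plain value truncation with duplicates
allowed — only one objective is optimized at a time, so no Pareto
machinery is needed; the first generation selects from the initial random
parents alone); a mating pool of parent-population size is drawn from the
archive by binary tournament (ties broken by a fair coin); crossover is
applied to consecutive pool pairs with probability $p_{cx}$ and mutation
to each individual with probability $p_{mut}$; the varied pool becomes
the next parent population.  Elitism makes the per-generation best value
monotone, which the tests assert on every trajectory.

Defaults follow the study conditions: 1000 generations, 20 repeats,
archive 700; population 1000 with $p_{mut} = 0.9$, $p_{cx} = 0.3$ for the
block models (DEG/BLO) and population 2800 with $p_{mut} = 0.8$,
$p_{cx} = 0.4$ for the codon models (NUM/GEN).  All randomness flows from
one master seed: run $r$ of a configuration uses `seed + r - 1`, and
`runExperiment()` gives its maximization batch the block `seed + runs`
onwards.  The same seed reproduces a run bit-for-bit.  There is no early
stopping; instead each run reports a plateau statistic (final generations
without improvement) so convergence can be inspected.

Two implementation notes.  Population evaluation, the codon-model
operators and the block crossover are small C++ kernels (via Rcpp) using
R's RNG, so a DEG run at full budget takes about two seconds and a GEN
run about ten on one CPU; everything else is vectorized R.  When fewer
distinct solutions than the archive size exist the truncation simply
keeps duplicates; the archive-update rule under deduplication is not
specified by the source procedure, and truncation-with-duplicates is the
simplest faithful reading.

## Measures

* **Global distance** (`globalDistance()`):
  $GD = 100\,(F^{ref} - F^{best}) / (F^{worst} - F^{best})$, with
  $F^{best}$/$F^{worst}$ the best-of-runs extremes from minimizing and
  maximizing runs.  GD is deliberately *unclamped*: when a code set
  optimized for one position is evaluated at another position
  (`crossPositionGD()`, which keeps the denominator of the evaluated
  position's own optimization), the numerator can be negative.
* **Euclidean distances** (`euclideanToSet()`): the shortest distance in
  $(F_1, F_2, F_3)$-space from a reference code to the pooled set of
  extreme codes.  The pooled set (`extremeSet()`) contains every distinct
  archive member that ties its run's best value, because single-position
  optima typically form a layer of equally good but structurally
  different codes.
* **Structure distance** (`structureDistance()`): codes are encoded as
  1220 binary indicators (61 codons x 20 amino acids, codon-major with
  amino acids alphabetical within a codon — the order is frozen); SD is
  the Hamming distance between two such vectors, normalized by its
  maximum 122 (every codon reassigned flips two bits) and expressed in
  percent.  SD is a scaled Hamming distance and hence a metric.  The
  same binary encoding, stacked over a set of codes (`caMatrix()`), is
  the input for correspondence analysis; the ordination itself is
  delegated to standard multivariate tools and is out of scope here.
* **Random baselines** (`randomBaseline()`): mean cost, mean GD (with
  the reference replaced by each random code) and mean nearest-ED of $n$
  random codes, each with two-standard-deviation dispersions.  Under
  DEG/BLO random codes sit near the middle of the best-worst range
  (GD around 50%), while under GEN they lean markedly toward the
  minimizing extreme (GD around 30%) — a consequence of the near-uniform
  codon counts of surjective uniform assignment.
* **`pdm()`** is the older reference measure (distance from the random
  mean toward the best code), retained as a one-line variant.
* **`rankCorrelation()`** wraps Spearman's correlation (average ranks on
  ties) for relating SD to ED over a set of optimized codes.

## What the tests and the acceptance script establish

The cost function is checked against a brute-force oracle that loops over
all ordered codon pairs with string comparison; the pair set against
exhaustive enumeration; the space sizes against independent
Stirling-recurrence and complete-enumeration oracles (complete enumeration
is run for up to 8 items onto 4 labels, the recurrence cross-check up to
12 onto 6 and for the production sizes); operator closure along 1e5
chained mutation/crossover applications per model; and the EA against the
globally enumerated optimum of a restricted DEG subspace (the nine
two-codon amino acids, $9! = 362{,}880$ codes), which it recovers in at
least 9 of 10 seeded runs.

The headline reproductions, computed from scratch by
`scripts/acceptance.R` and asserted in the test suite with 10 EA runs per
direction at the full budget (population 1000/2800, 1000 generations):
GD of the summed cost under DEG near 7.3%, GD of the second position
under DEG near 80.1%, GD of the third position under BLO near 1.5%, GD of
the summed cost under GEN near 9%, and the exact DEG/third-position
optimality of the SGC (its $F_3$ equals the best achievable, GD 0%).
The single-swap structure example — moving Met to TGG and Trp to ATG
flips four indicators, SD $= 100 \cdot 4/122 = 3.3\%$ — is exact.
Percentages are printed to one decimal, rounding half to even, and the
big-integer scientific forms use the same rounding rule.

The stochastic tolerances (1.5–3 percentage points) reflect two real
sources of spread: EA stochasticity in the extremes, and the polarity
transcription.  With the bundled WOEC730101 values the DEG/BLO extremes
are reproduced essentially deterministically (the spaces are small enough
that independent restarts of a simple local search find the same best and
worst codes); the GEN extremes genuinely vary a few percent between run
batches.

## What the randomization does and does not emulate

Synthetic codes generated by the four models are the *study conditions*
themselves, not a stand-in for biological data: the object of analysis is
the combinatorial space of possible codes, and the SGC enters only as a
fixed reference point.  Passing tests therefore say nothing about, e.g.,
codon usage, transition/transversion bias, wobble pairing or weighted
mistranslation spectra — the cost is an unweighted sum over
single-nucleotide neighbor pairs by design, and non-standard stop sets or
a 21st amino acid are out of scope.

## Known limitations

* Only one objective is optimized at a time; joint Pareto optimization of
  $(F_1, F_2, F_3)$ is a non-goal.
* GD depends on the *found* extremes; under GEN the space is vast and the
  reported extremes are lower bounds on the true range, which is exactly
  why GD (a ratio) rather than a raw difference is the headline measure.
* The polarity scale is a transcription of a 1970s chromatographic index;
  alternative property matrices (hydropathy, substitution-matrix costs)
  are supported only through the pluggable scale interface.
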