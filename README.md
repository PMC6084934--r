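# codonEvolve

Tools for asking how good the standard genetic code (SGC) is at damping
the chemical effects of point mutations — and for answering with the best
and worst codes that are structurally possible, rather than with random
shuffles.

## The problem and the approach

The SGC assigns 61 sense codons to 20 amino acids (stops TAA/TAG/TGA
fixed).  Its robustness is scored by the polar-requirement cost

    F = sum over <i,j> in D of [ p(i) - p(j) ]^2

where `D` is the set of unordered sense-codon pairs differing at exactly
one position (263 pairs; stop-containing pairs are excluded) and `p(.)`
is the Woese polar requirement of the encoded amino acid.  The cost is
resolved by codon position (`F1`, `F2`, `F3`; `FT = F1+F2+F3`), because
the three positions play very different roles in translation.

An archive-based elitist evolutionary algorithm searches for codes that
*minimize* and codes that *maximize* each criterion under four structural
models — DEG (preserves synonymous blocks and degeneracy classes, 5.225e8
codes), BLO (preserves blocks, 20! = 2.433e18), NUM (preserves
per-amino-acid codon counts, 5.559e64) and GEN (surjectivity only,
8.788e78) — and the SGC is placed between the found extremes with the
**global distance**

    GD = 100 * (F_SGC - F_best) / (F_worst - F_best)   [%]

plus Euclidean distances in `(F1,F2,F3)`-space to the extreme-code sets
and a **structure distance** SD (Hamming distance between 1220-bit
codon-to-amino-acid indicator vectors, normalized by its maximum 122).
Exact code-space counts use built-in big-integer arithmetic.

## Worked example

```r
library(codonEvolve)

objectiveVector(standardCode())
#>      F1      F2      F3      FT
#>  379.52  920.14   12.04 1311.70

formatSci(spaceSize("DEG"))      # "5.225e8"  exact: 522547200
formatSci(totalSpaceSize(), 3)   # "1.51e84"  all codes incl. stop placement

# How optimal is the SGC at the third codon position, among all codes
# that keep its block and degeneracy structure (DEG)?
res <- runExperiment("DEG", "pos3", generations = 300, runs = 5,
                     popSize = 500, archiveSize = 250, seed = 7)
sprintf("fRef=%.2f fBest=%.2f fWorst=%.2f GD=%.2f%%",
        res$fRef, res$fBest, res$fWorst, res$gd)
#> "fRef=12.04 fBest=12.04 fWorst=678.54 GD=0.00%"
```

The minimizing runs cannot beat the SGC's third-position cost of 12.04:
the standard code is *exactly optimal* there within its own structural
class (GD = 0%), while the worst DEG code is 56 times costlier.  The
best-code layer contains many structurally different ties
(`length(res$sdBest)` is 1012 in this run); over full-budget runs the
closest of them to the SGC differs only in swapping the single codons of
Met and Trp:

```r
sw <- swapAminoAcids(standardCode(), "M", "W")  # Met at TGG, Trp at ATG
structureDistance(standardCode(), sw)
#> $sd       3.278689   (prints as 3.3%)
#> $hamming  4
polarityCost(sw, position = 3) == polarityCost(standardCode(), position = 3)
#> TRUE
```

By contrast the second position is poorly optimized: at full budget
(population 1000, 1000 generations, 10+ runs per direction) the DEG GD
for `pos2` is about 80%, i.e. closer to the worst code than to the best,
while the summed cost sits at GD of about 7% (DEG) and 9% (GEN).

A thin CLI covers the same operations
(`inst/exec/codonevolve space-size --model DEG`, `optimize`, `compare`,
`evaluate`, `measure`, `random-baseline`, `export-ca`, `make-fixtures`).

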