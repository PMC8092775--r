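# motifSpace

Combinatorics of the protein linear motif universe.

Short linear motifs (SLiMs) are compact protein subsequences — typically
fewer than 15 residues, inside intrinsically disordered regions — that
mediate a large share of protein–protein interactions. Curated resources
such as the ELM database describe each *motif class* by a regular
expression over the amino acid alphabet (`[LI].C.[DE]` for the Rb pocket B
binding ligand). Only a few hundred classes are known, and discovery has
not saturated. motifSpace implements, for analysts of motif databases, a
combinatorial theory of how many classes *could* coexist at a given level
of mutual sequence specificity, and what fraction of sequence space the
full potential repertoire would occupy.

## The model in brief

A motif class of length *n* is a tuple of allowed-residue sets
(A₁, …, Aₙ) over an alphabet of size *A* (20 by default); its *structure*
is e = (e₁, …, eₙ) with eᵢ = |Aᵢ|. Specificity between two classes is the
number of **motif-discriminating positions** (mdp): aligned positions,
both allowing at most 10 residues, whose allowed sets are disjoint —
minimised over all no-overhang alignments that match at least one pair of
fixed positions. For a family in which every pair keeps at least *k*
discriminating positions, the maximal size |M(k)| obeys

* |M(0)| ≤ ∏ᵢ C(A−1, eᵢ−1)  (per-position Erdős–Ko–Rado),
* ∏ᵢ ⌊A/eᵢ⌋ ≤ |M(1)| ≤ ∏ᵢ A/eᵢ  (constructive / pigeonhole),
* |M(k)| ≤ ∏ᵢ≤n−(k−1) A/eᵢ  (eᵢ sorted decreasing),
* |M(n)| = minᵢ ⌊A/eᵢ⌋  (exact),

and the potential occupancy of sequence space at level k ≥ 1 is
∏ᵢ(eᵢ/A) · |M(k)| — exactly 1 at k = 1. Shannon entropy of
post-translational-modification frequencies gives an effective number of
modifications (2^H) for expanded alphabets (20 → 29 or 33 letters).

## Worked example

```r
library(motifSpace)

a <- MotifClass("[LI].C.[DE]", identifier = "LIG_Rb_LxCxE",
                name = "Rb pocket B binding ligand")
b <- MotifClass("[FI].W", identifier = "TOY_FIW")

motifStructure(a)
#> [1]  2 20  1 20  2
countInstances(a)
#> [1] 1600

pairSpecificity(a, b)$alignmentTable
#>   offset alignval mdp
#> 1      0        1   1
#> 2      1        0   0
#> 3      2        1   2
mdp(a, b)
#> [1] 1
```

Three alignments of the shorter class against the longer; the middle one
matches no pair of fixed positions and is discarded; the informative ones
score 1 and 2, and the reported specificity is the minimum, one
motif-discriminating position — the most common separation between
naturally occurring motif classes.

```r
e <- motifStructure(a)
sapply(0:5, function(k) suppressWarnings(potentialClasses(e, 20, k)))
#> [1]  361 2000  100   10    1    1
m1Lower(e, 33)        # constructive bound on the 33-letter expanded alphabet
#> [1] 8448
classOccupancy(e, 20)
#> [1] 5e-04
potentialOccupancy(e, 20, k = 1)
#> [1] 1
```

At one discriminating position, 2000 classes of this structure can
coexist, and together their 1600-instance classes would tile sequence
space completely (2000 × 0.0005 = 1). Database-level analysis runs the
same calculation over a whole class table:

```r
db <- deduplicate(sampleMotifDatabase(172, seed = 1))$database
ps <- pairwiseSpecificity(db)
ps$histogram
#>    0    1    2    3    4    5    6 
#> 2731 5923 3102 1141  259   45    2
potentialDistribution(db, 20, k = 1)$median
#> [1] 8000
```

(A synthetic, seeded database stands in for a curated snapshot; real
tables load with `readClassTable()` from ELM-dialect TSV or JSON.)

## Package tour

| Area | Functions |
| --- | --- |
| Parsing & curation | `preprocessRegex()`, `parseMotifRegex()`, `MotifClass()`, `readClassTable()`, `writeClassTable()`, `deduplicate()` |
| Specificity | `mdp()`, `pairSpecificity()`, `alignments()`, `fixedPositions()`, `pairwiseSpecificity()` |
| Combinatorial bounds | `potentialClasses()`, `m0Upper()`, `m1Lower()`, `mkUpper()`, `mnExact()`, `buildDiscriminatingSet()`, `exhaustiveMaxDiscriminating()` |
| Occupancy | `classOccupancy()`, `potentialOccupancy()` |
| Alphabet expansion | `shannonEntropy()`, `effectiveNumber()`, `expandedAlphabetSize()`, `readPtmTable()` |
| Database analysis | `potentialDistribution()`, `occupancyDistribution()`, `alphabetSweep()`, `subsampleExperiment()`, `specificitySplitExperiment()`, `mismatchToleranceExperiment()`, `proteomeClassEstimate()` |
| Synthetic data | `sampleMotifDatabase()`, `exampleMotifDatabase()`, `samplePtmMixture()` |

The methods vignette (`vignettes/motif-universe.Rmd`) documents the model,
its assumptions, the numerical conventions (floor placement, median
definition, seeding) and the synthetic generator's design.
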