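---
title: "Estimating the size of the linear motif universe"
author: "motifSpace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the size of the linear motif universe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifSpace)
```

## The question

Short linear motifs (SLiMs) are compact protein subsequences — usually under
15 residues, in intrinsically disordered regions — that mediate a large share
of protein–protein interactions. Curated resources such as the ELM database
describe each *motif class* by a regular expression over the amino acid
alphabet: `[LI].C.[DE]` says "leucine or isoleucine, anything, cysteine,
anything, aspartate or glutamate". A few hundred classes are known, and the
discovery rate has not saturated. motifSpace implements a combinatorial
theory of how many classes *could* coexist, given that classes must remain
distinguishable in sequence space, and asks what fraction of all possible
subsequences the full potential repertoire would occupy.

## The model

A motif class of length $n$ is a tuple of allowed-residue sets
$\mathbf{A} = (A_1, \dots, A_n)$, $A_i \subseteq \mathcal{A}$, over an
alphabet $\mathcal{A}$ of size $A$ (20 by default). An *instance* is any
sequence $(a_1,\dots,a_n)$ with $a_i \in A_i$; the *structure* is the tuple
of set sizes $\mathbf{e} = (e_1,\dots,e_n)$, $e_i = |A_i|$. The model treats
all residues as exchangeable: only the structure enters the combinatorics.
This deliberately ignores the biophysics of particular amino acids, so the
counts below are upper-limit style estimates — evolutionary or biophysical
constraints can only shrink them.

### Specificity as motif-discriminating positions

Two equal-length classes are distinguished at position $i$ when
$A_i \cap B_i = \emptyset$ — no residue can satisfy both — *and* both
positions are fixed, i.e. allow at most 10 residues (half the canonical
alphabet; wildcard-like positions carry no specificity). The count of such
positions is the mdp value. For unequal lengths $n \ge m$ the shorter class
is slid along the longer one (no overhangs), alignments without a single
fixed–fixed position pair are discarded as uninformative, and the pairwise
mdp is the *minimum* over the informative alignments — a lower limit of the
distance in sequence space. When no alignment is informative the pair is
reported as mdp 0 with `informative = FALSE`, which deliberately places such
pairs in the "not separated" bin of the database histogram.

```{r}
a <- MotifClass("[LI].C.[DE]", "LIG_Rb_LxCxE")
b <- MotifClass("[FI].W", "TOY_FIW")
pairSpecificity(a, b)$alignmentTable
```

The three alignments score 1, (uninformative), 2; the reported mdp is 1.

### Counting potential classes

Fix a structure $\mathbf{e}$ and require every pair in a family of classes
to show at least $k$ disjoint coordinates (a *k-discriminating* family; in
this combinatorial setting disjointness is exact set disjointness, with no
fixedness threshold). Writing $|M(k)|$ for the maximal family size:

* $|M(0)| \le \prod_i \binom{A-1}{e_i-1}$ — position-wise Erdős–Ko–Rado
  bound for pairwise-*intersecting* families;
* $\prod_i \lfloor A/e_i \rfloor \;\le\; |M(1)| \;\le\; \prod_i A/e_i$ —
  the lower bound is constructive (disjoint blocks of consecutive symbols,
  `buildDiscriminatingSet()`), the upper bound follows from the pigeonhole
  principle;
* $|M(k)| \le \prod_{i \le n-(k-1)} A/e_i$ for $k < n$, with the $e_i$
  sorted in decreasing order before truncation so the bound is sharpest;
* $|M(n)| = \min_i \lfloor A/e_i \rfloor$ exactly.

`potentialClasses()` dispatches between these, flooring upper bounds once at
the end. Two conventions are pinned down by the worked structure
(2,20,1,20,2): the $k$-ladder 361, 2000, 100, 10, 1, 1 requires the single
end floor with descending sort, while the expanded-alphabet value
$\lfloor 33/2\rfloor \cdot 33 \cdot \lfloor 33/2\rfloor = 8448$ requires the
per-factor floor in the *lower* bound. The two floors are therefore applied
in exactly those places and nowhere else. The $|M(0)|$ product is evaluated
as stated even at positions with $2e_i > A$, where the Erdős–Ko–Rado
hypothesis fails (the ladder value 361 requires the literal
$\binom{19}{19} = 1$ factors); `m0Upper()` emits a validity warning there,
which database-level aggregation suppresses after the first class would
otherwise repeat it hundreds of times.

```{r}
e <- c(2, 20, 1, 20, 2)
vapply(0:5, function(k) suppressWarnings(potentialClasses(e, 20, k)),
       numeric(1))
m1Lower(e, 33)
```

### Sequence-space occupancy

One class of structure $\mathbf{e}$ covers $\prod_i e_i / A^n$ of the $A^n$
sequences of its length. If all potential classes existed at level
$k \ge 1$ (instances then belong to a single class), the occupied fraction
is $\prod_i (e_i/A) \cdot |M(k)|$ with the *unfloored* bound. The package
evaluates this by algebraic cancellation: after sorting the structure in
decreasing order only the $k-1$ smallest ratios $e_i/A$ survive. This makes
the $k=1$ value exactly 1.0 in floating point (an empty product) and the
$k=2$ value exactly $\min_i e_i / A$ — the identity the tests assert at
machine precision. At $k = n$ the exact, floored $|M(n)|$ is used instead,
with one precedence rule: for single-position structures $k = 1$ and
$k = n$ coincide, and the $k = 1$ identity (occupancy exactly 1) wins, so
full coverage at mild specificity holds for every structure. At $k = 0$
instances may belong to several classes at once, no closed form exists,
and the function refuses rather than guessing.

### Effective alphabet size

Post-translational modifications enlarge the chemical alphabet. Their
usage is extremely uneven (relative abundances span about five orders of
magnitude), so a raw count of modification types would be misleading. The
package uses the entropy device familiar from effective species numbers in
ecology: for a frequency mixture $p_i$, $H = -\sum_i p_i \log_2 p_i$ and
the effective number is $2^H$, rounded to the nearest integer for alphabet
construction. `expandedAlphabetSize(20, TRUE, 12) == 33` adds
selenocysteine and twelve effective modifications. Reproducing the
literature value 12.33 requires the full curated frequency table, which is
not redistributable here; the packaged
`ptm_frequencies_synthetic.tsv` carries the twelve dominant modification
names with *illustrative* counts and is never asserted against, and
`samplePtmMixture()` generates log-uniform mixtures with a configurable
dynamic range for testing.

## Database-level analysis

`readClassTable()` ingests ELM-dialect TSV (or a JSON dump), applying the
four preprocessing rules in order: shortest version of variable-length
repetitions (`{p,q}` → `{p}`, `{0,q}` deletes the token); terminal anchor
removal; modified-residue symbol mapping (default `U → C`, the only mapping
the source material documents — the map is a configurable argument
precisely because curated databases may need more entries); and iterative
trimming of flanking positions allowing eleven or more residues (a position
allowing exactly ten is kept). Preprocessing is idempotent, and parse
errors name the offending construct and its 1-based offset.
`deduplicate()` then removes same-name classes with zero discriminating
positions, keeping the highest-instance member of each redundant cluster.

`potentialDistribution()` and `occupancyDistribution()` evaluate the
per-class bounds and summarise them as the cumulative curve $P(X \ge x)$
with the median taken as the largest value whose cumulative fraction is at
least 0.5 — the convention matching that curve — alongside the standard
interpolated median. Classes shorter than $k$ are excluded from the level-k
distribution (k discriminating positions are undefined for them) and
counted in `nExcluded`, rather than being clamped to their own length.
`alphabetSweep()` tabulates medians across alphabet sizes in *both* bound
variants ("upper": end floor; "lower": per-factor floor), because the
source arithmetic uses the constructive variant for expanded alphabets and
the pigeonhole variant elsewhere; labelling both avoids silently mixing
them.

### Robustness experiments

Three seeded experiments probe the stability of the medians.
`subsampleExperiment()` (default: 25% of classes, 10 replicates) addresses
database incompleteness. `specificitySplitExperiment()` sorts classes by
their potential instance count and splits at the median — the middle class
of an odd-sized database joins the more-specific half, a documented
tie-break. `mismatchToleranceExperiment()` wildcards one uniformly chosen
position in a seeded share of classes. The modified subset is the prefix
of a single seeded permutation with one pre-drawn position per class, so
for a fixed seed the 50% database is nested inside the 100% database; the
per-class potential counts are then pointwise non-increasing and the
monotone decrease of the medians is a theorem the tests can assert, not a
tendency. All experiments restore the caller's RNG state.

## The synthetic generator

No curated snapshot ships with the package, so `sampleMotifDatabase()`
generates databases with the statistical shape the analysis assumes:
lengths on 3–10 with the mode near 5; a bimodal allowed-set-size
distribution (roughly half the positions allow 1–3 residues, a heavy mass
at 19–20 is wildcard-like, intermediate sizes are rare); heavy-tailed
log-normal instance counts (median ≈ 5, mean ≈ 10); and a planted fraction
(default 5%) of same-name redundant clones whose allowed sets are supersets
at one position — guaranteeing mdp 0 with their parent and a strictly lower
instance count, so they are exactly what `deduplicate()` removes. Terminal
positions are drawn from the size distribution truncated at ten residues,
because curated tables are flank-trimmed and a generator emulating the
*post-curation* state must respect that invariant (it also makes written
tables re-read losslessly). The distributions are qualitative
approximations chosen once; they are test scaffolding, not claims about any
database snapshot, and nothing asserts them against external counts.

What passing tests on synthetic data do show: the pipeline's bookkeeping
(pair counts, medians, reproducibility, curation) is correct, and the
qualitative conclusions (mdp mode at 1, thousands of potential classes at
$k = 1$) are robust to the generator's randomness. What they cannot show:
any numerical property tied to the particular curated class list, such as
its exact medians or histogram fractions — reproducing those requires that
list as input through `readClassTable()`.

## Numerical and scale choices

* Upper-bound floors add $10^{-9}$ before flooring so products of rationals
  that are mathematically integral (e.g. $2.5^4 = 39.0625$ vs
  $10 \cdot 10 \cdot 20$) are not pushed below the integer by floating-point
  rounding; all worked values are small enough for doubles to be exact.
* `exhaustiveMaxDiscriminating()` is the independent oracle for the bounds:
  it enumerates all $\prod_i \binom{A}{e_i}$ candidate classes (bitmask
  sets, deterministic lexicographic order), builds the pair-compatibility
  graph and takes `igraph::clique_num()`. The candidate cap defaults to
  $10^4$; exact maximum-clique is exponential in the worst case, and dense
  instances (structures with singleton positions) dominate the runtime —
  a single such length-3 instance over a 4-letter alphabet takes minutes —
  so the test suite enumerates every structure of length ≤ 2 over alphabets
  2–6 and every length-3 structure over alphabets 2–3, a family that runs
  in about a minute while still covering all small cases exhaustively.
* Property tests run on seeded batches (60 random class pairs for the mdp
  brute-force equivalence, 1000 random structures for the occupancy
  identity, 100 constructed families for pairwise verification); the
  database-level checks use a 172-class synthetic database, matching the
  scale of a curated snapshot.

## Known limitations

* The theory treats amino acids as interchangeable; structures, not
  sequences, drive every count. Biophysical realism is out of scope.
* Regular expressions with alternation or unbounded repetition are
  rejected rather than approximated; curated tables avoid them after
  preprocessing, but raw inputs containing them need manual curation
  first.
* The mdp alignment procedure ignores overhanging flanks of the shorter
  motif, underestimating the contribution of flanking positions to
  specificity (a documented property of the measure, inherited here).
* The symbol map for modified residues defaults to the single documented
  mapping (`U → C`); curating a fuller map is the user's responsibility.
* Occupancy at $k = 0$ is undefined by design; the package errors instead
  of extrapolating.
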