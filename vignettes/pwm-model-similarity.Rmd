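---
title: "Comparing TFBS models by the Jaccard index of their word sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing TFBS models by the Jaccard index of their word sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwmjaccard)
```

## The model

A transcription factor binding site (TFBS) model is a position weight
matrix $M$ of width $m$ together with a score threshold $t$. The matrix
assigns each DNA word $\omega \in \{A,C,G,T\}^m$ the additive score
$S(\omega, M) = \sum_i M(\omega_i, i)$, and the model recognizes the word
set $\Omega(M, t) = \{\omega : S(\omega, M) \ge t\}$ (the comparison is
inclusive). Words are weighted by an i.i.d. background: each letter is
drawn independently with probabilities $p(\alpha)$, so
$P(\omega) = \prod_i p(\omega_i)$. The P-value of a threshold is the
probability that a background word is recognized,
$P(M,t) = \sum_{s \ge t} Q(M,s)$, where $Q(M,s)$ is the probability of
attaining exactly score $s$.

Two aligned models are compared by the probability-weighted Jaccard index

$$J1(\Omega_1, \Omega_2) =
  \frac{P(\omega \in \Omega_1 \cap \Omega_2)}
       {P(\omega \in \Omega_1 \cup \Omega_2)},$$

which under a uniform background is literally
$|\Omega_1 \cap \Omega_2| / |\Omega_1 \cup \Omega_2|$. Matrices of
different widths (or at different offsets) are aligned by padding all
hanging positions with all-zero columns; zero columns leave every word
score, the distribution $Q$ and every P-value unchanged, so padding is
semantically free. The reported similarity

$$J2 = \max_{\text{shift } i,\ \text{orientation}} J1_i$$

maximizes over every relative shift with at least one overlapping column
($1-m_1 \le i \le m_2-1$, i.e. $2(m_1+m_2-1)$ alignments) and over the
reverse complement of the second matrix. $D2 = 1 - J2$ is a proper metric
on models compared at fixed P-value levels: identity and symmetry are
immediate, and the triangle inequality follows from embedding any three
models into one common alignment (padding is free, and the pairwise
optimal alignments can only improve on the inherited one).

The orientation search assumes a *strand-symmetric* background
($p(A)=p(T)$, $p(C)=p(G)$): only then does reverse-complementing a matrix
preserve its score distribution, so that the two orientations are compared
on an equal footing. `jaccard_best()` therefore refuses an asymmetric
background unless `both_strands = FALSE`.

## Exact computation

All probabilities are computed exactly by dynamic programming after
discretization: each cell is multiplied by a level $d$ and rounded *up*
(`ceiling`), and a real threshold $t$ maps to $\lceil d\,t \rceil$.
Rounding up, rather than to nearest, makes the derived integer threshold an
upper bound for the requested P-value. Integer scores make the state space
finite: the number of distinct scores is at most
$(\text{max\_score}-\text{min\_score})\,d\,m$.

* **Single matrix.** Position-by-position convolution of a dense mass
  vector gives $Q(M,s)$ over the attainable range; P-values are tail sums,
  and thresholds for P-values are found on the same vector.
* **Two matrices.** A sparse table keyed by prefix score pairs
  $(S_1, S_2)$ is advanced one aligned column at a time: each cell spawns
  four successors weighted by $p(\alpha)$, and duplicates are collapsed.
  After the last column, $P(\Omega_1 \cap \Omega_2)$ is the mass with
  $S_1 \ge t_1$ and $S_2 \ge t_2$; the union follows from
  $P_\cup = P_1 + P_2 - P_\cap$ with $P_1, P_2$ from the one-dimensional
  DP. With pruning enabled (the default inside `jaccard_best()`), cells
  whose score plus the best attainable suffix score cannot reach the
  threshold on either matrix are dropped; such prefixes can never
  contribute to the intersection, so the final sum is unchanged — the test
  suite asserts pruned and unpruned intersections are identical.

Probability mass is accumulated in double precision; the smallest word
probability at the widths used here ($m \le 30$) is far above underflow,
so no log-space arithmetic is needed. Results that are mathematically
exact integers (supports, thresholds) are exact in the implementation;
accumulated masses agree with enumeration to ~1e-15 relative.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `pvalue` | 0.0005 | shared P-value defining both thresholds; the same value for both models keeps the two word sets comparable in size |
| `d` (similarity) | 10 | discretization for J2/D2; coarse levels merge word ranks but shift J2 only mildly (the suite monitors $|J2_{d=100} - J2_{d=1000}| < 0.05$) |
| `d` (thresholds) | 10000 | threshold/P-value conversion needs finer score resolution than similarity |
| `d_rough` / `d_precise` | 5 / 10 | the two scanner passes (below) |
| `margin` | 0.05 | rough-pass allowance: entries with rough J2 ≥ cutoff − margin advance |
| cluster cut | 0.95 | a subtree is a cluster while its maximum pairwise D2 ≤ 0.95, i.e. its two most dissimilar motifs still share ≥ 5% of recognized words |

Thresholds may also be given directly as real scores (mapped by
$\lceil d\,t\rceil$); the P-value pathway is the default.

Because scores are discrete, a requested P-value is usually not exactly
attainable; both bracketing conventions are exposed. `strong` (default)
returns the smallest threshold with actual P-value ≤ requested — the
conservative choice; `weak` the largest threshold with actual ≥ requested.
When the requested value is exactly attainable the two can legitimately
differ (they bracket a zero-mass score plateau from opposite ends) while
reporting the same actual P-value.

## Alignment tie-breaking

Several alignments can attain the same J1 (e.g. palindromic motifs on both
strands). Ties are broken deterministically: direct orientation before
reverse complement, then smaller absolute shift, then the negative shift.
Candidates are visited in that preference order and a later candidate must
beat the incumbent by more than 1e-12 to replace it, which also absorbs
ulp-level asymmetries in float accumulation.

## The two-pass scanner

Scanning a collection for models similar to a query computes J2 at a cheap
rough level first and re-evaluates survivors precisely. The rough pass is a
heuristic filter — coarse discretization biases J2 downward because the
strong threshold's actual P-value lumps upward unevenly for the two models
— so its level matters. Measured on 50-motif synthetic collections at
P-value 0.0005 (nine perturbed queries, all entries with J2 > 0.05), the
maximum rough-pass underestimate of the precise J2 was:

| `d_rough` | 1 | 2 | 3 | 4 | 5 |
|---|---|---|---|---|---|
| max underestimate | 0.33 | 0.23 | 0.22 | 0.10 | 0.049 |

At `d_rough = 1` the filter misses genuine relatives outright, so the
default is `d_rough = 5`, the first level whose drift falls within the
default margin of 0.05. The scanner's soundness is asserted in the test
suite by comparing a default scan against the exhaustive precise
computation on a 50-motif collection; the two-pass result is required to
match exactly.

A second degenerate case arises at coarse levels: score lumping can leave
*no* attainable score with tail probability ≤ the requested P-value, so the
strong threshold would recognize the empty set and every similarity against
that entry — including an identical matrix — would be 0. Collection caches
therefore fall back to the weak threshold exactly when the strong actual
P-value is 0. The public `threshold_from_pvalue()` keeps the strict
semantics and reports what was asked.

## Clustering

`pairwise_matrix()` computes all-vs-all J2 at the collection's shared
P-value; `upgma_tree()` runs average-linkage clustering (via
`stats::hclust`) and exports an ultrametric tree in newick form, with two
leaves merged at distance $h$ placed at height $h/2$. `cut_clusters()`
descends from the root and accepts a subtree as a cluster when the maximum
*true* pairwise D2 among its leaves (not the cophenetic height) is at most
the cut; clusters and members are name-sorted, so the partition is
invariant to input file order.

## The synthetic generator

No external motif database ships with the package; `random_pwm()` provides
the study material. Its default model draws per-position letter
frequencies from a sparse Dirichlet (concentration 0.5, so most positions
have a dominant letter, as real motifs do) and converts them to log-odds
against the chosen background — giving realistic matrices that mix
positive and negative cells. `perturb_pwm()` adds seeded Gaussian noise
(default sd 0.3 score units) to emulate "same-TF" model pairs built from
different experiments; collections default to 50 motifs of widths 6–12.
All fixtures are reproducible from their seeds alone.

What the generator does *not* emulate: dinucleotide structure and other
non-i.i.d. composition of genomic sequence, width-correlated information
content, curated-database biases, or truly multi-modal binding (one TF
with several distinct motifs). Passing tests therefore demonstrate the
algebraic and algorithmic correctness of the measure on realistic matrix
shapes, not any biological claim about particular factors or databases.

## Problem sizes in the tests

The suite cross-checks the DP against full word enumeration (the
independent oracle) on 100 random pairs of widths 1–5 at $d = 100$, checks
the metric axioms on 20 models (all 1140 triangles), the threshold
contracts on 50 matrices × 4 P-values, scanner soundness on a 50-motif
collection, and the perturbed-versus-random separation on 50 pairs per
P-value level — sizes chosen so the whole suite runs comfortably on a
laptop while the enumeration oracle stays exact.

## Limitations

* The background is i.i.d. only. Extending the DP to order-$k$ Markov
  backgrounds multiplies the state space by $4^k$ and is out of scope.
* J2 depends (mildly) on the discretization level; values computed at
  different levels should not be mixed in one analysis.
* D2 is a metric only when all models are compared at one shared P-value
  level; mixing levels breaks the set-size comparability the proof relies
  on.
* The rough scan pass is a calibrated heuristic, not a proven bound; the
  margin absorbs the measured drift, and the exhaustive pass
  (`cutoff = 0, margin = 0`) is always available as ground truth.
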