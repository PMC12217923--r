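---
title: "Distance-based topological indices and QSPR models for tricyclic antidepressants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based topological indices and QSPR models for tricyclic antidepressants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

A drug molecule is reduced to its hydrogen-depleted graph $G(V, E)$: one
vertex per heavy atom, one edge per bond.  The graph is simple — bond
orders are collapsed, so a double or aromatic bond contributes the same
single edge as a single bond — and must be connected.  This is the
convention under which distance-based topological indices are defined, and
it is the only convention consistent with the observation that drugs with
isomorphic heavy-atom skeletons (amitriptyline/imipramine;
desipramine/nortriptyline/protriptyline) must share identical index
values even though their bond orders and heteroatom placements differ.

Two pair functions drive everything.  The *distance* $d(v_a, v_b)$ is the
shortest-path length between two vertices; the *detour distance*
$D(v_a, v_b)$ is the length of the longest **simple** path between them.
From these, five indices are computed over all unordered vertex pairs:

* Wiener index $W(G) = \sum_{a<b} d(v_a, v_b)$
* hyper-Wiener index $WW(G) = \sum_{a<b} \tfrac{1}{2}\left(d + d^2\right)$
* Harary index $H(G) = \sum_{a<b} 1/d(v_a, v_b)$
* detour index $D(G) = \sum_{a<b} D(v_a, v_b)$
* detour-Harary index $DH(G) = \sum_{a<b} 1/D(v_a, v_b)$

$W$, $WW$ and $D$ are exact integers ($d(d+1)$ is always even); $H$ and
$DH$ are kept at full double precision internally and rounded to four
decimals only when written into reports.  On a tree the unique simple path
between two vertices is also the shortest one, so $D(G) = W(G)$ and
$DH(G) = H(G)$ — a strong internal consistency check that the test suite
exercises on hundreds of random trees.

# Computing the detour matrix exactly

Longest simple path is NP-hard in general, but molecular graphs are sparse
(cyclomatic number, i.e. ring count, rarely above 6) and that structure can
be exploited exactly rather than heuristically.  `detour_matrix()`
decomposes the graph into biconnected components (blocks) through its
block-cut tree.  A simple path between vertices $u$ and $v$ traverses a
unique sequence of blocks, entering and leaving each through its cut
vertices, so

$$D(u, v) = \sum_{\text{blocks } B_i \text{ on the } u\!-\!v \text{ block path}} D_{B_i}(\text{entry}_i, \text{exit}_i).$$

Within each block, all simple paths are enumerated by depth-first search
with a visited set.  Enumeration cost is exponential only in the block
size, and drug-like blocks (a fused tricyclic system is one block of about
14 atoms and ring count 3) enumerate in milliseconds; pendant trees and
chains — typically most of the molecule — cost nothing.  The engine counts
its DFS steps and stops with an error if a budget (default $5\times 10^7$
steps) is exceeded, so an unexpectedly dense input fails loudly instead of
being silently approximated.  An independent whole-graph exhaustive oracle,
`brute_force_detour()`, is kept deliberately free of the block logic and
limited to 12 vertices; the test suite checks the engine against it
entrywise on 100 random graphs.

# The QSPR regression layer

For each index $TI$ and each physicochemical property $P$ (boiling point
°C, melting point °C, enthalpy of vaporisation kJ/mol, flash point °C,
molar refractivity cm³, polarizability $10^{-24}$ cm³, surface tension
dyn/cm, molar volume cm³) the simple linear model

$$P = A + b \cdot TI$$

is fitted by ordinary least squares, reporting Pearson $r$, $R^2$, the $F$
statistic on $(1, n-2)$ degrees of freedom, its upper-tail $p$-value, and
the standard error of estimate $SEE = \sqrt{RSS/(n-2)}$.  Significance is
declared at $p < 0.05$ with no multiple-testing correction, matching the
convention of the published analysis this package reproduces; with 40
fitted pairs that choice inflates the family-wise error rate, and users
drawing inferences (rather than reproducing tables) should adjust.
Normality of the property values is assumed, not tested.  A report cell
whose fit fails (for example a constant index column) is recorded as `NA`
without aborting the remaining 39 cells, and reports on fewer than 10
molecules carry a low-power warning.

# The fixture data and its repair

`load_drug_fixtures()` ships, for each of the fifteen drugs: a
standard-reference SMILES (data, validated against the heavy-atom count of
the molecular formula), the eight published property values, and the
published index values.  The published index table as printed contains a
duplicated "Alprazolam" label: its second row, whose values equal
Imipramine's, belongs to Amitriptyline (whose skeleton is
graph-isomorphic to Imipramine's) and is carried here under that name,
giving each drug exactly one row.

Recomputation from the structures reproduces 71 of the 75 published index
values exactly (integers bit-exact, reciprocal-sum indices to the four
printed decimals).  The four exceptions are defects of the printed table,
not of the structures: the printed Harary values for imipramine and
amitriptyline (70.1256/70.1254, recomputed 72.7087) are impossible for any
graph whose Wiener and hyper-Wiener values match the printed ones, since
all three indices are determined by the same distance multiset — and the
two printed values even differ from each other although the graphs are
isomorphic; the trimipramine Harary (printed 78.4616, recomputed 78.4611)
and buspirone detour-Harary (printed 57.3298, recomputed 57.3198) are
single-digit transcription slips.  The acceptance tests assert the printed
values faithfully and therefore fail on exactly those four cells; the
regular suite asserts the recomputed values, which were cross-checked with
an independent cheminformatics toolchain.

The regression layer, by contrast, reproduces the published statistical
tables only when fitted on the *printed* index table (verifiably: the
boiling-point–Harary fit returns the published 86.9197 + 4.9452·H(G) with
the printed Harary column and not with the recomputed one).  For that
reason `build_qspr_report(fixtures, indices = "published")` — the default —
runs on the published table shipped as data, while
`indices = "computed"` (and the `cmd_qspr()` pipeline) recomputes indices
from structures at full precision.  With the published inputs, all 320
regression statistics match the published tables to $5\times 10^{-4}$
except eight isolated cells that are digit-transposition misprints
contradicted by their own row (for instance a printed $F = 49.8686$ whose
own $R^2 = 0.7899$ implies $F = R^2(n-2)/(1-R^2) = 48.8686$, or a printed
$p = 1.1989$, impossible for a probability, recomputed as 0.1989); the
tests assert the self-consistent value for those cells.

# The synthetic-data generator

Property-based tests need graphs with the statistical character of drug
skeletons but no fixed structures.  `random_connected_graph(n, extra_edges)`
draws a uniform random labelled tree by Prüfer-sequence sampling
(uniformity matters: the tree-identity tests should not favour particular
tree shapes) and adds `extra_edges` distinct non-tree edges uniformly at
random, giving a connected simple graph with exactly that cyclomatic
number.  Defaults in `generate_qspr_dataset()` span 10–28 atoms and ring
counts 0–6, bracketing the fixture drugs (19–28 heavy atoms, 2–4 rings).
The generator then emits $p_i = A^* + b^* TI_i + \varepsilon_i$ with
i.i.d. Gaussian noise — exactly the generative model the regression layer
assumes, which is the point: parameter-recovery tests confirm the fitting
machinery against known truth.  What the generator deliberately does not
emulate: correlated properties, heteroatom effects, or any structure-noise
dependence; passing tests therefore validate the computational machinery,
not the chemical realism of linear index–property relationships.

All randomness flows through one `seed` argument (applied with a local RNG
scope, so callers' RNG state is untouched); nothing depends on hidden
global state.

# Numerical and design choices

* Vertices are indexed 1-based internally (the natural R convention);
  adjacency-list files use 0-based indices as an interchange format.
  Nothing observable depends on labelling — all indices are
  permutation-invariant, and the suite checks this by relabelling.
* SMILES parsing is delegated to ChemmineR/Open Babel; bond orders are then
  collapsed and hydrogens dropped in this package, so any valid SMILES
  input yields the unlabeled simple skeleton.
* Matrix entries are bounded by $n - 1 \le 40$ at molecular scale and all
  index sums stay far below $2^{53}$, so plain double/integer arithmetic is
  exact for $W$, $WW$ and $D$.
* Report CSVs print reals to four decimals (the convention of the
  published tables); JSON twins carry full precision.  Test comparisons
  against published values use $5\times10^{-5}$ for index values and
  $5\times10^{-4}$ for regression statistics, absorbing the print rounding
  of the inputs.
* Problem sizes in the test suite — graphs to 20 vertices, 100 graphs for
  the oracle equivalence, 1000 noise replicates on a fixed 50-molecule
  design for unbiasedness — were chosen to give comfortable statistical
  resolution while keeping the whole suite under a minute.

# Limitations

Stereochemistry, charges, tautomers and 3-D geometry are out of scope: the
indices are functions of the unlabeled skeleton only.  The detour engine's
exactness guarantee holds for graphs whose biconnected blocks are small;
dense non-molecular graphs will exhaust the step budget (by design, with an
error).  The QSPR layer implements simple one-predictor regressions only —
the published analysis uses nothing stronger — and its correlations for
melting point and surface tension are weak, which the published discussion
itself notes; no predictive claim beyond the reproduced tables is made.
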