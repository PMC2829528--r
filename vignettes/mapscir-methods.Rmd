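---
title: "Consensus-based multiple structure alignment: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-based multiple structure alignment: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapscir)
```

## The model

mapscir aligns a set of $K$ protein structures represented as ordered
C$\alpha$ traces, and simultaneously builds a *consensus pseudo-structure*:
a sequence of coordinate triples (and gaps) that summarises the family's
shared geometry. The objective is the Sum-of-Consensus (SC) distance,

$$\mathrm{SC} \;=\; \sum_{j=1}^{K} \big\lVert H_0 - (H_j - e\,t_j)R_j
\big\rVert_F^2,$$

with the conventions that a matched pair of triples contributes its squared
Euclidean distance, a triple against a gap contributes the squared gap
penalty $\rho^2$, two gaps contribute nothing, and gaps are unaffected by
the rigid transforms $(R_j, t_j)$. The consensus row $H_0$ is never
transformed: it defines the common frame, and the proteins move into it.
Minimising SC jointly over the correspondence, the transforms and the
consensus is intractable, so the driver performs block-coordinate descent:
each kind of update (DP realignment, center-star merge, per-protein
superposition, per-column consensus choice) is individually optimal given
the rest, hence the SC trace is non-increasing and the loop converges to a
local minimum. Like any local method, the result can depend on the starting
consensus; the `maxcore` strategy makes that choice data-driven.

Assumptions worth keeping in mind: alignments are *sequential* (no circular
permutations or order-violating equivalences), structures are treated as
rigid bodies (no hinge or flexible alignment), and only backbone C$\alpha$
geometry enters — residue identity influences nothing but the PIR output.

## Parameters

* **Gap penalty** (`gapPenalty`, default 16, `gapMode = "squared"`): the
  cost, in &Aring;$^2$, of any gap column. The default means a gap is as
  expensive as a 4&nbsp;&Aring; mismatch, the same length scale as the
  strict-core cutoff; pairs farther than 4&nbsp;&Aring; are cheaper to gap
  than to match. The published description of this algorithm states a gap
  penalty "value" of 16.0 while all of its cost formulas charge $\rho^2$ per
  gap; read literally ($\rho = 16$&nbsp;&Aring;) a gap would cost
  256&nbsp;&Aring;$^2$ and almost never be opened. We default to the
  square-cost reading ($\rho = 4$&nbsp;&Aring;), which matches the 4.0
  &Aring; core scale, and expose `gapMode = "linear"` for the literal one
  rather than deciding silently.
* **Convergence** (`eta`, default $10^{-4}$): the outer loop stops when
  $(\mathrm{SC}^{i-1} - \mathrm{SC}^i)/\max(\mathrm{SC}^{i-1}, 10^{-12}) <
  \eta$. A dimensionless threshold of $10^{-4}$ only makes sense as a
  *relative* change (SC itself is in &Aring;$^2$ and scales with $Kn$), so
  relative is the default; `etaMode = "absolute"` is available.
* **Inner tolerance** (`innerTol`, default $10^{-6}$&nbsp;&Aring;$^2$) and
  iteration caps (`maxInnerPair` 50, `maxInnerRefine` 100, `maxOuter` 100):
  the interleaved transform/consensus stage and the pairwise bootstrap have
  no natural stopping rule of their own; an absolute $10^{-6}$ on a
  quantity that decreases monotonically is far below any geometric signal.
* **Core cutoff** (`coreCutoff`, default 4.0&nbsp;&Aring;): strict-core
  distance threshold, the field's conventional value.
* **Consensus rule** (`consensusRule`, default `"strict"`): see below.

## Design choices made where the design was open

**Consensus update rule.** For a column with point set $\{p_i\}_{i \in
I_n}$ and $|I_g|$ protein gaps, the optimal consensus entry is the centroid
$x$ or a gap. The two-case comparison is often written as "centroid iff
$\sum_i \lVert x - p_i \rVert^2 < |I_n|\rho^2$", which silently drops the
$|I_g|\rho^2$ a consensus *triple* incurs against the gapped proteins — yet
that charge is part of the SC convention itself. The dropped term matters:
with the truncated ("literal") rule we observed SC increases across outer
iterations on random families (e.g. a trace 2608.0 → 2571.1 → 2581.6),
because a column can flip from gap back to a triple whose gap charges exceed
its savings. The default `"strict"` rule includes the $|I_g|\rho^2$ term,
making the update an exact per-column SC minimiser and the whole loop
provably monotone; `"literal"` is retained for comparison. The two rules
coincide whenever a column has no gaps. Ties choose the triple (keeps the
consensus maximal; deterministic either way).

**Center-star merging of insertions.** Residues that a protein aligns
*between* two consensus positions have no consensus anchor. We give the
insertion runs of all proteins at the same consensus slot *shared*,
left-aligned columns (the slot is as wide as the longest run), which is the
classic center-star behaviour. The alternative — a private column per
protein per inserted residue — satisfies the same projection contract but
behaves badly dynamically: each protein keeps re-matching its own copy of a
duplicated consensus position, regions absent from the initial consensus
never consolidate, and ground-truth correspondence recovery on synthetic
families plateaus around 92%; with shared columns it is ~99% or above.
Either way, projecting the merged matrix onto any (consensus, protein) pair
and dropping mutual-gap columns reproduces the input pairwise alignment
exactly — the property the convergence argument needs — and the SC at merge
time is identical under both layouts.

**Pairwise bootstrap.** The first outer iteration needs alignments between
structures in unrelated frames. Any pairwise structure aligner could be
plugged in here; ours is deliberately simple and deterministic: superpose
one of three gapless seed windows (N-terminal, C-terminal, centered; length
$\min(l_P, l_Q, 40)$), keep the seed whose DP alignment is cheapest, then
alternate match-column superposition with DP realignment until the cost
stalls. This is adequate for globally similar folds, which is the regime a
*global* SC objective targets anyway; it is documented as replaceable.

**DP details.** Needleman–Wunsch over squared distances with a constant
per-gap-column cost — no affine open/extend distinction, exactly as the
cost model defines, and terminal gaps cost the same as internal ones (a
uniform rule keeps the per-column bookkeeping of the consensus update
exact). Tie-breaking in the traceback is fixed (match over gap-in-moving
over gap-in-fixed) so results are reproducible to the bit. The DP kernel is
the one compiled (Rcpp) component.

**Core RMSD.** Defined here as the average over all $K(K-1)/2$ structure
pairs of the RMSD across core columns, in the final frames, with no
re-superposition — it measures the multiple alignment as produced. A
consensus-referenced variant of both the core test and the RMSD is
available (`reference = "consensus"`) for sensitivity checks.

**Degenerate inputs.** Rank-deficient cross-covariances (collinear points,
$n \le 2$ matches) use the same determinant sign rule; the optimum may be
non-unique and tests assert residual optimality rather than matrix
equality. All-zero covariance returns the identity with a warning. A column
whose proteins are all gapped proposes a consensus gap and is subsequently
stripped with the other all-gap columns.

**Structure input.** PDB parsing is delegated to bio3d; on top of its
table we keep C$\alpha$ atoms with blank or `'A'` altloc, first model only,
the 20 standard residues plus MSE→MET, and we ignore insertion codes and
numbering gaps (file order rules). These are the conventional
single-conformer choices of backbone-level aligners.

## The synthetic generator

`randomBackbone()` emulates only the geometric facts the algorithm is
sensitive to: fixed 3.8&nbsp;&Aring; consecutive-C$\alpha$ spacing,
persistent local direction with bond-angle jitter, and soft self-avoidance.
`makeFamily()` derives members by deletion indels (an insertion in one
member is a deletion in all others relative to an extended template, so
deletions alone already span the indel patterns the aligner faces), iid
Gaussian coordinate noise, and random rigid motions, recording the true
correspondence and motions. What it does *not* emulate: secondary
structure, Ramachandran statistics, correlated (domain-level) motions, or
genuinely divergent folds. Passing the closed-loop tests therefore shows
the optimisation machinery is correct and well-conditioned — it does not by
itself certify alignment quality on remote homologs, where the global
rigid-body assumption is the binding constraint.

Test problem sizes: the convergence sweep uses 200 families with $K \in
\{2..8\}$, lengths 20–120, noise up to 1&nbsp;&Aring; and deletion rates up
to 0.08; recovery studies use 80-residue, $K = 5$ families at
$\sigma = 0.3$&nbsp;&Aring;. These sizes exercise every code path at the
scale of typical curated families while keeping the whole suite fast.

## Known limitations

* Local optimisation: a poor initial consensus can trap the alignment;
  `maxcore` mitigates but does not eliminate this.
* Sequential, rigid, global alignment only — no circular permutations,
  hinges, or motif-local alignment.
* The consensus is geometric: its "residues" are pseudo-atoms (written as
  UNK), not inferred amino acids.
* The bootstrap pairwise aligner assumes global similarity; families whose
  members share only a small common core may need an external pairwise
  aligner in its place.
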