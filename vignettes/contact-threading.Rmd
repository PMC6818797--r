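---
title: "Contact-guided threading: model and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-guided threading: model and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Threading asks: given only sequence-derived information about a query
protein — a sequence profile, a predicted secondary structure, and a
predicted residue–residue contact map — which known template structure
shares its fold, and how do query residues map onto template residues?
`conthread` implements a contact-map-centred answer: the dominant
eigenvectors of a contact map are compact per-residue descriptors of the
fold's topology, and aligning the query's predicted eigen-profile against
each template's native eigen-profile turns fold recognition into a
standard dynamic-programming alignment.

# The model

## Contact maps and eigen-profiles

A contact map for a chain of length $L$ is the symmetric 0/1 matrix $M$
with $M_{ij} = 1$ when the C-beta atoms (C-alpha for glycine) of residues
$i$ and $j$ lie within a cutoff (default 8 Å). `decompose()` takes the
eigendecomposition $M = V \Lambda V^\top$ and keeps the top $K$ (default
7) positive eigenvalues. For a sign mask $m \in \{\pm 1\}^K$ the
per-residue profile vectors are

$$ U_i[k] \;=\; m_k \,\sqrt{\lambda_k}\; v_{ik}, \qquad k = 1, \dots, K. $$

With the square-root scaling, $U U^\top$ reproduces the rank-$K$
truncation $V_K \Lambda_K V_K^\top$ of the map exactly — this is the
natural symmetric factorisation, and it is what the test suite verifies
entrywise. A `scaling = "linear"` option ($m_k \lambda_k v_{ik}$) is kept
as a switch; it weights high eigenvalues more aggressively and its Gram
matrix reproduces $V_K \Lambda_K^2 V_K^\top$ instead.

Predicted query contacts are filtered before decomposition by
`select_contacts()`: candidates are pairs with sequence separation
$\ge 5$, plus separation-4 pairs whose five residues sit in one
contiguous helix. Candidates are split into long ($\ge 24$), medium
(12–23) and short ($\le 11$) separation classes, and the top
$\mathrm{round}(\sigma L)$ by predicted probability are kept per class
with $\sigma = 1.79, 0.41, 0.31$ (2.51 $L$ contacts in total when the
prediction is dense enough).

## The combined match score

For query residue $i$ and template residue $j$:

$$ S(i,j) \;=\; w_1 S_{cm} + w_2 S_{prof} + w_3 S_{ss} + w_4, \qquad
   w = (0.5,\, 0.4,\, 0.1,\, 0.1). $$

* $S_{cm}(i,j) = U_i \cdot P_j \,/\, \max(|U_i|, |P_j|)^2$, the eigen-profile
  match between query vector $U_i$ and template vector $P_j$ (0 when both
  vanish). It is bounded by 1 in absolute value and equals 1 exactly for
  identical non-zero vectors.
* $S_{prof}$ is a symmetrised profile–profile score: the cross products of
  one side's frequencies with the other side's log-odds, averaged, and
  clipped to $[-5, 5]$.
* $S_{ss} = \pm c_i$, the query's predicted-confidence of its most likely
  state, signed by agreement with the template state.
* $w_4$ is a constant shift that rewards extending the alignment.

Gap penalties are composed from per-term penalties with the same weights:
opening costs $g_o = -1.0$ and extension $g_e = 0.5(-0.1) + 0.4(-0.1) +
0.1(-0.077) = -0.0977$ per gapped residue.

## Alignment

`nw_affine()` is an affine-gap dynamic program (implemented in C++) in
two modes. The default free-ends mode charges nothing for unaligned
leading and trailing residues of *either* chain — implemented with
restart semantics, $D(i,j) = S(i,j) + \max(0, V(i-1,j-1))$, answer
$\max(0, \max_{ij} D)$ — so only internal gaps cost $g_o + g_e \ell$.
A fully global mode charges terminal gaps too. Tie-breaking is
deterministic (first-best end cell in row-major order; diagonal preferred
over vertical over horizontal), so results are bit-reproducible. The DP
is validated against an exhaustive brute-force oracle on hundreds of
random small matrices in both modes.

## The sign-mask search

Eigenvectors are defined only up to sign, so the query profile must be
searched over sign masks. `align_enumerative()` runs the DP for every
mask over the first $k$ components, cumulatively for $k = 1, \dots, K$:
$\sum_{k=1}^{K} 2^k$ alignments, i.e. 254 at $K = 7$. Ties prefer fewer
components and then the lexicographically earlier mask (all-positive
first). `align_greedy()` fixes one component sign at a time (ties keep
$+1$), costing only $2K$ alignments; it can never beat the enumerative
score but is close in practice and much cheaper. Because the mask
enumeration covers all sign combinations, the best alignment is invariant
to the eigen-solver's arbitrary sign conventions on either side — a
property the test suite checks directly by negating random column
subsets.

## Two-stage threading and ranking

`thread()` scans the whole template library with the greedy search at
$K = 2$, ranks templates by CMO$_q$ — the fraction of query contacts
$(i,j)$ whose aligned template pair $(a_i, a_j)$ is also a template
contact — and standardises the stage-1 scores into population Z-scores.
The top `m_refine` (default 1000) templates are re-aligned with the full
enumerative search at $K = 7$ and re-ranked. Sorting keys include the
template id so the final ranking is independent of library iteration
order.

Two post-threading quantities are provided for downstream model building:
`e_con()`, a continuous, monotone piecewise restraint energy on an
aligned-contact distance (flat $-U$ below 8 Å, two sine ramps, flat $+U$
beyond 80 Å, midpoint parameter $D = 16$ Å), and `c_score()`, a
log-composite confidence built from decoy-population statistics.

# The toy generator

Real templates require PDB structures and sequence profiles from external
pipelines, so the package ships a deterministic toy generator used by the
tests and the acceptance script. `make_toy_structure()` builds idealised
folds from a topology string: helices with 1.5 Å rise, 100° twist and a
3.0 Å anchor radius; strands as 3.4 Å-rise zigzags; segments packed side
by side with alternating direction (4.8 Å strand spacing, 9.0 Å helix
spacing) and loops interpolated with small seeded jitter. The geometry is
designed so that native contact maps show the hallmark patterns (helix
$i, i+4$ ladders, antiparallel cross-strand ladders).
`perturb_contact_map()` simulates an imperfect contact predictor with a
false-negative drop rate, false-positive additions at separation $\ge 5$,
and probabilities that rank true contacts above false ones.
`toy_fold_set()` provides six distinct small folds; self-recognition of a
noisy query against this library is the package's end-to-end check.

The generator's scope is deliberately narrow: chains of tens of residues,
idealised secondary-structure geometry, single chains, no side-chain
packing. It exists to give the algorithms structurally meaningful inputs
with known ground truth, not to imitate real proteins.

# Numerical choices and limitations

* **Square-root eigenvalue scaling** is the default because it is the
  symmetric factorisation whose Gram matrix is the rank-$K$ map
  truncation; the linear form remains available via `scaling`.
* **Greedy cost is $2K$ alignments** — one pair of sign choices per
  component, fixed sequentially.
* **Degenerate eigenvalues**: when eigenvalues coincide, the
  eigendecomposition is not unique; `decompose()` fixes a deterministic
  orientation per column (largest-magnitude entry positive), which makes
  runs reproducible but the chosen basis within a degenerate eigenspace
  is still solver-dependent in principle. The alignment score is
  invariant to column signs, not to rotations inside a degenerate block.
* **Strict inequality at the contact cutoff**: pairs at exactly the
  cutoff distance are not contacts.
* **Population (divide-by-$n$) standard deviation** is used for Z-scores,
  with an all-equal population mapping to all-zero scores.
* The coordinate-based secondary-structure assigner `ss_from_coords()` is
  a coarse geometric rule (compact $i..i{+}4$ window runs for helix,
  extended $i{-}1..i{+}1$ span for strand) intended for idealised or
  high-quality coordinates; it is not a hydrogen-bond-based assigner and
  misassigns distorted or very short elements.
* Tested problem sizes are small (chains up to ~100 residues, libraries
  of a handful of templates); the algorithms are polynomial
  ($O(L^2)$ per DP, times the mask budget) and carry no further
  size-specific tuning.
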