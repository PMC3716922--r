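---
title: "Reducing multi-labeled trees: the model behind mulred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing multi-labeled trees: the model behind mulred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mulred)
```

## The problem

Multi-labeled trees (MUL-trees) arise whenever several sequences map to the
same taxon: gene families with paralogs, biogeographic trees labeled by
areas, co-speciation studies labeled by hosts.  Because two leaves can share
a label, a single MUL-tree may simultaneously display `bc|de` and `bd|ce`
for the same four taxa — conflicting statements no species tree can satisfy.
Yet the same tree usually also carries a large body of *conflict-free*
topological signal.  `mulred` extracts exactly that signal and discards
everything else, with a guarantee that nothing conflict-free is lost and
nothing new is invented.

## Information content

For an edge $(u,v)$ of an unrooted MUL-tree, deleting the edge splits the
leaves into two sides; the label set $M$ then partitions into $M_u$ (labels
found only on the $u$ side), $M_v$ (only on the $v$ side) and $C$ (labels
with leaves on both sides).  The edge *resolves* the quartet topology
$ab|cd$ when $a,b \in M_u$ and $c,d \in M_v$, so it resolves
$\binom{|M_u|}{2}\binom{|M_v|}{2}$ quartets; an edge with fewer than two
exclusive labels on either side is *uninformative*.  The information content
$I(T)$ is the union of the resolved sets over all edges.  Labels in $C$
never take part: that is what makes $I(T)$ conflict-free, and constructively
so — relabeling all duplicate copies with fresh names
(`relabel_to_singly()`) yields a singly-labeled tree displaying every
quartet of $I(T)$.

```{r}
fx <- example_multree()
fx
edge_partition(fx, c(2, 3))
information_content(fx)
```

The conflicting statements a MUL-tree makes are still visible through the
weaker *leafwise* display relation (`conflicting_label_sets()`), but they
are quarantined from the information content by construction.

## The maximally reduced form

A leaf is *prunable* and an internal edge *contractible* when removing it
leaves $I(T)$ unchanged; the package additionally treats *prune all copies
of one label* as an elementary reduction step.  This third operation is not
redundant: in the tree

```{r}
t <- parse_newick("((a,b,L),c,d,(e,f,L));")[[1]]
```

the label `L` lies in $C$ of every internal edge and so appears in no
quartet, and pruning both copies of `L` preserves $I(T)$ exactly — but
pruning either *single* copy strands the other copy in an exclusive side and
creates new quartets.  Without the label-level step the reduction would be
stuck at a fixed point that still carries dead weight, and different
operation orders could end at different trees.  With it, the fixed point —
the **maximally reduced form (MRF)** — is unique up to isomorphism, and
equal information content implies equal MRFs, which turns "same conflict-free
signal" into an equivalence the package can decide via `canonical_form()`.

`mrf()` computes the MRF in three phases, all driven by one $O(nm)$
bottom-up count matrix (`partition_counts()`) rather than by materialized
quartet sets:

1. **Uninformative edges** are contracted in one batch; contraction never
   changes another edge's partition, so one pass suffices.
2. **Subsumed edges.**  For adjacent informative internal edges the quartet
   sets are comparable exactly when exclusive-side cardinalities coincide
   (`edge_subsumption()` decides in constant time), because the far
   exclusive set of the outer edge is always nested in the inner one's.  On
   a hit the subsumed edge is contracted together with every internal edge
   branching off the shared node, and equal quartet sets allow the branching
   subtrees to be deleted whole.  Since comparable edges always line up
   along a path, scanning adjacent pairs until quiescence is exhaustive.
   Counts are recomputed after every action; the cardinality shortcut is
   only trusted between informative edges, so edges demoted mid-phase simply
   wait for the next pass.
3. **Redundant leaves**: whole labels outside every quartet, duplicate
   copies sharing a pendant node (first copy in traversal order survives —
   the choice cannot affect the isomorphism class), and copies attached at
   interior (spanning-degree $\ge 3$) nodes of their label's spanning
   subtree.  All spanning subtrees are read off the one count matrix and
   pruned in a single batch, which is exact because removing one label's
   redundant copies cannot change another label's spanning degrees.

The pipeline repeats until a pass changes nothing (every operation strictly
decreases the node count, so this terminates immediately in practice and is
bounded by the node count in principle).  The re-run is a deliberate safety
margin: a subtle gap in any phase degrades to wasted work, never to a wrong
tree.  `mrf(tree, verify = TRUE)` additionally certifies the fixed point by
brute force.  Empirically the whole computation behaves quadratically in
the leaf count; a 1000-leaf tree reduces in seconds.

### Degenerate inputs

A tree whose information content is empty (fewer than four distinct labels,
a star, or duplicates arranged so that no edge resolves anything) reduces to
the **empty tree**, written `";"`, with `noInformation = TRUE` in the
report.  This is a deliberate choice of the strict fixed point: every leaf
of such a tree is removable without changing the (empty) information
content.  Callers who prefer to keep the original tree can branch on the
flag.

## The reference reducer

`reference_mrf()` is the package's independent oracle: it applies the
*definition* rather than the algorithm, scanning single-leaf prunes,
single-edge contractions and label prunes in a seeded random order and
accepting any operation that leaves a freshly recomputed $I(T)$ unchanged.
It shares no code path with `mrf()` beyond the elementary edit operations,
and the test suite requires the two to agree, under several scan orders, on
hundreds of random trees — this is the uniqueness property made executable.

## Restriction to a singly-labeled tree

`restrict_to_unique_labels()` deletes every leaf whose label still occurs
twice in the MRF and re-contracts edges the deletions left uninformative.
Unlike step 1 this *can* lose quartets — irreducibly multi-labeled MRFs
exist (`search_irreducible()` finds them), and for those no singly-labeled
tree has the same information content — but it never invents a topology
that conflicts with the MRF's.  `reduce_two_step()` runs both steps and
reports taxon loss after each, measured on distinct labels (taxa), not leaf
copies.

## The simulator and what it does (not) emulate

`random_multree(n_labels, n_extra, seed)` grows a random binary tree by
sequential leaf attachment and then inserts `n_extra` duplicate leaves, each
at a uniformly random label and edge.  `random_corpus()` draws 8–24 distinct
labels per tree and Binomial(n, 0.25) duplicate insertions.  These defaults
are the package's own realism choice: they produce the structural
phenomenon that matters for reduction — duplicate labels scattered across
the tree at a moderate density, as in small gene-family clusters — while
avoiding the near-degenerate strata (4–7 labels with heavy duplication)
where most trees carry no information at all.  The simulator does **not**
model duplication/loss processes, rate variation, or inference error;
passing tests on simulated corpora therefore demonstrates the correctness
and accounting of the reduction, not any biological claim about real gene
families.  On such corpora the naive baseline (drop all MUL-taxa up front)
loses at least as many taxa as the two-step reduction on every tree; the
per-tree guarantee holds whenever every once-occurring label takes part in
some quartet, which the corpus defaults make overwhelmingly likely, and the
corpus summary verifies it tree by tree.

## Numerical and representational choices

* All label ordering uses byte (`radix`) order, so canonical quartet strings
  and canonical forms are locale-independent.
* Quartets are canonical strings `"a,b|c,d"` (sides sorted internally,
  smaller side first); sets of them are plain character vectors, which keeps
  the oracles transparent.
* `canonical_form()` roots at the centroid (or the midpoint of the centroid
  edge) and sorts subtree signatures — an AHU-style code extended to label
  multisets; node identity is never serialized.
* Newick parsing is delegated to `ape::read.tree()`, with single-quoted
  labels shielded behind placeholders (ape does not honor Newick quoting)
  and degree-2 roots and singleton chains normalized away on input.  Branch
  lengths and internal node names are read and discarded: the method is
  purely topological.
* Trees with 0, 1 or 2 nodes are first-class values (the empty tree is a
  legitimate MRF), which is why emission is a small dedicated writer rather
  than a round trip through `phylo`.

## Known limitations

* Rooted semantics (triplets instead of quartets) are out of scope; rooted
  inputs are unrooted on entry.
* `information_content()` and the brute-force tools materialize $O(m^4)$
  quartets and guard against large label sets; the production pipeline has
  no such limit.
* Support values and branch lengths are ignored, and polytomies are left
  as-is (never refined).
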