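# mulred — conflict-free information and reduction of multi-labeled trees

Phylogenetic trees in which two or more leaves carry the same taxon label —
**MUL-trees** — are everywhere: gene-family trees with paralogs,
biogeographic cladograms labeled by areas, co-speciation trees labeled by
hosts.  Such a tree can assert two incompatible topologies for the same four
taxa, but it usually also carries a large amount of perfectly consistent
signal.  `mulred` is for anyone who wants that signal and nothing else:
supertree and supermatrix pipelines that need singly-labeled inputs, tree
databases that want to deduplicate and compare gene trees, or analyses of
how much of a MUL-tree's content survives its duplications.

## The model

For an edge $(u,v)$, the label set $M$ splits into $M_u^{uv}$ (labels only
on the $u$ side), $M_v^{uv}$ (only on the $v$ side) and $C^{uv}$ (labels on
both sides).  The edge resolves the quartet $ab|cd$ when $a,b \in M_u^{uv}$
and $c,d \in M_v^{uv}$, and the **information content**

$$I(T) \;=\; \bigcup_{(u,v) \in E(T)} \Delta(u,v), \qquad
\Delta(u,v) = \{\, ab|cd : a,b \in M_u^{uv},\; c,d \in M_v^{uv} \,\}$$

is provably conflict-free: no four-label set appears with two topologies.
A leaf or internal edge whose removal keeps $I(T)$ unchanged is redundant;
removing redundancies exhaustively yields the **maximally reduced form
(MRF)**, which is unique up to isomorphism — two MUL-trees have the same
conflict-free content exactly when their MRFs coincide.  `mrf()` computes
the MRF in $O(n^2)$ from per-edge partition cardinalities, never
materializing $I(T)$; a second step, `restrict_to_unique_labels()`, drops
the labels that are still duplicated in the MRF and returns a singly-labeled
tree, losing some quartets but never inventing one.

## A worked example

The package ships a small MUL-tree in which `b` and `c` occur twice:

```r
library(mulred)
fx <- example_multree()
fx
#> MUL-tree: 8 leaves, 6 distinct labels, 4 internal nodes
#>   multiply-occurring: b(2), c(2)
#>   ((((b,d),c,e),b,c),a,f);
```

Its conflict-free content is six quartets, all separating `{a,f}` from the
rest — the duplicated `b` and `c` sit on both sides of the central edges and
contribute nothing but conflict (for instance `{b,c,d,e}` is displayed both
as `bc|de` and `bd|ce`; see `conflicting_label_sets(fx)`):

```r
information_content(fx)
#> [1] "a,f|b,c" "a,f|b,d" "a,f|b,e" "a,f|c,d" "a,f|c,e" "a,f|d,e"

mrf(fx)
#> maximally reduced form
#> MUL-tree: 6 leaves, 6 distinct labels, 2 internal nodes
#>   ((b,c,e,d),a,f);
#>   contractions: 1 uninformative, 1 subsumed; 0 subtrees deleted
#>   leaves pruned: 0 no-quartet, 2 sibling, 0 spanning
#>   taxon loss: 0.00% (step 1)
```

The MRF keeps all six taxa, is singly labeled, and its single internal edge
resolves exactly the six quartets above — the tree got smaller, the
information did not.  A case where taxa genuinely carry no signal:

```r
reduce_two_step(parse_newick("((a,b,L),c,d,(e,f,L));")[[1]])
#> two-step reduction
#>   MRF: ((a,b),(e,f),c,d);
#>   singly-labeled: ((a,b),(e,f),c,d);
#>   contractions: 0 uninformative, 0 subsumed; 0 subtrees deleted
#>   leaves pruned: 2 no-quartet, 0 sibling, 0 spanning
#>   taxon loss: 14.29% (step 1), 14.29% (after step 2)
```

Here `L` straddles every internal edge, appears in no quartet, and both of
its copies are pruned as a unit (pruning only one would *create* quartets —
the reason taxon-level pruning is an elementary operation here).

## Command line

```sh
exec/mulred reduce IN.nwk -o MRF.nwk [--singly SINGLY.nwk] [--report R.json]
exec/mulred simulate --labels 12 --dups 4 --seed 7 -n 100 -o CORPUS.nwk
exec/mulred stats CORPUS.nwk -o STATS.json --tsv STATS.tsv
```

`reduce` writes one MRF per input tree (a tree with no information becomes
the empty statement `;`); `stats` runs the two-step reduction over a corpus
and reports category fractions and taxon-loss percentages.

## Further reading

`vignettes/mulred-methods.Rmd` documents the model, the three-phase
algorithm, the degenerate cases, and what the simulator does and does not
emulate.
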