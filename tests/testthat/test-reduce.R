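# the reduction phases, the pipeline, the reference oracle and restriction

test_that("uninformative internal edges are contracted, information kept", {
  fx <- example_multree()
  t1 <- contract_uninformative(fx)
  # the (v,w) edge has far exclusive set {d}: exactly one contraction
  expect_equal(nrow(internal_edges(t1)), nrow(internal_edges(fx)) - 1L)
  expect_setequal(information_content(t1), information_content(fx))
  # singly-labeled trees have no uninformative internal edge
  s <- random_multree(8, 0, seed = 3)
  expect_true(is_isomorphic(contract_uninformative(s), s))
  star <- multree(rbind(c(5, 1), c(5, 2), c(5, 3), c(5, 4)),
                  c("a", "b", "c", "d", NA))
  expect_true(is_isomorphic(contract_uninformative(star), star))
  set.seed(201)
  for (i in 1:25) {
    t <- rand_tree()
    expect_setequal(information_content(contract_uninformative(t)),
                    information_content(t))
  }
})

test_that("edge subsumption decisions from counts match brute-force set relations", {
  set.seed(202)
  checked <- 0L
  for (i in 1:40) {
    t <- contract_uninformative(rand_tree(4:8, 0:5))
    ie <- internal_edges(t)
    if (nrow(ie) < 2L) next
    pc <- partition_counts(t)
    for (a in seq_len(nrow(ie) - 1L)) {
      for (b in (a + 1L):nrow(ie)) {
        if (!is_informative(t, ie[a, ]) || !is_informative(t, ie[b, ])) next
        da <- edge_quartets(t, ie[a, ])
        db <- edge_quartets(t, ie[b, ])
        truth <- if (setequal(da, db)) "equal"
        else if (all(da %in% db)) "innerSubset"
        else if (all(db %in% da)) "outerSubset"
        else "incomparable"
        expect_equal(edge_subsumption(t, pc, ie[a, ], ie[b, ]), truth)
        checked <- checked + 1L
      }
    }
    expect_equal(edge_subsumption(t, pc, ie[1, ], ie[1, ]), "equal")
  }
  expect_gt(checked, 50L)
  # stale counts are refused
  t <- example_multree()
  pc <- partition_counts(t)
  t2 <- contract_uninformative(t)
  ie <- internal_edges(t2)
  expect_error(edge_subsumption(t2, pc, ie[1, ], ie[2, ]), "stale")
})

test_that("subsumed-edge contraction reaches a pairwise-incomparable state", {
  fx <- contract_uninformative(example_multree())
  t2 <- contract_subsumed(fx)
  expect_equal(nrow(internal_edges(t2)), 1L)
  expect_setequal(information_content(t2), information_content(fx))
  # singly-labeled trees with all edges informative are untouched
  s <- random_multree(9, 0, seed = 4)
  expect_true(is_isomorphic(contract_subsumed(s), s))
  set.seed(203)
  for (i in 1:25) {
    t <- contract_uninformative(rand_tree())
    r <- contract_subsumed(t)
    expect_setequal(information_content(r), information_content(t))
    pc <- partition_counts(r)
    ie <- internal_edges(r)
    if (nrow(ie) < 2L) next
    for (a in seq_len(nrow(ie) - 1L)) for (b in (a + 1L):nrow(ie)) {
      if (!is_informative(r, ie[a, ]) || !is_informative(r, ie[b, ])) next
      expect_equal(edge_subsumption(r, pc, ie[a, ], ie[b, ]), "incomparable")
    }
  }
})

test_that("a subtree hanging between equal-content edges is deleted whole", {
  # path (a,b,x) - v - (c,d,x) with a lone x hanging off the middle node:
  # both path edges resolve exactly {ab|cd}, so the branch at v is deleted
  # outright and the path collapses to a single edge
  t <- parse_newick("((a,b,x),x,(c,d,x));")[[1]]
  r <- mrf(t)
  expect_setequal(information_content(r$tree), information_content(t))
  expect_equal(information_content(t), "a,b|c,d")
  expect_gte(r$report$subtreesDeleted, 1L)
  expect_false("x" %in% distinct_labels(r$tree))
  expect_true(is_isomorphic(r$tree, parse_newick("((a,b),(c,d));")[[1]]))
})

test_that("labels outside every quartet are pruned wholesale", {
  # L sits in C of every internal edge: pruning either single copy would
  # create quartets, pruning the label preserves information exactly
  t <- parse_newick("((a,b,L),c,d,(e,f,L));")[[1]]
  ic <- information_content(t)
  p <- prune_uninvolved_labels(t)
  expect_false("L" %in% distinct_labels(p))
  expect_setequal(information_content(p), ic)
  # a tree with empty information content loses everything
  star <- parse_newick("(a,b,c,d);")[[1]]
  expect_equal(n_nodes(prune_uninvolved_labels(star)), 0L)
})

test_that("sibling duplicates collapse to one copy per pendant node", {
  t <- parse_newick("((a,a,a,b),(c,d));")[[1]]
  d <- dedupe_sibling_leaves(t)
  expect_equal(label_multiplicity(d)[["a"]], 1L)
  expect_equal(n_leaves(d), 4L)
  s <- random_multree(7, 0, seed = 6)
  expect_true(is_isomorphic(dedupe_sibling_leaves(s), s))
  set.seed(204)
  for (i in 1:20) {
    t <- rand_tree()
    expect_setequal(information_content(dedupe_sibling_leaves(t)),
                    information_content(t))
  }
})

test_that("spanning-subtree pruning drops interior copies and is idempotent", {
  # label x at three pendant nodes along a caterpillar: the middle copy is
  # interior to the spanning subtree (pendant degree 3 there) and goes; the
  # end copies, at spanning degree 2, stay
  t <- parse_newick("((a,x),b,x,(c,x));")[[1]]
  t <- dedupe_sibling_leaves(t)
  p <- prune_spanning_redundant(t)
  expect_equal(label_multiplicity(p)[["x"]], 2L)
  expect_setequal(information_content(p), information_content(t))
  # two copies span a path: both ends kept
  t2 <- parse_newick("((a,x),(b,c),(d,x));")[[1]]
  expect_equal(label_multiplicity(prune_spanning_redundant(t2))[["x"]], 2L)
  set.seed(205)
  for (i in 1:20) {
    t <- dedupe_sibling_leaves(rand_tree())
    p1 <- prune_spanning_redundant(t)
    expect_true(is_isomorphic(prune_spanning_redundant(p1), p1))
    expect_setequal(information_content(p1), information_content(t))
  }
})

test_that("the worked example reduces to the six-leaf singly-labeled tree", {
  fx <- example_multree()
  r <- mrf(fx, verify = TRUE)
  m <- r$tree
  expect_equal(n_leaves(m), 6L)
  expect_true(all(label_multiplicity(m) == 1L))
  expect_equal(nrow(internal_edges(m)), 1L)
  p <- edge_partition(m, internal_edges(m)[1, ])
  expect_true(setequal(p$mU, c("a", "f")) || setequal(p$mV, c("a", "f")))
  expect_length(information_content(m), 6L)
  expect_setequal(information_content(m), information_content(fx))
  expect_false(r$report$noInformation)
  # the informal contraction narrative: contracting (v,w) then (u,v)
  # changes nothing about the information content
  c1 <- contract_edge(fx, c(3, 4))
  c2 <- contract_edge(c1, c(2, 3))
  expect_setequal(information_content(c2), information_content(fx))
})

test_that("trees without information reduce to the empty tree", {
  star <- parse_newick("(a,b,c,d,e);")[[1]]
  r <- mrf(star)
  expect_equal(n_nodes(r$tree), 0L)
  expect_true(r$report$noInformation)
  expect_equal(write_newick(r$tree), ";")
  # fewer than four distinct labels
  r2 <- mrf(parse_newick("((a,b),(a,c));")[[1]])
  expect_true(r2$report$noInformation)
})

test_that("reduction reports serialize with their accounting fields", {
  r <- mrf(example_multree())
  js <- jsonlite::fromJSON(report_json(r$report))
  expect_named(js, c("phase1Contractions", "phase2Contractions",
                     "subtreesDeleted", "leavesPruned", "taxaLostStep1",
                     "taxaLostStep2", "noInformation"))
  expect_equal(js$phase1Contractions, 1L)
  expect_equal(js$leavesPruned$pendantDedupe, 2L)
  expect_equal(js$taxaLostStep1, 0)
})

test_that("the pipeline agrees with the brute-force reference reducer", {
  set.seed(206)
  for (i in 1:40) {
    t <- rand_tree(4:7, 0:4)
    if (n_leaves(t) > 11) next
    m <- mrf(t)$tree
    expect_true(is_isomorphic(m, reference_mrf(t, seed = i)))
  }
  expect_error(reference_mrf(random_multree(20, 0, seed = 1)), "max_leaves")
})

test_that("restriction to unique labels is conservative", {
  fx_mrf <- mrf(example_multree())$tree
  expect_true(is_isomorphic(restrict_to_unique_labels(fx_mrf), fx_mrf))
  # an MRF whose every label is duplicated restricts to nothing
  hit <- parse_newick("((a,a),(b,b),(c,c),(d,d));")[[1]]
  expect_equal(n_nodes(restrict_to_unique_labels(mrf(hit)$tree)), 0L)
  set.seed(207)
  for (i in 1:25) {
    m <- mrf(rand_tree(4:8, 0:5))$tree
    s <- restrict_to_unique_labels(m)
    expect_true(n_nodes(s) == 0L || all(label_multiplicity(s) == 1L))
    im <- information_content(m); is_ <- information_content(s)
    sup_m <- mulred:::.quartet_support(im)
    sup_s <- mulred:::.quartet_support(is_)
    shared <- intersect(sup_m, sup_s)
    # no topology on surviving labels conflicts with the MRF's
    expect_equal(im[match(shared, sup_m)], is_[match(shared, sup_s)])
  }
})

test_that("two-step reduction fills the complete loss accounting", {
  ts <- reduce_two_step(example_multree())
  expect_equal(ts$report$taxaLostStep1, 0)
  expect_equal(ts$report$taxaLostStep2, 0)
  expect_true(is_isomorphic(ts$singly, ts$mrf))
  hit <- parse_newick("((a,a),(b,b),(c,c),(d,d));")[[1]]
  ts2 <- reduce_two_step(hit)
  expect_equal(ts2$report$taxaLostStep2, 100)
})
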