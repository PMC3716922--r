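# data model, Newick I/O, edit operations, partitions, canonical form

test_that("parsing handles duplicate labels, rooted inputs and singletons", {
  t1 <- parse_newick("((a,f),(b,c));")[[1]]
  expect_equal(n_leaves(t1), 4L)
  expect_equal(distinct_labels(t1), c("a", "b", "c", "f"))

  t2 <- parse_newick("((a,b),(a,b));")[[1]]
  expect_equal(n_leaves(t2), 4L)
  expect_equal(unname(label_multiplicity(t2)), c(2L, 2L))

  # singleton chain collapses to the two-leaf tree a-b
  t3 <- parse_newick("((a,(b)));")[[1]]
  expect_equal(n_nodes(t3), 2L)
  expect_equal(sort(t3$label), c("a", "b"))

  # several trees, one per line
  ts <- parse_newick("((a,f),(b,c));\n((a,b),(a,b));")
  expect_length(ts, 2L)

  expect_error(parse_newick("((a,b),(c,d)"), "parse error in tree 1")
  expect_error(parse_newick("((a,b),(c,d));\n((x,y);"),
               "parse error in tree 2 \\(line 2\\)")
  expect_error(parse_newick("   "), "no Newick statement")
})

test_that("normalization unroots, suppresses degree-2 nodes and is idempotent", {
  # rooted binary input -> unrooted quartet tree with one internal edge
  q <- parse_newick("((a,b),(c,d));")[[1]]
  expect_equal(n_nodes(q), 6L)
  expect_equal(nrow(internal_edges(q)), 1L)

  raw <- multree(rbind(c(5, 1), c(5, 6), c(6, 7), c(7, 2), c(7, 3)),
                 c("a", "b", "c", NA, NA, NA, NA), validate = FALSE)
  nm <- normalize_multree(raw)   # chain a - x - y - (b,c): x,y suppressed
  expect_equal(n_nodes(nm), 4L)
  expect_silent(validate_multree(nm))
  expect_true(is_isomorphic(normalize_multree(nm), nm))
})

test_that("newick round trip preserves the canonical form", {
  expect_equal(write_newick(multree_empty()), ";")
  one <- parse_newick("abc;")[[1]]
  expect_equal(write_newick(one), "abc;")
  two <- parse_newick("(a,b);")[[1]]
  expect_equal(canonical_form(parse_newick(write_newick(two))[[1]]),
               canonical_form(two))
  fx <- example_multree()
  expect_equal(canonical_form(parse_newick(write_newick(fx))[[1]]),
               canonical_form(fx))
  set.seed(421)
  for (i in 1:25) {
    t <- rand_tree()
    expect_equal(canonical_form(parse_newick(write_newick(t))[[1]]),
                 canonical_form(t))
  }
  # quoting of awkward labels survives
  odd <- multree(rbind(c(4, 1), c(4, 2), c(4, 3)),
                 c("sp one", "x(y)", "a'b", NA))
  expect_equal(canonical_form(parse_newick(write_newick(odd))[[1]]),
               canonical_form(odd))
})

test_that("label multiplicities count leaves per taxon", {
  fx <- example_multree()
  expect_equal(distinct_labels(fx), c("a", "b", "c", "d", "e", "f"))
  mul <- label_multiplicity(fx)
  expect_equal(mul[["b"]], 2L)
  expect_equal(mul[["c"]], 2L)
  expect_equal(sum(mul), n_leaves(fx))

  t <- parse_newick("((a,a),(a,b));")[[1]]
  expect_equal(label_multiplicity(t), c(a = 3L, b = 1L))
  expect_equal(unname(label_multiplicity(random_multree(6, 0, seed = 1))),
               rep(1L, 6))
})

test_that("pruning a leaf renormalizes and can empty the tree", {
  t <- parse_newick("((a,b),(b,c));")[[1]]
  b1 <- which(t$label == "b")[1]
  p <- prune_leaf(t, b1)
  expect_equal(n_leaves(p), 3L)
  expect_equal(nrow(internal_edges(p)), 0L)   # 3-leaf star

  q <- parse_newick("((a,b),(c,d));")[[1]]
  expect_equal(n_leaves(prune_leaf(q, which(q$label == "a"))), 3L)

  expect_error(prune_leaf(q, internal_edges(q)[1, 1]), "leaf")

  # pruning every leaf one by one never violates an invariant
  set.seed(7)
  for (i in 1:10) {
    t <- rand_tree(4:6, 0:3)
    while (n_nodes(t) > 0L) {
      t <- prune_leaf(t, leaves(t)[1])
      expect_silent(validate_multree(t))
    }
    expect_equal(n_nodes(t), 0L)
  }
})

test_that("contracting an internal edge merges endpoints, keeps leaves", {
  q <- parse_newick("((a,b),(c,d));")[[1]]
  s <- contract_edge(q, internal_edges(q)[1, ])
  expect_equal(n_nodes(s), 5L)          # 4-leaf star
  expect_equal(nrow(internal_edges(s)), 0L)
  expect_error(contract_edge(q, c(which(q$label == "a"),
                                  internal_edges(q)[1, 1])), "pendant")
  set.seed(8)
  for (i in 1:10) {
    t <- rand_tree()
    ie <- internal_edges(t)
    if (!nrow(ie)) next
    t2 <- contract_edge(t, ie[sample.int(nrow(ie), 1), ])
    expect_equal(n_leaves(t2), n_leaves(t))
    expect_equal(n_nodes(t2), n_nodes(t) - 1L)
  }
})

test_that("edge partitions split the label set into mU / mV / common", {
  fx <- example_multree()
  p <- edge_partition(fx, c(2, 3))      # the (u,v) edge
  expect_equal(p$mU, c("a", "f"))
  expect_equal(p$mV, c("d", "e"))
  expect_equal(p$common, c("b", "c"))
  # orientation symmetry
  p2 <- edge_partition(fx, c(3, 2))
  expect_equal(p2$mU, p$mV)
  expect_equal(p2$mV, p$mU)

  # pendant edge to a uniquely-labeled leaf
  pa <- edge_partition(fx, c(1, which(fx$label == "a")))
  expect_equal(pa$mV, "a")

  # partition property on random trees; singly-labeled => common empty
  set.seed(33)
  for (i in 1:20) {
    t <- rand_tree()
    labs <- distinct_labels(t)
    for (k in seq_len(nrow(t$edge))) {
      p <- edge_partition(t, t$edge[k, ])
      expect_equal(sort(c(p$mU, p$mV, p$common)), labs)
      expect_equal(length(p$mU) + length(p$mV) + length(p$common),
                   length(labs))
    }
  }
  s <- random_multree(7, 0, seed = 2)
  for (k in seq_len(nrow(s$edge))) {
    expect_length(edge_partition(s, s$edge[k, ])$common, 0L)
  }
})

test_that("partition counts agree with per-edge recomputation", {
  set.seed(55)
  for (i in 1:12) {
    t <- rand_tree(4:10, 0:8)
    if (n_leaves(t) > 25) next
    pc <- partition_counts(t)
    m <- length(distinct_labels(t))
    tab <- pc$table
    for (r in seq_len(nrow(tab))) {
      p <- edge_partition(t, c(tab$u[r], tab$v[r]))
      expect_equal(tab$mExclusive[r], length(p$mU))
      expect_equal(tab$nDistinct[r], length(p$mU) + length(p$common))
    }
    # |M_u| = |M| - n_v for every directed edge
    key <- paste(tab$u, tab$v)
    rev <- match(paste(tab$v, tab$u), key)
    expect_equal(tab$mExclusive, m - tab$nDistinct[rev])
  }
})

test_that("canonical form identifies isomorphic trees and separates others", {
  a <- parse_newick("((a,b),(c,d));")[[1]]
  b <- parse_newick("((d,c),(b,a));")[[1]]
  expect_true(is_isomorphic(a, b))
  expect_false(is_isomorphic(a, parse_newick("((a,c),(b,d));")[[1]]))
  set.seed(77)
  for (i in 1:60) {
    t <- rand_tree()
    expect_true(is_isomorphic(t, shuffle_multree(t)))
  }
  # multiplicities matter
  expect_false(is_isomorphic(parse_newick("((a,b),(a,c));")[[1]],
                             parse_newick("((a,b),(b,c));")[[1]]))
})
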