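#' Simulate a random MUL-tree
#'
#' Grows a random binary tree on `n_labels` uniquely-labeled leaves by
#' seeded sequential attachment (each new leaf subdivides a uniformly chosen
#' edge), then performs `n_extra` duplicate-leaf insertions: each picks a
#' uniformly random existing label and a uniformly random edge, subdivides
#' the edge and attaches a new leaf carrying that label.  This emulates the
#' structural phenomenon that matters for reduction — duplicate labels
#' scattered across the tree — not any particular biological duplication
#' process.
#'
#' The same configuration and seed always yield the bitwise-identical tree
#' (and Newick string).
#'
#' @param n_labels number of distinct labels (at least 4); labels are
#'   `t1 ... tN`.
#' @param n_extra number of duplicate-leaf insertions (leaf count becomes
#'   `n_labels + n_extra`).
#' @param seed integer seed; `NULL` draws from the current RNG stream.
#' @return a `multree`.
#' @examples
#' random_multree(6, 3, seed = 1)
#' @export
random_multree <- function(n_labels, n_extra = 0L, seed = NULL) {
  n_labels <- as.integer(n_labels); n_extra <- as.integer(n_extra)
  if (n_labels < 4L) stop("'n_labels' must be at least 4")
  if (n_extra < 0L) stop("'n_extra' must be non-negative")
  .with_seed(seed, {
    labs <- paste0("t", seq_len(n_labels))
    # start from the 3-leaf star: center node 4
    label <- c(labs[1:3], NA_character_)
    edge <- rbind(c(4L, 1L), c(4L, 2L), c(4L, 3L))
    attach_leaf <- function(lab) {
      k <- sample.int(nrow(edge), 1L)
      mid <- length(label) + 1L
      lfn <- length(label) + 2L
      label <<- c(label, NA_character_, lab)
      edge <<- rbind(edge[-k, , drop = FALSE],
                     c(edge[k, 1L], mid), c(mid, edge[k, 2L]), c(mid, lfn))
    }
    for (i in seq_len(n_labels - 3L)) attach_leaf(labs[3L + i])
    for (i in seq_len(n_extra)) attach_leaf(labs[sample.int(n_labels, 1L)])
    multree(edge, label)
  })
}

#' The worked conflict example
#'
#' A small MUL-tree on labels `a ... f` with `b` and `c` doubled, built
#' around the internal path `t - u - v - w` (node ids 1-4): `t` bears leaves
#' `a, f`; `u` bears the first copies of `b, c`; `v` bears the second `c`
#' and `e`; `w` bears the second `b` and `d`.  It is the package's running
#' example: the edge `(u, v) = (2, 3)` partitions the labels into
#' `{a,f} / {d,e} / {b,c}`; edge `(t, u) = (1, 2)` resolves `af|bc`; the
#' four-label set `{b,c,d,e}` is displayed with two conflicting topologies;
#' and the maximally reduced form is the singly-labeled six-leaf tree with a
#' single internal edge separating `{a,f}` from `{b,c,d,e}`.
#'
#' @return a `multree` with attribute `path_nodes` naming the internal path.
#' @examples
#' fx <- example_multree()
#' edge_partition(fx, c(2, 3))
#' mrf(fx)$tree
#' @export
example_multree <- function() {
  label <- c(rep(NA_character_, 4L),
             "a", "f", "b", "c", "c", "e", "b", "d")
  edge <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L),
                c(1L, 5L), c(1L, 6L),
                c(2L, 7L), c(2L, 8L),
                c(3L, 9L), c(3L, 10L),
                c(4L, 11L), c(4L, 12L))
  out <- multree(edge, label)
  attr(out, "path_nodes") <- c(t = 1L, u = 2L, v = 3L, w = 4L)
  out
}

#' Search for an irreducibly multi-labeled tree
#'
#' Scans seeded random MUL-trees until one is found whose maximally reduced
#' form still carries a label of multiplicity two or more.  Such trees
#' witness that no singly-labeled tree can have exactly their information
#' content: restricting their MRF to once-occurring labels necessarily
#' loses quartets.
#'
#' @param n_labels,n_extra generator configuration per candidate (keep the
#'   implied leaf count small; every candidate is fully reduced).
#' @param seeds integer vector of seeds to try, in order.
#' @return `NULL` if the search is exhausted, else a list with the generating
#'   `seed`, the `tree`, and its multi-labeled `mrf`.
#' @export
search_irreducible <- function(n_labels = 6L, n_extra = 4L, seeds = 0:999) {
  for (s in seeds) {
    t <- random_multree(n_labels, n_extra, seed = s)
    m <- mrf(t)$tree
    if (n_nodes(m) > 0L && any(label_multiplicity(m) >= 2L)) {
      return(list(seed = s, tree = t, mrf = m))
    }
  }
  NULL
}

#' Simulate a corpus of MUL-trees
#'
#' Each tree draws its number of distinct labels uniformly from
#' `labels_range` and its number of duplicate-leaf insertions from
#' Binomial(nLabels, `dup_rate`).  The defaults (8-24 labels, 25%
#' duplication) emulate small gene-family clusters with a moderate density
#' of scattered duplicates.
#'
#' @param n_trees corpus size.
#' @param seed integer seed for the whole corpus.
#' @param labels_range length-2 integer range for distinct label counts.
#' @param dup_rate per-label duplication probability.
#' @return a list of `multree` objects.
#' @export
random_corpus <- function(n_trees, seed = 1L, labels_range = c(8L, 24L),
                          dup_rate = 0.25) {
  stopifnot(n_trees >= 1L, length(labels_range) == 2L,
            labels_range[1L] >= 4L)
  .with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      nl <- sample(labels_range[1L]:labels_range[2L], 1L)
      ne <- stats::rbinom(1L, nl, dup_rate)
      random_multree(nl, ne)
    })
  })
}

#' Corpus-level reduction statistics
#'
#' Runs the two-step reduction on every tree and aggregates the accounting
#' the reduction experiments report: per-tree distinct-label losses after
#' step 1 (the MRF) and step 2 (restriction to once-occurring labels), the
#' naive baseline that drops every MUL-taxon at the outset, and the three
#' outcome categories — trees with essentially no information (empty MRF or
#' a restriction with no internal edge), trees whose MRF is already singly
#' labeled (set A), and trees only the restriction step makes singly labeled
#' (set B).  Taxon loss is measured on distinct labels, not leaf copies.
#'
#' @param trees non-empty list of `multree` objects.
#' @return an object of class `mul_corpus_stats`: a list with the summary
#'   fields (`nTrees`, `fracNoInformation`, `fracSinglyLabeledMRF`,
#'   `fracRestrictedInStep2`, `meanTaxonLossStep1`, `meanTaxonLossStep2`,
#'   `meanNaiveLoss`, all fractions in [0,1] and losses in percent) and a
#'   per-tree data frame `perTree`.
#' @export
corpus_summary <- function(trees) {
  if (inherits(trees, "multree")) trees <- list(trees)
  if (!length(trees)) stop("empty corpus")
  rows <- lapply(seq_along(trees), function(i) {
    t <- trees[[i]]
    mul <- label_multiplicity(t)
    m <- length(mul)
    ts <- reduce_two_step(t)
    e <- ts$singly$edge
    has_internal <- nrow(e) > 0L &&
      any(is.na(ts$singly$label[e[, 1L]]) & is.na(ts$singly$label[e[, 2L]]))
    category <-
      if (n_nodes(ts$mrf) == 0L || !has_internal) "noInformation"
      else if (all(label_multiplicity(ts$mrf) == 1L)) "A"
      else "B"
    data.frame(
      tree = i,
      leaves = n_leaves(t),
      distinctLabels = m,
      mrfLeaves = n_leaves(ts$mrf),
      restrictedLeaves = n_leaves(ts$singly),
      lossStep1 = ts$report$taxaLostStep1,
      lossStep2 = ts$report$taxaLostStep2,
      naiveLoss = if (m) 100 * sum(mul >= 2L) / m else 0,
      category = category,
      stringsAsFactors = FALSE)
  })
  per_tree <- do.call(rbind, rows)
  structure(list(
    nTrees = length(trees),
    fracNoInformation = mean(per_tree$category == "noInformation"),
    fracSinglyLabeledMRF = mean(per_tree$category == "A"),
    fracRestrictedInStep2 = mean(per_tree$category == "B"),
    meanTaxonLossStep1 = mean(per_tree$lossStep1),
    meanTaxonLossStep2 = mean(per_tree$lossStep2),
    meanNaiveLoss = mean(per_tree$naiveLoss),
    perTree = per_tree), class = "mul_corpus_stats")
}

#' @export
print.mul_corpus_stats <- function(x, ...) {
  cat(sprintf("corpus of %d trees\n", x$nTrees))
  cat(sprintf("  no information: %.1f%%   singly-labeled MRF: %.1f%%   restricted in step 2: %.1f%%\n",
              100 * x$fracNoInformation, 100 * x$fracSinglyLabeledMRF,
              100 * x$fracRestrictedInStep2))
  cat(sprintf("  mean taxon loss: %.2f%% (step 1), %.2f%% (after step 2), %.2f%% (naive)\n",
              x$meanTaxonLossStep1, x$meanTaxonLossStep2, x$meanNaiveLoss))
  invisible(x)
}

#' Serialize corpus statistics
#'
#' `corpus_stats_json()` emits the summary (without the per-tree table) as
#' JSON; `write_corpus_stats()` writes the JSON and, optionally, the
#' per-tree table as TSV.
#'
#' @param stats a `mul_corpus_stats`.
#' @param json,tsv output paths (`tsv = NULL` skips the table).
#' @return the JSON string / the `json` path, invisibly.
#' @export
corpus_stats_json <- function(stats) {
  x <- unclass(stats)
  x$perTree <- NULL
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @rdname corpus_stats_json
#' @export
write_corpus_stats <- function(stats, json, tsv = NULL) {
  writeLines(corpus_stats_json(stats), json)
  if (!is.null(tsv)) {
    utils::write.table(stats$perTree, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(json)
}
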