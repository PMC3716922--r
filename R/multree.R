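#' mulred: reduction of multi-labeled phylogenetic trees
#'
#' Tools for working with MUL-trees (phylogenetic trees in which two or more
#' leaves may carry the same taxon label), for computing their conflict-free
#' quartet information content, and for reducing them to the unique maximally
#' reduced form (MRF) that preserves that information content.  A restriction
#' step yields a singly-labeled tree suitable for supertree and supermatrix
#' methods, and a seeded simulator plus corpus summaries support experiments
#' on synthetic gene-family trees.
#'
#' @section Main entry points:
#' \itemize{
#'   \item [parse_newick()], [write_newick()] — Newick I/O with duplicate
#'     leaf labels.
#'   \item [information_content()], [edge_quartets()] — quartet semantics.
#'   \item [mrf()], [restrict_to_unique_labels()], [reduce_two_step()] —
#'     the reduction pipeline.
#'   \item [random_multree()], [random_corpus()], [corpus_summary()] —
#'     simulation and corpus statistics.
#' }
#'
#' @keywords internal
"_PACKAGE"

#' Construct a MUL-tree
#'
#' A MUL-tree is an unrooted tree whose leaves carry taxon labels; unlike an
#' ordinary phylogeny, several leaves may share the same label.  Internally a
#' tree is a pair: an integer edge matrix over node ids `1..n`, and a
#' character vector of per-node labels in which internal nodes are `NA`.
#'
#' Node identity is internal bookkeeping only: two trees are considered equal
#' when they are isomorphic as leaf-label-multiset-preserving unrooted trees
#' (see [is_isomorphic()]).
#'
#' @param edge two-column integer matrix of undirected edges (node id pairs).
#' @param label character vector, one entry per node; `NA` marks an internal
#'   node, any non-`NA` entry makes the node a leaf with that taxon label.
#' @param validate check the MUL-tree invariants (connected, acyclic, leaves
#'   of degree 1, internal nodes of degree at least 3).
#' @return an object of class `multree`.
#' @examples
#' # the unrooted quartet tree ab|cd
#' t <- multree(rbind(c(5, 6), c(5, 1), c(5, 2), c(6, 3), c(6, 4)),
#'              c("a", "b", "c", "d", NA, NA))
#' t
#' @export
multree <- function(edge, label, validate = TRUE) {
  if (is.null(edge) || length(edge) == 0L) {
    edge <- matrix(integer(0), ncol = 2L)
  }
  edge <- as.matrix(edge)
  storage.mode(edge) <- "integer"
  if (ncol(edge) != 2L) stop("'edge' must have two columns")
  x <- structure(list(edge = edge, label = as.character(label)),
                 class = "multree")
  if (validate) validate_multree(x)
  x
}

#' The empty MUL-tree
#'
#' The empty tree (no nodes at all) is the documented result of reducing a
#' tree with empty information content; see [mrf()].
#' @return an empty `multree`.
#' @export
multree_empty <- function() {
  multree(matrix(integer(0), ncol = 2L), character(0), validate = FALSE)
}

#' @export
print.multree <- function(x, ...) {
  n <- n_nodes(x)
  if (n == 0L) {
    cat("MUL-tree: empty\n")
    return(invisible(x))
  }
  lv <- leaves(x)
  m <- length(distinct_labels(x))
  cat(sprintf("MUL-tree: %d leaves, %d distinct labels, %d internal nodes\n",
              length(lv), m, n - length(lv)))
  mul <- label_multiplicity(x)
  mul <- mul[mul >= 2L]
  if (length(mul)) {
    cat("  multiply-occurring:",
        paste(sprintf("%s(%d)", names(mul), mul), collapse = ", "), "\n")
  }
  cat(" ", write_newick(x), "\n")
  invisible(x)
}

#' Validate the invariants of a MUL-tree
#'
#' Checks connectivity, acyclicity (edge count `n - 1`), leaf degree exactly
#' one and internal degree at least three.  Trees with zero or one node are
#' valid degenerate cases (a one-node tree must be a labeled leaf).
#'
#' @param x a `multree`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_multree <- function(x) {
  stopifnot(inherits(x, "multree"))
  n <- length(x$label)
  e <- x$edge
  if (n == 0L) {
    if (nrow(e) != 0L) stop("empty tree must have no edges")
    return(invisible(x))
  }
  if (nrow(e) != n - 1L) stop("a tree on ", n, " nodes needs ", n - 1L,
                              " edges, found ", nrow(e))
  if (n == 1L) {
    if (is.na(x$label[1L])) stop("a single-node tree must be a labeled leaf")
    return(invisible(x))
  }
  if (any(e < 1L | e > n)) stop("edge endpoint out of range")
  if (any(e[, 1L] == e[, 2L])) stop("self-loop in edge matrix")
  deg <- tabulate(c(e[, 1L], e[, 2L]), n)
  is_lf <- !is.na(x$label)
  if (any(deg[is_lf] != 1L)) stop("every leaf must have degree exactly 1")
  if (any(deg[!is_lf] < 3L)) stop("internal nodes must have degree >= 3")
  if (any(is.na(x$label[deg == 1L]) & n > 1L))
    stop("degree-1 node without a label")
  # connectivity: BFS from node 1
  adj <- .mt_adj(x)
  seen <- logical(n); seen[1L] <- TRUE; front <- 1L
  while (length(front)) {
    nb <- unique(unlist(adj[front], use.names = FALSE))
    front <- nb[!seen[nb]]
    seen[front] <- TRUE
  }
  if (!all(seen)) stop("tree is not connected")
  invisible(x)
}

# adjacency lists (list of integer neighbor vectors, one per node)
.mt_adj <- function(tree) {
  n <- length(tree$label)
  if (n == 0L) return(list())
  e <- tree$edge
  ends <- c(e[, 1L], e[, 2L])
  other <- c(e[, 2L], e[, 1L])
  unname(split(other, factor(ends, levels = seq_len(n))))
}

.mt_degree <- function(tree) {
  tabulate(c(tree$edge[, 1L], tree$edge[, 2L]), length(tree$label))
}

#' Tree size accessors
#'
#' @param tree a `multree`.
#' @return `n_nodes()`: total node count; `n_leaves()`: leaf count;
#'   `leaves()`: integer ids of the leaf nodes.
#' @export
n_nodes <- function(tree) length(tree$label)

#' @rdname n_nodes
#' @export
n_leaves <- function(tree) sum(!is.na(tree$label))

#' @rdname n_nodes
#' @export
leaves <- function(tree) which(!is.na(tree$label))

#' Distinct labels and label multiplicities
#'
#' `distinct_labels()` returns the label set M of the tree; labels returned by
#' `label_multiplicity()` with multiplicity two or more are the MUL-taxa.
#' Multiplicities always sum to the leaf count.
#'
#' @param tree a `multree`.
#' @return a sorted character vector, respectively a named integer vector.
#' @export
distinct_labels <- function(tree) {
  sort(unique(tree$label[!is.na(tree$label)]), method = "radix")
}

#' @rdname distinct_labels
#' @export
label_multiplicity <- function(tree) {
  labs <- distinct_labels(tree)
  tab <- tabulate(match(tree$label, labs), length(labs))
  names(tab) <- labs
  tab
}

#' Normalize a tree into MUL-tree form
#'
#' Suppresses every degree-2 node (merging its two incident edges), removes
#' dangling unlabeled nodes, and renumbers nodes compactly.  A rooted binary
#' Newick's degree-2 root is unrooted by the same rule.  Idempotent: an
#' already-normalized tree comes back isomorphic (indeed identical).
#'
#' @param tree a `multree`, possibly violating the degree invariants.
#' @return a valid, normalized `multree`.
#' @export
normalize_multree <- function(tree) {
  n <- length(tree$label)
  if (n == 0L) return(multree_empty())
  adj <- .mt_adj(tree)
  alive <- rep(TRUE, n)
  is_lf <- !is.na(tree$label)
  queue <- which(!is_lf & lengths(adj) <= 2L)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    if (!alive[v] || is_lf[v]) next
    nb <- adj[[v]]
    d <- length(nb)
    if (d > 2L) next
    alive[v] <- FALSE
    if (d == 1L) {
      u <- nb
      adj[[u]] <- adj[[u]][adj[[u]] != v]
      if (!is_lf[u] && length(adj[[u]]) <= 2L) queue <- c(queue, u)
    } else if (d == 2L) {
      a <- nb[1L]; b <- nb[2L]
      adj[[a]] <- c(adj[[a]][adj[[a]] != v], b)
      adj[[b]] <- c(adj[[b]][adj[[b]] != v], a)
    }
    adj[[v]] <- integer(0)
  }
  keep <- which(alive)
  if (!length(keep)) return(multree_empty())
  idx <- integer(n); idx[keep] <- seq_along(keep)
  ev <- rep.int(seq_len(n), lengths(adj))
  eu <- unlist(adj, use.names = FALSE)
  sel <- ev < eu
  multree(cbind(idx[ev[sel]], idx[eu[sel]], deparse.level = 0),
          tree$label[keep])
}

# induced subgraph on `keep` (must stay connected), then re-normalize
.mt_induced <- function(tree, keep) {
  if (!length(keep)) return(multree_empty())
  keep <- sort(keep)
  n <- length(tree$label)
  idx <- integer(n); idx[keep] <- seq_along(keep)
  e <- tree$edge
  sel <- idx[e[, 1L]] > 0L & idx[e[, 2L]] > 0L
  raw <- multree(cbind(idx[e[sel, 1L]], idx[e[sel, 2L]], deparse.level = 0),
                 tree$label[keep], validate = FALSE)
  normalize_multree(raw)
}

#' Prune a leaf
#'
#' Deletes leaf `leaf` from the tree; if its former neighbor drops to degree
#' two it is suppressed, so the result is again a normalized MUL-tree.  When
#' the removed leaf was the last bearer of its label, the label set shrinks.
#'
#' @param tree a `multree`.
#' @param leaf integer node id of a leaf.
#' @return the pruned `multree` (possibly empty).
#' @export
prune_leaf <- function(tree, leaf) {
  leaf <- as.integer(leaf)
  if (length(leaf) != 1L || leaf < 1L || leaf > n_nodes(tree) ||
      is.na(tree$label[leaf]))
    stop("'leaf' must be the id of a leaf node")
  .mt_induced(tree, setdiff(seq_len(n_nodes(tree)), leaf))
}

# batch leaf removal (all ids must be leaves)
.mt_prune_leaves <- function(tree, ids) {
  if (!length(ids)) return(tree)
  stopifnot(all(!is.na(tree$label[ids])))
  .mt_induced(tree, setdiff(seq_len(n_nodes(tree)), ids))
}

#' Contract an internal edge
#'
#' Deletes internal edge `edge` and identifies its endpoints; the merged node
#' inherits all other incident edges.  Node count decreases by exactly one and
#' the leaf set is unchanged.  Contraction is only defined for internal edges
#' (neither endpoint a leaf).
#'
#' @param tree a `multree`.
#' @param edge length-2 integer vector `c(u, v)` naming an existing internal
#'   edge.
#' @return the contracted `multree`.
#' @export
contract_edge <- function(tree, edge) {
  edge <- as.integer(edge)
  if (length(edge) != 2L) stop("'edge' must be a pair of node ids")
  if (!.mt_has_edge(tree, edge)) stop("no such edge in tree")
  if (any(!is.na(tree$label[edge])))
    stop("cannot contract a pendant edge (an endpoint is a leaf)")
  .mt_contract_batch(tree, matrix(edge, ncol = 2L))
}

.mt_has_edge <- function(tree, edge) {
  e <- tree$edge
  any((e[, 1L] == edge[1L] & e[, 2L] == edge[2L]) |
      (e[, 1L] == edge[2L] & e[, 2L] == edge[1L]))
}

# contract a set of internal edges simultaneously (union-find); partitions of
# surviving edges are unaffected, so batching equals sequential contraction
.mt_contract_batch <- function(tree, edges) {
  if (nrow(edges) == 0L) return(tree)
  n <- length(tree$label)
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1L]); b <- find(edges[k, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  rep_of <- vapply(seq_len(n), find, integer(1))
  e <- cbind(rep_of[tree$edge[, 1L]], rep_of[tree$edge[, 2L]],
             deparse.level = 0)
  e <- e[e[, 1L] != e[, 2L], , drop = FALSE]
  keep <- sort(unique(rep_of))
  idx <- integer(n); idx[keep] <- seq_along(keep)
  multree(cbind(idx[e[, 1L]], idx[e[, 2L]], deparse.level = 0),
          tree$label[keep])
}

# all nodes on the `b` side of edge (a, b), via BFS that never crosses a
.mt_side_nodes <- function(tree, a, b) {
  adj <- .mt_adj(tree)
  n <- length(tree$label)
  seen <- logical(n)
  seen[a] <- TRUE   # block
  seen[b] <- TRUE
  front <- b
  out <- b
  while (length(front)) {
    nb <- unlist(adj[front], use.names = FALSE)
    nb <- unique(nb[!seen[nb]])
    seen[nb] <- TRUE
    out <- c(out, nb)
    front <- nb
  }
  out
}
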