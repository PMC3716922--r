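#' Per-edge label partition
#'
#' Deleting edge `(u, v)` splits the tree into a u-side and a v-side.  The
#' label set M then partitions into `mU` (labels occurring only on the
#' u-side), `mV` (only on the v-side) and `common` (labels with leaves on
#' both sides, the set C of the edge).  These three sets drive everything
#' else: an edge resolves quartets from pairs of `mU` against pairs of `mV`.
#'
#' This function recomputes the partition by direct traversal of the two
#' sides; [partition_counts()] computes all cardinalities at once and is what
#' the reduction pipeline uses.
#'
#' @param tree a normalized `multree`.
#' @param edge length-2 integer vector `c(u, v)`; the edge must exist.
#' @return a list with sorted character vectors `mU`, `mV`, `common`.
#' @examples
#' fx <- example_multree()
#' edge_partition(fx, c(2, 3))   # the (u,v) edge: {a,f} / {d,e} / {b,c}
#' @export
edge_partition <- function(tree, edge) {
  edge <- as.integer(edge)
  if (!.mt_has_edge(tree, edge)) stop("no such edge in tree")
  u <- edge[1L]; v <- edge[2L]
  vside <- .mt_side_nodes(tree, u, v)
  lab_v <- tree$label[vside]
  lab_v <- unique(lab_v[!is.na(lab_v)])
  all_lab <- distinct_labels(tree)
  uside <- setdiff(seq_len(n_nodes(tree)), vside)
  lab_u <- tree$label[uside]
  lab_u <- unique(lab_u[!is.na(lab_u)])
  list(mU = sort(setdiff(lab_u, lab_v), method = "radix"),
       mV = sort(setdiff(lab_v, lab_u), method = "radix"),
       common = sort(intersect(lab_u, lab_v), method = "radix"))
}

# ---- the shared counting engine -------------------------------------------
#
# Root the tree at an internal node and accumulate, bottom-up, the per-label
# leaf counts of every rooted subtree (an m x n integer matrix).  From it,
# for the edge (parent[v], v):
#   n distinct on the child side   = #{l : cnt[l,v] > 0}
#   |M| exclusive to child side    = #{l : cnt[l,v] == tot[l]}
#   |M| exclusive to parent side   = #{l : cnt[l,v] == 0}
# One pass costs O(n * m) time and memory, the budget the whole reduction is
# designed around.
.mt_counts <- function(tree) {
  n <- n_nodes(tree)
  labs <- distinct_labels(tree)
  m <- length(labs)
  if (n == 0L) {
    return(list(n = 0L, m = 0L, labels = labs))
  }
  lab_id <- match(tree$label, labs)
  adj <- .mt_adj(tree)
  root <- which(is.na(tree$label))[1L]
  if (is.na(root)) root <- 1L
  ord <- .mt_preorder(adj, root)
  size <- rep(1L, n)
  cnt <- matrix(0L, nrow = m, ncol = n)
  lf <- which(!is.na(tree$label))
  cnt[cbind(lab_id[lf], lf)] <- 1L
  if (n >= 2L) {
    for (k in n:2) {
      v <- ord$pre[k]
      p <- ord$parent[v]
      cnt[, p] <- cnt[, p] + cnt[, v]
      size[p] <- size[p] + size[v]
    }
  }
  tot <- cnt[, root]
  n_child <- .colSums(cnt > 0L, m, n)
  excl_child <- .colSums(cnt == tot, m, n)   # tot recycles down columns
  excl_par <- .colSums(cnt == 0L, m, n)
  list(n = n, m = m, labels = labs, lab_id = lab_id, adj = adj,
       root = root, parent = ord$parent, pre = ord$pre, pos = ord$pos,
       size = size, cnt = cnt, tot = tot,
       n_child = n_child, n_par = m - excl_child,
       excl_child = excl_child, excl_par = excl_par)
}

# |M_b^{ab}|: labels exclusive to the b side of edge (a, b)
.excl_dir <- function(eng, a, b) {
  if (eng$parent[b] == a) eng$excl_child[b]
  else if (eng$parent[a] == b) eng$excl_par[a]
  else stop("(", a, ",", b, ") is not an edge of the rooted orientation")
}

# n_b^{ab}: distinct labels on the b side of edge (a, b)
.ndist_dir <- function(eng, a, b) {
  if (eng$parent[b] == a) eng$n_child[b]
  else if (eng$parent[a] == b) eng$n_par[a]
  else stop("(", a, ",", b, ") is not an edge of the rooted orientation")
}

# is `node` inside the rooted subtree of `v`? (preorder interval test)
.in_subtree <- function(eng, v, node) {
  pv <- eng$pos[v]
  pn <- eng$pos[node]
  pn >= pv && pn < pv + eng$size[v]
}

#' Partition cardinalities for every directed edge
#'
#' For each edge `(u, v)` and each of its two directions, the number of
#' distinct labels on that side and the number of labels exclusive to that
#' side.  Computed for the whole tree in one bottom-up pass.  These counts
#' are what the reduction algorithm consults: by the cardinality lemmas, the
#' quartet sets of two edges on a common path can be compared from the counts
#' alone (see [edge_subsumption()]).
#'
#' The returned object is tied to the tree it was computed from; consumers
#' such as [edge_subsumption()] refuse stale counts if the tree has been
#' modified since.
#'
#' @param tree a normalized `multree`.
#' @return an object of class `mul_partition_counts`: a data frame with
#'   columns `u`, `v`, `nDistinct` (distinct labels on the u side) and
#'   `mExclusive` (labels exclusive to the u side), two rows per undirected
#'   edge, plus the engine internals as attributes.
#' @export
partition_counts <- function(tree) {
  eng <- .mt_counts(tree)
  n <- eng$n
  if (n <= 1L) {
    df <- data.frame(u = integer(0), v = integer(0),
                     nDistinct = integer(0), mExclusive = integer(0))
  } else {
    child <- setdiff(seq_len(n), eng$root)
    par <- eng$parent[child]
    df <- data.frame(
      u = c(child, par),
      v = c(par, child),
      nDistinct = c(eng$n_child[child], eng$n_par[child]),
      mExclusive = c(eng$excl_child[child], eng$excl_par[child]))
  }
  structure(list(table = df, m = eng$m),
            engine = eng, tree_edge = tree$edge, tree_label = tree$label,
            class = "mul_partition_counts")
}

#' @export
print.mul_partition_counts <- function(x, ...) {
  cat(sprintf("partition counts: %d directed edges, %d labels\n",
              nrow(x$table), x$m))
  print(utils::head(x$table, 10L))
  if (nrow(x$table) > 10L) cat("  ...\n")
  invisible(x)
}

.check_counts_fresh <- function(tree, counts) {
  if (!inherits(counts, "mul_partition_counts"))
    stop("'counts' must come from partition_counts()")
  if (!identical(attr(counts, "tree_edge"), tree$edge) ||
      !identical(attr(counts, "tree_label"), tree$label))
    stop("stale counts: the tree was modified after partition_counts()")
  attr(counts, "engine")
}

#' Compare the quartet sets of two edges from counts alone
#'
#' Any two distinct edges of a tree lie on a common path; orient it so the
#' path runs from `inner`'s far endpoint through both edges.  The far
#' exclusive set of the outer edge is always contained in that of the inner
#' edge, so, by the cardinality lemmas, the two quartet sets are comparable
#' exactly when cardinalities coincide: equal far-side exclusive counts mean
#' the inner edge's quartets are a subset of the outer's, equal near-side
#' counts the reverse, both mean equality.  The decision is O(1) given
#' [partition_counts()].
#'
#' The cardinality criterion presupposes both edges are informative (as they
#' are in the reduction pipeline, which contracts uninformative edges first):
#' an uninformative edge's empty quartet set is vacuously contained in any
#' other, which cardinalities alone cannot witness.
#'
#' @param tree a normalized `multree`.
#' @param counts the result of [partition_counts()] on `tree` (an error is
#'   raised if the tree changed since — stale counts).
#' @param inner,outer length-2 integer vectors naming existing edges.
#' @return one of `"equal"`, `"innerSubset"` (the inner edge's quartet set is
#'   a proper subset of the outer's), `"outerSubset"`, `"incomparable"`.
#' @export
edge_subsumption <- function(tree, counts, inner, outer) {
  eng <- .check_counts_fresh(tree, counts)
  inner <- as.integer(inner); outer <- as.integer(outer)
  if (!.mt_has_edge(tree, inner) || !.mt_has_edge(tree, outer))
    stop("both 'inner' and 'outer' must be edges of the tree")
  if (all(sort(inner) == sort(outer))) return("equal")
  # orient: u on the side of `inner` away from `outer`, x on the side of
  # `outer` away from `inner`
  uv <- .orient_away(eng, inner, outer)   # c(u, v)
  xw <- .orient_away(eng, outer, inner)   # c(x, w)
  w <- xw[2L]; x <- xw[1L]
  far_inner <- .excl_dir(eng, uv[1L], uv[2L])   # |M_v^{uv}|
  far_outer <- .excl_dir(eng, w, x)             # |M_x^{wx}|
  near_inner <- .excl_dir(eng, uv[2L], uv[1L])  # |M_u^{uv}|
  near_outer <- .excl_dir(eng, x, w)            # |M_w^{wx}|
  if (far_inner == far_outer && near_inner == near_outer) "equal"
  else if (far_inner == far_outer) "innerSubset"
  else if (near_inner == near_outer) "outerSubset"
  else "incomparable"
}

# return edge `e` as c(a, b) with `other` lying on the b side
.orient_away <- function(eng, e, other) {
  a <- e[1L]; b <- e[2L]
  child <- if (eng$parent[b] == a) b else a
  par <- if (child == b) a else b
  ref <- other[1L]
  if (.in_subtree(eng, child, ref)) c(par, child) else c(child, par)
}
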