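# Quartet strings are canonical: each side's two labels sorted (byte order)
# and joined with ",", sides joined with "|", smaller side string first.
# Equality of quartet topologies is then plain string equality.

.pair_strings <- function(x) {
  # x: sorted character vector; all unordered pairs as "a,b"
  k <- length(x)
  if (k < 2L) return(character(0))
  cm <- utils::combn(x, 2L)
  paste(cm[1L, ], cm[2L, ], sep = ",")
}

.join_quartets <- function(pu, pv) {
  if (!length(pu) || !length(pv)) return(character(0))
  g1 <- rep(pu, times = length(pv))
  g2 <- rep(pv, each = length(pu))
  ifelse(g1 < g2, paste0(g1, "|", g2), paste0(g2, "|", g1))
}

.quartet_support <- function(qs) {
  # the sorted 4-label set of each quartet, as "a,b,c,d"
  vapply(strsplit(qs, "[|,]"), function(x)
    paste(sort(x, method = "radix"), collapse = ","), character(1))
}

#' Quartets resolved by one edge
#'
#' Edge `(u, v)` resolves the quartet topology `ab|cd` when `a`, `b` are
#' distinct labels exclusive to the u side and `c`, `d` distinct labels
#' exclusive to the v side.  The resolved set therefore has size
#' `choose(|mU|, 2) * choose(|mV|, 2)`; an edge with fewer than two exclusive
#' labels on either side resolves nothing and is uninformative.
#'
#' @param tree a normalized `multree`.
#' @param edge length-2 integer vector naming an existing edge.
#' @return character vector of canonical quartet strings `"a,b|c,d"`.
#' @examples
#' fx <- example_multree()
#' edge_quartets(fx, c(1, 2))   # the (t,u) edge resolves af against {b,c,d,e}
#' @export
edge_quartets <- function(tree, edge) {
  p <- edge_partition(tree, edge)
  .join_quartets(.pair_strings(p$mU), .pair_strings(p$mV))
}

#' Is an edge informative?
#'
#' `TRUE` exactly when the edge resolves at least one quartet, i.e. both
#' exclusive sides of its label partition have two or more labels.
#'
#' @inheritParams edge_quartets
#' @return `TRUE` or `FALSE`.
#' @export
is_informative <- function(tree, edge) {
  p <- edge_partition(tree, edge)
  length(p$mU) >= 2L && length(p$mV) >= 2L
}

#' Conflict-free quartet information content of a MUL-tree
#'
#' The information content I(T) is the union, over all edges, of the quartets
#' each edge resolves.  These quartets are provably conflict-free: no
#' four-label set appears with two different topologies (see
#' [is_conflict_free()]), and there is always a singly-labeled tree
#' displaying all of them (see [relabel_to_singly()]).
#'
#' The quartet set is materialized explicitly — O(m^4) in the number of
#' distinct labels — so this is an oracle/analysis tool for moderate label
#' counts; the reduction pipeline itself never materializes I(T).
#'
#' @param tree a normalized `multree`.
#' @param max_labels guard against accidental combinatorial blow-up; raise it
#'   deliberately if you really want I(T) for a large label set.
#' @return sorted character vector of canonical quartet strings; empty for
#'   trees with fewer than four distinct labels.
#' @export
information_content <- function(tree, max_labels = 40L) {
  labs <- distinct_labels(tree)
  if (length(labs) > max_labels)
    stop("tree has ", length(labs), " distinct labels; information_content ",
         "materializes O(m^4) quartets (raise 'max_labels' to force)")
  n <- n_nodes(tree)
  if (n < 2L || length(labs) < 4L) return(character(0))
  e <- tree$edge
  out <- vector("list", nrow(e))
  for (k in seq_len(nrow(e))) {
    out[[k]] <- edge_quartets(tree, e[k, ])
  }
  sort(unique(unlist(out, use.names = FALSE)), method = "radix")
}

#' Check a quartet set for topological conflicts
#'
#' A set of quartets is conflict-free when no two members share the same
#' four-label support set with different bipartitions (`ab|cd` vs `ac|bd`).
#' The information content of any MUL-tree passes this check.
#'
#' @param qs character vector of canonical quartet strings (as produced by
#'   [edge_quartets()] or [information_content()]).
#' @return `TRUE` or `FALSE`.
#' @export
is_conflict_free <- function(qs) {
  qs <- unique(qs)
  if (length(qs) < 2L) return(TRUE)
  !anyDuplicated(.quartet_support(qs))
}

#' Four-label sets displayed with conflicting topologies
#'
#' A weaker, leafwise notion of display: edge `(u, v)` displays `ab|cd`
#' leafwise when some leaves labeled `a` and `b` lie on its u side and some
#' leaves labeled `c` and `d` on its v side (labels shared across the edge
#' may take part, unlike in [edge_quartets()]).  A four-label set is
#' conflicting when at least two distinct topologies on it are displayed
#' leafwise somewhere in the tree.  Only the formally resolved set I(T) is
#' guaranteed conflict-free; this function surfaces the conflicts that
#' duplicate labels induce.
#'
#' @param tree a normalized `multree`.
#' @param max_labels guard as in [information_content()].
#' @return sorted character vector of conflicting support sets `"a,b,c,d"`;
#'   empty for singly-labeled trees.
#' @export
conflicting_label_sets <- function(tree, max_labels = 25L) {
  labs <- distinct_labels(tree)
  if (length(labs) > max_labels)
    stop("too many labels for leafwise conflict scan (raise 'max_labels')")
  if (n_nodes(tree) < 2L || length(labs) < 4L) return(character(0))
  e <- tree$edge
  seen <- character(0)
  for (k in seq_len(nrow(e))) {
    p <- edge_partition(tree, e[k, ])
    lu <- sort(c(p$mU, p$common), method = "radix")
    lv <- sort(c(p$mV, p$common), method = "radix")
    q <- .join_quartets(.pair_strings(lu), .pair_strings(lv))
    # drop degenerate combinations where the two sides share a label
    four <- strsplit(q, "[|,]")
    q <- q[vapply(four, function(x) !anyDuplicated(x), logical(1))]
    seen <- unique(c(seen, q))
  }
  sup <- .quartet_support(seen)
  sort(unique(sup[duplicated(sup)]), method = "radix")
}

#' Relabel a MUL-tree into a singly-labeled tree
#'
#' For every multiply-occurring label, one leaf (the first in a deterministic
#' depth-first traversal) keeps the label and every other copy receives a
#' fresh label `"<label>#k"`.  The leaf count is unchanged and the
#' information content can only grow: every quartet of the input is still
#' resolved in the output, which is the constructive reason I(T) is
#' conflict-free.
#'
#' @param tree a normalized `multree`.
#' @param keep policy for which copy keeps the original label; only
#'   `"first-dfs"` is implemented.
#' @return a singly-labeled `multree` with the same topology.
#' @export
relabel_to_singly <- function(tree, keep = c("first-dfs")) {
  keep <- match.arg(keep)
  n <- n_nodes(tree)
  if (n == 0L) return(tree)
  adj <- .mt_adj(tree)
  ord <- .mt_preorder(adj, 1L)
  label <- tree$label
  existing <- distinct_labels(tree)
  seen <- new.env(parent = emptyenv())
  for (v in ord$pre) {
    lab <- label[v]
    if (is.na(lab)) next
    k <- (if (is.null(seen[[lab]])) 0L else seen[[lab]]) + 1L
    seen[[lab]] <- k
    if (k > 1L) {
      fresh <- paste0(lab, "#", k)
      if (fresh %in% existing)
        stop("fresh label '", fresh, "' collides with an existing label")
      label[v] <- fresh
    }
  }
  multree(tree$edge, label)
}

#' Export a quartet set as text
#'
#' One canonical quartet per line, sorted, for diffing between runs or tools.
#'
#' @param qs character vector of quartet strings.
#' @param path file to write.
#' @return the path, invisibly.
#' @export
write_quartets <- function(qs, path) {
  writeLines(sort(unique(qs), method = "radix"), path)
  invisible(path)
}
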