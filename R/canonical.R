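#' Canonical form and isomorphism of MUL-trees
#'
#' `canonical_form()` produces a text signature that is invariant under node
#' renumbering and child reordering, and that distinguishes trees with
#' different topologies or leaf label multisets: two normalized trees are
#' isomorphic exactly when their canonical forms are equal strings.
#'
#' The construction is an AHU-style canonical code extended to label
#' multisets: the unrooted tree is rooted at its centroid (for a centroid
#' pair, at the midpoint of the centroid edge, which is an
#' isomorphism-invariant choice), and subtree signatures are sorted
#' lexicographically (byte order) at every node; a leaf's signature is its
#' label.
#'
#' @param tree a normalized `multree`.
#' @return a character scalar.
#' @export
canonical_form <- function(tree) {
  n <- n_nodes(tree)
  if (n == 0L) return(";")
  if (n == 1L) return(paste0("<", tree$label[1L], ">"))
  adj <- .mt_adj(tree)
  cent <- .mt_centroids(tree, adj)
  sig <- function(v, par) {
    if (!is.na(tree$label[v])) return(paste0("<", tree$label[v], ">"))
    kids <- adj[[v]][adj[[v]] != par]
    ks <- vapply(kids, sig, character(1), par = v)
    paste0("(", paste(sort(ks, method = "radix"), collapse = ","), ")")
  }
  if (length(cent) == 1L) {
    sig(cent, 0L)
  } else {
    two <- sort(c(sig(cent[1L], cent[2L]), sig(cent[2L], cent[1L])),
                method = "radix")
    paste0("(", paste(two, collapse = ","), ")")
  }
}

# centroid node(s): minimize the largest component left by deleting the node;
# a tree has one centroid or two adjacent ones
.mt_centroids <- function(tree, adj = .mt_adj(tree)) {
  n <- n_nodes(tree)
  ord <- .mt_preorder(adj, 1L)
  size <- rep(1L, n)
  for (k in n:2) {
    v <- ord$pre[k]
    size[ord$parent[v]] <- size[ord$parent[v]] + size[v]
  }
  maxcomp <- vapply(seq_len(n), function(v) {
    kids <- adj[[v]][adj[[v]] != ord$parent[v]]
    max(c(n - size[v], size[kids]))
  }, integer(1))
  which(maxcomp == min(maxcomp))
}

# iterative DFS preorder with parent pointers (parent[root] = 0)
.mt_preorder <- function(adj, root) {
  n <- length(adj)
  parent <- integer(n)
  pre <- integer(n)
  stack <- root
  k <- 0L
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    k <- k + 1L
    pre[k] <- v
    nb <- adj[[v]]
    nb <- nb[nb != parent[v]]
    parent[nb] <- v
    stack <- c(stack, nb)
  }
  pos <- integer(n); pos[pre] <- seq_len(n)
  list(pre = pre, parent = parent, pos = pos)
}

#' @rdname canonical_form
#' @param t1,t2 normalized `multree` objects.
#' @return `is_isomorphic()`: `TRUE` or `FALSE`.
#' @export
is_isomorphic <- function(t1, t2) {
  identical(canonical_form(t1), canonical_form(t2))
}
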