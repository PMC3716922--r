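# shared helpers: small random trees, an isomorphism scrambler, and an
# independent quartet oracle for singly-labeled trees

# a random MUL-tree drawn from the current RNG stream
rand_tree <- function(labels = 4:9, extras = 0:5) {
  random_multree(sample(labels, 1L), sample(extras, 1L))
}

# re-emit a tree with permuted node ids and shuffled edge rows; the result is
# a different concrete object representing the same (isomorphic) tree
shuffle_multree <- function(tree) {
  n <- n_nodes(tree)
  if (n < 2L) return(tree)
  perm <- sample.int(n)
  e <- cbind(perm[tree$edge[, 1L]], perm[tree$edge[, 2L]], deparse.level = 0)
  flip <- sample(c(TRUE, FALSE), nrow(e), replace = TRUE)
  e[flip, ] <- e[flip, c(2L, 1L)]
  e <- e[sample.int(nrow(e)), , drop = FALSE]
  lab <- character(n)
  lab[perm] <- tree$label
  multree(e, lab)
}

# canonical quartet string, independent of the package's internals
qstr <- function(a, b, c, d) {
  s1 <- paste(sort(c(a, b), method = "radix"), collapse = ",")
  s2 <- paste(sort(c(c, d), method = "radix"), collapse = ",")
  if (s1 < s2) paste0(s1, "|", s2) else paste0(s2, "|", s1)
}

# independent oracle: quartets displayed by a SINGLY-labeled tree, from the
# four-point condition on path-length distances (no edge partitions involved)
brute_quartets_singly <- function(tree) {
  labs <- distinct_labels(tree)
  stopifnot(all(label_multiplicity(tree) == 1L))
  if (length(labs) < 4L) return(character(0))
  lf <- leaves(tree)
  lf <- lf[match(labs, tree$label[lf])]
  d <- tree_distances(tree)[lf, lf, drop = FALSE]
  out <- character(0)
  idx <- utils::combn(length(labs), 4L)
  for (k in seq_len(ncol(idx))) {
    q <- idx[, k]
    s12 <- d[q[1], q[2]] + d[q[3], q[4]]
    s13 <- d[q[1], q[3]] + d[q[2], q[4]]
    s14 <- d[q[1], q[4]] + d[q[2], q[3]]
    s <- c(s12, s13, s14)
    if (sum(s == min(s)) == 1L) {
      pick <- which.min(s)
      ab <- switch(pick, c(1L, 2L), c(1L, 3L), c(1L, 4L))
      cd <- setdiff(1:4, ab)
      out <- c(out, qstr(labs[q[ab[1]]], labs[q[ab[2]]],
                         labs[q[cd[1]]], labs[q[cd[2]]]))
    }
  }
  sort(out, method = "radix")
}

# all-pairs path lengths (edge counts) via repeated BFS
tree_distances <- function(tree) {
  n <- n_nodes(tree)
  adj <- mulred:::.mt_adj(tree)
  d <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    front <- s
    while (length(front)) {
      nb <- unique(unlist(adj[front], use.names = FALSE))
      nb <- nb[is.na(dist[nb])]
      dist[nb] <- dist[front[1L]] + 1L  # BFS layers: all of `front` equal
      front <- nb
    }
    d[s, ] <- dist
  }
  d
}

internal_edges <- function(tree) {
  e <- tree$edge
  e[is.na(tree$label[e[, 1L]]) & is.na(tree$label[e[, 2L]]), , drop = FALSE]
}
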