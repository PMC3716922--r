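# The three-phase reduction to the maximally reduced form (MRF).
#
# Phase 1 contracts uninformative internal edges (an exclusive side with at
# most one label).  Phase 2 repeatedly finds adjacent internal edges with
# comparable quartet sets, contracts the subsumed edge together with the
# internal edges branching off the shared node, and — when the two sets are
# equal — deletes the branching subtrees outright.  Phase 3 prunes leaves:
# whole labels that appear in no resolved quartet, duplicate copies sharing a
# pendant node, and copies attached at interior nodes of their label's
# spanning subtree.  Each operation preserves the information content
# exactly; the pipeline repeats until a verified fixed point (every operation
# strictly decreases the node count, so termination is immediate).

#' Contract all uninformative internal edges
#'
#' An internal edge whose partition has at most one exclusive label on either
#' side resolves no quartet and can be contracted without touching the
#' information content.  Contraction leaves the partitions of all other
#' edges unchanged, so a single batch pass suffices: afterwards every
#' internal edge has at least two exclusive labels on each side.  Pendant
#' edges are never contracted.
#'
#' @param tree a normalized `multree`.
#' @return the contracted `multree`.
#' @export
contract_uninformative <- function(tree) {
  .phase_uninformative(tree)$tree
}

.phase_uninformative <- function(tree) {
  n <- n_nodes(tree)
  if (n < 2L) return(list(tree = tree, contracted = 0L))
  eng <- .mt_counts(tree)
  child <- setdiff(seq_len(n), eng$root)
  par <- eng$parent[child]
  internal <- is.na(tree$label[child]) & is.na(tree$label[par])
  weak <- internal & (eng$excl_child[child] <= 1L | eng$excl_par[child] <= 1L)
  if (!any(weak)) return(list(tree = tree, contracted = 0L))
  edges <- cbind(par[weak], child[weak], deparse.level = 0)
  list(tree = .mt_contract_batch(tree, edges), contracted = sum(weak))
}

#' Contract subsumed adjacent edges (with branch handling)
#'
#' After [contract_uninformative()], the only remaining contractible edges
#' are those whose quartet set is contained in a neighbor's.  For adjacent
#' internal edges `(u,v)` and `(v,w)`, containment is detected in constant
#' time from partition cardinalities; on a hit the subsumed edge is
#' contracted along with every internal edge incident to `v` or inside a
#' subtree branching out of `v`, and when the two quartet sets are equal the
#' branching subtrees are deleted entirely (their leaves resolve nothing the
#' path does not).  Counts are recomputed after each action; the sweep
#' restarts until no comparable adjacent pair remains — and then, because
#' comparable edges always line up along a path, no comparable pair remains
#' at any distance.
#'
#' @param tree a normalized `multree`, ideally already stripped of
#'   uninformative edges.
#' @return the reduced `multree`.
#' @export
contract_subsumed <- function(tree) {
  .phase_subsumed(tree)$tree
}

.phase_subsumed <- function(tree) {
  contracted <- 0L
  subtrees_deleted <- 0L
  repeat {
    n <- n_nodes(tree)
    if (n < 2L) break
    eng <- .mt_counts(tree)
    hit <- .find_subsumed_pair(tree, eng)
    if (is.null(hit)) break
    u <- hit$u; v <- hit$v; w <- hit$w
    branches <- setdiff(eng$adj[[v]], c(u, w))
    if (hit$relation == "equal") {
      drop <- integer(0)
      for (z in branches) drop <- c(drop, .mt_side_nodes(tree, v, z))
      subtrees_deleted <- subtrees_deleted + length(branches)
      contracted <- contracted + 1L           # (u,v) merges into (v,w)
      tree <- .mt_induced(tree, setdiff(seq_len(n), drop))
    } else {
      # hit$sub is the subsumed edge, c(a, v): contract it plus every
      # internal edge incident to v or inside a branch subtree
      edges <- matrix(hit$sub, ncol = 2L)
      for (z in branches) {
        if (is.na(tree$label[z])) edges <- rbind(edges, c(v, z))
        side <- .mt_side_nodes(tree, v, z)
        inb <- tree$edge[, 1L] %in% side & tree$edge[, 2L] %in% side
        if (any(inb)) {
          be <- tree$edge[inb, , drop = FALSE]
          int <- is.na(tree$label[be[, 1L]]) & is.na(tree$label[be[, 2L]])
          edges <- rbind(edges, be[int, , drop = FALSE])
        }
      }
      contracted <- contracted + nrow(edges)
      tree <- .mt_contract_batch(tree, edges)
    }
  }
  list(tree = tree, contracted = contracted,
       subtrees_deleted = subtrees_deleted)
}

# scan for adjacent internal edges (u,v), (v,w) with comparable quartet sets
.find_subsumed_pair <- function(tree, eng) {
  internal <- which(is.na(tree$label))
  for (v in internal) {
    nbs <- eng$adj[[v]]
    nbs <- nbs[is.na(tree$label[nbs])]
    if (length(nbs) < 2L) next
    for (i in seq_len(length(nbs) - 1L)) {
      for (j in (i + 1L):length(nbs)) {
        u <- nbs[i]; w <- nbs[j]
        far_uv <- .excl_dir(eng, u, v)   # |M_v^{uv}| (side holding w)
        far_vw <- .excl_dir(eng, v, w)   # |M_w^{vw}|
        near_uv <- .excl_dir(eng, v, u)  # |M_u^{uv}|
        near_vw <- .excl_dir(eng, w, v)  # |M_v^{vw}| (side holding u)
        # the cardinality criterion is only a valid subset test between
        # informative edges; uninformative ones fall to the next phase-1 pass
        if (near_uv < 2L || far_uv < 2L || near_vw < 2L || far_vw < 2L) next
        sub_uv <- far_uv == far_vw       # quartets(u,v) within quartets(v,w)
        sub_vw <- near_uv == near_vw     # quartets(v,w) within quartets(u,v)
        if (sub_uv && sub_vw) {
          return(list(u = u, v = v, w = w, relation = "equal"))
        } else if (sub_uv) {
          return(list(u = u, v = v, w = w, relation = "subset",
                      sub = c(u, v)))
        } else if (sub_vw) {
          return(list(u = u, v = v, w = w, relation = "subset",
                      sub = c(v, w)))
        }
      }
    }
  }
  NULL
}

#' Prune labels that take part in no quartet
#'
#' A label appears in some resolved quartet exactly when some edge carries it
#' in an exclusive side with at least two labels while the opposite exclusive
#' side also has at least two.  Labels failing this everywhere contribute
#' nothing to the information content, and removing all of their leaves at
#' once leaves every other edge partition — hence I(T) — unchanged.  A tree
#' with empty information content loses all its leaves here.
#'
#' @param tree a normalized `multree`.
#' @return the pruned `multree` (possibly empty).
#' @export
prune_uninvolved_labels <- function(tree) {
  .phase_uninvolved(tree)$tree
}

.phase_uninvolved <- function(tree) {
  n <- n_nodes(tree)
  if (n == 0L) return(list(tree = tree, pruned = 0L))
  eng <- .mt_counts(tree)
  m <- eng$m
  part <- rep(FALSE, m)
  qual <- which(eng$excl_child >= 2L & eng$excl_par >= 2L)
  qual <- setdiff(qual, eng$root)
  for (v in qual) {
    part <- part | (eng$cnt[, v] == eng$tot) | (eng$cnt[, v] == 0L)
  }
  dead <- eng$labels[!part]
  if (!length(dead)) return(list(tree = tree, pruned = 0L))
  ids <- which(tree$label %in% dead)
  list(tree = .mt_prune_leaves(tree, ids), pruned = length(ids))
}

#' Remove duplicate leaves sharing a pendant node
#'
#' When several leaves with the same label hang off one pendant node, all but
#' one are redundant: they sit on the same side of every edge, so the edge
#' partitions do not change when the extra copies go.  The copy with the
#' smallest node id survives (deterministic; irrelevant to the isomorphism
#' class of the result).
#'
#' @param tree a normalized `multree`.
#' @return the deduplicated `multree`.
#' @export
dedupe_sibling_leaves <- function(tree) {
  .phase_dedupe(tree)$tree
}

.phase_dedupe <- function(tree) {
  lf <- leaves(tree)
  if (length(lf) < 2L || nrow(tree$edge) == 0L)
    return(list(tree = tree, pruned = 0L))
  e <- tree$edge
  nbr <- integer(n_nodes(tree))
  sel1 <- !is.na(tree$label[e[, 1L]])
  nbr[e[sel1, 1L]] <- e[sel1, 2L]
  sel2 <- !is.na(tree$label[e[, 2L]])
  nbr[e[sel2, 2L]] <- e[sel2, 1L]
  lf <- sort(lf)
  key <- paste(nbr[lf], tree$label[lf])
  extra <- lf[duplicated(key)]
  if (!length(extra)) return(list(tree = tree, pruned = 0L))
  list(tree = .mt_prune_leaves(tree, extra), pruned = length(extra))
}

#' Prune duplicate leaves interior to their label's spanning subtree
#'
#' For a multiply-occurring label, consider the minimal subtree spanning all
#' of its leaves.  A copy whose pendant node has degree three or more within
#' that subtree is redundant: the label already reaches both sides of every
#' edge it touches through the other copies.  Copies at degree-2 pendant
#' nodes (the "ends" of the spanning subtree) are the ones that carry the
#' label's contribution and are kept.  Requires [dedupe_sibling_leaves()]
#' first, so no pendant node holds two copies of one label.
#'
#' All labels are handled from one shared count matrix and pruned in a single
#' batch: removing one label's redundant copies cannot alter another label's
#' spanning-subtree degrees.
#'
#' @param tree a normalized `multree`.
#' @return the pruned `multree`.
#' @export
prune_spanning_redundant <- function(tree) {
  .phase_spanning(tree)$tree
}

.phase_spanning <- function(tree) {
  n <- n_nodes(tree)
  if (n < 2L) return(list(tree = tree, pruned = 0L))
  eng <- .mt_counts(tree)
  mul <- which(eng$tot >= 2L)
  if (!length(mul)) return(list(tree = tree, pruned = 0L))
  child <- setdiff(seq_len(n), eng$root)
  par <- eng$parent[child]
  drop <- integer(0)
  for (li in mul) {
    cl <- eng$cnt[li, child]
    span <- cl > 0L & cl < eng$tot[li]      # edges inside the spanning subtree
    subdeg <- tabulate(c(child[span], par[span]), n)
    lvs <- which(!is.na(tree$label) & eng$lab_id == li)
    pend <- ifelse(eng$parent[lvs] != 0L, eng$parent[lvs], NA_integer_)
    # a leaf's neighbor is its parent unless the leaf is the root (excluded
    # because .mt_counts roots at an internal node whenever one exists)
    bad <- lvs[!is.na(pend) & subdeg[pend] >= 3L]
    drop <- c(drop, bad)
  }
  if (!length(drop)) return(list(tree = tree, pruned = 0L))
  list(tree = .mt_prune_leaves(tree, unique(drop)),
       pruned = length(unique(drop)))
}

#' Maximally reduced form of a MUL-tree
#'
#' Runs the reduction pipeline — uninformative-edge contraction, subsumed-
#' edge contraction with branch handling, no-quartet label pruning, sibling
#' deduplication, spanning-subtree pruning — and repeats it until nothing
#' changes.  The result is the unique smallest tree with exactly the same
#' conflict-free quartet information content as the input; a tree with empty
#' information content reduces to the empty tree, flagged `noInformation`.
#'
#' With `verify = TRUE` (intended for small trees) the fixed point is
#' additionally certified by brute force: no single leaf prune or internal
#' edge contraction leaves the information content unchanged.
#'
#' @param tree a `multree` (normalized on entry).
#' @param verify brute-force certification of the fixed point; costs
#'   O(operations x quartets) and errors if the certificate fails.
#' @return a list of class `mul_reduction` with elements `tree` (the MRF) and
#'   `report` (a [reduction report][reduction_report]).
#' @examples
#' r <- mrf(example_multree())
#' r$tree
#' r$report
#' @export
mrf <- function(tree, verify = FALSE) {
  tree <- normalize_multree(tree)
  labs0 <- distinct_labels(tree)
  rep0 <- list(phase1Contractions = 0L, phase2Contractions = 0L,
               subtreesDeleted = 0L,
               leavesPruned = list(noQuartetLabel = 0L, pendantDedupe = 0L,
                                   spanningRule = 0L))
  repeat {
    n0 <- n_nodes(tree)
    p1 <- .phase_uninformative(tree)
    p2 <- .phase_subsumed(p1$tree)
    p3 <- .phase_uninvolved(p2$tree)
    p4 <- .phase_dedupe(p3$tree)
    p5 <- .phase_spanning(p4$tree)
    tree <- p5$tree
    rep0$phase1Contractions <- rep0$phase1Contractions + p1$contracted
    rep0$phase2Contractions <- rep0$phase2Contractions + p2$contracted
    rep0$subtreesDeleted <- rep0$subtreesDeleted + p2$subtrees_deleted
    rep0$leavesPruned$noQuartetLabel <-
      rep0$leavesPruned$noQuartetLabel + p3$pruned
    rep0$leavesPruned$pendantDedupe <-
      rep0$leavesPruned$pendantDedupe + p4$pruned
    rep0$leavesPruned$spanningRule <-
      rep0$leavesPruned$spanningRule + p5$pruned
    if (n_nodes(tree) == n0) break
  }
  if (verify) .verify_fixed_point(tree)
  kept <- distinct_labels(tree)
  rep0$taxaLostStep1 <- if (length(labs0))
    100 * (length(labs0) - length(kept)) / length(labs0) else 0
  rep0$taxaLostStep2 <- NA_real_
  rep0$noInformation <- n_nodes(tree) == 0L
  structure(list(tree = tree, report = structure(rep0,
                                                 class = "mul_reduction_report")),
            class = "mul_reduction")
}

#' @export
print.mul_reduction <- function(x, ...) {
  cat("maximally reduced form\n")
  print(x$tree)
  print(x$report)
  invisible(x)
}

#' Reduction report
#'
#' Accounting attached to every [mrf()] / [reduce_two_step()] run: the number
#' of edges contracted in each phase, subtrees deleted, leaves pruned by each
#' rule, the percentage of distinct input labels lost by the reduction
#' (`taxaLostStep1`), the total percentage lost after restriction to unique
#' labels (`taxaLostStep2`, `NA` when the restriction step was not run), and
#' whether the tree had no information at all (`noInformation`, i.e. the MRF
#' is empty).  Serialize with [report_json()].
#'
#' @name reduction_report
NULL

#' @export
print.mul_reduction_report <- function(x, ...) {
  cat(sprintf(paste0("  contractions: %d uninformative, %d subsumed; ",
                     "%d subtrees deleted\n"),
              x$phase1Contractions, x$phase2Contractions, x$subtreesDeleted))
  cat(sprintf("  leaves pruned: %d no-quartet, %d sibling, %d spanning\n",
              x$leavesPruned$noQuartetLabel, x$leavesPruned$pendantDedupe,
              x$leavesPruned$spanningRule))
  cat(sprintf("  taxon loss: %.2f%% (step 1)", x$taxaLostStep1))
  if (!is.na(x$taxaLostStep2)) cat(sprintf(", %.2f%% (after step 2)",
                                           x$taxaLostStep2))
  cat(if (x$noInformation) "; no information content\n" else "\n")
  invisible(x)
}

#' @rdname reduction_report
#' @param report a `mul_reduction_report`.
#' @return `report_json()`: a JSON string.
#' @export
report_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                   na = "null", pretty = TRUE)
}

# certify that no single prune/contract preserves I (debug / small trees)
.verify_fixed_point <- function(tree) {
  icur <- information_content(tree)
  for (lf in leaves(tree)) {
    t2 <- prune_leaf(tree, lf)
    if (setequal(information_content(t2), icur))
      stop("fixed-point certificate failed: leaf ", lf, " is still prunable")
  }
  e <- tree$edge
  for (k in seq_len(nrow(e))) {
    if (any(!is.na(tree$label[e[k, ]]))) next
    t2 <- contract_edge(tree, e[k, ])
    if (setequal(information_content(t2), icur))
      stop("fixed-point certificate failed: edge (", e[k, 1L], ",",
           e[k, 2L], ") is still contractible")
  }
  invisible(TRUE)
}

#' Brute-force reference reducer
#'
#' Applies the definition of the maximally reduced form literally: scan all
#' candidate operations — prune one leaf, contract one internal edge, prune
#' every leaf of one label — in a seeded random order, apply the first whose
#' result has exactly the same information content (recomputed from scratch
#' each time), and repeat until no operation applies.  Slow by construction;
#' guarded to small trees.  Serves as the independent oracle for [mrf()]:
#' whatever the operation order, the fixed point is the same tree up to
#' isomorphism.
#'
#' Label-level pruning is part of the operation set because removing every
#' copy of a label that resolves no quartet preserves the information content
#' even when removing any single copy would create new quartets.
#'
#' @param tree a normalized `multree`.
#' @param seed integer seed for the scan order.
#' @param max_leaves size guard; an error is raised beyond it.
#' @return the maximally reduced `multree`.
#' @export
reference_mrf <- function(tree, seed = 1L, max_leaves = 15L) {
  if (n_leaves(tree) > max_leaves)
    stop("reference_mrf is a brute-force oracle; tree exceeds 'max_leaves'")
  tree <- normalize_multree(tree)
  .with_seed(seed, {
    icur <- information_content(tree)
    repeat {
      ops <- .enumerate_ops(tree)
      if (!length(ops)) break
      ops <- ops[sample.int(length(ops))]
      applied <- FALSE
      for (op in ops) {
        t2 <- switch(op$type,
                     prune = prune_leaf(tree, op$node),
                     contract = contract_edge(tree, op$edge),
                     prune_label = .mt_prune_leaves(
                       tree, which(tree$label %in% op$label)))
        i2 <- information_content(t2)
        if (setequal(i2, icur)) {
          tree <- t2
          icur <- i2
          applied <- TRUE
          break
        }
      }
      if (!applied) break
    }
    tree
  })
}

.enumerate_ops <- function(tree) {
  ops <- list()
  for (lf in leaves(tree)) ops[[length(ops) + 1L]] <-
    list(type = "prune", node = lf)
  e <- tree$edge
  for (k in seq_len(nrow(e))) {
    if (all(is.na(tree$label[e[k, ]]))) ops[[length(ops) + 1L]] <-
      list(type = "contract", edge = e[k, ])
  }
  for (lab in distinct_labels(tree)) ops[[length(ops) + 1L]] <-
    list(type = "prune_label", label = lab)
  ops
}

#' Restrict an MRF to its once-occurring labels
#'
#' The second step of the two-step program: delete every leaf whose label
#' still occurs more than once in the (maximally reduced) tree, yielding a
#' singly-labeled tree — possibly empty.  Unlike step 1 this can lose
#' quartets, but it never invents any: the result displays no topology on
#' surviving labels that conflicts with the input's information content.
#' Edges left uninformative by the deletions are contracted so the emitted
#' tree is clean.
#'
#' @param tree a `multree`, normally the MRF from [mrf()].
#' @return a singly-labeled `multree` (possibly empty).
#' @export
restrict_to_unique_labels <- function(tree) {
  mul <- label_multiplicity(tree)
  dup <- names(mul)[mul >= 2L]
  if (length(dup)) {
    tree <- .mt_prune_leaves(tree, which(tree$label %in% dup))
  }
  contract_uninformative(normalize_multree(tree))
}

#' The full two-step reduction
#'
#' Convenience wrapper: compute the MRF, then restrict it to once-occurring
#' labels, and fill the complete taxon-loss accounting (percentages of the
#' input's distinct labels absent after each step).
#'
#' @param tree a `multree`.
#' @return a list of class `mul_two_step` with elements `mrf`, `singly` and
#'   `report`.
#' @export
reduce_two_step <- function(tree) {
  labs0 <- distinct_labels(tree)
  r <- mrf(tree)
  singly <- restrict_to_unique_labels(r$tree)
  rep <- r$report
  kept2 <- distinct_labels(singly)
  rep$taxaLostStep2 <- if (length(labs0))
    100 * (length(labs0) - length(kept2)) / length(labs0) else 0
  structure(list(mrf = r$tree, singly = singly, report = rep),
            class = "mul_two_step")
}

#' @export
print.mul_two_step <- function(x, ...) {
  cat("two-step reduction\n  MRF: ")
  cat(write_newick(x$mrf), "\n  singly-labeled: ")
  cat(write_newick(x$singly), "\n")
  print(x$report)
  invisible(x)
}
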