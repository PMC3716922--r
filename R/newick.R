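#' Parse Newick text into MUL-trees
#'
#' Reads one or more Newick statements (separated by semicolons and/or
#' newlines).  Duplicate leaf labels are permitted and preserved verbatim;
#' branch lengths and internal node names are parsed and discarded — the
#' methods in this package are purely topological.  Each tree is normalized
#' on the way in (see [normalize_multree()]): rooted inputs are unrooted by
#' suppressing the degree-2 root, singleton chains are collapsed.
#'
#' Parsing itself is delegated to [ape::read.tree()]; a statement ape cannot
#' parse raises an error naming the offending statement and its line.
#'
#' @param text character scalar or vector of Newick text.
#' @return a list of `multree` objects, one per non-empty statement, in input
#'   order.
#' @examples
#' parse_newick("((a,b),(a,b));")[[1]]
#' @export
parse_newick <- function(text) {
  text <- paste(text, collapse = "\n")
  # split into statements, remembering the line each one starts on
  bits <- strsplit(text, ";", fixed = TRUE)[[1L]]
  nl <- function(s) nchar(gsub("[^\n]", "", s))
  starts <- integer(length(bits))
  line <- 1L
  for (i in seq_along(bits)) {
    lead <- sub("\\S.*$", "", bits[i])         # whitespace before content
    starts[i] <- line + nl(lead)
    line <- line + nl(bits[i])
  }
  keep <- grepl("\\S", bits)
  bits <- bits[keep]; starts <- starts[keep]
  if (!length(bits)) stop("no Newick statement found")
  out <- vector("list", length(bits))
  for (i in seq_along(bits)) {
    out[[i]] <- .parse_one_newick(trimws(bits[i]), i, starts[i])
  }
  out
}

.parse_one_newick <- function(stmt, idx, line) {
  fail <- function(why) {
    stop(sprintf("parse error in tree %d (line %d): %s", idx, line, why),
         call. = FALSE)
  }
  # a bare label is a single-leaf tree; ape cannot represent it
  if (!grepl("[(),]", stmt)) {
    lab <- .strip_quotes(stmt)
    if (!nzchar(lab)) fail("empty statement")
    return(multree(matrix(integer(0), ncol = 2L), lab, validate = FALSE))
  }
  # shield single-quoted labels (with '' escapes) behind placeholder tokens;
  # ape::read.tree does not honor Newick quoting
  quoted <- character(0)
  mq <- gregexpr("'(?:[^']|'')*'", stmt, perl = TRUE)[[1L]]
  if (mq[1L] != -1L) {
    quoted <- regmatches(stmt, list(mq))[[1L]]
    stem <- "qlbl"
    while (any(grepl(stem, stmt, fixed = TRUE))) stem <- paste0(stem, "x")
    for (k in seq_along(quoted)) {
      stmt <- sub(quoted[k], paste0(stem, k, "end"), stmt, fixed = TRUE)
    }
    names(quoted) <- paste0(stem, seq_along(quoted), "end")
  }
  ph <- NULL
  wrn <- NULL
  ph <- withCallingHandlers(
    tryCatch(ape::read.tree(text = paste0(stmt, ";")),
             error = function(e) NULL),
    warning = function(w) {
      wrn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  if (is.null(ph)) fail(if (is.null(wrn)) "malformed Newick" else wrn)
  if (inherits(ph, "multiPhylo")) ph <- ph[[1L]]
  if (length(quoted)) {
    hitq <- ph$tip.label %in% names(quoted)
    ph$tip.label[hitq] <- vapply(quoted[ph$tip.label[hitq]],
                                 .strip_quotes, character(1))
  }
  nt <- length(ph$tip.label)
  if (nt < 1L) fail("tree has no leaves")
  raw <- multree(ph$edge,
                 c(ph$tip.label, rep(NA_character_, ph$Nnode)),
                 validate = FALSE)
  out <- normalize_multree(raw)
  if (n_leaves(out) < 1L) fail("tree has no leaves")
  out
}

.strip_quotes <- function(x) {
  x <- trimws(x)
  if (grepl("^'.*'$", x)) x <- gsub("''", "'", substr(x, 2L, nchar(x) - 1L))
  x
}

#' Read and write multi-tree Newick files
#'
#' `read_multree()` parses a file with one Newick statement per line (or
#' several per line, semicolon-separated).  `write_multree()` writes one
#' statement per line.
#'
#' @param path file path.
#' @param trees a `multree` or list of them.
#' @return `read_multree()`: a list of `multree`; `write_multree()`: the path,
#'   invisibly.
#' @export
read_multree <- function(path) {
  parse_newick(readLines(path, warn = FALSE))
}

#' @rdname read_multree
#' @export
write_multree <- function(trees, path) {
  if (inherits(trees, "multree")) trees <- list(trees)
  writeLines(vapply(trees, write_newick, character(1)), path)
  invisible(path)
}

#' Emit a MUL-tree as Newick
#'
#' Output carries no branch lengths or internal names.  Duplicate labels are
#' written verbatim (no disambiguating suffixes).  Labels containing
#' characters outside `[A-Za-z0-9_.-]` are single-quoted.  The empty tree is
#' written as the conventional empty statement `";"`.  Round trip:
#' `parse_newick(write_newick(t))[[1]]` is isomorphic to `t`.
#'
#' @param tree a `multree`.
#' @return a Newick string, semicolon-terminated.
#' @export
write_newick <- function(tree) {
  n <- n_nodes(tree)
  if (n == 0L) return(";")
  if (n == 1L) return(paste0(.nwk_quote(tree$label[1L]), ";"))
  adj <- .mt_adj(tree)
  root <- which(is.na(tree$label))[1L]
  if (is.na(root)) {
    # two-leaf tree: no internal node at all
    return(paste0("(", .nwk_quote(tree$label[1L]), ",",
                  .nwk_quote(tree$label[2L]), ");"))
  }
  emit <- function(v, par) {
    if (!is.na(tree$label[v])) return(.nwk_quote(tree$label[v]))
    kids <- adj[[v]][adj[[v]] != par]
    paste0("(", paste(vapply(kids, emit, character(1), par = v),
                      collapse = ","), ")")
  }
  paste0(emit(root, 0L), ";")
}

.nwk_quote <- function(x) {
  bad <- grepl("[^A-Za-z0-9_.-]", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}
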