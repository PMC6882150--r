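# Internal preorder-indexed representation of a rooted binary tree.
#
# Vertices are numbered 1..nv in preorder, so the root is vertex 1 and the
# subtree of vertex v is exactly the index interval [v, subtreeEnd[v]].  That
# interval test gives O(1) ancestor/descendant queries, which the DTL dynamic
# program relies on for transfer ("incomparable vertex") scans.  Internal
# vertices get deterministic synthetic labels from their preorder index so that
# all outputs are reproducible; leaf labels come from the input Newick.

#' @importFrom ape read.tree
NULL

# Build the indexed form from a children list (list of integer(2) or NULL) and
# leaf labels, renumbering vertices in preorder with child order preserved.
.indexFromChildren <- function(children, labels, rootVertex) {
  nv <- length(children)
  newId <- integer(nv)
  order <- integer(nv)
  k <- 0L
  stack <- rootVertex
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    newId[v] <- k
    order[k] <- v
    ch <- children[[v]]
    if (!is.null(ch)) stack <- c(stack, rev(ch)) # left child popped first
  }
  childMat <- matrix(NA_integer_, nv, 2L)
  parent <- integer(nv)
  for (v in seq_len(nv)) {
    ch <- children[[order[v]]]
    if (!is.null(ch)) {
      childMat[v, ] <- newId[ch]
      parent[newId[ch]] <- v
    }
  }
  isLeaf <- is.na(childMat[, 1L])
  lab <- character(nv)
  lab[] <- ifelse(isLeaf, labels[order], paste0("n", seq_len(nv)))
  subtreeEnd <- integer(nv)
  for (v in nv:1) {
    subtreeEnd[v] <- if (isLeaf[v]) v else max(subtreeEnd[childMat[v, ]])
  }
  structure(list(
    nv = nv, nTips = sum(isLeaf), parent = parent, children = childMat,
    isLeaf = isLeaf, label = lab, subtreeEnd = subtreeEnd,
    clade = character(nv)
  ), class = "dtlTree")
}

# canonical clade signature per vertex: sorted leaf labels of its subtree,
# joined by "|"; invariant under child swaps, used for canonical event keys
.addCladeKeys <- function(tr) {
  nv <- tr$nv
  leaves <- vector("list", nv)
  for (v in nv:1) {
    leaves[[v]] <- if (tr$isLeaf[v]) tr$label[v] else
      sort(c(leaves[[tr$children[v, 1L]]], leaves[[tr$children[v, 2L]]]))
  }
  tr$clade <- vapply(leaves, function(x) paste(x, collapse = "|"), character(1))
  tr
}

.isDtlTree <- function(x) inherits(x, "dtlTree")

# ancestor-or-equal in the preorder interval sense
.ancEq <- function(tr, a, b) a <= b & b <= tr$subtreeEnd[a]

.validTree <- function(tr) {
  msg <- character(0)
  if (!is.list(tr) || is.null(tr$nv)) return("not an indexed tree")
  if (tr$nv != 2L * tr$nTips - 1L)
    msg <- c(msg, sprintf("vertex count %d != 2*%d-1 (not binary)", tr$nv, tr$nTips))
  lab <- tr$label[tr$isLeaf]
  if (anyDuplicated(lab))
    msg <- c(msg, paste0("duplicate leaf label(s): ",
                         paste(unique(lab[duplicated(lab)]), collapse = ", ")))
  if (length(msg)) msg else TRUE
}

# Convert an ape phylo to the indexed form (validating binarity)
.indexPhylo <- function(phy) {
  nt <- length(phy$tip.label)
  nn <- phy$Nnode
  nv <- nt + nn
  children <- vector("list", nv)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; c <- phy$edge[i, 2L]
    children[[p]] <- c(children[[p]], c)
  }
  deg <- lengths(children)
  internal <- which(deg > 0L)
  bad <- internal[deg[internal] != 2L]
  if (length(bad)) {
    stop("tree is not binary: vertex ", bad[1L], " has ", deg[bad[1L]],
         " children (exactly 2 required)", call. = FALSE)
  }
  if (any(deg[seq_len(nt)] != 0L))
    stop("malformed tree: tip with children", call. = FALSE)
  rootVertex <- setdiff(seq_len(nv), phy$edge[, 2L])
  if (length(rootVertex) != 1L)
    stop("tree must have a single root", call. = FALSE)
  labels <- c(phy$tip.label, rep("", nn))
  .addCladeKeys(.indexFromChildren(children, labels, rootVertex))
}

#' Read a rooted binary tree from Newick
#'
#' Parses a rooted, strictly binary Newick tree.  Branch lengths and internal
#' labels are accepted and discarded (the DTL model used here is undated).  The
#' degenerate single-leaf tree (\code{"A;"} or \code{"(A);"}) is supported.
#'
#' @param file path to a Newick file, or \code{NULL} if \code{text} is given.
#' @param text a Newick string (used when \code{file} is \code{NULL}).
#' @return an indexed tree object (class \code{"dtlTree"}) with vertices
#'   numbered in preorder; use \code{\link{writeNewickTree}} to serialize.
#' @examples
#' tr <- readNewickTree(text = "((A,B),C);")
#' writeNewickTree(tr)
#' @export
readNewickTree <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'file' or 'text'")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  txt <- trimws(text)
  if (!nzchar(txt)) stop("malformed Newick: empty input", call. = FALSE)
  # degenerate single-leaf tree, which ape cannot represent
  m <- regmatches(txt, regexec("^\\(?([^(),:;]+?)(:[0-9.eE+-]+)?\\)?;?$", txt))[[1]]
  if (length(m)) {
    lab <- trimws(m[2])
    tr <- .indexFromChildren(list(NULL), lab, 1L)
    return(.addCladeKeys(tr))
  }
  phy <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(phy))
    stop("malformed Newick near: ", substr(txt, 1, 60), call. = FALSE)
  .indexPhylo(phy)
}

#' Serialize an indexed tree to Newick
#'
#' @param tree an indexed tree from \code{\link{readNewickTree}}.
#' @return a single Newick string (topology and leaf labels only).
#' @export
writeNewickTree <- function(tree) {
  stopifnot(.isDtlTree(tree))
  rec <- function(v) {
    if (tree$isLeaf[v]) return(tree$label[v])
    paste0("(", rec(tree$children[v, 1L]), ",", rec(tree$children[v, 2L]), ")")
  }
  paste0(rec(1L), ";")
}

#' Leaf labels of an indexed tree
#' @param tree an indexed tree.
#' @return character vector of leaf labels (preorder).
#' @export
treeLeaves <- function(tree) tree$label[tree$isLeaf]

# swap the children of the given internal vertices (test utility for
# child-order invariance); vertices given as preorder indices
.swapChildren <- function(tree, at) {
  children <- vector("list", tree$nv)
  for (v in seq_len(tree$nv)) {
    if (!tree$isLeaf[v]) {
      ch <- tree$children[v, ]
      if (v %in% at) ch <- rev(ch)
      children[[v]] <- ch
    }
  }
  .addCladeKeys(.indexFromChildren(children, tree$label, 1L))
}
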