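#' @import methods
NULL

setOldClass("dtlTree")

#' DTLInstance: a duplication-transfer-loss reconciliation problem
#'
#' Bundles a rooted binary species tree \eqn{S}, a rooted binary gene tree
#' \eqn{G}, a leaf-to-leaf mapping \eqn{\phi} (gene leaf to species leaf; need
#' not be one-to-one nor onto), and non-negative event costs for duplication,
#' transfer and loss.  Speciation is a null event of cost zero.
#'
#' @slot speciesTree,geneTree indexed trees (see \code{\link{readNewickTree}}).
#' @slot mapping named character vector: names are gene leaf labels, values
#'   species leaf labels.
#' @slot costs named numeric of length 3 with names \code{d}, \code{t},
#'   \code{l}.
#' @export
setClass("DTLInstance", representation(
  speciesTree = "dtlTree", geneTree = "dtlTree",
  mapping = "character", costs = "numeric"
))

setValidity("DTLInstance", function(object) {
  msg <- character(0)
  for (nm in c("speciesTree", "geneTree")) {
    v <- .validTree(slot(object, nm))
    if (!isTRUE(v)) msg <- c(msg, paste0(nm, ": ", v))
  }
  if (length(msg)) return(msg)
  gl <- treeLeaves(object@geneTree)
  sl <- treeLeaves(object@speciesTree)
  miss <- setdiff(gl, names(object@mapping))
  if (length(miss))
    msg <- c(msg, paste0("mapping is missing gene leaf/leaves: ",
                         paste(miss, collapse = ", ")))
  extra <- setdiff(names(object@mapping), gl)
  if (length(extra))
    msg <- c(msg, paste0("mapping names unknown gene leaf/leaves: ",
                         paste(extra, collapse = ", ")))
  badImg <- setdiff(object@mapping, sl)
  if (length(badImg))
    msg <- c(msg, paste0("mapping image is not a species leaf: ",
                         paste(badImg, collapse = ", ")))
  if (length(object@costs) != 3L ||
      !all(c("d", "t", "l") %in% names(object@costs)))
    msg <- c(msg, "costs must be a named numeric c(d=, t=, l=)")
  else if (any(object@costs < 0) || any(!is.finite(object@costs)))
    msg <- c(msg, paste0("event costs must be finite and non-negative, got: ",
                         paste(names(object@costs)[object@costs < 0 | !is.finite(object@costs)],
                               collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct and validate a DTLInstance
#'
#' @param speciesTree,geneTree indexed trees (from \code{\link{readNewickTree}})
#'   or Newick strings.
#' @param mapping named character vector (gene leaf -> species leaf) as
#'   returned by \code{\link{readLeafMapping}}.
#' @param costs numeric of length 3: duplication, transfer and loss costs, in
#'   that order (or named \code{d}, \code{t}, \code{l}).
#' @return a validated \code{DTLInstance}.
#' @examples
#' inst <- DTLInstance("((A,B),C);", "(a,c);", c(a = "A", c = "C"), c(1, 1, 1))
#' inst
#' @export
DTLInstance <- function(speciesTree, geneTree, mapping, costs) {
  if (is.character(speciesTree)) speciesTree <- readNewickTree(text = speciesTree)
  if (is.character(geneTree)) geneTree <- readNewickTree(text = geneTree)
  costs <- as.numeric(costs)
  if (is.null(names(costs)) || !all(c("d", "t", "l") %in% names(costs)))
    names(costs) <- c("d", "t", "l")
  costs <- costs[c("d", "t", "l")]
  new("DTLInstance", speciesTree = speciesTree, geneTree = geneTree,
      mapping = mapping, costs = costs)
}

#' Validate a DTLInstance
#'
#' Runs the class validity checks (mapping totality, image containment,
#' non-negative costs, binary trees) and returns the instance unchanged.
#' @param inst a \code{DTLInstance}.
#' @return \code{inst}, invisibly on success; errors otherwise.
#' @export
validateInstance <- function(inst) {
  validObject(inst)
  invisible(inst)
}

#' DPTables: the DTL dynamic-programming tables
#'
#' Rows are gene-tree vertices, columns species-tree vertices, both in
#' preorder.  \code{eventCost[g,s]} is the minimum cost of reconciling the
#' subtree of \eqn{g} given \eqn{g} is placed exactly at \eqn{s};
#' \code{descendCost[g,s]} additionally allows a loss chain descending from
#' \eqn{s}; \code{outsideCost[g,s]} is the cheapest placement of \eqn{g} at a
#' vertex incomparable to \eqn{s} (transfer recipients).  \code{optCost} is the
#' MPR cost.
#' @export
setClass("DPTables", representation(
  eventCost = "matrix", descendCost = "matrix", outsideCost = "matrix",
  optCost = "numeric"
))

#' ReconGraph: the DAG of all maximum parsimony reconciliations
#'
#' Mapping nodes are (gene vertex, species vertex) pairs; event nodes are
#' speciation/duplication/transfer/loss/contemporaneous tuples.  Every
#' root-to-sink traversal (one event child per mapping node, all mapping
#' children per event node) is an MPR, and every MPR appears as exactly one
#' traversal.
#'
#' @slot instance the \code{DTLInstance} the graph was built from.
#' @slot mapG,mapS integer vectors: gene/species preorder index per mapping
#'   node.
#' @slot evType integer code per event node (1=S, 2=D, 3=T, 4=L, 5=C).
#' @slot evParent parent mapping node of each event node.
#' @slot evC1,evC2 mapping-node children of each event node (0 = none).
#' @slot evCost numeric event cost.
#' @slot mapEvPtr,mapEvIdx CSR adjacency mapping node -> event children.
#' @slot mapParPtr,mapParIdx CSR adjacency mapping node -> event parents.
#' @slot sources mapping nodes of the form (root(G), s) achieving the optimum.
#' @slot mapOrder topological order of mapping nodes (ancestors first).
#' @slot optCost the MPR cost.
#' @export
setClass("ReconGraph", representation(
  instance = "DTLInstance",
  mapG = "integer", mapS = "integer",
  evType = "integer", evParent = "integer",
  evC1 = "integer", evC2 = "integer", evCost = "numeric",
  mapEvPtr = "integer", mapEvIdx = "integer",
  mapParPtr = "integer", mapParIdx = "integer",
  sources = "integer", mapOrder = "integer",
  optCost = "numeric"
))

#' ReconSubgraph: a union of traversals of a ReconGraph
#'
#' Represents a cluster of MPRs (or the full MPR space) as node-membership
#' masks over a fixed parent \code{ReconGraph}; edges are inherited.
#' @slot graph the parent \code{ReconGraph}.
#' @slot mapMember,evMember logical membership masks.
#' @slot sources included source mapping nodes.
#' @export
setClass("ReconSubgraph", representation(
  graph = "ReconGraph", mapMember = "logical", evMember = "logical",
  sources = "integer"
))

setValidity("ReconSubgraph", function(object) {
  g <- object@graph
  if (length(object@mapMember) != length(g@mapG)) return("mapMember length mismatch")
  if (length(object@evMember) != length(g@evType)) return("evMember length mismatch")
  if (!all(object@sources %in% g@sources)) return("sources not sources of the parent graph")
  if (!all(object@mapMember[object@sources])) return("source not a member")
  TRUE
})

#' SubgraphStats: cached statistics of a reconciliation subgraph
#'
#' @slot mprCount number of traversals T (exact for T < 2^53).
#' @slot belowMap,belowEv completions beneath each mapping/event node.
#' @slot eventCount traversals containing each event node, c(e).
#' @slot support c(e)/T per event node (NA outside the subgraph).
#' @slot meanSupport mean support over non-contemporaneous member events.
#' @slot meanPairDist mean pairwise symmetric distance between member MPRs.
#' @export
setClass("SubgraphStats", representation(
  mprCount = "numeric", belowMap = "numeric", belowEv = "numeric",
  eventCount = "numeric", support = "numeric",
  meanSupport = "numeric", meanPairDist = "numeric"
))

#' Traversal: one MPR as a set of event nodes
#'
#' @slot graph the parent \code{ReconGraph}.
#' @slot eventNodes sorted integer ids of the event nodes E(R).
#' @slot rootNode the source mapping node used.
#' @export
setClass("Traversal", representation(
  graph = "ReconGraph", eventNodes = "integer", rootNode = "integer"
))

#' MPRCluster: a reconciliation subgraph plus its statistics
#' @slot subgraph a \code{ReconSubgraph}.
#' @slot stats the \code{SubgraphStats} of that subgraph.
#' @export
setClass("MPRCluster", representation(
  subgraph = "ReconSubgraph", stats = "SubgraphStats"
))

#' MPRClustering: a set of clusters of MPR space
#' @slot clusters list of \code{MPRCluster}.
#' @slot level the subtraversal depth L used for initialization.
#' @export
setClass("MPRClustering", representation(
  clusters = "list", level = "integer"
))

setValidity("MPRClustering", function(object) {
  if (length(object@clusters) < 1L) return("a clustering has at least 1 cluster")
  if (!all(vapply(object@clusters, is, logical(1), "MPRCluster")))
    return("clusters must be MPRCluster objects")
  TRUE
})

#' MergeHistory: the full agglomeration record
#'
#' @slot initialN number of initial clusters N.
#' @slot criterion "support" or "distance".
#' @slot merges data.frame with one row per merge (k before the merge, the
#'   indices of the merged pair in creation order, pair and merged WAS/WAD,
#'   local improvements).
#' @slot perK data.frame with one row per clustering size k (N..1): WAS, WAD.
#' @slot clusterStats list (by k) of per-cluster data.frames (size, sigma, mu).
#' @slot complete FALSE if a timeout truncated the agglomeration.
#' @slot kept list of retained \code{MPRClustering} snapshots, named by k.
#' @export
setClass("MergeHistory", representation(
  initialN = "integer", criterion = "character",
  merges = "data.frame", perK = "data.frame", clusterStats = "list",
  complete = "logical", kept = "list"
))

setValidity("MergeHistory", function(object) {
  if (object@complete && nrow(object@merges) != object@initialN - 1L)
    return("a complete history has exactly N-1 merges")
  TRUE
})
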