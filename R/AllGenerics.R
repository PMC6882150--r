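#' Accessors for DTLInstance components
#' @param x a \code{DTLInstance}.
#' @return the corresponding component.
#' @name instance-accessors
NULL

#' @rdname instance-accessors
#' @export
setGeneric("speciesTree", function(x) standardGeneric("speciesTree"))
#' @rdname instance-accessors
#' @export
setGeneric("geneTree", function(x) standardGeneric("geneTree"))
#' @rdname instance-accessors
#' @export
setGeneric("leafMapping", function(x) standardGeneric("leafMapping"))
#' @rdname instance-accessors
#' @export
setGeneric("eventCosts", function(x) standardGeneric("eventCosts"))

setMethod("speciesTree", "DTLInstance", function(x) x@speciesTree)
setMethod("geneTree", "DTLInstance", function(x) x@geneTree)
setMethod("leafMapping", "DTLInstance", function(x) x@mapping)
setMethod("eventCosts", "DTLInstance", function(x) x@costs)

#' Optimal (maximum parsimony) reconciliation cost
#' @param x a \code{DPTables}, \code{ReconGraph} or \code{ReconSubgraph}.
#' @return the minimum total event cost over all reconciliations.
#' @export
setGeneric("optCost", function(x) standardGeneric("optCost"))
setMethod("optCost", "DPTables", function(x) x@optCost)
setMethod("optCost", "ReconGraph", function(x) x@optCost)
setMethod("optCost", "ReconSubgraph", function(x) x@graph@optCost)

#' Number of maximum parsimony reconciliations
#' @param x a \code{ReconGraph}, \code{ReconSubgraph}, \code{MPRCluster} or
#'   \code{SubgraphStats}.
#' @return the number of MPRs (traversals), exact below 2^53.
#' @export
setGeneric("mprCount", function(x) standardGeneric("mprCount"))

#' Sources of a reconciliation (sub)graph
#' @param x a \code{ReconGraph} or \code{ReconSubgraph}.
#' @return integer ids of the source mapping nodes.
#' @export
setGeneric("sourceNodes", function(x) standardGeneric("sourceNodes"))
setMethod("sourceNodes", "ReconGraph", function(x) x@sources)
setMethod("sourceNodes", "ReconSubgraph", function(x) x@sources)

#' @describeIn instance-accessors compact display methods
#' @param object object to display
#' @aliases show,DTLInstance-method show,ReconGraph-method
#'   show,ReconSubgraph-method show,Traversal-method show,MPRCluster-method
#'   show,MPRClustering-method show,MergeHistory-method
#' @exportMethod show
setMethod("show", "DTLInstance", function(object) {
  cat("DTLInstance\n",
      "  species tree: ", object@speciesTree$nTips, " leaves\n",
      "  gene tree:    ", object@geneTree$nTips, " leaves\n",
      "  costs: d=", object@costs[["d"]], " t=", object@costs[["t"]],
      " l=", object@costs[["l"]], "\n", sep = "")
})

setMethod("show", "ReconGraph", function(object) {
  cat("ReconGraph: ", length(object@mapG), " mapping nodes, ",
      length(object@evType), " event nodes, ",
      length(object@sources), " source(s); MPR cost ", object@optCost,
      "\n", sep = "")
})

setMethod("show", "ReconSubgraph", function(object) {
  cat("ReconSubgraph: ", sum(object@mapMember), "/", length(object@mapMember),
      " mapping nodes, ", sum(object@evMember), "/", length(object@evMember),
      " event nodes, ", length(object@sources), " source(s)\n", sep = "")
})

setMethod("show", "Traversal", function(object) {
  cat("Traversal (one MPR): ", length(object@eventNodes),
      " event nodes, total cost ",
      sum(object@graph@evCost[object@eventNodes]), "\n", sep = "")
})

setMethod("show", "MPRCluster", function(object) {
  cat("MPRCluster: |C|=", format(object@stats@mprCount),
      ", sigma=", signif(object@stats@meanSupport, 4),
      ", mu=", signif(object@stats@meanPairDist, 4), "\n", sep = "")
})

setMethod("show", "MPRClustering", function(object) {
  cat("MPRClustering with k=", length(object@clusters),
      " cluster(s) (initial level L=", object@level, ")\n", sep = "")
  sizes <- vapply(object@clusters, function(cl) cl@stats@mprCount, numeric(1))
  cat("  cluster sizes:", paste(format(sizes), collapse = ", "), "\n")
})

setMethod("show", "MergeHistory", function(object) {
  cat("MergeHistory: N=", object@initialN, " initial clusters, criterion '",
      object@criterion, "', ", nrow(object@merges), " merge(s)",
      if (!object@complete) " [truncated by timeout]", "\n", sep = "")
})
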