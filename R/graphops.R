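# Algebra over reconciliation (sub)graphs: counting, supports, distances,
# medians, sampling, enumeration, closure and union.
#
# All statistics are defined over a ReconSubgraph; a full ReconGraph is lifted
# with fullSubgraph().  Contemporaneous (C) events are present in every MPR of
# every subgraph, so by default they are excluded from mean support, mean
# pairwise distance and median weights (they contribute support identically 1
# and distance identically 0); includeContemporaneous = TRUE restores them in
# the support mean.

#' Lift a reconciliation graph to its full subgraph
#' @param graph a \code{ReconGraph}.
#' @return a \code{ReconSubgraph} containing every node.
#' @export
fullSubgraph <- function(graph) {
  new("ReconSubgraph", graph = graph,
      mapMember = rep(TRUE, length(graph@mapG)),
      evMember = rep(TRUE, length(graph@evType)),
      sources = graph@sources)
}

.asSubgraph <- function(x) {
  if (is(x, "ReconGraph")) fullSubgraph(x)
  else if (is(x, "ReconSubgraph")) x
  else if (is(x, "MPRCluster")) x@subgraph
  else stop("expected a ReconGraph, ReconSubgraph or MPRCluster")
}

#' Compute (and cache) the counting statistics of a subgraph
#'
#' Two-pass completion counting: \code{belowMap}/\code{belowEv} count partial
#' traversals beneath a node, \code{aboveMap} counts completions above, and
#' the number of traversals containing event node e is
#' \code{c(e) = above(e) * prod(below of children)}.  The mean pairwise
#' symmetric distance uses the per-event decomposition: event e separates
#' exactly \code{c(e) * (T - c(e))} unordered pairs of MPRs.
#'
#' @param x a \code{ReconGraph}, \code{ReconSubgraph} or \code{MPRCluster}.
#' @param includeContemporaneous include C events in the support mean.
#' @return a \code{SubgraphStats}.
#' @export
subgraphStats <- function(x, includeContemporaneous = FALSE) {
  if (is(x, "MPRCluster")) return(x@stats)
  sub <- .asSubgraph(x)
  g <- sub@graph
  res <- cpp_subgraph_stats(g@mapEvPtr, g@mapEvIdx, g@evC1, g@evC2, g@evType,
                            sub@mapMember, sub@evMember, sub@sources,
                            g@mapOrder)
  T <- res$mprCount
  if (T >= 2^53)
    warning("MPR count exceeds 2^53; counts are correctly rounded doubles, ",
            "no longer exact integers")
  support <- ifelse(sub@evMember, res$eventCount / T, NA_real_)
  meanSupport <- res$meanSupport
  if (includeContemporaneous) {
    keep <- sub@evMember
    meanSupport <- mean(support[keep])
  }
  new("SubgraphStats", mprCount = T, belowMap = res$belowMap,
      belowEv = res$belowEv, eventCount = res$eventCount, support = support,
      meanSupport = meanSupport, meanPairDist = res$meanPairDist)
}

setMethod("mprCount", "SubgraphStats", function(x) x@mprCount)
setMethod("mprCount", "ReconSubgraph", function(x) subgraphStats(x)@mprCount)
setMethod("mprCount", "ReconGraph", function(x) subgraphStats(x)@mprCount)
setMethod("mprCount", "MPRCluster", function(x) x@stats@mprCount)

#' Event support values of a subgraph
#'
#' The support (frequency) of an event node is the fraction of the subgraph's
#' MPRs that include it.
#' @param x a \code{ReconGraph}, \code{ReconSubgraph} or \code{MPRCluster}.
#' @param stats optional precomputed \code{SubgraphStats}.
#' @return numeric vector over all event nodes of the parent graph: support in
#'   (0, 1] for member events, NA outside the subgraph.
#' @export
eventSupport <- function(x, stats = subgraphStats(x)) stats@support

#' Mean event support of a subgraph
#'
#' Unweighted mean of support over the subgraph's non-contemporaneous event
#' nodes; defined as 1 for subgraphs whose MPRs consist only of
#' contemporaneous leaf associations.
#' @inheritParams eventSupport
#' @return a number in (0, 1].
#' @export
meanSupport <- function(x, stats = subgraphStats(x)) stats@meanSupport

#' Mean pairwise symmetric distance of a subgraph
#'
#' Average over all unordered pairs of the subgraph's MPRs of the symmetric
#' distance |E(R1) xor E(R2)|; 0 when the subgraph holds fewer than 2 MPRs.
#' @inheritParams eventSupport
#' @return a non-negative number.
#' @export
meanPairwiseDistance <- function(x, stats = subgraphStats(x)) stats@meanPairDist

#' Median traversal of a subgraph
#'
#' Returns a traversal minimizing the summed symmetric distance to all MPRs in
#' the subgraph, computed by maximizing the sum of \code{c(e) - T/2} over the
#' chosen non-contemporaneous events with a best-choice DP.  Ties are broken
#' deterministically toward canonically smaller event nodes and sources.
#' @inheritParams eventSupport
#' @return a \code{Traversal}.
#' @export
medianTraversal <- function(x, stats = subgraphStats(x)) {
  sub <- .asSubgraph(x)
  g <- sub@graph
  res <- cpp_median(g@mapEvPtr, g@mapEvIdx, g@evC1, g@evC2, g@evType,
                    sub@mapMember, sub@evMember, sub@sources, g@mapOrder,
                    stats@eventCount, stats@mprCount)
  new("Traversal", graph = g, eventNodes = as.integer(res$events),
      rootNode = as.integer(res$root))
}

#' Sample traversals uniformly at random
#'
#' Draws i.i.d. uniform MPRs from the subgraph by the weighted backtrace: the
#' source is chosen with probability below/T and each event child with
#' probability proportional to its completion count.  Uses R's RNG, so wrap in
#' \code{set.seed()} for reproducibility.
#' @param x a \code{ReconGraph}, \code{ReconSubgraph} or \code{MPRCluster}.
#' @param count number of samples (positive).
#' @param stats optional precomputed \code{SubgraphStats}.
#' @return list of \code{Traversal} objects.
#' @export
sampleTraversals <- function(x, count, stats = subgraphStats(x)) {
  if (!is.numeric(count) || count <= 0)
    stop("'count' must be a positive integer")
  sub <- .asSubgraph(x)
  g <- sub@graph
  raw <- cpp_sample(g@mapEvPtr, g@mapEvIdx, g@evC1, g@evC2,
                    sub@mapMember, sub@evMember, sub@sources,
                    stats@belowMap, stats@belowEv, stats@mprCount,
                    as.integer(count))
  lapply(raw, function(evs) {
    evs <- as.integer(evs)
    # the root is the unique source among the event parents
    root <- intersect(g@evParent[evs], sub@sources)[1L]
    new("Traversal", graph = g, eventNodes = evs, rootNode = as.integer(root))
  })
}

#' Enumerate all traversals of a subgraph
#'
#' Exhaustive, for oracle-scale subgraphs only: refuses if the subgraph holds
#' more than \code{limit} MPRs.
#' @param x a \code{ReconGraph}, \code{ReconSubgraph} or \code{MPRCluster}.
#' @param limit maximum number of traversals to materialize.
#' @param stats optional precomputed \code{SubgraphStats}.
#' @return list of \code{Traversal} objects, in deterministic order.
#' @export
enumerateTraversals <- function(x, limit = 1e4, stats = subgraphStats(x)) {
  sub <- .asSubgraph(x)
  g <- sub@graph
  T <- stats@mprCount
  if (T > limit)
    stop("subgraph holds ", format(T), " traversals, above the limit of ",
         format(limit))
  evKids <- function(m) {
    if (g@mapEvPtr[m + 1L] == g@mapEvPtr[m]) return(integer(0))
    evs <- g@mapEvIdx[(g@mapEvPtr[m] + 1L):g@mapEvPtr[m + 1L]]
    evs[sub@evMember[evs]]
  }
  trav <- list()
  for (r in sub@sources) {
    acc <- list()
    # expand mapping nodes one at a time, depth-first over choice combinations
    expand <- function(frontier, evs) {
      if (!length(frontier)) {
        acc[[length(acc) + 1L]] <<- sort(evs)
        return(invisible())
      }
      m <- frontier[1L]
      rest <- frontier[-1L]
      for (e in evKids(m)) {
        kids <- c(g@evC1[e], g@evC2[e])
        kids <- kids[kids > 0L]
        expand(c(rest, kids), c(evs, e))
      }
      invisible()
    }
    expand(r, integer(0))
    trav <- c(trav, lapply(acc, function(evs)
      new("Traversal", graph = g, eventNodes = as.integer(evs),
          rootNode = as.integer(r))))
  }
  trav
}

#' Closure of a prefix plus frontier into a reconciliation subgraph
#'
#' Includes the given prefix nodes and everything reachable from the frontier
#' mapping nodes, with all full-graph edges among included nodes.  Used to
#' turn a subtraversal into an initial cluster.
#' @param graph a \code{ReconGraph}.
#' @param frontier integer ids of frontier mapping nodes.
#' @param prefixMap,prefixEv integer ids of prefix mapping/event nodes.
#' @return a \code{ReconSubgraph}.
#' @export
closureFrom <- function(graph, frontier, prefixMap = integer(0),
                        prefixEv = integer(0)) {
  res <- cpp_closure(graph@mapEvPtr, graph@mapEvIdx, graph@evC1, graph@evC2,
                     as.integer(frontier), as.integer(prefixMap),
                     as.integer(prefixEv),
                     length(graph@mapG), length(graph@evType))
  srcs <- graph@sources[res$mapMember[graph@sources]]
  new("ReconSubgraph", graph = graph, mapMember = res$mapMember,
      evMember = res$evMember, sources = as.integer(srcs))
}

#' Union of two reconciliation subgraphs
#'
#' Node-set and edge-set union (edges are inherited from the shared parent
#' graph); sources are the union of sources.  The union can contain MPRs
#' absent from both operands.
#' @param a,b \code{ReconSubgraph}s of the same \code{ReconGraph}.
#' @return a \code{ReconSubgraph}.
#' @export
graphUnion <- function(a, b) {
  a <- .asSubgraph(a); b <- .asSubgraph(b)
  if (!identical(a@graph@mapG, b@graph@mapG) ||
      !identical(a@graph@optCost, b@graph@optCost) ||
      length(a@evMember) != length(b@evMember))
    stop("subgraphs belong to different reconciliation graphs")
  new("ReconSubgraph", graph = a@graph,
      mapMember = a@mapMember | b@mapMember,
      evMember = a@evMember | b@evMember,
      sources = sort(union(a@sources, b@sources)))
}

#' Total event cost of a traversal
#' @param x a \code{Traversal}.
#' @return the summed event cost (equals the MPR cost of the instance).
#' @export
traversalCost <- function(x) sum(x@graph@evCost[x@eventNodes])

#' Does a subgraph contain a traversal?
#' @param x a \code{ReconSubgraph} (or graph/cluster).
#' @param traversal a \code{Traversal} of the same parent graph.
#' @return logical.
#' @export
containsTraversal <- function(x, traversal) {
  sub <- .asSubgraph(x)
  all(sub@evMember[traversal@eventNodes])
}
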