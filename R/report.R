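# Serialization and reporting: reconciliation graph JSON, traversal reports,
# merge-history JSON/CSV round-trip, and distance histograms.

#' @importFrom jsonlite write_json read_json toJSON
NULL

.evLabel <- function(graph, e) {
  paste0(.EVTYPES[graph@evType[e]], "_(", graph@mapG[graph@evParent[e]], ",",
         graph@mapS[graph@evParent[e]], ")")
}

# numbers that may be Inf: serialize the sentinel as "inf"
.numOrInf <- function(x) {
  if (length(x) == 1L) {
    if (is.infinite(x)) return("inf")
    return(x)
  }
  lapply(x, .numOrInf)
}

#' Serialize a reconciliation graph to JSON
#'
#' Writes the node lists (mapping nodes, event nodes with type tags and
#' association lists), adjacency and sources, for debugging and
#' cross-implementation comparison.
#' @param graph a \code{ReconGraph}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeReconGraphJSON <- function(graph, file) {
  nEv <- length(graph@evType)
  evs <- lapply(seq_len(nEv), function(e) {
    assoc <- list()
    for (c in c(graph@evC1[e], graph@evC2[e])) {
      if (c > 0L) assoc[[length(assoc) + 1L]] <-
          c(g = graph@mapG[c], s = graph@mapS[c])
    }
    list(id = e, type = .EVTYPES[graph@evType[e]],
         g = graph@mapG[graph@evParent[e]], s = graph@mapS[graph@evParent[e]],
         associations = assoc, cost = graph@evCost[e])
  })
  maps <- lapply(seq_along(graph@mapG), function(m) {
    evIdx <- .evChildrenOf(graph, m)
    list(id = m, g = graph@mapG[m], s = graph@mapS[m], events = as.list(evIdx))
  })
  doc <- list(optCost = graph@optCost,
              sources = as.list(graph@sources),
              mappingNodes = maps, eventNodes = evs)
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Text report of one reconciliation
#'
#' One line per gene vertex with its species placement and event type, plus
#' one line per loss.  Vertices are named by leaf label where available, else
#' by preorder index.
#' @param traversal a \code{Traversal}.
#' @return character vector of report lines.
#' @export
traversalReport <- function(traversal) {
  g <- traversal@graph
  inst <- g@instance
  gt <- geneTree(inst); st <- speciesTree(inst)
  vn <- function(tr, v) if (nzchar(tr$label[v])) tr$label[v] else paste0("v", v)
  evs <- traversal@eventNodes
  typ <- g@evType[evs]
  lines <- character(0)
  for (i in order(g@mapG[g@evParent[evs]], g@mapS[g@evParent[evs]], typ)) {
    e <- evs[i]
    gp <- g@evParent[e]
    gv <- vn(gt, g@mapG[gp]); sv <- vn(st, g@mapS[gp])
    lines <- c(lines, switch(.EVTYPES[typ[i]],
      S = paste0("gene ", gv, " -> species ", sv, " : speciation"),
      D = paste0("gene ", gv, " -> species ", sv, " : duplication"),
      T = {
        c2 <- g@evC2[e]
        paste0("gene ", gv, " -> species ", sv, " : transfer (recipient ",
               vn(gt, g@mapG[c2]), " -> ", vn(st, g@mapS[c2]), ")")
      },
      L = paste0("gene ", gv, " passes species ", sv, " : loss"),
      C = paste0("gene ", gv, " -> species ", sv, " : contemporaneous leaf")
    ))
  }
  lines
}

#' Traversal as a JSON event-tuple list
#' @param traversal a \code{Traversal}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeTraversalJSON <- function(traversal, file) {
  g <- traversal@graph
  evs <- lapply(traversal@eventNodes, function(e) {
    assoc <- list()
    for (c in c(g@evC1[e], g@evC2[e])) {
      if (c > 0L) assoc[[length(assoc) + 1L]] <- c(g = g@mapG[c], s = g@mapS[c])
    }
    list(type = .EVTYPES[g@evType[e]], g = g@mapG[g@evParent[e]],
         s = g@mapS[g@evParent[e]], associations = assoc)
  })
  jsonlite::write_json(list(cost = traversalCost(traversal), events = evs),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a merge history as JSON and per-k CSV
#'
#' The JSON carries the whole record (merge tree, per-k statistics,
#' per-cluster statistics); the CSV has one row per k with WAS, WAD, the
#' improvement score for the history's criterion and the local improvement.
#' Infinite scores are serialized as the string \code{"inf"}.
#' @param history a \code{MergeHistory}.
#' @param jsonFile,csvFile output paths (either may be \code{NULL} to skip).
#' @return invisibly, a list of the paths written.
#' @export
writeMergeHistory <- function(history, jsonFile = NULL, csvFile = NULL) {
  if (!is.null(jsonFile)) {
    doc <- list(
      initialN = history@initialN,
      criterion = history@criterion,
      complete = history@complete,
      merges = history@merges,
      perK = history@perK,
      clusterStats = history@clusterStats
    )
    doc$merges$localWAS <- .numOrInf(doc$merges$localWAS)
    doc$merges$localWAD <- .numOrInf(doc$merges$localWAD)
    jsonlite::write_json(doc, jsonFile, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  if (!is.null(csvFile)) {
    utils::write.csv(perKTable(history), csvFile, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(list(json = jsonFile, csv = csvFile))
}

#' Per-k summary table of a merge history
#'
#' @param history a complete \code{MergeHistory}.
#' @return data.frame with columns k, WAS, WAD, improvement,
#'   local_improvement (the last is NA at k = N and k = 1 has no merge ...
#'   local improvement is defined for the k that a merge reduced).
#' @export
perKTable <- function(history) {
  pk <- history@perK[order(-history@perK$k), ]
  imp <- vapply(pk$k, function(k)
    if (1 %in% history@perK$k) improvement(history, k) else NA_real_,
    numeric(1))
  loc <- vapply(pk$k, function(k) {
    row <- history@merges[history@merges$k == k, ]
    if (nrow(row) == 1L) {
      if (history@criterion == "support") row$localWAS else row$localWAD
    } else NA_real_
  }, numeric(1))
  fmt <- function(x) ifelse(is.infinite(x), "inf",
                            trimws(format(x, digits = 12, trim = TRUE)))
  data.frame(k = pk$k, WAS = pk$was, WAD = pk$wad,
             improvement = fmt(imp), local_improvement = fmt(loc))
}

#' Read a merge history back from its JSON serialization
#' @param jsonFile path written by \code{\link{writeMergeHistory}}.
#' @return a \code{MergeHistory} (statistics only; subgraphs are not
#'   serialized).
#' @export
readMergeHistory <- function(jsonFile) {
  doc <- jsonlite::read_json(jsonFile, simplifyVector = TRUE)
  fromInf <- function(x) {
    if (is.list(x)) x <- unlist(x)
    as.numeric(ifelse(x == "inf", Inf, suppressWarnings(as.numeric(x))))
  }
  merges <- as.data.frame(doc$merges)
  if (nrow(merges)) {
    merges$localWAS <- fromInf(merges$localWAS)
    merges$localWAD <- fromInf(merges$localWAD)
  }
  cs <- lapply(doc$clusterStats, as.data.frame)
  new("MergeHistory", initialN = as.integer(doc$initialN),
      criterion = doc$criterion, merges = merges,
      perK = as.data.frame(doc$perK), clusterStats = cs,
      complete = doc$complete, kept = list())
}

#' Pairwise symmetric-distance histogram of a subgraph
#'
#' For small spaces (MPR count at most \code{maxEnumerate}) the distances of
#' all unordered pairs are enumerated exactly; otherwise \code{samples}
#' traversals are drawn uniformly (seed the RNG beforehand) and the distances
#' of all their pairs are used.
#' @param x a \code{ReconGraph}, \code{ReconSubgraph} or \code{MPRCluster}.
#' @param maxEnumerate exact-enumeration threshold on the MPR count.
#' @param samples number of sampled traversals beyond that threshold.
#' @param breaks number of histogram bins (passed to \code{hist}).
#' @return data.frame with columns lower, upper, count.
#' @export
distanceHistogram <- function(x, maxEnumerate = 200L, samples = 1000L,
                              breaks = 20L) {
  sub <- .asSubgraph(x)
  stats <- subgraphStats(sub)
  travs <- if (stats@mprCount <= maxEnumerate)
    enumerateTraversals(sub, limit = maxEnumerate, stats = stats)
  else
    sampleTraversals(sub, samples, stats = stats)
  sets <- lapply(travs, function(t) t@eventNodes)
  nT <- length(sets)
  if (nT < 2L)
    return(data.frame(lower = numeric(0), upper = numeric(0),
                      count = integer(0)))
  dists <- numeric(nT * (nT - 1L) / 2L)
  k <- 0L
  for (i in seq_len(nT - 1L)) {
    for (j in (i + 1L):nT) {
      k <- k + 1L
      dists[k] <- length(sets[[i]]) + length(sets[[j]]) -
        2L * sum(sets[[i]] %in% sets[[j]])
    }
  }
  h <- graphics::hist(dists, breaks = breaks, plot = FALSE)
  data.frame(lower = utils::head(h$breaks, -1L),
             upper = utils::tail(h$breaks, -1L), count = h$counts)
}
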