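# Initial cluster construction from depth-L subtraversals and agglomerative
# merging under weighted-average-support (WAS) or weighted-average-distance
# (WAD) linkage, with improvement diagnostics.

# ---- subtraversals -------------------------------------------------------

# a subtraversal is list(map=, ev=, frontier=, source=): the partial traversal
# grown L expansion rounds from one source; frontier holds its mapping-node
# leaves that are not yet closed by a contemporaneous event

.levelZero <- function(graph) {
  lapply(graph@sources, function(s)
    list(map = s, ev = integer(0), frontier = s, source = s))
}

.evChildrenOf <- function(graph, m) {
  if (graph@mapEvPtr[m + 1L] == graph@mapEvPtr[m]) return(integer(0))
  graph@mapEvIdx[(graph@mapEvPtr[m] + 1L):graph@mapEvPtr[m + 1L]]
}

# number of subtraversals the next expansion round would produce
.nextLevelCount <- function(graph, subs) {
  total <- 0
  for (st in subs) {
    nOpt <- 1
    for (m in st$frontier) {
      evs <- .evChildrenOf(graph, m)
      if (length(evs) == 1L && graph@evType[evs] == 5L) next # closed by C
      nOpt <- nOpt * length(evs)
    }
    total <- total + nOpt
  }
  total
}

.allComplete <- function(graph, subs) {
  for (st in subs) {
    for (m in st$frontier) {
      evs <- .evChildrenOf(graph, m)
      if (!(length(evs) == 1L && graph@evType[evs] == 5L)) return(FALSE)
    }
  }
  TRUE
}

# one expansion round: close C frontier nodes, then take the cartesian
# product of event choices over the expandable frontier
.expandLevel <- function(graph, subs) {
  out <- vector("list", 0L)
  for (st in subs) {
    closedEv <- integer(0)
    expandable <- integer(0)
    options <- list()
    for (m in st$frontier) {
      evs <- .evChildrenOf(graph, m)
      if (length(evs) == 1L && graph@evType[evs] == 5L) {
        closedEv <- c(closedEv, evs)
      } else {
        expandable <- c(expandable, m)
        options[[length(options) + 1L]] <- evs
      }
    }
    base <- st
    base$ev <- c(base$ev, closedEv)
    if (!length(expandable)) {
      base$frontier <- integer(0) # complete: carried forward unchanged
      out[[length(out) + 1L]] <- base
      next
    }
    # cartesian product over per-node event choices
    idx <- rep(1L, length(options))
    repeat {
      chosen <- vapply(seq_along(options),
                       function(i) options[[i]][idx[i]], integer(1))
      kids <- c(graph@evC1[chosen], graph@evC2[chosen])
      kids <- kids[kids > 0L]
      out[[length(out) + 1L]] <- list(
        map = c(base$map, kids),
        ev = c(base$ev, chosen),
        frontier = kids,
        source = base$source
      )
      j <- length(options)
      repeat {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= length(options[[j]])) break
        idx[j] <- 1L
        j <- j - 1L
        if (j == 0L) break
      }
      if (j == 0L) break
    }
  }
  out
}

#' Subtraversals at a given level
#'
#' Level 0 is one subtraversal per source.  Level i+1 extends every level-i
#' subtraversal by choosing one event child for each expandable frontier
#' mapping node (all combinations); frontier nodes whose only child is a
#' contemporaneous event are closed.  At the largest possible level the
#' subtraversals are complete traversals, one per MPR.
#'
#' @param graph a \code{ReconGraph}.
#' @param L level (non-negative integer).
#' @return list of subtraversals, each a list with elements \code{map},
#'   \code{ev}, \code{frontier}, \code{source} (integer node ids).
#' @export
subtraversalsAtLevel <- function(graph, L) {
  stopifnot(L >= 0)
  subs <- .levelZero(graph)
  i <- 0L
  while (i < L) {
    subs <- .expandLevel(graph, subs)
    i <- i + 1L
  }
  subs
}

# ---- initial clustering --------------------------------------------------

.clusterFromSubtraversal <- function(graph, st) {
  sub <- closureFrom(graph, frontier = st$frontier, prefixMap = st$map,
                     prefixEv = st$ev)
  new("MPRCluster", subgraph = sub, stats = subgraphStats(sub))
}

#' Construct the initial clustering from depth-L subtraversals
#'
#' Finds the smallest level L whose subtraversal count reaches
#' \code{minClusters} (or the largest feasible level if it is never reached),
#' refusing or falling back to the previous level when a level would exceed
#' \code{cap} clusters, and closes each subtraversal into a reconciliation
#' subgraph.  The initial clusters partition MPR space: every MPR lies in
#' exactly one of them.
#'
#' @param graph a \code{ReconGraph}.
#' @param minClusters desired minimum number of initial clusters.
#' @param cap maximum number of initial clusters tolerated.
#' @param strict if \code{TRUE}, exceeding \code{cap} is an error; otherwise
#'   the previous level is used (so fewer than \code{minClusters} clusters may
#'   result).
#' @return an \code{MPRClustering}; its \code{level} slot records L and the
#'   number of clusters N is \code{length(clusters(x))}.
#' @export
initialClusters <- function(graph, minClusters = 25L, cap = 200L,
                            strict = FALSE) {
  stopifnot(minClusters >= 1L, cap >= minClusters)
  subs <- .levelZero(graph)
  level <- 0L
  if (length(subs) > cap)
    warning("the reconciliation graph has ", length(subs),
            " sources, already above the cap of ", cap)
  while (length(subs) < minClusters && !.allComplete(graph, subs)) {
    nxt <- .nextLevelCount(graph, subs)
    if (nxt > cap) {
      if (strict)
        stop("level ", level + 1L, " would produce ", nxt,
             " initial clusters, above the cap of ", cap,
             " (level ", level, " has ", length(subs), ")")
      break # fall back: stay at the current level
    }
    subs <- .expandLevel(graph, subs)
    level <- level + 1L
  }
  clusters <- lapply(subs, function(st) .clusterFromSubtraversal(graph, st))
  new("MPRClustering", clusters = clusters, level = level)
}

#' Clusters of an MPRClustering
#' @param x an \code{MPRClustering}.
#' @return list of \code{MPRCluster}.
#' @export
clusters <- function(x) x@clusters

# ---- linkage objectives --------------------------------------------------

.clusterSizes <- function(cl) vapply(cl, function(x) x@stats@mprCount, numeric(1))
.clusterSigma <- function(cl) vapply(cl, function(x) x@stats@meanSupport, numeric(1))
.clusterMu <- function(cl) vapply(cl, function(x) x@stats@meanPairDist, numeric(1))

.asClusterList <- function(x) {
  if (is(x, "MPRClustering")) x@clusters
  else if (is.list(x)) x
  else stop("expected an MPRClustering or a list of MPRCluster")
}

#' Weighted average support of a clustering
#'
#' \eqn{WAS = \sum_i |C_i| \sigma_i / \sum_i |C_i|}, where \eqn{|C_i|} is the
#' MPR count and \eqn{\sigma_i} the mean event support of cluster i.
#' @param x an \code{MPRClustering} or list of \code{MPRCluster}.
#' @return a number in (0, 1].
#' @export
was <- function(x) {
  cl <- .asClusterList(x)
  w <- .clusterSizes(cl)
  sum(w * .clusterSigma(cl)) / sum(w)
}

#' Weighted average distance of a clustering
#'
#' \eqn{WAD = \sum_i |C_i| \mu_i / \sum_i |C_i|}, where \eqn{\mu_i} is the
#' mean pairwise symmetric distance within cluster i.
#' @param x an \code{MPRClustering} or list of \code{MPRCluster}.
#' @return a non-negative number.
#' @export
wad <- function(x) {
  cl <- .asClusterList(x)
  w <- .clusterSizes(cl)
  sum(w * .clusterMu(cl)) / sum(w)
}

# ---- agglomeration -------------------------------------------------------

.LINKTOL <- 1e-12

#' Agglomerative clustering of MPR space
#'
#' Greedy gradient heuristic: at every step, evaluate the merge of each
#' unordered pair of clusters (statistics are recomputed on the union
#' subgraph, which can contain MPRs absent from both parts) and perform the
#' merge that most increases WAS (criterion "support") or most decreases WAD
#' (criterion "distance"); merging continues to a single cluster even when no
#' merge improves the objective.  Ties are broken toward the pair that was
#' created earliest.  Pair statistics are cached and only pairs touching the
#' last merge are re-evaluated.
#'
#' @param clustering an \code{MPRClustering} with at least 2 clusters (from
#'   \code{\link{initialClusters}}).
#' @param criterion \code{"support"} or \code{"distance"}.
#' @param timeout optional wall-clock limit in seconds; on expiry a partial
#'   history is returned with \code{complete = FALSE}.
#' @param keepK integer vector of cluster counts whose clusterings should be
#'   retained in the result's \code{kept} list (named by k).
#' @return a \code{MergeHistory}.
#' @export
agglomerate <- function(clustering, criterion = c("support", "distance"),
                        timeout = Inf, keepK = integer(0)) {
  criterion <- match.arg(criterion)
  cl <- .asClusterList(clustering)
  N <- length(cl)
  if (N < 2L) stop("agglomeration needs at least 2 initial clusters")
  t0 <- Sys.time()

  alive <- cl
  createdId <- seq_len(N) # creation order, used for deterministic tie-breaks
  nextId <- N + 1L
  kept <- list()
  level <- if (is(clustering, "MPRClustering")) clustering@level else 0L

  snapshotK <- function(k) {
    if (k %in% keepK)
      kept[[as.character(k)]] <<- new("MPRClustering", clusters = alive,
                                      level = level)
  }

  statRow <- function() {
    data.frame(size = .clusterSizes(alive), sigma = .clusterSigma(alive),
               mu = .clusterMu(alive))
  }
  perK <- data.frame(k = N, was = was(alive), wad = wad(alive))
  clusterStats <- stats::setNames(list(statRow()), as.character(N))
  merges <- data.frame()
  snapshotK(N)

  # pair cache: union statistics keyed by creation ids "i_j" (i < j)
  cache <- new.env(parent = emptyenv())
  pairKey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  pairStats <- function(ia, ib) {
    key <- pairKey(createdId[ia], createdId[ib])
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    u <- graphUnion(alive[[ia]]@subgraph, alive[[ib]]@subgraph)
    s <- subgraphStats(u)
    val <- list(T = s@mprCount, sigma = s@meanSupport, mu = s@meanPairDist)
    cache[[key]] <- val
    val
  }

  complete <- TRUE
  while (length(alive) >= 2L) {
    if (is.finite(timeout) &&
        as.numeric(difftime(Sys.time(), t0, units = "secs")) > timeout) {
      complete <- FALSE
      break
    }
    k <- length(alive)
    w <- .clusterSizes(alive)
    sg <- .clusterSigma(alive)
    mu <- .clusterMu(alive)
    sumW <- sum(w)
    sumWS <- sum(w * sg)
    sumWM <- sum(w * mu)

    best <- NULL
    for (ia in seq_len(k - 1L)) {
      for (ib in (ia + 1L):k) {
        ps <- pairStats(ia, ib)
        w2 <- sumW - w[ia] - w[ib] + ps$T
        obj <- if (criterion == "support")
          (sumWS - w[ia] * sg[ia] - w[ib] * sg[ib] + ps$T * ps$sigma) / w2
        else
          (sumWM - w[ia] * mu[ia] - w[ib] * mu[ib] + ps$T * ps$mu) / w2
        better <- if (is.null(best)) TRUE
          else if (criterion == "support") obj > best$obj + .LINKTOL
          else obj < best$obj - .LINKTOL
        tie <- !is.null(best) && abs(obj - best$obj) <= .LINKTOL
        if (better || (tie && .pairBefore(createdId[ia], createdId[ib],
                                          best$ca, best$cb))) {
          best <- list(ia = ia, ib = ib, obj = obj, ps = ps,
                       ca = createdId[ia], cb = createdId[ib])
        }
      }
    }

    ia <- best$ia; ib <- best$ib; ps <- best$ps
    u <- graphUnion(alive[[ia]]@subgraph, alive[[ib]]@subgraph)
    merged <- new("MPRCluster", subgraph = u, stats = subgraphStats(u))

    # local improvement: the two clusters versus their agglomeration
    wasPair <- (w[ia] * sg[ia] + w[ib] * sg[ib]) / (w[ia] + w[ib])
    wadPair <- (w[ia] * mu[ia] + w[ib] * mu[ib]) / (w[ia] + w[ib])
    wasMerged <- merged@stats@meanSupport
    wadMerged <- merged@stats@meanPairDist
    localWAS <- wasPair / wasMerged
    localWAD <- if (wadPair > 0) wadMerged / wadPair else Inf

    merges <- rbind(merges, data.frame(
      k = k, idA = createdId[ia], idB = createdId[ib], idMerged = nextId,
      wasPair = wasPair, wadPair = wadPair,
      wasMerged = wasMerged, wadMerged = wadMerged,
      localWAS = localWAS, localWAD = localWAD
    ))

    # drop cache entries touching the merged pair
    for (key in ls(cache)) {
      ids <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
      if (any(ids %in% c(createdId[ia], createdId[ib]))) rm(list = key, envir = cache)
    }

    alive <- c(alive[-c(ia, ib)], merged)
    createdId <- c(createdId[-c(ia, ib)], nextId)
    nextId <- nextId + 1L

    kNew <- length(alive)
    perK <- rbind(perK, data.frame(k = kNew, was = was(alive), wad = wad(alive)))
    clusterStats[[as.character(kNew)]] <- statRow()
    snapshotK(kNew)
  }

  new("MergeHistory", initialN = N, criterion = criterion,
      merges = merges, perK = perK, clusterStats = clusterStats,
      complete = complete, kept = kept)
}

# is pair (a1, b1) before (a2, b2) in creation order? (lexicographic)
.pairBefore <- function(a1, b1, a2, b2) {
  p1 <- sort(c(a1, b1)); p2 <- sort(c(a2, b2))
  p1[1L] < p2[1L] || (p1[1L] == p2[1L] && p1[2L] < p2[2L])
}

# ---- improvement scores --------------------------------------------------

#' Improvement score of a k-clustering
#'
#' For the support criterion, WAS at k divided by WAS of the whole space
#' (k = 1); for the distance criterion, the whole-space mean pairwise distance
#' divided by WAD at k.  Division by zero yields \code{Inf}.
#' @param history a complete \code{MergeHistory}.
#' @param k number of clusters (1..N).
#' @param criterion \code{"support"} or \code{"distance"} (defaults to the
#'   history's own criterion).
#' @return a number (1.0 at k = 1).
#' @export
improvement <- function(history, k, criterion = history@criterion) {
  criterion <- match.arg(criterion, c("support", "distance"))
  pk <- history@perK
  if (!(1 %in% pk$k))
    stop("history is incomplete; whole-space baseline unavailable")
  if (!(k %in% pk$k)) stop("k = ", k, " not in history (k range ",
                           min(pk$k), "..", max(pk$k), ")")
  if (k == 1L) return(1.0)
  atK <- pk[pk$k == k, ]
  at1 <- pk[pk$k == 1L, ]
  if (criterion == "support") atK$was / at1$was
  else if (atK$wad > 0) at1$wad / atK$wad else Inf
}

#' Local improvement at k
#'
#' Compares the pair of clusters whose merge reduced k clusters to k-1
#' against their agglomeration: \code{WAS({Ca, Cb}) / WAS({Cab})} for support,
#' \code{WAD({Cab}) / WAD({Ca, Cb})} for distance.
#' @inheritParams improvement
#' @param k number of clusters before the merge (2..N).
#' @return a positive number (\code{Inf} when the pair's WAD is zero).
#' @export
localImprovement <- function(history, k, criterion = history@criterion) {
  criterion <- match.arg(criterion, c("support", "distance"))
  row <- history@merges[history@merges$k == k, ]
  if (nrow(row) != 1L)
    stop("no merge at k = ", k, " in history")
  if (criterion == "support") row$localWAS else row$localWAD
}
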