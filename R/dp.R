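# The undated DTL maximum-parsimony dynamic program and the construction of
# the reconciliation graph encoding every co-optimal reconciliation.
#
# Conventions: gene vertices g and species vertices s are preorder indices
# into the instance's indexed trees; event type codes are
# 1=S (speciation), 2=D (duplication), 3=T (transfer), 4=L (loss),
# 5=C (contemporaneous leaf association).  Speciation and C are free; D, T, L
# carry the instance costs.  Cost comparisons use an absolute 1e-9 tolerance
# so that tied optima are recovered reliably for real-valued costs.

.EPS <- 1e-9
.feq <- function(a, b) {
  (is.infinite(a) & is.infinite(b) & sign(a) == sign(b)) |
    (is.finite(a) & is.finite(b) & abs(a - b) <= .EPS)
}

.EVTYPES <- c("S", "D", "T", "L", "C")

#' Compute the DTL dynamic-programming tables
#'
#' Fills the placement, descend and outside cost tables for every
#' (gene vertex, species vertex) pair and the optimal reconciliation cost.
#' For an internal gene vertex \eqn{g} with children \eqn{g', g''} placed at
#' species vertex \eqn{s}: a speciation sends the children into the two child
#' subtrees of \eqn{s} (losses charged per skipped edge), a duplication keeps
#' both at-or-below \eqn{s}, and a transfer keeps one at-or-below \eqn{s} and
#' sends the other to the cheapest vertex incomparable to \eqn{s} (the
#' recipient maps to that vertex directly, so no recipient-side losses arise).
#'
#' @param inst a validated \code{\link{DTLInstance}}.
#' @return a \code{DPTables} object.
#' @examples
#' inst <- dtlFixture("toy3")
#' optCost(computeDPTables(inst))
#' @export
computeDPTables <- function(inst) {
  validateInstance(inst)
  gt <- geneTree(inst); st <- speciesTree(inst)
  m <- gt$nv; n <- st$nv
  d <- inst@costs[["d"]]; t <- inst@costs[["t"]]; l <- inst@costs[["l"]]
  sIdxOf <- stats::setNames(which(st$isLeaf), st$label[st$isLeaf])
  EC <- matrix(Inf, m, n); DC <- matrix(Inf, m, n); OC <- matrix(Inf, m, n)
  for (g in m:1) {
    if (gt$isLeaf[g]) {
      EC[g, sIdxOf[[inst@mapping[[gt$label[g]]]]]] <- 0
    } else {
      g1 <- gt$children[g, 1L]; g2 <- gt$children[g, 2L]
      for (s in seq_len(n)) {
        best <- Inf
        if (!st$isLeaf[s]) {
          s1 <- st$children[s, 1L]; s2 <- st$children[s, 2L]
          best <- min(best, DC[g1, s1] + DC[g2, s2], DC[g1, s2] + DC[g2, s1])
        }
        best <- min(best, d + DC[g1, s] + DC[g2, s])
        best <- min(best, t + DC[g1, s] + OC[g2, s], t + DC[g2, s] + OC[g1, s])
        EC[g, s] <- best
      }
    }
    # descend: allow a loss chain from s down into its subtree
    for (s in n:1) {
      DC[g, s] <- if (st$isLeaf[s]) EC[g, s] else
        min(EC[g, s], l + min(DC[g, st$children[s, 1L]], DC[g, st$children[s, 2L]]))
    }
    # outside: cheapest placement at a vertex incomparable to s, via the
    # standard two-pass (subtree minima down, exclusion minima from the root)
    down <- numeric(n)
    for (s in n:1) {
      down[s] <- if (st$isLeaf[s]) EC[g, s] else
        min(EC[g, s], down[st$children[s, 1L]], down[st$children[s, 2L]])
    }
    excl <- rep(Inf, n)
    for (s in seq_len(n)) {
      if (!st$isLeaf[s]) {
        c1 <- st$children[s, 1L]; c2 <- st$children[s, 2L]
        excl[c1] <- min(excl[s], down[c2])
        excl[c2] <- min(excl[s], down[c1])
      }
    }
    OC[g, ] <- excl
  }
  new("DPTables", eventCost = EC, descendCost = DC, outsideCost = OC,
      optCost = min(EC[1L, ]))
}

#' Build the reconciliation graph of all MPRs
#'
#' Backtracks every argmin choice of the dynamic program.  Sources are all
#' placements of the gene root achieving the optimal cost; loss chains insert
#' pass-through mapping nodes; contemporaneous leaf associations terminate the
#' graph.  Every traversal of the result is an MPR and vice versa.
#'
#' @param inst a validated \code{\link{DTLInstance}}.
#' @param tables the \code{DPTables} for \code{inst} (computed if missing).
#' @return a \code{ReconGraph}.
#' @examples
#' g <- buildReconGraph(dtlFixture("toy3"))
#' g
#' @export
buildReconGraph <- function(inst, tables = computeDPTables(inst)) {
  gt <- geneTree(inst); st <- speciesTree(inst)
  m <- gt$nv; n <- st$nv
  d <- inst@costs[["d"]]; t <- inst@costs[["t"]]; l <- inst@costs[["l"]]
  EC <- tables@eventCost; DC <- tables@descendCost; OC <- tables@outsideCost
  opt <- tables@optCost
  if (!is.finite(opt))
    stop("instance has no feasible reconciliation", call. = FALSE)

  present <- matrix(FALSE, m, n)
  doneDirect <- matrix(FALSE, m, n)
  doneDescend <- matrix(FALSE, m, n)
  ev <- new.env(parent = emptyenv())
  ev$type <- integer(0); ev$g <- integer(0); ev$s <- integer(0)
  ev$c1g <- integer(0); ev$c1s <- integer(0)
  ev$c2g <- integer(0); ev$c2s <- integer(0)
  ev$cost <- numeric(0)
  addEvent <- function(type, g, s, c1g = 0L, c1s = 0L, c2g = 0L, c2s = 0L,
                       cost = 0) {
    i <- length(ev$type) + 1L
    ev$type[i] <- type; ev$g[i] <- g; ev$s[i] <- s
    ev$c1g[i] <- c1g; ev$c1s[i] <- c1s; ev$c2g[i] <- c2g; ev$c2s[i] <- c2s
    ev$cost[i] <- cost
  }

  direct <- function(g, s) {
    if (doneDirect[g, s]) return(invisible())
    doneDirect[g, s] <<- TRUE
    present[g, s] <<- TRUE
    ec <- EC[g, s]
    if (gt$isLeaf[g]) {
      addEvent(5L, g, s) # contemporaneous; ec == 0 here by construction
      return(invisible())
    }
    g1 <- gt$children[g, 1L]; g2 <- gt$children[g, 2L]
    if (!st$isLeaf[s]) {
      s1 <- st$children[s, 1L]; s2 <- st$children[s, 2L]
      if (.feq(DC[g1, s1] + DC[g2, s2], ec)) {
        addEvent(1L, g, s, g1, s1, g2, s2)
        descend(g1, s1); descend(g2, s2)
      }
      if (.feq(DC[g1, s2] + DC[g2, s1], ec)) {
        addEvent(1L, g, s, g1, s2, g2, s1)
        descend(g1, s2); descend(g2, s1)
      }
    }
    if (.feq(d + DC[g1, s] + DC[g2, s], ec)) {
      addEvent(2L, g, s, g1, s, g2, s, cost = d)
      descend(g1, s); descend(g2, s)
    }
    for (pair in list(c(g1, g2), c(g2, g1))) {
      keep <- pair[1L]; move <- pair[2L]
      if (.feq(t + DC[keep, s] + OC[move, s], ec)) {
        # all incomparable recipients achieving the outside optimum
        for (sh in seq_len(n)) {
          if (!.ancEq(st, s, sh) && !.ancEq(st, sh, s) &&
              .feq(EC[move, sh], OC[move, s])) {
            addEvent(3L, g, s, keep, s, move, sh, cost = t)
            descend(keep, s); direct(move, sh)
          }
        }
      }
    }
    invisible()
  }

  descend <- function(g, s) {
    if (doneDescend[g, s]) return(invisible())
    doneDescend[g, s] <<- TRUE
    present[g, s] <<- TRUE
    dc <- DC[g, s]
    if (.feq(EC[g, s], dc)) direct(g, s)
    if (!st$isLeaf[s]) {
      for (sc in st$children[s, ]) {
        if (.feq(l + DC[g, sc], dc)) {
          addEvent(4L, g, s, g, sc, cost = l)
          descend(g, sc)
        }
      }
    }
  }

  for (s in which(.feq(EC[1L, ], opt))) direct(1L, s)

  # --- assemble canonical node tables ------------------------------------
  keyOf <- function(g, s) (as.integer(g) - 1L) * n + as.integer(s)
  mapKeys <- which(t(present)) # t(): key order (g-1)*n+s ascending
  mapId <- integer(m * n)
  mapId[mapKeys] <- seq_along(mapKeys)
  mapG <- as.integer((mapKeys - 1L) %/% n + 1L)
  mapS <- as.integer((mapKeys - 1L) %% n + 1L)

  nEv <- length(ev$type)
  # canonical event order: (g, s, type rank, child keys)
  c1k <- ifelse(ev$c1g > 0L, keyOf(ev$c1g, ev$c1s), 0L)
  c2k <- ifelse(ev$c2g > 0L, keyOf(ev$c2g, ev$c2s), 0L)
  # canonicalize association order within an event (associations are sets)
  swap <- ev$c2g > 0L & c2k < c1k
  tmp <- c1k[swap]; c1k[swap] <- c2k[swap]; c2k[swap] <- tmp
  o <- order(ev$g, ev$s, ev$type, c1k, c2k)
  evType <- ev$type[o]; evG <- ev$g[o]; evS <- ev$s[o]
  evCost <- ev$cost[o]
  evParent <- mapId[keyOf(evG, evS)]
  evC1 <- ifelse(c1k[o] > 0L, mapId[pmax(c1k[o], 1L)], 0L)
  evC2 <- ifelse(c2k[o] > 0L, mapId[pmax(c2k[o], 1L)], 0L)

  nMap <- length(mapKeys)
  # CSR mapping -> event children (events are parent-major sorted)
  cnt <- tabulate(evParent, nbins = nMap)
  mapEvPtr <- c(0L, cumsum(cnt))
  mapEvIdx <- seq_len(nEv) # already grouped by parent in canonical order

  # CSR mapping -> event parents
  childOf <- c(evC1, evC2)
  evOf <- rep.int(seq_len(nEv), 2L)
  keep <- childOf > 0L
  childOf <- childOf[keep]; evOf <- evOf[keep]
  op <- order(childOf, evOf)
  cntP <- tabulate(childOf, nbins = nMap)
  mapParPtr <- c(0L, cumsum(cntP))
  mapParIdx <- evOf[op]

  sources <- sort(mapId[keyOf(1L, which(.feq(EC[1L, ], opt)))])

  # topological order of mapping nodes, ancestors first
  mapOrder <- .topoOrder(nMap, mapEvPtr, mapEvIdx, evC1, evC2, sources)

  new("ReconGraph", instance = inst,
      mapG = mapG, mapS = mapS,
      evType = as.integer(evType), evParent = as.integer(evParent),
      evC1 = as.integer(evC1), evC2 = as.integer(evC2), evCost = evCost,
      mapEvPtr = as.integer(mapEvPtr), mapEvIdx = as.integer(mapEvIdx),
      mapParPtr = as.integer(mapParPtr), mapParIdx = as.integer(mapParIdx),
      sources = as.integer(sources), mapOrder = mapOrder,
      optCost = opt)
}

# depth-first topological order (ancestors before descendants) of mapping
# nodes; iterative two-phase DFS to avoid deep recursion on long loss chains
.topoOrder <- function(nMap, mapEvPtr, mapEvIdx, evC1, evC2, sources) {
  state <- integer(nMap) # 0 unvisited, 1 in progress, 2 done
  post <- integer(nMap); np <- 0L
  cap <- 2L * length(evC1) + nMap + 8L
  stackN <- integer(cap); stackE <- logical(cap); sp <- 0L
  for (src in sources) {
    if (state[src] != 0L) next
    sp <- sp + 1L; stackN[sp] <- src; stackE[sp] <- FALSE
    while (sp > 0L) {
      v <- stackN[sp]
      if (state[v] == 2L) { sp <- sp - 1L; next }
      if (!stackE[sp]) {
        stackE[sp] <- TRUE
        state[v] <- 1L
        if (mapEvPtr[v + 1L] > mapEvPtr[v]) {
          evs <- mapEvIdx[(mapEvPtr[v] + 1L):mapEvPtr[v + 1L]]
          kids <- c(evC1[evs], evC2[evs])
          kids <- kids[kids > 0L]
          kids <- unique(kids[state[kids] == 0L])
          for (kd in kids) {
            sp <- sp + 1L; stackN[sp] <- kd; stackE[sp] <- FALSE
          }
        }
      } else {
        state[v] <- 2L
        np <- np + 1L
        post[np] <- v
        sp <- sp - 1L
      }
    }
  }
  if (np != nMap) {
    # nodes unreachable from sources would violate the construction invariant
    stop("internal error: reconciliation graph has unreachable mapping nodes")
  }
  rev(post[seq_len(np)])
}

#' Reconcile: DP plus reconciliation graph in one call
#'
#' @param inst a validated \code{\link{DTLInstance}}.
#' @return a \code{ReconGraph}.
#' @export
reconcile <- function(inst) buildReconGraph(inst)
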