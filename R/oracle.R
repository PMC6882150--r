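# Brute-force oracle: score an explicit reconciliation mapping by applying the
# event definitions directly, and enumerate all valid mappings of small
# instances.  This path is deliberately independent of the dynamic program and
# the reconciliation graph so the two can check each other.

# events as a data.frame in the tuple representation used by the graph:
# type code, (g,s) of the event, and up to two (g,s) association pairs
.emptyEventDF <- function() {
  data.frame(type = integer(0), g = integer(0), s = integer(0),
             c1g = integer(0), c1s = integer(0),
             c2g = integer(0), c2s = integer(0), cost = numeric(0))
}

#' Infer the events induced by a full reconciliation mapping
#'
#' Given a placement of every gene-tree vertex on a species-tree vertex that
#' extends the leaf mapping and respects the ancestry constraints, returns the
#' induced speciation, duplication, transfer, loss and contemporaneous events
#' in the tuple representation used by the reconciliation graph, plus the
#' summed event cost.  Transfer recipients map directly to their placement, so
#' no recipient-side losses arise.
#'
#' @param inst a validated \code{\link{DTLInstance}}.
#' @param phi integer vector of length \code{geneTree(inst)$nv}: species
#'   preorder index per gene vertex (preorder).
#' @return list with \code{events} (a data.frame of event tuples) and
#'   \code{cost}.
#' @examples
#' inst <- dtlFixture("toy3")
#' inferEvents(inst, c(1L, 3L, 5L)) # root at the species root: speciation
#' @export
inferEvents <- function(inst, phi) {
  gt <- geneTree(inst); st <- speciesTree(inst)
  m <- gt$nv
  if (length(phi) != m) stop("phi must place every gene vertex")
  phi <- as.integer(phi)
  d <- inst@costs[["d"]]; t <- inst@costs[["t"]]; l <- inst@costs[["l"]]
  sIdxOf <- stats::setNames(which(st$isLeaf), st$label[st$isLeaf])

  etype <- integer(0); eg <- integer(0); es <- integer(0)
  c1g <- integer(0); c1s <- integer(0); c2g <- integer(0); c2s <- integer(0)
  ecost <- numeric(0)
  push <- function(ty, g, s, a1g = 0L, a1s = 0L, a2g = 0L, a2s = 0L, co = 0) {
    i <- length(etype) + 1L
    etype[i] <<- ty; eg[i] <<- g; es[i] <<- s
    c1g[i] <<- a1g; c1s[i] <<- a1s; c2g[i] <<- a2g; c2s[i] <<- a2s
    ecost[i] <<- co
  }

  vertexType <- integer(m) # per internal g: 1 S, 2 D, 3 T
  # child association start: where each non-root gene vertex is associated
  # just below its parent's event (the loss chain runs from there to phi[g])
  assocStart <- integer(m)

  for (g in seq_len(m)) {
    if (gt$isLeaf[g]) {
      target <- sIdxOf[[inst@mapping[[gt$label[g]]]]]
      if (phi[g] != target)
        stop("phi violates the leaf mapping at gene leaf '", gt$label[g], "'")
      push(5L, g, phi[g])
      next
    }
    g1 <- gt$children[g, 1L]; g2 <- gt$children[g, 2L]
    sg <- phi[g]; sa <- phi[g1]; sb <- phi[g2]
    # constraint (1): phi(g) must not be a strict descendant of a child image
    for (sc in c(sa, sb)) {
      if (sc != sg && .ancEq(st, sc, sg))
        stop("invalid mapping: phi(g) is a descendant of a child image (g=", g, ")")
    }
    inA <- .ancEq(st, sg, sa); inB <- .ancEq(st, sg, sb)
    if (!inA && !inB)
      stop("invalid mapping: no child image at or below phi(g) (g=", g, ")")
    isSpec <- FALSE
    if (!st$isLeaf[sg]) {
      sl <- st$children[sg, 1L]; sr <- st$children[sg, 2L]
      aL <- .ancEq(st, sl, sa); aR <- .ancEq(st, sr, sa)
      bL <- .ancEq(st, sl, sb); bR <- .ancEq(st, sr, sb)
      if ((aL && bR) || (aR && bL)) {
        isSpec <- TRUE
        s1 <- if (aL) sl else sr
        s2 <- if (aL) sr else sl
        push(1L, g, sg, g1, s1, g2, s2)
        vertexType[g] <- 1L
        assocStart[g1] <- s1; assocStart[g2] <- s2
      }
    }
    if (!isSpec) {
      if (inA && inB) {
        push(2L, g, sg, g1, sg, g2, sg, co = d)
        vertexType[g] <- 2L
        assocStart[g1] <- sg; assocStart[g2] <- sg
      } else {
        keep <- if (inA) g1 else g2
        move <- if (inA) g2 else g1
        sm <- phi[move]
        if (.ancEq(st, sg, sm) || .ancEq(st, sm, sg))
          stop("invalid mapping: transfer recipient comparable to donor (g=", g, ")")
        push(3L, g, sg, keep, sg, move, sm, co = t)
        vertexType[g] <- 3L
        assocStart[keep] <- sg
        assocStart[move] <- sm # direct: no recipient-side losses
      }
    }
  }

  # loss chains: walk from the association start down to the placement
  for (g in seq_len(m)) {
    if (g == 1L) next
    v <- assocStart[g]
    while (v != phi[g]) {
      if (!.ancEq(st, v, phi[g]))
        stop("internal error: association start not ancestral (g=", g, ")")
      nxt <- st$children[v, 1L]
      if (!.ancEq(st, nxt, phi[g])) nxt <- st$children[v, 2L]
      push(4L, g, v, g, nxt, co = l)
      v <- nxt
    }
  }

  events <- data.frame(type = etype, g = eg, s = es,
                       c1g = c1g, c1s = c1s, c2g = c2g, c2s = c2s,
                       cost = ecost)
  list(events = events, cost = sum(ecost))
}

# canonical per-event string keys from an event data.frame; with
# canonical=TRUE vertices are named by their clade signatures so keys are
# invariant under child-order swaps in either input tree
.eventKeysDF <- function(df, gt, st, canonical = FALSE) {
  gname <- function(i) if (canonical) gt$clade[i] else as.character(i)
  sname <- function(i) if (canonical) st$clade[i] else as.character(i)
  pairKey <- function(pg, ps) ifelse(pg > 0L,
                                     paste0(gname(pmax(pg, 1L)), "@", sname(pmax(ps, 1L))), "")
  p1 <- pairKey(df$c1g, df$c1s)
  p2 <- pairKey(df$c2g, df$c2s)
  swap <- nzchar(p2) & p2 < p1
  tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
  paste0(.EVTYPES[df$type], "_", gname(df$g), "@", sname(df$s),
         "{", p1, ";", p2, "}")
}

#' Canonical event keys of a traversal or event table
#'
#' @param x a \code{Traversal}, or a data.frame of event tuples as returned in
#'   \code{inferEvents(...)$events} (then \code{graph} must supply the trees).
#' @param graph the parent \code{ReconGraph} (only for data.frame input, to
#'   resolve trees; ignored for \code{Traversal}).
#' @param canonical if \code{TRUE}, vertices are identified by clade leaf sets
#'   (invariant under child-order swaps); otherwise by preorder index.
#' @return sorted character vector of event keys.
#' @export
eventKeys <- function(x, graph = NULL, canonical = FALSE) {
  if (is(x, "Traversal")) {
    g <- x@graph
    df <- data.frame(type = g@evType[x@eventNodes],
                     g = g@mapG[g@evParent[x@eventNodes]],
                     s = g@mapS[g@evParent[x@eventNodes]],
                     c1g = ifelse(g@evC1[x@eventNodes] > 0L,
                                  g@mapG[pmax(g@evC1[x@eventNodes], 1L)], 0L),
                     c1s = ifelse(g@evC1[x@eventNodes] > 0L,
                                  g@mapS[pmax(g@evC1[x@eventNodes], 1L)], 0L),
                     c2g = ifelse(g@evC2[x@eventNodes] > 0L,
                                  g@mapG[pmax(g@evC2[x@eventNodes], 1L)], 0L),
                     c2s = ifelse(g@evC2[x@eventNodes] > 0L,
                                  g@mapS[pmax(g@evC2[x@eventNodes], 1L)], 0L))
    inst <- g@instance
    return(sort(.eventKeysDF(df, geneTree(inst), speciesTree(inst), canonical)))
  }
  if (is.null(graph)) stop("supply 'graph' for data.frame input")
  inst <- graph@instance
  sort(.eventKeysDF(x, geneTree(inst), speciesTree(inst), canonical))
}

#' Canonical keys of every event node of a reconciliation graph
#'
#' @param graph a \code{ReconGraph}.
#' @param canonical if \code{TRUE}, vertices are identified by clade leaf sets
#'   (invariant under child-order swaps).
#' @return sorted character vector, one key per event node.
#' @export
graphEventKeys <- function(graph, canonical = FALSE) {
  ec <- function(v, what) ifelse(v > 0L, what[pmax(v, 1L)], 0L)
  df <- data.frame(type = graph@evType,
                   g = graph@mapG[graph@evParent],
                   s = graph@mapS[graph@evParent],
                   c1g = ec(graph@evC1, graph@mapG),
                   c1s = ec(graph@evC1, graph@mapS),
                   c2g = ec(graph@evC2, graph@mapG),
                   c2s = ec(graph@evC2, graph@mapS))
  inst <- graph@instance
  sort(.eventKeysDF(df, geneTree(inst), speciesTree(inst), canonical))
}

#' Enumerate all valid reconciliation mappings by brute force
#'
#' Exhausts every assignment of internal gene vertices to species vertices,
#' keeps those satisfying the reconciliation-mapping constraints, and scores
#' each with \code{\link{inferEvents}}.  Intended as an independent oracle on
#' tiny instances.
#'
#' @param inst a validated \code{\link{DTLInstance}}.
#' @param limit refuse if the raw assignment space exceeds this many
#'   combinations.
#' @return list with \code{mappings} (list of \code{list(phi, cost, events)})
#'   and \code{minCost}.
#' @export
enumerateReconciliations <- function(inst, limit = 1e6) {
  gt <- geneTree(inst); st <- speciesTree(inst)
  m <- gt$nv; n <- st$nv
  internals <- which(!gt$isLeaf)
  if (length(internals) && n^length(internals) > limit)
    stop("assignment space has ", n^length(internals),
         " combinations, above the limit of ", limit)
  sIdxOf <- stats::setNames(which(st$isLeaf), st$label[st$isLeaf])
  phi <- integer(m)
  for (g in which(gt$isLeaf)) phi[g] <- sIdxOf[[inst@mapping[[gt$label[g]]]]]

  out <- list()
  # assign internal vertices children-first so constraints prune early
  ord <- rev(internals) # decreasing preorder: children before parents
  feasibleAt <- function(g) {
    # constraints at g given its children are placed
    g1 <- gt$children[g, 1L]; g2 <- gt$children[g, 2L]
    sg <- phi[g]; sa <- phi[g1]; sb <- phi[g2]
    if ((sa != sg && .ancEq(st, sa, sg)) || (sb != sg && .ancEq(st, sb, sg)))
      return(FALSE)
    inA <- .ancEq(st, sg, sa); inB <- .ancEq(st, sg, sb)
    if (!inA && !inB) return(FALSE)
    if (xor(inA, inB)) {
      sm <- if (inA) sb else sa
      if (.ancEq(st, sg, sm) || .ancEq(st, sm, sg)) return(FALSE)
    }
    TRUE
  }
  rec <- function(i) {
    if (i > length(ord)) {
      sc <- inferEvents(inst, phi)
      out[[length(out) + 1L]] <<- list(phi = phi, cost = sc$cost,
                                       events = sc$events)
      return(invisible())
    }
    g <- ord[i]
    for (s in seq_len(n)) {
      phi[g] <<- s
      if (feasibleAt(g)) rec(i + 1L)
    }
    phi[g] <<- 0L
    invisible()
  }
  rec(1L)
  costs <- vapply(out, `[[`, numeric(1), "cost")
  list(mappings = out, minCost = if (length(costs)) min(costs) else Inf)
}
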