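# Seeded random DTL instance generator and hand-built fixtures, so that every
# operation is testable without external data.

.DEFAULT_COST_GRID <- list(c(1, 1, 1), c(2, 3, 1), c(1, 4, 1))

# uniform random binary topology over the given (already shuffled) labels by
# recursive random splits of the leaf vector
.randomTopology <- function(labels) {
  nv <- 2L * length(labels) - 1L
  children <- vector("list", nv)
  labs <- character(nv)
  cnt <- 0L
  build <- function(ls) {
    cnt <<- cnt + 1L
    v <- cnt
    if (length(ls) == 1L) {
      labs[v] <<- ls
    } else {
      j <- if (length(ls) == 2L) 1L else sample.int(length(ls) - 1L, 1L)
      c1 <- build(ls[seq_len(j)])
      c2 <- build(ls[(j + 1L):length(ls)])
      children[[v]] <<- c(c1, c2)
    }
    v
  }
  build(sample(labels))
  .addCladeKeys(.indexFromChildren(children, labs, 1L))
}

#' Generate a random DTL instance
#'
#' Draws uniform random binary topologies for the species and gene trees
#' (recursive random splits of the leaf set), a leaf mapping, and an event
#' cost triple from the grid.  Identical seeds give identical instances.
#'
#' @param seed integer seed (mandatory for reproducibility).
#' @param nSpeciesLeaves,nGeneLeaves leaf counts (>= 1).
#' @param mappingMode \code{"random"} (each gene leaf mapped to a uniformly
#'   drawn species leaf, with replacement) or \code{"bijective"} (gene leaves
#'   paired with distinct species leaves; requires
#'   \code{nGeneLeaves <= nSpeciesLeaves}).
#' @param costGrid list of numeric cost triples (duplication, transfer, loss)
#'   from which one is drawn.
#' @return a validated \code{\link{DTLInstance}}.
#' @examples
#' inst <- randomDTLInstance(1, 4, 4)
#' @export
randomDTLInstance <- function(seed, nSpeciesLeaves = 4L, nGeneLeaves = 4L,
                              mappingMode = c("random", "bijective"),
                              costGrid = .DEFAULT_COST_GRID) {
  mappingMode <- match.arg(mappingMode)
  stopifnot(nSpeciesLeaves >= 1L, nGeneLeaves >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sLab <- paste0("S", seq_len(nSpeciesLeaves))
  gLab <- paste0("g", seq_len(nGeneLeaves))
  st <- .randomTopology(sLab)
  gt <- .randomTopology(gLab)
  mapping <- if (mappingMode == "bijective") {
    if (nGeneLeaves > nSpeciesLeaves)
      stop("bijective mapping needs nGeneLeaves <= nSpeciesLeaves")
    stats::setNames(sample(sLab, nGeneLeaves), gLab)
  } else {
    stats::setNames(sample(sLab, nGeneLeaves, replace = TRUE), gLab)
  }
  costs <- costGrid[[sample.int(length(costGrid), 1L)]]
  DTLInstance(st, gt, mapping, costs)
}

#' Hand-built reference instances
#'
#' \describe{
#'   \item{leaf1}{single-leaf gene and species trees; one reconciliation of
#'     cost 0.}
#'   \item{dup1}{two gene leaves on a single species leaf with costs
#'     (1, 4, 1); the only feasible event is a duplication.}
#'   \item{toy3}{gene cherry (a,c) on S = ((A,B),C) with unit costs; a small
#'     space of co-optimal reconciliations mixing speciation-plus-loss and
#'     transfers.}
#'   \item{tie_grid}{a list of small instances with deliberate cost ties whose
#'     MPR counts fall in [2, 100].}
#' }
#' All documented statistics of these fixtures are asserted against the
#' brute-force enumeration oracle in the test suite, not hard-coded.
#'
#' @param name one of \code{"leaf1"}, \code{"dup1"}, \code{"toy3"},
#'   \code{"tie_grid"}.
#' @return a \code{\link{DTLInstance}}, or a list of them for
#'   \code{"tie_grid"}.
#' @export
dtlFixture <- function(name = c("leaf1", "dup1", "toy3", "tie_grid")) {
  name <- match.arg(name)
  switch(name,
    leaf1 = DTLInstance("A;", "a;", c(a = "A"), c(1, 1, 1)),
    dup1 = DTLInstance("A;", "(a,b);", c(a = "A", b = "A"), c(1, 4, 1)),
    toy3 = DTLInstance("((A,B),C);", "(a,c);", c(a = "A", c = "C"),
                       c(1, 1, 1)),
    tie_grid = list(
      DTLInstance("((A,B),C);", "(a,c);", c(a = "A", c = "C"), c(1, 1, 1)),
      DTLInstance("((A,B),(C,D));", "((a,b),(c,d));",
                  c(a = "A", b = "C", c = "B", d = "D"), c(1, 1, 1)),
      DTLInstance("((A,(B,D)),C);", "((b,d),(c,a));",
                  c(a = "C", b = "C", c = "A", d = "D"), c(1, 1, 1)),
      DTLInstance("((B,C),(A,D));", "((a,b),(d,c));",
                  c(a = "A", b = "C", c = "C", d = "A"), c(1, 1, 1))
    )
  )
}
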