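# Shared oracle helpers: everything here goes through the brute-force
# enumeration path (enumerateReconciliations / enumerateTraversals), which is
# independent of the DP + counting implementation under test.

# canonical "set of event sets" of the optimal reconciliations, by brute force
oracleOptimalEventSets <- function(inst, graph, canonical = FALSE) {
  en <- enumerateReconciliations(inst)
  opts <- Filter(function(m) abs(m$cost - en$minCost) < 1e-9, en$mappings)
  sort(vapply(opts, function(m)
    paste(eventKeys(m$events, graph = graph, canonical = canonical),
          collapse = " & "), character(1)))
}

# canonical "set of event sets" of all graph traversals
traversalEventSets <- function(graph, limit = 1e5, canonical = FALSE) {
  sort(vapply(enumerateTraversals(graph, limit = limit), function(t)
    paste(eventKeys(t, canonical = canonical), collapse = " & "),
    character(1)))
}

# statistics of a subgraph recomputed from an explicit traversal list
enumeratedStats <- function(x, limit = 1e4) {
  sub <- if (is(x, "ReconGraph")) fullSubgraph(x) else x
  travs <- enumerateTraversals(sub, limit = limit)
  sets <- lapply(travs, function(t) t@eventNodes)
  T <- length(sets)
  g <- if (is(x, "ReconGraph")) x else sub@graph
  cnt <- numeric(length(g@evType))
  for (s in sets) cnt[s] <- cnt[s] + 1
  pairDist <- function(a, b) length(a) + length(b) - 2 * sum(a %in% b)
  dists <- numeric(0)
  if (T >= 2) {
    dists <- unlist(lapply(seq_len(T - 1), function(i)
      vapply((i + 1):T, function(j) pairDist(sets[[i]], sets[[j]]),
             numeric(1))))
  }
  nonC <- which(cnt > 0 & g@evType != 5L)
  medianTotal <- min(vapply(sets, function(a)
    sum(vapply(sets, function(b) pairDist(a, b), numeric(1))), numeric(1)))
  list(T = T, count = cnt,
       support = ifelse(cnt > 0, cnt / T, NA_real_),
       sigma = if (length(nonC)) mean(cnt[nonC] / T) else 1.0,
       mu = if (T >= 2) mean(dists) else 0,
       dists = dists,
       medianTotal = medianTotal)
}

# deterministic scan for random oracle-scale instances with T in [lo, hi]
oracleInstances <- function(nWanted, lo = 2, hi = 500, maxLeaves = 6L,
                            seedStart = 1L, seedMax = 4000L) {
  out <- list()
  seed <- seedStart - 1L
  while (length(out) < nWanted && seed < seedMax) {
    seed <- seed + 1L
    nS <- 3L + (seed %% (maxLeaves - 2L))
    nG <- 3L + ((seed %/% 3L) %% (maxLeaves - 2L))
    inst <- randomDTLInstance(seed, nS, nG)
    g <- reconcile(inst)
    T <- mprCount(g)
    if (T >= lo && T <= hi) out[[length(out) + 1L]] <- list(inst = inst, graph = g)
  }
  out
}

# path to the installed command-line script; run it with Rscript
cliScript <- function() {
  p <- system.file("exec", "dtlclust", package = "dtlclust")
  if (!nzchar(p)) p <- file.path(find.package("dtlclust"), "exec", "dtlclust")
  p
}

runCli <- function(args) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(rscript, c(cliScript(), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}

toy3Files <- function(dir) {
  writeInstanceFiles(dtlFixture("toy3"), dir, "toy3")
}
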