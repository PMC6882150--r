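// Per-subgraph kernels over a fixed reconciliation graph.
//
// The graph is passed as flat arrays (1-based ids from R; 0 means "none"):
//   mapEvPtr/mapEvIdx : CSR adjacency, mapping node -> event children
//   evC1/evC2         : mapping-node children of each event node
//   evType            : 1=S 2=D 3=T 4=L 5=C
//   mapOrder          : topological order of mapping nodes, ancestors first
// A subgraph is a pair of membership masks plus its included sources.
// Counts are IEEE doubles: exact integers up to 2^53, correctly rounded
// beyond; the clustering linkage only ever consumes ratios of these.

#include <Rcpp.h>
using namespace Rcpp;

// below/above two-pass completion counting, event supports, mean support and
// mean pairwise symmetric distance of one subgraph
// [[Rcpp::export]]
List cpp_subgraph_stats(IntegerVector mapEvPtr, IntegerVector mapEvIdx,
                        IntegerVector evC1, IntegerVector evC2,
                        IntegerVector evType,
                        LogicalVector mapMember, LogicalVector evMember,
                        IntegerVector sources, IntegerVector mapOrder) {
  const int nMap = mapMember.size();
  const int nEv = evMember.size();
  NumericVector belowMap(nMap), belowEv(nEv), aboveMap(nMap), eventCount(nEv);

  for (int idx = nMap - 1; idx >= 0; --idx) {
    const int m = mapOrder[idx] - 1;
    if (!mapMember[m]) continue;
    double bm = 0.0;
    for (int p = mapEvPtr[m]; p < mapEvPtr[m + 1]; ++p) {
      const int e = mapEvIdx[p] - 1;
      if (!evMember[e]) continue;
      double be = 1.0;
      if (evC1[e] > 0) be *= belowMap[evC1[e] - 1];
      if (evC2[e] > 0) be *= belowMap[evC2[e] - 1];
      belowEv[e] = be;
      bm += be;
    }
    belowMap[m] = bm;
  }

  double T = 0.0;
  for (int i = 0; i < sources.size(); ++i) T += belowMap[sources[i] - 1];

  for (int i = 0; i < sources.size(); ++i) aboveMap[sources[i] - 1] = 1.0;
  for (int idx = 0; idx < nMap; ++idx) {
    const int m = mapOrder[idx] - 1;
    if (!mapMember[m]) continue;
    const double am = aboveMap[m];
    if (am == 0.0) continue;
    for (int p = mapEvPtr[m]; p < mapEvPtr[m + 1]; ++p) {
      const int e = mapEvIdx[p] - 1;
      if (!evMember[e]) continue;
      eventCount[e] = am * belowEv[e];
      const int c1 = evC1[e], c2 = evC2[e];
      if (c1 > 0) aboveMap[c1 - 1] += am * (c2 > 0 ? belowMap[c2 - 1] : 1.0);
      if (c2 > 0) aboveMap[c2 - 1] += am * (c1 > 0 ? belowMap[c1 - 1] : 1.0);
    }
  }

  double supSum = 0.0, distSum = 0.0;
  int nSup = 0;
  for (int e = 0; e < nEv; ++e) {
    if (!evMember[e] || evType[e] == 5) continue;
    ++nSup;
    supSum += eventCount[e] / T;
    distSum += eventCount[e] * (T - eventCount[e]);
  }
  const double sigma = (nSup > 0) ? supSum / nSup : 1.0;
  const double mu = (T >= 2.0) ? distSum / (T * (T - 1.0) / 2.0) : 0.0;

  return List::create(_["mprCount"] = T, _["belowMap"] = belowMap,
                      _["belowEv"] = belowEv, _["eventCount"] = eventCount,
                      _["meanSupport"] = sigma, _["meanPairDist"] = mu);
}

// median traversal: maximize the sum of (c(e) - T/2) over chosen non-C
// events via a best-choice DP; ties broken toward the smallest event id
// (events are canonically ordered), then the smallest source
// [[Rcpp::export]]
List cpp_median(IntegerVector mapEvPtr, IntegerVector mapEvIdx,
                IntegerVector evC1, IntegerVector evC2, IntegerVector evType,
                LogicalVector mapMember, LogicalVector evMember,
                IntegerVector sources, IntegerVector mapOrder,
                NumericVector eventCount, double T) {
  const int nMap = mapMember.size();
  NumericVector best(nMap);
  IntegerVector choice(nMap); // chosen event id (1-based), 0 = none

  for (int idx = nMap - 1; idx >= 0; --idx) {
    const int m = mapOrder[idx] - 1;
    if (!mapMember[m]) continue;
    double bb = R_NegInf;
    int bc = 0;
    for (int p = mapEvPtr[m]; p < mapEvPtr[m + 1]; ++p) {
      const int e = mapEvIdx[p] - 1;
      if (!evMember[e]) continue;
      double v = (evType[e] == 5) ? 0.0 : (eventCount[e] - T / 2.0);
      if (evC1[e] > 0) v += best[evC1[e] - 1];
      if (evC2[e] > 0) v += best[evC2[e] - 1];
      if (v > bb) { bb = v; bc = e + 1; }
    }
    best[m] = bb;
    choice[m] = bc;
  }

  int root = -1;
  double rb = R_NegInf;
  for (int i = 0; i < sources.size(); ++i) {
    const int s = sources[i] - 1;
    if (best[s] > rb) { rb = best[s]; root = s; }
  }
  if (root < 0) stop("subgraph has no source");

  std::vector<int> events;
  std::vector<int> stack;
  stack.push_back(root);
  while (!stack.empty()) {
    const int m = stack.back();
    stack.pop_back();
    const int e = choice[m];
    if (e == 0) stop("internal error: mapping node without chosen event");
    events.push_back(e);
    if (evC1[e - 1] > 0) stack.push_back(evC1[e - 1] - 1);
    if (evC2[e - 1] > 0) stack.push_back(evC2[e - 1] - 1);
  }
  std::sort(events.begin(), events.end());
  return List::create(_["events"] = wrap(events), _["root"] = root + 1);
}

// i.i.d. uniform traversals via the weighted backtrace: source picked
// proportionally to its completion count, each event child proportionally to
// its below count; uses R's RNG so set.seed() governs reproducibility
// [[Rcpp::export]]
List cpp_sample(IntegerVector mapEvPtr, IntegerVector mapEvIdx,
                IntegerVector evC1, IntegerVector evC2,
                LogicalVector mapMember, LogicalVector evMember,
                IntegerVector sources, NumericVector belowMap,
                NumericVector belowEv, double T, int nSamples) {
  List out(nSamples);
  std::vector<int> events, stack;
  for (int it = 0; it < nSamples; ++it) {
    events.clear();
    stack.clear();
    double u = unif_rand() * T;
    int root = sources[sources.size() - 1] - 1;
    for (int i = 0; i < sources.size(); ++i) {
      const int s = sources[i] - 1;
      u -= belowMap[s];
      if (u <= 0.0) { root = s; break; }
    }
    stack.push_back(root);
    while (!stack.empty()) {
      const int m = stack.back();
      stack.pop_back();
      double v = unif_rand() * belowMap[m];
      int pick = -1;
      for (int p = mapEvPtr[m]; p < mapEvPtr[m + 1]; ++p) {
        const int e = mapEvIdx[p] - 1;
        if (!evMember[e]) continue;
        pick = e;
        v -= belowEv[e];
        if (v <= 0.0) break;
      }
      if (pick < 0) stop("internal error: mapping node without member event");
      events.push_back(pick + 1);
      if (evC1[pick] > 0) stack.push_back(evC1[pick] - 1);
      if (evC2[pick] > 0) stack.push_back(evC2[pick] - 1);
    }
    std::sort(events.begin(), events.end());
    out[it] = wrap(events);
  }
  return out;
}

// reachability closure: prefix nodes plus everything reachable from the
// frontier mapping nodes, with all full-graph edges among included nodes
// [[Rcpp::export]]
List cpp_closure(IntegerVector mapEvPtr, IntegerVector mapEvIdx,
                 IntegerVector evC1, IntegerVector evC2,
                 IntegerVector frontier,
                 IntegerVector prefixMap, IntegerVector prefixEv,
                 int nMap, int nEv) {
  LogicalVector mapMember(nMap), evMember(nEv);
  for (int i = 0; i < prefixMap.size(); ++i) mapMember[prefixMap[i] - 1] = true;
  for (int i = 0; i < prefixEv.size(); ++i) evMember[prefixEv[i] - 1] = true;
  std::vector<int> stack;
  std::vector<bool> seen(nMap, false);
  for (int i = 0; i < frontier.size(); ++i) {
    const int m = frontier[i] - 1;
    mapMember[m] = true;
    if (!seen[m]) { seen[m] = true; stack.push_back(m); }
  }
  while (!stack.empty()) {
    const int m = stack.back();
    stack.pop_back();
    for (int p = mapEvPtr[m]; p < mapEvPtr[m + 1]; ++p) {
      const int e = mapEvIdx[p] - 1;
      evMember[e] = true;
      for (int k = 0; k < 2; ++k) {
        const int c = (k == 0 ? evC1[e] : evC2[e]);
        if (c > 0 && !seen[c - 1]) {
          seen[c - 1] = true;
          mapMember[c - 1] = true;
          stack.push_back(c - 1);
        }
      }
    }
  }
  return List::create(_["mapMember"] = mapMember, _["evMember"] = evMember);
}
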