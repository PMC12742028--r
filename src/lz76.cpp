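#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

// LZ76 phrase count of a binary sequence (exhaustive-history parse).
//
// A phrase ends at the first position where the candidate phrase
// s[l..l+j] does not occur starting before l (occurrences may overlap
// the phrase itself); an unterminated final phrase counts as one.
//
// Implemented with a suffix automaton of the full sequence plus the
// minimal end position of each state's occurrence class: s[l..l+j]
// occurs starting before l iff minEnd(state) <= l+j-1. This gives an
// O(n) parse, so million-sample constant and random sequences are both
// cheap. Correctness is pinned to a literal brute-force parse in the
// test suite.

struct Sam {
  std::vector<int> len, link, minEnd;
  std::vector<std::array<int, 2>> nxt;
  std::vector<bool> clone;
  int last;
  explicit Sam(int cap) {
    len.reserve(2 * cap); link.reserve(2 * cap);
    minEnd.reserve(2 * cap); nxt.reserve(2 * cap); clone.reserve(2 * cap);
    newState(0, -1, -1, false);
    last = 0;
  }
  int newState(int l, int lk, int me, bool cl) {
    len.push_back(l); link.push_back(lk); minEnd.push_back(me);
    nxt.push_back({-1, -1}); clone.push_back(cl);
    return (int)len.size() - 1;
  }
  void add(int c, int pos) {
    int cur = newState(len[last] + 1, -1, pos, false);
    int p = last;
    while (p != -1 && nxt[p][c] == -1) { nxt[p][c] = cur; p = link[p]; }
    if (p == -1) {
      link[cur] = 0;
    } else {
      int q = nxt[p][c];
      if (len[p] + 1 == len[q]) {
        link[cur] = q;
      } else {
        int cl = newState(len[p] + 1, link[q], minEnd[q], true);
        nxt[cl] = nxt[q];
        while (p != -1 && nxt[p][c] == q) { nxt[p][c] = cl; p = link[p]; }
        link[q] = cl;
        link[cur] = cl;
      }
    }
    last = cur;
  }
};

// [[Rcpp::export]]
int lz76_count_cpp(IntegerVector s) {
  const int n = s.size();
  if (n < 1) stop("empty sequence");
  for (int t = 0; t < n; ++t)
    if (s[t] != 0 && s[t] != 1) stop("sequence must be binary (0/1)");
  if (n == 1) return 1;

  Sam sam(n);
  for (int i = 0; i < n; ++i) sam.add(s[i], i);
  // propagate minimal end positions up the suffix-link tree
  std::vector<int> order(sam.len.size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return sam.len[a] > sam.len[b]; });
  for (int v : order) {
    int p = sam.link[v];
    if (p >= 0 && sam.minEnd[v] >= 0 &&
        (sam.minEnd[p] < 0 || sam.minEnd[v] < sam.minEnd[p]))
      sam.minEnd[p] = sam.minEnd[v];
  }

  int c = 0, l = 0;
  while (l < n) {
    int state = 0, j = 0;
    bool unterminated = false;
    while (true) {
      if (l + j >= n) { unterminated = true; break; }
      int to = sam.nxt[state][s[l + j]];
      bool seen_before = false;
      if (to != -1 && sam.minEnd[to] <= l + j - 1) seen_before = true;
      if (!seen_before) break;
      state = to;
      ++j;
    }
    ++c;
    l = unterminated ? n : l + j + 1;
  }
  return c;
}
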