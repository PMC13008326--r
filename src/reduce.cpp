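#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Persistence of a filtered 2-D cubical complex (V-construction) by column
// reduction over Z/2, optionally extended (coned complex).
//
// Cells are indexed 1..N in the order: vertices (1..V), edges (V+1..V+E),
// squares (V+E+1..N). `edges` holds the two vertex ids of each edge,
// `square_edges` the four edge ids (1..E) of each square. `asc_pos` gives
// each cell's (1-based) column position in the ascending filtration order;
// when `extended` is true, position 1 is reserved for the cone vertex, the
// ascending cells occupy 2..N+1 as given, and `desc_pos` places the coned
// cells at N+2..2N+1 in descending order of minimum vertex value.
//
// Returns the (birth, death) column pairs; zero columns never used as a
// pivot are returned in the `essential` attribute.
// [[Rcpp::export]]
IntegerMatrix eph_reduce(int V, IntegerMatrix edges, IntegerMatrix square_edges,
                         IntegerVector asc_pos, IntegerVector desc_pos,
                         bool extended) {
  const int E = edges.nrow();
  const int S = square_edges.nrow();
  const int N = V + E + S;
  const int M = extended ? 2 * N + 1 : N;
  std::vector<std::vector<int>> cols(M + 1);  // 1-based columns
  for (int i = 1; i <= N; ++i) {
    std::vector<int> &c = cols[asc_pos[i - 1]];
    if (i <= V) {
      // vertex: empty boundary
    } else if (i <= V + E) {
      int e = i - V - 1;
      c.push_back(asc_pos[edges(e, 0) - 1]);
      c.push_back(asc_pos[edges(e, 1) - 1]);
    } else {
      int s = i - V - E - 1;
      for (int k = 0; k < 4; ++k)
        c.push_back(asc_pos[V + square_edges(s, k) - 1]);
    }
    std::sort(c.begin(), c.end());
    if (extended) {
      std::vector<int> &d = cols[desc_pos[i - 1]];
      d.push_back(asc_pos[i - 1]);
      if (i <= V) {
        d.push_back(1);  // cone vertex
      } else if (i <= V + E) {
        int e = i - V - 1;
        d.push_back(desc_pos[edges(e, 0) - 1]);
        d.push_back(desc_pos[edges(e, 1) - 1]);
      } else {
        int s = i - V - E - 1;
        for (int k = 0; k < 4; ++k)
          d.push_back(desc_pos[V + square_edges(s, k) - 1]);
      }
      std::sort(d.begin(), d.end());
    }
  }
  // column dimensions, for the twist (clearing) optimization: reduce
  // higher-dimensional columns first and clear each pivot column.
  std::vector<int> coldim(M + 1, 0);
  for (int i = 1; i <= N; ++i) {
    int d = (i <= V) ? 0 : (i <= V + E ? 1 : 2);
    coldim[asc_pos[i - 1]] = d;
    if (extended) coldim[desc_pos[i - 1]] = d + 1;
  }
  int maxdim = extended ? 3 : 2;
  std::vector<int> pivot(M + 1, -1);
  std::vector<bool> cleared(M + 1, false);
  std::vector<int> birth, death;
  std::vector<int> tmp;
  for (int d = maxdim; d >= 0; --d) {
    for (int j = 1; j <= M; ++j) {
      if (coldim[j] != d || cleared[j]) continue;
      std::vector<int> &c = cols[j];
      while (!c.empty()) {
        int low = c.back();
        int k = pivot[low];
        if (k < 0) break;
        tmp.clear();
        std::set_symmetric_difference(c.begin(), c.end(),
                                      cols[k].begin(), cols[k].end(),
                                      std::back_inserter(tmp));
        c.swap(tmp);
      }
      if (!c.empty()) {
        int low = c.back();
        pivot[low] = j;
        birth.push_back(low);
        death.push_back(j);
        cols[low].clear();
        cleared[low] = true;
      }
    }
  }
  std::vector<bool> paired(M + 1, false);
  for (size_t t = 0; t < birth.size(); ++t) {
    paired[birth[t]] = true;
    paired[death[t]] = true;
  }
  std::vector<int> essential;
  for (int j = 1; j <= M; ++j)
    if (!paired[j]) essential.push_back(j);
  IntegerMatrix out(birth.size(), 2);
  for (size_t t = 0; t < birth.size(); ++t) {
    out(t, 0) = birth[t];
    out(t, 1) = death[t];
  }
  colnames(out) = CharacterVector::create("birth", "death");
  out.attr("essential") = wrap(essential);
  return out;
}
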