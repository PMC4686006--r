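#include <Rcpp.h>
#include <queue>
#include <vector>

using namespace Rcpp;

// Absolute fuzzy connectedness on a 4-connected pixel grid.
//
// connectivity(d) = max over paths from the seed set to d of the minimum
// pair affinity along the path.  Computed by best-first label setting (the
// widest-path variant of Dijkstra): pop the pixel with the largest tentative
// strength; its value is then final, because any alternative path through a
// weaker pixel cannot beat it (path strength is min-composed and affinities
// are <= 1).  Heap tie order therefore cannot change the result.
//
// h: nr x (nc-1) affinities between (r,c) and (r,c+1)
// v: (nr-1) x nc affinities between (r,c) and (r+1,c)
// seeds: m x 2 matrix of 1-based (row, col)
// [[Rcpp::export(name = ".afc_connectivity")]]
NumericMatrix afc_connectivity_cpp(NumericMatrix h, NumericMatrix v,
                                   IntegerMatrix seeds, int nr, int nc) {
  NumericMatrix conn(nr, nc);
  std::fill(conn.begin(), conn.end(), 0.0);
  std::vector<bool> done((size_t)nr * nc, false);

  typedef std::pair<double, int> Node;  // (strength, flat index r + c*nr)
  std::priority_queue<Node> heap;

  for (int i = 0; i < seeds.nrow(); ++i) {
    int r = seeds(i, 0) - 1, c = seeds(i, 1) - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("seed out of bounds");
    conn(r, c) = 1.0;
    heap.push(Node(1.0, r + c * nr));
  }

  while (!heap.empty()) {
    Node top = heap.top();
    heap.pop();
    int idx = top.second;
    if (done[idx]) continue;
    done[idx] = true;
    int r = idx % nr, c = idx / nr;
    double s = conn(r, c);

    // relax the 4 neighbours through the pair affinity
    // left
    if (c > 0) {
      double w = std::min(s, h(r, c - 1));
      if (w > conn(r, c - 1)) {
        conn(r, c - 1) = w;
        heap.push(Node(w, r + (c - 1) * nr));
      }
    }
    // right
    if (c + 1 < nc) {
      double w = std::min(s, h(r, c));
      if (w > conn(r, c + 1)) {
        conn(r, c + 1) = w;
        heap.push(Node(w, r + (c + 1) * nr));
      }
    }
    // up
    if (r > 0) {
      double w = std::min(s, v(r - 1, c));
      if (w > conn(r - 1, c)) {
        conn(r - 1, c) = w;
        heap.push(Node(w, (r - 1) + c * nr));
      }
    }
    // down
    if (r + 1 < nr) {
      double w = std::min(s, v(r, c));
      if (w > conn(r + 1, c)) {
        conn(r + 1, c) = w;
        heap.push(Node(w, (r + 1) + c * nr));
      }
    }
  }
  return conn;
}
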