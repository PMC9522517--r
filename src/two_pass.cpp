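#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Union-find with path compression; roots resolved fully in pass two.
static int uf_find(std::vector<int>& parent, int x) {
  int root = x;
  while (parent[root] != root) root = parent[root];
  while (parent[x] != root) {
    int next = parent[x];
    parent[x] = root;
    x = next;
  }
  return root;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a);
  int rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass connected-component labeling of a binary grid.
// Pass one scans in raster order (rows top to bottom, left to right),
// assigning provisional labels from the already-visited neighbours and
// recording label equivalences; pass two resolves the equivalence classes
// and renumbers components 1..n in the raster order in which each
// component's first pixel was encountered.
// [[Rcpp::export]]
IntegerMatrix cpp_two_pass_label(const LogicalMatrix& mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> parent(1, 0); // provisional labels start at 1
  int next_label = 0;

  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      if (!mask(y, x)) continue;
      // previously-visited neighbours in raster order
      int neigh[4];
      int nn = 0;
      if (x > 0 && mask(y, x - 1)) neigh[nn++] = lab(y, x - 1);
      if (y > 0) {
        if (connectivity == 8 && x > 0 && mask(y - 1, x - 1))
          neigh[nn++] = lab(y - 1, x - 1);
        if (mask(y - 1, x)) neigh[nn++] = lab(y - 1, x);
        if (connectivity == 8 && x + 1 < w && mask(y - 1, x + 1))
          neigh[nn++] = lab(y - 1, x + 1);
      }
      if (nn == 0) {
        ++next_label;
        parent.push_back(next_label);
        lab(y, x) = next_label;
      } else {
        int m = neigh[0];
        for (int k = 1; k < nn; ++k) m = std::min(m, neigh[k]);
        lab(y, x) = m;
        for (int k = 0; k < nn; ++k) uf_union(parent, m, neigh[k]);
      }
    }
  }

  // pass two: one sweep assigning final labels (first-encounter order)
  std::vector<int> final_label(next_label + 1, 0);
  int n_comp = 0;
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      int l = lab(y, x);
      if (l == 0) continue;
      int r = uf_find(parent, l);
      if (final_label[r] == 0) final_label[r] = ++n_comp;
      lab(y, x) = final_label[r];
    }
  }
  lab.attr("n_components") = n_comp;
  return lab;
}
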