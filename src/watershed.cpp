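#include <Rcpp.h>
#include <queue>
#include <vector>

using namespace Rcpp;

// Seeded watershed by priority flood. Seeds are grown over `height`,
// restricted to `mask`. Each pixel is queued at its own height; among equal
// heights the earliest insertion wins, which makes the result deterministic
// and lets ideal (target-derived) height maps reproduce the original
// partition exactly on the ridge between touching objects.
// [[Rcpp::export(name = ".watershed_flood")]]
IntegerMatrix watershed_flood(NumericMatrix height, IntegerMatrix seeds,
                              LogicalMatrix mask) {
  const int H = height.nrow(), W = height.ncol();
  if (seeds.nrow() != H || seeds.ncol() != W || mask.nrow() != H ||
      mask.ncol() != W)
    stop("height, seeds and mask must share the same shape");

  IntegerMatrix out(H, W);

  struct Entry {
    double h;
    long long order;
    int idx;
    int label;
  };
  struct Cmp {
    bool operator()(const Entry& a, const Entry& b) const {
      if (a.h != b.h) return a.h > b.h;   // lowest height first
      return a.order > b.order;           // FIFO among equal heights
    }
  };
  std::priority_queue<Entry, std::vector<Entry>, Cmp> pq;
  long long counter = 0;

  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (seeds(i, j) > 0 && mask(i, j)) {
        int idx = j * H + i;
        pq.push({height(i, j), counter++, idx, seeds(i, j)});
      }

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  while (!pq.empty()) {
    Entry e = pq.top();
    pq.pop();
    int i = e.idx % H, j = e.idx / H;
    if (out(i, j) != 0) continue;
    out(i, j) = e.label;
    for (int k = 0; k < 4; ++k) {
      int ni = i + dr[k], nj = j + dc[k];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      if (!mask(ni, nj) || out(ni, nj) != 0) continue;
      pq.push({height(ni, nj), counter++, nj * H + ni, e.label});
    }
  }
  return out;
}
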