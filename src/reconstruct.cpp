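#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Grayscale morphological reconstruction by dilation (8-connectivity),
// hybrid raster/anti-raster sweep followed by FIFO queue propagation
// (Vincent 1993). marker must be <= mask everywhere; returns the
// reconstruction of marker under mask.

// [[Rcpp::export(name = ".reconstructDilateCpp")]]
NumericMatrix reconstructDilateCpp(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix J(clone(marker));

  // clip marker under mask
  for (int i = 0; i < nr * nc; ++i)
    if (J[i] > mask[i]) J[i] = mask[i];

  // forward raster scan: neighbours already visited in column-major order
  // (previous column, and previous row within this column)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = J(r, c);
      if (r > 0 && J(r - 1, c) > v) v = J(r - 1, c);
      if (c > 0) {
        if (J(r, c - 1) > v) v = J(r, c - 1);
        if (r > 0 && J(r - 1, c - 1) > v) v = J(r - 1, c - 1);
        if (r < nr - 1 && J(r + 1, c - 1) > v) v = J(r + 1, c - 1);
      }
      if (v > mask(r, c)) v = mask(r, c);
      J(r, c) = v;
    }
  }

  // backward scan + seed the queue
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double v = J(r, c);
      if (r < nr - 1 && J(r + 1, c) > v) v = J(r + 1, c);
      if (c < nc - 1) {
        if (J(r, c + 1) > v) v = J(r, c + 1);
        if (r < nr - 1 && J(r + 1, c + 1) > v) v = J(r + 1, c + 1);
        if (r > 0 && J(r - 1, c + 1) > v) v = J(r - 1, c + 1);
      }
      if (v > mask(r, c)) v = mask(r, c);
      J(r, c) = v;
      // enqueue if a later-scanned neighbour could still be raised
      bool enq = false;
      if (r < nr - 1 && J(r + 1, c) < J(r, c) && J(r + 1, c) < mask(r + 1, c)) enq = true;
      if (!enq && c < nc - 1) {
        if (J(r, c + 1) < J(r, c) && J(r, c + 1) < mask(r, c + 1)) enq = true;
        else if (r < nr - 1 && J(r + 1, c + 1) < J(r, c) && J(r + 1, c + 1) < mask(r + 1, c + 1)) enq = true;
        else if (r > 0 && J(r - 1, c + 1) < J(r, c) && J(r - 1, c + 1) < mask(r - 1, c + 1)) enq = true;
      }
      if (enq) fifo.push(r + c * nr);
    }
  }

  const int drs[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dcs[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int r = p % nr, c = p / nr;
    double jp = J(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + drs[k], cc = c + dcs[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      double jq = J(rr, cc), mq = mask(rr, cc);
      if (jq < jp && jq < mq) {
        J(rr, cc) = jp < mq ? jp : mq;
        fifo.push(rr + cc * nr);
      }
    }
  }
  return J;
}
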