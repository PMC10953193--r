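#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 6-connected component labelling on a binary 3D mask (dim c(Z, Y, X)).
// Labels are 1..n in discovery order, background 0.
// [[Rcpp::export]]
IntegerVector label3d_cpp(const LogicalVector& mask, IntegerVector dim) {
  const int Z = dim[0], Y = dim[1], X = dim[2];
  const size_t n = static_cast<size_t>(Z) * Y * X;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      const size_t i = q.front(); q.pop();
      const int z = i % Z, y = (i / Z) % Y, x = i / (static_cast<size_t>(Z) * Y);
      const int dz[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dx[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        const int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) continue;
        const size_t j = zz + static_cast<size_t>(Z) * (yy + static_cast<size_t>(Y) * xx);
        if (mask[j] && !lab[j]) { lab[j] = next; q.push(j); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// One 6-connected (city-block) dilation step, iterated r times.
// [[Rcpp::export]]
LogicalVector dilate3d_cpp(const LogicalVector& mask, IntegerVector dim, int r) {
  const int Z = dim[0], Y = dim[1], X = dim[2];
  const size_t n = static_cast<size_t>(Z) * Y * X;
  std::vector<char> cur(n), nxt(n);
  for (size_t i = 0; i < n; ++i) cur[i] = mask[i];
  for (int it = 0; it < r; ++it) {
    nxt = cur;
    for (int x = 0; x < X; ++x)
      for (int y = 0; y < Y; ++y)
        for (int z = 0; z < Z; ++z) {
          const size_t i = z + static_cast<size_t>(Z) * (y + static_cast<size_t>(Y) * x);
          if (cur[i]) continue;
          if ((z > 0 && cur[i - 1]) || (z < Z - 1 && cur[i + 1]) ||
              (y > 0 && cur[i - Z]) || (y < Y - 1 && cur[i + Z]) ||
              (x > 0 && cur[i - static_cast<size_t>(Z) * Y]) ||
              (x < X - 1 && cur[i + static_cast<size_t>(Z) * Y]))
            nxt[i] = 1;
        }
    cur.swap(nxt);
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = cur[i] != 0;
  out.attr("dim") = dim;
  return out;
}
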