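// Queue-based pixel algorithms: connected-component labeling, the
// interior-expansion instance decoder, and marker-based watershed.
// All matrices are column-major (R layout), indexed (row, col).

#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

static inline int idx(int r, int c, int H) { return c * H + r; }

struct Neigh {
  int dr[8], dc[8], n;
  explicit Neigh(int connectivity) {
    static const int DR4[] = {-1, 1, 0, 0}, DC4[] = {0, 0, -1, 1};
    static const int DR8[] = {-1, 1, 0, 0, -1, -1, 1, 1},
                     DC8[] = {0, 0, -1, 1, -1, 1, -1, 1};
    n = (connectivity == 4) ? 4 : 8;
    const int* r = (connectivity == 4) ? DR4 : DR8;
    const int* c = (connectivity == 4) ? DC4 : DC8;
    for (int k = 0; k < n; ++k) { dr[k] = r[k]; dc[k] = c[k]; }
  }
};

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  Neigh nb(connectivity);
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < W; ++c0) for (int r0 = 0; r0 < H; ++r0) {
    if (!mask(r0, c0) || lab(r0, c0)) continue;
    ++next;
    stack.clear(); stack.push_back(idx(r0, c0, H));
    lab(r0, c0) = next;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int r = p % H, c = p / H;
      for (int k = 0; k < nb.n; ++k) {
        int rr = r + nb.dr[k], cc = c + nb.dc[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (mask(rr, cc) && !lab(rr, cc)) {
          lab(rr, cc) = next;
          stack.push_back(idx(rr, cc, H));
        }
      }
    }
  }
  return lab;
}

// Interior expansion: synchronized seeded growth over a 3-class probability
// field. Frontier pixels claim admissible unassigned neighbours each
// iteration; a pixel claimable by two labels in one iteration is contested
// and stays unassigned; stepping past the boundary-probability crest marks
// the crest pixel for discard (unless it is an original seed pixel).
//
// Admissibility of q from p: background is not the argmax class at q, and
// (p_boundary(q) >= p_boundary(p) - eps  OR  interior is argmax at q).
// A neighbour q that is non-background-dominant but whose boundary
// probability has dropped (ridge descent) stops growth in that direction
// and flags p as a last-iteration boundary pixel, removed at the end.
// [[Rcpp::export(name = ".cpp_interior_expansion")]]
IntegerMatrix cpp_interior_expansion(const NumericMatrix& p_bg,
                                     const NumericMatrix& p_in,
                                     const NumericMatrix& p_bd,
                                     const IntegerMatrix& seeds,
                                     int connectivity, double eps,
                                     int max_iterations) {
  const int H = seeds.nrow(), W = seeds.ncol(), N = H * W;
  Neigh nb(connectivity);
  IntegerMatrix lab(clone(seeds));
  std::vector<char> is_seed(N), contested(N), discard(N);
  std::vector<int> frontier, next_frontier, claim(N, 0);
  std::vector<int> touched;

  // argmax class per pixel: 0 bg, 1 interior, 2 boundary (ties favour
  // the non-background class so plateaus at equality can still grow)
  std::vector<char> amax(N);
  for (int c = 0; c < W; ++c) for (int r = 0; r < H; ++r) {
    double b = p_bg(r, c), i = p_in(r, c), d = p_bd(r, c);
    char a;
    if (i >= b && i >= d) a = 1;        // interior wins ties
    else if (d >= b)      a = 2;        // then boundary
    else                  a = 0;
    amax[idx(r, c, H)] = a;
  }
  for (int p = 0; p < N; ++p) if (lab[p]) { is_seed[p] = 1; frontier.push_back(p); }

  for (int it = 0; it < max_iterations && !frontier.empty(); ++it) {
    touched.clear();
    for (size_t f = 0; f < frontier.size(); ++f) {
      int p = frontier[f];
      int r = p % H, c = p / H, lp = lab[p];
      double pb_p = p_bd(r, c);
      for (int k = 0; k < nb.n; ++k) {
        int rr = r + nb.dr[k], cc = c + nb.dc[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        int q = idx(rr, cc, H);
        if (lab[q] || contested[q]) continue;
        if (amax[q] == 0) continue;                    // background-dominant: stop
        bool admissible = (p_bd(rr, cc) >= pb_p - eps) || amax[q] == 1;
        if (!admissible) {                             // past the crest
          if (!is_seed[p]) discard[p] = 1;
          continue;
        }
        if (claim[q] == 0) { claim[q] = lp; touched.push_back(q); }
        else if (claim[q] != lp && claim[q] != -1) { claim[q] = -1; contested[q] = 1; }
      }
    }
    next_frontier.clear();
    for (size_t t = 0; t < touched.size(); ++t) {
      int q = touched[t];
      if (claim[q] > 0) { lab[q] = claim[q]; next_frontier.push_back(q); }
      claim[q] = 0;
    }
    frontier.swap(next_frontier);
  }
  for (int p = 0; p < N; ++p) if (discard[p] && !is_seed[p]) lab[p] = 0;
  return lab;
}

// Meyer's flooding from markers: pixels inside `region` are flooded in
// order of increasing elevation; a pixel first reached from one labeled
// region takes that label, pixels reached by competing labels become
// watershed lines (label 0).
// [[Rcpp::export(name = ".cpp_marker_watershed")]]
IntegerMatrix cpp_marker_watershed(const NumericMatrix& elevation,
                                   const IntegerMatrix& markers,
                                   const LogicalMatrix& region,
                                   int connectivity) {
  const int H = markers.nrow(), W = markers.ncol();
  Neigh nb(connectivity);
  IntegerMatrix lab(clone(markers));
  typedef std::pair<double, std::pair<long long, int> > QE; // (elev, (order, pixel))
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  long long order = 0;
  std::vector<char> queued(H * W, 0);

  for (int c = 0; c < W; ++c) for (int r = 0; r < H; ++r)
    if (lab(r, c) > 0) {
      pq.push(QE(elevation(r, c), std::make_pair(order++, idx(r, c, H))));
      queued[idx(r, c, H)] = 1;
    }
  while (!pq.empty()) {
    int p = pq.top().second.second; pq.pop();
    int r = p % H, c = p / H, lp = lab(r, c);
    if (lp <= 0) continue;
    for (int k = 0; k < nb.n; ++k) {
      int rr = r + nb.dr[k], cc = c + nb.dc[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      int q = idx(rr, cc, H);
      if (!region(rr, cc) || queued[q] || lab(rr, cc) != 0) continue;
      lab(rr, cc) = lp;
      queued[q] = 1;
      pq.push(QE(elevation(rr, cc), std::make_pair(order++, q)));
    }
  }
  return lab;
}

// im2col gather: xm is (H*W) x C, idx is (H*W) x (k*k) of 1-based source
// indices with 0 marking zero padding. Output (H*W) x (k*k*C), offset
// fastest then channel, matching the (k, k, Cin, Cout) weight layout.
// [[Rcpp::export(name = ".cpp_gather_cols")]]
NumericMatrix cpp_gather_cols(const NumericMatrix& xm, const IntegerMatrix& idx) {
  const int N = xm.nrow(), C = xm.ncol(), K = idx.ncol();
  NumericMatrix out(N, K * C);
  for (int ch = 0; ch < C; ++ch) {
    const double* xcol = &xm(0, ch);
    for (int o = 0; o < K; ++o) {
      double* ocol = &out(0, ch * K + o);
      const int* icol = &idx(0, o);
      for (int p = 0; p < N; ++p) {
        int s = icol[p];
        ocol[p] = (s > 0) ? xcol[s - 1] : 0.0;
      }
    }
  }
  return out;
}

// col2im scatter-add, inverse of the gather above.
// [[Rcpp::export(name = ".cpp_scatter_cols")]]
NumericMatrix cpp_scatter_cols(const NumericMatrix& dcols, const IntegerMatrix& idx,
                               int C) {
  const int N = idx.nrow(), K = idx.ncol();
  NumericMatrix out(N, C);
  for (int ch = 0; ch < C; ++ch) {
    double* ocol = &out(0, ch);
    for (int o = 0; o < K; ++o) {
      const double* dcol = &dcols(0, ch * K + o);
      const int* icol = &idx(0, o);
      for (int p = 0; p < N; ++p) {
        int s = icol[p];
        if (s > 0) ocol[s - 1] += dcol[p];
      }
    }
  }
  return out;
}
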