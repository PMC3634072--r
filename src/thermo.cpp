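// Thermodynamic core: single-stem hairpin folding (full DP with
// traceback and a banded whole-contig scan), intermolecular duplex
// hybridization DP, and a seed-weighted complementarity Smith-Waterman.
// Bases are encoded A=0, C=1, G=2, U=3, N/other=4 (never pairs).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e9;

struct Model {
  double stack[16][16];   // [outer 5'b*4+3'b][inner 5'b*4+3'b]; INF if invalid
  double hairpin_base, hairpin_slope;
  double bulge_base, bulge_slope;
  double internal_base, internal_slope;
  int min_loop, max_interior;
  bool pairable[5][5];
};

static Model make_model(List params) {
  Model m;
  NumericMatrix s16 = params["stack16"];
  for (int i = 0; i < 16; ++i)
    for (int j = 0; j < 16; ++j) m.stack[i][j] = s16(i, j);
  m.hairpin_base = params["hairpin_base"];
  m.hairpin_slope = params["hairpin_slope"];
  m.bulge_base = params["bulge_base"];
  m.bulge_slope = params["bulge_slope"];
  m.internal_base = params["internal_base"];
  m.internal_slope = params["internal_slope"];
  m.min_loop = params["min_loop"];
  m.max_interior = params["max_interior"];
  for (int x = 0; x < 5; ++x)
    for (int y = 0; y < 5; ++y)
      m.pairable[x][y] = (x < 4 && y < 4 && m.stack[x * 4 + y][x * 4 + y] < INF / 2);
  return m;
}

static inline double loop_step(const Model& m, int d1, int d2,
                               int pout, int pin) {
  if (d1 == 0 && d2 == 0) return m.stack[pout][pin];
  if (d1 == 0 || d2 == 0) return m.bulge_base + m.bulge_slope * (d1 + d2);
  return m.internal_base + m.internal_slope * (d1 + d2);
}

// ---------------------------------------------------------------------------
// Full single-stem fold of one sequence, with traceback.
// Returns NULL when no structure with dG < 0 exists.
// [[Rcpp::export(name = ".fold_full_cpp")]]
SEXP fold_full_cpp(IntegerVector seq, List params) {
  Model m = make_model(params);
  int n = seq.size();
  if (n < m.min_loop + 2) return R_NilValue;
  std::vector<double> W((size_t)n * n, INF);
  std::vector<int> np((size_t)n * n, 0), ck((size_t)n * n, -2),
      cl((size_t)n * n, -2), ll((size_t)n * n, 0);
  auto idx = [n](int i, int j) { return (size_t)i * n + j; };

  for (int d = m.min_loop + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      int bi = seq[i], bj = seq[j];
      if (!m.pairable[bi][bj]) continue;
      int pij = bi * 4 + bj;
      double best = INF; int bnp = 0, bk = -2, bl = -2, bll = 0;
      // close with a terminal loop
      if (d - 1 >= m.min_loop) {
        best = m.hairpin_base + m.hairpin_slope * (d - 1 - m.min_loop);
        bnp = 1; bk = -1; bl = -1; bll = d - 1;
      }
      // extend inward
      for (int d1 = 0; d1 <= m.max_interior; ++d1) {
        int k = i + 1 + d1;
        if (k >= j) break;
        for (int d2 = 0; d2 + d1 <= m.max_interior; ++d2) {
          int l = j - 1 - d2;
          if (l <= k) break;
          double w = W[idx(k, l)];
          if (w >= INF / 2) continue;
          double e = w + loop_step(m, d1, d2, pij, seq[k] * 4 + seq[l]);
          int npk = np[idx(k, l)] + 1;
          if (e < best - 1e-12 ||
              (std::fabs(e - best) <= 1e-12 && npk > bnp)) {
            best = e; bnp = npk; bk = k; bl = l; bll = ll[idx(k, l)];
          }
        }
      }
      if (best < INF / 2) {
        W[idx(i, j)] = best; np[idx(i, j)] = bnp;
        ck[idx(i, j)] = bk; cl[idx(i, j)] = bl; ll[idx(i, j)] = bll;
      }
    }
  }

  // best closing pair: lowest energy, ties to 5'-most then longest span
  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i)
    for (int j = n - 1; j > i; --j) {
      double w = W[idx(i, j)];
      if (w >= INF / 2) continue;
      bool better = w < best - 1e-12;
      bool tie = std::fabs(w - best) <= 1e-12 && bi >= 0;
      if (better ||
          (tie && (i < bi || (i == bi && (j - i) > (bj - bi))))) {
        best = w; bi = i; bj = j;
      }
    }
  if (bi < 0 || best >= -1e-12) return R_NilValue;

  std::vector<int> pi, pj;
  int i = bi, j = bj;
  while (i >= 0) {
    pi.push_back(i); pj.push_back(j);
    int k = ck[idx(i, j)], l = cl[idx(i, j)];
    if (k < 0) break;
    i = k; j = l;
  }
  IntegerMatrix pairs(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) { pairs(k, 0) = pi[k]; pairs(k, 1) = pj[k]; }
  return List::create(_["dG"] = best, _["pairs"] = pairs,
                      _["outer_i"] = bi, _["outer_j"] = bj,
                      _["loop_len"] = ll[idx(bi, bj)]);
}

// ---------------------------------------------------------------------------
// Banded scan: score every closing pair with span within [min_len, max_len]
// over a whole contig; report cells passing the hairpin thresholds.
// [[Rcpp::export(name = ".stem_scan_cpp")]]
DataFrame stem_scan_cpp(IntegerVector seq, List params, int min_len,
                        int max_len, int min_pairs, int max_loop,
                        double dg_max) {
  Model m = make_model(params);
  int n = seq.size();
  int B = max_len;  // spans d = j - i in 1 .. B-1
  if (n < min_len) return DataFrame::create(
      _["start"] = IntegerVector(0), _["end"] = IntegerVector(0),
      _["dG"] = NumericVector(0), _["npairs"] = IntegerVector(0),
      _["loop_len"] = IntegerVector(0));
  std::vector<double> W((size_t)n * B, INF);
  std::vector<short> np((size_t)n * B, 0), ll((size_t)n * B, 0);
  auto idx = [B](int i, int d) { return (size_t)i * B + d; };

  std::vector<int> oi, oj; std::vector<double> oe;
  std::vector<int> onp, oll;

  for (int d = m.min_loop + 1; d < B; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      int bi = seq[i], bj = seq[j];
      if (!m.pairable[bi][bj]) continue;
      int pij = bi * 4 + bj;
      double best = INF; int bnp = 0, bll = 0;
      if (d - 1 >= m.min_loop) {
        best = m.hairpin_base + m.hairpin_slope * (d - 1 - m.min_loop);
        bnp = 1; bll = d - 1;
      }
      for (int d1 = 0; d1 <= m.max_interior; ++d1) {
        int k = i + 1 + d1;
        int dmax = d - 2 - d1;
        if (dmax < 1) break;
        const size_t row = (size_t)k * B;
        for (int d2 = 0; d2 + d1 <= m.max_interior; ++d2) {
          int dp = d - 2 - d1 - d2;
          if (dp < 1) break;
          double w = W[row + dp];
          if (w >= INF / 2) continue;
          int l = j - 1 - d2;
          double e = w + loop_step(m, d1, d2, pij, seq[k] * 4 + seq[l]);
          int npk = np[row + dp] + 1;
          if (e < best - 1e-12 ||
              (std::fabs(e - best) <= 1e-12 && npk > bnp)) {
            best = e; bnp = npk; bll = ll[row + dp];
          }
        }
      }
      if (best < INF / 2) {
        W[idx(i, d)] = best; np[idx(i, d)] = (short)bnp; ll[idx(i, d)] = (short)bll;
        if (d + 1 >= min_len && best <= dg_max && bnp >= min_pairs &&
            bll <= max_loop) {
          oi.push_back(i); oj.push_back(j); oe.push_back(best);
          onp.push_back(bnp); oll.push_back(bll);
        }
      }
    }
  }
  IntegerVector start(oi.begin(), oi.end()), end(oj.size());
  for (size_t k = 0; k < oj.size(); ++k) end[k] = oj[k] + 1;
  return DataFrame::create(_["start"] = start, _["end"] = end,
                           _["dG"] = NumericVector(oe.begin(), oe.end()),
                           _["npairs"] = IntegerVector(onp.begin(), onp.end()),
                           _["loop_len"] = IntegerVector(oll.begin(), oll.end()));
}

// ---------------------------------------------------------------------------
// Intermolecular duplex DP: pairs (i on miRNA, j on target) extend with
// i increasing and j decreasing; interior loops/bulges up to max_interior
// unpaired bases per step; no intramolecular pairs; helix initiation 0.
// [[Rcpp::export(name = ".duplex_cpp")]]
SEXP duplex_cpp(IntegerVector mir, IntegerVector tgt, List params,
                bool all_sites, int max_sites) {
  Model mo = make_model(params);
  int M = mir.size(), N = tgt.size();
  std::vector<double> H((size_t)M * N, INF);
  std::vector<int> ts((size_t)M * N, -1), ms((size_t)M * N, -1);
  std::vector<int> pk((size_t)M * N, -2), pl((size_t)M * N, -2);
  auto idx = [N](int i, int j) { return (size_t)i * N + j; };

  for (int i = 0; i < M; ++i) {
    for (int j = N - 1; j >= 0; --j) {
      if (!mo.pairable[mir[i]][tgt[j]]) continue;
      int pij = mir[i] * 4 + tgt[j];
      double best = 0.0; int bk = -1, bl = -1, bts = j, bms = i;
      for (int d1 = 0; d1 <= mo.max_interior; ++d1) {
        int k = i - 1 - d1;
        if (k < 0) break;
        const size_t row = (size_t)k * N;
        for (int d2 = 0; d2 + d1 <= mo.max_interior; ++d2) {
          int l = j + 1 + d2;
          if (l >= N) break;
          double h = H[row + l];
          if (h >= INF / 2) continue;
          double e = h + loop_step(mo, d1, d2, mir[k] * 4 + tgt[l], pij);
          if (e < best - 1e-12) {
            best = e; bk = k; bl = l; bts = ts[row + l]; bms = ms[row + l];
          }
        }
      }
      H[idx(i, j)] = best; pk[idx(i, j)] = bk; pl[idx(i, j)] = bl;
      ts[idx(i, j)] = bts; ms[idx(i, j)] = bms;
    }
  }

  // candidate complete duplexes: all cells with energy < 0
  std::vector<size_t> cand;
  for (size_t c = 0; c < H.size(); ++c)
    if (H[c] < -1e-12) cand.push_back(c);
  if (cand.empty()) return R_NilValue;
  std::stable_sort(cand.begin(), cand.end(), [&](size_t a, size_t b) {
    if (H[a] != H[b]) return H[a] < H[b];
    return (a % N) < (b % N);  // tie: leftmost target end
  });

  int nkeep = all_sites ? max_sites : 1;
  std::vector<size_t> kept;
  std::vector<std::pair<int, int> > spans;  // [t_start, t_end) kept sites
  for (size_t c : cand) {
    if ((int)kept.size() >= nkeep) break;
    int t0 = (int)(c % N), t1 = ts[c] + 1;
    bool clash = false;
    for (auto& s : spans)
      if (t0 < s.second && s.first < t1) { clash = true; break; }
    if (clash) continue;
    kept.push_back(c);
    spans.push_back(std::make_pair(t0, t1));
  }

  List out(kept.size());
  for (size_t k = 0; k < kept.size(); ++k) {
    size_t c = kept[k];
    int i = (int)(c / N), j = (int)(c % N);
    std::vector<int> qi, qj;
    int ci = i, cj = j;
    while (ci >= 0) {
      qi.push_back(ci); qj.push_back(cj);
      int nk = pk[idx(ci, cj)], nl = pl[idx(ci, cj)];
      if (nk < 0) break;
      ci = nk; cj = nl;
    }
    IntegerMatrix pairs(qi.size(), 2);
    // reverse so pairs run 5'->3' along the miRNA
    for (size_t q = 0; q < qi.size(); ++q) {
      pairs(qi.size() - 1 - q, 0) = qi[q];
      pairs(qi.size() - 1 - q, 1) = qj[q];
    }
    out[k] = List::create(_["dG"] = H[c], _["pairs"] = pairs,
                          _["t_start"] = j, _["t_end"] = ts[c] + 1,
                          _["m_start"] = ms[c], _["m_end"] = i + 1);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Seed-weighted complementarity Smith-Waterman (affine gaps).
// a = miRNA 5'->3'; b = target reversed so both run in pairing register.
// Pair scores: wc, gu, mismatch; doubled at miRNA positions 2..8 (1-based).
// [[Rcpp::export(name = ".comp_scan_cpp")]]
DataFrame comp_scan_cpp(IntegerVector mir, IntegerVector tgt_rev,
                        double wc, double gu, double mismatch,
                        double gap_open, double gap_ext,
                        double seed_weight, int seed_from, int seed_to,
                        double threshold, int max_sites) {
  int M = mir.size(), N = tgt_rev.size();
  const double NEG = -1e9;
  std::vector<double> H((size_t)(M + 1) * (N + 1), 0.0),
      E((size_t)(M + 1) * (N + 1), NEG), F((size_t)(M + 1) * (N + 1), NEG);
  std::vector<signed char> mv((size_t)(M + 1) * (N + 1), 0),
      mvE((size_t)(M + 1) * (N + 1), 0), mvF((size_t)(M + 1) * (N + 1), 0);
  auto idx = [N](int i, int j) { return (size_t)i * (N + 1) + j; };
  auto pscore = [&](int i, int j) {  // 1-based i over miRNA, j over rev target
    int x = mir[i - 1], y = tgt_rev[j - 1];
    double s;
    bool isWC = (x == 0 && y == 3) || (x == 3 && y == 0) ||
                (x == 2 && y == 1) || (x == 1 && y == 2);
    bool isGU = (x == 2 && y == 3) || (x == 3 && y == 2);
    s = isWC ? wc : (isGU ? gu : mismatch);
    if (i >= seed_from && i <= seed_to) s *= seed_weight;
    return s;
  };

  for (int i = 1; i <= M; ++i) {
    for (int j = 1; j <= N; ++j) {
      double eH = H[idx(i, j - 1)] - gap_open, eE = E[idx(i, j - 1)] - gap_ext;
      double e = std::max(eH, eE);
      mvE[idx(i, j)] = (eE > eH) ? 1 : 0;
      double fH = H[idx(i - 1, j)] - gap_open, fF = F[idx(i - 1, j)] - gap_ext;
      double f = std::max(fH, fF);
      mvF[idx(i, j)] = (fF > fH) ? 1 : 0;
      double dg = H[idx(i - 1, j - 1)] + pscore(i, j);
      double h = 0.0; signed char mvv = 0;          // 0 = local start
      if (dg > h) { h = dg; mvv = 1; }              // 1 = diagonal
      if (e > h) { h = e; mvv = 2; }                // 2 = gap consuming target
      if (f > h) { h = f; mvv = 3; }                // 3 = gap consuming miRNA
      H[idx(i, j)] = h; E[idx(i, j)] = e; F[idx(i, j)] = f; mv[idx(i, j)] = mvv;
    }
  }

  std::vector<size_t> cand;
  for (int i = 1; i <= M; ++i)
    for (int j = 1; j <= N; ++j)
      if (H[idx(i, j)] >= threshold) cand.push_back(idx(i, j));
  std::stable_sort(cand.begin(), cand.end(), [&](size_t a, size_t b) {
    if (H[a] != H[b]) return H[a] > H[b];
    return a < b;
  });

  std::vector<std::pair<int, int> > spans;  // on reversed target, [j0, j1)
  std::vector<double> oscore;
  std::vector<int> ot0, ot1, om0, om1;
  for (size_t c : cand) {
    if ((int)oscore.size() >= max_sites) break;
    int i = (int)(c / (N + 1)), j = (int)(c % (N + 1));
    // traceback with an explicit H/E/F state machine
    int ci = i, cj = j;
    int state = 0;  // 0 = H, 1 = E, 2 = F
    while (ci > 0 && cj > 0) {
      if (state == 0) {
        signed char v = mv[idx(ci, cj)];
        if (v == 0) break;
        if (v == 1) { --ci; --cj; }
        else if (v == 2) state = 1;
        else state = 2;
      } else if (state == 1) {
        signed char v = mvE[idx(ci, cj)];
        --cj;
        if (v == 0) state = 0;
      } else {
        signed char v = mvF[idx(ci, cj)];
        --ci;
        if (v == 0) state = 0;
      }
    }
    int j0 = cj, j1 = j;            // reversed-target span (j0, j1]
    int rt0 = N - j1, rt1 = N - j0; // original coordinates, 0-based half-open
    bool clash = false;
    for (auto& s : spans)
      if (rt0 < s.second && s.first < rt1) { clash = true; break; }
    if (clash) continue;
    spans.push_back(std::make_pair(rt0, rt1));
    oscore.push_back(H[idx(i, j)]);
    ot0.push_back(rt0); ot1.push_back(rt1);
    om0.push_back(ci); om1.push_back(i);
  }
  return DataFrame::create(_["score"] = NumericVector(oscore.begin(), oscore.end()),
                           _["t_start"] = IntegerVector(ot0.begin(), ot0.end()),
                           _["t_end"] = IntegerVector(ot1.begin(), ot1.end()),
                           _["m_start"] = IntegerVector(om0.begin(), om0.end()),
                           _["m_end"] = IntegerVector(om1.begin(), om1.end()));
}
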