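// Alignment engines: exhaustive Smith-Waterman (oracle-grade), seeded local
// search with ungapped + affine-gapped X-drop extension, affine global DP with
// optional free end gaps, and DUST-style low-complexity scoring.
//
// Conventions: gap of length k costs gap_open + k * gap_extend (BLAST style);
// all coordinates returned to R are 1-based inclusive.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

static const double NEG_INF = -1e18;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default:  return -1;
  }
}

// ---------------------------------------------------------------------------
// Global affine alignment. free_ends = true gives zero-cost terminal gaps in
// both sequences. Traceback tie order: diagonal, then gap in b (consume a),
// then gap in a (consume b). Scores are doubles so fractional gap costs
// (e.g. ClustalW's 6.66) are representable exactly enough.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_extend,
                      bool free_ends) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("empty sequence in global alignment");
  if ((double)m * (double)n > 6e7) stop("global alignment too large");

  // state 0 = M (a[i] vs b[j]), 1 = E (gap in b, consume a), 2 = F (gap in a)
  std::vector<double> M((m + 1) * (n + 1), NEG_INF),
                      E((m + 1) * (n + 1), NEG_INF),
                      F((m + 1) * (n + 1), NEG_INF);
  // traceback: for each state, which state we came from (0/1/2, 3 = origin)
  std::vector<uint8_t> tbM((m + 1) * (n + 1), 3), tbE((m + 1) * (n + 1), 3),
                       tbF((m + 1) * (n + 1), 3);
  auto idx = [n](int i, int j) { return i * (n + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) {
    E[idx(i, 0)] = free_ends ? 0.0 : -(gap_open + i * gap_extend);
    tbE[idx(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n; ++j) {
    F[idx(0, j)] = free_ends ? 0.0 : -(gap_open + j * gap_extend);
    tbF[idx(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M
      double best = M[idx(i - 1, j - 1)]; uint8_t who = 0;
      if (E[idx(i - 1, j - 1)] > best) { best = E[idx(i - 1, j - 1)]; who = 1; }
      if (F[idx(i - 1, j - 1)] > best) { best = F[idx(i - 1, j - 1)]; who = 2; }
      if (best > NEG_INF / 2) { M[idx(i, j)] = best + s; tbM[idx(i, j)] = who; }
      // E: gap in b (vertical)
      double open_from = M[idx(i - 1, j)] - (gap_open + gap_extend); uint8_t whoE = 0;
      double ext_from  = E[idx(i - 1, j)] - gap_extend;
      double ffrom     = F[idx(i - 1, j)] - (gap_open + gap_extend);
      if (ffrom > open_from) { open_from = ffrom; whoE = 2; }
      if (ext_from >= open_from) { E[idx(i, j)] = ext_from; tbE[idx(i, j)] = 1; }
      else { E[idx(i, j)] = open_from; tbE[idx(i, j)] = whoE; }
      // free terminal gap down the last column
      if (free_ends && j == n) {
        double freev = M[idx(i - 1, j)]; uint8_t fw = 0;
        if (E[idx(i - 1, j)] > freev) { freev = E[idx(i - 1, j)]; fw = 1; }
        if (F[idx(i - 1, j)] > freev) { freev = F[idx(i - 1, j)]; fw = 2; }
        if (freev > E[idx(i, j)]) { E[idx(i, j)] = freev; tbE[idx(i, j)] = fw; }
      }
      // F: gap in a (horizontal)
      double openF = M[idx(i, j - 1)] - (gap_open + gap_extend); uint8_t whoF = 0;
      double extF  = F[idx(i, j - 1)] - gap_extend;
      double efrom = E[idx(i, j - 1)] - (gap_open + gap_extend);
      if (efrom > openF) { openF = efrom; whoF = 1; }
      if (extF >= openF) { F[idx(i, j)] = extF; tbF[idx(i, j)] = 2; }
      else { F[idx(i, j)] = openF; tbF[idx(i, j)] = whoF; }
      if (free_ends && i == m) {
        double freeh = M[idx(i, j - 1)]; uint8_t fw = 0;
        if (E[idx(i, j - 1)] > freeh) { freeh = E[idx(i, j - 1)]; fw = 1; }
        if (F[idx(i, j - 1)] > freeh) { freeh = F[idx(i, j - 1)]; fw = 2; }
        if (freeh > F[idx(i, j)]) { F[idx(i, j)] = freeh; tbF[idx(i, j)] = fw; }
      }
    }
  }

  // terminal cell: tie order M, E, F
  double sc = M[idx(m, n)]; int state = 0;
  if (E[idx(m, n)] > sc) { sc = E[idx(m, n)]; state = 1; }
  if (F[idx(m, n)] > sc) { sc = F[idx(m, n)]; state = 2; }

  std::string aa, bb;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    uint8_t prev;
    if (state == 0) {
      prev = tbM[idx(i, j)];
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j;
    } else if (state == 1) {
      prev = tbE[idx(i, j)];
      aa.push_back(a[i - 1]); bb.push_back('-'); --i;
    } else {
      prev = tbF[idx(i, j)];
      aa.push_back('-'); bb.push_back(b[j - 1]); --j;
    }
    if (prev == 3) break;
    state = prev;
  }
  while (i > 0) { aa.push_back(a[i - 1]); bb.push_back('-'); --i; }
  while (j > 0) { aa.push_back('-'); bb.push_back(b[j - 1]); --j; }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  return List::create(_["score"] = sc, _["a_aln"] = aa, _["b_aln"] = bb);
}

// ---------------------------------------------------------------------------
// Exhaustive local (Smith-Waterman) alignment with affine gaps. Used as the
// independent optimum for the seeded heuristic, and wherever an exact local
// optimum on short sequences is wanted.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_smith_waterman(std::string a, std::string b,
                        double match, double mismatch,
                        double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = -1,
                        _["b_start"] = 0, _["b_end"] = -1,
                        _["a_aln"] = "", _["b_aln"] = "");
  if ((double)m * (double)n > 6e7) stop("Smith-Waterman too large");
  std::vector<double> M((m + 1) * (n + 1), 0.0),
                      E((m + 1) * (n + 1), NEG_INF),
                      F((m + 1) * (n + 1), NEG_INF);
  std::vector<uint8_t> tbM((m + 1) * (n + 1), 3), tbE((m + 1) * (n + 1), 3),
                       tbF((m + 1) * (n + 1), 3);
  auto idx = [n](int i, int j) { return i * (n + 1) + j; };
  double best = 0.0; int bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double dM = M[idx(i - 1, j - 1)]; uint8_t who = 0;
      if (E[idx(i - 1, j - 1)] > dM) { dM = E[idx(i - 1, j - 1)]; who = 1; }
      if (F[idx(i - 1, j - 1)] > dM) { dM = F[idx(i - 1, j - 1)]; who = 2; }
      double cand = dM + s;
      if (cand < 0) { cand = 0; who = 3; }           // restart
      M[idx(i, j)] = cand; tbM[idx(i, j)] = who;
      double openE = M[idx(i - 1, j)] - (gap_open + gap_extend); uint8_t whoE = 0;
      double fprev = F[idx(i - 1, j)] - (gap_open + gap_extend);
      if (fprev > openE) { openE = fprev; whoE = 2; }
      double extE = E[idx(i - 1, j)] - gap_extend;
      if (extE >= openE) { E[idx(i, j)] = extE; tbE[idx(i, j)] = 1; }
      else { E[idx(i, j)] = openE; tbE[idx(i, j)] = whoE; }
      double openF = M[idx(i, j - 1)] - (gap_open + gap_extend); uint8_t whoF = 0;
      double eprev = E[idx(i, j - 1)] - (gap_open + gap_extend);
      if (eprev > openF) { openF = eprev; whoF = 1; }
      double extF = F[idx(i, j - 1)] - gap_extend;
      if (extF >= openF) { F[idx(i, j)] = extF; tbF[idx(i, j)] = 2; }
      else { F[idx(i, j)] = openF; tbF[idx(i, j)] = whoF; }
      if (M[idx(i, j)] > best) { best = M[idx(i, j)]; bi = i; bj = j; }
    }
  }

  if (best <= 0)
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = -1,
                        _["b_start"] = 0, _["b_end"] = -1,
                        _["a_aln"] = "", _["b_aln"] = "");

  std::string aa, bb;
  int i = bi, j = bj, state = 0;
  while (true) {
    uint8_t prev;
    if (state == 0) {
      prev = tbM[idx(i, j)];
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j;
    } else if (state == 1) {
      prev = tbE[idx(i, j)];
      aa.push_back(a[i - 1]); bb.push_back('-'); --i;
    } else {
      prev = tbF[idx(i, j)];
      aa.push_back('-'); bb.push_back(b[j - 1]); --j;
    }
    if (prev == 3) break;
    state = prev;
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["score"] = best,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj,
                      _["a_aln"] = aa, _["b_aln"] = bb);
}

// ---------------------------------------------------------------------------
// Gapped X-drop extension from an anchor, one direction. Returns the number
// of query/subject residues consumed by the best extension (ending on an
// aligned pair) and its score. dir = +1 extends right of (qi, sj) exclusive,
// dir = -1 extends left. qi/sj are 0-based anchor boundary positions: the
// first residue considered is q[qi], s[sj] (dir=+1) or q[qi], s[sj] (dir=-1).
// ---------------------------------------------------------------------------
static void xdrop_extend(const std::string &q, const std::string &s,
                         int qi, int sj, int dir,
                         double match, double mismatch,
                         double gap_open, double gap_extend, double X,
                         int &best_dq, int &best_ds, double &best_score) {
  best_dq = 0; best_ds = 0; best_score = 0.0;
  const int m = q.size(), n = s.size();
  int amax = (dir > 0) ? (m - qi) : (qi + 1);
  int bmax = (dir > 0) ? (n - sj) : (sj + 1);
  if (amax <= 0 || bmax <= 0) return;

  // rows indexed by a (query residues consumed), columns by b
  int lo = 0, hi = 0;                       // inclusive b-window for row a-1
  std::vector<double> Mp(1, 0.0), Ep(1, NEG_INF), Fp(1, NEG_INF);
  double best = 0.0;

  // row 0: pure gaps in q
  {
    int b = 1; double sc = -(gap_open + gap_extend);
    std::vector<double> M0, E0, F0; M0.push_back(0.0); E0.push_back(NEG_INF); F0.push_back(NEG_INF);
    while (b <= bmax && sc >= best - X) {
      M0.push_back(NEG_INF); E0.push_back(NEG_INF); F0.push_back(sc);
      sc -= gap_extend; ++b;
    }
    Mp = M0; Ep = E0; Fp = F0; lo = 0; hi = (int)Mp.size() - 1;
  }

  for (int a = 1; a <= amax; ++a) {
    int nlo = lo, nhi = std::min(hi + 1, bmax);
    if (nlo > nhi) break;
    std::vector<double> M(nhi - nlo + 1, NEG_INF), E(nhi - nlo + 1, NEG_INF),
                        F(nhi - nlo + 1, NEG_INF);
    char qc = (dir > 0) ? q[qi + a - 1] : q[qi - a + 1];
    bool any = false;
    for (int b = nlo; b <= nhi; ++b) {
      double m_d = NEG_INF, e_d = NEG_INF, f_d = NEG_INF;
      // previous-row values at b-1 (diag) and b (vertical)
      auto getp = [&](const std::vector<double> &V, int bb) -> double {
        if (bb < lo || bb > hi) return NEG_INF;
        return V[bb - lo];
      };
      if (b >= 1) {
        char sc_ = (dir > 0) ? s[sj + b - 1] : s[sj - b + 1];
        double sub = (qc == sc_) ? match : mismatch;
        double prev = std::max(getp(Mp, b - 1), std::max(getp(Ep, b - 1), getp(Fp, b - 1)));
        if (prev > NEG_INF / 2) m_d = prev + sub;
      }
      { // E: gap in subject (consume query)
        double op = std::max(getp(Mp, b), getp(Fp, b)) - (gap_open + gap_extend);
        double ex = getp(Ep, b) - gap_extend;
        e_d = std::max(op, ex);
      }
      if (b - nlo >= 1) { // F: gap in query (consume subject), same row
        double op = std::max(M[b - nlo - 1], E[b - nlo - 1]) - (gap_open + gap_extend);
        double ex = F[b - nlo - 1] - gap_extend;
        f_d = std::max(op, ex);
      } else if (b == 0) {
        // handled by E only
      }
      double h = std::max(m_d, std::max(e_d, f_d));
      if (h < best - X) { m_d = e_d = f_d = NEG_INF; }
      M[b - nlo] = m_d; E[b - nlo] = e_d; F[b - nlo] = f_d;
      if (m_d > NEG_INF / 2 || e_d > NEG_INF / 2 || f_d > NEG_INF / 2) any = true;
      if (m_d > best) { best = m_d; best_dq = a; best_ds = b; }
    }
    if (!any) break;
    // shrink window to live cells
    int L = nlo, H = nhi;
    while (L <= H) {
      int k = L - nlo;
      if (M[k] > NEG_INF / 2 || E[k] > NEG_INF / 2 || F[k] > NEG_INF / 2) break;
      ++L;
    }
    while (H >= L) {
      int k = H - nlo;
      if (M[k] > NEG_INF / 2 || E[k] > NEG_INF / 2 || F[k] > NEG_INF / 2) break;
      --H;
    }
    if (L > H) break;
    std::vector<double> M2(M.begin() + (L - nlo), M.begin() + (H - nlo + 1));
    std::vector<double> E2(E.begin() + (L - nlo), E.begin() + (H - nlo + 1));
    std::vector<double> F2(F.begin() + (L - nlo), F.begin() + (H - nlo + 1));
    Mp.swap(M2); Ep.swap(E2); Fp.swap(F2);
    lo = L; hi = H;
  }
  best_score = best;
}

// ---------------------------------------------------------------------------
// Seeded local search, one strand. Exact word seeds from a query hash table,
// ungapped X-drop extension along the diagonal, then gapped X-drop extension
// for segments reaching `trigger`. Returns hit extents and scores; the caller
// computes E-values, culls and builds alignment strings.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
DataFrame cpp_seeded_search(std::string q, std::string s,
                            double match, double mismatch,
                            double gap_open, double gap_extend,
                            int word, double xdrop, double gxdrop,
                            double trigger, LogicalVector qmask) {
  const int m = q.size(), n = s.size();
  std::vector<int> q1v, q2v, s1v, s2v; std::vector<double> scv;
  if (m < word || n < word)
    return DataFrame::create(_["q1"] = q1v, _["q2"] = q2v, _["s1"] = s1v,
                             _["s2"] = s2v, _["score"] = scv);

  bool use_mask = qmask.size() == m;

  // hash query words (2-bit packed); skip masked or ambiguous words
  std::unordered_map<uint64_t, std::vector<int> > words;
  {
    uint64_t key = 0; int run = 0;
    const uint64_t maskbits = (word >= 32) ? ~0ULL : ((1ULL << (2 * word)) - 1);
    for (int i = 0; i < m; ++i) {
      int c = base_code(q[i]);
      bool bad = (c < 0) || (use_mask && qmask[i]);
      if (bad) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & maskbits;
      if (++run >= word) words[key].push_back(i - word + 1);
    }
  }
  if (words.empty())
    return DataFrame::create(_["q1"] = q1v, _["q2"] = q2v, _["s1"] = s1v,
                             _["s2"] = s2v, _["score"] = scv);

  std::unordered_map<long long, int> covered; // diag -> subject idx already extended past

  uint64_t key = 0; int run = 0;
  const uint64_t maskbits = (word >= 32) ? ~0ULL : ((1ULL << (2 * word)) - 1);
  for (int j = 0; j < n; ++j) {
    int c = base_code(s[j]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & maskbits;
    if (++run < word) continue;
    auto it = words.find(key);
    if (it == words.end()) continue;
    const int sj0 = j - word + 1;
    for (int qi0 : it->second) {
      long long diag = (long long)sj0 - (long long)qi0;
      auto cv = covered.find(diag);
      if (cv != covered.end() && cv->second >= sj0) continue;

      // ungapped extension around the seed
      int qa = qi0, qb = qi0 + word - 1, sa = sj0, sb = sj0 + word - 1;
      double seg = word * match;
      { // right
        double cur = seg, bestu = seg; int bq = qb, bs = sb;
        int qq = qb + 1, ss = sb + 1;
        while (qq < m && ss < n) {
          cur += (q[qq] == s[ss]) ? match : mismatch;
          if (cur > bestu) { bestu = cur; bq = qq; bs = ss; }
          if (cur < bestu - xdrop) break;
          ++qq; ++ss;
        }
        qb = bq; sb = bs; seg = bestu;
      }
      { // left
        double cur = seg, bestu = seg; int bq = qa, bs = sa;
        int qq = qa - 1, ss = sa - 1;
        while (qq >= 0 && ss >= 0) {
          cur += (q[qq] == s[ss]) ? match : mismatch;
          if (cur > bestu) { bestu = cur; bq = qq; bs = ss; }
          if (cur < bestu - xdrop) break;
          --qq; --ss;
        }
        qa = bq; sa = bs; seg = bestu;
      }
      covered[diag] = sb;
      if (seg < trigger) continue;

      int ldq, lds, rdq, rds; double lsc, rsc;
      xdrop_extend(q, s, qa - 1, sa - 1, -1, match, mismatch,
                   gap_open, gap_extend, gxdrop, ldq, lds, lsc);
      xdrop_extend(q, s, qb + 1, sb + 1, +1, match, mismatch,
                   gap_open, gap_extend, gxdrop, rdq, rds, rsc);
      int hq1 = qa - ldq, hs1 = sa - lds, hq2 = qb + rdq, hs2 = sb + rds;
      double total = seg + lsc + rsc;
      q1v.push_back(hq1 + 1); q2v.push_back(hq2 + 1);
      s1v.push_back(hs1 + 1); s2v.push_back(hs2 + 1);
      scv.push_back(total);
    }
  }
  return DataFrame::create(_["q1"] = q1v, _["q2"] = q2v, _["s1"] = s1v,
                           _["s2"] = s2v, _["score"] = scv);
}

// ---------------------------------------------------------------------------
// DUST-style low-complexity mask: triplet score sum c*(c-1)/2 over a sliding
// window, normalised by (#triplets - 1); positions inside any window whose
// score exceeds the threshold are masked.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_dust_mask(std::string s, int window, double threshold) {
  const int n = s.size();
  LogicalVector mask(n, false);
  if (n < 8) return mask;
  int w = std::min(window, n);

  std::vector<int> tri(n, -1); // triplet id starting at position i
  for (int i = 0; i + 2 < n; ++i) {
    int a = base_code(s[i]), b = base_code(s[i + 1]), c = base_code(s[i + 2]);
    if (a >= 0 && b >= 0 && c >= 0) tri[i] = (a << 4) | (b << 2) | c;
  }

  std::vector<int> counts(64, 0);
  long long ssum = 0; int valid = 0;
  auto add = [&](int t) { if (t >= 0) { ssum += counts[t]; counts[t]++; valid++; } };
  auto del = [&](int t) { if (t >= 0) { counts[t]--; ssum -= counts[t]; valid--; } };

  // initialise window [0, w-3] of triplet starts
  for (int i = 0; i + 2 < w; ++i) add(tri[i]);
  for (int start = 0; start + w <= n; ++start) {
    if (valid > 1) {
      double score = (double)ssum / (double)(valid - 1);
      if (score > threshold)
        for (int k = start; k < start + w; ++k) mask[k] = true;
    }
    // slide: remove triplet at `start`, add triplet at start + w - 2
    if (start + w <= n - 1) {
      del(tri[start]);
      if (start + w - 2 + 2 < n) add(tri[start + w - 2]);
    }
  }
  return mask;
}
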