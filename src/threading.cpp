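// Monte Carlo engine for block-list protein alignments: the seven movers,
// incremental (changed-column) energy evaluation, simulated-annealing and
// replica-exchange drivers, and the structure-based scores (Kabsch
// superposition, TM-score, RMSD, DALI elastic similarity).
//
// Conventions: residue indices are 1-based; a block is (queryStart,
// templateStart, length) with closed intervals. All randomness comes from
// R's RNG (unif_rand), so set.seed() at the R level makes every run
// reproducible.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cmath>
#include <cstdio>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Block { int qs, ts, len; };

static std::vector<Block> blocksFromMatrix(const IntegerMatrix& m) {
  std::vector<Block> a(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) a[i] = Block{m(i, 0), m(i, 1), m(i, 2)};
  return a;
}

static IntegerMatrix blocksToMatrix(const std::vector<Block>& a) {
  IntegerMatrix m(a.size(), 3);
  for (size_t i = 0; i < a.size(); ++i) {
    m(i, 0) = a[i].qs; m(i, 1) = a[i].ts; m(i, 2) = a[i].len;
  }
  colnames(m) = CharacterVector::create("queryStart", "templateStart", "length");
  return m;
}

// structural + constraint validity (ordering, bounds, min length, min count)
static bool checkBlocks(const std::vector<Block>& a, int qlen, int tlen,
                        int minLen, int minBlocks) {
  if ((int)a.size() < minBlocks) return false;
  int pq = 0, pt = 0;
  for (const Block& b : a) {
    if (b.len < minLen || b.len < 1) return false;
    if (b.qs <= pq || b.ts <= pt) return false;
    if (b.qs + b.len - 1 > qlen || b.ts + b.len - 1 > tlen) return false;
    pq = b.qs + b.len - 1;
    pt = b.ts + b.len - 1;
  }
  return true;
}

static std::vector<Block> canonBlocks(const std::vector<Block>& a) {
  std::vector<Block> out;
  for (const Block& b : a) {
    if (!out.empty() && out.back().qs + out.back().len == b.qs &&
        out.back().ts + out.back().len == b.ts) {
      out.back().len += b.len;
    } else {
      out.push_back(b);
    }
  }
  return out;
}

static std::string canonKey(const std::vector<Block>& a) {
  std::vector<Block> c = canonBlocks(a);
  std::string key;
  char buf[40];
  for (const Block& b : c) {
    std::snprintf(buf, sizeof(buf), "%d,%d,%d;", b.qs, b.ts, b.len);
    key += buf;
  }
  return key;
}

// ---------------------------------------------------------------- RNG utils

static inline int runifInt(int a, int b) { // inclusive, a <= b
  int r = a + (int)std::floor(unif_rand() * (double)(b - a + 1));
  if (r > b) r = b;
  return r;
}

// P(N) proportional to 2^-N, truncated to 1..maxN
static int rShrinkLen(int maxN) {
  if (maxN <= 1) return 1;
  double Z = 1.0 - std::pow(0.5, (double)maxN);
  double u = unif_rand() * Z, acc = 0.0;
  for (int N = 1; N <= maxN; ++N) {
    acc += std::pow(0.5, (double)N);
    if (u <= acc) return N;
  }
  return maxN;
}

// [[Rcpp::export]]
IntegerVector cpp_shrink_lengths(int n, int maxN) {
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rShrinkLen(maxN);
  return out;
}

// ---------------------------------------------------------------- movers
// Each mover mutates a copy of the block list; returns false when the move
// is geometrically infeasible. Ids: 1 shift, 2 shrink/expand, 3 part-jump,
// 4 split, 5 merge, 6 annihilate, 7 create.

static bool mvShift(std::vector<Block>& a, int qlen, int tlen) {
  int n = a.size();
  if (n == 0) return false;
  int b = runifInt(0, n - 1);
  int loQ = b > 0 ? a[b - 1].qs + a[b - 1].len : 1;
  int hiQ = b < n - 1 ? a[b + 1].qs - a[b].len : qlen - a[b].len + 1;
  int loT = b > 0 ? a[b - 1].ts + a[b - 1].len : 1;
  int hiT = b < n - 1 ? a[b + 1].ts - a[b].len : tlen - a[b].len + 1;
  long nq = (long)hiQ - loQ + 1, nt = (long)hiT - loT + 1;
  if (nq < 1 || nt < 1) return false;
  long total = nq * nt - 1; // exclude the current placement
  if (total < 1) return false;
  long cur = (long)(a[b].qs - loQ) * nt + (a[b].ts - loT);
  long r = (long)std::floor(unif_rand() * (double)total);
  if (r >= total) r = total - 1;
  if (r >= cur) ++r;
  a[b].qs = loQ + (int)(r / nt);
  a[b].ts = loT + (int)(r % nt);
  return true;
}

static bool mvShrinkExpand(std::vector<Block>& a, int qlen, int tlen, int minLen) {
  int n = a.size();
  if (n == 0) return false;
  int b = runifInt(0, n - 1);
  // combos: 0 shrink-left 1 shrink-right 2 expand-left 3 expand-right
  int maxN[4];
  maxN[0] = maxN[1] = a[b].len - minLen;
  int loQ = b > 0 ? a[b - 1].qs + a[b - 1].len : 1;
  int loT = b > 0 ? a[b - 1].ts + a[b - 1].len : 1;
  int hiQ = b < n - 1 ? a[b + 1].qs - 1 : qlen;
  int hiT = b < n - 1 ? a[b + 1].ts - 1 : tlen;
  maxN[2] = std::min(a[b].qs - loQ, a[b].ts - loT);
  maxN[3] = std::min(hiQ - (a[b].qs + a[b].len - 1), hiT - (a[b].ts + a[b].len - 1));
  int ok[4], nok = 0;
  for (int c = 0; c < 4; ++c) if (maxN[c] >= 1) ok[nok++] = c;
  if (nok == 0) return false;
  int c = ok[runifInt(0, nok - 1)];
  int N = rShrinkLen(maxN[c]);
  switch (c) {
    case 0: a[b].qs += N; a[b].ts += N; a[b].len -= N; break;
    case 1: a[b].len -= N; break;
    case 2: a[b].qs -= N; a[b].ts -= N; a[b].len += N; break;
    case 3: a[b].len += N; break;
  }
  return true;
}

static bool mvPartJump(std::vector<Block>& a, int minLen) {
  int n = a.size();
  if (n < 2) return false;
  // candidates: (donor, direction); donor must keep >= minLen residues
  std::vector<std::pair<int, int>> cand; // (block, 0=left/1=right)
  for (int b = 0; b < n; ++b) {
    if (a[b].len <= minLen) continue;
    if (b > 0) cand.push_back({b, 0});
    if (b < n - 1) cand.push_back({b, 1});
  }
  if (cand.empty()) return false;
  std::pair<int, int> ch = cand[runifInt(0, (int)cand.size() - 1)];
  int b = ch.first;
  int nj = runifInt(1, a[b].len - minLen);
  if (ch.second == 0) { // tail of previous block grows along its diagonal
    a[b - 1].len += nj;
    a[b].qs += nj; a[b].ts += nj; a[b].len -= nj;
  } else {              // next block extends left along its own diagonal
    a[b + 1].qs -= nj; a[b + 1].ts -= nj; a[b + 1].len += nj;
    a[b].len -= nj;
  }
  return true;
}

static bool mvSplit(std::vector<Block>& a, int minLen) {
  int n = a.size();
  std::vector<int> cand;
  for (int b = 0; b < n; ++b) if (a[b].len >= 2 * minLen) cand.push_back(b);
  if (cand.empty()) return false;
  int b = cand[runifInt(0, (int)cand.size() - 1)];
  int leftLen = runifInt(minLen, a[b].len - minLen);
  Block right{a[b].qs + leftLen, a[b].ts + leftLen, a[b].len - leftLen};
  a[b].len = leftLen;
  a.insert(a.begin() + b + 1, right);
  return true;
}

static bool mvMerge(std::vector<Block>& a, int minBlocks) {
  int n = a.size();
  if (n - 1 < minBlocks || n < 2) return false;
  std::vector<int> cand;
  for (int b = 0; b + 1 < n; ++b)
    if (a[b].qs + a[b].len == a[b + 1].qs && a[b].ts + a[b].len == a[b + 1].ts)
      cand.push_back(b);
  if (cand.empty()) return false;
  int b = cand[runifInt(0, (int)cand.size() - 1)];
  a[b].len += a[b + 1].len;
  a.erase(a.begin() + b + 1);
  return true;
}

static bool mvAnnihilate(std::vector<Block>& a, int minBlocks) {
  int n = a.size();
  if (n == 0 || n - 1 < minBlocks) return false;
  a.erase(a.begin() + runifInt(0, n - 1));
  return true;
}

static bool mvCreate(std::vector<Block>& a, int qlen, int tlen, int minLen) {
  int n = a.size();
  // slot s: gap before block s (s = 0..n); counts of feasible placements
  std::vector<long> cnt(n + 1, 0);
  long total = 0;
  for (int s = 0; s <= n; ++s) {
    int qlo = (s > 0 ? a[s - 1].qs + a[s - 1].len : 1);
    int qhi = (s < n ? a[s].qs : qlen + 1) - minLen;
    int tlo = (s > 0 ? a[s - 1].ts + a[s - 1].len : 1);
    int thi = (s < n ? a[s].ts : tlen + 1) - minLen;
    long cq = (long)qhi - qlo + 1, ct = (long)thi - tlo + 1;
    if (cq > 0 && ct > 0) cnt[s] = cq * ct;
    total += cnt[s];
  }
  if (total == 0) return false;
  long r = (long)std::floor(unif_rand() * (double)total);
  if (r >= total) r = total - 1;
  int s = 0;
  while (r >= cnt[s]) { r -= cnt[s]; ++s; }
  int qlo = (s > 0 ? a[s - 1].qs + a[s - 1].len : 1);
  int tlo = (s > 0 ? a[s - 1].ts + a[s - 1].len : 1);
  int thi = (s < (int)a.size() ? a[s].ts : tlen + 1) - minLen;
  long ct = (long)thi - tlo + 1;
  Block nb{qlo + (int)(r / ct), tlo + (int)(r % ct), minLen};
  a.insert(a.begin() + s, nb);
  return true;
}

static bool applyMover(int id, std::vector<Block>& a, int qlen, int tlen,
                       int minLen, int minBlocks) {
  switch (id) {
    case 1: return mvShift(a, qlen, tlen);
    case 2: return mvShrinkExpand(a, qlen, tlen, minLen);
    case 3: return mvPartJump(a, minLen);
    case 4: return mvSplit(a, minLen);
    case 5: return mvMerge(a, minBlocks);
    case 6: return mvAnnihilate(a, minBlocks);
    case 7: return mvCreate(a, qlen, tlen, minLen);
  }
  stop("unknown mover id");
  return false;
}

// [[Rcpp::export]]
List cpp_propose(IntegerMatrix blocks, int qlen, int tlen, int minLen,
                 int minBlocks, int moverId) {
  std::vector<Block> a = blocksFromMatrix(blocks);
  bool ok = applyMover(moverId, a, qlen, tlen, minLen, minBlocks);
  return List::create(_["feasible"] = ok, _["blocks"] = blocksToMatrix(a));
}

// ------------------------------------------------------ structure scoring

// Kabsch superposition of the aligned pairs indexed by `subset`; fills the
// distance of EVERY pair under that superposition.
static void superposeDists(const arma::mat& Q, const arma::mat& T,
                           const std::vector<std::pair<int, int>>& pairs,
                           const std::vector<int>& subset,
                           std::vector<double>& d) {
  int m = pairs.size(), k = subset.size();
  arma::rowvec qc(3, arma::fill::zeros), tc(3, arma::fill::zeros);
  for (int idx : subset) {
    qc += Q.row(pairs[idx].first - 1);
    tc += T.row(pairs[idx].second - 1);
  }
  qc /= (double)k; tc /= (double)k;
  arma::mat H(3, 3, arma::fill::zeros);
  for (int idx : subset) {
    H += (Q.row(pairs[idx].first - 1) - qc).t() *
         (T.row(pairs[idx].second - 1) - tc);
  }
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double dsign = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = dsign;
  arma::mat R = U * D * V.t(); // q_centred * R approximates t_centred
  d.resize(m);
  for (int i = 0; i < m; ++i) {
    arma::rowvec qr = (Q.row(pairs[i].first - 1) - qc) * R;
    arma::rowvec tr = T.row(pairs[i].second - 1) - tc;
    d[i] = arma::norm(qr - tr, 2);
  }
}

static double tmD0(int Lnorm) {
  if (Lnorm <= 15) return 0.5;
  double d0 = 1.24 * std::cbrt((double)Lnorm - 15.0) - 1.8;
  return d0 < 0.5 ? 0.5 : d0;
}

static double tmFromSeed(const arma::mat& Q, const arma::mat& T,
                         const std::vector<std::pair<int, int>>& pairs,
                         int Lnorm, double d0, std::vector<int> S,
                         int maxIter) {
  int m = pairs.size();
  std::vector<double> d;
  double best = 0.0;
  double dcut = std::max(d0, 3.5);
  for (int it = 0; it < maxIter; ++it) {
    superposeDists(Q, T, pairs, S, d);
    double sc = 0.0;
    for (int i = 0; i < m; ++i) sc += 1.0 / (1.0 + (d[i] / d0) * (d[i] / d0));
    sc /= (double)Lnorm;
    if (sc > best) best = sc;
    std::vector<int> Snew;
    double dc = dcut;
    for (int bump = 0; bump < 40; ++bump) {
      Snew.clear();
      for (int i = 0; i < m; ++i) if (d[i] <= dc) Snew.push_back(i);
      if ((int)Snew.size() >= 3) break;
      dc += 0.5;
    }
    if ((int)Snew.size() < 3) break;
    if (Snew == S) break;
    S.swap(Snew);
  }
  return best;
}

static double tmScorePairs(const arma::mat& Q, const arma::mat& T,
                           const std::vector<std::pair<int, int>>& pairs,
                           int Lnorm, bool thorough) {
  int m = pairs.size();
  if (m < 3 || Lnorm < 1) return 0.0;
  double d0 = tmD0(Lnorm);
  // the fast (sampling) path uses a single all-pairs seed and a short
  // iteration cap; the thorough path adds fragment-window seeds
  int maxIter = thorough ? 20 : 8;
  std::vector<int> all(m);
  for (int i = 0; i < m; ++i) all[i] = i;
  double best = tmFromSeed(Q, T, pairs, Lnorm, d0, all, maxIter);
  if (thorough) {
    int lens[5] = {m / 2, m / 4, m / 8, 4, 3};
    for (int li = 0; li < 5; ++li) {
      int L = std::max(3, lens[li]);
      if (L >= m) continue;
      int step = std::max(1, (m - L) / 20);
      for (int start = 0; start + L <= m; start += step) {
        std::vector<int> S(L);
        for (int i = 0; i < L; ++i) S[i] = start + i;
        double sc = tmFromSeed(Q, T, pairs, Lnorm, d0, S, maxIter);
        if (sc > best) best = sc;
      }
    }
  }
  return best;
}

static double rmsdPairs(const arma::mat& Q, const arma::mat& T,
                        const std::vector<std::pair<int, int>>& pairs) {
  int m = pairs.size();
  if (m == 0) return 0.0;
  std::vector<int> all(m);
  for (int i = 0; i < m; ++i) all[i] = i;
  std::vector<double> d;
  superposeDists(Q, T, pairs, all, d);
  double ss = 0.0;
  for (double di : d) ss += di * di;
  return std::sqrt(ss / (double)m);
}

// Holm-Sander elastic similarity: 0.2 per aligned pair on the diagonal plus
// single-counted sum over unordered pair-of-pairs.
static double daliPairs(const arma::mat& Q, const arma::mat& T,
                        const std::vector<std::pair<int, int>>& pairs) {
  int m = pairs.size();
  double sim = 0.2 * (double)m;
  for (int a = 0; a < m; ++a) {
    for (int b = a + 1; b < m; ++b) {
      double dQ = arma::norm(Q.row(pairs[a].first - 1) - Q.row(pairs[b].first - 1), 2);
      double dT = arma::norm(T.row(pairs[a].second - 1) - T.row(pairs[b].second - 1), 2);
      double ds = 0.5 * (dQ + dT);
      if (ds <= 0) continue;
      sim += (0.2 - std::fabs(dQ - dT) / ds) * std::exp(-(ds / 20.0) * (ds / 20.0));
    }
  }
  return sim;
}

static std::vector<std::pair<int, int>> pairsFromBlocks(const std::vector<Block>& a) {
  std::vector<std::pair<int, int>> p;
  for (const Block& b : a)
    for (int k = 0; k < b.len; ++k) p.push_back({b.qs + k, b.ts + k});
  return p;
}

// [[Rcpp::export]]
double cpp_tm_score(NumericMatrix qcoords, NumericMatrix tcoords,
                    IntegerMatrix pairs, int Lnorm, bool thorough) {
  arma::mat Q(qcoords.begin(), qcoords.nrow(), 3, false);
  arma::mat T(tcoords.begin(), tcoords.nrow(), 3, false);
  std::vector<std::pair<int, int>> p(pairs.nrow());
  for (int i = 0; i < pairs.nrow(); ++i) p[i] = {pairs(i, 0), pairs(i, 1)};
  return tmScorePairs(Q, T, p, Lnorm, thorough);
}

// [[Rcpp::export]]
double cpp_rmsd(NumericMatrix qcoords, NumericMatrix tcoords, IntegerMatrix pairs) {
  arma::mat Q(qcoords.begin(), qcoords.nrow(), 3, false);
  arma::mat T(tcoords.begin(), tcoords.nrow(), 3, false);
  std::vector<std::pair<int, int>> p(pairs.nrow());
  for (int i = 0; i < pairs.nrow(); ++i) p[i] = {pairs(i, 0), pairs(i, 1)};
  return rmsdPairs(Q, T, p);
}

// [[Rcpp::export]]
double cpp_dali(NumericMatrix qcoords, NumericMatrix tcoords, IntegerMatrix pairs) {
  arma::mat Q(qcoords.begin(), qcoords.nrow(), 3, false);
  arma::mat T(tcoords.begin(), tcoords.nrow(), 3, false);
  std::vector<std::pair<int, int>> p(pairs.nrow());
  for (int i = 0; i < pairs.nrow(); ++i) p[i] = {pairs(i, 0), pairs(i, 1)};
  return daliPairs(Q, T, p);
}

// ------------------------------------------------------------ energy model

struct ECtx {
  int qlen = 0, tlen = 0;
  bool hasBig = false; NumericMatrix big;
  bool hasGap = false; double gOpen = 0, gExt = 0; bool gTermFree = true;
  std::vector<std::pair<int, int>> contacts;
  bool hasSgp = false; double sgpCoef = 0;
  bool hasGo = false; double goW = 0, goCut2 = 64.0;
  bool hasMj = false; double mjW = 0; NumericMatrix mjTab; std::vector<int> qseq;
  bool hasTm = false; double tmW = 0; int tmLnorm = 0;
  bool hasRmsd = false; double rmsdW = 0;
  bool hasDali = false; double daliW = 0;
  arma::mat qx, tx;
};

static ECtx parseCtx(List ctx) {
  ECtx c;
  c.qlen = as<int>(ctx["qlen"]);
  c.tlen = as<int>(ctx["tlen"]);
  if (!Rf_isNull(ctx["big"])) { c.hasBig = true; c.big = as<NumericMatrix>(ctx["big"]); }
  if (!Rf_isNull(ctx["gap"])) {
    List g = ctx["gap"];
    c.hasGap = true;
    c.gOpen = as<double>(g["open"]);
    c.gExt = as<double>(g["extend"]);
    c.gTermFree = as<bool>(g["terminalFree"]);
  }
  if (!Rf_isNull(ctx["contacts"])) {
    IntegerMatrix cm = as<IntegerMatrix>(ctx["contacts"]);
    for (int i = 0; i < cm.nrow(); ++i) c.contacts.push_back({cm(i, 0), cm(i, 1)});
  }
  if (!Rf_isNull(ctx["sgp"])) { c.hasSgp = true; c.sgpCoef = as<double>(List(ctx["sgp"])["coef"]); }
  if (!Rf_isNull(ctx["golike"])) {
    List g = ctx["golike"];
    c.hasGo = true;
    c.goW = as<double>(g["w"]);
    double cut = as<double>(g["cutoff"]);
    c.goCut2 = cut * cut;
  }
  if (!Rf_isNull(ctx["twobody"])) {
    List g = ctx["twobody"];
    c.hasMj = true;
    c.mjW = as<double>(g["w"]);
    c.mjTab = as<NumericMatrix>(g["table"]);
    IntegerVector qs = g["qseq"]; // 1..20, 0 = unknown
    c.qseq.assign(qs.begin(), qs.end());
  }
  if (!Rf_isNull(ctx["qcoords"])) {
    NumericMatrix q = as<NumericMatrix>(ctx["qcoords"]);
    c.qx = arma::mat(q.begin(), q.nrow(), 3);
  }
  if (!Rf_isNull(ctx["tcoords"])) {
    NumericMatrix t = as<NumericMatrix>(ctx["tcoords"]);
    c.tx = arma::mat(t.begin(), t.nrow(), 3);
  }
  if (!Rf_isNull(ctx["tm"])) {
    List g = ctx["tm"];
    c.hasTm = true;
    c.tmW = as<double>(g["w"]);
    c.tmLnorm = as<int>(g["Lnorm"]);
  }
  if (!Rf_isNull(ctx["rmsd"])) { c.hasRmsd = true; c.rmsdW = as<double>(List(ctx["rmsd"])["w"]); }
  if (!Rf_isNull(ctx["dali"])) { c.hasDali = true; c.daliW = as<double>(List(ctx["dali"])["w"]); }
  return c;
}

static void buildQmap(const std::vector<Block>& a, int qlen, std::vector<int>& qmap) {
  qmap.assign(qlen + 1, 0);
  for (const Block& b : a)
    for (int k = 0; k < b.len; ++k) qmap[b.qs + k] = b.ts + k;
}

static double bigEnergyMap(const ECtx& c, const std::vector<int>& qmap) {
  if (!c.hasBig) return 0.0;
  double e = 0.0;
  for (int i = 1; i <= c.qlen; ++i)
    if (qmap[i] > 0) e += c.big(i - 1, qmap[i] - 1);
  return e;
}

static double gapEnergy(const ECtx& c, const std::vector<Block>& a) {
  if (!c.hasGap || a.empty()) return 0.0;
  double e = 0.0;
  for (size_t i = 1; i < a.size(); ++i) {
    int gq = a[i].qs - (a[i - 1].qs + a[i - 1].len);
    int gt = a[i].ts - (a[i - 1].ts + a[i - 1].len);
    if (gq > 0) e += c.gOpen + (gq - 1) * c.gExt;
    if (gt > 0) e += c.gOpen + (gt - 1) * c.gExt;
  }
  if (!c.gTermFree) {
    int gq = a.front().qs - 1, gt = a.front().ts - 1;
    if (gq > 0) e += c.gOpen + (gq - 1) * c.gExt;
    if (gt > 0) e += c.gOpen + (gt - 1) * c.gExt;
    gq = c.qlen - (a.back().qs + a.back().len - 1);
    gt = c.tlen - (a.back().ts + a.back().len - 1);
    if (gq > 0) e += c.gOpen + (gq - 1) * c.gExt;
    if (gt > 0) e += c.gOpen + (gt - 1) * c.gExt;
  }
  return e;
}

static double contactEnergy(const ECtx& c, const std::vector<Block>& a) {
  if (c.contacts.empty() || !(c.hasSgp || c.hasGo || c.hasMj)) return 0.0;
  std::vector<int> tq(c.tlen + 1, 0); // template -> query partner
  for (const Block& b : a)
    for (int k = 0; k < b.len; ++k) tq[b.ts + k] = b.qs + k;
  double e = 0.0;
  for (const auto& ct : c.contacts) {
    int qi = tq[ct.first], qj = tq[ct.second];
    if (c.hasSgp && (qi == 0 || qj == 0)) e += c.sgpCoef;
    if (qi > 0 && qj > 0) {
      if (c.hasGo) {
        double d2 = arma::accu(arma::square(c.qx.row(qi - 1) - c.qx.row(qj - 1)));
        if (d2 <= c.goCut2) e -= c.goW;
      }
      if (c.hasMj) {
        int a1 = c.qseq[qi - 1], a2 = c.qseq[qj - 1];
        if (a1 > 0 && a2 > 0) e += c.mjW * c.mjTab(a1 - 1, a2 - 1);
      }
    }
  }
  return e;
}

static double structEnergy(const ECtx& c, const std::vector<Block>& a) {
  if (!(c.hasTm || c.hasRmsd || c.hasDali)) return 0.0;
  std::vector<std::pair<int, int>> p = pairsFromBlocks(a);
  double e = 0.0;
  // sampler uses the fast single-seed TM refinement; see tmScorePairs
  if (c.hasTm) e += c.tmW * (-tmScorePairs(c.qx, c.tx, p, c.tmLnorm, false));
  if (c.hasRmsd) e += c.rmsdW * rmsdPairs(c.qx, c.tx, p);
  if (c.hasDali) e += c.daliW * (-daliPairs(c.qx, c.tx, p));
  return e;
}

static double otherEnergy(const ECtx& c, const std::vector<Block>& a) {
  return gapEnergy(c, a) + contactEnergy(c, a) + structEnergy(c, a);
}

// [[Rcpp::export]]
double cpp_energy_total(IntegerMatrix blocks, List ctx) {
  ECtx c = parseCtx(ctx);
  std::vector<Block> a = blocksFromMatrix(blocks);
  std::vector<int> qmap;
  buildQmap(a, c.qlen, qmap);
  return bigEnergyMap(c, qmap) + otherEnergy(c, a);
}

// ------------------------------------------------------------ MC machinery

struct ChainState {
  std::vector<Block> a;
  std::vector<int> qmap;
  double Ebig = 0, Eoth = 0;
  double E() const { return Ebig + Eoth; }
};

static void initChain(ChainState& s, const ECtx& c) {
  buildQmap(s.a, c.qlen, s.qmap);
  s.Ebig = bigEnergyMap(c, s.qmap);
  s.Eoth = otherEnergy(c, s.a);
}

struct MoverStats {
  long att[7] = {0}, acc[7] = {0}, inf[7] = {0};
};

// one Metropolis step; returns whether the proposal was accepted
static bool stepChain(ChainState& s, const ECtx& c, double T,
                      const double* cumw, double totw,
                      int minLen, int minBlocks, MoverStats& st) {
  double u = unif_rand() * totw;
  int mv = 0;
  while (mv < 6 && cumw[mv] < u) ++mv;
  st.att[mv]++;
  std::vector<Block> b = s.a;
  if (!applyMover(mv + 1, b, c.qlen, c.tlen, minLen, minBlocks)) {
    st.inf[mv]++;
    return false;
  }
  std::vector<int> nm;
  buildQmap(b, c.qlen, nm);
  double dbig = 0.0;
  if (c.hasBig) {
    for (int i = 1; i <= c.qlen; ++i) {
      if (nm[i] != s.qmap[i]) {
        if (nm[i] > 0) dbig += c.big(i - 1, nm[i] - 1);
        if (s.qmap[i] > 0) dbig -= c.big(i - 1, s.qmap[i] - 1);
      }
    }
  }
  double noth = otherEnergy(c, b);
  double dE = dbig + (noth - s.Eoth);
  bool accept = dE <= 0 || unif_rand() < std::exp(-dE / T);
  if (accept) {
    s.a.swap(b);
    s.qmap.swap(nm);
    s.Ebig += dbig;
    s.Eoth = noth;
    st.acc[mv]++;
  }
  return accept;
}

struct RecStore {
  struct Rec { std::vector<Block> a; double E; double temp; int cycle; };
  std::unordered_map<std::string, size_t> idx;
  std::vector<Rec> recs;
  size_t maxKeep = 1000;
  double admitE = R_PosInf;

  void add(const std::vector<Block>& a, double E, double temp, int cycle) {
    if (recs.size() >= maxKeep && E > admitE) return;
    std::string key = canonKey(a);
    auto it = idx.find(key);
    if (it != idx.end()) return; // same canonical alignment already kept
    idx[key] = recs.size();
    recs.push_back(Rec{canonBlocks(a), E, temp, cycle});
    if (recs.size() > 2 * maxKeep) prune();
  }
  void prune() {
    std::vector<size_t> ord(recs.size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
    std::partial_sort(ord.begin(), ord.begin() + maxKeep, ord.end(),
                      [&](size_t x, size_t y) { return recs[x].E < recs[y].E; });
    std::vector<Rec> kept;
    kept.reserve(maxKeep);
    for (size_t i = 0; i < maxKeep; ++i) kept.push_back(recs[ord[i]]);
    recs.swap(kept);
    idx.clear();
    for (size_t i = 0; i < recs.size(); ++i) idx[canonKey(recs[i].a)] = i;
    admitE = recs.empty() ? R_PosInf
                          : std::max_element(recs.begin(), recs.end(),
                                             [](const Rec& x, const Rec& y) { return x.E < y.E; })->E;
  }
  List toR() const {
    List out(recs.size());
    for (size_t i = 0; i < recs.size(); ++i) {
      out[i] = List::create(_["blocks"] = blocksToMatrix(recs[i].a),
                            _["energy"] = recs[i].E,
                            _["temperature"] = recs[i].temp,
                            _["cycle"] = recs[i].cycle);
    }
    return out;
  }
};

static List moverStatsToR(const MoverStats& st) {
  IntegerVector att(7), acc(7), inf(7);
  for (int i = 0; i < 7; ++i) { att[i] = st.att[i]; acc[i] = st.acc[i]; inf[i] = st.inf[i]; }
  return List::create(_["attempted"] = att, _["accepted"] = acc, _["infeasible"] = inf);
}

// [[Rcpp::export]]
List cpp_run_remc(List init, List ctxList, NumericVector temps, int innerSteps,
                  int cycles, int minLen, int minBlocks, NumericVector moverW,
                  int sampleEvery, int maxRecords, int stopStable) {
  ECtx c = parseCtx(ctxList);
  int nr = temps.size();
  double cumw[7], totw = 0;
  for (int i = 0; i < 7; ++i) { totw += moverW[i]; cumw[i] = totw; }
  if (totw <= 0) stop("all mover weights are zero");

  std::vector<ChainState> ch(nr);
  RecStore store;
  store.maxKeep = maxRecords;
  MoverStats st;
  double bestE = R_PosInf;
  std::vector<Block> bestBlocks;
  for (int r = 0; r < nr; ++r) {
    ch[r].a = blocksFromMatrix(as<IntegerMatrix>(init[r]));
    initChain(ch[r], c);
    store.add(ch[r].a, ch[r].E(), temps[r], 0);
    if (ch[r].E() < bestE) { bestE = ch[r].E(); bestBlocks = ch[r].a; }
  }
  std::vector<std::vector<double>> samples(nr);
  IntegerVector xAtt(std::max(nr - 1, 0)), xAcc(std::max(nr - 1, 0));
  double prevBest = bestE;
  int stable = 0, cyclesRun = 0;

  for (int cy = 1; cy <= cycles; ++cy) {
    for (int r = 0; r < nr; ++r) {
      for (int k = 1; k <= innerSteps; ++k) {
        bool acc = stepChain(ch[r], c, temps[r], cumw, totw, minLen, minBlocks, st);
        if (acc) {
          double E = ch[r].E();
          store.add(ch[r].a, E, temps[r], cy);
          if (E < bestE) { bestE = E; bestBlocks = ch[r].a; }
        }
        if (sampleEvery > 0 && k % sampleEvery == 0) samples[r].push_back(ch[r].E());
      }
    }
    // alternate even/odd adjacent pairings
    for (int i = (cy - 1) % 2; i + 1 < nr; i += 2) {
      double arg = (1.0 / temps[i] - 1.0 / temps[i + 1]) * (ch[i].E() - ch[i + 1].E());
      xAtt[i]++;
      if (arg >= 0 || unif_rand() < std::exp(arg)) {
        std::swap(ch[i], ch[i + 1]);
        xAcc[i]++;
      }
    }
    cyclesRun = cy;
    if (std::fabs(bestE - prevBest) < 1e-12) {
      ++stable;
    } else {
      stable = 0;
      prevBest = bestE;
    }
    if (stopStable > 0 && stable >= stopStable) break;
    Rcpp::checkUserInterrupt();
  }

  List samp(nr);
  for (int r = 0; r < nr; ++r) samp[r] = wrap(samples[r]);
  return List::create(
      _["records"] = store.toR(),
      _["bestEnergy"] = bestE,
      _["bestBlocks"] = blocksToMatrix(bestBlocks),
      _["samples"] = samp,
      _["moverStats"] = moverStatsToR(st),
      _["exchangeAttempted"] = xAtt,
      _["exchangeAccepted"] = xAcc,
      _["cyclesRun"] = cyclesRun);
}

// [[Rcpp::export]]
List cpp_run_sa(IntegerMatrix init, List ctxList, NumericVector temps,
                int stepsPerStage, int minLen, int minBlocks,
                NumericVector moverW, int sampleEvery, int maxRecords) {
  ECtx c = parseCtx(ctxList);
  double cumw[7], totw = 0;
  for (int i = 0; i < 7; ++i) { totw += moverW[i]; cumw[i] = totw; }
  if (totw <= 0) stop("all mover weights are zero");

  ChainState s;
  s.a = blocksFromMatrix(init);
  initChain(s, c);
  RecStore store;
  store.maxKeep = maxRecords;
  MoverStats st;
  double bestE = s.E();
  std::vector<Block> bestBlocks = s.a;
  store.add(s.a, s.E(), temps[0], 0);
  std::vector<double> samples;

  for (int t = 0; t < temps.size(); ++t) {
    for (int k = 1; k <= stepsPerStage; ++k) {
      bool acc = stepChain(s, c, temps[t], cumw, totw, minLen, minBlocks, st);
      if (acc) {
        store.add(s.a, s.E(), temps[t], t + 1);
        if (s.E() < bestE) { bestE = s.E(); bestBlocks = s.a; }
      }
      if (sampleEvery > 0 && k % sampleEvery == 0) samples.push_back(s.E());
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["records"] = store.toR(),
      _["bestEnergy"] = bestE,
      _["bestBlocks"] = blocksToMatrix(bestBlocks),
      _["samples"] = wrap(samples),
      _["moverStats"] = moverStatsToR(st),
      _["cyclesRun"] = (int)temps.size());
}

// Runs a chain and, at every accepted move, compares the incrementally
// maintained big-matrix energy with a from-scratch recomputation, and the
// proposal with the validity rules. Returns the worst discrepancy seen.
// [[Rcpp::export]]
List cpp_delta_check(IntegerMatrix init, List ctxList, double temperature,
                     int nMoves, int minLen, int minBlocks, NumericVector moverW) {
  ECtx c = parseCtx(ctxList);
  double cumw[7], totw = 0;
  for (int i = 0; i < 7; ++i) { totw += moverW[i]; cumw[i] = totw; }
  ChainState s;
  s.a = blocksFromMatrix(init);
  initChain(s, c);
  MoverStats st;
  double maxDiff = 0.0;
  long nAcc = 0, nInvalid = 0;
  for (int k = 0; k < nMoves; ++k) {
    bool acc = stepChain(s, c, temperature, cumw, totw, minLen, minBlocks, st);
    if (acc) {
      ++nAcc;
      std::vector<int> qm;
      buildQmap(s.a, c.qlen, qm);
      double full = bigEnergyMap(c, qm) + otherEnergy(c, s.a);
      double diff = std::fabs(full - s.E());
      if (diff > maxDiff) maxDiff = diff;
      if (!checkBlocks(s.a, c.qlen, c.tlen, minLen, minBlocks)) ++nInvalid;
    }
    if (k % 8192 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["maxDiscrepancy"] = maxDiff, _["accepted"] = nAcc,
                      _["invalid"] = nInvalid);
}
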