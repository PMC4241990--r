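#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh) with full traceback.
//
// Sequences are plain std::strings; `alphabet` maps characters to rows of
// `smat`.  Characters outside the alphabet (including the '#' masking
// character) hit a sentinel row scoring BAD against everything, so masked
// regions can never be aligned through.
//
// gap cost for a run of length L is gap_open + (L-1)*gap_ext (both <= 0).

static const int BAD = -10000;

static inline std::vector<int> encode(const std::string& s,
                                      const std::string& alphabet) {
  std::vector<int> idx(256, -1);
  for (size_t i = 0; i < alphabet.size(); ++i)
    idx[(unsigned char)alphabet[i]] = (int)i;
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = idx[(unsigned char)s[i]];
  return out;
}

// traceback codes packed per cell:
//   bits 0-1: source of M   (0 diag-M, 1 diag-Ix, 2 diag-Iy, 3 local start)
//   bit 2   : Ix opened from M (else extended)
//   bit 3   : Iy opened from M (else extended)
// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, std::string alphabet,
               IntegerMatrix smat, double gap_open, double gap_ext,
               std::string type) {
  const bool local = (type == "local");
  const int n = (int)a.size(), m = (int)b.size();
  const int K = (int)alphabet.size();
  std::vector<int> ea = encode(a, alphabet), eb = encode(b, alphabet);
  // flat copy of the scoring matrix: avoids per-cell SEXP access
  std::vector<double> S((size_t)K * K);
  for (int x = 0; x < K; ++x)
    for (int y = 0; y < K; ++y) S[(size_t)x * K + y] = smat(x, y);

  const double NEG = -1e18;
  std::vector<double> Mprev(m + 1), Mcur(m + 1);
  std::vector<double> Xprev(m + 1), Xcur(m + 1);  // Ix: gap in a (consumes b)
  std::vector<double> Yprev(m + 1), Ycur(m + 1);  // Iy: gap in b (consumes a)
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);

  Mprev[0] = 0.0;
  Xprev[0] = Yprev[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG;
    Yprev[j] = NEG;
    Xprev[j] = local ? NEG : gap_open + (j - 1) * gap_ext;
  }

  double best = local ? 0.0 : NEG;
  int bi = 0, bj = 0;  // end cell of best alignment (local) / (n,m) global
  char bstate = 'M';

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG;
    Xcur[0] = NEG;
    Ycur[0] = local ? NEG : gap_open + (i - 1) * gap_ext;
    const int ca = ea[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int cb = eb[j - 1];
      const double sub =
          (ca < 0 || cb < 0) ? BAD : S[(size_t)ca * K + cb];
      uint8_t code = 0;

      // M
      double dM = Mprev[j - 1], dX = Xprev[j - 1], dY = Yprev[j - 1];
      double mbest = dM;
      int msrc = 0;
      if (dX > mbest) { mbest = dX; msrc = 1; }
      if (dY > mbest) { mbest = dY; msrc = 2; }
      if (local && mbest <= 0.0) { mbest = 0.0; msrc = 3; }
      double mval = mbest + sub;
      code |= (uint8_t)msrc;
      Mcur[j] = mval;

      // Ix: gap in a, consumes b[j-1]
      double xo = Mcur[j - 1] + gap_open;
      double xe = Xcur[j - 1] + gap_ext;
      if (xo >= xe) { Xcur[j] = xo; code |= 4; }
      else Xcur[j] = xe;

      // Iy: gap in b, consumes a[i-1]
      double yo = Mprev[j] + gap_open;
      double ye = Yprev[j] + gap_ext;
      if (yo >= ye) { Ycur[j] = yo; code |= 8; }
      else Ycur[j] = ye;

      tb[(size_t)i * (m + 1) + j] = code;

      if (local && Mcur[j] > best) {
        best = Mcur[j]; bi = i; bj = j; bstate = 'M';
      }
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }

  if (!local) {
    bi = n; bj = m;
    best = Mprev[m]; bstate = 'M';
    if (Xprev[m] > best) { best = Xprev[m]; bstate = 'X'; }
    if (Yprev[m] > best) { best = Yprev[m]; bstate = 'Y'; }
  }

  // traceback
  std::vector<int> acols, bcols;  // 1-based positions, 0 = gap
  int i = bi, j = bj;
  char st = bstate;
  if (local && best <= 0.0) {
    return List::create(
        _["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0, _["b_start"] = 0,
        _["b_end"] = 0, _["n_match"] = 0, _["n_mismatch"] = 0,
        _["n_gapcols"] = 0, _["a_cols"] = IntegerVector(0),
        _["b_cols"] = IntegerVector(0));
  }
  while (i > 0 || j > 0) {
    uint8_t code = tb[(size_t)i * (m + 1) + j];
    if (st == 'M') {
      if (i == 0 || j == 0) break;  // global boundary handled below
      int msrc = code & 3;
      if (local && msrc == 3) {  // local alignment start
        acols.push_back(i); bcols.push_back(j);
        --i; --j;
        break;
      }
      acols.push_back(i); bcols.push_back(j);
      --i; --j;
      st = (msrc == 0) ? 'M' : (msrc == 1 ? 'X' : 'Y');
      if (!local && (i == 0 && j == 0)) break;
      if (!local && (i == 0 || j == 0)) {
        // remaining is a boundary gap in global mode
        while (j > 0) { acols.push_back(0); bcols.push_back(j); --j; }
        while (i > 0) { acols.push_back(i); bcols.push_back(0); --i; }
        break;
      }
    } else if (st == 'X') {  // gap in a, consumed b[j-1]
      acols.push_back(0); bcols.push_back(j);
      bool fromM = (code & 4) != 0;
      --j;
      st = fromM ? 'M' : 'X';
      if (!local && i == 0) {
        while (j > 0) { acols.push_back(0); bcols.push_back(j); --j; }
        break;
      }
    } else {  // 'Y': gap in b, consumed a[i-1]
      acols.push_back(i); bcols.push_back(0);
      bool fromM = (code & 8) != 0;
      --i;
      st = fromM ? 'M' : 'Y';
      if (!local && j == 0) {
        while (i > 0) { acols.push_back(i); bcols.push_back(0); --i; }
        break;
      }
    }
  }
  std::reverse(acols.begin(), acols.end());
  std::reverse(bcols.begin(), bcols.end());

  int a_start = 0, a_end = 0, b_start = 0, b_end = 0;
  int n_match = 0, n_mismatch = 0, n_gap = 0;
  for (size_t kcol = 0; kcol < acols.size(); ++kcol) {
    int ai = acols[kcol], bjp = bcols[kcol];
    if (ai > 0 && a_start == 0) a_start = ai;
    if (bjp > 0 && b_start == 0) b_start = bjp;
    if (ai > 0) a_end = ai;
    if (bjp > 0) b_end = bjp;
    if (ai > 0 && bjp > 0) {
      if (a[ai - 1] == b[bjp - 1]) ++n_match; else ++n_mismatch;
    } else ++n_gap;
  }
  (void)K;
  return List::create(
      _["score"] = best, _["a_start"] = a_start, _["a_end"] = a_end,
      _["b_start"] = b_start, _["b_end"] = b_end, _["n_match"] = n_match,
      _["n_mismatch"] = n_mismatch, _["n_gapcols"] = n_gap,
      _["a_cols"] = wrap(acols), _["b_cols"] = wrap(bcols));
}

// Exact k-mer matches between query and subject.
// Returns a 2-column integer matrix (qpos, spos), 1-based start positions.
// Positions containing characters outside the alphabet never seed.
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_seeds(std::string q, std::string s, int k,
                             std::string alphabet) {
  std::vector<int> eq = encode(q, alphabet), es = encode(s, alphabet);
  const int K = (int)alphabet.size();
  const int nq = (int)q.size(), ns = (int)s.size();
  if (nq < k || ns < k) return IntegerMatrix(0, 2);

  std::unordered_multimap<uint64_t, int> table;
  table.reserve(ns);
  uint64_t key = 0, mask = 1;
  for (int i = 0; i < k; ++i) mask *= (uint64_t)K;
  int run = 0;
  for (int i = 0; i < ns; ++i) {
    if (es[i] < 0) { run = 0; key = 0; continue; }
    key = (key * (uint64_t)K + (uint64_t)es[i]) % mask;
    if (++run >= k) table.emplace(key, i - k + 2);  // 1-based start
  }
  std::vector<int> qp, sp;
  key = 0; run = 0;
  for (int i = 0; i < nq; ++i) {
    if (eq[i] < 0) { run = 0; key = 0; continue; }
    key = (key * (uint64_t)K + (uint64_t)eq[i]) % mask;
    if (++run >= k) {
      auto range = table.equal_range(key);
      for (auto it = range.first; it != range.second; ++it) {
        // verify (hash is positional-exact here, but guard collisions)
        int qs = i - k + 2, ss = it->second;
        bool ok = true;
        for (int t = 0; t < k; ++t)
          if (q[qs - 1 + t] != s[ss - 1 + t]) { ok = false; break; }
        if (ok) { qp.push_back(qs); sp.push_back(ss); }
      }
    }
  }
  IntegerMatrix out((int)qp.size(), 2);
  for (size_t i = 0; i < qp.size(); ++i) {
    out(i, 0) = qp[i];
    out(i, 1) = sp[i];
  }
  return out;
}

// Ungapped x-drop extension of a seed in both directions.
// Returns the best ungapped segment score through the seed.
// [[Rcpp::export]]
double cpp_ungapped_extend(std::string q, std::string s, int qpos, int spos,
                           int k, std::string alphabet, IntegerMatrix smat,
                           double xdrop) {
  std::vector<int> eq = encode(q, alphabet), es = encode(s, alphabet);
  double score = 0.0;
  for (int t = 0; t < k; ++t) {
    int ca = eq[qpos - 1 + t], cb = es[spos - 1 + t];
    score += (ca < 0 || cb < 0) ? BAD : smat(ca, cb);
  }
  // right
  double run = 0.0, bestrun = 0.0;
  int i = qpos - 1 + k, j = spos - 1 + k;
  while (i < (int)q.size() && j < (int)s.size()) {
    int ca = eq[i], cb = es[j];
    run += (ca < 0 || cb < 0) ? BAD : smat(ca, cb);
    if (run > bestrun) bestrun = run;
    if (bestrun - run > xdrop) break;
    ++i; ++j;
  }
  score += bestrun;
  // left
  run = 0.0; bestrun = 0.0;
  i = qpos - 2; j = spos - 2;
  while (i >= 0 && j >= 0) {
    int ca = eq[i], cb = es[j];
    run += (ca < 0 || cb < 0) ? BAD : smat(ca, cb);
    if (run > bestrun) bestrun = run;
    if (bestrun - run > xdrop) break;
    --i; --j;
  }
  return score + bestrun;
}
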