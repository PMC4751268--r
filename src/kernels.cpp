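#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 2-bit DNA encoding; -1 for anything outside ACGT.
static inline int base2int(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}
static inline char int2base(int v) { return "ACGT"[v]; }
static inline int compl2(int v) { return 3 - v; }

static std::vector<int> encode(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base2int(s[i]);
  return v;
}

// ---------------------------------------------------------------------------
// MUM-style anchors: maximal exact matches seeded by k-mers whose occurrence
// count (forward + reverse strand combined) is exactly 1 in each genome.
// ---------------------------------------------------------------------------

struct KmerCount { int32_t count; int32_t pos; int8_t strand; };

// counts[kmer] over fwd and rc windows of seq
static void count_kmers(const std::vector<int> &e, int k,
                        std::unordered_map<uint64_t, KmerCount> &tab) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  int n = (int)e.size();
  for (int i = 0; i < n; ++i) {
    int b = e[i];
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)compl2(b) << (2 * (k - 1)));
    if (++valid < k) continue;
    int start = i - k + 1;
    auto f = tab.find(fwd);
    if (f == tab.end()) tab[fwd] = {1, start, 0}; else f->second.count++;
    if (rev != fwd) {
      auto r = tab.find(rev);
      if (r == tab.end()) tab[rev] = {1, start, 1}; else r->second.count++;
    } else {
      tab[fwd].count++;  // palindromic k-mer counts on both strands
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_find_anchors(std::string seqA, std::string seqB, int k) {
  std::vector<int> ea = encode(seqA), eb = encode(seqB);
  int na = (int)ea.size(), nb = (int)eb.size();
  std::unordered_map<uint64_t, KmerCount> tabA, tabB;
  tabA.reserve(2 * na); tabB.reserve(2 * nb);
  count_kmers(ea, k, tabA);
  count_kmers(eb, k, tabB);

  // diagonal -> furthest posA already covered, to dedupe seeds of one anchor
  std::unordered_map<int64_t, int64_t> doneF, doneR;
  std::vector<int> outA, outB, outL;
  std::vector<int> outRev;

  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0;
  int valid = 0;
  for (int i = 0; i < na; ++i) {
    int b = ea[i];
    if (b < 0) { valid = 0; fwd = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    if (++valid < k) continue;
    int a0 = i - k + 1;
    auto fa = tabA.find(fwd);
    if (fa == tabA.end() || fa->second.count != 1) continue;
    auto fb = tabB.find(fwd);
    if (fb == tabB.end() || fb->second.count != 1) continue;
    int b0 = fb->second.pos;
    if (fb->second.strand == 0) {
      // forward match A[a0..) == B[b0..)
      int64_t diag = (int64_t)b0 - a0;
      auto d = doneF.find(diag);
      if (d != doneF.end() && d->second >= a0) continue;
      int s_a = a0, s_b = b0;
      while (s_a > 0 && s_b > 0 && ea[s_a - 1] >= 0 && ea[s_a - 1] == eb[s_b - 1]) { --s_a; --s_b; }
      int e_a = a0 + k, e_b = b0 + k;
      while (e_a < na && e_b < nb && ea[e_a] >= 0 && ea[e_a] == eb[e_b]) { ++e_a; ++e_b; }
      doneF[diag] = e_a;
      outA.push_back(s_a); outB.push_back(s_b); outL.push_back(e_a - s_a); outRev.push_back(0);
    } else {
      // reverse match: A[a0..a0+k) == revcomp(B[b0..b0+k))
      int64_t anti = (int64_t)a0 + b0 + k;  // invariant under extension
      auto d = doneR.find(anti);
      if (d != doneR.end() && d->second >= a0) continue;
      int s_a = a0, e_b = b0 + k;
      while (s_a > 0 && e_b < nb && ea[s_a - 1] >= 0 && eb[e_b] >= 0 &&
             ea[s_a - 1] == compl2(eb[e_b])) { --s_a; ++e_b; }
      int e_a = a0 + k, s_b = b0;
      while (e_a < na && s_b > 0 && ea[e_a] >= 0 && eb[s_b - 1] >= 0 &&
             ea[e_a] == compl2(eb[s_b - 1])) { ++e_a; --s_b; }
      doneR[anti] = e_a;
      outA.push_back(s_a); outB.push_back(s_b); outL.push_back(e_a - s_a); outRev.push_back(1);
    }
  }
  return DataFrame::create(_["posA"] = outA, _["posB"] = outB,
                           _["length"] = outL, _["reverse"] = outRev);
}

// ---------------------------------------------------------------------------
// Maximum-weight collinear chain (weighted LIS). Anchors must be given sorted
// by posA (ties by posB). Returns 1-based indices of the best chain.
// Requires strictly increasing posA and posB along the chain.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_chain_lis(IntegerVector posA, IntegerVector posB, IntegerVector len) {
  int n = posA.size();
  if (n == 0) return IntegerVector(0);
  std::vector<double> best(n);
  std::vector<int> prev(n, -1);
  for (int i = 0; i < n; ++i) {
    best[i] = (double)len[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (posA[j] < posA[i] && posB[j] < posB[i]) {
        double cand = best[j] + (double)len[i];
        if (cand > best[i] + 1e-9) { best[i] = cand; prev[i] = j; }
        // tie: keep predecessor with smaller posA (j scanned in increasing order
        // of posA, so the first-seen equal-weight predecessor is kept)
      }
      if (posA[j] >= posA[i]) break;  // sorted input: no later j can precede i
    }
  }
  int argmax = 0;
  for (int i = 1; i < n; ++i)
    if (best[i] > best[argmax] + 1e-9) argmax = i;
  std::vector<int> chain;
  for (int i = argmax; i >= 0; i = prev[i]) chain.push_back(i + 1);
  std::reverse(chain.begin(), chain.end());
  return wrap(chain);
}

// ---------------------------------------------------------------------------
// Banded global (Needleman-Wunsch) alignment with unit scores
// match +1, mismatch -1, gap -2 (linear). Returns score and per-column ops:
// 0 = match, 1 = mismatch, 2 = base in A only (gap in B), 3 = base in B only.
// Band: positions j allowed in [lo(i), hi(i)] around the interpolated diagonal.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_banded_global(std::string a, std::string b, int band,
                       int match = 1, int mismatch = -1, int gap = -2) {
  int na = (int)a.size(), nb = (int)b.size();
  if (na == 0 || nb == 0) {
    IntegerVector ops(na + nb, na > 0 ? 2 : 3);
    return List::create(_["score"] = gap * (na + nb), _["ops"] = ops);
  }
  int diff = nb - na;
  int lo_off = std::min(0, diff) - band, hi_off = std::max(0, diff) + band;
  int width = hi_off - lo_off + 1;
  const int NEG = -1000000000;
  std::vector<int> S((size_t)(na + 1) * width, NEG);
  auto idx = [&](int i, int j) { return (size_t)i * width + (j - i - lo_off); };
  auto inband = [&](int i, int j) { int o = j - i; return o >= lo_off && o <= hi_off && j >= 0 && j <= nb; };
  S[idx(0, 0)] = 0;
  for (int j = 1; j <= nb && inband(0, j); ++j) S[idx(0, j)] = gap * j;
  for (int i = 1; i <= na; ++i) {
    int jlo = std::max(0, i + lo_off), jhi = std::min(nb, i + hi_off);
    for (int j = jlo; j <= jhi; ++j) {
      int bestv = NEG;
      if (j > 0 && inband(i - 1, j - 1) && S[idx(i - 1, j - 1)] > NEG) {
        int sub = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? match : mismatch;
        bestv = S[idx(i - 1, j - 1)] + sub;
      }
      if (inband(i - 1, j) && S[idx(i - 1, j)] > NEG)
        bestv = std::max(bestv, S[idx(i - 1, j)] + gap);
      if (j > 0 && inband(i, j - 1) && S[idx(i, j - 1)] > NEG)
        bestv = std::max(bestv, S[idx(i, j - 1)] + gap);
      S[idx(i, j)] = bestv;
    }
  }
  // traceback
  std::vector<int> ops;
  ops.reserve(na + nb);
  int i = na, j = nb;
  while (i > 0 || j > 0) {
    int cur = S[idx(i, j)];
    if (i > 0 && j > 0 && inband(i - 1, j - 1) && S[idx(i - 1, j - 1)] > NEG) {
      int sub = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? match : mismatch;
      if (S[idx(i - 1, j - 1)] + sub == cur) {
        ops.push_back(a[i - 1] == b[j - 1] ? 0 : 1); --i; --j; continue;
      }
    }
    if (i > 0 && inband(i - 1, j) && S[idx(i - 1, j)] > NEG && S[idx(i - 1, j)] + gap == cur) {
      ops.push_back(2); --i; continue;
    }
    if (j > 0 && inband(i, j - 1) && S[idx(i, j - 1)] > NEG && S[idx(i, j - 1)] + gap == cur) {
      ops.push_back(3); --j; continue;
    }
    stop("banded alignment traceback failed");
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = S[idx(na, nb)], _["ops"] = wrap(ops));
}

// ---------------------------------------------------------------------------
// Full-DP pairwise alignment with configurable free ends (linear gap cost).
// free_a: leading/trailing gaps in a (i.e. unaligned b overhangs) are free.
// free_b: leading/trailing gaps in b (unaligned a overhangs) are free.
// Returns ops as above plus counts restricted to the aligned core (columns
// between the first and last match/mismatch when ends are free).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_endfree_align(std::string a, std::string b, bool free_a, bool free_b,
                       int match = 1, int mismatch = -1, int gap = -2,
                       bool treat_n_mismatch = true) {
  int na = (int)a.size(), nb = (int)b.size();
  std::vector<int> S((size_t)(na + 1) * (nb + 1));
  auto idx = [&](int i, int j) { return (size_t)i * (nb + 1) + j; };
  for (int j = 0; j <= nb; ++j) S[idx(0, j)] = free_a ? 0 : gap * j;
  for (int i = 1; i <= na; ++i) {
    S[idx(i, 0)] = free_b ? 0 : gap * i;
    for (int j = 1; j <= nb; ++j) {
      int sub = (a[i - 1] == b[j - 1] && (!treat_n_mismatch || a[i - 1] != 'N'))
        ? match : mismatch;
      int v = S[idx(i - 1, j - 1)] + sub;
      v = std::max(v, S[idx(i - 1, j)] + gap);
      v = std::max(v, S[idx(i, j - 1)] + gap);
      S[idx(i, j)] = v;
    }
  }
  // terminal cell: allow free trailing overhangs
  int bi = na, bj = nb, bestv;
  bestv = S[idx(na, nb)];
  if (free_a) for (int j = 0; j <= nb; ++j) if (S[idx(na, j)] > bestv) { bestv = S[idx(na, j)]; bi = na; bj = j; }
  if (free_b) for (int i = 0; i <= na; ++i) if (S[idx(i, nb)] > bestv) { bestv = S[idx(i, nb)]; bi = i; bj = nb; }
  std::vector<int> ops;
  // trailing free overhang recorded as ops but flagged via core bounds
  for (int j = nb; j > bj; --j) ops.push_back(3);
  for (int i = na; i > bi; --i) ops.push_back(2);
  size_t trail = ops.size();
  int i = bi, j = bj;
  int prev = -1;  // prefer continuing a gap on score ties: keeps long
                  // insertions as one contiguous run instead of letting the
                  // traceback scatter them across chance matches
  while (i > 0 && j > 0) {
    int cur = S[idx(i, j)];
    int sub = (a[i - 1] == b[j - 1] && (!treat_n_mismatch || a[i - 1] != 'N'))
      ? match : mismatch;
    bool can_d = S[idx(i - 1, j - 1)] + sub == cur;
    bool can_u = S[idx(i - 1, j)] + gap == cur;
    bool can_l = S[idx(i, j - 1)] + gap == cur;
    int op;
    if (prev == 2 && can_u) op = 2;
    else if (prev == 3 && can_l) op = 3;
    else if (can_d) op = a[i - 1] == b[j - 1] ? 0 : 1;
    else if (can_u) op = 2;
    else op = 3;
    ops.push_back(op);
    if (op <= 1) { --i; --j; } else if (op == 2) --i; else --j;
    prev = op;
  }
  // leading overhang: if ends are free and we are at a border, stop tracing
  // through the free region but still record it
  size_t lead_start = ops.size();
  while (i > 0) { ops.push_back(2); --i; }
  while (j > 0) { ops.push_back(3); --j; }
  size_t lead = ops.size() - lead_start;
  bool lead_free = (free_a && bj >= 0 && lead > 0 && a.size() == 0) ? true : false;
  (void)lead_free;
  std::reverse(ops.begin(), ops.end());
  // core = columns excluding free terminal overhangs
  size_t start_core = (free_a || free_b) ? lead : 0;
  size_t end_core = ops.size() - ((free_a || free_b) ? trail : 0);
  // if ends are not free the leading run is a real gap; lead counted as core
  if (!free_a && !free_b) { start_core = 0; end_core = ops.size(); }
  int matches = 0, mismatches = 0, gaps = 0;
  for (size_t kk = start_core; kk < end_core; ++kk) {
    if (ops[kk] == 0) ++matches;
    else if (ops[kk] == 1) ++mismatches;
    else ++gaps;
  }
  return List::create(_["score"] = bestv, _["ops"] = wrap(ops),
                      _["core_start"] = (int)start_core, _["core_end"] = (int)end_core,
                      _["matches"] = matches, _["mismatches"] = mismatches,
                      _["gaps"] = gaps);
}

// ---------------------------------------------------------------------------
// Maximal repeat discovery within one genome: exact k-mer seeds in direct and
// inverted orientation, ungapped x-drop extension, per-diagonal merging.
// Returns candidate pairs; identity filtering is finished in R.
// ---------------------------------------------------------------------------

struct Rep { int a, b, len, mism; bool inverted; };

static void extend_direct(const std::vector<int> &e, int i, int j, int k,
                          int xdrop, Rep &out) {
  // i < j; extend A=[i..), B=[j..) with mismatches allowed under x-drop
  int n = (int)e.size();
  int sa = i, sb = j, ea = i + k, eb = j + k, mism = 0;
  // right
  int score = 0, best = 0, bea = ea, beb = eb, bm = 0, cm = 0;
  while (eb < n && ea < sb) {  // keep intervals non-overlapping: ea must stay <= start of B copy... relaxed later
    if (e[ea] < 0 || e[eb] < 0) break;
    score += (e[ea] == e[eb]) ? 1 : -3;
    cm += (e[ea] != e[eb]);
    ++ea; ++eb;
    if (score > best) { best = score; bea = ea; beb = eb; bm = cm; }
    if (best - score > xdrop) break;
  }
  ea = bea; eb = beb; mism += bm;
  // left
  score = 0; best = 0; bm = 0; int bsa = sa, bsb = sb; cm = 0;
  while (sa > 0 && sb > ea) {
    if (e[sa - 1] < 0 || e[sb - 1] < 0) break;
    score += (e[sa - 1] == e[sb - 1]) ? 1 : -3;
    cm += (e[sa - 1] != e[sb - 1]);
    --sa; --sb;
    if (score > best) { best = score; bsa = sa; bsb = sb; bm = cm; }
    if (best - score > xdrop) break;
  }
  sa = bsa; sb = bsb; mism += bm;
  out = {sa, bsb, ea - sa, mism, false};
}

static void extend_inverted(const std::vector<int> &e, int i, int j, int k,
                            int xdrop, Rep &out) {
  // A[i..i+k) == revcomp(B[j..j+k)), i + k <= j assumed
  int n = (int)e.size();
  int sa = i, ea = i + k, sb = j, eb = j + k, mism = 0;
  // extend right in A <-> left in B
  int score = 0, best = 0, bea = ea, bsb = sb, cm = 0, bm = 0;
  while (ea < n && sb > ea) {
    if (e[ea] < 0 || e[sb - 1] < 0) break;
    bool ok = (e[ea] == compl2(e[sb - 1]));
    score += ok ? 1 : -3; cm += !ok;
    ++ea; --sb;
    if (score > best) { best = score; bea = ea; bsb = sb; bm = cm; }
    if (best - score > xdrop) break;
  }
  ea = bea; sb = bsb; mism += bm;
  // extend left in A <-> right in B
  score = 0; best = 0; int bsa = sa, beb = eb; cm = 0; bm = 0;
  while (sa > 0 && eb < n) {
    if (e[sa - 1] < 0 || e[eb] < 0) break;
    bool ok = (e[sa - 1] == compl2(e[eb]));
    score += ok ? 1 : -3; cm += !ok;
    --sa; ++eb;
    if (score > best) { best = score; bsa = sa; beb = eb; bm = cm; }
    if (best - score > xdrop) break;
  }
  sa = bsa; eb = beb; mism += bm;
  out = {sa, sb, ea - sa, mism, true};
}

// [[Rcpp::export]]
DataFrame cpp_self_repeats(std::string seq, int k, int min_len, int max_occ,
                           int xdrop = 30) {
  std::vector<int> e = encode(seq);
  int n = (int)e.size();
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_map<uint64_t, std::vector<int>> pos;
  pos.reserve(2 * n);
  uint64_t fwd = 0; int valid = 0;
  for (int i = 0; i < n; ++i) {
    if (e[i] < 0) { valid = 0; fwd = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)e[i]) & mask;
    if (++valid < k) continue;
    pos[fwd].push_back(i - k + 1);
  }
  std::unordered_map<int64_t, int> doneD, doneI;  // diag/antidiag -> covered end
  std::vector<int> oa, ob, ol, om; std::vector<int> oi;
  for (auto &kv : pos) {
    const std::vector<int> &pf = kv.second;
    // direct pairs: same k-mer at two positions
    if ((int)pf.size() >= 2 && (int)pf.size() <= max_occ) {
      for (size_t x = 0; x < pf.size(); ++x)
        for (size_t y = x + 1; y < pf.size(); ++y) {
          int i = pf[x], j = pf[y];
          if (j - i < min_len) continue;  // copies would overlap
          int64_t diag = (int64_t)(j - i);
          int64_t key = diag * (int64_t)(n + 1);
          auto d = doneD.find(key);
          if (d != doneD.end() && d->second >= i) continue;
          Rep r; extend_direct(e, i, j, k, xdrop, r);
          doneD[key] = r.a + r.len;
          if (r.len >= min_len && r.b >= r.a + r.len) {
            oa.push_back(r.a); ob.push_back(r.b); ol.push_back(r.len);
            om.push_back(r.mism); oi.push_back(0);
          }
        }
    }
    // inverted pairs: k-mer and its revcomp
    uint64_t rc = 0; uint64_t kk = kv.first;
    for (int t = 0; t < k; ++t) { rc = (rc << 2) | (3 - (kk & 3)); kk >>= 2; }
    if (rc < kv.first) continue;  // handle each pair once
    auto it = pos.find(rc);
    if (it == pos.end()) continue;
    const std::vector<int> &pr = it->second;
    if ((int)pf.size() * (int)pr.size() > max_occ * max_occ) continue;
    for (int i : pf)
      for (int j : pr) {
        if (rc == kv.first && j <= i) continue;
        int lo = std::min(i, j), hi = std::max(i, j);
        if (hi - lo < min_len) continue;
        int64_t anti = (int64_t)lo + hi + k;
        auto d = doneI.find(anti);
        if (d != doneI.end() && d->second >= lo) continue;
        Rep r; extend_inverted(e, lo, hi, k, xdrop, r);
        doneI[anti] = r.a + r.len;
        if (r.len >= min_len && r.b >= r.a + r.len) {
          oa.push_back(r.a); ob.push_back(r.b); ol.push_back(r.len);
          om.push_back(r.mism); oi.push_back(1);
        }
      }
  }
  return DataFrame::create(_["startA"] = oa, _["startB"] = ob, _["length"] = ol,
                           _["mismatches"] = om, _["inverted"] = oi);
}

// ---------------------------------------------------------------------------
// Direct-orientation repeats between two different sequences (for flanking
// direct-repeat detection). Seeds k-mers of s1 against s2, ungapped x-drop.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_cross_repeats(std::string s1, std::string s2, int k, int min_len,
                            int xdrop = 30) {
  std::vector<int> e1 = encode(s1), e2 = encode(s2);
  int n1 = (int)e1.size(), n2 = (int)e2.size();
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_map<uint64_t, std::vector<int>> pos2;
  uint64_t fwd = 0; int valid = 0;
  for (int i = 0; i < n2; ++i) {
    if (e2[i] < 0) { valid = 0; fwd = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)e2[i]) & mask;
    if (++valid < k) continue;
    pos2[fwd].push_back(i - k + 1);
  }
  std::unordered_map<int64_t, int> done;
  std::vector<int> o1, o2, ol, om;
  fwd = 0; valid = 0;
  for (int i = 0; i < n1; ++i) {
    if (e1[i] < 0) { valid = 0; fwd = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)e1[i]) & mask;
    if (++valid < k) continue;
    int a0 = i - k + 1;
    auto it = pos2.find(fwd);
    if (it == pos2.end()) continue;
    for (int b0 : it->second) {
      int64_t diag = (int64_t)b0 - a0;
      auto d = done.find(diag);
      if (d != done.end() && d->second >= a0) continue;
      // ungapped x-drop extension across the two sequences
      int sa = a0, sb = b0, ea = a0 + k, eb = b0 + k, mism = 0;
      int score = 0, best = 0, bea = ea, cm = 0, bm = 0;
      while (ea < n1 && eb < n2 && e1[ea] >= 0 && e2[eb] >= 0) {
        score += (e1[ea] == e2[eb]) ? 1 : -3; cm += (e1[ea] != e2[eb]);
        ++ea; ++eb;
        if (score > best) { best = score; bea = ea; bm = cm; }
        if (best - score > xdrop) break;
      }
      ea = bea; mism += bm;
      score = 0; best = 0; int bsa = sa; cm = 0; bm = 0;
      while (sa > 0 && sb > 0 && e1[sa - 1] >= 0 && e2[sb - 1] >= 0) {
        score += (e1[sa - 1] == e2[sb - 1]) ? 1 : -3; cm += (e1[sa - 1] != e2[sb - 1]);
        --sa; --sb;
        if (score > best) { best = score; bsa = sa; bm = cm; }
        if (best - score > xdrop) break;
      }
      sa = bsa; mism += bm;
      done[diag] = ea;
      int len = ea - sa;
      if (len >= min_len) {
        o1.push_back(sa); o2.push_back(b0 - (a0 - sa)); ol.push_back(len); om.push_back(mism);
      }
    }
  }
  return DataFrame::create(_["start1"] = o1, _["start2"] = o2,
                           _["length"] = ol, _["mismatches"] = om);
}

// ---------------------------------------------------------------------------
// Affine-gap Smith-Waterman for proteins, optionally banded around a diagonal
// range [dlo, dhi] (d = j - i). band disabled when dlo > dhi.
// Gap of length L costs open + ext*L.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
int cpp_sw_score(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                 int open, int ext, int dlo = 1, int dhi = 0) {
  int na = a.size(), nb = b.size();
  bool banded = dlo <= dhi;
  const int NEG = -1000000000;
  std::vector<int> H(nb + 1, 0), E(nb + 1, NEG);
  int best = 0;
  for (int i = 1; i <= na; ++i) {
    int Hdiag = 0, F = NEG;
    int Hprev0 = H[0];
    H[0] = 0;
    int jlo = 1, jhi = nb;
    if (banded) { jlo = std::max(1, i + dlo); jhi = std::min(nb, i + dhi); }
    if (jlo > 1) { Hdiag = 0; }
    for (int j = 1; j <= nb; ++j) {
      if (banded && (j < jlo || j > jhi)) { Hdiag = H[j]; H[j] = 0; E[j] = NEG; continue; }
      int hd = (j == 1) ? Hprev0 : Hdiag;
      Hdiag = H[j];
      E[j] = std::max(E[j] - ext, H[j] - open - ext);
      F = std::max(F - ext, ((j == jlo) ? 0 : H[j - 1]) - open - ext);
      // note: F uses current row's H[j-1] which is already updated
      int v = hd + sub(a[i - 1], b[j - 1]);
      v = std::max(v, E[j]);
      v = std::max(v, F);
      v = std::max(v, 0);
      H[j] = v;
      if (v > best) best = v;
    }
  }
  return best;
}

// ---------------------------------------------------------------------------
// Full affine-gap Smith-Waterman with traceback (for hit statistics).
// Returns best score, 1-based query/subject spans, matches, mismatches,
// gap columns and aligned length of the optimal local alignment.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_sw_align(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                  int open, int ext) {
  int na = a.size(), nb = b.size();
  const int NEG = -1000000000;
  std::vector<int> H((size_t)(na + 1) * (nb + 1), 0);
  std::vector<int> E((size_t)(na + 1) * (nb + 1), NEG);
  std::vector<int> F((size_t)(na + 1) * (nb + 1), NEG);
  auto ix = [&](int i, int j) { return (size_t)i * (nb + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      E[ix(i, j)] = std::max(E[ix(i, j - 1)] - ext, H[ix(i, j - 1)] - open - ext);
      F[ix(i, j)] = std::max(F[ix(i - 1, j)] - ext, H[ix(i - 1, j)] - open - ext);
      int v = H[ix(i - 1, j - 1)] + sub(a[i - 1], b[j - 1]);
      v = std::max(v, E[ix(i, j)]);
      v = std::max(v, F[ix(i, j)]);
      v = std::max(v, 0);
      H[ix(i, j)] = v;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj, matches = 0, mism = 0, gaps = 0, cols = 0;
  int state = 0;  // 0 = H, 1 = E (gap in a), 2 = F (gap in b)
  while (i > 0 && j > 0) {
    if (state == 0) {
      int h = H[ix(i, j)];
      if (h == 0) break;
      if (h == H[ix(i - 1, j - 1)] + sub(a[i - 1], b[j - 1])) {
        if (a[i - 1] == b[j - 1]) ++matches; else ++mism;
        ++cols; --i; --j;
      } else if (h == E[ix(i, j)]) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++gaps; ++cols;
      if (E[ix(i, j)] == H[ix(i, j - 1)] - open - ext) { --j; state = 0; }
      else { --j; }
    } else {
      ++gaps; ++cols;
      if (F[ix(i, j)] == H[ix(i - 1, j)] - open - ext) { --i; state = 0; }
      else { --i; }
    }
  }
  return List::create(_["score"] = best, _["qstart"] = i + 1, _["qend"] = bi,
                      _["sstart"] = j + 1, _["send"] = bj,
                      _["matches"] = matches, _["mismatches"] = mism,
                      _["gaps"] = gaps, _["length"] = cols);
}
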