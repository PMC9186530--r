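#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <cstdint>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

// splitmix64 finalizer; used only to decide which k-mers are sampled
static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Scan all k-mers of `seq`, returning the sampled subset (canonical encode
// hashed mod w == 0; w = 1 keeps every position). The returned `code` is the
// exact 2-bit encoding of the canonical (strand-collapsed) k-mer, stored in a
// double: exact for k <= 26 (52 bits). `fwd` says whether the forward strand
// spelled the canonical form. Positions containing non-ACGT bases are skipped.
// [[Rcpp::export]]
DataFrame cpp_kmer_scan(std::string seq, int k, int w) {
  int n = (int) seq.size();
  std::vector<int> pos;
  std::vector<double> code;
  std::vector<int> fwd;
  if (k > 26) stop("k must be <= 26 for exact k-mer encoding");
  if (n < k) {
    return DataFrame::create(_["pos"] = IntegerVector(0),
                             _["code"] = NumericVector(0),
                             _["fwd"] = LogicalVector(0));
  }
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t f = 0, r = 0;
  int valid = 0;
  int shift = 2 * (k - 1);
  for (int i = 0; i < n; i++) {
    int b = base2bits(seq[i]);
    if (b < 0) { valid = 0; f = 0; r = 0; continue; }
    f = ((f << 2) | (uint64_t) b) & mask;
    r = (r >> 2) | (((uint64_t) (3 - b)) << shift);
    valid++;
    if (valid >= k) {
      uint64_t canon = f < r ? f : r;
      if (w <= 1 || (mix64(canon) % (uint64_t) w) == 0) {
        pos.push_back(i - k + 1);
        code.push_back((double) canon);
        fwd.push_back(f <= r ? 1 : 0);
      }
    }
  }
  return DataFrame::create(_["pos"] = wrap(pos), _["code"] = wrap(code),
                           _["fwd"] = wrap(fwd));
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; i++) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); j++) {
      char c = s[s.size() - 1 - j];
      switch (c) {
      case 'A': r[j] = 'T'; break; case 'C': r[j] = 'G'; break;
      case 'G': r[j] = 'C'; break; case 'T': r[j] = 'A'; break;
      default: r[j] = 'N';
      }
    }
    out[i] = r;
  }
  return out;
}

// Maximal perfect tandem runs for one period: positions i where
// s[i] == s[i+p]. Returns (start, end) 0-based half-open tract intervals
// meeting the length/copies thresholds, for each period 1..max_unit.
// [[Rcpp::export]]
DataFrame cpp_perfect_tandems(std::string s, int max_unit, int min_length,
                              double min_copies) {
  int n = (int) s.size();
  std::vector<int> starts, ends, periods;
  for (int p = 1; p <= max_unit && p < n; p++) {
    int run = 0;
    for (int i = p; i <= n; i++) {
      bool eq = (i < n) && (s[i] == s[i - p]);
      if (eq) {
        run++;
      } else {
        if (run > 0) {
          int tract = run + p;
          int s0 = i - run - p;
          if (tract >= min_length && (double) tract / p >= min_copies) {
            starts.push_back(s0);
            ends.push_back(s0 + tract);
            periods.push_back(p);
          }
        }
        run = 0;
      }
    }
  }
  return DataFrame::create(_["start"] = wrap(starts), _["end"] = wrap(ends),
                           _["period"] = wrap(periods));
}

// Banded global edit distance between full strings a and b (band on |i-j|).
// Returns band+... a large value if the band is exceeded.
// [[Rcpp::export]]
int cpp_banded_edit(std::string a, std::string b, int band) {
  int n = (int) a.size(), m = (int) b.size();
  if (n == 0 || m == 0) return n + m;
  band = std::max(band, std::abs(n - m) + 1);
  int W = 2 * band + 1;
  const int INF = 1 << 28;
  // padded rows: cell c in [1..W] corresponds to j = i + (c - 1 - band)
  std::vector<int> prev(W + 2, INF), cur(W + 2, INF);
  for (int j = 0; j <= band && j <= m; j++) prev[j + 1 + band] = j;
  const char *A = a.data();
  const char *B = b.data();
  for (int i = 1; i <= n; i++) {
    int jlo = std::max(0, i - band), jhi = std::min(m, i + band);
    int *pv = prev.data();
    int *cv = cur.data();
    cv[jlo - i + band] = INF;
    int j = jlo;
    if (j == 0) { cv[1 + band - i] = i; j = 1; }
    const char ai = A[i - 1];
    for (; j <= jhi; j++) {
      int c = j - i + 1 + band;
      int v = pv[c] + (ai != B[j - 1]);
      int up = pv[c + 1] + 1;
      if (up < v) v = up;
      int lf = cv[c - 1] + 1;
      if (lf < v) v = lf;
      cv[c] = v;
    }
    cv[jhi - i + 2 + band] = INF;
    std::swap(prev, cur);
  }
  int c = m - n + 1 + band;
  if (c < 1 || c > W) return INF;
  return prev[c];
}

// Dovetail overlap distance. b is placed on a at offset `diag` (a_pos =
// b_pos + diag). The implied overlap region runs from the cut to whichever
// read ends first; alignment is banded and anchored at the cut, with a free
// end on the longer side. Returns list(dist, len) where len is the length of
// the shorter side of the overlap region.
static List overlap_dist_one(const std::string &a, const std::string &b,
                             int diag, int band, int max_span);

// Dovetail overlap distance with b placed on a at offset diag. When
// max_span > 0 and the overlap is longer than 2*max_span, identity is
// verified on BOTH ends of the overlap region (a bounded slice each):
// verifying only one end would let an alignment that is homologous there
// but garbage at the other end (e.g. a repeat-internal match running into
// non-homologous flank) pass the identity floor.
// [[Rcpp::export]]
List cpp_overlap_dist(std::string a, std::string b, int diag, int band,
                      int max_span = 0) {
  int la = (int) a.size(), lb = (int) b.size();
  int a_lo = std::max(0, diag), b_lo = std::max(0, -diag);
  int na0 = la - a_lo, nb0 = lb - b_lo;
  if (na0 <= 0 || nb0 <= 0)
    return List::create(_["dist"] = NA_INTEGER, _["len"] = 0);
  if (max_span > 0 && std::min(na0, nb0) > 2 * max_span) {
    List lead = overlap_dist_one(a, b, diag, band, max_span);
    std::string ar(a.rbegin(), a.rend());
    std::string br(b.rbegin(), b.rend());
    List trail = overlap_dist_one(ar, br, la - lb - diag, band, max_span);
    int d1 = IntegerVector(lead["dist"])[0];
    int d2 = IntegerVector(trail["dist"])[0];
    if (d1 == NA_INTEGER || d2 == NA_INTEGER)
      return List::create(_["dist"] = NA_INTEGER, _["len"] = 0);
    return List::create(
      _["dist"] = d1 + d2,
      _["len"] = IntegerVector(lead["len"])[0] +
                 IntegerVector(trail["len"])[0]);
  }
  return overlap_dist_one(a, b, diag, band, max_span);
}

static List overlap_dist_one(const std::string &a, const std::string &b,
                             int diag, int band, int max_span) {
  int la = (int) a.size(), lb = (int) b.size();
  int a_lo = std::max(0, diag), b_lo = std::max(0, -diag);
  int na = la - a_lo, nb = lb - b_lo;
  if (na <= 0 || nb <= 0) return List::create(_["dist"] = NA_INTEGER, _["len"] = 0);
  if (max_span > 0) { // verify identity on a bounded leading slice
    if (na > max_span) na = max_span;
    if (nb > max_span) nb = max_span;
  }
  const int INF = 1 << 28;
  int W = 2 * band + 1;
  // padded rows: cell c in [1..W] corresponds to j = i + (c - 1 - band)
  std::vector<int> prev(W + 2, INF), cur(W + 2, INF);
  for (int j = 0; j <= band && j <= nb; j++) prev[j + 1 + band] = j;
  int best_end = INF;
  const char *A = a.data() + a_lo;
  const char *B = b.data() + b_lo;
  int imax = std::min(na, nb + band); // rows beyond are fully out of band
  for (int i = 1; i <= imax; i++) {
    int jlo = std::max(0, i - band), jhi = std::min(nb, i + band);
    if (jlo > jhi) break;
    int *pv = prev.data();
    int *cv = cur.data();
    cv[jlo - i + band] = INF;           // left pad for first j
    int j = jlo;
    if (j == 0) { cv[1 + band - i] = i; j = 1; }
    const char ai = A[i - 1];
    for (; j <= jhi; j++) {
      int c = j - i + 1 + band;
      int v = pv[c] + (ai != B[j - 1]);
      int up = pv[c + 1] + 1;
      if (up < v) v = up;
      int lf = cv[c - 1] + 1;
      if (lf < v) v = lf;
      cv[c] = v;
    }
    cv[jhi - i + 2 + band] = INF;       // right pad
    if (i == na) {
      for (int jj = jlo; jj <= jhi; jj++) {
        int v = cv[jj - i + 1 + band];
        if (v < best_end) best_end = v;
      }
    } else if (nb >= i - band && nb <= i + band) {
      int v = cv[nb - i + 1 + band];
      if (v < best_end) best_end = v;
    }
    std::swap(prev, cur);
  }
  int len = std::min(na, nb);
  return List::create(_["dist"] = best_end >= INF ? NA_INTEGER : best_end,
                      _["len"] = len);
}

// Exact dovetail / containment check with masked positions as wildcards.
// b placed on a at offset diag; checks the full implied region
// position-wise (masking absorbs substitutions inside simple repeats;
// repeat-length differences are instead normalised away during
// correction, so that all reads agree on tract lengths and positional
// matching stays valid).
// [[Rcpp::export]]
bool cpp_check_dovetail(std::string a, std::string b,
                        LogicalVector maskA, LogicalVector maskB, int diag) {
  int la = (int) a.size(), lb = (int) b.size();
  int a_lo = std::max(0, diag), b_lo = std::max(0, -diag);
  int n = std::min(la - a_lo, lb - b_lo);
  if (n <= 0) return false;
  for (int i = 0; i < n; i++) {
    int ai = a_lo + i, bi = b_lo + i;
    if (a[ai] != b[bi] && !maskA[ai] && !maskB[bi]) return false;
  }
  return true;
}

struct AlnCell { int32_t score; };

// Align one query onto the target window implied by diag, banded global with
// traceback, and accumulate pileup evidence into counts / insertion maps.
static bool accumulate_query(const std::string &target, const std::string &q,
                             int diag, int band,
                             std::vector<int> &cntA, std::vector<int> &cntC,
                             std::vector<int> &cntG, std::vector<int> &cntT,
                             std::vector<int> &cntGap, std::vector<int> &covj,
                             std::unordered_map<int, std::map<std::string, int> > &ins) {
  int lt = (int) target.size(), lq = (int) q.size();
  int t_lo = std::max(0, diag), q_lo = std::max(0, -diag);
  int nt = std::min(lt - t_lo, lq - q_lo + band); // target window (free-ish end)
  int nq = std::min(lq - q_lo, lt - t_lo + band);
  if (nt <= 0 || nq <= 0) return false;
  const int INF = 1 << 28;
  int W = 2 * band + 1;
  int Wp = W + 2; // padded rows; cell c in [1..W] is j = i + (c - 1 - band)
  // dp over rows i in 0..nt (target), cols j in [i-band, i+band] (query)
  std::vector<int> dp((size_t)(nt + 1) * Wp, INF);
  std::vector<uint8_t> op((size_t)(nt + 1) * Wp, 0); // 1=diag 2=up(del in q) 3=left(ins in q)
  for (int j = 0; j <= band && j <= nq; j++) {
    dp[(size_t) j + 1 + band] = j;
    op[(size_t) j + 1 + band] = j == 0 ? 0 : 3;
  }
  const char *T = target.data() + t_lo;
  const char *Q = q.data() + q_lo;
  for (int i = 1; i <= nt; i++) {
    int jlo = std::max(0, i - band), jhi = std::min(nq, i + band);
    int *cv = dp.data() + (size_t) i * Wp;
    const int *pv = dp.data() + (size_t)(i - 1) * Wp;
    uint8_t *ov = op.data() + (size_t) i * Wp;
    int j = jlo;
    if (j == 0) {
      cv[1 + band - i] = i;
      ov[1 + band - i] = 2;
      j = 1;
    }
    const char ti = T[i - 1];
    for (; j <= jhi; j++) {
      int c = j - i + 1 + band;
      int v = pv[c] + (ti != Q[j - 1]);
      uint8_t o = 1;
      int up = pv[c + 1] + 1;
      if (up < v) { v = up; o = 2; }
      int lf = cv[c - 1] + 1;
      if (lf < v) { v = lf; o = 3; }
      cv[c] = v; ov[c] = o;
    }
  }
  // pick end: prefer consuming the query fully (j == nq) at the best row,
  // else target fully consumed
  int bi = -1, bj = -1, bscore = INF;
  for (int i = std::max(0, nq - band); i <= std::min(nt, nq + band); i++) {
    int c = nq - i + 1 + band;
    if (c >= 1 && c <= W && dp[(size_t) i * Wp + c] < bscore) {
      bscore = dp[(size_t) i * Wp + c]; bi = i; bj = nq;
    }
  }
  for (int j = std::max(0, nt - band); j <= std::min(nq, nt + band); j++) {
    int c = j - nt + 1 + band;
    if (c >= 1 && c <= W && dp[(size_t) nt * Wp + c] < bscore) {
      bscore = dp[(size_t) nt * Wp + c]; bi = nt; bj = j;
    }
  }
  if (bi < 0 || bscore >= INF) return false;
  // traceback, accumulating evidence
  int i = bi, j = bj;
  std::string pending; // reversed insertion collected before target col i
  while (i > 0 || j > 0) {
    uint8_t o = op[(size_t) i * Wp + (j - i + 1 + band)];
    if (o == 0) break;
    if (o == 1) {
      if (!pending.empty()) {
        std::string s(pending.rbegin(), pending.rend());
        ins[t_lo + i][s]++;
        pending.clear();
      }
      char qc = q[q_lo + j - 1];
      int t = t_lo + i - 1;
      switch (qc) {
      case 'A': cntA[t]++; break; case 'C': cntC[t]++; break;
      case 'G': cntG[t]++; break; case 'T': cntT[t]++; break;
      }
      i--; j--;
    } else if (o == 2) {
      if (!pending.empty()) {
        std::string s(pending.rbegin(), pending.rend());
        ins[t_lo + i][s]++;
        pending.clear();
      }
      cntGap[t_lo + i - 1]++;
      i--;
    } else { // insertion in query relative to target, lands before target col i
      pending += q[q_lo + j - 1];
      j--;
    }
  }
  if (!pending.empty()) {
    std::string s(pending.rbegin(), pending.rend());
    ins[t_lo][s]++;
  }
  // junction coverage over the aligned target span (interior junctions)
  for (int t = t_lo + 1; t < t_lo + bi; t++) covj[t]++;
  return true;
}

// Majority-vote correction of one compressed read from its aligned partners.
// queries are already orientation-adjusted; diags give the target offset of
// each query. mask: masked target positions are never altered. Returns
// list(bases, src) where src maps each corrected position to its source
// position in the input (0-based; -1 for inserted bases).
// [[Rcpp::export]]
List cpp_correct_read(std::string target, CharacterVector queries,
                      IntegerVector diags, int band, LogicalVector mask,
                      int min_depth, double min_ratio,
                      double mask_ratio = 0) {
  int lt = (int) target.size();
  std::vector<int> cntA(lt, 0), cntC(lt, 0), cntG(lt, 0), cntT(lt, 0),
      cntGap(lt, 0), covj(lt + 1, 1);
  std::unordered_map<int, std::map<std::string, int> > ins;
  // the read supports itself
  for (int t = 0; t < lt; t++) {
    switch (target[t]) {
    case 'A': cntA[t]++; break; case 'C': cntC[t]++; break;
    case 'G': cntG[t]++; break; case 'T': cntT[t]++; break;
    }
  }
  for (int qi = 0; qi < queries.size(); qi++) {
    std::string q = as<std::string>(queries[qi]);
    accumulate_query(target, q, diags[qi], band, cntA, cntC, cntG, cntT,
                     cntGap, covj, ins);
  }
  std::string out; out.reserve(lt + 16);
  std::vector<int> src; src.reserve(lt + 16);
  const char *syms = "ACGT-";
  for (int t = 0; t <= lt; t++) {
    // insertions land before column t; junctions inside masks use the
    // (stricter) mask ratio when enabled, so simple-repeat length errors
    // are normalised toward the pileup consensus
    bool masked_j = (t < lt && mask[t]) || (t > 0 && mask[t - 1]);
    double jr = masked_j ? mask_ratio : min_ratio;
    if (!masked_j || mask_ratio > 0) {
      auto it = ins.find(t);
      if (it != ins.end()) {
        int topc = 0; const std::string *tops = nullptr;
        for (auto &kv : it->second)
          if (kv.second > topc) { topc = kv.second; tops = &kv.first; }
        int without = covj[t] - topc;
        if (tops && topc >= min_depth && topc >= jr * std::max(1, without) &&
            topc > without) {
          out += *tops;
          for (size_t z = 0; z < tops->size(); z++) src.push_back(-1);
        }
      }
    }
    if (t == lt) break;
    char tc = target[t];
    double cr = mask[t] ? mask_ratio : min_ratio;
    if (mask[t] && mask_ratio <= 0) { out += tc; src.push_back(t); continue; }
    int counts[5] = { cntA[t], cntC[t], cntG[t], cntT[t], cntGap[t] };
    int maj = 0;
    for (int s = 1; s < 5; s++) if (counts[s] > counts[maj]) maj = s;
    // strict majority required
    bool tie = false;
    for (int s = 0; s < 5; s++) if (s != maj && counts[s] == counts[maj]) tie = true;
    char mc = syms[maj];
    int own = 0;
    switch (tc) {
    case 'A': own = counts[0]; break; case 'C': own = counts[1]; break;
    case 'G': own = counts[2]; break; case 'T': own = counts[3]; break;
    }
    if (!tie && mc != tc && counts[maj] >= min_depth &&
        counts[maj] >= cr * std::max(1, own)) {
      if (mc == '-') continue; // deleted
      out += mc; src.push_back(t);
    } else {
      out += tc; src.push_back(t);
    }
  }
  return List::create(_["bases"] = out, _["src"] = wrap(src));
}
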