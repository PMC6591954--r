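#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <cstdint>
#include <climits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// k-mer index over a reference string (2-bit encoded, N-containing k-mers
// skipped).  Held behind an external pointer so a reference is indexed once
// per run.
// ---------------------------------------------------------------------------

struct KmerIndex {
  int k;
  int len;
  std::unordered_map<uint64_t, std::vector<int> > map;
};

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// [[Rcpp::export]]
SEXP cpp_index_kmers(std::string seq, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->len = (int)seq.size();
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t h = 0;
  int run = 0;
  for (int i = 0; i < (int)seq.size(); ++i) {
    int b = base2bit(seq[i]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++run >= k) idx->map[h].push_back(i - k + 1);
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// Best diagonal bucket shared between read and reference: count of collinear
// k-mer hits and the diagonal range they span.  Diagonals are bucketed
// (width `bucket`) and adjacent buckets merged so indel drift still counts as
// collinear; k-mers with > max_hits reference positions are skipped as
// repeats.
// [[Rcpp::export]]
List cpp_seed_hits(SEXP idx_ptr, std::string read, int bucket, int max_hits) {
  XPtr<KmerIndex> idx(idx_ptr);
  const int k = idx->k;
  const int m = (int)read.size();
  if (m < k) return List::create(_["count"] = 0, _["diag_lo"] = 0, _["diag_hi"] = 0);
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::unordered_map<int64_t, int> buckets;
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < m; ++i) {
    int b = base2bit(read[i]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      auto it = idx->map.find(h);
      if (it == idx->map.end()) continue;
      const std::vector<int>& pos = it->second;
      if ((int)pos.size() > max_hits) continue;
      int q = i - k + 1;
      for (int p : pos) {
        int64_t d = (int64_t)p - (int64_t)q;
        int64_t bk = (d >= 0) ? d / bucket : -(((-d) + bucket - 1) / bucket);
        buckets[bk] += 1;
      }
    }
  }
  if (buckets.empty())
    return List::create(_["count"] = 0, _["diag_lo"] = 0, _["diag_hi"] = 0);
  int best = 0; int64_t best_bk = 0; bool first = true;
  for (auto& kv : buckets) {
    int c = kv.second;
    auto nb = buckets.find(kv.first + 1);
    if (nb != buckets.end()) c += nb->second;
    if (first || c > best || (c == best && kv.first < best_bk)) {
      best = c; best_bk = kv.first; first = false;
    }
  }
  return List::create(_["count"] = best,
                      _["diag_lo"] = (double)(best_bk * bucket),
                      _["diag_hi"] = (double)((best_bk + 2) * bucket));
}

// ---------------------------------------------------------------------------
// Banded affine-gap alignment: global in the query, end-gaps free on the
// target, restricted to diagonals d = j - i in [d_lo, d_hi].  Penalties are
// positive; a gap of length g costs gap_open + g * gap_extend.  Traceback
// tie-breaking prefers match/mismatch over deletion over insertion so
// alignments (hence error events) are deterministic.
// ---------------------------------------------------------------------------

static const int NEG = INT_MIN / 4;

struct OpRun { char op; int len; };

static void push_op(std::vector<OpRun>& ops, char op) {
  if (!ops.empty() && ops.back().op == op) ops.back().len++;
  else ops.push_back(OpRun{op, 1});
}

// [[Rcpp::export]]
List cpp_align_banded(std::string query, std::string target,
                      int match, int mismatch, int gap_open, int gap_extend,
                      int d_lo, int d_hi) {
  const int m = (int)query.size(), n = (int)target.size();
  if (m == 0 || n == 0) stop("empty sequence in alignment");
  if (d_lo > d_hi) stop("invalid band: d_lo > d_hi");
  if (d_hi < -m || d_lo > n)
    return List::create(_["ok"] = false, _["band_hit"] = true);
  const int W = d_hi - d_lo + 1;
  const int oe = gap_open + gap_extend, ext = gap_extend;

  std::vector<int> Mprev(W, NEG), Xprev(W, NEG), Yprev(W, NEG);
  std::vector<int> Mcur(W, NEG), Xcur(W, NEG), Ycur(W, NEG);
  // per-cell traceback byte: bits 0-1 M pred (0=M,1=X,2=Y); bit 2 X pred
  // (0=M,1=X); bit 3 Y pred (0=M,1=Y)
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 0);

  for (int w = 0; w < W; ++w) {           // row 0: free leading target gap
    int j = 0 + d_lo + w;
    if (j >= 0 && j <= n) Mprev[w] = 0;
  }

  for (int i = 1; i <= m; ++i) {
    std::fill(Mcur.begin(), Mcur.end(), NEG);
    std::fill(Xcur.begin(), Xcur.end(), NEG);
    std::fill(Ycur.begin(), Ycur.end(), NEG);
    uint8_t* tbrow = &tb[(size_t)i * W];
    const int bq = base2bit(query[i - 1]);
    const int jlo = std::max(0, i + d_lo), jhi = std::min(n, i + d_hi);
    for (int j = jlo; j <= jhi; ++j) {
      const int w = j - i - d_lo;
      uint8_t t = 0;
      if (j >= 1) {
        // M: diagonal predecessor (i-1, j-1) = same w, previous row
        const int bt = base2bit(target[j - 1]);
        const int s = (bq >= 0 && bq == bt) ? match : -mismatch;
        const int pm = Mprev[w], px = Xprev[w], py = Yprev[w];
        int best = pm; uint8_t code = 0;
        if (px > best) { best = px; code = 1; }
        if (py > best) { best = py; code = 2; }
        if (best > NEG) { Mcur[w] = best + s; t |= code; }
        // X (deletion, consumes target): (i, j-1) = w-1, same row
        if (w >= 1) {
          const int om = (Mcur[w - 1] > NEG) ? Mcur[w - 1] - oe : NEG;
          const int ox = (Xcur[w - 1] > NEG) ? Xcur[w - 1] - ext : NEG;
          if (om >= ox) { if (om > NEG) Xcur[w] = om; }
          else { Xcur[w] = ox; t |= 4; }
        }
      }
      // Y (insertion, consumes query): (i-1, j) = w+1, previous row
      if (w + 1 < W) {
        const int om = (Mprev[w + 1] > NEG) ? Mprev[w + 1] - oe : NEG;
        const int oy = (Yprev[w + 1] > NEG) ? Yprev[w + 1] - ext : NEG;
        if (om >= oy) { if (om > NEG) Ycur[w] = om; }
        else { Ycur[w] = oy; t |= 8; }
      }
      tbrow[w] = t;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  // end: max over last row, states M or Y (trailing target gap is free;
  // ending in a deletion is never optimal).  Prefer M on ties, then lower j.
  int best = NEG, bw = -1, bstate = 0;
  for (int w = 0; w < W; ++w) {
    int j = m + d_lo + w;
    if (j < 0 || j > n) continue;
    if (Mprev[w] > best) { best = Mprev[w]; bw = w; bstate = 0; }
    if (Yprev[w] > best) { best = Yprev[w]; bw = w; bstate = 2; }
  }
  if (bw < 0 || best <= NEG)
    return List::create(_["ok"] = false, _["band_hit"] = true);

  // traceback
  std::vector<OpRun> rops;
  bool band_hit = false;
  int i = m, w = bw, state = bstate;  // state: 0 M, 1 X, 2 Y
  int t1 = m + d_lo + bw;             // one past last aligned target column
  while (i > 0) {
    if (w == 0 || w == W - 1) band_hit = true;
    const uint8_t t = tb[(size_t)i * W + w];
    if (state == 0) {
      const int j = i + d_lo + w;
      const int bqq = base2bit(query[i - 1]), btt = base2bit(target[j - 1]);
      push_op(rops, (bqq >= 0 && bqq == btt) ? '=' : 'X');
      state = (int)(t & 3);  // 0 M, 1 X, 2 Y
      i -= 1;                // w unchanged (diagonal)
    } else if (state == 1) {
      push_op(rops, 'D');
      state = (t & 4) ? 1 : 0;
      w -= 1;
    } else {
      push_op(rops, 'I');
      state = (t & 8) ? 2 : 0;
      i -= 1; w += 1;
      if (w >= W) return List::create(_["ok"] = false, _["band_hit"] = true);
    }
  }
  int t0 = i + d_lo + w;  // i == 0

  // assemble forward ops; convert terminal I to query clipping, trim
  // terminal D into the free target gap
  std::vector<OpRun> ops(rops.rbegin(), rops.rend());
  int q0 = 0, q1 = m;
  while (!ops.empty()) {
    OpRun f = ops.front();
    if (f.op == 'I') { q0 += f.len; ops.erase(ops.begin()); }
    else if (f.op == 'D') { t0 += f.len; ops.erase(ops.begin()); }
    else break;
  }
  while (!ops.empty()) {
    OpRun b = ops.back();
    if (b.op == 'I') { q1 -= b.len; ops.pop_back(); }
    else if (b.op == 'D') { t1 -= b.len; ops.pop_back(); }
    else break;
  }
  if (ops.empty()) return List::create(_["ok"] = false, _["band_hit"] = band_hit);

  std::string cig;
  long nmatch = 0, nmis = 0, nins = 0, ndel = 0;
  char buf[16];
  for (auto& o : ops) {
    snprintf(buf, sizeof(buf), "%d%c", o.len, o.op);
    cig += buf;
    switch (o.op) {
      case '=': nmatch += o.len; break;
      case 'X': nmis += o.len; break;
      case 'I': nins += o.len; break;
      case 'D': ndel += o.len; break;
    }
  }
  return List::create(_["ok"] = true, _["score"] = best, _["cigar"] = cig,
                      _["q0"] = q0, _["q1"] = q1, _["t0"] = t0, _["t1"] = t1,
                      _["band_hit"] = band_hit,
                      _["nmatch"] = (double)nmatch, _["nmismatch"] = (double)nmis,
                      _["nins"] = (double)nins, _["ndel"] = (double)ndel);
}

// ---------------------------------------------------------------------------
// cigar utilities
// ---------------------------------------------------------------------------

static std::vector<OpRun> parse_cigar(const std::string& cig) {
  std::vector<OpRun> ops;
  int len = 0;
  for (char c : cig) {
    if (c >= '0' && c <= '9') { len = len * 10 + (c - '0'); }
    else {
      if (len <= 0) stop("malformed cigar");
      ops.push_back(OpRun{c, len});
      len = 0;
    }
  }
  if (len != 0) stop("malformed cigar");
  return ops;
}

// [[Rcpp::export]]
DataFrame cpp_cigar_ops(std::string cigar) {
  std::vector<OpRun> ops = parse_cigar(cigar);
  CharacterVector op(ops.size());
  IntegerVector len(ops.size());
  for (size_t i = 0; i < ops.size(); ++i) {
    op[i] = std::string(1, ops[i].op);
    len[i] = ops[i].len;
  }
  return DataFrame::create(_["op"] = op, _["len"] = len,
                           _["stringsAsFactors"] = false);
}

// Query interval [qs, qe) corresponding to target interval [ref_s, ref_e) of
// an alignment with target start t0 and query start q0.
// [[Rcpp::export]]
IntegerVector cpp_query_interval(std::string cigar, int t0, int q0,
                                 int ref_s, int ref_e) {
  std::vector<OpRun> ops = parse_cigar(cigar);
  long t = t0, q = q0;
  long qs = -1, qe = -1;
  for (auto& o : ops) {
    const bool ct = (o.op == '=' || o.op == 'X' || o.op == 'D');
    const bool cq = (o.op == '=' || o.op == 'X' || o.op == 'I');
    const long tnext = ct ? t + o.len : t;
    const long qnext = cq ? q + o.len : q;
    if (ct && tnext > ref_s && t < ref_e) {
      const long lo = std::max((long)ref_s, t), hi = std::min((long)ref_e, tnext);
      long q_lo = q, q_hi = q;
      if (cq) { q_lo = q + (lo - t); q_hi = q + (hi - t); }
      if (qs < 0) qs = q_lo;
      qe = q_hi;
    }
    t = tnext; q = qnext;
  }
  if (qs < 0) { qs = 0; qe = 0; }
  return IntegerVector::create((int)qs, (int)qe);
}

// ---------------------------------------------------------------------------
// Pileup polishing: majority vote over aligned reads.  Alignments target the
// draft (doubled draft when wrap = true; positions taken modulo ref_len).
// An insertion is emitted only when its most common inserted string occurs in
// at least half of the reads covering the junction.  Ties at a position keep
// the draft symbol when prefer_current, else take the lexicographically
// smallest symbol (bases before deletion).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
std::string cpp_pileup_polish(std::string draft, int ref_len, bool wrap,
                              IntegerVector t0s, IntegerVector q0s,
                              CharacterVector cigars, CharacterVector seqs,
                              int min_depth, bool prefer_current) {
  const int L = ref_len;
  if ((int)draft.size() < L) stop("draft shorter than ref_len");
  std::vector<int> cnt(5L * L, 0);   // A,C,G,T,del
  std::vector<int> cov(L, 0);
  std::map<int, std::map<std::string, int> > ins;

  const int nal = t0s.size();
  for (int a = 0; a < nal; ++a) {
    std::string cig = as<std::string>(cigars[a]);
    std::string seq = as<std::string>(seqs[a]);
    std::vector<OpRun> ops = parse_cigar(cig);
    long t = t0s[a], q = q0s[a];
    for (auto& o : ops) {
      if (o.op == '=' || o.op == 'X') {
        for (int x = 0; x < o.len; ++x) {
          int p = (int)(t + x); if (wrap) p %= L;
          if (p < 0 || p >= L) continue;
          cov[p]++;
          int b = base2bit(seq[q + x]);
          if (b >= 0) cnt[(size_t)p * 5 + b]++;
        }
        t += o.len; q += o.len;
      } else if (o.op == 'D') {
        for (int x = 0; x < o.len; ++x) {
          int p = (int)(t + x); if (wrap) p %= L;
          if (p < 0 || p >= L) continue;
          cov[p]++;
          cnt[(size_t)p * 5 + 4]++;
        }
        t += o.len;
      } else if (o.op == 'I') {
        int p = (int)t; if (wrap) p %= L;
        if (p >= 0 && p < L) ins[p][seq.substr(q, o.len)]++;
        q += o.len;
      } else stop("unexpected cigar op in pileup");
    }
  }

  std::string out;
  out.reserve(L + L / 10);
  static const char BASES[5] = {'A', 'C', 'G', 'T', '-'};
  for (int p = 0; p < L; ++p) {
    // insertion before position p
    auto ii = ins.find(p);
    if (ii != ins.end() && cov[p] >= min_depth && cov[p] > 0) {
      int bc = 0; std::string bs;
      for (auto& kv : ii->second) {
        if (kv.second > bc || (kv.second == bc && kv.first < bs)) {
          bc = kv.second; bs = kv.first;
        }
      }
      if (2 * bc >= cov[p]) out += bs;
    }
    const char dbase = draft[p];
    if (cov[p] < min_depth) { out += dbase; continue; }
    const int* c = &cnt[(size_t)p * 5];
    int best = -1, bi = 0;
    for (int b = 0; b < 5; ++b) if (c[b] > best) { best = c[b]; bi = b; }
    if (prefer_current) {
      const int db = base2bit(dbase);
      if (db >= 0 && c[db] == best) bi = db;
    }
    if (best <= 0) { out += dbase; continue; }  // covered but no votes (all N)
    if (bi < 4) out += BASES[bi];
    // bi == 4: deletion wins, emit nothing
  }
  return out;
}
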