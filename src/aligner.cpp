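#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Seeded read mapper used by the alignment layer: a sorted k-mer index over a
// set of reference sequences, an end-to-end (mismatch-only) verifier and a
// seeded local Smith-Waterman with affine gaps. Coordinates returned to R are
// 1-based; read coordinates of '-' strand hits are converted back to the
// as-sequenced orientation so that all alignments of one read share a frame.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static inline char comp_char(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp_char(s[i]);
  return r;
}

struct RefIndex {
  int k;
  std::string seq;                 // concatenated references
  std::vector<uint64_t> off;       // start of each reference in `seq`
  std::vector<uint64_t> len;
  std::vector<std::string> names;
  std::vector<uint64_t> keys;      // (kmer << 34) | global_pos, sorted
};

// [[Rcpp::export]]
SEXP sb_build_index(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 8 || k > 15) stop("k must be in [8, 15]");
  RefIndex* idx = new RefIndex();
  idx->k = k;
  size_t total = 0;
  for (int i = 0; i < seqs.size(); ++i) total += LENGTH(STRING_ELT(seqs, i));
  idx->seq.reserve(total);
  for (int i = 0; i < seqs.size(); ++i) {
    idx->off.push_back(idx->seq.size());
    std::string s = as<std::string>(seqs[i]);
    idx->len.push_back(s.size());
    idx->names.push_back(as<std::string>(names[i]));
    idx->seq += s;
  }
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  idx->keys.reserve(total);
  for (size_t r = 0; r < idx->off.size(); ++r) {
    uint64_t start = idx->off[r], n = idx->len[r];
    if ((int64_t)n < k) continue;
    uint64_t kmer = 0; int valid = 0;
    for (uint64_t p = 0; p < n; ++p) {
      int c = base_code(idx->seq[start + p]);
      if (c > 3) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        uint64_t pos = start + p - k + 1;
        idx->keys.push_back((kmer << 34) | pos);
      }
    }
  }
  std::sort(idx->keys.begin(), idx->keys.end());
  XPtr<RefIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List sb_index_info(SEXP idxp) {
  XPtr<RefIndex> idx(idxp);
  return List::create(_["k"] = idx->k,
                      _["names"] = wrap(idx->names),
                      _["lengths"] = wrap(idx->len),
                      _["n_kmers"] = (double)idx->keys.size());
}

static inline void lookup(const RefIndex& I, uint64_t kmer,
                          const uint64_t*& a, const uint64_t*& b) {
  uint64_t lo = kmer << 34, hi = (kmer + 1) << 34;
  a = std::lower_bound(I.keys.data(), I.keys.data() + I.keys.size(), lo);
  b = std::lower_bound(a, I.keys.data() + I.keys.size(), hi);
}

// encode k-mer of s at offset o; returns false if it contains a non-ACGT base
static inline bool encode_kmer(const std::string& s, size_t o, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[o + i]);
    if (c > 3) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

// reference id containing global position p (assumes p valid)
static inline size_t ref_of(const RefIndex& I, uint64_t p) {
  size_t lo = 0, hi = I.off.size();
  while (hi - lo > 1) {
    size_t mid = (lo + hi) / 2;
    if (I.off[mid] <= p) lo = mid; else hi = mid;
  }
  return lo;
}

struct E2EHit { uint64_t gs; int strand; int mm; };

// [[Rcpp::export]]
DataFrame sb_map_end_to_end(CharacterVector reads, SEXP idxp,
                            int max_mm, int max_hits, int seed_step) {
  XPtr<RefIndex> idx(idxp);
  const RefIndex& I = *idx;
  std::vector<int> o_read, o_ref, o_mm, o_nhits;
  std::vector<double> o_pos;
  std::vector<std::string> o_strand;
  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    int L = (int)fwd.size();
    if (L < I.k) continue;
    std::vector<E2EHit> hits;
    for (int strand = 0; strand < 2; ++strand) {
      std::string s = strand ? revcomp(fwd) : fwd;
      std::vector<int> offs;
      for (int o = 0; o <= L - I.k; o += seed_step) offs.push_back(o);
      if (offs.empty() || offs.back() != L - I.k) offs.push_back(L - I.k);
      std::vector<int64_t> cand;
      for (int o : offs) {
        uint64_t kmer;
        if (encode_kmer(s, o, I.k, kmer)) {
          const uint64_t *a, *b;
          lookup(I, kmer, a, b);
          for (const uint64_t* it = a; it != b; ++it) {
            int64_t gs = (int64_t)(*it & ((1ULL << 34) - 1)) - o;
            if (gs >= 0) cand.push_back(gs);
          }
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (int64_t gs : cand) {
        size_t r = ref_of(I, (uint64_t)gs);
        if ((uint64_t)gs + L > I.off[r] + I.len[r]) continue;
        int mm = 0;
        for (int i = 0; i < L && mm <= max_mm; ++i) {
          char a = s[i], b = I.seq[gs + i];
          int ca = base_code(a), cb = base_code(b);
          if (ca > 3 || cb > 3 || ca != cb) ++mm;
        }
        if (mm <= max_mm) hits.push_back({(uint64_t)gs, strand, mm});
      }
    }
    if (hits.empty()) continue;
    std::stable_sort(hits.begin(), hits.end(),
                     [](const E2EHit& a, const E2EHit& b) { return a.mm < b.mm; });
    int nh = (int)hits.size();
    int keep = std::min(nh, max_hits);
    for (int h = 0; h < keep; ++h) {
      size_t r = ref_of(I, hits[h].gs);
      o_read.push_back(ri + 1);
      o_ref.push_back((int)r + 1);
      o_pos.push_back((double)(hits[h].gs - I.off[r]) + 1.0);
      o_strand.push_back(hits[h].strand ? "-" : "+");
      o_mm.push_back(hits[h].mm);
      o_nhits.push_back(nh);
    }
  }
  return DataFrame::create(_["read"] = o_read, _["ref"] = o_ref, _["pos"] = o_pos,
                           _["strand"] = o_strand, _["mm"] = o_mm,
                           _["nhits"] = o_nhits, _["stringsAsFactors"] = false);
}

struct SWRes { int score, qstart, qlen, rstart, rlen, nm, gaps;
  std::vector<int> mmq; };

// Alignment columns for end trimming: 0 = match, 1 = mismatch, 2 = gap in
// query (consumes ref), 3 = gap in ref (consumes query).
// Local alignments may over-extend past a true junction when a mismatch is
// recouped by chance matches; requiring the terminal `clean` columns to be
// exact matches (trimming otherwise) keeps alignment ends at clean
// boundaries so read-coordinate overlaps reflect genuine microhomology.
static void trim_path(std::vector<uint8_t>& path, int clean,
                      int& drop_front, int& drop_back) {
  drop_front = drop_back = 0;
  if (clean <= 0) return;
  int lo = 0, hi = (int)path.size();  // active range [lo, hi)
  bool changed = true;
  while (changed && hi > lo) {
    changed = false;
    for (int i = lo; i < std::min(lo + clean, hi); ++i)
      if (path[i] != 0) { lo = i + 1; changed = true; break; }
    for (int i = hi - 1; i >= std::max(hi - clean, lo); --i)
      if (path[i] != 0) { hi = i; changed = true; break; }
  }
  drop_front = lo;
  drop_back = (int)path.size() - hi;
}

// local Smith-Waterman with affine gaps (gap of length g costs open + g*ext)
static SWRes sw_local(const std::string& q, const std::string& r,
                      int ma, int mi, int go, int ge, int clean_end = 6) {
  int n = (int)q.size(), m = (int)r.size();
  SWRes res = {0, 0, 0, 0, 0, 0};
  if (n == 0 || m == 0) return res;
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), F(m + 1, INT32_MIN / 2);
  // traceback: 0 stop, 1 diag, 2 from E (left), 3 from F (up)
  std::vector<uint8_t> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tbE((size_t)(n + 1) * (m + 1), 0); // 1 = opened here
  std::vector<uint8_t> tbF((size_t)(n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int E = INT32_MIN / 2;
    Hcur[0] = 0;
    int cq = base_code(q[i - 1]);
    for (int j = 1; j <= m; ++j) {
      size_t at = (size_t)i * (m + 1) + j;
      int eopen = Hcur[j - 1] + go + ge, eext = E + ge;
      if (eopen >= eext) { E = eopen; tbE[at] = 1; } else { E = eext; tbE[at] = 0; }
      int fopen = Hprev[j] + go + ge, fext = F[j] + ge;
      if (fopen >= fext) { F[j] = fopen; tbF[at] = 1; } else { F[j] = fext; tbF[at] = 0; }
      int cr = base_code(r[j - 1]);
      int sub = (cq <= 3 && cq == cr) ? ma : mi;
      int diag = Hprev[j - 1] + sub;
      int h = 0; uint8_t tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E > h) { h = E; tb = 2; }
      if (F[j] > h) { h = F[j]; tb = 3; }
      Hcur[j] = h; tbH[at] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  if (best <= 0) return res;
  // traceback, recording alignment columns end-to-start
  int i = bi, j = bj, state = 0; // 0 = in H
  std::vector<uint8_t> path;
  while (i > 0 && j > 0) {
    size_t at = (size_t)i * (m + 1) + j;
    if (state == 0) {
      uint8_t tb = tbH[at];
      if (tb == 0) break;
      if (tb == 1) {
        int cq = base_code(q[i - 1]), cr = base_code(r[j - 1]);
        path.push_back((cq <= 3 && cq == cr) ? 0 : 1);
        --i; --j;
      } else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // E: gap consuming reference
      path.push_back(2); if (tbE[at]) state = 0;
      --j;
    } else { // F: gap consuming query
      path.push_back(3); if (tbF[at]) state = 0;
      --i;
    }
  }
  std::reverse(path.begin(), path.end());
  int df, dbk;
  trim_path(path, clean_end, df, dbk);
  int n_cols = (int)path.size();
  int qs = i, rs = j;
  for (int t = 0; t < df; ++t) { if (path[t] != 2) ++qs; if (path[t] != 3) ++rs; }
  int qe = qs, re = rs, score = 0, nm = 0, gaps = 0;
  uint8_t prev = 0;
  for (int t = df; t < n_cols - dbk; ++t) {
    uint8_t c = path[t];
    if (c == 0) score += ma;
    else if (c == 1) { score += mi; ++nm; res.mmq.push_back(qe); }
    else { score += (c == prev) ? ge : go + ge; ++nm; ++gaps; }
    if (c != 2) ++qe;
    if (c != 3) ++re;
    prev = c;
  }
  if (score <= 0 || qe == qs) { res.mmq.clear(); return res; }
  res.score = score;
  res.qstart = qs; res.qlen = qe - qs;
  res.rstart = rs; res.rlen = re - rs;
  res.nm = nm; res.gaps = gaps;
  return res;
}

struct LocalHit { size_t ref; uint64_t pos; int q; int qlen; int rlen; int strand; int score; int nm; int gaps; std::string mmq; };

// [[Rcpp::export]]
DataFrame sb_map_local(CharacterVector reads, SEXP idxp,
                       int match, int mismatch, int gap_open, int gap_extend,
                       int min_score, int max_hits, int seed_step) {
  XPtr<RefIndex> idx(idxp);
  const RefIndex& I = *idx;
  const int pad = 12, band = 16;
  std::vector<int> o_read, o_q, o_qlen, o_rlen, o_score, o_nm, o_gaps, o_ref;
  std::vector<double> o_pos;
  std::vector<std::string> o_strand, o_mmq;
  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    int L = (int)fwd.size();
    if (L < I.k) continue;
    std::vector<LocalHit> hits;
    for (int strand = 0; strand < 2; ++strand) {
      std::string s = strand ? revcomp(fwd) : fwd;
      std::vector<int> offs;
      for (int o = 0; o <= L - I.k; o += seed_step) offs.push_back(o);
      if (offs.empty() || offs.back() != L - I.k) offs.push_back(L - I.k);
      std::vector<int64_t> diags;
      for (int o : offs) {
        uint64_t kmer;
        if (encode_kmer(s, o, I.k, kmer)) {
          const uint64_t *a, *b;
          lookup(I, kmer, a, b);
          if (b - a <= 64) // skip hyper-repetitive seeds
            for (const uint64_t* it = a; it != b; ++it)
              diags.push_back((int64_t)(*it & ((1ULL << 34) - 1)) - o);
        }
      }
      if (diags.empty()) continue;
      std::sort(diags.begin(), diags.end());
      size_t gstart = 0;
      for (size_t gi = 1; gi <= diags.size(); ++gi) {
        if (gi == diags.size() || diags[gi] - diags[gi - 1] > band) {
          int64_t dmin = diags[gstart], dmax = diags[gi - 1];
          gstart = gi;
          int64_t center = (dmin + dmax) / 2 + L / 2;
          if (center < 0) center = 0;
          if (center >= (int64_t)I.seq.size()) center = I.seq.size() - 1;
          size_t r = ref_of(I, (uint64_t)center);
          int64_t ws = dmin - pad, we = dmax + L + pad;
          if (ws < (int64_t)I.off[r]) ws = I.off[r];
          if (we > (int64_t)(I.off[r] + I.len[r])) we = I.off[r] + I.len[r];
          if (we - ws < I.k) continue;
          std::string win = I.seq.substr(ws, we - ws);
          SWRes sw = sw_local(s, win, match, mismatch, gap_open, gap_extend);
          if (sw.score <= min_score) continue;
          int q1; // 1-based start in as-sequenced orientation
          if (strand == 0) q1 = sw.qstart + 1;
          else q1 = L - (sw.qstart + sw.qlen) + 1;
          // mismatch positions in as-sequenced read coordinates
          std::string mmq;
          for (size_t z = 0; z < sw.mmq.size(); ++z) {
            int c = strand == 0 ? sw.mmq[z] + 1 : L - sw.mmq[z];
            if (!mmq.empty()) mmq += ",";
            mmq += std::to_string(c);
          }
          hits.push_back({r, (uint64_t)ws + sw.rstart - I.off[r], q1, sw.qlen,
                          sw.rlen, strand, sw.score, sw.nm, sw.gaps, mmq});
        }
      }
    }
    if (hits.empty()) continue;
    std::sort(hits.begin(), hits.end(), [](const LocalHit& a, const LocalHit& b) {
      if (a.score != b.score) return a.score > b.score;
      if (a.ref != b.ref) return a.ref < b.ref;
      if (a.pos != b.pos) return a.pos < b.pos;
      return a.q < b.q;
    });
    // dedupe identical placements
    hits.erase(std::unique(hits.begin(), hits.end(), [](const LocalHit& a, const LocalHit& b) {
      return a.ref == b.ref && a.pos == b.pos && a.q == b.q && a.strand == b.strand;
    }), hits.end());
    int keep = std::min((int)hits.size(), max_hits);
    for (int h = 0; h < keep; ++h) {
      o_read.push_back(ri + 1);
      o_ref.push_back((int)hits[h].ref + 1);
      o_pos.push_back((double)hits[h].pos + 1.0);
      o_q.push_back(hits[h].q);
      o_qlen.push_back(hits[h].qlen);
      o_rlen.push_back(hits[h].rlen);
      o_strand.push_back(hits[h].strand ? "-" : "+");
      o_score.push_back(hits[h].score);
      o_nm.push_back(hits[h].nm);
      o_gaps.push_back(hits[h].gaps);
      o_mmq.push_back(hits[h].mmq);
    }
  }
  return DataFrame::create(_["read"] = o_read, _["ref"] = o_ref, _["pos"] = o_pos,
                           _["q"] = o_q, _["qlen"] = o_qlen, _["rlen"] = o_rlen,
                           _["strand"] = o_strand, _["score"] = o_score,
                           _["nm"] = o_nm, _["gaps"] = o_gaps,
                           _["mmq"] = o_mmq, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List sb_sw_align(std::string query, std::string ref,
                 int match, int mismatch, int gap_open, int gap_extend) {
  SWRes sw = sw_local(query, ref, match, mismatch, gap_open, gap_extend);
  return List::create(_["score"] = sw.score,
                      _["qstart"] = sw.qstart + 1, _["qlen"] = sw.qlen,
                      _["rstart"] = sw.rstart + 1, _["rlen"] = sw.rlen,
                      _["nm"] = sw.nm);
}
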