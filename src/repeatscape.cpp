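// Core sequence kernels: local alignment, k-mer candidate prefilter,
// batch pair alignment for the read-similarity graph, best-hit search
// against small target libraries, and a seed-and-extend read mapper.
//
// Conventions: bases outside A/C/G/T (e.g. N) never match anything,
// including themselves.  All coordinates returned to R are 0-based
// half-open on the forward strand of the respective sequence.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4; // N or anything else: never matches
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

static std::vector<int> revcomp_codes(const std::vector<int>& v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int c = v[v.size() - 1 - i];
    r[i] = (c < 4) ? 3 - c : 4;
  }
  return r;
}

struct AlnResult {
  int score = 0;
  int matches = 0;
  int columns = 0;
  int a0 = 0, a1 = 0; // query span, 0-based half-open
  int b0 = 0, b1 = 0; // target span
};

// Smith-Waterman, linear gap penalty, full traceback.
static AlnResult sw_align(const std::vector<int>& a, const std::vector<int>& b,
                          int match, int mismatch, int gap) {
  const int n = (int)a.size(), m = (int)b.size();
  AlnResult res;
  if (n == 0 || m == 0) return res;
  // H is (n+1) x (m+1); traceback codes: 0 stop, 1 diag, 2 up (gap in b), 3 left
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  const int* bpc = b.data();
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    int srow[5] = {mismatch, mismatch, mismatch, mismatch, mismatch};
    if (ai < 4) srow[ai] = match;
    int* cu = cur.data();
    const int* pr = prev.data();
    cu[0] = 0;
    uint8_t* tbrow = &tb[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      int diag = pr[j - 1] + srow[bpc[j - 1]];
      int up = pr[j] + gap;
      int left = cu[j - 1] + gap;
      int h = diag; uint8_t t = 1;
      if (up > h) { h = up; t = 2; }
      if (left > h) { h = left; t = 3; }
      if (h <= 0) { h = 0; t = 0; }
      cu[j] = h; tbrow[j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  if (best == 0) return res;
  // traceback
  int i = bi, j = bj, matches = 0, columns = 0;
  while (i > 0 && j > 0) {
    uint8_t t = tb[(size_t)i * (m + 1) + j];
    if (t == 0) break;
    if (t == 1) {
      ++columns;
      if (a[i - 1] < 4 && a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (t == 2) { ++columns; --i; }
    else { ++columns; --j; }
  }
  res.score = best; res.matches = matches; res.columns = columns;
  res.a0 = i; res.a1 = bi; res.b0 = j; res.b1 = bj;
  return res;
}

// Score-only Smith-Waterman (no traceback): used as a cheap first pass in
// batch mode.  A qualifying edge (identity >= t, columns >= c0) has score
// >= (3t - 2) * c0 under +1/-1/-2 scoring, so pairs below that bound can
// be rejected without a traceback.
static int sw_score(const std::vector<int>& a, const std::vector<int>& b,
                    int match, int mismatch, int gap) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  const int* bp = b.data();
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    // branchless substitution scores: srow[x] = match iff x == ai (and
    // both are real bases)
    int srow[5] = {mismatch, mismatch, mismatch, mismatch, mismatch};
    if (ai < 4) srow[ai] = match;
    int* cu = cur.data();
    const int* pr = prev.data();
    cu[0] = 0;
    int rowbest = 0;
    for (int j = 1; j <= m; ++j) {
      int h = pr[j - 1] + srow[bp[j - 1]];
      h = std::max(h, pr[j] + gap);
      h = std::max(h, cu[j - 1] + gap);
      h = std::max(h, 0);
      cu[j] = h;
      rowbest = std::max(rowbest, h);
    }
    best = std::max(best, rowbest);
    std::swap(prev, cur);
  }
  return best;
}

// [[Rcpp::export(name = ".rs_sw_align")]]
List rs_sw_align(std::string a, std::string b,
                 int match, int mismatch, int gap, bool try_revcomp) {
  std::vector<int> ca = encode(a), cb = encode(b);
  AlnResult fwd = sw_align(ca, cb, match, mismatch, gap);
  int strand = 1;
  AlnResult best = fwd;
  if (try_revcomp) {
    std::vector<int> ra = revcomp_codes(ca);
    AlnResult rev = sw_align(ra, cb, match, mismatch, gap);
    if (rev.score > fwd.score) {
      // map query span back to forward-strand coordinates
      int L = (int)ca.size();
      int q0 = L - rev.a1, q1 = L - rev.a0;
      rev.a0 = q0; rev.a1 = q1;
      best = rev; strand = -1;
    }
  }
  return List::create(
    _["score"] = best.score, _["matches"] = best.matches,
    _["columns"] = best.columns,
    _["a_start"] = best.a0, _["a_end"] = best.a1,
    _["b_start"] = best.b0, _["b_end"] = best.b1,
    _["strand"] = strand);
}

// k-mer candidate pair generation with canonical (strand-collapsed) k-mers.
// Returns a 2-column matrix of 1-based read indices (i < j).
// [[Rcpp::export(name = ".rs_candidate_pairs")]]
IntegerMatrix rs_candidate_pairs(CharacterVector seqs, int k, int min_shared) {
  const int n = seqs.size();
  if (k < 1 || k > 31) stop("kmer_len must be in 1..31");
  std::unordered_map<uint64_t, std::vector<int>> buckets;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::vector<std::vector<uint64_t>> read_kmers(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    std::vector<int> c = encode(s);
    if ((int)c.size() < k) continue;
    uint64_t f = 0, rc = 0;
    int valid = 0;
    std::vector<uint64_t> mine;
    for (size_t i = 0; i < c.size(); ++i) {
      if (c[i] >= 4) { valid = 0; f = 0; rc = 0; continue; }
      f = ((f << 2) | (uint64_t)c[i]) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - c[i]) << (2 * (k - 1)));
      if (++valid >= k) mine.push_back(f < rc ? f : rc);
    }
    std::sort(mine.begin(), mine.end());
    mine.erase(std::unique(mine.begin(), mine.end()), mine.end());
    read_kmers[r] = std::move(mine);
    for (uint64_t km : read_kmers[r]) buckets[km].push_back(r);
  }
  std::vector<int> cnt(n, 0), touched;
  std::vector<int> out_i, out_j;
  for (int r = 0; r < n; ++r) {
    touched.clear();
    for (uint64_t km : read_kmers[r]) {
      const std::vector<int>& b = buckets[km];
      for (int j : b) {
        if (j <= r) continue;
        if (cnt[j] == 0) touched.push_back(j);
        ++cnt[j];
      }
    }
    for (int j : touched) {
      if (cnt[j] >= min_shared) { out_i.push_back(r + 1); out_j.push_back(j + 1); }
      cnt[j] = 0;
    }
  }
  IntegerMatrix out(out_i.size(), 2);
  for (size_t q = 0; q < out_i.size(); ++q) { out(q, 0) = out_i[q]; out(q, 1) = out_j[q]; }
  return out;
}

// Batch pair alignment: align seqs[ia] vs seqs[ib] (1-based index vectors),
// both orientations, and return rows for pairs meeting the identity and
// overlap-columns thresholds.  overlap threshold is precomputed per pair in R
// as min_overlap_fraction * min(len).
// [[Rcpp::export(name = ".rs_align_pairs_batch")]]
DataFrame rs_align_pairs_batch(CharacterVector seqs, IntegerVector ia,
                               IntegerVector ib, double min_identity,
                               double min_overlap_fraction,
                               int match, int mismatch, int gap) {
  const int n = seqs.size();
  std::vector<std::vector<int>> fw(n), rv(n);
  std::vector<int> lens(n);
  for (int i = 0; i < n; ++i) {
    fw[i] = encode(as<std::string>(seqs[i]));
    rv[i] = revcomp_codes(fw[i]);
    lens[i] = (int)fw[i].size();
  }
  std::vector<int> oi, oj;
  std::vector<double> oident, ofrac;
  // minimum possible score of a qualifying alignment: each of its >= c0
  // columns is a match (+1) or a non-match costing at least 1, and at
  // most (1 - t) of them are non-matches
  const double score_slope = 3.0 * min_identity - 2.0;
  for (int q = 0; q < ia.size(); ++q) {
    int i = ia[q] - 1, j = ib[q] - 1;
    int shorter = std::min(lens[i], lens[j]);
    if (shorter == 0) continue;
    int fs = sw_score(fw[i], fw[j], match, mismatch, gap);
    int rs = sw_score(rv[i], fw[j], match, mismatch, gap);
    if (score_slope > 0) {
      int bound = (int)std::floor(score_slope * min_overlap_fraction * shorter);
      if (fs < bound && rs < bound) continue;
    }
    AlnResult b = (rs > fs) ? sw_align(rv[i], fw[j], match, mismatch, gap)
                            : sw_align(fw[i], fw[j], match, mismatch, gap);
    if (b.columns == 0) continue;
    double ident = (double)b.matches / (double)b.columns;
    double frac = (double)b.columns / (double)shorter;
    if (frac > 1.0) frac = 1.0;
    if (ident >= min_identity && (double)b.columns >= min_overlap_fraction * shorter) {
      oi.push_back(ia[q]); oj.push_back(ib[q]);
      oident.push_back(ident); ofrac.push_back(frac);
    }
  }
  return DataFrame::create(_["i"] = oi, _["j"] = oj,
                           _["identity"] = oident,
                           _["overlap_fraction"] = ofrac);
}

// Best local alignment of each query against a set of targets, both strands.
// Only alignments with identity >= min_identity and columns >= min_cols
// compete; per query the highest-scoring qualifying hit is reported
// (target = 0 if none qualifies).  Query coordinates are forward-strand.
// [[Rcpp::export(name = ".rs_best_hits")]]
DataFrame rs_best_hits(CharacterVector queries, CharacterVector targets,
                       double min_identity, int min_cols,
                       int match, int mismatch, int gap) {
  const int nq = queries.size(), nt = targets.size();
  std::vector<std::vector<int>> tg(nt);
  for (int t = 0; t < nt; ++t) tg[t] = encode(as<std::string>(targets[t]));
  IntegerVector target(nq), score(nq), columns(nq), q0(nq), q1(nq), t0(nq), t1(nq), strand(nq);
  NumericVector identity(nq), nmatches(nq);
  // a qualifying alignment scores at least this much (see batch aligner)
  const double slope = 3.0 * min_identity - 2.0;
  const int bound = (slope > 0) ? (int)std::floor(slope * min_cols) : 0;
  for (int q = 0; q < nq; ++q) {
    std::vector<int> qf = encode(as<std::string>(queries[q]));
    std::vector<int> qr = revcomp_codes(qf);
    int L = (int)qf.size();
    // score-only pass over all (target, strand), then traceback in score
    // order until a qualifying alignment is found: that alignment is the
    // best-scoring qualifying one.
    std::vector<std::tuple<int, int, int>> cand; // (-score, target, strand)
    for (int t = 0; t < nt; ++t) {
      for (int s = 0; s < 2; ++s) {
        int sc = sw_score(s == 0 ? qf : qr, tg[t], match, mismatch, gap);
        if (sc >= bound && sc > 0) cand.emplace_back(-sc, t, s);
      }
    }
    std::sort(cand.begin(), cand.end());
    int b_target = 0, b_score = 0, b_cols = 0, b_q0 = 0, b_q1 = 0, b_t0 = 0, b_t1 = 0, b_strand = 1, b_m = 0;
    double b_id = 0.0;
    for (auto& c : cand) {
      int t = std::get<1>(c), s = std::get<2>(c);
      AlnResult a = sw_align(s == 0 ? qf : qr, tg[t], match, mismatch, gap);
      if (a.columns < min_cols || a.columns == 0) continue;
      double ident = (double)a.matches / (double)a.columns;
      if (ident < min_identity) continue;
      b_score = a.score; b_cols = a.columns; b_id = ident; b_m = a.matches;
      b_target = t + 1; b_strand = (s == 0) ? 1 : -1;
      if (s == 0) { b_q0 = a.a0; b_q1 = a.a1; }
      else { b_q0 = L - a.a1; b_q1 = L - a.a0; }
      b_t0 = a.b0; b_t1 = a.b1;
      break;
    }
    target[q] = b_target; score[q] = b_score;
    identity[q] = b_id; columns[q] = b_cols; nmatches[q] = b_m;
    q0[q] = b_q0; q1[q] = b_q1; t0[q] = b_t0; t1[q] = b_t1;
    strand[q] = b_strand;
  }
  return DataFrame::create(_["target"] = target, _["score"] = score,
                           _["identity"] = identity, _["matches"] = nmatches,
                           _["columns"] = columns,
                           _["q_start"] = q0, _["q_end"] = q1,
                           _["t_start"] = t0, _["t_end"] = t1,
                           _["strand"] = strand);
}

// ---- seed-and-extend read mapper -----------------------------------------

// Banded global alignment of a full read against target starting near
// anchor position, affine-style gap costs, returns penalty and edit counts.
struct ExtResult {
  bool ok = false;
  int penalty = 0, nm = 0, go = 0, ge = 0;
};

static ExtResult extend_read(const std::vector<int>& read,
                             const std::vector<int>& tgt, int anchor,
                             int band, int mism_pen, int go_pen, int ge_pen,
                             int max_edit, int max_go, int max_ge) {
  // read position i aligns near target position anchor + i; band on offset.
  const int L = (int)read.size();
  const int W = 2 * band + 1;
  const int INF = 1 << 28;
  // last move: 0 = diagonal, 1 = gap consuming a read base, 2 = gap
  // consuming a target base; first base of a gap run pays go_pen, the
  // rest pay ge_pen.
  struct Cell { int pen, nm, go, ge; uint8_t last; };
  const Cell DEAD = {INF, 0, 0, 0, 0};
  std::vector<Cell> prev(W, DEAD), cur(W, DEAD);
  prev[band] = {0, 0, 0, 0, 0};
  // allow the alignment to start with extra target bases (gap in read)
  for (int w = band + 1; w < W; ++w) {
    int g = w - band;
    prev[w] = {go_pen + (g - 1) * ge_pen, 0, 1, g - 1, 2};
  }
  for (int i = 1; i <= L; ++i) {
    for (int w = 0; w < W; ++w) cur[w] = DEAD;
    for (int w = 0; w < W; ++w) {
      int j = anchor + (i - 1) + (w - band); // target index aligned to read[i-1]
      // diagonal: consume read[i-1] and target[j]
      if (prev[w].pen < INF && j >= 0 && j < (int)tgt.size()) {
        bool m = (read[i - 1] < 4) && (read[i - 1] == tgt[j]);
        int p = prev[w].pen + (m ? 0 : mism_pen);
        if (p < cur[w].pen) {
          cur[w] = prev[w];
          cur[w].pen = p; cur[w].last = 0;
          if (!m) cur[w].nm++;
        }
      }
      // gap consuming a read base: offset decreases by 1
      if (w + 1 < W && prev[w + 1].pen < INF) {
        bool ext = (prev[w + 1].last == 1);
        int p = prev[w + 1].pen + (ext ? ge_pen : go_pen);
        if (p < cur[w].pen) {
          cur[w] = prev[w + 1];
          cur[w].pen = p; cur[w].last = 1;
          if (ext) cur[w].ge++; else cur[w].go++;
        }
      }
      // gap consuming a target base: offset increases by 1, same i
      if (w - 1 >= 0 && cur[w - 1].pen < INF) {
        bool ext = (cur[w - 1].last == 2);
        int p = cur[w - 1].pen + (ext ? ge_pen : go_pen);
        if (p < cur[w].pen) {
          cur[w] = cur[w - 1];
          cur[w].pen = p; cur[w].last = 2;
          if (ext) cur[w].ge++; else cur[w].go++;
        }
      }
    }
    std::swap(prev, cur);
  }
  ExtResult res;
  int bw = -1, bp = INF;
  for (int w = 0; w < W; ++w) if (prev[w].pen < bp) { bp = prev[w].pen; bw = w; }
  if (bw < 0 || bp >= INF) return res;
  const Cell& c = prev[bw];
  int gapbases = c.go + c.ge;
  if (c.nm + gapbases > max_edit) return res;
  if (c.go > max_go || c.ge > max_ge) return res;
  res.ok = true; res.penalty = c.pen; res.nm = c.nm; res.go = c.go; res.ge = c.ge;
  return res;
}

static uint64_t pack_kmer(const std::vector<int>& c, int pos, int k, bool* ok) {
  uint64_t f = 0;
  for (int i = 0; i < k; ++i) {
    if (c[pos + i] >= 4) { *ok = false; return 0; }
    f = (f << 2) | (uint64_t)c[pos + i];
  }
  *ok = true;
  return f;
}

// Map each read against targets with a seeded, banded extension honoring
// BWA-aln-style limits.  Returns, per read, all hits achieving the minimum
// penalty (possibly several rows), or no row if unmapped.
// [[Rcpp::export(name = ".rs_map_reads")]]
DataFrame rs_map_reads(CharacterVector reads, CharacterVector targets,
                       int seed_len, int seed_max_mismatch, int max_edit,
                       int max_gap_open, int max_gap_ext,
                       int mismatch_penalty, int gap_open_penalty,
                       int gap_ext_penalty) {
  const int nt = targets.size();
  std::vector<std::vector<int>> tg(nt);
  std::unordered_multimap<uint64_t, std::pair<int, int>> index; // kmer -> (target, pos)
  for (int t = 0; t < nt; ++t) {
    tg[t] = encode(as<std::string>(targets[t]));
    const std::vector<int>& c = tg[t];
    for (int p = 0; p + seed_len <= (int)c.size(); ++p) {
      bool ok; uint64_t km = pack_kmer(c, p, seed_len, &ok);
      if (ok) index.emplace(km, std::make_pair(t, p));
    }
  }
  std::vector<int> out_read, out_target, out_penalty, out_edits, out_strand;
  const int band = max_gap_open > max_gap_ext ? max_gap_open + 1 : max_gap_ext + 1;
  for (int r = 0; r < reads.size(); ++r) {
    std::vector<int> rf = encode(as<std::string>(reads[r]));
    if ((int)rf.size() < seed_len) continue;
    std::vector<int> rr = revcomp_codes(rf);
    int best_pen = 1 << 28;
    std::vector<std::tuple<int, int, int, int>> hits; // target, penalty, edits, strand
    for (int s = 0; s < 2; ++s) {
      const std::vector<int>& rd = (s == 0) ? rf : rr;
      bool ok; uint64_t seed0 = pack_kmer(rd, 0, seed_len, &ok);
      if (!ok) continue;
      // enumerate seed variants with <= seed_max_mismatch substitutions
      std::vector<uint64_t> variants;
      variants.push_back(seed0);
      if (seed_max_mismatch >= 1) {
        for (int p1 = 0; p1 < seed_len; ++p1) {
          int sh1 = 2 * (seed_len - 1 - p1);
          uint64_t orig1 = (seed0 >> sh1) & 3ULL;
          for (uint64_t b1 = 0; b1 < 4; ++b1) {
            if (b1 == orig1) continue;
            uint64_t v1 = (seed0 & ~(3ULL << sh1)) | (b1 << sh1);
            variants.push_back(v1);
            if (seed_max_mismatch >= 2) {
              for (int p2 = p1 + 1; p2 < seed_len; ++p2) {
                int sh2 = 2 * (seed_len - 1 - p2);
                uint64_t orig2 = (v1 >> sh2) & 3ULL;
                for (uint64_t b2 = 0; b2 < 4; ++b2) {
                  if (b2 == orig2) continue;
                  variants.push_back((v1 & ~(3ULL << sh2)) | (b2 << sh2));
                }
              }
            }
          }
        }
      }
      // candidate anchor positions, deduplicated
      std::vector<std::pair<int, int>> anchors;
      for (uint64_t v : variants) {
        auto range = index.equal_range(v);
        for (auto it = range.first; it != range.second; ++it)
          anchors.push_back(it->second);
      }
      std::sort(anchors.begin(), anchors.end());
      anchors.erase(std::unique(anchors.begin(), anchors.end()), anchors.end());
      for (auto& a : anchors) {
        ExtResult e = extend_read(rd, tg[a.first], a.second, band,
                                  mismatch_penalty, gap_open_penalty,
                                  gap_ext_penalty, max_edit, max_gap_open,
                                  max_gap_ext);
        if (!e.ok) continue;
        if (e.penalty < best_pen) {
          best_pen = e.penalty;
          hits.clear();
        }
        if (e.penalty == best_pen) {
          hits.emplace_back(a.first + 1, e.penalty, e.nm + e.go + e.ge,
                            s == 0 ? 1 : -1);
        }
      }
    }
    // deduplicate hits on same target (keep one row per target+strand)
    std::sort(hits.begin(), hits.end());
    hits.erase(std::unique(hits.begin(), hits.end()), hits.end());
    for (auto& h : hits) {
      out_read.push_back(r + 1);
      out_target.push_back(std::get<0>(h));
      out_penalty.push_back(std::get<1>(h));
      out_edits.push_back(std::get<2>(h));
      out_strand.push_back(std::get<3>(h));
    }
  }
  return DataFrame::create(_["read"] = out_read, _["target"] = out_target,
                           _["penalty"] = out_penalty, _["edits"] = out_edits,
                           _["strand"] = out_strand);
}
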