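// Seed-and-extend local realignment of short-read mates against a small
// reference genome, plus an exhaustive Smith-Waterman scanner. The two code
// paths are intentionally independent: cpp_realign() uses a sorted k-mer
// index with windowed affine-gap alignment, cpp_sw_scan() runs the full DP
// over an entire subject and is used as a brute-force reference in tests.
//
// Scoring (shared contract): match +1, mismatch -2; a gap of length L costs
// gap_open + (L-1) * gap_extend with defaults 2 and 1.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static const int SCORE_MATCH = 1;
static const int SCORE_MISMATCH = -2;
static const int GAP_OPEN = 2;   // cost of the first gap base
static const int GAP_EXTEND = 1; // cost of each further gap base

// ---------------------------------------------------------------------------
// Local alignment with payload propagation (no traceback matrices): each DP
// cell carries the origin and the match/aligned-base counts of the best path
// reaching it, so the winning local alignment is fully described at its
// maximum cell.
// ---------------------------------------------------------------------------

struct Cell {
  int score;
  int qs, ss;    // 0-based origin (query, subject)
  int mat;       // matching columns
  int qal;       // query bases in M columns (matches + mismatches)
  int cols;      // total alignment columns
};

struct Aln {
  int score = 0;
  int qstart = 0, qend = 0; // half-open on query
  int sstart = 0, send = 0; // half-open on subject
  int matches = 0, aligned = 0, cols = 0;
};

static inline int base_score(char a, char b) {
  if (a == 'N' || b == 'N') return SCORE_MISMATCH;
  return (a == b) ? SCORE_MATCH : SCORE_MISMATCH;
}

// Smith-Waterman of query q against subject s[0..slen); returns best local hit.
static Aln sw_best(const std::string& q, const char* s, int slen) {
  const int m = (int)q.size();
  std::vector<Cell> H(m + 1), Hprev(m + 1), E(m + 1);
  Cell zero{0, -1, -1, 0, 0, 0};
  std::fill(Hprev.begin(), Hprev.end(), zero);
  Aln best;
  for (int j = 1; j <= slen; ++j) {
    std::fill(E.begin(), E.end(), zero);
    H[0] = zero;
    Cell Fcol = zero; // gap in subject, runs down the column
    for (int i = 1; i <= m; ++i) {
      // E: gap in query (consume subject base j)
      Cell e1 = Hprev[i]; e1.score -= GAP_OPEN; e1.cols += 1;
      Cell e2 = E[i];     e2.score -= GAP_EXTEND; e2.cols += 1;
      E[i] = (e1.score >= e2.score) ? e1 : e2;
      // F: gap in subject (consume query base i)
      Cell f1 = H[i - 1]; f1.score -= GAP_OPEN; f1.cols += 1;
      Cell f2 = Fcol;     f2.score -= GAP_EXTEND; f2.cols += 1;
      Fcol = (f1.score >= f2.score) ? f1 : f2;
      // diagonal
      Cell d = Hprev[i - 1];
      if (d.score <= 0) { d = zero; d.qs = i - 1; d.ss = j - 1; }
      int sc = base_score(q[i - 1], s[j - 1]);
      d.score += sc; d.cols += 1; d.qal += 1;
      if (sc > 0) d.mat += 1;
      Cell bestc = d;
      if (E[i].score > bestc.score) bestc = E[i];
      if (Fcol.score > bestc.score) bestc = Fcol;
      if (bestc.score <= 0) { bestc = zero; }
      H[i] = bestc;
      if (bestc.score > best.score) {
        best.score = bestc.score;
        best.qstart = bestc.qs; best.qend = i;
        best.sstart = bestc.ss; best.send = j;
        best.matches = bestc.mat; best.aligned = bestc.qal;
        best.cols = bestc.cols;
      }
    }
    std::swap(H, Hprev);
  }
  return best;
}

// ---------------------------------------------------------------------------
// Exhaustive scan: repeatedly take the best local alignment and mask it out,
// until the score drops below keep_fraction * first_best or max_hits reached.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_sw_scan(std::string query, std::string subject,
                      int min_aligned = 1, double keep_fraction = 0.5,
                      int max_hits = 64) {
  std::vector<char> subj(subject.begin(), subject.end());
  std::vector<int> score, sstart, send, qstart, qend, matches, aligned, cols;
  int first_best = -1;
  for (int it = 0; it < max_hits; ++it) {
    Aln a = sw_best(query, subj.data(), (int)subj.size());
    if (a.score <= 0) break;
    if (first_best < 0) first_best = a.score;
    if (a.score < keep_fraction * first_best) break;
    if (a.aligned >= min_aligned) {
      score.push_back(a.score);
      sstart.push_back(a.sstart); send.push_back(a.send);
      qstart.push_back(a.qstart); qend.push_back(a.qend);
      matches.push_back(a.matches); aligned.push_back(a.aligned);
      cols.push_back(a.cols);
    }
    for (int p = a.sstart; p < a.send; ++p) subj[p] = 'N';
  }
  return DataFrame::create(
      _["sstart"] = sstart, _["send"] = send,
      _["qstart"] = qstart, _["qend"] = qend,
      _["score"] = score, _["matches"] = matches,
      _["aligned"] = aligned, _["cols"] = cols);
}

// ---------------------------------------------------------------------------
// Genome k-mer index
// ---------------------------------------------------------------------------

struct GenomeIndex {
  std::vector<std::string> names;
  std::vector<std::string> seqs;      // uppercase
  std::vector<uint64_t> offsets;      // global offset of each chromosome
  uint64_t total = 0;
  int k = 16;
  std::vector<uint64_t> entries;      // (kmer << 32) | global_pos, sorted
  int chrom_of(uint64_t gpos) const {
    int lo = 0, hi = (int)offsets.size() - 1;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (offsets[mid] <= gpos) lo = mid; else hi = mid - 1;
    }
    return lo;
  }
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k = 16) {
  if (k < 8 || k > 16) stop("k must be in [8, 16]");
  GenomeIndex* gi = new GenomeIndex();
  gi->k = k;
  uint64_t off = 0;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (auto& c : s) c = (char)std::toupper((unsigned char)c);
    gi->names.push_back(as<std::string>(names[i]));
    gi->offsets.push_back(off);
    off += s.size();
    gi->seqs.push_back(std::move(s));
  }
  gi->total = off;
  if (off >= (1ULL << 32)) { delete gi; stop("genome too large for index (>4 Gb)"); }
  const uint64_t mask = (k == 16) ? 0xFFFFFFFFULL : ((1ULL << (2 * k)) - 1);
  for (size_t c = 0; c < gi->seqs.size(); ++c) {
    const std::string& s = gi->seqs[c];
    uint64_t kmer = 0; int valid = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int code = base_code(s[p]);
      if (code < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)code) & mask;
      if (++valid >= k) {
        uint64_t gpos = gi->offsets[c] + p - k + 1;
        gi->entries.push_back((kmer << 32) | gpos);
      }
    }
  }
  std::sort(gi->entries.begin(), gi->entries.end());
  XPtr<GenomeIndex> ptr(gi, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP idx) {
  XPtr<GenomeIndex> gi(idx);
  return List::create(_["names"] = wrap(gi->names), _["k"] = gi->k,
                      _["n_kmers"] = (double)gi->entries.size(),
                      _["total"] = (double)gi->total);
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: c = 'N';
    }
  }
  return r;
}

struct Hit {
  int chrom; int start; int end; char strand;
  int score; int matches; int aligned; int cols;
  int qstart; int qend;
};

static void align_candidates(const GenomeIndex& gi, const std::string& q,
                             char strand, std::vector<uint64_t>& cands,
                             int pad, int min_aligned, std::vector<Hit>& hits) {
  if (cands.empty()) return;
  std::sort(cands.begin(), cands.end());
  const int qlen = (int)q.size();
  int64_t last = -1000000;
  for (uint64_t cand : cands) {
    if ((int64_t)cand - last < 16) continue; // same diagonal cluster
    last = (int64_t)cand;
    int c = gi.chrom_of(cand);
    int64_t cstart = (int64_t)cand - (int64_t)gi.offsets[c];
    int64_t w0 = std::max((int64_t)0, cstart - pad);
    int64_t w1 = std::min((int64_t)gi.seqs[c].size(), cstart + qlen + pad);
    if (w1 - w0 < 1) continue;
    Aln a = sw_best(q, gi.seqs[c].data() + w0, (int)(w1 - w0));
    if (a.score <= 0 || a.aligned < min_aligned) continue;
    Hit h;
    h.chrom = c; h.start = (int)(w0 + a.sstart); h.end = (int)(w0 + a.send);
    h.strand = strand; h.score = a.score; h.matches = a.matches;
    h.aligned = a.aligned; h.cols = a.cols;
    if (strand == '+') { h.qstart = a.qstart; h.qend = a.qend; }
    else { h.qstart = qlen - a.qend; h.qend = qlen - a.qstart; }
    hits.push_back(h);
  }
}

// [[Rcpp::export]]
DataFrame cpp_realign(SEXP idx, std::string query, int min_aligned = 50,
                      int seed_step = 11, int pad = 30,
                      int max_seed_hits = 4096, int max_candidates = 20000) {
  XPtr<GenomeIndex> gi(idx);
  const int k = gi->k;
  for (auto& c : query) c = (char)std::toupper((unsigned char)c);
  const uint64_t mask = (k == 16) ? 0xFFFFFFFFULL : ((1ULL << (2 * k)) - 1);
  std::vector<Hit> hits;
  std::string qrc = revcomp(query);
  for (int s = 0; s < 2; ++s) {
    const std::string& q = (s == 0) ? query : qrc;
    const int qlen = (int)q.size();
    if (qlen < k) continue;
    std::vector<uint64_t> cands;
    std::vector<int> offs;
    for (int o = 0; o + k <= qlen; o += seed_step) offs.push_back(o);
    if (offs.empty() || offs.back() != qlen - k) offs.push_back(qlen - k);
    for (int o : offs) {
      uint64_t kmer = 0; bool ok = true;
      for (int i = 0; i < k; ++i) {
        int code = base_code(q[o + i]);
        if (code < 0) { ok = false; break; }
        kmer = (kmer << 2) | (uint64_t)code;
      }
      if (!ok) continue;
      kmer &= mask;
      uint64_t lo = kmer << 32, hi = lo | 0xFFFFFFFFULL;
      auto it0 = std::lower_bound(gi->entries.begin(), gi->entries.end(), lo);
      auto it1 = std::upper_bound(it0, gi->entries.end(), hi);
      if (it1 - it0 > max_seed_hits) continue; // low-complexity seed
      for (auto it = it0; it != it1; ++it) {
        int64_t gpos = (int64_t)(*it & 0xFFFFFFFFULL);
        int64_t cand = gpos - o;
        if (cand < 0) cand = 0;
        cands.push_back((uint64_t)cand);
        if ((int)cands.size() > max_candidates) break;
      }
      if ((int)cands.size() > max_candidates) break;
    }
    align_candidates(*gi, q, (s == 0) ? '+' : '-', cands, pad, min_aligned, hits);
  }
  // dedupe: among hits overlapping >=50% of the shorter, keep the best score
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.chrom != b.chrom) return a.chrom < b.chrom;
    if (a.start != b.start) return a.start < b.start;
    return a.score > b.score;
  });
  std::vector<Hit> keep;
  for (const Hit& h : hits) {
    bool dup = false;
    for (auto it = keep.rbegin(); it != keep.rend(); ++it) {
      if (it->chrom != h.chrom || it->end <= h.start) break;
      int ov = std::min(it->end, h.end) - std::max(it->start, h.start);
      int shorter = std::min(it->end - it->start, h.end - h.start);
      if (ov * 2 >= shorter) {
        if (h.score > it->score) *it = h;
        dup = true; break;
      }
    }
    if (!dup) keep.push_back(h);
  }
  int n = (int)keep.size();
  CharacterVector chrom(n), strand(n);
  IntegerVector start(n), end(n), score(n), matches(n), aligned(n), cols(n),
      qstart(n), qend(n);
  for (int i = 0; i < n; ++i) {
    chrom[i] = gi->names[keep[i].chrom];
    start[i] = keep[i].start; end[i] = keep[i].end;
    strand[i] = std::string(1, keep[i].strand);
    score[i] = keep[i].score; matches[i] = keep[i].matches;
    aligned[i] = keep[i].aligned; cols[i] = keep[i].cols;
    qstart[i] = keep[i].qstart; qend[i] = keep[i].qend;
  }
  return DataFrame::create(
      _["chrom"] = chrom, _["start"] = start, _["end"] = end,
      _["strand"] = strand, _["score"] = score, _["matches"] = matches,
      _["aligned"] = aligned, _["cols"] = cols,
      _["qstart"] = qstart, _["qend"] = qend,
      _["stringsAsFactors"] = false);
}
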