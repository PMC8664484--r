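#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// ---- ordered-map dynamic programming aligner ----
//
// Monotone pairing of query labels onto reference labels. A transition from
// matched pair (i0, j0) to (i, j) merges the intervening fragments on each
// map (at most `delta` fragments per side); its cost is
// (x - y)^2 / (v * (x + y) + 1) for merged interval lengths x, y, and every
// label merged over costs `pmiss`. Each matched pair earns bonus `B`.
// Alignment ends are free (glocal), so the best chain may start and end at
// any label pair.

// [[Rcpp::export]]
List cpp_mapalign_dp(NumericVector q, NumericVector r, double v, double B,
                     double pmiss, int delta, bool traceback) {
  const int n = q.size(), m = r.size();
  if (n < 2 || m < 2)
    stop("ordered-map alignment needs at least 2 labels per map");
  std::vector<double> S((size_t)n * m), C((size_t)n * m, 0.0);
  std::vector<int> P((size_t)n * m, -1);
  double best = R_NegInf;
  int besti = 0, bestj = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = B;      // start a new chain at (i, j)
      int parent = -1;
      double cpair = 0.0;
      for (int di = 1; di <= delta && di <= i; ++di) {
        const double x = q[i] - q[i - di];
        for (int dj = 1; dj <= delta && dj <= j; ++dj) {
          const double y = r[j] - r[j - dj];
          const double cost = (x - y) * (x - y) / (v * (x + y) + 1.0);
          const size_t p0 = (size_t)(i - di) * m + (j - dj);
          const double cand = S[p0] + B - cost - pmiss * (di - 1 + dj - 1);
          if (cand > s) {
            s = cand;
            parent = (int)p0;
            cpair = cost;
          }
        }
      }
      const size_t pp = (size_t)i * m + j;
      S[pp] = s;
      P[pp] = parent;
      C[pp] = (parent >= 0 ? C[parent] : 0.0) + cpair;
      if (s > best) { best = s; besti = i; bestj = j; }
    }
  }
  if (!traceback)
    return List::create(_["score"] = best);
  std::vector<int> qi, ri;
  int cur = besti * m + bestj;
  double sizing = C[cur];
  while (cur >= 0) {
    qi.push_back(cur / m + 1);  // 1-based label indices
    ri.push_back(cur % m + 1);
    cur = P[cur];
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(ri.begin(), ri.end());
  return List::create(_["score"] = best, _["q"] = wrap(qi), _["r"] = wrap(ri),
                      _["sizing_cost"] = sizing);
}

// ---- unique k-mer anchor placement ----

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static void collect_kmers(const std::string& s, int k,
                          std::unordered_map<uint64_t, int64_t>& idx,
                          int64_t seq_tag_base) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t code = 0;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run < k) continue;
    int64_t pos = (int64_t)(i + 1 - k);  // 0-based kmer start
    auto it = idx.find(code);
    if (it == idx.end()) idx.emplace(code, seq_tag_base + pos);
    else it->second = -1;  // duplicate anywhere -> not usable as anchor
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': case 'a': c = 'T'; break;
      case 'C': case 'c': c = 'G'; break;
      case 'G': case 'g': c = 'C'; break;
      case 'T': case 't': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

struct Block {
  int ctg, ref, strand;
  int64_t ctg_start, ctg_end, ref_start, ref_end;  // 0-based half-open
  double identity;
  int n_anchors;
};

// Place contigs on reference sequences from unique exact k-mer anchors.
// Anchors sharing (reference, diagonal) are chained into ungapped blocks;
// blocks are split where successive anchors are farther apart than
// max_spacing, extended outward while bases match, and kept when they reach
// min_block bp at >= min_identity ungapped identity.
// [[Rcpp::export]]
DataFrame cpp_place_contigs(CharacterVector ref_names, CharacterVector ref_seqs,
                            CharacterVector ctg_names, CharacterVector ctg_seqs,
                            int k, int min_block, double min_identity,
                            int max_spacing) {
  if (k < 15 || k > 32) stop("anchor k must be in [15, 32]");
  const int nref = ref_seqs.size(), nctg = ctg_seqs.size();
  std::vector<std::string> refs(nref);
  for (int i = 0; i < nref; ++i) refs[i] = as<std::string>(ref_seqs[i]);
  std::unordered_map<uint64_t, int64_t> idx;
  const int64_t TAG = 1LL << 40;  // sequences < 1 Tb apiece
  for (int i = 0; i < nref; ++i) collect_kmers(refs[i], k, idx, (int64_t)i * TAG);

  std::vector<Block> out;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  for (int c = 0; c < nctg; ++c) {
    const std::string fwd = as<std::string>(ctg_seqs[c]);
    for (int strand = 0; strand < 2; ++strand) {
      const std::string s = strand ? revcomp(fwd) : fwd;
      // anchors grouped by (ref, diagonal)
      std::unordered_map<int64_t, std::vector<std::pair<int64_t, int64_t> > > gr;
      uint64_t code = 0;
      int run = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int b = base_code(s[i]);
        if (b < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)b) & mask;
        if (++run < k) continue;
        auto it = idx.find(code);
        if (it == idx.end() || it->second < 0) continue;
        int64_t rseq = it->second / TAG, rpos = it->second % TAG;
        int64_t cpos = (int64_t)(i + 1 - k);
        int64_t diag = rpos - cpos;
        gr[rseq * (2 * TAG) + (diag + TAG)].push_back({cpos, rpos});
      }
      for (auto& kv : gr) {
        int rseq = (int)(kv.first / (2 * TAG));
        auto& v = kv.second;
        std::sort(v.begin(), v.end());
        const std::string& RR = refs[rseq];
        size_t lo = 0;
        for (size_t hi = 1; hi <= v.size(); ++hi) {
          if (hi < v.size() && v[hi].first - v[hi - 1].first <= max_spacing) {
            // never chain across an N/ambiguity run in the reference
            // (e.g. straight through a gap whose emitted N count equals
            // the true span): that must stay two flank blocks
            bool clean = true;
            for (int64_t t = v[hi - 1].second + k; t < v[hi].second; ++t)
              if (base_code(RR[t]) < 0) { clean = false; break; }
            if (clean) continue;
          }
          // block v[lo..hi)
          int64_t c0 = v[lo].first, c1 = v[hi - 1].first + k;
          int64_t r0 = v[lo].second, r1 = v[hi - 1].second + k;
          const std::string& R = refs[rseq];
          while (c0 > 0 && r0 > 0 && s[c0 - 1] == R[r0 - 1] &&
                 base_code(s[c0 - 1]) >= 0) { --c0; --r0; }
          while (c1 < (int64_t)s.size() && r1 < (int64_t)R.size() &&
                 s[c1] == R[r1] && base_code(s[c1]) >= 0) { ++c1; ++r1; }
          int64_t len = c1 - c0;
          if (len >= min_block) {
            int64_t match = 0;
            for (int64_t t = 0; t < len; ++t)
              if (s[c0 + t] == R[r0 + t]) ++match;
            double ident = (double)match / (double)len;
            if (ident >= min_identity) {
              Block blk;
              blk.ctg = c; blk.ref = rseq; blk.strand = strand;
              blk.ref_start = r0; blk.ref_end = r1;
              blk.identity = ident; blk.n_anchors = (int)(hi - lo);
              if (strand == 0) { blk.ctg_start = c0; blk.ctg_end = c1; }
              else {  // coordinates on the original (forward) contig
                blk.ctg_start = (int64_t)fwd.size() - c1;
                blk.ctg_end = (int64_t)fwd.size() - c0;
              }
              out.push_back(blk);
            }
          }
          lo = hi;
        }
      }
    }
  }
  const int no = (int)out.size();
  CharacterVector ocid(no), orid(no), ori(no);
  NumericVector cs(no), ce(no), rs(no), re(no), ident(no), abp(no);
  IntegerVector nanch(no);
  for (int i = 0; i < no; ++i) {
    ocid[i] = ctg_names[out[i].ctg];
    orid[i] = ref_names[out[i].ref];
    ori[i] = out[i].strand ? "-" : "+";
    cs[i] = (double)out[i].ctg_start + 1;  // 1-based inclusive
    ce[i] = (double)out[i].ctg_end;
    rs[i] = (double)out[i].ref_start + 1;
    re[i] = (double)out[i].ref_end;
    ident[i] = out[i].identity;
    abp[i] = (double)(out[i].ctg_end - out[i].ctg_start);
    nanch[i] = out[i].n_anchors;
  }
  return DataFrame::create(
    _["contig_id"] = ocid, _["seq_id"] = orid,
    _["contig_start"] = cs, _["contig_end"] = ce,
    _["seq_start"] = rs, _["seq_end"] = re, _["orientation"] = ori,
    _["identity"] = ident, _["aligned_bp"] = abp, _["n_anchors"] = nanch,
    _["stringsAsFactors"] = false);
}

// ---- best suffix/prefix overlap between two flank windows ----
//
// Finds the longest L >= min_overlap such that the last L bases of `left`
// match the first L bases of `right` at >= min_identity. Candidate L values
// come from exact k-mer probes taken from the start of `right` at offsets
// 0, probe_step, 2*probe_step, ... and located in `left`.
// [[Rcpp::export]]
List cpp_best_overlap(std::string left, std::string right, int k,
                      int min_overlap, double min_identity, int probe_step) {
  const int64_t nl = (int64_t)left.size(), nr = (int64_t)right.size();
  int64_t bestL = 0;
  double bestId = 0.0;
  if (nl < min_overlap || nr < min_overlap)
    return List::create(_["length"] = 0.0, _["identity"] = 0.0);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::vector<int64_t> cand;
  for (int64_t j = 0; j + k <= nr && j <= nl - min_overlap + k;
       j += probe_step) {
    uint64_t probe = 0;
    bool ok = true;
    for (int t = 0; t < k; ++t) {
      int b = base_code(right[j + t]);
      if (b < 0) { ok = false; break; }
      probe = (probe << 2) | (uint64_t)b;
    }
    if (!ok) continue;
    uint64_t code = 0;
    int run = 0;
    for (int64_t i = 0; i < nl; ++i) {
      int b = base_code(left[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run < k) continue;
      if (code == probe) {
        int64_t p = i + 1 - k;     // left pos of right[j..j+k)
        int64_t L = nl - (p - j);  // implied overlap length
        if (p - j >= 0 && L >= min_overlap && L <= nl && L <= nr)
          cand.push_back(L);
      }
    }
  }
  std::sort(cand.begin(), cand.end(), std::greater<int64_t>());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  for (int64_t L : cand) {
    int64_t match = 0;
    for (int64_t t = 0; t < L; ++t)
      if (left[nl - L + t] == right[t] && base_code(right[t]) >= 0) ++match;
    double ident = (double)match / (double)L;
    if (ident >= min_identity) { bestL = L; bestId = ident; break; }
  }
  return List::create(_["length"] = (double)bestL, _["identity"] = bestId);
}
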