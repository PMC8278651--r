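#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

// 2-bit encoding; -1 for non-ACGT
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

// murmur3 64-bit finalizer: avalanching hash of the packed k-mer code
static inline uint64_t fmix64(uint64_t x) {
  x ^= x >> 33;
  x *= 0xff51afd7ed558ccdULL;
  x ^= x >> 33;
  x *= 0xc4ceb9fe1a85ec53ULL;
  x ^= x >> 33;
  return x;
}

// enumerate canonical k-mer hashes of seq (k <= 31); windows with ambiguous
// bases are skipped
static void canonical_hashes(const std::string& seq, int k,
                             std::vector<uint64_t>& out) {
  const size_t n = seq.size();
  if ((int)n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rc = 0;
  int valid = 0;  // length of current valid run
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++valid >= k) {
      uint64_t canon = fwd < rc ? fwd : rc;
      out.push_back(fmix64(canon));
    }
  }
}

// [[Rcpp::export]]
std::vector<std::string> cpp_revcomp(const std::vector<std::string>& seqs) {
  std::vector<std::string> out(seqs.size());
  for (size_t i = 0; i < seqs.size(); ++i) {
    const std::string& s = seqs[i];
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r) c = comp_base(c);
    out[i] = r;
  }
  return out;
}

// Bottom-s MinHash sketch of canonical k-mer hashes. Hashes are returned as
// doubles of (hash >> 11), i.e. 53-bit values exactly representable in a
// double, sorted ascending.
// [[Rcpp::export]]
NumericVector cpp_sketch(const std::vector<std::string>& contigs, int k, int s) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::vector<uint64_t> all;
  for (const std::string& ctg : contigs) canonical_hashes(ctg, k, all);
  if (all.empty()) stop("no valid k-mers: sequence shorter than k?");
  std::sort(all.begin(), all.end());
  all.erase(std::unique(all.begin(), all.end()), all.end());
  size_t keep = std::min((size_t)s, all.size());
  NumericVector out(keep);
  for (size_t i = 0; i < keep; ++i) out[i] = (double)(all[i] >> 11);
  return out;
}

// Distinct canonical k-mer hash count (for diagnostics)
// [[Rcpp::export]]
double cpp_kmer_count(const std::vector<std::string>& contigs, int k) {
  std::vector<uint64_t> all;
  for (const std::string& ctg : contigs) canonical_hashes(ctg, k, all);
  std::sort(all.begin(), all.end());
  all.erase(std::unique(all.begin(), all.end()), all.end());
  return (double)all.size();
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// mismatches of query placed at target[start..], early exit beyond cap
static int count_mm(const std::string& q, const std::string& t, size_t start,
                    int cap) {
  int mm = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    if (q[i] != t[start + i]) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// Exact-seed index of all q-mers of a text (forward strand, packed code ->
// start positions). Ambiguous bases break the window.
static void build_index(const std::string& text, int q,
                        std::unordered_multimap<uint64_t, uint32_t>& idx) {
  const size_t n = text.size();
  if ((int)n < q) return;
  const uint64_t mask = (q == 32) ? ~0ULL : ((1ULL << (2 * q)) - 1);
  uint64_t code = 0;
  int valid = 0;
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(text[i]);
    if (c < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (++valid >= q) idx.emplace(code, (uint32_t)(i + 1 - q));
  }
}

static bool encode_window(const std::string& s, size_t start, int q,
                          uint64_t& code) {
  code = 0;
  for (int i = 0; i < q; ++i) {
    int c = base_code(s[start + i]);
    if (c < 0) return false;
    code = (code << 2) | (uint64_t)c;
  }
  return true;
}

// Best ungapped placement of `query` in `text` (one strand) with at most
// `cap` mismatches, using (cap+1) disjoint pigeonhole seeds of length q.
// Returns mismatch count or cap+1 if none.
static int best_ungapped_one_strand(
    const std::string& query, const std::string& text, int cap,
    const std::unordered_multimap<uint64_t, uint32_t>& idx, int q,
    long* best_pos) {
  const long L = (long)query.size(), n = (long)text.size();
  int best = cap + 1;
  if (L > n) return best;
  for (int s = 0; s <= cap; ++s) {
    long off = (long)s * q;
    if (off + q > L) break;
    uint64_t code;
    if (!encode_window(query, off, q, code)) continue;
    auto range = idx.equal_range(code);
    for (auto it = range.first; it != range.second; ++it) {
      long start = (long)it->second - off;
      if (start < 0 || start + L > n) continue;
      int mm = count_mm(query, text, (size_t)start, best - 1);
      if (mm < best) {
        best = mm;
        if (best_pos) *best_pos = start;
        if (best == 0) return 0;
      }
    }
  }
  return best;
}

// Fragment presence: for each fragment, is there an ungapped hit on either
// strand of the genome with <= max_mm mismatches? Pigeonhole seeding makes
// the scan exact (every qualifying placement has one clean seed).
// [[Rcpp::export]]
LogicalVector cpp_fragment_hits(const std::vector<std::string>& fragments,
                                const std::vector<std::string>& contigs,
                                int max_mm) {
  // seed length per fragment: min(31, floor(L / (max_mm + 1))), >= 8 required
  // for indexed seeding; shorter fragments fall back to a direct scan
  std::unordered_map<int, std::vector<std::unordered_multimap<uint64_t, uint32_t>>> indexes;
  LogicalVector out(fragments.size());
  for (size_t f = 0; f < fragments.size(); ++f) {
    const std::string& frag = fragments[f];
    const long L = (long)frag.size();
    int q = (int)std::min(31L, L / (max_mm + 1));
    bool hit = false;
    std::string frc = revcomp(frag);
    if (q >= 8) {
      auto& idxset = indexes[q];
      if (idxset.empty()) {
        idxset.resize(contigs.size());
        for (size_t c = 0; c < contigs.size(); ++c)
          build_index(contigs[c], q, idxset[c]);
      }
      for (size_t c = 0; c < contigs.size() && !hit; ++c) {
        if (best_ungapped_one_strand(frag, contigs[c], max_mm, idxset[c], q, nullptr) <= max_mm)
          hit = true;
        else if (best_ungapped_one_strand(frc, contigs[c], max_mm, idxset[c], q, nullptr) <= max_mm)
          hit = true;
      }
    } else {
      // brute force for very short fragments
      for (size_t c = 0; c < contigs.size() && !hit; ++c) {
        const std::string& t = contigs[c];
        if ((long)t.size() < L) continue;
        for (size_t p = 0; p + L <= t.size() && !hit; ++p) {
          if (count_mm(frag, t, p, max_mm) <= max_mm) hit = true;
          else if (count_mm(frc, t, p, max_mm) <= max_mm) hit = true;
        }
      }
    }
    out[f] = hit;
  }
  return out;
}

// Best ungapped identity of each tile against a target sequence, both
// strands, q-mer seeding. identity = 1 - mm/len when mm <= cap(len), else 0.
// cap(len) = floor((1 - min_identity) * len), additionally bounded by the
// pigeonhole guarantee floor(len/q) - 1: placements with more mismatches than
// that bound are not reported. q = 9 gives an exact scan down to 90% identity
// for 150-nt tiles.
// [[Rcpp::export]]
NumericVector cpp_tile_identities(const std::vector<std::string>& tiles,
                                  const std::string& target,
                                  double min_identity, int q = 9) {
  if (q < 6 || q > 31) stop("seed length q must be in 6..31");
  std::unordered_multimap<uint64_t, uint32_t> idx;
  build_index(target, q, idx);
  NumericVector out(tiles.size());
  for (size_t i = 0; i < tiles.size(); ++i) {
    const std::string& tile = tiles[i];
    const long L = (long)tile.size();
    int cap = (int)std::floor((1.0 - min_identity) * L);
    int nseeds = (int)(L / q);
    int use_cap = std::min(cap, nseeds - 1);  // seeds guarantee up to nseeds-1
    if (use_cap < 0) { out[i] = 0.0; continue; }
    int best = use_cap + 1;
    std::string trc = revcomp(tile);
    for (int strand = 0; strand < 2 && best > 0; ++strand) {
      const std::string& qs = strand == 0 ? tile : trc;
      for (int s = 0; s < nseeds && best > 0; ++s) {
        long off = (long)s * q;
        uint64_t code;
        if (!encode_window(qs, off, q, code)) continue;
        auto range = idx.equal_range(code);
        for (auto it = range.first; it != range.second; ++it) {
          long start = (long)it->second - off;
          if (start < 0 || start + L > (long)target.size()) continue;
          int mm = count_mm(qs, target, (size_t)start, best - 1);
          if (mm < best) best = mm;
          if (best == 0) break;
        }
      }
    }
    out[i] = (best <= use_cap) ? 1.0 - (double)best / L : 0.0;
  }
  return out;
}

// split [0, n) into tiles of tile_len, merging a terminal remainder shorter
// than min_last into the previous tile (single short sequence stays whole)
static void tile_bounds(long n, int tile_len, int min_last,
                        std::vector<std::pair<long, long>>& out) {
  out.clear();
  if (n <= tile_len) { out.emplace_back(0, n); return; }
  for (long s = 0; s < n; s += tile_len)
    out.emplace_back(s, std::min(n, s + (long)tile_len));
  if (out.size() > 1 &&
      (out.back().second - out.back().first) < (long)min_last) {
    out[out.size() - 2].second = out.back().second;
    out.pop_back();
  }
}

// best identity of one tile (given as string) against an indexed target
static double tile_best_identity(const std::string& tile,
                                 const std::string& target,
                                 const std::unordered_multimap<uint64_t, uint32_t>& idx,
                                 int q, double min_identity) {
  const long L = (long)tile.size();
  int cap = (int)std::floor((1.0 - min_identity) * L);
  int nseeds = (int)(L / q);
  int use_cap = std::min(cap, nseeds - 1);
  if (use_cap < 0) return 0.0;
  int best = use_cap + 1;
  std::string trc = revcomp(tile);
  for (int strand = 0; strand < 2 && best > 0; ++strand) {
    const std::string& qs = strand == 0 ? tile : trc;
    for (int s = 0; s < nseeds && best > 0; ++s) {
      long off = (long)s * q;
      uint64_t code;
      if (!encode_window(qs, off, q, code)) continue;
      auto range = idx.equal_range(code);
      for (auto it = range.first; it != range.second; ++it) {
        long start = (long)it->second - off;
        if (start < 0 || start + L > (long)target.size()) continue;
        int mm = count_mm(qs, target, (size_t)start, best - 1);
        if (mm < best) best = mm;
        if (best == 0) break;
      }
    }
  }
  return (best <= use_cap) ? 1.0 - (double)best / L : 0.0;
}

// Greedy centroid clustering of sequences (caller passes them longest-first):
// a sequence joins the first centroid it matches at > identity mean tile
// identity over > coverage of the centroid length; else it founds a new
// centroid. Returns the 1-based index of each sequence's centroid sequence.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(const std::vector<std::string>& seqs,
                                 double identity, double coverage,
                                 int tile_len = 150, int q = 9) {
  const double scan_id = std::max(0.5, identity - 0.05);
  std::vector<int> centroids;
  std::vector<std::unordered_multimap<uint64_t, uint32_t>> cindex;
  IntegerVector out(seqs.size());
  std::vector<std::pair<long, long>> tb;
  for (size_t i = 0; i < seqs.size(); ++i) {
    const std::string& s = seqs[i];
    tile_bounds((long)s.size(), tile_len, 50, tb);
    std::vector<std::string> tiles;
    for (auto& b : tb) tiles.push_back(s.substr(b.first, b.second - b.first));
    int hit = -1;
    for (size_t c = 0; c < centroids.size(); ++c) {
      const std::string& cent = seqs[centroids[c]];
      double cov_len = 0, id_wsum = 0, tot_len = 0;
      for (auto& t : tiles) {
        double id = tile_best_identity(t, cent, cindex[c], q, scan_id);
        tot_len += t.size();
        if (id > 0) { cov_len += t.size(); id_wsum += id * t.size(); }
      }
      double cov = cov_len / (double)cent.size();
      if (cov > coverage && cov_len > 0 && id_wsum / cov_len > identity) {
        hit = (int)c;
        break;
      }
    }
    if (hit < 0) {
      centroids.push_back((int)i);
      cindex.emplace_back();
      build_index(s, q, cindex.back());
      out[i] = (int)i + 1;
    } else {
      out[i] = centroids[hit] + 1;
    }
  }
  return out;
}

// Read mapping: exact 31-mer seed + ungapped end-to-end extension inside the
// target; score = -mismatch_penalty * mismatches; best hit per read with
// score > min_score kept; equal-score hits on different targets are ties and
// the read is dropped (tie = true rows are excluded from the result).
// [[Rcpp::export]]
DataFrame cpp_map_reads(const std::vector<std::string>& reads,
                        const std::vector<std::string>& targets,
                        int seed_len, double mismatch_penalty,
                        double min_score) {
  if (seed_len < 8 || seed_len > 31) stop("seed_len must be in 8..31");
  // joint index: code -> packed (target << 32 | pos)
  std::unordered_multimap<uint64_t, uint64_t> idx;
  for (size_t t = 0; t < targets.size(); ++t) {
    const std::string& txt = targets[t];
    const size_t n = txt.size();
    if ((int)n < seed_len) continue;
    const uint64_t mask = (1ULL << (2 * seed_len)) - 1;
    uint64_t code = 0; int valid = 0;
    for (size_t i = 0; i < n; ++i) {
      int c = base_code(txt[i]);
      if (c < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)c) & mask;
      if (++valid >= seed_len)
        idx.emplace(code, ((uint64_t)t << 32) | (uint64_t)(i + 1 - seed_len));
    }
  }
  std::vector<int> r_read, r_target, r_pos, r_mm;
  std::vector<double> r_score;
  std::vector<std::string> r_strand;
  int max_mm_allowed = (int)std::floor(-min_score / mismatch_penalty);

  for (size_t r = 0; r < reads.size(); ++r) {
    const std::string& fwd = reads[r];
    const long L = (long)fwd.size();
    if (L < seed_len) continue;
    std::string rev = revcomp(fwd);
    int best = max_mm_allowed + 1;
    long best_target = -1, best_pos = -1;
    int best_strand = 0;
    bool tie = false;
    std::vector<long> offsets;
    for (long off = 0; off + seed_len <= L; off += 7) offsets.push_back(off);
    if (offsets.empty() || offsets.back() != L - seed_len)
      offsets.push_back(L - seed_len);
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = strand == 0 ? fwd : rev;
      std::unordered_set<uint64_t> seen;
      for (long off : offsets) {
        uint64_t code;
        if (!encode_window(q, (size_t)off, seed_len, code)) continue;
        auto range = idx.equal_range(code);
        for (auto it = range.first; it != range.second; ++it) {
          long t = (long)(it->second >> 32);
          long start = (long)(it->second & 0xffffffffULL) - off;
          if (start < 0 || start + L > (long)targets[t].size()) continue;
          uint64_t key = ((uint64_t)t << 40) | ((uint64_t)strand << 39) |
                         (uint64_t)start;
          if (!seen.insert(key).second) continue;
          int mm = count_mm(q, targets[t], (size_t)start, best);
          if (mm < best) {
            best = mm; best_target = t; best_pos = start; best_strand = strand;
            tie = false;
          } else if (mm == best && best <= max_mm_allowed && t != best_target) {
            tie = true;
          }
        }
      }
    }
    double score = -mismatch_penalty * best;
    if (best <= max_mm_allowed && score > min_score && !tie) {
      r_read.push_back((int)r + 1);
      r_target.push_back((int)best_target + 1);
      r_pos.push_back((int)best_pos + 1);
      r_strand.push_back(best_strand == 0 ? "+" : "-");
      r_mm.push_back(best);
      r_score.push_back(score);
    }
  }
  return DataFrame::create(
      _["read"] = r_read, _["target"] = r_target, _["pos"] = r_pos,
      _["strand"] = r_strand, _["mismatches"] = r_mm, _["score"] = r_score,
      _["stringsAsFactors"] = false);
}

// Semi-global (pattern-global, text free-ends) Levenshtein matches of a
// pattern in a text: every site with edit distance <= max_edit, collapsed to
// the minimal-distance alignment per site. Returns 1-based inclusive
// [start, end] on the text and the distance.
// [[Rcpp::export]]
DataFrame cpp_semiglobal_matches(const std::string& pattern,
                                 const std::string& text, int max_edit) {
  const long m = (long)pattern.size(), n = (long)text.size();
  std::vector<int> prev(n + 1), cur(n + 1), endrow(n + 1);
  for (long j = 0; j <= n; ++j) prev[j] = 0;  // free start in text
  for (long i = 1; i <= m; ++i) {
    cur[0] = (int)i;
    for (long j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (pattern[i - 1] == text[j - 1] ? 0 : 1);
      int del = prev[j] + 1;   // gap in text
      int ins = cur[j - 1] + 1;  // gap in pattern
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  endrow = prev;
  // candidate end positions <= max_edit; cluster nearby ends, keep argmin
  std::vector<long> ends; std::vector<int> dists;
  long j = 1;
  while (j <= n) {
    if (endrow[j] <= max_edit) {
      long best_j = j; int best_d = endrow[j];
      long jj = j;
      while (jj + 1 <= n && endrow[jj + 1] <= max_edit && jj + 1 - best_j <= m) {
        ++jj;
        if (endrow[jj] < best_d) { best_d = endrow[jj]; best_j = jj; }
      }
      ends.push_back(best_j); dists.push_back(best_d);
      j = jj + 1;
    } else ++j;
  }
  // recover start per end by reverse semi-global DP on a local window
  std::vector<int> starts(ends.size());
  for (size_t e = 0; e < ends.size(); ++e) {
    long end = ends[e];
    long lo = std::max(1L, end - m - max_edit);
    long wlen = end - lo + 1;
    // align reversed pattern to reversed window, pattern-global, free end
    std::string rp(pattern.rbegin(), pattern.rend());
    std::string rw;
    rw.reserve(wlen);
    for (long x = end; x >= lo; --x) rw.push_back(text[x - 1]);
    std::vector<int> p2(wlen + 1), c2(wlen + 1);
    for (long jj = 0; jj <= wlen; ++jj) p2[jj] = (int)jj;  // anchored at end
    for (long i = 1; i <= m; ++i) {
      c2[0] = (int)i;
      for (long jj = 1; jj <= wlen; ++jj) {
        int sub = p2[jj - 1] + (rp[i - 1] == rw[jj - 1] ? 0 : 1);
        int del = p2[jj] + 1;
        int ins = c2[jj - 1] + 1;
        c2[jj] = std::min(sub, std::min(del, ins));
      }
      std::swap(p2, c2);
    }
    long best_jj = 1; int best_d = p2[1];
    for (long jj = 1; jj <= wlen; ++jj)
      if (p2[jj] < best_d) { best_d = p2[jj]; best_jj = jj; }
    starts[e] = (int)(end - best_jj + 1);
  }
  IntegerVector s_out(ends.size()), e_out(ends.size()), d_out(ends.size());
  for (size_t e = 0; e < ends.size(); ++e) {
    s_out[e] = starts[e]; e_out[e] = (int)ends[e]; d_out[e] = dists[e];
  }
  return DataFrame::create(_["start"] = s_out, _["end"] = e_out,
                           _["dist"] = d_out);
}
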