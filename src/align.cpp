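// Seed-and-extend nucleotide matching used by read mapping, ANI, spacer and
// CRISPR searches. All engines are ungapped (diagonal) except the read
// subtraction gate, which allows a single indel via a split-diagonal scan.
// Coordinates are 0-based half-open throughout; R wrappers convert where a
// 1-based interface is presented.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Enumerate valid k-mers of s as 2-bit packed keys; f(pos, key).
template <typename F>
static void for_each_kmer(const std::string& s, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0;
  int run = 0;
  const int n = (int)s.size();
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) f(i - k + 1, key);
  }
}

struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<uint64_t>> map; // (ref << 32) | pos
};

static void index_sequence(KmerIndex& idx, const std::string& s, int refid) {
  for_each_kmer(s, idx.k, [&](int pos, uint64_t key) {
    idx.map[key].push_back(((uint64_t)refid << 32) | (uint32_t)pos);
  });
}

// Count matching bases of read against ref at offset `diag` (read pos i maps
// to ref pos diag + i). Positions falling outside the reference count as
// aligned-but-mismatched only if clip = false; with clip = true the overlap
// is reported separately so callers can gate on aligned fraction.
static void diagonal_matches(const std::string& read, const std::string& ref,
                             long diag, int& matches, int& aligned) {
  const int L = (int)read.size(), R = (int)ref.size();
  int i0 = (int)std::max(0L, -diag);
  int i1 = (int)std::min((long)L, (long)R - diag);
  matches = 0; aligned = std::max(0, i1 - i0);
  for (int i = i0; i < i1; ++i)
    if (read[i] == ref[(int)(diag + i)]) ++matches;
}

// Collect candidate (ref, diagonal) pairs for one read against an index.
// Seeds are sampled every `step` positions: a shared exact run of at least
// k + step - 1 bases is always discovered, so for near-identical reads
// (error runs far longer than k) stride sampling loses nothing.
static void read_candidates(const std::string& read, const KmerIndex& idx,
                            size_t max_bucket, int step,
                            std::vector<std::pair<int, long>>& out) {
  std::unordered_set<uint64_t> seen;
  for_each_kmer(read, idx.k, [&](int pos, uint64_t key) {
    if (step > 1 && pos % step != 0) return;
    auto it = idx.map.find(key);
    if (it == idx.map.end() || it->second.size() > max_bucket) return;
    for (uint64_t packed : it->second) {
      int ref = (int)(packed >> 32);
      long rpos = (long)(uint32_t)packed;
      long diag = rpos - pos;
      uint64_t dedup = ((uint64_t)ref << 40) ^ (uint64_t)(diag + (1L << 34));
      if (seen.insert(dedup).second) out.emplace_back(ref, diag);
    }
  });
  std::sort(out.begin(), out.end());
}

// [[Rcpp::export(name = ".cpp_map_reads")]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector refs,
                        int k, double min_ident, double min_cov,
                        int max_bucket, int step) {
  KmerIndex idx; idx.k = k;
  std::vector<std::string> refstr(refs.size());
  for (int r = 0; r < refs.size(); ++r) {
    refstr[r] = as<std::string>(refs[r]);
    index_sequence(idx, refstr[r], r);
  }
  std::vector<int> out_read, out_ref, out_start, out_matches, out_aligned;
  std::vector<std::pair<int, long>> cand;
  for (int q = 0; q < reads.size(); ++q) {
    std::string read = as<std::string>(reads[q]);
    const int L = (int)read.size();
    cand.clear();
    read_candidates(read, idx, (size_t)max_bucket, step, cand);
    int best_ref = -1, best_matches = -1, best_aligned = 0;
    long best_diag = 0;
    for (auto& cd : cand) {
      int matches, aligned;
      diagonal_matches(read, refstr[cd.first], cd.second, matches, aligned);
      if (aligned < min_cov * L) continue;
      if (matches < min_ident * aligned) continue;
      // ties resolved by caller-supplied reference order (refs are expected
      // pre-sorted, longest first then id), then leftmost diagonal
      if (matches > best_matches) {
        best_matches = matches; best_ref = cd.first;
        best_diag = cd.second; best_aligned = aligned;
      }
    }
    if (best_ref >= 0) {
      out_read.push_back(q + 1);
      out_ref.push_back(best_ref + 1);
      out_start.push_back((int)best_diag);
      out_matches.push_back(best_matches);
      out_aligned.push_back(best_aligned);
    }
  }
  return DataFrame::create(_["read"] = out_read, _["ref"] = out_ref,
                           _["start"] = out_start, _["matches"] = out_matches,
                           _["aligned"] = out_aligned);
}

// Ungapped matched blocks between a and b found by exact k-mer seeding,
// one block per seeded diagonal, spanning the outermost seeds and clipped
// to both sequences.
// [[Rcpp::export(name = ".cpp_ani_blocks")]]
DataFrame cpp_ani_blocks(std::string a, std::string b, int k, int max_bucket) {
  KmerIndex idx; idx.k = k;
  index_sequence(idx, b, 0);
  std::unordered_map<long, std::pair<int, int>> diag; // diag -> min/max apos
  for_each_kmer(a, k, [&](int pos, uint64_t key) {
    auto it = idx.map.find(key);
    if (it == idx.map.end() || it->second.size() > (size_t)max_bucket) return;
    for (uint64_t packed : it->second) {
      long d = (long)pos - (long)(uint32_t)packed;
      auto di = diag.find(d);
      if (di == diag.end()) diag[d] = {pos, pos};
      else {
        if (pos < di->second.first) di->second.first = pos;
        if (pos > di->second.second) di->second.second = pos;
      }
    }
  });
  std::vector<long> keys;
  keys.reserve(diag.size());
  for (auto& kv : diag) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  std::vector<int> astart, aend, bstart, bend, matches;
  const long alen = (long)a.size(), blen = (long)b.size();
  for (long d : keys) {
    auto& mm = diag[d];
    long s = std::max((long)mm.first, d);
    long e = std::min({(long)mm.second + k, blen + d, alen});
    if (e <= s) continue;
    int m = 0;
    for (long i = s; i < e; ++i) if (a[(int)i] == b[(int)(i - d)]) ++m;
    astart.push_back((int)s); aend.push_back((int)e);
    bstart.push_back((int)(s - d)); bend.push_back((int)(e - d));
    matches.push_back(m);
  }
  return DataFrame::create(_["astart"] = astart, _["aend"] = aend,
                           _["bstart"] = bstart, _["bend"] = bend,
                           _["matches"] = matches);
}

// Ungapped matched blocks between every query and every reference in one
// pass: the references are indexed once and each query is scanned once.
// Same block definition as cpp_ani_blocks, keyed by (query, ref, diagonal).
// [[Rcpp::export(name = ".cpp_content_blocks")]]
DataFrame cpp_content_blocks(CharacterVector queries, CharacterVector refs,
                             int k, int max_bucket) {
  KmerIndex idx; idx.k = k;
  std::vector<std::string> refstr(refs.size());
  for (int r = 0; r < refs.size(); ++r) {
    refstr[r] = as<std::string>(refs[r]);
    index_sequence(idx, refstr[r], r);
  }
  std::vector<int> out_q, out_r, astart, aend, bstart, bend, matches;
  for (int q = 0; q < queries.size(); ++q) {
    std::string a = as<std::string>(queries[q]);
    const long alen = (long)a.size();
    // (ref, diag) -> min/max query position
    std::map<std::pair<int, long>, std::pair<int, int>> diag;
    for_each_kmer(a, k, [&](int pos, uint64_t key) {
      auto it = idx.map.find(key);
      if (it == idx.map.end() || it->second.size() > (size_t)max_bucket)
        return;
      for (uint64_t packed : it->second) {
        int ref = (int)(packed >> 32);
        long d = (long)pos - (long)(uint32_t)packed;
        auto kk = std::make_pair(ref, d);
        auto di = diag.find(kk);
        if (di == diag.end()) diag[kk] = {pos, pos};
        else {
          if (pos < di->second.first) di->second.first = pos;
          if (pos > di->second.second) di->second.second = pos;
        }
      }
    });
    for (auto& kv : diag) {
      int r = kv.first.first;
      long d = kv.first.second;
      const std::string& b = refstr[r];
      const long blen = (long)b.size();
      long s = std::max((long)kv.second.first, d);
      long e = std::min({(long)kv.second.second + k, blen + d, alen});
      if (e <= s) continue;
      int m = 0;
      for (long i = s; i < e; ++i) if (a[(int)i] == b[(int)(i - d)]) ++m;
      out_q.push_back(q + 1); out_r.push_back(r + 1);
      astart.push_back((int)s); aend.push_back((int)e);
      bstart.push_back((int)(s - d)); bend.push_back((int)(e - d));
      matches.push_back(m);
    }
  }
  return DataFrame::create(_["query"] = out_q, _["ref"] = out_r,
                           _["astart"] = astart, _["aend"] = aend,
                           _["bstart"] = bstart, _["bend"] = bend,
                           _["matches"] = matches);
}

// Full-length spacer occurrences in refs with at most max_mm substitutions,
// seeded by exact words of length `word`. For max_mm <= 1 and spacers of
// >= 2*word+1 bases the seeding is lossless (pigeonhole: one mismatch leaves
// an exact run of at least word bases).
// [[Rcpp::export(name = ".cpp_spacer_hits")]]
DataFrame cpp_spacer_hits(CharacterVector spacers, CharacterVector refs,
                          int max_mm, int word) {
  KmerIndex idx; idx.k = word;
  std::vector<std::string> sp(spacers.size());
  for (int s = 0; s < spacers.size(); ++s) {
    sp[s] = as<std::string>(spacers[s]);
    index_sequence(idx, sp[s], s);
  }
  std::vector<int> out_sp, out_ref, out_start, out_mm;
  for (int r = 0; r < refs.size(); ++r) {
    std::string ref = as<std::string>(refs[r]);
    std::unordered_set<uint64_t> seen;
    for_each_kmer(ref, word, [&](int pos, uint64_t key) {
      auto it = idx.map.find(key);
      if (it == idx.map.end()) return;
      for (uint64_t packed : it->second) {
        int s = (int)(packed >> 32);
        int off = (int)(uint32_t)packed;
        long start = (long)pos - off;
        const std::string& spc = sp[s];
        if (start < 0 || start + (long)spc.size() > (long)ref.size()) continue;
        uint64_t dedup = ((uint64_t)s << 32) | (uint32_t)start;
        if (!seen.insert(dedup).second) continue;
        int mm = 0;
        for (size_t i = 0; i < spc.size() && mm <= max_mm; ++i)
          if (spc[i] != ref[(size_t)start + i]) ++mm;
        if (mm <= max_mm) {
          out_sp.push_back(s + 1); out_ref.push_back(r + 1);
          out_start.push_back((int)start); out_mm.push_back(mm);
        }
      }
    });
  }
  return DataFrame::create(_["spacer"] = out_sp, _["ref"] = out_ref,
                           _["start"] = out_start, _["mismatches"] = out_mm);
}

// Best identity of read against any candidate placement in refs, allowing at
// most one indel (split between adjacent diagonals). Identity is counted
// over read positions: an unaligned or inserted read base scores as a
// mismatch, so identity = matches / read length.
// [[Rcpp::export(name = ".cpp_subtract_hits")]]
LogicalVector cpp_subtract_hits(CharacterVector reads, CharacterVector refs,
                                int k, double min_ident, int max_indel,
                                int max_bucket, int step) {
  if (max_indel > 1) stop("max_indel > 1 is not supported");
  KmerIndex idx; idx.k = k;
  std::vector<std::string> refstr(refs.size());
  for (int r = 0; r < refs.size(); ++r) {
    refstr[r] = as<std::string>(refs[r]);
    index_sequence(idx, refstr[r], r);
  }
  LogicalVector out(reads.size());
  std::vector<std::pair<int, long>> cand;
  std::vector<int> m0, mp, mm;
  for (int q = 0; q < reads.size(); ++q) {
    std::string read = as<std::string>(reads[q]);
    const int L = (int)read.size();
    const int need = (int)std::ceil(min_ident * L);
    cand.clear();
    read_candidates(read, idx, (size_t)max_bucket, step, cand);
    bool hit = false;
    for (auto& cd : cand) {
      const std::string& ref = refstr[cd.first];
      const long d = cd.second, R = (long)ref.size();
      auto at = [&](long rp, int i) {
        return (rp >= 0 && rp < R && read[i] == ref[(int)rp]) ? 1 : 0;
      };
      int ung = 0;
      for (int i = 0; i < L; ++i) ung += at(d + i, i);
      int best = ung;
      if (max_indel >= 1) {
        m0.assign(L, 0); mp.assign(L, 0); mm.assign(L, 0);
        for (int i = 0; i < L; ++i) {
          m0[i] = at(d + i, i);
          mp[i] = at(d + 1 + i, i);   // suffix after a deleted read gap
          mm[i] = at(d - 1 + i, i);   // suffix after an inserted read base
        }
        // deletion in read (extra ref base): prefix on d, suffix on d+1
        int suf = 0;
        std::vector<int> sufp(L + 1, 0);
        for (int i = L - 1; i >= 0; --i) { suf += mp[i]; sufp[i] = suf; }
        int pre = 0;
        for (int s = 0; s <= L; ++s) {
          int sc = pre + sufp[s];
          if (sc > best) best = sc;
          if (s < L) pre += m0[s];
        }
        // insertion in read (read base s unaligned): prefix d, suffix d-1
        suf = 0;
        std::vector<int> sufm(L + 1, 0);
        for (int i = L - 1; i >= 0; --i) { suf += mm[i]; sufm[i] = suf; }
        pre = 0;
        for (int s = 0; s < L; ++s) {
          int sc = pre + (s + 1 <= L ? sufm[s + 1] : 0);
          if (sc > best) best = sc;
          pre += m0[s];
        }
      }
      if (best >= need) { hit = true; break; }
    }
    out[q] = hit;
  }
  return out;
}

// CRT-style tandem repeat array detection: exact seed of length `seedlen`
// recurring within the repeat+spacer window founds an array; copies are
// extended maximally, then the array is walked outward allowing up to
// max_mm substitutions per additional copy.
// [[Rcpp::export(name = ".cpp_detect_crispr")]]
List cpp_detect_crispr(std::string s, int min_rep, int max_rep,
                       int min_spacer, int max_spacer, int min_copies,
                       int max_mm, int seedlen) {
  const int n = (int)s.size();
  std::unordered_map<uint64_t, std::vector<int>> pos;
  for_each_kmer(s, seedlen, [&](int p, uint64_t key) {
    pos[key].push_back(p);
  });
  auto mismatches = [&](int a, int b, int len, int cap) {
    int mm = 0;
    for (int i = 0; i < len && mm <= cap; ++i)
      if (s[a + i] != s[b + i]) ++mm;
    return mm;
  };
  List arrays;
  const int dmin = min_rep + min_spacer, dmax = max_rep + max_spacer;
  int i = 0;
  uint64_t key = 0, mask = (1ULL << (2 * seedlen)) - 1;
  // recompute rolling key per i (simple; genomes are modest)
  while (i + seedlen <= n) {
    key = 0;
    bool ok = true;
    for (int t = 0; t < seedlen; ++t) {
      int c = base_code(s[i + t]);
      if (c < 0) { ok = false; break; }
      key = ((key << 2) | (uint64_t)c) & mask;
    }
    if (!ok) { ++i; continue; }
    auto it = pos.find(key);
    int j = -1;
    if (it != pos.end()) {
      for (int p : it->second) {
        if (p - i >= dmin && p - i <= dmax) { j = p; break; }
        if (p - i > dmax) break;
      }
    }
    if (j < 0) { ++i; continue; }
    // extend the seeded pair into a maximal shared word
    int l = 0;
    while (i - l - 1 >= 0 && s[i - l - 1] == s[j - l - 1]) ++l;
    int r = 0;
    while (i + seedlen + r < j - l && j + seedlen + r < n &&
           s[i + seedlen + r] == s[j + seedlen + r]) ++r;
    int rep_len = l + seedlen + r;
    rep_len = std::min(rep_len, max_rep);
    rep_len = std::min(rep_len, (j - i) - min_spacer);
    if (rep_len < min_rep) { ++i; continue; }
    int spacer_len = (j - i) - rep_len;
    if (spacer_len < min_spacer || spacer_len > max_spacer) { ++i; continue; }
    int start1 = i - l, start2 = j - l;
    std::vector<int> starts = {start1, start2};
    // walk right
    int cur = start2;
    while (true) {
      int best_t = -1, best_mm = max_mm + 1;
      for (int t = cur + rep_len + min_spacer;
           t <= cur + rep_len + max_spacer && t + rep_len <= n; ++t) {
        int mmv = mismatches(start1, t, rep_len, max_mm);
        if (mmv < best_mm) { best_mm = mmv; best_t = t; }
      }
      if (best_t < 0 || best_mm > max_mm) break;
      starts.push_back(best_t);
      cur = best_t;
    }
    // walk left
    cur = start1;
    while (true) {
      int best_t = -1, best_mm = max_mm + 1;
      for (int t = cur - rep_len - max_spacer;
           t <= cur - rep_len - min_spacer; ++t) {
        if (t < 0) continue;
        int mmv = mismatches(start1, t, rep_len, max_mm);
        if (mmv < best_mm) { best_mm = mmv; best_t = t; }
      }
      if (best_t < 0 || best_mm > max_mm) break;
      starts.insert(starts.begin(), best_t);
      cur = best_t;
    }
    std::sort(starts.begin(), starts.end());
    if ((int)starts.size() >= min_copies) {
      arrays.push_back(List::create(
        _["start"] = starts.front(),
        _["end"] = starts.back() + rep_len,
        _["repeat_len"] = rep_len,
        _["repeat_starts"] = IntegerVector(starts.begin(), starts.end())));
      i = starts.back() + rep_len;
    } else {
      ++i;
    }
  }
  return arrays;
}
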