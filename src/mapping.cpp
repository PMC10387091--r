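#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// 2-bit nucleotide encoding; -1 for anything outside ACGT (upper case).
static inline int enc(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}
static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  case 'N': return 'N';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(std::string(seqs[i]));
  return out;
}

// Collect all k-mer hashes of s into (hash, position) pairs; windows containing
// non-ACGT bases are skipped.
template <typename F>
static void for_each_kmer(const std::string& s, int k, F fun) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int e = enc(s[i]);
    if (e < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)e) & mask;
    if (++run >= k) fun(h, (int)(i + 1 - k));
  }
}

struct SeedIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // hash -> packed (seq_idx << 32 | pos)
  std::unordered_map<uint64_t, std::vector<uint64_t>> table;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 1 || k > 32) stop("seed length k must be in 1..32");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s(seqs[i]);
    if ((int)s.size() < k)
      stop("scaffold '%s' is shorter than the seed length", std::string(names[i]).c_str());
    idx->names.push_back(std::string(names[i]));
    idx->seqs.push_back(s);
    for_each_kmer(s, k, [&](uint64_t h, int pos) {
      idx->table[h].push_back(((uint64_t)i << 32) | (uint32_t)pos);
    });
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
int cpp_index_k(SEXP xp) { return XPtr<SeedIndex>(xp)->k; }

// [[Rcpp::export]]
int cpp_index_n_seeds(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  size_t n = 0;
  for (auto& kv : idx->table) n += kv.second.size();
  return (int)n;
}

// [[Rcpp::export]]
DataFrame cpp_index_lookup(SEXP xp, std::string seed) {
  XPtr<SeedIndex> idx(xp);
  if ((int)seed.size() != idx->k) stop("seed length does not match index k");
  std::vector<int> si, pos;
  uint64_t h = 0;
  bool ok = true;
  for (char c : seed) { int e = enc(c); if (e < 0) { ok = false; break; } h = (h << 2) | (uint64_t)e; }
  if (ok) {
    auto it = idx->table.find(h);
    if (it != idx->table.end())
      for (uint64_t p : it->second) { si.push_back((int)(p >> 32)); pos.push_back((int)(p & 0xffffffffULL)); }
  }
  return DataFrame::create(_["seq_idx"] = si, _["pos"] = pos);
}

static int hamming(const std::string& a, const std::string& t, int tpos) {
  int mm = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != t[tpos + i]) ++mm;
  return mm;
}

// Map reads by exact-seed chaining on (scaffold, diagonal, strand) plus full-length
// ungapped extension. Returns one row per candidate placement (capped at max_hits
// per read after sorting by mismatches, then scaffold name, position, strand).
// [[Rcpp::export]]
DataFrame cpp_map_reads(SEXP xp, CharacterVector reads, int max_hits, bool best_only) {
  XPtr<SeedIndex> idx(xp);
  const int k = idx->k;
  std::vector<int> o_read, o_tidx, o_tstart, o_mm;
  std::vector<int> o_strand; // 0 = plus, 1 = minus
  std::vector<int> o_unique;

  struct Cand { int tidx, tstart, strand, mm; };
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string fwd(reads[r]);
    int len = (int)fwd.size();
    if (len < k) continue;
    std::string rev = revcomp(fwd);
    std::unordered_set<uint64_t> seen;
    std::vector<Cand> cands;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = strand == 0 ? fwd : rev;
      for_each_kmer(q, k, [&](uint64_t h, int qpos) {
        auto it = idx->table.find(h);
        if (it == idx->table.end()) return;
        for (uint64_t p : it->second) {
          int tidx = (int)(p >> 32);
          int tpos = (int)(p & 0xffffffffULL);
          int tstart = tpos - qpos;
          if (tstart < 0) continue;
          if (tstart + len > (int)idx->seqs[tidx].size()) continue;
          uint64_t key = ((uint64_t)strand << 63) | ((uint64_t)tidx << 32) | (uint32_t)tstart;
          if (!seen.insert(key).second) continue;
          cands.push_back({tidx, tstart, strand, hamming(q, idx->seqs[tidx], tstart)});
        }
      });
    }
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end(), [&](const Cand& a, const Cand& b) {
      if (a.mm != b.mm) return a.mm < b.mm;
      int c = idx->names[a.tidx].compare(idx->names[b.tidx]);
      if (c != 0) return c < 0;
      if (a.tstart != b.tstart) return a.tstart < b.tstart;
      return a.strand < b.strand;
    });
    int best = cands[0].mm;
    bool uniq = cands.size() == 1 || cands[1].mm > best;
    int keep = std::min((int)cands.size(), max_hits);
    if (best_only) {
      int nb = 0;
      while (nb < keep && cands[nb].mm == best) ++nb;
      keep = nb;
    }
    for (int i = 0; i < keep; ++i) {
      o_read.push_back((int)r + 1);
      o_tidx.push_back(cands[i].tidx + 1);
      o_tstart.push_back(cands[i].tstart);
      o_strand.push_back(cands[i].strand);
      o_mm.push_back(cands[i].mm);
      o_unique.push_back(uniq && cands[i].mm == best ? 1 : 0);
    }
  }
  return DataFrame::create(
    _["read"] = o_read, _["target_idx"] = o_tidx, _["target_start"] = o_tstart,
    _["minus"] = o_strand, _["mismatches"] = o_mm, _["unique_best"] = o_unique);
}

// Brute-force oracle: minimum Hamming distance over every full-length placement on
// both strands of every reference sequence. Returns all placements achieving it.
// [[Rcpp::export]]
DataFrame cpp_hamming_scan(CharacterVector refs, CharacterVector names, std::string read) {
  int len = (int)read.size();
  std::string rev = revcomp(read);
  int best = len + 1;
  std::vector<int> ti, ts, st;
  for (R_xlen_t i = 0; i < refs.size(); ++i) {
    std::string t(refs[i]);
    for (int pos = 0; pos + len <= (int)t.size(); ++pos) {
      for (int strand = 0; strand < 2; ++strand) {
        const std::string& q = strand == 0 ? read : rev;
        int mm = hamming(q, t, pos);
        if (mm < best) { best = mm; ti.clear(); ts.clear(); st.clear(); }
        if (mm == best) { ti.push_back((int)i + 1); ts.push_back(pos); st.push_back(strand); }
      }
    }
  }
  DataFrame out = DataFrame::create(_["target_idx"] = ti, _["target_start"] = ts, _["minus"] = st);
  out.attr("mismatches") = best <= len ? best : NA_INTEGER;
  return out;
}

// Which of `kmers` (all the same length) occur, on either strand, as an exact
// substring of any read?
// [[Rcpp::export]]
LogicalVector cpp_kmers_in_reads(CharacterVector kmers, CharacterVector reads) {
  LogicalVector found(kmers.size(), false);
  if (kmers.size() == 0) return found;
  int k = (int)std::string(kmers[0]).size();
  if (k < 1 || k > 32) stop("kmer length must be in 1..32");
  std::unordered_map<uint64_t, std::vector<int>> want;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s(kmers[i]);
    if ((int)s.size() != k) stop("all kmers must have equal length");
    int n_add = 0;
    for_each_kmer(s, k, [&](uint64_t h, int) { want[h].push_back((int)i); ++n_add; });
    std::string rc = revcomp(s);
    for_each_kmer(rc, k, [&](uint64_t h, int) { want[h].push_back((int)i); ++n_add; });
    if (n_add == 0) stop("kmer contains non-ACGT characters");
  }
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s(reads[r]);
    for_each_kmer(s, k, [&](uint64_t h, int) {
      auto it = want.find(h);
      if (it != want.end()) for (int i : it->second) found[i] = true;
    });
  }
  return found;
}

// Which reads contain (on either strand of the read) at least one of `kmers`?
// [[Rcpp::export]]
LogicalVector cpp_reads_with_kmers(CharacterVector kmers, CharacterVector reads) {
  LogicalVector hit(reads.size(), false);
  if (kmers.size() == 0) return hit;
  int k = (int)std::string(kmers[0]).size();
  if (k < 1 || k > 32) stop("kmer length must be in 1..32");
  std::unordered_set<uint64_t> want;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s(kmers[i]);
    if ((int)s.size() != k) stop("all kmers must have equal length");
    for_each_kmer(s, k, [&](uint64_t h, int) { want.insert(h); });
    std::string rc = revcomp(s);
    for_each_kmer(rc, k, [&](uint64_t h, int) { want.insert(h); });
  }
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s(reads[r]);
    bool any = false;
    for_each_kmer(s, k, [&](uint64_t h, int) {
      if (!any && want.count(h)) any = true;
    });
    hit[r] = any;
  }
  return hit;
}

// Per-base A/C/G/T counts over one reference sequence from ungapped placements.
// seqs[i] is the read as sequenced; minus[i] placements are reverse-complemented
// before being laid down.
// [[Rcpp::export]]
IntegerMatrix cpp_base_counts(int ref_len, IntegerVector starts, LogicalVector minus,
                              CharacterVector seqs) {
  IntegerMatrix counts(4, ref_len);
  for (R_xlen_t i = 0; i < starts.size(); ++i) {
    std::string s(seqs[i]);
    if (minus[i]) s = revcomp(s);
    int st = starts[i];
    for (size_t j = 0; j < s.size(); ++j) {
      int p = st + (int)j;
      if (p < 0 || p >= ref_len) continue;
      int e = enc(s[j]);
      if (e >= 0) counts(e, p) += 1;
    }
  }
  return counts;
}

// Per-base oracle for germline-specific region detection: scan base by base,
// emitting maximal runs with testis depth >= 1 and kidney depth == 0, length >=
// min_len. Used as an independent cross-check of the rle-based implementation.
// [[Rcpp::export]]
DataFrame cpp_scan_germline_runs(IntegerVector testis, IntegerVector kidney, int min_len) {
  if (testis.size() != kidney.size()) stop("track length mismatch");
  std::vector<int> st, en;
  int n = (int)testis.size();
  int run_start = -1;
  for (int i = 0; i <= n; ++i) {
    bool ok = i < n && testis[i] >= 1 && kidney[i] == 0;
    if (ok && run_start < 0) run_start = i;
    if (!ok && run_start >= 0) {
      if (i - run_start >= min_len) { st.push_back(run_start); en.push_back(i); }
      run_start = -1;
    }
  }
  return DataFrame::create(_["start"] = st, _["end"] = en);
}
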