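// Seed-and-extend ungapped bisulfite alignment against a small (mitochondrial
// scale) reference held fully in memory.
//
// Each read is matched in the four bisulfite conversion modes:
//   mode 1: CtoT(read)          vs CtoT(genome)   (OT mate orientation)
//   mode 2: CtoT(revcomp(read)) vs CtoT(genome)   (complement of mode 1)
//   mode 3: GtoA(read)          vs GtoA(genome)   (CTOB mate orientation)
//   mode 4: GtoA(revcomp(read)) vs GtoA(genome)   (complement of mode 3)
// Converted-space comparison makes the alignment blind to methylation state.
// The unique best hit (fewest mismatches, strictly better than the runner-up
// across all modes) is reported; ties leave the read unmapped. Circular
// references are handled by doubling the sequence and reporting start
// positions modulo length.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return 4;
  }
}

static std::string convert_ct(const std::string& s) {
  std::string r = s;
  for (char& c : r) if (c == 'C') c = 'T';
  return r;
}

static std::string convert_ga(const std::string& s) {
  std::string r = s;
  for (char& c : r) if (c == 'G') c = 'A';
  return r;
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default: c = 'N';
    }
  }
  return r;
}

typedef std::unordered_map<uint64_t, std::vector<int32_t> > KmerIndex;

// index k-mers starting at 0..L-1 of `dbl` (doubled reference)
static KmerIndex build_index(const std::string& dbl, int L, int k) {
  KmerIndex idx;
  idx.reserve(L * 2);
  for (int p = 0; p < L; ++p) {
    uint64_t key = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = base_code(dbl[p + j]);
      if (c > 3) { ok = false; break; }
      key = (key << 2) | (uint64_t)c;
    }
    if (ok) idx[key].push_back(p);
  }
  return idx;
}

static inline bool kmer_key(const std::string& s, int pos, int k,
                            uint64_t& key) {
  key = 0;
  for (int j = 0; j < k; ++j) {
    int c = base_code(s[pos + j]);
    if (c > 3) return false;
    key = (key << 2) | (uint64_t)c;
  }
  return true;
}

static inline int count_mm(const std::string& q, const std::string& dbl,
                           int start, int cap) {
  int mm = 0;
  const int n = (int)q.size();
  for (int j = 0; j < n; ++j) {
    if (q[j] != dbl[start + j]) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

struct Best {
  int mm = INT_MAX;
  int mm2 = INT_MAX;  // runner-up
  int mode = 0;
  int start = -1;     // 0-based on [0, L)
};

// [[Rcpp::export(name = ".align_reads_cpp")]]
DataFrame align_reads_cpp(CharacterVector reads, std::string ref,
                          bool circular, int k, int max_mm) {
  const int L = (int)ref.size();
  if (k < 8 || k > 31) stop("seed length k must be in [8, 31]");
  std::string ref_ct = convert_ct(ref);
  std::string ref_ga = convert_ga(ref);
  std::string dbl_ct = ref_ct + (circular ? ref_ct : std::string());
  std::string dbl_ga = ref_ga + (circular ? ref_ga : std::string());

  KmerIndex idx_ct = build_index(circular ? dbl_ct : ref_ct,
                                 circular ? L : std::max(0, L - k + 1), k);
  KmerIndex idx_ga = build_index(circular ? dbl_ga : ref_ga,
                                 circular ? L : std::max(0, L - k + 1), k);

  const int n = reads.size();
  IntegerVector out_mode(n), out_start(n), out_mm(n), out_mm2(n);
  LogicalVector out_unique(n);

  std::vector<std::pair<int, int> > seen;  // (mode, start) candidates tried

  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    const int len = (int)r.size();
    Best best;
    if (len >= k) {
      std::string rc = revcomp(r);
      std::string q[4] = { convert_ct(r), convert_ct(rc),
                           convert_ga(r), convert_ga(rc) };
      int offs[3] = { 0, (len - k) / 2, len - k };
      seen.clear();
      for (int m = 0; m < 4; ++m) {
        const KmerIndex& idx = (m < 2) ? idx_ct : idx_ga;
        const std::string& dbl = (m < 2) ? dbl_ct : dbl_ga;
        for (int s = 0; s < 3; ++s) {
          int off = offs[s];
          if (s > 0 && off == offs[s - 1]) continue;
          uint64_t key;
          if (!kmer_key(q[m], off, k, key)) continue;
          KmerIndex::const_iterator it = idx.find(key);
          if (it == idx.end()) continue;
          for (size_t c = 0; c < it->second.size(); ++c) {
            int start = it->second[c] - off;
            if (circular) {
              start = ((start % L) + L) % L;
            } else if (start < 0 || start + len > L) {
              continue;
            }
            bool dup = false;
            for (size_t z = 0; z < seen.size(); ++z) {
              if (seen[z].first == m && seen[z].second == start) {
                dup = true; break;
              }
            }
            if (dup) continue;
            seen.push_back(std::make_pair(m, start));
            int cap = (best.mm2 == INT_MAX) ? len : best.mm2;
            int mm = count_mm(q[m], dbl, start, cap);
            if (mm < best.mm) {
              best.mm2 = best.mm;
              best.mm = mm;
              best.mode = m + 1;
              best.start = start;
            } else if (mm < best.mm2) {
              best.mm2 = mm;
            }
          }
        }
      }
    }
    if (best.start >= 0 && best.mm <= max_mm) {
      out_mode[i] = best.mode;
      out_start[i] = best.start + 1;  // 1-based
      out_mm[i] = best.mm;
      out_mm2[i] = (best.mm2 == INT_MAX) ? NA_INTEGER : best.mm2;
      out_unique[i] = (best.mm2 == INT_MAX) || (best.mm < best.mm2);
    } else {
      out_mode[i] = NA_INTEGER;
      out_start[i] = NA_INTEGER;
      out_mm[i] = NA_INTEGER;
      out_mm2[i] = NA_INTEGER;
      out_unique[i] = false;
    }
  }

  return DataFrame::create(
    _["mode"] = out_mode, _["start"] = out_start, _["mismatches"] = out_mm,
    _["second_mismatches"] = out_mm2, _["unique"] = out_unique
  );
}
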