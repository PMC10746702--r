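// k-mer counting and read assignment.
//
// k-mers are 2-bit encoded (A=0,C=1,G=2,T=3) into 64-bit words, which caps
// k at 31; the canonical form of a k-mer is the lexicographic minimum of the
// k-mer and its reverse complement. Windows containing any non-ACGT symbol
// (N and friends) are skipped. Both the histogram and the read assigner
// stream with rolling forward/reverse codes, so each base is O(1).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

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

// Visit every canonical k-mer of seq, calling f(code).
template <typename F>
static void for_each_canonical(const char* seq, int n, int k, F f) {
  if (n < k) return;
  uint64_t fwd = 0, rev = 0;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  const int shift = 2 * (k - 1);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++valid >= k) f(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export(name = ".kmer_hist_cpp")]]
IntegerMatrix kmer_hist_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_map<uint64_t, uint32_t> counts;
  counts.reserve(1 << 20);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* p = CHAR(STRING_ELT(seqs, s));
    int n = LENGTH(STRING_ELT(seqs, s));
    for_each_canonical(p, n, k, [&](uint64_t code) { ++counts[code]; });
  }
  std::unordered_map<uint32_t, uint32_t> hist;
  for (const auto& kv : counts) ++hist[kv.second];
  IntegerMatrix out(hist.size(), 2);
  R_xlen_t i = 0;
  for (const auto& kv : hist) {
    out(i, 0) = (int)kv.first;  // multiplicity
    out(i, 1) = (int)kv.second; // number of distinct k-mers
    ++i;
  }
  colnames(out) = CharacterVector::create("multiplicity", "n_kmers");
  return out;
}

// Assign each read to the contig sharing the most canonical k-mers.
// Returns 1-based contig indices; 0 = unassigned (tie or no shared k-mer).
// [[Rcpp::export(name = ".kmer_assign_cpp")]]
IntegerVector kmer_assign_cpp(CharacterVector reads, CharacterVector contigs,
                              int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  // index: k-mer -> contig index, or -1 when the k-mer occurs in several
  // contigs (overflow list holds the full set, deduplicated per k-mer)
  std::unordered_map<uint64_t, int32_t> index;
  std::unordered_map<uint64_t, std::vector<int32_t> > overflow;
  index.reserve(1 << 21);
  for (int ci = 0; ci < contigs.size(); ++ci) {
    const char* p = CHAR(STRING_ELT(contigs, ci));
    int n = LENGTH(STRING_ELT(contigs, ci));
    for_each_canonical(p, n, k, [&](uint64_t code) {
      auto it = index.find(code);
      if (it == index.end()) {
        index.emplace(code, ci);
      } else if (it->second >= 0) {
        if (it->second != ci) {
          overflow[code] = {it->second, ci};
          it->second = -1;
        }
      } else {
        std::vector<int32_t>& v = overflow[code];
        if (v.back() != ci) v.push_back(ci);
      }
    });
  }
  int nc = contigs.size();
  std::vector<int32_t> tally(nc, 0);
  std::vector<int32_t> touched;
  IntegerVector out(reads.size());
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* p = CHAR(STRING_ELT(reads, r));
    int n = LENGTH(STRING_ELT(reads, r));
    touched.clear();
    for_each_canonical(p, n, k, [&](uint64_t code) {
      auto it = index.find(code);
      if (it == index.end()) return;
      if (it->second >= 0) {
        if (tally[it->second]++ == 0) touched.push_back(it->second);
      } else {
        for (int32_t ci : overflow[code]) {
          if (tally[ci]++ == 0) touched.push_back(ci);
        }
      }
    });
    int best = -1, best_count = 0;
    bool tie = false;
    for (int32_t ci : touched) {
      if (tally[ci] > best_count) {
        best = ci; best_count = tally[ci]; tie = false;
      } else if (tally[ci] == best_count) {
        tie = true;
      }
      tally[ci] = 0;
    }
    out[r] = (best >= 0 && !tie) ? best + 1 : 0;
  }
  return out;
}
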