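#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

// 2-bit base codes; 4 = ambiguous (anything not ACGT/acgt)
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

// Fixed 64-bit invertible integer mix (splitmix64 finalizer); unseeded so
// minimizer selection is fully deterministic across runs.
static inline uint64_t hash64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static const uint64_t KM_INVALID = UINT64_MAX;

static std::string hash_hex(uint64_t h) {
  static const char *dig = "0123456789abcdef";
  std::string s(16, '0');
  for (int t = 15; t >= 0; --t) {
    s[t] = dig[h & 0xf];
    h >>= 4;
  }
  return s;
}

// (w,k)-minimizer winnowing over one sequence.
// For every window of w consecutive k-mers the k-mer with minimal hash is
// selected (leftmost on hash ties); consecutive windows selecting the same
// position emit it once. K-mers covering non-ACGT bases and k-mers equal to
// their own reverse complement are skipped (treated as absent). Positions are
// 0-based END coordinates of the k-mer; strand is '+' when the forward k-mer
// is the lexicographically smaller of the pair.
// [[Rcpp::export]]
DataFrame extract_minimizers_cpp(std::string seq, int k, int w) {
  size_t L = seq.size();
  std::vector<std::string> out_hash;
  std::vector<int> out_pos;
  std::vector<std::string> out_strand;
  if (k < 1 || w < 1)
    stop("k and w must be >= 1");
  if (k > 31)
    stop("k must be <= 31 for 64-bit packing");
  if (L >= (size_t)k) {
    size_t m = L - k + 1;                       // number of k-mer slots
    std::vector<uint64_t> h(m, KM_INVALID);
    std::vector<uint8_t> fwd_lt(m, 1);          // forward < revcomp ?
    uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : UINT64_MAX;
    uint64_t kf = 0, kr = 0;
    int shift = 2 * (k - 1), run = 0;           // run = valid bases in window
    for (size_t p = 0; p < L; ++p) {
      int c = base_code(seq[p]);
      if (c < 4) {
        kf = ((kf << 2) | (uint64_t)c) & mask;
        kr = (kr >> 2) | ((uint64_t)(3 - c) << shift);
        ++run;
      } else {
        kf = kr = 0;
        run = 0;
      }
      if (run >= k) {
        size_t t = p - (size_t)k + 1;           // k-mer slot index
        if (kf != kr) {                         // skip palindromic k-mers
          uint64_t canon = kf < kr ? kf : kr;
          h[t] = hash64(canon);
          fwd_lt[t] = kf < kr ? 1 : 0;
        }
      }
    }
    if (m >= (size_t)w) {
      long long last_sel = -1;
      for (size_t s = 0; s + (size_t)w <= m; ++s) {
        size_t best = s;
        for (size_t t = s + 1; t < s + (size_t)w; ++t)
          if (h[t] < h[best]) best = t;         // leftmost minimal hash
        if (h[best] == KM_INVALID) continue;    // window has no valid k-mer
        if ((long long)best != last_sel) {
          out_hash.push_back(hash_hex(h[best]));
          out_pos.push_back((int)(best + k - 1));
          out_strand.push_back(fwd_lt[best] ? "+" : "-");
          last_sel = (long long)best;
        }
      }
    }
  }
  return DataFrame::create(_["hash"] = out_hash,
                           _["pos"] = out_pos,
                           _["strand"] = out_strand,
                           _["stringsAsFactors"] = false);
}
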