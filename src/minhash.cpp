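#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// 64-bit finalizer (splitmix64); good avalanche, cheap, deterministic.
static inline uint64_t mix64(uint64_t z) {
    z += 0x9e3779b97f4a7c15ULL;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
}

// Canonical k-mer hashes of one nucleotide sequence. A k-mer is hashed as the
// lexicographic minimum of itself and its reverse complement (2-bit encoded);
// windows containing non-ACGT characters are skipped. Hashes are truncated to
// 53 bits so they round-trip exactly through R doubles.
// [[Rcpp::export(name = ".kmerHashes")]]
NumericVector kmer_hashes(const std::string& seq, int k) {
    const uint64_t mask53 = (1ULL << 53) - 1;
    size_t n = seq.size();
    std::vector<double> out;
    if (k < 1 || n < (size_t)k) return NumericVector(0);
    out.reserve(n - k + 1);

    const uint64_t kmask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t fwd = 0, rev = 0;
    int valid = 0;  // number of consecutive valid bases ending here
    for (size_t i = 0; i < n; ++i) {
        int code;
        switch (seq[i]) {
            case 'A': case 'a': code = 0; break;
            case 'C': case 'c': code = 1; break;
            case 'G': case 'g': code = 2; break;
            case 'T': case 't': code = 3; break;
            default: code = -1;
        }
        if (code < 0) { valid = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)code) & kmask;
        rev = (rev >> 2) | ((uint64_t)(3 - code) << (2 * (k - 1)));
        if (++valid >= k) {
            uint64_t canon = fwd < rev ? fwd : rev;
            out.push_back((double)(mix64(canon) & mask53));
        }
    }
    return wrap(out);
}
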