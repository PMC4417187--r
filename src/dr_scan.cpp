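#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Enumerate every maximal same-strand repeated pair of length >= min_len.
//
// For each offset d = pos2 - pos1, positions i where seq[i] == seq[i + d]
// form runs; each run of length L >= min_len is exactly one maximal pair
// (extending it one base either way breaks equality or hits a boundary),
// and each maximal pair has a unique offset, so none is reported twice.
//
// The comparison is bit-parallel: bases are packed 2 bits each, 32 per
// 64-bit word. For a chunk of 32 positions, XOR of the aligned and
// offset-shifted words marks equal bases with two zero bits; those are
// folded to a 32-bit equality mask whose runs of ones are extracted with
// count-trailing-zero scans, carrying open runs across chunk boundaries.
// O(n^2 / 32) word operations: a mitochondrial genome scans in ~0.1 s.

static inline uint64_t compress_even_bits(uint64_t x) {
    // input: bits only at even positions 0,2,..,62; output: packed low 32
    x &= 0x5555555555555555ULL;
    x = (x | (x >> 1)) & 0x3333333333333333ULL;
    x = (x | (x >> 2)) & 0x0F0F0F0F0F0F0F0FULL;
    x = (x | (x >> 4)) & 0x00FF00FF00FF00FFULL;
    x = (x | (x >> 8)) & 0x0000FFFF0000FFFFULL;
    x = (x | (x >> 16)) & 0x00000000FFFFFFFFULL;
    return x;
}

// [[Rcpp::export]]
DataFrame scan_direct_repeats_cpp(std::string seq, int min_len) {
    const int n = (int) seq.size();
    std::vector<int> p1, p2, len;
    if (n >= 2 && min_len >= 1) {
        const int W = (n + 31) / 32;
        std::vector<uint64_t> P(W + 2, 0ULL);
        for (int i = 0; i < n; ++i) {
            int code;
            switch (seq[i]) {
                case 'A': code = 0; break;
                case 'C': code = 1; break;
                case 'G': code = 2; break;
                case 'T': code = 3; break;
                default: stop("sequence contains characters outside A,C,G,T");
            }
            P[i >> 5] |= ((uint64_t) code) << (2 * (i & 31));
        }
        for (int d = 1; d < n; ++d) {
            const int m = n - d;          // comparable positions at offset d
            int run = 0;
            for (int i0 = 0; i0 < m; i0 += 32) {
                const int v = (m - i0 < 32) ? (m - i0) : 32;
                const uint64_t a = P[i0 >> 5]; // i0 is word-aligned
                const int q = (i0 + d) >> 5;
                const int r2 = 2 * ((i0 + d) & 31);
                const uint64_t b = r2 ? (P[q] >> r2) | (P[q + 1] << (64 - r2))
                                      : P[q];
                const uint64_t y = ~(a ^ b);
                uint64_t eq = compress_even_bits(y & (y >> 1));
                if (v < 32) eq &= (1ULL << v) - 1ULL;
                int pos = 0;
                while (pos < v) {
                    const uint64_t rem = eq >> pos;
                    if (rem & 1ULL) {
                        int ones = (int) __builtin_ctzll(~rem);
                        if (ones > v - pos) ones = v - pos;
                        run += ones;
                        pos += ones;
                        if (pos < v) {     // mismatch ends the run here
                            if (run >= min_len) {
                                const int start = i0 + pos - run;
                                p1.push_back(start);
                                p2.push_back(start + d);
                                len.push_back(run);
                            }
                            run = 0;
                        }
                    } else {
                        int zeros = rem ? (int) __builtin_ctzll(rem)
                                        : v - pos;
                        if (zeros > v - pos) zeros = v - pos;
                        if (run >= min_len) {  // run carried into this chunk
                            const int start = i0 + pos - run;
                            p1.push_back(start);
                            p2.push_back(start + d);
                            len.push_back(run);
                        }
                        run = 0;
                        pos += zeros;
                    }
                }
            }
            if (run >= min_len) {          // run reaching the sequence end
                p1.push_back(m - run);
                p2.push_back(m - run + d);
                len.push_back(run);
            }
        }
    }
    return DataFrame::create(_["pos1"] = p1, _["pos2"] = p2,
                             _["length"] = len);
}
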