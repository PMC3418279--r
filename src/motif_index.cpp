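#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int base_idx(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;   // N or anything else: window is discarded
    }
}

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
    return __builtin_popcountll(x);
#else
    int n = 0;
    while (x) { x &= x - 1; ++n; }
    return n;
#endif
}

// Depth-first expansion of the degenerate alphabet, one position at a time.
// T holds, for every concrete suffix of length L - j, the bitset of promoters
// containing (prefix-so-far + that suffix). Expanding position j to a
// degenerate letter ORs the tables of its constituent bases; at a leaf the
// popcount is the number of promoters harboring the fully degenerate word.
struct IndexDFS {
    int L, W, A;
    const std::vector<std::vector<int> >& lm;  // letter -> concrete base indices
    std::vector<std::vector<uint64_t> > buf;   // per-depth suffix tables
    std::vector<R_xlen_t> pow4;
    int* counts;
    R_xlen_t out;
    R_xlen_t leaves_since_check;

    IndexDFS(int L_, int W_, const std::vector<std::vector<int> >& lm_, int* counts_)
        : L(L_), W(W_), A((int)lm_.size()), lm(lm_), counts(counts_), out(0),
          leaves_since_check(0) {
        pow4.resize(L + 1);
        pow4[0] = 1;
        for (int i = 1; i <= L; ++i) pow4[i] = pow4[i - 1] * 4;
        buf.resize(L + 1);
        for (int j = 1; j <= L; ++j)
            buf[j].assign((size_t)pow4[L - j] * W, 0);
    }

    void run(int j, const std::vector<uint64_t>& T) {
        if (j == L) {
            long long c = 0;
            for (int w = 0; w < W; ++w) c += popcount64(T[w]);
            counts[out++] = (int)c;
            if (++leaves_since_check >= 1048576) {
                leaves_since_check = 0;
                Rcpp::checkUserInterrupt();
            }
            return;
        }
        const R_xlen_t suf = pow4[L - j - 1];
        std::vector<uint64_t>& T2 = buf[j + 1];
        for (int a = 0; a < A; ++a) {
            const std::vector<int>& bases = lm[a];
            const int nb = (int)bases.size();
            for (R_xlen_t s = 0; s < suf; ++s) {
                const size_t o2 = (size_t)s * W;
                for (int w = 0; w < W; ++w) {
                    uint64_t acc = 0;
                    for (int b = 0; b < nb; ++b)
                        acc |= T[((size_t)bases[b] * suf + s) * W + w];
                    T2[o2 + w] = acc;
                }
            }
            run(j + 1, T2);
        }
    }
};

// Promoter-presence counts for every degenerate word of length L over the
// given alphabet. letter_matches: list of integer vectors (0-based indices
// into A,C,G,T) giving each letter's concrete match set, in digit order.
// [[Rcpp::export]]
IntegerVector count_index_cpp(CharacterVector seqs, int L, List letter_matches) {
    const int A = letter_matches.size();
    if (L < 1 || L > 14) stop("word length L out of supported range");
    std::vector<std::vector<int> > lm(A);
    for (int i = 0; i < A; ++i) {
        IntegerVector v = letter_matches[i];
        for (int j = 0; j < v.size(); ++j) {
            if (v[j] < 0 || v[j] > 3) stop("match set indices must be in 0..3");
            lm[i].push_back(v[j]);
        }
    }
    long long total = 1;
    for (int i = 0; i < L; ++i) {
        total *= A;
        if (total > INT_MAX) stop("|alphabet|^L exceeds supported array size");
    }
    R_xlen_t n4 = 1;
    for (int i = 0; i < L; ++i) n4 *= 4;

    const int n = seqs.size();
    const int W = n == 0 ? 1 : (n + 63) / 64;
    std::vector<uint64_t> T0((size_t)n4 * W, 0);
    const R_xlen_t mask = n4 - 1;
    for (int i = 0; i < n; ++i) {
        const char* s = CHAR(STRING_ELT(seqs, i));
        R_xlen_t code = 0;
        int run = 0;
        for (const char* p = s; *p; ++p) {
            const int b = base_idx(*p);
            if (b < 0) { run = 0; code = 0; continue; }
            code = ((code << 2) | b) & mask;
            if (++run >= L)
                T0[(size_t)code * W + (i >> 6)] |= 1ULL << (i & 63);
        }
    }

    IntegerVector counts((R_xlen_t)total);
    IndexDFS dfs(L, W, lm, INTEGER(counts));
    dfs.run(0, T0);
    return counts;
}

// Occurrence tally over concrete L-mers: total instance count and sum of
// 1-based start positions for each of the 4^L words, across all promoters.
// [[Rcpp::export]]
List occurrence_tally_cpp(CharacterVector seqs, int L) {
    if (L < 1 || L > 14) stop("word length L out of supported range");
    R_xlen_t n4 = 1;
    for (int i = 0; i < L; ++i) n4 *= 4;
    NumericVector cnt(n4), psum(n4);
    const R_xlen_t mask = n4 - 1;
    for (int i = 0; i < seqs.size(); ++i) {
        const char* s = CHAR(STRING_ELT(seqs, i));
        R_xlen_t code = 0;
        int run = 0;
        long long pos = 0;  // 0-based index of current char
        for (const char* p = s; *p; ++p, ++pos) {
            const int b = base_idx(*p);
            if (b < 0) { run = 0; code = 0; continue; }
            code = ((code << 2) | b) & mask;
            if (++run >= L) {
                cnt[code] += 1.0;
                psum[code] += (double)(pos - L + 2);  // 1-based start
            }
        }
    }
    return List::create(_["count"] = cnt, _["pos_sum"] = psum);
}

// All 1-based start positions, per promoter, where the degenerate word
// matches. allow: L x 4 logical matrix, allow(i, b) true iff base b (A,C,G,T)
// is matched at word position i. 'N' in the sequence matches nothing.
// [[Rcpp::export]]
List collect_positions_cpp(CharacterVector seqs, LogicalMatrix allow) {
    const int L = allow.nrow();
    if (allow.ncol() != 4) stop("allow must have 4 columns");
    bool tab[32][4];
    if (L > 32) stop("word length too large");
    for (int i = 0; i < L; ++i)
        for (int b = 0; b < 4; ++b)
            tab[i][b] = allow(i, b);
    List out(seqs.size());
    for (int i = 0; i < seqs.size(); ++i) {
        const char* s = CHAR(STRING_ELT(seqs, i));
        const int len = (int)LENGTH(STRING_ELT(seqs, i));
        std::vector<int> hits;
        for (int start = 0; start + L <= len; ++start) {
            bool ok = true;
            for (int j = 0; j < L; ++j) {
                const int b = base_idx(s[start + j]);
                if (b < 0 || !tab[j][b]) { ok = false; break; }
            }
            if (ok) hits.push_back(start + 1);
        }
        out[i] = IntegerVector(hits.begin(), hits.end());
    }
    out.names() = seqs.names();
    return out;
}
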