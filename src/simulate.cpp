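#include <Rcpp.h>
#include <cmath>
#include "kmer_index.h"

using namespace Rcpp;

// Finalize simulated reads: reverse-complement the flagged ones, then apply
// i.i.d. substitution errors at `rate` (uniform choice among the three
// alternative bases).  Uses the R RNG, so results are governed by set.seed().
// Error positions are drawn by geometric skipping to keep the number of RNG
// draws proportional to the number of errors.
// [[Rcpp::export]]
CharacterVector cpp_finish_reads(CharacterVector seqs, LogicalVector revcomp,
                                 double rate) {
    const int n = seqs.size();
    CharacterVector out(n);
    std::string s;
    const char* bases = "ACGT";
    const double log1m = (rate > 0 && rate < 1) ? std::log1p(-rate) : 0.0;
    RNGScope scope;
    for (int r = 0; r < n; ++r) {
        s.assign(CHAR(STRING_ELT(seqs, r)));
        const int L = (int)s.size();
        if (revcomp[r]) {
            std::string rc(L, 'N');
            for (int i = 0; i < L; ++i) rc[L - 1 - i] = nt_complement(s[i]);
            s.swap(rc);
        }
        if (rate > 0) {
            if (rate >= 1) rate = 0.999999;
            double pos = std::floor(std::log(unif_rand()) / log1m);
            while (pos < L) {
                int i = (int)pos;
                uint8_t c = nt_code(s[i]);
                if (c != 255) {
                    int alt = (int)(unif_rand() * 3.0);
                    if (alt > 2) alt = 2;
                    // pick among the 3 bases != current
                    int b = (alt >= c) ? alt + 1 : alt;
                    s[i] = bases[b];
                }
                pos += 1.0 + std::floor(std::log(unif_rand()) / log1m);
            }
        }
        out[r] = s;
    }
    return out;
}

// Reverse complement of a character vector of sequences.
// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
    const int n = seqs.size();
    CharacterVector out(n);
    std::string s;
    for (int r = 0; r < n; ++r) {
        s.assign(CHAR(STRING_ELT(seqs, r)));
        const int L = (int)s.size();
        std::string rc(L, 'N');
        for (int i = 0; i < L; ++i) rc[L - 1 - i] = nt_complement(s[i]);
        out[r] = rc;
    }
    return out;
}
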