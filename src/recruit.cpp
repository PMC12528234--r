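#include <Rcpp.h>
#include <algorithm>
#include "kmer_index.h"

using namespace Rcpp;

// Build the recruiter index over a concatenated reference.
// block_start/block_end are half-open global intervals of the contig
// blocks, sorted in canonical order (genome id lexicographic, contig
// order); k-mers never span block boundaries.
// [[Rcpp::export]]
SEXP cpp_index_build(std::string ref, IntegerVector block_start,
                     IntegerVector block_end, int k) {
    XPtr<RefIndex> p(new RefIndex(), true);
    p->ref = std::move(ref);
    p->bs.assign(block_start.begin(), block_start.end());
    p->be.assign(block_end.begin(), block_end.end());
    p->idx.build(p->ref, p->bs, p->be, k);
    return p;
}

// TRUE iff the external pointer still holds a live index (it does not
// survive serialization).
// [[Rcpp::export]]
bool cpp_index_ok(SEXP xp) {
    if (TYPEOF(xp) != EXTPTRSXP) return false;
    return R_ExternalPtrAddr(xp) != NULL;
}

// Competitive best-hit placement of reads on an indexed reference.
//
// Candidate loci are found by exact k-mer seeding on both strands (probing
// every seed_stride-th k-mer start; the terminal k-mer is always probed)
// and scored by full-length ungapped mismatch count.  The best placement
// (fewest mismatches) is kept iff 100*(L - mm)/L >= min_identity; ties are
// broken by evaluation order -- ascending global coordinate on the +
// strand, then ascending global coordinate on the - strand -- which
// realizes the documented (genome id, coordinate, + strand) tie-break.
//
// Returns per read: found (logical), gstart (0-based global), strand
// (0 = +, 1 = -), mismatches.
// [[Rcpp::export]]
List cpp_recruit(SEXP xp, CharacterVector reads, double min_identity,
                 int seed_stride) {
    XPtr<RefIndex> p(xp);
    const RefIndex& R = *p;
    const int k = R.idx.k;
    const int n_reads = reads.size();

    LogicalVector found(n_reads);
    IntegerVector gstart(n_reads), strand(n_reads), mism(n_reads);

    const uint64_t kmask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    std::vector<int> cand, hitpos;
    std::string seq, rcseq;

    for (int r = 0; r < n_reads; ++r) {
        found[r] = false;
        seq.assign(CHAR(STRING_ELT(reads, r)));
        const int L = (int)seq.size();
        if (L < k) continue;

        const int mm_max =
            (int)std::floor(L * (1.0 - min_identity / 100.0) + 1e-9);
        bool have = false;
        int bpos = -1, bstrand = 0, bmm = 0;

        rcseq.resize(L);
        for (int i = 0; i < L; ++i) rcseq[L - 1 - i] = nt_complement(seq[i]);

        for (int st = 0; st < 2; ++st) {
            const std::string& q = (st == 0) ? seq : rcseq;
            cand.clear();
            for (int s = 0;; s += seed_stride) {
                if (s > L - k) {
                    if (s - seed_stride == L - k) break;
                    s = L - k;  // always probe the terminal seed
                }
                uint64_t km = 0;
                bool ok = true;
                for (int j = 0; j < k; ++j) {
                    uint8_t c = nt_code(q[s + j]);
                    if (c == 255) { ok = false; break; }
                    km = ((km << 2) | c) & kmask;
                }
                if (ok) {
                    hitpos.clear();
                    R.idx.lookup(km, hitpos);
                    for (int pp : hitpos) {
                        int c0 = pp - s;
                        if (c0 >= 0) cand.push_back(c0);
                    }
                }
                if (s == L - k) break;
            }
            std::sort(cand.begin(), cand.end());
            cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

            for (int c0 : cand) {
                int b = block_of(R.bs, R.be, c0);
                if (b < 0 || c0 + L > R.be[b]) continue;
                int limit = have ? bmm - 1 : mm_max;
                if (limit < 0) continue;
                int mm = 0;
                const char* rp = R.ref.data() + c0;
                for (int j = 0; j < L; ++j) {
                    if (rp[j] != q[j] && ++mm > limit) break;
                }
                if (mm <= limit) {
                    have = true; bpos = c0; bstrand = st; bmm = mm;
                    if (bmm == 0) break;
                }
            }
            if (have && bmm == 0) break;
        }
        if (have) {
            found[r] = true;
            gstart[r] = bpos;
            strand[r] = bstrand;
            mism[r] = bmm;
        }
    }
    return List::create(_["found"] = found, _["gstart"] = gstart,
                        _["strand"] = strand, _["mismatches"] = mism);
}
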