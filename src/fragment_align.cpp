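#include <Rcpp.h>
#include <algorithm>
#include "kmer_index.h"

using namespace Rcpp;

// Banded semi-global alignment of one fragment against a reference window.
// The fragment is aligned end-to-end; leading/trailing gaps on the window
// side are free.  Scores: match +1, mismatch -1, gap -2 (linear).  With
// these scores a gap pair is never preferred over a mismatch, so purely
// substitutional divergence stays on the main diagonal.
static void banded_align(const char* frag, int F, const char* win, int W,
                         int c0, int band, int& matches, int& columns,
                         int& frag_aligned) {
    const int NEG = -1000000000;
    const int width = 2 * band + 1;
    std::vector<int> D((size_t)(F + 1) * width, NEG);
    auto at = [&](int i, int j) -> int& {
        return D[(size_t)i * width + (j - (i + c0 - band))];
    };
    auto inband = [&](int i, int j) {
        return j >= std::max(0, i + c0 - band) &&
               j <= std::min(W, i + c0 + band);
    };
    for (int j = std::max(0, c0 - band); j <= std::min(W, c0 + band); ++j)
        at(0, j) = 0;  // free leading window gap
    for (int i = 1; i <= F; ++i) {
        int jlo = std::max(0, i + c0 - band), jhi = std::min(W, i + c0 + band);
        for (int j = jlo; j <= jhi; ++j) {
            int best = NEG;
            if (j > 0 && inband(i - 1, j - 1) && at(i - 1, j - 1) > NEG) {
                int sc = at(i - 1, j - 1) +
                         ((frag[i - 1] == win[j - 1]) ? 1 : -1);
                best = std::max(best, sc);
            }
            if (inband(i - 1, j) && at(i - 1, j) > NEG)
                best = std::max(best, at(i - 1, j) - 2);   // gap in window
            if (j > 0 && inband(i, j - 1) && at(i, j - 1) > NEG)
                best = std::max(best, at(i, j - 1) - 2);   // gap in fragment
            at(i, j) = best;
        }
    }
    int jbest = -1, sbest = NEG;
    for (int j = std::max(0, F + c0 - band);
         j <= std::min(W, F + c0 + band); ++j) {
        if (inband(F, j) && at(F, j) > sbest) { sbest = at(F, j); jbest = j; }
    }
    matches = 0; columns = 0; frag_aligned = 0;
    if (jbest < 0) return;
    int i = F, j = jbest;
    while (i > 0) {
        int cur = at(i, j);
        if (j > 0 && inband(i - 1, j - 1) && at(i - 1, j - 1) > NEG &&
            cur == at(i - 1, j - 1) + ((frag[i - 1] == win[j - 1]) ? 1 : -1)) {
            if (frag[i - 1] == win[j - 1]) ++matches;
            ++columns; ++frag_aligned; --i; --j;
        } else if (inband(i - 1, j) && at(i - 1, j) > NEG &&
                   cur == at(i - 1, j) - 2) {
            ++columns; --i;
        } else if (j > 0 && inband(i, j - 1) && at(i, j - 1) > NEG &&
                   cur == at(i, j - 1) - 2) {
            ++columns; --j;
        } else {
            break;  // unreachable for a consistent DP
        }
    }
}

// Best-locus alignment of genome fragments against an indexed reference
// (external pointer from cpp_index_build).  For each fragment, candidate
// diagonal offsets are collected by exact k-mer seeding on both strands
// (stride seed_stride); the offset with the most seed votes (ties:
// smallest offset, + strand first) is refined by banded semi-global
// alignment.  Returns per fragment: found, identity (percent over
// alignment columns) and aligned fragment bases.
// [[Rcpp::export]]
List cpp_fragment_align(SEXP xp, CharacterVector fragments, int seed_stride,
                        int band) {
    XPtr<RefIndex> p(xp);
    const RefIndex& R = *p;
    const int k = R.idx.k;

    const int nf = fragments.size();
    LogicalVector found(nf);
    NumericVector identity(nf);
    IntegerVector aligned(nf);

    const uint64_t kmask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    std::vector<int> cand, hitpos;
    std::string seq, rcseq;

    for (int f = 0; f < nf; ++f) {
        found[f] = false; identity[f] = NA_REAL; aligned[f] = 0;
        seq.assign(CHAR(STRING_ELT(fragments, f)));
        const int F = (int)seq.size();
        if (F < k) continue;
        rcseq.resize(F);
        for (int i = 0; i < F; ++i) rcseq[F - 1 - i] = nt_complement(seq[i]);

        int best_votes = 0, best_off = -1, best_strand = 0;
        for (int st = 0; st < 2; ++st) {
            const std::string& q = (st == 0) ? seq : rcseq;
            cand.clear();
            for (int s = 0;; s += seed_stride) {
                if (s > F - k) {
                    if (s - seed_stride == F - k) break;
                    s = F - k;
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
                        int off = pp - s;
                        if (off >= -band) cand.push_back(off);
                    }
                }
                if (s == F - k) break;
            }
            if (cand.empty()) continue;
            std::sort(cand.begin(), cand.end());
            int i = 0, n = (int)cand.size();
            while (i < n) {
                int j = i;
                while (j < n && cand[j] == cand[i]) ++j;
                if (j - i > best_votes) {
                    best_votes = j - i; best_off = cand[i]; best_strand = st;
                }
                i = j;
            }
        }
        if (best_votes == 0) continue;

        int b = block_of(R.bs, R.be, std::max(best_off, 0));
        if (b < 0) continue;
        int rstart = std::max(R.bs[b], best_off - band);
        int rend = std::min(R.be[b], best_off + F + band);
        if (rend <= rstart) continue;
        int c0 = best_off - rstart;
        const std::string& q = (best_strand == 0) ? seq : rcseq;
        int matches, columns, frag_aligned;
        banded_align(q.data(), F, R.ref.data() + rstart, rend - rstart, c0,
                     band, matches, columns, frag_aligned);
        if (columns <= 0) continue;
        found[f] = true;
        identity[f] = 100.0 * matches / columns;
        aligned[f] = frag_aligned;
    }
    return List::create(_["found"] = found, _["identity"] = identity,
                        _["aligned"] = aligned);
}
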