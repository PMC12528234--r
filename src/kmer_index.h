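#ifndef METABREADTH_KMER_INDEX_H
#define METABREADTH_KMER_INDEX_H

#include <cstdint>
#include <string>
#include <vector>

// 2-bit nucleotide codes; 255 marks anything outside {A,C,G,T}.
inline uint8_t nt_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 255;
    }
}

inline char nt_complement(char c) {
    switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
    }
}

inline uint64_t splitmix64(uint64_t x) {
    x += 0x9e3779b97f4a7c15ULL;
    x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
    x = (x ^ (x >> 27)) * 0x94d4a2fa58dcf7ffULL;
    return x ^ (x >> 31);
}

// Open-addressing k-mer -> positions index over the forward strand of a
// concatenated reference.  Positions are stored CSR-style; k-mers spanning a
// block (contig) boundary or containing a non-ACGT base are not indexed.
struct KmerIndex {
    int k;
    uint64_t mask_bits;       // table size - 1 (power of two)
    std::vector<uint64_t> keys;   // UINT64_MAX = empty slot
    std::vector<uint32_t> offsets;   // per slot, into positions
    std::vector<uint32_t> positions;
    // small membership prefilter (1 hash); most absent k-mers are rejected
    // with a single access to a cache-resident bit array
    std::vector<uint64_t> bloom;
    uint64_t bloom_mask;

    static constexpr uint64_t EMPTY = UINT64_MAX;

    size_t find_slot(uint64_t key) const {
        uint64_t h = splitmix64(key) & mask_bits;
        while (keys[h] != EMPTY && keys[h] != key)
            h = (h + 1) & mask_bits;
        return (size_t)h;
    }

    bool maybe_present(uint64_t key) const {
        uint64_t b = splitmix64(key ^ 0xda942042e4dd58b5ULL) & bloom_mask;
        return (bloom[b >> 6] >> (b & 63)) & 1ULL;
    }

    void bloom_insert(uint64_t key) {
        uint64_t b = splitmix64(key ^ 0xda942042e4dd58b5ULL) & bloom_mask;
        bloom[b >> 6] |= 1ULL << (b & 63);
    }

    void build(const std::string& ref, const std::vector<int>& block_start,
               const std::vector<int>& block_end, int k_) {
        k = k_;
        const size_t n = ref.size();
        size_t cap = 16;
        while (cap < 2 * n) cap <<= 1;
        mask_bits = cap - 1;
        keys.assign(cap, EMPTY);
        std::vector<uint32_t> counts(cap, 0);

        uint64_t nbits = 64;
        while (nbits < 32 * (uint64_t)(n + 1)) nbits <<= 1;
        bloom_mask = nbits - 1;
        bloom.assign(nbits >> 6, 0);

        std::vector<uint8_t> code(n);
        for (size_t i = 0; i < n; ++i) code[i] = nt_code(ref[i]);

        const uint64_t kmask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

        // first pass: count occurrences per k-mer within each block
        for (size_t b = 0; b < block_start.size(); ++b) {
            int bs = block_start[b], be = block_end[b];
            if (be - bs < k) continue;
            uint64_t km = 0;
            int run = 0;  // valid bases accumulated
            for (int i = bs; i < be; ++i) {
                if (code[i] == 255) { run = 0; km = 0; continue; }
                km = ((km << 2) | code[i]) & kmask;
                if (++run >= k) {
                    size_t s = find_slot(km);
                    if (keys[s] == EMPTY) keys[s] = km;
                    counts[s]++;
                    bloom_insert(km);
                }
            }
        }
        offsets.assign(cap + 1, 0);
        uint64_t tot = 0;
        for (size_t s = 0; s < cap; ++s) { offsets[s] = (uint32_t)tot; tot += counts[s]; }
        offsets[cap] = (uint32_t)tot;
        positions.assign(tot, 0);
        std::vector<uint32_t> cursor(cap, 0);

        for (size_t b = 0; b < block_start.size(); ++b) {
            int bs = block_start[b], be = block_end[b];
            if (be - bs < k) continue;
            uint64_t km = 0;
            int run = 0;
            for (int i = bs; i < be; ++i) {
                if (code[i] == 255) { run = 0; km = 0; continue; }
                km = ((km << 2) | code[i]) & kmask;
                if (++run >= k) {
                    size_t s = find_slot(km);
                    positions[offsets[s] + cursor[s]++] = (uint32_t)(i - k + 1);
                }
            }
        }
    }

    // appends the start positions of `km` to out
    void lookup(uint64_t km, std::vector<int>& out) const {
        if (!maybe_present(km)) return;
        size_t s = find_slot(km);
        if (keys[s] == EMPTY) return;
        for (uint32_t i = offsets[s]; i < offsets[s + 1]; ++i)
            out.push_back((int)positions[i]);
    }
};

// A built recruiter index: the concatenated post-excision reference, its
// contig-block layout and the k-mer position index.  Held by R as an
// external pointer so many calls against one reference pay the build cost
// once.
struct RefIndex {
    std::string ref;
    std::vector<int> bs, be;
    KmerIndex idx;
};

// index of the block containing global position p, or -1
inline int block_of(const std::vector<int>& block_start,
                    const std::vector<int>& block_end, int p) {
    if (p < 0) return -1;
    // binary search over sorted block starts
    int lo = 0, hi = (int)block_start.size() - 1, ans = -1;
    while (lo <= hi) {
        int mid = (lo + hi) / 2;
        if (block_start[mid] <= p) { ans = mid; lo = mid + 1; }
        else hi = mid - 1;
    }
    if (ans >= 0 && p < block_end[ans]) return ans;
    return -1;
}

#endif
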