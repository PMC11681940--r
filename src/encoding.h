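#ifndef PANCORE_ENCODING_H
#define PANCORE_ENCODING_H

#include <string>
#include <vector>
#include <cstdint>
#include <algorithm>

// Amino acid codes: 0-19 standard residues (alphabetical), 20 = X (unknown),
// 21 = * (stop), 22 = gap. Unrecognised characters map to X.
inline int aaCode(char c) {
    switch (c) {
    case 'A': return 0;  case 'C': return 1;  case 'D': return 2;
    case 'E': return 3;  case 'F': return 4;  case 'G': return 5;
    case 'H': return 6;  case 'I': return 7;  case 'K': return 8;
    case 'L': return 9;  case 'M': return 10; case 'N': return 11;
    case 'P': return 12; case 'Q': return 13; case 'R': return 14;
    case 'S': return 15; case 'T': return 16; case 'V': return 17;
    case 'W': return 18; case 'Y': return 19;
    case 'X': return 20; case '*': return 21; case '-': return 22;
    default:  return 20;
    }
}

// Distinct k-mer hashes of a sequence (base-22 over residue codes; windows
// containing gaps are skipped). Sorted and deduplicated.
inline std::vector<uint32_t> distinctKmers(const std::string &s, int k) {
    std::vector<uint32_t> out;
    const int n = (int)s.size();
    if (n < k) return out;
    out.reserve(n - k + 1);
    for (int i = 0; i + k <= n; ++i) {
        uint32_t h = 0;
        bool ok = true;
        for (int j = 0; j < k; ++j) {
            int c = aaCode(s[i + j]);
            if (c == 22) { ok = false; break; }
            h = h * 22u + (uint32_t)c;
        }
        if (ok) out.push_back(h);
    }
    std::sort(out.begin(), out.end());
    out.erase(std::unique(out.begin(), out.end()), out.end());
    return out;
}

// |A n B| for sorted unique vectors.
inline int sharedCount(const std::vector<uint32_t> &a,
                       const std::vector<uint32_t> &b) {
    int n = 0;
    size_t i = 0, j = 0;
    while (i < a.size() && j < b.size()) {
        if (a[i] < b[j]) ++i;
        else if (b[j] < a[i]) ++j;
        else { ++n; ++i; ++j; }
    }
    return n;
}

// k-mer identity estimate: shared distinct k-mers over the smaller k-mer set.
inline double kmerIdent(const std::vector<uint32_t> &a,
                        const std::vector<uint32_t> &b) {
    size_t m = std::min(a.size(), b.size());
    if (m == 0) return 0.0;
    return (double)sharedCount(a, b) / (double)m;
}

#endif
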