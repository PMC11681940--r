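#include <Rcpp.h>
#include "encoding.h"
using namespace Rcpp;

static const double NEG = -1e30;

// Gotoh global alignment with affine gaps (gap of length L costs
// gapOpen + L * gapExt). `look` is a 128x128 substitution lookup indexed by
// raw character codes.
static void gotohGlobal(const std::string &a, const std::string &b,
                        const double *look, double go, double ge,
                        std::string &outA, std::string &outB, double &score) {
    const int n = (int)a.size(), m = (int)b.size();
    if (n == 0 || m == 0) {
        outA = a + std::string(m, '-');
        outB = std::string(n, '-') + b;
        score = (n + m) > 0 ? -(go + ge * (n + m)) : 0.0;
        return;
    }
    const int W = m + 1;
    std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
        Y((n + 1) * W, NEG);
    std::vector<unsigned char> tM((n + 1) * W), tX((n + 1) * W),
        tY((n + 1) * W);
    M[0] = 0.0;
    for (int i = 1; i <= n; ++i) {
        X[i * W] = -(go + ge * i);
        tX[i * W] = 1;
    }
    for (int j = 1; j <= m; ++j) {
        Y[j] = -(go + ge * j);
        tY[j] = 2;
    }
    for (int i = 1; i <= n; ++i) {
        const int ai = (int)(unsigned char)a[i - 1];
        for (int j = 1; j <= m; ++j) {
            const int c = i * W + j, d = (i - 1) * W + (j - 1),
                      u = (i - 1) * W + j, l = i * W + (j - 1);
            double s = look[ai + 128 * (int)(unsigned char)b[j - 1]];
            // M
            double best = M[d]; unsigned char t = 0;
            if (X[d] > best) { best = X[d]; t = 1; }
            if (Y[d] > best) { best = Y[d]; t = 2; }
            M[c] = best + s; tM[c] = t;
            // X: gap in b (consume a)
            best = M[u] - go - ge; t = 0;
            if (X[u] - ge > best) { best = X[u] - ge; t = 1; }
            if (Y[u] - go - ge > best) { best = Y[u] - go - ge; t = 2; }
            X[c] = best; tX[c] = t;
            // Y: gap in a (consume b)
            best = M[l] - go - ge; t = 0;
            if (X[l] - go - ge > best) { best = X[l] - go - ge; t = 1; }
            if (Y[l] - ge > best) { best = Y[l] - ge; t = 2; }
            Y[c] = best; tY[c] = t;
        }
    }
    int i = n, j = m;
    int state = 0;
    const int e = n * W + m;
    score = M[e];
    if (X[e] > score) { score = X[e]; state = 1; }
    if (Y[e] > score) { score = Y[e]; state = 2; }
    std::string ra, rb;
    ra.reserve(n + m); rb.reserve(n + m);
    while (i > 0 || j > 0) {
        const int c = i * W + j;
        if (state == 0) {
            ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
            state = tM[c]; --i; --j;
        } else if (state == 1) {
            ra.push_back(a[i - 1]); rb.push_back('-');
            state = tX[c]; --i;
        } else {
            ra.push_back('-'); rb.push_back(b[j - 1]);
            state = tY[c]; --j;
        }
    }
    outA.assign(ra.rbegin(), ra.rend());
    outB.assign(rb.rbegin(), rb.rend());
}

// [[Rcpp::export]]
List globalAlignCpp(std::string a, std::string b, NumericMatrix lookup,
                    double gapOpen, double gapExt) {
    std::string ra, rb;
    double score;
    gotohGlobal(a, b, lookup.begin(), gapOpen, gapExt, ra, rb, score);
    int match = 0, len = (int)ra.size();
    for (int t = 0; t < len; ++t)
        if (ra[t] != '-' && ra[t] == rb[t]) ++match;
    double ident = len > 0 ? (double)match / (double)len : 1.0;
    return List::create(_["alignedA"] = ra, _["alignedB"] = rb,
                        _["score"] = score, _["identity"] = ident);
}

// Merge two alignments given a pairwise global alignment of their
// (ungapped) representative rows.
static void mergeMsa(const std::vector<std::string> &m1, int rep1,
                     const std::vector<std::string> &m2, int rep2,
                     const std::string &ar1, const std::string &ar2,
                     std::vector<std::string> &out) {
    const int n1 = (int)m1.size(), n2 = (int)m2.size();
    const int L1 = n1 ? (int)m1[0].size() : 0, L2 = n2 ? (int)m2[0].size() : 0;
    out.assign(n1 + n2, std::string());
    size_t total = ar1.size() + L1 + L2;
    for (auto &s : out) s.reserve(total);
    const std::string &r1 = m1[rep1], &r2 = m2[rep2];
    int p1 = 0, p2 = 0;
    auto emit1 = [&](int col) {
        for (int r = 0; r < n1; ++r) out[r].push_back(m1[r][col]);
        for (int r = 0; r < n2; ++r) out[n1 + r].push_back('-');
    };
    auto emit2 = [&](int col) {
        for (int r = 0; r < n1; ++r) out[r].push_back('-');
        for (int r = 0; r < n2; ++r) out[n1 + r].push_back(m2[r][col]);
    };
    auto emitBoth = [&](int c1, int c2) {
        for (int r = 0; r < n1; ++r) out[r].push_back(m1[r][c1]);
        for (int r = 0; r < n2; ++r) out[n1 + r].push_back(m2[r][c2]);
    };
    for (size_t t = 0; t < ar1.size(); ++t) {
        char x = ar1[t], y = ar2[t];
        if (x != '-') while (p1 < L1 && r1[p1] == '-') { emit1(p1); ++p1; }
        if (y != '-') while (p2 < L2 && r2[p2] == '-') { emit2(p2); ++p2; }
        if (x != '-' && y != '-') { emitBoth(p1, p2); ++p1; ++p2; }
        else if (x != '-') { emit1(p1); ++p1; }
        else { emit2(p2); ++p2; }
    }
    while (p1 < L1) { emit1(p1); ++p1; }
    while (p2 < L2) { emit2(p2); ++p2; }
}

// Progressive multiple alignment: UPGMA guide tree over pairwise k-mer
// distances, groups merged through a global alignment of their longest
// (representative) members. Rows returned in input order; ungapping row i
// reproduces input i.
// [[Rcpp::export]]
CharacterVector msaCpp(CharacterVector seqs, NumericMatrix lookup,
                       double gapOpen, double gapExt, int k) {
    const int n = seqs.size();
    std::vector<std::string> sq(n);
    for (int i = 0; i < n; ++i) sq[i] = as<std::string>(seqs[i]);
    if (n == 1) return seqs;

    std::vector<std::vector<uint32_t>> km(n);
    for (int i = 0; i < n; ++i) km[i] = distinctKmers(sq[i], k);
    std::vector<double> D(n * n, 0.0);
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
            D[i * n + j] = D[j * n + i] = 1.0 - kmerIdent(km[i], km[j]);

    // cluster state
    std::vector<bool> active(n, true);
    std::vector<int> size(n, 1);
    std::vector<std::vector<int>> members(n);
    std::vector<std::vector<std::string>> msas(n);
    std::vector<int> rep(n);      // row index of representative within msa
    std::vector<int> repLen(n);   // ungapped length of representative
    for (int i = 0; i < n; ++i) {
        members[i] = {i};
        msas[i] = {sq[i]};
        rep[i] = 0;
        repLen[i] = (int)sq[i].size();
    }
    for (int step = 0; step < n - 1; ++step) {
        int bi = -1, bj = -1;
        double best = 1e300;
        for (int i = 0; i < n; ++i) {
            if (!active[i]) continue;
            for (int j = i + 1; j < n; ++j) {
                if (!active[j]) continue;
                if (D[i * n + j] < best - 1e-12) {
                    best = D[i * n + j]; bi = i; bj = j;
                }
            }
        }
        // align representatives and merge
        std::string u1, u2;
        for (char c : msas[bi][rep[bi]]) if (c != '-') u1.push_back(c);
        for (char c : msas[bj][rep[bj]]) if (c != '-') u2.push_back(c);
        std::string a1, a2;
        double sc;
        gotohGlobal(u1, u2, lookup.begin(), gapOpen, gapExt, a1, a2, sc);
        std::vector<std::string> merged;
        mergeMsa(msas[bi], rep[bi], msas[bj], rep[bj], a1, a2, merged);
        // new representative: longer of the two (tie: first)
        int newRep, newRepLen;
        if (repLen[bj] > repLen[bi]) {
            newRep = (int)msas[bi].size() + rep[bj]; newRepLen = repLen[bj];
        } else {
            newRep = rep[bi]; newRepLen = repLen[bi];
        }
        // UPGMA distance update into slot bi
        for (int t = 0; t < n; ++t) {
            if (!active[t] || t == bi || t == bj) continue;
            double d = (D[bi * n + t] * size[bi] + D[bj * n + t] * size[bj]) /
                       (double)(size[bi] + size[bj]);
            D[bi * n + t] = D[t * n + bi] = d;
        }
        msas[bi] = std::move(merged);
        members[bi].insert(members[bi].end(), members[bj].begin(),
                           members[bj].end());
        rep[bi] = newRep;
        repLen[bi] = newRepLen;
        size[bi] += size[bj];
        active[bj] = false;
        msas[bj].clear();
    }
    int root = 0;
    while (!active[root]) ++root;
    CharacterVector out(n);
    for (size_t r = 0; r < members[root].size(); ++r)
        out[members[root][r]] = msas[root][r];
    out.attr("names") = seqs.attr("names");
    return out;
}

// Pairwise distance from an alignment: 1 - fraction of identical positions
// over columns where neither row has a gap; pairs with no overlapping
// columns get distance 1.
// [[Rcpp::export]]
NumericMatrix msaDistanceCpp(CharacterVector rows) {
    const int n = rows.size();
    std::vector<std::string> m(n);
    for (int i = 0; i < n; ++i) m[i] = as<std::string>(rows[i]);
    NumericMatrix D(n, n);
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            int ov = 0, id = 0;
            const std::string &a = m[i], &b = m[j];
            for (size_t t = 0; t < a.size(); ++t) {
                if (a[t] == '-' || b[t] == '-') continue;
                ++ov;
                if (a[t] == b[t]) ++id;
            }
            double d = ov == 0 ? 1.0 : 1.0 - (double)id / (double)ov;
            D(i, j) = D(j, i) = d;
        }
    }
    return D;
}
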