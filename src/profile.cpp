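#include <Rcpp.h>
#include <unordered_map>
#include "encoding.h"
using namespace Rcpp;

static const double NEG = -1e30;

// Local (Smith-Waterman) alignment of a sequence against a positional
// log-odds profile (rows = profile columns, cols = 22 residue codes).
// Returns the optimal local score, and percent identity of the aligned
// span measured against the profile consensus.
static void profileLocal(const NumericMatrix &lo, const std::string &cons,
                         const std::string &seq, double go, double ge,
                         double &score, double &pident, int &alnLen) {
    const int L = lo.nrow(), m = (int)seq.size();
    std::vector<int> code(m);
    for (int j = 0; j < m; ++j) {
        int c = aaCode(seq[j]);
        code[j] = c > 21 ? 20 : c;
    }
    const int W = m + 1;
    std::vector<double> M((L + 1) * W, 0.0), X((L + 1) * W, NEG),
        Y((L + 1) * W, NEG);
    std::vector<unsigned char> tM((L + 1) * W, 3), tX((L + 1) * W),
        tY((L + 1) * W);
    double best = 0.0;
    int bi = 0, bj = 0;
    for (int i = 1; i <= L; ++i) {
        M[i * W] = 0.0;
        for (int j = 1; j <= m; ++j) {
            const int c = i * W + j, d = (i - 1) * W + (j - 1),
                      u = (i - 1) * W + j, l = i * W + (j - 1);
            double s = lo(i - 1, code[j - 1]);
            double v = M[d]; unsigned char t = 0;
            if (X[d] > v) { v = X[d]; t = 1; }
            if (Y[d] > v) { v = Y[d]; t = 2; }
            if (v < 0.0) { v = 0.0; t = 3; }   // local restart
            M[c] = v + s; tM[c] = t;
            v = M[u] - go - ge; t = 0;
            if (X[u] - ge > v) { v = X[u] - ge; t = 1; }
            X[c] = v; tX[c] = t;
            v = M[l] - go - ge; t = 0;
            if (Y[l] - ge > v) { v = Y[l] - ge; t = 2; }
            Y[c] = v; tY[c] = t;
            if (M[c] > best) { best = M[c]; bi = i; bj = j; }
        }
    }
    score = best;
    if (best <= 0.0) { pident = 0.0; alnLen = 0; return; }
    int i = bi, j = bj, state = 0, match = 0, len = 0;
    while (true) {
        const int c = i * W + j;
        if (state == 0) {
            ++len;
            if (cons[i - 1] == seq[j - 1]) ++match;
            unsigned char t = tM[c];
            --i; --j;
            if (t == 3) break; // local alignment starts at this cell
            state = t;
        } else if (state == 1) {
            ++len; state = tX[c]; --i;
        } else {
            ++len; state = tY[c]; --j;
        }
        if (i == 0 || j == 0) break;
    }
    pident = len > 0 ? (double)match / (double)len : 0.0;
    alnLen = len;
}

// [[Rcpp::export]]
List profileLocalAlignCpp(NumericMatrix logodds, std::string consensus,
                          std::string seq, double gapOpen, double gapExt) {
    double score, pident;
    int alnLen;
    profileLocal(logodds, consensus, seq, gapOpen, gapExt, score, pident,
                 alnLen);
    return List::create(_["score"] = score, _["pctIdentity"] = pident,
                        _["alnLen"] = alnLen);
}

// Search many profiles against many sequences. Candidate (profile, seq)
// pairs are generated through a shared-k-mer index over the profile
// consensus sequences; candidates with consensus k-mer identity >= minFrac
// are scored by local profile alignment.
// [[Rcpp::export]]
DataFrame profileSearchCpp(List logoddsList, CharacterVector consensi,
                           CharacterVector seqs, int k, double minFrac,
                           double gapOpen, double gapExt) {
    const int np = consensi.size(), ns = seqs.size();
    std::vector<std::vector<uint32_t>> pkm(np);
    std::unordered_map<uint32_t, std::vector<int>> index;
    std::vector<std::string> cons(np);
    for (int p = 0; p < np; ++p) {
        cons[p] = as<std::string>(consensi[p]);
        pkm[p] = distinctKmers(cons[p], k);
        for (uint32_t h : pkm[p]) index[h].push_back(p);
    }
    std::vector<NumericMatrix> los(np);
    for (int p = 0; p < np; ++p) los[p] = as<NumericMatrix>(logoddsList[p]);

    std::vector<int> outSeq, outProf;
    std::vector<double> outScore, outIdent;
    std::vector<int> count(np, 0), touched;
    for (int s = 0; s < ns; ++s) {
        std::string sq = as<std::string>(seqs[s]);
        std::vector<uint32_t> km = distinctKmers(sq, k);
        touched.clear();
        for (uint32_t h : km) {
            auto it = index.find(h);
            if (it == index.end()) continue;
            for (int p : it->second) {
                if (count[p] == 0) touched.push_back(p);
                ++count[p];
            }
        }
        for (int p : touched) {
            size_t m = std::min(km.size(), pkm[p].size());
            double f = m == 0 ? 0.0 : (double)count[p] / (double)m;
            count[p] = 0;
            if (f < minFrac) continue;
            double score, pident;
            int alnLen;
            profileLocal(los[p], cons[p], sq, gapOpen, gapExt, score, pident,
                         alnLen);
            if (score <= 0.0) continue;
            outSeq.push_back(s + 1);
            outProf.push_back(p + 1);
            outScore.push_back(score);
            outIdent.push_back(pident);
        }
    }
    return DataFrame::create(_["seq"] = wrap(outSeq),
                             _["profile"] = wrap(outProf),
                             _["score"] = wrap(outScore),
                             _["pctIdentity"] = wrap(outIdent));
}
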