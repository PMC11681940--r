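#include <Rcpp.h>
#include <unordered_map>
#include "encoding.h"
using namespace Rcpp;

// [[Rcpp::export]]
double kmerIdentityCpp(std::string a, std::string b, int k) {
    return kmerIdent(distinctKmers(a, k), distinctKmers(b, k));
}

// Greedy incremental preclustering. `seqs` must already be sorted by
// decreasing length (ties by name); each sequence joins the earliest-founded
// precluster whose representative (= founder, the longest member) has k-mer
// identity >= minIdentity, else founds a new precluster. Returns 1-based
// precluster index per sequence, in founding order.
// [[Rcpp::export]]
IntegerVector preclusterCpp(CharacterVector seqs, double minIdentity, int k) {
    const int n = seqs.size();
    IntegerVector assign(n);
    std::vector<std::vector<uint32_t>> repKmers;   // per precluster rep
    std::unordered_map<uint32_t, std::vector<int>> index; // kmer -> rep ids
    std::vector<int> count;   // scratch: shared-kmer count per rep
    std::vector<int> touched;
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        std::vector<uint32_t> km = distinctKmers(s, k);
        // count shared kmers with every candidate representative
        touched.clear();
        for (uint32_t h : km) {
            auto it = index.find(h);
            if (it == index.end()) continue;
            for (int r : it->second) {
                if (count[r] == 0) touched.push_back(r);
                ++count[r];
            }
        }
        int best = -1;
        for (int r : touched) {
            size_t m = std::min(km.size(), repKmers[r].size());
            double ident = m == 0 ? 0.0 : (double)count[r] / (double)m;
            if (ident >= minIdentity && (best < 0 || r < best)) best = r;
        }
        for (int r : touched) count[r] = 0;
        if (best >= 0) {
            assign[i] = best + 1;
        } else {
            int id = (int)repKmers.size();
            for (uint32_t h : km) index[h].push_back(id);
            repKmers.push_back(std::move(km));
            count.push_back(0);
            assign[i] = id + 1;
        }
    }
    return assign;
}

// Farthest-first (maximin) traversal over sequences with d = 1 - k-mer
// identity. pivot is a 0-based index chosen (seeded) by the caller; the
// first pick maximises distance to the pivot. Ties broken by
// lexicographically smallest name. Returns selection order (1-based) and
// novelty (min distance to previously selected; sentinel 1.0 for the first).
// [[Rcpp::export]]
List ficlinKmerCpp(CharacterVector seqs, CharacterVector names, int k,
                   int nSelect, int pivot, double stopNovelty) {
    const int n = seqs.size();
    std::vector<std::vector<uint32_t>> km(n);
    for (int i = 0; i < n; ++i)
        km[i] = distinctKmers(as<std::string>(seqs[i]), k);
    std::vector<std::string> nm(n);
    for (int i = 0; i < n; ++i) nm[i] = as<std::string>(names[i]);

    std::vector<bool> used(n, false);
    std::vector<double> minDist(n);
    std::vector<int> order;
    std::vector<double> novelty;

    // first pick: farthest from pivot
    int first = -1;
    double bestD = -1.0;
    for (int i = 0; i < n; ++i) {
        double d = 1.0 - kmerIdent(km[pivot], km[i]);
        if (d > bestD + 1e-12 ||
            (std::abs(d - bestD) <= 1e-12 && (first < 0 || nm[i] < nm[first]))) {
            bestD = d; first = i;
        }
    }
    used[first] = true;
    order.push_back(first);
    novelty.push_back(1.0);
    for (int i = 0; i < n; ++i)
        minDist[i] = 1.0 - kmerIdent(km[first], km[i]);

    while ((int)order.size() < nSelect) {
        int pick = -1;
        double best = -1.0;
        for (int i = 0; i < n; ++i) {
            if (used[i]) continue;
            if (minDist[i] > best + 1e-12 ||
                (std::abs(minDist[i] - best) <= 1e-12 &&
                 (pick < 0 || nm[i] < nm[pick]))) {
                best = minDist[i]; pick = i;
            }
        }
        if (pick < 0) break;
        if (best < stopNovelty) break;
        used[pick] = true;
        order.push_back(pick);
        novelty.push_back(best);
        for (int i = 0; i < n; ++i) {
            if (used[i]) continue;
            double d = 1.0 - kmerIdent(km[pick], km[i]);
            if (d < minDist[i]) minDist[i] = d;
        }
    }
    return List::create(_["order"] = wrap(order), _["novelty"] = wrap(novelty));
}

// For every sequence, the representative (subset of indices, 0-based) with
// maximal k-mer identity; ties broken by lexicographically smallest
// representative name. Returns 0-based index into `reps`.
// [[Rcpp::export]]
IntegerVector nearestRepCpp(CharacterVector seqs, IntegerVector reps,
                            CharacterVector names, int k) {
    const int n = seqs.size(), nr = reps.size();
    std::vector<std::vector<uint32_t>> km(n);
    for (int i = 0; i < n; ++i)
        km[i] = distinctKmers(as<std::string>(seqs[i]), k);
    std::vector<std::string> repNm(nr);
    std::vector<int> repOrder(nr); // reps sorted by name for tie-breaking
    for (int r = 0; r < nr; ++r) repNm[r] = as<std::string>(names[reps[r]]);
    for (int r = 0; r < nr; ++r) repOrder[r] = r;
    std::sort(repOrder.begin(), repOrder.end(),
              [&](int a, int b) { return repNm[a] < repNm[b]; });
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        int best = repOrder[0];
        double bestI = -1.0;
        for (int rr : repOrder) {
            double id = kmerIdent(km[i], km[reps[rr]]);
            if (id > bestI + 1e-12) { bestI = id; best = rr; }
        }
        out[i] = best;
    }
    return out;
}

// Candidate pairs (i < j, 0-based) of sequences with k-mer identity
// >= minFrac, found through a shared-k-mer inverted index.
// [[Rcpp::export]]
List kmerCandidatePairsCpp(CharacterVector seqs, int k, double minFrac) {
    const int n = seqs.size();
    std::vector<std::vector<uint32_t>> km(n);
    for (int i = 0; i < n; ++i)
        km[i] = distinctKmers(as<std::string>(seqs[i]), k);
    std::unordered_map<uint32_t, std::vector<int>> index;
    for (int i = 0; i < n; ++i)
        for (uint32_t h : km[i]) index[h].push_back(i);
    std::vector<int> I, J;
    std::vector<double> F;
    std::vector<int> count(n, 0), touched;
    for (int i = 0; i < n; ++i) {
        touched.clear();
        for (uint32_t h : km[i]) {
            auto it = index.find(h);
            for (int j : it->second) {
                if (j <= i) continue;
                if (count[j] == 0) touched.push_back(j);
                ++count[j];
            }
        }
        for (int j : touched) {
            size_t m = std::min(km[i].size(), km[j].size());
            double f = m == 0 ? 0.0 : (double)count[j] / (double)m;
            if (f >= minFrac) { I.push_back(i); J.push_back(j); F.push_back(f); }
            count[j] = 0;
        }
    }
    return List::create(_["i"] = wrap(I), _["j"] = wrap(J), _["frac"] = wrap(F));
}
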