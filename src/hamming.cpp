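#include <Rcpp.h>
#include <unordered_map>
#include <string>
using namespace Rcpp;

// Hamming distance with early exit once `limit` is exceeded.
// Returns limit + 1 when the true distance is > limit.
// N mismatches every base including N (conservative: no edges through
// ambiguous calls).
static inline int hamming_capped(const char* a, const char* b, int len, int limit) {
    int d = 0;
    for (int i = 0; i < len; ++i) {
        if (a[i] != b[i] || a[i] == 'N') {
            if (++d > limit) return limit + 1;
        }
    }
    return d;
}

// All pairs of equal-length sequences at Hamming distance exactly 1.
// Sequences are grouped by length; within a group the scan is quadratic with
// early exit at distance 2, which is fast in practice because unrelated
// V(D)J rearrangements diverge within the first few bases.
// [[Rcpp::export(name = ".hamming1_edges")]]
IntegerMatrix hamming1_edges(CharacterVector seqs) {
    int n = seqs.size();
    std::unordered_map<int, std::vector<int>> by_len;
    std::vector<const char*> ptr(n);
    std::vector<int> len(n);
    for (int i = 0; i < n; ++i) {
        ptr[i] = CHAR(STRING_ELT(seqs, i));
        len[i] = LENGTH(STRING_ELT(seqs, i));
        by_len[len[i]].push_back(i);
    }
    std::vector<int> from, to;
    for (auto& kv : by_len) {
        std::vector<int>& idx = kv.second;
        int m = idx.size();
        int L = kv.first;
        for (int a = 0; a < m; ++a) {
            for (int b = a + 1; b < m; ++b) {
                if (hamming_capped(ptr[idx[a]], ptr[idx[b]], L, 1) == 1) {
                    from.push_back(idx[a] + 1);
                    to.push_back(idx[b] + 1);
                }
            }
        }
        if (m > 1 && (double)m * m > 5e7) Rcpp::checkUserInterrupt();
    }
    IntegerMatrix out(from.size(), 2);
    for (size_t i = 0; i < from.size(); ++i) {
        out(i, 0) = from[i];
        out(i, 1) = to[i];
    }
    return out;
}

// Minimum equal-length Hamming distance from each query to a set of member
// sequences, capped at cutoff + 1. NA when no member has the query's length.
// [[Rcpp::export(name = ".min_hamming_to_set")]]
IntegerVector min_hamming_to_set(CharacterVector queries, CharacterVector members,
                                 int cutoff) {
    int nq = queries.size(), nm = members.size();
    std::vector<const char*> mp(nm);
    std::vector<int> ml(nm);
    for (int j = 0; j < nm; ++j) {
        mp[j] = CHAR(STRING_ELT(members, j));
        ml[j] = LENGTH(STRING_ELT(members, j));
    }
    IntegerVector out(nq);
    for (int i = 0; i < nq; ++i) {
        const char* q = CHAR(STRING_ELT(queries, i));
        int ql = LENGTH(STRING_ELT(queries, i));
        int best = NA_INTEGER;
        for (int j = 0; j < nm; ++j) {
            if (ml[j] != ql) continue;
            int lim = (best == NA_INTEGER) ? cutoff : best - 1;
            if (lim < 0) break;
            int d = hamming_capped(q, mp[j], ql, lim);
            if (d <= lim) best = d;
            else if (best == NA_INTEGER) best = cutoff + 1;
            if (best == 0) break;
        }
        out[i] = best;
        if (i % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}

// Index (1-based) of the member attaining the minimum distance for each query,
// with ties broken by lower member index; 0 when no equal-length member is
// within cutoff. Used for single-assignment of sequences to clonotypes.
// [[Rcpp::export(name = ".argmin_hamming_groups")]]
List argmin_hamming_groups(CharacterVector queries, List member_sets, int cutoff) {
    int nq = queries.size(), ng = member_sets.size();
    IntegerVector best_group(nq), best_dist(nq);
    std::vector<std::vector<const char*>> mp(ng);
    std::vector<std::vector<int>> ml(ng);
    for (int g = 0; g < ng; ++g) {
        CharacterVector mem = member_sets[g];
        mp[g].resize(mem.size());
        ml[g].resize(mem.size());
        for (int j = 0; j < mem.size(); ++j) {
            mp[g][j] = CHAR(STRING_ELT(mem, j));
            ml[g][j] = LENGTH(STRING_ELT(mem, j));
        }
    }
    for (int i = 0; i < nq; ++i) {
        const char* q = CHAR(STRING_ELT(queries, i));
        int ql = LENGTH(STRING_ELT(queries, i));
        int bg = 0, bd = cutoff + 1;
        for (int g = 0; g < ng; ++g) {
            for (size_t j = 0; j < mp[g].size(); ++j) {
                if (ml[g][j] != ql) continue;
                int d = hamming_capped(q, mp[g][j], ql, bd - 1);
                if (d < bd) {  // strictly smaller: ties keep the lower group id
                    bd = d;
                    bg = g + 1;
                }
            }
        }
        best_group[i] = bg;
        best_dist[i] = (bg == 0) ? NA_INTEGER : bd;
        if (i % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    return List::create(_["group"] = best_group, _["dist"] = best_dist);
}
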