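#include <Rcpp.h>
using namespace Rcpp;

// Windowed sparse r^2 extraction.
//
// Z:      samples x variants matrix of standardized dosages (each column mean 0,
//         sd 1 computed with the n-1 denominator), variants sorted by (chrom, pos).
// chrom:  integer chromosome codes, constant within a chromosome run.
// pos:    base-pair positions, non-decreasing within a chromosome.
// window: maximum |pos_i - pos_j| for a pair to be examined.
// r2_floor: pairs with r^2 below this are dropped (treated as 0 downstream).
//
// Returns parallel vectors (i, j, r2) with i < j, 1-based. Self pairs
// (r^2 = 1) are implicit and added by the R-side accessors.
// [[Rcpp::export]]
List ld_pairs_cpp(NumericMatrix Z, IntegerVector chrom, NumericVector pos,
                  double window, double r2_floor) {
    const int n = Z.nrow(), m = Z.ncol();
    const double denom = static_cast<double>(n - 1);
    std::vector<int> ii, jj;
    std::vector<double> rr;
    for (int i = 0; i < m; ++i) {
        const double *zi = &Z(0, i);
        for (int j = i + 1; j < m; ++j) {
            if (chrom[j] != chrom[i]) break;
            if (pos[j] - pos[i] > window) break;
            const double *zj = &Z(0, j);
            double s = 0.0;
            for (int k = 0; k < n; ++k) s += zi[k] * zj[k];
            double r = s / denom;
            double r2 = r * r;
            if (r2 > 1.0) r2 = 1.0; // guard fp overshoot for identical columns
            if (r2 >= r2_floor) {
                ii.push_back(i + 1);
                jj.push_back(j + 1);
                rr.push_back(r2);
            }
        }
    }
    return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["r2"] = wrap(rr));
}

// Greedy LD pruning over a fixed adjacency, one visiting order per call.
//
// order:   0-based visiting order over the n candidates.
// adj_ptr: CSR row pointers (length n + 1, 0-based offsets into adj_idx).
// adj_idx: 0-based neighbour ids; an edge means r^2 >= the pruning threshold.
//
// A candidate is kept iff no already-kept neighbour was visited before it.
// [[Rcpp::export]]
LogicalVector greedy_prune_cpp(IntegerVector order, IntegerVector adj_ptr,
                               IntegerVector adj_idx) {
    const int n = order.size();
    LogicalVector keep(n, false);
    std::vector<char> kept(n, 0);
    for (int v = 0; v < n; ++v) {
        int u = order[v];
        bool ok = true;
        for (int e = adj_ptr[u]; e < adj_ptr[u + 1]; ++e) {
            if (kept[adj_idx[e]]) { ok = false; break; }
        }
        if (ok) { kept[u] = 1; keep[u] = true; }
    }
    return keep;
}
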