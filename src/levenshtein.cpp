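#include <Rcpp.h>
using namespace Rcpp;

// Strict Levenshtein (unit-cost substitution/insertion/deletion, no
// transposition) over integer code-point vectors; two-row DP.
static int lev_core(const int* a, int na, const int* b, int nb) {
    if (na == 0) return nb;
    if (nb == 0) return na;
    std::vector<int> prev(nb + 1), cur(nb + 1);
    for (int j = 0; j <= nb; ++j) prev[j] = j;
    for (int i = 1; i <= na; ++i) {
        cur[0] = i;
        const int ai = a[i - 1];
        for (int j = 1; j <= nb; ++j) {
            int cost = (ai == b[j - 1]) ? 0 : 1;
            int d = prev[j - 1] + cost;              // substitute
            if (prev[j] + 1 < d) d = prev[j] + 1;    // delete from a
            if (cur[j - 1] + 1 < d) d = cur[j - 1] + 1; // insert into a
            cur[j] = d;
        }
        std::swap(prev, cur);
    }
    return prev[nb];
}

// [[Rcpp::export]]
int lev_int(IntegerVector a, IntegerVector b) {
    return lev_core(INTEGER(a), a.size(), INTEGER(b), b.size());
}

// enc: one element per variety, each a list over glosses holding an integer
// code-point vector, or NULL where the form is missing.  Returns the
// pairwise-complete mean normalized distance and the shared-gloss count.
// [[Rcpp::export]]
List pairwise_ldn_core(List enc) {
    const int n = enc.size();
    NumericMatrix mean(n, n);
    IntegerMatrix support(n, n);
    std::vector<List> vars(n);
    for (int i = 0; i < n; ++i) vars[i] = as<List>(enc[i]);
    const int g = n > 0 ? vars[0].size() : 0;

    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            double acc = 0.0;
            int cnt = 0;
            for (int k = 0; k < g; ++k) {
                SEXP fa = vars[i][k], fb = vars[j][k];
                if (Rf_isNull(fa) || Rf_isNull(fb)) continue;
                IntegerVector va(fa), vb(fb);
                int la = va.size(), lb = vb.size();
                int lmax = la > lb ? la : lb;
                // empty forms are rejected upstream; lmax >= 1 here
                acc += (double) lev_core(INTEGER(va), la, INTEGER(vb), lb) / lmax;
                ++cnt;
            }
            support(i, j) = support(j, i) = cnt;
            double v = cnt > 0 ? acc / cnt : NA_REAL;
            mean(i, j) = mean(j, i) = v;
        }
    }
    return List::create(_["mean"] = mean, _["support"] = support);
}
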