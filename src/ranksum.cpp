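#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Midranks (average ranks for ties) of v into rank; idx is scratch.
static void midranks(const std::vector<double>& v, std::vector<double>& rank,
                     std::vector<int>& idx, double& tie_term) {
    int n = v.size();
    idx.resize(n);
    rank.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [&v](int a, int b) { return v[a] < v[b]; });
    tie_term = 0.0;
    int i = 0;
    while (i < n) {
        int j = i;
        while (j + 1 < n && v[idx[j + 1]] == v[idx[i]]) ++j;
        double r = 0.5 * (i + j) + 1.0;
        int t = j - i + 1;
        if (t > 1) tie_term += (double)t * t * t - t;
        for (int k = i; k <= j; ++k) rank[idx[k]] = r;
        i = j + 1;
    }
}

// Two-sided Mann-Whitney U p-value, normal approximation with tie
// correction and continuity correction (matches wilcox.test(correct=TRUE)).
static double ranksum_p_normal(const std::vector<double>& x,
                               const std::vector<double>& y) {
    int nx = x.size(), ny = y.size();
    int n = nx + ny;
    std::vector<double> v;
    v.reserve(n);
    v.insert(v.end(), x.begin(), x.end());
    v.insert(v.end(), y.begin(), y.end());
    std::vector<double> rank;
    std::vector<int> idx;
    double tie_term;
    midranks(v, rank, idx, tie_term);
    double rsum = 0.0;
    for (int i = 0; i < nx; ++i) rsum += rank[i];
    double U = rsum - (double)nx * (nx + 1) / 2.0;
    double mu = (double)nx * ny / 2.0;
    double sig2 = (double)nx * ny / 12.0 *
        ((double)n + 1.0 - tie_term / ((double)n * (n - 1)));
    if (sig2 <= 0.0) return 1.0;
    double z = U - mu;
    double cc = std::min(0.5, std::fabs(z));  // continuity correction
    z = (std::fabs(z) - cc) / std::sqrt(sig2);
    double p = 2.0 * R::pnorm(z, 0.0, 1.0, 0, 0);
    return p > 1.0 ? 1.0 : p;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_ranksum_p")]]
double cpp_ranksum_p(NumericVector x, NumericVector y) {
    std::vector<double> xv(x.begin(), x.end());
    std::vector<double> yv(y.begin(), y.end());
    return ranksum_p_normal(xv, yv);
}

//' All-pairs two-sided rank-sum p-values between columns of m.
//' Rows are paired observations (species); columns are windows.
//' @noRd
// [[Rcpp::export(name = ".cpp_pairwise_ranksum_p")]]
NumericMatrix cpp_pairwise_ranksum_p(NumericMatrix m) {
    int S = m.nrow(), W = m.ncol();
    NumericMatrix out(W, W);
    std::fill(out.begin(), out.end(), NA_REAL);
    std::vector<double> x(S), y(S);
    for (int i = 0; i < W; ++i) {
        for (int j = i + 1; j < W; ++j) {
            for (int s = 0; s < S; ++s) {
                x[s] = m(s, i);
                y[s] = m(s, j);
            }
            double p = ranksum_p_normal(x, y);
            out(i, j) = p;
            out(j, i) = p;
        }
    }
    return out;
}

//' Column medians of a numeric matrix.
//' @noRd
// [[Rcpp::export(name = ".cpp_col_medians")]]
NumericVector cpp_col_medians(NumericMatrix m) {
    int n = m.nrow(), W = m.ncol();
    NumericVector out(W);
    std::vector<double> v(n);
    for (int j = 0; j < W; ++j) {
        for (int i = 0; i < n; ++i) v[i] = m(i, j);
        std::sort(v.begin(), v.end());
        out[j] = (n % 2 == 1) ? v[n / 2]
                              : 0.5 * (v[n / 2 - 1] + v[n / 2]);
    }
    return out;
}
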