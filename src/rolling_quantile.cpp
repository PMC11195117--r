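#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Rolling percentile with a centered window truncated at the trace edges.
// The window for frame i (0-based) is [i - half, i + half] intersected with
// the trace; the quantile uses linear interpolation between order statistics
// (the type-7 convention). A sorted copy of the window is maintained
// incrementally: one insertion and at most one removal per frame.

static double interp_quantile(const std::vector<double>& s, double p) {
    const int n = s.size();
    if (n == 1) return s[0];
    double h = (n - 1) * p;
    int lo = (int)std::floor(h);
    if (lo >= n - 1) return s[n - 1];
    return s[lo] + (h - lo) * (s[lo + 1] - s[lo]);
}

// [[Rcpp::export(name = ".rolling_quantile_cpp")]]
NumericVector rolling_quantile_cpp(NumericVector x, int half, double p) {
    const int n = x.size();
    NumericVector out(n);
    std::vector<double> win;
    win.reserve(2 * half + 2);
    // seed with the window of frame 0: [0, min(half, n-1)]
    int right = std::min(half, n - 1);
    for (int j = 0; j <= right; ++j)
        win.insert(std::lower_bound(win.begin(), win.end(), x[j]), x[j]);
    out[0] = interp_quantile(win, p);
    for (int i = 1; i < n; ++i) {
        int add = i + half;          // entering sample
        int drop = i - half - 1;     // sample leaving on the left
        if (add < n)
            win.insert(std::lower_bound(win.begin(), win.end(), x[add]), x[add]);
        if (drop >= 0)
            win.erase(std::lower_bound(win.begin(), win.end(), x[drop]));
        out[i] = interp_quantile(win, p);
    }
    return out;
}
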