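#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Built-in secondary-structure backend: weighted base-pair maximization
// (Nussinov-style O(n^3) dynamic program) with a minimum hairpin loop of
// 3 nt.  Pair weights approximate pair stabilities in kcal/mol:
// G:C 3.0, A:U 2.0, G:U 1.0.  The reported "MFE" is minus the achieved
// total weight.  This is a deliberately simple, fully deterministic
// stand-alone model; the thermodynamic RNAfold backend is preferred when
// available.

static double pair_weight(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3.0;
    if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2.0;
    if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1.0;
    return -1.0; // sentinel: cannot pair
}

// [[Rcpp::export(name = ".fold_nussinov")]]
List fold_nussinov(std::string seq) {
    const int n = (int) seq.size();
    const int minloop = 3;
    if (n == 0) return List::create(_["structure"] = "", _["mfe"] = 0.0);
    std::vector<std::vector<double>> W(n, std::vector<double>(n, 0.0));
    for (int len = minloop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            double best = W[i + 1][j]; // i unpaired
            if (W[i][j - 1] > best) best = W[i][j - 1];
            double pw = pair_weight(seq[i], seq[j]);
            if (pw > 0 && j - i - 1 >= minloop) {
                double v = pw + (j - i - 1 > 0 ? W[i + 1][j - 1] : 0.0);
                if (v > best) best = v;
            }
            for (int k = i + 1; k < j; ++k) { // bifurcation
                double v = W[i][k] + W[k + 1][j];
                if (v > best) best = v;
            }
            W[i][j] = best;
        }
    }
    // deterministic traceback mirroring the recursion order above
    std::string db(n, '.');
    std::vector<std::pair<int,int>> stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j || j - i < minloop + 1) continue;
        double w = W[i][j];
        if (w == W[i + 1][j]) { stack.push_back(std::make_pair(i + 1, j)); continue; }
        if (w == W[i][j - 1]) { stack.push_back(std::make_pair(i, j - 1)); continue; }
        double pw = pair_weight(seq[i], seq[j]);
        if (pw > 0 && j - i - 1 >= minloop &&
            w == pw + (j - i - 1 > 0 ? W[i + 1][j - 1] : 0.0)) {
            db[i] = '('; db[j] = ')';
            stack.push_back(std::make_pair(i + 1, j - 1));
            continue;
        }
        bool split = false;
        for (int k = i + 1; k < j; ++k) {
            if (w == W[i][k] + W[k + 1][j]) {
                stack.push_back(std::make_pair(i, k));
                stack.push_back(std::make_pair(k + 1, j));
                split = true;
                break;
            }
        }
        if (!split) stop("traceback failure"); // unreachable
    }
    return List::create(_["structure"] = db, _["mfe"] = -W[0][n - 1]);
}

// [[Rcpp::export(name = ".hamming_scan")]]
IntegerVector hamming_scan(std::string pattern, std::string subject) {
    // Hamming distance of `pattern` against every window of `subject`;
    // used by the mismatch-tolerant contaminant filter.
    int m = (int) pattern.size(), n = (int) subject.size();
    if (n < m) return IntegerVector(0);
    IntegerVector out(n - m + 1);
    for (int s = 0; s + m <= n; ++s) {
        int d = 0;
        for (int i = 0; i < m; ++i) d += (pattern[i] != subject[s + i]);
        out[s] = d;
    }
    return out;
}
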