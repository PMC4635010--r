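#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <limits>

using namespace Rcpp;

// Gotoh global alignment with affine gaps.
// Gap of length k costs gap_open + (k - 1) * gap_extend (both passed as
// negative numbers), so gap_open == gap_extend degenerates to linear gaps.
// Traceback is deterministic: on ties prefer the diagonal (match) state,
// then the vertical state (gap in b), then the horizontal state (gap in a);
// within a gap state, prefer closing the gap (coming from M) over extending.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
    const int n = a.size(), m = b.size();
    const size_t w = m + 1;

    // rolling score rows, full byte traceback (predecessor state per cell)
    std::vector<double> Mp(w), Xp(w), Yp(w), Mc(w), Xc(w), Yc(w);
    // 0 = from M, 1 = from X, 2 = from Y
    std::vector<uint8_t> tbM((n + 1) * w), tbX((n + 1) * w), tbY((n + 1) * w);

    Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
        Mp[j] = NEG_INF;
        Xp[j] = NEG_INF;
        Yp[j] = gap_open + (j - 1) * gap_extend;
        tbY[j] = (j == 1) ? 0 : 2;
    }

    for (int i = 1; i <= n; ++i) {
        Mc[0] = NEG_INF;
        Yc[0] = NEG_INF;
        Xc[0] = gap_open + (i - 1) * gap_extend;
        tbX[i * w] = (i == 1) ? 0 : 1;
        for (int j = 1; j <= m; ++j) {
            const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;

            // M: diagonal move; predecessor preference M > X > Y
            double best = Mp[j - 1]; uint8_t from = 0;
            if (Xp[j - 1] > best) { best = Xp[j - 1]; from = 1; }
            if (Yp[j - 1] > best) { best = Yp[j - 1]; from = 2; }
            Mc[j] = best + s;
            tbM[i * w + j] = from;

            // X: consume a[i-1] against a gap in b (vertical)
            best = Mp[j] + gap_open; from = 0;
            if (Xp[j] + gap_extend > best) { best = Xp[j] + gap_extend; from = 1; }
            if (Yp[j] + gap_open > best) { best = Yp[j] + gap_open; from = 2; }
            Xc[j] = best;
            tbX[i * w + j] = from;

            // Y: consume b[j-1] against a gap in a (horizontal)
            best = Mc[j - 1] + gap_open; from = 0;
            if (Xc[j - 1] + gap_open > best) { best = Xc[j - 1] + gap_open; from = 1; }
            if (Yc[j - 1] + gap_extend > best) { best = Yc[j - 1] + gap_extend; from = 2; }
            Yc[j] = best;
            tbY[i * w + j] = from;
        }
        std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
        if (i % 256 == 0) Rcpp::checkUserInterrupt();
    }

    // final state choice: M > X > Y on ties
    double score = Mp[m]; uint8_t state = 0;
    if (Xp[m] > score) { score = Xp[m]; state = 1; }
    if (Yp[m] > score) { score = Yp[m]; state = 2; }

    std::string ra, rb;
    ra.reserve(n + m); rb.reserve(n + m);
    int i = n, j = m;
    while (i > 0 || j > 0) {
        if (i == 0) state = 2;
        else if (j == 0) state = 1;
        const uint8_t from = (state == 0) ? tbM[i * w + j]
                           : (state == 1) ? tbX[i * w + j]
                                          : tbY[i * w + j];
        if (state == 0) {
            ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
            --i; --j;
        } else if (state == 1) {
            ra.push_back(a[i - 1]); rb.push_back('-');
            --i;
        } else {
            ra.push_back('-'); rb.push_back(b[j - 1]);
            --j;
        }
        state = from;
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());

    return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                        _["score"] = score);
}
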