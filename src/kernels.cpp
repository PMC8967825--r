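#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3D arrays arrive in R's column-major layout with dim = (d1, d2, d3)
// = (planes, rows, cols); linear index = i1 + d1*(i2 + d2*i3), 0-based.

static inline int reflect_idx(int i, int n) {
    // 'reflect' boundary: ... c b a | a b c | c b a ...
    if (n == 1) return 0;
    int period = 2 * n;
    i = ((i % period) + period) % period;
    return (i < n) ? i : (period - 1 - i);
}

// [[Rcpp::export(name = ".cpp_gaussian_blur3")]]
NumericVector cpp_gaussian_blur3(NumericVector vol, IntegerVector dim,
                                 NumericVector sigma_vox) {
    const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
    std::vector<double> src(vol.begin(), vol.end());
    std::vector<double> dst(src.size());

    const int dims[3] = {d1, d2, d3};
    const long strides[3] = {1L, (long)d1, (long)d1 * d2};

    for (int ax = 0; ax < 3; ++ax) {
        double s = sigma_vox[ax];
        if (s <= 0) continue;
        int r = (int)std::ceil(4.0 * s);
        if (r < 1) r = 1;
        std::vector<double> k(2 * r + 1);
        double ksum = 0.0;
        for (int t = -r; t <= r; ++t) {
            k[t + r] = std::exp(-0.5 * (double)t * t / (s * s));
            ksum += k[t + r];
        }
        for (double &kv : k) kv /= ksum;

        const int n = dims[ax];
        const long st = strides[ax];
        // iterate over all lines along axis ax
        int oa = (ax == 0) ? 1 : 0;      // first other axis
        int ob = (ax == 2) ? 1 : 2;      // second other axis
        for (int ib = 0; ib < dims[ob]; ++ib) {
            for (int ia = 0; ia < dims[oa]; ++ia) {
                long base = (long)ia * strides[oa] + (long)ib * strides[ob];
                for (int i = 0; i < n; ++i) {
                    double acc = 0.0;
                    for (int t = -r; t <= r; ++t) {
                        int j = reflect_idx(i + t, n);
                        acc += k[t + r] * src[base + (long)j * st];
                    }
                    dst[base + (long)i * st] = acc;
                }
            }
        }
        std::swap(src, dst);
    }
    NumericVector out(src.begin(), src.end());
    out.attr("dim") = dim;
    return out;
}

// [[Rcpp::export(name = ".cpp_largest_component26")]]
LogicalVector cpp_largest_component26(LogicalVector mask, IntegerVector dim) {
    const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
    const long n = (long)d1 * d2 * d3;
    std::vector<int> label(n, 0);
    int ncomp = 0;
    long best_size = 0;
    int best_label = 0;
    std::vector<long> stack;

    for (long s = 0; s < n; ++s) {
        if (!mask[s] || label[s]) continue;
        ++ncomp;
        long size = 0;
        stack.clear();
        stack.push_back(s);
        label[s] = ncomp;
        while (!stack.empty()) {
            long v = stack.back();
            stack.pop_back();
            ++size;
            int i1 = (int)(v % d1);
            int i2 = (int)((v / d1) % d2);
            int i3 = (int)(v / ((long)d1 * d2));
            for (int a = -1; a <= 1; ++a) {
                int j1 = i1 + a;
                if (j1 < 0 || j1 >= d1) continue;
                for (int b = -1; b <= 1; ++b) {
                    int j2 = i2 + b;
                    if (j2 < 0 || j2 >= d2) continue;
                    for (int c = -1; c <= 1; ++c) {
                        if (!a && !b && !c) continue;
                        int j3 = i3 + c;
                        if (j3 < 0 || j3 >= d3) continue;
                        long w = j1 + (long)d1 * (j2 + (long)d2 * j3);
                        if (mask[w] && !label[w]) {
                            label[w] = ncomp;
                            stack.push_back(w);
                        }
                    }
                }
            }
        }
        if (size > best_size) { best_size = size; best_label = ncomp; }
    }

    LogicalVector out(n, false);
    for (long s = 0; s < n; ++s) out[s] = (label[s] == best_label) && best_label;
    out.attr("dim") = dim;
    return out;
}

// Foreground voxels with at least one 6-neighbour that is background;
// the volume border counts as background.
// [[Rcpp::export(name = ".cpp_boundary6")]]
LogicalVector cpp_boundary6(LogicalVector mask, IntegerVector dim) {
    const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
    const long n = (long)d1 * d2 * d3;
    LogicalVector out(n, false);
    for (long s = 0; s < n; ++s) {
        if (!mask[s]) continue;
        int i1 = (int)(s % d1);
        int i2 = (int)((s / d1) % d2);
        int i3 = (int)(s / ((long)d1 * d2));
        bool bnd =
            (i1 == 0 || !mask[s - 1]) || (i1 == d1 - 1 || !mask[s + 1]) ||
            (i2 == 0 || !mask[s - d1]) || (i2 == d2 - 1 || !mask[s + d1]) ||
            (i3 == 0 || !mask[s - (long)d1 * d2]) ||
            (i3 == d3 - 1 || !mask[s + (long)d1 * d2]);
        out[s] = bnd;
    }
    out.attr("dim") = dim;
    return out;
}

// 1-based linear indices of voxels >= every 26-neighbour and >= thr.
// [[Rcpp::export(name = ".cpp_local_maxima26")]]
IntegerVector cpp_local_maxima26(NumericVector vol, IntegerVector dim,
                                 double thr) {
    const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
    const long n = (long)d1 * d2 * d3;
    std::vector<int> keep;
    for (long s = 0; s < n; ++s) {
        double v = vol[s];
        if (v < thr) continue;
        int i1 = (int)(s % d1);
        int i2 = (int)((s / d1) % d2);
        int i3 = (int)(s / ((long)d1 * d2));
        bool ismax = true;
        for (int a = -1; a <= 1 && ismax; ++a) {
            int j1 = i1 + a;
            if (j1 < 0 || j1 >= d1) continue;
            for (int b = -1; b <= 1 && ismax; ++b) {
                int j2 = i2 + b;
                if (j2 < 0 || j2 >= d2) continue;
                for (int c = -1; c <= 1; ++c) {
                    if (!a && !b && !c) continue;
                    int j3 = i3 + c;
                    if (j3 < 0 || j3 >= d3) continue;
                    if (vol[j1 + (long)d1 * (j2 + (long)d2 * j3)] > v) {
                        ismax = false;
                        break;
                    }
                }
            }
        }
        if (ismax) keep.push_back((int)(s + 1));
    }
    return IntegerVector(keep.begin(), keep.end());
}
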