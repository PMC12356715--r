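#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Uniform B-spline interpolation after Unser's recursive prefiltering.
// Mirror (whole-sample symmetric) boundaries throughout, matching the
// initialisation of the causal/anticausal IIR passes.

static void splinePoles(int degree, std::vector<double> &poles) {
    poles.clear();
    switch (degree) {
    case 0:
    case 1:
        break;
    case 2:
        poles.push_back(std::sqrt(8.0) - 3.0);
        break;
    case 3:
        poles.push_back(std::sqrt(3.0) - 2.0);
        break;
    case 4:
        poles.push_back(std::sqrt(664.0 - std::sqrt(438976.0)) + std::sqrt(304.0) - 19.0);
        poles.push_back(std::sqrt(664.0 + std::sqrt(438976.0)) - std::sqrt(304.0) - 19.0);
        break;
    case 5:
        poles.push_back(std::sqrt(135.0 / 2.0 - std::sqrt(17745.0 / 4.0)) + std::sqrt(105.0 / 4.0) - 13.0 / 2.0);
        poles.push_back(std::sqrt(135.0 / 2.0 + std::sqrt(17745.0 / 4.0)) - std::sqrt(105.0 / 4.0) - 13.0 / 2.0);
        break;
    default:
        stop("spline degree must be in 0..5");
    }
}

static double initialCausal(const double *line, int n, int stride, double z) {
    // sum_{k} s[k] z^k truncated at machine-negligible weight
    int horizon = (int)std::ceil(std::log(1e-14) / std::log(std::fabs(z)));
    if (horizon < n) {
        double zk = z, sum = line[0];
        for (int k = 1; k < horizon; k++) {
            sum += zk * line[k * stride];
            zk *= z;
        }
        return sum;
    }
    // full mirror formula
    double zk = z, z2n = std::pow(z, n - 1), iz = 1.0 / z;
    double sum = line[0] + z2n * line[(n - 1) * stride];
    z2n *= z2n * iz;
    for (int k = 1; k < n - 1; k++) {
        sum += (zk + z2n) * line[k * stride];
        zk *= z;
        z2n *= iz;
    }
    return sum / (1.0 - std::pow(z, 2 * n - 2));
}

static void filterLine(double *line, int n, int stride, const std::vector<double> &poles) {
    if (n == 1) return;
    double gain = 1.0;
    for (size_t p = 0; p < poles.size(); p++)
        gain *= (1.0 - poles[p]) * (1.0 - 1.0 / poles[p]);
    for (int k = 0; k < n; k++) line[k * stride] *= gain;
    for (size_t p = 0; p < poles.size(); p++) {
        double z = poles[p];
        line[0] = initialCausal(line, n, stride, z);
        for (int k = 1; k < n; k++)
            line[k * stride] += z * line[(k - 1) * stride];
        line[(n - 1) * stride] = (z / (z * z - 1.0)) *
            (line[(n - 1) * stride] + z * line[(n - 2) * stride]);
        for (int k = n - 2; k >= 0; k--)
            line[k * stride] = z * (line[(k + 1) * stride] - line[k * stride]);
    }
}

// [[Rcpp::export(name = ".bsplinePrefilter")]]
NumericVector bsplinePrefilter(NumericVector data, IntegerVector dim, int degree) {
    if (degree < 0 || degree > 5) stop("spline degree must be in 0..5");
    NumericVector out = clone(data);
    if (degree < 2) return out;
    std::vector<double> poles;
    splinePoles(degree, poles);
    int nx = dim[0], ny = dim[1], nz = dim[2];
    double *ptr = out.begin();
    for (int z = 0; z < nz; z++)
        for (int y = 0; y < ny; y++)
            filterLine(ptr + (size_t)z * nx * ny + (size_t)y * nx, nx, 1, poles);
    for (int z = 0; z < nz; z++)
        for (int x = 0; x < nx; x++)
            filterLine(ptr + (size_t)z * nx * ny + x, ny, nx, poles);
    for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++)
            filterLine(ptr + (size_t)y * nx + x, nz, (size_t)nx * ny, poles);
    return out;
}

static inline int mirrorIndex(int i, int n) {
    if (n == 1) return 0;
    int period = 2 * n - 2;
    i = i % period;
    if (i < 0) i += period;
    return (i >= n) ? period - i : i;
}

static inline double bsplineKernel(double x, int degree) {
    x = std::fabs(x);
    switch (degree) {
    case 0:
        return (x < 0.5) ? 1.0 : (x == 0.5 ? 0.5 : 0.0);
    case 1:
        return (x < 1.0) ? 1.0 - x : 0.0;
    case 2:
        if (x < 0.5) return 0.75 - x * x;
        if (x < 1.5) { double t = x - 1.5; return 0.5 * t * t; }
        return 0.0;
    case 3:
        if (x < 1.0) return 2.0 / 3.0 - x * x + 0.5 * x * x * x;
        if (x < 2.0) { double t = 2.0 - x; return t * t * t / 6.0; }
        return 0.0;
    case 4:
        if (x < 0.5) {
            double x2 = x * x;
            return x2 * (x2 * 0.25 - 0.625) + 115.0 / 192.0;
        }
        if (x < 1.5) {
            return x * (x * (x * (5.0 - x) / 6.0 - 1.25) + 5.0 / 24.0) + 55.0 / 96.0;
        }
        if (x < 2.5) {
            double t = x - 2.5; t *= t;
            return t * t / 24.0;
        }
        return 0.0;
    case 5:
        if (x < 1.0) {
            double x2 = x * x;
            return x2 * x2 * (3.0 - x) / 12.0 - 0.5 * x2 + 0.55;
        }
        if (x < 2.0) {
            return x * (x * (x * (x * (x / 24.0 - 0.375) + 1.25) - 1.75) + 0.625) + 0.425;
        }
        if (x < 3.0) {
            double t = 3.0 - x;
            double t2 = t * t;
            return t2 * t2 * t / 120.0;
        }
        return 0.0;
    }
    return 0.0;
}

// coords: n x 3 matrix of 0-based voxel coordinates in the coefficient grid
// [[Rcpp::export(name = ".bsplineSample")]]
NumericVector bsplineSample(NumericVector coef, IntegerVector dim,
                            NumericMatrix coords, int degree, bool zeroOutside) {
    if (degree < 0 || degree > 5) stop("spline degree must be in 0..5");
    int nx = dim[0], ny = dim[1], nz = dim[2];
    int n = coords.nrow();
    NumericVector out(n);
    int support = degree + 1;
    std::vector<int> ix(support), iy(support), iz(support);
    std::vector<double> wx(support), wy(support), wz(support);
    const double *cf = coef.begin();
    double half = (degree + 1) / 2.0;
    for (int i = 0; i < n; i++) {
        double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
        if (ISNAN(x) || ISNAN(y) || ISNAN(z)) { out[i] = NA_REAL; continue; }
        if (zeroOutside &&
            (x < -0.5 || x > nx - 0.5 || y < -0.5 || y > ny - 0.5 ||
             z < -0.5 || z > nz - 0.5)) {
            out[i] = 0.0;
            continue;
        }
        int kx0 = (int)std::ceil(x - half), ky0 = (int)std::ceil(y - half),
            kz0 = (int)std::ceil(z - half);
        // degenerate tie when x - half is an integer: ceil collapses the
        // support by one; nudge to keep degree+1 taps (weight of extra tap = 0)
        for (int s = 0; s < support; s++) {
            ix[s] = mirrorIndex(kx0 + s, nx); wx[s] = bsplineKernel(x - (kx0 + s), degree);
            iy[s] = mirrorIndex(ky0 + s, ny); wy[s] = bsplineKernel(y - (ky0 + s), degree);
            iz[s] = mirrorIndex(kz0 + s, nz); wz[s] = bsplineKernel(z - (kz0 + s), degree);
        }
        double acc = 0.0;
        for (int c = 0; c < support; c++) {
            if (wz[c] == 0.0) continue;
            double accz = 0.0;
            size_t offz = (size_t)iz[c] * nx * ny;
            for (int b = 0; b < support; b++) {
                if (wy[b] == 0.0) continue;
                double accy = 0.0;
                size_t offy = offz + (size_t)iy[b] * nx;
                for (int a = 0; a < support; a++)
                    accy += wx[a] * cf[offy + ix[a]];
                accz += wy[b] * accy;
            }
            acc += wz[c] * accz;
        }
        out[i] = acc;
    }
    return out;
}
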