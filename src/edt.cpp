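#include <Rcpp.h>
using namespace Rcpp;

// 1D squared Euclidean distance transform (lower-envelope algorithm of
// Felzenszwalb & Huttenlocher), sample positions q*h for grid step h (mm).
static void dt1d(const double* f, double* d, int* v, double* z, int n, double h) {
    if (n == 1) { d[0] = f[0]; return; }
    int k = 0;
    v[0] = 0;
    z[0] = -std::numeric_limits<double>::infinity();
    z[1] = std::numeric_limits<double>::infinity();
    for (int q = 1; q < n; q++) {
        double s = 0.0;
        while (true) {
            double xq = q * h, xv = v[k] * h;
            s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
            if (k > 0 && s <= z[k]) k--; else break;
        }
        k++;
        v[k] = q;
        z[k] = s;
        z[k + 1] = std::numeric_limits<double>::infinity();
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        double xq = q * h;
        while (z[k + 1] < xq) k++;
        double dx = xq - v[k] * h;
        d[q] = dx * dx + f[v[k]];
    }
}

// Exact 3D Euclidean distance transform with anisotropic spacing.
// Input: binary volume (non-zero = foreground). Output: distance (mm) from
// every voxel to the nearest background (zero) voxel inside the volume;
// background voxels map to 0. If the volume has no background voxel every
// distance is +Inf.
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(IntegerVector mask, IntegerVector dims, NumericVector spacing) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    // large finite stand-in for +Inf keeps the envelope intersections finite
    const double BIG = 1e20;
    for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] != 0 ? BIG : 0.0;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x
    for (int k = 0; k < nz; k++)
        for (int j = 0; j < ny; j++) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
            for (int i = 0; i < nx; i++) f[i] = out[base + i];
            dt1d(f.data(), d.data(), v.data(), z.data(), nx, spacing[0]);
            for (int i = 0; i < nx; i++) out[base + i] = d[i];
        }
    // pass along y
    for (int k = 0; k < nz; k++)
        for (int i = 0; i < nx; i++) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + i;
            for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)j * nx];
            dt1d(f.data(), d.data(), v.data(), z.data(), ny, spacing[1]);
            for (int j = 0; j < ny; j++) out[base + (R_xlen_t)j * nx] = d[j];
        }
    // pass along z
    for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
            R_xlen_t base = (R_xlen_t)j * nx + i;
            for (int k = 0; k < nz; k++) f[k] = out[base + (R_xlen_t)k * nx * ny];
            dt1d(f.data(), d.data(), v.data(), z.data(), nz, spacing[2]);
            for (int k = 0; k < nz; k++) {
                double val = std::sqrt(d[k]);
                out[base + (R_xlen_t)k * nx * ny] =
                    (val > 1e9) ? std::numeric_limits<double>::infinity() : val;
            }
        }
    return out;
}
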