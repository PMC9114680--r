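#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labelling of a 3D binary volume (BFS flood fill).
// Returns integer labels 1..K, 0 for background.
// [[Rcpp::export(name = ".ccl3d_cpp")]]
IntegerVector ccl3d_cpp(IntegerVector mask, IntegerVector dims) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector lab(n, 0);
    std::vector<R_xlen_t> queue;
    int next = 0;
    for (R_xlen_t s = 0; s < n; s++) {
        if (mask[s] == 0 || lab[s] != 0) continue;
        next++;
        lab[s] = next;
        queue.clear();
        queue.push_back(s);
        while (!queue.empty()) {
            R_xlen_t cur = queue.back();
            queue.pop_back();
            int k = cur / (nx * ny);
            int rem = cur % (nx * ny);
            int j = rem / nx;
            int i = rem % nx;
            for (int dk = -1; dk <= 1; dk++)
                for (int dj = -1; dj <= 1; dj++)
                    for (int di = -1; di <= 1; di++) {
                        if (di == 0 && dj == 0 && dk == 0) continue;
                        int ii = i + di, jj = j + dj, kk = k + dk;
                        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny ||
                            kk < 0 || kk >= nz) continue;
                        R_xlen_t t = (R_xlen_t)kk * nx * ny +
                                     (R_xlen_t)jj * nx + ii;
                        if (mask[t] != 0 && lab[t] == 0) {
                            lab[t] = next;
                            queue.push_back(t);
                        }
                    }
        }
    }
    return lab;
}
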