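#include <Rcpp.h>
#include <vector>
#include <limits>
#include <functional>
using namespace Rcpp;

// Large finite stand-in for +Inf so parabola intersections stay well defined;
// any true squared distance on a raster is bounded by nrow^2 + ncol^2.
static const double EDT_INF = 1e15;

// 1D lower-envelope squared distance transform (Felzenszwalb & Huttenlocher).
// f: sampled function (0 at sites, EDT_INF elsewhere); writes d[q] = min_p (q-p)^2 + f[p].
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = 0;
    v[0] = 0;
    z[0] = -std::numeric_limits<double>::infinity();
    z[1] = std::numeric_limits<double>::infinity();
    for (int q = 1; q < n; ++q) {
        double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
                   (2.0 * q - 2.0 * v[k]);
        while (s <= z[k]) {
            --k;
            s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
                (2.0 * q - 2.0 * v[k]);
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = std::numeric_limits<double>::infinity();
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        double dq = q - (double)v[k];
        d[q] = dq * dq + f[v[k]];
    }
}

// Exact squared Euclidean distance transform: for every pixel, the squared
// distance (in pixel units, centre-to-centre) to the nearest nonzero pixel of
// `sites`. Pixels with no site anywhere get a value >= 1e15 (treat as Inf).
// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(IntegerMatrix sites) {
    int nr = sites.nrow(), nc = sites.ncol();
    NumericMatrix out(nr, nc);
    std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));

    // pass 1: columns
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) f[i] = sites(i, j) != 0 ? 0.0 : EDT_INF;
        dt1d(f, d, nr);
        for (int i = 0; i < nr; ++i) out(i, j) = d[i];
    }
    // pass 2: rows
    for (int i = 0; i < nr; ++i) {
        for (int j = 0; j < nc; ++j) f[j] = out(i, j);
        dt1d(f, d, nc);
        for (int j = 0; j < nc; ++j) out(i, j) = d[j];
    }
    return out;
}

// Connected-component labeling of a binary matrix under 4- or 8-connectivity.
// Labels are compacted to 1..n in order of first appearance in column-major
// scan order, so the result is fully deterministic.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(IntegerMatrix mask, int connectivity) {
    if (connectivity != 4 && connectivity != 8)
        stop("connectivity must be 4 or 8");
    int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    std::vector<int> parent;
    parent.reserve(1024);
    parent.push_back(0); // label 0 unused

    std::function<int(int)> find = [&](int x) {
        while (parent[x] != x) {
            parent[x] = parent[parent[x]];
            x = parent[x];
        }
        return x;
    };
    auto unite = [&](int a, int b) {
        a = find(a); b = find(b);
        if (a != b) parent[std::max(a, b)] = std::min(a, b);
    };

    int next = 1;
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            if (mask(i, j) == 0) continue;
            int up   = (i > 0)           ? lab(i - 1, j)     : 0;
            int left = (j > 0)           ? lab(i, j - 1)     : 0;
            int ul = 0, dl = 0;
            if (connectivity == 8) {
                ul = (i > 0 && j > 0)      ? lab(i - 1, j - 1) : 0;
                dl = (i < nr - 1 && j > 0) ? lab(i + 1, j - 1) : 0;
            }
            int lbl = 0;
            for (int nb : {up, left, ul, dl}) {
                if (nb == 0) continue;
                if (lbl == 0) lbl = nb;
                else unite(lbl, nb);
            }
            if (lbl == 0) {
                lbl = next++;
                parent.push_back(lbl);
            }
            lab(i, j) = lbl;
        }
    }
    // compact in column-major first-appearance order
    std::vector<int> remap(next, 0);
    int out_n = 0;
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            if (lab(i, j) == 0) continue;
            int r = find(lab(i, j));
            if (remap[r] == 0) remap[r] = ++out_n;
            lab(i, j) = remap[r];
        }
    }
    return lab;
}

// Paint filled disks into an integer label image. A pixel (1-based row i,
// col j) has centre (x, y) = (j - 0.5, i - 0.5) in pixel units; it is painted
// with the disk id when the centre lies within radius r of the disk centre.
// Later disks overwrite earlier ones where footprints overlap.
// [[Rcpp::export]]
IntegerMatrix paint_disks_cpp(int nrow, int ncol, NumericVector cx,
                              NumericVector cy, NumericVector r) {
    IntegerMatrix lab(nrow, ncol);
    int n = cx.size();
    for (int k = 0; k < n; ++k) {
        double x = cx[k], y = cy[k], rad = r[k], r2 = rad * rad;
        int j0 = std::max(0, (int)std::floor(x - rad));
        int j1 = std::min(ncol - 1, (int)std::ceil(x + rad));
        int i0 = std::max(0, (int)std::floor(y - rad));
        int i1 = std::min(nrow - 1, (int)std::ceil(y + rad));
        for (int j = j0; j <= j1; ++j) {
            double dx = (j + 0.5) - x;
            for (int i = i0; i <= i1; ++i) {
                double dy = (i + 0.5) - y;
                if (dx * dx + dy * dy <= r2) lab(i, j) = k + 1;
            }
        }
    }
    return lab;
}

// Distance from each query point to the nearest point on a closed polygon
// boundary (vertices in order, implicit closure). Pixel-unit coordinates.
// [[Rcpp::export]]
NumericVector dist_to_polygon_cpp(NumericVector px, NumericVector py,
                                  NumericVector vx, NumericVector vy) {
    int n = px.size(), m = vx.size();
    NumericVector out(n);
    for (int k = 0; k < n; ++k) {
        double best = std::numeric_limits<double>::infinity();
        for (int e = 0; e < m; ++e) {
            double ax = vx[e], ay = vy[e];
            double bx = vx[(e + 1) % m], by = vy[(e + 1) % m];
            double abx = bx - ax, aby = by - ay;
            double len2 = abx * abx + aby * aby;
            double t = len2 > 0 ? ((px[k] - ax) * abx + (py[k] - ay) * aby) / len2 : 0.0;
            t = std::max(0.0, std::min(1.0, t));
            double dx = px[k] - (ax + t * abx), dy = py[k] - (ay + t * aby);
            double d2 = dx * dx + dy * dy;
            if (d2 < best) best = d2;
        }
        out[k] = std::sqrt(best);
    }
    return out;
}
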