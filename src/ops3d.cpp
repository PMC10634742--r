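#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Dense 3D tensor ops for the segmentation network.  Tensors are plain R
// arrays in column-major order with dim (X, Y, Z, C, N); convolution kernels
// have dim (K, K, K, Cin, Cout) with odd K and zero ("same") padding.

static inline R_xlen_t idx5(int x, int y, int z, int c, int n,
                            int X, int Y, int Z, int C) {
    return (R_xlen_t)x +
           (R_xlen_t)X * (y + (R_xlen_t)Y * (z + (R_xlen_t)Z * (c + (R_xlen_t)C * n)));
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
    IntegerVector xd = x.attr("dim");
    IntegerVector wd = w.attr("dim");
    if (xd.size() != 5 || wd.size() != 5)
        stop("conv3d_fwd: x must be 5-d (X,Y,Z,C,N), w must be 5-d (K,K,K,Cin,Cout)");
    const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3], N = xd[4];
    const int K = wd[0], Co = wd[4];
    if (wd[3] != Ci) stop("conv3d_fwd: channel mismatch");
    if (K % 2 == 0) stop("conv3d_fwd: kernel size must be odd");
    const int h = K / 2;
    const R_xlen_t vox = (R_xlen_t)X * Y * Z;

    NumericVector y(vox * Co * N);
    y.attr("dim") = IntegerVector::create(X, Y, Z, Co, N);
    double *yp = REAL(y);
    const double *xp = REAL(x), *wp = REAL(w), *bp = REAL(b);

    for (int n = 0; n < N; n++)
        for (int co = 0; co < Co; co++) {
            const double bb = bp[co];
            double *dst = yp + vox * (co + (R_xlen_t)Co * n);
            for (R_xlen_t i = 0; i < vox; i++) dst[i] = bb;
        }

    for (int n = 0; n < N; n++)
        for (int co = 0; co < Co; co++)
            for (int ci = 0; ci < Ci; ci++)
                for (int kz = 0; kz < K; kz++) {
                    const int dz = kz - h;
                    for (int ky = 0; ky < K; ky++) {
                        const int dy = ky - h;
                        for (int kx = 0; kx < K; kx++) {
                            const int dx = kx - h;
                            const double wv =
                                wp[kx + (R_xlen_t)K * (ky + (R_xlen_t)K * (kz + (R_xlen_t)K * (ci + (R_xlen_t)Ci * co)))];
                            if (wv == 0.0) continue;
                            const int z0 = std::max(0, -dz), z1 = std::min(Z, Z - dz);
                            const int y0 = std::max(0, -dy), y1 = std::min(Y, Y - dy);
                            const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
                            for (int z = z0; z < z1; z++)
                                for (int yy = y0; yy < y1; yy++) {
                                    double *yrow = yp + idx5(0, yy, z, co, n, X, Y, Z, Co);
                                    const double *xrow =
                                        xp + idx5(dx, yy + dy, z + dz, ci, n, X, Y, Z, Ci);
                                    for (int xx = x0; xx < x1; xx++)
                                        yrow[xx] += wv * xrow[xx];
                                }
                        }
                    }
                }
    return y;
}

// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
    IntegerVector xd = x.attr("dim");
    IntegerVector wd = w.attr("dim");
    const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3], N = xd[4];
    const int K = wd[0], Co = wd[4];
    const int h = K / 2;

    NumericVector gx(x.size());
    gx.attr("dim") = xd;
    NumericVector gw(w.size());
    gw.attr("dim") = wd;
    NumericVector gb(Co);

    double *gxp = REAL(gx), *gwp = REAL(gw), *gbp = REAL(gb);
    const double *xp = REAL(x), *wp = REAL(w), *gyp = REAL(gy);
    const R_xlen_t vox = (R_xlen_t)X * Y * Z;

    for (int n = 0; n < N; n++)
        for (int co = 0; co < Co; co++) {
            const double *g = gyp + vox * (co + (R_xlen_t)Co * n);
            double acc = 0.0;
            for (R_xlen_t i = 0; i < vox; i++) acc += g[i];
            gbp[co] += acc;
        }

    for (int n = 0; n < N; n++)
        for (int co = 0; co < Co; co++)
            for (int ci = 0; ci < Ci; ci++)
                for (int kz = 0; kz < K; kz++) {
                    const int dz = kz - h;
                    for (int ky = 0; ky < K; ky++) {
                        const int dy = ky - h;
                        for (int kx = 0; kx < K; kx++) {
                            const int dx = kx - h;
                            const R_xlen_t wi =
                                kx + (R_xlen_t)K * (ky + (R_xlen_t)K * (kz + (R_xlen_t)K * (ci + (R_xlen_t)Ci * co)));
                            const double wv = wp[wi];
                            const int z0 = std::max(0, -dz), z1 = std::min(Z, Z - dz);
                            const int y0 = std::max(0, -dy), y1 = std::min(Y, Y - dy);
                            const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
                            double acc = 0.0;
                            for (int z = z0; z < z1; z++)
                                for (int yy = y0; yy < y1; yy++) {
                                    const double *grow = gyp + idx5(0, yy, z, co, n, X, Y, Z, Co);
                                    const double *xrow =
                                        xp + idx5(dx, yy + dy, z + dz, ci, n, X, Y, Z, Ci);
                                    double *gxrow =
                                        gxp + idx5(dx, yy + dy, z + dz, ci, n, X, Y, Z, Ci);
                                    for (int xx = x0; xx < x1; xx++) {
                                        acc += xrow[xx] * grow[xx];
                                        gxrow[xx] += wv * grow[xx];
                                    }
                                }
                            gwp[wi] += acc;
                        }
                    }
                }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling; also returns 0-based argmax linear indices into x.
// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector x) {
    IntegerVector xd = x.attr("dim");
    const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3], N = xd[4];
    if (X % 2 || Y % 2 || Z % 2) stop("maxpool3d_fwd: spatial dims must be even");
    const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;

    NumericVector y((R_xlen_t)Xo * Yo * Zo * C * N);
    y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C, N);
    IntegerVector am(y.size());
    double *yp = REAL(y);
    int *ap = INTEGER(am);
    const double *xp = REAL(x);

    R_xlen_t o = 0;
    for (int n = 0; n < N; n++)
        for (int c = 0; c < C; c++)
            for (int zo = 0; zo < Zo; zo++)
                for (int yo = 0; yo < Yo; yo++)
                    for (int xo = 0; xo < Xo; xo++, o++) {
                        double best = -1e300;
                        R_xlen_t bi = 0;
                        for (int dz = 0; dz < 2; dz++)
                            for (int dy = 0; dy < 2; dy++)
                                for (int dx = 0; dx < 2; dx++) {
                                    const R_xlen_t i = idx5(2 * xo + dx, 2 * yo + dy,
                                                            2 * zo + dz, c, n, X, Y, Z, C);
                                    if (xp[i] > best) { best = xp[i]; bi = i; }
                                }
                        yp[o] = best;
                        ap[o] = (int)bi;
                    }
    return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd(NumericVector gy, IntegerVector argmax, IntegerVector xdim) {
    R_xlen_t len = 1;
    for (int i = 0; i < xdim.size(); i++) len *= xdim[i];
    NumericVector gx(len);
    gx.attr("dim") = xdim;
    double *gxp = REAL(gx);
    const double *gyp = REAL(gy);
    const int *ap = INTEGER(argmax);
    for (R_xlen_t i = 0; i < gy.size(); i++) gxp[ap[i]] += gyp[i];
    return gx;
}

// Nearest-neighbour upsampling by a factor of 2 per spatial axis.
// [[Rcpp::export]]
NumericVector upsample3d_fwd(NumericVector x) {
    IntegerVector xd = x.attr("dim");
    const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3], N = xd[4];
    const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
    NumericVector y((R_xlen_t)Xo * Yo * Zo * C * N);
    y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C, N);
    double *yp = REAL(y);
    const double *xp = REAL(x);
    R_xlen_t o = 0;
    for (int n = 0; n < N; n++)
        for (int c = 0; c < C; c++)
            for (int zo = 0; zo < Zo; zo++)
                for (int yo = 0; yo < Yo; yo++)
                    for (int xo = 0; xo < Xo; xo++, o++)
                        yp[o] = xp[idx5(xo / 2, yo / 2, zo / 2, c, n, X, Y, Z, C)];
    return y;
}

// [[Rcpp::export]]
NumericVector upsample3d_bwd(NumericVector gy) {
    IntegerVector yd = gy.attr("dim");
    const int Xo = yd[0], Yo = yd[1], Zo = yd[2], C = yd[3], N = yd[4];
    const int X = Xo / 2, Y = Yo / 2, Z = Zo / 2;
    NumericVector gx((R_xlen_t)X * Y * Z * C * N);
    gx.attr("dim") = IntegerVector::create(X, Y, Z, C, N);
    double *gxp = REAL(gx);
    const double *gyp = REAL(gy);
    R_xlen_t o = 0;
    for (int n = 0; n < N; n++)
        for (int c = 0; c < C; c++)
            for (int zo = 0; zo < Zo; zo++)
                for (int yo = 0; yo < Yo; yo++)
                    for (int xo = 0; xo < Xo; xo++, o++)
                        gxp[idx5(xo / 2, yo / 2, zo / 2, c, n, X, Y, Z, C)] += gyp[o];
    return gx;
}
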