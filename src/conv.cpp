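// Valid 2-D convolution forward/backward for small time-series CNNs.
// Arrays are R column-major: x (H, W, Cin, N), w (kh, kw, Cin, Cout),
// outputs (Ho, Wo, Cout, N) with Ho = H - kh + 1, Wo = W - kw + 1.
// im2col + GEMM per sample; backward recomputes the patch matrix instead of
// caching it, keeping memory flat in batch size.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col(const double* xn, int H, int W, int Cin, int kh, int kw,
                   int Ho, int Wo, arma::mat& cols) {
    for (int c = 0; c < Cin; ++c)
        for (int dw = 0; dw < kw; ++dw)
            for (int dh = 0; dh < kh; ++dh) {
                const int q = dh + kh * (dw + kw * c);
                double* col = cols.colptr(q);
                for (int wo = 0; wo < Wo; ++wo) {
                    const double* src = xn + dh + (size_t)H * ((wo + dw) + (size_t)W * c);
                    std::copy(src, src + Ho, col + (size_t)wo * Ho);
                }
            }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
    IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
    const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
    const int kh = wd[0], kw = wd[1], Cout = wd[3];
    if (wd[2] != Cin) stop("weight/input channel mismatch");
    if (H < kh || W < kw) stop("input smaller than kernel");
    const int Ho = H - kh + 1, Wo = W - kw + 1, nPos = Ho * Wo, P = kh * kw * Cin;
    arma::mat Wm(w.begin(), P, Cout, false, true);
    arma::rowvec bv(b.begin(), Cout);
    NumericVector out((R_xlen_t)nPos * Cout * N);
    out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
    arma::mat cols(nPos, P);
    for (int n = 0; n < N; ++n) {
        im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin, kh, kw, Ho, Wo, cols);
        arma::mat Y = cols * Wm;
        Y.each_row() += bv;
        std::copy(Y.begin(), Y.end(), out.begin() + (size_t)n * nPos * Cout);
    }
    return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dout,
                    bool need_dx = true) {
    IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
    const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
    const int kh = wd[0], kw = wd[1], Cout = wd[3];
    const int Ho = H - kh + 1, Wo = W - kw + 1, nPos = Ho * Wo, P = kh * kw * Cin;
    arma::mat Wm(w.begin(), P, Cout, false, true);
    NumericVector dx((R_xlen_t)H * W * Cin * N);
    dx.attr("dim") = xd;
    arma::mat dW(P, Cout, arma::fill::zeros);
    arma::rowvec db(Cout, arma::fill::zeros);
    arma::mat cols(nPos, P);
    for (int n = 0; n < N; ++n) {
        const double* xn = x.begin() + (size_t)n * H * W * Cin;
        im2col(xn, H, W, Cin, kh, kw, Ho, Wo, cols);
        arma::mat dY(const_cast<double*>(dout.begin()) + (size_t)n * nPos * Cout,
                     nPos, Cout, false, true);
        dW += cols.t() * dY;
        db += arma::sum(dY, 0);
        if (!need_dx) continue;
        arma::mat dcols = dY * Wm.t();   // nPos x P
        double* dxn = dx.begin() + (size_t)n * H * W * Cin;
        for (int c = 0; c < Cin; ++c)
            for (int dw_ = 0; dw_ < kw; ++dw_)
                for (int dh = 0; dh < kh; ++dh) {
                    const int q = dh + kh * (dw_ + kw * c);
                    const double* col = dcols.colptr(q);
                    for (int wo = 0; wo < Wo; ++wo) {
                        double* dst = dxn + dh + (size_t)H * ((wo + dw_) + (size_t)W * c);
                        const double* src = col + (size_t)wo * Ho;
                        for (int ho = 0; ho < Ho; ++ho) dst[ho] += src[ho];
                    }
                }
    }
    NumericVector dwOut(w.length());
    dwOut.attr("dim") = wd;
    std::copy(dW.begin(), dW.end(), dwOut.begin());
    return List::create(_["dx"] = dx, _["dw"] = dwOut,
                        _["db"] = NumericVector(db.begin(), db.end()));
}

// Per-channel helpers for batch norm on (H, W, C, N) arrays: y = a[c]*x + b[c],
// per-channel sums, and per-channel dot products.

// [[Rcpp::export]]
NumericVector cpp_chan_affine(NumericVector x, NumericVector a, NumericVector b) {
    IntegerVector xd = x.attr("dim");
    const size_t nPos = (size_t)xd[0] * xd[1];
    const int C = xd[2], N = xd[3];
    NumericVector out(x.length());
    out.attr("dim") = xd;
    const double* src = x.begin();
    double* dst = out.begin();
    for (int n = 0; n < N; ++n)
        for (int c = 0; c < C; ++c) {
            const double ac = a[c], bc = b[c];
            for (size_t i = 0; i < nPos; ++i, ++src, ++dst) *dst = ac * *src + bc;
        }
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_chan_sums(NumericVector x) {
    IntegerVector xd = x.attr("dim");
    const size_t nPos = (size_t)xd[0] * xd[1];
    const int C = xd[2], N = xd[3];
    NumericVector out(C);
    const double* src = x.begin();
    for (int n = 0; n < N; ++n)
        for (int c = 0; c < C; ++c) {
            double s = 0;
            for (size_t i = 0; i < nPos; ++i, ++src) s += *src;
            out[c] += s;
        }
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_chan_dot(NumericVector x, NumericVector y) {
    IntegerVector xd = x.attr("dim");
    const size_t nPos = (size_t)xd[0] * xd[1];
    const int C = xd[2], N = xd[3];
    NumericVector out(C);
    const double* sx = x.begin();
    const double* sy = y.begin();
    for (int n = 0; n < N; ++n)
        for (int c = 0; c < C; ++c) {
            double s = 0;
            for (size_t i = 0; i < nPos; ++i, ++sx, ++sy) s += *sx * *sy;
            out[c] += s;
        }
    return out;
}

// Leaky ReLU forward returning activation and slope mask in one pass.

// [[Rcpp::export]]
List cpp_lrelu(NumericVector x, double slope) {
    NumericVector y(x.length()), m(x.length());
    y.attr("dim") = x.attr("dim");
    m.attr("dim") = x.attr("dim");
    for (R_xlen_t i = 0; i < x.length(); ++i) {
        if (x[i] >= 0) { y[i] = x[i]; m[i] = 1.0; }
        else { y[i] = slope * x[i]; m[i] = slope; }
    }
    return List::create(_["y"] = y, _["m"] = m);
}
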