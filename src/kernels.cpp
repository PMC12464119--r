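// Computational kernels: im2col 3D convolution support, the selective
// state-space scan recurrence and its adjoint, and 3D windowed
// multi-head attention. Tensors are column-major arrays in channel-first
// layout (C, X, Y, Z); token matrices are (tokens x channels).

#include <RcppArmadillo.h>
#include <dlfcn.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Pin the BLAS thread pool (OpenBLAS oversubscription is ruinous for the
// many small/medium GEMMs this workload issues). No-op for other BLASes.
// [[Rcpp::export]]
bool cpp_set_blas_threads(int n) {
  typedef void (*fn_t)(int);
  fn_t f = (fn_t)dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (f == nullptr) return false;
  f(n);
  return true;
}

static inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col3(NumericVector x, IntegerVector dims, int k,
                          int stride, int pad) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int Xo = out_extent(X, k, stride, pad);
  const int Yo = out_extent(Y, k, stride, pad);
  const int Zo = out_extent(Z, k, stride, pad);
  const int K3 = k * k * k;
  NumericMatrix out(C * K3, (R_xlen_t)Xo * Yo * Zo);
  const double *px = x.begin();
  double *po = out.begin();
  const R_xlen_t ncolrow = (R_xlen_t)C * K3;
  R_xlen_t col = 0;
  for (int oz = 0; oz < Zo; ++oz) {
    for (int oy = 0; oy < Yo; ++oy) {
      for (int ox = 0; ox < Xo; ++ox, ++col) {
        double *dst = po + col * ncolrow;
        int r = 0;
        for (int kz = 0; kz < k; ++kz) {
          const int iz = oz * stride - pad + kz;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride - pad + ky;
            for (int kx = 0; kx < k; ++kx, r += C) {
              const int ix = ox * stride - pad + kx;
              if (ix >= 0 && ix < X && iy >= 0 && iy < Y && iz >= 0 && iz < Z) {
                const double *src =
                    px + (R_xlen_t)C * (ix + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz));
                memcpy(dst + r, src, C * sizeof(double));
              } else {
                memset(dst + r, 0, C * sizeof(double));
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im3(NumericMatrix cols, IntegerVector dims, int k,
                          int stride, int pad) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int Xo = out_extent(X, k, stride, pad);
  const int Yo = out_extent(Y, k, stride, pad);
  const int Zo = out_extent(Z, k, stride, pad);
  const int K3 = k * k * k;
  NumericVector out((R_xlen_t)C * X * Y * Z);
  double *po = out.begin();
  const double *pc = cols.begin();
  const R_xlen_t ncolrow = (R_xlen_t)C * K3;
  R_xlen_t col = 0;
  for (int oz = 0; oz < Zo; ++oz) {
    for (int oy = 0; oy < Yo; ++oy) {
      for (int ox = 0; ox < Xo; ++ox, ++col) {
        const double *src = pc + col * ncolrow;
        int r = 0;
        for (int kz = 0; kz < k; ++kz) {
          const int iz = oz * stride - pad + kz;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride - pad + ky;
            for (int kx = 0; kx < k; ++kx, r += C) {
              const int ix = ox * stride - pad + kx;
              if (ix >= 0 && ix < X && iy >= 0 && iy < Y && iz >= 0 && iz < Z) {
                double *dst =
                    po + (R_xlen_t)C * (ix + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz));
                for (int c = 0; c < C; ++c) dst[c] += src[r + c];
              }
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, X, Y, Z);
  return out;
}

// ---- selective state-space scan --------------------------------------------
// u, delta: (C, L, M); B, Cc: (N, L, M); Alog: (C, N); D: (C).
// Unidirectional forward recurrence along the L dimension, independent
// per sequence m and channel c, with shared input-dependent B_t, C_t:
//   h_t = exp(delta_t * A) h_{t-1} + delta_t B_t u_t,  y_t = C_t . h_t + D u_t
// where A = -exp(Alog) guarantees stability.

// [[Rcpp::export]]
List cpp_sscan_fwd(NumericVector u, NumericVector delta, NumericVector B,
                   NumericVector Cc, NumericMatrix Alog, NumericVector D,
                   int C, int L, int M, int N, bool want_cache) {
  NumericVector y((R_xlen_t)C * L * M);
  NumericVector hs(want_cache ? (R_xlen_t)C * N * L * M : 0);
  std::vector<double> A((size_t)C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) A[c + (size_t)C * n] = -std::exp(Alog(c, n));
  std::vector<double> h((size_t)C * N);
  const double *pu = u.begin(), *pd = delta.begin(), *pB = B.begin(),
               *pC = Cc.begin(), *pD = D.begin();
  double *py = y.begin();
  double *ph = want_cache ? hs.begin() : nullptr;
  for (int m = 0; m < M; ++m) {
    std::fill(h.begin(), h.end(), 0.0);
    const R_xlen_t baseCL = (R_xlen_t)C * L * m;
    const R_xlen_t baseNL = (R_xlen_t)N * L * m;
    for (int t = 0; t < L; ++t) {
      const double *ut = pu + baseCL + (R_xlen_t)C * t;
      const double *dt = pd + baseCL + (R_xlen_t)C * t;
      const double *Bt = pB + baseNL + (R_xlen_t)N * t;
      const double *Ct = pC + baseNL + (R_xlen_t)N * t;
      double *yt = py + baseCL + (R_xlen_t)C * t;
      for (int c = 0; c < C; ++c) {
        const double d = dt[c], uu = ut[c];
        double acc = 0.0;
        double *hc = h.data() + c;
        const double *Ac = A.data() + c;
        for (int n = 0; n < N; ++n) {
          const double a = std::exp(d * Ac[(size_t)C * n]);
          const double hn = a * hc[(size_t)C * n] + d * Bt[n] * uu;
          hc[(size_t)C * n] = hn;
          acc += Ct[n] * hn;
        }
        yt[c] = acc + pD[c] * uu;
      }
      if (want_cache) {
        memcpy(ph + (R_xlen_t)C * N * (t + (R_xlen_t)L * m), h.data(),
               (size_t)C * N * sizeof(double));
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, L, M);
  return List::create(_["y"] = y, _["h"] = hs);
}

// [[Rcpp::export]]
List cpp_sscan_bwd(NumericVector u, NumericVector delta, NumericVector B,
                   NumericVector Cc, NumericMatrix Alog, NumericVector D,
                   NumericVector hs, NumericVector gy, int C, int L, int M,
                   int N) {
  NumericVector gu((R_xlen_t)C * L * M), gdelta((R_xlen_t)C * L * M);
  NumericVector gB((R_xlen_t)N * L * M), gC((R_xlen_t)N * L * M);
  NumericMatrix gAlog(C, N);
  NumericVector gD(C);
  std::vector<double> A((size_t)C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) A[c + (size_t)C * n] = -std::exp(Alog(c, n));
  std::vector<double> gh((size_t)C * N);
  std::vector<double> gA((size_t)C * N, 0.0);
  const double *pu = u.begin(), *pd = delta.begin(), *pB = B.begin(),
               *pC = Cc.begin(), *pD = D.begin(), *ph = hs.begin(),
               *pg = gy.begin();
  for (int m = 0; m < M; ++m) {
    std::fill(gh.begin(), gh.end(), 0.0);
    const R_xlen_t baseCL = (R_xlen_t)C * L * m;
    const R_xlen_t baseNL = (R_xlen_t)N * L * m;
    for (int t = L - 1; t >= 0; --t) {
      const double *ut = pu + baseCL + (R_xlen_t)C * t;
      const double *dt = pd + baseCL + (R_xlen_t)C * t;
      const double *Bt = pB + baseNL + (R_xlen_t)N * t;
      const double *Ct = pC + baseNL + (R_xlen_t)N * t;
      const double *gyt = pg + baseCL + (R_xlen_t)C * t;
      const double *ht = ph + (R_xlen_t)C * N * (t + (R_xlen_t)L * m);
      const double *htm1 =
          (t > 0) ? ph + (R_xlen_t)C * N * ((t - 1) + (R_xlen_t)L * m) : nullptr;
      double *gut = gu.begin() + baseCL + (R_xlen_t)C * t;
      double *gdt = gdelta.begin() + baseCL + (R_xlen_t)C * t;
      double *gBt = gB.begin() + baseNL + (R_xlen_t)N * t;
      double *gCt = gC.begin() + baseNL + (R_xlen_t)N * t;
      for (int c = 0; c < C; ++c) {
        const double g = gyt[c], d = dt[c], uu = ut[c];
        gD[c] += g * uu;
        double guc = pD[c] * g;
        double gdc = 0.0;
        double *ghc = gh.data() + c;
        double *gAc = gA.data() + c;
        const double *Ac = A.data() + c;
        for (int n = 0; n < N; ++n) {
          const size_t off = (size_t)C * n;
          const double hn = ht[c + off];
          gCt[n] += g * hn;
          double ghn = ghc[off] + g * Ct[n];
          const double hprev = htm1 ? htm1[c + off] : 0.0;
          const double a = std::exp(d * Ac[off]);
          gdc += ghn * (Ac[off] * a * hprev + Bt[n] * uu);
          gBt[n] += ghn * d * uu;
          guc += ghn * d * Bt[n];
          gAc[off] += ghn * d * a * hprev;
          ghc[off] = ghn * a;
        }
        gut[c] += guc;
        gdt[c] += gdc;
      }
    }
  }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      gAlog(c, n) = gA[c + (size_t)C * n] * A[c + (size_t)C * n];
  gu.attr("dim") = IntegerVector::create(C, L, M);
  gdelta.attr("dim") = IntegerVector::create(C, L, M);
  gB.attr("dim") = IntegerVector::create(N, L, M);
  gC.attr("dim") = IntegerVector::create(N, L, M);
  return List::create(_["gu"] = gu, _["gdelta"] = gdelta, _["gB"] = gB,
                      _["gC"] = gC, _["gAlog"] = gAlog, _["gD"] = gD);
}

// ---- 3D windowed multi-head attention --------------------------------------
// qkv: (nwin*T, 3C) with C = H*hd; rpb: (nrel, H) relative-position bias
// table indexed by rpb_idx (T*T, values 1..nrel); masks: (T*T, nmask)
// additive masks; maskid: (nwin) 1-based mask column per window.

// [[Rcpp::export]]
NumericMatrix cpp_winattn_fwd(NumericMatrix qkv, NumericMatrix rpb,
                              IntegerVector rpb_idx, NumericMatrix masks,
                              IntegerVector maskid, int T, int H, int hd) {
  const int nwin = qkv.nrow() / T;
  const int C = H * hd;
  const double scale = 1.0 / std::sqrt((double)hd);
  arma::mat Q(qkv.begin(), qkv.nrow(), 3 * C, false);
  NumericMatrix out(qkv.nrow(), C);
  arma::mat O(out.begin(), out.nrow(), C, false, true);
  arma::mat S(T, T), Bh(T, T);
  for (int h = 0; h < H; ++h) {
    // bias matrix for this head
    const double *tab = &rpb(0, h);
    for (int j = 0; j < T; ++j)
      for (int i = 0; i < T; ++i)
        Bh(i, j) = tab[rpb_idx[i + (R_xlen_t)T * j] - 1];
    for (int w = 0; w < nwin; ++w) {
      arma::mat q = Q.submat(w * T, h * hd, (w + 1) * T - 1, (h + 1) * hd - 1);
      arma::mat k =
          Q.submat(w * T, C + h * hd, (w + 1) * T - 1, C + (h + 1) * hd - 1);
      arma::mat v = Q.submat(w * T, 2 * C + h * hd, (w + 1) * T - 1,
                             2 * C + (h + 1) * hd - 1);
      S = q * k.t() * scale + Bh;
      const int mid = maskid[w] - 1;
      if (mid >= 0) {
        const double *mk = &masks(0, mid);
        for (int j = 0; j < T; ++j)
          for (int i = 0; i < T; ++i) S(i, j) += mk[i + (R_xlen_t)T * j];
      }
      // row softmax
      for (int i = 0; i < T; ++i) {
        double mx = S.row(i).max();
        double sum = 0.0;
        for (int j = 0; j < T; ++j) {
          double e = std::exp(S(i, j) - mx);
          S(i, j) = e;
          sum += e;
        }
        S.row(i) /= sum;
      }
      O.submat(w * T, h * hd, (w + 1) * T - 1, (h + 1) * hd - 1) = S * v;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_winattn_bwd(NumericMatrix qkv, NumericMatrix rpb,
                     IntegerVector rpb_idx, NumericMatrix masks,
                     IntegerVector maskid, NumericMatrix gO_, int T, int H,
                     int hd) {
  const int nwin = qkv.nrow() / T;
  const int C = H * hd;
  const double scale = 1.0 / std::sqrt((double)hd);
  arma::mat Q(qkv.begin(), qkv.nrow(), 3 * C, false);
  arma::mat gO(gO_.begin(), gO_.nrow(), C, false);
  NumericMatrix gqkv(qkv.nrow(), 3 * C);
  arma::mat G(gqkv.begin(), gqkv.nrow(), 3 * C, false, true);
  NumericMatrix grpb(rpb.nrow(), H);
  arma::mat S(T, T), Bh(T, T), gS(T, T);
  for (int h = 0; h < H; ++h) {
    const double *tab = &rpb(0, h);
    for (int j = 0; j < T; ++j)
      for (int i = 0; i < T; ++i)
        Bh(i, j) = tab[rpb_idx[i + (R_xlen_t)T * j] - 1];
    double *gtab = &grpb(0, h);
    for (int w = 0; w < nwin; ++w) {
      arma::mat q = Q.submat(w * T, h * hd, (w + 1) * T - 1, (h + 1) * hd - 1);
      arma::mat k =
          Q.submat(w * T, C + h * hd, (w + 1) * T - 1, C + (h + 1) * hd - 1);
      arma::mat v = Q.submat(w * T, 2 * C + h * hd, (w + 1) * T - 1,
                             2 * C + (h + 1) * hd - 1);
      S = q * k.t() * scale + Bh;
      const int mid = maskid[w] - 1;
      if (mid >= 0) {
        const double *mk = &masks(0, mid);
        for (int j = 0; j < T; ++j)
          for (int i = 0; i < T; ++i) S(i, j) += mk[i + (R_xlen_t)T * j];
      }
      for (int i = 0; i < T; ++i) {
        double mx = S.row(i).max();
        double sum = 0.0;
        for (int j = 0; j < T; ++j) {
          double e = std::exp(S(i, j) - mx);
          S(i, j) = e;
          sum += e;
        }
        S.row(i) /= sum;
      }
      arma::mat go = gO.submat(w * T, h * hd, (w + 1) * T - 1, (h + 1) * hd - 1);
      arma::mat gA = go * v.t();
      arma::vec rs = arma::sum(S % gA, 1);
      gS = S % (gA.each_col() - rs);
      // accumulate relative-position-bias gradient
      for (int j = 0; j < T; ++j)
        for (int i = 0; i < T; ++i)
          gtab[rpb_idx[i + (R_xlen_t)T * j] - 1] += gS(i, j);
      G.submat(w * T, 2 * C + h * hd, (w + 1) * T - 1, 2 * C + (h + 1) * hd - 1) =
          S.t() * go;
      G.submat(w * T, h * hd, (w + 1) * T - 1, (h + 1) * hd - 1) =
          gS * k * scale;
      G.submat(w * T, C + h * hd, (w + 1) * T - 1, C + (h + 1) * hd - 1) =
          gS.t() * q * scale;
    }
  }
  return List::create(_["gqkv"] = gqkv, _["grpb"] = grpb);
}
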