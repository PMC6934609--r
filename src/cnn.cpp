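// Minimal CNN engine: 3x3 same-padding convolutions via im2col + GEMM,
// ReLU, 2x2/stride-2 max pooling, fully connected layers with inverted
// dropout, softmax cross-entropy. Forward + backward for one mini-batch,
// with support for freezing the first `n_frozen_conv` convolutional layers
// (their gradients are neither computed nor propagated below them).
//
// Layout conventions:
//   - A convolutional activation is a matrix (C, B*S*S); column b*S*S + p
//     holds the C-channel vector at spatial position p = r + c*S of image b.
//   - Conv weights are (C_out, 9*C_in): kernel position k (row-major over
//     the 3x3 window, offsets dr,dc in {-1,0,1}) occupies rows [k*C_in, ...).
//   - Input images arrive as a cube (S, S, B*C_in); image b channel ch is
//     slice b*C_in + ch, intensities already scaled to [0, 1].
// All randomness (dropout) uses the R RNG, so set.seed() governs it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;

static const int KDR[9] = {-1, -1, -1, 0, 0, 0, 1, 1, 1};
static const int KDC[9] = {-1, 0, 1, -1, 0, 1, -1, 0, 1};

static mat im2col3x3(const mat &A, const int C, const int S, const int B) {
  mat col((uword)9 * C, (uword)B * S * S, fill::zeros);
  for (int k = 0; k < 9; ++k) {
    const int dr = KDR[k], dc = KDC[k];
    const int r0 = std::max(0, -dr), r1 = std::min(S - 1, S - 1 - dr);
    for (int b = 0; b < B; ++b) {
      const uword base = (uword)b * S * S;
      for (int c = 0; c < S; ++c) {
        const int cs = c + dc;
        if (cs < 0 || cs >= S) continue;
        for (int r = r0; r <= r1; ++r) {
          std::memcpy(col.colptr(base + (uword)c * S + r) + (uword)k * C,
                      A.colptr(base + (uword)cs * S + (r + dr)),
                      C * sizeof(double));
        }
      }
    }
  }
  return col;
}

static void col2im3x3(const mat &dcol, const int C, const int S, const int B,
                      mat &dA) {
  for (int k = 0; k < 9; ++k) {
    const int dr = KDR[k], dc = KDC[k];
    const int r0 = std::max(0, -dr), r1 = std::min(S - 1, S - 1 - dr);
    for (int b = 0; b < B; ++b) {
      const uword base = (uword)b * S * S;
      for (int c = 0; c < S; ++c) {
        const int cs = c + dc;
        if (cs < 0 || cs >= S) continue;
        for (int r = r0; r <= r1; ++r) {
          const double *src = dcol.colptr(base + (uword)c * S + r) + (uword)k * C;
          double *dst = dA.colptr(base + (uword)cs * S + (r + dr));
          for (int i = 0; i < C; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

static mat maxpool2(const mat &Z, const int C, const int S, const int B,
                    Mat<unsigned char> &amax) {
  const int Sh = S / 2;
  mat out(C, (uword)B * Sh * Sh);
  amax.set_size(C, (uword)B * Sh * Sh);
  for (int b = 0; b < B; ++b) {
    const uword ibase = (uword)b * S * S, obase = (uword)b * Sh * Sh;
    for (int c2 = 0; c2 < Sh; ++c2) {
      for (int r2 = 0; r2 < Sh; ++r2) {
        const uword p0 = ibase + (uword)(2 * c2) * S + 2 * r2;
        const double *z[4] = {Z.colptr(p0), Z.colptr(p0 + 1),
                              Z.colptr(p0 + S), Z.colptr(p0 + S + 1)};
        const uword po = obase + (uword)c2 * Sh + r2;
        double *o = out.colptr(po);
        unsigned char *am = amax.colptr(po);
        for (int ch = 0; ch < C; ++ch) {
          int best = 0;
          double v = z[0][ch];
          for (int q = 1; q < 4; ++q)
            if (z[q][ch] > v) { v = z[q][ch]; best = q; }
          o[ch] = v;
          am[ch] = (unsigned char)best;
        }
      }
    }
  }
  return out;
}

static mat unpool2(const mat &dP, const Mat<unsigned char> &amax, const int C,
                   const int S, const int B) {
  const int Sh = S / 2;
  mat dZ(C, (uword)B * S * S, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword ibase = (uword)b * S * S, obase = (uword)b * Sh * Sh;
    for (int c2 = 0; c2 < Sh; ++c2) {
      for (int r2 = 0; r2 < Sh; ++r2) {
        const uword po = obase + (uword)c2 * Sh + r2;
        const uword p0 = ibase + (uword)(2 * c2) * S + 2 * r2;
        const double *dp = dP.colptr(po);
        const unsigned char *am = amax.colptr(po);
        for (int ch = 0; ch < C; ++ch) {
          const uword p = p0 + (am[ch] == 1 ? 1 : 0) +
                          (am[ch] >= 2 ? (uword)S : 0) + (am[ch] == 3 ? 1 : 0);
          dZ.colptr(p)[ch] += dp[ch];
        }
      }
    }
  }
  return dZ;
}

static void relu_inplace(mat &Z) {
  double *p = Z.memptr();
  const uword n = Z.n_elem;
  for (uword i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = 0;
}

// dZ entries are zeroed wherever the stored post-ReLU activation is 0.
static void relu_backward(mat &dZ, const mat &act) {
  double *p = dZ.memptr();
  const double *a = act.memptr();
  const uword n = dZ.n_elem;
  for (uword i = 0; i < n; ++i)
    if (a[i] <= 0) p[i] = 0;
}

// [[Rcpp::export]]
List cnn_batch_cpp(const List &weights, const arma::cube &X,
                   const arma::ivec &y, const List &arch,
                   const bool training, const bool want_grads,
                   const bool want_features, const int n_frozen_conv) {
  const ivec conv_filters = Rcpp::as<ivec>(arch["conv_filters"]);
  const Rcpp::LogicalVector pool_after = arch["pool_after"];
  const ivec fc_units = Rcpp::as<ivec>(arch["fc_units"]);
  const int K = Rcpp::as<int>(arch["n_classes"]);
  const int C0 = Rcpp::as<int>(arch["in_channels"]);
  const int S0 = Rcpp::as<int>(arch["input_size"]);
  const double dropout_p = Rcpp::as<double>(arch["dropout_p"]);
  const int L = conv_filters.n_elem;
  const int nfc = fc_units.n_elem;
  const int B = X.n_slices / C0;

  const List convW = weights["conv"], fcW = weights["fc"];

  // ---- pack input ----
  mat A(C0, (uword)B * S0 * S0);
  for (int b = 0; b < B; ++b) {
    const uword base = (uword)b * S0 * S0;
    for (int ch = 0; ch < C0; ++ch) {
      const double *src = X.slice((uword)b * C0 + ch).memptr();
      for (uword p = 0; p < (uword)S0 * S0; ++p) A(ch, base + p) = src[p];
    }
  }

  // ---- conv stack forward ----
  std::vector<mat> cols(L), acts(L);
  std::vector<Mat<unsigned char>> amaxs(L);
  std::vector<int> Sin(L);
  int S = S0, Cin = C0;
  for (int l = 0; l < L; ++l) {
    Sin[l] = S;
    const List wl = convW[l];
    const mat W = Rcpp::as<mat>(wl["W"]);
    const vec bv = Rcpp::as<vec>(wl["b"]);
    mat col = im2col3x3(A, Cin, S, B);
    mat Z = W * col;
    Z.each_col() += bv;
    relu_inplace(Z);
    if (want_grads && l >= n_frozen_conv) cols[l] = std::move(col);
    if (pool_after[l]) {
      A = maxpool2(Z, conv_filters[l], S, B, amaxs[l]);
      S /= 2;
    } else {
      A = Z;
    }
    if (want_grads) acts[l] = std::move(Z);
    Cin = conv_filters[l];
  }

  // ---- flatten: per-image block of A is already contiguous ----
  const int feat0 = Cin * S * S;
  mat H(const_cast<double *>(A.memptr()), feat0, B);  // copies

  // ---- fully connected forward ----
  std::vector<mat> fcin(nfc + 1), masks(nfc);
  const double keep = 1.0 - dropout_p;
  for (int j = 0; j < nfc; ++j) {
    fcin[j] = H;
    const List wj = fcW[j];
    H = Rcpp::as<mat>(wj["W"]) * H;
    H.each_col() += Rcpp::as<vec>(wj["b"]);
    relu_inplace(H);
    if (training && dropout_p > 0) {
      mat M(H.n_rows, H.n_cols);
      double *mp = M.memptr();
      for (uword i = 0; i < M.n_elem; ++i)
        mp[i] = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
      masks[j] = M;
      H %= M;
    }
  }
  fcin[nfc] = H;  // penultimate activations feed the output layer
  const List wout = fcW[nfc];
  mat O = Rcpp::as<mat>(wout["W"]) * H;
  O.each_col() += Rcpp::as<vec>(wout["b"]);

  // ---- softmax + cross-entropy ----
  mat P = O;
  double loss = 0.0;
  int n_correct = 0;
  for (int b = 0; b < B; ++b) {
    vec pb = P.col(b);
    pb -= pb.max();
    pb = exp(pb);
    pb /= accu(pb);
    P.col(b) = pb;
    loss -= std::log(std::max(pb[y[b]], 1e-300));
    if ((int)pb.index_max() == y[b]) ++n_correct;
  }
  loss /= B;

  List out = List::create(Rcpp::Named("loss") = loss,
                          Rcpp::Named("n_correct") = n_correct,
                          Rcpp::Named("prob") = Rcpp::wrap(mat(P.t())));
  if (want_features) out["features"] = Rcpp::wrap(mat(fcin[nfc].t()));
  if (!want_grads) return out;

  // ---- backward ----
  mat dH = P;
  for (int b = 0; b < B; ++b) dH(y[b], b) -= 1.0;
  dH /= B;

  List fc_grads(nfc + 1);
  for (int j = nfc; j >= 0; --j) {
    const List wj = fcW[j];
    const mat W = Rcpp::as<mat>(wj["W"]);
    mat gW = dH * fcin[j].t();
    vec gb = sum(dH, 1);
    fc_grads[j] = List::create(Rcpp::Named("W") = Rcpp::wrap(gW),
                               Rcpp::Named("b") = Rcpp::wrap(gb));
    if (j > 0) {
      dH = W.t() * dH;
      if (training && dropout_p > 0) dH %= masks[j - 1];
      relu_backward(dH, fcin[j]);
    } else {
      dH = W.t() * dH;  // gradient w.r.t. flattened conv output
    }
  }

  List conv_grads(L);
  mat dA(dH.memptr(), Cin, (uword)B * S * S);  // copies; same layout
  for (int l = L - 1; l >= 0; --l) {
    mat dZ = pool_after[l] ? unpool2(dA, amaxs[l], conv_filters[l], Sin[l], B)
                           : std::move(dA);
    relu_backward(dZ, acts[l]);
    if (l >= n_frozen_conv) {
      mat gW = dZ * cols[l].t();
      vec gb = sum(dZ, 1);
      conv_grads[l] = List::create(Rcpp::Named("W") = Rcpp::wrap(gW),
                                   Rcpp::Named("b") = Rcpp::wrap(gb));
    }
    if (l > n_frozen_conv && l > 0) {
      const List wl = convW[l];
      const mat W = Rcpp::as<mat>(wl["W"]);
      const int Cprev = (l == 0) ? C0 : (int)conv_filters[l - 1];
      mat dcol = W.t() * dZ;
      dA.zeros(Cprev, (uword)B * Sin[l] * Sin[l]);
      col2im3x3(dcol, Cprev, Sin[l], B, dA);
    } else {
      break;
    }
  }

  out["grads"] = List::create(Rcpp::Named("conv") = conv_grads,
                              Rcpp::Named("fc") = fc_grads);
  return out;
}
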