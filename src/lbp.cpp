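#include <Rcpp.h>
using namespace Rcpp;

// Neighbor offsets in the documented order: clockwise from the top-left
// neighbor. Bit n carries weight 2^n.
static const int DR[8] = {-1, -1, -1, 0, 1, 1, 1, 0};
static const int DC[8] = {-1, 0, 1, 1, 1, 0, -1, -1};

// [[Rcpp::export]]
IntegerMatrix lbp_map_cpp(const IntegerMatrix &img) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix out(H - 2, W - 2);
  for (int r = 1; r < H - 1; ++r) {
    for (int c = 1; c < W - 1; ++c) {
      const int center = img(r, c);
      int code = 0;
      for (int n = 0; n < 8; ++n) {
        if (img(r + DR[n], c + DC[n]) >= center) code |= (1 << n);
      }
      out(r - 1, c - 1) = code;
    }
  }
  return out;
}

// Concatenated 256-bin histograms of non-overlapping N x N patches tiled
// over the largest fitting grid of the code map, row-major patch order.
// [[Rcpp::export]]
IntegerVector lbp_patch_hist_cpp(const IntegerMatrix &codes, const int N) {
  const int H = codes.nrow(), W = codes.ncol();
  const int npr = H / N, npc = W / N;
  IntegerVector out(npr * npc * 256);  // zero-initialized
  for (int pr = 0; pr < npr; ++pr) {
    for (int pc = 0; pc < npc; ++pc) {
      const int off = (pr * npc + pc) * 256;
      for (int r = pr * N; r < (pr + 1) * N; ++r)
        for (int c = pc * N; c < (pc + 1) * N; ++c)
          out[off + codes(r, c)] += 1;
    }
  }
  out.attr("dim") = R_NilValue;
  return out;
}
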