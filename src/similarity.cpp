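#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Ring-kernel aggregation of pairwise TIC similarity over an ROI crop.
//
// For every pixel of the H x W crop, averages the pairwise similarity
// (Pearson correlation, band-averaged Welch magnitude-squared coherence,
// binned mutual information) between the pixel TIC and the TICs at all
// ring-kernel offsets that fall inside the crop. Pixels with fewer than
// half of the kernel offsets inside the crop, or with a degenerate
// (zero-variance) TIC, are returned as NA.
//
// z       : n x P standardized TICs (columns = pixels, column-major crop)
// fft_re/fft_im : (nseg*nfreq) x P detrended+tapered segment spectra
// sxx     : nfreq x P  per-pixel segment-summed spectral power
// bins    : n x P equal-frequency bin labels in 1..B
// valid   : length-P flag (TIC has variance)
// offsets : K x 2 (dr, dc) ring offsets
// [[Rcpp::export]]
NumericMatrix ring_similarity_core(NumericMatrix z,
                                   NumericMatrix fft_re,
                                   NumericMatrix fft_im,
                                   NumericMatrix sxx,
                                   IntegerMatrix bins, int B,
                                   LogicalVector valid,
                                   IntegerMatrix offsets,
                                   int H, int W) {
  const int n = z.nrow();
  const int P = z.ncol();
  const int K = offsets.nrow();
  const int nfreq = sxx.nrow();
  const int nspec = fft_re.nrow();
  const int nseg = nfreq > 0 ? nspec / nfreq : 0;
  NumericMatrix out(P, 3);
  std::fill(out.begin(), out.end(), NA_REAL);

  const double* zp0 = REAL(z);
  const double* re0 = REAL(fft_re);
  const double* im0 = REAL(fft_im);
  const double* sx0 = REAL(sxx);
  const int* bn0 = INTEGER(bins);
  const int* offr = INTEGER(offsets);           // column 0
  const int* offc = INTEGER(offsets) + K;       // column 1

  // log table for the plug-in MI (all counts are in 1..n)
  std::vector<double> logt(n + 1, 0.0);
  for (int i = 1; i <= n; ++i) logt[i] = std::log((double)i);
  const double logn = logt[n];

  // per-pixel marginal bin counts
  std::vector<int> marg(B * P, 0);
  for (int p = 0; p < P; ++p) {
    const int* bp = bn0 + (size_t)p * n;
    int* mp = marg.data() + (size_t)p * B;
    for (int t = 0; t < n; ++t) ++mp[bp[t] - 1];
  }

  std::vector<int> joint(B * B);

  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const int p = c * H + r;
      if (!valid[p]) continue;
      const double* zp = zp0 + (size_t)p * n;
      const double* rep = re0 + (size_t)p * nspec;
      const double* imp = im0 + (size_t)p * nspec;
      const double* sxp = sx0 + (size_t)p * nfreq;
      const int* bp = bn0 + (size_t)p * n;
      const int* mp = marg.data() + (size_t)p * B;

      int n_in = 0, n_used = 0;
      double acc_cor = 0.0, acc_coh = 0.0, acc_mi = 0.0;
      for (int k = 0; k < K; ++k) {
        const int rr = r + offr[k];
        const int cc = c + offc[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        ++n_in;
        const int q = cc * H + rr;
        if (!valid[q]) continue;
        const double* zq = zp0 + (size_t)q * n;
        const double* req = re0 + (size_t)q * nspec;
        const double* imq = im0 + (size_t)q * nspec;
        const double* sxq = sx0 + (size_t)q * nfreq;
        const int* bq = bn0 + (size_t)q * n;
        const int* mq = marg.data() + (size_t)q * B;

        // Pearson correlation of standardized TICs
        double s = 0.0;
        for (int t = 0; t < n; ++t) s += zp[t] * zq[t];
        const double cor = s / (n - 1);

        // band-averaged magnitude-squared coherence
        double coh = 0.0;
        int nb = 0;
        for (int f = 0; f < nfreq; ++f) {
          const double sa = sxp[f], sb = sxq[f];
          if (sa <= 0.0 || sb <= 0.0) continue;
          double sre = 0.0, sim = 0.0;
          for (int sg = 0; sg < nseg; ++sg) {
            const int row = sg * nfreq + f;
            const double xr = rep[row], xi = imp[row];
            const double yr = req[row], yi = imq[row];
            sre += xr * yr + xi * yi;
            sim += xi * yr - xr * yi;
          }
          coh += (sre * sre + sim * sim) / (sa * sb);
          ++nb;
        }
        if (nb == 0) continue;
        coh /= nb;

        // plug-in mutual information on equal-frequency bins (nats)
        std::memset(joint.data(), 0, sizeof(int) * B * B);
        for (int t = 0; t < n; ++t) {
          ++joint[(bp[t] - 1) * B + (bq[t] - 1)];
        }
        double mi = 0.0;
        for (int a = 0; a < B; ++a) {
          if (mp[a] == 0) continue;
          const double la = logt[mp[a]];
          const int* ja = joint.data() + a * B;
          for (int b = 0; b < B; ++b) {
            const int cj = ja[b];
            if (cj == 0) continue;
            mi += cj * (logt[cj] + logn - la - logt[mq[b]]);
          }
        }
        mi /= n;

        acc_cor += cor;
        acc_coh += coh;
        acc_mi += mi;
        ++n_used;
      }
      if (2 * n_in < K || n_used == 0) continue;
      out(p, 0) = acc_coh / n_used;
      out(p, 1) = acc_cor / n_used;
      out(p, 2) = acc_mi / n_used;
    }
  }
  return out;
}
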