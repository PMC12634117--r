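// Fast DSP primitives for the pre-processing chain: zero-phase IIR
// filtering (forward-backward with odd-reflection padding) and zero-phase
// polyphase rational resampling with a Kaiser-windowed sinc anti-alias FIR.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

vec iir_filter(const vec& b, const vec& a, const vec& x) {
  const int nb = b.n_elem, na = a.n_elem, n = x.n_elem;
  vec y(n, fill::zeros);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < nb; ++j)
      if (i - j >= 0) acc += b(j) * x(i - j);
    for (int j = 1; j < na; ++j)
      if (i - j >= 0) acc -= a(j) * y(i - j);
    y(i) = acc / a(0);
  }
  return y;
}

double bessel_i0(double x) {
  // power series; converges quickly for the beta values used here
  double sum = 1.0, term = 1.0;
  for (int k = 1; k < 60; ++k) {
    term *= (x / (2.0 * k)) * (x / (2.0 * k));
    sum += term;
    if (term < 1e-16 * sum) break;
  }
  return sum;
}

}  // namespace

// Zero-phase IIR filtering: odd-reflection padding at both ends (3 filter
// lengths), filter forward, reverse, filter, reverse, unpad.
// [[Rcpp::export]]
arma::vec cpp_filtfilt(arma::vec b, arma::vec a, arma::vec x) {
  const int n = x.n_elem;
  const int ord = std::max(b.n_elem, a.n_elem) - 1;
  const int pad = std::min(3 * std::max(ord, 1) * 4, n - 1);
  vec xe(n + 2 * pad);
  for (int i = 0; i < pad; ++i) xe(i) = 2 * x(0) - x(pad - i);
  xe.subvec(pad, pad + n - 1) = x;
  for (int i = 0; i < pad; ++i) xe(pad + n + i) = 2 * x(n - 1) - x(n - 2 - i);
  vec y = iir_filter(b, a, xe);
  y = reverse(y);
  y = iir_filter(b, a, y);
  y = reverse(y);
  return y.subvec(pad, pad + n - 1);
}

// Kaiser-windowed sinc lowpass for resampling by p/q; odd length, symmetric.
// [[Rcpp::export]]
arma::vec cpp_resample_fir(int p, int q, int half_order = 10, double beta = 5.0) {
  const int m = std::max(p, q);
  const int L = 2 * half_order * m + 1;
  const int c = (L - 1) / 2;
  vec h(L);
  const double i0b = bessel_i0(beta);
  for (int j = 0; j < L; ++j) {
    const double t = j - c;
    const double sinc = (t == 0) ? 1.0 / m
                                 : std::sin(datum::pi * t / m) / (datum::pi * t);
    const double r = 2.0 * t / (L - 1);
    const double w = bessel_i0(beta * std::sqrt(std::max(0.0, 1.0 - r * r))) / i0b;
    h(j) = sinc * w;
  }
  return h;
}

// Polyphase rational resampling by p/q, zero phase: output n estimates the
// input at position n*q/p (0-based input-sample units).
// [[Rcpp::export]]
arma::vec cpp_resample(arma::vec x, int p, int q, arma::vec h) {
  const int n = x.n_elem;
  const int L = h.n_elem;
  const int c = (L - 1) / 2;
  const long n_out = (static_cast<long>(n) * p) / q;
  vec y(n_out, fill::zeros);
  for (long m = 0; m < n_out; ++m) {
    const long pos = m * q + c;  // centre tap position on the upsampled grid
    double acc = 0.0;
    // xu[i] nonzero only when i % p == 0 (xu[i] = x[i/p])
    long jstart = pos % p == 0 ? 0 : 0;
    for (long j = pos % p; j < L; j += p) {
      const long iu = pos - j;
      if (iu < 0) break;
      const long ii = iu / p;
      if (ii < n && iu % p == 0) acc += h(j) * x(ii);
    }
    (void)jstart;
    y(m) = p * acc;
  }
  return y;
}
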