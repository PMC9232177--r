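// Triangular first-step-analysis recurrences for the stochastic SIR chain.
//
// State (i, n): i infectives among n = i + s survivors of an initial
// population of size N.  Events: recovery at rate a = i*delta (i -> i-1,
// n -> n-1) and infection at rate b = i*(n-i)*eta/N (i -> i+1).  The mean
// time to extinction T[i,n] and mean total ever infected M[i,n] satisfy
//   T[i,n] = (1 + a*T[i-1,n-1] + b*T[i+1,n]) / (a+b)
//   M[i,n] = (a*(M[i-1,n-1]+1) + b*M[i+1,n]) / (a+b)
// with boundaries T[0,n] = M[0,n] = 0, M[i,i] = i and
// T[i,i] = sum_{j<=i} 1/(j*delta).  The sweep runs n = 1..N with i
// descending n..1, so within a column M[i+1,n] precedes M[i,n] and only
// the previous column is ever read: two columns suffice (streaming mode).
//
// The same sweep is instantiated over std::complex<double> for the
// complex-perturbation sensitivities, and a manual-tandem variant
// propagates the analytically differentiated recurrence alongside.

#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

template <typename S>
static void sir_sweep(int N, S delta, S eta,
                      std::vector<S>& Tcur, std::vector<S>& Mcur,
                      std::vector<S>* Tfull, std::vector<S>* Mfull) {
  std::vector<S> Tprev(N + 1, S(0)), Mprev(N + 1, S(0));
  std::fill(Tcur.begin(), Tcur.end(), S(0));
  std::fill(Mcur.begin(), Mcur.end(), S(0));
  const int stride = N + 1;
  for (int n = 1; n <= N; ++n) {
    Tcur[n] = Tprev[n - 1] + S(1) / (S(n) * delta);
    Mcur[n] = S(n);
    for (int i = n - 1; i >= 1; --i) {
      S a = S(i) * delta;
      S b = S(i) * S(n - i) * eta / S(N);
      S c = S(1) / (a + b);
      Tcur[i] = c * (S(1) + a * Tprev[i - 1] + b * Tcur[i + 1]);
      Mcur[i] = c * (a * (Mprev[i - 1] + S(1)) + b * Mcur[i + 1]);
    }
    Tcur[0] = S(0);
    Mcur[0] = S(0);
    if (Tfull) {
      for (int i = 0; i <= n; ++i) {
        (*Tfull)[i + (size_t)n * stride] = Tcur[i];
        (*Mfull)[i + (size_t)n * stride] = Mcur[i];
      }
    }
    Tprev.swap(Tcur);
    Mprev.swap(Mcur);
  }
  // after the final swap the N-column lives in Tprev/Mprev
  Tcur.swap(Tprev);
  Mcur.swap(Mprev);
}

// [[Rcpp::export(name = ".sir_grids_real")]]
List sir_grids_real(int N, double delta, double eta, bool full) {
  std::vector<double> Tcol(N + 1), Mcol(N + 1);
  std::vector<double> Tfull, Mfull;
  if (full) {
    Tfull.assign((size_t)(N + 1) * (N + 1), 0.0);
    Mfull.assign((size_t)(N + 1) * (N + 1), 0.0);
  }
  sir_sweep<double>(N, delta, eta, Tcol, Mcol,
                    full ? &Tfull : nullptr, full ? &Mfull : nullptr);
  List out = List::create(_["Tcol"] = NumericVector(Tcol.begin(), Tcol.end()),
                          _["Mcol"] = NumericVector(Mcol.begin(), Mcol.end()));
  if (full) {
    NumericMatrix Tm(N + 1, N + 1), Mm(N + 1, N + 1);
    std::copy(Tfull.begin(), Tfull.end(), Tm.begin());
    std::copy(Mfull.begin(), Mfull.end(), Mm.begin());
    out["T"] = Tm;
    out["M"] = Mm;
  }
  return out;
}

static ComplexVector to_cplx_vec(const std::vector<std::complex<double> >& v) {
  ComplexVector out(v.size());
  for (size_t k = 0; k < v.size(); ++k) {
    out[k].r = v[k].real();
    out[k].i = v[k].imag();
  }
  return out;
}

// [[Rcpp::export(name = ".sir_grids_complex")]]
List sir_grids_complex(int N, Rcomplex delta, Rcomplex eta, bool full) {
  typedef std::complex<double> C;
  C d(delta.r, delta.i), e(eta.r, eta.i);
  std::vector<C> Tcol(N + 1), Mcol(N + 1), Tfull, Mfull;
  if (full) {
    Tfull.assign((size_t)(N + 1) * (N + 1), C(0));
    Mfull.assign((size_t)(N + 1) * (N + 1), C(0));
  }
  sir_sweep<C>(N, d, e, Tcol, Mcol,
               full ? &Tfull : nullptr, full ? &Mfull : nullptr);
  List out = List::create(_["Tcol"] = to_cplx_vec(Tcol),
                          _["Mcol"] = to_cplx_vec(Mcol));
  if (full) {
    ComplexVector Tm = to_cplx_vec(Tfull), Mm = to_cplx_vec(Mfull);
    Tm.attr("dim") = Dimension(N + 1, N + 1);
    Mm.attr("dim") = Dimension(N + 1, N + 1);
    out["T"] = Tm;
    out["M"] = Mm;
  }
  return out;
}

// Manual tandem differentiation: quotient rule applied to a = i*delta,
// b = i*(n-i)*eta/N, c = 1/(a+b) with d a/d delta = i, d b/d eta =
// i*(n-i)/N, d c/d theta = -c^2 * d(a+b)/d theta, and the differentiated
// boundary rows dT[i,i]/d delta = -sum_{j<=i} 1/(j*delta^2), dM[i,i] = 0.
// [[Rcpp::export(name = ".sir_grids_manual")]]
List sir_grids_manual(int N, double delta, double eta, bool full) {
  const int stride = N + 1;
  const size_t cells = (size_t)stride * stride;
  std::vector<double> Tp(stride, 0), Mp(stride, 0),
      dTdp(stride, 0), dTep(stride, 0), dMdp(stride, 0), dMep(stride, 0);
  std::vector<double> Tc(stride, 0), Mc(stride, 0),
      dTdc(stride, 0), dTec(stride, 0), dMdc(stride, 0), dMec(stride, 0);
  std::vector<std::vector<double>*> fulls;
  std::vector<std::vector<double> > store;
  if (full) store.assign(6, std::vector<double>(cells, 0.0));

  for (int n = 1; n <= N; ++n) {
    Tc[n] = Tp[n - 1] + 1.0 / (n * delta);
    dTdc[n] = dTdp[n - 1] - 1.0 / (n * delta * delta);
    dTec[n] = dTep[n - 1];
    Mc[n] = n;
    dMdc[n] = 0.0;
    dMec[n] = 0.0;
    for (int i = n - 1; i >= 1; --i) {
      double a = i * delta;
      double b = (double)i * (n - i) * eta / N;
      double c = 1.0 / (a + b);
      double da = i;                       // d a / d delta
      double db = (double)i * (n - i) / N; // d b / d eta
      double dcd = -c * c * da;
      double dce = -c * c * db;
      double T1 = Tp[i - 1], T2 = Tc[i + 1];
      double M1 = Mp[i - 1], M2 = Mc[i + 1];
      double Tcore = 1.0 + a * T1 + b * T2;
      double Mcore = a * (M1 + 1.0) + b * M2;
      Tc[i] = c * Tcore;
      Mc[i] = c * Mcore;
      dTdc[i] = dcd * Tcore + c * (da * T1 + a * dTdp[i - 1] + b * dTdc[i + 1]);
      dTec[i] = dce * Tcore + c * (db * T2 + a * dTep[i - 1] + b * dTec[i + 1]);
      dMdc[i] = dcd * Mcore + c * (da * (M1 + 1.0) + a * dMdp[i - 1] + b * dMdc[i + 1]);
      dMec[i] = dce * Mcore + c * (db * M2 + a * dMep[i - 1] + b * dMec[i + 1]);
    }
    Tc[0] = Mc[0] = dTdc[0] = dTec[0] = dMdc[0] = dMec[0] = 0.0;
    if (full) {
      std::vector<double>* cols[6] = {&Tc, &Mc, &dTdc, &dTec, &dMdc, &dMec};
      for (int q = 0; q < 6; ++q)
        for (int i = 0; i <= n; ++i)
          store[q][i + (size_t)n * stride] = (*cols[q])[i];
    }
    Tp.swap(Tc); Mp.swap(Mc);
    dTdp.swap(dTdc); dTep.swap(dTec);
    dMdp.swap(dMdc); dMep.swap(dMec);
  }
  List out = List::create(
      _["Tcol"] = NumericVector(Tp.begin(), Tp.end()),
      _["Mcol"] = NumericVector(Mp.begin(), Mp.end()),
      _["dTddelta_col"] = NumericVector(dTdp.begin(), dTdp.end()),
      _["dTdeta_col"] = NumericVector(dTep.begin(), dTep.end()),
      _["dMddelta_col"] = NumericVector(dMdp.begin(), dMdp.end()),
      _["dMdeta_col"] = NumericVector(dMep.begin(), dMep.end()));
  if (full) {
    const char* nm[6] = {"T", "M", "dTddelta", "dTdeta", "dMddelta", "dMdeta"};
    for (int q = 0; q < 6; ++q) {
      NumericMatrix m(stride, stride);
      std::copy(store[q].begin(), store[q].end(), m.begin());
      out[nm[q]] = m;
    }
  }
  return out;
}

// Exact (direct-method) Gillespie simulation of the SIR chain.  Uses R's
// RNG so runs are reproducible under set.seed().  Returns one row per run:
// extinction time and total ever infected.
// [[Rcpp::export(name = ".sir_ssa_runs")]]
NumericMatrix sir_ssa_runs(int s0, int i0, double delta, double eta,
                           int runs) {
  RNGScope scope;
  const int N = s0 + i0;
  NumericMatrix out(runs, 2);
  for (int r = 0; r < runs; ++r) {
    int i = i0, n = N;
    double t = 0.0;
    double infected = i0;
    while (i > 0) {
      double a = i * delta;
      double b = (double)i * (n - i) * eta / N;
      double total = a + b;
      t += R::exp_rand() / total;
      if (R::unif_rand() * total < a) {
        --i; --n;          // recovery
      } else {
        ++i; infected += 1; // infection
      }
    }
    out(r, 0) = t;
    out(r, 1) = infected;
  }
  return out;
}
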