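// Reservoir state propagation. The dynamics are the explicit-Euler
// discretization (dt = 1 sample) of a leaky tanh reservoir:
//   q_{t+1} = q_t + (1/tau) * (-gamma * q_t + tanh(C q_t + F x_{t+1}))
//             + eps * u_t,  u_t ~ U(-1, 1) i.i.d. per node.
// The sparse connectivity arrives as the column-compressed slots of a
// dgCMatrix; the matvec is hand-rolled to keep the per-step cost at the
// nonzero count. Noise uses R's RNG so runs are reproducible under
// set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix esn_run_states_cpp(const IntegerVector& Cp,
                                 const IntegerVector& Ci,
                                 const NumericVector& Cx,
                                 const NumericMatrix& Fin,
                                 const NumericMatrix& x,
                                 const NumericVector& q0,
                                 double gamma, double tau, double eps) {
  const int N = Fin.nrow();
  const int K = Fin.ncol();
  const int T = x.ncol();
  NumericMatrix Q(N, T);
  double* Qp = REAL(Q);
  std::vector<double> q(q0.begin(), q0.end());
  std::vector<double> drive(N);
  const double inv_tau = 1.0 / tau;
  for (int t = 0; t < T; ++t) {
    // drive = F x_t
    for (int i = 0; i < N; ++i) drive[i] = 0.0;
    for (int k = 0; k < K; ++k) {
      const double xk = x(k, t);
      const double* fcol = &Fin(0, k);
      for (int i = 0; i < N; ++i) drive[i] += fcol[i] * xk;
    }
    // drive += C q (column-compressed)
    for (int j = 0; j < N; ++j) {
      const double qj = q[j];
      if (qj == 0.0) continue;
      for (int k = Cp[j]; k < Cp[j + 1]; ++k) {
        drive[Ci[k]] += Cx[k] * qj;
      }
    }
    bool finite = true;
    if (eps > 0.0) {
      for (int i = 0; i < N; ++i) {
        q[i] += inv_tau * (-gamma * q[i] + std::tanh(drive[i]))
              + eps * R::runif(-1.0, 1.0);
        finite = finite && std::isfinite(q[i]);
      }
    } else {
      for (int i = 0; i < N; ++i) {
        q[i] += inv_tau * (-gamma * q[i] + std::tanh(drive[i]));
        finite = finite && std::isfinite(q[i]);
      }
    }
    if (!finite) stop("non-finite reservoir state at step %d", t + 1);
    std::copy(q.begin(), q.end(), Qp + (std::size_t)t * N);
  }
  return Q;
}
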