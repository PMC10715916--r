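#include <Rcpp.h>
using namespace Rcpp;

// Core numerics for the opinion-dynamics model: the perception filter,
// the multiplicative (Bayesian) social update, one implicit diffusion step
// (backward-time centred-space with zero Dirichlet ghost points), and the
// asynchronous society update loop. All randomness comes from R's RNG so a
// single set.seed() on the R side drives network, initial opinions and
// update order reproducibly.

static inline double vec_sum(const double *x, int m) {
  double s = 0.0;
  for (int b = 0; b < m; ++b) s += x[b];
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_perceive(NumericVector x, double alpha) {
  int m = x.size();
  NumericVector out(m);
  double u = (1.0 - alpha) / m;  // uniform reference mass per point
  for (int b = 0; b < m; ++b) out[b] = alpha * x[b] + u;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_social_update(NumericVector xi, NumericVector xj,
                                double alpha) {
  int m = xi.size();
  NumericVector out(m);
  double u = (1.0 - alpha) / m;
  for (int b = 0; b < m; ++b) out[b] = xi[b] * (alpha * xj[b] + u);
  double s = vec_sum(REAL(out), m);
  if (s < 1e-300)
    stop("posterior mass underflow in social update (total mass %g)", s);
  for (int b = 0; b < m; ++b) out[b] /= s;
  return out;
}

// Solve (I - r*L) x_new = x where L is the second-difference operator with
// zero Dirichlet values at ghost points one spacing outside the grid.
// Constant-coefficient tridiagonal system: diag 1+2r, off-diagonals -r.
// Thomas algorithm with coefficients precomputed by the caller:
//   cp[i]    = c_i'        (modified upper-diagonal terms)
//   denom[i] = b - a*cp[i-1]
static void btcs_solve(const double *x, double *out, int m, double r,
                       const double *cp, const double *inv_denom,
                       double *work) {
  if (r == 0.0) {
    for (int b = 0; b < m; ++b) out[b] = x[b];
    return;
  }
  // forward sweep: work holds d'
  work[0] = x[0] * inv_denom[0];
  for (int b = 1; b < m; ++b)
    work[b] = (x[b] + r * work[b - 1]) * inv_denom[b];
  // back substitution (upper coefficient is -r, so subtract cp * next)
  out[m - 1] = work[m - 1];
  for (int b = m - 2; b >= 0; --b)
    out[b] = work[b] - cp[b] * out[b + 1];
}

static void btcs_coefficients(int m, double r, double *cp, double *inv_denom) {
  double diag = 1.0 + 2.0 * r;
  double d = diag;
  inv_denom[0] = 1.0 / d;
  cp[0] = -r * inv_denom[0];
  for (int b = 1; b < m; ++b) {
    d = diag + r * cp[b - 1];
    inv_denom[b] = 1.0 / d;
    cp[b] = -r * inv_denom[b];
  }
}

// [[Rcpp::export]]
NumericVector cpp_diffuse_step(NumericVector x, double r, bool normalize) {
  int m = x.size();
  NumericVector out(m);
  if (r == 0.0) {
    for (int b = 0; b < m; ++b) out[b] = x[b];
    return out;
  }
  std::vector<double> cp(m), denom(m), work(m);
  btcs_coefficients(m, r, cp.data(), denom.data());
  btcs_solve(REAL(x), REAL(out), m, r, cp.data(), denom.data(), work.data());
  if (normalize) {
    double s = vec_sum(REAL(out), m);
    for (int b = 0; b < m; ++b) out[b] /= s;
  }
  return out;
}

static inline double dot_mean(const double *x, const double *b, int m) {
  double s = 0.0;
  for (int k = 0; k < m; ++k) s += x[k] * b[k];
  return s;
}

static double pop_sd(const double *mu, int n) {
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += mu[i];
  m /= n;
  double v = 0.0;
  for (int i = 0; i < n; ++i) v += (mu[i] - m) * (mu[i] - m);
  return std::sqrt(v / n);
}

// Asynchronous society update. `opinions` is m x n (one column per agent)
// and is copied, not modified. Adjacency in CSR form with 0-based targets.
// Each step draws a fresh uniform permutation of agents; a visited agent
// interacts with probability q with a uniformly chosen neighbour (reading
// its current, possibly already-updated opinion) and otherwise diffuses.
// Records sigma (population SD of agent means) at t = 0..steps and,
// if mean_stride > 0, the per-agent means every mean_stride steps.
// Stops early at first passage sigma < sigma_cons when stop_at_consensus.
// [[Rcpp::export]]
List cpp_run_society(NumericMatrix opinions, NumericVector grid_points,
                     IntegerVector identity, IntegerVector adj_targets,
                     IntegerVector adj_offsets, double alpha_in,
                     double alpha_out, double q, double r, int steps,
                     double sigma_cons, bool stop_at_consensus,
                     int mean_stride) {
  int m = opinions.nrow(), n = opinions.ncol();
  NumericMatrix X = clone(opinions);
  const double *bp = REAL(grid_points);

  std::vector<double> cp(m), denom(m), work(m), buf(m), mu(n);
  if (r > 0.0) btcs_coefficients(m, r, cp.data(), denom.data());

  for (int i = 0; i < n; ++i) mu[i] = dot_mean(&X(0, i), bp, m);

  int n_rec = (mean_stride > 0) ? steps / mean_stride + 1 : 0;
  NumericMatrix mean_traj = (n_rec > 0) ? NumericMatrix(n, n_rec)
                                        : NumericMatrix(0, 0);
  NumericVector sigma(steps + 1);
  std::vector<int> perm(n);

  sigma[0] = pop_sd(mu.data(), n);
  if (n_rec > 0)
    for (int i = 0; i < n; ++i) mean_traj(i, 0) = mu[i];

  int consensus_step = -1;
  if (sigma[0] < sigma_cons) consensus_step = 0;
  int t_done = 0;

  if (!(stop_at_consensus && consensus_step >= 0)) {
    for (int t = 1; t <= steps; ++t) {
      // Fisher-Yates permutation from R's RNG
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (int i = n - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(perm[i], perm[j]);
      }
      for (int s = 0; s < n; ++s) {
        int a = perm[s];
        int deg = adj_offsets[a + 1] - adj_offsets[a];
        double u = unif_rand();
        double *xa = &X(0, a);
        if (u < q && deg > 0) {
          int pick = (int)(unif_rand() * deg);
          if (pick >= deg) pick = deg - 1;
          int j = adj_targets[adj_offsets[a] + pick];
          double alpha = (identity[a] == identity[j]) ? alpha_in : alpha_out;
          const double *xj = &X(0, j);
          double um = (1.0 - alpha) / m, tot = 0.0;
          for (int b = 0; b < m; ++b) {
            xa[b] *= alpha * xj[b] + um;
            tot += xa[b];
          }
          if (tot < 1e-300)
            stop("posterior mass underflow during simulation");
          double inv = 1.0 / tot, mean = 0.0;
          for (int b = 0; b < m; ++b) {
            xa[b] *= inv;
            mean += xa[b] * bp[b];
          }
          mu[a] = mean;
        } else if (r > 0.0) {
          btcs_solve(xa, buf.data(), m, r, cp.data(), denom.data(),
                     work.data());
          double tot = vec_sum(buf.data(), m);
          double inv = 1.0 / tot, mean = 0.0;
          for (int b = 0; b < m; ++b) {
            xa[b] = buf[b] * inv;
            mean += xa[b] * bp[b];
          }
          mu[a] = mean;
        }
      }
      sigma[t] = pop_sd(mu.data(), n);
      t_done = t;
      if (n_rec > 0 && t % mean_stride == 0)
        for (int i = 0; i < n; ++i) mean_traj(i, t / mean_stride) = mu[i];
      if (consensus_step < 0 && sigma[t] < sigma_cons) {
        consensus_step = t;
        if (stop_at_consensus) break;
      }
      if (t % 256 == 0) checkUserInterrupt();
    }
  }

  NumericVector sigma_out(t_done + 1);
  for (int t = 0; t <= t_done; ++t) sigma_out[t] = sigma[t];
  NumericVector means(n);
  for (int i = 0; i < n; ++i) means[i] = mu[i];

  List out = List::create(
      _["sigma"] = sigma_out, _["consensus_step"] = consensus_step,
      _["steps_run"] = t_done, _["opinions"] = X, _["means"] = means);
  if (n_rec > 0) {
    int last_rec = t_done / mean_stride;
    out["mean_trajectory"] = mean_traj(Range(0, n - 1), Range(0, last_rec));
  }
  return out;
}
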