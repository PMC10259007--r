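// BayesC-pi Gibbs sampler for single-trait GWAS with fixed group (day)
// effects and an IID dam effect. Each SNP effect is zero with probability
// 1 - pi and Gaussian N(0, sigma_a^2) otherwise; pi has a Beta prior and is
// resampled each cycle conditional on the number of included SNPs.
// Variances carry scaled inverse chi-square priors. Uses R's RNG so runs
// are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".bayescpi_cpp")]]
List bayescpi_cpp(NumericVector y,
                  NumericMatrix X,      // fixed-effect design (dense)
                  IntegerVector dam,    // 0-based dam index per record, -1 = none
                  int n_dam,
                  NumericMatrix Z,      // column-centred genotypes
                  int n_cycles, int burn_in, int thin,
                  double alpha_pi, double beta_pi,
                  double fix_pi,        // < 0: estimate pi; otherwise fixed
                  double nu_a, double s2_a,
                  double nu_d, double s2_d,
                  double nu_e, double s2_e) {
  const int n = y.size();
  const int q = X.ncol();
  const int p = Z.ncol();
  if (burn_in >= n_cycles) stop("burn_in must be smaller than n_cycles");
  if (thin < 1) stop("thin must be >= 1");

  std::vector<double> e(y.begin(), y.end());
  std::vector<double> b(q, 0.0), d(n_dam, 0.0), a(p, 0.0);
  std::vector<int> delta(p, 0);

  // column sums of squares
  std::vector<double> xpx(q, 0.0), zpz(p, 0.0);
  for (int j = 0; j < q; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xpx[j] = s;
  }
  for (int l = 0; l < p; ++l) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, l) * Z(i, l);
    zpz[l] = s;
  }
  std::vector<int> dam_n(n_dam, 0);
  for (int i = 0; i < n; ++i) if (dam[i] >= 0) dam_n[dam[i]]++;

  double vy = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) my += y[i];
  my /= n;
  for (int i = 0; i < n; ++i) vy += (y[i] - my) * (y[i] - my);
  vy /= (n - 1);
  if (vy <= 0.0) stop("zero phenotypic variance");

  double vare = 0.5 * vy;
  double vard = (n_dam > 0) ? 0.05 * vy : 0.0;
  double vara = s2_a;
  double pi = (fix_pi >= 0.0) ? fix_pi : alpha_pi / beta_pi;

  // fixed SNP update order for the run, drawn once (seeded via R's RNG)
  std::vector<int> ord(p);
  for (int l = 0; l < p; ++l) ord[l] = l;
  for (int l = p - 1; l > 0; --l) {
    int k = (int)std::floor(unif_rand() * (l + 1));
    if (k > l) k = l;
    std::swap(ord[l], ord[k]);
  }

  std::vector<double> P_sum(p, 0.0), a_sum(p, 0.0), gebv_sum(n, 0.0);
  int n_saved = 0;
  int n_keep = (n_cycles - burn_in) / thin + 1;
  NumericMatrix traces(n_keep, 6); // vare, vard, vara, pi, m, var(gv)
  int trace_row = 0;
  double pi_sum = 0.0, vara_sum = 0.0, vard_sum = 0.0, vare_sum = 0.0;

  for (int cyc = 1; cyc <= n_cycles; ++cyc) {
    // fixed effects, flat prior
    for (int j = 0; j < q; ++j) {
      if (xpx[j] <= 0.0) continue;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      rhs += xpx[j] * b[j];
      double mean = rhs / xpx[j];
      double bnew = mean + norm_rand() * std::sqrt(vare / xpx[j]);
      double diff = bnew - b[j];
      if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] -= X(i, j) * diff;
      b[j] = bnew;
    }

    // dam effects
    if (n_dam > 0) {
      std::vector<double> rhs(n_dam, 0.0);
      for (int i = 0; i < n; ++i) if (dam[i] >= 0) rhs[dam[i]] += e[i];
      for (int j = 0; j < n_dam; ++j) {
        if (dam_n[j] == 0) { d[j] = 0.0; continue; }
        double C = dam_n[j] + vare / vard;
        double mean = (rhs[j] + dam_n[j] * d[j]) / C;
        double dnew = mean + norm_rand() * std::sqrt(vare / C);
        double diff = dnew - d[j];
        d[j] = dnew;
        rhs[j] = 0.0;
        if (diff != 0.0) {
          for (int i = 0; i < n; ++i) if (dam[i] == j) e[i] -= diff;
        }
      }
      double ssd = 0.0;
      for (int j = 0; j < n_dam; ++j) ssd += d[j] * d[j];
      vard = (ssd + nu_d * s2_d) / Rf_rchisq(nu_d + n_dam);
    }

    // SNP effects with spike-and-slab mixture
    int m_incl = 0;
    double ssa = 0.0;
    const double log_prior_odds =
      std::log(std::max(pi, 1e-300)) - std::log(std::max(1.0 - pi, 1e-300));
    for (int t = 0; t < p; ++t) {
      int l = ord[t];
      double rhs = 0.0;
      const double* zcol = &Z(0, l);
      for (int i = 0; i < n; ++i) rhs += zcol[i] * e[i];
      if (a[l] != 0.0) rhs += zpz[l] * a[l];
      double v1 = zpz[l] * vara + vare;
      double logodds = log_prior_odds + 0.5 * std::log(vare / v1) +
        0.5 * rhs * rhs * vara / (vare * v1);
      int incl;
      if (pi >= 1.0) incl = 1;
      else if (logodds > 35.0) incl = 1;
      else if (logodds < -35.0) incl = 0;
      else incl = (unif_rand() < 1.0 / (1.0 + std::exp(-logodds))) ? 1 : 0;

      double a_old = a[l];
      if (incl) {
        double C = zpz[l] + vare / vara;
        double mean = rhs / C;
        double anew = mean + norm_rand() * std::sqrt(vare / C);
        double diff = anew - a_old;
        if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] -= zcol[i] * diff;
        a[l] = anew;
        delta[l] = 1;
        ++m_incl;
        ssa += anew * anew;
      } else {
        if (a_old != 0.0) for (int i = 0; i < n; ++i) e[i] += zcol[i] * a_old;
        a[l] = 0.0;
        delta[l] = 0;
      }
    }

    // pi from its Beta conditional on the number of included SNPs
    if (fix_pi < 0.0) {
      pi = Rf_rbeta(alpha_pi + m_incl, (beta_pi - alpha_pi) + (p - m_incl));
      if (pi <= 0.0) pi = 1e-12;
      if (pi >= 1.0) pi = 1.0 - 1e-12;
    }

    // SNP-effect and residual variances
    vara = (ssa + nu_a * s2_a) / Rf_rchisq(nu_a + m_incl);
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    vare = (sse + nu_e * s2_e) / Rf_rchisq(nu_e + n);

    if (cyc > burn_in && (cyc - burn_in) % thin == 0) {
      ++n_saved;
      double gmean = 0.0, gss = 0.0;
      for (int i = 0; i < n; ++i) {
        double xb = 0.0;
        for (int j = 0; j < q; ++j) xb += X(i, j) * b[j];
        double wd = (dam[i] >= 0) ? d[dam[i]] : 0.0;
        double gv = y[i] - e[i] - xb - wd; // = Z a for this cycle
        gebv_sum[i] += gv;
        gmean += gv;
      }
      gmean /= n;
      for (int i = 0; i < n; ++i) {
        double xb = 0.0;
        for (int j = 0; j < q; ++j) xb += X(i, j) * b[j];
        double wd = (dam[i] >= 0) ? d[dam[i]] : 0.0;
        double gv = y[i] - e[i] - xb - wd;
        gss += (gv - gmean) * (gv - gmean);
      }
      for (int l = 0; l < p; ++l) {
        P_sum[l] += delta[l];
        a_sum[l] += a[l];
      }
      pi_sum += pi; vara_sum += vara; vard_sum += vard; vare_sum += vare;
      if (trace_row < n_keep) {
        traces(trace_row, 0) = vare;
        traces(trace_row, 1) = vard;
        traces(trace_row, 2) = vara;
        traces(trace_row, 3) = pi;
        traces(trace_row, 4) = m_incl;
        traces(trace_row, 5) = gss / (n - 1);
        ++trace_row;
      }
    }
  }

  NumericVector P(p), ahat(p), gebv(n);
  for (int l = 0; l < p; ++l) {
    P[l] = P_sum[l] / n_saved;
    ahat[l] = a_sum[l] / n_saved;
  }
  for (int i = 0; i < n; ++i) gebv[i] = gebv_sum[i] / n_saved;

  return List::create(
    Named("p_incl") = P,
    Named("effect") = ahat,
    Named("gebv") = gebv,
    Named("pi_mean") = pi_sum / n_saved,
    Named("vara_mean") = vara_sum / n_saved,
    Named("vard_mean") = vard_sum / n_saved,
    Named("vare_mean") = vare_sum / n_saved,
    Named("n_saved") = n_saved,
    Named("traces") = traces(Range(0, trace_row - 1), _));
}
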