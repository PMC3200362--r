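#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Red-black successive over-relaxation for the discretized linearized
// Poisson-Boltzmann equation
//
//   sum_d eps_d (phi_nbr - phi_0) - lam * phi_0 + src_0 = 0
//
// phi      : nx*ny*nz potential (kT/e), boundary nodes hold Dirichlet values
// epsx     : dielectric on the edge (i,j,k)-(i+1,j,k), stored on the node grid
// lam      : screening term eps_w * kappa^2 * h^2 * ion_accessibility, per node
// src      : 4*pi*C*q_i/h per node (C = e^2/(kT * 1 Angstrom))
// tol      : relative update tolerance; tol <= 0 runs exactly maxit sweeps,
//            which keeps the iteration affine in the source (superposition
//            holds to rounding)
// [[Rcpp::export]]
List cpp_sor_lpb(NumericVector phi, NumericVector epsx, NumericVector epsy,
                 NumericVector epsz, NumericVector lam, NumericVector src,
                 int nx, int ny, int nz, double omega, double tol, int maxit) {
  const int nxy = nx * ny;
  double *p = REAL(phi);
  const double *ex = REAL(epsx), *ey = REAL(epsy), *ez = REAL(epsz);
  const double *lm = REAL(lam), *sq = REAL(src);
  double maxdiff = 0.0, maxphi = 0.0;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    maxdiff = 0.0;
    maxphi = 0.0;
    for (int parity = 0; parity < 2; ++parity) {
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          int i0 = 1 + ((j + k + parity) % 2);
          for (int i = i0; i < nx - 1; i += 2) {
            const int id = i + nx * j + nxy * k;
            const double exm = ex[id - 1], exp_ = ex[id];
            const double eym = ey[id - nx], eyp = ey[id];
            const double ezm = ez[id - nxy], ezp = ez[id];
            const double denom = exm + exp_ + eym + eyp + ezm + ezp + lm[id];
            const double rhs = exm * p[id - 1] + exp_ * p[id + 1] +
                               eym * p[id - nx] + eyp * p[id + nx] +
                               ezm * p[id - nxy] + ezp * p[id + nxy] + sq[id];
            const double pnew = (1.0 - omega) * p[id] + omega * rhs / denom;
            const double d = std::fabs(pnew - p[id]);
            if (d > maxdiff) maxdiff = d;
            const double a = std::fabs(pnew);
            if (a > maxphi) maxphi = a;
            p[id] = pnew;
          }
        }
      }
    }
    if (tol > 0.0 && maxdiff <= tol * (maxphi + 1e-300)) break;
  }
  if (it > maxit) it = maxit;
  return List::create(_["phi"] = phi, _["iters"] = it,
                      _["rel_update"] = maxdiff / (maxphi + 1e-300));
}

// Metropolis Monte Carlo over protonation microstates.
//
// Energy in pK units (i.e. divided by ln(10)*kT):
//   E(x) = sum_i x_i * (mu_i - pk_i) + 0.5 * sum_{i!=j} W_ij P_i P_j
//          + sum_pairs pen * (1-x_a)*(1-x_b)
// with P_i = x_i - xref_i.  mu_i is pH for proton sites (solution redox
// potential in pK-equivalents for electron sites); pk_i the intrinsic
// pKa plus any bias.  Uses R's RNG: set.seed() upstream gives bit
// reproducibility.
//
// frozen sites are never flipped.  pairlist (0-based, 2 columns) holds
// strongly coupled pairs proposed as joint flips once per sweep.
// [[Rcpp::export]]
List cpp_mc_titrate(IntegerVector x0, NumericVector mu, NumericVector pk,
                    NumericMatrix W, IntegerVector xref, IntegerVector frozen,
                    IntegerMatrix excl, NumericVector excl_pen,
                    IntegerMatrix pairlist, int nburn, int nsweep) {
  RNGScope scope;
  const int n = x0.size();
  std::vector<int> x(n);
  for (int i = 0; i < n; ++i) x[i] = x0[i];
  std::vector<double> meanx(n, 0.0);
  long accepted = 0, attempted = 0;
  const double LN10 = 2.302585092994046;

  auto dE_flip = [&](int i) {
    // energy change for flipping site i, in pK units
    const double dP = 1.0 - 2.0 * x[i];  // P_new - P_old = x_new - x_old
    double d = dP * (mu[i] - pk[i]);
    double coup = 0.0;
    for (int j = 0; j < n; ++j)
      if (j != i) coup += W(i, j) * (x[j] - xref[j]);
    d += dP * coup;
    for (int e = 0; e < excl.nrow(); ++e) {
      const int a = excl(e, 0), b = excl(e, 1);
      if (a == i)
        d += excl_pen[e] * ((1 - (1 - x[a])) - (1 - x[a])) * (1 - x[b]);
      else if (b == i)
        d += excl_pen[e] * (1 - x[a]) * ((1 - (1 - x[b])) - (1 - x[b]));
    }
    return d;
  };

  auto metro = [&](double d) {
    if (d <= 0.0) return true;
    return unif_rand() < std::exp(-LN10 * d);
  };

  for (int sweep = 0; sweep < nburn + nsweep; ++sweep) {
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      ++attempted;
      const double d = dE_flip(i);
      if (metro(d)) { x[i] = 1 - x[i]; ++accepted; }
    }
    for (int pr = 0; pr < pairlist.nrow(); ++pr) {
      const int a = pairlist(pr, 0), b = pairlist(pr, 1);
      if (frozen[a] || frozen[b]) continue;
      ++attempted;
      const double da = dE_flip(a);
      x[a] = 1 - x[a];
      const double db = dE_flip(b);
      x[a] = 1 - x[a];  // restore before the joint decision
      // joint flip energy: flip a, then b in the flipped-a field
      if (metro(da + db)) { x[a] = 1 - x[a]; x[b] = 1 - x[b]; ++accepted; }
    }
    if (sweep >= nburn)
      for (int i = 0; i < n; ++i) meanx[i] += x[i];
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = meanx[i] / nsweep;
  return List::create(_["mean"] = out,
                      _["acceptance"] = attempted ? (double)accepted / attempted : 0.0,
                      _["final"] = IntegerVector(x.begin(), x.end()));
}
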