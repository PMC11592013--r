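// Explicit-dynamics element kernel: precomputed shape gradients, mean-dilatation
// (B-bar) strain substitution, incremental-objective small-strain update with
// radial-return J2 plasticity, Cowper-Symonds rate scaling, ductile damage with
// fracture-energy softening and element deletion.
//
// Unit system throughout: mm - N - s - tonne (stress MPa, energy mJ).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// small 3x3 helpers (stress stored Voigt [xx,yy,zz,xy,yz,xz], tensor shears)

static inline void voigt_to_mat(const double* v, double m[3][3]) {
  m[0][0] = v[0]; m[1][1] = v[1]; m[2][2] = v[2];
  m[0][1] = m[1][0] = v[3];
  m[1][2] = m[2][1] = v[4];
  m[0][2] = m[2][0] = v[5];
}

static inline void mat_to_voigt(const double m[3][3], double* v) {
  v[0] = m[0][0]; v[1] = m[1][1]; v[2] = m[2][2];
  v[3] = m[0][1]; v[4] = m[1][2]; v[5] = m[0][2];
}

// Rotate symmetric tensor s (Voigt) by the incremental rotation generated by
// the spin axial vector w: Cayley form Q = (I - W/2)^-1 (I + W/2), which is
// exactly orthogonal (preserves the stress norm to round-off) and agrees with
// the exact rotation to O(theta^3) per increment.
static void rotate_voigt(double* s, const double w[3]) {
  double th2 = w[0]*w[0] + w[1]*w[1] + w[2]*w[2];
  if (th2 < 1e-300) return;
  double den = 1.0 + 0.25*th2;
  // closed Cayley form: Q = I + (A + A^2/2) / (1 + |w|^2/4), A = [w]_x
  double Q[3][3];
  double A01 = -w[2], A02 = w[1], A12 = -w[0];
  double A10 = w[2], A20 = -w[1], A21 = w[0];
  // Q = I + (A + A*A/2)/den
  double AA00 = A01*A10 + A02*A20;
  double AA11 = A10*A01 + A12*A21;
  double AA22 = A20*A02 + A21*A12;
  double AA01 = A02*A21, AA02 = A01*A12, AA10 = A12*A20;
  double AA12 = A10*A02, AA20 = A21*A10, AA21 = A20*A01;
  Q[0][0] = 1.0 + 0.5*AA00/den;
  Q[1][1] = 1.0 + 0.5*AA11/den;
  Q[2][2] = 1.0 + 0.5*AA22/den;
  Q[0][1] = (A01 + 0.5*AA01)/den;
  Q[0][2] = (A02 + 0.5*AA02)/den;
  Q[1][0] = (A10 + 0.5*AA10)/den;
  Q[1][2] = (A12 + 0.5*AA12)/den;
  Q[2][0] = (A20 + 0.5*AA20)/den;
  Q[2][1] = (A21 + 0.5*AA21)/den;
  double S[3][3], T[3][3], R[3][3];
  voigt_to_mat(s, S);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      T[i][j] = 0.0;
      for (int m = 0; m < 3; ++m) T[i][j] += Q[i][m] * S[m][j];
    }
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      R[i][j] = 0.0;
      for (int m = 0; m < 3; ++m) R[i][j] += T[i][m] * Q[j][m];
    }
  mat_to_voigt(R, s);
}

// ---------------------------------------------------------------------------
// material evaluation

struct MatPar {
  double E, nu, lambda, mu, kappa;
  std::vector<double> heps, hsig;   // hardening curve (eps_pl, sigma) MPa
  double csD, csn;                  // Cowper-Symonds
  bool cs_on;
};

static MatPar parse_mat(const List& m) {
  MatPar p;
  p.E  = as<double>(m["E"]);
  p.nu = as<double>(m["nu"]);
  p.mu = p.E / (2.0 * (1.0 + p.nu));
  p.lambda = p.E * p.nu / ((1.0 + p.nu) * (1.0 - 2.0 * p.nu));
  p.kappa = p.lambda + 2.0 * p.mu / 3.0;
  NumericVector he = m["hard_eps"], hs = m["hard_sig"];
  p.heps.assign(he.begin(), he.end());
  p.hsig.assign(hs.begin(), hs.end());
  p.csD = as<double>(m["cs_D"]);
  p.csn = as<double>(m["cs_n"]);
  p.cs_on = as<bool>(m["cs_enabled"]);
  return p;
}

static inline double hard_sigma(const MatPar& p, double ep) {
  const std::vector<double>& x = p.heps;
  const std::vector<double>& y = p.hsig;
  size_t n = x.size();
  if (ep <= x[0]) return y[0];
  if (ep >= x[n-1]) return y[n-1];
  size_t i = 1;
  while (x[i] < ep) ++i;
  double t = (ep - x[i-1]) / (x[i] - x[i-1]);
  return y[i-1] + t * (y[i] - y[i-1]);
}

static inline double rate_R(const MatPar& p, double rate) {
  if (!p.cs_on || rate <= 0.0) return 1.0;
  return 1.0 + std::pow(rate / p.csD, 1.0 / p.csn);
}

// radial return: solve q_trial - 3 mu dl - R(dl/dt) sigma_h(ep + dl) = 0
static double solve_return(const MatPar& p, double q_trial, double ep,
                           double dt, bool rate_on) {
  // g(dl) = q_trial - 3 mu dl - R(dl/dt) sigma_h(ep+dl), monotone decreasing;
  // safeguarded Newton (bisection fallback keeps the bracket)
  double lo = 0.0, hi = q_trial / (3.0 * p.mu);
  double dl = 0.5 * hi;
  for (int it = 0; it < 60; ++it) {
    double R = 1.0, dRddl = 0.0;
    if (rate_on) {
      double r = dl / dt;
      if (r > 0.0) {
        double t = std::pow(r / p.csD, 1.0 / p.csn);
        R = 1.0 + t;
        dRddl = t / (p.csn * r) / dt;      // d/d(dl) of (r/D)^(1/n)
      }
    }
    double sh = hard_sigma(p, ep + dl);
    // local hardening slope
    double hps = 0.0;
    {
      const std::vector<double>& x = p.heps;
      size_t nn = x.size();
      double e2 = ep + dl;
      if (nn > 1 && e2 < x[nn-1]) {
        size_t i = 1;
        while (x[i] < e2) ++i;
        hps = (p.hsig[i] - p.hsig[i-1]) / (x[i] - x[i-1]);
      }
    }
    double g = q_trial - 3.0 * p.mu * dl - R * sh;
    if (std::fabs(g) < 1e-10 * q_trial + 1e-12) break;
    if (g > 0.0) lo = dl; else hi = dl;
    double gp = -3.0 * p.mu - dRddl * sh - R * hps;
    double step = g / gp;
    double next = dl - step;
    if (next <= lo || next >= hi) next = 0.5 * (lo + hi);
    if (hi - lo < 1e-18) break;
    dl = next;
  }
  return dl;
}

// single integration-point stress update; deps is the Voigt strain increment
// (tensor shears), w the spin axial vector over the step.
static void point_update(const MatPar& p, double* sig, double& eps_pl,
                         const double* deps, const double* w, double dt,
                         bool rate_on, double& dlam, double& q_out) {
  rotate_voigt(sig, w);
  double tr = deps[0] + deps[1] + deps[2];
  double st[6];
  for (int i = 0; i < 3; ++i)
    st[i] = sig[i] + p.lambda * tr + 2.0 * p.mu * deps[i];
  for (int i = 3; i < 6; ++i)
    st[i] = sig[i] + 2.0 * p.mu * deps[i];
  double pm = (st[0] + st[1] + st[2]) / 3.0;
  double sd[6] = {st[0]-pm, st[1]-pm, st[2]-pm, st[3], st[4], st[5]};
  double j2 = 0.5*(sd[0]*sd[0]+sd[1]*sd[1]+sd[2]*sd[2])
            + sd[3]*sd[3]+sd[4]*sd[4]+sd[5]*sd[5];
  double q = std::sqrt(3.0 * j2);
  double sy0 = hard_sigma(p, eps_pl);       // quasi-static yield at R = 1
  dlam = 0.0;
  if (q > sy0 * (1.0 + 1e-12) && q > 0.0) {
    dlam = solve_return(p, q, eps_pl, dt, rate_on);
    double f = 1.0 - 3.0 * p.mu * dlam / q;
    for (int i = 0; i < 6; ++i) sd[i] *= f;
    eps_pl += dlam;
    q *= f;
  }
  for (int i = 0; i < 3; ++i) sig[i] = sd[i] + pm;
  for (int i = 3; i < 6; ++i) sig[i] = sd[i];
  q_out = q;
}

// rate-dependent onset strain from the damage table, log10-interpolated
static double onset_eps(const NumericVector& trate, const NumericVector& teps,
                        double rate) {
  int n = trate.size();
  // first strictly positive tabulated rate
  int i0 = 0;
  while (i0 < n && trate[i0] <= 0.0) ++i0;
  if (i0 >= n) return teps[n-1];
  if (rate <= trate[i0]) return teps[0];      // quasi-static plateau
  if (rate >= trate[n-1]) return teps[n-1];
  double lr = std::log10(rate);
  for (int i = i0; i < n - 1; ++i) {
    double a = std::log10(trate[i]), b = std::log10(trate[i+1]);
    if (lr >= a && lr <= b) {
      double t = (lr - a) / (b - a);
      return teps[i] + t * (teps[i+1] - teps[i]);
    }
  }
  return teps[n-1];
}

// [[Rcpp::export]]
double cpp_onset_strain(NumericVector table_rate, NumericVector table_eps,
                        double rate) {
  return onset_eps(table_rate, table_eps, rate);
}

// [[Rcpp::export]]
List cpp_point_stress_update(NumericVector stress, double eps_pl,
                             NumericVector deps, NumericVector spin,
                             double dt, List mat) {
  MatPar p = parse_mat(mat);
  double s[6], de[6], w[3];
  for (int i = 0; i < 6; ++i) { s[i] = stress[i]; de[i] = deps[i]; }
  for (int i = 0; i < 3; ++i) w[i] = spin[i];
  double ep = eps_pl, dl, q;
  point_update(p, s, ep, de, w, dt, p.cs_on, dl, q);
  return List::create(_["stress"] = NumericVector(s, s + 6),
                      _["eps_pl"] = ep,
                      _["delta_eps_pl"] = dl,
                      _["eps_dot_pl"] = dt > 0 ? dl / dt : 0.0,
                      _["q"] = q);
}

// ---------------------------------------------------------------------------
// geometry precompute

// trilinear hex shape derivatives at natural point (xi, eta, ze)
static void hex_dN(double xi, double eta, double ze, double dN[8][3]) {
  const double sx[8] = {-1, 1, 1,-1,-1, 1, 1,-1};
  const double sy[8] = {-1,-1, 1, 1,-1,-1, 1, 1};
  const double sz[8] = {-1,-1,-1,-1, 1, 1, 1, 1};
  for (int a = 0; a < 8; ++a) {
    dN[a][0] = 0.125 * sx[a] * (1 + sy[a]*eta) * (1 + sz[a]*ze);
    dN[a][1] = 0.125 * sy[a] * (1 + sx[a]*xi)  * (1 + sz[a]*ze);
    dN[a][2] = 0.125 * sz[a] * (1 + sx[a]*xi)  * (1 + sy[a]*eta);
  }
}

static void hex_N(double xi, double eta, double ze, double N[8]) {
  const double sx[8] = {-1, 1, 1,-1,-1, 1, 1,-1};
  const double sy[8] = {-1,-1, 1, 1,-1,-1, 1, 1};
  const double sz[8] = {-1,-1,-1,-1, 1, 1, 1, 1};
  for (int a = 0; a < 8; ++a)
    N[a] = 0.125 * (1 + sx[a]*xi) * (1 + sy[a]*eta) * (1 + sz[a]*ze);
}

// Precompute per-gauss-point gradients w.r.t. reference coordinates, weights,
// element volumes, characteristic lengths, mean (volume-averaged) gradients,
// and lumped shape-function integrals.
// conn: E x 8 integer matrix (1-based, tet rows use columns 1..4)
// nen:  4 or 8 per element
// [[Rcpp::export]]
List cpp_fem_precompute(NumericMatrix nodes, IntegerMatrix conn,
                        IntegerVector nen) {
  int E = conn.nrow();
  IntegerVector ngp(E), gp_off(E);
  int total_gp = 0;
  for (int e = 0; e < E; ++e) {
    ngp[e] = (nen[e] == 8) ? 8 : 1;
    gp_off[e] = total_gp;
    total_gp += ngp[e];
  }
  // flattened: dNdx[(gp_global*8 + a)*3 + k]
  NumericVector dNdx(total_gp * 8 * 3), wJ(total_gp);
  NumericVector vol(E), Le(E), Lcfl(E);
  NumericVector gbar(E * 8 * 3);     // mean gradients
  NumericVector nlump(E * 8);        // integral of N_a over element
  const double g = 1.0 / std::sqrt(3.0);

  for (int e = 0; e < E; ++e) {
    int ne = nen[e];
    double X[8][3];
    for (int a = 0; a < ne; ++a) {
      int nd = conn(e, a) - 1;
      for (int k = 0; k < 3; ++k) X[a][k] = nodes(nd, k);
    }
    double V = 0.0;
    if (ne == 4) {
      // constant-strain tetrahedron
      double d1[3], d2[3], d3[3];
      for (int k = 0; k < 3; ++k) {
        d1[k] = X[1][k] - X[0][k];
        d2[k] = X[2][k] - X[0][k];
        d3[k] = X[3][k] - X[0][k];
      }
      double det = d1[0]*(d2[1]*d3[2]-d2[2]*d3[1])
                 - d1[1]*(d2[0]*d3[2]-d2[2]*d3[0])
                 + d1[2]*(d2[0]*d3[1]-d2[1]*d3[0]);
      V = det / 6.0;
      if (V <= 0.0) stop("non-positive volume in element %d", e + 1);
      // gradients of linear shape functions: rows of inverse Jacobian
      double J[3][3] = {{d1[0], d2[0], d3[0]},
                        {d1[1], d2[1], d3[1]},
                        {d1[2], d2[2], d3[2]}};
      double inv[3][3];
      double idet = 1.0 / det;
      inv[0][0] =  (J[1][1]*J[2][2]-J[1][2]*J[2][1]) * idet;
      inv[0][1] = -(J[0][1]*J[2][2]-J[0][2]*J[2][1]) * idet;
      inv[0][2] =  (J[0][1]*J[1][2]-J[0][2]*J[1][1]) * idet;
      inv[1][0] = -(J[1][0]*J[2][2]-J[1][2]*J[2][0]) * idet;
      inv[1][1] =  (J[0][0]*J[2][2]-J[0][2]*J[2][0]) * idet;
      inv[1][2] = -(J[0][0]*J[1][2]-J[0][2]*J[1][0]) * idet;
      inv[2][0] =  (J[1][0]*J[2][1]-J[1][1]*J[2][0]) * idet;
      inv[2][1] = -(J[0][0]*J[2][1]-J[0][1]*J[2][0]) * idet;
      inv[2][2] =  (J[0][0]*J[1][1]-J[0][1]*J[1][0]) * idet;
      int gpg = gp_off[e];
      for (int k = 0; k < 3; ++k) {
        double s = inv[0][k] + inv[1][k] + inv[2][k];
        dNdx[(gpg*8 + 0)*3 + k] = -s;
        dNdx[(gpg*8 + 1)*3 + k] = inv[0][k];
        dNdx[(gpg*8 + 2)*3 + k] = inv[1][k];
        dNdx[(gpg*8 + 3)*3 + k] = inv[2][k];
      }
      wJ[gpg] = V;
      for (int a = 0; a < 4; ++a) {
        for (int k = 0; k < 3; ++k)
          gbar[(e*8 + a)*3 + k] = dNdx[(gpg*8 + a)*3 + k];
        nlump[e*8 + a] = V / 4.0;
      }
    } else {
      // 8-node hex, 2x2x2 Gauss
      for (int q = 0; q < 8; ++q) {
        double xi  = g * ((q & 1) ? 1 : -1);
        double eta = g * ((q & 2) ? 1 : -1);
        double ze  = g * ((q & 4) ? 1 : -1);
        double dN[8][3], N[8];
        hex_dN(xi, eta, ze, dN);
        hex_N(xi, eta, ze, N);
        double J[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
        for (int a = 0; a < 8; ++a)
          for (int i = 0; i < 3; ++i)
            for (int k = 0; k < 3; ++k)
              J[i][k] += X[a][i] * dN[a][k];
        double det = J[0][0]*(J[1][1]*J[2][2]-J[1][2]*J[2][1])
                   - J[0][1]*(J[1][0]*J[2][2]-J[1][2]*J[2][0])
                   + J[0][2]*(J[1][0]*J[2][1]-J[1][1]*J[2][0]);
        if (det <= 0.0) stop("non-positive Jacobian in element %d", e + 1);
        double inv[3][3];
        double idet = 1.0 / det;
        inv[0][0] =  (J[1][1]*J[2][2]-J[1][2]*J[2][1]) * idet;
        inv[0][1] = -(J[0][1]*J[2][2]-J[0][2]*J[2][1]) * idet;
        inv[0][2] =  (J[0][1]*J[1][2]-J[0][2]*J[1][1]) * idet;
        inv[1][0] = -(J[1][0]*J[2][2]-J[1][2]*J[2][0]) * idet;
        inv[1][1] =  (J[0][0]*J[2][2]-J[0][2]*J[2][0]) * idet;
        inv[1][2] = -(J[0][0]*J[1][2]-J[0][2]*J[1][0]) * idet;
        inv[2][0] =  (J[1][0]*J[2][1]-J[1][1]*J[2][0]) * idet;
        inv[2][1] = -(J[0][0]*J[2][1]-J[0][1]*J[2][0]) * idet;
        inv[2][2] =  (J[0][0]*J[1][1]-J[0][1]*J[1][0]) * idet;
        int gpg = gp_off[e] + q;
        wJ[gpg] = det;                     // unit Gauss weights for 2x2x2
        for (int a = 0; a < 8; ++a) {
          for (int k = 0; k < 3; ++k) {
            double v = 0.0;
            for (int m = 0; m < 3; ++m) v += dN[a][m] * inv[m][k];
            dNdx[(gpg*8 + a)*3 + k] = v;
          }
          nlump[e*8 + a] += N[a] * det;
        }
        V += det;
      }
      vol[e] = V;
      for (int a = 0; a < 8; ++a)
        for (int k = 0; k < 3; ++k) {
          double s = 0.0;
          for (int q = 0; q < 8; ++q) {
            int gpg = gp_off[e] + q;
            s += dNdx[(gpg*8 + a)*3 + k] * wJ[gpg];
          }
          gbar[(e*8 + a)*3 + k] = s / V;
        }
    }
    if (ne == 4) vol[e] = wJ[gp_off[e]];
    Le[e] = std::cbrt(vol[e]);        // softening localisation length
    // CFL length: shortest element edge (conservative for flat elements)
    {
      static const int hex_ed[12][2] = {{0,1},{1,2},{2,3},{3,0},{4,5},{5,6},
                                        {6,7},{7,4},{0,4},{1,5},{2,6},{3,7}};
      static const int tet_ed[6][2] = {{0,1},{0,2},{0,3},{1,2},{1,3},{2,3}};
      int ned = (ne == 8) ? 12 : 6;
      double lmin = R_PosInf;
      for (int ed = 0; ed < ned; ++ed) {
        int a = (ne == 8) ? hex_ed[ed][0] : tet_ed[ed][0];
        int b = (ne == 8) ? hex_ed[ed][1] : tet_ed[ed][1];
        double l2 = 0.0;
        for (int k = 0; k < 3; ++k) {
          double d = X[a][k] - X[b][k];
          l2 += d * d;
        }
        if (l2 < lmin) lmin = l2;
      }
      Lcfl[e] = std::sqrt(lmin);
    }
  }
  return List::create(_["dNdx"] = dNdx, _["wJ"] = wJ, _["gbar"] = gbar,
                      _["nlump"] = nlump, _["vol"] = vol, _["Le"] = Le,
                      _["Lcfl"] = Lcfl, _["ngp"] = ngp, _["gp_off"] = gp_off,
                      _["total_gp"] = total_gp);
}

// [[Rcpp::export]]
NumericVector cpp_lumped_mass(List pre, IntegerMatrix conn, IntegerVector nen,
                              NumericVector rho_e, int n_nodes) {
  NumericVector nlump = pre["nlump"];
  NumericVector m(n_nodes);
  int E = conn.nrow();
  for (int e = 0; e < E; ++e)
    for (int a = 0; a < nen[e]; ++a)
      m[conn(e, a) - 1] += rho_e[e] * nlump[e*8 + a];
  return m;
}

// stateless linear-elastic internal force (modal stiffness, oracles);
// same B-bar formulation as the dynamic kernel.
// [[Rcpp::export]]
NumericMatrix cpp_elastic_forces(List pre, IntegerMatrix conn,
                                 IntegerVector nen, NumericMatrix disp,
                                 NumericVector lambda_e, NumericVector mu_e) {
  NumericVector dNdx = pre["dNdx"], wJ = pre["wJ"], gbar = pre["gbar"];
  IntegerVector ngp = pre["ngp"], gp_off = pre["gp_off"];
  int E = conn.nrow(), N = disp.nrow();
  NumericMatrix f(N, 3);
  for (int e = 0; e < E; ++e) {
    int ne = nen[e];
    double u[8][3];
    int nd[8];
    for (int a = 0; a < ne; ++a) {
      nd[a] = conn(e, a) - 1;
      for (int k = 0; k < 3; ++k) u[a][k] = disp(nd[a], k);
    }
    double kap = lambda_e[e] + 2.0 * mu_e[e] / 3.0;
    double trb = 0.0;
    for (int a = 0; a < ne; ++a)
      for (int k = 0; k < 3; ++k)
        trb += u[a][k] * gbar[(e*8 + a)*3 + k];
    for (int q = 0; q < ngp[e]; ++q) {
      int gpg = gp_off[e] + q;
      double L[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
      for (int a = 0; a < ne; ++a)
        for (int i = 0; i < 3; ++i)
          for (int k = 0; k < 3; ++k)
            L[i][k] += u[a][i] * dNdx[(gpg*8 + a)*3 + k];
      double eps[3][3];
      for (int i = 0; i < 3; ++i)
        for (int k = 0; k < 3; ++k)
          eps[i][k] = 0.5 * (L[i][k] + L[k][i]);
      double tr = eps[0][0] + eps[1][1] + eps[2][2];
      double sm = kap * trb;                      // B-bar mean stress
      double sig[3][3];
      for (int i = 0; i < 3; ++i)
        for (int k = 0; k < 3; ++k) {
          double dev = eps[i][k] - (i == k ? tr / 3.0 : 0.0);
          sig[i][k] = 2.0 * mu_e[e] * dev + (i == k ? sm : 0.0);
        }
      double smean = (sig[0][0] + sig[1][1] + sig[2][2]) / 3.0;
      for (int a = 0; a < ne; ++a)
        for (int i = 0; i < 3; ++i) {
          double fi = 0.0;
          for (int k = 0; k < 3; ++k) {
            double sd = sig[i][k] - (i == k ? smean : 0.0);
            fi += sd * dNdx[(gpg*8 + a)*3 + k];
          }
          fi += smean * gbar[(e*8 + a)*3 + i];
          f(nd[a], i) += fi * wJ[gpg];
        }
    }
  }
  return f;
}

// ---------------------------------------------------------------------------
// full incremental step: constitutive update + damage + assembly.
// Mutates state vectors in place (allocated once in R, never duplicated).
// phase: 1 = cortical (rate-dependent, ductile damage), 2 = trabecular
// (rate-independent plasticity, strain-cap deletion).
// [[Rcpp::export]]
List cpp_internal_forces_step(List pre, IntegerMatrix conn, IntegerVector nen,
                              IntegerVector phase, List mat_cort, List mat_trab,
                              List dam,
                              NumericMatrix du, int n_nodes, double dt,
                              NumericVector stress, NumericVector eps_pl,
                              NumericVector omega, NumericVector dmg,
                              NumericVector u_pl, NumericVector sy0_onset,
                              NumericVector rate_s, IntegerVector deleted,
                              bool elastic_only) {
  NumericVector dNdx = pre["dNdx"], wJ = pre["wJ"], gbar = pre["gbar"];
  NumericVector Le = pre["Le"];
  IntegerVector ngp = pre["ngp"], gp_off = pre["gp_off"];
  MatPar pc = parse_mat(mat_cort), pt = parse_mat(mat_trab);

  NumericVector trate = dam["table_rate"], teps = dam["table_eps"];
  double G = as<double>(dam["G"]);
  double trab_cap = as<double>(dam["trabecular_cap"]);
  double del_thr = as<double>(dam["deletion_threshold"]);
  double alpha = as<double>(dam["rate_smoothing"]);
  bool dam_on = as<bool>(dam["enabled"]) && !elastic_only;

  int E = conn.nrow();
  NumericMatrix f(n_nodes, 3);
  double dW_int = 0.0, dW_pl = 0.0, dW_dam = 0.0;
  std::vector<int> newly_deleted;

  for (int e = 0; e < E; ++e) {
    if (deleted[e]) continue;
    int ne = nen[e];
    const MatPar& p = (phase[e] == 1) ? pc : pt;
    double u[8][3];
    int nd[8];
    for (int a = 0; a < ne; ++a) {
      nd[a] = conn(e, a) - 1;
      for (int k = 0; k < 3; ++k) u[a][k] = du(nd[a], k);
    }
    double trb = 0.0;
    for (int a = 0; a < ne; ++a)
      for (int k = 0; k < 3; ++k)
        trb += u[a][k] * gbar[(e*8 + a)*3 + k];

    double d_old = dmg[e];
    double sum_dlam = 0.0, sum_ep = 0.0;
    double sum_qdlw = 0.0, sum_wint = 0.0;
    double fe[8][3];
    for (int a = 0; a < ne; ++a) fe[a][0] = fe[a][1] = fe[a][2] = 0.0;

    for (int q = 0; q < ngp[e]; ++q) {
      int gpg = gp_off[e] + q;
      double L[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
      for (int a = 0; a < ne; ++a)
        for (int i = 0; i < 3; ++i)
          for (int k = 0; k < 3; ++k)
            L[i][k] += u[a][i] * dNdx[(gpg*8 + a)*3 + k];
      double tr = L[0][0] + L[1][1] + L[2][2];
      double de[6];
      de[0] = L[0][0] + (trb - tr) / 3.0;
      de[1] = L[1][1] + (trb - tr) / 3.0;
      de[2] = L[2][2] + (trb - tr) / 3.0;
      de[3] = 0.5 * (L[0][1] + L[1][0]);
      de[4] = 0.5 * (L[1][2] + L[2][1]);
      de[5] = 0.5 * (L[0][2] + L[2][0]);
      double w[3] = {0.5 * (L[2][1] - L[1][2]),
                     0.5 * (L[0][2] - L[2][0]),
                     0.5 * (L[1][0] - L[0][1])};
      double* s = &stress[6 * gpg];
      double s_old[6];
      for (int i = 0; i < 6; ++i) s_old[i] = s[i];
      double ep = eps_pl[gpg], dl = 0.0, qeq = 0.0;
      if (elastic_only) {
        rotate_voigt(s, w);
        double trd = de[0] + de[1] + de[2];
        for (int i = 0; i < 3; ++i) s[i] += p.lambda * trd + 2.0 * p.mu * de[i];
        for (int i = 3; i < 6; ++i) s[i] += 2.0 * p.mu * de[i];
      } else {
        point_update(p, s, ep, de, w, dt, p.cs_on, dl, qeq);
        eps_pl[gpg] = ep;
      }
      if (!std::isfinite(s[0]) || !std::isfinite(s[3]))
        stop("non-finite stress in element %d at step dt=%g", e + 1, dt);
      sum_dlam += dl;
      sum_ep += ep;
      double wint = 0.0;
      for (int i = 0; i < 3; ++i) wint += 0.5 * (s_old[i] + s[i]) * de[i];
      for (int i = 3; i < 6; ++i) wint += (s_old[i] + s[i]) * de[i]; // 2x shear
      sum_wint += wint * wJ[gpg];
      sum_qdlw += qeq * dl * wJ[gpg];
      // force assembled after the damage update (per-element factor)
      for (int a = 0; a < ne; ++a) {
        double sm = (s[0] + s[1] + s[2]) / 3.0;
        double sd0 = s[0] - sm, sd1 = s[1] - sm, sd2 = s[2] - sm;
        const double* g1 = &dNdx[(gpg*8 + a)*3];
        fe[a][0] += (sd0*g1[0] + s[3]*g1[1] + s[5]*g1[2]
                     + sm * gbar[(e*8 + a)*3 + 0]) * wJ[gpg];
        fe[a][1] += (s[3]*g1[0] + sd1*g1[1] + s[4]*g1[2]
                     + sm * gbar[(e*8 + a)*3 + 1]) * wJ[gpg];
        fe[a][2] += (s[5]*g1[0] + s[4]*g1[1] + sd2*g1[2]
                     + sm * gbar[(e*8 + a)*3 + 2]) * wJ[gpg];
      }
    }

    // element-level damage bookkeeping
    if (dam_on) {
      int m = ngp[e];
      double mean_dl = sum_dlam / m;
      double mean_ep = sum_ep / m;
      if (phase[e] == 1) {
        double r_inst = mean_dl / dt;
        rate_s[e] += alpha * (r_inst - rate_s[e]);
        if (mean_dl > 0.0) {
          double eon = onset_eps(trate, teps, rate_s[e]);
          omega[e] += mean_dl / eon;
          if (omega[e] >= 1.0 && sy0_onset[e] <= 0.0) {
            double R = rate_R(pc, rate_s[e]);
            sy0_onset[e] = R * hard_sigma(pc, mean_ep);
          }
          if (sy0_onset[e] > 0.0) {
            u_pl[e] += Le[e] * mean_dl;
            double uf = 2.0 * G / sy0_onset[e];
            double dnew = u_pl[e] / uf;
            if (dnew > 1.0) dnew = 1.0;
            if (dnew > dmg[e]) dmg[e] = dnew;
          }
        }
        if (dmg[e] >= del_thr) {
          deleted[e] = 1;
          newly_deleted.push_back(e + 1);
        }
      } else if (mean_ep >= trab_cap) {
        deleted[e] = 1;
        newly_deleted.push_back(e + 1);
      }
    }

    double d_mid = 0.5 * (d_old + dmg[e]);
    dW_int += (1.0 - d_mid) * sum_wint;
    dW_pl += (1.0 - d_mid) * sum_qdlw;
    if (sy0_onset[e] > 0.0)       // softening branch: post-initiation work
      dW_dam += (1.0 - d_mid) * sum_qdlw;

    double fac = 1.0 - dmg[e];
    if (deleted[e]) fac = 0.0;
    for (int a = 0; a < ne; ++a)
      for (int k = 0; k < 3; ++k)
        f(nd[a], k) += fac * fe[a][k];
  }
  return List::create(_["force"] = f, _["dW_int"] = dW_int,
                      _["dW_plastic"] = dW_pl, _["dW_damage"] = dW_dam,
                      _["newly_deleted"] = wrap(newly_deleted));
}

// ---------------------------------------------------------------------------
// analytic finite-cylinder clearance (lateral surface + end caps)
// [[Rcpp::export]]
List cpp_cylinder_clearance(NumericMatrix pts, NumericVector origin,
                            NumericVector axis, double half_len,
                            double radius) {
  int n = pts.nrow();
  NumericVector cl(n);
  NumericMatrix nrm(n, 3);
  double a0 = axis[0], a1 = axis[1], a2 = axis[2];
  for (int i = 0; i < n; ++i) {
    double d0 = pts(i,0) - origin[0];
    double d1 = pts(i,1) - origin[1];
    double d2 = pts(i,2) - origin[2];
    double z = d0*a0 + d1*a1 + d2*a2;
    double r0 = d0 - z*a0, r1 = d1 - z*a1, r2 = d2 - z*a2;
    double r = std::sqrt(r0*r0 + r1*r1 + r2*r2);
    double er0, er1, er2;
    if (r > 1e-12) { er0 = r0/r; er1 = r1/r; er2 = r2/r; }
    else { // arbitrary unit vector orthogonal to axis
      if (std::fabs(a0) < 0.9) { er0 = 1 - a0*a0; er1 = -a0*a1; er2 = -a0*a2; }
      else { er0 = -a1*a0; er1 = 1 - a1*a1; er2 = -a1*a2; }
      double nn = std::sqrt(er0*er0 + er1*er1 + er2*er2);
      er0 /= nn; er1 /= nn; er2 /= nn;
    }
    double az = std::fabs(z), sz = (z >= 0) ? 1.0 : -1.0;
    if (az <= half_len) {
      double lat = r - radius;          // signed lateral clearance
      if (lat >= 0.0) {
        cl[i] = lat;
        nrm(i,0) = er0; nrm(i,1) = er1; nrm(i,2) = er2;
      } else {
        // inside: nearest surface is lateral or cap
        if (-lat <= half_len - az) {
          cl[i] = lat;
          nrm(i,0) = er0; nrm(i,1) = er1; nrm(i,2) = er2;
        } else {
          cl[i] = -(half_len - az);
          nrm(i,0) = sz*a0; nrm(i,1) = sz*a1; nrm(i,2) = sz*a2;
        }
      }
    } else {
      double dz = az - half_len;
      if (r <= radius) {
        cl[i] = dz;
        nrm(i,0) = sz*a0; nrm(i,1) = sz*a1; nrm(i,2) = sz*a2;
      } else {
        double dr = r - radius;
        cl[i] = std::sqrt(dz*dz + dr*dr);
        double nn = cl[i];
        nrm(i,0) = (dr*er0 + dz*sz*a0) / nn;
        nrm(i,1) = (dr*er1 + dz*sz*a1) / nn;
        nrm(i,2) = (dr*er2 + dz*sz*a2) / nn;
      }
    }
  }
  return List::create(_["clearance"] = cl, _["normal"] = nrm);
}
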