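#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ideal backbone geometry (Engh-Huber-style constants, see R/geometry.R)
static const double B_N_CA = 1.458, B_CA_C = 1.525, B_C_N = 1.329, B_C_O = 1.231;
static const double A_N_CA_C = 111.2, A_CA_C_N = 116.2, A_C_N_CA = 121.7,
                    A_CA_C_O = 120.5;
static const double CB_GAMMA = 51.7;  // out-of-plane angle of the CA->CEN axis
static const double DEG = M_PI / 180.0;

static inline void cross3(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline void unit3(double *v) {
  double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  v[0] /= n; v[1] /= n; v[2] /= n;
}

// Natural-extension reference frame: place D from A-B-C with bond length d,
// bond angle theta(B,C,D) and torsion tau(A,B,C,D), both in degrees.
static void nerf(const double *A, const double *B, const double *C,
                 double d, double theta, double tau, double *D) {
  double th = theta * DEG, ta = tau * DEG;
  double bc[3] = {C[0] - B[0], C[1] - B[1], C[2] - B[2]};
  unit3(bc);
  double ab[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
  double n[3];
  cross3(ab, bc, n);
  unit3(n);
  double m[3];
  cross3(n, bc, m);  // completes right-handed frame (bc, m, n)
  double d2[3] = {-d * std::cos(th), d * std::sin(th) * std::cos(ta),
                  d * std::sin(th) * std::sin(ta)};
  for (int k = 0; k < 3; ++k)
    D[k] = C[k] + d2[0] * bc[k] + d2[1] * m[k] + d2[2] * n[k];
}

// Build N, CA, C, O, CEN coordinates for an L-residue chain from dihedrals
// (degrees). Row layout: residue-major, atoms in the order N, CA, C, O, CEN.
// Residue 1 is placed in the canonical frame: CA at the origin, N on the
// negative x axis, C in the xy plane.
// [[Rcpp::export]]
NumericMatrix cpp_build_backbone(NumericVector omega, NumericVector phi,
                                 NumericVector psi, NumericVector cen_r) {
  int L = phi.size();
  if (omega.size() != L || psi.size() != L || cen_r.size() != L)
    stop("dihedral and radius vectors must have equal length");
  NumericMatrix out(5 * L, 3);
  std::vector<double> N(3 * L), CA(3 * L), C(3 * L);
  N[0] = -B_N_CA; N[1] = 0.0; N[2] = 0.0;
  CA[0] = CA[1] = CA[2] = 0.0;
  double al = (180.0 - A_N_CA_C) * DEG;
  C[0] = B_CA_C * std::cos(al); C[1] = B_CA_C * std::sin(al); C[2] = 0.0;
  for (int i = 1; i < L; ++i) {
    nerf(&N[3 * (i - 1)], &CA[3 * (i - 1)], &C[3 * (i - 1)],
         B_C_N, A_CA_C_N, psi[i - 1], &N[3 * i]);
    nerf(&CA[3 * (i - 1)], &C[3 * (i - 1)], &N[3 * i],
         B_N_CA, A_C_N_CA, omega[i], &CA[3 * i]);
    nerf(&C[3 * (i - 1)], &N[3 * i], &CA[3 * i],
         B_CA_C, A_N_CA_C, phi[i], &C[3 * i]);
  }
  for (int i = 0; i < L; ++i) {
    double O[3];
    double tau_o = psi[i] + 180.0;
    nerf(&N[3 * i], &CA[3 * i], &C[3 * i], B_C_O, A_CA_C_O, tau_o, O);
    // side-chain pseudo-atom: tetrahedral direction off the N-CA-C frame
    double n1[3] = {N[3 * i] - CA[3 * i], N[3 * i + 1] - CA[3 * i + 1],
                    N[3 * i + 2] - CA[3 * i + 2]};
    double n2[3] = {C[3 * i] - CA[3 * i], C[3 * i + 1] - CA[3 * i + 1],
                    C[3 * i + 2] - CA[3 * i + 2]};
    unit3(n1); unit3(n2);
    double u[3] = {n1[0] + n2[0], n1[1] + n2[1], n1[2] + n2[2]};
    unit3(u);
    double v[3];
    cross3(n1, n2, v);
    unit3(v);
    double cg = std::cos(CB_GAMMA * DEG), sg = std::sin(CB_GAMMA * DEG);
    int r = 5 * i;
    for (int k = 0; k < 3; ++k) {
      out(r + 0, k) = N[3 * i + k];
      out(r + 1, k) = CA[3 * i + k];
      out(r + 2, k) = C[3 * i + k];
      out(r + 3, k) = O[k];
      out(r + 4, k) = CA[3 * i + k] + cen_r[i] * (-cg * u[k] + sg * v[k]);
    }
  }
  return out;
}

static inline double dist3(const NumericMatrix &X, int i, int j) {
  double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1), dz = X(i, 2) - X(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Surrogate coarse-grained energy terms from coordinates in the
// cpp_build_backbone layout. ss codes: 0 = H, 1 = E, 2 = L.
// Returns (steric, vdw_attract, rg, hbond, ss_pair).
// [[Rcpp::export]]
NumericVector cpp_energy_terms(NumericMatrix coords, NumericVector phi,
                               NumericVector psi, IntegerVector ss) {
  int L = ss.size();
  if (coords.nrow() != 5 * L)
    stop("coordinate matrix does not match sequence length");
  const double r_clash = 4.0;
  double steric = 0.0;
  for (int i = 0; i < 5 * L; ++i) {
    int ri = i / 5;
    for (int j = i + 1; j < 5 * L; ++j) {
      int rj = j / 5;
      if (rj - ri < 2) continue;
      double d = dist3(coords, i, j);
      if (d < r_clash) steric += (r_clash - d) * (r_clash - d);
    }
  }
  double vdw = 0.0;
  for (int i = 0; i < L; ++i)
    for (int j = i + 1; j < L; ++j) {
      double d = dist3(coords, 5 * i + 4, 5 * j + 4);
      if (d >= 4.5 && d <= 6.5) vdw -= 1.0;
    }
  // radius of gyration over CA + CEN
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < L; ++i) {
    cx += coords(5 * i + 1, 0) + coords(5 * i + 4, 0);
    cy += coords(5 * i + 1, 1) + coords(5 * i + 4, 1);
    cz += coords(5 * i + 1, 2) + coords(5 * i + 4, 2);
  }
  cx /= 2 * L; cy /= 2 * L; cz /= 2 * L;
  double sq = 0.0;
  for (int i = 0; i < L; ++i) {
    for (int a = 1; a < 5; a += 3) {  // rows CA (1) and CEN (4)
      double dx = coords(5 * i + a, 0) - cx, dy = coords(5 * i + a, 1) - cy,
             dz = coords(5 * i + a, 2) - cz;
      sq += dx * dx + dy * dy + dz * dz;
    }
  }
  double rg = std::sqrt(sq / (2 * L));
  double hb = 0.0;
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j) {
      if (std::abs(i - j) < 3) continue;
      double d = dist3(coords, 5 * i + 3, 5 * j + 0);  // O_i .. N_j
      if (d >= 2.6 && d <= 3.4) hb -= 1.0;
    }
  double mism = 0.0;
  for (int i = 0; i < L; ++i) {
    int obs = 2;  // loop
    if (phi[i] >= -100 && phi[i] <= -30 && psi[i] >= -80 && psi[i] <= -5)
      obs = 0;
    else if (phi[i] >= -180 && phi[i] <= -60 && psi[i] >= 60 && psi[i] <= 180)
      obs = 1;
    if (obs != ss[i]) mism += 1.0;
  }
  return NumericVector::create(steric, vdw, rg, hb, mism);
}

// Fused build + score: weighted sum of the five terms for a dihedral genome.
// The single call used inside Monte Carlo / refinement loops.
// [[Rcpp::export]]
double cpp_score_conformation(NumericVector omega, NumericVector phi,
                              NumericVector psi, NumericVector cen_r,
                              IntegerVector ss, NumericVector w) {
  NumericMatrix coords = cpp_build_backbone(omega, phi, psi, cen_r);
  NumericVector t = cpp_energy_terms(coords, phi, psi, ss);
  double s = 0.0;
  for (int k = 0; k < 5; ++k) s += t[k] * w[k];
  return s;
}
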