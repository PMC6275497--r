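// Coarse-grained force field and constrained Langevin dynamics.
//
// Units: kJ/mol, nm, ps, K.  kB = 0.0083145 kJ/mol/K.
// Tether force is reported in pN (1 kJ/mol/nm = 1.66054 pN), positive when
// the chain end is pulled beyond the rest length x0.
//
// All randomness goes through R's RNG so trajectories are bit-reproducible
// under set.seed().

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double KB = 0.0083145;
static const double PN_PER_KJMOLNM = 1.66054;

struct Vec3 {
  double x, y, z;
};

static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

// Packed system prepared by R (see .pack_system in R/system.R).
struct System {
  int n;
  std::vector<int> mobile_idx;        // 0-based indices of mobile beads
  std::vector<bool> is_mobile;
  std::vector<double> mass;
  std::vector<int> kind;              // 0-based kind index
  int nkind;
  // bonds
  std::vector<int> bi, bj;
  std::vector<double> br0, bk;
  std::vector<bool> bcons;
  // angles
  std::vector<int> ai, aj, ak;
  std::vector<double> atheta0, akf;
  // dihedrals
  std::vector<int> di, dj, dk, dl;
  std::vector<double> dphi0, dkf;
  // native contacts
  std::vector<int> ci, cj;
  std::vector<double> cr0, ceps;
  // pairwise repulsion tables (kind x kind), absolute coefficients
  std::vector<double> pA, pB, pC, pEps;
  // hydrophobic LJ 12-6 pairs
  std::vector<int> hi, hj;
  std::vector<double> hsig, heps;
  // tether (optional): harmonic, unconstrained, force-reporting
  bool has_tether;
  int ti, tj;                         // anchor, chain end
  double tks, tx0;
  // umbrella bias on Q
  double k_umb, q0;
  // Q switching
  double qgamma, qlambda;
  double cutoff;
  std::unordered_set<long long> excl; // nonbonded exclusions, key i*n+j (i<j)
  std::vector<std::pair<int, int>> mm_pairs; // non-excluded mobile-mobile pairs
  std::vector<int> cons;   // indices of constrained bonds, chain order
  bool tri;                // constrained bonds form a simple chain
  std::vector<double> w;   // inverse masses (0 for immobile beads)
};

static inline long long pkey(const System &S, int i, int j) {
  if (i > j) std::swap(i, j);
  return (long long)i * (long long)S.n + (long long)j;
}

static System unpack(const List &sys) {
  System S;
  NumericMatrix pos = sys["pos"];
  S.n = pos.nrow();
  LogicalVector mob = sys["mobile"];
  S.is_mobile.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.is_mobile[i] = mob[i];
    if (mob[i]) S.mobile_idx.push_back(i);
  }
  NumericVector mass = sys["mass"];
  S.mass.assign(mass.begin(), mass.end());
  IntegerVector kind = sys["kind"];
  S.kind.resize(S.n);
  for (int i = 0; i < S.n; ++i) S.kind[i] = kind[i] - 1;
  S.nkind = as<int>(sys["nkind"]);

  IntegerMatrix bonds = sys["bonds"];
  NumericVector br0 = sys["bond_r0"], bk = sys["bond_k"];
  LogicalVector bc = sys["bond_constrained"];
  for (int m = 0; m < bonds.nrow(); ++m) {
    S.bi.push_back(bonds(m, 0) - 1);
    S.bj.push_back(bonds(m, 1) - 1);
    S.br0.push_back(br0[m]);
    S.bk.push_back(bk[m]);
    S.bcons.push_back(bc[m]);
  }
  IntegerMatrix ang = sys["angles"];
  NumericVector at0 = sys["angle_theta0"], akf = sys["angle_k"];
  for (int m = 0; m < ang.nrow(); ++m) {
    S.ai.push_back(ang(m, 0) - 1);
    S.aj.push_back(ang(m, 1) - 1);
    S.ak.push_back(ang(m, 2) - 1);
    S.atheta0.push_back(at0[m]);
    S.akf.push_back(akf[m]);
  }
  IntegerMatrix dih = sys["dihedrals"];
  NumericVector dp0 = sys["dihedral_phi0"], dkf = sys["dihedral_k"];
  for (int m = 0; m < dih.nrow(); ++m) {
    S.di.push_back(dih(m, 0) - 1);
    S.dj.push_back(dih(m, 1) - 1);
    S.dk.push_back(dih(m, 2) - 1);
    S.dl.push_back(dih(m, 3) - 1);
    S.dphi0.push_back(dp0[m]);
    S.dkf.push_back(dkf[m]);
  }
  IntegerMatrix con = sys["contacts"];
  NumericVector cr0 = sys["contact_r0"], ceps = sys["contact_eps"];
  for (int m = 0; m < con.nrow(); ++m) {
    S.ci.push_back(con(m, 0) - 1);
    S.cj.push_back(con(m, 1) - 1);
    S.cr0.push_back(cr0[m]);
    S.ceps.push_back(ceps[m]);
  }
  NumericMatrix pA = sys["pair_A"], pB = sys["pair_B"], pC = sys["pair_C"],
                pE = sys["pair_eps"];
  int K = S.nkind;
  S.pA.resize(K * K);
  S.pB.resize(K * K);
  S.pC.resize(K * K);
  S.pEps.resize(K * K);
  for (int a = 0; a < K; ++a)
    for (int b = 0; b < K; ++b) {
      S.pA[a * K + b] = pA(a, b);
      S.pB[a * K + b] = pB(a, b);
      S.pC[a * K + b] = pC(a, b);
      S.pEps[a * K + b] = pE(a, b);
    }
  IntegerMatrix hp = sys["hp_pairs"];
  NumericVector hs = sys["hp_sigma"], he = sys["hp_eps"];
  for (int m = 0; m < hp.nrow(); ++m) {
    S.hi.push_back(hp(m, 0) - 1);
    S.hj.push_back(hp(m, 1) - 1);
    S.hsig.push_back(hs[m]);
    S.heps.push_back(he[m]);
  }
  S.has_tether = as<bool>(sys["has_tether"]);
  if (S.has_tether) {
    S.ti = as<int>(sys["tether_i"]) - 1;
    S.tj = as<int>(sys["tether_j"]) - 1;
    S.tks = as<double>(sys["tether_ks"]);
    S.tx0 = as<double>(sys["tether_x0"]);
  } else {
    S.ti = S.tj = -1;
    S.tks = S.tx0 = 0.0;
  }
  S.k_umb = as<double>(sys["k_umb"]);
  S.q0 = as<double>(sys["q0"]);
  S.qgamma = as<double>(sys["q_gamma"]);
  S.qlambda = as<double>(sys["q_lambda"]);
  S.cutoff = as<double>(sys["cutoff"]);
  IntegerMatrix ex = sys["exclusions"];
  for (int m = 0; m < ex.nrow(); ++m)
    S.excl.insert(pkey(S, ex(m, 0) - 1, ex(m, 1) - 1));
  int nm = (int)S.mobile_idx.size();
  for (int a = 0; a < nm; ++a) {
    int i = S.mobile_idx[a];
    for (int b = a + 1; b < nm; ++b) {
      int j = S.mobile_idx[b];
      if (S.pEps[S.kind[i] * S.nkind + S.kind[j]] == 0.0) continue;
      if (S.excl.count(pkey(S, i, j))) continue;
      S.mm_pairs.emplace_back(i, j);
    }
  }
  S.w.resize(S.n);
  for (int i = 0; i < S.n; ++i)
    S.w[i] = S.is_mobile[i] ? 1.0 / S.mass[i] : 0.0;
  for (size_t m = 0; m < S.bi.size(); ++m)
    if (S.bcons[m]) S.cons.push_back((int)m);
  // tridiagonal structure: consecutive constraints share exactly one bead
  // (jk of constraint k equals ik of constraint k+1), no other sharing
  S.tri = true;
  for (size_t c = 0; c + 1 < S.cons.size(); ++c) {
    if (S.bj[S.cons[c]] != S.bi[S.cons[c + 1]]) { S.tri = false; break; }
  }
  if (S.tri) {
    std::vector<int> uses(S.n, 0);
    for (int m : S.cons) { uses[S.bi[m]]++; uses[S.bj[m]]++; }
    for (int i = 0; i < S.n; ++i)
      if (uses[i] > 2) { S.tri = false; break; }
  }
  return S;
}

// Box-Muller normal variates driven by R's uniform stream.
static double gauss_cache = 0.0;
static bool gauss_have = false;
static inline double rnorm_fast() {
  if (gauss_have) {
    gauss_have = false;
    return gauss_cache;
  }
  double u1 = std::max(unif_rand(), 1e-300), u2 = unif_rand();
  double r = std::sqrt(-2.0 * std::log(u1));
  gauss_cache = r * std::sin(2.0 * M_PI * u2);
  gauss_have = true;
  return r * std::cos(2.0 * M_PI * u2);
}

struct Energies {
  double bond = 0, angle = 0, dihedral = 0, contact = 0, repulsion = 0,
         hp = 0, tether = 0, bias = 0;
  double Q = NA_REAL, x = NA_REAL, F_pN = NA_REAL;
  double Fv[3] = {NA_REAL, NA_REAL, NA_REAL}; // force vector, pN
  double total() const {
    return bond + angle + dihedral + contact + repulsion + hp + tether + bias;
  }
};

// Repulsive pair: V = eps * (A/r^12 - B/r^10 + C/r^6), truncated at cutoff.
static inline void pair_repulsion(const System &S, const std::vector<Vec3> &x,
                                  int i, int j, Energies &E,
                                  std::vector<Vec3> &f) {
  int K = S.nkind;
  int idx = S.kind[i] * K + S.kind[j];
  double eps = S.pEps[idx];
  if (eps == 0.0) return;
  Vec3 d = sub(x[i], x[j]);
  double r2 = dot(d, d);
  if (r2 > S.cutoff * S.cutoff) return;
  if (r2 < 1e-12) r2 = 1e-12;
  double inv2 = 1.0 / r2;
  double i6 = inv2 * inv2 * inv2;
  double i10 = i6 * inv2 * inv2;
  double i12 = i10 * inv2;
  double A = S.pA[idx], B = S.pB[idx], C = S.pC[idx];
  E.repulsion += eps * (A * i12 - B * i10 + C * i6);
  // fac = -(dV/dr)/r, expressible in r^2 only
  double fac = eps * (12.0 * A * i12 - 10.0 * B * i10 + 6.0 * C * i6) * inv2;
  // soft-core clamp deep inside the core: the cap engages only where the
  // pair energy is already tens of kT (Boltzmann-forbidden), and keeps
  // hard-collision oscillation frequencies integrable at the default step
  if (fac * fac * r2 > 4e6) fac = 2e3 / std::sqrt(r2);
  f[i].x += fac * d.x; f[i].y += fac * d.y; f[i].z += fac * d.z;
  f[j].x -= fac * d.x; f[j].y -= fac * d.y; f[j].z -= fac * d.z;
}

// Full force/energy evaluation. nbrs: per-mobile-bead static neighbour list
// (null => evaluate all static beads directly).
static void eval_forces(const System &S, const std::vector<Vec3> &x,
                        Energies &E, std::vector<Vec3> &f,
                        const std::vector<std::vector<int>> *nbrs) {
  int n = S.n;
  for (int i = 0; i < n; ++i) f[i] = {0, 0, 0};
  E = Energies();

  // unconstrained bonds (harmonic)
  for (size_t m = 0; m < S.bi.size(); ++m) {
    if (S.bcons[m]) continue;
    Vec3 d = sub(x[S.bi[m]], x[S.bj[m]]);
    double r = norm(d);
    double dr = r - S.br0[m];
    E.bond += 0.5 * S.bk[m] * dr * dr;
    double fac = -S.bk[m] * dr / std::max(r, 1e-12);
    f[S.bi[m]].x += fac * d.x; f[S.bi[m]].y += fac * d.y; f[S.bi[m]].z += fac * d.z;
    f[S.bj[m]].x -= fac * d.x; f[S.bj[m]].y -= fac * d.y; f[S.bj[m]].z -= fac * d.z;
  }

  // angles: V = ka/2 (theta - theta0)^2.  |grad theta| is bounded (the
  // sin theta in the numerator cancels the 1/sin theta), so only exact
  // collinearity needs a numerical floor.
  for (size_t m = 0; m < S.ai.size(); ++m) {
    const Vec3 &ri = x[S.ai[m]], &rj = x[S.aj[m]], &rk = x[S.ak[m]];
    Vec3 u = sub(ri, rj), v = sub(rk, rj);
    double nu = norm(u), nv = norm(v);
    double ct = dot(u, v) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double theta = std::acos(ct);
    double st = std::sqrt(std::max(1.0 - ct * ct, 1e-12));
    double dVdt = S.akf[m] * (theta - S.atheta0[m]);
    E.angle += 0.5 * S.akf[m] * (theta - S.atheta0[m]) * (theta - S.atheta0[m]);
    // dtheta/dri = -(1/st) * (v/(nu*nv) - ct*u/nu^2)
    Vec3 gi = {-(v.x / (nu * nv) - ct * u.x / (nu * nu)) / st,
               -(v.y / (nu * nv) - ct * u.y / (nu * nu)) / st,
               -(v.z / (nu * nv) - ct * u.z / (nu * nu)) / st};
    Vec3 gk = {-(u.x / (nu * nv) - ct * v.x / (nv * nv)) / st,
               -(u.y / (nu * nv) - ct * v.y / (nv * nv)) / st,
               -(u.z / (nu * nv) - ct * v.z / (nv * nv)) / st};
    f[S.ai[m]].x -= dVdt * gi.x; f[S.ai[m]].y -= dVdt * gi.y; f[S.ai[m]].z -= dVdt * gi.z;
    f[S.ak[m]].x -= dVdt * gk.x; f[S.ak[m]].y -= dVdt * gk.y; f[S.ak[m]].z -= dVdt * gk.z;
    f[S.aj[m]].x += dVdt * (gi.x + gk.x);
    f[S.aj[m]].y += dVdt * (gi.y + gk.y);
    f[S.aj[m]].z += dVdt * (gi.z + gk.z);
  }

  // dihedrals: V = k [1 - cos(phi - phi0)] + k/2 [1 - cos 3(phi - phi0)],
  // multiplied by smooth masks g(sin^2 theta) of the two bending angles.
  // The torsion is undefined at collinear bends and its torque diverges
  // there; the mask switches the term off conservatively (energy and
  // gradient together) below sin(theta) ~ 0.14.
  for (size_t m = 0; m < S.di.size(); ++m) {
    const Vec3 &ri = x[S.di[m]], &rj = x[S.dj[m]], &rk = x[S.dk[m]],
               &rl = x[S.dl[m]];
    Vec3 b1 = sub(rj, ri), b2 = sub(rk, rj), b3 = sub(rl, rk);
    Vec3 n1 = cross(b1, b2), n2 = cross(b2, b3);
    double B1 = std::max(dot(b1, b1), 1e-12);
    double B2 = std::max(dot(b2, b2), 1e-12);
    double B3 = std::max(dot(b3, b3), 1e-12);
    double n1sq = dot(n1, n1), n2sq = dot(n2, n2);
    double u1 = n1sq / (B1 * B2), u2 = n2sq / (B3 * B2);
    const double uc = 0.02; // mask fully on above sin^2(theta) = 0.02
    double dg1 = 0.0, dg2 = 0.0, g1 = 1.0, g2 = 1.0;
    if (u1 < uc) {
      double t = u1 / uc;
      g1 = t * t * (3.0 - 2.0 * t);
      dg1 = (6.0 * t - 6.0 * t * t) / uc;
    }
    if (u2 < uc) {
      double t = u2 / uc;
      g2 = t * t * (3.0 - 2.0 * t);
      dg2 = (6.0 * t - 6.0 * t * t) / uc;
    }
    if (g1 == 0.0 || g2 == 0.0) continue;
    double nb2 = std::sqrt(B2);
    double phi = std::atan2(dot(cross(n1, n2), b2) / nb2, dot(n1, n2));
    double dphi = phi - S.dphi0[m];
    double k = S.dkf[m];
    double T = (1.0 - std::cos(dphi)) + 0.5 * (1.0 - std::cos(3.0 * dphi));
    double dT = std::sin(dphi) + 1.5 * std::sin(3.0 * dphi);
    E.dihedral += k * T * g1 * g2;
    // torque part, scaled by the masks
    double pref = k * dT * g1 * g2;
    double n1s = std::max(n1sq, 1e-12), n2s = std::max(n2sq, 1e-12);
    Vec3 Fi = {pref * nb2 / n1s * n1.x, pref * nb2 / n1s * n1.y,
               pref * nb2 / n1s * n1.z};
    Vec3 Fl = {-pref * nb2 / n2s * n2.x, -pref * nb2 / n2s * n2.y,
               -pref * nb2 / n2s * n2.z};
    double t1 = dot(b1, b2) / B2;
    double t3 = dot(b3, b2) / B2;
    Vec3 Fj = {-Fi.x - t1 * Fi.x + t3 * Fl.x, -Fi.y - t1 * Fi.y + t3 * Fl.y,
               -Fi.z - t1 * Fi.z + t3 * Fl.z};
    Vec3 Fk = {-Fl.x + t1 * Fi.x - t3 * Fl.x, -Fl.y + t1 * Fi.y - t3 * Fl.y,
               -Fl.z + t1 * Fi.z - t3 * Fl.z};
    f[S.di[m]].x += Fi.x; f[S.di[m]].y += Fi.y; f[S.di[m]].z += Fi.z;
    f[S.dj[m]].x += Fj.x; f[S.dj[m]].y += Fj.y; f[S.dj[m]].z += Fj.z;
    f[S.dk[m]].x += Fk.x; f[S.dk[m]].y += Fk.y; f[S.dk[m]].z += Fk.z;
    f[S.dl[m]].x += Fl.x; f[S.dl[m]].y += Fl.y; f[S.dl[m]].z += Fl.z;
    // mask-gradient part: forces from -k T d(g1 g2)
    if (dg1 != 0.0 || dg2 != 0.0) {
      double c1m = -k * T * g2 * dg1; // multiplies grad u1
      double c2m = -k * T * g1 * dg2; // multiplies grad u2
      // grad_b1 u1 = 2 (b2 x n1)/(B1 B2) - 2 u1 b1 / B1, etc.
      Vec3 q1 = cross(b2, n1), q2 = cross(n1, b1);
      Vec3 du1_b1 = {2.0 * q1.x / (B1 * B2) - 2.0 * u1 * b1.x / B1,
                     2.0 * q1.y / (B1 * B2) - 2.0 * u1 * b1.y / B1,
                     2.0 * q1.z / (B1 * B2) - 2.0 * u1 * b1.z / B1};
      Vec3 du1_b2 = {2.0 * q2.x / (B1 * B2) - 2.0 * u1 * b2.x / B2,
                     2.0 * q2.y / (B1 * B2) - 2.0 * u1 * b2.y / B2,
                     2.0 * q2.z / (B1 * B2) - 2.0 * u1 * b2.z / B2};
      Vec3 q3 = cross(b3, n2), q4 = cross(n2, b2);
      Vec3 du2_b2 = {2.0 * q3.x / (B3 * B2) - 2.0 * u2 * b2.x / B2,
                     2.0 * q3.y / (B3 * B2) - 2.0 * u2 * b2.y / B2,
                     2.0 * q3.z / (B3 * B2) - 2.0 * u2 * b2.z / B2};
      Vec3 du2_b3 = {2.0 * q4.x / (B3 * B2) - 2.0 * u2 * b3.x / B3,
                     2.0 * q4.y / (B3 * B2) - 2.0 * u2 * b3.y / B3,
                     2.0 * q4.z / (B3 * B2) - 2.0 * u2 * b3.z / B3};
      // map b-gradients to atoms (b1 = rj-ri, b2 = rk-rj, b3 = rl-rk);
      // the c coefficients already carry the force sign
      f[S.di[m]].x -= c1m * du1_b1.x;
      f[S.di[m]].y -= c1m * du1_b1.y;
      f[S.di[m]].z -= c1m * du1_b1.z;
      f[S.dj[m]].x += c1m * (du1_b1.x - du1_b2.x) - c2m * du2_b2.x;
      f[S.dj[m]].y += c1m * (du1_b1.y - du1_b2.y) - c2m * du2_b2.y;
      f[S.dj[m]].z += c1m * (du1_b1.z - du1_b2.z) - c2m * du2_b2.z;
      f[S.dk[m]].x += c1m * du1_b2.x + c2m * (du2_b2.x - du2_b3.x);
      f[S.dk[m]].y += c1m * du1_b2.y + c2m * (du2_b2.y - du2_b3.y);
      f[S.dk[m]].z += c1m * du1_b2.z + c2m * (du2_b2.z - du2_b3.z);
      f[S.dl[m]].x += c2m * du2_b3.x;
      f[S.dl[m]].y += c2m * du2_b3.y;
      f[S.dl[m]].z += c2m * du2_b3.z;
    }
  }

  // native contacts, 12-10 Go well + smooth Q and its bias in one pass
  int ncon = (int)S.ci.size();
  double Q = 0.0;
  static std::vector<double> svals, rvals;
  svals.resize(ncon);
  rvals.resize(ncon);
  for (int m = 0; m < ncon; ++m) {
    Vec3 d = sub(x[S.ci[m]], x[S.cj[m]]);
    double r = std::max(norm(d), 1e-9);
    double rr = S.cr0[m] / r;
    double rr2 = rr * rr;
    double rr10 = rr2 * rr2 * rr2 * rr2 * rr2;
    double rr12 = rr10 * rr2;
    E.contact += S.ceps[m] * (5.0 * rr12 - 6.0 * rr10);
    double dVdr = S.ceps[m] * (-60.0 * rr12 + 60.0 * rr10) / r;
    double fac = -dVdr / r;
    f[S.ci[m]].x += fac * d.x; f[S.ci[m]].y += fac * d.y; f[S.ci[m]].z += fac * d.z;
    f[S.cj[m]].x -= fac * d.x; f[S.cj[m]].y -= fac * d.y; f[S.cj[m]].z -= fac * d.z;
    double g = S.qgamma * (r - S.qlambda * S.cr0[m]);
    g = std::max(-40.0, std::min(40.0, g));
    double s = 1.0 / (1.0 + std::exp(g));
    svals[m] = s;
    rvals[m] = r;
    Q += s;
  }
  if (ncon > 0) {
    Q /= ncon;
    E.Q = Q;
    if (S.k_umb > 0.0) {
      double dQ = Q - S.q0;
      E.bias = 0.5 * S.k_umb * dQ * dQ;
      for (int m = 0; m < ncon; ++m) {
        double s = svals[m];
        double dsdr = -S.qgamma * s * (1.0 - s);
        double dVdr = S.k_umb * dQ * dsdr / ncon;
        Vec3 d = sub(x[S.ci[m]], x[S.cj[m]]);
        double fac = -dVdr / rvals[m];
        f[S.ci[m]].x += fac * d.x; f[S.ci[m]].y += fac * d.y; f[S.ci[m]].z += fac * d.z;
        f[S.cj[m]].x -= fac * d.x; f[S.cj[m]].y -= fac * d.y; f[S.cj[m]].z -= fac * d.z;
      }
    }
  }

  // hydrophobic LJ 12-6 pairs
  for (size_t m = 0; m < S.hi.size(); ++m) {
    Vec3 d = sub(x[S.hi[m]], x[S.hj[m]]);
    double r = std::max(norm(d), 1e-9);
    double sr = S.hsig[m] / r;
    double sr6 = sr * sr * sr;
    sr6 = sr6 * sr6;
    double sr12 = sr6 * sr6;
    E.hp += 4.0 * S.heps[m] * (sr12 - sr6);
    double dVdr = 4.0 * S.heps[m] * (-12.0 * sr12 + 6.0 * sr6) / r;
    double fac = -dVdr / r;
    f[S.hi[m]].x += fac * d.x; f[S.hi[m]].y += fac * d.y; f[S.hi[m]].z += fac * d.z;
    f[S.hj[m]].x -= fac * d.x; f[S.hj[m]].y -= fac * d.y; f[S.hj[m]].z -= fac * d.z;
  }

  // tether
  if (S.has_tether) {
    Vec3 d = sub(x[S.tj], x[S.ti]);
    double r = std::max(norm(d), 1e-9);
    double dr = r - S.tx0;
    E.tether = 0.5 * S.tks * dr * dr;
    E.x = r;
    E.F_pN = S.tks * dr * PN_PER_KJMOLNM; // > 0 when pulling (x > x0)
    // force vector along the tether (anchor -> chain end): its time
    // average measures chain tension without the radial shell-entropy bias
    E.Fv[0] = E.F_pN * d.x / r;
    E.Fv[1] = E.F_pN * d.y / r;
    E.Fv[2] = E.F_pN * d.z / r;
    double fac = -S.tks * dr / r;
    f[S.tj].x += fac * d.x; f[S.tj].y += fac * d.y; f[S.tj].z += fac * d.z;
    f[S.ti].x -= fac * d.x; f[S.ti].y -= fac * d.y; f[S.ti].z -= fac * d.z;
  }

  // nonbonded repulsion: mobile-mobile (precomputed pair list)
  for (const auto &pr : S.mm_pairs) pair_repulsion(S, x, pr.first, pr.second, E, f);
  // mobile-static
  int nm = (int)S.mobile_idx.size();
  if (nbrs) {
    for (int a = 0; a < nm; ++a) {
      int i = S.mobile_idx[a];
      for (int j : (*nbrs)[a]) pair_repulsion(S, x, i, j, E, f);
    }
  } else {
    for (int a = 0; a < nm; ++a) {
      int i = S.mobile_idx[a];
      for (int j = 0; j < n; ++j) {
        if (S.is_mobile[j]) continue;
        if (S.excl.count(pkey(S, i, j))) continue;
        pair_repulsion(S, x, i, j, E, f);
      }
    }
  }
}

static void build_nbrs(const System &S, const std::vector<Vec3> &x,
                       double skin, std::vector<std::vector<int>> &nbrs) {
  int nm = (int)S.mobile_idx.size();
  nbrs.assign(nm, {});
  double rc = S.cutoff + skin;
  double rc2 = rc * rc;
  for (int a = 0; a < nm; ++a) {
    int i = S.mobile_idx[a];
    for (int j = 0; j < S.n; ++j) {
      if (S.is_mobile[j]) continue;
      if (S.excl.count(pkey(S, i, j))) continue;
      Vec3 d = sub(x[i], x[j]);
      if (dot(d, d) < rc2) nbrs[a].push_back(j);
    }
  }
}

// Thomas solve of a tridiagonal system (in place on rhs).
static void thomas(std::vector<double> &a, std::vector<double> &b,
                   std::vector<double> &c, std::vector<double> &d) {
  int n = (int)b.size();
  for (int i = 1; i < n; ++i) {
    double mfac = a[i] / b[i - 1];
    b[i] -= mfac * c[i - 1];
    d[i] -= mfac * d[i - 1];
  }
  d[n - 1] /= b[n - 1];
  for (int i = n - 2; i >= 0; --i) d[i] = (d[i] - c[i] * d[i + 1]) / b[i];
}

// Newton iteration with direct tridiagonal solves for a chain of bond
// constraints (M-SHAKE / RATTLE position stage).  Corrections act along
// the constraint gradients evaluated at the reference configuration
// (pre-drift positions), as RATTLE requires for symplectic constrained
// dynamics; passing x itself as reference gives plain M-SHAKE.
static int shake_chain(const System &S, std::vector<Vec3> &x,
                       const std::vector<Vec3> &xref, double tol,
                       int max_iter) {
  int m = (int)S.cons.size();
  if (m == 0) return 0;
  std::vector<double> lo(m), di(m), up(m), rhs(m);
  std::vector<Vec3> r(m), rr(m);
  for (int k = 0; k < m; ++k) {
    int mm = S.cons[k];
    rr[k] = sub(xref[S.bi[mm]], xref[S.bj[mm]]);
  }
  int it;
  for (it = 0; it < max_iter; ++it) {
    double worst = 0.0;
    for (int k = 0; k < m; ++k) {
      int mm = S.cons[k];
      r[k] = sub(x[S.bi[mm]], x[S.bj[mm]]);
      double rn = norm(r[k]);
      double viol = std::fabs(rn - S.br0[mm]);
      if (viol > worst) worst = viol;
      rhs[k] = -(dot(r[k], r[k]) - S.br0[mm] * S.br0[mm]);
    }
    if (worst < tol) break;
    for (int k = 0; k < m; ++k) {
      int mm = S.cons[k];
      di[k] = 4.0 * (S.w[S.bi[mm]] + S.w[S.bj[mm]]) * dot(r[k], rr[k]);
      if (k > 0) {
        lo[k] = -4.0 * S.w[S.bi[mm]] * dot(r[k], rr[k - 1]); // shared bead
      } else lo[k] = 0.0;
      if (k + 1 < m) {
        up[k] = -4.0 * S.w[S.bj[mm]] * dot(r[k], rr[k + 1]);
      } else up[k] = 0.0;
    }
    thomas(lo, di, up, rhs);
    // damp the Newton step when far from the constraint manifold
    double dmax = 0.0;
    for (int k = 0; k < m; ++k) {
      int mm = S.cons[k];
      double wmax = std::max(S.w[S.bi[mm]], S.w[S.bj[mm]]);
      double step = std::fabs(2.0 * rhs[k]) * wmax * norm(rr[k]);
      if (step > dmax) dmax = step;
    }
    double damp = (dmax > 0.1) ? 0.1 / dmax : 1.0;
    for (int k = 0; k < m; ++k) {
      int mm = S.cons[k];
      double l2 = 2.0 * damp * rhs[k];
      x[S.bi[mm]].x += S.w[S.bi[mm]] * l2 * rr[k].x;
      x[S.bi[mm]].y += S.w[S.bi[mm]] * l2 * rr[k].y;
      x[S.bi[mm]].z += S.w[S.bi[mm]] * l2 * rr[k].z;
      x[S.bj[mm]].x -= S.w[S.bj[mm]] * l2 * rr[k].x;
      x[S.bj[mm]].y -= S.w[S.bj[mm]] * l2 * rr[k].y;
      x[S.bj[mm]].z -= S.w[S.bj[mm]] * l2 * rr[k].z;
    }
  }
  return it;
}

// Direct velocity constraint projection for a chain (exact, one solve).
static void rattle_chain(const System &S, const std::vector<Vec3> &x,
                         std::vector<Vec3> &v) {
  int m = (int)S.cons.size();
  if (m == 0) return;
  std::vector<double> lo(m), di(m), up(m), rhs(m);
  std::vector<Vec3> r(m);
  for (int k = 0; k < m; ++k) {
    int mm = S.cons[k];
    r[k] = sub(x[S.bi[mm]], x[S.bj[mm]]);
    rhs[k] = -2.0 * dot(r[k], sub(v[S.bi[mm]], v[S.bj[mm]]));
    di[k] = 4.0 * (S.w[S.bi[mm]] + S.w[S.bj[mm]]) * dot(r[k], r[k]);
  }
  for (int k = 0; k < m; ++k) {
    int mm = S.cons[k];
    lo[k] = (k > 0) ? -4.0 * S.w[S.bi[mm]] * dot(r[k], r[k - 1]) : 0.0;
    up[k] = (k + 1 < m) ? -4.0 * S.w[S.bj[mm]] * dot(r[k], r[k + 1]) : 0.0;
  }
  thomas(lo, di, up, rhs);
  for (int k = 0; k < m; ++k) {
    int mm = S.cons[k];
    double l2 = 2.0 * rhs[k];
    v[S.bi[mm]].x += S.w[S.bi[mm]] * l2 * r[k].x;
    v[S.bi[mm]].y += S.w[S.bi[mm]] * l2 * r[k].y;
    v[S.bi[mm]].z += S.w[S.bi[mm]] * l2 * r[k].z;
    v[S.bj[mm]].x -= S.w[S.bj[mm]] * l2 * r[k].x;
    v[S.bj[mm]].y -= S.w[S.bj[mm]] * l2 * r[k].y;
    v[S.bj[mm]].z -= S.w[S.bj[mm]] * l2 * r[k].z;
  }
}

// Iterative fallbacks for non-chain constraint topologies.
static int shake_iter(const System &S, std::vector<Vec3> &x, double tol,
                      int max_iter) {
  int it;
  for (it = 0; it < max_iter; ++it) {
    double worst = 0.0;
    for (size_t m = 0; m < S.bi.size(); ++m) {
      if (!S.bcons[m]) continue;
      int i = S.bi[m], j = S.bj[m];
      Vec3 d = sub(x[i], x[j]);
      double r = norm(d);
      double diff = r - S.br0[m];
      if (std::fabs(diff) > worst) worst = std::fabs(diff);
      double wi = S.w[i], wj = S.w[j];
      double wsum = wi + wj;
      if (wsum == 0.0) continue;
      double corr = diff / (r * wsum);
      x[i].x -= wi * corr * d.x; x[i].y -= wi * corr * d.y; x[i].z -= wi * corr * d.z;
      x[j].x += wj * corr * d.x; x[j].y += wj * corr * d.y; x[j].z += wj * corr * d.z;
    }
    if (worst < tol) break;
  }
  return it;
}

static void rattle_iter(const System &S, const std::vector<Vec3> &x,
                        std::vector<Vec3> &v, double tol, int max_iter) {
  for (int it = 0; it < max_iter; ++it) {
    double worst = 0.0;
    for (size_t m = 0; m < S.bi.size(); ++m) {
      if (!S.bcons[m]) continue;
      int i = S.bi[m], j = S.bj[m];
      Vec3 d = sub(x[i], x[j]);
      double r2 = dot(d, d);
      Vec3 dv = sub(v[i], v[j]);
      double rv = dot(d, dv);
      if (std::fabs(rv) > worst) worst = std::fabs(rv);
      double wi = S.w[i], wj = S.w[j];
      double wsum = wi + wj;
      if (wsum == 0.0) continue;
      double g = rv / (r2 * wsum);
      v[i].x -= wi * g * d.x; v[i].y -= wi * g * d.y; v[i].z -= wi * g * d.z;
      v[j].x += wj * g * d.x; v[j].y += wj * g * d.y; v[j].z += wj * g * d.z;
    }
    if (worst < tol) break;
  }
}

static int do_shake(const System &S, std::vector<Vec3> &x,
                    const std::vector<Vec3> &xref, double tol, int max_iter) {
  if (S.tri) return shake_chain(S, x, xref, tol, max_iter);
  return shake_iter(S, x, tol, max_iter);
}

static void do_rattle(const System &S, const std::vector<Vec3> &x,
                      std::vector<Vec3> &v, double tol, int max_iter) {
  if (S.tri) { rattle_chain(S, x, v); return; }
  rattle_iter(S, x, v, tol, max_iter);
}

// [[Rcpp::export]]
List cpp_eval(List sys, NumericMatrix pos) {
  System S = unpack(sys);
  std::vector<Vec3> x(S.n);
  for (int i = 0; i < S.n; ++i) x[i] = {pos(i, 0), pos(i, 1), pos(i, 2)};
  Energies E;
  std::vector<Vec3> f(S.n);
  eval_forces(S, x, E, f, nullptr);
  NumericMatrix fo(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    fo(i, 0) = f[i].x; fo(i, 1) = f[i].y; fo(i, 2) = f[i].z;
  }
  return List::create(
      _["energy"] = E.total(),
      _["terms"] = NumericVector::create(
          _["bond"] = E.bond, _["angle"] = E.angle, _["dihedral"] = E.dihedral,
          _["contact"] = E.contact, _["repulsion"] = E.repulsion,
          _["hp"] = E.hp, _["tether"] = E.tether, _["bias"] = E.bias),
      _["forces"] = fo, _["Q"] = E.Q, _["x"] = E.x, _["F_pN"] = E.F_pN);
}

// Geodesic BAOAB Langevin with RATTLE constraints.  friction = 0 gives the
// NVE (velocity Verlet / RATTLE) limit.  Returns reduced observables per
// frame and, optionally, mobile-bead positions.
// [[Rcpp::export]]
List cpp_run(List sys, NumericMatrix pos, Nullable<NumericMatrix> vel0,
             double dt, double friction, double temperature, int n_steps,
             int stride, int equil, bool record_pos, double shake_tol,
             int nlist_every, double skin) {
  System S = unpack(sys);
  std::vector<Vec3> x(S.n), v(S.n, {0, 0, 0}), f(S.n);
  for (int i = 0; i < S.n; ++i) x[i] = {pos(i, 0), pos(i, 1), pos(i, 2)};

  RNGScope scope;
  gauss_have = false;
  if (vel0.isNotNull()) {
    NumericMatrix vm(vel0);
    for (int i = 0; i < S.n; ++i) v[i] = {vm(i, 0), vm(i, 1), vm(i, 2)};
  } else if (temperature > 0) {
    for (int i : S.mobile_idx) {
      double sd = std::sqrt(KB * temperature / S.mass[i]);
      v[i] = {rnorm_fast() * sd, rnorm_fast() * sd, rnorm_fast() * sd};
    }
    do_rattle(S, x, v, 1e-12, 100);
  }

  do_shake(S, x, x, shake_tol, 1000);
  std::vector<std::vector<int>> nbrs;
  bool use_nl = S.n > (int)S.mobile_idx.size();
  if (use_nl) build_nbrs(S, x, skin, nbrs);
  Energies E;
  eval_forces(S, x, E, f, use_nl ? &nbrs : nullptr);

  double c1 = (friction > 0) ? std::exp(-friction * dt) : 1.0;
  double c2 = (friction > 0) ? std::sqrt(1.0 - c1 * c1) : 0.0;

  int total = equil + n_steps;
  int n_frames = (n_steps > 0) ? (n_steps + stride - 1) / stride : 0;
  NumericVector t_out(n_frames), q_out(n_frames), x_out(n_frames),
      F_out(n_frames), E_out(n_frames), K_out(n_frames),
      Fx_out(n_frames), Fy_out(n_frames), Fz_out(n_frames);
  NumericVector pos_out;
  int nmob = (int)S.mobile_idx.size();
  if (record_pos) pos_out = NumericVector((R_xlen_t)n_frames * nmob * 3);
  int frame = 0;

  std::vector<Vec3> xu(S.n), xdr(S.n);
  for (int step = 0; step < total; ++step) {
    if (use_nl && step % nlist_every == 0 && step > 0) build_nbrs(S, x, skin, nbrs);
    // B half kick + tangent projection
    for (int i : S.mobile_idx) {
      double a = 0.5 * dt / S.mass[i];
      v[i].x += a * f[i].x; v[i].y += a * f[i].y; v[i].z += a * f[i].z;
    }
    do_rattle(S, x, v, 1e-8, 50);
    // A half drift: RATTLE position stage (constraint corrections along
    // pre-drift gradients, impulse folded into v)
    double h = 0.5 * dt;
    xu = x;
    for (int i : S.mobile_idx) {
      x[i].x += h * v[i].x; x[i].y += h * v[i].y; x[i].z += h * v[i].z;
    }
    xdr = x;
    do_shake(S, x, xu, shake_tol, 1000);
    for (int i : S.mobile_idx) {
      v[i].x += (x[i].x - xdr[i].x) / h;
      v[i].y += (x[i].y - xdr[i].y) / h;
      v[i].z += (x[i].z - xdr[i].z) / h;
    }
    // O: Ornstein-Uhlenbeck + tangent projection
    if (friction > 0) {
      for (int i : S.mobile_idx) {
        double sd = std::sqrt(KB * temperature / S.mass[i]);
        v[i].x = c1 * v[i].x + c2 * sd * rnorm_fast();
        v[i].y = c1 * v[i].y + c2 * sd * rnorm_fast();
        v[i].z = c1 * v[i].z + c2 * sd * rnorm_fast();
      }
      do_rattle(S, x, v, 1e-8, 50);
    }
    // A half drift
    xu = x;
    for (int i : S.mobile_idx) {
      x[i].x += h * v[i].x; x[i].y += h * v[i].y; x[i].z += h * v[i].z;
    }
    xdr = x;
    do_shake(S, x, xu, shake_tol, 1000);
    for (int i : S.mobile_idx) {
      v[i].x += (x[i].x - xdr[i].x) / h;
      v[i].y += (x[i].y - xdr[i].y) / h;
      v[i].z += (x[i].z - xdr[i].z) / h;
    }
    // force + B half kick + tangent projection
    eval_forces(S, x, E, f, use_nl ? &nbrs : nullptr);
    for (int i : S.mobile_idx) {
      double a = 0.5 * dt / S.mass[i];
      v[i].x += a * f[i].x; v[i].y += a * f[i].y; v[i].z += a * f[i].z;
    }
    do_rattle(S, x, v, 1e-8, 50);

    if (!std::isfinite(E.total())) {
      stop("trajectory diverged at step %d (non-finite energy)", step);
    }
    if (step % 100 == 0) {
      for (int i : S.mobile_idx) {
        if (std::fabs(x[i].x) > 1e4 || std::fabs(x[i].y) > 1e4 ||
            std::fabs(x[i].z) > 1e4) {
          stop("trajectory diverged at step %d (runaway coordinates)", step);
        }
      }
    }
    int prod = step - equil;
    if (prod >= 0 && prod % stride == 0 && frame < n_frames) {
      t_out[frame] = (prod + 1) * dt;
      q_out[frame] = E.Q;
      x_out[frame] = E.x;
      F_out[frame] = E.F_pN;
      Fx_out[frame] = E.Fv[0];
      Fy_out[frame] = E.Fv[1];
      Fz_out[frame] = E.Fv[2];
      E_out[frame] = E.total();
      double ke = 0.0;
      for (int i : S.mobile_idx) ke += 0.5 * S.mass[i] * dot(v[i], v[i]);
      K_out[frame] = ke;
      if (record_pos) {
        for (int a = 0; a < nmob; ++a) {
          int i = S.mobile_idx[a];
          R_xlen_t off = ((R_xlen_t)frame * nmob + a) * 3;
          pos_out[off] = x[i].x; pos_out[off + 1] = x[i].y; pos_out[off + 2] = x[i].z;
        }
      }
      ++frame;
    }
  }

  NumericMatrix pos_fin(S.n, 3), vel_fin(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    pos_fin(i, 0) = x[i].x; pos_fin(i, 1) = x[i].y; pos_fin(i, 2) = x[i].z;
    vel_fin(i, 0) = v[i].x; vel_fin(i, 1) = v[i].y; vel_fin(i, 2) = v[i].z;
  }
  List out = List::create(
      _["t"] = t_out, _["Q"] = q_out, _["x"] = x_out, _["F_pN"] = F_out,
      _["E"] = E_out, _["E_kin"] = K_out,
      _["F_x"] = Fx_out, _["F_y"] = Fy_out, _["F_z"] = Fz_out,
      _["pos_final"] = pos_fin, _["vel_final"] = vel_fin,
      _["n_frames"] = frame);
  if (record_pos) {
    out["positions"] = pos_out;
    out["n_mobile"] = nmob;
  }
  return out;
}

// Kinetic Monte Carlo (BKL / Gillespie) for the four-state arrest-escape
// scheme: UA -(kf)-> FA, FA -(ku)-> UA, UA -(keu)-> UR, FA -(kef)-> FR,
// with UR and FR absorbing.  Returns per-replica escape time (Inf if
// still arrested at t_total) and the state index at t_total
// (1=UA, 2=FA, 3=UR, 4=FR).
// [[Rcpp::export]]
List cpp_kmc(double kf, double ku, double keu, double kef, double t_total,
             int n_replicas) {
  RNGScope scope;
  IntegerVector state_end(n_replicas);
  NumericVector t_abs(n_replicas);
  for (int rep = 0; rep < n_replicas; ++rep) {
    int s = 1; // UA
    double t = 0.0;
    while (true) {
      double r1, r2, rtot;
      if (s == 1) { r1 = kf; r2 = keu; } else { r1 = ku; r2 = kef; }
      rtot = r1 + r2;
      if (rtot <= 0.0) { t = R_PosInf; break; } // stuck, never escapes
      double delta = unif_rand();
      double dtk = -std::log(std::max(unif_rand(), 1e-300)) / rtot;
      t += dtk;
      if (t > t_total) break;
      if (delta * rtot < r1) {
        s = (s == 1) ? 2 : 1; // fold / unfold
      } else {
        s = (s == 1) ? 3 : 4; // escape
        break;
      }
    }
    if (s == 3 || s == 4) {
      state_end[rep] = s;
      t_abs[rep] = t;
    } else {
      state_end[rep] = s;
      t_abs[rep] = R_PosInf;
    }
  }
  return List::create(_["state"] = state_end, _["t_escape"] = t_abs);
}
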