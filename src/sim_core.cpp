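// Core numerics: planar articulated rigid-body dynamics (generalized
// coordinates over an optional 3-DoF floating base plus 1-DoF revolute
// joints), Hill-type muscular-tendon actuators with compliant tendons,
// Hunt-Crossley foot-ground contact, and the closed-loop fixed-step RK4
// simulation with sample-exact delay buffers.
//
// All angles are radians, lengths metres, forces newtons. The R layer owns
// unit conversion (degrees at the config/report boundary only).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

inline arma::vec2 rot(double th, const arma::vec2& v) {
  const double c = std::cos(th), s = std::sin(th);
  return arma::vec2{c * v[0] - s * v[1], s * v[0] + c * v[1]};
}
// 90-degree CCW rotation: S(v) = (-v_y, v_x); d/dth R(th) v = S(R(th) v).
inline arma::vec2 perp(const arma::vec2& v) { return arma::vec2{-v[1], v[0]}; }

// ---------------------------------------------------------------------------
// Plant
// ---------------------------------------------------------------------------

struct Plant {
  int nseg = 0, nj = 0, ndof = 0;
  bool base_free = true;
  double grav = 9.81;
  arma::vec3 base_pose;              // used when the base is pinned
  std::vector<int> parent;           // -1 for root; parents precede children
  std::vector<int> jidx;             // joint index attaching segment to parent
  arma::mat anchor_p, anchor_c;      // 2 x nseg, joint anchors (parent/child frame)
  arma::vec mass, inertia;           // per segment
  arma::mat com;                     // 2 x nseg, CoM in segment frame
  arma::vec jstiff, jdamp, jneutral; // passive joint properties (per joint)
  // contact
  int contact_mode = 0;              // 0 none, 1 Hunt-Crossley, 2 static support
  std::vector<int> cp_seg, cp_role, cp_foot; // role: 0 heel, 1 toe, 2 other
  arma::mat cp_pos;                  // 2 x ncp, point in segment frame
  double mu_s = 0.9, mu_d = 0.9, mu_v = 0.6, v_t = 0.1, E = 1e8, b = 0.5;
  double ground_y = 0.0;
  // ancestor joint lists per segment (joint indices on path from root)
  std::vector<std::vector<int>> anc;

  int ncp() const { return (int)cp_seg.size(); }
  int qcol(int j) const { return base_free ? 3 + j : j; }
};

Plant parse_plant(const List& pl) {
  Plant p;
  p.nseg = as<int>(pl["nseg"]);
  p.nj = as<int>(pl["nj"]);
  p.base_free = as<bool>(pl["base_free"]);
  p.grav = as<double>(pl["gravity"]);
  p.ndof = p.base_free ? 3 + p.nj : p.nj;
  NumericVector bp = pl["base_pose"];
  p.base_pose = arma::vec3{bp[0], bp[1], bp[2]};
  p.parent = as<std::vector<int>>(pl["parent"]);
  p.jidx = as<std::vector<int>>(pl["jidx"]);
  p.anchor_p = as<arma::mat>(pl["anchor_p"]);
  p.anchor_c = as<arma::mat>(pl["anchor_c"]);
  p.mass = as<arma::vec>(pl["mass"]);
  p.inertia = as<arma::vec>(pl["inertia"]);
  p.com = as<arma::mat>(pl["com"]);
  p.jstiff = as<arma::vec>(pl["jstiff"]);
  p.jdamp = as<arma::vec>(pl["jdamp"]);
  p.jneutral = as<arma::vec>(pl["jneutral"]);
  p.contact_mode = as<int>(pl["contact_mode"]);
  p.cp_seg = as<std::vector<int>>(pl["cp_seg"]);
  p.cp_role = as<std::vector<int>>(pl["cp_role"]);
  p.cp_foot = as<std::vector<int>>(pl["cp_foot"]);
  p.cp_pos = as<arma::mat>(pl["cp_pos"]);
  List cpar = pl["contact"];
  p.mu_s = as<double>(cpar["mu_s"]);
  p.mu_d = as<double>(cpar["mu_d"]);
  p.mu_v = as<double>(cpar["mu_v"]);
  p.v_t = as<double>(cpar["v_t"]);
  p.E = as<double>(cpar["E"]);
  p.b = as<double>(cpar["b"]);
  // ancestor joint chains
  p.anc.resize(p.nseg);
  for (int s = 0; s < p.nseg; ++s) {
    int cur = s;
    while (p.parent[cur] >= 0) {
      p.anc[s].push_back(p.jidx[cur]);
      cur = p.parent[cur];
    }
    std::reverse(p.anc[s].begin(), p.anc[s].end());
  }
  return p;
}

// Kinematic snapshot for one generalized state.
struct Kin {
  arma::mat o, ov;     // segment frame origins and their velocities (2 x nseg)
  arma::vec phi, phid; // segment world angles / angular velocities
  arma::mat w, wv;     // joint world positions / velocities (2 x nj)
  arma::mat pc, pcv;   // segment CoM world positions / velocities (2 x nseg)
  arma::vec2 oroot, ovroot;
};

void kinematics(const Plant& p, const arma::vec& gp, const arma::vec& gv, Kin& k) {
  k.o.set_size(2, p.nseg); k.ov.set_size(2, p.nseg);
  k.phi.set_size(p.nseg);  k.phid.set_size(p.nseg);
  k.w.set_size(2, std::max(p.nj, 1)); k.wv.set_size(2, std::max(p.nj, 1));
  k.pc.set_size(2, p.nseg); k.pcv.set_size(2, p.nseg);
  const int off = p.base_free ? 3 : 0;
  for (int s = 0; s < p.nseg; ++s) {
    if (p.parent[s] < 0) {
      if (p.base_free) {
        k.o.col(s) = arma::vec2{gp[0], gp[1]};
        k.phi[s] = gp[2];
        k.ov.col(s) = arma::vec2{gv[0], gv[1]};
        k.phid[s] = gv[2];
      } else {
        k.o.col(s) = arma::vec2{p.base_pose[0], p.base_pose[1]};
        k.phi[s] = p.base_pose[2];
        k.ov.col(s).zeros();
        k.phid[s] = 0.0;
      }
    } else {
      const int pa = p.parent[s], j = p.jidx[s];
      arma::vec2 wj = k.o.col(pa) + rot(k.phi[pa], p.anchor_p.col(s));
      arma::vec2 wjv = k.ov.col(pa) + k.phid[pa] * perp(wj - k.o.col(pa));
      k.w.col(j) = wj; k.wv.col(j) = wjv;
      k.phi[s] = k.phi[pa] + gp[off + j];
      k.phid[s] = k.phid[pa] + gv[off + j];
      k.o.col(s) = wj - rot(k.phi[s], p.anchor_c.col(s));
      k.ov.col(s) = wjv - k.phid[s] * perp(wj - k.o.col(s));
    }
    k.pc.col(s) = k.o.col(s) + rot(k.phi[s], p.com.col(s));
    k.pcv.col(s) = k.ov.col(s) + k.phid[s] * perp(k.pc.col(s) - k.o.col(s));
  }
  int root = 0;
  for (int s = 0; s < p.nseg; ++s) if (p.parent[s] < 0) { root = s; break; }
  k.oroot = k.o.col(root);
  k.ovroot = k.ov.col(root);
}

// Translational Jacobian of a point attached to segment s: the column for a
// rotational coordinate with pivot w is S(x - w); base translations are
// identity columns. Columns are dense over the (few) active coordinates.
inline void point_jacobian_apply(const Plant& p, const Kin& k, int s,
                                 const arma::vec2& x, const arma::vec2& f,
                                 arma::vec& Q) {
  if (p.base_free) {
    Q[0] += f[0];
    Q[1] += f[1];
    Q[2] += arma::dot(perp(x - k.oroot), f);
  }
  for (int j : p.anc[s]) {
    arma::vec2 col = perp(x - arma::vec2(k.w.col(j)));
    Q[p.qcol(j)] += arma::dot(col, f);
  }
}

// Assemble M(q) and the velocity bias h(q, v) (Coriolis/centrifugal), and the
// generalized gravity force.  Returns everything needed for M vdot = Q - h.
void mass_bias(const Plant& p, const Kin& k, const arma::vec& gv,
               arma::mat& M, arma::vec& h, arma::vec& Qg) {
  const int n = p.ndof;
  M.zeros(n, n); h.zeros(n); Qg.zeros(n);
  std::vector<int> cols; cols.reserve(n);
  std::vector<arma::vec2> Jv; Jv.reserve(n);
  std::vector<double> Jw; Jw.reserve(n);
  for (int s = 0; s < p.nseg; ++s) {
    const double m = p.mass[s], I = p.inertia[s];
    if (p.parent[s] < 0 && !p.base_free) {
      // pinned root is welded to the world: no dynamic contribution
      continue;
    }
    cols.clear(); Jv.clear(); Jw.clear();
    const arma::vec2 x = k.pc.col(s);
    if (p.base_free) {
      cols.push_back(0); Jv.push_back(arma::vec2{1, 0}); Jw.push_back(0);
      cols.push_back(1); Jv.push_back(arma::vec2{0, 1}); Jw.push_back(0);
      cols.push_back(2); Jv.push_back(perp(x - k.oroot)); Jw.push_back(1);
    }
    for (int j : p.anc[s]) {
      cols.push_back(p.qcol(j));
      Jv.push_back(perp(x - arma::vec2(k.w.col(j))));
      Jw.push_back(1);
    }
    const size_t na = cols.size();
    // CoM acceleration with vdot = 0 (bias acceleration)
    arma::vec2 a0{0, 0};
    if (p.base_free) a0 += gv[2] * perp(k.pcv.col(s) - k.ovroot);
    for (int j : p.anc[s])
      a0 += gv[p.qcol(j)] * perp(k.pcv.col(s) - arma::vec2(k.wv.col(j)));
    for (size_t a = 0; a < na; ++a) {
      h[cols[a]] += m * arma::dot(Jv[a], a0);
      Qg[cols[a]] += -m * p.grav * Jv[a][1];
      for (size_t bcol = a; bcol < na; ++bcol) {
        const double mij = m * arma::dot(Jv[a], Jv[bcol]) + I * Jw[a] * Jw[bcol];
        M(cols[a], cols[bcol]) += mij;
        if (bcol != a) M(cols[bcol], cols[a]) += mij;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Muscles
// ---------------------------------------------------------------------------

struct Curves {
  double gamma = 0.45;       // active force-length width
  double pe_k = 5.0;         // passive exponential shape
  double pe_span = 0.7;      // passive normalized to 1 at lhat = 1 + pe_span
  double eps0 = 0.049;       // tendon strain at which f_T = 1
  double toe_frac = 0.5;     // toe region ends at toe_frac * eps0
  double fv_kcc = 4.0;       // concentric curvature
  double fv_ke = 12.5;       // eccentric curvature
  double fv_fmax = 1.4;      // eccentric plateau
  double beta = 0.1;         // fiber damping (damped equilibrium)
};

Curves parse_curves(const List& cl) {
  Curves c;
  c.gamma = as<double>(cl["gamma"]);
  c.pe_k = as<double>(cl["pe_k"]);
  c.pe_span = as<double>(cl["pe_span"]);
  c.eps0 = as<double>(cl["eps0"]);
  c.toe_frac = as<double>(cl["toe_frac"]);
  c.fv_kcc = as<double>(cl["fv_kcc"]);
  c.fv_ke = as<double>(cl["fv_ke"]);
  c.fv_fmax = as<double>(cl["fv_fmax"]);
  c.beta = as<double>(cl["beta"]);
  return c;
}

inline double fl_active(const Curves& c, double l) {
  const double d = l - 1.0;
  return std::exp(-d * d / c.gamma);
}
inline double fpe_passive(const Curves& c, double l) {
  if (l <= 1.0) return 0.0;
  return std::expm1(c.pe_k * (l - 1.0) / c.pe_span) / std::expm1(c.pe_k);
}
inline double ft_tendon(const Curves& c, double e) {
  if (e <= 0.0) return 0.0;
  const double etoe = c.toe_frac * c.eps0;
  const double klin = 1.0 / (c.eps0 - 0.5 * etoe);
  if (e < etoe) return 0.5 * klin * e * e / etoe;
  return klin * (e - 0.5 * etoe);
}
inline double fv_hill(const Curves& c, double v) {
  if (v <= -1.0) return 0.0;
  if (v < 0.0) return (1.0 + v) / (1.0 - c.fv_kcc * v);
  return c.fv_fmax - (c.fv_fmax - 1.0) / (1.0 + c.fv_ke * v);
}
inline double fv_hill_d(const Curves& c, double v) {
  if (v <= -1.0) return 0.0;
  if (v < 0.0) {
    const double d = 1.0 - c.fv_kcc * v;
    return (1.0 + c.fv_kcc) / (d * d);
  }
  const double d = 1.0 + c.fv_ke * v;
  return (c.fv_fmax - 1.0) * c.fv_ke / (d * d);
}

// Damped-equilibrium fiber rate: solve a*fL*fV(v) + beta*v = rhs for the
// normalized fiber velocity v.  Monotone in v; safeguarded Newton.
inline double solve_fiber_vel(const Curves& c, double afl, double rhs) {
  double lo = -1.5, hi = 3.0;
  auto g = [&](double v) { return afl * fv_hill(c, v) + c.beta * v - rhs; };
  double glo = g(lo), ghi = g(hi);
  if (glo >= 0.0) return lo;
  if (ghi <= 0.0) return hi;
  double v = 0.0;
  for (int it = 0; it < 40; ++it) {
    const double gv = g(v);
    if (std::abs(gv) < 1e-12) return v;
    if (gv > 0.0) hi = v; else lo = v;
    const double dg = afl * fv_hill_d(c, v) + c.beta;
    double vn = v - gv / dg;
    if (!(vn > lo && vn < hi)) vn = 0.5 * (lo + hi);
    if (std::abs(vn - v) < 1e-12) return vn;
    v = vn;
  }
  return v;
}

struct Muscles {
  int nm = 0;
  arma::vec F0, lopt, lts, vmax, tact, tdact, amin, L0path;
  arma::mat r;       // nm x nj moment arms (signed; + toward flexion)
  arma::vec qref;    // reference posture for the length map
  Curves curves;
};

Muscles parse_muscles(const List& ml) {
  Muscles m;
  m.nm = as<int>(ml["nm"]);
  if (m.nm == 0) { m.curves = Curves(); return m; }
  m.F0 = as<arma::vec>(ml["F0"]);
  m.lopt = as<arma::vec>(ml["lopt"]);
  m.lts = as<arma::vec>(ml["lts"]);
  m.vmax = as<arma::vec>(ml["vmax"]);
  m.tact = as<arma::vec>(ml["tact"]);
  m.tdact = as<arma::vec>(ml["tdact"]);
  m.amin = as<arma::vec>(ml["amin"]);
  m.L0path = as<arma::vec>(ml["L0"]);
  m.r = as<arma::mat>(ml["r"]);
  m.qref = as<arma::vec>(ml["qref"]);
  m.curves = parse_curves(ml["curves"]);
  return m;
}

inline void mt_length_vel(const Muscles& m, int i, const arma::vec& q,
                          const arma::vec& qd, double& L, double& Ld) {
  L = m.L0path[i];
  Ld = 0.0;
  for (arma::uword j = 0; j < m.r.n_cols; ++j) {
    const double rij = m.r(i, j);
    if (rij != 0.0) {
      L -= rij * (q[j] - m.qref[j]);
      Ld -= rij * qd[j];
    }
  }
}

inline double act_delta(double a, double u, double ta, double td) {
  return (u > a) ? ta * (0.5 + 1.5 * a) : td / (0.5 + 1.5 * a);
}

// Static fiber equilibrium at activation a and muscular-tendon length L:
// bisection on fiber length.  Used for state initialization.
double fiber_equilibrium(const Curves& c, double a, double L, double lopt,
                         double lts) {
  double lo = 1e-6, hi = std::max(L - 1e-9, 2e-6);
  auto g = [&](double lf) {
    const double eps = (L - lf - lts) / lts;
    return ft_tendon(c, eps) - a * fl_active(c, lf / lopt) -
           fpe_passive(c, lf / lopt);
  };
  if (g(lo) <= 0.0) return lo;
  if (g(hi) >= 0.0) return hi;
  for (int it = 0; it < 80; ++it) {
    const double mid = 0.5 * (lo + hi);
    if (g(mid) > 0.0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// ---------------------------------------------------------------------------
// Contact
// ---------------------------------------------------------------------------

inline double mu_of_v(const Plant& p, double v) {
  const double u = v / p.v_t;
  return p.mu_v * v + p.mu_d * std::tanh(4.0 * u) +
         (p.mu_s - p.mu_d) * (2.0 * u / (1.0 + u * u));
}

inline double hc_normal(const Plant& p, double h, double hdot) {
  if (h <= 0.0) return 0.0;
  const double f = p.E * std::pow(h, 1.5) * (1.0 + 1.5 * p.b * hdot);
  return f > 0.0 ? f : 0.0;
}

inline arma::vec joint_part(const arma::vec& v, int off, int nj) {
  return nj > 0 ? arma::vec(v.subvec(off, off + nj - 1)) : arma::vec();
}

// ---------------------------------------------------------------------------
// Coupled derivative
// ---------------------------------------------------------------------------

struct Model {
  Plant plant;
  Muscles mus;
  // controller (fixed-size vectors over muscles)
  arma::vec kp, kd, uff, ctrlL0, ctrlVmax;
};

struct DerivOut {
  arma::vec gvdot;
  arma::vec adot, lfdot;
  arma::vec tendonF;
  arma::vec cpRy, cpRx, cpX; // per contact point (HC mode)
};

// Full coupled derivative.  u_del: delayed excitation per muscle (ZOH over a
// control step).  Contact forces enter the dynamics in HC mode only.
void deriv(const Model& mod, const arma::vec& gp, const arma::vec& gv,
           const arma::vec& a, const arma::vec& lf, const arma::vec& u_del,
           DerivOut& out, Kin& k) {
  const Plant& p = mod.plant;
  const Muscles& m = mod.mus;
  const int off = p.base_free ? 3 : 0;
  kinematics(p, gp, gv, k);
  arma::vec Q(p.ndof, arma::fill::zeros);
  // muscles
  out.adot.set_size(m.nm); out.lfdot.set_size(m.nm); out.tendonF.set_size(m.nm);
  const arma::vec q = joint_part(gp, off, p.nj);
  const arma::vec qd = joint_part(gv, off, p.nj);
  for (int i = 0; i < m.nm; ++i) {
    double L, Ld;
    mt_length_vel(m, i, q, qd, L, Ld);
    const double ai = std::min(std::max(a[i], 0.0), 1.0);
    out.adot[i] = (u_del[i] - a[i]) /
                  act_delta(ai, u_del[i], m.tact[i], m.tdact[i]);
    const double lhat = lf[i] / m.lopt[i];
    const double eps = (L - lf[i] - m.lts[i]) / m.lts[i];
    const double ft = ft_tendon(m.curves, eps);
    const double afl = ai * fl_active(m.curves, lhat);
    const double rhs = ft - fpe_passive(m.curves, lhat);
    const double vhat = solve_fiber_vel(m.curves, afl, rhs);
    out.lfdot[i] = vhat * m.vmax[i];
    const double F = m.F0[i] * ft;
    out.tendonF[i] = F;
    for (int j = 0; j < p.nj; ++j) {
      const double rij = m.r(i, j);
      if (rij != 0.0) Q[p.qcol(j)] += rij * F;
    }
  }
  // passive joint properties
  for (int j = 0; j < p.nj; ++j)
    Q[p.qcol(j)] += -p.jstiff[j] * (q[j] - p.jneutral[j]) - p.jdamp[j] * qd[j];
  // Hunt-Crossley contact
  const int ncp = p.ncp();
  out.cpRy.zeros(ncp); out.cpRx.zeros(ncp); out.cpX.zeros(ncp);
  if (p.contact_mode == 1) {
    for (int cidx = 0; cidx < ncp; ++cidx) {
      const int s = p.cp_seg[cidx];
      const arma::vec2 x = k.o.col(s) + rot(k.phi[s], p.cp_pos.col(cidx));
      const arma::vec2 xv = k.ov.col(s) + k.phid[s] * perp(x - arma::vec2(k.o.col(s)));
      const double h = p.ground_y - x[1];
      const double hdot = -xv[1];
      const double Ry = hc_normal(p, h, hdot);
      double Rx = 0.0;
      if (Ry > 0.0) {
        const double vs = std::abs(xv[0]);
        Rx = -((xv[0] >= 0.0) ? 1.0 : -1.0) * mu_of_v(p, vs) * Ry;
        point_jacobian_apply(p, k, s, x, arma::vec2{Rx, Ry}, Q);
      }
      out.cpRy[cidx] = Ry; out.cpRx[cidx] = Rx; out.cpX[cidx] = x[0];
    }
  }
  arma::mat M; arma::vec h, Qg;
  mass_bias(p, k, gv, M, h, Qg);
  out.gvdot = arma::solve(M, Q + Qg - h, arma::solve_opts::likely_sympd);
}

// Support-mode ground reaction: with the root welded to the world and the
// feet flat, the ground wrench balances the rate of change of whole-body
// momentum; the CoP follows, and heel/toe shares come from a moment balance
// across the support span.
void support_reaction(const Plant& p, const Kin& k, const arma::vec& gv,
                      const arma::vec& gvdot, double& Rtot, double& copx) {
  // CoM accelerations: a_i = bias + sum_cols Jv * vdot
  double Fy = 0.0, Mz = 0.0, mgx = 0.0, W = 0.0;
  for (int s = 0; s < p.nseg; ++s) {
    const double m = p.mass[s];
    arma::vec2 acc{0, 0};
    double phidd = 0.0;
    if (!(p.parent[s] < 0 && !p.base_free)) {
      if (p.base_free) {
        acc += arma::vec2{gvdot[0], gvdot[1]};
        acc += gvdot[2] * perp(k.pc.col(s) - k.oroot);
        acc += gv[2] * perp(k.pcv.col(s) - k.ovroot);
        phidd += gvdot[2];
      }
      for (int j : p.anc[s]) {
        const int c = p.qcol(j);
        acc += gvdot[c] * perp(k.pc.col(s) - arma::vec2(k.w.col(j)));
        acc += gv[c] * perp(k.pcv.col(s) - arma::vec2(k.wv.col(j)));
        phidd += gvdot[c];
      }
    }
    Fy += m * acc[1];
    Mz += m * (k.pc(0, s) * acc[1] - k.pc(1, s) * acc[0]) + p.inertia[s] * phidd;
    mgx += m * p.grav * k.pc(0, s);
    W += m * p.grav;
  }
  Rtot = W + Fy;
  copx = (Rtot != 0.0) ? (Mz + mgx) / Rtot : NA_REAL;
}

} // namespace

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".kin_core")]]
List kin_core(List plant, NumericVector gp, NumericVector gv) {
  Plant p = parse_plant(plant);
  Kin k;
  kinematics(p, as<arma::vec>(gp), as<arma::vec>(gv), k);
  return List::create(_["o"] = k.o, _["phi"] = k.phi, _["ov"] = k.ov,
                      _["phid"] = k.phid, _["w"] = k.w, _["wv"] = k.wv,
                      _["com"] = k.pc, _["comv"] = k.pcv);
}

// [[Rcpp::export(name = ".fd_core")]]
List fd_core(List plant, NumericVector gp, NumericVector gv,
             NumericVector joint_torques, List ext_forces) {
  Plant p = parse_plant(plant);
  Kin k;
  arma::vec gpv = as<arma::vec>(gp), gvv = as<arma::vec>(gv);
  kinematics(p, gpv, gvv, k);
  arma::vec Q(p.ndof, arma::fill::zeros);
  for (int j = 0; j < p.nj; ++j) Q[p.qcol(j)] += joint_torques[j];
  const arma::vec q = joint_part(gpv, p.base_free ? 3 : 0, p.nj);
  const arma::vec qd = joint_part(gvv, p.base_free ? 3 : 0, p.nj);
  for (int j = 0; j < p.nj; ++j)
    Q[p.qcol(j)] += -p.jstiff[j] * (q[j] - p.jneutral[j]) - p.jdamp[j] * qd[j];
  for (int i = 0; i < ext_forces.size(); ++i) {
    List ef = ext_forces[i];
    const int s = as<int>(ef["segment"]);
    NumericVector pt = ef["point"], fo = ef["force"];
    arma::vec2 x = k.o.col(s) + rot(k.phi[s], arma::vec2{pt[0], pt[1]});
    point_jacobian_apply(p, k, s, x, arma::vec2{fo[0], fo[1]}, Q);
  }
  arma::mat M; arma::vec h, Qg;
  mass_bias(p, k, gvv, M, h, Qg);
  if (arma::rcond(M) < 1e-14)
    stop("singular mass matrix (degenerate inertia configuration)");
  arma::vec vdot = arma::solve(M, Q + Qg - h);
  return List::create(_["gvdot"] = vdot, _["M"] = M, _["bias"] = h,
                      _["gravity_force"] = Qg);
}

// [[Rcpp::export(name = ".energy_core")]]
double energy_core(List plant, NumericVector gp, NumericVector gv) {
  Plant p = parse_plant(plant);
  Kin k;
  kinematics(p, as<arma::vec>(gp), as<arma::vec>(gv), k);
  double T = 0.0, V = 0.0;
  for (int s = 0; s < p.nseg; ++s) {
    if (p.parent[s] < 0 && !p.base_free) continue;
    T += 0.5 * p.mass[s] * arma::dot(k.pcv.col(s), k.pcv.col(s)) +
         0.5 * p.inertia[s] * k.phid[s] * k.phid[s];
    V += p.mass[s] * p.grav * k.pc(1, s);
  }
  return T + V;
}

// [[Rcpp::export(name = ".muscle_curves_core")]]
List muscle_curves_core(List curves, double lhat, double vhat, double eps) {
  Curves c = parse_curves(curves);
  return List::create(_["fl"] = fl_active(c, lhat),
                      _["fpe"] = fpe_passive(c, lhat),
                      _["ft"] = ft_tendon(c, eps),
                      _["fv"] = fv_hill(c, vhat));
}

// [[Rcpp::export(name = ".fiber_equilibrium_core")]]
double fiber_equilibrium_core(List curves, double a, double L, double lopt,
                              double lts) {
  return fiber_equilibrium(parse_curves(curves), a, L, lopt, lts);
}

// Closed-loop simulation.
// controller: list(kp, kd, uff, L0, vmax, tau_fb, tau_trans)
// sim: list(duration, dt, control_step, record_stride, com_fail_height,
//           monitor_failure)
// init: list(gp, gv, a0, lf0 (optional))
// [[Rcpp::export(name = ".sim_core")]]
List sim_core(List plant, List muscles, List controller, List sim, List init) {
  Model mod;
  mod.plant = parse_plant(plant);
  mod.mus = parse_muscles(muscles);
  const Plant& p = mod.plant;
  const Muscles& mus = mod.mus;
  const int nm = mus.nm;
  const int off = p.base_free ? 3 : 0;

  const double duration = as<double>(sim["duration"]);
  const double dt = as<double>(sim["dt"]);
  const double cs = as<double>(sim["control_step"]);
  const int record_stride = as<int>(sim["record_stride"]);
  const double com_fail = as<double>(sim["com_fail_height"]);
  const bool monitor = as<bool>(sim["monitor_failure"]);

  const int nsub = std::max(1, (int)std::lround(cs / dt));
  const double dtr = cs / nsub;
  const int nsteps = (int)std::lround(duration / cs);

  arma::vec gp = as<arma::vec>(init["gp"]), gv = as<arma::vec>(init["gv"]);
  arma::vec a(std::max(nm, 1), arma::fill::zeros),
      lf(std::max(nm, 1), arma::fill::zeros);
  if (nm > 0) {
    a = as<arma::vec>(init["a0"]);
    if (init.containsElementNamed("lf0") && !Rf_isNull(init["lf0"])) {
      lf = as<arma::vec>(init["lf0"]);
    } else {
      const arma::vec q0 = joint_part(gp, off, p.nj);
      const arma::vec qd0(p.nj, arma::fill::zeros);
      for (int i = 0; i < nm; ++i) {
        double L, Ld;
        mt_length_vel(mus, i, q0, qd0, L, Ld);
        lf[i] = fiber_equilibrium(mus.curves, a[i], L, mus.lopt[i], mus.lts[i]);
      }
    }
  }

  double tau_fb = 0.0, tau_trans = 0.0;
  arma::vec kp, kd, uff, cL0, cVmax;
  if (nm > 0) {
    kp = as<arma::vec>(controller["kp"]);
    kd = as<arma::vec>(controller["kd"]);
    uff = as<arma::vec>(controller["uff"]);
    cL0 = as<arma::vec>(controller["L0"]);
    cVmax = as<arma::vec>(controller["vmax"]);
    tau_fb = as<double>(controller["tau_fb"]);
    tau_trans = as<double>(controller["tau_trans"]);
  }
  const int nfb = (int)std::lround(tau_fb / cs);
  const int ntr = (int)std::lround(tau_trans / cs);

  // delay buffers (ring): size delay+1 so that read-after-write returns the
  // sample written exactly delay steps earlier
  const int szf = nfb + 1, szt = ntr + 1;
  arma::mat bufL(std::max(nm, 1), szf), bufLd(std::max(nm, 1), szf),
      bufU(std::max(nm, 1), szt);
  int headf = 0, headt = 0;

  // initial sensor values / commands fill the pre-history
  arma::vec u_del(std::max(nm, 1), arma::fill::zeros);
  if (nm > 0) {
    const arma::vec q0 = joint_part(gp, off, p.nj);
    const arma::vec qd0 = joint_part(gv, off, p.nj);
    for (int i = 0; i < nm; ++i) {
      double L, Ld;
      mt_length_vel(mus, i, q0, qd0, L, Ld);
      bufL.row(i).fill(L);
      bufLd.row(i).fill(Ld);
      const double ufb = kp[i] * (L - cL0[i]) / cL0[i] + kd[i] * Ld / cVmax[i];
      const double u = std::min(1.0, std::max(0.0, uff[i] + ufb));
      bufU.row(i).fill(u);
    }
    u_del = bufU.col(0);
  }

  // recording layout: t | gp | gv | com(2) | cop | a | F | Ry per point
  const int ncp = p.ncp();
  const int reccols = 1 + p.ndof * 2 + 3 + (nm > 0 ? 2 * nm : 0) + ncp;
  const int nrec = nsteps / record_stride + 2;
  arma::mat rec(nrec, reccols, arma::fill::zeros);
  int irec = 0;

  DerivOut d1, d2, d3, d4;
  Kin k;
  double T_fail = duration;
  bool failed = false, blewup = false;

  const double totmass = [&] {
    double Wm = 0.0;
    for (int s = 0; s < p.nseg; ++s)
      if (!(p.parent[s] < 0 && !p.base_free)) Wm += p.mass[s];
    return Wm;
  }();

  auto record_and_monitor = [&](int step) -> bool {
    const double t = step * cs;
    // state-derived quantities at control-step resolution
    deriv(mod, gp, gv, a, lf, u_del, d1, k);
    double comx = 0.0, comy = 0.0;
    for (int s = 0; s < p.nseg; ++s) {
      if (p.parent[s] < 0 && !p.base_free) continue;
      comx += p.mass[s] * k.pc(0, s);
      comy += p.mass[s] * k.pc(1, s);
    }
    comx /= totmass; comy /= totmass;
    double copx = NA_REAL;
    arma::vec Ry(std::max(ncp, 1), arma::fill::zeros);
    bool foot_unloaded = false;
    if (p.contact_mode == 1) {
      double sR = 0.0, sxR = 0.0;
      for (int cidx = 0; cidx < ncp; ++cidx) {
        Ry[cidx] = d1.cpRy[cidx];
        sR += Ry[cidx];
        sxR += d1.cpX[cidx] * Ry[cidx];
        if ((p.cp_role[cidx] == 0 || p.cp_role[cidx] == 1) && Ry[cidx] <= 0.0)
          foot_unloaded = true;
      }
      copx = sR > 0.0 ? sxR / sR : NA_REAL;
      if (sR <= 0.0) foot_unloaded = true;
    } else if (p.contact_mode == 2) {
      double Rtot;
      support_reaction(p, k, gv, d1.gvdot, Rtot, copx);
      // distribute over the support span per foot via a moment balance
      double xh = 0.0, xt = 0.0;
      bool have = false;
      for (int cidx = 0; cidx < ncp; ++cidx) {
        Kin& kk = k;
        const int s = p.cp_seg[cidx];
        const arma::vec2 x = kk.o.col(s) + rot(kk.phi[s], p.cp_pos.col(cidx));
        if (p.cp_role[cidx] == 0) { xh = x[0]; have = true; }
        if (p.cp_role[cidx] == 1) xt = x[0];
      }
      if (have && Rtot > 0.0) {
        const double Rtoe = Rtot * (copx - xh) / (xt - xh);
        const double Rheel = Rtot - Rtoe;
        for (int cidx = 0; cidx < ncp; ++cidx) {
          if (p.cp_role[cidx] == 0) Ry[cidx] = Rheel;
          if (p.cp_role[cidx] == 1) Ry[cidx] = Rtoe;
        }
        if (Rheel <= 0.0 || Rtoe <= 0.0) foot_unloaded = true;
      } else {
        foot_unloaded = true;
      }
    }
    if (step % record_stride == 0 && irec < nrec) {
      int cpos = 0;
      rec(irec, cpos++) = t;
      for (int i2 = 0; i2 < p.ndof; ++i2) rec(irec, cpos++) = gp[i2];
      for (int i2 = 0; i2 < p.ndof; ++i2) rec(irec, cpos++) = gv[i2];
      rec(irec, cpos++) = comx;
      rec(irec, cpos++) = comy;
      rec(irec, cpos++) = copx;
      for (int i2 = 0; i2 < nm; ++i2) rec(irec, cpos++) = a[i2];
      for (int i2 = 0; i2 < nm; ++i2) rec(irec, cpos++) = d1.tendonF[i2];
      for (int cidx = 0; cidx < ncp; ++cidx) rec(irec, cpos++) = Ry[cidx];
      ++irec;
    }
    if (monitor && (comy < com_fail || (p.contact_mode != 0 && foot_unloaded))) {
      T_fail = t;
      failed = true;
      return true;
    }
    return false;
  };

  auto control_update = [&](int /*step*/) {
    if (nm == 0) return;
    const arma::vec q = joint_part(gp, off, p.nj);
    const arma::vec qd = joint_part(gv, off, p.nj);
    headf = (headf + 1) % szf;
    headt = (headt + 1) % szt;
    for (int i = 0; i < nm; ++i) {
      double L, Ld;
      mt_length_vel(mus, i, q, qd, L, Ld);
      bufL(i, headf) = L;
      bufLd(i, headf) = Ld;
    }
    const int readf = (headf - nfb % szf + szf) % szf;
    for (int i = 0; i < nm; ++i) {
      const double Lf = bufL(i, readf), Ldf = bufLd(i, readf);
      const double ufb = kp[i] * (Lf - cL0[i]) / cL0[i] + kd[i] * Ldf / cVmax[i];
      bufU(i, headt) = std::min(1.0, std::max(0.0, uff[i] + ufb));
    }
    const int readt = (headt - ntr % szt + szt) % szt;
    u_del = bufU.col(readt);
  };

  // t = 0: record + monitor (buffers pre-filled above)
  bool stop_now = record_and_monitor(0);
  arma::vec gpa, gva, gpb, gvb, gpc, gvc;
  arma::vec aa, ab, ac, lfa, lfb, lfc;

  for (int step = 0; step < nsteps && !stop_now; ++step) {
    for (int ss = 0; ss < nsub; ++ss) {
      // RK4 on the coupled state (gp, gv, a, lf) with u_del held
      deriv(mod, gp, gv, a, lf, u_del, d1, k);
      gpa = gp + 0.5 * dtr * gv;  gva = gv + 0.5 * dtr * d1.gvdot;
      aa = a; lfa = lf;
      if (nm) { aa += 0.5 * dtr * d1.adot; lfa += 0.5 * dtr * d1.lfdot; }
      deriv(mod, gpa, gva, aa, lfa, u_del, d2, k);
      gpb = gp + 0.5 * dtr * gva; gvb = gv + 0.5 * dtr * d2.gvdot;
      ab = a; lfb = lf;
      if (nm) { ab += 0.5 * dtr * d2.adot; lfb += 0.5 * dtr * d2.lfdot; }
      deriv(mod, gpb, gvb, ab, lfb, u_del, d3, k);
      gpc = gp + dtr * gvb;       gvc = gv + dtr * d3.gvdot;
      ac = a; lfc = lf;
      if (nm) { ac += dtr * d3.adot; lfc += dtr * d3.lfdot; }
      deriv(mod, gpc, gvc, ac, lfc, u_del, d4, k);
      gp += (dtr / 6.0) * (gv + 2.0 * gva + 2.0 * gvb + gvc);
      gv += (dtr / 6.0) *
            (d1.gvdot + 2.0 * d2.gvdot + 2.0 * d3.gvdot + d4.gvdot);
      if (nm) {
        a += (dtr / 6.0) * (d1.adot + 2.0 * d2.adot + 2.0 * d3.adot + d4.adot);
        lf += (dtr / 6.0) *
              (d1.lfdot + 2.0 * d2.lfdot + 2.0 * d3.lfdot + d4.lfdot);
        for (int i = 0; i < nm; ++i) {
          if (a[i] < mus.amin[i]) a[i] = mus.amin[i];
          if (a[i] > 1.0) a[i] = 1.0;
          if (lf[i] < 1e-6) lf[i] = 1e-6;
        }
      }
    }
    if (!gp.is_finite() || !gv.is_finite() || (nm && !(a.is_finite() && lf.is_finite()))) {
      T_fail = (step + 1) * cs;
      failed = true;
      blewup = true;
      break;
    }
    control_update(step + 1);
    stop_now = record_and_monitor(step + 1);
  }

  rec.resize(irec, reccols);
  return List::create(_["record"] = rec, _["T_fail"] = T_fail,
                      _["failed"] = failed, _["numeric_blowup"] = blewup,
                      _["final_gp"] = gp, _["final_gv"] = gv, _["final_a"] = a,
                      _["final_lf"] = lf, _["ncp"] = ncp, _["nm"] = nm);
}
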