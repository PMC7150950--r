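// Lagrangian tracking core: analytic tube/tree flow evaluation and the
// one-way-coupled ellipsoid particle stepper.
//
// The translational update is an exponential integrator that is exact for
// linear (Stokes) drag with coefficients frozen over the step, evaluated at
// a midpoint predictor position; orientation follows quasi-steady Jeffery
// dynamics integrated with RK2 on the unit sphere.  Walls are the lateral
// capsule/cone surfaces of the segments; contact (including fiber-tip
// interception) is tested every step against the local candidate segments.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
};
static inline Vec3 operator+(const Vec3& a, const Vec3& b) {
  return Vec3(a.x + b.x, a.y + b.y, a.z + b.z);
}
static inline Vec3 operator-(const Vec3& a, const Vec3& b) {
  return Vec3(a.x - b.x, a.y - b.y, a.z - b.z);
}
static inline Vec3 operator*(double s, const Vec3& a) {
  return Vec3(s * a.x, s * a.y, s * a.z);
}
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x);
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
static inline Vec3 normalize(const Vec3& a) {
  double n = norm(a);
  return n > 0 ? (1.0 / n) * a : Vec3(0, 0, 0);
}

struct Mat3 {
  double m[3][3];
  Mat3() { for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) m[i][j] = 0; }
  Vec3 mul(const Vec3& v) const {
    return Vec3(m[0][0] * v.x + m[0][1] * v.y + m[0][2] * v.z,
                m[1][0] * v.x + m[1][1] * v.y + m[1][2] * v.z,
                m[2][0] * v.x + m[2][1] * v.y + m[2][2] * v.z);
  }
};

struct Waveform {
  int type;       // 0 = dpi, 1 = constant
  double P;       // peak flow, m^3/s
  double tr, th, T;
  double Q(double t) const {
    if (type == 1) return (t >= 0 && t <= T) ? P : 0.0;
    if (t <= 0 || t >= T) return 0.0;
    if (t < tr) {
      double s = std::sin(M_PI * t / (2.0 * tr));
      return P * s * s;
    }
    if (t <= th) return P;
    double c = std::cos(M_PI_2 * (t - th) / (T - th));
    return P * c * c;
  }
};

struct Domain {
  int n;
  std::vector<Vec3> o, d;
  std::vector<double> len, r1, r0, taper, frac;
  std::vector<int> parent;              // -1 if root
  std::vector<std::vector<int>> child;
  std::vector<int> terminal;            // 1 if terminal outlet
  Waveform wf;
  double flow_scale;
  Vec3 gravity; // unit vector

  double radius_at(int j, double s) const {
    if (s < taper[j]) {
      double w = 1.0 - s / taper[j];
      return r1[j] + (r0[j] - r1[j]) * w;
    }
    return r1[j];
  }
  double slope_at(int j, double s) const {
    return (s < taper[j]) ? (r1[j] - r0[j]) / taper[j] : 0.0;
  }

  // signed inside distance to the lateral (capsule/cone) surface of seg j
  double inside(int j, const Vec3& p, double* s_out = nullptr) const {
    Vec3 rel = p - o[j];
    double s = dot(rel, d[j]);
    if (s_out) *s_out = s;
    double sc = s < 0 ? 0 : (s > len[j] ? len[j] : s);
    Vec3 ax = rel - sc * d[j];
    double slope = slope_at(j, sc);
    return (radius_at(j, sc) - norm(ax)) / std::sqrt(1.0 + slope * slope);
  }

  // velocity and (optionally) gradient of the analytic laminar field in
  // segment j; G[i][k] = du_i/dx_k
  void flow(int j, const Vec3& p, double t, Vec3& u, Mat3* G) const {
    Vec3 rel = p - o[j];
    double s = dot(rel, d[j]);
    double sc = s < 0 ? 0 : (s > len[j] ? len[j] : s);
    Vec3 ax = rel - s * d[j];
    double r = norm(ax);
    double R = radius_at(j, sc);
    double Rp = slope_at(j, sc);
    double Qs = wf.Q(t) * flow_scale * frac[j];
    double ub = Qs / (M_PI * R * R);
    double rho = r / R;
    if (rho > 1.0) rho = 1.0;
    Vec3 e = (r > 1e-12 * R) ? (1.0 / r) * ax : Vec3(0, 0, 0);
    double ux = 2.0 * ub * (1.0 - rho * rho);
    double ur = 2.0 * ub * Rp * rho * (1.0 - rho * rho);
    u = ux * d[j] + ur * e;
    if (!G) return;
    Mat3& g = *G;
    double dux_dr = -4.0 * ub * rho / R;
    double dux_dx = 4.0 * ub * (Rp / R) * (2.0 * rho * rho - 1.0);
    double dur_dr = 2.0 * ub * Rp * (1.0 - 3.0 * rho * rho) / R;
    double ur_r   = 2.0 * ub * Rp * (1.0 - rho * rho) / R;
    double dur_dx = -2.0 * ub * (Rp * Rp / R) * rho * (3.0 - 5.0 * rho * rho);
    const Vec3& D = d[j];
    if (r > 1e-12 * R) {
      Vec3 T = cross(D, e);
      double Dv[3] = {D.x, D.y, D.z};
      double Ev[3] = {e.x, e.y, e.z};
      double Tv[3] = {T.x, T.y, T.z};
      for (int i = 0; i < 3; ++i)
        for (int k = 0; k < 3; ++k)
          g.m[i][k] = dux_dr * Dv[i] * Ev[k] + dux_dx * Dv[i] * Dv[k] +
                      dur_dr * Ev[i] * Ev[k] + ur_r * Tv[i] * Tv[k] +
                      dur_dx * Ev[i] * Dv[k];
    } else {
      // on-axis limit: e x e + t x t -> I - d x d, radial-shear terms vanish
      double c = 2.0 * ub * Rp / R;
      double Dv[3] = {D.x, D.y, D.z};
      for (int i = 0; i < 3; ++i)
        for (int k = 0; k < 3; ++k)
          g.m[i][k] = dux_dx * Dv[i] * Dv[k] +
                      c * ((i == k ? 1.0 : 0.0) - Dv[i] * Dv[k]);
    }
  }
};

static Domain unpack_domain(const List& pack) {
  Domain dm;
  NumericMatrix o = pack["seg_o"], d = pack["seg_d"];
  NumericVector len = pack["len"], r1 = pack["radius"], r0 = pack["radius0"],
                tp = pack["taper"], fr = pack["frac"];
  IntegerVector par = pack["parent"], term = pack["terminal"];
  List kids = pack["children"];
  dm.n = o.nrow();
  dm.o.resize(dm.n); dm.d.resize(dm.n);
  for (int i = 0; i < dm.n; ++i) {
    dm.o[i] = Vec3(o(i, 0), o(i, 1), o(i, 2));
    dm.d[i] = Vec3(d(i, 0), d(i, 1), d(i, 2));
  }
  dm.len = as<std::vector<double>>(len);
  dm.r1 = as<std::vector<double>>(r1);
  dm.r0 = as<std::vector<double>>(r0);
  dm.taper = as<std::vector<double>>(tp);
  dm.frac = as<std::vector<double>>(fr);
  dm.parent = as<std::vector<int>>(par); // 0-based, -1 root
  dm.terminal = as<std::vector<int>>(term);
  dm.child.resize(dm.n);
  for (int i = 0; i < dm.n; ++i) {
    IntegerVector k = kids[i];
    dm.child[i] = as<std::vector<int>>(k); // 0-based
  }
  List wf = pack["waveform"];
  dm.wf.type = as<int>(wf["type"]);
  dm.wf.P = as<double>(wf["P"]);
  dm.wf.tr = as<double>(wf["tr"]);
  dm.wf.th = as<double>(wf["th"]);
  dm.wf.T = as<double>(wf["T"]);
  dm.flow_scale = as<double>(pack["flow_scale"]);
  NumericVector gv = pack["gravity"];
  dm.gravity = Vec3(gv[0], gv[1], gv[2]);
  return dm;
}

// Assignment score for flow evaluation: the capsule inside-distance,
// penalized when the point lies beyond the segment's axial range.  The
// spherical end caps belong to the wall model only; without the penalty a
// particle crossing a junction would keep the parent's axial field while
// inside the parent's end cap and never feel the daughter's convergence.
static double assign_score(const Domain& dm, int j, const Vec3& p) {
  double s;
  double din = dm.inside(j, p, &s);
  if (s < 0) return din - 5.0 * (-s);
  if (s > dm.len[j]) return din - 5.0 * (s - dm.len[j]);
  return din;
}

// containing segment = argmax of inside distance over all segments
static int locate_global(const Domain& dm, const Vec3& p, double* best_out) {
  int best = -1;
  double bd = -1e300, bs = -1e300;
  for (int j = 0; j < dm.n; ++j) {
    double d = dm.inside(j, p);
    if (d > bd) bd = d;
    double sc = assign_score(dm, j, p);
    if (sc > bs) { bs = sc; best = j; }
  }
  if (best_out) *best_out = bd;
  return best;
}

// [[Rcpp::export]]
NumericMatrix cpp_field_velocity(List pack, NumericMatrix pts, double t) {
  Domain dm = unpack_domain(pack);
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    Vec3 p(pts(i, 0), pts(i, 1), pts(i, 2));
    double wd;
    int j = locate_global(dm, p, &wd);
    if (wd <= 0) continue; // outside lumen: zero velocity
    Vec3 u;
    dm.flow(j, p, t, u, nullptr);
    out(i, 0) = u.x; out(i, 1) = u.y; out(i, 2) = u.z;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_field_gradient(List pack, NumericVector x, double t) {
  Domain dm = unpack_domain(pack);
  Vec3 p(x[0], x[1], x[2]);
  double wd;
  int j = locate_global(dm, p, &wd);
  NumericVector out(9);
  if (wd <= 0) return out;
  Vec3 u;
  Mat3 G;
  dm.flow(j, p, t, u, &G);
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      out[c * 3 + r] = G.m[r][c]; // column-major for R matrix(,3,3)
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_wall_distance(List pack, NumericMatrix pts) {
  Domain dm = unpack_domain(pack);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p(pts(i, 0), pts(i, 1), pts(i, 2));
    double wd;
    locate_global(dm, p, &wd);
    out[i] = wd;
  }
  return out;
}

struct Fiber {
  double a_p, b_p, AR, d_stk, t0, rho_p, mass, Kpar, Kperp, lambda;
  bool sphere;
};

struct Air { double mu, rho, g; };

// candidate segments for local queries around segment j
static void candidates(const Domain& dm, int j, std::vector<int>& cand) {
  cand.clear();
  cand.push_back(j);
  int p = dm.parent[j];
  if (p >= 0) {
    cand.push_back(p);
    for (int s : dm.child[p]) if (s != j) cand.push_back(s);
    int gp = dm.parent[p];
    if (gp >= 0) cand.push_back(gp);
  }
  for (int c : dm.child[j]) cand.push_back(c);
}

static double wd_local(const Domain& dm, const std::vector<int>& cand,
                       const Vec3& p) {
  double bd = -1e300;
  for (int j : cand) {
    double d = dm.inside(j, p);
    if (d > bd) bd = d;
  }
  return bd;
}

static Vec3 jeffery_rate(const Mat3& G, const Vec3& p, double lambda) {
  // S p and W p from G: S = (G + G^T)/2, W = (G - G^T)/2
  Vec3 Gp = G.mul(p);
  Vec3 GTp(G.m[0][0] * p.x + G.m[1][0] * p.y + G.m[2][0] * p.z,
           G.m[0][1] * p.x + G.m[1][1] * p.y + G.m[2][1] * p.z,
           G.m[0][2] * p.x + G.m[1][2] * p.y + G.m[2][2] * p.z);
  Vec3 Sp = 0.5 * (Gp + GTp);
  Vec3 Wp = 0.5 * (Gp - GTp);
  return Wp + lambda * (Sp - dot(p, Sp) * p);
}

// status codes
enum { AIRBORNE = 1, DEPOSITED = 2, EXITED = 3 };
// mechanisms
enum { MECH_NONE = 0, MECH_INTERCEPT = 1, MECH_SED = 2, MECH_IMPACT = 3 };

// [[Rcpp::export]]
NumericMatrix cpp_track(List pack, List fiber_pack, List air_pack,
                        NumericMatrix x0, NumericMatrix v0, NumericMatrix p0,
                        NumericVector t_inj, IntegerVector seg0,
                        List opts) {
  Domain dm = unpack_domain(pack);
  Fiber fb;
  fb.a_p = as<double>(fiber_pack["a_p"]);
  fb.b_p = as<double>(fiber_pack["b_p"]);
  fb.AR = as<double>(fiber_pack["AR"]);
  fb.d_stk = as<double>(fiber_pack["d_stk"]);
  fb.t0 = as<double>(fiber_pack["t0"]);
  fb.rho_p = as<double>(fiber_pack["rho_p"]);
  fb.mass = as<double>(fiber_pack["mass"]);
  fb.Kpar = as<double>(fiber_pack["K_par"]);
  fb.Kperp = as<double>(fiber_pack["K_perp"]);
  fb.lambda = as<double>(fiber_pack["lambda"]);
  fb.sphere = fb.AR <= 1.0 + 1e-12;
  Air air;
  air.mu = as<double>(air_pack["mu"]);
  air.rho = as<double>(air_pack["rho"]);
  air.g = as<double>(air_pack["g"]);

  double t_end = as<double>(opts["t_end"]);
  double dt_max = as<double>(opts["dt_max"]);
  double dt_min = as<double>(opts["dt_min"]);
  double courant = as<double>(opts["courant"]);
  double ang_fac = as<double>(opts["ang_factor"]);
  bool lift_on = as<bool>(opts["lift"]);
  double sed_frac = as<double>(opts["sed_fraction"]);
  double fixed_dt = as<double>(opts["fixed_dt"]); // <= 0: adaptive

  double nu = air.mu / air.rho;
  Vec3 gvec = air.g * dm.gravity;
  double apar = air.mu * fb.Kpar / fb.mass;
  double aper = air.mu * fb.Kperp / fb.mass;

  // fiber contact sampling offsets along the axis (tips + every a_p/2,
  // capped at 64 points); spheres use the center only
  std::vector<double> soff;
  if (fb.sphere) {
    soff.push_back(0.0);
  } else {
    int m = (int)std::ceil(2.0 * fb.b_p / (0.5 * fb.a_p)) + 1;
    if (m > 64) m = 64;
    if (m < 3) m = 3;
    for (int k = 0; k < m; ++k)
      soff.push_back(-fb.b_p + 2.0 * fb.b_p * k / (m - 1));
  }

  int n = x0.nrow();
  NumericMatrix out(n, 17);
  std::vector<int> cand;

  for (int i = 0; i < n; ++i) {
    Vec3 x(x0(i, 0), x0(i, 1), x0(i, 2));
    Vec3 v(v0(i, 0), v0(i, 1), v0(i, 2));
    Vec3 pv = normalize(Vec3(p0(i, 0), p0(i, 1), p0(i, 2)));
    double t = t_inj[i];
    int seg = seg0[i] - 1;
    int status = AIRBORNE, mech = MECH_NONE;
    double wd_at_contact = NA_REAL;
    long nsteps = 0;

    while (status == AIRBORNE && t < t_end) {
      // --- relocate: segment with max inside distance among neighbors
      candidates(dm, seg, cand);
      double s_cur;
      dm.inside(seg, x, &s_cur);
      if (s_cur > dm.len[seg] && dm.terminal[seg]) {
        status = EXITED;
        break;
      }
      {
        double bd = -1e300;
        int bj = seg;
        for (int j : cand) {
          double d = assign_score(dm, j, x);
          if (d > bd) { bd = d; bj = j; }
        }
        seg = bj;
      }
      candidates(dm, seg, cand);

      // --- time step
      double dt;
      double R = dm.r1[seg];
      if (fixed_dt > 0) {
        dt = fixed_dt;
      } else {
        Vec3 uq;
        dm.flow(seg, x, t, uq, nullptr);
        double speed = std::max(norm(v), norm(uq)) + 1e-12;
        dt = std::min(dt_max, courant * R / speed);
        if (!fb.sphere) {
          // resolve rotation: ||grad u|| ~ 4 ub / R local shear scale
          double shear = 4.0 * norm(uq) / R + 1e-12;
          dt = std::min(dt, ang_fac / shear);
        }
        if (dt < dt_min) dt = dt_min;
      }
      if (t + dt > t_end) dt = t_end - t;

      // --- flow at midpoint predictor
      Vec3 xm = x + (0.5 * dt) * v;
      int segm = seg;
      {
        double bd = -1e300;
        for (int j : cand) {
          double d = assign_score(dm, j, xm);
          if (d > bd) { bd = d; segm = j; }
        }
      }
      Vec3 u;
      Mat3 G;
      dm.flow(segm, xm, t + 0.5 * dt, u, &G);

      // --- forces
      Vec3 urel = u - v;
      Vec3 f = gvec; // specific force (per mass)
      if (lift_on) {
        Vec3 om(G.m[2][1] - G.m[1][2], G.m[0][2] - G.m[2][0],
                G.m[1][0] - G.m[0][1]);
        double nom = norm(om);
        if (nom > 1e-12) {
          Vec3 FL = (1.615 * air.mu * fb.d_stk * fb.d_stk /
                     std::sqrt(nu * nom)) * cross(urel, om);
          f = f + (1.0 / fb.mass) * FL;
        }
      }

      // --- exponential translational update (exact for frozen coefficients)
      Vec3 fpar = dot(f, pv) * pv;
      Vec3 fper = f - fpar;
      Vec3 veq = u + (1.0 / apar) * fpar + (1.0 / aper) * fper;
      Vec3 dv = v - veq;
      Vec3 dvpar = dot(dv, pv) * pv;
      Vec3 dvper = dv - dvpar;
      double E1 = std::exp(-apar * dt), E2 = std::exp(-aper * dt);
      Vec3 vn = veq + E1 * dvpar + E2 * dvper;
      Vec3 xn = x + dt * veq + ((1.0 - E1) / apar) * dvpar +
                ((1.0 - E2) / aper) * dvper;

      // --- orientation update (quasi-steady Jeffery, RK2, renormalized)
      if (!fb.sphere) {
        Vec3 k1 = jeffery_rate(G, pv, fb.lambda);
        Vec3 pm = normalize(pv + (0.5 * dt) * k1);
        Vec3 k2 = jeffery_rate(G, pm, fb.lambda);
        pv = normalize(pv + dt * k2);
      }

      x = xn;
      v = vn;
      t += dt;
      ++nsteps;

      if (std::isnan(x.x) || std::isnan(v.x) || std::isnan(pv.x)) {
        stop("integration blow-up: particle %d at t = %g s", i + 1, t);
      }

      // --- contact detection (deposition on any wall contact)
      double wd_center = wd_local(dm, cand, x);
      bool contact = false;
      Vec3 cpos = x;
      if (fb.sphere) {
        contact = wd_center <= fb.a_p;
      } else if (wd_center <= fb.b_p + fb.a_p) {
        for (double s : soff) {
          Vec3 q = x + s * pv;
          if (wd_local(dm, cand, q) <= fb.a_p) {
            contact = true;
            cpos = q;
            break;
          }
        }
      }
      if (contact) {
        status = DEPOSITED;
        wd_at_contact = wd_center;
        if (!fb.sphere && wd_center > fb.a_p) {
          mech = MECH_INTERCEPT;
        } else {
          double vg = dot(v, dm.gravity);
          mech = (vg > sed_frac * norm(v)) ? MECH_SED : MECH_IMPACT;
        }
        x = cpos; // record the contact location
      }
    }

    out(i, 0) = status;
    out(i, 1) = t;
    out(i, 2) = x.x; out(i, 3) = x.y; out(i, 4) = x.z;
    out(i, 5) = v.x; out(i, 6) = v.y; out(i, 7) = v.z;
    out(i, 8) = pv.x; out(i, 9) = pv.y; out(i, 10) = pv.z;
    out(i, 11) = seg + 1;
    out(i, 12) = mech;
    out(i, 13) = wd_at_contact;
    out(i, 14) = nsteps;
    out(i, 15) = t_inj[i];
    out(i, 16) = NA_REAL; // reserved
  }
  colnames(out) = CharacterVector::create(
    "status", "t", "x", "y", "z", "vx", "vy", "vz", "px", "py", "pz",
    "segment", "mechanism", "wall_dist", "n_steps", "t_inject", "aux");
  return out;
}
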