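// Fixed-step semi-implicit Euler integrator for the patellofemoral
// simulation. Mirrors the pure-R reference engine (world.R) operation for
// operation; all quantities in SI (m, N, kg, s). Deterministic: no RNG.

#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3(double x_ = 0, double y_ = 0, double z_ = 0) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  Vec3& operator+=(const Vec3& o) { x += o.x; y += o.y; z += o.z; return *this; }
  Vec3& operator-=(const Vec3& o) { x -= o.x; y -= o.y; z -= o.z; return *this; }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
};

struct Quat {
  double w, x, y, z;
  Quat(double w_ = 1, double x_ = 0, double y_ = 0, double z_ = 0)
      : w(w_), x(x_), y(y_), z(z_) {}
  Quat mul(const Quat& b) const {
    return Quat(w * b.w - x * b.x - y * b.y - z * b.z,
                w * b.x + x * b.w + y * b.z - z * b.y,
                w * b.y - x * b.z + y * b.w + z * b.x,
                w * b.z + x * b.y - y * b.x + z * b.w);
  }
  void normalize() {
    double n = std::sqrt(w * w + x * x + y * y + z * z);
    w /= n; x /= n; y /= n; z /= n;
  }
  // rotate a body vector to world
  Vec3 rotate(const Vec3& v) const {
    double r11 = 1 - 2 * (y * y + z * z), r12 = 2 * (x * y - w * z),
           r13 = 2 * (x * z + w * y);
    double r21 = 2 * (x * y + w * z), r22 = 1 - 2 * (x * x + z * z),
           r23 = 2 * (y * z - w * x);
    double r31 = 2 * (x * z - w * y), r32 = 2 * (y * z + w * x),
           r33 = 1 - 2 * (x * x + y * y);
    return Vec3(r11 * v.x + r12 * v.y + r13 * v.z,
                r21 * v.x + r22 * v.y + r23 * v.z,
                r31 * v.x + r32 * v.y + r33 * v.z);
  }
  // rotate a world vector to body (transpose)
  Vec3 rotate_t(const Vec3& v) const {
    double r11 = 1 - 2 * (y * y + z * z), r12 = 2 * (x * y - w * z),
           r13 = 2 * (x * z + w * y);
    double r21 = 2 * (x * y + w * z), r22 = 1 - 2 * (x * x + z * z),
           r23 = 2 * (y * z - w * x);
    double r31 = 2 * (x * z - w * y), r32 = 2 * (y * z + w * x),
           r33 = 1 - 2 * (x * x + y * y);
    return Vec3(r11 * v.x + r21 * v.y + r31 * v.z,
                r12 * v.x + r22 * v.y + r32 * v.z,
                r13 * v.x + r23 * v.y + r33 * v.z);
  }
};

struct Profile {
  double R, floor_y, w_neg, w_pos, outer_slope, shelf, shelf_width, z0, z1;
  // returns false when no bone at x; otherwise elevation e and slope de
  bool eval(double x, double& e, double& de) const {
    if (x >= -w_neg && x <= w_pos) {
      double s = std::sqrt(R * R - x * x);
      e = floor_y + R - s;
      de = x / s;
      return true;
    }
    if (x < -(w_neg + shelf_width) || x > w_pos + shelf_width) return false;
    if (x < -w_neg) {
      double apex = floor_y + (R - std::sqrt(R * R - w_neg * w_neg));
      double v = apex - outer_slope * (-x - w_neg);
      if (v <= shelf) { e = shelf; de = 0; } else { e = v; de = outer_slope; }
      return true;
    }
    double apex = floor_y + (R - std::sqrt(R * R - w_pos * w_pos));
    double v = apex - outer_slope * (x - w_pos);
    if (v <= shelf) { e = shelf; de = 0; } else { e = v; de = -outer_slope; }
    return true;
  }
};

static Vec3 getv(const List& w, const char* nm) {
  NumericVector v = w[nm];
  return Vec3(v[0], v[1], v[2]);
}

// [[Rcpp::export(name = ".cpp_run_simulation")]]
List cpp_run_simulation(List w) {
  const Vec3 origin = getv(w, "origin");
  NumericMatrix quad_local = w["quad_local"];
  NumericMatrix lig_local = w["lig_local"];
  NumericMatrix tub = w["tub"];
  NumericVector tendon_rest = w["tendon_rest"];
  NumericVector lig_rest = w["lig_rest"];
  const double k_spring = as<double>(w["k_spring"]);
  NumericMatrix pts = w["pts"];
  const double k_pt = as<double>(w["k_pt"]);
  const double c_pt = as<double>(w["c_pt"]);
  const double mu = as<double>(w["mu"]);
  List prl = w["profile"];
  Profile pr;
  pr.R = as<double>(prl["R"]); pr.floor_y = as<double>(prl["floor"]);
  pr.w_neg = as<double>(prl["w_neg"]); pr.w_pos = as<double>(prl["w_pos"]);
  pr.outer_slope = as<double>(prl["outer_slope"]);
  pr.shelf = as<double>(prl["shelf"]);
  pr.shelf_width = as<double>(prl["shelf_width"]);
  pr.z0 = as<double>(prl["z0"]); pr.z1 = as<double>(prl["z1"]);
  const double m = as<double>(w["m"]);
  NumericVector inertia = w["inertia"];
  const double m_j = as<double>(w["m_j"]);
  const double lam = as<double>(w["lam"]);
  const double lam_j = as<double>(w["lam_j"]);
  List mm = w["muscle"];
  const double Fmax = as<double>(mm["Fmax"]);
  const double L0 = as<double>(mm["L0"]);
  const double vmax = as<double>(mm["vmax"]);
  const double fl_width = as<double>(mm["fl_width"]);
  const double fv_shape = as<double>(mm["fv_shape"]);
  const double fv_cap = as<double>(mm["fv_cap"]);
  const double k_shape = as<double>(mm["k_shape"]);
  const double Lmax = as<double>(mm["Lmax"]);
  const double dt = as<double>(w["dt"]);
  const int n_steps = as<int>(w["n_steps"]);
  const int sample_every = as<int>(w["sample_every"]);
  const double ramp_end = as<double>(w["ramp_end"]);
  const double plateau = as<double>(w["plateau"]);
  const Vec3 gravity = getv(w, "gravity");
  const double v_guard = as<double>(w["v_guard"]);
  const double w_guard = as<double>(w["w_guard"]);

  Vec3 x = getv(w, "x0");
  NumericVector q0 = w["q0"];
  Quat q(q0[0], q0[1], q0[2], q0[3]);
  Vec3 j = getv(w, "j0");
  Vec3 v(0, 0, 0), wb(0, 0, 0), vj(0, 0, 0);
  double Lnorm_prev = (origin - j).norm() / L0;

  const int n_pts = pts.nrow();
  const int n_out = n_steps / sample_every + 1;
  NumericMatrix out(n_out, 14);
  int row = 0;
  double fail_time = -1.0;
  double max_fric_win = 0.0;

  // per-step diagnostics captured at sampling instants
  Vec3 rc_last(0, 0, 0);
  int ncont_last = 0;
  double Tm_last = 0.0;

  for (int stepi = 0; stepi <= n_steps; ++stepi) {
    double t = stepi * dt;
    double a = plateau * std::min(t / ramp_end, 1.0);

    Vec3 F = gravity * m;
    Vec3 tau(0, 0, 0);
    Vec3 Fj(0, 0, 0);

    // tendon springs
    for (int s = 0; s < 3; ++s) {
      Vec3 att = x + q.rotate(Vec3(quad_local(s, 0), quad_local(s, 1),
                                   quad_local(s, 2)));
      Vec3 d = att - j;
      double len = d.norm();
      double el = len - tendon_rest[s];
      if (el > 0) {
        Vec3 f = d * (k_spring * el / len);
        F -= f;
        tau += (att - x).cross(f * -1.0);
        Fj += f;
      }
    }

    // Hill muscle element
    Vec3 dm = origin - j;
    double Lm = dm.norm();
    double Lnorm = Lm / L0;
    double vshort = -(Lnorm - Lnorm_prev) / dt;
    double ffl = std::exp(-std::pow((Lnorm - 1) / fl_width, 2));
    double ffv;
    if (vshort >= 0) {
      double vc = std::min(vshort, vmax);
      ffv = std::max(0.0, (1 - vc / vmax) / (1 + vc / (fv_shape * vmax)));
    } else {
      ffv = fv_cap - (fv_cap - 1) * std::exp(vshort / (fv_shape * vmax));
    }
    double fpe = Lnorm > 1
        ? (std::exp((k_shape / Lmax) * (Lnorm - 1)) - 1) /
              (std::exp(k_shape) - 1)
        : 0.0;
    double Tm = a * Fmax * ffl * ffv + Fmax * fpe;
    if (Tm < 0) Tm = 0;
    Fj += dm * (Tm / Lm);

    // ligament springs
    for (int s = 0; s < 3; ++s) {
      Vec3 att = x + q.rotate(Vec3(lig_local(s, 0), lig_local(s, 1),
                                   lig_local(s, 2)));
      Vec3 d = Vec3(tub(s, 0), tub(s, 1), tub(s, 2)) - att;
      double len = d.norm();
      double el = len - lig_rest[s];
      if (el > 0) {
        Vec3 f = d * (k_spring * el / len);
        F += f;
        tau += (att - x).cross(f);
      }
    }

    // contact
    Vec3 ww = q.rotate(wb);
    Vec3 rc(0, 0, 0);
    int ncont = 0;
    for (int i = 0; i < n_pts; ++i) {
      Vec3 p = x + q.rotate(Vec3(pts(i, 0), pts(i, 1), pts(i, 2)));
      if (p.z < pr.z0 || p.z > pr.z1) continue;
      double e, de;
      if (!pr.eval(p.x, e, de)) continue;
      double depth = e - p.y;
      if (depth <= 0) continue;
      double nn = std::sqrt(1 + de * de);
      Vec3 nv(-de / nn, 1 / nn, 0);
      Vec3 r = p - x;
      Vec3 vp = v + ww.cross(r);
      double vn = vp.dot(nv);
      double fn = k_pt * depth - c_pt * vn;
      if (fn <= 0) continue;
      Vec3 vt = vp - nv * vn;
      double st = vt.norm();
      Vec3 f = nv * fn;
      if (st > 0) {
        Vec3 ft = vt * (-mu * fn / (st + 1e-4));
        f += ft;
        double frac = ft.norm() / fn;
        if (frac > max_fric_win) max_fric_win = frac;
      }
      F += f;
      tau += r.cross(f);
      rc += f;
      ++ncont;
    }

    rc_last = rc; ncont_last = ncont; Tm_last = Tm;

    // sample before advancing so t = 0 is recorded
    if (stepi % sample_every == 0 && row < n_out) {
      out(row, 0) = t;
      out(row, 1) = x.x * 1e3; out(row, 2) = x.y * 1e3; out(row, 3) = x.z * 1e3;
      out(row, 4) = q.w; out(row, 5) = q.x; out(row, 6) = q.y; out(row, 7) = q.z;
      out(row, 8) = rc.x * 1e-3; out(row, 9) = rc.y * 1e-3;
      out(row, 10) = rc.z * 1e-3;
      out(row, 11) = Tm * 1e-3;
      out(row, 12) = ncont;
      out(row, 13) = max_fric_win;
      max_fric_win = 0.0;
      ++row;
    }
    if (stepi == n_steps) break;

    // advance junction (3-dof point, implicit mass-proportional damping)
    vj = (vj + Fj * (dt / m_j)) * (1.0 / (1.0 + lam_j * dt));
    j += vj * dt;
    Lnorm_prev = Lnorm;

    // advance patella
    v = (v + F * (dt / m)) * (1.0 / (1.0 + lam * dt));
    x += v * dt;
    Vec3 tau_b = q.rotate_t(tau);
    Vec3 alpha(tau_b.x / inertia[0], tau_b.y / inertia[1],
               tau_b.z / inertia[2]);
    wb = (wb + alpha * dt) * (1.0 / (1.0 + lam * dt));
    Quat dq = q.mul(Quat(0, wb.x, wb.y, wb.z));
    q = Quat(q.w + 0.5 * dt * dq.w, q.x + 0.5 * dt * dq.x,
             q.y + 0.5 * dt * dq.y, q.z + 0.5 * dt * dq.z);
    q.normalize();

    if (!std::isfinite(x.x + x.y + x.z + v.x + v.y + v.z) ||
        v.norm() > v_guard || wb.norm() > w_guard) {
      fail_time = t + dt;
      break;
    }
  }

  return List::create(_["samples"] = out, _["rows"] = row,
                      _["fail_time"] = fail_time);
}
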