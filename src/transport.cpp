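// Weighted Monte Carlo photon transport in a multilayer cylindrical finger
// model. Geometry: concentric annular shells about the z axis plus embedded
// axis-parallel cylinders (vessels, bone), bounded by absorbing end caps.
// Implicit-capture weighting with Russian roulette; Henyey-Greenstein
// scattering; unpolarized Fresnel reflection/refraction at refractive-index
// mismatches. All lengths in mm.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

// -- counter-seeded RNG: splitmix64-seeded xoshiro256**, one stream per photon
// so results are reproducible regardless of execution order.
inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256 {
  uint64_t s[4];
  void seed(uint64_t sd) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sd);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5ULL, 7) * 9ULL;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform strictly inside (0,1): safe for log()
  double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

const double EPS_PUSH = 1e-7;   // nudge across boundaries (mm)
const double EPS_T    = 1e-9;   // minimum accepted flight distance (mm)
const int AMBIENT = -1;

struct Geometry {
  // annuli: r_in, r_out, region id  (ordered, non-overlapping)
  std::vector<double> ann_rin, ann_rout;
  std::vector<int>    ann_reg;
  // embedded axis-parallel cylinders: cx, cy, radius, region id
  std::vector<double> cyl_cx, cyl_cy, cyl_r;
  std::vector<int>    cyl_reg;
  // distinct radial shell surfaces (includes outer radius)
  std::vector<double> shells;
  double outer_radius, zlen;

  int locate(double x, double y, double z) const {
    if (z < 0.0 || z > zlen) return AMBIENT;
    double r2 = x * x + y * y;
    if (r2 > outer_radius * outer_radius) return AMBIENT;
    for (size_t i = 0; i < cyl_r.size(); ++i) {
      double dx = x - cyl_cx[i], dy = y - cyl_cy[i];
      if (dx * dx + dy * dy < cyl_r[i] * cyl_r[i]) return cyl_reg[i];
    }
    for (size_t i = 0; i < ann_rin.size(); ++i) {
      if (r2 >= ann_rin[i] * ann_rin[i] && r2 < ann_rout[i] * ann_rout[i])
        return ann_reg[i];
    }
    return ann_reg.empty() ? AMBIENT : ann_reg.back();  // numerical edge
  }
};

// surface hit descriptor: kind 0 = radial shell, 1 = embedded cylinder, 2 = cap
struct Hit { double t; int kind; int idx; };

// smallest positive root of |p_xy + t d_xy - c|^2 = r^2 beyond EPS_T
inline void circle_roots(double px, double py, double dx, double dy,
                         double cx, double cy, double r, Hit &best,
                         int kind, int idx) {
  double a = dx * dx + dy * dy;
  if (a < 1e-16) return;
  double rx = px - cx, ry = py - cy;
  double b = rx * dx + ry * dy;
  double c = rx * rx + ry * ry - r * r;
  double disc = b * b - a * c;
  if (disc < 0.0) return;
  double sq = std::sqrt(disc);
  double t1 = (-b - sq) / a, t2 = (-b + sq) / a;
  if (t1 > EPS_T && t1 < best.t) { best.t = t1; best.kind = kind; best.idx = idx; }
  else if (t2 > EPS_T && t2 < best.t) { best.t = t2; best.kind = kind; best.idx = idx; }
}

inline Hit next_boundary(const Geometry &g, const double p[3], const double d[3]) {
  Hit best; best.t = std::numeric_limits<double>::infinity();
  best.kind = -1; best.idx = -1;
  for (size_t i = 0; i < g.shells.size(); ++i)
    circle_roots(p[0], p[1], d[0], d[1], 0.0, 0.0, g.shells[i], best, 0, (int)i);
  for (size_t i = 0; i < g.cyl_r.size(); ++i)
    circle_roots(p[0], p[1], d[0], d[1], g.cyl_cx[i], g.cyl_cy[i], g.cyl_r[i],
                 best, 1, (int)i);
  if (d[2] > 1e-16) {
    double t = (g.zlen - p[2]) / d[2];
    if (t > EPS_T && t < best.t) { best.t = t; best.kind = 2; best.idx = 1; }
  } else if (d[2] < -1e-16) {
    double t = (0.0 - p[2]) / d[2];
    if (t > EPS_T && t < best.t) { best.t = t; best.kind = 2; best.idx = 0; }
  }
  return best;
}

// Henyey-Greenstein cos(theta) sample
inline double hg_cost(double g, double u) {
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 + g - 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
  return c;
}

// rotate direction d by (cost, phi) about itself (standard MC frame update)
inline void deflect(double d[3], double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cosp = std::cos(phi), sinp = std::sin(phi);
  double ux = d[0], uy = d[1], uz = d[2];
  if (std::fabs(uz) > 0.99999) {
    d[0] = sint * cosp;
    d[1] = sint * sinp;
    d[2] = (uz >= 0.0) ? cost : -cost;
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    d[0] = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
    d[1] = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
    d[2] = -sint * cosp * den + uz * cost;
  }
  double nrm = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
}

// unpolarized Fresnel reflectance; ci = cos(incidence) > 0
inline double fresnel_R(double n1, double n2, double ci, double &ct) {
  double sin2t = (n1 / n2) * (n1 / n2) * (1.0 - ci * ci);
  if (sin2t >= 1.0) { ct = 0.0; return 1.0; }  // total internal reflection
  ct = std::sqrt(1.0 - sin2t);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

inline double ang_dist_deg(double a, double b) {
  double d = std::fabs(a - b);
  d -= 360.0 * std::floor(d / 360.0);
  return d > 180.0 ? 360.0 - d : d;
}

}  // namespace

// [[Rcpp::export]]
List mc_transport(NumericMatrix annuli, NumericMatrix cylinders,
                  NumericMatrix props, LogicalVector is_micro,
                  LogicalVector is_artery,
                  double outer_radius, double zlen,
                  double led_angle, double led_aperture,
                  double pd_angle, double pd_aperture, double axial_extent,
                  int n_photons, double seed,
                  double roulette_threshold, double roulette_survival,
                  int max_steps, bool collimated, double n_ambient) {
  Geometry g;
  g.outer_radius = outer_radius; g.zlen = zlen;
  for (int i = 0; i < annuli.nrow(); ++i) {
    g.ann_rin.push_back(annuli(i, 0));
    g.ann_rout.push_back(annuli(i, 1));
    g.ann_reg.push_back((int)annuli(i, 2));
    if (annuli(i, 0) > 1e-12) g.shells.push_back(annuli(i, 0));
    g.shells.push_back(annuli(i, 1));
  }
  for (int i = 0; i < cylinders.nrow(); ++i) {
    g.cyl_cx.push_back(cylinders(i, 0));
    g.cyl_cy.push_back(cylinders(i, 1));
    g.cyl_r.push_back(cylinders(i, 2));
    g.cyl_reg.push_back((int)cylinders(i, 3));
  }
  // dedupe shells
  std::sort(g.shells.begin(), g.shells.end());
  g.shells.erase(std::unique(g.shells.begin(), g.shells.end(),
                 [](double a, double b){ return std::fabs(a - b) < 1e-12; }),
                 g.shells.end());

  const int K = props.nrow();
  const double deg2rad = M_PI / 180.0;
  const double z_center = zlen / 2.0;

  double launched = 0.0, absorbed = 0.0, escaped = 0.0;
  double detected = 0.0, det_micro = 0.0, det_artery = 0.0;
  long det_count = 0, det_micro_count = 0, det_artery_count = 0;
  long n_capped = 0;

  uint64_t base = static_cast<uint64_t>(seed);

  for (int ph = 0; ph < n_photons; ++ph) {
    Xoshiro256 rng;
    uint64_t sd = base ^ (0xD1342543DE82EF95ULL * (static_cast<uint64_t>(ph) + 1ULL));
    rng.seed(sd);

    // launch on LED patch, just inside the outer boundary
    double a0 = (led_angle + led_aperture * (rng.unif() - 0.5)) * deg2rad;
    double z0 = z_center + axial_extent * (rng.unif() - 0.5);
    double r0 = outer_radius - EPS_PUSH;
    double p[3] = { r0 * std::cos(a0), r0 * std::sin(a0), z0 };
    // inward surface normal at the launch point
    double nin[3] = { -std::cos(a0), -std::sin(a0), 0.0 };
    double d[3];
    if (collimated) {
      d[0] = nin[0]; d[1] = nin[1]; d[2] = nin[2];
    } else {
      // Lambertian about the inward normal: cos(theta) = sqrt(u)
      double ct = std::sqrt(rng.unif());
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * rng.unif();
      // tangent frame (t1 along circumference, t2 along z)
      double t1[3] = { -nin[1], nin[0], 0.0 };
      double t2[3] = { 0.0, 0.0, 1.0 };
      for (int k = 0; k < 3; ++k)
        d[k] = ct * nin[k] + st * (std::cos(phi) * t1[k] + std::sin(phi) * t2[k]);
    }

    double w = 1.0;
    launched += 1.0;
    uint32_t flags = 0;
    int reg = g.locate(p[0], p[1], p[2]);
    if (reg == AMBIENT) { escaped += w; continue; }  // degenerate geometry
    bool alive = true;
    int step = 0;

    while (alive) {
      if (++step > max_steps) { absorbed += w; ++n_capped; alive = false; break; }
      flags |= (1u << reg);
      double mu_a = props(reg, 0), mu_s = props(reg, 1);
      double gg = props(reg, 2), n1 = props(reg, 3);
      double mu_t = mu_a + mu_s;
      double s = (mu_t > 0.0) ? -std::log(rng.unif()) / mu_t
                              : std::numeric_limits<double>::infinity();
      Hit hit = next_boundary(g, p, d);
      if (!std::isfinite(hit.t) && !std::isfinite(s)) {  // should not happen
        absorbed += w; alive = false; break;
      }
      if (s < hit.t) {
        // interaction inside the current region
        p[0] += s * d[0]; p[1] += s * d[1]; p[2] += s * d[2];
        double da = w * mu_a / mu_t;
        absorbed += da; w -= da;
        double cost = hg_cost(gg, rng.unif());
        double phi = 2.0 * M_PI * rng.unif();
        deflect(d, cost, phi);
        if (w < roulette_threshold) {
          if (rng.unif() < roulette_survival) {
            // survival boost debited from the absorbed tally: keeps
            // launched = absorbed + escaped + detected exact per run
            double boost = w * (1.0 / roulette_survival - 1.0);
            absorbed -= boost; w += boost;
          } else {
            absorbed += w; w = 0.0; alive = false;
          }
        }
      } else {
        // advance to the boundary surface
        p[0] += hit.t * d[0]; p[1] += hit.t * d[1]; p[2] += hit.t * d[2];
        if (hit.kind == 2) {            // absorbing end cap
          escaped += w; alive = false; break;
        }
        // surface normal, oriented against the direction of travel
        double nx, ny;
        if (hit.kind == 0) { nx = p[0]; ny = p[1]; }
        else { nx = p[0] - g.cyl_cx[hit.idx]; ny = p[1] - g.cyl_cy[hit.idx]; }
        double nn = std::sqrt(nx * nx + ny * ny);
        if (nn < 1e-14) { nx = 1.0; ny = 0.0; } else { nx /= nn; ny /= nn; }
        double ci = -(d[0] * nx + d[1] * ny);
        if (ci < 0.0) { nx = -nx; ny = -ny; ci = -ci; }
        if (ci > 1.0) ci = 1.0;
        // region on the far side
        double q[3] = { p[0] + EPS_PUSH * d[0], p[1] + EPS_PUSH * d[1],
                        p[2] + EPS_PUSH * d[2] };
        int reg2 = g.locate(q[0], q[1], q[2]);
        double n2 = (reg2 == AMBIENT) ? n_ambient : props(reg2, 3);
        if (std::fabs(n1 - n2) < 1e-12) {
          // index matched: pass through
          if (reg2 == AMBIENT) {
            double ang = std::atan2(p[1], p[0]) / deg2rad;
            if (ang < 0.0) ang += 360.0;
            bool on_pd = ang_dist_deg(ang, pd_angle) <= pd_aperture / 2.0 &&
                         std::fabs(p[2] - z_center) <= axial_extent / 2.0;
            if (on_pd) {
              detected += w; ++det_count;
              bool mic = false, art = false;
              for (int r2 = 0; r2 < K; ++r2) {
                if (flags & (1u << r2)) {
                  if (is_micro[r2]) mic = true;
                  if (is_artery[r2]) art = true;
                }
              }
              if (mic) { det_micro += w; ++det_micro_count; }
              if (art) { det_artery += w; ++det_artery_count; }
            } else {
              escaped += w;
            }
            alive = false;
          } else {
            p[0] = q[0]; p[1] = q[1]; p[2] = q[2];
            reg = reg2;
          }
        } else {
          double ct;
          double R = fresnel_R(n1, n2, ci, ct);
          if (rng.unif() < R) {
            // specular reflection, stay in current region
            d[0] += 2.0 * ci * nx;
            d[1] += 2.0 * ci * ny;
            double nrm = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
            d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
            // nudge back into the current region along the (new) direction
            p[0] += EPS_PUSH * d[0]; p[1] += EPS_PUSH * d[1]; p[2] += EPS_PUSH * d[2];
          } else {
            // refract (Snell)
            double eta = n1 / n2;
            d[0] = eta * d[0] + (eta * ci - ct) * nx;
            d[1] = eta * d[1] + (eta * ci - ct) * ny;
            d[2] = eta * d[2];
            double nrm = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
            d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
            if (reg2 == AMBIENT) {
              double ang = std::atan2(p[1], p[0]) / deg2rad;
              if (ang < 0.0) ang += 360.0;
              bool on_pd = ang_dist_deg(ang, pd_angle) <= pd_aperture / 2.0 &&
                           std::fabs(p[2] - z_center) <= axial_extent / 2.0;
              if (on_pd) {
                detected += w; ++det_count;
                bool mic = false, art = false;
                for (int r2 = 0; r2 < K; ++r2) {
                  if (flags & (1u << r2)) {
                    if (is_micro[r2]) mic = true;
                    if (is_artery[r2]) art = true;
                  }
                }
                if (mic) { det_micro += w; ++det_micro_count; }
                if (art) { det_artery += w; ++det_artery_count; }
              } else {
                escaped += w;
              }
              alive = false;
            } else {
              p[0] += EPS_PUSH * d[0]; p[1] += EPS_PUSH * d[1]; p[2] += EPS_PUSH * d[2];
              reg = reg2;
            }
          }
        }
      }
    }
  }

  return List::create(
    _["launched_weight"] = launched,
    _["absorbed_weight"] = absorbed,
    _["escaped_weight"] = escaped,
    _["detected_weight"] = detected,
    _["detected_weight_through_microcirculation"] = det_micro,
    _["detected_weight_through_artery"] = det_artery,
    _["detected_count"] = (double)det_count,
    _["detected_micro_count"] = (double)det_micro_count,
    _["detected_artery_count"] = (double)det_artery_count,
    _["n_step_capped"] = (double)n_capped);
}
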