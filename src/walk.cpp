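// Correlated random-walk stepping inside a patch-corridor landscape with
// specular wall reflection. Hot path of the ground-truth generator and the
// null movement model; semantics mirror the R reference implementation
// (reflect_path) tested against it.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Geom {
  double P, W, L, xlo, xhi, block_y;
  bool corridor, blocked;

  bool inside(double x, double y) const {
    if (x < 0 || x >= W || y < 0) return false;
    if (y < P) return true;
    if (!corridor) return false;
    if (y < P + L) return x >= xlo && x < xhi;
    return y < 2 * P + L;
  }

  // zone code: 0 Start, 1 Corridor, 2 Target, 3 Control
  int zone(double, double y) const {
    if (!corridor) return 3;
    if (y < P) return 0;
    if (y < P + L) return 1;
    return 2;
  }
};

struct Wall {
  int orient; // 0 vertical (x = pos), 1 horizontal (y = pos)
  double pos, lo, hi;
};

void build_walls(const Geom &g, std::vector<Wall> &w) {
  w.clear();
  double P = g.P, W = g.W, L = g.L;
  if (!g.corridor) {
    w.push_back({1, 0.0, 0.0, W});
    w.push_back({1, P, 0.0, W});
    w.push_back({0, 0.0, 0.0, P});
    w.push_back({0, W, 0.0, P});
  } else {
    double PL = P + L, TT = 2 * P + L;
    w.push_back({1, 0.0, 0.0, W});
    w.push_back({1, TT, 0.0, W});
    w.push_back({0, 0.0, 0.0, P});
    w.push_back({0, 0.0, PL, TT});
    w.push_back({0, W, 0.0, P});
    w.push_back({0, W, PL, TT});
    w.push_back({0, g.xlo, P, PL});
    w.push_back({0, g.xhi, P, PL});
    w.push_back({1, P, 0.0, g.xlo});
    w.push_back({1, P, g.xhi, W});
    w.push_back({1, PL, 0.0, g.xlo});
    w.push_back({1, PL, g.xhi, W});
  }
  if (g.blocked) w.push_back({1, g.block_y, 0.0, W});
}

const double EPS = 1e-9;

// Specular reflection of (x0,y0)->(x1,y1); returns final point and whether
// the heading's x/y component must flip (odd number of bounces per axis).
void reflect_path(double x0, double y0, double &x1, double &y1,
                  bool &flip_x, bool &flip_y, const std::vector<Wall> &walls) {
  flip_x = flip_y = false;
  for (int it = 0; it < 24; ++it) {
    double dx = x1 - x0, dy = y1 - y0;
    double best_t = R_PosInf;
    int best_j = -1;
    for (size_t j = 0; j < walls.size(); ++j) {
      const Wall &w = walls[j];
      double t, c;
      if (w.orient == 0) {
        if (std::fabs(dx) < EPS) continue;
        t = (w.pos - x0) / dx;
        if (t <= EPS || t > 1) continue;
        c = y0 + t * dy;
      } else {
        if (std::fabs(dy) < EPS) continue;
        t = (w.pos - y0) / dy;
        if (t <= EPS || t > 1) continue;
        c = x0 + t * dx;
      }
      if (c < walls[j].lo - EPS || c > walls[j].hi + EPS) continue;
      if (t < best_t) { best_t = t; best_j = (int)j; }
    }
    if (best_j < 0) break;
    const Wall &w = walls[best_j];
    if (w.orient == 0) {
      double yc = y0 + best_t * (y1 - y0);
      x1 = 2 * w.pos - x1;
      flip_x = !flip_x;
      x0 = w.pos + ((x0 > w.pos) - (x0 < w.pos)) * EPS;
      y0 = yc;
    } else {
      double xc = x0 + best_t * (x1 - x0);
      y1 = 2 * w.pos - y1;
      flip_y = !flip_y;
      y0 = w.pos + ((y0 > w.pos) - (y0 < w.pos)) * EPS;
      x0 = xc;
    }
  }
}

} // namespace

// Advance agents by n_steps of a correlated random walk. One normal deviate
// per agent per step is drawn from R's RNG stream (agent order), so results
// are reproducible under set.seed() and identical to the R reference.
//
// geom: c(patch_length, patch_width, corridor_length, band_lo, band_hi,
//         has_corridor, block_y [NA if none])
// turn_sd_step: per-agent SD of the turning angle for one step (already
//   scaled by sqrt(dt / dt_ref)). When modulate is true, speed and turn SD
//   are multiplied per step by the zone multipliers (Start, Corridor,
//   Target, Control) of each agent's current zone.
// [[Rcpp::export]]
List cpp_step_agents(NumericVector x, NumericVector y, NumericVector heading,
                     NumericVector speed_um_s, NumericVector turn_sd_step,
                     double dt, int n_steps, NumericVector geom,
                     bool modulate, NumericVector speed_mult,
                     NumericVector turn_mult) {
  int n = x.size();
  Geom g;
  g.P = geom[0]; g.W = geom[1]; g.L = geom[2];
  g.xlo = geom[3]; g.xhi = geom[4];
  g.corridor = geom[5] > 0.5;
  g.blocked = !NumericVector::is_na(geom[6]);
  g.block_y = g.blocked ? geom[6] : -1.0;

  std::vector<Wall> walls;
  build_walls(g, walls);

  NumericVector ox = clone(x), oy = clone(y), oh = clone(heading);
  for (int s = 0; s < n_steps; ++s) {
    for (int i = 0; i < n; ++i) {
      double sd = turn_sd_step[i], sp = speed_um_s[i];
      if (modulate) {
        int z = g.zone(ox[i], oy[i]);
        sd *= turn_mult[z];
        sp *= speed_mult[z];
      }
      double h = oh[i] + norm_rand() * sd;
      double step = sp * dt / 1000.0;
      double px = ox[i] + step * std::cos(h);
      double py = oy[i] + step * std::sin(h);
      bool out = !g.inside(px, py);
      if (g.blocked && (oy[i] - g.block_y) * (py - g.block_y) < 0) out = true;
      if (out) {
        bool fx, fy;
        double rx = px, ry = py;
        reflect_path(ox[i], oy[i], rx, ry, fx, fy, walls);
        bool ok = g.inside(rx, ry);
        if (ok && g.blocked &&
            (oy[i] - g.block_y) * (ry - g.block_y) < 0) ok = false;
        if (ok) {
          px = rx; py = ry;
          double hx = std::cos(h) * (fx ? -1.0 : 1.0);
          double hy = std::sin(h) * (fy ? -1.0 : 1.0);
          h = std::atan2(hy, hx);
        } else {
          px = ox[i]; py = oy[i];
          h = h + M_PI;
        }
      }
      ox[i] = px; oy[i] = py; oh[i] = h;
    }
  }
  return List::create(_["x"] = ox, _["y"] = oy, _["heading"] = oh);
}
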