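#include <Rcpp.h>
using namespace Rcpp;

// Correlated random walk of the anchor point with bout-structured seeking
// and reflecting chamber walls. The walker alternates between exploration
// (heading = normalize(rho*h + (1-rho)*noise)) and seeking bouts during
// which a drift term seek_weight*unit(target-pos) joins the blend. Bouts
// start with per-frame probability seek_prob and end on arrival within
// attract_radius of the target, so lever attraction controls how often the
// walker approaches the lever. Step lengths are exponential with mean
// step_mean, scaled by seek_speed during a bout: goal-directed approach
// runs faster than exploratory ambling, so seeking propensity expresses in
// both lever approach and locomotion, as in the behavioral phenotype. Uses
// R's RNG so results are reproducible from set.seed().
// [[Rcpp::export]]
List crw_core(int n_frames, double rho, double step_mean,
              NumericVector chamber, NumericVector attract_pt,
              NumericVector start, double attract_radius,
              double seek_prob, double seek_weight, double seek_speed) {
  NumericMatrix pos(n_frames, 2);
  NumericMatrix head(n_frames, 2);
  LogicalVector seek(n_frames);
  const double xmin = chamber[0], xmax = chamber[1];
  const double ymin = chamber[2], ymax = chamber[3];
  double px = start[0], py = start[1];
  double a = R::runif(0.0, 2.0 * M_PI);
  double hx = std::cos(a), hy = std::sin(a);
  bool seeking = false;
  pos(0, 0) = px; pos(0, 1) = py;
  head(0, 0) = hx; head(0, 1) = hy;
  seek[0] = false;
  for (int t = 1; t < n_frames; ++t) {
    double dx = attract_pt[0] - px, dy = attract_pt[1] - py;
    double dn = std::sqrt(dx * dx + dy * dy);
    if (!seeking && seek_prob > 0.0 && R::unif_rand() < seek_prob) {
      seeking = true;
    }
    if (seeking && dn <= attract_radius) {
      seeking = false;  // arrived
    }
    double nx = R::rnorm(0.0, 1.0), ny = R::rnorm(0.0, 1.0);
    double nn = std::sqrt(nx * nx + ny * ny);
    if (nn > 0) { nx /= nn; ny /= nn; }
    double vx = rho * hx + (1.0 - rho) * nx;
    double vy = rho * hy + (1.0 - rho) * ny;
    if (seeking && dn > 1e-9) {
      vx += seek_weight * dx / dn;
      vy += seek_weight * dy / dn;
    }
    double vn = std::sqrt(vx * vx + vy * vy);
    if (vn < 1e-12) { vx = nx; vy = ny; vn = 1.0; }
    hx = vx / vn; hy = vy / vn;
    double mu = seeking ? step_mean * seek_speed : step_mean;
    double step = mu > 0 ? R::rexp(mu) : 0.0;
    px += step * hx;
    py += step * hy;
    for (int k = 0; k < 16; ++k) {  // mirror until inside (long steps)
      bool refl = false;
      if (px < xmin) { px = 2 * xmin - px; hx = -hx; refl = true; }
      if (px > xmax) { px = 2 * xmax - px; hx = -hx; refl = true; }
      if (py < ymin) { py = 2 * ymin - py; hy = -hy; refl = true; }
      if (py > ymax) { py = 2 * ymax - py; hy = -hy; refl = true; }
      if (!refl) break;
    }
    px = std::min(std::max(px, xmin), xmax);
    py = std::min(std::max(py, ymin), ymax);
    pos(t, 0) = px; pos(t, 1) = py;
    head(t, 0) = hx; head(t, 1) = hy;
    seek[t] = seeking;
  }
  return List::create(_["pos"] = pos, _["heading"] = head,
                      _["seeking"] = seek);
}
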