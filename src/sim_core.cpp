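#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-second stochastic stepper for one individual in a circular arena.
//
// Behavioural states: 0 = roaming, 1 = dwelling, 2 = quiescent.
// Roaming draws exponential speeds around speedScale with a persistent
// heading (wrapped-normal turning noise, sd = 1/sqrt(kappa)); dwelling is
// isotropic small-amplitude jitter at dwellSpeedFrac * speedScale;
// quiescence is strictly stationary.  The `activity` vector (one value per
// step) multiplies the dwell->roam entry probability, which is how aging and
// day-level volatility modulate movement.  Boundary handling is specular
// velocity reflection plus a radial bias toward the annulus at
// edgeRadiusFrac * arenaR ("coffee-ring" occupancy).  Every realised
// per-step displacement is clamped to maxSpeed * dt, including after
// reflection, so the speed bound holds exactly.
//
// Uses R's RNG (RNGScope via Rcpp attributes), so results are reproducible
// under set.seed() on the R side.
// [[Rcpp::export]]
NumericMatrix simCoreCpp(int nSteps, double dt, double arenaR,
                         NumericVector activity,
                         double pRoamToDwell, double pDwellToRoam,
                         double pDwellToQuiescent, double pQuiescentToDwell,
                         double speedScale, double dwellSpeedFrac,
                         double kappa, double edgePull, double edgeRadiusFrac,
                         double maxSpeed,
                         double x0, double y0, double heading0) {
  if (activity.size() < nSteps)
    stop("activity vector shorter than nSteps");
  NumericMatrix pos(nSteps + 1, 2);
  double x = x0, y = y0, heading = heading0;
  int state = 1;
  const double sigmaTurn = (kappa > 0.0) ? 1.0 / std::sqrt(kappa) : M_PI;
  const double dwellSpeed = dwellSpeedFrac * speedScale;
  const double ringR = edgeRadiusFrac * arenaR;
  const double maxStep = maxSpeed * dt;
  pos(0, 0) = x;
  pos(0, 1) = y;
  for (int i = 0; i < nSteps; ++i) {
    const double a = activity[i];
    const double u = unif_rand();
    if (state == 0) {
      if (u < pRoamToDwell) state = 1;
    } else if (state == 1) {
      double pr = pDwellToRoam * a;
      if (pr > 1.0) pr = 1.0;
      if (u < pr) state = 0;
      else if (u < pr + pDwellToQuiescent) state = 2;
    } else {
      if (u < pQuiescentToDwell) state = 1;
    }
    double dx = 0.0, dy = 0.0;
    if (state == 0) {
      heading += norm_rand() * sigmaTurn;
      double sp = -speedScale * std::log(unif_rand());
      if (sp > maxSpeed) sp = maxSpeed;
      dx = sp * dt * std::cos(heading);
      dy = sp * dt * std::sin(heading);
    } else if (state == 1) {
      const double th = unif_rand() * 2.0 * M_PI;
      double sp = -dwellSpeed * std::log(unif_rand());
      if (sp > maxSpeed) sp = maxSpeed;
      dx = sp * dt * std::cos(th);
      dy = sp * dt * std::sin(th);
    }
    if (state != 2 && edgePull > 0.0) {
      const double r = std::sqrt(x * x + y * y);
      if (r > 1e-9) {
        const double stepLen = std::sqrt(dx * dx + dy * dy);
        const double pull = edgePull * stepLen * (ringR - r) / arenaR;
        dx += pull * x / r;
        dy += pull * y / r;
      }
    }
    {  // speed bound before the move
      const double stepLen = std::sqrt(dx * dx + dy * dy);
      if (stepLen > maxStep) {
        dx *= maxStep / stepLen;
        dy *= maxStep / stepLen;
      }
    }
    double xn = x + dx, yn = y + dy;
    double r = std::sqrt(xn * xn + yn * yn);
    if (r > arenaR) {
      // specular reflection of the velocity about the tangent at contact,
      // position folded radially back inside
      const double nx = xn / r, ny = yn / r;
      const double vdotn = dx * nx + dy * ny;
      const double rdx = dx - 2.0 * vdotn * nx;
      const double rdy = dy - 2.0 * vdotn * ny;
      heading = std::atan2(rdy, rdx);
      double rNew = 2.0 * arenaR - r;
      if (rNew < 0.0) rNew = 0.0;
      xn *= rNew / r;
      yn *= rNew / r;
      // re-clamp the realised chord so the per-frame speed bound still holds
      const double cdx = xn - x, cdy = yn - y;
      const double chord = std::sqrt(cdx * cdx + cdy * cdy);
      if (chord > maxStep) {
        xn = x + cdx * maxStep / chord;
        yn = y + cdy * maxStep / chord;
      }
    }
    x = xn;
    y = yn;
    pos(i + 1, 0) = x;
    pos(i + 1, 1) = y;
  }
  return pos;
}

// Within-block bootstrap of a decline slope.
//
// blockEntries: list of numeric vectors, the retained displacement entries
// (um) of each block; blockTimes: block start times in days.  Each
// replicate resamples every block's entries with replacement (preserving the
// entry count), sums them to a resampled block total (converted to mm) and
// takes the OLS slope of total vs time.  Blocks with no retained entries
// contribute a fixed total of 0.  Returns nBoot slopes (mm per block per
// day).  Uses R's RNG.
// [[Rcpp::export]]
NumericVector bootSlopesCpp(List blockEntries, NumericVector blockTimes,
                            int nBoot) {
  const int B = blockEntries.size();
  if (B != blockTimes.size())
    stop("blockEntries and blockTimes lengths differ");
  double tbar = 0.0;
  for (int b = 0; b < B; ++b) tbar += blockTimes[b];
  tbar /= B;
  double sxx = 0.0;
  for (int b = 0; b < B; ++b) {
    const double d = blockTimes[b] - tbar;
    sxx += d * d;
  }
  if (sxx <= 0.0) stop("zero variance in block times");
  std::vector<std::vector<double> > entries(B);
  std::vector<double> w(B);
  for (int b = 0; b < B; ++b) {
    entries[b] = as<std::vector<double> >(blockEntries[b]);
    w[b] = (blockTimes[b] - tbar) / sxx;
  }
  NumericVector out(nBoot);
  for (int rep = 0; rep < nBoot; ++rep) {
    double slope = 0.0;
    for (int b = 0; b < B; ++b) {
      const int m = (int)entries[b].size();
      double s = 0.0;
      for (int j = 0; j < m; ++j) {
        int k = (int)(unif_rand() * m);
        if (k >= m) k = m - 1;
        s += entries[b][k];
      }
      slope += w[b] * (s / 1000.0);
    }
    out[rep] = slope;
  }
  return out;
}
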