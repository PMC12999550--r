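#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Product-limit machinery for right-censored, optionally left-truncated
// (delayed entry) data.  Risk set at t is Y(t) = #{j : L_j < t <= T_j}:
// a truncated subject enters the risk set strictly after its entry time.
// Tied events are aggregated; censored observations tied with an event
// time remain in the risk set for that event.

struct KmPoint {
  double time;
  int nrisk;
  int nevent;
  double surv;
};

static std::vector<KmPoint> km_points(const NumericVector &time,
                                      const IntegerVector &status,
                                      const NumericVector &entry) {
  const int n = time.size();
  std::vector<std::pair<double, unsigned char>> obs(n);
  bool truncated = false;
  for (int i = 0; i < n; ++i) {
    obs[i] = {time[i], static_cast<unsigned char>(status[i])};
    if (entry[i] > 0.0) truncated = true;
  }
  std::sort(obs.begin(), obs.end(),
            [](const std::pair<double, unsigned char> &a,
               const std::pair<double, unsigned char> &b) {
              return a.first < b.first;
            });
  std::vector<double> ent;
  if (truncated) {
    ent.assign(entry.begin(), entry.end());
    std::sort(ent.begin(), ent.end());
  }

  std::vector<KmPoint> pts;
  pts.reserve(64);
  double surv = 1.0;
  int it = 0;   // #{time < t} as we advance
  int ie = 0;   // #{entry < t}
  while (it < n) {
    const double t = obs[it].first;
    int d = 0, tied = 0;
    while (it + tied < n && obs[it + tied].first == t) {
      if (obs[it + tied].second == 1) ++d;
      ++tied;
    }
    if (truncated) {
      while (ie < n && ent[ie] < t) ++ie;
    } else {
      ie = n;  // all entries are 0 < t for any positive time
    }
    if (d > 0) {
      const int Y = ie - it;  // #{entry < t} - #{time < t}
      // Y >= d by construction (every event at t is in the risk set)
      surv *= 1.0 - static_cast<double>(d) / static_cast<double>(Y);
      if (surv < 0.0) surv = 0.0;
      pts.push_back({t, Y, d, surv});
    }
    it += tied;
  }
  return pts;
}

// [[Rcpp::export(name = ".km_curve_cpp")]]
List km_curve_cpp(NumericVector time, IntegerVector status,
                  NumericVector entry) {
  std::vector<KmPoint> pts = km_points(time, status, entry);
  const int k = pts.size();
  NumericVector t(k), s(k);
  IntegerVector y(k), d(k);
  for (int i = 0; i < k; ++i) {
    t[i] = pts[i].time;
    y[i] = pts[i].nrisk;
    d[i] = pts[i].nevent;
    s[i] = pts[i].surv;
  }
  return List::create(_["time"] = t, _["n_risk"] = y, _["n_event"] = d,
                      _["surv"] = s, _["n"] = time.size());
}

// RMST point estimate and Greenwood-type variance on [0, tau].
// Returns (mu, var, n_events_within_tau).
// [[Rcpp::export(name = ".rmst_arm_cpp")]]
NumericVector rmst_arm_cpp(NumericVector time, IntegerVector status,
                           NumericVector entry, double tau) {
  std::vector<KmPoint> pts = km_points(time, status, entry);
  double area = 0.0, tprev = 0.0, sprev = 1.0;
  int nev = 0;
  std::vector<double> cumarea;  // area on [0, t_i] for event times <= tau
  std::vector<int> used;
  cumarea.reserve(pts.size());
  used.reserve(pts.size());
  for (size_t i = 0; i < pts.size(); ++i) {
    if (pts[i].time > tau) break;
    area += sprev * (pts[i].time - tprev);
    cumarea.push_back(area);
    used.push_back(static_cast<int>(i));
    nev += pts[i].nevent;
    tprev = pts[i].time;
    sprev = pts[i].surv;
  }
  area += sprev * (tau - tprev);
  const double mu = area;
  double var = 0.0;
  for (size_t j = 0; j < used.size(); ++j) {
    const KmPoint &p = pts[used[j]];
    if (p.nrisk <= p.nevent) continue;  // curve hit zero: residual area is 0
    const double A = mu - cumarea[j];   // area of S on (t_i, tau]
    var += A * A * static_cast<double>(p.nevent) /
           (static_cast<double>(p.nrisk) *
            static_cast<double>(p.nrisk - p.nevent));
  }
  return NumericVector::create(mu, var, static_cast<double>(nev));
}
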