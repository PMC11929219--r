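#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Objective codes: 0 = euclidean, 1 = squared euclidean, 2 = travel cost.
// Travel cost needs the overhead-ratio matrix, per-patient cached nearest
// anchor, bus-stop distance and age, plus the tariff parameters; stations'
// nearest anchors are recomputed whenever a centroid moves (O(K) scan).
struct Objective {
  int code;
  int n;
  const double *px, *py, *w;
  // travel-cost fields
  const int *pa;        // patient anchor index, 0-based
  const double *busd;   // Euclidean distance to nearest bus stop (m)
  const double *age;    // years
  NumericMatrix ratio;  // K x K overhead ratios (NA = unreachable)
  const double *ax, *ay;
  int K;
  double walk_th, bus_th, bus_fare, taxi_age, car_km, taxi_base, taxi_km,
      trips;
  const int *prec;      // mode precedence, codes 0 walk 1 taxi 2 bus 3 car
  int nprec;
};

static int nearest_anchor(const Objective &o, double x, double y) {
  int best = 0;
  double bd = R_PosInf;
  for (int a = 0; a < o.K; ++a) {
    double dx = o.ax[a] - x, dy = o.ay[a] - y;
    double d = dx * dx + dy * dy;
    if (d < bd) { bd = d; best = a; }
  }
  return best;
}

// Cost of serving patient i from a station at (sx, sy) whose nearest anchor
// is sa (ignored unless code == 2). Unweighted (per visit / per patient).
static double pair_cost(const Objective &o, int i, double sx, double sy,
                        int sa) {
  double dx = o.px[i] - sx, dy = o.py[i] - sy;
  double de2 = dx * dx + dy * dy;
  if (o.code == 1) return de2;
  double de = std::sqrt(de2);
  if (o.code == 0) return de;
  double r = o.ratio(o.pa[i], sa);
  if (ISNAN(r))
    stop("patient-station pair is unreachable under the travel-cost objective");
  double d = de * r;  // estimated road distance, metres
  for (int m = 0; m < o.nprec; ++m) {
    switch (o.prec[m]) {
    case 0: if (de < o.walk_th) return 0.0; break;
    case 1:
      if (o.age[i] >= o.taxi_age)
        return o.trips * (o.taxi_base + o.taxi_km * d / 1000.0);
      break;
    case 2: if (o.busd[i] < o.bus_th) return o.trips * o.bus_fare; break;
    case 3: return o.trips * o.car_km * d / 1000.0;
    }
  }
  return o.trips * o.car_km * d / 1000.0;  // car as fall-through
}

static Objective make_objective(List spec) {
  Objective o;
  o.code = as<int>(spec["code"]);
  NumericVector px = spec["px"], py = spec["py"], w = spec["w"];
  o.n = px.size();
  o.px = px.begin(); o.py = py.begin(); o.w = w.begin();
  o.K = 0; o.nprec = 0;
  o.pa = NULL; o.busd = NULL; o.age = NULL; o.ax = NULL; o.ay = NULL;
  o.prec = NULL;
  if (o.code == 2) {
    IntegerVector pa = spec["pa"];
    NumericVector busd = spec["busd"], age = spec["age"];
    NumericMatrix ratio = spec["ratio"];
    NumericVector ax = spec["ax"], ay = spec["ay"];
    NumericVector par = spec["params"];
    IntegerVector prec = spec["prec"];
    o.pa = pa.begin(); o.busd = busd.begin(); o.age = age.begin();
    o.ratio = ratio; o.ax = ax.begin(); o.ay = ay.begin();
    o.K = ax.size();
    o.walk_th = par[0]; o.bus_th = par[1]; o.bus_fare = par[2];
    o.taxi_age = par[3]; o.car_km = par[4]; o.taxi_base = par[5];
    o.taxi_km = par[6]; o.trips = par[7];
    o.prec = prec.begin(); o.nprec = prec.size();
  }
  return o;
}

static void station_anchors(const Objective &o, const std::vector<double> &cx,
                            const std::vector<double> &cy,
                            std::vector<int> &sa) {
  if (o.code != 2) return;
  int k = cx.size();
  sa.resize(k);
  for (int j = 0; j < k; ++j) sa[j] = nearest_anchor(o, cx[j], cy[j]);
}

// Assign every patient to its cost-minimizing station (ties: lowest index).
// Returns the weighted total objective; fills assignment and per-patient
// minimum (unweighted) cost. The Euclidean objectives share the
// squared-distance argmin (monotone transform), so both use a tight
// vectorizable loop; sqrt is applied once per patient for the plain
// Euclidean cost.
static double assign_all(const Objective &o, const std::vector<double> &cx,
                         const std::vector<double> &cy,
                         const std::vector<int> &sa, std::vector<int> &assign,
                         std::vector<double> &mincost) {
  int k = cx.size();
  double total = 0.0;
  if (o.code != 2) {
    for (int i = 0; i < o.n; ++i) {
      double xi = o.px[i], yi = o.py[i];
      int best = 0;
      double bc = R_PosInf;
      for (int j = 0; j < k; ++j) {
        double dx = xi - cx[j], dy = yi - cy[j];
        double d2 = dx * dx + dy * dy;
        if (d2 < bc) { bc = d2; best = j; }
      }
      if (o.code == 0) bc = std::sqrt(bc);
      assign[i] = best;
      mincost[i] = bc;
      total += o.w[i] * bc;
    }
    return total;
  }
  for (int i = 0; i < o.n; ++i) {
    int best = 0;
    double bc = pair_cost(o, i, cx[0], cy[0], sa[0]);
    for (int j = 1; j < k; ++j) {
      double c = pair_cost(o, i, cx[j], cy[j], sa[j]);
      if (c < bc) { bc = c; best = j; }
    }
    assign[i] = best;
    mincost[i] = bc;
    total += o.w[i] * bc;
  }
  return total;
}

// Weighted arithmetic-mean centroid update. A station whose cluster empties
// is relocated to the patient currently farthest (largest pair cost) from
// its assigned station; repairs use distinct patients.
static void update_centroids(const Objective &o, const std::vector<int> &assign,
                             const std::vector<double> &mincost,
                             std::vector<double> &cx, std::vector<double> &cy) {
  int k = cx.size();
  std::vector<double> sx(k, 0.0), sy(k, 0.0), sw(k, 0.0);
  for (int i = 0; i < o.n; ++i) {
    int j = assign[i];
    sx[j] += o.w[i] * o.px[i];
    sy[j] += o.w[i] * o.py[i];
    sw[j] += o.w[i];
  }
  std::vector<bool> used(o.n, false);
  for (int j = 0; j < k; ++j) {
    if (sw[j] > 0.0) {
      cx[j] = sx[j] / sw[j];
      cy[j] = sy[j] / sw[j];
    } else {
      int far = -1;
      double fd = -1.0;
      for (int i = 0; i < o.n; ++i)
        if (!used[i] && mincost[i] > fd) { fd = mincost[i]; far = i; }
      if (far >= 0) {
        used[far] = true;
        cx[j] = o.px[far];
        cy[j] = o.py[far];
      }
    }
  }
}

// iters x (assign, update), then a final assignment; returns final cost.
static double kmeans_core(const Objective &o, std::vector<double> &cx,
                          std::vector<double> &cy, int iters,
                          std::vector<int> &assign,
                          std::vector<double> &mincost) {
  std::vector<int> sa;
  for (int it = 0; it < iters; ++it) {
    station_anchors(o, cx, cy, sa);
    assign_all(o, cx, cy, sa, assign, mincost);
    update_centroids(o, assign, mincost, cx, cy);
  }
  station_anchors(o, cx, cy, sa);
  return assign_all(o, cx, cy, sa, assign, mincost);
}

// [[Rcpp::export]]
List cpp_assign(List objective, NumericVector cx, NumericVector cy) {
  Objective o = make_objective(objective);
  std::vector<double> vx(cx.begin(), cx.end()), vy(cy.begin(), cy.end());
  std::vector<int> sa, assign(o.n);
  std::vector<double> mincost(o.n);
  station_anchors(o, vx, vy, sa);
  double total = assign_all(o, vx, vy, sa, assign, mincost);
  IntegerVector a(o.n);
  NumericVector mc(o.n);
  for (int i = 0; i < o.n; ++i) { a[i] = assign[i] + 1; mc[i] = mincost[i]; }
  return List::create(_["assignment"] = a, _["cost"] = total,
                      _["pair_cost"] = mc);
}

// [[Rcpp::export]]
List cpp_kmeans(List objective, NumericVector cx, NumericVector cy,
                int iters) {
  Objective o = make_objective(objective);
  std::vector<double> vx(cx.begin(), cx.end()), vy(cy.begin(), cy.end());
  std::vector<int> assign(o.n);
  std::vector<double> mincost(o.n);
  double cost = kmeans_core(o, vx, vy, iters, assign, mincost);
  IntegerVector a(o.n);
  for (int i = 0; i < o.n; ++i) a[i] = assign[i] + 1;
  return List::create(_["cx"] = NumericVector(vx.begin(), vx.end()),
                      _["cy"] = NumericVector(vy.begin(), vy.end()),
                      _["assignment"] = a, _["cost"] = cost);
}

// Random swap: start from the supplied initial centroids polished by
// `iters` k-means iterations, then T trials of (replace one uniformly
// random station with a uniformly random patient location, polish with
// `iters` k-means iterations, accept iff strictly lower cost). Uses R's
// RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_random_swap(List objective, NumericVector init_cx,
                     NumericVector init_cy, int T, int iters) {
  Objective o = make_objective(objective);
  int k = init_cx.size();
  std::vector<double> cx(init_cx.begin(), init_cx.end()),
      cy(init_cy.begin(), init_cy.end());
  std::vector<int> assign(o.n), cand_assign(o.n);
  std::vector<double> mincost(o.n), cand_mincost(o.n);
  double cost = kmeans_core(o, cx, cy, iters, assign, mincost);
  double init_cost = cost;

  NumericMatrix history(T, 3);  // trial, candidate cost, accepted
  for (int t = 0; t < T; ++t) {
    int j = (int)(unif_rand() * k); if (j >= k) j = k - 1;
    int m = (int)(unif_rand() * o.n); if (m >= o.n) m = o.n - 1;
    std::vector<double> tx = cx, ty = cy;
    tx[j] = o.px[m];
    ty[j] = o.py[m];
    double cand = kmeans_core(o, tx, ty, iters, cand_assign, cand_mincost);
    bool accepted = cand < cost;
    if (accepted) {
      cx.swap(tx); cy.swap(ty);
      assign = cand_assign;
      mincost = cand_mincost;
      cost = cand;
    }
    history(t, 0) = t + 1;
    history(t, 1) = cand;
    history(t, 2) = accepted ? 1.0 : 0.0;
    if (t % 256 == 0) Rcpp::checkUserInterrupt();
  }
  IntegerVector a(o.n);
  NumericVector mc(o.n);
  for (int i = 0; i < o.n; ++i) { a[i] = assign[i] + 1; mc[i] = mincost[i]; }
  return List::create(_["cx"] = NumericVector(cx.begin(), cx.end()),
                      _["cy"] = NumericVector(cy.begin(), cy.end()),
                      _["assignment"] = a, _["cost"] = cost,
                      _["pair_cost"] = mc, _["initial_cost"] = init_cost,
                      _["history"] = history);
}
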