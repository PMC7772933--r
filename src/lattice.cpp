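#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Chain constraints on the cubic lattice, in SQUARED lattice distances:
//   bonded (consecutive) pairs: d2 in {2..10} \ {8}
//   any other pair (excluded volume): d2 >= 2 and d2 != 8
static inline bool bond_ok(int d2) { return d2 >= 2 && d2 <= 10 && d2 != 8; }
static inline bool ev_ok(int d2)   { return d2 >= 2 && d2 != 8; }

static inline int sqdist(const int* a, const int* b) {
  int dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// uniform integer in [0, k)
static inline int randint(int k) {
  int r = (int)(unif_rand() * k);
  return r >= k ? k - 1 : r;
}

// all integer offsets whose squared length is a legal bond length
static std::vector<std::array<int, 3> > bond_offsets() {
  std::vector<std::array<int, 3> > off;
  for (int x = -3; x <= 3; ++x)
    for (int y = -3; y <= 3; ++y)
      for (int z = -3; z <= 3; ++z) {
        int d2 = x * x + y * y + z * z;
        if (bond_ok(d2)) off.push_back({x, y, z});
      }
  return off;
}

// the 26-site Moore neighbourhood (single-site displacement moves)
static std::vector<std::array<int, 3> > moore_offsets() {
  std::vector<std::array<int, 3> > off;
  for (int x = -1; x <= 1; ++x)
    for (int y = -1; y <= 1; ++y)
      for (int z = -1; z <= 1; ++z)
        if (x || y || z) off.push_back({x, y, z});
  return off;
}

static inline bool in_bounds(const int* p, int side) {
  return p[0] >= 0 && p[0] < side && p[1] >= 0 && p[1] < side &&
         p[2] >= 0 && p[2] < side;
}

// is `site` a valid position for bead `u` given all other beads?
static bool site_valid(const std::vector<std::array<int, 3> >& xyz,
                       int u, const int* site, int side) {
  int n = (int)xyz.size();
  if (!in_bounds(site, side)) return false;
  for (int j = 0; j < n; ++j) {
    if (j == u) continue;
    int d2 = sqdist(site, xyz[j].data());
    if (j == u - 1 || j == u + 1) {
      if (!bond_ok(d2)) return false;
    } else {
      if (!ev_ok(d2)) return false;
    }
  }
  return true;
}

// [[Rcpp::export]]
IntegerMatrix cpp_init_chain(int n, int side,
                             Nullable<NumericMatrix> centers_,
                             Nullable<NumericVector> radius_,
                             int backtrack, int restarts) {
  static const std::vector<std::array<int, 3> > BOND = bond_offsets();
  bool constrained = centers_.isNotNull();
  NumericMatrix centers;
  NumericVector radius;
  if (constrained) {
    centers = NumericMatrix(centers_);
    radius = NumericVector(radius_);
  }
  auto in_ball = [&](int k, const int* p) {
    if (!constrained) return true;
    double r = radius[k];
    if (!R_finite(r)) return true;
    double dx = p[0] - centers(k, 0), dy = p[1] - centers(k, 1),
           dz = p[2] - centers(k, 2);
    return dx * dx + dy * dy + dz * dz <= r * r;
  };

  std::vector<std::array<int, 3> > xyz;
  xyz.reserve(n);
  int n_restart = 0, n_backtrack = 0;
  const int backtracks_per_restart = 200;

  while (true) {
    xyz.clear();
    // first bead: uniform over its admissible region (sample the ball's
    // bounding cube when a domain constraint is active)
    {
      std::array<int, 3> p;
      int tries = 0;
      bool boxed = constrained && R_finite(radius[0]);
      do {
        if (boxed) {
          int r = (int)std::ceil(radius[0]);
          for (int d = 0; d < 3; ++d)
            p[d] = (int)std::lround(centers(0, d)) - r + randint(2 * r + 1);
        } else {
          p = {randint(side), randint(side), randint(side)};
        }
        if (++tries > 100000)
          stop("could not place first bead inside its domain constraint");
      } while (!in_bounds(p.data(), side) || !in_ball(0, p.data()));
      xyz.push_back(p);
    }
    bool failed = false;
    while ((int)xyz.size() < n) {
      int k = (int)xyz.size();
      const int* prev = xyz[k - 1].data();
      std::vector<std::array<int, 3> > cand;
      for (const auto& o : BOND) {
        std::array<int, 3> s = {prev[0] + o[0], prev[1] + o[1], prev[2] + o[2]};
        if (!in_bounds(s.data(), side)) continue;
        if (!in_ball(k, s.data())) continue;
        bool ok = true;
        for (int j = 0; j + 1 < k; ++j) {
          if (!ev_ok(sqdist(s.data(), xyz[j].data()))) { ok = false; break; }
        }
        if (ok) cand.push_back(s);
      }
      if (cand.empty()) {
        // dead end: drop up to `backtrack` beads and retry
        int keep = std::max(1, k - backtrack);
        xyz.resize(keep);
        if (++n_backtrack > backtracks_per_restart) { failed = true; break; }
      } else {
        xyz.push_back(cand[randint((int)cand.size())]);
      }
    }
    if (!failed) break;
    n_backtrack = 0;
    if (++n_restart > restarts)
      stop("chain initialization failed after %d restarts", restarts);
  }

  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = xyz[i][d];
  return out;
}

static std::vector<std::array<int, 3> > as_xyz(const IntegerMatrix& m) {
  std::vector<std::array<int, 3> > xyz(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) xyz[i] = {m(i, 0), m(i, 1), m(i, 2)};
  return xyz;
}

// [[Rcpp::export]]
List cpp_propose_move(IntegerMatrix coords, int side) {
  static const std::vector<std::array<int, 3> > MOORE = moore_offsets();
  std::vector<std::array<int, 3> > xyz = as_xyz(coords);
  int n = (int)xyz.size();
  int u = randint(n);
  const auto& o = MOORE[randint(26)];
  std::array<int, 3> s = {xyz[u][0] + o[0], xyz[u][1] + o[1], xyz[u][2] + o[2]};
  bool valid = site_valid(xyz, u, s.data(), side);
  return List::create(_["bead"] = u + 1,
                      _["old_site"] = IntegerVector::create(xyz[u][0], xyz[u][1], xyz[u][2]),
                      _["new_site"] = IntegerVector::create(s[0], s[1], s[2]),
                      _["valid"] = valid);
}

// [[Rcpp::export]]
List cpp_random_moves(IntegerMatrix coords, int side, int n_moves) {
  static const std::vector<std::array<int, 3> > MOORE = moore_offsets();
  std::vector<std::array<int, 3> > xyz = as_xyz(coords);
  int n = (int)xyz.size();
  long applied = 0, trials = 0;
  long max_trials = 1000L * (long)n_moves + 1000L;
  while (applied < n_moves && trials < max_trials) {
    ++trials;
    int u = randint(n);
    const auto& o = MOORE[randint(26)];
    std::array<int, 3> s = {xyz[u][0] + o[0], xyz[u][1] + o[1], xyz[u][2] + o[2]};
    if (site_valid(xyz, u, s.data(), side)) { xyz[u] = s; ++applied; }
  }
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = xyz[i][d];
  return List::create(_["coords"] = out, _["applied"] = (double)applied,
                      _["trials"] = (double)trials);
}

// L = sum_{i<j} w * (d_ij - delta_ij)^2 / delta_ij^2
// [[Rcpp::export]]
double cpp_loss(IntegerMatrix coords, NumericMatrix delta, double w) {
  int n = coords.nrow();
  double L = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int dx = coords(i, 0) - coords(j, 0), dy = coords(i, 1) - coords(j, 1),
          dz = coords(i, 2) - coords(j, 2);
      double d = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
      double t = delta(i, j);
      double r = (d - t) / t;
      L += w * r * r;
    }
  }
  return L;
}

// change in loss from moving bead u (0-based) to new_site; O(n)
static double pair_delta(const std::vector<std::array<int, 3> >& xyz, int u,
                         const int* site, const NumericMatrix& delta, double w) {
  int n = (int)xyz.size();
  double dL = 0.0;
  for (int j = 0; j < n; ++j) {
    if (j == u) continue;
    double dn = std::sqrt((double)sqdist(site, xyz[j].data()));
    double dd = std::sqrt((double)sqdist(xyz[u].data(), xyz[j].data()));
    double t = delta(u, j);
    double rn = (dn - t) / t, ro = (dd - t) / t;
    dL += w * (rn * rn - ro * ro);
  }
  return dL;
}

// [[Rcpp::export]]
double cpp_pair_delta_loss(IntegerMatrix coords, NumericMatrix delta,
                           int bead, IntegerVector new_site, double w) {
  std::vector<std::array<int, 3> > xyz = as_xyz(coords);
  int site[3] = {new_site[0], new_site[1], new_site[2]};
  return pair_delta(xyz, bead - 1, site, delta, w);
}

// Simulated annealing with Metropolis-Hastings acceptance.
// quota/cap are absolute per-temperature counts; cooling T_c = t0 * rate^c;
// halts after `stop_failed` consecutive temperatures missing the quota.
// [[Rcpp::export]]
List cpp_anneal(IntegerMatrix coords, int side, NumericMatrix delta, double w,
                double t0, double rate, int quota, double cap_,
                int stop_failed, int max_temps) {
  const long cap = (long)cap_;
  static const std::vector<std::array<int, 3> > MOORE = moore_offsets();
  std::vector<std::array<int, 3> > xyz = as_xyz(coords);
  int n = (int)xyz.size();
  double L = cpp_loss(coords, delta, w);
  const double L0 = L;
  std::vector<double> tr_T, tr_trials, tr_acc, tr_loss, tr_lossmin;
  int fails = 0;
  long acc_total = 0;

  for (int c = 0; c < max_temps; ++c) {
    double T = t0 * std::pow(rate, (double)c);
    long trials = 0, accepted = 0;
    double lmin = L;
    while (accepted < quota && trials < cap) {
      ++trials;
      int u = randint(n);
      const auto& o = MOORE[randint(26)];
      std::array<int, 3> s = {xyz[u][0] + o[0], xyz[u][1] + o[1], xyz[u][2] + o[2]};
      if (!site_valid(xyz, u, s.data(), side)) continue;  // constraint rejection
      double dE = pair_delta(xyz, u, s.data(), delta, w);
      bool acc = (dE < 0.0) || (unif_rand() < std::exp(-dE / T));
      if (acc) {
        xyz[u] = s;
        L += dE;
        ++accepted;
        if (++acc_total % 10000 == 0) {
          // periodic full recomputation bounds floating-point drift
          IntegerMatrix cur(n, 3);
          for (int i = 0; i < n; ++i)
            for (int d = 0; d < 3; ++d) cur(i, d) = xyz[i][d];
          L = cpp_loss(cur, delta, w);
        }
        if (L < lmin) lmin = L;
      }
    }
    tr_T.push_back(T); tr_trials.push_back((double)trials);
    tr_acc.push_back((double)accepted); tr_loss.push_back(L);
    tr_lossmin.push_back(lmin);
    fails = (accepted < quota) ? fails + 1 : 0;
    if (fails >= stop_failed) break;
  }

  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = xyz[i][d];
  int nt = (int)tr_T.size();
  NumericMatrix trace(nt, 5);
  for (int i = 0; i < nt; ++i) {
    trace(i, 0) = tr_T[i]; trace(i, 1) = tr_trials[i]; trace(i, 2) = tr_acc[i];
    trace(i, 3) = tr_loss[i]; trace(i, 4) = tr_lossmin[i];
  }
  return List::create(_["coords"] = out, _["trace"] = trace,
                      _["loss_initial"] = L0,
                      _["loss_final"] = cpp_loss(out, delta, w));
}

// Full O(n^2) constraint audit. Returns number of violations (0 = pass)
// plus up to 20 human-readable descriptions.
// [[Rcpp::export]]
List cpp_audit(IntegerMatrix coords, int side) {
  int n = coords.nrow();
  int bad = 0;
  std::vector<std::string> msgs;
  auto note = [&](const std::string& m) {
    ++bad;
    if ((int)msgs.size() < 20) msgs.push_back(m);
  };
  for (int i = 0; i < n; ++i) {
    int p[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
    if (!in_bounds(p, side))
      note("bead " + std::to_string(i + 1) + " out of bounds");
  }
  for (int i = 0; i < n; ++i) {
    int pi[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
    for (int j = i + 1; j < n; ++j) {
      int pj[3] = {coords(j, 0), coords(j, 1), coords(j, 2)};
      int d2 = sqdist(pi, pj);
      if (j == i + 1) {
        if (!bond_ok(d2))
          note("bond " + std::to_string(i + 1) + "-" + std::to_string(j + 1) +
               " squared length " + std::to_string(d2));
      } else {
        if (!ev_ok(d2))
          note("pair " + std::to_string(i + 1) + "-" + std::to_string(j + 1) +
               " squared distance " + std::to_string(d2));
      }
    }
  }
  return List::create(_["n_violations"] = bad,
                      _["messages"] = wrap(msgs));
}

// Insert (factor-1) beads into each gap of a (rescaled) coarse chain.
// `coarse` must already live in the fine lattice of side `side`.
// Beads are laid down sequentially toward the straight-line interpolation
// targets, with growing randomisation across retry attempts per gap.
// [[Rcpp::export]]
IntegerMatrix cpp_insert_beads(IntegerMatrix coarse, int factor, int side,
                               int attempts) {
  static const std::vector<std::array<int, 3> > BOND = bond_offsets();
  int nc = coarse.nrow();
  int k = factor;
  std::vector<std::array<int, 3> > fine;
  fine.reserve(nc + (k - 1) * (nc - 1));
  std::vector<std::array<int, 3> > coarse_xyz = as_xyz(coarse);
  fine.push_back(coarse_xyz[0]);

  for (int g = 0; g + 1 < nc; ++g) {
    const auto& A = coarse_xyz[g];
    const auto& B = coarse_xyz[g + 1];
    bool placed_gap = false;
    for (int attempt = 0; attempt < attempts && !placed_gap; ++attempt) {
      std::vector<std::array<int, 3> > seg;  // the k-1 inserted beads
      bool ok = true;
      for (int j = 1; j < k; ++j) {
        const int* prev = seg.empty() ? A.data() : seg.back().data();
        double tx = A[0] + (B[0] - A[0]) * (double)j / k;
        double ty = A[1] + (B[1] - A[1]) * (double)j / k;
        double tz = A[2] + (B[2] - A[2]) * (double)j / k;
        // candidates: bond-valid wrt prev, EV-valid wrt everything placed
        // and all remaining coarse anchors; last one must bond to B
        std::vector<std::array<int, 3> > cand;
        std::vector<double> score;
        for (const auto& o : BOND) {
          std::array<int, 3> s = {prev[0] + o[0], prev[1] + o[1], prev[2] + o[2]};
          if (!in_bounds(s.data(), side)) continue;
          int d2B = sqdist(s.data(), B.data());
          if (j == k - 1) { if (!bond_ok(d2B)) continue; }
          else           { if (!ev_ok(d2B)) continue; }
          // EV against every committed bead except the direct predecessor
          // (the bond to the predecessor is enforced by the offset set)
          bool valid = true;
          size_t nfine = fine.size();
          for (size_t m = 0; m < nfine && valid; ++m) {
            if (seg.empty() && m == nfine - 1) continue;  // prev == fine.back()
            if (!ev_ok(sqdist(s.data(), fine[m].data()))) valid = false;
          }
          for (size_t m = 0; m + 1 < seg.size() && valid; ++m)
            if (!ev_ok(sqdist(s.data(), seg[m].data()))) valid = false;
          if (!valid) continue;
          // EV against coarse anchors not yet reached (g+2 .. nc-1)
          for (int m = g + 2; m < nc && valid; ++m)
            if (!ev_ok(sqdist(s.data(), coarse_xyz[m].data()))) valid = false;
          if (!valid) continue;
          double dx = s[0] - tx, dy = s[1] - ty, dz = s[2] - tz;
          cand.push_back(s);
          score.push_back(dx * dx + dy * dy + dz * dz);
        }
        if (cand.empty()) { ok = false; break; }
        // pick among the best few, widening with each failed attempt
        int pool = std::min((int)cand.size(), 1 + attempt / 3);
        std::vector<int> idx(cand.size());
        for (size_t t = 0; t < idx.size(); ++t) idx[t] = (int)t;
        std::partial_sort(idx.begin(), idx.begin() + pool, idx.end(),
                          [&](int a, int b) { return score[a] < score[b]; });
        seg.push_back(cand[idx[randint(pool)]]);
      }
      if (ok) {
        for (const auto& s : seg) fine.push_back(s);
        fine.push_back(B);
        placed_gap = true;
      }
    }
    if (!placed_gap)
      stop("bead insertion failed in gap %d after %d attempts", g + 1, attempts);
  }

  IntegerMatrix out((int)fine.size(), 3);
  for (size_t i = 0; i < fine.size(); ++i)
    for (int d = 0; d < 3; ++d) out((int)i, d) = fine[i][d];
  return out;
}

// Repair pass for chains built by snapping continuous coordinates to the
// lattice (e.g. helices): move invalid beads to the nearest valid site
// within a small search radius, iterating until the audit is clean.
// [[Rcpp::export]]
List cpp_repair_chain(IntegerMatrix coords, int side, int max_pass) {
  std::vector<std::array<int, 3> > xyz = as_xyz(coords);
  int n = (int)xyz.size();
  bool clean = false;
  for (int pass = 0; pass < max_pass && !clean; ++pass) {
    clean = true;
    int rad = 2 + pass / 10;  // widen the search as passes accumulate
    for (int i = 0; i < n; ++i) {
      if (site_valid(xyz, i, xyz[i].data(), side)) continue;
      clean = false;
      std::array<int, 3> best = xyz[i];
      double best_d = R_PosInf;
      for (int x = -rad; x <= rad; ++x)
        for (int y = -rad; y <= rad; ++y)
          for (int z = -rad; z <= rad; ++z) {
            std::array<int, 3> s = {xyz[i][0] + x, xyz[i][1] + y, xyz[i][2] + z};
            if (!site_valid(xyz, i, s.data(), side)) continue;
            double d = x * x + y * y + z * z + 0.01 * unif_rand();
            if (d < best_d) { best_d = d; best = s; }
          }
      if (R_finite(best_d)) xyz[i] = best;
    }
  }
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = xyz[i][d];
  return List::create(_["coords"] = out, _["valid"] = clean);
}
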