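// Agent-based resource-driven neurite growth core.
//
// Trees are flat arrays of cylindrical agents. Model 2's global resource
// decay is tracked lazily (value + step of last update) so a step costs
// O(active tips), not O(all agents); values are materialised on export.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// splitmix64: tiny, seedable, deterministic across platforms.
struct GrowRng {
  uint64_t s;
  explicit GrowRng(uint64_t seed) : s(seed ^ 0x9E3779B97F4A7C15ULL) {}
  uint64_t nextu() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() {  // (0,1)
    return ((nextu() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {  // polar method
    double u, v, r2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    return u * std::sqrt(-2.0 * std::log(r2) / r2);
  }
};

struct Vec3 {
  double x, y, z;
};

inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm3(Vec3 a) { return std::sqrt(dot(a, a)); }

Vec3 random_unit(GrowRng& rng) {
  for (;;) {
    Vec3 u = {rng.norm(), rng.norm(), rng.norm()};
    double n = norm3(u);
    if (n > 1e-12) return (1.0 / n) * u;
  }
}

// Unit vector at angle theta from o within the plane spanned by o and a
// random perpendicular direction.
Vec3 deflect(Vec3 o, double theta, GrowRng& rng, Vec3& perp_out) {
  Vec3 w;
  for (;;) {
    Vec3 u = random_unit(rng);
    w = u - dot(u, o) * o;
    double n = norm3(w);
    if (n > 1e-9) {
      w = (1.0 / n) * w;
      break;
    }
  }
  perp_out = w;
  return std::cos(theta) * o + std::sin(theta) * w;
}

struct Params {
  int model_id;
  double p_bra, R, v, r_min, r_0, l_max;
  double theta_b, theta_s;  // radians
  double w_rand, w_old, w_grad;
  int n_steps;
  int max_nodes;
};

Params read_params(const List& p) {
  Params q;
  q.model_id = as<int>(p["model_id"]);
  q.p_bra = as<double>(p["p_bra"]);
  q.R = as<double>(p["R"]);
  q.v = as<double>(p["v"]);
  q.r_min = as<double>(p["r_min"]);
  q.r_0 = as<double>(p["r_0"]);
  q.l_max = as<double>(p["l_max"]);
  q.theta_b = as<double>(p["theta_bifurcate_deg"]) * M_PI / 180.0;
  q.theta_s = as<double>(p["theta_side_deg"]) * M_PI / 180.0;
  q.w_rand = as<double>(p["w_rand"]);
  q.w_old = as<double>(p["w_old"]);
  q.w_grad = as<double>(p["w_grad"]);
  q.n_steps = as<int>(p["n_steps"]);
  q.max_nodes = as<int>(p["max_nodes"]);
  return q;
}

struct Tree {
  std::vector<Vec3> start, end, ori;
  std::vector<double> res;       // resource at step `res_step`
  std::vector<int> res_step;     // step index of last explicit update
  std::vector<int> parent;       // -1 = attached to soma
  std::vector<int> nchild;
  std::vector<int> type;         // 3 basal, 4 apical
  std::vector<double> diam;
  std::vector<char> alive;

  int add(Vec3 s, Vec3 e, Vec3 o, double r, int step, int par, int ty, double d) {
    start.push_back(s);
    end.push_back(e);
    ori.push_back(o);
    res.push_back(r);
    res_step.push_back(step);
    parent.push_back(par);
    nchild.push_back(0);
    type.push_back(ty);
    diam.push_back(d);
    alive.push_back(1);
    if (par >= 0) nchild[par]++;
    return static_cast<int>(start.size()) - 1;
  }
  int size() const { return static_cast<int>(start.size()); }
};

// Resource of node i materialised at step `at`, honouring Model 2's global
// decay with floor r_min - R (a value already below the floor is kept).
double materialise(const Tree& tr, int i, int at, const Params& p) {
  double r = tr.res[i];
  if (p.model_id != 2) return r;
  int k = at - tr.res_step[i];
  if (k <= 0) return r;
  double lo = p.r_min - p.R;
  if (r <= lo) return r;
  return std::max(r - p.R * k, lo);
}

void simulate(Tree& tr, const Params& p, Vec3 grad, GrowRng& rng) {
  double gn = norm3(grad);
  Vec3 ghat = (gn > 0) ? (1.0 / gn) * grad : Vec3{0, 0, 0};

  std::vector<int> active;
  for (int i = 0; i < tr.size(); ++i)
    if (tr.nchild[i] == 0 && tr.res[i] > p.r_min) active.push_back(i);

  for (int step = 0; step < p.n_steps; ++step) {
    if (active.empty()) break;
    std::vector<int> next_active;
    next_active.reserve(active.size() + 8);

    for (size_t a = 0; a < active.size(); ++a) {
      int tip = active[a];

      // --- elongation ---------------------------------------------------
      Vec3 u = random_unit(rng);
      Vec3 d = p.w_rand * u + p.w_old * tr.ori[tip] + p.w_grad * ghat;
      double dn = norm3(d);
      if (dn < 1e-12)
        stop("degenerate elongation direction (zero resultant vector)");
      d = (1.0 / dn) * d;
      tr.end[tip] = tr.end[tip] + p.v * d;
      tr.ori[tip] = d;
      tr.res[tip] -= p.R;
      tr.res_step[tip] = step;

      int cur = tip;
      double len = norm3(tr.end[tip] - tr.start[tip]);
      if (len > p.l_max) {
        // collinear split into equal halves; distal carries the resource
        Vec3 mid = 0.5 * (tr.start[tip] + tr.end[tip]);
        if (tr.size() >= p.max_nodes) stop("tree exceeded max_nodes");
        int dist = tr.add(mid, tr.end[tip], tr.ori[tip], tr.res[tip], step,
                          tip, tr.type[tip], tr.diam[tip]);
        tr.end[tip] = mid;
        cur = dist;
      }

      // --- branching ----------------------------------------------------
      bool branched = false;
      if (p.p_bra > 0 && rng.unif() < p.p_bra) {
        branched = true;
        Vec3 at = tr.end[cur];
        if (tr.size() + 2 > p.max_nodes) stop("tree exceeded max_nodes");
        if (p.model_id == 1) {
          Vec3 w;
          Vec3 d1 = deflect(tr.ori[cur], p.theta_b, rng, w);
          Vec3 d2 = std::cos(p.theta_b) * tr.ori[cur] - std::sin(p.theta_b) * w;
          int c1 = tr.add(at, at, d1, tr.res[cur], step, cur, tr.type[cur], tr.diam[cur]);
          int c2 = tr.add(at, at, d2, tr.res[cur], step, cur, tr.type[cur], tr.diam[cur]);
          if (tr.res[c1] > p.r_min) next_active.push_back(c1);
          if (tr.res[c2] > p.r_min) next_active.push_back(c2);
        } else {
          // continuation inherits resource and orientation; side branch
          // starts fresh at r_0 with a deflected orientation
          Vec3 w;
          int c1 = tr.add(at, at, tr.ori[cur], tr.res[cur], step, cur,
                          tr.type[cur], tr.diam[cur]);
          Vec3 ds = deflect(tr.ori[cur], p.theta_s, rng, w);
          int c2 = tr.add(at, at, ds, p.r_0, step, cur, tr.type[cur], tr.diam[cur]);
          next_active.push_back(c1);  // provisional; decay check below
          next_active.push_back(c2);
        }
      }
      if (!branched) next_active.push_back(cur);
    }

    // --- Model 2 global decay (explicit for candidate tips, lazy else) --
    std::vector<int> keep;
    keep.reserve(next_active.size());
    for (size_t a = 0; a < next_active.size(); ++a) {
      int i = next_active[a];
      if (p.model_id == 2) {
        double lo = p.r_min - p.R;
        if (tr.res[i] > lo) tr.res[i] = std::max(tr.res[i] - p.R, lo);
        tr.res_step[i] = step + 1;
      }
      if (tr.res[i] > p.r_min) keep.push_back(i);
    }
    active.swap(keep);
  }

  // materialise all resources at the final step
  for (int i = 0; i < tr.size(); ++i) {
    tr.res[i] = materialise(tr, i, p.n_steps, p);
    tr.res_step[i] = p.n_steps;
  }
}

// prune never-elongated (zero-length) daughters; parents may become tips
void prune_tree(Tree& tr) {
  bool changed = true;
  while (changed) {
    changed = false;
    for (int i = tr.size() - 1; i >= 0; --i) {
      if (!tr.alive[i] || tr.nchild[i] != 0) continue;
      if (norm3(tr.end[i] - tr.start[i]) < 1e-9) {
        tr.alive[i] = 0;
        if (tr.parent[i] >= 0) tr.nchild[tr.parent[i]]--;
        changed = true;
      }
    }
  }
}

Tree tree_from_r(const NumericMatrix& nodes) {
  // columns: start xyz, end xyz, ori xyz, resource, parent (0 = soma), type, diameter
  Tree tr;
  int n = nodes.nrow();
  for (int i = 0; i < n; ++i) {
    Vec3 s = {nodes(i, 0), nodes(i, 1), nodes(i, 2)};
    Vec3 e = {nodes(i, 3), nodes(i, 4), nodes(i, 5)};
    Vec3 o = {nodes(i, 6), nodes(i, 7), nodes(i, 8)};
    double on = norm3(o);
    if (on < 1e-12) {
      Vec3 c = e - s;
      double cn = norm3(c);
      o = (cn > 1e-12) ? (1.0 / cn) * c : Vec3{0, 0, 1};
    } else {
      o = (1.0 / on) * o;
    }
    int par = static_cast<int>(nodes(i, 10)) - 1;  // R is 1-based, 0 = soma
    tr.add(s, e, o, nodes(i, 9), 0, par, static_cast<int>(nodes(i, 11)),
           nodes(i, 12));
  }
  return tr;
}

NumericMatrix tree_to_r(const Tree& tr) {
  int n_alive = 0;
  std::vector<int> newid(tr.size(), -1);
  for (int i = 0; i < tr.size(); ++i)
    if (tr.alive[i]) newid[i] = n_alive++;
  NumericMatrix out(n_alive, 13);
  for (int i = 0; i < tr.size(); ++i) {
    if (!tr.alive[i]) continue;
    int r = newid[i];
    out(r, 0) = tr.start[i].x; out(r, 1) = tr.start[i].y; out(r, 2) = tr.start[i].z;
    out(r, 3) = tr.end[i].x;   out(r, 4) = tr.end[i].y;   out(r, 5) = tr.end[i].z;
    out(r, 6) = tr.ori[i].x;   out(r, 7) = tr.ori[i].y;   out(r, 8) = tr.ori[i].z;
    out(r, 9) = tr.res[i];
    out(r, 10) = (tr.parent[i] < 0) ? 0 : newid[tr.parent[i]] + 1;
    out(r, 11) = tr.type[i];
    out(r, 12) = tr.diam[i];
  }
  return out;
}

// Section lengths: maximal unbranched paths between soma attachments,
// branch points and tips. selection: 0 all, 3 basal, 4 apical.
std::vector<double> section_lengths(const Tree& tr, int selection) {
  std::vector<double> lens;
  std::vector<int> sec(tr.size(), -1);
  for (int i = 0; i < tr.size(); ++i) {  // parents precede children
    if (!tr.alive[i]) continue;
    if (selection != 0 && tr.type[i] != selection) continue;
    int par = tr.parent[i];
    bool head = (par < 0) || !tr.alive[par] || tr.nchild[par] >= 2 ||
                (selection != 0 && tr.type[par] != selection);
    if (head) {
      sec[i] = static_cast<int>(lens.size());
      lens.push_back(0.0);
    } else {
      sec[i] = sec[par];
    }
    lens[sec[i]] += norm3(tr.end[i] - tr.start[i]);
  }
  return lens;
}

void qois_from_sections(const std::vector<double>& lens, double* out) {
  int n = static_cast<int>(lens.size());
  if (n == 0) {
    out[0] = out[1] = out[2] = out[3] = NA_REAL;
    return;
  }
  double s = 0, s2 = 0;
  for (int i = 0; i < n; ++i) s += lens[i];
  double mu = s / n;
  for (int i = 0; i < n; ++i) s2 += (lens[i] - mu) * (lens[i] - mu);
  out[0] = n;
  out[1] = mu;
  out[2] = std::sqrt(s2 / n);  // population convention
  out[3] = s;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_simulate_tree(NumericMatrix init, List params,
                                NumericVector gradient, double seed,
                                bool prune = true) {
  Params p = read_params(params);
  Tree tr = tree_from_r(init);
  GrowRng rng(static_cast<uint64_t>(seed));
  Vec3 g = {gradient[0], gradient[1], gradient[2]};
  simulate(tr, p, g, rng);
  if (prune) prune_tree(tr);
  return tree_to_r(tr);
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_qois(NumericMatrix init, List params,
                                NumericVector gradient, NumericVector seeds,
                                int selection) {
  Params p = read_params(params);
  Vec3 g = {gradient[0], gradient[1], gradient[2]};
  int m = seeds.size();
  NumericMatrix out(m, 4);
  for (int j = 0; j < m; ++j) {
    Tree tr = tree_from_r(init);
    GrowRng rng(static_cast<uint64_t>(seeds[j]));
    simulate(tr, p, g, rng);
    prune_tree(tr);
    std::vector<double> lens = section_lengths(tr, selection);
    double q[4];
    qois_from_sections(lens, q);
    for (int k = 0; k < 4; ++k) out(j, k) = q[k];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_section_lengths(NumericMatrix nodes, int selection) {
  Tree tr = tree_from_r(nodes);
  std::vector<double> lens = section_lengths(tr, selection);
  return wrap(lens);
}
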