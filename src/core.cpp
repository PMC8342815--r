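// Voxel-grid primitives and the FAST codelet tracer.
//
// Conventions shared with the R side:
//  - volumes are R arrays with dim = c(nz, ny, nx); a voxel (z, y, x)
//    (1-based in R) has 0-based linear index z0 + y0*nz + x0*nz*ny;
//  - all index vectors crossing the R/C++ boundary are 0-based;
//  - coordinates returned to R are 1-based (z, y, x) doubles.

#include <Rcpp.h>
#include <array>
#include <deque>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Grid {
  int nz, ny, nx;
  R_xlen_t n;
  std::vector<std::array<int, 3>> offs;  // (dz, dy, dx)

  Grid(const IntegerVector& dims, int connectivity) {
    nz = dims[0];
    ny = dims[1];
    nx = dims[2];
    n = (R_xlen_t)nz * ny * nx;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dx && !dy && !dz) continue;
          int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
          if (connectivity == 6 && man != 1) continue;
          offs.push_back({dz, dy, dx});
        }
  }

  inline void zyx(R_xlen_t i, int& z, int& y, int& x) const {
    z = (int)(i % nz);
    R_xlen_t r = i / nz;
    y = (int)(r % ny);
    x = (int)(r / ny);
  }

  inline R_xlen_t idx(int z, int y, int x) const {
    return (R_xlen_t)z + (R_xlen_t)y * nz + (R_xlen_t)x * nz * ny;
  }

  template <typename F>
  inline void for_neighbors(R_xlen_t i, F f) const {
    int z, y, x;
    zyx(i, z, y, x);
    for (const auto& o : offs) {
      int zz = z + o[0], yy = y + o[1], xx = x + o[2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      f(idx(zz, yy, xx));
    }
  }
};

}  // namespace

// Label connected components of a voxel set. Returns a component id
// (1-based, in discovery order over the sorted input) per input voxel.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector dims, IntegerVector idx,
                                   int connectivity) {
  Grid g(dims, connectivity);
  std::vector<char> member(g.n, 0);
  std::vector<int> label(g.n, 0);
  std::vector<R_xlen_t> sorted(idx.begin(), idx.end());
  std::sort(sorted.begin(), sorted.end());
  for (R_xlen_t v : sorted) member[v] = 1;

  int nlab = 0;
  std::deque<R_xlen_t> q;
  for (R_xlen_t s : sorted) {
    if (label[s]) continue;
    ++nlab;
    label[s] = nlab;
    q.push_back(s);
    while (!q.empty()) {
      R_xlen_t v = q.front();
      q.pop_front();
      g.for_neighbors(v, [&](R_xlen_t u) {
        if (member[u] && !label[u]) {
          label[u] = nlab;
          q.push_back(u);
        }
      });
    }
  }

  IntegerVector out(idx.size());
  for (R_xlen_t k = 0; k < idx.size(); ++k) out[k] = label[idx[k]];
  return out;
}

static std::vector<int> bfs_source_field(const Grid& g,
                                         const IntegerVector& idx,
                                         R_xlen_t seed) {
  std::vector<int> sf(g.n, 0);   // 0 = not in set / unreached
  std::vector<char> member(g.n, 0);
  for (R_xlen_t k = 0; k < idx.size(); ++k) member[idx[k]] = 1;
  if (!member[seed]) stop("seed voxel is not a member of the voxel set");
  sf[seed] = 1;
  std::deque<R_xlen_t> q{seed};
  while (!q.empty()) {
    R_xlen_t v = q.front();
    q.pop_front();
    g.for_neighbors(v, [&](R_xlen_t u) {
      if (member[u] && !sf[u]) {
        sf[u] = sf[v] + 1;
        q.push_back(u);
      }
    });
  }
  return sf;
}

// Geodesic source field: path distance from the seed plus 1 (seed = 1).
// Returns one value per input voxel; 0 marks voxels unreachable from the seed.
// [[Rcpp::export]]
IntegerVector cpp_source_field(IntegerVector dims, IntegerVector idx,
                               double seed, int connectivity) {
  Grid g(dims, connectivity);
  std::vector<int> sf = bfs_source_field(g, idx, (R_xlen_t)seed);
  IntegerVector out(idx.size());
  for (R_xlen_t k = 0; k < idx.size(); ++k) out[k] = sf[idx[k]];
  return out;
}

namespace {

struct Branch {
  int id = 0, parent = 0;
  std::vector<std::array<double, 3>> cps;  // central points, 1-based (z,y,x)
  std::array<double, 3> sp{};              // start point
  std::array<double, 3> bp{};              // retracted branch point
  std::array<double, 3> ep{};              // end point
  bool has_bp = false, has_ep = false;
  std::vector<R_xlen_t> vox;               // claimed member voxels
  std::vector<R_xlen_t> front;             // sf in {pos, pos+1}
  int pos = 2;
};

inline std::array<double, 3> com_of(const Grid& g,
                                    const std::vector<R_xlen_t>& vs) {
  double sz = 0, sy = 0, sx = 0;
  for (R_xlen_t v : vs) {
    int z, y, x;
    g.zyx(v, z, y, x);
    sz += z + 1;
    sy += y + 1;
    sx += x + 1;
  }
  double m = (double)vs.size();
  return {sz / m, sy / m, sx / m};
}

}  // namespace

// FAST trace of the connected component containing `seed`.
//
// A codelet at position p is the set of voxels with source field in
// {p-1, p, p+1} reachable from the branch front; its center of mass is the
// branch central point at that step. When the codelet splits into k >= 2
// connected components (each with >= min_comp voxels) the branch ends at a
// branch point retracted `retract` steps back along its central points, and
// each component seeds a child branch whose gap to the branch point is
// filled with interpolated central points. Voxels claimed by an earlier
// branch are never re-entered (first-claim exclusion; breaks loops).
// Tracing aborts once more than `bmax` branches have been created.
// [[Rcpp::export]]
List cpp_fast_trace(IntegerVector dims, IntegerVector idx, double seed_,
                    int connectivity, double bmax, int retract, int min_comp) {
  Grid g(dims, connectivity);
  R_xlen_t seed = (R_xlen_t)seed_;
  std::vector<int> sf = bfs_source_field(g, idx, seed);

  std::vector<int> claimed(g.n, 0);
  std::vector<int> vstamp(g.n, 0), fstamp(g.n, 0);
  int stamp = 0;
  std::vector<Branch> branches;
  std::deque<int> queue;  // branch indices awaiting propagation
  bool aborted = false;

  // Flood the window {p-1, p, p+1} from the given seeds; returns connected
  // components (each a sorted voxel list) in order of smallest member index.
  auto flood_components = [&](const std::vector<R_xlen_t>& seeds, int p,
                              int bid) {
    ++stamp;
    std::vector<std::vector<R_xlen_t>> comps;
    for (R_xlen_t s : seeds) fstamp[s] = stamp;
    for (R_xlen_t s : seeds) {
      if (vstamp[s] == stamp) continue;
      std::vector<R_xlen_t> comp;
      std::deque<R_xlen_t> q{s};
      vstamp[s] = stamp;
      while (!q.empty()) {
        R_xlen_t v = q.front();
        q.pop_front();
        comp.push_back(v);
        g.for_neighbors(v, [&](R_xlen_t u) {
          if (vstamp[u] == stamp) return;
          int s_u = sf[u];
          if (s_u < p - 1 || s_u > p + 1) return;
          if (claimed[u] != 0 && claimed[u] != bid && fstamp[u] != stamp)
            return;
          vstamp[u] = stamp;
          q.push_back(u);
        });
      }
      std::sort(comp.begin(), comp.end());
      comps.push_back(std::move(comp));
    }
    std::sort(comps.begin(), comps.end(),
              [](const std::vector<R_xlen_t>& a,
                 const std::vector<R_xlen_t>& b) { return a[0] < b[0]; });
    return comps;
  };

  auto claim_new = [&](const std::vector<R_xlen_t>& comp, Branch& b) {
    for (R_xlen_t v : comp)
      if (!claimed[v]) {
        claimed[v] = b.id;
        b.vox.push_back(v);
      }
  };

  auto set_front = [&](Branch& b, const std::vector<R_xlen_t>& comp, int p) {
    b.front.clear();
    for (R_xlen_t v : comp)
      if (sf[v] == p || sf[v] == p + 1) b.front.push_back(v);
    b.pos = p;
  };

  // Root branch: initial codelet at position 2 (source fields 1, 2, 3).
  {
    Branch root;
    root.id = 1;
    auto comps = flood_components({seed}, 2, 1);
    const auto& comp = comps[0];
    claim_new(comp, root);
    root.sp = com_of(g, comp);
    root.cps.push_back(root.sp);
    bool has_next = false;
    for (R_xlen_t v : comp)
      if (sf[v] == 3) {
        has_next = true;
        break;
      }
    if (!has_next) {
      root.has_ep = true;
      root.ep = root.sp;
      branches.push_back(std::move(root));
    } else {
      set_front(root, comp, 2);
      branches.push_back(std::move(root));
      queue.push_back(0);
    }
  }

  while (!queue.empty() && !aborted) {
    int bi = queue.front();
    queue.pop_front();
    bool active = true;
    while (active) {
      Branch& b = branches[bi];
      int p = b.pos + 1;
      if (b.front.empty()) {
        b.has_ep = true;
        b.ep = b.cps.back();
        break;
      }
      auto comps = flood_components(b.front, p, b.id);
      if (comps.empty()) {
        b.has_ep = true;
        b.ep = b.cps.back();
        break;
      }
      // components big enough to carry a branch
      std::vector<int> big;
      for (int k = 0; k < (int)comps.size(); ++k)
        if ((int)comps[k].size() >= min_comp) big.push_back(k);

      if (comps.size() == 1 || big.size() <= 1) {
        // continue as a single branch, absorbing sub-threshold spurs
        std::vector<R_xlen_t> comp;
        if (big.size() == 1 && comps.size() > 1) {
          for (int k = 0; k < (int)comps.size(); ++k)
            for (R_xlen_t v : comps[k]) comp.push_back(v);
          std::sort(comp.begin(), comp.end());
        } else if (comps.size() == 1) {
          comp = comps[0];
        } else {  // several components, all tiny: absorb and terminate
          for (const auto& c : comps)
            for (R_xlen_t v : c) comp.push_back(v);
          claim_new(comp, b);
          b.cps.push_back(com_of(g, comp));
          b.has_ep = true;
          b.ep = b.cps.back();
          break;
        }
        claim_new(comp, b);
        std::array<double, 3> com = com_of(g, comp);
        b.cps.push_back(com);
        bool has_next = false;
        for (R_xlen_t v : comp)
          if (sf[v] == p + 1) {
            has_next = true;
            break;
          }
        if (!has_next) {
          b.has_ep = true;
          b.ep = com;
          break;
        }
        // restrict the next front to the continuing component
        if (big.size() == 1 && comps.size() > 1)
          set_front(b, comps[big[0]], p);
        else
          set_front(b, comp, p);
      } else {
        // split: retract the branch point and launch one child per component
        int bp_i = std::max(0, (int)b.cps.size() - 1 - retract);
        b.bp = b.cps[bp_i];
        b.has_bp = true;
        b.cps.resize(bp_i + 1);
        // absorb tiny components into the parent
        for (int k = 0; k < (int)comps.size(); ++k) {
          bool is_big =
              std::find(big.begin(), big.end(), k) != big.end();
          if (!is_big) claim_new(comps[k], b);
        }
        std::array<double, 3> bpt = b.bp;
        int parent_id = b.id;
        for (int k : big) {
          if ((double)branches.size() + 1 > bmax) {
            aborted = true;
            break;
          }
          Branch ch;
          ch.id = (int)branches.size() + 1;
          ch.parent = parent_id;
          const auto& comp = comps[k];
          ch.sp = com_of(g, comp);
          // gap between the retracted branch point and the child start is
          // filled with interpolated central points ("local tracing")
          double dz = ch.sp[0] - bpt[0], dy = ch.sp[1] - bpt[1],
                 dx = ch.sp[2] - bpt[2];
          double dist = std::sqrt(dz * dz + dy * dy + dx * dx);
          int ngap = std::max(0, (int)std::lround(dist) - 1);
          for (int s = 1; s <= ngap; ++s) {
            double f = (double)s / (ngap + 1);
            ch.cps.push_back(
                {bpt[0] + f * dz, bpt[1] + f * dy, bpt[2] + f * dx});
          }
          ch.cps.push_back(ch.sp);
          claim_new(comp, ch);
          set_front(ch, comp, p);
          branches.push_back(std::move(ch));
          queue.push_back((int)branches.size() - 1);
        }
        break;
      }
    }
    if (aborted) break;
  }

  // package for R
  int nb = (int)branches.size();
  List out(nb);
  for (int k = 0; k < nb; ++k) {
    Branch& b = branches[k];
    NumericMatrix cps(b.cps.size(), 3);
    for (int r = 0; r < (int)b.cps.size(); ++r)
      for (int c = 0; c < 3; ++c) cps(r, c) = b.cps[r][c];
    std::sort(b.vox.begin(), b.vox.end());
    IntegerVector vox(b.vox.size());
    for (R_xlen_t r = 0; r < (R_xlen_t)b.vox.size(); ++r)
      vox[r] = (int)b.vox[r];
    out[k] = List::create(
        _["id"] = b.id, _["parent"] = b.parent, _["central_points"] = cps,
        _["start_point"] = NumericVector::create(b.sp[0], b.sp[1], b.sp[2]),
        _["branch_point"] =
            b.has_bp ? (SEXP)NumericVector::create(b.bp[0], b.bp[1], b.bp[2])
                     : R_NilValue,
        _["end_point"] =
            b.has_ep ? (SEXP)NumericVector::create(b.ep[0], b.ep[1], b.ep[2])
                     : R_NilValue,
        _["voxel_index"] = vox);
  }
  return List::create(_["branches"] = out, _["aborted"] = aborted,
                      _["n_branches"] = nb);
}
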