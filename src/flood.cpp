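// Per-voxel flood loops for the split engine. Everything else in the package
// is vectorised R; these two kernels are the only truly sequential
// algorithms.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Seeded watershed flood on an 8-bit intensity volume restricted to a mask.
//
// Priority of a voxel is 255 - intensity (bright cytoplasm floods before dark
// membrane). Flooding follows rising water levels: a voxel is claimed at
// level max(parent's claim level, own priority), so fronts cannot sneak below
// a ridge they have already crossed. Within one level the flood advances in
// synchronous breadth-first waves; when two fronts propose the same voxel in
// the same wave, the proposal whose originating seed appears earlier in the
// seed list wins. The result therefore depends only on (level, wave, seed
// rank) per voxel — never on queue arrival order — which is what makes a
// box-bounded flood agree exactly with the unbounded one whenever the box
// contains the whole merging border.
//
// intensity: integer 0..255, length nx*ny*nz, x fastest (dim c(nx, ny, nz))
// mask:      logical, same layout
// seed_idx:  0-based linear indices (in order; first seed at a voxel wins)
// seed_lab:  positive labels parallel to seed_idx
// [[Rcpp::export]]
IntegerVector flood_fill_cpp(IntegerVector intensity, LogicalVector mask,
                             IntegerVector dims, IntegerVector seed_idx,
                             IntegerVector seed_lab) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> rank_of(n, -1);        // seed rank that claimed the voxel
  std::vector<int> best_rank(n, -1);      // per-wave conflict resolution
  std::vector<int> stamp(n, -1);          // wave id a proposal was seen in

  struct Prop { int v, label, rank; };
  std::vector<std::vector<Prop> > bucket(256);

  // seeds claim their voxels up front, in list order
  for (int i = 0; i < seed_idx.size(); ++i) {
    int v = seed_idx[i];
    if (v < 0 || v >= n || !mask[v] || lab[v] != 0) continue;
    lab[v] = seed_lab[i];
    rank_of[v] = i;
    int p = 255 - intensity[v];
    if (p < 0) p = 0;
    if (p > 255) p = 255;
    bucket[p].push_back(Prop{v, seed_lab[i], i});
  }

  const int sx = 1, sy = nx, sz = nx * ny;
  int wave_id = 0;
  std::vector<Prop> cur, nxt, claimed;
  for (int level = 0; level < 256; ++level) {
    cur.swap(bucket[level]);
    while (!cur.empty()) {
      ++wave_id;
      claimed.clear();
      // phase 1: resolve this wave's claims by seed rank
      for (size_t i = 0; i < cur.size(); ++i) {
        int v = cur[i].v;
        bool is_seed_entry = (rank_of[v] == cur[i].rank && lab[v] == cur[i].label);
        if (lab[v] != 0 && !is_seed_entry) continue;   // claimed earlier
        if (is_seed_entry) {                            // seed expands itself
          if (stamp[v] != wave_id) { stamp[v] = wave_id; claimed.push_back(cur[i]); }
          continue;
        }
        if (stamp[v] != wave_id) {
          stamp[v] = wave_id;
          best_rank[v] = cur[i].rank;
          claimed.push_back(cur[i]);
        } else if (cur[i].rank < best_rank[v]) {
          best_rank[v] = cur[i].rank;
          for (size_t j = 0; j < claimed.size(); ++j)
            if (claimed[j].v == v) { claimed[j] = cur[i]; break; }
        }
      }
      // phase 2: commit claims, then propose unclaimed 6-neighbours
      for (size_t i = 0; i < claimed.size(); ++i) {
        int v = claimed[i].v;
        if (lab[v] == 0) { lab[v] = claimed[i].label; rank_of[v] = claimed[i].rank; }
      }
      for (size_t i = 0; i < claimed.size(); ++i) {
        int v = claimed[i].v;
        int x = v % nx, y = (v / nx) % ny, z = v / sz;
        for (int d = 0; d < 6; ++d) {
          int w;
          switch (d) {
            case 0: if (x == 0) continue;       w = v - sx; break;
            case 1: if (x == nx - 1) continue;  w = v + sx; break;
            case 2: if (y == 0) continue;       w = v - sy; break;
            case 3: if (y == ny - 1) continue;  w = v + sy; break;
            case 4: if (z == 0) continue;       w = v - sz; break;
            default: if (z == nz - 1) continue; w = v + sz; break;
          }
          if (!mask[w] || lab[w] != 0) continue;
          int p = 255 - intensity[w];
          if (p < 0) p = 0;
          if (p > 255) p = 255;
          Prop pr{w, lab[v], rank_of[v]};
          if (p <= level) nxt.push_back(pr);
          else bucket[p].push_back(pr);
        }
      }
      cur.swap(nxt);
      nxt.clear();
    }
  }
  return lab;
}

// 6-connected component labelling of a binary mask; background stays 0,
// components are numbered 1..k in scan order of their first voxel.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  const int sx = 1, sy = nx, sz = nx * ny;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back((int)s);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / sz;
      for (int d = 0; d < 6; ++d) {
        int w;
        switch (d) {
          case 0: if (x == 0) continue;       w = v - sx; break;
          case 1: if (x == nx - 1) continue;  w = v + sx; break;
          case 2: if (y == 0) continue;       w = v - sy; break;
          case 3: if (y == ny - 1) continue;  w = v + sy; break;
          case 4: if (z == 0) continue;       w = v - sz; break;
          default: if (z == nz - 1) continue; w = v + sz; break;
        }
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}
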