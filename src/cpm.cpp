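// Cellular-Potts engine: 3D lattice, effective-energy evaluation, Metropolis
// voxel-copy kinetics, mechanical link objects and their Poisson turnover,
// cohesotaxis-biased lamellipodium placement and cell-cell link intercalation.
//
// Coordinate conventions: internally 0-based (x fastest); the R API is 1-based.
// owner values: -1 substrate (immutable z = lowest layer), 0 medium, >0 cell id.
// type codes (tau): 0 medium, 1 substrate, 2 leader, 3 follower.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// xoshiro256++ with splitmix64 seeding: fast, deterministic across platforms
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t v) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(v);
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t operator()() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
};

static const int KIND_CC = 0;   // cell-cell elastic
static const int KIND_FS = 1;   // follower-substrate elastic
static const int KIND_LAM = 2;  // lamellipodium, constant tension

struct LinkObj {
  int kind;
  int a;            // cell id (always a cell)
  int b;            // cell id for KIND_CC, else -1
  double ax, ay, az;// anchor (internal coords) for KIND_FS / KIND_LAM
  double lambda;
  double L;         // target length (unused for KIND_LAM)
  int age;
  bool satisfied;   // KIND_LAM only
  bool alive;
};

struct EngineCfg {
  double J[4][4];
  double lambda_volume, v_target, temperature;
  double lambda_tissue, lambda_lamellipodia, lambda_follower_substrate;
  double zeta_lamellipodia, zeta_substrate, zeta_tissue;
  double chi, kappa;
  double L_cc, L_fs;
  int max_neighbors;
  bool lam_blocked;
  bool bias_far;
  bool connectivity;
  double reach_tol;
};

// 26-neighborhood offsets, and the 13 "positive" half used for pair sums
static int OFF26[26][3];
static int OFF13[13][3];
static const int OFF6[6][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}
};
static bool offs_init = false;
static void init_offsets() {
  if (offs_init) return;
  int k26 = 0, k13 = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        OFF26[k26][0] = dx; OFF26[k26][1] = dy; OFF26[k26][2] = dz; ++k26;
        if (dz > 0 || (dz == 0 && (dy > 0 || (dy == 0 && dx > 0)))) {
          OFF13[k13][0] = dx; OFF13[k13][1] = dy; OFF13[k13][2] = dz; ++k13;
        }
      }
  offs_init = true;
}

class Engine {
public:
  int nx, ny, nz, nxy, nsite;
  int noff26[26];
  std::vector<int> owner;
  int ncell;
  std::vector<int> ctype;                 // 1 leader, 2 follower (per id, index 0 unused)
  std::vector<int> vol;
  std::vector<long long> sx, sy, sz;
  std::vector<char> alive;
  std::vector<int> subcount;            // voxels per cell at the substrate-adjacent layer
  std::vector<std::vector<int> > vox;     // voxel indices per cell
  std::vector<int> voxpos;                // index of voxel within its cell's list
  std::vector<LinkObj> links;
  std::vector<std::vector<int> > clinks;  // link indices per cell
  EngineCfg cfg;
  Xoshiro rng;
  long long mcs;
  long long n_breaks, n_reforms;
  long long acc_count, att_count;

  Engine(const List& state, const List& config) :
    mcs(0), n_breaks(0), n_reforms(0), acc_count(0), att_count(0) {
    init_offsets();
    IntegerVector own = state["owner"];
    IntegerVector dm = own.attr("dim");
    nx = dm[0]; ny = dm[1]; nz = dm[2];
    nxy = nx * ny; nsite = nxy * nz;
    owner.assign(own.begin(), own.end());
    IntegerVector ct = state["cell_type"];
    ncell = ct.size();
    ctype.assign(ncell + 1, 0);
    for (int i = 0; i < ncell; ++i) ctype[i + 1] = ct[i];
    vol.assign(ncell + 1, 0);
    sx.assign(ncell + 1, 0); sy.assign(ncell + 1, 0); sz.assign(ncell + 1, 0);
    alive.assign(ncell + 1, 0);
    subcount.assign(ncell + 1, 0);
    vox.assign(ncell + 1, std::vector<int>());
    voxpos.assign(nsite, -1);
    clinks.assign(ncell + 1, std::vector<int>());
    for (int idx = 0; idx < nsite; ++idx) {
      int o = owner[idx];
      int z = idx / nxy;
      if (z == 0) {
        if (o != -1) stop("lowest z-layer must be substrate");
      } else if (o == -1) {
        stop("substrate voxels outside the lowest z-layer");
      }
      if (o > 0) {
        if (o > ncell) stop("owner id exceeds number of cells");
        int x = idx % nx, y = (idx / nx) % ny;
        vol[o] += 1; sx[o] += x; sy[o] += y; sz[o] += z;
        if (z == 1) subcount[o] += 1;
        voxpos[idx] = (int)vox[o].size();
        vox[o].push_back(idx);
        alive[o] = 1;
      }
    }
    for (int k = 0; k < 26; ++k)
      noff26[k] = OFF26[k][0] + nx * (OFF26[k][1] + ny * OFF26[k][2]);
    readCfg(config);
    readLinks(state);
    long long t = mcs; // silence unused warnings on some compilers
    (void)t;
    List st = state;
    if (st.containsElementNamed("mcs")) mcs = (long long)as<double>(st["mcs"]);
  }

  void readCfg(const List& config) {
    NumericMatrix Jm = config["contact_energy"];
    if (Jm.nrow() != 4 || Jm.ncol() != 4) stop("contact_energy must be 4x4");
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) cfg.J[i][j] = Jm(i, j);
    cfg.lambda_volume = as<double>(config["lambda_volume"]);
    cfg.v_target = as<double>(config["v_target"]);
    cfg.temperature = as<double>(config["temperature"]);
    if (cfg.temperature <= 0) stop("temperature must be > 0");
    cfg.lambda_tissue = as<double>(config["lambda_tissue"]);
    cfg.lambda_lamellipodia = as<double>(config["lambda_lamellipodia"]);
    cfg.lambda_follower_substrate = as<double>(config["lambda_follower_substrate"]);
    cfg.zeta_lamellipodia = as<double>(config["zeta_lamellipodia"]);
    cfg.zeta_substrate = as<double>(config["zeta_substrate"]);
    cfg.zeta_tissue = as<double>(config["zeta_tissue"]);
    if (cfg.zeta_lamellipodia < 0 || cfg.zeta_substrate < 0 || cfg.zeta_tissue < 0)
      stop("Poisson rates zeta must be >= 0");
    cfg.chi = as<double>(config["chi_lamellipodia"]);
    cfg.kappa = as<double>(config["kappa"]);
    cfg.L_cc = as<double>(config["link_target_length"]);
    cfg.L_fs = as<double>(config["substrate_link_target_length"]);
    cfg.max_neighbors = as<int>(config["max_reformed_neighbors"]);
    cfg.lam_blocked = as<bool>(config["lamellipodia_blocked"]);
    cfg.connectivity = as<bool>(config["connectivity_constraint"]);
    std::string bt = as<std::string>(config["bias_toward"]);
    cfg.bias_far = (bt != "near");
    cfg.reach_tol = as<double>(config["reach_tolerance"]);
  }

  void readLinks(const List& state) {
    List lk = state["links"];
    IntegerVector kind = lk["kind"], av = lk["a"], bv = lk["b"], age = lk["age"];
    NumericVector axv = lk["anchor_x"], ayv = lk["anchor_y"], azv = lk["anchor_z"];
    NumericVector lam = lk["lambda"], tl = lk["target_length"];
    LogicalVector sat = lk["satisfied"];
    int n = kind.size();
    for (int i = 0; i < n; ++i) {
      LinkObj L;
      L.kind = kind[i];
      L.a = av[i];
      L.b = (bv[i] == NA_INTEGER) ? -1 : bv[i];
      L.ax = NumericVector::is_na(axv[i]) ? 0 : axv[i] - 1.0;
      L.ay = NumericVector::is_na(ayv[i]) ? 0 : ayv[i] - 1.0;
      L.az = NumericVector::is_na(azv[i]) ? 0 : azv[i] - 1.0;
      L.lambda = lam[i];
      L.L = tl[i];
      L.age = age[i];
      L.satisfied = sat[i] == TRUE;
      L.alive = true;
      if (L.a < 1 || L.a > ncell || !alive[L.a]) stop("link endpoint a is not a live cell");
      if (L.kind == KIND_CC) {
        if (L.b < 1 || L.b > ncell || !alive[L.b]) stop("cell-cell link endpoint b is not a live cell");
      } else if (L.kind == KIND_LAM) {
        if (ctype[L.a] != 1) stop("lamellipodium link on a non-leader cell");
      } else if (L.kind == KIND_FS) {
        if (ctype[L.a] != 2) stop("follower-substrate link on a non-follower cell");
      }
      int li = (int)links.size();
      links.push_back(L);
      clinks[L.a].push_back(li);
      if (L.kind == KIND_CC) clinks[L.b].push_back(li);
    }
  }

  inline int tau(int o) const {
    if (o == 0) return 0;
    if (o == -1) return 1;
    return ctype[o] + 1;
  }
  inline double cx(int c) const { return (double)sx[c] / vol[c]; }
  inline double cy(int c) const { return (double)sy[c] / vol[c]; }
  inline double cz(int c) const { return (double)sz[c] / vol[c]; }

  inline double runif01() { return (rng() >> 11) * (1.0 / 9007199254740992.0); }
  inline int randint(int n) {
    int r = (int)(runif01() * n);
    return r >= n ? n - 1 : r;
  }
  inline bool fires(double zeta) {
    if (zeta <= 0) return false;
    return runif01() < (1.0 - std::exp(-zeta));
  }

  static inline double epos(const LinkObj& L, double pax, double pay, double paz,
                            double pbx, double pby, double pbz) {
    double dx = pax - pbx, dy = pay - pby, dz = paz - pbz;
    double l = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (L.kind == KIND_LAM) return L.satisfied ? 0.0 : L.lambda * l;
    double d = l - L.L;
    return L.lambda * d * d;
  }

  double link_energy(const LinkObj& L) const {
    if (!L.alive) return 0.0;
    double pax = cx(L.a), pay = cy(L.a), paz = cz(L.a);
    if (L.kind == KIND_CC)
      return epos(L, pax, pay, paz, cx(L.b), cy(L.b), cz(L.b));
    return epos(L, pax, pay, paz, L.ax, L.ay, L.az);
  }

  double total_energy() const {
    double H = 0.0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int idx = x + nx * (y + ny * z);
          int o = owner[idx];
          int to = tau(o);
          for (int k = 0; k < 13; ++k) {
            int x2 = x + OFF13[k][0], y2 = y + OFF13[k][1], z2 = z + OFF13[k][2];
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 >= nz) continue;
            int o2 = owner[x2 + nx * (y2 + ny * z2)];
            if (o2 != o) H += cfg.J[to][tau(o2)];
          }
        }
    for (int c = 1; c <= ncell; ++c)
      if (alive[c]) {
        double dv = vol[c] - cfg.v_target;
        H += cfg.lambda_volume * dv * dv;
      }
    for (size_t i = 0; i < links.size(); ++i)
      if (links[i].alive) H += link_energy(links[i]);
    return H;
  }

  // change in H if owner(src) copies into tgt (indices)
  double delta_H(int tgt, int src) {
    int a = owner[src], b = owner[tgt];
    int x = tgt % nx, y = (tgt / nx) % ny, z = tgt / nxy;
    int ta = tau(a), tb = tau(b);
    double dH = 0.0;
    if (x > 0 && x < nx - 1 && y > 0 && y < ny - 1 && z > 0 && z < nz - 1) {
      for (int k = 0; k < 26; ++k) {
        int o2 = owner[tgt + noff26[k]];
        int t2 = tau(o2);
        if (o2 != a) dH += cfg.J[ta][t2];
        if (o2 != b) dH -= cfg.J[tb][t2];
      }
    } else {
      for (int k = 0; k < 26; ++k) {
        int x2 = x + OFF26[k][0], y2 = y + OFF26[k][1], z2 = z + OFF26[k][2];
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
        int o2 = owner[x2 + nx * (y2 + ny * z2)];
        int t2 = tau(o2);
        if (o2 != a) dH += cfg.J[ta][t2];
        if (o2 != b) dH -= cfg.J[tb][t2];
      }
    }
    double vt = cfg.v_target;
    if (a > 0) {
      double v = vol[a];
      dH += cfg.lambda_volume * ((v + 1 - vt) * (v + 1 - vt) - (v - vt) * (v - vt));
    }
    if (b > 0) {
      double v = vol[b];
      // a cell losing its last voxel is removed from the registry with its
      // links, so its entire volume term leaves H
      dH -= cfg.lambda_volume * (v - vt) * (v - vt);
      if (vol[b] > 1)
        dH += cfg.lambda_volume * (v - 1 - vt) * (v - 1 - vt);
    }
    if (a > 0 || b > 0) {
      bool bdies = (b > 0 && vol[b] == 1);
      double cax = 0, cay = 0, caz = 0, cbx = 0, cby = 0, cbz = 0;
      if (a > 0) {
        cax = (sx[a] + x) / (vol[a] + 1.0);
        cay = (sy[a] + y) / (vol[a] + 1.0);
        caz = (sz[a] + z) / (vol[a] + 1.0);
      }
      if (b > 0 && !bdies) {
        cbx = (sx[b] - x) / (vol[b] - 1.0);
        cby = (sy[b] - y) / (vol[b] - 1.0);
        cbz = (sz[b] - z) / (vol[b] - 1.0);
      }
      // new position of a link endpoint cell under the hypothetical copy
      struct PosFn {
        const Engine* e; int a, b; bool bdies;
        double cax, cay, caz, cbx, cby, cbz;
        void operator()(int c, double& px, double& py, double& pz) const {
          if (c == a) { px = cax; py = cay; pz = caz; }
          else if (c == b) { px = cbx; py = cby; pz = cbz; }
          else { px = e->cx(c); py = e->cy(c); pz = e->cz(c); }
        }
      } newpos = { this, a, b, bdies, cax, cay, caz, cbx, cby, cbz };
      double dLink = 0.0;
      if (a > 0) {
        const std::vector<int>& la = clinks[a];
        for (size_t q = 0; q < la.size(); ++q) {
          const LinkObj& L = links[la[q]];
          if (!L.alive) continue;
          dLink -= link_energy(L);
          if (bdies && (L.a == b || (L.kind == KIND_CC && L.b == b))) continue;
          double pax, pay, paz; newpos(L.a, pax, pay, paz);
          if (L.kind == KIND_CC) {
            double pbx, pby, pbz; newpos(L.b, pbx, pby, pbz);
            dLink += epos(L, pax, pay, paz, pbx, pby, pbz);
          } else {
            dLink += epos(L, pax, pay, paz, L.ax, L.ay, L.az);
          }
        }
      }
      if (b > 0) {
        const std::vector<int>& lb = clinks[b];
        for (size_t q = 0; q < lb.size(); ++q) {
          const LinkObj& L = links[lb[q]];
          if (!L.alive) continue;
          if (a > 0 && (L.a == a || (L.kind == KIND_CC && L.b == a))) continue; // counted above
          dLink -= link_energy(L);
          if (bdies) continue; // all of b's remaining links vanish with it
          double pax, pay, paz; newpos(L.a, pax, pay, paz);
          if (L.kind == KIND_CC) {
            double pbx, pby, pbz; newpos(L.b, pbx, pby, pbz);
            dLink += epos(L, pax, pay, paz, pbx, pby, pbz);
          } else {
            dLink += epos(L, pax, pay, paz, L.ax, L.ay, L.az);
          }
        }
      }
      dH += dLink;
    }
    return dH;
  }

  void delete_link(int li) {
    LinkObj& L = links[li];
    if (!L.alive) return;
    L.alive = false;
    dropFrom(clinks[L.a], li);
    if (L.kind == KIND_CC) dropFrom(clinks[L.b], li);
  }
  static void dropFrom(std::vector<int>& v, int li) {
    for (size_t i = 0; i < v.size(); ++i)
      if (v[i] == li) { v[i] = v.back(); v.pop_back(); return; }
  }

  void kill_cell(int c) {
    alive[c] = 0;
    std::vector<int> ls = clinks[c];
    for (size_t i = 0; i < ls.size(); ++i) delete_link(ls[i]);
    clinks[c].clear();
  }

  void apply_copy(int tgt, int src) {
    int a = owner[src], b = owner[tgt];
    int x = tgt % nx, y = (tgt / nx) % ny, z = tgt / nxy;
    owner[tgt] = a;
    if (b > 0) {
      int pos = voxpos[tgt];
      std::vector<int>& vb = vox[b];
      int last = vb.back();
      vb[pos] = last; voxpos[last] = pos; vb.pop_back();
      vol[b] -= 1; sx[b] -= x; sy[b] -= y; sz[b] -= z;
      if (z == 1) subcount[b] -= 1;
      if (vol[b] == 0) kill_cell(b);
    }
    if (a > 0) {
      voxpos[tgt] = (int)vox[a].size();
      vox[a].push_back(tgt);
      vol[a] += 1; sx[a] += x; sy[a] += y; sz[a] += z;
      if (z == 1) subcount[a] += 1;
    }
  }

  // Local connectivity criterion: removing voxel t from its owner must not
  // split the owner's voxels within t's 26-neighborhood into more than one
  // 26-connected component. Prevents cell pinch-off during rearrangement
  // (pre-existing isolated fragments - empty local neighbor set - may still
  // be absorbed).
  bool removal_safe(int tgt) const {
    int b = owner[tgt];
    int x = tgt % nx, y = (tgt / nx) % ny, z = tgt / nxy;
    int pos[26][3];
    bool is_face[26];
    int n = 0, first_face = -1, n_face = 0;
    for (int k = 0; k < 26; ++k) {
      int x2 = x + OFF26[k][0], y2 = y + OFF26[k][1], z2 = z + OFF26[k][2];
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
      if (owner[x2 + nx * (y2 + ny * z2)] != b) continue;
      pos[n][0] = x2; pos[n][1] = y2; pos[n][2] = z2;
      bool f = std::abs(OFF26[k][0]) + std::abs(OFF26[k][1]) + std::abs(OFF26[k][2]) == 1;
      is_face[n] = f;
      if (f) { if (first_face < 0) first_face = n; ++n_face; }
      ++n;
    }
    if (n_face <= 1) return true; // nothing to bridge (or an isolated scrap)
    bool seen[26] = { false };
    int stack[26], sp = 0;
    stack[sp++] = first_face; seen[first_face] = true;
    int face_visited = 1;
    while (sp > 0 && face_visited < n_face) {
      int i = stack[--sp];
      for (int j = 0; j < n; ++j) {
        if (seen[j]) continue;
        int dx = std::abs(pos[i][0] - pos[j][0]);
        int dy = std::abs(pos[i][1] - pos[j][1]);
        int dz = std::abs(pos[i][2] - pos[j][2]);
        if (dx + dy + dz == 1) { // face-adjacency paths through the patch
          seen[j] = true; stack[sp++] = j;
          if (is_face[j]) ++face_visited;
        }
      }
    }
    return face_visited == n_face;
  }

  void sweep() {
    int nfree = nsite - nxy; // non-substrate sites
    double invT = 1.0 / cfg.temperature;
    for (int k = 0; k < nfree; ++k) {
      ++att_count;
      int x = randint(nx), y = randint(ny), z = 1 + randint(nz - 1);
      int tgt = x + nx * (y + ny * z);
      int d = randint(6);
      int x2 = x + OFF6[d][0], y2 = y + OFF6[d][1], z2 = z + OFF6[d][2];
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 1 || z2 >= nz) continue;
      int src = x2 + nx * (y2 + ny * z2);
      if (owner[src] == owner[tgt]) continue;
      double dH = delta_H(tgt, src);
      if (dH <= 0 || runif01() < std::exp(-dH * invT)) {
        // legality check deferred to energetically accepted moves only
        if (cfg.connectivity && owner[tgt] > 0 && !removal_safe(tgt)) continue;
        apply_copy(tgt, src);
        ++acc_count;
      }
    }
  }

  // --- cohesotaxis -------------------------------------------------------

  // cell voxels with >= 1 face neighbor of medium, coordinates sorted lexicographically
  std::vector<int> free_edge(int c) const {
    std::vector<int> out;
    const std::vector<int>& vc = vox[c];
    for (size_t i = 0; i < vc.size(); ++i) {
      int idx = vc[i];
      int x = idx % nx, y = (idx / nx) % ny, z = idx / nxy;
      for (int k = 0; k < 6; ++k) {
        int x2 = x + OFF6[k][0], y2 = y + OFF6[k][1], z2 = z + OFF6[k][2];
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
        if (owner[x2 + nx * (y2 + ny * z2)] == 0) { out.push_back(idx); break; }
      }
    }
    std::sort(out.begin(), out.end(), [this](int i, int j) {
      int xi = i % nx, yi = (i / nx) % ny, zi = i / nxy;
      int xj = j % nx, yj = (j / nx) % ny, zj = j / nxy;
      if (xi != xj) return xi < xj;
      if (yi != yj) return yi < yj;
      return zi < zj;
    });
    return out;
  }

  // cell voxels with >= 1 face neighbor owned by a *different cell* (not medium/substrate)
  std::vector<int> cc_border(int c) const {
    std::vector<int> out;
    const std::vector<int>& vc = vox[c];
    for (size_t i = 0; i < vc.size(); ++i) {
      int idx = vc[i];
      int x = idx % nx, y = (idx / nx) % ny, z = idx / nxy;
      for (int k = 0; k < 6; ++k) {
        int x2 = x + OFF6[k][0], y2 = y + OFF6[k][1], z2 = z + OFF6[k][2];
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
        int o = owner[x2 + nx * (y2 + ny * z2)];
        if (o > 0 && o != c) { out.push_back(idx); break; }
      }
    }
    return out;
  }

  // Logistic with steepness s = 2^kappa over the fixed viewing window
  // [-5, 5]: kappa -> -6 flattens toward uniform (no migratory bias) and
  // kappa -> +6 saturates into a step that spreads the mass evenly over the
  // far-from-contact half of the sorted list.
  static std::vector<double> bias_weights_vec(int n, double kappa) {
    std::vector<double> w((size_t)n, 1.0);
    if (n == 1) return w;
    double s = std::pow(2.0, kappa);
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      double x = -5.0 + 10.0 * i / (n - 1.0);
      double f = 1.0 / (1.0 + std::exp(-s * x));
      w[i] = f; tot += f;
    }
    for (int i = 0; i < n; ++i) w[i] /= tot;
    return w;
  }

  // pick a free-edge voxel via the cohesotaxis weighting; u in [0,1) supplies
  // the random variate so the selection is testable in isolation.
  // Returns -1 when the cell has no free edge.
  int select_dir_voxel(int c, double kappa, bool bias_far, double u) const {
    std::vector<int> fe = free_edge(c);
    int n = (int)fe.size();
    if (n == 0) return -1;
    std::vector<int> border = cc_border(c);
    std::vector<double> key((size_t)n, 0.0);
    bool uniform = border.empty();
    if (!uniform) {
      for (int i = 0; i < n; ++i) {
        int idx = fe[i];
        double x = idx % nx, y = (int)(idx / nx) % ny, z = idx / nxy;
        double s = 0.0;
        for (size_t j = 0; j < border.size(); ++j) {
          int bidx = border[j];
          double dx = x - bidx % nx;
          double dy = y - (int)(bidx / nx) % ny;
          double dz = z - bidx / nxy;
          s += std::sqrt(dx * dx + dy * dy + dz * dz);
        }
        key[i] = s;
      }
    }
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(), [&](int i, int j) {
      if (key[i] != key[j]) return key[i] < key[j];
      return i < j; // fe already lexicographic
    });
    std::vector<double> w;
    if (uniform) w.assign((size_t)n, 1.0 / n);
    else w = bias_weights_vec(n, kappa);
    double acc = 0.0;
    int pick = n - 1;
    for (int i = 0; i < n; ++i) {
      double wi = bias_far ? w[i] : w[n - 1 - i];
      acc += wi;
      if (u < acc) { pick = i; break; }
    }
    return fe[ord[pick]];
  }

  // --- per-timestep link dynamics ---------------------------------------

  int find_link(int c, int kind) const {
    const std::vector<int>& lc = clinks[c];
    for (size_t i = 0; i < lc.size(); ++i)
      if (links[lc[i]].alive && links[lc[i]].kind == kind) return lc[i];
    return -1;
  }
  int cc_count(int c) const {
    int n = 0;
    const std::vector<int>& lc = clinks[c];
    for (size_t i = 0; i < lc.size(); ++i)
      if (links[lc[i]].alive && links[lc[i]].kind == KIND_CC) ++n;
    return n;
  }
  bool has_cc_link(int c, int o) const {
    const std::vector<int>& lc = clinks[c];
    for (size_t i = 0; i < lc.size(); ++i) {
      const LinkObj& L = links[lc[i]];
      if (L.alive && L.kind == KIND_CC && (L.a == o || L.b == o)) return true;
    }
    return false;
  }

  int add_link(int kind, int a, int b, double ax, double ay, double az,
               double lambda, double L) {
    LinkObj lk;
    lk.kind = kind; lk.a = a; lk.b = b;
    lk.ax = ax; lk.ay = ay; lk.az = az;
    lk.lambda = lambda; lk.L = L;
    lk.age = 0; lk.satisfied = false; lk.alive = true;
    int li = (int)links.size();
    links.push_back(lk);
    clinks[a].push_back(li);
    if (kind == KIND_CC) clinks[b].push_back(li);
    return li;
  }

  void make_lamellipodium(int c) {
    double u = runif01();
    int v = select_dir_voxel(c, cfg.kappa, cfg.bias_far, u);
    if (v < 0) return; // fully surrounded: behaves as a follower
    double vx = v % nx, vy = (v / nx) % ny;
    // direction projected onto the substrate plane: the anchor sits chi
    // voxels beyond the selected voxel, measured in-plane
    double dx = vx - cx(c), dy = vy - cy(c);
    double nrm = std::sqrt(dx * dx + dy * dy);
    if (nrm < 1e-9) {
      double th = 2.0 * M_PI * runif01();
      dx = std::cos(th); dy = std::sin(th); nrm = 1.0;
    }
    double ax = vx + cfg.chi * dx / nrm;
    double ay = vy + cfg.chi * dy / nrm;
    ax = std::min(std::max(ax, 0.0), nx - 1.0);
    ay = std::min(std::max(ay, 0.0), ny - 1.0);
    add_link(KIND_LAM, c, -1, ax, ay, 0.0, cfg.lambda_lamellipodia, 0.0);
  }

  void lam_turnover() {
    for (int c = 1; c <= ncell; ++c) {
      if (!alive[c] || ctype[c] != 1) continue;
      if (!fires(cfg.zeta_lamellipodia)) continue;
      int li = find_link(c, KIND_LAM);
      if (li >= 0) delete_link(li);
      if (!cfg.lam_blocked) make_lamellipodium(c);
    }
  }

  bool substrate_contact(int c) const { return subcount[c] > 0; }

  void fs_turnover() {
    for (int c = 1; c <= ncell; ++c) {
      if (!alive[c] || ctype[c] != 2) continue;
      int li = find_link(c, KIND_FS);
      if (!substrate_contact(c)) {
        if (li >= 0) delete_link(li);
        continue;
      }
      if (li < 0) {
        add_link(KIND_FS, c, -1, cx(c), cy(c), 0.0,
                 cfg.lambda_follower_substrate, cfg.L_fs);
      } else if (fires(cfg.zeta_substrate)) {
        links[li].ax = cx(c); links[li].ay = cy(c); links[li].az = 0.0;
        links[li].age = 0;
      }
    }
  }

  std::vector<int> adjacent_cells(int c) const {
    std::vector<int> nb;
    const std::vector<int>& vc = vox[c];
    for (size_t i = 0; i < vc.size(); ++i) {
      int idx = vc[i];
      int x = idx % nx, y = (idx / nx) % ny, z = idx / nxy;
      for (int k = 0; k < 6; ++k) {
        int x2 = x + OFF6[k][0], y2 = y + OFF6[k][1], z2 = z + OFF6[k][2];
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
        int o = owner[x2 + nx * (y2 + ny * z2)];
        if (o > 0 && o != c && std::find(nb.begin(), nb.end(), o) == nb.end())
          nb.push_back(o);
      }
    }
    std::sort(nb.begin(), nb.end());
    return nb;
  }

  void try_reform(int c) {
    if (!alive[c]) return;
    if (cc_count(c) >= cfg.max_neighbors) return;
    std::vector<int> nb = adjacent_cells(c);
    std::vector<int> elig;
    for (size_t i = 0; i < nb.size(); ++i) {
      int o = nb[i];
      if (!alive[o]) continue;
      if (has_cc_link(c, o)) continue;
      if (cc_count(o) >= cfg.max_neighbors) continue;
      elig.push_back(o);
    }
    if (elig.empty()) return;
    int o = elig[randint((int)elig.size())];
    add_link(KIND_CC, c, o, 0, 0, 0, cfg.lambda_tissue, cfg.L_cc);
    ++n_reforms;
  }

  void intercalation() {
    if (cfg.zeta_tissue <= 0) return;
    std::vector<int> broken;
    int nlink = (int)links.size();
    for (int i = 0; i < nlink; ++i)
      if (links[i].alive && links[i].kind == KIND_CC && fires(cfg.zeta_tissue))
        broken.push_back(i);
    for (size_t i = 0; i < broken.size(); ++i) {
      int li = broken[i];
      if (!links[li].alive) continue;
      int a = links[li].a, b = links[li].b;
      delete_link(li);
      ++n_breaks;
      int chooser = (runif01() < 0.5) ? a : b;
      try_reform(chooser);
    }
  }

  void update_satisfied_and_ages() {
    for (size_t i = 0; i < links.size(); ++i) {
      LinkObj& L = links[i];
      if (!L.alive) continue;
      if (L.kind == KIND_LAM && !L.satisfied) {
        double dx = cx(L.a) - L.ax, dy = cy(L.a) - L.ay;
        if (std::sqrt(dx * dx + dy * dy) <= cfg.reach_tol) L.satisfied = true;
      }
      L.age += 1;
    }
  }

  void step() {
    sweep();
    lam_turnover();
    fs_turnover();
    intercalation();
    update_satisfied_and_ages();
    ++mcs;
  }

  // --- measurement helpers ----------------------------------------------

  int substrate_cells() const {
    int n = 0;
    for (int c = 1; c <= ncell; ++c)
      if (alive[c] && substrate_contact(c)) ++n;
    return n;
  }

  // medium columns at the substrate-adjacent z-layer within a 1-based gap square
  int free_area(int gx0, int gx1, int gy0, int gy1) const {
    int n = 0;
    for (int y = gy0 - 1; y <= gy1 - 1; ++y)
      for (int x = gx0 - 1; x <= gx1 - 1; ++x)
        if (owner[x + nx * (y + ny * 1)] == 0) ++n;
    return n;
  }

  int link_count(int kind) const {
    int n = 0;
    for (size_t i = 0; i < links.size(); ++i)
      if (links[i].alive && links[i].kind == kind) ++n;
    return n;
  }

  List export_links() const {
    int n = 0;
    for (size_t i = 0; i < links.size(); ++i) if (links[i].alive) ++n;
    IntegerVector kind(n), a(n), b(n), age(n);
    NumericVector ax(n), ay(n), az(n), lambda(n), tl(n);
    LogicalVector sat(n);
    int k = 0;
    for (size_t i = 0; i < links.size(); ++i) {
      const LinkObj& L = links[i];
      if (!L.alive) continue;
      kind[k] = L.kind; a[k] = L.a;
      b[k] = (L.kind == KIND_CC) ? L.b : NA_INTEGER;
      if (L.kind == KIND_CC) {
        ax[k] = NA_REAL; ay[k] = NA_REAL; az[k] = NA_REAL;
      } else {
        ax[k] = L.ax + 1.0; ay[k] = L.ay + 1.0; az[k] = L.az + 1.0;
      }
      lambda[k] = L.lambda; tl[k] = L.L; age[k] = L.age;
      sat[k] = L.satisfied;
      ++k;
    }
    return List::create(_["kind"] = kind, _["a"] = a, _["b"] = b,
                        _["anchor_x"] = ax, _["anchor_y"] = ay, _["anchor_z"] = az,
                        _["lambda"] = lambda, _["target_length"] = tl,
                        _["age"] = age, _["satisfied"] = sat);
  }

  IntegerVector export_owner() const {
    IntegerVector out(owner.begin(), owner.end());
    out.attr("dim") = IntegerVector::create(nx, ny, nz);
    return out;
  }
};

// [[Rcpp::export]]
double cpp_total_energy(List state, List config) {
  Engine e(state, config);
  return e.total_energy();
}

// [[Rcpp::export]]
double cpp_delta_energy(List state, List config, IntegerVector source, IntegerVector target) {
  Engine e(state, config);
  auto toidx = [&](IntegerVector v) {
    int x = v[0] - 1, y = v[1] - 1, z = v[2] - 1;
    if (x < 0 || x >= e.nx || y < 0 || y >= e.ny || z < 0 || z >= e.nz)
      stop("voxel outside the lattice");
    return x + e.nx * (y + e.ny * z);
  };
  int s = toidx(source), t = toidx(target);
  if (s / e.nxy == 0 || t / e.nxy == 0)
    stop("copy attempts involving substrate voxels are not allowed");
  if (e.owner[s] == e.owner[t])
    stop("source and target voxels have the same owner");
  return e.delta_H(t, s);
}

// [[Rcpp::export]]
List cpp_run(List state, List config, int n_mcs, int seed, int sample_every,
             IntegerVector gap, bool stop_when_closed, int close_threshold) {
  Engine e(state, config);
  e.rng.seed((uint64_t)seed);
  bool has_gap = gap.size() == 4;
  int nsamp_max = n_mcs / std::max(sample_every, 1) + 2;
  std::vector<double> s_mcs; s_mcs.reserve(nsamp_max);
  std::vector<int> s_sub; s_sub.reserve(nsamp_max);
  std::vector<int> s_area; s_area.reserve(nsamp_max);
  std::vector<double> s_acc; s_acc.reserve(nsamp_max);
  std::vector<int> s_lam; s_lam.reserve(nsamp_max);
  std::vector<int> s_cc; s_cc.reserve(nsamp_max);
  std::vector<double> cxs, cys, czs; // per sample x per cell (NA when dead)
  long long acc_prev = 0, att_prev = 0;
  bool closed = false;

  auto record = [&]() {
    s_mcs.push_back((double)e.mcs);
    s_sub.push_back(e.substrate_cells());
    int fa = has_gap ? e.free_area(gap[0], gap[1], gap[2], gap[3]) : NA_INTEGER;
    s_area.push_back(fa);
    long long att = e.att_count - att_prev, acc = e.acc_count - acc_prev;
    s_acc.push_back(att > 0 ? (double)acc / att : NA_REAL);
    acc_prev = e.acc_count; att_prev = e.att_count;
    s_lam.push_back(e.link_count(KIND_LAM));
    s_cc.push_back(e.link_count(KIND_CC));
    for (int c = 1; c <= e.ncell; ++c) {
      if (e.alive[c]) {
        cxs.push_back(e.cx(c) + 1.0);
        cys.push_back(e.cy(c) + 1.0);
        czs.push_back(e.cz(c) + 1.0);
      } else {
        cxs.push_back(NA_REAL); cys.push_back(NA_REAL); czs.push_back(NA_REAL);
      }
    }
    if (has_gap && fa <= close_threshold) closed = true;
  };

  record();
  for (int t = 1; t <= n_mcs; ++t) {
    e.step();
    if (sample_every > 0 && (t % sample_every == 0)) {
      record();
      if (stop_when_closed && closed) break;
    }
    if (t % 200 == 0) Rcpp::checkUserInterrupt();
  }
  if (sample_every <= 0 || ( (n_mcs % sample_every) != 0 && !(stop_when_closed && closed) )) {
    record();
  }

  int nsamp = (int)s_mcs.size();
  NumericVector cent(cxs.size() * 3);
  // layout: [sample, cell, coord] column-major like an R array dim c(nsamp, ncell, 3)
  for (int s = 0; s < nsamp; ++s)
    for (int c = 0; c < e.ncell; ++c) {
      cent[s + nsamp * c] = cxs[(size_t)s * e.ncell + c];
      cent[s + nsamp * (c + e.ncell)] = cys[(size_t)s * e.ncell + c];
      cent[s + nsamp * (c + 2 * e.ncell)] = czs[(size_t)s * e.ncell + c];
    }
  cent.attr("dim") = IntegerVector::create(nsamp, e.ncell, 3);

  IntegerVector vols(e.ncell);
  LogicalVector aliv(e.ncell);
  for (int c = 1; c <= e.ncell; ++c) { vols[c - 1] = e.vol[c]; aliv[c - 1] = e.alive[c] != 0; }

  return List::create(
    _["owner"] = e.export_owner(),
    _["links"] = e.export_links(),
    _["mcs"] = (double)e.mcs,
    _["volumes"] = vols,
    _["alive"] = aliv,
    _["samples"] = List::create(
      _["mcs"] = NumericVector(s_mcs.begin(), s_mcs.end()),
      _["substrate_cells"] = IntegerVector(s_sub.begin(), s_sub.end()),
      _["free_area"] = IntegerVector(s_area.begin(), s_area.end()),
      _["acceptance"] = NumericVector(s_acc.begin(), s_acc.end()),
      _["n_lamellipodium"] = IntegerVector(s_lam.begin(), s_lam.end()),
      _["n_cell_cell"] = IntegerVector(s_cc.begin(), s_cc.end()),
      _["centroid"] = cent),
    _["n_breaks"] = (double)e.n_breaks,
    _["n_reforms"] = (double)e.n_reforms,
    _["acceptance_overall"] = e.att_count > 0 ? (double)e.acc_count / e.att_count : NA_REAL,
    _["closed"] = closed);
}

static IntegerMatrix idx_to_coords(const Engine& e, const std::vector<int>& idx) {
  IntegerMatrix out((int)idx.size(), 3);
  for (size_t i = 0; i < idx.size(); ++i) {
    out(i, 0) = idx[i] % e.nx + 1;
    out(i, 1) = (idx[i] / e.nx) % e.ny + 1;
    out(i, 2) = idx[i] / e.nxy + 1;
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_free_edge_voxels(List state, List config, int cell_id) {
  Engine e(state, config);
  if (cell_id < 1 || cell_id > e.ncell || !e.alive[cell_id]) stop("not a live cell id");
  return idx_to_coords(e, e.free_edge(cell_id));
}

// [[Rcpp::export]]
IntegerMatrix cpp_cell_border_voxels(List state, List config, int cell_id) {
  Engine e(state, config);
  if (cell_id < 1 || cell_id > e.ncell || !e.alive[cell_id]) stop("not a live cell id");
  std::vector<int> b = e.cc_border(cell_id);
  std::sort(b.begin(), b.end(), [&e](int i, int j) {
    int xi = i % e.nx, yi = (i / e.nx) % e.ny, zi = i / e.nxy;
    int xj = j % e.nx, yj = (j / e.nx) % e.ny, zj = j / e.nxy;
    if (xi != xj) return xi < xj;
    if (yi != yj) return yi < yj;
    return zi < zj;
  });
  return idx_to_coords(e, b);
}

// [[Rcpp::export]]
NumericVector cpp_bias_weights(int n, double kappa) {
  if (n < 1) stop("n must be >= 1");
  std::vector<double> w = Engine::bias_weights_vec(n, kappa);
  return NumericVector(w.begin(), w.end());
}

// [[Rcpp::export]]
IntegerVector cpp_select_direction_voxel(List state, List config, int cell_id,
                                         double kappa, bool bias_far, double u) {
  Engine e(state, config);
  if (cell_id < 1 || cell_id > e.ncell || !e.alive[cell_id]) stop("not a live cell id");
  int v = e.select_dir_voxel(cell_id, kappa, bias_far, u);
  if (v < 0) stop("cell has no free-edge voxel");
  return IntegerVector::create(v % e.nx + 1, (v / e.nx) % e.ny + 1, v / e.nxy + 1);
}

// number of face-connected components per cell (fragmentation diagnostic)
// [[Rcpp::export]]
IntegerVector cpp_component_counts(List state, List config) {
  Engine e(state, config);
  IntegerVector out(e.ncell);
  std::vector<int> comp(e.nsite, -1);
  for (int c = 1; c <= e.ncell; ++c) {
    if (!e.alive[c]) { out[c - 1] = 0; continue; }
    int ncomp = 0;
    const std::vector<int>& vc = e.vox[c];
    for (size_t i = 0; i < vc.size(); ++i) comp[vc[i]] = 0;
    std::vector<int> stack;
    for (size_t i = 0; i < vc.size(); ++i) {
      if (comp[vc[i]] != 0) continue;
      ++ncomp;
      stack.push_back(vc[i]);
      comp[vc[i]] = ncomp;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int x = idx % e.nx, y = (idx / e.nx) % e.ny, z = idx / e.nxy;
        for (int k = 0; k < 6; ++k) {
          int x2 = x + OFF6[k][0], y2 = y + OFF6[k][1], z2 = z + OFF6[k][2];
          if (x2 < 0 || x2 >= e.nx || y2 < 0 || y2 >= e.ny || z2 < 0 || z2 >= e.nz) continue;
          int j = x2 + e.nx * (y2 + e.ny * z2);
          if (e.owner[j] == c && comp[j] == 0) { comp[j] = ncomp; stack.push_back(j); }
        }
      }
    }
    for (size_t i = 0; i < vc.size(); ++i) comp[vc[i]] = -1;
    out[c - 1] = ncomp;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_cell_table(List state, List config) {
  Engine e(state, config);
  IntegerVector id(e.ncell), type(e.ncell), volume(e.ncell);
  NumericVector x(e.ncell), y(e.ncell), z(e.ncell);
  LogicalVector aliv(e.ncell), sub(e.ncell);
  for (int c = 1; c <= e.ncell; ++c) {
    id[c - 1] = c; type[c - 1] = e.ctype[c]; volume[c - 1] = e.vol[c];
    aliv[c - 1] = e.alive[c] != 0;
    if (e.alive[c]) {
      x[c - 1] = e.cx(c) + 1; y[c - 1] = e.cy(c) + 1; z[c - 1] = e.cz(c) + 1;
      sub[c - 1] = e.substrate_contact(c);
    } else {
      x[c - 1] = NA_REAL; y[c - 1] = NA_REAL; z[c - 1] = NA_REAL;
      sub[c - 1] = false;
    }
  }
  return List::create(_["id"] = id, _["type"] = type, _["volume"] = volume,
                      _["x"] = x, _["y"] = y, _["z"] = z,
                      _["alive"] = aliv, _["substrate_contact"] = sub);
}
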