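// Lattice self-assembly of polyominoes from interacting square tiles.
//
// A genotype encodes the edge colours of n_tiles tile types (4 edges x
// log2(n_colours) bits per edge). Colour 0 is neutral; colour 2k-1 binds
// only colour 2k (k >= 1); the top colour of an even-sized palette is
// unpaired. Assembly seeds tile type 0 and repeatedly picks a random open
// bond, attaching a uniformly chosen matching tile/orientation. A genotype
// maps to a phenotype only when `repeats` independent random assembly
// orders all terminate within the grid limit with the identical canonical
// shape; otherwise the outcome is UND (unbounded/non-deterministic),
// returned as NA.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>

using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4B9D9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  int next(int n) { return static_cast<int>(splitmix64(s) % static_cast<uint64_t>(n)); }
};

// partner colour under the pairing 1<->2, 3<->4, ...; -1 = binds nothing
inline int partner(int c, int n_colours) {
  if (c == 0) return -1;
  int p = (c % 2 == 1) ? c + 1 : c - 1;
  return (p >= 1 && p < n_colours) ? p : -1;
}

// directions: 0=N, 1=E, 2=S, 3=W (N = -row, E = +col)
const int DR[4] = {-1, 0, 1, 0};
const int DC[4] = {0, 1, 0, -1};

struct Bond {
  int16_t r, c;   // empty target cell
  int8_t back;    // direction from target back toward the placed tile
  int8_t need;    // colour required on the candidate tile's `back` edge
};

struct Model {
  int n_tiles, n_colours, grid_limit, repeats;
  int bits_per_edge;
  bool reflect;
  std::vector<int> col;  // col[t * 4 + e]
  // reusable assembly workspace (cleared incrementally between runs)
  std::vector<uint8_t> occ;
  std::vector<int> touched;
  std::vector<Bond> bonds;
  void decode(uint32_t g) {
    for (int t = 0; t < n_tiles; ++t)
      for (int e = 0; e < 4; ++e)
        col[t * 4 + e] =
            (g >> (bits_per_edge * (4 * t + e))) & ((1u << bits_per_edge) - 1);
  }
  // edge colour of tile t rotated r quarter-turns clockwise, facing dir d
  inline int edge(int t, int r, int d) const { return col[t * 4 + ((d - r + 4) & 3)]; }
};

// canonical key "RxC:bits" minimized over the 4 rotations, optionally also
// over the 4 mirrored rotations (reflection identification)
std::string canonical_key(const std::vector<uint8_t> &occ, int nr, int nc,
                          int r0, int c0, int stride, bool reflect) {
  std::string best;
  int n_tr = reflect ? 8 : 4;
  for (int tr = 0; tr < n_tr; ++tr) {
    int rot = tr & 3;
    bool mir = tr >= 4;  // mirror columns before rotating
    int outr = (rot % 2 == 0) ? nr : nc;
    int outc = (rot % 2 == 0) ? nc : nr;
    std::string key = std::to_string(outr) + "x" + std::to_string(outc) + ":";
    key.reserve(key.size() + outr * outc);
    for (int i = 0; i < outr; ++i) {
      for (int j = 0; j < outc; ++j) {
        int r, c;  // source cell in the un-rotated grid
        switch (rot) {
          case 0: r = i;            c = j;            break;
          case 1: r = nr - 1 - j;   c = i;            break; // 90 cw
          case 2: r = nr - 1 - i;   c = nc - 1 - j;   break;
          default: r = j;           c = nc - 1 - i;   break; // 270 cw
        }
        if (mir) c = nc - 1 - c;
        key.push_back(occ[(r0 + r) * stride + (c0 + c)] ? '1' : '0');
      }
    }
    if (best.empty() || key < best) best = key;
  }
  return best;
}

// one stochastic assembly; returns canonical key, or "" when the bounding
// box exceeds grid_limit (unbounded growth)
std::string assemble_once(Model &m, Rng &rng) {
  const int G = 2 * m.grid_limit + 4;
  const int ctr = m.grid_limit + 2;
  std::vector<uint8_t> &occ = m.occ;
  std::vector<Bond> &bonds = m.bonds;
  for (int cell : m.touched) occ[cell] = 0;
  m.touched.clear();
  bonds.clear();
  int minr = ctr, maxr = ctr, minc = ctr, maxc = ctr;

  auto place = [&](int r, int c, int t, int rot) {
    occ[r * G + c] = 1;
    m.touched.push_back(r * G + c);
    if (r < minr) minr = r;
    if (r > maxr) maxr = r;
    if (c < minc) minc = c;
    if (c > maxc) maxc = c;
    for (int d = 0; d < 4; ++d) {
      int nr = r + DR[d], nc = c + DC[d];
      if (occ[nr * G + nc]) continue;
      int p = partner(m.edge(t, rot, d), m.n_colours);
      if (p >= 0)
        bonds.push_back({static_cast<int16_t>(nr), static_cast<int16_t>(nc),
                         static_cast<int8_t>((d + 2) & 3),
                         static_cast<int8_t>(p)});
    }
  };

  place(ctr, ctr, 0, 0);
  int match_t[32], match_r[32];
  while (!bonds.empty()) {
    int idx = rng.next(static_cast<int>(bonds.size()));
    Bond b = bonds[idx];
    bonds[idx] = bonds.back();
    bonds.pop_back();
    if (occ[b.r * G + b.c]) continue;  // stale: cell filled meanwhile
    int n_match = 0;
    for (int t = 0; t < m.n_tiles; ++t)
      for (int r = 0; r < 4; ++r)
        if (m.edge(t, r, b.back) == b.need) {
          match_t[n_match] = t;
          match_r[n_match] = r;
          ++n_match;
        }
    if (n_match == 0) continue;
    int pick = (n_match == 1) ? 0 : rng.next(n_match);
    place(b.r, b.c, match_t[pick], match_r[pick]);
    if (maxr - minr + 1 > m.grid_limit || maxc - minc + 1 > m.grid_limit)
      return std::string();
  }
  return canonical_key(occ, maxr - minr + 1, maxc - minc + 1, minr, minc, G,
                       m.reflect);
}

// full determinism-checked phenotype of one genotype; "" = UND
std::string phenotype_of(Model &m, uint32_t g, uint64_t base_seed) {
  m.decode(g);
  // if the seed tile's edges cannot bind anything, the result is always a
  // single tile; skip the stochastic repeats
  bool seed_binds = false;
  for (int e = 0; e < 4 && !seed_binds; ++e) {
    int p = partner(m.col[e], m.n_colours);
    if (p < 0) continue;
    for (int k = 0; k < m.n_tiles * 4; ++k)
      if (m.col[k] == p) { seed_binds = true; break; }
  }
  if (!seed_binds) return "1x1:1";
  uint64_t s = base_seed * 0x9E3779B97F4A7C15ULL ^ (static_cast<uint64_t>(g) << 1);
  Rng rng(s);
  std::string first = assemble_once(m, rng);
  if (first.empty()) return std::string();
  for (int rep = 1; rep < m.repeats; ++rep) {
    std::string k = assemble_once(m, rng);
    if (k != first) return std::string();
  }
  return first;
}

Model make_model(int n_tiles, int n_colours, int repeats, int grid_limit,
                 bool reflect) {
  if (n_tiles < 1 || n_colours < 2 || repeats < 1 || grid_limit < 2)
    stop("invalid polyomino model parameters");
  int bpe = 0;
  while ((1 << bpe) < n_colours) ++bpe;
  if ((1 << bpe) != n_colours) stop("n_colours must be a power of two");
  if (bpe * 4 * n_tiles > 30) stop("genotype exceeds 30 bits");
  Model m;
  m.n_tiles = n_tiles;
  m.n_colours = n_colours;
  m.repeats = repeats;
  m.grid_limit = grid_limit;
  m.bits_per_edge = bpe;
  m.reflect = reflect;
  m.col.assign(n_tiles * 4, 0);
  int g = 2 * grid_limit + 4;
  m.occ.assign(g * g, 0);
  m.touched.reserve(grid_limit * grid_limit + 8);
  m.bonds.reserve(256);
  return m;
}

}  // namespace

// [[Rcpp::export]]
CharacterVector poly_assemble_batch(IntegerVector genotypes, int n_tiles,
                                    int n_colours, int repeats, int grid_limit,
                                    double seed, bool reflect = false) {
  Model m = make_model(n_tiles, n_colours, repeats, grid_limit, reflect);
  uint64_t base_seed = static_cast<uint64_t>(seed);
  std::unordered_map<uint32_t, std::string> cache;
  cache.reserve(genotypes.size());
  CharacterVector out(genotypes.size());
  for (R_xlen_t i = 0; i < genotypes.size(); ++i) {
    if (i % 100000 == 0) checkUserInterrupt();
    uint32_t g = static_cast<uint32_t>(genotypes[i]);
    auto it = cache.find(g);
    std::string ph;
    if (it != cache.end()) {
      ph = it->second;
    } else {
      ph = phenotype_of(m, g, base_seed);
      cache.emplace(g, ph);
    }
    if (ph.empty())
      out[i] = NA_STRING;
    else
      out[i] = ph;
  }
  return out;
}

// [[Rcpp::export]]
List poly_enumerate_space(int n_tiles, int n_colours, int repeats,
                          int grid_limit, double seed, bool reflect = false) {
  Model m = make_model(n_tiles, n_colours, repeats, grid_limit, reflect);
  uint64_t base_seed = static_cast<uint64_t>(seed);
  uint64_t space = 1ULL << (m.bits_per_edge * 4 * n_tiles);
  std::unordered_map<std::string, double> counts;
  double n_und = 0;
  for (uint64_t g = 0; g < space; ++g) {
    if (g % 1000000 == 0) checkUserInterrupt();
    std::string ph = phenotype_of(m, static_cast<uint32_t>(g), base_seed);
    if (ph.empty())
      n_und += 1;
    else
      counts[ph] += 1;
  }
  CharacterVector shapes(counts.size());
  NumericVector n(counts.size());
  R_xlen_t i = 0;
  for (const auto &kv : counts) {
    shapes[i] = kv.first;
    n[i] = kv.second;
    ++i;
  }
  return List::create(_["shape"] = shapes, _["count"] = n,
                      _["n_und"] = n_und);
}
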