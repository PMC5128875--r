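// Event-driven discontinuous molecular dynamics core.
//
// Particles move ballistically between exactly resolved discontinuous
// events: hard-core collisions, square-well crossings, bond-wall
// reflections, hydrogen-bond formation/breaking, Andersen thermostat ghost
// kicks, and neighbour-list rebuild ghosts.  Potential energy is tracked
// through discrete shell occupancy (never through distances), so energy
// bookkeeping across events is exact up to floating-point impulse error.
//
// Scheduling contract: each bead stores the earliest event among its pairs
// (the globally earliest pair event is necessarily the minimum of both of
// its beads), an indexed binary heap keyed by (time, bead id) supplies the
// global minimum, and all affected predictions are recomputed eagerly after
// every event.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <functional>
#include <unordered_map>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------- RNG ----
struct Pcg32 {
  uint64_t state, inc;
  double spare; bool has_spare;
  Pcg32(uint64_t seed, uint64_t seq = 54u) : spare(0), has_spare(false) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double uniform() {  // in (0, 1)
    return (next() + 1.0) * (1.0 / 4294967297.0);
  }
  double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = uniform(), u2 = uniform();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    spare = r * std::sin(a); has_spare = true;
    return r * std::cos(a);
  }
  double expo(double rate) { return -std::log(uniform()) / rate; }
};

// -------------------------------------------------------------- engine ---
enum EvKind { EV_NONE = 0, EV_CORE, EV_WALL_LO, EV_WALL_HI, EV_WELL_IN,
              EV_WELL_OUT, EV_HB_FORM, EV_HB_IN, EV_HB_OUT };

// smallest positive root of c3 t^3 + c2 t^2 + c1 t + c0 = 0 (Inf if none)
static double smallestPosRoot(double c3, double c2, double c1, double c0) {
  const double inf = std::numeric_limits<double>::infinity();
  double roots[3]; int nr = 0;
  if (std::fabs(c3) < 1e-14 * (std::fabs(c2) + std::fabs(c1) + 1.0)) {
    if (std::fabs(c2) < 1e-14 * (std::fabs(c1) + 1.0)) {
      if (c1 == 0) return inf;
      roots[nr++] = -c0 / c1;
    } else {
      double disc = c1 * c1 - 4 * c2 * c0;
      if (disc < 0) return inf;
      double s = std::sqrt(disc);
      double q = -(c1 + (c1 >= 0 ? s : -s)) / 2;
      roots[nr++] = q / c2;
      if (q != 0) roots[nr++] = c0 / q;
    }
  } else {
    double a = c2 / c3, b = c1 / c3, c = c0 / c3;
    double p = b - a * a / 3.0;
    double q = 2.0 * a * a * a / 27.0 - a * b / 3.0 + c;
    double off = -a / 3.0;
    double disc = q * q / 4.0 + p * p * p / 27.0;
    if (disc > 0) {
      double sq = std::sqrt(disc);
      double u = std::cbrt(-q / 2.0 + sq);
      double v = std::cbrt(-q / 2.0 - sq);
      roots[nr++] = u + v + off;
    } else {
      double r = std::sqrt(-p * p * p / 27.0);
      double phi = std::acos(std::min(1.0, std::max(-1.0,
                    -q / (2.0 * r))));
      double m = 2.0 * std::cbrt(r);
      roots[nr++] = m * std::cos(phi / 3.0) + off;
      roots[nr++] = m * std::cos((phi + 2.0 * M_PI) / 3.0) + off;
      roots[nr++] = m * std::cos((phi + 4.0 * M_PI) / 3.0) + off;
    }
  }
  double best = inf;
  for (int k = 0; k < nr; ++k) {
    double t = roots[k];
    if (!std::isfinite(t) || t <= 1e-9) continue;
    // one Newton polish
    for (int it = 0; it < 2; ++it) {
      double f = ((c3 * t + c2) * t + c1) * t + c0;
      double df = (3 * c3 * t + 2 * c2) * t + c1;
      if (df != 0) t -= f / df;
    }
    if (t > 1e-9 && t < best) best = t;
  }
  return best;
}

struct PairPot {
  // type: 0 none, 1 bond, 2 core-only, 3 sc-well, 4 hb
  int type;
  double lo, hi;          // bond walls
  double rads[3];         // ascending radii (core first)
  double U[4];            // U[k] energy between rads[k-1] and rads[k]
  int m;                  // number of radii
};

struct Engine {
  int N;
  double L;
  std::vector<double> px, py, pz, vx, vy, vz, pt;  // pt: per-bead time
  std::vector<int> chain, res, kind, aa;           // kind: 0NH 1CA 2CO 3SC
  std::vector<double> mass;

  // tables
  double bbDiam[3];
  std::vector<double> scDiam;               // 20
  std::vector<double> wDepth, wRange, wDepth2, wRange2;  // 20x20 (col-major)
  bool hasWell2;
  double squeezeFactor;
  double hbCore, hbRange, epsHB, auxMin, cosThresh;
  int minSeqSep; bool parallelOn;
  int sbResA, sbAaA, sbResB, sbAaB; double sbFactor;

  // bonds
  std::unordered_map<uint64_t, int> bondOf;  // key -> bond idx
  std::vector<double> bondLo, bondHi;
  std::vector<std::vector<int>> bondsOf;     // bead -> bonded partners

  // neighbour lists with cached pair potentials (rebuilt each epoch)
  struct Nb { int j; PairPot p; };
  std::vector<std::vector<Nb>> nbr;
  double horizon, skin;

  // dynamic pair state
  std::unordered_map<uint64_t, int> zone;    // SC pairs inside a well
  std::vector<int> hbPartner;                // bead index or -1

  // lookup (chain, res, kind) -> bead
  int minChain, nChain, minRes, nRes;
  std::vector<int> lut;

  // chirality walls (L-isomer preservation): one group per side-chain
  // residue; an event fires when det(NH-CA, CO-CA, SC-CA) drops to the
  // margin and reflects the velocity component along the constraint
  // gradient (exact, momentum- and energy-conserving)
  int G;
  std::vector<int> chNH, chCA, chCO, chSC;
  std::vector<double> chMargin;
  std::vector<int> groupOf;
  std::vector<double> chT;

  // events
  std::vector<double> evT;     // per-bead pair-event time
  std::vector<int> evPartner;
  std::vector<int> evKind;
  std::vector<double> evRad;
  std::vector<double> kickT;
  // heap
  std::vector<int> heap, hpos;

  // bookkeeping
  double t, pe, ke;
  double vmax, dispBudget, lastBudgetT, rebuildT;
  double Ttarget, kickRate;
  Pcg32 rng;
  double collisions;
  std::unordered_map<std::string, double> counts;
  std::string error;

  Engine(uint64_t seed) : rng(seed) {}

  // ---- helpers
  inline uint64_t pkey(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (uint64_t)i * (uint64_t)N + (uint64_t)j;
  }
  inline double mimg(double d) const {
    if (d > 0.5 * L) d -= L * std::floor(d / L + 0.5);
    else if (d < -0.5 * L) d -= L * std::floor(d / L + 0.5);
    return d;
  }
  inline void rel(int i, int j, double at, double dr[3], double dv[3]) const {
    dr[0] = mimg((px[i] + vx[i] * (at - pt[i])) -
                 (px[j] + vx[j] * (at - pt[j])));
    dr[1] = mimg((py[i] + vy[i] * (at - pt[i])) -
                 (py[j] + vy[j] * (at - pt[j])));
    dr[2] = mimg((pz[i] + vz[i] * (at - pt[i])) -
                 (pz[j] + vz[j] * (at - pt[j])));
    dv[0] = vx[i] - vx[j]; dv[1] = vy[i] - vy[j]; dv[2] = vz[i] - vz[j];
  }
  inline void posAt(int i, double at, double out[3]) const {
    out[0] = px[i] + vx[i] * (at - pt[i]);
    out[1] = py[i] + vy[i] * (at - pt[i]);
    out[2] = pz[i] + vz[i] * (at - pt[i]);
  }
  inline void advanceBead(int i, double at) {
    px[i] += vx[i] * (at - pt[i]);
    py[i] += vy[i] * (at - pt[i]);
    pz[i] += vz[i] * (at - pt[i]);
    pt[i] = at;
  }
  inline double dist2At(int a, int b, double at) const {
    double pa[3], pb[3];
    posAt(a, at, pa); posAt(b, at, pb);
    double dx = mimg(pa[0] - pb[0]), dy = mimg(pa[1] - pb[1]),
           dz = mimg(pa[2] - pb[2]);
    return dx * dx + dy * dy + dz * dz;
  }
  inline int lookup(int c, int r, int k) const {
    if (c < minChain || c >= minChain + nChain) return -1;
    if (r < minRes || r >= minRes + nRes) return -1;
    return lut[(((size_t)(c - minChain) * nRes) + (r - minRes)) * 4 + k];
  }
  inline double beadDiam(int i) const {
    return kind[i] == 3 ? scDiam[aa[i]] : bbDiam[kind[i]];
  }
  inline double wellDepthOf(int i, int j) const {
    double d = wDepth[aa[i] * 20 + aa[j]];
    bool hit = (aa[i] == sbAaA && res[i] == sbResA &&
                aa[j] == sbAaB && res[j] == sbResB) ||
               (aa[j] == sbAaA && res[j] == sbResA &&
                aa[i] == sbAaB && res[i] == sbResB);
    return hit ? d * sbFactor : d;
  }

  PairPot classify(int i, int j) const {
    PairPot p; p.type = 0; p.m = 0;
    auto it = bondOf.find(pkey(i, j));
    if (it != bondOf.end()) {
      p.type = 1; p.lo = bondLo[it->second]; p.hi = bondHi[it->second];
      return p;
    }
    bool same = chain[i] == chain[j];
    int dres = std::abs(res[i] - res[j]);
    double core = 0.5 * (beadDiam(i) + beadDiam(j));
    if (same && dres <= 1) {
      p.type = 2; p.m = 1; p.rads[0] = core * squeezeFactor;
      p.U[0] = INF; p.U[1] = 0;
      return p;
    }
    bool nhco = (kind[i] == 0 && kind[j] == 2) ||
                (kind[i] == 2 && kind[j] == 0);
    if (nhco && (!same || dres >= minSeqSep)) {
      p.type = 4; p.m = 2;
      p.rads[0] = hbCore; p.rads[1] = hbRange;
      p.U[0] = INF; p.U[1] = -epsHB; p.U[2] = 0;
      return p;
    }
    if (kind[i] == 3 && kind[j] == 3) {
      double d1 = wellDepthOf(i, j);
      double r1 = wRange[aa[i] * 20 + aa[j]];
      double d2 = hasWell2 ? wDepth2[aa[i] * 20 + aa[j]] : 0.0;
      double r2 = hasWell2 ? wRange2[aa[i] * 20 + aa[j]] : 0.0;
      if (d1 != 0.0 && d2 != 0.0) {
        p.type = 3; p.m = 3;
        p.rads[0] = core; p.rads[1] = r1; p.rads[2] = r2;
        p.U[0] = INF; p.U[1] = -d1; p.U[2] = -d2; p.U[3] = 0;
        return p;
      }
      if (d1 != 0.0) {
        p.type = 3; p.m = 2;
        p.rads[0] = core; p.rads[1] = r1;
        p.U[0] = INF; p.U[1] = -d1; p.U[2] = 0;
        return p;
      }
    }
    p.type = 2; p.m = 1; p.rads[0] = core; p.U[0] = INF; p.U[1] = 0;
    return p;
  }

  inline int zoneOf(int i, int j, const PairPot& p) const {
    if (p.type == 3) {
      auto it = zone.find(pkey(i, j));
      return it == zone.end() ? p.m : it->second;
    }
    if (p.type == 4) {
      return (hbPartner[i] == j) ? 1 : p.m;  // formed: inside the HB well
    }
    return p.m;
  }

  // earliest positive crossing of radius R for straight-line relative
  // motion; from inside (want outward root) or outside (inward root)
  static double crossTime(const double dr[3], const double dv[3], double R,
                          bool fromInside) {
    double a = dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2];
    if (a <= 0) return INF;
    double b = 2.0 * (dr[0] * dv[0] + dr[1] * dv[1] + dr[2] * dv[2]);
    double c = dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2] - R * R;
    if (fromInside) {
      if (c > 0) c = 0;  // FP guard: treat as exactly on the shell
      double disc = b * b - 4 * a * c;
      double s = std::sqrt(disc);
      double tt = (-b + s) / (2 * a);
      return tt > 0 ? tt : INF;
    }
    if (b >= 0) return INF;         // receding
    if (c < 0) c = 0;               // FP guard
    double disc = b * b - 4 * a * c;
    if (disc <= 0) return INF;      // misses the shell
    double s = std::sqrt(disc);
    double tt = (2 * c) / (-b + s); // stable small root
    return tt > 0 ? tt : (c == 0 ? INF : 0.0);
  }

  // predict the earliest event for pair (i, j); returns time and fills
  // kind/radius
  double predictPair(int i, int j, const PairPot& p, double at, int& ek,
                     double& rad) {
    double dr[3], dv[3];
    rel(i, j, at, dr, dv);
    ek = EV_NONE; rad = 0;
    if (p.type == 1) {
      double tlo = crossTime(dr, dv, p.lo, false);
      double thi = crossTime(dr, dv, p.hi, true);
      if (tlo < thi) { ek = EV_WALL_LO; rad = p.lo; return at + tlo; }
      if (std::isfinite(thi)) { ek = EV_WALL_HI; rad = p.hi; return at + thi; }
      return INF;
    }
    double best = INF; int bk = EV_NONE; double br = 0;
    if (p.type == 4) {
      // hydrogen-bond pair: the well applies only while the bond is
      // formed; an unformed pair sees the hard core plus (when both
      // partners are free and the pair is outside the range) a formation
      // attempt at the range crossing
      double tcore = crossTime(dr, dv, p.rads[0], false);
      if (tcore < best) { best = tcore; br = p.rads[0]; bk = EV_CORE; }
      if (hbPartner[i] == j) {
        double tout = crossTime(dr, dv, p.rads[1], true);
        if (tout < best) { best = tout; br = p.rads[1]; bk = EV_HB_OUT; }
      } else if (hbPartner[i] < 0 && hbPartner[j] < 0) {
        double c = dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2] -
                   hbRange * hbRange;
        if (c > 1e-9) {
          double tf = crossTime(dr, dv, hbRange, false);
          if (tf < best) { best = tf; br = hbRange; bk = EV_HB_FORM; }
        }
      }
      if (!std::isfinite(best)) { ek = EV_NONE; return INF; }
      ek = bk; rad = br;
      return at + best;
    }
    int z = zoneOf(i, j, p);
    // inward crossing of rads[z-1]
    if (z >= 1 && z <= p.m) {
      double tin = crossTime(dr, dv, p.rads[z - 1], false);
      if (tin < best) {
        best = tin; br = p.rads[z - 1];
        bk = (z == 1) ? EV_CORE : EV_WELL_IN;
      }
    }
    // outward crossing of rads[z]
    if (z < p.m) {
      double tout = crossTime(dr, dv, p.rads[z], true);
      if (tout < best) {
        best = tout; br = p.rads[z];
        bk = EV_WELL_OUT;
      }
    }
    if (!std::isfinite(best)) { ek = EV_NONE; return INF; }
    ek = bk; rad = br;
    return at + best;
  }

  // ---- heap keyed by (beadKey(i), i); ids >= N are chirality groups
  inline double beadKey(int i) const {
    if (i >= N) return chT[i - N];
    return evT[i] < kickT[i] ? evT[i] : kickT[i];
  }
  inline bool hless(int a, int b) const {
    double ka = beadKey(a), kb = beadKey(b);
    return ka < kb || (ka == kb && a < b);
  }
  void siftUp(int p) {
    while (p > 0) {
      int par = (p - 1) / 2;
      if (hless(heap[p], heap[par])) {
        std::swap(heap[p], heap[par]);
        hpos[heap[p]] = p; hpos[heap[par]] = par;
        p = par;
      } else break;
    }
  }
  void siftDown(int p) {
    int n = (int)heap.size();
    for (;;) {
      int l = 2 * p + 1, r = l + 1, s = p;
      if (l < n && hless(heap[l], heap[s])) s = l;
      if (r < n && hless(heap[r], heap[s])) s = r;
      if (s == p) break;
      std::swap(heap[p], heap[s]);
      hpos[heap[p]] = p; hpos[heap[s]] = s;
      p = s;
    }
  }
  void heapFix(int bead) { siftUp(hpos[bead]); siftDown(hpos[bead]); }

  // recompute the earliest pair event of bead i (over neighbours + bonds)
  void recomputeBead(int i, double at) {
    double best = INF; int bp = -1, bk = EV_NONE; double br = 0;
    const std::vector<Nb>& nb = nbr[i];
    for (size_t q = 0; q < nb.size(); ++q) {
      int ek; double rad;
      double tt = predictPair(i, nb[q].j, nb[q].p, at, ek, rad);
      if (tt < best) { best = tt; bp = nb[q].j; bk = ek; br = rad; }
    }
    evT[i] = best; evPartner[i] = bp; evKind[i] = bk; evRad[i] = br;
    heapFix(i);
  }

  static inline double det3(const double a[3], const double b[3],
                            const double c[3]) {
    return a[0] * (b[1] * c[2] - b[2] * c[1]) -
           a[1] * (b[0] * c[2] - b[2] * c[0]) +
           a[2] * (b[0] * c[1] - b[1] * c[0]);
  }

  void predictGroup(int g, double at) {
    double pn[3], pa[3], pc[3], ps[3];
    posAt(chNH[g], at, pn); posAt(chCA[g], at, pa);
    posAt(chCO[g], at, pc); posAt(chSC[g], at, ps);
    double A[3], B[3], C[3], X[3], Y[3], Z[3];
    for (int d = 0; d < 3; ++d) {
      A[d] = pn[d] - pa[d]; B[d] = pc[d] - pa[d]; C[d] = ps[d] - pa[d];
    }
    int bn = chNH[g], ba = chCA[g], bc = chCO[g], bs = chSC[g];
    X[0] = vx[bn] - vx[ba]; X[1] = vy[bn] - vy[ba]; X[2] = vz[bn] - vz[ba];
    Y[0] = vx[bc] - vx[ba]; Y[1] = vy[bc] - vy[ba]; Y[2] = vz[bc] - vz[ba];
    Z[0] = vx[bs] - vx[ba]; Z[1] = vy[bs] - vy[ba]; Z[2] = vz[bs] - vz[ba];
    double sgn = chMargin[g] >= 0 ? 1.0 : -1.0;  // wall on the init side
    double c0 = sgn * det3(A, B, C) - std::fabs(chMargin[g]);
    double c1 = sgn * (det3(X, B, C) + det3(A, Y, C) + det3(A, B, Z));
    double c2 = sgn * (det3(X, Y, C) + det3(X, B, Z) + det3(A, Y, Z));
    double c3 = sgn * det3(X, Y, Z);
    double tt = smallestPosRoot(c3, c2, c1, c0);
    chT[g] = std::isfinite(tt) ? at + tt : INF;
    heapFix(N + g);
  }

  bool executeChir(int g, double at) {
    int bd[4] = { chNH[g], chCA[g], chCO[g], chSC[g] };
    for (int q = 0; q < 4; ++q) advanceBead(bd[q], at);
    double A[3], B[3], C[3];
    A[0] = px[chNH[g]] - px[chCA[g]];
    A[1] = py[chNH[g]] - py[chCA[g]];
    A[2] = pz[chNH[g]] - pz[chCA[g]];
    B[0] = px[chCO[g]] - px[chCA[g]];
    B[1] = py[chCO[g]] - py[chCA[g]];
    B[2] = pz[chCO[g]] - pz[chCA[g]];
    C[0] = px[chSC[g]] - px[chCA[g]];
    C[1] = py[chSC[g]] - py[chCA[g]];
    C[2] = pz[chSC[g]] - pz[chCA[g]];
    double sgn = chMargin[g] >= 0 ? 1.0 : -1.0;
    // gradients of det wrt each bead position
    double gn[3], gc[3], gs[3], ga[3];
    gn[0] = B[1] * C[2] - B[2] * C[1];
    gn[1] = B[2] * C[0] - B[0] * C[2];
    gn[2] = B[0] * C[1] - B[1] * C[0];
    gc[0] = C[1] * A[2] - C[2] * A[1];
    gc[1] = C[2] * A[0] - C[0] * A[2];
    gc[2] = C[0] * A[1] - C[1] * A[0];
    gs[0] = A[1] * B[2] - A[2] * B[1];
    gs[1] = A[2] * B[0] - A[0] * B[2];
    gs[2] = A[0] * B[1] - A[1] * B[0];
    for (int d = 0; d < 3; ++d) {
      gn[d] *= sgn; gc[d] *= sgn; gs[d] *= sgn;
      ga[d] = -(gn[d] + gc[d] + gs[d]);
    }
    double* grads[4] = { gn, ga, gc, gs };
    double dgdt = 0, denom = 0;
    double vv[4][3];
    for (int q = 0; q < 4; ++q) {
      int b = bd[q];
      vv[q][0] = vx[b]; vv[q][1] = vy[b]; vv[q][2] = vz[b];
      for (int d = 0; d < 3; ++d) {
        dgdt += grads[q][d] * vv[q][d];
        denom += grads[q][d] * grads[q][d] / mass[b];
      }
    }
    if (dgdt < 0 && denom > 0) {
      double lam = dgdt / denom;
      vx[chNH[g]] -= 2 * lam * gn[0] / mass[chNH[g]];
      vy[chNH[g]] -= 2 * lam * gn[1] / mass[chNH[g]];
      vz[chNH[g]] -= 2 * lam * gn[2] / mass[chNH[g]];
      vx[chCA[g]] -= 2 * lam * ga[0] / mass[chCA[g]];
      vy[chCA[g]] -= 2 * lam * ga[1] / mass[chCA[g]];
      vz[chCA[g]] -= 2 * lam * ga[2] / mass[chCA[g]];
      vx[chCO[g]] -= 2 * lam * gc[0] / mass[chCO[g]];
      vy[chCO[g]] -= 2 * lam * gc[1] / mass[chCO[g]];
      vz[chCO[g]] -= 2 * lam * gc[2] / mass[chCO[g]];
      vx[chSC[g]] -= 2 * lam * gs[0] / mass[chSC[g]];
      vy[chSC[g]] -= 2 * lam * gs[1] / mass[chSC[g]];
      vz[chSC[g]] -= 2 * lam * gs[2] / mass[chSC[g]];
      counts["chirality"] += 1;
      for (int q = 0; q < 4; ++q) noteSpeed(bd[q], at);
      for (int q = 0; q < 4; ++q) recomputeBead(bd[q], at);
      // watchers of the four beads
      for (int q = 0; q < 4; ++q) {
        const std::vector<Nb>& nb = nbr[bd[q]];
        for (size_t s = 0; s < nb.size(); ++s) {
          int k = nb[s].j;
          bool isMember = false;
          for (int q2 = 0; q2 < 4; ++q2) if (k == bd[q2]) isMember = true;
          if (isMember) continue;
          for (int q2 = 0; q2 < 4; ++q2) {
            if (evPartner[k] == bd[q2]) { recomputeBead(k, at); break; }
          }
        }
      }
      predictGroup(g, at);
      return true;
    }
    counts["chirality_noop"] += 1;
    predictGroup(g, at);
    return false;
  }

  void invalidateGroups(int i, int j, double at) {
    if (G == 0) return;
    int gi = i >= 0 ? groupOf[i] : -1;
    int gj = j >= 0 ? groupOf[j] : -1;
    if (gi >= 0) predictGroup(gi, at);
    if (gj >= 0 && gj != gi) predictGroup(gj, at);
  }

  void recomputeAffected(int i, int j, double at) {
    recomputeBead(i, at);
    if (j >= 0) recomputeBead(j, at);
    // beads whose stored event points at i or j
    const std::vector<Nb>* lists[2] = { &nbr[i], j >= 0 ? &nbr[j] : 0 };
    for (int q = 0; q < 2; ++q) {
      if (!lists[q]) continue;
      const std::vector<Nb>& nb = *lists[q];
      for (size_t s = 0; s < nb.size(); ++s) {
        int k = nb[s].j;
        if (k == i || k == j) continue;
        if (evPartner[k] == i || evPartner[k] == j) recomputeBead(k, at);
      }
    }
  }

  void rebuild(double at) {
    for (int i = 0; i < N; ++i) advanceBead(i, at);
    double h2 = horizon * horizon;
    for (int i = 0; i < N; ++i) nbr[i].clear();
    for (int i = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j) {
        double dx = mimg(px[i] - px[j]);
        double dy = mimg(py[i] - py[j]);
        double dz = mimg(pz[i] - pz[j]);
        if (dx * dx + dy * dy + dz * dz <= h2) {
          PairPot p = classify(i, j);
          Nb a; a.j = j; a.p = p;
          Nb b; b.j = i; b.p = p;
          nbr[i].push_back(a); nbr[j].push_back(b);
        }
      }
    }
    // bonded pairs are tracked regardless of distance
    for (int i = 0; i < N; ++i) {
      for (size_t q = 0; q < bondsOf[i].size(); ++q) {
        int j = bondsOf[i][q];
        bool present = false;
        for (size_t s = 0; s < nbr[i].size(); ++s) {
          if (nbr[i][s].j == j) { present = true; break; }
        }
        if (!present) {
          PairPot p = classify(i, j);
          Nb a; a.j = j; a.p = p;
          Nb b; b.j = i; b.p = p;
          nbr[i].push_back(a); nbr[j].push_back(b);
        }
      }
    }
    vmax = 0;
    for (int i = 0; i < N; ++i) {
      double v2 = vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
      if (v2 > vmax) vmax = v2;
    }
    vmax = std::sqrt(vmax);
    dispBudget = 0; lastBudgetT = at;
    rebuildT = vmax > 0 ? at + 0.5 * skin / vmax : INF;
    for (int i = 0; i < N; ++i) recomputeBead(i, at);
    for (int g = 0; g < G; ++g) predictGroup(g, at);
  }

  void noteSpeed(int i, double at) {
    double v = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    if (v > vmax) {
      dispBudget += vmax * (at - lastBudgetT);
      lastBudgetT = at;
      vmax = v;
      rebuildT = vmax > 0 ?
        at + (0.5 * skin - dispBudget) / vmax : INF;
      if (rebuildT < at) rebuildT = at;
    }
  }

  // HB formation eligibility (geometry criteria) at time `at`
  bool hbEligible(int nh, int co, double at) {
    int ci = chain[nh], ri = res[nh], cj = chain[co], rj = res[co];
    if (ci == cj && std::abs(ri - rj) < minSeqSep) return false;
    int auxA[2] = { lookup(ci, ri, 1), lookup(ci, ri - 1, 2) };
    for (int q = 0; q < 2; ++q) {
      if (auxA[q] >= 0 && dist2At(auxA[q], co, at) < auxMin * auxMin)
        return false;
    }
    int auxB[2] = { lookup(cj, rj, 1), lookup(cj, rj + 1, 0) };
    for (int q = 0; q < 2; ++q) {
      if (auxB[q] >= 0 && dist2At(auxB[q], nh, at) < auxMin * auxMin)
        return false;
    }
    if (parallelOn) {
      int a1 = lookup(ci, ri - 1, 1), b1 = lookup(ci, ri + 1, 1);
      int a2 = lookup(cj, rj - 1, 1), b2 = lookup(cj, rj + 1, 1);
      if (a1 >= 0 && b1 >= 0 && a2 >= 0 && b2 >= 0) {
        double p1a[3], p1b[3], p2a[3], p2b[3];
        posAt(a1, at, p1a); posAt(b1, at, p1b);
        posAt(a2, at, p2a); posAt(b2, at, p2b);
        double u1[3] = { mimg(p1b[0] - p1a[0]), mimg(p1b[1] - p1a[1]),
                         mimg(p1b[2] - p1a[2]) };
        double u2[3] = { mimg(p2b[0] - p2a[0]), mimg(p2b[1] - p2a[1]),
                         mimg(p2b[2] - p2a[2]) };
        double n1 = std::sqrt(u1[0]*u1[0] + u1[1]*u1[1] + u1[2]*u1[2]);
        double n2 = std::sqrt(u2[0]*u2[0] + u2[1]*u2[1] + u2[2]*u2[2]);
        double dot = (u1[0]*u2[0] + u1[1]*u2[1] + u1[2]*u2[2]) / (n1 * n2);
        if (dot < cosThresh) return false;
      }
    }
    return true;
  }

  // execute the pair event stored on bead i; returns true if it counted as
  // a collision (velocity-changing event)
  bool executePair(int i, double at, double tolScale) {
    int j = evPartner[i];
    int ek = evKind[i];
    double R = evRad[i];
    advanceBead(i, at); advanceBead(j, at);
    double dr[3], dv[3];
    rel(i, j, at, dr, dv);
    double r2 = dr[0]*dr[0] + dr[1]*dr[1] + dr[2]*dr[2];
    double r = std::sqrt(r2);
    if (std::fabs(r - R) > 1e-6 * tolScale) {
      error = "pair not at the discontinuity at event time";
      return false;
    }
    double rh[3] = { dr[0] / r, dr[1] / r, dr[2] / r };
    double s = dv[0]*rh[0] + dv[1]*rh[1] + dv[2]*rh[2];
    double mi = mass[i], mj = mass[j];
    double mu = mi * mj / (mi + mj);

    double dU = 0.0;        // potential-energy step if the crossing happens
    bool crossing = false;  // step event (vs pure reflection)
    PairPot p = classify(i, j);
    int z = zoneOf(i, j, p);
    int znew = z;
    switch (ek) {
    case EV_CORE: case EV_WALL_LO: case EV_WALL_HI:
      break;  // pure reflection
    case EV_WELL_IN: case EV_HB_IN:
      crossing = true; znew = z - 1;
      dU = (znew == 0) ? INF : p.U[znew] - p.U[z];
      break;
    case EV_WELL_OUT: case EV_HB_OUT:
      crossing = true; znew = z + 1;
      dU = p.U[znew] - p.U[z];
      break;
    case EV_HB_FORM:
      if (hbPartner[i] < 0 && hbPartner[j] < 0 && s < 0 &&
          hbEligible(kind[i] == 0 ? i : j, kind[i] == 0 ? j : i, at)) {
        crossing = true; znew = 1; dU = -epsHB;
      } else {
        // transparent pass; no impulse
        counts["hb_reject"] += 1;
        recomputeAffected(i, j, at);
        return false;
      }
      break;
    default:
      error = "unknown event kind"; return false;
    }

    double snew;
    const char* label = 0;
    if (!crossing || !std::isfinite(dU)) {
      snew = -s;  // reflection (core, wall, or inward step onto the core)
      label = (ek == EV_WALL_LO || ek == EV_WALL_HI) ? "bond_wall" : "core";
      dU = 0; znew = z;
    } else {
      double s2 = s * s - 2.0 * dU / mu;
      if (s2 > 0) {
        // the crossing goes through: radial speed rescales, direction kept
        snew = (s < 0 ? -1.0 : 1.0) * std::sqrt(s2);
        label = (ek == EV_HB_FORM) ? "hb_form" :
                (ek == EV_HB_OUT) ? "hb_break" :
                (ek == EV_HB_IN || ek == EV_WELL_IN) ? "well_in" :
                "well_out";
      } else {
        snew = -s;  // bounce: not enough radial kinetic energy
        dU = 0; znew = z;
        label = "bounce";
      }
    }
    // impulse
    double J = mu * (snew - s);
    vx[i] += J / mi * rh[0]; vy[i] += J / mi * rh[1]; vz[i] += J / mi * rh[2];
    vx[j] -= J / mj * rh[0]; vy[j] -= J / mj * rh[1]; vz[j] -= J / mj * rh[2];
    ke -= dU; pe += dU;

    // registry / zone updates
    if (label && std::string(label) == "hb_form") {
      hbPartner[i] = j; hbPartner[j] = i;
      counts["hb_form"] += 1;
    } else if (label && std::string(label) == "hb_break") {
      hbPartner[i] = -1; hbPartner[j] = -1;
      counts["hb_break"] += 1;
    } else {
      counts[label] += 1;
    }
    if (p.type == 3) {
      if (znew == p.m) zone.erase(pkey(i, j));
      else zone[pkey(i, j)] = znew;
    }
    // snap the pair exactly onto the shell (guards constraint audits)
    double corr = (R - r);
    double wi = mj / (mi + mj), wj = mi / (mi + mj);
    px[i] += rh[0] * corr * wi; py[i] += rh[1] * corr * wi;
    pz[i] += rh[2] * corr * wi;
    px[j] -= rh[0] * corr * wj; py[j] -= rh[1] * corr * wj;
    pz[j] -= rh[2] * corr * wj;

    noteSpeed(i, at); noteSpeed(j, at);
    recomputeAffected(i, j, at);
    invalidateGroups(i, j, at);
    return true;
  }
};

// --------------------------------------------------------------- driver ---

// [[Rcpp::export]]
List cpp_dmd_run(NumericMatrix xyz, NumericMatrix vel,
                 IntegerVector chain, IntegerVector res, IntegerVector kind,
                 IntegerVector aa, NumericVector mass,
                 IntegerMatrix bonds, NumericVector bond_lo,
                 NumericVector bond_hi,
                 double box,
                 NumericVector bb_diam, NumericVector sc_diam,
                 NumericVector w_depth, NumericVector w_range,
                 NumericVector w_depth2, NumericVector w_range2,
                 double squeeze_factor,
                 double hb_core, double hb_range, double eps_hb,
                 double aux_min, int min_seq_sep, bool parallel_on,
                 double cos_thresh,
                 int sb_res_a, int sb_aa_a, int sb_res_b, int sb_aa_b,
                 double sb_factor,
                 IntegerVector hb_partner,
                 IntegerMatrix chirality, NumericVector chir_margin,
                 double n_collisions, double t_target, double kick_rate,
                 double seed,
                 double observe_every, double snapshot_every,
                 double contact_cut, int min_contacts,
                 double skin) {
  Engine E((uint64_t)seed);
  int N = xyz.nrow();
  E.N = N; E.L = box;
  E.px.resize(N); E.py.resize(N); E.pz.resize(N);
  E.vx.resize(N); E.vy.resize(N); E.vz.resize(N);
  E.pt.assign(N, 0.0);
  E.chain.resize(N); E.res.resize(N); E.kind.resize(N); E.aa.resize(N);
  E.mass.resize(N);
  for (int i = 0; i < N; ++i) {
    E.px[i] = xyz(i, 0); E.py[i] = xyz(i, 1); E.pz[i] = xyz(i, 2);
    E.vx[i] = vel(i, 0); E.vy[i] = vel(i, 1); E.vz[i] = vel(i, 2);
    E.chain[i] = chain[i]; E.res[i] = res[i]; E.kind[i] = kind[i];
    E.aa[i] = aa[i]; E.mass[i] = mass[i];
  }
  for (int k = 0; k < 3; ++k) E.bbDiam[k] = bb_diam[k];
  E.scDiam.assign(sc_diam.begin(), sc_diam.end());
  E.wDepth.assign(w_depth.begin(), w_depth.end());
  E.wRange.assign(w_range.begin(), w_range.end());
  E.hasWell2 = w_depth2.size() == 400;
  if (E.hasWell2) {
    E.wDepth2.assign(w_depth2.begin(), w_depth2.end());
    E.wRange2.assign(w_range2.begin(), w_range2.end());
  }
  E.squeezeFactor = squeeze_factor;
  E.hbCore = hb_core; E.hbRange = hb_range; E.epsHB = eps_hb;
  E.auxMin = aux_min; E.minSeqSep = min_seq_sep;
  E.parallelOn = parallel_on; E.cosThresh = cos_thresh;
  E.sbResA = sb_res_a; E.sbAaA = sb_aa_a;
  E.sbResB = sb_res_b; E.sbAaB = sb_aa_b; E.sbFactor = sb_factor;

  int M = bonds.nrow();
  E.bondLo.resize(M); E.bondHi.resize(M);
  E.bondsOf.assign(N, std::vector<int>());
  for (int m = 0; m < M; ++m) {
    int a = bonds(m, 0), b = bonds(m, 1);
    E.bondOf[E.pkey(a, b)] = m;
    E.bondLo[m] = bond_lo[m]; E.bondHi[m] = bond_hi[m];
    E.bondsOf[a].push_back(b); E.bondsOf[b].push_back(a);
  }

  // lookup table
  int minC = N ? E.chain[0] : 0, maxC = minC;
  int minR = N ? E.res[0] : 0, maxR = minR;
  for (int i = 0; i < N; ++i) {
    minC = std::min(minC, E.chain[i]); maxC = std::max(maxC, E.chain[i]);
    minR = std::min(minR, E.res[i]); maxR = std::max(maxR, E.res[i]);
  }
  E.minChain = minC; E.nChain = maxC - minC + 1;
  E.minRes = minR; E.nRes = maxR - minR + 1;
  E.lut.assign((size_t)E.nChain * E.nRes * 4, -1);
  for (int i = 0; i < N; ++i) {
    E.lut[(((size_t)(E.chain[i] - minC) * E.nRes) +
           (E.res[i] - minR)) * 4 + E.kind[i]] = i;
  }

  // horizon
  double maxRange = hb_range;
  for (int k = 0; k < 400; ++k) maxRange = std::max(maxRange, E.wRange[k]);
  if (E.hasWell2) {
    for (int k = 0; k < 400; ++k) maxRange = std::max(maxRange, E.wRange2[k]);
  }
  for (int m = 0; m < M; ++m) maxRange = std::max(maxRange, E.bondHi[m]);
  E.skin = skin;
  E.horizon = maxRange + skin;
  E.nbr.assign(N, std::vector<Engine::Nb>());

  E.hbPartner.assign(N, -1);
  for (int i = 0; i < N; ++i) E.hbPartner[i] = hb_partner[i];

  // chirality groups
  E.G = chirality.nrow();
  E.chNH.resize(E.G); E.chCA.resize(E.G); E.chCO.resize(E.G);
  E.chSC.resize(E.G); E.chMargin.resize(E.G);
  E.groupOf.assign(N, -1);
  E.chT.assign(E.G, INF);
  for (int g = 0; g < E.G; ++g) {
    E.chNH[g] = chirality(g, 0); E.chCA[g] = chirality(g, 1);
    E.chCO[g] = chirality(g, 2); E.chSC[g] = chirality(g, 3);
    E.chMargin[g] = chir_margin[g];
    E.groupOf[E.chNH[g]] = g; E.groupOf[E.chCA[g]] = g;
    E.groupOf[E.chCO[g]] = g; E.groupOf[E.chSC[g]] = g;
  }

  // initial PE and well occupancy (order-deterministic double loop)
  E.pe = 0;
  for (int i = 0; i < N; ++i) {
    if (E.kind[i] != 3) continue;
    for (int j = i + 1; j < N; ++j) {
      if (E.kind[j] != 3) continue;
      PairPot p = E.classify(i, j);
      if (p.type != 3) continue;
      double d2 = E.dist2At(i, j, 0.0);
      int z = p.m;
      for (int q = p.m - 1; q >= 1; --q) {
        if (d2 < p.rads[q] * p.rads[q]) z = q;
      }
      if (z < p.m) { E.zone[E.pkey(i, j)] = z; E.pe += p.U[z]; }
    }
  }
  for (int i = 0; i < N; ++i) {
    if (E.hbPartner[i] >= 0 && i < E.hbPartner[i]) E.pe += -eps_hb;
  }
  E.ke = 0;
  for (int i = 0; i < N; ++i) {
    E.ke += 0.5 * E.mass[i] * (E.vx[i]*E.vx[i] + E.vy[i]*E.vy[i] +
                               E.vz[i]*E.vz[i]);
  }

  // events
  E.evT.assign(N, INF); E.evPartner.assign(N, -1);
  E.evKind.assign(N, EV_NONE); E.evRad.assign(N, 0.0);
  E.kickT.assign(N, INF);
  E.Ttarget = t_target; E.kickRate = kick_rate;
  if (kick_rate > 0) {
    for (int i = 0; i < N; ++i) E.kickT[i] = E.rng.expo(kick_rate);
  }
  E.heap.resize(N + E.G); E.hpos.resize(N + E.G);
  for (int i = 0; i < N + E.G; ++i) { E.heap[i] = i; E.hpos[i] = i; }
  E.t = 0; E.collisions = 0;
  E.rebuild(0.0);
  for (int g = 0; g < E.G; ++g) E.predictGroup(g, 0.0);

  // observables
  std::vector<double> obColl, obTime, obPe, obKe, obTinst, obTavg,
      obPeAvg, obNhb, obNhbInter, obClust;
  double nextObs = observe_every > 0 ? observe_every : INF;
  double nextSnap = snapshot_every > 0 ? snapshot_every : INF;
  List snaps;
  std::vector<double> snapT, snapColl, snapPe;

  double lastKeT = 0.0;
  double keAccum = 0.0, peAccum = 0.0;
  double lastRecT = 0.0;

  auto bumpKe = [&](double at) {
    keAccum += E.ke * (at - lastKeT);
    peAccum += E.pe * (at - lastKeT);
    lastKeT = at;
  };

  auto clusterStat = [&](double at, double& nhb, double& nhbInter,
                         double& cmax) {
    nhb = 0; nhbInter = 0;
    for (int i = 0; i < N; ++i) {
      if (E.hbPartner[i] >= 0) {
        nhb += 0.5;
        if (E.chain[i] != E.chain[E.hbPartner[i]]) nhbInter += 0.5;
      }
    }
    // chain contact graph via union-find
    std::unordered_map<long long, int> contacts;
    for (int i = 0; i < N; ++i) {
      const std::vector<Engine::Nb>& nb = E.nbr[i];
      for (size_t q = 0; q < nb.size(); ++q) {
        int j = nb[q].j;
        if (j <= i) continue;
        if (E.chain[i] == E.chain[j]) continue;
        if (E.dist2At(i, j, at) <= contact_cut * contact_cut) {
          int ca = std::min(E.chain[i], E.chain[j]);
          int cb = std::max(E.chain[i], E.chain[j]);
          contacts[(long long)ca * 100000 + cb] += 1;
        }
      }
    }
    std::unordered_map<int, int> parent;
    std::function<int(int)> find = [&](int x) {
      if (parent.find(x) == parent.end()) parent[x] = x;
      while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
      return x;
    };
    for (int i = 0; i < N; ++i) find(E.chain[i]);
    for (std::unordered_map<long long, int>::iterator it = contacts.begin();
         it != contacts.end(); ++it) {
      if (it->second >= min_contacts) {
        int a = find((int)(it->first / 100000));
        int b = find((int)(it->first % 100000));
        if (a != b) parent[a] = b;
      }
    }
    std::unordered_map<int, int> size;
    cmax = 0;
    for (std::unordered_map<int, int>::iterator it = parent.begin();
         it != parent.end(); ++it) {
      int r = find(it->first);
      size[r] += 1;
      if (size[r] > cmax) cmax = size[r];
    }
  };

  long long guardSame = 0; double guardT = -1;
  long long maxEvents = (long long)(n_collisions * 1000 + 1e7);
  long long eventsDone = 0;

  while (E.collisions < n_collisions && E.error.empty()) {
    if (++eventsDone > maxEvents) {
      E.error = "event cascade exceeded the safety budget";
      break;
    }
    int b = E.heap[0];
    double tEv = E.beadKey(b);
    double tAct = std::min(tEv, E.rebuildT);
    if (!std::isfinite(tAct)) { E.error = "no future events"; break; }
    // zero-time loop guard
    if (tAct <= guardT + 1e-15) {
      if (++guardSame > 2000000) {
        E.error = "zero-time event loop detected"; break;
      }
    } else { guardSame = 0; guardT = tAct; }

    if (E.rebuildT <= tEv) {
      E.dispBudget += E.vmax * (E.rebuildT - E.lastBudgetT);
      E.rebuild(E.rebuildT);
      E.t = E.rebuildT > E.t ? E.rebuildT : E.t;
      continue;
    }
    E.t = tEv;
    if (b >= N) {
      // chirality wall
      bool reflected = E.executeChir(b - N, tEv);
      if (reflected) {
        E.collisions += 1;
        if (E.collisions >= nextObs || E.collisions >= nextSnap) {
          // fall through to the shared recording below via flags
        }
      }
      if (reflected && E.collisions >= nextObs) {
        double nhb, nhbInter, cmax;
        clusterStat(tEv, nhb, nhbInter, cmax);
        obColl.push_back(E.collisions);
        obTime.push_back(tEv);
        obPe.push_back(E.pe);
        obKe.push_back(E.ke);
        obTinst.push_back(2.0 * E.ke / (3.0 * N));
        double Tav = (tEv - lastRecT) > 0 ?
          2.0 * keAccum / (3.0 * N * (tEv - lastRecT)) :
          2.0 * E.ke / (3.0 * N);
        obTavg.push_back(Tav);
        obPeAvg.push_back((tEv - lastRecT) > 0 ?
          peAccum / (tEv - lastRecT) : E.pe);
        keAccum = 0.0; peAccum = 0.0; lastKeT = tEv; lastRecT = tEv;
        obNhb.push_back(nhb);
        obNhbInter.push_back(nhbInter);
        obClust.push_back(cmax);
        nextObs += observe_every;
      }
      continue;
    }
    if (E.kickT[b] <= E.evT[b]) {
      // thermostat ghost kick
      bumpKe(tEv);
      E.advanceBead(b, tEv);
      double m = E.mass[b];
      double sd = std::sqrt(E.Ttarget / m);
      double v2old = E.vx[b]*E.vx[b] + E.vy[b]*E.vy[b] + E.vz[b]*E.vz[b];
      E.vx[b] = sd * E.rng.normal();
      E.vy[b] = sd * E.rng.normal();
      E.vz[b] = sd * E.rng.normal();
      double v2new = E.vx[b]*E.vx[b] + E.vy[b]*E.vy[b] + E.vz[b]*E.vz[b];
      E.ke += 0.5 * m * (v2new - v2old);
      E.counts["ghost"] += 1;
      E.kickT[b] = tEv + E.rng.expo(E.kickRate);
      E.noteSpeed(b, tEv);
      E.recomputeAffected(b, -1, tEv);
      E.invalidateGroups(b, -1, tEv);
    } else {
      bumpKe(tEv);
      bool counted = E.executePair(b, tEv, 1.0);
      if (!E.error.empty()) break;
      if (counted) {
        E.collisions += 1;
        if (E.collisions >= nextObs) {
          double nhb, nhbInter, cmax;
          clusterStat(tEv, nhb, nhbInter, cmax);
          obColl.push_back(E.collisions);
          obTime.push_back(tEv);
          obPe.push_back(E.pe);
          obKe.push_back(E.ke);
          obTinst.push_back(2.0 * E.ke / (3.0 * N));
          // keAccum holds the time integral of KE since the last record
          double Tav = (tEv - lastRecT) > 0 ?
            2.0 * keAccum / (3.0 * N * (tEv - lastRecT)) :
            2.0 * E.ke / (3.0 * N);
          obTavg.push_back(Tav);
          obPeAvg.push_back((tEv - lastRecT) > 0 ?
            peAccum / (tEv - lastRecT) : E.pe);
          keAccum = 0.0; peAccum = 0.0; lastKeT = tEv; lastRecT = tEv;
          obNhb.push_back(nhb);
          obNhbInter.push_back(nhbInter);
          obClust.push_back(cmax);
          nextObs += observe_every;
        }
        if (E.collisions >= nextSnap) {
          NumericMatrix sp(N, 3);
          for (int i = 0; i < N; ++i) {
            double pcur[3]; E.posAt(i, tEv, pcur);
            sp(i, 0) = pcur[0]; sp(i, 1) = pcur[1]; sp(i, 2) = pcur[2];
          }
          snaps.push_back(sp);
          snapT.push_back(tEv); snapColl.push_back(E.collisions);
          snapPe.push_back(E.pe);
          nextSnap += snapshot_every;
        }
      }
    }
  }

  // final sync
  double tFin = E.t;
  for (int i = 0; i < N; ++i) E.advanceBead(i, tFin);

  NumericMatrix outPos(N, 3), outVel(N, 3);
  for (int i = 0; i < N; ++i) {
    outPos(i, 0) = E.px[i]; outPos(i, 1) = E.py[i]; outPos(i, 2) = E.pz[i];
    outVel(i, 0) = E.vx[i]; outVel(i, 1) = E.vy[i]; outVel(i, 2) = E.vz[i];
  }
  IntegerVector outHb(N);
  for (int i = 0; i < N; ++i) outHb[i] = E.hbPartner[i];
  CharacterVector cn; NumericVector cv;
  for (std::unordered_map<std::string, double>::iterator it =
         E.counts.begin(); it != E.counts.end(); ++it) {
    cn.push_back(it->first); cv.push_back(it->second);
  }
  cv.attr("names") = cn;
  DataFrame obs = DataFrame::create(
    _["collisions"] = obColl, _["time"] = obTime, _["pe"] = obPe,
    _["ke"] = obKe, _["t_inst"] = obTinst, _["t_avg"] = obTavg,
    _["pe_avg"] = obPeAvg, _["n_hb"] = obNhb,
    _["n_hb_inter"] = obNhbInter, _["largest_cluster"] = obClust);
  return List::create(
    _["pos"] = outPos, _["vel"] = outVel, _["time"] = tFin,
    _["collisions"] = E.collisions, _["hb_partner"] = outHb,
    _["pe"] = E.pe, _["ke"] = E.ke, _["counts"] = cv,
    _["observables"] = obs, _["snapshots"] = snaps,
    _["snapshot_time"] = wrap(snapT),
    _["snapshot_collisions"] = wrap(snapColl),
    _["snapshot_pe"] = wrap(snapPe),
    _["error"] = E.error);
}

// earliest positive crossing time of |dr + dv t| = radius (minimum image
// already applied by the caller); returns Inf when unreachable
// [[Rcpp::export]]
double cpp_pair_time(NumericVector dr, NumericVector dv, double radius,
                     bool from_inside) {
  double a[3] = { dr[0], dr[1], dr[2] };
  double b[3] = { dv[0], dv[1], dv[2] };
  return Engine::crossTime(a, b, radius, from_inside);
}
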