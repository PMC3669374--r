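#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// Metropolis kernel for the bond-fluctuation chain on an L^3 cubic lattice.
// A residue is anchored at one lattice site; excluded volume is either the
// classical 8-site cube (default) or the anchor site alone ("site" mode);
// consecutive residues are joined by bonds drawn from an allowed vector set;
// non-adjacent residues interact through a truncated generalized LJ potential
//   U(r) = |eps|*(sigma/r)^12 + eps*(sigma/r)^6   for r < r_c, else 0.
// The running total energy is maintained incrementally from local shell sums.

namespace {

struct Engine {
  int N, L;
  bool periodic;
  bool cube_ev;                      // classical 8-site cube excluded volume
  std::vector<int> occ_cube;         // cube-site -> residue index (cube mode)
  std::vector<int> x, y, z;          // wrapped coordinates in [0, L)
  std::vector<double> ux, uy, uz;    // unwrapped coordinates
  std::vector<int> occ;              // site -> residue index, or -1
  std::vector<int> seq;              // residue type codes 0..19
  const double *eps;                 // 20x20 column-major
  double sigma, rc2;
  // bond lookup table over component deltas in [-bhw, bhw]
  int bhw, bdim;
  std::vector<unsigned char> bond_ok;
  // interaction shell offsets (d2 < rc^2; d2 == rc^2 sites contribute 0)
  std::vector<int> sox, soy, soz;
  std::vector<double> inv6, inv12;   // indexed by d2 of shell offset

  int lmask = 0;                     // L-1 when L is a power of two, else 0
  inline int site(int xi, int yi, int zi) const { return xi + L * (yi + L * zi); }
  inline int wrap(int a) const {
    if (lmask) return a & lmask;
    int r = a % L; return r < 0 ? r + L : r;
  }
  inline int mimg(int d) const {
    if (!periodic) return d;
    if (2 * d >= L) d -= L; else if (2 * d < -L) d += L;
    return d;
  }
  inline bool bondValid(int dx, int dy, int dz) const {
    dx = mimg(dx); dy = mimg(dy); dz = mimg(dz);
    if (std::abs(dx) > bhw || std::abs(dy) > bhw || std::abs(dz) > bhw) return false;
    return bond_ok[(dx + bhw) + bdim * ((dy + bhw) + bdim * (dz + bhw))] != 0;
  }
  inline double pairU(double e, int d2) const {
    return std::fabs(e) * inv12[d2] + e * inv6[d2];
  }

  // interaction energy of residue i as if anchored at (xi,yi,zi); covalent
  // neighbours and i itself are excluded from the contact sum
  double localEnergy(int i, int xi, int yi, int zi) const {
    double E = 0.0;
    const int si = seq[i];
    const size_t ns = sox.size();
    for (size_t k = 0; k < ns; ++k) {
      int nx = xi + sox[k], ny = yi + soy[k], nz = zi + soz[k];
      if (periodic) { nx = wrap(nx); ny = wrap(ny); nz = wrap(nz); }
      else if (nx < 0 || nx >= L || ny < 0 || ny >= L || nz < 0 || nz >= L) continue;
      int j = occ[site(nx, ny, nz)];
      if (j < 0 || j == i || j == i - 1 || j == i + 1) continue;
      int d2 = sox[k] * sox[k] + soy[k] * soy[k] + soz[k] * soz[k];
      E += pairU(eps[si + 20 * seq[j]], d2);
    }
    return E;
  }

  // mark/clear the 8 cube sites of residue i anchored at (xi,yi,zi)
  void cubeSet(int i, int xi, int yi, int zi, int val) {
    for (int ox = 0; ox <= 1; ++ox)
      for (int oy = 0; oy <= 1; ++oy)
        for (int oz = 0; oz <= 1; ++oz) {
          int cx = xi + ox, cy = yi + oy, cz = zi + oz;
          if (periodic) { cx = wrap(cx); cy = wrap(cy); cz = wrap(cz); }
          occ_cube[site(cx, cy, cz)] = val;
        }
  }
  // true when the cube anchored at (xi,yi,zi) collides with any residue != i
  bool cubeBlocked(int i, int xi, int yi, int zi) const {
    for (int ox = 0; ox <= 1; ++ox)
      for (int oy = 0; oy <= 1; ++oy)
        for (int oz = 0; oz <= 1; ++oz) {
          int cx = xi + ox, cy = yi + oy, cz = zi + oz;
          if (periodic) { cx = wrap(cx); cy = wrap(cy); cz = wrap(cz); }
          int o = occ_cube[site(cx, cy, cz)];
          if (o >= 0 && o != i) return true;
        }
    return false;
  }

  double totalEnergy() const {
    double E = 0.0;
    for (int i = 0; i < N; ++i) E += localEnergy(i, x[i], y[i], z[i]);
    return 0.5 * E;
  }
};

void buildShell(Engine &eng, double rc) {
  eng.rc2 = rc * rc;
  int m = (int)std::floor(rc + 1e-12);
  int maxd2 = (int)std::floor(eng.rc2 + 1e-9);
  eng.inv6.assign(maxd2 + 1, 0.0);
  eng.inv12.assign(maxd2 + 1, 0.0);
  double s2 = eng.sigma * eng.sigma;
  for (int d2 = 1; d2 <= maxd2; ++d2) {
    if ((double)d2 >= eng.rc2 - 1e-12) continue;  // at/beyond cutoff: zero
    double r6 = std::pow(s2 / (double)d2, 3.0);
    eng.inv6[d2] = r6;
    eng.inv12[d2] = r6 * r6;
  }
  // scan only offsets that can carry energy (strictly inside the cutoff)
  for (int dx = -m; dx <= m; ++dx)
    for (int dy = -m; dy <= m; ++dy)
      for (int dz = -m; dz <= m; ++dz) {
        int d2 = dx * dx + dy * dy + dz * dz;
        if (d2 == 0 || (double)d2 >= eng.rc2 - 1e-12) continue;
        eng.sox.push_back(dx); eng.soy.push_back(dy); eng.soz.push_back(dz);
      }
}

void buildBondTable(Engine &eng, const IntegerMatrix &bonds) {
  int mx = 0;
  for (int k = 0; k < bonds.nrow(); ++k)
    for (int c = 0; c < 3; ++c) mx = std::max(mx, std::abs(bonds(k, c)));
  eng.bhw = mx + 1;  // single-site moves can push a component one beyond
  eng.bdim = 2 * eng.bhw + 1;
  eng.bond_ok.assign((size_t)eng.bdim * eng.bdim * eng.bdim, 0);
  for (int k = 0; k < bonds.nrow(); ++k) {
    int dx = bonds(k, 0), dy = bonds(k, 1), dz = bonds(k, 2);
    eng.bond_ok[(dx + eng.bhw) + eng.bdim * ((dy + eng.bhw) + eng.bdim * (dz + eng.bhw))] = 1;
  }
}

const int AX6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};

} // namespace

// [[Rcpp::export]]
List cpp_run_mc(IntegerMatrix coords, IntegerVector seq_ids, NumericMatrix eps,
                IntegerMatrix bonds, double temperature, int n_mcs,
                int record_every, int box, bool periodic,
                double rc, double sigma, int neighborhood, bool cube_ev,
                bool record_frames, bool record_site_energy) {
  Engine eng;
  eng.N = coords.nrow(); eng.L = box; eng.periodic = periodic;
  eng.lmask = (box & (box - 1)) == 0 ? box - 1 : 0;
  eng.cube_ev = cube_ev;
  eng.sigma = sigma; eng.eps = eps.begin();
  if (eps.nrow() != 20 || eps.ncol() != 20) stop("eps must be 20x20");
  if (cube_ev) eng.occ_cube.assign((size_t)box * box * box, -1);
  eng.x.resize(eng.N); eng.y.resize(eng.N); eng.z.resize(eng.N);
  eng.ux.resize(eng.N); eng.uy.resize(eng.N); eng.uz.resize(eng.N);
  eng.seq.assign(seq_ids.begin(), seq_ids.end());
  eng.occ.assign((size_t)box * box * box, -1);
  buildShell(eng, rc);
  buildBondTable(eng, bonds);

  const int hi = (!periodic && cube_ev) ? box - 1 : box;   // cube must fit
  for (int i = 0; i < eng.N; ++i) {
    int xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    if (xi < 0 || xi >= hi || yi < 0 || yi >= hi || zi < 0 || zi >= hi)
      stop("coordinate out of box at residue %d", i + 1);
    int s = eng.site(xi, yi, zi);
    if (eng.occ[s] >= 0) stop("duplicate lattice site at residue %d", i + 1);
    if (cube_ev) {
      if (eng.cubeBlocked(i, xi, yi, zi))
        stop("cube overlap at residue %d", i + 1);
      eng.cubeSet(i, xi, yi, zi, i);
    }
    eng.occ[s] = i;
    eng.x[i] = xi; eng.y[i] = yi; eng.z[i] = zi;
  }
  // unwrap along the backbone so bond vectors, R_g and COM are physical even
  // when the grown chain crossed a periodic boundary
  eng.ux[0] = eng.x[0]; eng.uy[0] = eng.y[0]; eng.uz[0] = eng.z[0];
  for (int i = 1; i < eng.N; ++i) {
    eng.ux[i] = eng.ux[i-1] + eng.mimg(eng.x[i] - eng.x[i-1]);
    eng.uy[i] = eng.uy[i-1] + eng.mimg(eng.y[i] - eng.y[i-1]);
    eng.uz[i] = eng.uz[i-1] + eng.mimg(eng.z[i] - eng.z[i-1]);
  }
  for (int i = 0; i + 1 < eng.N; ++i)
    if (!eng.bondValid(eng.x[i+1] - eng.x[i], eng.y[i+1] - eng.y[i], eng.z[i+1] - eng.z[i]))
      stop("bond %d-%d not in allowed set", i + 1, i + 2);

  const int nmoves = (neighborhood == 26) ? 26 : 6;
  int mv26[26][3]; {
    int k = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz)
          if (dx || dy || dz) { mv26[k][0]=dx; mv26[k][1]=dy; mv26[k][2]=dz; ++k; }
  }

  double E = eng.totalEnergy();
  const int nrec = n_mcs / record_every;
  NumericVector rec_t(nrec), rec_E(nrec), rec_rg(nrec), rec_acc(nrec);
  NumericMatrix rec_com(nrec, 3);
  NumericMatrix frames;      // nrec x 3N unwrapped, optional
  NumericMatrix site_e;      // nrec x N, optional
  if (record_frames) frames = NumericMatrix(nrec, 3 * eng.N);
  if (record_site_energy) site_e = NumericMatrix(nrec, eng.N);

  long acc_win = 0, att_win = 0;
  int irec = 0;
  RNGScope rngScope;

  for (int sweep = 1; sweep <= n_mcs; ++sweep) {
    for (int a = 0; a < eng.N; ++a) {
      ++att_win;
      int i = (int)(unif_rand() * eng.N);
      if (i == eng.N) i = eng.N - 1;
      int m = (int)(unif_rand() * nmoves);
      if (m == nmoves) m = nmoves - 1;
      int dx, dy, dz;
      if (nmoves == 6) { dx = AX6[m][0]; dy = AX6[m][1]; dz = AX6[m][2]; }
      else { dx = mv26[m][0]; dy = mv26[m][1]; dz = mv26[m][2]; }
      int nx = eng.x[i] + dx, ny = eng.y[i] + dy, nz = eng.z[i] + dz;
      if (eng.periodic) { nx = eng.wrap(nx); ny = eng.wrap(ny); nz = eng.wrap(nz); }
      else if (nx < 0 || nx >= hi || ny < 0 || ny >= hi || nz < 0 || nz >= hi)
        continue;
      if (eng.occ[eng.site(nx, ny, nz)] >= 0) continue;   // excluded volume
      if (cube_ev && eng.cubeBlocked(i, nx, ny, nz)) continue;
      if (i > 0 && !eng.bondValid(nx - eng.x[i-1], ny - eng.y[i-1], nz - eng.z[i-1]))
        continue;
      if (i + 1 < eng.N && !eng.bondValid(eng.x[i+1] - nx, eng.y[i+1] - ny, eng.z[i+1] - nz))
        continue;
      double dE = eng.localEnergy(i, nx, ny, nz) - eng.localEnergy(i, eng.x[i], eng.y[i], eng.z[i]);
      if (dE > 0.0 && unif_rand() >= std::exp(-dE / temperature)) continue;
      if (cube_ev) {
        eng.cubeSet(i, eng.x[i], eng.y[i], eng.z[i], -1);
        eng.cubeSet(i, nx, ny, nz, i);
      }
      eng.occ[eng.site(eng.x[i], eng.y[i], eng.z[i])] = -1;
      eng.occ[eng.site(nx, ny, nz)] = i;
      eng.x[i] = nx; eng.y[i] = ny; eng.z[i] = nz;
      eng.ux[i] += dx; eng.uy[i] += dy; eng.uz[i] += dz;
      E += dE;
      ++acc_win;
    }
    if (sweep % record_every == 0 && irec < nrec) {
      double cx = 0, cy = 0, cz = 0;
      for (int i = 0; i < eng.N; ++i) { cx += eng.ux[i]; cy += eng.uy[i]; cz += eng.uz[i]; }
      cx /= eng.N; cy /= eng.N; cz /= eng.N;
      double rg2 = 0;
      for (int i = 0; i < eng.N; ++i) {
        double a = eng.ux[i] - cx, b = eng.uy[i] - cy, c = eng.uz[i] - cz;
        rg2 += a * a + b * b + c * c;
      }
      rec_t[irec] = sweep; rec_E[irec] = E;
      rec_rg[irec] = std::sqrt(rg2 / eng.N);
      rec_com(irec, 0) = cx; rec_com(irec, 1) = cy; rec_com(irec, 2) = cz;
      rec_acc[irec] = att_win > 0 ? (double)acc_win / (double)att_win : 0.0;
      if (record_frames)
        for (int i = 0; i < eng.N; ++i) {
          frames(irec, i) = eng.ux[i];
          frames(irec, eng.N + i) = eng.uy[i];
          frames(irec, 2 * eng.N + i) = eng.uz[i];
        }
      if (record_site_energy)
        for (int i = 0; i < eng.N; ++i)
          site_e(irec, i) = eng.localEnergy(i, eng.x[i], eng.y[i], eng.z[i]);
      acc_win = 0; att_win = 0;
      ++irec;
    }
  }

  IntegerMatrix fin(eng.N, 3);
  NumericMatrix finu(eng.N, 3);
  for (int i = 0; i < eng.N; ++i) {
    fin(i, 0) = eng.x[i]; fin(i, 1) = eng.y[i]; fin(i, 2) = eng.z[i];
    finu(i, 0) = eng.ux[i]; finu(i, 1) = eng.uy[i]; finu(i, 2) = eng.uz[i];
  }

  List out = List::create(
    _["times"] = rec_t, _["energies"] = rec_E, _["rg"] = rec_rg,
    _["com"] = rec_com, _["acc_rate"] = rec_acc,
    _["final_coords"] = fin, _["final_unwrapped"] = finu,
    _["final_energy"] = E, _["recomputed_energy"] = eng.totalEnergy());
  if (record_frames) out["frames"] = frames;
  if (record_site_energy) out["site_energies"] = site_e;
  return out;
}

// Shell-sum total energy; independent of the R-side O(N^2) double loop.
// [[Rcpp::export]]
double cpp_total_energy(IntegerMatrix coords, IntegerVector seq_ids,
                        NumericMatrix eps, int box, bool periodic,
                        double rc, double sigma) {
  Engine eng;
  eng.N = coords.nrow(); eng.L = box; eng.periodic = periodic;
  eng.lmask = (box & (box - 1)) == 0 ? box - 1 : 0;
  eng.sigma = sigma; eng.eps = eps.begin();
  eng.x.resize(eng.N); eng.y.resize(eng.N); eng.z.resize(eng.N);
  eng.seq.assign(seq_ids.begin(), seq_ids.end());
  eng.occ.assign((size_t)box * box * box, -1);
  buildShell(eng, rc);
  for (int i = 0; i < eng.N; ++i) {
    eng.x[i] = coords(i, 0); eng.y[i] = coords(i, 1); eng.z[i] = coords(i, 2);
    eng.occ[eng.site(eng.x[i], eng.y[i], eng.z[i])] = i;
  }
  return eng.totalEnergy();
}
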