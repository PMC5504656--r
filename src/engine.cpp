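// Daily asynchronous update loop of the lattice tumor model.
//
// All stochastic draws use R's RNG (unif_rand), so set.seed() in R makes
// every entry point reproducible. Cells are passed as an integer matrix
// with columns {i, j, k, lineage, ccr5, divisions, state}; voxel
// coordinates are 0-based. Occupancy is rebuilt per call from the cell
// table; out-of-bounds voxels count as occupied (static walls).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

constexpr int LIN_STEM = 0, LIN_PROG = 1;
constexpr int CCR5_LOW = 0, CCR5_HIGH = 1;
constexpr int ST_PROLIF = 0, ST_QUIESCENT = 1, ST_SENESCENT = 2;

struct Cell {
  int i, j, k, lineage, ccr5, div, state;
};

struct Par {
  double pProlifStem, pProlifProg, pSymmetric, pConv, pConvHyp;
  int divisionLimit;
  int stepsLow, stepsHigh, maxSteps;
  double hypMig, hypProlif;
  bool hypoxiaOn, maraviroc, senescentMigrate;
  int nx, ny, nz;
};

Par parsePar(const List& p) {
  Par q;
  q.pProlifStem = as<double>(p["pProlifStem"]);
  q.pProlifProg = as<double>(p["pProlifProg"]);
  q.pSymmetric = as<double>(p["pSymmetric"]);
  q.pConv = as<double>(p["pCcr5Convert"]);
  q.pConvHyp = as<double>(p["pCcr5ConvertHypoxic"]);
  q.divisionLimit = as<int>(p["divisionLimit"]);
  q.stepsLow = as<int>(p["stepsCcr5Low"]);
  q.stepsHigh = as<int>(p["stepsCcr5High"]);
  q.maxSteps = as<int>(p["maxStepsPerDay"]);
  q.hypMig = as<double>(p["hypoxiaMigrationFactor"]);
  q.hypProlif = as<double>(p["hypoxiaProlifFactor"]);
  q.hypoxiaOn = as<bool>(p["hypoxiaOn"]);
  q.maraviroc = as<bool>(p["maravirocOn"]);
  q.senescentMigrate = as<bool>(p["senescentMigrate"]);
  IntegerVector d = p["dims"];
  q.nx = d[0]; q.ny = d[1]; q.nz = d[2];
  return q;
}

inline int lin(const Par& p, int i, int j, int k) {
  return i + p.nx * (j + p.ny * k);
}

// uniform integer in [0, n)
inline int runifInt(int n) {
  int v = static_cast<int>(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

std::vector<Cell> readCells(const IntegerMatrix& m) {
  std::vector<Cell> cells(m.nrow());
  for (int r = 0; r < m.nrow(); ++r)
    cells[r] = {m(r, 0), m(r, 1), m(r, 2), m(r, 3), m(r, 4), m(r, 5),
                m(r, 6)};
  return cells;
}

IntegerMatrix writeCells(const std::vector<Cell>& cells) {
  IntegerMatrix m(static_cast<int>(cells.size()), 7);
  for (size_t r = 0; r < cells.size(); ++r) {
    m(r, 0) = cells[r].i; m(r, 1) = cells[r].j; m(r, 2) = cells[r].k;
    m(r, 3) = cells[r].lineage; m(r, 4) = cells[r].ccr5;
    m(r, 5) = cells[r].div; m(r, 6) = cells[r].state;
  }
  colnames(m) = CharacterVector::create("i", "j", "k", "lineage", "ccr5",
                                        "divisions", "state");
  return m;
}

std::vector<int> buildOcc(const Par& p, const std::vector<Cell>& cells) {
  std::vector<int> occ(static_cast<size_t>(p.nx) * p.ny * p.nz, 0);
  for (size_t r = 0; r < cells.size(); ++r) {
    int at = lin(p, cells[r].i, cells[r].j, cells[r].k);
    if (occ[at] != 0) stop("two cells occupy one voxel");
    occ[at] = static_cast<int>(r) + 1;
  }
  return occ;
}

// Collect free Moore-neighbor voxels of (i,j,k); walls count occupied.
// excl (if >= 0) is a linear voxel index excluded from the result.
int freeNeighbors(const Par& p, const std::vector<int>& occ, int i, int j,
                  int k, int excl, int out[26][3]) {
  int n = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int ii = i + di, jj = j + dj, kk = k + dk;
        if (ii < 0 || jj < 0 || kk < 0 || ii >= p.nx || jj >= p.ny ||
            kk >= p.nz)
          continue;
        int at = lin(p, ii, jj, kk);
        if (occ[at] != 0 || at == excl) continue;
        out[n][0] = ii; out[n][1] = jj; out[n][2] = kk;
        ++n;
      }
  return n;
}

bool allNeighborsOccupied(const Par& p, const std::vector<int>& occ, int i,
                          int j, int k) {
  int nb[26][3];
  return freeNeighbors(p, occ, i, j, k, -1, nb) == 0;
}

// Random walk of nSteps voxel steps. For multi-step walks the voxel the
// cell occupied immediately before its current one is excluded as a
// destination; steps with no eligible free neighbor are skipped. If
// path is non-null, successive positions (including the start) are
// appended.
void walk(const Par& p, std::vector<int>& occ, Cell& c, int cellIdx1,
          int nSteps, std::vector<int>* path) {
  int prev = -1;
  bool noBacktrack = nSteps > 1;
  if (path) {
    path->push_back(c.i); path->push_back(c.j); path->push_back(c.k);
  }
  for (int s = 0; s < nSteps; ++s) {
    int nb[26][3];
    int nf = freeNeighbors(p, occ, c.i, c.j, c.k, noBacktrack ? prev : -1,
                           nb);
    if (nf == 0) continue;
    int pick = runifInt(nf);
    int from = lin(p, c.i, c.j, c.k);
    prev = from;
    c.i = nb[pick][0]; c.j = nb[pick][1]; c.k = nb[pick][2];
    occ[from] = 0;
    occ[lin(p, c.i, c.j, c.k)] = cellIdx1;
    if (path) {
      path->push_back(c.i); path->push_back(c.j); path->push_back(c.k);
    }
  }
}

int migrationSteps(const Par& p, int ccr5, bool hypoxic) {
  int base = (ccr5 == CCR5_HIGH && !p.maraviroc) ? p.stepsHigh : p.stepsLow;
  double s = base;
  if (hypoxic) s *= p.hypMig;
  int steps = static_cast<int>(s + 0.5);
  if (base > 0 && steps < 1) steps = 1;
  if (steps > p.maxSteps) steps = p.maxSteps;
  return steps;
}

// One division attempt (rule order per the daily flowchart): a
// progenitor at its division limit senesces instead of dividing; the
// division probability (halved in hypoxia) is drawn; the daughter is
// placed on a uniformly chosen free Moore neighbor; stem divisions are
// symmetric with probability pSymmetric; a symmetric division's
// daughter converts to CCR5-high with the (hypoxia-dependent)
// conversion probability, otherwise daughters inherit the parent's
// CCR5 class. Returns true if a daughter was placed.
bool attemptDivision(const Par& p, std::vector<int>& occ,
                     std::vector<Cell>& cells, size_t idx, bool hypoxic,
                     double forceProb) {
  Cell& c = cells[idx];
  if (c.state != ST_PROLIF) return false;
  if (c.lineage == LIN_PROG && c.div >= p.divisionLimit) {
    c.state = ST_SENESCENT;
    return false;
  }
  double pr = (c.lineage == LIN_STEM) ? p.pProlifStem : p.pProlifProg;
  if (forceProb >= 0) pr = forceProb;
  if (hypoxic) pr *= p.hypProlif;
  if (unif_rand() >= pr) return false;
  int nb[26][3];
  int nf = freeNeighbors(p, occ, c.i, c.j, c.k, -1, nb);
  if (nf == 0) return false;
  int pick = runifInt(nf);
  bool symmetric = (c.lineage == LIN_STEM) ? (unif_rand() < p.pSymmetric)
                                           : true;
  c.div += 1;
  Cell d;
  d.i = nb[pick][0]; d.j = nb[pick][1]; d.k = nb[pick][2];
  d.lineage = (c.lineage == LIN_STEM && !symmetric) ? LIN_PROG : c.lineage;
  // Within a compartment the daughter shares the parent's post-increment
  // cycle count; an asymmetric stem division founds a fresh progenitor
  // clone with a full division budget.
  d.div = (d.lineage == c.lineage) ? c.div : 0;
  double pConv = hypoxic ? p.pConvHyp : p.pConv;
  d.ccr5 = (symmetric && unif_rand() < pConv) ? CCR5_HIGH : c.ccr5;
  d.state = ST_PROLIF;
  if (d.lineage == LIN_PROG && d.div >= p.divisionLimit)
    d.state = ST_SENESCENT;
  if (c.lineage == LIN_PROG && c.div >= p.divisionLimit)
    c.state = ST_SENESCENT;
  cells.push_back(d);
  occ[lin(p, d.i, d.j, d.k)] = static_cast<int>(cells.size());
  return true;
}

inline bool voxelHypoxic(const Par& p, const LogicalVector& hyp,
                         const Cell& c) {
  if (!p.hypoxiaOn || hyp.size() == 0) return false;
  return hyp[lin(p, c.i, c.j, c.k)];
}

}  // namespace

// One day of the asynchronous update sweep: iterate over a uniformly
// shuffled snapshot of the cells alive at day start; each cell is
// (re)classified for quiescence, then migrates and attempts division.
// Daughters born today do not act. Senescent death is applied
// separately (in R) so the caller owns the bookkeeping.
// [[Rcpp::export(name = "cpp_step_day")]]
List cpp_step_day(IntegerMatrix cellsIn, List params, LogicalVector hypoxic) {
  Par p = parsePar(params);
  std::vector<Cell> cells = readCells(cellsIn);
  std::vector<int> occ = buildOcc(p, cells);
  int n0 = static_cast<int>(cells.size());

  std::vector<int> order(n0);
  for (int r = 0; r < n0; ++r) order[r] = r;
  for (int r = n0 - 1; r > 0; --r)
    std::swap(order[r], order[runifInt(r + 1)]);

  int births = 0;
  for (int t = 0; t < n0; ++t) {
    size_t idx = order[t];
    bool hyp = voxelHypoxic(p, hypoxic, cells[idx]);
    if (cells[idx].state != ST_SENESCENT) {
      // quiescence (re)evaluation: fully enclosed -> quiescent; a free
      // neighbor reverts a quiescent cell to its proliferative state
      if (allNeighborsOccupied(p, occ, cells[idx].i, cells[idx].j,
                               cells[idx].k)) {
        cells[idx].state = ST_QUIESCENT;
        continue;
      }
      cells[idx].state = ST_PROLIF;
    } else if (!p.senescentMigrate) {
      continue;
    }
    int steps = migrationSteps(p, cells[idx].ccr5, hyp);
    walk(p, occ, cells[idx], static_cast<int>(idx) + 1, steps, nullptr);
    if (cells[idx].state == ST_PROLIF)
      births += attemptDivision(p, occ, cells, idx, hyp, -1.0);
  }
  return List::create(_["cells"] = writeCells(cells), _["births"] = births);
}

// [[Rcpp::export(name = "cpp_migrate_cell")]]
List cpp_migrate_cell(IntegerMatrix cellsIn, List params, int index,
                      int nSteps) {
  Par p = parsePar(params);
  std::vector<Cell> cells = readCells(cellsIn);
  if (index < 1 || index > static_cast<int>(cells.size()))
    stop("cell index out of range");
  std::vector<int> occ = buildOcc(p, cells);
  std::vector<int> path;
  walk(p, occ, cells[index - 1], index, nSteps, &path);
  int npos = static_cast<int>(path.size()) / 3;
  IntegerMatrix pm(npos, 3);
  for (int r = 0; r < npos; ++r)
    for (int c = 0; c < 3; ++c) pm(r, c) = path[3 * r + c];
  colnames(pm) = CharacterVector::create("i", "j", "k");
  return List::create(_["cells"] = writeCells(cells), _["path"] = pm);
}

// [[Rcpp::export(name = "cpp_attempt_division")]]
List cpp_attempt_division(IntegerMatrix cellsIn, List params, int index,
                          bool hypoxic, double forceProb) {
  Par p = parsePar(params);
  std::vector<Cell> cells = readCells(cellsIn);
  if (index < 1 || index > static_cast<int>(cells.size()))
    stop("cell index out of range");
  std::vector<int> occ = buildOcc(p, cells);
  bool divided = attemptDivision(p, occ, cells, index - 1, hypoxic,
                                 forceProb);
  return List::create(_["cells"] = writeCells(cells),
                      _["divided"] = divided);
}

// [[Rcpp::export(name = "cpp_check_quiescence")]]
bool cpp_check_quiescence(IntegerMatrix cellsIn, List params, int index) {
  Par p = parsePar(params);
  std::vector<Cell> cells = readCells(cellsIn);
  if (index < 1 || index > static_cast<int>(cells.size()))
    stop("cell index out of range");
  std::vector<int> occ = buildOcc(p, cells);
  const Cell& c = cells[index - 1];
  return allNeighborsOccupied(p, occ, c.i, c.j, c.k);
}

// [[Rcpp::export(name = "cpp_migration_steps")]]
int cpp_migration_steps(List params, int ccr5, bool hypoxic) {
  Par p = parsePar(params);
  return migrationSteps(p, ccr5, hypoxic);
}

// Outer-boundary surface extraction for the shape metrics: free voxels
// are flood-filled (6-connectivity) from the lattice boundary; a mask
// voxel is surface iff some Moore neighbor is exterior-connected free
// space. Interior cavities are not periphery; a mask that fills the
// lattice has no surface.
// [[Rcpp::export(name = "cpp_exterior_surface")]]
LogicalVector cpp_exterior_surface(IntegerMatrix coords,
                                   IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = static_cast<size_t>(nx) * ny * nz;
  std::vector<char> occ(nvox, 0), ext(nvox, 0);
  int n = coords.nrow();
  auto at = [&](int i, int j, int k) {
    return static_cast<size_t>(i) + static_cast<size_t>(nx) *
           (static_cast<size_t>(j) + static_cast<size_t>(ny) * k);
  };
  for (int r = 0; r < n; ++r) occ[at(coords(r, 0), coords(r, 1),
                                     coords(r, 2))] = 1;
  std::vector<int> stack;
  auto push = [&](int i, int j, int k) {
    size_t a = at(i, j, k);
    if (!occ[a] && !ext[a]) {
      ext[a] = 1;
      stack.push_back(i); stack.push_back(j); stack.push_back(k);
    }
  };
  for (int j = 0; j < ny; ++j)
    for (int k = 0; k < nz; ++k) { push(0, j, k); push(nx - 1, j, k); }
  for (int i = 0; i < nx; ++i)
    for (int k = 0; k < nz; ++k) { push(i, 0, k); push(i, ny - 1, k); }
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) { push(i, j, 0); push(i, j, nz - 1); }
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!stack.empty()) {
    int k = stack.back(); stack.pop_back();
    int j = stack.back(); stack.pop_back();
    int i = stack.back(); stack.pop_back();
    for (const auto& d : d6) {
      int ii = i + d[0], jj = j + d[1], kk = k + d[2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      push(ii, jj, kk);
    }
  }
  LogicalVector out(n);
  for (int r = 0; r < n; ++r) {
    bool surf = false;
    int i = coords(r, 0), j = coords(r, 1), k = coords(r, 2);
    for (int dk = -1; dk <= 1 && !surf; ++dk)
      for (int dj = -1; dj <= 1 && !surf; ++dj)
        for (int di = -1; di <= 1 && !surf; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
              kk >= nz)
            continue;
          if (ext[at(ii, jj, kk)]) surf = true;
        }
    out[r] = surf;
  }
  return out;
}
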