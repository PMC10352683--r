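// The lattice engine: eight-stage per-step timeline on a toroidal grid.
//
// Stages (1)-(6) — MLP forward, expression update, gene instability, phenotype
// update, class transitions, dedifferentiation — are per-cell and read no other
// cell's mid-step values (neighbour lookups in stage 6 use the start-of-step
// class snapshot). Stage (7) executes one sampled phenotypic action per cell in
// a fresh uniformly-random site permutation with sequential conflict
// resolution; stage (8) is a scheduled excision.
//
// RNG order (documented contract): cells in row-major order for stages 1-6
// (per cell: G age signs, G uniform z's, then instability / phenotype /
// conversion / dedifferentiation draws as reached), one Fisher-Yates
// permutation, then per-site action draws in permutation order.

#include "kernels.h"
#include <set>
using namespace Rcpp;

namespace {

struct Grid {
  int N, N2, G, C;
  std::vector<int> cls, age, tacFlag, tacGen, lineage;
  std::vector<double> E;   // N2 x G, cell-major (cell idx * G + gene)
  std::vector<double> P;   // N2 x 4
  std::vector<int> nbr;    // N2 x 8 neighbour indices (torus, excl. self)
};

inline int wrap(int a, int N) { return (a % N + N) % N; }

void build_neighbours(Grid& g) {
  g.nbr.resize((size_t)g.N2 * 8);
  int k = 0;
  for (int y = 0; y < g.N; ++y)
    for (int x = 0; x < g.N; ++x) {
      int idx = y * g.N + x, m = 0;
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0) continue;
          g.nbr[(size_t)idx * 8 + m++] = wrap(y + dy, g.N) * g.N + wrap(x + dx, g.N);
        }
      ++k;
    }
}

inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

struct Params {
  // panel
  std::vector<int> T, pairsI, pairsJ;
  NumericMatrix WXsigns, WY, Uinc, Dinc;
  double mbar, nu, beta, bernoulliP, ageWeight;
  int upsilon;
  // fields
  NumericMatrix conc;          // N2 x C
  std::vector<int> activeFrom, activeTo;
  double carcinogenGain;
  // config
  double scale, instabilityProb, phenotypeModProb, cscProb, dediffProb;
  bool cscFromNormalStem;
  int dediffStemMax, dediffEmptyMin;
  double moveProb, killProb, tacBoost;
  int theta;
  NumericMatrix initP;         // 6 x 4
  double wP, wA, wAge, cancerBonus, lifespanTissue, lifespanStem;
  int excisionMode, excisionAtStep, excisionDelaySteps, excisionRings;
};

inline double cell_fitness(const Grid& g, const Params& pp, int idx) {
  return fca_fitness(&g.P[(size_t)idx * 4], g.age[idx], g.cls[idx],
                     pp.lifespanTissue, pp.lifespanStem,
                     pp.wP, pp.wA, pp.wAge, pp.cancerBonus);
}

inline bool is_cancer(int cls) { return cls == CSC || cls == TC; }
inline bool is_stem(int cls) { return cls == NSC || cls == MNSC || cls == CSC; }

struct LineageTrack {
  std::vector<int> count, extinct;
  void kill(int lin, int t) {
    if (--count[lin] == 0) extinct[lin] = t;
  }
};

void clear_cell(Grid& g, int idx) {
  g.cls[idx] = EMPTY;
  g.age[idx] = 0; g.tacFlag[idx] = 0; g.tacGen[idx] = 0; g.lineage[idx] = 0;
  std::fill(g.E.data() + (size_t)idx * g.G,
            g.E.data() + (size_t)(idx + 1) * g.G, 0.0);
  std::fill(g.P.data() + (size_t)idx * 4,
            g.P.data() + (size_t)(idx + 1) * 4, 0.0);
}

void copy_cell(Grid& g, int from, int to) {
  g.cls[to] = g.cls[from]; g.age[to] = g.age[from];
  g.tacFlag[to] = g.tacFlag[from]; g.tacGen[to] = g.tacGen[from];
  g.lineage[to] = g.lineage[from];
  std::copy(g.E.data() + (size_t)from * g.G,
            g.E.data() + (size_t)(from + 1) * g.G,
            g.E.data() + (size_t)to * g.G);
  std::copy(g.P.data() + (size_t)from * 4,
            g.P.data() + (size_t)(from + 1) * 4,
            g.P.data() + (size_t)to * 4);
}

void reset_phenotype(Grid& g, const Params& pp, int idx) {
  for (int i = 0; i < 4; ++i) g.P[(size_t)idx * 4 + i] = pp.initP(g.cls[idx], i);
}

// Place a daughter of `parent` at `target` (already vacated). Mitosis resets
// both ages; a TAC division advances the generation counter on both cells.
void place_daughter(Grid& g, LineageTrack& lt, int parent, int target) {
  copy_cell(g, parent, target);
  if (g.tacFlag[parent]) {
    ++g.tacGen[parent];
    g.tacGen[target] = g.tacGen[parent];
  }
  g.age[parent] = 0; g.age[target] = 0;
  ++lt.count[g.lineage[parent]];
}

}  // namespace

// [[Rcpp::export(name = ".cppSimulate")]]
List cppSimulate(IntegerVector cls, IntegerVector age, NumericMatrix E,
                 NumericMatrix P, IntegerVector tacFlag, IntegerVector tacGen,
                 IntegerVector lineage, int N, int tStart, List panel,
                 List fields, List cfg, int nSteps, int recordStride,
                 IntegerVector snapshotSteps, int nLineages,
                 List events0) {
  Grid g;
  g.N = N; g.N2 = N * N;
  g.G = E.ncol(); g.C = as<NumericMatrix>(fields["conc"]).ncol();
  g.cls.assign(cls.begin(), cls.end());
  g.age.assign(age.begin(), age.end());
  g.tacFlag.assign(tacFlag.begin(), tacFlag.end());
  g.tacGen.assign(tacGen.begin(), tacGen.end());
  g.lineage.assign(lineage.begin(), lineage.end());
  g.E.resize((size_t)g.N2 * g.G);
  g.P.resize((size_t)g.N2 * 4);
  for (int i = 0; i < g.N2; ++i) {
    for (int j = 0; j < g.G; ++j) g.E[(size_t)i * g.G + j] = E(i, j);
    for (int j = 0; j < 4; ++j) g.P[(size_t)i * 4 + j] = P(i, j);
  }
  build_neighbours(g);

  Params pp;
  pp.T = as<std::vector<int>>(panel["T"]);
  pp.pairsI = as<std::vector<int>>(panel["pairsI"]);
  pp.pairsJ = as<std::vector<int>>(panel["pairsJ"]);
  pp.WXsigns = as<NumericMatrix>(panel["WXsigns"]);
  pp.WY = as<NumericMatrix>(panel["WY"]);
  pp.Uinc = as<NumericMatrix>(panel["Uinc"]);
  pp.Dinc = as<NumericMatrix>(panel["Dinc"]);
  pp.mbar = panel["mbar"]; pp.upsilon = panel["upsilon"];
  pp.nu = panel["nu"]; pp.beta = panel["beta"];
  pp.bernoulliP = panel["bernoulliP"]; pp.ageWeight = panel["ageWeight"];
  pp.conc = as<NumericMatrix>(fields["conc"]);
  pp.activeFrom = as<std::vector<int>>(fields["activeFrom"]);
  pp.activeTo = as<std::vector<int>>(fields["activeTo"]);
  pp.carcinogenGain = fields["gain"];
  pp.scale = cfg["expressionScale"];
  pp.instabilityProb = cfg["instabilityProb"];
  pp.phenotypeModProb = cfg["phenotypeModProb"];
  pp.cscProb = cfg["cscProb"];
  pp.cscFromNormalStem = cfg["cscFromNormalStem"];
  pp.dediffProb = cfg["dediffProb"];
  pp.dediffStemMax = cfg["dediffStemMax"];
  pp.dediffEmptyMin = cfg["dediffEmptyMin"];
  pp.moveProb = cfg["moveProb"]; pp.killProb = cfg["killProb"];
  pp.tacBoost = cfg["tacBoost"]; pp.theta = cfg["theta"];
  pp.initP = as<NumericMatrix>(cfg["initP"]);
  pp.wP = cfg["wP"]; pp.wA = cfg["wA"]; pp.wAge = cfg["wAge"];
  pp.cancerBonus = cfg["cancerBonus"];
  pp.lifespanTissue = cfg["lifespanTissueSteps"];
  pp.lifespanStem = cfg["lifespanStemSteps"];
  pp.excisionMode = cfg["excisionMode"];
  pp.excisionAtStep = cfg["excisionAtStep"];
  pp.excisionDelaySteps = cfg["excisionDelaySteps"];
  pp.excisionRings = cfg["excisionRings"];

  double capInstab = pp.scale / pp.nu;   // max per-pair instability change

  LineageTrack lt;
  lt.count.assign(nLineages + 1, 0);
  lt.extinct.assign(nLineages + 1, -1);
  for (int i = 0; i < g.N2; ++i)
    if (g.cls[i] != EMPTY) ++lt.count[g.lineage[i]];

  int firstMutated = events0["firstMutated"], firstCSC = events0["firstCSC"],
      firstTC = events0["firstTC"], excisionStep = events0["excisionStep"],
      recurrenceStep = events0["recurrenceStep"];

  RNGScope rng;

  std::vector<int> cls0(g.N2), perm(g.N2);
  std::vector<unsigned char> acted(g.N2);
  std::vector<double> Xin(g.C + 1), bias(g.G), Y(g.G);
  std::vector<unsigned char> linSeen(nLineages + 1);

  // time-series rows collected as flat doubles
  int seriesNcol = 15 + g.G;
  std::vector<double> series;
  std::set<int> snapSet(snapshotSteps.begin(), snapshotSteps.end());
  List snapshots;
  std::vector<int> snapAt;

  auto record_row = [&](int t, const std::vector<long>& actCount, long actTotal) {
    int occ = 0, nByClass[7] = {0, 0, 0, 0, 0, 0, 0};
    std::vector<double> meanE(g.G, 0.0);
    std::fill(linSeen.begin(), linSeen.end(), 0);
    int cancerLin = 0;
    for (int i = 0; i < g.N2; ++i) {
      ++nByClass[g.cls[i]];
      if (g.cls[i] == EMPTY) continue;
      ++occ;
      for (int j = 0; j < g.G; ++j) meanE[j] += g.E[(size_t)i * g.G + j];
      if (is_cancer(g.cls[i]) && !linSeen[g.lineage[i]]) {
        linSeen[g.lineage[i]] = 1;
        ++cancerLin;
      }
    }
    series.push_back(t);
    for (int c = 0; c < 7; ++c) series.push_back((double)nByClass[c] / g.N2);
    series.push_back((double)(nByClass[1] + nByClass[3] + nByClass[4] +
                              nByClass[5]) / g.N2);
    for (int a = 0; a < 4; ++a)
      series.push_back(actTotal > 0 ? (double)actCount[a] / actTotal : NA_REAL);
    int nPos = 0;
    for (int j = 0; j < g.G; ++j) {
      double m = occ > 0 ? meanE[j] / occ : NA_REAL;
      series.push_back(m);
      if (occ > 0 && fca_pos_mutated(m, pp.T[j], pp.mbar)) ++nPos;
    }
    series.push_back(occ > 0 ? (double)nPos / g.G : NA_REAL);
    series.push_back(cancerLin);
  };

  std::vector<long> act0(4, 0);
  record_row(tStart, act0, 0);
  if (snapSet.count(tStart)) {
    snapshots.push_back(IntegerVector(g.cls.begin(), g.cls.end()));
    snapAt.push_back(tStart);
  }

  for (int step = 1; step <= nSteps; ++step) {
    int t = tStart + step;
    std::copy(g.cls.begin(), g.cls.end(), cls0.begin());

    // ---- stages 1-6, per cell in row-major order --------------------------
    for (int idx = 0; idx < g.N2; ++idx) {
      if (cls0[idx] == EMPTY) continue;
      double* e = &g.E[(size_t)idx * g.G];
      double* p = &g.P[(size_t)idx * 4];

      // (1) MLP forward on exposure + age, with memoryless mutation bias
      for (int i = 0; i < g.C; ++i) {
        bool active = (t - 1) >= pp.activeFrom[i] && (t - 1) <= pp.activeTo[i];
        Xin[i] = active ? pp.conc(idx, i) * pp.carcinogenGain : 0.0;
      }
      Xin[g.C] = g.age[idx];
      fca_mutation_bias(e, g.G, pp.mbar, pp.beta, bias.data());
      fca_forward(Xin.data(), g.C, g.G, pp.WXsigns.begin(), pp.ageWeight,
                  pp.WY.begin(), bias.data(), pp.nu, pp.bernoulliP, Y.data());

      // (2) expression update, (3) gene instability, (4) phenotype update
      fca_update_expression(e, Y.data(), g.G, pp.scale);
      fca_gene_instability(e, g.G, pp.pairsI.data(), pp.pairsJ.data(),
                           (int)pp.pairsI.size(), pp.T.data(), pp.mbar,
                           pp.instabilityProb, capInstab);
      fca_phenotype_update(p, e, g.G, pp.Uinc.begin(), pp.Dinc.begin(),
                           pp.mbar, pp.phenotypeModProb);

      // (5) class transitions: mutation status, TAC conversion, CSC conversion
      int c = g.cls[idx];
      if (c <= MNSC) {
        int nPos = 0;
        for (int j = 0; j < g.G; ++j)
          if (fca_pos_mutated(e[j], pp.T[j], pp.mbar)) ++nPos;
        bool mut = nPos >= pp.upsilon;
        int newc = (c <= MNTC) ? (mut ? MNTC : NTC) : (mut ? MNSC : NSC);
        if (newc != c) {
          g.cls[idx] = newc;
          reset_phenotype(g, pp, idx);
          c = newc;
        }
      }
      if (g.tacFlag[idx] && g.tacGen[idx] >= pp.theta) {
        g.tacFlag[idx] = 0;
        g.tacGen[idx] = 0;
      }
      if (c == MNSC || (pp.cscFromNormalStem && c == NSC)) {
        if (unif_rand() < pp.cscProb) {
          g.cls[idx] = CSC;
          reset_phenotype(g, pp, idx);
          c = CSC;
        }
      }

      // (6) dedifferentiation (neighbour classes from start-of-step snapshot)
      if (c == NTC || c == MNTC || c == TC) {
        int nStem = 0, nEmpty = 0;
        const int* nb = &g.nbr[(size_t)idx * 8];
        for (int m = 0; m < 8; ++m) {
          int nc = cls0[nb[m]];
          if (is_stem(nc)) ++nStem;
          else if (nc == EMPTY) ++nEmpty;
        }
        if (nStem <= pp.dediffStemMax || nEmpty >= pp.dediffEmptyMin) {
          if (unif_rand() < pp.dediffProb) {
            g.cls[idx] = (c == NTC) ? NSC : (c == MNTC) ? MNSC : CSC;
            reset_phenotype(g, pp, idx);
          }
        }
      }
    }

    // ---- stage 7: sampled phenotypic action, random order, sequential -----
    for (int i = 0; i < g.N2; ++i) perm[i] = i;
    for (int i = g.N2 - 1; i > 0; --i)
      std::swap(perm[i], perm[rand_int(i + 1)]);
    std::fill(acted.begin(), acted.end(), 0);

    std::vector<long> actCount(4, 0);
    long actTotal = 0;

    for (int k = 0; k < g.N2; ++k) {
      int idx = perm[k];
      if (g.cls[idx] == EMPTY || acted[idx]) continue;
      acted[idx] = 1;

      double pv[4];
      for (int i = 0; i < 4; ++i) pv[i] = g.P[(size_t)idx * 4 + i];
      if (g.tacFlag[idx]) {                       // TAC proliferation boost
        double shift = std::min(pp.tacBoost, pv[1]);
        pv[0] += shift; pv[1] -= shift;
      }
      double u = unif_rand(), cum = 0.0;
      int action = 3;
      for (int a = 0; a < 4; ++a) {
        cum += pv[a];
        if (u < cum) { action = a; break; }
      }
      int c = g.cls[idx];
      // differentiation by a non-stem class (possible after phenotype drift)
      // is treated as quiescence
      if (action == 3 && !is_stem(c)) action = 1;
      ++actCount[action];
      ++actTotal;

      if (action == 0 || action == 3) {           // proliferate / differentiate
        int tgt = g.nbr[(size_t)idx * 8 + rand_int(8)];
        bool ok = false;
        if (g.cls[tgt] == EMPTY) ok = true;
        else {
          double fv = cell_fitness(g, pp, tgt), fp = cell_fitness(g, pp, idx);
          if (fv < fp) ok = true;
          else if (is_cancer(c) && !is_cancer(g.cls[tgt]))
            ok = unif_rand() < pp.killProb;
          if (ok && g.cls[tgt] != EMPTY) lt.kill(g.lineage[tgt], t);
        }
        if (ok) {
          place_daughter(g, lt, idx, tgt);
          if (action == 3) {                      // daughter is a fresh TAC
            g.cls[tgt] = (c == NSC) ? NTC : (c == MNSC) ? MNTC : TC;
            g.tacFlag[tgt] = 1; g.tacGen[tgt] = 0;
            reset_phenotype(g, pp, tgt);
          }
          acted[tgt] = 1;
        }
      } else if (action == 2) {                   // apoptosis
        lt.kill(g.lineage[idx], t);
        clear_cell(g, idx);
      } else {                                    // quiescence, possible move
        if (unif_rand() < pp.moveProb) {
          int tgt = g.nbr[(size_t)idx * 8 + rand_int(8)];
          bool ok = false;
          if (g.cls[tgt] == EMPTY) ok = true;
          else if (is_cancer(c)) {
            bool allowed = !is_cancer(g.cls[tgt]) ||
                           cell_fitness(g, pp, tgt) < cell_fitness(g, pp, idx);
            if (allowed && unif_rand() < pp.killProb) {
              lt.kill(g.lineage[tgt], t);
              ok = true;
            }
          }
          if (ok) {
            copy_cell(g, idx, tgt);
            acted[tgt] = 1;
            clear_cell(g, idx);
          }
        }
      }
    }

    // ---- stage 8: scheduled excision --------------------------------------
    if (pp.excisionMode > 0 && excisionStep < 0) {
      bool trigger = (pp.excisionAtStep >= 0)
                         ? (t >= pp.excisionAtStep)
                         : (firstTC >= 0 && t >= firstTC + pp.excisionDelaySteps);
      if (trigger) {
        std::vector<unsigned char> rm(g.N2, 0);
        int r = pp.excisionRings;
        for (int y = 0; y < g.N; ++y)
          for (int x = 0; x < g.N; ++x) {
            int idx = y * g.N + x, c = g.cls[idx];
            if (c == TC) {                        // TC plus surrounding rings
              for (int dy = -r; dy <= r; ++dy)
                for (int dx = -r; dx <= r; ++dx)
                  rm[wrap(y + dy, g.N) * g.N + wrap(x + dx, g.N)] = 1;
            } else if (c == CSC) rm[idx] = 1;
            else if (pp.excisionMode == 2 && (c == MNTC || c == MNSC)) rm[idx] = 1;
          }
        for (int idx = 0; idx < g.N2; ++idx)
          if (rm[idx] && g.cls[idx] != EMPTY) {
            lt.kill(g.lineage[idx], t);
            clear_cell(g, idx);
          }
        excisionStep = t;
      }
    }

    // ---- close of step: ageing, event detection, recording ----------------
    int nByClass[7] = {0, 0, 0, 0, 0, 0, 0};
    for (int idx = 0; idx < g.N2; ++idx) {
      if (g.cls[idx] != EMPTY) ++g.age[idx];
      ++nByClass[g.cls[idx]];
    }
    int nMut = nByClass[1] + nByClass[3] + nByClass[4] + nByClass[5];
    if (firstMutated < 0 && nMut > 0) firstMutated = t;
    if (firstCSC < 0 && nByClass[4] > 0) firstCSC = t;
    if (firstTC < 0 && nByClass[5] > 0) firstTC = t;
    if (recurrenceStep < 0 && excisionStep >= 0 && t > excisionStep &&
        nByClass[5] > 0)
      recurrenceStep = t;

    if (step % recordStride == 0 || step == nSteps)
      record_row(t, actCount, actTotal);
    if (snapSet.count(t)) {
      snapshots.push_back(IntegerVector(g.cls.begin(), g.cls.end()));
      snapAt.push_back(t);
    }
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }

  int nrow = (int)(series.size() / seriesNcol);
  NumericMatrix seriesMat(nrow, seriesNcol);
  for (int r = 0; r < nrow; ++r)
    for (int cidx = 0; cidx < seriesNcol; ++cidx)
      seriesMat(r, cidx) = series[(size_t)r * seriesNcol + cidx];

  NumericMatrix Eout(g.N2, g.G), Pout(g.N2, 4);
  for (int i = 0; i < g.N2; ++i) {
    for (int j = 0; j < g.G; ++j) Eout(i, j) = g.E[(size_t)i * g.G + j];
    for (int j = 0; j < 4; ++j) Pout(i, j) = g.P[(size_t)i * 4 + j];
  }

  return List::create(
      _["cls"] = IntegerVector(g.cls.begin(), g.cls.end()),
      _["age"] = IntegerVector(g.age.begin(), g.age.end()),
      _["E"] = Eout, _["P"] = Pout,
      _["tacFlag"] = IntegerVector(g.tacFlag.begin(), g.tacFlag.end()),
      _["tacGen"] = IntegerVector(g.tacGen.begin(), g.tacGen.end()),
      _["lineage"] = IntegerVector(g.lineage.begin(), g.lineage.end()),
      _["t"] = tStart + nSteps,
      _["series"] = seriesMat,
      _["events"] = List::create(
          _["firstMutated"] = firstMutated, _["firstCSC"] = firstCSC,
          _["firstTC"] = firstTC, _["excisionStep"] = excisionStep,
          _["recurrenceStep"] = recurrenceStep),
      _["snapshots"] = snapshots, _["snapshotSteps"] = IntegerVector(snapAt.begin(), snapAt.end()),
      _["lineageCount"] = IntegerVector(lt.count.begin(), lt.count.end()),
      _["lineageExtinct"] = IntegerVector(lt.extinct.begin(), lt.extinct.end()));
}
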