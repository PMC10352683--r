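// Per-cell computational kernels shared by the lattice engine and the exported
// R-level operations. All stochastic kernels consume R's RNG stream so that a
// set.seed() on the R side makes every simulation bit-reproducible.

#include "kernels.h"
using namespace Rcpp;

// Hidden + output layer of the per-cell gene MLP.
// x = [carcinogen levels (C), age]; the age column of W_X is ageWeight with a
// freshly drawn Bernoulli(+/-1) sign per gene (consumes G uniforms).
void fca_forward(const double* x, int C, int G,
                 const double* WXsigns,   /* G x C, column-major */
                 double ageWeight,
                 const double* WY,        /* G x G, column-major */
                 const double* bias,      /* G */
                 double nu, double bernoulliP,
                 double* Y /* out, G */) {
  std::vector<double> H(G);
  for (int j = 0; j < G; ++j) {
    double sgn = (unif_rand() < bernoulliP) ? 1.0 : -1.0;
    double acc = 0.0;
    for (int i = 0; i < C; ++i) acc += WXsigns[j + i * G] * x[i];
    acc += sgn * ageWeight * x[C];
    H[j] = fca_gamma(acc, nu);
  }
  for (int j = 0; j < G; ++j) {
    double acc = bias[j];
    for (int k = 0; k < G; ++k) acc += WY[j + k * G] * H[k];
    Y[j] = fca_gamma(acc, nu);
  }
}

// e_j += z_j * scale * delta_j, z_j ~ U(0,1) independent (consumes G uniforms).
void fca_update_expression(double* E, const double* delta, int G, double scale) {
  for (int j = 0; j < G; ++j) E[j] += unif_rand() * scale * delta[j];
}

// Mutation bias (memoryless): +beta / -beta / 0 by expression vs threshold.
void fca_mutation_bias(const double* E, int G, double mbar, double beta,
                       double* bias) {
  for (int j = 0; j < G; ++j)
    bias[j] = (E[j] >= mbar) ? beta : (E[j] <= -mbar ? -beta : 0.0);
}

// Gene instability: mutated genes act on the genes they are related to.
// A positively mutated source pushes the target toward its cancer direction;
// a gene mutated in the protective direction repairs the target toward 0.
// Per accepted pair the move is u * cap, u ~ U(0,1); repair never overshoots 0.
void fca_gene_instability(double* E, int G,
                          const int* pi, const int* pj, int nPairs,
                          const int* T, double mbar,
                          double pMod, double cap) {
  for (int k = 0; k < nPairs; ++k) {
    int i = pi[k], j = pj[k];
    if (std::fabs(E[i]) < mbar) continue;           // only mutated genes act
    if (unif_rand() >= pMod) continue;
    double u = unif_rand();
    if (fca_pos_mutated(E[i], T[i], mbar)) {
      E[j] += (T[j] == 1 ? 1.0 : -1.0) * u * cap;   // toward cancer direction
    } else {
      double step = u * cap;                        // repair toward 0
      if (E[j] > 0.0) E[j] = std::max(0.0, E[j] - step);
      else if (E[j] < 0.0) E[j] = std::min(0.0, E[j] + step);
    }
  }
}

// Phenotype-probability update. Genes past threshold contribute their U/D
// increment column with probability pMod; every non-quiescence change is
// balanced against quiescence; result is clipped at 0 and renormalized.
void fca_phenotype_update(double* P, const double* E, int G,
                          const double* Uinc, const double* Dinc, /* 4 x G */
                          double mbar, double pMod) {
  for (int j = 0; j < G; ++j) {
    const double* col;
    if (E[j] >= mbar) col = Uinc + 4 * j;
    else if (E[j] <= -mbar) col = Dinc + 4 * j;
    else continue;
    if (unif_rand() >= pMod) continue;
    for (int i = 0; i < 4; ++i) P[i] += col[i];
    P[1] -= (col[0] + col[2] + col[3]);             // balance against quiescence
  }
  double s = 0.0;
  for (int i = 0; i < 4; ++i) { if (P[i] < 0.0) P[i] = 0.0; s += P[i]; }
  if (s > 0.0) for (int i = 0; i < 4; ++i) P[i] /= s;
  else { P[1] = 1.0; P[0] = P[2] = P[3] = 0.0; }
}

// Fitness: increasing in proliferation, decreasing in apoptosis and age
// (age measured in expected lifespans of the class), cancer classes get a bonus.
double fca_fitness(const double* P, int age, int cls,
                   double lifespanTissue, double lifespanStem,
                   double wP, double wA, double wAge, double bonus) {
  double lifespan = (cls == NSC || cls == MNSC || cls == CSC) ? lifespanStem
                                                              : lifespanTissue;
  double f = wP * P[0] - wA * P[2] - wAge * ((double)age / lifespan);
  if (cls == CSC || cls == TC) f += bonus;
  return f;
}

// ---- R-facing wrappers -----------------------------------------------------

// [[Rcpp::export(name = ".cppMlpForward")]]
NumericVector cppMlpForward(NumericVector x, NumericMatrix WXsigns,
                            double ageWeight, NumericMatrix WY,
                            NumericVector bias, double nu, double bernoulliP) {
  int G = WY.nrow(), C = WXsigns.ncol();
  if (x.size() != C + 1) stop("network-error: input length must be C+1");
  if (bias.size() != G || WXsigns.nrow() != G || WY.ncol() != G)
    stop("network-error: dimension mismatch");
  NumericVector Y(G);
  fca_forward(x.begin(), C, G, WXsigns.begin(), ageWeight, WY.begin(),
              bias.begin(), nu, bernoulliP, Y.begin());
  return Y;
}

// [[Rcpp::export(name = ".cppUpdateExpression")]]
NumericVector cppUpdateExpression(NumericVector E, NumericVector delta,
                                  double scale) {
  if (E.size() != delta.size()) stop("network-error: length mismatch");
  NumericVector out = clone(E);
  fca_update_expression(out.begin(), delta.begin(), out.size(), scale);
  return out;
}

// [[Rcpp::export(name = ".cppGeneInstability")]]
NumericVector cppGeneInstability(NumericVector E, IntegerVector pairsI,
                                 IntegerVector pairsJ, IntegerVector T,
                                 double mbar, double pMod, double cap) {
  NumericVector out = clone(E);
  fca_gene_instability(out.begin(), out.size(), pairsI.begin(), pairsJ.begin(),
                       pairsI.size(), T.begin(), mbar, pMod, cap);
  return out;
}

// [[Rcpp::export(name = ".cppPhenotypeUpdate")]]
NumericMatrix cppPhenotypeUpdate(NumericMatrix P, NumericMatrix E,
                                 NumericMatrix Uinc, NumericMatrix Dinc,
                                 double mbar, double pMod) {
  int n = P.nrow(), G = E.ncol();
  if (E.nrow() != n) stop("state-error: row mismatch");
  NumericMatrix out = clone(P);
  std::vector<double> p(4), e(G);
  for (int r = 0; r < n; ++r) {
    for (int i = 0; i < 4; ++i) p[i] = out(r, i);
    for (int j = 0; j < G; ++j) e[j] = E(r, j);
    fca_phenotype_update(p.data(), e.data(), G, Uinc.begin(), Dinc.begin(),
                         mbar, pMod);
    for (int i = 0; i < 4; ++i) out(r, i) = p[i];
  }
  return out;
}

// [[Rcpp::export(name = ".cppFitness")]]
double cppFitness(NumericVector P, int age, int cls, double lifespanTissue,
                  double lifespanStem, double wP, double wA, double wAge,
                  double bonus) {
  return fca_fitness(P.begin(), age, cls, lifespanTissue, lifespanStem,
                     wP, wA, wAge, bonus);
}
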