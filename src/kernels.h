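#ifndef FIELDCA_KERNELS_H
#define FIELDCA_KERNELS_H

#include <Rcpp.h>

// Cell classes, Table-2 coding
enum CellClass { NTC = 0, MNTC = 1, NSC = 2, MNSC = 3, CSC = 4, TC = 5, EMPTY = 6 };

// gamma(xi) = xi / (1 + nu * xi^2); odd, peak 1/(2*sqrt(nu)) at xi = 1/sqrt(nu)
inline double fca_gamma(double xi, double nu) {
  return xi / (1.0 + nu * xi * xi);
}

inline bool fca_pos_mutated(double e, int gene_type, double mbar) {
  return (gene_type == 0) ? (e <= -mbar) : (e >= mbar);
}

void fca_forward(const double* x, int C, int G, const double* WXsigns,
                 double ageWeight, const double* WY, const double* bias,
                 double nu, double bernoulliP, double* Y);
void fca_update_expression(double* E, const double* delta, int G, double scale);
void fca_mutation_bias(const double* E, int G, double mbar, double beta,
                       double* bias);
void fca_gene_instability(double* E, int G, const int* pi, const int* pj,
                          int nPairs, const int* T, double mbar, double pMod,
                          double cap);
void fca_phenotype_update(double* P, const double* E, int G,
                          const double* Uinc, const double* Dinc, double mbar,
                          double pMod);
double fca_fitness(const double* P, int age, int cls, double lifespanTissue,
                   double lifespanStem, double wP, double wA, double wAge,
                   double bonus);

#endif
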