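#' Positive mutation of a single gene
#'
#' A gene is positively mutated (mutated toward cancer) when a tumor
#' suppressor is downregulated past the threshold (\eqn{e \le -\bar M}) or an
#' oncogene is upregulated past it (\eqn{e \ge \bar M}).
#'
#' @param e gene expression (vectorized).
#' @param geneType 0 = tumor suppressor, 1 = oncogene (recycled).
#' @param MBar positive mutation threshold.
#' @return logical.
#' @export
positivelyMutated <- function(e, geneType, MBar = 0.1) {
  stopifnot(MBar > 0)
  ifelse(geneType == 0, e <= -MBar, e >= MBar)
}

#' Count positively mutated genes; classify a mutated cell
#'
#' A cell is classed as mutated when it carries at least \code{Upsilon}
#' positively mutated genes.
#'
#' @param E expression vector.
#' @param Type gene-type vector (0/1), same length.
#' @param MBar mutation threshold.
#' @return \code{countPositiveMutations}: integer count in 0..G.
#' @export
countPositiveMutations <- function(E, Type, MBar = 0.1) {
  stopifnot(length(E) == length(Type))
  sum(positivelyMutated(E, Type, MBar))
}

#' @rdname countPositiveMutations
#' @param count number of positively mutated genes.
#' @param Upsilon minimum count for a mutated cell.
#' @export
isMutatedCell <- function(count, Upsilon = 4L) {
  count >= Upsilon
}

#' One genetic-instability update of a cell's expressions
#'
#' Mutated genes act on the genes they are related to (rows of the panel's
#' relationship matrix): a positively mutated source nudges each related gene
#' toward that gene's own cancer direction, while a gene mutated in the
#' protective direction nudges related genes back toward normal expression
#' (never overshooting 0). Each related pair acts independently with
#' probability \code{pMod}, moving the target by \eqn{u \cdot}\code{cap},
#' \eqn{u \sim U(0,1)}; the default cap is \eqn{1/\nu}, scaled by the
#' calibration factor.
#'
#' @param E expression vector.
#' @param panel a [GenePanel-class].
#' @param pMod per-pair modification probability.
#' @param nu activation parameter setting the change cap.
#' @param scale expression-change calibration factor.
#' @return updated expression vector.
#' @export
geneInstabilityStep <- function(E, panel, pMod = 0.45, nu = 1e6, scale = 1) {
  stopifnot(pMod >= 0, pMod <= 1, length(E) == nGenes(panel))
  pr <- .relationPairs(panel)
  .cppGeneInstability(E, pr$i, pr$j, panel@geneType, panel@MBar, pMod,
                      scale / nu)
}

# 0-based (source, target) pairs of the relationship matrix, row-major
.relationPairs <- function(panel) {
  idx <- which(t(panel@R) == 1)
  j <- (idx - 1) %% nGenes(panel)          # target (column of R)
  i <- (idx - 1) %/% nGenes(panel)         # source (row of R)
  list(i = as.integer(i), j = as.integer(j))
}

#' Phenotype-probability update from mutated genes
#'
#' Every gene past the mutation threshold contributes, with probability
#' \code{pModPh}, its increment column (up-column for expression at or above
#' the threshold, down-column at or below its negative). Each non-quiescence
#' change is balanced by an equal opposite change to quiescence; the result
#' is clipped at 0 and renormalized to sum 1.
#'
#' @param P phenotype probability 4-vector (p, q, a, d).
#' @param E expression vector.
#' @param panel a [GenePanel-class].
#' @param pModPh per-gene modification probability.
#' @return updated probability 4-vector.
#' @export
phenotypeUpdate <- function(P, E, panel, pModPh = 0.35) {
  stopifnot(length(P) == 4, all(P >= 0), abs(sum(P) - 1) < 1e-9)
  drop(.cppPhenotypeUpdate(matrix(P, 1), matrix(E, 1), panel@Uinc,
                           panel@Dinc, panel@MBar, pModPh))
}

#' Initial phenotype-probability table
#'
#' Builds the per-class table of initial (p, q, a, d) probabilities. With
#' \eqn{\bar a_1 = \tilde c/\bar c_1} and \eqn{\bar a_2 = \tilde c/\bar c_2}
#' the initial apoptosis probabilities of tissue and stem cells, the rows are
#' (columns p, q, a, d):
#' \itemize{
#' \item NTC: \eqn{(\bar p_1 \bar a_1,\; 1 - \bar a_1(\bar p_1 + 1),\;
#'   \bar a_1,\; 0)}
#' \item MNTC: apoptosis divided by \eqn{\bar\alpha}
#' \item NSC: stem analogue with differentiation mass \eqn{\bar d \tilde d}
#' \item MNSC: stem analogue, apoptosis divided by \eqn{\bar\alpha}
#' \item CSC: apoptosis divided by \eqn{(5\bar\alpha)^2}
#' \item TC: tissue analogue, apoptosis divided by \eqn{(5\bar\alpha)^2}
#' }
#' where \eqn{\tilde d = 1/(2^{\Theta+1} - 2)} is the differentiation
#' probability implied by a transit-amplifying lineage of \eqn{\Theta}
#' generations. Quiescence takes the remainder, so each row sums to 1
#' exactly.
#'
#' @param cellCycleHours cell-cycle length (hours per time-step).
#' @param lifespanTissueHours,lifespanStemHours expected lifespans.
#' @param pBar1,pBar2 proliferation factors of tissue and stem classes.
#' @param alphaBar apoptotic factor of mutated classes.
#' @param dBar differentiation factor.
#' @param theta maximum TAC generations.
#' @return An [InitialPhenotypeTable-class].
#' @examples
#' tb <- initialPhenotypeTable()
#' tb@table["NTC", ]  # (0.026, 0.934, 0.04, 0)
#' @export
initialPhenotypeTable <- function(cellCycleHours = 10,
                                  lifespanTissueHours = 250,
                                  lifespanStemHours = 25550,
                                  pBar1 = 0.65, pBar2 = 14.75,
                                  alphaBar = 1.625, dBar = 1.485,
                                  theta = 2L) {
  a1 <- cellCycleHours / lifespanTissueHours
  a2 <- cellCycleHours / lifespanStemHours
  dt <- 1 / (2^(theta + 1) - 2)
  dd <- dBar * dt
  row <- function(p, aBase, aDiv, diff) {
    a <- aBase / aDiv
    c(p * aBase, 1 - p * aBase - a - diff, a, diff)
  }
  tb <- rbind(
    NTC  = row(pBar1, a1, 1, 0),
    MNTC = row(pBar1, a1, alphaBar, 0),
    NSC  = row(pBar2, a2, 1, dd),
    MNSC = row(pBar2, a2, alphaBar, dd),
    CSC  = row(pBar2, a2, (5 * alphaBar)^2, dd),
    TC   = row(pBar1, a1, (5 * alphaBar)^2, 0)
  )
  colnames(tb) <- c("p", "q", "a", "d")
  new("InitialPhenotypeTable", table = tb,
      params = list(cellCycleHours = cellCycleHours,
                    lifespanTissueHours = lifespanTissueHours,
                    lifespanStemHours = lifespanStemHours,
                    pBar1 = pBar1, pBar2 = pBar2, alphaBar = alphaBar,
                    dBar = dBar, theta = as.integer(theta),
                    a1 = a1, a2 = a2, dTilde = dt))
}

#' Initial phenotype vector for a cell class
#'
#' @param cls class code 0..5 (empty cells carry no phenotype).
#' @param table an [InitialPhenotypeTable-class].
#' @return probability 4-vector (p, q, a, d).
#' @export
initialPhenotype <- function(cls, table = initialPhenotypeTable()) {
  if (!cls %in% 0:5) stop("state-error: cls must be a non-empty class 0..5")
  table@table[cls + 1L, ]
}

#' Cell state constructor
#'
#' @param cls class code 0..6.
#' @param age age in time-steps.
#' @param E expression vector.
#' @param P phenotype probability 4-vector.
#' @param tacFlag,tacGen TAC status and generation.
#' @param lineage lineage id.
#' @return A [CellState-class].
#' @export
cellState <- function(cls, age = 0L, E = numeric(10),
                      P = initialPhenotype(cls), tacFlag = 0L, tacGen = 0L,
                      lineage = 1L) {
  new("CellState", cls = as.integer(cls), age = as.integer(age),
      E = E, P = P, tacFlag = as.integer(tacFlag),
      tacGen = as.integer(tacGen), lineage = as.integer(lineage))
}

#' Sample a phenotypic action
#'
#' Categorical draw from a cell's phenotype-probability vector; performed
#' once per cell per time-step by the automaton.
#'
#' @param P probability 4-vector (p, q, a, d).
#' @return one of "proliferation", "quiescence", "apoptosis",
#'   "differentiation".
#' @export
chooseAction <- function(P) {
  stopifnot(length(P) == 4, all(P >= 0), abs(sum(P) - 1) < 1e-9)
  .ACTIONS[sample.int(4L, 1L, prob = P)]
}

#' Cell fitness
#'
#' \eqn{f = w_p P_p - w_a P_a - w_{age} \cdot age/L + bonus \cdot 1[cls \in
#' \{CSC, TC\}]}, where \eqn{L} is the expected lifespan of the class in
#' time-steps: high fitness means high proliferation, low apoptosis, young
#' age, and cancer classes carry an additive bonus.
#'
#' @param cell a [CellState-class] (non-empty).
#' @param config a [SimConfig-class] supplying the weights and lifespans.
#' @return numeric fitness score.
#' @export
cellFitness <- function(cell, config = simConfig()) {
  if (cell@cls == 6L) stop("state-error: empty cells have no fitness")
  w <- config@fitnessWeights
  .cppFitness(cell@P, cell@age, cell@cls,
              config@lifespanTissueHours / config@cellCycleHours,
              config@lifespanStemHours / config@cellCycleHours,
              w[1], w[2], w[3], w[4])
}

setMethod("show", "InitialPhenotypeTable", function(object) {
  cat("InitialPhenotypeTable (rows p, q, a, d; theta =",
      object@params$theta, ")\n")
  print(round(object@table, 6))
})

setMethod("show", "CellState", function(object) {
  cls <- c("NTC", "MNTC", "NSC", "MNSC", "CSC", "TC", "empty")[object@cls + 1]
  cat("CellState:", cls, "age", object@age, "lineage", object@lineage)
  if (object@tacFlag) cat(" TAC(gen ", object@tacGen, ")", sep = "")
  cat("\n")
})
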