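#' @import methods
NULL

#' Gene panel: annotation and parameter matrices for the gene network
#'
#' A \code{GenePanel} bundles everything gene-specific the simulator needs:
#' the tumor-suppressor/oncogene type vector, the per-carcinogen sign matrix
#' (the carcinogen columns of the input weight matrix), the output weight
#' matrix of the gene network, the gene relationship matrix used during the
#' genetic-instability stage, and the phenotype increment matrices.
#'
#' @slot geneNames character vector of gene symbols (length G).
#' @slot geneType integer vector, 0 = tumor suppressor, 1 = oncogene.
#' @slot carcinogenNames character vector naming the carcinogen columns.
#' @slot WXsigns G x C matrix with entries in \{-1, 0, +1\}: +1 means the
#'   carcinogen upregulates the gene.
#' @slot WY G x G output weight matrix of the gene network.
#' @slot R G x G binary gene relationship matrix (zero diagonal).
#' @slot Uinc,Dinc 4 x G phenotype increment matrices (rows: proliferation,
#'   quiescence, apoptosis, differentiation) applied when a gene is past the
#'   mutation threshold in the up/down direction; \code{Uinc == -Dinc}.
#' @slot MBar positive mutation threshold on gene expression.
#' @slot Upsilon minimum number of positively mutated genes for a cell to be
#'   classed as mutated.
#' @slot incrementMagnitude magnitude of a single phenotype increment.
#' @slot ageWeight magnitude of the age column of the input weight matrix.
#' @slot annotations list of per-gene annotation lists (as read from a panel
#'   file); kept for provenance and round-tripping.
#'
#' @seealso [hnsccPanel()], [genePanel()], [readGenePanel()]
#' @export
setClass("GenePanel", representation(
  geneNames = "character",
  geneType = "integer",
  carcinogenNames = "character",
  WXsigns = "matrix",
  WY = "matrix",
  R = "matrix",
  Uinc = "matrix",
  Dinc = "matrix",
  MBar = "numeric",
  Upsilon = "integer",
  incrementMagnitude = "numeric",
  ageWeight = "numeric",
  annotations = "list"
))

setValidity("GenePanel", function(object) {
  G <- length(object@geneNames)
  C <- length(object@carcinogenNames)
  msg <- character(0)
  if (length(object@geneType) != G || !all(object@geneType %in% c(0L, 1L)))
    msg <- c(msg, "geneType must be a 0/1 vector of length G")
  if (!identical(dim(object@WXsigns), c(G, C)) ||
      !all(object@WXsigns %in% c(-1, 0, 1)))
    msg <- c(msg, "WXsigns must be G x C with entries in {-1,0,+1}")
  if (!identical(dim(object@WY), c(G, G)))
    msg <- c(msg, "WY must be G x G")
  if (!identical(dim(object@R), c(G, G)) || !all(object@R %in% c(0, 1)))
    msg <- c(msg, "R must be a binary G x G matrix")
  if (any(diag(object@R) != 0))
    msg <- c(msg, "diag(R) must be zero: genes cannot modify themselves")
  if (!identical(dim(object@Uinc), c(4L, G)) ||
      !identical(dim(object@Dinc), c(4L, G)))
    msg <- c(msg, "Uinc and Dinc must be 4 x G")
  if (max(abs(object@Uinc + object@Dinc)) > 0)
    msg <- c(msg, "Uinc must equal -Dinc")
  if (!all(abs(object@Uinc) %in% c(0, object@incrementMagnitude)))
    msg <- c(msg, "|Uinc| entries must be 0 or incrementMagnitude")
  if (object@MBar <= 0) msg <- c(msg, "MBar must be positive")
  if (object@Upsilon < 1) msg <- c(msg, "Upsilon must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Parameters of the per-cell gene network
#'
#' @slot nu activation parameter: the activation \eqn{\gamma(\xi) = \xi /
#'   (1 + \nu \xi^2)} bounds every output by \eqn{1/(2\sqrt\nu)}.
#' @slot beta magnitude of the mutation bias applied to genes past the
#'   mutation threshold.
#' @slot bernoulliP success probability of the per-step Bernoulli sign flips
#'   of the age weight.
#' @export
setClass("NetworkParams", representation(
  nu = "numeric", beta = "numeric", bernoulliP = "numeric"
))

setValidity("NetworkParams", function(object) {
  msg <- character(0)
  if (object@nu <= 0) msg <- c(msg, "nu must be positive")
  if (object@beta <= 0) msg <- c(msg, "beta must be positive")
  if (object@bernoulliP < 0 || object@bernoulliP > 1)
    msg <- c(msg, "bernoulliP must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Spatial carcinogen field with an on/off schedule
#'
#' The concentration pattern is static in space over a run; the schedule
#' (a step window) gates it on and off.
#'
#' @slot name label, e.g. "alcohol" or "smoking".
#' @slot concentration N x N nonnegative matrix; element \code{[row, col]}
#'   is the concentration at 0-based lattice coordinates
#'   \code{(x, y) = (col - 1, row - 1)}.
#' @slot activeFrom,activeTo first and last time-step (inclusive) at which
#'   the field is switched on.
#' @export
setClass("CarcinogenField", representation(
  name = "character",
  concentration = "matrix",
  activeFrom = "numeric",
  activeTo = "numeric"
))

setValidity("CarcinogenField", function(object) {
  if (any(object@concentration < 0))
    return("concentration must be nonnegative")
  if (nrow(object@concentration) != ncol(object@concentration))
    return("concentration must be square")
  TRUE
})

#' Initial phenotype-probability table
#'
#' One row of initial (proliferation, quiescence, apoptosis, differentiation)
#' probabilities per cell class 0..5, built from the cell-cycle length, the
#' tissue and stem-cell lifespans, the proliferation factors, the apoptotic
#' factor and the differentiation factor. Every row sums to 1 by construction.
#'
#' @slot table 6 x 4 matrix, rows in class order NTC, MNTC, NSC, MNSC, CSC,
#'   TC; columns p, q, a, d.
#' @slot params named list of the scalars the table was built from.
#' @export
setClass("InitialPhenotypeTable", representation(
  table = "matrix", params = "list"
))

setValidity("InitialPhenotypeTable", function(object) {
  tb <- object@table
  if (!identical(dim(tb), c(6L, 4L))) return("table must be 6 x 4")
  if (any(tb < 0) || any(tb > 1)) return("entries must be probabilities")
  if (max(abs(rowSums(tb) - 1)) > 1e-12) return("rows must sum to 1")
  TRUE
})

#' A single lattice occupant
#'
#' Mostly useful for unit-level work with the per-cell rules; the lattice
#' engine stores the same fields in flat arrays.
#'
#' @slot cls integer class code 0..6 (0 NTC, 1 MNTC, 2 NSC, 3 MNSC, 4 CSC,
#'   5 TC, 6 empty).
#' @slot age nonnegative age in time-steps, measured since the last mitosis.
#' @slot E gene-expression vector (length G).
#' @slot P phenotype-probability vector (p, q, a, d), summing to 1.
#' @slot tacFlag 1 while the cell is a transit-amplifying cell.
#' @slot tacGen TAC generation counter.
#' @slot lineage integer lineage identifier.
#' @export
setClass("CellState", representation(
  cls = "integer", age = "integer", E = "numeric", P = "numeric",
  tacFlag = "integer", tacGen = "integer", lineage = "integer"
))

setValidity("CellState", function(object) {
  msg <- character(0)
  if (!object@cls %in% 0:6) msg <- c(msg, "cls must be in 0..6")
  if (object@age < 0) msg <- c(msg, "age must be nonnegative")
  if (object@cls != 6L) {
    if (any(object@P < 0) || abs(sum(object@P) - 1) > 1e-9)
      msg <- c(msg, "P must be a probability 4-vector")
  }
  if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' All tunable scalars of the cellular automaton, with defaults for the
#' head-and-neck squamous cell carcinoma setting. See the package vignette
#' for the meaning, unit and provenance of each parameter.
#'
#' @export
setClass("SimConfig", representation(
  seedFractions = "numeric",
  theta = "integer",
  moveProb = "numeric",
  killProb = "numeric",
  cscProb = "numeric",
  cscFromNormalStem = "logical",
  dediffProb = "numeric",
  dediffStemMax = "integer",
  dediffEmptyMin = "integer",
  instabilityProb = "numeric",
  phenotypeModProb = "numeric",
  cellCycleHours = "numeric",
  lifespanTissueHours = "numeric",
  lifespanStemHours = "numeric",
  pBar1 = "numeric",
  pBar2 = "numeric",
  alphaBar = "numeric",
  dBar = "numeric",
  tacBoost = "numeric",
  carcinogenGain = "numeric",
  expressionScale = "numeric",
  network = "NetworkParams",
  excisionMode = "character",
  excisionDelayMonths = "numeric",
  excisionAtStep = "numeric",
  excisionRings = "integer",
  fitnessWeights = "numeric",
  hoursPerMonth = "numeric",
  coldStart = "logical"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  sf <- object@seedFractions
  if (length(sf) != 3 || any(sf < 0) || abs(sum(sf) - 1) > 1e-9)
    msg <- c(msg, "seedFractions must be 3 nonnegative values summing to 1")
  for (nm in c("moveProb", "killProb", "cscProb", "dediffProb",
               "instabilityProb", "phenotypeModProb"))
    if (slot(object, nm) < 0 || slot(object, nm) > 1)
      msg <- c(msg, paste(nm, "must be in [0,1]"))
  if (!object@excisionMode %in% c("none", "tumor", "field"))
    msg <- c(msg, "excisionMode must be none, tumor or field")
  if (length(object@fitnessWeights) != 4)
    msg <- c(msg, "fitnessWeights must have length 4 (wP, wA, wAge, bonus)")
  if (object@cellCycleHours <= 0) msg <- c(msg, "cellCycleHours must be > 0")
  if (length(msg)) msg else TRUE
})

#' Toroidal lattice state
#'
#' The complete state of the automaton at one time-step: an N x N grid of
#' cell classes plus the per-cell age, gene-expression and phenotype arrays,
#' TAC bookkeeping and lineage identifiers. Per-cell arrays are stored with
#' one row per lattice site, sites in column-major order of the class matrix.
#'
#' @export
setClass("LatticeState", representation(
  N = "integer",
  cls = "matrix",
  age = "matrix",
  E = "matrix",
  P = "matrix",
  tacFlag = "matrix",
  tacGen = "matrix",
  lineage = "matrix",
  t = "integer",
  nLineages = "integer",
  geneNames = "character"
))

setValidity("LatticeState", function(object) {
  N <- object@N
  msg <- character(0)
  if (!identical(dim(object@cls), c(N, N))) msg <- c(msg, "cls must be N x N")
  if (!all(object@cls %in% 0:6)) msg <- c(msg, "classes must be in 0..6")
  if (nrow(object@E) != N * N) msg <- c(msg, "E must have N^2 rows")
  if (!identical(dim(object@P), c(N * N, 4L)))
    msg <- c(msg, "P must be N^2 x 4")
  if (length(msg)) msg else TRUE
})

#' Result of a simulation run
#'
#' @slot series data.frame of per-step class fractions, phenotype-action
#'   fractions, mean gene expressions, the fraction of genes whose
#'   population-mean expression is positively mutated, and the number of
#'   lineages holding cancer-class cells.
#' @slot events named list of event steps (first mutated cell, first CSC,
#'   first TC, excision, recurrence); \code{NA} when the event did not occur.
#' @slot finalState the [LatticeState-class] at the last step.
#' @slot lineages per-lineage summary table (sizes, extinction step).
#' @slot snapshots list of class matrices captured at requested steps.
#' @slot metadata config echo, seed, calibration and package version.
#' @export
setClass("SimResult", representation(
  series = "data.frame",
  events = "list",
  finalState = "LatticeState",
  lineages = "data.frame",
  snapshots = "list",
  metadata = "list"
))
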