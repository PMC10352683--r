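.CLASS_NAMES <- c("NTC", "MNTC", "NSC", "MNSC", "CSC", "TC", "empty")

#' Simulation configuration constructor
#'
#' Defaults are the head-and-neck squamous cell carcinoma setting: seed
#' composition 64.5\% normal tissue cells, 6.5\% normal stem cells, 29\%
#' empty; \eqn{\Theta = 2} transit-amplifying generations; quiescent move
#' probability 0.25; cancer kill probability 0.2; stem-to-cancer-stem
#' conversion probability 2.5e-6 per step; dedifferentiation probability
#' 1e-4, attempted when a non-stem cell sees no stem cells or at least six
#' empty sites in its neighborhood; genetic-instability probability 0.45;
#' phenotype modification probability 0.35; 10-hour cell cycle; tissue and
#' stem lifespans 250 h and 25,550 h.
#'
#' \code{carcinogenGain} and \code{expressionScale} are the calibration
#' factors discussed in the vignette; both default to 1 (the uncalibrated
#' printed parameterization) and are recorded in run metadata.
#'
#' @param seedFractions named numeric (NTC, NSC, empty) summing to 1.
#' @param theta maximum TAC generations.
#' @param moveProb probability a quiescent cell attempts to move.
#' @param killProb probability a CSC/TC displaces a fitter or occupying cell.
#' @param cscProb per-step probability a mutated stem cell becomes a CSC.
#' @param cscFromNormalStem also allow unmutated stem cells to convert.
#' @param dediffProb dedifferentiation probability once triggered.
#' @param dediffStemMax trigger when stem neighbors are at most this many.
#' @param dediffEmptyMin trigger when empty neighbors are at least this many.
#' @param instabilityProb per-related-pair gene-instability probability.
#' @param phenotypeModProb per-gene phenotype modification probability.
#' @param cellCycleHours hours per time-step.
#' @param lifespanTissueHours,lifespanStemHours expected lifespans in hours.
#' @param pBar1,pBar2,alphaBar,dBar initial-phenotype factors
#'   (see [initialPhenotypeTable()]).
#' @param tacBoost proliferation-probability boost while a cell is a TAC.
#' @param carcinogenGain input gain applied to carcinogen concentrations.
#' @param expressionScale global expression-change scale factor.
#' @param network a [NetworkParams-class].
#' @param excisionMode "none", "tumor" (remove TC/CSC plus rings around TCs)
#'   or "field" (additionally remove all mutated classes).
#' @param excisionDelayMonths delay between first tumor cell and excision.
#' @param excisionAtStep fixed excision step (overrides the delay trigger
#'   when not \code{NA}).
#' @param excisionRings Chebyshev radius removed around each tumor cell.
#' @param fitnessWeights numeric (wP, wA, wAge, cancerBonus).
#' @param hoursPerMonth calendar conversion (730.5 h).
#' @param coldStart start all cell ages at 0 instead of uniformly over one
#'   expected lifespan.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(seedFractions = c(NTC = 0.645, NSC = 0.065,
                                        empty = 0.29),
                      theta = 2L, moveProb = 0.25, killProb = 0.2,
                      cscProb = 2.5e-6, cscFromNormalStem = FALSE,
                      dediffProb = 1e-4, dediffStemMax = 0L,
                      dediffEmptyMin = 6L, instabilityProb = 0.45,
                      phenotypeModProb = 0.35, cellCycleHours = 10,
                      lifespanTissueHours = 250, lifespanStemHours = 25550,
                      pBar1 = 0.65, pBar2 = 14.75, alphaBar = 1.625,
                      dBar = 1.485, tacBoost = 1 / 3, carcinogenGain = 1,
                      expressionScale = 1, network = networkParams(),
                      excisionMode = "none", excisionDelayMonths = 18,
                      excisionAtStep = NA_real_, excisionRings = 2L,
                      fitnessWeights = c(wP = 1, wA = 1, wAge = 1,
                                         cancerBonus = 1),
                      hoursPerMonth = 730.5, coldStart = FALSE) {
  new("SimConfig", seedFractions = seedFractions, theta = as.integer(theta),
      moveProb = moveProb, killProb = killProb, cscProb = cscProb,
      cscFromNormalStem = cscFromNormalStem, dediffProb = dediffProb,
      dediffStemMax = as.integer(dediffStemMax),
      dediffEmptyMin = as.integer(dediffEmptyMin),
      instabilityProb = instabilityProb, phenotypeModProb = phenotypeModProb,
      cellCycleHours = cellCycleHours,
      lifespanTissueHours = lifespanTissueHours,
      lifespanStemHours = lifespanStemHours, pBar1 = pBar1, pBar2 = pBar2,
      alphaBar = alphaBar, dBar = dBar, tacBoost = tacBoost,
      carcinogenGain = carcinogenGain, expressionScale = expressionScale,
      network = network, excisionMode = excisionMode,
      excisionDelayMonths = excisionDelayMonths,
      excisionAtStep = excisionAtStep,
      excisionRings = as.integer(excisionRings),
      fitnessWeights = fitnessWeights, hoursPerMonth = hoursPerMonth,
      coldStart = coldStart)
}

#' Steps per month implied by the cell-cycle length
#' @param config a [SimConfig-class].
#' @return numeric steps per month.
#' @export
stepsPerMonth <- function(config) {
  config@hoursPerMonth / config@cellCycleHours
}

.initTable <- function(config) {
  initialPhenotypeTable(config@cellCycleHours, config@lifespanTissueHours,
                        config@lifespanStemHours, config@pBar1, config@pBar2,
                        config@alphaBar, config@dBar, config@theta)
}

#' Initialize a lattice
#'
#' Sites are seeded NTC / NSC / empty with exact-count randomized rounding,
#' so realized class fractions match the configured fractions to within one
#' lattice site. Expressions start at 0, phenotypes at the class's initial
#' row, ages uniformly over one expected lifespan (or 0 under
#' \code{coldStart}), and each non-empty cell founds a unique lineage.
#'
#' @param N lattice size.
#' @param config a [SimConfig-class].
#' @param panel a [GenePanel-class].
#' @return A [LatticeState-class] at t = 0.
#' @examples
#' st <- initGrid(16, simConfig(), hnsccPanel())
#' classFractions(st)
#' @export
initGrid <- function(N, config = simConfig(), panel = hnsccPanel()) {
  frac <- config@seedFractions
  if (abs(sum(frac) - 1) > 1e-9 || any(frac < 0))
    stop("config-error: seedFractions must be nonnegative and sum to 1")
  N2 <- N * N
  ideal <- frac * N2
  counts <- floor(ideal)
  rem <- N2 - sum(counts)
  if (rem > 0) {
    extra <- sample(3L, rem, replace = FALSE, prob = pmax(ideal - counts,
                                                          1e-12))
    counts[extra] <- counts[extra] + 1
  }
  classes <- rep(c(0L, 2L, 6L), times = counts)
  cls <- sample(classes)                        # random placement

  G <- nGenes(panel)
  tb <- .initTable(config)@table
  P <- matrix(0, N2, 4, dimnames = list(NULL, c("p", "q", "a", "d")))
  occ <- cls != 6L
  P[cls == 0L, ] <- rep(tb["NTC", ], each = sum(cls == 0L))
  P[cls == 2L, ] <- rep(tb["NSC", ], each = sum(cls == 2L))

  age <- integer(N2)
  if (!config@coldStart) {
    lifeT <- config@lifespanTissueHours / config@cellCycleHours
    lifeS <- config@lifespanStemHours / config@cellCycleHours
    age[cls == 0L] <- as.integer(floor(runif(sum(cls == 0L), 0, lifeT)))
    age[cls == 2L] <- as.integer(floor(runif(sum(cls == 2L), 0, lifeS)))
  }

  lineage <- integer(N2)
  lineage[occ] <- seq_len(sum(occ))

  new("LatticeState", N = as.integer(N), cls = matrix(cls, N, N),
      age = matrix(age, N, N),
      E = matrix(0, N2, G, dimnames = list(NULL, geneNames(panel))), P = P,
      tacFlag = matrix(0L, N, N), tacGen = matrix(0L, N, N),
      lineage = matrix(lineage, N, N), t = 0L,
      nLineages = sum(occ), geneNames = geneNames(panel))
}

#' Moore neighborhood on the torus
#'
#' The focal site plus its eight surrounding sites, with periodic wraparound.
#'
#' @param x,y 0-based lattice coordinates.
#' @param N lattice size.
#' @return 9 x 2 integer matrix of (x, y) coordinates, focal site first.
#' @export
mooreNeighborhood <- function(x, y, N) {
  d <- c(0L, -1L, 1L)
  coords <- expand.grid(dx = d, dy = d)
  cbind(x = (x + coords$dx) %% N, y = (y + coords$dy) %% N)
}

.fieldsConc <- function(fields, N, C) {
  conc <- matrix(0, N * N, max(C, 1))
  from <- to <- integer(max(C, 1))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (!identical(dim(f@concentration), c(N, N)))
      stop("config-error: field '", f@name, "' does not match lattice size")
    conc[, i] <- as.vector(f@concentration)
    from[i] <- max(as.integer(min(f@activeFrom, .Machine$integer.max)), 0L)
    to[i] <- as.integer(min(f@activeTo, .Machine$integer.max - 1))
  }
  if (!length(fields)) { from[] <- 1L; to[] <- 0L }   # never active
  list(conc = conc, activeFrom = from, activeTo = to)
}

#' Run the cellular automaton
#'
#' Advances a [LatticeState-class] by \code{steps} time-steps under the
#' eight-stage timeline: per-cell gene-network forward pass, expression
#' update, genetic instability, phenotype update, class transitions
#' (mutation status, TAC maturation, CSC conversion), dedifferentiation, one
#' sampled phenotypic action with competition and quiescent movement, and a
#' scheduled excision. Identical (state, config, seed) give bit-identical
#' trajectories.
#'
#' @param state a [LatticeState-class] (from [initGrid()] or a previous run).
#' @param panel a [GenePanel-class].
#' @param fields list of [CarcinogenField-class] objects (may be empty for a
#'   carcinogen-free run; its length must otherwise equal the panel's
#'   carcinogen count).
#' @param config a [SimConfig-class].
#' @param steps number of time-steps.
#' @param recordStride record a time-series row every this many steps.
#' @param snapshotSteps integer steps at which to capture class snapshots.
#' @param seed optional integer; when given, \code{set.seed(seed)} is called
#'   and the seed recorded in metadata.
#' @return A [SimResult-class].
#' @examples
#' set.seed(1)
#' st <- initGrid(24, simConfig(), hnsccPanel())
#' res <- runSimulation(st, hnsccPanel(), list(), simConfig(), steps = 5)
#' head(timeSeries(res))
#' @export
runSimulation <- function(state, panel, fields = list(),
                          config = simConfig(), steps,
                          recordStride = 1L, snapshotSteps = integer(0),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- nCarcinogens(panel)
  if (length(fields) && length(fields) != C)
    stop("config-error: need one field per panel carcinogen (", C, ")")
  N <- state@N
  G <- nGenes(panel)
  pr <- .relationPairs(panel)
  panelList <- list(
    T = panel@geneType, pairsI = pr$i, pairsJ = pr$j,
    WXsigns = panel@WXsigns, WY = panel@WY,
    Uinc = panel@Uinc, Dinc = panel@Dinc,
    mbar = panel@MBar, upsilon = panel@Upsilon,
    nu = config@network@nu, beta = config@network@beta,
    bernoulliP = config@network@bernoulliP, ageWeight = panel@ageWeight)
  fl <- .fieldsConc(fields, N, C)
  fl$gain <- config@carcinogenGain
  spm <- stepsPerMonth(config)
  cfgList <- list(
    expressionScale = config@expressionScale,
    instabilityProb = config@instabilityProb,
    phenotypeModProb = config@phenotypeModProb,
    cscProb = config@cscProb,
    cscFromNormalStem = config@cscFromNormalStem,
    dediffProb = config@dediffProb,
    dediffStemMax = config@dediffStemMax,
    dediffEmptyMin = config@dediffEmptyMin,
    moveProb = config@moveProb, killProb = config@killProb,
    tacBoost = config@tacBoost, theta = config@theta,
    initP = unname(.initTable(config)@table),
    wP = config@fitnessWeights[[1]], wA = config@fitnessWeights[[2]],
    wAge = config@fitnessWeights[[3]],
    cancerBonus = config@fitnessWeights[[4]],
    lifespanTissueSteps = config@lifespanTissueHours / config@cellCycleHours,
    lifespanStemSteps = config@lifespanStemHours / config@cellCycleHours,
    excisionMode = match(config@excisionMode,
                         c("none", "tumor", "field")) - 1L,
    excisionAtStep = if (is.na(config@excisionAtStep)) -1L
                     else as.integer(config@excisionAtStep),
    excisionDelaySteps = as.integer(round(config@excisionDelayMonths * spm)),
    excisionRings = config@excisionRings)

  ev0 <- list(firstMutated = -1L, firstCSC = -1L, firstTC = -1L,
              excisionStep = -1L, recurrenceStep = -1L)

  out <- .cppSimulate(as.vector(state@cls), as.vector(state@age), state@E,
                      state@P, as.vector(state@tacFlag),
                      as.vector(state@tacGen), as.vector(state@lineage),
                      N, state@t, panelList, fl, cfgList,
                      as.integer(steps), as.integer(recordStride),
                      as.integer(snapshotSteps), state@nLineages, ev0)

  final <- new("LatticeState", N = N,
               cls = matrix(out$cls, N, N), age = matrix(out$age, N, N),
               E = `dimnames<-`(out$E, list(NULL, geneNames(panel))),
               P = `dimnames<-`(out$P, list(NULL, c("p", "q", "a", "d"))),
               tacFlag = matrix(out$tacFlag, N, N),
               tacGen = matrix(out$tacGen, N, N),
               lineage = matrix(out$lineage, N, N), t = as.integer(out$t),
               nLineages = state@nLineages, geneNames = geneNames(panel))

  series <- as.data.frame(out$series)
  colnames(series) <- c("step", paste0("frac", .CLASS_NAMES), "fracMutated",
                        paste0("frac", c("Proliferation", "Quiescence",
                                         "Apoptosis", "Differentiation")),
                        paste0("meanExpr_", geneNames(panel)),
                        "fracGenesPositive", "cancerLineages")
  series$months <- series$step / spm

  ev <- lapply(out$events, function(x) if (x < 0) NA_integer_ else x)
  lineages <- .lineageSummary(final, out$lineageCount, out$lineageExtinct)
  ev$finalClonality <- classifyClonality(lineages)

  snaps <- lapply(out$snapshots, matrix, nrow = N)
  names(snaps) <- out$snapshotSteps

  meta <- list(package = "fieldCA",
               version = as.character(utils::packageVersion("fieldCA")),
               date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
               seed = seed, N = N, steps = steps,
               carcinogens = vapply(fields, function(f) f@name, character(1)),
               carcinogenGain = config@carcinogenGain,
               expressionScale = config@expressionScale,
               config = .configAsList(config))

  new("SimResult", series = series, events = ev, finalState = final,
      lineages = lineages, snapshots = snaps, metadata = meta)
}

.configAsList <- function(config) {
  nm <- slotNames(config)
  out <- lapply(nm, function(s) {
    v <- slot(config, s)
    if (is(v, "NetworkParams"))
      list(nu = v@nu, beta = v@beta, bernoulliP = v@bernoulliP)
    else v
  })
  names(out) <- nm
  out
}

.lineageSummary <- function(state, count, extinct) {
  cls <- as.vector(state@cls)
  lin <- as.vector(state@lineage)
  occ <- cls != 6L
  n <- state@nLineages
  size <- tabulate(lin[occ], nbins = n)
  mutated <- tabulate(lin[occ & cls %in% c(1L, 3L, 4L, 5L)], nbins = n)
  cancer <- tabulate(lin[occ & cls %in% c(4L, 5L)], nbins = n)
  extinctStep <- extinct[-1][seq_len(n)]       # drop slot for id 0
  extinctStep[extinctStep < 0] <- NA_integer_
  data.frame(lineage = seq_len(n), founder = seq_len(n), foundingStep = 0L,
             size = size, mutatedSize = mutated, cancerSize = cancer,
             extinctStep = extinctStep)
}

#' Excise the tumor or the whole cancer field
#'
#' \code{mode = "tumor"} empties every tumor cell and cancer stem cell plus
#' every site within a Chebyshev radius of \code{rings} of any tumor cell;
#' \code{mode = "field"} additionally empties every mutated cell.
#'
#' @param state a [LatticeState-class].
#' @param mode "tumor" or "field".
#' @param rings Chebyshev radius removed around each tumor cell.
#' @return the excised [LatticeState-class].
#' @export
excise <- function(state, mode = c("tumor", "field"), rings = 2L) {
  mode <- match.arg(mode)
  N <- state@N
  cls <- state@cls
  rm <- cls == 4L | cls == 5L
  tc <- which(cls == 5L, arr.ind = TRUE)
  if (nrow(tc)) {
    for (dy in -rings:rings) for (dx in -rings:rings) {
      rows <- (tc[, 1] - 1 + dy) %% N + 1
      colsi <- (tc[, 2] - 1 + dx) %% N + 1
      rm[cbind(rows, colsi)] <- TRUE
    }
  }
  if (mode == "field") rm <- rm | cls == 1L | cls == 3L
  idx <- which(rm)
  if (length(idx)) {
    state@cls[idx] <- 6L
    state@age[idx] <- 0L
    state@tacFlag[idx] <- 0L
    state@tacGen[idx] <- 0L
    state@lineage[idx] <- 0L
    state@E[idx, ] <- 0
    state@P[idx, ] <- 0
  }
  validObject(state)
  state
}

#' @rdname latticeAccessors
#' @param x a [LatticeState-class] or [SimResult-class].
#' @export
setMethod("gridSize", "LatticeState", function(x) x@N)

#' Lattice accessors
#'
#' @name latticeAccessors
#' @rdname latticeAccessors
#' @export
setMethod("classCounts", "LatticeState", function(x) {
  out <- tabulate(as.vector(x@cls) + 1L, nbins = 7L)
  names(out) <- .CLASS_NAMES
  out
})

#' @rdname latticeAccessors
#' @export
setMethod("classFractions", "LatticeState", function(x)
  classCounts(x) / x@N^2)

setMethod("show", "LatticeState", function(object) {
  cat("LatticeState ", object@N, " x ", object@N, " at t = ", object@t,
      "\n", sep = "")
  print(classCounts(object))
})

#' Result accessors
#'
#' @name simResultAccessors
#' @param x a [SimResult-class].
#' @rdname simResultAccessors
#' @export
setMethod("timeSeries", "SimResult", function(x) x@series)

#' @rdname simResultAccessors
#' @export
setMethod("eventRecord", "SimResult", function(x) x@events)

#' @rdname simResultAccessors
#' @export
setMethod("finalState", "SimResult", function(x) x@finalState)

#' @rdname latticeAccessors
#' @export
setMethod("gridSize", "SimResult", function(x) x@finalState@N)

#' @rdname latticeAccessors
#' @export
setMethod("classCounts", "SimResult", function(x) classCounts(x@finalState))

#' @rdname latticeAccessors
#' @export
setMethod("classFractions", "SimResult", function(x)
  classFractions(x@finalState))

setMethod("show", "SimResult", function(object) {
  s <- object@series
  cat("SimResult:", gridSize(object), "x", gridSize(object), "lattice,",
      nrow(s), paste0("recorded steps (t up to ", max(s$step), ")\n"))
  ev <- object@events
  cat("  events: first mutated =", ev$firstMutated,
      " first CSC =", ev$firstCSC, " first TC =", ev$firstTC, "\n")
  if (!is.na(ev$excisionStep))
    cat("  excision at", ev$excisionStep, " recurrence at",
        ev$recurrenceStep, "\n")
  cat("  final clonality:", ev$finalClonality, "\n")
})
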