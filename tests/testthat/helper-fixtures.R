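# Shared fixtures: a tiny synthetic three-gene panel for unit-level checks,
# the default HNSCC panel, and the calibrated configuration used by the
# simulation experiments (see the vignette for the calibration rationale).

hnscc <- hnsccPanel()

# three genes: one suppressor driven down by carcinogen 1, one oncogene
# driven up by both, one unconnected passenger regulated by the first two
tinyPanel <- function() {
  genePanel(
    list(
      list(name = "S1", type = "suppressor", carcinogenSigns = c(-1L, 0L),
           phenotypeEffects = c(proliferation = "up", apoptosis = "down"),
           activates = c(G2 = "up", P3 = "down"), relatedToAll = FALSE),
      list(name = "G2", type = "oncogene", carcinogenSigns = c(1L, 1L),
           phenotypeEffects = c(proliferation = "up"),
           activates = c(S1 = "up"), relatedToAll = FALSE),
      list(name = "P3", type = "oncogene", carcinogenSigns = c(0L, 0L),
           phenotypeEffects = character(0), activates = character(0),
           relatedToAll = FALSE)
    ),
    carcinogenNames = c("c1", "c2")
  )
}

calibratedConfig <- function(...) {
  simConfig(carcinogenGain = 1e-3, expressionScale = 5, ...)
}

bothFields <- function(N, shape = c("uniform", "gaussian"), level = 1,
                       sigma = N / 15) {
  shape <- match.arg(shape)
  conc <- if (shape == "uniform") uniformField(N, level)
          else gaussianField(N, sigma = sigma)
  list(carcinogenField("alcohol", conc), carcinogenField("smoking", conc))
}

oneField <- function(N, which = c("smoking", "alcohol"), conc = NULL) {
  which <- match.arg(which)
  if (is.null(conc)) conc <- gaussianField(N)
  zero <- uniformField(N, 0)
  list(carcinogenField("alcohol", if (which == "alcohol") conc else zero),
       carcinogenField("smoking", if (which == "smoking") conc else zero))
}

# hand-built lattice: cls is an N x N matrix of class codes; expressions,
# phenotypes and ages can be overridden per site (row index into N^2 arrays)
customState <- function(cls, panel = hnscc, config = simConfig(),
                        E = NULL, P = NULL, age = NULL, tacFlag = NULL,
                        tacGen = NULL) {
  N <- nrow(cls)
  G <- nGenes(panel)
  tb <- initialPhenotypeTable(config@cellCycleHours,
                              config@lifespanTissueHours,
                              config@lifespanStemHours, config@pBar1,
                              config@pBar2, config@alphaBar, config@dBar,
                              config@theta)@table
  v <- as.vector(cls)
  Pm <- matrix(0, N * N, 4)
  occ <- v != 6L
  Pm[occ, ] <- tb[v[occ] + 1L, ]
  if (!is.null(P)) Pm <- P
  Em <- if (is.null(E)) matrix(0, N * N, G) else E
  lin <- integer(N * N)
  lin[occ] <- seq_len(sum(occ))
  new("LatticeState", N = as.integer(N), cls = cls,
      age = if (is.null(age)) matrix(0L, N, N) else age,
      E = Em, P = Pm,
      tacFlag = if (is.null(tacFlag)) matrix(0L, N, N) else tacFlag,
      tacGen = if (is.null(tacGen)) matrix(0L, N, N) else tacGen,
      lineage = matrix(lin, N, N), t = 0L, nLineages = sum(occ),
      geneNames = geneNames(panel))
}

# phenotype override helper: same vector for every occupied site
forceP <- function(state, p) {
  occ <- as.vector(state@cls) != 6L
  state@P[occ, ] <- rep(p, each = sum(occ))
  state
}

# run in chunks until an event fires (events are absolute steps, so chunked
# runs can be stitched); returns list(state, eventStep, steps)
runUntil <- function(state, panel, fields, config, event, maxSteps,
                     chunk = 250L) {
  done <- 0L
  repeat {
    res <- runSimulation(state, panel, fields, config,
                         steps = min(chunk, maxSteps - done),
                         recordStride = chunk)
    state <- finalState(res)
    ev <- eventRecord(res)[[event]]
    done <- done + min(chunk, maxSteps - done)
    if (!is.na(ev)) return(list(state = state, eventStep = ev, steps = done))
    if (done >= maxSteps) return(list(state = state, eventStep = NA,
                                      steps = done))
  }
}
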