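test_that("positive mutation depends on direction and threshold", {
  expect_true(positivelyMutated(-0.15, 0, 0.1))    # suppressor down
  expect_true(positivelyMutated(0.15, 1, 0.1))     # oncogene up
  expect_false(positivelyMutated(0.05, 0, 0.1))
  expect_false(positivelyMutated(0.05, 1, 0.1))
  expect_false(positivelyMutated(0.15, 0, 0.1))    # wrong direction
  expect_false(positivelyMutated(-0.15, 1, 0.1))
  expect_true(positivelyMutated(-0.1, 0, 0.1))     # boundary inclusive
})

test_that("mutated-cell classification counts positive genes against Upsilon", {
  Type <- hnscc@geneType
  E <- numeric(10)
  expect_equal(countPositiveMutations(E, Type), 0L)
  E[1:3] <- -0.2; E[6] <- 0.2                      # 3 suppressors + 1 oncogene
  expect_equal(countPositiveMutations(E, Type), 4L)
  expect_true(isMutatedCell(4L, 4L))
  expect_false(isMutatedCell(3L, 4L))
})

test_that("gene instability pushes from mutated sources and repairs toward 0", {
  G <- nGenes(hnscc)
  # nothing mutated, all zero -> unchanged
  set.seed(1)
  expect_equal(geneInstabilityStep(numeric(G), hnscc), numeric(G))

  # TP53 positively mutated, pMod = 1: every related gene moves toward its
  # own cancer direction by at most cap = scale/nu
  E <- numeric(G); E[1] <- -0.15
  set.seed(2)
  E2 <- geneInstabilityStep(E, hnscc, pMod = 1, nu = 1e6, scale = 1)
  delta <- E2 - E
  expect_equal(delta[1], 0)                        # no self-modification
  dir <- ifelse(hnscc@geneType == 1L, 1, -1)
  expect_true(all(delta[-1] * dir[-1] > 0))        # TP53 relates to all
  expect_true(all(abs(delta) <= 1e-6 + 1e-18))

  # repair: TP53 mutated the protective way pulls related genes toward 0,
  # never overshooting
  E <- rep(5e-7, G); E[1] <- 0.15                  # suppressor up = protective
  set.seed(3)
  E3 <- geneInstabilityStep(E, hnscc, pMod = 1)
  expect_true(all(E3[-1] >= 0 & E3[-1] <= E[-1]))

  # unmutated genes exert no influence at all
  E <- runif(G, -0.05, 0.05)
  set.seed(4)
  expect_equal(geneInstabilityStep(E, hnscc, pMod = 1), E)
})

test_that("instability respects the per-pair probability and change cap", {
  G <- nGenes(hnscc)
  E <- numeric(G); E[1] <- -0.15
  set.seed(9)
  reps <- t(replicate(500, geneInstabilityStep(E, hnscc, pMod = 0.45) - E))
  # per-pair change magnitude never exceeds 1/nu
  expect_lte(max(abs(reps)), 1e-6)
  # acceptance frequency near pMod (each target gene has one mutated source)
  hit <- mean(reps[, 2] != 0)
  expect_lt(abs(hit - 0.45), 4 * sqrt(0.45 * 0.55 / 500))
})

test_that("phenotype updates stay on the simplex and follow the gene table", {
  P0 <- initialPhenotype(0)
  # no gene past threshold -> unchanged
  set.seed(1)
  expect_equal(phenotypeUpdate(P0, numeric(10), hnscc), unname(P0))

  # mutated TP53 with pModPh = 1: proliferation rises, apoptosis falls,
  # per-gene step magnitude 1e-6
  E <- numeric(10); E[1] <- -0.15
  set.seed(2)
  P1 <- phenotypeUpdate(P0, E, hnscc, pModPh = 1)
  # per-gene step magnitude 1e-6 up to the closing renormalization
  expect_equal(P1[1] - P0[["p"]], 1e-6, tolerance = 0.05)
  expect_equal(P1[3] - P0[["a"]], -1e-6, tolerance = 0.05)
  expect_equal(sum(P1), 1)

  # randomized property: simplex preserved under arbitrary expressions
  set.seed(3)
  for (i in 1:200) {
    P <- as.numeric(rmultinom(1, 100, c(0.1, 0.6, 0.2, 0.1))) / 100
    E <- runif(10, -0.5, 0.5)
    P2 <- phenotypeUpdate(P, E, hnscc, pModPh = runif(1))
    expect_true(all(P2 >= 0))
    expect_equal(sum(P2), 1, tolerance = 1e-12)
  }
})

test_that("initial phenotype table reproduces the published construction", {
  tb <- initialPhenotypeTable()
  expect_equal(tb@params$a1, 0.04)                     # 10/250
  expect_equal(tb@params$a2, 10 / 25550)               # ~3.914e-4
  expect_equal(tb@params$dTilde, 1 / 6)                # theta = 2
  # NTC row (p, q, a, d) with pBar1 = 0.65
  expect_equal(unname(tb@table["NTC", ]), c(0.026, 0.934, 0.04, 0))
  # mutated classes divide apoptosis by alphaBar, cancer by (5 alphaBar)^2
  expect_equal(tb@table[["MNTC", "a"]], 0.04 / 1.625)
  expect_equal(tb@table[["TC", "a"]], 0.04 / (5 * 1.625)^2)
  expect_equal(tb@table[["CSC", "a"]], (10 / 25550) / (5 * 1.625)^2)
  # stem classes carry differentiation mass dBar * dTilde
  expect_equal(tb@table[["NSC", "d"]], 1.485 / 6)
  expect_equal(tb@table[["NTC", "d"]], 0)
  expect_equal(unname(rowSums(tb@table)), rep(1, 6), tolerance = 1e-12)

  # rows telescope to 1 for any admissible parameter set
  for (i in 1:20) {
    tb2 <- initialPhenotypeTable(cellCycleHours = runif(1, 8, 24),
                                 lifespanTissueHours = runif(1, 100, 500),
                                 lifespanStemHours = runif(1, 1e4, 5e4),
                                 pBar1 = runif(1, 0.1, 2),
                                 pBar2 = runif(1, 1, 20),
                                 alphaBar = runif(1, 1, 3),
                                 dBar = runif(1, 0.5, 2),
                                 theta = sample(1:4, 1))
    expect_equal(unname(rowSums(tb2@table)), rep(1, 6), tolerance = 1e-12)
  }
  expect_error(initialPhenotype(6), "state-error")
})

test_that("phenotypic actions are sampled from the probability vector", {
  expect_equal(chooseAction(c(1, 0, 0, 0)), "proliferation")
  expect_equal(chooseAction(c(0, 0, 1, 0)), "apoptosis")
  set.seed(20)
  draws <- replicate(2000, chooseAction(c(0.3, 0.4, 0.2, 0.1)))
  f <- table(factor(draws, levels = c("proliferation", "quiescence",
                                      "apoptosis", "differentiation"))) / 2000
  expect_true(all(abs(f - c(0.3, 0.4, 0.2, 0.1)) <
                  4 * sqrt(c(0.3, 0.4, 0.2, 0.1) * 0.9 / 2000)))
})

test_that("fitness is monotone in age, apoptosis, proliferation and class", {
  cfg <- simConfig()
  young <- cellState(0L, age = 2L)
  old <- cellState(0L, age = 20L)
  expect_lt(cellFitness(old, cfg), cellFitness(young, cfg))
  # identical phenotype and age, tumor class gains the cancer bonus
  ntc <- cellState(0L, age = 5L, P = c(0.1, 0.8, 0.1, 0))
  tc <- cellState(5L, age = 5L, P = c(0.1, 0.8, 0.1, 0))
  expect_gt(cellFitness(tc, cfg), cellFitness(ntc, cfg))
  # higher proliferation wins, higher apoptosis loses
  hiP <- cellState(0L, age = 5L, P = c(0.3, 0.6, 0.1, 0))
  hiA <- cellState(0L, age = 5L, P = c(0.1, 0.6, 0.3, 0))
  expect_gt(cellFitness(hiP, cfg), cellFitness(ntc, cfg))
  expect_lt(cellFitness(hiA, cfg), cellFitness(ntc, cfg))
  # deterministic
  expect_identical(cellFitness(ntc, cfg), cellFitness(ntc, cfg))
  expect_error(cellFitness(cellState(6L, P = c(1, 0, 0, 0))), "state-error")
})
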