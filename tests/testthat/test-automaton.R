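noFields <- list()

test_that("grid seeding hits the configured composition within one site", {
  set.seed(1)
  st <- initGrid(128, simConfig(), hnscc)
  cc <- classCounts(st)
  N2 <- 128^2
  expect_true(cc["NTC"] %in% c(10567L, 10568L))        # 64.5% of 16384
  expect_true(abs(cc["NSC"] - 0.065 * N2) <= 1)
  expect_true(abs(cc["empty"] - 0.29 * N2) <= 1)
  expect_equal(sum(cc), N2)
  # only NTC / NSC / empty at t = 0
  expect_equal(unname(cc[c("MNTC", "MNSC", "CSC", "TC")]), rep(0L, 4))
  expect_true(all(st@E == 0))
  # every occupied site founds a unique lineage
  lin <- as.vector(st@lineage)[as.vector(st@cls) != 6L]
  expect_equal(sort(lin), seq_along(lin))
  # identical seed -> identical grid
  set.seed(7); a <- initGrid(32, simConfig(), hnscc)
  set.seed(7); b <- initGrid(32, simConfig(), hnscc)
  expect_identical(a@cls, b@cls)
  expect_identical(a@age, b@age)
})

test_that("moore neighborhood wraps on the torus and contains the focal cell", {
  nb <- mooreNeighborhood(0, 0, 4)
  expect_equal(nrow(nb), 9L)
  expect_true(any(nb[, "x"] == 0 & nb[, "y"] == 0))    # itself
  expect_true(any(nb[, "x"] == 3 & nb[, "y"] == 3))    # wraparound corner
  # every site appears in exactly 9 neighborhoods
  N <- 4
  hits <- matrix(0L, N, N)
  for (x in 0:(N - 1)) for (y in 0:(N - 1)) {
    nb <- mooreNeighborhood(x, y, N)
    hits[cbind(nb[, "y"] + 1, nb[, "x"] + 1)] <-
      hits[cbind(nb[, "y"] + 1, nb[, "x"] + 1)] + 1L
  }
  expect_true(all(hits == 9L))
})

test_that("site conservation and determinism hold over steps", {
  cfg <- simConfig()
  set.seed(5)
  st <- initGrid(24, cfg, hnscc)
  res <- runSimulation(st, hnscc, noFields, cfg, steps = 30)
  s <- timeSeries(res)
  fr <- as.matrix(s[, paste0("frac", c("NTC", "MNTC", "NSC", "MNSC", "CSC",
                                       "TC", "empty"))])
  expect_equal(rowSums(fr), rep(1, nrow(fr)), tolerance = 1e-12)

  run <- function() {
    set.seed(99)
    st <- initGrid(20, cfg, hnscc)
    runSimulation(st, hnscc, noFields, cfg, steps = 25)
  }
  a <- run(); b <- run()
  expect_identical(timeSeries(a), timeSeries(b))
  expect_identical(finalState(a)@cls, finalState(b)@cls)
  expect_identical(finalState(a)@E, finalState(b)@E)
})

test_that("sampled phenotypic actions follow the probability vector", {
  # all-quiescent cells never proliferate/apoptose; pure apoptosis empties
  cfg <- simConfig(moveProb = 0, dediffProb = 0)
  set.seed(2)
  st <- customState(matrix(0L, 12, 12))
  stQ <- forceP(st, c(0, 1, 0, 0))
  res <- runSimulation(stQ, hnscc, noFields, cfg, steps = 1)
  expect_equal(unname(classCounts(res)["NTC"]), 144L)
  expect_equal(timeSeries(res)$fracQuiescence[2], 1)

  stA <- forceP(st, c(0, 0, 1, 0))
  res <- runSimulation(stA, hnscc, noFields, cfg, steps = 1)
  expect_equal(unname(classCounts(res)["empty"]), 144L)

  # multinomial frequencies on stem cells (all four actions admissible)
  p <- c(0.2, 0.5, 0.2, 0.1)
  set.seed(3)
  big <- forceP(customState(matrix(2L, 60, 60)), p)
  res <- runSimulation(big, hnscc, noFields, cfg, steps = 1)
  f <- unlist(timeSeries(res)[2, paste0("frac", c("Proliferation",
        "Quiescence", "Apoptosis", "Differentiation"))])
  se <- sqrt(p * (1 - p) / 3600)
  expect_true(all(abs(f - p) < 4 * se))
})

test_that("proliferation competes by fitness and resets ages", {
  # lone proliferating cell on an empty grid always places a daughter
  cfg <- simConfig(moveProb = 0, dediffProb = 0)
  cls <- matrix(6L, 7, 7); cls[4, 4] <- 0L
  set.seed(4)
  st <- forceP(customState(cls), c(1, 0, 0, 0))
  st@age[4, 4] <- 9L
  res <- runSimulation(st, hnscc, noFields, cfg, steps = 1)
  fs <- finalState(res)
  expect_equal(unname(classCounts(fs)["NTC"]), 2L)
  expect_true(all(fs@age[fs@cls == 0L] == 1L))   # both reset, then aged once
  # daughter inherits the parent lineage
  expect_equal(unique(as.vector(fs@lineage)[as.vector(fs@cls) == 0L]), 1L)

  # normal parent facing a uniformly fitter occupied neighborhood never wins
  cls <- matrix(0L, 5, 5)
  set.seed(6)
  st <- forceP(customState(cls), c(1, 0, 0, 0))
  age <- matrix(0L, 5, 5); age[3, 3] <- 20L      # focal much older = less fit
  st@age <- age
  res <- runSimulation(st, hnscc, noFields,
                       simConfig(moveProb = 0, killProb = 0, dediffProb = 0), steps = 1)
  expect_equal(unname(classCounts(res)["NTC"]), 25L)  # no net change
})

test_that("a forced transit-amplifying lineage stays within its budget", {
  # single TAC, always proliferating, unlimited space: the clone may reach
  # at most 2^(theta+1) - 2 = 6 cells beyond the founder, and every cell
  # converts once its generation counter reaches theta
  cfg <- simConfig(moveProb = 0, dediffProb = 0)
  cls <- matrix(6L, 12, 12); cls[6, 6] <- 0L
  tf <- matrix(0L, 12, 12); tf[6, 6] <- 1L
  set.seed(8)
  st <- forceP(customState(cls, tacFlag = tf), c(1, 0, 0, 0))
  maxTac <- 0L
  for (i in 1:6) {
    res <- runSimulation(st, hnscc, noFields, cfg, steps = 1)
    st <- finalState(res)
    expect_true(all(st@tacGen <= cfg@theta))           # never past theta
    maxTac <- max(maxTac, sum(st@tacFlag == 1L))
    st <- forceP(st, c(1, 0, 0, 0))
  }
  expect_lte(maxTac, 2^(cfg@theta + 1) - 2)
  expect_equal(sum(st@tacFlag), 0L)                    # all converted
  expect_gte(sum(st@cls == 0L), 4L)                    # the amplified output
})

test_that("differentiation spawns TACs that inherit lineage and class fate", {
  cfg <- simConfig(moveProb = 0, dediffProb = 0)
  for (cl in c(2L, 3L, 4L)) {
    cls <- matrix(6L, 7, 7); cls[4, 4] <- cl
    E <- matrix(0, 49, nGenes(hnscc))
    if (cl == 3L) E[25, 1:4] <- -0.2      # keep the MNSC mutated
    set.seed(cl)
    st <- forceP(customState(cls, E = E), c(0, 0, 0, 1))
    res <- runSimulation(st, hnscc, noFields,
                         simConfig(moveProb = 0, cscProb = 0, dediffProb = 0), steps = 1)
    fs <- finalState(res)
    target <- c(`2` = 0L, `3` = 1L, `4` = 5L)[as.character(cl)]
    idx <- which(as.vector(fs@cls) == target)
    expect_length(idx, 1L)
    expect_equal(as.vector(fs@tacFlag)[idx], 1L)
    expect_equal(as.vector(fs@lineage)[idx], 1L)       # inherited
  }
})

test_that("dedifferentiation follows its neighborhood trigger", {
  # no stem cells anywhere: every tissue cell reverts when forced
  cfg <- simConfig(dediffProb = 1, moveProb = 0)
  set.seed(11)
  st <- forceP(customState(matrix(0L, 6, 6)), c(0, 1, 0, 0))
  res <- runSimulation(st, hnscc, noFields, cfg, steps = 1)
  expect_equal(unname(classCounts(res)["NSC"]), 36L)

  # a stem neighbor and a crowded neighborhood block the trigger
  cls <- matrix(0L, 3, 3); cls[1, 1] <- 2L
  set.seed(12)
  st <- forceP(customState(cls), c(0, 1, 0, 0))
  res <- runSimulation(st, hnscc, noFields, cfg, steps = 1)
  expect_equal(unname(classCounts(res)["NSC"]), 1L)    # only the original
})

test_that("stem-to-cancer conversion requires mutation by default", {
  cls <- matrix(6L, 5, 5); cls[3, 3] <- 3L
  E <- matrix(0, 25, 10); E[13, 1:4] <- -0.2
  cfg <- simConfig(cscProb = 1, moveProb = 0)
  set.seed(13)
  st <- forceP(customState(cls, E = E), c(0, 1, 0, 0))
  res <- runSimulation(st, hnscc, noFields, cfg, steps = 1)
  expect_equal(unname(classCounts(res)["CSC"]), 1L)
  expect_equal(as.vector(finalState(res)@lineage)[13], 1L)   # kept

  # unmutated stem cells convert only under the permissive flag
  cls[3, 3] <- 2L
  set.seed(14)
  st <- forceP(customState(cls), c(0, 1, 0, 0))
  res <- runSimulation(st, hnscc, noFields, cfg, steps = 1)
  expect_equal(unname(classCounts(res)["CSC"]), 0L)
  res <- runSimulation(st, hnscc, noFields,
                       simConfig(cscProb = 1, cscFromNormalStem = TRUE,
                                 moveProb = 0), steps = 1)
  expect_equal(unname(classCounts(res)["CSC"]), 1L)
})

test_that("quiescent movement conserves cells; only cancer classes displace", {
  # fully occupied normal tissue: nobody can move anywhere
  cfg <- simConfig(moveProb = 1, dediffProb = 0)
  set.seed(15)
  st <- forceP(customState(matrix(0L, 6, 6)), c(0, 1, 0, 0))
  res <- runSimulation(st, hnscc, noFields, cfg, steps = 1)
  expect_equal(unname(classCounts(res)["NTC"]), 36L)

  # a TC in a full normal neighborhood displaces at rate moveProb * killProb
  cls <- matrix(0L, 5, 5); cls[3, 3] <- 5L
  moved <- 0L
  set.seed(16)
  for (i in 1:400) {
    st <- forceP(customState(cls), c(0, 1, 0, 0))
    res <- runSimulation(st, hnscc, noFields,
                         simConfig(moveProb = 0.25, killProb = 0.2, dediffProb = 0),
                         steps = 1)
    if (unname(classCounts(res)["empty"]) == 1L) moved <- moved + 1L
  }
  rate <- moved / 400
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / 400))
})

test_that("excision removes the prescribed classes and rings", {
  cls <- matrix(0L, 12, 12)
  cls[6, 6] <- 5L          # tumor cell
  cls[2, 10] <- 4L         # distant CSC
  cls[1, 1] <- 1L          # mutated tissue far away
  cls[6, 9] <- 3L          # mutated stem just outside the 2-ring
  st <- customState(cls)

  tum <- excise(st, "tumor", rings = 2L)
  expect_equal(sum(tum@cls == 5L) + sum(tum@cls == 4L), 0L)
  expect_equal(tum@cls[1, 1], 1L)                      # field retained
  expect_equal(tum@cls[6, 9], 3L)
  # the full Chebyshev-2 block around the TC is emptied
  expect_true(all(tum@cls[4:8, 4:8] == 6L))

  fld <- excise(st, "field", rings = 2L)
  expect_true(all(fld@cls %in% c(0L, 2L, 6L)))         # only healthy left

  # excising an all-healthy grid only empties rings around nothing
  healthy <- customState(matrix(0L, 8, 8))
  same <- excise(healthy, "tumor")
  expect_identical(same@cls, healthy@cls)
})

test_that("stronger exposure does not delay the first mutated cell", {
  cfg <- calibratedConfig()
  run <- function(level) {
    set.seed(21)
    st <- initGrid(64, cfg, hnscc)
    res <- runSimulation(st, hnscc,
                         oneField(64, "smoking", uniformField(64, level)),
                         cfg, steps = 900, recordStride = 300)
    ev <- eventRecord(res)$firstMutated
    if (is.na(ev)) 901L else ev
  }
  expect_lt(run(1), run(0.25))
})
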