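test_that("recorded rows carry valid fractions and match the engine", {
  set.seed(41)
  st <- initGrid(32, simConfig(), hnscc)
  row <- recordStep(st, hnscc)
  fr <- unlist(row[paste0("frac", c("NTC", "MNTC", "NSC", "MNSC", "CSC",
                                    "TC", "empty"))])
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_equal(unname(fr[1]), unname(classFractions(st)["NTC"]))
  expect_true(abs(fr["fracNTC"] - 0.645) < 1 / 32^2 + 1e-12)
  expect_equal(row$fracMutated, 0)
  expect_equal(row$cancerLineages, 0L)

  # engine series agrees with an R-side scan of the final state
  res <- runSimulation(st, hnscc, list(), simConfig(), steps = 10)
  last <- timeSeries(res)[nrow(timeSeries(res)), ]
  scan <- recordStep(finalState(res), hnscc)
  expect_equal(last$fracNTC, scan$fracNTC)
  expect_equal(last$fracempty, scan$fracempty)
  expect_equal(last$meanExpr_TP53, scan$meanExpr_TP53)

  # all-empty grid: means flagged missing, fractions still defined
  empty <- customState(matrix(6L, 4, 4))
  row <- recordStep(empty, hnscc)
  expect_equal(row$fracMutated, 0)
  expect_true(is.na(row$meanExpr_TP53))
  expect_true(is.na(row$fracGenesPositive))
})

test_that("positively-mutated gene fraction supports both aggregations", {
  cls <- matrix(0L, 3, 3)
  st <- customState(cls)
  E <- matrix(0, 9, 10)
  E[1:5, 1] <- -0.3        # TP53 strongly down in most cells
  E[1, 6] <- 0.15          # EGFR up in one cell only
  st@E <- E
  expect_equal(fractionGenesPositive(st, hnscc, "population-mean"), 0.1)
  expect_equal(fractionGenesPositive(st, hnscc, "per-cell"),
               mean(c(rep(0.1, 5), rep(0, 4)) + c(0.1, rep(0, 8))))
})

test_that("events are detected from series and engine agree", {
  set.seed(42)
  cfg <- simConfig()
  st <- initGrid(24, cfg, hnscc)
  res <- runSimulation(st, hnscc, list(), cfg, steps = 20)
  # homeostasis run: all events missing
  ev <- detectEvents(res)
  expect_true(is.na(ev$firstMutated))
  expect_true(is.na(ev$firstCSC))
  expect_true(is.na(ev$firstTC))
  evS <- detectEvents(timeSeries(res))
  expect_true(is.na(evS$firstMutated))

  # crafted series: CSC at 7, TC at 10
  s <- data.frame(step = 0:12, fracMutated = c(rep(0, 5), rep(0.01, 8)),
                  fracCSC = c(rep(0, 7), rep(1e-4, 6)),
                  fracTC = c(rep(0, 10), rep(1e-4, 3)))
  ev <- detectEvents(s)
  expect_equal(ev$firstMutated, 5L)
  expect_equal(ev$firstCSC, 7L)
  expect_equal(ev$firstTC, 10L)
})

test_that("time series and metadata round-trip through disk", {
  set.seed(43)
  cfg <- simConfig(carcinogenGain = 1e-3, expressionScale = 5)
  st <- initGrid(16, cfg, hnscc)
  res <- runSimulation(st, hnscc, bothFields(16), cfg, steps = 5, seed = 43)
  s <- timeSeries(res)
  f <- withr::local_tempfile(fileext = ".csv")
  writeTimeSeries(s, f)
  s2 <- readTimeSeries(f)
  expect_equal(s2$step, s$step)                       # integers bit-exact
  for (cn in colnames(s))
    expect_equal(s2[[cn]], s[[cn]], tolerance = 1e-12)

  g <- withr::local_tempfile(fileext = ".json")
  writeRunMetadata(res@metadata, g)
  m <- readRunMetadata(g)
  expect_equal(m$seed, 43)
  expect_equal(m$expressionScale, 5)
  expect_equal(m$carcinogenGain, 1e-3)
  expect_equal(m$config$cscProb, 2.5e-6)
  expect_equal(m$config$seedFractions, c(0.645, 0.065, 0.29),
               ignore_attr = TRUE)
})

test_that("replicate summaries aggregate events and clonality", {
  set.seed(44)
  cfg <- simConfig()
  reps <- lapply(1:2, function(i) {
    st <- initGrid(16, cfg, hnscc)
    runSimulation(st, hnscc, list(), cfg, steps = 5, seed = 100 + i)
  })
  sm <- replicateSummary(list(control = reps))
  expect_equal(sm$nReps, 2L)
  expect_equal(sm$nNone, 2L)
  expect_equal(sm$seeds, "101;102")
  # a single replicate reproduces that replicate's record
  one <- replicateSummary(list(solo = reps[1]))
  expect_true(is.na(one$firstMutatedMedian) ||
              one$firstMutatedMedian == eventRecord(reps[[1]])$firstMutated)
})

test_that("snapshot colors follow the class color map", {
  cols <- classColors()
  expect_equal(unname(cols["TC"]), "#FF0000")
  expect_equal(unname(cols["empty"]), "#FFFFFF")
  expect_named(cols, c("NTC", "MNTC", "NSC", "MNSC", "CSC", "TC", "empty"))
  cls <- matrix(c(0L, 5L, 6L, 2L), 2, 2)
  f <- withr::local_tempfile(fileext = ".png")
  writeSnapshotPNG(cls, f)
  img <- png::readPNG(f)
  expect_equal(dim(img)[1:2], c(2L, 2L))
  expect_equal(img[1, 2, ], c(1, 1, 1))               # empty site is white
  expect_equal(img[2, 1, ], c(1, 0, 0))               # tumor cell is red
})

test_that("snapshots captured during a run match requested steps", {
  set.seed(45)
  cfg <- simConfig()
  st <- initGrid(16, cfg, hnscc)
  res <- runSimulation(st, hnscc, list(), cfg, steps = 6,
                       snapshotSteps = c(0L, 3L, 6L))
  expect_named(res@snapshots, c("0", "3", "6"))
  expect_equal(res@snapshots[["0"]], st@cls)
  expect_equal(res@snapshots[["6"]], finalState(res)@cls)
})
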