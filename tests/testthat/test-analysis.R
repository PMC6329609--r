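test_that("dominant fates: silence, detection threshold and tie-breaks", {
  net <- buildSRTwoModule(3)
  k <- simulateTissue(net, zeroMorphogenProgram(), growthSchedule(8),
                      tEnd = 5, dt = 0.01)
  expect_true(all(dominantFate(k, 5)@fates == 0L))
  expect_error(dominantFate(k, 1.234), "grid")
  # hand-set a frame: strong gene 2, exact tie between genes 1 and 3
  f <- frameIndex(k, 5)
  a1 <- SummarizedExperiment::assay(k, "g1"); a1[, f] <- 0.6
  a3 <- SummarizedExperiment::assay(k, "g3"); a3[, f] <- 0.6
  SummarizedExperiment::assay(k, "g1") <- a1
  SummarizedExperiment::assay(k, "g3") <- a3
  expect_true(all(dominantFate(k, 5, epsilonG = 0.3)@fates == 1L))
  expect_true(all(dominantFate(k, 5, epsilonG = 0.7)@fates == 0L))
})

test_that("boundary detection reads a fate pattern left to right", {
  uni <- new("FatePattern", fates = rep(2L, 6), epsilonG = 0.3, time = 0)
  expect_identical(nrow(detectBoundaries(uni)), 0L)
  pat <- new("FatePattern", fates = c(1L, 1L, 2L, 2L, 3L), epsilonG = 0.3,
             time = 0)
  b <- detectBoundaries(pat)
  expect_equal(b$position, c(2.5, 4.5))
  expect_equal(b$left, c(1L, 2L))
  expect_equal(b$right, c(2L, 3L))
  expect_identical(fateSequence(pat), c(1L, 2L, 3L))
})

test_that("steady-state detection distinguishes converged from moving tissue", {
  ff <- cachedScenario("ff_static")$kymograph
  expect_true(isSteady(ff, c(50, 60)))
  sr <- cachedScenario("sr2m_static")$kymograph
  expect_false(isSteady(sr, c(50, 60), excludeCells = 48:50))
  # a silent tissue, once its residual leak has equilibrated, is steady
  k0 <- simulateTissue(buildSRTwoModule(3), zeroMorphogenProgram(),
                       growthSchedule(8), tEnd = 40, dt = 0.01)
  expect_true(isSteady(k0, c(30, 40)))
  expect_error(isSteady(ff, c(60, 50)), "increasing")
  grown <- simulateTissue(buildSRTwoModule(3),
                          morphogenProgram("composite", xi = 5),
                          growthSchedule(8, 12, 2, 0.5), tEnd = 15, dt = 0.01)
  expect_error(isSteady(grown, c(3, 9)), "growth")
})

test_that("activation times are ordered at the pole and absent without input", {
  sr <- cachedScenario("sr2m_static")$kymograph
  on <- activationTimes(sr, 50)
  expect_true(all(!is.na(on)))
  expect_true(all(diff(on) > 0))
  k0 <- simulateTissue(buildSRTwoModule(3), zeroMorphogenProgram(),
                       growthSchedule(8), tEnd = 10, dt = 0.01)
  expect_true(all(is.na(activationTimes(k0, 4))))
  expect_error(activationTimes(sr, 999), "lineage")
})

test_that("onsets shift later with distance from the pole (kinematic waves)", {
  sr <- cachedScenario("sr2m_static")$kymograph
  for (g in geneNames(sr)) {
    on <- vapply(seq_len(nrow(sr)), function(c)
      activationTimes(sr, c)[g], numeric(1))
    on <- on[!is.na(on)]          # anterior-of-freeze cells never fire
    expect_true(all(diff(rev(on)) >= 0), info = g)
  }
})

test_that("region partition follows the morphogen and the pulse time", {
  sr <- cachedScenario("sr2m_static")$kymograph
  p1 <- partitionRegions(sr, 10)
  p2 <- partitionRegions(sr, 200)
  expect_identical(p1@activeZone, p2@activeZone)  # static gradient
  expect_identical(sort(c(p1@activeZone, p1@anterior)),
                   seq_len(nrow(sr)))
  ax <- cachedScenario("axn_rnai")$kymograph
  pa <- partitionRegions(ax, 55)
  expect_gte(length(pa@activeZone) / length(cellsAlive(ax, 55)), 0.9)
  prot <- makeReinduction(1, 100, 6, 2)
  pOn <- partitionRegions(sr, 100, prot)
  expect_identical(pOn@hsAnterior, pOn@anterior)
  expect_error(partitionRegions(sr, 50, prot), "before the pulse")
})

test_that("a zero-effect protocol classifies as restored, not re-induced", {
  net <- buildSRTwoModule(4)
  pr <- morphogenProgram("static", xi = 5)
  prot <- makeReinduction(1, 20, 6, 1e-12)
  ctrl <- simulateTissue(net, pr, growthSchedule(12), tEnd = 40, dt = 0.01)
  pert <- simulateTissue(net, pr, growthSchedule(12), tEnd = 40, dt = 0.01,
                         protocol = prot)
  rep0 <- resetAssay(pert, ctrl, prot)
  expect_false(rep0@anteriorErased)
  expect_false(rep0@sequenceReinduced)
  expect_true(rep0@finalPatternRestored)
})

test_that("proportion standard errors follow the binomial formula", {
  expect_identical(proportionSE(0.5, 16), 0.125)
  expect_equal(proportionSE(0.8, 15), 0.10328, tolerance = 1e-4)
  expect_identical(proportionSE(0, 7), 0)
  expect_identical(proportionSE(1, 7), 0)
  expect_error(proportionSE(1.2, 10), "\\[0, 1\\]")
  expect_error(proportionSE(0.5, 0), "positive")
  # maximized at p = 1/2 for fixed n
  p <- seq(0, 1, by = 0.05)
  expect_identical(p[which.max(proportionSE(p, 15))], 0.5)
})
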