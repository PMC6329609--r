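test_that("a noise-free identical ensemble gives degenerate proportions", {
  net <- buildSRTwoModule(3)
  pr <- morphogenProgram("static", xi = 5)
  ens <- simulateEnsemble(net, pr, growthSchedule(12), tEnd = 20,
                          size = 4, seed = 1, jitterSigma = 0,
                          noiseSigma = 0, dt = 0.01)
  sc <- scoreRegions(ens, windows = list(c(5, 15)))
  expect_true(all(sc$p %in% c(0, 1)))
  expect_true(all(sc$SE == 0))
  expect_true(all(sc$n == 4))
  expect_error(scoreRegions(list(), windows = list(c(5, 15))), "non-empty")
})

test_that("proportions count detecting embryos and report their SE", {
  net <- buildSRTwoModule(3)
  pr <- morphogenProgram("static", xi = 5)
  ens <- simulateEnsemble(net, pr, growthSchedule(12), tEnd = 20,
                          size = 5, seed = 1, jitterSigma = 0,
                          noiseSigma = 0, dt = 0.01)
  # silence gene 1 in two embryos: p must drop from 1 to 3/5
  for (e in 1:2) {
    a <- SummarizedExperiment::assay(ens[[e]], "g1")
    a[] <- 0
    SummarizedExperiment::assay(ens[[e]], "g1") <- a
  }
  sc <- scoreRegions(ens, windows = list(c(5, 15)))
  row <- sc[sc$region == "AZ" & sc$gene == "g1", ]
  expect_equal(row$p, 0.6)
  expect_equal(row$SE, proportionSE(0.6, 5))
})

test_that("scores are invariant to embryo relabeling", {
  net <- buildSRTwoModule(3)
  pr <- morphogenProgram("static", xi = 5)
  ens <- simulateEnsemble(net, pr, growthSchedule(12), tEnd = 20,
                          size = 5, seed = 7, dt = 0.01)
  s1 <- scoreRegions(ens, windows = list(c(5, 15)))
  s2 <- scoreRegions(rev(ens), windows = list(c(5, 15)))
  expect_equal(s1$p, s2$p)
})

test_that("ensembles are seeded and reproducible", {
  net <- buildSRTwoModule(3)
  pr <- morphogenProgram("static", xi = 5)
  e1 <- simulateEnsemble(net, pr, growthSchedule(12), tEnd = 10,
                         size = 2, seed = 42, dt = 0.01)
  e2 <- simulateEnsemble(net, pr, growthSchedule(12), tEnd = 10,
                         size = 2, seed = 42, dt = 0.01)
  expect_identical(geneMatrix(e1[[2]], 1), geneMatrix(e2[[2]], 1))
  e3 <- simulateEnsemble(net, pr, growthSchedule(12), tEnd = 10,
                         size = 2, seed = 43, dt = 0.01)
  expect_false(identical(geneMatrix(e1[[2]], 1), geneMatrix(e3[[2]], 1)))
  expect_error(simulateEnsemble(net, pr, growthSchedule(12), tEnd = 10,
                                size = 2, dt = 0.01), "seed")
})
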