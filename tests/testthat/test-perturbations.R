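test_that("protocol constructors validate their events", {
  p <- makeReinduction(1, tOn = 10, duration = 6, amplitude = 2)
  expect_s4_class(p, "PerturbationProtocol")
  expect_error(makeReinduction(1, 10, duration = -1), "positive")
  expect_error(makeRnai(1, scale = 1), "\\[0, 1\\)")
  expect_error(mergeProtocols(makeReinduction(1, 10, 6, 2),
                              makeReinduction(1, 12, 6, 2)),
               "overlap")
  expect_error(perturbationProtocol(list(list(type = "melt"))), "unknown")
})

test_that("the timer is not a valid re-induction target", {
  net <- buildFFTG(3, 30)
  pr <- morphogenProgram("static", xi = 5)
  expect_error(
    simulateTissue(net, pr, growthSchedule(10), tEnd = 20, dt = 0.01,
                   protocol = makeReinduction(4, 5, 6, 2)),
    "timer")
})

test_that("a vanishing pulse is a null perturbation", {
  net <- buildSRTwoModule(4)
  pr <- morphogenProgram("static", xi = 5)
  ctrl <- simulateTissue(net, pr, growthSchedule(12), tEnd = 20, dt = 0.01)
  tiny <- simulateTissue(net, pr, growthSchedule(12), tEnd = 20, dt = 0.01,
                         protocol = makeReinduction(1, 8, 6, 1e-12))
  for (g in 1:4)
    expect_lt(max(abs(geneMatrix(tiny, g) - geneMatrix(ctrl, g))), 1e-9)
})

test_that("clamp mode pins the concentration exactly during the window", {
  net <- buildSRTwoModule(4)
  pr <- morphogenProgram("static", xi = 5)
  k <- simulateTissue(net, pr, growthSchedule(12), tEnd = 20, dt = 0.01,
                      protocol = makeReinduction(2, 8, 4, 0.77,
                                                mode = "clamp"))
  tt <- frameTimes(k)
  inWin <- tt > 8 & tt < 12
  g2 <- geneMatrix(k, 2)
  expect_true(all(g2[, inWin] == 0.77))
  # released afterwards: decays away from the clamp value
  expect_true(all(g2[, tt >= 13] != 0.77))
})

test_that("knockdown scales production and full knockdown silences the gene", {
  net <- buildSRTwoModule(4)
  pr <- morphogenProgram("static", xi = 5)
  ctrl <- simulateTissue(net, pr, growthSchedule(12), tEnd = 40, dt = 0.01)
  near1 <- simulateTissue(net, pr, growthSchedule(12), tEnd = 40, dt = 0.01,
                          protocol = makeRnai(1, scale = 1 - 1e-12))
  expect_lt(max(abs(geneMatrix(near1, 1) - geneMatrix(ctrl, 1))), 1e-9)
  ko <- simulateTissue(net, pr, growthSchedule(12), tEnd = 40, dt = 0.01,
                       protocol = makeRnai(1, scale = 0))
  eps <- detectionThreshold(net)
  expect_lt(max(geneMatrix(ko, 1)), eps)
  # downstream onset delayed or absent relative to control
  onC <- activationTimes(ctrl, 12)["g2"]
  onK <- activationTimes(ko, 12)["g2"]
  expect_true(is.na(onK) || onK > onC)
})

test_that("protocols survive a serialization round trip", {
  p <- mergeProtocols(makeReinduction(1, 30, 6, 2),
                      makeRnai(3, 0.2, from = 5),
                      makeAxnRnai(morphogenProgram("composite", xi = 10), 100))
  q <- protocolFromParams(protocolParams(p))
  expect_identical(protocolParams(q), protocolParams(p))
})

test_that("events are local in time: pre-pulse frames are untouched", {
  net <- buildSRTwoModule(4)
  pr <- morphogenProgram("static", xi = 5)
  ctrl <- simulateTissue(net, pr, growthSchedule(12), tEnd = 20, dt = 0.01)
  pert <- simulateTissue(net, pr, growthSchedule(12), tEnd = 20, dt = 0.01,
                         protocol = makeReinduction(1, 15, 4, 2))
  tt <- frameTimes(ctrl)
  pre <- tt <= 15
  for (g in 1:4)
    expect_identical(geneMatrix(pert, g)[, pre], geneMatrix(ctrl, g)[, pre])
})

test_that("the morphogen override switches the recorded field at its onset", {
  net <- buildSRTwoModule(3)
  base <- morphogenProgram("composite", xi = 5)
  prot <- makeAxnRnai(base, tissueLength = 12, from = 10)
  k <- simulateTissue(net, base, growthSchedule(12), tEnd = 20, dt = 0.01,
                      protocol = prot)
  mor <- morphogenMatrix(k)
  d <- (12 - seq_len(12)) + 0.5
  f5 <- frameIndex(k, 5); f15 <- frameIndex(k, 15)
  expect_equal(unname(mor[, f5]),
               unname(evaluateMorphogen(base, d, rep(5, 12))),
               tolerance = 1e-12)
  ax <- axnVariant(base, 12)
  expect_equal(unname(mor[, f15]),
               unname(evaluateMorphogen(ax, d, rep(15, 12))),
               tolerance = 1e-12)
})
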