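test_that("morphogen regimes follow their closed forms", {
  st <- morphogenProgram("static", MAmp = 0.8, xi = 10)
  expect_equal(evaluateMorphogen(st, 0, 0), 0.8)
  expect_equal(evaluateMorphogen(st, 10 * log(2), 5), 0.4, tolerance = 1e-12)
  bu <- morphogenProgram("buildup", xi = 10, tauBuild = 4)
  expect_equal(evaluateMorphogen(bu, c(0, 3, 11), 0), rep(0, 3))
  expect_equal(evaluateMorphogen(bu, 0, 4), 1 - exp(-1), tolerance = 1e-12)
  de <- morphogenProgram("decaying", xi = 10, tDecayStart = 5, tauDecay = 2)
  expect_equal(evaluateMorphogen(de, 0, 3), 1)
  expect_equal(evaluateMorphogen(de, 0, 7), exp(-1), tolerance = 1e-12)
  expect_error(evaluateMorphogen(st, -1, 0), "non-negative")
  expect_error(evaluateMorphogen(st, 0, -1), "non-negative")
  expect_error(morphogenProgram("buildup", xi = 10), "tau_build")
  expect_error(morphogenProgram("nonsense"), "regime")
})

test_that("morphogen fields are monotone in space and time", {
  progs <- list(morphogenProgram("static"),
                morphogenProgram("buildup", tauBuild = 5),
                morphogenProgram("decaying", tDecayStart = 4, tauDecay = 3),
                morphogenProgram("buildup_decay", tauBuild = 5,
                                 tDecayStart = 10, tauDecay = 3),
                morphogenProgram("composite"),
                morphogenProgram("axn", xiAxn = 500))
  d <- seq(0, 60, by = 2)
  for (pr in progs) {
    for (t in c(0, 2, 8, 20)) {
      M <- evaluateMorphogen(pr, d, t)
      expect_true(all(M >= 0 & M <= pr@M_amp))
      expect_true(all(diff(M) <= 0), info = pr@regime)
    }
    tgrid <- seq(0, 30, by = 1)
    Mt <- evaluateMorphogen(pr, rep(5, length(tgrid)), tgrid)
    if (pr@regime == "decaying")
      expect_true(all(diff(Mt[tgrid >= 4]) <= 0))
    if (pr@regime == "buildup")
      expect_true(all(diff(Mt) >= 0))
  }
})

test_that("composite reduces to static while the pole is stationary", {
  co <- morphogenProgram("composite", xi = 8)
  st <- morphogenProgram("static", xi = 8)
  d <- seq(0.5, 30, by = 1)
  expect_equal(evaluateMorphogen(co, d, 7), evaluateMorphogen(st, d, 7))
  net <- buildSRTwoModule(3)
  k1 <- simulateTissue(net, co, growthSchedule(12), tEnd = 10, dt = 0.01)
  k2 <- simulateTissue(net, st, growthSchedule(12), tEnd = 10, dt = 0.01)
  expect_identical(geneMatrix(k1, 1), geneMatrix(k2, 1))
  expect_identical(morphogenMatrix(k1), morphogenMatrix(k2))
})

test_that("germ types combine gradient regime and growth as expected", {
  lg <- germTypeProgram("long", nFinal = 100, totalTime = 100)
  expect_identical(lg$schedule@n_final - lg$schedule@n0, 0L)
  expect_identical(lg$schedule@rate, 0)
  sg <- germTypeProgram("short", n0 = 50, nFinal = 100, totalTime = 100)
  expect_identical(sg$schedule@t_start, 0)
  expect_gt(sg$schedule@rate, 0)
  ig0 <- germTypeProgram("intermediate", n0 = 50, nFinal = 100,
                         totalTime = 100, blastodermTime = 0)
  expect_equal(scheduleParams(ig0$schedule), scheduleParams(sg$schedule))
  expect_equal(programParams(ig0$program)[c("regime", "xi")],
               programParams(sg$program)[c("regime", "xi")])
  expect_error(germTypeProgram("short", n0 = 50, nFinal = 40), "at least")
})

test_that("the posteriorized variant covers the whole embryo and is idempotent", {
  base <- morphogenProgram("composite", xi = 10)
  ax <- axnVariant(base, tissueLength = 100)
  expect_identical(ax@regime, "axn")
  expect_gte(ax@xi_axn, 1000)
  expect_gte(evaluateMorphogen(ax, 99.5, 50), 0.9 * ax@M_amp)
  expect_equal(evaluateMorphogen(ax, 0, 123), ax@M_amp)
  ax2 <- axnVariant(ax, tissueLength = 100)
  expect_equal(programParams(ax2), programParams(ax))
})

test_that("growth schedules validate their invariants", {
  expect_error(growthSchedule(10, 5), "n_final")
  expect_error(growthSchedule(10, 20, 0, 0), "rate = 0")
  expect_error(growthSchedule(10, 10, 0, 1), "rate = 0")
  ok <- growthSchedule(10, 20, 2, 0.5)
  expect_identical(ok@n_final, 20L)
})
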