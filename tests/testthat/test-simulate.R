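test_that("tissue initialization produces the documented shapes", {
  net <- buildFF(5)
  st <- initTissue(net, 50)
  expect_identical(dim(st), c(50L, 5L))
  expect_true(all(st == 0))
  fftg <- buildFFTG(5, 100)
  expect_identical(dim(initTissue(fftg, 50)), c(50L, 6L))
  cust <- matrix(0, 10, 5); cust[3, 1] <- 1
  k <- simulateTissue(buildFF(5), zeroMorphogenProgram(), growthSchedule(10),
                      tEnd = 1, dt = 0.01,
                      init = initTissue(net, 10, "custom", cust))
  expect_identical(geneMatrix(k, 1)[3, 1], 1)
  expect_error(initTissue(net, 10, "custom", matrix(0, 10, 4)), "matrix")
})

test_that("without morphogen a naive tissue stays silent", {
  pr <- zeroMorphogenProgram()
  for (net in list(buildFF(5), buildFFTG(5, 30), buildSRTwoModule(5),
                   buildSRDecayMod(5))) {
    k <- simulateTissue(net, pr, growthSchedule(20), tEnd = 30, dt = 0.01)
    mx <- max(vapply(geneNames(k), function(g)
      max(geneMatrix(k, g)), numeric(1)))
    expect_lt(mx, 1e-3)
  }
})

test_that("cells are autonomous: tissue run equals per-cell integration", {
  # growing tissue; each lineage re-integrated alone against the morphogen
  # course implied by its distance-from-pole history
  net <- buildSRTwoModule(5)
  gp <- germTypeProgram("intermediate", n0 = 10, nFinal = 20, totalTime = 30,
                        blastodermTime = 4, xi = 4)
  dt <- 0.005
  kym <- simulateTissue(net, gp$program, gp$schedule, tEnd = 30, dt = dt)
  birth <- birthTimes(kym)
  sch <- gp$schedule
  nAliveAt <- function(t)
    sch@n0 + sum(birth[birth > 0] <= t + 1e-12)
  worst <- 0
  for (c in seq_len(nrow(kym))) {
    b <- birth[c]
    dFun <- function(t) nAliveAt(t + b) - c + 0.5
    tr <- integrateCell(net, list(program = gp$program, distance = dFun),
                        tEnd = 30 - b, dt = dt)
    tt <- frameTimes(kym)
    sel <- which(tt >= b - 1e-9)
    for (g in seq_len(5)) {
      ref <- geneMatrix(kym, g)[c, sel]
      worst <- max(worst, max(abs(tr[seq_along(sel), g] - ref)))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("the integrator is fourth-order accurate", {
  net <- buildSRTwoModule(5)
  a <- integrateCell(net, 0.6, tEnd = 20, dt = 0.01)
  b <- integrateCell(net, 0.6, tEnd = 20, dt = 0.005)
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("a constant-morphogen French Flag cell reaches a genuine fixed point", {
  net <- buildFF(5)
  tr <- integrateCell(net, 0.45, tEnd = 50, dt = 0.005)
  gEnd <- tr[nrow(tr), ]
  expect_lt(max(abs(derivative(net, gEnd, 0.45))), 1e-8)
  tr10 <- integrateCell(net, 0.45, tEnd = 500, dt = 0.005)
  expect_lt(max(abs(tr10[nrow(tr10), ] - gEnd)), 1e-8)
  # starting at the fixed point, the trajectory stays there
  tr2 <- integrateCell(net, 0.45, g0 = gEnd, tEnd = 5, dt = 0.005)
  expect_lt(max(abs(sweep(tr2, 2, gEnd))), 1e-9)
})

test_that("simulations are bit-for-bit deterministic", {
  net <- buildSRTwoModule(4)
  pr <- morphogenProgram("static", xi = 5)
  k1 <- simulateTissue(net, pr, growthSchedule(15, 20, 2, 1), tEnd = 15,
                       dt = 0.005)
  k2 <- simulateTissue(net, pr, growthSchedule(15, 20, 2, 1), tEnd = 15,
                       dt = 0.005)
  for (g in c(geneNames(k1), "morphogen"))
    expect_identical(SummarizedExperiment::assay(k1, g),
                     SummarizedExperiment::assay(k2, g))
})

test_that("growth appends naive posterior cells with consistent bookkeeping", {
  net <- buildSRTwoModule(3)
  pr <- morphogenProgram("composite", xi = 5)
  k <- simulateTissue(net, pr, growthSchedule(10, 18, 3, 0.5), tEnd = 25,
                      dt = 0.01)
  birth <- birthTimes(k)
  expect_identical(birth[1:10], rep(0, 10))
  expect_equal(birth[11:18], 3 + (1:8) * 2, tolerance = 1e-9)
  expect_false(is.unsorted(birth))
  # once born, present in every later frame; absent before
  mor <- morphogenMatrix(k)
  tt <- frameTimes(k)
  for (c in c(11, 15, 18)) {
    expect_true(all(is.na(mor[c, tt < birth[c] - 1e-9])))
    expect_true(all(!is.na(mor[c, tt >= birth[c] - 1e-9])))
  }
  expect_identical(anyDuplicated(rownames(k)), 0L)
  # recorded morphogen matches the program evaluated at the live geometry
  f <- frameIndex(k, 20)
  alive <- cellsAlive(k, 20)
  d <- (length(alive) - alive) + 0.5
  expect_equal(unname(mor[alive, f]),
               unname(evaluateMorphogen(pr, d, rep(20, length(alive)))),
               tolerance = 1e-12)
})

test_that("an independent stiff solver reproduces the trajectories", {
  skip_if_not_installed("deSolve")
  net <- buildSRTwoModule(5)
  rhs <- function(t, y, parms) list(derivative(net, y, 0.7))
  sol <- deSolve::lsoda(rep(0, 5), seq(0, 20, by = 0.5), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  mine <- integrateCell(net, 0.7, tEnd = 20, dt = 0.005)
  sel <- seq(1, 201, by = 5)   # every 0.5 time units
  expect_lt(max(abs(mine[sel, ] - sol[, -1])), 1e-6)
})

test_that("invalid grids and diverging states raise errors", {
  net <- buildFF(3)
  pr <- morphogenProgram("static", xi = 5)
  expect_error(simulateTissue(net, pr, growthSchedule(5), tEnd = 10,
                              dt = 0.3, dtOut = 0.1), "dt <= dtOut")
  expect_error(simulateTissue(net, pr, growthSchedule(5), tEnd = 10,
                              dt = 0.03, dtOut = 0.1), "multiple")
  init <- matrix(2e6, 5, 3)
  expect_error(simulateTissue(net, pr, growthSchedule(5), tEnd = 1,
                              dt = 0.01, init = init), "instability")
})
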