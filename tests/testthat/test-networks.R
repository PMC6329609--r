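test_that("regulatory response is a proper sigmoid", {
  expect_equal(regulatoryResponse(0, 20), 0.5)
  expect_equal(regulatoryResponse(1e6, 20), 1, tolerance = 1e-12)
  expect_equal(regulatoryResponse(-1e6, 20), 0, tolerance = 1e-12)
  u <- seq(-2, 2, by = 0.25)
  expect_equal(regulatoryResponse(-u, 7), 1 - regulatoryResponse(u, 7))
  expect_true(all(diff(regulatoryResponse(u, 20)) > 0))
  expect_error(regulatoryResponse(NaN, 20), "finite")
  expect_error(regulatoryResponse(Inf, 20), "finite")
  expect_error(regulatoryResponse(0, -1), "positive")
})

test_that("French Flag builder encodes graded activation and one-way repression", {
  net <- buildFF(3)
  expect_identical(netFamily(net), "FF")
  expect_true(all(diff(net@rho) < 0))
  expect_lt(net@W_dyn[1, 3], 0)
  expect_identical(net@W_dyn[3, 1], 0)
  expect_true(all(net@W_dyn[lower.tri(net@W_dyn, diag = TRUE)] == 0))
  net1 <- buildFF(1)
  expect_identical(dim(net1@W_dyn), c(1L, 1L))
  expect_identical(net1@W_dyn[1, 1], 0)
  expect_error(buildFF(0), ">= 1")
  expect_error(buildFF(3, params = list(theta = -1)), "positive")
  expect_error(buildFF(3, params = list(bogus = 1)), "unknown")
})

test_that("FF steady dominant fate is a non-decreasing staircase in M", {
  # fixed-point scan: long single-cell integration at each morphogen level
  net <- buildFF(5)
  eps <- detectionThreshold(net)
  dom <- vapply(seq(0, 1, by = 0.05), function(M) {
    g <- integrateCell(net, M, tEnd = 60, dt = 0.005)
    gf <- g[nrow(g), ]
    if (max(gf) < eps) 0L else which.max(gf)
  }, integer(1))
  expect_false(is.unsorted(dom))
  expect_identical(dom[1], 0L)
  expect_identical(dom[length(dom)], 5L)
})

test_that("FF long-run state is independent of small random initialization", {
  net <- buildFF(5)
  set.seed(11)
  for (M in c(0.18, 0.35, 0.7)) {
    a <- integrateCell(net, M, tEnd = 60, dt = 0.005)
    b <- integrateCell(net, M, g0 = runif(5, 0, 0.01), tEnd = 60, dt = 0.005)
    expect_lt(max(abs(a[nrow(a), ] - b[nrow(b), ])), 1e-8)
  }
})

test_that("timer gene integrates morphogen exposure", {
  net <- buildFFTG(5, tEndScenario = 100)
  expect_identical(nStates(net), 6L)
  expect_identical(net@geneNames[6], "timer")
  # no morphogen, no decay: timer constant
  tr <- integrateCell(net, 0, g0 = c(rep(0, 5), 0.37), tEnd = 5, dt = 0.01)
  expect_equal(unname(tr[, "timer"]), rep(0.37, nrow(tr)), tolerance = 1e-12)
  # constant morphogen: exactly linear accumulation
  tr <- integrateCell(net, 0.6, tEnd = 10, dt = 0.01)
  tgrid <- seq(0, 10, by = 0.1)
  expect_equal(unname(tr[, "timer"]), net@timer$kappa * 0.6 * tgrid,
               tolerance = 1e-10)
})

test_that("two-module cascade activates sequentially and locks fates", {
  net <- buildSRTwoModule(5)
  lvl <- halfMaxLevel(net)
  for (m in c(1, 0.5, 0.25)) {
    tr <- integrateCell(net, m, tEnd = 120, dt = 0.005)
    on <- onsetsFromTrajectory(tr, lvl)
    expect_true(all(!is.na(on)), info = paste("m =", m))
    expect_true(all(diff(on) > 0), info = paste("m =", m))
  }
  # multistability at m = 0: any single-high state persists
  for (k in 1:5) {
    g0 <- rep(0, 5); g0[k] <- 1
    fin <- integrateCell(net, 0, g0 = g0, tEnd = 80, dt = 0.005)
    fin <- fin[nrow(fin), ]
    expect_gt(fin[k], detectionThreshold(net))
    expect_lt(max(fin[-k]), 1e-3)
  }
  # the naive all-off state is stable
  fin <- integrateCell(net, 0, tEnd = 80, dt = 0.005)
  expect_lt(max(fin[nrow(fin), ]), 1e-3)
  expect_error(buildSRTwoModule(1), "at least 2")
})

test_that("decay-modulation dynamics freeze completely without morphogen", {
  net <- buildSRDecayMod(5)
  expect_identical(unname(derivative(net, runif(5), 0)), rep(0, 5))
  g0 <- c(0.3, 0.8, 0.1, 0, 0.5)
  tr <- integrateCell(net, 0, g0 = g0, tEnd = 20, dt = 0.01)
  expect_equal(unname(tr[nrow(tr), ]), g0, tolerance = 1e-12)
  expect_error(buildSRDecayMod(1), "at least 2")
})

test_that("morphogen level is a pure clock multiplier for decay modulation", {
  # time-rescaling oracle: g(t; m) must equal g(m t; 1)
  net <- buildSRDecayMod(5)
  ref <- integrateCell(net, 1, tEnd = 40, dt = 0.002)      # dtOut = 0.1
  for (m in c(0.25, 0.5, 0.75)) {
    tr <- integrateCell(net, m, tEnd = 40, dt = 0.002, dtOut = 0.4)
    k <- 0:100
    expect_lt(max(abs(tr[k + 1, ] - ref[1 + k * m * 4, ])), 1e-4)
  }
})

test_that("speed-regulated onsets get earlier, not later, with morphogen", {
  net <- buildSRTwoModule(5)
  lvl <- halfMaxLevel(net)
  grid <- c(0.25, 0.4, 0.6, 0.8, 1)
  ons <- sapply(grid, function(m)
    onsetsFromTrajectory(integrateCell(net, m, tEnd = 120, dt = 0.005), lvl))
  for (g in 1:5)
    expect_true(all(diff(ons[g, ]) <= 1e-9),
                info = paste("gene", g, "onset not non-increasing in m"))
})

test_that("derivative matches the trajectory's finite differences", {
  nets <- list(buildFF(4), buildFFTG(4, 50), buildSRTwoModule(4),
               buildSRDecayMod(4))
  for (net in nets) {
    M <- 0.6
    tr <- integrateCell(net, M, tEnd = 2, dt = 1e-4, dtOut = 1e-4)
    i <- 5001  # t = 0.5
    fd <- (tr[i + 1, ] - tr[i - 1, ]) / (2e-4)
    expect_equal(unname(derivative(net, tr[i, ], M)), unname(fd),
                 tolerance = 1e-5)
  }
})

test_that("derivative rejects malformed input", {
  net <- buildSRTwoModule(3)
  expect_error(derivative(net, rep(0, 4), 0.5), "length")
  expect_error(derivative(net, c(0, NA, 0), 0.5), "finite")
  expect_error(derivative(net, rep(0, 3), -0.1), "non-negative")
})

test_that("class validity enforces the family contracts", {
  net <- buildSRTwoModule(3)
  bad <- net; bad@W_stat <- NULL
  expect_error(validObject(bad), "static")
  bad <- net; bad@lam0 <- c(-1, 0.2, 0.2)
  expect_error(validObject(bad), "decay")
  ff <- buildFF(3)
  bad <- ff; bad@rho <- c(1, 2, 3)
  expect_error(validObject(bad), "decreasing")
  srdm <- buildSRDecayMod(3)
  bad <- srdm; bad@lam1 <- rep(0, 3)
  expect_error(validObject(bad), "lam1")
})
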