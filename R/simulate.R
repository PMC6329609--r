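#' @include networks.R morphogen.R
NULL

#' Initialize a tissue state
#'
#' @param network a [GeneNetwork-class].
#' @param n0 number of cells (>= 1).
#' @param init `"zero"` (all concentrations 0) or `"custom"`.
#' @param state for `init = "custom"`: an `n0 x nStates(network)` matrix.
#' @return Numeric matrix of per-cell state vectors, cells in rows
#'   (anterior to posterior), usable as the `init` argument of
#'   [simulateTissue()].
#' @export
initTissue <- function(network, n0, init = c("zero", "custom"), state = NULL) {
  init <- match.arg(init)
  if (!is.numeric(n0) || n0 < 1) stop("n0 must be >= 1")
  ns <- nStates(network)
  if (init == "zero") {
    m <- matrix(0, as.integer(n0), ns)
  } else {
    if (is.null(state) || !is.matrix(state) ||
        !all(dim(state) == c(n0, ns)))
      stop("custom state must be an n0 x ", ns, " matrix")
    m <- state
  }
  colnames(m) <- network@geneNames
  m
}

.checkGrid <- function(dt, dtOut, tEnd) {
  if (dt <= 0 || dtOut <= 0 || tEnd <= 0) stop("dt, dtOut, tEnd must be > 0")
  if (dt > dtOut || dtOut > tEnd) stop("need dt <= dtOut <= tEnd")
  if (abs(dtOut / dt - round(dtOut / dt)) > 1e-8)
    stop("dtOut must be an integer multiple of dt")
  if (abs(tEnd / dtOut - round(tEnd / dtOut)) > 1e-8)
    stop("tEnd must be an integer multiple of dtOut")
}

.protocolMatrices <- function(protocol, network, tEnd) {
  reinduce <- matrix(0, 0, 5)
  rnai <- matrix(0, 0, 3)
  override <- NULL
  tOverride <- -1
  if (!is.null(protocol)) {
    stopifnot(is(protocol, "PerturbationProtocol"))
    n <- nGenes(network)
    for (ev in protocol@events) {
      if (ev$type == "reinduce") {
        if (ev$gene < 1 || ev$gene > n)
          stop("re-induction target must be a fate gene (1..", n,
               "); the timer is not a fate gene")
        if (ev$t_on < 0 || ev$t_off > tEnd)
          stop("protocol event outside [0, tEnd]")
        reinduce <- rbind(reinduce,
          c(ev$gene, ev$t_on, ev$t_off, ev$amplitude,
            ifelse(ev$mode == "clamp", 1, 0)))
      } else if (ev$type == "rnai") {
        if (ev$gene < 1 || ev$gene > n) stop("rnai target must be a fate gene")
        if (ev$from < 0 || ev$from > tEnd)
          stop("protocol event outside [0, tEnd]")
        rnai <- rbind(rnai, c(ev$gene, ev$scale, ev$from))
      } else if (ev$type == "morphogen_override") {
        if (!is.null(override)) stop("at most one morphogen override")
        if (ev$from < 0 || ev$from > tEnd)
          stop("protocol event outside [0, tEnd]")
        override <- ev$program
        tOverride <- ev$from
      }
    }
  }
  list(reinduce = reinduce, rnai = rnai, override = override,
       tOverride = tOverride)
}

#' Simulate a 1-D tissue of autonomous cells
#'
#' Integrates every cell's family-specific ODE under its local morphogen
#' concentration with a deterministic fixed-step fourth-order Runge-Kutta
#' scheme. Cells are autonomous (no spatial coupling); their only spatial
#' input is the morphogen evaluated at their current distance from the
#' posterior pole, `(n_alive - cell index) - 0.5` in cell units. Growth
#' appends naive all-zero cells at the posterior, aligned to integration
#' step boundaries; protocol events modify production terms, pin
#' concentrations, or replace the morphogen program at their stated times.
#'
#' @param network a [GeneNetwork-class].
#' @param program a [MorphogenProgram-class].
#' @param schedule a [GrowthSchedule-class].
#' @param tEnd simulation end time.
#' @param dt integration step (default 0.001 time units).
#' @param dtOut output frame spacing (default 0.1; integer multiple of `dt`).
#' @param protocol optional [PerturbationProtocol-class].
#' @param init optional initial state matrix from [initTissue()]; defaults
#'   to all-zero.
#' @param seed recorded in the metadata for provenance (the core is
#'   noise-free).
#' @return A [Kymograph-class].
#' @examples
#' net <- buildSRTwoModule(3)
#' kym <- simulateTissue(net, morphogenProgram("static", xi = 4),
#'                       growthSchedule(20), tEnd = 30, dt = 0.01)
#' dim(kym)
#' @export
simulateTissue <- function(network, program, schedule, tEnd,
                           dt = 0.001, dtOut = 0.1, protocol = NULL,
                           init = NULL, seed = NA_integer_) {
  stopifnot(is(network, "GeneNetwork"), is(program, "MorphogenProgram"),
            is(schedule, "GrowthSchedule"))
  .checkGrid(dt, dtOut, tEnd)
  ns <- nStates(network)
  if (is.null(init)) init <- initTissue(network, schedule@n0)
  if (!all(dim(init) == c(schedule@n0, ns)))
    stop("init must be an n0 x ", ns, " matrix")
  pm <- .protocolMatrices(protocol, network, tEnd)
  out <- .simulateCore(.netToCore(network), .progToCore(program),
                       if (is.null(pm$override)) NULL
                       else .progToCore(pm$override),
                       pm$tOverride,
                       schedule@n0, schedule@n_final, schedule@t_start,
                       schedule@rate, pm$reinduce, pm$rnai,
                       tEnd, dt, dtOut, init)
  .makeKymograph(out, network, program, schedule, protocol,
                 dt, dtOut, tEnd, seed)
}

#' Integrate a single cell
#'
#' Single-cell counterpart of [simulateTissue()], against an arbitrary
#' morphogen time course: a constant, a function of time, or a
#' [MorphogenProgram-class] evaluated at a fixed (or time-varying) distance
#' from the pole. Used as the per-cell oracle for fixed-point scans and
#' cell-autonomy checks.
#'
#' @param network a [GeneNetwork-class].
#' @param M a single number, a function `M(t)`, or a list
#'   `list(program =, distance =)` where `distance` is a number or a
#'   function of time giving the cell's distance from the posterior pole.
#'   A distance function is sampled at integration-step starts and held
#'   fixed over each step, exactly as the tissue engine treats a cell's
#'   geometry, so growing-tissue runs can be reproduced cell by cell.
#' @param g0 initial state (default all-zero).
#' @param tEnd,dt,dtOut as in [simulateTissue()].
#' @return Numeric matrix: one row per output frame (times in `rownames`),
#'   one column per state variable.
#' @export
integrateCell <- function(network, M, g0 = NULL, tEnd = 50,
                          dt = 0.001, dtOut = 0.1) {
  .checkGrid(dt, dtOut, tEnd)
  ns <- nStates(network)
  if (is.null(g0)) g0 <- rep(0, ns)
  if (length(g0) != ns) stop("g0 must have length ", ns)
  nSteps <- round(tEnd / dt)
  tGrid <- seq(0, tEnd, by = dt / 2)
  Mgrid <- if (is.numeric(M) && length(M) == 1) {
    rep(M, length(tGrid))
  } else if (is.function(M)) {
    vapply(tGrid, M, numeric(1))
  } else if (is.list(M) && !is.null(M$program)) {
    d <- M$distance
    if (is.function(d)) {
      # mirror the tissue engine: the distance from the pole is sampled at
      # each step start and held fixed across the step's three stage times
      t0 <- (seq_len(nSteps) - 1) * dt
      dStep <- vapply(t0, d, numeric(1))
      stages <- c(t(cbind(t0, t0 + dt / 2, t0 + dt)))
      evaluateMorphogen(M$program, rep(dStep, each = 3), stages)
    } else {
      evaluateMorphogen(M$program, rep(d, length(tGrid)), tGrid)
    }
  } else stop("M must be a number, a function of time, or list(program, distance)")
  if (any(Mgrid < 0)) stop("morphogen time course must be non-negative")
  out <- .integrateCellCore(.netToCore(network), Mgrid, g0, tEnd, dt, dtOut)
  rownames(out) <- format(seq(0, tEnd, by = dtOut), trim = TRUE)
  colnames(out) <- network@geneNames
  out
}
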