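#' @include perturbations.R
NULL

.defaultEpsG <- function(kym) {
  np <- S4Vectors::metadata(kym)$network
  0.3 * max(np$R / (np$lam0 + np$lam1))
}

.defaultHalfMax <- function(kym) {
  np <- S4Vectors::metadata(kym)$network
  0.5 * max(np$R / (np$lam0 + np$lam1))
}

.defaultEpsM <- function(kym) 0.1 * S4Vectors::metadata(kym)$network$M_max

.geneArray <- function(kym) {
  # lineages x frames x fate genes
  gn <- geneNames(kym)
  arr <- array(NA_real_, c(nrow(kym), ncol(kym), length(gn)),
               dimnames = list(rownames(kym), NULL, gn))
  for (k in seq_along(gn))
    arr[, , k] <- SummarizedExperiment::assay(kym, gn[k])
  arr
}

#' Dominant fate of each cell at a time point
#'
#' Per cell, the fate-gene index (the FFTG timer is excluded) with the
#' highest concentration, provided it reaches the detection threshold;
#' otherwise `0` ("none"). Ties break toward the lower gene index. Cells
#' not yet born are `NA`.
#'
#' @param kym a [Kymograph-class].
#' @param t a time on the output grid.
#' @param epsilonG detection threshold; defaults to 30% of the maximal
#'   attainable concentration.
#' @return A [FatePattern-class].
#' @export
dominantFate <- function(kym, t, epsilonG = NULL) {
  if (is.null(epsilonG)) epsilonG <- .defaultEpsG(kym)
  f <- frameIndex(kym, t)
  gn <- geneNames(kym)
  mat <- vapply(gn, function(g) geneMatrix(kym, g)[, f],
                numeric(nrow(kym)))
  fates <- apply(mat, 1, function(x) {
    if (all(is.na(x))) return(NA_integer_)
    if (max(x) < epsilonG) 0L else which.max(x)
  })
  new("FatePattern", fates = as.integer(fates), epsilonG = epsilonG,
      time = t)
}

#' Boundaries between adjacent fate domains
#'
#' @param pattern a [FatePattern-class].
#' @return Data frame with one row per boundary: `position` (half-integer
#'   between the two cells, anterior to posterior), `left`, `right` fates
#'   (0 = none). Unborn cells are skipped.
#' @export
detectBoundaries <- function(pattern) {
  f <- pattern@fates[!is.na(pattern@fates)]
  idx <- which(!is.na(pattern@fates))
  if (length(f) < 2)
    return(data.frame(position = numeric(0), left = integer(0),
                      right = integer(0)))
  ch <- which(diff(f) != 0)
  data.frame(position = idx[ch] + 0.5, left = f[ch], right = f[ch + 1])
}

#' Ordered sequence of distinct fates, anterior to posterior
#'
#' Collapses a fate pattern to its run-length sequence, dropping "none"
#' and unborn cells -- the object compared across germ-type scenarios.
#'
#' @param pattern a [FatePattern-class].
#' @return Integer vector of fates in anterior-to-posterior order.
#' @export
fateSequence <- function(pattern) {
  f <- pattern@fates[!is.na(pattern@fates) & pattern@fates != 0L]
  if (!length(f)) return(integer(0))
  rle(f)$values
}

#' Has the tissue reached a steady state over a time window?
#'
#' True if and only if the maximum over cells, fate genes and consecutive
#' frame pairs in the window of `|g(t + dt_out) - g(t)| / dt_out` is below
#' `tol`. Windows containing growth events are ill-defined (the comparison
#' would mix cell sets) and are an error. The FFTG timer, which grows
#' without bound under a sustained gradient by construction, is excluded.
#'
#' @param kym a [Kymograph-class].
#' @param window `c(t1, t2)` inside the run.
#' @param tol rate tolerance (default 1e-6 concentration per time unit).
#' @param excludeCells lineage indices to ignore (e.g. the few posterior
#'   cells that sit in the absorbing terminal state).
#' @return Logical scalar.
#' @export
isSteady <- function(kym, window, tol = 1e-6, excludeCells = integer()) {
  tt <- frameTimes(kym)
  if (window[1] >= window[2]) stop("window must be increasing")
  if (window[1] < min(tt) - 1e-9 || window[2] > max(tt) + 1e-9)
    stop("window must lie inside the run")
  birth <- birthTimes(kym)
  if (any(birth > window[1] + 1e-9 & birth <= window[2] + 1e-9))
    stop("window contains growth events; steadiness is ill-defined there")
  sel <- which(tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9)
  if (length(sel) < 2) stop("window must span at least two frames")
  cells <- setdiff(which(birth <= window[1] + 1e-9), excludeCells)
  dtOut <- tt[2] - tt[1]
  rate <- 0
  for (g in geneNames(kym)) {
    m <- geneMatrix(kym, g)[cells, sel, drop = FALSE]
    rate <- max(rate, max(abs(m[, -1, drop = FALSE] -
                              m[, -ncol(m), drop = FALSE])) / dtOut)
  }
  rate < tol
}

#' Maximum rate of change over a window
#'
#' The quantity [isSteady()] thresholds, useful for convergence-time scans.
#' @inheritParams isSteady
#' @return Numeric scalar, max |dg/dt| over cells, fate genes, frames.
#' @export
maxRate <- function(kym, window, excludeCells = integer()) {
  tt <- frameTimes(kym)
  sel <- which(tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9)
  birth <- birthTimes(kym)
  cells <- setdiff(which(birth <= window[1] + 1e-9), excludeCells)
  dtOut <- tt[2] - tt[1]
  rate <- 0
  for (g in geneNames(kym)) {
    m <- geneMatrix(kym, g)[cells, sel, drop = FALSE]
    rate <- max(rate, max(abs(m[, -1, drop = FALSE] -
                              m[, -ncol(m), drop = FALSE]), na.rm = TRUE) / dtOut)
  }
  rate
}

#' Gene activation (onset) times of one lineage
#'
#' The first output frame at which each fate gene's concentration reaches
#' the onset level, coming from below (an upward crossing); `NA` if never
#' reached. Onsets are reported at output-frame resolution.
#'
#' @param kym a [Kymograph-class].
#' @param lineage lineage index or id.
#' @param level onset level; defaults to half-maximal expression.
#' @param after only count crossings at `t > after` (default: from birth).
#' @return Named numeric vector of onset times (`NA` = never crossed).
#' @export
activationTimes <- function(kym, lineage, level = NULL, after = -Inf) {
  if (is.character(lineage)) lineage <- match(lineage, rownames(kym))
  if (is.na(lineage) || lineage < 1 || lineage > nrow(kym))
    stop("no such lineage")
  if (is.null(level)) level <- .defaultHalfMax(kym)
  tt <- frameTimes(kym)
  gn <- geneNames(kym)
  out <- stats::setNames(rep(NA_real_, length(gn)), gn)
  for (g in gn) {
    x <- geneMatrix(kym, g)[lineage, ]
    above <- !is.na(x) & x >= level
    prevBelow <- c(TRUE, !above[-length(above)] | is.na(x[-length(x)]))
    hit <- which(above & prevBelow & tt > after)
    if (length(hit)) out[g] <- tt[hit[1]]
  }
  out
}

#' Partition cells into active zone, anterior, and heat-shock anterior
#'
#' The active zone is the set of born cells whose recorded local morphogen
#' is at least `epsilonM` at the query time (the caudal-expressing zone);
#' the anterior is every other born cell; the heat-shock anterior is the
#' anterior as of the protocol's pulse-onset time, tracked by lineage.
#'
#' @param kym a [Kymograph-class].
#' @param t query time on the output grid.
#' @param protocol optional [PerturbationProtocol-class] with a
#'   re-induction event; without one the heat-shock anterior is empty.
#' @param epsilonM morphogen threshold (default 10% of the pole amplitude).
#' @return A [RegionPartition-class].
#' @export
partitionRegions <- function(kym, t, protocol = NULL, epsilonM = NULL) {
  if (is.null(epsilonM)) epsilonM <- .defaultEpsM(kym)
  f <- frameIndex(kym, t)
  mor <- morphogenMatrix(kym)
  born <- which(!is.na(mor[, f]))
  az <- born[mor[born, f] >= epsilonM]
  ant <- setdiff(born, az)
  tOn <- NA_real_
  hs <- integer(0)
  if (!is.null(protocol)) {
    w <- reinductionWindow(protocol)
    tOn <- unname(w["t_on"])
    if (t < tOn - 1e-9)
      stop("heat-shock anterior is undefined before the pulse onset")
    f0 <- frameIndex(kym, .snapToGrid(kym, tOn))
    born0 <- which(!is.na(mor[, f0]))
    hs <- born0[mor[born0, f0] < epsilonM]
  }
  new("RegionPartition", activeZone = as.integer(az),
      anterior = as.integer(ant), hsAnterior = as.integer(hs),
      time = t, tOn = tOn, epsilonM = epsilonM)
}

.snapToGrid <- function(kym, t) {
  tt <- frameTimes(kym)
  tt[which.min(abs(tt - t))]
}

#' Re-induction reset assay
#'
#' Compares a perturbed run (transient ubiquitous re-induction of the
#' leading gene) against its control to classify the patterning mechanism:
#'
#' \describe{
#'   \item{anteriorErased}{at the erasure horizon (pulse end plus two decay
#'     times, capped at the end of the run), at least 90\% of
#'     heat-shock-anterior cells have every non-leader fate gene below
#'     detection: the already formed pattern was deleted.}
#'   \item{sequenceReinduced}{some active-zone lineage (born before the
#'     pulse) re-runs the cascade: every gene that was below half-max at
#'     pulse onset, together with the leader, shows ordered post-pulse
#'     onsets in the perturbed run, and at least one non-leader gene among
#'     them never comes back on in the control -- so the re-run is not
#'     just the natural continuation of the sequence, nor the exogenous
#'     pulse itself.}
#'   \item{finalPatternRestored}{the final dominant-fate maps of perturbed
#'     and control runs differ in fewer than 5\% of cells.}
#'   \item{anteriorFateLoss}{fraction of heat-shock-anterior cells, among
#'     those whose control fate is a non-leader gene, whose control fate
#'     gene is below detection at the end of the perturbed run -- the
#'     "already established expression" metric that separates the
#'     module-switching from the decay-modulation realization.}
#' }
#'
#' Classification: `threshold_free` if the sequence was re-induced,
#' `threshold_based` if the final pattern was restored without
#' re-induction, otherwise `mixed`.
#'
#' @param kymPerturbed,kymControl [Kymograph-class] runs on identical grids
#'   with identical growth.
#' @param protocol the [PerturbationProtocol-class] applied to the
#'   perturbed run.
#' @param epsilonG,epsilonM detection and morphogen thresholds (defaults
#'   as elsewhere).
#' @param horizon optional override of the erasure-check time.
#' @return A [ResetReport-class].
#' @export
resetAssay <- function(kymPerturbed, kymControl, protocol,
                       epsilonG = NULL, epsilonM = NULL, horizon = NULL) {
  if (!all(dim(kymPerturbed) == dim(kymControl)) ||
      max(abs(frameTimes(kymPerturbed) - frameTimes(kymControl))) > 1e-9)
    stop("perturbed and control kymographs must share their grid")
  if (is.null(epsilonG)) epsilonG <- .defaultEpsG(kymControl)
  if (is.null(epsilonM)) epsilonM <- .defaultEpsM(kymControl)
  w <- reinductionWindow(protocol)
  leader <- as.integer(w["gene"])
  tOn <- .snapToGrid(kymControl, w["t_on"])
  tEnd <- max(frameTimes(kymControl))
  np <- S4Vectors::metadata(kymPerturbed)$network
  lamPos <- np$lam0[np$lam0 > 0]
  decayTime <- if (length(lamPos)) 2 / min(lamPos) else Inf
  if (is.null(horizon)) horizon <- min(w["t_off"] + decayTime, tEnd)
  horizon <- .snapToGrid(kymPerturbed, horizon)

  regions <- partitionRegions(kymPerturbed, tOn, protocol, epsilonM)
  hs <- regions@hsAnterior
  az <- regions@activeZone
  gn <- geneNames(kymControl)
  halfMax <- .defaultHalfMax(kymControl)

  # erasure in the heat-shock anterior
  fH <- frameIndex(kymPerturbed, horizon)
  nonLeader <- setdiff(seq_along(gn), leader)
  erased <- vapply(hs, function(c) {
    all(vapply(nonLeader, function(k)
      geneMatrix(kymPerturbed, gn[k])[c, fH] < epsilonG, logical(1)))
  }, logical(1))
  anteriorErased <- length(hs) > 0 && mean(erased) >= 0.9

  # persistence of established anterior fates (control-fate loss)
  fEnd <- frameIndex(kymPerturbed, tEnd)
  ctrlFates <- dominantFate(kymControl, tEnd, epsilonG)@fates
  hsNL <- hs[!is.na(ctrlFates[hs]) & ctrlFates[hs] != 0 &
             ctrlFates[hs] != leader]
  anteriorFateLoss <- if (!length(hsNL)) 0 else
    mean(vapply(hsNL, function(c)
      geneMatrix(kymPerturbed, gn[ctrlFates[c]])[c, fEnd] < epsilonG,
      logical(1)))

  # cascade re-run inside the active zone
  f0 <- frameIndex(kymControl, tOn)
  birth <- birthTimes(kymPerturbed)
  azOld <- az[birth[az] <= tOn + 1e-9]
  sequenceReinduced <- FALSE
  for (c in azOld) {
    ctrlAt <- vapply(gn, function(g) geneMatrix(kymControl, g)[c, f0],
                     numeric(1))
    S <- which(ctrlAt < halfMax)
    need <- sort(union(S, leader))
    onsP <- activationTimes(kymPerturbed, c, level = halfMax, after = tOn)
    if (any(is.na(onsP[need]))) next
    if (is.unsorted(onsP[need], strictly = FALSE)) next
    Snl <- setdiff(S, leader)
    if (!length(Snl)) next
    onsC <- activationTimes(kymControl, c, level = halfMax, after = tOn)
    # diagnostic only if the re-run includes a non-leader gene the control
    # never re-activates (the leader's own pulse onset is exogenous)
    if (!any(!is.na(onsP[Snl]) & is.na(onsC[Snl]))) next
    sequenceReinduced <- TRUE
    break
  }

  # final pattern comparison
  fatP <- dominantFate(kymPerturbed, tEnd, epsilonG)@fates
  cmp <- !is.na(fatP) & !is.na(ctrlFates)
  diffFrac <- mean(fatP[cmp] != ctrlFates[cmp])
  finalPatternRestored <- diffFrac < 0.05

  classification <- if (sequenceReinduced) "threshold_free"
                    else if (finalPatternRestored) "threshold_based"
                    else "mixed"
  new("ResetReport", anteriorErased = anteriorErased,
      sequenceReinduced = sequenceReinduced,
      finalPatternRestored = finalPatternRestored,
      anteriorFateLoss = anteriorFateLoss,
      classification = classification,
      details = list(t_on = tOn, horizon = horizon, leader = leader,
                     erased_fraction = if (length(hs)) mean(erased) else NA,
                     final_diff_fraction = diffFrac,
                     n_hs_anterior = length(hs), n_active_zone = length(az)))
}

setMethod("show", "FatePattern", function(object) {
  f <- object@fates
  lab <- ifelse(is.na(f), ".", ifelse(f == 0, "-", as.character(f)))
  cat("FatePattern at t =", object@time, "(epsilon_g =",
      signif(object@epsilonG, 3), ")\n")
  cat("  A->P:", paste(lab, collapse = ""), "\n")
})

setMethod("show", "RegionPartition", function(object) {
  cat("RegionPartition at t =", object@time, ":",
      length(object@activeZone), "active-zone,",
      length(object@anterior), "anterior,",
      length(object@hsAnterior), "heat-shock-anterior cells\n")
})

setMethod("show", "ResetReport", function(object) {
  cat("ResetReport:", object@classification, "\n")
  cat("  anterior erased:      ", object@anteriorErased, "\n")
  cat("  sequence re-induced:  ", object@sequenceReinduced, "\n")
  cat("  final pattern restored:", object@finalPatternRestored, "\n")
  cat("  anterior fate loss:   ", signif(object@anteriorFateLoss, 3), "\n")
})
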