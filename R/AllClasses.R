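#' @include AllGenerics.R
NULL

#' GeneNetwork: a patterning network family plus its parameters
#'
#' Container for one of the four network families and everything the
#' per-cell ODE needs: regulatory wiring, morphogen (or timer) coupling,
#' production ceilings, decay rates and the sigmoid steepness.
#'
#' Families:
#' \describe{
#'   \item{FF}{French Flag: the morphogen activates each gene with a graded
#'     strength `rho`; cross-repression of earlier genes by later ones
#'     sharpens the threshold readout.}
#'   \item{FFTG}{French Flag with a Timer Gene: identical fate-gene wiring,
#'     but thresholds are read from a near-non-decaying timer that
#'     integrates morphogen exposure.}
#'   \item{SR2M}{Speed Regulation by module switching: a dynamic cascade
#'     module (sequential activation) and a static multistable module
#'     (fate locking), mixed convexly by the normalized morphogen.}
#'   \item{SRDM}{Speed Regulation by decay modulation: the normalized
#'     morphogen multiplies both production and decay of a cascade, so it
#'     sets the literal speed of state transitions.}
#' }
#'
#' @slot family character; one of `"FF"`, `"FFTG"`, `"SR2M"`, `"SRDM"`.
#' @slot geneNames character; fate-gene identifiers, plus `"timer"` last for
#'   FFTG.
#' @slot W_dyn numeric matrix (n x n); entry (i, j) is the signed weight of
#'   gene j on gene i in the dynamic/cascade wiring (cross-repression wiring
#'   for FF/FFTG).
#' @slot W_stat numeric matrix (n x n) or `NULL`; static multistable wiring
#'   (SR2M only).
#' @slot rho numeric; per-gene coupling of the external driver (morphogen
#'   for FF, timer for FFTG fate genes; unused by SR2M/SRDM).
#' @slot h_dyn,h_stat numeric; per-gene biases of the two wirings.
#' @slot R numeric; per-gene production-rate ceilings (> 0).
#' @slot lam0 numeric; per-gene basal decay rates (>= 0).
#' @slot lam1 numeric; per-gene morphogen-scaled decay rates (SRDM only).
#' @slot k_sig positive sigmoid steepness.
#' @slot M_max positive morphogen normalization constant.
#' @slot timer list; for FFTG: `kappa` (production gain), `lam_T` (decay),
#'   `T_ref` (normalization). Empty for other families.
#'
#' @seealso [buildFF()], [buildFFTG()], [buildSRTwoModule()],
#'   [buildSRDecayMod()], [derivative()]
#' @export
setClass("GeneNetwork",
  representation(family = "character", geneNames = "character",
                 W_dyn = "matrix", W_stat = "ANY",
                 rho = "numeric", h_dyn = "numeric", h_stat = "numeric",
                 R = "numeric", lam0 = "numeric", lam1 = "numeric",
                 k_sig = "numeric", M_max = "numeric", timer = "list"))

setValidity("GeneNetwork", function(object) {
  msgs <- character()
  fam <- object@family
  if (length(fam) != 1 || !fam %in% c("FF", "FFTG", "SR2M", "SRDM"))
    return("family must be one of FF, FFTG, SR2M, SRDM")
  n <- length(object@rho)
  chkvec <- function(x, nm) {
    if (length(x) != n) msgs <<- c(msgs, paste0(nm, " must have length ", n))
    if (!all(is.finite(x))) msgs <<- c(msgs, paste0(nm, " must be finite"))
  }
  chkvec(object@h_dyn, "h_dyn"); chkvec(object@h_stat, "h_stat")
  chkvec(object@R, "R"); chkvec(object@lam0, "lam0"); chkvec(object@lam1, "lam1")
  if (!all(dim(object@W_dyn) == c(n, n)) || !all(is.finite(object@W_dyn)))
    msgs <- c(msgs, "W_dyn must be a finite n x n matrix")
  expectedNames <- if (fam == "FFTG") n + 1L else n
  if (length(object@geneNames) != expectedNames)
    msgs <- c(msgs, "geneNames length inconsistent with family/n_genes")
  if (fam == "FFTG" && utils::tail(object@geneNames, 1) != "timer")
    msgs <- c(msgs, "FFTG networks must name their last state 'timer'")
  if (any(object@R <= 0)) msgs <- c(msgs, "production ceilings R must be > 0")
  if (any(object@lam0 < 0) || any(object@lam1 < 0))
    msgs <- c(msgs, "decay rates must be >= 0")
  if (length(object@k_sig) != 1 || object@k_sig <= 0)
    msgs <- c(msgs, "k_sig must be a positive scalar")
  if (length(object@M_max) != 1 || object@M_max <= 0)
    msgs <- c(msgs, "M_max must be a positive scalar")
  if (fam %in% c("FF", "FFTG")) {
    if (n > 1 && any(diff(object@rho) >= 0))
      msgs <- c(msgs, "FF/FFTG require rho strictly decreasing in gene index")
    W <- object@W_dyn
    if (any(W > 0))
      msgs <- c(msgs, "FF/FFTG wiring admits repression only (W_dyn <= 0)")
    if (any(W[lower.tri(W, diag = TRUE)] != 0))
      msgs <- c(msgs, "FF/FFTG repression must come from later genes only")
  }
  if (fam == "FFTG") {
    tm <- object@timer
    need <- c("kappa", "lam_T", "T_ref")
    if (!all(need %in% names(tm))) {
      msgs <- c(msgs, "FFTG timer parameters kappa, lam_T, T_ref required")
    } else {
      if (tm$kappa <= 0 || tm$T_ref <= 0 || tm$lam_T < 0)
        msgs <- c(msgs, "timer requires kappa > 0, T_ref > 0, lam_T >= 0")
      if (tm$lam_T > 0.01 * min(object@lam0))
        msgs <- c(msgs, "timer decay must be negligible (lam_T <= 0.01 min lam0)")
    }
  }
  if (fam == "SR2M") {
    Ws <- object@W_stat
    if (is.null(Ws)) {
      msgs <- c(msgs, "SR2M requires the static wiring W_stat")
    } else {
      if (!all(dim(Ws) == c(n, n)) || !all(is.finite(Ws)))
        msgs <- c(msgs, "W_stat must be a finite n x n matrix")
      else if (any(diag(Ws) <= 0) || any(Ws[row(Ws) != col(Ws)] >= 0))
        msgs <- c(msgs,
          "W_stat needs self-activation on the diagonal and mutual repression off it")
    }
  }
  if (fam == "SRDM") {
    if (!is.null(object@W_stat))
      msgs <- c(msgs, "SRDM has no static module (W_stat must be absent)")
    if (any(object@lam1 <= 0))
      msgs <- c(msgs, "SRDM requires morphogen-scaled decay lam1 > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' MorphogenProgram: the imposed space-time morphogen field
#'
#' Describes M(d, t) where d is the distance from the posterior pole in cell
#' units. The spatial profile is exponential with length scale `xi`
#' (`xi_axn` for the posteriorized variant); temporal regimes multiply it by
#' buildup and/or decay factors. The `composite` regime is the static
#' profile anchored to the current pole: its apparent retraction is realized
#' entirely by tissue elongation.
#'
#' @slot regime one of `"static"`, `"buildup"`, `"decaying"`,
#'   `"buildup_decay"`, `"composite"`, `"axn"`.
#' @slot M_amp positive posterior-pole amplitude.
#' @slot xi positive exponential length scale (cells).
#' @slot tau_build buildup time constant (NA unless used).
#' @slot t_decay_start,tau_decay decay onset and time constant (NA unless used).
#' @slot t_germband time at which growth anchors the gradient to a retracting
#'   pole (composite; informational).
#' @slot xi_axn long length scale of the posteriorized (axn-like) gradient.
#' @seealso [morphogenProgram()], [evaluateMorphogen()], [axnVariant()]
#' @export
setClass("MorphogenProgram",
  representation(regime = "character", M_amp = "numeric", xi = "numeric",
                 tau_build = "numeric", t_decay_start = "numeric",
                 tau_decay = "numeric", t_germband = "numeric",
                 xi_axn = "numeric"))

setValidity("MorphogenProgram", function(object) {
  msgs <- character()
  regimes <- c("static", "buildup", "decaying", "buildup_decay",
               "composite", "axn")
  if (length(object@regime) != 1 || !object@regime %in% regimes)
    return(paste("regime must be one of:", paste(regimes, collapse = ", ")))
  if (object@M_amp <= 0) msgs <- c(msgs, "M_amp must be positive")
  if (object@xi <= 0) msgs <- c(msgs, "xi must be positive")
  if (object@regime %in% c("buildup", "buildup_decay") &&
      (is.na(object@tau_build) || object@tau_build <= 0))
    msgs <- c(msgs, "buildup regimes require tau_build > 0")
  if (object@regime %in% c("decaying", "buildup_decay") &&
      (is.na(object@tau_decay) || object@tau_decay <= 0 ||
       is.na(object@t_decay_start)))
    msgs <- c(msgs, "decay regimes require t_decay_start and tau_decay > 0")
  if (object@regime == "axn" && (is.na(object@xi_axn) || object@xi_axn <= 0))
    msgs <- c(msgs, "axn regime requires xi_axn > 0")
  if (length(msgs)) msgs else TRUE
})

#' GrowthSchedule: posterior elongation of the cell field
#'
#' New, naive (all-zero) cells are appended at the posterior end, one every
#' `1/rate` time units starting at `t_start + 1/rate`, until `n_final` cells
#' exist. `rate = 0` means a non-growing tissue.
#'
#' @slot n0 initial cell count.
#' @slot n_final final cell count (`>= n0`).
#' @slot t_start time at which growth begins.
#' @slot rate cells added per time unit (>= 0).
#' @seealso [growthSchedule()], [simulateTissue()]
#' @export
setClass("GrowthSchedule",
  representation(n0 = "integer", n_final = "integer",
                 t_start = "numeric", rate = "numeric"))

setValidity("GrowthSchedule", function(object) {
  msgs <- character()
  if (object@n0 < 1) msgs <- c(msgs, "n0 must be >= 1")
  if (object@n_final < object@n0) msgs <- c(msgs, "n_final must be >= n0")
  if (object@rate < 0) msgs <- c(msgs, "rate must be >= 0")
  if ((object@rate == 0) != (object@n_final == object@n0))
    msgs <- c(msgs, "rate = 0 exactly when no cells are added")
  if (length(msgs)) msgs else TRUE
})

#' PerturbationProtocol: timed events applied during integration
#'
#' An ordered list of events, each a named list with a `type` field:
#' \describe{
#'   \item{reinduce}{`gene`, `t_on`, `t_off`, `amplitude`, `mode`
#'     (`"additive"` adds the amplitude to the gene's production rate in
#'     every cell; `"clamp"` pins the concentration to the amplitude).}
#'   \item{rnai}{`gene`, `scale` in `[0, 1)`, `from`; scales the gene's
#'     production ceiling from time `from` on.}
#'   \item{morphogen_override}{`program` (a [MorphogenProgram-class]),
#'     `from`; replaces the morphogen program from time `from` on.}
#' }
#'
#' @slot events list of event lists.
#' @seealso [makeReinduction()], [makeRnai()], [makeAxnRnai()],
#'   [mergeProtocols()]
#' @export
setClass("PerturbationProtocol", representation(events = "list"))

setValidity("PerturbationProtocol", function(object) {
  msgs <- character()
  seen <- list(reinduce = list())
  for (ev in object@events) {
    if (!is.list(ev) || is.null(ev$type)) return("each event must be a list with a type")
    if (ev$type == "reinduce") {
      if (ev$t_on >= ev$t_off) msgs <- c(msgs, "reinduce requires t_on < t_off")
      if (ev$amplitude <= 0) msgs <- c(msgs, "reinduce amplitude must be > 0")
      if (!ev$mode %in% c("additive", "clamp"))
        msgs <- c(msgs, "reinduce mode must be additive or clamp")
      for (prev in seen$reinduce)
        if (prev$gene == ev$gene && ev$t_on < prev$t_off && prev$t_on < ev$t_off)
          msgs <- c(msgs, "re-induction events overlap for the same gene")
      seen$reinduce <- c(seen$reinduce, list(ev))
    } else if (ev$type == "rnai") {
      if (ev$scale < 0 || ev$scale >= 1)
        msgs <- c(msgs, "rnai scale must lie in [0, 1)")
    } else if (ev$type == "morphogen_override") {
      if (!is(ev$program, "MorphogenProgram"))
        msgs <- c(msgs, "morphogen_override needs a MorphogenProgram")
    } else msgs <- c(msgs, paste("unknown event type:", ev$type))
  }
  if (length(msgs)) msgs else TRUE
})

#' Kymograph: a space x time x gene record of a simulation
#'
#' Extends [SummarizedExperiment::SummarizedExperiment]: rows are cell
#' lineages (stable across growth, anterior to posterior), columns are
#' output frames on a uniform time grid, and there is one assay per state
#' variable (fate genes, plus `timer` for FFTG) plus a `morphogen` assay
#' holding the morphogen concentration each cell experienced. Entries of
#' cells not yet born are `NA` (a sentinel distinct from concentration 0);
#' `rowData` carries each lineage's birth time. `metadata()` records the
#' network parameter dump, morphogen program, growth schedule, protocol,
#' integrator settings and seed.
#'
#' @seealso [simulateTissue()], [geneMatrix()], [frameTimes()],
#'   [exportKymograph()]
#' @export
setClass("Kymograph", contains = "SummarizedExperiment")

setValidity("Kymograph", function(object) {
  msgs <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!"morphogen" %in% an) msgs <- c(msgs, "a morphogen assay is required")
  if (is.null(object$time)) msgs <- c(msgs, "colData must carry frame times")
  else if (length(object$time) > 1) {
    steps <- diff(object$time)
    if (any(abs(steps - steps[1]) > 1e-9))
      msgs <- c(msgs, "frame times must be uniform")
  }
  born <- colSums(!is.na(SummarizedExperiment::assay(object, "morphogen")))
  if (is.unsorted(born)) msgs <- c(msgs, "cell counts must be non-decreasing")
  if (length(msgs)) msgs else TRUE
})

#' FatePattern: per-cell dominant fates at one time point
#'
#' @slot fates integer; per cell, the dominant fate-gene index, `0` for no
#'   detectable expression, `NA` for cells not yet born.
#' @slot epsilonG detection threshold used.
#' @slot time the query time.
#' @seealso [dominantFate()], [detectBoundaries()], [fateSequence()]
#' @export
setClass("FatePattern",
  representation(fates = "integer", epsilonG = "numeric", time = "numeric"))

#' RegionPartition: active zone / anterior / heat-shock anterior
#'
#' Cell-lineage index sets at a query time: the active zone is where the
#' recorded morphogen is at least `epsilonM` (the abstraction of the
#' caudal-expressing zone); the anterior is every other born cell; the
#' heat-shock anterior is the anterior as it was at the protocol's pulse
#' onset, tracked by lineage.
#'
#' @slot activeZone,anterior,hsAnterior integer lineage indices.
#' @slot time,tOn query time and pulse-onset time (`NA` without a protocol).
#' @slot epsilonM morphogen threshold used.
#' @seealso [partitionRegions()]
#' @export
setClass("RegionPartition",
  representation(activeZone = "integer", anterior = "integer",
                 hsAnterior = "integer", time = "numeric", tOn = "numeric",
                 epsilonM = "numeric"))

#' ResetReport: outcome of the leading-gene re-induction assay
#'
#' @slot anteriorErased logical; at the erasure horizon, did at least 90% of
#'   heat-shock-anterior cells lose all non-leader expression?
#' @slot sequenceReinduced logical; did the full ordered onset sequence recur
#'   in active-zone cells where the control shows no such re-run?
#' @slot finalPatternRestored logical; do the final dominant-fate maps of
#'   perturbed and control runs agree in at least 95% of cells?
#' @slot anteriorFateLoss numeric; fraction of heat-shock-anterior cells
#'   whose control fate gene fell below detection by the end of the run.
#' @slot classification `"threshold_free"`, `"threshold_based"` or `"mixed"`.
#' @slot details list of intermediate quantities.
#' @seealso [resetAssay()]
#' @export
setClass("ResetReport",
  representation(anteriorErased = "logical", sequenceReinduced = "logical",
                 finalPatternRestored = "logical", anteriorFateLoss = "numeric",
                 classification = "character", details = "list"))
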