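#' @include analysis.R
NULL

#' Standard error of a proportion
#'
#' `sqrt(p * (1 - p) / n)`: the binomial standard error used for
#' detectable-expression proportions over an embryo ensemble.
#'
#' @param p proportion in `[0, 1]`.
#' @param n positive ensemble size.
#' @return Non-negative numeric.
#' @examples
#' proportionSE(0.5, 16)   # 0.125
#' @export
proportionSE <- function(p, n) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]")
  if (any(!is.finite(n)) || any(n < 1)) stop("n must be a positive count")
  sqrt(p * (1 - p) / n)
}

#' Simulate an ensemble of variable embryos
#'
#' Produces `size` replicate simulations with embryo-to-embryo parameter
#' variability and measurement noise, emulating the variability behind
#' scored expression proportions: each embryo's production ceilings `R`
#' (and driver couplings `rho`, where the family uses them) receive
#' multiplicative log-normal jitter (`sdlog = jitterSigma`), and Gaussian
#' observation noise (`sd = noiseSigma`) is added to every recorded
#' concentration. The deterministic core is otherwise unchanged; all
#' randomness flows from `seed`.
#'
#' @param network a [GeneNetwork-class]; jitter is applied around its
#'   parameters.
#' @param program,schedule,tEnd,dt,dtOut,protocol as in [simulateTissue()].
#' @param size ensemble size (default 15, a typical egg-collection size).
#' @param seed integer seed (mandatory).
#' @param jitterSigma log-normal sd of the per-embryo parameter jitter.
#' @param noiseSigma sd of the additive observation noise.
#' @return List of [Kymograph-class] objects.
#' @export
simulateEnsemble <- function(network, program, schedule, tEnd,
                             protocol = NULL, size = 15, seed,
                             jitterSigma = 0.15, noiseSigma = 0.05,
                             dt = 0.001, dtOut = 0.1) {
  if (missing(seed)) stop("an ensemble needs an explicit seed")
  set.seed(as.integer(seed))
  n <- nGenes(network)
  lapply(seq_len(size), function(e) {
    net <- network
    net@R <- network@R * stats::rlnorm(n, 0, jitterSigma)
    if (any(network@rho > 0))
      net@rho <- network@rho * stats::rlnorm(n, 0, jitterSigma)
    kym <- simulateTissue(net, program, schedule, tEnd, dt = dt,
                          dtOut = dtOut, protocol = protocol, seed = seed)
    for (s in setdiff(SummarizedExperiment::assayNames(kym), "morphogen")) {
      a <- SummarizedExperiment::assay(kym, s)
      a <- a + matrix(stats::rnorm(length(a), 0, noiseSigma),
                      nrow(a), ncol(a))
      SummarizedExperiment::assay(kym, s) <- a
    }
    kym
  })
}

#' Region-based expression scoring of an ensemble
#'
#' For each time window, region (heat-shock anterior `HS-A`, anterior `A`,
#' active zone `AZ`) and fate gene, counts the proportion of embryos with
#' detectable expression: an embryo scores positive if any cell of the
#' region reaches `epsilonG` at any frame inside the window. The active
#' zone and anterior are determined per embryo at the window start; the
#' heat-shock anterior is fixed by lineage at the pulse onset, whatever
#' the window. Standard errors come from [proportionSE()].
#'
#' @param ensemble non-empty list of [Kymograph-class] runs sharing a grid.
#' @param protocol the shared [PerturbationProtocol-class] (or `NULL`; then
#'   only `A`/`AZ` are scored).
#' @param windows list of `c(t1, t2)` windows.
#' @param epsilonG,epsilonM thresholds (defaults as elsewhere).
#' @return Data frame with columns `window`, `region`, `gene`, `p`, `n`,
#'   `SE`.
#' @export
scoreRegions <- function(ensemble, protocol = NULL, windows,
                         epsilonG = NULL, epsilonM = NULL) {
  if (!length(ensemble)) stop("ensemble must be non-empty")
  if (is.numeric(windows)) windows <- list(windows)
  kym1 <- ensemble[[1]]
  if (is.null(epsilonG)) epsilonG <- .defaultEpsG(kym1)
  if (is.null(epsilonM)) epsilonM <- .defaultEpsM(kym1)
  gn <- geneNames(kym1)
  nEmb <- length(ensemble)
  regions <- if (is.null(protocol)) c("A", "AZ") else c("HS-A", "A", "AZ")
  rows <- list()
  for (wdx in seq_along(windows)) {
    win <- windows[[wdx]]
    label <- sprintf("%g-%g", win[1], win[2])
    tStart <- .snapToGrid(kym1, win[1])
    detected <- array(FALSE, c(nEmb, length(regions), length(gn)))
    for (e in seq_len(nEmb)) {
      kym <- ensemble[[e]]
      part <- partitionRegions(kym, tStart, NULL, epsilonM)
      hs <- integer(0)
      if (!is.null(protocol)) {
        tOn <- .snapToGrid(kym, unname(reinductionWindow(protocol)["t_on"]))
        hs <- partitionRegions(kym, tOn, protocol, epsilonM)@hsAnterior
      }
      cellSets <- list(`HS-A` = hs, A = part@anterior,
                       AZ = part@activeZone)[regions]
      tt <- frameTimes(kym)
      sel <- which(tt >= win[1] - 1e-9 & tt <= win[2] + 1e-9)
      for (k in seq_along(gn)) {
        m <- geneMatrix(kym, gn[k])[, sel, drop = FALSE]
        for (r in seq_along(regions)) {
          cells <- cellSets[[r]]
          detected[e, r, k] <- length(cells) > 0 &&
            any(m[cells, ] >= epsilonG, na.rm = TRUE)
        }
      }
    }
    for (r in seq_along(regions)) for (k in seq_along(gn)) {
      p <- mean(detected[, r, k])
      rows[[length(rows) + 1]] <-
        data.frame(window = label, region = regions[r], gene = gn[k],
                   p = p, n = nEmb, SE = proportionSE(p, nEmb))
    }
  }
  do.call(rbind, rows)
}

#' Write an expression-score table as CSV
#'
#' Columns mirror a source-data layout: collection window, region
#' (`HS-A`, `A`, `AZ`), gene, proportion, sample size, standard error.
#'
#' @param scores data frame from [scoreRegions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportScores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
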