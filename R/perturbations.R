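#' @include kymograph.R
NULL

#' Construct a perturbation protocol
#'
#' @param events list of event lists (see
#'   [PerturbationProtocol-class]); usually built with [makeReinduction()],
#'   [makeRnai()] and [makeAxnRnai()] and combined with [mergeProtocols()].
#' @return A [PerturbationProtocol-class].
#' @export
perturbationProtocol <- function(events = list())
  new("PerturbationProtocol", events = events)

#' Transient ubiquitous re-induction of a gene
#'
#' Models a heat-shock-driven pulse of the target gene in every cell.
#' In `"additive"` mode the amplitude is added to the gene's production
#' rate during the window (decay is untouched, so the product clears
#' naturally at the gene's decay rate after the pulse); in `"clamp"` mode
#' the concentration is pinned to the amplitude and released at `t_off`.
#' The exogenous term is not under morphogen control: it acts equally in
#' morphogen-free cells.
#'
#' @param gene fate-gene index.
#' @param tOn pulse onset time.
#' @param duration pulse length (default 6 time units, the observed
#'   persistence of the heat-shock product).
#' @param amplitude pulse strength (production rate for additive mode,
#'   concentration for clamp mode); a common choice is ten times the
#'   production ceiling.
#' @param mode `"additive"` or `"clamp"`.
#' @return A [PerturbationProtocol-class] with one event.
#' @export
makeReinduction <- function(gene, tOn, duration = 6, amplitude = 2,
                            mode = c("additive", "clamp")) {
  mode <- match.arg(mode)
  if (duration <= 0) stop("duration must be positive")
  perturbationProtocol(list(list(type = "reinduce", gene = as.integer(gene),
                                 t_on = tOn, t_off = tOn + duration,
                                 amplitude = amplitude, mode = mode)))
}

#' RNAi-style knockdown of a fate gene
#'
#' Scales the gene's production ceiling by `scale` from time `from` on
#' (`scale = 0`, the default, is a full parental knockdown).
#'
#' @param gene fate-gene index.
#' @param scale production scale factor in `[0, 1)`.
#' @param from time from which the knockdown acts.
#' @return A [PerturbationProtocol-class] with one event.
#' @export
makeRnai <- function(gene, scale = 0, from = 0) {
  if (scale < 0 || scale >= 1) stop("scale must lie in [0, 1)")
  perturbationProtocol(list(list(type = "rnai", gene = as.integer(gene),
                                 scale = scale, from = from)))
}

#' Posteriorizing morphogen override (axn-RNAi-like)
#'
#' Replaces the morphogen program by its [axnVariant()] from time `from`
#' on: a persistent, non-retracting gradient covering the whole embryo.
#' The growth schedule is unchanged.
#'
#' @param program the base [MorphogenProgram-class].
#' @param tissueLength final tissue length in cells.
#' @param from activation time (default 0).
#' @return A [PerturbationProtocol-class] with one event.
#' @export
makeAxnRnai <- function(program, tissueLength, from = 0) {
  perturbationProtocol(list(list(type = "morphogen_override",
                                 program = axnVariant(program, tissueLength),
                                 from = from)))
}

#' Merge perturbation protocols
#'
#' @param ... [PerturbationProtocol-class] objects.
#' @return A single [PerturbationProtocol-class] with all events.
#' @export
mergeProtocols <- function(...) {
  ps <- list(...)
  perturbationProtocol(do.call(c, lapply(ps, function(p) p@events)))
}

#' Parameter dump of a protocol
#' @param protocol a [PerturbationProtocol-class].
#' @return List of plain event descriptions (programs dumped via
#'   [programParams()]).
#' @export
protocolParams <- function(protocol) {
  lapply(protocol@events, function(ev) {
    if (ev$type == "morphogen_override")
      ev$program <- programParams(ev$program)
    ev
  })
}

#' Rebuild a protocol from its parameter dump
#' @param params a list as produced by [protocolParams()].
#' @return A [PerturbationProtocol-class].
#' @export
protocolFromParams <- function(params) {
  evs <- lapply(params, function(ev) {
    if (ev$type == "morphogen_override") {
      p <- ev$program
      ev$program <- morphogenProgram(p$regime, p$M_amp, p$xi, p$tau_build,
                                     p$t_decay_start, p$tau_decay,
                                     p$t_germband, p$xi_axn)
    }
    if (!is.null(ev$gene)) ev$gene <- as.integer(ev$gene)
    ev
  })
  perturbationProtocol(evs)
}

#' Pulse onset/offset of a protocol
#' @param protocol a [PerturbationProtocol-class].
#' @return Named numeric `c(t_on, t_off, gene)` of the earliest re-induction
#'   event, or an error if the protocol has none.
#' @export
reinductionWindow <- function(protocol) {
  evs <- Filter(function(e) e$type == "reinduce", protocol@events)
  if (!length(evs)) stop("protocol has no re-induction event")
  ev <- evs[[which.min(vapply(evs, `[[`, numeric(1), "t_on"))]]
  c(t_on = ev$t_on, t_off = ev$t_off, gene = ev$gene)
}

setMethod("show", "PerturbationProtocol", function(object) {
  cat("PerturbationProtocol with", length(object@events), "event(s)\n")
  for (ev in object@events) {
    if (ev$type == "reinduce")
      cat(sprintf("  reinduce gene %d: [%g, %g], amplitude %g, %s\n",
                  ev$gene, ev$t_on, ev$t_off, ev$amplitude, ev$mode))
    else if (ev$type == "rnai")
      cat(sprintf("  rnai gene %d: scale %g from t = %g\n",
                  ev$gene, ev$scale, ev$from))
    else
      cat(sprintf("  morphogen override (%s) from t = %g\n",
                  ev$program@regime, ev$from))
  }
})
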