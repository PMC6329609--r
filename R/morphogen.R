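#' @include AllClasses.R
NULL

#' Construct a morphogen program
#'
#' @param regime one of `"static"`, `"buildup"`, `"decaying"`,
#'   `"buildup_decay"`, `"composite"`, `"axn"`.
#' @param MAmp posterior-pole amplitude (default 1).
#' @param xi exponential length scale in cell units (default 10, i.e. 20%
#'   of a 50-cell blastoderm).
#' @param tauBuild buildup time constant (buildup regimes).
#' @param tDecayStart,tauDecay decay onset and time constant (decay regimes).
#' @param tGermband time at which the gradient anchors to a retracting pole
#'   (composite regime; informational -- retraction itself is realized by
#'   tissue growth).
#' @param xiAxn length scale of the posteriorized variant (axn regime).
#' @return A [MorphogenProgram-class].
#' @examples
#' pr <- morphogenProgram("static", xi = 10)
#' evaluateMorphogen(pr, d = 10 * log(2), t = 0)   # half-amplitude
#' @export
morphogenProgram <- function(regime = "static", MAmp = 1, xi = 10,
                             tauBuild = NA_real_, tDecayStart = NA_real_,
                             tauDecay = NA_real_, tGermband = NA_real_,
                             xiAxn = NA_real_) {
  new("MorphogenProgram", regime = regime, M_amp = MAmp, xi = xi,
      tau_build = as.numeric(tauBuild), t_decay_start = as.numeric(tDecayStart),
      tau_decay = as.numeric(tauDecay), t_germband = as.numeric(tGermband),
      xi_axn = as.numeric(xiAxn))
}

.regimeCode <- function(regime)
  match(regime, c("static", "buildup", "decaying", "buildup_decay",
                  "composite", "axn")) - 1L

.progToCore <- function(program) {
  list(regime_code = .regimeCode(program@regime),
       M_amp = program@M_amp, xi = program@xi,
       tau_build = ifelse(is.na(program@tau_build), 1, program@tau_build),
       t_decay_start = ifelse(is.na(program@t_decay_start), 0,
                              program@t_decay_start),
       tau_decay = ifelse(is.na(program@tau_decay), 1, program@tau_decay),
       xi_axn = ifelse(is.na(program@xi_axn), program@xi, program@xi_axn))
}

#' Parameter dump of a morphogen program
#' @param program a [MorphogenProgram-class].
#' @return Named list of plain values.
#' @export
programParams <- function(program) {
  list(regime = program@regime, M_amp = program@M_amp, xi = program@xi,
       tau_build = program@tau_build, t_decay_start = program@t_decay_start,
       tau_decay = program@tau_decay, t_germband = program@t_germband,
       xi_axn = program@xi_axn)
}

#' @rdname evaluateMorphogen
#' @export
setMethod("evaluateMorphogen", "MorphogenProgram", function(program, d, t) {
  if (any(d < 0)) stop("distance from the pole must be non-negative")
  if (any(t < 0)) stop("time must be non-negative")
  len <- if (program@regime == "axn") program@xi_axn else program@xi
  M <- program@M_amp * exp(-d / len)
  if (program@regime %in% c("buildup", "buildup_decay"))
    M <- M * (1 - exp(-t / program@tau_build))
  if (program@regime %in% c("decaying", "buildup_decay"))
    M <- M * exp(-pmax(0, t - program@t_decay_start) / program@tau_decay)
  M
})

#' Germ-type scenario: morphogen program plus growth schedule
#'
#' Encodes the three insect germ types as combinations of gradient regime
#' and posterior elongation:
#' \describe{
#'   \item{short}{the gradient retracts (via growth) from the start:
#'     a composite program with growth beginning at t = 0.}
#'   \item{intermediate}{a static blastoderm phase of `blastodermTime`,
#'     then elongation: the gradient is initially static and eventually
#'     retracts with axis elongation.}
#'   \item{long}{a static gradient on a full-length, non-growing tissue,
#'     with a terminal decay phase that freezes the pattern.}
#' }
#'
#' @param germ `"short"`, `"intermediate"` or `"long"`.
#' @param n0 initial cell count (short/intermediate; the long-germ tissue
#'   has `nFinal` cells throughout).
#' @param nFinal final cell count.
#' @param totalTime scenario duration; must accommodate the growth phase.
#' @param blastodermTime duration of the static blastoderm phase
#'   (intermediate germ; 0 reduces to the short-germ scenario).
#' @param rate growth rate in cells per time unit.
#' @param xi gradient length scale; defaults to 20% of the initial tissue.
#' @param tDecayStart,tauDecay long-germ terminal decay parameters.
#' @return `list(program = MorphogenProgram, schedule = GrowthSchedule)`.
#' @export
germTypeProgram <- function(germ = c("short", "intermediate", "long"),
                            n0 = 50, nFinal = 100, totalTime = 100,
                            blastodermTime = 6, rate = 1, xi = NULL,
                            tDecayStart = 10, tauDecay = 6) {
  germ <- match.arg(germ)
  if (nFinal < n0) stop("final length must be at least the initial length")
  if (germ == "long") {
    if (is.null(xi)) xi <- 0.2 * nFinal
    program <- morphogenProgram("decaying", xi = xi,
                                tDecayStart = tDecayStart, tauDecay = tauDecay)
    schedule <- growthSchedule(nFinal, nFinal, 0, 0)
  } else {
    if (is.null(xi)) xi <- 0.2 * n0
    tg <- if (germ == "short") 0 else blastodermTime
    growthEnd <- tg + (nFinal - n0) / rate
    if (growthEnd > totalTime)
      stop("totalTime too short for the growth phase (ends at ", growthEnd, ")")
    program <- morphogenProgram("composite", xi = xi, tGermband = tg)
    schedule <- growthSchedule(n0, nFinal, tg, rate)
  }
  list(program = program, schedule = schedule)
}

#' Posteriorized (axn-RNAi-like) morphogen variant
#'
#' Returns a program whose gradient covers the whole embryo: same pole
#' amplitude, but a length scale of at least ten times the tissue length,
#' no decay, and no retraction -- the tissue-wide, persistent gradient that
#' turns the entire embryo into an enlarged active zone (still a gradient,
#' not a plateau). Applying it twice is a no-op.
#'
#' @param program a [MorphogenProgram-class] to posteriorize.
#' @param tissueLength final tissue length in cells.
#' @return A [MorphogenProgram-class] with `regime = "axn"`.
#' @export
axnVariant <- function(program, tissueLength) {
  xiAxn <- max(10 * tissueLength,
               if (is.na(program@xi_axn)) 0 else program@xi_axn)
  morphogenProgram("axn", MAmp = program@M_amp, xi = program@xi,
                   xiAxn = xiAxn)
}

#' Construct a growth schedule
#'
#' @param n0,nFinal initial and final cell counts.
#' @param tStart time at which growth begins.
#' @param rate cells added per time unit (0 for a non-growing tissue).
#' @return A [GrowthSchedule-class].
#' @export
growthSchedule <- function(n0, nFinal = n0, tStart = 0, rate = 0) {
  new("GrowthSchedule", n0 = as.integer(n0), n_final = as.integer(nFinal),
      t_start = as.numeric(tStart), rate = as.numeric(rate))
}

#' Parameter dump of a growth schedule
#' @param schedule a [GrowthSchedule-class].
#' @return Named list.
#' @export
scheduleParams <- function(schedule) {
  list(n0 = schedule@n0, n_final = schedule@n_final,
       t_start = schedule@t_start, rate = schedule@rate)
}

setMethod("show", "MorphogenProgram", function(object) {
  cat("MorphogenProgram:", object@regime, " amplitude", object@M_amp,
      " xi", if (object@regime == "axn") object@xi_axn else object@xi, "\n")
})

setMethod("show", "GrowthSchedule", function(object) {
  if (object@rate == 0) {
    cat("GrowthSchedule: static tissue of", object@n0, "cells\n")
  } else {
    cat("GrowthSchedule:", object@n0, "->", object@n_final, "cells from t =",
        object@t_start, "at", object@rate, "cells per time unit\n")
  }
})
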