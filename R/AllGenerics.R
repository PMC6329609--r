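#' @include RcppExports.R
NULL

#' Network family tag
#'
#' @param x a [GeneNetwork-class] or [Kymograph-class] object.
#' @return Character scalar: one of `"FF"`, `"FFTG"`, `"SR2M"`, `"SRDM"`.
#' @export
setGeneric("netFamily", function(x) standardGeneric("netFamily"))

#' Number of fate genes
#'
#' The FFTG timer is an extra state variable, not a fate gene, and is not
#' counted.
#'
#' @param x a [GeneNetwork-class] or [Kymograph-class] object.
#' @return Integer scalar.
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' Fate-gene names
#'
#' @param x a [GeneNetwork-class] or [Kymograph-class] object.
#' @return Character vector of fate-gene identifiers (timer excluded).
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' Right-hand side of the per-cell ODE
#'
#' Evaluates the family-specific instantaneous rates of change for a single
#' cell, given its state and the local morphogen concentration. This is the
#' reference R implementation of the model equations; the simulation engine
#' integrates the same right-hand side in compiled code.
#'
#' @param network a [GeneNetwork-class].
#' @param g numeric state vector (fate genes, plus the timer as last element
#'   for the FFTG family).
#' @param M non-negative morphogen concentration.
#' @return Numeric vector of rates, same length and order as `g`.
#' @export
setGeneric("derivative", function(network, g, M) standardGeneric("derivative"))

#' Evaluate a morphogen program
#'
#' @param program a [MorphogenProgram-class].
#' @param d non-negative distance from the posterior pole, in cell units
#'   (vectorized).
#' @param t non-negative time (vectorized; recycled against `d`).
#' @return Numeric vector of morphogen concentrations in `[0, M_amp]`.
#' @export
setGeneric("evaluateMorphogen",
           function(program, d, t) standardGeneric("evaluateMorphogen"))
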