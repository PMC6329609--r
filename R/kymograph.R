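#' @include simulate.R
NULL

.makeKymograph <- function(core, network, program, schedule, protocol,
                           dt, dtOut, tEnd, seed) {
  conc <- core$conc
  nFrames <- dim(conc)[1]
  nCellsTot <- dim(conc)[2]
  ns <- dim(conc)[3]
  stateNames <- network@geneNames
  assays <- stats::setNames(
    lapply(seq_len(ns), function(k) t(conc[, , k])), stateNames)
  assays$morphogen <- t(core$morphogen)
  lineage <- sprintf("cell%03d", seq_len(nCellsTot))
  rd <- S4Vectors::DataFrame(lineage = lineage, birth = core$birth,
                             row.names = lineage)
  cd <- S4Vectors::DataFrame(time = core$times,
                             row.names = sprintf("f%d", seq_len(nFrames) - 1L))
  md <- list(network = networkParams(network),
             program = programParams(program),
             schedule = scheduleParams(schedule),
             protocol = if (is.null(protocol)) NULL
                        else protocolParams(protocol),
             integrator = list(dt = dt, dt_out = dtOut, t_end = tEnd,
                               method = "rk4"),
             seed = seed)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rd, colData = cd, metadata = md)
  new("Kymograph", se)
}

#' Frame times of a kymograph
#' @param kym a [Kymograph-class].
#' @return Numeric vector of output times.
#' @export
frameTimes <- function(kym) kym$time

#' Birth times of the cell lineages
#' @param kym a [Kymograph-class].
#' @return Numeric vector, one entry per lineage.
#' @export
birthTimes <- function(kym) SummarizedExperiment::rowData(kym)$birth

#' @rdname geneNames
#' @export
setMethod("geneNames", "Kymograph", function(x) {
  an <- SummarizedExperiment::assayNames(x)
  setdiff(an, c("morphogen", "timer"))
})

#' @rdname nGenes
#' @export
setMethod("nGenes", "Kymograph", function(x) length(geneNames(x)))

#' @rdname netFamily
#' @export
setMethod("netFamily", "Kymograph",
          function(x) S4Vectors::metadata(x)$network$family)

#' Concentration matrix of one gene
#'
#' @param kym a [Kymograph-class].
#' @param gene gene name or index.
#' @return Matrix (lineages x frames); `NA` marks cells not yet born.
#' @export
geneMatrix <- function(kym, gene) {
  if (is.numeric(gene)) gene <- geneNames(kym)[gene]
  SummarizedExperiment::assay(kym, gene)
}

#' Recorded morphogen field
#' @param kym a [Kymograph-class].
#' @return Matrix (lineages x frames) of local morphogen concentrations.
#' @export
morphogenMatrix <- function(kym) SummarizedExperiment::assay(kym, "morphogen")

#' Index of the output frame at a time
#' @param kym a [Kymograph-class].
#' @param t a time on the output grid (off-grid times are an error).
#' @return Integer frame index.
#' @export
frameIndex <- function(kym, t) {
  tt <- frameTimes(kym)
  i <- which(abs(tt - t) < 1e-9)
  if (length(i) != 1) stop("t = ", t, " is not on the output time grid")
  i
}

#' Cells alive at a time
#' @param kym a [Kymograph-class].
#' @param t query time (defaults to the final frame).
#' @return Integer vector of lineage indices born at or before `t`.
#' @export
cellsAlive <- function(kym, t = max(frameTimes(kym))) {
  which(birthTimes(kym) <= t + 1e-9)
}

setMethod("show", "Kymograph", function(object) {
  tt <- frameTimes(object)
  cat("Kymograph:", netFamily(object), "family,", nrow(object),
      "lineages x", ncol(object), "frames (t = 0 ..", max(tt), ")\n")
  cat("  states:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
  nb <- sum(birthTimes(object) > 0)
  if (nb > 0) cat(" ", nb, "cells born during growth\n")
})

## ---- export / import ----

#' Export a kymograph
#'
#' `format = "tsv"` writes a long-format table with columns `time`,
#' `lineage_id`, `cell_index_at_time`, `gene`, `concentration`,
#' `morphogen` (17 significant digits; one row per frame, alive cell and
#' state variable) plus a JSON metadata sidecar at `<path>.meta.json`
#' (absent protocol serialized as an explicit null). `format = "rds"`
#' writes a lossless binary container.
#'
#' @param kym a [Kymograph-class].
#' @param path output file path.
#' @param format `"tsv"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
exportKymograph <- function(kym, path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(kym, path)
    return(invisible(path))
  }
  tt <- frameTimes(kym)
  birth <- birthTimes(kym)
  states <- setdiff(SummarizedExperiment::assayNames(kym), "morphogen")
  mor <- morphogenMatrix(kym)
  rows <- vector("list", length(tt))
  for (f in seq_along(tt)) {
    alive <- which(birth <= tt[f] + 1e-9)
    for (s in states) {
      g <- SummarizedExperiment::assay(kym, s)[alive, f]
      rows[[length(states) * (f - 1) + match(s, states)]] <-
        data.frame(time = tt[f],
                   lineage_id = rownames(kym)[alive],
                   cell_index_at_time = seq_along(alive),
                   gene = s,
                   concentration = g,
                   morphogen = mor[alive, f])
    }
  }
  long <- do.call(rbind, rows)
  num <- vapply(long, is.numeric, logical(1))
  long[num] <- lapply(long[num], function(x) sprintf("%.17g", x))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- S4Vectors::metadata(kym)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       always_decimal = FALSE, pretty = TRUE)
  invisible(path)
}

#' Import a kymograph written by [exportKymograph()]
#'
#' @param path path to the TSV (with its `.meta.json` sidecar) or RDS file.
#' @return A [Kymograph-class].
#' @export
importKymograph <- function(path) {
  if (grepl("\\.rds$", path)) return(readRDS(path))
  long <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("numeric", "character", "integer",
                                           "character", "numeric", "numeric"))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  tt <- sort(unique(long$time))
  lineage <- sort(unique(long$lineage_id))
  states <- unique(long$gene)
  nF <- length(tt); nC <- length(lineage)
  fIdx <- match(long$time, tt)
  cIdx <- match(long$lineage_id, lineage)
  assays <- list()
  for (s in states) {
    m <- matrix(NA_real_, nC, nF, dimnames = list(lineage, NULL))
    sel <- long$gene == s
    m[cbind(cIdx[sel], fIdx[sel])] <- long$concentration[sel]
    assays[[s]] <- m
  }
  mor <- matrix(NA_real_, nC, nF, dimnames = list(lineage, NULL))
  sel <- long$gene == states[1]
  mor[cbind(cIdx[sel], fIdx[sel])] <- long$morphogen[sel]
  assays$morphogen <- mor
  birth <- vapply(lineage, function(l)
    min(long$time[long$lineage_id == l]), numeric(1))
  # cells alive at t = 0 were born at 0; growth births are step-aligned and
  # first appear on the next frame, so the metadata birth time is exact in
  # the sidecar; prefer it when present
  if (!is.null(meta$schedule)) {
    # recompute exact birth times from the schedule
    sch <- meta$schedule
    if (sch$rate > 0) {
      dt <- meta$integrator$dt
      extra <- seq_len(sch$n_final - sch$n0)
      due <- sch$t_start + extra / sch$rate
      birth[sch$n0 + extra] <- ceiling(due / dt - 1e-9) * dt
    } else birth[] <- 0
  }
  rd <- S4Vectors::DataFrame(lineage = lineage, birth = unname(birth),
                             row.names = lineage)
  cd <- S4Vectors::DataFrame(time = tt,
                             row.names = sprintf("f%d", seq_len(nF) - 1L))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rd, colData = cd, metadata = meta)
  new("Kymograph", se)
}

#' Plot a kymograph as stacked space-time images
#'
#' One panel per fate gene: time on the horizontal axis, cells (anterior
#' at the top) on the vertical axis, color intensity proportional to
#' concentration. Intended for quick inspection.
#'
#' @param kym a [Kymograph-class].
#' @param genes genes to draw (default all fate genes).
#' @return Invisibly, `NULL`.
#' @export
plotKymograph <- function(kym, genes = geneNames(kym)) {
  old <- graphics::par(mfrow = c(length(genes), 1),
                       mar = c(2, 3, 1.5, 0.5))
  on.exit(graphics::par(old))
  tt <- frameTimes(kym)
  for (g in genes) {
    m <- geneMatrix(kym, g)
    m[is.na(m)] <- 0
    graphics::image(tt, seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ]),
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    xlab = "", ylab = "cell", main = g, useRaster = TRUE)
  }
  invisible(NULL)
}
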