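#' @include AllClasses.R
NULL

#' Saturating regulatory response
#'
#' The logistic response used for every production term: a strictly
#' increasing, continuously differentiable sigmoid of the summed regulatory
#' input, with limits 0 and 1 and value 1/2 at zero input.
#'
#' @param u regulatory input (finite; vectorized).
#' @param kSig positive steepness.
#' @return `1 / (1 + exp(-kSig * u))`.
#' @examples
#' regulatoryResponse(0, 20)          # 0.5
#' regulatoryResponse(1e6, 20)        # 1
#' @export
regulatoryResponse <- function(u, kSig = 20) {
  if (!is.numeric(kSig) || length(kSig) != 1 || kSig <= 0)
    stop("kSig must be a positive scalar")
  if (!is.numeric(u) || any(!is.finite(u)))
    stop("invalid regulatory input: u must be finite")
  1 / (1 + exp(-kSig * u))
}

.mergeParams <- function(defaults, params) {
  if (is.null(params)) return(defaults)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter override(s): ", paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  defaults
}

.defaultGeneNames <- function(n) paste0("g", seq_len(n))

.newNetwork <- function(family, geneNames, W_dyn, W_stat, rho, h_dyn, h_stat,
                        R, lam0, lam1, k_sig, M_max, timer = list()) {
  new("GeneNetwork", family = family, geneNames = geneNames,
      W_dyn = W_dyn, W_stat = W_stat, rho = rho,
      h_dyn = h_dyn, h_stat = h_stat, R = R, lam0 = lam0, lam1 = lam1,
      k_sig = k_sig, M_max = M_max, timer = timer)
}

#' Build a French Flag network
#'
#' The morphogen activates gene i with strength `rho[i]`, strictly
#' decreasing in i, against a common bias `-theta`, so gene i's steady
#' activation requires `M > theta / rho[i]`: thresholds increase with gene
#' index. Later genes repress earlier ones with graded weights
#' `w(i, j) = wScale * theta * (rho[i]/rho[j] - 1) + wMin` (the more
#' strongly activated a gene, the more repression it receives from each
#' gene above it), which keeps the steady dominant fate a non-decreasing
#' staircase in M with no spurious winners at domain boundaries.
#'
#' Defaults (`n = 5`): `rho = 3 * (5:1)`, `theta = 2.4`, giving threshold
#' morphogen levels 0.16, 0.2, 0.267, 0.4 and 0.8. The last gene of the
#' speed-regulation cascades is absorbing because its self-activation
#' exceeds the cascade bias and nothing represses it.
#'
#' @param nGenes number of fate genes (>= 1).
#' @param params optional named list of overrides: `beta` (activation scale),
#'   `theta`, `wScale`, `wMin`, `R`, `lam0`, `kSig`, `MMax`, `rho`,
#'   `geneNames`.
#' @return A [GeneNetwork-class] with `family = "FF"`.
#' @examples
#' net <- buildFF(3)
#' netFamily(net)
#' @export
buildFF <- function(nGenes = 5, params = list()) {
  .buildThresholdNet(nGenes, params, timerDriven = FALSE)
}

.buildThresholdNet <- function(nGenes, params, timerDriven, tEndScenario = 100) {
  if (!is.numeric(nGenes) || nGenes < 1) stop("nGenes must be >= 1")
  nGenes <- as.integer(nGenes)
  p <- .mergeParams(list(beta = 3, theta = 2.4, wScale = 2.5, wMin = 1,
                         R = 1, lam0 = 1, kSig = 20, MMax = 1,
                         rho = NULL, geneNames = NULL,
                         kappa = NULL, lamT = 0, TRef = 1), params)
  for (nm in c("beta", "theta", "wScale", "wMin", "R", "kSig", "MMax"))
    if (p[[nm]] <= 0) stop(nm, " must be positive")
  if (p$lam0 < 0) stop("lam0 must be >= 0")
  rho <- if (is.null(p$rho)) p$beta * (nGenes:1) else p$rho
  W <- matrix(0, nGenes, nGenes)
  for (i in seq_len(nGenes)) for (j in seq_len(nGenes)) if (j > i)
    W[i, j] <- -(p$wScale * p$theta * (rho[i] / rho[j] - 1) + p$wMin)
  nm <- if (is.null(p$geneNames)) .defaultGeneNames(nGenes) else p$geneNames
  if (timerDriven) {
    kappa <- if (is.null(p$kappa)) 2 * p$TRef / (p$MMax * tEndScenario) else p$kappa
    .newNetwork("FFTG", c(nm, "timer"), W, NULL, rho,
                rep(-p$theta, nGenes), rep(0, nGenes),
                rep(p$R, nGenes), rep(p$lam0, nGenes), rep(0, nGenes),
                p$kSig, p$MMax,
                timer = list(kappa = kappa, lam_T = p$lamT, T_ref = p$TRef))
  } else {
    .newNetwork("FF", nm, W, NULL, rho,
                rep(-p$theta, nGenes), rep(0, nGenes),
                rep(p$R, nGenes), rep(p$lam0, nGenes), rep(0, nGenes),
                p$kSig, p$MMax)
  }
}

#' Build a French Flag network with a Timer Gene
#'
#' Fate-gene wiring identical to [buildFF()], except that the graded drive
#' `rho[i]` multiplies the normalized timer `T / T_ref` instead of the
#' morphogen. The timer obeys `dT/dt = kappa * M - lam_T * T` with
#' negligible decay (`lam_T = 0` by default), so it integrates morphogen
#' exposure; its accumulated level is what the fate thresholds read.
#'
#' The default timer gain is calibrated to the scenario duration:
#' `kappa = 2 * T_ref / (M_max * tEndScenario)`, so a cell held at the
#' posterior pole reaches `T_ref` around half the scenario, leaving the
#' late fates time to equilibrate before the end.
#'
#' @inheritParams buildFF
#' @param tEndScenario scenario end time used to calibrate the timer gain.
#' @param params as in [buildFF()], plus `kappa`, `lamT`, `TRef`.
#' @return A [GeneNetwork-class] with `family = "FFTG"`; its state vector
#'   has `nGenes + 1` entries, the timer last.
#' @export
buildFFTG <- function(nGenes = 5, tEndScenario = 100, params = list()) {
  .buildThresholdNet(nGenes, params, timerDriven = TRUE,
                     tEndScenario = tEndScenario)
}

.cascadeWiring <- function(n, aFwd, rBack, sDyn, sLast, h1, thD) {
  Wd <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1) Wd[i, i - 1] <- aFwd
    if (i < n) Wd[i, (i + 1):n] <- -rBack
  }
  diag(Wd) <- sDyn
  Wd[n, n] <- sLast
  list(Wd = Wd, hd = c(h1, rep(-thD, n - 1)))
}

#' Build a two-module Speed Regulation network
#'
#' The dynamic module is a one-way genetic cascade: each gene weakly
#' self-activates (`sDyn`), is activated by its predecessor (`aFwd`),
#' and is repressed by every later gene (`rBack`); gene 1 is
#' constitutively primed (`h1 > 0`) so the cascade self-starts wherever
#' the morphogen is present, and the last gene is absorbing. The static
#' module is a multistable mutually exclusive network (self-activation
#' `sAct`, mutual repression `sRep`, bias `-thS` keeping naive cells off).
#' The normalized morphogen `m = clip(M / M_max, 0, 1)` mixes the two
#' modules convexly inside a single sigmoid: the cascade runs fast at high
#' m, slows as the stabilizing static module gains weight, and freezes
#' below m of roughly 0.14 where whichever fate a cell holds is locked.
#'
#' The default production/decay scale `R = lam0 = 0.2` paces one fate
#' transition at roughly 3 time units at the pole, so the full sequence
#' spans an elongating tissue's active-zone residence time.
#'
#' @param nGenes number of fate genes (>= 2; a cascade needs at least two).
#' @param params optional overrides: `aFwd`, `rBack`, `sDyn`, `sLast`, `h1`,
#'   `thD`, `sAct`, `sRep`, `thS`, `R`, `lam0`, `kSig`, `MMax`, `geneNames`.
#' @return A [GeneNetwork-class] with `family = "SR2M"`.
#' @export
buildSRTwoModule <- function(nGenes = 5, params = list()) {
  if (!is.numeric(nGenes) || nGenes < 2)
    stop("a cascade needs at least 2 genes")
  nGenes <- as.integer(nGenes)
  p <- .mergeParams(list(aFwd = 24, rBack = 15, sDyn = 10.4, sLast = 11,
                         h1 = 3.5, thD = 9.6, sAct = 2, sRep = 2,
                         thS = 0.4, R = 0.2, lam0 = 0.2, kSig = 20,
                         MMax = 1, geneNames = NULL), params)
  for (nm in c("aFwd", "rBack", "sDyn", "sLast", "h1", "thD", "sAct",
               "sRep", "thS", "R", "kSig", "MMax"))
    if (p[[nm]] <= 0) stop(nm, " must be positive")
  cw <- .cascadeWiring(nGenes, p$aFwd, p$rBack, p$sDyn, p$sLast, p$h1, p$thD)
  Ws <- matrix(-p$sRep, nGenes, nGenes)
  diag(Ws) <- p$sAct
  nm <- if (is.null(p$geneNames)) .defaultGeneNames(nGenes) else p$geneNames
  .newNetwork("SR2M", nm, cw$Wd, Ws, rep(0, nGenes), cw$hd,
              rep(-p$thS, nGenes), rep(p$R, nGenes), rep(p$lam0, nGenes),
              rep(0, nGenes), p$kSig, p$MMax)
}

#' Build a decay-modulation Speed Regulation network
#'
#' The same one-way genetic cascade topology as the dynamic module of
#' [buildSRTwoModule()] -- here as a pulse relay (sub-latch self-activation
#' and moderate back-repression, so a re-induced wave can overrun a
#' resident terminal fate) and with no static module: instead the
#' normalized morphogen
#' `m = clip(M / M_max, 0, 1)` multiplies both the production and the decay
#' term, `dg_i/dt = m * R_i * phi(u_i) - (lam0_i + lam1_i * m) * g_i`. With
#' `lam0 = 0` (the default) the morphogen is a literal clock multiplier:
#' trajectories at morphogen level m are exactly the m = 1 trajectories
#' with time dilated by 1/m, and dynamics freeze completely at m = 0.
#'
#' @inheritParams buildSRTwoModule
#' @param params overrides: `aFwd`, `rBack`, `sDyn`, `sLast`, `h1`, `thD`,
#'   `R`, `lam0`, `lam1`, `kSig`, `MMax`, `geneNames`.
#' @return A [GeneNetwork-class] with `family = "SRDM"`.
#' @export
buildSRDecayMod <- function(nGenes = 5, params = list()) {
  if (!is.numeric(nGenes) || nGenes < 2)
    stop("a cascade needs at least 2 genes")
  nGenes <- as.integer(nGenes)
  p <- .mergeParams(list(aFwd = 24, rBack = 9, sDyn = 5, sLast = 11,
                         h1 = 3.5, thD = 9.6, R = 0.2, lam0 = 0,
                         lam1 = 0.2, kSig = 20, MMax = 1,
                         geneNames = NULL), params)
  for (nm in c("aFwd", "rBack", "sLast", "h1", "thD", "R", "lam1",
               "kSig", "MMax"))
    if (p[[nm]] <= 0) stop(nm, " must be positive")
  if (p$sDyn < 0) stop("sDyn must be >= 0")
  if (p$lam0 < 0) stop("lam0 must be >= 0")
  cw <- .cascadeWiring(nGenes, p$aFwd, p$rBack, p$sDyn, p$sLast, p$h1, p$thD)
  nm <- if (is.null(p$geneNames)) .defaultGeneNames(nGenes) else p$geneNames
  .newNetwork("SRDM", nm, cw$Wd, NULL, rep(0, nGenes), cw$hd,
              rep(0, nGenes), rep(p$R, nGenes), rep(p$lam0, nGenes),
              rep(p$lam1, nGenes), p$kSig, p$MMax)
}

## ---- accessors ----

#' @rdname netFamily
#' @export
setMethod("netFamily", "GeneNetwork", function(x) x@family)

#' @rdname nGenes
#' @export
setMethod("nGenes", "GeneNetwork", function(x) length(x@rho))

#' @rdname geneNames
#' @export
setMethod("geneNames", "GeneNetwork",
          function(x) x@geneNames[seq_len(nGenes(x))])

#' Number of state variables of a network
#'
#' `nGenes` plus one for the FFTG timer.
#' @param network a [GeneNetwork-class].
#' @return Integer scalar.
#' @export
nStates <- function(network) {
  nGenes(network) + as.integer(network@family == "FFTG")
}

#' Detection and half-maximal expression levels
#'
#' The detection threshold `epsilonG` defaults to 30% of the maximal
#' attainable concentration (`R / lam0`, or `R / lam1` for the
#' decay-modulation family), mimicking in-situ visibility; `halfMaxLevel`
#' is half of that maximum and is the default onset level of
#' [activationTimes()].
#'
#' @param network a [GeneNetwork-class].
#' @return Numeric scalar.
#' @export
detectionThreshold <- function(network) 0.3 * .maxLevel(network)

#' @rdname detectionThreshold
#' @export
halfMaxLevel <- function(network) 0.5 * .maxLevel(network)

.maxLevel <- function(network) {
  lam <- network@lam0 + network@lam1   # decay at full morphogen
  if (any(lam <= 0)) stop("network has a gene with no decay at full morphogen")
  max(network@R / lam)
}

## ---- derivative ----

#' @rdname derivative
#' @export
setMethod("derivative", "GeneNetwork", function(network, g, M) {
  ns <- nStates(network)
  if (length(g) != ns)
    stop("state vector has length ", length(g), ", expected ", ns)
  if (!all(is.finite(g))) stop("state vector must be finite")
  if (!is.numeric(M) || length(M) != 1 || !is.finite(M) || M < 0)
    stop("M must be a single non-negative number")
  n <- nGenes(network)
  k <- network@k_sig
  phi <- function(u) 1 / (1 + exp(-k * u))
  fam <- network@family
  if (fam == "FF") {
    u <- network@rho * M + drop(network@W_dyn %*% g) + network@h_dyn
    network@R * phi(u) - network@lam0 * g
  } else if (fam == "FFTG") {
    Tn <- g[n + 1] / network@timer$T_ref
    gf <- g[seq_len(n)]
    u <- network@rho * Tn + drop(network@W_dyn %*% gf) + network@h_dyn
    c(network@R * phi(u) - network@lam0 * gf,
      network@timer$kappa * M - network@timer$lam_T * g[n + 1])
  } else if (fam == "SR2M") {
    m <- min(max(M / network@M_max, 0), 1)
    u <- m * (drop(network@W_dyn %*% g) + network@h_dyn) +
      (1 - m) * (drop(network@W_stat %*% g) + network@h_stat)
    network@R * phi(u) - network@lam0 * g
  } else {
    m <- min(max(M / network@M_max, 0), 1)
    u <- drop(network@W_dyn %*% g) + network@h_dyn
    m * network@R * phi(u) - (network@lam0 + network@lam1 * m) * g
  }
})

## ---- parameter dump / core interface ----

#' JSON-serializable parameter dump of a network
#'
#' Captures every parameter needed to rebuild the network, for provenance
#' in kymograph metadata and config manifests.
#'
#' @param network a [GeneNetwork-class].
#' @return A named list of plain vectors/matrices.
#' @export
networkParams <- function(network) {
  list(family = network@family,
       n_genes = nGenes(network),
       gene_names = network@geneNames,
       W_dyn = unname(network@W_dyn),
       W_stat = if (is.null(network@W_stat)) NULL else unname(network@W_stat),
       rho = network@rho, h_dyn = network@h_dyn, h_stat = network@h_stat,
       R = network@R, lam0 = network@lam0, lam1 = network@lam1,
       k_sig = network@k_sig, M_max = network@M_max, timer = network@timer)
}

.familyCode <- function(family)
  match(family, c("FF", "FFTG", "SR2M", "SRDM")) - 1L

.netToCore <- function(network) {
  tm <- network@timer
  list(family_code = .familyCode(network@family),
       n_genes = nGenes(network),
       W_dyn = network@W_dyn, W_stat = network@W_stat,
       rho = network@rho, h_dyn = network@h_dyn, h_stat = network@h_stat,
       R = network@R, lam0 = network@lam0, lam1 = network@lam1,
       k_sig = network@k_sig, M_max = network@M_max,
       kappa = if (is.null(tm$kappa)) 0 else tm$kappa,
       lam_T = if (is.null(tm$lam_T)) 0 else tm$lam_T,
       T_ref = if (is.null(tm$T_ref)) 1 else tm$T_ref)
}

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork of family", object@family, "with", nGenes(object),
      "fate genes\n")
  cat("  genes:", paste(object@geneNames, collapse = ", "), "\n")
  cat("  R =", object@R[1], " lam0 =", object@lam0[1],
      if (object@family == "SRDM") paste(" lam1 =", object@lam1[1]) else "",
      " k_sig =", object@k_sig, "\n")
  if (object@family == "FFTG")
    cat("  timer: kappa =", object@timer$kappa, " lam_T =",
        object@timer$lam_T, " T_ref =", object@timer$T_ref, "\n")
})
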