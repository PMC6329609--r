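#' @include config.R
NULL

.presets <- function() {
  base <- defaultConfig()
  mod <- function(cfg, extra = list(), ...) {
    cfg <- .mergeConfig(cfg, extra)
    cfg <- .mergeConfig(cfg, list(...))
    class(cfg) <- c("segwaveConfig", "list")
    cfg
  }
  interGerm <- list(morphogen = list(regime = "composite", xi = 14,
                                     t_germband = 6),
                    growth = list(n0 = 50L, n_final = 100L, t_start = 6,
                                  rate = 1),
                    integrator = list(t_end = 100))
  reProtocol <- list(list(type = "reinduce", gene = 1L, t_on = 70,
                          t_off = 76, amplitude = 2, mode = "additive"))
  list(
    # threshold readout of a sustained static gradient: converges
    ff_static = mod(base, model = list(family = "FF"),
                    morphogen = list(regime = "static", xi = 10),
                    integrator = list(t_end = 60),
                    analysis = list(windows = list(c(50, 60)))),
    # gradient buildup accentuates the transient waves
    ff_buildup = mod(base, model = list(family = "FF"),
                     morphogen = list(regime = "buildup", xi = 10,
                                      tau_build = 10),
                     integrator = list(t_end = 80),
                     analysis = list(windows = list(c(70, 80)))),
    # sustained gradient: domains keep shrinking anteriorly, no steady state
    sr2m_static = mod(base,
                      morphogen = list(regime = "static", xi = 10),
                      integrator = list(t_end = 260)),
    # decaying gradient freezes the pattern
    sr2m_decaying = mod(base,
                        morphogen = list(regime = "decaying", xi = 10,
                                         t_decay_start = 10, tau_decay = 8),
                        integrator = list(t_end = 100),
                        analysis = list(windows = list(c(90, 100)))),
    sr2m_buildup_decay = mod(base,
                             morphogen = list(regime = "buildup_decay",
                                              xi = 10, tau_build = 8,
                                              t_decay_start = 25,
                                              tau_decay = 8),
                             integrator = list(t_end = 100),
                             analysis = list(windows = list(c(90, 100)))),
    # germ-type scenarios (two-module speed regulation)
    germ_short = mod(base,
                     morphogen = list(regime = "composite", xi = 14,
                                      t_germband = 0),
                     growth = list(n0 = 50L, n_final = 100L, t_start = 0,
                                   rate = 1),
                     integrator = list(t_end = 100)),
    germ_intermediate = mod(base, interGerm),
    germ_long = mod(base,
                    morphogen = list(regime = "decaying", xi = 20,
                                     t_decay_start = 10, tau_decay = 6),
                    growth = list(n0 = 100L, n_final = 100L, rate = 0),
                    integrator = list(t_end = 100)),
    # decay-modulation speed regulation, intermediate germ
    srdm_patterning = mod(base, interGerm, model = list(family = "SRDM")),
    # leading-gene re-induction during intermediate-germ patterning
    sr2m_reinduction = mod(base, interGerm, protocol = reProtocol),
    fftg_reinduction = mod(base, interGerm, model = list(family = "FFTG"),
                           protocol = list(list(type = "reinduce",
                                                gene = 1L, t_on = 70,
                                                t_off = 76, amplitude = 10,
                                                mode = "additive"))),
    srdm_reinduction = mod(base, interGerm,
                           model = list(family = "SRDM",
                                        params = list(lam0 = 0.002)),
                           protocol = reProtocol),
    # posteriorized (axn-RNAi-like) morphogen: whole embryo an active zone
    axn_rnai = mod(base,
                   morphogen = list(regime = "composite", xi = 14,
                                    t_germband = 0),
                   growth = list(n0 = 50L, n_final = 100L, t_start = 0,
                                 rate = 1),
                   integrator = list(t_end = 60),
                   protocol = list(list(type = "morphogen_override",
                                        program = list(regime = "axn",
                                                       M_amp = 1, xi = 10,
                                                       tau_build = NA,
                                                       t_decay_start = NA,
                                                       tau_decay = NA,
                                                       t_germband = NA,
                                                       xi_axn = 1000),
                                        from = 0))),
    axn_reinduction = mod(base,
                          morphogen = list(regime = "composite", xi = 14,
                                           t_germband = 0),
                          growth = list(n0 = 50L, n_final = 100L,
                                        t_start = 0, rate = 1),
                          integrator = list(t_end = 60),
                          protocol = list(list(type = "morphogen_override",
                                               program = list(regime = "axn",
                                                              M_amp = 1,
                                                              xi = 10,
                                                              tau_build = NA,
                                                              t_decay_start = NA,
                                                              tau_decay = NA,
                                                              t_germband = NA,
                                                              xi_axn = 1000),
                                               from = 0),
                                          list(type = "reinduce", gene = 1L,
                                               t_on = 40, t_off = 46,
                                               amplitude = 2,
                                               mode = "additive"))),
    # seeded ensemble scoring of the re-induction experiment
    hs_quantification = mod(base, interGerm, protocol = reProtocol,
                            integrator = list(dt = 0.002),
                            ensemble = list(size = 15L, seed = 4712L),
                            analysis = list(windows = list(c(60, 68),
                                                           c(80, 88),
                                                           c(88, 96))))
    # pulse 70-76; windows: pre-pulse, first post-pulse, later post-pulse
  )
}

#' Names of the built-in scenario presets
#' @return Character vector.
#' @export
presetNames <- function() names(.presets())

#' Configuration of a built-in scenario preset
#'
#' @param name one of [presetNames()].
#' @return An effective configuration usable with [runScenario()].
#' @export
presetConfig <- function(name) {
  ps <- .presets()
  if (!name %in% names(ps))
    stop("unknown preset '", name, "'; see presetNames()")
  ps[[name]]
}
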