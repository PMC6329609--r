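# segwave

Deterministic gene-network simulators for anterior–posterior (AP) axial
patterning, built to contrast **threshold-based** with **threshold-free**
mechanisms of morphogen interpretation.

In insect segmentation, gap genes partition the trunk into ordered fate
domains under a posteriorly localized morphogen gradient (the *caudal*
abstraction). Two mechanisms can produce the same final stripes:

* **French Flag (FF)**: morphogen concentration thresholds
  `M > theta / rho_i` set domain boundaries; expression is transiently
  dynamic but settles into a steady threshold readout. A variant, the
  **French Flag with a Timer Gene (FFTG)**, reads the thresholds from a
  near-non-decaying timer `dT/dt = kappa M` that integrates morphogen
  exposure, letting a threshold mechanism pattern elongating tissues too.
* **Speed Regulation (SR)**: every cell can step through the whole fate
  sequence; the morphogen only sets the *speed*. Domains are kinematic
  waves that never reach a steady state while the gradient persists.
  Two molecular realizations are implemented: **SR2M**, a dynamic cascade
  module and a static multistable module mixed convexly by the normalized
  morphogen `m`, and **SRDM**, a cascade whose production *and* decay are
  both multiplied by `m`, making morphogen a literal clock multiplier
  (`g(t; m) = g(m t; 1)` exactly).

All four families share one per-cell ODE form,
`dg_i/dt = R_i * phi(u_i) - lambda_i * g_i` with a logistic response
`phi`, integrated by a deterministic fixed-step RK4 core (Rcpp) over 1-D
fields of autonomous cells, with posterior growth, timed perturbations
(ubiquitous re-induction of the leading gene, RNAi, a posteriorized
embryo-covering gradient), and pattern analytics: fate maps, boundaries,
steady-state diagnostics, onset/wave statistics, region partitions
(active zone / anterior / heat-shock anterior), a reset assay that
classifies a run as `threshold_free` or `threshold_based`, and
region-based scoring of simulated embryo ensembles with binomial standard
errors `sqrt(p(1-p)/n)`.

Kymographs are `SummarizedExperiment` objects: rows are cell lineages,
columns are time frames, one assay per gene plus the recorded morphogen.

See the methods vignette
(`vignettes/speed-regulation-patterning.Rmd`) for the model equations,
parameter rationale, numerical conventions and limitations.

## Worked example

```r
library(segwave)

net <- buildSRTwoModule(5)
net
#> GeneNetwork of family SR2M with 5 fate genes
#>   genes: g1, g2, g3, g4, g5
#>   R = 0.2  lam0 = 0.2   k_sig = 20

# the morphogen sets the speed of the fate sequence: half-max onset times
# of the five genes in a single cell, at three morphogen levels
lvl <- halfMaxLevel(net)
for (m in c(1, 0.5, 0.25)) {
  tr <- integrateCell(net, m, tEnd = 120, dt = 0.005)
  on <- apply(tr, 2, function(x) {
    i <- which(x >= lvl)[1]
    if (is.na(i)) NA else (i - 1) * 0.1
  })
  cat(sprintf("m = %.2f  onsets: %s\n", m, paste(on, collapse = "  ")))
}
#> m = 1.00  onsets: 3.5  6.1  8.6  11.2  13.7
#> m = 0.50  onsets: 3.5  6.5  10.2  14.2  18.2
#> m = 0.25  onsets: 3.5  7.9  17.2  24.9  31.7

# intermediate-germ scenario with a transient re-induction of the leading
# gene at t = 70: the reset assay compares perturbed vs control runs
run <- runScenario("sr2m_reinduction")
run$resetReport
#> ResetReport: threshold_free
#>   anterior erased:       TRUE
#>   sequence re-induced:   TRUE
#>   final pattern restored: FALSE
#>   anterior fate loss:    1

fateSequence(dominantFate(run$control, 100))
#> [1] 1 2 3 4 5
```

The onsets are strictly ordered at every morphogen level and shift later
as `m` drops — the kinematic-wave signature. The reset assay reads: the
already-formed anterior pattern was erased (all non-leader genes fell
below detection in ≥ 90% of heat-shock-anterior cells), the full ordered
onset sequence recurred inside the active zone where the control shows no
such re-run, and consequently the final pattern was *not* restored — the
threshold-free verdict. Running the same protocol on the `fftg_reinduction`
preset instead returns `threshold_based` (pattern restored after a brief
dominance of the leader), and `srdm_reinduction` resets the active zone
while leaving established anterior expression intact (fate loss 0).

Scenario presets (`presetNames()`) cover the static/decaying/building
gradients, the short/intermediate/long germ-type scenarios, the three
re-induction experiments, the posteriorized-gradient (axn-RNAi-like)
phenotype, and a 15-embryo scored ensemble. `runScenario(name, outDir =
...)` writes the kymograph as long-format TSV with a JSON metadata
sidecar, the effective YAML configuration with an md5 manifest, and the
reset report / score CSV where applicable. A thin command-line front end
lives at `inst/scripts/segwave`.

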