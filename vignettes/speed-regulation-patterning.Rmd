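---
title: "Threshold-based and speed-regulated patterning: models and methods"
author: "segwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based and speed-regulated patterning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Insect anterior-posterior (AP) segmentation begins with gap genes, which
divide the trunk into broad fate domains under the control of a
posteriorly localized morphogen gradient (the *caudal* abstraction). Two
fundamentally different mechanisms can produce the same final striped
pattern:

* **Threshold-based (French Flag) patterning**: fixed morphogen
  concentration thresholds set the boundaries between fate domains. Gene
  expression may look dynamic during an initial transient, but it settles
  into a steady state dictated by the thresholds.
* **Threshold-free (Speed Regulation) patterning**: every cell is capable
  of stepping through the whole fate sequence; the morphogen only sets the
  *speed* at which it does so. Domains are kinematic waves that keep
  shrinking and shifting toward the low end of the gradient for as long as
  the gradient persists, and are stabilized only by gradient decay or
  retraction.

The decisive experiment is a *reset*: transiently re-induce the leading
gene of the cascade everywhere (a heat-shock-driven pulse) and watch
whether the sequence restarts (threshold-free: the clock lives in the
cross-regulation of the fate genes themselves) or the normal pattern
simply reasserts itself (threshold-based: the clock is external to the
fate genes). `segwave` implements both mechanisms as explicit gene
regulatory networks (GRNs), simulates them on static and elongating 1-D
cell fields, applies the in-silico perturbations, and quantifies the
outcomes the way embryo ensembles are scored.

## The four network families

All families share one functional form: each gene's production is a
saturating (logistic) response of a weighted sum of regulatory inputs,
bounded by a production ceiling, with linear decay:

$$ \frac{dg_i}{dt} = R_i\,\phi\!\left(u_i\right) - \lambda_i\,g_i,
   \qquad \phi(u) = \frac{1}{1 + e^{-k u}} . $$

The steepness is `k_sig = 20` throughout: steep enough that regulatory
decisions are switch-like, smooth enough that the ODEs are non-stiff and
transition *rates* can grade over orders of magnitude through the
sigmoid's tail -- the mechanism behind graded wave speeds below.
Concentrations, morphogen and time are dimensionless; one time unit is
nominally an hour of beetle development, used only to set protocol presets
(e.g. the 6-unit persistence of the heat-shock product).

### FF -- French Flag (`buildFF`)

The morphogen M activates gene i with strength `rho[i]` (default
`3*(5:1)`) against a common bias `-theta` (`theta = 2.4`), so gene i
requires `M > theta/rho[i]`: thresholds 0.16, 0.2, 0.27, 0.4, 0.8 for the
default five genes. Later (higher-threshold) genes repress earlier ones.
The repression weights are graded,

$$ w_{ij} = w_\text{scale}\,\theta\,(\rho_i/\rho_j - 1) + w_\text{min},
   \qquad w_\text{scale} = 2.5,\; w_\text{min} = 1, $$

so that each gene receives just enough repression from each gene above it
to be silenced wherever that gene wins. This was a genuinely open design
point: with a *uniform* repression weight, a gene that is only half-on at
its own threshold represses the genes below it by only half a weight,
and the most strongly activated gene then wins a sliver at every domain
boundary -- the steady fate map is not monotone in M. Grading the weights
by the activation ratio (the wiring diagrams' thicker-line-stronger
convention) removes those slivers; we verified monotonicity of the
steady dominant fate on a fine morphogen grid. With `R = lam0 = 1`, a
50-cell tissue converges below the steady-state tolerance by t of about
22.

### FFTG -- French Flag with a Timer Gene (`buildFFTG`)

Identical fate-gene wiring, but the thresholds read a *timer*
T instead of M: `dT/dt = kappa*M - lam_T*T` with `lam_T = 0` (negligible
decay is the family's defining assumption), and the fate drive is
`rho[i] * T/T_ref`. The timer integrates morphogen exposure, so a
retracting gradient leaves behind a frozen long-range timer gradient that
is read out exactly like a French Flag. The paper-gap here is the timer's
units: we calibrate the gain to the scenario, `kappa = 2*T_ref/tEnd`, so
a cell held at the pole reaches `T_ref` around mid-scenario and the late
fates still have time to equilibrate.

### SR2M -- Speed Regulation by module switching (`buildSRTwoModule`)

Two wirings share the same genes. The *dynamic module* is a one-way
cascade: forward activation by the predecessor (`aFwd = 24`), repression
of every earlier gene by every later one (`rBack = 15`), self-activation
(`sDyn = 10.4`) just above the cascade bias (`thD = 9.6`), a
constitutively primed first gene (`h1 = +3.5`), and an absorbing last
gene (`sLast = 11`). The *static module* is a multistable
winner-take-all network: self-activation `sAct = 2`, mutual repression
`sRep = 2`, bias `-thS = -0.4` that keeps naive cells off. The
normalized morphogen `m = clip(M/M_max, 0, 1)` mixes the two *inside*
one sigmoid:

$$ u_i = m\,(W^\text{dyn} g + h^\text{dyn})_i
       + (1 - m)\,(W^\text{stat} g + h^\text{stat})_i , $$

a convex mixing chosen over a sum of two sigmoids because it keeps every
production bounded by a single ceiling.

Why these numbers? Each inequality pins a behavior, and all of them were
verified by simulation during design:

* `sDyn > thD`: a gene, once on, **latches** at every morphogen level and
  is killed only by its successor's repression. Without the latch
  (weaker self-activation) a mid-gradient resident dies of its own accord
  before the successor locks in, the primed leader re-fires, and the
  cascade cycles instead of terminating.
* `rBack > h1 + sDyn`: the successor's repression beats the strongest
  latch (the primed leader's), so the relay always hands over.
* `sLast > thD`: the terminal gene self-sustains with no successor --
  the sequence ends rather than recycling.
* `sRep >= sAct`: the static module is mutually exclusive, so a frozen
  cell holds exactly one fate.
* `thS >= 0.35`: the all-off state is genuinely off
  (`phi(-k*thS) < 1e-3`).

The successor's net drive, `m(aFwd - thD) - (1-m)(thS + sRep)`, crosses
zero at `m* = 2.4/16.8 = 0.143`: above it the cascade runs at a rate that
rises with m (the sigmoid tail turns the linear drive into
orders-of-magnitude rate differences); below it whatever fate a cell
holds is locked by the static module. Near `m*` transitions slow without
bound (a saddle-node ghost), which is exactly why a sustained gradient
never yields a global steady state: some cell is always mid-transition.

Production and decay are scaled together, `R = lam0 = 0.2`. This joint
rescaling leaves trajectories identical up to exact 5x time dilation; it
is chosen so one fate transition at the pole takes about 3 time units and
the full five-gene sequence (about 14 units) fits inside a cell's
residence time in the active zone of an elongating tissue. With the fast
scale (`R = lam0 = 1`) every germband cell would complete the entire
sequence before leaving the zone and wavefront patterning would collapse
to a single terminal fate.

### SRDM -- Speed Regulation by decay modulation (`buildSRDecayMod`)

The same cascade topology with no static module; instead m multiplies
both production and decay:

$$ \frac{dg_i}{dt} = m\,R_i\,\phi\!\big((W^\text{dyn} g + h^\text{dyn})_i\big)
   - (\lambda_0 + \lambda_1 m)\,g_i , \qquad \lambda_0 = 0 . $$

With `lam0 = 0` the morphogen is a *literal clock multiplier*:
`g(t; m) = g(m t; 1)` exactly, and dynamics freeze completely at `m = 0`.
The cascade parameters differ from SR2M in two deliberate ways. First,
self-activation is sub-latch (`sDyn = 5 < thD`): SRDM's anterior
stability comes from the decay-scaled freezing, not from a latch, so
genes pulse and hand over. Second, back-repression is moderate
(`rBack = 9`): above `h1 + sDyn = 8.5` so the leader still dies on
schedule, but low enough that a re-induced wave can overrun the absorbing
terminal resident -- which SRDM, lacking a static module, has no other
way to erase. (In SR2M the re-induced leader erases residents through
the static module's mutual repression; with SR2M's stronger `rBack` an
SRDM re-run would stall behind its own terminal gene.)

## Morphogen programs, tissue and growth

The morphogen is an imposed field (no transport PDE), exponential in the
distance d from the posterior pole, `M = M_amp * exp(-d/xi)`, with
optional buildup and/or decay factors in time. The `composite` regime is
the same static profile anchored to the *current* pole: retraction is
realized purely by tissue elongation, with no second bookkeeping
mechanism. The posteriorized (`axn`) variant replaces the length scale by
at least ten times the tissue length -- a persistent, embryo-covering,
still-graded field.

Cells are autonomous; they are indexed anterior to posterior and cell c's
distance from the pole with n live cells is `(n - c) - 0.5` (cell-centers
convention, stated here once and used everywhere). Growth appends naive
all-zero cells at the posterior, one per `1/rate` time units, aligned to
the first integration-step boundary at or after the due time. Within one
step a cell's distance is held fixed while the morphogen's time factors
advance; `integrateCell()` reproduces this convention exactly, which is
what makes the cell-autonomy check an identity to near machine precision
rather than an approximation.

The default gradient length scale is 20% of the tissue for non-growing
scenarios (`xi = 10` on 50 cells, 20 on 100). Elongating presets use
`xi = 14`: residence time in the active zone is `xi * ln(1/0.143) / rate`
(about 27 time units), which must comfortably exceed the full sequence
time under a receding gradient (about 19 units); at `xi = 10`-12 a
germband-born cell stalls one fate short of terminal and the germ-type
scenarios no longer agree.

## Numerical choices

* Fixed-step classical Runge-Kutta (order 4), default `dt = 0.001`,
  output every `dt_out = 0.1`. The kinetics are non-stiff by
  construction; fixed stepping buys bit-for-bit determinism and exact
  reproducibility of per-cell re-integration. Halving `dt` moves
  trajectories by less than 1e-6, and an independent adaptive stiff
  solver (deSolve's `lsoda`) agrees to the same tolerance.
* Pulse forcing acts on `[t_on, t_off)`; a step ending exactly at `t_on`
  is untouched (so pre-pulse frames of perturbed and control runs are
  bitwise identical), and a step ending exactly at `t_off` still sees the
  forcing. Clamp events pin the concentration after each full step inside
  the window.
* Onset (activation) times are reported at output-frame resolution: the
  first frame at which a gene reaches half-maximal expression from below.
  Frame quantization makes onset comparisons across conditions robust to
  sub-frame jitter.
* Dominant-fate ties break toward the lower gene index; cells below the
  detection threshold are "none"; cells not yet born are `NA` -- a
  sentinel distinct from concentration zero, with birth times carried in
  `rowData`.
* Detection thresholds: `epsilon_g = 0.3 * max(R/(lam0 + lam1))` (30% of
  the maximal attainable concentration, an in-situ-visibility analogue)
  and `epsilon_m = 0.1 * M_max` for the active zone (the
  morphogen-expressing region; the simulator has no germband morphology,
  so the zone is defined by the field itself). Both are conventions, both
  are arguments everywhere they are used.
* Numerical blow-up (|g| > 1e6) aborts with the offending time, cell and
  state named.

## The reset assay, operationally

`resetAssay()` compares a perturbed run against its control:

* **anteriorErased** -- at the erasure horizon (pulse end plus two decay
  times, capped at the end of the run), at least 90% of
  heat-shock-anterior cells have every non-leader gene below detection.
* **sequenceReinduced** -- some active-zone lineage born before the pulse
  shows ordered post-pulse onsets of the leader plus every gene that was
  below half-max at pulse onset, *and* at least one of those non-leader
  genes never comes back on in the control. The second clause is what
  makes the flag diagnostic: the pulse itself trivially gives the leader
  an onset, and in timer-driven tissue the remaining fates would have
  fired anyway.
* **finalPatternRestored** -- final dominant-fate maps differ in fewer
  than 5% of cells.
* **anteriorFateLoss** -- among heat-shock-anterior cells whose control
  fate is a non-leader gene, the fraction whose fate gene is below
  detection at the end of the perturbed run. This is the
  established-expression metric that separates the two speed-regulation
  realizations: module switching erases the anterior (loss near 1),
  decay modulation leaves it intact (loss near 0), because a
  morphogen-free SRDM cell can neither produce nor degrade.

Classification: `threshold_free` if the sequence was re-induced,
`threshold_based` if the final pattern was restored without re-induction,
otherwise `mixed`.

Re-induction presets pulse at t = 70, after elongation has ended and the
early-gene sequence has passed the active zone -- the in-silico analogue
of heat-shocking when the zone is void of early gap expression. The
default pulse is additive (production +`10*R` for 6 time units, decaying
naturally afterwards); clamp semantics are provided because whether the
endogenous locus stays pulse-responsive is not something the models
decide. For SRDM perturbation presets a small basal decay
(`lam0 = 0.002`, i.e. 1% of `lam1`) is enabled so the exogenous product
clears even in morphogen-free cells.

## The embryo-ensemble generator

`simulateEnsemble()` is the package's synthetic-data source for the
scoring pipeline. Deterministic simulations give degenerate detection
proportions (0 or 1), whereas scored egg collections reflect
embryo-to-embryo variability, so each replicate embryo receives
multiplicative log-normal jitter (sigma = 0.15) on its production
ceilings (and on the activation strengths where the family uses them),
and Gaussian observation noise (sigma = 0.05) is added to recorded
concentrations. The ensemble size default, 15, is a typical egg
collection. All randomness flows from one mandatory seed.

What this emulates -- parameter variability and measurement noise around
a shared deterministic program -- and what it does not: no stochastic
gene expression (the ODE core is deterministic by design), no
embryo-to-embryo differences in geometry or staging, no spatial noise
correlations. Passing scores therefore show that the *scoring pipeline*
(region partition, detection, proportions, standard errors) behaves as
intended under realistic variability, not that the models capture real
embryos' noise structure.

`scoreRegions()` counts, per time window, region and gene, the proportion
of embryos with any above-threshold cell in the region, with the binomial
standard error `sqrt(p(1-p)/n)`. Regions follow the experimental
definitions: the active zone and anterior are taken at the window start;
the heat-shock anterior is the anterior as of the pulse onset, tracked by
lineage.

## Problem sizes

The shipped presets use 50 blastoderm cells (growing to 100 where the
scenario elongates), five fate genes, run lengths of 60-260 time units,
and 15-embryo ensembles -- sizes at which every preset completes in
seconds on one CPU (the ensemble preset uses `dt = 0.002`, where the
integration error is still orders of magnitude below every tolerance
used). Larger fields and longer horizons only make the qualitative
contrasts sharper; the single-cell analyses above are size-independent.

## Known limitations

* The five-gene cascade is an abstraction: real gap genes have repeated
  (second trunk) domains and interact with the pair-rule tier; neither is
  modeled.
* The FFTG blastoderm-to-germband handoff leaves a small non-monotonic
  seam in the final fate map (late blastoderm cells accumulate a timer
  head start relative to early germband cells); per-cell onset order is
  unaffected.
* The morphogen is imposed, not transported; cells neither move nor
  divide asymmetrically; there is no diffusive coupling -- all by design,
  to keep the patterning logic cell-autonomous and auditable.
* Parameter defaults are one calibrated realization per family. The
  qualitative contracts (sequential onsets, monotone speed in m,
  multistability, the reset dichotomy) hold over substantial
  neighborhoods, but the defaults are not fits to measured rates.
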