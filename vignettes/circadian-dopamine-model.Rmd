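---
title: "The circadian clock / dopamine model: methods and numerical choices"
author: "circadopa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The circadian clock / dopamine model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

`circadopa` simulates a deterministic, single-cell model of the mammalian
circadian clock and its downstream influence on three dopaminergic
variables. Sixteen coupled ODEs, all concentrations in nM and rates in
nM/hr, organized in three interlocking blocks:

**Core clock.** The BMAL1-CLOCK heterodimer ($BC$) drives transcription of
Period and Cryptochrome. Cytosolic PER passes through four phosphorylation
stages $P_1 \ldots P_4$; $P_4$ binds cytosolic CRY ($C$) to form $PC$,
which enters the nucleus as $PC_N$ and also dissociates there into nuclear
PER ($P_N$) and nuclear CRY ($C_N$). Repression is two-fold:

* *Sequestration.* $PC_N$ binds $BC$ stoichiometrically with dissociation
  constant $K_d$. The active fraction of the activator is the free
  fraction
  $$BC_{fr} = f(BC, PC_N, K_d), \qquad
    f(P, I, D) = \frac{P - I - D + \sqrt{(P-I-D)^2 + 4DP}}{2P},$$
  the positive root of the one-site binding quadratic.
* *Direct repression by nuclear CRY.* Every $BC$-driven production term is
  multiplied by $\mathcal{F}(C_N) = \rho_c / (1 + k_c C_N)^{n_c}$, which
  decreases from $\rho_c$ toward zero.

**Secondary loop.** $BC_{fr}$ drives the orphan nuclear receptors REV-ERB
(Hill term $\mathcal{G}_1$, exponent $n = 2$, half-saturation
$\kappa_{rev}$) and ROR (Michaelis term $\mathcal{G}_2$, half-saturation
$\kappa$). REV-ERB and ROR compete at the RORE element of the Bmal1
promoter: with $f_s = f(S, REV, \epsilon_s)$ the fraction of Bmal1 ($S$)
not bound by REV-ERB, production of $S$ is
$$\frac{dS}{dt} = \beta
  + \underbrace{\frac{\rho_s}{(1 + k_s(1 - f_s))^{n_s}}}_{\text{repression}}
  + \underbrace{\alpha_s f_s \frac{ROR}{ROR + \kappa_s}}_{\text{activation}}
  - d_s S,$$
and $BC$ integrates $S$ slowly ($dBC/dt = \beta_{bc} S - d_{bc} BC$,
a 10-hour time constant that is important below).

**Dopaminergic block.** Tyrosine hydroxylase ($TH$, rate-limiting for
dopamine synthesis) and the D3 receptor ($DRD3$) carry the same
REV-ERB/ROR competition kernel with their own constants; monoamine oxidase
($MAO$, dopamine degradation) is produced in direct proportion to
$\mathcal{F}(C_N)\,BC_{fr}$ and turns over very slowly
($d_m = 0.016$/hr, a ~62 hr time constant). These variables are read-outs:
they do not feed back on the clock.

**Light.** A 12:12 light-dark day enters as the sinusoid
$\ell(t) = \xi \sin(\pi t / 12) + 1$ with $\xi = 2/3$, multiplying only
the light-induced $P_1$ production term. Simulation time is
Zeitgeber-anchored: $t \bmod 24$ is ZT, lights-on at ZT0, $\ell$ maximal
at ZT6, dark spanning ZT12--24.

The ~50 rate and shape constants ship as the defaults of
`clock_params()`; they are the model's reference values and are not fit by
this package.

## Numerical choices

**Free-fraction kernel.** $f$ has two removable singularities that the
reference parameter set actually reaches. At $P = 0$ the formula is $0/0$;
we use the analytic limit $f \to D/(D+I)$ (and 1 when $I = D = 0$). The
REV-ERB/Bmal1 dissociation constant is exactly $\epsilon_s = 0$
(tight binding), for which $f = \max(0, 1 - I/P)$. When $P - I - D < 0$
the root is evaluated in the rationalized form $2D / (\sqrt{\cdot} - (P-I-D))$
to avoid cancellation. Inside the integrator the kernel clamps the tiny
negative excursions a tolerance-controlled solver can produce.

**Integration.** `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`,
dense output every 0.05 hr. The system is mildly stiff (time constants
from ~20 minutes for $S$ to ~62 hr for MAO). The test suite cross-checks a
48-hr trajectory against an independent fixed-step classical Runge-Kutta
integration at $dt = 10^{-3}$ hr (sup-norm agreement below $10^{-4}$
relative) and checks tolerance-halving convergence.

**Entrainment.** `entrain_clock()` integrates day by day and declares
convergence when the sup-norm difference between consecutive 24-hr cycles,
relative to each variable's peak, falls below `cycle_tol = 1e-4` for *all
16 variables* — MAO is always the binding constraint. The default minimum
burn-in of 40 days leaves a residual near $10^{-7}$; the residual history
is stored on the returned trajectory for diagnosis.

**Initial conditions and multistability.** The model does not specify
initial conditions; the convention is every state at 0.1 nM. While
exploring robustness we found that the light-forced system is
*multistable*: starts far from the convention (e.g. drawn uniformly on
$[0,4]^{16}$) can lock onto a secondary 24-hr entrained solution whose PER
peak sits about 1.3 hr earlier. The conventional start selects the branch
on which all of the model's published behaviour lives, and moderate
perturbations of it (tested up to a factor $e^{\pm 1}$ per state) return
to that cycle. Anyone changing parameters substantially should re-check
which branch they are on (compare `peak_time(ent, "P1")` against ~ZT3.8).

**Constant darkness.** "DD" is implemented as a constant multiplier
`dd_level`, default 1 — the sinusoid's mean, which removes the modulation
without changing the mean drive. The free-running period under this
convention is ~16.5 hr, shorter than 24 hr as expected for the mouse
oscillator, though the shortfall is strongly level-dependent
(`dd_level = 0.2` gives ~23.3 hr); only the inequality, not the magnitude,
should be read as a model prediction. The free-running cycle needs ~3-4
weeks to settle after release from LD before per-variable period estimates
agree.

## Perturbation protocols

**CRY deficiency** multiplies the CRY production rate `r5` by
$1 - \text{knockdown}$ (default 95%, `r5` $5 \to 0.25$). Under LD the
clock stays rhythmic with elevated PER; under DD it collapses to a fixed
point (near-constant PER), reproducing the arrhythmicity of Cry-null
mutants.

**REV-ERB agonist.** A single injection is an instantaneous jump of the
17th state `Ag`, which decays with half-life 4.8 hr (exactly five
half-lives per day) and acts as an additional REV-ERB-equivalent repressor
*in the Bmal1 equation only* ($f_s = f(S, REV + Ag, \epsilon_s)$); the
REV-ERB equation and the TH/DRD3 equations are untouched, matching the
model's definition. An off-by-default flag (`agonist_affects_da`) exposes
the biologically plausible extension in which TH and DRD3 repression also
sees the agonist. The default dose is twice the entrained REV-ERB peak
(deliberately exaggerated); "peak" means peak *concentration* over the
final entrained control cycle.

The simulated phase response deserves honesty: the agonist reaches nuclear
PER only through $S \to BC \to P_1 \to$ (four phosphorylation stages)
$\to P_N$, roughly a 12-hr pipeline, so the first post-injection $P_N$
peak after a ZT0 injection is essentially unshifted; the delay appears
from the second peak (~1.6 hr at the default dose, within the 1--3 hr
band reported for such agonists) and light re-entrains the clock within
2--3 days. Because $\epsilon_s = 0$ clamps the repression once
$REV + Ag \ge S$, the response *saturates in dose*; and because the
entrained cycle is locally stable under the strong forcing
($\xi = 2/3$), no injection time we tested (including ZT9, at doses up to
10x the REV-ERB peak) produces a permanent loss of rhythmicity — injection
timing changes the transient, not the fate. The acceptance suite states
the stricter literature-derived expectations and leaves the two that the
model cannot meet failing, rather than loosening them.

## Rhythm metrics

* Peaks/troughs on the final cycle are located on the 0.05 hr grid and
  refined by a local quadratic through three points, giving sub-grid
  accuracy (validated on off-grid synthetic sinusoids).
* `period_estimate()` averages the last two peak-to-peak intervals and
  needs at least three peaks; flat signals (range below $10^{-9}$ of the
  peak) return the `NA` arrhythmicity sentinel throughout.
* `phase_shift()` compares treated and control peak times within
  successive 24-hr windows, wrapped to $(-12, 12]$ hr, positive = delay
  (rightward shift). `reentrainment_time()` reports the first day from
  which the absolute shift stays below 0.5 hr, or `NA` if it never does.
* Phase labels are SCN-referenced by default. For comparisons with ventral
  striatum expression data, `ventral_striatum_offset()` returns the
  relabelling offset that places the entrained REV-ERB peak at ZT14 (the
  offset magnitude is a reporting convention, not a dynamical change; only
  the resulting peak label is constrained).

## Driving a dopamine model

`expression_profiles()` exports the final entrained cycle of TH and MAO
scaled to a maximum of exactly 1 on a uniform ZT grid ($E_{TH}(t)$,
$E_{MAO}(t)$; TH low during light and high during dark, MAO nearly
antiphasic). The coupling contract for an external dopamine
synthesis/release/reuptake model is multiplicative: scale that model's TH
$V_{max}$ by $E_{TH}(t)$ and its MAO $V_{max}$ by $E_{MAO}(t)$, from the
tabulated CSV or a callable. `coupling_profiles()` applies the four
regional parameter adjustments used for this purpose
($\alpha_{th} = 3.7$, $b_{th} = 0$, $\epsilon_{th} = 0.3$, $d_m = 0.02$)
before entraining — these apply only to the coupling computation, not to
the stand-alone clock simulations. The dopamine model itself is outside
this package's scope, as are the resulting extracellular dopamine / HVA
predictions.

## What the tests do and do not show

The suite checks internal mathematical structure (closed-form limits of
the kernels, decay oracles, solver cross-checks, positivity, periodicity)
and the model's published quantitative checkpoints (entrained 24-hr
period; nuclear PER-CRY peak at ZT12; ~9 hr cytosolic-to-nuclear PER lag;
REV-ERB/ROR co-peaking with troughs at <5% and 40% of peak; TH
trough/peak 0.5 peaking at night; MAO trough/peak 0.79 peaking near ZT6 in
antiphase to TH; CRY-deficiency and darkness responses). Problem sizes:
40-day entrainments, a 30-day darkness run, 8-day agonist experiments — a
full suite run takes well under a minute. All of this exercises the model
against *itself* and against the qualitative shape of published rodent
data; it does not validate the model against raw experimental time series
(the `rmse()` utility accepts user-supplied sparse time-value points for
that purpose), and parameters are expected to vary across species, brain
regions and individuals.

```{r example}
library(circadopa)
ent <- entrain_clock() # ~2 s: 40 simulated days
rhythm_summary(ent, c("P1", "PC_N", "P_N", "REV", "ROR", "TH", "MAO"))
exp0 <- agonist_experiment(entrained = ent, injection_ZT = 0)
phase_shift(exp0$treated, exp0$control, "P_N")
```
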