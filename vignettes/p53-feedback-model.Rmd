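---
title: "Modelling the p53-Mdm2 negative feedback loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the p53-Mdm2 negative feedback loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53loop)
```

## The model

The tumor suppressor p53 integrates a wide range of cellular stress
signals — DNA damage, hypoxia, oncogene activation, nutrient
deprivation — and yet produces stress-specific downstream responses.
`p53loop` simulates the core regulatory motif behind this behaviour: the
negative feedback loop in which p53 transcriptionally activates its own
inhibitor Mdm2, an E3 ubiquitin ligase that binds p53 and targets it for
degradation.

The deterministic layer tracks four concentrations (nM): free nuclear
p53 ($p$), Mdm2 mRNA ($m_m$), free Mdm2 ($m$), and the p53–Mdm2 complex
($c$):

$$
\begin{aligned}
\dot p   &= \sigma - \alpha p - k_f\,p\,m + k_b\,c + \gamma c\\
\dot m_m &= k_t\,p^2 - \beta m_m\\
\dot m   &= k_{tl}\,m_m - \gamma m - k_f\,p\,m + (k_b + \delta)\,c\\
\dot c   &= k_f\,p\,m - (k_b + \delta + \gamma)\,c
\end{aligned}
$$

p53 is produced at a constant rate $\sigma$ and removed through two
routes: an Mdm2-independent route ($\alpha$, an effective rate lumping
spontaneous degradation, nuclear export, sequestration and inactivating
modification) and the Mdm2-dependent route ($\delta$), which acts on the
complex. Transcription of *mdm2* is activated by p53 with a Hill
exponent of 2, reflecting the double p53 binding site at the *mdm2*
promoter. Mdm2 is removed at rate $\gamma$ whether free or bound.

There is **no explicit transcriptional time delay**. Oscillations arise
purely from the nonlinearity of complex formation: the fast binding
($k_f$, with dissociation $k_b$ and dissociation constant
$k_D = k_b/k_f$) sequesters p53 and makes its effective degradation
strongly nonlinear.

### Degradation bookkeeping for the bound moieties

When a degradation event hits one member of the complex, the other
member is released. The package's default convention (`variant =
"release"`) is: $\delta\,c$ destroys the p53 moiety and releases free
Mdm2; $\gamma\,c$ destroys the Mdm2 moiety and releases free p53 (Mdm2's
half-life is the same free or bound). An alternative convention, in
which $\gamma$ acting on the complex destroys both moieties, is
available as `variant = "codegrade"`; at default rates it shifts the
resting equilibrium by under 2%, so the distinction is immaterial for
the headline behaviour, but the switch keeps the assumption explicit and
testable.

### Default parameters

| parameter | meaning | default |
|---|---|---|
| $\sigma$ | p53 production | 1000 nM/h |
| $\alpha$ | Mdm2-independent p53 removal | 0.1 /h |
| $\delta$ | Mdm2-dependent p53 degradation | 11 /h |
| $k_t$ | *mdm2* transcription | 0.03 /(nM h) |
| $k_{tl}$ | Mdm2 translation | 1.4 /h |
| $\beta$ | mRNA degradation | 0.6 /h |
| $\gamma$ | Mdm2 removal (free or bound) | 0.2 /h |
| $k_b$ | complex dissociation | 7200 /h |
| $k_D$ | dissociation constant $k_b/k_f$ | 1.44 nM |

$k_D$ is treated as the derived member of the pair $(k_b, k_D)$:
assigning $k_D$ (directly or through a stress fold change) rewrites
$k_f = k_b/k_D$ with $k_b$ fixed. Units are frozen at nM and hours
throughout the deterministic layer.

At these defaults the system has a unique equilibrium with total p53
($p + c$) of about 108 nM, almost all of it complexed (free p53
$\approx 17$ nM), and a high p53 turnover — the hallmark of the
unstressed "resting" cell. The package interprets the model's
$\approx 100$ nM resting p53 level as **total** p53: the free
concentration at these rate constants is necessarily far below 100 nM,
since $\sigma \approx \delta c$ forces $c \approx 91$ nM at rest.

```{r}
eq <- p53_steady_states(p53_parameters())[[1]]
eq$state
total_p53(eq$state)
```

## Equilibria, stability and the oscillation onset

`p53_steady_states()` reduces the steady-state equations to one scalar
equation in $p$ (using $m_m = (k_t/\beta)p^2$, the total-Mdm2 balance
$m + c = (k_{tl}/\gamma) m_m$, and the complex quasi-balance), solves it
by bracketed bisection on $[10^{-6}, 10^4]$ nM with relative tolerance
$10^{-10}$, and polishes the root by Newton iteration on the full
four-dimensional system. An independent check is available through the
equivalent cubic in $p$ (solved with `polyroot()` in the test suite).
Stability comes from the eigenvalues of the analytic Jacobian; real
parts are compared to zero with a tolerance of $10^{-8}$ per hour.

Doubling $\gamma$ destabilises the resting state through a
complex-conjugate eigenvalue pair — a Hopf onset — so the onset of
oscillations lies between one- and two-fold the default Mdm2 removal
rate, which the test suite verifies by classifying both endpoints.

## Time courses, stresses, and oscillation metrics

`p53_simulate()` integrates with `deSolve::ode` (`lsoda`, rtol
$10^{-8}$, atol $10^{-6}$ nM) and applies stress events as parameter
switches at exact event times, restarting the integrator at each switch.
Stresses are fold-change multipliers on named parameters
(`stress_scenario()`), each constrained to the direction its biology
dictates.

The settled-regime summary (`oscillation_metrics()`) uses the last half
of the span by default. Definitions, fixed once and used everywhere
(including the spikyness contour):

* **amplitude** = max − min over the settled window;
* **average** = trapezoidal time average;
* **spikyness** = amplitude / average; oscillations with spikyness
  $\ge 2$ are "spiky" (the boundary value counts as spiky);
* **oscillation floor**: amplitude $< 10^{-3} \times$ average is
  classified steady, with peak level equal to the average;
* **peaks**: local maxima with a prominence of at least 1% of the
  window range and at least 0.25 h apart (suppressing solver ripple),
  refined by a local quadratic fit; height ties break to the earlier
  peak. A window whose amplitude is above the floor but which contains
  fewer than three peaks, or fewer than five putative periods, raises an
  "unsettled" error rather than returning silent numbers.

`classify_response()` standardises the protocol: start from the resting
state (or, when no stable equilibrium exists, from the end of a 300 h
pre-equilibration run), integrate 200 h, summarise free p53 on the last
100 h. Free p53 is the default reported species.

## Built-in stresses and the DNA-damage calibration

Each packaged stress touches only the parameters its biology motivates:
Nutlin ($k_D\uparrow$ only), DNA damage ($\gamma\uparrow$,
$\delta\downarrow$, $k_D\uparrow$), hypoxia ($k_t\downarrow$,
$\delta\downarrow$), oncogene activation and nitric oxide
($\delta\downarrow$), ribonucleotide depletion ($\sigma\uparrow$).
Published sources give only the directions, not the magnitudes, so the
uncalibrated stresses default to 5-fold in the indicated direction —
chosen so stresses are comparable at matched fold changes — and every
magnitude is overridable.

DNA damage is the exception: single-cell irradiation experiments pin its
response schedule (first free-p53 peak near 30 min, second near 6 h,
third between 9 and 13 h, height ratios $h_1/h_2 \approx 2$ and
$h_1/h_3 \approx 2.5$). `calibrate_dna_damage()` fits the three
multipliers against these targets with a deterministic search: a
$7^3$ log-spaced coarse grid over $\gamma$-fold $\in [1, 50]$,
$\delta$-fold $\in [1/50, 1]$, $k_D$-fold $\in [1, 50]$, followed by
shrinking local refinement around the five best coarse candidates (the
loss surface is multimodal; single-start refinement can strand on a
boundary). The loss is the sum of squared relative errors on
$(t_1, t_2, h_1/h_2, h_1/h_3)$ against $(0.5\,\mathrm{h}, 6\,\mathrm{h},
2, 2.5)$ plus a hinge penalty when $t_3$ leaves $[9, 13]$ h. The
packaged scenario freezes the fitted result
($\gamma \times 3.13$, $\delta \times 0.613$, $k_D \times 2.66$), which
reproduces peaks at 0.49 h, 5.9 h and 9.4 h with height ratios 1.98 and
2.46.

The SNP309 promoter polymorphism is modelled as a resting-state shift:
the G allele raises *mdm2* transcription, so `snp309_variant()` scales
$k_t$ (TT $\times 1$, GG $\times g$, TG the geometric mean — no
quantitative allele dosage is published, so only the ordering is
asserted anywhere). Stress runs for a variant start from the variant's
own resting state; the response to a fixed stress weakens monotonically
as $k_t$ grows, and a sufficiently strong shift suppresses stress-induced
oscillations entirely.

## Phase diagrams and sensitivity

`phase_diagram()` classifies every cell of a two-parameter grid with the
standardised protocol above (each cell starts from its own resting state
when one exists) and extracts the spikyness = 2 level set by linear
interpolation on grid edges (marching squares, interpolating in log
coordinates on log axes; disconnected pieces allowed). Failed cells are
recorded per cell and never abort a scan; rerunning a scan reproduces
every cell bitwise. Defaults of 40 x 40 cells keep a full diagram at
about 1600 ODE runs; the test suite uses much smaller grids (down to
2 x 3) around the oscillation onset, which the package treats as
sufficient because every cell is an independent run of the same
protocol.

`sensitivity_curve()` varies one parameter over folds $[1/5, 5]$
(log-spaced, fold 1 exact) and reports the settled average free p53
relative to fold 1. $\beta$ and $k_{tl}$ are excluded by construction:
time and mRNA-concentration units can be rescaled so both equal 1, so
their variation is redundant with the remaining parameters.

Two slope summaries are reported. `max_slope` is the largest local
log-log finite difference; `mean_slope` is the total variation of the
log response over the log fold span. Parameter *rankings* use
`mean_slope`, a deliberate design choice: curves that cross the
oscillation onset (e.g. $k_D$ reduced below $\approx 0.8$-fold, or
$\gamma$ raised past $\approx 1.8$-fold) pick up a short steep kink at
the regime change, so the local maximum measures proximity to the onset
rather than how strongly the parameter moves the p53 level overall.
Under `mean_slope` the model cleanly separates the sensitive parameters
($\gamma$, $\delta$, $k_t$, $\sigma$; 0.39–0.47) from the insensitive
ones ($k_D$ 0.21, $\alpha$ 0.001) — which is also why stresses acting
only on $k_D$ (Nutlin) or $\alpha$ barely move the average p53 level,
while the average is nearly flat in $\gamma$ just past the onset even
though the *peak* level keeps rising there.

## The stochastic layer

`build_reactions()` translates the equations term by term into ten
elementary channels over integer copy numbers; `ssa_run()` samples them
with the exact direct method (exponential waiting times, propensity-
weighted channel choice) in compiled code. Two choices matter:

* **Transcription** uses the combinatorial dimer form
  $k_t/\Omega\; n_p (n_p - 1)$ rather than $n_p^2$: exact for pair
  occupancy of the double promoter site, and identical to the
  mean-field $p^2$ term up to $O(1/\Omega)$.
* **Volume scaling**: the reference cell is a sphere of radius 6 µm, so
  $\Omega \approx 545$ molecules/nM and the 100 nM resting level is
  about 50,000 molecules (large enough that demographic noise is
  negligible). `volume_context(scale_factor)` shrinks the volume; the
  packaged default for visibly noisy simulations is the 500-fold
  reduction, at which the first damage peak stays timed while the third
  jitters strongly.

Each run uses its own xoshiro256++ stream seeded explicitly (replicate
$i$ of an ensemble uses `seed * 1000003 + i`), independent of R's global
RNG, so ensembles are reproducible per seed. Initial counts are the
resting concentrations times $\Omega$, rounded to the nearest integer.
Peak statistics on count trajectories apply a 0.1 h moving-average
pre-smoother before the shared peak detector, because shot noise
produces spurious single-sample maxima.

### Problem sizes for stochastic validation

Exact SSA cost scales linearly with $\Omega$: at the reference volume
the fast binding/unbinding cycle alone fires $\sim 10^{10}$ times in a
12 h damage response, so the package validates mean-field convergence at
a 12-fold reduced volume, where demographic noise is strictly larger
and the check is therefore conservative: the measured sup-norm deviation
of a 20-run ensemble mean from the ODE falls steadily (10.9% at
1/200 volume, 6.4% at 1/100, ~3% at 1/50 and 1/25, 1.9% at 1/12) as the
volume grows toward reference; the residual deviation at reduced volume
is dominated by ensemble phase decoherence around the later peaks, an
O(1/volume) effect that vanishes at realistic molecule numbers. Peak-time variability uses 100 runs at
the 500-fold reduction, and the noise-monotonicity check compares 30-run
ensembles at 1/200, 1/500 and 1/2000 volume.

## SBML exchange

`sbml_export()` writes SBML Level 3 Version 2 with explicit nM and hour
unit definitions and a *reaction-based* encoding — the same ten channels
as the stochastic layer, so one reaction set is the single source of
truth for the ODEs, the SSA and the exchange format. `sbml_import()`
reads parameters (rejecting non-positive rates by name), stoichiometry
and kinetic laws (content MathML), and `sbml_diff()` evaluates an
imported document against a reference parameter set at random states,
reporting term-level discrepancies rather than silently overwriting
them — the intended mechanism for reconciling externally deposited
versions of the model.

## What the simulated conditions do and do not show

All quantitative checks run on conditions generated by the package
itself: the Table-of-defaults parameter set, fold-change stresses with
published directions, and the calibrated damage schedule. They test that
the implementation reproduces the model's documented behaviour — not
that the model captures any particular cell line. Known limitations:

* stress magnitudes other than DNA damage are conventions (5-fold), not
  measurements;
* the mapping from p53 dynamics to physiological outcome (arrest vs
  apoptosis) is outside the model;
* demographic (intrinsic) noise is the only stochasticity modelled; the
  cell-to-cell variability seen experimentally likely has extrinsic
  sources, which the volume-reduction device mimics only qualitatively;
* the single-loop model omits known regulators (Wip1, MdmX) and any
  explicit transcriptional delay — by design, since its point is that
  complex-formation nonlinearity alone suffices for oscillations.
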