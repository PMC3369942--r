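---
title: "An agent-based model of sarcomeric pattern formation in actomyosin bundles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of sarcomeric pattern formation in actomyosin bundles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Striated muscle myofibrils — and the striated stress fibers of some
non-muscle cells — show near-crystalline order: actin filament plus ends
are anchored at periodically spaced Z-bands, with bipolar myosin II
filaments localized midway between them, near the actin minus ends.
Passive diffusive sorting cannot build this order on realistic time
scales, so active processes must. `sarcsim` implements a one-dimensional
agent-based model of an initially disordered bundle in which just two
active ingredients — actin **treadmilling** and **processive plus-end
crosslinking** — drive polarity sorting, cluster coalescence, and the
emergence of periodic (sarcomeric) order, with bipolar myosin both
transported to its correct A-band position and acting as the repulsive
spacer that arrests coalescence at a finite sarcomere spacing.

## The model

All quantities are in simulation units: lengths in the mean filament
length $\ell$, time in $T = \ell/v$ with $v$ the treadmilling speed,
forces in $\gamma \ell v$ with $\gamma$ the cytosolic drag per unit
filament length.

**Filaments.** Rigid polar rods on a periodic ring $[0, L)$, described by
plus-end position, orientation $\sigma = \pm 1$, and length.
Treadmilling (polymerization at the plus end, matched depolymerization at
the minus end) makes the monomers move at $u = V - \sigma v$ when the
plus end moves at $V$; a free filament satisfies $V = \sigma v$ with its
monomers at rest.

**Plus-end crosslinking.** Two filaments in different clusters whose plus
ends are a distance $d$ apart link irreversibly at rate
$k_0 e^{-(d/\delta)^2}$.  Linked plus ends form a cluster (a nascent
Z-band / I-Z-I complex) that moves as one unit; merging clusters take the
weight-averaged position, with weights equal to filament numbers.  An
isolated cluster's force balance gives the closed-form velocity
$V = v\,(\Sigma l_+ - \Sigma l_-)/(\Sigma l_+ + \Sigma l_-)$ — clusters
drift by the statistical imbalance of their two filament populations,
so smaller clusters move faster, which is what lets the pattern coarsen.

**Myosin.** A bipolar minifilament is a rigid connector of length
$L_{my}$ with two polarity-specific binding sites (the left site binds
only $\sigma = -1$ filaments, the right only $\sigma = +1$ — the
geometry of motor heads walking toward plus ends).  Sites attach and
detach as Poisson processes ($k_{on}$, $k_{off}$) and walk with a linear
force–velocity relation $w = v_0 (1 - F/F_{stall})$, extrapolated past
stall so that strong backward load can drag a motor backwards.  For a
doubly bound myosin the massless-connector subsystem (force balance,
shared connector velocity, force–velocity at both sites) has the closed
form implemented in `myosin_pair_force()`; eliminating the internal
forces leaves each bridging myosin contributing a symmetric coupling
$\kappa = F_{stall}/(2 v_0)$ and a constant polarity-dependent drive to
the global force balance.

**Mechanics.** Inertia is negligible, so each time step solves the exact
linear force balance $A V = b$ over all mobile units (cytosolic drag,
optional inter-filament sliding friction $\zeta$ per unit overlap,
myosin couplings), then advances positions with an explicit Euler step.
Because forces are linear in velocities and independent of position
while the interaction topology is fixed, the only discretization error
is in event timing and advection — tested to converge at first order in
`dt`.  The solve residual stays below $10^{-9}$ along entire runs.

**The conveyor belt.** A filament grafted at its plus end polymerizes
against the crosslinker and its body streams away from the Z-band
(local retrograde flow).  A bound myosin site's offset from the plus end
obeys $\dot{\mathrm{off}} = v - w$: whenever treadmilling outpaces
walking, myosin rides the conveyor toward the minus end and drops off in
the future A-band.  Myosins bridging two *neighboring* clusters push
them apart with a static per-bridge force $F_{stall}(v - v_0)/v_0$ —
the difference between polymerization-driven flow and active walking —
which is the repulsion that sets a regular spacing.

## Parameters and the critical myosin force

Defaults (all in simulation units): $L = 20$, $N_{actin} = 100$,
$N_{myosin} = 100$, $k_0 = 10$, $\delta = 0.1$, $k_{on} = 10$,
$k_{off} = 2.5$, $L_{my} = 0.5$, $F_{stall} = 0.5$, $dt = 10^{-3}$,
$T_{end} = 100$.

The unloaded walking speed is tied to the active force through a motor
mobility $\mu$: $v_0 = \mu F_{stall}$, default $\mu = 0.2$.  This
coupling is what produces a *critical force*: the per-bridge repulsion
becomes $v/\mu - F_{stall}$, monotone decreasing in the active force and
vanishing at $F^* = v/\mu = 5$.  Below $F^*$, treadmilling wins, myosin
is swept to the A-band, and clusters arrest at a regular spacing; the
ordering time scale $\tau$ (from an exponential-saturation fit
$S(t) = S_{sat}(1 - e^{-t/\tau})$) grows as $F_{stall} \to F^*$.  Above
$F^*$ walking outpaces treadmilling: myosin accumulates at the plus ends
(wrong polarity sorting, localization $\to 0$) and its contractile pull
drives runaway coalescence into one or two giant clusters.  With $v_0$
held *fixed* instead, the repulsion $F(v-v_0)/v_0$ would only grow with
force and no critical force exists — which is why the mobility coupling
is the model's default.

The remaining myosin numbers were set once from a force balance, then
frozen: a drifting cluster of $n$ filaments exerts a typical net
polymerization force $\sim \sqrt{n}\,\gamma \ell v \approx 3$, so
arresting coalescence at the filament-length-set spacing needs one or
two bridges per gap at repulsion $\approx 4.5$ each
($\mu = 0.2$, $F = 0.5$), which requires a myosin:actin ratio near 1 and
an ensemble duty ratio $k_{on}/(k_{on}+k_{off}) = 0.8$ — justified by
the many-headed minifilament acting as an effectively processive
crosslinker.  At weaker, shorter-lived myosin coverage the repulsion
cannot match the drift and the bundle coarsens past the sarcomere scale
into a few giant clusters.

With these conditions the bundle reproducibly arrests at $M = 8$
clusters with Bragg spacing $\lambda^* = 2.5 = 2\ell + L_{my}$ — two
filament lengths plus the myosin connector, i.e. the longest filaments
set the spacing.

## Order metrics

Order is quantified by the structure factor over cluster positions
$X_a$ and weights $N_a$,
$S(q_m) = |\sum_a N_a e^{i q_m X_a}|^2 / (\sum_a N_a)^2$, evaluated at
ring-commensurate $q_m = 2\pi m/L$.  The height of the principal Bragg
peak within the wavelength window $[\ell, 4\ell]$ is the sarcomeric
order parameter $S^*$; the same functional with unit weights on myosin
centers gives $S^*_{my}$.  The window excludes the trivial
long-wavelength modes so that a fully coalesced two-blob state is not
scored by its envelope; note, however, two limitations we measured and
document rather than patch:

* a state of 2–4 giant clusters still produces large values at
  *in-window* modes (a single cluster has $S \equiv 1$ at every mode),
  so $S^*$ alone cannot certify "no order" in strongly coalesced
  states — above the critical force, coalescence itself is the
  diagnostic (cluster count, localization), not a small $S^*$;
* the windowed arg-max wavelength $\lambda^*$ occasionally locks onto an
  in-window *harmonic* of the fundamental in weakly ordered states, so
  seed-averaged $\lambda^*$ is noisy even when the modal spacing clearly
  shifts.  Exact analytic ties (perfect lattices) are resolved to the
  fundamental via a relative $10^{-12}$ tie tolerance.

"Terminal" observables are means over the final $10\,T$ of a run; the
cluster count additionally reports its change over that window (zero
change = kinetic arrest).

## Stochastic events

Per step, in fixed order: myosin detachment, attachment, crosslinking
with iterated pairwise merging in ascending id order (order-independence
is a tested property), optional single-filament dissociation, turnover
*or* severing, the mechanics solve, and the Euler advance.  The ordering
is a convention — forces act on the post-event topology.  Three
dynamical modes probe robustness:

* **Polydispersity**: static log-normal lengths, moment-matched to mean
  $\ell$ and relative s.d. $\sigma_\ell$; order degrades and spacing
  widens with $\sigma_\ell$ (exponential lengths are provided as the
  comparison case that fails to order).
* **Turnover**: catastrophes remove a filament wholesale at rate
  $k_{to}$ and renucleate a fresh one elsewhere (count strictly
  conserved).  Actin order $S^*$ decays with $k_{to}$ while myosin
  banding $S^*_{my}$ survives — partial polarity sorting suffices to
  position myosin.
* **Severing with growth**: plus ends grow at $v$, a severing agent
  lands anywhere on a filament at rate $r$ per unit length (the
  "antenna" effect) and the minus-end fragment dissolves.  The
  stationary length density solves
  $v p'(l) = r(1 - P(l)) - r l p(l)$; `severing_steady_pdf()`
  integrates this as a closed $(p, P)$ ODE system (deSolve) on a grid to
  $8\sqrt{v/r}$.  The equation also has the closed form
  $p(l) = (r/v)\, l\, e^{-r l^2/(2v)}$ (a Rayleigh density, mean
  $\sqrt{\pi v / 2 r}$), which the tests use as an independent oracle
  against both the ODE solution and the event-driven sampler.  The
  preset uses $r = \pi/2$ so the stationary mean equals $\ell$.

Cluster merges snap member plus ends to the weighted-average position;
bound myosin sites keep their laboratory position and have their offset
recomputed (detaching if they fall off the filament) — the alternative,
keeping offsets, would stretch the rigid connector.  Sites whose offset
leaves $[0, \mathrm{length}]$ during advection detach (drop-off at
either end; whether motors stall or fall at filament ends is not
constrained by the biology we model, and drop-off avoids an artificial
pile-up at minus ends).

## Numerical and design choices

* Coordinates live on the half-open ring $[0, L)$; the minimum-image
  tie at exactly $L/2$ breaks toward the negative representative, so
  results are bit-reproducible.
* The crosslink pair search cuts off at $4\delta$ (rate
  $< 2\times10^{-7} k_0$ beyond); cluster-pair link probability uses
  the exact complement $1-(1-p_1)^{N_a N_b}$ over member pairs.
* One global R RNG stream per replicate (`set.seed`), consumed
  identically by the compiled core via R's generator: identical
  (configuration, seed) pairs give byte-identical trajectory files.
* The compiled core (RcppArmadillo) and the pure-R reference stepper
  implement the same per-step semantics; tests verify exact agreement
  on deterministic configurations and statistical agreement elsewhere.
* The saturation fit is bounded Levenberg–Marquardt with fixed,
  data-derived initialization, so it is deterministic; all-zero or
  constant series are flagged degenerate instead of fitted.
* Problem sizes in the test-suite runs are the presets themselves
  ($N = 100$, $10^5$ steps); scans use 3–5 replicate seeds.

## What the synthetic conditions do and do not show

The generator emulates premyofibril-scale conditions: a single bundle of
~100 filaments on a 20-length ring, random initial positions and
orientations, no external template.  Passing tests show that the
*mechanism* — treadmilling + plus-end tracking crosslinking + bipolar
myosin — self-organizes periodic order robustly across stochastic
replicates, length polydispersity, and turnover.  They do not show
quantitative agreement with any real myofibril: transverse structure,
filament flexibility and buckling, excluded volume, titin-like
elasticity, anchorage, and force-dependent polymerization are all
outside the model, and absolute rates are effective, not measured.

## Known limitations

* The $S^*$/$\lambda^*$ metrics lose discriminating power in strongly
  coalesced states (see above).
* Event probabilities use the per-step complement $1 - e^{-k\,dt}$;
  multiple events of one kind per filament per step are neglected
  (negligible at $k\,dt \lesssim 10^{-2}$).
* The repulsion range is bounded by $2\ell + L_{my}$; bundles whose
  density cannot sustain one bridge per gap at that spacing coarsen
  further (a real effect of the model, but it makes terminal cluster
  counts sensitive to myosin numbers).
* Reversible plus-end crosslinking is limited to a single dissociation
  rate `k_diss`; Z-band internal remodeling is not modeled.
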