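---
title: "Polar yield-space elementary mode analysis and hybrid cybernetic modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polar yield-space elementary mode analysis and hybrid cybernetic modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarflux)
```

## The problem

Batch cultures of mammalian production cells (CHO being the canonical host)
show strongly dynamic metabolism: glucose-fueled growth with lactate overflow
(the Warburg-like phase), followed by a switch to lactate reconsumption as
glucose runs out. Steady-state flux methods (FBA/MFA) capture snapshots of
this behavior; describing the whole trajectory needs a dynamic model whose
internal flux states are biologically admissible. Elementary flux modes
(EFMs) — the minimal, non-decomposable steady-state pathways of a
stoichiometric network — provide those admissible states, but realistic
networks have millions of them, and selecting the small *active* subset that
explains a given culture is the hard part.

`polarflux` implements a complete desk-scale stack for this workflow:

1. **Network handling** — a bespoke TSV dialect plus minimal SBML reading,
   validation, stoichiometric matrices, reversible-reaction splitting.
2. **An EFM engine** — double-description enumeration for small networks,
   a streaming importer and strict directional-constraint filter for large
   externally computed sets, and per-mode yield vectors.
3. **PSYA** — a polar (module + angle) re-description of the yield solution
   space used to pick a minimal active set of modes around an experimental
   yield point, with a lumped (LPSYA) virtual mode; plus CMOA
   (objective-function) and simplified YSA/LYSA baselines.
4. **A segregated two-population physiology model** of the batch culture,
   with fitting and error metrics.
5. **Dynamic profiles** driven by a selected mode, and a full **hybrid
   cybernetic model (HCM)** with matching-law regulation and a
   genetic-algorithm parameter fit.
6. **EMPA** — a minimal-adjustment perturbation walk through the polar mode
   cloud for metabolic-engineering target exploration.

## The physiological culture model

Total biomass $X$ (mM) follows a logistic law
$\dot X = \mu_{max} X (1 - X/X_{max})$; dead biomass grows first-order from
its own level, $\dot X_d = k_d X_d$; viable biomass is $X_v = X - X_d$.
Viable cells are segregated into an exponential fraction
$\Psi^e = 1 - X/X_{max}$ and a stationary fraction $\Psi^s = X/X_{max}$
($\Psi^e + \Psi^s = 1$), each with its own signed maximum specific rate per
metabolite (negative = consumption). Each rate is saturated
Michaelis–Menten-style by a *key driver*: glucose and glutamine drive
themselves; lactate is driven by glucose in the exponential phase (overflow)
and by lactate itself in the stationary phase (reconsumption, with a fitted
negative stationary rate); glutamate is driven by glutamine in both phases.

Integration is explicit Euler at $\Delta t = 0.1$ h — the model is *defined*
by its discrete update equations, and the step is three orders of magnitude
below the time scale of observable change. Concentrations are floored at
zero; because every consumption term is saturated by its own or its driver's
concentration, flooring also switches consumption off at exhaustion.

The printed form of the dead-biomass equation uses $X_d$ itself, which is
known to overestimate death late in culture; it is implemented as printed.
The stationary-phase glutamine saturation constant is $K_n$ (one printed
equation shows $K_g$ there; we read that as a typographical slip since the
model declares exactly three saturation constants $K_g, K_n, K_l$).

### Fitting

`fit_physio()` is a staged bounded least-squares fit evaluated at the
observation times:

1. $\mu_{max}, X_{max}$ against total biomass (the logistic is autonomous);
2. $k_d$ against dead biomass alone — keeping the tiny dead-cell signal
   from being swamped by the viable-cell SSE;
3. with biomass frozen, each metabolite's $(q^e, q^s, K)$ in driver order
   (GLC, GLN, then LAC given the fitted GLC trajectory, then GLU given
   GLN).

Each stage is L-BFGS-B with tight tolerances (`factr = 10`,
`ndeps = 1e-7`); on noiseless self-generated data all fourteen parameters
return to well under 1% relative error, which is the module's acceptance
surface.

### Error metrics

`error_metrics()` reports SSE, prediction error $PE = \sqrt{SSE/n}$, MAPE
(with zero-valued observations excluded and counted — the familiar
small-denominator pathology, demonstrated in the tests by the
$e=0.1, m=0.2 \Rightarrow$ 100% case), and MPPE. The printed MPPE
typesetting is ambiguous about where $n$ sits under the radical, so **both**
readings are always computed: `mppe` $= 100\sqrt{SSE/(\sum e^2 \cdot n)}$
(the printed form) and `mppe_alt` $= 100\sqrt{SSE/\sum e^2}$ (the
normalized-RMSE reading suggested by the accompanying prose). Neither is
silently chosen.

One algebraic note: for the printed update equations, equal exponential and
stationary specific rates do *not* make the apparent yield $\Delta M /
\Delta X$ time-constant (the numerator scales with $X_v$, the denominator
with $X \Psi^e$). The case that is exactly constant — and that the tests
assert — is saturated exponential-phase-only uptake with $k_d = 0$, where
the yield equals $q^e/\mu_{max}$ up to the first-order Euler stencil offset.

## The polar yield space (PSYA)

Each mode with nonzero biomass flux becomes a point of per-biomass yields
$Y = (Y_{g/x}, Y_{n/x}, Y_{l/x}, Y_{u/x})$ (flux-magnitude ratios; ordering
rule: substrates before products, larger participation first). The polar
re-description is

$$\lambda = \lVert Y \rVert, \qquad
\cos\theta_j = \frac{\lVert Y_{1..j}\rVert}{\lVert Y_{1..j+1}\rVert},$$

so all angles lie in $[0^\circ, 90^\circ]$ for nonnegative yields:
$\theta_1 = 0^\circ$ means pure first-coordinate (glucose) consumption and
$\theta_1 = 90^\circ$ pure second-coordinate (glutamine). The printed ratio
is inverted here — as printed it exceeds 1 and has no arccosine — which is
the only convention under which the published interpretation of the angle
axes holds. An all-zero prefix takes $\theta = 90^\circ$ by convention,
which keeps the inverse map (`from_polar()`) exact; round trips reproduce
yield vectors to below $10^{-9}$ relative.

A measured culture state enters the same space as module $\Gamma$ and
angles $\Phi$. Each mode is scored by

$$\Upsilon = \Big(\frac{\lambda - \Gamma}{\Gamma}\Big)^2 +
\sum_j \Big(\frac{\theta_j - \Phi_j}{\Phi_j}\Big)^2,$$

with elementwise relative angle errors ($\Upsilon = 0$ iff the polar points
coincide). Components with $\Phi_j = 0$ would divide by zero; they
contribute an absolute squared difference scaled by $90^\circ$ instead,
keeping the score continuous at the axes. The alternative reading of the
angle term as a scalar dot product before squaring cannot be distinguished
from the printed text; the elementwise sum is implemented.

### Active-set construction

The first member minimizes $\Upsilon$ (ties to the lowest mode index).
Subsequent members are chosen greedily by the combined criterion
$d(\text{candidate}, \text{experimental point}) - d(\text{candidate},
\text{centroid of selected})$ in normalized polar coordinates
$(\lambda/\Gamma,\ \theta/90^\circ)$ — drawn toward the data, pushed away
from the current set. The published procedure states both influences but
not their combination; the difference keeps both monotone and is
deterministic. Selection stops when the experimental point lies inside the
members' convex hull in measured-yield space, tested by convex-combination
least squares (weights $\ge 0$, $\sum w = 1$, solved with `quadprog` plus a
$10^{-10}$ ridge) with residual $\le 10^{-6}$, or at the simplex-dimension
cap (#measured yields + 1). When the point is outside the hull of all
candidates, the nearest-$\Upsilon$ set is returned with a warning and a
separating-direction certificate derived from the least-distance solution.

`lump_modes()` (LPSYA) combines the biomass-normalized members with the
convex weights; the lump satisfies the steady-state balance by linearity
but is flagged *virtual* — it is generally not support-minimal.

### Baselines

*CMOA* ranks modes by the published list of eleven FBA-style objectives.
Ratio objectives are scale-invariant on rays; "flux units" alone is not, so
modes are normalized to unit biomass flux before summing $|v|$. "Reaction
steps" is the support size. Ties break to the lowest index.

*YSA/LYSA* is a documented simplification of the Song–Ramkrishna
algorithms (full fidelity is out of scope): the first member is the nearest
mode in Cartesian measured-yield space; growth is greedy simplex-volume
maximization among candidates that strictly reduce the containment
residual. This reproduces the published qualitative contrast — YSA builds
the large, robust polyhedron, PSYA the tight one — which the tests assert
on a two-triangle fixture.

## Dynamic profiles from one mode

Over the exponential-phase horizon (default 48 h) a selected or lumped mode
renders metabolite profiles by flux proportionality:
$\Delta M_i = (Z_i / Z_X)\, \Delta X$ per Euler step, where $Z_i$ is the
mode's signed net exchange of external metabolite $i$ and $Z_X$ its biomass
flux, with $\Delta X$ from the physiological model. Profiles are exactly
linear in mode weights, and exchange ratios $\Delta M_i/\Delta M_k =
Z_i/Z_k$ hold at every step before flooring. `compare_selectors()` scores
any set of selections against observed data with the full metric set; CPU
time is reported as informational only.

## The hybrid cybernetic model

Each selected mode (one per *family*; here family 1 prefers glucose,
family 2 lactate) behaves like a pathway catalyzed by a key enzyme. The
uptake kernel is Michaelis–Menten in the family's preferential metabolite,
$r_i = k_i \frac{M}{K_i + M} e_i v_i$, with $e_i \in [0,1]$ the relative
enzyme level. Regulation follows the matching laws on per-mode *returns*
$R_i$ (carbon consumption by default: kernel $\times$ enzyme $\times$
$\sum |Z|\cdot$carbon over consumed externals):

$$u_i = \frac{R_i}{\sum_j R_j}, \qquad v_i = \frac{R_i}{\max_j R_j}.$$

At substrate exhaustion all returns vanish; $u$ falls back to uniform and
$v$ to 1 so the ODEs stay defined. Enzymes are integrated in relative form

$$\frac{de_i}{dt} = \beta_i\,\frac{M}{K_i+M}\,u_i - (\beta_i + \mu)\,e_i,$$

equivalent to the absolute enzyme balance divided by
$e^{max} = \alpha/\beta$; $\alpha$ then only sets the absolute scale. With
$u = 1$, saturating substrate and $\mu = 0$ the fixed point is exactly
$e = 1$, which the tests verify. The printed enzyme balance adds the growth
dilution term with a positive sign, contrary to standard cybernetic
formulations; the default is the standard negative dilution and
`dilution = "positive"` exposes the printed sign. The dilution rate is the
previous step's $\mu$ (one-step lag avoids an implicit update). No enzyme
rate constants are printed for CHO; the defaults $\alpha = 0.01$,
$\beta = 0.05\ \mathrm{h^{-1}}$ are conventions on the scale used for
microbial cybernetic models and should be overridden when calibrating.
Initial relative enzymes default to the published 0.9/0.1 family split, and
the diauxic switch (lactate rise then fall) *emerges* from the matching
laws — there is no hard-coded phase change.

The Euler core is compiled (Rcpp) because the genetic-algorithm fit
evaluates it thousands of times; refining $\Delta t$ tenfold changes final
concentrations by well under 1%.

### The genetic-algorithm fit

As published: $k = 1$, $K = 10$ starts; each generation perturbs one
parameter per candidate by a random factor (0.25–4, log-uniform), runs a
200-step SSE-driven local minimization per candidate, then crosses the best
with the second best by acquiring the second-best's perturbed parameter;
stops on constant SSE or more than ten generations without improvement,
with a final polish. The local step is a simplex pass followed by a bounded
quasi-Newton refine in log-parameter space — the exploratory pass matters,
because the pure gradient path from $(1, 10)$ can stall on a $k/K$ ridge
where $k M/(K+M) \approx (k/K)M$ mimics the data. The whole fit is
deterministic for a fixed seed and the best SSE is non-increasing across
generations. On noiseless two-family data the generating $k$ (and $K$)
come back to well under the 5% acceptance tolerance.

`flux_snapshots()` reconstructs whole-network, biomass-normalized flux
distributions at chosen times as the regulated combination
$\sum_i r_i v_i \cdot \text{flux}_i$; by linearity every snapshot satisfies
the internal steady-state balance.

## EMPA: perturbation walks

Starting from a validated mode, EMPA repeatedly hops to the unvisited mode
closest in normalized polar coordinates ($\lambda$ scaled by the start
mode's module, angles by $90^\circ$, over *all* reaction yields — the walk
crosses the whole polytope, not just the measured coordinates) among those
whose target-reaction yield moves strictly in the queried direction.
Visited modes leave the candidate pool, so no cycles; ties break to the
lowest index. Stop rules: target-yield fold change relative to the start
mode (default 10$\times$), halving of the target's polar angle, or
knockout (yield 0). Direction-violating modes may not be stepped through
even transiently — the strict-monotonicity reading; the alternative is
noted but not implemented. `path_report()` tabulates tracked-reaction
yields against the target fold change with least-squares slopes (the
"apparent linear relationship" summary).

## The synthetic world

The generator emulates the published experimental design, not its numbers:
28 mM glucose, 8 mM glutamine, inoculum at the mM-biomass equivalent of
$10^6$ cells/mL, 144 h with 24 h sampling, multiplicative Gaussian
analyzer noise (default $\sigma = 5\%$; additive available). The
cells-to-mM biomass conversion is a dataset-level calibration that the
source literature cites but does not print, so `biomass_conversion` has no
hidden default; the synthetic world simply states its inoculum in mM
(0.25). The canonical truth kinetics ($\mu_{max} = 0.035\,h^{-1}$,
$X_{max} = 18$ mM, glucose-driven lactate overflow with stationary
reconsumption) were chosen once as plausible CHO-scale values producing the
qualitative published behavior: monotone glucose decline, lactate peak
mid-culture, glutamine persisting into the stationary phase.

Random truth sets for the recovery harness are screened for
*identifiability*: a sampled set in which glutamine is exhausted during the
exponential phase makes the stationary-phase glutamine parameters literally
insensitive (their terms never act), and no estimator can recover a
parameter with zero trajectory sensitivity. The screen (glutamine > 0.3 mM
at 96 h, glucose exhausted by 96 h, ≥ 15% lactate decline from peak)
matches the emulated culture's qualitative design; recovery tolerances were
not adjusted.

What a green test establishes: the estimators invert the package's own
generative models under the stated noise, the enumeration engine agrees
with an independent brute-force oracle on every network small enough to
enumerate exhaustively, and the selection/walk procedures satisfy their
stated geometric invariants. What it does not establish: agreement with
the published CHO dataset's fitted values — those live in supplementary
tables (network SM1, parameters SM2, flux tables SM3) that are not
available to this package, which is also why the published constrained
mode counts (7,855 / 153,574 / 4,032,330 / 18,110,823) are represented by
an importer + filter pathway and a deliberately failing acceptance check
rather than a recomputation.

## Numerical choices, in one place

- Explicit Euler, $\Delta t = 0.1$ h everywhere user-facing; recovery
  *tests* run at $\Delta t = 0.2$ h over 96 h where the check is parameter
  recovery, not trajectory parity (stated next to each test).
- Flux tolerance $10^{-9}$ for "strictly positive" constraint and support
  decisions; EM rays canonicalized to max-abs-entry 1, fully reversible
  modes oriented first-nonzero-positive so the $\pm$ pair collapses.
- Containment: `quadprog` with a $10^{-10}$ ridge; residual $\le 10^{-6}$;
  non-containment certified by the separating direction $y_{exp} -
  \hat y$.
- Degenerate cases: all-zero yield prefixes $\to 90^\circ$; $\Phi_j = 0
  \to$ absolute angle error over $90^\circ$; $\sum R = 0 \to$ uniform
  $u$, $v = 1$; concentrations floored at 0.
- Determinism: every tie breaks to the lowest mode index; every stochastic
  step takes an explicit seed.

## Known limitations

- The enumeration engine is for desk-scale networks (default cap 32 split
  reactions); genome-scale sets must be computed externally and imported.
- YSA/LYSA are simplified baselines, not the published algorithms.
- The physiology model inherits the printed first-order death law and its
  late-phase overestimation.
- EMPA paths are stoichiometric possibilities, not claims of biological
  realizability; slopes summarize the walked modes only.
- The polar description depends on the yield ordering; alternative
  permutations give slightly different selections (exposed as an argument,
  matching the published observation).
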