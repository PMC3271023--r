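---
title: "Modeling the glioma microenvironment: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the glioma microenvironment: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomaTME)
```

## The model

gliomaTME simulates the co-evolution of a glioblastoma and its cellular
microenvironment in a well-mixed 1-ml control volume. Five cell
populations — quiescent stem-like cells (QSC), activated stem-like cells
(ASC), glioma cells (GC), astrocytes and microglia — are coupled to 15
soluble mediators (cytokines, growth factors, chemokines) through 69
Hill-modulated signaling pathways, giving 20 coupled differential
equations.

Each **cell population** $c_i$ evolves as

$$\frac{dc_i}{dt} = J_i(t) \;+\; r_i \prod_j M_{ij}(t)\, L_i(t)\, A_i(t)\, c_i
  \;-\; d_i \prod_k M_{ik}(t)\, c_i
  \;+\; \sum_{s} \kappa_{s\to i} \prod_m M_m(t)\, c_s
  \;-\; \sum_{i \to s'} \kappa_{i\to s'} \prod_m M_m(t)\, c_i$$

where $r_i$ and $d_i$ are basal proliferation and decay rates (1/day),
$\kappa$ are conversion rates between cell states (activation,
deactivation, differentiation, dedifferentiation, neoplastic mutation),
and $J_i$ collects discrete jump events (below). Three multiplicative
factors regulate proliferation:

* **Hill modulation.** Every pathway edge contributes a factor driven by
  its source cytokine concentration $x$ through
  $h(x) = x^n/(K^n + x^n)$. Up-edges scale a rate by
  $1 + (a - 1)h \in [1, a]$ (amplitude $a \ge 1$ is the maximal
  fold-change); down-edges scale it by $1 - (1 - a)h \in (a, 1]$
  (residual fraction $a \in [0,1]$). Factors from multiple edges onto the
  same process combine multiplicatively, so each edge can be ablated
  independently.
* **Crowding.** $L_i = \max(0,\, 1 - \sum_j c_j / \bar c_i)$ uses the
  *total* cell density against a per-population saturating concentration
  $\bar c_i$, expressing competition for shared space: astrocytes are
  displaced as the tumor expands rather than killed directly.
* **Angiogenesis.** Glioma proliferation is additionally gated by
  $A = A_{\min} + (1 - A_{\min})\, h(x_{\mathrm{VEGF}}; K_A, n_A)$,
  a saturating function of VEGF with an avascular floor $A_{\min}$. The
  functional form is a package choice (the gate is pluggable): a Hill
  curve in VEGF captures both the avascular limit on early growth and
  the loss of the gate under VEGF deprivation.

Each **cytokine** $x_j$ evolves as secretion minus first-order decay:

$$\frac{dx_j}{dt} = \sum_{\text{producers } p} q_{jp} \prod M(t)\, c_p
  \;-\; \frac{\ln 2}{\tau_j} \prod M(t)\, x_j$$

with per-cell secretion rates $q_{jp}$ (pg/cell/day) and half-life
$\tau_j$ (days). Secretion and decay can themselves carry Hill
modulation (e.g., MIF and TNF-α up-regulate VEGF secretion; IL-10 and
TGF-β suppress TNF-α production, which is what makes TNF-α peak early
and then decline).

## Stochastic layers

Three noise sources, matching the three kinds of biological fluctuation
the model distinguishes:

1. **Truncated Gaussian white noise on production/regulation
   constants.** At every step each secretion rate is drawn as
   $q\,(1 + \sigma_p \xi)$ with $\xi \sim N(0,1)$, truncated into
   $[0, 2q]$. Default $\sigma_p = 0.1$.
2. **Bounded noise on proliferation/conversion rates.** A sine-Wiener
   process: $z = \sin\theta$ with $d\theta = \sqrt{2/\tau_n}\, dW$,
   applied as $r\,(1 + \sigma_r z)$. The perturbation is confined to
   $[-1, 1]$ by construction and has the arcsine law as stationary
   distribution. Defaults $\sigma_r = 0.15$, $\tau_n = 5$ days.
3. **Poisson jump events** for discrete, low-count processes: microglia
   recruitment (immigration at a rate modulated by glioma-derived
   chemoattractants through the network's `recruitment` edges) and
   stochastic stem-cell conversion bursts (QSC→ASC, ASC→GC seeding).
   Events arrive at rate $\lambda$ per day; each moves
   $1 + \mathrm{Pois}(\mu - 1)$ cells, with cell number conserved for
   conversion-type events. In the 1-ml volume, counts and
   concentrations coincide numerically.

The concrete forms (multiplicative truncated Gaussian, sine-Wiener,
per-step Poisson thinning) are this package's documented realizations of
the three verbal noise classes; intensities are part of the shipped
calibration since no reference values exist.

## Numerical scheme

One step of the stochastic integrator: refresh the noisy rates, advance
the deterministic skeleton by one classical fixed-step RK4 step with
those rates frozen, apply jump events, clip negative undershoots to zero
(counted and reported in the trajectory metadata). With all intensities
zero and no jump processes, the scheme reduces *exactly* to
deterministic RK4 — the deterministic-limit tests rely on bitwise
agreement at `1e-9`. The default step is `dt = 0.01` day; halving it
changes ensemble means by well under the ensemble spread. The
deterministic system can also be integrated with the adaptive
Dormand–Prince 5(4) method (via deSolve's `ode45` running on the
independent pure-R derivative); the two routes agree to better than
0.1% relative on the glioma trace of the default model, which doubles
as a cross-check of the compiled engine against the R-side assembly.

Reproducibility: all randomness flows through R's RNG (`set.seed`);
per-run ensemble seeds are drawn deterministically from a master seed.
Identical seeds give bitwise-identical CSV exports.

## The default network as a synthetic-data generator

The shipped glioma network (`default_glioma_spec()`,
`inst/extdata/glioma_network.yaml`) *is* the study system: no external
data enter a simulation. Its roster — 5 cell types, 15 mediators, 69
edges — reconstructs the interactions named in the glioma literature:
growth-promoting loops (IL-1β, IL-6, IL-10, TGF-β, EGF, VEGF, HGF,
G-CSF, SCF, MIF), PGE2 inhibition of glioma proliferation, EGF/FGF/MIF
survival signaling, astrocyte-derived IL-1β driving TNF-α/IL-6
secretion, MIF/TNF-α induction of VEGF, TNF-α induction of MMP-9, and
microglia recruitment by glioma-derived GM-CSF/MIF. MMP-9 is included
as the 15th mediator, modeled as a terminal invasion marker (produced,
but with no receptor-mediated edge). Because the primary source's full
edge table is not published in the main text, the roster is a
reconstruction, shipped as an editable data file rather than code.

Rate constants are the package's own default calibration, chosen so
that the baseline simulation reproduces the canonical picture of glioma
development: stem-cell activation completing within the first month; a
long pre-tumor phase; a rapid expansion phase with the detection
threshold (10^6 cells/ml) crossed at a median of months 6–10; and a
malignant plateau near 1.5×10^7 cells/ml, with astrocytes displaced
late and microglia rising steadily. The same calibration produces the
stage-dependence of microglia depletion (cure before ~5×10^4 cells/ml,
months of postponement at ~2×10^5, no response at 10^6) and the
synergy of the four-cytokine combination blockade. What passing these
checks shows is *internal* consistency with that qualitative clinical
picture — not fit to any patient data; absolute cytokine concentrations
(pg/ml) are nominal, and only their ratios to the Hill constants are
meaningful.

Virtual patients perturb this baseline: each profile multiplies the 29
tunable parameters — 15 cytokine production rates (`p_<id>`) and 14
receptor expression levels (`r_<id>`) — by log-uniform draws from
[0.5, 2]. Receptor expression enters by scaling an edge's $K$ by the
reciprocal multiplier (more receptor, stronger response at the same
ligand level). A structural consequence worth knowing: for any cytokine
whose entire effect flows through its edges, $h(m x, K) = h(x, K/m)$
makes the production and receptor multipliers mathematically
equivalent, so their sensitivity factors coincide; VEGF is the
exception because the angiogenesis gate's $K_A$ is deliberately not
receptor-scaled. The three shipped fixture patients are synthetic
reconstructions drawn with fixed seeds (101–103).

## Therapies and outcomes

Therapy plans are trigger + intervention lists. Triggers fire once at a
fixed time or at the first upward crossing of a species threshold;
interventions multiply basal rates for their duration (permanent by
default, matching the no-washout design of the experiments):
apoptosis multipliers on a cell's decay rate, production
inhibition/enhancement on all secretion rates of a cytokine, receptor
blockade on the $K$ of its edges. Stacked interventions compose
multiplicatively. Treated and control runs share the seed and consume
the identical noise stream, so differences are attributable to the
therapy alone.

The benefit metric follows the stage of administration: postponement of
the detection crossing when therapy precedes detection (runs that never
recur are credited with the remaining horizon), and the change in the
survival proxy — the time for the glioma population to grow from 10^6
to 1.5×10^7 cells/ml — otherwise. Months are fixed at 30.4 days.

## Sensitivity analysis

The sensitivity factor of parameter $x_i$ is the normalized local
derivative of the objective $F$ at the profile $\mathbf{x}^0$,
estimated by a central finite difference on the ensemble median with
common random numbers:

$$S_i = \frac{F(x_i^0(1+\delta)) - F(x_i^0(1-\delta))}
             {2\,\delta\, F(\mathbf{x}^0)}, \qquad \delta = 0.1 .$$

$F$ defaults to the survival proxy; when a perturbed ensemble never
completes the 10^6 → 1.5×10^7 window within the horizon, the profile
substitutes the tumorigenesis time (months to first detection) for that
parameter and flags the switch in the report, so objectives can differ
across rows of one report. Negative $S_i$ marks a pro-tumor parameter:
the combination designer picks the $k$ most negative for inhibition,
breaking ties by $|S|$ and then lexicographically. Monte Carlo standard
errors come from the per-run paired differences. Local sensitivities
only: global methods (Sobol, Morris) are out of scope.

## Degenerate inputs and edge policies

* Negative integrator undershoots are clipped to zero and counted, not
  fatal — jump noise makes hard failures impractical.
* Crossing times are linearly interpolated between samples; absent
  crossings are `NA`, and every consumer treats `NA` explicitly
  (flagged objectives, horizon-credited benefits).
* A patient multiplier of exactly 0 is accepted by `apply_profile()`
  for ablation experiments (a silenced source stays at zero); sampled
  profiles are always strictly positive.
* Cytokine trace classes: early-peak requires the global maximum before
  detection plus a ≥10% decline (the decline tolerance is configurable,
  since any boundary between "peak" and "plateau" is a judgment call);
  monotone-increase tolerates dips of 2% of the range; everything else
  is phase-correlated. Early-peak takes precedence, and on the default
  calibration FGF (whose astrocyte source declines late) joins TNF-α in
  that class.

## Problem sizes used by the test suite

The shipped checks run the full model over 365 days: a 50-replicate
ensemble at `dt = 0.01` day for the three-phase calibration, 15 paired
replicates per depletion stage, 12 paired replicates per therapy arm
for the combination comparison, and 8 replicates per arm (at
`dt = 0.02` day, within the step-size robustness of the scheme) for the
29-parameter sensitivity profile with 12-seed paired intervention
checks. These sizes were chosen so the median statistics they assert
are stable at the default noise intensities.

## Limitations

* Well-mixed volume: no spatial structure, diffusion or invasion
  geometry; MMP-9 is tracked as a marker only.
* No pharmacokinetics: interventions are step changes in rates.
* The 69-edge roster and all rate constants are a documented
  reconstruction/calibration, not fitted to data; conclusions are
  qualitative orderings (phases, stage-dependence, synergy), not
  quantitative predictions for any real patient.
* Cell populations are continuous concentrations except for the
  explicit jump processes; demographic noise below ~10^3 cells/ml is
  under-resolved by design.
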