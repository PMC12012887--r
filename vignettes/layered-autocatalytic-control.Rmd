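---
title: "Resource-aware layered autocatalytic integral feedback: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource-aware layered autocatalytic integral feedback: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(layeredIFC)
```

# Scope

`layeredIFC` models biomolecular and population-level control circuits in
which production reactions compete for a shared, conserved pool of
resources (ribosomes, polymerases, growth-limiting nutrients).  Its core
subject is a family of *autocatalytic integral feedback controllers*:
controller species that make more of themselves, so that the balance
condition of their own replication acts as an integrator.  The package
provides

* the reduced quasi-steady-state (QSS) rate laws for resource-limited
  production up to the bimolecular level, together with the full
  elementary mass-action expansion used as a validation oracle;
* the minimal (single-species) autocatalytic motif and the layered
  (two-species) motif that restores robust perfect adaptation (RPA) under
  resource competition, with closed-form set-points;
* a ratiometric two-branch variant regulating the *ratio* of two outputs;
* application circuits: embedded gene-expression control under external
  resource loads, a two-pool operon gene-ratio circuit, and generalized
  Lotka–Volterra realizations in microbial consortia (population control
  and coculture composition control);
* a deterministic simulation engine with scheduled step disturbances,
  steady-state detection, equilibrium finding, linearized stability
  analysis and two-parameter stability-region scans, plus a YAML
  configuration layer and shipped presets.

Concentrations and time are in arbitrary units in the intracellular
models; population circuits use hours and densities normalised to the
carrying capacity.

# The resource-competition framework

## Reduced rate laws

Let a pool hold a conserved total `R_tot` of resource.  Competing
production reactions occupy resource through intermediary complexes that
are assumed to equilibrate fast (dynamic-equilibrium assumption).
Eliminating the complexes yields the free-resource concentration

$$ r \;=\; \frac{R_{\mathrm{tot}}/(1+Q_0)}
{1 + \sum_i w^u_i s^u_i + \sum_i\left(w^{ab}_i a_i b_i + w^a_i a_i\right)}, $$

where $Q_0$ aggregates all zeroth-order (constant-demand) reactions and
the *competition gains* $w$ are lumped positive constants, one occupancy
term per competing reaction.  Production rates are then
$\beta^z r$, $\beta^u s r$ and $\beta^b a b r$ for zeroth-order,
unimolecular and bimolecular reactions.  Four bimolecular scenarios are
distinguished by the order of complex formation; scenarios 1 and 3 have
$w^a = 0$ structurally.  All gains are treated as free model parameters:
nothing downstream depends on how they arise from elementary constants.

```{r}
pool <- resource_pool("ribosomes", R_tot = 100, Q0 = 1e-3)
rx <- competitive_reaction("unimolecular", beta_star = 1,
                           substrates = "m", w_u = 1, pool_id = "ribosomes")
free_resource(pool, list(rx), list(m = 1))
```

## The mass-action oracle and the lumping convention

`expand_to_mass_action()` rebuilds the elementary network (explicit free
resource, binding/unbinding at rates multiplied by $1/\varepsilon$,
catalytic release) for the zeroth-order, unimolecular and bimolecular
scenario-1/2 reactions.  Because only binding and unbinding are
accelerated while catalysis stays on the slow time scale, the exact
$\varepsilon \to 0$ limit of each complex is its binding/unbinding
balance.  The package therefore maps elementary rates to reduced
parameters as

* gain = product of (binding/unbinding) ratios along the
  complex-formation chain, scaled by $1/(1+Q_0)$;
* $\beta$ = catalysis rate × that raw gain.

This is the limit-exact convention for the $\varepsilon$-family the
oracle integrates.  The familiar Michaelis–Menten-type lumping (with
"unbinding + catalysis" in the denominator) is recovered when catalysis
is much slower than unbinding — which is also the regime in which the
dynamic-equilibrium assumption is biologically justified, and the regime
the test suite samples (catalysis rates a few permil to a few percent of
unbinding).  Two further conditions keep the reduced and full models
comparable at the stated 2% tolerance: substrate concentrations well
above the pool size (so the substrate mass sequestered in complexes is
negligible) and, for scenario 1, weak pre-dimerisation (the dimer is not
bounded by the resource total).  These conditions are properties of the
*comparison*, not of the reduced model itself.

Scenarios 3 and 4 are supported throughout the reduced layer (rate laws,
gains, validation), but no elementary expansion is generated for them:
the order of elementary steps that distinguishes them requires rate
inequalities that are part of their derivation, and the oracle exercises
scenarios 1–2 plus the lower orders, which pin every quantity the
package computes.

# Controller motifs

## Minimal autocatalytic motif

A single controller species $Z_1$ with resource-limited positive
autoregulation, catalytically inhibited by the regulated output $x_n$,
and resource-limited actuation into the process:

$$ \dot z_1 = z_1\left(\alpha_1^\star r - \theta\, x_n\right), \qquad
   \dot x = f(x, r) + k^\star z_1 r . $$

Zero is absorbing for $z_1$; the integral action lives in the balance
$\alpha_1^\star r^* = \theta x_n^*$.  Without competition ($r$ constant
at $R_{\mathrm{eff}}$) the output adapts perfectly to process
disturbances at $x_n^* = \alpha_1^\star R_{\mathrm{eff}}/\theta$.  With
competition, $r$ depends on $z_1$ and the process load, the balance
couples to the process, and adaptation fails — the package's default
parameterization shows 13–17% steady-state error after a 20% actuation
step, shrinking as the gains shrink.

The process-side occupancy enters the resource denominator as
$w_{z1} z_1 + \bar w_{\mathrm{lin}} x_n + \bar w_{\mathrm{quad}} x_n^2$:
an aggregate linear plus quadratic load carried by the output level,
standing for the unimolecular and (scenario-1) bimolecular demand of the
process network.

## Layered autocatalytic motif

The layered motif adds a second autocatalytic species $Z_2$ whose
replication reads both the output and the free resource (a bimolecular,
resource-limited autocatalysis) and which is removed at a constant rate:

$$ \dot z_1 = z_1(\alpha_1^\star r - \theta x_n), \qquad
   \dot z_2 = z_2(\alpha_2^\star x_n r - \gamma_{c2}). $$

The two layers interact *only* through the shared resource.  At a
strictly positive equilibrium the two balances pin both regulated
quantities from controller constants alone:

$$ x_n^* = \Sigma = \sqrt{\frac{\alpha_1^\star \gamma_{c2}}
   {\alpha_2^\star\,\theta}}, \qquad
   r^* = \frac{\gamma_{c2}}{\alpha_2^\star\,\Sigma}, $$

so $r^*\Sigma = \gamma_{c2}/\alpha_2^\star$ exactly.  $Z_2$ acts as an
active buffer: it absorbs resource when the pool is slack and releases
it when the process demands more, holding $r$ at $r^*$.  Consequently
the output rejects persistent steps in every process- and resource-side
parameter ($k^\star$, $\gamma_{p1}$, $b^\star_{p1}$, $Q_0$,
$R_{\mathrm{tot}}$, the gains) as long as the post-step equilibrium
stays feasible and stable.  $\gamma_{c2} > 0$ is structurally required
(with $\gamma_{c2}=0$ the $z_2$ balance degenerates); at cellular scale
dilution provides it for free.  Tuning: $\Sigma$ moves with
$\alpha_1^\star\gamma_{c2}/\alpha_2^\star$, while the ratio
$\gamma_{c2}/\alpha_2^\star$ independently retunes $r^*$ at fixed
$\Sigma$.

```{r}
ctl <- layered_motif_params(alpha1_star = 4, alpha2_star = 0.25,
                            gamma_c2 = 0.25, sense_gain = 1, k_star = 1,
                            w1 = 1, w2 = 1)
layered_setpoint(ctl)
```

## Embedded gene-expression control and feasibility

Closing the layered motif around the default expression plant
$f(x_1, r) = b^\star_{p1} r - \gamma_{p1} x_1$ gives a
three-state closed loop whose strictly positive equilibrium exists iff

* $\gamma_{p1}\alpha_2^\star\Sigma^2 > b^\star_{p1}\gamma_{c2}$ (the
  actuated branch must carry positive flux), and
* $R_{\mathrm{tot}} > r^* + w_1\gamma_{p1}\Sigma/k^\star$ (enough
  capacity; for $k^\star \to \infty$ this degenerates to
  $R_{\mathrm{tot}} > r^*$),

and is locally asymptotically stable whenever
$2\gamma_{c2} \le \gamma_{p1}$ (a sufficient criterion; the package
verifies it numerically on thousands of random feasible
parameterizations, finding no counterexample).  External genetic load
modules that draw on the pool only through zeroth-order demand enter the
model solely through the aggregate $Q_0$; a step in $Q_0$ is equivalent
to a simultaneous rescaling of the gains and $R_{\mathrm{tot}}$ and is
rejected like any other disturbance.

## Ratiometric motif

For two outputs $x_1, x_2$ the controller is doubled and cross-wired:
each branch's controller is *stimulated* by the opposite output,
*inhibited* by its own, and both share the pool:

$$ \dot z_1 = z_1\big(\alpha_1^\star H_1(x_2) G_1(r) - \theta_1 x_1\big),
\qquad
   \dot z_2 = z_2\big(\alpha_2^\star H_2(x_1) G_2(r) - \theta_2 x_2\big). $$

Controller removal is assumed negligible (nonzero removal rates are
accepted and demonstrate *imperfect* ratiometric adaptation).  At any
strictly positive equilibrium, eliminating $r$ between the two balances
yields the *ratio manifold* tying $x_1^*$ to $x_2^*$ through controller
constants alone.  With linear responses it is the line
$x_1^* = \Gamma x_2^*$ through the origin, with

$$ \Gamma = \sqrt{\frac{\alpha_1^\star\,\theta_2}
   {\alpha_2^\star\,\theta_1}}, \qquad
   r^* = \sqrt{\frac{\theta_1\theta_2}{\alpha_1^\star\alpha_2^\star}} $$

(response slopes folded into the $\alpha$'s): perfect ratiometric
control with parallel resource regulation.  Saturating (Hill) responses
bend the line into a monotone nonlinear manifold whose slope at the
origin matches the linear limit with the responses' initial slopes.
Actuation is a design hook: the default wiring actuates only the first
branch ($u_1 = k_1^\star z_1 r$), which suffices because the second
branch is steered through the shared resource.  One-sided actuation can
only *raise* the first output, so a commanded $\Gamma$ is feasible only
above the open-loop ratio — the operon defaults command $\Gamma = 3$
against open-loop ratios between 0.25 and 2.

## Operon gene-ratio circuit (two pools)

The operon circuit transcribes two genes on one polycistronic mRNA
$m_P$ (transcription limited by pool $R_1$) and translates both from
that shared transcript (translation limited by pool $R_2$), so
transcriptional competition cancels from the open-loop ratio
$x_1^*/x_2^* = \eta_1^\star\gamma_{x2}/(\eta_2^\star\gamma_{x1})$ — which
still tracks every change in the degradation rates.  The ratiometric
controller is embedded with direct transcriptional actuation from $Z_1$
to $X_1$ (an explicit actuation transcript $m_1$; a quasi-steady-state
mRNA reduction is available as a flag).  Controller production requires
both pools, so its lumped autocatalysis multiplies $r_1 r_2$; the two
balances then give $x_1^*/x_2^* = \Gamma$ and the resource-product
relation $r_1^* r_2^* = (\theta_1/\alpha_1^\star)\,\Gamma$: the
controller regulates the *product* of the two available resource levels
in proportion to the commanded ratio.

# Population-level realizations

Cell growth is nature's autocatalysis: logistic growth under a shared
carrying capacity supplies both the positive autoregulation and the
resource coupling.  The free-capacity factor
$\phi = 1 - (\text{weighted community density})/N_m$ plays the role of
$r$.

## Consortium controller

Two strains in one medium: $N_1$ grows at intrinsic rate $\mu_1$, is
killed by the output at gain $\theta_1$ and diluted at $\gamma$; $N_2$'s
intrinsic growth is *induced* by the output ($\mu_2 = \rho_{xn} x_n$,
first-order by default, optionally saturating).  Matching the layered
balances gives the output set-point

$$ x^* = \frac{-\gamma + \sqrt{\gamma^2 +
   4\theta_1\mu_1\gamma/\rho_{xn}}}{2\theta_1}, $$

dependent only on controller-strain constants — not on the carrying
capacity, the competition coefficients or the process.  A nonzero
dilution plays $\gamma_{c2}$'s role; with $\gamma = 0$ the positive
set-point degenerates, so batch operation needs an engineered death
rate.

## Three-strain population control

The controller pair regulates a target strain $N_3$ through two
orthogonal quorum-sensing channels: $N_1$ secretes $A_1$, which induces
$N_3$'s growth (actuation); $N_3$ secretes $A_3$, which kills $N_1$ and
induces $N_2$ (sensing).  AHLs follow birth–death dynamics with birth
proportional to the source density.  The regulated level
$a_3^*$ (and the $N_3^* = \delta_3 a_3^*/\sigma_3$ it encodes) has the
same closed form as above with $\rho_3$ in place of $\rho_{xn}$ and is
insensitive to $N_{m3}$, $c_{13}$, $c_{31}$ and the actuation gain — the
package verifies ±50% perturbations of all three leave $a_3^*$ within
$10^{-3}$ while coexistence holds, and that controller-side gains move
it by far more than 1%.

## Coculture composition control

Four strains: controller strains $N_1, N_2$ (retained in the reactor)
and process strains $N_3, N_4$ (diluted at $\gamma$).  The quorum-sensing
wiring mirrors the ratiometric motif: $A_1 (N_1) \to N_3$ and
$A_2 (N_2) \to N_4$ growth actuation; $A_4 (N_4) \to N_1$ and
$A_3 (N_3) \to N_2$ growth sensing; and the toxin channels
$A_3 \dashv N_1$, $A_4 \dashv N_2$ closing each branch's self-inhibition.
The toxin gains $\theta_3, \theta_4$ are structurally necessary: with
growth-stimulating sensing alone every positive stationary point forces
the controller-side free capacity to zero and the equilibrium set
becomes a one-parameter family, contradicting a unique commanded
composition.  The closed form is

$$ \frac{N_3^*}{N_4^*} = \Gamma =
   \sqrt{\frac{\rho_4\theta_4}{\rho_3\theta_3}}\cdot
   \frac{\delta_3\sigma_4}{\delta_4\sigma_3}, \qquad
   \phi_c^* = \sqrt{\frac{\theta_3\theta_4}{\rho_3\rho_4}}, $$

so quadrupling the sensing gain $\rho_4$ doubles the commanded ratio.
Admissibility requires $\rho_3\rho_4 > \theta_3\theta_4$ (controller
coexistence below capacity) and a dilution slow enough for the process
strains to persist; `coculture_ratio_setpoint(check_admissible = TRUE)`
reports the violated inequality.  Retention of the controller strains is
a structural flag: diluting them too (`retentive_controller = FALSE`)
demonstrates the imperfect-adaptation regime (the default circuit then
settles ≈5% off the commanded ratio).

# Default parameterizations

Printed reference values are used where they exist: the layered-motif
defaults carry $\alpha_2^\star = \gamma_{c2} = 0.25$, $w_1 = w_2 = 1$,
$R_{\mathrm{tot}} = 100$, nominal $Q_0 = 10^{-3}$, an actuation step
$1 \to 50$ at $t = 15$, initial conditions $(x_1, z_1, z_2) =
(0, 0.1, 50)$, and $\gamma_{c2} = \gamma_{p1}/2$ (the stability
criterion's boundary).  The remaining constants are package choices,
fixed once:

* layered motif: $\alpha_1^\star = 4$, $\theta = 1$ (so $\Sigma = 2$,
  $r^* = 0.5$), $b^\star_{p1} = 0.5$ — a fast sensing layer so the
  reference step response settles within the plotted window;
* minimal motif: $\alpha_1^\star = 0.1$, $\theta = 1$,
  $k^\star = 0.2$, $b^\star_{p1} = 0.02$, $\gamma_{p1} = 2$, gains
  $(w_{z1}, \bar w_{\mathrm{lin}}, \bar w_{\mathrm{quad}}) =
  (10, 0.5, 0.05)$, resource levels $\{50, 100, 200\}$ — a regime where
  the controller's own occupancy dominates the denominator, which is
  exactly where the single-layer motif's failure is visible;
* operon circuit: $\Gamma = 3$ with translation-side dominance
  ($\eta_{\mathrm{act}} = 12$) so the commanded ratio clears all four
  open-loop ratios $\{0.25, 0.5, 1, 2\}$ ($\gamma_{x2} \in
  \{0.5, 1, 2, 4\}$, $\gamma_{x1} = 2$);
* population circuits (hours): growth rates near 1/h, AHL decay a few
  per hour, dilution a few percent per hour, capacities normalised to 1
  — magnitudes typical of engineered E. coli consortia in chemostat-type
  setups.  Nominals were chosen, once, to give a comfortably stable and
  coexistent reference point: population control at
  $(\mu_1, \theta_1, \rho_3, \rho_1, \delta, N_{m3}, \gamma) =
  (1.5, 0.3, 5, 6, 3, 2, 0.05)$; coculture at
  $(\rho_{1,2}, \rho_3, \theta_{3,4}, \delta_{1,2}, \delta_{3,4},
  \gamma) = (5, 4, 3, 3, 4, 0.025)$ with $\rho_4 = 16$ commanding
  $\Gamma = 2$.  These margins keep every stated perturbation test
  (±50% of the insensitive parameters, the 4-fold $\rho_4$ step, γ and
  $\rho_2$ variations) inside the coexistence region.

# Numerical choices

* Integration: `deSolve::ode` with lsoda (stiff-capable), relative
  tolerance $10^{-8}$ and absolute $10^{-10}$ for plain simulation;
  piecewise integration across disturbance events with the event times
  on the output grid, so parameter steps are exact and runs are
  bit-reproducible.
* Steady-state detection: geometric-horizon integration until
  $\lVert\dot x\rVert_\infty/(\lVert x\rVert_\infty + 1) < 10^{-9}$,
  hard budget $10^6$ time units, then damped-Newton polishing of the RHS
  root (accepted only if it reduces the residual and stays
  non-negative).  Oscillatory or slow non-convergence is reported, not
  guessed.
* Jacobians: central differences with step
  $\max(10^{-6}, 10^{-6}|x_i|)$; stability margin $10^{-8}$, eigenvalues
  within the margin reported as marginal and excluded from "stable";
  positivity threshold for strictly positive equilibria $10^{-9}$.
* Equilibrium tie-break: when several equilibria exist, the one reached
  by forward integration from the seed state is returned.
* Negative undershoot: magnitudes below the absolute tolerance are
  clipped to zero in trajectory *outputs* only, never in solver state.
* Autocatalytic states are absorbing at zero by construction
  ($\dot z = z\,(\cdot)$); started positive they remain positive for
  all finite times, and boundary (extinct-controller) equilibria are
  reported as found-but-not-positive.

Problem sizes used by the shipped checks: 20 random oracle networks of
at most 3 reactions integrated at $\varepsilon \in \{1, 10^{-1},
10^{-3}\}$ over 20 time units; 1000 random feasible parameterizations
for the stability sweep; 20 random stable parameterizations for the
set-point comparison; single runs for each application circuit.

# What the synthetic conditions do and do not show

All inputs are synthetic: parameter sets, disturbance schedules and
random networks generated in code.  They emulate the *structure* of
resource-limited circuits — conserved pools, fast complex equilibration,
catalytic (non-consuming) production, logistic competition, well-mixed
QS signalling — under exactly the disturbance classes the theory covers
(persistent steps in rates, loads and totals).  Passing tests therefore
demonstrate the implemented dynamics realise the claimed structural
properties (set-points from controller constants, RPA, ratio manifolds,
insensitivity sets, sufficiency of the stability criterion within the
sampled ranges).  They do not show robustness to what the models omit:
stochastic low-copy effects (autocatalytic extinction is almost sure on
infinite horizons in the noise-dominated regime; deterministic
high-copy operation is assumed throughout), saturation beyond the
provided Hill options, mechanistic growth–burden feedback, spatial
structure, consumable (non-catalytic) resources, or time-varying
resource totals.

# Known limitations

* The sufficient stability criterion is certified only numerically here;
  no Lyapunov/global analysis is provided, and the scan verdicts are
  local.
* `steady_state` can report convergence on the slow manifold near an
  absorbing boundary when a controller species collapses; downstream
  code should check the `positive` flag of `find_positive_equilibrium`
  when the distinction matters.
* The elementary oracle covers bimolecular scenarios 1–2; scenarios 3–4
  exist only in the reduced layer.
* Multi-pool support is limited to reactions drawing from a single pool
  each (the operon circuit uses two pools, one per reaction stage);
  reactions requiring two pools simultaneously are rejected.
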