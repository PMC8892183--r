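---
title: "Modeling passive posture change with tiltsim: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling passive posture change with tiltsim: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(tiltsim)
```

This vignette is the package's own account of its science: the model
equations and their assumptions, the parameters that matter, the
numerical choices, and the design decisions taken where the design was
genuinely open. All computations shown are performed by the package
itself; the figures of merit quoted here are the ones computed by the
test suite and by `scripts/acceptance.R`, nothing else.

## 1. What the model is

`tiltsim` simulates the closed human circulation as a coupled 1D–0D
system under gravity:

* **24 one-dimensional arterial segments** (ascending aorta to the
  distal posterior tibial arteries, with carotid, vertebral, brachial,
  celiac, renal, pelvic and coronary branches) carry pulse-wave
  propagation;
* **31 lumped (0D) compartments** represent the arteriolar, capillary,
  venular and venous beds of five body regions (head, arms, upper
  abdomen, lower abdomen, legs), three venae cavae and the pulmonary
  circulation;
* **four heart chambers** with time-varying elastance, four cardiac
  valves and two venous valves close the loop;
* **short-term regulation** comprises the arterial baroreflex, the
  cardiopulmonary reflex, cerebral autoregulation and an
  intracranial-pressure model.

A posture protocol prescribes the tilt angle $\alpha(t)$ as a
cosinusoidal ramp whose mean slope equals the requested tilting rate;
gravity enters the 1D momentum balance as an axial source
$g A \sin\alpha\,\ell$ (with $\ell$ the signed projection of the vessel
axis on the head–feet body axis) and the 0D side as Stevino pressure
generators $\rho g (z_j - z_i)\sin\alpha$ on the venous and caval
links, where $z$ is measured from the right atrium, feetward positive.

Assumptions worth keeping in mind: blood is Newtonian with a
flat-parabolic velocity profile (profile exponent $\zeta = 9$, momentum
correction $\chi = 1.1$); vessels are straight, axisymmetric and
longitudinally tethered; the supine position is the unloaded reference
(at $\alpha = 0$ the antero-posterior gravity component is neglected);
microvascular compartments are anatomically confined and carry no
hydrostatic column; posture change is strictly passive (no muscle
pump).

## 2. The parameters that matter

All parameters live in `inst/extdata/healthy_male.yaml` as editable
data (SI units for 1D geometry, clinical units — mmHg, ml, s — for the
0D side). The most influential groups:

* **Wall stiffness.** Each vessel specifies a reference pulse wave
  speed `wave_speed_ref` (m/s, 4.9 in the ascending aorta to 9.5 in the
  tibial arteries); the tube-law coefficient is derived as
  $\beta = 2\rho c_0^2\sqrt{A_0}$. `reference_pressure_mmHg` (80 mmHg)
  is the pressure at which $A = A_0$. The Kelvin–Voigt coefficient
  `gamma_visc` (3–9 Pa·s·m) damps high-frequency wave content; it is
  also what keeps the explicit scheme robust, so it should not be set
  to zero on the full tree.
* **Regional resistances.** Arteriolar resistances set the flow split
  (upper abdomen 1.38, legs 3.5, head carotid 16 mmHg·s/ml per
  terminal, etc.) and with the capillary/venular/venous resistances
  produce a supine total peripheral resistance near 1 mmHg·s/ml at a
  cardiac output of ~5.8 l/min.
* **Venous compliances and the legs law.** The upper-abdominal
  (splanchnic) vein dominates total compliance (38 ml/mmHg); the legs
  vein follows the saturating law with `C0` = 19 ml/mmHg and
  `deltaV_max` = 480 ml, which caps orthostatic pooling at a
  physiological few hundred ml.
* **Total blood volume** (5700 ml) is distributed at initialization
  over the 1D tree (grid measure), chambers, coronary bed and 0D
  compartments proportionally to the configured volumes, exactly (the
  first output sample of `V_total` equals the configured total to
  rounding).
* **Heart.** Chamber elastances (`E_max` 2.8 / `E_min` 0.13 mmHg/ml in
  the LV) with a two-phase raised-cosine activation whose systolic
  duration scales as $0.45\sqrt{RR}$ s, so systole occupies a growing
  fraction of the beat as heart rate rises.
* **Regulation gains.** Sigmoid steepness $\nu = 7$; effector gains and
  time constants (HR fast, $\tau$ = 3 s; vascular resistance
  $\tau$ = 6 s; venous tone slow, $\tau$ = 20 s). These defaults were
  calibrated on the shipped configuration so that the supine operating
  point and the steady-state 70° head-up-tilt response land on standard
  clinical values (HR +20–25 %, SV −33 %, CO −19 %, CVP −80 %,
  brachial mean pressure +10 %); the regulation literature provides
  the structure, not transferable numeric gains, so calibration against
  the target physiology is part of the model definition.

## 3. Numerical scheme and choices

**1D.** The spatial discretization stores cell averages (target cell
size `dx` = 0.05 m in the default "reduced" desk-scale mode, 0.025 m in
"full" mode; every vessel keeps at least two cells). Time integration
is the two-step explicit predictor–corrector (Richtmyer/Lax–Wendroff)
scheme. Boundary and junction coupling uses the method of
characteristics: the outgoing Riemann invariant
$W_\pm = u \pm 4(c - c_0)$ is extrapolated from the boundary cell
(advanced by the gravity and friction sources over the travel distance)
and combined with the external relation — prescribed flow at the aortic
root, pressure-plus-characteristic-impedance at terminal beds, mass and
total-pressure conservation at bifurcations (Newton iteration,
residuals converged to ~1e-13 relative, hard failure above 1e-9). The
resulting *star state* provides the boundary face flux of the next
update, a formulation chosen so that the discrete volume budget of the
tree telescopes exactly to the star flows: global blood volume is
conserved to rounding (measured drift below 0.01 ml/s on the full
model, against a 0.5 %/min requirement), while boundary cells still
receive genuine conservative updates and transmit waves cleanly
(spurious reflection at an identical-continuation junction below 2 %).

During development a node-based two-step (MacCormack) variant with
characteristic boundary overwriting was evaluated behind the same
`advance_vessel` contract; it passed the wave oracles but either leaked
volume at the boundary nodes or, when patched to conserve, reflected
spuriously. The flux-form Richtmyer boundary treatment dominates it on
both axes, which is why it is the single shipped scheme.

**Viscoelasticity** is handled operator-split: the Kelvin–Voigt term is
evaluated from the previous step's flow gradient and added as a frozen
momentum source, keeping the scheme explicit.

**0D.** All compartments, chambers, valves and regulation states are
advanced by the matching explicit two-step (Heun) rule with the same
global constant time step (`dt` = 2e-4 s by default; the CFL bound of
every vessel is audited and a violation aborts with the vessel name and
the required step). Compartment *volumes* are the integrated states;
pressures are derived through the (possibly non-linear) constitutive
law, so 0D mass conservation is exact by construction. Controlled
arteriolar inertances scale with the instantaneous resistance factor so
that the explicit R/L eigenvalue stays bounded under vasoconstriction —
the arteriolar inertance is a sub-millisecond time constant either way
and has no visible hemodynamic effect.

**1D–0D exchange** is explicit and staggered: the 0D side integrates
against the star fluxes of the current step; flow continuity at every
terminal is exact by construction and pressure continuity is imposed in
the star solve.

**Beats and steady states.** Beat boundaries are the ventricular
activation onsets (valid during transients); the commanded RR is
updated at each onset from the heart-rate effector, clamped to 40–180
bpm. A phase is "steady" when the beat-averaged root MAP and the RR of
10 consecutive beats deviate from their window mean by less than 1e-3
relative (1e-4 reproduces a limit cycle to that tolerance at
`dt` = 1e-4). Regulation targets (supine mean aortic-carotid pressure,
supine mean right-atrial pressure, supine mean CBF) are captured
automatically at the end of the pre-tilt steady phase, never
hard-coded. Tilt-down protocols first ascend at a configurable
preparatory rate (default 4°/s) and reach a steady tilted state before
the studied descent.

**Degenerate inputs.** Non-positive areas abort with the vessel named;
a 0°→0° schedule is a valid supine-only protocol; `A_min = 0` cardiac
valves close completely (the effective area is floored at 1e-6 cm²,
i.e. a numerically closed orifice); afferent pressures are clamped
positive with a warning before entering the power-law sigmoid.

## 4. Open design decisions

* **Compact arterial tree.** The default tree has 24 segments rather
  than a 55+-segment atlas tree: every measurement site and every
  regional bed used by the tilt analyses is present, and a compact tree
  keeps the closed loop calibratable and desk-scale. The geometry is
  data, not code; a larger tree is a configuration file away.
* **Elastance shape.** Two-phase raised-cosine activation (ventricles)
  and a late single bump (atria), rather than a double-Hill form: the
  raised cosine makes activation onset and time-to-peak exact
  anchors and is C¹; with the $\sqrt{RR}$ systole scaling it reproduces
  the systole/diastole re-balancing at high heart rate that shapes the
  tilted waveforms.
* **Reflex combination.** The cardiopulmonary reflex reuses the
  baroreflex efferent equation with its own afferent and adds its
  contribution on the shared vascular effectors (resistance, venous
  tone) only — additive superposition is the natural reading of "same
  efferent equation, second afferent".
* **Afferent averaging** is an exponential moving average with a 2 s
  time constant (a beat-synchronous mean is an accepted alternative
  behind the same contract); effector dynamics are pure first-order
  lags without transport delays, which reproduces the observed
  non-oscillatory transients; delays could be added in configuration.
* **Intracranial pressure.** Davson's equation with the dural pressure
  referenced to CVP minus the head-to-heart column while the jugular
  (superior vena cava) pressure is positive, and to the column above
  the zero-transmural collapse point beyond the collapse angle. The two
  branches coincide exactly at the collapse condition, so $p_{ic}$ is
  continuous in $\alpha$; applied as extravascular pressure on the
  cerebral veins only, it keeps their transmural pressure within
  ±2 mmHg at 70°.
* **Viscoelastic coefficient units.** The Kelvin–Voigt term
  $\Gamma/(A_0\sqrt{A})\,\partial_t A$ is a pressure when $\Gamma$
  carries Pa·s·m; the configuration documents and uses that unit.
* **Gravity source sign convention.** `axial_gravity_term()` returns
  the body force per unit length measured along the feet-to-head
  direction ($-\rho g A \sin\alpha\,\ell$): negative for feetward
  vessels, where gravity drives flow distally. The solver divides by
  $\rho$ and flips the sign into the flow equation, so hydrostatic
  equilibrium reproduces a pressure that increases feetward.

## 5. What the default configuration emulates — and what it does not

The shipped `healthy_male` configuration represents a generic healthy
adult male: 5700 ml blood volume, supine HR 68 bpm, MAP ~100 mmHg, CO
~5.8 l/min, CBF ~12 ml/s, CVP ~8 mmHg, and the anatomical heights that
set the orthostatic columns (heart-to-foot ~1.37 m, head-to-heart
~0.31 m, legs-vein-to-abdominal-cava ~0.55 m). Passing the package's
checks on this configuration demonstrates that the coupled model
reproduces the canonical steady-state and transient orthostatic
physiology *of that reference subject*; it does not demonstrate
subject-specific fidelity, pathology (orthostatic hypotension,
syncope), active standing, or long-duration adaptation.

Known limitations, deliberate in scope: no long-term (renal, hormonal,
metabolic) regulation; no transcapillary filtration; no venous
stress-relaxation; no collapsible-tube treatment of the jugular veins
(collapse enters only through the intracranial-pressure branch); no
muscular pumping; no respiratory oscillation of the intrathoracic
pressure; no coronary autoregulation.

## 6. Problem sizes used by the tests and the acceptance script

The package's own verification runs use the reduced desk-scale grid
(`dx` = 0.05 m, `dt` = 2e-4 s, ~110 cells over the tree, output at
200 Hz): a full 70° head-up-tilt protocol (~90–130 beats including both
steady phases) integrates in well under a minute on one CPU. The rate
sweep uses 35, 8, 4 and 2.5 °/s protocols, and the tilt-up/tilt-down
asymmetry comparison runs the slowest (1.4 °/s) pair. The solver
oracles (analytic wave speed, hydrostatic equilibrium, closed-end
pressure doubling, matched-impedance absorption, junction mass
conservation, grid convergence) run on metre-scale single vessels and a
symmetric bifurcation in seconds. Halving `dt` changes the
beat-averaged supine MAP by well under 0.1 %, and halving `dx` changes
the steady tilt response by ~1 %, which is the package's basis for
treating the reduced grid as the default study condition.
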