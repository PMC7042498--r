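---
title: "Lumped-parameter modelling of central systemic-to-pulmonary shunts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lumped-parameter modelling of central systemic-to-pulmonary shunts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shuntr)
```

## The clinical problem

Newborns with pulmonary artery (PA) atresia or critical stenosis cannot
perfuse their lungs adequately. A palliative central shunt — a synthetic graft
from the ascending aorta to the pulmonary artery — re-routes part of the
cardiac output into the lungs until corrective surgery is possible. The
surgeon must pick a graft diameter: too small and oxygenation suffers; too
large and the lungs flood, the systemic circulation is starved, and the heart
carries a larger energetic burden. When some antegrade flow persists through
the stenosed native main pulmonary artery (MPA), that residual flow interacts
with the shunt flow and shifts the optimum.

`shuntr` models this trade-off at desk scale with a steady-state
zero-dimensional (0D) flow network, sweeping shunt diameter and stenosis
severity over a 35-case design grid and reporting the field's standard
metrics: the pulmonary-to-systemic flow ratio $Q_P/Q_S$, the left/right
pulmonary flow split $Q_{LPA}/Q_{RPA}$, power loss (PL) and relative power
loss (RPL), the shunt Reynolds number, and systemic oxygen delivery $DO_2$.

## The circulation model

Two pressure nodes — aortic and pulmonary — are bridged by the shunt element
and drained by six linear outlet resistances representing the downstream
vascular beds: innominate (IA), left carotid (LCA), left subclavian (LSA) and
descending aorta (DAO) on the systemic side, left and right pulmonary arteries
(LPA, RPA) on the pulmonary side. Inflows are prescribed: the stenosis ratio

$$\alpha = \frac{Q_{MPA}}{CO}, \qquad \alpha \in [0, 0.30],$$

grades the native stenosis ($\alpha = 0$ is atresia), and the cardiac output
splits as $Q_{AAO} = (1-\alpha)\,CO$ into the aorta and $Q_{MPA} =
\alpha\,CO$ into the pulmonary node. At $\alpha = 0$ the MPA inlet is removed
entirely. The split is the model's closure of the inlet boundary conditions:
it keeps $Q_{AAO} + Q_{MPA} = CO$ and is the only split consistent with the
definition of $\alpha$ as a flow fraction.

The shunt is the one nonlinear element:

$$\Delta P = \frac{128\,\mu L}{\pi d^4}\,Q
  \;+\; K\,\frac{\rho}{2}\left(\frac{Q}{A}\right)^2 \mathrm{sign}(Q),$$

a Poiseuille term for the graft lumen plus a quadratic minor loss for the two
anastomoses. No 0D constitutive law is published for this geometry, so the
classical pipe-plus-fitting form is adopted; it is odd and strictly monotone
in $Q$, which guarantees a unique steady state. Each outlet can also be
expressed as a porous-zone viscous coefficient $X = R\,A/(\mu\,l)$
(`viscous_resistance()`), the form used to impose lumped resistances in 3D
CFD solvers.

### Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| outlet resistances | 2383, 4792, 4260, 1152, 131, 131 | MPa·s·m⁻³ | published patient-specific set (IA, LCA, LSA, DAO, LPA, RPA) |
| blood $\rho$, $\mu$ | 1060, 0.005 | kg/m³, Pa·s | Newtonian incompressible blood |
| shunt length $L$ | 20 | mm | typical central-shunt graft scale (not published) |
| minor-loss $K$ | 1.5 | — | entrance + tee-junction order of magnitude (not published) |
| porous length $l$ | 10 | mm | per-outlet porous-zone length (not published) |
| cardiac output | 2.122–2.798 | L/min | per-diameter table; CO depends on diameter only, not $\alpha$ |
| `lpa_rpa_asymmetry` | 1 | — | multiplier on the LPA series resistance |
| reference pressure | 0 | Pa | venous pressure neglected (see below) |

Outlets discharge to 0 Pa because the published resistances were calibrated
against *mean arterial pressure* and no venous pressure is reported;
absorbing a venous offset into the resistances would double-count it. The
solver accepts any other reference pressure.

Whether the stenosed MPA should be driven by prescribed flow or prescribed
pressure is not decidable from the source material; prescribed flow is used
because $\alpha$ is defined as a flow ratio, which makes the $\alpha$-grid
exact by construction.

## Numerical scheme

`solve_steady()` runs damped Newton iteration on the two node pressures. The
shunt flow is recovered from the pressure difference through the closed-form
inverse of the shunt law, so the nonlinear constitutive relation holds exactly
at every iterate and the residual is purely the nodal flow imbalance. The
initial guess is the linearised ($K = 0$) network, from which Newton converges
quadratically in 3–8 iterations for every grid case.

The convergence *contract* is a nodal flow residual below $10^{-10}$ m³/s
(stricter than the $10^{-8}$ kg/s mass-conservation bound reported with each
solution), but iteration continues to the numerical rounding floor
(~$10^{-20}$ m³/s, stopping when the residual stops improving). The extra one
or two quadratic steps are free and they keep the energy bookkeeping
consistent: with an $O(10^{-10})$ m³/s imbalance, the port-based power loss
and the element-dissipation sum would disagree at the $10^{-6}$ relative
level, defeating the $10^{-8}$ consistency oracle below.

A converged solution with negative (pulmonary-to-aortic) shunt flow is
physically meaningful but clinically alarming; it is returned with a
`shunt_reversed` flag and a typed warning, never silently.

## Energy bookkeeping

Power loss is the total-pressure energy budget over the domain ports (two
inlets, six outlets), with the port mean velocity $v = Q/A$:

$$PL = \sum_{in}\left(p + \tfrac12 \rho v^2\right) Q
  \;-\; \sum_{out}\left(p + \tfrac12 \rho v^2\right) Q .$$

RPL divides PL by the *inlet energy flux* $\sum_{in}(p + \tfrac12\rho v^2)Q$.
A formula without the flow factor $Q$ in the denominator would not be a ratio
of powers; the flux form is the dimensionally consistent reading of
"relative power loss" and is the one implemented.

`element_dissipation()` recomputes the same quantity by a second route — each
element's total-pressure drop times its flow, with the node-side kinetic head
taken from that node's inlet port velocity. Under this convention the two
routes agree *algebraically* whenever mass is conserved, so their comparison
(asserted to $10^{-8}$ relative across the grid) is a genuine consistency
oracle on the solver's port states and mass balance rather than a tautology
of shared code.

Two caveats on interpreting PL/RPL. First, the 0D domain *contains* the
downstream resistances, so nearly all inlet energy is dissipated inside it
and RPL sits near 87–99%; a 3D anatomical domain excludes the downstream
beds and reports 22–42%. Second, absolute PL values of the 3D solution
reflect local jet and vortex structure the 0D network cannot represent. Only
directions of change are asserted: PL falls as $\alpha$ rises at fixed
diameter, matching the 3D trend.

## Oxygen transport

At steady state the lungs load what the body consumes
($S\dot{V}O_2 = C\dot{V}O_2$):

$$Q_S\,(C_{art} - C_{ven}) = C\dot{V}O_2, \qquad
  Q_P\,(C_{pv} - C_{art}) = S\dot{V}O_2 .$$

Eliminating the contents with $CO = Q_S + Q_P$ and $r = Q_P/Q_S$ gives the
delivery formula

$$DO_2 = \frac{CO \cdot C_{pv}}{1 + r} - \frac{C\dot{V}O_2}{r} = Q_S\,C_{art},$$

with $C_{pv} = 0.2112$ mL O₂/mL blood (96% pulmonary venous saturation, used
directly rather than re-derived from a carrying capacity) and
$C\dot{V}O_2 = 18$ mL O₂/min, both fixed — no exercise scaling, mirroring the
model's short-term post-operative scope. Operating points where the balance
has no physical solution ($C_{art} \le 0$, $C_{ven} < 0$ or $DO_2 \le 0$)
raise typed errors, and the sweep driver marks such rows
`oxygen_infeasible` instead of clipping or dropping them. The feasibility
boundary $Q_P = C\dot{V}O_2 / C_{pv}$ is tested on flows so the boundary
itself errors regardless of rounding.

```{r do2}
oxygen_delivery(1.01, 2122)   # balanced 3 mm point: ~205.15 mL O2/min
oxygen_delivery(2.96, 2798)   # wide-open 5 mm shunt at alpha = 30%
```

## Boundary-condition calibration

`calibrate_outlet_resistances()` reproduces the resistance-tuning procedure:
given a clinical mean arterial pressure (MAP, estimated as diastolic + pulse
pressure / 3 — the standard cuff formula; the source does not define its
mean) and per-outlet fractions of systemic flow, the single-node parallel
identity $R_i = (MAP - P_{ref})/(f_i\,Q_S)$ returns resistances that
reproduce both targets exactly at the calibration operating point. Because
the "physiological flow distribution" percentages behind the published
resistances are not reported, the default fractions are those implied by the
published values themselves ($f_i \propto 1/R_i$); calibration at those
fractions and the matching operating point returns the published set, and the
round trip recovers arbitrary synthetic patients to $10^{-8}$ relative.
Calibration touches the systemic side only — pulmonary downstream
resistance (PVR) is held at its fixed value throughout, so that only shunt
diameter and $\alpha$ vary across the design grid. With the published resistances and $Q_S = CO/(1+1.01)$ at
$CO = 2.122$ L/min, the model MAP misses the clinical 74.33 mmHg by about
2.6%, inside the 5% acceptance bound conventionally used when tuning
resistance boundary conditions.

## The virtual-patient generator

`generate_patient()` emulates patient-to-patient variability around the
published reference set: resistances are drawn log-normally (median at the
reference value, coefficient of variation 0.2 by default — log-normal keeps
them positive, and 20% is a realistic between-patient spread for vascular
resistance); lumen areas scale uniformly by ±20% around pediatric-scale
defaults (12 mm ascending aorta, 8 mm MPA, 3–8 mm branches — no lumen sizes
are published); the LPA/RPA asymmetry factor is uniform on [0.8, 1.25] and
the shunt loss coefficient on [1.0, 2.0]. Generation is seeded and leaves the
caller's RNG state untouched.

What the generator does *not* emulate: actual 3D branching geometry, vessel
compliance, and any correlation structure between beds (draws are
independent). A green test on synthetic patients therefore establishes that
the *pipeline* is correct and stable over a realistic parameter cloud — not
that the 0D model reproduces any particular patient's CFD values.

## The design grid

```{r grid}
res <- run_grid(reference_patient(), sweep_grid())
res[res$alpha %in% c(0, 0.30) & res$diameter_mm %in% c(3, 5),
    c("diameter_mm", "alpha", "qp_qs", "pl_mW", "rpl_pct", "do2_ml_min")]
```

The qualitative structure matches patient-specific 3D CFD analyses of the
same configuration: $Q_P/Q_S$ rises with both
diameter and $\alpha$; $DO_2$ falls as the shunt steals systemic flow; PL
falls with increasing $\alpha$. The absolute $Q_P/Q_S$ level of the 0D
network is higher than the CFD's (e.g. 1.32 vs 1.01 at 3 mm, $\alpha = 0$)
because the lumped shunt law lacks the 3D anastomosis losses; CFD-level
$Q_P/Q_S$, $Q_{LPA}/Q_{RPA}$ and PL values are treated as fixtures for
direction-of-change checks, not as predictions to reproduce.

## Known limitations

* Steady state only; no pulsatility, compliance or inertance (rigid-wall
  mean-flow surrogate).
* The shunt minor-loss coefficient and length are engineering defaults, not
  identified from data; absolute flow splits shift with them.
* The mean-flow shunt Reynolds number (≈1300–2000 across the grid) is far
  below the ≈4500 local 3D value, which evidently reflects a local jet
  velocity; only the sanity bound Re < 10⁴ is asserted.
* Oxygen parameters are constants; the model cannot predict whole-body
  responses (exercise, CO autoregulation).
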