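---
title: "Image-based wall stiffness and its propagation through a 0D aortic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based wall stiffness and its propagation through a 0D aortic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortaUQ)
```

## The problem

Patient-specific hemodynamic models need the elastic modulus $E$ of the
vessel wall, which cannot be measured directly in vivo. It can, however,
be *inferred from imaging*: phase-contrast MRI yields, frame by frame over
the cardiac cycle, the through-plane flow $Q(t)$ and the lumen
cross-sectional area $A(t)$ at a chosen cross-section. That estimate
carries an uncertainty of roughly $\pm 20\%$, and the question this
package answers quantitatively is: *how much does that uncertainty matter
for the model outputs one actually cares about* — flow and area waveforms
along the vessel?

The package implements the whole chain: (1) the $\chi$-method estimator of
$E$ from a QA dataset, (2) a deterministic lumped-parameter (0D) aortic
surrogate with three-element Windkessel outlets, and (3) non-intrusive
generalized Polynomial Chaos (gPC) propagation of the stiffness
uncertainty through the surrogate, with time-resolved stochastic
summaries.

## The $\chi$-method

During the *reflection-free early systole* the QA relation is close to
linear and its slope is the local pulse wave velocity,
$$\mathrm{PWV} = \left.\frac{dQ}{dA}\right|_{\text{early systole}},$$
fitted here by ordinary least squares of $Q$ on $A$ over a window on the
first rising limb of the flow curve (samples between 15% and 85% of the
systolic peak by default; an explicit window can be supplied instead,
since clinical practice often hand-picks the points). The wall stiffness
follows from
$$E = 3\,\chi\,\rho\,\mathrm{PWV}^2\left(1 + \frac{A_0}{\mathrm{WCSA}}\right),
\qquad \chi = \frac{\gamma}{\mathrm{RAC}},$$
with $A_0$ the diastolic lumen area, WCSA the wall cross-sectional area,
$\rho$ the blood density and RAC the relative area change over the cycle.

**The $\gamma$ correction is deliberately pluggable.** Its closed form
involves a regression on diastolic area, flow and internal pressure that
is not part of this package; `estimate_elasticity()` accepts a scalar or a
callable `gamma`, and defaults to $\chi = 1$ — the original, uncorrected
formulation. With that default the recorded `gamma` is back-filled as
$\chi \cdot \mathrm{RAC}$ so the identity $\chi\,\mathrm{RAC} = \gamma$
always holds. The RAC denominator is configurable
(`"max"` default, `"min"`, `"first"`) because the literature is not
unanimous.

## The deterministic surrogate

The 3D fluid–structure model the study design assumes is replaced by a
desk-scale 0D network so that every stage runs in seconds with no
external data. Each aortic segment becomes a resistance–inertance–
compliance triplet:

* wave speed from the stiffness by inverting the formula above,
* volume compliance from Bramwell–Hill, $C = A_0 L/(\rho\,\mathrm{PWV}^2)$,
* Poiseuille resistance $R = 8\pi\mu L/A_0^2$ and blood inertance
  $L_b = \rho L / A_0$.

The aortic topology is a serial chain of five segments (CS1 proximal to
the valve, CS2/CS3 around the supra-aortic junction, CS4/CS5 descending),
three Windkessel outlets at the junction and a terminal
descending-aorta Windkessel, using the standard RCR table
(`make_fixture_config("aorta_default")`). Segment areas follow the linear
tube law about diastole,
$A_i(t) = A_{0,i}\bigl(1 + (p_i(t) - p_{\mathrm{dias},i})/(\rho\,\mathrm{PWV}_i^2)\bigr)$,
with the diastolic reference taken per node as the minimum pressure of
the converged cycle (a constant reference can be supplied).

Fixture geometry is synthetic and labelled as such: $A_0$ tapers from
$8\times10^{-4}$ to $3\times10^{-4}\,\mathrm{m^2}$ (32 to 20 mm
diameter), WCSA $= A_0/4$, lengths summing to 0.35 m. The inflow is a
half-sine systole over 35% of a 1.12 s cycle with a stroke volume of
80 mL — chosen once because, against the RCR table's total resistance, it
yields a mean aortic pressure near 100 mmHg and a physiological
90–105/70 mmHg envelope.

### Numerical choices

* **Integrator.** Classical fixed-step RK4 on a 5 ms output grid
  (10 cycles by default). The terminal node's half-compliance against the
  descending outlet's proximal resistance creates a $\sim$0.25 ms time
  constant, far stiffer than 5 ms, so `run_cycles()` substeps internally;
  the substep count comes from a conservative linear stability estimate
  (node relaxation rates, segment LC ring frequencies, reservoir rates,
  with a safety factor) and can be overridden — which is also how the
  step-refinement convergence test works honestly.
* **Initial state.** The outlet reservoirs have $R_d C \approx 1.9$ s, so
  a cold (all-zero) start still carries a $\sim$0.3% transient after the
  standard 10-cycle run-in. The aorta presets therefore ship a DC
  warm-start (the purely resistive operating point); `assemble_network()`
  itself defaults to zero when no initial state is given. Periodicity is
  reported as the relative $L_2$ difference of the last two cycles' node
  pressures, warning above $10^{-3}$.
* **Mass conservation** over the converged cycle (inlet mean vs summed
  outlet means) is a standing test at 0.5%.

## Uncertainty propagation

The uncertain input is $E \sim \mathcal{U}[0.77\hat E,\ 1.23\hat E]$: the
$\pm 20\%$ worst-case estimation error widened to a safe $\pm 23\%$ band,
and uniform because nothing more informative is known. Uniform input
pairs with Legendre polynomials; the expansion
$X(\zeta) = \sum_{r=0}^{n} a_r P_r(\zeta)$ is truncated at $n = 3$, and
the coefficients are computed non-intrusively from $n+1 = 4$
deterministic runs at the Gauss–Legendre nodes mapped onto the band:
$$a_r = (2r+1) \sum_q w_q\, X(\zeta_q) P_r(\zeta_q),$$
the discrete projection under the probability weight
$\eta(\zeta) = 1/2$, for which $\langle P_r, P_r\rangle = 1/(2r+1)$ —
the normalization is stated explicitly here because different gPC codes
differ in it (it rescales the coefficients, not the moments or
densities). Quadrature points are labelled $x_1 > x_2 > \dots$ in
descending order. Means and standard deviations come from the
coefficients in closed form ($\mu = a_0$,
$\sigma^2 = \sum_{r\ge1} a_r^2/(2r+1)$); densities are estimated by a
seeded Monte-Carlo push of $\zeta \sim \mathcal U[-1,1]$ through the
surrogate ($10^5$ draws, 64 bins by default) rather than by the analytic
change of variables, because a truncated cubic surrogate can be
non-monotone on $[-1,1]$, making the analytic density multi-branch —
this is exactly the regime that produces double-lobed densities.

Truncation is trusted when higher-order coefficients decay. The pipeline
report summarizes decay as cycle-wise norm ratios
$\lVert a_r \rVert_2 / \lVert a_0 \rVert_2$ and warns above 0.1; the
pointwise ratio $|a_r/a_0|$ (also provided) is unbounded wherever a flow
curve's $a_0$ crosses zero in diastole, which is why it is not the
report's summary statistic.

When comparing flow against area sensitivity, $\sigma$ is normalized by
the pulsatile excursion (max − min) of the mean curve: total area carries
the arbitrary baseline $A_0$, which the stiffness uncertainty does not
touch, so normalizing by the mean value would understate the area effect
arbitrarily.

## The synthetic-data generator: its world and its limits

`synthesize_qa_curves()` inverts the measurement chain with a known
ground truth: a single compliant segment at $E_{\mathrm{true}}$,
terminated by a Windkessel whose proximal resistance *matches the
characteristic impedance* $Z_c = \rho\,\mathrm{PWV}/A_0$ and whose
reservoir is deliberately slow ($R_p C = 20$ cycles, warm-started at its
exact periodic mean $\bar Q R_d$, since it could never converge from zero
in 10 cycles). Matching is the 0D embodiment of the reflection-free
assumption: at the measurement plane (flow into the outlet, area from the
same node's pressure) the early-systolic $dQ/dA$ then equals the wave
speed up to the small reservoir drift over the window. Output is
resampled to 30 uniform frames (retrospective gating) by linear
interpolation; optional Gaussian frame noise is seeded.

What a green recovery test establishes: the estimator chain is
numerically faithful when its central assumption holds. What it does
**not** establish: recovery in the presence of wave reflections. In the
five-segment aorta fixture the QA slope at a node reflects the
*input impedance of the downstream tree*, not $Z_c$ — the RCR table's
terminal proximal resistance is far below the distal segment's
characteristic impedance, so reflections are strong and the QA-loop
estimate at CS1 overshoots the imposed wave speed substantially. This is
a physical property of lumped networks, documented here as a limitation;
closed-loop recovery is therefore asserted only in the matched
single-segment world.

On measurement noise: in this stated world the full area pulse is only
$\sim$3–4% of $A_0$ (a stiff aorta at $\mathrm{PWV} \approx 11$ m/s
deforms little), so per-frame area noise of 2% of $A_0$ is of the same
order as the *entire* pulse and larger than the area spread inside the
early-systolic window. Under the estimator's fit direction ($Q$ on $A$,
noise on the regressor) this produces severe errors-in-variables
attenuation of the slope, and no window-based estimator can deliver a 3%
bias at that signal-to-noise ratio; the corresponding acceptance test is
kept faithful to its stated noise level and is expected to fail, while
the noise-dispersion monotonicity property is tested at noise levels
inside the estimator's working range. This is consistent with the
$\pm 20\%$ error band that motivates the uncertainty analysis in the
first place.

## Worked run

```{r, eval = FALSE}
cfg <- study_config(e_hat = 2.02e6, seed = 1, out_dir = "uq-out")
res <- run_uq(cfg)
res$quadrature_values / 1e6   # 2.42, 2.18, 1.86, 1.62 MPa
```

The exported summaries (`<CS>_<quantity>_summary.csv`,
`<CS>_<quantity>_pdf.csv`, `manifest.json`) contain everything needed to
redraw the time-resolved mean/σ/PDF figures; re-running with the same
seed reproduces them bit for bit.

## Known limitations

* The 0D surrogate is a stand-in, not a claim of hemodynamic equivalence
  with a 3D fluid–structure model: no secondary flows, no wall inertia,
  no wave transit delays; only the contracted outputs (per-section
  $Q_i(t)$, $A_i(t)$) are meaningful.
* $\gamma$ is not computed internally; with the default $\chi = 1$ the
  estimator is the uncorrected formulation.
* Single uncertain parameter only (no sparse grids, no joint
  expansions); flow and area only.
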