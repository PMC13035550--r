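---
title: "A multiscale cardiopulmonary model of postnatal hyperoxia in pediatric rats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale cardiopulmonary model of postnatal hyperoxia in pediatric rats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Postnatal hyperoxia in rat pups (85% oxygen for the first two weeks of
life, "Hx"; room-air littermates "Nx") is a standard rodent model of human
preterm birth: at postnatal day 21 the exposed animals show pulmonary
hypertension, right-ventricular (RV) dysfunction, and depressed cardiac
mitochondrial capacity. `ratheart` implements a subject-specific,
multiscale model of this system — crossbridge kinetics inside a
biventricular spherical-cap heart inside a closed-loop circulation — along
with the analysis workflow that turns per-animal catheter data into
calibrated models and derived physiologic markers. This vignette is the
package's own account of the model, its assumptions, and the numerical and
design choices behind it.

## The model

### Calcium activation

Cytosolic Ca$^{2+}$ is prescribed, not solved: a raised-cosine rise of
amplitude 2 µM above a diastolic floor of 0.1610 µM over a fraction
$k_\mathrm{TS}$ of the cycle, a raised-cosine decay over $k_\mathrm{TR}$,
and the floor otherwise. The two timing fractions are subject-specific
calibration parameters; the floor and amplitude are fixed for all animals.
Thin-filament regulation is a permissible/non-permissible pseudo-state pair
gated by Ca$^{2+}$ binding to troponin C with rates $k_\mathrm{on}
\mathrm{Ca}^{n_H}$ and $k_\mathrm{off}$. The cooperativity exponent
$n_H = 3.6$ is a fixed model constant within the physiological range for
rat myocardium (Hill coefficients of 3–6); because the half-activation
point scales as $(k_\mathrm{off}/k_\mathrm{on})^{1/n_H}$, a proportional
increase of $k_\mathrm{on}$ and decrease of $k_\mathrm{off}$ shift the
steady-state force–pCa curve identically, a property the test suite checks.

### Crossbridge moments

Each wall carries a five-state crossbridge pool — loosely attached $A_1$,
strongly attached $A_2$, post-ratchet $A_3$, unattached $U$, and
super-relaxed $U_\mathrm{SR}$ — with the attached-state strain
distributions represented by their 0th–2nd moments (9 moment states plus
the non-permissible and super-relaxed fractions, 11 kinetic states per
wall). Attachment inserts heads at zero strain with flux
$k_a \cdot \mathrm{OV}(L_s) \cdot P$, where OV is a piecewise-linear
thick-filament overlap tent (knots at 1.50, 1.95, 2.40, 3.30 µm, unit
plateau) and $P$ the permissible unattached fraction. Transition rates are
strain-independent except the exit from $A_3$, which carries a Boltzmann
factor on the residual stroke energy,
$k_3 \exp\!\big(k_{\mathrm{stiff},2}(\Delta r - \bar s_3)/\sigma_B\big)$
(clamped at the base rate for lengthening). This term does two things:
during shortening it accelerates cycling (a force–velocity effect), and at
isometric steady state it saturates the stiffness-to-force map, so a 70%
increase of $k_{\mathrm{stiff},2}$ raises maximal force by only a few
percent — the regime the hyperoxia parameterization requires. With
constant rates the moment hierarchy is exactly closed (no closure
approximation beyond the strain-linearized $A_3$ exit, which uses the mean
strain $\bar s_3 = p_3^1/p_3^0$).

Metabolites enter the rates as factors normalized to 1 at the nominal
cytosolic pool (ATP 8 mM, ADP 0.05 mM, Pi 1 mM): the reverse of the
loose-to-strong transition scales with [Pi] (the rebinding pathway,
exactly zero at zero Pi), and the $A_3$ exit passes through ADP release
(competitively slowed via $K_D$) and ATP binding (saturable via $K_T$) in
series. The hyperoxic ±5% metabolite shifts therefore slow the exit and
raise force slightly, in the direction the force–pCa screen requires.

Active stress is
$\sigma_\mathrm{XB} = \mathrm{OV}\,(k_{\mathrm{stiff},1}(p_2^1+p_3^1) +
k_{\mathrm{stiff},2}\,\Delta r\, p_3^0)$; passive stress is a one-sided
power law $k_\mathrm{passive}(L_s - L_{sc0})^\gamma$ (zero below slack —
collagen carries no compression); a linear series element
$K_{SE}(L_{s,\mathrm{wall}} - L_s)$ transmits the wall stress, and the
contractile length evolves so the balance
$\sigma_{SE} = \sigma_\mathrm{XB} + \sigma_\mathrm{pas} +
\eta\,\mathrm{d}L_s/\mathrm{d}t$ holds identically. The viscosity is small
($\eta = 0.025$ kPa·s/µm): larger values act as an unphysical brake on
diastolic refilling at rat heart rates.

### Biventricular geometry and circulation

The LV free wall, septum, and RV free wall are three thick spherical caps
meeting at a circular junction: four unknowns (three cap heights $x_m$,
positive toward the RV, and the junction radius $y_m$) satisfy the two
cavity-volume constraints and the axial and radial midwall tension
balances. Midwall area, curvature, wall strain (with the standard
thick-wall corrections in the dimensionless thickness $z$), and the cap
sarcomere length $L_{s,\mathrm{wall}} = L_{s,\mathrm{ref}} e^{\varepsilon_f}$
follow from the geometry; transmural pressures come from the axial tension
components, which makes the trans-septal pressure difference automatically
consistent with the septal Laplace relation. There is no pericardium
(catheterized rodent preparations rupture it). The tension normalization
is fixed by the thin-wall spherical limit $P = 2\sigma h/r$, which the
tests verify against the closed form.

A note on uniqueness: with *prescribed* (dead) wall stresses the junction
balance admits buckled septal roots — a genuine snap-through. With the
elastic closure (stress from the strain-dependent series element) the flat
septum is the unique equilibrium of the mirror-symmetric configuration,
and the dynamic model always operates in the elastic setting; the
fixed-stress mode exists for unit-level analysis only.

The circulation is six compartments (LV, RV, systemic and pulmonary
arteries and veins) with linear compliances, linear vascular resistances,
and ideal-diode valves `max(dP, 0)/R`. The full system has 46 states: 33
crossbridge, 3 contractile lengths, 4 TriSeg unknowns (algebraic rows of a
singular mass matrix), and 6 volumes, whose derivatives sum to zero
exactly.

### Numerics

The right-hand side is compiled C, integrated cycle-by-cycle with the
implicit Radau method (relative tolerance 1e-7, absolute 1e-9) as an
index-1 DAE. Steady state is declared when both ventricles' per-cycle
EDV/ESV change by less than 1e-3 (relative), with a 40-cycle budget;
a typical simulation needs 15–35 cycles and runs in ~0.2 s. Initial
conditions: ventricles at the record's end-diastolic volumes, geometry
solved by damped Newton (staged: stress-uniform first, elastic refinement
second, with a small cascade of starting shapes), crossbridges detached
with the super-relaxed pool at its kinetic resting fraction, and vascular
volumes distributed as zero-pressure volumes plus a compliance-weighted
share of the remainder so the total is exactly the blood volume. The
force–pCa experiment does not integrate at all: at constant Ca and zero
sliding velocity the first moments vanish and the occupancies solve a
linear chain, leaving one scalar root-find in $L_s$; the time-integration
route is retained as an independent oracle in the test suite and agrees to
better than 1e-4.

## Nominal parameterization

Each animal's 54-parameter set is built from its record: blood volume at
0.06 mL/g bodyweight; wall volumes from condition-specific wall-weight
ratios (Nx 3.8 and 0.86 mg/g, Hx 3.2 and 1.00 mg/g for LV+septum and RV;
LV takes 2/3 and septum 1/3 of the combined weight; density 1.055 g/mL,
and the ratio units are read as mg wall per g bodyweight — the only
plausible dimension for values of 0.86–3.8); a 20% pediatric reduction of
the attachment rate applied to all walls; and record-driven circulation
values (systemic resistance from a mean-pressure target of 0.75 × LV ESP,
pulmonary resistance from 0.88 × RV ESP, compliances from pulse-pressure
targets, and the pulmonary compliance target chosen so the normoxic value
lands near the reported 0.027 cm³/kPa).

Midwall reference areas are anchored at end diastole: the balanced cap
geometry at the measured EDVs (which is independent of the reference
areas) is solved first, and each wall's reference area is then set so its
end-diastolic sarcomere strain carries the measured end-diastolic
pressure through the passive curve. The septum is anchored with the LV
(same tissue). The RV is the exception: it is anchored at ~1.4 mmHg — the
value this model family characteristically produces, under-predicting
measured RV EDP by 2–4 mmHg — because forcing the thin RV wall to carry
the full measured EDP gives it an outsized diastolic stress share that
suppresses the systolic septal dynamics. The same flat end-diastolic RV
behavior is visible in the calibration residuals.

The remaining cellular constants are the package's own pediatric-rat
values, fixed once against the study conditions: the closed-loop steady
state at the normoxic group-average record reproduces LV/RV end-systolic
pressures and mean PA pressure near their group means; the paired
force–pCa experiment under the hyperoxia modifiers (RV
$k_\mathrm{off}$ −40%, $k_{\mathrm{stiff},1,2}$ +70%, metabolites ±5%)
yields a ≈ +1% pCa50 shift and ≈ +1.7% Fmax change, which pins $n_H$ and
$\sigma_B$; and all eleven directional single-parameter effects on the
force–pCa curve hold. The Ca-rise fraction default ($k_\mathrm{TS} =
0.08$, a ~14 ms upstroke) puts the timing parameters in the influential
regime of the sensitivity ranking, as observed for this model class. On
the hyperoxic side, no extra afterload dial is needed: the record-driven
pulmonary resistance rises by ~55% simply because the Hx group's RV
end-systolic pressures are higher.

The Pi sign ambiguity (a stated 5% increase beside a printed −5) is kept
as an option: `apply_hyperoxia_modifiers(p, pi_sign = "text")` (default,
+5%) or `"printed"` (−5%); the effect on every reported quantity is well
below its tolerance.

## Sensitivity, subset selection, calibration

Local sensitivity is a centered difference on log-parameters (h = 0.01)
of the concatenated LV/RV pressure and volume signals (4 × 50 points) for
the 18 organ-scale and timing parameters. Each animal's per-parameter
scalar is the Euclidean norm of its column — the reduction is a package
choice; the normalized values span [0, 1] per animal and parameters above
0.1 count as influential. The calibration subset is the intersection of
the influential sets across conditions (which is what drops marginal
compliances flagged in only one group) and must pass the Fisher
information screen $\mathrm{cond}(S^\top S) < 10^8$; at the normoxic
group-average parameterization the ten-parameter subset (two resistances,
three reference areas, three wall volumes, two timing fractions) has a
condition number of order 1e4–1e5.

Calibration minimizes 208 residuals — four dynamic blocks scaled by
$1/\sqrt{N}$ and the data-trace maximum, plus eight relative static
endpoint residuals (the $1/\sqrt{N}$ scaling is what gives the static
octet its larger relative weight) — with bounded Levenberg–Marquardt on
log-parameters. Box bounds follow the multiplicative-log rule for shape
parameters with areas in mm² and volumes in mm³ (the rule is
unit-dependent and collapses for values near 1, so O(10–100) units are
the only workable reading), [0.1, 10] × log-nominal for the resistances,
and absolute boxes (0.001–0.1, 0.3–0.5) for the timing fractions. The
first start is always the nominal point (nominal geometry seeds the
calibration); the rest are drawn within ±50% of log-nominal and clipped.
Three robustness policies are the package's own: starts whose first
simulation fails are contracted deterministically toward log-nominal;
failed simulations inside the optimizer return a constant 1e3 penalty
vector; finite-difference steps are widened (`epsfcn`) above the
steady-state truncation noise, and a final polish stage restarts the
trust region from the winning start with a tighter steady-state tolerance
(2e-4). On noise-free synthetic data the ten parameters are recovered
with a median absolute relative error of ~2%; with the default
measurement noise, ~12%.

## Data preparation

Raw catheter recordings are processed in a fixed order: beat averaging in
phase space (robust to heart-rate jitter), LV/RV harmonization (common
period = mean of the two; common stroke volume = LV stroke volume; RV
keeps its measured ESV and its trace is rescaled affinely so RV EDV =
RV ESV + SV), negative-EDP correction (uniform upward shift to the
condition-and-sex group reference, pulse pressure preserved), isovolumic
enforcement, and resampling to the half-open 50-point grid. Isovolumic
enforcement is a circular running median (exact on monotone and plateau
segments, so ejection and filling are untouched) followed by flattening
of the plateaus around the volume extremes to their medians. Endpoints
follow the convention of pressure extremes at the volume extremes: EDP is
the *minimum* pressure over the near-EDV band and ESP the *maximum* over
the near-ESV band (a 2% stroke-volume band), which makes the octet robust
to noise on the isovolumic segments and to end-diastolic samples caught
just after contraction onset.

## Derived metrics

Mean PA pressure is the cycle average of the PA compartment pressure.
Stroke work is the shoelace area of the PV loop (cross-checked against a
trapezoidal $\oint P\,\mathrm{d}V$ to 0.1%). Myofiber power intensity is
the discrete time derivative of the cumulative $\int \sigma_\mathrm{XB}
\mathrm{d}L_s$ work integral, reported as its cycle maximum in W/m²
(1 kPa·µm/s = 1e-3 W/m²). Mean systolic septal curvature uses the strict
valve window (inflow closure to outflow closure). The septal *bounce*
(maximal curvature drop from the cycle start) uses a wider window, from
inflow-valve closure through mid rapid filling: in this model, as in the
clinical descriptions of rapid leftward septal motion, the hyperoxic dip
develops around isovolumic relaxation and early filling, and a
strictly-systolic window would miss it entirely; dips in diastasis are
still excluded. The RC-time (pulmonary resistance × compliance) and the
R/C afterload ratio come directly from the parameters, with the
compliance also restated in cm³/kPa.

## The synthetic cohort

Because the animal data are not deposited, cohorts are generated: records
drawn around the group-average hemodynamics (SDs scaled with the
dispersion setting `cv`, so `cv = 0` collapses each group), nominal
parameters built per record, lognormal between-animal jitter (default CV
10% — an assumption, not a measured dispersion) on the calibration-type
parameters, and the hyperoxia modifiers for the Hx group. Recordings
emulate the sequential conductance-catheter protocol: 20–50 replicated
beats with independent LV/RV period jitter, additive i.i.d. Gaussian
pressure/volume noise, and two artifact types (a negative-EDP offset, an
isovolumic volume spike). Not emulated: autocorrelated catheter noise,
gain drift, respiratory modulation, or beat-to-beat physiologic
variability beyond period jitter — so passing recovery tests demonstrate
correctness of the pipeline under the stated noise model, not performance
on raw laboratory signals. Anchored mode maps the simulated traces
affinely onto the record's endpoint octet (catheter emulation for
group-average studies); unanchored mode replicates the pure model output
(parameter-recovery ground truth).

## Problem sizes in the shipped tests

The test suite runs the full pipeline at reduced scale as the package's
standing configuration: single-animal recovery with 2 starts, the
group-average calibrations with 4 starts and 30 iterations, directional
cohort checks with 3 animals per condition, and sensitivity screens on
the two group-average animals. The full 20-start protocol is available
through the same functions and multiplies runtimes accordingly.

## Limitations

The calcium transient is prescribed rather than coupled to excitation;
metabolite concentrations are fixed inputs (only the ±5% hyperoxic shifts
of the mitochondrial state are represented, not mitochondrial dynamics);
there are no atria, pericardium, or nonlinear vascular elements; the
54-entry parameter registry and several cellular rate constants are the
package's own documented construction where no published values exist for
this pediatric preparation; and the RV end-diastolic pressure is
deliberately under-predicted (see the anchoring discussion above), so RV
EDP residuals carry little information in calibration.
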