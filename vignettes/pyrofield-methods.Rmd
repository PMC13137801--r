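---
title: "Models and numerical methods in pyrofield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in pyrofield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pyrofield models Zr-doped barium titanate (BTZ, BaTi$_{0.85}$Zr$_{0.15}$O$_3$)
pyroelectric nanocatalysts at desk scale: the ferroelectric thermodynamics
that sets the pyroelectric coefficient, the phase-field dynamics of the
nanodomain structure, the lumped photothermal device response, and the
band-edge thermodynamics of reactive-oxygen-species (ROS) generation. This
vignette records the models, their assumptions, the tunable parameters, and
the numerical choices, in the order the analysis scripts use them.

## Landau–Devonshire thermodynamics

The bulk free-energy density is the sextic cubic-symmetric polynomial in the
polarization components $P_1,P_2,P_3$ (C/m$^2$),

$$f_{\mathrm{bulk}} = \alpha_1 \sum_i P_i^2 + \alpha_{11}\sum_i P_i^4 +
\alpha_{12}\sum_{i<j}P_i^2P_j^2 + \alpha_{111}\sum_i P_i^6 +
\alpha_{112}\sum_i P_i^4(P_j^2{+}P_k^2) + \alpha_{123}P_1^2P_2^2P_3^2,$$

with coefficients linear in temperature. Coefficient sets ship as JSON
configs (`inst/extdata/materials/`): `btz` is the fitted composition of
interest; `bto` is a standard literature single-crystal set for pristine
BaTiO$_3$ (marked as such in its config — it is *not* fitted in-house).
All energies are J/m$^3$; `j_m3_to_j_cm3()`/`j_cm3_to_j_m3()` are the only
unit conversions and nothing rescales silently.

Phase minima are computed analytically. On each symmetry line (tetragonal
T: one nonzero component; orthorhombic O: two equal; rhombohedral R: three
equal) the energy collapses to $Ap^2+Bp^4+Cp^6$, so stationarity is a
quadratic in $p^2$. Of the real positive roots the lower-energy one is kept;
at a degenerate double root the larger-$|P|$ root is taken (it is the
minimum whenever the quartic coefficient is negative, the usual situation
near a first-order transition). If no real ferroelectric root exists, or the
best well sits at energy $\ge 0$, the paraelectric record ($P_s=0$, energy
0) is returned — so metastable wells above the paraelectric reference count
as paraelectric in the stable-phase diagram.

The spontaneous-polarization curve $P_s(T)$ picks the minimum-energy phase
per temperature at constant stress and field, and the pyroelectric
coefficient is its derivative $\rho = dP_s/dT$ by central differences
(one-sided at the ends), reported in µC m$^{-2}$ K$^{-1}$. $\rho$ keeps the
defining sign (negative approaching the transition); `rho_magnitude()` and
`enhancement_percent()` compare magnitudes, as coefficient comparisons in
the literature do. With the shipped BTZ set the model's stable-phase
sequence terminates near 302 K, which is where $|\rho|$ peaks; "room
temperature" defaults to 298 K throughout, with 273 K used where all three
ferroelectric wells are needed (they all exist there).

Two caveats the package surfaces rather than hides. First, evaluated in SI
units the BTZ inter-phase energy gaps are of order $10^4$–$10^5$ J/m$^3$
(hundredths of a J/cm$^3$); literature discussions of such gaps often quote
single-digit J/cm$^3$ figures, a discrepancy of unit convention we do not
resolve — `analysis/01` reports both units and no coefficient is tuned.
Second, at 313 K the BTZ set has no ferroelectric stationary points at all
(the stationarity discriminant is negative on every symmetry line), so
polarization-rotation barrier profiles are only defined where the wells
exist; the heating trend is instead checked on the phase-minimum energies,
whose gaps shrink to zero between 298 K and 313 K.

Barrier profiles between two minima default to the straight segment in
$P$-space (101 samples); an `"arc"` mode rotates the direction along the
great circle with $|P|$ interpolated linearly. Endpoints are pinned to the
analytic minima, so endpoint energies agree with `minimize_phase()` to
machine precision.

## TDGL phase-field solver

The polarization field on a periodic 2D (default $256^2$-class, reduced
sizes allowed) or 3D grid relaxes by the time-dependent Ginzburg–Landau
gradient flow of the total free energy

$$F = f_{\mathrm{bulk}} + f_{\mathrm{grad}} + f_{\mathrm{elastic}} +
f_{\mathrm{elec}}.$$

2D grids carry full 3-component vectors with $\partial/\partial z = 0$, so
T, O and R variants all remain representable in plane-section maps.

**Nondimensionalization.** No physical mobility is specified, so the
kinetic coefficient is folded into a reduced time $t^*$:
$\partial P_i/\partial t^* = -(1/\alpha_0)\,\delta F/\delta P_i$ with
$\alpha_0 = 10^7$ C$^{-2}$m$^2$N, an energy-scale normalizer of the order of
$|\alpha_1|$ a few tens of kelvin below the BTZ transition. Only $t^*$ and
step counts are exposed.

**Gradient energy.** With the configured ratios ($G_{11}/G_{110}=1.5$,
$G_{12}/G_{110}=0$, $G_{44}/G_{110}=0.75$, $G_{110}=7.04\times10^{-11}$
C$^{-2}$m$^4$N) the cross terms vanish and
$f_{\mathrm{grad}} = \tfrac12[G_{11}\sum_i(\partial_iP_i)^2 +
G_{44}\sum_{i\ne j}(\partial_jP_i)^2]$, giving the exactly diagonal Fourier
kernel $K_i(k)=G_{11}k_i^2+G_{44}\sum_{j\ne i}k_j^2$ that the stepper treats
fully implicitly. The default spacing of 1 nm resolves the
$\sqrt{G_{110}/|\alpha_1|}\approx 3$ nm wall width.

**Electrostatics.** The electrostatic density is taken as
$f_{\mathrm{elec}} = -(\mathbf{E}_{\mathrm{appl}}+\mathbf{E}_{\mathrm{RF}})
\cdot\mathbf{P} - \tfrac12\,\mathbf{E}_{\mathrm{dep}}\cdot\mathbf{P}$
(applied-field and random-defect-field work plus the dipolar self-energy);
an ambiguous $\tfrac12(\mathbf{E}\cdot\mathbf{P})$ shorthand sometimes seen
for this term is not usable dimensionally-consistently for both
contributions at once, so the standard form above is adopted. The
depolarization field is the longitudinal spectral projection
$\mathbf{E}_{\mathrm{dep}}(k) = -(\hat{k}\cdot\mathbf{P}(k))\hat{k}/
(\varepsilon_0\varepsilon_b)$ with background permittivity
$\varepsilon_b = 45$ (typical of the BaTiO$_3$ family's non-polar
background). The $k=0$ mode is zero by default (short-circuit: no
macroscopic depolarization); an open-circuit flag depolarizes the mean too.
Depolarization is **on by default**: it is the physics that penalizes
charged walls and stabilizes multidomain states — with electrostatics off,
unpinned gradient flow coarsens many random starts to a single variant.

**Random-defect field.** Point defects enter as a static field
$\mathbf{E}_{\mathrm{RF}}$: a fraction $c=0.05$ of cells (drawn without
replacement, seeded) carries i.i.d. zero-mean Gaussian components of
$\sigma_E = 5\times10^5$ V/m. Both parameters are config values; the
defaults are a mild pinning strength, an order below the bulk coercive
scale, chosen once as a plausible dilute-defect level.

**Elasticity.** Electrostriction couples strain to polarization through the
eigenstrain $\varepsilon^0_{ij}=Q_{ijkl}P_kP_l$ ($Q_{11}=0.1$,
$Q_{12}=-0.034$, $Q_{44}=0.029$, engineering shears). The mechanical
problem is solved in the periodic zero-mean-stress setting with homogeneous
cubic stiffness obtained by analytically inverting the compliances; the
acoustic tensor is inverted in closed form per wavevector, with an
ill-conditioning guard. The shipped compliance set
($s_{11}=9.1\times10^{-12}$, $s_{12}=-3.2\times10^{-10}$,
$s_{44}=8.2\times10^{-10}$ m$^2$/N) is **not positive definite**
($s_{11}+2s_{12}<0$), an anomaly we flag rather than correct: the derived
stiffness has a negative bulk-modulus eigenvalue, so `elastic_on` defaults
to FALSE and the elastic code path is exercised explicitly in tests and
available per config. No inhomogeneous moduli, no finite-size boundary
conditions.

**Time stepping.** Semi-implicit Fourier-spectral first order: the linear
gradient kernel (and, when on, the linear depolarization operator, via a
per-wavevector Sherman–Morrison solve) is implicit; bulk, elastic and
static-field forces are explicit. The explicit part bounds the step:
forward-Euler stability requires $dt < 2\alpha_0/\Lambda$ with $\Lambda$
the largest absolute bulk-Hessian eigenvalue over the relevant $|P|$ range;
`tdgl_stability_dt()` evaluates this bound (sampled over the 26 variant
directions up to $1.2\times$ the largest $P_s$). The default $dt=0.05$ sits
well inside the bound for the shipped materials near their working
temperatures; divergence ($|P|$ beyond $10\times$ the largest Landau
minimum, or non-finite) aborts with advice to reduce $dt$. Evolution is
bit-deterministic for fixed inputs, and $P\equiv 0$ is an exact fixed point
without applied or defect fields.

**Hysteresis protocol.** Loops sweep one applied-field component through
the closed triangle $0\to+E_{\max}\to-E_{\max}\to+E_{\max}$ (the initial
leg is the virgin branch; the cycle proper starts at the first $+E_{\max}$
sample), evolving a fixed number of equilibration steps per field value —
fixed steps, not convergence detection, so loops are reproducible — and
recording the spatial mean of the swept component. Default sweeps use the
x-component, matching plane-section domain maps.

## Domain-variant classification

The 26 ferroelectric variants are the $\langle100\rangle$ (6, T),
$\langle110\rangle$ (12, O) and $\langle111\rangle$ (8, R) unit directions
of the cubic parent, in the canonical order T-block, O-block, R-block, each
block lexicographic in $(x,y,z)$ — the order that makes tie-breaks
reproducible. A cell with $|\mathbf P|$ below threshold is paraelectric;
otherwise it takes the variant of maximal cosine, which is scale-invariant
and always succeeds (the angle tolerance only flags "uncertain" cells in
exports; wall cells inherit their nearest direction). The default threshold
is 5% of the largest single-domain $P_s$ at the state's temperature — low
enough to keep polar-region interiors, high enough to exclude wall dips —
with a 0.01 C/m$^2$ floor where the model is paraelectric.

## Lumped photothermal device model

The particle suspension is one thermal mass with Newtonian exchange. Each
laser on/off stage is a closed-form exponential toward its own steady state
($T_{ss}$ while heating, ambient while cooling) with time constant
$\tau = C_{\mathrm{eff}}/h$; stitching stages gives an exact, continuous
trace with no ODE discretization error. Full coupled finite-element
electro-thermal simulation is deliberately out of scope: the device
response is evaluated with the lumped relation

$$V = \frac{p\,\Delta T\,a}{\varepsilon_r\varepsilon_0},$$

where $\varepsilon$ must be read as the *absolute* permittivity
$\varepsilon_r\varepsilon_0$ for the units to close. Defaults: $p = 400$
µC m$^{-2}$ K$^{-1}$, $\varepsilon_r = 2400$, and $a = 3000$ nm — the
simulation-cell cube edge, which reproduces the reference peak potential to
better than 1% where a particle diameter would not; $\Delta T$ is the
heating-stage peak rise. Calibration solves two conditions — a 10 K rise
after the 70 s on-stage and return to within 0.5 K of ambient after the
100 s off-stage — by bisecting for $\tau$ on the cooling condition
($\tau \approx 33.4$ s) and then fixing the loss coefficient from the
absorbed power ($1.0$ W/cm$^2$ over the cell face). Currents use
$i = pA\,dT/dt$ (signed; positive while heating) and per-stage charge
$Q = pA\,\Delta T$, which is also the exact time integral of $i$.

## Band alignment, ROS feasibility and Tauc extraction

Band edges convert from XPS quantities through
$E_{\mathrm{NHE}}/\mathrm{V} = \Phi + E_f - 4.44$ (work function $\Phi$,
valence-band edge $E_f$, both eV; 4.44 eV is the absolute NHE potential).
One-electron levels let eV and V magnitudes be identified. The VB-XPS edge
values are user inputs (the leading-edge vs onset convention is not fixed);
the shipped worked values invert the reported VBMs at $\Phi = 4.2$ eV. The
CBM is $\mathrm{VBM} - E_g$. Feasibility gating is purely thermodynamic: a
reduction is permitted when the CBM lies below the half-reaction potential,
an oxidation when the VBM lies above it; the default ladder is
O$_2$/•O$_2^-$ at $-0.33$ V, H$_2$O$_2$/•OH at $+0.73$ V and OH$^-$/•OH at
$+1.5$ V vs NHE. Margins are signed and change sign exactly at equality. No
kinetics are modelled — feasibility is necessary, not sufficient.

Tauc extraction plots $(\alpha h\nu)^n$ against $h\nu$ with $n=2$ for a
direct gap (the conventional choice for this material family, and the
default) or $n=\tfrac12$ for indirect, fits the steepest linear region and
returns the x-intercept. Window auto-selection: among contiguous windows
(width the larger of 8 points and a tenth of the spectrum) with
$R^2 \ge 0.995$, take the one of maximal slope; fall back to the top-slope
quartile of the rising edge; abort with diagnostics if even that fits below
$R^2 = 0.9$. Explicit windows are accepted for reproducibility, and the
result is invariant under positive scaling of the absorbance.

## Synthetic fixtures: what they emulate, and what not

All stochastic inputs come from seeded generators with a fixed
seed-splitting scheme (stream $k$ reseeds at
$(1009\,\mathrm{seed} + 7919k) \bmod (2^{31}{-}1)$), so outputs are
byte-reproducible and adding a generator never shifts existing streams.
Random initial fields are i.i.d. uniform per component — an idealization of
a quenched multiphase state with no spatial correlation, unlike as-grown
microstructures. Defect fields are dilute i.i.d. Gaussian point fields with
exact occupancy. Composite variant fields use largest-remainder
apportionment so requested fractions with integer cell counts are recovered
exactly, and return their generating labels as ground truth. Synthetic
absorption edges follow $\alpha = (h\nu - E_g)^{1/2}/h\nu$ above the gap,
so the direct Tauc signal $(\alpha h\nu)^2 = h\nu - E_g$ is exactly linear
— which is what makes the noise-free recovery contract ($\le 10^{-3}$ eV)
attainable — with multiplicative Gaussian noise and an optional Urbach
tail (off by default). None of the generators emulate instrument artifacts
(baselines, scattering, saturation), so passing recovery tests bounds
algorithmic error only, not what raw measured spectra would show.

## Problem sizes and test tolerances

The property suite runs at reduced scales chosen to keep the full suite in
minutes on one CPU while staying in the asymptotic regime of each check:
multiphase-relaxation properties at $128^2$ cells and 5000 steps (five
seeds give $\ge 3$ coexisting variants, usually O/R with T traces);
Lyapunov monotonicity at $16^2$ with $dt$ at half the stability bound over
ten seeds; the 0-D oracle against an adaptive high-order ODE integration at
$10^{-6}$ relative using small steps over a short transient (the
first-order stepper's global error is $O(dt)$, so the tolerance dictates
the step); hysteresis at $32^2$ with 250 equilibration steps per field
value, where loops close and are antisymmetric within 2% of saturation;
and a $64\to128$-cell neutral-wall refinement test agreeing below 2%. The
analysis scripts use the same scales and state them in their output.

## Known limitations

Single first-order semi-implicit stepping only; homogeneous elasticity with
a flagged non-positive-definite compliance input; no heat-diffusion
coupling inside the grid, no nanoparticle surface/shape boundary
conditions; thermodynamic (not kinetic) ROS feasibility; Landau
coefficients are inputs, never fitted; no Helmholtz-to-Gibbs
renormalization of coefficients under strain or field.
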