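---
title: "From simulation observables to CNT rate curves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From simulation observables to CNT rate curves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cntrates)
```

# Scope and model

`cntrates` assembles classical-nucleation-theory (CNT) nucleation and
growth rate curves for molecular model systems from the observables a
molecular-dynamics study produces: biphasic configurations, enthalpy and
volume tables, diffusion series. CNT treats a crystal nucleus as a
sphere whose free-energy cost balances a bulk gain against a surface
penalty, giving the barrier $\Delta W = \tfrac{16}{3}\gamma^3/\Delta
G_v^2$ and the rates

$$N = \rho_{liq}^{4/3}\sqrt{\frac{\gamma}{k_B T}}\, D\,
  e^{-\Delta W/k_B T}, \qquad
  U = A_U f \left[1 - e^{-\Delta G/k_B T}\right],\quad
  A_U = \frac{D\,a}{\lambda^2}.$$

Assumptions inherited from CNT and carried by the package: spherical
nuclei with a sharp interface, capillarity (a bulk $\gamma$ applies to
nanoscale nuclei), diffusion-limited attachment kinetics (both rates
exactly linear in $D$), and normal growth ($f = 1$ by default, with a
hook for other mechanisms). Because of the linearity in $D$, the package
exposes $N/D$ as a first-class diagnostic: it is the part of the
prediction that survives when two systems differ only in their dynamics.

Two dimensional-consistency points are resolved explicitly rather than
inherited from loose notation in the CFM/CNT literature:

* the lattice spacing in $A_U$ is $a = \rho_{cr}^{-1/3}$ (a length;
  the exponent $+1/3$ sometimes printed would make $U$ not a velocity);
* $\Delta G$ in the growth exponent is per molecule (J), while the
  barrier uses the volumetric $\Delta G_v = \Delta G \cdot \rho_{cr}$
  (J/m³); the two are linked by the crystal number density.

Internally everything is SI; conventional units (nm, ps, kJ/mol, mJ/m²,
nm⁻³) appear only at I/O boundaries, and `nucleationRate()` /
`growthRate()` audit their unit algebra on every call.

# Interfacial stiffness by the capillary fluctuation method

A quasi-one-dimensional crystal–melt interface (thin axis much smaller
than the lateral axis) fluctuates with the equipartition spectrum

$$\langle |h(q_n)|^2 \rangle = \frac{k_B T_m}{L_x L_z \tilde\gamma\,
q_n^2}, \qquad q_n = \frac{2\pi n}{L_x},$$

so the stiffness $\tilde\gamma$ follows from the intercept of a fixed
slope-$(-2)$ fit of $\ln\langle|h(q)|^2\rangle$ against $\ln q$. The
stiffness is reported as the estimate of $\gamma_m$ itself (single
crystallographic orientation, weak-anisotropy assumption).

Conventions that matter and are fixed package-wide:

* **DFT normalization.** $h(q_n) = \frac{1}{M}\sum_j h(x_j)
  e^{-i q_n x_j}$ on $M$ uniform grid points. The equipartition formula
  holds with the $k_B T_m/(L_x L_z)$ prefactor only under a stated
  convention; generator (`sampleCapillaryModes()`) and estimator
  (`powerSpectrum()`, `fitStiffness()`) share this one, and a Parseval
  identity test pins it down.
* **Interface localization.** The Steinhardt order-parameter profile in
  each capillary is fitted with the slab form
  $o(y) = o_l + \frac{o_s - o_l}{2}\left[\tanh\frac{y-h_1}{\delta_1} -
  \tanh\frac{y-h_2}{\delta_2}\right]$, which equals $o_s$ inside the
  crystal slab and $o_l$ outside. The additive-tanh variant that
  circulates in parts of the CFM literature does not reproduce the bulk
  levels in its asymptotic limits; it remains available as
  `form = "printed"` for comparison.
* **Periodic boundary.** Before binning, the normal coordinate is
  cyclically shifted so the crystal slab is contiguous and centered
  (circular mean weighted by the order parameter); interface 1 is then
  always the lower interface, which keeps the two height fields
  consistently labeled across frames.
* **Fit window.** Mode 1 is excluded by default (drift and finite-size
  contamination); the automatic window extends from mode 2 while the
  cumulative unconstrained slope stays within ±0.3 of −2, and any
  explicit window can be supplied. The unconstrained slope is always
  reported as a quality check; deviations beyond tolerance are recorded
  in the estimate, not fatal.
* **Errors.** The fixed-slope intercept standard error comes from the
  residual scatter over the window; `estimateStiffness()` replaces it
  with a block-average over sample subsets when enough fields exist.

At 2000 sampled fields the estimator recovers injected stiffnesses of
1–8 mJ/m² within a few percent (10% is the tested bound); at 20000
within 3%.

# Order parameter and phase classification

The rotationally invariant bond-orientational order parameter is
computed at molecular geometric centers (unweighted mean of the four
sites for the rhombus molecule):

$$q_{lm}(i) = \frac{1}{N_b(i)}\sum_{j \in nb(i)} Y_{lm}(\hat r_{ij}),
\qquad q_l(i) = \sqrt{\frac{4\pi}{2l+1}\sum_m |q_{lm}(i)|^2}.$$

The default variant is the neighbor-averaged $\bar q_6$ with a
12-nearest-neighbor criterion — the combination the CFM literature most
commonly uses for crystal/liquid discrimination — with plain $q_l$,
$l = 4$, and cutoff criteria selectable, and the variant in use recorded
in pipeline logs. Two exact identities anchor the implementation: a
single-neighbor molecule has $q_l = 1$ (spherical-harmonic addition
theorem), and the 12 ideal FCC directions give $q_6 = 0.5745243$,
matched to $10^{-10}$ against an independently computed reference.

Classification is solid iff the value reaches a threshold; the default
threshold is the midpoint $(o_s + o_l)/2$ of fitted bulk levels when a
profile fit exists, otherwise the midpoint of a two-means split of the
values. A fixed constant is deliberately not hard-wired: the bulk levels
depend on the variant and the thermal state.

A caveat for k-nearest-neighbor criteria on *ideal* lattices: a k-cut
can fall inside a degenerate distance shell (e.g. at the corner of a
truncated perfect crystal), where the neighbor choice — and hence the
order parameter — is not a continuous function of the coordinates.
Thermal configurations break such ties generically; the invariance tests
jitter ideal fixtures for exactly this reason.

# Driving force, Turnbull scaling, transitions

With $\Delta H(T) = H_{liq} - H_{cr}$ from the two enthalpy branches,
the entropy difference integrates the classical relation
$T = (\partial H/\partial S)_p$ from the melting boundary condition
$\Delta S_m = \Delta H_m/T_m$:

$$\Delta S(T) = \Delta S_m + \int_{T_m}^{T}
\frac{1}{T'}\frac{d\Delta H}{dT'}\,dT', \qquad
\Delta G(T) = -\int_{T_m}^{T} \Delta S(T')\,dT'.$$

Numerics: centered finite differences for $d\Delta H/dT$ (one-sided at
the grid ends; an optional smoothing polynomial of configurable degree
handles noisy simulated enthalpies), trapezoid integration supporting
non-uniform grids. On 1 K grids the integrators match the constant- and
linear-$\Delta H$ closed forms to $10^{-4}$ relative, and
$\Delta G(T_m) = 0$ holds exactly by construction. The Turnbull law
scales $\gamma$ down from $\gamma_m$ with the crystal-density and
melting-enthalpy ratios; the scaled $\gamma(T)$ — not the constant
$\gamma_m$ — enters both the barrier and the $\sqrt{\gamma/k_BT}$
prefactor by default (`gammaMode = "constant"` is available), since
computing $\gamma(T)$ and then ignoring it in the rate would make the
scaling step purposeless.

The transition detector returns the largest single-step volume change
exceeding a threshold, reporting the grid point at which the new branch
is first attained; heating-vs-cooling semantics (melting vs
crystallization) belong to the caller, as hysteresis makes them
path-dependent.

# Dynamics

MSD uses all time origins (sliding window) via the FFT autocorrelation
identity; diffusion is the fitted slope over a user-chosen lag window
divided by 6, with the log–log slope of the window reported as a
diffusive-regime check (1 ± 0.1). The VFT law is fitted in
$\log_{10}(1/D)$ space, which weights decades evenly and matches how
such fits are usually quoted; $T_0$ is bounded to $[0, \min T)$ and an
optimum pinned at the data edge is rejected. Noiseless VFT data is
recovered to machine precision across random parameter draws
(property-tested), and the Arrhenius limit fits $T_0 \approx 0$.

One sign judgement: the VFT parameter sets the two demo systems are
quoted with, $\log_{10}(1/D_0) = -10.68$ and $-11.10$, would put
$D_0$ near $10^{11}$ m²/s — about eighteen orders of magnitude above any
molecular diffusivity. With the sign read as positive, $D(T_m)$ lands at
a few $10^{-13}$ m²/s, typical of a liquid near melting. Parameter
*recovery* is sign-agnostic (the tests use the values verbatim), but the
packaged demo uses the positive reading so its illustrative rate curves
have physically sensible magnitudes.

# The synthetic-data module

The generators replace multi-nanosecond MD with constructions whose
ground truth is known exactly:

* **Capillary ensembles** are sampled directly in Fourier space (each
  mode an independent complex Gaussian at the equipartition variance)
  and inverse-transformed — the CFM estimator only uses the stationary
  spectrum, so no dynamics are needed. Empirical mode variances converge
  to the target as $1/\sqrt{n}$.
* **Biphasic configurations** place an FCC slab at the crystal density
  against an ideal-gas-random liquid with a minimum-separation rejection
  (0.7× the crystal nearest-neighbor distance, enforced against both
  phases). This emulates the order-parameter *contrast* of a real
  crystal–melt system, not liquid structure: no pair correlations, no
  thermal broadening of the crystal peaks, atomically sharp interfaces.
  Passing tests therefore validate the analysis chain, not claims about
  real interfacial widths.
* **Thermodynamic branches** are linear in $T$ (constant heat
  capacities) with the melting discontinuity imposed exactly. The demo's
  $\Delta H_m = 1.5\,k_B T_m$ and heat capacities ($\approx 4 k_B$
  liquid, $3 k_B$ crystal) are free fixture parameters — no measured
  values exist for the demo systems — chosen near simple-liquid melting
  entropies and the Dulong–Petit value; densities invert the demo
  per-molecule volumes.
* **Brownian trajectories** have per-axis step variance $2D\,dt$, so
  the Einstein relation is exact in expectation; unwrapped coordinates
  are retained.
* **VFT series** evaluate the law with optional Gaussian noise in
  $\log_{10}$ units. The demo diffusion grid spans $0.93$–$2.2\,T_m$:
  a fit restricted to a narrow near-$T_m$ window is degenerate in
  $(B, T_0)$, and a realistic simulated $D(T)$ dataset extends well
  above melting.

All generators take explicit integer seeds and restore the caller's RNG
state; there is no hidden global randomness.

# Pipeline, problem sizes, limitations

`runPipeline()` drives fixtures → order → CFM → thermo → VFT → rates
from one config (`demoConfig()` parameterizes the two demo systems:
$T_m = 150/326$ K, $\gamma_m = 2.53/4.15$ mJ/m², charges
$\pm 0.5/\pm 0.75\,e$, volume steps 0.086→0.094 nm³ at 220 K and
0.088→0.101 nm³ at 420 K), logging the RIOP variant, profile form, DFT
convention and fit window actually used. `compareSystems()` overlays two
runs on a reduced-temperature grid and tabulates $N$, $U$, $D$ and $N/D$
ratios.

Problem sizes are chosen for convergence at interactive cost: 2000
spectrum samples put the mode-variance standard error near 2% per mode
(intercept error well under 1% over a 9-mode window); the 1728-molecule
biphasic fixture yields ≥95% label recovery; 200 walkers × 2000 steps
recover $D$ within a few percent. Scaling any of them up tightens the
recovery proportionally to $1/\sqrt{n}$.

Known limitations: no multi-orientation stiffness anisotropy (single
orientation, $\gamma_m \approx \tilde\gamma_m$); no cleaving-method
route to $\gamma$; no mean-first-passage-time nucleation analysis; the
demo's absolute $N$/$U$ magnitudes are illustrative because the
underlying MD observables (true $H(T)$, $\rho(T)$, $D(T)$) are not
reproduced by the fixtures; XTC/TRR trajectory reading is out of scope
(GRO/XYZ carry the configurations).
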