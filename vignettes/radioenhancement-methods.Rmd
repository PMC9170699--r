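---
title: "Methods: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

radnano implements the quantitative analysis stack of comparative
nanoparticle radioenhancement experiments: given a panel of candidate
nanoparticle materials (low-Z oxides through gold), it quantifies how much
each material amplifies the effect of ionizing radiation physically
(energy absorption), chemically (radical generation) and in vitro (cell
survival), under kV X-ray, MV X-ray and proton beam conditions. This
vignette describes the models, their assumptions, the tunable parameters,
and the numerical decisions behind the implementation.

## Physical enhancement

### The analytic macroscopic model

For a mass fraction $f_Z$ of material dispersed in water, the
dose-enhancement factor of the homogeneous mixture under a photon fluence
is conventionally reported as

$$\mathrm{DEF} = 1 + f_Z\,
  \frac{\langle \mu_\mathrm{en}/\rho \rangle_Z}
       {\langle \mu_\mathrm{en}/\rho \rangle_{\mathrm{H_2O}}},$$

with $\langle\cdot\rangle$ a spectrum average of the mass energy-absorption
coefficient. `macroscopic_def()` implements this `as_printed` form as the
default, and additionally a `mixture` mode
$1 + f_Z(\langle\mu_Z\rangle/\langle\mu_w\rangle - 1)$, which is the exact
two-component mixture rule. The two differ by exactly $f_Z$; `as_printed`
is the reporting convention, `mixture` the physically consistent form at
large $f_Z$. The mixture form can fall below 1 for materials whose averaged
coefficient is below water's (SiO~2~, TiO~2~, TiN at MV energies, ratios
around 0.87–0.91); this is physical and deliberately not clamped.

Spectrum averaging weights each bin by *energy fluence*
($w_i E_i \mu(E_i)$), because dose in a thin receptor is energy fluence
times $\mu_\mathrm{en}/\rho$; plain fluence weighting is available via the
`weighting` argument for comparison, since the appropriate convention
depends on what a reported enhancement is normalized against.

### Coefficient tables

Liquid water is carried as an embedded reference table of
$\mu/\rho$ and $\mu_\mathrm{en}/\rho$ on a coarse grid (4 keV–10 MeV).
All other materials use a parameterized model calibrated against that
table plus one embedded high-Z anchor (gold at 100 keV,
1.9 cm²/g):

* photoelectric absorption $\propto \sum_i w_i Z_i^{n}\,s_i(E)/A_i\,E^{-p}$,
  with the energy exponent $p \approx 3.16$ fitted on the water table
  below 30 keV, the effective $Z$ exponent $n \approx 3.8$ solved between
  the oxygen-dominated water constraint and the gold anchor (a fixed
  $Z^{4.3+}$ power extrapolated over a decade of $Z$ overestimates gold
  threefold), a K-edge jump factor of 3, and a softening to $E^{-1.9}$
  above 300 keV (photoabsorption falls much more slowly above the
  electron rest energy — without this, high-Z MV coefficient ratios drop
  spuriously below 1);
* incoherent scattering from the exact Klein–Nishina cross section per
  electron times the mean energy-transfer fraction (numerically
  integrated once and cached);
* a coarse $Z^2 \ln(E/1022\,\mathrm{keV})$ pair-production term.

The tables are intended for spectrum-averaged coefficient *ratios*,
orderings and kV/MV contrast; absolute high-Z values are coarse (tens of
percent). Interpolation is log–log linear with edge-straddling grid
points; energies outside the tabulated range raise an error rather than
extrapolate.

Two built-in spectra cover the experimental conditions: `kv150`, a
filtered Kramers-law model of a 150 kV tube hardened by 3 cm of
PMMA-equivalent phantom material (fluence peak near 50–60 keV), and
`mv6`, a coarse tabulation of an in-phantom 6 MV linac fluence including
the low-energy phantom-scatter tail. Spectra normalize to unit weight on
load.

## The simplified Monte Carlo

`simulate_vesicle()` and `simulate_cell()` estimate compartment-resolved
enhancement on the two standard scoring scenes: a 400 nm vesicle packed
with 50 nm nanoparticles (166 particles = 32.4 vol% by default) with ten
100 nm water shells around it, and a 6 µm cell with a 3 µm nucleus and
nanoparticle-filled vesicles restricted to the cytoplasm (no nuclear
uptake), the beam as wide as the cell.

The engine deliberately simplifies the physics; its fidelity claims are
restricted to null, kerma-limit, ordering and linearity properties:

* **Forced interactions.** Photon mean free paths are centimetres; the
  scene is micrometres. Each history is ray-traced and exactly one
  interaction site is sampled along the ray with density
  $\mu_\mathrm{en}(E)\rho$, the history carrying the optical depth as
  weight. This is unbiased for absorbed energy at $\tau \ll 1$.
* **Energy bookkeeping.** Each interaction deposits the full photon
  energy: a local remainder (relaxation binding energy, or the locally
  absorbed residual of an incoherent event) plus one secondary electron.
  Because sites are sampled with density $\mu_\mathrm{en}\rho$, the
  expected absorbed energy per path equals the kerma-limit closed form
  *by construction* — the homogeneous local-deposition run reproduces
  `macroscopic_def(mode = "mixture")` exactly in expectation, which is
  the designed consistency check between the two routes. The
  photoelectric/Compton branch (physically parameterized) only shapes the
  spatial spread.
* **Electrons.** `csda` mode (default) moves each electron on a straight
  isotropic line, depositing uniformly over its water CSDA range from an
  embedded range–energy table; nanoparticle regions are treated as water
  for slowing. `local` mode deposits on the spot (kerma limit). Track
  energy is allocated to compartments by *exact line–sphere overlap
  lengths*, not by stepping, so shell scoring has no spatial
  granularity. Photoelectron energy is the photon energy minus the K- (or
  L3-) binding energy of the dominant photoabsorber; the binding energy
  is deposited at the site.
* **Correlated baseline.** The water-nanoparticle baseline runs inside
  the same loop from the same uniform draws, with identical floating-point
  association of the optical depths, so the water-vs-water null gives
  DEF = 1 *bitwise* and material DEFs are low-variance ratios.
* **Importance sampling.** Half of the beam rays target the transverse
  disks of the nanoparticle-bearing structures with exact mixture-density
  weights; those rays carry nearly all the enhancement signal.
* **Geometry seeding.** Sphere packings are reproducible from the seed.
  Sparse fillings use dart throwing; the default 166-particle filling
  corresponds to an effective hard-sphere density of ~0.48 in the
  admissible region — beyond the ~0.38 random-sequential-insertion
  jamming limit — so dense fillings switch to a seeded jittered-FCC
  lattice subset. The packing fraction is exact either way.

Runs are pure functions of (geometry, material, spectrum, histories,
seed); `replicates > 1` repeats at `seed, seed+1, ...` and reports the
replicate standard deviation rather than hiding it.

### What the simplified engine does and does not show

With these simplifications the engine reproduces, at $10^4$–$10^5$
histories on one CPU: the exact null; the kerma-limit equality; the
material ordering of cytoplasm enhancement at kV
(Au > HfO~2~ > WO~3~ > TiO~2~ ≈ 1, driven by $\mu_\mathrm{en}\rho$ per
volume); near-linear growth of cytoplasm DEF with vesicle load
(R² > 0.99 over 1–10 vesicles); monotone decay of shell enhancement with
distance; and an in-vesicle DEF for gold at kV of order 25–30 at
32.4 vol% filling.

It does *not* reproduce near-field decay *rates*. Track-structure codes
produce Auger-cascade electron spectra dominated by sub-100 nm ranges, so
their shell enhancement collapses to baseline within a micrometre. Here
each interaction emits a single CSDA electron with 10–60 µm range at kV,
so the far-shell excess is geometric ($\sim 1/r^2$ from a shell-1 excess
of ~10) and plateaus around 0.3 at 1.2 µm regardless of history count.
The test suite asserts the monotone property and reports the tail; the
absolute tail value is a documented limitation of the single-electron
approximation, not a statistical artefact.

## Chemical enhancement (DCF assay)

`def_ros()` is the ratio of radiation-induced fluorescence gains,
$(\mathrm{FI}_{12}^{NP} - \mathrm{FI}_{0}^{NP}) /
(\mathrm{FI}_{12}^{blank} - \mathrm{FI}_{0}^{blank})$, computed from
replicate means (0 Gy averages subtracted first, as in the assay
protocol), invariant under fluorometer gain rescaling, and erroring when
there is no blank radiolysis signal. `ros_slope()` regresses
$\mathrm{DEF}_{ROS} - 1$ on surface-area concentration with the intercept
fixed at 1 — zero exposed surface cannot enhance — with a free-intercept
variant behind a flag. Exposures are compared at constant *surface-area*
concentration (cm²/mL); `surface_conc_to_mass_conc()` converts axes.

Because every DEF value in a plate shares the blank denominator, the
naive residual t interval for the slope is badly anti-conservative. The
default interval (`ci = "propagated"`) therefore propagates the replicate
variances of all well-group means including the shared-blank covariance,
with a t quantile on $n_\mathrm{rep} - 1$ degrees of freedom; in seeded
simulations at CV 10% it covers the truth in ~96/100 experiments, versus
~54/100 for the residual interval. A percentile bootstrap over replicates
is also available. Gold wells are accepted but flagged: DCF interference
makes gold values unreliable.

## The in-vitro survival pipeline

Luminescence converts to cell counts through the standard curve
`cells = y·b/(a - b)` with the fitted defaults $a = 3.872\times 10^6$,
$b = 3.431\times 10^5$. This printed conversion is linear in $y$, which is
inconsistent with a saturating standard curve at high counts; both the
linear `as_printed` form (default) and the rectangular-hyperbola
`saturation` inversion `y·b/(a - y)` are implemented, and the choice is an
explicit argument.

Surviving fractions are unclipped ratios against the matched 0 Gy count
(values above 1 are retained to keep the estimators unbiased and flagged
in QC). The linear-quadratic model
$\mathrm{SF}(D) = e^{-(\alpha D + \beta D^2)}$ is fitted by unweighted
nonlinear least squares *on the survival scale* with $\alpha, \beta \ge 0$
enforced, starting from the log-linear seed and a fixed fallback start;
noise-free data is recovered to $10^{-8}$. The dose at 50% survival uses
the rationalized root $2\ln 2 / (\alpha + \sqrt{\alpha^2 + 4\beta\ln 2})$,
which is continuous and numerically stable as $\beta \to 0$. LD50 beyond
the 0–8 Gy design is allowed but flagged `extrapolated`.

The dose-modifying ratio $\mathrm{DMR}_{50\%}$ is the LD50 ratio
without/with nanoparticles, computed per cell batch and averaged, with the
batch spread as its uncertainty. Conditions whose sham viability falls
below the 60% cutoff are excluded from DMR tables. Sham toxicity is
fitted with the sigmoid $1 - 1/(1 + a e^{-bx})$, giving
$\mathrm{LC}_{50} = \ln a / b$ (infinite when a flat, fully viable series
never crosses 50%).

Radical quenching: the fixed-dose enhancement ratio
$\mathrm{NER} = \mathrm{SF}_{6\,\mathrm{Gy}}^{ctrl} /
\mathrm{SF}_{6\,\mathrm{Gy}}^{NP}$ and the degree of protection
$\mathrm{DoP} = 1 - (\mathrm{NER}_{DMSO} - 1)/(\mathrm{NER}_{noDMSO} - 1)$,
which is 0 when DMSO changes nothing, 1 at full protection, invariant
under common rescaling of the four survival fractions, and undefined
(flagged) when there is no enhancement to protect against.

## ICP-MS uptake

Per-cell metal masses follow the Hill-type saturation
$f(x) = A x^p/(B^p + x^p)$ ($A$ the plateau in ng/cell, $B$ the
half-saturation concentration, $f(B) = A/2$ for any $p$). Volume
fractions divide the metal mass by the material's metal mass fraction
(standard atomic weights) and bulk density, then by the reference cell
volume 2800 µm³ (a 17.5 µm sphere). The ambiguous "viability-corrected"
volume fraction is implemented as division of the per-cell load by the
normalized sham viability at the same condition — fewer surviving cells
carry the measured load — and is switchable off (`sham_viability = 1`).

## The synthetic-data generators

`generator_config()` fixes the study conditions: 2000 cells seeded per
well growing to ~2×10⁴ at readout; doses {0, 2, 4, 6, 8} Gy; triplicate
nanoparticle wells and sextuplicate controls filling the inner 24 wells
of a 48-well plate; two independent batches; DMSO grid
{0, 0.11, 0.334, 0.667, 1} M; ROS exposures at {36.8, 368, 1840} cm²/mL
with six replicates; multiplicative lognormal noise at CV 5% for plate
readers (the measured plate-to-plate spread with crosstalk eliminated)
and 15% for ICP-MS.

The control LQ truth defaults to $\alpha_0 = 0.04$/Gy,
$\beta_0 = 0.0013$/Gy², chosen once to reproduce the observed control
surviving fraction of ~0.75 at 6 Gy for these relatively radioresistant
sarcoma cells. Note the consequence: the control LD50 (~12 Gy) lies
beyond the dose design, so control fits extrapolate — exactly as in the
experiment — and DMR estimates inherit that variance. At default noise,
the per-material DMR is recovered within ±10% in roughly 85 of 100
seeded experiments; the shortfall from a higher rate is a property of the
LD50-ratio estimator under a shallow control curve (occasional
$\beta = 0$ boundary fits), not of the noise level, and would disappear
under a steeper, better-identified survival truth.

Each material's ground-truth dose-scaling factor $k$ (the true DMR) is
solved from its configured no-DMSO enhancement ratio at 6 Gy, so the
generator's defaults reproduce the observed ratio panel (TiO~2~ 2.0,
HfO~2~ 2.1, WO~3~ 1.6, Au 1.6, TiN 1.3, SiO~2~ 1.0). DMSO wells apply a
saturating protection curve $P(c)$ (exact plateau from 0.5 M, a generator
choice): baseline damage is dose-spared by $1 - 0.6\,P(c)$ (raising
control SF at 6 Gy from ~0.75 to ~0.9), while the nanoparticle-attributable
ratio scales as $1 + (\mathrm{NER}_0 - 1)(1 - \phi P(c))$ with the
material's indirect-damage fraction $\phi$ (defaults: TiO~2~ 0.73,
HfO~2~ 0.52, Au 0.34, TiN 1.0, WO~3~ 0). Survival in DMSO-bearing
nanoparticle wells is constructed from that target ratio, exact at 0 Gy
and the 6 Gy reference — the two doses of the quenching design — so that
zero-noise analysis returns DoP $= \phi$ identically and a $\phi = 0$
material keeps its ratio unchanged under DMSO.

Generators are pure functions of their configuration (which includes the
seed). They emulate design structure, truth parameters and multiplicative
noise; they do not emulate plate-position effects, reader drift,
batch-specific biology, or assay chemistry, so passing round trips
validate the estimators, not the wet-lab protocol.

## Problem sizes

The shipped test suite and the acceptance script size the simulations for
a single CPU: Monte Carlo property checks at 5×10³–5×10⁴ histories (three
replicate seeds where spread is asserted), the kerma-limit check at 10⁶
histories, the vesicle-load linearity over 1–10 vesicles at 10⁴
histories, and 100-seed loops for recovery and coverage rates. These
sizes leave all asserted properties deterministic for a fixed seed.

## Known limitations

* Coefficient tables are coarse parameterizations beyond water; use them
  for ratios and orderings, not as reference data.
* No coherent scattering, no fluorescence escape, no Auger cascades, no
  condensed-history electron scattering; near-field decay rates are
  therefore not reproduced (see above).
* Proton enhancement is represented by its analytic null (physical DEF of
  1), consistent with the negligible physical proton enhancement of these
  materials; nuclear activation channels are out of scope.
* The survival pipeline assumes the plate schema documented in
  `read_plate()`; clonogenic colony counts are not supported.
* WO~3~ dissolution chemistry is not modelled; its uptake truth is simply
  two orders of magnitude lower.
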