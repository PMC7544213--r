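---
title: "Models and methods behind nmrbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nmrbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrbind)
```

nmrbind implements the quantitative chain used to ask two questions about
a tandem-domain RNA-binding protein in solution: *do the two folded
domains tumble as one rigid body or move independently?* and *how strongly,
and with what stoichiometry, does the construct bind its RNA element?*
This vignette records the models, their assumptions, the defaults and the
numerical choices, in enough detail that a maintainer can judge when each
is appropriate.

## Chemical shift perturbations and fast-exchange Kd

Two amide spectra are compared per residue; shift differences are stored
signed (`other − ref`) and combined as

$$\Delta\delta(^{15}\mathrm{N},{}^{1}\mathrm{H}) =
  \sqrt{\tfrac12\left(\Delta\delta_H^2 + (0.14\,\Delta\delta_N)^2\right)}.$$

The nitrogen weight 0.14 compensates the wider ^15^N shift range. It is
fixed by default because every downstream threshold (notably the
"large shift" cutoff of 0.025 ppm, applied strictly as `>`) assumes it;
`n_weight` can be overridden explicitly, which departs from the
convention and should be stated alongside any numbers so produced.

Titration analysis assumes two-state binding in fast exchange: each
observed peak is the population-weighted average of free and bound
positions, with the bound fraction given exactly by the single-site
depletion quadratic

$$f_b = \frac{(P + L + K_d) - \sqrt{(P + L + K_d)^2 - 4PL}}{2P}.$$

`fit_kd_from_titration()` performs nonlinear least squares on
$\delta_{obs}(L)$. The key structural observation is that the bound-state
endpoints enter the model *linearly*: for any candidate $K_d$ they can be
profiled out in closed form per residue and dimension. The fit is
therefore a one-dimensional optimisation over $\log K_d$ (golden-section
on $[10^{-3}, 10^{6}]$ µM), which cannot get stuck in the multi-parameter
local minima a naive joint optimisation risks. ^15^N residuals are
weighted by 0.14 so both dimensions contribute on a common scale. The
default is one global $K_d$ shared across residues — the appropriate model
for a single binding event — with a per-residue mode as a diagnostic for
heterogeneous behaviour. The standard error comes from the curvature of
the profiled residual surface at the optimum.

Flat titrations (no residue moves more than 10^-6^ ppm) are rejected as
unidentifiable rather than returning an arbitrary number.

Peak matching (`match_peaks()`) is greedy in ascending weighted distance
with a hard cutoff (default 0.1 ppm): at desk scale with tens to a couple
hundred peaks, greedy matching differs from optimal assignment only in
contrived near-tie geometries, and its failure mode (leaving a peak
unmatched) is the safe one for assignment transfer.

## ^15^N relaxation and rotational correlation time

Per-residue rates are converted to times and averaged arithmetically; by
default **every** residue contributes. A `noe_cutoff` filter is available
to exclude flexible tails and linkers, whose fast internal motions bias
$T_1/T_2$ downward, but it is off by default so that the default matches
the plain "average over residues" convention; when a profile visibly
contains low-NOE tails the two choices can disagree by several percent
and both numbers are worth reporting.

The correlation time uses the closed form

$$\tau_c = \frac{1}{4\pi\nu_N}\sqrt{6\,\frac{T_1}{T_2} - 7},$$

valid for rigid isotropic tumbling with dipolar/CSA-dominated relaxation
near the spectral-density regime where only $J(0)$ and $J(\omega_N)$
matter. It is an approximation: round-tripping rates from the full
dipolar+CSA forward model (`forward_relaxation_rates()`, with
$r_{NH} = 1.02$ Å, $\Delta\sigma = -160$ ppm, model-free spectral
density) recovers the generating $\tau_c$ to about 1% over 5–15 ns at 500
and 850 MHz — comfortably within the 10% the estimator is trusted to. The
^15^N frequency is derived from the ^1^H field by
$|\gamma_N/\gamma_H| = 0.101329$.

`predicted_tau_c()` supplies the rigid-body expectation against which the
measured value is judged. The widely used web calculator for this
estimate does not publish its formula, so the package implements a
reconstruction, not the tool: a Stokes–Einstein-motivated model that is
linear in molecular weight at fixed temperature and scales as
$\eta(T)/T$ across temperature, with water viscosity from the standard
correlation $\eta(T) = 2.414\times10^{-5}\cdot10^{247.8/(T-140)}$ Pa s.
The single coefficient ($k \approx 6.15\times10^{-4}$ ns/Da) is
calibrated once, by least squares through the origin, on two bundled
single-domain reference values at 25 °C, and validated against three
further reference points (two temperatures, two molecular weights) which
it reproduces within 2%. The linear-in-MW assumption ignores shape and
hydration differences; it is adequate for globular single-chain
constructs in the 10–30 kDa range and should not be extrapolated far
beyond.

`rigidity_report()` encodes the verdict logic: measured/predicted below
$1 - \text{margin}$ (default margin 0.10) means the domains reorient at
least partly independently; within the band, tumbling is consistent with
one rigid body; above it, tumbling is slowed — disordered tails or a
bound ligand. The 10% margin matches the accuracy of the closed-form
estimator itself, so verdicts are never sharper than the measurement.

## RDC alignment tensors and the rigidity test

An amide RDC reports the orientation of its N–H bond vector relative to
the molecular alignment frame: $D = \mathbf{v}^T A \mathbf{v}$ with $A$ a
traceless symmetric order tensor. Fitting is linear in the five
independent elements of $A$ and is solved through the SVD of the design
matrix built from direction cosines. Couplings are fitted **directly in
Hz**, absorbing the dipolar prefactor into the tensor, so $D_a$ comes out
in the units in which it is conventionally tabulated and no $r^3$
physical constants enter the fit. Unweighted fitting is the default;
$1/\sigma^2$ weighting is available when uncertainties are supplied.

The design-matrix condition number is always computed: above 100 the fit
warns (near-collinear bond vectors, e.g. a single ideal helix), and a
rank-deficient geometry is an error rather than a silent garbage tensor.

`tensor_params()` eigendecomposes the fitted matrix, orders principal
values by magnitude ($|A_{zz}| \ge |A_{yy}| \ge |A_{xx}|$), and reports
$D_a = A_{zz}/2$ and rhombicity $R = (A_{xx} - A_{yy})/3D_a \in [0, 2/3]$.
Euler angles use the ZYZ convention; because the principal frame is
defined only up to axis sign flips, the reported angles are canonicalised
to the representative with $\theta \in [0°, 90°]$. Different software
uses different conventions and canonicalisations, so Euler angles should
only ever be compared within one convention; $D_a$, $R$ and the R-factor
are convention-free and are what the round-trip tests validate. When
$A_{xx}$ and $A_{yy}$ are numerically degenerate the rhombicity is
snapped to exactly 0 or 2/3 and flagged.

The quality factor is
$R_{\%} = 100\sqrt{\langle(D_{obs}-D_{calc})^2\rangle / 2\langle D_{obs}^2\rangle}$
— twice the mean squared observed coupling in the denominator, the
standard normalisation (a random tensor scores ~100%, $D_{calc}=0$
scores $100/\sqrt2 \approx 70.7\%$).

The rigidity test (`fit_domains()`): if two domains are rigidly attached
they share one alignment frame, so a joint five-parameter fit across both
should do essentially as well as ten parameters of separate fits. If they
reorient independently, each domain has its own effective tensor and the
joint fit degrades sharply. The comparison metric is the percent increase
of the joint R-factor over the RDC-count-weighted mean of the per-domain
R-factors; simulated two-domain data with distinct generating tensors at
1 Hz noise shows increases well above 50%, while a shared generating
tensor keeps the joint fit within noise of the separate ones. Residue
selection (e.g. restricting to secondary-structure elements to avoid
structural noise from flexible loops) is the caller's responsibility via
the `residues` argument — the package deliberately does not guess
secondary structure.

## ITC isotherm models

Units are chosen so no conversion constants appear: concentrations in µM,
cell volume in mL, enthalpies in kcal/mol, heats in µcal
(kcal/mol × mL × µM = µcal). Exothermic heats are negative.

Concentration bookkeeping models perfusion displacement: each injection
of volume $v$ dilutes existing cell contents by $(1 - v/V_0)$, with fresh
titrant added and subsequently diluted identically. The cell volume is
not part of the data files and defaults to 1.4 mL, typical of the
instrument class; it is configurable. Per-injection heats are differences
of cumulative cell heat content with the midpoint ("instantaneous
mixing") displacement correction
$\Delta q_i = Q_i - Q_{i-1} + \frac{v_i}{V_0}\frac{Q_i + Q_{i-1}}{2}$,
matching common vendor practice. Pre-injections (`use_flag = 0`, e.g. the
customary small 2 µL first injection) are excluded from fitting but kept
in the concentration bookkeeping.

One note on heat conservation: the sum of per-injection heats of a
saturating one-site titration approaches $n\,\Delta H\,V_0\,[M]_0$ only
as closely as displacement allows — material expelled from the cell
before equivalence never reports its binding heat. For schedules that
saturate within the first few injections the budget closes to ~1%; for
schedules where equivalence falls mid-titration the deficit reaches
several percent. This is a property of the physics of a perfusion cell,
not a numerical error.

The one-site model uses the exact depletion quadratic with site
concentration $n[M]$. The two-site model is **sequential-macroscopic**
(stepwise constants $K_1$, $K_2$, enthalpies per step): the binding
polynomial $P = 1 + K_1[X] + K_1K_2[X]^2$ gives species fractions, and
the free titrant is solved per injection from the mass balance
$X_t = [X] + M_t\,(K_1[X] + 2K_1K_2[X]^2)/P$ by bracketed root finding
(the root is guaranteed bracketed in $[0, X_t]$ for positive inputs)
followed by one Newton polish, leaving the residual at machine precision
— tight enough that the $K_2 \to 0$ limit reproduces the one-site model
to 10^-9^ µcal. An independent-sites variant is provided as a
configuration switch because weak biphasic isotherms rarely distinguish
the two schemes; fitted parameters from either should be reported with
that caveat.

`fit_isotherm()` is Levenberg–Marquardt on the chosen forward model with
log-parameterised $K_d$ (and $n$) to keep them positive. Start values
follow the classic heuristics — $n$ from the molar ratio at the steepest
heat change, $\Delta H$ from the first usable heat per mole injected —
with a small multi-start over $K_d$ spanning c ≈ 0.1–100, keeping the
best converged fit. The Wiseman $c = n[M]_0/K_d$ is reported and a
warning raised outside $[1, 1000]$, where one-site parameters become
poorly determined. A constant per-injection offset can be fitted
(`fit_offset = TRUE`) or supplied via a dilution-control run whose mean
heat is subtracted.

`equivalence_ratio()` locates the transition midpoint as the extremum of
the discrete first derivative of heat versus molar ratio, refined by a
local quadratic through the three surrounding derivative points. Its
resolution is intrinsically limited to about one injection spacing of the
molar-ratio grid; with a typical 30-injection schedule that spacing is
~0.3 ratio units, and estimates should be quoted with that granularity.

## The synthetic-data module

The generators exist so that every analysis stage has a test bed whose
ground truth is known exactly; their defaults are the study conditions
the analyses were designed around (200 µM protein titrated to a 1:3 RNA
ratio, ~52 µM Kd; 500/850 MHz fields with their bundled delay schedules;
≥27-injection schedules led by a 2 µL pre-injection; tensors of a few Hz
with realistic rhombicities).

What they emulate:

- **Structures**: ideal-geometry backbones (helix, strand, or two
  helical domains related by an exact recorded rotation), built by
  internal-coordinate chain construction; amide H placed 1.02 Å from N in
  the peptide plane, anti to the C′–N–CA bisector. This geometry is
  needed because tensor fitting consumes H coordinates.
- **RDCs**: back-calculated from known tensors (optionally one per
  domain) plus independent Gaussian noise.
- **Relaxation**: rates from the rigid/model-free forward model, with an
  optional order-parameter profile (low-S² tails get an internal
  correlation time, default 0.8 ns, and show the depressed NOE real tails
  do); decay mode emits clean exponentials at the bundled delay lists.
- **Titrations**: fast-exchange population-averaged shifts on the
  depletion binding curve; broadening via the fast-exchange-limit
  closed form $R_{ex} = p_f p_b \Delta\omega^2 / k_{ex}$ applied as the
  intensity factor $R_2^0/(R_2^0 + R_{ex})$, with $\Delta\omega$ from the
  larger of the two dimensions' endpoint differences. This reproduces the
  qualitative shift-broaden-resharpen pattern of intermediate-fast
  exchange; it is *not* a Bloch–McConnell lineshape simulation and makes
  no claim about intermediate-slow regimes.
- **Isotherms**: forward-model heats plus Gaussian noise.

What they deliberately do not emulate: peak overlap, spectrometer
artifacts and baseline distortion, heteroscedastic or correlated noise,
anisotropic diffusion, and raw thermogram baselines. Passing tests on
synthetic data therefore demonstrate the *estimators* are correct and
stable under the stated noise models — not that real spectra free of
those complications.

All generators are deterministic under a fixed seed (noise is drawn in a
seed-scoped RNG context that restores the caller's RNG state), and every
generator's zero-noise output, fed to its matching analysis stage,
recovers the generating parameters — exactly for the linear RDC fit and
ITC, within the stated approximation for $\tau_c$.

## Degenerate inputs, tie-breaks, tolerances

- Duplicate residue numbers in any table are an error naming the residue;
  non-numeric fields are an error naming the line.
- Shift windows (¹H 0–14 ppm, ¹⁵N 90–140 ppm) warn rather than fail:
  unusual shifts are suspicious, not impossible.
- Residues present in only one spectrum are flagged unmatched and
  excluded from CSP statistics (the alternative — treating them as zero —
  biases profiles downward; exclusion is the default and the flag makes
  the choice auditable).
- Prolines and chain-terminal residues without a buildable H are skipped
  from vector extraction with a notice, never silently.
- B-factor projection clips to the PDB field range [0, 999.99] and scales
  CSPs by 100 by default (0.0608 ppm → B = 6.08).
- The exponential-decay fit bounds the rate positive and refuses
  all-equal intensities and duplicate delays.

## Problem sizes

The bundled tests and the acceptance script run at desk scale: 20–40
residues or vectors per structure, 6-point titrations, 28–30-injection
isotherms, and 20 replicates where a stochastic claim is being made. The
full suite completes in well under a minute on one core; the demo
pipeline (`run_pipeline(demo_config())`) in about half a second.

## Known limitations

- No NMR-STAR/BMRB or mmCIF ingestion; tables are bespoke headered
  TSV/CSV, and structures are PDB-format only.
- No per-residue model-free fitting, anisotropic diffusion tensors, or
  reduced spectral density mapping; the τc estimator assumes isotropic
  tumbling.
- No lineshape fitting for $k_{ex}$/$\Delta\omega$; broadening is
  simulated, not inverted.
- R2 is treated as exchange-free in the τc estimate (CPMG-type
  measurement assumed); a large unsuppressed $R_{ex}$ inflates τc.
- Euler angles are reported in one fixed convention and are not
  comparable across software conventions.
- ITC fitting assumes integrated per-injection heats; raw power traces,
  baseline correction and global multi-experiment fits are out of scope.
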