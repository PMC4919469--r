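---
title: "Mapping and quantifying competing effector interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and quantifying competing effector interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effectormap)
```

# The problem

A Rho-family GTPase presents one effector-binding surface to several
competing partners. `effectormap` analyses the three kinds of data that
characterize such competition — scintillation proximity assay (SPA)
titrations, NMR chemical shift perturbation (CSP) titrations, and
pyrene-actin polymerization time courses — together with the coupled
binding equilibria that link them. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generators do and do not emulate.

# Binding equilibria with ligand depletion

## Model

For receptor R, ligand L and competitor C sharing a single site (complexes
RL and RC, constants $K_L$ and $K_C$), the equilibrium state satisfies two
mass-action relations and three mass balances. Eliminating everything in
favor of free receptor $r$ gives the residual

$$g(r) = r\left(1 + \frac{L_t}{K_L + r} + \frac{C_t}{K_C + r}\right) - R_t,$$

which is strictly increasing on $[0, R_t]$ with $g(0) \le 0 \le g(R_t)$, so
the physical root is unique and always bracketed. We locate it by bisection
to near machine precision and polish with a few Newton steps using the
analytic derivative; the binary case is evaluated in the cancellation-free
closed form $x = 2 R_t L_t / (b + \sqrt{b^2 - 4 R_t L_t})$,
$b = R_t + L_t + K$.

Two modelling decisions are deliberate:

* **No approximations.** The assays this package serves run at totals
  comparable to (SPA: 30 nM reporters near a 32 nM Kd) or far above (NMR:
  hundreds of micromolar) the dissociation constants, where the free
  concentration differs substantially from the total. The hyperbolic
  isotherm and the Cheng–Prusoff correction are both biased there; the
  exact solution costs microseconds.
* **No ternary species.** RL and RC exclude each other; a three-protein
  complex is outside the model. This matches the fast-exchange displacement
  observation the model is used to interpret: when peak positions of the
  weak effector return to their free-state values upon addition of one
  equivalent of the tight effector, the population is a two-state mixture.

Dissociation constants below $10^{-15}$ M are clamped to that floor — a
numerically safe proxy for infinitely tight binding. Concentrations are
molar internally; parsers accept `nM`/`uM`/`mM` suffixes because assay
tables mix units.

## Fast-exchange observables

In the fast-exchange regime a resonance sits at the population-weighted
average $(1-f)\,\delta_\mathrm{free} + f\,\delta_\mathrm{bound}$ per
dimension. Combined with the exact competition solution this predicts
displacement titrations: at 600 µM each of receptor, tight effector
($K_d$ 37 nM) and weak effector ($K_d$ 5 µM) the weak effector is ~8%
bound (spectrum indistinguishable from free), while at 0.25 equivalents of
the tight effector it is ~73% bound (spectrum intermediate).

# SPA titration fitting

The forward model per titration point is

$$s_i = s_\mathrm{max}\,\phi_i + b \; (+\, m\,c_i),$$

where $\phi_i$ is the exactly solved occupancy of the bead-immobilized
receptor, $b$ the background and the optional linear term $m c_i$ models
nonspecific signal (off by default: the assays handle nonspecific signal
by restricting the concentration range, so fitting it would be
over-parameterized on typical 12-point series). Direct mode varies the
ligand against a fixed receptor; competition mode varies an unlabelled
competitor against the fixed reporter pair, with the reporter Kd held at
its independently determined value (the self-competition control both
validates that value and defines the fully displaced background).

Fitting is Levenberg–Marquardt (`minpack.lm::nls.lm`) on $\log_{10} K_d$ —
positivity plus good conditioning across the nM–µM span — with uniform
weights by default and an optional $1/s$ quasi-Poisson weighting for raw
counts (replicate structure of typical count data is unknown, so uniform
is the honest default). The reported `kd_se` is the delta-method standard
error from the local covariance, computed from a central-difference
Jacobian with absolute step floors (relative steps degenerate when the
background fits to ~0 on clean data). Percent-of-maximum normalization is
display-only; fitting always operates on corrected counts so the error
model stays on the measurement scale. Initial $K_d$ is the concentration
at half-maximal corrected signal; non-convergence is flagged, never
silently returned.

At the reporter design (30 nM/30 nM pair, reporter Kd 32 nM, competitor
Kd 5 µM, 5% multiplicative noise, 12-point grids spanning ~0.1–20× the
competitor Kd) the acceptance script measures median bias of a few percent
and ≥ 90% coverage of the 3-SE interval over 200 seeded replicates.

# CSP interface mapping

The pipeline reproduces the standard interface-mapping workflow:

1. **Matching.** Free and complex peak lists pair strictly by
   (residue number, atom group). Free entries missing from the complex are
   *disappeared* (intermediate-exchange broadening); pairs with either
   member overlapped are *overlapped*.
2. **Combined CSP.** $\delta = \sqrt{\Delta\delta_H^2 + (w\,
   \Delta\delta_X)^2}$ with $w = 0.2$ by default — the conventional 1/5
   weighting that places the ¹⁵N shift range on the ¹H scale; $w$ is
   configurable for ¹³C data or other conventions.
3. **Sentinels.** Disappeared residues are assigned a fixed CSP larger
   than the data set's maximum observed value, so they rank above every
   shifted peak while being excluded from the spectrum statistics. Two
   presets ship (`fig4`: 0.2 ppm with a mean threshold; `fig5`: 0.1 ppm
   with mean + 1 SD — appropriate when widespread disappearance leaves the
   spectrum mean low); `sentinel = NULL` auto-selects 105% of the observed
   maximum, following the same rule without a fixed value. A configured
   sentinel at or below the observed maximum raises an error naming the
   offending residue rather than silently re-ranking it.
4. **Significance.** Threshold = mean (or mean + 1 SD) over observed,
   non-sentinel, non-overlapped CSPs; comparisons are strict, so ties are
   not significant. Disappeared residues are always significant,
   overlapped never (no reliable measurement exists for them).
5. **Side-chain evidence.** ¹³C HSQC side-chain pairs that disappear or
   shift significantly widen the significant set (logical OR) — backbone
   amides alone under-report interfaces because they are hydrogen-bonded
   inside helices.
6. **Accessibility filter.** Significant residues with relative solvent
   accessibility strictly below 50% are classed buried and unavailable for
   binding; the cutoff is configurable.
7. **Restraints.** Active = significant and surface-accessible; passive =
   surface residues with any heavy atom within 6.5 Å of an active residue
   (the conventional automatic definition; configurable). Output is a
   plain listing plus CNS-dialect ambiguous restraints, each active
   residue of one molecule restrained to the union of active + passive of
   the partner at a 2.0 Å effective distance, deterministically ordered.

The pipeline is invariant to input row order, and residue numbering is the
author numbering of the peak lists throughout — no renumbering.

# Solvent accessibility

The Shrake–Rupley implementation samples each heavy atom's expanded sphere
($r_\mathrm{vdW} + 1.4$ Å) with an antipodally symmetrized golden-spiral
point set (default 960 points), counts points not occluded by any
neighbor, and scales by $4\pi(r+p)^2$. The point set is deterministic and
each atom receives a deterministic golden-angle rotation of it, which
decorrelates the per-atom quadrature error so residue sums converge faster
— residue areas change by under 2% when the point count doubles, and
totals are rotation/translation invariant to ~0.5% (quadrature
tolerance). Radii: C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å; unknown
elements fall back to 1.70 Å with a warning; hydrogens are ignored.
Relative accessibility divides by theoretical Gly-X-Gly maxima (values can
exceed 100% at termini); an empirical table can be supplied since
reference conventions differ between programs. Only the first model of a
multi-model PDB is used unless requested otherwise — ensemble averaging is
a separate analysis decision the package does not make implicitly.
Neighbor queries use an inclusive cutoff (distance exactly at the cutoff
counts), documented because the boundary case is otherwise ambiguous.

# Actin polymerization rates

"Maximal rate from the linear region" is operationalized as the maximum
ordinary-least-squares slope over a sliding window, default width 10% of
the trace (minimum 3 points), ties broken to the earliest window. No
baseline subtraction is applied — rates are raw slopes in AU/s, which is
what bar-chart comparisons of conditions need, and slope extraction is
invariant to constant offsets anyway. Condition summaries report
mean ± SE (SD/√n), with n = 1 groups flagged rather than given a
meaningless zero error. Note the estimator's known property: under
additive noise the *maximum* over windows is biased slightly upward;
wider windows trade that bias against curvature bias near the inflection.
On a dense logistic trace $F = K/(1 + e^{-r(t - t_0)})$ a 31-point window
recovers the closed-form maximal slope $rK/4$ within 2%.

# Synthetic data: what it does and does not emulate

Each generator is a pure function of (parameters, seed) — RNG state is
saved and restored, identical seeds give byte-identical output — and
returns a ground-truth record so end-to-end tests read planted values from
the data, not from test constants.

* `gen_spa_series`: exact forward model plus multiplicative Gaussian noise
  (counts are large, so a constant CV is the natural first model) and a
  paired background-only control. Defaults mirror the reporter design:
  30 nM/30 nM pair, reporter Kd 32 nM. Not emulated: radioligand decay,
  bead-settling drift, plate effects.
* `gen_titration_peaklists`: 60 residues, labelled protein at 200 µM,
  planted Kd 5 µM, ratio series 1:0 → 1:4 — the concentration regime of a
  weak-affinity HSQC titration. Eight fast-exchange residues move along
  fixed vectors (combined magnitudes 0.09–0.18 ppm, below the 0.2 ppm
  preset sentinel, as in a real weak-binding dataset) scaled by the exact
  bound fraction; six intermediate-exchange residues are removed outright
  at ratios ≥ 1:0.5 — hard removal, not lineshape simulation, because the
  pipeline consumes peak lists, not spectra. Peak-position noise is
  additive Gaussian, SD `noise_sd` in ¹H and 5 × `noise_sd` in ¹⁵N so the
  weighted CSP contribution is isotropic. Not emulated: gradual broadening,
  peak overlap emerging mid-titration, assignment errors.
* `gen_hairpin_structure`: two ideal anti-parallel poly-alanine helices
  (3.6 res/turn, 1.5 Å rise, Cβ pseudo-side-chains) at a 10 Å axis
  separation, with ground-truth facing/outward classes (helix termini
  excluded — end exposure swamps packing there) and the ≤ 6.5 Å contact
  map. It is a geometry fixture, not a physical model: no loop residues,
  no side-chain diversity, no packing relaxation.
* `gen_actin_trace`: lag → linear → plateau with hard clamps, so the
  planted maximal slope is exactly the linear-region rate; additive
  Gaussian noise. Not emulated: nucleation-elongation mechanism, pyrene
  quantum-yield calibration.

Passing tests on these generators therefore demonstrate correctness of the
*analysis* under the declared noise models; they cannot certify behavior
under real-data pathologies the generators do not produce (baseline drift,
mis-assignment, exchange-regime crossover).

# Problem sizes and numerical tolerances

The test suite and acceptance script use 1,000 random systems for the
solver-vs-oracle comparison (agreement to 1e-9 relative), 200 replicate
competition fits at 5% noise, 100 seeded CSP titrations at noise SD =
0.25 × the planted shift magnitude, and 960-point SASA quadrature —
sizes chosen so the full pipeline re-runs in well under a minute while
leaving the statistical checks comfortably powered. Mean/SD thresholds are
reproducible to 1e-12 against independent recomputation; equilibrium mass
balances close to 1e-9 relative.

# Known limitations

* Kinetics (on/off rates), cooperativity, multivalency and membrane
  avidity are out of scope; only equilibrium populations are modelled.
* The SPA error model is single-curve; no global multi-curve fitting or
  Bayesian posteriors.
* CSP analysis does not estimate Kd from shift trajectories (affinities
  come from SPA) and does not model exchange rates.
* SASA uses a fixed heavy-atom radius table; no united-atom or
  element-specific probe adjustments.
* The restraint writer emits the CNS `assign` dialect only.
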