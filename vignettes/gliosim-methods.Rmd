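---
title: "Methods: the two-compartment growth model, its discretization, and the scenario ensemble"
author: "gliosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-compartment growth model, its discretization, and the scenario ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliosim)
```

## The model and its assumptions

`gliosim` simulates the evolution of a recurrent glioblastoma between two
surveillance MRI scans with a two-compartment reaction-diffusion model on
the patient's labeled brain domain. Tumor cells are split into a
proliferating density $p(x,t)$ and a quiescent density $q(x,t)$, both
dimensionless fractions of a carrying capacity normalized to 1:

$$
\frac{\partial p}{\partial t}
 = \nabla \cdot \big(D(x)\,\nabla p\big)
 + \underbrace{\rho(x)\,p\,\big[1-\delta(p+q)\big]}_{\text{growth}}
 - \underbrace{k(x)\,p\,\delta(p+q)}_{\text{quiescence}},
\qquad
\frac{\partial q}{\partial t} = k(x)\,p\,\delta(p+q).
$$

The switch $\delta(u) = \min(u,1)^3$ is the Beta(3,1) cumulative
distribution function of the total density, so $\delta(0)=0$ and
$\delta(1)=1$: where the tumor is sparse, growth is nearly exponential
($\dot p \approx \rho p$); where it approaches capacity, the reaction
degenerates to a pure transfer $p \to q$. Quiescent cells accumulate
irreversibly and do not diffuse — they represent the dense, hypoxic or
treated tissue that appears hypointense on T1 imaging. The quiescence term
deliberately lumps *all* treatment effects (radiation, chemotherapy,
anti-angiogenic agents) into one net rate: with surveillance imaging as the
only data source there is no basis for separate treatment terms, and the
model's purpose is to generate a realistic *range* of outcomes, not a
mechanistic treatment forecast.

Key structural assumptions:

* **Isotropic diffusion, fixed anatomy.** Motility is scalar and piecewise
  constant ($D_w$ in white matter and segmented tumor, $D_w/2$ in gray
  matter, 0 in CSF/background). There is no mass effect, no tensor
  anisotropy, no domain deformation.
* **Monotone quiescence.** $q$ never decreases, so the model cannot
  represent rapid clearance of dense tissue; strongly shrinking tumors are
  known to be approximated poorly.
* **No stochastic components.** All randomness in the package lives in the
  phantom generator's intensity noise; the model and solver are
  deterministic, and ensemble output is bit-reproducible across runs and
  worker counts.

## Parameters

Each scenario fixes seven quantities (class `model_parameters`):

| parameter | units | meaning | default levels |
|---|---|---|---|
| `khat0` | d | quiescence halving time, edema/normal tissue | 14, 35, 56 |
| `rhohat0` | d | growth doubling time, edema/normal tissue | 21, 35, 49 |
| `D_w` | mm²/d | diffusivity in white matter and tumor | 0.015, 0.030, 0.060 |
| `I_e` | — | density window counted as edema | [0.012,0.03], [0.016,0.04], [0.024,0.06] |
| `I_c` | — | density window counted as enhancing | [0.16,0.80], [0.22,0.40], [0.30,0.50] |
| `khat1` | d | quiescence halving time, enhancing region | 18, 37, 58 |
| `rhohat1` | d | growth doubling time, enhancing region | 27, 57, 97 |

Rates enter the equations as $\log(2)/\hat t$. The doubling/halving-time
parameterization matches the ranges reported in the clinical literature for
GBM volume kinetics (roughly 14–50 days doubling before treatment, halving
times of order two months under radiotherapy); diffusivities of
0.015–0.06 mm²/d sit in the middle of the published (and very wide) range
for infiltrative glioma. The windows $I_e < I_c$ encode that edema
corresponds to low tumor-cell density and contrast enhancement to high
density; they are used twice, once to impute initial densities from
intensities and once to re-segment the simulated field.

Two modeling choices were genuinely open and are resolved as follows:

* **Rates outside the segmentations.** The parameterization defines rates
  only for enhancing and edematous tissue, yet cells diffuse beyond both.
  We apply the edema-region values (`khat0`, `rhohat0`) to *all*
  non-enhancing brain tissue, on the grounds that the edema parameters are
  the model's low-density regime and infiltrating cells are at low density.
* **Necrotic core.** Voxels segmented as necrotic are initialized as pure
  quiescent tissue with total density `q_core = 0.9` — above every default
  scenario's $I_c$ upper bound, so the core never re-classifies as
  enhancing, and entirely in $q$ because necrosis reflects high cellularity
  without net growth. No published value exists for this density; 0.9 is a
  documented package choice (argument `q_core` of
  `impute_initial_state()`).
* **Resection cavity.** The cavity is fluid-filled: its voxels are
  relabeled CSF at load time, removing them from the diffusion domain
  (no cells, no flux). This too is a documented assumption rather than a
  published rule.

## Initialization from images

Within the enhancing mask, T1C intensities are min–max normalized over the
mask to $s \in [0,1]$ and $p = I_c^{lo} + s\,(I_c^{hi}-I_c^{lo})$; within
the edema mask, T2/FLAIR intensities are normalized likewise and the map is
decreasing, $p = I_e^{hi} - s\,(I_e^{hi}-I_e^{lo})$. The linear
intensity–density relationship follows the empirical literature on MR
signal vs. cellularity. Min–max normalization *within each mask* is a
package choice (no normalization convention is published); a
constant-intensity mask maps to the window midpoint (the 0/0 guard). All
imputed density starts in $p$; $q$ starts at zero outside the necrotic
core.

## Discretization and time integration

**Space.** A second-order finite-volume scheme on the anisotropic voxel
grid. The diffusivity on each face between neighboring voxels is the
*harmonic mean* of the two voxel values, which (i) is the standard
conservative choice for discontinuous coefficients and (ii) makes every
face touching a zero-$D$ voxel (CSF, background, skull) a no-flux face
automatically — no boundary bookkeeping, and cells can never leak out of
brain tissue. Because each face flux enters its two voxels with opposite
signs, the discrete operator conserves total mass exactly; with the
reactions switched off the solver conserves mass to rounding error
(the test suite requires $10^{-8}$ relative over 60 days).

**Time.** An adaptive second-order Runge–Kutta–Chebyshev (RKC) integrator,
written for this package: an explicit stabilized method whose stage count
grows with the square root of the diffusion stiffness, the standard choice
for mildly stiff parabolic problems of exactly this kind. The stage count
per step is set from a conservative Gershgorin bound on the spectral radius
of the semi-discrete operator plus a bound on the reaction Jacobian; step
size is controlled by the embedded second-order error estimate
$0.8(y_n - y_{n+1}) + 0.4\,h\,(F_n + F_{n+1})$ against
`abs_tol + rel_tol * |y|` (defaults $10^{-7}$, $10^{-4}$), with steps
capped at `max_step_days` (default 1 d). Correctness is defined
behaviorally, not by solver internals: halving `rel_tol` must change the
virtual enhancing-voxel count by well under 0.5%, and uniform-field runs
must match an independent high-accuracy integration of the well-mixed
two-compartment ODE (diffusion vanishes for uniform fields) to $10^{-3}$
relative at 60 days. Both properties are asserted in the test suite, the
oracle being `deSolve::ode` at tolerances $10^{-10}$.

**Numerical positivity.** Explicit schemes can undershoot zero by rounding
amounts near sharp mask edges. The right-hand side evaluates the reactions
on densities clamped to $[0,\infty)$, and at the end of each accepted step
any value in the band $[-10^{-9}, 0)$ is zeroed; a value below $-10^{-9}$
aborts the run with an error rather than being silently clipped. The
$\delta$ switch saturates at 1 for totals above capacity, so transient
local overshoot $p+q > 1$ from diffusive influx only accelerates the
$p \to q$ transfer that pulls it back down. Ties in best-scenario selection
go to the lowest scenario index.

## The scenario ensemble

The same 18 parameter sets simulate every tumor. They form a three-level
orthogonal-array (Taguchi) design over the seven parameters: the two most
sensitive parameters, `khat0` and `rhohat0`, are crossed completely (each
of their 9 level pairs occurs exactly twice), and the remaining parameters
are balanced across levels. The table is embedded as package data
(`inst/extdata/scenarios_default.csv`) rather than regenerated, and
`validate_design()` brute-force checks pair balance, level balance, and
window disjointness on every table it is given — custom CSV tables with the
same schema are accepted throughout, so denser designs (e.g. 12 levels /
144 runs) need no code change.

One caveat the balance checker surfaces deliberately: in the published
18-row table the `khat1` column occurs 6/5/7 times across its three levels
rather than 6/6/6 (pairwise-balance analysis suggests a single misprinted
row; a true three-level orthogonal array would be exactly balanced). We
ship the table as published, and `validate_design()` honestly reports the
`khat1` level-balance failure while all other checks pass. Users who need a
strictly balanced design can supply a corrected CSV.

## What the phantom emulates — and what it does not

`make_brain_grid()` builds a concentric-ellipsoid brain (background, gray
shell, white interior, paired CSF ventricles) at clinical surveillance
resolution — anisotropic voxels of about $0.9 \times 0.9 \times 7$ mm.
`make_baseline_study()` plants a spherical tumor: optional necrotic core,
enhancing rim whose ground-truth density falls radially across $I_c$, and
an edema halo spanning $I_e$; intensities are synthesized by the exact
inverse of the imputation maps, plus additive Gaussian noise (default
`noise_sd = 0.02`, masks noise-free — segmentations are treated as ground
truth). With zero noise, imputation recovers the ground-truth density to
$10^{-9}$, which pins down the full imputation pipeline.
`make_followup_by_simulation()` closes the loop by simulating forward and
re-encoding the result as a follow-up study, giving pairs with a known
generating scenario for parameter-recovery tests.

The phantom emulates geometry, intensity–density structure, anisotropy,
and file-set layout. It does **not** emulate MRI physics (bias fields,
motion, multi-scanner variation), irregular tumor shapes, infiltration
along tracts, co-registration error between time points, or manual
segmentation variability. Passing the phantom suite therefore demonstrates
that the *computational pipeline* is correct and self-consistent — that the
solver meets its invariants and that the generating scenario is recovered
from synthetic follow-ups — not that the model fits clinical tumors; the
latter requires patient archives outside the scope of a code package.

## Problem sizes and runtime choices

The test suite runs phantoms between $32\times32\times8$ and
$48\times48\times10$ voxels — large enough for distinct tissue layers,
nested tumor shells, and several hundred enhancing voxels, small enough
that the full 18-scenario, 60-day ensemble completes in well under a minute
on one CPU core. A $64\times64\times12$ ensemble completes in a few
minutes; cost scales linearly in voxel count and roughly with
$\sqrt{D_w}\,/$ step size in time.

## Known limitations

* Tumors that shrink rapidly (large observed volume reductions) are poorly
  matched: the model has no mechanism for removing dense tissue.
* The narrow enhancing windows mean a growing tumor can *lose* enhancing
  voxels as its core saturates past $I_c^{hi}$ — a feature of the virtual
  segmentation, mirrored in how dense cores stop enhancing, but one that
  makes voxel counts non-monotone in time.
* Overlap scores compare masks on the assumption of perfect co-registration;
  on real data, registration error sets a ceiling on attainable agreement.
* The agreement score is Jaccard-type: for equal-size masks overlapping
  half of each, $A = 1/3$ while containment $C = 1/2$ — worth keeping in
  mind when comparing against Dice-type numbers ($2|S\cap R|/(|S|+|R|)$),
  which would give $0.5$ for that configuration.
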