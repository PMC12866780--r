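---
title: "Multiscale tissue analysis with mechisto: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale tissue analysis with mechisto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechisto)
```

This vignette is the package's own account of the science it implements:
the constitutive models and their assumptions, the tunable parameters and
why their defaults are what they are, what the synthetic-data generators
emulate (and do not), and the numerical choices made where the design was
genuinely open.

## 1. Force sensing and units

Tissue forces are estimated from the deflection of a calibrated microbeam.
`beam_force()` uses the end-loaded Euler-Bernoulli cantilever,
$F = 3 E_b I \delta / L^3$ with $I = \pi \Phi^4/64$, with defaults
matching the typical instrument configuration ($E_b = 411$ GPa,
$L = 57\text{--}59$ mm, $\Phi$ from the small-beam set for indentation and
the large-beam set for compression). Commercial instruments calibrate
their beams empirically, and that calibration is not public; when a
measured stiffness $k$ (N/m) is available it can be supplied in
`cantilever_spec()` and bypasses the formula entirely. Beam selection per
specimen is configuration, not something the package infers.

All internal quantities are SI (s, m, N, Pa). CSV columns must declare
units by suffix (`force_mN`, `deflection_um`, ...); undeclared units are a
hard error rather than a guess, because silent unit mistakes are the
dominant failure mode for this kind of data.

## 2. Local indentation

The flat-punch (Sneddon) solution
$F = E\,\tfrac{2R}{1-\nu^2}\,\delta$ is linear in $\delta$ with no offset,
so `fit_sneddon()` regresses the per-hold steady forces through the
origin; the closed-form slope is also checked against a brute-force grid
search in the tests. Defaults: $R = 38.1\ \mu$m, $\nu = 0.5$
(incompressible). The steady force of each hold is the mean over the final
`window_fraction` of the hold (default 0.2): the protocol's 1-min holds
leave some residual relaxation, and tail averaging suppresses it; how the
original steady states were extracted from holds (last sample vs tail
mean) is not fixed by the protocol, which is exactly why the window is a
parameter. Total indentations above 5% of specimen height trigger a
warning, since the solution assumes small deformation.

## 3. Unconfined compression and the neo-Hookean equilibrium

Strains follow the geometric definitions
$\varepsilon_{rr} = r_c/R_0 - 1$, $\varepsilon_{zz} = h_c/H_0 - 1$, and
the axial Cauchy stress is $\sigma = F/(\pi r_c^2)$, kept signed (negative
in compression); moduli are reported positive. The Poisson ratio is the
negative through-origin slope of $\varepsilon_{rr}$ on $\varepsilon_{zz}$,
clamped to $(0, 0.5]$ with a flag when the data fall outside.

For the equilibrium response $W = \tfrac{c}{2}(I_C - 3)$, the stress
expression under unconfined compression with traction-free lateral
surfaces is $\sigma_{zz} = c(\lambda_z^2 - \lambda_r^2)$ when the lateral
stretch is measured; without lateral measurements the incompressible
kinematics $\lambda_r = \lambda_z^{-1/2}$ give the classical uniaxial
$\sigma = c(\lambda_z^2 - \lambda_z^{-1})$. Both reduce to the same curve
in the incompressible limit, both are implemented
(`use_measured_lambda_r`), and the choice is recorded in the fit object.
The model is linear in $c$, so the least-squares estimate is closed form,
and $E = 2c(1+\nu)$ ($= 3c$ at $\nu = 0.5$) enables comparison with the
indentation modulus; for strains within 1% the two agree with the linear
slope $\sigma/\varepsilon$ to within 5% by construction of the model,
which the test suite verifies.

Preconditioning cycles, if present in a record, are outside the fitted
window: fitting starts at the protocol origin, so preconditioned records
should be trimmed to the protocol start on read.

## 4. Nonlinear Maxwell-Wiechert stress relaxation

The viscoelastic model is a nonlinear equilibrium spring,
$\sigma_i^0 = c_a e^{c_b \varepsilon_i} \varepsilon_i$, in parallel with
two Maxwell elements sharing stiffness $c_m$ and carrying viscosities
$\eta_1 < \eta_2$ (fast/slow ordering enforced by relabeling). Within hold
$i$ each element's spring strain follows the printed closed form
$$\varepsilon^s_{ij}(t) =
  \frac{\eta_j\,\hat\varepsilon_{ij}}
       {\eta_j + \hat\varepsilon_{ij}\, c_m\, (t - t_i)},$$
with carry-over
$\hat\varepsilon_{ij} = \varepsilon_i - \varepsilon_{i-1} +
\varepsilon^s_{(i-1)j}(t_i)$ and initial conditions $\varepsilon_0 = 0$,
$\varepsilon^s_{0j}(t_1) = 0$. This closed form is the solution of the
quadratic dashpot law
$\dot\varepsilon^s = -(c_m/\eta)(\varepsilon^s)^2$ — an algebraic, not
exponential, decay — and the tests verify it against independent ODE
integration to $10^{-8}$ relative accuracy.

**Sign convention.** The closed form relaxes toward zero only for
positive spring strains; for negative arguments its denominator vanishes
at a finite critical time (the implementation raises a domain error
reporting that time). The module therefore operates on compressive
strain/stress *magnitudes*: steps are positive strains and stresses are
positive, which yields the physically expected monotone relaxation toward
the equilibrium stress within every hold and makes "equilibrium data"
extractable at all. The signed kinematics remain in the compression
module; the generator converts magnitudes to signed stresses and forces.
With this convention $c_b > 0$ encodes stiffening with increasing
compression.

**Fitting.** `fit_viscoelastic()` follows the two-step scheme: (1)
end-of-hold stresses (mean of the final 10% of each hold) are fitted with
the nonlinear-spring law, using an exact log-linearization as the start;
(2) $(c_m, \eta_1, \eta_2)$ are fitted to the full hold trace by
Levenberg-Marquardt with 8 multi-starts over a log-spaced grid of
$(\eta_1, \eta_2)$ scaled to the characteristic value
$c_m \bar\varepsilon\, T_\text{hold}$ (for the quadratic dashpot the
relaxation timescale is $\eta/(c_m \varepsilon)$, not $\eta/c_m$). Bounds:
$c_a, c_m \in [1, 10^6]$ Pa, $c_b \in [-50, 50]$,
$\eta \in [1, 10^8]$ Pa·s. (3) Because the slow branch has typically not
fully decayed by the end of a 2-min hold, the "equilibrium" stresses of
step 1 are slightly contaminated and its $(c_a, c_b)$ inherit a bias; a
final joint Levenberg-Marquardt polish of all five parameters (default
`refine = TRUE`) removes it, and `refine = FALSE` returns the literal
two-step result. Ramps are excluded from the fit: the hold solution is
written for post-step relaxation, and holds dominate the record. A
`slow_eta` flag is raised when $\eta_2/c_m$ exceeds 10× the hold duration,
warning that the slow time constant is poorly constrained by the record
length.

## 5. Stain colorimetry

Classification happens in HSL space (bi-cone), computed in floating point
from normalized 8-bit RGB without gamma correction. The band definitions
are the printed ones: MTC blue H 150–249° (S 0–1, L 0.01–1) for total
collagen; PSR red 324–12° (wrapping through 0°), orange 13–52°, yellow
53–72°, green 73–180°, all at S 0.1–1, L 0.1–0.93. Printed integer bounds
are treated as inclusive and compared half-open as $[lo, hi+1)$ after
unrolling the wraparound, so adjacent printed bands partition the hue
circle without double counting. Background cutoffs (lightness ≥ 0.95 =
white background for MTC; ≤ 0.05 = black for PSR) are configurable
defaults, as the original thresholding scripts are unpublished. Area
fractions are reported over tissue (non-background) pixels and need not
sum to one; representative-region cropping is user input, not automated.

## 6. Fiber architecture

Fiber angles are axial data (a fiber at $\theta$ is the same as at
$\theta + 180^\circ$), so the Orientation Index doubles the angles before
computing the mean resultant length $\bar R$:
$OI = \bar R = 1 - \text{circular variance}$. Without doubling, uniformly
random axial angles would give $OI \approx 0.64$ rather than the stated 0,
which is why axial mode is the default; the non-axial mode is retained for
comparison with a literal circular-variance computation on raw angles, and
the choice is recorded per call. The OI is unweighted by default (each
fiber counts once); a length-weighted variant exists but is off, since
nothing in the upstream fiber tables mandates weighting.

## 7. Cell phenotyping

Features are z-scored across the whole table (population SD by default;
sample SD by option, and the choice is recorded), aspect ratio =
major/minor axis. Clustering uses a symmetrized kNN graph (Euclidean
distance in z-space, $k = 15$ by default — the resolution 0.1 is fixed by
the analysis design, $k$ is not, so it is exposed) and Louvain modularity
optimization; the seed is mandatory and scoped, so labels are reproducible.
The phenotype rule compares cluster means of z(PanCK), z(Vimentin) and
z(area) to the across-cluster medians: PanCK decides epithelial vs
non-epithelial (ties resolved toward the marker axis), area splits
large/small, and Vimentin acts as a consistency check — clusters whose
Vimentin direction matches their PanCK direction are flagged ambiguous
rather than reassigned. The kNN graph is built from a dense distance
matrix, which is appropriate for the $10^3$–$10^4$ cells of a typical
per-sample table but not for millions of cells at once.

## 8. Group statistics

The Scheirer-Ray-Hare test ranks all observations together (midranks for
ties) and computes each effect's $H = SS_\text{effect}/MS_\text{total}$
against a chi-square law. Sums of squares come from Type II model
comparisons on the ranks, so unbalanced designs are handled; with a
degenerate second factor the factor-A statistic reduces exactly to
tie-corrected Kruskal-Wallis $H$, which the tests assert. Both the
tie-corrected denominator ($SS_\text{total}/(N-1)$ from the midranks, the
default) and the uncorrected $N(N+1)/12$ are available, since published
descriptions of the test differ on this point. Kruskal-Wallis delegates
to `stats::kruskal.test`; Dunn's pairwise z statistics use the joint rank
sums with tie correction and Bonferroni adjustment
$p_\text{adj} = \min(1, m\,p)$.

## 9. Synthetic data: what it emulates, and what it does not

Every generator is a pure function of (parameters, seed) — RNG state is
scoped and restored — and writes its ground truth as a YAML sidecar that
fully determines regeneration.

* **Mechanics.** Stepped protocols match the standard designs: 5 × 1%
  steps with 1-min holds for indentation, 8 × 2.5% (20% total) with 2-min
  holds for compression. Noise is Gaussian on force/stress. The default
  viscoelastic truth ($c_a = 1000$ Pa, $c_b = 2$, $c_m = 500$ Pa,
  $\eta_1 = 150$, $\eta_2 = 1500$ Pa·s) sits at the soft-tissue stiffness
  scale (equilibrium tangent ≈ 1 kPa, consistent with moduli of a few kPa
  at 20% compression) with fast/slow relaxation times of roughly 10 s and
  100 s under the protocol — identifiable from, but not trivially short
  relative to, the 2-min holds. No published raw curves are being matched;
  these are study-scale conditions, not specimen fits.
* **Histology.** Rasters are block-composed: smooth random fields carve
  contiguous class regions with irregular boundaries at exact pixel
  counts, so area-fraction recovery also exercises background masking;
  colors are drawn from the interior of each printed HSL band and 8-bit
  quantized. They are not photorealistic — no staining gradients, no
  illumination drift, no out-of-band tissue — so passing recovery tests
  shows the colorimetric bookkeeping is correct, not that real slides
  classify perfectly.
* **Fibers.** Axial angles come from a von Mises draw on $2\theta$
  (Best-Fisher sampler) halved — the standard axial construction —
  with $\kappa = 0$ the uniform case; lengths/widths are Gaussian
  truncated at zero.
* **Cells.** Four archetypes mirror the phenotype rule, with log-normal
  areas and marker intensities (positive, right-skewed); group effects
  shift log-locations per onset × tissue group, defaulting to the
  qualitative contrasts of interest (smaller cells in early-onset
  tissue, stronger marker shifts in cancer). Spatial context, segmentation
  errors and marker bleed-through are not modeled.

## 10. Problem sizes and numerical choices

The test suite exercises: 200-replicate Sneddon recovery at 2% force
noise (mean within 1%), 100-replicate five-parameter viscoelastic
recovery at 1% stress noise (median relative error ≤ 10% per parameter),
512² raster fraction recovery (≤ 0.01 absolute per band), 1000-replicate
null calibration of Scheirer-Ray-Hare and Kruskal-Wallis (type-I error
within [0.035, 0.065] at α = 0.05), and 50-replicate null-nonlinearity
identification. These sizes keep the full suite in the minutes range
while leaving Monte-Carlo bands narrow enough to be informative.

Numerical details worth knowing: through-origin regressions are closed
form; the viscoelastic fit uses `minpack.lm::nls.lm` (residual-function
interface, robust to boundary solutions such as a vanishing Maxwell
stiffness); equilibrium starts come from exact log-linearization of the
nonlinear spring; negative fitted stiffnesses are clamped to zero with a
flag rather than silently reported; and CSV round trips preserve 12+
significant digits.

## 11. Known limitations

Single-axis loading only (no multiaxial or anisotropic constitutive
models); two Maxwell elements, not a continuous relaxation spectrum; no
adhesion or substrate correction in indentation; no stain deconvolution or
slide tiling; ridge detection and deep-learning segmentation are consumed
as tables, not reimplemented; and the statistics module stops at
rank-based tests with Bonferroni control — mixed models are out of scope.
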