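---
title: "Sequential simulation-trained inference for multi-fiber dMRI microstructure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential simulation-trained inference for multi-fiber dMRI microstructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fiberlfi)
```

# The model

A white-matter imaging voxel may contain up to three coherently oriented
fiber populations. Under the *standard model of diffusion*, fiber $i$
contributes a two-compartment kernel to the measured attenuation: an
intra-axonal "stick" with parallel diffusivity $D_{a,i}$ and an
extra-axonal anisotropic Gaussian with parallel and perpendicular
diffusivities $D_{e,i}^\parallel, D_{e,i}^\perp$. Writing
$t_i^* = (p^\top m_i)^2$ for the squared projection of the gradient
direction $p$ on the fiber axis $m_i$, and folding each fiber's mixture
weight and intra-axonal volume fraction into signal fractions
$z_{i,1}, z_{i,2}$, the noiseless multi-shell attenuation in the
high-orientation-concentration limit is

$$
f(p, b) = \sum_{i=1}^{n} z_{i,1} e^{-b D_{a,i} t_i^*} +
  z_{i,2} e^{-b D_{e,i}^\perp - b (D_{e,i}^\parallel - D_{e,i}^\perp) t_i^*},
\qquad \sum_i z_{i,1} + z_{i,2} = 1 ,
$$

with iid Gaussian measurement noise of variance $\sigma_e^2$ on the
b0-normalized attenuations. Units are $\mathrm{ms}/\mu m^2$ for b-values
and $\mu m^2/\mathrm{ms}$ for diffusivities, so all exponents are
dimensionless; `read_gradient_table()` converts the conventional
$\mathrm{s/mm^2}$ at I/O. The voxel's orientation content is an
antipodally symmetric ODF, modeled as an equal-weight mixture of Watson
densities with a large, fixed concentration.

Direct maximum-likelihood inversion of this model is notoriously
ill-posed: the extra-axonal parallel diffusivity in particular moves the
signal so little under typical two-shell designs ($b \le 3$) that very
different values are statistically indistinguishable at realistic SNR
($\approx 16$). `run_identifiability_experiment()` reproduces this:
50-start Levenberg–Marquardt maximum likelihood on replicate single-fiber
datasets with the orientation fixed at truth still leaves a mean absolute
error in $D_e^\parallel$ that is a large fraction of its prior range.
This motivates a fully Bayesian treatment with honest uncertainty
reporting rather than reliance on point estimates.

# The sequential inference pipeline

The method decomposes inference into subproblems, each solved by an
inverse model trained on simulations from the prior:

1. **Orientation inversion and model selection.** Per-shell signals are
   fitted in a degree-8 real symmetric spherical-harmonic basis
   (`fit_sh()`); a trained inverse operator (`inverter_model()`) maps the
   multi-shell harmonic representation to a discretized ODF on a level-4
   icosphere, and the fiber count and orientations are the ODF modes
   (`find_odf_peaks()`).
2. **Orientation uncertainty.** A parametric bootstrap re-noises the
   *fitted* (smoothed) signals at the estimated noise variance, re-inverts
   each replicate, and classifies replicate peaks to the original
   estimates; each fiber gets a detection rate and an angular dispersion
   (`dr_ad()`).
3. **Demixing.** Conditional on the orientations, the signal is an
   additive model in the coordinates $t_i^*$; each shell is decomposed
   into per-fiber *centered* (integral-zero), monotone-nonincreasing
   decay curves on $[0,1]$ (`fit_additive_model()`). Centering is what
   makes the per-fiber curves identifiable; each fiber's curve depends on
   its own kernel only, which justifies inferring kernels fiber by fiber.
4. **Amortized kernel posteriors.** A mixture density network
   (`mdn_model()`) maps a fiber's demixed curves to a 3-component Gaussian
   mixture over $(D_a, D_e^\parallel, D_e^\perp, z_1, z_2)$; samples are
   rejected outside the diffusivity constraints and jointly rescaled onto
   the fraction simplex. Point estimates are the posterior mean and an
   approximate MAP that re-scores paired candidate draws under the exact
   Gaussian likelihood; marginal uncertainty is reported as
   highest-density regions (`hdr()`).

`run_inference()` executes the full pipeline for one voxel;
`infer_volume()` drives it over a masked NIfTI volume.

# The synthetic-data generator

`generate_dataset()` draws voxel configurations from biologically
constrained priors: parallel diffusivities uniform on
$[0.2, 3]\,\mu m^2/\mathrm{ms}$; $0 < D_e^\perp < 0.8\,D_e^\parallel$
(rejection from a box proposal); axes uniform on the hemisphere with all
pairwise crossing angles $\ge 10^\circ$ and, for three fibers, the
second-smallest angle $\ge 30^\circ$; signal fractions flat-Dirichlet with
every intra-axonal fraction $\ge 0.1$; fiber count uniform on $\{1,2,3\}$
(the count prior is not pinned down by the biology; it is configurable).
Signals are simulated on an HCP-like two-shell design ($b = 1, 3$,
60 directions per shell, 12 b0 volumes) with Gaussian noise of standard
deviation $0.0620$ by default — the level estimated from real b0 images
of such acquisitions.

The generator emulates single-voxel signals only. It does not emulate
spatial correlation between voxels, Rician or spatially varying noise,
imperfect b0 normalization, or orientation dispersion beyond the
high-concentration Watson limit (fanning). Passing tests therefore
demonstrate correctness of the method under its own generative
assumptions, not robustness to the misspecifications present in real
data.

# The ODF inverter

The inverse operator minimizing the sampling-based Bayes risk between
rendered target ODFs and mapped signals is rotationally equivariant, so
the model class is built from operations that commute with rotations:

* a **conditioned response**: per-degree, per-shell deconvolution kernels
  predicted from rotation-invariant signal features (per-shell mean
  attenuation and normalized degree-2/4 spectral power), learned by
  closed-form regression on the training set. Conditioning the kernel on
  invariants adapts the deconvolution to each voxel's microstructure
  without breaking equivariance — the mechanism a free-form equivariant
  network would have to discover by gradient descent;
* **unrolled constrained deconvolution**: 60 ADMM iterations of
  super-resolved (degree-12) spherical deconvolution under pointwise
  nonnegativity on the mesh. Positivity is what suppresses the ringing
  of band-limited deconvolution and lets genuinely weak fiber lobes
  (weight ratios down to $\sim 0.1$ under the prior) survive;
* a **spectral output head**: per-degree gains fitted to the rendered
  equal-weight Watson targets by ridge-penalized risk minimization
  (closed-form start, minibatch Adam refinement). The ridge shrinks gains
  at degrees the deconvolution barely populates, which would otherwise
  amplify clutter.

Equivariance is verified as a property (`equivariance_error()`, median
relative error under random rotations, tolerance 0.05 — the residual
error is mesh-quadrature discretization, not architecture).

Design choices that were genuinely open:

* **Target concentration.** Rendered training targets use Watson
  $\kappa = 50$: on a level-4 mesh with a degree-16 output system a
  $\kappa = 100$ target leaves about 21% of its energy outside the
  representable band (measured by projection), which would dominate the
  Bayes risk with irreducible truncation error; $\kappa = 50$ leaves
  under 5% and is still sharply peaked relative to the $10^\circ$
  minimum crossing angle.
* **Peak detection defaults.** Relative threshold 0.1 and minimum
  separation $25^\circ$: the positivity-constrained output is
  clutter-suppressed, so the low threshold retains weak true lobes while
  the separation prunes residual band-limit ring maxima. These were
  selected on validation simulations (noiseless and noisy one- and
  two-fiber voxels) before the final evaluation runs.
* **Mesh numerics.** Vertex quadrature weights are one-third incident
  triangle areas rescaled to $4\pi$; harmonic analysis on the mesh uses
  the weighted least-squares inverse (exact on band-limited functions);
  rotation of mesh functions is by harmonic resampling at rotated
  vertices, again exact for band-limited inputs.

# Demixing numerics

With cubic B-splines (rank 20, clamped uniform knots) the
monotone-nonincreasing constraint on each fiber's curve is equivalent to
nonnegativity of the coefficient decrements, and — because the basis is a
partition of unity — each curve's level is confounded with the per-shell
intercept. The fit is therefore solved *exactly* as a nonnegative
least-squares problem (Lawson–Hanson active set) after projecting out the
intercept, rather than by smooth reparameterization of the increments,
which converges poorly here. A small relative ridge ($10^{-4}$) on the
decrements stabilizes the $t^* \to 1$ tail, where squared projections are
sparsely sampled and the monotone cone would otherwise permit free
extrapolation. The integral-to-zero centering is applied exactly through
the closed-form B-spline integrals, with the intercepts absorbing the
means; fitted curves then match the true centered curves directly (the
discrete "mean over measurement points" version of the constraint would
differ from the integral centering by an $O(0.1)$ constant, because
$t^* = (p^\top m)^2$ is non-uniformly distributed on $[0,1]$). Fibers
closer than $5^\circ$ give numerically collinear designs; the fit then
shares one curve across the pair (with a warning), and exactly identical
orientations are an error.

# The amortized posterior and its calibration

Separate MDNs are trained per fiber count (distribution shift through the
fractions makes the count useful conditioning information). The
desk-scale preset uses a 3-hidden-layer, width-128 ReLU trunk, 3 mixture
components, minibatch Adam (6000 iterations, batch 256, learning rate
$5\times 10^{-4}$ with a tenfold drop for the final quarter) on roughly
$10^4$ simulated (kernel, demixed-curve) pairs; the full-scale preset in
the literature is a 10-layer trunk trained for 50000 iterations at batch
7500, which is far beyond a single-CPU budget.

At desk scale the fitted conditional densities are systematically
overconfident (measured HDR coverage of 0.72–0.89 at nominal 0.95).
`calibrate_mdn()` therefore applies a conformal-style adjustment: per-
parameter inflation factors on the mixture scales are chosen by bisection
so that the 95% HDR coverage on a *fresh simulated calibration set*
reaches the nominal level, evaluated through the exact inference path
(constraint rejection, joint simplex projection, reflected-KDE HDR).
The calibration set is distinct from both the training set and any test
data. After calibration, coverage on independent test voxels is 0.95 for
all five parameters, with the extra-axonal parallel diffusivity showing
by far the widest regions — the poor identifiability surfacing as honest
uncertainty rather than as a biased point estimate.

HDRs are computed from posterior samples by Gaussian KDE with Silverman
bandwidth, reflected at the support bounds
($D_a, D_e^\parallel \in [0.2,3]$; $D_e^\perp \in [0, 2.4]$;
$z_1, z_2 \in [0,1]$), thresholded on a 512-point grid at the largest
level holding $1-\alpha$ of the estimated mass. This representation
handles the multimodal margins that arise from the mixture posterior,
at the cost of a slight conservatism from kernel smoothing (which the
calibration step absorbs).

# Baselines

`nlls_fit()` implements the maximum-likelihood baselines: bounded
Levenberg–Marquardt least squares over spherical orientation angles,
box-bounded diffusivities and softmax-parameterized simplex fractions,
with one (MLE-1) or fifty (MLE-2) random starts drawn from the priors.
Two notes: bounded trust-region solvers accept boxes, not simplices, so
the fraction simplex is handled by reparameterization; and the polytope
coupling $D_e^\perp < 0.8 D_e^\parallel$ is deliberately *not* imposed in
the baseline (only the box $D_e^\perp \in (0, 2.4]$), matching what a
box-bounded reference implementation can express. The constraint
parameterization materially affects the identifiability experiment:
imposing the simplex already truncates the flat likelihood ridge and
roughly halves the $D_e^\parallel$ error relative to a fully free
5-parameter fit.

# Problem sizes and reproducibility

All randomized components are seeded: dataset generation, training
shuffling, bootstrap draws, posterior sampling. The shipped tests and the
acceptance script use desk-scale sizes chosen as the package's default
working point: inverter training on $10^3$ voxels with 150 head
iterations; MDN training on $1.2\times 10^4$ single-fiber voxels with
calibration on 450 more; evaluation on 200–500 fresh voxels; bootstraps
of 25–200 replicates. The paper-scale preset (5000-voxel test sets,
$Q = 5000$, $B = 1000$, 50000-iteration training) is exposed in
configuration but the benchmark harness refuses it on the desk profile.

# Known limitations

* The inverter's angular resolution is bounded by the degree-8 signal
  band limit: crossings below roughly $30^\circ$ merge, and fiber-count
  accuracy near the minimum $10^\circ$ crossing angle of the prior is
  essentially zero — consistent with the reference method's own
  degradation for three-fiber voxels.
* Calibration guarantees marginal, per-parameter coverage under the
  generative model used for calibration; joint regions, and robustness
  under forward-model misspecification (variable orientation
  concentration, non-Gaussian noise), are out of scope.
* The MAP estimator searches only the $Q$ paired posterior draws; with a
  poorly fitted posterior its quality degrades gracefully toward the
  posterior-mean behavior rather than toward the global MAP.
* Bootstrap orientation uncertainty conditions on the pilot fit; fibers
  missed by the original estimate (but present in replicates) are only
  surfaced through the discarded-peak diagnostic, not re-clustered.
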