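---
title: "Diffusion microstructure imaging of acute stroke: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion microstructure imaging of acute stroke: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmipipe)
```

## The signal model

`dmipipe` analyses diffusion-weighted MRI of acute ischemic stroke with the
three-compartment "standard model" of white matter. Each voxel mixes

* an **intra-axonal stick**: water moves only along the axon direction $n$,
  with axial diffusivity $D_{a,i}$;
* an **extra-axonal zeppelin**: an axially symmetric tensor with axial
  diffusivity $D_{a,e}$ and radial diffusivity $D_{r,e}$;
* a **free-water ball** (CSF and perivascular fluid): isotropic diffusion
  with diffusivity fixed at $D_{csf} = 3\,\mu m^2/ms$.

For a gradient direction $g$ and b-value $b$ (internally ms/µm², so that
$b \cdot D$ is dimensionless; 1000 s/mm² = 1 ms/µm²) a single coherent fiber
gives

$$
S(b, g) = v_i\, e^{-b D_{a,i} (g \cdot n)^2}
        + v_e\, e^{-b D_{r,e} - b (D_{a,e} - D_{r,e})(g \cdot n)^2}
        + v_c\, e^{-3 b},
$$

with volume fractions $v_i + v_e + v_c = 1$ and $S(0) = 1$. Compartments are
assumed non-exchanging and diffusion-time dependence is neglected; T1/T2
compartment weighting is not modelled.

Real voxels contain dispersed fiber populations. The mesostructure nuisance
is modelled as a Watson orientation distribution
$W(n) \propto e^{\kappa (\mu \cdot n)^2}$ with mean direction $\mu$ and
concentration $\kappa$ ($\kappa = 0$ uniform, $\kappa \to \infty$ coherent).
`dispersed_signal()` computes the spherical convolution of the single-fiber
kernel with this distribution.

### Numerical evaluation of the convolution

Because both kernel and distribution are axially symmetric, the convolution
collapses (Funk–Hecke) to a one-dimensional Legendre series:

$$
S_\kappa(b, g) = \sum_{\ell \text{ even}} c_\ell(b)\, w_\ell(\kappa)\,
P_\ell(g \cdot \mu),
$$

where $c_\ell$ are the Legendre series coefficients of the kernel (computed
by 64-node Gauss–Legendre quadrature) and
$w_\ell(\kappa) = E[P_\ell(t)]$ under the Watson axis marginal
$p(t) \propto e^{\kappa t^2}$ on $[-1, 1]$. The series is truncated at
$\ell = 20$; for the largest attenuation the model admits
($bD = 6$) the truncation error is about $10^{-6}$. The Watson means use
200-node Gauss–Legendre quadrature for $\kappa \le 400$ and, beyond that, a
Gauss–Laguerre rule after the substitution $u = \kappa(1 - t^2)$, which
resolves the boundary layer at $t = \pm 1$ for arbitrarily large $\kappa$.
This is why the implementation reproduces the coherent single-fiber limit to
better than $10^{-4}$ even at $\kappa = 10^6$ — a fixed point grid on the
sphere cannot do that, which is the reason this semi-analytic quadrature was
chosen over a Lebedev-style grid. Both quadrature orders are arguments of
`dispersed_signal()` and the limit behaviour is covered by tests.

## Rotation-invariant features

Estimating six parameters per voxel from a fast clinical acquisition is
ill-posed voxel-by-voxel in the raw signal domain, and raw signals depend on
the unknown fiber geometry. The pipeline therefore reduces each voxel to
three features that are invariant under rotations of the subject and — for
the spherical means — under changes of fiber dispersion:

* `f0_inner`: spherical-mean signal on the inner radial bin,
* `f0_outer`: spherical-mean signal on the outer radial bin,
* `p2`: the order-2 rotational power $\sqrt{\sum_m c_{2m}^2}$ of a real
  spherical-harmonic fit on the outer bin,

all normalized by the voxel's mean $b=0$ signal. Restricting to
spherical-harmonic order 2 is deliberate: higher orders are too noisy at
this acquisition quality, and order ≤ 2 on two radial bins yields exactly
three independent features — fewer than the five free model parameters, so
some posterior ambiguity is irreducible (see *Limitations*).

Conventions (fixed and applied identically at training and inference):
orthonormal real spherical harmonics; the two shells of the two-shell
protocol are the radial bins, while the hexagonal q-ball protocol is split
at $b = 1$ ms/µm²; `p2` uses the outer bin only, where anisotropy encoding
is strongest. Invariance under joint rotation of the gradient table is exact
by construction (each SH order transforms orthogonally), and is verified to
$10^{-6}$ under 20 random rotations in the test suite.

## The simulation-trained Bayesian estimator

Rather than fitting the model per voxel, a regressor is trained on simulated
data to approximate the Bayesian posterior mean of the parameters given the
features:

1. **Prior** (`prior_config()`): flat Dirichlet on the fraction simplex;
   $D_{a,i}, D_{a,e} \sim U[0, 3]$, $D_{r,e} \sim U[0, 1.5]$ µm²/ms with
   rejection under the branch constraint
   $D_{a,i} > D_{a,e} + 2 D_{r,e}$ (which resolves a known degeneracy of the
   standard model for single-diffusion-encoding data); Watson $\kappa$
   log-uniform on $[0.25, 64]$ with a 15 % atom at exactly 0 and uniform
   random mean directions (mesostructure nuisance); SNR uniform on
   $[15, 60]$. The prior is generic — deliberately *not* adapted to stroke.
2. **Simulation**: for each prior draw, noiseless signals on the target
   scheme, Rician corruption at the drawn SNR
   ($S' = \sqrt{(S + n_1)^2 + n_2^2}$, $n_i \sim N(0, s_0/\mathrm{SNR})$,
   SNR defined at $b = 0$), then the same feature computation used at
   inference time.
3. **Regression** (`fit_regressor()`): each of the six parameters is
   regressed on the full cubic expansion (20 monomials) of the standardized
   feature triple, with a ridge penalty of $10^{-6}$ purely as a
   conditioning safeguard. Default training size is 20 000 samples
   (1000 samples per coefficient).
4. **Prediction** (`predict_maps()`): raw outputs are clipped — fractions to
   $[0, 1]$ and renormalized to the simplex, diffusivities to $[0, 3]$. An
   estimator stores the scheme it was trained for and refuses volumes
   acquired differently.

The slow reference the regressor approximates is implemented as
`posterior_mean_oracle()`: an importance-sampling posterior mean over prior
samples with a Gaussian kernel in feature space, whose scale is measured
empirically from repeated noisy simulations (`estimate_feature_noise()`).
The acceptance surface of the estimator is *agreement with this oracle*
(mean absolute deviation below 0.05 for fractions and 0.15 µm²/ms for
diffusivities on held-out noisy simulations), **not** unbiased truth
recovery — with three features and five free parameters the posterior mean
is necessarily biased toward the prior in weakly identified directions.

## Conventional DWI contrasts

`compute_adc()` implements the clinical apparent diffusion coefficient from
the $b = 0$ and $b = 1$ ms/µm² frames,
$\mathrm{ADC} = -\ln(\bar S_{b}/\bar S_0)/b$, averaging over directions
before the logarithm (trace-weighted convention). Voxels with non-positive
ratios are excluded rather than clamped. `mean_dwi()` provides the averaged
high-b image ($b \ge 1.8$ ms/µm² by default). The hexagonal q-ball preset
has no shell at exactly $b = 1$ (its shells sit at 2/3, 4/3 and 2), so ADC
on that protocol must be retargeted explicitly (`b_target = 4/3`).

## Lesion analysis

Infarct-core segmentation is threshold-based with the convention that
*lesion = value below threshold*, both for ADC (the 0.620 µm²/ms literature
guide) and for the primary DMI contrast $D_{a,i}$. Evaluation pools voxels
across subjects and computes the exact empirical ROC: every observed value
(plus $\pm\infty$) is a candidate threshold, AUC is the trapezoid integral
— identical to the pairwise concordance probability with ties counted ½ —
and the operating point maximizes Youden's $J =$ sensitivity $+$
specificity $- 1$, with ties broken toward the lower (more specific)
threshold. Four ground-truth variants are evaluated pairwise: the DMI-based
mask, the DWI-based mask, their intersection and their union. Contralateral
reference regions are produced by an exact grid flip across the x midline
(no registration — the phantom is midline-aligned by construction) with
optional CSF clipping, and descriptive statistics report mean and 5th/95th
percentiles (linear-interpolation convention, R type 7).

## The digital stroke phantom

Patient data cannot be redistributed, so `phantom_config()` /
`phantom_dataset()` generate a fully synthetic study: a spherical brain
(radius 20 voxels on a 48³ grid) with a 2-voxel CSF rim, a 4-voxel cortical
gray-matter ribbon, a white-matter core, a central CSF ventricle, and a
spherical lesion (radius 5 voxels ≈ 5.9 mL at the default 1.5×1.5×5 mm
voxels, matching a typical small MCA infarct) offset into one hemisphere.
Default tissue parameters are *conventions*, not measured values:

| tissue | $v_i$ | $v_e$ | $v_c$ | $D_{a,i}$ | $D_{a,e}$ | $D_{r,e}$ | $\kappa$ |
|--------|------:|------:|------:|----------:|----------:|----------:|---------:|
| white matter | 0.45 | 0.45 | 0.10 | 2.4 | 1.2 | 0.5 | 64 |
| gray matter  | 0.35 | 0.55 | 0.10 | 2.0 | 1.0 | 0.5 | 4 |
| CSF          | 0    | 0    | 1    | –   | –   | –   | – |
| lesion       | 0.65 | 0.30 | 0.05 | 1.4 | 0.7 | 0.3 | 64 |

They encode the qualitative acute-stroke pattern — all diffusivities
reduced (axial intra-axonal most strongly), intra-axonal fraction up,
extra-axonal and free-water fractions down — and place the analytic ADC at
roughly 0.74 (WM), 0.65 (GM) and 0.45 (lesion) µm²/ms around the 0.620
clinical guide, with the $D_{a,i}$ contrast straddling 2 µm²/ms. A
one-voxel partial-volume layer at every tissue boundary mixes the two
adjacent tissues 50/50 so that evaluation sees genuinely ambiguous voxels.
Rician noise is added at SNR 30 (at $b=0$) by default. Geometry and truth
masks depend only on the configuration; the noise depends only on the seed,
so truth is reproducible independently of the noise realization.

What the phantom does **not** emulate: real anatomy and registration error,
eddy-current/motion artifacts, Gibbs ringing, spatially varying coil
sensitivity, leukoencephalopathy-like confounds, and rater subjectivity
(synthetic "raters" are morphological erosions/dilations of the truth).
Passing phantom tests therefore demonstrates internal consistency of the
pipeline under its own noise model, not clinical performance.

### Problem sizes

Defaults were chosen so a complete study runs interactively on one CPU:
20 000 training samples, a 48³ phantom (≈ 33 500 brain voxels, 71 frames),
and 10⁵ Monte-Carlo samples for the posterior-mean oracle. The full test
suite and the acceptance script each run in about a minute.

## Design decisions and degenerate inputs

* b-values ≤ 50 s/mm² are classed as $b=0$ (vendor rounding tolerance).
* The hexagonal q-ball direction set is a deterministic FCC-lattice
  construction (28 innermost non-origin points, ordered by radius then
  lexicographically, scaled to max $b = 2$); since the estimator is trained
  per scheme, only self-consistency matters, not the exact point set.
* Feature computation drops voxels whose mean $b=0$ signal is not positive
  and removes them from the processing mask instead of emitting NaNs.
* If all importance weights of the posterior-mean oracle underflow, the
  kernel width is doubled with a warning rather than failing.
* Fractions predicted outside the simplex are clipped then renormalized; an
  all-zero row falls back to the uninformative (⅓, ⅓, ⅓).
* ROC ties in Youden's $J$ resolve to the lowest threshold; the threshold
  sweep uses all observed values, avoiding any grid-resolution choice.
* All randomness (prior, training noise, phantom noise) flows from explicit
  integer seeds; identical seeds give bit-identical estimator files and
  phantom volumes.

## Limitations

The feature set carries three numbers per voxel against five free model
parameters, so the posterior is partly prior-driven; parameter maps show
plausible but biased contrast (e.g. white-matter $D_{a,i}$ of 2.4 µm²/ms is
typically mapped near 2.6). In voxels that are almost pure free water the
intra-axonal diffusivity is unidentifiable *in principle* — its posterior
reverts to the prior mean and fluctuates with noise. Combined with the
deliberate partial-volume layer this bounds the pooled lesion-vs-rest
discriminability of $D_{a,i}$ on the default phantom: the importance-
sampling oracle shows the same CSF/boundary overlap as the polynomial
regressor, i.e. the limit is information-theoretic, not an implementation
artifact. The ROC machinery itself is exact (verified against brute-force
concordance), and the estimator matches its Bayesian reference within the
stated tolerances; claims about clinical discriminability must come from
clinical data, which this package deliberately does not ship.
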