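---
title: "Recovering metal K-edge shifts from simulated serial crystallography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering metal K-edge shifts from simulated serial crystallography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfxspread)
```

## The problem

The oxidation state of a metal atom in a protein leaves a spectroscopic
fingerprint in diffraction data: the atom's K absorption edge moves by one
to two electron volts when the atom is oxidized or reduced, and with it the
wavelength-dependent anomalous corrections $\Delta f'(E)$ and
$\Delta f''(E)$ to its scattering factor. Spatially resolved anomalous
dispersion (SPREAD) aims to read this shift out of serial femtosecond
crystallography (SFX) data: thousands of still diffraction images, one
destructive X-ray pulse per micro-crystal, each with unknown orientation,
illuminated volume and slightly different unit cell. The canonical target is
manganese in photosystem II with a polychromatic beam centered near
6550 eV.

`sfxspread` builds the whole problem at desk scale on synthetic data: a
pixel-level forward simulator of diffraction-spot "shoeboxes", a classical
maximum-likelihood solver for the edge shift, and a physics-informed
variational autoencoder (P-VAE) that additionally learns a penalized
correction to a deliberately mis-specified forward model and returns a
posterior distribution rather than a point estimate.

## Forward model

The structure factor of reflection $\mathbf h$ at photon energy $E$ is

$$F_{\mathbf h}(E) \;=\; \sum_m o_m\,
  \bigl[f^0_m(|Q|) + \Delta f'_m(E) + i\,\Delta f''_m(E)\bigr]\,
  e^{2\pi i\, \mathbf r_m \cdot \mathbf h}\,
  e^{-B_m |Q|^2/4},$$

with occupancies $o_m$, fractional coordinates $\mathbf r_m$, isotropic
B factors $B_m$, and the d-spacing convention $|Q| = 1/d_{\mathbf h}$ (note
the B-factor exponent differs by $(2\pi)^2$ between conventions; the whole
package uses $1/d$). Non-anomalous factors $f^0$ come from bundled
Cromer–Mann 4-Gaussian coefficients for H, C, N, O, S, Mn and Fe. Only
atoms with an attached anomalous curve contribute $\Delta f'$,
$\Delta f''$; energy, not wavelength, is the canonical spectral variable
($\lambda[\unicode{x212B}] = 12398.42/E[\mathrm{eV}]$ appears only in the
geometry layer).

### The anomalous curve and the Kramers–Kronig transform

No published tabulation is bundled. The reference Mn-like curve is
synthetic: $\Delta f''$ is a smoothed absorption step (logistic width
1.2 eV, plateau step 3.35 e) plus a white-line Gaussian (amplitude 2.3 e,
3.5 eV above the edge, 2 eV sd) on a 6400–6700 eV grid at 1 eV spacing,
and $\Delta f'$ is derived from it by the package's own finite-grid
Kramers–Kronig transform, so the pair is dispersion-consistent by
construction. The transform implements the near-edge dispersion relation
$f'(E) = \pi^{-1}\,\mathrm{PV}\!\int f''(E')/(E - E')\,dE'$ with the
principal value handled by omitting the singular grid point under
trapezoid end weights. That choice makes the transform exactly linear and
translation-equivariant on the grid interior; its absolute accuracy
degrades near the grid edges where tail contributions are truncated, which
is why the accuracy oracle (a Lorentzian against its closed-form Hilbert
pair) is evaluated at least three linewidths away from the edges. An
oxidation-state change is modeled as a rigid translation of the whole
curve (`shift_edge`), which preserves the Kramers–Kronig consistency
automatically.

### Still shots and shoeboxes

A still shot has a Haar-random orientation $U$, a log-normal scale $g$
(illuminated volume times pulse intensity), slightly jittered cell
lengths, and — in the default *explicit* mosaic mode — `n_domains` = 24
mosaic-domain rotations drawn from an isotropic 1.0 mrad distribution.
Spot intensity sums incoherently over domains and over a 30-channel
Gaussian spectrum (FWHM 30 eV, centered 6550 eV, spanning ±45 eV). The
lattice interference profile of a coherent block of $N_a N_b N_c$ cells is
approximated by an isotropic Gaussian of the reciprocal-space offset from
the Bragg condition, peak $(N_aN_bN_c)^2$ and width
$\sigma_r = 1/(2\pi \bar N \bar a)$ (geometric means); this keeps the
pixel kernel cheap and differentiable while retaining size broadening.

The *smooth* mosaic mode is the analytic limit of the domain sum, and it
is anisotropic on purpose: mosaic rotations preserve $|q|$, so they smear
the reciprocal peak only perpendicular to $\hat q$. The smooth kernel
therefore keeps the domain-size width $\sigma_r$ along $\hat q$ — the
direction that selects which spectrum channels diffract — and widens only
the tangential plane to
$\sigma_t^2 = \sigma_r^2 + (|q|\,\Delta_{\mathrm{mos}})^2$, with amplitude
scaled by $\sigma_r^2/\sigma_t^2$ so the integrated intensity is
preserved. An isotropic approximation here measurably biases the
recovered edge shift, because it leaks spectral acceptance width.

Expected pixel counts are
$g \sum_E w_E\,|F(E)|^2 \sum_d \tfrac{1}{n_d}\,\mathrm{profile}
(\|q_p(E) - q_d\|)\,\Omega_p\,\Phi + b$,
with per-pixel solid angle $\Omega_p$ (inverse-square with obliquity;
polarization omitted, absorbed by the per-shot scale at this scale of
realism), flux constant $\Phi$ and flat background $b$; observed counts
are independent Poisson draws. Shoeboxes are fixed 9×9 pixel blocks
centered on the predicted impact pixel (half-open integer pixel
coordinates, fast axis first), clipped at the panel edge. Shot metadata
carries DIALS-style *estimates*: the true orientation composed with a
0.5 mrad random rotation and the true scale times a 5% log-normal factor;
the exact per-shot cell. The ground truth is returned in a sidecar object
that no inference stage reads.

One RNG stream seeded once per dataset, with draws in a fixed order
(shots, then domains, then pixels), makes every dataset bit-reproducible;
the dataset container is a serialized bundle with text exports (CSV
reflection table, SHELX-style hkl, 3-column curve text).

## Classical inversion

The baseline fit maximizes the Poisson likelihood of every shoebox pixel
over the edge shift $\Delta E$ (applied to the reference curve, which
keeps the KK coupling exact), per-shot scales and per-shoebox flat
backgrounds, starting from the metadata estimates. Because $|F(E)|^2$
splits as $|A + c(E)M|^2$ with $A, M$ fixed by geometry and
$c = \Delta f' + i \Delta f''$, evaluating a new shift costs one curve
interpolation — the geometric pixel kernels are precomputed once per
dataset.

Rather than one joint quasi-Newton run over thousands of parameters, the
solver uses variable projection: scales and backgrounds are one-parameter
convex Poisson regressions solved exactly by damped Fisher scoring at
each candidate shift, and the profiled objective is minimized by a coarse
scan plus Brent search. The profile solve is exactly what the
profile-likelihood interval needs anyway, the accepted-iterate loss trace
is non-increasing by construction, and the full analytic gradient is kept
for convergence checks (noise-free data generated at the initial
parameters returns at iteration zero).

Two per-shot geometric nuisances are then refined (and the shift
re-optimized): a small-angle orientation correction around the metadata
estimate, bounded at 5 mrad, and a log multiplier on the tangential
profile width. The width refinement exists because 24 explicit domain
draws realize a random per-shot effective mosaic width that a fixed
smooth model mis-states; both corrections are refined per shot by
Nelder–Mead on the shot's pixel likelihood with the compiled kernel.

Uncertainty comes either from the profile likelihood (deviance against
the $\chi^2_1$ quantile) or a parametric bootstrap (counts redrawn from
the fitted intensities, local refits, percentile interval). Bootstrap
coverage is a property of a well-specified model, and the suite verifies
it in matched-generator mode. A free-per-channel mode
(`fit_curve_free`) releases $\Delta f''$ on a coarse knot grid with a
second-difference smoothness penalty and re-derives $\Delta f'$ by the KK
transform at every step; it is the exploratory alternative to the scalar
shift, not the headline estimator.

## The P-VAE

The hierarchical latent structure, all standardized so priors are
$\mathcal N(0,1)$:

* dataset level — the edge shift, prior sd 3 eV, with a *free*
  (non-amortized) Gaussian posterior: one global quantity gains nothing
  from amortization except noise;
* image level — per-shot log-scale around the metadata estimate, prior
  sd 0.1;
* shoebox level — per-shoebox log-background around the perimeter
  estimate, prior sd 0.5.

The encoder is a one-hidden-layer (16 tanh units) network on the
log1p-transformed 9×9 counts plus normalized metadata — resolution,
detector radius, integrated counts, perimeter background, and
deliberately *not* the raw Miller indices, which could let metadata
over-explain the data. Two Gaussian heads emit the shoebox-level
posterior and a per-shoebox contribution to the image-level posterior;
contributions are pooled across a shot by natural-parameter averaging.
Output heads are zero-initialized, so the untrained posterior equals the
prior exactly.

The generator is the same physics forward model the classical fit uses,
composed with a learned multiplicative correction
$\exp\{\theta^\top \phi(u, v)\}$ in log-intensity space, where $\phi$ is
a five-term low-order polynomial basis in panel coordinates: invertible,
positive, exactly the identity at $\theta = 0$, and penalized by
$w\,\|\theta\|^2$. The loss is the single-sample reparameterized negative
ELBO plus that penalty; KL terms are closed-form diagonal-Gaussian
expressions. All gradients — through the Poisson reconstruction, the
curve interpolation, the pooling, and the encoder — are derived by hand
and verified against central finite differences in the test suite; with
no automatic differentiation in the stack this is the price of admission,
and the gradient test is the package's most important single check.

Training is full-batch Adam (the datasets are desk-scale; one batch is
one epoch and keeps the bookkeeping deterministic) with a fresh
reparameterization draw per epoch, a step learning-rate decay (×0.2
after 60%, ×0.02 after 85% of epochs) and Polyak averaging of the final
15% of epochs — single-sample ELBO gradients otherwise leave parameters
jittering at a noise floor rather than settling. A 10% shot holdout is
tracked by its mean per-pixel deviance. The conjugate linear-Gaussian toy
(`optimize_gaussian_toy`), whose evidence is analytic and whose optimal
posterior is exact, validates the ELBO machinery end to end: the
optimized bound must meet the evidence from below.

Two evaluation conventions matter and are worth stating precisely:

* *Correction efficacy* is measured on held-out shots with per-shot
  nuisances re-solved exactly for both the corrected and uncorrected
  models. Amortized-encoder nuisances on unseen shots carry enough noise
  to drown a ±10% gain field; the refit comparison isolates the
  correction itself and treats both models identically.
* *Penalty dominance* (a huge $w$ must pin the correction at the
  identity) is checked under the fully well-specified generator (smooth
  mosaic mode, exact orientation metadata). Under the default explicit-
  domain generator the forward model carries a persistent, deliberate
  misfit that the correction genuinely absorbs — a real residual signal,
  not a failure of the penalty — so the identity limit is only a theorem
  when no model error of any kind is present.

## What the generator emulates, and what it does not

The synthetic conditions are: orthorhombic 15×18×22 Å cell, P1, six
atoms with one Mn-like anomalous site, resolution cut 2.3 Å, a
512×512-pixel flat panel at 60 mm with 0.2 mm pixels, 200 shots by
default, up to 16 reflections per shot, flat background 2 counts/pixel,
flux calibrated once so strong spots peak at a few hundred counts.
Omitted on purpose: multi-panel geometry, detector point spread and
parallax, polarization, air scatter, beam divergence, SASE spectral
spikes (the spectrum is a smooth Gaussian), space-group symmetry,
solvent scattering, spot finding and indexing (Miller indices are
assigned by construction, as DIALS would provide them). Passing tests
therefore demonstrate correctness of the method under these idealized
conditions, not performance on real SFX data — in particular, real
spectra fluctuate shot to shot and real mosaicity is far richer than a
Gaussian misorientation model.

Problem sizes in the test suite are scaled to the property being tested:
full 200-shot datasets over ten seeds for the headline recovery check
(bias and RMSE of the recovered shift), 60-shot datasets for the
P-VAE/classical cross-checks and correction efficacy, 16–30 shots for
interval-coverage and calibration simulations, and toy designs of a few
shots for oracle and gradient checks.

## Numerical choices and degenerate inputs

* Fractional coordinates are reduced mod 1 at construction; phases never
  change.
* Curve evaluation outside the tabulated grid is an error that names the
  offending atom; edge shifts beyond the grid span are rejected.
* The acceptance shell for reflection prediction is
  `shell_mult` (default 3) times the combined width
  $\sqrt{\sigma_r^2 + (|q| \Delta_{\mathrm{mos}})^2}$; widening it can
  only grow the predicted set.
* Expected-count floors (1e-12) guard the Poisson log; a nonpositive
  model intensity is an error, not a silent clamp.
* Backgrounds are initialized from the shoebox perimeter mean, floored at
  0.05 counts.
* The inner Fisher-scoring steps are clipped at ±1 in log space and
  halved while the objective would increase, so the nuisance solve is
  monotone even far from the optimum.
* Ties in the Brent bracket default toward the coarse-scan minimum; the
  scan grid always contains the initial shift.
* An integer-grid-step edge shift makes the generator's tabulated curve
  and the solver's interpolated curve coincide exactly; fractional shifts
  differ at second order in the grid spacing (double interpolation),
  which is visible only in exact fixed-point tests, not in recovery.

## Known limitations

* One anomalous curve is fitted; multiple species with distinct curves
  would need the decomposition extended beyond a single $c(E) M$ term.
* The image-level latent hierarchy omits an orientation-jitter latent;
  orientation error is handled by the classical refinement stage instead,
  and inside the P-VAE it surfaces as residual misfit.
* Variational posteriors are diagonal Gaussians and may under-cover; the
  calibration check in the suite is deliberately loose (a binomial bound
  on 90% intervals covering a true null).
* The correction basis is a five-term panel polynomial — enough for
  smooth gain fields, not for per-pixel defects.
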