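# sfxspread

Spatially resolved anomalous dispersion (SPREAD) at desk scale: simulate
serial femtosecond crystallography (SFX) diffraction-spot shoeboxes with
wavelength-dependent anomalous scattering, then recover the K-edge shift
of an anomalous metal site — the fingerprint of its oxidation state — by
classical maximum likelihood and by a physics-informed variational
autoencoder (P-VAE) that also corrects a mis-specified forward model and
quantifies uncertainty.

## The science in one paragraph

A metal atom's K absorption edge moves by ~1–2 eV with oxidation state,
and with it the anomalous corrections Δf′(E), Δf″(E) to its scattering
factor. In SFX, thousands of micro-crystals are each imaged once with a
polychromatic XFEL pulse (here centered at 6550 eV, near the Mn edge);
every still shot has unknown orientation, scale and slightly different
cell. The structure factor of reflection **h** at energy E is

    F_h(E) = Σ_m o_m [f⁰_m(|Q|) + Δf′_m(E) + i Δf″_m(E)]
                 · exp(2πi r_m·h) · exp(−B_m |Q|²/4),     |Q| = 1/d_h

and measured spot intensity is ∝ |F_h(E)|², summed incoherently over
mosaic domains and spectrum channels. Δf′ and Δf″ are coupled by the
Kramers–Kronig dispersion relation, so a single scalar — the edge shift
ΔE applied to a reference curve — parameterizes the chemistry. The
package simulates pixel-level shoeboxes under these physics (with Poisson
noise, mosaic domains, per-shot nuisances and DIALS-style imperfect
metadata), then inverts them.

## Worked example

```r
library(sfxspread)

cfg <- default_config()
cfg$crystal$edge_shift_true <- 2   # emulate an oxidized Mn site: +2 eV
cfg$dataset$n_shots <- 60

sim <- simulate_dataset(cfg, seed = 1)
print(sim$data)
#> <spread_dataset> 60 shots, 958 shoeboxes, seed 1

fit <- fit_edge_shift(build_design(sim$data), config = cfg)
fit$edge_shift_ci <- edge_shift_interval(fit, "profile", level = 0.9)
print(fit)
#> <spread_fit> edge shift +1.682 eV, NLL 158056.33, converged
#>   CI [+1.378, +1.893] eV

pv <- train_pvae(build_design(sim$data), cfg, seed = 2)
print(pv)
#> <pvae_fit> edge-shift posterior +1.853 +/- 0.685 eV (300 epochs)
```

The injected truth is +2 eV. The classical fit profiles the Poisson
likelihood of all ~78,000 shoebox pixels over the edge shift, per-shot
scales and per-shoebox backgrounds (starting from the imperfect metadata
estimates) and reports a point estimate with a 90% profile-likelihood
interval; at this reduced 60-shot scale the estimate sits within a few
tenths of an eV of truth (at the default 200 shots it tightens further —
the test suite measures bias and RMSE over ten seeds). The P-VAE returns
a posterior distribution over the shift whose mean agrees with the
classical estimate and whose spread is the uncertainty statement the
classical point estimate lacks.

Model-error experiments inject a smooth multiplicative detector gain
field, a background gradient, or a mosaic misspecification into the
generator (`inject_model_error`); the P-VAE's learned log-multiplicative
correction — identity at zero parameters, penalized for deviating —
lowers held-out per-pixel deviance under the injected gain field and
collapses to the identity when the penalty dominates.

A CLI wraps the same functions
(`Rscript inst/cli/spread.R simulate|fit|pvae|kk|report ...`), and
`run_experiment()` drives simulate → fit → P-VAE → JSON report + plots
with every artifact stamped by the configuration hash; identical config
and seed reproduce every output byte for byte.

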