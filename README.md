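# nucleostruct

Quantification pipelines for nucleolar structure and phase-separation
dynamics, with ground-truth simulators for every data type.

The nucleolus — the membrane-less organelle where ribosomal RNA is
transcribed — reorganizes when RNA polymerase I is inhibited: in
interphase cells the granular component (marked by NPM1) condenses into a
single round body, while cells that divide without Pol I activity fail to
reassemble a nucleolus and scatter their nucleolar proteins into dispersed
puncta. This package implements the three quantitative readouts used to
characterize these phenotypes, each driven by a synthetic-data generator
with known ground truth so the whole analysis chain is testable without
microscope data:

1. **FRAP fitting.** Whole-structure bleaches recover by nucleoplasmic
   exchange and are fit with a single exponential
   `F(t) = P (1 − exp(−t/τ))`. Half-structure bleaches additionally mix
   internally and are fit with a constrained double exponential
   `F(t) = P − A₁ exp(−t/τ₁) − A₂ exp(−t/τ₂)`, `P = A₁ + A₂`, holding τ₂
   fixed at the whole-bleach value so that the fast constant τ₁ isolates
   internal mixing. Percent recovery is `100 P`. Group comparison by
   Student's t test.
2. **Immunogold densitometry.** Two-pass detection of 12 nm then 6 nm
   gold particles with a scale-normalized Laplacian-of-Gaussian filter
   (σ = d / (2√2·pixel size)), characteristic-scale class assignment,
   exclusion zones around the large particles, and per-class densities in
   particles/nm² inside a nucleolar outline.
3. **Time-lapse morphometry.** Per-channel segmentation of nucleolar
   components in 3-channel movies (UBF/FBL/NPM1), nearest-centroid cell
   tracking, per-cell time series of puncta counts, NPM1 area and
   sphericity (circularity `4πA/P²` in 2-D, `π^{1/3}(6V)^{2/3}/S` in 3-D),
   population means with t-based 95% CIs, and rule-based classification of
   each cell as normal, condensed, or fragmented.

See `vignettes/nucleolar-quantification.Rmd` for the models, estimator
details and design decisions.

## Worked example

Recover the fast mixing constant from a simulated control-condition
half-FRAP ensemble, using the full whole-then-half constrained protocol:

```r
library(nucleostruct)

res <- frap_recovery_protocol(tau1 = 3.33, tau_whole = 25, n = 30,
                              seed_base = 0)
sprintf("tau2 fixed from whole fits: %.2f s", res$tau2_fixed)
#> "tau2 fixed from whole fits: 24.78 s"
sprintf("mean recovered tau1: %.3f s (true 3.33 s)", res$mean_tau1)
#> "mean recovered tau1: 3.345 s (true 3.33 s)"
```

Thirty whole-bleach curves (true τ = 25 s) are simulated and fit first;
their mean fitted constant (24.78 s) is injected as the fixed τ₂ of every
half-bleach fit, and the fast constant comes back within 0.5% of its
generating value. An inhibited-regime ensemble (τ₁ = 9.05 s) separates
cleanly from the control one:

```r
inh <- frap_recovery_protocol(tau1 = 9.05, tau_whole = 50, n = 30,
                              seed_base = 0, condition = "inhibited")
compare_groups(res$half_fits, inh$half_fits, field = "tau1")
#> <group_comparison> tau1: 3.345 +/- 0.209 (n=30) vs 9.099 +/- 0.712 (n=30); t=-42.464, p=2.189e-45
```

Detect immunogold particles on a synthetic electron micrograph and
compute densities inside the nucleolar outline:

```r
sim <- simulate_em_image(em_sim_params(seed = 1))   # 30 + 60 in-ROI particles
ps  <- detect_two_pass(sim$field)
particle_density(sim$field, ps)
#> <density_result> sim_em (control): 12nm 30 (6.31e-05/nm^2), 6nm 59 (0.000124/nm^2) in 4.76e+05 nm^2
```

All 30 large particles and 59 of 60 small ones are recovered (the counts
divided by the 4.76×10⁵ nm² outline area give the per-class densities).

End-to-end runs (simulate → analyze → summarize, with a resolved config
and manifest written beside the outputs) go through `run_pipeline()`, or
the thin CLI wrapper:

```sh
Rscript inst/cli/nucleostruct.R frap --out runs/demo --seed 1
```

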