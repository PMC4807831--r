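# washoutpet

Dose monitoring in hadron therapy relies on PET imaging of the β⁺ emitters
(mostly ¹¹C) produced by the beam, but the PET signal is degraded by
*biological washout*: transport of the radionuclides away from where they
were produced, on top of physical radioactive decay. `washoutpet`
implements an analysis pipeline for the point-source approach to measuring
washout in vivo: a ~1 µL deposit of a ¹¹C tracer is injected directly into
the tissue of interest and followed with a dynamic preclinical PET
acquisition, once in the living animal and once post mortem. Comparing the
two acquisitions separates the biological signal into two components.

## The model

After correcting the measured activity for physical decay
(A_meas(t) = C_bio(t) · A_phys(t)), the biological part of the point-source
signal is modelled as the product of two mono-exponential components:

    C_bio,alive(t) = exp(−λ_wash t) · exp(−λ_tiss t)
    C_bio,dead(t)  = exp(−λ_tiss t)

* the **tissular** component (rate λ_tiss) is passive, concentration-driven
  diffusion, the only transport left in non-perfused (dead) tissue;
* the **washout** component (rate λ_wash) is perfusion-driven clearance,
  present only in the living animal.

The dead-condition fit gives λ_tiss directly; because the alive curve is a
product of exponentials its fitted rate is the sum λ_tiss + λ_wash, so the
washout rate is recovered by subtraction and reported as a half-life
T½ = ln2/λ. The three-exponential (fast/medium/slow) washout
parameterization used in earlier radioactive-beam experiments is also
available (`fit_mizuno()`).

The package covers the full chain:

* **simulation** — seeded synthetic 4D studies: Gaussian point source
  (deposit spread ⊕ scanner PSF in quadrature), 25-frame dynamic protocol
  (10×30 s, 5×60 s, 10×300 s), physical ¹¹C decay, Poisson counting noise,
  lognormal inter-animal variability (`simulate_study()`);
* **extraction** — the 50%-of-first-frame-maximum ROI rule, mask
  propagation across frames, frame-averaged decay correction, FWHM
  measurement (`select_roi()`, `extract_tac()`, `measure_fwhm()`);
* **fitting** — frame-averaged single-exponential fits, alive/dead
  decomposition, constrained multi-exponential fits, group summaries
  (`fit_single_exponential()`, `decompose_washout()`, `summarize_group()`);
* **orchestration** — YAML-configured end-to-end runs writing NIfTI
  volumes, TAC CSVs, result tables, plots and a checksummed manifest
  (`run_pipeline()`).

## Worked example

Simulate a 4-animal brain study with Poisson noise and inter-animal
variability, then recover both half-lives through the full image pipeline:

```r
library(washoutpet)

res <- recover_tissue(preset_params("brain"), n_animals = 4, seed = 42,
                      noise = TRUE,
                      injection = injection_spec(activity = c(0.7e6, 1.1e6)))
res$animals[, c("animal_id", "halflife_tiss_hat", "halflife_wash_hat")]
#> # A tibble: 4 × 3
#>   animal_id halflife_tiss_hat halflife_wash_hat
#>       <int>             <dbl>             <dbl>
#> 1         1             2794.              286.
#> 2         2             2722.              335.
#> 3         3             2784.              271.
#> 4         4             2929.              334.

dplyr::bind_rows(
  summarize_group(res$animals$halflife_tiss_hat, "brain", "tissular"),
  summarize_group(res$animals$halflife_wash_hat, "brain", "washout"))
#> # A tibble: 2 × 5
#>   tissue component     n mean_halflife sd_halflife
#>   <chr>  <chr>     <int>         <dbl>       <dbl>
#> 1 brain  tissular      4         2807.        87.5
#> 2 brain  washout       4          307.        33.0
```

The generative group means here were a tissular half-life of 2878 s and a
washout half-life of 330 s; the recovered group means (2807 ± 88 s and
307 ± 33 s) scatter around them with the spread induced by the 10%
inter-animal coefficient of variation and counting noise. Ground truth per
animal is returned alongside (`lambda_tiss_true`, `lambda_wash_true`) for
recovery checks.

A whole configured run (volumes, masks, TACs, fits, summaries, plots,
manifest):

```r
run_pipeline(pipeline_config(tissue = "tumor", n_animals = 4, seed = 1),
             out_dir = "tumor_run")
```

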