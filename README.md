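# bcdgrad

Quantitative analysis of anterior morphogen gradient formation in the early
*Drosophila* embryo, from raw 3D confocal stacks to a fitted
reaction-diffusion model.

The *bicoid* (*bcd*) mRNA is deposited at the anterior pole of the egg and
translated into the Bicoid transcription factor, whose exponentially
decaying nuclear concentration gradient patterns the anterior-posterior
(AP) axis. This package implements the full measurement-and-modelling chain
used to study how that gradient forms:

1. **Single-molecule FISH particle calling.** Image stacks are realigned by
   slice-to-slice cross-correlation and converted to photon-equivalent
   units using a patch mean-variance gain fit. Each slice is filtered with
   a balanced difference-of-Gaussians kernel (center sigma 1.5 px, surround
   2.5 px), local maxima above a threshold of 150 become candidate
   particles, axial repeats ("shadows") are linked across z, and each
   candidate is fitted with an elliptical Gaussian
   `I(x,y) = offset + amplitude * G(x - x_c, y - y_c; r_x, r_y, theta)`
   (jointly with its neighbours when patches overlap). Accepted particles
   require 0.7 < r_x, r_y < 2.5 px, amplitude > offset and at least one
   shadow; particle intensity is `amplitude * r_x * r_y`.
2. **Spatial statistics.** Particles are projected onto the AP axis
   (fractional egg length x/L) and the cortex-depth coordinate d/L, giving
   binned count/intensity distributions, cumulative anterior fractions and
   per-stage totals.
3. **Nuclear gradient quantification.** Nuclei are segmented in 3D,
   depth attenuation is corrected with the uniform histone-RFP reference
   channel, autofluorescent background is estimated from nuclei at 85-95%
   EL, and `log(intensity) ~ x/L` fits over x/L in [0.1, 0.7] give the
   gradient amplitude and decay length (length constant, in EL units).
4. **Extended SDD model.** The synthesis-diffusion-degradation equation
   `dc/dt = D lap(c) - c/tau + rho` is integrated by forward Euler on a
   masked ellipsoid grid (10 um spacing, no-flux boundaries), with the
   source active only between two nuclear cycles and diffusion shut off
   late, and compared to measured profiles through a chi-square with a
   single global scale. An exhaustive grid search over
   (D, tau, timing) finds the best fit; a realistic extended source is
   compared against an anterior point source.
5. **Synthetic data with ground truth.** A seedable generator produces
   anterior-graded particle fields (wedge and cup geometries), rendered
   image stacks with Poisson noise and per-slice gain, two-channel nuclear
   stacks, and forward-simulated gradient series, so every stage is
   testable end to end without any external data.

## Worked example

```r
library(bcdgrad)

model <- reduced_embryo_model(stage = 12)        # blastoderm, cup geometry
particles <- sample_particles(model, 320, seed = 1)
rendered <- render_stack(particles, model,
                         render_spec(gain = seq(2.2, 2.8, length.out = 16),
                                     read_noise_sd = 3, seed = 2),
                         dims = c(200, 512, 16))

stack <- realign_stack(rendered$stack)
stack <- normalize_slices(stack, estimate_gains(stack, seed = 3))
detected <- detect_particles(stack)
proj <- project_particles(detected, known_registration(model, c(200, 512, 16)))

nrow(detected)
#> [1] 201
round(100 * intensity_fraction(proj, 0.2), 1)
#> [1] 94.4
median(detected$eccentricity)
#> [1] 0.01298
```

201 of the 320 rendered particles are recovered (dim single-transcript
particles near the detection threshold account for most misses), 94.4% of
the detected fluorescence lies in the anterior 20% of the egg, and detected
particles are nearly circular, as expected for diffraction-limited spots.

Fitting the reaction-diffusion model to a forward-simulated noisy gradient
series:

```r
geo <- sdd_geometry(300, 120, 20)
sources <- default_sources(geo, seed = 1, n_particles = 5000)
series <- simulate_gradient_series(sdd_params(D = 3.1, tau = 100),
                                   noise_fraction = 0.1, seed = 4,
                                   geometry = geo, sources = sources)
fit <- sdd_grid_search(series, geo, sources,
                       default_grids(D = c(1, 3.1, 8), tau = c(30, 100, 400)))
fit
#> <sdd_fit> 9 grid points (realistic source), best chi2 = 98.11
#>   best: D = 3.1 um^2/s, tau = 100 min, source n.c. 6-12, D off at 12
```

The search recovers the generating diffusion coefficient and degradation
lifetime at their grid points.

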