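# chargecloud

Charge-cloud simulation and subpixel interaction-position estimation for
edge-on ("deep") silicon photon-counting CT detectors.

## The problem

A deep silicon sensor presents a 500 μm thick wafer edge-on to the x-ray
beam and reads it out with a fine row of strip electrodes — here 51
strips at 12 μm pitch (10 μm electrodes), biased at 200 V.  A Compton
interaction deposits a few keV, the recoil electron liberates one
electron–hole pair per 3.6 eV, and the pairs drift and diffuse to the
electrodes.  Because diffusion grows with drift time, the charge cloud
collected on the strip plane is wider for interactions far from the
strips: the *shape* of the shared signal therefore encodes the
interaction position at far better than single-strip precision.

`chargecloud` simulates this chain end to end and implements the
estimator:

1. **Event generation** — photon energies from a filtered 140 kVp tube
   spectrum (Kramers continuum × 8.48 mm Al, 0.8 mm Be, 30 cm soft
   tissue), interaction types from silicon cross sections, recoil
   energies from the Klein–Nishina electron spectrum, origins uniform in
   the central pixel, and condensed-history electron tracks
   (CSDA-range power law R(T) = 0.0171 T^1.75 μm, 20 sub-deposits,
   optional Si-K fluorescence split).
2. **Charge transport** — per-carrier drift–diffusion time stepping
   (dt = 2 ns) in the uniform field E = V/d, with the Canali
   field-dependent mobility for drift and the Einstein relation
   D = (kT/e)·μ₀ for diffusion.
3. **Signal induction** — Shockley–Ramo theorem on a 2D weighting
   potential solved from Laplace's equation (reference electrode at 1,
   all others grounded) by a sparse direct solver; in the default
   endpoint mode the per-pair algebra reduces exactly to one full charge
   on the strip where the hole lands.
4. **Readout** — independent Gaussian electronic noise of σ = 0.22 keV
   per strip and a lowest threshold of 4σ = 0.88 keV.
5. **Position estimation** — per event, a Gaussian
   f(x) = a·exp(−(x−b)²/2c²) is least-squares fitted to the 51
   (strip centre, energy) points; Xe = b, and the width c is mapped to
   depth through a power-law calibration c_fit(y) = α·y^β + γ fitted on
   the simulated dataset, with out-of-range widths sent to the mean
   depth of such events.
6. **Resolution metrics** — PSFs (error histograms) with Gaussian-fit
   FWHM, and MTFs (|DFT| of the PSF) with the 5 % crossing frequency in
   lp/cm.

## Worked example

```r
library(chargecloud)

ds  <- generate_fixture_dataset(n_events = 200)
s   <- ds$signals[1, ]          # 8 keV recoil at X0 = -4.8 um, Y0 = 20 um
round(s[24:28], 3)
#> 0.000 1.282 6.710 0.000 0.000
fit <- fit_charge_cloud_gaussian(s, ds$geometry)
sprintf("a = %.2f keV, b = %.2f um, c = %.2f um", fit$a, fit$b, fit$c)
#> "a = 17.29 keV, b = -4.51 um, c = 3.28 um"
```

The 8 keV interaction 20 μm above the strips shares charge between
strips 25 and 26; the fitted centre b = −4.51 μm estimates the true
x position (−4.8 μm) to a fraction of the 12 μm pitch.  (The fitted
amplitude is a shape parameter only — it does not measure the deposited
energy.)

A complete reduced study (simulate, calibrate, estimate, summarise; a
couple of minutes on one core):

```r
run <- run_full_study(study_config(n_events = 5000, seed = 1))
print(run)
#> study_report: 5000 events (seed 1)
#>     ideal_mae_x_um     ideal_rms_x_um     ideal_mae_y_um     ideal_rms_y_um
#>              0.474              0.742             16.066             27.056
#>    ideal_fwhm_x_um    ideal_fwhm_y_um ideal_mtf5_x_lp_cm ideal_mtf5_y_lp_cm
#>              0.839             26.957          12570.503            366.613
#>     noise_mae_x_um     noise_rms_x_um     noise_mae_y_um     noise_rms_y_um
#>              1.414              1.915             87.607            114.749
#>    noise_fwhm_x_um    noise_fwhm_y_um noise_mtf5_x_lp_cm noise_mtf5_y_lp_cm
#>              1.862             66.084           5196.064            117.387
```

The ideal rows are the noiseless, thresholdless analysis; the noise rows
apply the 0.22 keV / 0.88 keV readout to the same signals.  The headline
reading: with realistic noise the estimator still localises interactions
to ~1.4 μm (mean absolute error) along the wafer and ~90 μm in depth —
micrometre-class resolution from a 12 μm pixel.

A command-line front end with `simulate`, `calibrate`, `estimate`,
`metrics`, `full-study` and `fixtures` subcommands is installed at
`inst/cli/chargecloud.R`.

## Limitations

The electron tracks are a documented condensed-history stand-in, not a
full coupled electron–photon Monte Carlo; externally computed track
tables can be substituted via `read_track_table()`.  Coulomb repulsion
and charge trapping are excluded, readout electronics are not simulated
beyond the noise-plus-threshold model, and the attenuation /
cross-section fixtures are approximate.  See the methods vignette
(`vignettes/charge-cloud-method.Rmd`) for the model, parameter and
numerical-design discussion.
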