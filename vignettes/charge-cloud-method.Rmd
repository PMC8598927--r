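---
title: "Charge-cloud position estimation in deep silicon: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-cloud position estimation in deep silicon: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chargecloud` simulates an edge-on silicon strip detector for
photon-counting CT and estimates x-ray interaction positions from the
shape of the collected charge cloud.  This vignette explains the model,
its assumptions, the tunable parameters, the numerical choices, and the
limits of what the simulation can show.

## Detector model

The sensor is a silicon wafer of thickness $d = 500\,\mu m$ read out by
$51$ strip electrodes of width $10\,\mu m$ at a pitch of
$p = 12\,\mu m$ on the front surface ($y = 0$), with a single backside
electrode at $y = d$ biased at $+200\,$V.  The coordinate origin is the
centre of the middle strip (index 26); strip $k$ is centred at
$(k - 26)\,p$.  Because the pitch is small against the thickness, the
drift field is taken uniform, $E = V/d = 4000$ V/cm, pointing in $-y$:
holes drift to the strips, electrons to the backside.  Field-line
bending near the strips, space charge and depletion non-uniformity are
neglected.  The model is two-dimensional: the electrodes are assumed
long in $z$ and all $z$ structure is ignored.

## Event generation

**Spectrum.** Photon energies are sampled from a Kramers bremsstrahlung
continuum, $N(E) \propto (E_{max} - E)/E$ at 140 kVp, attenuated by
8.48 mm aluminium, 0.8 mm beryllium and 300 mm of soft tissue using the
bundled mass-attenuation tables.  The tables (and the silicon
photoelectric / incoherent / coherent partial cross sections used to
classify interaction types) are approximate fixtures: they are accurate
to the ten-percent level, which is adequate for shaping the energy
distribution but means spectrum-dependent scalars — such as the Compton
fraction of primaries — are only approximately reproducible.  A
measured spectrum can be supplied through `read_spectrum_table()`.

**Interactions.** Interaction types are drawn in proportion to the
partial cross sections at the photon energy.  Only primary Compton
events are position-analysed: photoelectric primaries are counted for
spectrum bookkeeping, Rayleigh events deposit nothing, and secondary
photons are not tracked (in the application they are absorbed by
tungsten sheets between wafers).  Recoil-electron energies follow the
Klein–Nishina electron spectrum, sampled by rejection with the
forward-scatter bound; recoils are therefore confined below the Compton
edge ($\approx 49.8$ keV at 140 keV).  Interaction origins are uniform
over the $12 \times 500\,\mu m^2$ area of the central pixel.

**Electron tracks.** The recoil electron is modelled by a
condensed-history toy generator: the energy is deposited in 20 equal
parts along a random-walk path whose total length is $0.7 \times R(T)$,
with the CSDA-range power law $R(T) = 0.0171\,T^{1.75}\,\mu m$ ($T$ in
keV, fitted to silicon electron ranges in the 1–50 keV regime), a
Gaussian direction change of 0.6 rad per step, and — with probability
0.007 per event — a 1.74 keV Si-K fluorescence deposit displaced by an
exponential range of mean 4 μm.  Every constant is exposed in
`track_config()`.  This generator reproduces the energy-dependent
*scale* of track extent, which is what drives the estimator's x error
and the width-calibration scatter; it does not reproduce detailed track
morphology (delta rays, straggling correlations).  Externally computed
tracks can be injected through `read_track_table()`, which is the
supported route to exact-physics track sets.

**Pairs.** Deposited energy converts to electron–hole pairs by integer
division with the silicon pair energy $w = 3.6$ eV (per-deposit
rounding, no Fano fluctuation, as the plain division is the documented
procedure).  Both carriers of a pair start at the deposit position.

## Charge transport and signal induction

Carriers advance in time steps of $dt = 2$ ns.  Per step, the position
changes by the drift displacement $\pm v_d\,dt$ along $y$ plus
independent Gaussian diffusion kicks of variance $2 D\, dt$ in $x$ and
in $y$.  Drift uses the Canali field-dependent mobility
$v_d = \mu_0 E / (1 + (\mu_0 E / v_{sat})^\beta)^{1/\beta}$ with the
standard 300 K silicon parameter set ($\mu_{0,e} = 1417$,
$\mu_{0,h} = 471$ cm²/Vs; $v_{sat,e} = 1.07\times10^7$,
$v_{sat,h} = 8.37\times10^6$ cm/s; $\beta_e = 1.109$,
$\beta_h = 1.213$); diffusion uses the constant low-field mobility
through the Einstein relation $D = (kT/e)\mu_0$ at $T = 300$ K (room
temperature; the temperature is otherwise unspecified in the problem).
A carrier is collected when it crosses its electrode plane; the last
partial step is interpolated onto the boundary, and the outer side
walls reflect.  Trapping and Coulomb repulsion are excluded; published
estimates put the repulsion effect at a 10–15 % cloud-size increase,
which should be kept in mind when reading absolute widths.

Induced signals follow the Shockley–Ramo theorem.  The weighting
potential $W$ of the reference strip solves the 2D Laplace equation
with that strip at unit potential and every other electrode grounded,
discretised with the 5-point stencil and factorised with a sparse
Cholesky decomposition (default grid 0.25 μm, which puts ≥ 8 nodes
across the 2 μm inter-electrode gap; the discrete residual is checked
after the solve).  Two boundary details are not dictated by the
physical statement of the problem and are therefore configuration
switches:

* **Gap condition.** The oxide gaps between strip electrodes carry a
  zero-normal-derivative (insulating) condition by default — the
  standard choice for floating oxide between implants — with a linear
  Dirichlet ramp between neighbouring electrode values as the
  alternative (`gap_bc = "linear"`).
* **Lateral truncation.** The map is solved on ±5 pitches around the
  reference strip.  A single strip's weighting potential is laterally
  almost flat a few pitches away (pitch ≪ thickness), so the default
  side wall is insulating (zero gradient), which perturbs the solution
  far less than grounding it; `sidewall_bc = "grounded"` brackets the
  truncation error from the other side.  Strip potentials beyond the
  solved extent evaluate to the truncation value 0.

The canonical signal computation is the endpoint form of the Ramo
theorem: strip $k$ accumulates $q\,[W_k(\mathrm{end}) -
W_k(\mathrm{start})]$ per carrier.  For fully collected pairs this
algebra telescopes: the electron's and hole's bulk terms cancel and the
pair leaves exactly one elementary charge on the strip where the hole
lands.  The default fast mode therefore transports holes only and bins
their landing positions (a hole landing in a gap is attributed to the
nearest electrode edge); the explicit both-carrier delta-W mode and the
time-resolved trace mode $i(t) = q\,\mathrm{d}W/\mathrm{d}t$ are kept
as validation routes, and the test suite verifies that trace integrals
match endpoint delta-W to quadrature accuracy and that both signal
methods agree on shared paths.

## Readout model

Electronic noise is Gaussian with $\sigma = 0.22$ keV per strip,
independent between strips, added to the integrated strip energies (the
pulse-processing chain itself is not simulated).  The lowest threshold
is $4\sigma = 0.88$ keV: sub-threshold strips are zeroed before the
fit and an event registers if any strip survives.  The analytic
noise-count interval is `sampling_interval / P(exceedance)`; with
10 ns sampling and the 4σ threshold the two-sided convention gives
≈ 158 μs.  Whether noise counts should be counted one- or two-sided is
not fixed by the model; the two-sided convention is the default here
because it is the one consistent with the rounded 150 μs figure usually
quoted for this configuration, and the one-sided variant is available
(`sides = 1`).

## Position estimation

Per event, $f(x) = a\,e^{-(x-b)^2/2c^2}$ is fitted by
Levenberg–Marquardt (analytic Jacobian, 200 iterations, relative
tolerance $10^{-10}$) to the 51 (strip centre, energy) points,
zero strips included; the initial values are the signal maximum, the
energy-weighted centroid and the RMS width (floored at 1 μm).  In the
noisy analysis $b$ is constrained to ±30 μm — five strips around the
illuminated pixel, the largest footprint a real event produces there,
so anything further out is noise — while the ideal analysis is
unconstrained.  $X_e = b$.

Two degeneracies deserve note.  A single informative strip cannot
constrain $c$; such events report the strip centre and a floor width of
0.1 μm.  With exactly two informative strips an exact interpolant
exists for a whole interval of widths (the zero strips only penalise
the wide end), so the optimiser settles at the narrow end; these events
consequently fall below the calibration's lower bound and take the
boundary-mean arm of the estimator, exactly like the single-strip
cluster.  This is the estimator's honest behaviour, not a failure to
converge.

The width-depth calibration fits $c_{fit}(y) = \alpha y^\beta + \gamma$
(all parameters positive, hence monotone) to the (width, true depth)
scatter of the same simulated dataset, excluding widths below 4 μm
(ideal) or 6.6 μm (noisy) where the degenerate clusters live.  A pure
power law $\alpha y^\beta$ cannot make the below-range branch reachable
(it would force $c_{fit}(0) = 0$), which is why the offset $\gamma$ is
part of the form.  Depth estimation then follows three branches:
widths below $c_{fit}(0)$ map to the mean true depth of such events,
widths above $c_{fit}(d)$ to the corresponding upper mean, and widths
in range invert the power law in closed form, clamped to $[0, d]$.
Calibrating and evaluating on the same dataset mirrors the reference
procedure; a fitted calibration can be saved, reloaded and applied to
an independent dataset for split-sample operation.  Noisy-analysis
metrics are computed over registered events only, since unregistered
events produce no estimate.

## Resolution metrics

PSFs are area-normalised, zero-centred histograms of $X_e - X_0$
(0.2 μm bins) and $Y_e - Y_0$ (5 μm bins).  The estimator's PSFs are a
sharp core riding on heavy non-Gaussian wings — the below-range depth
branch maps many events to one mean depth, producing broad plateaus —
so a Gaussian fitted over the full range answers a different question
than a resolution figure should.  The canonical FWHM is therefore a
Gaussian least-squares fit restricted to the central lobe (the
contiguous bins above half maximum, at least five bins), multi-started
over width scales and reported as $2\sqrt{2\ln 2}\,\sigma$; for a true
Gaussian this recovers $\sigma$ exactly, and for core-plus-wings shapes
it summarises the core, which is also what dominates the
high-frequency tail of the MTF.  The full-range fit and the direct
half-maximum crossing are reported alongside.

MTFs are the magnitude of the DFT of the binned PSF density,
zero-padded eightfold, normalised to unity at zero frequency, with the
frequency axis in lp/cm.  The 5 % resolution figure is the first
downward crossing, linearly interpolated.  Two caveats are inherent to
this definition.  First, plateau-like PSF wings contribute a sinc-type
ripple whose minima can graze the 5 % line, so the first crossing can
jump between well-separated frequencies under small changes in the PSF
— it is a discontinuous functional of the data.  Second, with $10^4$
events the histogram noise floor in the MTF is of order $10^{-2}$,
comparable to the 5 % level in the regions where the noisy-depth MTF
hovers; crossings quoted at this scale carry that uncertainty, and the
test suite's tolerance bands account for it.  Because the PSFs are not
Gaussian, the fitted FWHM and the measured 5 % crossing are related by
the Gaussian closed form only approximately — agreement is typically
within ten to fifteen percent, limited by how sharply the core is
peaked relative to the wings, not by either computation.

## Problem sizes

The reference study conditions use $10^5$ events
(`study_config()`'s default).  The package's own test suite runs one
shared study of $10^4$ events — the smallest scale at which the
histogram-based resolution metrics are stable — plus small targeted
datasets for unit properties, and `scripts/acceptance.R` likewise
recomputes the headline numbers at $10^4$ events.  At that scale mean
absolute errors are stable to a few percent, while FWHM and 5 %
crossing figures inherit the instabilities described above.

## What passing tests do and do not show

The simulation reproduces the *mechanism* — diffusion-encoded depth,
subpixel centroiding, the noise/threshold degradation — and the test
suite pins the physics to independent oracles: the closed-form strip
weighting potential, Klein–Nishina quadrature, random-walk variance,
Ramo path independence, and round-trip parameter recovery.  What the
tests cannot show is fidelity to real detector data: the track
generator and spectrum fixtures are approximations, repulsion and
trapping are excluded, and the readout is idealised.  Statistics that
depend on detailed track structure (notably the ideal-case depth error
and the noisy-depth MTF crossing) are reproducible only at the level of
a few tens of percent, and conclusions drawn from this package should
be limited accordingly.
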