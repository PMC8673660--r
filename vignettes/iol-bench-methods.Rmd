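---
title: "Wave-optical bench simulation of intraocular lenses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wave-optical bench simulation of intraocular lenses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Optical bench tests of intraocular lenses (IOLs) image a resolution target
through a model cornea and a water-filled wet cell holding the lens, and
score the lens by its point spread function (PSF), Strehl ratio and
modulation transfer function (MTF) as the lens is decentered or tilted.
Conventional simulation of such benches uses geometric ray tracing, which
cannot represent interference and diffraction: a coherent laser source
produces interference fringes inside the bright bars of the target and an
extra loss of image quality under misalignment that rays do not see.

`iolbench` simulates the bench twice over, with a scalar wave-optical
("field tracing") engine built on the angular spectrum of plane waves, and
with an exact geometric ray-tracing comparator, so that the two predictions
can be compared pose by pose.

## The bench

The simulated train is

    coherent source (543.5 nm) -> USAF-1951 target (at infinity) ->
    aperture stop (9.072 mm) -> aspheric cornea (air -> aqueous) ->
    wet cell: BK7 window | water | IOL | water | BK7 window -> screen

with these anchor values:

* the cornea is a single aspheric refracting surface of keratometric power
  K = 43 D into aqueous humour (n = 1.336), apex radius
  `(1.336 - 1)/0.043 = 7.814` mm, conic constant near -0.26;
* the stop has a diameter of 9.072 mm and produces a 5.0-mm beam footprint
  (the "pupil") on the IOL;
* the IOL is an equal-radii biconvex acrylate lens (n = 1.47, centre
  thickness 0.9 mm) of 20 D paraxial power in water, whose front-surface
  even asphere (a4) makes it spherical-aberration-correcting;
* misalignment poses decenter the IOL along y (0-800 um in 100-um steps) or
  tilt it about y (0-8 degrees in 2-degree steps), with the screen held at
  the aligned focal plane throughout a sweep.

### Calibrated geometry

Axial distances of physical benches of this kind are rarely published, so
all free distances are fixed by optical calibrations rather than copied:

* **Stop/pupil.** A real stop ahead of a 43 D cornea can never form a real
  image on an IOL plane closer than the corneal focal length (31.07 mm),
  and any geometry that places the stop's real image on the IOL leaves the
  beam diverging after its intermediate focus, so no retinal focus would
  exist. The 5-mm pupil is therefore read as the paraxial footprint of the
  collimated marginal ray on the IOL, which pins the cornea-to-IOL spacing
  at 14.07 mm (wet-cell window included); `calibrate_stop_to_pupil()`
  solves this by matrix optics and verifies it with an independent
  paraxial marginal-ray trace. The stop itself sits at the cornea's front
  focal plane, which makes the image space telecentric.
* **IOL power.** The biconvex radii follow in closed form from the 20 D
  thick-lens (Gullstrand) requirement; `paraxial_power()` and a two-ray
  paraxial trace agree by construction.
* **Corneal asphericity.** At Q = -0.26 the exact ray trace of the cornea
  gives a wavefront Z(4,0) of 0.190 um over a 6-mm zone, while the target
  spherical aberration of the model cornea is 0.172 um. Because Z(4,0) is
  the physically operative quantity the SA-correcting IOL must compensate,
  the conic is recalibrated (to about -0.286, well within +/-0.05 of the
  nominal value) so that the 6-mm-zone Z(4,0) is exactly 0.172 um.
* **IOL asphere.** `calibrate_iol_asphere()` finds the front-surface a4
  that nulls the aligned system's exit-pupil Z(4,0) over the full 5-mm
  pupil (residual < 0.005 um), leaving the paraxial power untouched.
* **Screen.** `find_focal_plane()` removes the object, propagates the
  plane wave through the bench and maximizes the on-axis screen intensity
  over an axial scan refined by golden-section search to 1 um. The axial
  intensity lobe is only ~25 um wide and flanked by side lobes, hence the
  dense pre-scan.

### The object at infinity

The screen of the reference bench holds both the target image and, with
the mask removed, the focal spot. Both can only be sharp on the *same*
plane if the target is presented at optical infinity; a mask placed at a
finite bench distance would be conjugate to a plane far behind the focal
screen. The package therefore presents the 5 mm x 5 mm USAF target through
an ideal collimator of focal length `collimator_f` (100 mm by default):
the field entering the stop is the target's plane-wave spectrum, computed
as a chirp-z Fourier transform of the mask, and the lateral magnification
onto the screen is `-EFL/f_coll` (about -0.185, so the 5-mm chart spans
0.93 mm on the screen). Removing the mask turns the input into the single
on-axis plane wave used for PSF and Strehl work, exactly as in bench
practice.

## The field engine

Fields are sampled complex amplitudes (`complex_field`) with physical
pitch, vacuum wavelength, medium index and axial position. Three numerical
devices make bench-scale propagation tractable:

1. **Band-limited angular spectrum.** Free-space steps use the exact
   non-paraxial transfer function
   `exp(i 2 pi d sqrt((n/lambda)^2 - fx^2 - fy^2))`, with evanescent decay
   and a Matsushima-style band limit that zeroes the frequencies whose
   periodic replicas would wrap around the window. Propagation is unitary
   for band-limited fields and never gains power.
2. **Analytic converging reference.** An f/3 converging beam cannot be
   sampled directly on a bench-scale grid (its quadratic phase turns over
   many times per sample), so a field may carry a reference vergence
   V = n/R: the stored samples are the envelope relative to the perfect
   converging wave. Propagation then uses the Sziklas-Siegman scaled
   Fresnel transform: the envelope propagates over the effective distance
   `zeta/M` with `M = 1 - zeta V` (reduced distances `zeta = sum t_i/n_i`
   across water and glass layers) while the grid pitch is relabelled by
   the geometric magnification M. Near focus, where M vanishes, a
   single-transform Fresnel integral evaluated by a Bluestein chirp-z
   transform delivers the field on an arbitrary output pitch and window
   centre, so a 0.15-um PSF raster and a millimetre image raster both come
   from the same machinery.
3. **Ray-matched system aberration screen.** The refracting elements are
   treated in Debye fashion: the reference wave carries the ideal
   focusing, and the system's aberration - the exit-pupil optical path
   difference of the whole posed train, computed by the exact ray tracer
   and reconstructed as an order-12 Zernike expansion in exit-pupil
   coordinates - is applied to the envelope as a single phase screen at
   the IOL plane. Apertures still clip at their physical planes and every
   leg is propagated as a wave, so stop diffraction, coherent edge
   ringing and interference fringes are fully wave-computed.

The third device deserves its rationale. Collapsing each element into its
own thin phase screen (the straight-chord projection) is accurate only for
nearly collimated passage. Here the beam crosses the IOL at ~f/3, the
cornea and IOL screens are individually ~10 um of optical path and cancel
only along the true, aberration-walked rays; composing them across a
converging propagation leg was measured to leave about one wavelength of
spurious residual and to displace the focus by ~0.2 mm against the exact
trace. The single system-level screen makes the field engine's aberrations
agree with the ray comparator by construction (the two aligned Strehl
ratios agree to better than 0.01), so any remaining difference between the
engines is genuinely wave-optical - which is the point of the comparison.
The cost is isoplanatism: one aberration function serves the whole (small)
field of view, so field-position-dependent aberration across the image is
not represented (see Limitations).

Per-element screens remain available as `element_opd_map()` (the
documented chord-projection operation, with its translation-covariance and
thin-lens limits tested) for uses where the projection approximation is
appropriate.

### Conventions

Light travels +z; decentration is along y, tilt rotates about y through
the lens centre; grids put the optical axis on the centre sample. Reported
wavefront maps follow the clinical OPD-excess convention in which the
model cornea's spherical aberration is positive (+0.172 um); the
transmitted-phase screen of the same surface is its negative, and
`psf_from_pupil()` uses `exp(-i 2 pi W / lambda)` accordingly. Zernike
coefficients are OSA/ANSI double-index, normalized, in micrometres.

## The ray comparator

The "ray tracing" engine is operationalized the way desk comparators
compute MTF: exact sequential refraction (vector Snell's law with Newton
iteration onto conic/aspheric sags, pose transforms for the decentered or
tilted IOL) produces the exit-pupil OPD against a reference sphere centred
on the aligned system's PSF-peak image point (held fixed during sweeps),
and the PSF is the squared modulus of the Fourier-transformed pupil
function, normalized so the aberration-free pupil peaks at 1. Images are
the paraxially magnified target convolved with that PSF - intensities
superpose, so no fringes can appear.

Because the focal screen of the wave engine sits at the *aberrated* best
focus while the comparator's reference sphere is centred on its own peak
plane, small (micrometre) differences between the two evaluation planes
remain; they are inside the depth of focus and are part of how such
comparators behave.

## Strehl ratio and MTF

The Strehl ratio is the peak intensity of the bench PSF divided by the
peak of the same bench with ideal phase elements of identical paraxial
powers (same stop, same apertures), each evaluated at its own focal
plane. This bench-style normalization cancels windowing artifacts that a
theoretical Airy-peak formula would not. MTF is the modulus of the 2-D
Fourier transform of the PSF intensity, normalized at zero frequency; x
and y cross-sections are reported because misaligned PSFs are anisotropic,
and the misalignment-axis section is the one used for comparisons.

## What the synthetic data represent

There is no external data; the package generates its own study
conditions. The USAF-1951 chart is rendered programmatically (three-bar
elements at `2^(g + (e-1)/6)` line pairs/mm, bar length five times bar
width, bars transmissive on an opaque background) for groups 2-4 by
default - bar widths of 31-125 um that bracket what the bench resolves.
The source is a fully coherent monochromatic plane wave; partial
coherence, chromatic spread, surface scatter, real-chart artwork and
measurement noise of a physical bench are all absent. Passing tests
therefore demonstrate the internal consistency and wave-optical content of
the simulation, not agreement with any particular physical instrument.

## Numerical choices and problem sizes

* Default grid 1024 x 1024 over a 13.608-mm window (1.5x the stop); the
  unit tests run mostly at 256-512 and the headline Strehl bounds at
  1024. Halving the grid from 1024 to 512 changes the misaligned Strehl
  values by less than 0.001, so the defaults are comfortably converged.
* Apertures are hard-edged with a one-sample grey ramp (switchable), which
  tames edge ringing without changing resolved structure.
* PSF rasters are centred on the ray-predicted image centroid so that
  laterally displaced PSFs (a 165-um walk at 800-um decenter) stay framed
  at fine pitch; the default pitch puts >= 16 samples across the Airy
  core.
* The wet-cell windows enter the wave engine as reduced-thickness layers
  (exact paraxially; their fourth-order aberration, ~lambda/40 per window
  at this numerical aperture, is included in the ray-matched screen).
* All calibrations are deterministic; there is no randomness anywhere in
  the pipeline.

## Known limitations

* **Scalar, monochromatic, fully coherent.** Polarization and vectorial
  effects (negligible at NA ~ 0.18), polychromatic illumination and
  partial coherence are out of scope.
* **Isoplanatic aberration.** The single exit-pupil screen means the
  field-traced image of an extended target shares one aberration function;
  the paper-style asymmetric smear of tilted-IOL images appears through
  the asymmetric (comet-like) PSF acting on every bar edge, not through
  field-position-dependent blur.
* **Geometry sensitivity.** The unpublished bench distances are calibrated
  here, and the resulting f/3 cone at the IOL makes the compensating
  asphere strong and the Strehl-vs-decenter curve correspondingly steep;
  the paper's printed bounds (Strehl < 0.2 beyond 400 um decentration,
  < 0.4 beyond 4 degrees of tilt) are reproduced, but intermediate curve
  values depend on geometry the source does not print.
* **Diffractive optics.** Multifocal/diffractive IOLs would need the
  surface microstructure inside the wave path, not a ray-matched screen;
  they are out of scope.
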