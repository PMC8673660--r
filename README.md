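# iolbench

Wave-optical ("field tracing") simulation of an optical bench for
intraocular lenses (IOLs), with a geometric ray-tracing comparator.

Bench testing is how IOL image quality is scored before and after market:
a model cornea and a wet cell holding the lens image a USAF-1951
resolution target onto a screen, and the point spread function (PSF),
Strehl ratio and modulation transfer function (MTF) are recorded while
the lens is decentered or tilted. Ray-tracing simulations of such benches
ignore the wave nature of light; with a coherent laser source the real
bench shows interference fringes inside the bright target bars and a
steeper loss of image quality under misalignment than rays predict.
`iolbench` computes both answers for the same bench so they can be
compared pose by pose.

## What it simulates

A collimated 543.5-nm beam carries the target (presented at infinity)
through a 9.072-mm aperture stop, an aspheric model cornea (43 D into
aqueous, conic constant calibrated near −0.26 so the corneal wavefront has
spherical aberration Z(4,0) = 0.172 µm over a 6-mm zone), a water-filled
wet cell with plane BK7 windows, and a 20 D equal-radii biconvex acrylate
IOL (n = 1.47) whose front-surface asphere is calibrated to null the
system spherical aberration — an SA-correcting IOL. The stop produces a
5-mm pupil on the IOL; the screen sits at the aligned focal plane and
stays there while the IOL is decentered (0–800 µm) or tilted (0–8°).

Two engines share this bench:

* **Field tracing** — scalar diffraction by the band-limited angular
  spectrum of plane waves, `U₂ = F⁻¹[F[U₁]·exp(i2πd√((n/λ)² − fx² − fy²))]`,
  with an analytic converging reference (Sziklas–Siegman scaled Fresnel
  propagation) through the focusing legs, chirp-z (Bluestein) sampling of
  focal-plane fields at arbitrary pitch, and the system's exact-ray
  exit-pupil aberration applied as a phase screen at the IOL plane.
  Interference and diffraction are fully represented.
* **Ray tracing** — exact sequential refraction (vector Snell on
  conic/aspheric sags, rigid-body pose of the IOL), exit-pupil optical
  path difference against a reference sphere, and the classic FFT
  pupil-function PSF/MTF. Intensities superpose; no interference.

Metrics: Strehl ratio (peak intensity against the same bench with ideal
phase elements), MTF by Fourier transform of the PSF, OSA/ANSI Zernike
wavefront coefficients (µm), and coherent vs geometric images of the
generated USAF-1951 target.

## Worked example

```r
library(iolbench)

bench <- build_bench()            # assemble + calibrate the default bench
bench <- focus_bench(bench)       # place the screen at the aligned focus
print(bench)
#> <model_eye_bench>
#>   lambda 543.5 nm | stop 9.072 mm at z=0.000 | cornea R 7.8140 mm Q -0.2857 at z=23.256
#>   IOL R +13.3589/-13.3589 mm, a4 -0.002526, t 0.90 mm, n 1.470 at z=37.3224 (pupil 5.000 mm)
#>   pose: decenter 0 um, tilt 0 deg | screen_z 51.1693 mm

cornea_z40(bench$cornea$surface)        # corneal SA over a 6-mm zone (um)
#> [1] 0.172
paraxial_power(bench$iol, 1.336)        # IOL power in water (D)
#> [1] 20

ref <- compute_field_psf(bench, ideal = TRUE)   # diffraction-limited ref.
psf <- compute_field_psf(bench)
strehl(psf, ref)                        # aligned, SA-corrected bench
#> [1] 0.956
ray_psf(bench, output_pitch = psf$pitch)$strehl # ray comparator agrees
#> [1] 0.949

dec <- run_decenter_sweep(bench, samples = 512)
print(dec)
#> <sweep_result> decenter sweep, 9 poses (0, 100, ..., 800)
#>  pose strehl_field strehl_ray
#>     0      0.95587    0.94851
#>   500      0.01068    0.00665
#>   800      0.00169    0.00659   (abridged)
```

The field-traced Strehl is below 0.2 for every decentration of 500 µm or
more and below 0.4 for tilts beyond 4°, with the field engine reporting
lower values than the ray comparator once the lens is misaligned — while
the two agree to better than 0.01 when the lens is centred. Coherent
images of the target show ~23% intensity modulation (fringes) inside the
bright bars where the geometric image is smooth to <2%:

```r
tg <- generate_usaf_target(extent = 2, samples = 512, groups = 3)
im <- simulate_image(bench, tg, engine = "field")   # fringed
ir <- simulate_image(bench, tg, engine = "ray")     # smooth
```

A thin command-line wrapper reproduces the full experiment
(Strehl-vs-pose curves for both engines plus MTF overlay panels for the
aligned, 200-µm-decenter and 8°-tilt cases, as CSV + PNG):

```sh
Rscript scripts/sweep.R --axis both --grid 1024 --out results/sweeps
```

## Package layout

* `R/field_core.R` — sampled complex fields, angular-spectrum and scaled
  Fresnel/chirp-z propagation, apertures, phase masks, TIFF export.
* `R/surfaces.R` — conic/aspheric surfaces, lens elements with pose,
  exact refraction, thin-element OPD maps.
* `R/raytrace.R` — vectorized bundle tracing, exit-pupil OPD, FFT pupil
  PSF, geometric image simulation.
* `R/eye_model.R` — bench assembly, stop/pupil, IOL power and asphere
  calibrations, focal-plane search, field pipeline.
* `R/targets.R` — USAF-1951 generator and plane-wave source.
* `R/metrics.R` — Zernike fits, Strehl, MTF, image simulation.
* `R/sweeps.R` — decentration/tilt sweeps and report rendering.
* `vignettes/iol-bench-methods.Rmd` — models, conventions, numerical
  choices and limitations.
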