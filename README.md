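# srrcmr

Complete spatiotemporal (4D) myocardial strain from multi-view cine
cardiac MR, in R.

Routine cine CMR delivers a handful of thick, widely spaced short-axis
(SA) slices — fine for volumes, but heavily anisotropic for motion: the
left ventricle twists and shortens *through* the imaging planes, and
strain estimated from an SA stack alone distorts exactly the
longitudinal components that matter most.  `srrcmr` implements a
super-resolution route around this: combine LR slice stacks acquired at
several orientations (SA plus orthogonally- or radially-sampled
long-axis views) into one near-isotropic high-resolution 4D volume,
track the motion, and report full 3D strain over the cardiac cycle.
It is aimed at small-animal (mouse-scale) imaging, where rapid cardiac
motion makes dense isotropic acquisition impractical, but nothing in the
pipeline is species-specific.

The chain is:

1. **Tissue classification** — every LR pixel is labelled chamber
   (blood pool), myocardium, or surroundings by three-class Otsu
   thresholds (or supplied endo/epicardial contours, resampled into
   smooth 3D iso-surfaces by triangulation and radial-basis-function
   smoothing).
2. **Tissue-class-specific super-resolution reconstruction** — each
   plane's pixels are scattered into world space via the DICOM-style
   position/orientation metadata (Rodrigues rotations for axis/angle
   geometry); one scattered-data interpolant per tissue class (`linear`
   or smooth `natural` scheme) is evaluated on a structured HR grid
   whose in-plane counts scale with the resampling ratio r1, with a
   class-mean intensity prior of weight lambda:
   `x = argmin sum_j sum_k ||y_j^k - A_j^k x_j^k||^2 +
   lambda sum ((x_j - mu_j)/sigma_j)^2`.
3. **Diffeomorphic demons registration** of consecutive HR frames
   (three pyramid levels, 500/400/300 iterations), minimizing the
   three-term energy `||F - M o c||^2/sigma_i^2 + ||u - c||^2/sigma_x^2
   + ||grad u||^2/sigma_T^2` with update-field exponentiation.
4. **Strain** — the deformation gradient is propagated between
   increments, `F = prod_i (I + du_i/dX)`, Green–Lagrange strain
   `E = (F'F - I)/2` is rotated into radial–circumferential–longitudinal
   components `E_RCZ = Q E Q'`, and the package reports GLS (masked mean
   E_ZZ), AHA 16-segment tables, and a non-physical flag (any strain
   beyond 50 %).

Validation is built in: an analytic contracting-LV phantom (incompressible
wall, prescribed torsion and longitudinal/circumferential shortening,
exact closed-form displacement and strain) is sliced, degraded, pushed
through the pipeline, and scored against its own ground truth — strain
MSE time courses, SSIM/RMS image quality, a slice-protocol ablation, and
cohort coefficient-of-variation analyses.  See
`vignettes/srrcmr-methods.Rmd` for the models, parameter defaults and
their rationale, and known limitations.

## Worked example

```r
library(srrcmr)

ph <- generate_phantom(phantom_spec())   # default mouse-scale phantom
res <- run_pipeline(phantom = ph, n_sa = 8, n_la = 5,
                    la_mode = "orthogonal", frames = 5)
print(res)
```

```
<srr_pipeline_result> srr, 8 SA + 5 LA (orthogonal)
  grid 64x64x80, ES frame 5
  GLS at ES: -11.72 %
  ES strain MSE (percent scale): E_RR = 39.43, E_CC = 7.08, E_ZZ = 15.31
  non-physical voxel fraction at ES: 0.0000
```

Reading this: the phantom's true GLS at end-systole is −13.6 %; the
pipeline recovers −11.7 %.  The ES mean-squared errors are on the
percent-strain scale, so `E_CC = 7.1` means the circumferential strain
field is recovered to about 2.7 % strain RMS; radial strain is the
hardest component (steep transmural thickening gradient) and
longitudinal the one that the multi-view reconstruction exists to fix —
the SA-only baseline (`run_pipeline(..., n_la = 0)`) scores
`E_ZZ = 216` on the same phantom and flags 28 % of wall voxels as
non-physical, versus none for the SR pipeline.

A thin command-line front end over the same functions lives in
`inst/cli/srrcmr.R` (`phantom` and `run` subcommands).

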