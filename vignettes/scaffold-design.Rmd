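---
title: "Designing anisotropic porous bone scaffolds with a self-learning convolutional surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing anisotropic porous bone scaffolds with a self-learning convolutional surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scafmatch)
```

## The problem

A bone scaffold that replaces a defected piece of cancellous bone should
deform like the tissue it replaces: too stiff and it shields the surrounding
bone from load (stress shielding, followed by resorption), too compliant and
it fails under physiological loading. Cancellous bone is anisotropic, so a
single "effective modulus" is not an adequate design target; the quantity to
match is the full in-plane elasticity matrix

$$
\begin{pmatrix} \sigma_x \\ \sigma_y \\ \tau_{xy} \end{pmatrix}
=
\begin{pmatrix} c_{11} & c_{12} & c_{13} \\
                c_{12} & c_{22} & c_{23} \\
                c_{13} & c_{23} & c_{33} \end{pmatrix}
\begin{pmatrix} \varepsilon_x \\ \varepsilon_y \\ \gamma_{xy} \end{pmatrix},
$$

under the plane-stress assumption appropriate for thin 2D sections. The
package implements the full chain: a CT-like image of trabecular bone is
converted into a heterogeneous voxel finite element (FE) model and
homogenized into its elasticity matrix; a discrete wall-lattice scaffold
with 36 thickness variables is searched for the design whose homogenized
matrix best matches that target; and because FE evaluation of every
candidate is far too slow for a $3^{36}$ design space, a small
convolutional network (CNN) trained on FE labels serves as the surrogate
ranking function inside a self-learning archive-based optimizer.

## From image to elasticity matrix

### Preprocessing chain

`synth_slices()` generates trabecular-bone-like grayscale slices (see
below); real slices can be supplied as `grayscale_field` objects instead.
The chain is:

1. **Gaussian smoothing** (`smooth_field()`), sigma 1.2 px, kernel truncated
   at 2 standard deviations. "Support" is interpreted as the truncation
   radius in sigmas, the usual micro-FE image-processing convention.
   Boundary handling is circular, so the grayscale mass is conserved
   exactly and constant fields pass through unchanged.
2. **Maximum-intensity projection** (`max_projection()`) over 15 randomly
   selected slices. Projecting several thin sections onto one plane
   thickens the apparent network so the derived 2D FE model stays
   connected.
3. **vBMD calibration** (`calibrate_vbmd()`): the scanner's linear map from
   grayscale to hydroxyapatite-equivalent density (mg/cm^3). The synthetic
   generator emits fields already on a vBMD-like scale, so the default is
   the identity; negative calibrated densities are clamped to zero.
4. **Ash density** (`vbmd_to_ash()`): the affine relation
   $\rho_{ash} = 0.877\,\rho_{HA} + 0.079$, applied exactly as printed with
   both densities in mg/cm^3. The additive constant is only physically
   meaningful in g/cm^3, which the source leaves ambiguous; since the
   conversion to the modulus law applies a configurable `unit_scale`
   (default mg to g) immediately afterwards, the ambiguity amounts to a
   0.08 mg/cm^3 offset and is immaterial in practice. Both unit readings
   are selectable.
5. **Density-modulus law** (`ash_to_modulus()`):
   $E[\mathrm{MPa}] = 10500\,\rho_{ash}[\mathrm{g/cm^3}]^{2.29}$ by
   default, a widely used vertebral relation; coefficient, exponent and
   unit scale are configurable because the underlying calibration is
   scanner- and site-specific. Void/marrow elements are floored at
   $10^{-6}$ of the reference modulus so the FE system never becomes
   singular while contributing negligible stiffness.

### Voxel homogenization

Each pixel becomes one 4-node bilinear plane-stress element (2x2 Gauss
quadrature); pixel `(i, j)` sits at $x = (j-\tfrac12)h$, $y = (i-\tfrac12)h$
with row 1 at $y = 0$ (no image flip). Three canonical load cases are
applied as kinematic uniform boundary conditions — the affine displacement
$u = \bar\varepsilon x$ imposed on every boundary node, with the engineering
shear split symmetrically ($\gamma_{xy}/2$ off-diagonal):

* $\varepsilon_x = -0.1$: $c_{11} = \bar\sigma_x/\varepsilon_x$,
  $c_{12} = \bar\sigma_y/\varepsilon_x$, $c_{13} = \bar\tau_{xy}/\varepsilon_x$;
* $\varepsilon_y = -0.1$: $c_{22} = \bar\sigma_y/\varepsilon_y$,
  $c_{23} = \bar\tau_{xy}/\varepsilon_y$ (plus a redundant
  $c_{21} = \bar\sigma_x/\varepsilon_y$ kept as a symmetry diagnostic);
* $\gamma_{xy} = +0.1$: $c_{33} = \bar\tau_{xy}/\gamma_{xy}$.

Average stresses are area-weighted means of element-centroid stresses over
the whole domain, floor-stiffness elements included; this convention is
validated against the closed-form plate matrix (a homogeneous plate under
affine boundary data is reproduced exactly by bilinear elements). The
response is linear, so the strain magnitude (default 0.1 as a convention)
does not affect the matrix; periodic boundary conditions are out of scope.
The sparse symmetric system is solved by a supernodal Cholesky
factorization with a deterministic ordering; the symbolic analysis is
computed once per grid shape and reused across designs, which is what makes
labelling thousands of scaffolds practical.

```{r oracle}
plate <- plane_stress_model(matrix(113800, 40, 40), poisson = 0.34,
                            element_size = 0.2)
print(homogenize(plate)) # equals E/(1-nu^2) etc. to solver precision
```

## The scaffold design space

`scaffold_design()` describes a 3x3 grid of 6 mm square cells (18 x 18 mm
overall, sized for a vertebral defect). Each cell owns four walls — left,
top, bottom, right — drawn inward from its own edges and spanning the full
edge, each with an independent thickness from {0.2, 0.4, 0.6} mm; 0.2 mm is
the minimal strut printable by selective laser melting, and the discrete
3-level range keeps the search space $3^{36}$ rather than continuous.
Abutting walls of neighboring cells stack, so each variable's material
contribution stays independent. The wall-per-edge layout is a stated
convention: it realizes "four thicknesses per cell", guarantees a connected
frame for any design, and makes the 2x2-block matrix encoding natural. The
base material is Ti-6Al-4V (E = 113.8 GPa, Poisson ratio 0.34).

`encode_design()`/`decode_design()` map a design to the 6x6 thickness
matrix consumed by the CNN (cell `(r, c)` fills the 2x2 block at rows
`2r-1:2r`, columns `2c-1:2c` in the order left, top / bottom, right) and
back; the map is bijective. `rasterize_design()` produces the voxel FE
model at a configurable pitch (0.1 mm default so walls are 2/4/6 px; 0.2 mm
keeps everything commensurate and is used throughout the scaled protocol
below). `enumerate_periodic()` yields the 81-design conventional space
(every cell identical).

```{r design}
d <- random_design(seed = 7)
encode_design(d)
porosity(d)
```

## The matching objective

Raw differences between elastic constants span orders of magnitude, so each
entry is compared relatively and weighted. With the base-material Poisson
ratio $\nu$:

$$
w = \begin{pmatrix}
\tfrac{1}{1-\nu^2} & \tfrac{\nu}{1-\nu^2} & 0 \\
\tfrac{\nu}{1-\nu^2} & \tfrac{1}{1-\nu^2} & 0 \\
0 & 0 & \tfrac{1}{2(1+\nu)}
\end{pmatrix},
\qquad
a_{ij} = \Big(\frac{c'_{ij} - c_{ij}}{c_{ij}}\Big)^2,
\qquad
f = \sum_{i,j} \frac{w_{ij}}{\hat w}\, a_{ij},
$$

where $\hat w = \sum w_{ij}$. The $(1,3)$/$(2,3)$ entries carry zero weight
(their contribution to in-plane anisotropy of a wall lattice is negligible)
and are short-circuited before any division, so a near-zero target
$c_{13}$ never faults. The sum runs over the full 3x3 index set, so the
symmetric off-diagonal is counted twice — the convention forced by
$\hat w$ including both $w_{12}$ and $w_{21}$; the alternative would only
rescale $f$ by a constant. $f \ge 0$ with equality exactly when all
weighted constants match.

For reporting, objective values are compressed with
$\mathrm{Log}_f = (\ln f + 1)/\ln f_{max}$ (natural logarithm; $f_{max}$ is
the maximum over the dataset being reported, shared by both series of a
paired comparison — the squared correlation is invariant to that choice).

## The convolutional surrogate

`cnn_spec()`/`cnn_build()`/`cnn_fit()` implement a deliberately small CNN:
three 3x3 same-padding convolution stages (widths 32/64/128) each followed
by max pooling and dropout 0.10, then fully connected layers 128 - 64 -
head. A 6x6 input cannot survive three stride-2 poolings, so the pools go
6 to 3 to 2 and the third "pooling" is a global average. Inputs are the 6x6
thickness matrices normalized to {0, 0.5, 1}; labels are the six FE
constants divided by the solid-plate $c_{11}$ reference (the default
"constants" head — one trained model is then reusable for any target, with
$f$ computed downstream; a scalar-$f$ head is selectable). Training
minimizes the mean absolute error with mini-batch Adam (batch 128, initial
rate $10^{-3}$, halved every 80 epochs to damp late-training oscillation of
the validation error, 200 epochs), with an 80/20 train/validation split.
The per-epoch cross-validation curve records both the loss-scale MAE and
the objective-scale MAE $\frac1n\sum_i |f_i^{FE} - f_i^{CNN}|$ used as the
optimizer's trust gate. Everything — split, shuffling, dropout,
initialization — is driven by explicit seeds, and the whole network
(forward, backward, Adam) is implemented in dense R linear algebra; the
gradients are verified against central differences in the test suite.

Prediction power is assessed on fresh designs with `evaluate_power()`:
squared Pearson correlation of the log-transformed FE and CNN objectives,
plus a Bland-Altman analysis (mean difference, +-1.96 SD limits, fraction
within limits) of the untransformed values.

## The self-learning optimizer

`self_learning_optimize()` maintains an archive (default 100) of the best
FE-verified designs. Each iteration: propose candidates (default 10,000,
deduplicated against everything already verified), rank them by the
surrogate, FE-verify the top `archive_size` entrants, and merge elitist-ly
by verified objective, additionally retaining members whose surrogate error
$|f_{CNN} - f_{FE}|$ is below the cross-validation MAE gate. The loop stops
once every archive member's error is below the gate (the surrogate is then
trustworthy on the elite set) or at the iteration backstop. FE verification
is applied to archive entrants only; verifying all candidates would erase
the surrogate's speed advantage.

The candidate stream mixes uniform random designs with 1-3-site mutations
of archive members and always includes the single-site neighbourhood of the
incumbent. Uniform sampling alone cannot refine a design inside a $3^{36}$
lattice (the chance of re-drawing a near-optimal design is nil), so the
mutation component is what lets the archive converge; it is the package's
realization of the "optimization variable" refinement step, with the
surrogate deciding which candidates are worth the FE cost.

Once the archive satisfies the gate, a final **FE-exact polish** refines the
incumbent by single-site steepest descent: all not-yet-verified neighbours
are FE-evaluated and the best strict improvement is taken, repeatedly, up
to a configurable FE budget. This phase exists because the surrogate cannot
steer the endgame: near an achievable optimum the objective differences
between neighbouring designs (order $10^{-3}$) fall below the surrogate's
own prediction error (order $10^{-1}$), so surrogate ranking there is
essentially arbitrary and the last few refinement decisions must be made by
finite elements. In recovery experiments (targets generated from known
designs) the loop plus polish reaches $f_{FE} \sim 10^{-4}$ within a few
hundred FE evaluations. Ranking ties are broken lexicographically on the
encoded matrix so the argmin is unique; optional fine-tuning of the
surrogate on the FE-verified samples accumulated during the search (the
"unsupervised learning" arm) is off by default so the core loop is free of
retraining variance.

`conventional_optimize()` is the exhaustive baseline over the 81 periodic
designs — an exact oracle for the conventional one-cell design space — and
`compare_methods()` runs both optimizers over a set of targets and
summarizes signed relative errors of $c_{11}, c_{12}, c_{22}, c_{33}$
(MIN/Q1/Q2/Q3/MAX/AVG, quartiles by linear interpolation).

## The synthetic bone generator

The cadaver HR-pQCT scans behind the original study are not distributed,
so `synth_slices()` emulates them: anisotropic Gaussian random fields
(spectral synthesis, correlation lengths `correlation_length_x/_y` in mm
controlling trabecular spacing and in-plane anisotropy) are mapped
monotonically to a vBMD-like grayscale with a step-plus-ramp map — pixels
above the $(1 - \phi)$ quantile of the slice-set maximum projection become
bone phase at `vbmd_base + vbmd_scale * excess`, the rest marrow at zero —
reproducing the bimodal bone/marrow histogram of a projected section and
hitting the requested solid fraction $\phi$ by construction.

Defaults are chosen to emulate the regime the original comparison operates
in: the published designed-vs-target agreement (relative errors of a few
percent with absolute Bland-Altman differences of hundreds of MPa) implies
bone targets with elasticity on the GPa scale, i.e. dense, plate-like
15-slice projections of well-mineralized vertebral bone. The defaults —
solid fraction 0.8, bone-phase base 1100 mg/cm^3, ramp 250 mg/cm^3,
correlation lengths 1.0/0.5 mm — give (with the default density law and
bone Poisson ratio 0.30) a target around $c_{11} \approx 4.3$ GPa,
$c_{22} \approx 3.3$ GPa, $c_{33} \approx 1.4$ GPa at the 0.2 mm raster:
anisotropic and of the same order as the wall-lattice design space
($c_{11}$ from 7.8 to 23.9 GPa). What the generator does *not* emulate:
plate/rod microarchitecture, cortical remnants, scanner noise and beam
hardening, and the image-calibration specifics of any real device. Passing
tests on synthetic targets therefore demonstrate the machinery — labelling,
learning, searching, comparing — not clinical accuracy on real scans.

## Scaled protocol and numerical choices

The package's standard experiment (used by the test suite and by
`scripts/acceptance.R`) runs at sizes chosen for a desktop-class single
CPU:

* target and scaffolds rasterized at 0.2 mm (90 x 90 elements; every wall
  width stays an exact pixel multiple),
* 3,000 distinct FE-labelled random designs, split 2,400/600,
* batch 128, 200 epochs, constant learning rate $10^{-3}$ with a
  bias-corrected Polyak average of the weights (decay 0.995) as the scored
  and returned model — at these problem sizes the fit is
  optimization-limited, so decaying the rate freezes progress early, while
  the averaged weights remove the mini-batch/dropout noise that would
  otherwise make single-epoch validation readings a lottery,
* 500 fresh evaluation designs for the prediction-power analysis,
* recovery experiments with 1,000 candidates and a 25-member archive per
  iteration, 25-iteration backstop, FE-polish budget 2,000.

Other numerical choices: division guard $10^{-9}$ (relative) on weighted
target entries; E-floor $10^{-6}$ of the reference modulus; strict
thickness validation (no snapping onto the lattice); circular boundary
handling in both the Gaussian filter and the spectral field synthesis;
supernodal Cholesky with a deterministic fill-reducing ordering. Known
limitations: kinematic uniform boundary conditions overestimate stiffness
relative to periodic homogenization (the stiffest admissible convention);
the wall-per-edge cell layout is one reading of the lattice topology; the
surrogate is trained per material/raster convention and must be retrained
if those change; and the 2D plane-stress setting ignores out-of-plane
architecture entirely.
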