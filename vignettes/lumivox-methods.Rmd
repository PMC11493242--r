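---
title: "Precomputed ambient light fields for cinematic volume rendering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precomputed ambient light fields for cinematic volume rendering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumivox)
```

## The problem

Cinematic rendering of CT and MR volumes aims for film-quality global
illumination, but full path tracing is far too slow for the interactive
camera work clinicians expect. The expensive part is the low-frequency
*ambient* term: the smooth, shadow-free illumination that every visible
voxel receives from all directions. Because it is low-frequency and
camera-independent, it can be computed once per (volume, transfer function)
pair and reused for every frame.

`lumivox` implements this split. A precomputation stage fills a
voxel-aligned **ambient light field** by photon mapping from a spherical
arrangement of large circular light sources — the principle of the
shadowless surgical lamp: when light arrives from enough directions over a
large enough solid angle, the umbra behind any occluder vanishes and the
illumination becomes smooth. A rendering stage then ray-casts the
classified volume and fuses the interpolated ambient light with per-ray
transmitted light.

## Light-source geometry

The volume's circumscribed sphere has centre $R_{center}$ (the centre of
the physical bounding box) and radius $R_{radius}$ (half the box
diagonal). For each of $n$ unit directions $\vec D$ a circular area source
is placed at

$$P_{ray} = R_{center} + R_{radius}\,\vec D,$$

facing the centre ($\vec L = -\vec D$), with all source intensities equal
and summing to one. Directions come from a spherical Fibonacci lattice:
deterministic, nearly uniform for any $n$, and close to antipodally
balanced, which is what the shadowless-lamp argument needs. The default
$n = 72$ gives a mean angular gap of roughly $25°$ between sources.

Each source is a disk perpendicular to its direction. Rays start from
low-discrepancy (golden-angle spiral) points on the disk and all travel
along the source direction, so a source of disk radius $\ge R_{radius}$
covers the entire volume. The default disk radius is $1.05\,R_{radius}$;
smaller radii deliberately under-cover the volume and are only useful for
coverage experiments (below).

## Photon transport

Photons march through the volume at a fixed step (default half the
smallest voxel spacing). A sample whose transfer-function opacity $\alpha$
is zero is inert. At each sample with $\alpha > 0$ the photon energy $L$
splits:

$$L_T = L(1-\alpha), \qquad L_R = L\,F', \qquad L_C = L - L_R - L_T,$$

where $F'=\min(F, \alpha)$ clamps the Schlick reflectance

$$F = F_0 + (1-F_0)(1-\cos\theta)^5$$

($\cos\theta$ between the local intensity-gradient normal and the ray) so
the deposited share $L_C$ can never go negative; the three shares sum to
the input energy exactly, by construction. $L_C$ is added to the ambient
field cell containing the sample (nearest-cell deposition — chosen over
trilinear splatting because it keeps hand-computed and enumerated photon
traces exact). The transmitted share continues along the same direction;
the reflected share spawns a child photon mirrored about the gradient
normal. Where the gradient magnitude falls below a threshold the normal is
undefined, no child is spawned, and the would-be reflected energy stays in
the deposit — this keeps conservation exact in homogeneous regions.

A photon (or child) is dropped when its energy falls below
$\varepsilon$ *of its root photon's initial energy* (default
$10^{-3}$) or when the reflection depth exceeds `max_depth` (default 8).
Expressing $\varepsilon$ relative to the initial energy makes the traced
split tree independent of how total emission is normalised across
photons. For every photon,

$$\text{deposited} + \text{exited} + \text{dropped} = \text{initial energy}$$

to within $10^{-9}$ (in practice, machine precision), and the whole field
sums to at most the unit total emission.

### Default parameters

| parameter | default | meaning |
|---|---|---|
| `n_lights` | 72 | sources on the circumscribed sphere |
| `rays_per_light` | 1024 | photons per source |
| `epsilon` | 1e-3 | termination threshold, fraction of initial energy |
| `max_depth` | 8 | reflection recursion cap |
| `F0` | 0.04 | Schlick normal-incidence reflectance (typical dielectric) |
| `step` | 0.5 | march step, fraction of min voxel spacing (mm/mm) |
| `disk_radius_scale` | 1.05 | disk radius / $R_{radius}$ |

`F0 = 0.04` is the conventional dielectric normal-incidence reflectance;
`rays_per_light`, `epsilon` and `max_depth` bound the split tree at desk
scale. `step` is a resolution knob: the split equations are per *event*,
not per unit length, so halving the step roughly doubles the number of
interaction events along a path. Traces intended to be checked by hand
(one event per voxel) use `step = 1`.

## Rendering

Rays are cast per pixel (orthographic by default, with pixel pitch
defaulting to the voxel pitch so image resolution follows the axial
data). At each sample the trilinearly interpolated intensity $T(p)$ is
classified by the transfer function into $(C, \alpha)$; samples with
$\alpha = 0$ are skipped. Ambient light is read from the field by
inverse-distance weighting over the 8 surrounding cell centres,

$$L_{interp}(P) = \frac{\sum_i L_i / D_i}{\sum_i 1 / D_i},$$

which, unlike plain trilinear weights, never lets an isolated zero cell
pull a sample on a lit surface to zero; a query within $10^{-9}$ mm of a
cell centre returns that cell exactly. (Plain trilinear interpolation is
available as an option.) The 8-corner neighbourhood is this package's
choice of neighbour set.

Transmitted light enters the volume with unit energy and needs no
refraction term ($F_0 = 0$ on the view ray — adding refraction there costs
time and slightly lowers contrast for little visual gain), so per sample

$$L_{CT} = L\,\alpha, \qquad L \leftarrow L(1-\alpha).$$

The two lighting terms fuse linearly with fixed brightness coefficients:

$$C_{fusion} = C\,\alpha\,(L_{interp}\,dim_1 + L_{CT}\,dim_2),$$

and the pixel colour is the plain sum of all $C_{fusion}$ along the ray
(no front-to-back over-compositing), clamped to $[0,1]$ at the end.
Marching stops when the accumulated opacity $\sum\alpha$ reaches 1 — we
read the termination rule "accumulated transparency greater than 1" as
accumulated *opacity*, since transparency accumulating past 1 has no
physical meaning. Rays that meet no material return the background colour.

Because the fusion equation is linear in $(dim_1, dim_2)$ and the
termination rule does not depend on them, a fused render equals
$dim_1 \cdot$ (ambient-only) $+\; dim_2 \cdot$ (transmitted-only)
pixelwise before clamping — the basis of the ablation tooling.

**Choosing $dim_1$:** total emission is normalised to 1, so individual
field cells hold energies of order $1/\text{(lit cells)}$ — around
$10^{-5}$–$10^{-4}$ for a $64^3$ phantom. $dim_1$ must absorb this scale;
values of a few hundred to a few thousand give mid-grey ambient renders at
these problem sizes, and the right value scales with the number of lit
cells. $dim_2$ is naturally $O(1)$ because transmitted energy enters at 1.
The defaults $dim_1 = dim_2 = 0.5$ are neutral placeholders for callers
who set their own scales.

## Synthetic phantoms

All tests and examples run on analytic phantoms, not medical data:
uniform blocks, solid spheres, hollow spherical shells, two-material
blocks, and a single-voxel column whose photon trace is hand-computable
(a unit axial photon through two $\alpha = 0.5$ voxels with $F_0=0$
deposits exactly $0.5$ then $0.25$ and exits with $0.25$). The default
shell is sized like a cranial vault — outer radius $0.45\times$ the grid
width, 4-voxel wall — so that it nearly fills the grid and sub-coverage
source radii leave a visible umbra. Phantoms are deterministic functions
of their spec (kind, geometry, intensity levels, noise sigma, seed);
Gaussian intensity noise is opt-in and off by default so analytic
predicates stay exact.

What phantoms do not emulate: anatomical texture, CT reconstruction
artefacts, beam hardening, partial-volume mixtures of more than two
materials, and anisotropic in-plane/through-plane resolution typical of
clinical series. Passing tests therefore certify the transport and fusion
mathematics and the geometric behaviour of the light arrangement, not
image quality on clinical data.

## Numerical choices

* Geometry is in physical mm; voxel $(i,j,k)$ (0-based) sits at
  `origin + (i,j,k) * spacing` (voxel-centre convention); the bounding box
  for ray clipping includes the outer half-voxel margin.
* The deposit is computed as $L - L_R - L_T$ (not $L(\alpha - F')$) so
  per-event conservation is exact in floating point; a sub-ulp negative
  deposit is clamped to zero.
* Out-of-box samples carry no material: clamped sampling returns 0, and
  the renderer returns the background for rays that miss everything.
* The ambient field's grid is voxel-aligned (one cell per voxel). An
  alternative "physical" sizing of the slice axis,
  $V_{pz} = (V_z - 1) P_s$ with $P_s$ the slice spacing in in-plane pixel
  units, is exposed by `field_dimensions()` for workflows that resample
  the slice axis, but the voxel-aligned grid is the operative default:
  the field must be co-registered cell-for-cell with the volume.
* Degenerate axes (1-voxel-wide oracle phantoms) collapse gracefully in
  trilinear sampling; volume *files* still require all dimensions
  $\ge 2$.
* Determinism: all randomness (lattice rotation, disk spirals, phantom
  noise) derives from explicit integer seeds; photon deposits are pure
  additions, so accumulation order cannot change results.

## Coverage versus source radius

With all sources at equal intensity, growing the source disks shrinks the
unlit ("black, non-rendered") part of the material: a disk of radius
$\ge R_{radius}$ covers the whole volume, while smaller disks leave parts
of the phantom outside every beam. The package measures this as the count
of zero-valued field cells among $\alpha > 0$ voxels.

One subtlety matters when reproducing this experiment with a fixed photon
budget: the umbra argument concerns *geometric coverage*, and holds when
emission per unit source area is fixed. If instead the *photon count* per
source is fixed while the disk grows, ray density on the disk falls with
the square of the radius — and once the beams already cover the phantom
geometrically, sparser sampling leaves more cells unvisited, so the
zero-cell count can rise again at large radii even though geometric
coverage is complete. On the default shell phantom with 12 lights and 256
rays per light, geometric coverage saturates between $0.25$ and
$0.5\,R_{radius}$, and at $1.0\,R_{radius}$ (where roughly three quarters
of rays miss the phantom entirely) sampling sparsity dominates the count.
Scaling `rays_per_light` with the disk area recovers the monotone
behaviour.

## Problem sizes

The examples, tests and the acceptance script run at desk scale, chosen
so the whole suite completes in seconds on one core: $64^3$ phantoms with
72 lights $\times$ 1024 rays for symmetry studies, 12 lights $\times$ 256
rays for coverage studies, $4^3$–$8^3$ volumes for exhaustive split-tree
enumeration, and $64^2$–$128^2$ renders. Clinical-resolution volumes
($512^2 \times$ several hundred slices) work with the same code but need
proportionally more photons for an equally smooth field.

## Known limitations

* The renderer has no direct key-light term and therefore no hard
  shadows: illumination is ambient + transmitted only.
* The pixel colour is a plain clamped sum, not an over-composited
  integral, so background does not show through thin semi-transparent
  material.
* The field is scalar: colour enters only through the transfer function
  at fusion time, so there is no spectral (RGB) photon transport and no
  colour bleeding.
* Nearest-cell deposition makes the field slightly blocky at low photon
  counts; inverse-distance gathering smooths most of it.
* One CPU thread; the design keeps photon traces independent (deposits
  are pure additions) so a parallel accumulation into per-worker fields
  summed deterministically would preserve bit-reproducibility.
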