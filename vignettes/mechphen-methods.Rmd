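---
title: "Methods: traction, mitochondrial morphometrics, scoring and spectra in mechphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: traction, mitochondrial morphometrics, scoring and spectra in mechphen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechphen)
```

mechphen implements the computational layer of a mechano-metabolic study of
3D cell migration: cells embedded in a pliable collagen I matrix pull on the
surrounding fibres, and the mode of migration (rounded-amoeboid vs
elongated-mesenchymal) correlates with Myosin II activity, adhesion,
mitochondrial network shape and cellular energy state. Four largely
independent analysis chains live in one package because they are read out
from the same experiments: direct 3D traction force microscopy, mitochondrial
morphometrics, scalar cell/tissue scores, and 1D NMR spectral preprocessing.
Every chain has a synthetic-data generator with stored ground truth, so all
claims made by the test suite are verifiable without any external data.

## Direct 3D traction force microscopy

### Model and assumptions

The collagen matrix is treated as a purely elastic, continuous, homogeneous
and isotropic medium. With that assumption the chain is

1. **Displacements** between consecutive reflectance frames, by
   block-matching particle image velocimetry (PIV).
2. **Strain** from displacement gradients: either the full small-strain
   tensor \(\varepsilon = \tfrac12(\nabla u + \nabla u^\top)\), or a
   "diagonal" variant that keeps only the axis strains
   \(\varepsilon_{ii} = \partial u_i / \partial x_i\) as principal strains.
3. **Stress** by the linear isotropic constitutive law
   \(\delta = 2\mu\varepsilon\), with the shear modulus from
   \(E = 2\mu(1 + \nu)\).
4. **Principal stresses** \(\lambda_1 \ge \lambda_2 \ge \lambda_3\) and unit
   eigenvectors \(V_i\) of \(\delta\) per node; the eigenvalues are the
   traction solutions and the eigenvectors the normals they act on
   (the Cauchy relation \(\tau = \delta \cdot n\)).
5. **Traction magnitude** \(|T| = \sqrt{T_x^2 + T_y^2 + T_z^2}\).

Defaults are \(E = 28\) Pa and \(\nu = 0.25\), giving \(\mu = 11.2\) Pa.
An alternative stiffness near 19 Pa (typical of AFM indentation measurements
of comparable gels) can be supplied through `elastic_params()`, but is never
mixed in silently.

This is a *direct* method: no inverse problem is solved, so the output is a
stress field consistent with the measured strain rather than a regularised
force reconstruction. Out of scope by design: boundary-element or Fourier
traction cytometry, finite elements, fibrous or viscoelastic constitutive
models.

### Design choices that were genuinely open

* **Strain mode.** The method description that motivated this package fills
  only the diagonal of a symmetric strain tensor, while printing the full
  tensor. Both readings are implemented (`strain_field(mode =)`); they agree
  exactly for shear-free fields, which the tests verify. `"full"` is the
  default because it is the standard small-strain definition and
  frame-invariant (a 90° rotation of the displacement field rotates the
  traction map, tested to 1e-8).
* **Traction composition.** Combining eigenvalues with eigenvectors admits
  two readings: \(T = \sum_i \lambda_i V_i\) in the lab frame
  (`mode = "components"`), or the basis-independent principal magnitude
  \(\sqrt{\sum_i \lambda_i^2}\) (`mode = "principal"`, the default, since it
  is invariant to the eigenbasis and reproduces scalar stress maps). The two
  coincide for axis-aligned eigenvectors.
* **Derivative filter.** Gaussian-derivative filtering at scale 1 node by
  default; `smoothing = 0` switches to plain central differences, which is
  what the finite-difference oracle in the tests checks against.
* **Eigen ties.** Eigenvalues are sorted descending; for degenerate
  eigenvalues any orthonormal basis of the eigenspace is accepted, so tests
  assert the reconstruction \(\sum_i \lambda_i V_i V_i^\top = \delta\)
  rather than specific vectors.

### PIV engine

For each node of a regular mesh, the interrogation window from frame A is
matched against a search region in frame B by normalised cross-correlation,
computed in the frequency domain with local-sum normalisation. The
correlation peak is refined per axis with a three-point Gaussian fit,
giving sub-voxel precision (~0.1 voxel worst-case bias on identity frames;
rigid translations are recovered to ~0.005 voxel in the median). Nodes whose
window is flat or whose correlation peak falls below 0.3 are flagged
untracked with zero displacement, then filled by inverse-distance-weighted
interpolation of the 9 nearest tracked nodes ("nearest 9" is read as the 9
nearest tracked mesh nodes in 3D Euclidean distance, which reduces to the
2D behaviour on a single plane).

Defaults — window 32×32×8 voxels, search radius 10 in-plane and 3 in z, node
spacing 16×16×4 — bracket the few-voxel displacements seen at 2-minute frame
intervals. For the 128×128×16 phantom used throughout the tests the window
is scaled to 24×24×6 with spacing 8×8×2, keeping ≥3 mesh planes in z.

Two engines exist: the default single-pass dense 3D search, and a
plane-wise mode (`plane = "xy" | "xz" | "yz"`) where the out-of-plane search
is clamped to zero and `reconstruct_3d()` fuses the three passes by
averaging each Cartesian component over the two passes that measure it. The
two engines agree on rigid motion, which the tests enforce. Optional
z-resampling of stacks to a finer grid is deliberately not performed by
default: tracking on native z avoids inventing data.

### What the phantom emulates, and what it does not

`generate_fibre_stack()` draws random straight 3D segments with uniform
orientation (any fibrous high-frequency texture suffices for correlation
tracking), blurs with an isotropic Gaussian PSF, and adds Gaussian noise
clipped at zero. `warp_stack()` applies a *backward* (pull) resample through
trilinear interpolation, so the stored contraction field is exactly what a
tracker should report between the two frames. The phantom does **not** model
confocal PSF anisotropy, backscatter physics, fibre buckling or any cell
biology; passing tests therefore demonstrate correctness of the numerical
chain, not robustness to every optical artefact of real reflectance stacks.
Test-scale phantoms are 128×128×16 voxels (full 512×512×90 acquisitions are
supported by configuration, at proportional cost).

## Mitochondrial morphometrics

Two independent readouts distinguish punctate/fragmented from
networked/fused mitochondria:

* **Object circularity.** The image is decomposed into difference-of-
  Gaussian bands at radii 1–32 in powers of two, the non-negative bands are
  combined per pixel (max by default; sum available), a white top-hat with a
  disk of radius 4 flattens uneven background, the result is thresholded
  (Otsu by default), objects under 10 px are deleted, and each object gets
  circularity \(4\pi A / P^2\).
* **Branches per cell.** The image is rescaled to 8-bit, adaptively
  thresholded with a 2.25 µm block, skeletonised (Zhang–Suen), and branches
  are counted as the connected skeleton segments between junctions, where a
  junction is a pixel with crossing number ≥ 3. The full 3×3 junction
  cluster is removed before segment labelling so arms that pass diagonally
  around a junction do not stay connected; spurs shorter than 2 px hanging
  off a junction are pruned as rasterisation artefacts; isolated puncta
  count as one branch each.

Numerical choices worth knowing:

* **Perimeter estimator.** Counting boundary pixels overestimates the
  perimeter of a rasterised disk badly enough to push circularity to ~1.27,
  outside the valid (0, 1.1] range. mechphen instead measures the marching-
  squares contour length of the σ=1 Gaussian-smoothed mask at level 0.5
  (disk → 1.00, 40×1 line → 0.08, monotone in ellipse aspect ratio), falling
  back to the raw staircase contour for thin shapes the blur erases.
* **C-value convention.** The adaptive threshold admits a pixel when its
  8-bit intensity exceeds the local block mean *plus* the C offset
  (default 28). A subtractive convention (`convention = "subtract"`) is
  also provided, but it classifies every pixel of a flat region as
  foreground (any intensity exceeds its own mean minus a positive offset),
  which makes background-dominated images degenerate — hence it is not the
  default.
* **Morphology and blur.** Grayscale erosion/dilation and the separable
  Gaussian blur use edge replication, so a constant image is a fixed point
  of the opening and every DoG band of a constant image is exactly zero.
  Kernels are truncated at 3σ or the image size, whichever is smaller.
* **3D images.** Circularity is defined on 2D images or maximum projections;
  a sphericity variant for volumetric data is a possible extension but no
  reference definition was adopted.
* **Branch semantics.** "Branches" are skeleton-graph edges (segments), not
  branch points + 1; with that convention a straight filament is 1 branch
  and a Y is 3.

The phantom generator draws either well-separated disks (fragmented) or a
single star of thick arms (fused) and stores the truth tables from the
drawing primitives. Over 20 seeded pairs at defaults, object counts rank
fragmented above fused and branch counts rank fused below fragmented with
100% sign consistency.

## Cell and tissue scoring

All scalar formulas are exact and vectorised, with tibble-first wrappers:

* roundness \(= 4A/(\pi\,\mathrm{major\_axis}^2)\), major axis from second
  moments, clipped to [0, 1] (1 = rounded, 0 = spindle-shaped);
* pMLC2 stain fraction = thresholded stain area within the cell mask over
  the mask area (Otsu within the mask by default, since no fixed cutoff is
  canonical);
* adhesion % = 100 × cells after washing / cells before washing;
* 3D invasion index = cells at 50 µm / cells at the bottom;
* ratio images (e.g. PercevalHR ATP:ADP) = per-pixel numerator /
  max(denominator, floor), with sub-floor pixels flagged invalid and
  excluded from summaries (floor default 1 intensity unit);
* histologic score \(Hs = 1(\%\,\text{light}) + 2(\%\,\text{moderate}) +
  3(\%\,\text{strong}) \in [0, 300]\);
* amoeboid score \(As = \text{roundness} \times Hs_{\mathrm{pMLC2}}
  \in [0, 300]\), summarised per ROI as the mean over detections.

The intensity-class cutoffs that produce the light/moderate/strong
percentages are scanner- and marker-specific; the scorer deliberately
consumes percentages rather than raw thresholds, and is agnostic about
whether they are percentages of cells or of stained area.

## NMR spectral preprocessing

The chain is segment-wise FFT peak alignment (PAFFT), then probabilistic
quotient normalisation (PQN), then pareto scaling; the output matrix feeds
any external multivariate tool (PLS-DA itself is out of scope).

* **PAFFT.** Each spectrum is split into fixed segments (default 64 points,
  maximum shift 20 — the method's customary defaults; the reference is the
  mean spectrum by default). Per segment, the integer lag maximising the
  frequency-domain cross-correlation is found and the segment is shifted by
  its negative, padding with the boundary value. Flat segments (no signal in
  either the sample or the reference) carry no alignment information and are
  left untouched. Matrix shape and segment count never change. Only
  segments containing signal can be aligned: a peak sitting on a segment
  border is attenuated by the padding, which is why the generator's test
  peaks are placed mid-segment.
* **PQN.** Quotients against the point-wise median spectrum are taken over a
  support set where the reference exceeds 5× its median positive level
  (keeping baseline noise out of the quotient pool); the dilution factor is
  the median quotient. With a median reference the factors are defined up to
  the cohort scale (a cohort of dilutions 0.5/1/2/4 recovers them divided by
  their median); passing an explicit reference spectrum recovers absolute
  factors. Re-normalising an already-normalised noise-free matrix leaves
  factors at exactly 1; with noise the median reference changes slightly, so
  idempotence is approximate.
* **Pareto.** Columns are mean-centred and divided by \(\sqrt{s}\) with the
  n−1 standard deviation estimator (documented because the identity tests
  depend on it: the scaled column variance equals the original column sd).
  Log-scaling before multivariate analysis is available to the user but not
  chained by default, since log and pareto serve different downstream
  models.
* **Peak areas** are plain trapezoidal integrals over a ppm window.

The spectrum generator forms each sample as
dilution × (segment-shifted Lorentzian mixture) + noise, clipped at zero,
and stores shifts and dilutions. Because noise is added after dilution
scaling, weakly diluted samples carry proportionally more noise — the
dilution-recovery tests therefore bound the *median* factor error at 5%
(50 seeded simulations) with a 10% cap on the worst factor.

## Problem sizes and determinism

Tests and the acceptance checks run at desk scale by choice: 128×128×16
traction phantoms (~360 mesh nodes), 256×256 mitochondrial images, 1024-point
spectra, 20-seed separation loops and 50-seed dilution loops. Every
generator is a pure function of its seed (`withr::with_seed`), so identical
seeds give bit-identical inputs on any platform.
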