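# mechphen

Mechano-metabolic phenotyping of 3D cell migration, in R.

Cells migrating through a pliable collagen I matrix choose between a
rounded-amoeboid mode (high cortical Myosin II, low adhesion, low traction)
and an elongated-mesenchymal mode (high adhesion, strong matrix traction,
high mitochondrial respiration). Studying that axis requires four
computational readouts that this package implements as one tested pipeline:

1. **Direct 3D traction force microscopy** on collagen reflectance stacks:
   block-matching PIV displacement tracking with sub-voxel refinement and
   interpolation of untracked nodes, displacement-gradient strain
   `ε = (∇u + ∇uᵀ)/2`, linear-elastic Cauchy stress `δ = 2με` with
   `E = 2μ(1+ν)` (defaults `E = 28 Pa`, `ν = 0.25`, so `μ = 11.2 Pa`),
   per-node principal stresses `λ₁ ≥ λ₂ ≥ λ₃` with eigenvectors, traction
   magnitude `|T| = √(Tx² + Ty² + Tz²)`, and jet-coloured stress maps.
2. **Mitochondrial morphometrics**: per-object circularity `4πA/P²` via a
   difference-of-Gaussian decomposition (radii 1–32, powers of 2), top-hat
   enhancement (radius 4) and a 10-px size filter; and branches per cell via
   adaptive mean thresholding (block 2.25 µm, C-value 28) followed by
   skeletonisation and skeleton-graph branch counting.
3. **Cell and tissue scores**: roundness `4A/(π·major²)`, stained-area
   fraction per cell, adhesion percentage, 3D invasion index, ratiometric
   biosensor (ATP:ADP) images, histologic score
   `Hs = 1·(%light) + 2·(%moderate) + 3·(%strong)` ∈ [0, 300] and amoeboid
   score `As = roundness × Hs(pMLC2)` ∈ [0, 300].
4. **NMR spectral preprocessing**: segment-wise FFT peak alignment (PAFFT),
   probabilistic quotient normalisation (PQN), pareto scaling, trapezoidal
   peak areas.

Every stage has a synthetic-data generator with stored ground truth
(fibrous stacks warped by a known contraction field, fragmented vs fused
mitochondrial phantoms, staining tables, peak-shifted and dilution-scaled
spectra), so the whole pipeline is testable with no external data.

The API is tidyverse-native: tabular results are tibbles, fitted/derived
objects have `tidy()`, `glance()` and `autoplot()` methods, and the chains
compose with the pipe.

## Worked example: traction from a contracting phantom

```r
library(mechphen)

# a synthetic collagen reflectance stack and its deformation under a
# cell-like contraction (amplitude 2 um, radius 20 um, centred mid-stack)
params  <- fibre_phantom_params(grid_shape = c(128, 128, 16),
                                voxel_size = c(1, 1, 1),
                                n_fibres = 400, noise_sd = 2, seed = 17)
frame_a <- generate_fibre_stack(params)
field   <- make_contraction_field(center = c(64, 64, 8), amplitude = 2,
                                  radius = 20, grid_shape = c(128, 128, 16))
frame_b <- warp_stack(frame_a, field)

grid <- track_displacements(frame_a, frame_b, window = c(24, 24, 6),
                            search = c(5, 5, 2), node_spacing = c(8, 8, 2))
glance(grid)
#> # A tibble: 1 × 5
#>   n_nodes n_untracked frac_untracked median_quality peak_magnitude
#>     <int>       <int>          <dbl>          <dbl>          <dbl>
#> 1     363           0              0          0.947           1.36

traction <- compute_traction(fill_untracked(grid),
                             elastic_params(E = 28, v = 0.25))
glance(traction)
#> # A tibble: 1 × 3
#>   peak_Pa mean_Pa p95_Pa
#>     <dbl>   <dbl>  <dbl>
#> 1    3.00   0.799   2.05

autoplot(render_stress_map(traction))  # jet map, red = matrix under traction
```

The tracker recovers the 2 µm contraction with ~0.3 voxel RMSE; the peak
traction (3 Pa here, a few tenths of the 11.2 Pa shear modulus times the
peak strain) localises at the contraction centre. `peak_magnitude` is the
largest tracked displacement in micrometres; `median_quality` is the
normalised correlation peak across nodes.

Tissue scoring works directly on detection tables:

```r
det <- data.frame(detection_id = 1:2, roundness = c(1, 0),
                  pct_light = c(0, 0), pct_moderate = c(0, 0),
                  pct_strong = c(100, 0))
score_detections(det)
#> # A tibble: 2 × 7
#>   detection_id roundness pct_light pct_moderate pct_strong    Hs    As
#>          <int>     <dbl>     <dbl>        <dbl>      <dbl> <dbl> <dbl>
#> 1            1         1         0            0        100   300   300
#> 2            2         0         0            0          0     0     0
```

A core with 100% strong staining scores the maximum `Hs = 300`; a fully
rounded detection carrying it scores `As = 300`, while a maximally
elongated detection with no pMLC2 signal scores `As = 0`.

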