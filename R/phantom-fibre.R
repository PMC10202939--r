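#' Parameters for the synthetic collagen-fibre reflectance phantom
#'
#' Bundles the knobs of the fibrous 3D texture generator: grid size, physical
#' voxel size, number of fibres, fibre brightness, point-spread blur and
#' additive noise. The defaults give a desk-scale stand-in for a reflectance
#' stack of a collagen I matrix (512 x 512 x 90 full acquisitions are
#' supported by raising `grid_shape`).
#'
#' @param grid_shape Integer length-3, voxels per axis (x, y, z); each >= 16.
#' @param voxel_size Micrometres per voxel per axis.
#' @param n_fibres Number of straight fibre segments to draw (>= 0; 0 gives
#'   an empty scene).
#' @param fibre_intensity Peak fibre intensity, arbitrary units.
#' @param psf_sigma Gaussian point-spread sigma, voxels (>= 0).
#' @param noise_sd Additive Gaussian noise sd, arbitrary units (>= 0); the
#'   result is clipped at zero.
#' @param seed Integer seed; identical seeds give bit-identical phantoms.
#'
#' @return A `fibre_phantom_params` list.
#' @export
fibre_phantom_params <- function(grid_shape = c(128, 128, 16),
                                 voxel_size = c(0.5, 0.5, 1),
                                 n_fibres = 400,
                                 fibre_intensity = 100,
                                 psf_sigma = 1,
                                 noise_sd = 2,
                                 seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  if (any(grid_shape < 16L)) {
    abort("`grid_shape` axes must all be >= 16 voxels.")
  }
  if (n_fibres < 0) abort("`n_fibres` must be >= 0.")
  if (psf_sigma < 0) abort("`psf_sigma` must be >= 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(
    list(grid_shape = grid_shape,
         voxel_size = rep_len(as.numeric(voxel_size), 3L),
         n_fibres = as.integer(n_fibres),
         fibre_intensity = fibre_intensity,
         psf_sigma = psf_sigma, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "fibre_phantom_params")
}

# Rasterise a 3D segment into logical array `mask` by stepping at half-voxel
# increments and marking the nearest voxel.
rasterise_segment <- function(mask, p0, p1) {
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len / 0.5))
  t <- seq(0, 1, length.out = n)
  pts <- round(cbind(p0[1] + t * (p1[1] - p0[1]),
                     p0[2] + t * (p1[2] - p0[2]),
                     p0[3] + t * (p1[3] - p0[3])))
  d <- dim(mask)
  keep <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
    pts[, 2] >= 1 & pts[, 2] <= d[2] &
    pts[, 3] >= 1 & pts[, 3] <= d[3]
  mask[pts[keep, , drop = FALSE]] <- TRUE
  mask
}

#' Generate a synthetic collagen-fibre reflectance stack
#'
#' Draws `n_fibres` random straight line segments with uniformly random
#' orientation through a 3D grid, convolves with an isotropic Gaussian
#' point-spread function and adds Gaussian noise clipped at zero. The
#' rasterised fibre mask (before blur and noise) is attached as attribute
#' `"fibre_mask"` so the scene's true foreground is available as ground
#' truth.
#'
#' @param params A [fibre_phantom_params()] object.
#'
#' @return An [image_stack()] whose `voxels` carry the phantom; attribute
#'   `fibre_mask` is the logical ground-truth fibre raster.
#' @export
#'
#' @examples
#' stack <- generate_fibre_stack(fibre_phantom_params(n_fibres = 50, seed = 7))
#' mean(attr(stack, "fibre_mask"))  # true foreground fraction
generate_fibre_stack <- function(params) {
  if (!inherits(params, "fibre_phantom_params")) {
    abort("`params` must come from fibre_phantom_params().")
  }
  g <- params$grid_shape
  withr::with_seed(params$seed, {
    mask <- array(FALSE, g)
    if (params$n_fibres > 0) {
      # length scale: fibres span a good fraction of the grid
      lmax <- 0.8 * max(g)
      for (i in seq_len(params$n_fibres)) {
        p0 <- runif(3) * g + 0.5
        dir <- rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        len <- runif(1, 0.2, 1) * lmax
        mask <- rasterise_segment(mask, p0, p0 + dir * len)
      }
    }
    vox <- array(0, g)
    vox[mask] <- params$fibre_intensity
    if (params$psf_sigma > 0) vox <- gauss_blur3(vox, params$psf_sigma)
    if (params$noise_sd > 0) {
      vox <- vox + array(rnorm(prod(g), sd = params$noise_sd), g)
    }
    vox[vox < 0] <- 0
  })
  out <- image_stack(vox, voxel_size = params$voxel_size, time_index = 0L)
  attr(out, "fibre_mask") <- mask
  out
}

#' Radial contraction deformation field
#'
#' Models the matrix displacement around a pulling cell: every point is
#' displaced toward `center` with Gaussian-decaying magnitude,
#' \eqn{u(x) = -A\, e^{-\|x-c\|^2/(2 R^2)}\, (x-c)/\max(\|x-c\|, \epsilon)}.
#' The magnitude never exceeds `amplitude` and vanishes at the centre and at
#' infinity.
#'
#' @param center Length-3 centre of contraction, micrometres.
#' @param amplitude Peak displacement magnitude, micrometres (>= 0).
#' @param radius Gaussian decay radius, micrometres (> 0).
#' @param grid_shape Voxels per axis of the target grid.
#' @param voxel_size Micrometres per voxel per axis.
#'
#' @return A [deformation_field()].
#' @export
make_contraction_field <- function(center, amplitude, radius,
                                   grid_shape = c(128, 128, 16),
                                   voxel_size = c(1, 1, 1)) {
  if (amplitude < 0) abort("`amplitude` must be >= 0.")
  if (radius <= 0) abort("`radius` must be > 0.")
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  eps <- 1e-9
  x <- (seq_len(grid_shape[1]) - 1) * voxel_size[1]
  y <- (seq_len(grid_shape[2]) - 1) * voxel_size[2]
  z <- (seq_len(grid_shape[3]) - 1) * voxel_size[3]
  dx <- array(rep(x - center[1], times = grid_shape[2] * grid_shape[3]),
              grid_shape)
  dy <- array(rep(rep(y - center[2], each = grid_shape[1]),
                  times = grid_shape[3]), grid_shape)
  dz <- array(rep(z - center[3], each = grid_shape[1] * grid_shape[2]),
              grid_shape)
  r <- sqrt(dx^2 + dy^2 + dz^2)
  mag <- -amplitude * exp(-r^2 / (2 * radius^2)) / pmax(r, eps)
  u <- array(0, c(grid_shape, 3))
  u[, , , 1] <- mag * dx
  u[, , , 2] <- mag * dy
  u[, , , 3] <- mag * dz
  deformation_field(u, voxel_size = voxel_size)
}

#' Warp an image stack by a deformation field
#'
#' Backward (pull) warp: the output at voxel position \eqn{x} samples the
#' input at \eqn{x - u(x)} by trilinear interpolation, so the stored field is
#' exactly the displacement a tracker should recover from the original frame
#' to the warped frame. A zero field reproduces the input.
#'
#' @param stack An [image_stack()].
#' @param field A [deformation_field()] on the same grid (displacements in
#'   micrometres).
#'
#' @return Warped [image_stack()] with `time_index` advanced by one.
#' @export
warp_stack <- function(stack, field) {
  if (!inherits(stack, "image_stack")) abort("`stack` must be an image_stack.")
  if (!inherits(field, "deformation_field")) {
    abort("`field` must be a deformation_field.")
  }
  d <- dim(stack$voxels)
  if (!all(d == field$grid_shape)) {
    abort("stack and field shapes do not match.")
  }
  vs <- stack$voxel_size
  ix <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  iy <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  iz <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  xi <- ix - field$u[, , , 1] / vs[1]
  yi <- iy - field$u[, , , 2] / vs[2]
  zi <- iz - field$u[, , , 3] / vs[3]
  warped <- array(trilinear_sample(stack$voxels, c(xi), c(yi), c(zi)), d)
  warped[warped < 0] <- 0
  out <- image_stack(warped, voxel_size = vs,
                     time_index = stack$time_index + 1L, dt = stack$dt)
  out
}
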