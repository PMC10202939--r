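#' 3D image stack with physical voxel spacing
#'
#' Container for one time point of a confocal acquisition: a 3D voxel grid
#' (x, y, z) plus the physical voxel size in micrometres per axis, the frame
#' index and the frame interval. Reflectance (collagen fibre) and fluorescence
#' channels are represented as separate stacks.
#'
#' @param voxels Numeric 3D array of non-negative intensities, indexed
#'   `[x, y, z]`.
#' @param voxel_size Numeric length-3 vector, micrometres per voxel along
#'   (x, y, z). All entries must be positive.
#' @param time_index Integer frame number (default 0).
#' @param dt Minutes between consecutive frames (default 2, the interval used
#'   for live 3D collagen imaging).
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size = c(1, 1, 1), time_index = 0L,
                        dt = 2) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3D array (x, y, z).")
  }
  if (!all(is.finite(voxels)) || any(voxels < 0)) {
    abort("voxel intensities must be finite and >= 0.")
  }
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) abort("`voxel_size` must be positive per axis.")
  structure(
    list(voxels = voxels, voxel_size = voxel_size,
         time_index = as.integer(time_index), dt = dt),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d x %d x %d voxels, voxel size (%g, %g, %g) um, t = %d\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$time_index))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Smooth 3D deformation field on a voxel grid
#'
#' Ground-truth displacement field: one 3-vector (micrometres) per voxel.
#' Stored as a 4D array `[x, y, z, component]`.
#'
#' @param u 4D numeric array `[nx, ny, nz, 3]` of displacements in
#'   micrometres.
#' @param voxel_size Micrometres per voxel along (x, y, z).
#'
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(u, voxel_size = c(1, 1, 1)) {
  if (!is.array(u) || length(dim(u)) != 4L || dim(u)[4] != 3L) {
    abort("`u` must be a 4D array [nx, ny, nz, 3].")
  }
  if (!all(is.finite(u))) abort("deformation field must be finite everywhere.")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  structure(list(u = u, grid_shape = dim(u)[1:3], voxel_size = voxel_size),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  g <- x$grid_shape
  mx <- max(sqrt(apply(x$u^2, 1:3, sum)))
  cat(sprintf("<deformation_field> %d x %d x %d nodes, max |u| = %.3g um\n",
              g[1], g[2], g[3], mx))
  invisible(x)
}

# --- shared numeric helpers -------------------------------------------------

# Truncated Gaussian kernel (normalised); radius 3*sigma.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# First-derivative-of-Gaussian kernel: odd, sums to 0, and normalised so a
# unit ramp responds with slope exactly 1.
gauss_deriv_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  xk <- seq(-r, r)
  k <- xk * dnorm(xk, sd = sigma)
  k / sum(xk * k)
}

# Separable convolution of a 3D array along one axis with edge replication.
conv_axis3 <- function(a, k, axis) {
  if (length(k) == 1L) return(a * k)
  d <- dim(a)
  r <- (length(k) - 1L) / 2L
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  idx <- c(rep(1L, r), seq_len(dp[1]), rep(dp[1], r))  # replicate edges
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = dp[1], ncol = ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * mp[seq_len(dp[1]) + (j - 1L), , drop = FALSE]
  }
  aperm(array(out, dp), order(perm))
}

# Isotropic (or per-axis) Gaussian blur of a 3D array.
gauss_blur3 <- function(a, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    if (sigma[ax] > 0) a <- conv_axis3(a, gauss_kernel(sigma[ax]), ax)
  }
  a
}

# Trilinear sampling of 3D array `a` at fractional voxel coordinates
# (1-based). Points outside the grid return `fill`.
trilinear_sample <- function(a, xi, yi, zi, fill = 0) {
  d <- dim(a)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  inside <- x0 >= 1 & x0 <= d[1] - 1 & y0 >= 1 & y0 <= d[2] - 1 &
    z0 >= 1 & z0 <= d[3] - 1
  # exact grid points on the far faces
  on_face <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  x0c <- pmin(pmax(x0, 1L), d[1] - 1L)
  y0c <- pmin(pmax(y0, 1L), d[2] - 1L)
  z0c <- pmin(pmax(z0, 1L), d[3] - 1L)
  fxc <- ifelse(inside | on_face, xi - x0c, 0)
  fyc <- ifelse(inside | on_face, yi - y0c, 0)
  fzc <- ifelse(inside | on_face, zi - z0c, 0)
  lin <- function(ix, iy, iz) a[cbind(ix, iy, iz)]
  v <-
    lin(x0c,     y0c,     z0c)     * (1 - fxc) * (1 - fyc) * (1 - fzc) +
    lin(x0c + 1, y0c,     z0c)     * fxc       * (1 - fyc) * (1 - fzc) +
    lin(x0c,     y0c + 1, z0c)     * (1 - fxc) * fyc       * (1 - fzc) +
    lin(x0c + 1, y0c + 1, z0c)     * fxc       * fyc       * (1 - fzc) +
    lin(x0c,     y0c,     z0c + 1) * (1 - fxc) * (1 - fyc) * fzc +
    lin(x0c + 1, y0c,     z0c + 1) * fxc       * (1 - fyc) * fzc +
    lin(x0c,     y0c + 1, z0c + 1) * (1 - fxc) * fyc       * fzc +
    lin(x0c + 1, y0c + 1, z0c + 1) * fxc       * fyc       * fzc
  v[!(inside | on_face)] <- fill
  v
}
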